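#' Default phantom geometry for a TG-119-like case
#'
#' Returns the geometry parameters used by [make_phantom()]. The four cases
#' emulate the roles of the AAPM TG-119 test suite at desk scale: a
#' head-and-neck-like volume with cord and parotids, a prostate-like target
#' with bladder and rectum, and two C-shape targets wrapping a central cord
#' (an "easy" and a "hard" variant differing in the PTV-to-cord gap). All
#' lengths are mm; the lattice is centred on the isocentre with the gantry
#' rotating in the x-z (axial) plane and leaf rows running along y.
#'
#' @param case_name one of [mlcqa_cases()].
#' @param dim integer grid dimensions `(nx, ny, nz)`.
#' @param spacing voxel spacing in mm (default 2 mm isotropic).
#' @return a list of geometry parameters (class `phantom_spec`).
#' @export
default_phantom_spec <- function(case_name, dim = c(48L, 48L, 48L),
                                 spacing = c(2, 2, 2)) {
  case_name <- match.arg(case_name, mlcqa_cases())
  base <- list(case_name = case_name, dim = as.integer(dim),
               spacing = as.numeric(spacing))
  geom <- switch(case_name,
    c_shape_easy = list(outer_radius = 25, inner_radius = 12, cord_radius = 4,
                        gap_half_angle = 45, half_length = 20),
    c_shape_hard = list(outer_radius = 25, inner_radius = 8, cord_radius = 4,
                        gap_half_angle = 45, half_length = 20),
    prostate = list(ptv_semi = c(18, 14, 12),
                    bladder_centre = c(0, 26, 8), bladder_semi = c(14, 9, 9),
                    rectum_radius = 7, rectum_centre_z = -20,
                    rectum_y = c(-30, 6)),
    head_and_neck = list(ptv_semi = c(30, 22, 20), ptv_centre = c(0, 0, 4),
                         cord_radius = 4, cord_z = -30, cord_margin = 10,
                         parotid_radius = 8, parotid_centre = c(32, 0, -10)))
  structure(c(base, geom), class = "phantom_spec")
}

#' Build a TG-119-like phantom structure set
#'
#' Constructs PTV and OAR masks on a common dose-grid lattice. Masks are
#' deterministic functions of the spec; OARs are carved out of the PTV so the
#' masks are disjoint, and for the C-shape cases the cord must sit fully
#' inside the gap enclosed by the PTV annulus (violations raise an error).
#'
#' @param case_name one of [mlcqa_cases()].
#' @param spec a `phantom_spec`; defaults to [default_phantom_spec()].
#' @return a list with elements `structures` (a [structure_set()]), `dim`,
#'   `spacing`, `origin`, `case_name`, and `spec`; class `phantom`.
#' @export
make_phantom <- function(case_name, spec = default_phantom_spec(case_name)) {
  case_name <- match.arg(case_name, mlcqa_cases())
  stopifnot(inherits(spec, "phantom_spec"), spec$case_name == case_name)
  d <- spec$dim; sp <- spec$spacing
  origin <- -(d - 1) / 2 * sp
  x <- origin[1] + (seq_len(d[1]) - 1) * sp[1]
  y <- origin[2] + (seq_len(d[2]) - 1) * sp[2]
  z <- origin[3] + (seq_len(d[3]) - 1) * sp[3]
  X <- array(rep(x, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(z, each = d[1] * d[2]), dim = d)

  ellipsoid <- function(centre, semi) {
    ((X - centre[1]) / semi[1])^2 + ((Y - centre[2]) / semi[2])^2 +
      ((Z - centre[3]) / semi[3])^2 <= 1
  }

  masks <- switch(case_name,
    c_shape_easy = ,
    c_shape_hard = {
      r <- sqrt(X^2 + Z^2)
      ang <- atan2(Z, X) * 180 / pi  # 90 deg = +z (anterior)
      in_length <- abs(Y) <= spec$half_length
      gap <- abs(ang - 90) <= spec$gap_half_angle
      ptv <- r >= spec$inner_radius & r <= spec$outer_radius &
        in_length & !gap
      cord <- r <= spec$cord_radius & in_length
      if (any(ptv & cord)) stop("C-shape PTV overlaps the cord")
      list(PTV = ptv, cord = cord)
    },
    prostate = {
      ptv <- ellipsoid(c(0, 0, 0), spec$ptv_semi)
      bladder <- ellipsoid(spec$bladder_centre, spec$bladder_semi)
      rectum <- sqrt(X^2 + (Z - spec$rectum_centre_z)^2) <= spec$rectum_radius &
        Y >= spec$rectum_y[1] & Y <= spec$rectum_y[2]
      ptv <- ptv & !bladder & !rectum
      list(PTV = ptv, bladder = bladder, rectum = rectum)
    },
    head_and_neck = {
      ptv <- ellipsoid(spec$ptv_centre, spec$ptv_semi)
      cord <- sqrt(X^2 + (Z - spec$cord_z)^2) <= spec$cord_radius
      cord_avoid <- sqrt(X^2 + (Z - spec$cord_z)^2) <=
        spec$cord_radius + spec$cord_margin
      pc <- spec$parotid_centre
      par_l <- ellipsoid(c(-pc[1], pc[2], pc[3]), rep(spec$parotid_radius, 3))
      par_r <- ellipsoid(pc, rep(spec$parotid_radius, 3))
      ptv <- ptv & !cord_avoid & !par_l & !par_r
      list(PTV = ptv, cord = cord, parotid_L = par_l, parotid_R = par_r)
    })
  for (nm in setdiff(names(masks), "PTV")) {
    if (any(masks[[nm]] & masks$PTV)) stop("PTV overlaps OAR ", nm)
  }
  if (!any(masks$PTV)) stop("empty PTV mask")
  structure(list(structures = structure_set(masks, sp, origin),
                 dim = d, spacing = sp, origin = origin,
                 case_name = case_name, spec = spec),
            class = "phantom")
}
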