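#' Domain objects for segmented-MLC IMRT plans and dose grids
#'
#' A plan is a list of beams; a beam is a list of control points; each control
#' point carries one MLC aperture (two opposing leaf banks) and a fractional
#' meterset (MU) weight. Leaf tip positions are in IEC beam-limiting-device
#' coordinates (mm); bank A holds the negative-side leaves, so for every leaf
#' pair `bank_a <= bank_b` (opposing leaves must not pass each other).
#'
#' @param bank_a,bank_b numeric vectors of leaf tip positions (mm), one entry
#'   per leaf pair; `bank_a[i] <= bank_b[i]` for all `i`.
#' @param mu_weight fractional meterset weight of the segment (dimensionless,
#'   `>= 0`). Error injection never alters MU weights.
#' @return `control_point()` returns an object of class `mlc_control_point`.
#' @export
control_point <- function(bank_a, bank_b, mu_weight) {
  stopifnot(length(bank_a) == length(bank_b), is.numeric(mu_weight),
            length(mu_weight) == 1L, mu_weight >= 0)
  bad <- which(bank_a > bank_b + 1e-9)
  if (length(bad)) {
    stop("leaf collision (bank_a > bank_b) at leaf row(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(bank_a = as.numeric(bank_a), bank_b = as.numeric(bank_b),
                 mu_weight = as.numeric(mu_weight)),
            class = "mlc_control_point")
}

#' @rdname control_point
#' @param gantry_angle gantry angle in degrees (IEC; 0 = beam from anterior).
#' @param control_points list of `mlc_control_point` objects; their MU weights
#'   must sum to a positive value.
#' @param leaf_width leaf width (mm) projected at isocentre.
#' @param leaf_edges optional vector of leaf-row boundary coordinates (mm)
#'   along the leaf-row axis, length `n_leaves + 1`; defaults to rows of
#'   `leaf_width` centred on zero.
#' @return `mlc_beam()` returns an object of class `mlc_beam`.
#' @export
mlc_beam <- function(gantry_angle, control_points, leaf_width = 5,
                     leaf_edges = NULL) {
  stopifnot(is.list(control_points), length(control_points) >= 1L)
  n_leaves <- length(control_points[[1L]]$bank_a)
  for (cp in control_points) {
    stopifnot(inherits(cp, "mlc_control_point"),
              length(cp$bank_a) == n_leaves)
  }
  total_mu <- sum(vapply(control_points, `[[`, numeric(1), "mu_weight"))
  if (total_mu <= 0) stop("beam meterset must be positive")
  if (is.null(leaf_edges)) {
    leaf_edges <- (seq_len(n_leaves + 1L) - 1L - n_leaves / 2) * leaf_width
  }
  stopifnot(length(leaf_edges) == n_leaves + 1L, all(diff(leaf_edges) > 0))
  structure(list(gantry_angle = as.numeric(gantry_angle),
                 control_points = control_points,
                 leaf_width = as.numeric(leaf_width),
                 leaf_edges = as.numeric(leaf_edges)),
            class = "mlc_beam")
}

#' @rdname control_point
#' @param case_name phantom/plan case; one of `"head_and_neck"`,
#'   `"prostate"`, `"c_shape_easy"`, `"c_shape_hard"`.
#' @param beams list of `mlc_beam` objects.
#' @param label error-class tag attached to the plan (default
#'   `"error_free"`).
#' @return `mlc_plan()` returns an object of class `mlc_plan`.
#' @export
mlc_plan <- function(case_name, beams, label = "error_free") {
  case_name <- match.arg(case_name, mlcqa_cases())
  stopifnot(is.list(beams), length(beams) >= 1L)
  for (b in beams) stopifnot(inherits(b, "mlc_beam"))
  structure(list(case_name = case_name, beams = beams,
                 label = as.character(label)),
            class = "mlc_plan")
}

#' @rdname control_point
#' @export
mlcqa_cases <- function() {
  c("head_and_neck", "prostate", "c_shape_easy", "c_shape_hard")
}

#' Validate the MLC collision invariant of a plan
#'
#' Checks that `bank_a <= bank_b` holds for every leaf pair at every control
#' point of every beam.
#'
#' @param plan an `mlc_plan`.
#' @param tol numeric slack (mm) permitted before a pair counts as colliding.
#' @return `TRUE` invisibly; otherwise an error naming beam, control point
#'   and leaf row.
#' @export
validate_plan <- function(plan, tol = 1e-9) {
  stopifnot(inherits(plan, "mlc_plan"))
  for (bi in seq_along(plan$beams)) {
    cps <- plan$beams[[bi]]$control_points
    for (ci in seq_along(cps)) {
      bad <- which(cps[[ci]]$bank_a > cps[[ci]]$bank_b + tol)
      if (length(bad)) {
        stop(sprintf("collision in beam %d, control point %d, leaf row(s) %s",
                     bi, ci, paste(bad, collapse = ", ")))
      }
    }
  }
  invisible(TRUE)
}

#' Total meterset weight of a plan
#'
#' @param plan an `mlc_plan`.
#' @return sum of all control-point MU weights over all beams.
#' @export
plan_total_mu <- function(plan) {
  sum(vapply(plan$beams, function(b) {
    sum(vapply(b$control_points, `[[`, numeric(1), "mu_weight"))
  }, numeric(1)))
}

#' @export
print.mlc_plan <- function(x, ...) {
  ncp <- vapply(x$beams, function(b) length(b$control_points), integer(1))
  cat(sprintf("<mlc_plan> case=%s label=%s beams=%d control points=%s\n",
              x$case_name, x$label, length(x$beams),
              paste(ncp, collapse = "/")))
  invisible(x)
}

#' 3D dose grid
#'
#' A scalar dose array on a regular lattice. Per-beam planar dose maps are
#' represented as single-slice grids (`dim(values)[3] == 1`). Voxel indexing
#' follows the DICOM convention: `origin` is the centre of the first voxel.
#'
#' @param values numeric 3D array of dose in Gy (all values `>= 0`).
#' @param spacing voxel spacing `(dx, dy, dz)` in mm, strictly positive;
#'   default 2 mm isotropic.
#' @param origin coordinates (mm) of the centre of voxel `[1, 1, 1]`.
#' @return an object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L,
            length(spacing) == 3L, all(spacing > 0), length(origin) == 3L)
  if (any(values < -1e-9)) stop("dose values must be non-negative")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels @ %s mm, dose range [%.4g, %.4g] Gy\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

same_lattice <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Structure set on a dose-grid lattice
#'
#' @param masks named list of logical 3D arrays (PTV and organs at risk),
#'   all with the same dimensions.
#' @param spacing,origin lattice geometry shared with the dose grid.
#' @return an object of class `structure_set`.
#' @export
structure_set <- function(masks, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  stopifnot(is.list(masks), length(masks) >= 1L, !is.null(names(masks)))
  d <- dim(masks[[1L]])
  for (m in masks) stopifnot(is.logical(m), identical(dim(m), d))
  structure(list(masks = masks, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "structure_set")
}
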