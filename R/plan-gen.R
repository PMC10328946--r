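# Seed isolation: run code with a fixed RNG state without disturbing the
# caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Beam's-eye-view u-extent of the PTV per leaf row for one gantry angle.
# u runs along leaf travel (x at gantry 0), v along leaf rows (y).
bev_aperture <- function(phantom, gantry_angle, leaf_edges, margin = 4) {
  th <- gantry_angle * pi / 180
  d <- phantom$dim; sp <- phantom$spacing; or <- phantom$origin
  idx <- which(phantom$structures$masks$PTV, arr.ind = TRUE)
  px <- or[1] + (idx[, 1] - 1) * sp[1]
  py <- or[2] + (idx[, 2] - 1) * sp[2]
  pz <- or[3] + (idx[, 3] - 1) * sp[3]
  u <- px * cos(th) + pz * sin(th)
  n_rows <- length(leaf_edges) - 1L
  a <- rep(0, n_rows); b <- rep(0, n_rows)
  row <- findInterval(py, leaf_edges, rightmost.closed = TRUE)
  for (r in seq_len(n_rows)) {
    sel <- row == r
    if (any(sel)) {
      a[r] <- min(u[sel]) - margin
      b[r] <- max(u[sel]) + margin
    }
  }
  list(bank_a = a, bank_b = b, open = b > a)
}

#' Generate a segmented-MLC IMRT plan for a phantom case
#'
#' Builds `n_beams` equally spaced coplanar beams. Each beam's aperture
#' conforms to the beam's-eye-view outline of the PTV (plus a margin), and
#' each of its `n_control_points` segments applies a random inward
#' modulation of the leaf openings with a random MU weight, emulating
#' step-and-shoot fluence modulation. All apertures are collision-free by
#' construction and the plan is deterministic given `seed`.
#'
#' @param phantom a `phantom` from [make_phantom()].
#' @param n_beams number of beams (`>= 1`).
#' @param n_control_points segments per beam.
#' @param seed integer seed controlling segment modulation and MU weights.
#' @param leaf_width leaf width in mm.
#' @param margin aperture margin (mm) beyond the PTV outline.
#' @param modulation maximum inward excursion of each leaf per segment, as a
#'   fraction of the local row opening (in `[0, 0.5)`).
#' @return an `mlc_plan` with label `"error_free"`.
#' @export
make_plan <- function(phantom, n_beams = 9, n_control_points = 5, seed = 1,
                      leaf_width = 5, margin = 4, modulation = 0.35) {
  stopifnot(inherits(phantom, "phantom"), n_beams >= 1,
            n_control_points >= 1, modulation >= 0, modulation < 0.5)
  ext_y <- (phantom$dim[2] - 1) * phantom$spacing[2]
  n_rows <- ceiling(ext_y / leaf_width)
  leaf_edges <- (seq_len(n_rows + 1L) - 1 - n_rows / 2) * leaf_width
  angles <- (seq_len(n_beams) - 1L) * 360 / n_beams
  with_seed(seed, {
    beams <- lapply(angles, function(ang) {
      ap <- bev_aperture(phantom, ang, leaf_edges, margin)
      w <- runif(n_control_points, 0.5, 1.5)
      w <- w / sum(w)
      cps <- lapply(seq_len(n_control_points), function(k) {
        width <- ap$bank_b - ap$bank_a
        shrink_a <- runif(n_rows, 0, modulation) * width
        shrink_b <- runif(n_rows, 0, modulation) * width
        a <- ifelse(ap$open, ap$bank_a + shrink_a, ap$bank_a)
        b <- ifelse(ap$open, ap$bank_b - shrink_b, ap$bank_b)
        control_point(a, b, w[k])
      })
      mlc_beam(ang, cps, leaf_width = leaf_width, leaf_edges = leaf_edges)
    })
    mlc_plan(phantom$case_name, beams)
  })
}

#' Dose-engine configuration
#'
#' Parameters of the synthetic fluence-projection dose engine that stands in
#' for a clinical convolution dose calculation.
#'
#' @param penumbra_sigma Gaussian fluence blur in mm (beam penumbra).
#' @param fraction_gy dose scale: the PTV mean (3D) and the open-field level
#'   of per-beam maps, in Gy. Default 2 Gy, matching a 200 cGy fraction.
#' @param transmission MLC leaf transmission, fraction in `[0, 0.05]`.
#' @param noise_sd Gaussian noise added to per-beam dose maps (Gy).
#'   Default 0: the emulated workflow recalculates dose in a planning
#'   system, which is deterministic; noise is only for emulating
#'   measurement-based maps, and at the 1 cGy discretisation bin it
#'   fragments the homogeneous runs that carry the systematic-error
#'   texture signature.
#' @param attenuation linear attenuation coefficient (per mm) of the
#'   depth-dose falloff.
#' @return a list of class `dose_engine_config`.
#' @export
dose_engine_config <- function(penumbra_sigma = 3, fraction_gy = 2,
                               transmission = 0.02, noise_sd = 0,
                               attenuation = 0.006) {
  stopifnot(penumbra_sigma > 0, fraction_gy > 0,
            transmission >= 0, transmission <= 0.05, noise_sd >= 0,
            attenuation >= 0)
  structure(list(penumbra_sigma = penumbra_sigma, fraction_gy = fraction_gy,
                 transmission = transmission, noise_sd = noise_sd,
                 attenuation = attenuation),
            class = "dose_engine_config")
}

gauss_blur2d <- function(m, sigma_vox) {
  if (sigma_vox <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- dnorm(seq(-r, r), sd = sigma_vox)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(0, r), v, rep(0, r))
    out <- numeric(n)
    for (i in seq_len(2 * r + 1L)) out <- out + k[i] * vp[i:(i + n - 1L)]
    out
  }
  m <- apply(m, 2, pad_conv)
  t(apply(m, 1, pad_conv))
}

# MU-weighted fluence of one beam on the (u, v) map lattice, including leaf
# transmission, with fractional voxel coverage at leaf edges so sub-voxel
# leaf shifts change the map.
beam_fluence <- function(beam, u, v, du, dv, transmission) {
  n_rows <- length(beam$leaf_edges) - 1L
  row_cov <- matrix(0, length(v), n_rows)
  for (r in seq_len(n_rows)) {
    lo <- beam$leaf_edges[r]; hi <- beam$leaf_edges[r + 1L]
    row_cov[, r] <- pmax(0, (pmin(hi, v + dv / 2) - pmax(lo, v - dv / 2)) / dv)
  }
  flu <- matrix(0, length(u), length(v))
  for (cp in beam$control_points) {
    cp_flu <- matrix(0, length(u), length(v))
    for (r in seq_len(n_rows)) {
      cov <- row_cov[, r]
      if (all(cov == 0)) next
      open_u <- pmax(0, pmin(1,
        (pmin(cp$bank_b[r], u + du / 2) - pmax(cp$bank_a[r], u - du / 2)) / du))
      f <- open_u + transmission * (1 - open_u)
      cp_flu <- cp_flu + outer(f, cov)
    }
    flu <- flu + cp$mu_weight * cp_flu
  }
  flu
}

bilinear_sample <- function(m, xi, yi) {
  # m indexed [i, j]; xi, yi fractional 1-based indices; outside -> 0
  nx <- nrow(m); ny <- ncol(m)
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  val <- numeric(length(xi))
  ok <- x0 >= 1 & x0 + 1 <= nx & y0 >= 1 & y0 + 1 <= ny
  if (any(ok)) {
    i00 <- cbind(x0[ok], y0[ok]); i10 <- cbind(x0[ok] + 1, y0[ok])
    i01 <- cbind(x0[ok], y0[ok] + 1); i11 <- cbind(x0[ok] + 1, y0[ok] + 1)
    val[ok] <- m[i00] * (1 - fx[ok]) * (1 - fy[ok]) +
      m[i10] * fx[ok] * (1 - fy[ok]) +
      m[i01] * (1 - fx[ok]) * fy[ok] +
      m[i11] * fx[ok] * fy[ok]
  }
  val
}

#' Compute synthetic dose for a plan on a phantom
#'
#' The engine rasterises each control point's MLC aperture into an
#' MU-weighted fluence map (fractional voxel coverage at leaf tips, leaf
#' transmission under closed leaves), blurs it with a Gaussian penumbra, and
#' (a) scales it to a per-beam planar dose map at the isocentre plane, and
#' (b) forward-projects it through the phantom with exponential depth
#' attenuation and sums over beams to a 3D dose grid. Dose is linear in MU
#' and deterministic given `seed` (which only drives map noise).
#'
#' @param plan an `mlc_plan`.
#' @param phantom the matching `phantom`.
#' @param config a [dose_engine_config()].
#' @param seed integer seed for per-beam map noise; `NULL` disables noise.
#' @param scale 3D normalisation factor in Gy per unit projected fluence.
#'   `NULL` (default) chooses it so the PTV mean equals
#'   `config$fraction_gy`; pass the `scale` returned for the error-free plan
#'   when recomputing dose for an error plan, so both share one absolute
#'   calibration.
#' @param volume if `FALSE`, skip the 3D dose (returns maps only).
#' @return list with `dose` (3D [dose_grid()] or `NULL`), `beam_maps`
#'   (list of single-slice `dose_grid`s, one per beam), and `scale`.
#' @export
compute_dose <- function(plan, phantom, config = dose_engine_config(),
                         seed = NULL, scale = NULL, volume = TRUE) {
  stopifnot(inherits(plan, "mlc_plan"), inherits(phantom, "phantom"),
            inherits(config, "dose_engine_config"))
  if (plan$case_name != phantom$case_name) {
    stop("plan and phantom case mismatch")
  }
  sp <- phantom$spacing
  if (abs(sp[1] - sp[3]) > 1e-9) stop("axial spacing must be isotropic")
  du <- sp[1]; dv <- sp[2]
  ext_xz <- (phantom$dim[c(1, 3)] - 1) * sp[c(1, 3)]
  half_u <- sqrt(sum(ext_xz^2)) / 2 + 4 * config$penumbra_sigma
  nu <- 2L * ceiling(half_u / du) + 1L
  u <- (seq_len(nu) - (nu + 1) / 2) * du
  v <- phantom$origin[2] + (seq_len(phantom$dim[2]) - 1) * dv
  sigma_vox <- config$penumbra_sigma / du

  if (!is.null(seed)) set.seed(seed)
  fluences <- list(); beam_maps <- list()
  for (bi in seq_along(plan$beams)) {
    flu <- beam_fluence(plan$beams[[bi]], u, v, du, dv, config$transmission)
    flu <- gauss_blur2d(flu, sigma_vox)
    fluences[[bi]] <- flu
    m <- config$fraction_gy * flu
    if (!is.null(seed) && config$noise_sd > 0) {
      m <- m + matrix(rnorm(length(m), 0, config$noise_sd), nrow(m))
    }
    m <- pmax(m, 0)
    beam_maps[[bi]] <- dose_grid(array(m, dim = c(nu, length(v), 1L)),
                                 spacing = c(du, dv, sp[3]),
                                 origin = c(u[1], v[1], 0))
  }

  dose <- NULL
  if (volume) {
    d <- phantom$dim; or <- phantom$origin
    x <- or[1] + (seq_len(d[1]) - 1) * sp[1]
    y <- or[2] + (seq_len(d[2]) - 1) * sp[2]
    z <- or[3] + (seq_len(d[3]) - 1) * sp[3]
    X <- array(rep(x, times = d[2] * d[3]), dim = d)
    Y <- array(rep(rep(y, each = d[1]), times = d[3]), dim = d)
    Z <- array(rep(z, each = d[1] * d[2]), dim = d)
    raw <- array(0, dim = d)
    for (bi in seq_along(plan$beams)) {
      th <- plan$beams[[bi]]$gantry_angle * pi / 180
      uu <- X * cos(th) + Z * sin(th)
      ww <- X * sin(th) + Z * cos(th)
      depth <- max(ww) - ww
      ui <- (uu - u[1]) / du + 1
      vi <- (Y - v[1]) / dv + 1
      f <- bilinear_sample(fluences[[bi]], as.numeric(ui), as.numeric(vi))
      raw <- raw + array(f, dim = d) * exp(-config$attenuation * depth)
    }
    if (is.null(scale)) {
      ptv_mean <- mean(raw[phantom$structures$masks$PTV])
      if (ptv_mean <= 0) stop("zero PTV dose; cannot normalise")
      scale <- config$fraction_gy / ptv_mean
    }
    dose <- dose_grid(raw * scale, spacing = sp, origin = or)
  }
  list(dose = dose, beam_maps = beam_maps, scale = scale)
}
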