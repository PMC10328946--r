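#' Gamma-analysis acceptance criteria
#'
#' @param dose_tolerance dose-difference tolerance as a percentage of the
#'   local reference dose (local normalisation, the default) or of the
#'   global reference maximum.
#' @param dta distance-to-agreement tolerance in mm.
#' @param low_dose_threshold voxels with reference dose below this
#'   percentage of the reference maximum are excluded (default 10).
#' @param normalization `"local"` (default) or `"global"`.
#' @return an object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_tolerance = 3, dta = 2,
                           low_dose_threshold = 10,
                           normalization = c("local", "global")) {
  normalization <- match.arg(normalization)
  stopifnot(dose_tolerance > 0, dta > 0,
            low_dose_threshold >= 0, low_dose_threshold < 100)
  structure(list(dose_tolerance = dose_tolerance, dta = dta,
                 low_dose_threshold = low_dose_threshold,
                 normalization = normalization),
            class = "gamma_criteria")
}

#' Gamma index between two dose grids
#'
#' Computes the per-voxel gamma index of `evaluated` against `reference`:
#' the minimum over displaced evaluated positions of
#' `sqrt((distance/DTA)^2 + (dose difference/tolerance)^2)`, searched
#' exhaustively within `radius_mult * DTA` on a sub-voxel lattice of step
#' `step_frac * DTA` with trilinear interpolation of the evaluated grid.
#' With local normalisation the dose tolerance is a percentage of the local
#' reference dose. Voxels below the low-dose threshold are excluded (NA in
#' the map). Works on 3D grids and on single-slice (per-beam) maps alike.
#'
#' @param reference,evaluated aligned [dose_grid()]s (same lattice).
#' @param criteria a [gamma_criteria()].
#' @param step_frac search step as a fraction of DTA (default 0.1).
#' @param radius_mult search radius as a multiple of DTA (default 3).
#' @return list of class `gamma_result`: `gamma_map` (array, NA below
#'   threshold), `pass_rate` (fraction of evaluated voxels with gamma <= 1),
#'   `n_evaluated`, and `criteria`.
#' @export
gamma_index <- function(reference, evaluated, criteria = gamma_criteria(),
                        step_frac = 0.1, radius_mult = 3) {
  stopifnot(inherits(reference, "dose_grid"), inherits(evaluated, "dose_grid"),
            inherits(criteria, "gamma_criteria"))
  if (!same_lattice(reference, evaluated)) {
    stop("reference and evaluated grids are not on the same lattice")
  }
  if (max(reference$values) <= 0) stop("reference maximum must be positive")
  g <- gamma_map_cpp(as.numeric(reference$values),
                     as.numeric(evaluated$values),
                     dim(reference$values), reference$spacing,
                     criteria$dose_tolerance / 100, criteria$dta,
                     criteria$low_dose_threshold / 100,
                     criteria$normalization == "local",
                     max(reference$values), step_frac, radius_mult)
  n_eval <- sum(!is.na(g))
  if (n_eval == 0) stop("empty evaluation region: all voxels below threshold")
  structure(list(gamma_map = g,
                 pass_rate = sum(g <= 1, na.rm = TRUE) / n_eval,
                 n_evaluated = n_eval, criteria = criteria),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm (%s): pass rate %.4f over %d voxels\n",
              x$criteria$dose_tolerance, x$criteria$dta,
              x$criteria$normalization, x$pass_rate, x$n_evaluated))
  invisible(x)
}
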