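#' Cumulative dose-volume histogram
#'
#' Voxel-counting cumulative DVH of the dose inside a structure mask:
#' `V(d)` = percentage of the structure's voxels receiving at least dose
#' `d`. Starts at 100% at zero dose, is non-increasing, and reaches 0 above
#' the maximum dose.
#'
#' @param dose a [dose_grid()].
#' @param mask logical array on the same lattice (nonempty).
#' @param bin_width dose bin width in Gy (default 0.01).
#' @param structure_name optional name carried on the curve.
#' @return list of class `dvh_curve`: `dose` (bin edges, Gy), `volume`
#'   (cumulative %, same length), `differential` (% per bin), `structure`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.01,
                        structure_name = "structure") {
  stopifnot(inherits(dose, "dose_grid"), is.logical(mask),
            identical(dim(mask), dim(dose$values)))
  if (!any(mask)) stop("empty mask")
  d <- dose$values[mask]
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  counts <- tabulate(findInterval(d, edges, rightmost.closed = FALSE),
                     nbins = length(edges))
  diff_pct <- counts / length(d) * 100
  cum <- rev(cumsum(rev(diff_pct)))
  structure(list(dose = edges, volume = cum, differential = diff_pct,
                 structure = structure_name),
            class = "dvh_curve")
}

#' Scalar DVH metrics
#'
#' Mean dose, D95 and D2: the minimum dose received by the hottest 95% and
#' 2% of the structure volume (voxel-counting quantiles).
#'
#' @param dose a [dose_grid()].
#' @param mask logical array on the dose lattice.
#' @return named numeric vector `mean`, `D95`, `D2` (Gy).
#' @export
dvh_metrics <- function(dose, mask) {
  stopifnot(any(mask))
  d <- dose$values[mask]
  c(mean = mean(d),
    D95 = unname(quantile(d, probs = 0.05, type = 1)),
    D2 = unname(quantile(d, probs = 0.98, type = 1)))
}

#' Relative DVH differences between error and error-free doses
#'
#' For each structure and metric, the relative percentage difference
#' `100 * (error - error_free) / error_free`, flagged against the clinical
#' criteria: any PTV underdose (negative difference) or an OAR difference
#' of 3% or more (inclusive).
#'
#' @param free,err [dose_grid()]s on the same lattice.
#' @param structures a [structure_set()]; the mask named `"PTV"` is treated
#'   as target, all others as OARs.
#' @param oar_criterion OAR flag threshold in percent (default 3).
#' @return data frame with columns structure, metric, error_free, error,
#'   relative_diff_pct, exceeds_criterion.
#' @export
dvh_relative_difference <- function(free, err, structures,
                                    oar_criterion = 3) {
  stopifnot(inherits(structures, "structure_set"))
  if (!same_lattice(free, err)) stop("lattice mismatch")
  rows <- list()
  for (nm in names(structures$masks)) {
    mf <- dvh_metrics(free, structures$masks[[nm]])
    me <- dvh_metrics(err, structures$masks[[nm]])
    for (k in names(mf)) {
      if (mf[[k]] == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          structure = nm, metric = k, error_free = 0, error = me[[k]],
          relative_diff_pct = NA_real_, exceeds_criterion = NA)
        next
      }
      rel <- 100 * (me[[k]] - mf[[k]]) / mf[[k]]
      flag <- if (nm == "PTV") rel < 0 else rel >= oar_criterion
      rows[[length(rows) + 1L]] <- data.frame(
        structure = nm, metric = k, error_free = mf[[k]], error = me[[k]],
        relative_diff_pct = rel, exceeds_criterion = flag)
    }
  }
  do.call(rbind, rows)
}
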