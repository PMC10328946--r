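#' MLC position-error specifications
#'
#' `systematic_error_spec()` describes a one-bank systematic shift: every
#' selected leaf on the chosen bank is translated by `shift` mm to the right
#' (+x in beam-limiting-device coordinates) at every control point.
#' `random_error_spec()` describes independent Gaussian perturbations of all
#' leaves on both banks with per-bank mean `mu` and standard deviation
#' `sigma`.
#'
#' @param shift systematic shift in mm (`> 0`; the study grid is 0.5, 1.0,
#'   1.5, 2.0 mm).
#' @param bank which bank is shifted, `"B"` (default) or `"A"`. Bank B is
#'   the positive-side bank, so a rightward (+x) shift of bank B opens the
#'   field edge toward the surrounding normal tissue; a rightward shift of
#'   bank A advances its leaves into the field.
#' @param restrict_to_ptv_adjacent if `TRUE` (default) only leaf pairs whose
#'   row is open at that control point (the pairs shaping the PTV field
#'   edge) are shifted.
#' @return a spec object.
#' @export
systematic_error_spec <- function(shift, bank = c("B", "A"),
                                  restrict_to_ptv_adjacent = TRUE) {
  bank <- match.arg(bank)
  stopifnot(is.numeric(shift), length(shift) == 1L, shift >= 0)
  structure(list(shift = shift, bank = bank,
                 restrict_to_ptv_adjacent = restrict_to_ptv_adjacent),
            class = "systematic_error_spec")
}

#' @rdname systematic_error_spec
#' @param mu per-bank mean displacement in mm (study grid: 0, 1, 2 mm).
#' @param sigma standard deviation in mm (study value: 1 mm).
#' @param seed integer seed; draws are deterministic given the seed.
#' @param direction `"widen"` (default): bank A draws mean `-mu`, bank B
#'   mean `+mu`, so the mean displacement opens the field; `"same"`: both
#'   banks draw mean `+mu` (a mean translation).
#' @export
random_error_spec <- function(mu, sigma = 1, seed = 1,
                              direction = c("widen", "same")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(mu), length(mu) == 1L, sigma > 0)
  structure(list(mu = mu, sigma = sigma, seed = as.integer(seed),
                 direction = direction),
            class = "random_error_spec")
}

#' Inject a systematic one-bank MLC shift into a plan
#'
#' At every control point, each selected leaf on the chosen bank is
#' translated by `+shift` mm. If the shifted leaf would pass the opposing
#' leaf it is capped at the opposing position (the pair closes). MU weights
#' are never altered.
#'
#' @param plan a collision-free `mlc_plan`.
#' @param spec a [systematic_error_spec()].
#' @return the perturbed `mlc_plan`, labelled
#'   `"systematic_<shift>mm"`.
#' @export
inject_systematic <- function(plan, spec) {
  stopifnot(inherits(plan, "mlc_plan"), inherits(spec, "systematic_error_spec"))
  validate_plan(plan)
  out <- plan
  for (bi in seq_along(out$beams)) {
    cps <- out$beams[[bi]]$control_points
    for (ci in seq_along(cps)) {
      cp <- cps[[ci]]
      sel <- if (spec$restrict_to_ptv_adjacent) {
        cp$bank_b - cp$bank_a > 1e-9
      } else rep(TRUE, length(cp$bank_a))
      if (spec$bank == "A") {
        cp$bank_a[sel] <- pmin(cp$bank_a[sel] + spec$shift, cp$bank_b[sel])
      } else {
        cp$bank_b[sel] <- cp$bank_b[sel] + spec$shift
      }
      cps[[ci]] <- cp
    }
    out$beams[[bi]]$control_points <- cps
  }
  out$label <- sprintf("systematic_%gmm", spec$shift)
  validate_plan(out)
  out
}

#' Inject random Gaussian MLC position errors into a plan
#'
#' Every leaf on both banks at every control point receives an independent
#' Gaussian draw (per-bank signed mean, see [random_error_spec()]). Draws
#' that would make a pair collide are re-drawn from the same distribution
#' until collision-free, as re-randomising avoids a collision without
#' distorting the error distribution elsewhere. MU weights are never
#' altered; output is deterministic given the spec seed.
#'
#' @param plan a collision-free `mlc_plan`.
#' @param spec a [random_error_spec()].
#' @param max_redraws safety bound on consecutive rejected draws for one
#'   pair before erroring (pathological geometry).
#' @return the perturbed `mlc_plan`, labelled `"random_<mu>mm"`.
#' @export
inject_random <- function(plan, spec, max_redraws = 1e6) {
  stopifnot(inherits(plan, "mlc_plan"), inherits(spec, "random_error_spec"))
  validate_plan(plan)
  mu_a <- if (spec$direction == "widen") -spec$mu else spec$mu
  mu_b <- spec$mu
  out <- plan
  with_seed(spec$seed, {
    for (bi in seq_along(out$beams)) {
      cps <- out$beams[[bi]]$control_points
      for (ci in seq_along(cps)) {
        cp <- cps[[ci]]
        n <- length(cp$bank_a)
        da <- rnorm(n, mu_a, spec$sigma)
        db <- rnorm(n, mu_b, spec$sigma)
        bad <- which(cp$bank_a + da > cp$bank_b + db)
        for (i in bad) {
          tries <- 0L
          repeat {
            da[i] <- rnorm(1, mu_a, spec$sigma)
            db[i] <- rnorm(1, mu_b, spec$sigma)
            if (cp$bank_a[i] + da[i] <= cp$bank_b[i] + db[i]) break
            tries <- tries + 1L
            if (tries > max_redraws) stop("could not avoid collision at leaf ", i)
          }
        }
        cp$bank_a <- cp$bank_a + da
        cp$bank_b <- cp$bank_b + db
        cps[[ci]] <- cp
      }
      out$beams[[bi]]$control_points <- cps
    }
  })
  out$label <- sprintf("random_%gmm", spec$mu)
  validate_plan(out)
  out
}

#' Build a labelled suite of error-free and error plans
#'
#' For each input plan this produces one error-free copy, one plan per
#' systematic shift, and one plan per random mean, each labelled; the
#' downstream class label maps error-free to 0 and any error to 1.
#'
#' @param plans nonempty list of `mlc_plan`s.
#' @param systematic_shifts numeric vector of one-bank shifts (mm).
#' @param random_mus numeric vector of Gaussian means (mm).
#' @param seed integer; random-error seeds are derived deterministically
#'   from it.
#' @param sigma Gaussian sigma (mm) shared by all random specs.
#' @return a list of `mlc_plan`s with `$label` set.
#' @export
build_error_suite <- function(plans, systematic_shifts = c(0.5, 1, 1.5, 2),
                              random_mus = c(0, 1, 2), seed = 1, sigma = 1) {
  stopifnot(is.list(plans), length(plans) >= 1L)
  out <- list()
  k <- 0L
  for (pi in seq_along(plans)) {
    p <- plans[[pi]]
    p$label <- "error_free"
    out[[length(out) + 1L]] <- p
    for (s in systematic_shifts) {
      out[[length(out) + 1L]] <- inject_systematic(p, systematic_error_spec(s))
    }
    for (m in random_mus) {
      k <- k + 1L
      out[[length(out) + 1L]] <-
        inject_random(p, random_error_spec(m, sigma, seed = seed + 1000L * k))
    }
  }
  out
}
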