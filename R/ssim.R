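#' SSIM configuration
#'
#' Regularisation constants are recomputed from `K1`, `K2` and the dynamic
#' range `L` as `C1 = (K1*L)^2`, `C2 = (K2*L)^2`, `C3 = C2/2`; they are
#' never stored. The default `L = 200` corresponds to the fraction dose of
#' 200 cGy when maps are expressed in cGy.
#'
#' @param K1,K2 regularisation factors (defaults 0.01 and 0.03).
#' @param L dynamic range of the maps (default 200).
#' @param window `"gaussian"` (11x11, sigma 1.5 — the canonical SSIM
#'   window) or `"global"` (one window spanning the whole map, which makes
#'   the closed-form constant-image cases exact).
#' @param alpha,beta,gamma exponents of the luminance, contrast and
#'   structure terms (defaults 1).
#' @return an object of class `ssim_config`.
#' @export
ssim_config <- function(K1 = 0.01, K2 = 0.03, L = 200,
                        window = c("gaussian", "global"),
                        alpha = 1, beta = 1, gamma = 1) {
  window <- match.arg(window)
  stopifnot(K1 > 0, K2 > 0, L > 0)
  structure(list(K1 = K1, K2 = K2, L = L, window = window,
                 alpha = alpha, beta = beta, gamma = gamma),
            class = "ssim_config")
}

gauss_kernel1d <- function(size = 11L, sigma = 1.5) {
  k <- dnorm(seq_len(size) - (size + 1) / 2, sd = sigma)
  k / sum(k)
}

# "Valid" separable 2D convolution (no padding) of each slice.
conv2_valid <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  n1 <- nrow(m) - 2L * r; n2 <- ncol(m) - 2L * r
  if (n1 < 1 || n2 < 1) stop("map smaller than the SSIM window")
  out <- matrix(0, n1, ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * m[i:(i + n1 - 1L), , drop = FALSE]
  out2 <- matrix(0, n1, n2)
  for (j in seq_along(k)) out2 <- out2 + k[j] * out[, j:(j + n2 - 1L), drop = FALSE]
  out2
}

#' Structural similarity between two dose maps
#'
#' Computes the SSIM index and its luminance, contrast and structure
#' subcomponents from windowed means, standard deviations and
#' cross-variance:
#' `l = (2*mux*muy + C1) / (mux^2 + muy^2 + C1)`,
#' `c = (2*sx*sy + C2) / (sx^2 + sy^2 + C2)`,
#' `s = (sxy + C3) / (sx*sy + C3)`,
#' and `SSIM = l^alpha * c^beta * s^gamma`, averaged over windows. With the
#' default exponents and `C3 = C2/2` the per-window SSIM equals `l*c*s`
#' exactly. 3D grids are windowed slice by slice.
#'
#' @param x,y [dose_grid()]s (or plain matrices/arrays) on the same lattice;
#'   shapes must match exactly (no silent resampling).
#' @param config an [ssim_config()].
#' @return list of class `ssim_result` with `ssim`, `luminance`,
#'   `contrast`, `structure` (means over windows).
#' @export
ssim_index <- function(x, y, config = ssim_config()) {
  xv <- if (inherits(x, "dose_grid")) x$values else x
  yv <- if (inherits(y, "dose_grid")) y$values else y
  if (is.matrix(xv)) xv <- array(xv, c(dim(xv), 1L))
  if (is.matrix(yv)) yv <- array(yv, c(dim(yv), 1L))
  if (!identical(dim(xv), dim(yv))) stop("shape mismatch between x and y")
  C1 <- (config$K1 * config$L)^2
  C2 <- (config$K2 * config$L)^2
  C3 <- C2 / 2

  stats_for <- function(a, b) {
    if (config$window == "global") {
      n <- length(a)
      mx <- mean(a); my <- mean(b)
      # population (biased) moments, as in the reference implementation
      vx <- mean(a^2) - mx^2; vy <- mean(b^2) - my^2
      vxy <- mean(a * b) - mx * my
      list(mx = mx, my = my, vx = max(vx, 0), vy = max(vy, 0), vxy = vxy)
    } else {
      k <- gauss_kernel1d()
      mx <- conv2_valid(a, k); my <- conv2_valid(b, k)
      vx <- conv2_valid(a^2, k) - mx^2
      vy <- conv2_valid(b^2, k) - my^2
      vxy <- conv2_valid(a * b, k) - mx * my
      list(mx = mx, my = my, vx = pmax(vx, 0), vy = pmax(vy, 0), vxy = vxy)
    }
  }

  l_all <- c(); c_all <- c(); s_all <- c(); ssim_all <- c()
  for (k3 in seq_len(dim(xv)[3])) {
    st <- stats_for(xv[, , k3], yv[, , k3])
    sx <- sqrt(st$vx); sy <- sqrt(st$vy)
    l <- (2 * st$mx * st$my + C1) / (st$mx^2 + st$my^2 + C1)
    cc <- (2 * sx * sy + C2) / (st$vx + st$vy + C2)
    ss <- (st$vxy + C3) / (sx * sy + C3)
    l_all <- c(l_all, l); c_all <- c(c_all, cc); s_all <- c(s_all, ss)
    ssim_all <- c(ssim_all,
                  l^config$alpha * cc^config$beta * ss^config$gamma)
  }
  structure(list(ssim = mean(ssim_all), luminance = mean(l_all),
                 contrast = mean(c_all), structure = mean(s_all)),
            class = "ssim_result")
}

#' @export
print.ssim_result <- function(x, ...) {
  cat(sprintf("<ssim_result> ssim=%.5f l=%.5f c=%.5f s=%.5f\n",
              x$ssim, x$luminance, x$contrast, x$structure))
  invisible(x)
}
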