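#' Simulated error-free dose map (0.01 mm shift)
#'
#' A subtracted "error-free" map needs two error-free maps; subtracting a
#' map from itself gives all zeros and no texture. The stand-in is the map
#' itself translated by a tiny distance (0.01 mm by default) along x via
#' linear interpolation, which is statistically indistinguishable from the
#' original (see [validate_simulated_error_free()]) yet yields a non-trivial
#' subtracted map.
#'
#' @param dose a [dose_grid()].
#' @param shift_mm translation along x in mm (default 0.01).
#' @return the translated `dose_grid`.
#' @export
make_simulated_error_free <- function(dose, shift_mm = 0.01) {
  stopifnot(inherits(dose, "dose_grid"))
  f <- shift_mm / dose$spacing[1]
  if (f == 0) return(dose)
  stopifnot(abs(f) < 1)
  v <- dose$values
  n <- dim(v)[1]
  shifted <- v
  if (f > 0) {
    # value at x comes from x - shift: blend with the left neighbour
    shifted[2:n, , ] <- (1 - f) * v[2:n, , , drop = FALSE] +
      f * v[1:(n - 1), , , drop = FALSE]
  } else {
    g <- -f
    shifted[1:(n - 1), , ] <- (1 - g) * v[1:(n - 1), , , drop = FALSE] +
      g * v[2:n, , , drop = FALSE]
  }
  dose_grid(shifted, dose$spacing, dose$origin)
}

#' Validate a simulated error-free map against the original
#'
#' Paired Wilcoxon signed-rank test and Spearman rank correlation over the
#' flattened voxel values. The simulated map is acceptable when the two are
#' statistically similar (high rho, non-significant Wilcoxon).
#'
#' @param a,b [dose_grid()]s (or arrays) of identical shape.
#' @return list with `wilcoxon_p`, `spearman_rho`, `spearman_p`, and
#'   `degenerate` (`TRUE` when all pairs are tied and the Wilcoxon test is
#'   undefined).
#' @export
validate_simulated_error_free <- function(a, b) {
  av <- if (inherits(a, "dose_grid")) as.numeric(a$values) else as.numeric(a)
  bv <- if (inherits(b, "dose_grid")) as.numeric(b$values) else as.numeric(b)
  stopifnot(length(av) == length(bv))
  degenerate <- all(av == bv)
  wp <- if (degenerate) NA_real_ else
    suppressWarnings(wilcox.test(av, bv, paired = TRUE)$p.value)
  ct <- suppressWarnings(cor.test(av, bv, method = "spearman"))
  list(wilcoxon_p = wp, spearman_rho = unname(ct$estimate),
       spearman_p = ct$p.value, degenerate = degenerate)
}

#' Subtracted dose map
#'
#' Voxelwise difference of two aligned dose grids, tagged with its error
#' class (`sub_error_free`, `sub_systematic`, or `sub_random`).
#'
#' @param minuend,subtrahend aligned [dose_grid()]s (the error, or simulated
#'   error-free, map minus the error-free map).
#' @param class_label one of `"sub_error_free"`, `"sub_systematic"`,
#'   `"sub_random"`.
#' @return object of class `subtracted_map` with `values` (may be
#'   negative), `spacing`, `class_label`.
#' @export
subtract_dose <- function(minuend, subtrahend,
                          class_label = c("sub_error_free", "sub_systematic",
                                          "sub_random")) {
  class_label <- match.arg(class_label)
  stopifnot(inherits(minuend, "dose_grid"), inherits(subtrahend, "dose_grid"))
  if (!same_lattice(minuend, subtrahend)) stop("lattice mismatch")
  structure(list(values = minuend$values - subtrahend$values,
                 spacing = minuend$spacing, class_label = class_label),
            class = "subtracted_map")
}

trilinear_resample <- function(v, spacing, new_spacing) {
  d <- dim(v)
  out_d <- pmax(1L, as.integer(floor((d - 1) * spacing / new_spacing)) + 1L)
  gi <- lapply(1:3, function(a) {
    if (out_d[a] == 1L) return(rep(1, 1))
    (seq_len(out_d[a]) - 1) * new_spacing[a] / spacing[a] + 1
  })
  # clamp to grid
  gi <- lapply(1:3, function(a) pmin(gi[[a]], d[a]))
  x0 <- lapply(1:3, function(a) pmin(floor(gi[[a]]), d[a] - (d[a] > 1)))
  fr <- lapply(1:3, function(a) gi[[a]] - x0[[a]])
  out <- array(0, out_d)
  for (bx in 0:1) for (by in 0:1) for (bz in 0:1) {
    wx <- if (bx == 0) 1 - fr[[1]] else fr[[1]]
    wy <- if (by == 0) 1 - fr[[2]] else fr[[2]]
    wz <- if (bz == 0) 1 - fr[[3]] else fr[[3]]
    ix <- pmin(x0[[1]] + bx, dim(v)[1])
    iy <- pmin(x0[[2]] + by, dim(v)[2])
    iz <- pmin(x0[[3]] + bz, dim(v)[3])
    w <- outer(outer(wx, wy), wz)
    out <- out + w * v[ix, iy, iz, drop = FALSE]
  }
  out
}

#' Resample and discretise a subtracted dose map
#'
#' Trilinearly resamples to the target spacing (2 mm isotropic by default;
#' identity when already on that lattice) and maps values to integer gray
#' levels with a fixed bin width anchored at the map minimum:
#' `level = floor((value - min) / bin_width) + 1`. Values are scaled to cGy
#' (`value_scale = 100`) before binning so that the study's bin width of 1
#' corresponds to 1 cGy on maps stored in Gy.
#'
#' @param map a `subtracted_map` or [dose_grid()].
#' @param new_spacing target spacing mm (default 2 isotropic).
#' @param bin_width bin size in (scaled) intensity units (default 1).
#' @param value_scale multiplicative scale applied before binning
#'   (default 100: Gy to cGy).
#' @return object of class `discretized_volume`: `levels` (integer array,
#'   in `1..n_levels`), `n_levels`, `values` (resampled continuous array,
#'   scaled), `bin_width`.
#' @export
resample_and_discretize <- function(map, new_spacing = c(2, 2, 2),
                                    bin_width = 1, value_scale = 100) {
  stopifnot(bin_width > 0)
  v <- if (inherits(map, "dose_grid") || inherits(map, "subtracted_map")) {
    map$values
  } else map
  spacing <- if (is.list(map) && !is.null(map$spacing)) map$spacing else
    new_spacing
  if (any(abs(spacing - new_spacing) > 1e-9)) {
    v <- trilinear_resample(v, spacing, new_spacing)
  }
  v <- v * value_scale
  lv <- array(as.integer(floor((v - min(v)) / bin_width)) + 1L, dim(v))
  structure(list(levels = lv, n_levels = max(lv), values = v,
                 bin_width = bin_width),
            class = "discretized_volume")
}

as_discretized <- function(vol) {
  if (inherits(vol, "discretized_volume")) return(vol)
  if (is.array(vol) || is.matrix(vol)) {
    if (is.matrix(vol)) vol <- array(vol, c(dim(vol), 1L))
    lv <- array(as.integer(vol), dim(vol))
    stopifnot(all(lv >= 1L))
    return(structure(list(levels = lv, n_levels = max(lv),
                          values = lv * 1.0, bin_width = 1),
                     class = "discretized_volume"))
  }
  stop("expected a discretized_volume or an integer array of levels")
}

# The 13 unique 3D directions (distance one voxel).
directions13 <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

dir_slices <- function(d, off) {
  # index vectors for the (from, to) voxel pair sets of one direction
  rng <- function(n, o) {
    if (o == 0) list(seq_len(n), seq_len(n))
    else if (o > 0) list(seq_len(n - o), seq_len(n - o) + o)
    else list(seq_len(n + o) - o, seq_len(n + o))
  }
  list(rng(d[1], off[1]), rng(d[2], off[2]), rng(d[3], off[3]))
}

#' Gray-level co-occurrence (GLCM) features
#'
#' Symmetric co-occurrence counts at one-voxel distance, summed over the 13
#' unique 3D directions and normalised to probabilities `p(i, j)`.
#' Features: Energy `sum p^2`, Contrast `sum (i-j)^2 p`, Correlation,
#' Entropy (`-sum p log2 p`), Homogeneity `sum p / (1 + |i-j|)`,
#' Dissimilarity `sum |i-j| p`.
#'
#' @param vol a `discretized_volume` (or integer level array).
#' @return named numeric vector of 6 features.
#' @export
glcm_features <- function(vol) {
  vol <- as_discretized(vol)
  lv <- vol$levels; d <- dim(lv); L <- vol$n_levels
  counts <- numeric(L * L)
  for (k in seq_len(nrow(directions13()))) {
    off <- directions13()[k, ]
    if (any(abs(off) >= d)) next
    s <- dir_slices(d, off)
    a <- lv[s[[1]][[1]], s[[2]][[1]], s[[3]][[1]], drop = FALSE]
    b <- lv[s[[1]][[2]], s[[2]][[2]], s[[3]][[2]], drop = FALSE]
    if (length(a) == 0) next
    idx <- c((a - 1L) * L + b, (b - 1L) * L + a)  # symmetric
    counts <- counts + tabulate(idx, nbins = L * L)
  }
  tot <- sum(counts)
  if (tot == 0) {  # single voxel: degenerate
    return(c(GLCM_Energy = 1, GLCM_Contrast = 0, GLCM_Correlation = NA,
             GLCM_Entropy = 0, GLCM_Homogeneity = 1, GLCM_Dissimilarity = 0))
  }
  p <- counts / tot
  i <- rep(seq_len(L), each = L)   # first index of pair
  j <- rep(seq_len(L), times = L)  # second
  # note: idx encoding above is (a-1)*L + b -> i = a, j = b
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  s_i <- sqrt(sum((i - mu_i)^2 * p)); s_j <- sqrt(sum((j - mu_j)^2 * p))
  corr <- if (s_i > 0 && s_j > 0) {
    sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j)
  } else NA_real_
  nz <- p > 0
  c(GLCM_Energy = sum(p^2),
    GLCM_Contrast = sum((i - j)^2 * p),
    GLCM_Correlation = corr,
    GLCM_Entropy = -sum(p[nz] * log2(p[nz])),
    GLCM_Homogeneity = sum(p / (1 + abs(i - j))),
    GLCM_Dissimilarity = sum(abs(i - j) * p))
}

# Runs (level, length) for one direction, fully vectorised: each voxel is
# assigned to its lattice line and position along it, then run-length
# encoded within lines.
runs_for_direction <- function(lv, off) {
  d <- dim(lv)
  x <- rep(seq_len(d[1]), times = d[2] * d[3])
  y <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  z <- rep(seq_len(d[3]), each = d[1] * d[2])
  steps_back <- function(coord, n, o) {
    if (o == 0) rep(Inf, length(coord))
    else if (o > 0) coord - 1L else n - coord
  }
  t <- pmin(steps_back(x, d[1], off[1]), steps_back(y, d[2], off[2]),
            steps_back(z, d[3], off[3]))
  sx <- x - t * off[1]; sy <- y - t * off[2]; sz <- z - t * off[3]
  line <- sx + d[1] * (sy + d[2] * sz)
  ord <- order(line, t)
  v <- as.integer(lv)[ord]
  ln <- line[ord]
  brk <- c(TRUE, diff(ln) != 0 | diff(v) != 0)
  rid <- cumsum(brk)
  list(level = v[brk], length = tabulate(rid))
}

#' Gray-level run-length (GLRLM) features
#'
#' Run-length matrices are built per direction (13 unique 3D directions)
#' and the 11 standard features (SRE, LRE, LGRE, HGRE, SRLGE, SRHGE, LRLGE,
#' LRHGE, GLNU, RLNU, RP) are averaged over directions. LRHGE, the long-run
#' high-gray-level emphasis, is `sum r(i,j) i^2 j^2 / N_runs`.
#'
#' @param vol a `discretized_volume` (or integer level array).
#' @return named numeric vector of 11 features.
#' @export
glrlm_features <- function(vol) {
  vol <- as_discretized(vol)
  lv <- vol$levels
  nv <- length(lv)
  dirs <- directions13()
  acc <- NULL
  for (k in seq_len(nrow(dirs))) {
    r <- runs_for_direction(lv, dirs[k, ])
    N <- length(r$level)
    i2 <- r$level^2; j2 <- r$length^2
    f <- c(SRE = sum(1 / j2) / N, LRE = sum(j2) / N,
           LGRE = sum(1 / i2) / N, HGRE = sum(i2) / N,
           SRLGE = sum(1 / (i2 * j2)) / N, SRHGE = sum(i2 / j2) / N,
           LRLGE = sum(j2 / i2) / N, LRHGE = sum(i2 * j2) / N,
           GLNU = sum(tapply(rep(1, N), r$level, sum)^2) / N,
           RLNU = sum(tapply(rep(1, N), r$length, sum)^2) / N,
           RP = N / nv)
    acc <- if (is.null(acc)) f else acc + f
  }
  out <- acc / nrow(dirs)
  names(out) <- paste0("GLRLM_", names(out))
  out
}

#' Neighbourhood gray-level difference (NGLDM) features
#'
#' For each voxel, the absolute difference between its gray level and the
#' mean level of its available 26-neighbours is accumulated per level
#' (`s_i`); with level probabilities `p_i` this yields Coarseness
#' `1 / sum(p_i s_i)` (capped at 1e6 for uniform volumes), Contrast, and
#' Busyness, following the 26-connected 3D convention.
#'
#' @param vol a `discretized_volume` (or integer level array).
#' @return named numeric vector of 3 features.
#' @export
ngldm_features <- function(vol) {
  vol <- as_discretized(vol)
  lv <- vol$levels; d <- dim(lv)
  nb_sum <- array(0, d); nb_cnt <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    off <- c(dx, dy, dz)
    if (any(abs(off) >= d)) next
    s <- dir_slices(d, off)
    nb_sum[s[[1]][[1]], s[[2]][[1]], s[[3]][[1]]] <-
      nb_sum[s[[1]][[1]], s[[2]][[1]], s[[3]][[1]], drop = FALSE] +
      lv[s[[1]][[2]], s[[2]][[2]], s[[3]][[2]], drop = FALSE]
    nb_cnt[s[[1]][[1]], s[[2]][[1]], s[[3]][[1]]] <-
      nb_cnt[s[[1]][[1]], s[[2]][[1]], s[[3]][[1]], drop = FALSE] + 1
  }
  ok <- nb_cnt > 0
  diffs <- abs(lv[ok] - nb_sum[ok] / nb_cnt[ok])
  levs <- lv[ok]
  Nv <- sum(ok)
  lev_tab <- sort(unique(levs))
  s_i <- vapply(lev_tab, function(g) sum(diffs[levs == g]), numeric(1))
  n_i <- vapply(lev_tab, function(g) sum(levs == g), numeric(1))
  p_i <- n_i / Nv
  Ng <- length(lev_tab)
  ps <- sum(p_i * s_i)
  coarseness <- if (ps > 0) min(1 / ps, 1e6) else 1e6
  contrast <- if (Ng > 1) {
    (sum(outer(p_i, p_i) * outer(lev_tab, lev_tab, "-")^2) /
       (Ng * (Ng - 1))) * (sum(s_i) / Nv)
  } else 0
  ipi <- lev_tab * p_i
  denom <- sum(abs(outer(ipi, ipi, "-")))
  busyness <- if (denom > 0) ps / denom else 0
  c(NGLDM_Coarseness = coarseness, NGLDM_Contrast = contrast,
    NGLDM_Busyness = busyness)
}

#' Gray-level zone-length (GLZLM) features
#'
#' Zones are 26-connected components of equal gray level, computed directly
#' in 3D. The zone matrix `z(i, j)` counts zones of level `i` and size `j`;
#' the 11 features (SZE, LZE, LGZE, HGZE, SZLGE, SZHGE, LZLGE, LZHGE, GLNU,
#' ZLNU, ZP) use the same emphases as the run-length features with run
#' length replaced by zone size. GLNU is
#' `sum_i (sum_j z(i,j))^2 / N_zones`.
#'
#' @param vol a `discretized_volume` (or integer level array).
#' @return named numeric vector of 11 features.
#' @export
glzlm_features <- function(vol) {
  vol <- as_discretized(vol)
  lv <- vol$levels
  labels <- label_zones_cpp(as.integer(lv), dim(lv))
  sizes <- tabulate(labels)
  zl <- as.integer(lv)[match(seq_along(sizes), as.integer(labels))]
  N <- length(sizes)
  i2 <- zl^2; j2 <- as.numeric(sizes)^2
  out <- c(SZE = sum(1 / j2) / N, LZE = sum(j2) / N,
           LGZE = sum(1 / i2) / N, HGZE = sum(i2) / N,
           SZLGE = sum(1 / (i2 * j2)) / N, SZHGE = sum(i2 / j2) / N,
           LZLGE = sum(j2 / i2) / N, LZHGE = sum(i2 * j2) / N,
           GLNU = sum(tapply(rep(1, N), zl, sum)^2) / N,
           ZLNU = sum(tapply(rep(1, N), sizes, sum)^2) / N,
           ZP = N / length(lv))
  names(out) <- paste0("GLZLM_", names(out))
  out
}

#' Conventional and histogram features
#'
#' Mean intensity (the one conventional feature) plus histogram skewness
#' and excess kurtosis, computed on the resampled continuous values.
#'
#' @param vol a `discretized_volume` (continuous values are used) or a
#'   numeric array.
#' @return named numeric vector of 3 features; skewness and kurtosis are
#'   `NA` for zero-variance input.
#' @export
histogram_and_conventional_features <- function(vol) {
  v <- if (inherits(vol, "discretized_volume")) as.numeric(vol$values) else
    as.numeric(vol)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) {
    return(c(Conv_MeanIntensity = m, Hist_Skewness = NA_real_,
             Hist_Kurtosis = NA_real_))
  }
  c(Conv_MeanIntensity = m,
    Hist_Skewness = mean((v - m)^3) / m2^1.5,
    Hist_Kurtosis = mean((v - m)^4) / m2^2 - 3)
}

#' The 34-feature dosiomics manifest
#'
#' Stable names of the 34 features extracted from each subtracted dose map:
#' 1 conventional, 2 histogram, and 31 texture features from GLCM (6),
#' GLRLM (11), NGLDM (3), GLZLM (11). The identity of the feature set
#' follows LIFEx v7.1 conventions and is an interpretation: the study
#' counts the categories but does not enumerate the features.
#'
#' @return character vector of 34 names.
#' @export
feature_manifest <- function() {
  c("Conv_MeanIntensity", "Hist_Skewness", "Hist_Kurtosis",
    "GLCM_Energy", "GLCM_Contrast", "GLCM_Correlation", "GLCM_Entropy",
    "GLCM_Homogeneity", "GLCM_Dissimilarity",
    paste0("GLRLM_", c("SRE", "LRE", "LGRE", "HGRE", "SRLGE", "SRHGE",
                       "LRLGE", "LRHGE", "GLNU", "RLNU", "RP")),
    "NGLDM_Coarseness", "NGLDM_Contrast", "NGLDM_Busyness",
    paste0("GLZLM_", c("SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE",
                       "LZLGE", "LZHGE", "GLNU", "ZLNU", "ZP")))
}

#' Extract the 34-feature dosiomics vector from a subtracted dose map
#'
#' Resamples to 2 mm, discretises with bin width 1 (cGy), and concatenates
#' the conventional/histogram and GLCM/GLRLM/NGLDM/GLZLM features in
#' manifest order. Deterministic: identical input gives identical output.
#'
#' @param map a `subtracted_map`, `dose_grid`, or numeric array.
#' @param ... passed to [resample_and_discretize()].
#' @return named numeric vector of length 34 (names =
#'   [feature_manifest()]).
#' @export
extract_features <- function(map, ...) {
  vol <- resample_and_discretize(map, ...)
  out <- c(histogram_and_conventional_features(vol),
           glcm_features(vol), glrlm_features(vol),
           ngldm_features(vol), glzlm_features(vol))
  stopifnot(identical(names(out), feature_manifest()))
  out
}

#' Z-score a feature table
#'
#' Standardises each feature column over all rows of the dataset:
#' `(x - mean) / sd`. Zero-variance columns are dropped with a warning.
#'
#' @param table data frame or matrix of numeric feature columns (rows =
#'   subtracted maps).
#' @return data frame of standardised columns.
#' @export
zscore_features <- function(table) {
  table <- as.data.frame(table)
  if (nrow(table) < 2L) stop("z-scoring needs at least two rows")
  sds <- vapply(table, sd, numeric(1))
  drop <- is.na(sds) | sds == 0
  if (any(drop)) {
    warning("dropping zero-variance column(s): ",
            paste(names(table)[drop], collapse = ", "))
    table <- table[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  means <- vapply(table, mean, numeric(1))
  as.data.frame(scale(table, center = means, scale = sds))
}
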