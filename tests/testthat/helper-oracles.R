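# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops and hand-rolled interpolation, used only on tiny
# inputs.

oracle_interp3 <- function(v, x, y, z) {
  # x, y, z: 1-based fractional indices
  d <- dim(v)
  if (x < 1 || y < 1 || z < 1 || x > d[1] || y > d[2] || z > d[3]) return(NA)
  x0 <- min(floor(x), d[1] - (d[1] > 1)); fx <- x - x0
  y0 <- min(floor(y), d[2] - (d[2] > 1)); fy <- y - y0
  z0 <- min(floor(z), d[3] - (d[3] > 1)); fz <- z - z0
  x1 <- min(x0 + 1, d[1]); y1 <- min(y0 + 1, d[2]); z1 <- min(z0 + 1, d[3])
  c00 <- v[x0, y0, z0] * (1 - fx) + v[x1, y0, z0] * fx
  c10 <- v[x0, y1, z0] * (1 - fx) + v[x1, y1, z0] * fx
  c01 <- v[x0, y0, z1] * (1 - fx) + v[x1, y0, z1] * fx
  c11 <- v[x0, y1, z1] * (1 - fx) + v[x1, y1, z1] * fx
  (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz
}

# Exhaustive search over the full offset lattice (no early exit); the
# interpolation is vectorised over offsets but written independently of the
# package's C++ path.
oracle_gamma <- function(ref, eval, spacing, dd_pct, dta, threshold_pct = 10,
                         step_frac = 0.1, radius_mult = 3) {
  d <- dim(ref)
  thr <- threshold_pct / 100 * max(ref)
  step <- step_frac * dta
  n <- floor(radius_mult * dta / step)
  grid1 <- function(size) if (size > 1) (-n):n else 0L
  offs <- expand.grid(dx = grid1(d[1]), dy = grid1(d[2]), dz = grid1(d[3]))
  offs <- offs[with(offs, (dx^2 + dy^2 + dz^2) * step^2 <=
                      (radius_mult * dta)^2 + 1e-12), ]
  ox <- offs$dx * step; oy <- offs$dy * step; oz <- offs$dz * step
  dist2 <- (ox^2 + oy^2 + oz^2) / dta^2
  interp_vec <- function(x, y, z) {
    ok <- x >= 1 & y >= 1 & z >= 1 & x <= d[1] & y <= d[2] & z <= d[3]
    out <- rep(NA_real_, length(x))
    if (!any(ok)) return(out)
    x <- x[ok]; y <- y[ok]; z <- z[ok]
    clamp0 <- function(v, size) pmin(floor(v), size - (size > 1))
    x0 <- clamp0(x, d[1]); y0 <- clamp0(y, d[2]); z0 <- clamp0(z, d[3])
    fx <- x - x0; fy <- y - y0; fz <- z - z0
    x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
    at <- function(a, b, c) eval[cbind(a, b, c)]
    c00 <- at(x0, y0, z0) * (1 - fx) + at(x1, y0, z0) * fx
    c10 <- at(x0, y1, z0) * (1 - fx) + at(x1, y1, z0) * fx
    c01 <- at(x0, y0, z1) * (1 - fx) + at(x1, y0, z1) * fx
    c11 <- at(x0, y1, z1) * (1 - fx) + at(x1, y1, z1) * fx
    out[ok] <- (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
      (c01 * (1 - fy) + c11 * fy) * fz
    out
  }
  out <- array(NA_real_, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    rv <- ref[i, j, k]
    if (rv < thr) next
    tol <- dd_pct / 100 * rv
    ev <- interp_vec(i + ox / spacing[1], j + oy / spacing[2],
                     k + oz / spacing[3])
    out[i, j, k] <- sqrt(min(dist2 + ((ev - rv) / tol)^2, na.rm = TRUE))
  }
  out
}

# Integer voxel-offset brute force: no interpolation at all, plain loops.
oracle_gamma_voxel <- function(ref, eval, spacing, dd_pct, dta,
                               threshold_pct = 10, radius_mult = 3) {
  d <- dim(ref)
  thr <- threshold_pct / 100 * max(ref)
  nmax <- floor(radius_mult * dta / min(spacing))
  out <- array(NA_real_, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    rv <- ref[i, j, k]
    if (rv < thr) next
    tol <- dd_pct / 100 * rv
    best <- Inf
    for (dz in -nmax:nmax) for (dy in -nmax:nmax) for (dx in -nmax:nmax) {
      dist2 <- (dx * spacing[1])^2 + (dy * spacing[2])^2 + (dz * spacing[3])^2
      if (dist2 > (radius_mult * dta)^2 + 1e-12) next
      q <- c(i + dx, j + dy, k + dz)
      if (!inside(q, d)) next
      g2 <- dist2 / dta^2 + ((eval[q[1], q[2], q[3]] - rv) / tol)^2
      if (g2 < best) best <- g2
    }
    out[i, j, k] <- sqrt(best)
  }
  out
}

oracle_dirs13 <- function() {
  list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
       c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
       c(0, 1, 1), c(0, 1, -1),
       c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

inside <- function(p, d) all(p >= 1) && all(p <= d)

# Symmetric co-occurrence probabilities p(i, j), 13 directions, distance 1.
oracle_glcm_p <- function(lv) {
  d <- dim(lv); L <- max(lv)
  counts <- matrix(0, L, L)
  for (dir in oracle_dirs13()) {
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      q <- c(i, j, k) + dir
      if (!inside(q, d)) next
      a <- lv[i, j, k]; b <- lv[q[1], q[2], q[3]]
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  counts / sum(counts)
}

oracle_glcm_features <- function(lv) {
  p <- oracle_glcm_p(lv)
  L <- nrow(p)
  i <- row(p); j <- col(p)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  s_i <- sqrt(sum((i - mu_i)^2 * p)); s_j <- sqrt(sum((j - mu_j)^2 * p))
  nz <- p > 0
  c(GLCM_Energy = sum(p^2),
    GLCM_Contrast = sum((i - j)^2 * p),
    GLCM_Correlation = if (s_i > 0 && s_j > 0)
      sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j) else NA,
    GLCM_Entropy = -sum(p[nz] * log2(p[nz])),
    GLCM_Homogeneity = sum(p / (1 + abs(i - j))),
    GLCM_Dissimilarity = sum(abs(i - j) * p))
}

# Runs (level, length) for one direction by explicit line walking.
oracle_runs <- function(lv, dir) {
  d <- dim(lv)
  runs_level <- integer(0); runs_len <- integer(0)
  seen <- array(FALSE, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    p <- c(i, j, k)
    if (inside(p - dir, d)) next  # not a line start
    # walk the line
    line <- integer(0)
    q <- p
    while (inside(q, d)) {
      line <- c(line, lv[q[1], q[2], q[3]])
      q <- q + dir
    }
    r <- rle(line)
    runs_level <- c(runs_level, r$values)
    runs_len <- c(runs_len, r$lengths)
  }
  list(level = runs_level, length = runs_len)
}

oracle_rl_feats <- function(level, len, nvox) {
  N <- length(level)
  i2 <- level^2; j2 <- len^2
  c(SRE = sum(1 / j2) / N, LRE = sum(j2) / N,
    LGRE = sum(1 / i2) / N, HGRE = sum(i2) / N,
    SRLGE = sum(1 / (i2 * j2)) / N, SRHGE = sum(i2 / j2) / N,
    LRLGE = sum(j2 / i2) / N, LRHGE = sum(i2 * j2) / N,
    GLNU = sum(table(level)^2) / N, RLNU = sum(table(len)^2) / N,
    RP = N / nvox)
}

oracle_glrlm_features <- function(lv) {
  acc <- NULL
  for (dir in oracle_dirs13()) {
    r <- oracle_runs(lv, dir)
    f <- oracle_rl_feats(r$level, r$length, length(lv))
    acc <- if (is.null(acc)) f else acc + f
  }
  out <- acc / 13
  names(out) <- paste0("GLRLM_", names(out))
  out
}

# 26-connected flood fill for zones.
oracle_zones <- function(lv) {
  d <- dim(lv)
  lab <- array(0L, d)
  nxt <- 0L
  coords <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  for (s in seq_len(nrow(coords))) {
    p0 <- as.integer(coords[s, ])
    if (lab[p0[1], p0[2], p0[3]] != 0L) next
    nxt <- nxt + 1L
    queue <- list(p0)
    lab[p0[1], p0[2], p0[3]] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        q <- p + c(dx, dy, dz)
        if (!inside(q, d)) next
        if (lab[q[1], q[2], q[3]] == 0L &&
            lv[q[1], q[2], q[3]] == lv[p[1], p[2], p[3]]) {
          lab[q[1], q[2], q[3]] <- nxt
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  sizes <- as.integer(table(lab))
  levels <- vapply(seq_len(nxt), function(z) lv[lab == z][1], numeric(1))
  list(level = levels, size = sizes)
}

oracle_glzlm_features <- function(lv) {
  z <- oracle_zones(lv)
  f <- oracle_rl_feats(z$level, z$size, length(lv))
  names(f) <- paste0("GLZLM_",
                     c("SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE",
                       "LZLGE", "LZHGE", "GLNU", "ZLNU", "ZP"))
  f
}

oracle_ngldm_features <- function(lv) {
  d <- dim(lv)
  diffs <- c(); levs <- c()
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(i + dx, j + dy, k + dz)
      if (inside(q, d)) nb <- c(nb, lv[q[1], q[2], q[3]])
    }
    if (length(nb)) {
      diffs <- c(diffs, abs(lv[i, j, k] - mean(nb)))
      levs <- c(levs, lv[i, j, k])
    }
  }
  Nv <- length(levs)
  lev_tab <- sort(unique(levs))
  s_i <- vapply(lev_tab, function(g) sum(diffs[levs == g]), numeric(1))
  p_i <- vapply(lev_tab, function(g) mean(levs == g), numeric(1))
  Ng <- length(lev_tab)
  ps <- sum(p_i * s_i)
  coarse <- if (ps > 0) min(1 / ps, 1e6) else 1e6
  contrast <- if (Ng > 1) {
    acc <- 0
    for (a in seq_len(Ng)) for (b in seq_len(Ng)) {
      acc <- acc + p_i[a] * p_i[b] * (lev_tab[a] - lev_tab[b])^2
    }
    acc / (Ng * (Ng - 1)) * sum(s_i) / Nv
  } else 0
  ip <- lev_tab * p_i
  den <- 0
  for (a in seq_len(Ng)) for (b in seq_len(Ng)) den <- den + abs(ip[a] - ip[b])
  c(NGLDM_Coarseness = coarse, NGLDM_Contrast = contrast,
    NGLDM_Busyness = if (den > 0) ps / den else 0)
}

# Small fixture helpers -------------------------------------------------------

random_level_array <- function(dim, n_levels, seed) {
  set.seed(seed)
  array(sample.int(n_levels, prod(dim), replace = TRUE), dim = dim)
}

tiny_phantom <- function(case = "c_shape_easy", dim = c(32L, 32L, 16L)) {
  make_phantom(case, default_phantom_spec(case, dim = dim))
}

tiny_plan_setup <- function(case = "c_shape_easy", n_beams = 3, n_cp = 3,
                            seed = 42, dim = c(32L, 32L, 16L)) {
  ph <- tiny_phantom(case, dim)
  list(phantom = ph,
       plan = make_plan(ph, n_beams = n_beams, n_control_points = n_cp,
                        seed = seed))
}
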