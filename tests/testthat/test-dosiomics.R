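test_that("the 0.01 mm translation behaves like linear interpolation", {
  g <- dose_grid(array(rep(seq(0, 62, by = 2), 8 * 4), c(32, 8, 4)))
  expect_identical(make_simulated_error_free(g, 0)$values, g$values)
  # linear ramp d(x) = x: interior shifts by exactly the translation
  sh <- make_simulated_error_free(g, 0.01)
  n <- dim(g$values)[1]
  expect_equal(sh$values[2:n, , ], g$values[2:n, , ] - 0.01,
               tolerance = 1e-12)
})

test_that("simulated error-free maps are statistically similar to the original", {
  s <- tiny_plan_setup(n_beams = 1)
  m <- compute_dose(s$plan, s$phantom, seed = 3, volume = FALSE)$beam_maps[[1]]
  sim <- make_simulated_error_free(m)
  v <- validate_simulated_error_free(m, sim)
  expect_gt(v$spearman_rho, 0.97)
  expect_gt(v$wilcoxon_p, 0.05)
  expect_false(v$degenerate)
  # identical inputs flag the degenerate Wilcoxon case
  expect_true(validate_simulated_error_free(m, m)$degenerate)
  # independent random grids: rho near zero
  set.seed(8)
  a <- array(runif(1000), c(10, 10, 10)); b <- array(runif(1000), c(10, 10, 10))
  expect_lt(abs(validate_simulated_error_free(a, b)$spearman_rho),
            3 / sqrt(1000))
})

test_that("subtraction is voxelwise, label-preserving, and shift-monotone", {
  s <- tiny_plan_setup(n_beams = 1)
  cfg <- dose_engine_config(noise_sd = 0)
  free <- compute_dose(s$plan, s$phantom, cfg, volume = FALSE)$beam_maps[[1]]
  expect_equal(max(abs(subtract_dose(free, free, "sub_error_free")$values)), 0)
  expect_identical(subtract_dose(free, free, "sub_systematic")$class_label,
                   "sub_systematic")
  sub_of <- function(shift) {
    err <- compute_dose(inject_systematic(s$plan, systematic_error_spec(shift)),
                        s$phantom, cfg, volume = FALSE)$beam_maps[[1]]
    subtract_dose(err, free, "sub_systematic")
  }
  expect_gt(mean(abs(sub_of(2.0)$values)), mean(abs(sub_of(0.5)$values)))
  other <- dose_grid(array(1, c(3, 3, 1)))
  expect_error(subtract_dose(free, other), "mismatch")
})

test_that("discretisation is min-anchored with floor binning", {
  v <- array(c(0, 1, 2.4, 0.2), c(4, 1, 1))
  d <- resample_and_discretize(v, new_spacing = c(2, 2, 2), bin_width = 1,
                               value_scale = 1)
  expect_equal(as.numeric(d$levels), c(1, 2, 3, 1))
  expect_equal(d$n_levels, 3L)
  # shifting by a constant changes nothing
  d2 <- resample_and_discretize(v + 5, new_spacing = c(2, 2, 2),
                                bin_width = 1, value_scale = 1)
  expect_identical(d$levels, d2$levels)
  # constant map: a single level is allowed
  dc <- resample_and_discretize(array(3, c(2, 2, 2)),
                                new_spacing = c(2, 2, 2), value_scale = 1)
  expect_equal(dc$n_levels, 1L)
})

test_that("resampling to the native 2 mm lattice is the identity", {
  set.seed(11)
  g <- structure(list(values = array(runif(60), c(5, 4, 3)),
                      spacing = c(2, 2, 2), class_label = "sub_error_free"),
                 class = "subtracted_map")
  d <- resample_and_discretize(g, value_scale = 1)
  expect_equal(d$values, g$values, tolerance = 1e-12)
  # 1 mm input is downsampled: coarse grid has half the extent per axis
  g1 <- structure(list(values = array(runif(8 * 8 * 2), c(8, 8, 2)),
                       spacing = c(1, 1, 2), class_label = "sub_error_free"),
                  class = "subtracted_map")
  d1 <- resample_and_discretize(g1, value_scale = 1)
  expect_equal(dim(d1$values)[1:2], c(4L, 4L))
  expect_equal(d1$values[1, 1, 1], g1$values[1, 1, 1], tolerance = 1e-12)
})

test_that("GLCM features match brute-force enumeration", {
  # hand-checkable 2x2x1: levels [[1,2],[2,1]]
  lv <- array(c(1L, 2L, 2L, 1L), c(2, 2, 1))
  f <- glcm_features(lv)
  o <- oracle_glcm_features(lv)
  expect_equal(f, o, tolerance = 1e-12)
  # hand enumeration: 6 unordered pairs (axis 4 mixed, diagonals 1+1 equal);
  # symmetric p: p(1,2)=p(2,1)=4/12, p(1,1)=p(2,2)=2/12 ->
  # Energy = 2*(4/12)^2 + 2*(2/12)^2 = 5/18
  expect_equal(unname(f["GLCM_Energy"]), 5 / 18, tolerance = 1e-12)

  for (seed in 1:4) {
    lv <- random_level_array(c(4, 4, 4), n_levels = 3, seed = seed)
    expect_equal(glcm_features(lv), oracle_glcm_features(lv),
                 tolerance = 1e-12)
  }
  # constant volume: a single co-occurrence cell
  expect_equal(unname(glcm_features(array(1L, c(3, 3, 3)))["GLCM_Energy"]), 1)
})

test_that("GLCM energy drops when uniform texture is randomised", {
  energies <- vapply(1:10, function(s) {
    unname(glcm_features(random_level_array(c(4, 4, 4), 4, s))["GLCM_Energy"])
  }, numeric(1))
  expect_lt(mean(energies), 1)
})

test_that("GLRLM features match brute-force enumeration", {
  # single-axis constant line: one run, LRHGE = g^2 * N^2
  lv <- array(3L, c(1, 1, 6))
  r <- oracle_runs(lv, c(0, 0, 1))
  expect_equal(r$level, 3L)
  expect_equal(r$length, 6L)
  expect_equal(unname(oracle_rl_feats(r$level, r$length, 6)["LRHGE"]),
               9 * 36)
  # alternating levels: all runs length 1 along that axis
  alt <- array(rep(c(1L, 2L), 4), c(8, 1, 1))
  ra <- oracle_runs(alt, c(1, 0, 0))
  expect_true(all(ra$length == 1L))

  for (seed in 5:8) {
    lv <- random_level_array(c(4, 4, 4), 3, seed)
    expect_equal(glrlm_features(lv), oracle_glrlm_features(lv),
                 tolerance = 1e-12)
  }
  # single-slice volumes work (out-of-plane runs have length 1)
  lv2 <- random_level_array(c(4, 4, 1), 3, 99)
  expect_equal(glrlm_features(lv2), oracle_glrlm_features(lv2),
               tolerance = 1e-12)
})

test_that("NGLDM features match brute-force enumeration", {
  expect_equal(unname(ngldm_features(array(2L, c(3, 3, 3)))["NGLDM_Contrast"]),
               0)
  # single deviant centre voxel
  lv <- array(1L, c(3, 3, 3)); lv[2, 2, 2] <- 3L
  expect_equal(ngldm_features(lv), oracle_ngldm_features(lv),
               tolerance = 1e-12)
  for (seed in 9:11) {
    lv <- random_level_array(c(4, 4, 4), 3, seed)
    expect_equal(ngldm_features(lv), oracle_ngldm_features(lv),
                 tolerance = 1e-12)
  }
  # invariance under global level shift with min-anchored rebinning
  v <- array(runif(27, 0, 5), c(3, 3, 3))
  f1 <- ngldm_features(resample_and_discretize(v, value_scale = 1))
  f2 <- ngldm_features(resample_and_discretize(v + 7, value_scale = 1))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("GLZLM features match the flood-fill oracle", {
  # one constant volume = one zone; GLNU = 1
  expect_equal(unname(glzlm_features(array(2L, c(3, 3, 2)))["GLZLM_GLNU"]), 1)
  # two disjoint equal-level zones of sizes 2 and 3 at the same level
  lv <- array(1L, c(7, 1, 1))
  lv[c(1, 2)] <- 2L; lv[c(5, 6, 7)] <- 2L
  # zones: level2 size2, level1 size2 (cells 3,4), level2 size3
  z <- oracle_zones(lv)
  expect_equal(sort(z$size), c(2, 2, 3))
  f <- glzlm_features(lv)
  # GLNU: level-2 zones count 2, level-1 zones count 1 -> (4 + 1)/3
  expect_equal(unname(f["GLZLM_GLNU"]), 5 / 3, tolerance = 1e-12)
  for (seed in 12:15) {
    lv <- random_level_array(c(4, 4, 4), 3, seed)
    expect_equal(glzlm_features(lv), oracle_glzlm_features(lv),
                 tolerance = 1e-12)
  }
})

test_that("histogram features use standardised moments", {
  sym <- array(rep(c(-1, 0, 1), 3), c(9, 1, 1))
  f <- histogram_and_conventional_features(sym)
  expect_equal(unname(f["Hist_Skewness"]), 0, tolerance = 1e-12)
  set.seed(16)
  z <- array(rnorm(1e5), c(100, 100, 10))
  fz <- histogram_and_conventional_features(z)
  expect_lt(abs(fz["Hist_Kurtosis"]), 3 * sqrt(24 / 1e5))
  expect_lt(abs(fz["Hist_Skewness"]), 3 * sqrt(6 / 1e5))
  # constant input flags moments as undefined
  fc <- histogram_and_conventional_features(array(2, c(4, 1, 1)))
  expect_true(is.na(fc["Hist_Skewness"]))
  expect_equal(unname(fc["Conv_MeanIntensity"]), 2)
})

test_that("the feature vector has exactly the 34 manifest names, deterministically", {
  expect_length(feature_manifest(), 34L)
  set.seed(17)
  v <- array(rnorm(6 * 6 * 3, 0, 0.1), c(6, 6, 3))
  sub <- structure(list(values = v, spacing = c(2, 2, 2),
                        class_label = "sub_random"),
                   class = "subtracted_map")
  f1 <- extract_features(sub)
  f2 <- extract_features(sub)
  expect_identical(f1, f2)
  expect_identical(names(f1), feature_manifest())
})

test_that("z-scoring standardises columns and preserves rank order", {
  set.seed(18)
  tab <- data.frame(a = rnorm(20, 5, 2), b = runif(20), c = 1)
  expect_warning(z <- zscore_features(tab), "zero-variance")
  expect_equal(ncol(z), 2L)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_identical(order(z$a), order(tab$a))
  expect_error(zscore_features(tab[1, ]), "two rows")
})
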