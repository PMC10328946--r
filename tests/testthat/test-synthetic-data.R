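test_that("phantom masks are deterministic, disjoint, and correctly placed", {
  ph1 <- tiny_phantom("c_shape_easy")
  ph2 <- tiny_phantom("c_shape_easy")
  expect_identical(ph1$structures$masks, ph2$structures$masks)

  # cord fully enclosed by the gap inside the PTV annulus
  cs <- ph1$structures$masks
  expect_false(any(cs$PTV & cs$cord))
  idx <- which(cs$cord, arr.ind = TRUE)
  r <- sqrt((ph1$origin[1] + (idx[, 1] - 1) * 2)^2 +
              (ph1$origin[3] + (idx[, 3] - 1) * 2)^2)
  expect_true(max(r) < ph1$spec$inner_radius)

  pr <- tiny_phantom("prostate", dim = c(40L, 40L, 40L))
  pm <- pr$structures$masks
  ym <- function(m) mean(pr$origin[2] + (which(m, arr.ind = TRUE)[, 2] - 1) * 2)
  zm <- function(m) mean(pr$origin[3] + (which(m, arr.ind = TRUE)[, 3] - 1) * 2)
  expect_gt(ym(pm$bladder), ym(pm$PTV))  # bladder superior
  expect_lt(zm(pm$rectum), zm(pm$PTV))   # rectum posterior
})

test_that("overlapping PTV and cord geometry is rejected for the C-shape", {
  spec <- default_phantom_spec("c_shape_hard", dim = c(32L, 32L, 16L))
  spec$cord_radius <- spec$inner_radius + 4  # cord pokes into the annulus
  expect_error(make_phantom("c_shape_hard", spec), "overlap")
})

test_that("plans are reproducible given a seed and collision-free", {
  s <- tiny_plan_setup()
  p2 <- make_plan(s$phantom, 3, 3, seed = 42)
  expect_identical(s$plan, p2)
  p3 <- make_plan(s$phantom, 3, 3, seed = 43)
  expect_false(identical(s$plan, p3))
  expect_true(validate_plan(s$plan))
  for (b in s$plan$beams) for (cp in b$control_points) {
    expect_true(all(cp$bank_a <= cp$bank_b))
  }
})

test_that("dose is linear in MU", {
  s <- tiny_plan_setup(n_beams = 2)
  cfg <- dose_engine_config(noise_sd = 0)
  r1 <- compute_dose(s$plan, s$phantom, cfg, scale = 1)
  doubled <- s$plan
  for (bi in seq_along(doubled$beams)) {
    for (ci in seq_along(doubled$beams[[bi]]$control_points)) {
      doubled$beams[[bi]]$control_points[[ci]]$mu_weight <-
        2 * doubled$beams[[bi]]$control_points[[ci]]$mu_weight
    }
  }
  r2 <- compute_dose(doubled, s$phantom, cfg, scale = 1)
  expect_equal(r2$dose$values, 2 * r1$dose$values, tolerance = 1e-12)
  expect_equal(r2$beam_maps[[1]]$values, 2 * r1$beam_maps[[1]]$values,
               tolerance = 1e-12)
})

test_that("a fully closed MLC leaves only transmission", {
  s <- tiny_plan_setup(n_beams = 1, n_cp = 1)
  closed <- s$plan
  cp <- closed$beams[[1]]$control_points[[1]]
  mid <- (cp$bank_a + cp$bank_b) / 2
  closed$beams[[1]]$control_points[[1]] <- control_point(mid, mid, cp$mu_weight)
  cfg <- dose_engine_config(noise_sd = 0, transmission = 0.02)
  m <- compute_dose(closed, s$phantom, cfg, volume = FALSE)$beam_maps[[1]]
  open <- compute_dose(s$plan, s$phantom, cfg, volume = FALSE)$beam_maps[[1]]
  expect_lte(max(m$values), 0.021 * max(open$values) / 0.9)
  # transmission-level plateau under the (closed) leaves
  expect_gt(median(m$values[m$values > 0]), 0)
})

test_that("shifting one bank moves the 50% isodose edge by the shift", {
  # single rectangular aperture; geometric oracle for edge displacement
  ph <- tiny_phantom("prostate", dim = c(40L, 40L, 40L))
  edges <- seq(-40, 40, by = 5)
  n_rows <- length(edges) - 1L
  cp <- control_point(rep(-20, n_rows), rep(20, n_rows), 1)
  plan <- mlc_plan("prostate", list(mlc_beam(0, list(cp), 5, edges)))
  cfg <- dose_engine_config(noise_sd = 0)
  free <- compute_dose(plan, ph, cfg, volume = FALSE)$beam_maps[[1]]
  shifted <- inject_systematic(plan, systematic_error_spec(2, bank = "B"))
  err <- compute_dose(shifted, ph, cfg, volume = FALSE)$beam_maps[[1]]
  edge_at <- function(map) {
    prof <- map$values[, dim(map$values)[2] / 2, 1]
    half <- max(prof) / 2
    i <- max(which(prof >= half))  # right edge crossing
    # linear interpolation between i and i+1
    x <- map$origin[1] + (i - 1) * map$spacing[1]
    x + (prof[i] - half) / (prof[i] - prof[i + 1]) * map$spacing[1]
  }
  displacement <- edge_at(err) - edge_at(free)
  expect_lt(abs(displacement - 2), 1)  # within half a voxel
})

test_that("translating all apertures translates the blurred fluence", {
  s <- tiny_plan_setup(n_beams = 1, n_cp = 2)
  cfg <- dose_engine_config(noise_sd = 0)
  base <- compute_dose(s$plan, s$phantom, cfg, volume = FALSE)$beam_maps[[1]]
  moved <- s$plan
  for (ci in seq_along(moved$beams[[1]]$control_points)) {
    cp <- moved$beams[[1]]$control_points[[ci]]
    moved$beams[[1]]$control_points[[ci]] <-
      control_point(cp$bank_a + 2, cp$bank_b + 2, cp$mu_weight)
  }
  shifted <- compute_dose(moved, s$phantom, cfg, volume = FALSE)$beam_maps[[1]]
  n <- dim(base$values)[1]
  # interior only: the penumbra convolution zero-pads at the map boundary
  inner <- 7:(n - 7)
  expect_equal(shifted$values[inner + 1, , ], base$values[inner, , ],
               tolerance = 1e-10)
})

test_that("error-free dose maps from identical seeds are bit-identical", {
  s <- tiny_plan_setup(n_beams = 2)
  r1 <- compute_dose(s$plan, s$phantom, seed = 7, volume = FALSE)
  r2 <- compute_dose(s$plan, s$phantom, seed = 7, volume = FALSE)
  expect_identical(r1$beam_maps, r2$beam_maps)
})
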