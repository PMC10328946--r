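make_two_leaf_plan <- function(a = c(-10, 9.8), b = c(10, 10)) {
  mlc_plan("prostate",
           list(mlc_beam(0, list(control_point(a, b, 1)), leaf_width = 5)))
}

test_that("systematic injection shifts the chosen bank and caps at collisions", {
  plan <- make_two_leaf_plan(a = c(10, 9.8), b = c(30, 10))
  # zero shift is the identity (modulo label)
  z <- inject_systematic(plan, systematic_error_spec(0))
  z$label <- plan$label
  expect_identical(z, plan)

  outA <- inject_systematic(plan, systematic_error_spec(2, bank = "A"))
  cp <- outA$beams[[1]]$control_points[[1]]
  expect_equal(cp$bank_a[1], 12)          # 10 + 2
  expect_equal(cp$bank_a[2], 10)          # capped at opposing leaf: closed
  expect_equal(cp$bank_b, c(30, 10))      # other bank untouched

  outB <- inject_systematic(plan, systematic_error_spec(1.5, bank = "B"))
  expect_equal(outB$beams[[1]]$control_points[[1]]$bank_b, c(31.5, 11.5))
  expect_true(validate_plan(outB))
})

test_that("systematic injection only touches pairs that are open", {
  plan <- make_two_leaf_plan(a = c(-10, 5), b = c(10, 5))  # row 2 closed
  out <- inject_systematic(plan, systematic_error_spec(1, bank = "B"))
  cp <- out$beams[[1]]$control_points[[1]]
  expect_equal(cp$bank_b, c(11, 5))
  all_rows <- inject_systematic(
    plan, systematic_error_spec(1, bank = "B",
                                restrict_to_ptv_adjacent = FALSE))
  expect_equal(all_rows$beams[[1]]$control_points[[1]]$bank_b, c(11, 6))
})

test_that("systematic shifts compose additively absent capping", {
  s <- tiny_plan_setup()
  one <- inject_systematic(inject_systematic(s$plan,
                                             systematic_error_spec(0.5)),
                           systematic_error_spec(1.0))
  two <- inject_systematic(s$plan, systematic_error_spec(1.5))
  for (bi in seq_along(one$beams)) {
    for (ci in seq_along(one$beams[[bi]]$control_points)) {
      expect_equal(one$beams[[bi]]$control_points[[ci]]$bank_b,
                   two$beams[[bi]]$control_points[[ci]]$bank_b)
    }
  }
})

test_that("random injection is seed-deterministic and collision-free", {
  s <- tiny_plan_setup()
  spec <- random_error_spec(1, sigma = 1, seed = 11)
  r1 <- inject_random(s$plan, spec)
  r2 <- inject_random(s$plan, spec)
  expect_identical(r1, r2)
  r3 <- inject_random(s$plan, random_error_spec(1, sigma = 1, seed = 12))
  expect_false(identical(r1, r3))
  for (b in r1$beams) for (cp in b$control_points) {
    expect_true(all(cp$bank_a <= cp$bank_b))
  }
})

test_that("random shifts with mu = 0 have mean near zero (CLT bound)", {
  # wide pairs so no redraws distort the distribution
  n_rows <- 60L
  cps <- replicate(12, control_point(rep(-100, n_rows), rep(100, n_rows),
                                     1 / 12), simplify = FALSE)
  plan <- mlc_plan("prostate", list(mlc_beam(0, cps, leaf_width = 2)))
  out <- inject_random(plan, random_error_spec(0, sigma = 1, seed = 5))
  shifts <- c()
  for (ci in seq_along(cps)) {
    shifts <- c(shifts,
                out$beams[[1]]$control_points[[ci]]$bank_a - (-100),
                out$beams[[1]]$control_points[[ci]]$bank_b - 100)
  }
  n <- length(shifts)
  expect_gte(n, 1e3)
  expect_lt(abs(mean(shifts)), 3 / sqrt(n))
  expect_lt(abs(sd(shifts) - 1), 0.1)
})

test_that("random mu widens the field on average under the default convention", {
  n_rows <- 60L
  cps <- replicate(10, control_point(rep(-100, n_rows), rep(100, n_rows),
                                     0.1), simplify = FALSE)
  plan <- mlc_plan("prostate", list(mlc_beam(0, cps, leaf_width = 2)))
  out <- inject_random(plan, random_error_spec(2, sigma = 1, seed = 9))
  da <- c(); db <- c()
  for (ci in seq_along(cps)) {
    da <- c(da, out$beams[[1]]$control_points[[ci]]$bank_a + 100)
    db <- c(db, out$beams[[1]]$control_points[[ci]]$bank_b - 100)
  }
  expect_lt(mean(da), -1.5)  # bank A moves left
  expect_gt(mean(db), 1.5)   # bank B moves right
  same <- inject_random(plan, random_error_spec(2, sigma = 1, seed = 9,
                                                direction = "same"))
  da2 <- same$beams[[1]]$control_points[[1]]$bank_a + 100
  expect_gt(mean(da2), 1.5)  # same-signed convention translates both banks
})

test_that("MU is conserved by every injection", {
  s <- tiny_plan_setup()
  mu0 <- plan_total_mu(s$plan)
  expect_equal(plan_total_mu(inject_systematic(s$plan,
                                               systematic_error_spec(2))), mu0)
  expect_equal(plan_total_mu(inject_random(s$plan,
                                           random_error_spec(2, seed = 3))),
               mu0)
})

test_that("the error suite has the expected size, labels, and determinism", {
  s <- tiny_plan_setup(n_beams = 2)
  suite <- build_error_suite(list(s$plan), systematic_shifts = c(0.5, 1, 1.5, 2),
                             random_mus = c(0, 1, 2), seed = 1)
  expect_length(suite, 8L)  # 1 + 4 + 3
  labels <- vapply(suite, `[[`, character(1), "label")
  expect_equal(labels[1], "error_free")
  expect_equal(sum(grepl("^systematic", labels)), 4L)
  expect_equal(sum(grepl("^random", labels)), 3L)
  suite2 <- build_error_suite(list(s$plan),
                              systematic_shifts = c(0.5, 1, 1.5, 2),
                              random_mus = c(0, 1, 2), seed = 1)
  expect_identical(suite, suite2)
})
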