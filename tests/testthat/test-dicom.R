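test_that("RT Plan files round-trip all pipeline fields", {
  s <- tiny_plan_setup(n_beams = 3)
  path <- tempfile(fileext = ".dcm")
  write_rtplan(s$plan, path)
  back <- read_rtplan(path)
  expect_equal(length(back$beams), 3L)
  expect_identical(back$case_name, s$plan$case_name)
  expect_identical(back$label, s$plan$label)
  for (bi in seq_along(s$plan$beams)) {
    b0 <- s$plan$beams[[bi]]; b1 <- back$beams[[bi]]
    expect_equal(b1$gantry_angle, b0$gantry_angle)
    expect_equal(b1$leaf_edges, b0$leaf_edges)
    for (ci in seq_along(b0$control_points)) {
      # leaf positions are written at 8 significant digits; positions on a
      # 0.1 mm-ish lattice round-trip bit-exactly
      expect_equal(b1$control_points[[ci]]$bank_a,
                   b0$control_points[[ci]]$bank_a, tolerance = 1e-6)
      expect_equal(b1$control_points[[ci]]$bank_b,
                   b0$control_points[[ci]]$bank_b, tolerance = 1e-6)
      expect_equal(b1$control_points[[ci]]$mu_weight,
                   b0$control_points[[ci]]$mu_weight, tolerance = 1e-6)
    }
  }
  unlink(path)
})

test_that("exact leaf positions survive a write/read cycle bit-exactly", {
  cp <- control_point(c(-12.5, -10.1), c(4.5, 20.3), 0.25)
  plan <- mlc_plan("prostate",
                   list(mlc_beam(45, list(cp, control_point(
                     c(-10, -8), c(2, 18), 0.75)), leaf_width = 5)))
  path <- tempfile(fileext = ".dcm")
  write_rtplan(plan, path)
  back <- read_rtplan(path)
  expect_identical(back$beams[[1]]$control_points[[1]]$bank_a, cp$bank_a)
  expect_identical(back$beams[[1]]$control_points[[1]]$bank_b, cp$bank_b)
  unlink(path)
})

test_that("injected plans survive the DICOM cycle within 1e-3 mm", {
  s <- tiny_plan_setup()
  err <- inject_random(s$plan, random_error_spec(1, seed = 21))
  path <- tempfile(fileext = ".dcm")
  write_rtplan(err, path)
  back <- read_rtplan(path)
  for (bi in seq_along(err$beams)) {
    for (ci in seq_along(err$beams[[bi]]$control_points)) {
      expect_lt(max(abs(back$beams[[bi]]$control_points[[ci]]$bank_a -
                          err$beams[[bi]]$control_points[[ci]]$bank_a)), 1e-3)
    }
  }
  unlink(path)
})

test_that("collision-violating plans are refused at write time", {
  plan <- mlc_plan("prostate",
                   list(mlc_beam(0, list(control_point(c(-10, -5), c(10, 5),
                                                       1)))))
  plan$beams[[1]]$control_points[[1]]$bank_a[2] <- 7  # corrupt
  path <- tempfile(fileext = ".dcm")
  expect_error(write_rtplan(plan, path), "leaf row\\(s\\) 2")
  expect_false(file.exists(path))
})

test_that("RT Dose files round-trip geometry exactly and dose to a quantum", {
  set.seed(10)
  v <- array(runif(12 * 10 * 4, 0, 2.5), c(12, 10, 4))
  g <- dose_grid(v, spacing = c(2, 2, 3), origin = c(-11, -9, -4.5))
  path <- tempfile(fileext = ".dcm")
  write_rtdose(g, path)
  back <- read_rtdose(path)
  expect_identical(dim(back$values), dim(g$values))
  expect_equal(back$spacing, g$spacing)
  expect_equal(back$origin, g$origin)
  quantum <- 10^ceiling(log10(max(v) / (2^31 - 1)))
  expect_lte(max(abs(back$values - g$values)), quantum)
  unlink(path)

  const <- dose_grid(array(2, c(6, 6, 2)))
  write_rtdose(const, path)
  expect_equal(unique(as.numeric(read_rtdose(path)$values)), 2,
               tolerance = 1e-8)
  unlink(path)
})

test_that("reader rejects non-uniform slice spacing and wrong SOP class", {
  path <- tempfile(fileext = ".dcm")
  s <- tiny_plan_setup(n_beams = 1)
  write_rtplan(s$plan, path)
  expect_error(read_rtdose(path), "not an RT Dose")

  # hand-build a dose with irregular frame offsets via the writer internals
  g <- dose_grid(array(1, c(4, 4, 3)), spacing = c(2, 2, 2))
  write_rtdose(g, path)
  raw_bytes <- readBin(path, raw(), file.size(path))
  # GridFrameOffsetVector "0\2\4" -> make it "0\2\5"
  pat <- charToRaw("0\\2\\4")
  hit <- which(vapply(seq_len(length(raw_bytes) - length(pat) + 1L),
                      function(i) all(raw_bytes[i:(i + length(pat) - 1L)] ==
                                        pat), logical(1)))[1]
  raw_bytes[hit + length(pat) - 1L] <- charToRaw("5")
  writeBin(raw_bytes, path)
  expect_error(read_rtdose(path), "non-uniform slice spacing")
  unlink(path)
})

test_that("files we write are readable by an independent DICOM implementation", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  s <- tiny_plan_setup(n_beams = 2)
  path <- tempfile(fileext = ".dcm")
  write_rtplan(s$plan, path)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "import pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "cp = ds.BeamSequence[0].ControlPointSequence[0]",
    "pos = [float(x) for x in cp.BeamLimitingDevicePositionSequence[0].LeafJawPositions]",
    "print(json.dumps({'n_beams': len(ds.BeamSequence), 'pos': pos}))"),
    script)
  out <- suppressWarnings(system2(py, c(script, path), stdout = TRUE,
                                  stderr = FALSE))
  skip_if(length(out) == 0 || !nzchar(out[1]), "pydicom unavailable")
  parsed <- jsonlite::fromJSON(out[length(out)])
  expect_equal(parsed$n_beams, 2L)
  cp <- s$plan$beams[[1]]$control_points[[1]]
  expect_equal(parsed$pos, c(cp$bank_a, cp$bank_b), tolerance = 1e-6)
  unlink(c(path, script))
})
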