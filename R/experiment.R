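#' Experiment configuration
#'
#' Fully describes one end-to-end run: cases, suite sizes, error magnitudes,
#' index settings, class schemes, split and seed. A run is a deterministic
#' function of (config, seed, code version).
#'
#' @param cases character vector of case names ([mlcqa_cases()]).
#' @param n_beams beams per case (the per-beam dose map is the analysis
#'   unit; the study's suites used 36/28/36 beams per case).
#' @param n_control_points segments per beam.
#' @param systematic_shifts mm; cycled over the beams so every beam
#'   contributes one sub-systematic map (default 0.5, 1, 1.5, 2).
#' @param random_mus mm; cycled over the random-error beams (default
#'   0, 1, 2).
#' @param random_fraction fraction of beams receiving random errors
#'   (default 0.75, mirroring 27 random-error beams out of 36).
#' @param gamma_criteria_list list of [gamma_criteria()] evaluated per beam.
#' @param ssim an [ssim_config()].
#' @param engine a [dose_engine_config()].
#' @param class_schemes subset of `"Class_I"`, `"Class_II"`, `"Class_III"`:
#'   I = error-free vs (systematic + random), II = error-free vs
#'   systematic, III = error-free vs random.
#' @param split_fraction training fraction (default 0.7).
#' @param cv_folds,cv_repeats cross-validation geometry (defaults 10, 10,
#'   the study's repeated 10-fold CV; smaller suites need fewer folds so
#'   that every fold sees both classes).
#' @param phantom_dim phantom lattice dimensions.
#' @param dvh if `TRUE`, run the 3D dose / DVH comparison stage.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(cases = "head_and_neck", n_beams = 12,
                              n_control_points = 5,
                              systematic_shifts = c(0.5, 1, 1.5, 2),
                              random_mus = c(0, 1, 2),
                              random_fraction = 0.75,
                              gamma_criteria_list = list(
                                gamma_criteria(3, 3), gamma_criteria(3, 2),
                                gamma_criteria(2, 2), gamma_criteria(1, 1)),
                              ssim = ssim_config(),
                              engine = dose_engine_config(),
                              class_schemes = c("Class_I", "Class_II",
                                                "Class_III"),
                              split_fraction = 0.7,
                              cv_folds = 10, cv_repeats = 10,
                              phantom_dim = c(48L, 48L, 48L),
                              dvh = TRUE, seed = 1) {
  cases <- match.arg(cases, mlcqa_cases(), several.ok = TRUE)
  class_schemes <- match.arg(class_schemes,
                             c("Class_I", "Class_II", "Class_III"),
                             several.ok = TRUE)
  structure(as.list(environment()), class = "experiment_config")
}

scheme_classes <- function(scheme) {
  switch(scheme,
         Class_I = c("sub_error_free", "sub_systematic", "sub_random"),
         Class_II = c("sub_error_free", "sub_systematic"),
         Class_III = c("sub_error_free", "sub_random"),
         stop("unknown scheme ", scheme))
}

map_indices_row <- function(free_map, err_map, sub_map, config) {
  feats <- extract_features(sub_map)
  gam <- vapply(config$gamma_criteria_list, function(cr) {
    gamma_index(free_map, err_map, cr)$pass_rate
  }, numeric(1))
  names(gam) <- vapply(config$gamma_criteria_list, function(cr) {
    sprintf("gamma_%g_%g", cr$dose_tolerance, cr$dta)
  }, character(1))
  ss <- ssim_index(free_map$values * 100, err_map$values * 100, config$ssim)
  c(feats, gam,
    ssim = ss$ssim, ssim_luminance = ss$luminance,
    ssim_contrast = ss$contrast, ssim_structure = ss$structure)
}

#' Build the per-beam index table for one case
#'
#' Simulates the error-free plan, injects errors, computes per-beam dose
#' maps, forms the three classes of subtracted maps, and rows of
#' 34 dosiomics features + gamma pass rates + SSIM components. Every beam
#' contributes one sub-error-free and one sub-systematic map (shift cycled
#' over `systematic_shifts`); the first `random_fraction` of beams
#' contribute one sub-random map each (mean cycled over `random_mus`).
#'
#' @param case_name case to simulate.
#' @param config an [experiment_config()].
#' @return data frame: metadata columns (case, beam, class_label,
#'   magnitude, label) followed by index columns.
#' @export
build_case_table <- function(case_name, config) {
  case_idx <- match(case_name, mlcqa_cases())
  phantom <- make_phantom(case_name,
                          default_phantom_spec(case_name,
                                               dim = config$phantom_dim))
  plan <- make_plan(phantom, config$n_beams, config$n_control_points,
                    seed = config$seed + 100L * case_idx)
  noise_seed <- config$seed + 100L * case_idx + 1L
  free <- compute_dose(plan, phantom, config$engine, seed = noise_seed,
                       volume = FALSE)

  n <- config$n_beams
  shift_of <- rep_len(config$systematic_shifts, n)
  n_rand <- round(config$random_fraction * n)
  mu_of <- rep_len(config$random_mus, n_rand)

  sys_plans <- lapply(unique(shift_of), function(s) {
    compute_dose(inject_systematic(plan, systematic_error_spec(s)),
                 phantom, config$engine, seed = noise_seed + 10L,
                 volume = FALSE)
  })
  names(sys_plans) <- as.character(unique(shift_of))
  rnd_plans <- lapply(unique(mu_of), function(m) {
    spec <- random_error_spec(m, seed = config$seed + 100L * case_idx +
                                7L * match(m, unique(mu_of)))
    compute_dose(inject_random(plan, spec), phantom, config$engine,
                 seed = noise_seed + 20L, volume = FALSE)
  })
  names(rnd_plans) <- as.character(unique(mu_of))

  rows <- list()
  add_row <- function(meta, idx_row) {
    rows[[length(rows) + 1L]] <<- cbind(meta, as.data.frame(t(idx_row)))
  }
  for (b in seq_len(n)) {
    fmap <- free$beam_maps[[b]]
    # sub-error-free: 0.01 mm-shifted stand-in minus the original
    sim <- make_simulated_error_free(fmap)
    add_row(data.frame(case = case_name, beam = b,
                       class_label = "sub_error_free", magnitude = 0,
                       label = 0L),
            map_indices_row(fmap, sim,
                            subtract_dose(sim, fmap, "sub_error_free"),
                            config))
    smap <- sys_plans[[as.character(shift_of[b])]]$beam_maps[[b]]
    add_row(data.frame(case = case_name, beam = b,
                       class_label = "sub_systematic",
                       magnitude = shift_of[b], label = 1L),
            map_indices_row(fmap, smap,
                            subtract_dose(smap, fmap, "sub_systematic"),
                            config))
    if (b <= n_rand) {
      rmap <- rnd_plans[[as.character(mu_of[b])]]$beam_maps[[b]]
      add_row(data.frame(case = case_name, beam = b,
                         class_label = "sub_random",
                         magnitude = mu_of[b], label = 1L),
              map_indices_row(fmap, rmap,
                              subtract_dose(rmap, fmap, "sub_random"),
                              config))
    }
  }
  do.call(rbind, rows)
}

dvh_stage <- function(case_name, config) {
  case_idx <- match(case_name, mlcqa_cases())
  phantom <- make_phantom(case_name,
                          default_phantom_spec(case_name,
                                               dim = config$phantom_dim))
  plan <- make_plan(phantom, config$n_beams, config$n_control_points,
                    seed = config$seed + 100L * case_idx)
  free <- compute_dose(plan, phantom, config$engine, seed = NULL,
                       volume = TRUE)
  out <- list()
  for (s in config$systematic_shifts) {
    err <- compute_dose(inject_systematic(plan, systematic_error_spec(s)),
                        phantom, config$engine, seed = NULL,
                        scale = free$scale, volume = TRUE)
    dd <- dvh_relative_difference(free$dose, err$dose, phantom$structures)
    dd$error_type <- "systematic"; dd$magnitude <- s
    out[[length(out) + 1L]] <- dd
  }
  for (m in config$random_mus) {
    spec <- random_error_spec(m, seed = config$seed + 100L * case_idx +
                                31L * match(m, config$random_mus))
    err <- compute_dose(inject_random(plan, spec), phantom, config$engine,
                        seed = NULL, scale = free$scale, volume = TRUE)
    dd <- dvh_relative_difference(free$dose, err$dose, phantom$structures)
    dd$error_type <- "random"; dd$magnitude <- m
    out[[length(out) + 1L]] <- dd
  }
  res <- do.call(rbind, out)
  res$case <- case_name
  res
}

#' Run the full error-characterisation experiment
#'
#' Executes the whole workflow on synthetic suites: simulate plans and
#' doses, inject systematic and random MLC errors, compute gamma / SSIM /
#' dosiomics indices on (subtracted) per-beam dose maps, z-score, run the
#' selection cascade and train gated logistic-regression classifiers per
#' class scheme, and (optionally) quantify DVH differences. Deterministic
#' given the config seed.
#'
#' @param config an [experiment_config()].
#' @return list of class `run_report`: `feature_table`, per-scheme
#'   `selection` and `models`, `index_summary` (mean gamma/SSIM per error
#'   type and magnitude), `dvh` (or `NULL`), `config`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  tabs <- lapply(config$cases, build_case_table, config = config)
  feature_table <- do.call(rbind, tabs)

  meta_cols <- c("case", "beam", "class_label", "magnitude", "label")
  idx_cols <- setdiff(names(feature_table), meta_cols)
  models <- list(); selections <- list()
  for (scheme in config$class_schemes) {
    keep <- feature_table$class_label %in% scheme_classes(scheme)
    sub <- feature_table[keep, , drop = FALSE]
    x <- suppressWarnings(zscore_features(sub[, idx_cols, drop = FALSE]))
    x <- x[, colSums(is.na(x)) == 0, drop = FALSE]
    sel <- select_indices(x, sub$label)
    selections[[scheme]] <- sel
    feats <- sel$surviving
    if (length(feats) == 0L) {
      models[[scheme]] <- NULL
      next
    }
    models[[scheme]] <- train_and_evaluate(
      x[, feats, drop = FALSE], sub$label,
      split_fraction = config$split_fraction, seed = config$seed,
      cv_folds = config$cv_folds, cv_repeats = config$cv_repeats)
  }

  grp <- interaction(feature_table$class_label, feature_table$magnitude,
                     drop = TRUE)
  summary_cols <- intersect(c(grep("^gamma_", idx_cols, value = TRUE),
                              "ssim", "ssim_luminance", "ssim_contrast",
                              "ssim_structure"), idx_cols)
  index_summary <- aggregate(feature_table[, summary_cols],
                             by = list(class_label = feature_table$class_label,
                                       magnitude = feature_table$magnitude),
                             FUN = mean)

  dvh <- if (isTRUE(config$dvh)) {
    do.call(rbind, lapply(config$cases, dvh_stage, config = config))
  } else NULL

  structure(list(feature_table = feature_table, selection = selections,
                 models = models, index_summary = index_summary,
                 dvh = dvh, config = config),
            class = "run_report")
}

#' Write a run report to disk
#'
#' Emits `feature_table.csv`, `index_summary.csv`, `dvh.csv` (when
#' present), and `report.json` (selection, model metrics, gate flags,
#' config echo) under `dir`.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$feature_table, file.path(dir, "feature_table.csv"),
            row.names = FALSE)
  write.csv(report$index_summary, file.path(dir, "index_summary.csv"),
            row.names = FALSE)
  if (!is.null(report$dvh)) {
    write.csv(report$dvh, file.path(dir, "dvh.csv"), row.names = FALSE)
  }
  js <- list(
    seed = report$config$seed,
    cases = report$config$cases,
    schemes = lapply(names(report$models), function(s) {
      m <- report$models[[s]]
      list(scheme = s,
           selected = report$selection[[s]]$surviving,
           metrics = as.list(m$metrics),
           model_p = m$model_p,
           final_model = m$final_model,
           n_train = m$n_train, n_test = m$n_test)
    }))
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
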