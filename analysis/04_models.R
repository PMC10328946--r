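#!/usr/bin/env Rscript
# Stage 4: index selection and gated logistic-regression classifiers for the
# three class schemes on the head-and-neck suite (36 error-free / 36
# systematic 2 mm / 27 random mu = 1 mm beams). Writes selection and model
# reports and prints the acceptance-gate outcome per scheme.

suppressMessages(library(mlcqa))

config <- experiment_config(
  cases = "head_and_neck",
  n_beams = 36, n_control_points = 5,
  systematic_shifts = 2, random_mus = 1, random_fraction = 0.75,
  gamma_criteria_list = list(gamma_criteria(3, 2), gamma_criteria(2, 2)),
  class_schemes = c("Class_I", "Class_II", "Class_III"),
  split_fraction = 0.7, dvh = FALSE, seed = 2026L)

report <- run_experiment(config)
write_run_report(report, "results/models")

for (scheme in names(report$models)) {
  m <- report$models[[scheme]]
  message(sprintf(
    "%-9s selected [%s]  auc=%.3f acc=%.3f prec=%.3f sens=%.3f spec=%.3f  p=%.2g  final=%s",
    scheme, paste(m$features, collapse = ", "),
    m$metrics[["auc"]], m$metrics[["accuracy"]], m$metrics[["precision"]],
    m$metrics[["sensitivity"]], m$metrics[["specificity"]],
    m$model_p, m$final_model))
}
message("full reports under results/models/")
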