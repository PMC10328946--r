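#' Holm-Bonferroni step-down adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "holm")`: step-down
#' adjustment with enforced monotonicity, clipped at 1.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
holm_bonferroni <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = "holm")
}

#' Spearman correlation filter
#'
#' Computes all pairwise Spearman rank correlations with Holm-Bonferroni
#' adjusted p-values; for every significant pair with `|rho|` above the
#' threshold, one member is removed. The tie-break drops the member with
#' the larger mean `|rho|` against all other remaining features (keeping
#' the less redundant index). Constant columns are dropped with a warning
#' (rho undefined).
#'
#' @param table data frame of numeric feature columns.
#' @param rho_threshold removal threshold on `|rho|` (default 0.8).
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return list of class `selection_stage`: `surviving` (names),
#'   `removed` (data frame: feature, partner, rho, p_adjusted).
#' @export
correlation_filter <- function(table, rho_threshold = 0.8, alpha = 0.05) {
  table <- as.data.frame(table)
  stopifnot(ncol(table) >= 2L, nrow(table) >= 3L)
  sds <- vapply(table, sd, numeric(1))
  if (any(sds == 0 | is.na(sds))) {
    warning("dropping constant column(s): ",
            paste(names(table)[sds == 0 | is.na(sds)], collapse = ", "))
    table <- table[, !(sds == 0 | is.na(sds)), drop = FALSE]
  }
  nm <- names(table)
  k <- length(nm)
  rho <- suppressWarnings(cor(table, method = "spearman"))
  pr <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    pr[a, b] <- pr[b, a] <- suppressWarnings(
      cor.test(table[[a]], table[[b]], method = "spearman")$p.value)
  }
  padj <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  ut <- upper.tri(pr)
  padj[ut] <- holm_bonferroni(pr[ut])
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]

  alive <- nm
  removed <- data.frame(feature = character(), partner = character(),
                        rho = numeric(), p_adjusted = numeric())
  repeat {
    sub_r <- rho[alive, alive, drop = FALSE]
    sub_p <- padj[alive, alive, drop = FALSE]
    hot <- which(abs(sub_r) > rho_threshold & sub_p < alpha &
                   upper.tri(sub_r), arr.ind = TRUE)
    if (nrow(hot) == 0) break
    # worst pair first
    worst <- hot[which.max(abs(sub_r[hot])), , drop = FALSE]
    a <- alive[worst[1]]; b <- alive[worst[2]]
    mean_abs <- function(f) mean(abs(rho[f, setdiff(alive, f)]))
    drop_f <- if (mean_abs(a) >= mean_abs(b)) a else b
    keep_f <- if (drop_f == a) b else a
    removed <- rbind(removed, data.frame(
      feature = drop_f, partner = keep_f,
      rho = rho[drop_f, keep_f], p_adjusted = padj[drop_f, keep_f]))
    alive <- setdiff(alive, drop_f)
    if (length(alive) < 2L) break
  }
  structure(list(surviving = alive, removed = removed),
            class = "selection_stage")
}

fit_logistic <- function(table, labels, features = names(table)) {
  df <- as.data.frame(table)[, features, drop = FALSE]
  df$.y <- labels
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  attr(fit, "separation") <- sep
  fit
}

#' Backward stepwise elimination (AIC)
#'
#' Starts from the full logistic model on all candidate features and
#' removes terms by AIC (`stats::step`, backward) until no removal improves
#' the criterion. Perfect separation is flagged; when it occurs, ridge
#' (L2-penalised) coefficients are additionally reported as a stabilised
#' reference fit, and the AIC trace is interpreted with caution.
#'
#' @param table data frame of numeric feature columns.
#' @param labels 0/1 vector (or factor) of class labels.
#' @return list of class `selection_stage`: `surviving`, `removed`, `trace`
#'   (the AIC steps), `separation` flag, and `penalized_coefficients`
#'   (ridge, only when separation was detected and glmnet is available).
#' @export
backward_stepwise <- function(table, labels) {
  table <- as.data.frame(table)
  stopifnot(ncol(table) >= 1L)
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  # step() re-evaluates the glm call in this frame, so `df` must live here
  df <- table
  df$.y <- y
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  red <- suppressWarnings(step(fit, direction = "backward", trace = 0))
  surv <- setdiff(names(coef(red)), "(Intercept)")
  surv <- intersect(names(table), sub("^`|`$", "", surv))
  pen <- NULL
  if (sep && requireNamespace("glmnet", quietly = TRUE) && ncol(table) >= 2L) {
    gfit <- glmnet::glmnet(as.matrix(table), y, family = "binomial",
                           alpha = 0, lambda = 0.05)
    pen <- as.numeric(coef(gfit))
    names(pen) <- rownames(coef(gfit))
  }
  structure(list(surviving = surv,
                 removed = setdiff(names(table), surv),
                 trace = red$anova, separation = sep,
                 penalized_coefficients = pen),
            class = "selection_stage")
}

#' Variance-inflation-factor filter
#'
#' Computes each feature's VIF, `1 / (1 - R^2)` of the feature regressed on
#' all the others, and iteratively drops the highest-VIF feature while any
#' VIF is at or above the limit. Singular designs give `R^2 ~ 1` and are
#' therefore dropped first.
#'
#' @param table data frame of numeric feature columns (at least 2).
#' @param limit removal limit (default 4: features with `VIF >= 4` go).
#' @return list of class `selection_stage`: `surviving`, `removed`
#'   (data frame feature/vif), `vif` (final values).
#' @export
vif_filter <- function(table, limit = 4) {
  table <- as.data.frame(table)
  stopifnot(ncol(table) >= 2L)
  vif_of <- function(df) {
    vapply(seq_along(df), function(j) {
      r2 <- summary(lm(df[[j]] ~ ., data = df[, -j, drop = FALSE]))$r.squared
      r2 <- min(r2, 1 - 1e-12)
      1 / (1 - r2)
    }, numeric(1))
  }
  alive <- table
  removed <- data.frame(feature = character(), vif = numeric())
  while (ncol(alive) >= 2L) {
    v <- vif_of(alive)
    if (max(v) < limit) break
    j <- which.max(v)
    removed <- rbind(removed,
                     data.frame(feature = names(alive)[j], vif = v[j]))
    alive <- alive[, -j, drop = FALSE]
  }
  final_vif <- if (ncol(alive) >= 2L) setNames(vif_of(alive), names(alive))
    else setNames(rep(1, ncol(alive)), names(alive))
  structure(list(surviving = names(alive), removed = removed,
                 vif = final_vif),
            class = "selection_stage")
}

#' Run the full index-selection cascade
#'
#' Applies the stages in the study's fixed order: Spearman correlation
#' filter (Holm-adjusted, `|rho| > 0.8`), backward stepwise elimination
#' (AIC), then VIF `< 4`. The order is not configurable.
#'
#' @param table data frame of numeric feature columns.
#' @param labels 0/1 class labels (error-free = 0, error = 1).
#' @param rho_threshold,alpha,vif_limit stage parameters.
#' @return list of class `selection_report` with per-stage results and
#'   `surviving`.
#' @export
select_indices <- function(table, labels, rho_threshold = 0.8, alpha = 0.05,
                           vif_limit = 4) {
  s1 <- correlation_filter(table, rho_threshold, alpha)
  t1 <- as.data.frame(table)[, s1$surviving, drop = FALSE]
  s2 <- backward_stepwise(t1, labels)
  surviving <- s2$surviving
  s3 <- NULL
  if (length(surviving) >= 2L) {
    s3 <- vif_filter(t1[, surviving, drop = FALSE], vif_limit)
    surviving <- s3$surviving
  }
  structure(list(correlation = s1, stepwise = s2, vif = s3,
                 surviving = surviving),
            class = "selection_report")
}
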