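#' Paired t-test for serial QTc change
#'
#' Two-sided paired Student t-test between two timepoints measured on the
#' same subjects.  Identical vectors are the boundary case t = 0, p = 1; a
#' nonzero constant shift has zero variance of the differences and the t
#' statistic is undefined, reported as a degenerate-test error.
#'
#' @param a,b Paired numeric vectors (same subjects, two timepoints),
#'   n >= 3.
#' @return List: `t`, `df`, `p`, `mean_diff`, `ci` (95% CI of the mean
#'   difference).
#' @export
paired_qtc_test <- function(a, b) {
  qts_check(is.numeric(a) && is.numeric(b), "invalid_parameter",
            "inputs must be numeric")
  qts_check(length(a) == length(b), "invalid_parameter",
            "paired samples must have equal length")
  qts_check(length(a) >= 3, "invalid_parameter", "need n >= 3 pairs")
  qts_check(all(is.finite(a)) && all(is.finite(b)), "invalid_parameter",
            "non-finite values in paired samples")
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, df = length(d) - 1L, p = 1, mean_diff = 0,
                  ci = c(0, 0)))
    qts_error("degenerate_test",
              "constant nonzero difference: paired t statistic undefined")
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = unname(tt$estimate), ci = as.numeric(tt$conf.int))
}

#' Spearman rank correlation
#'
#' Rank correlation with mid-ranks for ties (equivalently, Pearson
#' correlation of the rank vectors), invariant under strictly monotone
#' transforms of either argument.
#'
#' @param x,y Numeric vectors, equal length, n >= 3.
#' @return List: `r`, `p` (two-sided), `n`.
#' @export
spearman_cor <- function(x, y) {
  qts_check(is.numeric(x) && is.numeric(y) && length(x) == length(y),
            "invalid_parameter", "x and y must be numeric, equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  qts_check(length(x) >= 3, "invalid_parameter", "need n >= 3")
  qts_check(sd(x) > 0 && sd(y) > 0, "undefined_correlation",
            "correlation undefined for constant input")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

## ---- model-result container ----------------------------------------------

new_model_result <- function(type, coefficients, n, outcome,
                             r2 = NA_real_, adj_r2 = NA_real_,
                             separated = FALSE, n_dropped = 0L) {
  structure(list(type = type, coefficients = coefficients, n = n,
                 outcome = outcome, r2 = r2, adj_r2 = adj_r2,
                 separated = separated, n_dropped = n_dropped),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s regression, outcome: %s, n = %d\n",
              x$type, x$outcome, x$n))
  if (x$separated) {
    cat("  complete separation detected: no estimates reported\n")
    return(invisible(x))
  }
  est_lab <- if (x$type == "logistic") "OR" else "Coeff."
  cat(sprintf("  %-28s %10s (Std. Err.)  P-value   95%% CI\n", "",
              est_lab))
  co <- x$coefficients
  for (i in seq_len(nrow(co)))
    cat(sprintf("  %-28s %10.3f (%.3f)  %8.4g   (%.3f-%.3f)\n",
                co$term[i], co$estimate[i], co$se[i], co$p[i],
                co$ci_lo[i], co$ci_hi[i]))
  if (!is.na(x$r2))
    cat(sprintf("  R2 %.3f, adjusted R2 %.3f\n", x$r2, x$adj_r2))
  invisible(x)
}

## rows with finite values in all used columns; returns index + count message
finite_rows <- function(data, cols) {
  ok <- rep(TRUE, nrow(data))
  for (cl in cols) {
    v <- data[[cl]]
    ok <- ok & if (is.numeric(v)) is.finite(v) else !is.na(v)
  }
  dropped <- sum(!ok)
  if (dropped > 0)
    message(sprintf("dropping %d row(s) with non-finite values", dropped))
  ok
}

#' Univariate screen of candidate predictors
#'
#' Fits each candidate alone against the outcome (ordinary least squares
#' for a continuous outcome, logistic regression for a binary one) and
#' flags the candidates whose two-sided Wald p-value falls below `alpha`
#' (default 0.1) for entry into the multivariable model.
#'
#' @param data Cohort data frame.
#' @param outcome Name of the outcome column.  Logical/binary columns get a
#'   logistic fit, numeric ones a linear fit (`type` overrides).
#' @param candidates Character vector of candidate predictor columns.
#' @param alpha Screening level (default 0.1).
#' @param type `"auto"`, `"linear"` or `"logistic"`.
#' @return Data frame: `variable`, `estimate`, `se`, `p`, `selected`; the
#'   screening level is carried in the `"alpha"` attribute.  Rows with
#'   non-finite values are dropped per candidate with a message.
#' @export
univariate_screen <- function(data, outcome, candidates, alpha = 0.1,
                              type = c("auto", "linear", "logistic")) {
  type <- match.arg(type)
  qts_check(is.data.frame(data) && outcome %in% names(data),
            "invalid_parameter", "`outcome` not found in `data`")
  qts_check(all(candidates %in% names(data)), "invalid_parameter",
            sprintf("candidate column(s) missing: %s",
                    paste(setdiff(candidates, names(data)), collapse = ", ")))
  check_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  y_raw <- data[[outcome]]
  if (type == "auto") {
    binary <- is.logical(y_raw) ||
      length(unique(y_raw[!is.na(y_raw)])) == 2L
    type <- if (binary) "logistic" else "linear"
  }
  out <- data.frame(variable = character(0), estimate = numeric(0),
                    se = numeric(0), p = numeric(0), selected = logical(0))
  for (v in candidates) {
    ok <- finite_rows(data, c(outcome, v))
    d <- data.frame(.y = y_raw[ok], .x = data[[v]][ok])
    if (is.character(d$.x)) d$.x <- factor(d$.x)
    est <- se <- p <- NA_real_
    fit <- tryCatch({
      if (type == "logistic")
        suppressWarnings(glm(.y ~ .x, data = d, family = binomial()))
      else lm(.y ~ .x, data = d)
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      sm <- coef(summary(fit))
      if (nrow(sm) >= 2 && !is.na(sm[2, 1])) {
        est <- sm[2, 1]; se <- sm[2, 2]; p <- sm[2, 4]
      }
    }
    out <- rbind(out, data.frame(variable = v, estimate = est, se = se,
                                 p = p, selected = !is.na(p) && p < alpha))
  }
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

coef_table <- function(fit, transform = identity, wald = FALSE) {
  sm <- coef(summary(fit))
  ci <- if (wald) suppressMessages(stats::confint.default(fit)) else
    suppressMessages(confint(fit))
  data.frame(term = rownames(sm), estimate = transform(sm[, 1]),
             se = sm[, 2], p = sm[, 4],
             ci_lo = transform(ci[, 1]), ci_hi = transform(ci[, 2]),
             row.names = NULL)
}

check_full_rank <- function(fit) {
  cf <- coef(fit)
  if (anyNA(cf))
    qts_error("rank_deficient",
              sprintf("design is rank deficient; aliased column(s): %s",
                      paste(names(cf)[is.na(cf)], collapse = ", ")))
  invisible(TRUE)
}

#' Linear model for log-transformed infarct mass
#'
#' Ordinary least squares of the natural log of the LGE mass on the
#' selected predictors.  Subjects with zero (or negative) LGE -- complete
#' salvage, log undefined -- are excluded with a message; they remain
#' available to the logistic/ROC analyses.
#'
#' @param data Cohort data frame.
#' @param variables Predictor column names (e.g. survivors of
#'   [univariate_screen()]).
#' @param lge_col Column holding the LGE mass (g or %LV), default
#'   `"lge_g"`.
#' @return A [`model_result`][print.model_result] with coefficient table
#'   (estimate, SE, p, 95% CI), R^2 and adjusted R^2.
#' @export
fit_linear_log_lge <- function(data, variables, lge_col = "lge_g") {
  qts_check(is.data.frame(data) && lge_col %in% names(data),
            "invalid_parameter", sprintf("column `%s` not found", lge_col))
  qts_check(length(variables) >= 1 && all(variables %in% names(data)),
            "invalid_parameter", "predictor column(s) missing from `data`")
  pos <- !is.na(data[[lge_col]]) & data[[lge_col]] > 0
  n_zero <- sum(!pos)
  if (n_zero > 0)
    message(sprintf(
      "dropping %d subject(s) with zero LGE (log undefined)", n_zero))
  d <- data[pos, , drop = FALSE]
  ok <- finite_rows(d, c(lge_col, variables))
  d <- d[ok, , drop = FALSE]
  d$.y <- log(d[[lge_col]])
  f <- stats::reformulate(variables, response = ".y")
  fit <- lm(f, data = d)
  check_full_rank(fit)
  sm <- summary(fit)
  new_model_result("linear", coef_table(fit), n = nrow(d),
                   outcome = sprintf("log(%s)", lge_col),
                   r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                   n_dropped = n_zero + sum(!ok))
}

#' Logistic model for poor myocardial salvage
#'
#' Maximum-likelihood logistic regression of the salvage outcome on the
#' selected predictors, reporting odds ratios with Wald 95% confidence
#' intervals.  The outcome coding is explicit: with `event = "below"` (the
#' default) the modelled event is MSI < `msi_cut` (poor salvage); the
#' switch exposes the opposite coding.  Complete separation is flagged and
#' no estimates are returned.
#'
#' @inheritParams fit_linear_log_lge
#' @param msi_cut Salvage threshold defining the event (default 0.6).
#' @param msi_col Column holding MSI, default `"msi"`.
#' @param event `"below"`: event is MSI < cut; `"above"`: MSI >= cut.
#' @return A [`model_result`][print.model_result]; `coefficients$estimate`
#'   are odds ratios, `se` is on the log-odds scale.
#' @export
fit_logistic_msi <- function(data, variables, msi_cut = 0.6,
                             msi_col = "msi", event = c("below", "above")) {
  event <- match.arg(event)
  qts_check(is.data.frame(data) && msi_col %in% names(data),
            "invalid_parameter", sprintf("column `%s` not found", msi_col))
  qts_check(length(variables) >= 1 && all(variables %in% names(data)),
            "invalid_parameter", "predictor column(s) missing from `data`")
  check_number(msi_cut, "msi_cut", lower = 0, upper = 1,
               strict_lower = TRUE)
  ok <- finite_rows(data, c(msi_col, variables))
  d <- data[ok, , drop = FALSE]
  y <- if (event == "below") d[[msi_col]] < msi_cut else
    d[[msi_col]] >= msi_cut
  qts_check(length(unique(y)) == 2, "one_class",
            "both outcome classes must be present")
  d$.y <- y
  f <- stats::reformulate(variables, response = ".y")
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(f, data = d, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  check_full_rank(fit)
  outcome <- sprintf("%s %s %.2f", msi_col,
                     if (event == "below") "<" else ">=", msi_cut)
  if (separated)
    return(new_model_result("logistic", NULL, n = nrow(d),
                            outcome = outcome, separated = TRUE,
                            n_dropped = sum(!ok)))
  new_model_result("logistic", coef_table(fit, transform = exp, wald = TRUE),
                   n = nrow(d), outcome = outcome, n_dropped = sum(!ok))
}

#' Empirical ROC curve with the Youden-optimal cut-off
#'
#' Computes the empirical ROC of a continuous score against a binary
#' outcome over all observed thresholds (rule: positive when
#' `score >= threshold`, so a score that rises with event risk gives
#' AUC > 0.5).  The AUC is the trapezoidal area, identical to the
#' Mann--Whitney U statistic rescaled (ties counted 1/2).  The reported
#' cut-off maximizes the Youden index J = sensitivity + specificity - 1;
#' ties in J are broken toward higher specificity, then toward the higher
#' threshold.
#'
#' @param scores Numeric scores.
#' @param outcome Binary outcome (logical, 0/1, or 2-level factor with the
#'   event as the second level).
#' @return Object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `cutoff`, `sensitivity_at_cutoff`,
#'   `specificity_at_cutoff`, `youden`.
#' @export
roc_youden <- function(scores, outcome) {
  qts_check(is.numeric(scores) && all(is.finite(scores)),
            "invalid_parameter", "`scores` must be finite numeric")
  if (is.factor(outcome)) outcome <- outcome == levels(outcome)[2]
  outcome <- as.logical(outcome)
  qts_check(length(outcome) == length(scores) && !anyNA(outcome),
            "invalid_parameter", "`outcome` must be binary, same length")
  qts_check(any(outcome) && any(!outcome), "one_class",
            "both outcome classes must be present")
  thr <- c(sort(unique(scores)), Inf)
  pos <- scores[outcome]; neg <- scores[!outcome]
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  ## trapezoidal AUC over the ROC polygon (fpr increasing)
  fpr <- rev(1 - spec); tpr <- rev(sens)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  j <- sens + spec - 1
  best <- which(j > max(j) - 1e-12)
  best <- best[order(spec[best], thr[best], decreasing = TRUE)][1]
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, cutoff = thr[best],
                 sensitivity_at_cutoff = sens[best],
                 specificity_at_cutoff = spec[best], youden = j[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f; Youden cut-off %g", x$auc, x$cutoff))
  cat(sprintf(" (sens %.0f%%, spec %.0f%%, J = %.2f)\n",
              100 * x$sensitivity_at_cutoff, 100 * x$specificity_at_cutoff,
              x$youden))
  invisible(x)
}

#' Cohen's kappa for observer agreement
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` between two
#' categorical rating vectors, with expected agreement from the product of
#' the marginal distributions.  When both raters use a single shared
#' category, pe = 1 and kappa is undefined (error).
#'
#' @param a,b Equal-length categorical vectors (factor, character, or
#'   values coercible to character).
#' @param categories Optional explicit category set (needed when a category
#'   is absent from the data).
#' @return List: `kappa`, `observed_agreement`, `expected_agreement`,
#'   `table` (the confusion matrix).
#' @export
cohen_kappa <- function(a, b, categories = NULL) {
  qts_check(length(a) == length(b) && length(a) >= 1, "invalid_parameter",
            "ratings must have equal, positive length")
  if (is.null(categories))
    categories <- sort(unique(c(as.character(a), as.character(b))))
  fa <- factor(as.character(a), levels = categories)
  fb <- factor(as.character(b), levels = categories)
  qts_check(!anyNA(fa) && !anyNA(fb), "invalid_parameter",
            "ratings contain values outside `categories`")
  tab <- table(fa, fb)
  p <- tab / sum(tab)
  po <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  qts_check(pe < 1, "undefined_kappa",
            "kappa undefined: a single shared category (pe = 1)")
  list(kappa = (po - pe) / (1 - pe), observed_agreement = po,
       expected_agreement = pe, table = tab)
}
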