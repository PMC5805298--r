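# Independent oracles and small fixtures used across test files.

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Spearman oracle: mid-rank both vectors, then plain Pearson correlation.
spearman_oracle <- function(x, y) cor(rank(x), rank(y))

# ROC oracle: exhaustive enumeration over every candidate threshold
# (rule: positive when score >= t), trapezoidal AUC over the full polygon,
# Youden maximizer with ties broken toward higher specificity then higher
# threshold.  Written independently of the package implementation.
roc_oracle <- function(scores, outcome) {
  outcome <- as.logical(outcome)
  thr <- c(sort(unique(scores)), Inf)
  res <- t(vapply(thr, function(t) {
    c(sens = mean(scores[outcome] >= t),
      spec = mean(scores[!outcome] < t))
  }, numeric(2)))
  fpr <- 1 - res[, "spec"]; tpr <- res[, "sens"]
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(o)]) / 2)
  j <- res[, "sens"] + res[, "spec"] - 1
  cand <- which(abs(j - max(j)) < 1e-12)
  cand <- cand[order(res[cand, "spec"], thr[cand], decreasing = TRUE)][1]
  list(auc = auc, cutoff = thr[cand], j = max(j))
}

# Mann-Whitney AUC oracle: pairwise comparisons with ties counted 1/2.
auc_mann_whitney <- function(scores, outcome) {
  outcome <- as.logical(outcome)
  pos <- scores[outcome]; neg <- scores[!outcome]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Roster carrying the published per-criterion exclusion counts for a
# screening cohort of 86 anterior infarcts (8,6,2,4,3,2,2,2,4,1,2 across
# the eleven criteria; 50 subjects remain).
make_screening_roster <- function() {
  counts <- c(previous_mi = 8, af_or_antiarrhythmics = 6,
              catecholamines = 2, late_pci = 4, bundle_branch_block = 3,
              incomplete_reperfusion = 2, electrolyte_imbalance = 2,
              conduction_disorder = 2, qt_unmeasurable = 4,
              pericardial_effusion = 1, competing_trial = 2)
  n <- 86
  roster <- data.frame(subject_id = sprintf("P%02d", seq_len(n)))
  for (cr in exclusion_criteria()) roster[[cr]] <- rep(FALSE, n)
  at <- 0
  for (cr in names(counts)) {
    idx <- at + seq_len(counts[[cr]])
    roster[[cr]][idx] <- TRUE
    at <- at + counts[[cr]]
  }
  roster
}
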