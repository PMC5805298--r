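#' Exclusion criteria for the study filter
#'
#' Canonical flag names, in the protocol's a)--k) order: previous MI;
#' atrial fibrillation or antiarrhythmic drugs; catecholamine
#' administration; PCI performed more than 12 h after chest-pain onset;
#' bundle branch block; incomplete reperfusion; electrolyte imbalance;
#' conduction disorder (AV block or pre-excitation, one criterion);
#' technical difficulties in QT measurement; pericardial effusion;
#' enrolment in a competing trial.
#'
#' @return Character vector of the eleven flag column names, in order.
#' @export
exclusion_criteria <- function() {
  c("previous_mi", "af_or_antiarrhythmics", "catecholamines", "late_pci",
    "bundle_branch_block", "incomplete_reperfusion",
    "electrolyte_imbalance", "conduction_disorder", "qt_unmeasurable",
    "pericardial_effusion", "competing_trial")
}

#' Apply the exclusion filter to a subject roster
#'
#' Removes every subject carrying at least one exclusion flag and tabulates
#' exclusions per criterion.  A subject with several flags is counted under
#' the first matching criterion in the a)--k) order (so the per-criterion
#' counts are well defined and sum to the number excluded).
#'
#' @param roster Data frame with `subject_id` and one logical column per
#'   criterion in [exclusion_criteria()].
#' @return List: `included` (rows with no flag), `excluded` (rows with the
#'   assigned `reason`), `counts` (named integer vector per criterion),
#'   `n_input`, `n_excluded`, `n_included`.
#' @export
apply_exclusions <- function(roster) {
  crit <- exclusion_criteria()
  qts_check(is.data.frame(roster) && nrow(roster) >= 1, "invalid_parameter",
            "`roster` must be a non-empty data frame")
  qts_check(all(c("subject_id", crit) %in% names(roster)),
            "invalid_parameter",
            sprintf("roster missing column(s): %s",
                    paste(setdiff(c("subject_id", crit), names(roster)),
                          collapse = ", ")))
  flags <- as.matrix(roster[crit])
  qts_check(is.logical(flags) && !anyNA(flags), "invalid_parameter",
            "exclusion flags must be TRUE/FALSE without NA")
  any_flag <- rowSums(flags) > 0
  ## first matching criterion, in listed order
  reason <- rep(NA_character_, nrow(roster))
  reason[any_flag] <- crit[apply(flags[any_flag, , drop = FALSE], 1,
                                 which.max)]
  counts <- vapply(crit, function(cr) sum(reason == cr, na.rm = TRUE),
                   integer(1))
  excluded <- roster[any_flag, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[any_flag]
  list(included = roster[!any_flag, , drop = FALSE],
       excluded = excluded, counts = counts,
       n_input = nrow(roster), n_excluded = sum(any_flag),
       n_included = sum(!any_flag))
}

## Anterior lead weights used when synthesizing waveforms from a programmed
## dispersion.  The extreme anterior lead always carries the programmed
## value exactly (weight 1 is the max for positive dispersions, the min
## multiplier for negative ones), so max(anterior) - min(inferior)
## reproduces the programmed statistic in both directions.
ant_qtc_spread <- function(ma) {
  w <- if (ma >= 0) c(V2 = 1, V3 = 0.7, V4 = 0.6, V5 = 0.5) else
    c(V2 = 1.5, V3 = 1.2, V4 = 1.1, V5 = 1)
  ma * w
}

## Simulate + measure the serial ECGs for one subject, returning per-
## timepoint dispersion rows computed by the delineation pipeline itself.
measure_subject_ecgs <- function(cohort_row, rr_s, fs_hz, n_beats,
                                 noise_sd_mv, seed0) {
  rows <- vector("list", length(TIMEPOINTS))
  for (k in seq_along(TIMEPOINTS)) {
    tp <- TIMEPOINTS[k]
    qtc_inf <- cohort_row[[paste0("qtc_mean_", tp)]]
    ma <- cohort_row[[paste0("delta_ma_", tp)]]
    qtc <- c(qtc_inf + ant_qtc_spread(ma),
             II = qtc_inf, III = qtc_inf, aVF = qtc_inf)
    qt <- qtc * sqrt(rr_s)
    rec <- simulate_ecg(qt_ms = qt, rr_s = rr_s, noise_sd_mv = noise_sd_mv,
                        fs_hz = fs_hz, n_beats = n_beats,
                        subject_id = cohort_row$subject_id, timepoint = tp,
                        seed = seed0 + k)
    rows[[k]] <- qtc_dispersion(measure_leads(rec))
  }
  do.call(rbind, rows)
}

## Build the per-subject CMR phantom whose sector geometry encodes the
## programmed salvage index, then quantify it.
quantify_subject_cmr <- function(cohort_row, noise_frac, seed0) {
  span_e <- 70 + 60 * runif(1)    # edema arc, degrees
  msi <- cohort_row$msi
  span_i <- (span_e - 10) * (1 - msi)
  infarct_geom <- if (span_i >= 5)
    list(theta = c(5, 5 + span_i), slices = 2:5) else NULL
  mvo_geom <- if (!is.null(infarct_geom) && isTRUE(cohort_row$mvo_present) &&
                    span_i >= 40)
    list(theta = c(15, 35), slices = 3:4, radii = c(24, 28)) else NULL
  ph <- simulate_cmr_phantom(edema_geom = list(theta = c(0, span_e),
                                               slices = 2:5),
                             infarct_geom = infarct_geom,
                             mvo_geom = mvo_geom,
                             noise_sd = noise_frac * 10,
                             subject_id = cohort_row$subject_id,
                             seed = seed0)
  quantify_cmr(ph)
}

#' Run the full synthetic analysis pipeline end to end
#'
#' Orchestrates the complete chain on a simulated cohort: exclusion filter,
#' per-timepoint ECG synthesis and delineation (the dispersion statistics
#' are *measured* from waveforms, not copied from the generator), CMR
#' phantom quantification (masses and salvage index measured by the SD
#' thresholds), cohort merge, and the association suite (paired QTc test,
#' Spearman correlations, univariate screen, log-LGE linear model, logistic
#' salvage model, ROC with Youden cut-off, agreement kappa between measured
#' and programmed salvage classes).  All randomness derives from `seed`,
#' fanned out deterministically per stage and subject, so a fixed seed
#' reproduces the bundle exactly.
#'
#' @param n_subjects Cohort size before exclusions.
#' @param seed Master RNG seed.
#' @param out_dir Optional directory: result tables (CSV/JSON), ROC
#'   coordinates and a manifest are written there.
#' @param msi_cut Salvage threshold for the logistic/ROC outcome.
#' @param screen_alpha Univariate screening level.
#' @param exclusion_rate Overall probability that a roster subject carries
#'   some exclusion flag.
#' @param ecg_fs_hz,ecg_n_beats,ecg_noise_sd_mv Waveform synthesis settings.
#' @param cmr_noise_frac Phantom noise as a fraction of the nominal remote
#'   SD.
#' @param cohort_args Extra arguments passed to [simulate_cohort()].
#' @param cmr_studies Optional named list (by subject id) of pre-built
#'   [`cmr_study`][simulate_cmr_phantom] objects replacing phantom
#'   generation; subjects mapped to `NULL` are dropped with a logged
#'   reason.
#' @param verbose Emit progress messages.
#' @return Object of class `qts_pipeline`: subject accounting
#'   (`n_input = n_excluded + n_dropped + n_analyzed`), exclusion counts,
#'   the measured analysis `table`, per-subject `dispersion` rows, cohort
#'   `timecourse` summary, `models` (screen + linear + logistic), `roc`,
#'   `kappa`, `correlations`, `paired_test`, `truth`, and `config`.
#' @export
run_pipeline <- function(n_subjects = 30, seed = 1, out_dir = NULL,
                         msi_cut = 0.6, screen_alpha = 0.1,
                         exclusion_rate = 0.1,
                         ecg_fs_hz = 250, ecg_n_beats = 3,
                         ecg_noise_sd_mv = 0.005, cmr_noise_frac = 0.5,
                         cohort_args = list(), cmr_studies = NULL,
                         verbose = TRUE) {
  check_number(n_subjects, "n_subjects", lower = 5)
  check_number(msi_cut, "msi_cut", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(screen_alpha, "screen_alpha", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(exclusion_rate, "exclusion_rate", lower = 0, upper = 0.9)
  seed <- check_seed(seed)
  say <- function(...) if (verbose) message(sprintf(...))

  ## stage 1: roster + exclusion filter -----------------------------------
  set.seed(seed)
  crit <- exclusion_criteria()
  roster <- data.frame(subject_id = sprintf("S%03d", seq_len(n_subjects)))
  for (cr in crit)
    roster[[cr]] <- runif(n_subjects) < exclusion_rate / length(crit)
  excl <- apply_exclusions(roster)
  say("exclusion filter: %d of %d subjects excluded", excl$n_excluded,
      excl$n_input)

  ## stage 2: cohort ground truth ------------------------------------------
  cohort <- do.call(simulate_cohort,
                    c(list(n = excl$n_included, seed = seed + 1),
                      cohort_args))
  tab <- cohort$table
  tab$subject_id <- excl$included$subject_id

  ## stages 3-4: per-subject ECG measurement + CMR quantification ----------
  set.seed(seed + 2)
  rr <- round(60 / pmin(85, pmax(55, rnorm(nrow(tab), 72, 8))), 3)
  ## lengthen RR where needed so the subject's longest QT fits in the beat
  qtc_cols <- c(outer(c("qtc_mean_", "delta_ma_"), TIMEPOINTS, paste0))
  for (i in seq_len(nrow(tab))) {
    q_max <- max(vapply(TIMEPOINTS, function(tp)
      max(tab[[paste0("qtc_mean_", tp)]][i] +
            c(0, ant_qtc_spread(tab[[paste0("delta_ma_", tp)]][i]))),
      numeric(1))) / 1000
    s_min <- (q_max + sqrt(q_max^2 + 4 * (ECG_GUARD + 0.02))) / 2
    rr[i] <- max(rr[i], round(1.02 * s_min^2, 3))
  }
  disp <- list(); quant <- list(); dropped <- list()
  for (i in seq_len(nrow(tab))) {
    sid <- tab$subject_id[i]
    res <- tryCatch({
      d <- measure_subject_ecgs(tab[i, ], rr_s = rr[i], fs_hz = ecg_fs_hz,
                                n_beats = ecg_n_beats,
                                noise_sd_mv = ecg_noise_sd_mv,
                                seed0 = seed * 1000L + i * 10L)
      q <- if (!is.null(cmr_studies)) {
        st <- cmr_studies[[sid]]
        qts_check(!is.null(st), "missing_input",
                  sprintf("no CMR study provided for %s", sid))
        quantify_cmr(st)
      } else {
        set.seed(seed * 1000L + 5000L + i)
        quantify_subject_cmr(tab[i, ], noise_frac = cmr_noise_frac,
                             seed0 = seed * 1000L + 5000L + i)
      }
      list(d = d, q = q)
    }, qtsalvage_error = function(e) conditionMessage(e))
    if (is.character(res)) {
      say("dropping subject %s: %s", sid, res)
      dropped[[sid]] <- res
    } else {
      res$d$subject_id <- sid
      disp[[sid]] <- res$d
      quant[[sid]] <- as.data.frame(res$q)
    }
  }
  qts_check(length(disp) >= 5, "insufficient_cohort",
            "fewer than 5 analyzable subjects after drops")
  dispersion <- do.call(rbind, disp)
  cmr_tab <- do.call(rbind, quant)
  rownames(dispersion) <- rownames(cmr_tab) <- NULL

  ## stage 5: merge measured quantities into the analysis table ------------
  keep <- tab$subject_id %in% names(disp)
  ana <- tab[keep, c("subject_id", "age", "sex", "lvef_pct",
                     "awm_segments", "peak_troponin_ng_ml")]
  for (tp in TIMEPOINTS) {
    m <- dispersion[dispersion$timepoint == tp, ]
    ana[[paste0("delta_ma_", tp)]] <-
      m$delta_ma_ms[match(ana$subject_id, m$subject_id)]
    ana[[paste0("qtc_mean_", tp)]] <-
      m$mean_qtc_ms[match(ana$subject_id, m$subject_id)]
  }
  ana <- merge(ana, cmr_tab, by = "subject_id", sort = FALSE)

  ## stage 6: association suite --------------------------------------------
  tc <- do.call(rbind, lapply(TIMEPOINTS, function(tp) {
    m <- dispersion[dispersion$timepoint == tp, ]
    data.frame(timepoint = tp, mean_qtc_ms = mean(m$mean_qtc_ms),
               delta_ma_ms = mean(m$delta_ma_ms))
  }))
  timecourse <- timecourse_summary(tc)
  peak_tp <- timecourse$peak_qtc_timepoint
  paired <- paired_qtc_test(ana[[paste0("qtc_mean_", peak_tp)]],
                            ana$qtc_mean_admission)
  correlations <- list(
    lge_g = spearman_cor(ana$delta_ma_day6, ana$lge_g),
    lge_pct = spearman_cor(ana$delta_ma_day6, ana$lge_pct),
    msi = spearman_cor(ana$delta_ma_day6, ana$msi))

  candidates <- c("delta_ma_day6", "peak_troponin_ng_ml", "lvef_pct",
                  "awm_segments", "age", "sex")
  ana$log_lge_g <- ifelse(ana$lge_g > 0, log(ana$lge_g), NA)
  screen_lin <- suppressMessages(
    univariate_screen(ana, "log_lge_g", candidates, alpha = screen_alpha,
                      type = "linear"))
  ana$msi_low <- ana$msi < msi_cut
  screen_log <- suppressMessages(
    univariate_screen(ana, "msi_low", candidates, alpha = screen_alpha,
                      type = "logistic"))
  sel_lin <- screen_lin$variable[screen_lin$selected]
  if (!length(sel_lin)) sel_lin <- "delta_ma_day6"
  sel_log <- screen_log$variable[screen_log$selected]
  if (!length(sel_log)) sel_log <- "delta_ma_day6"
  linear <- suppressMessages(fit_linear_log_lge(ana, sel_lin))
  logistic <- suppressMessages(
    fit_logistic_msi(ana, sel_log, msi_cut = msi_cut))
  roc <- roc_youden(ana$delta_ma_day6, ana$msi_low)
  kappa <- cohen_kappa(ana$msi_low,
                       tab$msi[match(ana$subject_id,
                                     tab$subject_id)] < msi_cut,
                       categories = c("FALSE", "TRUE"))

  bundle <- structure(list(
    n_input = n_subjects, n_excluded = excl$n_excluded,
    n_dropped = length(dropped), n_analyzed = nrow(ana),
    exclusion_counts = excl$counts, dropped = dropped,
    table = ana, dispersion = dispersion, cmr = cmr_tab,
    timecourse = timecourse, paired_test = paired,
    correlations = correlations,
    models = list(screen_linear = screen_lin, screen_logistic = screen_log,
                  linear = linear, logistic = logistic),
    roc = roc, kappa = kappa, truth = cohort$truth,
    config = list(seed = seed, msi_cut = msi_cut,
                  screen_alpha = screen_alpha, ecg_fs_hz = ecg_fs_hz,
                  ecg_n_beats = ecg_n_beats,
                  ecg_noise_sd_mv = ecg_noise_sd_mv,
                  cmr_noise_frac = cmr_noise_frac)),
    class = "qts_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(bundle, out_dir)
  bundle
}

model_to_df <- function(m) {
  if (is.null(m$coefficients)) return(data.frame(separated = TRUE))
  cbind(m$coefficients, r2 = m$r2, adj_r2 = m$adj_r2, n = m$n)
}

write_pipeline_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write.csv(bundle$table, p("analysis_table.csv"), row.names = FALSE)
  write.csv(bundle$dispersion, p("dispersion.csv"), row.names = FALSE)
  write.csv(bundle$cmr, p("cmr_quantification.csv"), row.names = FALSE)
  write.csv(model_to_df(bundle$models$linear), p("model_log_lge.csv"),
            row.names = FALSE)
  write.csv(model_to_df(bundle$models$logistic), p("model_msi.csv"),
            row.names = FALSE)
  write.csv(data.frame(threshold = bundle$roc$thresholds,
                       sensitivity = bundle$roc$sensitivity,
                       specificity = bundle$roc$specificity),
            p("roc_coordinates.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(timecourse = bundle$timecourse, paired_test = bundle$paired_test,
         correlations = bundle$correlations,
         roc = bundle$roc[c("auc", "cutoff", "sensitivity_at_cutoff",
                            "specificity_at_cutoff", "youden")],
         kappa = bundle$kappa$kappa,
         accounting = bundle[c("n_input", "n_excluded", "n_dropped",
                               "n_analyzed")],
         config = bundle$config,
         r_version = as.character(getRversion())),
    p("manifest.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
print.qts_pipeline <- function(x, ...) {
  cat(sprintf(
    "<qts_pipeline> %d enrolled = %d excluded + %d dropped + %d analyzed\n",
    x$n_input, x$n_excluded, x$n_dropped, x$n_analyzed))
  cat(sprintf("  QTc peak at %s; paired admission->peak p = %.3g\n",
              x$timecourse$peak_qtc_timepoint, x$paired_test$p))
  cat(sprintf("  Spearman dQTc(day6) vs MSI: r = %.2f (p = %.3g)\n",
              x$correlations$msi$r, x$correlations$msi$p))
  cat(sprintf("  ROC for MSI < %.1f: AUC %.2f, cut-off %.0f ms\n",
              x$config$msi_cut, x$roc$auc, x$roc$cutoff))
  invisible(x)
}
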