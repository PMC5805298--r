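## Beat geometry (seconds).  All waves are compact half-sine arches on a flat
## isoelectric baseline, so every landmark (QRS onset, T end) exists at an
## exact time instead of an asymptotic one.
ECG_QRS_DUR  <- 0.08   # QRS arch duration; R peak at onset + 0.04
ECG_T_DUR    <- 0.10   # T arch duration; T ends exactly at onset + QT
ECG_U_DUR    <- 0.06   # U arch duration
ECG_P_DUR    <- 0.08   # P arch duration
ECG_PQ_FLAT  <- 0.06   # flat PQ segment between P end and QRS onset
ECG_LEAD_IN  <- 0.25   # quiet signal before the first QRS onset
ECG_GUARD    <- 0.16   # required gap between T/U end and the next beat

#' Simulate a multi-lead ECG recording with known QT ground truth
#'
#' Generates an analytic surface-ECG approximation for the seven leads used
#' in anterior/inferior QTc dispersion analysis (V2--V5, II, III, aVF).
#' Each beat is a flat isoelectric baseline carrying compact half-sine
#' arches for the P wave, QRS complex, T wave and (optionally) a U wave.
#' The construction makes the delineation landmarks exact: the QRS departs
#' from the baseline at a known instant and the T wave returns to the
#' baseline exactly `qt_ms` later, so the programmed per-lead QT is the
#' ground truth against which any delineator can be scored.
#'
#' When a U wave is requested it is placed `tu_gap_ms` after the T peak; the
#' two arches meet (or overlap) so that the clean signal has a nadir between
#' the T and U peaks -- the landmark the clinical "measure to the T--U
#' nadir" rule refers to.  The sample index of that nadir is computed from
#' the noise-free signal and returned as the ground-truth T end.
#'
#' @param qt_ms Programmed QT interval in ms: a single value recycled to all
#'   leads, or a named vector with one entry per lead.
#' @param hr_bpm Heart rate in beats per minute (ignored if `rr_s` given).
#' @param rr_s R--R interval in seconds; overrides `hr_bpm`.
#' @param pq_level_mv Isoelectric (PQ-segment) level in mV.
#' @param qrs_amp_mv,t_amp_mv,p_amp_mv,u_amp_mv Arch amplitudes in mV.
#'   `u_amp_mv = 0` (default) omits the U wave.
#' @param tu_gap_ms Separation between T peak and U peak in ms.
#' @param noise_sd_mv SD of additive white Gaussian noise, mV.
#' @param drift_mv_per_s Linear baseline drift slope, mV/s (0 = flat).
#' @param fs_hz Sampling rate in Hz (>= 250).
#' @param n_beats Number of beats to generate (>= 1).
#' @param leads Character vector of lead names to generate.
#' @param subject_id,timepoint Metadata carried on the recording; `timepoint`
#'   must be one of `"admission"`, `"post_pci"`, `"day1"` ... `"day6"`.
#' @param seed Optional RNG seed; a fixed seed reproduces the recording
#'   byte-for-byte.
#'
#' @return An object of class `ecg_recording`: a list with `signals` (samples
#'   x leads matrix, mV), `fs_hz`, `leads`, `subject_id`, `timepoint`, and
#'   `truth`, the ground-truth list holding the programmed per-lead QT,
#'   the R--R interval, per-lead/per-beat landmark sample indices
#'   (`onset_idx`, `r_idx`, `t_peak_idx`, `t_end_idx`, `u_peak_idx`) and the
#'   baseline parameters.
#'
#' @examples
#' rec <- simulate_ecg(qt_ms = 400, hr_bpm = 60, noise_sd_mv = 0, seed = 1)
#' rec$truth$qt_ms
#' @export
simulate_ecg <- function(qt_ms = 400, hr_bpm = 75, rr_s = NULL,
                         pq_level_mv = 0, qrs_amp_mv = 0.8, t_amp_mv = 0.3,
                         p_amp_mv = 0.1, u_amp_mv = 0, tu_gap_ms = 80,
                         noise_sd_mv = 0, drift_mv_per_s = 0,
                         fs_hz = 500, n_beats = 5,
                         leads = c(ANTERIOR_LEADS, INFERIOR_LEADS),
                         subject_id = "S01", timepoint = "admission",
                         seed = NULL) {
  if (is.null(rr_s)) {
    check_number(hr_bpm, "hr_bpm", lower = 0, strict_lower = TRUE)
    rr_s <- 60 / hr_bpm
  }
  check_number(rr_s, "rr_s", lower = 0, strict_lower = TRUE)
  check_number(fs_hz, "fs_hz", lower = 250)
  check_number(noise_sd_mv, "noise_sd_mv", lower = 0)
  check_number(n_beats, "n_beats", lower = 1)
  check_number(t_amp_mv, "t_amp_mv", lower = 0, strict_lower = TRUE)
  check_number(u_amp_mv, "u_amp_mv", lower = 0)
  qts_check(length(leads) >= 1 && !anyDuplicated(leads), "invalid_parameter",
            "`leads` must be a non-empty set of unique lead names")
  qts_check(timepoint %in% TIMEPOINTS, "invalid_parameter",
            sprintf("`timepoint` must be one of: %s",
                    paste(TIMEPOINTS, collapse = ", ")))

  if (length(qt_ms) == 1L) {
    qt_ms <- rep(qt_ms, length(leads))
    names(qt_ms) <- leads
  }
  qts_check(all(leads %in% names(qt_ms)), "invalid_parameter",
            "`qt_ms` must be named with one entry per lead")
  qt_ms <- qt_ms[leads]
  for (q in qt_ms) check_number(q, "qt_ms", lower = 0, strict_lower = TRUE)

  qt_s <- qt_ms / 1000
  tu_gap_s <- tu_gap_ms / 1000
  if (u_amp_mv > 0) {
    qts_check(tu_gap_s >= ECG_U_DUR / 2 + 0.02, "invalid_parameter",
              "`tu_gap_ms` too small: U wave would precede the T peak")
  }
  ## latest wave end relative to QRS onset, per lead
  last_end <- if (u_amp_mv > 0) {
    pmax(qt_s, qt_s - ECG_T_DUR / 2 + tu_gap_s + ECG_U_DUR / 2)
  } else qt_s
  qts_check(all(qt_s < rr_s), "invalid_parameter",
            "QT must be shorter than the RR interval")
  qts_check(all(last_end + ECG_GUARD <= rr_s), "invalid_parameter",
            sprintf(paste("beat waves would collide with the next beat's P",
                          "wave: need QT (+ U tail) <= RR - %g s"), ECG_GUARD))

  seed <- check_seed(seed)
  if (!is.null(seed)) set.seed(seed)

  n <- ceiling((ECG_LEAD_IN + n_beats * rr_s) * fs_hz)
  t <- (seq_len(n) - 1) / fs_hz
  onsets <- ECG_LEAD_IN + (seq_len(n_beats) - 1) * rr_s

  baseline <- pq_level_mv + drift_mv_per_s * t
  signals <- matrix(0, nrow = n, ncol = length(leads),
                    dimnames = list(NULL, leads))
  landmarks <- vector("list", length(leads))

  for (li in seq_along(leads)) {
    clean <- numeric(n)
    lm <- data.frame(lead = leads[li], beat = seq_len(n_beats),
                     onset_idx = NA_integer_, r_idx = NA_integer_,
                     t_peak_idx = NA_integer_, t_end_idx = NA_integer_,
                     u_peak_idx = NA_integer_)
    for (b in seq_len(n_beats)) {
      on <- onsets[b]
      qt <- qt_s[li]
      clean <- clean +
        half_sine(t, on - ECG_PQ_FLAT - ECG_P_DUR, ECG_P_DUR, p_amp_mv) +
        half_sine(t, on, ECG_QRS_DUR, qrs_amp_mv) +
        half_sine(t, on + qt - ECG_T_DUR, ECG_T_DUR, t_amp_mv)
      t_peak <- on + qt - ECG_T_DUR / 2
      lm$onset_idx[b]  <- round(on * fs_hz) + 1L
      lm$r_idx[b]      <- round((on + ECG_QRS_DUR / 2) * fs_hz) + 1L
      lm$t_peak_idx[b] <- round(t_peak * fs_hz) + 1L
      lm$t_end_idx[b]  <- round((on + qt) * fs_hz) + 1L
      if (u_amp_mv > 0) {
        u_peak <- t_peak + tu_gap_s
        clean <- clean +
          half_sine(t, u_peak - ECG_U_DUR / 2, ECG_U_DUR, u_amp_mv)
        lm$u_peak_idx[b] <- round(u_peak * fs_hz) + 1L
      }
    }
    if (u_amp_mv > 0) {
      ## ground-truth T end under the nadir rule: first minimum of the clean
      ## signal strictly between the T and U peaks of each beat
      for (b in seq_len(n_beats)) {
        i0 <- lm$t_peak_idx[b]; i1 <- lm$u_peak_idx[b]
        seg <- clean[i0:i1]
        lm$t_end_idx[b] <- i0 + which.min(seg) - 1L
      }
    }
    signals[, li] <- baseline + clean
    landmarks[[li]] <- lm
  }
  if (noise_sd_mv > 0)
    signals <- signals + matrix(rnorm(n * length(leads), 0, noise_sd_mv),
                                nrow = n)

  truth <- list(qt_ms = qt_ms, rr_s = rr_s, fs_hz = fs_hz,
                pq_level_mv = pq_level_mv, drift_mv_per_s = drift_mv_per_s,
                u_wave = u_amp_mv > 0, tu_gap_ms = tu_gap_ms,
                landmarks = do.call(rbind, landmarks))
  structure(list(subject_id = subject_id, timepoint = timepoint,
                 fs_hz = fs_hz, leads = leads, signals = signals,
                 truth = truth),
            class = "ecg_recording")
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording> subject %s, timepoint %s\n",
              x$subject_id, x$timepoint))
  cat(sprintf("  %d leads (%s), %d samples @ %g Hz (%.2f s)\n",
              length(x$leads), paste(x$leads, collapse = ", "),
              nrow(x$signals), x$fs_hz, nrow(x$signals) / x$fs_hz))
  cat(sprintf("  programmed QT: %s ms; RR %.3f s\n",
              paste(unique(x$truth$qt_ms), collapse = "/"), x$truth$rr_s))
  invisible(x)
}
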