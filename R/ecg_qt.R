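## --- R-peak detection -----------------------------------------------------

find_r_peaks <- function(x, fs_hz, min_dist_s = 0.25) {
  n <- length(x)
  if (n < 3) return(integer(0))
  med <- median(x)
  amp <- max(x - med)
  if (amp <= 0) return(integer(0))
  thr <- med + 0.5 * amp
  i <- 2:(n - 1)
  cand <- i[x[i] >= x[i - 1] & x[i] > x[i + 1] & x[i] > thr]
  if (!length(cand)) return(integer(0))
  ## greedy non-maximum suppression within the refractory distance
  min_dist <- round(min_dist_s * fs_hz)
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (c in cand)
    if (!length(kept) || all(abs(kept - c) >= min_dist)) kept <- c(kept, c)
  sort(kept)
}

#' Estimate the isoelectric baseline of one ECG lead
#'
#' The clinical convention defines the isoelectric reference as the line
#' joining consecutive PQ segments.  Each PQ segment is located as the
#' minimum-variance plateau in the interval immediately preceding the QRS;
#' the per-sample baseline is the piecewise-linear interpolation through the
#' PQ plateau levels, which follows any slow linear drift between beats.
#'
#' @param x Numeric voltage series for one lead (mV).
#' @param fs_hz Sampling rate (Hz).
#' @return An object of class `ecg_baseline`: list with `level` (per-sample
#'   baseline, mV), `pq_idx` / `pq_level_mv` (plateau centres and levels),
#'   `r_peaks` (detected R-peak sample indices) and `noise_sd_mv` (noise SD
#'   estimated on the PQ plateaus).
#' @seealso [delineate_qt()]
#' @export
estimate_baseline <- function(x, fs_hz) {
  check_number(fs_hz, "fs_hz", lower = 250)
  qts_check(is.numeric(x) && length(x) > fs_hz * 0.5, "insufficient_signal",
            "lead series too short")
  r_peaks <- find_r_peaks(x, fs_hz)
  qts_check(length(r_peaks) >= 2, "insufficient_signal",
            "fewer than 2 detectable beats in lead series")

  w <- max(3L, round(0.04 * fs_hz))     # plateau window
  lo <- round(0.16 * fs_hz); hi <- round(0.03 * fs_hz)
  pq_idx <- pq_level <- numeric(length(r_peaks))
  resid <- numeric(0)
  for (k in seq_along(r_peaks)) {
    a <- max(1L, r_peaks[k] - lo); b <- r_peaks[k] - hi
    if (b - a + 1 < w) { a <- max(1L, b - w + 1L) }
    starts <- a:(b - w + 1L)
    v <- vapply(starts, function(s) var(x[s:(s + w - 1L)]), numeric(1))
    s <- starts[which.min(v)]
    seg <- x[s:(s + w - 1L)]
    pq_idx[k] <- s + (w - 1L) / 2
    pq_level[k] <- mean(seg)
    resid <- c(resid, seg - mean(seg))
  }
  level <- stats::approx(pq_idx, pq_level, xout = seq_along(x), rule = 2)$y
  structure(list(level = level, pq_idx = pq_idx, pq_level_mv = pq_level,
                 r_peaks = r_peaks, noise_sd_mv = sd(resid)),
            class = "ecg_baseline")
}

## linear interpolation of the zero crossing between two samples; falls back
## to the inner sample when the pair is degenerate
zero_cross <- function(i0, v0, i1, v1, fallback) {
  if (!is.finite(v0) || !is.finite(v1) || abs(v1 - v0) < 1e-12)
    return(fallback)
  cross <- i0 + (0 - v0) / (v1 - v0) * (i1 - i0)
  if (cross < min(i0, i1) - 1 || cross > max(i0, i1) + 1) return(fallback)
  round(cross)
}

#' Delineate the QT interval of one ECG lead
#'
#' Implements the manual measurement rules used for serial post-infarction
#' ECGs: QT runs from QRS onset to the return of the T wave to the
#' isoelectric baseline; when a U wave follows the T wave, QT is measured to
#' the nadir between the T and U peaks instead.
#'
#' With more than one beat available, beats are aligned on their R peaks and
#' a sample-wise median beat is delineated (noise suppression without a
#' per-beat selection rule).  Departure/return from the baseline is decided
#' against a noise band of `max(3 x PQ noise SD, 0.02 mV)`; the T end must
#' stay inside the band for 10 ms.  Both landmarks are refined by linear
#' interpolation of the band crossing to the exact baseline crossing, so on
#' noise-free signals the programmed QT is recovered to within one sample.
#'
#' @inheritParams estimate_baseline
#' @param baseline An `ecg_baseline` for the same series (computed if
#'   missing).
#' @return List of class `qt_delineation`: `qt_ms`, landmark indices within
#'   the median beat (`onset_idx`, `t_peak_idx`, `t_end_idx`, `u_peak_idx`),
#'   `u_truncated` (TRUE when the T--U nadir rule was applied), `band_mv`,
#'   `noise_sd_mv`, the `median_beat` itself and `r_rel`, the R-peak index
#'   within it.
#' @export
delineate_qt <- function(x, fs_hz, baseline = estimate_baseline(x, fs_hz)) {
  qts_check(inherits(baseline, "ecg_baseline"), "invalid_parameter",
            "`baseline` must come from estimate_baseline()")
  r_peaks <- baseline$r_peaks
  y <- x - baseline$level

  ## median beat aligned on R peaks
  pre <- round(0.20 * fs_hz)
  min_rr <- min(diff(r_peaks))
  post <- min_rr - ceiling(0.19 * fs_hz)
  qts_check(post > round(0.15 * fs_hz), "insufficient_signal",
            "RR interval too short to contain a T wave window")
  use <- r_peaks[r_peaks - pre >= 1 & r_peaks + post <= length(y)]
  qts_check(length(use) >= 1, "insufficient_signal",
            "no complete beat window inside the recording")
  beats <- vapply(use, function(r) y[(r - pre):(r + post)],
                  numeric(pre + post + 1))
  m <- if (length(use) == 1L) drop(beats) else apply(beats, 1, median)
  r_rel <- pre + 1L

  ## noise band from the PQ stretch of the median beat
  pq <- m[(r_rel - round(0.10 * fs_hz)):(r_rel - round(0.04 * fs_hz))]
  noise_hat <- sd(pq)
  band <- max(3 * noise_hat, 0.02)

  ## QRS onset: walk back from R until the signal re-enters the band, then
  ## on to the actual baseline crossing, and interpolate it
  i <- r_rel
  while (i > 1 && abs(m[i]) > band) i <- i - 1L
  qts_check(i > 1, "lead_unmeasurable",
            "QRS onset not found above noise band")
  tol <- max(noise_hat, 1e-9)   # "at baseline" within the noise level
  lim <- max(2L, i - round(0.05 * fs_hz))
  while (i > lim && m[i] > tol) i <- i - 1L
  onset <- zero_cross(i, m[i], i + 1L, m[i + 1L], fallback = i)

  ## T peak: largest deflection after the QRS
  t_from <- r_rel + round(0.12 * fs_hz)
  qts_check(t_from < length(m), "lead_unmeasurable", "window too short")
  tp <- t_from + which.max(m[t_from:length(m)]) - 1L
  qts_check(m[tp] > band, "lead_unmeasurable",
            "no T wave detectable above noise band")

  ## U wave: second positive local extremum after the T peak, above the
  ## band and a 0.04 mV reading floor, and separated from the T wave by a
  ## return toward the baseline (otherwise noise wiggles on the T downslope
  ## would masquerade as U waves).  Candidates are sought on a lightly
  ## smoothed copy of the beat; landmark indices keep the original grid.
  w <- max(3L, round(0.01 * fs_hz)); if (w %% 2L == 0L) w <- w + 1L
  sm <- as.numeric(stats::filter(m, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- m[is.na(sm)]
  u_peak <- NA_integer_
  u_from <- tp + round(0.02 * fs_hz)
  u_to <- min(tp + round(0.30 * fs_hz), length(m) - 1L)
  if (u_from < u_to) {
    j <- (u_from):(u_to)
    is_max <- sm[j] >= sm[j - 1] & sm[j] > sm[j + 1] &
      sm[j] > max(band, 0.04)
    for (cand in j[is_max]) {
      if (min(sm[tp:cand]) <= band) { u_peak <- cand; break }
    }
  }

  if (!is.na(u_peak)) {
    ## measure to the nadir of the curve between T and U waves
    t_end <- tp + which.min(m[tp:u_peak]) - 1L
    u_flag <- TRUE
  } else {
    run <- max(2L, ceiling(0.01 * fs_hz))
    inside <- abs(m) <= band
    t_end <- NA_integer_
    for (j in (tp + 1L):(length(m) - run + 1L)) {
      if (all(inside[j:(j + run - 1L)])) { t_end <- j; break }
    }
    qts_check(!is.na(t_end), "lead_unmeasurable",
              "T wave does not return to the isoelectric baseline")
    ## walk from band entry to the actual baseline crossing, interpolate it
    z <- t_end
    zlim <- min(length(m), t_end + round(0.05 * fs_hz))
    while (z < zlim && m[z] > tol) z <- z + 1L
    t_end <- if (m[z] <= tol)
      zero_cross(z - 1L, m[z - 1L], z, m[z], fallback = z) else t_end
    u_flag <- FALSE
  }
  qts_check(t_end > onset, "lead_unmeasurable", "degenerate QT landmarks")

  structure(list(qt_ms = (t_end - onset) / fs_hz * 1000,
                 onset_idx = onset, t_peak_idx = tp, t_end_idx = t_end,
                 u_peak_idx = u_peak, u_truncated = u_flag,
                 band_mv = band, noise_sd_mv = noise_hat,
                 median_beat = m, r_rel = r_rel, n_beats_used = length(use)),
            class = "qt_delineation")
}

#' Bazett heart-rate correction of the QT interval
#'
#' `QTc = QT / sqrt(RR)` with QT in ms and RR in seconds, so that at
#' RR = 1 s (60 bpm) the corrected and uncorrected values coincide.
#'
#' @param qt_ms QT interval(s), ms; must be positive.
#' @param rr_s Preceding R--R interval(s), seconds; must be positive.
#' @return QTc in ms.
#' @examples
#' bazett_qtc(400, 0.64)  # 500
#' @export
bazett_qtc <- function(qt_ms, rr_s) {
  qts_check(is.numeric(qt_ms) && all(is.finite(qt_ms)) && all(qt_ms > 0),
            "domain_error", "`qt_ms` must be positive")
  qts_check(is.numeric(rr_s) && all(is.finite(rr_s)) && all(rr_s > 0),
            "domain_error", "`rr_s` must be positive")
  qt_ms / sqrt(rr_s)
}

#' Measure QT/RR/QTc on every lead of a recording
#'
#' Runs baseline estimation and QT delineation lead by lead, applies the
#' Bazett correction using the median R--R interval of the recording, and
#' collects the per-lead results.  Leads that fail delineation (flat signal,
#' no T wave above the noise band) are excluded and reported via the
#' `"excluded"` attribute, mirroring the clinical exclusion of leads with
#' technical difficulties in QT measurement.
#'
#' @param rec An [`ecg_recording`][simulate_ecg] (or compatible list with
#'   `signals`, `fs_hz`, `leads`).
#' @return A data frame of class `lead_qt` with one row per measurable lead:
#'   `lead`, `qt_ms`, `rr_s`, `qtc_ms`, `baseline_mv`, `u_truncated`.
#'   Attributes: `excluded` (named character of per-lead failure reasons),
#'   `subject_id`, `timepoint`.
#' @export
measure_leads <- function(rec) {
  qts_check(is.list(rec) && !is.null(rec$signals) && !is.null(rec$fs_hz),
            "invalid_parameter", "`rec` must be an ecg_recording")
  fs <- rec$fs_hz
  rows <- list(); excluded <- character(0)
  for (lead in colnames(rec$signals)) {
    x <- rec$signals[, lead]
    res <- tryCatch({
      bl <- estimate_baseline(x, fs)
      dq <- delineate_qt(x, fs, bl)
      rr <- median(diff(bl$r_peaks)) / fs
      data.frame(lead = lead, qt_ms = dq$qt_ms, rr_s = rr,
                 qtc_ms = bazett_qtc(dq$qt_ms, rr),
                 baseline_mv = mean(bl$pq_level_mv),
                 u_truncated = dq$u_truncated)
    }, qtsalvage_error = function(e) conditionMessage(e))
    if (is.character(res)) excluded[lead] <- res else rows[[lead]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lead = character(0), qt_ms = numeric(0), rr_s = numeric(0),
               qtc_ms = numeric(0), baseline_mv = numeric(0),
               u_truncated = logical(0))
  rownames(out) <- NULL
  structure(out, excluded = excluded, subject_id = rec$subject_id,
            timepoint = rec$timepoint, class = c("lead_qt", "data.frame"))
}

#' Anterior--inferior QTc dispersion at one timepoint
#'
#' Computes the two dispersion statistics contrasting the injured anterior
#' wall (chest leads V2--V5) with remote inferior myocardium (II, III, aVF):
#' \describe{
#'   \item{`delta_ma_ms`}{maximum anterior QTc minus minimum inferior QTc
#'     (the "MA" statistic);}
#'   \item{`delta_me_ms`}{mean anterior QTc minus mean inferior QTc
#'     (the "ME" statistic).}
#' }
#' `delta_ma_ms >= delta_me_ms` always, since max >= mean and min <= mean
#' over the same lead groups.  Group statistics are computed over the leads
#' actually measurable; ties for the extreme leads are broken by the fixed
#' order V2 < V3 < V4 < V5 and II < III < aVF.
#'
#' @param measurements A [`lead_qt`][measure_leads] data frame (one
#'   subject-timepoint).
#' @param timepoint Timepoint label; defaults to the attribute carried by
#'   `measurements`.
#' @return One-row data frame of class `qtc_dispersion`: `timepoint`,
#'   `delta_ma_ms`, `delta_me_ms`, `max_anterior_lead`, `min_inferior_lead`,
#'   `n_anterior`, `n_inferior`, `mean_qtc_ms` (all measured leads).
#' @export
qtc_dispersion <- function(measurements,
                           timepoint = attr(measurements, "timepoint")) {
  qts_check(is.data.frame(measurements) &&
              all(c("lead", "qtc_ms") %in% names(measurements)),
            "invalid_parameter",
            "`measurements` must have columns `lead` and `qtc_ms`")
  if (is.null(timepoint)) timepoint <- NA_character_
  ant <- measurements[measurements$lead %in% ANTERIOR_LEADS, ]
  inf <- measurements[measurements$lead %in% INFERIOR_LEADS, ]
  qts_check(nrow(ant) >= 1, "missing_leads",
            "no measurable anterior lead (V2-V5)")
  qts_check(nrow(inf) >= 1, "missing_leads",
            "no measurable inferior lead (II, III, aVF)")
  ## fixed-order tie-break for the reported extreme leads
  ant <- ant[order(match(ant$lead, ANTERIOR_LEADS)), ]
  inf <- inf[order(match(inf$lead, INFERIOR_LEADS)), ]
  i_max <- which.max(ant$qtc_ms)
  i_min <- which.min(inf$qtc_ms)
  structure(data.frame(timepoint = timepoint,
                       delta_ma_ms = ant$qtc_ms[i_max] - inf$qtc_ms[i_min],
                       delta_me_ms = mean(ant$qtc_ms) - mean(inf$qtc_ms),
                       max_anterior_lead = ant$lead[i_max],
                       min_inferior_lead = inf$lead[i_min],
                       n_anterior = nrow(ant), n_inferior = nrow(inf),
                       mean_qtc_ms = mean(measurements$qtc_ms)),
            subject_id = attr(measurements, "subject_id"),
            class = c("qtc_dispersion", "data.frame"))
}

#' Summarize the QTc / dispersion timecourse over serial ECGs
#'
#' Locates the peak of the mean QTc and of the MA dispersion statistic over
#' the serial timepoints (admission, post-PCI, day 1 ... day 6).  Missing
#' timepoints are skipped, not interpolated; ties are broken to the earliest
#' timepoint in schedule order.
#'
#' @param tc Data frame with columns `timepoint`, `mean_qtc_ms`,
#'   `delta_ma_ms` (one row per timepoint; e.g. stacked
#'   [qtc_dispersion()] rows for one subject, or cohort means).
#' @return List: `peak_qtc_timepoint`, `peak_qtc_ms`,
#'   `peak_delta_timepoint`, `peak_delta_ms`, `admission_qtc_ms`,
#'   `admission_delta_ms` (NA when admission is absent), `timepoints`.
#' @export
timecourse_summary <- function(tc) {
  qts_check(is.data.frame(tc) &&
              all(c("timepoint", "mean_qtc_ms", "delta_ma_ms") %in%
                    names(tc)),
            "invalid_parameter",
            "`tc` needs columns timepoint, mean_qtc_ms, delta_ma_ms")
  tc <- tc[tc$timepoint %in% TIMEPOINTS, , drop = FALSE]
  tc <- tc[order(match(tc$timepoint, TIMEPOINTS)), , drop = FALSE]
  qts_check(length(unique(tc$timepoint)) >= 2, "insufficient_series",
            "need at least 2 timepoints")
  adm <- tc[tc$timepoint == "admission", , drop = FALSE]
  list(peak_qtc_timepoint = tc$timepoint[which.max(tc$mean_qtc_ms)],
       peak_qtc_ms = max(tc$mean_qtc_ms),
       peak_delta_timepoint = tc$timepoint[which.max(tc$delta_ma_ms)],
       peak_delta_ms = max(tc$delta_ma_ms),
       admission_qtc_ms = if (nrow(adm)) adm$mean_qtc_ms[1] else NA_real_,
       admission_delta_ms = if (nrow(adm)) adm$delta_ma_ms[1] else NA_real_,
       timepoints = tc$timepoint)
}
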