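test_that("baseline follows the PQ plateaus, including linear drift", {
  rec <- simulate_ecg(qt_ms = 400, rr_s = 1, noise_sd_mv = 0, leads = "V2")
  bl <- estimate_baseline(rec$signals[, "V2"], rec$fs_hz)
  expect_lt(max(abs(bl$pq_level_mv)), 1e-9)

  rec2 <- simulate_ecg(qt_ms = 400, rr_s = 1, pq_level_mv = 0.1,
                       noise_sd_mv = 0, leads = "V2")
  bl2 <- estimate_baseline(rec2$signals[, "V2"], rec2$fs_hz)
  expect_equal(bl2$pq_level_mv, rep(0.1, length(bl2$pq_level_mv)))

  # drifting baseline: the interpolated level matches the programmed line
  # between the first and last PQ plateaus
  rec3 <- simulate_ecg(qt_ms = 400, rr_s = 1, drift_mv_per_s = 0.05,
                       noise_sd_mv = 0, leads = "V2")
  bl3 <- estimate_baseline(rec3$signals[, "V2"], rec3$fs_hz)
  idx <- ceiling(min(bl3$pq_idx)):floor(max(bl3$pq_idx))
  prog <- 0.05 * (idx - 1) / rec3$fs_hz
  expect_lt(max(abs(bl3$level[idx] - prog)), 1e-6)

  expect_error(estimate_baseline(rep(0, 5000), 500),
               class = "insufficient_signal")
})

test_that("noise-free delineation recovers the programmed QT exactly", {
  for (qt in c(320, 400, 480)) {
    for (rr in c(1, 0.857)) {   # grid-aligned and off-grid beat spacing
      rec <- simulate_ecg(qt_ms = qt, rr_s = rr, noise_sd_mv = 0,
                          n_beats = 3, leads = "V2")
      dq <- delineate_qt(rec$signals[, "V2"], rec$fs_hz)
      expect_lte(abs(dq$qt_ms - qt), 1000 / rec$fs_hz)
      expect_false(dq$u_truncated)
    }
  }
})

test_that("the U-wave nadir rule is applied when a U wave follows the T", {
  rec <- simulate_ecg(qt_ms = 500, hr_bpm = 55, u_amp_mv = 0.05,
                      tu_gap_ms = 80, noise_sd_mv = 0, leads = "V2")
  dq <- delineate_qt(rec$signals[, "V2"], rec$fs_hz)
  expect_true(dq$u_truncated)
  lm <- rec$truth$landmarks[1, ]
  truth_qt <- (lm$t_end_idx - lm$onset_idx) / rec$fs_hz * 1000
  expect_lte(abs(dq$qt_ms - truth_qt), 1000 / rec$fs_hz)
})

test_that("unmeasurable leads are excluded, not propagated", {
  rec <- simulate_ecg(qt_ms = 400, rr_s = 1, noise_sd_mv = 0,
                      leads = c("V2", "II", "aVF"))
  rec$signals[, "aVF"] <- 0   # flat line: no detectable beats
  m <- measure_leads(rec)
  expect_setequal(m$lead, c("V2", "II"))
  expect_named(attr(m, "excluded"), "aVF")
})

test_that("Bazett correction matches its closed form and domain", {
  expect_equal(bazett_qtc(400, 1), 400)
  expect_equal(bazett_qtc(400, 0.64), 500)
  expect_equal(bazett_qtc(435, 1), 435)
  # identity at RR = 1 s for any QT
  qt <- seq(200, 600, by = 25)
  expect_equal(bazett_qtc(qt, 1), qt)
  expect_error(bazett_qtc(400, 0), class = "domain_error")
  expect_error(bazett_qtc(-5, 1), class = "domain_error")
})

test_that("dispersion statistics match hand arithmetic and dominate", {
  m <- data.frame(lead = c("V2", "V3", "V4", "V5", "II", "III", "aVF"),
                  qtc_ms = c(480, 500, 510, 505, 430, 440, 435))
  d <- qtc_dispersion(m, timepoint = "day6")
  expect_equal(d$delta_ma_ms, 80)
  expect_equal(d$delta_me_ms, 498.75 - 435)
  expect_equal(d$max_anterior_lead, "V4")
  expect_equal(d$min_inferior_lead, "II")

  m$qtc_ms <- rep(450, 7)
  d0 <- qtc_dispersion(m)
  expect_equal(d0$delta_ma_ms, 0)
  expect_equal(d0$delta_me_ms, 0)
  expect_equal(d0$max_anterior_lead, "V2")  # fixed-order tie-break

  m1 <- data.frame(lead = c("V3", "III"), qtc_ms = c(470, 420))
  d1 <- qtc_dispersion(m1)
  expect_equal(d1$delta_ma_ms, d1$delta_me_ms)

  # max-min dominates mean difference for arbitrary lead values, and both
  # are invariant to reordering within the lead groups
  set.seed(5)
  for (i in 1:25) {
    mm <- data.frame(lead = c("V2", "V3", "V4", "V5", "II", "III", "aVF"),
                     qtc_ms = rnorm(7, 460, 40))
    dd <- qtc_dispersion(mm)
    expect_gte(dd$delta_ma_ms, dd$delta_me_ms)
    pp <- qtc_dispersion(mm[sample(7), ])
    expect_equal(dd$delta_ma_ms, pp$delta_ma_ms)
    expect_equal(dd$delta_me_ms, pp$delta_me_ms)
  }

  expect_error(qtc_dispersion(m[m$lead %in% c("II", "III"), ]),
               class = "missing_leads")
})

test_that("timecourse summary finds the peak with documented tie rules", {
  tps <- c("admission", "post_pci", paste0("day", 1:6))
  bump <- function(d) exp(-((d - 3)^2) / 4)
  tc <- data.frame(timepoint = tps,
                   mean_qtc_ms = 430 + 70 * bump(c(0, 0.05, 1:6)),
                   delta_ma_ms = 20 + 50 * bump(c(0, 0.05, 1:6)))
  s <- timecourse_summary(tc)
  expect_equal(s$peak_qtc_timepoint, "day3")
  expect_equal(s$peak_delta_timepoint, "day3")
  expect_equal(s$admission_qtc_ms, tc$mean_qtc_ms[1])

  tc$mean_qtc_ms <- seq(430, 500, length.out = 8)  # monotone: peak last
  expect_equal(timecourse_summary(tc)$peak_qtc_timepoint, "day6")

  tc$mean_qtc_ms <- rep(450, 8)                    # ties: earliest wins
  expect_equal(timecourse_summary(tc)$peak_qtc_timepoint, "admission")

  expect_error(timecourse_summary(tc[1, ]), class = "insufficient_series")
})

test_that("QT error stays small under realistic noise (median beat)", {
  set.seed(101)
  errs <- vapply(1:100, function(i) {
    rec <- simulate_ecg(qt_ms = 420, hr_bpm = 70, noise_sd_mv = 0.02,
                        n_beats = 3, leads = "V2",
                        seed = 7000 + i)
    m <- measure_leads(rec)
    if (nrow(m)) abs(m$qt_ms - 420) else NA_real_
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 10)
})
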