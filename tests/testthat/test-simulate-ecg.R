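test_that("waveforms carry the programmed geometry by construction", {
  rec <- simulate_ecg(qt_ms = 400, rr_s = 1, noise_sd_mv = 0, seed = 1)
  expect_s3_class(rec, "ecg_recording")
  expect_equal(unname(rec$truth$qt_ms), rep(400, 7))
  lm <- rec$truth$landmarks
  # ground-truth T end sits exactly QT after QRS onset, in every lead/beat
  expect_true(all((lm$t_end_idx - lm$onset_idx) / rec$fs_hz * 1000 == 400))
  # PQ segment is flat at the isoelectric level
  on <- lm$onset_idx[1]
  pq <- rec$signals[(on - round(0.05 * rec$fs_hz)):(on - 1), "V2"]
  expect_equal(pq, rep(0, length(pq)))
  # non-zero PQ level shifts the whole baseline
  rec2 <- simulate_ecg(qt_ms = 400, rr_s = 1, pq_level_mv = 0.1,
                       noise_sd_mv = 0)
  on2 <- rec2$truth$landmarks$onset_idx[1]
  expect_equal(unname(rec2$signals[on2 - 5, "V2"]), 0.1)
})

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_ecg(noise_sd_mv = 0.02, seed = 42)
  b <- simulate_ecg(noise_sd_mv = 0.02, seed = 42)
  expect_identical(a$signals, b$signals)
  c <- simulate_ecg(noise_sd_mv = 0.02, seed = 43)
  expect_false(identical(a$signals, c$signals))
})

test_that("a U wave produces exactly one nadir between the T and U peaks", {
  rec <- simulate_ecg(qt_ms = 500, hr_bpm = 55, u_amp_mv = 0.05,
                      tu_gap_ms = 80, noise_sd_mv = 0, leads = "V2")
  lm <- rec$truth$landmarks[1, ]
  seg <- rec$signals[lm$t_peak_idx:lm$u_peak_idx, "V2"]
  d <- diff(seg)
  # local minima inside the segment: first difference changes - to +
  minima <- sum(d[-length(d)] < 0 & d[-1] > 0)
  expect_equal(minima, 1)
  # the recorded ground-truth T end is that nadir
  expect_equal(lm$t_peak_idx + which.min(seg) - 1L, lm$t_end_idx)
})

test_that("parameter validation rejects impossible beats", {
  expect_error(simulate_ecg(qt_ms = 900, rr_s = 0.8),
               class = "invalid_parameter")
  expect_error(simulate_ecg(qt_ms = 700, rr_s = 0.75),
               class = "invalid_parameter")  # QT + guard > RR
  expect_error(simulate_ecg(noise_sd_mv = -1), class = "invalid_parameter")
  expect_error(simulate_ecg(fs_hz = 100), class = "invalid_parameter")
  expect_error(simulate_ecg(timepoint = "day9"),
               class = "invalid_parameter")
})
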