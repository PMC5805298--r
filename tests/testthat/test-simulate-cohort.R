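test_that("cohort tables are deterministic with valid marginals", {
  a <- simulate_cohort(n = 50, seed = 10)
  b <- simulate_cohort(n = 50, seed = 10)
  expect_identical(a$table, b$table)
  t <- a$table
  expect_true(all(t$msi >= 0 & t$msi <= 1))
  expect_false(anyDuplicated(t$subject_id) > 0)
  expect_true(all(t$lge_g <= t$aar_g))   # LGE = AAR * (1 - MSI)
  # dispersion dominance carried into the tabular simulation
  for (tp in c("admission", "day3", "day6"))
    expect_true(all(t[[paste0("delta_ma_", tp)]] >=
                      t[[paste0("delta_me_", tp)]]))
  expect_error(simulate_cohort(n = 1), class = "invalid_parameter")
})

test_that("programmed link strength controls the sample correlation", {
  # null slope: association washes out
  t0 <- simulate_cohort(n = 200, delta_slope = 0, seed = 11)$table
  expect_lt(abs(cor(t0$delta_ma_day6, t0$msi, method = "spearman")), 0.2)
  # negative slope, vanishing noise: perfect monotone (rank) association
  t1 <- simulate_cohort(n = 200, delta_slope = -110, delta_noise_sd = 0,
                        seed = 12)$table
  expect_equal(cor(t1$delta_ma_day6, t1$msi, method = "spearman"), -1)
})

test_that("the cohort-mean dispersion timecourse peaks on the programmed day", {
  t <- simulate_cohort(n = 120, seed = 13)$table
  tps <- c("admission", "post_pci", paste0("day", 1:6))
  tc <- data.frame(
    timepoint = tps,
    mean_qtc_ms = vapply(tps, function(tp)
      mean(t[[paste0("qtc_mean_", tp)]]), numeric(1)),
    delta_ma_ms = vapply(tps, function(tp)
      mean(t[[paste0("delta_ma_", tp)]]), numeric(1)))
  s <- timecourse_summary(tc)
  expect_equal(s$peak_qtc_timepoint, "day3")
  expect_equal(s$peak_delta_timepoint, "day3")
  expect_gt(s$peak_qtc_ms, s$admission_qtc_ms)
})
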