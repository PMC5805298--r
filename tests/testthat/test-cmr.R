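test_that("noise-free phantoms place lesions at exact SI offsets", {
  ph <- simulate_cmr_phantom(noise_sd = 0)
  expect_s3_class(ph, "cmr_study")
  expect_true(all(ph$t2w[ph$truth$edema] == 100 + 3 * 10))
  expect_true(all(ph$t2w[ph$myo_mask & !ph$truth$edema] == 100))
  # MVO core darker than remote on LGE
  expect_true(all(ph$lge[ph$truth$mvo] < 100))
  # masks nest
  expect_true(all(ph$truth$infarct[ph$truth$mvo]))
  expect_true(all(ph$truth$edema[ph$truth$infarct]))
})

test_that("an empty infarct geometry leaves LGE at remote statistics", {
  ph <- simulate_cmr_phantom(infarct_geom = NULL, mvo_geom = NULL,
                             noise_sd = 0)
  expect_true(all(ph$lge[ph$myo_mask] == 100))
  st <- remote_stats(ph$lge, ph$remote_mask)
  expect_equal(st$mean, 100)
  expect_equal(st$sd, 0)
})

test_that("phantom generation is deterministic and validates geometry", {
  a <- simulate_cmr_phantom(seed = 3)
  b <- simulate_cmr_phantom(seed = 3)
  expect_identical(a$t2w, b$t2w)
  expect_identical(a$lge, b$lge)
  expect_error(simulate_cmr_phantom(
    edema_geom = list(theta = c(0, 120), slices = 2:9)),
    class = "invalid_parameter")
  expect_error(simulate_cmr_phantom(
    infarct_geom = list(theta = c(100, 200), slices = 2:5)),
    class = "invalid_parameter")  # breaks infarct-in-edema nesting
  expect_error(simulate_cmr_phantom(edema_offset_sd = 1.5),
               class = "invalid_parameter")
})

test_that("remote statistics match closed forms", {
  v <- array(100, c(4, 4, 2)); roi <- array(TRUE, c(4, 4, 2))
  st <- remote_stats(v, roi)
  expect_equal(st$mean, 100); expect_equal(st$sd, 0)

  v2 <- array(c(90, 110, rep(0, 30)), c(4, 4, 2))
  roi2 <- array(c(TRUE, TRUE, rep(FALSE, 30)), c(4, 4, 2))
  st2 <- remote_stats(v2, roi2)
  expect_equal(st2$mean, 100)
  expect_equal(st2$sd, sqrt(200))   # sample SD of {90, 110}

  expect_error(remote_stats(v, array(FALSE, c(4, 4, 2))),
               class = "empty_roi")
})

test_that("SD thresholds are strict and ordered (5SD mask inside 2SD)", {
  v <- array(100, c(3, 3, 1)); myo <- array(TRUE, c(3, 3, 1))
  v[1, 1, 1] <- 125; v[1, 2, 1] <- 115; v[1, 3, 1] <- 149; v[2, 1, 1] <- 151
  st <- list(mean = 100, sd = 10)
  e <- segment_edema(v, myo, st)
  expect_true(e[1, 1, 1]); expect_false(e[1, 2, 1])   # threshold 120, strict
  i <- segment_infarct(v, myo, st)
  expect_false(i[1, 3, 1]); expect_true(i[2, 1, 1])   # threshold 150, strict
  # degenerate SD = 0: everything above the mean
  e0 <- segment_edema(v, myo, list(mean = 100, sd = 0))
  expect_equal(sum(e0), 4)
  # subset property on random volumes
  set.seed(8)
  for (k in 1:10) {
    vr <- array(rnorm(200, 100, 30), c(10, 10, 2))
    myr <- array(runif(200) < 0.7, c(10, 10, 2))
    expect_true(all(segment_edema(vr, myr, st) |
                      !segment_infarct(vr, myr, st)))
  }
})

test_that("noise-free segmentation recovers ground truth voxel-exactly", {
  ph <- simulate_cmr_phantom(noise_sd = 0, edema_offset_sd = 3,
                             infarct_offset_sd = 7)
  q <- quantify_cmr(ph)
  expect_identical(q$masks$edema, ph$truth$edema)
  expect_identical(q$masks$infarct, ph$truth$infarct)
  expect_identical(q$masks$mvo, ph$truth$mvo)
  expect_true(q$mvo_present)
  # different offsets strictly beyond their thresholds: still exact
  ph2 <- simulate_cmr_phantom(noise_sd = 0, edema_offset_sd = 2.4,
                              infarct_offset_sd = 5.5, mvo_offset_sd = -2)
  q2 <- quantify_cmr(ph2)
  expect_identical(q2$masks$edema, ph2$truth$edema)
  expect_identical(q2$masks$infarct, ph2$truth$infarct)
})

test_that("MVO must be enclosed by infarct within its slice", {
  ph <- simulate_cmr_phantom(mvo_geom = NULL, noise_sd = 0)
  st <- remote_stats(ph$lge, ph$remote_mask)
  inf <- segment_infarct(ph$lge, ph$myo_mask, st)
  mv <- detect_mvo(ph$lge, inf, st)
  expect_false(mv$present)
  expect_equal(sum(mv$mask), 0)

  # a dark region touching non-infarcted myocardium is rejected
  v <- array(100, c(8, 8, 1))
  inf2 <- array(FALSE, c(8, 8, 1))
  inf2[3:6, 3:6, 1] <- TRUE
  v[inf2] <- 200
  v[4:5, 4:5, 1] <- 40          # dark core fully inside -> MVO
  mv2 <- detect_mvo(v, inf2, list(mean = 100, sd = 10))
  expect_true(mv2$present)
  expect_equal(sum(mv2$mask), 4)
  v[4:5, 3, 1] <- 40            # extend the core outside the infarct rim
  inf2[4:5, 3, 1] <- FALSE
  mv3 <- detect_mvo(v, inf2, list(mean = 100, sd = 10))
  expect_false(mv3$present)
})

test_that("mask mass follows the closed form, additivity and scaling", {
  m <- array(FALSE, c(10, 10, 10)); m[seq_len(1000)] <- TRUE
  expect_equal(mask_mass(m, c(1.4, 2.2, 8), 1.05),
               1000 * 1.4 * 2.2 * 8 / 1000 * 1.05)
  expect_equal(mask_mass(array(FALSE, c(4, 4, 4)), c(1, 1, 1)), 0)
  a <- array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2))
  b <- array(c(FALSE, TRUE, rep(FALSE, 6)), c(2, 2, 2))
  expect_equal(mask_mass(a | b, c(1, 1, 1)),
               mask_mass(a, c(1, 1, 1)) + mask_mass(b, c(1, 1, 1)))
  expect_equal(mask_mass(a, c(2, 1, 1)), 2 * mask_mass(a, c(1, 1, 1)))
  expect_error(mask_mass(a, c(0, 1, 1)), class = "invalid_parameter")
})

test_that("salvage index endpoints, monotonicity and clipping hold", {
  expect_equal(round(compute_msi(62, 59), 2), 0.05)
  expect_equal(compute_msi(30, 0), 1)
  for (a in c(1, 17, 250)) expect_equal(compute_msi(a, a), 0)
  vals <- vapply(seq(0, 60, by = 10), function(i) compute_msi(60, i),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_warning(res <- compute_msi(30, 40), "clipped")
  expect_equal(res, 0)
  expect_error(compute_msi(0, 5), class = "undefined_msi")
})
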