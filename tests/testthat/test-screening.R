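test_that("cumulative-hazard-ratio convention reproduces the pinned values", {
  expect_equal(hazard_ratio(0.05, 0.05), 1)
  expect_equal(round(hazard_ratio(0.0417, 0.0592), 3), 0.698)
  expect_equal(round(hazard_ratio(0.0247, 0.0354), 3), 0.694)
  expect_error(hazard_ratio(0, 0.05), "within")
  expect_error(hazard_ratio(0.05, 1), "within")
})

test_that("scenarios validate and round-trip through YAML and JSON", {
  sc <- screening_scenario(onset_multiplier = 1.3, uptake = 0.486, name = "x")
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_scenario(sc, path)
    back <- read_scenario(path)
    expect_equal(unclass(back), unclass(sc))
  }
  expect_error(screening_scenario(uptake = 1.2), "\\[0, 1\\]")
  hua <- hua_county_scenario()
  expect_equal(hua$onset_multiplier, 0.469)
  expect_equal(c(hua$eligible_age_lo, hua$eligible_age_hi), c(45L, 69L))
  cx <- cixian_scenario()
  expect_equal(cx$onset_multiplier, 1.30)
  expect_equal(cx$uptake, 0.486)
  expect_equal(cx$followup, 10L)
})

test_that("lesion prevalence vanishes without onset and scales with regional risk", {
  p <- tbl_params(); lt <- tbl_lt()
  sc0 <- screening_scenario(onset_multiplier = 0, eligible_age_lo = 45,
                            eligible_age_hi = 69)
  rep0 <- truncated_prevalence_report(p, lt, sc0)
  expect_true(all(rep0$prevalence == 0))

  sc_lo <- screening_scenario(onset_multiplier = 0.469, eligible_age_lo = 45,
                              eligible_age_hi = 69)
  sc_hi <- screening_scenario(onset_multiplier = 1, eligible_age_lo = 45,
                              eligible_age_hi = 69)
  rep_lo <- truncated_prevalence_report(p, lt, sc_lo)
  rep_hi <- truncated_prevalence_report(p, lt, sc_hi)
  expect_true(all(rep_lo$prevalence < rep_hi$prevalence))
  # high-grade total = severe dysplasia + occult cancer
  expect_equal(rep_lo$prevalence[rep_lo$lesion == "total_high_grade"],
               sum(rep_lo$prevalence[rep_lo$lesion %in% c("SD", "undetected_ESCC")]))
})

test_that("screening with no uptake or no sensitivity leaves the arms identical", {
  p <- tbl_params(); lt <- tbl_lt()
  for (sc in list(screening_scenario(onset_multiplier = 1.3, uptake = 0,
                                     followup = 5),
                  screening_scenario(onset_multiplier = 1.3, sensitivity = 0,
                                     followup = 5))) {
    out <- simulate_trial(p, lt, sc)
    expect_equal(out$ci_screen, out$ci_control)
    expect_equal(out$hazard_ratio, 1)
  }
})

test_that("screening can only reduce the hazard, monotonically in its reach", {
  p <- tbl_params(); lt <- tbl_lt()
  grid <- seq(0.2, 1, length.out = 3)
  hr <- matrix(NA_real_, 3, 3)
  for (i in seq_along(grid)) for (j in seq_along(grid)) {
    sc <- screening_scenario(onset_multiplier = 1.3, uptake = grid[i],
                             sensitivity = grid[j], followup = 5)
    hr[i, j] <- simulate_trial(p, lt, sc)$hazard_ratio
  }
  expect_true(all(hr <= 1))
  expect_true(all(diff(hr[, 3]) <= 1e-12))   # non-increasing in uptake
  expect_true(all(diff(hr[3, ]) <= 1e-12))   # non-increasing in sensitivity
})

test_that("screen-detected cancer accounting is an explicit, documented switch", {
  p <- tbl_params(); lt <- tbl_lt()
  sc <- cixian_scenario()
  with_sd <- simulate_trial(p, lt, sc, count_screen_detected = TRUE)
  without <- simulate_trial(p, lt, sc, count_screen_detected = FALSE)
  expect_equal(with_sd$ci_control, without$ci_control)
  expect_gt(with_sd$ci_screen, without$ci_screen)
  expect_equal(with_sd$ci_screen - without$ci_screen, with_sd$screen_detected,
               tolerance = 1e-12)
})
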