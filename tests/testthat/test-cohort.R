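test_that("occupancy is conserved and absorbing quantities are monotone", {
  traj <- run_cohort(tbl_params(), tbl_lt())
  expect_true(all(abs(rowSums(traj$occupancy) - 1) < 1e-9))
  so <- state_occupancy(traj)
  expect_true(all(diff(so[, "DEATH"]) >= 0))
  expect_true(all(rowSums(traj$new_detections) >= 0))
  expect_true(all(traj$deaths >= 0))
})

test_that("an inert cohort stays entirely in the normal state", {
  traj <- run_cohort(inert_params(), flat_life_table(0))
  so <- state_occupancy(traj)
  expect_equal(unname(so[, "NORMAL"]), rep(1, nrow(so)))
})

test_that("zero onset multiplier produces no lesions or cancers ever", {
  traj <- run_cohort(tbl_params(), tbl_lt(), onset_multiplier = 0)
  so <- state_occupancy(traj)
  diseased <- setdiff(health_states(), c("NORMAL", "DEATH"))
  expect_true(all(so[, diseased] == 0))
  expect_equal(prevalence(traj, "BCH_MD", 40, 69), 0)
})

test_that("progression cannot skip the ordered lesion sequence", {
  p <- tbl_params()
  p$p_md_to_sd <- 0
  traj <- run_cohort(p, tbl_lt())
  so <- state_occupancy(traj)
  blocked <- c("SD", undetected_cancer_states(), detected_cancer_states())
  expect_true(all(so[, blocked] == 0))
})

test_that("transition rows are probability vectors with the stated structure", {
  p <- tbl_params(); lt <- tbl_lt()
  # absorbing death
  r <- transition_row("DEATH", 60, p, lt)
  expect_equal(unname(r["DEATH"]), 1)
  expect_equal(sum(r), 1)
  # detected TNM I: background mortality only
  q60 <- lt$qx[lt$age == 60]
  r <- transition_row("D1", 60, p, lt)
  expect_equal(unname(r["DEATH"]), q60)
  expect_equal(unname(r["D1"]), 1 - q60)
  expect_true(all(r[setdiff(health_states(), c("D1", "DEATH"))] == 0))
  # all hazards and mortality zero: identity row
  for (s in c("NORMAL", "MD", "U2", "D3")) {
    r <- transition_row(s, 50, inert_params(), flat_life_table(0))
    expect_equal(unname(r[s]), 1)
  }
  # rows always sum to one
  for (s in health_states()) {
    expect_equal(sum(transition_row(s, 70, p, lt)), 1, tolerance = 1e-12)
  }
})

test_that("two-compartment reduction matches the closed-form geometric solution", {
  # NORMAL -> BCH/mD -> (death only), constant onset and flat mortality
  pon_rate <- 0.03; q <- 0.01
  p <- inert_params()
  p$onset <- onset_params(log(pon_rate), 0, 0, 0)
  traj <- run_cohort(p, flat_life_table(q))
  so <- state_occupancy(traj)
  pon <- 1 - exp(-pon_rate)
  tt <- seq_len(nrow(so)) - 1
  n_exp <- (1 - pon - q)^tt
  b_exp <- vapply(tt, function(t) {
    if (t == 0) return(0)
    s <- 0:(t - 1)
    pon * sum((1 - pon - q)^s * (1 - q)^(t - 1 - s))
  }, numeric(1))
  expect_true(all(abs(so[, "NORMAL"] - n_exp) < 1e-9))
  expect_true(all(abs(so[, "BCH_MD"] - b_exp) < 1e-9))
  expect_true(all(abs(so[, "DEATH"] - (1 - n_exp - b_exp)) < 1e-9))
})

test_that("duration tunnel reduces to a memoryless compartment when alpha1 = 0", {
  p <- tbl_params()
  p$bchmd_to_md <- progression_params(-3.359, 0)
  traj <- run_cohort(p, tbl_lt())
  oracle <- memoryless_cohort(p, tbl_lt())
  expect_true(all(abs(state_occupancy(traj) - oracle) < 1e-9))
})

test_that("prevalence is a normalized survivor-weighted proportion", {
  traj <- run_cohort(tbl_params(), tbl_lt())
  expect_equal(prevalence(traj, alive_states(), 40, 69), 1)
  pv <- prevalence(traj, "SD", 45, 69)
  expect_gt(pv, 0); expect_lt(pv, 1)
  expect_error(prevalence(traj, "SD", 10, 20), "outside")
  expect_error(prevalence(traj, "NOPE", 40, 50), "unknown health state")
})

test_that("incidence and stage distribution follow the detection stream", {
  p <- tbl_params()
  p$det1 <- 0; p$det2 <- 0; p$det3 <- 0; p$det4 <- 0
  traj <- run_cohort(p, tbl_lt())
  expect_equal(incidence(traj, 40, 69), 0)
  expect_error(stage_distribution(traj, 40, 69), "no detections")

  p2 <- tbl_params()
  p2$det2 <- 0; p2$det3 <- 0; p2$det4 <- 0
  traj2 <- run_cohort(p2, tbl_lt())
  expect_equal(unname(stage_distribution(traj2, 15, 99)), c(1, 0, 0, 0))

  traj3 <- run_cohort(tbl_params(), tbl_lt())
  expect_equal(sum(stage_distribution(traj3, 15, 99)), 1, tolerance = 1e-12)
})

test_that("cohorts can start from a caller-supplied occupancy", {
  init <- c(NORMAL = 0.5, MD = 0.5)
  traj <- run_cohort(tbl_params(), tbl_lt(), start_age = 50, end_age = 60,
                     init = init)
  so <- state_occupancy(traj)
  expect_equal(unname(so[1, c("NORMAL", "MD")]), c(0.5, 0.5))
  expect_true(all(abs(rowSums(traj$occupancy) - 1) < 1e-9))
})

test_that("tidy export reproduces the occupancy matrix", {
  traj <- run_cohort(tbl_params(), tbl_lt(), start_age = 40, end_age = 45)
  df <- as.data.frame(traj)
  expect_named(df, c("cycle", "age", "state", "duration_index", "occupancy"))
  tot <- tapply(df$occupancy, df$age, sum)
  expect_true(all(abs(tot - 1) < 1e-9))
  expect_true(all(df$duration_index[df$state == "BCH_MD"] >= 0))
  expect_true(all(is.na(df$duration_index[df$state == "NORMAL"])))
})
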