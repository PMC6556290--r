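# a small, fast target set for calibration unit tests
small_targets <- function() {
  as_targets(data.frame(
    kind = c("prevalence", "prevalence", "incidence"),
    label = c("BCH_MD", "SD", "ESCC"),
    age_lo = c(40, 45, 60), age_hi = c(44, 69, 64),
    value = c(13.1, 1.0, 519.6),
    n_eff = c(1000, 1000, 1e5),
    stringsAsFactors = FALSE
  ))
}

test_that("binomial log-likelihood matches the pmf and is maximized at k/n", {
  tg <- list(kind = "stage_proportion", value = 0.5, n_eff = 10)
  expect_equal(binomial_loglik(tg, 0.5), log(choose(10, 5)) + 10 * log(0.5))
  expect_equal(binomial_loglik(tg, 0.5), -1.402, tolerance = 1e-3)
  # MLE property: no other model value scores higher
  for (p in c(0.1, 0.3, 0.45, 0.55, 0.9)) {
    expect_lt(binomial_loglik(tg, p), binomial_loglik(tg, 0.5))
  }
  # boundary model values are clipped to a finite, very negative value
  ll0 <- binomial_loglik(tg, 0)
  expect_true(is.finite(ll0))
  expect_lt(ll0, -100)
  expect_error(binomial_loglik(list(kind = "prevalence", value = 1, n_eff = 0), 0.5),
               "n_eff")
})

test_that("GOF decomposes into per-target contributions", {
  g <- gof(tbl_params(), small_targets(), tbl_lt())
  expect_equal(g$value, -2 * sum(g$table$loglik), tolerance = 1e-9)
  expect_equal(nrow(g$table), 3)
})

test_that("self-generated targets are optimally fit by the generating model", {
  p <- tbl_params(); lt <- tbl_lt()
  defs <- small_targets()
  mv <- model_values(p, defs, lt)
  defs$value <- ifelse(defs$kind == "prevalence", 100, 1e5) *
    round(mv * defs$n_eff) / defs$n_eff
  defs <- as_targets(defs)
  g_true <- gof(p, defs, lt)
  # the total equals the sum of the per-target maxima (binomial MLE at k/n)
  best <- sum(vapply(seq_len(nrow(defs)), function(i) {
    binomial_loglik(defs[i, ], round(mv[i] * defs$n_eff[i]) / defs$n_eff[i])
  }, numeric(1)))
  # gof evaluates the model proportion, which differs from the realized k/n
  # only by the rounding of k, so the score sits just above the attainable
  # minimum
  expect_gte(g_true$value, -2 * best - 1e-9)
  expect_equal(g_true$value, -2 * best, tolerance = 1e-3)
  # any perturbed parameter set does worse
  v <- params_to_vector(p); v["beta0"] <- v["beta0"] + 0.5
  g_pert <- gof(vector_to_params(v, p), defs, lt)
  expect_gt(g_pert$value, g_true$value)
})

test_that("GOF ranking is preserved under a common rescaling of n_eff", {
  p1 <- tbl_params()
  v <- params_to_vector(p1); v["alpha0"] <- v["alpha0"] + 0.4
  p2 <- vector_to_params(v, p1)
  tg1 <- small_targets()
  tg2 <- small_targets(); tg2$n_eff <- tg2$n_eff * 2
  d1 <- gof(p1, tg1, tbl_lt())$value - gof(p2, tg1, tbl_lt())$value
  d2 <- gof(p1, as_targets(tg2), tbl_lt())$value - gof(p2, as_targets(tg2), tbl_lt())$value
  expect_equal(sign(d1), sign(d2))
})

test_that("an empty-lesion model scores strictly worse than the point estimate", {
  null_p <- tbl_params()
  for (nm in c("p_md_to_sd", "p_u1_u2", "p_u2_u3", "p_u3_u4")) null_p[[nm]] <- 0
  null_p$bchmd_to_md <- progression_params(-30, 0)
  g_null <- suppressWarnings(gof(null_p, default_targets(), tbl_lt()))
  g_fit <- gof(tbl_params(), default_targets(), tbl_lt())
  expect_gt(g_null$value, g_fit$value)
})

test_that("GA minimizes a one-dimensional quadratic surrogate", {
  b <- data.frame(parameter = "x", lower = 0, upper = 1)
  res <- ga_search(b, ga_config(pop_size = 20, iterations = 200, seed = 7),
                   objective = function(v) (v[["x"]] - 0.3)^2)
  expect_lt(res$best_gof, 0.01)          # within 1% of the known minimum of 0
  expect_lt(abs(res$best[["x"]] - 0.3), 0.1)
  expect_lte(res$evaluations, 200)
})

test_that("GA without variation operators leaves the population invariant", {
  b <- data.frame(parameter = c("x", "y"), lower = c(0, 0), upper = c(1, 1))
  res <- ga_search(b, ga_config(pop_size = 10, iterations = 50, seed = 3,
                                p_crossover = 0, p_mutation = 0),
                   objective = function(v) sum(v^2))
  for (g in unique(res$results$generation)) {
    expect_equal(sort(res$results$gof[res$results$generation == g]),
                 sort(res$results$gof[res$results$generation == 0]))
  }
})

test_that("GA runs are bit-identical under a fixed seed", {
  b <- data.frame(parameter = c("x", "y"), lower = c(-1, -1), upper = c(1, 1))
  obj <- function(v) (v[["x"]] - 0.2)^2 + (v[["y"]] + 0.5)^2
  r1 <- ga_search(b, ga_config(pop_size = 12, iterations = 120, seed = 42), objective = obj)
  r2 <- ga_search(b, ga_config(pop_size = 12, iterations = 120, seed = 42), objective = obj)
  expect_identical(r1$results, r2$results)
  expect_identical(r1$best, r2$best)
})

test_that("good-fitting selection widens monotonically with the tolerance", {
  df <- data.frame(x = 1:6, gof = c(10, 11, 12, 15, 20, 30))
  expect_equal(nrow(select_good_fitting(df, delta = 0)), 1)
  expect_equal(nrow(select_good_fitting(df, delta = Inf)), 6)
  sizes <- vapply(c(0, 1, 2, 5, 10, 25),
                  function(d) nrow(select_good_fitting(df, delta = d)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
  # default rule: chi-squared 95th percentile on the target count
  expect_equal(nrow(select_good_fitting(df, n_targets = 1)),
               sum(df$gof <= 10 + qchisq(0.95, 1)))
})

test_that("SIR resampling frequencies follow the likelihood weights", {
  cand <- matrix(1:3, ncol = 1)
  # uniform weights: equal frequencies within 3 sigma
  res <- sir_resample(cand, c(0, 0, 0), 10000, seed = 11)
  freq <- tabulate(res$indices, 3) / 10000
  sig <- sqrt((1 / 3) * (2 / 3) / 10000)
  expect_true(all(abs(freq - 1 / 3) < 3 * sig))
  # a single dominant weight: the resample is that set alone
  res1 <- sir_resample(cand, c(0, -1e6, -1e6), 500, seed = 12)
  expect_true(all(res1$indices == 1))
  expect_equal(res1$n_unique, 1)
  # 9:1 likelihood ratio
  res9 <- sir_resample(matrix(1:2, ncol = 1), log(c(9, 1)), 1e5, seed = 13)
  f9 <- mean(res9$indices == 1)
  sig9 <- sqrt(0.9 * 0.1 / 1e5)
  expect_lt(abs(f9 - 0.9), 3 * sig9)
  # total underflow is an error, not a silent uniform
  expect_error(sir_resample(cand, rep(-Inf, 3), 10), "rescale")
})

test_that("posterior sampling stays within bounds and prefers better fits", {
  b <- parameter_bounds()
  ctr <- params_to_vector(tbl_params())
  sds <- default_parameter_sds()
  post <- posterior_sample(ctr, sds, b, n_samples = 30,
                           targets = small_targets(), life_table = tbl_lt(),
                           n_resample = 100, seed = 5)
  expect_equal(dim(post$proposals), c(30, nrow(b)))
  for (j in seq_len(nrow(b))) {
    expect_true(all(post$proposals[, j] >= b$lower[j] &
                    post$proposals[, j] <= b$upper[j]))
  }
  # fixed-sd parameters stay at the center
  expect_true(all(post$proposals[, "det1"] == ctr[["det1"]]))
  expect_gte(post$n_unique, 1)
})
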