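#' Calibration targets
#'
#' A target set is a data frame with one observed quantity per row and
#' columns:
#' \describe{
#'   \item{kind}{`"prevalence"`, `"incidence"` or `"stage_proportion"`.}
#'   \item{label}{lesion state (`BCH_MD`, `MD`, `SD`) for prevalence;
#'     TNM stage (`I`..`IV`) for stage proportions; `ESCC` for incidence.}
#'   \item{age_lo, age_hi}{age band in years.}
#'   \item{value}{observed value in its printed unit: percent for
#'     prevalence, cases per 100,000 person-years for incidence, a
#'     proportion for stage proportions.}
#'   \item{n_eff}{effective sample size (persons, or person-years for
#'     incidence) giving the binomial likelihood its weight.}
#' }
#' `read_targets()`/`write_targets()` round-trip this layout as CSV;
#' `default_targets()` loads the packaged 34-target set (age-specific
#' lesion prevalence and ESCC incidence transcribed from the calibration
#' data, plus four editable stage-at-diagnosis placeholders).
#' `target_proportion()` converts `value` to the per-person proportion
#' used by the likelihood.
#'
#' @param path File path for CSV input/output.
#' @param targets A targets data frame.
#' @return A validated targets data frame (classed `escc_targets`).
#' @export
read_targets <- function(path) {
  as_targets(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_targets
#' @export
write_targets <- function(targets, path) {
  utils::write.csv(as_targets(targets), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_targets
#' @export
default_targets <- function() {
  read_targets(system.file("extdata", "table2_targets.csv", package = "esccsim"))
}

#' @rdname read_targets
#' @export
as_targets <- function(targets) {
  need <- c("kind", "label", "age_lo", "age_hi", "value", "n_eff")
  if (!all(need %in% names(targets))) {
    stop("targets need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- !targets$kind %in% c("prevalence", "incidence", "stage_proportion")
  if (any(bad)) stop("unknown target kind: ", targets$kind[bad][1], call. = FALSE)
  if (any(targets$n_eff <= 0)) stop("n_eff must be > 0", call. = FALSE)
  if (any(targets$value < 0)) stop("target values must be >= 0", call. = FALSE)
  p <- target_proportion(targets)
  if (any(p > 1)) stop("target proportion > 1 after unit normalization", call. = FALSE)
  class(targets) <- unique(c("escc_targets", class(targets)))
  targets
}

#' @rdname read_targets
#' @export
target_proportion <- function(targets) {
  ifelse(targets$kind == "prevalence", targets$value / 100,
         ifelse(targets$kind == "incidence", targets$value / 1e5,
                targets$value))
}

#' Binomial log-likelihood of one calibration target
#'
#' Each target is treated as an independent binomial observation:
#' `k = round(p_obs * n_eff)` successes in `n_eff` trials, evaluated at the
#' model-predicted proportion (clipped to `[1e-12, 1 - 1e-12]` so a boundary
#' model value yields a very negative but finite log-likelihood).
#'
#' @param target One-row targets data frame (or list with `kind`, `value`,
#'   `n_eff`).
#' @param model_value Model-predicted proportion for the same quantity (for
#'   incidence targets: per person-year, i.e. rate per 100,000 divided by
#'   100,000).
#' @return Log-likelihood (scalar).
#' @export
#' @examples
#' binomial_loglik(list(kind = "stage_proportion", value = 0.5, n_eff = 10), 0.5)
binomial_loglik <- function(target, model_value) {
  n <- round(as.numeric(target$n_eff))
  if (length(n) != 1 || n <= 0) stop("n_eff must be a single value > 0", call. = FALSE)
  p_obs <- target_proportion(as.data.frame(target, stringsAsFactors = FALSE))
  k <- round(p_obs * n)
  p <- min(max(model_value, 1e-12), 1 - 1e-12)
  stats::dbinom(k, n, p, log = TRUE)
}

#' Model analogues of a target set
#'
#' Runs one cohort simulation and evaluates, for every target row, the model
#' quantity on the proportion scale: survivor-weighted lesion prevalence,
#' clinical incidence per person-year, or TNM stage share at diagnosis.
#' If the simulated cohort produces no detections at all, stage-proportion
#' targets are assigned a vanishing model value (with a warning) rather than
#' erroring, so that degenerate parameter sets can still be scored and
#' ranked during calibration.
#'
#' @inheritParams run_cohort
#' @param targets Targets data frame, see [read_targets()].
#' @return Numeric vector of model proportions, one per target row.
#' @export
model_values <- function(params, targets, life_table, onset_multiplier = 1) {
  targets <- as_targets(targets)
  traj <- run_cohort(params, life_table, onset_multiplier = onset_multiplier)
  vapply(seq_len(nrow(targets)), function(i) {
    tg <- targets[i, ]
    switch(tg$kind,
      prevalence = prevalence(traj, tg$label, tg$age_lo, tg$age_hi),
      incidence = incidence(traj, tg$age_lo, tg$age_hi) / 1e5,
      stage_proportion = {
        sd_ok <- tryCatch(stage_distribution(traj, tg$age_lo, tg$age_hi),
                          error = function(e) NULL)
        if (is.null(sd_ok)) {
          warning("no detections: stage-proportion target '", tg$label,
                  "' scored at the boundary", call. = FALSE)
          0
        } else {
          sd_ok[[match(tg$label, c("I", "II", "III", "IV"))]]
        }
      })
  }, numeric(1))
}

#' Goodness of fit of a parameter set
#'
#' The calibration score is `-2` times the summed binomial log-likelihoods
#' over all targets (lower is better; non-negative for binomial
#' likelihoods up to the additive constant of the chosen success counts).
#' Deterministic for fixed inputs.
#'
#' @inheritParams model_values
#' @return An object of class `escc_gof`: list with `value` (the score),
#'   `table` (targets plus `model_value` and `loglik` columns) and `params`.
#' @export
gof <- function(params, targets, life_table, onset_multiplier = 1) {
  targets <- as_targets(targets)
  if (nrow(targets) == 0) stop("empty target set", call. = FALSE)
  mv <- model_values(params, targets, life_table, onset_multiplier)
  ll <- vapply(seq_len(nrow(targets)),
               function(i) binomial_loglik(targets[i, ], mv[i]), numeric(1))
  tab <- as.data.frame(targets)
  tab$model_value <- mv
  tab$loglik <- ll
  structure(list(value = -2 * sum(ll), table = tab, params = params),
            class = "escc_gof")
}

#' @export
print.escc_gof <- function(x, ...) {
  cat(sprintf("GOF score (-2 sum log-likelihood): %.3f over %d targets\n",
              x$value, nrow(x$table)))
  invisible(x)
}

#' Genetic-algorithm configuration
#'
#' @param pop_size Chromosomes per generation.
#' @param p_crossover Probability of single-point crossover per parent pair.
#' @param p_mutation Probability that an offspring has one randomly chosen
#'   gene redrawn uniformly within its bounds.
#' @param iterations Total objective-function evaluations (the initial
#'   population counts); generations = `iterations / pop_size`.
#' @param seed Optional RNG seed; fixed seed gives bit-identical runs.
#' @param elitism Keep the best chromosome found so far in the population
#'   (makes the best-score trace monotone non-increasing).
#' @param elite_size Number of best current chromosomes that survive into
#'   the next generation unchanged (only used when `elitism` is on).
#' @param mutation Mutation operator: `"mixed"` (default) redraws the chosen
#'   gene uniformly within its bounds with probability `p_uniform` and
#'   otherwise perturbs it by a normal step of `mutation_sd` times the bound
#'   width (creep mutation, which lets the search refine near an optimum);
#'   `"uniform"` always redraws uniformly.
#' @param mutation_sd Creep step, as a fraction of each parameter's bound
#'   width.
#' @param p_uniform Probability that a mixed-operator mutation is a uniform
#'   redraw rather than a creep step.
#' @return A `ga_config` list.
#' @export
ga_config <- function(pop_size = 100, p_crossover = 0.8, p_mutation = 0.25,
                      iterations = 100000, seed = NULL, elitism = TRUE,
                      elite_size = 1, mutation = c("mixed", "uniform"),
                      mutation_sd = 0.05, p_uniform = 0.2) {
  mutation <- match.arg(mutation)
  stopifnot(pop_size >= 2, p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1, iterations >= 1,
            elite_size >= 1, elite_size < pop_size,
            mutation_sd > 0, p_uniform >= 0, p_uniform <= 1)
  structure(list(pop_size = as.integer(pop_size), p_crossover = p_crossover,
                 p_mutation = p_mutation, iterations = as.integer(iterations),
                 seed = seed, elitism = isTRUE(elitism),
                 elite_size = as.integer(elite_size), mutation = mutation,
                 mutation_sd = mutation_sd, p_uniform = p_uniform),
            class = "ga_config")
}

#' Genetic-algorithm calibration search
#'
#' Minimizes the goodness-of-fit score over the free-parameter box.  Parent
#' selection probability is proportional to the difference between a
#' chromosome's score and the worst score in the current population (uniform
#' fallback when all scores are equal); pairs recombine by single-point
#' crossover; mutation redraws one gene uniformly within its bounds.  With
#' elitism (default) the best score found is non-increasing across
#' generations.
#'
#' @param bounds Data frame `parameter`, `lower`, `upper`
#'   (see [parameter_bounds()]).
#' @param config A [ga_config()].
#' @param targets,life_table Inputs for the default GOF objective; ignored
#'   when `objective` is supplied.
#' @param objective Optional function taking a named free-parameter vector
#'   and returning the score to minimize (used for surrogate objectives and
#'   testing).
#' @param base_params Fixed quantities merged with each chromosome, see
#'   [vector_to_params()].
#' @param onset_multiplier Passed to the GOF objective.
#' @return An object of class `escc_ga_result`: `results` (every evaluated
#'   chromosome with its score and generation, ranked by score), `best`,
#'   `best_gof`, `trace` (per-generation best/median), `config`, `bounds`.
#' @export
ga_search <- function(bounds, config = ga_config(), targets = NULL,
                      life_table = NULL, objective = NULL,
                      base_params = default_parameters(),
                      onset_multiplier = 1) {
  stopifnot(all(c("parameter", "lower", "upper") %in% names(bounds)),
            all(bounds$lower < bounds$upper))
  if (is.null(objective)) {
    if (is.null(targets) || is.null(life_table)) {
      stop("either an objective or targets + life_table is required", call. = FALSE)
    }
    targets <- as_targets(targets)
    objective <- function(v) {
      gof(vector_to_params(v, base_params), targets, life_table,
          onset_multiplier)$value
    }
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- nrow(bounds)
  pnames <- bounds$parameter
  pop <- config$pop_size

  draw_uniform <- function(n) {
    m <- matrix(stats::runif(n * L, rep(bounds$lower, each = n),
                             rep(bounds$upper, each = n)), nrow = n)
    colnames(m) <- pnames
    m
  }
  eval_pop <- function(P) apply(P, 1, function(v) objective(stats::setNames(v, pnames)))

  P <- draw_uniform(pop)
  G <- eval_pop(P)
  evals <- pop
  all_P <- list(P); all_G <- list(G); all_gen <- list(rep(0L, pop))
  trace <- data.frame(generation = 0L, best = min(G), median = stats::median(G))
  gen <- 0L

  n_elite <- if (config$elitism) config$elite_size else 0L
  n_off <- pop - n_elite
  while (evals + n_off <= config$iterations) {
    gen <- gen + 1L
    if (config$p_crossover == 0 && config$p_mutation == 0) {
      # no variation operators: the population reproduces unchanged
      P_next <- P
      G_next <- eval_pop(P)
      evals <- evals + pop
      new_P <- P_next; new_G <- G_next
    } else {
      w <- max(G) - G
      if (!any(w > 0)) w <- rep(1, pop)   # degenerate population: uniform parents
      off <- matrix(NA_real_, n_off, L, dimnames = list(NULL, pnames))
      i <- 1L
      while (i <= n_off) {
        pr <- P[sample.int(pop, 2, replace = TRUE, prob = w), , drop = FALSE]
        if (L > 1 && stats::runif(1) < config$p_crossover) {
          k <- sample.int(L - 1L, 1)
          c1 <- c(pr[1, seq_len(k)], pr[2, seq.int(k + 1L, L)])
          c2 <- c(pr[2, seq_len(k)], pr[1, seq.int(k + 1L, L)])
        } else {
          c1 <- pr[1, ]; c2 <- pr[2, ]
        }
        off[i, ] <- c1
        if (i + 1L <= n_off) off[i + 1L, ] <- c2
        i <- i + 2L
      }
      mut <- stats::runif(n_off) < config$p_mutation
      for (j in which(mut)) {
        gidx <- sample.int(L, 1)
        if (config$mutation == "uniform" ||
            stats::runif(1) < config$p_uniform) {
          off[j, gidx] <- stats::runif(1, bounds$lower[gidx], bounds$upper[gidx])
        } else {
          step <- stats::rnorm(1, 0, config$mutation_sd *
                                 (bounds$upper[gidx] - bounds$lower[gidx]))
          off[j, gidx] <- min(max(off[j, gidx] + step, bounds$lower[gidx]),
                              bounds$upper[gidx])
        }
      }
      Goff <- eval_pop(off)
      evals <- evals + n_off
      if (n_elite > 0) {
        keep <- order(G)[seq_len(n_elite)]
        P_next <- rbind(P[keep, , drop = FALSE], off)
        G_next <- c(G[keep], Goff)
      } else {
        P_next <- off
        G_next <- Goff
      }
      new_P <- off; new_G <- Goff
    }
    P <- P_next; G <- G_next
    all_P[[length(all_P) + 1L]] <- new_P
    all_G[[length(all_G) + 1L]] <- new_G
    all_gen[[length(all_gen) + 1L]] <- rep(gen, nrow(new_P))
    trace <- rbind(trace, data.frame(generation = gen, best = min(unlist(all_G)),
                                     median = stats::median(G)))
  }

  res <- as.data.frame(do.call(rbind, all_P))
  res$gof <- unlist(all_G)
  res$generation <- unlist(all_gen)
  res <- res[order(res$gof), ]
  rownames(res) <- NULL
  best <- stats::setNames(as.numeric(res[1, pnames]), pnames)
  structure(list(results = res, best = best, best_gof = res$gof[1],
                 trace = trace, config = config, bounds = bounds,
                 evaluations = evals),
            class = "escc_ga_result")
}

#' @export
print.escc_ga_result <- function(x, ...) {
  cat(sprintf("GA calibration: %d evaluations, best GOF %.3f\n",
              x$evaluations, x$best_gof))
  invisible(x)
}

#' Select good-fitting parameter sets
#'
#' Keeps every evaluated set whose score is within `delta` of the best
#' score.  By default `delta` is the 95th percentile of a chi-squared
#' distribution with as many degrees of freedom as there are targets (the
#' selection rule is configurable; the notion of "good-fitting" is a
#' modeling choice, not a sharp statistical test).
#'
#' @param results An `escc_ga_result` or a data frame with a `gof` column.
#' @param delta Score tolerance above the best.
#' @param n_targets Degrees of freedom for the default `delta`.
#' @return Subset of the results data frame, ranked by score.
#' @export
select_good_fitting <- function(results, delta = NULL, n_targets = NULL) {
  df <- if (inherits(results, "escc_ga_result")) results$results else results
  stopifnot("gof" %in% names(df), nrow(df) > 0)
  if (is.null(delta)) {
    if (is.null(n_targets)) stop("supply delta or n_targets", call. = FALSE)
    delta <- stats::qchisq(0.95, df = n_targets)
  }
  df <- df[order(df$gof), ]
  df[df$gof <= df$gof[1] + delta, , drop = FALSE]
}

#' Sampling importance resampling
#'
#' Resamples parameter sets with replacement, with probability proportional
#' to their likelihood.  Weights are formed overflow-safely by
#' exponentiating log-likelihoods after subtracting the maximum.
#'
#' @param samples Matrix or data frame of parameter sets (one per row).
#' @param loglik Log-likelihood of each row (note: `-gof/2`).
#' @param n_resample Number of posterior draws.
#' @param seed Optional RNG seed.
#' @return List with `sample` (the resampled rows), `indices`, and
#'   `n_unique` (count of distinct original sets retained -- the effective
#'   unique weighted sample size).
#' @export
sir_resample <- function(samples, loglik, n_resample, seed = NULL) {
  samples <- as.matrix(samples)
  stopifnot(nrow(samples) == length(loglik), n_resample >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (!any(is.finite(loglik))) {
    stop("all importance weights underflowed to zero; rescale the log-likelihoods",
         call. = FALSE)
  }
  w <- exp(loglik - max(loglik[is.finite(loglik)]))
  w[!is.finite(w)] <- 0
  if (sum(w) <= 0) {
    stop("all importance weights underflowed to zero; rescale the log-likelihoods",
         call. = FALSE)
  }
  idx <- sample.int(nrow(samples), n_resample, replace = TRUE, prob = w)
  list(sample = samples[idx, , drop = FALSE], indices = idx,
       n_unique = length(unique(idx)))
}

#' Posterior parameter sample around a calibrated point estimate
#'
#' Draws proposal parameter sets from independent normal distributions
#' centered at the best-fitting free-parameter vector (truncated to the
#' calibration bounds), scores each proposal's likelihood by running the
#' cohort model, and applies [sir_resample()].  Each proposal costs one
#' cohort simulation, so `n_samples` should be scaled to the time available.
#'
#' @param center Named free-parameter vector (the best fit).
#' @param sds Named vector of proposal standard deviations; `NA` or `0`
#'   keeps that parameter fixed at `center`.
#' @param bounds Truncation bounds, see [parameter_bounds()].
#' @param n_samples Number of proposals.
#' @param targets,life_table Likelihood inputs.
#' @param n_resample Posterior draws (default `n_samples`).
#' @param seed Optional RNG seed.
#' @param base_params Fixed quantities, see [vector_to_params()].
#' @return As [sir_resample()], plus `proposals` and `loglik`.
#' @export
posterior_sample <- function(center, sds, bounds, n_samples, targets,
                             life_table, n_resample = n_samples, seed = NULL,
                             base_params = default_parameters()) {
  if (!is.null(seed)) set.seed(seed)
  targets <- as_targets(targets)
  pnames <- bounds$parameter
  stopifnot(all(pnames %in% names(center)))
  sds <- sds[pnames]
  sds[is.na(sds)] <- 0
  prop <- matrix(NA_real_, n_samples, length(pnames),
                 dimnames = list(NULL, pnames))
  for (j in seq_along(pnames)) {
    m <- center[[pnames[j]]]; s <- sds[[j]]
    if (s <= 0) {
      prop[, j] <- m
    } else {
      plo <- stats::pnorm((bounds$lower[j] - m) / s)
      phi <- stats::pnorm((bounds$upper[j] - m) / s)
      prop[, j] <- m + s * stats::qnorm(stats::runif(n_samples, plo, phi))
    }
  }
  ll <- apply(prop, 1, function(v) {
    -0.5 * gof(vector_to_params(v, base_params), targets, life_table)$value
  })
  out <- sir_resample(prop, ll, n_resample)
  out$proposals <- prop
  out$loglik <- ll
  out
}
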