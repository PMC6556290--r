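#' Target definitions of the packaged calibration set
#'
#' The 34 target definitions (kind, label, age band, effective sample size)
#' without observed values: 18 age-specific lesion-prevalence targets
#' (BCH/mD, MD, SD over six 5-year bands, 40-69; the open-ended oldest
#' prevalence band is assigned 65-69 to stay inside the 40-69 estimation
#' range), 12 ESCC incidence targets (5-year bands from 30-34; the
#' open-ended 85+ band is assigned 85-89), and 4 TNM stage-at-diagnosis
#' proportions.  Default effective sample sizes: 1,000 persons per
#' prevalence or stage target, 100,000 person-years per incidence target
#' (orders of magnitude of the source cohorts; the calibration ranking is
#' invariant to a common rescaling).
#'
#' @return Data frame of target definitions (no `value` column).
#' @export
target_definitions <- function() {
  prev_bands <- cbind(seq(40, 65, by = 5), c(seq(44, 64, by = 5), 69))
  inc_bands <- cbind(seq(30, 85, by = 5), seq(34, 89, by = 5))
  rbind(
    data.frame(kind = "incidence", label = "ESCC",
               age_lo = inc_bands[, 1], age_hi = inc_bands[, 2],
               n_eff = 1e5, stringsAsFactors = FALSE),
    do.call(rbind, lapply(c("BCH_MD", "MD", "SD"), function(lab) {
      data.frame(kind = "prevalence", label = lab,
                 age_lo = prev_bands[, 1], age_hi = prev_bands[, 2],
                 n_eff = 1000, stringsAsFactors = FALSE)
    })),
    data.frame(kind = "stage_proportion", label = c("I", "II", "III", "IV"),
               age_lo = 15, age_hi = 99, n_eff = 1000,
               stringsAsFactors = FALSE)
  )
}

#' Generate synthetic calibration targets from a known model
#'
#' Runs the cohort model at `params`, evaluates every target definition, and
#' replaces each true model proportion `p` with a binomial draw
#' `k/n_eff`, `k ~ Binomial(n_eff, p)` -- observed data as they would look
#' if the generating model were the truth.  Used by the parameter-recovery
#' tests: a calibration run against these targets should reproduce the
#' generating model's target-space outputs within binomial error.
#'
#' @inheritParams run_cohort
#' @param defs Target definitions, see [target_definitions()].
#' @param n_eff Effective sample size applied to every target (overrides
#'   the definitions' column when not `NULL`).
#' @param seed Optional RNG seed; fixed seed gives identical target sets.
#' @return An `escc_targets` data frame with a `value` column in the
#'   conventional units (percent, per 100,000, proportion).
#' @export
make_synthetic_targets <- function(params, life_table,
                                   defs = target_definitions(),
                                   n_eff = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(n_eff)) defs$n_eff <- n_eff
  defs$value <- 0   # placeholder so the model_values() contract sees targets
  p <- model_values(params, as_targets(defs), life_table)
  if (any(p < 0 | p > 1)) stop("model proportion outside [0, 1]", call. = FALSE)
  k <- stats::rbinom(length(p), round(defs$n_eff), p)
  phat <- k / round(defs$n_eff)
  defs$value <- ifelse(defs$kind == "prevalence", 100 * phat,
                       ifelse(defs$kind == "incidence", 1e5 * phat, phat))
  as_targets(defs)
}

# packaged observed calibration values: age-specific ESCC incidence
# (per 100,000) and lesion prevalence (%) in Chinese high-risk regions.
# The four stage-at-diagnosis proportions are editable placeholders at
# plausible Chinese cohort levels (their source is reported graphically
# only), flagged by the `source` column.
packaged_target_values <- function() {
  defs <- target_definitions()
  defs$value <- c(
    3.4, 12.4, 42.4, 93.1, 238.7, 475.8, 519.6, 636.8, 878.9, 925.1,
    1145.1, 967.6,                               # ESCC incidence
    13.1, 16.7, 21.1, 22.6, 25.8, 24.3,          # BCH/mD prevalence (%)
    1.24, 2.26, 3.62, 5.37, 5.5, 5.67,           # MD prevalence (%)
    0.34, 0.77, 1.71, 2.58, 2.64, 3.84,          # SD prevalence (%)
    0.15, 0.35, 0.30, 0.20                       # TNM stage placeholders
  )
  defs$source <- c(rep("registry", 12), rep("survey", 18),
                   rep("synthetic_placeholder", 4))
  as_targets(defs)
}

packaged_parameters <- function() {
  escc_parameters(
    onset = onset_params(-8.96, 0.20481, 0.00002, 0.00836),
    bchmd_to_md = progression_params(-3.359, 0.03668),
    p_md_to_sd = 0.1538, p_sd_to_u1 = 0.2094,
    p_u1_u2 = 0.1538, p_u2_u3 = 0.2094, p_u3_u4 = 0.4665,
    det1 = 0.5487, det2 = 0.3231, det3 = 0.0386, det4 = 0.3432,
    mort2 = 0.1515, mort3 = 0.3597, mort4 = 0.5647,
    onset_variant = "shifted"
  )
}

packaged_parameter_sds <- function() {
  c(beta0 = 0.461, beta1 = 0.01815, beta2 = 0, beta3 = 0.00134,
    alpha0 = 0.171, alpha1 = 0.0095,
    p_md_to_sd = NA, p_u1_u2 = NA, p_u2_u3 = NA, p_u3_u4 = NA,
    det1 = NA, det2 = NA, det3 = NA, det4 = NA)
}

#' Regenerate the packaged fixture files
#'
#' Deterministically rewrites every data file shipped under `extdata`:
#' `table1.json` (calibrated point estimates and standard deviations),
#' `table2_targets.csv` (the 34 calibration targets),
#' `life_table_cn2011_approx.csv` (the parametric background-mortality
#' approximation), and the two verification scenarios `hua_county.yaml`
#' and `cixian.yaml`.
#'
#' @param dir Output directory.
#' @return Character vector of the file paths written, invisibly.
#' @export
write_fixtures <- function(dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("table1.json", "table2_targets.csv",
                            "life_table_cn2011_approx.csv",
                            "hua_county.yaml", "cixian.yaml"))
  write_parameters(packaged_parameters(), paths[1],
                   sd = packaged_parameter_sds())
  write_targets(packaged_target_values(), paths[2])
  write_life_table(make_life_table(), paths[3])
  write_scenario(screening_scenario(onset_multiplier = 0.469,
                                    eligible_age_lo = 45, eligible_age_hi = 69,
                                    uptake = 1, sensitivity = 0.96,
                                    specificity = 0.63, followup = 0,
                                    name = "hua_county"), paths[4])
  write_scenario(screening_scenario(onset_multiplier = 1.30,
                                    eligible_age_lo = 40, eligible_age_hi = 69,
                                    uptake = 0.486, sensitivity = 0.96,
                                    specificity = 0.63, followup = 10,
                                    name = "cixian"), paths[5])
  invisible(paths)
}
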