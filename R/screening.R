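#' Screening scenario definition
#'
#' Describes a one-time endoscopic screening program layered on the natural
#' history: a regional risk adjustment multiplying the onset hazard, the
#' eligible age range, the proportion screened, test characteristics of
#' endoscopy with mucosal iodine staining, and the follow-up horizon.
#' Specificity is carried for yield/false-positive reporting; in the absence
#' of a harm model it does not alter disease dynamics.
#'
#' @param onset_multiplier Regional risk ratio applied to the onset hazard.
#' @param eligible_age_lo,eligible_age_hi Eligible ages (years, inclusive).
#' @param uptake Proportion of the eligible population screened.
#' @param sensitivity Detection probability per screened diseased person
#'   (high-grade dysplasia or cancer).
#' @param specificity True-negative probability per screened disease-free
#'   person.
#' @param followup Follow-up horizon in years.
#' @param screened_states States detectable (and, for lesions, treatable) at
#'   the screen.
#' @param name Optional scenario label.
#' @return An object of class `escc_scenario`.
#' @export
screening_scenario <- function(onset_multiplier = 1,
                               eligible_age_lo = 40, eligible_age_hi = 69,
                               uptake = 0.486, sensitivity = 0.96,
                               specificity = 0.63, followup = 10,
                               screened_states = c("MD", "SD", "U1", "U2",
                                                   "U3", "U4"),
                               name = NULL) {
  props <- c(uptake = uptake, sensitivity = sensitivity,
             specificity = specificity)
  if (any(!is.finite(props)) || any(props < 0) || any(props > 1)) {
    stop("uptake, sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(onset_multiplier >= 0, followup >= 0,
            eligible_age_lo >= 15, eligible_age_hi <= 100,
            eligible_age_lo <= eligible_age_hi)
  assert_states(screened_states)
  structure(list(onset_multiplier = onset_multiplier,
                 eligible_age_lo = as.integer(eligible_age_lo),
                 eligible_age_hi = as.integer(eligible_age_hi),
                 uptake = uptake, sensitivity = sensitivity,
                 specificity = specificity, followup = as.integer(followup),
                 screened_states = screened_states, name = name),
            class = "escc_scenario")
}

#' Read and write screening scenarios (YAML or JSON)
#'
#' Field names mirror [screening_scenario()].  The packaged scenarios
#' `hua_county.yaml` (risk multiplier 0.469, ages 45-69) and `cixian.yaml`
#' (risk multiplier 1.30, ages 40-69, 48.6% uptake, 10-year follow-up) can
#' be loaded with [hua_county_scenario()] / [cixian_scenario()].
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param scenario An `escc_scenario`.
#' @return `read_scenario()` returns an `escc_scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(screening_scenario, lst)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "escc_scenario"))
  lst <- unclass(scenario)
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname read_scenario
#' @export
hua_county_scenario <- function() {
  read_scenario(system.file("extdata", "hua_county.yaml", package = "esccsim"))
}

#' @rdname read_scenario
#' @export
cixian_scenario <- function() {
  read_scenario(system.file("extdata", "cixian.yaml", package = "esccsim"))
}

#' Truncated prevalence of lesions and occult cancer under a scenario
#'
#' Runs the natural history with the scenario's regional risk adjustment and
#' reports survivor-weighted prevalences over the eligible age range for:
#' BCH/mD, MD, SD, undetected (occult) ESCC, and total high-grade lesions
#' (severe dysplasia plus undetected cancer) -- the quantities an endoscopic
#' prevalence survey of that age band would probe.
#'
#' @inheritParams run_cohort
#' @param scenario An `escc_scenario`.
#' @return Data frame with columns `lesion` and `prevalence` (proportions).
#' @export
truncated_prevalence_report <- function(params, life_table, scenario) {
  stopifnot(inherits(scenario, "escc_scenario"))
  traj <- run_cohort(params, life_table,
                     onset_multiplier = scenario$onset_multiplier)
  lo <- scenario$eligible_age_lo; hi <- scenario$eligible_age_hi
  lesion <- c("BCH_MD", "MD", "SD", "undetected_ESCC", "total_high_grade")
  pv <- c(prevalence(traj, "BCH_MD", lo, hi),
          prevalence(traj, "MD", lo, hi),
          prevalence(traj, "SD", lo, hi),
          prevalence(traj, undetected_cancer_states(), lo, hi),
          prevalence(traj, c("SD", undetected_cancer_states()), lo, hi))
  data.frame(lesion = lesion, prevalence = pv, stringsAsFactors = FALSE)
}

#' Cumulative-hazard ratio from two cumulative incidences
#'
#' Under proportional hazards the hazard ratio equals the ratio of
#' cumulative hazards, `log(1 - ci_screen) / log(1 - ci_control)`.  This is
#' the convention used for the trial summaries.
#'
#' @param ci_screen,ci_control Cumulative incidences in `(0, 1)`.
#' @return Hazard ratio (screening vs control).
#' @export
#' @examples
#' hazard_ratio(0.0417, 0.0592)   # 0.698
hazard_ratio <- function(ci_screen, ci_control) {
  if (any(c(ci_screen, ci_control) <= 0) || any(c(ci_screen, ci_control) >= 1)) {
    stop("cumulative incidences must lie strictly within (0, 1)", call. = FALSE)
  }
  log(1 - ci_screen) / log(1 - ci_control)
}

#' Simulate a one-time screening trial
#'
#' Builds a trial cohort as the survivor-weighted cross-section of an
#' unscreened cohort over the eligible ages (people with previously detected
#' cancer are not enrolled), then follows two arms for `followup` years:
#' the control arm continues the natural history; the screening arm applies
#' a single baseline screen in which a fraction `uptake * sensitivity` of
#' each screened-state compartment is found -- screen-detected MD/SD are
#' treated curatively (returned to normal mucosa, duration and risk reset,
#' re-onset permitted), screen-detected occult cancers move to the
#' corresponding detected state.  Cumulative incidence is the fraction of
#' the baseline alive cohort clinically detected within follow-up.
#'
#' @inheritParams truncated_prevalence_report
#' @param count_screen_detected Count cancers found at the baseline screen
#'   as incident (as screening trials do).  Setting `FALSE` restricts
#'   incidence to post-baseline clinical detections.
#' @param weighting `"survivor"` (default) weights enrollment ages by the
#'   unscreened cohort's survivors; `"uniform"` weights all eligible ages
#'   equally.
#' @return An object of class `escc_screening_outcome`: cumulative
#'   incidences per arm, the hazard ratio, screening yield (true/false
#'   positives per enrollee), and the per-age detail.
#' @export
simulate_trial <- function(params, life_table, scenario,
                           count_screen_detected = TRUE,
                           weighting = c("survivor", "uniform")) {
  stopifnot(inherits(scenario, "escc_scenario"))
  weighting <- match.arg(weighting)
  mult <- scenario$onset_multiplier
  base <- run_cohort(params, life_table, onset_multiplier = mult)
  layout <- base$layout
  ages <- scenario$eligible_age_lo:scenario$eligible_age_hi
  if (max(ages) + scenario$followup > 100) {
    stop("follow-up extends beyond the simulated horizon (age 100)", call. = FALSE)
  }
  eff <- scenario$uptake * scenario$sensitivity
  lesion_treat <- intersect(scenario$screened_states, c("BCH_MD", "MD", "SD"))
  cancer_screen <- intersect(scenario$screened_states, undetected_cancer_states())

  detail <- data.frame(age = ages, weight = NA_real_, ci_control = NA_real_,
                       ci_screen = NA_real_, screen_detected = NA_real_,
                       false_positive = NA_real_)
  for (k in seq_along(ages)) {
    o <- base$occupancy[match(ages[k], base$ages), ]
    o[layout$D] <- 0   # prevalent detected cancer is not enrolled
    o[layout$X] <- 0
    w <- sum(o)
    detail$weight[k] <- if (weighting == "survivor") w else 1
    o <- o / w

    if (scenario$followup > 0) {
      ctrl <- run_cohort(params, life_table, start_age = ages[k],
                         end_age = ages[k] + scenario$followup,
                         onset_multiplier = mult, init = o)
      detail$ci_control[k] <- sum(ctrl$new_detections)
    } else detail$ci_control[k] <- 0

    os <- o
    for (s in lesion_treat) {
      cols <- state_columns(s, layout)
      moved <- sum(os[cols]) * eff
      os[cols] <- os[cols] * (1 - eff)
      os[layout$N] <- os[layout$N] + moved
    }
    sdet <- 0
    for (s in cancer_screen) {
      col <- state_columns(s, layout)
      found <- os[col] * eff
      os[col] <- os[col] - found
      os[state_columns(sub("U", "D", s), layout)] <-
        os[state_columns(sub("U", "D", s), layout)] + found
      sdet <- sdet + found
    }
    detail$screen_detected[k] <- sdet
    healthy <- sum(os[c(layout$N, layout$T)])   # normal + BCH/mD at screen
    detail$false_positive[k] <- scenario$uptake * healthy *
      (1 - scenario$specificity)
    if (scenario$followup > 0) {
      scr <- run_cohort(params, life_table, start_age = ages[k],
                        end_age = ages[k] + scenario$followup,
                        onset_multiplier = mult, init = os)
      detail$ci_screen[k] <- sum(scr$new_detections) +
        if (count_screen_detected) sdet else 0
    } else detail$ci_screen[k] <- if (count_screen_detected) sdet else 0
  }

  wts <- detail$weight / sum(detail$weight)
  ci_c <- sum(detail$ci_control * wts)
  ci_s <- sum(detail$ci_screen * wts)
  hr <- if (scenario$uptake * scenario$sensitivity == 0) 1 else
    hazard_ratio(ci_s, ci_c)
  structure(list(ci_control = ci_c, ci_screen = ci_s, hazard_ratio = hr,
                 screen_detected = sum(detail$screen_detected * wts),
                 false_positive = sum(detail$false_positive * wts),
                 detail = detail, scenario = scenario,
                 count_screen_detected = count_screen_detected,
                 weighting = weighting),
            class = "escc_screening_outcome")
}

#' @export
print.escc_screening_outcome <- function(x, ...) {
  cat(sprintf("One-time screening trial (%s), %d-year follow-up\n",
              if (is.null(x$scenario$name)) "scenario" else x$scenario$name,
              x$scenario$followup))
  cat(sprintf("  cumulative ESCC incidence: control %.3f%%, screening %.3f%%\n",
              100 * x$ci_control, 100 * x$ci_screen))
  cat(sprintf("  hazard ratio (screening vs control): %.3f\n", x$hazard_ratio))
  cat(sprintf("  screen-detected cancers: %.4f per enrollee; false positives: %.4f\n",
              x$screen_detected, x$false_positive))
  invisible(x)
}
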