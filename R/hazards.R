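#' Age-dependent hazard of developing BCH/mD from normal mucosa
#'
#' The annual rate of onset of the first precancerous lesion (basal cell
#' hyperplasia / mild dysplasia) follows a piecewise log-linear function of
#' age with knots at ages `A1` (entry, 15 y) and `A2` (40 y):
#' the log-hazard has intercept `beta0` at the left boundary, slope `beta1`
#' per year on the first age segment and a second-segment slope thereafter,
#' with a continuity correction at the knot so the log-hazard is continuous.
#' `beta3` holds the slope of a third segment above `A3`; with the default
#' `A3 = 100` that segment lies beyond the simulated horizon and the
#' parameter is inert.
#'
#' The time scale on which the slopes act is configurable because published
#' parameterizations of this functional form differ:
#' \describe{
#'   \item{`"shifted"`}{(default) slopes act on `u = age - A1`; second
#'     segment slope is `beta2`.}
#'   \item{`"shifted_beta3"`}{as `"shifted"` but with `beta3` as the
#'     second-segment slope.}
#'   \item{`"chronological"`}{slopes act on chronological age.}
#' }
#' The packaged default is the variant whose forward simulations deviate
#' least from the external verification data shipped with the package (see
#' the methods vignette).
#'
#' @param age Age in years; numeric vector, each element in `[A1, 100]`.
#' @param params An `escc_onset_params` object, see [onset_params()].
#' @param variant Onset time-scale convention, see Details.
#' @return Annual onset rate(s) `lambda1 > 0`.
#' @seealso [bchmd_progression_hazard()], [rate_to_prob()]
#' @export
#' @examples
#' onset_hazard(15, onset_params(-8.96, 0.20481, 0.00002, 0.00836)) # exp(-8.96)
onset_hazard <- function(age, params,
                         variant = c("shifted", "shifted_beta3", "chronological")) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "escc_onset_params"))
  if (any(!is.finite(age))) stop("age must be finite", call. = FALSE)
  if (any(age < params$A1 | age > 100)) {
    stop("age outside model range [", params$A1, ", 100]", call. = FALSE)
  }
  if (variant == "chronological") {
    u <- age
    knot <- params$A2
  } else {
    u <- age - params$A1
    knot <- params$A2 - params$A1
  }
  slope2 <- if (variant == "shifted_beta3") params$beta3 else params$beta2
  loglam <- ifelse(u < knot,
                   params$beta0 + params$beta1 * u,
                   params$beta0 + slope2 * u + knot * (params$beta1 - slope2))
  exp(loglam)
}

#' Onset hazard parameters
#'
#' Container for the piecewise log-linear onset hazard: baseline log-risk
#' `beta0` (dimensionless), log-risk slopes `beta1`, `beta2`, `beta3`
#' (per year), and age knots `A1 < A2 < A3` (years).
#'
#' @param beta0,beta1,beta2,beta3 Log-risk intercept and slopes.
#' @param A1,A2,A3 Age knots in years; defaults 15, 40 and 100 (the third
#'   knot effectively disables the third segment).
#' @return An object of class `escc_onset_params`.
#' @export
onset_params <- function(beta0, beta1, beta2, beta3, A1 = 15, A2 = 40, A3 = 100) {
  vals <- c(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
            A1 = A1, A2 = A2, A3 = A3)
  if (any(!is.finite(vals))) {
    stop("non-finite onset hazard parameter: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "), call. = FALSE)
  }
  if (!(A1 < A2 && A2 < A3)) stop("age knots must satisfy A1 < A2 < A3", call. = FALSE)
  structure(as.list(vals), class = "escc_onset_params")
}

#' Duration-dependent hazard of progression from BCH/mD to MD
#'
#' The annual rate of progression from the first lesion state to moderate
#' dysplasia decays with time already spent in the state:
#' `lambda2 = exp(alpha0 - alpha1 * duration)`.  A positive `alpha1` encodes
#' that lesions which have persisted without progressing are progressively
#' less likely to progress (selection of indolent lesions).
#'
#' @param duration Years spent in the BCH/mD state; numeric vector, `>= 0`.
#' @param params An `escc_progression_params` object, see
#'   [progression_params()].
#' @return Annual progression rate(s) `lambda2 > 0`.
#' @export
#' @examples
#' bchmd_progression_hazard(0, progression_params(-3.359, 0.03668)) # exp(-3.359)
bchmd_progression_hazard <- function(duration, params) {
  stopifnot(inherits(params, "escc_progression_params"))
  if (any(!is.finite(duration)) || any(duration < 0)) {
    stop("duration must be finite and >= 0", call. = FALSE)
  }
  exp(params$alpha0 - params$alpha1 * duration)
}

#' @param alpha0 Baseline log-risk (dimensionless).
#' @param alpha1 Log-risk decline per year of duration.
#' @rdname bchmd_progression_hazard
#' @export
progression_params <- function(alpha0, alpha1) {
  if (!is.finite(alpha0) || !is.finite(alpha1)) {
    stop("non-finite progression hazard parameter", call. = FALSE)
  }
  structure(list(alpha0 = alpha0, alpha1 = alpha1),
            class = "escc_progression_params")
}

#' Convert an annual rate to an annual transition probability
#'
#' Standard exponential conversion `p = 1 - exp(-rate)` for a constant
#' hazard acting over a one-year cycle.
#'
#' @param rate Non-negative annual rate(s).
#' @return Annual probability(ies) in `[0, 1)`.
#' @export
#' @examples
#' rate_to_prob(0.0347)
rate_to_prob <- function(rate) {
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop("rate must be finite and >= 0", call. = FALSE)
  }
  1 - exp(-rate)
}
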