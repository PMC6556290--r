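#' Full parameter set of the ESCC natural-history model
#'
#' Bundles every transition quantity of the model: the age-dependent onset
#' hazard (normal -> BCH/mD), the duration-dependent BCH/mD -> MD hazard,
#' fixed annual progression probabilities through the lesion and preclinical
#' cancer sequence, annual stage-specific clinical detection probabilities,
#' and annual disease-specific mortality probabilities for detected TNM
#' II-IV.  Detected TNM I carries background mortality only (taken as
#' equivalent to the general population after complete resection); undetected
#' cancer carries background mortality only.
#'
#' @param onset [onset_params()] object.
#' @param bchmd_to_md [progression_params()] object.
#' @param p_md_to_sd Annual probability MD -> SD.
#' @param p_sd_to_u1 Annual probability SD -> undetected TNM I.
#' @param p_u1_u2,p_u2_u3,p_u3_u4 Annual stage-progression probabilities for
#'   undetected cancer.
#' @param det1,det2,det3,det4 Annual stage-specific clinical detection
#'   probabilities.
#' @param mort2,mort3,mort4 Annual disease-specific mortality probabilities
#'   for detected TNM II-IV.
#' @param onset_variant Onset time-scale convention, see [onset_hazard()].
#' @return An object of class `escc_parameters`.
#' @seealso [default_parameters()] for the packaged calibrated point
#'   estimates.
#' @export
escc_parameters <- function(onset, bchmd_to_md,
                            p_md_to_sd, p_sd_to_u1,
                            p_u1_u2, p_u2_u3, p_u3_u4,
                            det1, det2, det3, det4,
                            mort2, mort3, mort4,
                            onset_variant = "shifted") {
  stopifnot(inherits(onset, "escc_onset_params"),
            inherits(bchmd_to_md, "escc_progression_params"))
  probs <- c(p_md_to_sd = p_md_to_sd, p_sd_to_u1 = p_sd_to_u1,
             p_u1_u2 = p_u1_u2, p_u2_u3 = p_u2_u3, p_u3_u4 = p_u3_u4,
             det1 = det1, det2 = det2, det3 = det3, det4 = det4,
             mort2 = mort2, mort3 = mort3, mort4 = mort4)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("probability parameter(s) outside [0, 1]: ",
         paste(names(probs)[!is.finite(probs) | probs < 0 | probs > 1],
               collapse = ", "),
         call. = FALSE)
  }
  onset_variant <- match.arg(onset_variant,
                             c("shifted", "shifted_beta3", "chronological"))
  structure(c(list(onset = onset, bchmd_to_md = bchmd_to_md),
              as.list(probs),
              list(onset_variant = onset_variant)),
            class = "escc_parameters")
}

#' Calibrated point-estimate parameters
#'
#' The packaged calibrated expected values of every model parameter,
#' read from the `table1.json` file shipped with the package (onset betas,
#' progression alphas, lesion/stage progression, detection and mortality
#' probabilities).
#'
#' @return An `escc_parameters` object.
#' @export
#' @examples
#' p <- default_parameters()
#' p$p_sd_to_u1   # 0.2094
default_parameters <- function() {
  read_parameters(system.file("extdata", "table1.json", package = "esccsim"))
}

#' Parameter standard deviations of the calibrated point estimates
#'
#' Standard deviations packaged alongside the point estimates, used as the
#' proposal scale for sampling importance resampling.  Parameters with no
#' reported uncertainty (fixed inputs) carry `NA`.
#'
#' @return Named numeric vector over [free_parameter_names()].
#' @export
default_parameter_sds <- function() {
  js <- jsonlite::read_json(system.file("extdata", "table1.json",
                                        package = "esccsim"),
                            simplifyVector = TRUE)
  v <- unlist(js$sd)
  out <- stats::setNames(rep(NA_real_, length(free_parameter_names())),
                         free_parameter_names())
  keep <- intersect(names(v), names(out))
  out[keep] <- v[keep]
  out
}

#' @export
print.escc_parameters <- function(x, ...) {
  cat("ESCC natural-history model parameters\n")
  cat(sprintf("  onset (variant %s): beta0=%.4g beta1=%.4g beta2=%.4g beta3=%.4g\n",
              x$onset_variant, x$onset$beta0, x$onset$beta1, x$onset$beta2,
              x$onset$beta3))
  cat(sprintf("  BCH/mD -> MD: alpha0=%.4g alpha1=%.4g\n",
              x$bchmd_to_md$alpha0, x$bchmd_to_md$alpha1))
  cat(sprintf("  lesion/stage progression: MD->SD %.4f, SD->U1 %.4f, U1->U2 %.4f, U2->U3 %.4f, U3->U4 %.4f\n",
              x$p_md_to_sd, x$p_sd_to_u1, x$p_u1_u2, x$p_u2_u3, x$p_u3_u4))
  cat(sprintf("  detection I-IV: %.4f %.4f %.4f %.4f\n",
              x$det1, x$det2, x$det3, x$det4))
  cat(sprintf("  mortality II-IV: %.4f %.4f %.4f\n", x$mort2, x$mort3, x$mort4))
  invisible(x)
}

#' Names of the calibrated (free) parameters
#'
#' The parameters estimated by calibration: the four onset betas, the two
#' progression alphas, MD -> SD, the three undetected-stage progression
#' probabilities and the four detection probabilities.  `p_sd_to_u1` and the
#' mortality probabilities are fixed external inputs.
#'
#' @return Character vector of length 14.
#' @export
free_parameter_names <- function() {
  c("beta0", "beta1", "beta2", "beta3", "alpha0", "alpha1",
    "p_md_to_sd", "p_u1_u2", "p_u2_u3", "p_u3_u4",
    "det1", "det2", "det3", "det4")
}

#' Plausible bounds for the free parameters
#'
#' Wide, inclusive search bounds for calibration, spanning several standard
#' deviations around the packaged point estimates plus room informed by the
#' sources of the fixed inputs.  Every packaged point estimate lies strictly
#' inside its bounds.
#'
#' @return Data frame with columns `parameter`, `lower`, `upper`.
#' @export
parameter_bounds <- function() {
  data.frame(
    parameter = free_parameter_names(),
    lower = c(-12, 0,    -0.02, 0,    -6,   0,
              0.01, 0.01, 0.01, 0.01,
              0.01, 0.01, 0.01, 0.01),
    upper = c(-6,  0.4,   0.02, 0.05, -1.5, 0.15,
              0.6,  0.6,  0.6,  0.9,
              0.9,  0.9,  0.9,  0.9),
    stringsAsFactors = FALSE
  )
}

#' Map between free-parameter vectors and full parameter sets
#'
#' `params_to_vector()` extracts the free parameters as a named numeric
#' vector; `vector_to_params()` rebuilds a full `escc_parameters` object by
#' combining a free-parameter vector with the fixed quantities of a base
#' parameter set.  Used by the calibration engine, whose chromosomes are
#' free-parameter vectors.
#'
#' @param params,base `escc_parameters` objects.
#' @param x Named numeric vector over [free_parameter_names()].
#' @return A named numeric vector, or an `escc_parameters` object.
#' @export
params_to_vector <- function(params) {
  stopifnot(inherits(params, "escc_parameters"))
  c(beta0 = params$onset$beta0, beta1 = params$onset$beta1,
    beta2 = params$onset$beta2, beta3 = params$onset$beta3,
    alpha0 = params$bchmd_to_md$alpha0, alpha1 = params$bchmd_to_md$alpha1,
    p_md_to_sd = params$p_md_to_sd,
    p_u1_u2 = params$p_u1_u2, p_u2_u3 = params$p_u2_u3,
    p_u3_u4 = params$p_u3_u4,
    det1 = params$det1, det2 = params$det2, det3 = params$det3,
    det4 = params$det4)
}

#' @rdname params_to_vector
#' @export
vector_to_params <- function(x, base = default_parameters()) {
  stopifnot(is.numeric(x), all(free_parameter_names() %in% names(x)))
  escc_parameters(
    onset = onset_params(x[["beta0"]], x[["beta1"]], x[["beta2"]], x[["beta3"]],
                         A1 = base$onset$A1, A2 = base$onset$A2,
                         A3 = base$onset$A3),
    bchmd_to_md = progression_params(x[["alpha0"]], x[["alpha1"]]),
    p_md_to_sd = x[["p_md_to_sd"]], p_sd_to_u1 = base$p_sd_to_u1,
    p_u1_u2 = x[["p_u1_u2"]], p_u2_u3 = x[["p_u2_u3"]],
    p_u3_u4 = x[["p_u3_u4"]],
    det1 = x[["det1"]], det2 = x[["det2"]], det3 = x[["det3"]],
    det4 = x[["det4"]],
    mort2 = base$mort2, mort3 = base$mort3, mort4 = base$mort4,
    onset_variant = base$onset_variant
  )
}

#' Read and write model parameters as JSON
#'
#' The JSON layout mirrors the parameter structure: a `params` block with
#' every model quantity on its natural scale, an optional `sd` block with
#' standard deviations, and an `onset_variant` string.
#'
#' @param path File path.
#' @param params `escc_parameters` object.
#' @param sd Optional named list/vector of standard deviations to store.
#' @return `read_parameters()` returns an `escc_parameters` object;
#'   `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- js$params
  escc_parameters(
    onset = onset_params(p$beta0, p$beta1, p$beta2, p$beta3,
                         A1 = p$A1, A2 = p$A2, A3 = p$A3),
    bchmd_to_md = progression_params(p$alpha0, p$alpha1),
    p_md_to_sd = p$p_md_to_sd, p_sd_to_u1 = p$p_sd_to_u1,
    p_u1_u2 = p$p_u1_u2, p_u2_u3 = p$p_u2_u3, p_u3_u4 = p$p_u3_u4,
    det1 = p$det1, det2 = p$det2, det3 = p$det3, det4 = p$det4,
    mort2 = p$mort2, mort3 = p$mort3, mort4 = p$mort4,
    onset_variant = if (is.null(js$onset_variant)) "shifted" else js$onset_variant
  )
}

#' @rdname read_parameters
#' @export
write_parameters <- function(params, path, sd = NULL) {
  stopifnot(inherits(params, "escc_parameters"))
  p <- c(params$onset[c("beta0", "beta1", "beta2", "beta3", "A1", "A2", "A3")],
         params$bchmd_to_md[c("alpha0", "alpha1")],
         params[c("p_md_to_sd", "p_sd_to_u1", "p_u1_u2", "p_u2_u3", "p_u3_u4",
                  "det1", "det2", "det3", "det4", "mort2", "mort3", "mort4")])
  out <- list(params = p, onset_variant = params$onset_variant)
  if (!is.null(sd)) out$sd <- as.list(sd)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
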