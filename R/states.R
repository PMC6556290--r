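#' Health states of the ESCC natural-history model
#'
#' The model follows a cohort through thirteen mutually exclusive health
#' states: normal esophageal mucosa; three ordered precancerous lesion states
#' (basal cell hyperplasia / mild dysplasia merged as `BCH_MD`, moderate
#' dysplasia `MD`, severe dysplasia `SD`); undetected (preclinical) cancer in
#' TNM stages I-IV (`U1`-`U4`); clinically detected cancer in TNM stages I-IV
#' (`D1`-`D4`); and `DEATH`, which is absorbing.  Progression is strictly
#' ordered -- there is no direct transition from normal mucosa to cancer and
#' no regression between lesion states.
#'
#' @return Character vector of the 13 state labels, in progression order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("NORMAL", "BCH_MD", "MD", "SD",
    "U1", "U2", "U3", "U4",
    "D1", "D2", "D3", "D4",
    "DEATH")
}

#' @rdname health_states
#' @export
alive_states <- function() setdiff(health_states(), "DEATH")

#' @rdname health_states
#' @export
undetected_cancer_states <- function() c("U1", "U2", "U3", "U4")

#' @rdname health_states
#' @export
detected_cancer_states <- function() c("D1", "D2", "D3", "D4")

assert_states <- function(states) {
  bad <- setdiff(states, health_states())
  if (length(bad) > 0) {
    stop("unknown health state(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(states)
}
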