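# Compartment layout.  BCH/mD carries annual duration-tunnel compartments so
# that the duration-dependent progression hazard of Eq.-type
# lambda2(T) = exp(alpha0 - alpha1 T) can be evaluated exactly; the tunnel is
# long enough (85 slots) for the full age-15-to-100 horizon, so no
# truncation ever occurs within a simulation.
TUNNEL <- 85L

compartment_layout <- function() {
  iN <- 1L
  iT <- seq.int(2L, 1L + TUNNEL)
  iMD <- TUNNEL + 2L
  iSD <- TUNNEL + 3L
  iU <- seq.int(TUNNEL + 4L, TUNNEL + 7L)
  iD <- seq.int(TUNNEL + 8L, TUNNEL + 11L)
  iX <- TUNNEL + 12L
  list(N = iN, T = iT, MD = iMD, SD = iSD, U = iU, D = iD, X = iX,
       n = TUNNEL + 12L)
}

# columns of the occupancy matrix belonging to each of the 13 states
state_columns <- function(states, layout = compartment_layout()) {
  assert_states(states)
  cols <- integer(0)
  for (s in states) {
    cols <- c(cols, switch(s,
      NORMAL = layout$N, BCH_MD = layout$T, MD = layout$MD, SD = layout$SD,
      U1 = layout$U[1], U2 = layout$U[2], U3 = layout$U[3], U4 = layout$U[4],
      D1 = layout$D[1], D2 = layout$D[2], D3 = layout$D[3], D4 = layout$D[4],
      DEATH = layout$X))
  }
  cols
}

# competing annual probabilities within one cycle are mutually exclusive;
# if they sum past 1 they are rescaled proportionally (degenerate parameter
# draws only -- never triggered by the packaged estimates)
scale_competing <- function(total) ifelse(total > 1, 1 / total, 1)

# one annual cycle.  o: compartment occupancy; pon: onset probability at this
# age (already risk-multiplied); q: background death probability; pprog:
# tunnel vector of BCH/mD progression probabilities by duration.
step_cycle <- function(o, pon, q, pprog, params, layout) {
  iN <- layout$N; iT <- layout$T; iMD <- layout$MD; iSD <- layout$SD
  iU <- layout$U; iD <- layout$D; iX <- layout$X
  nw <- numeric(layout$n)
  det <- numeric(4)

  # normal mucosa: onset vs background death
  sc <- scale_competing(pon + q)
  nw[iN] <- o[iN] * (1 - (pon + q) * sc)
  nw[iT[1]] <- o[iN] * pon * sc
  nw[iX] <- o[iN] * q * sc

  # BCH/mD duration tunnel: duration-dependent progression vs background
  # death; survivors advance one duration slot (last slot retains overflow,
  # unreachable within the 85-cycle horizon)
  ot <- o[iT]
  sct <- scale_competing(pprog + q)
  prog <- ot * pprog * sct
  died <- ot * q * sct
  stay <- ot - prog - died
  nw[iMD] <- sum(prog)
  adv <- c(0, stay[-TUNNEL])
  adv[TUNNEL] <- adv[TUNNEL] + stay[TUNNEL]
  nw[iT] <- nw[iT] + adv
  nw[iX] <- nw[iX] + sum(died)

  # MD and SD: fixed annual progression vs background death
  sc <- scale_competing(params$p_md_to_sd + q)
  nw[iSD] <- o[iMD] * params$p_md_to_sd * sc
  nw[iMD] <- nw[iMD] + o[iMD] * (1 - (params$p_md_to_sd + q) * sc)
  nw[iX] <- nw[iX] + o[iMD] * q * sc

  sc <- scale_competing(params$p_sd_to_u1 + q)
  nw[iU[1]] <- o[iSD] * params$p_sd_to_u1 * sc
  nw[iSD] <- nw[iSD] + o[iSD] * (1 - (params$p_sd_to_u1 + q) * sc)
  nw[iX] <- nw[iX] + o[iSD] * q * sc

  # undetected cancer: stage progression vs clinical detection vs background
  # death (no excess mortality while undetected)
  pu <- c(params$p_u1_u2, params$p_u2_u3, params$p_u3_u4, 0)
  pd <- c(params$det1, params$det2, params$det3, params$det4)
  for (s in 1:4) {
    os <- o[iU[s]]
    sc <- scale_competing(pu[s] + pd[s] + q)
    det[s] <- os * pd[s] * sc
    nw[iD[s]] <- nw[iD[s]] + det[s]
    if (s < 4) nw[iU[s + 1]] <- nw[iU[s + 1]] + os * pu[s] * sc
    nw[iU[s]] <- nw[iU[s]] + os * (1 - (pu[s] + pd[s] + q) * sc)
    nw[iX] <- nw[iX] + os * q * sc
  }

  # detected TNM I: background mortality only (post-resection survival taken
  # as equivalent to the general population); II-IV: disease-specific and
  # background mortality composed as independent competing risks
  nw[iD[1]] <- nw[iD[1]] + o[iD[1]] * (1 - q)
  nw[iX] <- nw[iX] + o[iD[1]] * q
  pm <- c(NA_real_, params$mort2, params$mort3, params$mort4)
  for (s in 2:4) {
    pdie <- 1 - (1 - q) * (1 - pm[s])
    nw[iD[s]] <- nw[iD[s]] + o[iD[s]] * (1 - pdie)
    nw[iX] <- nw[iX] + o[iD[s]] * pdie
  }

  nw[iX] <- nw[iX] + o[iX]
  list(o = nw, det = det)
}

#' Simulate the cohort natural history
#'
#' Runs the deterministic annual-cycle cohort simulation from `start_age` to
#' `end_age`.  The cohort starts entirely in the normal state (or in a
#' caller-supplied occupancy, used e.g. to continue a cross-section through a
#' screening follow-up).  Occupancy over all compartments, including death,
#' is conserved to within `1e-9` at every cycle; a violation aborts with an
#' internal consistency error.
#'
#' @param params An [escc_parameters()] object.
#' @param life_table An `escc_life_table` background-mortality table.
#' @param start_age,end_age Simulated age span in years (default 15 to 100).
#' @param onset_multiplier Dimensionless risk adjustment applied to the
#'   onset hazard `lambda1` only (regional risk ratio); all other
#'   transitions are unaffected.
#' @param init Optional initial occupancy: either a named vector over (a
#'   subset of) [health_states()] or a full compartment vector from a
#'   previous trajectory's `occupancy` row.  Default: all mass in `NORMAL`.
#' @return An object of class `escc_trajectory` with elements
#'   \describe{
#'     \item{occupancy}{matrix, one row per age `start_age..end_age`, one
#'       column per (state x duration) compartment; rows sum to 1.}
#'     \item{new_detections}{matrix, one row per cycle (age at cycle start),
#'       columns TNM I-IV: fraction of the cohort newly clinically detected.}
#'     \item{deaths}{per-cycle fraction dying.}
#'     \item{ages}{integer ages of the occupancy rows.}
#'   }
#' @seealso [prevalence()], [incidence()], [stage_distribution()]
#' @export
#' @examples
#' traj <- run_cohort(default_parameters(), make_life_table())
#' incidence(traj, 60, 64)   # per 100,000 person-years
run_cohort <- function(params, life_table, start_age = 15, end_age = 100,
                       onset_multiplier = 1, init = NULL) {
  stopifnot(inherits(params, "escc_parameters"))
  if (!is.finite(onset_multiplier) || onset_multiplier < 0) {
    stop("onset_multiplier must be finite and >= 0", call. = FALSE)
  }
  if (!(start_age >= params$onset$A1 && end_age <= 100 && start_age < end_age)) {
    stop("need ", params$onset$A1, " <= start_age < end_age <= 100", call. = FALSE)
  }
  layout <- compartment_layout()
  ncyc <- end_age - start_age
  qx <- qx_lookup(life_table)

  o0 <- numeric(layout$n)
  if (is.null(init)) {
    o0[layout$N] <- 1
  } else if (length(init) == layout$n) {
    o0 <- as.numeric(init)
  } else if (!is.null(names(init))) {
    assert_states(names(init))
    for (s in names(init)) {
      o0[state_columns(s, layout)[1]] <- o0[state_columns(s, layout)[1]] + init[[s]]
    }
  } else {
    stop("init must be a named state vector or a full compartment vector",
         call. = FALSE)
  }
  if (any(o0 < 0)) stop("negative initial occupancy", call. = FALSE)
  o0 <- o0 / sum(o0)

  ages <- start_age:end_age
  pon <- rate_to_prob(onset_multiplier *
                        onset_hazard(ages[-length(ages)], params$onset,
                                     variant = params$onset_variant))
  pprog <- rate_to_prob(bchmd_progression_hazard(0:(TUNNEL - 1),
                                                 params$bchmd_to_md))

  occ <- matrix(0, ncyc + 1, layout$n)
  det <- matrix(0, ncyc, 4, dimnames = list(NULL, c("I", "II", "III", "IV")))
  deaths <- numeric(ncyc)
  occ[1, ] <- o0
  for (t in seq_len(ncyc)) {
    st <- step_cycle(occ[t, ], pon[t], qx[ages[t] + 1], pprog, params, layout)
    if (abs(sum(st$o) - 1) > 1e-9) {
      stop("internal consistency error: occupancy not conserved at age ",
           ages[t], call. = FALSE)
    }
    occ[t + 1, ] <- st$o
    det[t, ] <- st$det
    deaths[t] <- st$o[layout$X] - occ[t, layout$X]
  }
  rownames(occ) <- ages
  rownames(det) <- ages[-length(ages)]
  structure(list(occupancy = occ, new_detections = det, deaths = deaths,
                 ages = ages, layout = layout, params = params,
                 onset_multiplier = onset_multiplier),
            class = "escc_trajectory")
}

#' One-cycle transition probabilities out of a health state
#'
#' Destination distribution, aggregated over the 13 states, for an
#' individual in `state` at `age` (with `duration_index` years already spent
#' in BCH/mD where relevant).  A thin probe over the same cycle kernel used
#' by [run_cohort()].
#'
#' @inheritParams run_cohort
#' @param state A label from [health_states()].
#' @param age Age in years at the start of the cycle.
#' @param duration_index Completed years in BCH/mD (only used for `BCH_MD`).
#' @return Named probability vector over the 13 states, summing to 1.
#' @export
transition_row <- function(state, age, params, life_table,
                           duration_index = 0, onset_multiplier = 1) {
  assert_states(state)
  layout <- compartment_layout()
  o <- numeric(layout$n)
  if (state == "BCH_MD") {
    stopifnot(duration_index >= 0, duration_index < TUNNEL)
    o[layout$T[duration_index + 1]] <- 1
  } else {
    o[state_columns(state, layout)[1]] <- 1
  }
  pon <- rate_to_prob(onset_multiplier *
                        onset_hazard(age, params$onset,
                                     variant = params$onset_variant))
  pprog <- rate_to_prob(bchmd_progression_hazard(0:(TUNNEL - 1),
                                                 params$bchmd_to_md))
  st <- step_cycle(o, pon, qx_lookup(life_table)[age + 1], pprog, params, layout)
  out <- vapply(health_states(),
                function(s) sum(st$o[state_columns(s, layout)]), numeric(1))
  names(out) <- health_states()
  out
}

#' Occupancy aggregated to the 13 health states
#'
#' @param traj An `escc_trajectory`.
#' @return Matrix with one row per age and one column per state.
#' @export
state_occupancy <- function(traj) {
  stopifnot(inherits(traj, "escc_trajectory"))
  out <- vapply(health_states(),
                function(s) rowSums(traj$occupancy[, state_columns(s, traj$layout),
                                                   drop = FALSE]),
                numeric(nrow(traj$occupancy)))
  rownames(out) <- traj$ages
  out
}

traj_rows <- function(traj, age_lo, age_hi, need_cycles = FALSE) {
  ages <- if (need_cycles) traj$ages[-length(traj$ages)] else traj$ages
  if (age_lo > age_hi || age_lo < min(ages) || age_hi > max(ages)) {
    stop("age range [", age_lo, ", ", age_hi, "] outside simulated ages",
         call. = FALSE)
  }
  which(ages >= age_lo & ages <= age_hi)
}

#' Survivor-weighted prevalence over an age range
#'
#' Occupancy of the requested states divided by the alive occupancy (all
#' states except death), summed over every simulated age in
#' `[age_lo, age_hi]`; ages with fewer survivors therefore contribute less
#' (truncated prevalence of a cohort cross-section).
#'
#' @param traj An `escc_trajectory`.
#' @param states Character vector of labels from [health_states()].
#' @param age_lo,age_hi Age range in years (inclusive).
#' @return Proportion in `[0, 1]`.
#' @export
prevalence <- function(traj, states, age_lo, age_hi) {
  stopifnot(inherits(traj, "escc_trajectory"), length(states) > 0)
  assert_states(states)
  rows <- traj_rows(traj, age_lo, age_hi)
  alive <- sum(traj$occupancy[rows, -traj$layout$X, drop = FALSE])
  if (alive <= 0) stop("undefined prevalence: no alive population in range",
                       call. = FALSE)
  sum(traj$occupancy[rows, state_columns(states, traj$layout), drop = FALSE]) / alive
}

#' Clinical ESCC incidence over an age range
#'
#' New clinical detections (first entry into any detected state, all TNM
#' stages -- the registry incidence event) per person-year alive, scaled to
#' 100,000 person-years.  Person-years are approximated by the alive
#' occupancy at each cycle start.
#'
#' @inheritParams prevalence
#' @return Rate per 100,000 person-years.
#' @export
incidence <- function(traj, age_lo, age_hi) {
  stopifnot(inherits(traj, "escc_trajectory"))
  rows <- traj_rows(traj, age_lo, age_hi, need_cycles = TRUE)
  py <- sum(traj$occupancy[rows, -traj$layout$X, drop = FALSE])
  if (py <= 0) stop("undefined incidence: no person-years in range", call. = FALSE)
  1e5 * sum(traj$new_detections[rows, , drop = FALSE]) / py
}

#' TNM stage distribution at diagnosis
#'
#' Per-stage share of new clinical detections accumulated over the age
#' range; sums to 1.
#'
#' @inheritParams prevalence
#' @return Named numeric vector of 4 proportions (stages I-IV).
#' @export
stage_distribution <- function(traj, age_lo, age_hi) {
  stopifnot(inherits(traj, "escc_trajectory"))
  rows <- traj_rows(traj, age_lo, age_hi, need_cycles = TRUE)
  tot <- colSums(traj$new_detections[rows, , drop = FALSE])
  if (sum(tot) <= 0) {
    stop("undefined stage distribution: no detections in range", call. = FALSE)
  }
  tot / sum(tot)
}

#' @export
print.escc_trajectory <- function(x, ...) {
  cat(sprintf("ESCC cohort trajectory: ages %d-%d, onset multiplier %.3g\n",
              min(x$ages), max(x$ages), x$onset_multiplier))
  cat(sprintf("  cumulative clinical detections: %.4f%%\n",
              100 * sum(x$new_detections)))
  cat(sprintf("  surviving at age %d: %.1f%%\n", max(x$ages),
              100 * (1 - x$occupancy[nrow(x$occupancy), x$layout$X])))
  invisible(x)
}

#' Tidy export of a trajectory
#'
#' @param x An `escc_trajectory`.
#' @param ... Unused.
#' @return Data frame with columns `cycle`, `age`, `state`,
#'   `duration_index` (`NA` outside the BCH/mD tunnel) and `occupancy`.
#' @export
as.data.frame.escc_trajectory <- function(x, ...) {
  layout <- x$layout
  comp_state <- character(layout$n)
  comp_dur <- rep(NA_integer_, layout$n)
  comp_state[layout$N] <- "NORMAL"
  comp_state[layout$T] <- "BCH_MD"
  comp_dur[layout$T] <- 0:(TUNNEL - 1)
  comp_state[layout$MD] <- "MD"; comp_state[layout$SD] <- "SD"
  comp_state[layout$U] <- c("U1", "U2", "U3", "U4")
  comp_state[layout$D] <- c("D1", "D2", "D3", "D4")
  comp_state[layout$X] <- "DEATH"
  n_age <- nrow(x$occupancy)
  data.frame(
    cycle = rep(seq_len(n_age) - 1L, times = layout$n),
    age = rep(x$ages, times = layout$n),
    state = rep(comp_state, each = n_age),
    duration_index = rep(comp_dur, each = n_age),
    occupancy = as.vector(x$occupancy),
    stringsAsFactors = FALSE
  )
}
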