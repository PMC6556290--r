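# shared fixtures for the test suite (built in code, no files)

tbl_params <- function() default_parameters()
tbl_lt <- function() default_life_table()

# life table with a constant annual death probability (flat hazard)
flat_life_table <- function(q = 0) {
  as_life_table(data.frame(age = 0:100, qx = q))
}

# parameter set with every transition probability zero and near-zero hazards
inert_params <- function() {
  escc_parameters(
    onset = onset_params(-30, 0, 0, 0),
    bchmd_to_md = progression_params(-30, 0),
    p_md_to_sd = 0, p_sd_to_u1 = 0, p_u1_u2 = 0, p_u2_u3 = 0, p_u3_u4 = 0,
    det1 = 0, det2 = 0, det3 = 0, det4 = 0,
    mort2 = 0, mort3 = 0, mort4 = 0
  )
}

# independent memoryless 13-state simulator (no duration tunnel), used as
# the oracle for the tunnel-equivalence property when alpha1 = 0.  It
# mirrors the model's competing-transition convention but is written
# separately from the package engine.
memoryless_cohort <- function(params, life_table, mult = 1,
                              start = 15, end = 100) {
  states <- health_states()
  qx <- life_table$qx[match(start:(end - 1), life_table$age)]
  occ <- matrix(0, end - start + 1, 13, dimnames = list(start:end, states))
  occ[1, "NORMAL"] <- 1
  pprog <- 1 - exp(-exp(params$bchmd_to_md$alpha0))  # alpha1 = 0: constant
  # the model's convention: competing events within a cycle are mutually
  # exclusive; if their probabilities sum past 1 they are rescaled
  nm <- function(tot) if (tot > 1) 1 / tot else 1
  for (t in seq_len(end - start)) {
    a <- start + t - 1
    o <- occ[t, ]; q <- qx[t]
    pon <- 1 - exp(-mult * onset_hazard(a, params$onset,
                                        variant = params$onset_variant))
    nw <- stats::setNames(numeric(13), states)
    nw["NORMAL"] <- o["NORMAL"] * (1 - (pon + q) * nm(pon + q))
    nw["BCH_MD"] <- o["NORMAL"] * pon * nm(pon + q) +
      o["BCH_MD"] * (1 - (pprog + q) * nm(pprog + q))
    nw["MD"] <- o["BCH_MD"] * pprog * nm(pprog + q) +
      o["MD"] * (1 - (params$p_md_to_sd + q) * nm(params$p_md_to_sd + q))
    nw["SD"] <- o["MD"] * params$p_md_to_sd * nm(params$p_md_to_sd + q) +
      o["SD"] * (1 - (params$p_sd_to_u1 + q) * nm(params$p_sd_to_u1 + q))
    pu <- c(params$p_u1_u2, params$p_u2_u3, params$p_u3_u4, 0)
    pd <- c(params$det1, params$det2, params$det3, params$det4)
    scu <- vapply(1:4, function(s) nm(pu[s] + pd[s] + q), numeric(1))
    nw["U1"] <- o["SD"] * params$p_sd_to_u1 * nm(params$p_sd_to_u1 + q) +
      o["U1"] * (1 - (pu[1] + pd[1] + q) * scu[1])
    for (s in 2:4) {
      us <- paste0("U", s)
      nw[us] <- o[paste0("U", s - 1)] * pu[s - 1] * scu[s - 1] +
        o[us] * (1 - (pu[s] + pd[s] + q) * scu[s])
    }
    nw["D1"] <- o["U1"] * pd[1] * scu[1] + o["D1"] * (1 - q)
    pm <- c(NA, params$mort2, params$mort3, params$mort4)
    for (s in 2:4) {
      ds <- paste0("D", s)
      nw[ds] <- o[paste0("U", s)] * pd[s] * scu[s] +
        o[ds] * (1 - q) * (1 - pm[s])
    }
    nw["DEATH"] <- o["DEATH"] + (sum(o) - o["DEATH"]) - sum(nw[1:12])
    occ[t + 1, ] <- nw
  }
  occ
}
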