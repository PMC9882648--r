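# Shared scenario builders for engine tests.

# Deterministic-friendly scenario: no falls, no deaths, fixed horizon.
quiet_scenario <- function(max_cycles = 30L, discount = 0) {
  sc <- generate_default_scenario(1)
  sc$hazard$fall_rate[] <- 0
  sc$pathway$mortality <- list(model = "constant", per_cycle = 0)
  sc$pathway$relocation[] <- 0
  sc$plan <- cycle_plan(14, 110, discount, max_cycles = max_cycles)
  sc
}

# Homogeneous, history-free scenario whose occupancy chain is Markov on the
# six settings: constant mortality, no attribute or history effects,
# identical injury splits in both living settings, origin-independent
# discharge destination, geometric lengths of stay.
homogeneous_scenario <- function(p_fall, p_mort,
                                 injury_split = NULL,
                                 p_disch_rac = 0.2,
                                 p_reloc = c(community_to_rac = 0.003,
                                             rac_to_community = 0.001),
                                 max_cycles = 50L) {
  sc <- generate_default_scenario(1)
  sc$hazard$fall_rate[] <- -log(1 - p_fall)
  sc$hazard$attribute_log_rr <- numeric(0)
  sc$hazard$history <- list(prior_fall_multiplier = 1,
                            prior_injury_multiplier = 1,
                            recent_fall_window = 0L,
                            recent_fall_multiplier = 1)
  if (!is.null(injury_split)) {
    cols <- colnames(sc$hazard$injury_split)
    sc$hazard$injury_split["COMMUNITY", ] <- injury_split[cols]
    sc$hazard$injury_split["RESIDENTIAL_AGED_CARE", ] <- injury_split[cols]
  }
  sc$pathway$mortality <- list(model = "constant", per_cycle = p_mort)
  sc$pathway$p_discharge_to_residential_care[] <- p_disch_rac
  sc$pathway$relocation <- p_reloc
  sc$plan$max_cycles <- as.integer(max_cycles)
  sc
}

# Independent cohort-Markov oracle: collapse the engine's within-cycle draw
# tree into a 6x6 transition matrix by direct enumeration of the branch
# probabilities. Valid only for homogeneous_scenario()-style parameters.
markov_oracle_matrix <- function(sc, p_fall, p_mort) {
  set <- fall_settings()
  inj <- colnames(sc$hazard$injury_split)
  s <- sc$hazard$injury_split["COMMUNITY", inj]
  e <- sc$pathway$p_ed_given_injury[inj]
  a <- sc$pathway$p_admit_given_ed[inj]
  d <- sc$pathway$p_death_fall[inj]
  d["NONE"] <- 0 # fall-death drawn only for injurious falls
  p_df <- sum(s * d)
  p_hosp <- sum(s * e * a * (1 - d))
  p_stay <- (1 - p_fall) + p_fall * sum(s * (1 - d) * (1 - e * a))
  P <- matrix(0, 6, 6, dimnames = list(set, set))
  for (L in c("COMMUNITY", "RESIDENTIAL_AGED_CARE")) {
    other <- setdiff(c("COMMUNITY", "RESIDENTIAL_AGED_CARE"), L)
    p_move <- if (L == "COMMUNITY") {
      sc$pathway$relocation[["community_to_rac"]]
    } else {
      sc$pathway$relocation[["rac_to_community"]]
    }
    P[L, "DEATH_OTHER"] <- p_mort
    P[L, "DEATH_FALL"] <- (1 - p_mort) * p_fall * p_df
    P[L, "HOSPITAL"] <- (1 - p_mort) * p_fall * p_hosp
    stay <- (1 - p_mort) * p_stay
    P[L, other] <- stay * p_move
    P[L, L] <- stay * (1 - p_move)
  }
  qH <- 1 / sc$pathway$mean_los_cycles[["HOSPITAL"]]
  qR <- 1 / sc$pathway$mean_los_cycles[["REHAB_HOSPITAL"]]
  pr <- sc$pathway$p_rehab_given_discharge
  prac <- sc$pathway$p_discharge_to_residential_care[["COMMUNITY"]]
  P["HOSPITAL", ] <- c(
    COMMUNITY = (1 - p_mort) * qH * (1 - pr) * (1 - prac),
    RESIDENTIAL_AGED_CARE = (1 - p_mort) * qH * (1 - pr) * prac,
    HOSPITAL = (1 - p_mort) * (1 - qH),
    REHAB_HOSPITAL = (1 - p_mort) * qH * pr,
    DEATH_FALL = 0, DEATH_OTHER = p_mort)[set]
  P["REHAB_HOSPITAL", ] <- c(
    COMMUNITY = (1 - p_mort) * qR * (1 - prac),
    RESIDENTIAL_AGED_CARE = (1 - p_mort) * qR * prac,
    HOSPITAL = 0,
    REHAB_HOSPITAL = (1 - p_mort) * (1 - qR),
    DEATH_FALL = 0, DEATH_OTHER = p_mort)[set]
  P["DEATH_FALL", "DEATH_FALL"] <- 1
  P["DEATH_OTHER", "DEATH_OTHER"] <- 1
  P
}

make_cohort_population <- function(n, age = 75) {
  lapply(seq_len(n), function(i) new_individual(sprintf("i%05d", i), age))
}
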