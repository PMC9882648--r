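# Microsimulation engine: structural assumptions, determinism, degenerate
# limits and conservation.

test_that("zero hazards leave an individual in the community with no events", {
  sc <- quiet_scenario(max_cycles = 40L)
  tr <- simulate_individual(new_individual("a", 75), sc, seed = 7)
  expect_equal(nrow(tr$events), 0L)
  expect_identical(tr$individual$setting, "COMMUNITY")
  expect_equal(tr$n_cycles, 40L)
  expect_true(all(tr$occupancy == "COMMUNITY"))
})

test_that("the deterministic limit emits the full pathway cascade in order", {
  sc <- quiet_scenario(max_cycles = 1L)
  cols <- colnames(sc$hazard$injury_split)
  split <- setNames(numeric(7), cols)
  split["HIP_FRACTURE"] <- 1
  sc$hazard$fall_rate["COMMUNITY"] <- 1e9 # p = 1 - exp(-1e9) == 1
  sc$hazard$injury_split["COMMUNITY", ] <- split
  sc$pathway$p_ed_given_injury[] <- 1
  sc$pathway$p_admit_given_ed[] <- 1
  sc$pathway$p_surgery_given_hip_admission <- 1
  sc$pathway$p_death_fall[] <- 0
  tr <- simulate_individual(new_individual("b", 75), sc, seed = 3)
  expect_identical(
    tr$events$event_kind,
    c("FALL", "INJURY", "ED_VISIT", "HOSPITAL_ADMISSION", "HIP_SURGERY")
  )
  expect_identical(tr$events$detail[2], "HIP_FRACTURE")
  expect_identical(tr$individual$setting, "HOSPITAL")
})

test_that("certain fall death ends the trajectory at the first fall", {
  sc <- quiet_scenario(max_cycles = 20L)
  cols <- colnames(sc$hazard$injury_split)
  split <- setNames(numeric(7), cols)
  split["WRIST_FRACTURE"] <- 1
  sc$hazard$fall_rate["COMMUNITY"] <- 1e9
  sc$hazard$injury_split["COMMUNITY", ] <- split
  sc$pathway$p_death_fall[] <- 1
  tr <- simulate_individual(new_individual("c", 75), sc, seed = 5)
  expect_identical(tr$individual$setting, "DEATH_FALL")
  expect_equal(tr$n_cycles, 1L)
  expect_identical(tr$events$event_kind[nrow(tr$events)], "DEATH")
})

test_that("trajectories are reproducible and a zero-cycle horizon is empty", {
  sc <- generate_default_scenario(1)
  sc$plan$max_cycles <- 60L
  a <- simulate_individual(new_individual("d", 80), sc, seed = 11)
  b <- simulate_individual(new_individual("d", 80), sc, seed = 11)
  expect_identical(a, b)
  # starting at max age gives a zero-cycle trajectory
  sc2 <- generate_default_scenario(1)
  tr0 <- simulate_individual(new_individual("e", 110), sc2, seed = 1)
  expect_equal(tr0$n_cycles, 0L)
  expect_equal(nrow(tr0$events), 0L)
})

test_that("cohort simulation conserves occupancy and respects absorption", {
  sc <- generate_default_scenario(1)
  sc$plan$max_cycles <- 80L
  # raise mortality so deaths occur within the horizon
  sc$pathway$mortality <- list(model = "constant", per_cycle = 0.01)
  pop <- make_cohort_population(300, age = 85)
  co <- simulate_cohort(pop, sc, master_seed = 42)
  expect_true(all(rowSums(co$occupancy) == 300))
  # absorption: no event after a DEATH event for any individual
  ev <- co$events
  for (id in unique(ev$individual_id[ev$event_kind == "DEATH"])) {
    pe <- ev[ev$individual_id == id, ]
    expect_equal(which(pe$event_kind == "DEATH"), nrow(pe))
  }
  # death-state occupancy is monotone non-decreasing
  dead <- co$occupancy[, "DEATH_FALL"] + co$occupancy[, "DEATH_OTHER"]
  expect_true(all(diff(dead) >= 0))
  # cohort of one equals simulate_individual under the same master seed
  co1 <- simulate_cohort(pop[1], sc, master_seed = 9)
  tr1 <- simulate_individual(pop[[1]], sc, seed = 9)
  expect_identical(co1$trajectories[[1]]$events, tr1$events)
  expect_identical(co1$trajectories[[1]]$occupancy, tr1$occupancy)
})

test_that("no cycle has two falls and no fall has two injuries", {
  sc <- generate_default_scenario(1)
  sc$plan$max_cycles <- 80L
  sc$hazard$fall_rate[] <- sc$hazard$fall_rate * 10 # stress the assumption
  co <- simulate_cohort(make_cohort_population(300), sc, master_seed = 17)
  ev <- co$events
  falls <- ev[ev$event_kind == "FALL", ]
  expect_equal(anyDuplicated(falls[, c("individual_id", "cycle")]), 0L)
  inj <- ev[ev$event_kind == "INJURY", ]
  expect_equal(anyDuplicated(inj[, c("individual_id", "cycle")]), 0L)
  expect_equal(as.numeric(multiple_injury_share(co)), 0)
})

test_that("multiple_injury_share flags hand-built violations and empty logs", {
  bad <- data.frame(
    individual_id = c("x", "x", "x", "y", "y"),
    cycle = c(3L, 3L, 3L, 1L, 1L),
    event_kind = c("FALL", "INJURY", "INJURY", "FALL", "INJURY"),
    detail = c(NA, "HIP_FRACTURE", "WRIST_FRACTURE", NA, "MINOR"),
    stringsAsFactors = FALSE
  )
  expect_warning(share <- multiple_injury_share(bad),
                 "one-injury-per-fall")
  expect_equal(as.numeric(share), 0.5)
  expect_equal(nrow(attr(share, "violations")), 1L)
  empty <- bad[0, ]
  expect_error(multiple_injury_share(empty), "no falls")
})

test_that("fall counts follow Binomial(K, p) under constant hazard", {
  p <- 0.06
  K <- 30L
  n <- 4000L
  sc <- homogeneous_scenario(p_fall = p, p_mort = 0,
                             injury_split = c(
                               HEAD_INJURY = 0, HIP_FRACTURE = 0,
                               VERTEBRAL_FRACTURE = 0, WRIST_FRACTURE = 0,
                               MODERATE = 0, MINOR = 0, NONE = 1),
                             p_reloc = c(community_to_rac = 0,
                                         rac_to_community = 0),
                             max_cycles = K)
  sc$pathway$p_ed_given_injury[] <- 0
  co <- simulate_cohort(make_cohort_population(n), sc, master_seed = 31)
  per_ind <- co$final$n_falls
  se <- sqrt(K * p * (1 - p) / n)
  expect_lt(abs(mean(per_ind) - K * p), 3 * se)
  # no one leaves the community when nothing else can happen
  expect_true(all(co$occupancy[, "COMMUNITY"] == n))
})

test_that("invalid parameters are rejected before any stepping", {
  sc <- generate_default_scenario(1)
  sc$pathway$p_admit_given_ed["MINOR"] <- 1.4
  expect_error(simulate_individual(new_individual("a", 75), sc, seed = 1),
               "p_admit_given_ed")
  sc2 <- generate_default_scenario(1)
  sc2$hazard$injury_split["COMMUNITY", "NONE"] <- 0.9 # breaks the sum
  expect_error(validate_parameters(sc2), "injury_split")
  sc3 <- generate_default_scenario(1)
  sc3$pathway$mean_los_cycles["HOSPITAL"] <- 0.5
  expect_error(validate_parameters(sc3), "mean_los_cycles")
})

test_that("per-purpose substreams keep purposes independent", {
  # adding draws to the pathway purpose must not change fall draws: compare
  # fall event cycles between a scenario with no pathway consumption and one
  # with certain ED visits (same seed, same fall hazard)
  base <- homogeneous_scenario(p_fall = 0.1, p_mort = 0, max_cycles = 30L,
                               p_reloc = c(community_to_rac = 0,
                                           rac_to_community = 0))
  base$pathway$p_ed_given_injury[] <- 0
  base$pathway$p_death_fall[] <- 0
  alt <- base
  alt$pathway$p_ed_given_injury[] <- 1
  alt$pathway$p_admit_given_ed[] <- 0
  alt$pathway$p_death_fall[] <- 0
  a <- simulate_individual(new_individual("s", 75), base, seed = 21)
  b <- simulate_individual(new_individual("s", 75), alt, seed = 21)
  expect_identical(a$events$cycle[a$events$event_kind == "FALL"],
                   b$events$cycle[b$events$event_kind == "FALL"])
})
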