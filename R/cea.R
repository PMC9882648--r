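## Cost-effectiveness layer: discounted cost/QALY accumulation over
## trajectories, dominance frontier, ICERs and net monetary benefit.

#' Per-cycle discount factor
#'
#' Start-of-cycle discounting with annual-rate conversion:
#' `d(t) = (1 + r)^(-t * cycle_length_days / 365)` for 0-indexed cycle `t`.
#' No half-cycle correction is applied: event timing is already
#' cycle-resolved in the microsimulation.
#'
#' @param t Cycle index (0-based), vectorized.
#' @param plan A [cycle_plan()].
#' @return Discount factors.
#' @export
discount_factor <- function(t, plan) {
  (1 + plan$discount_rate_annual)^(-(t * plan$cycle_length_days / 365))
}

#' Accumulate discounted costs and QALYs from one trajectory
#'
#' For each cycle `t` the individual contributes
#' `(state cost + event costs) * d(t)` to cost and
#' `(state utility * cycle length in years - injury disutility) * d(t)` to
#' QALYs, attributed to the setting occupied during cycle `t`. Injury event
#' costs combine the event-kind cost with the injury-type cost; injury
#' disutilities are one-time QALY decrements at the event cycle.
#'
#' @param trajectory Result of [simulate_individual()] (or one element of a
#'   cohort's `trajectories`).
#' @param econ Economic parameter block (state/event costs, utilities,
#'   disutilities), e.g. `scenario$econ`.
#' @param plan A [cycle_plan()] carrying the discount rate.
#' @param intervention Optional one-row intervention data frame
#'   (`fall_rate_ratio`, `cost_per_cycle`, `one_time_cost`); its one-time
#'   cost enters at cycle 0 and its per-cycle cost accrues, discounted, over
#'   the cycles lived.
#' @return List with `discounted_cost`, `discounted_qalys`, and undiscounted
#'   `raw_cost`, `raw_qalys`.
#' @export
accumulate_outcomes <- function(trajectory, econ, plan,
                                intervention = NULL) {
  occ <- trajectory$occupancy
  k <- length(occ)
  events <- trajectory$events
  missing_states <- setdiff(unique(occ),
                            names(econ$state_cost_per_cycle))
  missing_states <- union(missing_states,
                          setdiff(unique(occ), names(econ$state_utility)))
  if (length(missing_states)) {
    stop("no cost/utility defined for state(s): ",
         paste(missing_states, collapse = ", "))
  }
  dt_years <- plan$cycle_length_days / 365
  d <- discount_factor(seq_len(k) - 1L, plan)
  state_cost <- econ$state_cost_per_cycle[occ]
  state_util <- econ$state_utility[occ]
  ev_cost <- numeric(k)
  ev_disutil <- numeric(k)
  if (k > 0L && nrow(events)) {
    for (i in seq_len(nrow(events))) {
      tt <- events$cycle[i] + 1L
      kind <- events$event_kind[i]
      ck <- econ$event_cost[[kind]]
      if (is.null(ck)) stop("no cost defined for event kind: ", kind)
      ev_cost[tt] <- ev_cost[tt] + ck
      if (kind == "INJURY") {
        det <- events$detail[i]
        ev_cost[tt] <- ev_cost[tt] + econ$injury_cost[[det]]
        ev_disutil[tt] <- ev_disutil[tt] + econ$injury_disutility[[det]]
      }
    }
  }
  iv_cost <- numeric(k)
  if (!is.null(intervention) && k > 0L) {
    iv_cost <- rep(intervention$cost_per_cycle, k)
    iv_cost[1L] <- iv_cost[1L] + intervention$one_time_cost
  }
  cost_t <- state_cost + ev_cost + iv_cost
  qaly_t <- state_util * dt_years - ev_disutil
  list(
    discounted_cost = sum(cost_t * d),
    discounted_qalys = sum(qaly_t * d),
    raw_cost = sum(cost_t),
    raw_qalys = sum(qaly_t)
  )
}

cohort_outcomes <- function(cohort, econ, plan, intervention = NULL) {
  vals <- lapply(cohort$trajectories, accumulate_outcomes,
                 econ = econ, plan = plan, intervention = intervention)
  data.frame(
    individual_id = cohort$final$individual_id,
    cost = vapply(vals, `[[`, numeric(1L), "discounted_cost"),
    qaly = vapply(vals, `[[`, numeric(1L), "discounted_qalys"),
    stringsAsFactors = FALSE
  )
}

#' Incremental cost-effectiveness analysis across arms
#'
#' Sorts arms by mean cost, removes strictly dominated arms (a cheaper arm
#' is at least as effective), then removes arms subject to extended
#' dominance (their incremental ICER strictly exceeds that of the next, more
#' effective frontier arm), and computes ICERs between adjacent frontier
#' arms and net monetary benefit at willingness-to-pay `lambda`. Arms with
#' identical mean cost and effect are flagged as ties (deterministic
#' ordering by arm id; the duplicate is excluded from the frontier with an
#' undefined ICER).
#'
#' @param outcomes Either a per-arm summary data frame with columns `arm`,
#'   `cost`, `qaly` (optionally `cost_se`, `qaly_se`), or an individual-level
#'   data frame with columns `arm`, `cost`, `qaly` which is aggregated with
#'   Monte-Carlo standard errors.
#' @param lambda Willingness to pay per QALY.
#' @return Object of class `cea_result`: list with `arms` (summary table
#'   with `status`, `icer`, `nmb`), `frontier` (arm ids, cheapest first),
#'   `lambda`.
#' @export
incremental_analysis <- function(outcomes, lambda = 50000) {
  stopifnot(is.data.frame(outcomes),
            all(c("arm", "cost", "qaly") %in% names(outcomes)))
  if (anyDuplicated(outcomes$arm)) { # individual-level: aggregate
    agg <- function(v) tapply(v, outcomes$arm, mean)
    sem <- function(v) {
      tapply(v, outcomes$arm, function(x) stats::sd(x) / sqrt(length(x)))
    }
    arms <- data.frame(
      arm = names(agg(outcomes$cost)),
      cost = as.numeric(agg(outcomes$cost)),
      qaly = as.numeric(agg(outcomes$qaly)),
      cost_se = as.numeric(sem(outcomes$cost)),
      qaly_se = as.numeric(sem(outcomes$qaly)),
      stringsAsFactors = FALSE
    )
  } else {
    arms <- outcomes
    if (is.null(arms$cost_se)) arms$cost_se <- NA_real_
    if (is.null(arms$qaly_se)) arms$qaly_se <- NA_real_
  }
  if (nrow(arms) < 2L) stop("incremental analysis needs at least 2 arms")
  arms <- arms[order(arms$cost, arms$qaly, arms$arm), , drop = FALSE]
  rownames(arms) <- NULL
  arms$status <- "frontier"
  arms$dominated_by <- NA_character_

  # ties: identical mean cost and effect; keep the first id, flag the rest
  for (i in seq_len(nrow(arms))[-1L]) {
    same <- which(arms$cost[seq_len(i - 1L)] == arms$cost[i] &
                    arms$qaly[seq_len(i - 1L)] == arms$qaly[i] &
                    arms$status[seq_len(i - 1L)] != "tie")
    if (length(same)) {
      arms$status[i] <- "tie"
      arms$dominated_by[i] <- arms$arm[same[1L]]
    }
  }
  # strict dominance: some cheaper-or-equal, non-tied arm is >= effective
  repeat {
    changed <- FALSE
    live <- which(arms$status == "frontier")
    for (i in live) {
      others <- setdiff(live, i)
      dom <- others[(arms$cost[others] <= arms$cost[i] &
                       arms$qaly[others] > arms$qaly[i]) |
                      (arms$cost[others] < arms$cost[i] &
                         arms$qaly[others] >= arms$qaly[i])]
      if (length(dom)) {
        arms$status[i] <- "dominated"
        arms$dominated_by[i] <- arms$arm[dom[1L]]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # extended dominance: drop middle arms with non-monotone ICERs
  repeat {
    live <- which(arms$status == "frontier")
    if (length(live) < 3L) break
    icer <- diff(arms$cost[live]) / diff(arms$qaly[live])
    bad <- which(utils::head(icer, -1L) > utils::tail(icer, -1L))
    if (!length(bad)) break
    i <- live[bad[1L] + 1L]
    arms$status[i] <- "extended_dominated"
    arms$dominated_by[i] <- arms$arm[live[bad[1L] + 2L]]
  }
  live <- which(arms$status == "frontier")
  arms$icer <- NA_real_
  if (length(live) > 1L) {
    inc_cost <- diff(arms$cost[live])
    inc_qaly <- diff(arms$qaly[live])
    arms$icer[live[-1L]] <- ifelse(inc_qaly == 0, NA_real_,
                                   inc_cost / inc_qaly)
  }
  arms$nmb <- lambda * arms$qaly - arms$cost
  structure(
    list(arms = arms, frontier = arms$arm[live], lambda = lambda),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result> lambda =", format(x$lambda), "per QALY\n")
  df <- x$arms
  df$cost <- round(df$cost, 2)
  df$qaly <- round(df$qaly, 4)
  df$icer <- round(df$icer, 1)
  df$nmb <- round(df$nmb, 1)
  print(df[, c("arm", "cost", "qaly", "status", "icer", "nmb")],
        row.names = FALSE)
  invisible(x)
}

#' Run a full cost-effectiveness analysis over all intervention arms
#'
#' Generates the population once, then simulates every arm with the same
#' master seed so that arms share common random numbers (the default
#' variance-reduction policy: each individual's random streams are identical
#' across arms, and arms differ only through the intervention's effect on
#' the fall hazard and its costs). Returns per-arm discounted outcomes and
#' the incremental analysis.
#'
#' @param scenario A `fall_scenario`.
#' @param n Cohort size per arm.
#' @param seed Master seed (population and simulation streams).
#' @param lambda Willingness to pay per QALY.
#' @param common_random_numbers If `FALSE`, each arm uses an independent
#'   master seed derived from `seed` and the arm index.
#' @return Object of class `cea_run`: list with `result` (a `cea_result`),
#'   `by_arm` (individual-level outcomes), `meta` (seed, arm count,
#'   scenario provenance and parameter digest).
#' @export
run_cea <- function(scenario, n = 500L, seed = 1L, lambda = 50000,
                    common_random_numbers = TRUE) {
  validate_parameters(scenario)
  pop <- generate_population(scenario$population, seed = seed, n = n)
  inds <- population_to_individuals(pop)
  arms <- scenario$interventions
  out <- vector("list", nrow(arms))
  for (a in seq_len(nrow(arms))) {
    params_a <- scenario
    params_a$hazard$fall_rate <-
      scenario$hazard$fall_rate * arms$fall_rate_ratio[a]
    arm_seed <- if (common_random_numbers) seed else seed + a * 1000L
    cohort <- simulate_cohort(inds, params_a, master_seed = arm_seed)
    oc <- cohort_outcomes(cohort, scenario$econ, scenario$plan,
                          intervention = arms[a, , drop = FALSE])
    oc$arm <- arms$id[a]
    out[[a]] <- oc
  }
  by_arm <- do.call(rbind, out)
  res <- incremental_analysis(by_arm[, c("arm", "cost", "qaly")], lambda)
  structure(
    list(result = res, by_arm = by_arm,
         meta = list(seed = seed, n = n, lambda = lambda,
                     arms = nrow(arms),
                     provenance = scenario$meta$provenance,
                     scenario_digest = scenario_digest(scenario))),
    class = "cea_run"
  )
}

# md5 digest of the canonical YAML serialization, for run logging
scenario_digest <- function(scenario) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_scenario(scenario, tf)
  unname(tools::md5sum(tf))
}

#' @export
print.cea_run <- function(x, ...) {
  cat(sprintf("<cea_run> n = %d per arm, seed = %s, digest = %s\n",
              x$meta$n, format(x$meta$seed),
              substr(x$meta$scenario_digest, 1, 8)))
  print(x$result)
  invisible(x)
}
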