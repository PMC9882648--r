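## Individual-level state-transition (microsimulation) engine.
##
## Time advances in discrete cycles (default 14 days). Within a cycle the
## draw order is fixed for reproducibility: (1) background (non-fall) death;
## (2) a single fall draw for individuals in a living, fall-eligible setting;
## (3) a single injury draw conditional on the fall; (4) the care pathway
## cascade (ED visit -> hospital admission -> hip surgery) gated by the
## topology rules; (5) death due to the fall, conditional on injury;
## (6) length-of-stay bookkeeping for hospital / rehabilitation stays and
## residential relocation. The structure enforces at most one fall per cycle
## and at most one injury per fall.

`%||%` <- function(a, b) if (is.null(a)) b else a

PURPOSES <- c(mortality = 1L, fall = 2L, injury = 3L, pathway = 4L)
N_PATHWAY_DRAWS <- 8L # ed, admit, surgery, fall-death, los, rehab, dest, reloc

## ---- random streams ------------------------------------------------------

# One L'Ecuyer-CMRG stream per individual, one substream per draw purpose.
# Adding draws to one purpose therefore never perturbs another purpose, and
# per-individual results are independent of the order individuals are
# simulated in.
make_streams <- function(master_seed, n) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  suppressWarnings(set.seed(as.integer(master_seed), kind = "L'Ecuyer-CMRG"))
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    streams[[i]] <- s
  }
  streams
}

# Uniform draws from the purpose-specific substream of one individual stream.
substream_uniforms <- function(stream, purpose, n) {
  s <- stream
  for (j in seq_len(PURPOSES[[purpose]])) s <- parallel::nextRNGSubStream(s)
  old_seed <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", s, envir = globalenv())
  u <- stats::runif(n)
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
  u
}

## ---- plans and parameter validation --------------------------------------

#' Cycle plan
#'
#' Timing settings of the simulation: cycle length (default 14 days, i.e. the
#' one-fall-per-two-weeks resolution), the lifetime horizon cap
#' (`max_age_years`), an optional hard cap on the number of cycles (used for
#' fixed-horizon experiments), and the annual discount rate applied by the
#' economic layer.
#'
#' @param cycle_length_days Days per cycle (> 0).
#' @param max_age_years Simulation stops when an individual reaches this age.
#' @param discount_rate_annual Annual discount rate, >= 0.
#' @param max_cycles Optional fixed horizon in cycles (`NULL` = lifetime).
#' @return A list of class `cycle_plan`.
#' @export
cycle_plan <- function(cycle_length_days = 14, max_age_years = 110,
                       discount_rate_annual = 0, max_cycles = NULL) {
  stopifnot(cycle_length_days > 0, max_age_years > 0,
            discount_rate_annual >= 0,
            is.null(max_cycles) || max_cycles >= 0)
  structure(
    list(cycle_length_days = cycle_length_days,
         max_age_years = max_age_years,
         discount_rate_annual = discount_rate_annual,
         max_cycles = max_cycles),
    class = "cycle_plan"
  )
}

prob_in_01 <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)

#' Validate a scenario parameter set against the engine's requirements
#'
#' Checks that every per-cycle probability lies in [0, 1], injury splits sum
#' to one, lengths of stay are at least one cycle, utilities lie in [0, 1]
#' and costs are non-negative. Called by the simulation entry points before
#' any stepping; violations raise an error listing every failed check.
#'
#' @param params A scenario parameter list (see [generate_default_scenario()]).
#' @return `params`, invisibly, if valid.
#' @export
validate_parameters <- function(params) {
  bad <- character()
  hz <- params$hazard
  pw <- params$pathway
  ec <- params$econ
  inj <- injury_types()$injury
  if (!all(c("COMMUNITY", "RESIDENTIAL_AGED_CARE") %in% names(hz$fall_rate)) ||
      any(hz$fall_rate < 0)) {
    bad <- c(bad, "hazard$fall_rate: need non-negative per-cycle rates for COMMUNITY and RESIDENTIAL_AGED_CARE")
  }
  if (!is.matrix(hz$injury_split) ||
      !all(inj %in% colnames(hz$injury_split)) ||
      !prob_in_01(hz$injury_split) ||
      any(abs(rowSums(hz$injury_split) - 1) > 1e-8)) {
    bad <- c(bad, "hazard$injury_split: rows must be probability vectors over the injury taxonomy summing to 1")
  }
  hist_m <- hz$history
  if (any(c(hist_m$prior_fall_multiplier, hist_m$prior_injury_multiplier,
            hist_m$recent_fall_multiplier) <= 0) ||
      hist_m$recent_fall_window < 0) {
    bad <- c(bad, "hazard$history: multipliers must be positive, window non-negative")
  }
  for (nm in c("p_ed_given_injury", "p_admit_given_ed", "p_death_fall")) {
    v <- pw[[nm]]
    if (!all(inj %in% names(v)) || !prob_in_01(v)) {
      bad <- c(bad, sprintf("pathway$%s: probabilities by injury type in [0,1]", nm))
    }
  }
  for (nm in c("p_surgery_given_hip_admission", "p_rehab_given_discharge")) {
    if (!prob_in_01(pw[[nm]])) bad <- c(bad, sprintf("pathway$%s in [0,1]", nm))
  }
  if (!all(c("COMMUNITY", "RESIDENTIAL_AGED_CARE") %in%
           names(pw$p_discharge_to_residential_care)) ||
      !prob_in_01(pw$p_discharge_to_residential_care)) {
    bad <- c(bad, "pathway$p_discharge_to_residential_care: by pre-admission setting, in [0,1]")
  }
  if (!all(c("HOSPITAL", "REHAB_HOSPITAL") %in% names(pw$mean_los_cycles)) ||
      any(pw$mean_los_cycles < 1)) {
    bad <- c(bad, "pathway$mean_los_cycles: >= 1 cycle for HOSPITAL and REHAB_HOSPITAL")
  }
  if (!prob_in_01(pw$relocation)) {
    bad <- c(bad, "pathway$relocation in [0,1]")
  }
  mt <- pw$mortality
  if (is.null(mt$model) ||
      !(mt$model %in% c("constant", "gompertz"))) {
    bad <- c(bad, "pathway$mortality$model must be 'constant' or 'gompertz'")
  } else if (mt$model == "constant" && !prob_in_01(mt$per_cycle)) {
    bad <- c(bad, "pathway$mortality$per_cycle in [0,1]")
  } else if (mt$model == "gompertz" &&
             (mt$rate_per_year_at_ref < 0 || mt$log_slope_per_year < 0)) {
    bad <- c(bad, "pathway$mortality: gompertz parameters must be non-negative")
  }
  if (!is.null(ec)) {
    if (!prob_in_01(ec$state_utility)) {
      bad <- c(bad, "econ$state_utility in [0,1]")
    }
    if (any(c(ec$state_cost_per_cycle, ec$event_cost, ec$injury_cost) < 0) ||
        any(ec$injury_disutility < 0)) {
      bad <- c(bad, "econ costs and disutilities must be non-negative")
    }
  }
  if (!is.null(params$interventions)) {
    iv <- params$interventions
    if (any(iv$fall_rate_ratio <= 0) ||
        any(iv$cost_per_cycle < 0) || any(iv$one_time_cost < 0)) {
      bad <- c(bad, "interventions: fall_rate_ratio > 0, costs >= 0")
    }
  }
  if (length(bad)) {
    stop("invalid parameters:\n  ", paste(bad, collapse = "\n  "))
  }
  invisible(params)
}

## ---- hazard pieces -------------------------------------------------------

cycle_years <- function(plan) plan$cycle_length_days / 365

# Per-cycle probability of background (non-fall) death at a given age.
# The Gompertz form gives an exponentially age-increasing hazard, the
# standard shape for adult background mortality.
mortality_prob <- function(age, mortality, dt_years) {
  if (mortality$model == "constant") {
    return(mortality$per_cycle)
  }
  h <- mortality$rate_per_year_at_ref *
    exp(mortality$log_slope_per_year * (age - mortality$ref_age))
  1 - exp(-h * dt_years)
}

# Multiplicative modifier on the fall rate from attributes and history.
# Attribute effects are log-linear; age enters per year relative to 75.
# History effects: any prior fall, any prior injurious fall, and a fall
# within the recency window (the "post-fall" construct) each contribute a
# multiplier.
fall_multiplier <- function(ind, hazard, t) {
  log_m <- 0
  lrr <- hazard$attribute_log_rr
  if (length(lrr)) {
    for (a in names(lrr)) {
      val <- if (a == "older-age") ind$age - 75 else ind$attributes[[a]] %||% 0
      log_m <- log_m + lrr[[a]] * val
    }
  }
  m <- exp(log_m)
  h <- hazard$history
  if (ind$n_prior_falls > 0L) m <- m * h$prior_fall_multiplier
  if (ind$n_prior_injuries > 0L) m <- m * h$prior_injury_multiplier
  if (!is.na(ind$last_fall_cycle) &&
      (t - ind$last_fall_cycle) <= h$recent_fall_window) {
    m <- m * h$recent_fall_multiplier
  }
  m
}

## ---- individuals ---------------------------------------------------------

#' Construct an individual's initial state
#'
#' @param id Identifier.
#' @param age Age in years (>= 65 for the target population).
#' @param attributes Named list/vector of attribute values keyed by
#'   [attribute_registry()] ids.
#' @param setting Starting setting (default `"COMMUNITY"`; everyone enters
#'   the model community-dwelling).
#' @return A list of class `fall_individual`.
#' @export
new_individual <- function(id, age, attributes = list(),
                           setting = "COMMUNITY") {
  stopifnot(setting %in% fall_settings())
  structure(
    list(id = id, age = age, attributes = as.list(attributes),
         setting = setting, alive = TRUE,
         cycle = 0L, entry_cycle = 0L, origin_setting = setting,
         n_prior_falls = 0L, n_prior_injuries = 0L,
         last_fall_cycle = NA_integer_),
    class = "fall_individual"
  )
}

## ---- single cycle --------------------------------------------------------

#' Advance one individual by one cycle
#'
#' Executes the fixed within-cycle draw order on a set of uniform draws and
#' returns the updated individual together with the events emitted this
#' cycle. Exposed mainly for testing and for building bespoke simulation
#' loops; [simulate_individual()] and [simulate_cohort()] drive it with
#' per-purpose random substreams.
#'
#' @param ind A `fall_individual` (must be alive).
#' @param params Validated scenario parameters.
#' @param draws List with elements `mortality`, `fall`, `injury` (scalars in
#'   [0,1]) and `pathway` (numeric vector of 8 uniforms: ED, admission,
#'   surgery, fall-death, discharge, rehab-entry, destination, relocation).
#' @param plan A [cycle_plan()].
#' @return List with `individual` (updated) and `events` (list of emitted
#'   event records: cycle, event_kind, detail, setting_after).
#' @export
step_cycle <- function(ind, params, draws, plan = params$plan) {
  if (!ind$alive) stop("step_cycle: individual is not alive")
  t <- ind$cycle
  hz <- params$hazard
  pw <- params$pathway
  dt <- cycle_years(plan)
  events <- list()
  emit <- function(kind, detail = NA_character_) {
    events[[length(events) + 1L]] <<- list(
      cycle = t, event_kind = kind, detail = detail,
      setting_after = ind$setting)
  }

  # (1) background (non-fall) death
  if (draws$mortality < mortality_prob(ind$age, pw$mortality, dt)) {
    ind$setting <- "DEATH_OTHER"
    ind$alive <- FALSE
    emit("DEATH", "other")
  } else {
    fall_ok <- ind$setting %in% c("COMMUNITY", "RESIDENTIAL_AGED_CARE") ||
      (isTRUE(hz$falls_in_hospital) &&
         ind$setting %in% c("HOSPITAL", "REHAB_HOSPITAL"))
    fell <- FALSE
    injury <- "NONE"
    admitted_now <- FALSE
    if (fall_ok) {
      lambda <- hz$fall_rate[[ind$setting]] %||% 0
      p_fall <- 1 - exp(-lambda * fall_multiplier(ind, hz, t))
      if (draws$fall < p_fall) {
        fell <- TRUE
        emit("FALL")
        # (3) single injury draw, inverse-CDF on the setting's injury split
        split <- hz$injury_split[ind$setting, ]
        injury <- names(split)[findInterval(draws$injury, cumsum(split),
                                            left.open = TRUE) + 1L]
        if (injury != "NONE") emit("INJURY", injury)
        # (4) pathway cascade: ED gate, then admission, then hip surgery
        if (draws$pathway[1L] < pw$p_ed_given_injury[[injury]]) {
          emit("ED_VISIT", injury)
          if (draws$pathway[2L] < pw$p_admit_given_ed[[injury]]) {
            admitted_now <- TRUE
            ind$origin_setting <- ind$setting
            ind$setting <- "HOSPITAL"
            ind$entry_cycle <- t
            emit("HOSPITAL_ADMISSION", injury)
            if (injury == "HIP_FRACTURE" &&
                draws$pathway[3L] < pw$p_surgery_given_hip_admission) {
              emit("HIP_SURGERY")
            }
          }
        }
        # (5) death due to the fall, conditional on injury
        if (injury != "NONE" &&
            draws$pathway[4L] < pw$p_death_fall[[injury]]) {
          ind$setting <- "DEATH_FALL"
          ind$alive <- FALSE
          emit("DEATH", "fall")
        }
        ind$n_prior_falls <- ind$n_prior_falls + 1L
        if (injury != "NONE") ind$n_prior_injuries <- ind$n_prior_injuries + 1L
        ind$last_fall_cycle <- t
      }
    }
    # (6) length-of-stay bookkeeping and relocation
    if (ind$alive) {
      if (ind$setting == "HOSPITAL" && ind$entry_cycle < t) {
        q <- if (identical(pw$los_model, "fixed")) {
          as.numeric(t - ind$entry_cycle >= pw$mean_los_cycles[["HOSPITAL"]])
        } else 1 / pw$mean_los_cycles[["HOSPITAL"]]
        if (draws$pathway[5L] < q) {
          if (draws$pathway[6L] < pw$p_rehab_given_discharge) {
            ind$setting <- "REHAB_HOSPITAL"
            ind$entry_cycle <- t
            emit("REHAB_ADMISSION")
          } else {
            p_rac <- pw$p_discharge_to_residential_care[[ind$origin_setting]]
            dest <- if (draws$pathway[7L] < p_rac) {
              "RESIDENTIAL_AGED_CARE"
            } else "COMMUNITY"
            ind$setting <- dest
            ind$entry_cycle <- t
            emit("RELOCATION", dest)
          }
        }
      } else if (ind$setting == "REHAB_HOSPITAL" && ind$entry_cycle < t) {
        q <- if (identical(pw$los_model, "fixed")) {
          as.numeric(t - ind$entry_cycle >=
                       pw$mean_los_cycles[["REHAB_HOSPITAL"]])
        } else 1 / pw$mean_los_cycles[["REHAB_HOSPITAL"]]
        if (draws$pathway[5L] < q) {
          p_rac <- pw$p_discharge_to_residential_care[[ind$origin_setting]]
          dest <- if (draws$pathway[7L] < p_rac) {
            "RESIDENTIAL_AGED_CARE"
          } else "COMMUNITY"
          ind$setting <- dest
          ind$entry_cycle <- t
          emit("RELOCATION", dest)
        }
      } else if (!admitted_now &&
                 ind$setting %in% c("COMMUNITY", "RESIDENTIAL_AGED_CARE")) {
        p_move <- if (ind$setting == "COMMUNITY") {
          pw$relocation[["community_to_rac"]]
        } else {
          pw$relocation[["rac_to_community"]]
        }
        if (draws$pathway[8L] < p_move) {
          dest <- setdiff(c("COMMUNITY", "RESIDENTIAL_AGED_CARE"),
                          ind$setting)
          ind$setting <- dest
          ind$entry_cycle <- t
          emit("RELOCATION", dest)
        }
      }
    }
  }
  ind$age <- ind$age + dt
  ind$cycle <- t + 1L
  list(individual = ind, events = events)
}

## ---- trajectories --------------------------------------------------------

sim_with_stream <- function(ind, params, plan, stream) {
  dt <- cycle_years(plan)
  k_age <- max(0L, ceiling((plan$max_age_years - ind$age) / dt))
  k_max <- if (is.null(plan$max_cycles)) k_age else min(k_age, plan$max_cycles)
  if (k_max == 0L) {
    return(list(
      individual = ind,
      events = data.frame(cycle = integer(), event_kind = character(),
                          detail = character(), setting_after = character(),
                          stringsAsFactors = FALSE),
      occupancy = character(), n_cycles = 0L
    ))
  }
  u_m <- substream_uniforms(stream, "mortality", k_max)
  u_f <- substream_uniforms(stream, "fall", k_max)
  u_i <- substream_uniforms(stream, "injury", k_max)
  u_p <- matrix(substream_uniforms(stream, "pathway", k_max * N_PATHWAY_DRAWS),
                nrow = k_max, byrow = TRUE)
  occupancy <- character(k_max)
  all_events <- vector("list", k_max)
  t_done <- 0L
  for (t in seq_len(k_max)) {
    res <- step_cycle(ind, params,
                      draws = list(mortality = u_m[t], fall = u_f[t],
                                   injury = u_i[t], pathway = u_p[t, ]),
                      plan = plan)
    ind <- res$individual
    if (length(res$events)) all_events[[t]] <- res$events
    occupancy[t] <- ind$setting
    t_done <- t
    if (!ind$alive) break
  }
  ev <- unlist(all_events, recursive = FALSE)
  events <- if (length(ev)) {
    data.frame(
      cycle = vapply(ev, `[[`, integer(1L), "cycle"),
      event_kind = vapply(ev, `[[`, character(1L), "event_kind"),
      detail = vapply(ev, function(e) as.character(e$detail), character(1L)),
      setting_after = vapply(ev, `[[`, character(1L), "setting_after"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(cycle = integer(), event_kind = character(),
               detail = character(), setting_after = character(),
               stringsAsFactors = FALSE)
  }
  list(individual = ind, events = events,
       occupancy = occupancy[seq_len(t_done)], n_cycles = t_done)
}

#' Simulate a single individual's lifetime trajectory
#'
#' Runs the cycle loop until death, the maximum age, or the plan's fixed
#' horizon. Draws come from named per-purpose substreams of a single
#' L'Ecuyer-CMRG stream derived from `seed`, so the trajectory is exactly
#' reproducible and identical to a one-person [simulate_cohort()] run with
#' the same master seed.
#'
#' @param ind A [new_individual()].
#' @param params Scenario parameters (validated before stepping).
#' @param plan A [cycle_plan()]; defaults to `params$plan`.
#' @param seed Integer seed.
#' @return List with `individual` (final state), `events` (data frame),
#'   `occupancy` (character vector, setting occupied at the end of each
#'   cycle), `n_cycles`.
#' @export
simulate_individual <- function(ind, params, seed, plan = params$plan) {
  validate_parameters(params)
  stream <- make_streams(seed, 1L)[[1L]]
  sim_with_stream(ind, params, plan, stream)
}

#' Simulate a cohort
#'
#' Simulates each individual on an independent random stream derived from the
#' master seed (results do not depend on iteration order) and aggregates a
#' cycle-by-setting occupancy matrix in which dead individuals continue to be
#' counted in their death state, so every row sums to the cohort size.
#'
#' @param population List of [new_individual()] objects, or a data frame from
#'   [generate_population()].
#' @param params Scenario parameters.
#' @param master_seed Integer master seed.
#' @param plan A [cycle_plan()]; defaults to `params$plan`.
#' @return Object of class `fall_cohort`: list with `events` (one data frame
#'   with `individual_id`), `occupancy` (cycles x 6 count matrix),
#'   `trajectories` (per-individual `occupancy`/`n_cycles`), `final`
#'   (data frame of final states), `n`, `seed`.
#' @export
simulate_cohort <- function(population, params, master_seed,
                            plan = params$plan) {
  validate_parameters(params)
  if (is.data.frame(population)) population <- population_to_individuals(population)
  n <- length(population)
  stopifnot(n >= 1L)
  streams <- make_streams(master_seed, n)
  sims <- vector("list", n)
  for (i in seq_len(n)) {
    sims[[i]] <- sim_with_stream(population[[i]], params, plan, streams[[i]])
  }
  k_global <- max(vapply(sims, `[[`, integer(1L), "n_cycles"), 0L)
  settings <- fall_settings()
  occupancy <- matrix(0L, nrow = k_global, ncol = length(settings),
                      dimnames = list(NULL, settings))
  for (s in sims) {
    k_i <- s$n_cycles
    if (k_i > 0L) {
      idx <- match(s$occupancy, settings)
      for (t in seq_len(k_i)) {
        occupancy[t, idx[t]] <- occupancy[t, idx[t]] + 1L
      }
    }
    # carry the final state (death state, or censoring state at max age)
    # through the remaining cycles so each row sums to n
    if (k_i < k_global) {
      last <- if (k_i > 0L) s$occupancy[k_i] else s$individual$setting
      j <- match(last, settings)
      occupancy[(k_i + 1L):k_global, j] <-
        occupancy[(k_i + 1L):k_global, j] + 1L
    }
  }
  ids <- vapply(population, function(p) as.character(p$id), character(1L))
  ev_list <- lapply(seq_len(n), function(i) {
    ev <- sims[[i]]$events
    if (nrow(ev)) cbind(individual_id = ids[i], ev) else NULL
  })
  events <- do.call(rbind, ev_list)
  if (is.null(events)) {
    events <- data.frame(individual_id = character(), cycle = integer(),
                         event_kind = character(), detail = character(),
                         setting_after = character(), stringsAsFactors = FALSE)
  }
  final <- data.frame(
    individual_id = ids,
    final_setting = vapply(sims, function(s) s$individual$setting,
                           character(1L)),
    alive = vapply(sims, function(s) s$individual$alive, logical(1L)),
    n_cycles = vapply(sims, function(s) s$n_cycles, integer(1L)),
    n_falls = vapply(sims, function(s) s$individual$n_prior_falls,
                     integer(1L)),
    stringsAsFactors = FALSE
  )
  structure(
    list(events = events, occupancy = occupancy,
         trajectories = sims, final = final, n = n, seed = master_seed),
    class = "fall_cohort"
  )
}

#' @export
print.fall_cohort <- function(x, ...) {
  cat(sprintf("<fall_cohort> n = %d, %d cycles, %d events (seed %s)\n",
              x$n, nrow(x$occupancy), nrow(x$events), format(x$seed)))
  invisible(x)
}

## ---- structural audits ---------------------------------------------------

#' Share of fallers with more than one injury per fall
#'
#' Audits the one-injury-per-fall structural assumption in an event log. The
#' default engine can only ever produce 0; a non-zero share (possible in
#' hand-built logs) raises a validation warning listing the offending
#' faller-cycles.
#'
#' @param events Event log data frame with columns `individual_id`, `cycle`,
#'   `event_kind` (a `fall_cohort`'s `events` element, or compatible).
#' @return The fraction of fallers with at least one multi-injury fall, with
#'   attribute `violations` (data frame of offending individual/cycle pairs).
#' @export
multiple_injury_share <- function(events) {
  if (inherits(events, "fall_cohort")) events <- events$events
  falls <- events[events$event_kind == "FALL", , drop = FALSE]
  if (nrow(falls) == 0L) {
    stop("multiple_injury_share undefined: event log contains no falls")
  }
  inj <- events[events$event_kind == "INJURY", , drop = FALSE]
  fallers <- unique(falls$individual_id)
  if (nrow(inj)) {
    per_fall <- stats::aggregate(
      list(n_injuries = inj$event_kind),
      by = list(individual_id = inj$individual_id, cycle = inj$cycle),
      FUN = length
    )
    bad <- per_fall[per_fall$n_injuries > 1L, , drop = FALSE]
  } else {
    bad <- data.frame(individual_id = character(), cycle = integer(),
                      n_injuries = integer(), stringsAsFactors = FALSE)
  }
  share <- length(unique(bad$individual_id)) / length(fallers)
  if (nrow(bad)) {
    warning(sprintf(
      "one-injury-per-fall assumption violated for %d faller-cycle(s)",
      nrow(bad)))
  }
  structure(share, violations = bad)
}

#' Write a cohort's event log and occupancy matrix to CSV
#'
#' @param cohort A `fall_cohort`.
#' @param events_path,occupancy_path Output file paths (`NULL` to skip).
#' @return Invisible list of written paths.
#' @export
write_cohort <- function(cohort, events_path = NULL, occupancy_path = NULL) {
  stopifnot(inherits(cohort, "fall_cohort"))
  if (!is.null(events_path)) {
    utils::write.csv(cohort$events, events_path, row.names = FALSE)
  }
  if (!is.null(occupancy_path)) {
    occ <- data.frame(cycle = seq_len(nrow(cohort$occupancy)),
                      cohort$occupancy, check.names = FALSE)
    utils::write.csv(occ, occupancy_path, row.names = FALSE)
  }
  invisible(list(events = events_path, occupancy = occupancy_path))
}
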