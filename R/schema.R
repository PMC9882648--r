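## Model schema: the six-state structure, injury taxonomy, attribute
## registry and allowed transition topology of the fall prevention model.

#' Care-setting states of the model
#'
#' The six mutually exclusive, exhaustive states an individual can occupy in
#' a cycle: community dwelling (own home, retirement home, supportive housing
#' or assisted living), residential aged care (long-term care / nursing
#' home), hospital inpatient, rehabilitation hospital inpatient, death due to
#' a fall, and death from any other cause. Both death states are absorbing;
#' they are kept distinct so that fall-attributable mortality is reportable.
#'
#' @return Character vector of the six setting names.
#' @export
fall_settings <- function() {
  c("COMMUNITY", "RESIDENTIAL_AGED_CARE", "HOSPITAL", "REHAB_HOSPITAL",
    "DEATH_FALL", "DEATH_OTHER")
}

#' @rdname fall_settings
#' @export
absorbing_settings <- function() c("DEATH_FALL", "DEATH_OTHER")

#' Fall-injury taxonomy
#'
#' One injury type per fall (possibly `NONE`). `HEAD_INJURY` denotes an
#' intracranial bleed specifically; `MODERATE` covers dislocations or
#' fractures not named elsewhere; `MINOR` covers soft-tissue injuries such as
#' cuts, scrapes, bruises and sprains. `severity_rank` orders types for
#' reporting, most to least severe, with `NONE` last.
#'
#' @return Data frame with columns `injury`, `severity_rank`, `description`.
#' @export
injury_types <- function() {
  data.frame(
    injury = c("HEAD_INJURY", "HIP_FRACTURE", "VERTEBRAL_FRACTURE",
               "WRIST_FRACTURE", "MODERATE", "MINOR", "NONE"),
    severity_rank = 1:7,
    description = c(
      "intracranial bleed",
      "fracture of the hip",
      "fracture of a vertebra",
      "fracture of the wrist",
      "dislocations or fractures not otherwise listed",
      "soft tissue injury (cuts, scrapes, bruises, sprains)",
      "uninjurious fall"
    ),
    stringsAsFactors = FALSE
  )
}

#' Tracked event kinds
#'
#' Events recorded in each individual's history: the seven tracked clinical
#' events (fall, the four named fracture/injury types via `INJURY` with a
#' detail field, hip surgery, emergency department visit) plus bookkeeping
#' events for admissions, relocations and death.
#'
#' @return Character vector of event kinds.
#' @export
event_kinds <- function() {
  c("FALL", "INJURY", "ED_VISIT", "HOSPITAL_ADMISSION", "HIP_SURGERY",
    "REHAB_ADMISSION", "RELOCATION", "DEATH")
}

#' The 26-attribute registry
#'
#' Patient attributes that reached consensus for inclusion across both survey
#' rounds: 18 from round 1 and 8 from round 2. Each attribute carries a value
#' kind (binary flag, count, or continuous) and a `modeled` flag saying
#' whether the default hazard model attaches a multiplier to it. Value kinds
#' are binary except age (continuous, years) and polypharmacy (medication
#' count).
#'
#' @return Data frame with columns `id`, `label`, `value_kind`, `modeled`.
#' @export
attribute_registry <- function() {
  reg <- data.frame(
    id = c(
      "gait-balance-mobility", "history-of-falls", "impaired-vision",
      "older-age", "dementia-biological", "physical-inactivity",
      "fear-of-falling", "substance-use", "certain-medications",
      "transfer-assistance", "home-hazards", "use-of-restraints",
      "frailty", "parkinsons-disease", "stroke", "dementia-condition",
      "multiple-sclerosis", "osteoporosis",
      "incorrect-assistive-device-use", "unsupportive-footwear",
      "polypharmacy", "prolonged-hospital-stay", "cannot-afford-footwear",
      "social-isolation", "cannot-afford-medications", "psychiatric-illness"
    ),
    label = c(
      "Gait, balance, or mobility difficulties",
      "History of falls/previous falls", "Impaired vision", "Age, older age",
      "Dementia/cognitive impairment (biological factor)",
      "Physical inactivity", "Fear of falling", "Substance use",
      "Use of certain medications", "Need for transfer assistance",
      "Home hazards", "Use of restraints", "Overall frailty",
      "Parkinson's disease", "Stroke",
      "Dementia/cognitive impairment (health condition)",
      "Multiple sclerosis", "Osteoporosis",
      "Incorrect use of assistive devices", "Wearing unsupportive footwear",
      "Polypharmacy", "Prolonged hospital stay",
      "Unable to afford supportive footwear", "No social supports, isolated",
      "Unable to afford certain medications, nutritious food",
      "Psychiatric illness (including depression)"
    ),
    value_kind = "binary",
    modeled = FALSE,
    stringsAsFactors = FALSE
  )
  reg$value_kind[reg$id == "older-age"] <- "continuous"
  reg$value_kind[reg$id == "polypharmacy"] <- "count"
  reg$modeled[reg$id %in% c(
    "gait-balance-mobility", "history-of-falls", "impaired-vision",
    "older-age", "physical-inactivity", "fear-of-falling", "polypharmacy"
  )] <- TRUE
  reg
}

default_edges <- function() {
  rbind(
    data.frame(from = "COMMUNITY",
               to = c("RESIDENTIAL_AGED_CARE", "HOSPITAL",
                      "DEATH_FALL", "DEATH_OTHER")),
    data.frame(from = "RESIDENTIAL_AGED_CARE",
               to = c("COMMUNITY", "HOSPITAL", "DEATH_FALL", "DEATH_OTHER")),
    data.frame(from = "HOSPITAL",
               to = c("REHAB_HOSPITAL", "COMMUNITY", "RESIDENTIAL_AGED_CARE",
                      "DEATH_FALL", "DEATH_OTHER")),
    data.frame(from = "REHAB_HOSPITAL",
               to = c("COMMUNITY", "RESIDENTIAL_AGED_CARE",
                      "DEATH_FALL", "DEATH_OTHER"))
  )
}

# Mapping of the 14 consensus health states/events onto the model structure:
# 5 become setting states, 7 become tracked events (12 incorporated);
# post-fall is folded into event history (a recent-fall recency flag), and
# specialized dementia care is folded into the community setting because
# adding one specialized sub-setting would be inconsistent with omitting the
# others.
incorporation_map <- function() {
  data.frame(
    item_id = c(
      "independent-housing", "long-term-care-housing", "hospitalization",
      "rehabilitation-hospitalization", "death-due-to-fall",
      "fall", "hip-fracture", "vertebral-fracture", "wrist-fracture",
      "head-injury", "surgery-for-hip-fracture", "emergency-department-visit",
      "post-fall", "specialized-dementia-care"
    ),
    role = c(rep("state", 5L), rep("tracked_event", 7L),
             "folded", "excluded"),
    target = c(
      "COMMUNITY", "RESIDENTIAL_AGED_CARE", "HOSPITAL", "REHAB_HOSPITAL",
      "DEATH_FALL",
      "FALL", "INJURY:HIP_FRACTURE", "INJURY:VERTEBRAL_FRACTURE",
      "INJURY:WRIST_FRACTURE", "INJURY:HEAD_INJURY", "HIP_SURGERY",
      "ED_VISIT",
      "history:recent-fall-window", "COMMUNITY"
    ),
    stringsAsFactors = FALSE
  )
}

#' Construct the default fall model schema
#'
#' Assembles states, injury taxonomy, event kinds, attribute registry,
#' transition edges and pathway rules into a single queryable object.
#' Pathway rules are structural predicates the engine enforces within a
#' cycle: hospital admission from a living setting requires an emergency
#' department visit in the same cycle; rehabilitation is entered only from
#' hospital; hip surgery requires a hip fracture and a hospital admission; at
#' most one fall per cycle and one injury per fall.
#'
#' @param edges Optional replacement edge set (data frame `from`, `to`).
#' @param attributes Optional replacement attribute registry.
#' @return An object of class `fall_schema`.
#' @export
#' @examples
#' sch <- fall_schema()
#' validate_schema(sch)
fall_schema <- function(edges = default_edges(),
                        attributes = attribute_registry()) {
  structure(
    list(
      settings = fall_settings(),
      absorbing = absorbing_settings(),
      injuries = injury_types(),
      event_kinds = event_kinds(),
      attributes = attributes,
      edges = edges,
      pathway_rules = c(
        "ed_gate" = "admission to HOSPITAL from COMMUNITY or RESIDENTIAL_AGED_CARE requires an ED_VISIT in the same cycle",
        "rehab_from_hospital" = "REHAB_HOSPITAL entered only from HOSPITAL",
        "surgery_needs_hip" = "HIP_SURGERY only after HIP_FRACTURE and HOSPITAL_ADMISSION",
        "one_fall_per_cycle" = "at most one FALL event per cycle",
        "one_injury_per_fall" = "at most one INJURY event per fall"
      ),
      incorporation = incorporation_map()
    ),
    class = "fall_schema"
  )
}

#' @export
print.fall_schema <- function(x, ...) {
  cat("<fall_schema>\n")
  cat("  settings: ", paste(x$settings, collapse = ", "), "\n")
  cat("  injuries: ", nrow(x$injuries), " types; attributes: ",
      nrow(x$attributes), "; edges: ", nrow(x$edges), "\n", sep = "")
  invisible(x)
}

#' Validate a model schema
#'
#' Checks all structural invariants: exactly six settings with two absorbing
#' death states and no outgoing edges from them; one injury taxonomy entry
#' per type with `NONE` present; the attribute registry has exactly 26
#' entries; every edge endpoint is a known setting; rehabilitation is
#' reachable only from hospital. Violations are returned as data, not
#' raised as errors.
#'
#' @param schema A [fall_schema()].
#' @return Character vector of violation messages; empty if the schema is
#'   valid.
#' @export
validate_schema <- function(schema) {
  stopifnot(inherits(schema, "fall_schema"))
  v <- character()
  if (length(schema$settings) != 6L ||
      anyDuplicated(schema$settings)) {
    v <- c(v, "settings: must be exactly 6 distinct states")
  }
  if (!all(schema$absorbing %in% schema$settings)) {
    v <- c(v, "absorbing: unknown setting")
  }
  bad_abs <- intersect(schema$edges$from, schema$absorbing)
  for (s in bad_abs) {
    v <- c(v, sprintf("absorbing state has outgoing edge: %s", s))
  }
  unknown <- setdiff(unique(c(schema$edges$from, schema$edges$to)),
                     schema$settings)
  for (s in unknown) v <- c(v, sprintf("edge references unknown setting: %s", s))
  if (!"NONE" %in% schema$injuries$injury) {
    v <- c(v, "injury taxonomy lacks NONE")
  }
  if (anyDuplicated(schema$injuries$injury)) {
    v <- c(v, "duplicate injury types")
  }
  if (nrow(schema$attributes) != 26L) {
    v <- c(v, sprintf("attribute registry size != 26 (got %d)",
                      nrow(schema$attributes)))
  }
  if (anyDuplicated(schema$attributes$id)) {
    v <- c(v, "duplicate attribute ids")
  }
  bad_kind <- setdiff(unique(schema$attributes$value_kind),
                      c("binary", "count", "continuous"))
  for (k in bad_kind) v <- c(v, sprintf("unknown attribute value kind: %s", k))
  into_rehab <- schema$edges$from[schema$edges$to == "REHAB_HOSPITAL"]
  if (length(setdiff(into_rehab, "HOSPITAL"))) {
    v <- c(v, "REHAB_HOSPITAL entered from a non-hospital setting")
  }
  v
}

#' Allowed transitions out of a setting
#'
#' @param setting A setting name.
#' @param schema A [fall_schema()].
#' @return Character vector of successor settings (empty for absorbing
#'   states).
#' @export
#' @examples
#' allowed_transitions("DEATH_FALL") # character(0)
allowed_transitions <- function(setting, schema = fall_schema()) {
  stopifnot(inherits(schema, "fall_schema"))
  if (!setting %in% schema$settings) {
    stop(sprintf("unknown setting: %s", setting))
  }
  sort(unique(schema$edges$to[schema$edges$from == setting]))
}

#' Map consensus items onto the model structure
#'
#' Reports, for each consensus-included health state/event, whether the
#' default schema represents it as a setting state, a tracked event, folds it
#' into another construct (post-fall becomes a recency flag on event
#' history), or excludes it (specialized dementia care is folded into the
#' community setting). Items outside the known 14-item set are flagged
#' `unknown`.
#'
#' @param included_items Character vector of item ids (typically the
#'   cumulative health-state inclusion set from [delphi_analysis()]).
#' @param schema A [fall_schema()].
#' @return List with `mapping` (data frame `item_id`, `role`, `target`) and
#'   `counts` (named tally including `incorporated` = states + tracked
#'   events).
#' @export
incorporation_report <- function(included_items, schema = fall_schema()) {
  stopifnot(inherits(schema, "fall_schema"))
  included_items <- as.character(included_items)
  map <- schema$incorporation
  role <- map$role[match(included_items, map$item_id)]
  target <- map$target[match(included_items, map$item_id)]
  role[is.na(role)] <- "unknown"
  mapping <- data.frame(item_id = included_items, role = role,
                        target = target, stringsAsFactors = FALSE)
  counts <- c(
    state = sum(role == "state"),
    tracked_event = sum(role == "tracked_event"),
    folded = sum(role == "folded"),
    excluded = sum(role == "excluded"),
    unknown = sum(role == "unknown")
  )
  counts <- c(counts,
              incorporated = counts[["state"]] + counts[["tracked_event"]])
  list(mapping = mapping, counts = counts)
}

#' Write / read a schema as YAML
#'
#' Serializes the schema (states, injuries, events, attributes, edges,
#' pathway rules, incorporation map) to a YAML document; the round trip is
#' lossless.
#'
#' @param schema A [fall_schema()].
#' @param path Output file path.
#' @return `write_schema` returns `path` invisibly; `read_schema` returns a
#'   `fall_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "fall_schema"))
  doc <- list(
    settings = schema$settings,
    absorbing = schema$absorbing,
    injuries = schema$injuries,
    event_kinds = schema$event_kinds,
    attributes = schema$attributes,
    edges = schema$edges,
    pathway_rules = as.list(schema$pathway_rules),
    incorporation = schema$incorporation
  )
  yaml::write_yaml(doc, path, column.major = FALSE)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  doc <- yaml::read_yaml(path)
  need <- c("settings", "absorbing", "injuries", "event_kinds", "attributes",
            "edges", "pathway_rules", "incorporation")
  extra <- setdiff(names(doc), need)
  if (length(extra)) stop("unknown schema keys: ", paste(extra, collapse = ", "))
  missing_keys <- setdiff(need, names(doc))
  if (length(missing_keys)) {
    stop("schema file lacks keys: ", paste(missing_keys, collapse = ", "))
  }
  as_df <- function(x) {
    do.call(rbind, lapply(x, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  structure(
    list(
      settings = unlist(doc$settings),
      absorbing = unlist(doc$absorbing),
      injuries = as_df(doc$injuries),
      event_kinds = unlist(doc$event_kinds),
      attributes = as_df(doc$attributes),
      edges = as_df(doc$edges),
      pathway_rules = unlist(doc$pathway_rules),
      incorporation = as_df(doc$incorporation)
    ),
    class = "fall_schema"
  )
}
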