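## Modified-Delphi consensus engine.
##
## Panelists rate each candidate item on a 0-5 Likert scale, with an explicit
## "Don't Know" option. High agreement for inclusion means at least 80% of
## informative respondents (Don't Know excluded) rate the item 4 or 5; high
## agreement for exclusion means at least 80% rate it 2 or less; everything
## else is non-consensus and is re-rated in the next round.

#' Consensus criteria for a modified Delphi process
#'
#' Defines the high-agreement rule used to classify rating distributions.
#' Defaults correspond to the common "80% at 4+ on a 0-5 scale" rule:
#' inclusion when >= 80% of informative respondents rate an item at
#' `inclusion_min_rating` or above, exclusion when >= 80% rate it at
#' `exclusion_max_rating` or below, non-consensus otherwise.
#'
#' @param agreement_fraction Fraction of informative respondents required for
#'   high agreement, in (0, 1]. Default 0.80.
#' @param inclusion_min_rating Minimum rating counting towards inclusion
#'   (default 4).
#' @param exclusion_max_rating Maximum rating counting towards exclusion
#'   (default 2). Must be strictly less than `inclusion_min_rating`.
#' @param max_rounds Maximum number of survey rounds before the process stops
#'   regardless of consensus (default 3).
#' @return An object of class `consensus_criteria`.
#' @export
#' @examples
#' consensus_criteria()
consensus_criteria <- function(agreement_fraction = 0.80,
                               inclusion_min_rating = 4L,
                               exclusion_max_rating = 2L,
                               max_rounds = 3L) {
  stopifnot(
    is.numeric(agreement_fraction), length(agreement_fraction) == 1L,
    agreement_fraction > 0, agreement_fraction <= 1,
    inclusion_min_rating %in% 0:5, exclusion_max_rating %in% 0:5,
    exclusion_max_rating < inclusion_min_rating,
    max_rounds >= 1L
  )
  structure(
    list(
      agreement_fraction = agreement_fraction,
      inclusion_min_rating = as.integer(inclusion_min_rating),
      exclusion_max_rating = as.integer(exclusion_max_rating),
      max_rounds = as.integer(max_rounds)
    ),
    class = "consensus_criteria"
  )
}

#' Construct an item rating distribution
#'
#' Aggregate counts of panel ratings for one item in one survey round.
#'
#' @param item_id Short identifier, unique within a round.
#' @param counts Vector of 6 non-negative integer counts for ratings 0..5.
#' @param dont_know Number of "Don't Know" responses.
#' @param n_respondents Panel size for the round; must equal
#'   `sum(counts) + dont_know`.
#' @param item_label Free-text label (defaults to `item_id`).
#' @param item_kind `"health_state_event"` or `"patient_attribute"`.
#' @param round Survey round index (>= 1).
#' @return An object of class `rating_distribution`.
#' @export
#' @examples
#' rating_distribution("hip-fracture", c(0, 0, 0, 0, 1, 8),
#'                     dont_know = 2, n_respondents = 11)
rating_distribution <- function(item_id, counts, dont_know = 0L,
                                n_respondents = sum(counts) + dont_know,
                                item_label = item_id,
                                item_kind = c("health_state_event",
                                              "patient_attribute"),
                                round = 1L) {
  item_kind <- match.arg(item_kind)
  counts <- as.integer(counts)
  dont_know <- as.integer(dont_know)
  n_respondents <- as.integer(n_respondents)
  if (length(counts) != 6L || any(counts < 0L)) {
    stop("`counts` must be 6 non-negative integers (ratings 0..5)")
  }
  if (dont_know < 0L) stop("`dont_know` must be non-negative")
  if (sum(counts) + dont_know != n_respondents) {
    stop(sprintf(
      "counts (%d) + dont_know (%d) != n_respondents (%d) for item '%s'",
      sum(counts), dont_know, n_respondents, item_id
    ))
  }
  structure(
    list(
      item_id = as.character(item_id),
      item_label = as.character(item_label),
      item_kind = item_kind,
      round = as.integer(round),
      counts = counts,
      dont_know = dont_know,
      n_respondents = n_respondents
    ),
    class = "rating_distribution"
  )
}

#' @export
print.rating_distribution <- function(x, ...) {
  cat(sprintf("<rating_distribution> %s (round %d, %s)\n",
              x$item_id, x$round, x$item_kind))
  cat("  ratings 0..5:", x$counts, " don't know:", x$dont_know,
      " n:", x$n_respondents, "\n")
  invisible(x)
}

# Half-up rounding for display, e.g. 3.875 -> 3.88. base::round() rounds half
# to even, which would print 3.88 as 3.88 but 4.885 as 4.88; panel averages
# are conventionally rounded half up. The 1e-9 guard absorbs binary
# representation error in quotients such as 44/9.
round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  floor(x * m + 0.5 + 1e-9) / m
}

# Exact rational threshold comparison: is num/den >= frac? The fraction is
# rationalized to a denominator of 1e6 so that 8/10 >= 0.80 holds exactly,
# immune to binary floating-point representation of the threshold.
frac_ge <- function(num, den, frac) {
  num * 1e6 >= round(frac * 1e6) * den
}

informative_n <- function(dist) dist$n_respondents - dist$dont_know

#' Panel average rating of an item
#'
#' Mean rating over informative respondents: "Don't Know" responses are
#' excluded from both numerator and denominator. The `panel_average` element
#' is rounded half-up to 2 decimals for reporting; `raw` keeps full precision.
#'
#' @param dist A [rating_distribution()].
#' @return Named list with `panel_average` (2-decimal) and `raw`.
#' @export
#' @examples
#' d <- rating_distribution("hip-fracture", c(0, 0, 0, 0, 1, 8), 2)
#' panel_average(d)$panel_average # 4.89
panel_average <- function(dist) {
  stopifnot(inherits(dist, "rating_distribution"))
  n_inf <- informative_n(dist)
  if (n_inf < 1L) {
    stop(sprintf("no informative ratings for item '%s'", dist$item_id))
  }
  raw <- sum((0:5) * dist$counts) / n_inf
  list(panel_average = round_half_up(raw, 2L), raw = raw)
}

#' Classify one item against the consensus criteria
#'
#' Computes the fraction of informative respondents rating at or above the
#' inclusion threshold (`fraction_high`) and at or below the exclusion
#' threshold (`fraction_low`), and assigns the item to `inclusion`,
#' `exclusion` or `non_consensus`. Threshold comparisons use exact rational
#' arithmetic so that boundary cases such as 8/10 against 0.80 are inclusive.
#'
#' @param dist A [rating_distribution()].
#' @param criteria A [consensus_criteria()].
#' @return An object of class `item_classification`: list with `item_id`,
#'   `category`, `informative_n`, `fraction_high`, `fraction_low`,
#'   `panel_average`.
#' @export
#' @examples
#' d <- rating_distribution("vertebral-fracture", c(0, 0, 1, 1, 1, 7), 1)
#' classify_item(d)$category # "inclusion" (8/10 = 80%)
classify_item <- function(dist, criteria = consensus_criteria()) {
  stopifnot(inherits(dist, "rating_distribution"),
            inherits(criteria, "consensus_criteria"))
  n_inf <- informative_n(dist)
  if (n_inf < 1L) {
    stop(sprintf("no informative ratings for item '%s'", dist$item_id))
  }
  n_high <- sum(dist$counts[(criteria$inclusion_min_rating + 1L):6L])
  n_low <- sum(dist$counts[1L:(criteria$exclusion_max_rating + 1L)])
  category <- if (frac_ge(n_high, n_inf, criteria$agreement_fraction)) {
    "inclusion"
  } else if (frac_ge(n_low, n_inf, criteria$agreement_fraction)) {
    "exclusion"
  } else {
    "non_consensus"
  }
  structure(
    list(
      item_id = dist$item_id,
      item_kind = dist$item_kind,
      round = dist$round,
      category = category,
      informative_n = n_inf,
      fraction_high = n_high / n_inf,
      fraction_low = n_low / n_inf,
      panel_average = panel_average(dist)$panel_average
    ),
    class = "item_classification"
  )
}

#' Summarize one survey round
#'
#' Classifies every item rated in a round, tallies categories, and splits the
#' item set into items carried forward (non-consensus, to be re-rated) and
#' items retired from rating (inclusion or exclusion).
#'
#' @param dists List of [rating_distribution()] objects sharing one round
#'   index and panel size.
#' @param criteria A [consensus_criteria()].
#' @return An object of class `round_summary`: list with `round`, `items`
#'   (data frame of per-item classifications), `tally` (named counts),
#'   `carried_forward` and `retired` item id vectors.
#' @export
summarize_round <- function(dists, criteria = consensus_criteria()) {
  stopifnot(is.list(dists))
  if (length(dists) == 0L) {
    return(structure(
      list(round = NA_integer_,
           items = data.frame(item_id = character(), item_kind = character(),
                              category = character(), informative_n = integer(),
                              fraction_high = numeric(), fraction_low = numeric(),
                              panel_average = numeric(),
                              stringsAsFactors = FALSE),
           tally = c(inclusion = 0L, exclusion = 0L, non_consensus = 0L),
           carried_forward = character(), retired = character()),
      class = "round_summary"
    ))
  }
  ids <- vapply(dists, `[[`, character(1L), "item_id")
  if (anyDuplicated(ids)) {
    stop("duplicate item ids in round: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rounds <- vapply(dists, `[[`, integer(1L), "round")
  ns <- vapply(dists, `[[`, integer(1L), "n_respondents")
  if (length(unique(rounds)) != 1L) stop("items span multiple rounds")
  if (length(unique(ns)) != 1L) stop("items disagree on panel size")

  cls <- lapply(dists, classify_item, criteria = criteria)
  items <- data.frame(
    item_id = ids,
    item_kind = vapply(cls, `[[`, character(1L), "item_kind"),
    category = vapply(cls, `[[`, character(1L), "category"),
    informative_n = vapply(cls, `[[`, integer(1L), "informative_n"),
    fraction_high = vapply(cls, `[[`, numeric(1L), "fraction_high"),
    fraction_low = vapply(cls, `[[`, numeric(1L), "fraction_low"),
    panel_average = vapply(cls, `[[`, numeric(1L), "panel_average"),
    stringsAsFactors = FALSE
  )
  tally <- c(
    inclusion = sum(items$category == "inclusion"),
    exclusion = sum(items$category == "exclusion"),
    non_consensus = sum(items$category == "non_consensus")
  )
  structure(
    list(
      round = rounds[[1L]],
      items = items,
      tally = tally,
      carried_forward = items$item_id[items$category == "non_consensus"],
      retired = items$item_id[items$category != "non_consensus"]
    ),
    class = "round_summary"
  )
}

#' @export
print.round_summary <- function(x, ...) {
  cat(sprintf("<round_summary> round %s: %d items\n",
              x$round, nrow(x$items)))
  cat(sprintf("  inclusion %d | exclusion %d | non-consensus %d\n",
              x$tally[["inclusion"]], x$tally[["exclusion"]],
              x$tally[["non_consensus"]]))
  invisible(x)
}

#' Item set for the next survey round
#'
#' The next round re-rates every non-consensus item plus any newly proposed
#' items; items that reached inclusion or exclusion are retired from rating.
#' An empty result signals the natural stopping point of the process.
#'
#' @param summary A [summarize_round()] result.
#' @param new_items Character vector of newly proposed item ids.
#' @return Character vector of item ids to be rated next round.
#' @export
build_next_round <- function(summary, new_items = character()) {
  stopifnot(inherits(summary, "round_summary"))
  new_items <- as.character(new_items)
  clash <- intersect(new_items, summary$items$item_id)
  if (length(clash)) {
    stop("new items duplicate existing ids: ", paste(clash, collapse = ", "))
  }
  if (anyDuplicated(new_items)) stop("duplicate ids among new items")
  c(summary$carried_forward, new_items)
}

#' Cumulative inclusion set across rounds
#'
#' Union of all items classified as inclusion in any round. An item re-rated
#' in a later round takes its latest classification; items retired after
#' reaching inclusion stay included.
#'
#' @param summaries List of [summarize_round()] results, in round order.
#' @return Character vector of included item ids (first-inclusion order).
#' @export
cumulative_inclusions <- function(summaries) {
  stopifnot(is.list(summaries), length(summaries) >= 1L)
  out <- character()
  for (s in summaries) {
    stopifnot(inherits(s, "round_summary"))
    inc <- s$items$item_id[s$items$category == "inclusion"]
    out <- union(out, inc)
  }
  out
}

#' Read a ratings fixture file
#'
#' Reads a CSV with columns `item_id,item_label,item_kind,round,count_0,...,
#' count_5,dont_know,n_respondents` into a list of [rating_distribution()]
#' objects. The package ships the transcribed panel rating tables of the
#' two-round fall-model survey as
#' `system.file("extdata", "delphi_ratings.csv", package = "fallsim")`.
#'
#' @param path CSV file path.
#' @param round Optional round filter.
#' @param item_kind Optional kind filter (`"health_state_event"` or
#'   `"patient_attribute"`).
#' @return List of `rating_distribution` objects.
#' @export
read_ratings <- function(path, round = NULL, item_kind = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "item_label", "item_kind", "round",
            paste0("count_", 0:5), "dont_know", "n_respondents")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("ratings file lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!is.null(round)) df <- df[df$round == round, , drop = FALSE]
  if (!is.null(item_kind)) df <- df[df$item_kind == item_kind, , drop = FALSE]
  lapply(seq_len(nrow(df)), function(i) {
    rating_distribution(
      item_id = df$item_id[i],
      counts = as.integer(df[i, paste0("count_", 0:5)]),
      dont_know = df$dont_know[i],
      n_respondents = df$n_respondents[i],
      item_label = df$item_label[i],
      item_kind = df$item_kind[i],
      round = df$round[i]
    )
  })
}

#' Path to the packaged Delphi rating fixtures
#'
#' @param which `"ratings"` for the per-item rating distributions or
#'   `"published"` for the published per-item panel averages and
#'   classification blocks used in validation.
#' @return File path.
#' @export
delphi_fixture_path <- function(which = c("ratings", "published")) {
  which <- match.arg(which)
  fname <- switch(which,
                  ratings = "delphi_ratings.csv",
                  published = "delphi_published_summary.csv")
  system.file("extdata", fname, package = "fallsim", mustWork = TRUE)
}

#' Run the full two-round consensus analysis on the packaged fixtures
#'
#' Convenience wrapper: classifies both rounds for one item kind and returns
#' the per-round summaries plus the cumulative inclusion set.
#'
#' @param item_kind `"health_state_event"` or `"patient_attribute"`.
#' @param criteria A [consensus_criteria()].
#' @param path Ratings CSV; defaults to the packaged fixture.
#' @return List with `rounds` (list of `round_summary`) and `included`
#'   (character vector).
#' @export
delphi_analysis <- function(item_kind = c("health_state_event",
                                          "patient_attribute"),
                            criteria = consensus_criteria(),
                            path = delphi_fixture_path("ratings")) {
  item_kind <- match.arg(item_kind)
  rounds <- sort(unique(vapply(read_ratings(path, item_kind = item_kind),
                               `[[`, integer(1L), "round")))
  summaries <- lapply(rounds, function(r) {
    summarize_round(read_ratings(path, round = r, item_kind = item_kind),
                    criteria)
  })
  list(rounds = summaries, included = cumulative_inclusions(summaries))
}
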