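# Modified-Delphi consensus engine: classification rule, panel averages,
# round management, and exact reproduction of the published survey outcomes.

test_that("panel averages exclude Don't Know responses and round half-up", {
  # hip fracture, round 1: 1x4 + 8x5 over 9 informative respondents
  hip <- rating_distribution("hip-fracture", c(0, 0, 0, 0, 1, 8), 2)
  expect_equal(panel_average(hip)$panel_average, 4.89)
  expect_equal(panel_average(hip)$raw, 44 / 9)
  # dementia as biological factor: mean 4.40 over 10 informative
  dem <- rating_distribution("dementia-biological", c(0, 0, 0, 1, 4, 5), 1)
  expect_equal(panel_average(dem)$panel_average, 4.40)
  # degenerate: everyone rates 0
  zero <- rating_distribution("x", c(11, 0, 0, 0, 0, 0), 0)
  expect_equal(panel_average(zero)$panel_average, 0)
  # half-up at an exact .5 boundary: 31/8 = 3.875 -> 3.88
  osteo <- rating_distribution("osteoporosis", c(0, 1, 0, 0, 5, 2), 3)
  expect_equal(panel_average(osteo)$panel_average, 3.88)
  # no informative respondents is undefined
  dk <- rating_distribution("y", c(0, 0, 0, 0, 0, 0), 11)
  expect_error(panel_average(dk), "no informative ratings")
})

test_that("classification uses the 80% informative-respondent rule with exact boundaries", {
  # vertebral fracture round 1: 8/10 informative at >=4 is exactly 80% -> in
  vert <- rating_distribution("vertebral-fracture", c(0, 0, 1, 1, 1, 7), 1)
  cl <- classify_item(vert)
  expect_identical(cl$category, "inclusion")
  expect_equal(cl$fraction_high, 0.8)
  # post-fall round 1: 7/10 -> non-consensus
  pf <- rating_distribution("post-fall", c(0, 0, 1, 2, 1, 6), 1)
  expect_identical(classify_item(pf)$category, "non_consensus")
  # all ratings <= 2 -> exclusion
  low <- rating_distribution("z", c(0, 10, 0, 0, 0, 0), 0)
  expect_identical(classify_item(low)$category, "exclusion")
  expect_error(
    classify_item(rating_distribution("w", rep(0L, 6), 5)),
    "no informative ratings"
  )
})

test_that("classification is invariant to scaling all counts by a common factor", {
  dists <- read_ratings(delphi_fixture_path("ratings"), round = 1)
  for (k in c(2L, 7L)) {
    for (d in dists[seq(1, length(dists), by = 5)]) {
      scaled <- rating_distribution(d$item_id, d$counts * k, d$dont_know * k,
                                    item_kind = d$item_kind, round = d$round)
      expect_identical(classify_item(scaled)$category,
                       classify_item(d)$category)
    }
  }
})

test_that("round summaries reproduce the published tallies and carry-forward", {
  hs1 <- summarize_round(read_ratings(delphi_fixture_path("ratings"),
                                      round = 1,
                                      item_kind = "health_state_event"))
  expect_equal(unname(hs1$tally),
               c(9L, 0L, 11L)) # inclusion, exclusion, non-consensus
  pa1 <- summarize_round(read_ratings(delphi_fixture_path("ratings"),
                                      round = 1,
                                      item_kind = "patient_attribute"))
  expect_equal(unname(pa1$tally), c(18L, 0L, 20L))
  hs2 <- summarize_round(read_ratings(delphi_fixture_path("ratings"),
                                      round = 2,
                                      item_kind = "health_state_event"))
  expect_equal(hs2$tally[["inclusion"]], 5L)
  pa2 <- summarize_round(read_ratings(delphi_fixture_path("ratings"),
                                      round = 2,
                                      item_kind = "patient_attribute"))
  expect_equal(pa2$tally[["inclusion"]], 8L)

  # round 2 = round-1 non-consensus + the newly proposed items
  expect_length(build_next_round(hs1, c("ankle-fracture", "humerus-fracture",
                                        "alternate-level-of-care",
                                        "transitional-care-unit")), 15L)
  expect_length(build_next_round(pa1, c("diabetes", "cardiac-disease",
                                        "hypertension")), 23L)
  expect_setequal(build_next_round(hs1, character()), hs1$carried_forward)
  # the item sets actually rated in round 2 match the carry-forward logic
  expect_setequal(
    build_next_round(hs1, c("ankle-fracture", "humerus-fracture",
                            "alternate-level-of-care",
                            "transitional-care-unit")),
    hs2$items$item_id
  )
  expect_error(build_next_round(hs1, "post-fall"), "duplicate")

  # empty round and stopping criterion
  empty <- summarize_round(list())
  expect_equal(sum(empty$tally), 0L)
  expect_length(build_next_round(empty), 0L)
})

test_that("summarize_round rejects malformed rounds", {
  d1 <- rating_distribution("a", c(0, 0, 0, 0, 5, 5), 1)
  expect_error(summarize_round(list(d1, d1)), "duplicate item ids in round: a")
  d2 <- rating_distribution("b", c(0, 0, 0, 0, 5, 5), 1, round = 2)
  expect_error(summarize_round(list(d1, d2)), "multiple rounds")
  d3 <- rating_distribution("c", c(0, 0, 0, 0, 5, 4), 1)
  expect_error(summarize_round(list(d1, d3)), "panel size")
})

test_that("cumulative inclusions reach 14 health states/events and 26 attributes", {
  hs <- delphi_analysis("health_state_event")
  pa <- delphi_analysis("patient_attribute")
  expect_length(hs$included, 14L)
  expect_length(pa$included, 26L)
  # the 14-item set matches the published selection
  expect_setequal(hs$included, fall_schema()$incorporation$item_id)
  # the 26 attributes are exactly the attribute registry
  expect_setequal(pa$included, attribute_registry()$id)
  # monotone non-decreasing in rounds
  expect_true(all(cumulative_inclusions(hs$rounds[1]) %in% hs$included))
  expect_length(cumulative_inclusions(hs$rounds[1]), 9L)
})

test_that("every fixture row reproduces the published block and panel average", {
  pub <- utils::read.csv(delphi_fixture_path("published"),
                         stringsAsFactors = FALSE)
  dists <- read_ratings(delphi_fixture_path("ratings"))
  expect_equal(length(dists), nrow(pub))
  cls <- lapply(dists, classify_item)
  key <- paste(vapply(cls, `[[`, character(1), "item_id"),
               vapply(cls, `[[`, integer(1), "round"))
  m <- match(key, paste(pub$item_id, pub$round))
  expect_false(anyNA(m))
  expect_identical(vapply(cls, `[[`, character(1), "category"),
                   pub$published_group[m])
  expect_equal(vapply(cls, `[[`, numeric(1), "panel_average"),
               pub$published_average[m])
  # no item ever met exclusion criteria
  expect_false(any(vapply(cls, `[[`, character(1), "category") == "exclusion"))
})

test_that("fixture files are unchanged (transcription drift guard)", {
  expect_identical(
    unname(tools::md5sum(delphi_fixture_path("ratings"))),
    "ce22ed345bf922116352a8dee94139f3"
  )
  expect_identical(
    unname(tools::md5sum(delphi_fixture_path("published"))),
    "53fac9358e1bd242a9df6a2c961d1428"
  )
})

test_that("rating distributions enforce their count invariants", {
  expect_error(rating_distribution("a", c(1, 2, 3), 0), "6 non-negative")
  expect_error(
    rating_distribution("a", c(0, 0, 0, 0, 5, 5), 2, n_respondents = 11),
    "n_respondents"
  )
  expect_error(consensus_criteria(inclusion_min_rating = 2,
                                  exclusion_max_rating = 3))
})
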