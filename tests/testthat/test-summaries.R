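finalised_linkage <- function(matched_a = character(), matched_b = character(),
                              unique_a = character(), unique_b = character()) {
  structure(list(
    matched_pairs = tibble::tibble(record_id_A = matched_a,
                                   record_id_B = matched_b),
    unique_A = unique_a, unique_B = unique_b,
    pending_possibles = tibble::tibble()
  ), class = "linkage_result")
}

test_that("union_events counts every matched pair once and refuses pending links", {
  a <- ev(c("a1", "a2"), attack_type = c("facility", "personnel"))
  b <- ev("b1", source = "B", attack_type = "facility")
  lk <- finalised_linkage("a1", "b1", unique_a = "a2")
  un <- union_events(a, b, lk)
  expect_equal(nrow(un), 2)
  expect_equal(sum(un$matched), 1)
  expect_equal(sort(un$record_id), c("a1", "a2"))

  pending <- lk
  pending$pending_possibles <- tibble::tibble(record_id_A = "a2",
                                              record_id_B = "b1")
  expect_error(union_events(a, b, pending), "pending")
})

test_that("the attack-type table has stable shape, counts and percentages", {
  a <- ev(c("a1", "a2", "a3"),
          attack_type = c("facility", "facility", "personnel"))
  b <- ev(c("b1", "b2"), source = "B",
          attack_type = c("facility", "ambulance"))
  lk <- finalised_linkage("a1", "b1", unique_a = c("a2", "a3"),
                          unique_b = "b2")
  tab <- attack_type_table(a, b, lk)
  expect_equal(tab$attack_type, ATTACK_TYPES)
  expect_equal(tab$n_A[tab$attack_type == "facility"], 2)
  expect_equal(tab$pct_A[tab$attack_type == "facility"], 66.7)
  expect_equal(tab$n_matched[tab$attack_type == "facility"], 1)
  # every record of both sources counted exactly once in the totals
  expect_equal(sum(tab$n_total), nrow(a) + nrow(b))
  expect_equal(sum(tab$n_matched), 1)
  expect_equal(attr(tab, "denominators"), c(A = 3L, B = 2L, total = 5L))
})

test_that("attack-type percentage columns each sum to ~100", {
  run <- fixture_run()
  tab <- run$attack_type_table
  for (col in c("pct_A", "pct_B", "pct_total")) {
    expect_lt(abs(sum(tab[[col]]) - 100), 0.25)
  }
})

test_that("cross-source type disagreements of matched pairs are surfaced", {
  a <- ev("a1", attack_type = "facility")
  b <- ev("b1", source = "B", attack_type = "personnel")
  tab <- attack_type_table(a, b, finalised_linkage("a1", "b1"))
  conflicts <- attr(tab, "type_conflicts")
  expect_equal(nrow(conflicts), 1)
  expect_equal(conflicts$type_A, "facility")
  expect_equal(conflicts$type_B, "personnel")
  # tabulated under the source-A type
  expect_equal(tab$n_matched[tab$attack_type == "facility"], 1)
})

test_that("monthly counts cover all twelve months and track undated events", {
  a <- suppressWarnings(ev(c("a1", "a2", "a3"),
                           event_date = c("2017-02-10", "2017-02-20", NA)))
  un <- union_events(a, ev(character(0)), finalised_linkage(
    unique_a = c("a1", "a2", "a3")))
  mc <- monthly_counts(un)
  expect_equal(nrow(mc), 12)
  expect_equal(mc$n[mc$month == 2], 2)
  expect_equal(sum(mc$n), 2)
  expect_equal(attr(mc, "unknown_n"), 1)
})

test_that("the country table separates non-WHE, lost-by-definition and final", {
  events <- dplyr::bind_rows(
    ev(c("a1", "a2", "a3", "a4"),
       country = c("Iraq", "France", "Turkey", "Syria"),
       meets_definition = c("true", "true", "false", "true")),
    ev("b1", source = "B", country = "Yemen")
  )
  res <- apply_inclusion(events)
  ct <- country_table(events, res$outcomes)
  a_row <- ct[ct$source == "A", ]
  expect_equal(a_row$reported, 3) # Syria not counted
  expect_equal(a_row$excluded_non_whe, 1) # France
  expect_equal(a_row$excluded_by_definition, 1) # Turkey lost its only event
  expect_equal(a_row$final, 1) # Iraq
  b_row <- ct[ct$source == "B", ]
  expect_equal(b_row$reported, 1)
  expect_equal(b_row$final, 1)
})

test_that("the actor/location breakdown states the denominator of every share", {
  a <- ev(c("a1", "a2"), named_actor = c("msf_redcross", "none"),
          location_name = c("Baghdad", NA), setting = c("urban", "rural"))
  b <- ev("b1", source = "B", named_actor = "msf_redcross",
          location_name = "Baghdad", setting = "urban")
  lk <- finalised_linkage("a1", "b1", unique_a = "a2")
  bd <- actor_location_breakdown(a, b, lk)
  get <- function(stat, col) bd[[col]][bd$stat == stat]
  expect_equal(get("matched_msf_redcross", "n"), 1)
  expect_equal(get("matched_msf_redcross", "denom"), 1) # matched pairs
  expect_equal(get("unique_msf_redcross", "denom"), 1)  # unique events
  expect_equal(get("missing_location", "n"), 1)
  expect_equal(get("missing_location", "denom"), 3)     # all records
  expect_equal(get("missing_location", "pct"), 33.3)
  expect_equal(get("matched_capital_city", "n"), 1)     # Baghdad pair
  expect_equal(get("setting_urban", "n"), 2)
})

test_that("summary tables are deterministic across repeated calls", {
  run <- fixture_run()
  a <- run$included_a
  b <- run$included_b
  expect_equal(attack_type_table(a, b, run$linkage),
               attack_type_table(a, b, run$linkage))
  expect_equal(actor_location_breakdown(a, b, run$linkage),
               actor_location_breakdown(a, b, run$linkage))
})
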