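test_that("date agreement honours precision and tolerance", {
  a <- suppressWarnings(ev(as.character(1:6), event_date = c(
    "2017-05-10", "2017-05-10", "2017-05-10", "2017-05", "2017-05", NA)))
  b <- suppressWarnings(ev(as.character(1:6), source = "B", event_date = c(
    "2017-05-10", "2017-05-12", "2017-05-13", "2017-05", "2017-05-20", NA)))
  cmp <- compare_fields(a, b)
  expect_equal(cmp$date_cmp, c(
    "exact",        # same day
    "approximate",  # 2 days apart, at the tolerance
    "none",         # 3 days apart, beyond it
    "exact",        # both month precision, same month
    "approximate",  # month vs day, same month
    "unassessable"  # missing on both sides
  ))
  expect_equal(cmp$date_gap_days[2], 2)
  expect_true(is.na(cmp$date_gap_days[6]))
})

test_that("string agreement uses normalised Jaro-Winkler at the threshold", {
  a <- ev(as.character(1:4),
          location_name = c("Kandovar", "KANDOVAR  ", "Kandovar City", "Mosul"))
  b <- ev(as.character(1:4), source = "B",
          location_name = c("Kandovar", "kandovar", "Kandovar", NA))
  cmp <- compare_fields(a, b)
  expect_equal(cmp$location_cmp,
               c("exact", "exact", "approximate", "unassessable"))
  expect_gte(cmp$location_sim[3], 0.90)
})

test_that("pairs classify as definite, possible or unique per the two-exact rule", {
  agreement <- tibble::tibble(
    date_cmp     = c("exact", "exact",  "none",        "none",  "unassessable"),
    location_cmp = c("exact", "none",   "approximate", "none",  "unassessable"),
    name_cmp     = c("none",  "none",   "none",        "none",  "unassessable")
  )
  expect_equal(classify_pairs(agreement),
               c("definite", "possible", "possible", "unique", "unique"))
})

test_that("a copied dataset links one-to-one with nothing left unique", {
  a <- ev(sprintf("a%02d", 1:6),
          country = rep(c("Iraq", "Yemen"), each = 3),
          event_date = sprintf("2017-0%d-10", rep(1:3, 2)),
          location_name = rep(c("Mosul", "Erbil", "Basra"), 2),
          entity_name = paste("Clinic", 1:6))
  b <- a
  b$source <- "B"
  b$record_id <- sub("^a", "b", a$record_id)
  res <- link_events(a, b)
  expect_s3_class(res, "linkage_result")
  expect_equal(nrow(res$matched_pairs), 6)
  expect_equal(length(res$unique_A), 0)
  expect_equal(length(res$unique_B), 0)
  expect_equal(sub("^a", "b", res$matched_pairs$record_id_A),
               res$matched_pairs$record_id_B)
  expect_equal(nrow(res$pending_possibles), 0)
})

test_that("matching is one-to-one even with competing candidates", {
  # two A records and one B record agree on date+location; only one can match
  a <- ev(c("a1", "a2"), event_date = "2017-05-10",
          location_name = "Mosul", entity_name = c("Alpha", "Beta"))
  b <- ev("b1", source = "B", event_date = "2017-05-10",
          location_name = "Mosul", entity_name = "Alpha")
  res <- link_events(a, b)
  expect_equal(nrow(res$matched_pairs), 1)
  # the pair agreeing on all three fields outranks the two-field pair
  expect_equal(res$matched_pairs$record_id_A, "a1")
  expect_equal(res$unique_A, "a2")
})

test_that("records in disjoint countries never pair", {
  a <- ev("a1", country = "Iraq", event_date = "2017-05-10",
          location_name = "Crossing")
  b <- ev("b1", source = "B", country = "Yemen", event_date = "2017-05-10",
          location_name = "Crossing")
  res <- link_events(a, b)
  expect_equal(nrow(res$matched_pairs), 0)
  expect_equal(res$unique_A, "a1")
  expect_equal(res$unique_B, "b1")
})

test_that("linkage is symmetric in the two sources and invariant to row order", {
  bundle <- fixture_bundle()
  key <- truth_adjudicator(bundle$truth_key)
  inc_a <- apply_inclusion(bundle$a,
                           duplicates = drop_duplicates(bundle$a)$dropped$record_id)$included
  inc_b <- apply_inclusion(bundle$b,
                           duplicates = drop_duplicates(bundle$b)$dropped$record_id)$included
  fwd <- link_events(inc_a, inc_b, adjudicator = key)
  rev <- link_events(inc_b, inc_a, adjudicator = key)
  expect_equal(unordered_pairs(fwd), unordered_pairs(rev))
  expect_equal(sort(fwd$unique_A), sort(rev$unique_B))

  set.seed(42)
  shuf <- link_events(inc_a[sample(nrow(inc_a)), ], inc_b[sample(nrow(inc_b)), ],
                      adjudicator = key)
  expect_equal(unordered_pairs(shuf), unordered_pairs(fwd))
})

test_that("pending possibles warn without an adjudicator and resolve with one", {
  a <- ev("a1", event_date = "2017-05-10", location_name = "Mosul")
  b <- ev("b1", source = "B", event_date = "2017-05-11",
          location_name = "Baquba")
  expect_warning(res <- link_events(a, b), "pending adjudication")
  expect_equal(nrow(res$pending_possibles), 1)
  expect_equal(nrow(res$matched_pairs), 0)

  done <- apply_adjudication(res, tibble::tibble(
    record_id_A = "a1", record_id_B = "b1", decision = "definite"))
  expect_equal(nrow(done$matched_pairs), 1)
  expect_equal(done$matched_pairs$origin, "adjudicated")
  expect_equal(length(done$unique_A), 0)
  expect_equal(nrow(done$pending_possibles), 0)

  kept <- apply_adjudication(res, tibble::tibble(
    record_id_A = "a1", record_id_B = "b1", decision = "unique"))
  expect_equal(nrow(kept$matched_pairs), 0)
  expect_equal(kept$unique_A, "a1")

  expect_error(
    apply_adjudication(res, tibble::tibble(
      record_id_A = "zz", record_id_B = "b1", decision = "definite")),
    "unknown pair"
  )
})

test_that("review export and import round-trip adjudication decisions", {
  a <- ev("a1", event_date = "2017-05-10", location_name = "Mosul")
  b <- ev("b1", source = "B", event_date = "2017-05-11",
          location_name = "Baquba")
  suppressWarnings(res <- link_events(a, b))
  path <- tempfile(fileext = ".csv")
  review <- adjudicate_export(res, a, b, path)
  expect_equal(review$record_id_A, "a1")
  expect_equal(review$date_A, "2017-05-10")

  filled <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                            progress = FALSE)
  filled$decision <- "definite"
  readr::write_csv(filled, path, na = "")
  decisions <- adjudicate_import(path)
  done <- apply_adjudication(res, decisions)
  expect_equal(nrow(done$matched_pairs), 1)

  filled$decision <- "maybe"
  readr::write_csv(filled, path, na = "")
  expect_error(adjudicate_import(path), "definite")
})

test_that("linkage metrics score matched pairs against ground truth", {
  res <- structure(list(
    matched_pairs = tibble::tibble(record_id_A = c("a1", "a2"),
                                   record_id_B = c("b1", "b3")),
    unique_A = character(), unique_B = character(),
    pending_possibles = tibble::tibble()
  ), class = "linkage_result")
  truth <- tibble::tibble(record_id_A = c("a1", "a2"),
                          record_id_B = c("b1", "b2"))
  m <- linkage_metrics(res, truth)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)
})

test_that("link_events refuses two datasets from the same source", {
  a <- ev("a1")
  b <- ev("b1")
  expect_error(link_events(a, b), "different sources")
})
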