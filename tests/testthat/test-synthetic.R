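test_that("joint capture probability honours margins and odds ratio", {
  expect_equal(joint_capture_prob(0.3, 0.2, 1), 0.06)
  expect_gt(joint_capture_prob(0.3, 0.2, 3), 0.06) # positive dependence
  expect_lt(joint_capture_prob(0.3, 0.2, 0.3), 0.06)
  # stays within the Frechet bounds
  p11 <- joint_capture_prob(0.9, 0.8, 100)
  expect_lte(p11, 0.8)
  expect_gte(p11, 0.7)
})

test_that("certain capture yields two complete, perfectly keyed lists", {
  cfg <- generator_config(n_true = 40, p1 = 1, p2 = 1, seed = 7,
                          date_jitter_prob = 0, location_missing_prob = 0,
                          location_coarsen_prob = 0, name_perturb_prob = 0)
  bundle <- synthesize_datasets(generate_world(cfg))
  expect_equal(nrow(bundle$a), 40)
  expect_equal(nrow(bundle$b), 40)
  expect_equal(nrow(bundle$truth_key), 40)
  expect_true(all(bundle$truth_key$record_id_A %in% bundle$a$record_id))
  expect_true(all(bundle$truth_key$record_id_B %in% bundle$b$record_id))
})

test_that("latent events are distinct on country, date and location", {
  world <- generate_world(generator_config(n_true = 300, seed = 11))
  key <- paste(world$latent$country, world$latent$event_date,
               world$latent$location_name)
  expect_equal(anyDuplicated(key), 0)
})

test_that("the truth key is exactly the co-captured latent events", {
  world <- generate_world(generator_config(n_true = 200, seed = 3))
  bundle <- synthesize_datasets(world)
  expect_equal(nrow(bundle$truth_key), sum(world$capture$in_A & world$capture$in_B))
  expect_equal(nrow(bundle$a), sum(world$capture$in_A))
  expect_equal(nrow(bundle$b), sum(world$capture$in_B))
  expect_equal(anyDuplicated(bundle$truth_key$record_id_A), 0)
  expect_equal(anyDuplicated(bundle$truth_key$record_id_B), 0)
})

test_that("the default world draws an overlap consistent with its margins", {
  world <- generate_world(generator_config(seed = 20170101))
  m <- sum(world$capture$in_A & world$capture$in_B)
  # central 99.99% binomial interval around 600 * 0.275 * 0.205
  expect_gte(m, qbinom(5e-5, 600, 0.275 * 0.205))
  expect_lte(m, qbinom(1 - 5e-5, 600, 0.275 * 0.205))
})

test_that("date jitter is bounded by its configured magnitude", {
  cfg <- generator_config(n_true = 150, p1 = 1, p2 = 1, seed = 5,
                          date_jitter_prob = 1, date_jitter_max_days = 2,
                          location_missing_prob = 0, location_coarsen_prob = 0,
                          name_perturb_prob = 0)
  world <- generate_world(cfg)
  bundle <- synthesize_datasets(world)
  latent_dates <- world$latent$event_date[
    match(bundle$truth_key$latent_event_id, world$latent$latent_event_id)]
  b_dates <- bundle$b$event_date[
    match(bundle$truth_key$record_id_B, bundle$b$record_id)]
  gap <- abs(as.integer(b_dates) - as.integer(latent_dates))
  expect_true(all(gap >= 1 & gap <= 2))
})

test_that("planted duplicates are found by the deduplication rule", {
  cfg <- generator_config(n_true = 120, p1 = 1, p2 = 1, seed = 9,
                          entity_present_prob = 1,
                          date_jitter_prob = 0, location_missing_prob = 0,
                          location_coarsen_prob = 0, name_perturb_prob = 0,
                          duplicate_plant_count = 3)
  bundle <- synthesize_datasets(generate_world(cfg))
  groups <- find_duplicates(bundle$a)
  expect_gte(nrow(groups), 3)
  expect_equal(sum(grepl("-dup$", unlist(groups$record_ids))), 3)
})

test_that("contaminants carry the attributes that exclude them", {
  cfg <- generator_config(n_true = 100, seed = 13,
                          contam_non_whe = 0.2, contam_definition = 0.2,
                          contam_aggregated = 0.2)
  bundle <- synthesize_datasets(generate_world(cfg))
  extra <- bundle$a[grepl("^AC", bundle$a$record_id), ]
  expect_gt(nrow(extra), 0)
  status <- country_status(extra$country)
  excludable <- status == "non_whe" | !extra$meets_definition |
    extra$is_aggregated_report
  expect_true(all(excludable))
})

test_that("a fixed seed makes the generator byte-reproducible", {
  cfg <- generator_config(n_true = 80, seed = 123)
  b1 <- synthesize_datasets(generate_world(cfg))
  b2 <- synthesize_datasets(generate_world(cfg))
  expect_identical(b1$a, b2$a)
  expect_identical(b1$b, b2$b)
  expect_identical(b1$truth_key, b2$truth_key)
  b3 <- synthesize_datasets(generate_world(generator_config(n_true = 80, seed = 124)))
  expect_false(identical(b1$a, b3$a))
})

test_that("generator configuration rejects invalid probabilities", {
  expect_error(generator_config(p1 = 0), "p1")
  expect_error(generator_config(date_jitter_prob = 1.5), "probabilities")
  expect_error(generator_config(dependence_or = -1))
})

test_that("the dataset bundle writes valid, re-readable files", {
  dir <- tempfile("synth-")
  synthesize_datasets(generate_world(generator_config(n_true = 30, seed = 2)),
                      out_dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("events_a.csv", "events_b.csv", "truth_key.csv", "manifest.json")))))
  a <- suppressMessages(read_events(file.path(dir, "events_a.csv")))
  expect_gt(nrow(a), 0)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$n_true, 30)
  expect_equal(manifest$n_records_a, nrow(a))
})
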