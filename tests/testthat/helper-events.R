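# Build normalised event records from compact arguments; vectors recycle.
ev <- function(record_id, source = "A", country = "Iraq",
               event_date = "2017-03-01", location_name = NA_character_,
               entity_name = NA_character_, attack_type = "facility",
               setting = NA_character_, named_actor = NA_character_,
               meets_definition = "true", is_aggregated_report = "false",
               description = NA_character_) {
  normalize_events(tibble::tibble(
    record_id = as.character(record_id),
    source = source,
    country = country,
    event_date = event_date,
    location_name = location_name,
    entity_name = entity_name,
    attack_type = attack_type,
    setting = setting,
    named_actor = named_actor,
    meets_definition = meets_definition,
    is_aggregated_report = is_aggregated_report,
    description = description
  ))
}

# Cache the constructed fixture and its pipeline run: both are deterministic
# and several test files assert against them.
.cache <- new.env(parent = emptyenv())

fixture_bundle <- function() {
  if (is.null(.cache$bundle)) .cache$bundle <- make_paper_fixture()
  .cache$bundle
}

fixture_run <- function() {
  if (is.null(.cache$run)) {
    dir <- tempfile("fixture-run-")
    make_paper_fixture(out_dir = dir)
    cfg <- run_config(
      path_a = file.path(dir, "events_a.csv"),
      path_b = file.path(dir, "events_b.csv"),
      profile = "replication",
      truth_key_path = file.path(dir, "truth_key.csv")
    )
    .cache$run <- suppressMessages(run_pipeline(cfg))
    .cache$run_dir <- dir
  }
  .cache$run
}

unordered_pairs <- function(linkage) {
  sort(paste(pmin(linkage$matched_pairs$record_id_A,
                  linkage$matched_pairs$record_id_B),
             pmax(linkage$matched_pairs$record_id_A,
                  linkage$matched_pairs$record_id_B)))
}
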