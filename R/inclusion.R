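INCLUSION_REASONS <- c("ok", "duplicate", "country_non_whe", "country_excluded",
                       "definition_not_met", "aggregated_report")

#' Apply the study inclusion criteria
#'
#' Partitions events into included and excluded with one machine-readable
#' reason per record. Checks run in a fixed order — duplicate, country
#' scope, attack definition, aggregated report — and the first failing
#' check is the recorded reason. An event is included when it meets the
#' attack definition, occurred in a WHE country other than the excluded
#' Syrian Arab Republic, is an individually reported (not aggregated)
#' event, and is not a within-source duplicate.
#'
#' @param events Tibble of normalised event records (one source or both).
#' @param registry Country registry from [whe_registry()].
#' @param duplicates Optional character vector of record ids already flagged
#'   as within-source duplicates (e.g. `drop_duplicates()$dropped$record_id`).
#' @return List with `included` (tibble of retained events) and `outcomes`
#'   (tibble `record_id`, `source`, `included`, `reason`).
#' @export
apply_inclusion <- function(events, registry = whe_registry(),
                            duplicates = character()) {
  status <- country_status(events$country, registry)
  reason <- dplyr::case_when(
    events$record_id %in% duplicates ~ "duplicate",
    status == "non_whe" ~ "country_non_whe",
    status == "excluded" ~ "country_excluded",
    !events$meets_definition ~ "definition_not_met",
    events$is_aggregated_report ~ "aggregated_report",
    TRUE ~ "ok"
  )
  outcomes <- tibble::tibble(
    record_id = events$record_id,
    source = events$source,
    included = reason == "ok",
    reason = reason
  )
  list(included = events[outcomes$included, ], outcomes = outcomes)
}

#' Tabulate the inclusion funnel
#'
#' Counts inclusion outcomes by source and reason (the data-preparation
#' funnel: raw counts down to the analysis set). Zero-count reasons are kept
#' so the table shape is stable.
#'
#' @param outcomes Outcomes tibble from [apply_inclusion()] (one or more
#'   sources, row-bound).
#' @return Tibble with columns `source`, `reason`, `n`; per source the `n`
#'   column sums to that source's input size.
#' @export
funnel_counts <- function(outcomes) {
  grid <- tidyr::expand_grid(
    source = if (nrow(outcomes) > 0) sort(unique(outcomes$source)) else character(),
    reason = factor(INCLUSION_REASONS, levels = INCLUSION_REASONS)
  )
  counts <- outcomes |>
    dplyr::count(.data$source, reason = factor(.data$reason, levels = INCLUSION_REASONS))
  dplyr::left_join(grid, counts, by = c("source", "reason")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  reason = as.character(.data$reason))
}

#' Render the funnel as text
#'
#' Human-readable data-preparation summary: raw counts, exclusions by
#' reason, and the final analysis counts per source.
#'
#' @param outcomes Outcomes tibble from [apply_inclusion()].
#' @return Character vector of report lines, invisibly printed-ready.
#' @export
funnel_report <- function(outcomes) {
  fc <- funnel_counts(outcomes)
  lines <- character()
  for (src in unique(fc$source)) {
    sub <- fc[fc$source == src, ]
    total <- sum(sub$n)
    lines <- c(lines, sprintf("Source %s: %d raw record(s)", src, total))
    for (r in setdiff(INCLUSION_REASONS, "ok")) {
      n <- sub$n[sub$reason == r]
      if (n > 0) lines <- c(lines, sprintf("  - excluded (%s): %d", r, n))
    }
    lines <- c(lines, sprintf("  = included: %d", sub$n[sub$reason == "ok"]))
  }
  lines
}
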