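#' Read an event CSV
#'
#' Reads the event CSV dialect (UTF-8, header row, comma-delimited; booleans
#' `true`/`false`; absent values as empty cells), validates the schema and
#' normalises every row via [normalize_events()]. Row order is preserved.
#'
#' @param path Path to a CSV file.
#' @param source Optional source label (`"A"` or `"B"`); when given it
#'   overrides or fills in the file's `source` column.
#' @return A tibble of normalised event records.
#' @export
read_events <- function(path, source = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- setdiff(EVENT_COLUMNS, c("source"))
  if (!is.null(source)) raw$source <- source
  missing_cols <- setdiff(c(required, "source"), names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  events <- normalize_events(raw)
  dup <- events$record_id[duplicated(events$record_id)]
  if (length(dup) > 0) {
    stop("duplicate record_id within ", basename(path), ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  message(nrow(events), " record(s) read from ", basename(path))
  events
}

#' Write events in the event CSV dialect
#'
#' Inverse of [read_events()]: day-precision dates serialise as
#' `YYYY-MM-DD`, month-precision as `YYYY-MM`, unknown dates and absent
#' fields as empty cells, booleans as `true`/`false`.
#'
#' @param events A tibble of normalised event records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- tibble::tibble(
    record_id = events$record_id,
    source = events$source,
    event_date = dplyr::case_when(
      events$date_precision == "day" ~ format(events$event_date, "%Y-%m-%d"),
      events$date_precision == "month" ~ format(events$event_date, "%Y-%m"),
      TRUE ~ ""
    ),
    country = events$country,
    location_name = events$location_name,
    setting = events$setting,
    attack_type = events$attack_type,
    named_actor = events$named_actor,
    entity_name = events$entity_name,
    meets_definition = ifelse(events$meets_definition, "true", "false"),
    is_aggregated_report = ifelse(events$is_aggregated_report, "true", "false"),
    description = events$description
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# union-find used to build maximal duplicate groups
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Detect within-source duplicate reports
#'
#' Two reports of the same source are duplicates when they satisfy the
#' same definite-match rule used across sources (at least two of date,
#' location and entity name agreeing exactly; see [classify_pairs()]).
#' Candidate pairs are blocked by country. Groups are maximal (connected
#' components of the duplicate relation).
#'
#' @param events Tibble of event records sharing one source.
#' @param config Linkage configuration from [linkage_config()].
#' @return Tibble with one row per group: `group` (integer),
#'   `record_ids` (list of ids, sorted), `keep` (lexicographically smallest
#'   id) and `drop` (list of the other ids).
#' @export
find_duplicates <- function(events, config = linkage_config()) {
  if (nrow(events) == 0) return(empty_duplicate_groups())
  if (length(unique(events$source)) > 1) {
    stop("find_duplicates expects records from a single source", call. = FALSE)
  }
  events <- dplyr::arrange(events, .data$record_id)
  n <- nrow(events)
  parent <- seq_len(n)
  for (ctry in unique(events$country)) {
    idx <- which(events$country == ctry)
    if (length(idx) < 2) next
    combos <- utils::combn(idx, 2)
    a <- events[combos[1, ], ]
    b <- events[combos[2, ], ]
    agree <- compare_fields(a, b, config)
    exact2 <- (agree$date_cmp == "exact") + (agree$location_cmp == "exact") +
      (agree$name_cmp == "exact") >= 2
    for (k in which(exact2)) {
      ra <- uf_find(parent, combos[1, k])
      rb <- uf_find(parent, combos[2, k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  groups <- split(events$record_id, root)
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) == 0) return(empty_duplicate_groups())
  groups <- lapply(groups, sort)
  groups <- unname(groups[order(vapply(groups, `[[`, character(1), 1))])
  tibble::tibble(
    group = seq_along(groups),
    record_ids = unname(groups),
    keep = vapply(groups, `[[`, character(1), 1),
    drop = lapply(groups, function(g) g[-1])
  )
}

empty_duplicate_groups <- function() {
  tibble::tibble(group = integer(), record_ids = list(), keep = character(),
                 drop = list())
}

#' Remove within-source duplicates
#'
#' Keeps the lexicographically smallest record id of every duplicate group
#' (a deterministic, order-invariant policy) and drops the rest.
#'
#' @inheritParams find_duplicates
#' @return List with `events` (deduplicated tibble, input order preserved)
#'   and `dropped` (tibble `record_id`, `kept_as` for the audit trail).
#' @export
drop_duplicates <- function(events, config = linkage_config()) {
  groups <- find_duplicates(events, config)
  if (nrow(groups) == 0) {
    return(list(events = events,
                dropped = tibble::tibble(record_id = character(),
                                         kept_as = character())))
  }
  dropped <- tibble::tibble(
    record_id = unlist(groups$drop),
    kept_as = rep(groups$keep, lengths(groups$drop))
  )
  list(events = events[!events$record_id %in% dropped$record_id, ],
       dropped = dropped)
}
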