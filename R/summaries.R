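#' Build the union event set from a finalised linkage
#'
#' One row per distinct event: each matched pair contributes its source-A
#' record once (the pair-level representative), each unique event its own
#' record. A `matched` flag distinguishes the two.
#'
#' @param a,b Included event tibbles for the two sources.
#' @param linkage A finalised `linkage_result` (no pending possibles).
#' @return Tibble of events with an extra `matched` logical column.
#' @export
union_events <- function(a, b, linkage) {
  if (nrow(linkage$pending_possibles) > 0) {
    stop("linkage has pending possible matches; adjudicate first",
         call. = FALSE)
  }
  matched_a <- a[a$record_id %in% linkage$matched_pairs$record_id_A, ]
  uniq_a <- a[a$record_id %in% linkage$unique_A, ]
  uniq_b <- b[b$record_id %in% linkage$unique_B, ]
  dplyr::bind_rows(
    dplyr::mutate(matched_a, matched = TRUE),
    dplyr::mutate(uniq_a, matched = FALSE),
    dplyr::mutate(uniq_b, matched = FALSE)
  )
}

#' Attack-type comparison table
#'
#' Five fixed rows (access/delivery, ambulances, facilities, personnel,
#' patients), with per-source counts and percentages, a total column where
#' each source record counts once (matched events therefore count in both
#' source columns and twice in the total), and the number of matched pairs
#' per row. Matched pairs are tabulated under the source-A record's type;
#' cross-source type conflicts are recorded in the `type_conflicts`
#' attribute. Percentages round half-up to one decimal; denominators are
#' carried in the `denominators` attribute.
#'
#' @param a,b Included event tibbles.
#' @param linkage Finalised `linkage_result`.
#' @return Tibble with columns `attack_type`, `n_A`, `pct_A`, `n_B`,
#'   `pct_B`, `n_total`, `n_matched`, `pct_total`.
#' @export
attack_type_table <- function(a, b, linkage) {
  if (nrow(linkage$pending_possibles) > 0) {
    stop("linkage has pending possible matches; adjudicate first",
         call. = FALSE)
  }
  count_by <- function(events) {
    tab <- table(factor(events$attack_type, levels = ATTACK_TYPES))
    as.integer(tab)
  }
  n_a <- count_by(a)
  n_b <- count_by(b)
  mp <- linkage$matched_pairs
  type_a <- a$attack_type[match(mp$record_id_A, a$record_id)]
  type_b <- b$attack_type[match(mp$record_id_B, b$record_id)]
  n_m <- as.integer(table(factor(type_a, levels = ATTACK_TYPES)))
  conflicts <- tibble::tibble(
    record_id_A = mp$record_id_A, record_id_B = mp$record_id_B,
    type_A = type_a, type_B = type_b
  )[!is.na(type_a) & !is.na(type_b) & type_a != type_b, ]

  denom_a <- max(nrow(a), 1L)
  denom_b <- max(nrow(b), 1L)
  denom_t <- max(nrow(a) + nrow(b), 1L)
  out <- tibble::tibble(
    attack_type = ATTACK_TYPES,
    n_A = n_a,
    pct_A = round_half_up(100 * n_a / denom_a, 1),
    n_B = n_b,
    pct_B = round_half_up(100 * n_b / denom_b, 1),
    n_total = n_a + n_b,
    n_matched = n_m,
    pct_total = round_half_up(100 * (n_a + n_b) / denom_t, 1)
  )
  attr(out, "denominators") <- c(A = nrow(a), B = nrow(b),
                                 total = nrow(a) + nrow(b))
  attr(out, "type_conflicts") <- conflicts
  out
}

#' Country coverage comparison table
#'
#' Per source: the number of countries/territories with any reported event
#' (the excluded Syrian Arab Republic not counted), how many of those fell
#' outside the WHE framework, how many additional WHE countries lost all
#' their events to the definition and aggregation filters, and the number
#' of countries represented in the final included dataset.
#'
#' @param events Raw normalised events for both sources, row-bound.
#' @param outcomes Outcomes tibble from [apply_inclusion()] covering the
#'   same records.
#' @param registry Country registry.
#' @return Tibble with `source`, `reported`, `excluded_non_whe`,
#'   `excluded_by_definition`, `final`.
#' @export
country_table <- function(events, outcomes, registry = whe_registry()) {
  events <- dplyr::left_join(
    events,
    outcomes[, c("record_id", "source", "included", "reason")],
    by = c("record_id", "source")
  )
  events$status <- country_status(events$country, registry)
  per_source <- function(src) {
    ev <- events[events$source == src, ]
    ev_no_syria <- ev[ev$status != "excluded", ]
    reported <- length(unique(ev_no_syria$country))
    non_whe <- length(unique(ev_no_syria$country[ev_no_syria$status == "non_whe"]))
    in_scope <- ev_no_syria[ev_no_syria$status == "in_scope", ]
    final_countries <- unique(in_scope$country[in_scope$included])
    lost <- setdiff(unique(in_scope$country), final_countries)
    tibble::tibble(
      source = src,
      reported = reported,
      excluded_non_whe = non_whe,
      excluded_by_definition = length(lost),
      final = length(final_countries)
    )
  }
  dplyr::bind_rows(lapply(sort(unique(events$source)), per_source))
}

#' Monthly event counts over the union dataset
#'
#' Counts each matched pair once and each unique event once, by calendar
#' month. Events without at least month date precision are reported in the
#' `unknown_n` attribute rather than in the series.
#'
#' @param union A union tibble from [union_events()].
#' @return Tibble with `month` (1-12), `month_name`, `n`; attribute
#'   `unknown_n` holds the count of undated events.
#' @export
monthly_counts <- function(union) {
  dated <- union[union$date_precision != "unknown", ]
  mo <- as.integer(format(dated$event_date, "%m"))
  counts <- as.integer(table(factor(mo, levels = 1:12)))
  out <- tibble::tibble(
    month = 1:12,
    month_name = month.name,
    n = counts
  )
  attr(out, "unknown_n") <- sum(union$date_precision == "unknown")
  out
}

#' Actor and location breakdown
#'
#' Named-actor tallies and location/setting shares with the denominator of
#' every percentage stated explicitly (the study mixes record-level,
#' union-level, unique-event and matched-pair bases):
#' MSF/Red Cross involvement among matched pairs (base: matched pairs) and
#' among unique events (base: unique events); missing specific location,
#' urban and rural settings (base: all included records of both sources);
#' matched pairs located in the country's capital city (base: matched
#' pairs).
#'
#' @param a,b Included event tibbles.
#' @param linkage Finalised `linkage_result`.
#' @param capitals Named vector country -> capital, see [whe_capitals()].
#' @return Tibble with `stat`, `n_A`, `n_B`, `n`, `denom`, `pct`
#'   (percent, rounded half-up to one decimal).
#' @export
actor_location_breakdown <- function(a, b, linkage, capitals = whe_capitals()) {
  un <- union_events(a, b, linkage)
  mp <- linkage$matched_pairs
  m <- nrow(mp)
  uniq <- un[!un$matched, ]
  all_records <- dplyr::bind_rows(a, b)
  n_records <- nrow(all_records)

  matched_a <- a[match(mp$record_id_A, a$record_id), ]
  in_capital <- !is.na(matched_a$location_name) &
    normalize_text(matched_a$location_name) ==
      normalize_text(unname(capitals[matched_a$country]))

  row <- function(stat, n_a, n_b, n, denom) {
    tibble::tibble(stat = stat, n_A = n_a, n_B = n_b, n = n, denom = denom,
                   pct = round_half_up(100 * n / max(denom, 1L), 1))
  }
  dplyr::bind_rows(
    row("matched_msf_redcross", NA_integer_, NA_integer_,
        sum(matched_a$named_actor == "msf_redcross"), m),
    row("unique_msf_redcross",
        sum(uniq$named_actor == "msf_redcross" & uniq$source == "A"),
        sum(uniq$named_actor == "msf_redcross" & uniq$source == "B"),
        sum(uniq$named_actor == "msf_redcross"), nrow(uniq)),
    row("missing_location",
        sum(is.na(a$location_name)), sum(is.na(b$location_name)),
        sum(is.na(all_records$location_name)), n_records),
    row("setting_urban",
        sum(a$setting == "urban"), sum(b$setting == "urban"),
        sum(all_records$setting == "urban"), n_records),
    row("setting_rural",
        sum(a$setting == "rural"), sum(b$setting == "rural"),
        sum(all_records$setting == "rural"), n_records),
    row("setting_unknown",
        sum(a$setting == "unknown"), sum(b$setting == "unknown"),
        sum(all_records$setting == "unknown"), n_records),
    row("matched_capital_city", NA_integer_, NA_integer_,
        sum(in_capital), m)
  )
}
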