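# Constructed two-source fixture emulating the published 2017 comparison.
# Every count is built in, not sampled: raw 264/238 records; 3 planted
# within-source duplicates; country and definition exclusions leaving
# 165/122 included; 29 auto-definite + 16 possible matches of which 4 are
# adjudicated definite (33 matched, union 254); Table-4 attack-type
# marginals; monthly lows of 15 (June, July) and a high of 34 (December);
# actor, location and setting tallies.

fixture_counts <- function() {
  list(
    matched = c(
      "Afghanistan" = 5, "Central African Republic" = 3,
      "Democratic Republic of the Congo" = 5, "Iraq" = 5, "Libya" = 3,
      "Nigeria" = 4, "Pakistan" = 3, "South Sudan" = 3, "Sudan" = 2
    ),
    singles_a = c(
      "Afghanistan" = 14, "Iraq" = 13, "Democratic Republic of the Congo" = 11,
      "South Sudan" = 11, "Nigeria" = 10, "Libya" = 8, "Pakistan" = 8,
      "Central African Republic" = 7, "Sudan" = 6,
      "Yemen" = 8, "Somalia" = 7, "Mali" = 5, "Niger" = 4, "Cameroon" = 4,
      "Chad" = 3, "Burkina Faso" = 3, "Ukraine" = 3, "Colombia" = 2,
      "Bangladesh" = 1, "Egypt" = 1, "Ethiopia" = 1, "Jordan" = 1,
      "Lebanon" = 1
    ),
    singles_b = c(
      "Afghanistan" = 6, "Iraq" = 5, "Democratic Republic of the Congo" = 5,
      "South Sudan" = 4, "Nigeria" = 4, "Libya" = 3, "Pakistan" = 3,
      "Central African Republic" = 3, "Sudan" = 2,
      "Yemen" = 6, "Somalia" = 6, "Mali" = 5, "Niger" = 4, "Cameroon" = 3,
      "Chad" = 3, "Burkina Faso" = 3, "Ukraine" = 3, "Colombia" = 3,
      "Turkey" = 4, "Zimbabwe" = 3, "The Philippines" = 3, "Thailand" = 2,
      "Nepal" = 2, "Papua New Guinea" = 2, "West Bank and Gaza Strip" = 1,
      "The Gambia" = 1
    ),
    decoys = c(
      "Afghanistan" = 2, "Iraq" = 2, "Democratic Republic of the Congo" = 2,
      "South Sudan" = 1, "Nigeria" = 1, "Libya" = 1, "Pakistan" = 1,
      "Central African Republic" = 1, "Sudan" = 1
    ),
    capital_pairs = c(
      "Afghanistan" = 1, "Central African Republic" = 1,
      "Democratic Republic of the Congo" = 1, "Iraq" = 1, "Nigeria" = 1,
      "Pakistan" = 1, "South Sudan" = 1
    ),
    adjudicated_countries = c(
      "Afghanistan", "Democratic Republic of the Congo", "Iraq", "Nigeria"
    ),
    # monthly union-event quotas, January..December
    month_quota = c(21, 21, 21, 21, 21, 15, 15, 21, 21, 21, 22, 34),
    def_fail_a = c(
      "Turkey" = 3,
      "Afghanistan" = 1, "Iraq" = 1, "Democratic Republic of the Congo" = 1,
      "South Sudan" = 1, "Nigeria" = 1, "Libya" = 1, "Pakistan" = 1,
      "Central African Republic" = 1, "Sudan" = 1, "Yemen" = 1,
      "Somalia" = 1, "Mali" = 1, "Niger" = 1
    ),
    def_fail_b = c(
      "Angola" = 5, "Kenya" = 2, "Bangladesh" = 2, "Egypt" = 1,
      "Ethiopia" = 1, "Jordan" = 1,
      "Afghanistan" = 1, "Iraq" = 1, "Democratic Republic of the Congo" = 1,
      "South Sudan" = 1, "Nigeria" = 1, "Libya" = 1, "Pakistan" = 1,
      "Central African Republic" = 1, "Sudan" = 1, "Yemen" = 1,
      "Somalia" = 1, "Mali" = 1, "Niger" = 1, "Cameroon" = 1, "Chad" = 1,
      "Burkina Faso" = 1, "Ukraine" = 1, "Colombia" = 1, "Turkey" = 1,
      "Zimbabwe" = 1, "The Philippines" = 1, "Thailand" = 1
    ),
    syria_a = 30, syria_b = 25,
    non_whe_a = c(
      "France" = 4, "India" = 4, "Brazil" = 4, "Mexico" = 4,
      "Venezuela" = 4, "South Africa" = 4, "Russia" = 4,
      "United States" = 4, "Israel" = 4, "Greece" = 4, "Italy" = 4,
      "Uganda" = 4, "Burundi" = 3
    ),
    non_whe_b = c(
      "France" = 3, "India" = 3, "Brazil" = 3, "Mexico" = 3,
      "Venezuela" = 3, "South Africa" = 3, "Russia" = 2,
      "United States" = 2, "Israel" = 2, "Greece" = 2, "Italy" = 2,
      "Uganda" = 2, "Burundi" = 2, "Germany" = 2, "Spain" = 2,
      "United Kingdom" = 2, "Canada" = 2, "Australia" = 2, "Japan" = 2,
      "Vietnam" = 2, "Cambodia" = 2, "Malaysia" = 2, "Peru" = 2,
      "Bolivia" = 2, "Argentina" = 2
    )
  )
}

# stateful per-country date allocator: 7 day-slots per month (days 1, 5,
# ..., 25, so any two distinct slots are more than 2 days apart), with an
# optional global monthly quota for analysis-set events
new_date_allocator <- function(month_quota) {
  env <- new.env(parent = emptyenv())
  env$quota <- month_quota
  env$slots <- list()
  slot_count <- function(country, month) {
    env$slots[[paste(country, month)]] %||% 0L
  }
  take_slot <- function(country, month) {
    key <- paste(country, month)
    used <- env$slots[[key]] %||% 0L
    env$slots[[key]] <- used + 1L
    as.Date(sprintf("2017-%02d-%02d", month, 1L + 4L * used))
  }
  list(
    # consume `units` of one month's quota (1 for a lone event, 2 for a
    # decoy pair sharing a date) and return the date
    quota_date = function(country, units = 1L) {
      ord <- order(-env$quota, seq_along(env$quota))
      for (mo in ord) {
        if (env$quota[mo] >= units && slot_count(country, mo) < 7L) {
          env$quota[mo] <- env$quota[mo] - units
          return(take_slot(country, mo))
        }
      }
      stop("date allocator exhausted for ", country, call. = FALSE)
    },
    free_date = function(country) {
      for (mo in 1:12) {
        if (slot_count(country, mo) < 7L) return(take_slot(country, mo))
      }
      stop("date allocator exhausted for ", country, call. = FALSE)
    },
    remaining_quota = function() env$quota
  )
}

fixture_record <- function(record_id, source, event_date, country,
                           location_name, setting, attack_type, named_actor,
                           entity_name, meets_definition = TRUE,
                           description = "reported attack on health care") {
  tibble::tibble(
    record_id = record_id, source = source,
    event_date = event_date, date_precision = "day",
    country = country, location_name = location_name, setting = setting,
    attack_type = attack_type, named_actor = named_actor,
    entity_name = entity_name, meets_definition = meets_definition,
    is_aggregated_report = FALSE, description = description
  )
}

#' Construct the paper-emulation fixture
#'
#' Builds two deterministic event datasets that, run through the default
#' replication pipeline, reproduce the published comparison: raw counts
#' 264 and 238; three within-source duplicates; 16 and 34
#' definition-criteria exclusions; 165 and 122 included events; 29
#' automatic definite matches plus 16 possible matches of which
#' adjudication confirms 4 (33 matched, union 254, overlap 12.9%); the
#' attack-type marginals; monthly lows of 15 in June and July and a high
#' of 34 in December; and the actor, location and setting tallies. The
#' fixture is constructed, not sampled: it is a regression surface
#' emulating the published aggregates, not the underlying records.
#'
#' @param out_dir Optional directory; when given, writes `events_a.csv`,
#'   `events_b.csv`, `truth_key.csv` and `manifest.json`.
#' @return List with `a`, `b`, `truth_key`, `manifest`.
#' @export
make_paper_fixture <- function(out_dir = NULL) {
  fc <- fixture_counts()
  alloc <- new_date_allocator(fc$month_quota)
  adjudicated_words <- c(
    "Afghanistan" = "Kandovar",
    "Democratic Republic of the Congo" = "Mirbazar",
    "Iraq" = "Telkoram", "Nigeria" = "Zhobrani"
  )

  # per-country counters into the shared location word pool
  loc_counter <- new.env(parent = emptyenv())
  next_location <- function(country) {
    used <- loc_counter[[country]] %||% 0L
    loc_counter[[country]] <- used + 1L
    LOC_WORDS[used %% length(LOC_WORDS) + 1L]
  }

  ## ---- matched pairs -------------------------------------------------
  m_country <- rep(names(fc$matched), fc$matched)
  n_m <- length(m_country)
  within <- stats::ave(seq_len(n_m), m_country, FUN = seq_along)
  cap_quota <- fc$capital_pairs[m_country]
  cap_quota[is.na(cap_quota)] <- 0
  is_capital <- within <= cap_quota
  last_of_country <- within == stats::ave(within, m_country, FUN = max)
  is_adjudicated <- m_country %in% fc$adjudicated_countries & last_of_country
  m_type <- rep(c("ambulance", "facility", "personnel", "patient"),
                c(3, 9, 19, 2))
  m_actor <- rep(c("msf_redcross", "other", "none"), c(9, 3, 21))
  m_date <- as.Date(unname(vapply(m_country, function(ctry) {
    as.numeric(alloc$quota_date(ctry))
  }, numeric(1))), origin = "1970-01-01")
  m_loc_a <- character(n_m)
  m_loc_b <- character(n_m)
  for (i in seq_len(n_m)) {
    if (is_adjudicated[i]) {
      w <- adjudicated_words[[m_country[i]]]
      m_loc_a[i] <- paste(w, "City")
      m_loc_b[i] <- w
    } else if (is_capital[i]) {
      m_loc_a[i] <- m_loc_b[i] <- WHE_CAPITALS[[m_country[i]]]
    } else {
      m_loc_a[i] <- m_loc_b[i] <- next_location(m_country[i])
    }
  }
  m_entity_a <- paste(LOC_WORDS[rev(seq_len(n_m))],
                      FACILITY_TYPES[(within - 1L) %% 5L + 1L])
  m_entity_b <- ifelse(is_adjudicated, NA_character_, m_entity_a)

  matched_a <- fixture_record(
    sprintf("A-%04d", seq_len(n_m)), "A", m_date, m_country, m_loc_a,
    "urban", m_type, m_actor, m_entity_a
  )
  matched_b <- fixture_record(
    sprintf("B-%04d", seq_len(n_m)), "B", m_date, m_country, m_loc_b,
    "urban", m_type, m_actor, m_entity_b
  )
  truth_key <- tibble::tibble(
    record_id_A = matched_a$record_id,
    record_id_B = matched_b$record_id,
    latent_event_id = sprintf("F%03d", seq_len(n_m))
  )

  ## ---- unique (single-source) events ---------------------------------
  build_singles <- function(counts, decoy_counts, type_fill, setting_fill,
                            n_msf) {
    country <- rep(names(counts), counts)
    n <- length(country)
    within <- stats::ave(seq_len(n), country, FUN = seq_along)
    dq <- decoy_counts[country]
    dq[is.na(dq)] <- 0
    tibble::tibble(
      country = country,
      attack_type = rep(names(type_fill), type_fill),
      setting = rep(names(setting_fill), setting_fill),
      named_actor = rep(c("msf_redcross", "none"), c(n_msf, n - n_msf)),
      decoy_key = ifelse(within <= dq, paste(country, within), NA_character_)
    )
  }
  sa <- build_singles(
    fc$singles_a, fc$decoys,
    c(access_delivery = 2, ambulance = 17, facility = 38, personnel = 71,
      patient = 4),
    c(urban = 88, rural = 38, missing = 6), 15
  )
  sb <- build_singles(
    fc$singles_b, fc$decoys,
    c(access_delivery = 29, ambulance = 6, facility = 16, personnel = 34,
      patient = 4),
    c(urban = 45, rural = 10, missing = 34), 14
  )

  # decoy pairs share one allocated date (two union events, one day-slot);
  # every other single gets its own date
  decoy_dates <- new.env(parent = emptyenv())
  assign_dates <- function(df) {
    dates <- rep(as.Date(NA), nrow(df))
    for (i in seq_len(nrow(df))) {
      key <- df$decoy_key[i]
      if (!is.na(key)) {
        if (is.null(decoy_dates[[key]])) {
          decoy_dates[[key]] <- alloc$quota_date(df$country[i], units = 2L)
        }
        dates[i] <- decoy_dates[[key]]
      } else {
        dates[i] <- alloc$quota_date(df$country[i])
      }
    }
    dates
  }
  sa$event_date <- assign_dates(sa)
  sb$event_date <- assign_dates(sb)

  make_single_records <- function(df, source, prefix, id_offset) {
    loc <- vapply(seq_len(nrow(df)), function(i) {
      if (df$setting[i] == "missing") NA_character_
      else next_location(df$country[i])
    }, character(1))
    fixture_record(
      sprintf("%s-%04d", prefix, id_offset + seq_len(nrow(df))), source,
      df$event_date, df$country, loc,
      ifelse(df$setting == "missing", "unknown", df$setting),
      df$attack_type, df$named_actor, NA_character_
    )
  }
  singles_a <- make_single_records(sa, "A", "A", n_m)
  singles_b <- make_single_records(sb, "B", "B", n_m)

  ## ---- excluded records ----------------------------------------------
  build_excluded <- function(counts, source, prefix, id_offset,
                             meets_definition, description) {
    country <- rep(names(counts), counts)
    dates <- as.Date(unname(vapply(country, function(ctry) {
      as.numeric(alloc$free_date(ctry))
    }, numeric(1))), origin = "1970-01-01")
    fixture_record(
      sprintf("%s-%04d", prefix, id_offset + seq_along(country)), source,
      dates, country, NA_character_, "unknown", "facility", "none",
      NA_character_, meets_definition, description
    )
  }
  off_a <- n_m + nrow(singles_a)
  def_a <- build_excluded(fc$def_fail_a, "A", "A", off_a, FALSE,
                          "protest interfering with health services")
  off_a <- off_a + nrow(def_a)
  syr_a <- build_excluded(c("Syrian Arab Republic" = fc$syria_a), "A", "A",
                          off_a, TRUE, "reported attack on health care")
  off_a <- off_a + nrow(syr_a)
  non_a <- build_excluded(fc$non_whe_a, "A", "A", off_a, TRUE,
                          "reported attack outside WHE scope")

  off_b <- n_m + nrow(singles_b)
  def_b <- build_excluded(fc$def_fail_b, "B", "B", off_b, FALSE,
                          "protest interfering with health services")
  off_b <- off_b + nrow(def_b)
  syr_b <- build_excluded(c("Syrian Arab Republic" = fc$syria_b), "B", "B",
                          off_b, TRUE, "reported attack on health care")
  off_b <- off_b + nrow(syr_b)
  non_b <- build_excluded(fc$non_whe_b, "B", "B", off_b, TRUE,
                          "reported attack outside WHE scope")

  ## ---- planted within-source duplicates ------------------------------
  dup_from <- function(rec, new_id) {
    out <- rec
    out$record_id <- new_id
    out$description <- paste(out$description, "(repeat report)")
    out
  }
  dup_a <- dplyr::bind_rows(
    dup_from(singles_a[3, ], "A-9991"),
    dup_from(singles_a[4, ], "A-9992")
  )
  dup_b <- dup_from(singles_b[3, ], "B-9991")

  a <- dplyr::bind_rows(matched_a, singles_a, def_a, syr_a, non_a, dup_a)
  b <- dplyr::bind_rows(matched_b, singles_b, def_b, syr_b, non_b, dup_b)

  stopifnot(nrow(a) == 264, nrow(b) == 238,
            all(alloc$remaining_quota() == 0))

  manifest <- list(
    kind = "constructed_replication_fixture",
    n_records_a = nrow(a), n_records_b = nrow(b),
    planted_duplicates = 3L,
    included_a = 165L, included_b = 122L,
    matched = 33L, auto_definite = 29L, possible = 16L,
    adjudicated_definite = 4L
  )
  out <- list(a = a, b = b, truth_key = truth_key, manifest = manifest)
  if (!is.null(out_dir)) write_dataset_bundle(out, out_dir)
  out
}
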