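#' @importFrom rlang .data
#' @importFrom utils head
NULL

# controlled vocabularies shared by every stage
EVENT_SOURCES <- c("A", "B")
DATE_PRECISIONS <- c("day", "month", "unknown")
SETTINGS <- c("urban", "rural", "unknown")
ATTACK_TYPES <- c("access_delivery", "ambulance", "facility", "personnel", "patient")
NAMED_ACTORS <- c("msf_redcross", "other", "none")

EVENT_COLUMNS <- c(
  "record_id", "source", "event_date", "country", "location_name", "setting",
  "attack_type", "named_actor", "entity_name", "meets_definition",
  "is_aggregated_report", "description"
)

# Table-style layout of the 47 WHE countries/territories by emergency grade.
WHE_TABLE <- list(
  grade3 = c(
    "Iraq", "Nigeria", "South Sudan", "Syrian Arab Republic", "Yemen"
  ),
  grade2 = c(
    "Angola", "Cameroon", "Central African Republic",
    "Democratic Republic of the Congo", "Ecuador", "Ethiopia", "Haiti",
    "Libya", "Myanmar", "Niger", "Ukraine", "United Republic of Tanzania"
  ),
  grade1 = c(
    "Afghanistan", "Bangladesh", "Democratic People's Republic of Korea",
    "Fiji", "Indonesia", "Kenya", "Mali", "Nepal", "Pakistan",
    "Papua New Guinea", "Sri Lanka", "Thailand", "The Philippines",
    "West Bank and Gaza Strip"
  ),
  protracted = c(
    "Burkina Faso", "Chad", "Colombia", "Djibouti", "Egypt", "Guatemala",
    "Honduras", "Jordan", "Lebanon", "Mauritania", "Senegal", "Somalia",
    "Sudan", "The Gambia", "Turkey", "Zimbabwe"
  )
)

# alias -> canonical, keys already in normalize_text() form
COUNTRY_ALIASES <- c(
  "car" = "Central African Republic",
  "central african republic (car)" = "Central African Republic",
  "drc" = "Democratic Republic of the Congo",
  "dr congo" = "Democratic Republic of the Congo",
  "congo-kinshasa" = "Democratic Republic of the Congo",
  "democratic republic of congo" = "Democratic Republic of the Congo",
  "democratic republic of the congo (drc)" = "Democratic Republic of the Congo",
  "dprk" = "Democratic People's Republic of Korea",
  "north korea" = "Democratic People's Republic of Korea",
  "democratic people's republic of korea (dprk)" = "Democratic People's Republic of Korea",
  "tanzania" = "United Republic of Tanzania",
  "philippines" = "The Philippines",
  "gambia" = "The Gambia",
  "syria" = "Syrian Arab Republic",
  "burma" = "Myanmar",
  "turkiye" = "Turkey",
  "palestine" = "West Bank and Gaza Strip",
  "west bank" = "West Bank and Gaza Strip",
  "gaza" = "West Bank and Gaza Strip",
  "gaza strip" = "West Bank and Gaza Strip",
  "occupied palestinian territory" = "West Bank and Gaza Strip",
  "opt" = "West Bank and Gaza Strip",
  "cote d'ivoire" = "Ivory Coast",
  "usa" = "United States",
  "united states of america" = "United States",
  "uk" = "United Kingdom",
  "russian federation" = "Russia",
  "viet nam" = "Vietnam"
)

# countries outside the WHE framework that the canonicaliser recognises;
# needed so out-of-scope events can flow through normalisation and be
# excluded by the country filter rather than rejected as typos
NON_WHE_COUNTRIES <- c(
  "Algeria", "Argentina", "Australia", "Benin", "Bolivia", "Brazil",
  "Burundi", "Cambodia", "Canada", "Chile", "China", "France", "Germany",
  "Ghana", "Greece", "Guinea", "India", "Iran", "Israel", "Italy",
  "Ivory Coast", "Japan", "Liberia", "Malawi", "Malaysia", "Mexico",
  "Morocco", "Mozambique", "Peru", "Russia", "Rwanda", "Saudi Arabia",
  "Sierra Leone", "South Africa", "Spain", "Togo", "Tunisia", "Uganda",
  "United Kingdom", "United States", "Venezuela", "Vietnam", "Zambia"
)

WHE_CAPITALS <- c(
  "Iraq" = "Baghdad", "Nigeria" = "Abuja", "South Sudan" = "Juba",
  "Syrian Arab Republic" = "Damascus", "Yemen" = "Sanaa",
  "Angola" = "Luanda", "Cameroon" = "Yaounde",
  "Central African Republic" = "Bangui",
  "Democratic Republic of the Congo" = "Kinshasa", "Ecuador" = "Quito",
  "Ethiopia" = "Addis Ababa", "Haiti" = "Port-au-Prince",
  "Libya" = "Tripoli", "Myanmar" = "Naypyidaw", "Niger" = "Niamey",
  "Ukraine" = "Kyiv", "United Republic of Tanzania" = "Dodoma",
  "Afghanistan" = "Kabul", "Bangladesh" = "Dhaka",
  "Democratic People's Republic of Korea" = "Pyongyang", "Fiji" = "Suva",
  "Indonesia" = "Jakarta", "Kenya" = "Nairobi", "Mali" = "Bamako",
  "Nepal" = "Kathmandu", "Pakistan" = "Islamabad",
  "Papua New Guinea" = "Port Moresby", "Sri Lanka" = "Colombo",
  "Thailand" = "Bangkok", "The Philippines" = "Manila",
  "West Bank and Gaza Strip" = "Ramallah", "Burkina Faso" = "Ouagadougou",
  "Chad" = "N'Djamena", "Colombia" = "Bogota", "Djibouti" = "Djibouti",
  "Egypt" = "Cairo", "Guatemala" = "Guatemala City",
  "Honduras" = "Tegucigalpa", "Jordan" = "Amman", "Lebanon" = "Beirut",
  "Mauritania" = "Nouakchott", "Senegal" = "Dakar",
  "Somalia" = "Mogadishu", "Sudan" = "Khartoum", "The Gambia" = "Banjul",
  "Turkey" = "Ankara", "Zimbabwe" = "Harare"
)

#' WHE country registry
#'
#' The 47 countries and territories under the WHO Health Emergencies
#' framework (2016 grading) that define the study's geographic scope, with
#' their emergency grade. The Syrian Arab Republic is listed but excluded
#' from analysis: its reports were too incomplete to deduplicate or match
#' reliably.
#'
#' @return A tibble with columns `country` and `grade`
#'   (`grade3`, `grade2`, `grade1`, `protracted`), 47 rows, plus an
#'   `excluded` attribute holding the excluded country names.
#' @export
#' @examples
#' reg <- whe_registry()
#' nrow(reg) # 47
whe_registry <- function() {
  reg <- tibble::tibble(
    country = unlist(WHE_TABLE, use.names = FALSE),
    grade = rep(names(WHE_TABLE), lengths(WHE_TABLE))
  )
  attr(reg, "excluded") <- "Syrian Arab Republic"
  reg
}

#' Capital cities of the WHE countries
#'
#' Used by the location breakdown to flag events reported in a country's
#' capital. One entry per WHE country except the excluded Syrian Arab
#' Republic's is still present for completeness.
#'
#' @return Named character vector: country name -> capital city.
#' @export
whe_capitals <- function() WHE_CAPITALS

#' Canonicalise country names
#'
#' Maps free-text country names (including common abbreviations such as
#' "DRC", "CAR", "DPRK") to the canonical registry spelling. Recognised
#' non-WHE countries pass through so the inclusion stage can exclude them
#' with an explicit reason.
#'
#' @param x Character vector of country names.
#' @param record_id Optional character vector of record ids, used in error
#'   messages for unrecognised names.
#' @return Character vector of canonical names.
#' @export
canonical_country <- function(x, record_id = NULL) {
  known <- c(unlist(WHE_TABLE, use.names = FALSE), NON_WHE_COUNTRIES)
  lookup <- stats::setNames(known, normalize_text(known))
  lookup <- c(lookup, COUNTRY_ALIASES)
  key <- normalize_text(x)
  out <- unname(lookup[key])
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    ids <- if (is.null(record_id)) paste0("row ", bad) else record_id[bad]
    stop(
      "unrecognised country name(s): ",
      paste0(sprintf("'%s' (%s)", x[head(bad, 5)], head(ids, 5)), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' Scope status of a country under the WHE registry
#'
#' @param country Character vector of canonical country names.
#' @param registry A registry from [whe_registry()].
#' @return Character vector: `"in_scope"` for listed, non-excluded
#'   countries; `"excluded"` for listed-but-excluded (Syria); `"non_whe"`
#'   otherwise.
#' @export
#' @examples
#' country_status(c("Iraq", "Syrian Arab Republic", "France"))
country_status <- function(country, registry = whe_registry()) {
  excluded <- attr(registry, "excluded") %||% character()
  dplyr::case_when(
    country %in% excluded ~ "excluded",
    country %in% registry$country ~ "in_scope",
    TRUE ~ "non_whe"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  x
}

parse_event_date <- function(x) {
  x <- blank_to_na(x)
  n <- length(x)
  date <- as.Date(rep(NA, n))
  precision <- rep("unknown", n)
  for (i in seq_len(n)) {
    s <- x[[i]]
    if (is.na(s)) next
    s <- trimws(s)
    d <- NA
    # day-precision formats
    for (fmt in c("%Y-%m-%d", "%d %b %Y", "%d %B %Y", "%d/%m/%Y", "%b %d, %Y")) {
      d <- as.Date(s, format = fmt)
      if (!is.na(d)) break
    }
    if (!is.na(d)) {
      date[i] <- d
      precision[i] <- "day"
      next
    }
    # month-precision formats store the first of the month
    if (grepl("^\\d{4}-\\d{2}$", s)) {
      d <- as.Date(paste0(s, "-01"))
    } else {
      d <- as.Date(paste("01", s), format = "%d %b %Y")
      if (is.na(d)) d <- as.Date(paste("01", s), format = "%d %B %Y")
    }
    if (!is.na(d)) {
      date[i] <- d
      precision[i] <- "month"
    }
  }
  list(date = date, precision = precision)
}

#' Normalise raw event rows into the event-record schema
#'
#' Parses dates (day or month precision), canonicalises country names via
#' the alias table, converts blank cells to missing values and validates the
#' controlled vocabularies. Unparseable dates are kept with
#' `date_precision = "unknown"` and a warning; unrecognised countries are an
#' error naming the offending record.
#'
#' @param raw A data frame with at least `record_id`, `source` and
#'   `country` columns; other schema columns are optional and default to
#'   absent / `unknown` / sensible flags.
#' @return A tibble of normalised event records (one row per report).
#' @export
normalize_events <- function(raw) {
  raw <- tibble::as_tibble(raw)
  required <- c("record_id", "source", "country")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(raw)
  col <- function(name, default = NA_character_) {
    if (name %in% names(raw)) blank_to_na(raw[[name]]) else rep(default, n)
  }
  record_id <- as.character(raw$record_id)
  if (anyNA(record_id) || any(trimws(record_id) == "")) {
    stop("record_id must be present for every row", call. = FALSE)
  }
  source <- as.character(raw$source)
  if (!all(source %in% EVENT_SOURCES)) {
    stop("source must be one of: ", paste(EVENT_SOURCES, collapse = ", "),
         call. = FALSE)
  }

  parsed <- parse_event_date(col("event_date"))
  raw_date <- col("event_date")
  unparsed <- which(!is.na(raw_date) & parsed$precision == "unknown")
  if (length(unparsed) > 0) {
    warning("unparseable event_date for record(s): ",
            paste(head(record_id[unparsed], 5), collapse = ", "),
            "; kept with date_precision = 'unknown'", call. = FALSE)
  }

  setting <- col("setting", "unknown")
  setting[is.na(setting)] <- "unknown"
  if (!all(setting %in% SETTINGS)) {
    stop("setting must be one of: ", paste(SETTINGS, collapse = ", "),
         call. = FALSE)
  }
  attack_type <- col("attack_type")
  if (anyNA(attack_type) || !all(attack_type %in% ATTACK_TYPES)) {
    stop("attack_type must be one of: ", paste(ATTACK_TYPES, collapse = ", "),
         call. = FALSE)
  }
  named_actor <- col("named_actor", "none")
  named_actor[is.na(named_actor)] <- "none"
  if (!all(named_actor %in% NAMED_ACTORS)) {
    stop("named_actor must be one of: ", paste(NAMED_ACTORS, collapse = ", "),
         call. = FALSE)
  }
  as_flag <- function(x, default) {
    x <- blank_to_na(as.character(x))
    out <- rep(default, n)
    out[!is.na(x)] <- tolower(x[!is.na(x)]) %in% c("true", "t", "1", "yes")
    out
  }

  tibble::tibble(
    record_id = record_id,
    source = source,
    event_date = parsed$date,
    date_precision = parsed$precision,
    country = canonical_country(col("country"), record_id),
    location_name = col("location_name"),
    setting = setting,
    attack_type = attack_type,
    named_actor = named_actor,
    entity_name = col("entity_name"),
    meets_definition = if ("meets_definition" %in% names(raw)) {
      as_flag(raw$meets_definition, TRUE)
    } else rep(TRUE, n),
    is_aggregated_report = if ("is_aggregated_report" %in% names(raw)) {
      as_flag(raw$is_aggregated_report, FALSE)
    } else rep(FALSE, n),
    description = col("description")
  )
}
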