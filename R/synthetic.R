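# shared vocabulary for synthetic place / facility names; names are chosen
# to be mutually dissimilar under Jaro-Winkler at the default 0.90 threshold
LOC_WORDS <- c(
  "Abrizan", "Belkodu", "Chamrel", "Dovizzo", "Erkuna", "Fitoro",
  "Gazmite", "Hurlan", "Imzadi", "Jokhar", "Kelvasu", "Lumbezi",
  "Mintaka", "Norvand", "Opalti", "Pruzhen", "Quibala", "Rostevi",
  "Sablun", "Tergova", "Uvindi", "Vostran", "Welkara", "Xandipo",
  "Yerbun", "Zametti", "Ashgoro", "Brunte", "Caldozi", "Drivena",
  "Ekvato", "Fromasi", "Gilderu", "Hoztavi", "Irkella", "Jupanzi",
  "Kratovu", "Lendisha", "Movrater", "Nubliza", "Ostewin", "Panduri",
  "Quarzela", "Rivlano", "Stokhadi", "Trevundi", "Umgatti", "Vilkoro",
  "Wradben", "Xilophar", "Yuvandel", "Zorbetti", "Amtrevi", "Bindokar",
  "Cezvanu", "Dulopera", "Evkario", "Fandrosi", "Guzmelit", "Hivralta",
  "Ikorzade", "Jaglenu", "Krovessi", "Lantovu"
)
FACILITY_TYPES <- c("Hospital", "Clinic", "Health Centre", "Dispensary",
                    "Medical Post")

#' Configuration for the synthetic two-source world
#'
#' Describes a latent universe of attack events observed by two imperfect
#' lists. Defaults reflect the observed study conditions: a universe of 600
#' events with capture probabilities 0.275 and 0.205 reproduces, in
#' expectation, list sizes of about 165 and 122 with an overlap near 34.
#'
#' @param n_true Number of latent events.
#' @param p1,p2 Marginal capture probabilities of lists A and B.
#' @param dependence_or Odds ratio tilting joint capture (1 = independent
#'   lists; >1 = positive list dependence).
#' @param country_weights Named numeric vector of sampling weights over
#'   in-scope countries; default is a rank-1/k profile over the WHE
#'   registry minus the excluded Syrian Arab Republic (events concentrate
#'   in a few crisis countries, as in real surveillance data).
#' @param attack_type_weights,named_actor_weights,setting_weights Named
#'   weights over the controlled vocabularies.
#' @param entity_present_prob Probability a record carries a facility or
#'   victim name.
#' @param date_jitter_prob,date_jitter_max_days Probability and magnitude
#'   of calendar-day jitter applied to list-B dates.
#' @param location_missing_prob,location_coarsen_prob Probability that a
#'   list-B location is dropped, or coarsened to a district-level name.
#' @param name_perturb_prob Probability of a typographic perturbation of a
#'   list-B entity name.
#' @param contam_non_whe,contam_definition,contam_aggregated Contamination
#'   rates (per latent event, per source): out-of-scope countries,
#'   definition-failing events (protests), aggregated reports.
#' @param duplicate_plant_count Planted within-source duplicates per source.
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return A list with class `"generator_config"`.
#' @export
generator_config <- function(n_true = 600, p1 = 0.275, p2 = 0.205,
                             dependence_or = 1,
                             country_weights = NULL,
                             attack_type_weights = c(
                               access_delivery = 0.11, ambulance = 0.10,
                               facility = 0.25, personnel = 0.50,
                               patient = 0.04),
                             named_actor_weights = c(
                               msf_redcross = 0.13, other = 0.10, none = 0.77),
                             setting_weights = c(
                               urban = 0.70, rural = 0.17, unknown = 0.13),
                             entity_present_prob = 0.7,
                             date_jitter_prob = 0.3, date_jitter_max_days = 1,
                             location_missing_prob = 0.1,
                             location_coarsen_prob = 0.2,
                             name_perturb_prob = 0.2,
                             contam_non_whe = 0, contam_definition = 0,
                             contam_aggregated = 0,
                             duplicate_plant_count = 0, seed = 1L) {
  stopifnot(n_true >= 1, p1 > 0, p1 <= 1, p2 > 0, p2 <= 1, dependence_or > 0)
  probs <- c(date_jitter_prob, location_missing_prob, location_coarsen_prob,
             name_perturb_prob, contam_non_whe, contam_definition,
             contam_aggregated, entity_present_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(country_weights)) {
    reg <- whe_registry()
    in_scope <- setdiff(reg$country, attr(reg, "excluded"))
    country_weights <- stats::setNames(1 / seq_along(in_scope), in_scope)
  }
  structure(
    list(n_true = n_true, p1 = p1, p2 = p2, dependence_or = dependence_or,
         country_weights = country_weights,
         attack_type_weights = attack_type_weights,
         named_actor_weights = named_actor_weights,
         setting_weights = setting_weights,
         entity_present_prob = entity_present_prob,
         date_jitter_prob = date_jitter_prob,
         date_jitter_max_days = date_jitter_max_days,
         location_missing_prob = location_missing_prob,
         location_coarsen_prob = location_coarsen_prob,
         name_perturb_prob = name_perturb_prob,
         contam_non_whe = contam_non_whe,
         contam_definition = contam_definition,
         contam_aggregated = contam_aggregated,
         duplicate_plant_count = duplicate_plant_count,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# joint capture probability P(in both lists) at margins p1, p2 and a given
# odds ratio; OR = 1 reduces to independence p1 * p2
joint_capture_prob <- function(p1, p2, or) {
  if (abs(or - 1) < 1e-12) return(p1 * p2)
  a <- or - 1
  b <- -(a * (p1 + p2) + 1)
  c0 <- or * p1 * p2
  disc <- b^2 - 4 * a * c0
  p11 <- (-b - sqrt(disc)) / (2 * a)
  lo <- max(0, p1 + p2 - 1)
  hi <- min(p1, p2)
  min(max(p11, lo), hi)
}

#' Generate a latent event universe with two capture indicators
#'
#' Draws `n_true` latent attack events (country, date in 2017, location,
#' setting, attack type, actor, entity name) and, per event, a pair of
#' capture indicators with the configured margins and odds-ratio
#' dependence. Latent events are guaranteed distinct on
#' (country, date, location), so a noise-free world is perfectly linkable.
#'
#' @param config A [generator_config()].
#' @return List of class `"synthetic_world"` with `latent` (tibble),
#'   `capture` (tibble `latent_event_id`, `in_A`, `in_B`), `config`, and a
#'   derived `noise_seed` consumed by [synthesize_datasets()].
#' @export
generate_world <- function(config = generator_config()) {
  set.seed(config$seed)
  n <- config$n_true
  cw <- config$country_weights
  latent <- tibble::tibble(
    latent_event_id = sprintf("L%05d", seq_len(n)),
    country = sample(names(cw), n, replace = TRUE, prob = cw),
    event_date = as.Date("2017-01-01") + sample(0:364, n, replace = TRUE),
    location_name = sample(LOC_WORDS, n, replace = TRUE),
    setting = sample(names(config$setting_weights), n, replace = TRUE,
                     prob = config$setting_weights),
    attack_type = sample(names(config$attack_type_weights), n, replace = TRUE,
                         prob = config$attack_type_weights),
    named_actor = sample(names(config$named_actor_weights), n, replace = TRUE,
                         prob = config$named_actor_weights),
    entity_name = ifelse(
      stats::runif(n) < config$entity_present_prob,
      paste(sample(LOC_WORDS, n, replace = TRUE),
            sample(FACILITY_TYPES, n, replace = TRUE)),
      NA_character_
    )
  )
  # resample dates/locations until (country, date, location) is unique
  for (iter in 1:100) {
    key <- paste(latent$country, latent$event_date, latent$location_name)
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    dup <- dup & duplicated(key)
    if (!any(dup)) break
    k <- sum(dup)
    latent$event_date[dup] <- as.Date("2017-01-01") + sample(0:364, k, replace = TRUE)
    latent$location_name[dup] <- sample(LOC_WORDS, k, replace = TRUE)
  }
  p11 <- joint_capture_prob(config$p1, config$p2, config$dependence_or)
  cell <- sample(1:4, n, replace = TRUE,
                 prob = c(p11, config$p1 - p11, config$p2 - p11,
                          1 - config$p1 - config$p2 + p11))
  structure(
    list(
      latent = latent,
      capture = tibble::tibble(
        latent_event_id = latent$latent_event_id,
        in_A = cell %in% c(1L, 2L),
        in_B = cell %in% c(1L, 3L)
      ),
      config = config,
      noise_seed = sample.int(.Machine$integer.max, 1)
    ),
    class = "synthetic_world"
  )
}

jitter_dates <- function(dates, prob, max_days) {
  n <- length(dates)
  hit <- stats::runif(n) < prob & max_days > 0
  shift <- sample(c(-max_days:-1, 1:max_days), n, replace = TRUE)
  dates[hit] <- dates[hit] + shift[hit]
  dates
}

perturb_name <- function(x, prob) {
  hit <- which(!is.na(x) & stats::runif(length(x)) < prob)
  for (i in hit) {
    chars <- strsplit(x[i], "", fixed = TRUE)[[1]]
    if (stats::runif(1) < 0.5 && grepl(" ", x[i], fixed = TRUE)) {
      # token drop
      tokens <- strsplit(x[i], " ", fixed = TRUE)[[1]]
      x[i] <- paste(tokens[-length(tokens)], collapse = " ")
    } else {
      # single-character substitution
      j <- sample(length(chars), 1)
      chars[j] <- sample(letters, 1)
      x[i] <- paste(chars, collapse = "")
    }
  }
  x
}

latent_to_records <- function(latent, ids, source) {
  tibble::tibble(
    record_id = ids,
    source = source,
    event_date = latent$event_date,
    date_precision = "day",
    country = latent$country,
    location_name = latent$location_name,
    setting = latent$setting,
    attack_type = latent$attack_type,
    named_actor = latent$named_actor,
    entity_name = latent$entity_name,
    meets_definition = TRUE,
    is_aggregated_report = FALSE,
    description = paste("reported attack on health care,",
                        latent$attack_type, "in", latent$country)
  )
}

make_contaminants <- function(n_true, config, source, prefix) {
  draw <- function(rate) stats::rbinom(1, n_true, rate)
  n_non <- draw(config$contam_non_whe)
  n_def <- draw(config$contam_definition)
  n_agg <- draw(config$contam_aggregated)
  total <- n_non + n_def + n_agg
  if (total == 0) return(NULL)
  reg <- whe_registry()
  in_scope <- setdiff(reg$country, attr(reg, "excluded"))
  tibble::tibble(
    record_id = sprintf("%s%04d", prefix, seq_len(total)),
    source = source,
    event_date = as.Date("2017-01-01") + sample(0:364, total, replace = TRUE),
    date_precision = "day",
    country = c(sample(NON_WHE_COUNTRIES, n_non, replace = TRUE),
                sample(in_scope, n_def + n_agg, replace = TRUE)),
    location_name = sample(LOC_WORDS, total, replace = TRUE),
    setting = "urban",
    attack_type = sample(ATTACK_TYPES, total, replace = TRUE),
    named_actor = "none",
    entity_name = NA_character_,
    meets_definition = rep(c(TRUE, FALSE, TRUE), c(n_non, n_def, n_agg)),
    is_aggregated_report = rep(c(FALSE, FALSE, TRUE), c(n_non, n_def, n_agg)),
    description = rep(c("out-of-scope event", "protest event",
                        "aggregated report of several attacks"),
                      c(n_non, n_def, n_agg))
  )
}

plant_duplicates <- function(records, k) {
  eligible <- which(!is.na(records$location_name))
  k <- min(k, length(eligible))
  if (k == 0) return(NULL)
  picks <- sort(sample(eligible, k))
  dup <- records[picks, ]
  dup$record_id <- paste0(dup$record_id, "-dup")
  dup$description <- paste(dup$description, "(repeat report)")
  dup
}

#' Materialise the two observed datasets from a synthetic world
#'
#' Applies reporting noise to the list-B records (date jitter, location
#' coarsening to "Central District" or loss, typographic name
#' perturbation), appends contaminant events and planted duplicates per
#' the configuration, and returns (optionally writing) the two event
#' tables, the ground-truth match key and a manifest.
#'
#' @param world A `synthetic_world` from [generate_world()].
#' @param out_dir Optional directory; when given, writes
#'   `events_a.csv`, `events_b.csv`, `truth_key.csv`, `manifest.json`.
#' @return List with `a`, `b` (event tibbles), `truth_key` (tibble
#'   `record_id_A`, `record_id_B`, `latent_event_id`) and `manifest`.
#' @export
synthesize_datasets <- function(world, out_dir = NULL) {
  set.seed(world$noise_seed %% .Machine$integer.max)
  config <- world$config
  latent <- world$latent
  cap <- world$capture

  lat_a <- latent[cap$in_A, ]
  lat_b <- latent[cap$in_B, ]
  a <- latent_to_records(lat_a, sprintf("A%05d", seq_len(nrow(lat_a))), "A")
  b <- latent_to_records(lat_b, sprintf("B%05d", seq_len(nrow(lat_b))), "B")

  # reporting noise on list B
  b$event_date <- jitter_dates(b$event_date, config$date_jitter_prob,
                               config$date_jitter_max_days)
  nb <- nrow(b)
  u <- stats::runif(nb)
  b$location_name[u < config$location_missing_prob] <- NA_character_
  coarsen <- u >= config$location_missing_prob &
    u < config$location_missing_prob + config$location_coarsen_prob
  b$location_name[coarsen] <- "Central District"
  b$entity_name <- perturb_name(b$entity_name, config$name_perturb_prob)

  truth_key <- tibble::tibble(
    record_id_A = a$record_id[match(latent$latent_event_id[cap$in_A & cap$in_B],
                                    lat_a$latent_event_id)],
    record_id_B = b$record_id[match(latent$latent_event_id[cap$in_A & cap$in_B],
                                    lat_b$latent_event_id)],
    latent_event_id = latent$latent_event_id[cap$in_A & cap$in_B]
  )

  a <- dplyr::bind_rows(a, make_contaminants(config$n_true, config, "A", "AC"),
                        plant_duplicates(a, config$duplicate_plant_count))
  b <- dplyr::bind_rows(b, make_contaminants(config$n_true, config, "B", "BC"),
                        plant_duplicates(b, config$duplicate_plant_count))

  manifest <- list(
    seed = config$seed,
    n_true = config$n_true,
    p1 = config$p1, p2 = config$p2, dependence_or = config$dependence_or,
    n_records_a = nrow(a), n_records_b = nrow(b),
    n_co_captured = nrow(truth_key)
  )
  out <- list(a = a, b = b, truth_key = truth_key, manifest = manifest)
  if (!is.null(out_dir)) write_dataset_bundle(out, out_dir, config)
  out
}

write_dataset_bundle <- function(bundle, out_dir, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_events(bundle$a, file.path(out_dir, "events_a.csv"))
  write_events(bundle$b, file.path(out_dir, "events_b.csv"))
  readr::write_csv(bundle$truth_key, file.path(out_dir, "truth_key.csv"))
  manifest <- bundle$manifest
  if (!is.null(config)) {
    manifest$config <- config[setdiff(names(config), "country_weights")]
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
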