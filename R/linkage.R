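#' Linkage configuration
#'
#' Tolerances for cross-source field comparison. Dates at day precision are
#' approximate within `date_tolerance_days`; location and entity names are
#' approximate when the Jaro-Winkler similarity of their normalised text
#' reaches the respective threshold.
#'
#' @param date_tolerance_days Non-negative integer, default 2.
#' @param name_threshold,location_threshold Similarity thresholds in
#'   `(0, 1]`, default 0.90.
#' @return A list with class `"linkage_config"`.
#' @export
linkage_config <- function(date_tolerance_days = 2, name_threshold = 0.90,
                           location_threshold = 0.90) {
  stopifnot(date_tolerance_days >= 0, name_threshold > 0, name_threshold <= 1,
            location_threshold > 0, location_threshold <= 1)
  structure(
    list(date_tolerance_days = date_tolerance_days,
         name_threshold = name_threshold,
         location_threshold = location_threshold),
    class = "linkage_config"
  )
}

grade_string_field <- function(x, y, threshold) {
  n <- length(x)
  xn <- normalize_text(x)
  yn <- normalize_text(y)
  sim <- rep(NA_real_, n)
  cmp <- rep("unassessable", n)
  ok <- !is.na(xn) & !is.na(yn)
  if (any(ok)) {
    sim[ok] <- jaro_winkler(xn[ok], yn[ok])
    cmp[ok] <- dplyr::case_when(
      xn[ok] == yn[ok] ~ "exact",
      sim[ok] >= threshold ~ "approximate",
      TRUE ~ "none"
    )
  }
  list(cmp = cmp, sim = sim)
}

#' Grade field agreement for record pairs
#'
#' Compares aligned rows of `a` and `b` (row i against row i) on the three
#' identifying fields used for match classification: event date, location
#' and facility/victim name. Each field is graded `exact`, `approximate`,
#' `none`, or `unassessable` when absent on either side.
#'
#' Date grading honours precision: two day-precision dates are exact on the
#' same calendar day and approximate within the tolerance; two
#' month-precision dates are exact only in the same month; a day- and a
#' month-precision date are never exact but approximate within the same
#' month; unknown-precision dates are unassessable.
#'
#' @param a,b Event tibbles with equal row counts.
#' @param config A [linkage_config()].
#' @return Tibble with `date_cmp`, `location_cmp`, `name_cmp`,
#'   `location_sim`, `name_sim`, `date_gap_days`.
#' @export
compare_fields <- function(a, b, config = linkage_config()) {
  stopifnot(nrow(a) == nrow(b))
  n <- nrow(a)
  gap <- as.numeric(abs(as.integer(a$event_date) - as.integer(b$event_date)))
  same_month <- format(a$event_date, "%Y-%m") == format(b$event_date, "%Y-%m")
  pa <- a$date_precision
  pb <- b$date_precision
  date_cmp <- dplyr::case_when(
    pa == "unknown" | pb == "unknown" ~ "unassessable",
    pa == "day" & pb == "day" & gap == 0 ~ "exact",
    pa == "day" & pb == "day" & gap <= config$date_tolerance_days ~ "approximate",
    pa == "month" & pb == "month" & same_month ~ "exact",
    pa != pb & same_month ~ "approximate",
    TRUE ~ "none"
  )
  loc <- grade_string_field(a$location_name, b$location_name,
                            config$location_threshold)
  nam <- grade_string_field(a$entity_name, b$entity_name,
                            config$name_threshold)
  tibble::tibble(
    date_cmp = date_cmp,
    location_cmp = loc$cmp,
    name_cmp = nam$cmp,
    location_sim = loc$sim,
    name_sim = nam$sim,
    date_gap_days = ifelse(date_cmp == "unassessable", NA_real_, gap)
  )
}

#' Classify pair agreement into match status
#'
#' Rule-based three-way classification: a pair is a *definite* match when
#' at least two of the three fields agree exactly; a *possible* match when
#' it is not definite but at least one field is approximate or exactly one
#' is exact (these go to adjudication); otherwise the records are treated
#' as *unique* events. Unassessable fields never count toward the rule.
#'
#' @param agreement Tibble from [compare_fields()].
#' @return Character vector: `"definite"`, `"possible"`, or `"unique"`.
#' @export
classify_pairs <- function(agreement) {
  n_exact <- (agreement$date_cmp == "exact") +
    (agreement$location_cmp == "exact") + (agreement$name_cmp == "exact")
  n_approx <- (agreement$date_cmp == "approximate") +
    (agreement$location_cmp == "approximate") +
    (agreement$name_cmp == "approximate")
  dplyr::case_when(
    n_exact >= 2 ~ "definite",
    n_approx >= 1 | n_exact == 1 ~ "possible",
    TRUE ~ "unique"
  )
}

pair_score <- function(agreement) {
  credit <- function(cmp) (cmp == "exact") * 1 + (cmp == "approximate") * 0.5
  credit(agreement$date_cmp) + credit(agreement$location_cmp) +
    credit(agreement$name_cmp)
}

# deterministic, source-symmetric ordering for greedy one-to-one assignment
order_pairs <- function(pairs) {
  lo <- pmin(pairs$record_id_A, pairs$record_id_B)
  hi <- pmax(pairs$record_id_A, pairs$record_id_B)
  order(-pairs$score, pairs$date_gap_days, lo, hi, na.last = TRUE,
        method = "radix")
}

greedy_assign <- function(pairs, taken_a, taken_b) {
  keep <- logical(nrow(pairs))
  for (k in order_pairs(pairs)) {
    ra <- pairs$record_id_A[k]
    rb <- pairs$record_id_B[k]
    if (!(ra %in% taken_a) && !(rb %in% taken_b)) {
      keep[k] <- TRUE
      taken_a <- c(taken_a, ra)
      taken_b <- c(taken_b, rb)
    }
  }
  list(pairs = pairs[keep, ], taken_a = taken_a, taken_b = taken_b)
}

empty_pair_table <- function() {
  tibble::tibble(
    record_id_A = character(), record_id_B = character(),
    date_cmp = character(), location_cmp = character(),
    name_cmp = character(), location_sim = numeric(), name_sim = numeric(),
    date_gap_days = numeric(), score = numeric(), status = character()
  )
}

#' Link two event datasets
#'
#' Generates candidate pairs within identical-country blocks, grades and
#' classifies them, resolves definite matches to a one-to-one matching by
#' greedy assignment (score descending, then smaller date gap, then
#' lexicographic record ids — deterministic and symmetric in the two
#' sources), and hands the remaining possible matches to the adjudicator.
#' With no adjudicator, pending possibles are returned with a warning.
#'
#' @param a,b Event tibbles from the two sources (filtered and
#'   deduplicated); sources must differ.
#' @param config A [linkage_config()].
#' @param adjudicator Optional function taking the pending-pair tibble and
#'   returning a decision tibble (`record_id_A`, `record_id_B`, `decision`
#'   in `definite`/`unique`); see [truth_adjudicator()].
#' @return Object of class `"linkage_result"`: list with `matched_pairs`
#'   (tibble with ids, grades, score and `origin` auto/adjudicated),
#'   `unique_A`, `unique_B` (character vectors), `pending_possibles`
#'   (tibble, empty when adjudicated).
#' @export
link_events <- function(a, b, config = linkage_config(), adjudicator = NULL) {
  if (nrow(a) > 0 && nrow(b) > 0 && any(a$source %in% b$source)) {
    stop("link_events expects records from two different sources",
         call. = FALSE)
  }
  pairs <- empty_pair_table()
  for (ctry in intersect(unique(a$country), unique(b$country))) {
    ia <- which(a$country == ctry)
    ib <- which(b$country == ctry)
    grid <- expand.grid(i = ia, j = ib)
    block_a <- a[grid$i, ]
    block_b <- b[grid$j, ]
    agree <- compare_fields(block_a, block_b, config)
    agree$score <- pair_score(agree)
    agree$status <- classify_pairs(agree)
    block <- dplyr::bind_cols(
      tibble::tibble(record_id_A = block_a$record_id,
                     record_id_B = block_b$record_id),
      agree
    )
    pairs <- dplyr::bind_rows(pairs, block[block$status != "unique", ])
  }

  definite <- pairs[pairs$status == "definite", ]
  assigned <- greedy_assign(definite, character(), character())
  matched <- assigned$pairs
  if (nrow(matched) > 0) matched$origin <- "auto"

  pending <- pairs[pairs$status == "possible" &
                     !(pairs$record_id_A %in% assigned$taken_a) &
                     !(pairs$record_id_B %in% assigned$taken_b), ]

  result <- structure(
    list(
      matched_pairs = if (nrow(matched) > 0) matched else
        dplyr::mutate(empty_pair_table(), origin = character()),
      unique_A = setdiff(a$record_id, matched$record_id_A),
      unique_B = setdiff(b$record_id, matched$record_id_B),
      pending_possibles = pending,
      config = config
    ),
    class = "linkage_result"
  )
  if (!is.null(adjudicator)) {
    result <- apply_adjudication(result, adjudicator(pending))
  } else if (nrow(pending) > 0) {
    warning(nrow(pending), " possible match(es) pending adjudication",
            call. = FALSE)
  }
  result
}

#' Resolve pending possible matches
#'
#' Applies adjudication decisions to a linkage result: pending pairs marked
#' `definite` are promoted to matched pairs (greedy one-to-one, same
#' ordering as the automatic stage); everything else stays unique.
#'
#' @param result A `linkage_result` with pending possibles.
#' @param decisions Tibble with `record_id_A`, `record_id_B`, `decision`
#'   (`"definite"` or `"unique"`).
#' @return The updated `linkage_result` with empty `pending_possibles`.
#' @export
apply_adjudication <- function(result, decisions) {
  pending <- result$pending_possibles
  if (nrow(pending) == 0) {
    result$pending_possibles <- pending[0, ]
    return(result)
  }
  if (nrow(decisions) > 0) {
    known <- paste(pending$record_id_A, pending$record_id_B)
    unknown <- !(paste(decisions$record_id_A, decisions$record_id_B) %in% known)
    if (any(unknown)) {
      stop("adjudication decision for unknown pair(s): ",
           paste(decisions$record_id_A[unknown], decisions$record_id_B[unknown],
                 sep = "/", collapse = ", "), call. = FALSE)
    }
  }
  key <- paste(decisions$record_id_A[decisions$decision == "definite"],
               decisions$record_id_B[decisions$decision == "definite"])
  promote <- pending[paste(pending$record_id_A, pending$record_id_B) %in% key, ]
  assigned <- greedy_assign(promote, result$matched_pairs$record_id_A,
                            result$matched_pairs$record_id_B)
  newly <- assigned$pairs
  if (nrow(newly) > 0) {
    newly$origin <- "adjudicated"
    result$matched_pairs <- dplyr::bind_rows(result$matched_pairs, newly)
  }
  result$unique_A <- setdiff(result$unique_A, result$matched_pairs$record_id_A)
  result$unique_B <- setdiff(result$unique_B, result$matched_pairs$record_id_B)
  result$pending_possibles <- pending[0, ]
  result
}

#' Ground-truth adjudicator
#'
#' Builds an adjudicator from a synthetic truth key: a pending pair is
#' definite when the (unordered) id pair appears in the key, unique
#' otherwise. Stands in for the human consensus step when evaluating
#' linkage against simulated data.
#'
#' @param truth_key Tibble with `record_id_A`, `record_id_B`.
#' @return A function usable as the `adjudicator` of [link_events()].
#' @export
truth_adjudicator <- function(truth_key) {
  truth <- paste(pmin(truth_key$record_id_A, truth_key$record_id_B),
                 pmax(truth_key$record_id_A, truth_key$record_id_B))
  function(pending) {
    if (nrow(pending) == 0) {
      return(tibble::tibble(record_id_A = character(),
                            record_id_B = character(), decision = character()))
    }
    key <- paste(pmin(pending$record_id_A, pending$record_id_B),
                 pmax(pending$record_id_A, pending$record_id_B))
    tibble::tibble(
      record_id_A = pending$record_id_A,
      record_id_B = pending$record_id_B,
      decision = ifelse(key %in% truth, "definite", "unique")
    )
  }
}

#' Export pending possible matches for human review
#'
#' Writes the pending pairs side by side (both records' identifying fields
#' plus the agreement grades) with an empty `decision` column to fill in
#' with `definite` or `unique`.
#'
#' @param result A `linkage_result`.
#' @param a,b The event tibbles that were linked.
#' @param path Output CSV path.
#' @return The review tibble, invisibly.
#' @export
adjudicate_export <- function(result, a, b, path) {
  pending <- result$pending_possibles
  pick <- function(events, ids, col) {
    events[[col]][match(ids, events$record_id)]
  }
  review <- tibble::tibble(
    pair_id = seq_len(nrow(pending)),
    record_id_A = pending$record_id_A,
    record_id_B = pending$record_id_B,
    date_A = as.character(pick(a, pending$record_id_A, "event_date")),
    date_B = as.character(pick(b, pending$record_id_B, "event_date")),
    location_A = pick(a, pending$record_id_A, "location_name"),
    location_B = pick(b, pending$record_id_B, "location_name"),
    entity_A = pick(a, pending$record_id_A, "entity_name"),
    entity_B = pick(b, pending$record_id_B, "entity_name"),
    date_cmp = pending$date_cmp,
    location_cmp = pending$location_cmp,
    name_cmp = pending$name_cmp,
    decision = ""
  )
  readr::write_csv(review, path, na = "")
  invisible(review)
}

#' Import adjudication decisions from a review CSV
#'
#' @param path Review CSV written by [adjudicate_export()] with the
#'   `decision` column filled in.
#' @return Decision tibble for [apply_adjudication()].
#' @export
adjudicate_import <- function(path) {
  review <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                            progress = FALSE)
  needed <- c("record_id_A", "record_id_B", "decision")
  if (!all(needed %in% names(review))) {
    stop("review file must contain columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  bad <- !(review$decision %in% c("definite", "unique"))
  if (any(bad)) {
    stop("decision must be 'definite' or 'unique' for pair(s): ",
         paste(review$record_id_A[bad], review$record_id_B[bad], sep = "/",
               collapse = ", "), call. = FALSE)
  }
  review[, needed]
}

#' Score a linkage result against a truth key
#'
#' @param result A `linkage_result`.
#' @param truth_key Tibble with `record_id_A`, `record_id_B` (ground truth).
#' @return Tibble with `precision`, `recall`, `f1`, `n_matched`, `n_truth`.
#' @export
linkage_metrics <- function(result, truth_key) {
  found <- paste(pmin(result$matched_pairs$record_id_A,
                      result$matched_pairs$record_id_B),
                 pmax(result$matched_pairs$record_id_A,
                      result$matched_pairs$record_id_B))
  truth <- paste(pmin(truth_key$record_id_A, truth_key$record_id_B),
                 pmax(truth_key$record_id_A, truth_key$record_id_B))
  tp <- length(intersect(found, truth))
  precision <- if (length(found) == 0) 1 else tp / length(found)
  recall <- if (length(truth) == 0) 1 else tp / length(truth)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble::tibble(precision = precision, recall = recall, f1 = f1,
                 n_matched = length(found), n_truth = length(truth))
}

#' @export
print.linkage_result <- function(x, ...) {
  cat("Linkage result\n")
  cat("  matched pairs: ", nrow(x$matched_pairs),
      " (", sum(x$matched_pairs$origin == "adjudicated"), " adjudicated)\n",
      sep = "")
  cat("  unique in A:   ", length(x$unique_A), "\n", sep = "")
  cat("  unique in B:   ", length(x$unique_B), "\n", sep = "")
  if (nrow(x$pending_possibles) > 0) {
    cat("  PENDING possible matches: ", nrow(x$pending_possibles), "\n", sep = "")
  }
  invisible(x)
}
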