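#' Overlap between two lists
#'
#' Union size and percentage overlap of two partially overlapping event
#' lists: `union_n = r1 + r2 - m` and `overlap_pct = 100 * m / union_n`.
#' The percentage is reported raw; the replication profile truncates it to
#' one decimal (the convention under which 33/254 prints as 12.9), while
#' the default profile rounds half-up.
#'
#' @param r1,r2 Included event counts in lists 1 and 2.
#' @param m Count of events matched in both lists (`r12`).
#' @param pct_rule `"truncate"` or `"round"` for `overlap_pct_1dp`.
#' @return Tibble with `union_n`, `overlap_pct` (full precision) and
#'   `overlap_pct_1dp`.
#' @export
#' @examples
#' overlap_stats(165, 122, 33)
overlap_stats <- function(r1, r2, m, pct_rule = c("truncate", "round")) {
  pct_rule <- match.arg(pct_rule)
  stopifnot(r1 >= 0, r2 >= 0, m >= 0, m <= min(r1, r2))
  union_n <- r1 + r2 - m
  if (union_n == 0) stop("overlap percentage undefined for empty union",
                         call. = FALSE)
  pct <- 100 * m / union_n
  tibble::tibble(
    union_n = union_n,
    overlap_pct = pct,
    overlap_pct_1dp = if (pct_rule == "truncate") trunc_digits(pct, 1)
      else round_half_up(pct, 1)
  )
}

#' Two-list Chapman estimator of total population size
#'
#' The standard bias-corrected Chapman estimator is
#' `(r1+1)(r2+1)/(m+1) - 1`. The `"paper"` variant divides by `(m-1)`
#' instead — the equation as printed in the source study, which is the only
#' form consistent with its reported estimate — and is therefore larger;
#' it requires `m >= 2`.
#'
#' @param r1,r2 Event counts in the two lists.
#' @param m Overlap count.
#' @param variant `"standard"` (default) or `"paper"`.
#' @return The point estimate (real; callers reporting whole events floor
#'   it).
#' @export
#' @examples
#' chapman(165, 122, 33, variant = "paper") # 637.0625
#' chapman(165, 122, 33)                    # 599.53...
chapman <- function(r1, r2, m, variant = c("standard", "paper")) {
  variant <- match.arg(variant)
  stopifnot(r1 >= 0, r2 >= 0, m >= 0, m <= min(r1, r2))
  if (variant == "paper") {
    if (m <= 1) stop("the paper variant requires m >= 2", call. = FALSE)
    (r1 + 1) * (r2 + 1) / (m - 1) - 1
  } else {
    (r1 + 1) * (r2 + 1) / (m + 1) - 1
  }
}

#' Variance and confidence interval for the Chapman estimator
#'
#' Seber's variance for the bias-corrected two-list estimator,
#' `(r1+1)(r2+1)(r1-m)(r2-m) / ((m+1)^2 (m+2))`, with a
#' normal-approximation interval around the standard Chapman point
#' estimate, clipped below at the observed union size (the estimate can
#' never be smaller than the number of distinct events actually seen).
#'
#' @inheritParams chapman
#' @param level Confidence level in `(0, 1)`, default 0.95.
#' @return Tibble with `variance`, `ci_low`, `ci_high`.
#' @export
chapman_uncertainty <- function(r1, r2, m, level = 0.95) {
  stopifnot(m >= 1, m <= min(r1, r2))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  v <- (r1 + 1) * (r2 + 1) * (r1 - m) * (r2 - m) / ((m + 1)^2 * (m + 2))
  est <- chapman(r1, r2, m, "standard")
  z <- stats::qnorm(1 - (1 - level) / 2)
  union_n <- r1 + r2 - m
  tibble::tibble(
    variance = v,
    ci_low = max(union_n, est - z * sqrt(v)),
    ci_high = est + z * sqrt(v)
  )
}

#' Full capture-recapture summary for a linkage result
#'
#' Combines the observed list sizes and overlap with both Chapman variants,
#' Seber variance, confidence interval and per-list coverage
#' (`r / n_hat`, the estimated fraction of the event universe each list
#' captured).
#'
#' @param r1,r2,m Counts, or pass a `linkage_result` as `r1` to derive them.
#' @param level Confidence level.
#' @param pct_rule Percentage rule for the overlap, see [overlap_stats()].
#' @return One-row tibble with fields `r1`, `r2`, `m`, `union_n`,
#'   `overlap_pct`, `overlap_pct_1dp`, `n_hat_paper`, `n_hat_standard`,
#'   `n_hat_paper_floor`, `n_hat_standard_floor`, `variance`, `ci_low`,
#'   `ci_high`, `coverage_1`, `coverage_2`, `coverage_combined_raw`.
#' @export
capture_estimate <- function(r1, r2 = NULL, m = NULL, level = 0.95,
                             pct_rule = c("truncate", "round")) {
  if (inherits(r1, "linkage_result")) {
    res <- r1
    m <- nrow(res$matched_pairs)
    r1 <- length(res$unique_A) + m
    r2 <- length(res$unique_B) + m
  }
  ov <- overlap_stats(r1, r2, m, pct_rule)
  n_paper <- if (m >= 2) chapman(r1, r2, m, "paper") else NA_real_
  n_std <- chapman(r1, r2, m, "standard")
  unc <- if (m >= 1) chapman_uncertainty(r1, r2, m, level) else
    tibble::tibble(variance = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
  tibble::tibble(
    r1 = r1, r2 = r2, m = m,
    union_n = ov$union_n,
    overlap_pct = ov$overlap_pct,
    overlap_pct_1dp = ov$overlap_pct_1dp,
    n_hat_paper = n_paper,
    n_hat_standard = n_std,
    n_hat_paper_floor = floor(n_paper),
    n_hat_standard_floor = floor(n_std),
    variance = unc$variance,
    ci_low = unc$ci_low,
    ci_high = unc$ci_high,
    coverage_1 = r1 / n_std,
    coverage_2 = r2 / n_std,
    coverage_combined_raw = (r1 + r2) / n_std
  )
}
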