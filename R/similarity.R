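#' Normalise free text for comparison
#'
#' Case-folds, strips diacritics, collapses internal whitespace and trims.
#' Used for all location and entity-name comparisons so that trivially
#' different renderings of the same name ("Bangui " vs "BANGUI") compare
#' equal.
#'
#' @param x Character vector (may contain `NA`).
#' @return Character vector of the same length; `NA` stays `NA`.
#' @export
#' @examples
#' normalize_text(c("  Port-au-Prince ", "N'DJAMENA"))
normalize_text <- function(x) {
  out <- iconv(x, from = "", to = "ASCII//TRANSLIT")
  # iconv may return NA for untranslatable bytes; fall back to the original
  out[is.na(out) & !is.na(x)] <- x[is.na(out) & !is.na(x)]
  out <- tolower(out)
  out <- gsub("\\s+", " ", out)
  trimws(out)
}

#' Jaro-Winkler string similarity
#'
#' Standard Jaro similarity (matching window `floor(max(len)/2) - 1`,
#' transposition count halved) with the Winkler common-prefix boost
#' (scaling 0.1, prefix capped at 4 characters). Inputs are compared as-is;
#' callers wanting case/diacritic insensitivity should pass text through
#' [normalize_text()] first.
#'
#' @param a,b Character vectors, recycled to a common length.
#' @return Numeric vector of similarities in `[0, 1]`; `NA` where either
#'   input is `NA`.
#' @export
#' @examples
#' jaro_winkler("martha", "marhta")
jaro_winkler <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  vapply(seq_len(n), function(i) jw_one(a[[i]], b[[i]]), numeric(1))
}

jw_one <- function(a, b) {
  if (is.na(a) || is.na(b)) return(NA_real_)
  if (a == b) return(1)
  s1 <- strsplit(a, "", fixed = TRUE)[[1]]
  s2 <- strsplit(b, "", fixed = TRUE)[[1]]
  l1 <- length(s1)
  l2 <- length(s2)
  if (l1 == 0L || l2 == 0L) return(0)
  window <- max(floor(max(l1, l2) / 2) - 1, 0)
  m1 <- logical(l1)
  m2 <- logical(l2)
  for (i in seq_len(l1)) {
    lo <- max(1L, i - window)
    hi <- min(l2, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!m2[j] && s1[i] == s2[j]) {
        m1[i] <- TRUE
        m2[j] <- TRUE
        break
      }
    }
  }
  m <- sum(m1)
  if (m == 0) return(0)
  # transpositions: matched characters out of order, counted in halves
  t <- sum(s1[m1] != s2[m2]) / 2
  jaro <- (m / l1 + m / l2 + (m - t) / m) / 3
  prefix <- 0L
  for (k in seq_len(min(4L, l1, l2))) {
    if (s1[k] == s2[k]) prefix <- prefix + 1L else break
  }
  jaro + prefix * 0.1 * (1 - jaro)
}

# round-half-up to `digits` decimals; base round() is round-half-even, which
# does not reproduce reported percentages such as 4.9 from 6/122
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# truncate (toward zero) to `digits` decimals
trunc_digits <- function(x, digits = 1) {
  scale <- 10^digits
  trunc(x * scale) / scale
}
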