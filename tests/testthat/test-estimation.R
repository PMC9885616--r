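test_that("overlap statistics reproduce the union identity and percentage rules", {
  ov <- overlap_stats(165, 122, 33)
  expect_equal(ov$union_n, 254)
  expect_equal(ov$overlap_pct, 100 * 33 / 254)
  expect_equal(ov$overlap_pct_1dp, 12.9) # truncation, not rounding (13.0)
  expect_equal(overlap_stats(165, 122, 33, pct_rule = "round")$overlap_pct_1dp, 13.0)

  expect_equal(overlap_stats(10, 10, 10)$overlap_pct_1dp, 100)
  expect_equal(overlap_stats(5, 7, 0)$overlap_pct_1dp, 0)
  expect_error(overlap_stats(0, 0, 0), "empty union")
  expect_error(overlap_stats(5, 3, 4)) # m cannot exceed the smaller list
})

test_that("the paper-variant Chapman estimate reproduces the published total", {
  expect_equal(chapman(165, 122, 33, variant = "paper"), 166 * 123 / 32 - 1)
  expect_equal(chapman(165, 122, 33, variant = "paper"), 637.0625)
  expect_equal(floor(chapman(165, 122, 33, variant = "paper")), 637)
})

test_that("the standard Chapman estimator matches its closed form", {
  expect_equal(chapman(165, 122, 33), 166 * 123 / 34 - 1)
  expect_equal(chapman(50, 40, 20), 51 * 41 / 21 - 1)
  # complete overlap recovers the list size exactly
  for (r in c(1, 7, 33, 250)) expect_equal(chapman(r, r, r), r)
  expect_error(chapman(10, 10, 1, variant = "paper"), "m >= 2")
})

test_that("Chapman estimates are symmetric, monotone in overlap, and ordered", {
  expect_equal(chapman(165, 122, 33), chapman(122, 165, 33))
  expect_equal(chapman(165, 122, 33, "paper"), chapman(122, 165, 33, "paper"))
  ests <- vapply(5:40, function(m) chapman(165, 122, m), numeric(1))
  expect_true(all(diff(ests) < 0)) # more overlap, smaller universe
  for (m in 2:40) {
    expect_gt(chapman(165, 122, m, "paper"), chapman(165, 122, m, "standard"))
  }
  # the estimate never falls below the observed union
  for (m in 1:122) expect_gte(chapman(165, 122, m), 165 + 122 - m - 1e-9)
})

test_that("Seber variance and the clipped normal interval behave correctly", {
  unc <- chapman_uncertainty(165, 122, 33)
  v <- 166 * 123 * (165 - 33) * (122 - 33) / (34^2 * 35)
  expect_equal(unc$variance, v)
  est <- chapman(165, 122, 33)
  z <- qnorm(0.975)
  expect_equal(unc$ci_high, est + z * sqrt(v))
  expect_equal(unc$ci_low, max(254, est - z * sqrt(v)))
  expect_lt(unc$ci_low, est)

  # degenerate complete overlap: no uncertainty, interval collapses
  unc0 <- chapman_uncertainty(20, 20, 20)
  expect_equal(unc0$variance, 0)
  expect_equal(unc0$ci_low, unc0$ci_high)

  # tiny overlap forces the clip at the union size
  clipped <- chapman_uncertainty(165, 122, 2)
  expect_equal(clipped$ci_low, 165 + 122 - 2)

  expect_error(chapman_uncertainty(10, 10, 5, level = 1.2), "level")
  wide <- chapman_uncertainty(165, 122, 33, level = 0.99)
  expect_gt(wide$ci_high, unc$ci_high)
})

test_that("capture_estimate summarises a linkage result consistently", {
  res <- structure(list(
    matched_pairs = tibble::tibble(record_id_A = sprintf("a%d", 1:3),
                                   record_id_B = sprintf("b%d", 1:3)),
    unique_A = sprintf("a%d", 4:10),
    unique_B = sprintf("b%d", 4:8),
    pending_possibles = tibble::tibble()
  ), class = "linkage_result")
  est <- capture_estimate(res)
  expect_equal(est$r1, 10)
  expect_equal(est$r2, 8)
  expect_equal(est$m, 3)
  expect_equal(est$union_n, 15)
  expect_equal(est$n_hat_standard, chapman(10, 8, 3))
  expect_equal(est$n_hat_paper, chapman(10, 8, 3, "paper"))
  expect_equal(est$coverage_1, 10 / est$n_hat_standard)
  expect_equal(est$coverage_2 + est$coverage_1,
               est$coverage_combined_raw)

  # identical when called with explicit counts
  expect_equal(capture_estimate(10, 8, 3), est)

  # single-overlap case: paper variant undefined, the rest still reported
  est1 <- capture_estimate(10, 8, 1)
  expect_true(is.na(est1$n_hat_paper))
  expect_false(is.na(est1$n_hat_standard))
})
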