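---
title: "Comparing two event lists: linkage and capture-recapture methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing two event lists: linkage and capture-recapture methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duallist)
```

## The model

Two organisations independently compile lists of publicly reported attacks
on health care. Both sample, imperfectly, from the same latent universe of
events. Writing `r1` and `r2` for the number of qualifying events on each
list and `m` for the number of events present on both, two-list
capture-recapture treats presence on each list as a capture occasion and
estimates the universe size. The bias-corrected Chapman estimator is

$$\hat N = \frac{(r_1 + 1)(r_2 + 1)}{m + 1} - 1,$$

with Seber's variance
$(r_1+1)(r_2+1)(r_1-m)(r_2-m) / ((m+1)^2 (m+2))$ and a normal-approximation
interval that we clip below at the observed union $r_1 + r_2 - m$: whatever
the variance says, the universe cannot be smaller than the number of
distinct events actually observed.

The study we replicate prints the estimating equation with $m - 1$ in the
denominator, and its reported total is only consistent with that printed
form. We therefore implement both: `chapman(..., variant = "standard")` is
the usual estimator, `variant = "paper"` the printed one. The
`"replication"` pipeline profile reports the paper variant (floored to
whole events) so the published figure is recovered exactly; the
`"default"` profile reports the standard estimator, which is what new
analyses should use.

```{r headline}
overlap_stats(165, 122, 33)
chapman(165, 122, 33, variant = "paper")
chapman(165, 122, 33, variant = "standard")
```

Two further reporting conventions matter for exact replication and are
therefore explicit options rather than hidden behaviour:

* **Truncation versus rounding.** The published overlap share (33 of 254)
  is printed as 12.9%, which is the truncated value of 12.992; rounding
  would give 13.0. The replication profile truncates percentage ratios of
  this kind to one decimal; the default profile rounds.
* **Half-up rounding.** Published table percentages behave like ordinary
  "round half away from zero" rounding, not R's round-half-even. All table
  percentages use a half-up helper.

## The pipeline

Estimation is the easy part; the package spends most of its code producing
defensible `r1`, `r2`, `m`.

1. **Normalisation.** Events arrive as CSV with a documented schema. Dates
   carry a precision (`day`, `month`, `unknown`); month-precision dates are
   stored as the first of the month but are never compared as if a day were
   known. Country names are canonicalised against an alias table and must
   resolve; free-text locations and facility/victim names are compared
   case- and diacritic-insensitively.
2. **Within-source deduplication.** Repeat reports of one event inside a
   single source are detected with the same agreement rule used across
   sources (below), grouped transitively, and reduced to one record per
   group with a deterministic keep rule (lexicographically smallest id).
3. **Inclusion.** An event enters the analysis set when it meets the attack
   definition, is individually (not aggregately) reported, and occurred in
   one of the 47 WHO Health Emergencies (WHE) framework countries, minus
   one listed country excluded because its reporting was too incomplete to
   link reliably. Each excluded record carries exactly one
   machine-readable reason, assigned in a fixed order, so the funnel from
   raw reports to the analysis set is fully auditable.
4. **Linkage.** Candidate pairs are blocked by country. Three fields are
   graded per pair — event date, location, facility/victim name — each as
   exact, approximate, none, or unassessable when absent:
   * dates: exact on the same day (same month for two month-precision
     dates); approximate within a tolerance, default ±2 days, or when a
     day-precision and a month-precision date fall in the same month;
   * strings: exact after normalisation; approximate at Jaro-Winkler
     similarity ≥ 0.90 (default).

   A pair with at least two exact fields is a **definite** match; with at
   least one approximate or exactly one exact field it is a **possible**
   match; otherwise the records are unique. Definite matches are resolved
   one-to-one by a greedy assignment ordered by agreement score, then date
   gap, then record ids — deterministic and symmetric in the two sources.
   Possible matches go to adjudication: a review CSV round-trip for humans
   (`adjudicate_export()` / `adjudicate_import()`), or a ground-truth key
   (`truth_adjudicator()`) when evaluating on synthetic data.
5. **Summaries.** Attack-type, country-coverage, monthly and
   actor/location tables. The source material mixes percentage bases
   (per-source records, union events, unique events, matched pairs), so
   every share in `actor_location_breakdown()` carries its denominator as
   data. Flagging "capital city" events uses a registry of WHE-country
   capitals — a modelling choice documented here rather than inferred from
   data.

## Synthetic data: what it does and does not claim

`generate_world()` draws a latent universe of `n_true` events (default
600) with per-list capture probabilities (defaults 0.275 and 0.205, chosen
so expected list sizes match the observed 165 and 122) and an optional
odds-ratio dependence between the two lists. `synthesize_datasets()` then
materialises the two observed lists, applying reporting noise to list B
only (date jitter, location coarsening or loss, typographic name
perturbation), plus optional contaminants (out-of-scope countries,
definition failures, aggregated reports) and planted duplicates — and
returns a ground-truth match key.

This makes three evaluations possible, all exercised in the test suite:

```{r recovery}
est <- vapply(1:100, function(i) {
  cap <- generate_world(generator_config(seed = i))$capture
  chapman(sum(cap$in_A), sum(cap$in_B), sum(cap$in_A & cap$in_B))
}, numeric(1))
mean(est) # close to the true 600 under independent capture
```

* estimator recovery: the mean standard-Chapman estimate across simulated
  worlds sits within a few percent of `n_true` under independence, and the
  bias of violated independence can be produced on demand via
  `dependence_or`;
* linkage validity: with noise switched off, linkage against the truth key
  is perfect; at the default noise levels the pair F1 stays high at the
  default tolerances;
* pipeline robustness: contaminants and planted duplicates must leave
  through the documented exits (inclusion reasons, dedup groups), never
  through the matcher.

The replication sizes are modelling choices, not measurements: 600 latent
events and 500 simulation replicates keep the whole study on one CPU in
seconds while leaving Monte Carlo error well below the 5% recovery
tolerance.

## The packaged fixture

`make_paper_fixture()` builds, deterministically and in code, a two-source
dataset whose pipeline output reproduces the published aggregate figures:
264 and 238 raw reports; within-source duplicates; country and definition
exclusions leaving 165 and 122 included events; 29 automatically definite
plus 4 adjudicated matches (33 total, union 254, overlap 12.9%, paper-variant
estimate 637); and the published attack-type, country, monthly and
actor/location tallies. It is an *emulation constructed from published
aggregates* — the underlying record-level databases are not distributed —
so it serves as a regression surface for the pipeline, not as evidence
about the real events.

## Limitations

* Two-list estimation assumes a closed universe, correct linkage and
  capture independence (or a known dependence structure). Positive list
  dependence — likely when both sources monitor the same media — biases
  the estimate downward; the generator's `dependence_or` exists to make
  that bias visible, not to correct it.
* The paper-variant estimator is reported for replication only; it is not
  a recognised bias correction.
* Match classification uses three fields with fixed thresholds. The
  thresholds are configurable, but no claim is made that they are optimal
  beyond the synthetic evaluation shipped with the package.
* The WHE registry, alias table and capitals list are frozen as data in
  the package; analyses of other periods need their own registry.
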