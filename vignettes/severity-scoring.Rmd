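---
title: "Scoring severity and need in complex emergencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring severity and need in complex emergencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cescore)
```

## The model and its assumptions

`cescore` implements a multiplicative composite index for comparing the
severity of complex emergencies (CEs). The logic follows the disaster-model
tradition in which an ongoing hazard meets a susceptible population:
pre-existing **vulnerability** (development and health status) and current
**exposure** (the crisis footprint — displacement and people in need)
jointly determine how bad a situation is, and neither alone suffices. Four
indicators per dimension are classified into three ordinal severity levels
with fixed weights 0.5 (low/medium), 1.0 (high) and 1.5 (extreme); the
dimension sums (each in [2, 6]) are multiplied:

$$\text{severity} = \Big(\sum_{i=1}^{4} w_i^{\,\text{vuln}}\Big) \times
  \Big(\sum_{j=1}^{4} w_j^{\,\text{exp}}\Big) \in [4, 36]$$

$$\text{need} = \text{severity} \times \text{people in need (millions)}$$

The multiplication encodes two assumptions worth making explicit. First, a
highly vulnerable but unexposed population (or vice versa) is less severe
than one that is both; severity is super-additive in the two dimensions.
Second, escalating any single indicator always raises severity, and by more
when the other dimension is already bad — the model is monotone, which the
test suite verifies over random level assignments.

Using people in need both inside exposure (as a count and a proportion
indicator) and again as the multiplier of the need score means that quantity
enters twice; this is a known structural limitation of the index, tolerated
because people-in-need estimates are the most consistently available measure
of magnitude.

## Tunable parameters

* **Cut-offs** (`inst/extdata/default_model.yaml`). Each indicator carries
  two thresholds in its native units (e.g. percent literate, persons
  uprooted). The shipped values are provisional, chosen once from typical
  least-developed-country ranges of the underlying statistics; they are
  configuration, meant to be reviewed per assessment. Three vulnerability
  indicators (GNI per capita PPP, adult literacy, child underweight) and
  three exposure indicators (number and proportion uprooted, number in need)
  are the canonical choices; the fourth slot of each dimension is a
  documented placeholder — life expectancy at birth (a standard development
  component) and the proportion of the population in need (parallel to the
  uprooted pair). Both are plainly named and editable.
* **Missing policy** (`missing_policy()`). Default `strict`: any unresolved
  level leaves the dimension sum, severity and need unresolved.
  `impute_extreme` substitutes the extreme level (recording the
  substitution) — appropriate only when context knowledge justifies assuming
  the worst; `impute_level` substitutes any configured level.
* **Concordance window** (`compare_with_mortality(window = 1)`). A context
  counts as concordant when its severity rank and excess-mortality rank
  differ by at most `window` positions.
* **Colour bins** (`color_rule()`). Severity bars: yellow below 10, orange
  in [10, 20), red at 20 and above. Need bars: yellow below 50, orange in
  [50, 150), red at 150 and above. Colour codes are configurable; the
  semantics are fixed.

## Numerical choices and degenerate inputs

* **Boundary convention.** A raw value exactly at a cut-off is assigned the
  more severe level, in both directions (`higher_is_worse` and
  `lower_is_worse`), and the score bins use the same half-open construction
  (a severity of exactly 20 is red). Erring severe is the safer default in
  humanitarian triage, and one consistent rule keeps the mapping total.
* **Exactness.** Weights are halves, so dimension sums and severity are
  exact multiples of 0.25 in double precision; no rounding happens
  internally. CSV output formats scores to two decimals so repeated runs
  diff byte-identically.
* **Ties.** Rank correlation uses average ranks; a panel of identical
  severities has zero rank variance and the correlation is undefined (`NA`),
  which is propagated rather than masked.
* **Median of per-sector counts.** When appeals report people affected per
  sector, `median_affected()` reduces them to a median; for an even number
  of sectors the *lower* central value is returned (appeal figures are
  integer head-counts), with `rule = "interpolate"` for the conventional
  midpoint.
* **Degenerate inputs.** Empty panels, unknown indicator columns, non-finite
  values, negative people-in-need and sub-3 validation sets are rejected
  with classed errors (`cescore_input_error` / `cescore_config_error`),
  which the command line maps to exit codes 1 and 2.

## The reliability check

Excess mortality (direct plus indirect deaths per 100,000 per year) is a
recognised if late and noisy outcome measure of CE severity. Whether a
severity ranking "follows" a mortality ranking is inherently a judgement
call; the package operationalises it reproducibly as (a) Spearman's rank
correlation and (b) the rank-window concordance count, both reported so the
user sees the raw ordering. The window rule is a stated proxy, not a claim
about how any particular historical comparison was judged.

## What the synthetic generator emulates — and what it does not

`generate_panel()` produces assessment rounds with known ground truth: true
levels are drawn per indicator, then a raw value is drawn uniformly inside
the open interval of that level's cut-off bin (the bins beyond the outer
cut-offs are bounded by one cut-off span so draws stay finite), so
classification recovers the truth exactly — the round-trip property that
anchors the test suite. Missingness is applied afterwards, Bernoulli per
cell. `generate_mortality()` pairs each context with
$8\,e^{\text{severity}/8}$ times log-normal noise, strictly co-monotone with
severity when the noise is zero.

Defaults emulate a typical assessment round: 16 countries over 3 years;
levels 45/35/20 percent low-medium/high/extreme so panels mix all three
colours; 5 percent missingness (most indicator data is obtainable, a few
cells blank); people in need 0.1–12 million, the span seen across
contemporary appeals; mortality noise sd 0.3 on the log scale.

What the generator does **not** emulate: correlation between indicators of
one country (real development indicators co-move strongly), persistence
across years, informative missingness (data gaps concentrate in the worst
contexts), or the heavy-tailed distributions of real counts. Passing tests
therefore demonstrate that the scoring arithmetic, classification, policies
and rank comparison are correct — not that the index is valid for any real
country, which depends entirely on the cut-offs and data put into it.

## Problem sizes used by the test suite

The suite enumerates all 6,561 complete level assignments exactly;
round-trip recovery runs on a 1,000-country zero-missingness panel;
monotonicity is checked over all 8 escalation positions × 1,000 random
records; rank-correlation oracle equality over random sets of up to 12
contexts; missingness calibration on a 300-row panel (2,400 cells, within 3
standard errors). These sizes give exact or tight checks while the full
suite stays well under a minute.

## Known limitations

* The index compares "the worst of the worst"; a low score does not mean an
  absence of need.
* National-level only — no sub-national variation, no qualitative context,
  no adjustment for protracted-crisis dynamics.
* People in need enters the need score twice (see above).
* Cut-offs dominate the output; the shipped defaults are provisional and
  must be audited before real use.
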