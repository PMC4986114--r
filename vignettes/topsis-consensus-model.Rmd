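---
title: "A two-stage TOPSIS consensus model for drug reimbursement criteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage TOPSIS consensus model for drug reimbursement criteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topsisHTA)
```

## The decision problem

Health-insurance bodies must decide which new drugs enter the basic
reimbursement list. `topsisHTA` implements a consensus model for that
decision built from two expert-panel instruments:

1. **Stage 1 — importance screening.** A panel of experts (85 invited,
   45 complete in the reference study) marks the importance of every
   candidate criterion on a 1–100 scale. Criteria that the panel rates
   unimportant or rates without agreement are dropped; the reference study
   reduced 128 candidate criteria to 48 this way. Instrument reliability is
   summarised by Cronbach's alpha.
2. **Stage 2 — TOPSIS ranking.** The surviving criteria become the
   *alternatives* of a multi-criteria decision problem. The same panel
   scores each criterion on a 1–5 Likert scale against four fixed
   sub-criteria — cost-calculation simplicity, interpretability, precision,
   and updating capability — and the criteria are ranked by the Technique
   for Order Preference by Similarity to an Ideal Solution.

Ranks convert to points (`N + 1 − rank`, so 48 points for the top criterion
of 48) and a candidate drug is forwarded with a positive recommendation
when the points summed over the criteria it satisfies reach half the total
(588 of 1176 for a 48-criterion catalog).

## Stage 1: the mean/SD screen

For each criterion we compute the arithmetic mean and the sample (n−1)
standard deviation over non-missing responses. With the default thresholds
a criterion is excluded when its mean is below 60 **or** its SD exceeds 25.

The defining sentence of the screen is grammatically conjunctive ("a mean
less than 60 *and* a standard deviation more than 25"), but consensus
practice argues for the disjunctive reading: a high-variance criterion
lacks consensus regardless of its mean, and a low-mean criterion is
unimportant regardless of its variance. The raw stage-1 data that would
disambiguate the 128 → 48 reduction are not available, so both readings are
exposed: `mode = "any"` (disjunctive, the default) and `mode = "both"`
(literal conjunctive). `mode = "both"` always retains a superset of
`mode = "any"`.

Sample rather than population SD is used throughout because the 45
respondents are a sample of the expert population; which convention the
original analysis used is not recoverable. Stage-1 missing cells are simply
excluded from the per-criterion mean/SD — the impute-to-1 rule (below)
belongs to stage 2, where the ranking algorithm requires a complete matrix.
Means and SDs are carried at full precision internally and rounded to two
decimals only for presentation.

```{r screen-example}
cfg <- panel_config(seed = 42)
panel1 <- simulate_importance_panel(cfg)
screened <- screen_criteria(summarize_importance(panel1))
attr(screened, "n_retained")
```

## Stage 2: TOPSIS

Respondent non-responses are first imputed with 1, the Likert scale
minimum, mirroring the reference analysis, which had to enter a value for
every cell and scored unanswered items at the scale floor
(`impute_missing()`, which also counts the imputed cells for the run log).
The respondent dimension is then collapsed to a 48 × 4 decision matrix.
The aggregation is the arithmetic mean by default; the original report is
silent on this step, so median and geometric mean are selectable
alternatives (`aggregate_panel()`).

The classical TOPSIS steps follow (`run_topsis()` composes them, each is
also exported):

1. *Vector normalization*: `r_ij = x_ij / sqrt(sum_i x_ij^2)`, the
   canonical Hwang–Yoon choice, so every column has unit Euclidean norm.
2. *Weighting*: `v_ij = w_j r_ij`. No sub-criterion weights are published,
   so the default is equal weights (0.25 each), configurable per run.
3. *Ideal points*: per column, the best and worst weighted value; all four
   sub-criteria are phrased so that more is better, hence the all-`benefit`
   default, with `cost` available per column.
4. *Separations*: Euclidean distances `d⁺`, `d⁻` of each alternative from
   the ideal and anti-ideal points.
5. *Relative closeness*: `C = d⁻ / (d⁺ + d⁻)` in [0, 1]; rank 1 goes to the
   largest `C`.

Numerical conventions, chosen for bit-reproducible batch runs:

* exact ties in closeness are broken by the ascending numeric suffix of the
  criterion id;
* when every alternative is identical (`d⁺ = d⁻ = 0`), closeness is set to
  0.5 and flagged `degenerate` rather than raising an error;
* closeness and separations are rounded to three decimals only at output.

Note that TOPSIS is known to exhibit rank reversal when alternatives are
added or removed — the normalization couples the alternatives — so no such
stability is claimed or tested.

```{r topsis-example}
panel2 <- simulate_likert_panel(cfg, default_catalog())
res <- run_topsis(panel2)
head(as.data.frame(res)[order(res$ranks), ], 3)
```

## Points and the decision rule

`points_from_rank()` maps rank `r` of `N` to `N + 1 − r` points;
`total_points()` is `N(N+1)/2`. `score_drug()` sums the points of the
criteria a drug satisfies and compares the sum with
`threshold_fraction * total` (default 0.5). Two modelling choices are
documented rather than inferred, since the source text does not settle
them: a score exactly at the threshold counts as attainment, and
"satisfying" a criterion is binary — any per-criterion conditional logic
(e.g. whether a treatment duration is shorter than the comparator's) is
adjudicated by the user upstream.

## The published tables and their validator

The package ships the published 48-criterion catalog
(`default_catalog()`) and the published ranking — closeness, rank, `d⁺`,
`d⁻` to three decimals — as checksummed plain-text fixtures
(`load_published_fixture()`). The raw questionnaires were never deposited,
so the published ranking cannot be regenerated from inputs; what *can* be
checked is the internal arithmetic of the published tables, and
`validate_published_tables()` does so by recomputing `C = d⁻/(d⁺+d⁻)` from
the printed separations:

```{r validate}
validate_published_tables(load_published_fixture())
```

The report shows the two known discordances of the printed tables: the
criterion printed with closeness 0.351 sits one rank above one printed
0.352, and two rows (A6, A47) disagree with their own separations by more
than the 0.01 that 3-decimal rounding can explain (A6 by ≈ 0.014: even
pushing both its separations to the edge of their rounding intervals
cannot reconcile 0.352 with 0.023/0.068 ≈ 0.338). These are presumably
artifacts of unrounded internal values or typesetting; the validator
reports them, and the engine makes no attempt to reproduce them. Kendall's
tau between the published ranks and ranks re-derived from the published
closeness is 0.996.

## The synthetic panel generator

Because the raw panels are unavailable, every stage is exercised on
synthetic panels (`panel_config()`, `simulate_importance_panel()`,
`simulate_likert_panel()`) built from the simplest generators matching the
bounded, unimodal, respondent-noise structure of the instruments:

* **Stage 1**: per-criterion normal latents truncated to [1, 100] (drawn by
  inverse CDF) and rounded to integers. Default latent means span 45–90 and
  SDs 16–28 — a band bracketing the category-level means (≈ 72–80) and SDs
  (≈ 19–24) reported for the original panel, wide enough that a default
  screen separates criteria non-trivially.
* **Stage 2**: a latent standard normal per response, shifted by a
  per-(alternative, sub-criterion) location and cut at fixed thresholds
  (−1.5, −0.5, 0.5, 1.5) into the 1–5 scale, so a higher location gives
  stochastically larger responses. Default locations form an equally
  spaced gradient from +1 to −1 so a default run has a well-defined
  ranking.
* **Missingness** is completely at random at 1% per cell, matching the
  incidental non-response the original study describes.
* **Seeding**: one global seed drives independent derived streams for the
  two stages, so each panel is reproducible on its own and identical seeds
  give bit-identical panels.

The generator emulates panel sizes, score ranges, location-driven ordering
and sporadic missingness. It does **not** model rater severity, halo
effects, respondent correlation, or non-MCAR missingness; passing recovery
tests therefore demonstrates correctness of the pipeline under the stated
model, not robustness of the original study's conclusions to such effects.

Recovery checks run at the study's panel size (45 respondents): a planted
dominant alternative (latent location 1.2 against a field spread 0.2 to
−1.2) must take rank 1, and a planted 48-of-128 retained set (latent mean
80, SD 12, against decoys at mean 40 with SD 15 or 35) must be recovered
exactly by the 60/25 any-mode screen, each over 200 seeded replicates. The
decoy block fails the screen through its mean arm: truncation to [1, 100]
shrinks large latent SDs (a latent SD of 35–40 at moderate means yields
observed SDs near 25), so the SD arm alone cannot be planted far from the
threshold.

## Problem sizes in the test suite

The packaged tests compare the engine with an independently coded
straight-line reference on 1,000 random decision matrices up to 48 × 4
(agreement to 1e-10 on every intermediate quantity), run the two recovery
suites at 200 replicates each, and validate the published tables in full.
A complete run takes well under a minute on a single core.

## Known limitations

* The original 128-item stage-1 instrument is not recoverable; only its 48
  survivors are. The 128 → 48 reduction can therefore only be replayed on
  synthetic panels.
* Sub-criterion weights of the published run are unknown; equal weights are
  an assumption, and rankings can be sensitive to them.
* The points scheme ignores closeness magnitudes: rank gaps of 0.001 and
  0.15 in closeness earn the same one-point step.
* No fuzzy TOPSIS, AHP/entropy weighting, or alternative MCDA methods
  (ELECTRE, PROMETHEE) are provided.
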