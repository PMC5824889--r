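---
title: "Chemotaxonomic profiling of LC-MS metabolite data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemotaxonomic profiling of LC-MS metabolite data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Myxobacteria (order *Myxococcales*: suborder > family > genus > species >
strain) are prolific producers of secondary metabolites, and practical
natural-product discovery asks where to spend isolation effort. If
metabolite profiles track taxonomy — if genera carry genus-typical
compound families — then sampling a new genus should yield more chemical
novelty than sampling another strain of a well-covered species. `chemotax`
implements the analysis chain that makes this question quantitative for
untargeted LC-MS feature lists of strain extracts:

1. **De-replication** — annotate known compounds by accurate m/z,
   retention time and isotope-pattern matching against a reference library.
2. **Background filtering** — remove adsorber-resin polymer impurities and
   cultivation-medium features using blank-media extracts.
3. **Bucketing** — merge the features of all data sets into rectangular
   m/z–RT regions ("buckets"), the cross-strain unit of the unknowns
   analysis.
4. **Taxon-resolved distributions** — collapse the bucket × data set
   occurrence matrix to any rank, score genus specificity, count rank-level
   overlaps.
5. **Clustering** — UPGMA dendrograms of taxon profiles with bootstrap and
   approximately-unbiased clade support.
6. **Profile similarity** — bitvector cosine distances between binary
   strain profiles, stratified by the taxonomic relation of each strain
   pair, compared with strain-paired t-tests.

A synthetic-cohort generator with full feature-level ground truth stands in
for the proprietary instrument and peak-picking front end, so every stage
is testable without raw spectra.

## Data model

A cohort is two tidy tables. The *feature table* holds one row per LC-MS
feature: `mz` (150–2500), `rt` (minutes, 0.5–20.5 — the annotation window
of the acquisition method), `intensity` (counts, instrument range 2000 to
1.25e6) and an optional 3-peak isotope envelope `iso1..iso3` (relative
abundances, base peak = 1). The *registry* maps each `dataset_id` to its
strain, taxonomy and cultivation medium; rank mappings are validated to be
functions (one genus, one family; one family, one suborder). The species
sentinel `"unclassified"` marks strains without a species assignment.

The compound library carries, per compound: molecular formula, compound
family, reference retention time, and the ion adduct types under which the
compound has actually been observed — matching only ever considers those.

## Chemistry layer

Formulas are parsed into element counts against a bundled plain-text
isotope table (IUPAC masses and abundances; only elements whose principal
isotope is the lightest, so the monoisotopic peak is always the first
isotopologue group). Adduct m/z is `(mult * M + delta) / |charge|` with the
proton mass 1.00727646 Da; electron mass is neglected in the metal and
ammonium deltas (documented in `extdata/adducts.tsv`; the error is
~0.5 mDa, far below the 5 ppm matching gate at the masses involved).
Masses are kept at full precision internally and conventionally reported
to 4 decimal places.

Theoretical isotope patterns come from convolving per-element isotope
distributions over integer isotopologue groups (exact mass offsets carried
as abundance-weighted means), pruned below 1e-4 relative abundance. The
isotope-pattern *fit score* is 1000 × the RMS difference of base-peak
normalised abundances over the first `min(k)` groups. This replaces the
vendor-proprietary "mSigma" unit, which is not publicly defined: the score
keeps the same scale intuition (0 = identical, lower is better, default
acceptance threshold 50) and is fully specified, but numerical agreement
with vendor scores is not claimed. It is a pseudometric (symmetric, zero on
identical truncated patterns, empirically satisfies the triangle
inequality).

## Matching tolerances

De-replication accepts a (feature, compound, adduct) pair when all three
gates pass:

| gate | default | comparison |
|------|---------|------------|
| m/z error | 5 ppm | strict `<` |
| RT deviation | 0.15 min | inclusive `<=` |
| isotope fit | 50 | strict `<` |

The asymmetry follows the usual phrasing of such workflows ("less than
5 ppm", "not exceeding ± 0.15 min", "< 50"). Features without an isotope
envelope skip the third gate and the match is flagged `low_confidence`
rather than dropped — synthetic or third-party feature lists do not always
carry envelopes. When several compounds match one feature, all matches are
retained; no unique-assignment heuristic is invented. In-source fragments
are linked to parent ions by neutral-loss mass (H2O, NH3, CO, CO2, HCOOH,
HPO3, H3PO4 bundled; extensible) within a ppm tolerance taken on the
parent m/z.

## Window semantics

Both the blank-subtraction window and the bucket are stated as
"0.2 min and 0.03 m/z". That phrasing is ambiguous between full width and
half width (±). We read it as the **full width centered on the reference
point** — ± 0.1 min and ± 0.015 m/z, boundary inclusive — and use the same
convention in both places, so one rule covers both uses. The m/z window is
absolute, not ppm, as stated.

The polymer filter removes a feature iff RT ∈ [9, 13] min and either
m/z ∈ [500, 800] with intensity < 20000, or m/z ∈ [150, 500) ∪ (800, 1600]
with intensity < 5000. Interval endpoints on the stated boundaries are
inclusive, and the two m/z regimes partition at 500 and 800 with the
[500, 800] branch owning its endpoints; the boundary choice is arbitrary
but must be fixed for results to be exact, so it is documented here and
pinned by tests. Polymer filtering runs before blank subtraction. Media can
be grouped (`media_groups`) so one data set is filtered against the merged
blanks of several related media; the default is the identity grouping.

## Bucketing

No seeding or assignment order is canonical for rectangular bucketing, so
the package defines one deterministically: features of **all** data sets
are processed in descending intensity (ties: m/z, RT, dataset, feature id);
each feature joins the nearest existing bucket whose *running-mean* center
lies within the half-widths, else seeds a new bucket; final centers are the
plain average of member features (not intensity-weighted); frozen-center
passes then re-check membership against the final centers and re-seed
violators until containment holds (guaranteed to terminate — residual
violators become singletons after `max_pass` iterations, which is never
reached in practice). Intensity-descending order lets strong, stable
signals define bucket centers before noisy low-intensity features attach.
The result is a partition: every feature in exactly one bucket, all members
within ± 0.015 m/z and ± 0.1 min of their final center. A fixed-grid mode
(`mode = "grid"`) is available for comparison; it is faster but splits
clusters that straddle grid lines. One data set may contribute several
features to one bucket; occurrence matrices record binary presence, so this
does not affect downstream analyses.

Bucket-level annotation against the library uses the ppm and RT gates only
(bucket centers carry no isotope envelope).

## Taxon-level analyses

`collapse_matrix()` merges data-set columns by rank and counts occurrences.
Genus *specificity* of a bucket (or compound family) is the fraction of its
total detections that falls in its top genus — note this is a fraction of
*detections*, not of the genus's data sets. Classes use strict thresholds:
`unique` iff the fraction equals 1, `highly_specific` iff it exceeds 0.95,
else `nonspecific`; 19 of 20 detections (0.95 exactly) is nonspecific.
Because the statistic is a within-row fraction it is invariant to
duplicating all data sets of every genus equally, but it is *not* invariant
to unequal sampling across genera — which is why the unknowns analysis
runs on a genus-balanced subsample: genera with fewer than `min_n = 20`
data sets are excluded, genera above `cap = 50` contribute a uniform random
cap (seeded, without replacement). Subsampling is optional (`subsample`
toggle) because the known-compound survey runs on all data sets.

`rank_overlap_counts()` reports, for every set S of taxa, the number of
rows detected in exactly the taxa of S — the numbers behind Venn/Euler
summaries; drawing proportional-area diagrams is out of scope.

## Clustering and clade support

Profiles are compared by bitvector cosine distance
`1 − |a ∧ b| / sqrt(|a||b|)` on binarised profiles (the same metric as the
strain-level similarity analysis, for internal consistency; Euclidean on
counts is available). Zero-profile conventions: distance 1 against any
non-zero profile, 0 between two zero profiles — bounded and monotone, and
such columns are rare after preprocessing.

UPGMA is average-linkage agglomeration, delegated to `stats::hclust`
(ties resolved by hclust's deterministic merge order); merge heights are
reported as ultrametric node heights (d/2), so cophenetic distances equal
twice the node heights and ultrametric inputs are reproduced exactly.
Cophenetic correlation against the input distances is reported as a
goodness-of-fit summary.

Clade support resamples **rows** (buckets/compound families) with
replacement — the features are the sampling units, the taxa columns are
fixed — rebuilding the tree per replicate and counting bipartition
frequency (BP) for each clade of the point-estimate tree. The
approximately unbiased p-value (AU) uses the multiscale bootstrap: scales
r ∈ {0.5, 0.6, …, 1.4} of the row count, and per clade the weighted fit
`qnorm(1 − BP_r) = v·sqrt(r) + c/sqrt(r)` with AU = 1 − Φ(v − c),
the signed-distance/curvature decomposition underlying pvclust-style
supports. BP-only is the default (`method = "bp"`) since AU costs 10× the
replicates; the analysis scripts use `n_boot = 500`, the tests smaller
counts. Degenerate replicates (all-identical columns) produce a
zero-height tree and simply count against non-trivial clades.

## Profile similarity and the paired test

Every unordered pair of strains falls into at most one contrast series:
within species, between species within genus, between genera within
family, between suborders. Pairs that fit none (same suborder but
different families) are excluded, as are same-genus pairs involving an
`"unclassified"` species — their true species relation is unknowable, and
counting them as either within- or between-species would bias the two
series in opposite directions. Histograms are emitted both as counts and
densities (bin width 0.05 by default).

"Comparing means of similarity distributions with a paired t-test" requires
a pairing unit; the only unit that makes the test paired on this data is
the **strain**: each strain contributes (its mean distance over pairs in
contrast A, its mean distance over pairs in contrast B), and the two-sided
paired t statistic is computed on the per-strain differences with a 99%
confidence interval. An unpaired Welch fallback sits behind
`paired = FALSE`. Strains with pairs in only one contrast drop out; fewer
than two complete strains, or a constant non-zero difference, is an
explicit error (identical per-strain means return t = 0, p = 1).

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes, at
desk scale. Defaults (fixed once; they are the package's study conditions):

* taxonomy: 3 suborders × 2 families × 2 genera × 2 species × 3 strains =
  72 data sets (one per strain, no replicates), 12 genera;
* media: 5 blank media, assigned genus-typically by cycling, so several
  genera — including genera of different suborders — share a medium. This
  deliberately reproduces the confound that medium-driven features could
  mimic taxonomic clustering; after blank filtering, genera sharing only a
  medium must *not* cluster together, and the planted cohort lets tests
  verify that;
* compounds: per genus 3 genus-specific families, per species 1
  species-specific family, per taxonomic family 3 shared families, per
  suborder 3, plus 24 cosmopolitan families spanning 3 random genera each;
  ~15 produced families per strain (a free choice — no per-strain
  compound-count distribution is published — exposed in `cohort_spec()`);
  15% of families carry a +CH2 derivative; formulas sampled from CHNOPS
  with masses in 200–1200 Da; reference RTs uniform in 1–20 min; 1–3
  adducts per compound (always `[M+H]+`) plus a 15% chance of an in-source
  water-loss ion. The taxonomic layering of the shared pools is what makes
  profile distance grow monotonically with rank, the effect the analysis
  is designed to detect; species-specific families are the generator's
  addition that gives the within- vs between-species contrast a non-zero
  effect size;
* noise: per-feature iid m/z error of 0.6 ppm (the post-calibration
  residual of the instrument the method was developed on; run-level drift
  is assumed calibrated away and not modelled), RT jitter 0.03 min,
  intensities log10-normal (median 1e5, σ = 0.5) clipped to
  [2000, 1.25e6], 5% multiplicative envelope noise, detection probability
  0.8 per produced compound per data set;
* background: 5 centers per medium (identical across the data sets of a
  medium; optional jitter defaults to 0), kept clear of all library adduct
  positions by rejection sampling; 2 polymer features per data set confined
  to RT 9–13 min, m/z 500–800, intensity < 20000. This load yields a mean
  preprocessing reduction of ~20%, the figure reported for the real
  workflow.

Every feature carries exactly one provenance label (`compound` +
adduct, `background`, or `polymer`), so tests can score filtering,
de-replication and specificity recovery against planted truth. The same
seed yields byte-identical output files.

What the generator does **not** emulate: chromatographic peak shapes and
raw spectra (feature finding is upstream of this package), ion suppression
(also unhandled in the real workflow), retention-time drift across runs
(instrument stability is assumed), isotope fine structure, and realistic
compound-class mass defects. Passing tests therefore demonstrate that the
pipeline recovers planted structure under idealised, well-calibrated
conditions — they do not certify performance on data with alignment
problems or heavy matrix effects.

## Problem sizes and numerical choices

The bundled analyses and tests run the 72-data-set default cohort
(~2900 features, ~300 buckets), bootstrap supports at 100–500 replicates,
and replicate the rank-ordering check over 5 seeded cohorts; these sizes
keep the whole suite in the minutes range on one core while leaving every
statistical conclusion comfortably clear of its threshold. Scaling to
hundreds of data sets is a matter of the same calls on bigger tables; the
greedy bucketing scan is the only quadratic-ish step and remains practical
at a few hundred thousand features.

Floating-point notes: gate comparisons are exact (no epsilons), so a
deviation that is mathematically on an inclusive boundary may fall either
way at the 1e-16 level — tests probe boundaries with binary-exact values.
Quartiles use R's default type-7 interpolation; Tukey outliers are values
beyond 1.5 × IQR fences. Bucket ids are assigned in (m/z, RT) order of the
final centers, making outputs stable across runs.

## Known limitations

* The isotope-fit score is this package's own construction; thresholds
  tuned against vendor mSigma values elsewhere transfer only in spirit.
* Greedy bucketing depends on the processing order; the order is fixed and
  documented, but a different convention would draw slightly different
  bucket boundaries for features near window edges.
* AU p-values inherit the small-sample caveats of the multiscale-bootstrap
  fit: with few rows or extreme BP values the z-regression is poorly
  conditioned and the result is clamped to the trivial values 0/1.
* The paired t-test treats per-strain mean distances as exchangeable
  observations; strains of one species share pairs, so the differences are
  not strictly independent. The real analysis makes the same
  simplification.
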