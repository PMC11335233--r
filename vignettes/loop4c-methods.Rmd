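---
title: "Calling 4C-seq chromatin interactions with loop4c: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling 4C-seq chromatin interactions with loop4c}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loop4c)
```

# The measurement and its coordinate system

A 4C-seq library reports, for one fixed genomic anchor (the *bait* or
viewpoint), how often every other restriction fragment of the genome was
ligated to it in crosslinked chromatin. The native resolution unit is the
fragment of the primary restriction enzyme — here a six-cutter, HindIII
(A^AGCTT) or EcoRI (G^AATTC) — and the library chemistry additionally
requires a site of the secondary four-cutter Csp6I (G^TAC) inside a
fragment for it to form the circularizable product. `digest_genome()`
builds this coordinate system by scanning every start offset of each
chromosome for the recognition motif (so overlapping occurrences are
found) and cutting at `motif start + cut offset`. Fragments tile each
chromosome without gaps; this tiling is asserted after every digestion.
Fragments with no internal Csp6I site are flagged *blind* by
`flag_blind_fragments()` and drop out of all statistics — they cannot
produce signal, so leaving them in would only dilute the multiple-testing
family.

Only palindromic recognition sites are accepted. All three supported
enzymes cut palindromes, so a forward-strand scan is complete; a
non-palindromic motif is rejected with an error rather than silently
half-scanned. Coordinates are 0-based half-open throughout (BED
convention), so maps round-trip losslessly through the BED-like TSV
emitted by `write_fragment_bed()`.

One simplification is deliberate and isolated in this module: counting is
done at whole-primary-fragment resolution rather than at the sub-fragment
"fragment end" resolution some 4C tools use. Interactions are reported at
fragment resolution either way, and the blind flag captures the part of
the fragment-end logic that matters for validity.

# From reads to per-fragment signal

`count_reads()` assigns each mapped read to the fragment containing its
5' alignment position. 4C reads begin at restriction sites, so the 5'
end is the unambiguous anchor; no midpoint or overlap rule is needed, and
the assignment is testable against a one-line interval-membership brute
force. Duplicate reads are kept — 4C enrichment is expected to produce
many identical ligation junctions, and no deduplication step is modeled.
Reads on chromosomes absent from the map are tallied as *off-map* and
reported, never fatal.

Normalization is RPKM in its literal definition:

$$\mathrm{rpkm} = \frac{\text{raw}}{\text{fragment length (kb)} \times \text{mapped reads (millions)}}$$

Whether fragment-length normalization belongs in 4C RPKM is genuinely
ambiguous in common usage; it is implemented literally here and can be
switched off (`length_normalize = FALSE`), which reduces to per-million
scaling.

Two filters precede all statistics:

* **Bait-proximal exclusion** (`exclude_bait_proximal()`, default
  `n_exclude = 2`): the bait fragment and the two fragments on each side
  are dominated by self-ligation and re-ligation products and are removed.
* **Library QC** (`cis_fraction()`): a healthy 4C template maps the large
  majority of its reads to the bait chromosome; libraries under a 40%
  cis fraction are flagged.

# The cis-interaction model

Within a symmetric window of ±2 Mb around the bait (configurable;
`window_bp` in `bait_config()`), the caller models the dominant feature
of 4C signal: contact frequency decays monotonically with genomic
distance. The steps, per replicate library:

1. **Variance stabilization.** `transform_counts()` applies
   `log2(rpkm + 1)` — monotone, zero at zero, and variance-stabilizing to
   first order for counts whose standard deviation grows with the mean.
   No count-model VST is fitted: the transform is parameter-free, and the
   robust scale estimate below absorbs the residual mean-variance
   relationship. `sqrt` is available as an alternative.
2. **Decay trend.** `fit_decay()` fits an isotonic (monotone
   non-increasing) regression of the transformed signal on log10
   distance, separately for the upstream and downstream side of the bait.
   Isotonic regression enforces exactly the property the physics implies
   — monotone decay — without committing to a parametric shape, and has
   an exact pool-adjacent-violators reference against which the
   implementation is tested. Between fitted knots the trend is linearly
   interpolated; beyond the fitted range it is extended as a constant.
3. **Robust refit.** Enriched fragments are, by definition, outliers
   above the trend, and an isotonic fit will absorb an outlier into a
   local pooled block, shrinking the very signal being tested — the
   effect is strongest near the bait where the trend is steep. The caller
   therefore refits the trend once with initial candidate peaks
   (z above the call threshold) removed, and scores all fragments against
   the refit. Under the null almost nothing is removed and the two passes
   coincide.
4. **Scores.** `z = (value − fitted)/σ` with
   `σ = 1.4826 × median(|residuals|)`, floored at 1e-6 so a degenerate,
   perfectly flat profile cannot produce infinite z. The MAD is used
   rather than the standard deviation so the planted/true peaks do not
   inflate their own null scale. p-values are one-sided (upper tail):
   only enrichment over the trend constitutes a contact; depletion is
   not called.
5. **FDR.** Benjamini–Hochberg within the window, per library, with
   excluded and blind fragments omitted from the family size.
6. **Replicate concordance.** A fragment is a significant contact only if
   `z ≥ z_threshold` **and** `FDR ≤ 0.05` in *every* replicate. The
   default threshold is `z ≥ 2.0`; baits with intrinsically weaker signal
   (the Srebp1c viewpoint in the motivating design) conventionally use
   `z ≥ 1.5`, set per bait in `bait_config()`.
7. **Merging.** Runs of significant fragments separated by at most
   `merge_gap_fragments = 1` non-significant fragment merge into one
   reported interaction interval with its mean cross-replicate z. No
   published merging rule exists to match; one-fragment gap tolerance
   reflects that a contact spanning several fragments should be one arc,
   and the parameter is explicit.

One additional universe filter matters in practice:
`min_fragment_bp = 100`. A fragment much shorter than a sequencing read
cannot be uniquely mapped in real data, and in simulation a single read
landing on a 10–100 bp fragment produces an RPKM orders of magnitude
above the trend — an artifact that both replicates reproduce, defeating
replicate concordance. Removing sub-read-length fragments from the tested
universe (not merely down-weighting them) restored the caller's null
calibration; this is the standard treatment of tiny fragments in 4C
processing.

## Differential contacts between diets

`call_differential()` implements the average z-score-ratio rule at a
matched timepoint: with `mean_z` the replicate-averaged z per fragment
and condition, a fragment is an HF gain when

$$\frac{\max(\mathrm{mean\_z}_{HF}, \epsilon)}{\max(\mathrm{mean\_z}_{CD}, \epsilon)} \ge 1.5$$

*and* the fragment is a significant contact in HF; symmetrically for CD
gains. The `ε = 0.1` clip defines the ratio when a mean z is non-positive
(a strong contact over a null fragment then yields a large finite ratio);
it is configurable. Requiring significance in the gaining condition
prevents ratios between two noise fragments from ever being reported.

Two properties of this rule are worth knowing. First, it is
anti-symmetric by construction: the two orientations of the clipped ratio
are exact reciprocals, so a fragment is never simultaneously an HF and a
CD gain. Second, a contact significant under only one diet is
essentially always differential — the ratio against a null mean-z is
large by definition. That is the rule's intent (a diet-specific contact
*is* the finding), but it means the rule's specificity is inherited
entirely from the caller's FDR control, and that ratios between two
*moderate* z-scores are noisy: in exchangeable simulations where both
diets share the same true contacts at fold 4, roughly a fifth of the
shared significant fragments fluctuate past ratio 1.5 in one direction.
The package therefore reports the differential rate against the full
fragment universe in its calibration checks, and users comparing
conditions should read the per-fragment table (mean z in both diets, the
ratio and direction) rather than the binary flag alone. An alternative
count-model differential test (negative-binomial Wald) is a documented
non-goal: the z-ratio rule is the primary definition here, and the two
can disagree.

## Temporal classification

Within one diet, merged intervals called at ZT6 and ZT18 are matched by
at-least-1-bp overlap (`classify_temporal()`): overlapping calls at both
timepoints form a *stable* contact, the rest are time-specific. The three
classes partition the union of the two call sets by construction.
Matching could alternatively be done by fragment identity; interval
overlap was chosen because merged intervals, not fragments, are the
reported unit of an interaction.

# Trans-domain segmentation

Trans contacts are sparse at fragment resolution, so signal on each
non-bait chromosome is summed over fixed blocks of `k = 20` consecutive
usable fragments (`make_windows()`), log-transformed, and segmented by a
3-state (no/low/high signal) hidden Markov model with Gaussian emissions
(`segment_hmm()`). The HMM is fitted by EM with 10 seeded restarts, the
maximum-likelihood fit kept (ties broken by the earliest restart), states
relabeled by ascending emission mean so "high" is well-defined regardless
of initialization, and the Viterbi path returned. Standard deviations are
floored at 1e-3 of the track's overall spread to keep EM away from
zero-variance collapse; a perfectly constant track short-circuits to a
single low state and yields no domains. Windows labeled high in at least
`n_required = 2` replicates merge into reported domains
(`call_trans_domains()`).

The fixed-k block windowing is a documented simplification of
adaptive-window trans analyses: it preserves the two parameters that
define the analysis (k = 20 fragments of smoothing, support required in
n = 2 replicates) while keeping the segmentation exactly reproducible
and testable against an independent dynamic-programming Viterbi oracle.
A consequence of fitting 3 states to a chromosome with no real signal is
that the top state will label the upper tail of background noise;
replicate intersection suppresses most of this, but trans domains on
chromosomes with no planted/true signal should be treated as noise floor,
not discoveries.

# Genome context

`tad_overlap()` assigns an interaction interval to a TAD when the
interval is *contained* in the TAD expanded by `tolerance_bp = 200000`
on each side. Containment (rather than 1-bp intersection) reflects the
role of TADs as insulating containers for cis contacts; the looser
intersect rule is available by flag, and TADs may nest (all qualifying
TADs are returned). `fraction_in_bait_tad()` summarizes a call set as the
fraction of merged intervals confined to any TAD containing the bait.

`log2_ratio()` compares two normalized contact matrices on a shared bin
grid as `log2((A + pc)/(B + pc))` with a unit pseudocount by default; it
is exactly anti-symmetric in its arguments. "Increased" bins are marked
by a configurable threshold on this ratio (default ≥ 1, i.e. 2-fold) —
an explicit stand-in definition, since no canonical one exists. Matrix
I/O is dense TSV or 3-column COO; binary Hi-C containers are out of
scope.

# The synthetic-data generator

`sim_config()` fixes the study conditions the package is tested under;
`simulate_counts()` draws libraries from them. The generative model per
fragment:

* cis mean signal follows a power law,
  `mean_rpkm(d) = a (d/1000)^(-α)` with `a = 20000` RPKM at 1 kb and
  `α = 1`, distance floored at 1 kb and measured midpoint-to-midpoint.
  These values put near-bait fragments in the thousands of RPKM and
  fragments at 1–2 Mb at RPKM 10–20 — the orders of magnitude seen in
  real viewpoint profiles, and high enough that a planted fold-4 effect
  shifts the log2 signal by ~2 across the window;
* trans fragments sit at a flat background of 0.5 RPKM, so simulated
  libraries map >99% of reads in cis (well above the 40% QC floor);
* expected counts are `rpkm × fragment_kb × library/10^6` with a nominal
  library of 1e6 reads; raw counts are negative-binomial with
  `var = μ + φμ²` (the DESeq2-style dispersion parametrization). The
  default `φ = 0.05` represents the replicate-level dispersion of a good
  4C library; the caller's null calibration is additionally checked at a
  deliberately noisy `φ = 0.2`. `φ = 0` gives exact Poisson draws;
* planted cis fragments (default: 20 fragments at fold 4, spread over
  0.1–1.5 Mb on both sides) and planted trans window runs (default: one
  run of 120 fragments ≈ 6 windows at fold 8) multiply the mean in their
  active conditions only, so diet- or time-specific contacts can be
  planted with `conditions = "HF_ZT18"`-style masks;
* blind fragments draw zero counts; replicates are independent draws;
  every output is a pure function of `(config, seed)`.

The default map sizes — a 5 Mb cis chromosome with 2000 fragments and a
2 Mb trans chromosome with 800 — keep a full 8-library study under a
second to simulate, and the fragment maps are drawn directly (uniform
internal cut positions) rather than via sequence, since counts only need
coordinates. Sequence-level behavior is exercised separately:
`simulate_genome()` emits uniform-composition random DNA together with a
fragment map computed by its own position-by-position scan, which serves
as an independent oracle for the Biostrings-based digestion.

What the generator does *not* emulate, and hence what passing tests do
not show about real data: mappability and GC structure along the genome,
PCR-duplicate structure, undigested/self-ligation carry-over beyond the
excluded bait-proximal zone, genuinely heavy-tailed biological
variability between animals, and any correlation between replicates.
Recovery and calibration results on this generator are statements about
the caller's statistical machinery under its stated noise model, not
about any particular tissue or diet.

# Numerical and determinism choices

* Isotonic fits use `stats::isoreg` on negated values (non-increasing);
  ties in log10 distance are averaged at prediction time.
* σ floors (1e-6 absolute in the decay fit, 1e-3 relative in the HMM)
  guard degenerate flat inputs; both are documented parameters, not
  hidden constants.
* All simulation, EM-restart and study-level randomness flows from
  explicit integer seeds; `run_study()` derives HMM seeds from its master
  seed, and `write_fixture_bundle()`/`write_study_report()` format
  numbers with fixed precision so identical inputs produce byte-identical
  files.
* BH adjustment and normal tail probabilities come from base R
  (`p.adjust`, `pnorm`); the test suite checks them against a step-up
  brute force and numerical integration respectively, at the sizes where
  exhaustive comparison is feasible.

# Problem sizes used in validation

The shipped checks run the digestion oracle on 100 random genomes of
1–50 kb; the PAVA oracle on 1000 instances of n ≤ 12; caller calibration
on 50 null simulations of 2000 fragments at φ = 0.2; recovery on 10
simulations of the default fixture plus a fold dose-response at
{1.5, 2, 4, 8}; the differential rule against brute force on 200
fragments and 50 exchangeable null simulations; trans recovery of a
30-window block among 300 windows over 5 seeds; and byte-identity of two
full study runs under one master seed. These sizes were chosen so the
entire suite completes in about a minute on one core while every rate is
estimated from at least a few thousand Bernoulli trials.

# Known limitations

* The decay trend is fitted per side with no smoothness beyond
  monotonicity; in very sparse windows the fit is a step function and
  z-scores near step edges are conservative.
* The z-ratio differential rule has no error-rate guarantee of its own
  (see above); treat directions at moderate z with caution.
* Whole-fragment resolution slightly blurs contacts relative to
  fragment-end methods when a contact sits at one end of a long fragment.
* The HMM assumes Gaussian emissions on log2 window sums; for very low
  background (many empty windows) the log transform leaves a point mass
  at zero that the "no signal" state absorbs, which is intended but
  makes the low/no boundary uninformative there.
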