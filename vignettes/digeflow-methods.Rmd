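---
title: "Methods and design notes for digeflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for digeflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digeflow)
```

# The experimental design the package models

digeflow analyzes 2D-DIGE spot intensities from plants sampled under a
normoxic control, after 24 h of anoxia, and after 24 h of subsequent
re-aeration, with three biological replicates per condition and the two
organs (shoot, root) always processed as independent tables. The
central container, `spot_table`, holds a spots × samples intensity
matrix, its sample sheet, and two state flags (`log_transformed`,
`normalized`) so that stages can refuse inputs in the wrong state.
Missing intensities are carried as `NA` throughout; they are never
silently replaced by zero, and all per-condition summaries drop missing
replicates pairwise. PDQuest-style exports do not document how spots
absent from one gel were recorded, so explicit missingness is this
package's own policy.

# Normalization

Intensities are log2-transformed first; fluorescence spot volumes are
strictly positive, heavy-tailed quantities, and replicate noise is
approximately multiplicative, so the package's synthetic generator and
all downstream statistics operate on the log2 scale. Zeros, which occur
when a spot is undetected in one channel, would make the log undefined;
they are replaced by half the smallest positive intensity in the same
sample column and counted in a `zero_replaced` attribute. Half the
observed minimum is the conventional "below detection limit" surrogate;
any choice here is ad hoc, which is why the replacement is flagged
rather than silent.

Quantile normalization then forces every sample column to the common
distribution of mean order statistics. The implementation delegates to
`limma::normalizeQuantiles` (with tie averaging), the standard
microarray-era routine; the test suite verifies it against a by-hand
mean-of-sorted-columns computation and checks idempotence. Ranks within
columns are preserved, so no per-spot ordering across conditions is
affected.

# Per-spot significance

Three frameworks are provided; all test the omnibus condition effect.

**Kruskal–Wallis.** The rank H statistic with tie correction, referred
to the χ² distribution with k−1 degrees of freedom (via
`stats::kruskal.test`). With three replicates per condition (N = 9)
the permutation distribution of H is coarse and the χ² tail is
conservative: simulated null p-values are visibly non-uniform (the
mass sits above the uniform line and rejection at 0.05 occurs in well
under 5% of null spots). This is an intrinsic property of rank
statistics at this sample size, not an implementation artifact; the
package documents it and the acceptance suite records the uniformity
check for this test as failing at desk scale. The test remains useful
as a distribution-free cross-check on spots flagged by the moderated
framework.

**Random-intercept mixed model.** Condition enters as a fixed effect
and a single grouping factor (biological replicate by default, gel
batch optionally — the design descriptions are ambiguous about which
"sample" is the random unit, so the factor is a parameter) as a random
intercept. The variance ratio λ = σ²_b/σ²_e is profiled out of the
REML criterion and maximized by `stats::optimize` (golden-section plus
parabolic interpolation) on log λ with tolerance 1e-8, compared
explicitly against the λ = 0 boundary, and floored at zero. The
condition effect is tested by a Wald F. Denominator degrees of freedom
follow the containment rule N − k − (b − 1) when λ̂ > 0; when λ̂ = 0
the model *is* the one-way fixed-effects model and the test reduces
exactly to the one-way ANOVA F with N − k denominator degrees of
freedom. The unit tests verify the variance components and p-values
against `nlme::lme` whenever λ̂ > 0, and the ANOVA reduction at the
boundary. (nlme keeps the containment degrees of freedom even at the
boundary, so the two implementations differ only there — a deliberate
choice so that the no-block-effect limit is the familiar ANOVA.)

**Empirical-Bayes moderated F.** The one-way model is fitted per spot;
residual variances s²_g on d degrees of freedom are assumed
exchangeable draws from a scaled inverse-χ²(d₀, s₀²) prior. With
e_g = log s²_g − ψ(d/2) + log(d/2), moment matching gives

* ψ′(d₀/2) = var(e) − ψ′(d/2), solved by Newton inversion of the
  trigamma function (tolerance 1e-8, 100-iteration cap), and
* s₀² = exp(mean(e) + ψ(d₀/2) − log(d₀/2));

when var(e) does not exceed its sampling expectation under a common
variance, d₀ = ∞ and s₀² is the pooled mean variance. The posterior
variance s²_post = (d₀s₀² + d s²_g)/(d₀ + d) replaces s²_g in the F
statistic, which gains the prior degrees of freedom in its
denominator. The implementation is written from the closed forms and
is cross-checked in the tests against limma's `lmFit`/`eBayes` (exact
agreement of d₀, s₀², s²_post, F and p on toy tables). This moderated
framework is the package default for significant-spot selection, at
BH-adjusted p < 0.05 — the threshold itself is a configurable
convention, since reports of "significantly different" spots in this kind of
experiment rarely state the α used.

"FDR" and "BH" are the same step-up procedure; the package exposes
`{BH, Holm}` and accepts `FDR` as an alias of BH rather than
pretending three distinct corrections exist.

# Clustering and partition concordance

Samples (and optionally spots) are clustered on Euclidean distances of
normalized log2 intensities — the natural metric once columns share a
distribution; it is a parameter, not a hard-coded choice. k-means uses
k-means++ seeding with 10 restarts feeding `stats::kmeans` (Lloyd
iterations), keeping the lowest within-cluster sum of squares;
everything is deterministic given the mandatory seed. The elbow choice
of k is automated as the arg-max of the discrete second difference
WSS(k−1) − 2·WSS(k) + WSS(k+1), replacing manual inspection; the WSS
curve is attached to the result so a human can override. Hierarchical
clustering is complete-linkage on the distance matrix, with k chosen
by maximal mean silhouette width (`cluster::silhouette`) over
2…min(8, n−1), ties resolved to the smaller k.

Concordance between two partitions K and M is the sum over the
partition with more clusters (ties: the first argument) of the
best-matching set coefficient against the other partition, divided by
max(|K|, |M|). A joint index pairing (K_i with M_i) is undefined for
partitions of different sizes; the
best-match ("maximal Simpson coefficient") reading is adopted because
it reproduces S = 1 for identical partitions and matches the verbal
description. With the Simpson coefficient S = 1 means every smaller
cluster is embedded in a larger one; with Jaccard S = 1 only for
identical partitions. Note that this one-sided best-match score is not
symmetric in its arguments even for equal cluster counts; the ordering
convention (larger partition, ties to the first argument) is therefore
part of the definition.

# Trajectory classification

Spot condition means (C, A, R) are classified into four groups by a
total, scale-free rule: A strictly maximal → group 2 (anoxia-specific
peak); A strictly minimal → group 4 (anoxic dip, re-aeration
recovery); otherwise non-increasing C ≥ A ≥ R → group 1 (continuing
decline); everything else → group 3 (continuing accumulation).
"Strictly" uses a relative tolerance δ (default 0.05): x exceeds y
only when x > y(1+δ), so changes below 5% count as flat. The four
groups are conventionally described verbally, without quantitative
boundaries; this rule is the package's formalization, chosen because
it is total, invariant to positive rescaling, and reproduces every
per-protein verbal description of the annotated significant proteins
(13 shoot + 8 root), yielding the published group composition —
10 + 6 proteins in the continuing groups 1 and 3, i.e. 76% of the
annotations, with 3 anoxia-specific and 2 reoxygenation-specific
proteins. Those 21 encoded profiles ship as `annotated_profiles()`;
the numbers are qualitative renderings of the published descriptions
(only the ordering pattern matters), not measured intensities.

The condition-of-maximum label used for promoter grouping breaks ties
in the fixed order control > anoxia > re-aeration.

# The synthetic-data generator

`generate_spot_table` draws raw intensities as
2^(base + pattern·effect + N(0, σ)) with per-group condition patterns
(multiplying the log2 effect size):

| group | control | anoxia | re-aeration |
|-------|---------|--------|-------------|
| 1     | +1      | −0.5   | −1          |
| 2     |  0      | +1     | −1          |
| 3     | −1      | +0.5   | +1          |
| 4     |  0      | −1     | +1          |

Groups 1 and 3 carry the anoxia-initiated change into re-aeration, so
when they dominate a table the anoxic and re-aerated samples resemble
each other more than either resembles control — the qualitative
clustering behavior seen on real gels. Defaults are base 10 log2 units
(raw fluorescence around 10³ arbitrary units), effect 2 log2 units (a
four-fold swing, typical of clearly differential spots), noise σ = 0.3
on the log2 scale for general use; recovery benchmarks use σ = 0.1
with 20 spots per group, the regime in which a well-behaved classifier
should be near-perfect. The generator returns ground-truth labels, and
with σ → 0 classification is exact by construction.

`generate_promoters` draws i.i.d. backgrounds with the requested AT
fraction (no dinucleotide structure — real promoters have it, so AT
profiles of synthetic data are flat where real ones undulate), plants
IUPAC-realized motif copies at non-overlapping uniform positions on
random strands (rejection sampling, bounded retries), and records the
ground truth. By default, background windows that happen to match a
planted consensus on either strand are resampled, so the recorded
truth is exactly the scanner's expected output; this is what makes
hit-set equality a meaningful fidelity test. `generate_peaklist`
unions tryptic digest masses of a target and contaminant protein over
the 700–3500 Da scan window with uniform noise peaks. A
synthetic trypsin-like sequence ships as a fixture for the autolysis
examples (labelled synthetic; users supply the real protease sequence
of their batch).

What passing tests on these generators do *not* show: robustness to
gel warping, dye bias, spatially correlated spot overlap, missing-gel
structure, or promoter sequence composition beyond i.i.d. backgrounds.

# Protein physicochemistry

Molecular weights are residue-mass sums (average masses for
protein-level reporting, monoisotopic for peptides) plus one water;
the fixed cysteine carbamidomethylation (+57.02146 Da) is applied to
peptide fingerprint masses, matching iodoacetamide sample preparation,
and variable methionine oxidation (+15.99491 Da per site) can be
enabled to emit additional candidate masses (off by default so digest
listings stay minimal). Peptides can be reported as singly protonated
[M+H]⁺ (+1.007276 Da), the MALDI MS1 convention.

Isoelectric points solve Z(pH) = 0 by bisection on [0, 14] to 1e-3 pH
units, where Z sums Henderson–Hasselbalch terms for the termini and
the ionizable side chains. The EMBOSS pKa set is the default, with the
Bjellqvist (ExPASy-style) set selectable: both are widely used, and
the choice shifts pI by a few tenths of a unit without affecting
ordering. Z is strictly decreasing in pH and the termini guarantee a
sign change, so bisection always converges.

Tryptic digestion cleaves after K/R except before P, enumerating
peptides with up to the requested missed cleavages (default 2,
matching common search settings); concatenating the zero-missed
fragments reconstructs the input, which the property tests exploit.
Autolysis filtering removes peaks within a ±0.8 Da window (the MS1
peptide tolerance) of any contaminant mass and returns the removal
log. Rf-based molecular-weight estimation interpolates linearly in
(Rf, log10 MW) space between ladder anchors — gel migration is
approximately linear in log mass — and extrapolation outside the
anchors is flagged rather than refused.

# Promoters and binding sites

Upstream regions use 1-based negative offsets, −1 adjacent to the
annotated gene start. For a + strand gene starting at s the promoter
is genomic [s−500, s−1]; for a − strand gene ending at e it is the
reverse complement of [e+1, e+500]; contig-edge truncation shortens
the region and sets a flag. GFF3 is read with `rtracklayer`, sequences
with `Biostrings`.

Scanning matches IUPAC consensi exactly against degeneracy classes on
both strands (`Biostrings::matchPattern` with `fixed = FALSE`), and
position-weight matrices at a log-odds threshold defaulting to 80% of
the maximal achievable score — a common screening default; there is no
published threshold to inherit, so it is configurable. Overlapping
hits are all reported; collapsing policies vary across tools and any
collapsing is left to the caller. Minus-strand hits are reported at
their leftmost promoter coordinate so that hit sets from a sequence
and its reverse complement mirror exactly, a property the tests check.
Family summaries (percent of genes with ≥1 site; mean sites per gene,
zeros included) are computed over an explicit gene universe, optionally
split by the condition-of-maximum grouping, and are verified against
brute-force recounts. The bundled motif library is a small curated set
of published plant consensus elements (W-box, GCC-box, TATA box, MYB,
TCP, SBP, bZIP cores) intended for demonstrations and tests; real
analyses should load a full library TSV.

# Orchestration and problem sizes

`run_pipeline` chains the stages from a validated YAML configuration
with a mandatory seed, writes one TSV per stage plus a timestamped
parameter log, fails with the offending stage named while retaining
partial outputs, and supports a dry run that validates without
computing. The package's exported functions are the intended
programmatic surface; the pipeline driver is a convenience, not a
separate tool.

The test and acceptance workloads run at desk scale by design:
1,000-spot null tables for calibration checks, 500 seeded repetitions
for the false-discovery summary, 20 spots per trajectory group for
recovery, 30 × 500 bp promoters for scanner fidelity. These sizes give
stable Monte-Carlo estimates (binomial standard errors well below the
margins being asserted) while keeping a full run in the tens of
seconds.

# Known limitations

- The Kruskal–Wallis χ² approximation is conservative and discrete at
  n = 3 per condition (see above); its null p-values are not uniform
  at this design size.
- The mixed model fits a single variance component; crossed or nested
  multi-factor random structures are out of scope.
- Moderated testing is the omnibus condition F; pairwise moderated
  contrasts between specific conditions are not provided.
- The concordance score is a one-sided best-match index, asymmetric by
  definition; report the argument order alongside the score.
- Synthetic promoters are i.i.d.; positional AT structure and motif
  clustering in real promoters are not emulated, so positional-profile
  tests only exercise bookkeeping, not biology.
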