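---
title: "Detection-aware differential proteomics of two-organism cocultures"
author: "monomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection-aware differential proteomics of two-organism cocultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Label-free data-dependent acquisition (DDA) LC-MS/MS quantifies whatever the
instrument chooses to fragment. In every survey scan only the most intense
precursor ions — a "top N", typically the top 12 — are selected, so an ion's
chance of being identified grows with its abundance and shrinks with the
abundance of everything else eluting at the same time. When a phototrophic
alga hosts a heterotrophic bacterium that contributes at most ~10% of the
community biomass, the digest of a coculture pellet is dominated by algal
peptides. At a fixed injected peptide load, bacterial precursors are
systematically out-competed: fewer bacterial proteins are detected in
coculture than in a bacterial monoculture, and the ones still detected are
quantified from fewer peptides. A standard differential expression contrast
of coculture against the bacterial monoculture then reports a large share of
the bacterial proteome as "significantly decreased" — an artifact of
acquisition, not biology.

monomix implements both halves of the response to this problem:

1. an analysis pipeline whose steps (parsimony inference, roll-up,
   per-organism quantile normalization, limit-of-quantitation-gated Welch
   tests) match the established processing conventions for such data, and
2. a desk-scale simulator of the acquisition process itself, with ground
   truth, so that the artifact, the matched "mono-mix" control, and the
   benefit of peptide fractionation can be demonstrated and the pipeline's
   statistical behavior audited.

## The acquisition model

A simulated sample is a set of peptides with on-column amounts. For organism
$o$ with biomass fraction $f_o$ and total injected load $L$ (default 0.5 µg,
a 5 µl injection of a 0.10 µg/µl digest), each peptide–parent pair
contributes

$$ a = L \cdot f_o \cdot \frac{b_p \cdot \iota}{\sum_{o} b \cdot \iota} $$

where $b_p$ is the parent protein's relative copy mass (log-normal across
the proteome, `sdlog = 1.5` on the natural-log scale, spanning roughly four
orders of magnitude) and $\iota$ a per-peptide ionization efficiency
(log-normal, `sdlog = 0.7`). A peptide's amount is the sum over its parents;
amounts are conserved exactly by mixing and by fractionation (the mass
balance is tested to 1e-9 relative).

Acquisition proceeds window by window: peptides are ranked by a
hydrophobicity proxy (the Kyte–Doolittle GRAVY of the peptide sequence plus
a small uniform jitter — a monotone stand-in for retention time, which is
all the mechanism requires) into `n_rt_windows` equal-count retention-time
windows. Within each window up to `top_n` peptides are drawn without
replacement with probability proportional to
$a^{1/\texttt{selection\_softness}}$; softness 0 is deterministic top-N.
Dynamic exclusion is modeled implicitly: each peptide has one selection
opportunity per window. Selected peptides above the detection floor are
reported with abundance $a \cdot G \cdot 2^{\epsilon}$,
$\epsilon \sim N(0, \texttt{noise\_sigma}^2)$; unselected peptides are
absent from the output — missing, never zero. The detector gain $G$
(default $10^9$ counts/µg) puts reported values on the positive
extracted-ion-area scale (log2 values around 15–25). This matters: the
roll-up convention below *sums* log2 values, which only behaves sensibly
when they are positive, as they are for real area measurements.

Two defaults are calibrated against external anchors rather than chosen
freely:

* `selection_softness = 0.2`: replicate injections of a competitive
  (coculture-like) sample then share about 75% of their peptide
  identifications, the run-to-run reproducibility typical of DDA. A fully
  abundance-proportional draw (softness 1) gives ~33% overlap — an
  unrealistically erratic instrument; near-deterministic selection gives
  ~100% — unrealistically exact.
* `n_rt_windows = 90` (with `top_n = 12`, a per-run capacity of 1080
  peptides): at the default composition, coculture then detects roughly
  half the bacterial proteins seen in bacterial monoculture, the
  proteome-wide suppression magnitude observed on real instruments.

The remaining defaults state the experimental world: proteome sizes 460
(alga) and 100 (bacterium), preserving the ~4.6:1 protein-entry ratio of the
real search databases at desk scale; 6 observable peptides per protein on
average; a 5% peptide-sharing rate (2% of shared peptides crossing
organisms); 3 biological replicates with a per-replicate log2 sd of 0.25
(~19% CV); `noise_sigma = 0.3` (~23% CV) measurement noise; and a mono-mix
target-ratio error with log2 sd 0.5, reflecting the roughly two-fold
uncertainty of CFU-based bacterial density estimates (the reason matching a
mono-mix to its parallel coculture is hard in practice).

Fraction concatenation bins peptides into `n_fine_bins = 110` fine
hydrophobicity bins (one per collection minute of a typical high-pH
reversed-phase separation) and deals the bins round-robin into 1, 6, 12 or
24 fractions, each then acquired as an independent run. Every randomness
source derives from one master seed through a fixed affine splitting rule
(documented in the code), so experiments are reproducible sample-by-sample
and fraction-by-fraction.

### What the generator does not emulate

No m/z domain exists: no spectra, fragment ions, chromatographic peak
shapes, charge states, FAIMS separation (treated as part of overall
capacity) or search-engine FDR. Peptide sequences are random tryptic-like
strings, so sequence-level effects (missed-cleavage chemistry, modification
states) are out of scope. A green simulation-based test therefore
establishes that the *statistical* structure — fixed load, abundance-biased
selection, abundance-dependent missingness, replicate noise — behaves as
designed; it says nothing about spectrum-level processing.

## Quantification

**Parsimony.** Each peptide is assigned to exactly one of its candidate
proteins by the first deciding rule: (a) unique mapping; (b) exactly one
candidate also carries a *different* uniquely-mapping peptide (if several
candidates qualify the rule does not decide); (c) the candidate with
strictly the most other non-uniquely-mapping peptides; (d) the candidate
appearing first in the concatenated search database. Rule (d)'s "similar
maximal counts" is read as *exactly equal* counts after (c) — the only
testable reading. The implementation is validated against a brute-force
oracle that applies the rules literally.

**Roll-up.** Peptide abundances are log2-transformed and mean
central-tendency normalized (each sample shifted additively so its mean
equals the grand mean of per-sample means; fractionated and unfractionated
batches are processed separately), then grouped by gene and summed per
sample. Summing *log2* values is the stated convention of the simple
roll-up; it weights abundant peptides heavily and makes a protein's value
grow with its detected peptide count. Note the consequence: a true k-fold
change in a protein detected by $m$ peptides moves its rolled-up value by
$m \log_2 k$, so fold changes on this scale are peptide-count amplified.
Because the alternative — summing intensities and taking one log —
keeps protein fold changes on the peptide fold-change scale, it is exposed
as `mode = "log2_sum"`; the default remains the literal convention.
A peptide observed in several fractions of one sample is summed into that
sample before roll-up. Genes unobserved in a sample are missing, never
zero, and missing values are excluded everywhere, never imputed.

**Quantifiability filter.** Retained genes need at least two distinct
unique (single-candidate) peptides in some sample and detection in at least
two replicates of at least one condition.

## Normalization and testing

**Per-organism quantile normalization.** The two organisms' abundance
distributions differ by construction (the biomass ratio), so each
organism's submatrix is normalized separately. With complete data the
algorithm is the classic one: sort each sample, average rank-wise,
substitute. With missing values, each sample's observed values are mapped
onto the mean empirical quantile function (linear interpolation between
order statistics, grid $p_r = (r-1)/(n-1)$ over its own observed count);
ties receive the mean of their reference values. This reproduces the
complete-data behavior exactly and is deterministic under DDA missingness.
Samples with no observed values for an organism are left untouched.

One caveat discovered while validating at desk scale: with only a few
hundred quantified proteins per organism, the upper tail of the reference
distribution is sparse (neighboring order statistics 0.5–1 log2 unit
apart), so quantile substitution converts small rank jitter into sizable
value jitter for the most abundant proteins. At instrument scale
(thousands of proteins) the effect is minor. The package therefore allows
every downstream analysis to run on either the normalized or the
unnormalized matrix.

**Limit of quantitation (LOQ).** Mean minus two standard deviations of all
quantified log2 values in scope. The scope is per organism by default —
consistent with per-organism normalization — with a pooled "experiment"
scope available, since either reading of "in the experiment" is defensible.

**Differential expression.** Per gene with ≥2 non-missing replicates in
both arms: Welch's t-test on log2 values; fold change = mean(treatment) −
mean(control); Benjamini–Hochberg adjustment per organism over exactly the
tested genes. A call is significant only when |log2FC| > 1, adjusted
p < 0.05, *and* the mean abundance exceeds the LOQ in both arms. Genes with
zero variance in both arms are handled explicitly: equal means give p = 1;
unequal means are flagged degenerate and left untested — a degenerate gene
is never silently significant. Group-level comparisons use the two-tailed
Student's t-test on detected-protein counts and the Wilcoxon rank-sum test
on per-protein replicate-averaged abundances of genes detected in both
groups.

At n = 3 this design has limited power by construction: for a true 4-fold
change measured with ~0.3–0.45 log2 replicate scatter, the Welch statistic
(df ≈ 4) yields raw p around 0.002–0.01, and BH adjustment over a few
hundred tests leaves adjusted p hovering near 0.05. Recovery of individual
effects at n = 3 is therefore partial even in matched designs — consistent
with how few significant calls such experiments yield in practice — while
estimated fold changes on the intensity scale remain accurate (median
absolute error ≈ 0.3 log2 units in the validation suite).

**Z-scores, clustering, ordination, enrichment.** Per-protein condition
means are standardized across conditions (sd 0 profiles are flagged and
zeroed). k-means uses `iter.max = 1000` with 25 seeded restarts (restart
count is not part of the stated convention; 25 is a safe default) and an
inertia elbow curve over k = 1..k_max. PCA runs on proteins above the LOQ
and complete in every sample, column-centered and unscaled (the cited
implementations' default; scaling is an option). Term enrichment is the
one-sided hypergeometric over-representation test with Holm adjustment;
the default background is the organism's quantified-protein universe
(configurable — the appropriate universe is a judgment call), and terms
with fewer than two universe members are not tested.

## Physicochemical profiling

Isoelectric point: bisection (tolerance 1e-4 pH) on the
Henderson–Hasselbalch net charge using the EMBOSS pKa set (termini 8.6/3.6;
side chains C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1). GRAVY:
mean Kyte–Doolittle hydropathy. Molecular weight: Expasy average residue
masses plus one water. The value tables are embedded as named constants
with these sources; nonstandard letters are excluded from charge and GRAVY
with a warning and assigned the mean residue mass for MW. In-silico
digestion cleaves after K/R except before proline, with 0–1 missed
cleavages and peptide length 6–40 — the standard tryptic convention, since
no specific rule set is mandated by the upstream tools.

## Degenerate inputs and numerical choices

* Quantile grid $p_r=(r-1)/(n-1)$; a single observed value maps to the
  reference median ($p = 0.5$).
* Parsimony ties beyond rule (d) cannot occur (database order is strict).
* Empty compositions acquire to empty observation tables; empty
  significant lists enrich to empty results; empty matrices filter to
  empty matrices — all without error.
* Detection floor, not zero-filling, decides reportability; observed
  tables never contain zeros or infinities.
* All Monte-Carlo tolerances in the validation suite are stated as
  binomial or standard-error bounds at the simulated sample size.

## Limitations

* The simulator is a mechanism model, not a spectrum simulator; absolute
  detection counts are meaningful only relative to its own capacity
  parameter.
* The sum-of-log2 roll-up ties protein values to detected peptide counts;
  fold changes on that scale are count-amplified and should be interpreted
  qualitatively. Use `mode = "log2_sum"` when fold-change magnitudes matter.
* Quantile normalization at small protein counts adds top-tail noise (see
  above); at desk scale the unnormalized matched analysis can be the more
  powerful one.
* Isoform-level inference is out of scope: quantification collapses to
  genes, as the grouping convention dictates.
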