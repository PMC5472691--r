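---
title: "hyenabiome: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hyenabiome: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: what each stage
assumes, which knobs matter, what the synthetic world does and does not
emulate, and where a genuinely open design choice was made. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The study design being emulated

The pipeline targets multi-amplicon metabarcoding of carnivore feces: a
48 × 48 amplification array (a handful of bacterial 16S targets, the rest
eukaryote 18S), technical replicates per sample, water wells as negative
controls, and a companion McMaster flotation count of parasite eggs and
oocysts on a sample subset. Hosts carry two factors of interest: age class
(juvenile below 24 months, adult at or above) and, for adult females, a
standardized dominance rank distributed evenly over [-1, +1] with the median
scored 0; ranks of 0 or above are "high". Juveniles carry no rank — the
rank analysis concerns adult females only, and how juvenile rank would
relate to maternal rank is left open deliberately.

## Read preparation

**Quality filter.** Each mate is truncated at the first base with quality
at or below `truncQ = 2`, then cut to `truncLen = 170` bases; a pair is
rejected if either mate is then shorter than 170, contains any N
(`maxN = 0`), or carries more than `maxEE = 2` expected errors, where
`EE = sum(10^(-Q/10))`. These are the upstream tool's published settings and
are the package defaults.

**Primer stratification.** A pair joins an amplicon only when the forward
primer matches read 1 *starting at base 1 with zero mismatches* and the
reverse primer likewise matches read 2. IUPAC degeneracy in a primer counts
as a match; an N in a read never does. Three decisions here were open and
are the package's own:

* *Order of operations*: filtering precedes primer matching (truncation is
  applied pre-trim). Primers sit well inside the first 170 bases, so the
  assignment is unchanged relative to trim-first; doing it in this order
  lets one quality pass serve all amplicons.
* *Multi-matching pairs* (possible under degenerate overlap) go to the
  panel entry with the longest combined primer; an exact tie is left
  unassigned with a warning — deterministic and conservative.
* Reads shorter than the primer are unassigned, not an error.

## Variant inference (simplified by design)

The published error-model denoiser is an external algorithm; the package
replaces it with a fully specified stand-in that preserves the pipeline
contract. Reads are dereplicated exactly; unique sequences are visited in
decreasing abundance (ties broken lexicographically, so the order is total
and reproducible) and absorbed into the most abundant retained center within
Hamming distance `d_max = 1` whenever `count <= skew^d * count(center)` with
`skew = 0.1`. The rule is monotone in abundance and conserves reads when
`min_count = 1`. What is lost relative to a learned error model: no
quality-aware error rates, no pooled multi-sample inference — a deliberate
non-goal. At desk-scale depths the demo config uses `min_count = 2`:
singleton uniques are not callable as variants by any method, and dropping
them keeps the variant table to genuine templates and chimeras.

Mates are concatenated (forward + 10 × N + reverse-complement of reverse)
*before* collapsing, so each variant is one full concatenated sequence; the
N spacer never contributes classifier words because non-ACGT k-mers are
skipped.

**Bimera removal.** A variant is flagged in a sample when two distinct
parents, each at least twice as abundant there, reconstruct it exactly as
prefix-of-A + suffix-of-B; a variant flagged in a majority of the samples
where it occurs is removed table-wide, and the most abundant variant of an
amplicon is never removed. The 2× parent rule and the majority vote are this
package's documented defaults — the source analysis names no chimera
parameters.

## Replicate QC and normalization

Failed PCRs are found by complete-linkage hierarchical clustering of
Euclidean distances between log10(1 + count) replicate profiles, cut at
k = 2; the cluster holding the majority of water controls is the failure
cluster (ties go to the cluster with the lower mean total). Distance,
linkage and cut were unstated upstream; these were chosen for determinism
and because failed-vs-working PCRs are strongly bimodal. Surviving technical
replicates are summed per sample.

Two depth corrections coexist, mirroring the analysis split upstream:
*rarefaction* (multivariate hypergeometric subsampling to the smallest
sample total) for diversity estimates, where presence inflation matters
most, and *median scaling* (every sample's total scaled to the median
total — the only single-scalar reading of "scaling by the median of the per
sample counts" that makes samples comparable) for ordination, PLS and the
correlation screen. Differential abundance uses neither: it has its own
size-factor offsets.

## Taxonomy

The classifier is the classical naive-Bayes k-mer machine with
database-frequency smoothing: with `n(w)` of `N` references containing word
`w`, the prior is `Pr(w) = (n(w)+0.5)/(N+1)` and
`P(w|g) = (m(w,g)+Pr(w))/(M(g)+1)` over the `M(g)` references of genus `g`;
duplicate reference sequences of a genus count once. A query scores
`sum(log P(w|g))` over its 8-mers; 100 bootstrap resamples of `floor(W/8)`
words give per-level confidence as agreement with the winner's lineage, and
levels below `min_boot = 0.5` (the assignment tool's default; the source
states none) become UNDEFINED. Score ties — which arise exactly when a
query has no database support — are broken at random inside the bootstrap so
confidence splits rather than fixating on the first genus.

Genus agglomeration sums counts over variants sharing a genus, across
amplicons, then applies the exclusion ladder in its narrative order:
(1) variants without an informative genus (NA or any of
undefined/uncultured/unidentified/environmental/metagenome/incertae sedis,
case-insensitively); (2) genera that are the sole genus of their phylum;
(3) genera with an undefined phylum. Each drop count is logged. Phylum
accounting reports named-phyla totals and full totals including UNDEFINED
per domain, with functional roles (microbiome, eukaryome, parasites, food
items, passing material, undetermined) attached from a total role map.

## Coprology

The McMaster conversion is `epg = sum(chambers) * dilution /
(4 * 0.15 ml) = 25 * sum(chambers)` at the stated 1:15 dilution — the unique
multiplier consistent with published minimum non-zero intensities of 25.
Prevalence is positives/examined to one decimal (round-half-even);
intensity statistics are computed over positive samples only (the standard
"intensity of infection" convention), with a t interval for the mean (lower
bound floored at zero, raw value retained alongside) and an exact binomial
order-statistic interval for the median (NA below six positives, where
two-sided 95% coverage is unattainable). The published tables' own CI
method is unstated; this package's choice is documented here, not asserted
as theirs.

The correlation screen computes Spearman's rho (average ranks; two-sided p
from the t approximation on n-2 df, the standard tool's behaviour for n ≈ 32
with ties) between each morphotype's summed-size-class egg counts and
*every* node of the count hierarchy — genus through phylum plus declared
genus sets such as the coccidian genera whose oocysts are morphologically
indistinguishable — and reports the top four with an agreement flag
(target genus, ancestor of one, or declared set containing one).
Zero-variance nodes yield NA and are excluded from ranking. The predictive
companion model is OLS of `log10(1+FEC)` on `log10(1+count)`.

## Diversity and group tests

Chao1 uses the bias-corrected form `S + f1(f1-1)/(2(f2+1))` (defined at
`f2 = 0`, the standard tool's default); Shannon and Pielou use natural
logarithms, with `J = NA` below two taxa. Group comparisons use an exact
Mann-Whitney test whose two-sided p comes from the full permutation
distribution of the rank-sum, computed by a shift-algorithm dynamic program
over doubled midranks (integers even under ties) — equivalent to complete
enumeration, at polynomial cost. "Two-sided" doubles the smaller tail and
caps at 1; conventions differ under ties, so this one is stated explicitly.

## Composition

Bray-Curtis dissimilarities are computed on log10(1+x)-transformed
abundances; a pair of empty samples has no defined dissimilarity (NA).
Ordination is non-metric MDS (Kruskal stress-1, monotone regression),
best-of-restarts with the first start metric and the rest random — the
figure caption's "non-metric" is taken over the text's bare "MDS".

PLS-DA is NIPALS PLS1 on a ±1-coded response over column-centered
predictors. Leave-one-out cross-validation refits on n-1 samples and
classifies the held-out sample by the sign of the predicted response (the
source states no rule; sign of a ±1 response is the natural one); the
smallest axis count attaining maximal LOO accuracy is retained. One
calibration subtlety, verified in the acceptance suite: selecting the axis
count by maximal CV accuracy biases the *reported* accuracy upward under a
null, so the permutation-null check is run at a fixed single axis, where
the LOO classifier is chance-level as it should be.

Loading enrichment takes the axis-1 loading — or the elementwise product of
axes 1-2 when the model retained two or more, the "combined by
multiplication" reading; whether the published combined test used product
quartiles or a union of per-axis quartiles is ambiguous, and product is the
default here. Quartile boundaries are the 25th/75th percentiles with
boundary ties included (conservative and deterministic). The 2×2 tables are
tested with a Fisher exact test whose two-sided p sums hypergeometric
probabilities not exceeding the observed table's; the odds ratio is the
sample `ad/bc` (infinite over a zero denominator), a documented divergence
from the conditional-MLE OR of the standard implementation — their p-values
agree, and the tests assert that.

## Differential abundance

Median-of-ratios size factors (reference taxa positive in every sample;
fallback to taxa positive in ≥90% of samples with geometric means over
positive entries; a logged last resort of total-count ratios when even that
set is empty — synthetic genus tables are sparser than deep real surveys),
rescaled to geometric mean 1 and used as GLM offsets. Each taxon gets a
log-link negative-binomial GLM with its own maximum-likelihood dispersion
(method-of-moments initializer and fallback; no information sharing across
taxa — the reference tool's empirical-Bayes shrinkage is a documented
simplification out of scope), a likelihood-ratio test against the
intercept-only model at the *same* dispersion, chi-squared with 1 df, and
Benjamini-Hochberg adjustment over tested taxa only; taxa with fewer than
three positive samples are reported NA and excluded from the family.

## The synthetic world

`generate_truth()` states the emulated cohort: 35 adult females + 7
juveniles by default, log-normal genus abundances over a built-in pool of
65 genera across 17 phyla (about one third the named-genus richness of the
real survey, so effect sizes are scaled to the pool), an age effect of +5
bacterial genera in adults over a juvenile mean of 14 (mirroring reported
medians of 41 vs 49 at pool scale), a rank effect of +8 eukaryote genera in
high-ranking hosts, and a small always-present core (host *Crocuta* DNA and
three ubiquitous gut bacteria) — real fecal samples always contain both,
and the core anchors median-of-ratios size factors exactly as in real data.
Parasite lineages in the pool are real (e.g. *Ancylostoma* under
Rhabditida), so ancestor recovery in the correlation screen is meaningful.

`generate_reads()` emulates primer-prefixed paired reads with exact depth
per ordinary replicate, per-base substitution errors (0.002), chimeras as
two-parent prefix/suffix splices within an amplicon (1-2% by default, with
the junction kept inside the 170-base retained window so a chimera remains
distinguishable after trimming), PCR failures at 5% with near-zero Poisson
depth, water controls receiving only Poisson(5) cross-contamination, flat
per-read quality with a low-quality fraction and occasional early Q≤2
bases, and rare N bases. Egg counts follow
`log10(1+FEC) = a + b log10(1+abundance)` with negative-binomial
overdispersion on counted eggs, split multinomially over four chambers and
size classes.

What the generator does **not** emulate — and hence what a green test does
not establish: realistic error-rate structure along the read (quality is
flat per read), index hopping and primer-dimer artifacts, length variation
among amplicons of one target, chimeras spanning the reverse mate,
phylogenetically structured sequence similarity (references are random
sequences, so the classifier task is easier than against real SILVA-style
databases), and compositional coupling between taxa. Recovery results on
this world are contracts on the *pipeline logic*, not benchmarks of
sensitivity on real data.

One numerical note on the coprology coupling: at low abundance the McMaster
discretization (25 epg per counted egg) dominates the signal, attenuating
fitted log-log slopes regardless of the statistical machinery — a real
phenomenon, not an implementation artifact. The slope-recovery check
therefore states its low-noise regime explicitly (abundance meanlog 5,
dispersion 0), where the fitted slope is within ±0.05 of the true value.

## Known limitations

* The variant collapser is single-sample and quality-blind; rare true
  variants below the skew threshold of an abundant neighbour are absorbed.
* Dispersion estimation per taxon is noisy at small n; without shrinkage,
  power is below that of the reference empirical-Bayes tool.
* The classifier reports one lineage per reference database; conflicting
  taxonomies (a known issue for coccidian genera) must be reconciled by the
  user upstream.
* Exact Mann-Whitney cost grows with the squared total midrank sum; it is
  comfortable for cohort-scale n (≤ ~60 per group), not for thousands.
* `flag_failed_replicates()` requires at least one water control; without
  one it errors and suggests a threshold-based fallback rather than
  guessing.
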