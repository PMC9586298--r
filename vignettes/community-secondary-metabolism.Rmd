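---
title: "Modeling community-modulated secondary metabolism with cocomet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling community-modulated secondary metabolism with cocomet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocomet)
```

# The problem

Soil bacteria carry dozens of biosynthetic gene clusters (BGCs) — groups of
co-located genes that build secondary metabolites such as siderophores and
antibiotics — and most of those clusters are quiet in monoculture.  A
three-member model community (denoted B, F and K throughout this package,
for a *Bacillus*, a *Flavobacterium* and a *Pseudomonas*) makes it possible
to ask, factorially, how the presence of each neighbor changes (i) the
expression of each member's BGCs and (ii) the community metabolome measured
by untargeted LC-MS.  `cocomet` implements the computational half of that
experiment: expression quantification and effect sizes at the BGC level, a
per-molecular-feature factorial interaction model, knockout-anchored
presence/absence accounting, and ordination/clustering reports — together
with a synthetic study generator that plants known ground truth so every
stage can be tested for parameter recovery.

# The study design

Seven culture conditions (three monocultures, three pairwise cocultures,
and the full three-member community) plus sterile media blanks, with five
replicates each, are grown in two parallel genotype series: one with
wild-type K and one with a koreenceine-null (Δkec) K mutant that cannot
make the koreenceine family of alkaloid antibiotics.  `study_layout()`
builds this design (75 samples by default).  A sample sheet carries
`sample_id`, `condition` (a letter-set string over `BFK`, or `media`),
`genotype`, `replicate`, and a `series` column (`wt`/`kec`/`media`).  The
`series` column exists because the genotype alone cannot reconstruct the
two experimental batches: conditions without K carry genotype
`not_applicable` in *both* series, yet each series has its own set of
K-free cultures.  When the column is absent, `read_sample_sheet()` derives
a single wild-type series from the genotypes.

# BGC-level expression

Gene counts (one count matrix with `genome:gene` ids; genes of species
absent from a sample are zero) are scaled to counts per million with
`cpm()` — plain library-size scaling, with no between-sample normalization
factors, because that is the simplest defensible reading of a CPM-only
workflow; the choice is exposed as `cpm_method` in the configuration.
Genes whose maximum CPM across all samples falls strictly below the 2.5th
percentile of their genome's maxima are removed
(`low_expression_filter()`); percentiles use linear interpolation between
order statistics (R's `quantile(type = 7)`), fixed so that results are
reproducible across environments.  We read "maximum expression across
replicates" as the maximum over all samples of the experiment; a
per-condition alternative would be stricter, and the percentile is a
configuration value so either policy can be explored.

Fold changes use a pseudocount effect-size estimator on counts:

$$\Psi(k_A, k_B) = \frac{\psi_0(k_A + \tfrac12) - \psi_0(k_B +
\tfrac12)}{\ln 2} - \log_2 \frac{L_A}{L_B},$$

where $\psi_0$ is the digamma function and $L_A, L_B$ are library sizes.
This posterior-mean log~2~ fold change is finite for any non-negative
counts (including 0 vs 0), antisymmetric, and converges to the naive
$\log_2$ ratio for large counts.  `lfc_table()` applies it per gene or per
BGC region to each coculture-vs-monoculture contrast, summing counts
across replicates (and across member genes for regions) with library
sizes summed correspondingly; library sizes are per-genome totals, since
upstream read splitting assigns each read to its source genome.  The
estimator is applied to raw summed counts rather than CPM because it is
defined on counts; `lfc_input` switches to CPM-mean input if desired.
Median-centering of a genome's LFCs per contrast (`center`) is off by
default — centering is a convention of some effect-size workflows, and we
prefer the uncentered values to be visible — but it is tested and one flag
away.  BGC-wide expression is the exact sum of member-gene CPM
(`bgc_expression()`), with filtered member genes contributing zero and
counted per region.  `series_percent_change()` reports knockout-vs-wild-type
expression differences with the "X% higher" convention,
$(v_\text{mut} - v_\text{wt})/v_\text{wt}\times 100$.

# The factorial metabolome model

For each molecular feature $m$ the model of log-transformed abundance in
sample $i$ is

$$\log(y_{im}) = \beta_{0m} + \sum_{j \in \{B,F,K\}} \beta_{jm} x_{ij}
 + \sum_{j' \in \{BF,BK,FK\}} \beta_{j'm} x_{ij'}
 + \beta_{BFKm} x_{iBFK},$$

with $x \in \{-1, +1\}$.  Two interaction codings are provided.  The
default, *containment* coding, sets an interaction entry to $+1$ only when
**all** species of the term are present (a subset indicator), matching a
model written with subset indicators; *product* coding is the classical
effect coding where interaction columns are products of main-effect
columns.  The codings agree on main effects and differ exactly in samples
where some but not all species of a term are present.

A structural fact drives the main design decision of this module: over the
7 non-media conditions, either coding has rank 7 with null vector
proportional to $(1, -1, -1, -1, 1, 1, 1, -1)$ over (intercept, B, F, K,
BF, BK, FK, BFK) — the three-way term is aliased.  Only the all-absent
design point identifies all 8 terms.  The default fit therefore includes
the media blanks as that all-absent row (rank 8); a strict mode excludes
them, fits the maximal independent column subset in term order (intercept,
mains, pairs, triple) and flags the trailing dependent term as aliased.  A
three-way *t* statistic is only meaningful in the first mode, and we treat
the media-inclusive fit as the primary analysis for exactly that reason;
both behaviors are implemented and tested, and neither is asserted to be
what any particular published analysis did.  The two genotype series are
fitted as two separate models over the same seven conditions.

The response transform is $\ln(\text{area} + 1)$; the offset keeps zero
areas finite and is configurable (`log_offset`).  *t* statistics are
$\hat\beta/\mathrm{SE}$ from ordinary least squares with
$\mathrm{SE}^2 = s^2 [(X^\top X)^{-1}]_{jj}$, $s^2 =
\mathrm{RSS}/(n - \mathrm{rank})$; a perfect interpolation (zero residual)
is flagged and reported as infinite *t*.  `fit_ensemble()` fits every
feature against the shared design in one pass and summarises each term's
*t* distribution by median and interquartile range.  `tail_select()` flags
features in the upper/lower tail of a term's *t* ensemble (default 2.5%,
linear-interpolation quantiles); ties at a threshold are included, so a
degenerate all-equal ensemble selects everything rather than an arbitrary
subset.

# Presence/absence accounting

The detection threshold is anchored on analytes that are biologically
absent from the knockout series: koreenceine A, B and C cannot be made by
the Δkec mutant, so any signal their features show in Δkec samples is
noise, and `detection_baseline()` takes the maximum such peak area as the
presence threshold.  The maximum (rather than mean + k·sd) is the simplest
rule consistent with that logic and is the default; the threshold is a
plain number, so alternatives drop in.  A feature is "present" in a
condition when the median replicate area exceeds the threshold
(`presence_rule = "median"`, robust to one dropped injection; `any` and
`all` are provided because "seen in" has no unique formalisation).
Features present in the media blanks are media-derived and removed before
tallying.  `condition_tallies()` then counts features seen only in
multi-member cocultures, features seen only in the three-member community,
and — across matched conditions of the two genotype series — shared and
series-unique features with percentages of the per-comparison nonmedia
union, which always partition that union exactly.

# Ordination and clustering

`pca_profiles()` z-scales each feature (unit normalization) after dropping
zero-variance features, and returns scores, per-feature loadings for
discriminating-feature reports, and percent variance explained (summing to
100).  `spearman_linkage()` clusters samples on $1 - \rho_\text{Spearman}$
with average linkage — a common default for correlation distances; the
linkage is configurable since nothing in the analysis depends on it
structurally.  Spearman distances are invariant under strictly monotone
per-sample transforms, which makes the clustering insensitive to
sample-specific intensity scaling.

# The synthetic study generator

`generate_study()` composes `planted_truth()`, `generate_counts()` and
`generate_feature_table()` under one master seed (components use seed,
seed+1, seed+2 in that order; identical configuration and seed reproduce
the tables byte for byte).

**Feature classes.**  Of the default 1000 features, 100 are media-derived
(constant baseline in every sample), 93 are coculture-emergent — 18 seen
only in the three-member community and 75 only when a specific pair is
present (25 per pair) — and 20 are koreenceine-dependent, the first three
of which stand in for koreenceine A/B/C and anchor the detection baseline.
The emergent-class sizes mirror the observed scale of community-dependent
chemistry in three-member coculture metabolomes; five replicates per
condition likewise match common practice.  The remaining features are
"background": present everywhere, log-normal abundance (intercept
$\sim N(11.5, 1)$ in log peak-area units, i.e. areas around $10^5$), with
sparse main and pairwise effects (each term nonzero with probability 0.1,
size $\sim N(0, 0.5)$).  Background effects never touch the three-way
term, so the number of nonzero three-way effects is forced by the
configuration — the three-way term is reserved for the planted community
features, which is also what makes tail-recovery tests sharp.

**Presence patterns through the model.**  A pattern feature with effect
$e$ ($e = 3$ by default, natural-log units) on containment term $T$ and
intercept $\log(\text{floor}/10) + e$ has model mean
$\text{floor}/10$ wherever $T$ is not contained and
$(\text{floor}/10)\,e^{2e}$ where it is — i.e. the containment coding
itself encodes "only seen in" patterns.  Every feature is therefore
model-consistent at every design point, including the media blanks as the
all-absent point, and a noiseless fit recovers all planted effects
exactly.  "Absent" cells are pinned at exactly floor/10 (an explicit
detector-floor, one-tenth of the `detection_floor` of 1000 area units)
rather than drawn log-normally around it; this keeps presence calls
deterministic and mimics an instrument floor, at the cost of zero
residual variance in those cells (pattern features' *t* statistics are
accordingly somewhat larger than a homoskedastic model would give).  One
consequence of model-consistency worth knowing: background features are
*detected in media blanks* (their all-absent design point sits at their
baseline, not at the floor), so media subtraction removes them and the
presence tallies operate on the planted pattern features.  Real blanks
would sit at the floor for most cellular metabolites; the generator trades
that realism for exact identifiability of all eight model terms, and
passing tests therefore certify the modeling machinery, not the media
chemistry of real data.

**Counts.**  Gene baselines are log-normal (meanlog 4, sdlog 1) over 500
genes per genome; 5 regions of 10 consecutive genes per genome form the
BGC catalog.  Counts are negative-binomial with a single shared dispersion
of 0.1 (biological CV ≈ 0.32, a standard RNA-seq noise scale), mean
proportional to baseline × $2^{\text{planted LFC}}$, scaled to the
sample's library share (library sizes ~1M ± 25%, split evenly across the
species present; genes of absent species are zero).  The default planted
BGC fold changes are $\{-2, +1, +3\}$ log~2~ units on three B-genome
regions in the BK condition, and they are koreenceine-mediated: they apply
in the wild-type series only, so the knockout series shows the
"de-repressed" contrast.  Planting several large fold changes in one
genome shifts that genome's library total and couples the contrasts
compositionally — exactly as in real CPM-style pipelines — so
parameter-recovery exercises plant one region at a time.

**What the generator does not emulate:** chromatographic drift, adducts
and isotopes, missing-value mechanisms other than the detector floor,
gene-length effects, and between-replicate batch structure.

# Numerical choices and degenerate inputs

* Percentile/quantile definitions everywhere are linear interpolation
  between order statistics (`type = 7`).
* Rank decisions use LAPACK QR; aliasing follows term entry order, so the
  dependent trailing term (the three-way) is the one dropped in strict
  mode.
* Zero-residual fits report infinite *t* rather than dividing by zero;
  non-finite responses are recorded per feature, not silently dropped.
* An all-zero count column, an empty genome group, a constant sample
  profile (undefined Spearman correlation), a saturated model, and a
  region with no surviving member genes are all explicit errors or
  flagged warnings naming the offending unit.
* Result tables are written with 6 significant digits; round-tripping
  reproduces values to that precision.

# Problem sizes used by the test-suite

The shipped tests run the generator at desk scale: up to 5000 features ×
75 samples for tail-recovery properties (100 seeds), 500 genes/genome for
fold-change recovery (100 seeds per planted effect), and smaller tables
elsewhere.  Configuration overrides scale every dimension up to
paper-scale inputs (≈5000–6000 genes per genome, ≈5000 features) without
code changes.

# Known limitations

* The Ψ estimator's library correction uses observed totals, so a large
  planted (or real) expression shift feeds back into the denominator — a
  compositional bias of order $\log_2(1 + \text{share} \cdot (2^\delta -
  1))$ shared by all CPM-family pipelines.
* The two genotype series are fitted independently; no variance pooling
  across series is attempted.
* Presence calls are per-condition majority votes; no FDR-style control
  over tallies is attempted, matching the descriptive use of these
  counts.
* The interactive linked-brushing exploration of tail features is out of
  scope; `tail_select()` provides the selection logic only.
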