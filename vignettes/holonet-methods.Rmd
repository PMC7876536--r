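---
title: "Transkingdom co-abundance networks and the integrated holobiont heatmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transkingdom co-abundance networks and the integrated holobiont heatmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holonet)
```

## The problem

A host and its gut microbiota form one analytical unit — a holobiont — but
the two are measured by different assays (RNA-seq of the gut tissue, 16S
amplicon sequencing of the gut content) with different noise models, depths
and sparsity. `holonet` asks a deliberately modest statistical question with
a deliberately interpretable answer: which *groups* of host genes and which
*groups* of microbial taxa co-vary across the same animals, and which of
those group-level profiles co-vary with each other and with external
variables such as water type, diet, sex and body condition?

The unit of inference is therefore the network module, not the individual
feature. Each omics layer gets its own signed weighted co-abundance network;
each module is summarized by its eigennode (the first principal component of
its standardized member profiles — an eigengene for the host, an eigenOTU
for the microbiota); and putative transkingdom interactions are predicted by
correlating host eigennodes with microbiota eigennodes and with encoded host
traits across replicate groups. The three correlation blocks, assembled with
significance stars, form the integrated heatmap (iHAHI).

## Normalization and filtering

Host counts are TMM-normalized: each sample's scale factor is a
precision-weighted trimmed mean of per-feature log2 ratios against a
reference sample, with the canonical trims (30% on log-ratios, 5% on average
intensity) and factors rescaled to geometric mean one. We express the result
as `log2((count + 0.5) / (library size x factor) * 1e6)` — log2
counts-per-million. Genes are then filtered: a gene survives if its maximum
normalized expression reaches 1.0 (interpreted on the post-normalization
log2 scale; configurable) in at least one sample *and* its standard
deviation (n−1 denominator) is at least 0.15. The first rule removes the
never-expressed; the second removes genes too flat to carry network
information.

OTU counts are filtered *before* normalization — an OTU must contribute at
least 0.005% of the summed microbial abundance, with the boundary retained —
because that rule is defined on raw relative abundance. The survivors are
normalized by cumulative sum scaling: each sample's factor is the sum of its
counts at or below the sample's median nonzero count (the quantile is
configurable; we fix it rather than re-implement the originating package's
adaptive quantile heuristic, trading a rarely-exercised adaptation for
determinism), and values become `log2(count / factor * 1000 + 1)`. CSS is
exactly invariant to per-sample scalar multiplication of counts.

Outlier screening mirrors the field practice of eyeballing a sample
dendrogram, made explicit: samples are min-max scaled to [0, 1], clustered
by average linkage on Euclidean distance, and flagged when their merge
height exceeds the median merge height plus five robust standard deviations
(MADs). Flagging is advisory — the pipeline logs flags and only drops
samples when asked, and an explicit drop list reproduces hand-picked
removals.

## Network inference

**Correlation.** The similarity is the biweight midcorrelation, a robust
correlation that downweights observations far from the median
(weight `(1 − u²)²` with `u` the robust z-score against 9 MADs, zero beyond
`|u| ≥ 1`). The `maxPOutliers = 0.05` side-cap rescales `u` separately on
each side of the median so that at most 5% of observations per side can be
zero-weighted — a floor on how much data the robust weighting may discard.
Features with zero MAD (majority-tied profiles) fall back to Pearson for all
their pairs; constant features get correlation 0, and their adjacencies are
therefore near zero rather than missing.

**Signed adjacency and TOM.** Correlations map to edge weights by
`a = ((1 + cor)/2)^β`, so anti-correlated features get essentially no edge —
the signed convention, which keeps "up together" distinct from "mirror
images". β is chosen as the smallest candidate in 1..30 whose scale-free
fit index `R² × sign(−slope)` (from regressing log bin frequency on log mean
bin connectivity, ten equal-width connectivity bins) reaches 0.85; when no
candidate reaches the cut — common on small or strongly modular data, where
the degree distribution is blocky rather than scale-free — the best-fitting
candidate is used and flagged. The clustering similarity is the signed
weighted topological overlap, which rewards shared neighborhoods:
`TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`.

**Module detection.** Average-linkage clustering of `1 − TOM`, cut at a
height placed within the merge-height range by the sensitivity parameter:
`h* = base + span × (0.95 − 0.05 × (4 − deep_split))`. At the default
`deep_split = 4` the cut sits at 95% of the range. Two properties of this
placement matter and were verified on planted-module data. First, it is what
makes detection robust when the soft-threshold fallback lands on a large β:
extreme powers compress all TOM dissimilarities toward 1, and only a cut
near the top of the (rescaled) merge range still separates planted modules
from the noise canopy. Second, although a higher cut yields fewer *raw*
clusters, branches smaller than `min_module_size` are discarded to the
unassigned pool rather than counted, so on realistic co-abundance instances
a deeper split produces more countable modules — the sensitivity ordering
one expects. Label 0 is reserved throughout for unassigned ("grey") nodes,
and no PAM-style reassignment is performed (reassignment threshold 0).

**Trimming and merging.** The detection parameters are deliberately
permissive (minimum module size 2) so that small but coherent profiles are
not lost; quality control then comes from membership trimming: a node whose
correlation with its own module eigennode (KME) falls below 0.5 is
unassigned, and a module dissolves unless at least 2 nodes exceed KME 0.5.
Finally, modules whose eigennodes correlate above `1 − mergeCutHeight` are
merged iteratively (average linkage on `1 − cor`, recomputing eigennodes
until no pair remains inside the merge radius), with cut height 0.5 for the
host and 0.4 for the microbiota. Merging uses Pearson on eigennodes by
default — eigennodes are smooth module summaries, not raw features — with
bicor available as an option. Eigennodes are standardized (zero mean, unit
variance) and sign-oriented toward non-negative correlation with the module
mean profile; note that negating every member therefore negates the
eigennode, which preserves every downstream correlation.

**Centrality.** Per node we report the connectivity decomposition
`kTotal = kWithin + kOut` and `kDiff = kWithin − kOut` from the adjacency and
final partition; ranking members by `kWithin` identifies a module's hubs.

## Removing large latent effects

When one environmental axis (in the motivating study, the fresh-/salt-water
transition) dominates both layers, most module–module and module–trait
correlations reflect that single axis. The package estimates how many
leading principal components stand above chance by a permutation test on the
eigenvalue spectrum of the feature-standardized matrix: each feature row is
independently permuted (destroying cross-feature correlation while
preserving marginals), the spectrum recomputed B = 100 times, and
components are counted from the top while the observed eigenvalue fraction
exceeds the permutation 95th percentile at its position. Those components
are then regressed out of every (centered) feature, leaving residuals
exactly orthogonal to the removed sample scores. Re-running the network and
heatmap on corrected data deemphasizes the dominant axis and lets secondary
associations surface; on synthetic data with a planted water effect the
corrected run shows strictly fewer water-starred module associations than
the uncorrected run, and affected features decouple from the water vector
(|r| < 0.1 for the overwhelming majority).

## Traits and the integrated heatmap

Host variables are encoded per replicate group (feed × water × day): Day on
its native integer scale but flagged ordinal; WaterSW as a salt-water
indicator; the four-level feed variable one-hot encoded (FO, VO, FOVO,
VOFO); Female_ratio as the fraction of females among samples of known sex
(a group-level reading consistent with group-averaged correlations — the
variable is otherwise undefined at group level); and the condition factor
`CF = 10⁴ · W / L³` (W in grams, L in millimeters; N = 4 brings the range
near 1), averaged per fish and then per group rather than computed from
group-mean weight and length, keeping the per-fish definition primary.

Correlations are computed after averaging eigennodes within replicate
groups, which is what makes their p-values honest: replicates are not
independent observations. Day uses Spearman (Pearson on average ranks; under
tied ranks a monotone response yields ρ below 1, which is the correct
behavior of average ranks, and ρ = 1 requires distinct days); every other
variable and the host–microbiota block use Pearson. p-values come from the
two-sided t transform on n − 2 degrees of freedom; cells with zero variance
report p = 1 with a flag; |r| = 1 reports the smallest positive double, never
an exact zero. Stars are `*` p ≤ 0.05, `**` p ≤ 0.01, `***` p ≤ 0.001 on raw
p-values — reproducing the raw-p annotation convention of the motivating
analysis; a Benjamini–Hochberg option exists and is clearly a deviation when
switched on. The default row rule keeps host modules with at least one
significant trait association *and* at least one significant microbiota
association, the candidates worth reading. Columns are ordered by feed, then
water, then day. Enrichment of module gene sets against an annotation map
uses the classic one-sided hypergeometric test per term, with the network
gene universe as background; the graph-aware decorrelation algorithms of
GO-specific tools are out of scope, and terms are assumed pre-propagated.

## The synthetic holobiont generator

Every statistical claim above is validated against `generate_holobiont()`,
which plants known structure at the latent level and emits *counts*, so the
pipeline is exercised end to end including normalization. Per module a
latent factor is drawn over samples (standard normal, plus any configured
trait effect in latent-sd units); member features are
`√r · factor + √(1−r) · noise` with `r = 0.8` by default, so member pairs
correlate at r in the latent layer. Coupled host/microbe module pairs share
a latent component scaled to the configured cross-kingdom correlation. Host
counts are Poisson around log-normal gene means (log-mean range 3–6) times
log-normal library factors (sdlog 0.3); microbiota counts are negative
binomial (dispersion 0.3) around larger, more variable means (log-mean range
5–7, biological log-sd 1.5 — taxa swing over orders of magnitude) with an
extra Bernoulli dropout of 10%.

Two generator realities deserve emphasis. First, the count layer attenuates
the planted correlations: after TMM/CSS and log2, member pairs realize
r ≈ 0.65–0.7 (host) and lower for the microbiota, which is exactly why the
KME-trim threshold of 0.5 and not something stricter is the operative
quality gate. Second, independent Bernoulli dropout is the single most
destructive noise source for co-abundance signal — at 30% dropout of
abundant taxa the planted structure becomes statistically unrecoverable by
any correlation measure, because a zero is many robust standard deviations
from the median yet the 5% outlier cap forbids discarding 30% of
observations. The 10% default keeps the generator in the regime the method
is designed for (an abundance-filtered table, where most zeros have already
been removed with the rare taxa); real 16S data with heavier dropout would
need the abundance filter to do correspondingly more work. What passing
tests show is therefore recovery under moderate, realistic count noise —
not robustness to arbitrary sparsity.

## Numerical choices and degenerate inputs

Ties in module-label ordering break by smallest member id; labels are always
compacted to 1..K by decreasing size, so `hME1` is the largest host module.
Merging iterates at most 20 times (convergence is typically ≤ 3 iterations).
The quantile in CSS and the permutation count B are configurable; seeds are
mandatory wherever randomness exists, and the permutation estimator restores
the caller's RNG state. Single-feature matrices yield a 1×1 unit correlation
matrix; single-node dissimilarities yield one unassigned node; a constant
matrix clusters into one module (all distances zero). All writers emit
full-precision (`%.17g`) locale-independent numbers, which is what makes
pipeline reruns byte-identical.

## Known limitations

On *fully unstructured* data the simplified height cut over-assigns: chance
branches of size ≥ 2 pass the core test by construction (two positively
correlated noise features always correlate well with their own average), so
30–75% of pure-noise features can end up in small chance modules. The
original dynamic hybrid tree cut guards against this with branch-quality
gates (core scatter, cluster gap) that are out of scope here. In practice
the specificity burden falls on the significance layer — the iHAHI star
calibration is verified to hold at the nominal 5% on fully decoupled data —
and on the analyst reading module sizes: on data with real structure the
relative cut lands in the gap between module branches and the noise canopy,
and planted-module recovery is excellent (mean adjusted Rand index ≥ 0.9 at
the validation scale of 200 features × 56 samples). Problem sizes throughout
the test suite (≤ 300 features, ≤ 140 samples, 50–200 repetition seeds)
were chosen as the smallest at which the statistical properties under test
are stable.

Causal direction between coupled modules is out of scope by design: a
starred hME–mME cell is a *putative interaction*, a hypothesis generator to
be followed up at node level (`node_level_follow_up()`) and ultimately
experimentally.
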