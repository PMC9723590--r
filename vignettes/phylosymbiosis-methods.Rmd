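---
title: "Testing phylosymbiosis: models, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing phylosymbiosis: models, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the analysis chain

Phylosymbiosis is the pattern in which microbiome similarity
recapitulates host phylogenetic relatedness: closely related host species
carry more similar gut communities than distantly related ones. It is a
pattern, not a process — vertical co-diversification, phylogenetically
conserved host filtering, and phylogenetically structured ecology can all
produce it. `phylosym` implements the three complementary tests commonly
used to detect the pattern from 16S ASV data, plus the trait regressions
used to probe what drives it:

1. **Topological congruence.** Collapse the sample-level data to one
   community per host species, build a UPGMA dendrogram per beta-diversity
   metric, and compare its topology to the host phylogeny with the
   normalized Robinson-Foulds (RF) distance. Significance comes from
   replacing the dendrogram with random topologies: a dendrogram more
   congruent than nearly all random trees is evidence of phylosymbiosis.
2. **Distance correlation.** A one-tailed Mantel test (Pearson, permutation
   p) between the species-level microbiome distance matrix and the host
   patristic distance matrix.
3. **Phylogenetic signal.** Reduce each species-level distance matrix to
   principal coordinates and ask, per axis, whether the scores behave as a
   phylogenetically structured trait (Blomberg's K, Pagel's lambda), and
   likewise for Faith's PD.

Trait regressions then control for the host tree while testing ecology:
PGLS of each metric's PCo1 on diet and habitat PC1 scores (and their
interaction), and sample-level PERMANOVA with the sequential formula
`Diet_PC1 * Habitat_PC1 + family/genus/species`, guarded by PERMDISP
dispersion checks.

The contrast between beta-diversity metrics is itself informative. UniFrac
metrics weight branches of the microbial phylogeny, so variation carried
by old, deep clades counts more; Bray-Curtis and Jaccard treat all ASVs
as equally related ("star phylogeny") and so are dominated by recent,
tip-level variation. Diet effects that act on ancient clades are therefore
expected to surface in UniFrac-based regressions before they surface in
star-metric regressions.

## Data model and quality control

The canonical container is an integer count matrix with samples as rows
and ASVs as columns, with unique labels on both margins. Filtering follows
the standard PCR-control protocol: every ASV with a non-zero count in any
negative control is removed from all samples (blanket removal, not
abundance-based decontamination), controls are dropped, and samples with
fewer than the depth floor (default 2000 reads; "fewer than" is strict,
so a sample with exactly 2000 reads survives) are removed.

Rarefaction draws, per sample, a without-replacement subsample of exactly
`depth` reads (a multivariate hypergeometric draw). Each sample's draw is
seeded by hashing the sample id together with the master seed, so results
are independent of row order and any one sample can be replayed. Samples
below the target depth are dropped rather than erroring, matching the
usual pipeline order in which low-depth samples are discarded first.
Rarefaction happens once per pipeline run; all downstream distances use
the rarefied table.

## Diversity metrics

Bray-Curtis and Jaccard are delegated to `vegan::vegdist`. The UniFrac
engine is implemented here on an edge-by-tip incidence matrix of the
rooted microbial tree: for each branch we know which tips descend from it,
so community mass under every branch is one matrix product. Unweighted
UniFrac is the unique-to-either fraction of branch length among branches
leading to either community; weighted UniFrac is the unnormalized sum
`sum_i b_i |p_i^A - p_i^B|` (the common QIIME default), with the
normalized variant available by flag. Faith's PD sums branch lengths of
the minimal subtree connecting the root and the present tips; the
root-inclusive convention is the default, with a no-root variant behind a
flag. Pairs of all-zero samples are an error naming the sample, never a
silent zero. Every ASV with a non-zero count must be a tree tip; tips
absent from the table are harmless.

The test suite checks the four metrics against brute-force oracles that
enumerate root-to-tip paths edge by edge, on random trees of up to six
tips, at `1e-12`; on a unit star tree unweighted UniFrac reduces exactly
to Jaccard, which is also asserted.

## Species-level aggregation

Two reduction schemes produce one community per host species:

* **Mean ceiling**: `ceiling(mean(count))` per ASV across the species'
  samples. The ceiling keeps every ASV observed in any sample present in
  the average (a mean of 0.1 becomes 1, not 0), which matters for
  presence/absence metrics. Because ceiling inflates row sums above the
  rarefaction depth, the species table is re-rarefied to the common depth
  by default (`species_aggregation = "re_rarefy"`); a `renormalize`
  option leaves the counts as they are and relies on the metrics'
  relative-abundance invariance instead. Whether to re-rarefy at this
  point is genuinely open; both behaviors are provided and the default is
  the one that restores comparable sampling depth.
* **Random picking**: `n` replicate tables (default 10), each picking one
  sample per species. Species with at least `n` samples contribute `n`
  distinct samples (no reuse across replicates); smaller species recycle
  each sample `floor(n/s)` or `ceiling(n/s)` times with the assignment
  randomized. The recycling rule is our operationalization of reuse
  "in multiple trials"; only the multiplicity balance is pinned down, the
  assignment is random.

With 1 species-average and 10 random-pick datasets across four metrics,
the default congruence grid is 44 RF tests and 44 Mantel tests.

## Congruence tests: numerical choices

* **UPGMA** uses average linkage with merge heights at half the linkage
  distance, so cophenetic distances reproduce linkage distances and the
  dendrogram is ultrametric to 1e-9. Labels are sorted lexicographically
  before clustering so tied merges resolve identically on every platform.
* **RF distance** is computed on unrooted, non-trivial bipartitions even
  though the inputs are rooted. The normalization denominator is the total
  number of non-trivial splits in both trees — equal to `2(n-3)` for two
  fully resolved trees, and still well-defined for multifurcating
  dendrograms arising from tied merges. This denominator is a declared
  choice, not an inference.
* **The RF null** replaces the dendrogram with random binary topologies
  (random joins, labels permuted uniformly). P-values use the add-one rule
  `(1 + #{null <= obs}) / (1 + n_null)`, so p is never zero and the
  smallest attainable value at 10,000 null trees is below 1e-4.
* **Mantel** is Pearson on the lower-triangle distances, one-tailed
  (greater), since phylosymbiosis predicts a positive correlation;
  999 permutations by default.

## Signal and regression machinery

PCoA is classical scaling: double-center `-D^2/2`, eigendecompose, scale
eigenvectors by root-eigenvalues. Negative eigenvalues (routine for
Bray-Curtis) are reported but excluded from coordinates and explained
proportions; no Cailliez/Lingoes correction is applied by default, matching
common tool behavior. Requesting more axes than there are positive
eigenvalues truncates with a warning.

Blomberg's K and Pagel's lambda are delegated to `phytools::phylosig`;
the K permutation count is chosen so the reported p follows the same
add-one convention as the other permutation tests. Signal tests run
per-axis on the first five principal coordinates with no multiplicity
correction, mirroring common practice; they are exactly the same code path
used for any univariate species trait, so diet and habitat PC1 screening
needs no special machinery. Lambda on a star phylogeny is flagged as
unidentifiable rather than returning an arbitrary number, and on an
ultrametric tree the upper bound of lambda is 1 by construction.

PGLS is a GLS fit with residual covariance `sigma^2 V(lambda)`, `V` the
Brownian covariance of the host tree. `lambda = 1` (pure Brownian) is the
default, matching the convention of the comparative-methods tools that do
not profile lambda; `lambda = "ML"` profiles it on `[0, 1]`. Coefficients
get two-sided t-tests on `n - p - 1` degrees of freedom, the model p-value
is an F-test against the intercept-only GLS, and
`AIC = -2 logLik + 2 (p + 2)` counts slopes, intercept and variance. The
implementation is cross-checked against `nlme::gls` with a Brownian
correlation structure, and collapses exactly to OLS on a star tree.

PERMANOVA wraps `vegan::adonis2` with `by = "terms"` (sequential, additive
sums of squares) in the written order — diet, habitat, interaction, then
the taxonomic nesting — with free permutation of sample labels (no
strata). Single-level terms are dropped with a warning. PERMDISP embeds
the distance matrix, computes distances to group centroids, and permutes
group labels; singleton groups are tolerated but at least two groups must
have two or more members.

## The synthetic generator

`simulate_community()` emulates the kind of field study this analysis
targets: 15 host species in three family clades (5/7/3) on a unit-depth
host tree whose families split at relative depths 0 and 0.25 and whose
crowns sit at 0.5; per-species sample counts default to an uneven field
design ranging from 1 to 30 samples (160 in total); per-sample read
depths are uniform on 2000-10000 so rarefaction always has work to do.

Abundances follow a log-linear (softmax) model per sample. For ASV `j` in
a sample of species `s`:

* a per-ASV baseline `N(0, 1)` sets abundance heterogeneity;
* a host-structured effect `g_j(s)`, an independent Brownian trait per ASV
  on the host tree with rate `sigma_phy`, creates phylosymbiosis;
* if `j` sits in a microbial clade older than `tau_deep` (relative depth),
  `beta_diet * d_s * u_clade` adds a diet response shared by the whole
  clade, where `d_s` is a Brownian diet trait with Pagel structure
  `lambda_diet`;
* species-level `N(0, sigma_noise^2)` and individual-level
  `N(0, sigma_individual^2)` noise complete the log abundances, and reads
  are one multinomial draw per sample.

"Deep clade" is operationalized by cutting the microbial tree at relative
depth `tau_deep`: each crossing lineage defines a clade, and clades with
at least two tips get a shared loading. In Yule trees this covers most
tips at any moderate cut — deep clades are few and large — so the diet
effect is a coarse, clade-coherent signal, as intended. The softmax link
is the simplest compositional link with controllable effect sizes; a
logistic-normal alternative would add overdispersion realism but no new
qualitative behavior.

Defaults (`sigma_phy = 9`, `sigma_noise = 0.25`, `sigma_individual = 0.5`,
`beta_diet = 1`, `tau_deep = 0.3`, `lambda_diet = 0.7`) were chosen once
so that the default dataset reproduces the qualitative regime the analysis
is designed to detect — all four metrics significantly congruent with the
host tree, with correlation strength comparable across metrics — and a
phylogenetically structured diet. The diet-trait structure value mirrors
the degree of phylogenetic signal typically reported for primate diet.
Controls are spiked with a dedicated contaminant ASV set (traces of which
also leak into true samples), so the QC filters have something real to do.

What the generator does **not** emulate: taxonomic composition,
overdispersed (non-multinomial) counts, sequence errors or chimeras,
seasonality, within-species spatial structure, and any coupling between
habitat and the microbiome (habitat is deliberately unstructured noise, so
habitat terms act as negative controls). Passing tests on synthetic data
therefore demonstrate the statistical machinery and its calibration, not
biological realism of count distributions.

## Calibration and verification strategy

The test suite verifies each primitive against an independent oracle
(branch-path enumeration for UniFrac and PD, naive O(n^3) linkage for
UPGMA, exhaustive bipartitions for RF, direct group sums for the
PERMANOVA pseudo-F, `picante`/`phangorn`/`nlme`/`cmdscale` as external
cross-checks), then checks calibration by simulation: type-I error of the
permutation tests at nominal 5% (500 null replicates each), Blomberg's K
averaging 1 under Brownian motion on a 32-tip tree (500 draws), lambda
recovery at both ends on 64 tips (200 draws each), PGLS slope recovery
within 15% (200 draws), and the deep-clade diet regime producing more
frequent PGLS diet detection through UniFrac than through star metrics
(100 replicates). These problem sizes were chosen to make Monte-Carlo
error comfortably smaller than the tolerance being asserted while keeping
the suite quick to run.

## Known limitations

* **The RF randomization test is conservative.** The normalized RF
  distance between 15-tip topologies takes few values and the null mass
  concentrates near 1 (random trees almost never share splits). With the
  add-one rule and ties counted against rejection, the attainable type-I
  error at nominal 5% is about 2.5-3% at this tree size. Rejections are
  therefore trustworthy; the test simply cannot spend its full nominal
  level. The Mantel, PERMANOVA and PERMDISP tests are calibrated at
  nominal level.
* Normalized RF saturates quickly: almost any wrong topology scores near
  1, so it discriminates degrees of partial congruence poorly;
  branch-length-aware congruence scores are out of scope here.
* Mean-ceiling aggregation is biased upward for rare ASVs by design;
  interpret presence-based metrics on species-average data accordingly.
* PGLS fixes lambda at 1 by default; if residual phylogenetic structure is
  weaker, coefficient tests can be conservative or anticonservative. The
  `"ML"` option exists, but with 15 species the lambda estimate is noisy.
* PERMANOVA permutes labels freely; with nested taxonomy in the design the
  p-values for higher-level terms do not account for the hierarchy
  (restricted permutation schemes are not implemented).
* The sequential (type-I) sums of squares make term significance depend on
  formula order; the order used is the conventional
  diet, habitat, interaction, then taxonomy.
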