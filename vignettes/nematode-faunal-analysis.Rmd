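---
title: "Nematode faunal analysis: indices, metabolic footprints and co-occurrence networks"
author: "nemafauna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nematode faunal analysis: indices, metabolic footprints and co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemafauna)
```

Soil nematodes occupy every consumer level of the soil micro-food web, so
the composition of a nematode community — who eats what, and where each
taxon sits on the colonizer–persister (c-p) life-history gradient — is a
sensitive indicator of soil condition. `nemafauna` implements the full
indicator pipeline used in soil food-web assessment: trait-based
classification, the classical ecological indices, metabolic footprints
with the functional-footprint faunal profile, genus co-occurrence
networks, and the surrounding statistics. This vignette explains the
models, the defaults, and the choices made where the methodology leaves
room.

## The data model

Three tables drive everything:

* a **trait table** (`load_traits()`, `default_traits()`) mapping each
  genus to a trophic group (bacterivores Ba, fungivores Fu, plant
  parasites Pp, omnivores/predators Op), a c-p value (1–5; 1 =
  enrichment opportunist, 5 = persister) and a mean fresh body weight in
  µg;
* a **community matrix** (genera × samples) of abundances expressed per
  100 g of dry soil (`normalize_abundance()` converts extraction counts;
  `expand_identification()` allocates a total count over the genera found
  in a fixed identification subsample, conventionally 100 individuals);
* a **metadata table** keyed by sample, carrying treatment, replicate,
  dry mass, and any soil or plant covariates.

The packaged trait table covers 46 genera typical of temperate orchard and
arable soils (19 Ba, 6 Fu, 9 Pp, 12 Op). Trophic and c-p assignments
follow the standard conventions; a few genera are deliberately encoded as
they are commonly used in field studies of this design (e.g. *Filenchus*
as a fungivore, *Tylenchus* and *Psilenchus* as plant parasites), since
published usage varies between the fungal-feeding and plant-feeding
readings of these groups. Fresh weights are representative
literature-scale values, not measurements: absolute footprint magnitudes
therefore depend on the user's weight source (Nemaplex or their own), and
only relative comparisons within one trait table are meaningful. Every
function takes the trait table as an argument precisely so that these
assignments are data, not code.

Undefined quantities propagate as `NA`, never as 0: a sample without
plant parasites has no PPI and no WI, and a zero denominator in EI/SI is
an explicit missing value excluded from downstream ANOVA.

## Ecological indices

For one sample with genus abundances $N_i$:

* **Maturity index** $MI = \sum_i v_i f_i$ over free-living taxa (Ba, Fu,
  Op), where $v_i$ is the c-p value and $f_i$ the proportion of the
  free-living total. All c-p classes enter by default (the `cp_min = 2`
  option gives the MI(2–5) variant that drops c-p 1 opportunists).
* **Plant-parasite index** PPI: the same weighted mean restricted to Pp
  taxa, normalized within the Pp total.
* **Wasilewska index** $WI = (Ba + Fu)/Pp$ and **channel ratio**
  $NCR = Ba/(Ba + Fu)$, on trophic-group abundances.
* **Enrichment and structure indices** $EI = 100\,e/(e+b)$,
  $SI = 100\,s/(s+b)$, built from weighted guild components: enrichment
  $e$ (Ba1 at 3.2, Fu2 at 0.8), basal $b$ (Ba2 and Fu2 at 0.8), structure
  $s$ (Ba/Fu/Op of c-p 3–5 at 1.8/3.2/5.0, plus predatory c-p 2 taxa at
  0.8).

Two definitional points deserve emphasis. First, Fu2 contributes to
**both** the enrichment and the basal component; that double role is part
of the standard faunal-profile definition and is retained here (weights
are fully overridable via `load_guild_weights()`). Second, with omnivores
and predators merged into a single Op group, the predator part of the
structure component cannot be recovered from the group label alone below
c-p 3; the trait table therefore carries a `predator` flag, and a c-p 2
taxon enters the structure component only when flagged. Op taxa of c-p
3–5 always enter through the omnivore guilds. This is a convention of
this package, recorded here rather than attributed to any particular
source.

## Metabolic footprints and the faunal profile

The footprint of taxon $t$ is
$N_t\,(0.1\,W_t/m_t + 0.273\,W_t^{0.75})$ — a respiration term scaled by
life-course (c-p) and a production term scaling with body mass to the
3/4 power. Footprints add: by trophic group (BaF, FuF, PpF, OpF summing
exactly to the total NMF) and by life-history class (enrichment footprint
Fe over c-p 1–2, structure footprint Fs over c-p 3–5, also summing to
NMF). By default Fe/Fs include all taxa, because the c-p partition is
defined on the whole community; `free_living_only = TRUE` excludes plant
parasites for users who prefer the free-living reading, at the cost of
the partition identity.

`functional_footprint()` draws the faunal-profile rhombus: centre
$(SI, EI)$, horizontal half-diagonal $0.5\,F_s/k$, vertical half-diagonal
$0.5\,F_e/k$. Its area — computed by the shoelace formula and equal to
$F_e F_s / (2k^2)$ in closed form — is the functional metabolic
footprint. The conversion constant $k$ defaults to 1: the methodology
never fixes it, plot axes can be rescaled freely, and $k$ only matters
when comparing areas across studies, so it is exposed rather than hidden.

Quadrat labels partition the EI × SI plane at 50: A (high EI, low SI) is
an enriched but disturbed food web, B (high, high) a mature and stable
one, C (low EI, high SI) a structured but resource-poor one, D (low, low)
a degraded one. Points exactly on a boundary are assigned to the lower
(`<=`) quadrat — ties must land somewhere, and the conservative choice is
the less-enriched, less-structured reading. The quadrat depends on
(EI, SI) only; Fe and Fs shape the rhombus but never the label.

```{r faunal-profile}
profile <- functional_footprint(EI = 70, SI = 80, Fe = 60, Fs = 90, k = 10)
profile
```

## Co-occurrence networks

`correlation_matrix()` computes genus–genus Spearman correlations across
samples on relative abundances (the conventional input; raw abundances
via `relative = FALSE`). P-values use the t approximation on $n-2$
degrees of freedom, matching `cor.test(exact = FALSE)` and the behaviour
of the correlation tools commonly used for these networks; genera with
zero variance carry no rank information and are dropped with a warning.
`build_network()` keeps edges with $|r| > 0.6$ and $p < 0.05$ — the
absolute value matters, since negative (exclusion) edges are part of the
biology; a `signed_threshold` option keeps positive edges only, and an
optional Benjamini–Hochberg correction (`p_adjust = "BH"`) is off by
default because the conventional screen applies none.

Because "connectivity" is used ambiguously in the community-network
literature, `network_metrics()` reports both candidates — density × 100
(`connectance_pct`) and the average degree — without privileging either.
Hub taxa (`hub_taxa()`) are ranked by degree within trophic groups, with
ties broken by total absolute edge strength and then alphabetically, so
rankings are deterministic.

A caution that the package enforces with a warning rather than an error:
with only 3 replicate samples per treatment, a rank correlation
essentially cannot reach $p < 0.05$ at $|r| > 0.6$, so per-treatment
networks need more samples (the network test scenarios here use 12) or
must be interpreted as descriptive.

## Statistics

Abundances are `ln(x + 1)`-transformed before ANOVA (`ln_transform()`).
`one_way_anova()` is the classical fixed-effects F test; indices and
footprints are typically tested untransformed, and the transform is never
auto-applied to them. `duncan_mrt()` implements Duncan's multiple range
test from the studentized-range distribution: means sorted descending,
span-$p$ comparisons against
$R_p = q(1-\alpha_p,\,p,\,df_w)\sqrt{MSW/n_h}$ with the protection level
$\alpha_p = 1-(1-\alpha)^{p-1}$, the harmonic mean $n_h$ for unequal
groups, and the containment rule (a difference inside a non-significant
wider range is never declared significant). Quantiles come from
`qtukey()`, not printed tables, so results are reproducible to machine
precision; for two groups the procedure reduces exactly to Fisher's LSD.
Letters are assigned to maximal runs of non-separated means, `a` at the
largest mean.

`pcoa()` is classical metric MDS: Gower double-centering and
eigendecomposition. Negative eigenvalues (expected under Bray–Curtis) are
reported but excluded from coordinates, and explained fractions are taken
over the positive eigenvalues; `correction = "lingoes"` makes the matrix
Euclidean for users who want additive correction. Bray–Curtis is the
default community dissimilarity (`bray_curtis()`, via `vegan`), with the
distance choice left explicit because ordination conventions differ.

`mantel_test()` correlates the lower triangles of two distance matrices
(Spearman by default, consistent with the rank-based edge tests) and
permutes object labels of the second matrix;
$p = (1 + \#\{r^* \ge r\})/(n_{perm}+1)$, one-sided for positive
association, floor $1/(n_{perm}+1)$. Covariate distances are Euclidean on
centred, unit-variance covariates (`covariate_distance()`); constant
covariates contribute nothing rather than NaNs.

## The synthetic-data generator

Field studies of this design rarely deposit raw tables, so the package
ships a generator that emulates such a trial end-to-end: 4
treatments (CK, C2, C4, C8) × 3 plots, the 46-genus pool, negative
binomial counts (size 15 — moderate overdispersion typical of field
counts; a Poisson switch exists for exact-variance checks), a lognormal
plot-heterogeneity factor (sdlog 0.12), a multinomial 100-individual
identification subsample, and soil covariates built as baseline +
treatment shift + coupling to a standardized trophic-group abundance +
Gaussian noise. Default treatment effects plant the qualitative pattern
such studies report — fungivores ×1.6 under C4/C8, plant parasites ×1.5
under C2/C8, bacterivores ×1.5 under C4 — and the noise levels were
chosen so that a 3-replicate design detects the fungivore effect with
high power under ln-ANOVA (noncentrality ≈ 20 on F(3, 8) at these
settings), i.e. the planted effects are realistic *and* recoverable at
this level of replication. `generate_block_community()` additionally plants
exact two-block rank-correlation structure (equicorrelated Gaussian
factors, monotone lognormal transform) for validating the network filter.

```{r scenario}
scenario <- generate_scenario(scenario_config(seed = 1))
scenario
head(nema_indices(scenario$abundance, scenario$traits)[, 1:7])
```

What the generator deliberately does **not** emulate: taxonomic
misidentification, spatial autocorrelation between plots, seasonal
dynamics, compositional constraints from a fixed extraction volume, and
mechanistic soil chemistry. Tests passing on synthetic data therefore
demonstrate correctness of the computations and sensible statistical
behaviour under a plausible data-generating process — not field validity
of any particular threshold.

Everything stochastic takes an explicit seed (`with`-style, restoring the
global RNG state), and a scenario derives independent sub-streams for
community, subsample and covariates from its single seed, so a whole
study is reproducible from one integer.

## Problem sizes and numerical tolerances

The test-suite checks run at sizes chosen to make Monte-Carlo conclusions
stable while keeping the suite quick: 1,000 random communities for the
index and footprint oracle comparisons (relative tolerance 1e-12 and
1e-9), 10,000 draws for the rhombus-geometry identity, 100 seeds of
12-sample two-block tables for network recovery, 500 random datasets for
each Duncan property, 100 random point sets for PCoA inversion
(Procrustes residual below 1e-8), 500 independent pairs of 12-object
distance matrices at 999 permutations for Mantel calibration, and 200
scenario seeds for the ANOVA power check. One caveat worth knowing: the
between-block false-edge rate of the network filter is about 4.3% on
average (safely under the 5% expected from an exact 5%-level screen), but
all between-block pairs of one table share the same two latent factors,
so 100-seed estimates of that rate scatter with a standard deviation of
roughly 1.4 percentage points around the mean — individual re-runs of
that check can land on either side of 5%.

## Known limitations

* Absolute footprints inherit whatever fresh-weight source the trait
  table encodes; ship your own weights for publication.
* Index values at one c-p resolution: one c-p value and one weight per
  genus, no intra-genus variation.
* The network module is a thresholded-correlation screen, not an inverse
  model: it recovers strong monotone pairwise association, and at small
  sample sizes it is power-limited by design.
* RDA/constrained ordination is out of scope; export the aligned
  community and covariate tables and use a dedicated ordination tool.
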