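---
title: "Biome specialization, null models and tip diversification rates"
author: "biomediv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biome specialization, null models and tip diversification rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomediv)
```

## The scientific question

Vrba's resource-use hypothesis predicts that climate-driven fragmentation
of biomes acts most strongly on *biome specialists* — species confined to
a single biome — inflating both their speciation and extinction rates.
Two observable signatures follow: (i) clades should hold more biome
specialists than a random arrangement of the same biome richness would
produce, and (ii) specialists should carry higher recent diversification
rates than generalists. `biomediv` implements the full chain of analyses
needed to test both signatures in any clade for which a range–biome
overlap table and a time-calibrated phylogeny exist: occupancy scoring,
the biomic specialization index (BSI), a richness-constrained Monte Carlo
null model, equal-splits/DR tip rates, and phylogenetic comparative tests.

## From range overlaps to occupancy and BSI

The unit of habitat is one of ten global climatic-vegetation zones
(Walter's classification; `biome_codes()`), in a fixed column order. A
species occupies a biome when either of two inclusive rules holds:

* **range rule** — the biome covers at least 15% of the species'
  geographical range (`range_threshold = 0.15`);
* **patch rule** — the species covers at least 50% of an isolated patch
  of that biome (`patch_threshold = 0.50`).

Both thresholds are dimensionless fractions in (0, 1]; both boundaries
are inclusive ("15% or more", "50% or more"). The patch rule exists
because a species can dominate a small, isolated biome patch that is
nonetheless a negligible share of the species' total range; it is also
the only route to very high BSI, since at most six biomes can each hold
15% of one range.

The BSI of a species is simply its row sum in the binary occupancy
matrix: the number of biomes it inhabits. Categories use fixed cut
points: specialist (BSI = 1), semi-generalist (1 < BSI < 5), extreme
generalist (BSI ≥ 5).

Row fractions are taken at face value: rows may sum to less than 1
(coastal or unmapped area) and are never re-normalized; rows summing to
more than 1 + 1e-6 are rejected. A species that fails both rules in
every biome is biologically impossible under the source methodology but
can occur in arbitrary input; `apply_occupancy_rules()` reports such
species and excludes them, or — with `rescue_max_biome = TRUE` — assigns
each to its single largest-fraction biome. The default is OFF because no
published fallback exists; the rescue is an explicit, logged choice.

```{r occupancy-example}
ov <- overlap_table(data.frame(
  species = c("a", "a", "b"),
  biome = c("rainforest", "steppe", "steppe"),
  range_fraction = c(0.85, 0.15, 1)))
occ <- apply_occupancy_rules(ov)
compute_bsi(occ)
```

## The richness-constrained null model

Biomes differ enormously in species richness, so the observed number of
specialists cannot be judged against a uniform expectation. The null
model holds each biome's observed richness fixed and frees species
memberships: for each biome with richness $R_b$, exactly $R_b$ distinct
species are drawn uniformly without replacement from the full pool,
independently across biomes. Column sums of every randomized matrix
equal the observed richness vector exactly; row sums (BSI) vary freely.

Two design points deserve emphasis:

* **Class 0.** Because columns are randomized independently, a species
  can receive no presence at all. Such species are retained and tracked
  as BSI class 0, so per-replicate class counts always sum to the number
  of species and classes 1–10 remain directly comparable with the
  observed counts. The alternative — forbidding empty rows while keeping
  column sums fixed — requires a swap-based (fixed-fixed) algorithm that
  answers a different question and is deliberately out of scope.
* **Empirical p-values.** With $n$ replicates, the upper-tail p-value is
  $(1 + \#\{sim \ge obs\})/(n + 1)$; the lower tail is analogous and the
  two-sided value doubles the smaller tail (capped at 1). The add-one
  correction counts the observed arrangement as one more realization of
  the null, so p can never be 0 and the test is valid (super-uniform)
  at any replicate number. Direction (observed above or below the
  simulation mean) is reported separately, and both the mean and the
  median of each simulated statistic are returned.

Randomization draws come sequentially from one seeded RNG stream; the
implementation is single-threaded, so a single `set.seed()` at entry
makes the whole run bit-reproducible, which is the contract the tests
pin. Counts and proportions per class are monotone transforms of each
other at fixed $n$ and richness, so their empirical p-values coincide.

## Equal splits and the DR statistic

For tip $i$ with root-path edges $e_1$ (pendant) to $e_N$ (rootmost),
the equal-splits evolutionary isolation score is

$$ES_i = \sum_{j=1}^{N} \ell(e_j) \prod_{k<j} \frac{1}{c_k},$$

where $c_k$ is the number of daughters of the $k$-th node passed on the
way to the root — $\ell_1 + \ell_2/2 + \ell_3/4 + \dots$ on a strictly
bifurcating tree. The DR statistic is $DR_i = 1/ES_i$, in
events/lineage/Myr when branch lengths are Myr. DR up-weights branches
and splitting events close to the present and, on ultrametric trees, is
commonly read as a nonparametric proxy for recent net diversification.
No parametric diversification inference (birth–death ML, SSE
likelihoods) is attempted; DR is exactly the summary statistic used.

Numerical choices: a polytomy with $c$ daughters contributes factor
$1/c$, the natural generalization of the bifurcating $1/2$ that keeps
"equal splits" exact without forcing arbitrary resolutions; a root edge
present in the Newick file is excluded from every path; ultrametricity
is checked at relative tolerance 1e-3 on root-to-tip depths and violated
trees produce a warning, not an error, because published time-calibrated
trees routinely carry rounding jitter. Tip labels are matched to trait
tables after whitespace/underscore normalization, and unmatched species
on either side are listed, never silently dropped.

## Phylogenetic comparative tests

**PGLS with Pagel's λ.** The Brownian covariance $V$ of the tree has
$V_{ij}$ equal to the root-to-MRCA depth of tips $i, j$; Pagel's λ
multiplies the off-diagonal and leaves tip variances unchanged, so λ = 0
is a star tree and λ = 1 pure Brownian residuals. `pgls()` fits
$y = X\beta + \varepsilon$, $\varepsilon \sim N(0, \sigma^2 V(\lambda))$
by GLS (Cholesky whitening), profiling the full-ML Gaussian
log-likelihood over λ ∈ [0, 1] with bounded scalar optimization at
tolerance 1e-8 (`optimize()` never probes the exact endpoints, so both
are evaluated explicitly and taken if better). Full ML matches the
"maximum likelihood" profiling convention; REML is available behind
`reml = TRUE`. Coefficient t-tests use the unbiased residual variance
with $n - p$ degrees of freedom. The reported R² is the *adjusted* R² of
the whitened model against the whitened intercept-only fit under the
same $V(\hat\lambda)$. Every fit in the test suite is also checked
against a λ grid (profile log-likelihood at $\hat\lambda$ dominates
λ ∈ {0, .25, .5, .75, 1}) and, independently, against `nlme::gls` with
`ape::corPagel`.

**Phylogenetic ANOVA.** The observed one-way ANOVA F of a response
across groups is compared with F values from Brownian simulations on the
same tree, with the Brownian rate set to the ML estimate from the
observed response (Garland-style). Because F is scale- and
location-invariant, the simulated F distribution does not actually
depend on the estimated rate — which is precisely why the procedure is
exactly calibrated: observed and simulated F are exchangeable under the
null. p-values use the same add-one rule as the null model; optional
pairwise post-hoc contrasts compare pooled-SD t statistics with their
simulated distributions under Holm adjustment.

**Variance partitioning.** From adjusted R² of the three OLS fits
`y ~ x1`, `y ~ x2`, `y ~ x1 + x2`: unique₁ = R²(both) − R²(x2),
unique₂ = R²(both) − R²(x1), shared = R²(both) − unique₁ − unique₂,
unexplained = 1 − R²(both). The four fractions sum to 1 by algebraic
identity; the shared fraction can legitimately be negative (adjusted-R²
arithmetic) and is reported as-is. In the pipeline, range area enters
the DR model as log10(km²), since areas span orders of magnitude; raw
area is available via `area_transform = "identity"`.

## What the synthetic generators emulate

The generators make every stage testable without any download.

* `simulate_tree()` — forward-time constant-rate birth–death,
  conditioned on the tip count by stopping when the extant count first
  reaches the target, with the stopping epoch drawn uniformly inside the
  final inter-event interval (this avoids conditioning on an event at
  the present and tempers the "push of the past" in small trees);
  whole-clade extinctions are rejected and redrawn. Trees are
  ultrametric by construction.
* `simulate_state_tree()` — the same engine with a binary state,
  state-specific speciation/extinction rates and anagenetic flips at
  rates q01/q10, coded 1 = specialist, 0 = generalist. With
  state-independent rates it reduces in distribution to
  `simulate_tree()` (checked by a KS test on root ages).
* `simulate_bm_trait()` — multivariate normal tip values with covariance
  σ²·V(λ), plus optional fixed effects; the regression oracle for PGLS
  and the null generator for the phylogenetic ANOVA.
* `simulate_occupancy()` — a right-skewed occupancy world. Each species
  receives a home biome against remaining per-biome capacity; remaining
  per-biome quota is filled by sampling species with propensities drawn
  from a Gamma(θ): small θ concentrates extra presences on few species
  (many specialists, a few strong generalists), large θ spreads them.
  Fractions for each species' occupied set are a Dirichlet(θ) draw
  conditioned on every occupied biome holding ≥ 15% of the range, so the
  binary matrix round-trips exactly through `apply_occupancy_rules()`
  and realized richness matches the targets. Species with more than six
  biomes (impossible under the 15% rule alone) carry their overflow as
  isolated-patch records with coverage ≥ 50%. A purely unconditioned
  symmetric-Dirichlet draw cannot pin uneven richness targets, which is
  why the generator is constructive; θ remains the single skew dial with
  the intended limits (θ → 0 gives all specialists when targets sum to
  the species count).

`papilionid_preset()` fixes the study-scale conditions: 593 species, a
rainforest- and tropical-woodland-dominated richness vector whose total
presence mass (990) pins the mean BSI at 1.67, and θ = 0.5, calibrated
once so the specialist share falls in the mid-50% range with a handful
of extreme generalists. What the generator does **not** emulate: spatial
autocorrelation of ranges, phylogenetic signal in biome membership
(occupancy is drawn independently of any tree), realistic patch
geometry, and the identity of individual species. Passing tests
therefore demonstrate the statistical machinery — calibration,
invariances, directional recovery — not biological conclusions about any
real clade.

## The state-dependent power design

The directional experiment pairs the two-state simulator (specialists
speciating at twice the generalist rate, λ1 = 2λ0 = 0.2, equal
extinction 0.02, symmetric transitions) with the DR and PGLS stages, and
asks that specialists show higher mean DR and a negative DR-on-
specialization PGLS slope in at least 95 of 100 replicates. The
reproduction rate depends on tree size: a 200-replicate power analysis
(independent seeds) gave ≈ 97% wrong-sign-free slopes at 200 tips and
≈ 98.5% at 400 tips with q = 0.05 — the residual sign flips come from
the λ-ML GLS conditioning on clade-clustered states, not from small
state groups. The experiment therefore uses 400-tip trees, the smallest
size at which a ≥ 95/100 criterion has comfortable headroom.

## Problem sizes and tolerances

The shipped test suite uses: exhaustive null-model enumeration up to 3
species × 3 biomes against 4,000-replicate simulations; 1,000-trial
super-uniformity and phylogenetic-ANOVA calibration runs at 199
simulations each; 100 random ≤ 12-tip trees against a rational-
arithmetic equal-splits oracle at 1e-12; 100 Brownian PGLS recoveries on
200-tip trees (true slope 2.0, λ = 1); and 100 state-dependent
replicates at 400 tips. The acceptance script reruns the study-scale
preset with a 10,000-replicate null model and a 20-replicate
state-dependent contrast. These sizes were chosen so each Monte Carlo
standard error sits well inside the corresponding assertion band.

## Known limitations

* The null model randomizes columns independently; it is not a
  fixed-fixed (row- and column-preserving) null, by design.
* PGLS assumes an ultrametric-ish tree for the λ = 0 = OLS equivalence;
  on non-ultrametric trees λ = 0 weights tips by depth, as it should.
* The phylogenetic ANOVA simulates under Brownian motion only.
* DR is a nonparametric proxy; it is not an estimate of speciation rate
  under any explicit model, and no SSE-type likelihood is fitted.
* `variance_partition()` is ordinary (non-phylogenetic) adjusted-R²
  partitioning, mirroring standard practice; its fractions and the PGLS
  R² answer different questions and need not agree.
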