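---
title: "Models and methods behind mitopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopop)
```

`mitopop` analyses mitochondrial DNA variation in small, subdivided
populations: haplotype motifs called against a reference segment,
haplogroup frequencies per population, and the statistics that
archaeogenetic studies build on them.  This vignette records the models,
the numerical choices, and the reasoning behind the design decisions
that were genuinely open.

## Coordinates, motifs and the reference segment

All coordinates are 1-based and inclusive, following mtDNA convention;
strand is ignored and sequences are taken as given (reverse-complemented
input is detected and flipped during alignment).  A *motif* is the
canonical, position-sorted set of variant tokens that distinguishes a
sequence from the reference: substitutions (`16223T`), insertions
(`309.1C`; the `309iC` spelling is accepted on input and emitted in the
dotted form, which is what phylotree-style references use), deletions
(`16166d`) and back mutations (`@16189`, which only occur in tree edge
definitions and are resolved during composition).  Two motifs are
compared site-wise: the distance between `16223T` and `16223C` is one,
as is presence versus absence of a variant.

The default analysis window is HVRI, positions 16000–16400.  The
package ships a *synthetic* 401-bp reference segment
(`synthetic_hvri_reference()`, generated by a fixed Lehmer sequence so
the global RNG is untouched) and a *synthetic* reduced phylotree
(`inst/extdata/synthetic_phylotree.json`) whose labels follow standard
haplogroup nomenclature but whose defining variants were chosen against
that synthetic segment.  Every downstream statistic depends only on
variants relative to whatever reference is supplied, so these stand-ins
exercise the entire pipeline; analyses of real data should supply the
rCRS and a real tree through `ref_segment()` and `read_phylotree()`.

Hypermutable positions are excluded from phylogenetic analysis by
default: indels at 309, 522, 573 and 16193, and substitutions at 16519.
Excluded calls are reported alongside the kept motif, never silently
dropped.

## Haplogroup assignment

Assignment scores every tree node `h` with the Kulczynski measure

$$\mathrm{score}(h) = \tfrac12\left(\frac{|M \cap E_h|}{|E_h|} +
\frac{|M \cap E_h|}{|M|}\right),$$

where `E_h` is the node's cumulative defining motif (back mutations
applied, restricted to the analyzed segment) and `M` the observed
motif.  An empty `E_h` counts as a fully satisfied expectation and an
empty `M` as a fully explained observation, so the root scores 1 on an
empty motif.  Ties break toward the deeper node, then lexicographically.
Production haplogroup callers additionally weight variants by their
phylogenetic stability; the unweighted score is a deliberate
simplification that recovers the generating node exactly for clean
motifs and degrades gracefully under private mutations (≥ 95% recovery
at 0.5 expected private substitutions per sequence on the bundled
tree).

Ancient samples from one archaeological site may be close relatives, so
at most one is kept: one record per site-and-haplogroup for population
statistics, one record per site within a dated clade.  The record with
the smallest sample id wins, which makes the rule deterministic.

## Diversity, exact Fisher tests and asymmetry scans

Gene diversity uses Nei's unbiased estimator
$H = \frac{n}{n-1}(1 - \sum_i p_i^2)$ with sampling variance

$$V(H) = \frac{2}{n(n-1)}\left\{2(n-2)\left(\sum p_i^3 -
\left(\sum p_i^2\right)^2\right) + \sum p_i^2 -
\left(\sum p_i^2\right)^2\right\}.$$

The `n/(n−1)` correction makes `E[H]` equal the population quantity
`1 − Σp²` exactly under multinomial sampling, which the test suite
verifies by simulation.  Diversity can be computed at haplotype or
haplogroup granularity; the two differ whenever distinct haplotypes
share a haplogroup, so published tables mixing the two conventions can
only be reproduced at the granularity they were computed at.

The two-tailed Fisher test enumerates the full hypergeometric support
and sums every table probability not exceeding the observed one, with a
`1e−7` relative tolerance for floating ties — the convention used by the
standard implementations.  Terms are computed through log-gamma, so
totals in the hundreds lose no precision.  The asymmetry scan applies
this test category by category between two island groups (default east
= the two easternmost populations, west = the remaining four), pooling
all other categories as the complement, and supports excluding
populations to check whether a signal survives removal of strongly
drifted islands.

## Distances and ordination

Pairwise Φ_ST uses AMOVA variance components with 0/1 haplotype
distances, which reduces to a pure frequency statistic: with group
sizes `n₁, n₂`, `N = n₁+n₂` and within/pooled frequencies `p`, `P`,

$$SSD_g = \frac{n_g}{2}\Big(1-\sum_i p_{gi}^2\Big),\quad
SSD_T = \frac{N}{2}\Big(1-\sum_i P_i^2\Big),$$

`SSD_A = SSD_T − ΣSSD_g`, `σ²_w = ΣSSD_g/(N−2)`,
`n_c = N − (n₁²+n₂²)/N`, `σ²_a = (SSD_A − σ²_w)/n_c`, and
`Φ = σ²_a/(σ²_a+σ²_w)`.  Negative variance-component estimates are
truncated to zero so the linearized distance `D = Φ/(1−Φ)` stays a
dissimilarity; `Φ = 1` is capped at `10⁶`.  A molecular-distance variant
(weighting haplotype pairs by mutational distance) is out of scope.

Ordination is metric SMACOF: classical (Torgerson) scaling initializes
the configuration, and the Guttman transform
`X ← n⁻¹B(X)X` iterates until the stress-1 decrease falls below `1e−6`
(at most 1000 iterations).  Stress-1 is normalized by `Σδ²` with unit
weights.  Majorization guarantees a non-increasing stress sequence, and
on matrices that embed exactly in two dimensions the Torgerson start is
already optimal, so stress reaches numerical zero immediately.  The
seed only matters if the start is degenerate (all points coincident),
in which case a small jitter is applied.

## Weighted-least-squares admixture

Mixing proportions solve
$\min_m (h - Pm)^\top W (h - Pm)$ subject to $\sum_k m_k = 1$, with `h`
the hybrid's relative frequencies, `P` the parental frequency matrix and
`W = diag(1/(\bar p_i(1-\bar p_i)))`, `\bar p` the unweighted parental
mean; categories with `\bar p ∈ {0,1}` carry no information and are
dropped.  The sum constraint is enforced by substituting the last
component into the normal equations.  A solution outside the simplex is
handled either by clipping and renormalizing (default; transparent and
adequate when the violation is sampling noise) or by an active-set
non-negative solve of the same constrained problem (`constrain =
"nnls"`), which never has a larger weighted residual.  Collinear
parentals raise an explicit error rather than a pseudo-inverse guess.

Uncertainty comes by default from multinomial bootstrap of the hybrid
and every parental at their observed sample sizes (`B = 1000`,
seed-deterministic); a first-order analytic (GLS sandwich) alternative
treating parentals as fixed is provided for large samples.  Published
admixture tables from comparable studies do not state which convention
their ± values use, so both are exposed and the bootstrap is the
default.  Reproduction of any specific published table would require
that study's reference frequency panels; correctness is instead
certified by parameter recovery: hybrids of size 300 drawn from
`m = (0.56, 0.40, 0.04)` over well-separated parentals are recovered
with mean error below 0.03 per component, and per component the ±2
bootstrap-SE interval covers the truth in ≥ 90% of replicates.

## Median-joining networks

Nodes are haplotype motifs encoded as state vectors over their variant
sites; edge lengths count differing sites.  The ε-relaxed minimum
spanning network (union of all minimum spanning trees at ε = 0) is the
backbone; median (majority-consensus) vectors of node triplets supply
candidate unsampled intermediates.  Which candidates to keep is the
genuinely open design point.  Admitting every median of small connection
cost — the classical greedy rule — can both retain medians that lie on
no minimum-length structure and miss Steiner points reachable only
through triplets that are not yet linked.  `mitopop` therefore treats
parsimony as the admission criterion:

* **Small inputs (≤ 8 distinct haplotypes):** the full median closure
  is built, every subset of candidate medians (up to the Steiner bound
  of `n − 2` extra nodes, within an enumeration budget) is scored by the
  minimum spanning length of the augmented node set, and the union of
  all optimal configurations is kept — a configuration only counts if
  its medians can simultaneously attain degree ≥ 3 in a spanning tree of
  optimal length, since a degree-2 median is a redundant path point.
  The result is exactly the union of minimum-length (Steiner) networks,
  verified in the test suite against an independent exhaustive oracle on
  random inputs of up to 5 haplotypes over 6 variant columns.
* **Larger inputs:** a greedy round-based approximation admits a median
  when it strictly shortens the spanning length of the current node set,
  or ties it while attaining degree ≥ 3 in the augmented spanning
  network.

In both modes unsampled medians of degree ≤ 2 are pruned and the
spanning network recomputed until stable; sampled haplotypes are never
deleted.  All tie-breaks are lexicographic on the motif string, so the
construction is deterministic.  ε defaults to 0 and is exposed; ε > 0
relaxes both the spanning rounds and the admission tolerance.

## Rho dating

A genealogy is extracted from the network as the shortest-path tree
from a user-designated ancestral motif (reticulations resolve toward
the lexicographically smaller parent; an absent root may be inserted as
an unsampled node if it lies within one mutation of the network).  The
coalescence estimator is

$$\rho = \frac{1}{n}\sum_{\text{samples}} d(\text{sample},
\text{root}),\qquad
\sigma^2 = \frac{1}{n^2}\sum_{\text{links}} l_{\text{link}}\,
n_{\text{link}}^2,$$

with `l` the mutations on a link and `n_link` the sampled sequences
below it (Saillard's error).  Ages multiply by the clock's
years-per-substitution, default 3,624 — the standard
purifying-selection-corrected whole-mitogenome rate; HVRI-only data
evolve faster, so ages from HVRI motifs under the default clock are
upper-bound-flavoured and a segment-appropriate rate should be set via
`rate_config()`.  `date_clade()` chains the dating-scope dedup, the
hypermutable-site filter, network construction rooted at the clade's
cumulative motif, and ρ.  Note the Saillard error quantifies the
mutational sampling variance along a fixed genealogy; on a star of `n`
independent lineages it equals `ρ/n`, close to the Poisson variance of
the mean, and the ±2σ interval covers the true age in at least 90% of
simulated star clades in the validation suite.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with truth labels retained everywhere:

* island populations drawn multinomially from fixed haplogroup
  frequency vectors — the bundled default mirrors a six-population
  archipelago (70, 35, 53, 57, 87 and 20 samples; 322 in all) with
  strong founder effects in two western populations (one haplogroup at
  69/70 in one, another at 38/57 in the second) and several categories
  private to the eastern pair;
* sequences realized as the haplogroup motif plus
  `Poisson(private_mutation_rate)` private substitutions (default 0.2
  per sequence — rare, as observed in closely related island lineages;
  private mutations avoid the excluded positions so round trips are
  exact);
* admixed populations drawn multinomially from a known linear
  combination of parental frequency vectors;
* genealogies in which each root-tip path spans a known age, either as
  independent star lineages or along a random ultrametric coalescent
  topology (shared mutations through shared ancestry), with Poisson
  mutation counts at the clock rate.

What the generator does **not** emulate: post-mortem damage and
sequencing error, heteroplasmy, alignment artefacts around the HVRI
homopolymer tracts, rate heterogeneity among sites, and real phylotree
topology/weights.  Passing tests therefore certify the statistical
machinery, not robustness to those data pathologies.

## Numerical and testing choices

Problem sizes in the routine test run are chosen to keep the full suite
fast while leaving Monte-Carlo margins honest: 1,000 random tables for
the Fisher oracle, 200 count-vector pairs for the Φ_ST oracle, 100
SMACOF trials, 200 admixture replicates at n = 300, 100 dating
replicates at 200 lineages, and 40 random haplotype sets (plus the
hand-constructed corner cases) for the network oracle.  Degenerate
inputs are defined rather than left to chance: a zero Fisher margin
gives p = 1, a monomorphic sample has `H = SE = 0`, identical
populations have `Φ = 0` exactly, two-point MDS is always exact, a
single-haplotype clade dates to ρ = 0 and is flagged low-information.
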