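# mitopop

Mitochondrial haplotype and population-structure analysis for small,
subdivided populations — the kind of dataset produced by ancient-DNA
surveys of island archipelagos, where a few hundred hypervariable-region
(HVRI) sequences or whole mitogenomes per island must answer questions
about founder effects, asymmetric migration and admixture.

`mitopop` implements the full analysis chain as composable R functions:

* **Haplotyping** — global alignment of HVRI fragments against a
  reference segment (free end gaps, automatic reverse-complement
  detection), variant calling in standard mtDNA motif notation
  (`16223T`, `309.1C`, `16166d`, `@16189`), and haplogroup assignment
  against a reduced phylotree by the Kulczynski match score
  `½(|M∩E|/|E| + |M∩E|/|M|)`.
* **Diversity** — Nei's unbiased gene diversity
  `H = n/(n−1)(1 − Σ pᵢ²)` with its sampling standard error.
* **Geographic asymmetry** — exact two-tailed Fisher tests (full
  hypergeometric enumeration) contrasting haplogroup counts between
  island groups.
* **Population distances** — pairwise Φ_ST from AMOVA variance
  components with 0/1 haplotype distances, linearized as
  `D = Φ/(1−Φ)` (Slatkin), and metric MDS by SMACOF stress
  majorization.
* **Admixture** — Long's weighted-least-squares estimator of parental
  mixing proportions `m` minimizing `(h − Pm)ᵀW(h − Pm)` under
  `Σm = 1`, with bootstrap or analytic standard errors.
* **Networks & dating** — median-joining haplotype networks (exact
  minimum-length median network on small inputs, greedy approximation on
  large ones) and ρ-statistic coalescence ages with Saillard standard
  errors under a fixed clock (default one substitution per 3,624 years).
* **Synthetic data** — seed-deterministic generators for island
  populations, admixed samples and star/coalescent genealogies, so the
  whole pipeline is testable with known truth and no external data.

## Worked example

The bundled fixture table (19 haplogroup categories × 6 island
populations, n = 322) drives every frequency-based stage:

```r
library(mitopop)

tab <- island_freq_fixture()
population_sizes(tab)
#>     HIE     PAL     TFE     GOM     GCA LAN&FUE
#>      70      35      53      57      87      20

# near-fixation on the westernmost island: one haplotype at 69/70
nei_diversity(c(69, 1))
#> <gene diversity 2.86% +/- 2.76% (n = 70, k = 2)>

# which haplogroups are asymmetrically distributed east vs west?
asymmetry_scan(tab, categories = c("H4a1e", "L3b1a12", "U5", "U6c",
                                   "T2c1", "U6a"))
#>   category east west east_n west_n           p
#> 1    H4a1e    4    0    107    215 0.011738449
#> 2  L3b1a12    5    0    107    215 0.003802076
#> 3       U5    4    0    107    215 0.011738449
#> 4      U6c    6    0    107    215 0.001223381
#> 5     T2c1   17   15    107    215 0.016812119
#> 6      U6a    8    2    107    215 0.002896116
```

The six haplogroups are all significantly enriched in the two eastern
populations (107 of 322 samples); after dropping the two drifted western
islands the U6c signal persists (`p = 0.0332`).  Distances and
ordination follow directly:

```r
D <- distance_matrix(tab)          # linearized pairwise Phi_ST
fit <- smacof_mds(D)               # 2-D embedding, stress-1 reported
round(fit$stress, 3)
#> [1] 0.31
```

A dating run on a simulated star clade (20 lineages, true age 7,248
years, clock 3,624 y/substitution):

```r
tree <- read_phylotree(system.file("extdata", "synthetic_phylotree.json",
                                   package = "mitopop"))
root <- cumulative_motif(tree, "U6b1a")
sim  <- simulate_genealogy(root, 20, 7248, topology = "star", seed = 7)
samples <- data.frame(sample_id = sprintf("s%02d", 1:20), island = "GOM",
                      site = sprintf("site%d", 1:20), period = "ancient",
                      haplogroup = "U6b1a",
                      motif = vapply(sim$motifs, format, ""),
                      multiplicity = 1L)
date_clade(samples, "U6b1a", tree)
#> <rho 1.800 +/- 0.300 (n = 20): age 6523 +/- 1087 years>
```

The ρ estimate (mean mutational distance to the root, here over the
median-joining network) times the clock rate recovers the planted age
within one standard error.

`run_pipeline()` chains all stages from a single YAML or list config and
writes per-stage TSVs plus a reproducibility manifest; see
`?run_pipeline` and the thin CLI wrapper in `inst/cli/mitopop.R`.

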