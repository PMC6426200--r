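# Seed-deterministic synthetic data with the statistical structure the
# analysis assumes: island populations drawn multinomially from fixed
# haplogroup frequency vectors, near-identical HVRI sequences derived
# from haplogroup motifs plus rare private mutations, admixed populations
# drawn from known mixtures of parental frequency vectors, and rooted
# genealogies accumulating Poisson-distributed mutations under a known
# clock.  Every generator emits truth labels next to the data.

#' Multinomial population sample
#'
#' @param freqs Frequency vector (non-negative, summing to 1 within
#'   1e-9; renormalized exactly).
#' @param n Sample size.
#' @param seed Optional integer seed.
#' @return Integer count vector (named as `freqs`).
#' @export
sample_population <- function(freqs, n, seed = NULL) {
  if (any(freqs < 0)) stop("negative frequency")
  if (abs(sum(freqs) - 1) > 1e-9) stop("frequencies must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  stats::setNames(as.vector(stats::rmultinom(1, n, freqs)), names(freqs))
}

#' Archipelago simulation specification
#'
#' Describes a set of island populations by their haplogroup frequency
#' vectors, the motif realizing each haplogroup, and the rate of private
#' mutations per sampled sequence.
#'
#' @param islands Data frame with columns `label` and `n`.
#' @param freqs Matrix of haplogroup frequencies, categories in rows,
#'   one column per island label; columns sum to 1 within 1e-9.
#' @param motif_catalog Named list: category -> [motif()].
#' @param private_mutation_rate Poisson mean of extra private
#'   substitutions per sequence (default 0.2, about one private variant
#'   in five HVRI sequences -- rare, as in closely related island
#'   lineages).
#' @param reference A [ref_segment()], default the synthetic HVRI
#'   segment.
#' @param seed Integer seed.
#' @return List with class `"archipelago_spec"`.
#' @export
archipelago_spec <- function(islands, freqs, motif_catalog,
                             private_mutation_rate = 0.2,
                             reference = synthetic_hvri_reference(),
                             seed = 1L) {
  stopifnot(all(c("label", "n") %in% names(islands)),
            all(islands$n >= 0),
            all(islands$label %in% colnames(freqs)))
  if (any(abs(colSums(freqs) - 1) > 1e-9))
    stop("frequency columns must sum to 1")
  if (private_mutation_rate < 0) stop("private_mutation_rate must be >= 0")
  missing_motifs <- setdiff(rownames(freqs), names(motif_catalog))
  if (length(missing_motifs))
    stop("no motif for category: ", paste(missing_motifs, collapse = ", "))
  structure(list(islands = islands, freqs = freqs,
                 motif_catalog = motif_catalog,
                 private_mutation_rate = private_mutation_rate,
                 reference = reference, seed = as.integer(seed)),
            class = "archipelago_spec")
}

# positions where a private mutation may land: inside the segment, off
# the exclusion list, off the sites already in `taken` (internal)
free_positions <- function(reference, taken = integer(),
                           exclusions = default_exclusions()) {
  pos <- reference$start:reference$end
  setdiff(pos, c(exclusions$substitution_positions,
                 exclusions$indel_positions, taken))
}

# random substitution token at `pos` differing from the reference base
private_substitution <- function(pos, reference) {
  refbase <- substr(reference$sequence, pos - reference$start + 1L,
                    pos - reference$start + 1L)
  alt <- sample(setdiff(c("A", "C", "G", "T"), refbase), 1L)
  paste0(pos, alt)
}

#' Generate sequences and a truth table for an archipelago
#'
#' For each island, haplogroup counts are drawn multinomially from the
#' island's frequency vector; each sample's sequence realizes the
#' haplogroup motif plus `Poisson(private_mutation_rate)` random private
#' substitutions at non-excluded positions, so variant calling and
#' haplogroup assignment can be validated against the retained truth
#' labels.
#'
#' @param spec An [archipelago_spec()].
#' @return List: `sequences` (named character vector) and `samples`
#'   (data frame with `sample_id`, `island`, `site`, `period`,
#'   `haplogroup` (truth), `motif` (truth, canonical tokens),
#'   `multiplicity`).
#' @export
generate_sequences <- function(spec) {
  stopifnot(inherits(spec, "archipelago_spec"))
  set.seed(spec$seed)
  ref <- spec$reference
  seqs <- character(); rows <- list()
  counter <- 0L
  for (i in seq_len(nrow(spec$islands))) {
    lab <- spec$islands$label[i]; n <- spec$islands$n[i]
    if (n == 0L) next
    counts <- sample_population(spec$freqs[, lab], n)
    for (cat in rownames(spec$freqs)) {
      k <- counts[[cat]]
      if (k == 0L) next
      base <- motif(spec$motif_catalog[[cat]])
      for (s in seq_len(k)) {
        counter <- counter + 1L
        extra <- stats::rpois(1, spec$private_mutation_rate)
        taken <- motif_df(base)$position
        tokens <- character()
        if (extra > 0) {
          pool <- free_positions(ref, taken)
          pos <- sample(pool, min(extra, length(pool)))
          tokens <- vapply(pos, private_substitution, "", reference = ref)
        }
        m <- compose_variants(base, motif(tokens))
        sid <- sprintf("syn%04d", counter)
        seqs[sid] <- motif_to_sequence(m, ref)
        rows[[counter]] <- data.frame(
          sample_id = sid, island = lab,
          site = paste0(lab, "_site", 1 + (counter %% 3)),
          period = "ancient", haplogroup = cat, motif = format(m),
          multiplicity = 1L, stringsAsFactors = FALSE)
      }
    }
  }
  list(sequences = seqs, samples = do.call(rbind, rows))
}

#' Draw an admixed population from parental frequency vectors
#'
#' A multinomial draw of size `n` from `sum_k m_k * parental_k`.
#'
#' @param parentals List of frequency vectors over one category
#'   universe.
#' @param m Mixing proportions, summing to 1.
#' @param n Sample size.
#' @param seed Optional integer seed.
#' @return Integer count vector.
#' @export
generate_admixed <- function(parentals, m, n, seed = NULL) {
  if (abs(sum(m) - 1) > 1e-9 || any(m < 0))
    stop("mixing proportions must be non-negative and sum to 1")
  lens <- vapply(parentals, length, 0L)
  if (length(unique(lens)) != 1L || length(m) != length(parentals))
    stop("dimension mismatch between parentals and m")
  P <- vapply(parentals, function(x) x / sum(x), numeric(lens[1]))
  mix <- as.vector(P %*% m)
  sample_population(mix / sum(mix), n, seed = seed)
}

#' Simulate a rooted genealogy under a substitution clock
#'
#' Each root-to-tip path spans `age_years`, and mutations accrue as a
#' Poisson process at one substitution per `rate$years_per_substitution`
#' years.  `"star"` draws independent `Poisson(age/rate)` mutation counts
#' per lineage; `"yule"` draws a random ultrametric coalescent topology
#' (rescaled so every root-leaf path equals `age_years`) and mutates each
#' branch, so lineages share mutations through shared ancestry.
#' Mutations land at random non-excluded positions of the reference
#' segment not already used on that lineage's path.
#'
#' @param root Ancestral motif.
#' @param n_lineages Number of sampled lineages.
#' @param age_years True clade age.
#' @param rate A [rate_config()].
#' @param topology `"star"` or `"yule"`.
#' @param reference A [ref_segment()].
#' @param seed Optional integer seed.
#' @return List: `motifs` (one per lineage), `multiplicity` (all 1),
#'   `mutation_counts` (star only: per-lineage counts), `root`,
#'   `age_years`, `topology`.
#' @export
simulate_genealogy <- function(root, n_lineages, age_years,
                               rate = rate_config(),
                               topology = c("star", "yule"),
                               reference = synthetic_hvri_reference(),
                               seed = NULL) {
  topology <- match.arg(topology)
  if (age_years < 0) stop("age_years must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  root <- motif(root)
  mu <- age_years / rate$years_per_substitution
  mutate_lineage <- function(base, k) {
    if (k == 0) return(base)
    taken <- motif_df(base)$position
    pool <- free_positions(reference, taken)
    pos <- sample(pool, min(k, length(pool)))
    compose_variants(base, motif(vapply(pos, private_substitution, "",
                                        reference = reference)))
  }
  if (topology == "star") {
    ks <- stats::rpois(n_lineages, mu)
    motifs <- lapply(ks, function(k) mutate_lineage(root, k))
    return(list(motifs = motifs, multiplicity = rep(1L, n_lineages),
                mutation_counts = ks, root = root, age_years = age_years,
                topology = topology))
  }
  if (n_lineages == 1L) {
    motifs <- list(mutate_lineage(root, stats::rpois(1, mu)))
    return(list(motifs = motifs, multiplicity = 1L, mutation_counts = NULL,
                root = root, age_years = age_years, topology = topology))
  }
  phy <- ape::rcoal(n_lineages)
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length / depth * age_years
  ntip <- n_lineages
  root_node <- ntip + 1L
  node_motif <- vector("list", ntip + phy$Nnode)
  node_motif[[root_node]] <- root
  # walk edges parent-before-child (ape edge matrix is in preorder for rcoal,
  # but sort defensively by parent depth)
  depths <- ape::node.depth.edgelength(phy)
  ord <- order(depths[phy$edge[, 1]])
  for (k in ord) {
    par <- phy$edge[k, 1]; chd <- phy$edge[k, 2]
    len <- phy$edge.length[k]
    kmut <- stats::rpois(1, len / rate$years_per_substitution)
    node_motif[[chd]] <- mutate_lineage(node_motif[[par]], kmut)
  }
  list(motifs = node_motif[seq_len(ntip)],
       multiplicity = rep(1L, ntip), mutation_counts = NULL,
       root = root, age_years = age_years, topology = topology)
}

#' Bundled island haplogroup frequency fixture
#'
#' A hard-coded 19-category x 6-population table of ancient mtDNA
#' haplogroup counts across an island archipelago (two eastern
#' populations -- one of them the pooled pair of easternmost islands --
#' and four western), with strong founder effects in the westernmost
#' populations.  Column totals are 70, 35, 53, 57, 87 and 20 (grand
#' total 322).  It drives the frequency-only stages (diversity, Fisher
#' scan, distances, admixture parentals) without any external data.
#'
#' @return A [freq_table()].
#' @export
island_freq_fixture <- function() {
  cats <- c("H", "H1cf", "H4a1e", "HV0", "J", "K", "L1/L2", "L3",
            "L3b1a12", "M1", "Other T", "T2c1", "U5", "U6a", "U6b",
            "U6c", "U7", "W1e1", "X3a")
  m <- matrix(c(
    # HIE PAL TFE GOM GCA LAN&FUE
      12, 10, 15,  2, 33, 13,   # H
      57,  8,  6,  2,  1,  0,   # H1cf
       0,  0,  0,  0,  3,  1,   # H4a1e
       0,  0,  1,  0,  0,  0,   # HV0
       0,  3,  4,  5,  2,  0,   # J
       0,  1,  1,  1,  2,  0,   # K
       0,  2,  2,  1,  1,  0,   # L1/L2
       0,  0,  2,  4,  1,  0,   # L3
       0,  0,  0,  0,  5,  0,   # L3b1a12
       0,  0,  0,  0,  1,  0,   # M1
       0,  1,  0,  0,  3,  0,   # Other T
       0,  3, 12,  0, 15,  2,   # T2c1
       0,  0,  0,  0,  3,  1,   # U5
       0,  0,  2,  0,  6,  2,   # U6a
       0,  2,  8, 38,  4,  0,   # U6b
       0,  0,  0,  0,  5,  1,   # U6c
       1,  0,  0,  0,  0,  0,   # U7
       0,  1,  0,  0,  0,  0,   # W1e1
       0,  4,  0,  4,  2,  0),  # X3a
    nrow = 19, byrow = TRUE,
    dimnames = list(cats, c("HIE", "PAL", "TFE", "GOM", "GCA", "LAN&FUE")))
  freq_table(m)
}

#' Default archipelago specification
#'
#' An [archipelago_spec()] whose island frequency vectors are the
#' relative frequencies of [island_freq_fixture()] and whose motif
#' catalog comes from the bundled reduced phylotree, so the whole
#' pipeline can be demonstrated end to end on synthetic sequences.
#'
#' @param private_mutation_rate,seed Passed to [archipelago_spec()].
#' @return An [archipelago_spec()].
#' @export
default_archipelago_spec <- function(private_mutation_rate = 0.2, seed = 1L) {
  tab <- island_freq_fixture()
  tree <- read_phylotree(system.file("extdata", "synthetic_phylotree.json",
                                     package = "mitopop", mustWork = TRUE))
  reps <- c("H" = "H", "H1cf" = "H1cf", "H4a1e" = "H4a1e", "HV0" = "HV0",
            "J" = "J", "K" = "K", "L1/L2" = "L1b", "L3" = "L3",
            "L3b1a12" = "L3b1a12", "M1" = "M1", "Other T" = "T",
            "T2c1" = "T2c1", "U5" = "U5", "U6a" = "U6a", "U6b" = "U6b1a",
            "U6c" = "U6c", "U7" = "U7", "W1e1" = "W1e1", "X3a" = "X3a")
  seg <- synthetic_hvri_reference()
  catalog <- lapply(reps, function(lab) {
    df <- motif_df(cumulative_motif(tree, lab))
    motif(df$token[df$position >= seg$start & df$position <= seg$end])
  })
  names(catalog) <- names(reps)
  sizes <- population_sizes(tab)
  archipelago_spec(
    islands = data.frame(label = colnames(tab), n = as.integer(sizes),
                         stringsAsFactors = FALSE),
    freqs = sweep(unclass(tab), 2, sizes, "/"),
    motif_catalog = catalog,
    private_mutation_rate = private_mutation_rate,
    reference = seg, seed = seed)
}
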