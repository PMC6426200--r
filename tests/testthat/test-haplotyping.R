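# Alignment, variant calling, sequence reconstruction, haplogroup
# assignment and the relatedness dedup rule.

seg <- synthetic_hvri_reference()

test_that("alignment of identical and mutated sequences is exact", {
  aln <- align_to_reference(seg$sequence, seg)
  expect_equal(aln$identity, 1)
  expect_false(aln$reverse_complemented)
  expect_length(unclass(call_variants(aln)$motif), 0L)
  s <- motif_to_sequence(motif("16223T"), seg)
  cv <- call_variants(align_to_reference(s, seg))
  expect_equal(unclass(cv$motif), "16223T")
})

test_that("reverse-complemented input is detected and aligned", {
  s <- motif_to_sequence(motif("16223T 16311C"), seg)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  aln <- align_to_reference(rc, seg)
  expect_true(aln$reverse_complemented)
  expect_equal(unclass(call_variants(aln)$motif), c("16223T", "16311C"))
})

test_that("non-homologous and out-of-range sequences are rejected", {
  expect_error(align_to_reference(strrep("A", 401), seg), "identity")
  expect_error(align_to_reference("ACGT", seg), "outside")
})

test_that("excluded calls are reported separately, never dropped silently", {
  s <- motif_to_sequence(motif("16193.1C 16223T"), seg)
  cv <- call_variants(align_to_reference(s, seg))
  expect_equal(unclass(cv$motif), "16223T")
  expect_equal(unclass(cv$excluded), "16193.1C")
})

test_that("motif realization inverts variant calling off the exclusion set", {
  expect_equal(motif_to_sequence(motif(), seg), seg$sequence)
  expect_error(motif_to_sequence(motif("309.1C"), seg), "outside")
  # property: random substitution/deletion motifs round-trip exactly
  set.seed(11)
  excl <- default_exclusions()
  pool <- setdiff(seg$start:seg$end,
                  c(excl$substitution_positions, excl$indel_positions))
  for (rep in 1:100) {
    k <- sample(0:6, 1)
    pos <- sort(sample(pool, k))
    tokens <- vapply(pos, function(p) {
      refbase <- substr(seg$sequence, p - seg$start + 1L, p - seg$start + 1L)
      paste0(p, sample(setdiff(c("A", "C", "G", "T"), refbase), 1))
    }, "")
    m <- motif(tokens)
    cv <- call_variants(align_to_reference(motif_to_sequence(m, seg), seg))
    expect_identical(unclass(cv$motif), unclass(m))
    expect_length(unclass(cv$excluded), 0L)
  }
})

test_that("assignment scores follow the Kulczynski measure", {
  tree <- tiny_tree()
  # exact leaf motif scores 1
  res <- assign_haplogroup(motif("16111T 16223T"), tree)
  expect_equal(res$haplogroup, "A1")
  expect_equal(res$score, 1)
  # empty motif goes to the root with score 1
  res0 <- assign_haplogroup(motif(), tree)
  expect_equal(res0$haplogroup, "root")
  expect_equal(res0$score, 1)
  # hand evaluation: M = {16111T, 16223T, 16290T}, E_A1 = {16111T, 16223T}
  # -> (2/2 + 2/3) / 2 = 5/6
  res1 <- assign_haplogroup(motif("16111T 16223T 16290T"), tree)
  expect_equal(res1$haplogroup, "A1")
  expect_equal(res1$score, 5 / 6, tolerance = 1e-12)
  expect_equal(res1$expected_found, 2L)
  expect_equal(res1$expected_total, 2L)
  expect_equal(unclass(res1$private_variants), "16290T")
  # deterministic and invariant under motif token order
  res2 <- assign_haplogroup(motif(c("16290T", "16223T", "16111T")), tree)
  expect_identical(res2$haplogroup, res1$haplogroup)
  expect_identical(res2$score, res1$score)
  expect_error(assign_haplogroup(motif("16111T"), phylo_tree(list())),
               "root|empty")
})

test_that("assignment recovers the generating node for clean motifs", {
  tree <- fixture_tree()
  labels <- names(tree$nodes)
  set.seed(42)
  picks <- sample(labels, 500, replace = TRUE)
  hits <- vapply(picks, function(lab) {
    res <- assign_haplogroup(cumulative_motif(tree, lab), tree, segment = seg)
    res$haplogroup == lab && res$score == 1
  }, TRUE)
  expect_true(all(hits))
})

test_that("a sample lacking a back-mutated variant matches the derived node", {
  tree <- fixture_tree()
  # U6b1a's cumulative motif omits 16219G (back mutation of the U6 variant)
  m <- cumulative_motif(tree, "U6b1a")
  expect_false("16219G" %in% unclass(m))
  expect_equal(assign_haplogroup(m, tree)$haplogroup, "U6b1a")
})

test_that("site dedup keeps one ancient record per rule and scope", {
  samples <- data.frame(
    sample_id = c("b", "a", "c", "d", "e", "f"),
    island = "GCA",
    site = c("s1", "s1", "s1", "s2", "s1", "s1"),
    period = c("ancient", "ancient", "ancient", "ancient", "ancient",
               "modern"),
    haplogroup = c("H1cf", "H1cf", "U6b1a", "H1cf", "U6b1a", "H1cf"),
    motif = "", multiplicity = 1L, stringsAsFactors = FALSE)
  pa <- dedup_by_site(samples, "population-analysis")
  # one per (site, haplogroup): s1/H1cf -> "a" (smallest id), s1/U6b1a -> "c",
  # s2/H1cf -> "d"; the modern record is untouched
  expect_setequal(pa$sample_id, c("a", "c", "d", "f"))
  dt <- dedup_by_site(samples, "dating")
  # one ancient record per site
  expect_setequal(dt$sample_id, c("a", "d", "f"))
})
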