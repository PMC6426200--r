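# Synthetic-data generators: determinism, distributional behavior, and
# end-to-end recovery of the planted truth.

test_that("multinomial population sampling is seeded and exact", {
  expect_equal(unname(sample_population(c(1), 70, seed = 1)), 70L)
  expect_identical(sample_population(c(0.3, 0.7), 50, seed = 3),
                   sample_population(c(0.3, 0.7), 50, seed = 3))
  expect_error(sample_population(c(-0.1, 1.1), 10), "negative")
  expect_error(sample_population(c(0.5, 0.4), 10), "sum to 1")
  # law of large numbers: mean frequency within 3 Monte-Carlo SE
  set.seed(77)
  p <- c(0.6, 0.3, 0.1); n <- 40
  draws <- replicate(4000, sample_population(p, n) / n)
  mc_se <- sqrt(p * (1 - p) / n) / sqrt(4000)
  expect_true(all(abs(rowMeans(draws) - p) < 3 * mc_se + 1e-3))
})

test_that("admixed draws honor the mixture and its degenerate cases", {
  parentals <- list(c(0.8, 0.1, 0.1), c(0.1, 0.1, 0.8))
  x <- generate_admixed(parentals, m = c(1, 0), n = 500, seed = 5)
  # m = (1, 0): the mixture is parental 1 exactly
  set.seed(5)
  expect_equal(unname(x),
               unname(sample_population(parentals[[1]], 500)))
  expect_equal(sum(generate_admixed(parentals, c(0.5, 0.5), 1, seed = 2)), 1)
  expect_error(generate_admixed(parentals, c(0.7, 0.7), 10), "sum to 1")
  expect_error(generate_admixed(parentals, c(1), 10), "mismatch")
})

test_that("archipelago sequence generation retains recoverable truth", {
  spec <- default_archipelago_spec(private_mutation_rate = 0, seed = 42)
  # shrink to a fast subset: three islands, 12 samples each
  spec$islands <- data.frame(label = c("HIE", "GOM", "GCA"),
                             n = c(12L, 12L, 12L))
  out <- generate_sequences(spec)
  expect_equal(nrow(out$samples), 36L)
  expect_equal(length(out$sequences), 36L)
  tree <- fixture_tree()
  seg <- spec$reference
  hit <- vapply(seq_len(nrow(out$samples)), function(i) {
    s <- out$sequences[[out$samples$sample_id[i]]]
    cv <- call_variants(align_to_reference(s, seg))
    res <- assign_haplogroup(cv$motif, tree, segment = seg)
    cat_match <- mitopop:::match_category(
      res$haplogroup, rownames(spec$freqs))
    identical(cat_match, out$samples$haplogroup[i])
  }, TRUE)
  expect_true(all(hit))   # rate 0: perfect recovery
  # deterministic given the seed
  out2 <- generate_sequences(spec)
  expect_identical(out2$sequences, out$sequences)
  # empty island skipped
  spec$islands$n[2] <- 0L
  expect_equal(sort(unique(generate_sequences(spec)$samples$island)),
               c("GCA", "HIE"))
})

test_that("private mutations barely perturb haplogroup recovery", {
  spec <- default_archipelago_spec(private_mutation_rate = 0.5, seed = 9)
  spec$islands <- data.frame(label = c("TFE", "GCA"), n = c(20L, 20L))
  out <- generate_sequences(spec)
  tree <- fixture_tree()
  seg <- spec$reference
  hits <- vapply(seq_len(nrow(out$samples)), function(i) {
    res <- assign_haplogroup(motif(out$samples$motif[i]), tree,
                             segment = seg)
    identical(mitopop:::match_category(res$haplogroup,
                                       rownames(spec$freqs)),
              out$samples$haplogroup[i])
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("simulated genealogies scale with the clock", {
  root <- motif("16172C 16219G")
  sim0 <- simulate_genealogy(root, 10, 0, topology = "star", seed = 1)
  expect_true(all(vapply(sim0$motifs, function(m)
    identical(unclass(m), unclass(root)), TRUE)))
  expect_equal(rho_statistic(star_tree(sim0$motifs, root = root))$rho, 0)
  # star at one clock unit: mean rho near 1 over replicates
  set.seed(6)
  rhos <- replicate(40, {
    sim <- simulate_genealogy(motif(), 100, 3624, topology = "star")
    mean(sim$mutation_counts)
  })
  mc_se <- sd(rhos) / sqrt(length(rhos))
  expect_lt(abs(mean(rhos) - 1), 3 * mc_se + 0.01)
  # seed determinism, both topologies
  for (topo in c("star", "yule")) {
    a <- simulate_genealogy(motif(), 12, 5000, topology = topo, seed = 31)
    b <- simulate_genealogy(motif(), 12, 5000, topology = topo, seed = 31)
    expect_identical(vapply(a$motifs, format, ""),
                     vapply(b$motifs, format, ""))
  }
  expect_error(simulate_genealogy(motif(), 5, -1), ">= 0")
})

test_that("yule genealogies share mutations through common ancestry", {
  set.seed(15)
  # clock linearity: doubling the age doubles the expected tip depth
  depth_at <- function(age) {
    mean(replicate(30, {
      sim <- simulate_genealogy(motif(), 12, age, topology = "yule")
      mean(vapply(sim$motifs, length, 0L))
    }))
  }
  d1 <- depth_at(3624)
  d2 <- depth_at(7248)
  expect_gt(d2 / d1, 1.5)
  expect_lt(d2 / d1, 2.6)
})

test_that("the default archipelago spec mirrors the bundled fixture", {
  spec <- default_archipelago_spec()
  tab <- island_freq_fixture()
  expect_equal(spec$islands$n, unname(population_sizes(tab)))
  expect_equal(unname(colSums(spec$freqs)), rep(1, 6), tolerance = 1e-12)
  expect_setequal(names(spec$motif_catalog), rownames(tab))
  # catalog motifs are distinct, so categories are separable
  keys <- vapply(spec$motif_catalog, format, "")
  expect_false(anyDuplicated(keys) > 0)
})
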