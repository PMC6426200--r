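# Nei gene diversity, exact Fisher tests, frequency tabulation and the
# east/west asymmetry scan.

test_that("Nei diversity matches hand-computed configurations", {
  d <- nei_diversity(c(69, 1))
  expect_equal(round(100 * d$H, 2), 2.86)
  expect_equal(round(100 * d$SE, 2), 2.76)
  expect_equal(d$n, 70)
  expect_equal(d$k, 2)
  # monomorphic sample: H = 0, SE = 0
  d0 <- nei_diversity(c(5))
  expect_equal(d0$H, 0)
  expect_equal(d0$SE, 0)
  # all-distinct limit: H = 1 exactly under the unbiased estimator
  expect_equal(nei_diversity(rep(1, 8))$H, 1)
  expect_error(nei_diversity(c(1)), "at least 2")
})

test_that("Nei diversity is permutation-invariant and split-monotone", {
  set.seed(5)
  for (i in 1:25) {
    counts <- rmultinom(1, 40, rep(1 / 6, 6))[, 1]
    counts <- counts[counts > 0]
    expect_equal(nei_diversity(sample(counts))$H, nei_diversity(counts)$H)
    # splitting one count of 2 into two 1s increases H at fixed n
    if (any(counts == 2)) {
      j <- which(counts == 2)[1]
      split <- c(counts[-j], 1, 1)
      expect_gt(nei_diversity(split)$H, nei_diversity(counts)$H)
    }
  }
})

test_that("diversity estimator is unbiased under multinomial sampling", {
  # the n/(n-1) correction makes E[H] equal the population gene
  # diversity 1 - sum(p^2) exactly
  set.seed(21)
  p <- c(0.5, 0.3, 0.15, 0.05)
  n <- 50
  expected <- 1 - sum(p^2)
  reps <- replicate(10000, nei_diversity(rmultinom(1, n, p)[, 1])$H)
  mc_se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - expected), 3 * mc_se)
})

test_that("exact Fisher test reproduces printed east/west p-values", {
  expect_equal(round(fisher_exact_2x2(6, 0, 101, 215), 4), 0.0012)
  expect_equal(round(fisher_exact_2x2(4, 0, 103, 215), 4), 0.0117)
  expect_equal(fisher_exact_2x2(1, 0, 0, 1), 1.0)
  expect_equal(fisher_exact_2x2(0, 0, 5, 5), 1.0)  # zero margin
  expect_equal(fisher_exact_2x2(matrix(c(6, 101, 0, 215), 2, 2)),
               fisher_exact_2x2(6, 0, 101, 215))
  expect_error(fisher_exact_2x2(-1, 0, 0, 1), "non-negative")
})

test_that("Fisher enumeration agrees with the brute-force oracle", {
  set.seed(99)
  for (i in 1:400) {
    a <- sample(0:30, 1); b <- sample(0:30, 1)
    c_ <- sample(0:30, 1); d <- sample(0:30, 1)
    p <- fisher_exact_2x2(a, b, c_, d)
    q <- oracle_fisher_2x2(a, b, c_, d)
    expect_equal(p, q, tolerance = 1e-12)
  }
  # independent cross-check against the standard implementation
  for (i in 1:50) {
    a <- sample(0:25, 1); b <- sample(0:25, 1)
    c_ <- sample(0:25, 1); d <- sample(0:25, 1)
    if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) next
    expect_equal(fisher_exact_2x2(a, b, c_, d),
                 stats::fisher.test(matrix(c(a, c_, b, d), 2, 2))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("asymmetry scan reproduces all printed p-values on the fixture", {
  tab <- island_freq_fixture()
  sc <- asymmetry_scan(tab, categories = c("H4a1e", "L3b1a12", "U5", "U6c",
                                           "T2c1", "U6a"))
  expect_equal(sc$east_n, rep(107L, 6))
  expect_equal(sc$west_n, rep(215L, 6))
  expect_equal(round(sc$p, 4), c(0.0117, 0.0038, 0.0117, 0.0012, 0.0168,
                                 0.0029))
  red <- asymmetry_scan(tab, west = c("PAL", "TFE"), categories = "U6c")
  expect_equal(red$west_n, 88L)
  expect_equal(round(red$p, 4), 0.0332)
  # absent category skipped with a warning; zero-count category skipped
  expect_warning(asymmetry_scan(tab, categories = c("U6c", "ZZZ")),
                 "not in table")
  tab0 <- freq_table(rbind(unclass(tab), zero = rep(0L, 6)))
  expect_warning(sc0 <- asymmetry_scan(tab0, categories = "zero"),
                 "zero total")
  expect_equal(nrow(sc0), 0L)
  expect_error(asymmetry_scan(tab, east = "XXX"), "not in table")
})

test_that("frequency tabulation respects mixed-granularity schemas", {
  samples <- data.frame(
    sample_id = paste0("s", 1:7),
    island = c("GCA", "GCA", "TFE", "TFE", "LAN", "FUE", "GCA"),
    site = "x", period = "ancient",
    haplogroup = c("H1cf", "H3", "T2c1d", "T2b", "L1b", "L2a", "U6b1a"),
    motif = "", multiplicity = 1L, stringsAsFactors = FALSE)
  schema <- c("H", "H1cf", "T2c1", "Other T", "L1/L2", "U6b")
  tab <- haplogroup_frequencies(samples, categories = schema,
                                pool_lanfue = TRUE)
  expect_equal(unclass(tab)["H1cf", "GCA"], 1L)     # most specific wins
  expect_equal(unclass(tab)["H", "GCA"], 1L)        # H3 -> generic H
  expect_equal(unclass(tab)["T2c1", "TFE"], 1L)     # T2c1d -> T2c1
  expect_equal(unclass(tab)["Other T", "TFE"], 1L)  # T2b -> remainder bucket
  expect_equal(unclass(tab)["L1/L2", "LAN&FUE"], 2L)
  expect_equal(unclass(tab)["U6b", "GCA"], 1L)
  expect_equal(sum(tab), 7L)
  # empty input and single sample
  expect_equal(sum(haplogroup_frequencies(samples[0, , drop = FALSE])), 0L)
  one <- haplogroup_frequencies(samples[1, , drop = FALSE])
  expect_equal(sum(one), 1L)
  # no haplogroup: dropped with warning, or an error in strict mode
  samples$haplogroup[1] <- ""
  expect_warning(haplogroup_frequencies(samples), "no haplogroup")
  expect_error(haplogroup_frequencies(samples, strict = TRUE),
               "no haplogroup")
})
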