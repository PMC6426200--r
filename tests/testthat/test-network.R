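# Median-joining networks, rooted-tree extraction, and rho dating.

test_that("simple haplotype sets yield the expected network shapes", {
  # additive chain: no medians
  net <- median_joining(list("", "16126C", "16126C 16189C"))
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(sum(net$edges$length), 2L)
  expect_true(all(net$nodes$sampled))
  # three singleton motifs: star through the inferred reference median
  net2 <- median_joining(list("16126C", "16189C", "16223T"))
  expect_equal(nrow(net2$nodes), 4L)
  expect_equal(sum(net2$edges$length), 3L)
  med <- net2$nodes[!net2$nodes$sampled, ]
  expect_equal(med$motif, "")
  expect_equal(med$multiplicity, 0L)
  # single haplotype
  net1 <- median_joining(list("16126C 16189C"))
  expect_equal(nrow(net1$nodes), 1L)
  expect_equal(nrow(net1$edges), 0L)
  # duplicates merge with summed multiplicity
  net3 <- median_joining(list("16126C", "16126C", ""), c(1L, 2L, 1L))
  expect_equal(sort(net3$nodes$multiplicity), c(1L, 3L))
})

test_that("median-joining networks match the exhaustive Steiner oracle", {
  set.seed(1234)
  for (trial in 1:25) {
    nhap <- sample(2:5, 1)
    nc <- sample(max(2, ceiling(log2(nhap))):6, 1)
    inp <- random_haplotype_set(nhap, nc)
    or <- oracle_steiner_network(inp$mat)
    net <- median_joining(inp$motifs)
    expect_equal(sum(net$edges$length), or$union_length,
                 info = paste("trial", trial))
    expect_identical(network_node_keys(net, inp$sites), or$node_keys)
    # the network supports a spanning structure no longer than the MST
    # of the sampled haplotypes alone (medians are optional waypoints)
    sp <- network_best_spanning(net)
    expect_lte(sp$best, sp$mst_sampled)
    expect_equal(sp$best, or$tree_length)
  }
})

test_that("rooted trees resolve reticulation toward the smaller parent", {
  net <- median_joining(list("16126C", "16189C", "16126C 16189C", ""))
  expect_equal(nrow(net$edges), 4L)   # 4-cycle
  rt <- extract_rooted_tree(net, "")
  nd <- rt$nodes
  expect_equal(nd$depth[nd$motif == ""], 0L)
  expect_equal(nd$depth[nd$motif == "16126C 16189C"], 2L)
  # both spanning trees give equal root-leaf distances; the tie resolves
  # to the lexicographically smaller parent motif
  expect_equal(nd$parent[nd$motif == "16126C 16189C"], "16126C")
  # tree-shaped networks come back unchanged
  chain <- median_joining(list("", "16126C", "16126C 16189C"))
  rt2 <- extract_rooted_tree(chain, "")
  expect_equal(sum(!is.na(rt2$nodes$parent)), 2L)
  expect_equal(rt2$nodes$depth[rt2$nodes$motif == "16126C 16189C"], 2L)
  # single-node tree
  rt3 <- extract_rooted_tree(median_joining(list("16126C")), "16126C")
  expect_equal(nrow(rt3$nodes), 1L)
})

test_that("absent roots are inserted only within one mutation", {
  net <- median_joining(list("16126C", "16126C 16189C"))
  rt <- extract_rooted_tree(net, "")   # one step from 16126C
  expect_equal(rt$nodes$id[is.na(rt$nodes$parent)], ".")
  expect_false(rt$nodes$sampled[is.na(rt$nodes$parent)])
  far <- median_joining(list("16126C 16189C 16223T 16311C"))
  expect_error(extract_rooted_tree(far, ""), "not placeable")
  expect_error(extract_rooted_tree(net, "16362C", add_root = FALSE),
               "not a node")
})

test_that("rho and Saillard error match hand-evaluated genealogies", {
  # star: 4 lineages, each 2 mutations from the root
  tr <- star_tree(list("16126C 16189C", "16223T 16311C", "16093C 16129A",
                       "16148T 16172C"))
  r <- rho_statistic(tr)
  expect_equal(r$rho, 2)
  expect_equal(r$sigma^2, 4 * 2 / 16)      # sum l * n_l^2 / n^2 = 8/16
  expect_equal(r$age_years, 2 * 3624)
  expect_equal(r$age_SE_years, sqrt(0.5) * 3624)
  expect_false(r$low_information)
  # all samples identical to the root
  r0 <- rho_statistic(star_tree(list("", ""), root = motif()))
  expect_equal(r0$rho, 0)
  expect_equal(r0$sigma, 0)
  expect_equal(r0$age_years, 0)
  expect_true(r0$low_information)
  # rho = 1 converts to one clock unit
  r1 <- rho_statistic(star_tree(list("16126C")), rate_config(3624))
  expect_equal(r1$age_years, 3624)
  # nested chain: root -(1)- a -(1)- b, both sampled once:
  # rho = 3/2; sigma^2 = (1 * 2^2 + 1 * 1^2) / 4 = 5/4
  chain <- median_joining(list("16126C", "16126C 16189C", ""))
  rt <- extract_rooted_tree(chain, "")
  rt$nodes$sampled[rt$nodes$motif == ""] <- FALSE
  rt$nodes$multiplicity[rt$nodes$motif == ""] <- 0L
  r2 <- rho_statistic(rt)
  expect_equal(r2$rho, 1.5)
  expect_equal(r2$sigma^2, 1.25)
  # multiplicity weighting: duplicating a lineage changes rho accordingly
  tr_w <- star_tree(list("16126C 16189C", "16223T"), multiplicity = c(3L, 1L))
  expect_equal(rho_statistic(tr_w)$rho, (3 * 2 + 1) / 4)
})

test_that("clade dating is invariant to within-site duplicates", {
  tree <- fixture_tree()
  root <- cumulative_motif(tree, "U6b1a")
  sim <- simulate_genealogy(root, 12, 7248, topology = "star", seed = 5)
  samples <- data.frame(
    sample_id = sprintf("s%02d", 1:12), island = "GOM",
    site = sprintf("site%d", 1:12), period = "ancient",
    haplogroup = "U6b1a",
    motif = vapply(sim$motifs, format, ""), multiplicity = 1L,
    stringsAsFactors = FALSE)
  res <- date_clade(samples, "U6b1a", tree)
  expect_s3_class(res, "rho_result")
  expect_gte(res$rho, 0)
  # duplicating a sample at an existing site must not change the result
  dup <- samples[1, ]
  dup$sample_id <- "zz99"
  res_dup <- date_clade(rbind(samples, dup), "U6b1a", tree)
  expect_equal(res_dup$rho, res$rho)
  expect_equal(res_dup$sigma, res$sigma)
  # a single-haplotype clade is flagged low-information with rho 0
  one <- samples[1, ]
  one$motif <- format(root)
  res1 <- date_clade(one, "U6b1a", tree)
  expect_equal(res1$rho, 0)
  expect_true(res1$low_information)
  expect_error(date_clade(samples, "X3a", tree), "no samples")
})

test_that("descendant haplogroups are pooled into the dated clade", {
  tree <- fixture_tree()
  samples <- data.frame(
    sample_id = c("a", "b"), island = "GCA", site = c("s1", "s2"),
    period = "ancient", haplogroup = c("U6b", "U6b1a"),
    motif = c(format(cumulative_motif(tree, "U6b")),
              format(cumulative_motif(tree, "U6b1a"))),
    multiplicity = 1L, stringsAsFactors = FALSE)
  res <- date_clade(samples, "U6b", tree)
  expect_equal(res$n, 2)
})
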