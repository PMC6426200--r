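# Independent brute-force oracles and small generators used across the
# suite.  These deliberately re-derive each quantity by the most direct
# route available (full enumeration, explicit pair sums, Lagrange
# algebra) and never call the package implementation they check.

# --- exact Fisher oracle: direct hypergeometric enumeration ---------------
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- a + b + c + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == N) return(1.0)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, support) * choose(r2, c1 - support) / choose(N, c1)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- AMOVA Phi_ST oracle: explicit 0/1 pairwise-distance sums -------------
oracle_phist <- function(counts1, counts2) {
  lab1 <- rep(seq_along(counts1), counts1)   # individual category labels
  lab2 <- rep(seq_along(counts2), counts2)
  n1 <- length(lab1); n2 <- length(lab2); N <- n1 + n2
  allv <- c(lab1, lab2)
  pair_sum <- function(v) {
    s <- 0
    if (length(v) > 1) for (i in 1:(length(v) - 1))
      s <- s + sum(v[(i + 1):length(v)] != v[i])
    s
  }
  ssd_t <- pair_sum(allv) / N
  ssd_w <- pair_sum(lab1) / n1 + pair_sum(lab2) / n2
  ssd_a <- ssd_t - ssd_w
  sigma_w <- if (N > 2) ssd_w / (N - 2) else 0
  n_c <- N - (n1^2 + n2^2) / N
  sigma_a <- (ssd_a - sigma_w) / n_c
  if (sigma_a <= 0) return(0)
  min(1, sigma_a / (sigma_a + sigma_w))
}

# --- equality-constrained least-squares admixture oracle ------------------
# minimize ||h - P m||^2 subject to sum(m) = 1 via the Lagrange system
# [2 P'P, 1; 1', 0] [m; lambda] = [2 P'h; 1]
oracle_ls_admixture <- function(h, P) {
  K <- ncol(P)
  A <- rbind(cbind(2 * crossprod(P), 1), c(rep(1, K), 0))
  b <- c(2 * crossprod(P, h), 1)
  solve(A, b)[seq_len(K)]
}

# --- exhaustive optimal-Steiner-network oracle ----------------------------
# Terminals are rows of a state matrix ("." = reference).  Candidate
# Steiner vectors are every combination of observed column states (full
# pool).  The oracle enumerates candidate subsets up to nt - 2 points,
# finds the minimum spanning length, keeps every optimal subset whose
# points all attain degree >= 3 in one spanning tree of that length, and
# reports the union-of-MSTs network over terminals plus the union of the
# valid subsets.
oracle_dist_mat <- function(M) {
  n <- nrow(M); d <- matrix(0L, n, n)
  if (n > 1) for (i in 1:(n - 1)) {
    d[i, (i + 1):n] <- colSums(t(M[(i + 1):n, , drop = FALSE]) != M[i, ])
    d[(i + 1):n, i] <- d[i, (i + 1):n]
  }
  d
}
oracle_mst_len <- function(D, idx) {
  n <- length(idx)
  if (n < 2) return(0)
  used <- logical(n); used[1] <- TRUE
  key <- D[idx, idx[1]]; tot <- 0
  for (k in 2:n) {
    cand <- which(!used)
    v <- cand[which.min(key[cand])]
    tot <- tot + key[v]; used[v] <- TRUE
    key <- pmin(key, D[idx, idx[v]])
  }
  tot
}
oracle_msn_union <- function(d) {
  n <- nrow(d); edges <- NULL
  if (n < 2) return(NULL)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    w <- d[i, j]; comp <- seq_len(n)
    for (a in 1:(n - 1)) for (b in (a + 1):n) if (d[a, b] < w) {
      ca <- comp[a]; cb <- comp[b]
      if (ca != cb) comp[comp == cb] <- ca
    }
    if (comp[i] != comp[j]) edges <- rbind(edges, c(i, j, w))
  }
  edges
}
oracle_connected <- function(e, n) {
  comp <- seq_len(n)
  for (k in seq_len(nrow(e))) {
    a <- comp[e[k, 1]]; b <- comp[e[k, 2]]
    if (a != b) comp[comp == b] <- a
  }
  length(unique(comp)) == 1
}
oracle_valid_config <- function(D, nt, xidx, L) {
  if (length(xidx) == 0) return(TRUE)
  idx <- c(seq_len(nt), xidx)
  dsub <- D[idx, idx, drop = FALSE]
  pool <- oracle_msn_union(dsub)
  n <- length(idx)
  if (is.null(pool) || nrow(pool) < n - 1) return(FALSE)
  xpos <- (nt + 1):n
  for (comb in utils::combn(nrow(pool), n - 1, simplify = FALSE)) {
    e <- pool[comb, , drop = FALSE]
    if (sum(e[, 3]) != L) next
    if (!oracle_connected(e, n)) next
    deg <- tabulate(c(e[, 1], e[, 2]), nbins = n)
    if (all(deg[xpos] >= 3)) return(TRUE)
  }
  FALSE
}
oracle_steiner_network <- function(term_mat) {
  term_mat <- unname(term_mat)
  nt <- nrow(term_mat)
  states <- lapply(seq_len(ncol(term_mat)), function(j)
    unique(c(term_mat[, j], ".")))
  pool <- as.matrix(expand.grid(states, stringsAsFactors = FALSE))
  tkey <- unname(apply(term_mat, 1, paste, collapse = "|"))
  pkey <- unname(apply(pool, 1, paste, collapse = "|"))
  cand <- pool[!(pkey %in% tkey), , drop = FALSE]
  all_mat <- unname(rbind(term_mat, cand))
  D <- oracle_dist_mat(all_mat)
  max_extra <- min(max(0, nt - 2), nrow(cand))
  best <- Inf; opt <- list()
  for (k in 0:max_extra) {
    subs <- if (k == 0) list(integer()) else
      utils::combn(nrow(cand), k, simplify = FALSE)
    for (s in subs) {
      L <- oracle_mst_len(D, c(seq_len(nt), nt + s))
      if (L < best) { best <- L; opt <- list(s) }
      else if (L == best) opt <- c(opt, list(s))
    }
  }
  opt <- Filter(function(s) oracle_valid_config(D, nt, nt + s, best), opt)
  sidx <- sort(unique(unlist(opt)))
  idx <- c(seq_len(nt), nt + sidx)
  un <- oracle_msn_union(D[idx, idx, drop = FALSE])
  list(tree_length = best,
       union_length = if (is.null(un)) 0 else sum(un[, 3]),
       node_keys = sort(unname(apply(all_mat[idx, , drop = FALSE], 1,
                                     paste, collapse = "|"))))
}

# random distinct binary haplotype sets over <= 6 variant columns
random_haplotype_set <- function(nhap, ncol_) {
  sites <- 16051:(16050 + ncol_)
  alts <- c("A", "C", "G", "T")[1 + (seq_len(ncol_) %% 4)]
  repeat {
    rows <- matrix(sample(c(TRUE, FALSE), nhap * ncol_, TRUE), nhap, ncol_)
    if (!anyDuplicated(apply(rows, 1, paste, collapse = ""))) break
  }
  motifs <- lapply(seq_len(nhap), function(i) {
    on <- which(rows[i, ])
    motif(paste0(sites[on], alts[on]))
  })
  list(motifs = motifs,
       mat = ifelse(rows, matrix(alts, nhap, ncol_, byrow = TRUE), "."),
       sites = as.character(sites))
}

# network node keys expressed in a fixed column space, for comparison
# against the Steiner oracle
network_node_keys <- function(net, sites_all) {
  sort(unname(vapply(seq_len(nrow(net$nodes)), function(i) {
    st <- mitopop:::motif_states(motif(net$nodes$motif[i]))
    v <- rep(".", length(sites_all)); names(v) <- sites_all
    v[names(st)] <- st
    paste(v, collapse = "|")
  }, "")))
}

# Minimum spanning length achievable through a network's nodes when the
# sampled haplotypes are required and median nodes are optional.
network_best_spanning <- function(net) {
  mats <- mitopop:::encode_states(lapply(net$nodes$motif, motif))
  d <- mitopop:::hamming_rows(mats)
  samp <- which(net$nodes$sampled)
  med <- which(!net$nodes$sampled)
  best <- Inf
  subsets <- list(integer())
  if (length(med) > 0 && length(med) <= 10)
    for (k in seq_along(med))
      subsets <- c(subsets, utils::combn(length(med), k, simplify = FALSE))
  for (s in subsets) {
    idx <- c(samp, med[s])
    best <- min(best, mitopop:::mst_total(d[idx, idx, drop = FALSE]))
  }
  list(best = best,
       mst_sampled = mitopop:::mst_total(d[samp, samp, drop = FALSE]))
}

# --- shared fixtures ------------------------------------------------------
fixture_tree <- function() {
  read_phylotree(system.file("extdata", "synthetic_phylotree.json",
                             package = "mitopop", mustWork = TRUE))
}

tiny_tree <- function() {
  phylo_tree(list(
    root = list(parent = NA, variants = character()),
    A = list(parent = "root", variants = "16111T"),
    A1 = list(parent = "A", variants = "16223T")))
}
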