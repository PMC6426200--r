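# Median-joining haplotype networks and rho-statistic coalescence
# dating.
#
# Nodes are haplotype motifs; edge lengths count differing variant
# sites.  The construction is median joining with parsimony as the
# admission criterion for candidate medians (majority-consensus vectors
# of node triplets).  Small inputs are solved exactly: the full median
# closure is searched for every minimum-spanning-length configuration
# and their union is kept (mj_exact).  Larger inputs use a greedy
# round-based approximation in which a median is admitted when it
# shortens -- or ties, while attaining degree >= 3 -- the spanning
# length of the current node set (mj_greedy).  Admission by connection
# cost alone (the classical rule) can both miss Steiner points reachable
# only through unlinked triplets and retain medians lying on no
# minimum-length structure; the parsimony criterion keeps the network
# within the union of optimal (Steiner) configurations.  Unsampled
# medians of degree <= 2 are pruned; all tie-breaks are lexicographic on
# the motif string, making the construction deterministic.

#' Construct a haplotype network object
#'
#' Usually produced by [median_joining()]; the constructor validates
#' structure for hand-built or re-read networks.
#'
#' @param nodes Data frame: `id`, `motif` (canonical token string),
#'   `sampled` (logical), `multiplicity` (integer, 0 for medians).
#' @param edges Data frame: `from`, `to` (node ids), `length` (>= 1).
#' @param epsilon The tolerance used to build the network.
#' @return List with class `"haplotype_network"`.
#' @export
haplotype_network <- function(nodes, edges, epsilon = 0) {
  stopifnot(all(c("id", "motif", "sampled", "multiplicity") %in% names(nodes)),
            all(c("from", "to", "length") %in% names(edges)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (nrow(edges) && any(edges$length < 1)) stop("edge length must be >= 1")
  bad <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(bad)) stop("edge endpoint not a node: ", paste(bad, collapse = ", "))
  if (nrow(nodes) > 1L) {
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = nodes$id)
    if (igraph::components(g)$no != 1L) stop("network is not connected")
  }
  structure(list(nodes = nodes, edges = edges, epsilon = epsilon),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype network: %d nodes (%d sampled), %d edges, total length %d, epsilon %g>\n",
              nrow(x$nodes), sum(x$nodes$sampled), nrow(x$edges),
              sum(x$edges$length), x$epsilon))
  invisible(x)
}

# --- internal state-matrix machinery -------------------------------------

# Encode motifs as a character matrix over the union of their variant
# sites ("." = reference state).  Rows carry the canonical motif string
# as rownames-by-index bookkeeping (kept separately).
encode_states <- function(motifs) {
  maps <- lapply(motifs, motif_states)
  sites <- sort(unique(unlist(lapply(maps, names))))
  mat <- matrix(".", length(motifs), length(sites),
                dimnames = list(NULL, sites))
  for (i in seq_along(maps)) {
    mm <- maps[[i]]
    if (length(mm)) mat[i, names(mm)] <- mm
  }
  mat
}

# Motif string from one row of a state matrix.
states_to_motif_string <- function(states, sites) {
  on <- states != "."
  if (!any(on)) return("")
  tok <- character(sum(on))
  j <- 0L
  for (i in which(on)) {
    j <- j + 1L
    site <- sites[i]
    tok[j] <- if (grepl("\\.", site)) {
      paste0(sub("\\.", ".", site), states[i])      # insertion pos.idx + base
    } else if (states[i] == "-") {
      paste0(site, "d")
    } else {
      paste0(site, states[i])
    }
  }
  format(motif(tok))
}

# total length of a minimum spanning tree of a distance matrix (Prim)
mst_total <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  used <- logical(n); used[1] <- TRUE
  key <- d[, 1]
  tot <- 0
  for (k in 2:n) {
    cand <- which(!used)
    v <- cand[which.min(key[cand])]
    tot <- tot + key[v]
    used[v] <- TRUE
    key <- pmin(key, d[, v])
  }
  tot
}

hamming_rows <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0L, n, n)
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    di <- colSums(t(mat[(i + 1):n, , drop = FALSE]) != mat[i, ])
    d[i, (i + 1):n] <- di
    d[(i + 1):n, i] <- di
  }
  d
}

# epsilon-relaxed minimum spanning network over a distance matrix:
# rounds of the smallest inter-component distance w, admitting all
# inter-component links of cost <= w + epsilon as of the round start.
# For epsilon = 0 this is the union of all minimum spanning trees.
msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  from <- integer(); to <- integer()
  if (n < 2) return(cbind(from, to))
  comp <- seq_len(n)
  while (length(unique(comp)) > 1L) {
    inter <- outer(comp, comp, "!=") & upper.tri(d)
    w <- min(d[inter])
    sel <- which(inter & d <= w + epsilon, arr.ind = TRUE)
    from <- c(from, sel[, 1]); to <- c(to, sel[, 2])
    for (k in seq_len(nrow(sel))) {
      a <- comp[sel[k, 1]]; b <- comp[sel[k, 2]]
      if (a != b) comp[comp == b] <- a
    }
  }
  cbind(from, to)
}

# all distinct majority medians of row triplets of a state matrix; a
# three-way tie takes the state of the first row of the (row-sorted)
# triplet, so the result is order-independent after sorting
triple_medians <- function(M) {
  n <- nrow(M)
  out <- list()
  if (n >= 3) for (u in 1:(n - 2)) for (v in (u + 1):(n - 1))
    for (w in (v + 1):n) {
      a <- M[u, ]; b <- M[v, ]; c3 <- M[w, ]
      med <- ifelse(a == b | a == c3, a, ifelse(b == c3, b, a))
      key <- paste(med, collapse = "\r")
      if (is.null(out[[key]])) out[[key]] <- med
    }
  out
}

# union-find connectivity for an edge list over n nodes
edges_connect_all <- function(e, n) {
  comp <- seq_len(n)
  for (k in seq_len(nrow(e))) {
    a <- comp[e[k, 1]]; b <- comp[e[k, 2]]
    if (a != b) comp[comp == b] <- a
  }
  length(unique(comp)) == 1L
}

# Can sampled nodes 1..nt plus the candidate medians at sub_idx realize a
# spanning tree of total length L in which every median has degree >= 3?
# Enumerates (n-1)-edge subsets of the union-of-MSTs edge pool; above the
# enumeration cap it falls back to the necessary condition that every
# median has degree >= 3 in the pool itself.
mj_valid_config <- function(D, nt, sub_idx, L) {
  if (length(sub_idx) == 0L) return(TRUE)
  idx <- c(seq_len(nt), sub_idx)
  dsub <- D[idx, idx, drop = FALSE]
  n <- length(idx)
  pool <- msn_edges(dsub, 0)
  if (nrow(pool) < n - 1L) return(FALSE)
  xpos <- (nt + 1L):n
  deg_pool <- tabulate(c(pool[, 1], pool[, 2]), nbins = n)
  if (any(deg_pool[xpos] < 3L)) return(FALSE)
  if (choose(nrow(pool), n - 1L) > 20000) return(TRUE)
  w <- dsub[pool]
  for (comb in utils::combn(nrow(pool), n - 1L, simplify = FALSE)) {
    if (sum(w[comb]) != L) next
    e <- pool[comb, , drop = FALSE]
    if (!edges_connect_all(e, n)) next
    deg <- tabulate(c(e[, 1], e[, 2]), nbins = n)
    if (all(deg[xpos] >= 3L)) return(TRUE)
  }
  FALSE
}

# Exact small-sample construction: full median closure, then exhaustive
# search over candidate-median subsets for every minimum-length spanning
# configuration; returns the union of optimal configurations, or NULL
# when a budget is exceeded (caller falls back to mj_greedy).
mj_exact <- function(samp_mat, ns, epsilon, max_nodes,
                     closure_cap = 96L, subset_budget = 60000) {
  M <- samp_mat[order(apply(samp_mat, 1, paste, collapse = "\r")), ,
                drop = FALSE]
  keys <- apply(M, 1, paste, collapse = "\r")
  repeat {
    med <- triple_medians(M)
    new <- setdiff(names(med), keys)
    if (length(new) == 0L) break
    if (nrow(M) + length(new) > closure_cap) return(NULL)
    M <- rbind(M, do.call(rbind, med[new]))
    keys <- c(keys, new)
    ord <- order(keys)
    M <- M[ord, , drop = FALSE]; keys <- keys[ord]
  }
  samp_keys <- apply(samp_mat, 1, paste, collapse = "\r")
  cand <- M[!(keys %in% samp_keys), , drop = FALSE]
  nc <- nrow(cand)
  kmax <- min(nc, max(0L, ns - 2L))
  if (sum(choose(nc, 0:kmax)) > subset_budget) return(NULL)
  all_mat <- rbind(samp_mat, cand)
  D <- hamming_rows(all_mat)
  best <- Inf; opt <- list()
  for (k in 0:kmax) {
    subs <- if (k == 0L) list(integer()) else
      utils::combn(nc, k, simplify = FALSE)
    for (s in subs) {
      L <- mst_total(D[c(seq_len(ns), ns + s), c(seq_len(ns), ns + s),
                       drop = FALSE])
      if (L < best - epsilon) { best <- L; opt <- list(s) }
      else if (L <= best + epsilon) opt <- c(opt, list(s))
    }
  }
  opt <- Filter(function(s) mj_valid_config(D, ns, ns + s, best), opt)
  sel <- sort(unique(unlist(opt)))
  list(extra = cand[sel, , drop = FALSE])
}

# Greedy round-based approximation for larger sets: medians from all
# triplets of the current node set, admitted when they strictly shorten
# its minimum spanning length, or tie it while attaining degree >= 3 in
# the augmented spanning network.
mj_greedy <- function(samp_mat, epsilon, max_nodes) {
  mat <- samp_mat
  sampled <- rep(TRUE, nrow(mat))
  repeat {
    ord <- order(apply(mat, 1, paste, collapse = "\r"))
    mat <- mat[ord, , drop = FALSE]; sampled <- sampled[ord]
    d <- hamming_rows(mat)
    n <- nrow(mat)
    cand <- triple_medians(mat)
    existing <- apply(mat, 1, paste, collapse = "\r")
    cand <- cand[setdiff(names(cand), existing)]
    if (length(cand) == 0L) break
    L_cur <- mst_total(d)
    Lx <- vapply(cand, function(x) {
      dx <- colSums(t(mat) != x)
      mst_total(rbind(cbind(d, dx), c(dx, 0L)))
    }, 0)
    Lmin <- min(Lx)
    if (Lmin > L_cur + epsilon) break
    add <- if (Lmin < L_cur) {
      names(cand)[Lx <= Lmin + epsilon]
    } else {
      Filter(function(k) {
        x <- cand[[k]]
        dx <- colSums(t(mat) != x)
        daug <- rbind(cbind(d, dx), c(dx, 0L))
        ea <- msn_edges(daug, epsilon)
        sum(ea == n + 1L) >= 3L
      }, names(cand)[Lx <= Lmin + epsilon])
    }
    if (length(add) == 0L) break
    if (nrow(mat) + length(add) > max_nodes) {
      warning("median-joining network truncated at max_nodes = ", max_nodes)
      break
    }
    mat <- rbind(mat, do.call(rbind, cand[add]))
    sampled <- c(sampled, rep(FALSE, length(add)))
  }
  list(extra = mat[!sampled, , drop = FALSE])
}

#' Build a median-joining haplotype network
#'
#' @param motifs List of motifs (or token strings) of the sampled
#'   haplotypes.  Duplicates are merged with their multiplicities summed.
#' @param multiplicity Integer vector of counts per haplotype (default
#'   all 1).
#' @param epsilon Relaxation parameter of the algorithm; 0 (default)
#'   yields the sparsest network.
#' @param max_nodes Safety cap on network size.
#' @return A [haplotype_network()].  Median (inferred, unsampled) nodes
#'   have `sampled = FALSE` and multiplicity 0.
#' @export
#' @examples
#' net <- median_joining(list("16126C", "16126C 16189C", ""))
#' net$edges
median_joining <- function(motifs, multiplicity = NULL, epsilon = 0,
                           max_nodes = 500L) {
  if (length(motifs) < 1L) stop("need at least one haplotype")
  motifs <- lapply(motifs, motif)
  if (is.null(multiplicity)) multiplicity <- rep(1L, length(motifs))
  stopifnot(length(multiplicity) == length(motifs), all(multiplicity >= 1))
  keys <- vapply(motifs, format, "")
  ukeys <- unique(keys)
  # positional aggregation: "" (the reference motif) is a valid key
  mult <- as.integer(tapply(as.integer(multiplicity),
                            factor(keys, levels = ukeys), sum))
  motifs <- motifs[match(ukeys, keys)]
  mat <- encode_states(motifs)
  sites <- colnames(mat)
  ids <- ukeys
  sampled <- rep(TRUE, length(ids))
  if (ncol(mat) == 0L || length(ids) == 1L) {
    nodes <- data.frame(id = ifelse(nzchar(ids), ids, "."), motif = ids,
                        sampled = sampled, multiplicity = mult,
                        stringsAsFactors = FALSE)
    return(haplotype_network(nodes[1, , drop = FALSE],
                             data.frame(from = character(), to = character(),
                                        length = integer()),
                             epsilon = epsilon))
  }
  ns <- length(ids)
  # Two construction modes.  For small haplotype sets the median network
  # is computed exactly: build the full median closure, search subsets of
  # candidate medians for every minimum-length spanning configuration,
  # and keep the union of the optimal ones.  When the closure or the
  # subset enumeration would exceed its budget the construction falls
  # back to a greedy round-based approximation (medians admitted when
  # they shorten -- or tie with degree >= 3 -- the spanning length of the
  # current node set).
  grown <- NULL
  if (ns <= 8L) grown <- mj_exact(mat, ns, epsilon, max_nodes)
  if (is.null(grown)) grown <- mj_greedy(mat, epsilon, max_nodes)
  extra <- grown$extra
  if (nrow(extra)) {
    mat <- rbind(mat, extra)
    ids <- c(ids, vapply(seq_len(nrow(extra)), function(i)
      states_to_motif_string(extra[i, ], sites), ""))
    sampled <- c(sampled, rep(FALSE, nrow(extra)))
    mult <- c(mult, rep(0L, nrow(extra)))
  }
  ord <- order(!sampled, ids)
  mat <- mat[ord, , drop = FALSE]
  ids <- ids[ord]; sampled <- sampled[ord]; mult <- mult[ord]
  # prune unsampled medians of degree <= 2; recompute the spanning
  # network after each sweep until stable
  repeat {
    d <- hamming_rows(mat)
    e <- msn_edges(d, epsilon)
    deg <- tabulate(c(e[, 1], e[, 2]), nbins = length(ids))
    drop <- !sampled & deg <= 2L
    if (!any(drop)) break
    mat <- mat[!drop, , drop = FALSE]
    ids <- ids[!drop]; sampled <- sampled[!drop]; mult <- mult[!drop]
  }
  node_id <- ifelse(nzchar(ids), ids, ".")
  nodes <- data.frame(id = node_id, motif = ids, sampled = sampled,
                      multiplicity = mult, stringsAsFactors = FALSE)
  edges <- data.frame(from = node_id[e[, 1]], to = node_id[e[, 2]],
                      length = d[e], stringsAsFactors = FALSE)
  haplotype_network(nodes, edges, epsilon = epsilon)
}

#' Extract a rooted genealogy from a haplotype network
#'
#' Shortest-path (Dijkstra) tree from the designated ancestral haplotype;
#' where a node is reachable at equal cost through several parents, the
#' lexicographically smaller parent motif wins, so reticulations resolve
#' deterministically.
#'
#' @param net A [haplotype_network()].
#' @param root Ancestral motif.  If it is not a node of the network and
#'   `add_root = TRUE`, it is inserted as an unsampled node linked to its
#'   nearest node(s) (it must lie within one mutation of the network).
#' @param add_root Allow inserting an absent root, default `TRUE`.
#' @return List with class `"rooted_tree"`: data frame `nodes` with
#'   `id`, `motif`, `parent` (`NA` for the root), `link_length`,
#'   `sampled`, `multiplicity`, `depth` (mutations from root).
#' @export
extract_rooted_tree <- function(net, root, add_root = TRUE) {
  stopifnot(inherits(net, "haplotype_network"))
  root_str <- format(motif(root))
  nodes <- net$nodes
  edges <- net$edges
  if (!root_str %in% nodes$motif) {
    if (!add_root) stop("root motif is not a node of the network")
    dists <- vapply(nodes$motif, function(s)
      hamming_motif_distance(motif(s), motif(root_str)), 0L)
    if (min(dists) > 1L)
      stop("root not placeable: nearest network haplotype is ", min(dists),
           " mutations away")
    rid <- ifelse(nzchar(root_str), root_str, ".")
    nodes <- rbind(nodes, data.frame(id = rid, motif = root_str,
                                     sampled = FALSE, multiplicity = 0L,
                                     stringsAsFactors = FALSE))
    near <- which(dists == min(dists))
    edges <- rbind(edges, data.frame(from = rid, to = nodes$id[near],
                                     length = as.integer(min(dists)),
                                     stringsAsFactors = FALSE))
  }
  rid <- nodes$id[nodes$motif == root_str]
  n <- nrow(nodes)
  idx <- stats::setNames(seq_len(n), nodes$id)
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- idx[[edges$from[k]]]; j <- idx[[edges$to[k]]]
    adj[[i]] <- rbind(adj[[i]], c(j, edges$length[k]))
    adj[[j]] <- rbind(adj[[j]], c(i, edges$length[k]))
  }
  dist <- rep(Inf, n); parent <- rep(NA_integer_, n); plen <- rep(NA_integer_, n)
  dist[idx[[rid]]] <- 0
  done <- rep(FALSE, n)
  for (step in seq_len(n)) {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    # deterministic: smallest distance, then lexicographically smallest motif
    u <- cand[order(dist[cand], nodes$motif[cand])][1]
    done[u] <- TRUE
    if (!is.null(adj[[u]])) for (k in seq_len(nrow(adj[[u]]))) {
      v <- adj[[u]][k, 1]; w <- adj[[u]][k, 2]
      nd <- dist[u] + w
      better <- nd < dist[v] ||
        (nd == dist[v] && !is.na(parent[v]) &&
           nodes$motif[u] < nodes$motif[parent[v]])
      if (!done[v] && better) {
        dist[v] <- nd; parent[v] <- u; plen[v] <- w
      }
    }
  }
  if (any(!done[nodes$sampled]))
    stop("network is not connected from the root")
  out <- data.frame(id = nodes$id, motif = nodes$motif,
                    parent = ifelse(is.na(parent), NA_character_,
                                    nodes$id[parent]),
                    link_length = plen,
                    sampled = nodes$sampled,
                    multiplicity = nodes$multiplicity,
                    depth = as.integer(dist),
                    stringsAsFactors = FALSE)
  structure(list(nodes = out, root = rid), class = "rooted_tree")
}

#' Build a star genealogy directly from haplotypes
#'
#' Each distinct haplotype is attached to the root by a single link of
#' length equal to its mutational distance from the root -- the genealogy
#' implied when every lineage descends independently from the ancestor.
#' Used for dating simulated star clades without network inference.
#'
#' @param motifs List of motifs.
#' @param multiplicity Counts per motif (default 1).
#' @param root Ancestral motif (default the empty motif).
#' @return A `"rooted_tree"` as in [extract_rooted_tree()].
#' @export
star_tree <- function(motifs, multiplicity = NULL, root = motif()) {
  motifs <- lapply(motifs, motif)
  if (is.null(multiplicity)) multiplicity <- rep(1L, length(motifs))
  root_str <- format(motif(root))
  keys <- vapply(motifs, format, "")
  ukeys <- unique(keys)
  mult <- as.integer(tapply(as.integer(multiplicity),
                            factor(keys, levels = ukeys), sum))
  ids <- ifelse(nzchar(ukeys), ukeys, ".")
  rid <- ifelse(nzchar(root_str), root_str, ".")
  dists <- vapply(ukeys, function(s)
    hamming_motif_distance(motif(s), motif(root_str)), 0L, USE.NAMES = FALSE)
  nodes <- data.frame(id = ids, motif = ukeys,
                      parent = ifelse(ukeys == root_str, NA_character_, rid),
                      link_length = ifelse(ukeys == root_str, NA_integer_,
                                           dists),
                      sampled = TRUE,
                      multiplicity = mult,
                      depth = as.integer(dists),
                      stringsAsFactors = FALSE)
  if (!root_str %in% ukeys)
    nodes <- rbind(data.frame(id = rid, motif = root_str,
                              parent = NA_character_,
                              link_length = NA_integer_, sampled = FALSE,
                              multiplicity = 0L, depth = 0L,
                              stringsAsFactors = FALSE),
                   nodes)
  structure(list(nodes = nodes, root = rid), class = "rooted_tree")
}

#' Rho statistic and Saillard standard error on a rooted genealogy
#'
#' `rho` is the average mutational distance from the root over sampled
#' sequences (weighted by multiplicity).  Its standard error follows
#' Saillard's formula: `sigma^2 = (1/n^2) * sum over links of
#' l_link * n_link^2`, where `l_link` is the number of mutations on the
#' link and `n_link` the number of sampled sequences below it.  Ages are
#' `rho` and `sigma` times the clock's years-per-substitution.
#'
#' @param tree A `"rooted_tree"`.
#' @param rate A [rate_config()].
#' @return List with class `"rho_result"`: `rho`, `sigma`, `n`,
#'   `age_years`, `age_SE_years`, `low_information` (fewer than 2
#'   distinct sampled haplotypes).
#' @export
rho_statistic <- function(tree, rate = rate_config()) {
  stopifnot(inherits(tree, "rooted_tree"))
  nd <- tree$nodes
  n <- sum(nd$multiplicity[nd$sampled])
  if (n < 1) stop("no sampled sequences below the root")
  rho <- sum(nd$multiplicity[nd$sampled] * nd$depth[nd$sampled]) / n
  # sampled descendants below each link (link = node -> its parent)
  idx <- stats::setNames(seq_len(nrow(nd)), nd$id)
  below <- ifelse(nd$sampled, nd$multiplicity, 0L)
  ord <- order(nd$depth, decreasing = TRUE)   # children before parents
  for (i in ord) {
    p <- nd$parent[i]
    if (!is.na(p)) below[idx[[p]]] <- below[idx[[p]]] + below[i]
  }
  has_link <- !is.na(nd$parent)
  sigma2 <- sum(nd$link_length[has_link] * below[has_link]^2) / n^2
  ys <- rate$years_per_substitution
  distinct <- length(unique(nd$motif[nd$sampled & nd$multiplicity > 0]))
  structure(list(rho = rho, sigma = sqrt(sigma2), n = n,
                 age_years = rho * ys, age_SE_years = sqrt(sigma2) * ys,
                 low_information = distinct < 2L),
            class = "rho_result")
}

#' @export
print.rho_result <- function(x, ...) {
  cat(sprintf("<rho %.3f +/- %.3f (n = %d): age %.0f +/- %.0f years%s>\n",
              x$rho, x$sigma, x$n, x$age_years, x$age_SE_years,
              if (x$low_information) ", low information" else ""))
  invisible(x)
}

#' Date a haplogroup clade from sampled motifs
#'
#' Applies the dating-scope relatedness rule (one ancient sample per
#' site), filters hypermutable sites, builds the median-joining network
#' over the clade's motifs plus the clade's ancestral motif, roots the
#' network there, and returns the rho-statistic age.
#'
#' @param samples Sample data frame with `haplogroup`, `site`, `period`,
#'   `motif` columns.
#' @param haplogroup Clade label; members are samples assigned to this
#'   label or to any descendant in `tree` (nomenclature-prefix matches
#'   are also accepted).
#' @param tree A [phylo_tree()] providing the clade's ancestral motif.
#' @param rate A [rate_config()].
#' @param segment Optional [ref_segment()]; when given, the ancestral
#'   motif is restricted to it.
#' @param epsilon Median-joining tolerance.
#' @param exclusions Hypermutable-site rules, see [default_exclusions()].
#' @return A `"rho_result"` (with the network and rooted tree attached as
#'   attributes `network` and `tree`).
#' @export
date_clade <- function(samples, haplogroup, tree, rate = rate_config(),
                       segment = NULL, epsilon = 0,
                       exclusions = default_exclusions()) {
  in_tree <- names(tree$nodes)
  desc <- in_tree[vapply(in_tree, function(l) {
    cur <- l
    repeat {
      if (cur == haplogroup) return(TRUE)
      p <- tree$nodes[[cur]]$parent
      if (is.null(p) || is.na(p)) return(FALSE)
      cur <- p
    }
  }, TRUE)]
  member <- samples$haplogroup %in% desc |
    startsWith(samples$haplogroup, haplogroup)
  clade <- samples[member, , drop = FALSE]
  if (nrow(clade) == 0L) stop("no samples in clade ", sQuote(haplogroup))
  clade <- dedup_by_site(clade, scope = "dating")
  root_m <- cumulative_motif(tree, haplogroup)
  if (!is.null(segment)) {
    df <- motif_df(root_m)
    root_m <- motif(df$token[df$position >= segment$start &
                             df$position <= segment$end])
  }
  root_m <- filter_motif(root_m, exclusions)$kept
  motifs <- lapply(clade$motif, function(s)
    filter_motif(motif(s), exclusions)$kept)
  mult <- clade$multiplicity
  root_str <- format(root_m)
  keys <- vapply(motifs, format, "")
  all_m <- motifs; all_mult <- as.integer(mult)
  if (!root_str %in% keys) {
    # carry the ancestor into the network as an unsampled anchor: give it
    # multiplicity via a sampled=FALSE fixup below
    all_m <- c(all_m, list(root_m)); all_mult <- c(all_mult, 1L)
  }
  net <- median_joining(all_m, all_mult, epsilon = epsilon)
  if (!root_str %in% keys) {
    ridx <- net$nodes$motif == root_str
    net$nodes$sampled[ridx] <- FALSE
    net$nodes$multiplicity[ridx] <- 0L
  }
  rt <- extract_rooted_tree(net, root_m, add_root = TRUE)
  res <- rho_statistic(rt, rate)
  attr(res, "network") <- net
  attr(res, "tree") <- rt
  res
}
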