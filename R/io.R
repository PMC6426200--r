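# Readers and writers: FASTA, sample tables, frequency tables, the
# reduced phylotree (JSON), haplotype networks (JSON/GML) and run
# manifests.  TSV throughout for tables, with a header row.

#' Read a FASTA file
#'
#' Record ids are the first whitespace-delimited token of the header line;
#' sequences are uppercased and U is mapped to T.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (names = ids), in file
#'   order.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot read FASTA ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- gsub("U", "T", toupper(as.character(set)), fixed = TRUE)
  bad <- !grepl("^[ACGTRYSWKMBDHVN-]*$", seqs)
  if (any(bad))
    stop("non-IUPAC characters in record ", paste(ids[bad], collapse = ", "))
  stats::setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  invisible(path)
}

# Canonical island codes (Table-1-style two/three-letter codes).
ISLAND_CODES <- c("HIE", "PAL", "GOM", "TFE", "GCA", "LAN", "FUE",
                  "LAN&FUE", "other")

#' Read a sample table
#'
#' Tab-separated with a header.  Required columns: `sample_id`, `island`,
#' `period` (`ancient`/`modern`).  Optional: `site`, `haplogroup`,
#' `motif` (space-separated variant tokens), `multiplicity`.
#'
#' @param path TSV file.
#' @param ref_length Position bound for motif tokens.
#' @return A `data.frame` with columns `sample_id`, `island`, `site`,
#'   `period`, `haplogroup`, `motif` (canonical token string),
#'   `multiplicity`.  Unknown island codes are kept but flagged with a
#'   warning.
#' @export
read_sample_table <- function(path, ref_length = 16569L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = NULL,
                          colClasses = "character")
  req <- c("sample_id", "island", "period")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (opt in c("site", "haplogroup", "motif"))
    if (is.null(df[[opt]])) df[[opt]] <- ""
  if (is.null(df[["multiplicity"]])) df[["multiplicity"]] <- 1L
  df$multiplicity <- as.integer(df$multiplicity)
  if (any(is.na(df$multiplicity) | df$multiplicity < 1L))
    stop("multiplicity must be a positive integer")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!all(df$period %in% c("ancient", "modern")))
    stop("period must be 'ancient' or 'modern'")
  unknown <- setdiff(unique(df$island), ISLAND_CODES)
  if (length(unknown))
    warning("unknown island code(s): ", paste(unknown, collapse = ", "))
  df$motif <- vapply(seq_len(nrow(df)), function(i) {
    tryCatch(format(motif(df$motif[i], ref_length = ref_length)),
             error = function(e) stop("row ", i, ": ",
                                      conditionMessage(e), call. = FALSE))
  }, "")
  df[c("sample_id", "island", "site", "period", "haplogroup", "motif",
       "multiplicity")]
}

#' Write a sample table
#' @param samples Data frame as from [read_sample_table()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a haplogroup frequency table
#'
#' TSV with categories in the first column and one column of non-negative
#' integer counts per population.
#'
#' @param path TSV file.
#' @return A `freq_table`: integer matrix, categories in rows, populations
#'   in columns.
#' @export
read_freq_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  freq_table(m)
}

#' Construct a frequency table
#'
#' @param counts Numeric matrix of non-negative integers; rows are
#'   haplogroup/haplotype categories, columns are populations.
#' @return The matrix with class `"freq_table"`.
#' @export
freq_table <- function(counts) {
  m <- as.matrix(counts)
  if ((nrow(m) > 0L && is.null(rownames(m))) ||
      (ncol(m) > 0L && is.null(colnames(m))))
    stop("freq_table needs row (category) and column (population) names")
  if (is.null(rownames(m))) rownames(m) <- character(0)
  if (is.null(colnames(m))) colnames(m) <- character(0)
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(m < 0L))
    stop("counts must be non-negative integers")
  class(m) <- c("freq_table", class(m))
  m
}

#' Per-population sample sizes of a frequency table
#' @param freqs A `freq_table`.
#' @return Named integer vector of column totals.
#' @export
population_sizes <- function(freqs) colSums(unclass(freqs))

#' Write a frequency table
#' @param freqs A `freq_table`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(freqs, path) {
  df <- data.frame(haplogroup = rownames(freqs), unclass(freqs),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a reduced phylotree
#'
#' A rooted tree of haplogroup labels, each non-root node carrying the
#' variants that define it relative to its parent.  Back mutations
#' (`"@p"`) in a node's defining variants remove the inherited
#' substitution at `p` when cumulative motifs are computed.
#'
#' @param nodes Named list: `label -> list(parent = <label or NA>,
#'   variants = <character>)`.  Exactly one node (the root) has parent
#'   `NA`; the root carries no variants.
#' @return List with class `"phylo_tree"`: `root`, `nodes`.
#' @export
phylo_tree <- function(nodes) {
  parents <- vapply(nodes, function(n) {
    p <- n$parent
    if (is.null(p) || length(p) == 0L || is.na(p)) NA_character_ else p
  }, "")
  root <- names(nodes)[is.na(parents)]
  if (length(root) != 1L)
    stop("phylotree must have exactly one root (parent = NA)")
  if (length(nodes[[root]]$variants))
    stop("root node must carry no defining variants")
  bad <- setdiff(stats::na.omit(parents), names(nodes))
  if (length(bad)) stop("unknown parent label(s): ", paste(bad, collapse = ", "))
  # reachability & acyclicity
  for (lab in names(nodes)) {
    seen <- character()
    cur <- lab
    while (!is.na(parents[[cur]])) {
      if (cur %in% seen) stop("cycle in phylotree at ", lab)
      seen <- c(seen, cur)
      cur <- parents[[cur]]
    }
    if (cur != root) stop("node ", lab, " not reachable from root")
  }
  tree <- structure(list(root = root, nodes = nodes), class = "phylo_tree")
  # the tree is static: precompute every node's cumulative motif once
  tree$cumulative <- stats::setNames(
    lapply(names(nodes), function(lab) compute_cumulative(tree, lab)),
    names(nodes))
  tree
}

#' Read a reduced phylotree from JSON
#'
#' Expected layout: `{"nodes": {"H": {"parent": "root-label",
#' "variants": ["2706G", ...]}, ...}}`, the root having `"parent": null`.
#'
#' @param path JSON file.
#' @return A [phylo_tree()].
#' @export
read_phylotree <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$nodes)) stop("phylotree JSON must have a 'nodes' object")
  nodes <- lapply(j$nodes, function(n)
    list(parent = if (is.null(n$parent)) NA_character_ else n$parent,
         variants = as.character(unlist(n$variants))))
  phylo_tree(nodes)
}

#' Cumulative motif of a phylotree node
#'
#' Composes the defining variants along the root path, applying back
#' mutations, via [compose_variants()].
#'
#' @param tree A [phylo_tree()].
#' @param label Node label.
#' @return A [motif()].
#' @export
cumulative_motif <- function(tree, label) {
  if (!label %in% names(tree$nodes)) stop("unknown haplogroup ", sQuote(label))
  cached <- tree$cumulative[[label]]
  if (!is.null(cached)) return(cached)
  compute_cumulative(tree, label)
}

compute_cumulative <- function(tree, label) {
  path <- label
  cur <- label
  repeat {
    p <- tree$nodes[[cur]]$parent
    if (is.null(p) || is.na(p)) break
    path <- c(p, path)
    cur <- p
  }
  m <- motif()
  for (lab in path)
    m <- compose_variants(m, motif(as.character(tree$nodes[[lab]]$variants)))
  m
}

# Depth of a node (edges from root) -- used for assignment tie-breaks.
node_depth <- function(tree, label) {
  d <- 0L
  cur <- label
  repeat {
    p <- tree$nodes[[cur]]$parent
    if (is.null(p) || is.na(p)) break
    d <- d + 1L
    cur <- p
  }
  d
}

#' Write a haplotype network
#'
#' @param net A `haplotype_network` (see [median_joining()]).
#' @param path Output file.
#' @param format `"json"` or `"gml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("json", "gml")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(epsilon = net$epsilon,
           nodes = net$nodes,
           edges = net$edges),
      path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  } else {
    g <- network_to_igraph(net)
    igraph::write_graph(g, path, format = "gml")
  }
  invisible(path)
}

#' Read a haplotype network
#'
#' Inverse of [write_network()].
#'
#' @param path Input file.
#' @param format `"json"` or `"gml"`.
#' @return A `haplotype_network`.
#' @export
read_network <- function(path, format = c("json", "gml")) {
  format <- match.arg(format)
  if (format == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- as.data.frame(j$nodes, stringsAsFactors = FALSE)
    if (is.null(nodes$motif)) nodes$motif <- character(0)
    nodes$motif <- as.character(nodes$motif)
    nodes$motif[is.na(nodes$motif)] <- ""
    edges <- as.data.frame(j$edges, stringsAsFactors = FALSE)
    if (nrow(edges) == 0L)
      edges <- data.frame(from = character(), to = character(),
                          length = integer(), stringsAsFactors = FALSE)
    haplotype_network(nodes, edges, epsilon = j$epsilon)
  } else {
    g <- igraph::read_graph(path, format = "gml")
    igraph_to_network(g)
  }
}

# igraph conversion helpers (internal)
network_to_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    d = net$edges[, c("from", "to", "length"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = net$nodes$id,
                          motif = net$nodes$motif,
                          sampled = as.integer(net$nodes$sampled),
                          multiplicity = net$nodes$multiplicity,
                          stringsAsFactors = FALSE))
  igraph::graph_attr(g, "epsilon") <- net$epsilon
  g
}

igraph_to_network <- function(g) {
  v <- igraph::as_data_frame(g, what = "vertices")
  e <- igraph::as_data_frame(g, what = "edges")
  nodes <- data.frame(id = as.character(v$name),
                      motif = as.character(v$motif),
                      sampled = as.logical(as.integer(v$sampled)),
                      multiplicity = as.integer(v$multiplicity),
                      stringsAsFactors = FALSE)
  nodes$motif[is.na(nodes$motif)] <- ""
  eps <- igraph::graph_attr(g, "epsilon")
  if (is.null(eps)) eps <- 0
  edges <- data.frame(from = as.character(e$from), to = as.character(e$to),
                      length = as.integer(round(as.numeric(e$length))),
                      stringsAsFactors = FALSE)
  haplotype_network(nodes, edges, epsilon = eps)
}

#' Write a run manifest
#'
#' Records the parameters, seed and output files of a pipeline run as
#' JSON, for reproducibility.
#'
#' @param path Output file.
#' @param params Named list of parameters.
#' @param outputs Character vector of files produced.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params, outputs = character()) {
  jsonlite::write_json(
    list(package = "mitopop",
         version = as.character(utils::packageVersion("mitopop")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         params = params,
         outputs = outputs),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
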