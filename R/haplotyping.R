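# Sequence -> motif -> haplogroup.
#
# Sequences are near-identical to the reference segment, so a fixed-score
# global alignment with free end gaps is sufficient; scores are fixed for
# determinism (match +1, mismatch -1, gap open -2, gap extend -1).

# fixed scoring matrix, built once per session
.align_cache <- new.env(parent = emptyenv())
substitution_matrix <- function() {
  if (is.null(.align_cache$mat))
    .align_cache$mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE)
  .align_cache$mat
}

#' Align a sequence to a reference segment
#'
#' Global alignment with free end gaps, automatically trying both
#' orientations and keeping the one with the higher identity.  Alignments
#' with identity below `min_identity` are rejected as non-homologous.
#'
#' @param seq Nucleotide string (length within 0.5x--2x of the segment).
#' @param ref A [ref_segment()].
#' @param min_identity Reject threshold, default 0.8.
#' @return List with class `"mt_alignment"`: aligned `query` and
#'   `reference` strings (with `-` gaps), `ref_start` (reference
#'   coordinate of the first aligned reference base), `identity`,
#'   `reverse_complemented`.
#' @export
align_to_reference <- function(seq, ref, min_identity = 0.8) {
  stopifnot(inherits(ref, "ref_segment"))
  seq <- toupper(gsub("U", "T", as.character(seq)[1]))
  rlen <- nchar(ref$sequence)
  if (nchar(seq) < 0.5 * rlen || nchar(seq) > 2 * rlen)
    stop("sequence length ", nchar(seq), " outside [0.5x, 2x] of the ",
         rlen, " bp reference segment")
  mat <- substitution_matrix()
  do_align <- function(s) {
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(s),
      subject = Biostrings::DNAString(ref$sequence),
      type = "overlap", substitutionMatrix = mat,
      gapOpening = 2, gapExtension = 1)
  }
  # matches over the shorter of the two sequences: with free end gaps a
  # short high-identity overlap must not make junk look homologous
  identity_of <- function(aln) {
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    if (length(s) == 0L) return(0)
    sum(p == s & p != "-") / min(nchar(seq), rlen)
  }
  fwd <- do_align(seq)
  rev <- do_align(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq))))
  id_f <- identity_of(fwd); id_r <- identity_of(rev)
  revcomp <- id_r > id_f
  aln <- if (revcomp) rev else fwd
  ident <- max(id_f, id_r)
  if (ident < min_identity)
    stop(sprintf("alignment identity %.2f below %.2f: non-homologous sequence",
                 ident, min_identity))
  structure(list(
    query = as.character(Biostrings::alignedPattern(aln)),
    reference = as.character(Biostrings::alignedSubject(aln)),
    ref_start = ref$start + Biostrings::start(Biostrings::subject(aln)) - 1L,
    identity = ident,
    reverse_complemented = revcomp), class = "mt_alignment")
}

#' Call variants from an alignment
#'
#' Walks the aligned columns and emits canonical variant tokens:
#' substitutions (`"16223T"`), insertions relative to the reference
#' (`"16188.1C"`, indexed when several bases are inserted at one
#' position), and deletions (`"16166d"`).  Calls matching the exclusion
#' rules (indels at 309/522/573/16193, substitutions at 16519 by default)
#' are reported separately, not silently dropped.  Ambiguity codes and N
#' in the query are not called.
#'
#' @param alignment An `"mt_alignment"` from [align_to_reference()].
#' @param exclusions Rules as from [default_exclusions()].
#' @return List: `motif` (kept calls), `excluded` (calls removed by rule).
#' @export
call_variants <- function(alignment, exclusions = default_exclusions()) {
  stopifnot(inherits(alignment, "mt_alignment"))
  q <- strsplit(alignment$query, "")[[1]]
  r <- strsplit(alignment$reference, "")[[1]]
  stopifnot(length(q) == length(r))
  pos <- alignment$ref_start - 1L
  tokens <- character()
  ins_index <- 0L
  for (i in seq_along(r)) {
    if (r[i] != "-") {
      pos <- pos + 1L
      ins_index <- 0L
      if (q[i] == "-") {
        tokens <- c(tokens, paste0(pos, "d"))
      } else if (q[i] != r[i] && q[i] %in% c("A", "C", "G", "T")) {
        tokens <- c(tokens, paste0(pos, q[i]))
      }
    } else if (q[i] %in% c("A", "C", "G", "T")) {
      ins_index <- ins_index + 1L
      tokens <- c(tokens, paste0(pos, ".", ins_index, q[i]))
    }
  }
  f <- filter_motif(motif(tokens), exclusions)
  list(motif = f$kept, excluded = f$excluded)
}

#' Realize a motif as a sequence
#'
#' Inverse of variant calling: applies the motif's substitutions,
#' deletions and insertions to the reference segment.  Composed with
#' [align_to_reference()] and [call_variants()], this round-trips exactly
#' for motifs that avoid the excluded sites.
#'
#' @param m Motif.
#' @param ref A [ref_segment()].
#' @return Nucleotide string.
#' @export
motif_to_sequence <- function(m, ref) {
  stopifnot(inherits(ref, "ref_segment"))
  df <- motif_df(motif(m))
  if (any(df$kind == "back-mutation"))
    stop("back mutations cannot be realized as sequence edits")
  if (nrow(df) && (any(df$position < ref$start) || any(df$position > ref$end)))
    stop("variant outside reference segment ",
         ref$start, "-", ref$end, ": ",
         paste(df$token[df$position < ref$start | df$position > ref$end],
               collapse = ", "))
  chars <- as.list(strsplit(ref$sequence, "")[[1]])
  idx <- function(p) p - ref$start + 1L
  for (i in seq_len(nrow(df))) {
    j <- idx(df$position[i])
    cur <- chars[[j]]
    base <- substr(cur, 1, 1)  # reference base slot, may carry insertions
    tail <- substring(cur, 2)
    if (df$kind[i] == "substitution") {
      chars[[j]] <- paste0(df$state[i], tail)
    } else if (df$kind[i] == "deletion") {
      chars[[j]] <- paste0("", tail)
    } else if (df$kind[i] == "insertion") {
      chars[[j]] <- paste0(base, tail, df$state[i])
    }
  }
  paste(unlist(chars), collapse = "")
}

#' Assign a haplogroup to a motif
#'
#' Scores every node of the reduced phylotree with the Kulczynski
#' measure: `score(h) = (|M & E_h|/|E_h| + |M & E_h|/|M|) / 2`, where
#' `E_h` is the node's cumulative defining motif restricted to the
#' analyzed segment and `M` the observed motif.  Sites are matched on
#' `(position, insert_index, state)`.  An empty `E_h` contributes a full
#' first term (vacuously all expected variants found); an empty `M` a
#' full second term, so the root scores 1 on an empty motif.  Ties break
#' toward the deeper node, then lexicographically.
#'
#' @param m Observed motif.
#' @param tree A [phylo_tree()].
#' @param segment Optional [ref_segment()]; when given, expected variants
#'   outside `[start, end]` are ignored (HVRI-only data cannot be scored
#'   on coding-region variants).
#' @return List with class `"hg_assignment"`: `haplogroup`, `score`,
#'   `expected_found`, `expected_total`, `private_variants` (observed but
#'   not expected), `alternatives` (data frame of all labels and scores,
#'   ranked).
#' @export
assign_haplogroup <- function(m, tree, segment = NULL) {
  stopifnot(inherits(tree, "phylo_tree"))
  m <- motif(m)
  if (length(tree$nodes) == 0L) stop("empty phylotree")
  obs <- motif_states(m)
  obs_keys <- paste(names(obs), obs)
  labels <- names(tree$nodes)
  restrict <- function(mm) {
    if (is.null(segment)) return(mm)
    df <- motif_df(mm)
    motif(df$token[df$position >= segment$start & df$position <= segment$end])
  }
  score_one <- function(lab) {
    e <- motif_states(restrict(cumulative_motif(tree, lab)))
    e_keys <- paste(names(e), e)
    found <- length(intersect(obs_keys, e_keys))
    t1 <- if (length(e_keys) == 0L) 1 else found / length(e_keys)
    t2 <- if (length(obs_keys) == 0L) 1 else found / length(obs_keys)
    c(score = (t1 + t2) / 2, found = found, total = length(e_keys))
  }
  sc <- t(vapply(labels, score_one, c(score = 0, found = 0, total = 0)))
  depth <- vapply(labels, function(l) node_depth(tree, l), 0L)
  ord <- order(-sc[, "score"], -depth, labels)
  best <- ord[1]
  e_best <- motif_states(restrict(cumulative_motif(tree, labels[best])))
  e_keys <- paste(names(e_best), e_best)
  private <- motif(unclass(m)[!(obs_keys %in% e_keys)])
  structure(list(
    haplogroup = labels[best],
    score = unname(sc[best, "score"]),
    expected_found = as.integer(sc[best, "found"]),
    expected_total = as.integer(sc[best, "total"]),
    private_variants = private,
    alternatives = data.frame(haplogroup = labels[ord],
                              score = unname(sc[ord, "score"]),
                              row.names = NULL)),
    class = "hg_assignment")
}

#' @export
print.hg_assignment <- function(x, ...) {
  cat(sprintf("<haplogroup %s, score %.4f (%d/%d expected variants)>\n",
              x$haplogroup, x$score, x$expected_found, x$expected_total))
  invisible(x)
}

#' Deduplicate potentially related samples
#'
#' Ancient samples from one archaeological site may be relatives, so at
#' most one representative is kept: in `"population-analysis"` scope one
#' record per (site, haplogroup); in `"dating"` scope one record per site
#' outright (used within a single dated clade).  The record with the
#' smallest `sample_id` is retained; modern records pass through
#' untouched.
#'
#' @param samples Sample data frame (see [read_sample_table()]).
#' @param scope `"population-analysis"` or `"dating"`.
#' @return The filtered data frame.
#' @export
dedup_by_site <- function(samples, scope = c("population-analysis", "dating")) {
  scope <- match.arg(scope)
  anc <- samples$period == "ancient"
  key <- if (scope == "population-analysis")
    paste(samples$site, samples$haplogroup, sep = "\r") else samples$site
  keep <- rep(TRUE, nrow(samples))
  for (k in unique(key[anc])) {
    idx <- which(anc & key == k)
    if (length(idx) > 1L) {
      winner <- idx[order(samples$sample_id[idx])[1]]  # smallest id wins
      keep[setdiff(idx, winner)] <- FALSE
    }
  }
  samples[keep, , drop = FALSE]
}
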