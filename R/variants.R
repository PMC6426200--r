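# Variant tokens, motifs and reference segments.
#
# Variants are reported relative to a reference mitogenome in the field's
# haplotype notation: substitutions as "16223T", insertions as "309.1C"
# (one C inserted after position 309; ".2" for a second inserted base),
# deletions as "16166d", and back mutations as "@16189".  Coordinates are
# 1-based inclusive throughout.  A motif is the ordered set of variant
# tokens distinguishing a sequence from the reference; identical motifs
# define identical haplotypes.

# token vocabulary is tiny and parsing is pure, so results are memoized
.variant_cache <- new.env(parent = emptyenv())

#' Parse a variant token
#'
#' Accepts the canonical notations `"16223T"` (substitution), `"309.1C"` or
#' the equivalent `"309iC"` (insertion), `"16166d"` (deletion) and
#' `"@16189"` (back mutation), case-insensitively for the base letter.
#'
#' @param token Character scalar, one variant token.
#' @param ref_length Upper bound for admissible positions (default the
#'   mitogenome length, 16569).
#' @return A list with elements `position`, `kind` (one of
#'   `"substitution"`, `"insertion"`, `"deletion"`, `"back-mutation"`),
#'   `state` (nucleotide(s), or `""` for deletions/back mutations),
#'   `insert_index` (0 unless an insertion) and `token` (canonical form).
#' @export
#' @examples
#' parse_variant("16223T")
#' parse_variant("309iC")$token  # canonical "309.1C"
parse_variant <- function(token, ref_length = 16569L) {
  stopifnot(is.character(token), length(token) == 1L)
  key <- paste0(token, "\r", ref_length)
  hit <- .variant_cache[[key]]
  if (!is.null(hit)) return(hit)
  tok <- trimws(token)
  if (!nzchar(tok)) stop("empty variant token")
  out <- NULL
  if (grepl("^@[0-9]+$", tok)) {
    pos <- as.integer(sub("^@", "", tok))
    out <- list(position = pos, kind = "back-mutation", state = "",
                insert_index = 0L)
  } else if (grepl("^[0-9]+[dD]$", tok)) {
    pos <- as.integer(sub("[dD]$", "", tok))
    out <- list(position = pos, kind = "deletion", state = "",
                insert_index = 0L)
  } else if (grepl("^[0-9]+\\.[0-9]+[ACGTacgt]+$", tok)) {
    pos <- as.integer(sub("\\..*$", "", tok))
    rest <- sub("^[0-9]+\\.", "", tok)
    idx <- as.integer(sub("[ACGTacgt]+$", "", rest))
    state <- toupper(sub("^[0-9]+", "", rest))
    if (idx < 1L) stop("insertion index must be >= 1 in ", sQuote(token))
    out <- list(position = pos, kind = "insertion", state = state,
                insert_index = idx)
  } else if (grepl("^[0-9]+[iI][ACGTacgt]+$", tok)) {
    pos <- as.integer(sub("[iI].*$", "", tok))
    state <- toupper(sub("^[0-9]+[iI]", "", tok))
    out <- list(position = pos, kind = "insertion", state = state,
                insert_index = 1L)
  } else if (grepl("^[0-9]+[ACGTacgt]$", tok)) {
    pos <- as.integer(sub("[ACGTacgt]$", "", tok))
    state <- toupper(sub("^[0-9]+", "", tok))
    out <- list(position = pos, kind = "substitution", state = state,
                insert_index = 0L)
  } else {
    stop("unparseable variant token ", sQuote(token))
  }
  if (out$position < 1L || out$position > ref_length)
    stop("variant position out of range in ", sQuote(token),
         " (reference length ", ref_length, ")")
  out$token <- format_variant(out)
  .variant_cache[[key]] <- out
  out
}

#' Format a parsed variant canonically
#'
#' @param v A list as returned by [parse_variant()].
#' @return Character scalar: `"16223T"`, `"309.1C"`, `"16166d"` or
#'   `"@16189"`.
#' @export
format_variant <- function(v) {
  switch(v$kind,
    "substitution"  = paste0(v$position, v$state),
    "insertion"     = paste0(v$position, ".", v$insert_index, v$state),
    "deletion"      = paste0(v$position, "d"),
    "back-mutation" = paste0("@", v$position),
    stop("unknown variant kind ", sQuote(v$kind)))
}

#' Construct a motif from variant tokens
#'
#' A motif is a canonical, position-sorted set of variant tokens.  Tokens
#' may be supplied as a character vector or a single whitespace-separated
#' string.  Duplicate sites -- same `(position, insert_index, kind)` -- are
#' rejected; supplying the same token twice collapses silently.
#'
#' @param x Character vector of tokens, or one space-separated string.
#' @param ref_length Position bound passed to [parse_variant()].
#' @return Character vector of canonical tokens, sorted by
#'   `(position, insert_index)`, with class `"motif"`.
#' @export
#' @examples
#' motif("16223T 16311C")
#' motif(c("309iC", "16189C"))
motif <- function(x = character(), ref_length = 16569L) {
  if (length(x) == 1L && grepl("[[:space:]]", x))
    x <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  x <- x[nzchar(x)]
  if (length(x) == 0L) return(structure(character(), class = "motif"))
  parsed <- lapply(x, parse_variant, ref_length = ref_length)
  tok <- vapply(parsed, `[[`, "", "token")
  keep <- !duplicated(tok)
  parsed <- parsed[keep]
  tok <- tok[keep]
  key <- paste(vapply(parsed, `[[`, 0L, "position"),
               vapply(parsed, `[[`, 0L, "insert_index"),
               vapply(parsed, `[[`, "", "kind"))
  if (anyDuplicated(key))
    stop("conflicting variants at one site: ",
         paste(tok[duplicated(key) | duplicated(key, fromLast = TRUE)],
               collapse = ", "))
  ord <- order(vapply(parsed, `[[`, 0L, "position"),
               vapply(parsed, `[[`, 0L, "insert_index"))
  structure(tok[ord], class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  if (length(x) == 0L) cat("<motif: reference>\n")
  else cat("<motif:", paste(unclass(x), collapse = " "), ">\n")
  invisible(x)
}

#' @exportS3Method base::format
format.motif <- function(x, ...) paste(unclass(x), collapse = " ")

# Parsed data frame view of a motif (internal; fast constructor -- this
# sits on the hot path of assignment and network building)
motif_df <- function(m) {
  parsed <- lapply(unclass(m), parse_variant)
  out <- list(
    position = vapply(parsed, `[[`, 0L, "position"),
    kind = vapply(parsed, `[[`, "", "kind"),
    state = vapply(parsed, `[[`, "", "state"),
    insert_index = vapply(parsed, `[[`, 0L, "insert_index"),
    token = vapply(parsed, `[[`, "", "token"))
  class(out) <- "data.frame"
  attr(out, "row.names") <- .set_row_names(length(parsed))
  out
}

# Site -> state map for comparing motifs.  Sites are "pos" for
# substitutions/deletions and "pos.idx" for insertions; deletion state is
# "-".  Back mutations have no state of their own and are disallowed here:
# they only occur in phylotree edge definitions, where they are resolved
# by compose_variants() before any comparison.
motif_states <- function(m) {
  df <- motif_df(m)
  if (any(df$kind == "back-mutation"))
    stop("back mutations must be composed away before comparison")
  site <- ifelse(df$kind == "insertion",
                 paste0(df$position, ".", df$insert_index),
                 as.character(df$position))
  state <- ifelse(df$kind == "deletion", "-", df$state)
  stats::setNames(state, site)
}

#' Compose variant lists along a phylotree path
#'
#' Applies `new` on top of `base`: a back mutation `"@p"` in `new` removes
#' a substitution at position `p` inherited from `base` (restoring the
#' reference state); any other variant overwrites the inherited state at
#' its site.
#'
#' @param base,new Motifs (or token vectors).
#' @return The composed [motif()].
#' @export
compose_variants <- function(base, new) {
  base <- motif(base); new <- motif(new)
  bdf <- motif_df(base)
  ndf <- motif_df(new)
  back <- ndf$position[ndf$kind == "back-mutation"]
  keep <- !(bdf$position %in% back & bdf$kind == "substitution")
  bdf <- bdf[keep, , drop = FALSE]
  ndf <- ndf[ndf$kind != "back-mutation", , drop = FALSE]
  # new overwrites base at the same site
  bkey <- paste(bdf$position, bdf$insert_index)
  nkey <- paste(ndf$position, ndf$insert_index)
  bdf <- bdf[!(bkey %in% nkey), , drop = FALSE]
  motif(c(bdf$token, ndf$token))
}

#' Number of differing sites between two motifs
#'
#' Counts the `(position, insert_index)` sites at which the two motifs
#' imply different states, treating absence of a variant as the reference
#' state.  Two different substitutions at one position therefore count as
#' one difference, and presence-vs-absence of a variant as one.
#'
#' @param a,b Motifs.
#' @return Non-negative integer.
#' @export
#' @examples
#' hamming_motif_distance(motif("16223T 16311C"), motif("16311C 16362C"))
hamming_motif_distance <- function(a, b) {
  sa <- motif_states(motif(a)); sb <- motif_states(motif(b))
  sites <- union(names(sa), names(sb))
  xa <- sa[sites]; xa[is.na(xa)] <- "."
  xb <- sb[sites]; xb[is.na(xb)] <- "."
  sum(xa != xb)
}

#' Reference segment
#'
#' A named stretch of the reference mitogenome with 1-based inclusive
#' coordinates.  The default analysis window is the first hypervariable
#' region (HVRI), positions 16000--16400.
#'
#' @param name Segment name.
#' @param sequence IUPAC nucleotide string (uppercased; U mapped to T).
#' @param start 1-based start coordinate of the first base of `sequence`.
#' @return List with class `"ref_segment"`: `name`, `sequence`, `start`,
#'   `end`.
#' @export
ref_segment <- function(name, sequence, start = 1L) {
  sequence <- gsub("U", "T", toupper(as.character(sequence)[1]), fixed = TRUE)
  if (!grepl("^[ACGTRYSWKMBDHVN]*$", sequence))
    stop("non-IUPAC characters in reference segment ", sQuote(name))
  start <- as.integer(start)
  if (start < 1L) stop("start must be >= 1")
  structure(list(name = name, sequence = sequence, start = start,
                 end = start + nchar(sequence) - 1L),
            class = "ref_segment")
}

#' @export
print.ref_segment <- function(x, ...) {
  cat("<ref_segment ", x$name, ": ", x$start, "-", x$end, " (",
      nchar(x$sequence), " bp)>\n", sep = "")
  invisible(x)
}

#' Synthetic HVRI reference segment
#'
#' A fixed, deterministically generated 401-bp segment standing in for the
#' HVRI window (positions 16000--16400) of a reference mitogenome.  It is
#' synthetic -- the bases are pseudorandom, not the rCRS -- but since all
#' statistics downstream of variant calling depend only on variant
#' positions and states relative to whatever reference is supplied, it
#' supports simulation and testing of every stage.  Real analyses should
#' pass their own reference via [ref_segment()].
#'
#' @return A [ref_segment()] spanning 16000--16400.
#' @export
synthetic_hvri_reference <- function() {
  # small deterministic Lehmer generator so the global RNG stream is
  # untouched (products stay below 2^53, exact in doubles)
  n <- 401L
  state <- 987654321
  bases <- character(n)
  for (i in seq_len(n)) {
    state <- (state * 16807) %% 2147483647
    bases[i] <- c("A", "C", "G", "T")[state %% 4 + 1]
  }
  ref_segment("synthetic-HVRI", paste(bases, collapse = ""), 16000L)
}

#' Clock rate configuration
#'
#' The substitution clock used for coalescence dating: the expected number
#' of years per substitution over the whole mitogenome, corrected for
#' purifying selection.  The default, one substitution per 3624 years, is
#' the standard corrected whole-mitogenome rate.
#'
#' @param years_per_substitution Positive real; default 3624.
#' @return List with class `"rate_config"`.
#' @export
rate_config <- function(years_per_substitution = 3624) {
  if (!is.numeric(years_per_substitution) || years_per_substitution <= 0)
    stop("years_per_substitution must be strictly positive")
  structure(list(years_per_substitution = as.numeric(years_per_substitution)),
            class = "rate_config")
}

#' Default phylogenetic exclusion rules
#'
#' Hypermutable sites conventionally excluded from phylogenetic analysis:
#' indels around positions 309, 522, 573 and 16193, and hotspot
#' substitutions at 16519.
#'
#' @return List with `indel_positions` and `substitution_positions`.
#' @export
default_exclusions <- function() {
  list(indel_positions = c(309L, 522L, 573L, 16193L),
       substitution_positions = 16519L)
}

# Is a parsed variant excluded under the rules? (internal)
variant_excluded <- function(df, exclusions = default_exclusions()) {
  (df$kind %in% c("insertion", "deletion") &
     df$position %in% exclusions$indel_positions) |
  (df$kind == "substitution" &
     df$position %in% exclusions$substitution_positions)
}

#' Apply exclusion rules to a motif
#'
#' @param m Motif.
#' @param exclusions Rules as from [default_exclusions()].
#' @return List with `kept` and `excluded` motifs.
#' @export
filter_motif <- function(m, exclusions = default_exclusions()) {
  df <- motif_df(motif(m))
  if (nrow(df) == 0L)
    return(list(kept = motif(), excluded = motif()))
  drop <- variant_excluded(df, exclusions)
  list(kept = motif(df$token[!drop]), excluded = motif(df$token[drop]))
}
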