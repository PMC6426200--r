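# Frequency tables, Nei gene diversity, exact Fisher tests and the
# east/west asymmetry scan.

#' Tabulate haplogroup frequencies
#'
#' Counts samples per (population, category).  Categories may be given as
#' a schema of mixed granularity (e.g. a generic `"H"` alongside
#' `"H1cf"`): each sample counts toward the most specific schema entry
#' whose label is a nomenclature prefix of the sample's haplogroup.
#' Schema entries may pool clades with `"/"` (`"L1/L2"`) and a `"Other X"`
#' entry matches clade `X` when nothing more specific does.
#'
#' @param samples Sample data frame with `haplogroup` and a grouping
#'   column.
#' @param by Grouping column name, default `"island"`.
#' @param categories Optional character vector (the schema).  Default:
#'   the distinct haplogroups observed.
#' @param pool_lanfue Pool islands `LAN` and `FUE` into one `"LAN&FUE"`
#'   population (the two easternmost islands are routinely pooled when
#'   sample sizes are small).
#' @param strict Error on samples with an empty haplogroup (default
#'   drops them with a warning).
#' @return A [freq_table()] (categories x populations).  Samples matching
#'   no schema entry fall into an `"other"` row when present, otherwise a
#'   warning is raised and they are dropped.
#' @export
haplogroup_frequencies <- function(samples, by = "island", categories = NULL,
                                   pool_lanfue = FALSE, strict = FALSE) {
  hg <- as.character(samples$haplogroup)
  if (any(!nzchar(hg))) {
    if (strict) stop("sample(s) with no haplogroup: ",
                     paste(samples$sample_id[!nzchar(hg)], collapse = ", "))
    if (nrow(samples)) warning("dropping ", sum(!nzchar(hg)),
                               " sample(s) with no haplogroup")
    samples <- samples[nzchar(hg), , drop = FALSE]
    hg <- hg[nzchar(hg)]
  }
  pop <- as.character(samples[[by]])
  if (pool_lanfue) pop[pop %in% c("LAN", "FUE")] <- "LAN&FUE"
  if (is.null(categories)) categories <- sort(unique(hg))
  cat_of <- vapply(hg, match_category, "", categories = categories)
  unmatched <- is.na(cat_of)
  if (any(unmatched)) {
    warning("haplogroup(s) outside the category schema dropped: ",
            paste(unique(hg[unmatched]), collapse = ", "))
    cat_of <- cat_of[!unmatched]; pop <- pop[!unmatched]
    samples <- samples[!unmatched, , drop = FALSE]
  }
  if (nrow(samples) == 0L) {
    m <- matrix(0L, length(categories), 0L,
                dimnames = list(categories, character()))
    return(freq_table(m))
  }
  mult <- if (is.null(samples$multiplicity)) rep(1L, nrow(samples)) else
    samples$multiplicity
  tab <- tapply(mult, list(factor(cat_of, levels = categories),
                           factor(pop, levels = sort(unique(pop)))),
                sum, default = 0L)
  freq_table(tab)
}

# Most specific schema category matching a haplogroup label (internal).
# Matching is by nomenclature prefix; "A/B" entries match either clade;
# "Other X" matches clade X with the lowest possible specificity.
match_category <- function(hg, categories) {
  best <- NA_character_; best_len <- -1L
  for (cat in categories) {
    is_other <- grepl("^Other ", cat)
    alts <- strsplit(sub("^Other ", "", cat), "/", fixed = TRUE)[[1]]
    for (alt in alts) {
      if (startsWith(hg, alt)) {
        len <- if (is_other) 0L else nchar(alt)
        if (len > best_len) { best <- cat; best_len <- len }
      }
    }
  }
  if (is.na(best) && "other" %in% categories) best <- "other"
  best
}

#' Nei gene diversity with sampling standard error
#'
#' The unbiased estimator `H = n/(n-1) * (1 - sum(p_i^2))` of the
#' probability that two randomly drawn sequences differ, with Nei's
#' sampling variance
#' `V = 2/(n(n-1)) * (2(n-2)(sum p_i^3 - (sum p_i^2)^2) + sum p_i^2 -
#' (sum p_i^2)^2)`.
#'
#' @param counts Non-negative integer vector of category counts,
#'   `n = sum(counts) >= 2`.
#' @return List with class `"diversity"`: `H`, `SE`, `n`, `k` (categories
#'   with non-zero count).
#' @export
#' @examples
#' nei_diversity(c(69, 1))  # H = 2.86%, SE = 2.76%
nei_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("need at least 2 observations")
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  H <- n / (n - 1) * (1 - s2)
  V <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  structure(list(H = H, SE = sqrt(max(0, V)), n = n, k = length(counts)),
            class = "diversity")
}

#' @export
print.diversity <- function(x, ...) {
  cat(sprintf("<gene diversity %.2f%% +/- %.2f%% (n = %d, k = %d)>\n",
              100 * x$H, 100 * x$SE, x$n, x$k))
  invisible(x)
}

#' Exact two-tailed Fisher test for a 2x2 table
#'
#' Full enumeration over the hypergeometric support: the two-tailed p is
#' the sum of the probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table, with a
#' 1e-7 relative tolerance for floating-point ties.  Terms are computed
#' via log-gamma, so totals of several hundred are exact to machine
#' precision.  A zero margin yields p = 1.
#'
#' @param a,b,c,d Cell counts (rows: category present/absent; columns:
#'   the two groups), or a 2x2 matrix as `a`.
#' @return The two-tailed p-value.
#' @export
#' @examples
#' fisher_exact_2x2(6, 0, 101, 215)  # 0.0012
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- sum(cells)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == N) return(1.0)
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(N, c1)
  logp_obs <- logp[support == a]
  sum(exp(logp[logp <= logp_obs + log(1 + 1e-7)]))
}

#' Scan haplogroup categories for east/west asymmetry
#'
#' For each category, forms the 2x2 table of (category present/absent) x
#' (east/west) from pooled island counts and applies the exact two-tailed
#' Fisher test.  Populations can be excluded to probe whether a signal is
#' driven by single drifted islands.
#'
#' @param freqs A [freq_table()].
#' @param east,west Character vectors of population labels.  Defaults:
#'   east `c("GCA", "LAN&FUE")`, west `c("HIE", "PAL", "TFE", "GOM")`.
#' @param categories Categories to test; default all rows.  Categories
#'   absent from the table, or with zero total count, are skipped with a
#'   warning.
#' @return Data frame: `category`, `east`, `west` (counts), `east_n`,
#'   `west_n`, `p`.
#' @export
asymmetry_scan <- function(freqs,
                           east = c("GCA", "LAN&FUE"),
                           west = c("HIE", "PAL", "TFE", "GOM"),
                           categories = NULL) {
  pops <- colnames(freqs)
  missing_pop <- setdiff(c(east, west), pops)
  if (length(missing_pop))
    stop("population(s) not in table: ", paste(missing_pop, collapse = ", "))
  if (is.null(categories)) categories <- rownames(freqs)
  absent <- setdiff(categories, rownames(freqs))
  if (length(absent)) {
    warning("categories not in table skipped: ",
            paste(absent, collapse = ", "))
    categories <- intersect(categories, rownames(freqs))
  }
  n_e <- sum(unclass(freqs)[, east, drop = FALSE])
  n_w <- sum(unclass(freqs)[, west, drop = FALSE])
  rows <- lapply(categories, function(cat) {
    e <- sum(unclass(freqs)[cat, east])
    w <- sum(unclass(freqs)[cat, west])
    if (e + w == 0) {
      warning("category with zero total count skipped: ", cat)
      return(NULL)
    }
    data.frame(category = cat, east = e, west = w,
               east_n = n_e, west_n = n_w,
               p = fisher_exact_2x2(e, n_e - e, w, n_w - w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(category = character(), east = integer(),
                      west = integer(), east_n = integer(),
                      west_n = integer(), p = numeric())
  rownames(out) <- NULL
  out
}
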