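# Pairwise Phi_ST from haplotype/haplogroup frequencies (AMOVA variance
# components with 0/1 inter-haplotype distances), Slatkin linearization,
# and metric MDS by stress majorization (SMACOF).

#' Pairwise Phi_ST between two populations
#'
#' AMOVA with 0/1 (identity) inter-individual distances, so the statistic
#' is a pure function of category frequencies.  With group sizes `n_1`,
#' `n_2`, `N = n_1 + n_2`, within-group frequencies `p_gi` and pooled
#' frequencies `P_i`:
#' `SSD_g = (n_g/2)(1 - sum_i p_gi^2)`, `SSD_T = (N/2)(1 - sum_i P_i^2)`,
#' `SSD_A = SSD_T - sum_g SSD_g`, `sigma_w^2 = sum_g SSD_g / (N - 2)`,
#' `n_c = (N - (n_1^2 + n_2^2)/N) / (G - 1)`,
#' `sigma_a^2 = (SSD_A - sigma_w^2) / n_c`, and
#' `Phi_ST = sigma_a^2 / (sigma_a^2 + sigma_w^2)`.
#' Negative estimates are truncated to 0.
#'
#' @param counts1,counts2 Non-negative count vectors over a shared
#'   category universe (same length and order).
#' @return Phi_ST in `[0, 1]`.
#' @export
pairwise_phist <- function(counts1, counts2) {
  if (length(counts1) != length(counts2))
    stop("count vectors must share one category universe")
  n1 <- sum(counts1); n2 <- sum(counts2); N <- n1 + n2
  if (n1 == 0 || n2 == 0) stop("both populations must be non-empty")
  p1 <- counts1 / n1; p2 <- counts2 / n2
  P <- (counts1 + counts2) / N
  ssd1 <- n1 / 2 * (1 - sum(p1^2))
  ssd2 <- n2 / 2 * (1 - sum(p2^2))
  ssd_t <- N / 2 * (1 - sum(P^2))
  ssd_a <- ssd_t - (ssd1 + ssd2)
  sigma_w <- if (N > 2) (ssd1 + ssd2) / (N - 2) else 0
  n_c <- (N - (n1^2 + n2^2) / N)  # G - 1 = 1
  sigma_a <- (ssd_a - sigma_w) / n_c
  if (sigma_a <= 0) return(0)
  denom <- sigma_a + sigma_w
  if (denom <= 0) return(0)
  min(1, sigma_a / denom)
}

#' Slatkin linearization of Phi_ST
#'
#' `D = Phi / (1 - Phi)`, the transform that grows linearly with
#' divergence time under a drift model; `Phi = 1` is capped at `1e6` so
#' the result remains a usable dissimilarity.
#'
#' @param phi Phi_ST in `[0, 1]`.
#' @return Linearized distance `D >= 0`.
#' @export
linearize_fst <- function(phi) {
  if (any(phi < 0 | phi > 1)) stop("Phi_ST must lie in [0, 1]")
  ifelse(phi >= 1, 1e6, pmin(phi / (1 - phi), 1e6))
}

#' Linearized Phi_ST distance matrix
#'
#' All population pairs of a frequency table via [pairwise_phist()] and
#' [linearize_fst()].
#'
#' @param freqs A [freq_table()] with at least two non-empty populations.
#' @return Symmetric matrix with zero diagonal, class `"dist_matrix"`.
#' @export
distance_matrix <- function(freqs) {
  m <- unclass(freqs)
  if (ncol(m) < 2) stop("need at least 2 populations")
  if (any(colSums(m) == 0))
    stop("population with no samples: ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  k <- ncol(m)
  D <- matrix(0, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    D[i, j] <- D[j, i] <- linearize_fst(pairwise_phist(m[, i], m[, j]))
  }
  class(D) <- c("dist_matrix", class(D))
  D
}

#' Metric MDS by stress majorization (SMACOF)
#'
#' Embeds a dissimilarity matrix in `dims` dimensions by minimizing raw
#' stress with the Guttman transform, initialized by classical
#' (Torgerson) scaling.  Stress is reported as normalized stress-1,
#' `sqrt(sum (delta - d)^2 / sum delta^2)`, with unit weights; it is
#' non-increasing across iterations by construction.
#'
#' @param D Symmetric dissimilarity matrix (zero diagonal).
#' @param dims Embedding dimension, default 2; must be below the number
#'   of objects.
#' @param tol Stop when the stress-1 decrease falls below `tol`
#'   (default 1e-6).
#' @param max_iter Iteration cap, default 1000.
#' @param seed Used only to jitter a degenerate (rank-deficient)
#'   Torgerson start; the algorithm is otherwise deterministic.
#' @return List with class `"mds_config"`: `coordinates` (centered),
#'   `stress`, `stress_trace` (stress after init and after each
#'   iteration), `iterations`.
#' @export
smacof_mds <- function(D, dims = 2, tol = 1e-6, max_iter = 1000,
                       seed = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (dims >= n) stop("dims must be smaller than the number of objects")
  if (!isTRUE(all.equal(D, t(D))) || any(diag(D) != 0) || any(D < 0))
    stop("D must be symmetric, non-negative, with zero diagonal")
  labels <- rownames(D)
  denom <- sum(D^2) / 2  # over i < j
  stress1 <- function(X) {
    d <- as.matrix(stats::dist(X))
    if (denom == 0) return(0)
    sqrt(sum((D - d)^2) / 2 / denom)
  }
  if (denom == 0) {
    X <- matrix(0, n, dims, dimnames = list(labels, NULL))
    return(structure(list(coordinates = X, stress = 0, stress_trace = 0,
                          iterations = 0L), class = "mds_config"))
  }
  # Torgerson start
  X <- suppressWarnings(stats::cmdscale(D, k = dims))
  if (ncol(X) < dims)
    X <- cbind(X, matrix(0, n, dims - ncol(X)))
  if (any(!is.finite(X))) X[!is.finite(X)] <- 0
  if (all(stats::dist(X) < .Machine$double.eps)) {
    if (!is.null(seed)) set.seed(seed)
    X <- X + matrix(stats::rnorm(n * dims, sd = mean(D) / 10 + 1e-8), n, dims)
  }
  trace <- stress1(X)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    d <- as.matrix(stats::dist(X))
    B <- ifelse(d > 0, -D / pmax(d, .Machine$double.xmin), 0)
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    Xn <- B %*% X / n            # Guttman transform (unit weights)
    Xn <- sweep(Xn, 2, colMeans(Xn))
    s <- stress1(Xn)
    trace <- c(trace, s)
    X <- Xn
    if (trace[length(trace) - 1] - s < tol) break
  }
  X <- sweep(X, 2, colMeans(X))
  rownames(X) <- labels
  structure(list(coordinates = X, stress = trace[length(trace)],
                 stress_trace = trace, iterations = it),
            class = "mds_config")
}

#' @export
print.mds_config <- function(x, ...) {
  cat(sprintf("<MDS configuration: %d points, %d dims, stress-1 %.3g (%d iterations)>\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress,
              x$iterations))
  invisible(x)
}
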