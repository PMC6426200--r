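# Weighted-least-squares admixture: the mixing proportions m_k of K
# parental populations that best reproduce a hybrid population's
# haplogroup frequency vector, in Long's (1991) WLS formulation.

#' Weighted-least-squares admixture proportions
#'
#' Minimizes `(h - P m)' W (h - P m)` subject to `sum(m) = 1`, where `h`
#' is the hybrid's relative frequency vector, the columns of `P` are the
#' parental frequency vectors, and `W` is diagonal with
#' `w_i = 1 / (pbar_i (1 - pbar_i))`, `pbar` the unweighted mean of the
#' parental frequencies (categories with `pbar` of 0 or 1 carry no
#' information and are dropped).  The sum constraint is enforced by
#' substituting the last component into the normal equations.  Any
#' negative component is handled either by clipping to `[0, 1]` and
#' renormalizing (`constrain = "clip"`, the default, transparent rule) or
#' by an active-set non-negative solution of the same constrained problem
#' (`constrain = "nnls"`).
#'
#' @param hybrid Count (or frequency) vector of the hybrid population.
#' @param parentals List of count (or frequency) vectors, one per
#'   parental population, over the same category universe.
#' @param weights `"long"` (default) for the parental-mean weighting
#'   above, `"unweighted"` for ordinary least squares.
#' @param constrain `"clip"` or `"nnls"`.
#' @return List with class `"admixture"`: `m` (named proportions summing
#'   to 1), `residual` (weighted residual sum of squares at the returned
#'   `m`), `SE` (`NA` until filled by [bootstrap_admixture()]), `weights`,
#'   `constrain`, `categories_used`.
#' @export
#' @examples
#' p1 <- c(8, 1, 1) / 10; p2 <- c(1, 1, 8) / 10
#' wls_admixture(0.6 * p1 + 0.4 * p2, list(p1, p2))$m
wls_admixture <- function(hybrid, parentals,
                          weights = c("long", "unweighted"),
                          constrain = c("clip", "nnls")) {
  weights <- match.arg(weights)
  constrain <- match.arg(constrain)
  if (length(parentals) < 2) stop("need at least 2 parental populations")
  if (sum(hybrid) <= 0) stop("hybrid population is empty")
  lens <- vapply(parentals, length, 0L)
  if (any(lens != length(hybrid)))
    stop("hybrid and parentals must share one category universe")
  h <- hybrid / sum(hybrid)
  P <- vapply(parentals, function(x) x / sum(x), numeric(length(h)))
  K <- ncol(P)
  pbar <- rowMeans(P)
  keep <- pbar > 0 & pbar < 1
  if (sum(keep) < K)
    stop("too few informative categories (", sum(keep), ") for ", K,
         " parentals")
  w <- if (weights == "long") 1 / (pbar[keep] * (1 - pbar[keep])) else
    rep(1, sum(keep))
  hk <- h[keep]; Pk <- P[keep, , drop = FALSE]
  sol <- solve_constrained_wls(hk, Pk, w)
  m <- sol$m
  if (constrain == "clip") {
    if (any(m < 0)) {
      m <- pmin(pmax(m, 0), 1)
      if (sum(m) == 0) stop("all components clipped to zero")
      m <- m / sum(m)
    }
  } else {
    # active set: fix negative components at zero, re-solve on the rest
    active <- rep(FALSE, K)
    repeat {
      if (any(sol$m < -1e-12)) {
        active[!active][which.min(sol$m)] <- TRUE
        if (sum(!active) < 1) stop("no feasible non-negative solution")
        if (sum(!active) == 1) {
          m <- as.numeric(!active)
          break
        }
        sol <- solve_constrained_wls(hk, Pk[, !active, drop = FALSE], w)
      } else {
        m <- numeric(K)
        m[!active] <- pmax(sol$m, 0)
        m <- m / sum(m)
        break
      }
    }
  }
  names(m) <- names(parentals) %||% paste0("parental", seq_len(K))
  resid <- hk - Pk %*% m
  structure(list(m = m, residual = sum(w * resid^2), SE = rep(NA_real_, K),
                 weights = weights, constrain = constrain,
                 categories_used = sum(keep)),
            class = "admixture")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Solve min (h - P m)' diag(w) (h - P m)  s.t. sum(m) = 1, by
# substituting m_K = 1 - sum(m_-K) (internal).
solve_constrained_wls <- function(h, P, w) {
  K <- ncol(P)
  pK <- P[, K]
  A <- P[, -K, drop = FALSE] - pK    # reduced design
  y <- h - pK
  M <- crossprod(A, w * A)
  if (K > 1 && rcond(M) < 1e-12)
    stop("collinear parental populations: reduced normal matrix is singular")
  m_red <- solve(M, crossprod(A, w * y))
  m <- c(as.numeric(m_red), 1 - sum(m_red))
  list(m = m)
}

#' @export
print.admixture <- function(x, ...) {
  se <- ifelse(is.na(x$SE), "", sprintf(" +/- %.4f", x$SE))
  cat("<admixture (", x$weights, " WLS):\n", sep = "")
  for (k in seq_along(x$m))
    cat(sprintf("  %s: %.4f%s\n", names(x$m)[k], x$m[k], se[k]))
  cat(sprintf("  weighted RSS %.4g over %d categories>\n",
              x$residual, x$categories_used))
  invisible(x)
}

#' Bootstrap standard errors for admixture proportions
#'
#' Resamples the hybrid and every parental multinomially at their
#' observed sample sizes, re-estimates the proportions `B` times, and
#' reports the per-component standard deviation.  Counts (not
#' frequencies) must therefore be supplied.  Deterministic given `seed`.
#'
#' @param hybrid,parentals Count vectors as in [wls_admixture()].
#' @param B Number of replicates, default 1000 (must be >= 2).
#' @param seed Optional integer seed.
#' @param ... Passed to [wls_admixture()].
#' @return An `"admixture"` object with `SE` filled in and `n_boot`
#'   attached; `m` is the point estimate on the original data.
#' @export
bootstrap_admixture <- function(hybrid, parentals, B = 1000, seed = NULL,
                                ...) {
  if (B < 2) stop("B must be >= 2")
  fit <- wls_admixture(hybrid, parentals, ...)
  if (!is.null(seed)) set.seed(seed)
  n_h <- sum(hybrid)
  n_p <- vapply(parentals, sum, 0)
  reps <- matrix(NA_real_, B, length(fit$m))
  for (b in seq_len(B)) {
    hb <- as.vector(stats::rmultinom(1, n_h, hybrid / n_h))
    pb <- lapply(seq_along(parentals), function(k)
      as.vector(stats::rmultinom(1, n_p[k], parentals[[k]] / n_p[k])))
    names(pb) <- names(parentals)
    reps[b, ] <- tryCatch(wls_admixture(hb, pb, ...)$m,
                          error = function(e) rep(NA_real_, length(fit$m)))
  }
  ok <- stats::complete.cases(reps)
  if (sum(ok) < 2) stop("bootstrap failed in nearly all replicates")
  fit$SE <- apply(reps[ok, , drop = FALSE], 2, stats::sd)
  fit$n_boot <- sum(ok)
  fit
}

#' Analytic (GLS sandwich) standard errors for admixture proportions
#'
#' First-order standard errors treating the hybrid frequency vector as a
#' multinomial draw of size `n` at the fitted frequencies (parentals
#' taken as fixed): the covariance of the reduced WLS solution is
#' `(A'WA)^{-1} A'W V W A (A'WA)^{-1}` with `V` the multinomial
#' covariance of `h` divided by `n`.  An alternative to
#' [bootstrap_admixture()] for large samples.
#'
#' @param hybrid,parentals Count vectors as in [wls_admixture()].
#' @param ... Passed to [wls_admixture()].
#' @return An `"admixture"` object with `SE` filled in.
#' @export
analytic_admixture_se <- function(hybrid, parentals, ...) {
  fit <- wls_admixture(hybrid, parentals, ...)
  n_h <- sum(hybrid)
  h <- hybrid / n_h
  P <- vapply(parentals, function(x) x / sum(x), numeric(length(h)))
  K <- ncol(P)
  pbar <- rowMeans(P)
  keep <- pbar > 0 & pbar < 1
  w <- if (fit$weights == "long") 1 / (pbar[keep] * (1 - pbar[keep])) else
    rep(1, sum(keep))
  hk <- h[keep]; Pk <- P[keep, , drop = FALSE]
  A <- Pk[, -K, drop = FALSE] - Pk[, K]
  Minv <- solve(crossprod(A, w * A))
  V <- (diag(hk, nrow = length(hk)) - tcrossprod(hk)) / n_h
  G <- Minv %*% t(A * w)
  S <- G %*% V %*% t(G)
  se_red <- sqrt(pmax(0, diag(S)))
  # last component is 1 - sum of the others
  se_K <- sqrt(max(0, sum(S)))
  fit$SE <- c(se_red, se_K)
  fit
}
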