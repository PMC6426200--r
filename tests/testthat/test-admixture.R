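# Weighted-least-squares admixture estimation and its uncertainty.

p_sep <- list(A = c(70, 10, 10, 5, 5) / 100,
              B = c(5, 10, 10, 70, 5) / 100,
              C = c(5, 5, 10, 10, 70) / 100)

test_that("exact mixtures are recovered to numerical precision", {
  h <- 0.6 * p_sep$A + 0.4 * p_sep$B
  fit <- wls_admixture(h, p_sep[c("A", "B")])
  expect_equal(unname(fit$m), c(0.6, 0.4), tolerance = 1e-10)
  expect_lt(fit$residual, 1e-20)
  expect_equal(sum(fit$m), 1)
  # hybrid equal to one parental
  fit1 <- wls_admixture(p_sep$A, p_sep[c("A", "B")])
  expect_equal(unname(fit1$m), c(1, 0), tolerance = 1e-10)
  # three-way equal mix, checked against the Lagrange-multiplier oracle
  h3 <- Reduce(`+`, p_sep) / 3
  fit3 <- wls_admixture(h3, p_sep, weights = "unweighted")
  P <- vapply(p_sep, identity, numeric(5))
  expect_equal(unname(fit3$m), unname(oracle_ls_admixture(h3, P)),
               tolerance = 1e-10)
  expect_equal(unname(fit3$m), rep(1 / 3, 3), tolerance = 1e-10)
})

test_that("weighted and unweighted fits agree with the oracle off-model", {
  # noisy hybrid: unweighted solution must match the Lagrange oracle
  set.seed(3)
  h <- as.vector(rmultinom(1, 200, 0.5 * p_sep$A + 0.5 * p_sep$C)) / 200
  fit <- wls_admixture(h, p_sep, weights = "unweighted")
  P <- vapply(p_sep, identity, numeric(5))
  expect_equal(unname(fit$m), unname(oracle_ls_admixture(h, P)),
               tolerance = 1e-8)
})

test_that("estimates are invariant to scaling and category permutation", {
  h <- c(30, 20, 10, 25, 15)
  fit <- wls_admixture(h, p_sep)
  fit10 <- wls_admixture(10 * h, lapply(p_sep, function(x) 5 * x))
  expect_equal(fit10$m, fit$m, tolerance = 1e-12)
  set.seed(4)
  perm <- sample(5)
  fitp <- wls_admixture(h[perm], lapply(p_sep, function(x) x[perm]))
  expect_equal(fitp$m, fit$m, tolerance = 1e-12)
})

test_that("negative components are clipped or actively constrained", {
  # hybrid outside the simplex spanned by the parentals
  h <- c(0.9, 0.02, 0.02, 0.02, 0.04)
  fit <- wls_admixture(h, p_sep)
  expect_true(all(fit$m >= 0))
  expect_equal(sum(fit$m), 1)
  fit_nnls <- wls_admixture(h, p_sep, constrain = "nnls")
  expect_true(all(fit_nnls$m >= -1e-12))
  expect_equal(sum(fit_nnls$m), 1)
  # the active-set solution never has a larger weighted residual than
  # the clipped one
  expect_lte(fit_nnls$residual, fit$residual + 1e-12)
})

test_that("collinear parentals raise an explicit error", {
  expect_error(wls_admixture(p_sep$A, list(p_sep$B, p_sep$B)), "collinear")
  expect_error(wls_admixture(p_sep$A, list(p_sep$B)), "at least 2")
})

test_that("bootstrap standard errors are reproducible and consistent", {
  hybrid <- round(1000 * (0.6 * p_sep$A + 0.4 * p_sep$B))
  parentals <- lapply(p_sep[c("A", "B")], function(x) round(1000 * x))
  b1 <- bootstrap_admixture(hybrid, parentals, B = 100, seed = 7)
  b2 <- bootstrap_admixture(hybrid, parentals, B = 100, seed = 7)
  expect_identical(b1$SE, b2$SE)
  expect_true(all(b1$SE >= 0))
  expect_equal(b1$n_boot, 100)
  # large-sample, zero-noise limit: SE shrinks below 0.01
  big_h <- round(1e5 * (0.6 * p_sep$A + 0.4 * p_sep$B))
  big_p <- lapply(p_sep[c("A", "B")], function(x) round(1e5 * x))
  b3 <- bootstrap_admixture(big_h, big_p, B = 50, seed = 8)
  expect_true(all(b3$SE < 0.01))
  expect_error(bootstrap_admixture(hybrid, parentals, B = 1), "B must be")
})

test_that("analytic standard errors are finite and comparable in scale", {
  hybrid <- round(300 * (0.56 * p_sep$A + 0.40 * p_sep$B + 0.04 * p_sep$C))
  parentals <- lapply(p_sep, function(x) round(1000 * x))
  aa <- analytic_admixture_se(hybrid, parentals)
  bb <- bootstrap_admixture(hybrid, parentals, B = 200, seed = 9)
  expect_true(all(is.finite(aa$SE)))
  expect_true(all(aa$SE > 0))
  # same order of magnitude as the bootstrap
  expect_true(all(aa$SE / bb$SE > 0.2 & aa$SE / bb$SE < 5))
})
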