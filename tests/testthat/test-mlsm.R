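test_that("residualize returns least-squares residuals orthogonal to covariates", {
  set.seed(5)
  y <- rnorm(8)
  expect_equal(residualize(y, matrix(nrow = 8, ncol = 0)), y - mean(y))

  Z <- matrix(rnorm(16), 8, 2)
  yo <- residualize(y, Z)          # residuals are orthogonal to Z
  expect_equal(residualize(yo, Z), yo, tolerance = 1e-10)
  expect_lt(max(abs(crossprod(cbind(1, Z), yo))), 1e-10)

  # 6-subject hand case against the normal equations
  y6 <- c(3, 7, 1, 4, 9, 2)
  Z6 <- cbind(c(1, 2, 3, 4, 5, 6), c(0, 1, 0, 1, 0, 1))
  X <- cbind(1, Z6)
  beta <- solve(t(X) %*% X, t(X) %*% y6)
  expect_equal(residualize(y6, Z6), as.numeric(y6 - X %*% beta), tolerance = 1e-12)

  Zbad <- cbind(a = 1:6, b = 2 * (1:6))
  expect_error(residualize(y6, Zbad), "collinear.*b")
})

test_that("dtlvc scales rows to unit norm and flags empty rows", {
  X <- rbind(c(1, 1, 1, 1, 0), c(1, 0, 0, 0, 0), c(1, 1, 1, 1, 1))
  S <- dtlvc(X)
  expect_equal(S[1, 1], 0.5)             # 1/sqrt(4)
  expect_equal(S[2, 1], 1)
  expect_equal(unname(apply(S, 1, function(r) sqrt(sum(r^2)))), rep(1, 3))

  # nested lesions: same unit norm regardless of size
  nested <- rbind(c(1, 1, 0, 0, 0, 0), c(1, 1, 1, 1, 1, 1))
  Sn <- dtlvc(nested)
  expect_equal(sum(Sn[1, ]^2), sum(Sn[2, ]^2))

  Xz <- rbind(c(1, 0), c(0, 0)); rownames(Xz) <- c("s1", "s2")
  expect_error(dtlvc(Xz), "s2")
})

test_that("the SVR solver satisfies strong duality and the tube constraints", {
  set.seed(12)
  n <- 25; V <- 40
  X <- matrix(rbinom(n * V, 1, 0.35), n, V)
  X[rowSums(X) == 0, 1] <- 1
  Xs <- dtlvc(X)
  y <- 3 * Xs[, 3] - 2 * Xs[, 7] + rnorm(n, sd = 0.2)
  spec <- mlsm_spec(C = 2, epsilon = 0.05)
  fit <- fit_svr_map(Xs, y, spec, tol = 1e-8)
  w <- fit$w; b <- fit$intercept; beta <- fit$beta
  # back-projection reproduces the primal weights: objectives coincide
  r <- y - Xs %*% w - b
  primal <- 0.5 * sum(w^2) + spec$C * sum(pmax(abs(r) - spec$epsilon, 0))
  K <- tcrossprod(Xs)
  dual <- -0.5 * t(beta) %*% K %*% beta + sum(y * beta) -
    spec$epsilon * sum(abs(beta))
  expect_gte(primal - as.numeric(dual), -1e-8)   # weak duality
  expect_lt(primal - as.numeric(dual), 1e-4)     # strong duality at optimum
  expect_equal(sum(beta), 0, tolerance = 1e-8)
  expect_true(all(abs(beta) <= spec$C + 1e-8))
  # dual-feasible points inside the tube carry zero coefficients
  expect_true(all(abs(beta[abs(r) < spec$epsilon - 1e-6]) < 1e-6))
})

test_that("planted informative voxels carry the largest |weights|", {
  set.seed(40)
  n <- 60; V <- 80
  X <- matrix(rbinom(n * V, 1, 0.3), n, V)
  X[rowSums(X) == 0, 1] <- 1
  Xs <- dtlvc(X)
  y <- 5 * Xs[, 10] + 5 * Xs[, 20] + rnorm(n, sd = 0.3)
  fit <- fit_svr_map(Xs, y, mlsm_spec())
  expect_setequal(order(abs(fit$w), decreasing = TRUE)[1:2], c(10L, 20L))

  expect_warning(z <- fit_svr_map(Xs, rep(2, n), mlsm_spec()), "constant")
  expect_true(all(z$w == 0))
})

test_that("mlsm permutation p-values match a direct per-permutation refit", {
  set.seed(8)
  n <- 5; V <- 12
  X <- matrix(rbinom(n * V, 1, 0.5), n, V)
  X[rowSums(X) == 0, 1] <- 1
  Xs <- dtlvc(X)
  y <- rnorm(n)
  spec <- mlsm_spec(n_permutations = 120, seed = 2)
  expect_message(pr <- mlsm_permute(Xs, y, spec), "exhaustive")
  expect_true(pr$exhaustive)
  # oracle: every permutation refit one at a time
  perms <- all_perms_oracle(n)
  Wnull <- vapply(perms, function(p)
    fit_svr_map(Xs, y[p], spec)$w, numeric(V))
  p_oracle <- vapply(seq_len(V), function(v)
    mean(abs(Wnull[v, ]) >= abs(pr$w_obs[v]) - 1e-9), numeric(1))
  expect_equal(pr$p, p_oracle, tolerance = 1e-8)
})

test_that("full mlsm flags everything at alpha = 1 and is seed-stable", {
  co <- generate_cohort(tiny_config(n_subjects = 16))
  b <- harmonize(co$behavior)
  spec <- mlsm_spec(n_permutations = 40, alpha = 1, min_lesioned = 4, seed = 6)
  r1 <- suppressWarnings(mlsm(co$masks, b, spec))
  expect_identical(r1$significant_mask$data == 1L, r1$include)
  r2 <- suppressWarnings(mlsm(co$masks, b, spec))
  expect_identical(r1$p_map, r2$p_map)
})
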