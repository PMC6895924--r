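# GBLUP / AI-REML: dense-likelihood oracles, grid-search optimum, MME
# equivalence, shrinkage limits, accuracy evaluation.

# Direct dense evaluation of the restricted deviance (independent of the
# package's eigendecomposition path).
dense_m2ll <- function(y, X, V) {
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  beta <- solve(XtViX, crossprod(X, Vi %*% y))
  r <- y - drop(X %*% beta)
  as.numeric(determinant(V)$modulus) +
    as.numeric(determinant(XtViX)$modulus) +
    drop(crossprod(r, Vi %*% r)) +
    (length(y) - ncol(X)) * log(2 * pi)
}

make_K <- function(n, L, seed) {
  g <- make_test_geno(n, L, seed = seed)
  build_grm(g)$values
}

test_that("REML recovers the simulated heritability from a genomic kinship", {
  K <- make_K(400, 800, seed = 12)
  ids <- rownames(K)
  set.seed(13)
  cK <- chol(0.99 * K + 0.01 * diag(400))
  u <- sqrt(0.3) * drop(crossprod(cK, rnorm(400)))
  y <- setNames(1 + u + rnorm(400, 0, sqrt(0.7)), ids)
  fit <- gblup(y, K, blend = 0.01)
  expect_true(fit$converged)
  expect_lt(abs(fit$h2 - 0.3), 0.12)
  expect_gt(fit$sigma_u2, 0)
})

test_that("deviance at the optimum matches a dense evaluation", {
  K <- make_K(150, 300, seed = 14)
  ids <- rownames(K)
  set.seed(15)
  Kb <- 0.99 * K + 0.01 * diag(150)
  u <- drop(crossprod(chol(Kb), rnorm(150))) * sqrt(0.4)
  y <- setNames(2 + u + rnorm(150, 0, sqrt(0.6)), ids)
  fit <- gblup(y, K, blend = 0.01)
  V <- fit$sigma_u2 * Kb + fit$sigma_e2 * diag(150)
  expect_equal(fit$minus2logL,
               dense_m2ll(unname(y), matrix(1, 150, 1), V),
               tolerance = 1e-8)
  # the exported deviance evaluator agrees too
  expect_equal(gblup_deviance(y, K, fit$sigma_u2, fit$sigma_e2, blend = 0.01),
               fit$minus2logL, tolerance = 1e-10)
})

test_that("the REML optimum matches a profiled grid search", {
  K <- make_K(250, 500, seed = 16)
  ids <- rownames(K)
  set.seed(17)
  Kb <- 0.99 * K + 0.01 * diag(250)
  u <- drop(crossprod(chol(Kb), rnorm(250))) * sqrt(0.35)
  y <- setNames(u + rnorm(250, 0, sqrt(0.65)), ids)
  fit <- gblup(y, K, blend = 0.01)

  X <- matrix(1, 250, 1)
  grid <- seq(0.01, 0.99, by = 0.01)
  prof <- vapply(grid, function(h2) {
    W <- h2 * Kb + (1 - h2) * diag(250)
    Wi <- solve(W)
    XtWiX <- crossprod(X, Wi %*% X)
    beta <- solve(XtWiX, crossprod(X, Wi %*% y))
    r <- unname(y) - drop(X %*% beta)
    q <- drop(crossprod(r, Wi %*% r))
    s2 <- q / (250 - 1)
    as.numeric(determinant(W)$modulus) + as.numeric(determinant(XtWiX)$modulus) +
      (250 - 1) * (log(s2) + 1) + (250 - 1) * log(2 * pi)
  }, numeric(1))
  h2_grid <- grid[which.min(prof)]
  expect_lt(abs(fit$h2 - h2_grid), 0.015)
  # and the fitted deviance is no worse than the best grid point
  expect_lte(fit$minus2logL, min(prof) + 1e-6)
})

test_that("the null model deviance equals the closed-form iid Gaussian value", {
  set.seed(18)
  n <- 200
  ids <- sprintf("b%03d", 1:n)
  K <- diag(n); dimnames(K) <- list(ids, ids)
  y <- setNames(rnorm(n, 5, 1.3), ids)
  se2 <- 1.1
  got <- gblup_deviance(y, K, sigma_u2 = 0, sigma_e2 = se2, blend = 0)
  rss <- sum((y - mean(y))^2)
  closed <- n * log(se2) + log(n / se2) + rss / se2 + (n - 1) * log(2 * pi)
  expect_equal(got, closed, tolerance = 1e-10)
})

test_that("BLUP solutions match a dense mixed-model-equations solve", {
  n_all <- 50; n_tr <- 30
  K <- make_K(n_all, 200, seed = 19)
  all_ids <- rownames(K)
  train <- all_ids[1:n_tr]
  set.seed(20)
  y <- setNames(rnorm(n_tr, 1, 1), train)
  fit <- gblup(y, K, ids = train, blend = 0.01)

  Kb <- 0.99 * K + 0.01 * diag(n_all)
  X <- matrix(1, n_tr, 1)
  Z <- matrix(0, n_tr, n_all)
  Z[cbind(seq_len(n_tr), match(train, all_ids))] <- 1
  se2 <- fit$sigma_e2; su2 <- fit$sigma_u2
  C <- rbind(cbind(crossprod(X) / se2, crossprod(X, Z) / se2),
             cbind(crossprod(Z, X) / se2,
                   crossprod(Z) / se2 + solve(Kb) / su2))
  rhs <- c(crossprod(X, y) / se2, crossprod(Z, y) / se2)
  sol <- unname(solve(C, rhs))
  expect_equal(unname(coef(fit)), sol[1], tolerance = 1e-8)
  expect_equal(unname(predict(fit)), sol[-1], tolerance = 1e-8)
})

test_that("an individual genomically unrelated to training gets GEBV zero", {
  n <- 40
  K <- make_K(n, 150, seed = 21)
  ids <- rownames(K)
  K[n, ] <- 0; K[, n] <- 0; K[n, n] <- 1  # sever the last individual
  set.seed(22)
  y <- setNames(rnorm(n - 1), ids[-n])
  fit <- gblup(y, K, ids = ids[-n], blend = 0.01)
  expect_equal(unname(predict(fit, ids[n])), 0, tolerance = 1e-12)
})

test_that("heritability is invariant to a constant phenotype shift", {
  K <- make_K(120, 250, seed = 23)
  ids <- rownames(K)
  set.seed(24)
  u <- drop(crossprod(chol(0.99 * K + 0.01 * diag(120)), rnorm(120))) * 0.6
  y <- setNames(u + rnorm(120, 0, 0.8), ids)
  f1 <- gblup(y, K)
  f2 <- gblup(y + 100, K)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-6)
  expect_equal(unname(coef(f2) - coef(f1)), 100, tolerance = 1e-4)
})

test_that("simulate() reproduces the fitted variance scale", {
  set.seed(25)
  n <- 300
  ids <- sprintf("c%03d", 1:n)
  K <- diag(n); dimnames(K) <- list(ids, ids)
  y <- setNames(rnorm(n, 0, 1), ids)
  fit <- gblup(y, K, blend = 0)
  sims <- simulate(fit, nsim = 30, seed = 1)
  v <- mean(apply(sims, 2, var))
  expect_lt(abs(v - (fit$sigma_u2 + fit$sigma_e2)), 0.2)
})

test_that("input validation catches malformed calls", {
  K <- make_K(10, 30, seed = 26)
  y <- setNames(rnorm(10), rownames(K))
  expect_error(gblup(y, K, ids = c(rownames(K)[1:9], "ghost")), "absent")
  expect_error(gblup(y, K, blend = 1), "blend")
  expect_error(gblup(setNames(rep(1, 10), rownames(K)), K), "zero variance")
  expect_error(gblup(y, K, X = matrix(1, 10, 2)), "rank deficient")
})

test_that("accuracy and bias evaluation matches closed-form OLS", {
  set.seed(27)
  tbv <- setNames(rnorm(50), sprintf("v%02d", 1:50))
  gebv <- 0.4 * tbv + rnorm(50, 0, 0.3)
  ev <- evaluate_accuracy(tbv, gebv)
  expect_equal(ev$accuracy, cor(tbv, gebv), tolerance = 1e-12)
  ols <- lm(gebv ~ tbv)
  expect_equal(ev$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
  expect_equal(ev$slope, unname(coef(ols)[2]), tolerance = 1e-10)

  expect_equal(evaluate_accuracy(tbv, tbv)$accuracy, 1)
  expect_equal(evaluate_accuracy(tbv, tbv)$slope, 1)
  expect_equal(evaluate_accuracy(tbv, tbv)$intercept, 0, tolerance = 1e-12)
  expect_equal(evaluate_accuracy(tbv, -tbv)$accuracy, -1)
  expect_error(evaluate_accuracy(tbv[1:2], tbv[1:2]), "at least 3")
  expect_error(evaluate_accuracy(tbv, setNames(rep(1, 50), names(tbv))),
               "zero-variance")
})
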