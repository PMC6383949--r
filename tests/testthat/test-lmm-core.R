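test_that("rotation reproduces hand-computed and identity cases", {
  set.seed(1)
  y <- rnorm(2)
  K <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  spec <- model_spec(y, random_effects = list(K))
  # pure-residual vertex: V = I, no rotation effect
  r0 <- rotate_model(spec, 0)
  expect_equal(unname(t(r0$U)), diag(2))
  expect_equal(r0$logdetL, 0)
  expect_equal(r0$ystar, y)
  # hand 2x2 Cholesky at h2 = 0.5: V = [[1, .25], [.25, 1]]
  r1 <- rotate_model(spec, 0.5)
  Lo <- t(r1$U)
  expect_equal(Lo[2, ], c(0.25, sqrt(0.9375)), tolerance = 1e-12)
  expect_equal(r1$logdetL, 0.5 * log(0.9375), tolerance = 1e-12)
  # reconstruction property on random 20x20 problems
  for (i in 1:5) {
    K20 <- random_psd(20)
    sp <- model_spec(rnorm(20), random_effects = list(K20))
    h2 <- runif(1, 0, 0.9)
    rr <- rotate_model(sp, h2)
    V <- h2 * K20 + (1 - h2) * diag(20)
    expect_lt(max(abs(crossprod(rr$U) - V)), 1e-10)
  }
})

test_that("fit_gls matches hand OLS and a dense GLS oracle", {
  spec <- model_spec(c(1, 2, 3))
  rot <- rotate_model(spec, numeric(0))
  fit <- fit_gls(rot)
  expect_equal(unname(fit$alpha_hat), 2)
  expect_equal(fit$RSS, 2)
  expect_equal(fit$sigma2_ml, 2 / 3)
  # exact fit: RSS = 0
  spec2 <- model_spec(c(1, 2, 3), W = cbind(1, c(1, 2, 3)))
  expect_equal(fit_gls(rotate_model(spec2, numeric(0)))$RSS, 0, tolerance = 1e-20)
  # random weighted problem vs explicit V^{-1} oracle
  set.seed(4)
  n <- 25
  K <- random_psd(n)
  y <- rnorm(n)
  W <- cbind(1, rnorm(n))
  X <- matrix(rnorm(n * 2), n, 2)
  spec3 <- model_spec(y, W = W, random_effects = list(K))
  fit3 <- fit_gls(rotate_model(spec3, 0.6), marker = X)
  orc <- oracle_gls(y, W, X, list(K), 0.6)
  expect_equal(unname(fit3$coef), unname(orc$coef), tolerance = 1e-8)
  expect_equal(fit3$RSS, orc$RSS, tolerance = 1e-8)
  expect_equal(unname(fit3$xtx_inv), unname(orc$xtx_inv), tolerance = 1e-8)
  # rank deficiency is flagged, not silently pseudo-inverted
  fit4 <- fit_gls(rotate_model(spec3, 0.6), marker = cbind(W[, 2]))
  expect_identical(fit4$flag, "rank_deficient")
})

test_that("profile likelihoods agree with brute-force oracles", {
  set.seed(5)
  n <- 40
  K <- random_psd(n)
  y <- rnorm(n)
  W <- cbind(1, rnorm(n))
  spec <- model_spec(y, W = W, random_effects = list(K))
  # V = I: ML profile equals the OLS profile log-likelihood
  rot0 <- rotate_model(spec, 0)
  fit0 <- fit_gls(rot0)
  s2 <- fit0$RSS / n
  expect_equal(profile_loglik(rot0, fit0, "ML"),
               -0.5 * n * (log(2 * pi * s2) + 1), tolerance = 1e-10)
  # direct numerical maximization of the MVN log-density over (alpha, sigma2)
  h2 <- 0.45
  V <- h2 * K + (1 - h2) * diag(n)
  negll <- function(par) {
    a <- par[1:2]; s2 <- exp(par[3])
    r <- y - W %*% a
    0.5 * (n * log(2 * pi * s2) + as.numeric(determinant(V)$modulus) +
           drop(t(r) %*% solve(V, r)) / s2)
  }
  op <- optim(c(0, 0, 0), negll, control = list(reltol = 1e-14, maxit = 5000))
  rot <- rotate_model(spec, h2)
  fit <- fit_gls(rot)
  expect_equal(profile_loglik(rot, fit, "ML"), -op$value, tolerance = 1e-6)
  # REML against the dense restricted-likelihood oracle
  expect_equal(profile_loglik(rot, fit, "REML"),
               oracle_profile(y, W, NULL, list(K), h2, "REML"), tolerance = 1e-8)
  # REML invariance under full-rank reparameterization of the design
  Tm <- matrix(c(2, 1, 0.5, -1), 2, 2)
  specT <- model_spec(y, W = W %*% Tm, random_effects = list(K))
  fitT <- fit_gls(rotT <- rotate_model(specT, h2))
  expect_equal(profile_loglik(rotT, fitT, "REML"),
               profile_loglik(rot, fit, "REML"), tolerance = 1e-8)
})

test_that("likelihood computations match the dense oracle on small problems", {
  # the module's primary acceptance surface: n <= 50, explicit-V oracle, 1e-6
  set.seed(6)
  for (cfg in list(list(n = 30, L = 1), list(n = 50, L = 2))) {
    n <- cfg$n
    ZKZt <- replicate(cfg$L, random_psd(n), simplify = FALSE)
    y <- rnorm(n)
    W <- cbind(1, rnorm(n))
    X <- matrix(rbinom(n * 2, 2, 0.4), n, 2)
    spec <- model_spec(y, W = W, random_effects = ZKZt)
    for (rep in 1:5) {
      h2 <- runif(cfg$L, 0, 0.4)
      rot <- rotate_model(spec, h2)
      fit <- fit_gls(rot, marker = X)
      expect_equal(profile_loglik(rot, fit, "ML"),
                   oracle_profile(y, W, X, ZKZt, h2, "ML"), tolerance = 1e-6)
      expect_equal(profile_loglik(rot, fit, "REML"),
                   oracle_profile(y, W, X, ZKZt, h2, "REML"), tolerance = 1e-6)
    }
  }
})

test_that("Wald tests reduce to classical identities", {
  set.seed(7)
  n <- 30
  y <- rnorm(n)
  x <- rnorm(n)
  spec <- model_spec(y, random_effects = list())
  fit <- fit_gls(rotate_model(spec, numeric(0)), marker = x)
  # V = I, q = 1: F equals the squared OLS t-statistic
  wt <- wald_test(fit, c(0, 1))
  tstat <- summary(lm(y ~ x))$coefficients[2, 3]
  expect_equal(wt$statistic, tstat^2, tolerance = 1e-10)
  expect_equal(wt$p_value, pf(wt$statistic, 1, n - 2, lower.tail = FALSE))
  # contrast with M theta = 0: F = 0, p = 1
  fit0 <- fit_gls(rotate_model(model_spec(y - mean(y)), numeric(0)))
  M <- matrix(1, 1, 1)
  w0 <- wald_test(fit0, M)
  expect_equal(w0$statistic, 0, tolerance = 1e-20)
  expect_equal(w0$p_value, 1)
})

test_that("likelihood-ratio test matches the classical OLS statistic and calibrates", {
  set.seed(8)
  n <- 50
  y <- rnorm(n)
  x <- rnorm(n)
  spec0 <- model_spec(y)
  specA <- model_spec(y, W = cbind(1, x))
  r0 <- rotate_model(spec0, numeric(0))
  rA <- rotate_model(specA, numeric(0))
  ml0 <- profile_loglik(r0, fit_gls(r0), "ML")
  mlA <- profile_loglik(rA, fit_gls(rA), "ML")
  lrt <- likelihood_ratio_test(ml0, mlA, 1)
  classical <- n * log(sum(resid(lm(y ~ 1))^2) / sum(resid(lm(y ~ x))^2))
  expect_equal(lrt$statistic, classical, tolerance = 1e-8)
  # identical models: statistic 0, p 1
  same <- likelihood_ratio_test(mlA, mlA, 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # null calibration: empirical type-I error at alpha = 0.05 within +/- 0.02
  reject <- logical(1000)
  for (i in 1:1000) {
    yy <- rnorm(100); xx <- rnorm(100)
    rss0 <- sum(resid(lm(yy ~ 1))^2)
    rss1 <- sum(resid(lm(yy ~ xx))^2)
    stat <- 100 * log(rss0 / rss1)
    reject[i] <- pchisq(stat, 1, lower.tail = FALSE) < 0.05
  }
  expect_gt(mean(reject), 0.03)
  expect_lt(mean(reject), 0.07)
})

test_that("rotation succeeds across the whole grid and recovery is consistent", {
  set.seed(9)
  # any vertex with he2 > 0 yields a positive-definite V
  for (i in 1:3) {
    n <- 30
    ZKZt <- list(random_psd(n), random_psd(n))
    spec <- model_spec(rnorm(n), random_effects = ZKZt)
    grid <- build_grid(2, 5)
    for (v in seq_len(grid$g)) expect_silent(rotate_model(spec, grid$h2[v, ]))
  }
  # on average the true generating vertex beats a distant one
  n <- 100
  K <- gxe_kinship(diag(20), rep(as.character(1:20), each = 5))
  rownames(K) <- colnames(K) <- NULL
  spec_tmpl <- NULL
  diffs <- replicate(200, {
    y <- simulate_phenotype(list(K), 0.6)$y
    sp <- model_spec(y, random_effects = list(K))
    rt <- rotate_model(sp, 0.6); rd <- rotate_model(sp, 0.05)
    profile_loglik(rt, fit_gls(rt), "ML") - profile_loglik(rd, fit_gls(rd), "ML")
  })
  expect_gt(mean(diffs), 0)
})
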