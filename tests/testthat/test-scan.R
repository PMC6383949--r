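test_that("association tables handle empty, duplicated and degenerate markers", {
  set.seed(51)
  n <- 60
  K <- random_psd(n)
  y <- rnorm(n)
  spec <- model_spec(y, random_effects = list(K))
  cfg <- scan_config("wald", "full", m = 5, peg = "origin")
  # empty marker set: empty table, no error
  tab0 <- run_association_scan(spec, matrix(numeric(0), n, 0), cfg)
  expect_equal(nrow(tab0), 0)
  expect_true(all(c("marker", "beta", "p", "h2_1", "h2_e", "flag") %in% names(tab0)))
  # duplicated marker: identical rows; constant marker: flagged
  M <- cbind(a = rbinom(n, 2, 0.4), b = rbinom(n, 2, 0.3), c = 2)
  M <- cbind(M, d = M[, "a"])
  tab <- run_association_scan(spec, M, cfg)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$p[1], tab$p[4])
  expect_equal(tab$beta[1], tab$beta[4])
  expect_identical(tab$flag[3], "constant_marker")
  expect_true(is.na(tab$p[3]))
  expect_error(run_association_scan(spec, cbind(rep(1, n)), cfg), "usable")
})

test_that("fine-grid Wald p-values match the exact continuous-REML oracle", {
  # single-random-effect data, step 0.01: -log10(p) within 0.05 of the
  # brute-force exact LMM for every marker (desk-scale version; the full
  # 20-dataset sweep lives in the acceptance suite)
  set.seed(52)
  n <- 100
  G <- simulate_structured_genotypes(n, 80, blocks = 10, seed = 53)
  K <- additive_kinship(G)
  sim <- simulate_phenotype(list(K), 0.4, marker = G[, 5], effect_fraction = 0.05,
                            seed = 54)
  spec <- model_spec(sim$y, random_effects = list(K))
  idx <- c(1, 5, 10, 20, 40)
  M <- G[, idx]; rownames(M) <- NULL
  tab <- run_association_scan(spec, M, scan_config("wald", "full", m = 100,
                                                   peg = "origin"))
  for (j in seq_along(idx)) {
    p_exact <- oracle_exact_p(sim$y, spec$W, M[, j], list(K))
    if (p_exact > 1e-10)
      expect_lt(abs(-log10(tab$p[j]) + log10(p_exact)), 0.05)
  }
})

test_that("fast and full scans agree and the LRT/Bayes paths fill their columns", {
  pop <- make_gxe_population(n_acc = 50, p = 40, seed = 55)
  y <- simulate_phenotype(list(pop$KA, pop$KGxE), c(0.3, 0.3), seed = 56)$y
  spec <- model_spec(y, W = cbind(1, env = pop$env),
                     random_effects = list(pop$KA, pop$KGxE))
  M <- pop$Gx[, pop$poly][, 1:20]
  fast <- run_association_scan(spec, M, scan_config("wald", "fast", m = 10),
                               interaction = pop$env)
  full <- run_association_scan(spec, M, scan_config("wald", "full", m = 10),
                               interaction = pop$env)
  expect_equal(fast$p, full$p, tolerance = 1e-10)
  lrt <- run_association_scan(spec, M, scan_config("lrt", "full", m = 10),
                              interaction = pop$env)
  expect_true(all(lrt$p >= 0 & lrt$p <= 1))
  expect_true(all(lrt$F >= 0))
  bay <- run_association_scan(spec, M, scan_config("bayes", "fast", m = 10),
                              interaction = pop$env)
  expect_true(all(is.finite(bay$log10BF)))
})

test_that("build_gxe_design wires the interaction contrast", {
  set.seed(57)
  n <- 40
  spec <- model_spec(rnorm(n), random_effects = list(random_psd(n)))
  env <- rep(c(1, -1), n / 2)
  marker <- rbinom(n, 2, 0.5)
  d <- build_gxe_design(spec, marker, env)
  expect_equal(unname(d$X[, 2]), marker * env)
  expect_equal(ncol(d$spec$W), 2)
  expect_equal(which(d$M != 0), ncol(d$spec$W) + 2)
  expect_error(build_gxe_design(spec, marker, rep(1, n)), "constant")
  # all observations in one environment after subsetting: rank deficiency
  rot <- rotate_model(d$spec, 0.2)
  fit <- fit_gls(rot)
  expect_null(fit$flag)
})

test_that("a simulated interaction effect is detected on the interaction, not the main term", {
  set.seed(58)
  pop <- make_gxe_population(n_acc = 40, p = 30, seed = 59)
  grid <- build_grid(2, 5)
  p_int <- p_main <- numeric(100)
  for (i in 1:100) {
    mk <- pop$Gx[, sample(which(pop$poly), 1)]
    xs <- as.numeric(scale(mk * pop$env))
    y <- simulate_phenotype(list(pop$KA, pop$KGxE), c(0.3, 0.3), seed = 600 + i)$y +
      sqrt(0.1) * xs
    sp <- model_spec(y, W = cbind(1, env = pop$env),
                     random_effects = list(pop$KA, pop$KGxE))
    tab_i <- run_association_scan(sp, cbind(mk), scan_config("wald", "full", m = 5,
                                                             peg = "origin"),
                                  interaction = pop$env)
    tab_m <- run_association_scan(sp, cbind(mk), scan_config("wald", "full", m = 5,
                                                             peg = "origin"))
    p_int[i] <- tab_i$p[1]
    p_main[i] <- tab_m$p[1]
  }
  expect_lt(mean(-log10(p_main)), mean(-log10(p_int)))
})

test_that("genomic control matches its distributional oracle", {
  set.seed(60)
  draws <- rf(10000, 1, 312)
  lam <- genomic_control(draws, 1, 312)$lambda
  expect_gt(lam, 0.93); expect_lt(lam, 1.07)
  expect_equal(genomic_control(2 * draws, 1, 312)$lambda, 2 * lam)
  gc3 <- genomic_control(c(1, 2, 3), 1, 312)
  expect_equal(gc3$lambda, 2 / qf(0.5, 1, 312))
  expect_equal(gc3$corrected, c(1, 2, 3) / gc3$lambda)
  expect_error(genomic_control(rep(NA_real_, 5), 1, 10), "finite")
})

test_that("variance-component scan recovers truth and flags degenerate traits", {
  set.seed(61)
  # pure-noise traits: residual proportion dominates the posterior mean
  n <- 500
  groups <- rep(as.character(1:100), each = 5)
  Kg <- gxe_kinship(diag(100), groups); rownames(Kg) <- colnames(Kg) <- NULL
  spec <- model_spec(rnorm(n), random_effects = list(Kg))
  noise <- matrix(rnorm(n * 20), n, 20)
  vc0 <- variance_component_scan(noise, spec, m = 10)
  expect_gt(mean(vc0$postmean_h2_e), 0.8)
  # on-grid truth (0.4, 0.2), n = 800, m = 20: REML vertex equals truth for
  # a solid majority of replicates
  n2 <- 800
  G <- simulate_structured_genotypes(160, 300, blocks = 16, seed = 62)
  KA <- gxe_kinship(additive_kinship(G), rep(rownames(G), each = 5))
  Kc <- gxe_kinship(diag(160), rep(as.character(1:160), each = 5))
  rownames(KA) <- colnames(KA) <- rownames(Kc) <- colnames(Kc) <- NULL
  traits <- sapply(1:50, function(i)
    simulate_phenotype(list(KA, Kc), c(0.4, 0.2), seed = 700 + i)$y)
  spec2 <- model_spec(rnorm(n2), random_effects = list(KA, Kc))
  vc <- variance_component_scan(traits, spec2, m = 20)
  # per-replicate REML sd here is ~0.08-0.1 per coordinate, so exact-vertex
  # hits are rare; the estimator must be unbiased and concentrate within two
  # grid steps for most replicates
  expect_lt(abs(mean(vc$reml_h2_1) - 0.4), 0.05)
  expect_lt(abs(mean(vc$reml_h2_2) - 0.2), 0.05)
  hit2 <- abs(vc$reml_h2_1 - 0.4) <= 0.1 + 1e-9 &
    abs(vc$reml_h2_2 - 0.2) <= 0.1 + 1e-9
  expect_gte(mean(hit2), 0.6)
  expect_true(all(vc$p_nonzero_1 >= 0 & vc$p_nonzero_1 <= 1))
  # constant trait flagged; empty trait set allowed
  vc_c <- variance_component_scan(cbind(rep(1, n)), spec, m = 5)
  expect_identical(vc_c$flag[1], "constant_trait")
  expect_equal(nrow(variance_component_scan(matrix(numeric(0), n, 0), spec)), 0)
})
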