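# Shared fixture: two-environment population with additive + GxE random
# effects, no causal marker (unimodal REML surfaces).
pop <- make_gxe_population(n_acc = 60, p = 120, seed = 41)
y_fs <- simulate_phenotype(list(pop$KA, pop$KGxE), c(0.4, 0.4), seed = 42)$y
spec_fs <- model_spec(y_fs, W = cbind(1, env = pop$env),
                      random_effects = list(A = pop$KA, GxE = pop$KGxE))
Mk <- pop$Gx[, pop$poly][, 1:50]
h0_fs <- null_reml_vertex(spec_fs)

test_that("ball and ring geometry match the printed vertex counts", {
  # interior L = 3 ball: 27 vertices including the center
  b3 <- ball_vertices(c(0.2, 0.2, 0.2), 10)
  expect_equal(nrow(b3), 27)
  # interior L = 2 first ring (center excluded): 8 vertices
  r2 <- ball_vertices(c(0.4, 0.3), 10, include_center = FALSE)
  expect_equal(nrow(r2), 8)
  # near a simplex boundary the ball is clipped
  b_edge <- ball_vertices(c(0, 0.3), 10)
  expect_lt(nrow(b_edge), 9)
  expect_true(all(b_edge >= 0))
})

test_that("null REML refinement approaches the continuous optimum", {
  op <- oracle_reml_opt(y_fs, spec_fs$W, NULL, spec_fs$ZKZt)
  expect_lt(max(abs(h0_fs$h2 - op$h2)), 1 / 40 + 1e-8)
  expect_lte(h0_fs$score, op$value + 1e-6)
})

test_that("REML ball search reproduces the full-grid argmax on unimodal data", {
  grid <- build_grid(2, 10, peg = h0_fs$h2)
  gs <- grid_search(spec_fs, grid, markers = Mk, criterion = "REML",
                    interaction = pop$env)
  fs <- reml_ball_search(spec_fs, Mk, m = 10, h0 = h0_fs,
                         interaction = pop$env)
  expect_identical(unname(grid$h2[gs$best_idx, ]), unname(fs$best_vertex))
  expect_equal(unname(fs$best_score), unname(gs$best_score), tolerance = 1e-12)
  # evaluated set is a strict subset of the pegged grid
  expect_lt(nrow(fs$evaluated), grid$g)
  grid_keys <- apply(round(grid$h2 * 1e9) / 1e9, 1, paste, collapse = ",")
  ev_keys <- apply(round(fs$evaluated * 1e9) / 1e9, 1, paste, collapse = ",")
  expect_true(all(ev_keys %in% grid_keys))
  # guaranteed never below the null-vertex score
  rot0 <- rotate_model(spec_fs, h0_fs$h2)
  sc0 <- gridvc:::marker_scores(rot0, Mk, "REML", interaction = pop$env)$score +
    gridvc:::reml_design_logdet(spec_fs, Mk, pop$env)
  expect_true(all(fs$best_score >= sc0 - 1e-12))
  # trace: active set shrinks monotonically
  expect_true(all(diff(fs$trace$n_active) <= 0))
})

test_that("exhaustive ball search equals the full grid bit-for-bit", {
  grid <- build_grid(2, 10, peg = h0_fs$h2)
  gs <- grid_search(spec_fs, grid, markers = Mk, criterion = "REML",
                    interaction = pop$env)
  fse <- reml_ball_search(spec_fs, Mk, m = 10, h0 = h0_fs,
                          interaction = pop$env,
                          settings = search_settings(exhaustive = TRUE))
  expect_equal(nrow(fse$evaluated), grid$g)
  expect_identical(unname(fse$best_score), unname(gs$best_score))
  expect_identical(unname(fse$best_vertex), unname(grid$h2[gs$best_idx, ]))
})

test_that("adaptive posterior search refines sharp posteriors and stops on diffuse ones", {
  set.seed(43)
  groups <- rep(as.character(1:80), each = 5)
  K <- gxe_kinship(diag(80), groups)
  rownames(K) <- colnames(K) <- NULL
  # sharply peaked posterior (n = 400): at least one resolution doubling
  y <- simulate_phenotype(list(K), 0.5, seed = 44)$y
  sp <- model_spec(y, random_effects = list(K))
  ap <- adaptive_posterior_search(sp, m1 = 10)
  expect_gte(ap$final_m, 20)
  # final H covers >= 99% of the estimated mass
  expect_gte(sum(ap$posterior[ap$credible_set]), 0.99)
  # posterior mean matches the full fine grid per coordinate
  g40 <- build_grid(1, 40)
  p40 <- grid_posterior(grid_search(sp, g40, mode = "trait",
                                    criterion = "marginal")$scores[1, ], g40)
  expect_lt(max(abs(ap$posterior_mean_h2 - p40$posterior_mean_h2)), 0.01)
  # diffuse posterior (null data, n = 50, L = 2): terminates unrefined
  y0 <- rnorm(50)
  sp0 <- model_spec(y0, random_effects = list(random_psd(50), random_psd(50)))
  ap0 <- adaptive_posterior_search(sp0, m1 = 10)
  expect_equal(ap0$final_m, 10)
  # non-uniform priors are refused
  expect_error(adaptive_posterior_search(sp0, prior_weights = rep(1 / 55, 55)),
               "uniform")
})

test_that("adaptive means track the fine grid across simulated datasets", {
  set.seed(45)
  groups <- rep(as.character(1:80), each = 5)
  K <- gxe_kinship(diag(80), groups)
  rownames(K) <- colnames(K) <- NULL
  g40 <- build_grid(1, 40)
  for (i in 1:20) {
    y <- simulate_phenotype(list(K), 0.5)$y
    sp <- model_spec(y, random_effects = list(K))
    ap <- adaptive_posterior_search(sp, m1 = 10)
    p40 <- grid_posterior(grid_search(sp, g40, mode = "trait",
                                      criterion = "marginal")$scores[1, ], g40)
    expect_lt(max(abs(ap$posterior_mean_h2 - p40$posterior_mean_h2)), 0.01)
  }
})

test_that("ring search reproduces full-grid Bayes factors and stops early on null markers", {
  grid <- build_grid(2, 10, peg = h0_fs$h2)
  gsm <- grid_search(spec_fs, grid, markers = Mk, criterion = "marginal",
                     interaction = pop$env)
  nullm <- grid_search(spec_fs, grid, mode = "trait",
                       criterion = "marginal")$scores[1, ]
  bf_full <- vapply(seq_len(ncol(Mk)), function(j)
    bayes_factor(gsm$scores[j, ], nullm)$log10_BF, numeric(1))
  bf <- bf_ring_search(spec_fs, Mk, m = 10, h0 = h0_fs, interaction = pop$env)
  expect_lt(max(abs(bf$log10_BF - bf_full)), 0.01)
  # null-effect markers concentrate near h0 (n = 300): every marker hits the
  # 0.01% stopping rule within a few rings, well before the grid is exhausted
  # (the exact ring count tracks the posterior spread, here 2-4)
  pop2 <- make_gxe_population(n_acc = 150, p = 60, seed = 46)
  y2 <- simulate_phenotype(list(pop2$KA, pop2$KGxE), c(0.4, 0.4), seed = 47)$y
  spec2 <- model_spec(y2, W = cbind(1, env = pop2$env),
                      random_effects = list(pop2$KA, pop2$KGxE))
  bf2 <- bf_ring_search(spec2, pop2$Gx[, pop2$poly][, 1:30], m = 10,
                        interaction = pop2$env)
  expect_false(any(bf2$exhausted))
  expect_true(all(is.finite(bf2$stop_ring) & bf2$stop_ring <= 4))
  expect_lt(nrow(bf2$evaluated), build_grid(2, 10)$g)
  # zero stop fraction: every pegged vertex evaluated, exact reproduction
  bf0 <- bf_ring_search(spec_fs, Mk[, 1:8], m = 10, h0 = h0_fs,
                        interaction = pop$env,
                        settings = search_settings(ring_stop = 0))
  expect_equal(nrow(bf0$evaluated), grid$g)
  expect_equal(bf0$log10_BF, bf_full[1:8], tolerance = 1e-12)
})
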