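# Independent dense oracles (explicit V inverses and determinants, numeric
# optimization) and small fixture builders shared across test files. The
# oracles deliberately avoid the package's Cholesky-rotation code path.

# dense ML / REML profile log-likelihood with explicit V
oracle_profile <- function(y, W, X, ZKZt, h2, kind = c("REML", "ML")) {
  kind <- match.arg(kind)
  n <- length(y)
  V <- diag(1 - sum(h2), n)
  for (l in seq_along(ZKZt)) V <- V + h2[l] * ZKZt[[l]]
  Vi <- solve(V)
  D <- cbind(W, X)
  XtVX <- t(D) %*% Vi %*% D
  bh <- solve(XtVX, t(D) %*% Vi %*% y)
  r <- y - D %*% bh
  RSS <- drop(t(r) %*% Vi %*% r)
  ldV <- as.numeric(determinant(V)$modulus)
  k <- ncol(D)
  if (kind == "ML") {
    s2 <- RSS / n
    -0.5 * (n * log(2 * pi * s2) + ldV + n)
  } else {
    s2 <- RSS / (n - k)
    lF <- -0.5 * (n * log(2 * pi * s2) + ldV + RSS / s2)
    lF + 0.5 * (k * log(2 * pi * s2) +
                as.numeric(determinant(crossprod(D))$modulus) -
                as.numeric(determinant(XtVX)$modulus))
  }
}

# dense GLS with explicit V^{-1}
oracle_gls <- function(y, W, X, ZKZt, h2) {
  n <- length(y)
  V <- diag(1 - sum(h2), n)
  for (l in seq_along(ZKZt)) V <- V + h2[l] * ZKZt[[l]]
  Vi <- solve(V)
  D <- cbind(W, X)
  XtVX <- t(D) %*% Vi %*% D
  bh <- drop(solve(XtVX, t(D) %*% Vi %*% y))
  r <- y - D %*% bh
  RSS <- drop(t(r) %*% Vi %*% r)
  list(coef = bh, RSS = RSS, xtx_inv = solve(XtVX),
       sigma2_reml = RSS / (n - ncol(D)))
}

# continuous REML/ML maximization over the simplex (L = 1 or 2), dense path
oracle_reml_opt <- function(y, W, X, ZKZt, kind = "REML") {
  L <- length(ZKZt)
  f <- function(h2) {
    if (any(h2 < 0) || sum(h2) > 0.9999) return(-1e10)
    oracle_profile(y, W, X, ZKZt, h2, kind)
  }
  if (L == 1) {
    op <- stats::optimize(function(h) f(h), c(0, 0.9999), maximum = TRUE,
                          tol = 1e-8)
    list(h2 = op$maximum, value = op$objective)
  } else {
    starts <- list(rep(0.1, L), rep(0.3, L), rep(0.45, L), c(0.7, rep(0.05, L - 1)))
    best <- NULL
    for (s in starts) {
      op <- stats::optim(s, function(h) -f(h), method = "L-BFGS-B",
                         lower = rep(1e-6, L), upper = rep(0.999, L),
                         control = list(factr = 1e4))
      if (is.null(best) || -op$value > best$value)
        best <- list(h2 = op$par, value = -op$value)
    }
    best
  }
}

# exact-LMM Wald p-value for one marker: continuous REML, dense Wald F on
# the final (tested) coefficient
oracle_exact_p <- function(y, W, x, ZKZt, interaction = NULL) {
  X <- if (is.null(interaction)) cbind(x) else cbind(x, x * interaction)
  op <- oracle_reml_opt(y, W, X, ZKZt, "REML")
  g <- oracle_gls(y, W, X, ZKZt, op$h2)
  k <- length(g$coef)
  Fv <- g$coef[k]^2 / (g$sigma2_reml * g$xtx_inv[k, k])
  stats::pf(Fv, 1, length(y) - k, lower.tail = FALSE)
}

# two-environment population with additive + GxE random effects
make_gxe_population <- function(n_acc, p, seed, blocks = 10) {
  G0 <- simulate_structured_genotypes(n_acc, p, blocks = blocks, seed = seed)
  K <- additive_kinship(G0)
  acc <- rep(rownames(G0), each = 2)
  env <- rep(c(-1, 1), n_acc)
  Gx <- G0[acc, , drop = FALSE]
  rownames(Gx) <- NULL
  poly <- apply(G0, 2, stats::var) > 0
  list(G0 = G0, K = K, acc = acc, env = env, Gx = Gx, poly = poly,
       KA = gxe_kinship(K, acc), KGxE = gxe_kinship(K, acc, signs = env))
}

# one-vertex grid (for single-point Bayes-factor comparisons)
build_single_vertex_grid <- function(h2) {
  h2 <- matrix(h2, 1, length(h2),
               dimnames = list(NULL, paste0("h2_", seq_along(h2))))
  structure(list(h2 = h2, he2 = 1 - rowSums(h2), L = ncol(h2), m = NA,
                 peg = NULL, g = 1L),
            class = "vc_grid")
}

# random PSD matrix with unit-ish diagonal
random_psd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * 2 * n), n, 2 * n)
  K <- tcrossprod(A) / (2 * n)
  K / mean(diag(K))
}
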