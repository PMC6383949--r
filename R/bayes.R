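# Bayesian inference on the grid: normal-inverse-gamma marginal likelihoods,
# grid posteriors of variance-component proportions, Bayes factors, and
# discretization of continuous priors onto the grid.

#' Normal-inverse-gamma prior for the fixed effects and scale
#'
#' (theta, sigma^2) ~ NIG(0, Psi, a0, b0): theta | sigma^2 ~ N(0, sigma^2 Psi)
#' and sigma^2 ~ InvGamma(a0, b0). Improper flat components are declared via
#' `improper`: those coordinates get zero prior precision and their (infinite)
#' normalizing constants are dropped; the dropped constants are identical for
#' any two models sharing the same improper components, so Bayes factors
#' remain finite and exact. a0 = b0 = 0 is the improper scale-free limit for
#' sigma^2.
#'
#' @param Psi prior covariance scale of the coefficient vector: a matrix, a
#'   vector of diagonal entries, or a scalar (recycled). Entries on improper
#'   coordinates are ignored.
#' @param a0,b0 inverse-gamma hyperparameters (>= 0; both zero = improper).
#' @param improper logical vector marking flat coefficients (recycled).
#' @return object of class `nig_prior`.
#' @export
nig_prior <- function(Psi = 1, a0 = 0, b0 = 0, improper = FALSE) {
  stopifnot(a0 >= 0, b0 >= 0)
  structure(list(Psi = Psi, a0 = a0, b0 = b0, improper = improper),
            class = "nig_prior")
}

# expand prior to the dimension of the design; returns list(P0 = prior
# precision matrix with zero improper block, logdet_proper = log|Psi_proper|)
expand_prior <- function(prior, k) {
  imp <- rep_len(prior$improper, k)
  Psi <- prior$Psi
  if (is.matrix(Psi)) {
    if (nrow(Psi) != k) stop("Psi dimension does not match design")
  } else {
    Psi <- diag(rep_len(as.numeric(Psi), k), k)
  }
  P0 <- matrix(0, k, k)
  logdet_proper <- 0
  if (any(!imp)) {
    sub <- Psi[!imp, !imp, drop = FALSE]
    P0[!imp, !imp] <- solve(sub)
    logdet_proper <- as.numeric(determinant(sub)$modulus)
  }
  list(P0 = P0, logdet_proper = logdet_proper, improper = imp)
}

#' Log marginal likelihood of the data at one vertex under a NIG prior
#'
#' Integrates the coefficients and sigma^2 out of the whitened model:
#' log p(y | h^2) = -n/2 log(2 pi) - log|L| + 1/2 log|Psi*| - 1/2 log|Psi|
#'   + a0 log b0 - log Gamma(a0) + log Gamma(a*) - a* log b*,
#' with Psi* = (Psi^-1 + X~*'X~*)^-1, a* = a0 + n/2 and
#' b* = b0 + RSS_{y*,Psi}/2. Improper components contribute only constants
#' that cancel in Bayes-factor ratios and are dropped (see [nig_prior()]).
#'
#' @param rot a `rotated_model`.
#' @param prior an `nig_prior`.
#' @param marker optional unrotated extra design columns.
#' @return list of class `nig_posterior`: `log_marginal`, `a_star`, `b_star`,
#'   `theta_star` (posterior mean), `Psi_star_unit` (posterior covariance /
#'   sigma^2).
#' @export
nig_marginal_loglik <- function(rot, prior, marker = NULL) {
  stopifnot(inherits(rot, "rotated_model"), inherits(prior, "nig_prior"))
  spec <- rot$spec
  n <- spec$n
  Dstar <- cbind(rot$Wstar, rot$Xstar)
  if (!is.null(marker)) Dstar <- cbind(Dstar, rotate_columns(rot, marker))
  k <- ncol(Dstar)
  pr <- expand_prior(prior, k)
  Q <- pr$P0 + crossprod(Dstar)
  cq <- tryCatch(chol(Q), error = function(e)
    stop("posterior precision not positive definite (improper prior on a collinear design?)"))
  logdet_Q <- 2 * sum(log(diag(cq)))
  xty <- crossprod(Dstar, rot$ystar)
  theta_star <- backsolve(cq, backsolve(cq, xty, transpose = TRUE))
  rss_psi <- sum(rot$ystar^2) - sum(xty * theta_star)
  rss_psi <- max(rss_psi, 0)
  a_star <- prior$a0 + n / 2
  b_star <- prior$b0 + rss_psi / 2
  if (b_star <= 0) stop("degenerate posterior: b* <= 0 (response in span of design?)")
  const0 <- if (prior$a0 > 0) prior$a0 * log(prior$b0) - lgamma(prior$a0) else 0
  logml <- -n / 2 * log(2 * pi) - rot$logdetL -
    0.5 * logdet_Q - 0.5 * pr$logdet_proper +
    const0 + lgamma(a_star) - a_star * log(b_star)
  structure(list(log_marginal = logml, a_star = a_star, b_star = b_star,
                 rss_psi = rss_psi, theta_star = drop(theta_star),
                 Psi_star_unit = chol2inv(cq)),
            class = "nig_posterior")
}

#' Posterior over the grid from per-vertex log marginal likelihoods
#'
#' Softmax normalization on the log scale (shift-invariant by construction),
#' posterior mean of the proportion vector, and the smallest vertex set
#' covering a requested credible mass.
#'
#' @param log_marginals length-g vector of log p(y | h^2) values.
#' @param grid the `vc_grid` the marginals were computed on.
#' @param prior_weights per-vertex prior probabilities (default uniform);
#'   must sum to one.
#' @param mass credible mass for the reported vertex set (default 0.99).
#' @return object of class `posterior_grid`: `posterior`, `prior_weights`,
#'   `posterior_mean_h2` (length L+1, includes the residual proportion),
#'   `credible_set` (vertex indices), `grid`. Note that with a coarse grid
#'   the *boundaries* of credible sets are not reliable; means and joint
#'   densities are.
#' @export
grid_posterior <- function(log_marginals, grid, prior_weights = NULL,
                           mass = 0.99) {
  g <- length(log_marginals)
  stopifnot(inherits(grid, "vc_grid"), g == grid$g)
  if (is.null(prior_weights)) prior_weights <- rep(1 / g, g)
  if (abs(sum(prior_weights) - 1) > 1e-8) stop("prior weights must sum to 1")
  lp <- log_marginals + ifelse(prior_weights > 0, log(prior_weights), -Inf)
  norm <- logsumexp(lp)
  if (!is.finite(norm)) stop("all log marginal likelihoods are -Inf")
  post <- exp(lp - norm)
  post <- post / sum(post)
  pm <- c(drop(crossprod(grid$h2, post)), sum(grid$he2 * post))
  names(pm) <- c(colnames(grid$h2), "h2_e")
  ord <- order(post, decreasing = TRUE)
  ncover <- which(cumsum(post[ord]) >= mass - 1e-12)[1]
  structure(list(posterior = post, prior_weights = prior_weights,
                 posterior_mean_h2 = pm,
                 credible_set = sort(ord[seq_len(ncover)]),
                 log_normalizer = norm, grid = grid),
            class = "posterior_grid")
}

#' Bayes factor of alternative vs null model averaged over the grid
#'
#' BF = [sum_h2 p(y | h2, alt) p(h2)] / [sum_h2 p(y | h2, null) p(h2)],
#' assembled by log-sum-exp. Both score vectors must come from the same grid
#' and prior; the models must share their improper prior components.
#'
#' @param alt,null length-g vectors of log marginal likelihoods (or
#'   `grid_scores` objects with `criterion == "marginal"`).
#' @param prior_weights per-vertex prior probabilities (default uniform).
#' @return object of class `bayes_factor_result`: `log10_BF`, `log_BF`, and
#'   the two averaged log marginals.
#' @export
bayes_factor <- function(alt, null, prior_weights = NULL) {
  if (inherits(alt, "grid_scores")) alt <- drop(alt$scores)
  if (inherits(null, "grid_scores")) null <- drop(null$scores)
  if (length(alt) != length(null)) stop("alt and null were not computed on the same grid")
  g <- length(alt)
  if (is.null(prior_weights)) prior_weights <- rep(1 / g, g)
  lw <- ifelse(prior_weights > 0, log(prior_weights), -Inf)
  la <- logsumexp(alt + lw)
  ln <- logsumexp(null + lw)
  lbf <- la - ln
  structure(list(log_BF = lbf, log10_BF = lbf / log(10),
                 log_marg_alt = la, log_marg_null = ln),
            class = "bayes_factor_result")
}

#' Discretize a continuous prior over variance-component proportions
#'
#' Two rules are supported. `method = "nearest"` (the Monte-Carlo default)
#' draws from a sampler and assigns each draw to its nearest grid vertex;
#' draws landing outside the simplex (sum of proportions >= 1) are remapped
#' by renormalization and counted. `method = "density"` evaluates a density
#' at each vertex (midpoint rule over the equal-volume grid cells) and
#' normalizes; the two rules differ at simplex boundaries.
#'
#' @param x for "nearest": a function `n -> draws`, returning either an
#'   n x (L+1) matrix of standard deviations (one per variance component plus
#'   the residual, converted to proportions internally) or an n x L matrix of
#'   proportions. For "density": a function `h2 -> density` taking a length-L
#'   vertex.
#' @param grid target `vc_grid`.
#' @param n_draws Monte-Carlo sample size (default 1e4).
#' @param method "nearest" or "density".
#' @param seed optional seed stored with the weights for reproducibility.
#' @return numeric length-g weight vector summing to one, with attributes
#'   `n_remapped` and `seed`.
#' @export
discretize_prior <- function(x, grid, n_draws = 1e4,
                             method = c("nearest", "density"), seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "vc_grid"))
  g <- grid$g
  if (method == "density") {
    w <- apply(grid$h2, 1, x)
    if (any(w < 0) || all(w == 0)) stop("invalid density values")
    w <- w / sum(w)
    attr(w, "n_remapped") <- 0L
    return(w)
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- x(n_draws)
  draws <- as.matrix(draws)
  if (ncol(draws) == grid$L + 1) {            # standard deviations
    v <- draws^2
    draws <- v[, seq_len(grid$L), drop = FALSE] / rowSums(v)
  } else if (ncol(draws) != grid$L) {
    stop("sampler must return L proportions or L+1 standard deviations per draw")
  }
  bad <- rowSums(draws) >= 1 | apply(draws, 1, function(z) any(z < 0))
  n_remapped <- sum(bad)
  if (n_remapped > 0) {
    z <- abs(draws[bad, , drop = FALSE])
    draws[bad, ] <- z / (rowSums(z) + 1e-12) * (1 - 1e-6)
  }
  # nearest vertex by Euclidean distance, computed blockwise
  counts <- integer(g)
  sq_g <- rowSums(grid$h2^2)
  bs <- 2000L
  for (start in seq(1, n_draws, by = bs)) {
    idx <- start:min(start + bs - 1L, n_draws)
    D <- draws[idx, , drop = FALSE]
    aff <- D %*% t(grid$h2) -
      matrix(0.5 * sq_g, length(idx), g, byrow = TRUE)
    nearest <- max.col(aff, ties.method = "first")
    counts <- counts + tabulate(nearest, nbins = g)
  }
  w <- counts / sum(counts)
  attr(w, "n_remapped") <- n_remapped
  attr(w, "seed") <- seed
  w
}

#' Serialize a posterior grid as delimited text
#'
#' One row per vertex: the h^2 coordinates, residual proportion, prior and
#' posterior mass, at 17 significant digits.
#'
#' @param post a `posterior_grid`.
#' @param path output file.
#' @export
write_posterior <- function(post, path) {
  stopifnot(inherits(post, "posterior_grid"))
  grid <- post$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(colnames(grid$h2), "h2_e", "prior", "posterior"),
                   collapse = "\t"), con)
  for (i in seq_len(grid$g))
    writeLines(paste(fmt17(c(grid$h2[i, ], grid$he2[i], post$prior_weights[i],
                             post$posterior[i])), collapse = "\t"), con)
  invisible(path)
}
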