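# Conditional linear-model algebra at a fixed variance-component-proportion
# vertex: covariance assembly V = sum_l h_l^2 Z_l K_l Z_l' + h_e^2 I, its
# Cholesky rotation, GLS fitting, ML/REML profile likelihoods, and Wald /
# likelihood-ratio tests. All likelihoods are natural-log. Triangular solves
# are used throughout; explicit inverses appear only in test oracles.

#' Construct a mixed-model specification
#'
#' Bundles the response, fixed-effect designs and random-effect covariance
#' structures. Random-effect terms are supplied either as an n x n
#' observation-level covariance (incidence Z = I implied) or as
#' `list(K = <r x r>, Z = <n x r>)` / `list(K =, groups =, signs =)`; in all
#' cases the expanded observation-level covariance Z K Z' is precomputed once
#' and reused for every grid vertex.
#'
#' @param y length-n numeric response, no missing values.
#' @param W n x c covariate design including the intercept; defaults to an
#'   intercept-only column. Must be full column rank.
#' @param X optional n x p design of focal (marker) effects.
#' @param random_effects named list of random-effect terms (see above);
#'   length L, may be empty (pure iid model).
#' @return object of class `lmm_spec` with elements `y`, `W`, `X`, `ZKZt`
#'   (list of expanded covariances), and counts `n`, `c`, `p`, `L`.
#' @export
model_spec <- function(y, W = NULL, X = NULL, random_effects = list()) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("response contains missing values")
  if (is.null(W)) W <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  W <- as.matrix(W)
  if (nrow(W) != n) stop("W has wrong number of rows")
  if (anyNA(W)) stop("W contains missing values")
  if (qr(W)$rank < ncol(W)) stop("W is not full column rank")
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("X has wrong number of rows")
    if (anyNA(X)) stop("X contains missing values")
  }
  ZKZt <- lapply(random_effects, function(re) {
    if (is.matrix(re)) {
      if (nrow(re) != n || ncol(re) != n)
        stop("matrix random effect must be n x n (observation-level covariance)")
      return(re)
    }
    if (!is.list(re) || is.null(re$K)) stop("random effect must be a matrix or list(K=, Z=/groups=)")
    K <- as.matrix(re$K)
    if (!is.null(re$Z)) {
      Z <- as.matrix(re$Z)
    } else if (!is.null(re$groups)) {
      Z <- incidence_matrix(re$groups, levels = rownames(K))
    } else {
      if (nrow(K) != n) stop("random effect K is not n x n and no Z/groups given")
      Z <- diag(n)
    }
    if (nrow(Z) != n || ncol(Z) != nrow(K)) stop("incidence/covariance dimensions inconsistent")
    if (!is.null(re$signs)) {
      if (length(re$signs) != n || !all(re$signs %in% c(-1, 1)))
        stop("signs must be length-n +/-1")
      Z <- re$signs * Z
    }
    Z %*% K %*% t(Z)
  })
  structure(list(y = y, W = W, X = X, ZKZt = ZKZt,
                 n = n, c = ncol(W), p = if (is.null(X)) 0L else ncol(X),
                 L = length(ZKZt)),
            class = "lmm_spec")
}

#' A vertex on the variance-component-proportion simplex
#'
#' @param h2 length-L vector of variance-component proportions, all >= 0 with
#'   sum strictly below 1; the residual proportion is `1 - sum(h2)`.
#' @return numeric vector of class `grid_vertex` with attribute `he2`.
#' @export
grid_vertex <- function(h2) {
  h2 <- as.numeric(h2)
  if (any(h2 < 0)) stop("variance-component proportions must be non-negative")
  he2 <- 1 - sum(h2)
  if (he2 <= 0) stop("residual proportion must be strictly positive (sum(h2) < 1)")
  structure(h2, he2 = he2, class = "grid_vertex")
}

# assemble V at a vertex from the cached expanded covariances
assemble_V <- function(spec, h2) {
  he2 <- 1 - sum(h2)
  V <- diag(he2, spec$n)
  for (l in seq_len(spec$L)) if (h2[l] != 0) V <- V + h2[l] * spec$ZKZt[[l]]
  V
}

#' Cholesky rotation of the model at a vertex
#'
#' Assembles V = sum_l h_l^2 Z_l K_l Z_l' + h_e^2 I, computes its lower
#' Cholesky factor L (V = L L') once, and whitens the response and designs by
#' triangular solves: y* = L^-1 y etc. The rotation is reusable for any
#' additional marker columns rotated later with [rotate_columns()].
#'
#' @param spec an `lmm_spec`.
#' @param h2 vertex (plain numeric vector or [grid_vertex()]), length L.
#' @return object of class `rotated_model`: the upper Cholesky factor `U`
#'   (L = t(U)), `logdetL` = sum(log(diag(U))), whitened `ystar`, `Wstar`,
#'   `Xstar`, the vertex, and the originating spec.
#' @export
rotate_model <- function(spec, h2) {
  stopifnot(inherits(spec, "lmm_spec"))
  h2 <- as.numeric(h2)
  if (length(h2) != spec$L) stop("vertex length does not match number of random effects")
  h2[h2 < 0 & h2 > -1e-10] <- 0       # tolerate floating-point dust
  if (any(h2 < 0) || sum(h2) >= 1)
    stop("invalid vertex (", paste(h2, collapse = ","), "): need h2 >= 0 and sum < 1")
  V <- assemble_V(spec, h2)
  U <- tryCatch(chol(V), error = function(e)
    stop(sprintf("Cholesky failed at vertex (%s): %s",
                 paste(format(h2), collapse = ","), conditionMessage(e))))
  rot <- list(spec = spec, h2 = h2, he2 = 1 - sum(h2),
              U = U, logdetL = sum(log(diag(U))),
              ystar = backsolve(U, spec$y, transpose = TRUE),
              Wstar = backsolve(U, spec$W, transpose = TRUE),
              Xstar = if (is.null(spec$X)) NULL else backsolve(U, spec$X, transpose = TRUE))
  class(rot) <- "rotated_model"
  rot
}

#' Whiten additional columns with an existing rotation
#'
#' @param rot a `rotated_model`.
#' @param M n x k matrix of columns to rotate (e.g. marker dosages).
#' @return L^-1 M, computed by a triangular solve.
#' @export
rotate_columns <- function(rot, M) {
  backsolve(rot$U, as.matrix(M), transpose = TRUE)
}

#' Generalized least squares at a vertex
#'
#' Ordinary least squares on the whitened data, i.e. GLS on the original
#' scale. Marker columns may be passed unrotated (`marker`) and are whitened
#' with the stored rotation. Rank-deficient combined designs are returned as
#' a flagged fit (consumed upstream as a skipped test), never as a silent
#' pseudo-inverse.
#'
#' @param rot a `rotated_model`.
#' @param marker optional n x k matrix of additional (unrotated) focal
#'   columns appended to the design.
#' @return object of class `gls_fit` holding coefficient estimates, `RSS`,
#'   ML and REML scale estimates (`RSS/n` and `RSS/(n-c-p)`), the unit
#'   coefficient covariance `xtx_inv` = (X~*' X~*)^-1, and the log
#'   determinants needed by [profile_loglik()].
#' @export
fit_gls <- function(rot, marker = NULL) {
  stopifnot(inherits(rot, "rotated_model"))
  spec <- rot$spec
  n <- spec$n
  Dstar <- cbind(rot$Wstar, rot$Xstar)
  D <- cbind(spec$W, spec$X)
  if (!is.null(marker)) {
    marker <- as.matrix(marker)
    Dstar <- cbind(Dstar, rotate_columns(rot, marker))
    D <- cbind(D, marker)
  }
  k <- ncol(Dstar)
  qa <- qr(Dstar)
  if (qa$rank < k) {
    return(structure(list(flag = "rank_deficient", n = n, k = k,
                          c = spec$c, p = k - spec$c),
                     class = "gls_fit"))
  }
  coef <- qr.coef(qa, rot$ystar)
  res <- qr.resid(qa, rot$ystar)
  RSS <- sum(res^2)
  R <- qr.R(qa)[seq_len(k), seq_len(k), drop = FALSE]
  # undo any column pivoting before inverting R'R
  piv <- qa$pivot
  xtx_inv <- chol2inv(R)[order(piv), order(piv), drop = FALSE]
  logdet_xtx_star <- 2 * sum(log(abs(diag(R))))
  logdet_xtx <- as.numeric(determinant(crossprod(D), logarithm = TRUE)$modulus)
  structure(list(flag = NULL,
                 coef = coef,
                 alpha_hat = coef[seq_len(spec$c)],
                 beta_hat = if (k > spec$c) coef[(spec$c + 1):k] else numeric(0),
                 RSS = RSS,
                 sigma2_ml = RSS / n,
                 sigma2_reml = RSS / (n - k),
                 xtx_inv = xtx_inv,
                 logdet_xtx_star = logdet_xtx_star,
                 logdet_xtx = logdet_xtx,
                 n = n, k = k, c = spec$c, p = k - spec$c,
                 logdetL = rot$logdetL),
            class = "gls_fit")
}

#' ML / REML profile log-likelihood at a vertex
#'
#' ML: (n/2) * (log(n / (2 pi)) - 1 - log RSS) - log|L|.
#' REML adds the restricted-likelihood correction
#' 1/2 * (log|X~'X~| - log|X~*'X~*|) and replaces n by the residual degrees
#' of freedom n - c - p, i.e. the criterion profiled at
#' sigma2_REML = RSS / (n - c - p).
#'
#' @param rot the rotation the fit was computed on.
#' @param fit a `gls_fit` from [fit_gls()].
#' @param kind "REML" or "ML".
#' @return scalar profile log-likelihood; `-Inf` (with attribute
#'   `flag = "zero_rss"`) when RSS underflows to zero.
#' @export
profile_loglik <- function(rot, fit, kind = c("REML", "ML")) {
  kind <- match.arg(kind)
  if (!is.null(fit$flag) && identical(fit$flag, "rank_deficient"))
    stop("cannot profile a rank-deficient fit")
  n <- fit$n
  if (fit$RSS <= 0)
    return(structure(-Inf, flag = "zero_rss"))
  if (kind == "ML") {
    n / 2 * (log(n / (2 * pi)) - 1 - log(fit$RSS)) - rot$logdetL
  } else {
    nu <- n - fit$k
    nu / 2 * (log(nu / (2 * pi)) - 1 - log(fit$RSS)) - rot$logdetL +
      0.5 * (fit$logdet_xtx - fit$logdet_xtx_star)
  }
}

#' Wald F-test of a linear contrast
#'
#' F = (M theta)' (M (X~' V^-1 X~)^-1 M')^-1 (M theta) / (q sigma2_REML),
#' referred to an F distribution with q and df2 = n - c - p degrees of
#' freedom. The fit should come from the REML-best vertex.
#'
#' @param fit a `gls_fit`.
#' @param M q x (c+p) contrast matrix with independent rows.
#' @param df2 denominator degrees of freedom (default n - c - p).
#' @return list of class `test_result`: `statistic`, `df1`, `df2`, `p_value`,
#'   `flag`.
#' @export
wald_test <- function(fit, M, df2 = NULL) {
  if (!is.null(fit$flag)) {
    return(structure(list(statistic = NA_real_, df1 = NA, df2 = NA,
                          p_value = NA_real_, flag = fit$flag),
                     class = "test_result"))
  }
  M <- matrix(M, ncol = fit$k)
  q <- nrow(M)
  df2 <- df2 %||% (fit$n - fit$k)
  mt <- drop(M %*% fit$coef)
  mid <- M %*% fit$xtx_inv %*% t(M)
  sol <- tryCatch(solve(mid, mt), error = function(e) NULL)
  if (is.null(sol)) {
    return(structure(list(statistic = NA_real_, df1 = q, df2 = df2,
                          p_value = NA_real_, flag = "singular_contrast"),
                     class = "test_result"))
  }
  stat <- sum(mt * sol) / (q * fit$sigma2_reml)
  structure(list(statistic = stat, df1 = q, df2 = df2,
                 p_value = stats::pf(stat, q, df2, lower.tail = FALSE),
                 flag = NULL),
            class = "test_result")
}

#' Likelihood-ratio test from two ML profile log-likelihoods
#'
#' @param ml_null,ml_alt ML (not REML) profile log-likelihoods of nested
#'   models, each maximized over its own grid.
#' @param df difference in number of tested parameters (chi-square df).
#' @return `test_result` with the chi-square statistic (clamped at zero; a
#'   negative value beyond 1e-6 records a `grid_coarseness` warning flag).
#' @export
likelihood_ratio_test <- function(ml_null, ml_alt, df) {
  stat <- 2 * (ml_alt - ml_null)
  flag <- NULL
  if (stat < -1e-6) {
    warning("alternative log-likelihood below null beyond tolerance; grid may be too coarse")
    flag <- "grid_coarseness"
  }
  stat <- max(stat, 0)
  structure(list(statistic = stat, df1 = df, df2 = Inf,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 flag = flag),
            class = "test_result")
}
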