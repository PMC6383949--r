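# Simplex grid over variance-component proportions and the full
# (non-heuristic) grid search, reusing one Cholesky rotation per vertex
# across all markers or traits.

#' Number of vertices of a complete simplex grid
#'
#' Counts the step-1/m lattice vectors (h_1^2, ..., h_L^2) with all
#' proportions >= 0 and sum < 1 (origin included):
#' g = sum_{k=1}^{L} C(m, k) C(L-1, k-1), which equals C(m+L-1, L).
#'
#' @param L number of random effects (>= 1).
#' @param m divisions per proportion (step 1/m, >= 1).
#' @return integer vertex count.
#' @export
grid_size <- function(L, m) {
  stopifnot(L >= 1, m >= 1)
  k <- seq_len(L)
  sum(choose(m, k) * choose(L - 1, k - 1))
}

# recursive lexicographic enumeration of lattice points with sum < 1,
# given per-dimension candidate values (each sorted ascending)
enumerate_simplex <- function(values, prefix_sum = 0) {
  if (length(values) == 0L) return(matrix(numeric(0), 1, 0))
  v <- values[[1]]
  v <- v[prefix_sum + v < 1 - 1e-9]
  if (length(v) == 0L) return(matrix(numeric(0), 0, length(values)))
  out <- lapply(v, function(x) {
    rest <- enumerate_simplex(values[-1], prefix_sum + x)
    cbind(rep(x, nrow(rest)), rest)
  })
  do.call(rbind, out)
}

#' Build a simplex grid of variance-component proportions
#'
#' A rectangular grid with resolution 1/m over the L proportions, restricted
#' to h_l^2 >= 0 and sum(h^2) < 1 (so the residual proportion is strictly
#' positive and V is positive definite at every vertex). The grid is pegged
#' either to the origin (default: plain lattice {0, 1/m, ...}) or to an
#' arbitrary interior vertex such as the null-model REML estimate, in which
#' case the lattice is translated so one vertex coincides with the peg and
#' out-of-simplex vertices are clipped. Vertex order is deterministic
#' (lexicographic in (h_1^2, ..., h_L^2)).
#'
#' @param L number of random effects.
#' @param m divisions per proportion.
#' @param peg optional length-L vertex the grid is translated to contain.
#' @return object of class `vc_grid`: `h2` (g x L matrix), `he2`, `L`, `m`,
#'   `peg`.
#' @export
build_grid <- function(L, m, peg = NULL) {
  stopifnot(L >= 1, m >= 1)
  step <- 1 / m
  if (is.null(peg)) {
    vals <- replicate(L, seq(0, (m - 1) * step, by = step), simplify = FALSE)
  } else {
    peg <- as.numeric(peg)
    if (length(peg) != L) stop("peg has wrong length")
    if (any(peg < 0) || sum(peg) >= 1) stop("peg vertex outside the simplex")
    vals <- lapply(peg, function(pl) {
      off <- pl - floor(pl / step + 1e-9) * step
      # snap floating-point dust so no coordinate dips below zero
      if (off < 1e-9 || step - off < 1e-9) off <- 0
      seq(off, 1 - 1e-9, by = step)
    })
  }
  h2 <- enumerate_simplex(vals)
  # canonical float representation (shared with the heuristic searches) so
  # identical nominal vertices are bit-identical across construction paths
  h2 <- round(h2 * 1e9) / 1e9
  colnames(h2) <- paste0("h2_", seq_len(L))
  structure(list(h2 = h2, he2 = 1 - rowSums(h2), L = L, m = m, peg = peg,
                 g = nrow(h2)),
            class = "vc_grid")
}

#' @export
print.vc_grid <- function(x, ...) {
  cat(sprintf("simplex grid: L = %d random effects, step 1/%d, %d vertices%s\n",
              x$L, x$m, x$g,
              if (is.null(x$peg)) " (origin-pegged)"
              else sprintf(" (pegged at %s)", paste(format(x$peg), collapse = ", "))))
  invisible(x)
}

#' Full grid search over many tests
#'
#' Evaluates the chosen criterion at every grid vertex for every test,
#' performing exactly one Cholesky rotation per vertex regardless of the
#' number of tests. In `mode = "marker"` each test augments the covariate
#' design with one marker column (plus its environment interaction when
#' `interaction` is given); in `mode = "trait"` each column of `traits` is
#' scored against the null (covariate-only) model, sharing rotations across
#' traits.
#'
#' @param spec an `lmm_spec`; its `X` slot must be NULL (focal columns come
#'   from `markers`).
#' @param grid a `vc_grid` with `grid$L == spec$L`.
#' @param markers n x p matrix of marker dosages (marker mode).
#' @param criterion "REML", "ML" (profile log-likelihoods) or "marginal"
#'   (log marginal likelihood under the NIG prior in `prior`).
#' @param mode "marker" or "trait".
#' @param traits n x T matrix of responses for trait mode (defaults to
#'   `spec$y` as a single trait).
#' @param interaction optional length-n +/-1 environment vector; each marker
#'   contributes columns (x, x * env) and the tested contrast is the
#'   interaction column.
#' @param prior marker-effect prior variance (relative to sigma^2) for
#'   `criterion = "marginal"`; covariates get improper flat priors and
#'   sigma^2 the improper limit a0 = b0 = 0.
#' @return object of class `grid_scores`: `scores` (tests x g matrix),
#'   `best_idx`, `best_score`, per-test statistics at the best vertex
#'   (`stats`), the grid, and `n_chol` (the rotation count audit).
#' @export
grid_search <- function(spec, grid, markers = NULL,
                        criterion = c("REML", "ML", "marginal"),
                        mode = c("marker", "trait"),
                        traits = NULL, interaction = NULL, prior = 1) {
  criterion <- match.arg(criterion)
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "lmm_spec"), inherits(grid, "vc_grid"))
  if (grid$L != spec$L) stop("grid dimension does not match number of random effects")
  if (!is.null(spec$X)) stop("supply focal columns via `markers`, not spec$X")
  if (mode == "marker") {
    if (is.null(markers)) stop("marker mode requires a marker matrix")
    markers <- as.matrix(markers)
    if (nrow(markers) != spec$n) stop("markers do not align with spec samples")
    tests <- colnames(markers) %||% paste0("m", seq_len(ncol(markers)))
    ntest <- ncol(markers)
  } else {
    traits <- if (is.null(traits)) matrix(spec$y, ncol = 1) else as.matrix(traits)
    if (nrow(traits) != spec$n) stop("traits do not align with spec samples")
    tests <- colnames(traits) %||% paste0("t", seq_len(ncol(traits)))
    ntest <- ncol(traits)
  }
  g <- grid$g
  if (ntest == 0L) {
    return(structure(list(tests = character(0),
                          scores = matrix(numeric(0), 0, g),
                          best_idx = integer(0), best_score = numeric(0),
                          stats = NULL, grid = grid, criterion = criterion,
                          n_chol = 0L),
                     class = "grid_scores"))
  }
  cap <- getOption("gridvc.score_cap", 5e7)
  if (as.double(g) * max(ntest, 1) > cap)
    stop("score matrix would exceed the memory cap (see options(gridvc.score_cap=))")
  scores <- matrix(-Inf, max(ntest, 1), g, dimnames = list(tests, NULL))
  # vertex-constant REML term 0.5*log|X~'X~| of the *unrotated* design,
  # added back so reported scores equal the full REML profile values
  adjust <- if (criterion == "REML") {
    if (mode == "marker") reml_design_logdet(spec, markers, interaction)
    else rep(0.5 * as.numeric(determinant(crossprod(spec$W))$modulus), ntest)
  } else rep(0, max(ntest, 1))
  n_chol <- 0L
  best_idx <- rep(1L, max(ntest, 1))
  best_score <- rep(-Inf, max(ntest, 1))
  stats <- NULL
  for (v in seq_len(g)) {
    rot <- rotate_model(spec, grid$h2[v, ])
    n_chol <- n_chol + 1L
    sc <- if (mode == "marker") {
      marker_scores(rot, markers, criterion, interaction = interaction,
                    prior = prior)
    } else {
      trait_scores(rot, traits, criterion, prior = prior)
    }
    sc$score <- sc$score + adjust
    scores[, v] <- sc$score
    imp <- which(sc$score > best_score + 1e-12)
    if (v == 1L) imp <- seq_len(nrow(scores))
    if (length(imp)) {
      best_score[imp] <- sc$score[imp]
      best_idx[imp] <- v
      if (!is.null(sc$stats)) {
        if (is.null(stats)) stats <- sc$stats
        else stats[imp, ] <- sc$stats[imp, , drop = FALSE]
      }
    }
  }
  if (ntest == 0L) {
    scores <- scores[0, , drop = FALSE]
    best_idx <- integer(0); best_score <- numeric(0)
  }
  structure(list(tests = tests[seq_len(ntest)], scores = scores,
                 best_idx = best_idx, best_score = best_score,
                 stats = stats, grid = grid, criterion = criterion,
                 n_chol = n_chol),
            class = "grid_scores")
}

# 0.5*log|X~'X~| of the unrotated per-marker design [W, x] or [W, x, x*env];
# constant across vertices, needed to turn relative REML scores into full
# REML profile values.
reml_design_logdet <- function(spec, markers, interaction = NULL) {
  qa0 <- qr(spec$W)
  ld_W <- 2 * sum(log(abs(diag(qr.R(qa0)))))
  Mt <- qr.resid(qa0, markers)
  if (is.null(interaction)) {
    g11 <- colSums(Mt^2)
    0.5 * (ld_W + log(pmax(g11, .Machine$double.xmin)))
  } else {
    Et <- qr.resid(qa0, markers * interaction)
    d2 <- colSums(Mt^2) * colSums(Et^2) - colSums(Mt * Et)^2
    0.5 * (ld_W + log(pmax(d2, .Machine$double.xmin)))
  }
}

# --- vectorized per-vertex scoring -----------------------------------------
#
# All per-test quantities at one vertex are computed with dense matrix ops:
# markers are whitened in one triangular solve, residualized against the
# whitened covariates via one QR, and the 1x1 or 2x2 per-marker normal
# equations are solved in vector arithmetic. This is what makes one rotation
# per vertex serve tens of thousands of tests.

# scores and per-test statistics for marker tests at one vertex.
# Returns list(score, stats) where stats has columns:
# beta (tested effect), invg (unit variance of tested effect), RSS, k,
# logdet_xtx_star, rank_ok.
marker_scores <- function(rot, markers, criterion, interaction = NULL,
                          prior = 1) {
  spec <- rot$spec
  n <- spec$n
  A <- rot$Wstar
  qa <- qr(A)
  r0 <- qr.resid(qa, rot$ystar)
  RSS0 <- sum(r0^2)
  logdet_AtA <- 2 * sum(log(abs(diag(qr.R(qa)))))
  Mstar <- backsolve(rot$U, markers, transpose = TRUE)
  Mt <- qr.resid(qa, Mstar)
  p <- ncol(markers)
  tol <- 1e-10
  if (is.null(interaction)) {
    g11 <- colSums(Mt^2)
    rank_ok <- g11 > tol * pmax(colSums(Mstar^2), 1)
    g11safe <- ifelse(rank_ok, g11, 1)
    u1 <- as.numeric(crossprod(Mt, r0))
    quad <- u1^2 / g11safe
    RSS <- pmax(RSS0 - quad, 0)
    beta <- u1 / g11safe
    invg <- 1 / g11safe
    k <- ncol(A) + 1L
    logdet_extra <- log(g11safe)
    ridge <- g11 + 1 / prior
    RSSp <- pmax(RSS0 - u1^2 / ridge, 0)
    logdet_Q_extra <- log(ridge)
    q_m <- 1L
  } else {
    E <- markers * interaction
    Estar <- backsolve(rot$U, E, transpose = TRUE)
    Et <- qr.resid(qa, Estar)
    g11 <- colSums(Mt^2); g22 <- colSums(Et^2); g12 <- colSums(Mt * Et)
    det2 <- g11 * g22 - g12^2
    rank_ok <- det2 > tol * pmax(g11 * g22, 1)
    detsafe <- ifelse(rank_ok, det2, 1)
    u1 <- as.numeric(crossprod(Mt, r0))
    u2 <- as.numeric(crossprod(Et, r0))
    quad <- (g22 * u1^2 - 2 * g12 * u1 * u2 + g11 * u2^2) / detsafe
    RSS <- pmax(RSS0 - quad, 0)
    beta <- (-g12 * u1 + g11 * u2) / detsafe      # interaction coefficient
    invg <- g11 / detsafe                         # its unit variance
    k <- ncol(A) + 2L
    logdet_extra <- log(detsafe)
    # ridge for the NIG marginal: prior precision 1/prior on both columns
    a11 <- g11 + 1 / prior; a22 <- g22 + 1 / prior
    detp <- a11 * a22 - g12^2
    quadp <- (a22 * u1^2 - 2 * g12 * u1 * u2 + a11 * u2^2) / detp
    RSSp <- pmax(RSS0 - quadp, 0)
    logdet_Q_extra <- log(detp)
    q_m <- 2L
  }
  score <- switch(criterion,
    ML = {
      s <- n / 2 * (log(n / (2 * pi)) - 1 - log(RSS)) - rot$logdetL
      ifelse(rank_ok & RSS > 0, s, -Inf)
    },
    REML = {
      nu <- n - k
      s <- nu / 2 * (log(nu / (2 * pi)) - 1 - log(RSS)) - rot$logdetL -
        0.5 * (logdet_AtA + logdet_extra)
      ifelse(rank_ok & RSS > 0, s, -Inf)
    },
    marginal = {
      s <- -n / 2 * log(2 * pi) - rot$logdetL -
        0.5 * (logdet_AtA + logdet_Q_extra) - 0.5 * q_m * log(prior) +
        lgamma(n / 2) - n / 2 * log(RSSp / 2)
      ifelse(rank_ok & RSSp > 0, s, -Inf)
    })
  # REML criterion drops the vertex-constant unrotated-design determinant
  # 0.5*log|X~'X~|: it cancels in every within-marker comparison.
  score <- unname(score)
  stats <- cbind(beta = ifelse(rank_ok, beta, NA_real_),
                 invg = ifelse(rank_ok, invg, NA_real_),
                 RSS = ifelse(rank_ok, RSS, NA_real_),
                 RSSp = ifelse(rank_ok, RSSp, NA_real_),
                 k = k, rank_ok = as.numeric(rank_ok))
  list(score = score, stats = stats, RSS0 = RSS0, logdet_AtA = logdet_AtA)
}

# trait-mode scores at one vertex: each trait regressed on W only
trait_scores <- function(rot, traits, criterion, prior = 1) {
  spec <- rot$spec
  n <- spec$n
  A <- rot$Wstar
  qa <- qr(A)
  Ystar <- backsolve(rot$U, traits, transpose = TRUE)
  Rres <- qr.resid(qa, Ystar)
  RSS <- colSums(Rres^2)
  logdet_AtA <- 2 * sum(log(abs(diag(qr.R(qa)))))
  k <- ncol(A)
  score <- switch(criterion,
    ML = n / 2 * (log(n / (2 * pi)) - 1 - log(RSS)) - rot$logdetL,
    REML = {
      nu <- n - k
      nu / 2 * (log(nu / (2 * pi)) - 1 - log(RSS)) - rot$logdetL -
        0.5 * logdet_AtA
    },
    marginal = -n / 2 * log(2 * pi) - rot$logdetL - 0.5 * logdet_AtA +
      lgamma(n / 2) - n / 2 * log(RSS / 2))
  score[RSS <= 0] <- -Inf
  list(score = unname(score), stats = NULL)
}
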