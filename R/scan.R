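# Genome-wide association scans, multi-trait variance-component estimation,
# G-by-E designs, and genomic-control calibration diagnostics.

#' Configuration of an association scan
#'
#' @param method "wald" (REML grid + Wald F), "lrt" (ML grid + likelihood
#'   ratio) or "bayes" (NIG marginal likelihoods + Bayes factors).
#' @param search "fast" (accelerated ball/ring search pegged at the null
#'   REML estimate) or "full" (complete grid).
#' @param m grid resolution (divisions per proportion; the production-scale
#'   default is 100, i.e. step 0.01).
#' @param peg "null" (peg the grid at the null-model REML estimate) or
#'   "origin".
#' @param prior marker-effect prior variance relative to sigma^2 (bayes).
#' @param genomic_control also report the genomic-control inflation factor
#'   (reporting only: stored p-values are never silently corrected).
#' @param threshold genome-wide significance threshold (Bonferroni-style);
#'   default 2e-7.
#' @param standardize standardize marker dosages before testing? Default
#'   FALSE (effects stay on the dosage scale).
#' @param settings a [search_settings()] for the fast searches.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(method = c("wald", "lrt", "bayes"),
                        search = c("fast", "full"), m = 100,
                        peg = c("null", "origin"), prior = 1,
                        genomic_control = FALSE, threshold = 2e-7,
                        standardize = FALSE,
                        settings = search_settings()) {
  method <- match.arg(method)
  search <- match.arg(search)
  peg <- match.arg(peg)
  stopifnot(threshold > 0, threshold < 1, m >= 1)
  structure(list(method = method, search = search, m = m, peg = peg,
                 prior = prior, genomic_control = genomic_control,
                 threshold = threshold, standardize = standardize,
                 settings = settings),
            class = "scan_config")
}

#' Genome-wide single-marker association scan
#'
#' Tests every marker column against the null covariate model, re-estimating
#' the variance-component proportions per marker on the grid. With
#' `interaction` supplied, each marker contributes a main effect plus a
#' marker-by-environment column and only the interaction is tested (q = 1).
#' Markers failing rank or variance checks yield NA-flagged rows rather than
#' aborting the scan.
#'
#' @param spec null-model `lmm_spec` (no X; the environment main effect, if
#'   any, belongs in W).
#' @param markers n x p dosage matrix aligned to spec samples.
#' @param config a [scan_config()].
#' @param interaction optional length-n +/-1 environment vector.
#' @param marker_info optional data.frame with columns `chrom`, `pos` (rownames
#'   or order matching marker columns).
#' @return data.frame of class `association_table` with the fixed column set
#'   marker, chrom, pos, beta, se, F, df1, df2, p, h2_1..h2_L, h2_e, logREML,
#'   log10BF, flag.
#' @export
run_association_scan <- function(spec, markers, config = scan_config(),
                                 interaction = NULL, marker_info = NULL) {
  stopifnot(inherits(spec, "lmm_spec"), inherits(config, "scan_config"))
  markers <- as.matrix(markers)
  if (nrow(markers) != spec$n) stop("markers do not align with spec samples")
  p <- ncol(markers)
  labels <- colnames(markers) %||% paste0("m", seq_len(p))
  if (p == 0L) return(empty_association_table(spec$L))
  usable <- apply(markers, 2, function(x) stats::var(x) > 0)
  if (!any(usable)) stop("zero usable markers (all constant)")
  if (config$standardize) {
    markers[, usable] <- scale(markers[, usable, drop = FALSE])
  }
  L <- spec$L
  criterion <- switch(config$method, wald = "REML", lrt = "ML", bayes = "marginal")
  Msub <- markers[, usable, drop = FALSE]
  if (config$search == "fast") {
    if (config$method == "bayes") {
      res <- bf_ring_search(spec, Msub, m = config$m, settings = config$settings,
                            prior = config$prior, interaction = interaction)
      best_i <- apply(res$alt_logml, 1, which.max)
      best_vertex <- res$evaluated[best_i, , drop = FALSE]
      best_score <- apply(res$alt_logml, 1, max)
      stats <- NULL
      log10BF <- res$log10_BF
    } else {
      res <- reml_ball_search(spec, Msub, m = config$m, settings = config$settings,
                              interaction = interaction, criterion = criterion)
      best_vertex <- res$best_vertex
      best_score <- res$best_score
      stats <- res$stats
      log10BF <- rep(NA_real_, ncol(Msub))
    }
  } else {
    peg <- if (config$peg == "null") null_reml_vertex(spec, m_final = config$m)$h2 else NULL
    grid <- build_grid(L, config$m, peg = peg)
    gs <- grid_search(spec, grid, markers = Msub, criterion = criterion,
                      mode = "marker", interaction = interaction,
                      prior = config$prior)
    best_vertex <- grid$h2[gs$best_idx, , drop = FALSE]
    best_score <- gs$best_score
    stats <- gs$stats
    if (config$method == "bayes") {
      null_lm <- grid_search(spec, grid, mode = "trait", criterion = "marginal")$scores[1, ]
      log10BF <- vapply(seq_len(ncol(Msub)), function(j)
        bayes_factor(gs$scores[j, ], null_lm)$log10_BF, numeric(1))
    } else log10BF <- rep(NA_real_, ncol(Msub))
  }
  nu <- spec$n - spec$c - (if (is.null(interaction)) 1L else 2L)
  out <- empty_association_table(L, p)
  out$marker <- labels
  if (!is.null(marker_info)) {
    out$chrom <- marker_info$chrom[seq_len(p)]
    out$pos <- marker_info$pos[seq_len(p)]
  }
  ui <- which(usable)
  for (l in seq_len(L)) out[[paste0("h2_", l)]][ui] <- best_vertex[, l]
  out$h2_e[ui] <- 1 - rowSums(best_vertex)
  if (config$method == "wald") {
    rank_ok <- stats[, "rank_ok"] > 0
    sigma2 <- stats[, "RSS"] / (spec$n - stats[, "k"])
    Fv <- stats[, "beta"]^2 / (sigma2 * stats[, "invg"])
    out$beta[ui] <- ifelse(rank_ok, stats[, "beta"], NA)
    out$se[ui] <- ifelse(rank_ok, sqrt(sigma2 * stats[, "invg"]), NA)
    out$F[ui] <- ifelse(rank_ok, Fv, NA)
    out$df1[ui] <- 1
    out$df2[ui] <- nu
    out$p[ui] <- ifelse(rank_ok, stats::pf(Fv, 1, nu, lower.tail = FALSE), NA)
    out$logREML[ui] <- best_score
    out$flag[ui] <- ifelse(rank_ok, "", "rank_deficient")
  } else if (config$method == "lrt") {
    peg0 <- if (config$search == "fast") res$h0$h2 else NULL
    grid0 <- build_grid(L, config$m, peg = peg0)
    null_ml <- max(grid_search(spec, grid0, mode = "trait", criterion = "ML")$scores[1, ])
    q <- if (is.null(interaction)) 1L else 2L
    stat <- pmax(2 * (best_score - null_ml), 0)
    rank_ok <- stats[, "rank_ok"] > 0
    out$beta[ui] <- ifelse(rank_ok, stats[, "beta"], NA)
    out$F[ui] <- ifelse(rank_ok, stat, NA)       # chi-square statistic
    out$df1[ui] <- q
    out$df2[ui] <- Inf
    out$p[ui] <- ifelse(rank_ok, stats::pchisq(stat, q, lower.tail = FALSE), NA)
    out$flag[ui] <- ifelse(rank_ok, "", "rank_deficient")
  } else {
    out$log10BF[ui] <- log10BF
    out$flag[ui] <- ""
  }
  out$flag[!usable] <- "constant_marker"
  attr(out, "config") <- config
  if (config$genomic_control && config$method == "wald") {
    attr(out, "genomic_control") <- genomic_control(out$F, 1, nu)
  }
  out
}

empty_association_table <- function(L, p = 0) {
  out <- data.frame(marker = character(p), chrom = rep(NA_character_, p),
                    pos = rep(NA_real_, p), beta = rep(NA_real_, p),
                    se = rep(NA_real_, p), F = rep(NA_real_, p),
                    df1 = rep(NA_real_, p), df2 = rep(NA_real_, p),
                    p = rep(NA_real_, p), stringsAsFactors = FALSE)
  for (l in seq_len(L)) out[[paste0("h2_", l)]] <- rep(NA_real_, p)
  out$h2_e <- rep(NA_real_, p)
  out$logREML <- rep(NA_real_, p)
  out$log10BF <- rep(NA_real_, p)
  out$flag <- rep(NA_character_, p)
  class(out) <- c("association_table", "data.frame")
  out
}

#' Build a single-marker gene-by-environment design
#'
#' Adds the environment main effect to the covariates and sets
#' X = [marker, marker * env]; the Wald contrast selects only the
#' interaction column (q = 1). A constant environment is refused; an
#' interaction column collinear with the marker (all observations in one
#' environment) surfaces as a rank-deficiency flag downstream.
#'
#' @param spec base `lmm_spec`.
#' @param marker length-n dosage vector.
#' @param env length-n +/-1 environment vector.
#' @return list: updated `spec` (W gains env), `X` (n x 2), contrast matrix
#'   `M` (1 x (c+3)) selecting the interaction coefficient.
#' @export
build_gxe_design <- function(spec, marker, env) {
  stopifnot(inherits(spec, "lmm_spec"))
  env <- as.numeric(env)
  if (length(unique(env)) < 2) stop("environment vector is constant")
  if (!all(env %in% c(-1, 1))) stop("environment must be coded -1/+1")
  W2 <- cbind(spec$W, env = env)
  X <- cbind(marker = marker, interaction = marker * env)
  spec2 <- model_spec(spec$y, W = W2, X = X,
                      random_effects = spec$ZKZt)
  M <- matrix(0, 1, ncol(W2) + 2)
  M[1, ncol(W2) + 2] <- 1
  list(spec = spec2, X = X, M = M)
}

#' Genomic-control inflation factor
#'
#' lambda = median(observed F) / median of the reference F(df1, df2)
#' distribution; the expected value is 1 under a correctly specified model.
#' Corrected statistics (F / lambda) are returned for reporting; stored
#' p-values are never overwritten.
#'
#' @param F_stats vector of Wald F statistics (NAs dropped).
#' @param df1,df2 reference degrees of freedom.
#' @return list of class `gc_result`: `lambda`, `df1`, `df2`, `corrected`.
#' @export
genomic_control <- function(F_stats, df1, df2) {
  ok <- is.finite(F_stats)
  if (!any(ok)) stop("no finite statistics for genomic control")
  lambda <- stats::median(F_stats[ok]) / stats::qf(0.5, df1, df2)
  structure(list(lambda = lambda, df1 = df1, df2 = df2,
                 corrected = F_stats / lambda),
            class = "gc_result")
}

#' Variance-component estimation for many traits
#'
#' For each trait: REML-best vertex on the grid, full grid posterior under a
#' uniform prior (improper flat prior on the covariates, scale-free improper
#' prior on sigma^2), posterior mean of each proportion, and the posterior
#' probability that each component is non-zero (mass off the h_l^2 = 0
#' face). Rotations are shared across traits exactly as the marker scan
#' shares them across markers. Constant traits are NA-flagged.
#'
#' @param traits n x T matrix of (pre-normalized) traits.
#' @param spec null-model `lmm_spec` (its `y` is ignored).
#' @param m grid resolution (default 20, step 0.05).
#' @return data.frame of class `vc_table`: per trait the REML vertex, the
#'   posterior means, and P(h2_l > 0) per component; the posterior matrix is
#'   attached as attribute `posteriors`.
#' @export
variance_component_scan <- function(traits, spec, m = 20) {
  stopifnot(inherits(spec, "lmm_spec"))
  traits <- as.matrix(traits)
  nT <- ncol(traits)
  L <- spec$L
  labels <- colnames(traits) %||% paste0("t", seq_len(nT))
  grid <- build_grid(L, m)
  cols <- c("trait",
            paste0("reml_h2_", seq_len(L)), "reml_h2_e",
            paste0("postmean_h2_", seq_len(L)), "postmean_h2_e",
            paste0("p_nonzero_", seq_len(L)), "flag")
  if (nT == 0L) {
    out <- as.data.frame(matrix(nrow = 0, ncol = length(cols),
                                dimnames = list(NULL, cols)))
    class(out) <- c("vc_table", "data.frame")
    return(out)
  }
  ok <- apply(traits, 2, function(x) stats::var(x) > 0)
  reml <- grid_search(spec, grid, mode = "trait", criterion = "REML",
                      traits = traits[, ok, drop = FALSE])
  marg <- grid_search(spec, grid, mode = "trait", criterion = "marginal",
                      traits = traits[, ok, drop = FALSE])
  out <- data.frame(trait = labels, stringsAsFactors = FALSE)
  for (nm in cols[-1]) out[[nm]] <- if (nm == "flag") NA_character_ else NA_real_
  posteriors <- matrix(NA_real_, nT, grid$g, dimnames = list(labels, NULL))
  oki <- which(ok)
  for (jj in seq_along(oki)) {
    j <- oki[jj]
    bv <- grid$h2[reml$best_idx[jj], ]
    post <- grid_posterior(marg$scores[jj, ], grid)
    posteriors[j, ] <- post$posterior
    for (l in seq_len(L)) {
      out[[paste0("reml_h2_", l)]][j] <- bv[l]
      out[[paste0("postmean_h2_", l)]][j] <- post$posterior_mean_h2[l]
      out[[paste0("p_nonzero_", l)]][j] <-
        sum(post$posterior[grid$h2[, l] > 1e-12])
    }
    out$reml_h2_e[j] <- 1 - sum(bv)
    out$postmean_h2_e[j] <- post$posterior_mean_h2[L + 1]
    out$flag[j] <- ""
  }
  out$flag[!ok] <- "constant_trait"
  attr(out, "posteriors") <- posteriors
  attr(out, "grid") <- grid
  class(out) <- c("vc_table", "data.frame")
  out
}
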