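# Synthetic-data generator: structured genotypes (family blocks with
# Balding-Nichols-style differentiation), multi-random-effect phenotypes
# with stated variance proportions, block-diagonal population expansion, and
# the worst-case grid-vertex perturbation experiment.

#' Simulate structured genotype dosages
#'
#' Samples are partitioned into family blocks; each marker draws an
#' ancestral allele frequency and per-block frequencies from a
#' Balding-Nichols beta distribution with differentiation `fst`, so
#' within-block kinship exceeds between-block kinship. Dosages are binomial
#' in {0, 1, 2}.
#'
#' @param n,p numbers of samples and markers.
#' @param blocks number of family blocks (<= n).
#' @param fst between-block differentiation (0 = unstructured).
#' @param maf_range range of ancestral allele frequencies.
#' @param seed optional seed (recorded in attributes).
#' @return n x p dosage matrix with sample/marker dimnames and attributes
#'   `block` (length-n assignment), `seed`.
#' @export
simulate_structured_genotypes <- function(n, p, blocks = 10, fst = 0.3,
                                          maf_range = c(0.1, 0.9),
                                          seed = NULL) {
  stopifnot(n >= 1, p >= 1)
  if (blocks > n) stop("more blocks than samples")
  if (!is.null(seed)) set.seed(seed)
  block <- rep(seq_len(blocks), length.out = n)
  block <- sort(block)
  pa <- stats::runif(p, maf_range[1], maf_range[2])
  G <- matrix(0L, n, p, dimnames = list(paste0("ind_", seq_len(n)),
                                        paste0("snp_", seq_len(p))))
  for (b in seq_len(blocks)) {
    rows <- which(block == b)
    pb <- if (fst > 0)
      stats::rbeta(p, pa * (1 - fst) / fst, (1 - pa) * (1 - fst) / fst)
    else pa
    pb <- pmin(pmax(pb, 1e-4), 1 - 1e-4)
    G[rows, ] <- matrix(stats::rbinom(length(rows) * p, 2L, rep(pb, each = length(rows))),
                        length(rows), p)
  }
  attr(G, "block") <- block
  attr(G, "seed") <- seed
  G
}

#' Simulate a phenotype from kinships, variance proportions and one marker
#'
#' y = marker effect + sum_l (correlated draw with covariance K_l, weight
#' h_l^2) + iid residual. Weights are the *theoretical* variance proportions
#' and the components are scaled so the total phenotypic variance is one;
#' the residual proportion is 1 - sum(proportions) - effect_fraction. The
#' returned truth record (seed included) is sufficient to regenerate the
#' phenotype bit-exactly.
#'
#' @param kinships list of n x n observation-level covariance matrices.
#' @param proportions variance proportions, one per kinship.
#' @param marker optional length-n dosage vector for the causal effect
#'   (standardized internally).
#' @param effect_fraction fraction of variance explained by the marker
#'   (in [0, 0.2]).
#' @param seed optional seed.
#' @return list: `y`, `truth` (proportions, effect, seed, jitter used,
#'   realized variance fractions).
#' @export
simulate_phenotype <- function(kinships, proportions, marker = NULL,
                               effect_fraction = 0, seed = NULL) {
  stopifnot(length(kinships) == length(proportions), all(proportions >= 0))
  if (effect_fraction < 0 || effect_fraction > 0.2)
    stop("effect_fraction must lie in [0, 0.2]")
  resid_prop <- 1 - sum(proportions) - effect_fraction
  if (resid_prop < 0) stop("proportions + effect_fraction exceed 1")
  if (!is.null(seed)) set.seed(seed)
  n <- if (length(kinships)) nrow(kinships[[1]]) else length(marker)
  if (is.null(n)) stop("cannot infer sample size")
  y <- numeric(n)
  jitter <- rep(0, length(kinships))
  for (l in seq_along(kinships)) {
    K <- kinships[[l]]
    U <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(U)) {
      ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
      if (ev < -1e-8 * sum(diag(K)) / n) stop("non-PSD kinship in simulation")
      jitter[l] <- 1e-8
      U <- chol(K + diag(1e-8 * mean(diag(K)), n))
    }
    if (proportions[l] > 0)
      y <- y + sqrt(proportions[l]) * drop(crossprod(U, stats::rnorm(n))) /
        sqrt(mean(diag(K)))
  }
  y <- y + sqrt(resid_prop) * stats::rnorm(n)
  if (effect_fraction > 0) {
    if (is.null(marker)) stop("effect_fraction > 0 requires a marker")
    xs <- as.numeric(scale(marker))
    y <- y + sqrt(effect_fraction) * xs
  }
  realized <- c(proportions, residual = resid_prop, marker = effect_fraction)
  list(y = y,
       truth = list(proportions = proportions, effect_fraction = effect_fraction,
                    residual = resid_prop, seed = seed, jitter = jitter,
                    realized_variance = stats::var(y)))
}

#' Expand or subsample a population block-diagonally
#'
#' Expansion repeats the marker data `factor` times row-wise and each
#' covariance matrix block-diagonally (copies are unrelated, eigenvalues are
#' repeated); subsampling keeps the leading rows and the matching kinship
#' sub-blocks.
#'
#' @param genotypes n x p dosage matrix.
#' @param kinships list of n x n covariance matrices.
#' @param factor integer expansion factor (>= 1).
#' @param subsample optional number of leading individuals to keep (applied
#'   after expansion).
#' @return list with expanded `genotypes` and `kinships`.
#' @export
expand_population <- function(genotypes, kinships, factor = 1,
                              subsample = NULL) {
  stopifnot(factor >= 1, factor == round(factor))
  n <- nrow(genotypes)
  if (factor > 1) {
    genotypes <- do.call(rbind, replicate(factor, genotypes, simplify = FALSE))
    rownames(genotypes) <- paste0("ind_", seq_len(nrow(genotypes)))
    kinships <- lapply(kinships, function(K) {
      KB <- diag(factor) %x% K      # block-diagonal repetition
      rownames(KB) <- colnames(KB) <- rownames(genotypes)
      KB
    })
  }
  if (!is.null(subsample)) {
    if (subsample > nrow(genotypes)) stop("subsample larger than population")
    keep <- seq_len(subsample)
    genotypes <- genotypes[keep, , drop = FALSE]
    kinships <- lapply(kinships, function(K) K[keep, keep, drop = FALSE])
  }
  list(genotypes = genotypes, kinships = kinships)
}

#' Sign-combination neighbors of a vertex (worst-case grid perturbation)
#'
#' Returns the 2^L vertices obtained by perturbing every coordinate by
#' +/- delta, clipped to the simplex (out-of-simplex combinations are
#' dropped). Selecting the best REML score among these neighbors emulates a
#' grid whose vertices are maximally far from the optimum — the worst case
#' for a grid of step 2*delta.
#'
#' @param vertex length-L proportion vector.
#' @param delta perturbation (> 0), e.g. 0.05 for a step-0.1 grid.
#' @return matrix of valid neighbors (rows).
#' @export
perturb_vertex <- function(vertex, delta) {
  stopifnot(delta > 0)
  L <- length(vertex)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), L)))
  V <- sweep(signs * delta, 2, vertex, "+")
  keep <- apply(V, 1, function(z) all(z >= 0) && sum(z) < 1 - 1e-12)
  V[keep, , drop = FALSE]
}
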