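# Relationship-matrix construction: additive (VanRaden), pairwise-epistatic
# (Hadamard square), gene-by-environment (D Z K Z' D) and categorical
# covariances, plus the shared normalization used by all of them.

#' Validate a relationship matrix
#'
#' Checks symmetry (to 1e-10), positive semi-definiteness (smallest eigenvalue
#' >= -1e-8 * trace/n) and, optionally, that the mean diagonal equals one.
#' Small negative eigenvalues within tolerance are accepted, never clipped;
#' anything beyond tolerance is an error so that data problems surface early.
#'
#' @param K square numeric matrix with sample labels as dimnames.
#' @param normalized if TRUE additionally require mean(diag(K)) == 1 +/- 1e-10.
#' @return K, invisibly, with attribute "psd_checked" set.
#' @export
check_relationship_matrix <- function(K, normalized = FALSE) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  n <- nrow(K)
  if (max(abs(K - t(K))) > 1e-10)
    stop("relationship matrix is not symmetric (tolerance 1e-10)")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-8 * sum(diag(K)) / n
  if (min(ev) < -max(tol, 1e-12))
    stop(sprintf("relationship matrix is not positive semi-definite (min eigenvalue %.3e, tolerance %.3e)",
                 min(ev), -tol))
  if (normalized && abs(mean(diag(K)) - 1) > 1e-10)
    stop("relationship matrix flagged normalized but mean diagonal != 1")
  attr(K, "psd_checked") <- TRUE
  invisible(K)
}

#' Center and trace-normalize a relationship matrix
#'
#' Optionally centers K by projecting out the intercept (P K P with
#' P = I - 11'/n), then rescales so the mean diagonal element equals one
#' (K * n / trace(K)).
#'
#' @param K symmetric relationship matrix.
#' @param center project out the intercept before rescaling?
#' @return normalized matrix with mean diagonal exactly 1.
#' @export
normalize_kinship <- function(K, center = FALSE) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (max(abs(K - t(K))) > 1e-10) stop("K must be symmetric")
  if (center) {
    rm_ <- rowMeans(K)
    K <- K - outer(rm_, rep(1, ncol(K))) - outer(rep(1, nrow(K)), colMeans(K)) + mean(K)
  }
  tr <- sum(diag(K))
  if (abs(tr) < 1e-12) stop("cannot normalize: trace of K is zero")
  K * nrow(K) / tr
}

#' Additive genomic relationship matrix
#'
#' VanRaden's first method: K = (G - 2f)(G - 2f)' / (2 * sum_j f_j (1 - f_j)),
#' with f_j the observed allele frequency of marker j. Missing dosages are
#' mean-imputed per marker before construction. By default the result is then
#' centered (intercept projected out) and trace-normalized so the mean
#' diagonal is one.
#'
#' @param G n x p dosage matrix in [0, 2], samples in rows (rownames used as
#'   sample labels). NAs allowed (mean-imputed).
#' @param center project out the intercept from the final matrix?
#' @param normalize rescale to mean diagonal one?
#' @return n x n relationship matrix.
#' @export
additive_kinship <- function(G, center = TRUE, normalize = TRUE) {
  stopifnot(is.matrix(G), nrow(G) >= 2)
  if (anyNA(G)) {
    cm <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- cm[idx[, 2]]
  }
  f <- colMeans(G) / 2
  poly <- f > 0 & f < 1 & apply(G, 2, stats::var) > 0
  if (!any(poly)) stop("all markers are monomorphic; cannot build additive kinship")
  G <- G[, poly, drop = FALSE]
  f <- f[poly]
  M <- sweep(G, 2, 2 * f)
  K <- tcrossprod(M) / (2 * sum(f * (1 - f)))
  if (center || normalize) K <- normalize_kinship(K, center = center)
  dimnames(K) <- list(rownames(G), rownames(G))
  K
}

#' Pairwise-epistatic relationship matrix
#'
#' Element-wise (Hadamard) square of an additive relationship matrix,
#' re-normalized by default so its mean diagonal is one.
#'
#' @param K additive relationship matrix.
#' @param normalize rescale to mean diagonal one after squaring?
#' @return relationship matrix for additive-by-additive epistasis.
#' @export
epistatic_kinship <- function(K, normalize = TRUE) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (max(abs(K - t(K))) > 1e-10) stop("K must be symmetric")
  KE <- K * K
  if (normalize) KE <- normalize_kinship(KE, center = FALSE)
  KE
}

#' Incidence matrix mapping observations to levels
#'
#' @param groups length-n vector (factor/character) assigning each observation
#'   to one level.
#' @param levels optional level ordering (defaults to the order of appearance
#'   if `groups` is not a factor).
#' @return n x r 0/1 matrix with one 1 per row; colnames are the levels.
#' @export
incidence_matrix <- function(groups, levels = NULL) {
  groups <- as.character(groups)
  if (anyNA(groups)) stop("missing observation-to-level assignment")
  if (is.null(levels)) levels <- unique(groups)
  if (!all(groups %in% levels))
    stop("unmapped observation labels: ",
         paste(utils::head(setdiff(groups, levels), 5), collapse = ", "))
  Z <- matrix(0, length(groups), length(levels),
              dimnames = list(names(groups), levels))
  Z[cbind(seq_along(groups), match(groups, levels))] <- 1
  Z
}

#' Gene-by-environment relationship matrix
#'
#' Expands a level-wise relationship matrix K to the observation level and
#' sign-flips it across environments: D Z K Z' D, where Z maps the n
#' observations to the r levels of K and D is diagonal with entries +/-1
#' encoding the two environments. With all signs +1 this is the expanded
#' kinship Z K Z'; with K = I and all signs +1 it is the covariance of an
#' iid categorical (line/cage) effect.
#'
#' @param K r x r relationship matrix among levels (rownames = level labels).
#' @param groups length-n assignment of observations to rownames(K).
#' @param signs optional length-n vector of +/-1 (default all +1).
#' @return n x n relationship matrix.
#' @export
gxe_kinship <- function(K, groups, signs = NULL) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (is.null(rownames(K))) rownames(K) <- colnames(K) <- as.character(seq_len(nrow(K)))
  Z <- incidence_matrix(groups, levels = rownames(K))
  n <- nrow(Z)
  if (is.null(signs)) signs <- rep(1, n)
  if (length(signs) != n || !all(signs %in% c(-1, 1)))
    stop("signs must be a length-n vector of -1/+1")
  out <- (signs * Z) %*% K %*% t(signs * Z)
  rownames(out) <- colnames(out) <- names(groups) %||% rownames(Z)
  out
}

#' Write a relationship matrix as delimited text
#'
#' Header row of sample labels, first column of sample labels, values printed
#' with 17 significant digits so a read/write cycle is bit-exact.
#'
#' @param K relationship matrix with dimnames.
#' @param path output file.
#' @export
write_kinship <- function(K, path) {
  stopifnot(is.matrix(K), !is.null(rownames(K)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample", colnames(K)), collapse = "\t"), con)
  for (i in seq_len(nrow(K)))
    writeLines(paste(c(rownames(K)[i], fmt17(K[i, ])), collapse = "\t"), con)
  invisible(path)
}

#' Read a relationship matrix written by [write_kinship()]
#'
#' @param path delimited text file: header row plus first column of labels.
#' @return relationship matrix with dimnames.
#' @export
read_kinship <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           row.names = 1, colClasses = "character")
  K <- as.matrix(tab)
  storage.mode(K) <- "double"
  K
}
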