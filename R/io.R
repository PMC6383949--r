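# Readers and writers: delimited-text genotypes/phenotypes/kinships, PLINK
# .bed/.bim/.fam, and the deterministic results writer. No operation ever
# mutates an input file.

#' Read a delimited genotype matrix
#'
#' Samples x markers, header row of marker names, first column of sample
#' labels. Missing dosages are mean-imputed per marker (count reported via
#' attribute `n_imputed`).
#'
#' @param path text file (tab- or whitespace-delimited).
#' @return dosage matrix with dimnames.
#' @export
read_genotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, row.names = 1, check.names = FALSE)
  G <- as.matrix(tab)
  storage.mode(G) <- "double"
  n_imp <- sum(is.na(G))
  if (n_imp > 0) {
    cm <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- cm[idx[, 2]]
  }
  attr(G, "n_imputed") <- n_imp
  G
}

#' Write a genotype matrix as delimited text
#' @param G dosage matrix with dimnames.
#' @param path output file.
#' @export
write_genotypes <- function(G, path) {
  stopifnot(!is.null(rownames(G)), !is.null(colnames(G)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample", colnames(G)), collapse = "\t"), con)
  for (i in seq_len(nrow(G)))
    writeLines(paste(c(rownames(G)[i], fmt17(G[i, ])), collapse = "\t"), con)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Header row; first column must be the sample label. Non-numeric phenotype
#' columns are an explicit error when selected.
#'
#' @param path delimited text file.
#' @return data.frame with rownames = sample labels.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab[[1]])) stop("duplicated sample labels in phenotype file")
  rownames(tab) <- as.character(tab[[1]])
  tab[-1]
}

#' Read PLINK .bed/.bim/.fam genotypes
#'
#' Bit-exact decoding of the SNP-major .bed format; dosages count copies of
#' the A1 allele (00 -> 2, 10 -> 1, 11 -> 0, 01 -> missing). Missing calls
#' are mean-imputed with the count recorded in attribute `n_imputed`.
#' Positions in .bim are passed through untouched (1-based, as PLINK
#' defines them).
#'
#' @param prefix path prefix (without extension).
#' @return dosage matrix (samples x markers) with attributes `bim` and
#'   `fam` (data.frames) and `n_imputed`.
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  n <- nrow(fam); p <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = file.size(paste0(prefix, ".bed")))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes)")
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed files are supported")
  bpm <- ceiling(n / 4)
  if (length(raw) - 3 != bpm * p) stop(".bed size inconsistent with .bim/.fam")
  body <- as.integer(raw[-(1:3)])
  # decode all 2-bit genotype codes at once
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, body %/% 64L)
  lookup <- c(2, NA, 1, 0)   # 00, 01, 10, 11
  G <- matrix(NA_real_, n, p, dimnames = list(fam$iid, bim$id))
  for (j in seq_len(p)) {
    block <- codes[, ((j - 1) * bpm + 1):(j * bpm)]
    G[, j] <- lookup[block[seq_len(n)] + 1L]
  }
  n_imp <- sum(is.na(G))
  if (n_imp > 0) {
    cm <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- cm[idx[, 2]]
  }
  attr(G, "bim") <- bim
  attr(G, "fam") <- fam
  attr(G, "n_imputed") <- n_imp
  G
}

#' Write PLINK .bed/.bim/.fam genotypes
#'
#' Inverse of [read_plink()] for integer dosages in {0, 1, 2, NA}.
#'
#' @param G dosage matrix (samples x markers) with dimnames.
#' @param prefix output path prefix.
#' @param bim optional .bim data.frame (default: chromosome 1, positions
#'   1..p, alleles A/B).
#' @export
write_plink <- function(G, prefix, bim = NULL) {
  stopifnot(all(G %in% c(0, 1, 2) | is.na(G)))
  n <- nrow(G); p <- ncol(G)
  fam <- data.frame(fid = rownames(G), iid = rownames(G), pat = 0, mat = 0,
                    sex = 0, pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (is.null(bim))
    bim <- data.frame(chrom = 1, id = colnames(G), cm = 0, pos = seq_len(p),
                      a1 = "A", a2 = "B")
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  code <- matrix(0L, n, p)      # 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code[is.na(G)] <- 1L
  code[!is.na(G) & G == 1] <- 2L
  code[!is.na(G) & G == 0] <- 3L
  bpm <- ceiling(n / 4)
  out <- raw(3 + bpm * p)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  pad <- matrix(0L, 4 * bpm, p)
  pad[seq_len(n), ] <- code
  packed <- pad[c(TRUE, FALSE, FALSE, FALSE), , drop = FALSE] +
    4L * pad[c(FALSE, TRUE, FALSE, FALSE), , drop = FALSE] +
    16L * pad[c(FALSE, FALSE, TRUE, FALSE), , drop = FALSE] +
    64L * pad[c(FALSE, FALSE, FALSE, TRUE), , drop = FALSE]
  out[-(1:3)] <- as.raw(as.vector(packed))
  writeBin(out, paste0(prefix, ".bed"))
  invisible(prefix)
}

#' Align phenotype, genotype and kinship inputs on shared samples
#'
#' Restricts all inputs to the intersection of their sample labels,
#' preserving the phenotype file's order, and realigns kinship rows/columns.
#'
#' @param phenotypes data.frame with rownames = samples.
#' @param genotypes dosage matrix with rownames = samples.
#' @param kinships optional named list of relationship matrices.
#' @param verbose log the intersection size?
#' @return list with aligned `phenotypes`, `genotypes`, `kinships`,
#'   `samples`.
#' @export
align_inputs <- function(phenotypes, genotypes = NULL, kinships = NULL,
                         verbose = FALSE) {
  samples <- rownames(phenotypes)
  if (anyDuplicated(samples)) stop("duplicated sample labels")
  if (!is.null(genotypes)) samples <- samples[samples %in% rownames(genotypes)]
  for (K in kinships %||% list()) samples <- samples[samples %in% rownames(K)]
  if (length(samples) == 0) stop("empty sample intersection across inputs")
  dropped <- nrow(phenotypes) - length(samples)
  if (dropped > 0)
    gv_log(sprintf("dropped %d samples absent from some input; n = %d retained",
                   dropped, length(samples)), verbose = verbose)
  list(phenotypes = phenotypes[samples, , drop = FALSE],
       genotypes = if (is.null(genotypes)) NULL else genotypes[samples, , drop = FALSE],
       kinships = lapply(kinships %||% list(), function(K) K[samples, samples]),
       samples = samples)
}

#' Write an association or variance-component table
#'
#' Tab-separated text with a commented header recording package version,
#' seed, grid resolution and a configuration hash; numeric columns at 17
#' significant digits so identical runs are byte-identical.
#'
#' @param table an `association_table` or any data.frame.
#' @param path output file.
#' @param seed seed recorded in the header.
#' @param config optional `scan_config` summarized in the header.
#' @export
write_results <- function(table, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg_str <- if (is.null(config)) "" else
    paste(names(unlist(config)), unlist(config), sep = "=", collapse = ";")
  writeLines(c(
    sprintf("# gridvc %s", as.character(utils::packageVersion("gridvc"))),
    sprintf("# seed: %s", seed),
    sprintf("# config: %s", cfg_str),
    sprintf("# config_hash: %08x", config_hash(cfg_str))), con)
  if (nrow(table) == 0) {
    writeLines(paste(colnames(table), collapse = "\t"), con)
    return(invisible(path))
  }
  num <- vapply(table, is.numeric, logical(1))
  tab <- table
  for (j in which(num)) tab[[j]] <- fmt17(table[[j]])
  writeLines(paste(colnames(tab), collapse = "\t"), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}

# small deterministic string hash (31-polynomial, 31 bit) for self-describing
# output headers
config_hash <- function(s) {
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

#' Read back a results table written by [write_results()]
#' @param path results file.
#' @return data.frame (header comments skipped).
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
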