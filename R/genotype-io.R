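#' Genotype container
#'
#' Holds a sample-by-SNP matrix of allele dosages in \{0, 1, 2\} (counts of
#' the first/reference allele), with per-SNP and per-sample identifiers and
#' optional genomic coordinates. Missing genotypes are stored as \code{NA}
#' and are never silently imputed at read time.
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns; entries
#'   must be 0, 1, 2 or \code{NA}.
#' @param sample_ids character vector of unique sample identifiers.
#' @param snp_ids character vector of unique SNP identifiers.
#' @param chrom optional per-SNP chromosome codes.
#' @param pos optional per-SNP base-pair positions (1-based).
#'
#' @return An object of class \code{genotype_data}.
#' @export
genotype_data <- function(dosages, sample_ids = NULL, snp_ids = NULL,
                          chrom = NULL, pos = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  s <- ncol(dosages)
  if (n < 2L) stop("genotype_data requires at least 2 samples")
  if (s < 1L) stop("genotype_data requires at least 1 SNP")
  if (is.null(sample_ids)) sample_ids <- rownames(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  if (is.null(snp_ids)) snp_ids <- colnames(dosages)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(s))
  sample_ids <- as.character(sample_ids)
  snp_ids <- as.character(snp_ids)
  if (length(sample_ids) != n) stop("sample_ids length does not match rows")
  if (length(snp_ids) != s) stop("snp_ids length does not match columns")
  if (anyDuplicated(sample_ids)) stop("sample identifiers must be unique")
  if (anyDuplicated(snp_ids)) stop("SNP identifiers must be unique")
  obs <- dosages[!is.na(dosages)]
  if (length(obs) && !all(obs %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2 or NA")
  dimnames(dosages) <- list(sample_ids, snp_ids)
  structure(
    list(dosages = dosages, sample_ids = sample_ids, snp_ids = snp_ids,
         chrom = chrom, pos = pos),
    class = "genotype_data"
  )
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype_data: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$dosages)

# PLINK 1 .bed two-bit codes, SNP-major layout: within each byte the sample
# with the lowest index occupies the lowest-order bit pair.
#   00 -> homozygous first allele (dosage 2)
#   01 -> missing
#   10 -> heterozygous          (dosage 1)
#   11 -> homozygous second allele (dosage 0)
.bed_code_to_dosage <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

#' Read a PLINK 1 binary fileset
#'
#' Reads a \code{.bed}/\code{.bim}/\code{.fam} triplet (SNP-major layout)
#' into a \code{\link{genotype_data}} object. Dosages count copies of the
#' A1 allele from the \code{.bim} file; missing genotypes become \code{NA}.
#'
#' @param prefix path prefix; \code{prefix.bed}, \code{prefix.bim} and
#'   \code{prefix.fam} must all exist.
#' @return A \code{genotype_data} with \code{chrom}/\code{pos} from the
#'   \code{.bim} file (positions kept 1-based as stored).
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths)
    if (!file.exists(p)) stop("PLINK fileset member not found: ", p)
  fam <- utils::read.table(paths[3], header = FALSE,
                           stringsAsFactors = FALSE)
  bim <- utils::read.table(paths[2], header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(fam)
  s <- nrow(bim)
  sample_ids <- as.character(fam[[2]])
  if (anyDuplicated(sample_ids))
    sample_ids <- paste(fam[[1]], fam[[2]], sep = "_")

  raw <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || !identical(raw[1:2], .bed_magic[1:2]))
    stop("not a PLINK .bed file (bad magic bytes): ", paths[1])
  if (raw[3] != .bed_magic[3])
    stop("only SNP-major .bed files are supported: ", paths[1])
  nb <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != nb * s)
    stop(sprintf(
      "format error: %s holds %d data bytes but .fam/.bim imply %d (%d samples, %d SNPs)",
      paths[1], length(body), nb * s, n, s))

  bytes <- matrix(as.integer(body), nrow = nb, ncol = s)
  dosages <- matrix(NA_real_, nrow = n, ncol = s)
  for (k in 0:3) {
    idx <- seq.int(k + 1L, by = 4L, length.out = nb)
    idx <- idx[idx <= n]
    if (!length(idx)) next
    rows <- (idx - 1L) %/% 4L + 1L
    codes <- bitwAnd(bitwShiftR(bytes[rows, , drop = FALSE], 2L * k), 3L)
    dosages[idx, ] <- .bed_code_to_dosage[codes + 1L]
  }
  genotype_data(dosages, sample_ids = sample_ids,
                snp_ids = as.character(bim[[2]]),
                chrom = bim[[1]], pos = as.integer(bim[[4]]))
}

#' Write a PLINK 1 binary fileset
#'
#' Inverse of \code{\link{read_plink}}; writes SNP-major \code{.bed} plus
#' minimal \code{.bim}/\code{.fam} files so that a read/write/read cycle
#' preserves dosages and identifiers.
#'
#' @param g a \code{genotype_data}.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_data"))
  d <- g$dosages
  n <- nrow(d)
  s <- ncol(d)
  chrom <- if (is.null(g$chrom)) rep(1L, s) else g$chrom
  pos <- if (is.null(g$pos)) seq_len(s) else g$pos
  utils::write.table(
    data.frame(chrom, g$snp_ids, 0L, pos, "A", "B"),
    paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(g$sample_ids, g$sample_ids, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)

  # dosage -> two-bit code (see .bed_code_to_dosage)
  codes <- matrix(1L, nrow = n, ncol = s)   # default: missing (01)
  codes[!is.na(d) & d == 2] <- 0L
  codes[!is.na(d) & d == 1] <- 2L
  codes[!is.na(d) & d == 0] <- 3L
  nb <- ceiling(n / 4)
  pad <- nb * 4L - n
  if (pad > 0) codes <- rbind(codes, matrix(3L, nrow = pad, ncol = s))
  shift <- rep(c(0L, 2L, 4L, 6L), nb)
  grp <- rep(seq_len(nb), each = 4L)
  bytes <- vapply(seq_len(s), function(j) {
    as.integer(rowsum(bitwShiftL(codes[, j], shift), grp))
  }, integer(nb))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read genotypes from a dosage CSV
#'
#' Expects a header row of SNP identifiers, the first column holding sample
#' identifiers, and cells with dosages 0/1/2 (empty or NA for missing).
#'
#' @param path CSV file path.
#' @return A \code{genotype_data}.
#' @export
read_genotype_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  genotype_data(m, sample_ids = ids, snp_ids = colnames(tab)[-1])
}

#' Read a phenotype column
#'
#' Reads a delimited file with a header and a sample-identifier first
#' column, returning a named numeric vector. Missing values are kept as
#' \code{NA}; sample alignment happens later in \code{\link{align_samples}}.
#'
#' @param path CSV/TSV file path (separator inferred from the extension).
#' @param column phenotype column name; defaults to the second column.
#' @return Named numeric vector of phenotype values.
#' @export
read_phenotype <- function(path, column = NULL) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(column)) column <- colnames(tab)[2]
  if (!column %in% colnames(tab))
    stop("phenotype column not found: ", column)
  stats::setNames(as.numeric(tab[[column]]), as.character(tab[[1]]))
}

#' Read a covariate table
#'
#' Reads a delimited covariate file (sample identifiers in the first
#' column), adds an intercept column, and drops constant or duplicated
#' columns so the returned design matrix has full column rank.
#'
#' @param path CSV/TSV file path.
#' @return Numeric matrix with rownames set to sample identifiers and an
#'   \code{"(Intercept)"} first column.
#' @export
read_covariates <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  make_design(m)
}

#' Build a full-rank design matrix with an intercept
#'
#' @param covariates optional numeric matrix of covariates (no intercept).
#' @param n number of samples, required when \code{covariates} is NULL.
#' @return Numeric design matrix whose first column is the intercept.
#' @export
make_design <- function(covariates = NULL, n = NULL) {
  if (is.null(covariates)) {
    if (is.null(n)) stop("n is required when no covariates are given")
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  covariates <- as.matrix(covariates)
  keep <- apply(covariates, 2, function(v) stats::var(v, na.rm = TRUE) > 0)
  X <- cbind(`(Intercept)` = 1, covariates[, keep, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    warning("dropped linearly dependent covariate columns")
  }
  if (ncol(X) >= nrow(X))
    stop("more covariate columns than samples")
  X
}

#' Join genotypes, phenotype and covariates on sample identifiers
#'
#' Samples missing from any input (or with a missing phenotype value) are
#' dropped, with a message reporting the count. Order follows the genotype
#' object.
#'
#' @param geno a \code{genotype_data}.
#' @param pheno named numeric phenotype vector.
#' @param covariates optional covariate matrix with sample rownames.
#' @return List with elements \code{geno}, \code{y}, \code{X} restricted to
#'   the common samples.
#' @export
align_samples <- function(geno, pheno, covariates = NULL) {
  ids <- geno$sample_ids
  keep <- ids %in% names(pheno)[!is.na(pheno)]
  if (!is.null(covariates))
    keep <- keep & ids %in% rownames(covariates)
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " sample(s) dropped during join (missing phenotype ",
            "or absent from an input)")
  ids <- ids[keep]
  if (length(ids) < 10L)
    stop("fewer than 10 complete samples after joining inputs")
  g2 <- genotype_data(geno$dosages[keep, , drop = FALSE],
                      sample_ids = ids, snp_ids = geno$snp_ids,
                      chrom = geno$chrom, pos = geno$pos)
  X <- if (is.null(covariates)) make_design(n = length(ids))
       else make_design(covariates[ids, , drop = FALSE])
  list(geno = g2, y = unname(pheno[ids]), X = X)
}
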