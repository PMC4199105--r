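#' Standardize a genotype matrix
#'
#' Centres and scales every SNP column to zero mean and unit variance using
#' the observed (non-missing) entries, then sets missing entries to 0 --
#' i.e. the column mean, the standard mean imputation. SNPs with fewer than
#' two distinct observed dosages carry no information and are dropped with
#' a message.
#'
#' @param g a \code{\link{genotype_data}} or a plain dosage matrix.
#' @return Numeric matrix of standardized dosages with attributes
#'   \code{center}, \code{scale} (per retained SNP, for reuse on new
#'   samples) and \code{kept} (retained column indices in the input).
#' @export
standardize_genotypes <- function(g) {
  d <- if (inherits(g, "genotype_data")) g$dosages else as.matrix(g)
  nobs <- colSums(!is.na(d))
  mu <- colMeans(d, na.rm = TRUE)
  v <- apply(d, 2, stats::var, na.rm = TRUE)
  keep <- nobs >= 2L & !is.na(v) & v > 0
  if (!any(keep)) stop("no informative SNPs (all monomorphic or missing)")
  if (any(!keep))
    message(sum(!keep), " monomorphic/uninformative SNP(s) excluded")
  d <- d[, keep, drop = FALSE]
  mu <- mu[keep]
  sdv <- sqrt(v[keep])
  std <- sweep(sweep(d, 2, mu, "-"), 2, sdv, "/")
  std[is.na(std)] <- 0
  attr(std, "center") <- mu
  attr(std, "scale") <- sdv
  attr(std, "kept") <- which(keep)
  std
}

#' Genomic relatedness matrix
#'
#' Computes the realized-relationship kinship K = G G' / S from a
#' standardized sample-by-SNP matrix G. With unit-variance columns the mean
#' of diag(K) is close to 1, so the genetic variance component multiplying
#' K is interpretable on the trait scale.
#'
#' @param std standardized genotype matrix from
#'   \code{\link{standardize_genotypes}}.
#' @param normalize if TRUE, rescale so that mean(diag(K)) is exactly 1.
#' @return Symmetric positive semi-definite N x N matrix with attribute
#'   \code{normalized}.
#' @export
compute_kinship <- function(std, normalize = FALSE) {
  std <- as.matrix(std)
  if (!all(is.finite(std))) stop("non-finite entries in standardized genotypes")
  K <- tcrossprod(std) / ncol(std)
  K <- (K + t(K)) / 2
  if (normalize) K <- K * nrow(K) / sum(diag(K))
  attr(K, "normalized") <- normalize
  K
}

#' Relatedness between new samples and a training set
#'
#' Standardizes the test dosages with the training per-SNP centre/scale
#' (so both live in the same standardized SNP space) and returns the
#' test-by-train kinship block k* = G_test G_train' / S.
#'
#' @param train_std training standardized matrix (keeps its attributes).
#' @param test_geno \code{genotype_data} or dosage matrix for new samples;
#'   must contain the same SNPs, in order, as the training set before
#'   standardization dropped columns.
#' @return Numeric matrix, test samples in rows, training samples in
#'   columns.
#' @export
kinship_cross <- function(train_std, test_geno) {
  d <- if (inherits(test_geno, "genotype_data")) test_geno$dosages
       else as.matrix(test_geno)
  kept <- attr(train_std, "kept")
  ctr <- attr(train_std, "center")
  scl <- attr(train_std, "scale")
  if (is.null(kept) || is.null(ctr))
    stop("train_std must come from standardize_genotypes()")
  if (max(kept) > ncol(d))
    stop("SNP set mismatch: test genotypes have fewer SNPs than training")
  if (!is.null(colnames(d)) && !is.null(colnames(train_std)) &&
      !identical(colnames(d)[kept], colnames(train_std)))
    stop("SNP set mismatch between training and test genotypes")
  d <- d[, kept, drop = FALSE]
  std <- sweep(sweep(d, 2, ctr, "-"), 2, scl, "/")
  std[is.na(std)] <- 0
  tcrossprod(std, train_std) / ncol(train_std)
}
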