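#' Filter genes by expression variation and zero inflation
#'
#' Keeps genes whose standard deviation across samples is at least `sd_min`
#' and whose fraction of zero values is at most `max_zero_frac`.  Boundary
#' values are kept: removal requires SD strictly below the threshold or a
#' zero fraction strictly above it.  The SD rule is intended to be applied
#' to normalized counts.
#'
#' @param expression Samples x genes matrix.
#' @param sd_min Minimum standard deviation to keep a gene.
#' @param max_zero_frac Maximum tolerated fraction of zero counts.
#' @return List with `expression` (reduced matrix) and `report`
#'   (`genes_removed_sd`, `genes_removed_zeros`, `kept`).
#' @export
filter_genes <- function(expression, sd_min = 0.5, max_zero_frac = 0.30) {
  x <- assert_matrix(expression, "expression")
  if (nrow(x) == 0 || ncol(x) == 0) stop("`expression` is empty")
  sds <- col_sds(x)
  zf <- colMeans(x == 0)
  low_sd <- sds < sd_min
  high_zero <- zf > max_zero_frac
  keep <- !low_sd & !high_zero
  list(expression = x[, keep, drop = FALSE],
       report = list(genes_removed_sd = sum(low_sd),
                     genes_removed_zeros = sum(high_zero & !low_sd),
                     kept = colnames(x)[keep]))
}

#' Filter samples by duplication and genome-wide zero counts
#'
#' Removes exact-duplicate samples (keeping the first occurrence) and
#' samples whose fraction of zero-count genes exceeds `max_zero_gene_frac`.
#' Intended for raw counts.
#'
#' @param expression Samples x genes count matrix.
#' @param max_zero_gene_frac Maximum tolerated fraction of zero-count genes
#'   per sample.
#' @return List with `expression` and `report`
#'   (`samples_removed_duplicates`, `samples_removed_lowexpr`).
#' @export
filter_samples <- function(expression, max_zero_gene_frac = 0.50) {
  x <- assert_matrix(expression, "expression")
  if (nrow(x) == 0) stop("`expression` is empty")
  dup <- duplicated(x)
  zf <- rowMeans(x == 0)
  low <- zf > max_zero_gene_frac
  keep <- !dup & !low
  list(expression = x[keep, , drop = FALSE],
       report = list(samples_removed_duplicates = sum(dup),
                     samples_removed_lowexpr = sum(low & !dup)))
}

#' Upper-quartile normalization
#'
#' Scales every sample so that its 75th percentile of non-zero counts equals
#' the cross-sample mean of those percentiles.  Quantiles use linear
#' interpolation (`type = 7`).
#'
#' @param counts Samples x genes non-negative count matrix.
#' @param quantile_type Quantile convention passed to [stats::quantile()].
#' @return List with `normalized` matrix and `scale_factors` per sample.
#' @export
upper_quartile_normalize <- function(counts, quantile_type = 7) {
  x <- assert_matrix(counts, "counts")
  if (any(x < 0)) stop("counts must be non-negative")
  q3 <- apply(x, 1, function(r) {
    nz <- r[r > 0]
    if (!length(nz)) stop("sample with all-zero counts; remove it first")
    stats::quantile(nz, 0.75, type = quantile_type, names = FALSE)
  })
  fac <- mean(q3) / q3
  list(normalized = x * fac, scale_factors = fac)
}

#' Log2 transform with pseudocount
#'
#' `y = log2(x + pseudocount)`; monotone, maps 0 to 0 for the default
#' pseudocount of 1.
#'
#' @param x Non-negative matrix or vector.
#' @param pseudocount Offset added before taking logs.
#' @return Transformed object of the same shape.
#' @export
log2_transform <- function(x, pseudocount = 1) {
  if (any(x < 0)) stop("negative values cannot be log-transformed")
  log2(x + pseudocount)
}

#' Select enriched cell types
#'
#' A cell type is called enriched when at most `max_zero_frac` of its scores
#' across samples are zero and its standard deviation is strictly greater
#' than `sd_min`.
#'
#' @param cell_fractions Samples x cell-type matrix of scores in `[0, 1]`.
#' @param max_zero_frac Maximum tolerated fraction of zero scores.
#' @param sd_min Standard deviation must exceed this value.
#' @return Character vector of enriched cell-type names.
#' @export
enrich_cell_types <- function(cell_fractions, max_zero_frac = 0.30,
                              sd_min = 0.1) {
  x <- assert_matrix(cell_fractions, "cell_fractions")
  keep <- colMeans(x == 0) <= max_zero_frac & col_sds(x) > sd_min
  colnames(x)[keep]
}

#' Adjust expression for covariates and cell composition
#'
#' Regresses every gene on an intercept plus the supplied covariates and
#' cell fractions, returning least-squares residuals.  Residuals are
#' orthogonal to every design column; adjusting twice is a no-op.
#'
#' @param expression Samples x genes matrix.
#' @param covariates Optional data frame or matrix of covariates (factors
#'   are dummy-expanded).
#' @param cell_fractions Optional samples x cell-type matrix, typically
#'   restricted to [enrich_cell_types()] output.
#' @return Residual matrix with the same dimensions as `expression`.
#' @export
adjust_expression <- function(expression, covariates = NULL,
                              cell_fractions = NULL) {
  x <- assert_matrix(expression, "expression")
  X <- cbind(`(Intercept)` = rep(1, nrow(x)),
             design_from_df(covariates),
             cell_fractions)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient adjustment design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  res <- qr.resid(qx, x)
  dimnames(res) <- dimnames(x)
  res
}

#' First principal component of the genotype matrix
#'
#' Column-standardizes the dosage matrix (constant SNPs are dropped with a
#' warning), takes the leading left singular vector, and fixes its sign so
#' that the largest-magnitude SNP loading is positive.  The returned score
#' vector has unit norm.
#'
#' @param genotypes Samples x SNPs dosage matrix.
#' @return Named numeric vector, one score per sample.
#' @export
genotype_pc1 <- function(genotypes) {
  x <- assert_matrix(genotypes, "genotypes")
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 samples and >= 2 SNPs")
  sds <- col_sds(x)
  if (all(sds == 0)) stop("zero-variance genotype matrix")
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant SNP(s) dropped before PCA")
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- scale(x)
  sv <- svd(z, nu = 1, nv = 1)
  sgn <- sign(sv$v[which.max(abs(sv$v[, 1])), 1])
  stats::setNames(sgn * sv$u[, 1], rownames(x))
}

#' Count-scale preprocessing pipeline
#'
#' Applies the full count-based preparation in order: sample filtering
#' (duplicates, low-expression), upper-quartile normalization, gene
#' filtering (SD on normalized counts, zero fraction), then log2.
#'
#' @param counts Samples x genes raw count matrix.
#' @param sd_min,max_zero_frac Gene-filter thresholds (on normalized
#'   counts).
#' @param max_zero_gene_frac Sample-filter threshold.
#' @param pseudocount Log2 offset.
#' @return List with `expression` (log2 scale, filtered) and `report`.
#' @export
preprocess_counts <- function(counts, sd_min = 0.5, max_zero_frac = 0.30,
                              max_zero_gene_frac = 0.50, pseudocount = 1) {
  fs <- filter_samples(counts, max_zero_gene_frac)
  uq <- upper_quartile_normalize(fs$expression)
  fg <- filter_genes(uq$normalized, sd_min, max_zero_frac)
  list(expression = log2_transform(fg$expression, pseudocount),
       report = c(fs$report, fg$report[c("genes_removed_sd",
                                         "genes_removed_zeros")],
                  list(scale_factors = uq$scale_factors)))
}
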