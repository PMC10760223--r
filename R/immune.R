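#' Immune signature definition
#'
#' A named list of member genes with an aggregation rule.  The median is
#' the default aggregator; the geometric mean is the convention for
#' cytotoxicity-style signatures.
#'
#' @param name Signature label.
#' @param genes Character vector of member genes.
#' @param aggregator `"median"` or `"geometric_mean"`.
#' @return Object of class `immune_signature`.
#' @export
immune_signature <- function(name, genes,
                             aggregator = c("median", "geometric_mean")) {
  structure(list(name = name, genes = as.character(genes),
                 aggregator = match.arg(aggregator)),
            class = "immune_signature")
}

#' Score an immune signature per patient
#'
#' Assigns each sample the median of its member-gene expression values, or
#' their geometric mean for cytotoxicity-style signatures.  The geometric
#' mean is taken on the linear scale: log2 data are exponentiated first
#' (undoing the `log2(x + pseudocount)` transform), and when non-positive
#' values are present the mean is stabilized as
#' `exp(mean(log(v + pseudocount))) - pseudocount`.  Member genes missing
#' from the matrix are dropped with a warning; if none remain, an error.
#'
#' @param expression Samples x genes matrix.
#' @param signature An [immune_signature()].
#' @param scale `"log2"` or `"linear"`, the scale of `expression`.
#' @param pseudocount Offset used when undoing the log2 transform and when
#'   guarding the geometric mean against zeros.
#' @return Named numeric vector, one score per sample.
#' @export
score_signature <- function(expression, signature,
                            scale = c("log2", "linear"), pseudocount = 1) {
  stopifnot(inherits(signature, "immune_signature"))
  scale <- match.arg(scale)
  x <- assert_matrix(expression, "expression")
  present <- intersect(signature$genes, colnames(x))
  if (!length(present)) {
    stop("no member gene of '", signature$name, "' present in expression")
  }
  if (length(present) < length(signature$genes)) {
    warning(length(signature$genes) - length(present),
            " member gene(s) of '", signature$name, "' missing; dropped")
  }
  m <- x[, present, drop = FALSE]
  score <- if (signature$aggregator == "median") {
    apply(m, 1, stats::median)
  } else {
    v <- if (scale == "log2") pmax(2^m - pseudocount, 0) else m
    if (any(v <= 0)) {
      exp(rowMeans(log(v + pseudocount))) - pseudocount
    } else {
      exp(rowMeans(log(v)))
    }
  }
  stats::setNames(as.numeric(score), rownames(x))
}

#' Read immune-signature definitions from a two-column table
#'
#' Loads a TSV with columns `signature` and `gene` into a list of
#' [immune_signature()] objects.  Signatures whose name matches
#' `geometric_mean_for` (default: cytotoxicity-style names) use the
#' geometric mean; all others the median.  The file shipped at
#' `system.file("extdata", "immune_signatures_synthetic.tsv", package =
#' "txnetsig")` is a synthetic placeholder illustrating the format — real
#' analyses supply their own curated gene lists.
#'
#' @param path Path to the definitions TSV.
#' @param geometric_mean_for Regular expression for signature names scored
#'   by geometric mean.
#' @return Named list of [immune_signature()] objects.
#' @export
read_immune_signatures <- function(path,
                                   geometric_mean_for = "cytotox") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("signature", "gene") %in% names(tab)))
  groups <- split(tab$gene, tab$signature)
  out <- lapply(names(groups), function(nm) {
    agg <- if (grepl(geometric_mean_for, nm, ignore.case = TRUE))
      "geometric_mean" else "median"
    immune_signature(nm, groups[[nm]], agg)
  })
  stats::setNames(out, names(groups))
}

#' Correlate sub-network genes with immune-signature scores
#'
#' Pearson correlation of every gene against every signature score, with a
#' display mask marking correlations of magnitude at least `r_display`
#' (the heatmap display rule).  Zero-variance columns give `NA`.
#'
#' @param expression Samples x genes matrix restricted to the genes of
#'   interest.
#' @param scores Samples x signatures matrix (or data frame) of
#'   [score_signature()] outputs.
#' @param r_display Magnitude threshold for the display mask.
#' @return List `r` (genes x signatures correlation matrix), `display`
#'   (logical mask `|r| >= r_display`).
#' @export
correlate_genes_with_scores <- function(expression, scores,
                                        r_display = 0.4) {
  x <- assert_matrix(expression, "expression")
  s <- assert_matrix(scores, "scores")
  if (nrow(x) < 3) stop("need at least 3 samples")
  r <- suppressWarnings(stats::cor(x, s))
  r[!is.finite(r)] <- NA_real_
  list(r = r, display = !is.na(r) & abs(r) >= r_display)
}
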