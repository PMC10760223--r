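#' Enumerate cis gene-SNP pairs
#'
#' Pairs every gene with the SNPs lying within `window` bp of its
#' transcription start site on the same chromosome (inclusive boundary, so a
#' SNP exactly `window` bp away still counts).  SNPs or genes on
#' chromosomes absent from the other table are skipped with a warning.
#'
#' @param gene_annot Data frame `gene`, `chrom`, `tss` (1-based).
#' @param snp_annot Data frame `snp`, `chrom`, `pos` (1-based).
#' @param window cis window half-width in bp.
#' @return Data frame `gene`, `snp`, `distance_tss` (signed, pos - tss).
#' @export
map_cis_pairs <- function(gene_annot, snp_annot, window = 1e6) {
  stopifnot(all(c("gene", "chrom", "tss") %in% names(gene_annot)),
            all(c("snp", "chrom", "pos") %in% names(snp_annot)))
  lost <- setdiff(snp_annot$chrom, gene_annot$chrom)
  if (length(lost)) {
    warning("skipping SNPs on chromosome(s) without genes: ",
            paste(lost, collapse = ", "))
  }
  gr_g <- GenomicRanges::GRanges(
    gene_annot$chrom,
    IRanges::IRanges(pmax(gene_annot$tss - window, 1), gene_annot$tss + window))
  gr_s <- GenomicRanges::GRanges(snp_annot$chrom,
                                 IRanges::IRanges(snp_annot$pos, width = 1))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_g, gr_s))
  gi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  out <- data.frame(gene = gene_annot$gene[gi], snp = snp_annot$snp[si],
                    distance_tss = snp_annot$pos[si] - gene_annot$tss[gi])
  out[order(out$gene, out$distance_tss), , drop = FALSE]
}

# Exact OLS slope inference for one predictor with optional covariates.
.ols_slope <- function(y, x, covariates = NULL) {
  X <- cbind(`(Intercept)` = rep(1, length(y)), design_from_df(covariates),
             dosage = x)
  qx <- qr(X)
  cf <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- length(y) - qx$rank
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * XtXinv[ncol(X), ncol(X)])
  t_stat <- cf[["dosage"]] / se
  list(beta = cf[["dosage"]], se = se, t_stat = t_stat,
       p_nominal = 2 * stats::pt(-abs(t_stat), df), df = df)
}

#' Single cis-eQTL linear regression
#'
#' Ordinary least squares of one gene's (adjusted) expression on one SNP's
#' dosage with covariates in the model; returns the dosage slope, its t
#' statistic and the two-sided p-value.
#'
#' @param y Expression vector for one gene.
#' @param dosage Dosage vector for one SNP.
#' @param covariates Optional covariate data frame or matrix.
#' @return List `beta`, `se`, `t_stat`, `p_nominal`, `df`, or `NULL` (with a
#'   warning) when the dosage is constant.
#' @export
fit_cis_regression <- function(y, dosage, covariates = NULL) {
  k <- if (is.null(covariates)) 0 else NCOL(design_from_df(covariates))
  if (length(y) <= k + 2) stop("need n > number of covariates + 2")
  if (stats::sd(dosage) == 0) {
    warning("constant dosage; slope undefined, pair skipped")
    return(NULL)
  }
  .ols_slope(y, dosage, covariates)
}

# Residualize y (and each column of M) on [1 | covariates], then scale to
# unit norm; the Frisch-Waugh device that makes permutation scans a single
# cross-product.
.residual_unit <- function(m, covariates = NULL) {
  X <- cbind(rep(1, nrow(m)), design_from_df(covariates))
  r <- qr.resid(qr(X), m)
  nrm <- sqrt(colSums(r^2))
  list(unit = sweep(r, 2, pmax(nrm, .Machine$double.eps), "/"), norm = nrm)
}

#' Gene-level permutation-adjusted cis-eQTL p-value
#'
#' Residualizes the expression vector and every cis dosage column on the
#' covariates once, then permutes the residualized expression.  Each
#' permutation records the best (smallest) nominal p over the gene's cis
#' SNPs — equivalently the largest absolute correlation, since all SNPs
#' share one degree-of-freedom count.  The empirical gene-level p-value is
#' `(r + 1) / (B + 1)` where `r` counts permutations whose best statistic
#' meets or beats the observed one, so it can never be exactly zero.  In
#' adaptive mode the scan stops early once `r_stop` exceedances accumulate,
#' scaling the estimate by the permutations actually done.
#'
#' @param y Expression vector for one gene.
#' @param dosages Samples x cis-SNPs dosage matrix.
#' @param covariates Optional covariates.
#' @param n_perm Maximum number of permutations (>= 10).
#' @param adaptive Stop early once `r_stop` exceedances are seen.
#' @param seed Optional integer seed.
#' @param r_stop Adaptive stopping count.
#' @param block Permutations generated per batch.
#' @return List `p_adjusted`, `best_snp`, `beta`, `p_nominal` (best
#'   observed), `n_exceed`, `n_perm_used`.
#' @export
permutation_adjust <- function(y, dosages, covariates = NULL, n_perm = 10000,
                               adaptive = TRUE, seed = NULL, r_stop = 50,
                               block = 200) {
  n_perm <- assert_count(n_perm, "n_perm", min = 10)
  D <- assert_matrix(dosages, "dosages")
  if (is.null(colnames(D))) colnames(D) <- paste0("snp", seq_len(ncol(D)))
  keep <- col_sds(D) > 0
  if (!any(keep)) stop("no cis SNP with non-zero variance")
  if (!all(keep)) {
    warning(sum(!keep), " constant cis SNP(s) skipped")
    D <- D[, keep, drop = FALSE]
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  k <- if (is.null(covariates)) 0 else NCOL(design_from_df(covariates))
  df <- n - k - 2
  ru <- .residual_unit(cbind(y, D), covariates)
  yu <- ru$unit[, 1]
  Du <- ru$unit[, -1, drop = FALSE]
  r_obs_all <- abs(as.numeric(crossprod(Du, yu)))
  best <- which.max(r_obs_all)
  r_obs <- r_obs_all[best]
  t_obs <- r_obs * sqrt(df) / sqrt(max(1 - r_obs^2, .Machine$double.eps))
  hits <- 0L
  done <- 0L
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    idx <- vapply(seq_len(b), function(.) sample.int(n), integer(n))
    Y <- matrix(yu[idx], n, b)
    best_perm <- apply(abs(crossprod(Du, Y)), 2, max)
    hits <- hits + sum(best_perm >= r_obs - 1e-12)
    done <- done + b
    if (adaptive && hits >= r_stop) break
  }
  beta_obs <- fit_cis_regression(y, D[, best], covariates)
  list(p_adjusted = (hits + 1) / (done + 1),
       best_snp = colnames(D)[best],
       beta = beta_obs$beta,
       p_nominal = 2 * stats::pt(-abs(t_obs), df),
       n_exceed = hits, n_perm_used = done)
}

#' Call eGenes from gene-level adjusted p-values
#'
#' An eGene has at least one cis-eQTL with gene-level empirical p strictly
#' below `alpha`.
#'
#' @param gene_p Data frame with columns `gene`, `p_adjusted` and optionally
#'   `best_snp`.
#' @param alpha Gene-level significance threshold.
#' @return Subset of `gene_p` rows that qualify (possibly empty).
#' @export
select_egenes <- function(gene_p, alpha = 0.05) {
  stopifnot(all(c("gene", "p_adjusted") %in% names(gene_p)))
  gene_p[gene_p$p_adjusted < alpha, , drop = FALSE]
}

#' cis-eQTL scan over all genes
#'
#' Convenience wrapper running [map_cis_pairs()] and [permutation_adjust()]
#' for every gene with at least one cis SNP.
#'
#' @param expression Samples x genes matrix (already covariate-adjusted, or
#'   pass `covariates`).
#' @param genotypes Samples x SNPs dosage matrix.
#' @param gene_annot,snp_annot Annotation tables as in [map_cis_pairs()].
#' @param covariates Optional covariates forwarded to the per-gene scan.
#' @param window cis window (bp).
#' @param n_perm,adaptive,seed Permutation settings; per-gene seeds are
#'   derived from `seed`.
#' @return List with `gene_p` (gene, best_snp, beta, p_nominal, p_adjusted)
#'   and `cis_pairs`.
#' @export
eqtl_scan <- function(expression, genotypes, gene_annot, snp_annot,
                      covariates = NULL, window = 1e6, n_perm = 1000,
                      adaptive = TRUE, seed = 1) {
  pairs <- map_cis_pairs(gene_annot, snp_annot, window)
  genes <- intersect(colnames(expression), unique(pairs$gene))
  seeds <- derive_seeds(seed, max(length(genes), 1))
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    snps <- intersect(pairs$snp[pairs$gene == g], colnames(genotypes))
    if (!length(snps)) next
    fit <- permutation_adjust(expression[, g],
                              genotypes[, snps, drop = FALSE],
                              covariates, n_perm = n_perm,
                              adaptive = adaptive, seed = seeds[i])
    rows[[i]] <- data.frame(gene = g, best_snp = fit$best_snp,
                            beta = fit$beta, p_nominal = fit$p_nominal,
                            p_adjusted = fit$p_adjusted)
  }
  gene_p <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  list(gene_p = gene_p %||%
         data.frame(gene = character(), best_snp = character(),
                    beta = numeric(), p_nominal = numeric(),
                    p_adjusted = numeric()),
       cis_pairs = pairs)
}

#' Matched null SNP sets for enrichment testing
#'
#' Bins every SNP in the universe on each matching feature using
#' equal-frequency bins, forms the joint bin, and draws each null set by
#' replacing every target SNP with a SNP from the same joint bin, without
#' replacement within a set.  When a bin runs out of candidates it is
#' relaxed to the nearest bin (Euclidean distance between bin index
#' vectors), with a warning.
#'
#' @param target_snps Character vector of target SNP ids (subset of the
#'   universe).
#' @param features Data frame with a `snp` column plus numeric matching
#'   feature columns (e.g. maf, gene density, TSS distance).
#' @param n_sets Number of null sets.
#' @param bins Equal-frequency bins per feature.
#' @param seed Optional integer seed.
#' @return List of `n_sets` character vectors, each of length
#'   `length(target_snps)`.
#' @export
matched_null_sets <- function(target_snps, features, n_sets = 1000, bins = 5,
                              seed = NULL) {
  stopifnot("snp" %in% names(features))
  if (!all(target_snps %in% features$snp)) {
    stop("every target SNP must appear in `features`")
  }
  if (!is.null(seed)) set.seed(seed)
  fcols <- setdiff(names(features), "snp")
  if (!length(fcols)) {
    bin_id <- rep(1L, nrow(features))
    bin_mat <- matrix(1L, nrow(features), 1)
  } else {
    bin_mat <- vapply(fcols, function(f) {
      v <- features[[f]]
      br <- unique(stats::quantile(v, seq(0, 1, length.out = bins + 1),
                                   names = FALSE))
      if (length(br) < 2) return(rep(1L, length(v)))
      findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
    }, integer(nrow(features)))
    bin_id <- as.integer(factor(apply(bin_mat, 1, paste, collapse = ":")))
  }
  pools <- split(features$snp, bin_id)
  # per-bin mean index vector, for nearest-bin relaxation
  centers <- do.call(rbind, lapply(split(seq_len(nrow(features)), bin_id),
                                   function(i) colMeans(bin_mat[i, , drop = FALSE])))
  t_bin <- bin_id[match(target_snps, features$snp)]
  need <- table(t_bin)
  # fast path: every matching bin has enough candidates, so the bins can be
  # sampled independently (they are disjoint) for all sets at once
  if (all(vapply(names(need), function(b) length(pools[[b]]) >= need[[b]],
                 logical(1)))) {
    parts <- lapply(names(need), function(b) {
      pool <- pools[[b]]
      m <- need[[b]]
      draws <- vapply(seq_len(n_sets), function(.) {
        if (length(pool) == m) pool else sample(pool, m)
      }, character(m))
      matrix(draws, nrow = m)
    })
    big <- do.call(rbind, parts)
    return(lapply(seq_len(n_sets), function(j) big[, j]))
  }
  relax_warned <- FALSE
  draw_set <- function() {
    out <- character(0)
    used <- character(0)
    for (b in names(need)) {
      m <- need[[b]]
      pool <- setdiff(pools[[b]], used)
      if (length(pool) < m) {
        if (!relax_warned) {
          warning("matching bin exhausted; relaxing to nearest bin(s)")
          relax_warned <<- TRUE
        }
        dists <- sqrt(rowSums(sweep(centers, 2, centers[b, ])^2))
        for (nb in names(sort(dists))[-1]) {
          pool <- c(pool, setdiff(pools[[nb]], c(used, pool)))
          if (length(pool) >= m) break
        }
        if (length(pool) < m) stop("universe too small for matched sampling")
      }
      got <- if (length(pool) == m) pool else sample(pool, m)
      out <- c(out, got)
      used <- c(used, got)
    }
    out
  }
  lapply(seq_len(n_sets), function(.) draw_set())
}

#' Enrichment z-score of SNPs in genomic intervals
#'
#' Counts target SNPs falling inside any interval (BED semantics: 0-based,
#' half-open, so a 1-based SNP position `p` overlaps `[start, end)` when
#' `start < p <= end`), repeats the count for each matched null set, and
#' standardizes: `z = (observed - null mean) / null SD`.  A degenerate null
#' (SD 0) yields `z = NA` with `z_defined = FALSE`.
#'
#' @param target_snps Character vector of SNP ids.
#' @param snp_annot Data frame `snp`, `chrom`, `pos` covering targets and
#'   null sets.
#' @param intervals Data frame `chrom`, `start`, `end` (BED convention),
#'   e.g. from [read_bed()].
#' @param null_sets List of null SNP-id sets from [matched_null_sets()].
#' @param annotation Name recorded in the result.
#' @return List `annotation`, `observed`, `null_mean`, `null_sd`, `z`,
#'   `z_defined`.
#' @export
region_enrichment_z <- function(target_snps, snp_annot, intervals, null_sets,
                                annotation = "intervals") {
  if (length(null_sets) < 2) stop("need >= 2 null sets")
  gr_int <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(intervals$start + 1, intervals$end))
  gr_snp <- GenomicRanges::GRanges(snp_annot$chrom,
                                   IRanges::IRanges(snp_annot$pos, width = 1))
  in_interval <- GenomicRanges::countOverlaps(gr_snp, gr_int) > 0
  count_in <- function(snps) {
    idx <- match(snps, snp_annot$snp)
    if (anyNA(idx)) stop("SNP ids missing from `snp_annot`")
    sum(in_interval[idx])
  }
  observed <- count_in(target_snps)
  null_counts <- vapply(null_sets, count_in, numeric(1))
  mu <- mean(null_counts)
  sdv <- stats::sd(null_counts)
  list(annotation = annotation, observed = observed, null_mean = mu,
       null_sd = sdv,
       z = if (sdv > 0) (observed - mu) / sdv else NA_real_,
       z_defined = sdv > 0)
}

#' Read a BED file of annotation intervals
#'
#' Minimal three-column BED reader (chrom, start, end; 0-based half-open)
#' with strict validation: non-numeric coordinates or `start >= end` raise a
#' parse error naming the offending line.
#'
#' @param path Path to a BED file.
#' @return Data frame `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  out <- vector("list", sum(keep))
  j <- 0
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop(sprintf("BED parse error at line %d: < 3 fields", i))
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("BED parse error at line %d: non-numeric coordinates", i))
    }
    if (start >= end) {
      stop(sprintf("BED parse error at line %d: start >= end", i))
    }
    j <- j + 1
    out[[j]] <- data.frame(chrom = f[1], start = start, end = end)
  }
  if (j == 0) return(data.frame(chrom = character(), start = numeric(),
                                end = numeric()))
  do.call(rbind, out)
}
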