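#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with the study's
#' published value as default: gene/sample filters, cell-type enrichment
#' rules, the 1 Mb cis window with 10,000 adaptive permutations and the
#' 0.05 eGene level, 4 gene clusters, the `10^-i, i = 3..22` alpha grid
#' with FDR `q = 0.05` and the breakpoint rule, the 0.5 edge-validation
#' correlation, the 0.1 signature p-threshold and third-quartile
#' dichotomization, and the instrument-orientation levels.  The object
#' round-trips through YAML unchanged.
#'
#' @param seed Root seed; each stage derives a named sub-seed from it.
#' @param sd_min,max_zero_frac Gene-filter thresholds.
#' @param max_zero_gene_frac Sample-filter threshold.
#' @param cell_max_zero_frac,cell_sd_min Cell-type enrichment rules.
#' @param cis_window cis window half-width (bp).
#' @param n_perm,adaptive Permutation settings for the eQTL scan.
#' @param egene_alpha Gene-level eGene threshold.
#' @param k_clusters Gene clusters for network learning.
#' @param alpha_grid Integer exponents of the stability grid.
#' @param max_order PC conditioning order.
#' @param fdr_q FDR edge-screen level.
#' @param breakpoint_rule Candidate rule of [piecewise_breakpoint()].
#' @param alpha_iv,alpha_cond Instrument-orientation levels.
#' @param r_min Edge-validation correlation threshold.
#' @param p_max Signature significance threshold.
#' @param quantile_type Quantile convention (Q3 splits, UQ normalization).
#' @param stages Character vector of stages to run in [run_all()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, sd_min = 0.5, max_zero_frac = 0.30,
                            max_zero_gene_frac = 0.50,
                            cell_max_zero_frac = 0.30, cell_sd_min = 0.1,
                            cis_window = 1e6, n_perm = 10000,
                            adaptive = TRUE, egene_alpha = 0.05,
                            k_clusters = 4, alpha_grid = 3:22,
                            max_order = 3, fdr_q = 0.05,
                            breakpoint_rule = "min_p",
                            alpha_iv = 0.05, alpha_cond = 0.05,
                            r_min = 0.5, p_max = 0.1, quantile_type = 7,
                            stages = c("preprocess", "eqtl", "network",
                                       "validate", "subnetworks", "survival",
                                       "immune")) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write a cohort bundle to plain-text files
#'
#' Emits the same formats the pipeline reads: expression TSV (genes x
#' samples), genotype dosage TSV plus a minimal VCF (dosage re-encoded as
#' GT), annotation TSVs, covariates, cell fractions, survival, the
#' train/test split, and the generating configuration as YAML when
#' supplied.
#'
#' @param bundle A [cohort_bundle()].
#' @param dir Output directory (created if needed).
#' @param config Optional configuration list serialized alongside.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f, rn = FALSE) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE)
  }
  w(t(bundle$expression), "expression.tsv", rn = TRUE)
  w(t(bundle$genotypes), "genotypes.tsv", rn = TRUE)
  write_minimal_vcf(bundle$genotypes, bundle$snp_annot,
                    file.path(dir, "genotypes.vcf"))
  w(bundle$gene_annot, "gene_annot.tsv")
  w(bundle$snp_annot, "snp_annot.tsv")
  w(bundle$covariates, "covariates.tsv")
  w(bundle$cell_fractions, "cell_fractions.tsv", rn = TRUE)
  w(cbind(sample = rownames(bundle$survival), bundle$survival),
    "survival.tsv")
  w(data.frame(sample = names(bundle$split), split = unname(bundle$split)),
    "split.tsv")
  writeLines(bundle$scale, file.path(dir, "scale.txt"))
  if (!is.null(config)) {
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

# Minimal VCFv4.2 writer: dosage 0/1/2 -> GT 0/0, 0/1, 1/1.
write_minimal_vcf <- function(genotypes, snp_annot, path) {
  gt <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(genotypes)), function(j) {
    i <- match(colnames(genotypes)[j], snp_annot$snp)
    paste(c(snp_annot$chrom[i], snp_annot$pos[i], snp_annot$snp[i],
            "A", "G", ".", "PASS", ".", "GT",
            gt[genotypes[, j] + 1]), collapse = "\t")
  }, character(1))
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       rownames(genotypes)), collapse = "\t"),
               body), path)
}

#' Read genotype dosages from a minimal VCF
#'
#' Extracts the GT field and counts alternate alleles, returning a samples
#' x SNPs dosage matrix.  Uses the vcfR parser when available, otherwise a
#' strict fallback for the minimal files written by [write_cohort()].
#'
#' @param path VCF path.
#' @return Samples x SNPs integer dosage matrix.
#' @export
read_vcf_dosage <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    d <- apply(gt, 2, function(col)
      vapply(strsplit(col, "[/|]"), function(a) sum(a != "0"), numeric(1)))
    d <- matrix(as.integer(d), nrow = nrow(gt),
                dimnames = list(rownames(gt), colnames(gt)))
    return(t(d))
  }
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("VCF parse error: missing #CHROM header")
  cols <- strsplit(lines[hdr], "\t")[[1]]
  samples <- cols[-(1:9)]
  rows <- lines[-seq_len(hdr)]
  d <- t(vapply(rows, function(ln) {
    f <- strsplit(ln, "\t")[[1]]
    vapply(f[-(1:9)], function(g)
      sum(strsplit(g, "[/|]")[[1]] != "0"), numeric(1))
  }, numeric(length(samples))))
  ids <- vapply(rows, function(ln) strsplit(ln, "\t")[[1]][3], character(1))
  t(matrix(as.integer(d), nrow = length(rows),
           dimnames = list(ids, samples)))
}

#' Read pipeline inputs into an aligned cohort bundle
#'
#' Loads expression (genes x samples TSV), genotypes (dosage TSV or VCF),
#' annotations, covariates, cell fractions, survival and split tables, and
#' aligns them on the expression sample set.  Samples missing from any
#' required table raise an error naming the offenders.
#'
#' @param dir Directory produced by [write_cohort()], or `NULL` when
#'   `paths` is given.
#' @param paths Optional named list of file paths overriding the directory
#'   layout (`expression`, `genotypes`, `gene_annot`, `snp_annot`,
#'   `covariates`, `cell_fractions`, `survival`, `split`).
#' @return A [cohort_bundle()].
#' @export
read_inputs <- function(dir = NULL, paths = NULL) {
  p <- function(f) paths[[f]] %||% file.path(dir, paste0(f, ".tsv"))
  rt <- function(f, rn = FALSE) {
    utils::read.table(p(f), sep = "\t", header = TRUE,
                      row.names = if (rn) 1 else NULL,
                      check.names = FALSE, stringsAsFactors = FALSE)
  }
  expr <- t(as.matrix(rt("expression", rn = TRUE)))
  geno_path <- paths[["genotypes"]] %||% file.path(dir, "genotypes.tsv")
  geno <- if (grepl("\\.vcf$", geno_path)) read_vcf_dosage(geno_path) else
    t(as.matrix(utils::read.table(geno_path, sep = "\t", header = TRUE,
                                  row.names = 1, check.names = FALSE)))
  samples <- rownames(expr)
  for (comp in list(c("genotypes", "matrix"), c("covariates", "df"),
                    c("cell_fractions", "matrix"), c("survival", "df"),
                    c("split", "df"))) {
    obj_samples <- switch(comp[1],
                          genotypes = rownames(geno),
                          covariates = rt("covariates")$sample,
                          cell_fractions = rownames(rt("cell_fractions",
                                                       rn = TRUE)),
                          survival = rt("survival")$sample,
                          split = rt("split")$sample)
    miss <- setdiff(samples, obj_samples)
    if (length(miss)) {
      stop("sample(s) missing from ", comp[1], ": ",
           paste(miss, collapse = ", "))
    }
  }
  covar <- rt("covariates")
  cf <- as.matrix(rt("cell_fractions", rn = TRUE))
  surv <- rt("survival")
  rownames(surv) <- surv$sample
  split_df <- rt("split")
  scale_path <- paths[["scale"]] %||% file.path(dir, "scale.txt")
  scale <- if (file.exists(scale_path)) readLines(scale_path)[1] else "log2"
  cohort_bundle(
    expression = expr,
    genotypes = geno[samples, , drop = FALSE],
    gene_annot = rt("gene_annot"), snp_annot = rt("snp_annot"),
    covariates = covar[match(samples, covar$sample), , drop = FALSE],
    cell_fractions = cf[samples, , drop = FALSE],
    survival = surv[samples, c("time", "event"), drop = FALSE],
    split = stats::setNames(split_df$split,
                            split_df$sample)[samples],
    scale = scale)
}

# Write one result table with a provenance header.
write_stage_table <- function(x, path, stage, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# stage: %s\tconfig_hash: %s", stage, hash), con)
  suppressWarnings(utils::write.table(x, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, col.names = TRUE))
  close(con)
}

#' Run the full analysis pipeline
#'
#' Orchestrates preprocess -> cis-eQTL -> network learning (cluster, PC,
#' stability selection, orientation) -> held-out edge validation ->
#' sub-network extraction -> per-arm residualized Cox signatures with
#' Kaplan-Meier stratification.  Deterministic given `config$seed`.  A
#' stage absent from `config$stages` is skipped and its outputs are taken
#' from `prior` (a previous result), so stages can be toggled
#' individually.
#'
#' @param bundle A [cohort_bundle()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage writes its
#'   tables (TSV with a header naming the stage and config hash) plus a
#'   plain-text report.
#' @param priors Optional data frame `from`, `to` of prior-knowledge edge
#'   orientations.
#' @param prior Optional previous `txnetsig_result` supplying outputs of
#'   skipped stages.
#' @param immune_signatures Optional list of [immune_signature()] objects
#'   (e.g. from [read_immune_signatures()]); when given, sub-network genes
#'   are correlated against the per-sample scores.
#' @return List of class `txnetsig_result` with elements `expression_adj`,
#'   `enriched_cell_types`, `genotype_pc1`, `eqtl`, `egenes`, `clusters`,
#'   `networks`, `network`, `edge_table`, `validation`, `subnetworks`,
#'   `fits`, `signatures`, `stratification`, `config`.
#' @export
run_all <- function(bundle, config = pipeline_config(), out_dir = NULL,
                    priors = NULL, prior = NULL, immune_signatures = NULL) {
  stopifnot(inherits(bundle, "cohort_bundle"),
            inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  seeds <- derive_seeds(config$seed, 4,
                        c("eqtl", "cluster", "network", "survival"))
  res <- prior %||% list()
  res$config <- config
  on <- function(stage) stage %in% config$stages
  log_lines <- c(sprintf("txnetsig run, config hash %s", hash),
                 utils::capture.output(utils::str(unclass(config))))
  emit <- function(x, name, stage) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_stage_table(x, file.path(out_dir, paste0(name, ".tsv")),
                        stage, hash)
    }
  }

  train <- names(bundle$split)[bundle$split == "train"]
  test <- names(bundle$split)[bundle$split == "test"]

  if (on("preprocess")) {
    expr <- bundle$expression
    rep_pre <- NULL
    if (bundle$scale == "counts") {
      pc <- preprocess_counts(expr, config$sd_min, config$max_zero_frac,
                              config$max_zero_gene_frac)
      expr <- pc$expression
      rep_pre <- pc$report
    }
    enriched <- enrich_cell_types(bundle$cell_fractions,
                                  config$cell_max_zero_frac,
                                  config$cell_sd_min)
    pc1 <- genotype_pc1(bundle$genotypes[rownames(expr), , drop = FALSE])
    covar <- bundle$covariates[match(rownames(expr),
                                     bundle$covariates$sample), ]
    adj_covar <- covar[, setdiff(names(covar), c("sample", "arm")),
                       drop = FALSE]
    adj_covar$geno_pc1 <- pc1
    res$expression_adj <- adjust_expression(
      expr, adj_covar,
      bundle$cell_fractions[rownames(expr), enriched, drop = FALSE])
    res$enriched_cell_types <- enriched
    res$genotype_pc1 <- pc1
    res$preprocess_report <- rep_pre
    log_lines <- c(log_lines,
                   sprintf("preprocess: %d samples x %d genes; enriched cell types: %s",
                           nrow(res$expression_adj), ncol(res$expression_adj),
                           paste(enriched, collapse = ",")))
  }
  expr_adj <- res$expression_adj
  if (is.null(expr_adj)) stop("preprocess outputs unavailable")

  if (on("eqtl")) {
    scan <- eqtl_scan(expr_adj[train, , drop = FALSE],
                      bundle$genotypes[train, , drop = FALSE],
                      bundle$gene_annot, bundle$snp_annot,
                      window = config$cis_window, n_perm = config$n_perm,
                      adaptive = config$adaptive, seed = seeds[["eqtl"]])
    res$eqtl <- scan$gene_p
    res$egenes <- select_egenes(scan$gene_p, config$egene_alpha)
    emit(res$eqtl, "eqtl_gene_p", "eqtl")
    emit(res$egenes, "egenes", "eqtl")
    log_lines <- c(log_lines,
                   sprintf("eqtl: %d genes scanned (window %g bp, %d perms), %d eGenes at alpha %g",
                           nrow(res$eqtl), config$cis_window, config$n_perm,
                           nrow(res$egenes), config$egene_alpha))
  }

  if (on("network")) {
    tr <- expr_adj[train, , drop = FALSE]
    res$clusters <- cluster_genes(tr, k = config$k_clusters,
                                  seed = seeds[["cluster"]])
    nets <- list()
    stable <- list()
    fdr_all <- list()
    for (cl in sort(unique(res$clusters))) {
      genes_cl <- names(res$clusters)[res$clusters == cl]
      if (length(genes_cl) < 2) {
        nets[[as.character(cl)]] <- gene_network(genes_cl)
        next
      }
      dat <- tr[, genes_cl, drop = FALSE]
      curve <- stability_curve(dat, config$alpha_grid, config$max_order)
      bp <- piecewise_breakpoint(curve, rule = config$breakpoint_rule)
      hd_net <- curve$networks[[which.min(abs(curve$alphas - bp$alpha))]]
      fdr <- edge_fdr_selection(dat, q = config$fdr_q,
                                max_order = config$max_order)
      st <- stable_edges(fdr, hd_net)
      net_cl <- gene_network(genes_cl, skeleton = st,
                             sepsets = hd_net$sepsets,
                             test_max_p = hd_net$test_max_p)
      net_cl <- orient_v_structures(net_cl)
      if (!is.null(res$egenes) && nrow(res$egenes)) {
        net_cl <- orient_with_instruments(
          net_cl, res$egenes, bundle$genotypes[train, , drop = FALSE],
          tr, config$alpha_iv, config$alpha_cond)
      }
      nets[[as.character(cl)]] <- net_cl
      stable[[as.character(cl)]] <- st
      fdr_all[[as.character(cl)]] <- fdr[fdr$selected, , drop = FALSE]
      log_lines <- c(log_lines,
                     sprintf("network cluster %s: %d genes, alpha* = %g, %d stable edges",
                             cl, length(genes_cl), bp$alpha, nrow(st)))
    }
    res$networks <- nets
    # merged network over all clusters (within-cluster edges only)
    merged_skel <- do.call(rbind, lapply(nets, function(n) n$skeleton))
    merged_dir <- do.call(rbind, lapply(nets, function(n) n$directed))
    merged_sep <- do.call(c, unname(lapply(nets, function(n) n$sepsets)))
    res$network <- gene_network(colnames(tr), skeleton = merged_skel,
                                directed = merged_dir,
                                sepsets = merged_sep)
    if (!is.null(priors)) res$network <- apply_prior_edges(res$network, priors)
    res$stable_fdr <- do.call(rbind, fdr_all)
    res$stable_hd <- do.call(rbind, stable)
  }

  if (on("validate") && !is.null(res$network)) {
    res$validation <- validate_edges(expr_adj[train, , drop = FALSE],
                                     expr_adj[test, , drop = FALSE],
                                     res$network, r_min = config$r_min)
    log_lines <- c(log_lines,
                   sprintf("validate: %.1f%% of testable links validated (r > %g, %d test samples)",
                           100 * res$validation$fraction, config$r_min,
                           length(test)))
  }
  if (!is.null(res$network)) {
    res$edge_table <- network_edge_table(res$network,
                                         stable_fdr = res$stable_fdr,
                                         stable_hd = res$stable_hd,
                                         validation = res$validation$edges)
    emit(res$edge_table, "network_edges", "network")
  }

  if (on("subnetworks") && !is.null(res$network)) {
    anchors <- intersect(res$egenes$gene, res$network$nodes)
    res$subnetworks <- extract_subnetworks(res$network, anchors)
    log_lines <- c(log_lines, sprintf("subnetworks: %d eGene anchors",
                                      length(res$subnetworks)))
  }

  if (on("survival") && length(res$subnetworks)) {
    arms <- bundle$arms
    covar <- bundle$covariates
    fits <- list()
    sigs <- list()
    strat <- list()
    for (sn in res$subnetworks) {
      for (a in arms) {
        in_arm <- covar$arm == a
        if (sum(bundle$survival$event[in_arm]) < 10) next
        fit <- tryCatch(
          fit_cox_subnetwork(bundle$survival, sn, expr_adj,
                             covariates = covar,
                             cell_fractions = bundle$cell_fractions[
                               , res$enriched_cell_types, drop = FALSE],
                             arm = covar$arm, arm_label = a),
          error = function(e) NULL)
        if (is.null(fit)) next
        fits[[paste(sn$anchor, a, sep = ".")]] <- fit
        sig <- define_signature(fit, p_max = config$p_max)
        sigs[[paste(sn$anchor, a, sep = ".")]] <- sig
        if (nrow(sig$genes)) {
          grp <- stratify_patients(sig, expr_adj[in_arm, , drop = FALSE],
                                   config$quantile_type)
          km <- km_estimate(bundle$survival$time[in_arm],
                            bundle$survival$event[in_arm], grp)
          lr <- if (nlevels(droplevels(grp)) >= 2) {
            logrank_test(bundle$survival$time[in_arm],
                         bundle$survival$event[in_arm], grp)
          }
          strat[[paste(sn$anchor, a, sep = ".")]] <-
            list(groups = grp, km = km, logrank = lr)
        }
      }
    }
    res$fits <- fits
    res$signatures <- sigs
    res$stratification <- strat
    if (length(fits)) emit(do.call(rbind, fits), "cox_fits", "survival")
    log_lines <- c(log_lines,
                   sprintf("survival: %d sub-network x arm fits, %d non-empty signatures",
                           length(fits),
                           sum(vapply(sigs, function(s) nrow(s$genes) > 0,
                                      logical(1)))))
  }

  if (on("immune") && !is.null(immune_signatures) &&
      length(res$subnetworks)) {
    present <- vapply(immune_signatures, function(s)
      any(s$genes %in% colnames(bundle$expression)), logical(1))
    if (!all(present)) {
      warning(sum(!present), " immune signature(s) with no member gene in ",
              "the expression matrix skipped")
      immune_signatures <- immune_signatures[present]
    }
    scores <- vapply(immune_signatures, function(s)
      score_signature(bundle$expression, s, scale = bundle$scale),
      numeric(nrow(bundle$expression)))
    sub_genes <- sort(unique(unlist(lapply(res$subnetworks,
                                           function(s) s$members))))
    res$immune <- correlate_genes_with_scores(
      expr_adj[, sub_genes, drop = FALSE],
      scores[rownames(expr_adj), , drop = FALSE])
    emit(data.frame(gene = rownames(res$immune$r), res$immune$r,
                    check.names = FALSE), "immune_correlations", "immune")
    log_lines <- c(log_lines,
                   sprintf("immune: %d signatures scored against %d sub-network genes",
                           ncol(scores), length(sub_genes)))
  }

  if (!is.null(out_dir)) {
    writeLines(log_lines, file.path(out_dir, "report.txt"))
  }
  structure(res, class = "txnetsig_result")
}

#' @export
print.txnetsig_result <- function(x, ...) {
  cat("txnetsig_result\n")
  if (!is.null(x$expression_adj)) {
    cat(sprintf("  adjusted expression: %d x %d\n", nrow(x$expression_adj),
                ncol(x$expression_adj)))
  }
  if (!is.null(x$egenes)) cat(sprintf("  eGenes: %d\n", nrow(x$egenes)))
  if (!is.null(x$network)) {
    cat(sprintf("  network: %d stable edges (%d directed)\n",
                nrow(x$network$skeleton), nrow(x$network$directed)))
  }
  if (!is.null(x$signatures)) {
    cat(sprintf("  signatures: %d (non-empty: %d)\n", length(x$signatures),
                sum(vapply(x$signatures, function(s) nrow(s$genes) > 0,
                           logical(1)))))
  }
  invisible(x)
}
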