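#' Ground-truth generative model for a synthetic cohort
#'
#' Bundles everything the synthetic-data generator needs to produce a cohort
#' and everything downstream recovery tests need to score themselves against:
#' a gene DAG with linear structural-equation weights, per-gene noise levels
#' and means, a cis-eQTL map (which SNP drives which gene and how strongly),
#' per-arm Cox log hazard ratios for the survival generator, the exponential
#' baseline hazard and the target censoring fraction.
#'
#' @param genes Character vector of gene ids.
#' @param edges Data frame with columns `from`, `to`; must be acyclic.
#' @param weights Numeric vector of SEM edge weights aligned with `edges`
#'   rows.
#' @param noise_sd Named positive numeric vector of per-gene noise SDs
#'   (recycled if length 1).
#' @param gene_mean Named numeric vector of per-gene baseline means
#'   (recycled if length 1).
#' @param eqtl Data frame with columns `gene`, `snp`, `beta`, or `NULL`.
#' @param cox_effects Data frame with columns `arm`, `gene`, `log_hr`, or
#'   `NULL`.
#' @param baseline_hazard Positive exponential baseline hazard, events per
#'   month.
#' @param censor_rate Target fraction of censored observations in `[0, 1)`.
#'
#' @return An object of class `true_model` with a `topo_order` field.
#' @export
true_model <- function(genes, edges, weights = NULL, noise_sd = 1,
                       gene_mean = 0, eqtl = NULL, cox_effects = NULL,
                       baseline_hazard = log(2) / 30, censor_rate = 0.3) {
  genes <- as.character(genes)
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    stopifnot(all(c("from", "to") %in% names(edges)))
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (!all(c(edges$from, edges$to) %in% genes)) {
      stop("edges reference genes missing from `genes`")
    }
  } else {
    edges <- data.frame(from = character(), to = character())
  }
  topo <- topological_order(genes, edges)
  if (is.null(topo)) stop("`edges` contain a directed cycle; not a DAG")
  if (is.null(weights)) weights <- rep(1, nrow(edges))
  if (length(weights) != nrow(edges)) stop("one weight per edge required")
  expand <- function(v, default) {
    out <- rep(default, length(genes))
    names(out) <- genes
    if (length(v) == 1 && is.null(names(v))) out[] <- v else out[names(v)] <- v
    out
  }
  noise_sd <- expand(noise_sd, 1)
  if (any(noise_sd < 0)) stop("`noise_sd` must be non-negative")
  if (baseline_hazard <= 0) stop("`baseline_hazard` must be positive")
  censor_rate <- assert_prob(censor_rate, "censor_rate")
  structure(list(
    genes = genes, edges = edges, weights = as.numeric(weights),
    noise_sd = noise_sd, gene_mean = expand(gene_mean, 0),
    eqtl = eqtl, cox_effects = cox_effects,
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    topo_order = topo
  ), class = "true_model")
}

# Kahn topological sort; returns NULL when a cycle exists.
topological_order <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    tab <- table(edges$to)
    indeg[names(tab)] <- as.integer(tab)
  }
  out <- character(0)
  avail <- sort(names(indeg)[indeg == 0])
  indeg <- indeg
  edges_left <- edges
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    out <- c(out, v)
    if (nrow(edges_left)) {
      hit <- edges_left$from == v
      for (w in edges_left$to[hit]) {
        indeg[w] <- indeg[w] - 1L
        if (indeg[w] == 0L) avail <- sort(c(avail, w))
      }
      edges_left <- edges_left[!hit, , drop = FALSE]
    }
  }
  if (length(out) != length(nodes)) NULL else out
}

#' @export
print.true_model <- function(x, ...) {
  cat(sprintf("true_model: %d genes, %d edges, %d eQTL genes, %d Cox effects\n",
              length(x$genes), nrow(x$edges),
              if (is.null(x$eqtl)) 0L else nrow(x$eqtl),
              if (is.null(x$cox_effects)) 0L else nrow(x$cox_effects)))
  invisible(x)
}

#' Simulate a random gene DAG
#'
#' Draws a random topological order of the genes and includes each forward
#' pair as a directed edge independently with probability `edge_prob`, so the
#' result is acyclic by construction.
#'
#' @param n_genes Number of genes (>= 2).
#' @param edge_prob Probability of each forward pair being an edge.
#' @param seed Optional integer seed.
#' @return A partial [true_model()] carrying the edge set (unit weights,
#'   unit noise).
#' @export
simulate_dag <- function(n_genes, edge_prob, seed = NULL) {
  n_genes <- assert_count(n_genes, "n_genes", min = 2)
  edge_prob <- assert_prob(edge_prob, "edge_prob")
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  rank <- sample(n_genes)
  ord <- genes[order(rank)]
  from <- character(0); to <- character(0)
  if (edge_prob > 0) {
    for (i in seq_len(n_genes - 1)) {
      take <- stats::runif(n_genes - i) < edge_prob
      if (any(take)) {
        from <- c(from, rep(ord[i], sum(take)))
        to <- c(to, ord[(i + 1):n_genes][take])
      }
    }
  }
  true_model(genes, data.frame(from = from, to = to))
}

#' Simulate genotype dosages
#'
#' Each SNP's dosage is drawn independently as Binomial(2, maf)
#' (Hardy-Weinberg proportions), emulating post-QC common variants.
#'
#' @param n_samples,n_snps Dimensions of the dosage matrix.
#' @param maf_range Length-1 or length-2 numeric in `(0, 0.5]`; per-SNP minor
#'   allele frequencies are drawn uniformly from this interval.
#' @param seed Optional integer seed.
#' @param chrom Chromosome label used in the annotation.
#' @param positions Optional integer vector of 1-based SNP positions; drawn
#'   uniformly on a 250 Mb synthetic chromosome when omitted.
#' @return List with `genotypes` (samples x SNPs, entries 0/1/2) and
#'   `snp_annot` (snp, chrom, pos, maf).
#' @export
simulate_genotypes <- function(n_samples, n_snps, maf_range = c(0.05, 0.5),
                               seed = NULL, chrom = "1", positions = NULL) {
  n_samples <- assert_count(n_samples, "n_samples")
  n_snps <- assert_count(n_snps, "n_snps")
  if (any(maf_range <= 0) || any(maf_range > 0.5)) {
    stop("`maf_range` must lie in (0, 0.5]")
  }
  if (!is.null(seed)) set.seed(seed)
  maf <- if (length(maf_range) == 1) rep(maf_range, n_snps) else
    stats::runif(n_snps, maf_range[1], maf_range[2])
  geno <- matrix(stats::rbinom(n_samples * n_snps, 2, rep(maf, each = n_samples)),
                 nrow = n_samples)
  snps <- sprintf("rs%05d", seq_len(n_snps))
  colnames(geno) <- snps
  rownames(geno) <- sprintf("s%04d", seq_len(n_samples))
  if (is.null(positions)) positions <- sort(sample.int(2.5e8, n_snps))
  list(genotypes = geno,
       snp_annot = data.frame(snp = snps, chrom = chrom,
                              pos = as.integer(positions), maf = maf))
}

#' Simulate expression from a linear structural equation model
#'
#' Generates genes in topological order: each gene is a weighted sum of its
#' parents, plus a cis-eQTL dosage term when the gene is an eGene in the
#' model, plus optional cell-fraction loadings, plus Gaussian noise and a
#' baseline mean.  The output is on the log2-like continuous scale the
#' network stage's Gaussian partial-correlation tests assume.
#'
#' @param model A [true_model()].
#' @param genotypes Dosage matrix (samples x SNPs) covering `model$eqtl`
#'   SNPs; may be `NULL` when the model has no eQTL map.
#' @param cell_fractions Optional samples x cell-type matrix.
#' @param cell_loadings Optional genes x cell-type loading matrix (confounds
#'   expression with cell composition when non-zero).
#' @param n Number of samples; required when `genotypes` is `NULL`.
#' @param seed Optional integer seed.
#' @return Samples x genes numeric matrix.
#' @export
simulate_expression <- function(model, genotypes = NULL, cell_fractions = NULL,
                                cell_loadings = NULL, n = NULL, seed = NULL) {
  stopifnot(inherits(model, "true_model"))
  if (is.null(model$topo_order)) stop("model is cyclic")
  if (is.null(n)) {
    if (is.null(genotypes)) stop("supply `genotypes` or `n`")
    n <- nrow(genotypes)
  }
  if (!is.null(model$eqtl) && nrow(model$eqtl)) {
    if (is.null(genotypes) || !all(model$eqtl$snp %in% colnames(genotypes))) {
      stop("`genotypes` must cover every SNP in the model's eQTL map")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  p <- length(model$genes)
  expr <- matrix(0, n, p, dimnames = list(rownames(genotypes) %||%
                                            sprintf("s%04d", seq_len(n)),
                                          model$genes))
  parents <- split(seq_len(nrow(model$edges)), model$edges$to)
  for (g in model$topo_order) {
    x <- rep(model$gene_mean[[g]], n)
    idx <- parents[[g]]
    for (e in idx) {
      x <- x + model$weights[e] * expr[, model$edges$from[e]]
    }
    if (!is.null(model$eqtl)) {
      hit <- which(model$eqtl$gene == g)
      for (e in hit) {
        x <- x + model$eqtl$beta[e] * genotypes[, model$eqtl$snp[e]]
      }
    }
    if (!is.null(cell_fractions) && !is.null(cell_loadings) &&
        g %in% rownames(cell_loadings)) {
      x <- x + as.numeric(cell_fractions %*% cell_loadings[g, ])
    }
    if (model$noise_sd[[g]] > 0) x <- x + stats::rnorm(n, 0, model$noise_sd[[g]])
    expr[, g] <- x
  }
  expr
}

#' Simulate right-censored survival times under proportional hazards
#'
#' Event times are drawn by inverse-transform sampling from an exponential
#' baseline scaled by `exp(linear predictor)`, where the linear predictor
#' sums the model's per-arm log hazard ratios applied to mean-centered
#' expression.  Censoring is independent uniform on `[0, T_max]`, with
#' `T_max` calibrated so the expected censored fraction equals the model's
#' `censor_rate` (non-informative by construction).
#'
#' @param expression Samples x genes matrix on the scale the Cox effects are
#'   defined on (log2-like).
#' @param model A [true_model()] with `cox_effects`, `baseline_hazard`,
#'   `censor_rate`.
#' @param arms Character vector of arm labels per sample.
#' @param seed Optional integer seed.
#' @return Data frame with `time` (months) and `event` (1 = death observed).
#' @export
simulate_survival <- function(expression, model, arms, seed = NULL) {
  stopifnot(inherits(model, "true_model"))
  if (model$baseline_hazard <= 0) stop("`baseline_hazard` must be positive")
  n <- nrow(expression)
  if (length(arms) != n) stop("`arms` must have one label per sample")
  if (!is.null(seed)) set.seed(seed)
  lp <- rep(0, n)
  ce <- model$cox_effects
  if (!is.null(ce) && nrow(ce)) {
    if (!all(ce$gene %in% colnames(expression))) {
      stop("cox_effects reference genes absent from `expression`")
    }
    for (i in seq_len(nrow(ce))) {
      in_arm <- arms == ce$arm[i]
      x <- expression[, ce$gene[i]]
      lp[in_arm] <- lp[in_arm] + ce$log_hr[i] * (x[in_arm] - mean(x))
    }
  }
  t_event <- stats::rexp(n, rate = 1) / (model$baseline_hazard * exp(lp))
  if (model$censor_rate <= 0) {
    out <- data.frame(time = t_event, event = 1L)
  } else {
    # mean_i P(C_i < t_i) = mean(pmin(t/Tmax, 1)) decreases in Tmax; solve
    # for the Tmax matching the target censored fraction.
    f <- function(tm) mean(pmin(t_event / tm, 1)) - model$censor_rate
    tmax <- stats::uniroot(f, lower = min(t_event) * 1e-6,
                           upper = max(t_event) * 1e6)$root
    cens <- stats::runif(n, 0, tmax)
    out <- data.frame(time = pmin(t_event, cens),
                      event = as.integer(t_event <= cens))
  }
  rownames(out) <- rownames(expression)
  out
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the study conditions of the motivating cohort at desk
#' scale: 350 samples with joint expression + genotype data, a sparse gene
#' DAG of expected degree 2, cis SNPs placed within 1 Mb of their gene's
#' TSS on one synthetic chromosome, ~30% of genes carrying a cis-eQTL that
#' explains ~10% of expression variance, two treatment arms in roughly the
#' 203:163 proportion of the trial, a median baseline survival of 30 months,
#' 30% censoring, and a ~22% held-out test split mirroring the 103-sample
#' replication arm.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param n_snps_per_gene cis SNPs simulated per gene.
#' @param edge_prob DAG forward-pair edge probability; default gives
#'   expected degree 2.
#' @param weight_range Absolute SEM weight range; signs are random.
#' @param noise_sd Per-gene SEM noise SD.
#' @param maf_range Minor-allele-frequency interval.
#' @param eqtl_frac Fraction of genes given a cis-eQTL.
#' @param eqtl_var_explained Target fraction of gene variance explained by
#'   its eQTL dosage.
#' @param n_cell_types Number of simulated cell-fraction columns.
#' @param cell_loading_sd SD of gene/cell-type confounding loadings
#'   (0 = no confounding, so stages can be tested in isolation).
#' @param arms Arm labels.
#' @param arm_probs Arm assignment probabilities.
#' @param cox_genes_per_arm Genes per arm given a true survival effect.
#' @param cox_log_hr Log hazard ratios cycled over those genes.
#' @param baseline_hazard Exponential baseline hazard (events/month).
#' @param censor_rate Target censored fraction.
#' @param test_frac Held-out test fraction of samples.
#' @param gene_spacing Distance between consecutive gene TSSs (bp).
#' @param seed Root seed; every random choice in [simulate_cohort()] flows
#'   from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 350, n_genes = 50, n_snps_per_gene = 3,
                          edge_prob = 2 / (n_genes - 1),
                          weight_range = c(0.5, 1), noise_sd = 1,
                          maf_range = c(0.1, 0.5), eqtl_frac = 0.3,
                          eqtl_var_explained = 0.10, n_cell_types = 5,
                          cell_loading_sd = 0,
                          arms = c("bevacizumab", "cetuximab"),
                          arm_probs = c(0.55, 0.45),
                          cox_genes_per_arm = 2, cox_log_hr = c(0.5, -0.5),
                          baseline_hazard = log(2) / 30, censor_rate = 0.3,
                          test_frac = 0.22, gene_spacing = 2.5e6, seed = 1) {
  cfg <- as.list(environment())
  if (cfg$test_frac < 0 || cfg$test_frac >= 1) stop("`test_frac` must be in [0, 1)")
  if (length(cfg$arms) != length(cfg$arm_probs)) {
    stop("`arms` and `arm_probs` lengths differ")
  }
  structure(cfg, class = "cohort_config")
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Produces an aligned [cohort_bundle()] (expression, genotypes, annotations,
#' covariates, cell fractions, survival, train/test split) together with the
#' [true_model()] that generated it.  Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param as_counts If `TRUE`, also transform expression to a count-like
#'   scale (`round(2^x - 1)`) so the count-based preprocessing rules can be
#'   exercised; the bundle's `scale` field records which scale is stored.
#' @return List with elements `bundle` and `model`.
#' @export
simulate_cohort <- function(config = cohort_config(), as_counts = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- derive_seeds(config$seed, 8,
                        c("dag", "geno", "model", "covar", "cells",
                          "expr", "surv", "split"))
  p <- config$n_genes
  n <- config$n_samples

  model <- simulate_dag(p, config$edge_prob, seed = seeds[["dag"]])
  genes <- model$genes

  # One synthetic chromosome; genes spaced so cis windows barely overlap.
  tss <- as.integer(config$gene_spacing * seq_len(p))
  gene_annot <- data.frame(gene = genes, chrom = "1", tss = tss)

  n_snps <- p * config$n_snps_per_gene
  set.seed(seeds[["geno"]])
  pos <- as.integer(rep(tss, each = config$n_snps_per_gene) +
                      sample(seq(-1e6, 1e6), n_snps, replace = TRUE))
  geno <- simulate_genotypes(n, n_snps, config$maf_range,
                             seed = seeds[["geno"]], positions = pos)
  snp_annot <- geno$snp_annot

  set.seed(seeds[["model"]])
  model$weights <- stats::runif(nrow(model$edges), config$weight_range[1],
                                config$weight_range[2]) *
    sample(c(-1, 1), nrow(model$edges), replace = TRUE)
  model$noise_sd[] <- config$noise_sd
  model$gene_mean[] <- stats::runif(p, 3, 8)
  n_eqtl <- round(config$eqtl_frac * p)
  eqtl <- NULL
  if (n_eqtl > 0) {
    egenes <- sort(sample(genes, n_eqtl))
    snp_of <- snp_annot$snp[match(egenes, genes) * config$n_snps_per_gene -
                              config$n_snps_per_gene + 1L]
    maf <- snp_annot$maf[match(snp_of, snp_annot$snp)]
    ve <- config$eqtl_var_explained
    beta <- sqrt(ve / (1 - ve)) * config$noise_sd / sqrt(2 * maf * (1 - maf))
    eqtl <- data.frame(gene = egenes, snp = snp_of, beta = beta)
  }
  model$eqtl <- eqtl
  arm_labels <- sample(config$arms, n, replace = TRUE, prob = config$arm_probs)
  cox <- NULL
  if (config$cox_genes_per_arm > 0) {
    cox_genes <- lapply(config$arms, function(a)
      sort(sample(genes, config$cox_genes_per_arm)))
    cox <- data.frame(
      arm = rep(config$arms, each = config$cox_genes_per_arm),
      gene = unlist(cox_genes),
      log_hr = rep_len(config$cox_log_hr,
                       config$cox_genes_per_arm * length(config$arms)))
  }
  model$cox_effects <- cox
  model$baseline_hazard <- config$baseline_hazard
  model$censor_rate <- config$censor_rate

  set.seed(seeds[["covar"]])
  samples <- rownames(geno$genotypes)
  covariates <- data.frame(
    sample = samples,
    age = round(stats::rnorm(n, 60, 10)),
    sex = sample(c(0L, 1L), n, replace = TRUE),
    kras_mut = stats::rbinom(n, 1, 0.4),
    braf_mut = stats::rbinom(n, 1, 0.1),
    arm = arm_labels)

  set.seed(seeds[["cells"]])
  raw <- matrix(stats::rgamma(n * config$n_cell_types, shape = 0.5), n)
  # per-sample total immune content varies, as deconvolution scores do;
  # exactly compositional rows would also be collinear with an intercept
  cell_fractions <- stats::runif(n, 0.4, 0.8) * raw / rowSums(raw)
  dimnames(cell_fractions) <- list(samples,
                                   sprintf("cell%02d", seq_len(config$n_cell_types)))
  cell_loadings <- NULL
  if (config$cell_loading_sd > 0) {
    cell_loadings <- matrix(stats::rnorm(p * config$n_cell_types,
                                         sd = config$cell_loading_sd),
                            p, config$n_cell_types,
                            dimnames = list(genes, colnames(cell_fractions)))
  }

  expr <- simulate_expression(model, geno$genotypes, cell_fractions,
                              cell_loadings, seed = seeds[["expr"]])
  surv <- simulate_survival(expr, model, arm_labels, seed = seeds[["surv"]])

  set.seed(seeds[["split"]])
  n_test <- round(config$test_frac * n)
  test <- sample(samples, n_test)
  split <- stats::setNames(ifelse(samples %in% test, "test", "train"), samples)

  scale <- "log2"
  if (as_counts) {
    expr <- round(pmax(2^expr - 1, 0))
    scale <- "counts"
  }
  bundle <- cohort_bundle(expression = expr, genotypes = geno$genotypes,
                          gene_annot = gene_annot, snp_annot = snp_annot,
                          covariates = covariates,
                          cell_fractions = cell_fractions,
                          survival = surv, split = split, scale = scale,
                          arms = config$arms)
  list(bundle = bundle, model = model)
}

#' Aligned cohort container
#'
#' The unit every pipeline stage consumes: expression, genotype dosages,
#' annotations, covariates, cell fractions, survival and the train/test
#' split, all indexed by one shared sample set.  [validate_cohort()] is run
#' on construction.
#'
#' @param expression Samples x genes matrix.
#' @param genotypes Samples x SNPs dosage matrix with entries in `{0,1,2}`.
#' @param gene_annot Data frame `gene`, `chrom`, `tss` (1-based bp).
#' @param snp_annot Data frame `snp`, `chrom`, `pos` (1-based bp), `maf`.
#' @param covariates Data frame with a `sample` column and an `arm` column.
#' @param cell_fractions Samples x cell-type matrix, entries >= 0, rows
#'   summing to at most 1.
#' @param survival Data frame `time` (months > 0), `event` in `{0,1}`,
#'   rownames = samples.
#' @param split Named character vector mapping sample to `train`/`test`.
#' @param scale `"counts"` or `"log2"`, flagging the expression scale.
#' @param arms Declared arm label set.
#' @return An object of class `cohort_bundle`.
#' @export
cohort_bundle <- function(expression, genotypes, gene_annot, snp_annot,
                          covariates, cell_fractions, survival, split,
                          scale = c("log2", "counts"), arms = NULL) {
  b <- structure(list(
    expression = as.matrix(expression), genotypes = as.matrix(genotypes),
    gene_annot = as.data.frame(gene_annot), snp_annot = as.data.frame(snp_annot),
    covariates = as.data.frame(covariates),
    cell_fractions = as.matrix(cell_fractions),
    survival = as.data.frame(survival), split = split,
    scale = match.arg(scale),
    arms = arms %||% unique(as.character(covariates$arm))
  ), class = "cohort_bundle")
  validate_cohort(b)
  b
}

#' Check every cohort-bundle invariant
#'
#' Errors when any component disagrees on the sample index, sample ids are
#' duplicated, dosages leave `{0,1,2}`, cell fractions are negative or rows
#' exceed 1, survival times are non-positive, or an arm label falls outside
#' the declared arm set.
#'
#' @param bundle A [cohort_bundle()].
#' @return `bundle`, invisibly.
#' @export
validate_cohort <- function(bundle) {
  s <- rownames(bundle$expression)
  if (is.null(s) || anyDuplicated(s)) stop("duplicated or missing sample ids")
  for (comp in c("genotypes", "cell_fractions")) {
    if (!identical(rownames(bundle[[comp]]), s)) {
      stop(sprintf("`%s` sample index disagrees with expression", comp))
    }
  }
  if (!identical(bundle$covariates$sample, s)) {
    stop("`covariates$sample` disagrees with expression sample index")
  }
  if (!identical(rownames(bundle$survival), s)) {
    stop("`survival` sample index disagrees with expression")
  }
  if (!identical(sort(names(bundle$split)), sort(s))) {
    stop("`split` sample index disagrees with expression")
  }
  if (!all(bundle$genotypes %in% 0:2)) stop("genotype dosages must be 0, 1 or 2")
  if (any(bundle$cell_fractions < 0) ||
      any(rowSums(bundle$cell_fractions) > 1 + 1e-8)) {
    stop("cell fractions must be non-negative with row sums <= 1")
  }
  if (any(bundle$survival$time <= 0)) stop("survival times must be positive")
  if (!all(bundle$survival$event %in% 0:1)) stop("events must be 0/1")
  if (!all(bundle$covariates$arm %in% bundle$arms)) {
    stop("arm label outside the declared arm set")
  }
  invisible(bundle)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "cohort_bundle: %d samples x %d genes (%s scale), %d SNPs, arms: %s; %d test samples\n",
    nrow(x$expression), ncol(x$expression), x$scale, ncol(x$genotypes),
    paste(x$arms, collapse = "/"), sum(x$split == "test")))
  invisible(x)
}
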