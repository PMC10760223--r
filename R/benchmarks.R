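# Seeded calibration studies.  Each function sets up the generative
# condition it probes (via the simulate module), runs the corresponding
# pipeline operation, and reports a recovery or calibration rate.  They are
# the package's own evidence that the estimators behave as claimed, and are
# what the acceptance script reports.

#' Skeleton recovery study
#'
#' Simulates sparse linear-Gaussian SEMs and measures the F1 score of the
#' stable PC skeleton against the true undirected edge set.
#'
#' @param n_seeds Number of replicate cohorts.
#' @param n_genes,edge_prob DAG size and density (default: expected degree
#'   2).
#' @param n Samples per cohort.
#' @param alpha CI-test level.
#' @param seed Root seed.
#' @return List `f1` (per seed), `mean_f1`.
#' @export
bench_skeleton_recovery <- function(n_seeds = 10, n_genes = 50,
                                    edge_prob = 2 / (n_genes - 1),
                                    n = 500, alpha = 0.01, seed = 1) {
  seeds <- derive_seeds(seed, n_seeds)
  f1 <- vapply(seeds, function(s) {
    model <- simulate_dag(n_genes, edge_prob, seed = s)
    set.seed(s)
    model$weights <- stats::runif(nrow(model$edges), 0.5, 1) *
      sample(c(-1, 1), nrow(model$edges), replace = TRUE)
    expr <- simulate_expression(model, n = n, seed = s + 1)
    net <- pc_skeleton(expr, alpha = alpha)
    truth <- edge_key(model$edges$from, model$edges$to)
    est <- skeleton_keys(net)
    tp <- length(intersect(truth, est))
    prec <- if (length(est)) tp / length(est) else 0
    rec <- if (length(truth)) tp / length(truth) else 1
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  list(f1 = f1, mean_f1 = mean(f1))
}

#' Instrumental-variable orientation study
#'
#' Simulates `SNP -> A -> B` systems (the instrument explaining a set
#' fraction of A's variance), hands the A-B edge to the MR orientation
#' step, and reports how often an oriented edge points the right way and
#' whether any run produced a directed cycle.
#'
#' @param n_sims Number of simulated systems.
#' @param n Samples per system.
#' @param var_explained Instrument strength on the eGene.
#' @param effect A -> B SEM weight.
#' @param seed Root seed.
#' @return List `n_oriented`, `n_correct`, `accuracy`, `n_cycles`.
#' @export
bench_iv_orientation <- function(n_sims = 20, n = 1000, var_explained = 0.10,
                                 effect = 0.8, seed = 1) {
  seeds <- derive_seeds(seed, n_sims)
  oriented <- 0L; correct <- 0L; cycles <- 0L
  for (s in seeds) {
    set.seed(s)
    maf <- 0.3
    dose <- stats::rbinom(n, 2, maf)
    beta <- sqrt(var_explained / (1 - var_explained)) /
      sqrt(2 * maf * (1 - maf))
    a <- beta * dose + stats::rnorm(n)
    b <- effect * a + stats::rnorm(n)
    data <- cbind(A = a, B = b)
    geno <- cbind(s1 = dose)
    net <- gene_network(c("A", "B"),
                        skeleton = data.frame(a = "A", b = "B"))
    net <- orient_with_instruments(net,
                                   data.frame(gene = "A", best_snp = "s1"),
                                   geno, data)
    if (!directed_is_acyclic(net)) cycles <- cycles + 1L
    if (nrow(net$directed)) {
      oriented <- oriented + 1L
      if (net$directed$from[1] == "A" && net$directed$to[1] == "B") {
        correct <- correct + 1L
      }
    }
  }
  list(n_oriented = oriented, n_correct = correct,
       accuracy = if (oriented) correct / oriented else NA_real_,
       n_cycles = cycles)
}

#' Breakpoint recovery study
#'
#' Plants a changepoint in a Hamming-distance curve (flat, then a linear
#' rise), adds Gaussian noise, and reports how often
#' [piecewise_breakpoint()] recovers the exact changepoint index.
#'
#' @param n_fits Number of noisy curves.
#' @param true_k Planted changepoint exponent.
#' @param i_range Alpha-grid exponents.
#' @param base Flat level of the curve.
#' @param slope Post-changepoint slope per exponent step.
#' @param noise_sd Noise SD added to the curve.
#' @param seed Root seed.
#' @return List `hits` (logical per fit), `rate`.
#' @export
bench_breakpoint <- function(n_fits = 50, true_k = 10, i_range = 3:22,
                             base = 2, slope = 5, noise_sd = 0.5, seed = 1) {
  seeds <- derive_seeds(seed, n_fits)
  hits <- vapply(seeds, function(s) {
    set.seed(s)
    x <- i_range[-1]
    hd <- base + slope * pmax(x - true_k, 0) + stats::rnorm(length(x), 0,
                                                            noise_sd)
    bp <- piecewise_breakpoint(list(hd = hd, i_range = i_range))
    isTRUE(bp$i == true_k)
  }, logical(1))
  list(hits = hits, rate = mean(hits))
}

#' Edge-validation calibration study
#'
#' Builds a graph holding true parent-child edges whose neighbor
#' regression explains half the child's variance, plus declared edges
#' between independent gene pairs, and measures the validated fraction of
#' each kind on a held-out test set.
#'
#' @param n_true,n_null Numbers of true and null edges.
#' @param n_train,n_test Training and held-out sample sizes.
#' @param r_min Validation threshold.
#' @param seed Root seed.
#' @return List `true_rate`, `null_rate`.
#' @export
bench_edge_validation <- function(n_true = 30, n_null = 30, n_train = 350,
                                  n_test = 103, r_min = 0.5, seed = 1) {
  set.seed(derive_seeds(seed, 1))
  n <- n_train + n_test
  cols <- list()
  edges <- list()
  for (i in seq_len(n_true)) {
    p <- stats::rnorm(n)
    cols[[sprintf("tp%02d", i)]] <- p
    cols[[sprintf("tc%02d", i)]] <- p + stats::rnorm(n)  # neighbor R^2 = 0.5
    edges[[length(edges) + 1]] <- data.frame(a = sprintf("tp%02d", i),
                                             b = sprintf("tc%02d", i),
                                             truth = "true")
  }
  for (i in seq_len(n_null)) {
    cols[[sprintf("ua%02d", i)]] <- stats::rnorm(n)
    cols[[sprintf("ub%02d", i)]] <- stats::rnorm(n)
    edges[[length(edges) + 1]] <- data.frame(a = sprintf("ua%02d", i),
                                             b = sprintf("ub%02d", i),
                                             truth = "null")
  }
  x <- do.call(cbind, cols)
  edges <- do.call(rbind, edges)
  net <- gene_network(colnames(x), skeleton = edges[, c("a", "b")])
  val <- validate_edges(x[seq_len(n_train), ], x[n_train + seq_len(n_test), ],
                        net, r_min = r_min)
  keys <- edge_key(val$edges$a, val$edges$b)
  truth <- edges$truth[match(keys, edge_key(edges$a, edges$b))]
  list(true_rate = mean(val$edges$validated[truth == "true"]),
       null_rate = mean(val$edges$validated[truth == "null"]))
}

#' cis-eQTL null calibration and power study
#'
#' `bench_eqtl_calibration` scans fully null genes (no eQTL effect) and
#' reports the eGene rate at the given level — it should match the level.
#' `bench_eqtl_power` plants an eQTL of fixed variance explained and
#' reports the detection rate across seeds.
#'
#' @param n_genes Number of null genes scanned.
#' @param n Samples.
#' @param n_snps_per_gene cis SNPs per gene.
#' @param n_perm Permutations per gene.
#' @param alpha eGene level.
#' @param seed Root seed.
#' @return `bench_eqtl_calibration`: list `egene_rate`, `p` (per gene).
#' @export
bench_eqtl_calibration <- function(n_genes = 500, n = 350,
                                   n_snps_per_gene = 5, n_perm = 1000,
                                   alpha = 0.05, seed = 1) {
  seeds <- derive_seeds(seed, n_genes)
  p <- vapply(seeds, function(s) {
    set.seed(s)
    maf <- stats::runif(n_snps_per_gene, 0.1, 0.5)
    D <- vapply(maf, function(m) stats::rbinom(n, 2, m), numeric(n))
    y <- stats::rnorm(n)
    permutation_adjust(y, D, n_perm = n_perm, seed = s + 1)$p_adjusted
  }, numeric(1))
  list(egene_rate = mean(p < alpha), p = p)
}

#' @param n_seeds Number of planted-eQTL replicates.
#' @param var_explained Variance of the gene explained by its eQTL.
#' @rdname bench_eqtl_calibration
#' @return `bench_eqtl_power`: list `detection_rate`, `p` (per seed).
#' @export
bench_eqtl_power <- function(n_seeds = 20, n = 350, n_snps_per_gene = 5,
                             var_explained = 0.10, n_perm = 1000,
                             alpha = 0.05, seed = 1) {
  seeds <- derive_seeds(seed, n_seeds)
  p <- vapply(seeds, function(s) {
    set.seed(s)
    maf <- stats::runif(n_snps_per_gene, 0.1, 0.5)
    D <- vapply(maf, function(m) stats::rbinom(n, 2, m), numeric(n))
    beta <- sqrt(var_explained / (1 - var_explained)) /
      sqrt(2 * maf[1] * (1 - maf[1]))
    y <- beta * D[, 1] + stats::rnorm(n)
    permutation_adjust(y, D, n_perm = n_perm, seed = s + 1)$p_adjusted
  }, numeric(1))
  list(detection_rate = mean(p < alpha), p = p)
}

#' Residualized-Cox recovery study
#'
#' Simulates two-arm cohorts in which two genes of one sub-network carry
#' true log hazard ratios of +/- `log_hr` in one arm (one of them with an
#' upstream confounder gene), fits the residualized Cox model, and
#' reports: how often both estimates land within `tol` of the truth, how
#' often the signature contains both causal genes with the right
#' direction, and how often it wrongly contains a designated null gene.
#'
#' @param n_seeds Number of replicate cohorts.
#' @param n_per_arm Samples per treatment arm.
#' @param log_hr True log hazard ratio magnitude.
#' @param tol Estimation tolerance checked per seed.
#' @param p_max Signature threshold.
#' @param seed Root seed.
#' @return List `est_within_tol_rate`, `signature_recovery_rate`,
#'   `null_inclusion_rate`, per-seed `detail`.
#' @export
bench_cox_recovery <- function(n_seeds = 20, n_per_arm = 200, log_hr = 0.5,
                               tol = 0.2, p_max = 0.1, seed = 1) {
  seeds <- derive_seeds(seed, n_seeds)
  sn <- structure(list(anchor = "G1",
                       members = c("G1", "G2", "N1", "U1"),
                       upstream = list(G1 = "U1", G2 = character(0),
                                       N1 = character(0), U1 = character(0))),
                  class = "subnetwork")
  detail <- lapply(seeds, function(s) {
    set.seed(s)
    n <- 2 * n_per_arm
    u <- stats::rnorm(n)
    expr <- cbind(U1 = u, G1 = 0.7 * u + stats::rnorm(n),
                  G2 = stats::rnorm(n), N1 = stats::rnorm(n))
    rownames(expr) <- sprintf("s%04d", seq_len(n))
    arms <- rep(c("armA", "armB"), each = n_per_arm)
    model <- true_model(colnames(expr), data.frame(from = "U1", to = "G1"),
                        weights = 0.7,
                        cox_effects = data.frame(
                          arm = "armA", gene = c("G1", "G2"),
                          log_hr = c(log_hr, -log_hr)),
                        censor_rate = 0.3)
    surv <- simulate_survival(expr, model, arms, seed = s + 1)
    fit <- fit_cox_subnetwork(surv, sn, expr, arm = arms,
                              arm_label = "armA")
    sig <- define_signature(fit, p_max = p_max)
    est <- stats::setNames(fit$log_hr, fit$gene)
    within <- abs(est["G1"] - log_hr) <= tol && abs(est["G2"] + log_hr) <= tol
    got <- sig$genes
    rec <- ("G1" %in% got$gene &&
              got$direction[got$gene == "G1"] == "beneficial-low" &&
              "G2" %in% got$gene &&
              got$direction[got$gene == "G2"] == "beneficial-high")
    list(within_tol = within, recovered = rec,
         null_in = "N1" %in% got$gene, est = est)
  })
  list(est_within_tol_rate = mean(vapply(detail, `[[`, logical(1),
                                         "within_tol")),
       signature_recovery_rate = mean(vapply(detail, `[[`, logical(1),
                                             "recovered")),
       null_inclusion_rate = mean(vapply(detail, `[[`, logical(1),
                                         "null_in")),
       detail = detail)
}

#' Matched-null enrichment calibration study
#'
#' Null runs draw the target SNP set at random from the universe (so the
#' annotation is independent of the targets) and should give |z| < 3
#' almost always; the planted run places every target inside an interval
#' and should give a large positive z.
#'
#' @param n_runs Number of null runs.
#' @param n_universe,n_target Universe and target sizes.
#' @param n_sets Matched null sets per run.
#' @param seed Root seed.
#' @return List `null_ok_rate` (share of runs with |z| < 3), `null_z`,
#'   `planted_z`.
#' @export
bench_enrichment_calibration <- function(n_runs = 100, n_universe = 2000,
                                         n_target = 50, n_sets = 1000,
                                         seed = 1) {
  seeds <- derive_seeds(seed, n_runs + 1)
  set.seed(seeds[1])
  universe <- data.frame(
    snp = sprintf("u%05d", seq_len(n_universe)),
    chrom = "1",
    pos = sort(sample.int(1e7, n_universe)),
    maf = stats::runif(n_universe, 0.05, 0.5),
    tss_dist = stats::runif(n_universe, 0, 1e6),
    gene_density = stats::rpois(n_universe, 5))
  starts <- sort(sample.int(1e7 - 4e4, 50))
  intervals <- data.frame(chrom = "1", start = starts, end = starts + 4e4)
  features <- universe[, c("snp", "maf", "tss_dist", "gene_density")]
  annot <- universe[, c("snp", "chrom", "pos")]
  in_interval <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(annot$chrom,
                           IRanges::IRanges(annot$pos, width = 1)),
    GenomicRanges::GRanges(intervals$chrom,
                           IRanges::IRanges(intervals$start + 1,
                                            intervals$end))) > 0
  run_z <- function(targets, s) {
    ns <- matched_null_sets(targets, features, n_sets = n_sets, seed = s)
    region_enrichment_z(targets, annot, intervals, ns)$z
  }
  null_z <- vapply(seq_len(n_runs), function(i) {
    set.seed(seeds[i + 1])
    run_z(sample(universe$snp, n_target), seeds[i + 1] + 1)
  }, numeric(1))
  set.seed(seeds[1] + 1)
  planted <- sample(universe$snp[in_interval], n_target)
  planted_z <- run_z(planted, seeds[1] + 2)
  list(null_ok_rate = mean(abs(null_z) < 3), null_z = null_z,
       planted_z = planted_z)
}
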