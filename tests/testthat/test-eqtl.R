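test_that("cis pair mapping matches a brute-force double loop, boundary inclusive", {
  gene_annot <- data.frame(gene = c("gA", "gB", "gC"), chrom = "1",
                           tss = c(2e6, 5e6, 9e6))
  set.seed(1)
  snp_annot <- data.frame(snp = sprintf("r%02d", 1:10), chrom = "1",
                          pos = c(2e6, 3e6, 3e6 + 1, 1e6, 999999,
                                  sample.int(1e7, 5)))
  pairs <- map_cis_pairs(gene_annot, snp_annot, window = 1e6)
  # brute force oracle
  oracle <- do.call(rbind, lapply(seq_len(3), function(i) {
    hits <- which(abs(snp_annot$pos - gene_annot$tss[i]) <= 1e6)
    if (!length(hits)) return(NULL)
    data.frame(gene = gene_annot$gene[i], snp = snp_annot$snp[hits])
  }))
  expect_setequal(paste(pairs$gene, pairs$snp),
                  paste(oracle$gene, oracle$snp))
  # SNP exactly at TSS and at TSS +/- window included; one bp beyond excluded
  keys <- paste(pairs$gene, pairs$snp)
  expect_true("gA r01" %in% keys)   # at TSS
  expect_true("gA r02" %in% keys)   # TSS + 1e6 exactly
  expect_false("gA r03" %in% keys)  # TSS + 1e6 + 1
  expect_true("gA r04" %in% keys)   # TSS - 1e6 exactly
  expect_false("gA r05" %in% keys)  # TSS - 1e6 - 1
  # unknown chromosome skipped with warning
  expect_warning(map_cis_pairs(gene_annot,
                               data.frame(snp = "x", chrom = "2", pos = 1)),
                 "chromosome")
})

test_that("cis regression recovers exact fits and matches closed-form t", {
  dose <- c(0, 1, 2, 0, 1, 2)
  y <- 2 * dose
  fit <- fit_cis_regression(y + rnorm(6, sd = 1e-10), dose)
  expect_equal(fit$beta, 2, tolerance = 1e-6)
  expect_lt(fit$p_nominal, 1e-10)
  # hand linear-algebra oracle on a 6-point fixture
  y2 <- c(1.2, 0.7, 2.4, 1.9, 3.1, 2.2)
  X <- cbind(1, dose)
  b <- solve(t(X) %*% X, t(X) %*% y2)
  r <- y2 - X %*% b
  s2 <- sum(r^2) / (6 - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  fit2 <- fit_cis_regression(y2, dose)
  expect_equal(fit2$beta, b[2], tolerance = 1e-12)
  expect_equal(fit2$t_stat, b[2] / se, tolerance = 1e-12)
  expect_warning(fit_cis_regression(y2, rep(1, 6)), "constant")
})

test_that("covariate adjustment inside the scan agrees with Frisch-Waugh", {
  set.seed(2)
  n <- 200
  covar <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  dose <- rbinom(n, 2, 0.3)
  y <- 0.4 * dose + 0.5 * covar$age + rnorm(n)
  full <- fit_cis_regression(y, dose, covar)
  # residualize both sides first, then simple regression
  r_y <- resid(lm(y ~ age + sex, covar))
  r_d <- resid(lm(dose ~ age + sex, covar))
  b_fw <- sum(r_y * r_d) / sum(r_d^2)
  expect_equal(full$beta, b_fw, tolerance = 1e-10)
})

test_that("permutation adjustment obeys the (r+1)/(B+1) estimator", {
  set.seed(3)
  n <- 80
  dose <- cbind(s1 = rbinom(n, 2, 0.4), s2 = rbinom(n, 2, 0.3))
  # observed best beats all 99 permutations
  y <- 3 * dose[, "s1"] + rnorm(n, sd = 0.1)
  pa <- permutation_adjust(y, dose, n_perm = 99, adaptive = FALSE, seed = 4)
  expect_equal(pa$p_adjusted, 0.01)
  expect_equal(pa$best_snp, "s1")
  # order of cis SNPs is irrelevant
  pa2 <- permutation_adjust(y, dose[, 2:1], n_perm = 99, adaptive = FALSE,
                            seed = 4)
  expect_equal(pa2$p_adjusted, pa$p_adjusted)
  expect_equal(pa2$best_snp, "s1")
  expect_error(permutation_adjust(y, dose, n_perm = 5), "n_perm")
  # p is bounded away from 0 and by 1
  ynull <- rnorm(n)
  pn <- permutation_adjust(ynull, dose, n_perm = 99, adaptive = FALSE,
                           seed = 5)
  expect_gte(pn$p_adjusted, 1 / 100)
  expect_lte(pn$p_adjusted, 1)
})

test_that("eGene calls use a strict threshold", {
  gp <- data.frame(gene = c("a", "b", "c"),
                   p_adjusted = c(0.05, 0.049, 0.9))
  eg <- select_egenes(gp)
  expect_identical(eg$gene, "b")
  expect_equal(nrow(select_egenes(gp[0, ])), 0)
})

test_that("matched null sets respect size and bin composition", {
  # constant features: a single bin, uniform draws of the right size
  uni <- data.frame(snp = sprintf("u%03d", 1:200), maf = 0.2)
  tgt <- uni$snp[1:20]
  ns <- matched_null_sets(tgt, uni, n_sets = 50, seed = 6)
  expect_length(ns, 50)
  expect_true(all(lengths(ns) == 20))
  expect_true(all(unlist(ns) %in% uni$snp))
  expect_true(all(vapply(ns, anyDuplicated, numeric(1)) == 0))
  # planted two-bin universe: per-bin composition preserved exactly
  uni2 <- data.frame(snp = sprintf("v%03d", 1:300),
                     maf = rep(c(0.1, 0.4), each = 150))
  tgt2 <- c(uni2$snp[1:15], uni2$snp[151:155])  # 15 low-maf, 5 high-maf
  ns2 <- matched_null_sets(tgt2, uni2, n_sets = 30, bins = 2, seed = 7)
  for (s in ns2) {
    maf <- uni2$maf[match(s, uni2$snp)]
    expect_equal(sum(maf == 0.1), 15)
    expect_equal(sum(maf == 0.4), 5)
  }
})

test_that("region enrichment z handles saturation and planted signal", {
  snp_annot <- data.frame(snp = sprintf("s%03d", 1:100), chrom = "1",
                          pos = seq(100, 9e4, length.out = 100))
  # annotation covering everything: z undefined
  all_cov <- data.frame(chrom = "1", start = 0, end = 1e5)
  ns <- replicate(5, sample(snp_annot$snp, 10), simplify = FALSE)
  res <- region_enrichment_z(snp_annot$snp[1:10], snp_annot, all_cov, ns)
  expect_equal(res$observed, 10)
  expect_false(res$z_defined)
  # BED half-open semantics: pos == start excluded, pos == end included
  iv <- data.frame(chrom = "1", start = 100, end = 1000)
  annot <- data.frame(snp = c("a", "b", "c"), chrom = "1",
                      pos = c(100, 101, 1000))
  nres <- region_enrichment_z(
    c("a", "b", "c"), annot, iv,
    list(c("a", "b", "c"), c("a", "b", "c"), c("a", "a", "a")))
  expect_equal(nres$observed, 2)
  expect_error(region_enrichment_z("a", annot, iv, list("a")), "null sets")
})

test_that("BED reader validates coordinates with line numbers", {
  d <- withr::local_tempdir()
  ok <- file.path(d, "ok.bed")
  writeLines(c("track name=x", "1\t0\t100", "1\t50\t60"), ok)
  bed <- read_bed(ok)
  expect_equal(nrow(bed), 2)
  expect_equal(bed$start, c(0, 50))
  bad <- file.path(d, "bad.bed")
  writeLines(c("1\t0\t100", "1\t70\t60"), bad)
  expect_error(read_bed(bad), "line 2.*start >= end")
})
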