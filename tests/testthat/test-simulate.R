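test_that("simulate_dag produces acyclic graphs with the forced cases right", {
  expect_equal(nrow(simulate_dag(10, 0, seed = 1)$edges), 0)
  expect_equal(nrow(simulate_dag(2, 1, seed = 1)$edges), 1)
  m <- simulate_dag(50, 0.04, seed = 7)
  # depth-first cycle search as independent oracle
  adj <- split(m$edges$to, m$edges$from)
  visiting <- character(0)
  seen <- character(0)
  has_cycle <- FALSE
  dfs <- function(v) {
    if (v %in% visiting) {
      has_cycle <<- TRUE
      return()
    }
    if (v %in% seen) return()
    visiting <<- c(visiting, v)
    for (w in adj[[v]]) dfs(w)
    visiting <<- setdiff(visiting, v)
    seen <<- c(seen, v)
  }
  for (g in m$genes) dfs(g)
  expect_false(has_cycle)
  expect_error(simulate_dag(3.5, 0.1), "integer")
  expect_error(simulate_dag(10, 1.2), "probability")
})

test_that("genotype dosages follow Hardy-Weinberg proportions", {
  g <- simulate_genotypes(10000, 20, maf_range = 0.5, seed = 2)
  expect_true(all(g$genotypes %in% 0:2))
  expect_true(all(abs(colMeans(g$genotypes) - 1) < 0.03))
  g2 <- simulate_genotypes(5000, 10, maf_range = 0.2, seed = 3)
  freqs <- table(factor(g2$genotypes, levels = 0:2)) / length(g2$genotypes)
  expect_equal(as.numeric(freqs), c(0.64, 0.32, 0.04), tolerance = 0.05)
  expect_error(simulate_genotypes(10, 5, maf_range = 0), "maf")
})

test_that("the SEM generator matches its covariance algebra", {
  # degenerate: no parents, no eQTL, zero noise -> constant column
  m0 <- true_model(c("A", "B"), data.frame(from = "A", to = "B"),
                   weights = 2, noise_sd = c(A = 0, B = 1),
                   gene_mean = c(A = 5, B = 0))
  x0 <- simulate_expression(m0, n = 50, seed = 1)
  expect_true(all(x0[, "A"] == 5))
  # chain A -> B: cov(A, B) = w * var(A)
  w <- 0.7
  m <- true_model(c("A", "B"), data.frame(from = "A", to = "B"), weights = w)
  x <- simulate_expression(m, n = 20000, seed = 2)
  expect_equal(cov(x[, "A"], x[, "B"]), w * var(x[, "A"]), tolerance = 0.03)
  # chain A -> B -> C: partial correlation (A, C | B) vanishes
  m2 <- true_model(c("A", "B", "C"),
                   data.frame(from = c("A", "B"), to = c("B", "C")),
                   weights = c(0.8, 0.8))
  x2 <- simulate_expression(m2, n = 20000, seed = 3)
  expect_lt(abs(ci_test("A", "C", "B", x2)$r), 0.03)
  # eQTL term shifts expression by beta * dosage
  expect_error(simulate_expression(m2, n = 10,
                                   cell_fractions = NULL), NA)
})

test_that("survival generator matches its exponential and censoring targets", {
  genes <- c("A", "B")
  m <- true_model(genes, data.frame(from = character(), to = character()),
                  baseline_hazard = log(2) / 30, censor_rate = 0)
  x <- matrix(rnorm(5000 * 2), ncol = 2, dimnames = list(NULL, genes))
  s <- simulate_survival(x, m, rep("a", 5000), seed = 4)
  expect_true(all(s$event == 1))
  ks <- suppressWarnings(ks.test(s$time, "pexp", log(2) / 30))
  expect_gt(ks$p.value, 0.01)
  # censoring calibration
  m$censor_rate <- 0.3
  s2 <- simulate_survival(x, m, rep("a", 5000), seed = 5)
  expect_equal(mean(s2$event), 0.70, tolerance = 0.03)
  # positive log HR shortens survival across tertiles
  m3 <- true_model(genes, data.frame(from = character(), to = character()),
                   cox_effects = data.frame(arm = "a", gene = "A",
                                            log_hr = 0.7),
                   censor_rate = 0)
  s3 <- simulate_survival(x, m3, rep("a", 5000), seed = 6)
  ter <- cut(x[, "A"], quantile(x[, "A"], c(0, 1/3, 2/3, 1)),
             include.lowest = TRUE)
  means <- tapply(s3$time, ter, mean)
  expect_true(all(diff(means) < 0))
})

test_that("simulate_cohort is deterministic and satisfies bundle invariants", {
  cfg <- cohort_config(n_samples = 60, n_genes = 10, seed = 9)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  expect_silent(validate_cohort(c1$bundle))
  # split arithmetic
  cfg2 <- cohort_config(n_samples = 500, n_genes = 5, test_frac = 0.2,
                        seed = 10)
  b <- simulate_cohort(cfg2)$bundle
  expect_equal(sum(b$split == "test"), 100)
  # eQTL SNPs lie within the cis window of their gene's TSS
  mod <- c1$model
  if (!is.null(mod$eqtl)) {
    tss <- c1$bundle$gene_annot$tss[match(mod$eqtl$gene,
                                          c1$bundle$gene_annot$gene)]
    pos <- c1$bundle$snp_annot$pos[match(mod$eqtl$snp,
                                         c1$bundle$snp_annot$snp)]
    expect_true(all(abs(pos - tss) <= 1e6))
  }
  # cox genes are network genes
  expect_true(all(mod$cox_effects$gene %in% mod$genes))
})

test_that("cohort writers and readers round-trip the bundle", {
  cfg11 <- cohort_config(n_samples = 40, n_genes = 8, seed = 11)
  sc <- simulate_cohort(cfg11)
  d <- withr::local_tempdir()
  write_cohort(sc$bundle, d, config = cfg11)
  b2 <- read_inputs(d)
  expect_equal(sc$bundle$expression, b2$expression, tolerance = 1e-8)
  expect_equal(unname(sc$bundle$genotypes), unname(b2$genotypes))
  expect_identical(sc$bundle$split, b2$split)
  expect_equal(sc$bundle$survival$time, b2$survival$time, tolerance = 1e-8)
  # VCF dosages agree with the dosage matrix
  gv <- read_vcf_dosage(file.path(d, "genotypes.vcf"))
  expect_equal(unname(gv[rownames(sc$bundle$genotypes), ]),
               unname(sc$bundle$genotypes) + 0L,
               ignore_attr = TRUE)
  # config round-trips through YAML
  cfg <- yaml::read_yaml(file.path(d, "config.yaml"))
  expect_equal(cfg$n_samples, 40)
})
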