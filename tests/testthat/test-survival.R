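test_that("residualization is an orthogonal idempotent projection", {
  set.seed(1)
  G <- matrix(rnorm(30 * 2), 30, 2)
  g <- rnorm(30)
  gt <- residualize_on_upstream(g, G)
  expect_lt(max(abs(crossprod(cbind(1, G), gt))), 1e-8)
  expect_equal(residualize_on_upstream(gt, G), gt, tolerance = 1e-10)
  # no upstream: centering
  expect_equal(residualize_on_upstream(g), g - mean(g))
  # gene in the span of its upstream genes: zero residual
  gi <- 2 * G[, 1] - G[, 2] + 3
  expect_lt(max(abs(residualize_on_upstream(gi, G))), 1e-10)
  expect_warning(residualize_on_upstream(g, cbind(G, G[, 1])), "collinear")
})

test_that("the residualized Cox fit recovers a known two-group hazard ratio", {
  set.seed(2)
  n <- 2000
  grp <- rep(0:1, each = n / 2)
  time <- rexp(n, rate = ifelse(grp == 1, 2, 1))
  surv <- data.frame(time = time, event = 1L)
  expr <- cbind(G1 = grp + 0)
  rownames(expr) <- sprintf("s%04d", 1:n)
  sn <- make_subnetwork("G1", "G1", list(G1 = character(0)))
  fit <- fit_cox_subnetwork(surv, sn, expr)
  expect_equal(fit$log_hr, log(2), tolerance = 0.15)
  expect_true(fit$converged)
  expect_equal(fit$hr, exp(fit$log_hr))
  # too few events is an error
  surv0 <- data.frame(time = time[1:20], event = rep(0L, 20))
  expect_error(fit_cox_subnetwork(surv0, sn, expr[1:20, , drop = FALSE]),
               "events")
})

test_that("joint and per-gene Cox modes agree on a confounded sub-network", {
  set.seed(3)
  n <- 600
  u <- rnorm(n)
  expr <- cbind(U = u, G = 0.7 * u + rnorm(n))
  rownames(expr) <- sprintf("s%04d", 1:n)
  m <- true_model(colnames(expr), data.frame(from = "U", to = "G"),
                  weights = 0.7,
                  cox_effects = data.frame(arm = "a", gene = "G",
                                           log_hr = 0.5),
                  censor_rate = 0.2)
  surv <- simulate_survival(expr, m, rep("a", n), seed = 4)
  sn <- make_subnetwork("G", c("G", "U"),
                        list(G = "U", U = character(0)))
  joint <- fit_cox_subnetwork(surv, sn, expr, mode = "joint")
  per <- fit_cox_subnetwork(surv, sn, expr, mode = "per_gene")
  jg <- joint[joint$gene == "G", ]
  pg <- per[per$gene == "G", ]
  expect_equal(jg$log_hr, 0.5, tolerance = 0.2)
  expect_equal(pg$log_hr, jg$log_hr, tolerance = 0.15)
})

test_that("signatures keep only significant genes with the right direction", {
  fits <- data.frame(gene = c("m", "r", "x"),
                     hr = c(0.65, 1.37, 1.1),
                     log_hr = log(c(0.65, 1.37, 1.1)),
                     log_hr_se = 0.2,
                     p = c(0.05, 0.07, 0.45),
                     converged = TRUE, arm = "cetuximab",
                     subnetwork = "sn1")
  sig <- define_signature(fits, p_max = 0.1)
  expect_setequal(sig$genes$gene, c("m", "r"))
  expect_equal(sig$genes$direction[sig$genes$gene == "m"], "beneficial-high")
  expect_equal(sig$genes$direction[sig$genes$gene == "r"], "beneficial-low")
  # all p >= 0.1: empty signature allowed
  none <- define_signature(transform(fits, p = 0.5))
  expect_equal(nrow(none$genes), 0)
})

test_that("third-quartile dichotomization follows the strict boundary rule", {
  x <- 1:8  # Q3 = 6.25 under linear interpolation
  high <- dichotomize_third_quartile(x, "beneficial-high")
  expect_equal(sum(high), 2)
  expect_equal(which(high), 7:8)
  low <- dichotomize_third_quartile(x, "beneficial-low")
  expect_equal(sum(low), 6)
  expect_identical(low, !high)
  # constant vector: single state, warned
  expect_warning(all_eq <- dichotomize_third_quartile(rep(2, 6),
                                                      "beneficial-high"),
                 "constant")
  expect_equal(sum(all_eq), 0)
})

test_that("stratification partitions samples into the three states", {
  sig <- structure(list(arm = "a", subnetwork = "sn",
                        genes = data.frame(gene = c("g1", "g2"),
                                           hr = c(0.5, 2), p = 0.05,
                                           direction = c("beneficial-high",
                                                         "beneficial-low"))),
                   class = "signature")
  set.seed(5)
  expr <- cbind(g1 = rnorm(80), g2 = rnorm(80))
  grp <- stratify_patients(sig, expr)
  expect_equal(length(grp), 80)
  expect_false(anyNA(grp))
  b1 <- dichotomize_third_quartile(expr[, "g1"], "beneficial-high")
  b2 <- dichotomize_third_quartile(expr[, "g2"], "beneficial-low")
  expect_true(all(grp[b1 & b2] == "beneficial"))
  expect_true(all(grp[!b1 & !b2] == "non-beneficial"))
  expect_true(all(grp[xor(b1, b2)] == "mixed"))
  # single-gene signature: no mixed group possible
  sig1 <- sig; sig1$genes <- sig$genes[1, ]
  expect_false("mixed" %in% stratify_patients(sig1, expr))
})

test_that("Kaplan-Meier estimates match the product-limit definition", {
  km <- km_estimate(1:10, rep(1, 10))
  cv <- km$curves[["all"]]
  expect_equal(cv$surv[1], 1)
  expect_true(all(diff(cv$surv) <= 0))
  expect_equal(cv$surv[cv$time == 5], 0.5)
  expect_equal(unname(km$median_os["all"]), 5)
  # all censored: flat curve, undefined median
  km0 <- km_estimate(1:5, rep(0, 5))
  expect_true(all(km0$curves[["all"]]$surv == 1))
  expect_true(is.na(km0$median_os["all"]))
  # single event: one drop only
  km1 <- km_estimate(c(3, 4, 5, 6), c(1, 0, 0, 0))
  sv <- km1$curves[["all"]]
  expect_equal(sum(diff(sv$surv) < 0), 1)
  expect_equal(sv$surv[sv$time == 3], 0.75)
})

test_that("the log-rank test matches a manual O-E computation", {
  # identical groups: statistic 0
  t1 <- c(2, 4, 6, 8)
  lr0 <- logrank_test(c(t1, t1), rep(1, 8), rep(c("a", "b"), each = 4))
  expect_lt(lr0$statistic, 1e-10)
  # hand-checkable 6-subject fixture
  time <- c(1, 3, 5, 2, 4, 6)
  event <- c(1, 1, 0, 1, 1, 1)
  grp <- rep(c("a", "b"), each = 3)
  lr <- logrank_test(time, event, grp)
  expect_equal(lr$statistic, logrank_brute_force(time, event, grp),
               tolerance = 1e-10)
  # power under a strong hazard ratio
  ok <- vapply(1:20, function(s) {
    set.seed(s + 500)
    tt <- c(rexp(100, 1), rexp(100, 3))
    logrank_test(tt, rep(1, 200), rep(c("a", "b"), each = 100))$p < 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.9)
  expect_error(logrank_test(1:3, rep(1, 3), rep("a", 3)), "groups")
})

test_that("the rank-sum replication test is exact for small untied samples", {
  w <- wilcoxon_replication(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p, 0.1)  # 2 / choose(6, 3)
  expect_equal(wilcoxon_replication(c(2, 2, 2), c(2, 2, 2))$p, 1)
  expect_equal(wilcoxon_replication(c(1, 5, 9), c(1, 5, 9))$p, 1,
               tolerance = 1e-10)
  # power for a 2 SD shift
  ok <- vapply(1:20, function(s) {
    set.seed(s + 600)
    wilcoxon_replication(rnorm(30), rnorm(30, 2))$p < 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.9)
  expect_error(wilcoxon_replication(1:2, 1:5), ">= 3")
})
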