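test_that("the Fisher-z CI test matches its closed form", {
  d <- make_exact_cor(103, 0.5, seed = 1)
  ct <- ci_test("x", "y", data = d)
  expect_equal(ct$statistic, sqrt(100) * atanh(0.5), tolerance = 1e-8)
  # zero correlation gives p = 1
  d0 <- make_exact_cor(50, 0, seed = 2)
  expect_equal(ci_test("x", "y", data = d0)$p, 1, tolerance = 1e-10)
  # d-separation: chain A -> B -> C is independent given B
  ok <- vapply(1:10, function(s) {
    ci_test("A", "C", "B", make_chain(5000, seed = s + 100))$p > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("PC skeleton recovers chains and empties under the null", {
  # chain: A-B, B-C without A-C in most seeds
  ok <- vapply(1:10, function(s) {
    net <- pc_skeleton(make_chain(5000, seed = s + 200), alpha = 0.01)
    setequal(txnetsig:::skeleton_keys(net), c("A|B", "B|C"))
  }, logical(1))
  expect_gte(mean(ok), 0.9)
  # mutually independent genes: empty skeleton in most seeds
  empty <- vapply(1:10, function(s) {
    set.seed(s + 300)
    x <- matrix(rnorm(2000 * 6), ncol = 6,
                dimnames = list(NULL, paste0("g", 1:6)))
    nrow(pc_skeleton(x, alpha = 0.01)$skeleton) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.9)
})

test_that("the stable skeleton is invariant to gene order", {
  set.seed(4)
  m <- simulate_dag(12, 0.2, seed = 5)
  m$weights <- runif(nrow(m$edges), 0.5, 1)
  x <- simulate_expression(m, n = 400, seed = 6)
  net1 <- pc_skeleton(x, alpha = 0.05)
  perm <- sample(ncol(x))
  net2 <- pc_skeleton(x[, perm], alpha = 0.05)
  expect_identical(net1$skeleton, net2$skeleton)
  expect_identical(net1$sepsets[sort(names(net1$sepsets))],
                   net2$sepsets[sort(names(net2$sepsets))])
})

test_that("v-structures orient colliders but not chains", {
  net <- pc_skeleton(make_collider(5000, seed = 7), alpha = 0.01)
  net <- orient_v_structures(net)
  expect_setequal(paste(net$directed$from, net$directed$to),
                  c("A C", "B C"))
  chain_net <- pc_skeleton(make_chain(5000, seed = 8), alpha = 0.01)
  oriented <- orient_v_structures(chain_net)
  expect_equal(nrow(oriented$directed), 0)
  # no unshielded triple: output equals input
  tri <- gene_network(c("A", "B"), skeleton = data.frame(a = "A", b = "B"))
  expect_identical(orient_v_structures(tri)$directed, tri$directed)
})

test_that("instrument orientation points from the eGene and resists reversal", {
  # s -> A -> B: oriented A -> B
  set.seed(9)
  n <- 1000
  dose <- rbinom(n, 2, 0.3)
  a <- 0.5 * dose + rnorm(n)
  b <- 0.8 * a + rnorm(n)
  dat <- cbind(A = a, B = b)
  net <- gene_network(c("A", "B"), skeleton = data.frame(a = "A", b = "B"))
  out <- orient_with_instruments(net, data.frame(gene = "A", best_snp = "s"),
                                 cbind(s = dose), dat)
  expect_equal(out$directed, data.frame(from = "A", to = "B"))
  # s -> A <- B (B causes A): instrument says nothing about B, no orientation
  rev_ok <- vapply(1:10, function(sd) {
    set.seed(sd + 400)
    b2 <- rnorm(n)
    a2 <- 0.5 * dose + 0.8 * b2 + rnorm(n)
    o <- orient_with_instruments(net,
                                 data.frame(gene = "A", best_snp = "s"),
                                 cbind(s = dose), cbind(A = a2, B = b2))
    !(nrow(o$directed) && o$directed$from[1] == "A")
  }, logical(1))
  expect_gte(mean(rev_ok), 0.9)
  # missing instrument: warning, edge skipped
  expect_warning(
    orient_with_instruments(net, data.frame(gene = "A", best_snp = "zz"),
                            cbind(s = dose), dat),
    "missing")
})

test_that("prior edges orient but never create or contradict", {
  net <- gene_network(c("A", "B", "C"),
                      skeleton = data.frame(a = c("A", "B"), b = c("B", "C")))
  out <- apply_prior_edges(net, data.frame(from = "A", to = "B"))
  expect_equal(out$directed, data.frame(from = "A", to = "B"))
  # non-adjacent prior ignored with a log message
  expect_message(apply_prior_edges(net, data.frame(from = "A", to = "C")),
                 "ignored")
  # contradictory priors error as a 2-cycle
  expect_error(
    apply_prior_edges(net, data.frame(from = c("A", "B"), to = c("B", "A"))),
    "cycle")
})

test_that("the FDR edge screen matches brute-force Benjamini-Hochberg", {
  set.seed(10)
  m <- simulate_dag(8, 0.25, seed = 11)
  m$weights <- runif(nrow(m$edges), 0.6, 1)
  x <- simulate_expression(m, n = 300, seed = 12)
  fdr <- edge_fdr_selection(x, q = 0.05)
  expect_equal(fdr$selected, bh_brute_force(fdr$p, 0.05))
  # degenerate corners of the step-up rule
  expect_equal(bh_brute_force(c(0.01, 0.02, 0.20), 0.05), c(TRUE, TRUE, FALSE))
  expect_false(any(bh_brute_force(rep(1, 5), 0.05)))
  expect_true(all(bh_brute_force(rep(1e-5, 5), 0.05)))
})

test_that("Hamming distance counts adjacency differences, vs a brute-force oracle", {
  nodes <- paste0("g", 1:4)
  g_empty <- gene_network(nodes)
  g_one <- gene_network(nodes, skeleton = data.frame(a = "g1", b = "g2"))
  all_pairs <- t(combn(nodes, 2))
  g_full <- gene_network(nodes, skeleton = data.frame(a = all_pairs[, 1],
                                                      b = all_pairs[, 2]))
  expect_equal(hamming_distance(g_one, g_one), 0)
  expect_equal(hamming_distance(g_empty, g_one), 1)
  expect_equal(hamming_distance(g_empty, g_full), 6)
  # random graphs vs direct pairwise comparison
  set.seed(13)
  for (i in 1:5) {
    pick <- function() all_pairs[runif(6) < 0.5, , drop = FALSE]
    e1 <- pick(); e2 <- pick()
    n1 <- gene_network(nodes, skeleton = data.frame(a = e1[, 1], b = e1[, 2]))
    n2 <- gene_network(nodes, skeleton = data.frame(a = e2[, 1], b = e2[, 2]))
    brute <- sum(apply(all_pairs, 1, function(pr) {
      k <- paste(pr[1], pr[2], sep = "|")
      (k %in% txnetsig:::skeleton_keys(n1)) !=
        (k %in% txnetsig:::skeleton_keys(n2))
    }))
    expect_equal(hamming_distance(n1, n2), brute)
  }
  g_other <- gene_network(paste0("h", 1:4))
  expect_error(hamming_distance(g_empty, g_other), "node sets")
})

test_that("stability curves have the right length and vanish under the null", {
  set.seed(14)
  x <- matrix(rnorm(3000 * 4), ncol = 4,
              dimnames = list(NULL, paste0("g", 1:4)))
  sc <- stability_curve(x, i_range = 3:8)
  expect_length(sc$hd, 5)
  expect_true(all(sc$hd == 0))  # all skeletons empty at large n under the null
  expect_error(stability_curve(x, i_range = c(3, 5)), "contiguous")
})

test_that("the broken-stick fit recovers planted changepoints", {
  i_range <- 3:22
  x <- i_range[-1]
  # noise-free: flat at 2 until i = 10, then slope +5 per step
  hd <- 2 + 5 * pmax(x - 10, 0)
  bp <- piecewise_breakpoint(list(hd = hd, i_range = i_range))
  expect_equal(bp$i, 10)
  expect_equal(bp$alpha, 1e-10)
  # perfectly linear: no significant slope change, default + warning
  expect_warning(
    lin <- piecewise_breakpoint(list(hd = 2 + 3 * x, i_range = i_range)),
    "default")
  expect_true(is.na(lin$i))
  expect_equal(lin$alpha, 1e-3)
})

test_that("stable edges are the intersection of the two selections", {
  nodes <- c("A", "B", "C")
  hd_net <- gene_network(nodes,
                         skeleton = data.frame(a = c("A", "B"),
                                               b = c("B", "C")))
  fdr <- data.frame(a = c("A", "A"), b = c("B", "C"),
                    selected = c(TRUE, TRUE))
  st <- stable_edges(fdr, hd_net)
  expect_equal(paste(st$a, st$b), "A B")
  # disjoint -> empty; identical -> unchanged
  expect_equal(nrow(stable_edges(data.frame(a = "A", b = "C",
                                            selected = TRUE), hd_net)), 0)
  full <- stable_edges(data.frame(a = c("A", "B"), b = c("B", "C"),
                                  selected = TRUE), hd_net)
  expect_equal(full, hd_net$skeleton, ignore_attr = TRUE)
})

test_that("edge validation is exact for deterministic links and strict at the boundary", {
  set.seed(15)
  n <- 150
  p <- rnorm(n)
  x <- cbind(P = p, Q = p, R = rnorm(n))   # Q identical to its neighbor P
  net <- gene_network(c("P", "Q", "R"),
                      skeleton = data.frame(a = c("P", "Q"), b = c("Q", "R")))
  val <- validate_edges(x[1:100, ], x[101:150, ], net)
  expect_true(val$edges$validated[val$edges$a == "P"])
  expect_equal(val$gene_r[["Q"]], 1, tolerance = 1e-12)
  # strictness: r must strictly exceed the threshold
  val_strict <- validate_edges(x[1:100, ], x[101:150, ], net, r_min = 1)
  expect_false(any(val_strict$edges$validated))
  expect_error(validate_edges(x[1:100, ], x[101:102, ], net), "test samples")
  # independent gene almost never validates at n_test = 103
  bench <- bench_edge_validation(n_true = 5, n_null = 20, seed = 16)
  expect_lt(bench$null_rate, 0.05)
})

test_that("sub-network extraction applies the distance-2 rule", {
  # path e - a - b - c anchored at eGene e: c is three steps away
  net <- gene_network(c("e", "a", "b", "c"),
                      skeleton = data.frame(a = c("a", "a", "b"),
                                            b = c("e", "b", "c")),
                      directed = data.frame(from = c("e", "a"),
                                            to = c("a", "b")))
  sn <- extract_subnetworks(net, "e")[[1]]
  expect_setequal(sn$members, c("e", "a", "b"))
  expect_equal(sn$upstream[["b"]], c("a", "e"))
  expect_equal(sn$upstream[["e"]], character(0))
  # isolated eGene: singleton
  iso <- gene_network(c("e", "x"), skeleton = data.frame(a = "e", b = "x")[0, ])
  expect_equal(extract_subnetworks(iso, "e")[[1]]$members, "e")
  # star: all neighbors included
  star <- gene_network(c("e", paste0("n", 1:4)),
                       skeleton = data.frame(a = "e", b = paste0("n", 1:4)))
  expect_setequal(extract_subnetworks(star, "e")[[1]]$members,
                  c("e", paste0("n", 1:4)))
})

test_that("gene clustering recovers planted correlation blocks", {
  set.seed(17)
  n <- 200
  f1 <- rnorm(n); f2 <- rnorm(n)
  x <- cbind(sapply(1:5, function(i) f1 + 0.3 * rnorm(n)),
             sapply(1:5, function(i) f2 + 0.3 * rnorm(n)))
  colnames(x) <- paste0("g", 1:10)
  cl <- cluster_genes(x, k = 2, seed = 18)
  expect_equal(length(unique(cl[1:5])), 1)
  expect_equal(length(unique(cl[6:10])), 1)
  expect_false(cl[1] == cl[6])
  expect_equal(unname(cluster_genes(x, k = 1, seed = 1)),
               rep(1L, 10))
  expect_error(cluster_genes(x, k = 11), "exceeds")
})

test_that("network edge tables serialize direction and flags", {
  net <- gene_network(c("A", "B", "C"),
                      skeleton = data.frame(a = c("A", "B"), b = c("B", "C")),
                      directed = data.frame(from = "A", to = "B"))
  tab <- network_edge_table(net)
  expect_equal(tab$direction, c("->", "--"))
  expect_equal(names(tab), c("gene_a", "gene_b", "direction", "p",
                             "stable_fdr", "stable_hd", "validation_r"))
})
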