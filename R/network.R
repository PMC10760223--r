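#' Mixed gene-network container
#'
#' Holds the undirected skeleton, the directed subset of its edges, the
#' separating sets recorded when edges were removed, and (after a PC run)
#' the maximum p-value seen for every node pair, which feeds the FDR edge
#' screen.  The directed part must stay acyclic and a subset of skeleton
#' orientations.
#'
#' @param nodes Character vector of gene ids.
#' @param skeleton Data frame `a`, `b` of unordered edges (canonicalized so
#'   `a < b` lexicographically).
#' @param directed Data frame `from`, `to` of oriented skeleton edges.
#' @param sepsets Named list keyed `"a|b"` giving the conditioning set that
#'   separated a removed pair.
#' @param test_max_p Optional symmetric matrix of maximum CI-test p-values
#'   per pair.
#' @return An object of class `gene_network`.
#' @export
gene_network <- function(nodes, skeleton = NULL, directed = NULL,
                         sepsets = list(), test_max_p = NULL) {
  nodes <- as.character(nodes)
  skeleton <- canonical_edges(skeleton)
  directed <- if (is.null(directed) || !NROW(directed)) {
    data.frame(from = character(), to = character())
  } else {
    data.frame(from = as.character(directed[[1]]),
               to = as.character(directed[[2]]))
  }
  net <- structure(list(nodes = nodes, skeleton = skeleton,
                        directed = directed, sepsets = sepsets,
                        test_max_p = test_max_p),
                   class = "gene_network")
  check_network(net)
  net
}

canonical_edges <- function(edges) {
  if (is.null(edges) || !NROW(edges)) {
    return(data.frame(a = character(), b = character()))
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  out <- unique(data.frame(a = pmin(a, b), b = pmax(a, b)))
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_network <- function(net) {
  if (!all(c(net$skeleton$a, net$skeleton$b) %in% net$nodes)) {
    stop("skeleton references unknown nodes")
  }
  if (nrow(net$directed)) {
    dk <- edge_key(net$directed$from, net$directed$to)
    if (!all(dk %in% edge_key(net$skeleton$a, net$skeleton$b))) {
      stop("directed edges must orient skeleton edges")
    }
    if (anyDuplicated(dk)) stop("edge oriented in both directions")
    if (!directed_is_acyclic(net)) stop("directed part contains a cycle")
  }
  invisible(net)
}

directed_is_acyclic <- function(net) {
  if (!nrow(net$directed)) return(TRUE)
  g <- igraph::graph_from_data_frame(net$directed, directed = TRUE,
                                     vertices = net$nodes)
  igraph::is_dag(g)
}

skeleton_keys <- function(net) edge_key(net$skeleton$a, net$skeleton$b)

undirected_edges <- function(net) {
  keys <- skeleton_keys(net)
  dk <- if (nrow(net$directed)) edge_key(net$directed$from, net$directed$to)
        else character(0)
  net$skeleton[!(keys %in% dk), , drop = FALSE]
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d skeleton edges (%d directed)\n",
              length(x$nodes), nrow(x$skeleton), nrow(x$directed)))
  invisible(x)
}

#' Cluster genes by expression profile
#'
#' k-means on standardized gene profiles (each gene a point in sample
#' space), used to split the transcriptome into tractable blocks before
#' network learning.  Deterministic given `seed` (fixed restarts).
#'
#' @param expression Samples x genes matrix.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param nstart k-means restarts.
#' @return Named integer vector mapping gene to cluster.
#' @export
cluster_genes <- function(expression, k = 4, seed = 1, nstart = 25) {
  x <- assert_matrix(expression, "expression")
  k <- assert_count(k, "k")
  if (k > ncol(x)) stop("`k` exceeds the number of genes")
  z <- scale(x)
  z[, col_sds(x) == 0] <- 0
  set.seed(seed)
  km <- stats::kmeans(t(z), centers = k, nstart = nstart, iter.max = 100)
  stats::setNames(km$cluster, colnames(x))
}

# Partial correlation of variables i, j given S, from a correlation matrix.
.pcor <- function(C, i, j, S) {
  if (!length(S)) return(C[i, j])
  idx <- c(i, j, S)
  P <- tryCatch(solve(C[idx, idx]), error = function(e) NULL)
  if (is.null(P)) return(NA_real_)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

.pcor_pvalue <- function(r, n, card) {
  if (is.na(r)) return(NA_real_)
  if (abs(r) >= 1 - 1e-12) return(0)
  stat <- sqrt(max(n - card - 3, 1)) * abs(atanh(r))
  2 * stats::pnorm(-stat)
}

#' Gaussian conditional-independence test
#'
#' Fisher z-transform of the sample partial correlation of `x` and `y`
#' given `S`; the statistic `sqrt(n - |S| - 3) * |atanh(r)|` is referred to
#' a standard normal, two-sided.  A singular conditioning covariance yields
#' p = 1 with a warning (independence cannot be rejected).
#'
#' @param x,y Gene names (or column indices) in `data`.
#' @param S Conditioning set of gene names (possibly empty).
#' @param data Samples x genes matrix.
#' @return List `r` (partial correlation), `statistic`, `p`.
#' @export
ci_test <- function(x, y, S = character(0), data) {
  m <- assert_matrix(data, "data")
  cols <- c(x, y, S)
  C <- stats::cor(m[, cols, drop = FALSE])
  n <- nrow(m)
  if (n <= length(S) + 3) stop("need n > |S| + 3")
  r <- .pcor(C, 1, 2, if (length(S)) 2 + seq_along(S) else integer(0))
  if (is.na(r)) {
    warning("singular conditioning covariance; returning p = 1")
    return(list(r = NA_real_, statistic = 0, p = 1))
  }
  stat <- if (abs(r) >= 1 - 1e-12) Inf else
    sqrt(max(n - length(S) - 3, 1)) * abs(atanh(r))
  list(r = r, statistic = stat, p = 2 * stats::pnorm(-stat))
}

# Search, in canonical label order, for a separating subset of size `l`
# drawn from the frozen neighbourhoods of i then j.  Returns the first
# separating set found plus the largest p-value seen while trying.
.find_sepset <- function(C, n, i, j, frozen, l, alpha) {
  maxp <- 0
  try_sets <- function(nbrs) {
    nbrs <- setdiff(nbrs, c(i, j))
    if (length(nbrs) < l) return(NULL)
    sets <- if (l == 0) list(integer(0)) else
      lapply(utils::combn(seq_along(nbrs), l, simplify = FALSE),
             function(pos) nbrs[pos])
    for (S in sets) {
      p <- .pcor_pvalue(.pcor(C, i, j, S), n, l)
      if (is.na(p)) p <- 1  # singular: cannot reject independence
      maxp <<- max(maxp, p)
      if (p > alpha) return(S)
    }
    NULL
  }
  sep <- try_sets(which(frozen[i, ]))
  if (is.null(sep) && l > 0) sep <- try_sets(which(frozen[j, ]))
  list(sep = sep, maxp = maxp)
}

#' Order-independent (stable) PC skeleton search
#'
#' Starts from the complete graph and, for increasing conditioning-set size
#' `l = 0..max_order`, tests every still-adjacent pair against subsets of
#' size `l` of the endpoints' neighbourhoods *frozen at the start of the
#' level*; all removals of a level are applied together at its end.  The
#' resulting skeleton is therefore invariant to any permutation of the
#' input gene order.  The separating set of every removed pair is recorded
#' (it drives v-structure orientation), as is the maximum CI-test p-value
#' per pair (it drives the FDR edge screen).
#'
#' @param data Samples x genes matrix for one cluster.
#' @param alpha CI-test significance level in (0, 1); a pair is
#'   disconnected when some test exceeds it.
#' @param max_order Largest conditioning-set size searched.
#' @return A [gene_network()] with empty `directed` part.
#' @export
pc_skeleton <- function(data, alpha = 0.01, max_order = 3) {
  x <- assert_matrix(data, "data")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  genes <- colnames(x) %||% paste0("g", seq_len(ncol(x)))
  ord <- order(genes)
  genes <- genes[ord]
  C <- stats::cor(x[, ord, drop = FALSE])
  n <- nrow(x)
  p <- length(genes)
  adj <- matrix(TRUE, p, p, dimnames = list(genes, genes))
  diag(adj) <- FALSE
  sepsets <- list()
  maxp <- matrix(0, p, p, dimnames = list(genes, genes))
  for (l in 0:max_order) {
    if (n <= l + 3) break
    frozen <- adj
    removals <- list()
    for (i in seq_len(p - 1)) {
      for (j in seq.int(i + 1, p)) {
        if (!frozen[i, j]) next
        res <- .find_sepset(C, n, i, j, frozen, l, alpha)
        maxp[i, j] <- maxp[j, i] <- max(maxp[i, j], res$maxp)
        if (!is.null(res$sep)) {
          removals[[length(removals) + 1]] <- list(i = i, j = j, sep = res$sep)
        }
      }
    }
    for (r in removals) {
      adj[r$i, r$j] <- adj[r$j, r$i] <- FALSE
      sepsets[[paste(genes[r$i], genes[r$j], sep = "|")]] <-
        genes[sort(r$sep)]
    }
    if (!any(adj) || max(rowSums(adj)) - 1 < l + 1) break
  }
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  gene_network(genes,
               skeleton = data.frame(a = genes[idx[, 1]], b = genes[idx[, 2]]),
               sepsets = sepsets, test_max_p = maxp)
}

#' Orient v-structures
#'
#' For every unshielded triple `x - z - y` (x, y non-adjacent) in which `z`
#' does not belong to the recorded separating set of x and y, proposes the
#' collider orientation `x -> z <- y`.  Proposals are collected over all
#' triples first, then applied; any edge proposed in both directions
#' reverts to undirected (logged via message), making the step independent
#' of triple enumeration order.
#'
#' @param net A [gene_network()] with sepsets from [pc_skeleton()].
#' @return The network with collider edges added to `directed`.
#' @export
orient_v_structures <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  adj <- skeleton_adjacency(net)
  props <- character(0)
  for (key in names(net$sepsets)) {
    xy <- strsplit(key, "|", fixed = TRUE)[[1]]
    x <- xy[1]; y <- xy[2]
    if (!(x %in% rownames(adj)) || isTRUE(adj[x, y])) next
    zs <- rownames(adj)[adj[x, ] & adj[y, ]]
    zs <- setdiff(zs, net$sepsets[[key]])
    for (z in zs) props <- c(props, paste(x, z, sep = "\r"),
                             paste(y, z, sep = "\r"))
  }
  props <- unique(props)
  if (!length(props)) return(net)
  mat <- do.call(rbind, strsplit(props, "\r", fixed = TRUE))
  keys <- edge_key(mat[, 1], mat[, 2])
  conflicted <- keys %in% keys[duplicated(keys)]
  if (any(conflicted)) {
    message("v-structure conflicts on ", sum(conflicted) / 2,
            " edge(s); left undirected")
  }
  new_dir <- data.frame(from = mat[!conflicted, 1], to = mat[!conflicted, 2])
  net$directed <- unique(rbind(net$directed, new_dir))
  net <- .revert_directed_cycles(net)
  check_network(net)
}

skeleton_adjacency <- function(net) {
  p <- length(net$nodes)
  adj <- matrix(FALSE, p, p, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$skeleton)) {
    adj[cbind(net$skeleton$a, net$skeleton$b)] <- TRUE
    adj[cbind(net$skeleton$b, net$skeleton$a)] <- TRUE
  }
  adj
}

# Degenerate orientation patterns can close a directed cycle; revert the
# offending orientations to undirected rather than ship a cyclic graph.
.revert_directed_cycles <- function(net) {
  if (directed_is_acyclic(net)) return(net)
  warning("orientation produced a directed cycle; reverting offending edges")
  g <- igraph::graph_from_data_frame(net$directed, directed = TRUE,
                                     vertices = net$nodes)
  fas <- igraph::feedback_arc_set(g)
  drop <- igraph::as_ids(fas)
  keys_drop <- vapply(strsplit(drop, "|", fixed = TRUE),
                      function(e) paste(e[1], e[2], sep = "\r"), character(1))
  have <- paste(net$directed$from, net$directed$to, sep = "\r")
  net$directed <- net$directed[!(have %in% keys_drop), , drop = FALSE]
  net
}

#' Orient edges with cis-eQTL instruments (Mendelian randomization)
#'
#' For an undirected edge `A - B` where `A` is an eGene with instrument SNP
#' `s`: if `s` is marginally associated with `B` (p < `alpha_iv`) but that
#' association vanishes once `A` is conditioned on (p >= `alpha_cond`), the
#' instrument's effect on `B` flows through `A`, so the edge is oriented
#' `A -> B`.  If both endpoints qualify symmetrically the edge is left
#' undirected and the conflict logged.  Orientations that would close a
#' directed cycle are skipped with a warning.
#'
#' @param net A [gene_network()].
#' @param egenes Data frame `gene`, `best_snp` (e.g. [select_egenes()]
#'   output, with `best_snp` as instrument).
#' @param genotypes Samples x SNPs dosage matrix.
#' @param data Samples x genes expression matrix (same samples).
#' @param alpha_iv Significance level for the marginal instrument-outcome
#'   test.
#' @param alpha_cond Level below which the conditional association is still
#'   considered present (blocking orientation).
#' @return The network with MR-oriented edges added; conflicts recorded in
#'   `attr(net, "iv_conflicts")`.
#' @export
orient_with_instruments <- function(net, egenes, genotypes, data,
                                    alpha_iv = 0.05, alpha_cond = 0.05) {
  stopifnot(inherits(net, "gene_network"))
  snp_of <- stats::setNames(as.character(egenes$best_snp),
                            as.character(egenes$gene))
  und <- undirected_edges(net)
  conflicts <- character(0)
  qualifies <- function(a, b) {
    # does a's instrument point a -> b?
    if (!(a %in% names(snp_of))) return(FALSE)
    s <- snp_of[[a]]
    if (!(s %in% colnames(genotypes))) {
      warning("instrument ", s, " missing from genotypes; edge skipped")
      return(NA)
    }
    dose <- genotypes[, s]
    if (stats::sd(dose) == 0) return(NA)
    p_marg <- .ols_slope(data[, b], dose)$p_nominal
    p_cond <- .ols_slope(data[, b], dose, data[, a, drop = FALSE])$p_nominal
    p_marg < alpha_iv && p_cond >= alpha_cond
  }
  for (e in seq_len(nrow(und))) {
    a <- und$a[e]; b <- und$b[e]
    qa <- qualifies(a, b)
    qb <- qualifies(b, a)
    if (anyNA(c(qa, qb))) next
    if (qa && qb) {
      conflicts <- c(conflicts, edge_key(a, b))
      next
    }
    if (!qa && !qb) next
    prop <- if (qa) data.frame(from = a, to = b) else data.frame(from = b, to = a)
    cand <- net
    cand$directed <- rbind(cand$directed, prop)
    if (!directed_is_acyclic(cand)) {
      warning("MR orientation ", prop$from, " -> ", prop$to,
              " would create a cycle; skipped")
      next
    }
    net <- cand
  }
  if (length(conflicts)) {
    message("symmetric instrument evidence on ", length(conflicts),
            " edge(s); left undirected")
  }
  attr(net, "iv_conflicts") <- conflicts
  check_network(net)
}

#' Impose prior-knowledge edge orientations
#'
#' Orients existing skeleton edges according to a table of known regulatory
#' relations.  Priors never add an edge the data did not support: a prior
#' on a non-adjacent pair is ignored (logged).  Contradictory priors or a
#' prior closing a directed cycle raise an error naming the cycle.
#'
#' @param net A [gene_network()].
#' @param priors Data frame `from`, `to`.
#' @return The updated network.
#' @export
apply_prior_edges <- function(net, priors) {
  stopifnot(inherits(net, "gene_network"))
  if (!NROW(priors)) return(net)
  priors <- data.frame(from = as.character(priors[[1]]),
                       to = as.character(priors[[2]]))
  if (!all(c(priors$from, priors$to) %in% net$nodes)) {
    stop("prior references unknown nodes")
  }
  skel <- skeleton_keys(net)
  for (i in seq_len(nrow(priors))) {
    a <- priors$from[i]; b <- priors$to[i]
    key <- edge_key(a, b)
    if (!(key %in% skel)) {
      message("prior ", a, " -> ", b, " has no skeleton edge; ignored")
      next
    }
    have <- paste(net$directed$from, net$directed$to, sep = "\r")
    if (paste(b, a, sep = "\r") %in% have) {
      stop("contradictory orientation for edge ", a, " - ", b,
           " (directed cycle of length 2)")
    }
    if (paste(a, b, sep = "\r") %in% have) next
    net$directed <- rbind(net$directed, data.frame(from = a, to = b))
    if (!directed_is_acyclic(net)) {
      g <- igraph::graph_from_data_frame(net$directed, directed = TRUE,
                                         vertices = net$nodes)
      cyc <- igraph::shortest_paths(g, from = b, to = a, mode = "out")$vpath[[1]]
      stop("prior ", a, " -> ", b, " creates directed cycle: ",
           paste(c(igraph::as_ids(cyc), b), collapse = " -> "))
    }
  }
  check_network(net)
}

#' FDR screen over all within-cluster gene pairs
#'
#' Starts conceptually from the dense graph on the cluster and keeps pairs
#' whose association survives a Benjamini-Hochberg screen at level `q`.
#' Each pair's p-value is the *maximum* p over every conditional-
#' independence test attempted for it during a loose-alpha PC pass — a
#' conservative summary: a pair is only credited with dependence if no
#' attempted conditioning set came close to separating it.
#'
#' @param data Samples x genes matrix for one cluster.
#' @param q BH false-discovery level.
#' @param alpha_loose CI level of the screening PC pass (loose on purpose
#'   so weak pairs are still probed at higher orders).
#' @param max_order Maximum conditioning order of the screening pass.
#' @return Data frame `a`, `b`, `p`, `p_adj`, `selected` over all pairs.
#' @export
edge_fdr_selection <- function(data, q = 0.05, alpha_loose = 0.5,
                               max_order = 3) {
  net <- pc_skeleton(data, alpha = alpha_loose, max_order = max_order)
  mp <- net$test_max_p
  idx <- which(upper.tri(mp), arr.ind = TRUE)
  out <- data.frame(a = rownames(mp)[idx[, 1]], b = colnames(mp)[idx[, 2]],
                    p = mp[idx])
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$selected <- out$p_adj <= q
  out[order(out$a, out$b), , drop = FALSE]
}

#' Hamming distance between two networks
#'
#' Number of unordered node pairs whose skeleton adjacency differs.  Both
#' networks must share one node set.
#'
#' @param g1,g2 [gene_network()] objects (or data frames of edges over the
#'   same implicit node set).
#' @return Non-negative integer count.
#' @export
hamming_distance <- function(g1, g2) {
  stopifnot(inherits(g1, "gene_network"), inherits(g2, "gene_network"))
  if (!setequal(g1$nodes, g2$nodes)) stop("networks have different node sets")
  k1 <- skeleton_keys(g1)
  k2 <- skeleton_keys(g2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Skeletons along a significance grid
#'
#' Runs the stable PC skeleton at `alpha_i = 10^-i` for each `i` in
#' `i_range` and records the Hamming distance between each pair of
#' consecutive networks; the breakpoint of that curve locates the sparsity
#' level at which the network stops changing.
#'
#' @param data Samples x genes matrix for one cluster.
#' @param i_range Contiguous integer exponents (alpha = 10^-i).
#' @param max_order Passed to [pc_skeleton()].
#' @return Object of class `stability_curve`: `i_range`, `alphas`, `hd`
#'   (length `length(i_range) - 1`, attached to the larger exponent of each
#'   pair), `n_edges`, `networks`.
#' @export
stability_curve <- function(data, i_range = 3:22, max_order = 3) {
  if (any(diff(i_range) != 1)) stop("`i_range` must be contiguous")
  nets <- lapply(i_range, function(i) pc_skeleton(data, alpha = 10^-i,
                                                  max_order = max_order))
  hd <- vapply(seq_along(nets)[-1],
               function(k) hamming_distance(nets[[k]], nets[[k - 1]]),
               numeric(1))
  n_edges <- vapply(nets, function(n) nrow(n$skeleton), numeric(1))
  if (any(diff(n_edges) > 0)) {
    message("edge count increased at some grid step(s); ",
            "sparsity is not monotone here")
  }
  structure(list(i_range = i_range, alphas = 10^-i_range, hd = hd,
                 n_edges = n_edges, networks = nets),
            class = "stability_curve")
}

#' Broken-stick breakpoint of a Hamming-distance curve
#'
#' Fits, for every candidate breakpoint `k`, the two-segment model
#' `HD = b0 + b1 * x + b3 * (x - k) * I(x > k)` with `x = -log10(alpha)`,
#' and tests the slope-change coefficient `b3`.  Among candidates whose
#' slope change is significant at `sig_level`, the default rule picks the
#' most significant one (smallest p, the best-supported changepoint);
#' `"largest_i"` / `"smallest_i"` instead pick the extreme significant
#' exponent.  With no significant candidate the default alpha is returned
#' with a warning.
#'
#' @param fit A `stability_curve`, or a list with `hd` and `i_range`.
#' @param sig_level Significance level for the slope-change test.
#' @param rule Candidate selection rule.
#' @param default_i Exponent returned when nothing is significant.
#' @return Object of class `breakpoint_fit`: `alpha`, `i` (chosen
#'   exponent, `NA` when defaulted), `p_trace` (candidate, p), `coefs`,
#'   `rule`.
#' @export
piecewise_breakpoint <- function(fit, sig_level = 0.05,
                                 rule = c("min_p", "largest_i", "smallest_i"),
                                 default_i = NULL) {
  rule <- match.arg(rule)
  hd <- fit$hd
  x <- fit$i_range[-1]
  if (length(hd) < 4) stop("need >= 4 points on the curve")
  default_i <- default_i %||% min(fit$i_range)
  # a curve the single straight line already fits perfectly has no slope
  # change to find (and degenerate SEs would fake one)
  base_fit <- stats::lm(hd ~ x)
  if (suppressWarnings(summary(base_fit))$sigma^2 <=
      1e-12 * max(stats::var(hd), 1e-12)) {
    warning("curve is exactly linear; no breakpoint, returning default ",
            "alpha 10^-", default_i)
    return(structure(list(alpha = 10^-default_i, i = NA_integer_,
                          p_trace = NULL, coefs = NULL, rule = rule,
                          sig_level = sig_level),
                     class = "breakpoint_fit"))
  }
  cand <- x[x >= x[2] & x <= x[length(x) - 1]]
  rows <- lapply(cand, function(k) {
    z <- pmax(x - k, 0)
    fitk <- stats::lm(hd ~ x + z)
    sm <- suppressWarnings(summary(fitk))$coefficients
    if (!("z" %in% rownames(sm))) return(NULL)
    data.frame(candidate = k, beta0 = sm["(Intercept)", 1],
               beta1 = sm["x", 1], beta3 = sm["z", 1],
               p_beta3 = sm["z", 4],
               rss = sum(stats::residuals(fitk)^2))
  })
  trace <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  sig <- trace[!is.na(trace$p_beta3) & trace$p_beta3 < sig_level, ,
               drop = FALSE]
  if (!nrow(sig)) {
    warning("no significant breakpoint; returning default alpha 10^-",
            default_i)
    chosen <- NA_integer_
    alpha <- 10^-default_i
    coefs <- NULL
  } else {
    chosen <- switch(rule,
                     min_p = sig$candidate[which.min(sig$p_beta3)],
                     largest_i = max(sig$candidate),
                     smallest_i = min(sig$candidate))
    alpha <- 10^-chosen
    coefs <- sig[sig$candidate == chosen,
                 c("beta0", "beta1", "beta3", "p_beta3")]
  }
  structure(list(alpha = alpha, i = chosen, p_trace = trace, coefs = coefs,
                 rule = rule, sig_level = sig_level),
            class = "breakpoint_fit")
}

#' Intersect the two stability selections
#'
#' The stable edge set is the intersection of the FDR-screened pairs and
#' the skeleton of the network at the breakpoint-selected alpha — an edge
#' must survive both procedures.
#'
#' @param fdr_edges Output of [edge_fdr_selection()] (or any data frame
#'   `a`, `b` with a logical `selected` column; rows already filtered are
#'   also accepted).
#' @param hd_net The [gene_network()] chosen by the Hamming-distance
#'   breakpoint.
#' @return Data frame `a`, `b` of edges kept by both methods.
#' @export
stable_edges <- function(fdr_edges, hd_net) {
  stopifnot(inherits(hd_net, "gene_network"))
  fe <- as.data.frame(fdr_edges)
  if ("selected" %in% names(fe)) fe <- fe[fe$selected, , drop = FALSE]
  fk <- edge_key(fe$a, fe$b)
  keep <- skeleton_keys(hd_net) %in% fk
  hd_net$skeleton[keep, c("a", "b"), drop = FALSE]
}

#' Validate network edges on held-out samples
#'
#' For every gene with at least one neighbor in the graph, fits the
#' training-sample least-squares prediction of the gene from its direct
#' (upstream and downstream) neighbors, predicts the held-out samples, and
#' correlates observed with predicted expression.  A link counts as
#' validated when some endpoint's prediction correlation strictly exceeds
#' `r_min`.
#'
#' @param train,test Samples x genes matrices with disjoint sample sets.
#' @param net A [gene_network()].
#' @param r_min Validation threshold on the Pearson correlation.
#' @return List `gene_r` (per-gene correlation), `edges` (a, b, r,
#'   validated), `fraction` (validated share of testable links).
#' @export
validate_edges <- function(train, test, net, r_min = 0.5) {
  stopifnot(inherits(net, "gene_network"))
  if (nrow(test) < 3) stop("need at least 3 test samples")
  adj <- skeleton_adjacency(net)
  gene_r <- stats::setNames(rep(NA_real_, length(net$nodes)), net$nodes)
  for (g in net$nodes) {
    nbrs <- rownames(adj)[adj[g, ]]
    if (!length(nbrs) || !(g %in% colnames(train))) next
    X <- cbind(1, train[, nbrs, drop = FALSE])
    cf <- qr.coef(qr(X), train[, g])
    cf[is.na(cf)] <- 0
    pred <- as.numeric(cbind(1, test[, nbrs, drop = FALSE]) %*% cf)
    if (stats::sd(pred) == 0 || stats::sd(test[, g]) == 0) next
    gene_r[g] <- stats::cor(test[, g], pred)
  }
  ed <- net$skeleton
  if (nrow(ed)) {
    ed$r <- pmax(gene_r[ed$a], gene_r[ed$b], na.rm = TRUE)
    ed$r[is.infinite(ed$r)] <- NA_real_
    ed$validated <- !is.na(ed$r) & ed$r > r_min
  } else {
    ed$r <- numeric(0)
    ed$validated <- logical(0)
  }
  testable <- !is.na(ed$r)
  list(gene_r = gene_r, edges = ed,
       fraction = if (any(testable)) mean(ed$validated[testable]) else NA_real_)
}

#' Extract eGene-anchored sub-networks
#'
#' A sub-network is the set of genes within undirected graph distance 2 of
#' an eGene (its direct neighbors and their neighbors), together with an
#' upstream map: for every member, the ordered set of its ancestors under
#' the directed edges restricted to the members.  Sub-networks may overlap.
#'
#' @param net A [gene_network()].
#' @param egenes Character vector of eGene ids (must be nodes).
#' @return List of `subnetwork` objects (`anchor`, `members`, `upstream`).
#' @export
extract_subnetworks <- function(net, egenes) {
  stopifnot(inherits(net, "gene_network"))
  egenes <- as.character(egenes)
  if (!all(egenes %in% net$nodes)) stop("eGenes must be network nodes")
  gu <- igraph::graph_from_data_frame(net$skeleton, directed = FALSE,
                                      vertices = net$nodes)
  lapply(egenes, function(e) {
    d <- igraph::distances(gu, v = e)[1, ]
    members <- sort(names(d)[is.finite(d) & d <= 2])
    dir_sub <- net$directed[net$directed$from %in% members &
                              net$directed$to %in% members, , drop = FALSE]
    gd <- igraph::graph_from_data_frame(dir_sub, directed = TRUE,
                                        vertices = members)
    upstream <- lapply(stats::setNames(members, members), function(m) {
      anc <- igraph::as_ids(igraph::subcomponent(gd, m, mode = "in"))
      sort(setdiff(anc, m))
    })
    structure(list(anchor = e, members = members, upstream = upstream),
              class = "subnetwork")
  })
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("subnetwork anchored at %s: %d members\n", x$anchor,
              length(x$members)))
  invisible(x)
}

#' Serialize a network to an edge-list data frame
#'
#' One row per skeleton edge with direction (`->`, `<-`, `--`), the
#' max-p-value used by the FDR screen when available, and any stability or
#' validation annotations that have been attached.
#'
#' @param net A [gene_network()].
#' @param stable_fdr,stable_hd Optional data frames of edges flagged by the
#'   two stability procedures.
#' @param validation Optional `edges` element of [validate_edges()] output.
#' @return Data frame `gene_a`, `gene_b`, `direction`, `p`, `stable_fdr`,
#'   `stable_hd`, `validation_r`.
#' @export
network_edge_table <- function(net, stable_fdr = NULL, stable_hd = NULL,
                               validation = NULL) {
  sk <- net$skeleton
  keys <- skeleton_keys(net)
  dir <- rep("--", nrow(sk))
  if (nrow(net$directed)) {
    fwd <- paste(net$directed$from, net$directed$to, sep = "\r")
    dir[paste(sk$a, sk$b, sep = "\r") %in% fwd] <- "->"
    dir[paste(sk$b, sk$a, sep = "\r") %in% fwd] <- "<-"
  }
  p <- rep(NA_real_, nrow(sk))
  if (!is.null(net$test_max_p) && nrow(sk)) {
    p <- net$test_max_p[cbind(sk$a, sk$b)]
  }
  flag_in <- function(tab) {
    if (is.null(tab) || !NROW(tab)) return(rep(NA, nrow(sk)))
    keys %in% edge_key(tab$a, tab$b)
  }
  vr <- rep(NA_real_, nrow(sk))
  if (!is.null(validation) && NROW(validation)) {
    m <- match(keys, edge_key(validation$a, validation$b))
    vr <- validation$r[m]
  }
  data.frame(gene_a = sk$a, gene_b = sk$b, direction = dir, p = p,
             stable_fdr = flag_in(stable_fdr), stable_hd = flag_in(stable_hd),
             validation_r = vr)
}
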