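# Shared fixtures, built in code at test time.

# Chain A -> B -> C linear-Gaussian data.
make_chain <- function(n, w = 0.8, seed = 1) {
  set.seed(seed)
  a <- rnorm(n)
  b <- w * a + rnorm(n)
  cc <- w * b + rnorm(n)
  cbind(A = a, B = b, C = cc)
}

# Collider A -> C <- B data.
make_collider <- function(n, seed = 1) {
  set.seed(seed)
  a <- rnorm(n)
  b <- rnorm(n)
  cbind(A = a, B = b, C = a + b + rnorm(n))
}

# Two vectors with an exact sample correlation r (n samples).
make_exact_cor <- function(n, r, seed = 1) {
  set.seed(seed)
  u <- rnorm(n)
  v <- rnorm(n)
  u <- u - mean(u)
  v <- v - mean(v)
  v <- v - u * sum(u * v) / sum(u^2)
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  cbind(x = u, y = r * u + sqrt(1 - r^2) * v)
}

# A tiny deterministic sub-network object.
make_subnetwork <- function(anchor, members, upstream) {
  structure(list(anchor = anchor, members = members, upstream = upstream),
            class = "subnetwork")
}

# Brute-force Benjamini-Hochberg step-up selection.
bh_brute_force <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  passed <- which(p[ord] <= seq_len(m) / m * q)
  sel <- rep(FALSE, m)
  if (length(passed)) sel[ord[seq_len(max(passed))]] <- TRUE
  sel
}

# Brute-force unweighted two-group log-rank statistic (O - E)^2 / V.
logrank_brute_force <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- unique(group)[1]
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}
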