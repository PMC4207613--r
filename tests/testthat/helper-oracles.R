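# Independent oracles used across the suite. Each is deliberately written
# as brute force / exhaustive enumeration, independent of the package's
# implementation paths.

# Exhaustive per-focus enumeration of binomial thinning: every nucleus with
# m foci contributes over all 2^m success/failure vectors.
oracle_thin_enumerate <- function(k_per_nucleus, p, k_max = 6L) {
  out <- numeric(k_max + 1L)
  for (m in k_per_nucleus) {
    if (m == 0) {
      out[1] <- out[1] + 1
      next
    }
    vecs <- as.matrix(expand.grid(rep(list(c(0L, 1L)), m)))
    pr <- apply(vecs, 1, function(v) prod(ifelse(v == 1, p, 1 - p)))
    s <- rowSums(vecs)
    for (i in seq_along(s)) out[s[i] + 1L] <- out[s[i] + 1L] + pr[i]
  }
  out
}

# Two-sided Fisher p by full hypergeometric enumeration over all 2x2
# tables with the observed margins (point-probability convention).
oracle_fisher_enumerate <- function(a, na, b, nb) {
  m <- a + b
  x <- 0:m
  pr <- ifelse(x <= na & (m - x) <= nb,
               stats::dhyper(x, na, nb, m), 0)
  obs <- stats::dhyper(a, na, nb, m)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Exact two-sided rank-sum p by enumeration of all group assignments.
oracle_ranksum_enumerate <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  cmb <- utils::combn(n, n1)
  w_all <- colSums(matrix(r[cmb], nrow = n1))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Greedy matching of detected to true spots within a radius (um).
match_precision_recall <- function(true_xyz, det_xyz, radius = 0.3) {
  true_xyz <- as.matrix(true_xyz)
  det_xyz <- as.matrix(det_xyz)
  if (nrow(det_xyz) == 0)
    return(c(recall = 0, precision = NA_real_))
  used <- logical(nrow(det_xyz))
  tp <- 0
  for (i in seq_len(nrow(true_xyz))) {
    d <- sqrt(colSums((t(det_xyz) - true_xyz[i, ])^2))
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= radius) {
      used[j] <- TRUE
      tp <- tp + 1
    }
  }
  c(recall = tp / nrow(true_xyz), precision = tp / nrow(det_xyz))
}

cd_as_vector <- function(dist, k_max = attr(dist, "k_max")) {
  w <- as.numeric(unclass(dist))
  if (length(w) < k_max + 1) w <- c(w, numeric(k_max + 1 - length(w)))
  unname(w[seq_len(k_max + 1)])
}
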