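# Independent oracles used to check the implementation, written against
# different primitives than the code paths they verify.

# brute-force sample-entropy match counts via outer() distance matrices
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  dmax <- NULL
  for (k in 0:(m - 1)) {
    dk <- abs(outer(x[(1:nt) + k], x[(1:nt) + k], "-"))
    dmax <- if (is.null(dmax)) dk else pmax(dmax, dk)
  }
  dext <- abs(outer(x[(1:nt) + m], x[(1:nt) + m], "-"))
  up <- upper.tri(dmax)
  b <- sum(dmax[up] <= r)
  a <- sum((pmax(dmax, dext))[up] <= r)
  list(a = a, b = b, se = if (a > 0 && b > 0) -log(a / b) else NA_real_)
}

# exact two-sided Mann-Whitney p by full enumeration of group labelings
mw_enum_oracle <- function(a, b) {
  v <- c(a, b)
  n1 <- length(a)
  ranks <- rank(v)
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(v), n1)
  u_all <- apply(combs, 2, function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# all permutations of a vector (for exact Spearman on tiny n)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(all_perms(v[-i]), function(p) c(v[i], p))
  }))
}

spearman_perm_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(stats::cor(rx, ry))
  stats <- vapply(all_perms(seq_along(ry)),
                  function(p) abs(stats::cor(rx, ry[p])), numeric(1))
  mean(stats >= obs - 1e-9)
}

# exhaustive best-single-split search: minimal training error over all
# two-bin rules on one attribute
best_split_oracle <- function(values, labels) {
  ord <- order(values)
  v <- values[ord]; l <- as.character(labels)[ord]
  n <- length(v)
  classes <- unique(l)
  best <- list(error = Inf, boundary = NA_real_)
  cuts <- which(diff(v) > 0)
  for (k in cuts) {
    bnd <- (v[k] + v[k + 1]) / 2
    left <- l[1:k]; right <- l[(k + 1):n]
    err <- (length(left) - max(table(factor(left, classes)))) +
      (length(right) - max(table(factor(right, classes))))
    if (err < best$error) best <- list(error = err, boundary = bnd)
  }
  best
}

# analytic white-noise sample entropy for m = 2, fixed tolerance r_abs against
# the scale-1 SD sigma: the per-coordinate match probability of two iid
# N(0, sigma^2/tau) values is erf(r_abs / (2 sigma / sqrt(tau)))
white_noise_se <- function(tau, r = 0.15) {
  -log(2 * stats::pnorm(r / 2 * sqrt(tau) * sqrt(2)) - 1)
}

rand_ibi_like <- function(n, mean = 800, sd = 40) mean + sd * stats::rnorm(n)
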