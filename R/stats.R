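# exact Mann-Whitney null distribution by the count recursion ("shift
# algorithm") over the doubled mid-rank multiset: dp[k, s] = number of ways to
# choose k of the ranks with doubled-rank sum s. Ties are handled exactly
# because the recursion runs over the observed rank multiset.
mw_exact_tails <- function(ranks, n1, u_obs) {
  d <- as.integer(round(2 * ranks))
  S <- sum(d)
  dp <- matrix(0, nrow = n1 + 1L, ncol = S + 1L)
  dp[1L, 1L] <- 1
  for (v in d) {
    kmax <- n1
    for (k in kmax:1L) {
      src <- dp[k, 1:(S + 1L - v)]
      if (any(src != 0)) {
        dp[k + 1L, (v + 1L):(S + 1L)] <- dp[k + 1L, (v + 1L):(S + 1L)] + src
      }
    }
  }
  cnt <- dp[n1 + 1L, ]
  s_vals <- 0:S
  u_vals <- s_vals / 2 - n1 * (n1 + 1) / 2
  total <- sum(cnt)
  eps <- 1e-9
  list(
    p_le = sum(cnt[u_vals <= u_obs + eps]) / total,
    p_ge = sum(cnt[u_vals >= u_obs - eps]) / total,
    total = total
  )
}

#' Exact Mann-Whitney U test
#'
#' Rank-sum comparison of a numeric value between two groups. The U statistic
#' uses mid-ranks for ties. For combined sample sizes up to `exact_max` the
#' two-sided p-value is exact: the full null distribution of U over all
#' `choose(n1 + n2, n1)` group labelings of the observed rank multiset is
#' computed by a count recursion, and the smaller tail is doubled (capped at
#' 1). Above `exact_max` the tie-corrected normal approximation with
#' continuity correction is used and flagged `exact = FALSE`. The
#' normal-approximation `z` is always reported alongside for comparison with
#' software that prints z for exact tests.
#'
#' @param data a data frame.
#' @param value column with the measurement (tidy-eval).
#' @param group column with the two-level grouping factor (tidy-eval).
#' @param exact_max largest `n1 + n2` for which the exact distribution is
#'   enumerated (default 40; counts remain exactly representable in doubles).
#' @return A one-row tibble: `method`, `group1`, `group2`, `n1`, `n2`,
#'   `statistic` (U for `group1`), `z`, `p_value`, `exact`.
#' @export
#' @examples
#' d <- tibble::tibble(x = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
#' mann_whitney_exact(d, x, g)   # U = 0, exact two-sided p = 0.1
mann_whitney_exact <- function(data, value, group, exact_max = 40L) {
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- as.character(g[keep])
  lev <- if (is.factor(dplyr::pull(data, {{ group }}))) {
    levels(dplyr::pull(data, {{ group }}))
  } else {
    unique(g)
  }
  lev <- lev[lev %in% g]
  if (length(lev) != 2L) {
    stop_hrvci("hrvci_error_bad_argument",
               sprintf("`group` must have exactly 2 observed levels, found %d.", length(lev)))
  }
  a <- v[g == lev[1]]; b <- v[g == lev[2]]
  n1 <- length(a); n2 <- length(b)
  if (!n1 || !n2) stop_hrvci("hrvci_error_bad_argument", "both groups must be non-empty.")
  ranks <- rank(c(a, b))
  r1 <- sum(ranks[seq_len(n1)])
  u <- r1 - n1 * (n1 + 1) / 2
  # tie-corrected normal approximation with continuity correction
  nn <- n1 + n2
  ties <- table(ranks)
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  z <- if (sigma2 > 0) (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2) else 0
  exact <- nn <= exact_max
  if (exact) {
    tails <- mw_exact_tails(ranks, n1, u)
    p <- min(1, 2 * min(tails$p_le, tails$p_ge))
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  tibble(
    method = "Mann-Whitney U",
    group1 = lev[1], group2 = lev[2], n1 = n1, n2 = n2,
    statistic = u, z = z, p_value = p, exact = exact
  )
}

#' Spearman rank correlation test
#'
#' Correlation of mid-ranks (tie-corrected Pearson-on-ranks form). The
#' two-sided p-value uses the t approximation on `n - 2` degrees of freedom;
#' `method = "exact"` enumerates all `n!` permutations (available for
#' `n <= 10`) and reports the exact two-sided permutation p.
#'
#' @param data a data frame.
#' @param x,y numeric columns to correlate (tidy-eval).
#' @param method `"approx"` (default) or `"exact"`.
#' @return A one-row tibble: `method`, `n`, `rho`, `statistic` (t, approx
#'   only), `p_value`, `exact`.
#' @export
#' @examples
#' d <- tibble::tibble(x = 1:5, y = c(2, 1, 4, 3, 5))
#' spearman_test(d, x, y)$rho   # 0.8
spearman_test <- function(data, x, y, method = c("approx", "exact")) {
  method <- match.arg(method)
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 3L) stop_hrvci("hrvci_error_bad_argument", "need at least 3 paired observations.")
  if (length(yv) != n) stop_hrvci("hrvci_error_bad_argument", "`x` and `y` lengths differ.")
  rx <- rank(xv); ry <- rank(yv)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop_hrvci("hrvci_error_constant_input",
               "Spearman correlation is undefined for a constant input.")
  }
  rho <- stats::cor(rx, ry)
  if (method == "exact") {
    if (n > 10L) {
      stop_hrvci("hrvci_error_bad_argument",
                 "exact permutation p is available for n <= 10 only.")
    }
    p <- spearman_perm_p_cpp(rx, ry)
    return(tibble(method = "Spearman rank correlation", n = n, rho = rho,
                  statistic = NA_real_, p_value = p, exact = TRUE))
  }
  tstat <- if (abs(rho) < 1) rho * sqrt((n - 2) / (1 - rho^2)) else sign(rho) * Inf
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  tibble(method = "Spearman rank correlation", n = n, rho = rho,
         statistic = tstat, p_value = p, exact = FALSE)
}
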