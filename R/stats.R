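#' Fisher count test on retention vs splicing junction evidence
#'
#' Two-sided Fisher exact test on the 2x2 table
#' `[[retention_ctrl, splicing_ctrl], [retention_mut, splicing_mut]]`.
#' A table with any zero margin carries no information about the proportion
#' and returns p = 1 with `degenerate = TRUE`.
#'
#' @param retention_ctrl,splicing_ctrl,retention_mut,splicing_mut
#'   Non-negative integer counts (retention arm = EI + IE pooled; splicing
#'   arm = EE, by default doubled upstream — see [differential_ir_scan()]).
#' @return List with `p` and `degenerate`.
#' @export
fisher_count_test <- function(retention_ctrl, splicing_ctrl,
                              retention_mut, splicing_mut) {
  x <- c(retention_ctrl, splicing_ctrl, retention_mut, splicing_mut)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stopf("counts must be non-negative integers")
  m <- matrix(as.integer(round(x)), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L))
    return(list(p = 1, degenerate = TRUE))
  list(p = stats::fisher.test(m)$p.value, degenerate = FALSE)
}

#' Mann-Whitney U test with tie-aware exact small-sample p-values
#'
#' The U statistic is the number of pairs (x_i, y_j) with x_i > y_j, counting
#' ties as 1/2. When both groups have at most `exact_limit` observations the
#' two-sided p-value is computed from the exact permutation distribution of U
#' given the observed (possibly tied) values, via a dynamic program over the
#' rank multiset; p = min(1, 2 * min(P(U <= u), P(U >= u))). Otherwise the
#' normal approximation with tie correction is used (no continuity
#' correction).
#'
#' @param x,y Numeric vectors.
#' @param exact_limit Largest per-group size for the exact path.
#' @return List with `U`, `p`, `method`.
#' @export
mann_whitney_test <- function(x, y, exact_limit = 12L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stopf("empty group in Mann-Whitney test")
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  if (max(n1, n2) <= exact_limit) {
    p <- mw_exact_p(r, n1, U)
    list(U = U, p = p, method = "exact")
  } else {
    N <- n1 + n2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (U - n1 * n2 / 2) / sqrt(sigma2)
    list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
  }
}

# exact permutation distribution of the group-1 rank sum over all
# choose(N, n1) assignments, computed by DP over doubled (integer) ranks
mw_exact_p <- function(r, n1, U_obs) {
  r2 <- as.integer(round(2 * r))  # midranks doubled -> integers
  N <- length(r2)
  max_sum <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  # dp[k+1, s+1] = number of k-subsets with doubled-rank sum s
  dp <- matrix(0, nrow = n1 + 1L, ncol = max_sum + 1L)
  dp[1L, 1L] <- 1
  for (v in r2) {
    kmax <- n1
    for (k in kmax:1L) {
      src <- dp[k, ]
      nz <- which(src > 0)
      if (length(nz) > 0L) {
        tgt <- nz + v
        ok <- tgt <= max_sum + 1L
        dp[k + 1L, tgt[ok]] <- dp[k + 1L, tgt[ok]] + src[nz[ok]]
      }
    }
  }
  counts <- dp[n1 + 1L, ]
  total <- sum(counts)
  sums2 <- which(counts > 0) - 1L          # doubled rank sums
  u_vals <- sums2 / 2 - n1 * (n1 + 1) / 2  # corresponding U values
  w <- counts[counts > 0]
  eps <- 1e-9
  p_le <- sum(w[u_vals <= U_obs + eps]) / total
  p_ge <- sum(w[u_vals >= U_obs - eps]) / total
  min(1, 2 * min(p_le, p_ge))
}
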