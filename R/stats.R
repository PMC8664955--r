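#' Mann-Whitney U test with exact small-sample tie handling
#'
#' Two-sided rank-sum test. For `n1 * n2 <= 400` the p-value comes from the
#' exact permutation distribution of the rank sum, computed by a subset-sum
#' dynamic programme over the (possibly tied, average) ranks, so ties are
#' handled exactly; larger samples use the tie-corrected normal
#' approximation (no continuity correction). The reported `U` is for `x`.
#'
#' @param x,y Numeric samples, both non-empty.
#' @return List with `U`, `p` (two-sided), and `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  if (n1 * n2 <= 400) {
    # exact permutation distribution of W over all choose(N, n1) assignments
    r2 <- as.integer(round(2 * r)) # average ranks are half-integers
    maxs <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
    # dp[c + 1, s + 1] = number of size-c subsets with doubled-rank sum s
    dp <- matrix(0, n1 + 1L, maxs + 1L)
    dp[1L, 1L] <- 1
    for (ri in r2) {
      cmax <- n1
      for (cc in seq.int(min(cmax, n1), 1L)) {
        src <- dp[cc, seq_len(maxs + 1L - ri)]
        dp[cc + 1L, (ri + 1L):(maxs + 1L)] <-
          dp[cc + 1L, (ri + 1L):(maxs + 1L)] + src
      }
    }
    counts <- dp[n1 + 1L, ]
    total <- sum(counts)
    w2 <- as.integer(round(2 * W))
    p_le <- sum(counts[seq_len(w2 + 1L)]) / total
    p_ge <- sum(counts[(w2 + 1L):(maxs + 1L)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    list(U = U, p = p, method = "exact")
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (U - mu) / sqrt(sigma2)
    list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
  }
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; the p-value tests rho = 0 via the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))`. A constant vector has
#' no defined rank correlation and yields `NA` (the undefined marker used by
#' the correlation reports).
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @return List with `rho` and `p` (both `NA` for constant input).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) return(list(rho = NA_real_, p = NA_real_))
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2))
}

bonferroni <- function(p, family_size) pmin(1, p * family_size)

se_of <- function(x) sd(x) / sqrt(length(x))
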