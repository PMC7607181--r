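# Rank statistics implemented from formulas: Mann-Whitney U (exact by
# enumeration or tie-corrected normal approximation) and Spearman
# correlation.

# U statistic of x vs y by its definition: number of (x_i, y_j) pairs with
# x_i > y_j, counting ties as 1/2.
u_stat <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

#' Mann-Whitney U test
#'
#' Two-sided test of a location difference between two independent
#' samples. U is computed from average ranks. The p-value is exact - by
#' enumeration of all choose(n1+n2, n1) group labelings of the observed
#' values - when `n1 + n2 <= exact_limit` (default 12) and there are no
#' ties (or when `mode = "exact"` is forced); otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. Identical samples with zero rank variance return p = 1 with a
#' `zero_variance` flag.
#'
#' @param x,y numeric samples (non-empty).
#' @param mode "auto" (default), "exact", or "approx".
#' @param exact_limit combined-size switch point for auto mode.
#' @return list: `U` (for the first sample), `p.value`, `method`,
#'   `n` (c(n1, n2)), `ties`, `zero_variance`.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "approx"),
                         exact_limit = 12L) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y))
    abort("both samples must be non-empty", "ihcmet_param_error")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  comb <- c(x, y)
  has_ties <- anyDuplicated(comb) > 0L
  U <- u_stat(x, y)
  mu <- n1 * n2 / 2

  if (length(unique(comb)) == 1L)
    return(list(U = U, p.value = 1, method = "degenerate",
                n = c(n1, n2), ties = TRUE, zero_variance = TRUE))

  use_exact <- switch(mode,
                      exact = TRUE,
                      approx = FALSE,
                      auto = n <= exact_limit && !has_ties)
  if (use_exact) {
    idx <- combn(n, n1)
    devs <- apply(idx, 2L, function(i)
      abs(u_stat(comb[i], comb[-i]) - mu))
    pv <- mean(devs >= abs(U - mu) - 1e-9)
    return(list(U = U, p.value = pv, method = "exact",
                n = c(n1, n2), ties = has_ties, zero_variance = FALSE))
  }
  # normal approximation with tie correction and continuity correction
  tie_tab <- table(comb)
  tie_term <- sum(tie_tab^3 - tie_tab)
  v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0)
    return(list(U = U, p.value = 1, method = "approx",
                n = c(n1, n2), ties = has_ties, zero_variance = TRUE))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(v)
  pv <- min(1, 2 * pnorm(-abs(z)))
  list(U = U, p.value = pv, method = "approx",
       n = c(n1, n2), ties = has_ties, zero_variance = FALSE)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of average ranks (valid with ties); the
#' p-value uses the t approximation t = rho sqrt((n-2)/(1-rho^2)) with
#' n - 2 degrees of freedom, two-sided. A constant input vector has
#' undefined rho and is flagged.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list: `rho`, `p.value`, `n`, `constant_input`.
#' @export
spearman_cor <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3 || length(y) != n)
    abort("need paired samples with n >= 3", "ihcmet_param_error")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p.value = NA_real_, n = n,
                constant_input = TRUE))
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-15) {
    pv <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    pv <- 2 * pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p.value = pv, n = n, constant_input = FALSE)
}
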