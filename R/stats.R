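# Rank statistics for the single-cell comparisons.
# Hand-written on purpose with a fully specified contract (average-rank
# ties; exact enumeration for small samples) so tests can pin them against
# brute-force oracles and base R.

#' Spearman's rank correlation (average-rank ties)
#'
#' Pearson correlation of average ranks, the standard tie-aware definition
#' of Spearman's rho.
#'
#' @param x,y numeric vectors of equal length (>= 2); NA pairs dropped
#' @return rho in `[-1, 1]` (NA when either vector is constant)
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) return(NA_real_)
  sum(dx * dy) / den
}

# exact permutation distribution of U1 for pooled values z with group-1 size n
mw_exact_p <- function(z, n, u_obs) {
  N <- length(z)
  combs <- combn(N, n)
  r <- rank(z)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - n * (n + 1) / 2)
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

#' Mann-Whitney U test (two-sided)
#'
#' U is the number of (x, y) pairs with x > y, counting ties as 1/2
#' (equivalently the rank-sum form). The p value comes from exact
#' enumeration of the permutation distribution when both groups have at
#' most \code{exact_max} observations, and otherwise from the normal
#' approximation with tie correction (no continuity correction).
#'
#' @param x,y numeric samples
#' @param exact_max largest per-group size for the exact enumeration
#' @return list with \code{U} (for the first sample), \code{p.value},
#'   \code{method} (\code{"exact"} or \code{"normal"}), \code{n1},
#'   \code{n2}
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  z <- c(x, y)
  r <- rank(z)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    p <- mw_exact_p(z, n1, U)
    method <- "exact"
  } else {
    N <- n1 + n2
    ties <- table(z)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      zstat <- (U - n1 * n2 / 2) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(zstat))
    }
    method <- "normal"
  }
  list(U = U, p.value = min(1, p), method = method, n1 = n1, n2 = n2)
}
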