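# Two-sample proportion inference for family enrichment: exact two-sided
# Fisher tests (point-probability method), Newcombe-Wilson difference
# intervals, Benjamini-Hochberg and Storey q-values.

#' Exact two-sided Fisher test for a 2x2 table
#'
#' The two-sided p-value by the point-probability method: the sum of the
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (within a
#' small relative tolerance, as in common implementations).
#'
#' @param x1,n1 Successes and trials in the sample arm.
#' @param x2,n2 Successes and trials in the reference arm.
#' @return p-value in \[0, 1\] (vectorised over the four arguments).
#' @export
fisher_two_sided <- function(x1, n1, x2, n2) {
  stopifnot(all(n1 >= 1), all(n2 >= 1), all(x1 >= 0), all(x2 >= 0),
            all(x1 <= n1), all(x2 <= n2))
  args <- cbind(x1, n1, x2, n2)
  vapply(seq_len(nrow(args)), function(i) {
    x1 <- args[i, 1]; n1 <- args[i, 2]; x2 <- args[i, 3]; n2 <- args[i, 4]
    m <- x1 + x2                      # total successes
    lo <- max(0, m - n2); hi <- min(m, n1)
    support <- lo:hi
    d <- dhyper(support, m, n1 + n2 - m, n1)
    p0 <- d[support == x1]
    min(1, sum(d[d <= p0 * (1 + 1e-7)]))
  }, numeric(1))
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Successes (0 <= x <= n).
#' @param n Trials (>= 1).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Named vector `c(lower, upper)` (a 2-column matrix for
#'   vector input).
#' @export
wilson_interval <- function(x, n, alpha = 0.05) {
  stopifnot(all(x >= 0), all(x <= n), all(n >= 1))
  z <- qnorm(1 - alpha / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  l <- pmax(0, centre - half)
  u <- pmin(1, centre + half)
  if (length(x) == 1) c(lower = l, upper = u) else
    cbind(lower = l, upper = u)
}

#' Newcombe-Wilson interval for a difference of proportions
#'
#' The hybrid-score interval: with `p_i = x_i / n_i` and per-arm Wilson
#' limits `(l_i, u_i)`, the lower bound is
#' `(p1 - p2) - sqrt((p1 - l1)^2 + (u2 - p2)^2)` and the upper bound is
#' `(p1 - p2) + sqrt((u1 - p1)^2 + (p2 - l2)^2)`.
#'
#' @inheritParams fisher_two_sided
#' @param alpha Two-sided significance level (default 0.05 for 95% CIs).
#' @return Named vector `c(lower, upper)` (matrix for vector input).
#' @export
newcombe_diff_ci <- function(x1, n1, x2, n2, alpha = 0.05) {
  w1 <- wilson_interval(x1, n1, alpha)
  w2 <- wilson_interval(x2, n2, alpha)
  if (is.null(dim(w1))) w1 <- matrix(w1, ncol = 2)
  if (is.null(dim(w2))) w2 <- matrix(w2, ncol = 2)
  p1 <- x1 / n1; p2 <- x2 / n2
  d <- p1 - p2
  l <- d - sqrt((p1 - w1[, 1])^2 + (w2[, 2] - p2)^2)
  u <- d + sqrt((w1[, 2] - p1)^2 + (p2 - w2[, 1])^2)
  if (length(d) == 1) c(lower = l, upper = u) else
    cbind(lower = l, upper = u)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate control (wraps the standard adjustment).
#'
#' @param p_values Numeric vector of p-values.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Storey q-values with a single-lambda pi0 estimate
#'
#' `pi0 = #\{p > lambda\} / (m (1 - lambda))`, clipped to (0, 1\]; the
#' q-values are `pi0` times the Benjamini-Hochberg step-up values, capped
#' at 1.
#'
#' @param p_values Numeric vector of p-values.
#' @param lambda Tuning parameter in (0, 1) (default 0.5).
#' @return List with `q` (q-values in input order) and `pi0`.
#' @export
storey_q <- function(p_values, lambda = 0.5) {
  stopifnot(lambda > 0, lambda < 1,
            all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  m <- length(p_values)
  pi0 <- sum(p_values > lambda, na.rm = TRUE) / (m * (1 - lambda))
  if (pi0 <= 0) {
    warning("no p-values above lambda; pi0 clipped to 1/m")
    pi0 <- 1 / m
  }
  pi0 <- min(pi0, 1)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m / (m:1) * p_values[o]
  q <- pmin(1, cummin(q))[ro]
  list(q = q, pi0 = pi0)
}

#' Family enrichment table between a sample and the reference
#'
#' Per family: exact two-sided Fisher p, Newcombe-Wilson 95% CI of the
#' difference of proportions, BH and Storey q-values, and the p < 0.005
#' significance flag.
#'
#' @param counts data.frame with columns `family`, `x1`, `n1` (sample) and
#'   `x2`, `n2` (reference).
#' @param alpha CI level parameter (default 0.05).
#' @param sig_p Significance convention threshold (default 0.005).
#' @return data.frame with `family`, `p_value`, `ci_low`, `ci_high`,
#'   `q_bh`, `q_storey` and `significant`.
#' @export
enrichment_table <- function(counts, alpha = 0.05, sig_p = 0.005) {
  p <- fisher_two_sided(counts$x1, counts$n1, counts$x2, counts$n2)
  ci <- newcombe_diff_ci(counts$x1, counts$n1, counts$x2, counts$n2,
                         alpha)
  if (is.null(dim(ci))) ci <- matrix(ci, ncol = 2)
  st <- storey_q(p)
  data.frame(family = counts$family, p_value = p,
             ci_low = ci[, 1], ci_high = ci[, 2],
             q_bh = bh_fdr(p), q_storey = st$q,
             significant = p < sig_p, stringsAsFactors = FALSE)
}
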