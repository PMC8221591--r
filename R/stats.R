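#' Welch two-sample group test on delta CT values
#'
#' Two-sided Welch t test (unequal variances) comparing per-sample delta CT
#' values between groups — the documented approximation of the published
#' post hoc framework, since all statistics are computed on delta CT values.
#' Degenerate inputs (zero variance in both groups) are handled by an
#' exact-equality branch: `p = 1, t = 0` for equal means, `p = 0,
#' t = +/-Inf` otherwise.
#'
#' @param x,y numeric vectors (>= 2 values each), e.g. delta CT of the
#'   sleep and sleep-deprived groups.
#' @return list: `t`, `df`, `p`, `mean_diff` (`mean(y) - mean(x)`).
#' @export
groupTest <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("at least 2 values per group are required")
  }
  d <- mean(y) - mean(x)
  if (sd(x) == 0 && sd(y) == 0) {
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                df = length(x) + length(y) - 2L,
                p = if (d == 0) 1 else 0, mean_diff = d))
  }
  tt <- t.test(y, x, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = d)
}

#' Holm-Sidak step-down multiplicity adjustment
#'
#' Step-down Sidak: with the m raw p values sorted ascending, the i-th
#' adjusted value is `max over j <= i of 1 - (1 - p_(j))^(m - j + 1)`,
#' clipped at 1 and mapped back to the input order. Monotone by
#' construction; a single p value is returned unchanged.
#'
#' @param p numeric vector of raw p values in `[0, 1]`.
#' @param alpha significance level for the reject flags (default 0.05).
#' @return data.frame: `p`, `p_adj`, `reject` in input order.
#' @export
holmSidak <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p values must lie in [0, 1]")
  }
  m <- length(p)
  ord <- order(p)
  stepwise <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj_sorted <- pmin(cummax(stepwise), 1)
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  data.frame(p = p, p_adj = adj, reject = adj < alpha)
}
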