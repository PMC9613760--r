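#' Statistical power of an MR analysis with a binary outcome
#'
#' Non-centrality-based power calculation for a two-sided Wald test of a
#' causal odds ratio in Mendelian randomization, following the standard
#' summary-level formulation for binary outcomes: the odds ratio is
#' reparameterized as a risk difference
#' b01 = K (OR / (1 + K (OR - 1)) - 1) at case fraction K, its sampling
#' variance is v = (K (1 - K) - b01^2) / (N R2), and
#' power = Phi(-z_(1-alpha/2) + |b01| / sqrt(v)), where N is the outcome
#' GWAS size and R2 the fraction of exposure variance explained by the
#' instruments.
#'
#' @param n_total Outcome GWAS sample size N.
#' @param case_fraction Case fraction K in (0, 1).
#' @param odds_ratio Hypothesized causal odds ratio per exposure unit, > 0.
#' @param r_squared Variance in the exposure explained by the instruments,
#'   in (0, 1).
#' @param alpha Two-sided significance level (default 0.05).
#' @return A list of class `power_result`: `b01`, `variance_term`, `ncp`
#'   (|b01|/sqrt(v)), and `power` in \[0, 1\].
#' @examples
#' # 862 amblyopia cases among 417,030, OR 0.48, instruments explaining 5.3%
#' binary_outcome_power(417030, 862 / 417030, 0.48, 0.053)$power  # ~0.94
#' @export
binary_outcome_power <- function(n_total, case_fraction, odds_ratio,
                                 r_squared, alpha = 0.05) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  if (case_fraction <= 0 || case_fraction >= 1)
    stop("case_fraction must be in (0, 1)", call. = FALSE)
  if (odds_ratio <= 0) stop("odds_ratio must be > 0", call. = FALSE)
  if (r_squared <= 0 || r_squared >= 1)
    stop("r_squared must be in (0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  K <- case_fraction
  b01 <- K * (odds_ratio / (1 + K * (odds_ratio - 1)) - 1)
  v <- (K * (1 - K) - b01^2) / (n_total * r_squared)
  if (v <= 0)
    stop("R^2 and N imply degenerate variance", call. = FALSE)
  ncp <- abs(b01) / sqrt(v)
  power <- stats::pnorm(-stats::qnorm(1 - alpha / 2) + ncp)
  structure(list(b01 = b01, variance_term = v, ncp = ncp, power = power),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("MR power (binary outcome): %.1f%% (NCP %.2f)\n",
              100 * x$power, x$ncp))
  invisible(x)
}
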