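Z975 <- 1.959964  # qnorm(0.975) at the precision conventionally quoted

# p for a pooled estimate; se = 0 arises from degenerate perfect fits
# (zero-noise fixtures) and gets the limiting p rather than an error.
pooled_p <- function(beta, se) {
  if (se == 0) return(if (beta == 0) 1 else 0)
  ztest_p(beta, se)
}

mr_estimate <- function(method, n_snp, beta, se, level = 0.95,
                        degenerate = FALSE) {
  if (se > 0) {
    orci <- to_odds_ratio(beta, se, level)
  } else {
    orci <- c(or = exp(beta), ci_low = exp(beta), ci_high = exp(beta))
  }
  out <- data.frame(method = method, n_snp = as.integer(n_snp),
                    beta = beta, se = se, pvalue = pooled_p(beta, se),
                    or = orci[["or"]], ci_low = orci[["ci_low"]],
                    ci_high = orci[["ci_high"]],
                    stringsAsFactors = FALSE)
  attr(out, "degenerate") <- degenerate
  out
}

#' Per-SNP Wald ratios
#'
#' The per-variant causal estimate theta_j = beta_Yj / beta_Xj with
#' first-order delta-method standard error se_j = se_Yj / |beta_Xj| and
#' inverse-variance weight w_j = 1/se_j^2. Pairs with beta_x = 0 cannot form
#' a ratio and are dropped with a message.
#'
#' @param data A `harmonized_dataset` (or a data.frame with columns
#'   `variant_id`, `beta_x`, `se_x`, `beta_y`, `se_y`).
#' @return A data.frame with columns `variant_id`, `theta`, `se`, `weight`.
#' @export
wald_ratios <- function(data) {
  df <- if (inherits(data, "harmonized_dataset")) data$pairs else data
  zero <- df$beta_x == 0
  if (any(zero)) {
    message(sprintf("dropped %d pair(s) with zero exposure effect: %s",
                    sum(zero), paste(df$variant_id[zero], collapse = ", ")))
    df <- df[!zero, , drop = FALSE]
  }
  se <- df$se_y / abs(df$beta_x)
  data.frame(variant_id = df$variant_id, theta = df$beta_y / df$beta_x,
             se = se, weight = 1 / se^2, stringsAsFactors = FALSE)
}

#' Two-sided normal p-value
#'
#' p = 2 (1 - Phi(|beta/se|)); the large-sample z-test used for every pooled
#' estimate in this package.
#'
#' @param beta Estimate.
#' @param se Standard error, > 0.
#' @return The p-value.
#' @export
ztest_p <- function(beta, se) {
  if (any(se <= 0)) stop("se must be > 0", call. = FALSE)
  2 * stats::pnorm(-abs(beta / se))
}

#' Odds ratio with confidence interval from a log-odds estimate
#'
#' @param beta Log-odds estimate.
#' @param se Standard error, > 0.
#' @param level Confidence level in (0, 1); the interval is
#'   exp(beta -/+ z * se) with z the (1+level)/2 normal quantile.
#' @return Named numeric vector `or`, `ci_low`, `ci_high`.
#' @examples
#' round(to_odds_ratio(-0.731, 0.258), 2)  # 0.48 [0.29, 0.80]
#' @export
to_odds_ratio <- function(beta, se, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  if (se <= 0) stop("se must be > 0", call. = FALSE)
  z <- if (identical(level, 0.95)) Z975 else stats::qnorm((1 + level) / 2)
  c(or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se))
}

#' Inverse-variance weighted estimate
#'
#' Pools the Wald ratios as beta = sum(w_j theta_j) / sum(w_j), the weighted
#' average that is equivalent to weighted least-squares regression of outcome
#' on exposure effects through the origin. The fixed-effect standard error is
#' (sum w_j)^(-1/2). The multiplicative random-effects model rescales it by
#' sqrt(Q/(J-1)) with Q the Cochran heterogeneity statistic about the pooled
#' estimate; by default the dispersion factor is NOT floored at 1, so with
#' underdispersion (Q/(J-1) < 1) the random-effects SE is smaller than the
#' fixed-effect one. `floor_dispersion = TRUE` restores the floored variant.
#'
#' @param ratios Output of [wald_ratios()].
#' @param model `"random"` (default) or `"fixed"`.
#' @param floor_dispersion Floor sqrt(Q/(J-1)) at 1 (random model only).
#' @param level Confidence level for the odds-ratio interval.
#' @return A one-row `data.frame` (an MR estimate): `method`, `n_snp`,
#'   `beta`, `se`, `pvalue`, `or`, `ci_low`, `ci_high`. A single-ratio input
#'   returns that ratio flagged with attribute `degenerate`.
#' @export
mr_ivw <- function(ratios, model = c("random", "fixed"),
                   floor_dispersion = FALSE, level = 0.95) {
  model <- match.arg(model)
  J <- nrow(ratios)
  if (J == 0) stop("no ratios supplied", call. = FALSE)
  method <- paste0("ivw_", model)
  if (J == 1)
    return(mr_estimate(method, 1L, ratios$theta, ratios$se, level,
                       degenerate = TRUE))
  w <- ratios$weight
  beta <- sum(w * ratios$theta) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  if (model == "fixed") return(mr_estimate(method, J, beta, se_fixed, level))
  q <- cochran_q(ratios, beta, J - 1L)
  disp <- q$Q / (J - 1)
  if (floor_dispersion) disp <- max(disp, 1)
  mr_estimate(method, J, beta, se_fixed * sqrt(disp), level)
}

# Interpolated weighted median of ordered ratios: cumulative-weight midpoints
# s_j = cumsum(w')_j - w'_j/2 on normalized weights, linear interpolation of
# theta against s at s = 1/2; outside [s_1, s_J] the boundary theta is taken.
weighted_median_point <- function(theta, weight) {
  if (diff(range(weight)) == 0) weight <- rep(1, length(weight))
  ord <- order(theta)  # stable: ties keep input order
  theta <- theta[ord]; w <- weight[ord] / sum(weight)
  s <- cumsum(w) - w / 2
  if (length(unique(theta)) == 1) return(theta[1])
  stats::approx(s, theta, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Simple or weighted median estimate
#'
#' The 50% point of the cumulative-weight distribution over ordered Wald
#' ratios (equal weights for the simple median; inverse-variance weights for
#' the weighted median), computed by linear interpolation of the ordered
#' ratios against their standardized cumulative-weight midpoints. Consistent
#' when at least half the (weight of) instruments are valid. The standard
#' error is the SD of the estimate across `n_boot` parametric-bootstrap
#' replicates in which each ratio is redrawn as N(theta_j, se_j^2).
#'
#' @param ratios Output of [wald_ratios()]; at least 3 rows.
#' @param weighted Use inverse-variance weights (`TRUE`) or equal weights.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level for the odds-ratio interval.
#' @return A one-row MR-estimate data.frame (see [mr_ivw()]).
#' @export
mr_median <- function(ratios, weighted = TRUE, n_boot = 1000, seed = 1L,
                      level = 0.95) {
  J <- nrow(ratios)
  if (J < 3) stop("median estimator needs at least 3 ratios", call. = FALSE)
  w <- if (weighted) ratios$weight else rep(1, J)
  est <- weighted_median_point(ratios$theta, w)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    th <- stats::rnorm(J, ratios$theta, ratios$se)
    wb <- if (weighted) ratios$weight else rep(1, J)
    weighted_median_point(th, wb)
  }, numeric(1))
  mr_estimate(if (weighted) "weighted_median" else "simple_median",
              J, est, stats::sd(boots), level)
}

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum w_j (theta_j - reference)^2, referred to a chi-square upper tail
#' with the given degrees of freedom (J-1 about the IVW estimate; J-2 for the
#' residual Q of an Egger fit).
#'
#' @param ratios Output of [wald_ratios()].
#' @param reference Pooled estimate the deviations are taken about.
#' @param df Degrees of freedom, >= 1.
#' @return List with `Q`, `df`, `p`.
#' @export
cochran_q <- function(ratios, reference, df) {
  if (df < 1) stop("Cochran's Q requires df >= 1", call. = FALSE)
  Q <- sum(ratios$weight * (ratios$theta - reference)^2)
  list(Q = Q, df = as.integer(df), p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure effects
#' with a free intercept (weights 1/se_y^2), after orienting every pair so
#' that beta_x >= 0. The slope is a pleiotropy-robust causal estimate under
#' the InSIDE assumption; the intercept estimates the average directional
#' pleiotropic effect, and its two-sided test is the standard horizontal-
#' pleiotropy diagnostic. Standard errors follow the multiplicative-error
#' convention consistent with the unfloored random-effects IVW: coefficient
#' SEs are scaled by the residual dispersion sqrt(Q_egger/(J-2)) without
#' flooring at 1 (set `floor_dispersion = TRUE` to floor).
#'
#' @param data A `harmonized_dataset` or a data.frame with `beta_x`,
#'   `beta_y`, `se_y` (and `variant_id`); at least 3 SNPs.
#' @param floor_dispersion Floor the residual scaling at 1.
#' @param level Confidence level for the slope's odds-ratio interval.
#' @return List with `slope` (one-row MR-estimate data.frame, method
#'   `egger_slope`), `intercept`, `intercept_se`, `intercept_p`, and the
#'   residual heterogeneity `q_egger`, `df_egger`, `p_q_egger`.
#' @export
mr_egger <- function(data, floor_dispersion = FALSE, level = 0.95) {
  df <- if (inherits(data, "harmonized_dataset")) data$pairs else data
  J <- nrow(df)
  if (J < 3) stop("MR-Egger needs at least 3 SNPs", call. = FALSE)
  sgn <- ifelse(df$beta_x < 0, -1, 1)
  bx <- df$beta_x * sgn
  by <- df$beta_y * sgn
  w <- 1 / df$se_y^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  # summary(lm) SEs already carry the multiplicative residual scaling
  # sigma = sqrt(RSS_w/(J-2)); dividing by sigma recovers the fixed-error SE.
  sigma <- summary(fit)$sigma
  q_egger <- sum(w * stats::residuals(fit)^2)
  scale <- if (floor_dispersion && sigma < 1) 1 / sigma else 1
  slope_se <- cf["bx", "Std. Error"] * scale
  int_se <- cf["(Intercept)", "Std. Error"] * scale
  list(slope = mr_estimate("egger_slope", J, cf["bx", "Estimate"], slope_se,
                           level),
       intercept = cf["(Intercept)", "Estimate"],
       intercept_se = int_se,
       intercept_p = pooled_p(cf["(Intercept)", "Estimate"], int_se),
       q_egger = q_egger, df_egger = J - 2L,
       p_q_egger = stats::pchisq(q_egger, J - 2L, lower.tail = FALSE))
}

#' Run the full estimator battery with diagnostics
#'
#' Computes the four causal estimators (random- and fixed-effect IVW, simple
#' and weighted median) plus the MR-Egger slope, together with the Egger
#' intercept pleiotropy test and Cochran's Q heterogeneity statistics about
#' the IVW estimate (df = J-1) and the Egger fit (df = J-2).
#'
#' @param data A `harmonized_dataset`.
#' @param n_boot Bootstrap replicates for the median SEs.
#' @param seed Integer seed for the bootstrap.
#' @param floor_dispersion Floor multiplicative dispersion factors at 1.
#' @param level Confidence level.
#' @return List with `estimates` (data.frame, five rows) and `diagnostics`
#'   (list: `egger_intercept`, `egger_intercept_se`, `egger_intercept_p`,
#'   `q_ivw`, `df_ivw`, `p_q_ivw`, `q_egger`, `df_egger`, `p_q_egger`).
#' @export
run_all_methods <- function(data, n_boot = 1000, seed = 1L,
                            floor_dispersion = FALSE, level = 0.95) {
  ratios <- wald_ratios(data)
  if (nrow(ratios) == 0) stop("no usable instrument ratios", call. = FALSE)
  ivw_r <- mr_ivw(ratios, "random", floor_dispersion, level)
  ivw_f <- mr_ivw(ratios, "fixed", level = level)
  med_s <- mr_median(ratios, weighted = FALSE, n_boot, seed, level)
  med_w <- mr_median(ratios, weighted = TRUE, n_boot, seed, level)
  egg <- mr_egger(data, floor_dispersion, level)
  q <- cochran_q(ratios, ivw_f$beta, nrow(ratios) - 1L)
  estimates <- rbind(ivw_r, ivw_f, med_s, med_w, egg$slope)
  rownames(estimates) <- NULL
  list(estimates = estimates,
       diagnostics = list(egger_intercept = egg$intercept,
                          egger_intercept_se = egg$intercept_se,
                          egger_intercept_p = egg$intercept_p,
                          q_ivw = q$Q, df_ivw = q$df, p_q_ivw = q$p,
                          q_egger = egg$q_egger, df_egger = egg$df_egger,
                          p_q_egger = egg$p_q_egger))
}
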