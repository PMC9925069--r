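# Shared constructor for the one-row estimate tibble used by every method.
mr_estimate_row <- function(method, beta, se, n_snps, Q = NA_real_,
                            Q_df = NA_integer_, pvalue = NULL, df = NULL) {
  if (is.null(pvalue)) {
    pvalue <- if (is.null(df)) {
      2 * pnorm(-abs(beta / se))
    } else {
      2 * pt(-abs(beta / se), df = df)
    }
    if (se == 0) pvalue <- if (beta == 0) 1 else 0
  }
  tibble(
    method = method, beta = beta, se = se,
    ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
    pvalue = pvalue, n_snps = as.integer(n_snps),
    Q = Q, Q_df = as.integer(Q_df)
  )
}

#' Wald ratio causal estimate from a single variant
#'
#' Per-variant causal estimate `Gamma / gamma` with the first-order standard
#' error `s_Gamma / |gamma|` (exposure-side uncertainty ignored, as in
#' inverse-variance weighting with first-order weights). The 95% CI and
#' two-sided normal p-value are filled in.
#'
#' @param gamma,s_gamma Variant-exposure association and SE.
#' @param Gamma,s_Gamma Variant-outcome association and SE.
#' @return One-row estimate tibble (`method = "wald_ratio"`).
#' @examples
#' wald_ratio(gamma = 0.1, s_gamma = 0.01, Gamma = -0.05, s_Gamma = 0.02)
#' @export
wald_ratio <- function(gamma, s_gamma, Gamma, s_Gamma) {
  if (gamma == 0) abort("Wald ratio undefined: gamma = 0")
  stopifnot(s_Gamma > 0)
  mr_estimate_row("wald_ratio", beta = Gamma / gamma, se = s_Gamma / abs(gamma),
                  n_snps = 1L)
}

ratio_weights <- function(set) {
  list(ratio = set$Gamma / set$gamma,
       w = set$gamma^2 / set$s_Gamma^2)
}

#' Inverse-variance-weighted causal estimate
#'
#' Pools per-variant Wald ratios with first-order weights
#' `w_j = gamma_j^2 / s_Gamma_j^2`. Under the fixed-effects model the SE is
#' `(sum w_j)^(-1/2)`; under the multiplicative random-effects model it is
#' scaled by `max(1, sqrt(Q / (n - 1)))`, leaving the point estimate
#' unchanged. Cochran's Q (`sum w_j (ratio_j - beta)^2`, df `n - 1`) is
#' reported for `n >= 2`. A single-variant set returns the Wald ratio
#' exactly; a single variant under the multiplicative model falls back to
#' fixed with a message.
#'
#' @param set A `harmonised_set` (or tibble with `gamma`, `s_gamma`, `Gamma`,
#'   `s_Gamma`).
#' @param effects_model `"fixed"` (default) or `"multiplicative"`.
#' @return One-row estimate tibble.
#' @export
mr_ivw <- function(set, effects_model = c("fixed", "multiplicative")) {
  effects_model <- match.arg(effects_model)
  n <- nrow(set)
  if (n == 0) abort("mr_ivw: empty instrument set")
  if (any(set$gamma == 0)) abort("mr_ivw: gamma = 0 for some instrument")
  if (n == 1) {
    if (effects_model == "multiplicative") {
      inform("mr_ivw: single variant, multiplicative model falls back to fixed")
    }
    est <- wald_ratio(set$gamma, set$s_gamma, set$Gamma, set$s_Gamma)
    est$method <- "ivw_fixed"
    return(est)
  }
  rw <- ratio_weights(set)
  beta <- sum(rw$w * rw$ratio) / sum(rw$w)
  se <- sqrt(1 / sum(rw$w))
  Q <- sum(rw$w * (rw$ratio - beta)^2)
  method <- "ivw_fixed"
  if (effects_model == "multiplicative") {
    se <- se * max(1, sqrt(Q / (n - 1)))
    method <- "ivw_mre"
  }
  mr_estimate_row(method, beta, se, n_snps = n, Q = Q, Q_df = n - 1L)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome associations on the exposure
#' associations with a free intercept and weights `1 / s_Gamma^2`, after
#' re-orienting every instrument so `gamma_j > 0` (the conventional Egger
#' orientation). The slope is the pleiotropy-adjusted causal estimate; the
#' intercept estimates the average directional pleiotropic effect per variant
#' and its test is the directional-pleiotropy test. Both coefficient SEs are
#' inflated by `max(1, residual scale)` (under-dispersion is not allowed to
#' shrink them) and p-values use the t distribution with `n - 2` df.
#'
#' @inheritParams mr_ivw
#' @return Two-row estimate tibble: `egger_slope` then `egger_intercept`.
#' @export
mr_egger <- function(set) {
  n <- nrow(set)
  if (n < 3) abort("mr_egger requires at least 3 instruments")
  flip <- sign(set$gamma)
  x <- set$gamma * flip
  y <- set$Gamma * flip
  w <- 1 / set$s_Gamma^2
  fit <- lm(y ~ x, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  infl <- max(1, sigma) / sigma
  co <- sm$coefficients
  slope <- mr_estimate_row("egger_slope", co["x", 1], co["x", 2] * infl,
                           n_snps = n, df = n - 2)
  inter <- mr_estimate_row("egger_intercept", co["(Intercept)", 1],
                           co["(Intercept)", 2] * infl, n_snps = n, df = n - 2)
  bind_rows(slope, inter)
}

#' Weighted-median causal estimate
#'
#' Orders the per-variant ratio estimates and takes the value at the 50th
#' weight percentile, interpolating linearly between the cumulative weight
#' midpoints. Consistent when less than half the total weight comes from
#' invalid instruments. The SE comes from a parametric bootstrap: ratio
#' estimates are resampled from `N(ratio_j, se_j^2)` and the weighted median
#' recomputed `n_boot` times under a fixed seed.
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap (mandatory, for
#'   reproducibility).
#' @return One-row estimate tibble (`method = "weighted_median"`).
#' @export
weighted_median <- function(set, n_boot = 1000, seed) {
  n <- nrow(set)
  if (n < 3) abort("weighted_median requires at least 3 instruments")
  if (missing(seed) || is.null(seed)) abort("weighted_median requires a seed")
  rw <- ratio_weights(set)
  est <- weighted_median_point(rw$ratio, rw$w)
  ratio_se <- set$s_Gamma / abs(set$gamma)
  boot <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      weighted_median_point(rnorm(n, rw$ratio, ratio_se), rw$w)
    }, numeric(1))
  })
  mr_estimate_row("weighted_median", est, stats::sd(boot), n_snps = n)
}

# Interpolated weighted median of x with weights w (normalised internally).
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(x[1])
  if (cum[length(cum)] <= 0.5) return(x[length(x)])
  stats::approx(cum, x, xout = 0.5, ties = "ordered")$y
}

#' Unweighted (per-allele) inverse-variance pooling of outcome associations
#'
#' Pools the variant-outcome betas alone with weights `1 / s_Gamma^2`,
#' ignoring the exposure weighting entirely. The result is on the per-allele
#' scale, not per exposure unit; it is the alternative-weighting sensitivity
#' analysis for instruments whose exposure weights are in doubt.
#'
#' @inheritParams mr_ivw
#' @return One-row estimate tibble (`method = "unweighted_ivw"`).
#' @export
unweighted_ivw <- function(set) {
  n <- nrow(set)
  if (n == 0) abort("unweighted_ivw: empty instrument set")
  w <- 1 / set$s_Gamma^2
  beta <- sum(w * set$Gamma) / sum(w)
  se <- sqrt(1 / sum(w))
  Q <- if (n >= 2) sum(w * (set$Gamma - beta)^2) else NA_real_
  mr_estimate_row("unweighted_ivw", beta, se, n_snps = n, Q = Q,
                  Q_df = if (n >= 2) n - 1L else NA_integer_)
}

#' Fit the standard suite of MR estimators
#'
#' Convenience wrapper running IVW (the configured primary effects model),
#' MR-Egger and the bootstrap weighted median on one harmonised set, returning
#' an `mr_fit` object with [tidy()], [glance()] and [autoplot()] methods.
#' Methods whose preconditions fail on a small set (Egger and weighted median
#' need 3 variants) are skipped silently.
#'
#' @inheritParams mr_ivw
#' @param seed Seed for the weighted-median bootstrap.
#' @param n_boot Bootstrap replicates for the weighted median.
#' @return An object of class `mr_fit`.
#' @export
fit_mr <- function(set, effects_model = c("fixed", "multiplicative"),
                   seed = 1L, n_boot = 1000) {
  effects_model <- match.arg(effects_model)
  est <- list(mr_ivw(set, effects_model))
  if (nrow(set) >= 3) {
    est <- c(est, list(mr_egger(set), weighted_median(set, n_boot, seed)))
  }
  structure(
    list(estimates = bind_rows(est), data = as_tibble(set),
         effects_model = effects_model),
    class = "mr_fit"
  )
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("Two-sample MR fit:", nrow(x$data), "instruments,",
      x$effects_model, "effects IVW\n")
  print(x$estimates %>% mutate(or = exp(.data$beta)))
  invisible(x)
}
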