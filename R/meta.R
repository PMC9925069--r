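#' Convert an odds ratio with 95% CI to log scale
#'
#' `beta = ln(OR)`, `se = (ln(ci_high) - ln(ci_low)) / (2 * 1.959964)` — the
#' standard back-calculation used to ingest printed per-cohort OR tables into
#' a meta-analysis. Degenerate intervals (zero width, hence zero SE) are
#' rejected.
#'
#' @param or_point,ci_low,ci_high Odds ratio and its 95% CI bounds; all must
#'   be positive with `ci_low <= or_point <= ci_high` (vectorised).
#' @return Tibble with columns `beta` and `se`.
#' @examples
#' or_ci_to_log(0.80, 0.66, 0.96) # beta -0.2231, se 0.0956
#' @export
or_ci_to_log <- function(or_point, ci_low, ci_high) {
  if (any(c(or_point, ci_low, ci_high) <= 0)) {
    abort("odds ratios and CI bounds must be positive")
  }
  if (any(ci_low > or_point | or_point > ci_high)) {
    abort("require ci_low <= or <= ci_high")
  }
  se <- (log(ci_high) - log(ci_low)) / (2 * Z95)
  if (any(se == 0)) abort("degenerate interval: zero-width CI gives zero SE")
  tibble(beta = log(or_point), se = se)
}

#' Read a per-cohort odds-ratio table
#'
#' TSV with columns `cohort`, `outcome`, `or`, `ci_low`, `ci_high` — the
#' layout in which published per-cohort ORs are retyped for pooling.
#'
#' @param path Path to the TSV.
#' @return Tibble of cohort effects.
#' @export
read_cohort_effects <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cohort", "outcome", "or", "ci_low", "ci_high")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("cohort-effects table missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  x
}

#' Fixed-effects meta-analysis of per-cohort odds ratios
#'
#' Converts each cohort's OR and 95% CI to the log scale, pools the log-ORs
#' by inverse-variance weighting under a common-effect model, and reports the
#' pooled OR with Wald 95% CI and Cochran's Q. The pooling itself is
#' delegated to [metafor::rma()] with `method = "FE"`.
#'
#' @param effects Tibble with columns `or`, `ci_low`, `ci_high` and
#'   (optionally) `cohort`, `outcome`; at least 2 rows.
#' @return An object of class `mr_meta`: list with `pooled_or`, `ci_low`,
#'   `ci_high`, `beta`, `se`, `pvalue`, `Q`, `Q_df`, `weights` (per-cohort,
#'   sum 1) and the per-cohort log-scale input `cohorts`.
#' @examples
#' eff <- tibble::tibble(
#'   cohort = c("UK Biobank", "FinnGen"),
#'   outcome = c("sepsis", "streptococcal sepsis"),
#'   or = c(0.80, 0.79), ci_low = c(0.66, 0.48), ci_high = c(0.96, 1.31))
#' meta_fixed(eff) # pooled OR 0.80 (0.67-0.95)
#' @export
meta_fixed <- function(effects) {
  if (nrow(effects) < 2) abort("meta_fixed requires at least 2 cohorts")
  logs <- or_ci_to_log(effects$or, effects$ci_low, effects$ci_high)
  fit <- metafor::rma(yi = logs$beta, sei = logs$se, method = "FE")
  w <- (1 / logs$se^2) / sum(1 / logs$se^2)
  cohorts <- bind_cols(
    effects[, intersect(c("cohort", "outcome"), names(effects)), drop = FALSE],
    logs, tibble(weight = w)
  )
  structure(
    list(
      pooled_or = exp(as.numeric(fit$b)),
      ci_low = exp(fit$ci.lb), ci_high = exp(fit$ci.ub),
      beta = as.numeric(fit$b), se = fit$se, pvalue = fit$pval,
      Q = fit$QE, Q_df = nrow(effects) - 1L,
      weights = w, cohorts = cohorts
    ),
    class = "mr_meta"
  )
}

#' @export
print.mr_meta <- function(x, ...) {
  cat(sprintf("Fixed-effects meta-analysis of %d cohorts\n", nrow(x$cohorts)))
  cat(sprintf("Pooled OR %.2f (95%% CI %.2f-%.2f), p = %.3g, Q = %.2f on %d df\n",
              x$pooled_or, x$ci_low, x$ci_high, x$pvalue, x$Q, x$Q_df))
  invisible(x)
}
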