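#' Radial outlier scan of an instrument set
#'
#' Decomposes Cochran's Q from the first-order IVW fit into per-variant
#' contributions `q_j = w_j (ratio_j - beta_ivw)^2`, tests each against the
#' chi-square distribution with 1 df, and flags outliers at `alpha`
#' (Bonferroni-adjusted over the instrument count by default). Because the
#' same first-order weights are used as in the main IVW, the contributions
#' sum to Cochran's Q exactly. When any variant is flagged, the IVW is
#' recomputed once on the retained set (no iteration).
#'
#' @inheritParams mr_ivw
#' @param alpha Significance level for outlier flagging (default 0.05;
#'   `alpha = 0` flags nothing).
#' @param correction `"bonferroni"` (default: threshold `alpha / n_snps`) or
#'   `"none"`.
#' @return An object of class `mr_radial`: list with `per_snp` (tibble of
#'   `variant_id`, `q_contribution`, `q_pvalue`, `outlier`), `beta_all`,
#'   `beta_outliers_removed` (NA when nothing was flagged), `fit_all`,
#'   `fit_outliers_removed`, `alpha`, `correction`.
#' @export
radial_scan <- function(set, alpha = 0.05,
                        correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  n <- nrow(set)
  if (n < 3) abort("radial_scan requires at least 3 instruments")
  fit <- mr_ivw(set, "fixed")
  rw <- ratio_weights(set)
  q_j <- rw$w * (rw$ratio - fit$beta)^2
  p_j <- pchisq(q_j, df = 1, lower.tail = FALSE)
  thr <- if (correction == "bonferroni") alpha / n else alpha
  outlier <- p_j < thr
  per_snp <- tibble(variant_id = set$variant_id, q_contribution = q_j,
                    q_pvalue = p_j, outlier = outlier)
  fit2 <- NULL
  beta2 <- NA_real_
  if (any(outlier) && sum(!outlier) >= 1) {
    fit2 <- mr_ivw(set[!outlier, , drop = FALSE], "fixed")
    beta2 <- fit2$beta
  }
  structure(
    list(per_snp = per_snp, beta_all = fit$beta,
         beta_outliers_removed = beta2, fit_all = fit,
         fit_outliers_removed = fit2, alpha = alpha, correction = correction),
    class = "mr_radial"
  )
}

#' @export
print.mr_radial <- function(x, ...) {
  cat(sprintf("Radial scan: %d/%d instruments flagged (%s alpha = %g)\n",
              sum(x$per_snp$outlier), nrow(x$per_snp), x$correction, x$alpha))
  cat(sprintf("IVW all: %.4f; outliers removed: %s\n", x$beta_all,
              ifelse(is.na(x$beta_outliers_removed), "-",
                     sprintf("%.4f", x$beta_outliers_removed))))
  invisible(x)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate with each instrument removed in turn, under
#' the same effects model as the main analysis.
#'
#' @inheritParams mr_ivw
#' @return Tibble of class `mr_loo`: one row per left-out variant with
#'   `left_out`, `beta`, `se`, `ci_low`, `ci_high`, `pvalue`, `n_snps`.
#' @export
leave_one_out <- function(set, effects_model = c("fixed", "multiplicative")) {
  effects_model <- match.arg(effects_model)
  n <- nrow(set)
  if (n < 2) abort("leave_one_out requires at least 2 instruments")
  rows <- purrr::map(seq_len(n), function(i) {
    est <- mr_ivw(set[-i, , drop = FALSE], effects_model)
    tibble(left_out = set$variant_id[i], beta = est$beta, se = est$se,
           ci_low = est$ci_low, ci_high = est$ci_high, pvalue = est$pvalue,
           n_snps = est$n_snps)
  })
  out <- bind_rows(rows)
  class(out) <- c("mr_loo", class(out))
  out
}

#' Per-variant Wald ratios
#'
#' One Wald-ratio estimate per instrument; the single-instrument route of the
#' pipeline (e.g. the rs2228145-only analysis) is this function on a set of
#' size one.
#'
#' @inheritParams mr_ivw
#' @return Tibble: one row per variant with `variant_id` and the estimate
#'   columns.
#' @export
single_snp <- function(set) {
  rows <- purrr::map(seq_len(nrow(set)), function(i) {
    bind_cols(tibble(variant_id = set$variant_id[i]),
              wald_ratio(set$gamma[i], set$s_gamma[i],
                         set$Gamma[i], set$s_Gamma[i]))
  })
  if (length(rows) == 0) {
    return(tibble(variant_id = character(0)))
  }
  bind_rows(rows)
}

#' Re-run instrument selection and estimation under a scenario override
#'
#' Re-executes cis-window restriction, LD pruning, harmonisation and
#' estimation with one or more configuration keys overridden — the mechanism
#' behind restricted-window (10 kb), alternative-weighting (CHARGE-only
#' betas), unweighted and fixed-subset sensitivity analyses. The base state
#' is never modified.
#'
#' @param state List describing the base analysis: `exposure` (summary-stats
#'   tibble), `outcome` (summary-stats tibble), `region` ([gene_region()]),
#'   `ld` (correlation matrix or NULL to skip pruning), `window_bp`,
#'   `r2_threshold`, `effects_model`, `orientation`
#'   (`"per_unit_exposure_decrease"` applies [orient_to_blockade()]), `seed`.
#' @param override Named list of scenario overrides; recognised keys:
#'   `window_bp`, `weight_source` (replacement exposure panel),
#'   `unweighted` (logical: route to [unweighted_ivw()]),
#'   `instrument_subset` (character vector of variant IDs), `r2_threshold`.
#' @param scenario Label attached to the returned rows.
#' @return Tibble of tagged estimates (column `scenario` first); on a
#'   scenario yielding zero instruments, a one-row tibble with
#'   `failed = TRUE` and the reason, the run never aborts.
#' @export
rerun_with_config <- function(state, override = list(), scenario = "scenario") {
  unknown <- setdiff(names(override),
                     c("window_bp", "weight_source", "unweighted",
                       "instrument_subset", "r2_threshold"))
  if (length(unknown) > 0) {
    abort(paste0("unknown override key(s): ", paste(unknown, collapse = ", ")))
  }
  st <- utils::modifyList(state, override[intersect(names(override),
                                                    c("window_bp", "r2_threshold"))])
  exposure <- override$weight_source %||% st$exposure
  sel <- select_cis_window(exposure, st$region, st$window_bp %||% 3e5)
  if (!is.null(override$instrument_subset)) {
    sel <- sel %>% filter(.data$variant_id %in% override$instrument_subset)
  }
  if (!is.null(st$ld) && nrow(sel) > 0) {
    sel <- ld_prune(sel, st$ld, st$r2_threshold %||% 0.1)
  }
  if (nrow(sel) == 0) {
    return(tibble(scenario = scenario, failed = TRUE,
                  reason = "no instruments after selection"))
  }
  harm <- harmonise(sel, st$outcome)
  if ((st$orientation %||% "per_unit_exposure_decrease") ==
      "per_unit_exposure_decrease") {
    harm <- orient_to_blockade(harm)
  }
  if (nrow(harm) == 0) {
    return(tibble(scenario = scenario, failed = TRUE,
                  reason = "no instruments after harmonisation"))
  }
  est <- if (isTRUE(override$unweighted)) {
    unweighted_ivw(harm)
  } else if (nrow(harm) == 1) {
    single_snp(harm) %>% select(-"variant_id")
  } else {
    mr_ivw(harm, st$effects_model %||% "fixed")
  }
  bind_cols(tibble(scenario = scenario, failed = FALSE), est)
}
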