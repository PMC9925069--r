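#' Tidy an MR fit
#'
#' @param x An `mr_fit` from [fit_mr()].
#' @param exponentiate Also report the estimates as odds ratios.
#' @param ... Unused.
#' @return One row per method with estimate, SE, CI, p-value.
#' @method tidy mr_fit
#' @export
tidy.mr_fit <- function(x, exponentiate = TRUE, ...) {
  out <- x$estimates
  if (exponentiate) {
    out <- out %>% mutate(or = exp(.data$beta), or_ci_low = exp(.data$ci_low),
                          or_ci_high = exp(.data$ci_high))
  }
  out
}

#' @rdname tidy.mr_fit
#' @method glance mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  ivw <- x$estimates %>% filter(.data$method %in% c("ivw_fixed", "ivw_mre"))
  tibble(
    n_snps = ivw$n_snps[1], effects_model = x$effects_model,
    Q = ivw$Q[1], Q_df = ivw$Q_df[1],
    Q_pvalue = pchisq(ivw$Q[1], ivw$Q_df[1], lower.tail = FALSE)
  )
}

#' Tidy a radial outlier scan
#'
#' @param x An `mr_radial` from [radial_scan()].
#' @param ... Unused.
#' @method tidy mr_radial
#' @export
tidy.mr_radial <- function(x, ...) x$per_snp

#' @rdname tidy.mr_radial
#' @method glance mr_radial
#' @export
glance.mr_radial <- function(x, ...) {
  tibble(
    beta_all = x$beta_all, beta_outliers_removed = x$beta_outliers_removed,
    n_snps = nrow(x$per_snp), n_outliers = sum(x$per_snp$outlier),
    Q = sum(x$per_snp$q_contribution), alpha = x$alpha,
    correction = x$correction
  )
}

#' Tidy a fixed-effects meta-analysis
#'
#' @param x An `mr_meta` from [meta_fixed()].
#' @param ... Unused.
#' @return Per-cohort log-scale effects and pooling weights.
#' @method tidy mr_meta
#' @export
tidy.mr_meta <- function(x, ...) x$cohorts

#' @rdname tidy.mr_meta
#' @method glance mr_meta
#' @export
glance.mr_meta <- function(x, ...) {
  tibble(pooled_or = x$pooled_or, ci_low = x$ci_low, ci_high = x$ci_high,
         beta = x$beta, se = x$se, pvalue = x$pvalue, Q = x$Q, Q_df = x$Q_df)
}

#' Tidy a directional mixture fit
#'
#' @param x A `dir_mixture` from [fit_directional_mixture()].
#' @param ... Unused.
#' @return One row per variant: hard label, top-cluster probability, noise
#'   probability, then one `p_<k>` column per cluster.
#' @method tidy dir_mixture
#' @export
tidy.dir_mixture <- function(x, ...) {
  probs <- as_tibble(x$probabilities, .name_repair = ~ paste0("p_", .x))
  K_live <- ncol(x$probabilities) - 1L
  top <- if (K_live > 0) {
    apply(x$probabilities[, seq_len(K_live), drop = FALSE], 1, max)
  } else {
    rep(0, nrow(x$probabilities))
  }
  bind_cols(
    tibble(variant_id = names(x$labels), label = unname(x$labels),
           top_cluster_prob = unname(top),
           noise_prob = unname(x$probabilities[, K_live + 1])),
    probs
  )
}

#' @rdname tidy.dir_mixture
#' @method glance dir_mixture
#' @export
glance.dir_mixture <- function(x, ...) {
  tibble(K = x$K, K_effective = x$K_effective, loglik = x$loglik,
         n_iter = length(x$loglik_trace), converged = x$converged,
         n_noise = sum(x$labels == "noise"))
}
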