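#' Scatter plot of an MR fit
#'
#' Variant-outcome against variant-exposure associations with the IVW line
#' through the origin and, when fitted, the MR-Egger line with its intercept.
#'
#' @param object An `mr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_fit
#' @export
autoplot.mr_fit <- function(object, ...) {
  d <- object$data %>%
    mutate(g = abs(.data$gamma), G = .data$Gamma * sign(.data$gamma))
  est <- object$estimates
  ivw <- est %>% filter(.data$method %in% c("ivw_fixed", "ivw_mre"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$g, y = .data$G)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$G - Z95 * .data$s_Gamma,
                                        ymax = .data$G + Z95 * .data$s_Gamma),
                           width = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = ivw$beta[1],
                         colour = "#2166AC") +
    ggplot2::labs(x = "SNP effect on exposure (|gamma|)",
                  y = "SNP effect on outcome (log-odds)",
                  title = "Two-sample MR: instrument effects",
                  subtitle = sprintf("IVW slope %.3f (OR %.2f per exposure unit)",
                                     ivw$beta[1], exp(ivw$beta[1])))
  egger <- est %>% filter(.data$method == "egger_slope")
  if (nrow(egger) == 1) {
    inter <- est %>% filter(.data$method == "egger_intercept")
    p <- p + ggplot2::geom_abline(intercept = inter$beta, slope = egger$beta,
                                  colour = "#B2182B", linetype = "dashed")
  }
  p + ggplot2::theme_minimal()
}

#' Radial plot of per-variant Q contributions
#'
#' @param object An `mr_radial`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_radial
#' @export
autoplot.mr_radial <- function(object, ...) {
  d <- object$per_snp
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$variant_id,
                                                     .data$q_contribution),
                                  y = .data$q_contribution,
                                  fill = .data$outlier)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "#B2182B")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Contribution to Cochran's Q",
                  title = "Radial outlier scan") +
    ggplot2::theme_minimal()
}

#' Forest plot of leave-one-out estimates
#'
#' @param object An `mr_loo` from [leave_one_out()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_loo
#' @export
autoplot.mr_loo <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$beta, y = .data$left_out)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "IVW log-odds with variant removed", y = "Left-out variant",
                  title = "Leave-one-out analysis") +
    ggplot2::theme_minimal()
}

#' Forest plot of a meta-analysis
#'
#' @param object An `mr_meta` from [meta_fixed()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_meta
#' @export
autoplot.mr_meta <- function(object, ...) {
  d <- object$cohorts %>%
    mutate(label = if ("cohort" %in% names(object$cohorts)) {
      paste(.data$cohort, .data$outcome %||% "", sep = " ")
    } else {
      paste0("cohort ", row_number())
    })
  pooled <- tibble(label = "Pooled (fixed)", beta = object$beta,
                   se = object$se, weight = NA_real_)
  d <- bind_rows(d %>% select("label", "beta", "se", "weight"), pooled)
  ggplot2::ggplot(d, ggplot2::aes(x = exp(.data$beta),
                                  y = factor(.data$label,
                                             levels = rev(d$label)))) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = exp(.data$beta - Z95 * .data$se),
                                         xmax = exp(.data$beta + Z95 * .data$se)),
                            height = 0.15) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight), shape = 15,
                        show.legend = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (log scale)", y = NULL,
                  title = "Fixed-effects meta-analysis") +
    ggplot2::theme_minimal()
}

#' Membership-probability heat map of a directional mixture
#'
#' @param object A `dir_mixture`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dir_mixture
#' @export
autoplot.dir_mixture <- function(object, ...) {
  d <- tidy(object) %>%
    tidyr::pivot_longer(dplyr::starts_with("p_"), names_to = "component",
                        values_to = "probability")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$variant_id,
                                  fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Mixture component", y = NULL,
                  title = "Directional clustering membership") +
    ggplot2::theme_minimal()
}

#' Forest plot across outcomes
#'
#' Plots the primary IVW odds ratios of a results bundle, one row per
#' (cohort, outcome).
#'
#' @param bundle A `results_bundle` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_forest <- function(bundle) {
  d <- bundle$primary %>%
    filter(.data$method %in% c("ivw_fixed", "ivw_mre", "wald_ratio")) %>%
    mutate(label = paste(.data$cohort, .data$outcome, sep = ": "))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$or_ci_low,
                                         xmax = .data$or_ci_high),
                            height = 0.15) +
    ggplot2::geom_point(shape = 15) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "OR per unit exposure decrease (log scale)", y = NULL,
                  title = "Primary IVW estimates") +
    ggplot2::theme_minimal()
}
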