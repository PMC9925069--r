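CONFIG_KEYS <- c("exposure", "outcomes", "region", "window_bp", "r2_threshold",
                 "ld", "effects_model", "orientation", "palindrome_policy",
                 "freq_window", "seed", "n_boot", "sensitivity", "clustering",
                 "meta", "output_dir")

#' Validate an analysis configuration file
#'
#' Reads a YAML configuration describing a full run — exposure panel, outcome
#' panels keyed by (cohort, outcome), gene region, window and pruning
#' thresholds, LD matrix paths, effects model, orientation, sensitivity
#' scenarios, clustering block, and meta-analysis groupings — and checks
#' every invariant, reporting all violations in a single aggregated error.
#' Unknown top-level keys are rejected.
#'
#' @param path Path to the YAML file. Relative paths inside the file are
#'   resolved against the file's directory.
#' @return The validated configuration as a list of class `mr_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown) > 0) {
    note(paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) normalizePath(p) else file.path(base, p)
  }
  if (is.null(cfg$exposure$path)) {
    note("exposure.path is required")
  } else {
    cfg$exposure$path <- resolve(cfg$exposure$path)
    if (!file.exists(cfg$exposure$path)) {
      note(paste0("exposure panel not found: ", cfg$exposure$path))
    }
  }
  if (length(cfg$outcomes) == 0) note("at least one outcome panel is required")
  for (i in seq_along(cfg$outcomes)) {
    oc <- cfg$outcomes[[i]]
    if (is.null(oc$cohort) || is.null(oc$outcome) || is.null(oc$path)) {
      note(paste0("outcomes[", i, "] needs cohort, outcome and path"))
      next
    }
    cfg$outcomes[[i]]$path <- resolve(oc$path)
    if (!file.exists(cfg$outcomes[[i]]$path)) {
      note(paste0("outcome panel not found: ", cfg$outcomes[[i]]$path))
    }
  }
  if (is.null(cfg$region)) {
    note("region block (name, chrom, start, end) is required")
  } else if (any(!c("name", "chrom", "start", "end") %in% names(cfg$region))) {
    note("region block needs name, chrom, start, end")
  }
  if (!is.null(cfg$ld)) {
    cfg$ld$matrix <- resolve(cfg$ld$matrix)
    cfg$ld$ids <- resolve(cfg$ld$ids)
    if (!file.exists(cfg$ld$matrix %||% "")) note("ld.matrix not found")
    if (!file.exists(cfg$ld$ids %||% "")) note("ld.ids not found")
  }
  cfg$window_bp <- cfg$window_bp %||% 3e5
  cfg$r2_threshold <- cfg$r2_threshold %||% 0.1
  cfg$effects_model <- cfg$effects_model %||% "fixed"
  cfg$orientation <- cfg$orientation %||% "per_unit_exposure_decrease"
  cfg$palindrome_policy <- cfg$palindrome_policy %||% "infer_by_freq"
  cfg$freq_window <- cfg$freq_window %||% 0.08
  cfg$n_boot <- cfg$n_boot %||% 1000
  if (!cfg$effects_model %in% c("fixed", "multiplicative")) {
    note("effects_model must be 'fixed' or 'multiplicative'")
  }
  if (!cfg$orientation %in% c("per_unit_exposure_decrease",
                              "per_unit_exposure_increase")) {
    note("orientation must be per_unit_exposure_{decrease,increase}")
  }
  if (is.null(cfg$seed)) {
    note("seed is required (weighted-median bootstrap and clustering restarts)")
  }
  if (!is.null(cfg$clustering) && isTRUE(cfg$clustering$enabled) &&
      is.null(cfg$clustering$seed) && is.null(cfg$seed)) {
    note("clustering requires a seed")
  }
  if (!is.null(cfg$meta)) {
    if (is.null(cfg$meta$table)) {
      note("meta block requires 'table' (per-cohort OR TSV)")
    } else {
      cfg$meta$table <- resolve(cfg$meta$table)
      if (!file.exists(cfg$meta$table)) {
        note(paste0("meta table not found: ", cfg$meta$table))
      }
    }
    for (g in cfg$meta$groupings) {
      if (length(g$members) < 2) {
        note(paste0("meta grouping '", g$name %||% "?",
                    "' must name >= 2 cohort outcomes"))
      }
    }
  }
  if (length(problems) > 0) {
    abort(paste0("invalid configuration (", length(problems), " problem(s)):\n",
                 paste0("  - ", problems, collapse = "\n")),
          class = "cismr_config_error")
  }
  structure(cfg, class = "mr_config")
}

#' Run the full configured analysis
#'
#' Executes, per outcome panel: cis-window selection, LD pruning (when an LD
#' matrix is configured), harmonisation, orientation to the blockade scale,
#' the primary estimator suite (IVW, MR-Egger, weighted median), radial
#' outlier scan, leave-one-out, per-variant Wald ratios, and any configured
#' sensitivity scenarios; then cross-trait clustering (when enabled) and
#' fixed-effects meta-analysis of the configured cohort-OR groupings. A
#' failing outcome is logged and skipped, never aborting the rest. All
#' stochastic steps are driven by the configured seed, so a rerun with the
#' same configuration is byte-identical.
#'
#' @param cfg An `mr_config` from [validate_config()], or a path to a YAML
#'   file.
#' @return A `results_bundle`: list of tibbles `primary`, `sensitivity`,
#'   `single_snp`, `loo`, `radial`, `cluster_assignments`,
#'   `cluster_estimates`, `meta`, and `log` (per-stage provenance counts).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- validate_config(cfg)
  stopifnot(inherits(cfg, "mr_config"))
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  exposure <- read_sumstats(cfg$exposure$path, quiet = TRUE)
  say("exposure panel: %d variants (%d dropped on read)", nrow(exposure),
      attr(exposure, "dropped"))
  region <- gene_region(cfg$region$name, cfg$region$chrom,
                        cfg$region$start, cfg$region$end)
  ld <- if (!is.null(cfg$ld)) read_ld_matrix(cfg$ld$matrix, cfg$ld$ids)
  sel <- select_cis_window(exposure, region, cfg$window_bp)
  say("cis window %d bp: %d variants", as.integer(cfg$window_bp), nrow(sel))
  if (!is.null(ld)) {
    sel <- ld_prune(sel, ld, cfg$r2_threshold)
    say("LD pruning at r2 < %g: %d variants", cfg$r2_threshold, nrow(sel))
  }
  if (nrow(sel) == 0) abort("no instruments after selection")

  primary <- list(); sens <- list(); singles <- list()
  loos <- list(); radials <- list()
  harmonised_sets <- list()
  for (oc in cfg$outcomes) {
    tag <- tibble(cohort = oc$cohort, outcome = oc$outcome)
    res <- tryCatch({
      panel <- read_sumstats(oc$path, quiet = TRUE)
      harm <- harmonise(sel, panel, palindrome_policy = cfg$palindrome_policy,
                        freq_window = cfg$freq_window)
      say("%s/%s: %d harmonised, %d excluded", oc$cohort, oc$outcome,
          nrow(harm), nrow(exclusions(harm)))
      if (cfg$orientation == "per_unit_exposure_decrease") {
        harm <- orient_to_blockade(harm)
      }
      if (nrow(harm) == 0) abort("no harmonised instruments")
      harmonised_sets[[paste(oc$cohort, oc$outcome, sep = ":")]] <- harm

      if (nrow(harm) == 1) {
        est <- single_snp(harm) %>% select(-"variant_id")
      } else {
        fit <- fit_mr(harm, cfg$effects_model, seed = cfg$seed,
                      n_boot = cfg$n_boot)
        est <- fit$estimates
      }
      primary[[length(primary) + 1]] <-
        bind_cols(tag[rep(1, nrow(est)), ], est %>% mutate(
          or = exp(.data$beta), or_ci_low = exp(.data$ci_low),
          or_ci_high = exp(.data$ci_high)))
      ss <- single_snp(harm)
      singles[[length(singles) + 1]] <- bind_cols(tag[rep(1, nrow(ss)), ], ss)
      if (nrow(harm) >= 3) {
        rad_cfg <- cfg$sensitivity$radial %||% list()
        rad <- radial_scan(harm, alpha = rad_cfg$alpha %||% 0.05,
                           correction = rad_cfg$correction %||% "bonferroni")
        radials[[length(radials) + 1]] <-
          bind_cols(tag[rep(1, nrow(rad$per_snp)), ], rad$per_snp)
      }
      if (nrow(harm) >= 2) {
        lo <- leave_one_out(harm, cfg$effects_model)
        loos[[length(loos) + 1]] <- bind_cols(tag[rep(1, nrow(lo)), ],
                                               as_tibble(lo))
      }
      state <- list(exposure = exposure, outcome = panel, region = region,
                    ld = ld, window_bp = cfg$window_bp,
                    r2_threshold = cfg$r2_threshold,
                    effects_model = cfg$effects_model,
                    orientation = cfg$orientation, seed = cfg$seed)
      for (sc in cfg$sensitivity$scenarios %||% list()) {
        nm <- sc$name %||% "scenario"
        ov <- sc[setdiff(names(sc), "name")]
        out <- rerun_with_config(state, ov, scenario = nm)
        sens[[length(sens) + 1]] <- bind_cols(tag[rep(1, nrow(out)), ], out)
      }
      TRUE
    }, error = function(e) {
      say("FAILED %s/%s: %s", oc$cohort, oc$outcome, conditionMessage(e))
      FALSE
    })
    if (!res) next
  }

  cluster_assignments <- tibble()
  cluster_estimates <- tibble()
  if (isTRUE(cfg$clustering$enabled) && length(harmonised_sets) >= 2) {
    cl_res <- tryCatch({
      panels <- purrr::map(cfg$outcomes, function(oc) {
        read_sumstats(oc$path, quiet = TRUE)
      })
      names(panels) <- purrr::map_chr(cfg$outcomes, function(oc) {
        paste(oc$cohort, oc$outcome, sep = ":")
      })
      z <- build_trait_matrix(panels, exposure, sel$variant_id,
                              palindrome_policy = cfg$palindrome_policy,
                              freq_window = cfg$freq_window)
      fit <- fit_directional_mixture(
        z, K = cfg$clustering$K %||% 10,
        n_starts = cfg$clustering$n_starts %||% 50,
        seed = cfg$clustering$seed %||% cfg$seed,
        assign_threshold = cfg$clustering$assign_threshold %||% 0.8)
      say("clustering: %d traits, K_effective = %d, %d noise",
          ncol(z), fit$K_effective, sum(fit$labels == "noise"))
      cluster_assignments <- tidy(fit)
      first_set <- harmonised_sets[[1]]
      ids <- setdiff(unique(fit$labels), "noise")
      cluster_estimates <- bind_rows(purrr::map(ids, function(k) {
        cluster_mr(first_set, fit, k, cfg$effects_model)
      }))
      list(a = cluster_assignments, e = cluster_estimates)
    }, error = function(e) {
      say("clustering FAILED: %s", conditionMessage(e))
      NULL
    })
    if (!is.null(cl_res)) {
      cluster_assignments <- cl_res$a
      cluster_estimates <- cl_res$e
    }
  }

  meta <- tibble()
  if (!is.null(cfg$meta)) {
    tab <- read_cohort_effects(cfg$meta$table)
    meta <- bind_rows(purrr::map(cfg$meta$groupings, function(g) {
      members <- g$members
      sub <- tab %>%
        filter(paste(.data$cohort, .data$outcome, sep = ":") %in% members)
      if (nrow(sub) < length(members)) {
        say("meta grouping %s: %d/%d members found", g$name, nrow(sub),
            length(members))
      }
      m <- meta_fixed(sub)
      tibble(grouping = g$name, pooled_or = m$pooled_or, ci_low = m$ci_low,
             ci_high = m$ci_high, beta = m$beta, se = m$se,
             pvalue = m$pvalue, Q = m$Q, Q_df = m$Q_df,
             n_cohorts = nrow(sub))
    }))
  }

  structure(
    list(primary = bind_rows(primary), sensitivity = bind_rows(sens),
         single_snp = bind_rows(singles), loo = bind_rows(loos),
         radial = bind_rows(radials),
         cluster_assignments = cluster_assignments,
         cluster_estimates = cluster_estimates,
         meta = meta, log = log, config = cfg),
    class = "results_bundle"
  )
}

#' Write a results bundle as TSV files
#'
#' @param bundle A `results_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("primary", "sensitivity", "single_snp", "loo", "radial",
               "cluster_assignments", "cluster_estimates", "meta")) {
    write_results(bundle[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  writeLines(bundle$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Format a forest-plot table of primary results
#'
#' One row per (cohort, outcome) with the OR and 95% CI rendered to two
#' decimal places (trailing zeros trimmed, rounding half-even — R's default
#' IEC 60559 behaviour), ordered sepsis block first, then COVID, then other
#' infections, following the conventional presentation.
#'
#' @param bundle A `results_bundle`, or a tibble with `cohort`, `outcome`,
#'   `or`, `or_ci_low`, `or_ci_high`, `pvalue` (IVW rows are selected from a
#'   bundle).
#' @param group_order Character prefixes used to order outcome blocks.
#' @return Tibble with `cohort`, `outcome`, `display` (e.g.
#'   `"0.48 (0.3-0.78)"`), `pvalue`.
#' @export
forest_table <- function(bundle,
                         group_order = c("sepsis", "covid", "infection")) {
  tab <- if (inherits(bundle, "results_bundle")) bundle$primary else bundle
  if ("method" %in% names(tab)) {
    tab <- tab %>% filter(.data$method %in% c("ivw_fixed", "ivw_mre",
                                              "wald_ratio"))
  }
  if (nrow(tab) == 0) {
    return(tibble(cohort = character(0), outcome = character(0),
                  display = character(0), pvalue = numeric(0)))
  }
  block <- purrr::map_int(tolower(tab$outcome), function(o) {
    hit <- which(purrr::map_lgl(group_order, function(g) grepl(g, o)))
    if (length(hit) == 0) length(group_order) + 1L else min(hit)
  })
  tab %>%
    mutate(display = sprintf("%s (%s–%s)", fmt2(.data$or),
                             fmt2(.data$or_ci_low), fmt2(.data$or_ci_high)),
           .block = block) %>%
    arrange(.data$.block, .data$outcome, .data$cohort) %>%
    select("cohort", "outcome", "display", "pvalue")
}

# two decimals, half-even, trailing zeros trimmed ("0.30" -> "0.3")
fmt2 <- function(x) {
  out <- format(round(x, 2), trim = TRUE, scientific = FALSE)
  ifelse(grepl("\\.", out), sub("\\.?0+$", "", out), out)
}
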