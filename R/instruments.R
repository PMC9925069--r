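#' Define a gene region
#'
#' A small constructor for the cis locus around which instruments are
#' selected. Coordinates are 1-based inclusive on whatever genome build the
#' summary statistics share; the package never lifts over.
#'
#' @param name Locus label (e.g. `"IL6R"`).
#' @param chrom Chromosome as a string.
#' @param start,end 1-based inclusive gene bounds, `start <= end`.
#' @return A one-row tibble of class `gene_region`.
#' @export
gene_region <- function(name, chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end) {
    abort("gene_region requires integer start <= end")
  }
  out <- tibble(name = name, chrom = as.character(chrom),
                start = start, end = end)
  class(out) <- c("gene_region", class(out))
  out
}

#' Restrict summary statistics to a cis window around a gene
#'
#' Keeps exactly the variants on the region's chromosome whose position lies
#' in the closed interval `[start - window_bp, end + window_bp]`.
#'
#' @param records Summary-statistics tibble with `chrom` and `pos`.
#' @param region A [gene_region()].
#' @param window_bp Flanking window in base pairs (default 300,000; the
#'   restricted sensitivity analysis uses 10,000).
#' @return The filtered tibble (possibly empty, with a message).
#' @export
select_cis_window <- function(records, region, window_bp = 3e5) {
  lo <- region$start - window_bp
  hi <- region$end + window_bp
  out <- records %>%
    filter(.data$chrom == region$chrom, .data$pos >= lo, .data$pos <= hi)
  if (nrow(out) == 0) {
    inform(paste0("select_cis_window: no variants within ", window_bp,
                  " bp of ", region$name))
  }
  out
}

#' Greedy LD pruning of candidate instruments
#'
#' Standard clumping semantics: repeatedly keep the remaining variant with
#' the smallest exposure p-value (ties broken by smaller position, then
#' variant ID) and discard every remaining variant correlated with it at
#' `r2 >= r2_threshold`. The result is independent of input row order and
#' satisfies the pairwise `r2 < r2_threshold` invariant.
#'
#' @param records Summary-statistics tibble (`pvalue` used for ranking; if
#'   absent or missing it is derived from `beta`/`se`).
#' @param ld Square correlation matrix with dimnames covering all records.
#' @param r2_threshold Squared-correlation threshold; variants with
#'   `r2 >= r2_threshold` against a kept variant are dropped (default 0.1).
#' @return The pruned tibble, in canonical p-value/position order.
#' @export
ld_prune <- function(records, ld, r2_threshold = 0.1) {
  missing <- setdiff(records$variant_id, rownames(ld))
  if (length(missing) > 0) {
    abort(paste0("variants missing from the LD matrix: ",
                 paste(missing, collapse = ", ")))
  }
  p <- records$pvalue
  if (is.null(p)) p <- rep(NA_real_, nrow(records))
  fallback <- 2 * pnorm(-abs(records$beta / records$se))
  p <- if_else(is.na(p), fallback, p)
  ord <- order(p, records$pos, records$variant_id)
  remaining <- records[ord, , drop = FALSE]
  kept <- remaining[0, , drop = FALSE]
  while (nrow(remaining) > 0) {
    top <- remaining[1, , drop = FALSE]
    kept <- bind_rows(kept, top)
    r2 <- ld[top$variant_id, remaining$variant_id]^2
    remaining <- remaining[r2 < r2_threshold, , drop = FALSE]
  }
  kept
}

#' Instrument strength F-statistic
#'
#' First-order per-variant instrument strength, `(beta / se)^2`. Invariant
#' under allele reorientation (sign of `beta`).
#'
#' @param beta,se Exposure association and its standard error (vectorised).
#' @return Numeric vector of F-statistics.
#' @examples
#' f_statistic(-0.0558, 0.01) # ~31.1
#' @export
f_statistic <- function(beta, se) {
  stopifnot(all(se > 0))
  (beta / se)^2
}

#' Orient an instrument set to the drug-blockade scale
#'
#' Re-expresses every instrument per unit of exposure *decrease*: the
#' exposure beta is negated and the effect/other alleles swapped (with
#' `eaf -> 1 - eaf`), so that a positive causal estimate afterwards means the
#' outcome risk rises as the exposure falls — the convention under which
#' IL6R-blockade odds ratios are reported per unit of natural-log CRP
#' decrease. Outcome associations are untouched, so each Wald ratio flips
#' sign but keeps its magnitude. The function is an involution: applying it
#' twice restores the input.
#'
#' @param set A `harmonised_set` (or any tibble with `gamma`,
#'   `effect_allele`, `other_allele`, `eaf` columns).
#' @return The reoriented set, with attribute `orientation` set to
#'   `"per_unit_exposure_decrease"` (or back to
#'   `"per_unit_exposure_increase"` on the second application).
#' @export
orient_to_blockade <- function(set) {
  cur <- attr(set, "orientation") %||% "per_unit_exposure_increase"
  out <- set %>%
    mutate(
      gamma = -.data$gamma,
      eaf = if_else(is.na(.data$eaf), NA_real_, 1 - .data$eaf)
    )
  ea <- out$effect_allele
  out$effect_allele <- out$other_allele
  out$other_allele <- ea
  attr(out, "exclusions") <- attr(set, "exclusions")
  attr(out, "orientation") <- if (cur == "per_unit_exposure_increase") {
    "per_unit_exposure_decrease"
  } else {
    "per_unit_exposure_increase"
  }
  class(out) <- class(set)
  out
}
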