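#' Read a GWAS summary-statistics table
#'
#' Reads a tab-delimited summary-statistics file into the canonical tibble used
#' throughout the package: one row per variant with columns `variant_id`,
#' `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#' `pvalue`, `n`. Rows violating basic validity (identical alleles,
#' non-positive `se`, `eaf` outside (0,1), `pvalue` outside (0,1]) are dropped
#' with a message reporting the count; a file yielding zero valid rows is an
#' error.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param column_map Named character vector mapping canonical names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`) to the file's header names. Defaults to the
#'   conventional `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N` layout.
#'   `eaf`, `pvalue` and `n` may be absent from the file; the others are
#'   mandatory.
#' @param quiet Suppress the dropped-row message.
#' @return A tibble of validated summary statistics, ordered as in the file,
#'   with a `dropped` attribute holding the number of discarded rows.
#' @examples
#' path <- system.file("extdata", "cisil6r_exposure_synthetic.tsv",
#'   package = "cismr")
#' head(read_sumstats(path))
#' @export
read_sumstats <- function(path, column_map = default_column_map(), quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("summary-statistics file not found: ", path))
  column_map <- utils::modifyList(as.list(default_column_map()), as.list(column_map))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  mandatory <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                 "beta", "se")
  optional <- c("eaf", "pvalue", "n")
  for (canon in mandatory) {
    if (!column_map[[canon]] %in% names(raw)) {
      abort(paste0("mandatory column '", column_map[[canon]], "' (", canon,
                   ") missing from ", path))
    }
  }
  out <- tibble(
    variant_id    = raw[[column_map$variant_id]],
    chrom         = as.character(raw[[column_map$chrom]]),
    pos           = as.integer(raw[[column_map$pos]]),
    effect_allele = toupper(raw[[column_map$effect_allele]]),
    other_allele  = toupper(raw[[column_map$other_allele]]),
    beta          = as.numeric(raw[[column_map$beta]]),
    se            = as.numeric(raw[[column_map$se]])
  )
  for (canon in optional) {
    col <- column_map[[canon]]
    out[[canon]] <- if (col %in% names(raw)) as.numeric(raw[[col]]) else NA_real_
  }
  out$pos <- as.integer(out$pos)
  out$n <- as.integer(out$n)
  out <- out[, c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pvalue", "n")]
  valid <- validate_sumstats(out)
  dropped <- sum(!valid)
  if (dropped > 0 && !quiet) {
    inform(paste0("read_sumstats: dropped ", dropped, " invalid row",
                  if (dropped > 1) "s" else "", " from ", basename(path)))
  }
  out <- out[valid, , drop = FALSE]
  if (nrow(out) == 0) abort(paste0("no valid summary-statistic rows in ", path))
  attr(out, "dropped") <- dropped
  out
}

#' Default summary-statistics column map
#' @return Named character vector of canonical -> header names.
#' @export
default_column_map <- function() {
  c(variant_id = "SNP", chrom = "CHR", pos = "POS", effect_allele = "EA",
    other_allele = "OA", eaf = "EAF", beta = "BETA", se = "SE",
    pvalue = "P", n = "N")
}

validate_sumstats <- function(x) {
  ok <- !is.na(x$variant_id) & !is.na(x$beta) & !is.na(x$se) & x$se > 0
  ok <- ok & x$effect_allele %in% names(COMPLEMENT) &
    x$other_allele %in% names(COMPLEMENT) &
    x$effect_allele != x$other_allele
  ok <- ok & (is.na(x$eaf) | (x$eaf > 0 & x$eaf < 1))
  ok <- ok & (is.na(x$pvalue) | (x$pvalue > 0 & x$pvalue <= 1))
  ok & !is.na(ok)
}

#' Write a summary-statistics tibble in the package's TSV dialect
#'
#' @param x Canonical summary-statistics tibble.
#' @param path Output path.
#' @param column_map As in [read_sumstats()]; written headers.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path, column_map = default_column_map()) {
  out <- x[, names(column_map)[names(column_map) %in% names(x)]]
  names(out) <- column_map[names(out)]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

is_palindromic <- function(ea, oa) COMPLEMENT[ea] == oa

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns an outcome panel onto the exposure panel's effect alleles, so that
#' every retained variant reports the exposure association `gamma` and the
#' outcome association `Gamma` for the same allele. Direct matches and
#' allele-swapped matches (outcome effect allele equals exposure other allele)
#' are resolved by sign-flipping the outcome beta; strand flips (A<->T, C<->G
#' complements) are resolved by complementing before matching. Palindromic
#' variants (A/T or C/G pairs), for which strand cannot be resolved from the
#' alleles alone, are handled per `palindrome_policy`: under `"infer_by_freq"`
#' the orientation is taken from allele frequencies, accepted only when both
#' panels' frequencies are decisive (`|eaf - 0.5| > freq_window` in both), and
#' under `"drop"` all palindromic variants are excluded.
#'
#' @param exposure,outcome Canonical summary-statistics tibbles (see
#'   [read_sumstats()]). Variants are matched on `variant_id`.
#' @param palindrome_policy `"infer_by_freq"` (default) or `"drop"`.
#' @param freq_window Half-width of the ambiguous frequency zone around 0.5
#'   (default 0.08).
#' @return A tibble of class `harmonised_set`: columns `variant_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `gamma`, `s_gamma`, `Gamma`,
#'   `s_Gamma`, `palindromic`, `inferred_by_freq`, plus exposure `chrom`/`pos`.
#'   The `exclusions` attribute is a tibble of `variant_id` + `reason` for
#'   every exposure variant not retained (reasons: `unmatched_outcome`,
#'   `ambiguous_palindrome`, `palindrome_missing_eaf`, `palindrome_dropped`,
#'   `irreconcilable_alleles`).
#' @examples
#' exp <- tibble::tibble(variant_id = "rs1", chrom = "1", pos = 100L,
#'   effect_allele = "A", other_allele = "G", eaf = 0.3, beta = 0.1,
#'   se = 0.01, pvalue = 1e-8, n = 1000L)
#' out <- tibble::tibble(variant_id = "rs1", chrom = "1", pos = 100L,
#'   effect_allele = "G", other_allele = "A", eaf = 0.7, beta = 0.05,
#'   se = 0.02, pvalue = 0.01, n = 5000L)
#' harmonise(exp, out)$Gamma  # -0.05: outcome re-signed to the A allele
#' @export
harmonise <- function(exposure, outcome,
                      palindrome_policy = c("infer_by_freq", "drop"),
                      freq_window = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(freq_window >= 0, freq_window < 0.5)
  j <- match(exposure$variant_id, outcome$variant_id)
  matched <- !is.na(j)
  e <- exposure[matched, , drop = FALSE]
  o <- outcome[j[matched], , drop = FALSE]

  ea <- e$effect_allele; oa <- e$other_allele
  o_ea <- o$effect_allele; o_oa <- o$other_allele
  pal <- unname(COMPLEMENT[ea] == oa)

  # allele alignment for non-palindromic variants: direct, swapped, or the
  # same two cases after strand complement; anything else is irreconcilable
  c_ea <- unname(COMPLEMENT[o_ea]); c_oa <- unname(COMPLEMENT[o_oa])
  same <- (o_ea == ea & o_oa == oa) | (c_ea == ea & c_oa == oa)
  swapped <- (o_ea == oa & o_oa == ea) | (c_ea == oa & c_oa == ea)

  # palindromic variants: allele labels carry no strand information, so
  # orientation comes from allele frequency alone, and only when both panels
  # are decisively away from 0.5
  freq_ok <- !is.na(e$eaf) & !is.na(o$eaf) &
    abs(e$eaf - 0.5) > freq_window & abs(o$eaf - 0.5) > freq_window
  same_side <- (e$eaf < 0.5) == (o$eaf < 0.5)

  reason <- rep(NA_character_, nrow(e))
  sign_flip <- rep(NA_real_, nrow(e))
  np <- !pal
  sign_flip[np & same] <- 1
  sign_flip[np & swapped & !same] <- -1
  reason[np & !same & !swapped] <- "irreconcilable_alleles"
  if (palindrome_policy == "drop") {
    reason[pal] <- "palindrome_dropped"
  } else {
    pal_usable <- pal & same & freq_ok
    sign_flip[pal_usable & same_side] <- 1
    sign_flip[pal_usable & !same_side] <- -1
    reason[pal & !same] <- "irreconcilable_alleles"
    reason[pal & same & !freq_ok &
             (is.na(e$eaf) | is.na(o$eaf))] <- "palindrome_missing_eaf"
    reason[pal & same & !freq_ok &
             !(is.na(e$eaf) | is.na(o$eaf))] <- "ambiguous_palindrome"
  }
  keep <- !is.na(sign_flip)

  res <- tibble(
    variant_id = e$variant_id[keep], chrom = e$chrom[keep], pos = e$pos[keep],
    effect_allele = ea[keep], other_allele = oa[keep], eaf = e$eaf[keep],
    gamma = e$beta[keep], s_gamma = e$se[keep],
    pvalue_exposure = e$pvalue[keep],
    Gamma = o$beta[keep] * sign_flip[keep], s_Gamma = o$se[keep],
    palindromic = pal[keep],
    inferred_by_freq = pal[keep] & palindrome_policy == "infer_by_freq"
  )
  exclusions <- bind_rows(
    tibble(variant_id = exposure$variant_id[!matched],
           reason = rep("unmatched_outcome", sum(!matched))),
    tibble(variant_id = e$variant_id[!keep], reason = reason[!keep])
  )
  new_harmonised(res, exclusions)
}

new_harmonised <- function(x, exclusions = attr(x, "exclusions")) {
  attr(x, "exclusions") <- exclusions
  class(x) <- unique(c("harmonised_set", class(x)))
  x
}

#' Exclusion log of a harmonised set
#' @param x A `harmonised_set` as returned by [harmonise()].
#' @return Tibble with `variant_id` and `reason`.
#' @export
exclusions <- function(x) {
  attr(x, "exclusions") %||% tibble(variant_id = character(0), reason = character(0))
}

#' Find an LD proxy for a missing variant
#'
#' Returns the candidate variant with the highest squared correlation to the
#' target, provided it reaches `r2_min`; ties are broken by smaller genomic
#' position. Used when a variant is absent from a secondary outcome panel.
#'
#' @param target Variant ID to be proxied. Must be present in `ld`.
#' @param candidates Summary-statistics tibble of variants available in the
#'   outcome panel (needs `variant_id` and `pos`).
#' @param ld Square correlation matrix with variant IDs as dimnames (see
#'   [read_ld_matrix()]).
#' @param r2_min Minimum squared correlation to accept a proxy (default 0.8).
#' @return The proxy variant ID, or `NA_character_` when no candidate
#'   qualifies.
#' @export
find_proxy <- function(target, candidates, ld, r2_min = 0.8) {
  ids <- rownames(ld)
  if (!target %in% ids) {
    abort(paste0("target variant '", target, "' absent from the LD matrix"),
          class = "cismr_ld_missing")
  }
  cand <- candidates[candidates$variant_id %in% ids, , drop = FALSE]
  if (nrow(cand) == 0) return(NA_character_)
  r2 <- ld[target, cand$variant_id]^2
  ok <- r2 >= r2_min
  if (!any(ok)) return(NA_character_)
  cand <- cand[ok, , drop = FALSE]
  r2 <- r2[ok]
  best <- which(r2 == max(r2))
  if (length(best) > 1) best <- best[which.min(cand$pos[best])]
  cand$variant_id[best]
}

#' Read / write a plain-text LD matrix
#'
#' The on-disk format is a whitespace-delimited square numeric matrix plus a
#' companion index file with one variant ID per line, in matrix order.
#'
#' @param matrix_path Path to the square matrix.
#' @param ids_path Path to the one-ID-per-line index.
#' @return Numeric matrix with variant IDs as dimnames.
#' @export
read_ld_matrix <- function(matrix_path, ids_path) {
  ids <- readLines(ids_path)
  ids <- ids[nzchar(ids)]
  m <- as.matrix(utils::read.table(matrix_path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != length(ids) || ncol(m) != length(ids)) {
    abort("LD matrix dimensions do not match the variant-ID index")
  }
  if (max(abs(m - t(m))) > 1e-8) abort("LD matrix is not symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8) abort("LD matrix diagonal is not 1")
  rownames(m) <- colnames(m) <- ids
  m
}

#' @rdname read_ld_matrix
#' @param ld Matrix with variant-ID dimnames.
#' @export
write_ld_matrix <- function(ld, matrix_path, ids_path) {
  writeLines(rownames(ld), ids_path)
  utils::write.table(ld, matrix_path, row.names = FALSE, col.names = FALSE)
  invisible(matrix_path)
}

#' Write MR estimates to a tab-delimited results file
#'
#' One row per (outcome, method, scenario) with full numeric precision
#' (estimates survive a write/read round trip to at least 10 significant
#' digits).
#'
#' @param results Tibble of MR estimates (as produced by the estimator
#'   functions, optionally with `outcome`/`scenario` tag columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  readr::write_tsv(results, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
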