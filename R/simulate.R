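#' Define a two-sample simulation scenario
#'
#' Encodes the geometry of the study the simulator emulates. The defaults
#' mirror a large cis drug-target analysis: 26 instruments weighted by a
#' continuous exposure measured in ~522,681 individuals (the CHARGE + UK
#' Biobank hsCRP meta-analysis size) against a binary outcome GWAS of 11,643
#' cases and 474,841 controls (UK Biobank sepsis).
#'
#' @param n_snps Number of instruments.
#' @param maf_range Minor-allele frequency range (uniform draw), within
#'   (0, 0.5).
#' @param gamma_range Range of absolute per-allele exposure effects (trait SD
#'   units); signs are random. The default 0.02-0.12 keeps every instrument
#'   strong (F well above 30) at the default exposure sample size.
#' @param exposure_n Exposure GWAS sample size.
#' @param outcome_n_cases,outcome_n_controls Outcome case/control counts.
#' @param beta_causal True causal log-odds per exposure unit.
#' @param pleiotropy One of `pleiotropy_none()`, `pleiotropy_balanced(tau)`,
#'   `pleiotropy_directional(mu, tau)`, `pleiotropy_correlated(delta, tau)`.
#' @param ld_blocks Optional list of `list(size =, rho =)` blocks for
#'   [simulate_ld()]; sizes must sum to at most `n_snps` (remaining variants
#'   are independent).
#' @param palindromic_fraction Fraction of variants given A/T or C/G allele
#'   pairs (their MAF is drawn away from 0.5 so frequency inference stays
#'   decisive).
#' @param strand_flip_fraction Fraction of outcome records written on the
#'   opposite strand; a further independent half of records have their
#'   allele columns swapped. Both exercise harmonisation.
#' @param seed Master seed; all panels are reproducible from it.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n_snps = 26, maf_range = c(0.05, 0.45),
                         gamma_range = c(0.02, 0.12),
                         exposure_n = 522681,
                         outcome_n_cases = 11643, outcome_n_controls = 474841,
                         beta_causal = 0, pleiotropy = pleiotropy_none(),
                         ld_blocks = NULL,
                         palindromic_fraction = 0.15,
                         strand_flip_fraction = 0.15,
                         seed = 1L) {
  stopifnot(
    n_snps >= 1, maf_range[1] > 0, maf_range[1] <= maf_range[2],
    maf_range[2] < 0.5, exposure_n > 0, outcome_n_cases > 0,
    outcome_n_controls > 0
  )
  structure(
    list(n_snps = as.integer(n_snps), maf_range = maf_range,
         gamma_range = gamma_range, exposure_n = exposure_n,
         outcome_n_cases = outcome_n_cases,
         outcome_n_controls = outcome_n_controls,
         beta_causal = beta_causal, pleiotropy = pleiotropy,
         ld_blocks = ld_blocks,
         palindromic_fraction = palindromic_fraction,
         strand_flip_fraction = strand_flip_fraction,
         seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

#' @rdname sim_scenario
#' @export
pleiotropy_none <- function() list(type = "none")

#' @rdname sim_scenario
#' @param tau SD of the per-variant pleiotropic effect.
#' @export
pleiotropy_balanced <- function(tau) list(type = "balanced", tau = tau)

#' @rdname sim_scenario
#' @param mu Mean of the per-variant pleiotropic effect (directional
#'   pleiotropy; violates the zero-mean assumption IVW relies on, while the
#'   Egger intercept targets `mu`).
#' @export
pleiotropy_directional <- function(mu, tau) {
  list(type = "directional", mu = mu, tau = tau)
}

#' @rdname sim_scenario
#' @param delta Regression of the pleiotropic effect on the instrument
#'   strength (violates InSIDE-style independence).
#' @param frac Fraction of variants carrying the correlated pleiotropic
#'   effect (default 0.3, keeping invalid instruments below half the
#'   weight).
#' @export
pleiotropy_correlated <- function(delta, tau, frac = 0.3) {
  list(type = "correlated", delta = delta, tau = tau, frac = frac)
}

# Pleiotropic outcome effects. Directional pleiotropy is defined per
# exposure-increasing allele (sign-coupled to gamma): allele labels are
# arbitrary, so a mean shift is only meaningful on a fixed orientation.
pleio_draw <- function(p, gamma_true) {
  n <- length(gamma_true)
  switch(p$type,
    none = rep(0, n),
    balanced = rnorm(n, 0, p$tau),
    directional = sign(gamma_true) * rnorm(n, p$mu, p$tau),
    correlated = {
      invalid <- runif(n) < p$frac
      invalid * (p$delta * gamma_true + rnorm(n, 0, p$tau))
    },
    abort(paste0("unknown pleiotropy model: ", p$type))
  )
}

#' Simulate a two-sample MR data set with known truth
#'
#' Generates an exposure panel and an outcome panel of GWAS summary
#' statistics under a `sim_scenario`, together with the ground-truth ledger.
#' Per variant: MAF uniform in range; true exposure effect `gamma_j` of
#' random sign and uniform magnitude; exposure SE
#' `(2 n maf (1-maf))^(-1/2)` for a unit-variance exposure; pleiotropic
#' effect `alpha_j` per the scenario's model; true outcome effect
#' `Gamma_j = beta_causal * gamma_j + alpha_j`; outcome SE
#' `(2 n_eff maf (1-maf) phi (1-phi))^(-1/2)` with `phi` the case fraction
#' (logistic score approximation). Observed betas are normal draws around the
#' truth at those SEs. A configurable fraction of outcome records is written
#' strand-flipped and/or allele-swapped, and a fraction of variants is
#' palindromic, so harmonisation is always exercised. Allele frequencies are
#' reported without sampling noise on both panels.
#'
#' @param s A [sim_scenario()].
#' @return List with `exposure` and `outcome` (canonical summary-statistics
#'   tibbles), `truth` (per-variant `maf`, `gamma_true`, `alpha`,
#'   `Gamma_true`), `ld` ([simulate_ld()] output or NULL) and the scenario
#'   echo.
#' @export
simulate_two_sample <- function(s) {
  stopifnot(inherits(s, "sim_scenario"))
  withr::with_seed(s$seed, {
    n <- s$n_snps
    maf <- runif(n, s$maf_range[1], s$maf_range[2])
    pal <- runif(n) < s$palindromic_fraction
    # keep palindromic MAFs decisively below 0.5 - freq_window
    maf[pal] <- pmin(maf[pal], 0.40)
    gamma_true <- sample(c(-1, 1), n, replace = TRUE) *
      runif(n, s$gamma_range[1], s$gamma_range[2])
    s_gamma <- 1 / sqrt(2 * s$exposure_n * maf * (1 - maf))
    alpha <- pleio_draw(s$pleiotropy, gamma_true)
    Gamma_true <- s$beta_causal * gamma_true + alpha
    n_eff <- s$outcome_n_cases + s$outcome_n_controls
    phi <- s$outcome_n_cases / n_eff
    s_Gamma <- 1 / sqrt(2 * n_eff * maf * (1 - maf) * phi * (1 - phi))
    gamma_hat <- rnorm(n, gamma_true, s_gamma)
    Gamma_hat <- rnorm(n, Gamma_true, s_Gamma)

    ids <- paste0("rs", sprintf("%06d", sample.int(999999, n)))
    pos <- sort(sample.int(3e5, n)) + 154e6
    pal_pair <- matrix(c("A", "T", "C", "G"), 2)[, sample(1:2, n, TRUE)]
    npal_ea <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    npal_oa <- vapply(npal_ea, function(a) {
      sample(setdiff(setdiff(c("A", "C", "G", "T"), a),
                     unname(COMPLEMENT[a])), 1)
    }, character(1))
    ea <- ifelse(pal, pal_pair[1, ], npal_ea)
    oa <- ifelse(pal, pal_pair[2, ], unname(npal_oa))

    exposure <- tibble(
      variant_id = ids, chrom = "1", pos = as.integer(pos),
      effect_allele = ea, other_allele = oa, eaf = maf,
      beta = gamma_hat, se = s_gamma,
      pvalue = 2 * pnorm(-abs(gamma_hat / s_gamma)),
      n = as.integer(s$exposure_n)
    )
    # outcome panel: same variants, a fraction re-stranded and/or swapped
    flip_strand <- !pal & runif(n) < s$strand_flip_fraction
    swap <- runif(n) < 0.5
    o_ea <- ifelse(flip_strand, unname(COMPLEMENT[ea]), ea)
    o_oa <- ifelse(flip_strand, unname(COMPLEMENT[oa]), oa)
    out_ea <- ifelse(swap, o_oa, o_ea)
    out_oa <- ifelse(swap, o_ea, o_oa)
    outcome <- tibble(
      variant_id = ids, chrom = "1", pos = as.integer(pos),
      effect_allele = out_ea, other_allele = out_oa,
      eaf = ifelse(swap, 1 - maf, maf),
      beta = ifelse(swap, -Gamma_hat, Gamma_hat), se = s_Gamma,
      pvalue = 2 * pnorm(-abs(Gamma_hat / s_Gamma)),
      n = as.integer(n_eff)
    )
    truth <- tibble(
      variant_id = ids, maf = maf, gamma_true = gamma_true, alpha = alpha,
      Gamma_true = Gamma_true, s_gamma = s_gamma, s_Gamma = s_Gamma,
      palindromic = pal, strand_flipped = flip_strand, allele_swapped = swap
    )
    ld <- if (!is.null(s$ld_blocks)) simulate_ld(s$ld_blocks, ids = ids)
    list(exposure = exposure, outcome = outcome, truth = truth, ld = ld,
         scenario = s)
  })
}

#' Simulate a block-diagonal LD correlation matrix
#'
#' Within each block the correlation decays as `rho^|i-j|` (AR(1)); variants
#' beyond the listed blocks are mutually independent. The result is
#' symmetric with unit diagonal and positive definite for `|rho| < 1`.
#'
#' @param blocks List of `list(size =, rho =)`.
#' @param ids Optional variant IDs (length >= total block size); unnamed
#'   variants get `snp_<i>`.
#' @param n_total Total matrix dimension (default: sum of block sizes).
#' @return Correlation matrix with variant-ID dimnames.
#' @export
simulate_ld <- function(blocks, ids = NULL, n_total = NULL) {
  sizes <- vapply(blocks, `[[`, numeric(1), "size")
  rhos <- vapply(blocks, `[[`, numeric(1), "rho")
  stopifnot(all(sizes >= 1), all(abs(rhos) < 1))
  n <- n_total %||% sum(sizes)
  stopifnot(n >= sum(sizes))
  m <- diag(n)
  at <- 0
  for (b in seq_along(sizes)) {
    idx <- at + seq_len(sizes[b])
    m[idx, idx] <- rhos[b]^abs(outer(seq_len(sizes[b]), seq_len(sizes[b]), "-"))
    at <- at + sizes[b]
  }
  ids <- ids %||% paste0("snp_", seq_len(n))
  rownames(m) <- colnames(m) <- ids[seq_len(n)]
  m
}

#' Simulate a SNP x trait matrix with planted directional clusters
#'
#' Cluster rows scatter tightly about their cluster's mean direction (the
#' spread shrinking as `1/sqrt(concentration)`); noise rows are isotropic.
#' Rows are returned with random positive magnitudes so that unit-scaling
#' inside the mixture fit is exercised.
#'
#' @param J,T_traits Matrix dimensions (variants x traits).
#' @param clusters List of `list(size =, concentration =)`; total size plus
#'   noise must not exceed `J`. Optionally each cluster may carry a
#'   `direction` (unit vector of length `T_traits`); otherwise directions
#'   are drawn at random.
#' @param noise_fraction Fraction of rows that are isotropic noise (the
#'   remainder beyond the planted clusters is also noise).
#' @param seed Seed.
#' @return List with `z` (J x T matrix), `labels` (true labels, `"1"`,
#'   `"2"`, ..., `"noise"`), `directions` (cluster x trait matrix).
#' @export
simulate_trait_matrix <- function(J, T_traits, clusters, noise_fraction = NULL,
                                  seed = 1L) {
  sizes <- vapply(clusters, `[[`, numeric(1), "size")
  if (!is.null(noise_fraction)) {
    stopifnot(sum(sizes) + round(noise_fraction * J) <= J)
  }
  stopifnot(sum(sizes) <= J)
  withr::with_seed(as.integer(seed), {
    dirs <- t(vapply(clusters, function(cl) {
      d <- cl$direction %||% rnorm(T_traits)
      d / sqrt(sum(d^2))
    }, numeric(T_traits)))
    rows <- matrix(NA_real_, J, T_traits)
    labels <- rep("noise", J)
    at <- 0
    for (k in seq_along(clusters)) {
      kap <- clusters[[k]]$concentration
      for (i in seq_len(sizes[k])) {
        v <- dirs[k, ] + rnorm(T_traits) / sqrt(kap)
        rows[at + i, ] <- v / sqrt(sum(v^2))
      }
      labels[at + seq_len(sizes[k])] <- as.character(k)
      at <- at + sizes[k]
    }
    for (i in seq(at + 1, length.out = J - at)) {
      v <- rnorm(T_traits)
      rows[i, ] <- v / sqrt(sum(v^2))
    }
    mag <- exp(rnorm(J, mean = 1, sd = 0.5))
    z <- rows * mag
    rownames(z) <- paste0("rs", seq_len(J))
    colnames(z) <- paste0("trait_", seq_len(T_traits))
    names(labels) <- rownames(z)
    list(z = z, labels = labels, directions = dirs)
  })
}
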