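#' Build a standardised SNP x trait association matrix
#'
#' Harmonises each trait panel onto the exposure panel's effect alleles
#' (restricted to the instrument set), orients rows to the
#' exposure-increasing allele, and assembles the matrix of standardised
#' associations `z = Gamma / s_Gamma`. Traits missing any instrument are
#' dropped and recorded, so the matrix has no missing cells.
#'
#' @param panels Named list of outcome summary-statistics tibbles, one per
#'   trait.
#' @param exposure Exposure summary-statistics tibble.
#' @param instruments Character vector of instrument variant IDs (or a
#'   tibble with a `variant_id` column).
#' @param ... Passed to [harmonise()] (palindrome policy, frequency window).
#' @return Numeric matrix (variants x traits) with dimnames, with attribute
#'   `dropped_traits` naming traits excluded for incomplete coverage.
#' @export
build_trait_matrix <- function(panels, exposure, instruments, ...) {
  if (length(panels) < 2) abort("build_trait_matrix requires >= 2 trait panels")
  if (is.null(names(panels)) || any(!nzchar(names(panels)))) {
    abort("trait panels must be named")
  }
  ids <- if (is.data.frame(instruments)) instruments$variant_id else instruments
  exp_sub <- exposure %>% filter(.data$variant_id %in% ids)
  # orient so that every row refers to the exposure-increasing allele
  cols <- purrr::map(panels, function(panel) {
    h <- harmonise(exp_sub, panel, ...)
    h <- h %>% mutate(z = sign(.data$gamma) * .data$Gamma / .data$s_Gamma)
    setNames(h$z, h$variant_id)
  })
  complete <- purrr::map_lgl(cols, function(zz) all(ids %in% names(zz)))
  dropped <- names(panels)[!complete]
  if (length(dropped) > 0) {
    inform(paste0("build_trait_matrix: dropped incomplete trait(s): ",
                  paste(dropped, collapse = ", ")))
  }
  keep <- cols[complete]
  if (length(keep) < 2) abort("fewer than 2 traits with complete instrument coverage")
  z <- vapply(keep, function(zz) zz[ids], numeric(length(ids)))
  rownames(z) <- ids
  attr(z, "dropped_traits") <- dropped
  z
}

# log surface area of the unit sphere S^{d-1} in d dimensions
log_sphere_area <- function(d) log(2) + (d / 2) * log(pi) - lgamma(d / 2)

# log von Mises-Fisher density on S^{d-1}; vectorised over the dot products.
# kappa near zero degenerates to the uniform density.
log_vmf <- function(dot, kappa, d) {
  if (kappa < 1e-8) return(rep(-log_sphere_area(d), length(dot)))
  nu <- d / 2 - 1
  # log I_nu(kappa) via the exponentially scaled Bessel function
  log_bessel <- log(besselI(kappa, nu, expon.scaled = TRUE)) + kappa
  nu * log(kappa) - (d / 2) * log(2 * pi) - log_bessel + kappa * dot
}

# Concentration from the mean resultant length: Banerjee et al. closed form,
# refined by Newton steps on A_d(kappa) = rbar so the M-step is (numerically)
# exact and EM stays monotone; capped to keep the Bessel evaluation finite.
kappa_from_rbar <- function(rbar, d, kappa_max = 1e4) {
  rbar <- min(max(rbar, 1e-8), 1 - 1e-8)
  k <- rbar * (d - rbar^2) / (1 - rbar^2)
  for (i in 1:3) {
    if (k <= 0 || k >= kappa_max) break
    A <- besselI(k, d / 2, expon.scaled = TRUE) /
      besselI(k, d / 2 - 1, expon.scaled = TRUE)
    if (!is.finite(A) || A <= 0) break
    dA <- 1 - A^2 - (d - 1) / k * A
    step <- (A - rbar) / dA
    if (!is.finite(step)) break
    k_new <- k - step
    if (!is.finite(k_new) || k_new <= 0) break
    k <- k_new
  }
  min(max(k, 1e-8), kappa_max)
}

#' Noise-augmented directional mixture clustering
#'
#' Fits, by expectation-maximisation, a mixture of `K` concentrated
#' directional components (von Mises-Fisher: mean direction plus scalar
#' concentration) and one diffuse uniform "noise" component to the
#' unit-scaled rows of a SNP x trait association matrix. The noise component
#' absorbs variants whose multi-trait signature does not align with any
#' cluster. The best of `n_starts` seeded restarts by log-likelihood is
#' returned. Variants whose top cluster membership probability falls below
#' `assign_threshold` are hard-labelled `"noise"`; empty components simply
#' reduce the effective cluster count.
#'
#' @param z Numeric matrix (variants x traits), e.g. from
#'   [build_trait_matrix()]. Rows are scaled to unit length internally, so
#'   the fit is invariant to positive per-row rescaling.
#' @param K Number of directional components (default 10).
#' @param n_starts Random restarts (default 50).
#' @param seed Integer seed controlling all restarts.
#' @param assign_threshold Minimum top-cluster probability for a hard cluster
#'   label (default 0.8).
#' @param max_iter,tol EM iteration cap (default 500) and relative
#'   log-likelihood convergence tolerance (default 1e-8).
#' @param merge_cos Components whose mean directions are closer than this
#'   cosine are merged after EM (default 0.9): with a generous `K`, maximum
#'   likelihood happily splits one tight direction bundle across several
#'   coincident components, and merging reunites them. Antipodal directions
#'   are never merged.
#' @param min_size Components with fewer than this many expected members
#'   after merging are dissolved (default 4); without this, spare components
#'   latch onto accidental alignments among isotropic rows. Dissolved rows
#'   fall back to the noise component.
#' @param kappa_min Minimum concentration for a component to count as a
#'   cluster rather than background (default `3 * ncol(z)`): a component
#'   fitted to the best-aligned handful of isotropic rows attains a
#'   concentration of order the trait dimension, so only components clearly
#'   above that level are kept.
#' @return An object of class `dir_mixture`: list with `labels` (per-variant,
#'   cluster id as character or `"noise"`), `probabilities` (variants x
#'   (K_live + 1) matrix, last column `noise`), `mu` (live-component mean
#'   directions, unit rows), `kappa`, `pi` (mixing weights incl. noise),
#'   `loglik`, `loglik_trace`, `K`, `K_effective`, `converged`.
#' @export
fit_directional_mixture <- function(z, K = 10, n_starts = 50, seed,
                                    assign_threshold = 0.8,
                                    max_iter = 500, tol = 1e-8,
                                    merge_cos = 0.9, min_size = 4,
                                    kappa_min = NULL) {
  if (missing(seed) || is.null(seed)) abort("fit_directional_mixture requires a seed")
  stopifnot(K >= 1, nrow(z) >= K)
  x <- z / sqrt(rowSums(z^2))
  J <- nrow(x); d <- ncol(x)
  fits <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_starts), function(s) em_vmf_once(x, K, max_iter, tol))
  })
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  kappa_min <- kappa_min %||% 3 * d
  best <- consolidate_components(x, best, merge_cos, min_size, kappa_min,
                                 max_iter, tol)

  K_live <- length(best$kappa)
  probs <- best$resp
  colnames(probs) <- c(as.character(seq_len(K_live))[seq_len(K_live)], "noise")
  rownames(probs) <- rownames(z)
  if (K_live > 0) {
    top <- max.col(probs[, seq_len(K_live), drop = FALSE], ties.method = "first")
    top_p <- probs[cbind(seq_len(J), top)]
    noise_p <- probs[, K_live + 1]
    labels <- ifelse(top_p >= assign_threshold & top_p > noise_p,
                     as.character(top), "noise")
  } else {
    labels <- rep("noise", J)
  }
  names(labels) <- rownames(z)
  structure(
    list(labels = labels, probabilities = probs, mu = best$mu,
         kappa = best$kappa, pi = best$pi,
         loglik = best$loglik, loglik_trace = best$trace,
         K = K, K_effective = length(unique(labels[labels != "noise"])),
         assign_threshold = assign_threshold, converged = best$converged),
    class = "dir_mixture"
  )
}

# E step for a fitted parameter set; returns resp (J x (K+1)) and loglik.
e_step_vmf <- function(x, mu, kappa, pi_k) {
  J <- nrow(x); d <- ncol(x); K <- length(kappa)
  logp <- matrix(-Inf, J, K + 1)
  for (k in seq_len(K)) {
    if (pi_k[k] <= 0) next
    logp[, k] <- log(pi_k[k]) + log_vmf(drop(x %*% mu[k, ]), kappa[k], d)
  }
  logp[, K + 1] <- if (pi_k[K + 1] > 0) {
    log(pi_k[K + 1]) - log_sphere_area(d)
  } else {
    -Inf
  }
  m <- apply(logp, 1, max)
  lse <- m + log(rowSums(exp(logp - m)))
  list(resp = exp(logp - lse), loglik = sum(lse))
}

# Post-EM consolidation: (1) repeatedly merge component pairs whose mean
# directions are within merge_cos (re-running short EM after each merge),
# (2) dissolve components with fewer than min_size expected members, then
# recompute responsibilities. Plain maximum likelihood with a generous K
# otherwise shatters tight bundles across coincident components and fits
# spare components to chance alignments in the isotropic background.
consolidate_components <- function(x, fit, merge_cos, min_size, kappa_min,
                                   max_iter, tol) {
  repeat {
    K <- length(fit$kappa)
    if (K < 2) break
    cosim <- fit$mu %*% t(fit$mu)
    diag(cosim) <- -Inf
    live <- fit$pi[seq_len(K)] > 0
    cosim[!live, ] <- -Inf; cosim[, !live] <- -Inf
    if (max(cosim) <= merge_cos) break
    pair <- which(cosim == max(cosim), arr.ind = TRUE)[1, ]
    a <- min(pair); b <- max(pair)
    # combine weights and resultants, drop component b
    r_a <- fit$mu[a, ] * fit$pi[a] + fit$mu[b, ] * fit$pi[b]
    fit$pi[a] <- fit$pi[a] + fit$pi[b]
    fit$mu[a, ] <- r_a / sqrt(sum(r_a^2))
    # relax the concentration so the refit can re-collect the whole bundle;
    # a merged pair keeps the over-fitted huge kappa of its parts otherwise
    fit$kappa[a] <- min(fit$kappa[a], ncol(x))
    keep <- setdiff(seq_len(K), b)
    fit$mu <- fit$mu[keep, , drop = FALSE]
    fit$kappa <- fit$kappa[keep]
    fit$pi <- fit$pi[c(keep, K + 1)]
    fit <- em_vmf_refit(x, fit, max_iter = 25, tol = tol)
  }
  # dissolve components that are under-occupied or barely more concentrated
  # than chance alignments among isotropic rows (kappa of order the trait
  # dimension): those are background, not clusters
  K <- length(fit$kappa)
  if (K > 0) {
    es <- e_step_vmf(x, fit$mu, fit$kappa, fit$pi)
    nk <- colSums(es$resp)[seq_len(K)]
    keep <- which(nk >= min_size & fit$kappa >= kappa_min)
    if (length(keep) < K) {
      drop_mass <- sum(fit$pi[setdiff(seq_len(K), keep)])
      fit$mu <- fit$mu[keep, , drop = FALSE]
      fit$kappa <- fit$kappa[keep]
      fit$pi <- c(fit$pi[keep], fit$pi[K + 1] + drop_mass)
    }
  }
  es <- e_step_vmf(x, fit$mu, fit$kappa, fit$pi)
  fit$resp <- es$resp
  fit$loglik <- es$loglik
  fit
}

# A few monotone EM iterations from given parameters (after a merge).
em_vmf_refit <- function(x, fit, max_iter, tol) {
  d <- ncol(x); J <- nrow(x)
  mu <- fit$mu; kappa <- fit$kappa; pi_k <- fit$pi
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    es <- e_step_vmf(x, mu, kappa, pi_k)
    if (is.finite(ll_old) && (es$loglik - ll_old) <= tol * (abs(ll_old) + 1)) break
    ll_old <- es$loglik
    K <- length(kappa)
    nk <- colSums(es$resp)
    pi_k <- nk / J
    for (k in seq_len(K)) {
      if (nk[k] < 1e-10) { pi_k[k] <- 0; next }
      r_k <- drop(crossprod(es$resp[, k], x))
      rlen <- sqrt(sum(r_k^2))
      if (rlen < 1e-12) { kappa[k] <- 1e-8; next }
      mu[k, ] <- r_k / rlen
      kappa[k] <- kappa_from_rbar(rlen / nk[k], d)
    }
  }
  fit$mu <- mu; fit$kappa <- kappa; fit$pi <- pi_k
  fit
}

# One EM run from a random initialisation (RNG state supplied by caller).
em_vmf_once <- function(x, K, max_iter, tol) {
  J <- nrow(x); d <- ncol(x)
  init <- sample.int(J, K, replace = J < K)
  mu <- x[init, , drop = FALSE]
  # jitter so coincident seed rows do not collapse components at once
  mu <- mu + matrix(rnorm(K * d, sd = 0.01), K, d)
  mu <- mu / sqrt(rowSums(mu^2))
  kappa <- rep(10, K)
  pi_k <- rep(1 / (K + 1), K + 1)
  log_unif <- -log_sphere_area(d)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  resp <- NULL
  for (iter in seq_len(max_iter)) {
    # E step: log joint for K vMF components + uniform noise
    logp <- matrix(-Inf, J, K + 1)
    for (k in seq_len(K)) {
      if (pi_k[k] <= 0) next
      logp[, k] <- log(pi_k[k]) + log_vmf(drop(x %*% mu[k, ]), kappa[k], d)
    }
    logp[, K + 1] <- if (pi_k[K + 1] > 0) log(pi_k[K + 1]) + log_unif else -Inf
    m <- apply(logp, 1, max)
    lse <- m + log(rowSums(exp(logp - m)))
    ll <- sum(lse)
    resp <- exp(logp - lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll < ll_old - 1e-6 * (abs(ll_old) + 1)) {
      warn("EM log-likelihood decreased; returning current iterate")
      break
    }
    if (is.finite(ll_old) && (ll - ll_old) <= tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # M step
    nk <- colSums(resp)
    pi_k <- nk / J
    for (k in seq_len(K)) {
      if (nk[k] < 1e-10) { pi_k[k] <- 0; next }
      r_k <- drop(crossprod(resp[, k], x))
      rlen <- sqrt(sum(r_k^2))
      if (rlen < 1e-12) { kappa[k] <- 1e-8; next }
      mu[k, ] <- r_k / rlen
      kappa[k] <- kappa_from_rbar(rlen / nk[k], d)
    }
  }
  list(mu = mu, kappa = kappa, pi = pi_k, resp = resp,
       loglik = trace[length(trace)], trace = trace, converged = converged)
}

#' @export
print.dir_mixture <- function(x, ...) {
  cat(sprintf(
    "Directional mixture: K = %d (effective %d), %d variants, %d noise\n",
    x$K, x$K_effective, length(x$labels), sum(x$labels == "noise")))
  cat(sprintf("log-likelihood %.3f (%sconverged)\n", x$loglik,
              if (x$converged) "" else "not "))
  invisible(x)
}

#' Per-cluster MR estimate
#'
#' Restricts the harmonised instrument set to the members of one cluster and
#' reruns the IVW estimator, tagging the result with the cluster ID and size.
#'
#' @inheritParams mr_ivw
#' @param assignment A `dir_mixture` fit (or a named character vector of
#'   labels).
#' @param cluster_id Cluster label to analyse.
#' @return One-row estimate tibble with leading `cluster` and `cluster_size`
#'   columns.
#' @export
cluster_mr <- function(set, assignment, cluster_id,
                       effects_model = c("fixed", "multiplicative")) {
  labels <- if (inherits(assignment, "dir_mixture")) assignment$labels else assignment
  members <- names(labels)[labels == as.character(cluster_id)]
  sub <- set %>% filter(.data$variant_id %in% members)
  if (nrow(sub) == 0) {
    abort(paste0("cluster '", cluster_id, "' has no members in the instrument set"))
  }
  est <- if (nrow(sub) == 1) {
    single_snp(sub) %>% select(-"variant_id")
  } else {
    mr_ivw(sub, match.arg(effects_model))
  }
  bind_cols(tibble(cluster = as.character(cluster_id),
                   cluster_size = nrow(sub)), est)
}
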