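write_panel <- function(df, path = withr::local_tempfile(fileext = ".tsv",
                                                         .local_envir = parent.frame())) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

basic_panel <- function() {
  tibble::tibble(
    SNP = c("rs1", "rs2", "rs3"), CHR = "1", POS = c(100L, 200L, 300L),
    EA = c("A", "C", "G"), OA = c("G", "T", "A"), EAF = c(0.2, 0.3, 0.4),
    BETA = c(0.1, -0.05, 0.02), SE = c(0.01, 0.02, 0.01),
    P = c(1e-10, 0.01, 0.05), N = 1000L
  )
}

test_that("well-formed tables read cleanly and invalid rows are dropped", {
  p <- write_panel(basic_panel())
  x <- read_sumstats(p)
  expect_equal(nrow(x), 3)
  expect_equal(attr(x, "dropped"), 0)
  expect_named(x, c("variant_id", "chrom", "pos", "effect_allele",
                    "other_allele", "eaf", "beta", "se", "pvalue", "n"))

  bad <- basic_panel()
  bad$SE[2] <- 0
  p2 <- write_panel(bad)
  expect_message(x2 <- read_sumstats(p2), "dropped 1")
  expect_equal(nrow(x2), 2)
  expect_equal(attr(x2, "dropped"), 1)

  same_alleles <- basic_panel()
  same_alleles$OA[1] <- same_alleles$EA[1]
  expect_equal(attr(read_sumstats(write_panel(same_alleles), quiet = TRUE),
                    "dropped"), 1)
})

test_that("missing mandatory columns and empty tables are hard errors", {
  df <- basic_panel()
  df$BETA <- NULL
  expect_error(read_sumstats(write_panel(df)), "BETA")
  allbad <- basic_panel()
  allbad$SE <- 0
  expect_error(suppressMessages(read_sumstats(write_panel(allbad))),
               "no valid")
  expect_error(read_sumstats(tempfile()), "not found")
})

test_that("custom column maps are honoured", {
  df <- basic_panel()
  names(df) <- c("rsid", "chrom", "bp", "a1", "a2", "freq", "b", "stderr",
                 "pval", "samples")
  p <- write_panel(df)
  x <- read_sumstats(p, column_map = c(
    variant_id = "rsid", chrom = "chrom", pos = "bp", effect_allele = "a1",
    other_allele = "a2", eaf = "freq", beta = "b", se = "stderr",
    pvalue = "pval", n = "samples"))
  expect_equal(x$beta, c(0.1, -0.05, 0.02))
})

test_that("the cis instrument fixture loads all 26 variants", {
  x <- read_sumstats(cis_fixture_path())
  expect_equal(nrow(x), 26)
  expect_equal(attr(x, "dropped"), 0)
})

test_that("summary statistics survive a write/read round trip", {
  x <- read_sumstats(write_panel(basic_panel()))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(x, p2)
  y <- read_sumstats(p2)
  expect_equal(as.data.frame(y), as.data.frame(x), tolerance = 1e-12)
})

test_that("allele swaps flip the outcome sign and strand flips do not", {
  exp <- basic_panel()[1, ] |> write_panel() |> read_sumstats()
  # swapped alleles: outcome effect reported for the exposure's other allele
  out <- exp
  out$effect_allele <- "G"; out$other_allele <- "A"
  out$eaf <- 1 - exp$eaf; out$beta <- 0.05
  h <- harmonise(exp, out)
  expect_equal(h$Gamma, -0.05)
  # pure strand flip: complement alleles, same orientation
  out2 <- exp
  out2$effect_allele <- "T"; out2$other_allele <- "C"
  out2$beta <- 0.05
  h2 <- harmonise(exp, out2)
  expect_equal(h2$Gamma, 0.05)
  # irreconcilable allele pair
  out3 <- exp
  out3$effect_allele <- "C"; out3$other_allele <- "G"
  h3 <- harmonise(exp, out3)
  expect_equal(nrow(h3), 0)
  expect_equal(exclusions(h3)$reason, "irreconcilable_alleles")
})

test_that("palindromic variants follow the frequency-inference policy", {
  exp <- basic_panel()[1, ]
  exp$EA <- "A"; exp$OA <- "T"; exp$EAF <- 0.10
  exp <- read_sumstats(write_panel(exp))
  out <- exp
  out$eaf <- 0.12; out$beta <- 0.04
  h <- harmonise(exp, out, freq_window = 0.08)
  expect_equal(nrow(h), 1)
  expect_true(h$inferred_by_freq)
  expect_equal(h$Gamma, 0.04)
  # opposite frequency side implies the complementary-strand allele
  out_flip <- out
  out_flip$eaf <- 0.88
  expect_equal(harmonise(exp, out_flip, freq_window = 0.08)$Gamma, -0.04)
  # near-0.5 frequency is ambiguous
  out_amb <- out
  out_amb$eaf <- 0.49
  h_amb <- harmonise(exp, out_amb, freq_window = 0.08)
  expect_equal(nrow(h_amb), 0)
  expect_equal(exclusions(h_amb)$reason, "ambiguous_palindrome")
  # drop policy removes palindromes outright
  h_drop <- harmonise(exp, out, palindrome_policy = "drop")
  expect_equal(exclusions(h_drop)$reason, "palindrome_dropped")
  # missing frequency cannot be inferred
  out_na <- out
  out_na$eaf <- NA_real_
  expect_equal(exclusions(harmonise(exp, out_na))$reason,
               "palindrome_missing_eaf")
})

test_that("harmonisation is idempotent and double-flip invariant", {
  for (s in 1:5) {
    sim <- simulate_two_sample(sim_scenario(seed = s, n_snps = 20))
    h1 <- harmonise(sim$exposure, sim$outcome)
    # idempotence: re-harmonising the harmonised outcome changes nothing
    out_aligned <- sim$outcome
    idx <- match(h1$variant_id, out_aligned$variant_id)
    out_aligned <- out_aligned[idx, ]
    out_aligned$effect_allele <- h1$effect_allele
    out_aligned$other_allele <- h1$other_allele
    out_aligned$eaf <- h1$eaf
    out_aligned$beta <- h1$Gamma
    h2 <- harmonise(sim$exposure, out_aligned)
    expect_equal(h2$Gamma, h1$Gamma)
    expect_equal(h2$variant_id, h1$variant_id)
    # double flip: swap alleles, negate beta, mirror eaf in the outcome panel
    flipped <- sim$outcome
    tmp <- flipped$effect_allele
    flipped$effect_allele <- flipped$other_allele
    flipped$other_allele <- tmp
    flipped$beta <- -flipped$beta
    flipped$eaf <- 1 - flipped$eaf
    h3 <- harmonise(sim$exposure, flipped)
    expect_equal(h3$Gamma, h1$Gamma, tolerance = 1e-12)
    # count conservation
    expect_equal(nrow(h1) + nrow(exclusions(h1)), nrow(sim$exposure))
  }
})

test_that("proxy search returns the best qualifying candidate", {
  ld <- matrix(c(1, 0.975, 0.92, 0.71,
                 0.975, 1, 0.9, 0.7,
                 0.92, 0.9, 1, 0.6,
                 0.71, 0.7, 0.6, 1), 4, 4,
               dimnames = list(c("t", "a", "b", "c"), c("t", "a", "b", "c")))
  cand <- tibble::tibble(variant_id = c("a", "b", "c"), pos = c(30L, 10L, 20L))
  # r2 = {0.95, 0.85, 0.5} approx; best above threshold wins
  expect_equal(find_proxy("t", cand, ld, r2_min = 0.8), "a")
  # the target itself always wins when present (r2 = 1)
  cand_t <- dplyr::bind_rows(tibble::tibble(variant_id = "t", pos = 5L), cand)
  expect_equal(find_proxy("t", cand_t, ld, r2_min = 0.8), "t")
  # nothing qualifies
  expect_true(is.na(find_proxy("t", cand, ld, r2_min = 0.99)))
  # absent target is an error distinct from the empty result
  expect_error(find_proxy("zz", cand, ld), class = "cismr_ld_missing")
  # ties broken by position
  ld2 <- ld; ld2["t", "b"] <- ld2["b", "t"] <- ld2["t", "a"]
  expect_equal(find_proxy("t", cand, ld2, r2_min = 0.8), "b")
})

test_that("LD matrices round-trip through the plain-text format", {
  ld <- simulate_ld(list(list(size = 3, rho = 0.9), list(size = 2, rho = 0)))
  mp <- withr::local_tempfile(); ip <- withr::local_tempfile()
  write_ld_matrix(ld, mp, ip)
  ld2 <- read_ld_matrix(mp, ip)
  expect_equal(ld2, ld, tolerance = 1e-12)
  # malformed inputs rejected
  writeLines(c("a", "b"), ip)
  expect_error(read_ld_matrix(mp, ip), "dimensions")
})

test_that("results tables round-trip at full precision", {
  ests <- dplyr::bind_rows(lapply(1:5, function(i) {
    mr_ivw(make_harmonised(6, seed = i))
  }))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_results(ests, p)
  back <- read_results(p)
  expect_equal(back$beta, ests$beta, tolerance = 1e-10)
  expect_equal(back$se, ests$se, tolerance = 1e-10)
  # empty collection gives a header-only file
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_results(ests[0, ], p2)
  expect_equal(nrow(read_results(p2)), 0)
  expect_equal(length(readLines(p2)), 1)
})
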