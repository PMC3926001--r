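counts_row <- function(variant, sample, ref, alt) {
  tibble::tibble(variant_id = variant, sample_id = sample,
                 ref_reads = ref, alt_reads = alt)
}

test_that("variant eligibility applies the inclusive 50% heterozygosity rule", {
  mk_het <- function(n_het, n_total) {
    tibble::tibble(
      variant_id = "v1",
      sample_id = paste0("s", seq_len(n_total)),
      is_het = seq_len(n_total) <= n_het
    )
  }
  counts48 <- counts_row("v1", paste0("s", 1:48), 5, 5)
  expect_equal(eligible_variants(counts48, mk_het(24, 48)), "v1")
  expect_equal(length(eligible_variants(counts48, mk_het(0, 48))), 0)
  counts47 <- counts_row("v1", paste0("s", 1:47), 5, 5)
  expect_equal(length(eligible_variants(counts47, mk_het(23, 47))), 0)
})

test_that("ASM calls follow the strict frequency and inclusive depth rules", {
  counts <- dplyr::bind_rows(
    counts_row("v", "s1", 1, 7),    # freq 0.125 < 0.25 -> alt skew
    counts_row("v", "s2", 2, 6),    # freq exactly 0.25 -> no ASM (strict)
    counts_row("v", "s3", 3, 4),    # depth 7 < 8 -> untested
    counts_row("v", "s4", 7, 1),    # freq 0.875 > 0.75 -> ref skew
    counts_row("v", "s5", 6, 2)     # freq exactly 0.75 -> no ASM (strict)
  )
  asm <- call_asm(counts)
  expect_equal(asm$calls$status,
               c("asm_alt_skew", "no_asm", "untested", "asm_ref_skew",
                 "no_asm"))
  expect_true(is.na(asm$calls$ref_freq[3]))
  expect_equal(asm$variants$fraction_with_asm, 2 / 5)
})

test_that("ASM calling matches a recount oracle and label-swap symmetry", {
  set.seed(19)
  counts <- tibble::tibble(
    variant_id = sample(paste0("v", 1:8), 120, replace = TRUE),
    sample_id = sample(paste0("s", 1:15), 120, replace = TRUE),
    ref_reads = rpois(120, 6),
    alt_reads = rpois(120, 6)
  )
  asm <- call_asm(counts)
  # brute-force recount
  for (i in seq_len(nrow(counts))) {
    d <- counts$ref_reads[i] + counts$alt_reads[i]
    expected <- if (d < 8) "untested" else {
      f <- counts$ref_reads[i] / d
      if (f < 0.25) "asm_alt_skew" else if (f > 0.75) "asm_ref_skew"
      else "no_asm"
    }
    expect_equal(asm$calls$status[i], expected)
  }
  # swapping ref and alt flips skew direction, keeps tested status
  swapped <- call_asm(dplyr::rename(counts, ref_reads = alt_reads,
                                    alt_reads = ref_reads))
  flip <- c(asm_ref_skew = "asm_alt_skew", asm_alt_skew = "asm_ref_skew",
            no_asm = "no_asm", untested = "untested")
  expect_equal(swapped$calls$status, unname(flip[asm$calls$status]))
})

test_that("shared skew in MZ pairs yields near-perfect concordance", {
  cfg <- sim_config(n_asm_variants = 40, asm_skew = 0.95,
                    asm_depth_mean = 40, seed = 33)
  sim <- simulate_cohorts(cfg)
  counts <- simulate_asm_counts(cfg, sim$phenotypes)
  conc <- mz_skew_concordance(call_asm(counts), sim$phenotypes)
  expect_gt(conc$summary$concordant_fraction, 0.95)
})

test_that("without true skew the ASM call rate matches the binomial tail", {
  cfg <- sim_config(n_asm_variants = 150, asm_skew = 0.5, seed = 37)
  sim <- simulate_cohorts(cfg)
  counts <- simulate_asm_counts(cfg, sim$phenotypes)
  asm <- call_asm(counts)
  tested <- dplyr::filter(asm$calls, tested)
  # oracle: P(Bin(d, 0.5)/d < 0.25 or > 0.75) averaged over the observed
  # depth distribution
  tail_prob <- function(d) {
    pbinom(ceiling(0.25 * d) - 1, d, 0.5) +
      pbinom(floor(0.75 * d), d, 0.5, lower.tail = FALSE)
  }
  expected <- mean(tail_prob(tested$depth))
  observed <- mean(tested$status != "no_asm")
  se <- sqrt(expected * (1 - expected) / nrow(tested))
  expect_lt(abs(observed - expected), 4 * se + 0.005)
})

test_that("shallow variants are untested and pairs with one untested twin drop", {
  ph <- toy_pairs_pheno(c(48, 45, 49, 46))
  counts <- dplyr::bind_rows(
    counts_row("v1", "s1", 2, 3),   # depth 5: untested everywhere
    counts_row("v1", "s2", 3, 2),
    counts_row("v2", "s1", 9, 0),   # pair 1 informative and concordant
    counts_row("v2", "s2", 8, 1),
    counts_row("v2", "s3", 9, 1),   # pair 2: co-twin untested
    counts_row("v2", "s4", 3, 1)
  )
  asm <- call_asm(counts)
  expect_true(all(asm$calls$status[asm$calls$variant_id == "v1"] ==
                    "untested"))
  conc <- mz_skew_concordance(asm, ph, min_sample_fraction = 0)
  v2 <- dplyr::filter(conc$variants, variant_id == "v2")
  expect_equal(v2$n_informative, 1)   # the untested pair is excluded
  expect_true(v2$all_concordant)
  expect_false("v1" %in% conc$variants$variant_id)
})

test_that("skew-discordance correlation skips degenerate variants", {
  ph <- toy_pairs_pheno(c(48, 45, 49, 46, 50, 44, 47.5, 45.5))
  # identical ref frequencies in all co-twins -> zero variance -> skipped
  counts <- purrr::map_dfr(paste0("s", 1:8), function(s)
    counts_row("v1", s, 5, 5))
  res <- skew_vs_discordance(call_asm(counts), ph)
  expect_equal(res$status, "zero_variance")
  expect_true(is.na(res$r))
  # too few informative pairs
  counts2 <- dplyr::bind_rows(counts_row("v2", "s1", 9, 3),
                              counts_row("v2", "s2", 4, 6))
  res2 <- skew_vs_discordance(call_asm(counts2), ph)
  expect_equal(res2$status, "too_few_pairs")
})

test_that("null ASM skew-discordance p-values are not enriched for signal", {
  cfg <- sim_config(n_asm_variants = 60, asm_skew = 0.7,
                    asm_depth_mean = 30, seed = 41)
  sim <- simulate_cohorts(cfg)
  counts <- simulate_asm_counts(cfg, sim$phenotypes)
  res <- skew_vs_discordance(call_asm(counts), sim$phenotypes)
  ok <- dplyr::filter(res, status == "ok")
  expect_gt(nrow(ok), 30)
  expect_lt(mean(ok$p < 0.05), 0.15)
})
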