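test_that("the generator is byte-identical under a fixed seed", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 2e5, seed = 1)
  s1 <- simulate_pain_study(cfg)
  s2 <- simulate_pain_study(cfg)
  expect_identical(s1$bins, s2$bins)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$asm_counts, s2$asm_counts)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$t2_bins, s2$t2_bins)
  # a different seed changes the data
  s3 <- simulate_cohorts(sim_config(n_chromosomes = 1, chrom_length = 2e5,
                                    seed = 2))
  expect_false(identical(s1$phenotypes$hpst[1], s3$phenotypes$hpst[1]))
})

test_that("every discovery pair satisfies the discordance constraint", {
  for (seed in c(1, 7, 23)) {
    cfg <- sim_config(n_chromosomes = 1, chrom_length = 1e5, seed = seed)
    sim <- simulate_cohorts(cfg)
    d <- sim$phenotypes |>
      dplyr::filter(cohort == "discovery") |>
      dplyr::group_by(family_id) |>
      dplyr::summarise(d = abs(diff(hpst)), n = dplyr::n())
    expect_true(all(d$n == 2))
    expect_true(all(d$d >= cfg$discordance_min))
    expect_equal(nrow(d), cfg$n_mz_pairs)
  }
})

test_that("a null generator yields slopes centred at zero", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 1e6, n_true_dmrs = 0,
                    dmr_effect = 0, seed = 5)
  sim <- simulate_cohorts(cfg)
  unrel <- dplyr::filter(sim$phenotypes, cohort == "followup")
  res <- fit_unrelated_ewas(sim$bins, unrel, normalize = "none")
  z <- res$beta / res$se
  expect_lt(abs(mean(z)), 3 / sqrt(nrow(res)))
  expect_true(all(sim$truth$true_beta == 0))
})

test_that("impossible configurations are rejected with clear messages", {
  expect_error(sim_config(n_true_dmrs = -1), ">= 0")
  expect_error(sim_config(family_variance_fraction = 1), "family_variance")
  expect_error(sim_config(discordance_min = 0), "discordance_min")
  expect_error(sim_config(n_timepoint2 = 200), "cannot exceed")
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 2000, n_true_dmrs = 50)
  expect_error(simulate_cohorts(cfg), "exceeds the number of bins")
})

test_that("RMQ values are non-negative and the matrix carries both cohorts", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 1e5, seed = 3,
                    baseline_range = c(0, 1))   # truncation actually bites
  sim <- simulate_cohorts(cfg)
  values <- as.matrix(sim$bins[, sim$phenotypes$sample_id])
  expect_true(all(values >= 0))
  expect_true(any(values == 0))
  expect_equal(ncol(values), 100)
})

test_that("fragment sampling follows the methylation profile", {
  cfg <- sim_config(seed = 9)
  profile <- c(rep(1, 1000), rep(0, 4000))
  fr <- simulate_fragments(cfg, profile, n_fragments = 500,
                           fragment_length = 225)
  expect_true(all(fr$fragments$start < 1000))
  expect_equal(fr$total_reads, 500)
  # uniform profile: bin counts consistent with multinomial uniformity
  fr_u <- simulate_fragments(cfg, rep(1, 10225), n_fragments = 10000,
                             fragment_length = 225)
  counts <- table(cut(fr_u$fragments$start, breaks = seq(0, 10000, 1000),
                      include.lowest = TRUE))
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
  # degenerate inputs
  empty <- simulate_fragments(cfg, profile, n_fragments = 0)
  expect_equal(nrow(empty$fragments), 0)
  expect_equal(empty$total_reads, 0)
  expect_false(empty$usable)
  expect_error(simulate_fragments(cfg, rep(0, 5000)), "all-zero")
  expect_error(simulate_fragments(cfg, c(0.5, 2)), "\\[0, 1\\]")
})

test_that("simulated fragments feed quantification end to end", {
  cfg <- sim_config(seed = 10)
  profile <- rep(c(0.1, 0.9), each = 5000)
  fr <- simulate_fragments(cfg, profile, n_fragments = 5000)
  bm <- compute_rmq(fr$fragments, c(chr1 = 10000), scale = 1,
                    total_reads = c(s1 = fr$total_reads))
  # coverage mass concentrates in the methylated half
  lo <- sum(bm$s1[bm$start < 4000])
  hi <- sum(bm$s1[bm$start >= 5000])
  expect_gt(hi, 4 * lo)
})

test_that("ASM generator gives co-twins the same expected skew direction", {
  cfg <- sim_config(n_asm_variants = 30, asm_skew = 0.9,
                    asm_depth_mean = 60, seed = 13)
  sim <- simulate_cohorts(cfg)
  counts <- simulate_asm_counts(cfg, sim$phenotypes)
  ph <- dplyr::filter(sim$phenotypes, cohort == "discovery")
  freq <- counts |>
    dplyr::mutate(f = ref_reads / (ref_reads + alt_reads),
                  family_id = ph$family_id[match(sample_id, ph$sample_id)])
  agree <- freq |>
    dplyr::group_by(variant_id, family_id) |>
    dplyr::summarise(same_side = all(f > 0.5) || all(f < 0.5),
                     .groups = "drop")
  expect_gt(mean(agree$same_side), 0.98)
  # and the mean frequency magnitude matches the configured skew
  expect_equal(mean(abs(freq$f - 0.5) + 0.5), 0.9, tolerance = 0.02)
})

test_that("auxiliary tables have the promised structure", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 3e5, seed = 15)
  sim <- simulate_pain_study(cfg)
  # tissue panel: blood plus at least 7 brain tracks per region
  per_region <- sim$tissue_panel |>
    dplyr::group_by(region_id) |>
    dplyr::summarise(has_blood = any(tissue == "blood"),
                     n_brain = sum(tissue != "blood"))
  expect_true(all(per_region$has_blood))
  expect_true(all(per_region$n_brain >= 7))
  # array betas correlate positively with bin-level RMQ
  mean_rmq <- rowMeans(as.matrix(
    sim$bins[match(sim$array_betas$bin_id, sim$bins$bin_id),
             dplyr::filter(sim$phenotypes, timepoint == 1)$sample_id]
  ))
  expect_gt(cor(mean_rmq, sim$array_betas$beta), 0.5)
  # WBC proportions sum to one per sample
  sums <- sim$cell_counts |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(s = sum(proportion))
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-12)
  # genotyped subsample sizes mirror the study (48 discovery / 47 follow-up)
  geno_samples <- unique(sim$genotypes$sample_id)
  ph1 <- dplyr::filter(sim$phenotypes, timepoint == 1)
  expect_equal(sum(geno_samples %in%
                     ph1$sample_id[ph1$cohort == "discovery"]), 48)
  expect_equal(sum(geno_samples %in%
                     ph1$sample_id[ph1$cohort == "followup"]), 47)
})

test_that("meqtl_beta = 0 leaves scan estimates centred at zero", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 3e5, n_true_dmrs = 0,
                    n_meqtl_bins = 10, meqtl_beta = 0, seed = 17)
  sim <- simulate_pain_study(cfg)
  planted <- dplyr::filter(sim$truth, !is.na(meqtl_snp_id))
  res <- meqtl_scan(sim$bins, sim$genotypes, target_bins = planted$bin_id,
                    normalize = "none")
  hit <- dplyr::inner_join(dplyr::select(planted, bin_id, meqtl_snp_id),
                           res, by = c("bin_id", meqtl_snp_id = "snp_id"))
  expect_true(all(abs(hit$beta / hit$se) < 4))
  expect_lt(abs(mean(hit$beta / hit$se)), 1.5)
})
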