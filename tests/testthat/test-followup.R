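toy_genotypes <- function(snp_id, chrom, pos, samples, dosage) {
  tibble::tibble(snp_id = snp_id, chrom = chrom, pos = pos,
                 sample_id = samples, dosage = dosage)
}

test_that("meQTL scan applies the window and MAF filters", {
  set.seed(61)
  ph <- toy_singletons_pheno(rnorm(40, 47, 2))
  values <- matrix(rnorm(5 * 40, 5), nrow = 5,
                   dimnames = list(NULL, ph$sample_id))
  bm <- toy_bin_matrix(values)       # first bin chr1:0-1000
  g_in <- toy_genotypes("near", "chr1", 1000 + 49000, ph$sample_id,
                        rbinom(40, 2, 0.3))
  g_out <- toy_genotypes("far", "chr1", 1000 + 60000, ph$sample_id,
                         rbinom(40, 2, 0.3))
  g_rare <- toy_genotypes("rare", "chr1", 500L, ph$sample_id,
                          c(1, rep(0, 39)))  # maf 0.0125
  res <- meqtl_scan(bm, dplyr::bind_rows(g_in, g_out, g_rare),
                    target_bins = "chr1:0-1000")
  expect_true("near" %in% res$snp_id)
  expect_false("far" %in% res$snp_id)
  expect_false("rare" %in% res$snp_id)
})

test_that("meQTL regression equals the closed-form OLS oracle", {
  set.seed(62)
  ph <- toy_singletons_pheno(rnorm(30, 47, 2))
  g <- rbinom(30, 2, 0.4)
  y <- 5 + 0.5 * g + rnorm(30)
  values <- matrix(y, 1, 30, dimnames = list(NULL, ph$sample_id))
  bm <- toy_bin_matrix(values)
  gt <- toy_genotypes("s1snp", "chr1", 200L, ph$sample_id, g)
  res <- meqtl_scan(bm, gt, normalize = "none")
  fit <- summary(lm(y ~ g))$coefficients
  expect_equal(res$beta, fit[2, 1], tolerance = 1e-12)
  expect_equal(res$se, fit[2, 2], tolerance = 1e-12)
  expect_equal(res$p, fit[2, 4], tolerance = 1e-12)
  # a bin with no eligible SNP is reported, not dropped
  res2 <- meqtl_scan(bm, dplyr::mutate(gt, pos = 500000L))
  expect_equal(res2$status, "no_eligible_snp")
})

test_that("planted meQTL effects are recovered by the scan", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 5e5, n_true_dmrs = 0,
                    n_meqtl_bins = 8, meqtl_beta = 0.5, seed = 63)
  sim <- simulate_pain_study(cfg)
  unrel_geno <- dplyr::filter(
    sim$genotypes,
    sample_id %in% sim$phenotypes$sample_id[sim$phenotypes$cohort ==
                                              "followup"]
  )
  planted <- dplyr::filter(sim$truth, !is.na(meqtl_snp_id))
  res <- meqtl_scan(sim$bins, unrel_geno, target_bins = planted$bin_id,
                    normalize = "none")
  hit <- dplyr::inner_join(
    dplyr::select(planted, bin_id, meqtl_snp_id),
    res, by = c("bin_id", meqtl_snp_id = "snp_id")
  )
  expect_equal(nrow(hit), 8)
  expect_true(all(abs(hit$beta - cfg$meqtl_beta) < 2.5 * hit$se))
  # the causal SNP outranks the null SNP in the same window almost always
  best <- dplyr::filter(res, best)
  expect_gt(mean(best$snp_id %in% planted$meqtl_snp_id), 0.7)
})

test_that("WBC association flags the confounded bin with Bonferroni control", {
  set.seed(64)
  ph <- toy_pairs_pheno(rnorm(48, 47, 2))
  lymph <- runif(48, 0.2, 0.5)
  cc <- tidyr::expand_grid(sample_id = ph$sample_id,
                           cell_type = c("neutrophils", "lymphocytes")) |>
    dplyr::mutate(proportion = ifelse(cell_type == "lymphocytes",
                                      lymph[match(sample_id, ph$sample_id)],
                                      0.5))
  # constant neutrophil proportion is rejected
  expect_error(
    wbc_association(toy_bin_matrix(
      matrix(rnorm(48 * 2), 2, 48, dimnames = list(NULL, ph$sample_id))
    ), ph, cc),
    "no variance"
  )
  cc$proportion[cc$cell_type == "neutrophils"] <- runif(48, 0.4, 0.7)
  values <- matrix(rnorm(9 * 48, 5), 9, 48,
                   dimnames = list(NULL, ph$sample_id))
  values[3, ] <- 5 + 8 * lymph + rnorm(48, sd = 0.3)  # planted confounding
  bm <- toy_bin_matrix(values)
  res <- wbc_association(bm, ph, cc)
  expect_equal(unique(res$bonferroni_cut), 0.05 / 9)
  expect_equal(round(unique(res$bonferroni_cut), 4), 0.0056)
  sig <- dplyr::filter(res, significant)
  expect_true(all(sig$cell_type == "lymphocytes"))
  expect_equal(sig$bin_id, bm$bin_id[3])
})

test_that("longitudinal classes split at the inclusive 30% boundary", {
  ph <- dplyr::bind_rows(
    toy_singletons_pheno(c(47, 48, 49)),
    dplyr::mutate(toy_singletons_pheno(c(46, 50, 47.5)), timepoint = 2L)
  )
  m1 <- matrix(c(10, 10, 10), 1, 3,
               dimnames = list(NULL, paste0("u", 1:3)))
  m2 <- matrix(c(12.5, 14.5, 13.0), 1, 3,
               dimnames = list(NULL, paste0("u", 1:3)))
  # percent changes 25, 45, 30
  cl <- classify_longitudinal(toy_bin_matrix(m1), toy_bin_matrix(m2), ph,
                              min_variable = 1)
  expect_equal(cl$records$class, c("stable", "variable", "stable"))
  expect_equal(cl$records$percent_change, c(25, 45, 30))
  # identical timepoints: everything stable, no contrast computed
  cl2 <- classify_longitudinal(toy_bin_matrix(m1), toy_bin_matrix(m1), ph)
  expect_true(all(cl2$records$class == "stable"))
  expect_true(all(is.na(cl2$regions$p_contrast)))
  # zero baseline flagged and excluded
  m0 <- m1; m0[1, 1] <- 0
  cl3 <- classify_longitudinal(toy_bin_matrix(m0), toy_bin_matrix(m2), ph,
                               min_variable = 1)
  expect_equal(cl3$records$status[1], "undefined_baseline")
  # class counts invariant to sample order
  ord <- c("u3", "u1", "u2")
  cl4 <- classify_longitudinal(toy_bin_matrix(m1[, ord, drop = FALSE]),
                               toy_bin_matrix(m2[, ord, drop = FALSE]),
                               ph, min_variable = 1)
  expect_equal(sort(table(cl4$records$class)),
               sort(table(cl$records$class)))
})

test_that("planted susceptibility structure is detected in the contrast", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 3e5,
                    frac_variable_regions = 0.4, seed = 65)
  sim <- simulate_pain_study(cfg)
  cl <- classify_longitudinal(sim$bins, sim$t2_bins, sim$phenotypes)
  j <- dplyr::inner_join(cl$regions, sim$truth, by = "bin_id")
  # stable regions never exceed the 30% boundary by construction
  stable_records <- dplyr::inner_join(
    cl$records, dplyr::filter(sim$truth, longitudinal_class == "stable"),
    by = "bin_id"
  )
  expect_true(all(stable_records$percent_change < 30, na.rm = TRUE))
  # flagged regions concentrate in the truly variable class
  flagged <- dplyr::filter(j, susceptibility_consistent)
  expect_gt(nrow(flagged), 0)
  expect_gt(mean(flagged$longitudinal_class == "variable"), 0.9)
})

test_that("tissue sharing thresholds, degenerate cases and scale invariance", {
  mk_panel <- function(brain_levels, blood = 0.5) {
    tibble::tibble(
      region_id = "r1",
      tissue = c("blood", paste0("brain", seq_along(brain_levels))),
      level = c(blood, brain_levels)
    )
  }
  # one brain region within 10% of blood -> shared under any_region
  near <- tissue_sharing(mk_panel(c(0.54, 0.70, 0.70)))
  expect_true(near$regions$shared_any)
  expect_false(near$regions$shared_all)
  # all brain regions off by 0.10 = 20% of blood -> not shared
  off <- tissue_sharing(mk_panel(rep(0.60, 3)))
  expect_false(off$regions$shared_any)
  expect_false(off$regions$shared_all)
  # brain identical to blood: shared under both, correlation 1 across regions
  panel <- purrr::map_dfr(1:5, function(i) {
    tibble::tibble(region_id = paste0("r", i),
                   tissue = c("blood", "brainA", "brainB"),
                   level = rep(0.1 * i + 0.2, 3))
  })
  same <- tissue_sharing(panel)
  expect_true(all(same$regions$shared_any))
  expect_true(all(same$regions$shared_all))
  expect_equal(same$correlation$r, 1)
  # global rescaling leaves the sharing calls unchanged
  scaled <- tissue_sharing(dplyr::mutate(panel, level = level * 7))
  expect_equal(scaled$regions$shared_any, same$regions$shared_any)
  expect_equal(scaled$regions$shared_all, same$regions$shared_all)
})

test_that("array direction validation follows the sign-and-weak-p rule", {
  medip <- tibble::tibble(gene = c("A", "B", "C", "D"),
                          beta_ma = c(-0.2, -0.2, 0.3, 0.1))
  array <- tibble::tibble(
    gene = c("A", "B", "C"),
    effect = c(-0.1, 0.1, 0.05),
    p = c(0.03, 0.001, 0.2)
  )
  res <- platform_direction_validation(medip, array)
  expect_true(res$validated[res$gene == "A"])          # same sign, p < 0.05
  expect_false(res$validated[res$gene == "B"])         # opposite sign
  expect_false(res$validated[res$gene == "C"])         # weak p not reached
  expect_equal(res$status[res$gene == "D"], "not_assessable")
  expect_equal(attr(res, "fraction_validated"), 1 / 3)
})
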