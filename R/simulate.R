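#' Simulation configuration for a discordant-twin methylation study
#'
#' Collects the study-design constants emulated by the generators: a
#' discovery cohort of monozygotic twin pairs selected for within-pair trait
#' discordance, a second cohort of unrelated individuals with an unselected
#' trait distribution, a toy genome tiled into overlapping 1-kb bins, planted
#' differentially methylated regions, cis-meQTL SNPs, shared allele-specific
#' methylation skew within pairs, a second longitudinal timepoint and a
#' blood/brain tissue panel.
#'
#' Trait values are heat-pain suprathresholds in degrees Celsius: pair means
#' are drawn from Normal(`hpst_mean`, `hpst_sd`) with independent
#' within-pair deviations of sd `hpst_within_sd`, and discovery pairs are
#' rejection-sampled until the within-pair difference reaches
#' `discordance_min`. Unrelated individuals are drawn from the same marginal
#' without selection.
#'
#' @param n_mz_pairs Number of discordant MZ pairs in the discovery cohort.
#' @param n_unrelated Number of unrelated individuals in the second cohort.
#' @param n_chromosomes,chrom_length Toy genome shape (default 2 x 2.5 Mb,
#'   about 10,000 overlapping bins).
#' @param n_true_dmrs Number of bins with a planted trait effect.
#' @param dmr_effect Standardized planted slope: methylation sd units per
#'   marginal trait sd.
#' @param family_variance_fraction Fraction of the non-trait methylation
#'   variance shared within a pair, in [0, 1).
#' @param noise_sd Total non-trait methylation sd on the RMQ scale.
#' @param discordance_min Minimum within-pair trait difference (degrees C).
#' @param n_meqtl_bins Number of bins given a cis-meQTL SNP.
#' @param meqtl_beta Methylation shift per alternate allele (RMQ scale).
#' @param n_asm_variants Number of simulated ASM variants.
#' @param asm_skew Generative reference-allele fraction at skewed variants
#'   (0.5 means no real skew).
#' @param n_timepoint2 Number of discovery individuals with a second
#'   timepoint.
#' @param frac_variable_regions Fraction of regions with variable
#'   longitudinal methylation.
#' @param hpst_mean,hpst_sd,hpst_within_sd Trait distribution parameters
#'   (degrees C).
#' @param baseline_range Range of per-bin baseline RMQ means.
#' @param maf Minor allele frequency of simulated SNPs.
#' @param asm_depth_mean Mean of the Poisson read-depth distribution at ASM
#'   variants (spans depths below and above the depth-8 calling threshold).
#' @param seed Integer seed; the same seed yields byte-identical outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_mz_pairs = 25, n_unrelated = 50,
                       n_chromosomes = 2, chrom_length = 2.5e6,
                       n_true_dmrs = 20, dmr_effect = 0.3,
                       family_variance_fraction = 0.4, noise_sd = 1,
                       discordance_min = 2.0,
                       n_meqtl_bins = 5, meqtl_beta = 0.5,
                       n_asm_variants = 50, asm_skew = 0.9,
                       n_timepoint2 = 33, frac_variable_regions = 0.25,
                       hpst_mean = 47, hpst_sd = 1.5, hpst_within_sd = 1.5,
                       baseline_range = c(4, 10), maf = 0.3,
                       asm_depth_mean = 12, seed = 1) {
  cfg <- as.list(environment())
  counts <- c("n_mz_pairs", "n_unrelated", "n_chromosomes", "n_true_dmrs",
              "n_meqtl_bins", "n_asm_variants", "n_timepoint2")
  for (f in counts) {
    if (cfg[[f]] < 0) abort(paste0(f, " must be >= 0"))
  }
  if (cfg$discordance_min <= 0) abort("discordance_min must be > 0")
  if (cfg$family_variance_fraction < 0 || cfg$family_variance_fraction >= 1) {
    abort("family_variance_fraction must lie in [0, 1)")
  }
  for (f in c("frac_variable_regions", "asm_skew", "maf")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste0(f, " must lie in [0, 1]"))
  }
  if (cfg$n_timepoint2 > 2 * cfg$n_mz_pairs) {
    abort("n_timepoint2 cannot exceed the discovery cohort size")
  }
  structure(cfg, class = "sim_config")
}

sim_genome <- function(config) {
  setNames(rep(config$chrom_length, config$n_chromosomes),
           paste0("chr", seq_len(config$n_chromosomes)))
}

# marginal trait sd implied by the two-level trait model
sim_trait_sd <- function(config) {
  sqrt(config$hpst_sd^2 + config$hpst_within_sd^2)
}

#' Simulate the two study cohorts
#'
#' Generates phenotypes for `n_mz_pairs` discordant MZ pairs and
#' `n_unrelated` singletons, and a per-bin RMQ matrix over the toy genome in
#' which every bin follows `intercept + true_beta * (HPST - mean) + family
#' effect + residual`, with the family effect carrying
#' `family_variance_fraction` of the non-trait variance in the twin cohort.
#' `n_true_dmrs` randomly placed bins receive a non-zero `true_beta` (the
#' same raw slope in both cohorts; predominantly negative, mirroring
#' hypermethylation in low-pain individuals); all other bins are null.
#' Negative values are truncated at zero, as RMQ is a coverage sum.
#'
#' @param config A [sim_config()].
#' @return List with `phenotypes` (both cohorts), `bins` (bin matrix with all
#'   samples, `retained` set by [filter_bins()]) and `truth` (per bin
#'   `is_true_dmr`, `true_beta`, `meqtl_snp_id`, `longitudinal_class`).
#' @export
simulate_cohorts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  coords <- tile_bins(sim_genome(config))
  n_bins <- nrow(coords)
  if (config$n_true_dmrs > n_bins) {
    abort(paste0("n_true_dmrs (", config$n_true_dmrs,
                 ") exceeds the number of bins (", n_bins, ")"))
  }
  phenotypes <- sim_phenotypes(config)

  true_beta <- rep(0, n_bins)
  dmr_idx <- sample.int(n_bins, config$n_true_dmrs)
  if (config$n_true_dmrs > 0) {
    slope <- config$dmr_effect * config$noise_sd / sim_trait_sd(config)
    signs <- ifelse(runif(config$n_true_dmrs) < 0.7, -1, 1)
    true_beta[dmr_idx] <- signs * slope
  }
  mu <- runif(n_bins, config$baseline_range[1], config$baseline_range[2])

  disc <- filter(phenotypes, .data$cohort == "discovery")
  unrel <- filter(phenotypes, .data$cohort == "followup")
  fam_sd <- config$noise_sd * sqrt(config$family_variance_fraction)
  res_sd <- config$noise_sd * sqrt(1 - config$family_variance_fraction)

  centred <- function(h) h - config$hpst_mean
  fam_ids <- unique(disc$family_id)
  fam_eff <- matrix(rnorm(n_bins * length(fam_ids), sd = fam_sd),
                    nrow = n_bins)
  colnames(fam_eff) <- fam_ids
  y_disc <- mu + outer(true_beta, centred(disc$hpst)) +
    fam_eff[, disc$family_id] +
    matrix(rnorm(n_bins * nrow(disc), sd = res_sd), nrow = n_bins)
  y_unrel <- mu + outer(true_beta, centred(unrel$hpst)) +
    matrix(rnorm(n_bins * nrow(unrel), sd = config$noise_sd), nrow = n_bins)
  values <- pmax(cbind(y_disc, y_unrel), 0)
  colnames(values) <- c(disc$sample_id, unrel$sample_id)

  bins <- new_bin_matrix(coords, values) |> filter_bins()
  truth <- tibble(
    bin_id = bins$bin_id,
    is_true_dmr = seq_len(n_bins) %in% dmr_idx,
    true_beta = true_beta,
    meqtl_snp_id = NA_character_,
    longitudinal_class = ifelse(runif(n_bins) < config$frac_variable_regions,
                                "variable", "stable")
  )
  list(phenotypes = phenotypes, bins = bins, truth = truth)
}

sim_phenotypes <- function(config) {
  draw_pair <- function() {
    repeat {
      e <- rnorm(2, sd = config$hpst_within_sd)
      if (abs(e[1] - e[2]) >= config$discordance_min) return(e)
    }
  }
  pairs <- purrr::map_dfr(seq_len(config$n_mz_pairs), function(i) {
    centre <- rnorm(1, config$hpst_mean, config$hpst_sd)
    tibble(
      sample_id = paste0("mz", i, c("a", "b")),
      family_id = paste0("fam", i),
      zygosity = "MZ",
      hpst = centre + draw_pair(),
      age = round(runif(1, 40, 80)),
      cohort = "discovery",
      timepoint = 1L
    )
  })
  unrel <- tibble(
    sample_id = paste0("unrel", seq_len(config$n_unrelated)),
    family_id = paste0("ufam", seq_len(config$n_unrelated)),
    zygosity = "singleton",
    hpst = rnorm(config$n_unrelated, config$hpst_mean, sim_trait_sd(config)),
    age = round(runif(config$n_unrelated, 40, 80)),
    cohort = "followup",
    timepoint = 1L
  )
  bind_rows(pairs, unrel)
}

#' Simulate MeDIP fragments from a methylation profile
#'
#' Fragment start positions are sampled with density proportional to the
#' per-base-pair methylation level of `profile`; lengths are fixed at
#' `fragment_length` (fragments are kept inside the profile). The fragment
#' count doubles as the read-count denominator for RMQ.
#'
#' @param config A [sim_config()] (supplies the seed).
#' @param profile Numeric vector of per-bp methylation in [0, 1] along one
#'   chromosome.
#' @param n_fragments Number of fragments to draw; 0 yields an empty set with
#'   denominator 0 flagged unusable.
#' @param fragment_length Fragment length in bp.
#' @param chrom Chromosome name for the output records.
#' @param sample_id Sample label.
#' @return List with `fragments` (tibble `chrom`, `start`, `end`,
#'   `sample_id`), `total_reads` and `usable`.
#' @export
simulate_fragments <- function(config, profile, n_fragments = 10000,
                               fragment_length = 225, chrom = "chr1",
                               sample_id = "s1") {
  stopifnot(inherits(config, "sim_config"))
  if (any(profile < 0 | profile > 1)) abort("profile values must lie in [0, 1]")
  set.seed(config$seed)
  if (n_fragments == 0) {
    return(list(
      fragments = tibble(chrom = character(0), start = integer(0),
                         end = integer(0), sample_id = character(0)),
      total_reads = 0, usable = FALSE
    ))
  }
  if (all(profile == 0)) abort("all-zero methylation profile: nothing to sample")
  max_start <- length(profile) - fragment_length
  if (max_start < 1) abort("profile shorter than the fragment length")
  weights <- profile[seq_len(max_start)]
  if (all(weights == 0)) abort("no admissible fragment start with mass")
  starts <- sample.int(max_start, n_fragments, replace = TRUE,
                       prob = weights) - 1L
  list(
    fragments = tibble(
      chrom = chrom,
      start = starts,
      end = starts + as.integer(fragment_length),
      sample_id = sample_id
    ),
    total_reads = n_fragments,
    usable = TRUE
  )
}

#' Simulate allele-specific methylation read counts
#'
#' Each variant is assigned, per family, a skew direction shared by both
#' co-twins (allele-specific methylation tracks the haplotype, which MZ
#' co-twins share): the generative reference-read fraction is `asm_skew` or
#' `1 - asm_skew` with equal probability. Unrelated samples draw their own
#' direction. Depths are Poisson with mean `asm_depth_mean`, spanning values
#' below and above the depth-8 calling threshold.
#'
#' @param config A [sim_config()].
#' @param phenotypes Phenotype table from [simulate_cohorts()] (discovery
#'   samples are used).
#' @return Allele-count tibble: `variant_id`, `chrom`, `pos`, `sample_id`,
#'   `ref_reads`, `alt_reads`.
#' @export
simulate_asm_counts <- function(config, phenotypes) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ph <- filter(phenotypes, .data$cohort == "discovery")
  if (config$n_asm_variants == 0 || nrow(ph) == 0) {
    return(tibble(variant_id = character(0), chrom = character(0),
                  pos = integer(0), sample_id = character(0),
                  ref_reads = integer(0), alt_reads = integer(0)))
  }
  genome <- sim_genome(config)
  variants <- tibble(
    variant_id = paste0("var", seq_len(config$n_asm_variants)),
    chrom = sample(names(genome), config$n_asm_variants, replace = TRUE),
    pos = sample.int(config$chrom_length, config$n_asm_variants)
  )
  fams <- unique(ph$family_id)
  purrr::map_dfr(seq_len(nrow(variants)), function(v) {
    dir_ref <- setNames(runif(length(fams)) < 0.5, fams)
    p_ref <- ifelse(dir_ref[ph$family_id], config$asm_skew,
                    1 - config$asm_skew)
    depth <- rpois(nrow(ph), config$asm_depth_mean)
    ref <- rbinom(nrow(ph), depth, p_ref)
    tibble(
      variant_id = variants$variant_id[v],
      chrom = variants$chrom[v],
      pos = variants$pos[v],
      sample_id = ph$sample_id,
      ref_reads = ref,
      alt_reads = depth - ref
    )
  })
}

#' Simulate the auxiliary follow-up inputs
#'
#' Generates (i) genotypes with `n_meqtl_bins` cis-meQTL SNPs that shift the
#' carrying bin's methylation by `meqtl_beta` per alternate allele (plus an
#' equal number of null SNPs in the same windows), (ii) white-blood-cell
#' subtype proportions for the discovery samples, (iii) a blood plus
#' seven-brain-region tissue panel, (iv) a second-timepoint bin matrix whose
#' stable regions change by construction less than 30% and whose variable
#' regions change more in "labile" individuals who also drift more in the
#' trait, and (v) an array-style per-CpG beta table positively correlated
#' with bin RMQ.
#'
#' @param config A [sim_config()].
#' @param phenotypes,bins,truth Output of [simulate_cohorts()].
#' @return List: `genotypes`, `cell_counts`, `tissue_panel`, `t2_bins`,
#'   `phenotypes_t2` (trait rows at timepoint 2), `array_betas`, plus the
#'   meQTL-shifted `bins` and updated `truth`.
#' @export
simulate_auxiliary <- function(config, phenotypes, bins, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  samples <- bm_samples(bins)
  values <- bm_values(bins)

  # --- cis-meQTL SNPs ---------------------------------------------------
  eligible <- which(!truth$is_true_dmr & bins$retained)
  if (config$n_meqtl_bins > length(eligible)) {
    abort("n_meqtl_bins exceeds the number of eligible bins")
  }
  meqtl_idx <- sample(eligible, config$n_meqtl_bins)
  # genotypes are emitted for the typically genotyped subsample (2 discovery
  # and 3 follow-up individuals lack genotypes), though the latent dosages
  # shift methylation in everyone
  disc_ids <- filter(phenotypes, .data$cohort == "discovery")$sample_id
  unrel_ids <- filter(phenotypes, .data$cohort == "followup")$sample_id
  genotyped <- c(utils::head(disc_ids, max(0, length(disc_ids) - 2)),
                 utils::head(unrel_ids, max(0, length(unrel_ids) - 3)))
  genotyped <- intersect(genotyped, samples)
  genotypes <- tibble()
  for (k in seq_along(meqtl_idx)) {
    i <- meqtl_idx[k]
    sid <- paste0("snp", k)
    dosage <- setNames(rbinom(length(samples), 2, config$maf), samples)
    values[i, ] <- pmax(values[i, ] + config$meqtl_beta * dosage, 0)
    truth$meqtl_snp_id[i] <- sid
    genotypes <- bind_rows(
      genotypes,
      tibble(snp_id = sid, chrom = bins$chrom[i],
             pos = bins$start[i] + sample.int(1000, 1) - 1L,
             sample_id = genotyped, dosage = unname(dosage[genotyped])),
      tibble(snp_id = paste0(sid, "_null"), chrom = bins$chrom[i],
             pos = pmax(bins$start[i] - sample.int(40000, 1), 0L),
             sample_id = genotyped,
             dosage = rbinom(length(genotyped), 2, config$maf))
    )
  }
  bins_shifted <- new_bin_matrix(bins[, c("chrom", "start", "end")], values,
                                 retained = bins$retained)

  # --- WBC proportions --------------------------------------------------
  disc <- filter(phenotypes, .data$cohort == "discovery")
  wbc_means <- c(neutrophils = 0.55, lymphocytes = 0.33,
                 monocytes = 0.08, eosinophils = 0.04)
  raw <- purrr::map_dfr(disc$sample_id, function(s) {
    g <- stats::rgamma(4, shape = wbc_means * 60)
    tibble(sample_id = s, cell_type = names(wbc_means),
           proportion = g / sum(g))
  })
  cell_counts <- raw

  # --- blood/brain tissue panel ----------------------------------------
  brain_tissues <- c("inferior frontal gyrus", "middle frontal gyrus",
                     "left frontal gyrus", "entorhinal cortex",
                     "superior temporal gyrus", "visual cortex",
                     "cerebellum")
  n_regions <- 100
  region_id <- paste0("region", seq_len(n_regions))
  blood <- runif(n_regions, 0.2, 0.8)
  shared <- runif(n_regions) < 0.7
  tissue_panel <- purrr::map_dfr(seq_len(n_regions), function(i) {
    brain <- if (shared[i]) {
      blood[i] * (1 + rnorm(length(brain_tissues), sd = 0.03))
    } else {
      blood[i] * (1 + sample(c(-1, 1), 1) * runif(length(brain_tissues),
                                                  0.3, 0.8))
    }
    tibble(region_id = region_id[i],
           tissue = c("blood", brain_tissues),
           level = pmax(c(blood[i], brain), 0.01))
  })

  # --- longitudinal second timepoint -----------------------------------
  t2_samples <- disc$sample_id[seq_len(config$n_timepoint2)]
  labile <- setNames(runif(length(t2_samples)) < 0.4, t2_samples)
  m1 <- values[, t2_samples, drop = FALSE]
  cls <- truth$longitudinal_class
  factors <- matrix(1, nrow = nrow(m1), ncol = ncol(m1))
  for (j in seq_along(t2_samples)) {
    small <- 1 + runif(nrow(m1), -0.25, 0.25)
    big <- 1 + sample(c(-1, 1), nrow(m1), replace = TRUE) *
      runif(nrow(m1), 0.35, 0.95)
    factors[, j] <- ifelse(cls == "stable", small,
                           ifelse(labile[j], big, small))
  }
  t2_bins <- new_bin_matrix(bins[, c("chrom", "start", "end")],
                            m1 * factors, retained = bins$retained)
  ph1 <- filter(disc, .data$sample_id %in% t2_samples)
  phenotypes_t2 <- ph1 |>
    mutate(
      timepoint = 2L,
      hpst = .data$hpst + rnorm(nrow(ph1), sd = 0.5) +
        ifelse(labile[.data$sample_id], 1, 0) *
          sample(c(-1.5, 1.5), nrow(ph1), replace = TRUE),
      age = .data$age + 2
    )

  # --- array-style betas ------------------------------------------------
  cpg_idx <- sample(which(bins$retained), min(500, sum(bins$retained)))
  mean_rmq <- rowMeans(values[cpg_idx, , drop = FALSE])
  beta <- (rank(mean_rmq) / (length(cpg_idx) + 1)) +
    rnorm(length(cpg_idx), sd = 0.1)
  array_betas <- tibble(
    cpg_id = paste0("cg", seq_along(cpg_idx)),
    chrom = bins$chrom[cpg_idx],
    pos = as.integer(bins$start[cpg_idx] + 500L),
    bin_id = bins$bin_id[cpg_idx],
    beta = pmin(pmax(beta, 0), 1)
  )

  list(genotypes = genotypes, cell_counts = cell_counts,
       tissue_panel = tissue_panel, t2_bins = t2_bins,
       phenotypes_t2 = phenotypes_t2, array_betas = array_betas,
       bins = bins_shifted, truth = truth, labile = labile)
}

#' Simulate a complete study
#'
#' Convenience wrapper running [simulate_cohorts()], [simulate_asm_counts()]
#' and [simulate_auxiliary()] under one seed.
#'
#' @param config A [sim_config()].
#' @return Named list with all generated tables; `bins` carries the meQTL
#'   shifts and `phenotypes` both timepoints.
#' @export
simulate_pain_study <- function(config = sim_config()) {
  base <- simulate_cohorts(config)
  asm <- simulate_asm_counts(config, base$phenotypes)
  aux <- simulate_auxiliary(config, base$phenotypes, base$bins, base$truth)
  list(
    phenotypes = bind_rows(base$phenotypes, aux$phenotypes_t2),
    bins = aux$bins,
    truth = aux$truth,
    asm_counts = asm,
    genotypes = aux$genotypes,
    cell_counts = aux$cell_counts,
    tissue_panel = aux$tissue_panel,
    t2_bins = aux$t2_bins,
    array_betas = aux$array_betas,
    config = config
  )
}
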