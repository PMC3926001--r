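#' Cis-meQTL scan at target bins
#'
#' For each target bin and every SNP with minor allele frequency at least
#' `maf_min` whose position lies within `window` bp of either bin edge
#' (i.e. in `[start - window, end + window)`), fits an additive linear model
#' of inverse-normal methylation on allele dosage and reports the nominal
#' two-sided p. The best (smallest-p) SNP per bin is flagged.
#'
#' @param bins Bin-matrix tibble.
#' @param genotypes Long genotype table: `snp_id`, `chrom`, `pos`,
#'   `sample_id`, `dosage` (0-2).
#' @param target_bins Character vector of `bin_id`s to scan (default: all
#'   retained bins).
#' @param window Cis window in bp on either side of the bin.
#' @param maf_min Minimum minor allele frequency (computed from the dosages
#'   of the analysed samples).
#' @param normalize Methylation transform (see [normalize_scores()]).
#' @return Tibble: per (bin, SNP) `beta`, `se`, `p`, `maf`, `best`; bins with
#'   no eligible SNP appear once with `snp_id = NA` and `status =
#'   "no_eligible_snp"`.
#' @export
meqtl_scan <- function(bins, genotypes, target_bins = NULL,
                       window = 50000, maf_min = 0.05,
                       normalize = "inverse_normal") {
  need <- c("snp_id", "chrom", "pos", "sample_id", "dosage")
  if (!all(need %in% names(genotypes))) {
    abort("genotype table needs snp_id, chrom, pos, sample_id, dosage")
  }
  target_bins <- target_bins %||% bins$bin_id[bins$retained]
  tb <- bins[bins$bin_id %in% target_bins, , drop = FALSE]
  if (nrow(tb) == 0) abort("no target bins found in the matrix")
  samples <- intersect(bm_samples(bins), unique(genotypes$sample_id))
  if (length(samples) < 3) abort("too few samples shared with genotypes")
  values <- bm_values(tb, samples)
  if (normalize != "none") {
    values <- t(apply(values, 1, normalize_scores, method = normalize))
  }
  snp_meta <- genotypes |>
    distinct(.data$snp_id, .data$chrom, .data$pos)
  dosage_wide <- genotypes |>
    filter(.data$sample_id %in% samples) |>
    select("snp_id", "sample_id", "dosage") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "dosage")

  purrr::map_dfr(seq_len(nrow(tb)), function(i) {
    cand <- snp_meta |>
      filter(.data$chrom == tb$chrom[i],
             .data$pos >= tb$start[i] - window,
             .data$pos < tb$end[i] + window)
    y <- values[i, ]
    res <- purrr::map_dfr(cand$snp_id, function(sid) {
      g <- unlist(dosage_wide[dosage_wide$snp_id == sid, samples])
      m <- mean(g) / 2
      maf <- min(m, 1 - m)
      if (is.na(maf) || maf < maf_min) return(tibble())
      fit <- simple_ols(y, g)
      tibble(snp_id = sid, maf = maf, beta = fit$beta, se = fit$se,
             p = fit$p, n = length(g), status = "ok")
    })
    if (nrow(res) == 0) {
      return(tibble(bin_id = tb$bin_id[i], snp_id = NA_character_,
                    maf = NA_real_, beta = NA_real_, se = NA_real_,
                    p = NA_real_, n = length(samples),
                    status = "no_eligible_snp", best = FALSE))
    }
    res |>
      mutate(bin_id = tb$bin_id[i], .before = 1) |>
      mutate(best = .data$p == min(.data$p))
  })
}

# closed-form simple linear regression y ~ x with a t test on the slope
simple_ols <- function(y, x) {
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3 || sd(x) == 0) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_))
  }
  xc <- x - mean(x)
  beta <- sum(xc * y) / sum(xc^2)
  resid <- y - mean(y) - beta * xc
  se <- sqrt(sum(resid^2) / (n - 2) / sum(xc^2))
  list(beta = beta, se = se, p = 2 * pt(-abs(beta / se), df = n - 2))
}

#' White-blood-cell composition association at target bins
#'
#' Regresses normalized RMQ on each WBC subtype proportion as a fixed effect
#' with family as a random intercept (the same pair mixed model as the twin
#' EWAS), at a set of target bins. Significance is flagged at the
#' Bonferroni-corrected nominal level `alpha / n_target_bins`.
#'
#' @param bins Bin-matrix tibble.
#' @param phenotypes Phenotype table with `family_id`.
#' @param cell_counts Long table: `sample_id`, `cell_type`, `proportion` in
#'   [0, 1]. Samples without counts are dropped with a warning.
#' @param target_bins `bin_id`s to test (default: all retained).
#' @param alpha Family-wise level for the Bonferroni flag.
#' @param normalize Methylation transform.
#' @return Tibble: per (bin, cell type) `beta`, `se`, `p`, `bonferroni_cut`,
#'   `significant`.
#' @export
wbc_association <- function(bins, phenotypes, cell_counts,
                            target_bins = NULL, alpha = 0.05,
                            normalize = "inverse_normal") {
  need <- c("sample_id", "cell_type", "proportion")
  if (!all(need %in% names(cell_counts))) {
    abort("cell_counts needs sample_id, cell_type, proportion")
  }
  if (any(cell_counts$proportion < 0 | cell_counts$proportion > 1)) {
    abort("cell proportions must lie in [0, 1]")
  }
  target_bins <- target_bins %||% bins$bin_id[bins$retained]
  tb <- bins[bins$bin_id %in% target_bins, , drop = FALSE]
  cut <- alpha / nrow(tb)
  types <- unique(cell_counts$cell_type)
  wide <- cell_counts |>
    tidyr::pivot_wider(names_from = "cell_type", values_from = "proportion")
  ph <- phenotypes |>
    filter(.data$sample_id %in% bm_samples(bins)) |>
    inner_join(wide, by = "sample_id")
  missing <- setdiff(intersect(phenotypes$sample_id, bm_samples(bins)),
                     ph$sample_id)
  if (length(missing) > 0) {
    warn(paste0("dropping sample(s) without cell counts: ",
                paste(missing, collapse = ", ")))
  }
  purrr::map_dfr(types, function(ct) {
    if (sd(ph[[ct]]) == 0) {
      abort(paste0("cell proportion '", ct, "' has no variance"))
    }
    fit <- fit_twin_ewas(tb, ph, predictor = ct, normalize = normalize,
                         method = "exact")
    fit |>
      as_tibble() |>
      select("bin_id", "beta", "se", "p", "status") |>
      mutate(cell_type = ct, bonferroni_cut = cut,
             significant = !is.na(.data$p) & .data$p <= cut)
  })
}

#' Longitudinal stability classification and susceptibility contrast
#'
#' Per (region, sample), the percent change in methylation between the two
#' timepoints is `|m_t2 - m_t1| / m_t1 * 100` (records with `m_t1 = 0` are
#' flagged and excluded). Samples are classed `stable` (change 0-30%,
#' boundary inclusive) or `variable` (change above 30%). Per region, when the
#' variable class holds at least `min_variable` samples, the absolute trait
#' changes of the two classes are compared by a Wilcoxon rank-sum test, and
#' regions where the variable-class median exceeds the stable-class median
#' are flagged susceptibility-consistent.
#'
#' @param t1,t2 Bin matrices at the two timepoints (shared samples are used).
#' @param phenotypes Phenotype table with `timepoint` (1 and 2) and the trait,
#'   one row per sample per timepoint.
#' @param target_bins `bin_id`s to classify (default: retained bins of `t1`).
#' @param stable_max Upper bound (inclusive) of the stable percent-change
#'   class.
#' @param min_variable Minimum variable-class size for the contrast.
#' @param trait Trait column.
#' @return List with `records` (per region x sample) and `regions` (per
#'   region class counts, `p_contrast`, `susceptibility_consistent`).
#' @export
classify_longitudinal <- function(t1, t2, phenotypes, target_bins = NULL,
                                  stable_max = 30, min_variable = 6,
                                  trait = "hpst") {
  check_phenotypes(phenotypes, c("sample_id", trait, "timepoint"))
  samples <- intersect(bm_samples(t1), bm_samples(t2))
  if (length(samples) == 0) abort("no samples present at both timepoints")
  target_bins <- target_bins %||% t1$bin_id[t1$retained]
  b1 <- t1[t1$bin_id %in% target_bins, , drop = FALSE]
  b2 <- t2[match(b1$bin_id, t2$bin_id), , drop = FALSE]
  if (anyNA(b2$bin_id)) abort("timepoint-2 matrix lacks some target bins")
  m1 <- bm_values(b1, samples)
  m2 <- bm_values(b2, samples)
  ph1 <- filter(phenotypes, .data$timepoint == 1, .data$sample_id %in% samples)
  ph2 <- filter(phenotypes, .data$timepoint == 2, .data$sample_id %in% samples)
  d_trait <- setNames(
    ph2[[trait]][match(samples, ph2$sample_id)] -
      ph1[[trait]][match(samples, ph1$sample_id)],
    samples
  )
  records <- tidyr::expand_grid(bin_id = b1$bin_id, sample_id = samples) |>
    mutate(
      m_t1 = as.vector(m1[cbind(match(.data$bin_id, b1$bin_id),
                                match(.data$sample_id, samples))]),
      m_t2 = as.vector(m2[cbind(match(.data$bin_id, b1$bin_id),
                                match(.data$sample_id, samples))]),
      percent_change = ifelse(.data$m_t1 > 0,
                              abs(.data$m_t2 - .data$m_t1) / .data$m_t1 * 100,
                              NA_real_),
      class = dplyr::case_when(
        is.na(percent_change) ~ NA_character_,
        percent_change <= stable_max ~ "stable",
        TRUE ~ "variable"
      ),
      delta_trait = d_trait[.data$sample_id],
      status = ifelse(is.na(.data$percent_change), "undefined_baseline", "ok")
    )
  regions <- records |>
    filter(.data$status == "ok") |>
    group_by(.data$bin_id) |>
    summarise(
      n_stable = sum(.data$class == "stable"),
      n_variable = sum(.data$class == "variable"),
      median_abs_dtrait_stable = stats::median(
        abs(.data$delta_trait[.data$class == "stable"])),
      median_abs_dtrait_variable = stats::median(
        abs(.data$delta_trait[.data$class == "variable"])),
      p_contrast = if (.data$n_variable[1] >= min_variable &&
                       .data$n_stable[1] >= 1) {
        wilcox.test(abs(.data$delta_trait[.data$class == "variable"]),
                    abs(.data$delta_trait[.data$class == "stable"]),
                    exact = FALSE)$p.value
      } else NA_real_,
      .groups = "drop"
    ) |>
    mutate(
      susceptibility_consistent =
        !is.na(.data$p_contrast) &
        .data$median_abs_dtrait_variable > .data$median_abs_dtrait_stable
    )
  list(records = records, regions = regions)
}

#' Blood-brain tissue sharing of methylation levels
#'
#' A region's methylation is tissue-shared under the `any_region` criterion
#' when at least one brain tissue differs from blood by less than 10% of the
#' blood level, and under the stricter `all_regions` criterion when the mean
#' absolute difference over all brain tissues is below 10% of the blood
#' level. Also reports the Pearson correlation (with its two-sided t-based p)
#' between blood and mean-brain methylation across regions. Sharing calls are
#' invariant to a global rescaling of the panel.
#'
#' @param panel Long tissue panel: `region_id`, `tissue`, `level`; must
#'   include a `blood` tissue for every region.
#' @param target_regions Optional subset of `region_id`s.
#' @param tolerance Sharing tolerance as a fraction of the blood level.
#' @return List with `regions` (per region `shared_any`, `shared_all`,
#'   `status`) and `correlation` (tibble `r`, `p`, `n`).
#' @export
tissue_sharing <- function(panel, target_regions = NULL, tolerance = 0.10) {
  need <- c("region_id", "tissue", "level")
  if (!all(need %in% names(panel))) {
    abort("panel needs region_id, tissue, level")
  }
  if (!is.null(target_regions)) {
    panel <- filter(panel, .data$region_id %in% target_regions)
  }
  blood <- panel |>
    filter(.data$tissue == "blood") |>
    select("region_id", blood = "level")
  if (!all(unique(panel$region_id) %in% blood$region_id)) {
    abort("blood level missing for some regions")
  }
  brain <- panel |>
    filter(.data$tissue != "blood") |>
    inner_join(blood, by = "region_id")
  regions <- brain |>
    group_by(.data$region_id) |>
    summarise(
      blood = .data$blood[1],
      mean_brain = mean(.data$level),
      shared_any = any(abs(.data$level - .data$blood) <
                         tolerance * .data$blood),
      shared_all = mean(abs(.data$level - .data$blood)) <
        tolerance * .data$blood[1],
      .groups = "drop"
    ) |>
    mutate(
      status = ifelse(.data$blood > 0, "ok", "undefined_zero_blood"),
      shared_any = ifelse(.data$status == "ok", .data$shared_any, NA),
      shared_all = ifelse(.data$status == "ok", .data$shared_all, NA)
    )
  ok <- filter(regions, .data$status == "ok")
  r <- if (nrow(ok) > 2) cor(ok$blood, ok$mean_brain) else NA_real_
  correlation <- tibble(
    r = r,
    p = if (!is.na(r) && abs(r) < 1) cor_pvalue(r, nrow(ok)) else NA_real_,
    n = nrow(ok)
  )
  if (!is.na(r) && abs(r) == 1) correlation$p <- 0
  list(regions = regions, correlation = correlation)
}

#' Cross-platform direction validation of DMRs
#'
#' A gene-assigned DMR validates on an array platform when at least one array
#' CpG assigned to the same gene has an effect of the same sign and a nominal
#' p below `weak_p`. Genes without any assigned CpG are reported as not
#' assessable.
#'
#' @param medip_results Table with `gene` and `beta_ma` (one row per DMR).
#' @param array_results Table with `gene`, `effect`, `p` (one row per CpG).
#' @param weak_p Nominal array p-value regarded as weak evidence.
#' @return Tibble: per gene `validated`, `n_cpgs`, `status`, plus a
#'   `fraction_validated` attribute over assessable genes.
#' @export
platform_direction_validation <- function(medip_results, array_results,
                                          weak_p = 0.05) {
  stopifnot(all(c("gene", "beta_ma") %in% names(medip_results)),
            all(c("gene", "effect", "p") %in% names(array_results)))
  out <- medip_results |>
    as_tibble() |>
    mutate(.row = row_number()) |>
    left_join(array_results, by = "gene",
              relationship = "many-to-many") |>
    group_by(.data$.row, .data$gene, .data$beta_ma) |>
    summarise(
      n_cpgs = sum(!is.na(.data$effect)),
      validated = any(!is.na(.data$effect) &
                        sign(.data$effect) == sign(.data$beta_ma) &
                        .data$p < weak_p),
      .groups = "drop"
    ) |>
    mutate(status = ifelse(.data$n_cpgs == 0, "not_assessable", "ok"),
           validated = ifelse(.data$n_cpgs == 0, NA, .data$validated)) |>
    select(-".row")
  attr(out, "fraction_validated") <-
    mean(out$validated[out$status == "ok"])
  out
}
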