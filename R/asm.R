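#' Variants eligible for allele-specific methylation analysis
#'
#' Retains variants heterozygous in at least 50% of samples (boundary
#' inclusive: 24 of 48 qualifies). Imputation-quality filtering is accepted
#' upstream as precomputed heterozygosity flags.
#'
#' @param counts Allele-count table: `variant_id`, `sample_id`, `ref_reads`,
#'   `alt_reads`.
#' @param het_calls Tibble with `variant_id`, `sample_id`, `is_het` (logical).
#' @param min_het_fraction Minimum fraction of samples heterozygous.
#' @return Character vector of retained variant ids.
#' @export
eligible_variants <- function(counts, het_calls, min_het_fraction = 0.5) {
  stopifnot(all(c("variant_id", "sample_id", "is_het") %in% names(het_calls)))
  samples <- unique(counts$sample_id)
  het_calls |>
    filter(.data$sample_id %in% samples) |>
    group_by(.data$variant_id) |>
    summarise(frac = sum(.data$is_het) / length(samples), .groups = "drop") |>
    filter(.data$frac >= min_het_fraction) |>
    dplyr::pull("variant_id")
}

#' Call allele-specific methylation from allelic read counts
#'
#' A (variant, sample) observation is tested when its total MeDIP read depth
#' is at least `min_depth`; among tested observations the reference-allele
#' frequency `ref/(ref+alt)` indicates ASM when it is strictly below `low`
#' (skew toward the alternate allele) or strictly above `high` (skew toward
#' the reference allele). The per-variant summary records the fraction of
#' samples with an ASM call among samples with counts at the variant.
#'
#' @param counts Allele-count table: `variant_id`, `sample_id`, `ref_reads`,
#'   `alt_reads` (extra metadata columns are carried through).
#' @param min_depth Minimum read depth for a testable observation (inclusive).
#' @param low,high Reference-frequency bounds for an ASM call (strict
#'   inequalities).
#' @return An object of class `medip_asm`: list with `calls` (per
#'   observation: `ref_freq`, `status` in \{asm_ref_skew, asm_alt_skew,
#'   no_asm, untested\}) and `variants` (per variant: `n_samples`,
#'   `n_tested`, `n_asm`, `fraction_with_asm`).
#' @export
call_asm <- function(counts, min_depth = 8, low = 0.25, high = 0.75) {
  stopifnot(low < high)
  need <- c("variant_id", "sample_id", "ref_reads", "alt_reads")
  if (!all(need %in% names(counts))) {
    abort("counts table needs variant_id, sample_id, ref_reads, alt_reads")
  }
  if (any(counts$ref_reads < 0 | counts$alt_reads < 0)) {
    abort("negative read counts")
  }
  calls <- counts |>
    mutate(
      depth = .data$ref_reads + .data$alt_reads,
      tested = .data$depth >= min_depth,
      ref_freq = ifelse(.data$tested, .data$ref_reads / .data$depth, NA_real_),
      status = dplyr::case_when(
        !tested ~ "untested",
        ref_freq < low ~ "asm_alt_skew",
        ref_freq > high ~ "asm_ref_skew",
        TRUE ~ "no_asm"
      )
    )
  variants <- calls |>
    group_by(.data$variant_id) |>
    summarise(
      n_samples = n(),
      n_tested = sum(.data$tested),
      n_asm = sum(.data$status %in% c("asm_ref_skew", "asm_alt_skew")),
      fraction_with_asm = .data$n_asm / .data$n_samples,
      .groups = "drop"
    )
  structure(list(calls = calls, variants = variants,
                 min_depth = min_depth, low = low, high = high),
            class = "medip_asm")
}

#' @export
print.medip_asm <- function(x, ...) {
  cat("ASM call set:", nrow(x$variants), "variants,",
      nrow(x$calls), "observations\n")
  cat("  tested (depth >=", x$min_depth, "):", sum(x$calls$tested), "\n")
  cat("  ASM calls (ref freq <", x$low, "or >", x$high, "):",
      sum(x$calls$status %in% c("asm_ref_skew", "asm_alt_skew")), "\n")
  invisible(x)
}

#' Within-pair concordance of ASM skew in MZ twins
#'
#' A pair is informative at a variant when both co-twins are tested and both
#' carry an ASM call; it is concordant when the skew direction matches.
#' The summary is the fraction of variants - among those with ASM in at least
#' `min_sample_fraction` of samples and at least one informative pair - for
#' which every informative pair is concordant.
#'
#' @param asm A `medip_asm` object from [call_asm()].
#' @param phenotypes Phenotype table defining the MZ pairs.
#' @param min_sample_fraction Minimum per-variant ASM sample fraction for the
#'   summary denominator.
#' @return List with `variants` (per-variant `n_informative`, `n_concordant`,
#'   `all_concordant`) and `summary` (the concordance fraction).
#' @export
mz_skew_concordance <- function(asm, phenotypes, min_sample_fraction = 0.5) {
  pr <- twin_pairs(phenotypes, unique(asm$calls$sample_id))
  if (nrow(pr) == 0) abort("no MZ pairs with ASM data")
  calls <- asm$calls |>
    select("variant_id", "sample_id", "status")
  c1 <- pr |>
    inner_join(calls, by = c(sample_1 = "sample_id"),
               relationship = "many-to-many") |>
    rename(status_1 = "status")
  both <- c1 |>
    inner_join(calls, by = c("variant_id", sample_2 = "sample_id")) |>
    rename(status_2 = "status")
  is_asm <- function(s) s %in% c("asm_ref_skew", "asm_alt_skew")
  per_variant <- both |>
    filter(.data$status_1 != "untested", .data$status_2 != "untested",
           is_asm(.data$status_1), is_asm(.data$status_2)) |>
    group_by(.data$variant_id) |>
    summarise(
      n_informative = n(),
      n_concordant = sum(.data$status_1 == .data$status_2),
      all_concordant = .data$n_concordant == .data$n_informative,
      .groups = "drop"
    )
  eligible <- asm$variants |>
    filter(.data$fraction_with_asm >= min_sample_fraction) |>
    inner_join(per_variant, by = "variant_id")
  summary <- tibble(
    n_variants = nrow(eligible),
    concordant_fraction = if (nrow(eligible) > 0) {
      mean(eligible$all_concordant)
    } else NA_real_
  )
  list(variants = per_variant, eligible = eligible, summary = summary)
}

#' Within-pair ASM skew versus trait discordance
#'
#' For each variant with at least `min_pairs` pairs in which both co-twins
#' are tested, correlates the absolute within-pair difference in reference
#' allele frequency with the absolute within-pair trait difference across
#' pairs. Nominal two-sided p-values are reported without multiplicity
#' adjustment.
#'
#' @inheritParams mz_skew_concordance
#' @param trait Trait column (default `"hpst"`).
#' @param min_pairs Minimum informative pairs per variant.
#' @return Tibble: per variant `n_pairs`, `r`, `p`, `status`.
#' @export
skew_vs_discordance <- function(asm, phenotypes, trait = "hpst",
                                min_pairs = 3) {
  check_phenotypes(phenotypes, c("sample_id", "family_id", trait))
  pr <- twin_pairs(phenotypes, unique(asm$calls$sample_id))
  ph <- as_tibble(phenotypes)
  d_trait <- abs(ph[[trait]][match(pr$sample_1, ph$sample_id)] -
                   ph[[trait]][match(pr$sample_2, ph$sample_id)])
  pr$abs_d_trait <- d_trait
  freq <- asm$calls |>
    filter(.data$tested) |>
    select("variant_id", "sample_id", "ref_freq")
  both <- pr |>
    inner_join(freq, by = c(sample_1 = "sample_id"),
               relationship = "many-to-many") |>
    rename(freq_1 = "ref_freq") |>
    inner_join(freq, by = c("variant_id", sample_2 = "sample_id")) |>
    rename(freq_2 = "ref_freq") |>
    mutate(abs_d_freq = abs(.data$freq_1 - .data$freq_2))
  both |>
    group_by(.data$variant_id) |>
    summarise(
      n_pairs = n(),
      r = if (n() >= min_pairs && sd(.data$abs_d_freq) > 0 &&
              sd(.data$abs_d_trait) > 0) {
        cor(.data$abs_d_freq, .data$abs_d_trait)
      } else NA_real_,
      .groups = "drop"
    ) |>
    mutate(
      p = ifelse(is.na(.data$r), NA_real_, cor_pvalue(.data$r, .data$n_pairs)),
      status = dplyr::case_when(
        n_pairs < min_pairs ~ "too_few_pairs",
        is.na(r) ~ "zero_variance",
        TRUE ~ "ok"
      )
    )
}
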