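#' Run the two-cohort EWAS / permutation / meta-analysis pipeline
#'
#' Orchestrates the full association stage on a bin matrix containing both
#' cohorts: per-bin normalization (done once; permutations reuse it), the
#' twin mixed-model EWAS, the unrelated-cohort linear EWAS, family-preserving
#' (twin) and free (unrelated) phenotype permutations, per-replicate
#' fixed-effect meta-analysis with heterogeneity filtering applied
#' identically in observed data and permutations, permutation FDR estimation
#' for each cohort and for the meta-analysis, and the ranked DMR report.
#'
#' @param bins Bin-matrix tibble holding both cohorts' samples.
#' @param phenotypes Phenotype table (`cohort` column distinguishes
#'   `"discovery"` twins from `"followup"` unrelateds; timepoint-1 rows are
#'   used).
#' @param n_replicates Number of permutation replicates.
#' @param alpha Target FDR level.
#' @param covariates Fixed-effect covariates for both EWAS models.
#' @param n_pcs Methylation principal components for the unrelated model.
#' @param normalize Per-bin score transform.
#' @param het_p,het_i2 Heterogeneity filter thresholds.
#' @param seed Master seed; all stage seeds derive from it.
#' @return An object of class `medip_run`: list with `assoc_twin`,
#'   `assoc_unrelated`, `meta`, `fdr_twin`, `fdr_unrelated`, `fdr_ma`,
#'   `dmrs` and a `manifest` recording seeds, thresholds and a configuration
#'   hash. Reruns with identical inputs and seed are identical.
#' @export
run_pain_pipeline <- function(bins, phenotypes, n_replicates = 20,
                              alpha = 0.05, covariates = character(),
                              n_pcs = 0, normalize = "inverse_normal",
                              het_p = 0.01, het_i2 = 0.8, seed = 1) {
  check_phenotypes(phenotypes, c("sample_id", "family_id", "hpst", "cohort"))
  report <- validate_inputs(bins = bins, phenotypes = phenotypes,
                            action = "abort")
  ph <- filter(phenotypes, .data$timepoint == 1 |
                 !("timepoint" %in% names(phenotypes)))
  ph_twin <- filter(ph, .data$cohort == "discovery")
  ph_unrel <- filter(ph, .data$cohort == "followup")
  norm_bins <- normalize_bin_matrix(bins, method = normalize)

  assoc_twin <- fit_twin_ewas(norm_bins, ph_twin, covariates = covariates,
                              normalize = "none")
  assoc_unrel <- fit_unrelated_ewas(norm_bins, ph_unrel,
                                    covariates = covariates,
                                    normalize = "none", n_pcs = n_pcs)
  meta <- meta_analyse(assoc_twin, assoc_unrel, het_p = het_p,
                       het_i2 = het_i2)

  perm_twin_ph <- permute_phenotypes(ph_twin, n_replicates,
                                     scheme = "family_preserving",
                                     seed = seed)
  perm_unrel_ph <- permute_phenotypes(ph_unrel, n_replicates,
                                      scheme = "free", seed = seed + 1L)
  perm_twin <- purrr::map(perm_twin_ph, function(p) {
    fit_twin_ewas(norm_bins, p, covariates = covariates, normalize = "none")
  })
  perm_unrel <- purrr::map(perm_unrel_ph, function(p) {
    fit_unrelated_ewas(norm_bins, p, covariates = covariates,
                       normalize = "none", n_pcs = n_pcs)
  })

  fdr_twin <- estimate_fdr(assoc_twin, perm_twin, alpha = alpha)
  fdr_unrel <- estimate_fdr(assoc_unrel, perm_unrel, alpha = alpha)
  fdr_ma <- meta_permutation(meta, perm_twin, perm_unrel, alpha = alpha,
                             het_p = het_p, het_i2 = het_i2)
  dmrs <- rank_dmrs(meta, fdr_ma)

  manifest <- list(
    seed = seed,
    n_replicates = n_replicates,
    alpha = alpha,
    normalize = normalize,
    covariates = covariates,
    n_pcs = n_pcs,
    het_p = het_p,
    het_i2 = het_i2,
    n_bins_retained = sum(bins$retained),
    n_twin = nrow(ph_twin),
    n_unrelated = nrow(ph_unrel),
    threshold_twin = fdr_twin$threshold,
    threshold_unrelated = fdr_unrel$threshold,
    threshold_ma = fdr_ma$threshold,
    config_hash = rlang::hash(list(dim(bins), phenotypes, n_replicates,
                                   alpha, covariates, n_pcs, normalize,
                                   het_p, het_i2, seed)),
    package_version = as.character(utils::packageVersion("medipewas"))
  )
  structure(
    list(assoc_twin = assoc_twin, assoc_unrelated = assoc_unrel,
         meta = meta, fdr_twin = fdr_twin, fdr_unrelated = fdr_unrel,
         fdr_ma = fdr_ma, dmrs = dmrs, manifest = manifest,
         diagnostics = report),
    class = "medip_run"
  )
}

#' @export
print.medip_run <- function(x, ...) {
  m <- x$manifest
  cat("MeDIP-seq pain EWAS pipeline run\n")
  cat("  cohorts: ", m$n_twin, " twins + ", m$n_unrelated,
      " unrelated; ", m$n_bins_retained, " retained bins\n", sep = "")
  cat("  permutation replicates:", m$n_replicates, "\n")
  thr <- m$threshold_ma
  cat("  MA FDR ", m$alpha * 100, "% threshold: ",
      if (is.na(thr)) "undefined (no hits)" else format(thr, digits = 4),
      "\n", sep = "")
  cat("  significant DMRs:", sum(x$dmrs$significant), "\n")
  invisible(x)
}

#' Validate pipeline inputs
#'
#' Checks coordinate sanity (start < end, monotone bin tiling), sample
#' overlap between tables, and family integrity (MZ families of exactly 2
#' within a cohort/timepoint). Issues are classed `warning` or `fatal`.
#'
#' @param bins Optional bin matrix.
#' @param phenotypes Optional phenotype table.
#' @param fragments Optional fragment/BED table.
#' @param action `"report"` returns the diagnostics tibble; `"abort"` raises
#'   an error when any fatal issue is present.
#' @return Tibble with columns `level` ("warning"/"fatal") and `message`.
#' @export
validate_inputs <- function(bins = NULL, phenotypes = NULL, fragments = NULL,
                            action = c("report", "abort")) {
  action <- match.arg(action)
  issues <- list()
  note <- function(level, msg) {
    issues[[length(issues) + 1]] <<- tibble(level = level, message = msg)
  }
  if (!is.null(fragments)) {
    if (any(fragments$start >= fragments$end)) {
      note("fatal", "fragment/BED record with start >= end")
    }
    if (any(fragments$start < 0)) {
      note("fatal", "fragment record with negative start")
    }
  }
  if (!is.null(bins)) {
    if (any(bins$start >= bins$end)) {
      note("fatal", "bin with start >= end")
    }
    tiling <- bins |>
      group_by(.data$chrom) |>
      summarise(mono = !is.unsorted(.data$start, strictly = TRUE),
                .groups = "drop")
    if (any(!tiling$mono)) {
      note("fatal", "bin starts not strictly increasing within a chromosome")
    }
  }
  if (!is.null(phenotypes)) {
    ph <- phenotypes
    if ("timepoint" %in% names(ph)) ph <- filter(ph, .data$timepoint == 1)
    if ("zygosity" %in% names(ph)) {
      bad <- ph |>
        filter(.data$zygosity == "MZ") |>
        group_by(.data$family_id) |>
        summarise(size = n(), .groups = "drop") |>
        filter(.data$size != 2)
      if (nrow(bad) > 0) {
        note("fatal", paste0("MZ family of size != 2: ",
                             paste(bad$family_id, collapse = ", ")))
      }
    }
    if (!is.null(bins)) {
      absent <- setdiff(ph$sample_id, bm_samples(bins))
      if (length(absent) > 0) {
        note("warning", paste0("phenotype sample(s) absent from matrix: ",
                               paste(absent, collapse = ", ")))
      }
    }
  }
  report <- if (length(issues) == 0) {
    tibble(level = character(0), message = character(0))
  } else {
    bind_rows(issues)
  }
  if (action == "abort" && any(report$level == "fatal")) {
    abort(paste0("fatal input problems:\n  ",
                 paste(report$message[report$level == "fatal"],
                       collapse = "\n  ")))
  }
  report
}
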