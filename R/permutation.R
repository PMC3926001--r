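#' Permute phenotypes for null-distribution replicates
#'
#' Builds `n_replicates` phenotype tables with the trait column shuffled.
#' Under the `family_preserving` scheme the two co-twin values of each pair
#' move as a unit: value-pairs are shuffled across the pair families and the
#' within-pair assignment of the two values is randomized, so the within-pair
#' difference structure of the original trait is preserved under the null.
#' Singleton samples have their values shuffled freely among themselves.
#' Under `free`, values are shuffled across all samples.
#'
#' @param phenotypes Phenotype table with `sample_id`, `family_id` and the
#'   trait column.
#' @param n_replicates Number of permuted tables.
#' @param scheme `"family_preserving"` or `"free"`. Requesting
#'   family-preserving permutation on singleton-only data falls back to free
#'   with a warning.
#' @param trait Trait column to permute (default `"hpst"`).
#' @param seed Optional integer seed for reproducible replicates.
#' @return A list of `n_replicates` phenotype tibbles.
#' @export
permute_phenotypes <- function(phenotypes, n_replicates = 20,
                               scheme = c("family_preserving", "free"),
                               trait = "hpst", seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n_replicates >= 1)
  check_phenotypes(phenotypes, c("sample_id", "family_id", trait))
  if (!is.null(seed)) set.seed(seed)
  fam <- split(seq_len(nrow(phenotypes)), phenotypes$family_id)
  sizes <- lengths(fam)
  if (any(sizes > 2)) abort("families larger than 2 are not supported")
  pairs <- fam[sizes == 2]
  singles <- unlist(fam[sizes == 1], use.names = FALSE)
  if (scheme == "family_preserving" && length(pairs) == 0) {
    warn("no twin pairs present; falling back to free permutation")
    scheme <- "free"
  }
  purrr::map(seq_len(n_replicates), function(r) {
    out <- phenotypes
    y <- out[[trait]]
    if (scheme == "free") {
      out[[trait]] <- sample(y)
      return(out)
    }
    # shuffle value-pairs across families, randomize within-pair order
    vals <- lapply(pairs, function(idx) y[idx])
    vals <- vals[sample(length(vals))]
    for (i in seq_along(pairs)) {
      v <- vals[[i]]
      if (sample(c(TRUE, FALSE), 1)) v <- rev(v)
      y[pairs[[i]]] <- v
    }
    if (length(singles) > 1) {
      y[singles] <- y[sample(singles)]
    }
    out[[trait]] <- y
    out
  })
}

#' Permutation-based genome-wide FDR estimation
#'
#' At each threshold t on the grid of distinct observed p-values, the FDR
#' estimate is the pooled count of permutation p-values at or below t divided
#' by the number of replicates, divided by the count of observed p-values at
#' or below t (0/0 defined as 0). The raw ratio need not be monotone, so it
#' is monotonized by a running minimum toward smaller p; the reported
#' threshold at level `alpha` is the largest p with monotonized FDR <= alpha.
#'
#' @param observed Observed association table (any table with a `p` column)
#'   or a numeric vector of p-values.
#' @param permuted List of permutation-replicate tables (or p-value vectors)
#'   over the same bin universe.
#' @param alpha Target FDR level for the reported threshold.
#' @return An object of class `medip_fdr`: list with `grid` (tibble of
#'   `p`, `observed_hits`, `perm_hits_pooled`, `fdr_raw`, `fdr`),
#'   `threshold`, `alpha`, `n_replicates`.
#' @export
estimate_fdr <- function(observed, permuted, alpha = 0.05) {
  obs_p <- extract_p(observed)
  if (length(permuted) == 0) abort("permuted replicate list is empty")
  perm_p <- sort(unlist(lapply(permuted, extract_p), use.names = FALSE))
  R <- length(permuted)
  grid <- sort(unique(obs_p))
  if (length(grid) == 0) abort("no observed p-values")
  obs_sorted <- sort(obs_p)
  obs_hits <- findInterval(grid, obs_sorted)
  perm_hits <- findInterval(grid, perm_p)
  fdr_raw <- ifelse(obs_hits == 0 & perm_hits == 0, 0,
                    (perm_hits / R) / obs_hits)
  fdr <- rev(cummin(rev(fdr_raw)))
  ok <- which(fdr <= alpha)
  threshold <- if (length(ok) == 0) NA_real_ else grid[max(ok)]
  structure(
    list(
      grid = tibble(p = grid, observed_hits = obs_hits,
                    perm_hits_pooled = perm_hits,
                    fdr_raw = fdr_raw, fdr = fdr),
      threshold = threshold,
      alpha = alpha,
      n_replicates = R
    ),
    class = "medip_fdr"
  )
}

extract_p <- function(x) {
  p <- if (is.numeric(x)) x else {
    if (!"p" %in% names(x) && "p_ma" %in% names(x)) x$p_ma else x$p
  }
  if (is.null(p)) abort("no p-value column found")
  p[is.finite(p)]
}

#' @export
print.medip_fdr <- function(x, ...) {
  cat("Permutation FDR estimate (", x$n_replicates, " replicates)\n", sep = "")
  if (is.na(x$threshold)) {
    cat("  no p-value threshold attains FDR <=", x$alpha, "\n")
  } else {
    cat("  FDR ", x$alpha * 100, "% threshold: p <= ",
        format(x$threshold, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Meta-analysis permutation FDR
#'
#' Each pair of twin-cohort and unrelated-cohort permutation replicates
#' (replicate i with replicate i) is combined with the same fixed-effect
#' meta-analysis and heterogeneity filter as the observed data, and
#' [estimate_fdr()] is applied to the heterogeneity-filtered meta-analysis
#' p-values on both sides.
#'
#' @param observed_meta Observed `medip_meta` table.
#' @param twin_perms,unrelated_perms Equal-length lists of per-replicate
#'   association tables for the two cohorts.
#' @inheritParams meta_analyse
#' @param alpha Target FDR level.
#' @return A `medip_fdr` object.
#' @export
meta_permutation <- function(observed_meta, twin_perms, unrelated_perms,
                             alpha = 0.05, model = "fixed",
                             het_p = 0.01, het_i2 = 0.8) {
  if (length(twin_perms) != length(unrelated_perms)) {
    abort("unpaired replicate counts between cohorts")
  }
  perm_p <- purrr::map2(twin_perms, unrelated_perms, function(a, b) {
    m <- meta_analyse(a, b, model = model, het_p = het_p, het_i2 = het_i2)
    m$p_ma[m$het_pass]
  })
  estimate_fdr(observed_meta$p_ma[observed_meta$het_pass], perm_p,
               alpha = alpha)
}
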