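#' Per-bin intraclass correlation within MZ pairs
#'
#' One-way random-effects ANOVA ICC(1,1) for pairs of size 2:
#' `(MSB - MSW) / (MSB + MSW)`, where MSB/MSW are the between- and
#' within-pair mean squares of the bin's scores. Values lie in [-1, 1];
#' bins with zero total variance are flagged undefined.
#'
#' @param bins Bin-matrix tibble; only retained bins are analysed.
#' @param phenotypes Phenotype table; samples in families of exactly 2 are
#'   used as pairs.
#' @return Tibble of class `medip_icc`: `bin_id`, coordinates, `icc`, `msb`,
#'   `msw`, `status`.
#' @export
per_bin_icc <- function(bins, phenotypes) {
  pr <- twin_pairs(phenotypes, bm_samples(bins))
  if (nrow(pr) < 2) abort("per-bin ICC needs at least 2 complete pairs")
  sub <- bins[bins$retained, , drop = FALSE]
  y1 <- bm_values(sub, pr$sample_1)
  y2 <- bm_values(sub, pr$sample_2)
  k <- nrow(pr)
  m <- (y1 + y2) / 2
  grand <- rowMeans(m)
  msb <- unname(2 * rowSums((m - grand)^2) / (k - 1))
  msw <- unname(rowSums((y1 - y2)^2 / 2) / k)
  tot <- msb + msw
  out <- dplyr::bind_cols(
    sub[, c("bin_id", "chrom", "start", "end")],
    tibble(
      icc = ifelse(tot > 0, (msb - msw) / tot, NA_real_),
      msb = msb, msw = msw,
      status = ifelse(tot > 0, "ok", "zero_variance")
    )
  )
  class(out) <- c("medip_icc", class(out))
  out
}

# one row per complete family of 2 among the given samples; ordered so that
# sample_1 is the higher-trait co-twin when a trait is given
twin_pairs <- function(phenotypes, samples, trait = NULL) {
  check_phenotypes(phenotypes, "family_id")
  ph <- filter(phenotypes, .data$sample_id %in% samples)
  fam <- ph |>
    group_by(.data$family_id) |>
    filter(n() == 2) |>
    ungroup()
  # a missing co-twin in a twin family is worth a log line; singleton
  # families are expected and pass silently
  dropped <- setdiff(unique(ph$family_id), unique(fam$family_id))
  if ("zygosity" %in% names(ph)) {
    mz_fams <- unique(ph$family_id[ph$zygosity == "MZ"])
    dropped <- intersect(dropped, mz_fams)
  }
  if (length(dropped) > 0) {
    warn(paste0("dropping incomplete twin families: ",
                paste(dropped, collapse = ", ")))
  }
  if (!is.null(trait)) {
    fam <- fam |>
      group_by(.data$family_id) |>
      arrange(desc(.data[[trait]]), .by_group = TRUE) |>
      ungroup()
  }
  fam |>
    group_by(.data$family_id) |>
    summarise(sample_1 = .data$sample_id[1], sample_2 = .data$sample_id[2],
              .groups = "drop")
}

#' Within-pair difference association
#'
#' For every retained bin, computes the within-pair difference in methylation
#' between co-twins (higher-HPST twin minus lower-HPST twin, so the trait
#' difference is non-negative and the sign of the correlation is
#' interpretable; correlations are invariant to this ordering convention) and
#' correlates it with the within-pair trait difference across pairs
#' (Pearson and Spearman). Additionally fits an OLS of the normalized
#' methylation difference on the trait difference with the pair-mean of each
#' covariate as an adjustment term.
#'
#' @inheritParams per_bin_icc
#' @param covariates Phenotype columns whose pair means enter the regression
#'   (default `"age"`; use `character()` for none).
#' @param trait Trait column (default `"hpst"`).
#' @param normalize Transform applied to the per-bin difference vector before
#'   the regression (correlations always use raw differences).
#' @return Tibble of class `medip_withinpair`: per bin `pearson_r`,
#'   `spearman_r`, `beta`, `se`, `p`, `n_pairs`, `status`.
#' @export
within_pair_association <- function(bins, phenotypes,
                                    covariates = "age", trait = "hpst",
                                    normalize = "inverse_normal") {
  check_phenotypes(phenotypes, c("sample_id", "family_id", trait, covariates))
  pr <- twin_pairs(phenotypes, bm_samples(bins), trait = trait)
  if (nrow(pr) < 3) abort("within-pair association needs at least 3 pairs")
  ph <- as_tibble(phenotypes)
  idx <- function(ids) match(ids, ph$sample_id)
  d_trait <- ph[[trait]][idx(pr$sample_1)] - ph[[trait]][idx(pr$sample_2)]
  sub <- bins[bins$retained, , drop = FALSE]
  d_rmq <- bm_values(sub, pr$sample_1) - bm_values(sub, pr$sample_2)

  if (sd(d_trait) == 0) {
    out <- dplyr::bind_cols(
      sub[, c("bin_id", "chrom", "start", "end")],
      tibble(pearson_r = NA_real_, spearman_r = NA_real_,
             beta = NA_real_, se = NA_real_, p = NA_real_,
             n_pairs = nrow(pr), status = "constant_trait_difference")
    )
    class(out) <- c("medip_withinpair", class(out))
    return(out)
  }

  pearson <- row_cor(d_rmq, d_trait)
  spearman <- row_cor(t(apply(d_rmq, 1, rank)), rank(d_trait))

  X <- cbind(`(Intercept)` = 1, d_trait = d_trait)
  for (cv in covariates) {
    pm <- (ph[[cv]][idx(pr$sample_1)] + ph[[cv]][idx(pr$sample_2)]) / 2
    if (sd(pm) > 0) X <- cbind(X, setNames(data.frame(pm), cv)[[1]])
  }
  Y <- t(d_rmq)
  if (normalize != "none") Y <- apply(Y, 2, normalize_scores, method = normalize)
  n <- nrow(X); p <- ncol(X)
  A <- crossprod(X); Bm <- crossprod(X, Y)
  coef <- solve(A, Bm)
  rss <- pmax(colSums(Y^2) - colSums(Bm * coef), 0)
  sigma2 <- rss / (n - p)
  Ainv <- solve(A)
  beta <- coef[2, ]
  se <- sqrt(sigma2 * Ainv[2, 2])
  out <- dplyr::bind_cols(
    sub[, c("bin_id", "chrom", "start", "end")],
    tibble(
      pearson_r = pearson, spearman_r = spearman,
      beta = unname(beta), se = unname(se),
      p = ifelse(se > 0, 2 * pt(-abs(beta / se), df = n - p), NA_real_),
      n_pairs = nrow(pr),
      status = ifelse(se > 0, "ok", "degenerate")
    )
  )
  class(out) <- c("medip_withinpair", class(out))
  out
}

# Pearson correlation of every matrix row with one vector
row_cor <- function(m, v) {
  mc <- m - rowMeans(m)
  vc <- v - mean(v)
  denom <- sqrt(rowSums(mc^2) * sum(vc^2))
  unname(ifelse(denom > 0, as.vector(mc %*% vc) / denom, NA_real_))
}

#' MZ versus unrelated-pair genome-wide correlation contrast
#'
#' Computes, per MZ pair, the correlation of the two co-twins' methylation
#' profiles across retained bins, and compares the distribution with the
#' correlations of randomly drawn pairs of samples from different families.
#' With a shared family component of methylation variance, the MZ
#' distribution shifts upward relative to the unrelated one.
#'
#' @inheritParams per_bin_icc
#' @param n_random Number of random non-co-twin pairings drawn.
#' @param seed Optional seed for the random pairings.
#' @return An object of class `medip_pair_contrast`: list with `pairs`
#'   (tibble of `pair_type`, `sample_1`, `sample_2`, `r`) and `summary`
#'   (medians and a two-sided Wilcoxon rank-sum p).
#' @export
pairtype_correlation_contrast <- function(bins, phenotypes, n_random = 100,
                                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  samples <- intersect(phenotypes$sample_id, bm_samples(bins))
  pr <- twin_pairs(phenotypes, samples)
  if (nrow(pr) == 0) abort("no complete pairs present")
  sub <- bins[bins$retained, , drop = FALSE]
  values <- bm_values(sub, samples)
  fam <- setNames(phenotypes$family_id, phenotypes$sample_id)[samples]
  mz <- purrr::map_dbl(seq_len(nrow(pr)), function(i) {
    cor(values[, pr$sample_1[i]], values[, pr$sample_2[i]])
  })
  rnd <- purrr::map_dfr(seq_len(n_random), function(i) {
    repeat {
      s <- sample(samples, 2)
      if (fam[s[1]] != fam[s[2]]) break
    }
    tibble(sample_1 = s[1], sample_2 = s[2],
           r = cor(values[, s[1]], values[, s[2]]))
  })
  pairs <- tibble(pair_type = "MZ", sample_1 = pr$sample_1,
                  sample_2 = pr$sample_2, r = mz)
  if (nrow(rnd) > 0) {
    pairs <- bind_rows(pairs, mutate(rnd, pair_type = "unrelated",
                                     .before = 1))
  }
  structure(
    list(
      pairs = pairs,
      summary = tibble(
        median_mz = stats::median(mz),
        median_unrelated = if (nrow(rnd)) stats::median(rnd$r) else NA_real_,
        p_wilcox = if (nrow(rnd)) wilcox.test(mz, rnd$r)$p.value else NA_real_
      )
    ),
    class = "medip_pair_contrast"
  )
}
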