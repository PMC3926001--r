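#' Inverse-variance fixed-effect meta-analysis
#'
#' Combines per-study slope estimates with weights `w_i = 1/se_i^2`:
#' `beta_ma = sum(w*beta)/sum(w)`, `se_ma = 1/sqrt(sum(w))`, and a two-sided
#' normal p on `beta_ma/se_ma`.
#'
#' @param betas Numeric vector of study slopes.
#' @param ses Positive standard errors, same length.
#' @return A one-row tibble: `beta_ma`, `se_ma`, `p_ma`, `n_studies`.
#' @export
#' @examples
#' fixed_effect(c(-0.20, -0.27), c(0.04, 0.09))
fixed_effect <- function(betas, ses) {
  check_meta_input(betas, ses, min_k = 1)
  w <- 1 / ses^2
  beta_ma <- sum(w * betas) / sum(w)
  se_ma <- 1 / sqrt(sum(w))
  tibble(beta_ma = beta_ma, se_ma = se_ma,
         p_ma = 2 * pnorm(-abs(beta_ma / se_ma)),
         n_studies = length(betas))
}

#' Cochran's Q and I-squared heterogeneity statistics
#'
#' `Q = sum(w_i * (beta_i - beta_ma)^2)` against chi-square with k-1 df, and
#' `I2 = max(0, (Q - (k - 1)) / Q)`, the fraction of the total variability in
#' effect estimates attributable to between-study heterogeneity.
#'
#' @inheritParams fixed_effect
#' @return A one-row tibble: `q`, `p_q`, `i2`.
#' @export
heterogeneity <- function(betas, ses) {
  check_meta_input(betas, ses, min_k = 2)
  w <- 1 / ses^2
  beta_ma <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - beta_ma)^2)
  k <- length(betas)
  tibble(q = q,
         p_q = pchisq(q, df = k - 1, lower.tail = FALSE),
         i2 = if (q > 0) max(0, (q - (k - 1)) / q) else 0)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Between-study variance `tau2 = max(0, (Q - (k-1)) / (sum(w) -
#' sum(w^2)/sum(w)))` with fixed-effect weights w, then an inverse-variance
#' combination with weights `1/(se^2 + tau2)`. When `Q <= k - 1`, `tau2 = 0`
#' and the result equals [fixed_effect()] exactly.
#'
#' @inheritParams fixed_effect
#' @return A one-row tibble: `beta_ma`, `se_ma`, `p_ma`, `tau2`, `n_studies`.
#' @export
random_effects <- function(betas, ses) {
  check_meta_input(betas, ses, min_k = 2)
  w <- 1 / ses^2
  het <- heterogeneity(betas, ses)
  k <- length(betas)
  tau2 <- max(0, (het$q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (ses^2 + tau2)
  beta_ma <- sum(wr * betas) / sum(wr)
  se_ma <- 1 / sqrt(sum(wr))
  tibble(beta_ma = beta_ma, se_ma = se_ma,
         p_ma = 2 * pnorm(-abs(beta_ma / se_ma)),
         tau2 = tau2, n_studies = k)
}

check_meta_input <- function(betas, ses, min_k) {
  if (length(betas) == 0) abort("empty meta-analysis input")
  if (length(betas) != length(ses)) abort("betas and ses differ in length")
  if (any(!is.finite(ses)) || any(ses <= 0)) abort("all ses must be positive")
  if (length(betas) < min_k) {
    abort(paste0("at least ", min_k, " studies required"))
  }
  invisible(TRUE)
}

#' Per-bin two-cohort meta-analysis with heterogeneity filtering
#'
#' Joins two per-bin association tables on `bin_id` and combines them by
#' inverse-variance meta-analysis (fixed-effect by default, DerSimonian-Laird
#' random-effects optionally), computing Cochran's Q and I-squared per bin.
#' A bin passes the heterogeneity filter (`het_pass`) when `p_q > het_p` and
#' `i2 < het_i2`, i.e. no strong evidence that the two cohorts disagree.
#' Bins flagged non-`ok` in either cohort are dropped.
#'
#' @param assoc1,assoc2 `medip_ewas` tibbles (or any tables with `bin_id`,
#'   `beta`, `se`, `p`).
#' @param model `"fixed"` or `"random"`.
#' @param het_p Cochran's Q p-value below which a bin fails the filter.
#' @param het_i2 I-squared at or above which a bin fails the filter.
#' @return A tibble of class `medip_meta` with per-cohort estimates,
#'   `beta_ma`, `se_ma`, `p_ma`, `q`, `p_q`, `i2`, `het_pass`.
#' @export
meta_analyse <- function(assoc1, assoc2, model = c("fixed", "random"),
                         het_p = 0.01, het_i2 = 0.8) {
  model <- match.arg(model)
  a1 <- meta_side(assoc1, "_1")
  a2 <- meta_side(assoc2, "_2")
  j <- inner_join(a1, a2, by = c("bin_id", "chrom", "start", "end"))
  if (nrow(j) == 0) abort("cohorts share no bins")
  w1 <- 1 / j$se_1^2
  w2 <- 1 / j$se_2^2
  sw <- w1 + w2
  beta_fe <- (w1 * j$beta_1 + w2 * j$beta_2) / sw
  q <- w1 * (j$beta_1 - beta_fe)^2 + w2 * (j$beta_2 - beta_fe)^2
  p_q <- pchisq(q, df = 1, lower.tail = FALSE)
  i2 <- ifelse(q > 0, pmax(0, (q - 1) / q), 0)
  if (model == "fixed") {
    beta_ma <- beta_fe
    se_ma <- 1 / sqrt(sw)
  } else {
    tau2 <- pmax(0, (q - 1) / (sw - (w1^2 + w2^2) / sw))
    wr1 <- 1 / (j$se_1^2 + tau2)
    wr2 <- 1 / (j$se_2^2 + tau2)
    beta_ma <- (wr1 * j$beta_1 + wr2 * j$beta_2) / (wr1 + wr2)
    se_ma <- 1 / sqrt(wr1 + wr2)
  }
  out <- j |>
    mutate(
      beta_ma = beta_ma, se_ma = se_ma,
      p_ma = 2 * pnorm(-abs(beta_ma / se_ma)),
      q = q, p_q = p_q, i2 = i2,
      n_studies = 2L, model = model,
      het_pass = p_q > het_p & i2 < het_i2
    )
  class(out) <- c("medip_meta", class(out))
  out
}

meta_side <- function(assoc, suffix) {
  need <- c("bin_id", "beta", "se", "p")
  if (!all(need %in% names(assoc))) {
    abort("association table needs columns bin_id, beta, se, p")
  }
  if ("status" %in% names(assoc)) {
    assoc <- filter(assoc, .data$status == "ok")
  }
  keep <- intersect(c("bin_id", "chrom", "start", "end", "beta", "se", "p"),
                    names(assoc))
  out <- as_tibble(assoc)[, keep]
  names(out)[names(out) %in% c("beta", "se", "p")] <-
    paste0(c("beta", "se", "p"), suffix)
  out
}

#' Rank meta-analysis DMRs against a permutation FDR threshold
#'
#' Heterogeneity-filtered bins are sorted by meta-analysis p-value and flagged
#' significant when `p_ma` is at or below the permutation threshold at the
#' requested FDR level. Optionally, runs of overlapping significant bins are
#' collapsed into regions (off by default: overlapping half-shifted bins are
#' then reported separately).
#'
#' @param meta A `medip_meta` tibble.
#' @param fdr A `medip_fdr` object from [estimate_fdr()] or
#'   [meta_permutation()], or `NULL` to rank without significance calls.
#' @param collapse Collapse overlapping significant bins into regions.
#' @return Ranked tibble with `rank` and `significant`; collapsed regions (if
#'   requested) carry the member `bin_id`s in `region_bins`.
#' @export
rank_dmrs <- function(meta, fdr = NULL, collapse = FALSE) {
  out <- meta |>
    filter(.data$het_pass) |>
    arrange(.data$p_ma) |>
    mutate(rank = row_number())
  thr <- if (!is.null(fdr)) fdr$threshold else NA_real_
  out$significant <- if (is.na(thr)) FALSE else out$p_ma <= thr
  if (!collapse) return(out)
  sig <- out |>
    filter(.data$significant) |>
    arrange(.data$chrom, .data$start)
  if (nrow(sig) == 0) return(out)
  grp <- cumsum(c(1, diff_regions(sig)))
  regions <- sig |>
    mutate(.grp = grp) |>
    group_by(.data$chrom, .data$.grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              p_ma = min(.data$p_ma), beta_ma = .data$beta_ma[1],
              region_bins = paste(.data$bin_id, collapse = ","),
              .groups = "drop") |>
    select(-".grp")
  attr(out, "regions") <- regions
  out
}

# 1 where a sorted significant bin starts a new (non-overlapping) region
diff_regions <- function(sig) {
  if (nrow(sig) < 2) return(integer(0))
  new_chrom <- sig$chrom[-1] != sig$chrom[-nrow(sig)]
  gap <- sig$start[-1] >= sig$end[-nrow(sig)]
  as.integer(new_chrom | gap)
}
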