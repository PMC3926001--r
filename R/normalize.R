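#' Normalize a vector of per-bin scores
#'
#' `inverse_normal` maps average ranks r to `qnorm((r - 0.5) / n)`, the
#' rank-based inverse-normal transform that sends any continuous score
#' distribution to N(0,1); `zscore` centres and scales by the sample standard
#' deviation; `none` returns the input. Coverage-derived RMQ scores are
#' right-skewed, so the rank-based transform is the default throughout the
#' package.
#'
#' @param values Numeric vector (at least 3 finite values).
#' @param method One of `"inverse_normal"`, `"zscore"`, `"none"`.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' normalize_scores(c(1, 2, 3))
normalize_scores <- function(values,
                             method = c("inverse_normal", "zscore", "none")) {
  method <- match.arg(method)
  if (method == "none") return(values)
  if (sum(is.finite(values)) < 3) {
    abort("normalization needs at least 3 finite values")
  }
  if (method == "inverse_normal") {
    r <- rank(values, ties.method = "average", na.last = "keep")
    return(qnorm((r - 0.5) / sum(!is.na(r))))
  }
  s <- sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    abort("zscore normalization undefined for a constant vector")
  }
  (values - mean(values, na.rm = TRUE)) / s
}

#' Normalize every retained bin of a bin matrix
#'
#' Applies [normalize_scores()] across samples within each bin row. Intended
#' to be run once per data set: permutation replicates reuse the normalized
#' matrix because only phenotypes are shuffled.
#'
#' @param bins Bin-matrix tibble.
#' @param method Passed to [normalize_scores()].
#' @param samples Optional subset of sample columns to transform (others are
#'   dropped).
#' @return Bin matrix with transformed sample columns.
#' @export
normalize_bin_matrix <- function(bins, method = "inverse_normal",
                                 samples = NULL) {
  samples <- samples %||% bm_samples(bins)
  if (method == "none") {
    return(bins[, c(.bm_meta_cols, samples)])
  }
  values <- bm_values(bins, samples)
  norm <- t(apply(values, 1, normalize_scores, method = method))
  new_bin_matrix(bins[, c("chrom", "start", "end")], norm,
                 retained = bins$retained)
}
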