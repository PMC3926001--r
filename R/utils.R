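#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange left_join inner_join group_by
#'   summarise ungroup bind_rows row_number across all_of n desc distinct rename
#' @importFrom stats pnorm qnorm pt pchisq var sd cor optimize rnorm runif
#'   rbinom rpois prcomp setNames complete.cases wilcox.test
NULL

#' Two-sided p-value for a Pearson correlation
#'
#' Standard t reference: `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2`
#' degrees of freedom. Used for the blood-brain sharing correlation and the
#' ASM skew-discordance report.
#'
#' @param r Correlation coefficient(s) in [-1, 1].
#' @param n Number of paired observations (> 2).
#' @return Two-sided p-value(s).
#' @export
#' @examples
#' cor_pvalue(0.33, 100)
cor_pvalue <- function(r, n) {
  stopifnot(n > 2)
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / (1 - r^2))
  ifelse(abs(r) >= 1, 0, 2 * pt(-abs(t), df = n - 2))
}

# columns of a bin matrix that are not sample values
.bm_meta_cols <- c("chrom", "start", "end", "bin_id", "retained")

bm_samples <- function(bins) setdiff(names(bins), .bm_meta_cols)

# bins x samples numeric matrix, rownames = bin_id
bm_values <- function(bins, samples = NULL) {
  samples <- samples %||% bm_samples(bins)
  missing <- setdiff(samples, names(bins))
  if (length(missing) > 0) {
    abort(paste0("samples absent from bin matrix: ",
                 paste(missing, collapse = ", ")))
  }
  m <- as.matrix(bins[, samples, drop = FALSE])
  rownames(m) <- bins$bin_id
  m
}

bin_id <- function(chrom, start, end) paste0(chrom, ":", start, "-", end)

# assemble a bin matrix tibble from coordinates and a bins x samples matrix
new_bin_matrix <- function(coords, values, retained = TRUE) {
  stopifnot(nrow(coords) == nrow(values))
  out <- tibble(
    chrom = coords$chrom,
    start = as.integer(coords$start),
    end = as.integer(coords$end),
    bin_id = bin_id(coords$chrom, coords$start, coords$end),
    retained = rep_len(retained, nrow(coords))
  )
  vals <- as_tibble(as.data.frame(values))
  dplyr::bind_cols(out, vals)
}

check_phenotypes <- function(phenotypes,
                             required = c("sample_id", "family_id", "hpst")) {
  missing <- setdiff(required, names(phenotypes))
  if (length(missing) > 0) {
    abort(paste0("phenotype table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(phenotypes)
}
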