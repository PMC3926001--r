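#' Tile a genome into overlapping bins
#'
#' Bins of `bin_size` bp are laid down from position 0 of each chromosome with
#' consecutive starts `step` bp apart, so the default 1-kb/500-bp settings give
#' the half-overlapping bin grid used throughout the pipeline. Only bins fully
#' contained in the chromosome are kept.
#'
#' @param genome A data frame with columns `chrom` and `length` (bp), or a
#'   named numeric vector of chromosome lengths.
#' @param bin_size Bin width in bp.
#' @param step Distance between consecutive bin starts in bp.
#' @return A tibble with columns `chrom`, `start`, `end`, `bin_id`
#'   (0-based half-open coordinates).
#' @export
tile_bins <- function(genome, bin_size = 1000L, step = 500L) {
  genome <- as_genome(genome)
  stopifnot(bin_size > 0, step > 0)
  purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    starts <- seq(0L, max(0L, len - bin_size), by = step)
    starts <- starts[starts + bin_size <= len]
    tibble(
      chrom = genome$chrom[i],
      start = as.integer(starts),
      end = as.integer(starts + bin_size)
    )
  }) |>
    mutate(bin_id = bin_id(.data$chrom, .data$start, .data$end))
}

as_genome <- function(genome) {
  if (is.numeric(genome) && !is.null(names(genome))) {
    genome <- tibble(chrom = names(genome), length = unname(genome))
  }
  stopifnot(all(c("chrom", "length") %in% names(genome)))
  as_tibble(genome)
}

#' Extend single-end reads into MeDIP fragments
#'
#' Each aligned single-end read is extended by `extension` bp in its 3'
#' direction, so a 50-bp read with the default 175-bp extension yields a
#' 225-bp fragment (the expected MeDIP sonication fragment size). Paired-end
#' input bypasses extension: the records are taken to be the outer span of the
#' pair already.
#'
#' @param reads A data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `sample_id` and, for single-end input, `strand` ("+"/"-").
#' @param extension Extension in bp applied 3' of the read.
#' @param paired If `TRUE`, records are full fragments and returned unchanged.
#' @return A tibble of fragments with the same columns (minus `strand`).
#' @export
#' @examples
#' reads <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1050L,
#'                         strand = "+", sample_id = "s1")
#' extend_reads(reads, extension = 175)
extend_reads <- function(reads, extension = 175L, paired = FALSE) {
  reads <- as_tibble(reads)
  stopifnot(extension >= 0)
  if (any(reads$start >= reads$end)) {
    abort("malformed read intervals: start must be < end")
  }
  if (paired) {
    return(select(reads, -dplyr::any_of("strand")))
  }
  if (!"strand" %in% names(reads) || anyNA(reads$strand)) {
    abort("single-end reads must carry a strand for 3' extension")
  }
  fwd <- reads$strand == "+"
  reads |>
    mutate(
      start = as.integer(ifelse(fwd, .data$start,
                                pmax(0L, .data$start - extension))),
      end = as.integer(ifelse(fwd, .data$end + extension, .data$end))
    ) |>
    select(-"strand")
}

#' Compute per-bin RMQ scores from MeDIP fragments
#'
#' The relative methylation quantification (RMQ) score of a bin is the sum of
#' the per-base-pair MeDIP-fragment coverage over the bin, divided by the
#' sample's total autosomal post-QC read count and multiplied by `scale`
#' (a reads-per-million-style constant for numeric readability; downstream
#' association statistics are invariant to it because scores are normalized
#' before regression). A fragment spanning two overlapping bins contributes
#' its overlap to both.
#'
#' @param fragments Data frame of fragments: `chrom`, `start`, `end`,
#'   `sample_id` (0-based half-open).
#' @param genome Chromosome sizes (see [tile_bins()]).
#' @param bin_size,step Bin tiling parameters.
#' @param scale Multiplicative constant applied to every score.
#' @param total_reads Optional named vector or data frame
#'   (`sample_id`, `total_reads`) of per-sample denominators; defaults to the
#'   number of fragments per sample. Samples with denominator 0 are rejected.
#' @return A bin-matrix tibble: `chrom`, `start`, `end`, `bin_id`, `retained`
#'   and one numeric column per sample.
#' @export
compute_rmq <- function(fragments, genome, bin_size = 1000L, step = 500L,
                        scale = 1e6, total_reads = NULL) {
  fragments <- as_tibble(fragments)
  genome <- as_genome(genome)
  if (nrow(fragments) == 0) abort("no fragments supplied")
  if (any(fragments$start >= fragments$end)) {
    abort("malformed fragment intervals: start must be < end")
  }
  glen <- setNames(genome$length, genome$chrom)
  if (!all(fragments$chrom %in% names(glen))) {
    abort("fragment chromosome absent from genome")
  }
  if (any(fragments$start < 0) ||
      any(fragments$end > glen[fragments$chrom])) {
    abort("fragment coordinates outside chromosome bounds")
  }

  denom <- resolve_denominators(fragments, total_reads)
  bad <- names(denom)[denom <= 0]
  if (length(bad) > 0) {
    warn(paste0("rejecting sample(s) with zero read-count denominator: ",
                paste(bad, collapse = ", ")))
    denom <- denom[denom > 0]
    fragments <- filter(fragments, .data$sample_id %in% names(denom))
    if (nrow(fragments) == 0) abort("no samples with usable denominators")
  }

  bins <- tile_bins(genome, bin_size, step)
  samples <- names(denom)
  values <- matrix(0, nrow = nrow(bins), ncol = length(samples),
                   dimnames = list(bins$bin_id, samples))
  for (s in samples) {
    fr <- fragments[fragments$sample_id == s, ]
    cov <- GenomicRanges::coverage(
      GenomicRanges::GRanges(
        factor(fr$chrom, levels = names(glen)),
        IRanges::IRanges(start = fr$start + 1L, end = fr$end)
      ),
      width = glen
    )
    for (chr in unique(bins$chrom)) {
      idx <- which(bins$chrom == chr)
      v <- IRanges::Views(cov[[chr]],
                          start = bins$start[idx] + 1L,
                          end = bins$end[idx])
      values[idx, s] <- IRanges::viewSums(v)
    }
    values[, s] <- values[, s] / denom[[s]] * scale
  }
  new_bin_matrix(bins, values)
}

resolve_denominators <- function(fragments, total_reads) {
  counts <- table(fragments$sample_id)
  denom <- setNames(as.numeric(counts), names(counts))
  if (!is.null(total_reads)) {
    if (is.data.frame(total_reads)) {
      total_reads <- setNames(total_reads$total_reads, total_reads$sample_id)
    }
    missing <- setdiff(names(denom), names(total_reads))
    if (length(missing) > 0) {
      abort(paste0("total_reads missing for sample(s): ",
                   paste(missing, collapse = ", ")))
    }
    denom <- total_reads[names(denom)]
  }
  denom
}

#' Flag analysable bins
#'
#' A bin is retained for association analysis when its RMQ scores have
#' positive sample variance and at least `min_prop_nonzero` of the samples
#' have a score greater than zero (both thresholds inclusive of the boundary
#' fraction, so 1 nonzero sample out of 10 satisfies the default 10% rule).
#' Values are untouched; only the `retained` mask is updated.
#'
#' @param bins A bin-matrix tibble.
#' @param min_prop_nonzero Minimum fraction of samples with RMQ > 0.
#' @return The bin matrix with an updated `retained` column.
#' @export
filter_bins <- function(bins, min_prop_nonzero = 0.10) {
  values <- bm_values(bins)
  if (ncol(values) < 2) abort("bin filtering needs at least 2 samples")
  v <- apply(values, 1, var)
  prop <- rowMeans(values > 0)
  bins$retained <- unname(v > 0 & prop >= min_prop_nonzero)
  bins
}
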