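#' Read and write MeDIP fragments as 4-column BED
#'
#' Fragments travel as standard 0-based half-open BED with the sample id in
#' the name column. When the rtracklayer package is available it is used for
#' the conversion; otherwise a plain tab-separated reader/writer handles the
#' 4-column layout.
#'
#' @param path File path.
#' @return `read_fragments_bed()` returns a fragment tibble (`chrom`,
#'   `start`, `end`, `sample_id`).
#' @export
read_fragments_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    return(tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      sample_id = gr$name
    ))
  }
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "sample_id"),
                  col_types = "ciic")
}

#' @param fragments Fragment tibble.
#' @rdname read_fragments_bed
#' @export
write_fragments_bed <- function(fragments, path) {
  readr::write_tsv(
    fragments[, c("chrom", "start", "end", "sample_id")],
    path, col_names = FALSE
  )
  invisible(path)
}

#' Read and write a bin matrix as TSV
#'
#' Plain bins-by-samples tab-separated tables with the bin coordinates and
#' retained flag as leading columns.
#'
#' @param bins Bin-matrix tibble.
#' @param path File path.
#' @export
write_bin_matrix <- function(bins, path) {
  readr::write_tsv(bins, path)
  invisible(path)
}

#' @rdname write_bin_matrix
#' @export
read_bin_matrix <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("chrom", "start", "end", "bin_id", "retained") %in%
                  names(out)))
  out
}

#' Write a simulation configuration as YAML
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}
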