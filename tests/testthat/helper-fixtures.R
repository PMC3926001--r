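# small builders used across test files

# bin matrix straight from a bins x samples matrix over a 1-chromosome grid
toy_bin_matrix <- function(values, chrom = "chr1", bin_size = 1000L,
                           step = 500L) {
  n <- nrow(values)
  starts <- seq(0L, by = step, length.out = n)
  coords <- tibble::tibble(chrom = chrom, start = starts,
                           end = starts + bin_size)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  bm <- dplyr::bind_cols(
    coords,
    tibble::tibble(
      bin_id = paste0(chrom, ":", coords$start, "-", coords$end),
      retained = TRUE
    ),
    tibble::as_tibble(as.data.frame(values))
  )
  bm
}

# phenotypes for k MZ pairs (+ optional singletons), trait values supplied
toy_pairs_pheno <- function(hpst, age = NULL) {
  k <- length(hpst) / 2
  stopifnot(k == floor(k))
  tibble::tibble(
    sample_id = paste0("s", seq_along(hpst)),
    family_id = rep(paste0("f", seq_len(k)), each = 2),
    zygosity = "MZ",
    hpst = hpst,
    age = age %||% rep(60, length(hpst)),
    cohort = "discovery",
    timepoint = 1L
  )
}

toy_singletons_pheno <- function(hpst, prefix = "u") {
  tibble::tibble(
    sample_id = paste0(prefix, seq_along(hpst)),
    family_id = paste0(prefix, "fam", seq_along(hpst)),
    zygosity = "singleton",
    hpst = hpst,
    age = 60,
    cohort = "followup",
    timepoint = 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-base-pair brute-force coverage: sum of fragment coverage over each bin
brute_force_rmq <- function(fragments, genome, bin_size = 1000L,
                            step = 500L, scale = 1, total_reads = NULL) {
  bins <- medipewas::tile_bins(genome, bin_size, step)
  samples <- sort(unique(fragments$sample_id))
  denom <- table(fragments$sample_id)[samples]
  if (!is.null(total_reads)) denom <- total_reads[samples]
  out <- matrix(0, nrow(bins), length(samples),
                dimnames = list(bins$bin_id, samples))
  glen <- if (is.numeric(genome)) genome else setNames(genome$length, genome$chrom)
  for (s in samples) {
    fr <- fragments[fragments$sample_id == s, ]
    for (chr in unique(bins$chrom)) {
      cov <- integer(glen[[chr]])
      frc <- fr[fr$chrom == chr, ]
      for (i in seq_len(nrow(frc))) {
        idx <- (frc$start[i] + 1):frc$end[i]
        cov[idx] <- cov[idx] + 1L
      }
      bidx <- which(bins$chrom == chr)
      for (b in bidx) {
        out[b, s] <- sum(cov[(bins$start[b] + 1):bins$end[b]])
      }
    }
    out[, s] <- out[, s] / as.numeric(denom[[s]]) * scale
  }
  out
}

# brute-force permutation FDR recount for one threshold grid
brute_force_fdr <- function(obs_p, perm_list, alpha = 0.05) {
  grid <- sort(unique(obs_p))
  R <- length(perm_list)
  raw <- vapply(grid, function(t) {
    obs <- sum(obs_p <= t)
    perm <- sum(vapply(perm_list, function(p) sum(p <= t), numeric(1)))
    if (obs == 0 && perm == 0) 0 else (perm / R) / obs
  }, numeric(1))
  mono <- rev(cummin(rev(raw)))
  ok <- which(mono <= alpha)
  list(grid = grid, fdr_raw = raw, fdr = mono,
       threshold = if (length(ok)) grid[max(ok)] else NA_real_)
}

# one-way ANOVA ICC(1,1) oracle via aov() for pairs of size 2
anova_icc_oracle <- function(y1, y2) {
  k <- length(y1)
  d <- data.frame(y = c(y1, y2), g = factor(rep(seq_len(k), 2)))
  ms <- summary(stats::aov(y ~ g, data = d))[[1]]$`Mean Sq`
  (ms[1] - ms[2]) / (ms[1] + ms[2])
}
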