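#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a permutation FDR result
#'
#' @param x A `medip_fdr` object.
#' @param ... Unused.
#' @return The step-function grid as a tibble: `p`, `observed_hits`,
#'   `perm_hits_pooled`, `fdr_raw`, `fdr`.
#' @export
#' @method tidy medip_fdr
tidy.medip_fdr <- function(x, ...) x$grid

#' @rdname tidy.medip_fdr
#' @export
#' @method glance medip_fdr
glance.medip_fdr <- function(x, ...) {
  tibble(threshold = x$threshold, alpha = x$alpha,
         n_replicates = x$n_replicates,
         n_grid = nrow(x$grid))
}

#' One-row summaries of association and meta-analysis tables
#'
#' @param x A `medip_ewas` or `medip_meta` tibble.
#' @param ... Unused.
#' @export
#' @method glance medip_ewas
glance.medip_ewas <- function(x, ...) {
  tibble(
    n_bins = nrow(x),
    n_ok = sum(x$status == "ok"),
    n_flagged = sum(x$status != "ok"),
    model = x$model[1],
    lambda_gc = stats::median(stats::qchisq(x$p[x$status == "ok"],
                                            df = 1, lower.tail = FALSE)) /
      stats::qchisq(0.5, df = 1)
  )
}

#' @rdname glance.medip_ewas
#' @export
#' @method glance medip_meta
glance.medip_meta <- function(x, ...) {
  tibble(
    n_bins = nrow(x),
    n_het_pass = sum(x$het_pass),
    n_het_fail = sum(!x$het_pass),
    model = x$model[1]
  )
}

#' Tidy a pipeline run
#'
#' @param x A `medip_run` object.
#' @param ... Unused.
#' @return The ranked DMR table.
#' @export
#' @method tidy medip_run
tidy.medip_run <- function(x, ...) as_tibble(x$dmrs)

#' @rdname tidy.medip_run
#' @export
#' @method glance medip_run
glance.medip_run <- function(x, ...) {
  m <- x$manifest
  tibble(
    n_twin = m$n_twin, n_unrelated = m$n_unrelated,
    n_bins_retained = m$n_bins_retained,
    n_replicates = m$n_replicates,
    threshold_ma = m$threshold_ma,
    n_significant = sum(x$dmrs$significant)
  )
}
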