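#' Per-bin twin EWAS with a family random intercept
#'
#' For every retained bin, regresses (optionally normalized) RMQ scores on the
#' phenotype as a fixed effect with a random family intercept, the standard
#' model for monozygotic co-twin designs: the random intercept absorbs the
#' shared family component of methylation so the phenotype coefficient is
#' tested against the within- plus between-family residual structure.
#' Variance components are estimated by maximum likelihood (profile over the
#' intraclass correlation); the reported p is a two-sided Wald test of the
#' phenotype coefficient against the normal reference.
#'
#' @param bins Bin-matrix tibble (see [compute_rmq()]); only retained bins are
#'   analysed.
#' @param phenotypes Phenotype table with `sample_id`, `family_id` and the
#'   predictor column; samples must appear as columns of `bins`.
#' @param covariates Character vector of additional fixed-effect covariate
#'   columns in `phenotypes` (e.g. `"age"`).
#' @param predictor Name of the phenotype column to test (default `"hpst"`).
#' @param normalize Per-bin score transform (see [normalize_scores()]); use
#'   `"none"` if the matrix is already normalized.
#' @param method `"grid"` (vectorised profile over `rho_grid`, the default for
#'   genome scans) or `"exact"` (per-bin optimiser; slower, used for small
#'   target sets and oracle comparisons).
#' @param rho_grid Grid of intraclass-correlation values profiled under
#'   `method = "grid"`.
#' @return A tibble of class `medip_ewas`: one row per retained bin with
#'   `bin_id`, coordinates, `beta`, `se`, `p`, `rho` (fitted intraclass
#'   correlation), `n`, `model`, `status`.
#' @seealso [fit_unrelated_ewas()] for the singleton-cohort linear model.
#' @export
fit_twin_ewas <- function(bins, phenotypes, covariates = character(),
                          predictor = "hpst",
                          normalize = "inverse_normal",
                          method = c("grid", "exact"),
                          rho_grid = seq(0, 0.99, length.out = 67)) {
  method <- match.arg(method)
  check_phenotypes(phenotypes, c("sample_id", "family_id", predictor,
                                 covariates))
  ph <- filter(phenotypes, .data$sample_id %in% bm_samples(bins))
  if (length(unique(ph$family_id)) < 2) {
    abort("twin EWAS needs at least 2 families present in the matrix")
  }
  design <- ewas_design(ph, predictor, covariates)
  sub <- bins[bins$retained, , drop = FALSE]
  values <- bm_values(sub, ph$sample_id)
  if (normalize != "none") {
    values <- t(apply(values, 1, normalize_scores, method = normalize))
  }
  fit <- fit_pair_lmm(design$X, t(values), ph$family_id,
                      focal = design$focal, method = method,
                      rho_grid = rho_grid)
  out <- dplyr::bind_cols(
    sub[, c("bin_id", "chrom", "start", "end")],
    fit
  ) |>
    mutate(
      n = nrow(ph),
      model = "lmer",
      status = ifelse(is.finite(.data$se) & .data$se > 0, "ok", "degenerate"),
      p = ifelse(.data$status == "ok", .data$p, NA_real_)
    )
  class(out) <- c("medip_ewas", class(out))
  attr(out, "predictor") <- predictor
  out
}

#' Per-bin EWAS in a cohort of unrelated individuals
#'
#' Ordinary least squares of (optionally normalized) RMQ on the phenotype,
#' with optional covariates and up to three methylation principal components
#' computed once from the normalized retained matrix. P-values are two-sided
#' t tests of the phenotype coefficient.
#'
#' @inheritParams fit_twin_ewas
#' @param n_pcs Number of methylation principal components (0-3) added as
#'   covariates.
#' @return A tibble of class `medip_ewas` (same columns as
#'   [fit_twin_ewas()], with `model = "lm"` and `rho = NA`).
#' @export
fit_unrelated_ewas <- function(bins, phenotypes, covariates = character(),
                               predictor = "hpst",
                               normalize = "inverse_normal", n_pcs = 0) {
  check_phenotypes(phenotypes, c("sample_id", predictor, covariates))
  if (!n_pcs %in% 0:3) abort("n_pcs must be 0, 1, 2 or 3")
  ph <- filter(phenotypes, .data$sample_id %in% bm_samples(bins))
  sub <- bins[bins$retained, , drop = FALSE]
  values <- bm_values(sub, ph$sample_id)
  if (normalize != "none") {
    values <- t(apply(values, 1, normalize_scores, method = normalize))
  }
  design <- ewas_design(ph, predictor, covariates)
  X <- design$X
  if (n_pcs > 0) {
    pcs <- prcomp(t(values), center = TRUE, scale. = FALSE)$x
    if (ncol(pcs) < n_pcs) abort("not enough samples/bins for requested PCs")
    X <- cbind(X, pcs[, seq_len(n_pcs), drop = FALSE])
    colnames(X)[(ncol(X) - n_pcs + 1):ncol(X)] <- paste0("PC", seq_len(n_pcs))
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p) abort("more model terms than samples")
  if (qr(X)$rank < p) abort("collinear design (constant or redundant covariate)")
  Y <- t(values)                                 # samples x bins
  A <- crossprod(X)
  Bm <- crossprod(X, Y)
  coef <- solve(A, Bm)
  rss <- pmax(colSums(Y^2) - colSums(Bm * coef), 0)
  sigma2 <- rss / (n - p)
  Ainv <- solve(A)
  beta <- coef[design$focal, ]
  se <- sqrt(sigma2 * Ainv[design$focal, design$focal])
  out <- dplyr::bind_cols(
    sub[, c("bin_id", "chrom", "start", "end")],
    tibble(
      beta = unname(beta), se = unname(se),
      p = 2 * pt(-abs(beta / se), df = n - p),
      rho = NA_real_, sigma2 = unname(sigma2)
    )
  ) |>
    mutate(
      n = n,
      model = "lm",
      status = ifelse(is.finite(.data$se) & .data$se > 0, "ok", "degenerate"),
      p = ifelse(.data$status == "ok", .data$p, NA_real_)
    )
  class(out) <- c("medip_ewas", class(out))
  attr(out, "predictor") <- predictor
  out
}

# intercept + predictor + covariates design matrix in phenotype row order
ewas_design <- function(ph, predictor, covariates) {
  cols <- c(predictor, covariates)
  if (any(!complete.cases(ph[, cols]))) {
    abort("missing values in predictor/covariates")
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(ph[, cols, drop = FALSE]))
  list(X = X, focal = 2L)
}
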