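# Vectorised profile-ML fitter for the balanced-pair random-intercept model.
#
# Model per bin: y = X b + a_family + e, a ~ N(0, sg2_a), e ~ N(0, sg2_e),
# families of size 1 or 2. An orthogonal within-family transform (scaled pair
# sums and differences) diagonalises the covariance: difference components
# have variance sg2_e, sum components sg2_e * lambda with lambda = 1 + 2*gamma,
# singletons sg2_e * (1 + lambda)/2, where gamma = sg2_a / sg2_e. Given the
# intraclass correlation rho = gamma / (1 + gamma) the fit is weighted least
# squares, so the likelihood is profiled over a rho grid simultaneously for
# all bins; this is the same ML optimum lme4 finds bin by bin, computed with
# dense matrix algebra instead of one optimiser call per bin.

# build the transformed design/outcome; X is n x p, Y is n x B (samples rows)
pair_transform <- function(X, Y, family_id) {
  fam <- split(seq_along(family_id), family_id)
  sizes <- lengths(fam)
  if (any(sizes > 2)) {
    abort("families larger than 2 are not supported by the pair mixed model")
  }
  rows <- list(); types <- character(0)
  s2 <- sqrt(2)
  for (idx in fam) {
    if (length(idx) == 2) {
      rows[[length(rows) + 1]] <- list(
        x = (X[idx[1], ] + X[idx[2], ]) / s2,
        y = (Y[idx[1], ] + Y[idx[2], ]) / s2)
      types <- c(types, "sum")
      rows[[length(rows) + 1]] <- list(
        x = (X[idx[1], ] - X[idx[2], ]) / s2,
        y = (Y[idx[1], ] - Y[idx[2], ]) / s2)
      types <- c(types, "diff")
    } else {
      rows[[length(rows) + 1]] <- list(x = X[idx, ], y = Y[idx, ])
      types <- c(types, "single")
    }
  }
  list(
    X = do.call(rbind, lapply(rows, `[[`, "x")),
    Y = do.call(rbind, lapply(rows, `[[`, "y")),
    type = types
  )
}

pair_weights <- function(type, rho) {
  gamma <- rho / (1 - rho)
  lambda <- 1 + 2 * gamma
  w <- c(sum = 1 / lambda, diff = 1, single = 2 / (1 + lambda))[type]
  unname(w)
}

# profile log-likelihood pieces at one rho for all bins; returns list with
# ll (length B), and the weighted normal equations for reuse. Y2 = tr$Y^2 may
# be precomputed once for the grid path.
.pair_profile_at <- function(tr, rho, Y2 = NULL, reml = TRUE) {
  w <- pair_weights(tr$type, rho)
  if (is.null(Y2)) Y2 <- tr$Y^2
  # (X sqrt(w))'(Y sqrt(w)) = X'(wY); colSums((Y sqrt(w))^2) = w'Y^2
  A <- crossprod(tr$X * w, tr$X)
  B <- crossprod(tr$X, tr$Y * w)
  coef <- solve(A, B)
  rss <- pmax(as.vector(crossprod(Y2, w)) - colSums(B * coef), 1e-300)
  n <- nrow(tr$X)
  p <- ncol(tr$X)
  ll <- if (reml) {
    -(n - p) / 2 * log(rss / (n - p)) - sum(log(1 / w)) / 2 -
      determinant(A, logarithm = TRUE)$modulus / 2
  } else {
    -n / 2 * log(rss / n) - sum(log(1 / w)) / 2
  }
  list(ll = as.vector(ll), A = A, coef = coef, rss = rss)
}

# fit all bins: Y n x B, X n x p, focal = column index of the coefficient of
# interest. Returns tibble(beta, se, p, rho, sigma2).
fit_pair_lmm <- function(X, Y, family_id, focal,
                         method = c("grid", "exact"),
                         rho_grid = seq(0, 0.99, length.out = 67),
                         reml = TRUE) {
  method <- match.arg(method)
  tr <- pair_transform(X, Y, family_id)
  n <- nrow(X); p <- ncol(X); B <- ncol(Y)
  if (qr(X)$rank < p) abort("collinear design (constant or redundant covariate)")
  if (method == "exact") {
    res <- purrr::map_dfr(seq_len(B), function(j) {
      trj <- list(X = tr$X, Y = tr$Y[, j, drop = FALSE], type = tr$type)
      opt <- optimize(function(r) .pair_profile_at(trj, r, reml = reml)$ll,
                      interval = c(0, 0.995), maximum = TRUE, tol = 1e-9)
      .pair_stats_at(trj, opt$maximum, focal, n, p)
    })
    return(res)
  }
  best_ll <- rep(-Inf, B)
  best_ix <- rep(1L, B)
  Y2 <- tr$Y^2
  for (i in seq_along(rho_grid)) {
    ll <- .pair_profile_at(tr, rho_grid[i], Y2, reml = reml)$ll
    upd <- ll > best_ll
    best_ll[upd] <- ll[upd]
    best_ix[upd] <- i
  }
  out <- tibble(beta = numeric(B), se = numeric(B), p = numeric(B),
                df = numeric(B), rho = numeric(B), sigma2 = numeric(B))
  for (i in sort(unique(best_ix))) {
    j <- which(best_ix == i)
    trj <- list(X = tr$X, Y = tr$Y[, j, drop = FALSE], type = tr$type)
    out[j, ] <- .pair_stats_at(trj, rho_grid[i], focal, n, p)
  }
  out
}

# Wald statistics at a fixed rho. The residual scale uses the REML estimate
# RSS/(n - p); the t reference uses Kenward-Roger small-sample inference:
# the plug-in GLS variance is inflated for the uncertainty of the estimated
# variance components, and the degrees of freedom come from the matching
# Satterthwaite formula. Both corrections depend only on rho and the design,
# so they are computed once per rho group and shared by all its bins; a
# plain normal Wald test is visibly anti-conservative at a few dozen pairs.
.pair_stats_at <- function(tr, rho, focal, n, p) {
  pr <- .pair_profile_at(tr, rho)
  Ainv <- solve(pr$A)
  sigma2 <- pr$rss / (n - p)
  beta <- pr$coef[focal, ]
  kr <- .kr_adjust(tr, rho, focal, n, p)
  se <- sqrt(sigma2 * Ainv[focal, focal]) * kr$se_mult
  tibble(beta = unname(beta), se = unname(se),
         p = 2 * pt(-abs(beta / se), df = kr$df),
         df = kr$df, rho = rho, sigma2 = unname(sigma2))
}

# Kenward-Roger adjustment for the focal coefficient at variance ratio
# gamma = rho/(1-rho), in the transformed (diagonal-covariance) space where
# v_i = sg2_e * (u1_i + gamma * u2_i), u1 = 1, u2 = 0/2/1 for
# difference/sum/singleton components. Working at unit scale (the
# adjustment ratio and df are scale-free):
#   Phi    = (X'V^-1 X)^-1          P_j = -X' V^-1 D_j V^-1 X
#   Q_jk   = X' V^-1 D_j V^-1 D_k V^-1 X
#   I_R    = REML information, W = I_R^-1
#   Lambda = Phi [sum_jk W_jk (Q_jk - P_j Phi P_k)] Phi
# giving the inflated variance Phi_ff + 2 Lambda_ff and the Satterthwaite
# df 2 Theta^2 / Var(Theta) with Theta = Phi_ff, g_j = -[Phi P_j Phi]_ff.
.kr_adjust <- function(tr, rho, focal, n, p) {
  gamma <- rho / (1 - rho)
  u2 <- c(sum = 2, diff = 0, single = 1)[tr$type]
  u <- 1 + gamma * u2
  X <- tr$X
  A <- crossprod(X / u, X)
  Phi <- solve(A)
  P1 <- -crossprod(X / u^2, X)
  P2 <- -crossprod(X * (u2 / u^2), X)
  Q <- list(
    `11` = crossprod(X / u^3, X),
    `12` = crossprod(X * (u2 / u^3), X),
    `22` = crossprod(X * (u2^2 / u^3), X)
  )
  # REML information via Pmat = V^-1 - V^-1 X Phi X' V^-1
  Vx <- X / u
  Pmat <- diag(1 / u) - Vx %*% Phi %*% t(Vx)
  PP <- Pmat * Pmat
  d1 <- rep(1, n)
  IR <- matrix(c(
    sum(PP), as.numeric(t(d1) %*% PP %*% u2),
    as.numeric(t(u2) %*% PP %*% d1), as.numeric(t(u2) %*% PP %*% u2)
  ), 2, 2) / 2
  if (abs(det(IR)) < 1e-10 * (IR[1, 1]^2 + 1e-300)) {
    # variance components confounded (e.g. singletons only): classical OLS
    return(list(se_mult = 1, df = n - p))
  }
  W <- solve(IR)
  Ps <- list(`1` = P1, `2` = P2)
  M <- matrix(0, p, p)
  for (j in 1:2) for (k in 1:2) {
    M <- M + W[j, k] *
      (Q[[paste0(sort(c(j, k)), collapse = "")]] -
         Ps[[j]] %*% Phi %*% Ps[[k]])
  }
  Lambda <- Phi %*% M %*% Phi
  theta <- Phi[focal, focal]
  var_adj <- theta + 2 * Lambda[focal, focal]
  se_mult <- sqrt(max(var_adj, theta / 2) / theta)
  g <- vapply(Ps, function(Pj) -(Phi %*% Pj %*% Phi)[focal, focal],
              numeric(1))
  var_theta <- as.numeric(t(g) %*% W %*% g)
  df <- if (var_theta > 0) 2 * theta^2 / var_theta else n - p
  list(se_mult = se_mult, df = min(max(df, 1), n - p))
}
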