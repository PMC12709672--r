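#' CLR-transform assembly-process importances
#'
#' Zeros are replaced by a small pseudo-fraction (default 1e-6), rows are
#' renormalized to sum to 1, then the centred log-ratio is taken per sample
#' across the five processes, so each row sums to 0.
#'
#' @param importance Samples-by-processes matrix of non-negative fractions.
#' @param pseudo Replacement for exact zeros.
#' @return Numeric matrix, rows summing to 0.
#' @export
transform_processes <- function(importance, pseudo = 1e-6) {
  x <- as.matrix(importance)
  if (any(x < 0)) stop("process importances must be non-negative")
  x[x == 0] <- pseudo
  x <- x / rowSums(x)
  lx <- log(x)
  sweep(lx, 1L, rowMeans(lx), "-")
}

#' Log-transform environmental variables
#'
#' `log(x + 1)` elementwise; negative values are an error.
#'
#' @param x Numeric vector/matrix of non-negative values (NA passed through).
#' @return Transformed values, same shape.
#' @export
transform_env <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("negative environmental value")
  log1p(x)
}

# Draw train/test splits for Monte-Carlo CV; redraw splits whose training
# predictor is constant (max 100 tries each).
mc_splits <- function(x, n, n_rep, train_frac) {
  n_train <- max(2L, floor(train_frac * n))
  lapply(seq_len(n_rep), function(r) {
    for (try in 1:100) {
      tr <- sample(n, n_train)
      if (var(x[tr]) > 0 && length(tr) < n) return(tr)
    }
    stop("degenerate predictor: constant in every training split")
  })
}

r2cv_from_splits <- function(y, x, splits) {
  sse <- 0; sst <- 0
  for (tr in splits) {
    xt <- x[tr]; yt <- y[tr]
    b <- cov(xt, yt) / var(xt)
    a <- mean(yt) - b * mean(xt)
    te <- setdiff(seq_along(y), tr)
    pred <- a + b * x[te]
    sse <- sse + sum((y[te] - pred)^2)
    sst <- sst + sum((y[te] - mean(yt))^2)
  }
  if (sst == 0) return(NA_real_)   # (near-)constant response
  1 - sse / sst
}

#' Monte-Carlo cross-validated R-squared
#'
#' Repeatedly fits an intercept+slope model on a random 90\% training split
#' and predicts the held-out 10\%; squared errors are pooled over
#' repetitions: `R2CV = 1 - SSE / SST`, with SST measured against the
#' training mean of each repetition. Repetitions with a constant training
#' predictor are redrawn.
#'
#' @param y,x Numeric vectors (>= 10 complete pairs).
#' @param n_rep Number of random splits (default 1000).
#' @param train_frac Training fraction (default 0.9).
#' @param seed Integer seed.
#' @return Pooled cross-validated R-squared (can be negative under the
#'   null).
#' @export
mc_cv_r2 <- function(y, x, n_rep = 1000, train_frac = 0.9,
                     seed = 20231201) {
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 10) stop("need >= 10 complete pairs")
  with_seed(seed, {
    splits <- mc_splits(x, length(y), n_rep, train_frac)
    r2cv_from_splits(y, x, splits)
  })
}

#' Permutation p-value for a cross-validated association
#'
#' The test statistic is R2CV itself, recomputed under `n_perm` shufflings
#' of the response with predictors fixed; the observed statistic and every
#' permutation reuse the same `n_rep_inner` train/test splits, making the
#' statistics exchangeable under the null.
#' `p = (1 + #\{R2CV_perm >= R2CV_obs\}) / (n_perm + 1)`.
#'
#' @param y,x Numeric vectors.
#' @param n_perm Number of permutations (default 999).
#' @param n_rep_inner CV repetitions per evaluation (default 100).
#' @param train_frac Training fraction.
#' @param seed Integer seed.
#' @return A list: `p`, `obs` (R2CV at the inner budget).
#' @export
permutation_p <- function(y, x, n_perm = 999, n_rep_inner = 100,
                          train_frac = 0.9, seed = 20231201) {
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 10) stop("need >= 10 complete pairs")
  with_seed(seed, {
    splits <- mc_splits(x, length(y), n_rep_inner, train_frac)
    obs <- r2cv_from_splits(y, x, splits)
    if (is.na(obs)) return(list(p = NA_real_, obs = NA_real_))
    ge <- 0L
    for (r in seq_len(n_perm)) {
      rp <- r2cv_from_splits(sample(y), x, splits)
      if (!is.na(rp) && rp >= obs) ge <- ge + 1L
    }
    list(p = (1 + ge) / (n_perm + 1), obs = obs)
  })
}

#' Associate assembly processes with environmental variables
#'
#' Evaluates every (clr-transformed process, log-transformed environmental
#' variable) pair with [mc_cv_r2()] and [permutation_p()], BH-adjusts the
#' permutation p-values across the full pair set, and applies the
#' significance rule `adjusted p < 0.05 AND R2CV > 0.01`. Each pair draws
#' its randomness from a substream derived from the master seed and the
#' pair's names, so the full table is reproducible bit for bit.
#'
#' @param proc_clr Samples-by-processes matrix from [transform_processes()].
#' @param env Samples-by-variables matrix (already log-transformed via
#'   [transform_env()]; rows aligned with `proc_clr`).
#' @param n_rep CV repetitions for the reported R2CV (default 1000).
#' @param n_perm Permutations (default 999).
#' @param n_rep_inner CV repetitions inside the permutation test.
#' @param r2_min R2CV component of the significance rule (default 0.01).
#' @param seed Master seed.
#' @return A data.frame, one row per process x variable: `r2cv`,
#'   `slope_sign`, `p`, `p_adj`, `significant`.
#' @export
associate_all <- function(proc_clr, env, n_rep = 1000, n_perm = 999,
                          n_rep_inner = 100, r2_min = 0.01,
                          seed = 20231201) {
  stopifnot(nrow(proc_clr) == nrow(env))
  rows <- list()
  for (p in colnames(proc_clr)) for (v in colnames(env)) {
    y <- proc_clr[, p]; x <- env[, v]
    sub <- derive_seed(seed, paste(p, v, sep = "|"))
    r2 <- mc_cv_r2(y, x, n_rep = n_rep, seed = sub)
    pt <- permutation_p(y, x, n_perm = n_perm, n_rep_inner = n_rep_inner,
                        seed = sub + 1L)
    ok <- !is.na(y) & !is.na(x)
    slope <- cov(x[ok], y[ok]) / var(x[ok])
    rows[[paste(p, v)]] <- data.frame(
      process = p, variable = v, r2cv = r2,
      slope_sign = sign(slope), p = pt$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_adj <- bh_adjust(out$p)
  out$significant <- !is.na(out$p_adj) & out$p_adj < 0.05 &
    !is.na(out$r2cv) & out$r2cv > r2_min
  out
}

#' Variance inflation factors
#'
#' For each variable, the R-squared of its OLS regression on all other
#' variables gives `VIF = 1 / (1 - R^2)`; 1 means in-sample orthogonality,
#' and perfect collinearity is reported as `Inf`.
#'
#' @param env Samples-by-variables numeric matrix (complete rows used).
#' @return A data.frame with `variable` and `vif`.
#' @export
vif <- function(env) {
  env <- as.matrix(env)
  env <- env[complete.cases(env), , drop = FALSE]
  k <- ncol(env)
  if (nrow(env) < k + 2) stop("need at least k + 2 complete samples")
  out <- vapply(seq_len(k), function(j) {
    fit <- lm(env[, j] ~ env[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  data.frame(variable = colnames(env), vif = out, stringsAsFactors = FALSE)
}
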