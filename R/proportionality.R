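#' Per-genus preprocessing for proportionality analysis
#'
#' Applies, in order: (1) drop ASVs with zero counts across all samples;
#' (2) drop samples with zero counts across the genus's ASVs; (3) keep ASVs
#' present in at least 5\% of the remaining samples and in at least 3
#' samples; (4) drop ASVs with coefficient of variation below 0.1; (5) add a
#' pseudocount of 1 to every remaining cell. Returns `NULL` (with a message)
#' when fewer than 2 ASVs or 3 samples survive.
#'
#' @param cm Features-by-samples count matrix.
#' @param taxonomy Data.frame with `asv_id` and `genus`.
#' @param genus Genus to extract.
#' @param members Optional explicit ASV ids (overrides the taxonomy lookup,
#'   e.g. a divergence-linked component from [select_genera()]).
#' @param min_prev,min_samples Prevalence rule of step 3.
#' @param min_cv CV rule of step 4.
#' @param pseudocount Step 5 (default 1).
#' @return Filtered members-by-samples matrix with the pseudocount added.
#' @export
preprocess_genus <- function(cm, taxonomy, genus, members = NULL,
                             min_prev = 0.05, min_samples = 3,
                             min_cv = 0.1, pseudocount = 1) {
  if (is.null(members)) {
    if (!genus %in% taxonomy$genus) stop("unknown genus: ", genus)
    members <- taxonomy$asv_id[taxonomy$genus == genus]
  }
  x <- cm[intersect(rownames(cm), members), , drop = FALSE]
  x <- x[rowSums(x) > 0, , drop = FALSE]                      # (1)
  x <- x[, colSums(x) > 0, drop = FALSE]                      # (2)
  if (ncol(x)) {
    prev <- rowSums(x > 0)
    x <- x[prev >= max(min_samples, ceiling(min_prev * ncol(x))), ,
           drop = FALSE]                                      # (3)
  }
  if (nrow(x)) {
    cv <- apply(x, 1L, function(v) sd(v) / mean(v))
    x <- x[!is.na(cv) & cv >= min_cv, , drop = FALSE]         # (4)
  }
  if (nrow(x) < 2 || ncol(x) < 3) {
    message("genus ", genus, " skipped: fewer than 2 ASVs or 3 samples ",
            "after filtering")
    return(NULL)
  }
  x + pseudocount                                             # (5)
}

#' Proportionality (rho) matrix
#'
#' CLR-transforms the genus submatrix per sample and computes, for each ASV
#' pair, `rho = 1 - var(clr_i - clr_j) / (var(clr_i) + var(clr_j))` with
#' variances taken across samples. Rho is 1 for perfectly proportional
#' dynamics and bounded by \[-1, 1\].
#'
#' @param filtered Members-by-samples matrix from [preprocess_genus()]
#'   (already pseudocounted, strictly positive).
#' @return A symmetric matrix with unit diagonal; pairs with zero total
#'   variance are `NA`.
#' @export
rho_matrix <- function(filtered) {
  if (nrow(filtered) < 2 || ncol(filtered) < 3)
    stop("need >= 2 ASVs and >= 3 samples")
  z <- clr_transform(filtered, pseudocount = 0)
  n <- nrow(z)
  v <- apply(z, 1L, var)
  cc <- stats::cov(t(z))
  vd <- outer(v, v, "+") - 2 * cc          # var(z_i - z_j)
  denom <- outer(v, v, "+")
  rho <- 1 - vd / denom
  rho[denom == 0] <- NA_real_
  diag(rho) <- 1
  dimnames(rho) <- list(rownames(filtered), rownames(filtered))
  rho
}

#' Permutation-calibrated significance cutoff for rho
#'
#' Shuffles each ASV's counts independently across samples (destroying
#' inter-ASV association while preserving marginals), recomputes rho, and
#' estimates, for each candidate cutoff on a grid, the false discovery rate
#' as the mean permuted exceedance count divided by the observed exceedance
#' count. Returns the smallest cutoff achieving `FDR < fdr`; when no cutoff
#' attains the target all pairs are non-significant (`cutoff = Inf`).
#'
#' @param filtered Members-by-samples matrix from [preprocess_genus()].
#' @param n_perm Number of permutations (default 100; must be > 0).
#' @param fdr Target FDR (default 0.05).
#' @param seed Integer seed.
#' @param grid Candidate cutoffs (default 0 to 1 in steps of 0.05).
#' @return A list: `cutoff`, `fdr_curve` (data.frame cutoff/fdr), and
#'   `significant`, a logical matrix flagging pairs at or above the cutoff.
#' @export
calibrate_fdr_cutoff <- function(filtered, n_perm = 100, fdr = 0.05,
                                 seed = 20231201,
                                 grid = seq(0, 1, by = 0.05)) {
  if (n_perm <= 0) stop("n_perm must be > 0")
  obs <- rho_matrix(filtered)
  up <- upper.tri(obs)
  obs_v <- obs[up]
  n_exceed_obs <- vapply(grid, function(cc) sum(obs_v >= cc, na.rm = TRUE), 0)
  perm_exceed <- matrix(0, n_perm, length(grid))
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      pm <- t(apply(filtered, 1L, sample))
      pv <- rho_matrix(pm)[up]
      perm_exceed[r, ] <- vapply(grid,
                                 function(cc) sum(pv >= cc, na.rm = TRUE), 0)
    }
  })
  fdr_hat <- colMeans(perm_exceed) / pmax(1, n_exceed_obs)
  ok <- which(fdr_hat < fdr)
  cutoff <- if (length(ok)) grid[min(ok)] else Inf
  if (!is.finite(cutoff))
    message("no cutoff attains FDR < ", fdr, "; all pairs non-significant")
  sig <- !is.na(obs) & obs >= cutoff
  diag(sig) <- FALSE
  list(cutoff = cutoff,
       fdr_curve = data.frame(cutoff = grid, fdr = fdr_hat),
       significant = sig)
}

#' Select genera with enough closely related ASVs
#'
#' A genus qualifies when the largest connected component of its ASV graph,
#' linking pairs at nucleotide divergence <= `max_div`, has at least
#' `min_asvs` members (`rule = "component"`); analysis is restricted to that
#' component. The stricter `rule = "diameter"` requires all retained pairs
#' to be within `max_div` of each other.
#'
#' @param seqs Named character vector of sequences.
#' @param taxonomy Data.frame with `asv_id` and `genus`.
#' @param cm Optional count matrix restricting candidates to counted ASVs.
#' @param min_asvs Minimum component size (default 10).
#' @param max_div Maximum nucleotide divergence defining "closely related"
#'   (default 5 nt).
#' @param rule `"component"` (default) or `"diameter"`.
#' @return A named list mapping each qualifying genus to the ASV ids of its
#'   selected component.
#' @export
select_genera <- function(seqs, taxonomy, cm = NULL, min_asvs = 10,
                          max_div = 5, rule = c("component", "diameter")) {
  rule <- match.arg(rule)
  out <- list()
  for (g in unique(taxonomy$genus)) {
    ids <- taxonomy$asv_id[taxonomy$genus == g]
    if (!is.null(cm)) ids <- intersect(ids, rownames(cm))
    if (length(ids) < min_asvs) next
    dv <- pairwise_divergence(seqs, ids)
    # union-find over pairs within max_div
    comp <- setNames(seq_along(ids), ids)
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    link <- dv[dv$divergence <= max_div, , drop = FALSE]
    for (k in seq_len(nrow(link))) {
      a <- find(match(link$asv_1[k], ids))
      b <- find(match(link$asv_2[k], ids))
      if (a != b) comp[b] <- a
    }
    roots <- vapply(seq_along(ids), find, 0L)
    tab <- table(roots)
    big <- as.integer(names(tab)[which.max(tab)])
    members <- ids[roots == big]
    if (rule == "diameter") {
      dd <- dv[dv$asv_1 %in% members & dv$asv_2 %in% members, ]
      if (nrow(dd) && max(dd$divergence) > max_div) next
    }
    if (length(members) >= min_asvs) out[[g]] <- members
  }
  out
}

#' OLS fit of rho against nucleotide divergence
#'
#' @param rho Symmetric rho matrix ([rho_matrix()]).
#' @param divergence Data.frame from [pairwise_divergence()].
#' @param min_pairs Minimum pairs with both values (default 5).
#' @return One-row data.frame: slope, intercept, r2, p (two-sided slope
#'   test), n_pairs; or `NULL` when the fit is not possible (too few pairs
#'   or zero divergence variance).
#' @export
fit_rho_vs_divergence <- function(rho, divergence, min_pairs = 5) {
  key <- rownames(rho)
  dd <- divergence[divergence$asv_1 %in% key & divergence$asv_2 %in% key, ]
  if (!nrow(dd)) return(NULL)
  r <- rho[cbind(match(dd$asv_1, key), match(dd$asv_2, key))]
  ok <- !is.na(r)
  dd <- dd[ok, ]; r <- r[ok]
  if (length(r) < min_pairs) return(NULL)
  if (var(dd$divergence) == 0) {
    message("zero divergence variance; model skipped")
    return(NULL)
  }
  fit <- lm(r ~ dd$divergence)
  sm <- summary(fit)
  data.frame(slope = unname(coef(fit)[2L]),
             intercept = unname(coef(fit)[1L]),
             r2 = sm$r.squared,
             p = sm$coefficients[2L, 4L],
             n_pairs = length(r), stringsAsFactors = FALSE)
}

#' Per-ASV environmental niche centroids and rho vs environmental distance
#'
#' The niche centroid of an ASV is the abundance-weighted mean of
#' standardized log-scaled environmental variables across samples; the pair
#' distance is the Euclidean distance between centroids. Rho is then
#' regressed on that distance by OLS.
#'
#' @param cm Members-by-samples count matrix (raw counts for weighting).
#' @param meta Metadata with environmental columns.
#' @param env_vars Environmental variable names (missing ones are dropped
#'   with a message).
#' @return A matrix of centroids (ASVs x variables).
#' @export
niche_centroids <- function(cm, meta, env_vars) {
  miss <- setdiff(env_vars, colnames(meta))
  if (length(miss)) {
    message("dropping missing env variable(s): ", paste(miss, collapse = ", "))
    env_vars <- setdiff(env_vars, miss)
  }
  if (!length(env_vars)) stop("no environmental variables available")
  E <- as.matrix(meta[colnames(cm), env_vars, drop = FALSE])
  keep <- complete.cases(E)
  E <- scale(log1p(E[keep, , drop = FALSE]))
  w <- cm[, keep, drop = FALSE]
  ctr <- (w %*% E) / rowSums(w)
  rownames(ctr) <- rownames(cm)
  ctr
}

#' @rdname niche_centroids
#' @param rho Symmetric rho matrix.
#' @param centroids Output of [niche_centroids()].
#' @param min_pairs Minimum number of complete pairs.
#' @return For `fit_rho_vs_envdist`: one-row data.frame as in
#'   [fit_rho_vs_divergence()].
#' @export
fit_rho_vs_envdist <- function(rho, centroids, min_pairs = 5) {
  key <- intersect(rownames(rho), rownames(centroids))
  if (length(key) < 2) return(NULL)
  d <- as.matrix(dist(centroids[key, , drop = FALSE]))
  up <- upper.tri(d)
  r <- rho[key, key][up]
  x <- d[up]
  ok <- !is.na(r) & !is.na(x)
  if (sum(ok) < min_pairs || var(x[ok]) == 0) return(NULL)
  fit <- lm(r[ok] ~ x[ok])
  sm <- summary(fit)
  data.frame(slope = unname(coef(fit)[2L]),
             intercept = unname(coef(fit)[1L]),
             r2 = sm$r.squared, p = sm$coefficients[2L, 4L],
             n_pairs = sum(ok), stringsAsFactors = FALSE)
}

#' Genus-level niche proportionality analysis
#'
#' End-to-end per-genus workflow: select genera with at least `min_asvs`
#' closely related ASVs (divergence <= `max_div`), preprocess each genus,
#' compute rho with a permutation-calibrated FDR cutoff, and fit
#' rho ~ nucleotide divergence (and, when metadata is supplied,
#' rho ~ environmental niche distance). P-values are BH-adjusted across
#' genera within each model family.
#'
#' @param cm Features-by-samples count matrix.
#' @param seqs Named character vector of sequences.
#' @param taxonomy Data.frame with `asv_id` and `genus`.
#' @param meta Optional metadata for the environmental-distance model.
#' @param env_vars Environmental variables for niche centroids.
#' @param min_asvs,max_div,rule Genus selection (see [select_genera()]).
#' @param n_perm,fdr FDR calibration (see [calibrate_fdr_cutoff()]).
#' @param seed Master seed.
#' @return A list: `genus_models` (rho ~ divergence, one row per genus with
#'   `p_adj` and `significant`), `env_models` (rho ~ env distance), and
#'   `pairs`, a per-genus list with the rho matrix, cutoff and pair table.
#' @export
niche_proportionality <- function(cm, seqs, taxonomy, meta = NULL,
                                  env_vars = c("pH", "Fe", "Mn", "Zn", "Cu",
                                               "Cd", "sulfate", "EC", "DO",
                                               "ORP", "temperature"),
                                  min_asvs = 10, max_div = 5,
                                  rule = "component", n_perm = 100,
                                  fdr = 0.05, seed = 20231201) {
  sel <- select_genera(seqs, taxonomy, cm, min_asvs, max_div, rule)
  gm <- list(); em <- list(); pr <- list()
  for (g in names(sel)) {
    filt <- preprocess_genus(cm, taxonomy, g, members = sel[[g]])
    if (is.null(filt)) next
    rho <- rho_matrix(filt)
    cal <- calibrate_fdr_cutoff(filt, n_perm = n_perm, fdr = fdr,
                                seed = derive_seed(seed, g))
    dv <- pairwise_divergence(seqs, rownames(filt))
    fit <- fit_rho_vs_divergence(rho, dv)
    if (!is.null(fit)) gm[[g]] <- cbind(genus = g, fit)
    if (!is.null(meta)) {
      ctr <- niche_centroids(cm[rownames(filt), colnames(filt),
                                drop = FALSE],
                             meta, env_vars)
      ef <- fit_rho_vs_envdist(rho, ctr)
      if (!is.null(ef)) em[[g]] <- cbind(genus = g, ef)
    }
    pr[[g]] <- list(rho = rho, cutoff = cal$cutoff,
                    significant = cal$significant, divergence = dv)
  }
  finalize <- function(lst) {
    if (!length(lst)) return(NULL)
    df <- do.call(rbind, c(lst, list(make.row.names = FALSE)))
    df$p_adj <- bh_adjust(df$p)
    df$significant <- df$p_adj < 0.05
    df
  }
  list(genus_models = finalize(gm), env_models = finalize(em), pairs = pr)
}
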