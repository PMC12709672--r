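#' Alpha diversity (observed richness, Chao1, Shannon)
#'
#' Chao1 uses the bias-corrected estimator
#' `S_obs + f1 (f1 - 1) / (2 (f2 + 1))` with `f1`/`f2` the singleton and
#' doubleton counts; Shannon uses natural logs on relative abundances.
#' Empty samples yield `NA` records.
#'
#' @param cm Features-by-samples integer count matrix.
#' @return A data.frame, one row per sample: `sample_id`, `richness`,
#'   `chao1`, `shannon`.
#' @export
alpha_diversity <- function(cm) {
  res <- lapply(colnames(cm), function(s) {
    x <- cm[, s]
    if (sum(x) == 0)
      return(data.frame(sample_id = s, richness = NA_integer_,
                        chao1 = NA_real_, shannon = NA_real_))
    sobs <- sum(x > 0)
    f1 <- sum(x == 1); f2 <- sum(x == 2)
    chao <- sobs + f1 * (f1 - 1) / (2 * (f2 + 1))
    p <- x[x > 0] / sum(x)
    data.frame(sample_id = s, richness = sobs, chao1 = chao,
               shannon = -sum(p * log(p)), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

# Tie-corrected Dunn post-hoc z-tests after Kruskal-Wallis,
# Bonferroni-multiplied.
dunn_posthoc <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  N <- length(values)
  rk <- rank(values)
  tie <- table(rk)
  tiecor <- sum(tie^3 - tie) / (12 * (N - 1))
  rbar <- tapply(rk, groups, mean)
  ns <- table(groups)
  lev <- levels(groups)
  pairs <- combn(lev, 2L)
  n_pairs <- ncol(pairs)
  res <- lapply(seq_len(n_pairs), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    se <- sqrt((N * (N + 1) / 12 - tiecor) * (1 / ns[a] + 1 / ns[b]))
    z <- (rbar[a] - rbar[b]) / se
    data.frame(group_1 = a, group_2 = b, z = unname(z),
               p = min(1, 2 * pnorm(-abs(z)) * n_pairs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Rank-based group tests
#'
#' `method = "wilcoxon"`: all pairwise two-sided Wilcoxon rank-sum tests
#' with BH adjustment across the battery. `method =
#' "kruskal_dunn_bonferroni"`: a Kruskal-Wallis omnibus test followed by
#' Dunn's pairwise z-tests with Bonferroni multiplication. Returns `NULL`
#' (with a message) when fewer than 2 groups have at least 3 values.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @param method Test battery.
#' @return A list with `omnibus` (Kruskal-Wallis row, or `NULL`) and
#'   `pairwise` (data.frame of pairwise results).
#' @export
group_test <- function(values, groups,
                       method = c("wilcoxon", "kruskal_dunn_bonferroni")) {
  method <- match.arg(method)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(as.character(groups[ok]))
  sizes <- table(groups)
  if (sum(sizes >= 3) < 2) {
    message("degenerate groups: need >= 2 groups with >= 3 values")
    return(NULL)
  }
  if (method == "wilcoxon") {
    pairs <- combn(levels(groups), 2L)
    pw <- lapply(seq_len(ncol(pairs)), function(j) {
      a <- values[groups == pairs[1L, j]]
      b <- values[groups == pairs[2L, j]]
      p <- suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
      data.frame(group_1 = pairs[1L, j], group_2 = pairs[2L, j], p = p,
                 stringsAsFactors = FALSE)
    })
    pw <- do.call(rbind, c(pw, list(make.row.names = FALSE)))
    pw$p_adj <- bh_adjust(pw$p)
    list(omnibus = NULL, pairwise = pw)
  } else {
    kw <- kruskal.test(values, groups)
    list(omnibus = data.frame(statistic = unname(kw$statistic),
                              df = unname(kw$parameter),
                              p = kw$p.value),
         pairwise = dunn_posthoc(values, groups))
  }
}

#' Analysis of similarities (ANOSIM)
#'
#' `R = (mean between-group dissimilarity rank - mean within-group rank) /
#' (n(n-1)/4)`, with significance from permutation of group labels.
#'
#' @param d Square symmetric dissimilarity matrix or `dist`.
#' @param groups Group labels per sample (no singleton groups).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A list with `R` and `p`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 20231201) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups must match the dissimilarity matrix")
  if (min(table(groups)) < 2) stop("groups of size 1 are not allowed")
  up <- upper.tri(d)
  rk <- rank(d[up])
  stat <- function(g) {
    within <- outer(g, g, "==")[up]
    (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
  }
  R <- stat(groups)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(r)
    stat(sample(groups)), 0))
  list(R = R, p = (1 + sum(perm >= R)) / (n_perm + 1))
}

#' Spearman correlations between ASVs and environmental variables
#'
#' Per (ASV, variable) cell: tie-corrected Spearman rho with a two-sided
#' p-value, with significance stars (`*` p < 0.05, `**` p < 0.01) mirroring
#' heatmap conventions. Constant vectors yield `NA` cells.
#'
#' @param ra Features-by-samples relative-abundance matrix (already
#'   restricted to the sample subset of interest).
#' @param meta Metadata with environmental columns (rownames = sample ids).
#' @param env_vars Variables to correlate.
#' @return A data.frame: `asv_id`, `variable`, `rho`, `p`, `stars`.
#' @export
spearman_env <- function(ra, meta,
                         env_vars = c("pH", "Fe", "Mn", "Zn", "Cu", "Cd",
                                      "sulfate", "EC", "DO", "ORP",
                                      "temperature")) {
  env_vars <- intersect(env_vars, colnames(meta))
  E <- meta[colnames(ra), env_vars, drop = FALSE]
  rows <- list()
  for (a in rownames(ra)) for (v in env_vars) {
    x <- ra[a, ]; y <- E[[v]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 4 || var(x[ok]) == 0 || var(y[ok]) == 0) {
      rho <- NA_real_; p <- NA_real_
    } else {
      ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                      exact = FALSE))
      rho <- unname(ct$estimate); p <- ct$p.value
    }
    rows[[paste(a, v)]] <- data.frame(
      asv_id = a, variable = v, rho = rho, p = p,
      stars = if (is.na(p)) "" else if (p < 0.01) "**" else
        if (p < 0.05) "*" else "",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# t-approximation p-value for a correlation coefficient.
cor_p <- function(r, n) {
  t <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  2 * pt(-abs(t), n - 2)
}

#' Co-occurrence network edges
#'
#' All ASV-pair Spearman correlations, BH-adjusted across pairs; edges are
#' retained when `rho >= rho_min` (default 0.6, positive co-occurrence) and
#' adjusted `p < p_adj_max` (default 0.01). Each unordered pair appears
#' once.
#'
#' @param ra Features-by-samples relative-abundance matrix (>= 10 samples).
#' @param rho_min,p_adj_max Edge thresholds.
#' @return A data.frame of edges: `asv_1`, `asv_2`, `rho`, `p_adj`.
#' @export
cooccurrence_network <- function(ra, rho_min = 0.6, p_adj_max = 0.01) {
  if (ncol(ra) < 10) stop("need >= 10 samples")
  R <- suppressWarnings(cor(t(ra), method = "spearman"))
  up <- which(upper.tri(R), arr.ind = TRUE)
  rho <- R[up]
  p <- cor_p(rho, ncol(ra))
  p_adj <- bh_adjust(p)
  keep <- !is.na(rho) & rho >= rho_min & p_adj < p_adj_max
  data.frame(asv_1 = rownames(R)[up[keep, 1L]],
             asv_2 = rownames(R)[up[keep, 2L]],
             rho = rho[keep], p_adj = p_adj[keep],
             stringsAsFactors = FALSE)
}

#' Environment-community dissimilarity association (Mantel-type)
#'
#' Spearman Mantel correlation between Bray-Curtis community dissimilarity
#' and Euclidean distance on standardized log-scaled environmental
#' variables, with significance from matrix permutations. Samples with
#' incomplete environmental rows are dropped with a message.
#'
#' @param ra Features-by-samples relative-abundance matrix.
#' @param meta Metadata with environmental columns.
#' @param env_vars Variables defining environmental distance.
#' @param n_perm Matrix permutations (default 999).
#' @param seed Integer seed.
#' @return A list with `statistic` (Mantel r) and `p`.
#' @export
env_community_dissim <- function(ra, meta,
                                 env_vars = c("pH", "Fe", "Mn", "Zn", "Cu",
                                              "Cd", "sulfate", "EC", "DO",
                                              "ORP", "temperature"),
                                 n_perm = 999, seed = 20231201) {
  env_vars <- intersect(env_vars, colnames(meta))
  E <- as.matrix(meta[colnames(ra), env_vars, drop = FALSE])
  ok <- complete.cases(E)
  if (!all(ok))
    message("dropping ", sum(!ok), " sample(s) with incomplete env data")
  if (sum(ok) < 5) stop("need >= 5 samples with complete env data")
  dc <- vegan::vegdist(t(ra[, ok, drop = FALSE]), method = "bray")
  de <- dist(scale(log1p(E[ok, , drop = FALSE])))
  mt <- with_seed(seed, vegan::mantel(dc, de, method = "spearman",
                                      permutations = n_perm))
  list(statistic = unname(mt$statistic), p = mt$signif)
}
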