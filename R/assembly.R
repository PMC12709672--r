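#' Phylogenetic bins
#'
#' Groups tree tips by single-linkage clustering of cophenetic distance
#' truncated at `ds`; bins smaller than `min_size` are merged into the
#' phylogenetically nearest bin (minimum mean inter-bin cophenetic
#' distance). Bin weights are the mean across samples of the bin's summed
#' relative abundance and sum to 1.
#'
#' @param tree Rooted [ape::phylo] whose tips cover the analyzed ASVs.
#' @param cm Features-by-samples count matrix (rows must be tree tips; extra
#'   tips are pruned).
#' @param ds Cophenetic distance cut (default 0.2).
#' @param min_size Minimum bin size after merging (default 12).
#' @return A list of class `amd_bins`: `membership` (named bin id per ASV),
#'   `bins` (list of member vectors), `weights` (named, sums to 1), and the
#'   cophenetic distance matrix `coph`.
#' @export
build_bins <- function(tree, cm, ds = 0.2, min_size = 12) {
  ids <- rownames(cm)
  miss <- setdiff(ids, tree$tip.label)
  if (length(miss)) stop("tree is missing tips: ", paste(head(miss, 5),
                                                         collapse = ", "))
  if (length(setdiff(tree$tip.label, ids)))
    tree <- ape::keep.tip(tree, ids)
  if (all(tree$edge.length == 0)) stop("unresolved tree: all branch lengths zero")
  coph <- ape::cophenetic.phylo(tree)[ids, ids]
  memb <- cutree(hclust(as.dist(coph), method = "single"), h = ds)
  # merge undersized bins into the nearest (mean inter-bin distance) bin
  repeat {
    tab <- table(memb)
    if (length(tab) == 1L || min(tab) >= min_size) break
    small <- as.integer(names(tab)[which.min(tab)])
    inside <- memb == small
    others <- setdiff(unique(memb), small)
    md <- vapply(others, function(b)
      mean(coph[inside, memb == b, drop = FALSE]), 0)
    memb[inside] <- others[which.min(md)]
  }
  lev <- sort(unique(memb))
  bin_id <- paste0("bin", match(memb, lev))
  names(bin_id) <- ids
  bins <- split(ids, bin_id)
  ra <- to_relative(cm)
  w <- vapply(bins, function(m) mean(colSums(ra[m, , drop = FALSE])), 0)
  out <- list(membership = bin_id, bins = bins, weights = w / sum(w),
              coph = coph)
  class(out) <- "amd_bins"
  out
}

# Abundance-weighted beta mean-nearest-taxon / mean-pairwise distance
# between two within-bin relative abundance vectors (p1, p2 over member
# index sets A, B; D is the member cophenetic matrix).
bmntd_pair <- function(D, i1, p1, i2, p2) {
  m1 <- apply(D[i1, i2, drop = FALSE], 1L, min)
  m2 <- apply(D[i1, i2, drop = FALSE], 2L, min)
  0.5 * (sum(p1 * m1) + sum(p2 * m2))
}

bmpd_pair <- function(D, i1, p1, i2, p2) {
  as.numeric(p1 %*% D[i1, i2, drop = FALSE] %*% p2)
}

#' Null-model z-score of phylogenetic turnover for one sample pair in a bin
#'
#' Observed abundance-weighted beta-MNTD (or beta-MPD) within the bin,
#' standardized against a null distribution obtained by shuffling tip
#' identities among the bin's members while holding abundances fixed:
#' `z = (obs - mean(null)) / sd(null)` (the beta nearest taxon index when
#' `metric = "bMNTD"`).
#'
#' @param cm Features-by-samples count matrix.
#' @param coph Cophenetic distance matrix over (at least) the bin members.
#' @param members Bin member ASV ids.
#' @param pair Character vector of two sample ids.
#' @param metric `"bMNTD"` (default) or `"bMPD"`.
#' @param n_null Null replicates (default 199).
#' @param seed Integer seed.
#' @param weighted Abundance-weighted (default) or presence-based weights.
#' @param exclude_conspecifics For `bMNTD`, whether the nearest-taxon search
#'   ignores the focal taxon itself in the other sample (default `TRUE`).
#'   With amplicon data full of co-occurring near-identical variants,
#'   including conspecifics zeroes out every shared taxon's contribution
#'   and blinds the index precisely where microdiverse communities carry
#'   signal; excluding them asks where each taxon's nearest relative sits.
#' @return A list: `z`, `obs`, `null_mean`, `null_sd`. `z` is `NA` when the
#'   null spread is zero or the bin is absent from either sample.
#' @export
beta_index <- function(cm, coph, members, pair, metric = c("bMNTD", "bMPD"),
                       n_null = 199, seed = 20231201, weighted = TRUE,
                       exclude_conspecifics = TRUE) {
  metric <- match.arg(metric)
  D <- coph[members, members, drop = FALSE]
  if (metric == "bMNTD" && exclude_conspecifics) diag(D) <- Inf
  x1 <- cm[members, pair[1L]]
  x2 <- cm[members, pair[2L]]
  if (sum(x1) == 0 || sum(x2) == 0)
    return(list(z = NA_real_, obs = NA_real_, null_mean = NA_real_,
                null_sd = NA_real_))
  if (!weighted) { x1 <- as.numeric(x1 > 0); x2 <- as.numeric(x2 > 0) }
  i1 <- which(x1 > 0); i2 <- which(x2 > 0)
  p1 <- x1[i1] / sum(x1); p2 <- x2[i2] / sum(x2)
  fn <- if (metric == "bMNTD") bmntd_pair else bmpd_pair
  obs <- fn(D, i1, p1, i2, p2)
  if (!is.finite(obs))
    return(list(z = NA_real_, obs = NA_real_, null_mean = NA_real_,
                null_sd = NA_real_))
  m <- length(members)
  nulls <- with_seed(seed, vapply(seq_len(n_null), function(r) {
    pp <- sample(m)
    fn(D, pp[i1], p1, pp[i2], p2)
  }, 0))
  mu <- mean(nulls); sdev <- sd(nulls)
  z <- if (is.na(sdev) || sdev == 0) NA_real_ else (obs - mu) / sdev
  list(z = z, obs = obs, null_mean = mu, null_sd = sdev)
}

# Batched beta z-scores for all retained sample pairs of one bin. One set of
# `n_null` tip permutations is shared by all pairs; for each permutation the
# min-distance profile to every sample's present set is computed once, so a
# pair's null bMNTD is two weighted sums.
bin_beta_z <- function(counts_bin, D, metric = "bMNTD", n_null = 199,
                       seed = 1L, weighted = TRUE,
                       exclude_conspecifics = TRUE) {
  m <- nrow(counts_bin); n <- ncol(counts_bin)
  if (metric == "bMNTD" && exclude_conspecifics) diag(D) <- Inf
  if (!weighted) counts_bin <- (counts_bin > 0) + 0
  tot <- colSums(counts_bin)
  P <- sweep(counts_bin, 2L, pmax(tot, 1), "/")   # weighted presence
  present <- lapply(seq_len(n), function(s) which(counts_bin[, s] > 0))
  min_profile <- function(Dm) {
    # MD[i, s] = min_{j in present(s)} Dm[i, j]
    vapply(present, function(B) {
      if (!length(B)) return(rep(NA_real_, m))
      do.call(pmin, lapply(B, function(j) Dm[, j]))
    }, numeric(m))
  }
  pair_stat <- function(Dm) {
    if (metric == "bMNTD") {
      MD <- min_profile(Dm)
      X <- crossprod(P, MD)          # X[s1, s2] = sum_i P[i,s1] MD[i,s2]
      0.5 * (X + t(X))
    } else {
      X <- crossprod(P, Dm) %*% P
      0.5 * (X + t(X))
    }
  }
  obs <- pair_stat(D)
  nulls <- with_seed(seed, lapply(seq_len(n_null), function(r) {
    pp <- sample(m)
    pair_stat(D[pp, pp])
  }))
  obs[!is.finite(obs)] <- NA_real_
  arr <- simplify2array(nulls)
  mu <- apply(arr, c(1, 2), mean)
  sdev <- apply(arr, c(1, 2), sd)
  z <- (obs - mu) / sdev
  z[sdev == 0 | !is.finite(mu)] <- NA_real_
  empty <- tot == 0
  z[empty, ] <- NA_real_; z[, empty] <- NA_real_
  dimnames(z) <- list(colnames(counts_bin), colnames(counts_bin))
  z
}

#' Modified Raup-Crick turnover for one sample pair in a bin
#'
#' Observed within-bin Bray-Curtis dissimilarity compared to null
#' communities that preserve each sample's within-bin richness and total
#' reads, drawing taxa with probability proportional to occupancy and
#' filling abundances proportional to mean relative abundance.
#' `RC = 2 * ((#null < obs) + 0.5 * (#null = obs)) / n_null - 1`, in
#' \[-1, 1\]; +1 means far more turnover than expected by chance.
#'
#' @param cm Features-by-samples count matrix.
#' @param members Bin member ASV ids.
#' @param pair Character vector of two sample ids.
#' @param n_null Null replicates (default 999).
#' @param seed Integer seed.
#' @return RC value, or `NA` when the bin is empty in either sample.
#' @export
raup_crick <- function(cm, members, pair, n_null = 999, seed = 20231201) {
  x <- cm[members, , drop = FALSE]
  x1 <- x[, pair[1L]]; x2 <- x[, pair[2L]]
  if (sum(x1) == 0 || sum(x2) == 0) return(NA_real_)
  occ <- rowMeans(x > 0)
  mra <- rowMeans(to_relative(x[, colSums(x) > 0, drop = FALSE]))
  bc <- function(a, b) sum(abs(a - b)) / sum(a + b)
  obs <- bc(x1, x2)
  draw <- function(k, N) {
    v <- numeric(length(members))
    sel <- sample(length(members), k, prob = occ)
    v[sel] <- rmultinom(1L, N, mra[sel])
    v
  }
  k1 <- sum(x1 > 0); k2 <- sum(x2 > 0)
  N1 <- sum(x1); N2 <- sum(x2)
  nulls <- with_seed(seed, vapply(seq_len(n_null), function(r)
    bc(draw(k1, N1), draw(k2, N2)), 0))
  2 * ((sum(nulls < obs) + 0.5 * sum(nulls == obs)) / n_null) - 1
}

# Batched RC for selected pairs of a bin: per null replicate one null
# community is drawn per sample and Bray-Curtis is read off for all needed
# pairs.
bin_rc <- function(counts_bin, pairs_idx, n_null = 999, seed = 1L) {
  m <- nrow(counts_bin); n <- ncol(counts_bin)
  occ <- rowMeans(counts_bin > 0)
  pos <- colSums(counts_bin) > 0
  mra <- rowMeans(to_relative(counts_bin[, pos, drop = FALSE]))
  k <- colSums(counts_bin > 0); N <- colSums(counts_bin)
  bc <- function(a, b) {
    s <- sum(a + b)
    if (s == 0) return(NA_real_)
    sum(abs(a - b)) / s
  }
  obs <- apply(pairs_idx, 1L, function(pr)
    bc(counts_bin[, pr[1L]], counts_bin[, pr[2L]]))
  lt <- numeric(nrow(pairs_idx)); eq <- numeric(nrow(pairs_idx))
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      nullm <- matrix(0, m, n)
      for (s in which(k > 0)) {
        sel <- sample(m, k[s], prob = occ)
        nullm[sel, s] <- rmultinom(1L, N[s], mra[sel])
      }
      nb <- apply(pairs_idx, 1L, function(pr)
        bc(nullm[, pr[1L]], nullm[, pr[2L]]))
      lt <- lt + (nb < obs)
      eq <- eq + (nb == obs)
    }
  })
  2 * ((lt + 0.5 * eq) / n_null) - 1
}

#' Classify a sample pair's assembly process
#'
#' `z > z_thresh` = heterogeneous selection (HeS); `z < -z_thresh` =
#' homogeneous selection (HoS); otherwise RC decides: `rc > rc_thresh` =
#' dispersal limitation (DL), `rc < -rc_thresh` = homogenizing dispersal
#' (HD), else ecological drift (DR). Missing z falls through to DR.
#'
#' @param z Beta-index z-score(s).
#' @param rc Raup-Crick value(s); only consulted when `|z| <= z_thresh`.
#' @param z_thresh,rc_thresh Thresholds (defaults 1.96 and 0.95).
#' @return Character vector over `{HoS, HeS, DL, HD, DR}`.
#' @export
classify_process <- function(z, rc, z_thresh = 1.96, rc_thresh = 0.95) {
  out <- rep("DR", length(z))
  sel_he <- !is.na(z) & z > z_thresh
  sel_ho <- !is.na(z) & z < -z_thresh
  out[sel_he] <- "HeS"
  out[sel_ho] <- "HoS"
  mid <- !(sel_he | sel_ho)
  out[mid & !is.na(rc) & rc > rc_thresh] <- "DL"
  out[mid & !is.na(rc) & rc < -rc_thresh] <- "HD"
  out
}

#' Aggregate pair-bin process calls into process importances
#'
#' Community level: for each pair, bin weights are renormalized over the
#' bins retained for that pair and the indicator of each process is
#' weight-averaged; the community importance is the mean over pairs.
#' Sample level: the same restricted to pairs containing the sample. Five
#' fractions (HoS, HeS, DL, HD, DR) summing to 1 at every scope.
#'
#' @param pair_bin Data.frame with `sample_1`, `sample_2`, `bin`, `process`.
#' @param weights Named bin weights from [build_bins()].
#' @return A list: `community` (named numeric, sums to 1) and `sample`
#'   (samples x process matrix, rows sum to 1).
#' @export
aggregate_importance <- function(pair_bin, weights) {
  procs <- c("HoS", "HeS", "DL", "HD", "DR")
  pair_key <- paste(pair_bin$sample_1, pair_bin$sample_2, sep = "\r")
  w <- weights[pair_bin$bin]
  wn <- w / ave(w, pair_key, FUN = sum)      # renormalize per pair
  per_pair <- rowsum(wn * outer(pair_bin$process, procs, "=="),
                     pair_key)
  colnames(per_pair) <- procs
  community <- colMeans(per_pair)
  samples <- sort(unique(c(pair_bin$sample_1, pair_bin$sample_2)))
  keys <- do.call(rbind, strsplit(rownames(per_pair), "\r", fixed = TRUE))
  smat <- t(vapply(samples, function(s) {
    colMeans(per_pair[keys[, 1L] == s | keys[, 2L] == s, , drop = FALSE])
  }, numeric(5L)))
  list(community = community, sample = smat)
}

#' Phylogenetic-bin null-model partitioning of community assembly
#'
#' Full workflow: build phylogenetic bins, compute the null-model z-score of
#' phylogenetic turnover (beta-NTI by default) for every sample pair within
#' every bin, compute the modified Raup-Crick metric for pairs not decided
#' by selection, classify each pair-bin into one of five processes, and
#' aggregate to sample- and community-level importances with
#' abundance-based bin weights. Pairs where a bin is absent from one sample
#' are excluded for that bin (weights renormalized per pair); pairs with an
#' undefined z fall to drift.
#'
#' @param cm Features-by-samples count matrix.
#' @param tree Rooted phylogeny covering the ASVs.
#' @param ds,min_size Bin construction (see [build_bins()]).
#' @param metric `"bMNTD"` (beta-NTI, default) or `"bMPD"` (beta-NRI-style).
#' @param n_null_z,n_null_rc Null replicates for the z-score and Raup-Crick
#'   (defaults 199 and 999).
#' @param z_thresh,rc_thresh Classification thresholds.
#' @param weighted Abundance-weighted metrics (default TRUE).
#' @param exclude_conspecifics Nearest-taxon search ignores the focal taxon
#'   itself (see [beta_index()]).
#' @param seed Master seed (bins get derived substreams).
#' @return A list of class `amd_assembly`: `pair_bin` (long data.frame with
#'   z, rc, process), `bins`, `importance` (community named vector),
#'   `sample_importance` (samples x 5 matrix).
#' @export
assembly_processes <- function(cm, tree, ds = 0.2, min_size = 12,
                               metric = c("bMNTD", "bMPD"),
                               n_null_z = 199, n_null_rc = 999,
                               z_thresh = 1.96, rc_thresh = 0.95,
                               weighted = TRUE, exclude_conspecifics = TRUE,
                               seed = 20231201) {
  metric <- match.arg(metric)
  bins <- build_bins(tree, cm, ds = ds, min_size = min_size)
  samples <- colnames(cm)
  res <- list()
  for (b in names(bins$bins)) {
    mem <- bins$bins[[b]]
    sub <- cm[mem, , drop = FALSE]
    tot <- colSums(sub)
    keep <- which(tot > 0)
    if (length(keep) < 2) next
    z <- bin_beta_z(sub[, keep, drop = FALSE],
                    bins$coph[mem, mem, drop = FALSE],
                    metric = metric, n_null = n_null_z,
                    seed = derive_seed(seed, paste0("z_", b)),
                    weighted = weighted,
                    exclude_conspecifics = exclude_conspecifics)
    idx <- which(upper.tri(z), arr.ind = TRUE)
    df <- data.frame(sample_1 = samples[keep][idx[, 1L]],
                     sample_2 = samples[keep][idx[, 2L]],
                     bin = b, z = z[idx], rc = NA_real_,
                     stringsAsFactors = FALSE)
    need_rc <- which(is.na(df$z) | abs(df$z) <= z_thresh)
    if (length(need_rc)) {
      df$rc[need_rc] <- bin_rc(sub[, keep, drop = FALSE],
                               cbind(idx[need_rc, 1L], idx[need_rc, 2L]),
                               n_null = n_null_rc,
                               seed = derive_seed(seed, paste0("rc_", b)))
    }
    res[[b]] <- df
  }
  pair_bin <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  pair_bin$process <- classify_process(pair_bin$z, pair_bin$rc,
                                       z_thresh, rc_thresh)
  agg <- aggregate_importance(pair_bin, bins$weights)
  out <- list(pair_bin = pair_bin, bins = bins,
              importance = agg$community, sample_importance = agg$sample)
  class(out) <- "amd_assembly"
  out
}

#' @export
print.amd_assembly <- function(x, ...) {
  cat("Community assembly partition over", length(x$bins$bins), "bins:\n")
  print(round(x$importance, 3))
  invisible(x)
}
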