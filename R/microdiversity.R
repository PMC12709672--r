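#' Greedy centroid clustering of ASVs into OTUs
#'
#' Candidates are sorted by decreasing total read count (ties broken by ASV
#' id); each sequence joins the first existing centroid with global-alignment
#' identity at or above the threshold (default 98.7\%), otherwise it founds a
#' new cluster. Identity is matches / alignment columns, terminal gaps
#' excluded.
#'
#' @param seqs Named character vector of ASV sequences.
#' @param cm Features-by-samples count matrix (defines abundances; every
#'   counted ASV needs a sequence).
#' @param identity Identity threshold in \[0, 1\].
#' @return A data.frame, one row per OTU: `otu_id`, `centroid`, comma-joined
#'   `members`, `n_members`, `total_reads`; with attribute `membership`, a
#'   named vector mapping every ASV to its OTU.
#' @export
cluster_otus <- function(seqs, cm, identity = 0.987) {
  ids <- rownames(cm)
  miss <- setdiff(ids, names(seqs))
  if (length(miss))
    stop("missing sequence for counted ASV(s): ",
         paste(head(miss, 5), collapse = ", "))
  tot <- rowSums(cm)
  ord <- ids[order(-tot, ids)]
  centroids <- character(0)
  membership <- setNames(character(length(ids)), ids)
  for (a in ord) {
    assigned <- NA_character_
    if (length(centroids)) {
      st <- align_pair_stats(seqs[centroids], seqs[[a]])
      hit <- which(st[, "identity"] >= identity)
      if (length(hit)) assigned <- centroids[hit[1L]]
    }
    if (is.na(assigned)) {
      centroids <- c(centroids, a)
      assigned <- a
    }
    membership[a] <- assigned
  }
  otus <- lapply(centroids, function(cb) names(membership)[membership == cb])
  out <- data.frame(
    otu_id = paste0("OTU_", sub("^ASV_", "", centroids)),
    centroid = centroids,
    members = vapply(otus, paste, "", collapse = ","),
    n_members = lengths(otus),
    total_reads = vapply(otus, function(m) sum(tot[m]), 0),
    stringsAsFactors = FALSE)
  attr(out, "membership") <-
    setNames(out$otu_id[match(membership, out$centroid)], names(membership))
  out
}

#' Rarefy an OTU's member-by-sample counts
#'
#' Uniform subsample without replacement of exactly `depth` reads from the
#' flattened member-by-sample count multiset. OTUs whose total read count
#' does not exceed `depth` are not rarefied (return `NULL`); they are
#' excluded upstream.
#'
#' @param member_counts Members-by-samples count matrix for one OTU.
#' @param depth Target total (default 5000).
#' @param seed Integer seed.
#' @return A matrix of the same shape whose entries total exactly `depth`,
#'   or `NULL` when the OTU total is at or below `depth`.
#' @export
rarefy_otu <- function(member_counts, depth = 5000, seed = 1L) {
  x <- as.vector(member_counts)
  tot <- sum(x)
  if (tot <= depth) {
    message("OTU total (", tot, ") does not exceed depth ", depth,
            "; excluded")
    return(NULL)
  }
  with_seed(seed, {
    keep <- sample(rep.int(seq_along(x), x), depth)
    out <- tabulate(keep, nbins = length(x))
    matrix(out, nrow(member_counts), ncol(member_counts),
           dimnames = dimnames(member_counts))
  })
}

#' Effective microdiversity of a rarefied OTU
#'
#' `exp(Shannon)` of the member-ASV totals of the rarefied matrix: the
#' effective number of distinct ASVs within the OTU (1 = a single effective
#' genotype; equals the member count when members are equally abundant).
#'
#' @param rarefied Rarefied members-by-samples matrix ([rarefy_otu()]).
#' @return A single number >= 1.
#' @export
effective_microdiversity <- function(rarefied) {
  p <- rowSums(rarefied) / sum(rarefied)
  p <- p[p > 0]
  exp(-sum(p * log(p)))
}

#' Persistence and variability of a rarefied OTU
#'
#' Persistence is the fraction of samples whose OTU column total is at least
#' 1 read after rarefaction; variability is the coefficient of variation
#' (sd/mean) of per-sample OTU totals (NA when the mean is zero).
#'
#' @param rarefied Rarefied members-by-samples matrix.
#' @return A named numeric vector `c(persistence, variability)`.
#' @export
persistence_and_variability <- function(rarefied) {
  tot <- colSums(rarefied)
  m <- mean(tot)
  c(persistence = mean(tot >= 1),
    variability = if (m > 0) sd(tot) / m else NA_real_)
}

#' Within-OTU microdiversity profile
#'
#' Clusters ASVs into OTUs at the identity threshold, retains OTUs whose
#' cumulative read count exceeds `depth` (default 5000; below this the
#' Shannon index is unreliable), rarefies each retained OTU to exactly
#' `depth` reads, and computes effective microdiversity, persistence and
#' variability from that one subsample.
#'
#' @param cm Features-by-samples count matrix.
#' @param seqs Named character vector of ASV sequences.
#' @param depth Rarefaction depth and retention cutoff.
#' @param identity OTU identity threshold.
#' @param seed Master seed (each OTU gets a derived substream).
#' @param otus Optional precomputed [cluster_otus()] result.
#' @return A data.frame, one row per retained OTU: `otu_id`, `centroid`,
#'   `n_members`, `total_reads`, `effective_microdiversity`, `persistence`,
#'   `variability` and `microdiv_class` ("high" >= 2 effective ASVs, else
#'   "low"). The full OTU table is attached as attribute `otus`.
#' @export
microdiversity_profile <- function(cm, seqs, depth = 5000, identity = 0.987,
                                   seed = 20231201, otus = NULL) {
  if (is.null(otus)) otus <- cluster_otus(seqs, cm, identity)
  keep <- otus[otus$total_reads > depth, , drop = FALSE]
  rows <- lapply(seq_len(nrow(keep)), function(i) {
    mem <- strsplit(keep$members[i], ",")[[1L]]
    rar <- suppressMessages(
      rarefy_otu(cm[mem, , drop = FALSE], depth,
                 seed = derive_seed(seed, keep$otu_id[i])))
    pv <- persistence_and_variability(rar)
    data.frame(otu_id = keep$otu_id[i], centroid = keep$centroid[i],
               n_members = keep$n_members[i],
               total_reads = keep$total_reads[i],
               effective_microdiversity = effective_microdiversity(rar),
               persistence = pv[["persistence"]],
               variability = pv[["variability"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame()
  if (nrow(out))
    out$microdiv_class <- ifelse(out$effective_microdiversity >= 2,
                                 "high", "low")
  attr(out, "otus") <- otus
  out
}

#' Compare persistence and variability between microdiversity classes
#'
#' Two-sided Wilcoxon rank-sum tests of persistence and variability between
#' high (effective microdiversity >= 2) and low OTU classes, BH-adjusted
#' across the tested responses. Returns `NULL` (with a message) when either
#' class has fewer than 3 OTUs.
#'
#' @param records Data.frame from [microdiversity_profile()].
#' @return A data.frame with `response`, `p`, `p_adj`, group medians; or
#'   `NULL` for degenerate groups.
#' @export
compare_microdiv_groups <- function(records) {
  g <- records$microdiv_class
  if (length(unique(g)) < 2 || min(table(g)) < 3) {
    message("degenerate microdiversity groups; no test performed")
    return(NULL)
  }
  hi <- records[g == "high", ]
  lo <- records[g == "low", ]
  one <- function(resp) {
    x <- hi[[resp]]; y <- lo[[resp]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    p <- suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
    data.frame(response = resp, p = p,
               median_high = median(x), median_low = median(y),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("persistence"), one("variability"))
  out$p_adj <- bh_adjust(out$p)
  out
}
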