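# Global pairwise alignment with the standard amplicon scoring
# (match +1, mismatch -2, gap open -10, gap extend -1). Identity and
# divergence are computed over alignment columns with terminal gap columns
# excluded: identity = matches / columns, divergence = mismatch columns +
# internal gap columns.

# Exact fast path for equal-length pairs. With scoring {+1, -2, -10/-1} an
# alignment of two equal-length sequences that uses g >= 2 gap columns
# scores at most L - 22, while the ungapped alignment scores L - 3m for m
# mismatches; hence for m <= 7 the ungapped alignment is provably optimal
# and identity/divergence follow from the Hamming distance. Conversely,
# identity >= 0.95 forces nearly gap-free alignments, so pairs with
# m > 0.2 L can never reach such thresholds and are scored ungapped too.
hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

align_pair_stats <- function(queries, subject) {
  L <- nchar(subject)
  eq <- nchar(queries) == L
  m <- rep(NA_integer_, length(queries))
  m[eq] <- vapply(queries[eq], hamming, 0L, b = subject)
  fast <- eq & (m <= 7L | m > 0.2 * L)
  out <- matrix(NA_real_, length(queries), 2L,
                dimnames = list(NULL, c("identity", "divergence")))
  out[fast, "identity"] <- (L - m[fast]) / L
  out[fast, "divergence"] <- m[fast]
  if (any(!fast))
    out[!fast, ] <- align_pair_stats_full(queries[!fast], subject)
  out
}

align_pair_stats_full <- function(queries, subject) {
  subm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                   baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(queries), Biostrings::DNAString(subject),
    type = "global", substitutionMatrix = subm,
    gapOpening = 10, gapExtension = 1)
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  t(vapply(seq_along(pa), function(i) {
    p <- strsplit(pa[i], "")[[1L]]
    s <- strsplit(sa[i], "")[[1L]]
    gap <- p == "-" | s == "-"
    # trim terminal gap runs
    lo <- 1L; hi <- length(p)
    while (lo <= hi && gap[lo]) lo <- lo + 1L
    while (hi >= lo && gap[hi]) hi <- hi - 1L
    if (hi < lo) return(c(identity = 0, divergence = NA_real_))
    p <- p[lo:hi]; s <- s[lo:hi]; gap <- gap[lo:hi]
    ncols <- length(p)
    match <- sum(!gap & p == s)
    mism <- sum(!gap & p != s)
    c(identity = match / ncols, divergence = mism + sum(gap))
  }, c(identity = 0, divergence = 0)))
}

#' Pairwise nucleotide divergence
#'
#' Divergence between two ASV sequences is the number of substitution
#' columns plus internal gap columns in a global alignment (terminal gaps
#' excluded).
#'
#' @param seqs Named character vector of sequences.
#' @param ids ASV ids to compare (default: all).
#' @return A data.frame with `asv_1`, `asv_2` (each unordered pair once) and
#'   integer `divergence`.
#' @export
pairwise_divergence <- function(seqs, ids = names(seqs)) {
  miss <- setdiff(ids, names(seqs))
  if (length(miss)) stop("missing sequence for: ", paste(miss, collapse = ", "))
  if (length(ids) < 2) return(data.frame(asv_1 = character(),
                                         asv_2 = character(),
                                         divergence = integer()))
  pairs <- combn(ids, 2L)
  div <- numeric(ncol(pairs))
  for (j in unique(pairs[2L, ])) {
    sel <- which(pairs[2L, ] == j)
    div[sel] <- align_pair_stats(seqs[pairs[1L, sel]], seqs[[j]])[, "divergence"]
  }
  data.frame(asv_1 = pairs[1L, ], asv_2 = pairs[2L, ],
             divergence = as.integer(round(div)), stringsAsFactors = FALSE)
}
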