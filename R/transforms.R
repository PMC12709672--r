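#' Per-sample relative abundances
#'
#' Divides every sample column by its total. Samples with a zero total are an
#' error (never silently normalized), naming the offending sample.
#'
#' @param cm Features-by-samples count matrix.
#' @return A numeric matrix whose columns each sum to 1.
#' @export
to_relative <- function(cm) {
  tot <- colSums(cm)
  bad <- colnames(cm)[tot == 0]
  if (length(bad))
    stop("zero-total sample(s): ", paste(bad, collapse = ", "))
  sweep(cm, 2L, tot, "/")
}

#' Centred log-ratio transform
#'
#' Per sample (column), `log(x + pseudocount)` centred by the sample's mean
#' log value, so every column sums to zero. With `pseudocount = 0` on
#' strictly positive data the transform is invariant to per-sample scaling.
#'
#' @param cm Features-by-samples matrix of non-negative values.
#' @param pseudocount Added to every cell before the log (default 1).
#' @return A numeric matrix, same shape, columns summing to 0.
#' @export
clr_transform <- function(cm, pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  x <- cm + pseudocount
  if (any(x <= 0)) stop("clr needs strictly positive values after pseudocount")
  lx <- log(x)
  sweep(lx, 2L, colMeans(lx), "-")
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment. Values must lie in
#' \[0, 1\]; `NA`s propagate.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
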