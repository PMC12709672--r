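#' Abundance classification
#'
#' An ASV is `abundant` if its relative abundance reaches the threshold
#' (default 1\%) in at least one sample, inclusive; otherwise it is
#' `permanently_rare`.
#'
#' @param ra Features-by-samples relative-abundance matrix ([to_relative()]).
#' @param threshold Relative-abundance threshold (default 0.01).
#' @return Named character vector of labels.
#' @export
classify_abundance <- function(ra, threshold = 0.01) {
  mx <- apply(ra, 1L, max)
  setNames(ifelse(mx >= threshold, "abundant", "permanently_rare"),
           rownames(ra))
}

#' Occupancy classification
#'
#' Occupancy is the fraction of samples with at least one read. `broad`
#' requires occupancy >= `broad` (default 75\%), `narrow` occupancy <=
#' `narrow` (default 10\%), anything between is `intermediate`.
#'
#' @param cm Features-by-samples count matrix.
#' @param broad,narrow Occupancy cutoffs (both inclusive).
#' @return Named character vector of labels.
#' @export
classify_occupancy <- function(cm, broad = 0.75, narrow = 0.10) {
  occ <- rowMeans(cm >= 1)
  setNames(ifelse(occ >= broad, "broad",
                  ifelse(occ <= narrow, "narrow", "intermediate")),
           rownames(cm))
}

#' Sarle's bimodality coefficient (sample-corrected)
#'
#' `b = (g1^2 + 1) / (g2 + 3 (n-1)^2 / ((n-2)(n-3)))` with `g1` the
#' bias-corrected sample skewness and `g2` the bias-corrected sample excess
#' kurtosis. Approaches 1/3 for a normal sample and 1 for a balanced
#' two-point distribution. Undefined (`NA`) for `n < 4` or zero variance.
#'
#' @param x Numeric vector.
#' @return The coefficient, or `NA_real_` when undefined.
#' @export
bimodality_coefficient <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- sqrt(n * (n - 1)) / (n - 2) * m3 / m2^1.5
  g2 <- ((n + 1) * (m4 / m2^2 - 3) + 6) * (n - 1) / ((n - 2) * (n - 3))
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Conditionally rare taxa (CRT)
#'
#' Flags ASVs whose per-sample relative-abundance vector is bimodal
#' (coefficient >= `b_threshold`, default 0.9) and reaches
#' `abund_threshold` (default 1\%) in at least one sample: taxa that are
#' typically rare but occasionally bloom.
#'
#' @param ra Features-by-samples relative-abundance matrix.
#' @param b_threshold Bimodality-coefficient cutoff.
#' @param abund_threshold Maximum relative-abundance cutoff.
#' @return Named logical vector.
#' @export
detect_crt <- function(ra, b_threshold = 0.9, abund_threshold = 0.01) {
  b <- apply(ra, 1L, bimodality_coefficient)
  mx <- apply(ra, 1L, max)
  setNames(!is.na(b) & b >= b_threshold & mx >= abund_threshold,
           rownames(ra))
}

#' Full occupancy/abundance record table
#'
#' Runs all classifications on one count matrix, optionally restricted to a
#' metadata-defined sample subset (e.g. acidic samples only). Persistent
#' abundant taxa are those both `abundant` and `broad`.
#'
#' @param cm Features-by-samples count matrix.
#' @param meta Optional metadata data.frame (sample ids as rownames).
#' @param filter Optional expression over metadata columns selecting
#'   samples, as a one-sided formula or character string, e.g. `"pH < 4"`.
#' @param abund_threshold,broad,narrow,b_threshold Classification cutoffs.
#' @return A data.frame, one row per ASV: occupancy, max/mean relative
#'   abundance, abundance class, distribution class, `persistent_abundant`,
#'   `crt` and the bimodality coefficient.
#' @export
occupancy_classes <- function(cm, meta = NULL, filter = NULL,
                              abund_threshold = 0.01, broad = 0.75,
                              narrow = 0.10, b_threshold = 0.9) {
  if (!is.null(filter)) {
    if (is.null(meta)) stop("a metadata table is required to filter samples")
    expr <- if (inherits(filter, "formula")) filter[[2L]] else
      str2lang(filter)
    keep <- eval(expr, envir = meta)
    keep[is.na(keep)] <- FALSE
    cm <- cm[, rownames(meta)[keep], drop = FALSE]
  }
  if (ncol(cm) < 2) stop("need at least 2 samples after filtering")
  ra <- to_relative(cm)
  ab <- classify_abundance(ra, abund_threshold)
  oc <- classify_occupancy(cm, broad, narrow)
  b <- apply(ra, 1L, bimodality_coefficient)
  crt <- !is.na(b) & b >= b_threshold &
    apply(ra, 1L, max) >= abund_threshold
  data.frame(
    asv_id = rownames(cm),
    occupancy = rowMeans(cm >= 1),
    max_rel_abund = apply(ra, 1L, max),
    mean_rel_abund = rowMeans(ra),
    abundance_class = unname(ab),
    distribution_class = unname(oc),
    persistent_abundant = unname(ab == "abundant" & oc == "broad"),
    crt = unname(crt & ab == "abundant"),
    bimodality = unname(b),
    stringsAsFactors = FALSE)
}

#' Persistent abundant flag
#'
#' @param abundance_class,distribution_class Label vectors from
#'   [classify_abundance()] and [classify_occupancy()].
#' @return Logical vector: abundant AND broad.
#' @export
persistent_abundant <- function(abundance_class, distribution_class) {
  abundance_class == "abundant" & distribution_class == "broad"
}
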