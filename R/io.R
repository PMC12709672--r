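#' Read an ASV count table
#'
#' Reads a tab-delimited count table with a header row and identifiers in the
#' first column, and returns a validated features-by-samples integer matrix.
#' Cells must be non-negative integers; duplicated feature or sample
#' identifiers and ragged rows are rejected.
#'
#' @param path Path to a TSV file.
#' @param orientation Either `"features"` (features in rows, the storage
#'   convention) or `"samples"` (samples in rows; the table is transposed
#'   after reading).
#' @return An integer matrix, features in rows, samples in columns.
#' @export
read_count_table <- function(path, orientation = c("features", "samples")) {
  orientation <- match.arg(orientation)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    stop("ragged rows in count table: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  if (orientation == "samples") m <- t(m)
  storage.mode(m) <- "double"
  validate_counts(m)
  storage.mode(m) <- "integer"
  m
}

#' Write an ASV count table
#'
#' @param cm Features-by-samples count matrix.
#' @param path Output TSV path.
#' @param id_col Name for the identifier column.
#' @export
write_count_table <- function(cm, path, id_col = "asv_id") {
  df <- data.frame(rownames(cm), cm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Structural checks shared by readers and the simulator.
validate_counts <- function(cm) {
  if (!is.matrix(cm)) stop("counts must be a matrix")
  if (is.null(rownames(cm)) || is.null(colnames(cm)))
    stop("counts must carry feature and sample identifiers")
  if (anyDuplicated(rownames(cm))) stop("duplicate feature identifiers")
  if (anyDuplicated(colnames(cm))) stop("duplicate sample identifiers")
  if (anyNA(cm)) stop("missing values in count table")
  if (any(cm < 0)) stop("negative count in table")
  if (any(abs(cm - round(cm)) > 1e-8)) stop("non-integer count in table")
  invisible(TRUE)
}

#' Read per-sample metadata
#'
#' Tab-delimited, header row, first column is the sample identifier. Expected
#' (but not mandatory) columns: `habitat` (water/sediment), `event`, `site`,
#' and environmental variables such as `pH`, `Fe`, `Mn`, `Zn`, `Cu`, `Cd`,
#' `sulfate`, `EC`, `DO`, `ORP`, `temperature`. Missing values stay `NA`.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with rownames set to sample ids.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample identifiers in metadata")
  rownames(df) <- ids
  df <- df[, -1L, drop = FALSE]
  if ("pH" %in% colnames(df)) {
    ph <- df$pH
    if (any(!is.na(ph) & (ph <= 0 | ph >= 14)))
      stop("pH outside (0, 14) in metadata")
  }
  conc <- intersect(c("Fe", "Mn", "Zn", "Cu", "Cd", "sulfate"), colnames(df))
  for (v in conc)
    if (any(!is.na(df[[v]]) & df[[v]] < 0))
      stop("negative concentration for ", v)
  df
}

#' Write per-sample metadata
#' @param meta Data.frame with sample ids as rownames.
#' @param path Output TSV path.
#' @export
write_sample_metadata <- function(meta, path) {
  df <- data.frame(sample_id = rownames(meta), meta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ASV taxonomy table
#'
#' Tab-delimited with first column ASV id and a `genus` column (may be
#' `"unclassified"`).
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `asv_id`, `genus`, and any extra fields.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- "asv_id"
  if (!"genus" %in% colnames(df)) stop("taxonomy table needs a 'genus' column")
  if (anyDuplicated(df$asv_id)) stop("duplicate ASV identifiers in taxonomy")
  df
}

#' Read/write ASV sequences (FASTA)
#'
#' @param path FASTA path.
#' @return A named character vector of uppercase DNA sequences.
#' @export
read_sequences <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' @rdname read_sequences
#' @param seqs Named character vector of sequences.
#' @export
write_sequences <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read a rooted phylogeny (Newick)
#'
#' @param path Newick file; branch lengths required, all non-negative.
#' @return An [ape::phylo] object.
#' @export
read_phylo <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch length in tree")
  tr
}
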