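#' Multi-sample marker alignment
#'
#' A `marker_alignment` wraps an uppercase character matrix (samples in rows,
#' alignment columns in columns; gaps as `"-"`) together with a marker name.
#' All downstream marker statistics, distance and discrimination functions
#' take this container.
#'
#' @param seqs Character matrix of single characters, or a named list/vector of
#'   equal-length strings. Row names (or list names) are sample ids.
#' @param marker_name Name of the marker region.
#' @return An object of class `marker_alignment`.
#' @export
marker_alignment <- function(seqs, marker_name = "marker") {
  mat <- as_seq_matrix(seqs)
  if (ncol(mat) < 1) abort("alignment must have at least one column")
  if (is.null(rownames(mat)) || anyNA(rownames(mat)) || any(rownames(mat) == "")) {
    abort("every record needs a sample id (row or list names)")
  }
  if (anyDuplicated(rownames(mat))) {
    abort("duplicated sample ids in alignment")
  }
  structure(
    list(seqs = mat, marker_name = marker_name),
    class = "marker_alignment"
  )
}

#' Pairwise genome alignment
#'
#' Two equal-length gapped sequences with a designated reference. Columns
#' gapped in both sequences are dropped at construction (shared-gap
#' normalisation); the number removed is kept in `n_dropped_columns`.
#'
#' @param reference,other Character vectors of single characters (or single
#'   strings) of equal gapped length.
#' @param reference_id,other_id Sequence identifiers.
#' @return An object of class `aligned_pair`.
#' @export
aligned_pair <- function(reference, other,
                         reference_id = "reference", other_id = "other") {
  ref <- as_seq_vector(reference)
  oth <- as_seq_vector(other)
  if (length(ref) != length(oth)) {
    abort(sprintf("sequences differ in gapped length (%d vs %d)",
                  length(ref), length(oth)))
  }
  if (length(ref) == 0) abort("empty alignment")
  shared <- ref == "-" & oth == "-"
  n_dropped <- sum(shared)
  if (n_dropped > 0) {
    ref <- ref[!shared]
    oth <- oth[!shared]
    inform(sprintf("dropped %d column(s) gapped in both sequences", n_dropped))
  }
  structure(
    list(reference = ref, other = oth,
         reference_id = reference_id, other_id = other_id,
         n_dropped_columns = n_dropped),
    class = "aligned_pair"
  )
}

# Accepts a character matrix, a list/vector of strings, or an ape DNAbin
# matrix; returns an uppercase single-character matrix with "-" gaps.
as_seq_matrix <- function(x) {
  if (inherits(x, "DNAbin")) {
    x <- as.character(as.matrix(x))
  }
  if (is.matrix(x)) {
    mat <- toupper(x)
  } else {
    if (is.list(x)) x <- unlist(x)
    lens <- nchar(x)
    if (length(unique(lens)) > 1) {
      abort(sprintf("records have unequal lengths: %s",
                    paste(unique(lens), collapse = ", ")))
    }
    mat <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(mat) <- names(x)
  }
  mat
}

as_seq_vector <- function(x) {
  if (length(x) == 1 && nchar(x[1]) > 1) x <- strsplit(x, "")[[1]]
  toupper(as.character(x))
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat(sprintf("<marker_alignment> %s: %d samples x %d columns\n",
              x$marker_name, nrow(x$seqs), ncol(x$seqs)))
  invisible(x)
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("<aligned_pair> %s vs %s: %d aligned columns (%d shared-gap dropped)\n",
              x$reference_id, x$other_id, length(x$reference),
              x$n_dropped_columns))
  invisible(x)
}

#' Number of samples and alignment length
#'
#' @param x A `marker_alignment` or `aligned_pair`.
#' @return Integer.
#' @export
n_samples <- function(x) UseMethod("n_samples")

#' @export
n_samples.marker_alignment <- function(x) nrow(x$seqs)

#' @rdname n_samples
#' @export
alignment_length <- function(x) UseMethod("alignment_length")

#' @export
alignment_length.marker_alignment <- function(x) ncol(x$seqs)

#' @export
alignment_length.aligned_pair <- function(x) length(x$reference)

#' Sample identifiers of an alignment
#' @param x A `marker_alignment`.
#' @return Character vector.
#' @export
sample_ids <- function(x) rownames(x$seqs)

#' Translate between gapped (alignment-column) and ungapped coordinates
#'
#' Positions are 1-based. `gapped_to_ungapped()` returns `NA` at gap columns;
#' `ungapped_to_gapped()` is its inverse on non-gap positions, so the two form
#' a bijection between alignment columns carrying a base and positions on the
#' ungapped sequence.
#'
#' @param seq Character vector of single characters (gaps as `"-"`).
#' @param pos Integer positions to translate (default: all).
#' @return Integer vector of translated positions.
#' @export
gapped_to_ungapped <- function(seq, pos = seq_along(seq)) {
  idx <- cumsum(seq != "-")
  idx[seq == "-"] <- NA_integer_
  idx[pos]
}

#' @rdname gapped_to_ungapped
#' @export
ungapped_to_gapped <- function(seq, pos) {
  map <- which(seq != "-")
  if (any(pos < 1 | pos > length(map))) {
    abort("ungapped position out of range")
  }
  map[pos]
}

#' Ungapped length of a gapped sequence
#' @param seq Character vector of single characters.
#' @return Integer count of non-gap characters.
#' @export
ungapped_length <- function(seq) sum(seq != "-")

# Extract a column slice of a marker alignment as a new marker_alignment.
slice_alignment <- function(aln, start, length) {
  cols <- seq(start, start + length - 1L)
  marker_alignment(aln$seqs[, cols, drop = FALSE],
                   marker_name = aln$marker_name)
}
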