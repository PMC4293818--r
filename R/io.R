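#' Read an aligned FASTA file
#'
#' Reads a multiple alignment (`kind = "marker"`) or a two-genome pairwise
#' alignment (`kind = "genome_pair"`). Sequences are uppercased; for a genome
#' pair, columns gapped in both sequences are dropped and the count reported.
#' The first record of a genome pair is taken as the reference unless
#' `reference_id` names another record.
#'
#' @param path Path to an aligned FASTA file.
#' @param kind `"marker"` for a multi-sample marker alignment,
#'   `"genome_pair"` for a two-sequence genome alignment.
#' @param marker_name Marker name for `kind = "marker"`; defaults to the file
#'   name without extension.
#' @param reference_id For `kind = "genome_pair"`, the record id to use as the
#'   reference.
#' @return A [marker_alignment] or [aligned_pair].
#' @export
read_alignment <- function(path, kind = c("marker", "genome_pair"),
                           marker_name = NULL, reference_id = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  seqs <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(seqs) || length(seqs) == 0) {
    abort(sprintf("no sequences in %s", path))
  }
  lens <- lengths(seqs)
  if (length(unique(lens)) > 1) {
    abort(sprintf("records in %s are not aligned (lengths %s)",
                  path, paste(unique(lens), collapse = ", ")))
  }
  chr <- lapply(as.character(seqs), function(s) toupper(s))
  if (kind == "genome_pair") {
    if (length(chr) != 2) {
      abort(sprintf("genome pair must have exactly 2 records, found %d",
                    length(chr)))
    }
    ids <- names(chr)
    ref_idx <- 1L
    if (!is.null(reference_id)) {
      ref_idx <- match(reference_id, ids)
      if (is.na(ref_idx)) {
        abort(sprintf("reference id '%s' not among records: %s",
                      reference_id, paste(ids, collapse = ", ")))
      }
    }
    aligned_pair(chr[[ref_idx]], chr[[3L - ref_idx]],
                 reference_id = ids[ref_idx], other_id = ids[3L - ref_idx])
  } else {
    mat <- do.call(rbind, chr)
    rownames(mat) <- names(chr)
    marker_alignment(
      mat,
      marker_name = marker_name %||% sub("\\.[^.]*$", "", basename(path))
    )
  }
}

#' Write an alignment to FASTA
#'
#' @param x A [marker_alignment] or [aligned_pair].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  if (inherits(x, "aligned_pair")) {
    seqs <- setNames(
      list(x$reference, x$other),
      c(x$reference_id, x$other_id)
    )
  } else {
    seqs <- setNames(
      lapply(seq_len(nrow(x$seqs)), function(i) x$seqs[i, ]),
      rownames(x$seqs)
    )
  }
  ape::write.FASTA(ape::as.DNAbin(seqs), path)
  invisible(path)
}

#' Read a sample-to-species map
#'
#' A two-column TSV with header `sample_id<TAB>species`. Duplicate sample ids
#' are rejected.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `sample_id` and `species`.
#' @export
read_species_map <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         comment = "#")
  if (!all(c("sample_id", "species") %in% names(tab))) {
    abort("species map needs columns 'sample_id' and 'species'")
  }
  species_map(tab$sample_id, tab$species)
}

#' Construct a species map
#'
#' @param sample_id Character vector of sample ids.
#' @param species Character vector of species labels, same length.
#' @return A tibble with columns `sample_id` and `species`.
#' @export
species_map <- function(sample_id, species) {
  if (length(sample_id) != length(species)) {
    abort("sample_id and species must have equal length")
  }
  if (anyDuplicated(sample_id)) {
    dup <- unique(sample_id[duplicated(sample_id)])
    abort(sprintf("duplicated sample id(s) in species map: %s",
                  paste(dup, collapse = ", ")))
  }
  tibble(sample_id = as.character(sample_id), species = as.character(species))
}

# Species label per alignment row, error on missing samples.
species_of <- function(aln, species) {
  idx <- match(sample_ids(aln), species$sample_id)
  if (anyNA(idx)) {
    abort(sprintf("sample(s) missing from species map: %s",
                  paste(sample_ids(aln)[is.na(idx)], collapse = ", ")))
  }
  species$species[idx]
}

#' Read a feature table of annotated intervals
#'
#' A TSV with header and columns `start`, `end`, `category`, `name`;
#' coordinates are 1-based inclusive positions on the ungapped reference.
#' Categories must come from `coding`, `intron`, `spacer`, `rRNA`, `tRNA`.
#' Intervals of the same category may not overlap.
#'
#' @param path Path to the TSV file.
#' @param reference_length Optional ungapped reference length to validate
#'   bounds against.
#' @return A tibble with columns `start`, `end`, `category`, `name`, sorted by
#'   `start`.
#' @export
read_feature_table <- function(path, reference_length = NULL) {
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(start = "i", end = "i", .default = "c"),
    comment = "#"
  )
  if (!all(c("start", "end", "category", "name") %in% names(tab))) {
    abort("feature table needs columns start, end, category, name")
  }
  feature_table(tab$start, tab$end, tab$category, tab$name,
                reference_length = reference_length)
}

#' Construct a feature table
#'
#' @param start,end Integer vectors, 1-based inclusive interval bounds on the
#'   ungapped reference.
#' @param category Character vector over `coding`, `intron`, `spacer`,
#'   `rRNA`, `tRNA`.
#' @param name Feature names.
#' @param reference_length Optional bound check.
#' @return A tibble sorted by `start`.
#' @export
feature_table <- function(start, end, category, name = NA_character_,
                          reference_length = NULL) {
  tab <- tibble(start = as.integer(start), end = as.integer(end),
                category = as.character(category),
                name = as.character(name))
  bad_cat <- setdiff(unique(tab$category), FEATURE_CATEGORIES)
  if (length(bad_cat) > 0) {
    abort(sprintf("unknown feature categor%s: %s (allowed: %s)",
                  if (length(bad_cat) > 1) "ies" else "y",
                  paste(bad_cat, collapse = ", "),
                  paste(FEATURE_CATEGORIES, collapse = ", ")))
  }
  if (any(tab$start < 1) || any(tab$end < tab$start)) {
    abort("intervals must satisfy 1 <= start <= end")
  }
  if (!is.null(reference_length) && any(tab$end > reference_length)) {
    abort(sprintf("interval end beyond reference length %d", reference_length))
  }
  tab <- arrange(tab, .data$start, .data$end)
  for (cat in unique(tab$category)) {
    sub <- tab[tab$category == cat, ]
    if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)])) {
      abort(sprintf("overlapping intervals within category '%s'", cat))
    }
  }
  tab
}

# ---- report writers -------------------------------------------------------

report_header <- function(params = NULL) {
  version <- as.character(utils::packageVersion("minibarcodes"))
  lines <- sprintf("# minibarcodes %s", version)
  if (length(params) > 0) {
    lines <- c(lines, sprintf("# %s = %s", names(params),
                              vapply(params, function(p)
                                paste(format(p), collapse = ","), "")))
  }
  lines
}

#' Write a result table as TSV with a provenance header
#'
#' Writes comment lines naming the tool version and the parameters used,
#' followed by a tab-separated table.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param params Named list of parameters to record in the header.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(x, path, params = NULL) {
  writeLines(report_header(params), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a result as JSON with provenance fields
#'
#' @param x A list (or coercible) of results.
#' @param path Output path.
#' @param params Named list of parameters to record.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path, params = NULL) {
  payload <- c(
    list(tool = "minibarcodes",
         version = as.character(utils::packageVersion("minibarcodes")),
         parameters = params %||% list()),
    x
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
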