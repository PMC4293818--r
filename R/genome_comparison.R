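# Canonical 6-class substitution spectrum: each unordered strand pair
# (X>Y, complement(X)>complement(Y)) is represented by one label, reference
# base first. Covers all 12 ordered base pairs.
COLLAPSED_TYPES <- c("C>T", "T>C", "C>A", "A>C", "C>G", "A>T")

COLLAPSE_LOOKUP <- c(
  "C>T" = "C>T", "G>A" = "C>T",
  "T>C" = "T>C", "A>G" = "T>C",
  "C>A" = "C>A", "G>T" = "C>A",
  "A>C" = "A>C", "T>G" = "A>C",
  "C>G" = "C>G", "G>C" = "C>G",
  "A>T" = "A>T", "T>A" = "A>T"
)

#' Annotation category at reference positions
#'
#' Returns the category of the first feature interval containing each
#' position. Positions covered by no interval are `"spacer"` when they lie
#' between annotated intervals and `"unannotated"` when they fall before the
#' first or after the last interval.
#'
#' @param pos Integer vector of 1-based ungapped reference positions.
#' @param features A [feature_table] tibble.
#' @param reference_length Optional reference length; positions outside
#'   `[1, reference_length]` raise an error.
#' @return Character vector of categories.
#' @export
region_of <- function(pos, features, reference_length = NULL) {
  if (!is.null(reference_length) && any(pos < 1 | pos > reference_length)) {
    abort("position outside the reference sequence")
  }
  if (is.null(features) || nrow(features) == 0) {
    return(rep("unannotated", length(pos)))
  }
  out <- rep(NA_character_, length(pos))
  # first matching interval in start order
  for (i in rev(seq_len(nrow(features)))) {
    hit <- pos >= features$start[i] & pos <= features$end[i]
    out[hit] <- features$category[i]
  }
  inside <- pos >= min(features$start) & pos <= max(features$end)
  out[is.na(out) & inside] <- "spacer"
  out[is.na(out)] <- "unannotated"
  out
}

#' Classify substitutions between two aligned genomes
#'
#' Scans every alignment column where both sequences carry an unambiguous
#' base; each differing column yields one substitution event, classified as
#' transition or transversion and collapsed onto the strand-symmetric 6-class
#' spectrum (reference base first; each class also stands for its
#' complement). Columns inside detected microinversion loops are excluded by
#' default, since an inverted segment read column-by-column would inflate the
#' substitution count.
#'
#' @param pair An [aligned_pair].
#' @param features Optional [feature_table] for region stratification.
#' @param mask_inversions Exclude columns inside accepted inversion loops
#'   (default `TRUE`).
#' @param inversions Optional precomputed result of [detect_inversions()];
#'   computed with default parameters when `NULL` and masking is on.
#' @return An object of class `substitution_scan` with elements `events`
#'   (tibble: `column`, `ref_pos`, `ref_base`, `other_base`, `type`,
#'   `collapsed_type`, `region`) and `summary` (totals, Ts/Tv, spectrum,
#'   per-region counts). Use [tidy()][generics::tidy] for the event table and
#'   [glance()][generics::glance] for the one-row summary.
#' @export
classify_substitutions <- function(pair, features = NULL,
                                   mask_inversions = TRUE,
                                   inversions = NULL) {
  stopifnot(inherits(pair, "aligned_pair"))
  ref <- pair$reference
  oth <- pair$other
  keep <- is_base(ref) & is_base(oth) & ref != oth
  if (mask_inversions) {
    if (is.null(inversions)) inversions <- detect_inversions(pair)
    if (nrow(inversions) > 0) {
      for (i in seq_len(nrow(inversions))) {
        keep[inversions$col_start[i]:inversions$col_end[i]] <- FALSE
      }
    }
  }
  cols <- which(keep)
  ref_pos <- gapped_to_ungapped(ref, cols)
  rb <- ref[cols]
  ob <- oth[cols]
  type <- ifelse(is_transition(rb, ob), "transition", "transversion")
  events <- tibble(
    column = cols,
    ref_pos = ref_pos,
    ref_base = rb,
    other_base = ob,
    type = type,
    collapsed_type = unname(COLLAPSE_LOOKUP[paste0(rb, ">", ob)]),
    region = region_of(ref_pos, features,
                       reference_length = ungapped_length(ref))
  )
  structure(
    list(events = events, summary = summarise_substitutions(events)),
    class = "substitution_scan"
  )
}

summarise_substitutions <- function(events) {
  n_ts <- sum(events$type == "transition")
  n_tv <- sum(events$type == "transversion")
  spectrum <- table(factor(events$collapsed_type, levels = COLLAPSED_TYPES))
  by_region <- events |>
    group_by(region = .data$region) |>
    summarise(
      n_ts = sum(.data$type == "transition"),
      n_tv = sum(.data$type == "transversion"),
      n_total = n(),
      .groups = "drop"
    )
  list(
    n_total = nrow(events),
    n_transition = n_ts,
    n_transversion = n_tv,
    ts_tv = if (n_tv > 0) n_ts / n_tv else NA_real_,
    spectrum = tibble(collapsed_type = COLLAPSED_TYPES,
                      n = as.integer(spectrum)),
    by_region = by_region
  )
}

#' @export
print.substitution_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<substitution_scan> %d substitutions: %d Ts, %d Tv (Ts/Tv %s)\n",
              s$n_total, s$n_transition, s$n_transversion,
              if (is.na(s$ts_tv)) "undefined" else sprintf("%.2f", s$ts_tv)))
  invisible(x)
}

#' Transition/transversion ratio by annotation region
#'
#' @param x A `substitution_scan` from [classify_substitutions()].
#' @return Tibble with `region`, `n_ts`, `n_tv`, `n_total`, `ratio` (Ts/Tv to
#'   2 decimals, `NA` with `undefined = TRUE` when a region has no
#'   transversions).
#' @export
tstv_by_region <- function(x) {
  stopifnot(inherits(x, "substitution_scan"))
  x$summary$by_region |>
    mutate(
      ratio = ifelse(.data$n_tv > 0, round(.data$n_ts / .data$n_tv, 2),
                     NA_real_),
      undefined = .data$n_tv == 0
    )
}

#' Detect indel events between two aligned genomes
#'
#' An indel event is a maximal run of gap columns in exactly one sequence
#' (shared-gap columns are removed at load, so runs cannot straddle them).
#' Terminal gap runs are treated as missing sequence ends, not indels, and
#' are reported via a message. Polarity is not inferred: events carry the
#' identity of the gap-holding sequence (`carrier`), and insertion/deletion
#' wording is left to reporting relative to the chosen reference.
#'
#' @param pair An [aligned_pair].
#' @param features Optional [feature_table] for region annotation.
#' @return Tibble with one row per event: `col_start` (first gap column),
#'   `ref_pos` (ungapped reference position of the base preceding the gap
#'   run; 0 when the run follows position 0), `length`, `carrier`
#'   (`"reference"` or `"other"`), `region`.
#' @export
detect_indels <- function(pair, features = NULL) {
  stopifnot(inherits(pair, "aligned_pair"))
  ref_len <- ungapped_length(pair$reference)
  one <- function(seq, carrier) {
    r <- rle(seq == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gap <- which(r$values)
    if (length(gap) == 0) return(NULL)
    terminal <- starts[gap] == 1L | ends[gap] == length(seq)
    if (any(terminal)) {
      inform(sprintf("excluded %d terminal gap run(s) in %s as missing ends",
                     sum(terminal), carrier))
      gap <- gap[!terminal]
    }
    if (length(gap) == 0) return(NULL)
    tibble(col_start = starts[gap], length = r$lengths[gap],
           carrier = carrier)
  }
  events <- bind_rows(
    one(pair$reference, "reference"),
    one(pair$other, "other")
  )
  if (nrow(events) == 0) {
    return(tibble(col_start = integer(), ref_pos = integer(),
                  length = integer(), carrier = character(),
                  region = character()))
  }
  # reference position of the column preceding the run (0 at a leading run,
  # which cannot occur for reference-carrier events after terminal exclusion)
  ref_cum <- cumsum(pair$reference != "-")
  events |>
    mutate(ref_pos = ifelse(.data$col_start == 1L, 0L,
                            ref_cum[.data$col_start - 1L])) |>
    mutate(region = region_of(pmax(.data$ref_pos, 1L), features,
                              reference_length = ref_len)) |>
    arrange(.data$col_start) |>
    select("col_start", "ref_pos", "length", "carrier", "region")
}

#' Histogram of indel lengths
#'
#' Bins events by length 1..10 bp with a `">10"` tail bin.
#'
#' @param events Indel event tibble from [detect_indels()].
#' @return Tibble with `length_bin` and `n`.
#' @export
indel_length_histogram <- function(events) {
  bins <- c(as.character(1:10), ">10")
  binned <- ifelse(events$length > 10, ">10", as.character(events$length))
  tibble(
    length_bin = factor(bins, levels = bins),
    n = as.integer(table(factor(binned, levels = bins)))
  )
}

#' Detect short hairpin-flanked inversions (microinversions)
#'
#' A candidate is a maximal run of consecutive alignment columns that
#' mismatch or are gapped, with run length between `min_loop` and `max_loop`.
#' The candidate is accepted as an inversion when the reverse complement of
#' the reference segment (gaps removed) equals the other segment (gaps
#' removed) within `max_loop_mismatch` mismatches. The hairpin stem is found
#' by greedy outward extension on the ungapped reference: flank positions
#' `loop_start - j` and `loop_end + j` must be complementary. Events are kept
#' only when the stem reaches `min_stem`, which is what distinguishes a
#' mutational microinversion (the loop of a hairpin) from a coincidental
#' reverse-complement match.
#'
#' @param pair An [aligned_pair].
#' @param min_loop,max_loop Candidate loop length bounds in columns.
#' @param max_loop_mismatch Allowed mismatches between the reverse-complement
#'   of the reference loop and the other loop (default 0).
#' @param min_stem Minimum stem (inverted repeat) length in bp.
#' @param max_stem_scan Maximum outward extension when measuring the stem.
#' @return Tibble with one row per accepted inversion: `col_start`,
#'   `col_end` (alignment columns of the loop), `loop_start`, `loop_end`
#'   (ungapped reference coordinates), `loop_length`, `stem_length`,
#'   `stem_left`, `stem_right` (stem sequences on the reference).
#' @export
detect_inversions <- function(pair, min_loop = 5, max_loop = 60,
                              max_loop_mismatch = 0, min_stem = 3,
                              max_stem_scan = 60) {
  stopifnot(inherits(pair, "aligned_pair"))
  ref <- pair$reference
  oth <- pair$other
  diff_col <- ref == "-" | oth == "-" |
    (is_base(ref) & is_base(oth) & ref != oth)
  r <- rle(diff_col)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= min_loop & r$lengths <= max_loop)
  ref_ungapped <- ref[ref != "-"]
  empty <- tibble(col_start = integer(), col_end = integer(),
                  loop_start = integer(), loop_end = integer(),
                  loop_length = integer(), stem_length = integer(),
                  stem_left = character(), stem_right = character())
  if (length(cand) == 0) return(empty)
  rows <- purrr::map(cand, function(i) {
    cs <- starts[i]; ce <- ends[i]
    ref_seg <- ref[cs:ce]; ref_seg <- ref_seg[ref_seg != "-"]
    oth_seg <- oth[cs:ce]; oth_seg <- oth_seg[oth_seg != "-"]
    if (length(ref_seg) != length(oth_seg) || length(ref_seg) == 0) {
      return(NULL)
    }
    rc <- revcomp(ref_seg)
    mism <- sum(rc != oth_seg | !is_base(rc) | !is_base(oth_seg))
    if (mism > max_loop_mismatch) return(NULL)
    # loop position on the ungapped reference
    loop_start <- gapped_to_ungapped(ref, min(which(ref[cs:ce] != "-")) + cs - 1L)
    loop_end <- loop_start + length(ref_seg) - 1L
    stem <- 0L
    while (stem < max_stem_scan &&
           loop_start - stem - 1L >= 1L &&
           loop_end + stem + 1L <= length(ref_ungapped)) {
      a <- ref_ungapped[loop_start - stem - 1L]
      b <- ref_ungapped[loop_end + stem + 1L]
      if (is_base(a) && is_base(b) && a == complement_base(b)) {
        stem <- stem + 1L
      } else break
    }
    if (stem < min_stem) return(NULL)
    tibble(
      col_start = cs, col_end = ce,
      loop_start = loop_start, loop_end = loop_end,
      loop_length = length(ref_seg), stem_length = stem,
      stem_left = paste(ref_ungapped[(loop_start - stem):(loop_start - 1L)],
                        collapse = ""),
      stem_right = paste(ref_ungapped[(loop_end + 1L):(loop_end + stem)],
                         collapse = "")
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) empty else out
}
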