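# Per-pair comparison indicators for a pair of gapped sequences: which
# columns are comparable (both unambiguous bases) and which differ.
pair_indicators <- function(a, b) {
  comp <- is_base(a) & is_base(b)
  list(comparable = comp, different = comp & a != b)
}

#' Nucleotide diversity of an alignment
#'
#' Computes pi as the mean over all unordered sequence pairs of the
#' proportion of differing sites, where each pair is compared only at columns
#' where both sequences carry an unambiguous base (pairwise deletion). No
#' small-sample `n/(n-1)` correction is applied by default; the corrected
#' estimator is available via `corrected = TRUE`.
#'
#' @param aln A [marker_alignment] with at least 2 sequences, or an
#'   [aligned_pair].
#' @param corrected Apply the `n/(n-1)` sample-size correction
#'   (default `FALSE`).
#' @return pi in substitutions/site; `NA` with a warning when no pair has any
#'   comparable site.
#' @export
nucleotide_diversity <- function(aln, corrected = FALSE) {
  mat <- alignment_matrix(aln)
  n <- nrow(mat)
  if (n < 2) abort("nucleotide diversity needs at least 2 sequences")
  props <- c()
  n_excluded <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ind <- pair_indicators(mat[i, ], mat[j, ])
      m <- sum(ind$comparable)
      if (m == 0) {
        n_excluded <- n_excluded + 1L
      } else {
        props <- c(props, sum(ind$different) / m)
      }
    }
  }
  if (n_excluded > 0) {
    warn(sprintf("%d pair(s) with no comparable site excluded", n_excluded))
  }
  if (length(props) == 0) return(NA_real_)
  pi <- mean(props)
  if (corrected) pi <- pi * n / (n - 1)
  pi
}

alignment_matrix <- function(aln) {
  if (inherits(aln, "aligned_pair")) {
    rbind(reference = aln$reference, other = aln$other)
  } else if (inherits(aln, "marker_alignment")) {
    aln$seqs
  } else {
    as_seq_matrix(aln)
  }
}

#' Sliding-window nucleotide diversity
#'
#' Slides a fixed-length window along the alignment columns and computes pi
#' within each window. Gap columns count toward the window span but are
#' excluded from each pair's site comparison. The last partial window is
#' dropped; an alignment shorter than one window falls back to a single
#' full-length window with a warning.
#'
#' @param aln A [marker_alignment] or [aligned_pair].
#' @param window_length Window length in alignment columns (default 600).
#' @param step Step size in columns (default 25).
#' @return A tibble of class `diversity_track` with columns `window_start`,
#'   `midpoint`, `n_sites`, `pi`; window length and step are kept as
#'   attributes.
#' @export
sliding_pi <- function(aln, window_length = 600, step = 25) {
  mat <- alignment_matrix(aln)
  L <- ncol(mat)
  if (L < window_length) {
    warn(sprintf(
      "alignment (%d columns) shorter than the window (%d); using one full-length window",
      L, window_length))
    window_length <- L
  }
  starts <- seq(1L, L - window_length + 1L, by = step)
  n <- nrow(mat)
  pairs <- utils::combn(n, 2)
  # cumulative per-pair counts along columns -> O(1) per window per pair
  n_pairs <- ncol(pairs)
  cum_comp <- matrix(0, n_pairs, L + 1L)
  cum_diff <- matrix(0, n_pairs, L + 1L)
  for (p in seq_len(n_pairs)) {
    ind <- pair_indicators(mat[pairs[1, p], ], mat[pairs[2, p], ])
    cum_comp[p, ] <- c(0, cumsum(ind$comparable))
    cum_diff[p, ] <- c(0, cumsum(ind$different))
  }
  res <- purrr::map(starts, function(s) {
    e <- s + window_length
    comp <- cum_comp[, e] - cum_comp[, s]
    diff <- cum_diff[, e] - cum_diff[, s]
    ok <- comp > 0
    list(
      n_sites = max(comp),
      pi = if (any(ok)) mean(diff[ok] / comp[ok]) else NA_real_
    )
  })
  track <- tibble(
    window_start = starts,
    midpoint = starts + (window_length - 1) / 2,
    n_sites = vapply(res, `[[`, 0, "n_sites"),
    pi = vapply(res, `[[`, 0, "pi")
  )
  structure(track, class = c("diversity_track", class(track)),
            window_length = window_length, step = step)
}

#' Call divergence hotspots from a diversity track
#'
#' Maximal runs of consecutive windows whose pi exceeds the threshold are
#' merged into one hotspot spanning the first window's start to the last
#' window's end.
#'
#' @param track A `diversity_track` from [sliding_pi()].
#' @param threshold pi threshold (default 0.012).
#' @return Tibble with `start`, `end` (alignment columns), `peak_pi`,
#'   `threshold`.
#' @export
find_hotspots <- function(track, threshold = 0.012) {
  if (nrow(track) == 0) abort("empty diversity track")
  window_length <- attr(track, "window_length")
  above <- !is.na(track$pi) & track$pi > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- purrr::map(runs, function(i) {
    win <- starts[i]:ends[i]
    tibble(
      start = track$window_start[starts[i]],
      end = track$window_start[ends[i]] + window_length - 1L,
      peak_pi = max(track$pi[win]),
      threshold = threshold
    )
  }) |> bind_rows()
  if (nrow(out) == 0) {
    return(tibble(start = integer(), end = integer(),
                  peak_pi = double(), threshold = double()))
  }
  # window spans can reach past the gap separating two runs; merge any
  # intervals that overlap so hotspots stay disjoint
  merged <- out[1, ]
  for (i in seq_len(nrow(out))[-1]) {
    last <- nrow(merged)
    if (out$start[i] <= merged$end[last]) {
      merged$end[last] <- max(merged$end[last], out$end[i])
      merged$peak_pi[last] <- max(merged$peak_pi[last], out$peak_pi[i])
    } else {
      merged <- bind_rows(merged, out[i, ])
    }
  }
  merged
}

#' Marker variability statistics
#'
#' Summarises a marker alignment the way barcoding marker tables report
#' variability: aligned length, variable and parsimony-informative site
#' counts (with percentages of the aligned length, 2 decimals), nucleotide
#' diversity, indel event count, and haplotype count.
#'
#' A variable site has at least two distinct unambiguous bases among the
#' samples; a parsimony-informative site has at least two distinct
#' unambiguous bases each carried by at least two samples. Haplotypes are
#' distinct sequences after dropping every column that contains a gap or
#' ambiguity in any sample (complete deletion). Indel events are distinct
#' (start, length) maximal gap runs, shared gaps counting once however many
#' samples carry them.
#'
#' @param aln A [marker_alignment] with at least 2 sequences.
#' @return A one-row tibble with columns `marker`, `aligned_length`,
#'   `n_parsimony_informative`, `pct_parsimony_informative`,
#'   `n_variable_sites`, `pct_variable_sites`, `pi`, `n_indel_events`,
#'   `n_haplotypes`.
#' @export
marker_stats <- function(aln) {
  stopifnot(inherits(aln, "marker_alignment"))
  mat <- aln$seqs
  if (nrow(mat) < 2) abort("marker statistics need at least 2 sequences")
  L <- ncol(mat)
  counts_per_col <- apply(mat, 2, function(col) {
    tab <- table(col[is_base(col)])
    c(n_states = length(tab), n_shared = sum(tab >= 2))
  })
  variable <- counts_per_col["n_states", ] >= 2
  # parsimony-informative: >= 2 states each in >= 2 samples
  pinf <- counts_per_col["n_shared", ] >= 2
  # haplotypes: complete deletion of gap/ambiguous columns
  clean <- apply(mat, 2, function(col) all(is_base(col)))
  haplo <- if (any(clean)) {
    length(unique(apply(mat[, clean, drop = FALSE], 1, paste, collapse = "")))
  } else 1L
  # indel events: distinct (start, length) maximal gap runs over samples
  runs <- purrr::map(seq_len(nrow(mat)), function(i) {
    r <- rle(mat[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gap <- which(r$values)
    if (length(gap) == 0) return(NULL)
    tibble(start = starts[gap], length = r$lengths[gap])
  }) |> bind_rows()
  n_indels <- if (nrow(runs) == 0) 0L else nrow(dplyr::distinct(runs))
  tibble(
    marker = aln$marker_name,
    aligned_length = L,
    n_parsimony_informative = sum(pinf),
    pct_parsimony_informative = round(100 * sum(pinf) / L, 2),
    n_variable_sites = sum(variable),
    pct_variable_sites = round(100 * sum(variable) / L, 2),
    pi = nucleotide_diversity(aln),
    n_indel_events = n_indels,
    n_haplotypes = haplo
  )
}
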