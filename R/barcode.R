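#' Kimura 2-parameter distance between two gapped sequences
#'
#' Compared sites are columns where both sequences carry an unambiguous base.
#' With transition proportion `P` and transversion proportion `Q` over the
#' compared sites, the distance is
#' `d = -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)`. The distance is
#' undefined (`NA`) when there are no compared sites or a log argument is
#' non-positive (saturation).
#'
#' @param a,b Character vectors of single characters (or single strings) of
#'   equal gapped length.
#' @return The K2P distance in substitutions/site, or `NA_real_`.
#' @export
k2p_distance <- function(a, b) {
  a <- as_seq_vector(a)
  b <- as_seq_vector(b)
  if (length(a) != length(b)) {
    abort(sprintf("sequences differ in length (%d vs %d)",
                  length(a), length(b)))
  }
  comp <- is_base(a) & is_base(b)
  m <- sum(comp)
  if (m == 0) return(NA_real_)
  diff <- comp & a != b
  n_ts <- sum(diff & is_transition(a, b))
  n_tv <- sum(diff) - n_ts
  k2p_from_pq(n_ts / m, n_tv / m)
}

# Closed form on (P, Q); NA outside the domain.
k2p_from_pq <- function(P, Q) {
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  out <- rep(NA_real_, length(arg1))
  ok <- !is.na(arg1) & arg1 > 0 & arg2 > 0
  out[ok] <- -0.5 * log(arg1[ok]) - 0.25 * log(arg2[ok])
  out
}

#' Pairwise K2P distance matrix of a marker alignment
#'
#' @param aln A [marker_alignment] with at least 2 sequences.
#' @return A symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames, and `NA` for undefined pairs. The number of undefined pairs is
#'   reported via a message when positive.
#' @export
k2p_matrix <- function(aln) {
  mat <- alignment_matrix(aln)
  n <- nrow(mat)
  if (n < 2) abort("distance matrix needs at least 2 sequences")
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- k2p_distance(mat[i, ], mat[j, ])
    }
  }
  n_undef <- sum(is.na(d[upper.tri(d)]))
  if (n_undef > 0) {
    inform(sprintf("%d undefined pairwise distance(s)", n_undef))
  }
  d
}

#' Nearest-neighbour species discrimination
#'
#' For each sample, the nearest-neighbour set is every other sample at the
#' minimum defined K2P distance. Under the default `tie_rule = "all"` a
#' sample is discriminated only when that set is non-empty and entirely
#' conspecific (a tie with any heterospecific sample fails); `tie_rule =
#' "any"` accepts a tie that contains at least one conspecific sample. A
#' sample with no defined distance fails. A species succeeds when all of its
#' samples succeed. Pm is the percentage of discriminated samples.
#'
#' @param dmat Distance matrix from [k2p_matrix()] (or any symmetric matrix
#'   with sample-id dimnames and `NA` for undefined entries).
#' @param species A species map tibble (`sample_id`, `species`) covering
#'   every sample; at least 2 species required.
#' @param tie_rule `"all"` (default, conservative) or `"any"`.
#' @return An object of class `discrimination_result` with per-sample and
#'   per-species tibbles, `pm`, and counts. [tidy()][generics::tidy] returns
#'   the per-sample table, [glance()][generics::glance] a one-row summary.
#' @export
near_neighbour <- function(dmat, species, tie_rule = c("all", "any")) {
  tie_rule <- match.arg(tie_rule)
  ids <- rownames(dmat)
  idx <- match(ids, species$sample_id)
  if (anyNA(idx)) {
    abort(sprintf("sample(s) missing from species map: %s",
                  paste(ids[is.na(idx)], collapse = ", ")))
  }
  sp <- species$species[idx]
  if (length(unique(sp)) < 2) {
    abort("discrimination needs at least 2 species")
  }
  n <- nrow(dmat)
  nn_sets <- vector("list", n)
  nn_dist <- rep(NA_real_, n)
  success <- logical(n)
  for (i in seq_len(n)) {
    d <- dmat[i, ]
    d[i] <- NA_real_
    if (all(is.na(d))) {
      nn_sets[[i]] <- character()
      next
    }
    m <- min(d, na.rm = TRUE)
    nn <- which(!is.na(d) & d == m)
    conspecific <- sp[nn] == sp[i]
    nn_sets[[i]] <- ids[nn]
    nn_dist[i] <- m
    success[i] <- if (tie_rule == "all") all(conspecific) else any(conspecific)
  }
  res <- tibble(sample_id = ids, species = sp, nn_distance = nn_dist,
                nn_set = nn_sets, success = success)
  by_species <- res |>
    group_by(species = .data$species) |>
    summarise(n_samples = n(), success = all(.data$success),
              .groups = "drop")
  structure(
    list(
      samples = res,
      by_species = by_species,
      pm = 100 * sum(res$success) / n,
      n_success = sum(res$success),
      n_samples = n,
      tie_rule = tie_rule
    ),
    class = "discrimination_result"
  )
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf(
    "<discrimination_result> Pm = %.2f%% (%d/%d samples; %d/%d species; tie rule '%s')\n",
    x$pm, x$n_success, x$n_samples, sum(x$by_species$success),
    nrow(x$by_species), x$tie_rule))
  invisible(x)
}

# Discriminated-sample count for a distance matrix: the nearest-neighbour
# rule of near_neighbour() without the per-sample bookkeeping. Used inside
# the window scans, where it runs once per window.
nn_success_count <- function(dmat, sp, tie_rule) {
  n <- nrow(dmat)
  diag(dmat) <- NA_real_
  count <- 0L
  for (i in seq_len(n)) {
    d <- dmat[i, ]
    if (all(is.na(d))) next
    m <- min(d, na.rm = TRUE)
    conspecific <- sp[!is.na(d) & d == m] == sp[i]
    ok <- if (tie_rule == "all") all(conspecific) else any(conspecific)
    if (ok) count <- count + 1L
  }
  count
}

# Per-pair cumulative transition/transversion/comparable-site counts used by
# the window scans: counting inside any column window then costs O(1) per
# pair instead of a rescan.
pair_cumulants <- function(mat) {
  n <- nrow(mat)
  pairs <- utils::combn(n, 2)
  L <- ncol(mat)
  n_pairs <- ncol(pairs)
  cum_comp <- matrix(0L, n_pairs, L + 1L)
  cum_ts <- matrix(0L, n_pairs, L + 1L)
  cum_tv <- matrix(0L, n_pairs, L + 1L)
  for (p in seq_len(n_pairs)) {
    a <- mat[pairs[1, p], ]
    b <- mat[pairs[2, p], ]
    comp <- is_base(a) & is_base(b)
    diff <- comp & a != b
    ts <- diff & is_transition(a, b)
    cum_comp[p, ] <- c(0L, cumsum(comp))
    cum_ts[p, ] <- c(0L, cumsum(ts))
    cum_tv[p, ] <- c(0L, cumsum(diff & !ts))
  }
  list(pairs = pairs, comp = cum_comp, ts = cum_ts, tv = cum_tv, n = n, L = L)
}

# K2P distance matrix on the column window [s, s + len) from cumulants.
window_dmat <- function(cu, s, len, ids) {
  e <- s + len
  m <- cu$comp[, e] - cu$comp[, s]
  ts <- cu$ts[, e] - cu$ts[, s]
  tv <- cu$tv[, e] - cu$tv[, s]
  d_vec <- ifelse(m > 0, k2p_from_pq(ts / m, tv / m), NA_real_)
  d <- matrix(0, cu$n, cu$n, dimnames = list(ids, ids))
  d[t(cu$pairs)] <- d_vec
  d[t(cu$pairs[2:1, , drop = FALSE])] <- d_vec
  d
}

#' Discrimination power over all windows of one length
#'
#' Slides a window of `window_length` columns along the alignment (step
#' `window_step`), computes the K2P matrix within each window, and evaluates
#' nearest-neighbour discrimination on it. Windows are alignment-column
#' slices: gap columns count toward the nominal window length.
#'
#' @param aln A [marker_alignment].
#' @param species Species map tibble.
#' @param window_length Window length in alignment columns.
#' @param window_step Offset step between windows (default 1).
#' @param tie_rule Passed to [near_neighbour()].
#' @return A list with `windows` (tibble: `window_start`, `pm`, `n_success`),
#'   `max_pm`, `max_n_success`, and `best_start` (smallest start among the
#'   argmax windows).
#' @export
window_pm <- function(aln, species, window_length, window_step = 1,
                      tie_rule = c("all", "any")) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(inherits(aln, "marker_alignment"))
  L <- alignment_length(aln)
  if (window_length > L) {
    abort(sprintf("window length %d exceeds aligned length %d",
                  window_length, L))
  }
  sp <- species_of(aln, species) # validates coverage up front
  if (length(unique(sp)) < 2) abort("discrimination needs at least 2 species")
  cu <- pair_cumulants(aln$seqs)
  ids <- sample_ids(aln)
  n <- length(ids)
  starts <- seq(1L, L - window_length + 1L, by = window_step)
  counts <- vapply(starts, function(s) {
    nn_success_count(window_dmat(cu, s, window_length, ids), sp, tie_rule)
  }, 0L)
  rows <- tibble(window_start = starts, pm = 100 * counts / n,
                 n_success = counts)
  best <- which.max(rows$n_success)
  list(
    windows = rows,
    max_pm = rows$pm[best],
    max_n_success = rows$n_success[best],
    best_start = rows$window_start[best]
  )
}

#' Discrimination power as a function of window length
#'
#' For each length, reports the maximum Pm over all windows of that length
#' (the discrimination-power curve used to judge how short a marker can be
#' cut).
#'
#' @param aln A [marker_alignment].
#' @param species Species map tibble.
#' @param lengths Window lengths in bp (alignment columns); lengths exceeding
#'   the aligned length are skipped with a warning.
#' @param window_step Offset step between windows (default 1).
#' @param tie_rule Passed to [near_neighbour()].
#' @return Tibble with `length`, `max_pm`, `best_start`.
#' @export
pm_length_curve <- function(aln, species,
                            lengths = c(50, 100, 150, 200, 250, 300, 350),
                            window_step = 1, tie_rule = c("all", "any")) {
  tie_rule <- match.arg(tie_rule)
  L <- alignment_length(aln)
  skip <- lengths > L
  if (any(skip)) {
    warn(sprintf("skipping window length(s) beyond aligned length %d: %s",
                 L, paste(lengths[skip], collapse = ", ")))
    lengths <- lengths[!skip]
  }
  purrr::map(lengths, function(len) {
    w <- window_pm(aln, species, len, window_step = window_step,
                   tie_rule = tie_rule)
    tibble(length = len, max_pm = w$max_pm, best_start = w$best_start)
  }) |> bind_rows()
}

#' Shortest mini-barcode search
#'
#' Finds the shortest window length whose best window discriminates as many
#' samples as the full-length marker. The full-length discriminated-sample
#' count is computed first; window lengths `start`, `start + increment`, ...
#' are then scanned and the first length whose maximum window count equals
#' the full-length count (integer comparison, not floating percentages) is
#' returned together with the leftmost window attaining it.
#'
#' @param aln A [marker_alignment].
#' @param species Species map tibble.
#' @param start Starting window length in bp (default 50).
#' @param increment Length increment per round in bp (default 10).
#' @param window_step Offset step between windows of one length (default 1).
#' @param tie_rule Passed to [near_neighbour()].
#' @return An object of class `minibarcode_result`: `marker_name`,
#'   `shortest_length`, `best_window_start`, `pm_at_shortest`,
#'   `full_length_pm`, and `curve` (tibble of `length`, `max_pm`,
#'   `best_start` for every length scanned).
#' @export
shortest_minibarcode <- function(aln, species, start = 50, increment = 10,
                                 window_step = 1, tie_rule = c("all", "any")) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(inherits(aln, "marker_alignment"))
  L <- alignment_length(aln)
  if (L < start) {
    abort(sprintf("aligned length %d is shorter than the starting length %d",
                  L, start))
  }
  full <- window_pm(aln, species, L, tie_rule = tie_rule)
  target <- full$max_n_success
  lengths <- seq(start, L, by = increment)
  if (lengths[length(lengths)] < L) lengths <- c(lengths, L)
  curve <- list()
  found <- NULL
  for (len in lengths) {
    w <- window_pm(aln, species, len, window_step = window_step,
                   tie_rule = tie_rule)
    curve[[length(curve) + 1]] <-
      tibble(length = len, max_pm = w$max_pm, best_start = w$best_start)
    if (w$max_n_success == target) {
      found <- list(length = len, start = w$best_start, pm = w$max_pm)
      break
    }
  }
  if (is.null(found)) {
    warn("no scanned length reached the full-length discrimination count; returning full length")
    found <- list(length = L, start = 1L, pm = full$max_pm)
  }
  structure(
    list(
      marker_name = aln$marker_name,
      shortest_length = found$length,
      best_window_start = found$start,
      pm_at_shortest = found$pm,
      full_length_pm = full$max_pm,
      curve = bind_rows(curve)
    ),
    class = "minibarcode_result"
  )
}

#' @export
print.minibarcode_result <- function(x, ...) {
  cat(sprintf(
    "<minibarcode_result> %s: shortest %d bp at column %d (Pm %.2f%%; full-length Pm %.2f%%)\n",
    x$marker_name, x$shortest_length, x$best_window_start,
    x$pm_at_shortest, x$full_length_pm))
  invisible(x)
}
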