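# Brute-force oracles, independent of the package's incremental/cumulative
# code paths: everything here re-slices the alignment matrix and recounts
# from scratch.

ORACLE_BASES <- c("A", "C", "G", "T")

oracle_k2p <- function(a, b) {
  ok <- a %in% ORACLE_BASES & b %in% ORACLE_BASES
  m <- sum(ok)
  if (m == 0) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  purine_a <- a %in% c("A", "G")
  purine_b <- b %in% c("A", "G")
  ts <- sum(diff & (purine_a == purine_b))
  tv <- sum(diff) - ts
  P <- ts / m; Q <- tv / m
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

oracle_k2p_matrix <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- oracle_k2p(mat[i, ], mat[j, ])
  }
  d
}

oracle_pi <- function(mat) {
  n <- nrow(mat)
  props <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- mat[i, ] %in% ORACLE_BASES & mat[j, ] %in% ORACLE_BASES
    if (sum(ok) > 0) props <- c(props, sum(mat[i, ok] != mat[j, ok]) / sum(ok))
  }
  if (length(props) == 0) NA_real_ else mean(props)
}

# Per-sample nearest-neighbour success count by direct O(n^2) rescan.
oracle_nn_successes <- function(dmat, sp, tie_rule = "all") {
  n <- nrow(dmat)
  succ <- logical(n)
  for (i in seq_len(n)) {
    d <- dmat[i, -i]
    others <- sp[-i]
    if (all(is.na(d))) { succ[i] <- FALSE; next }
    m <- min(d, na.rm = TRUE)
    nn_sp <- others[!is.na(d) & d == m]
    succ[i] <- if (tie_rule == "all") all(nn_sp == sp[i]) else any(nn_sp == sp[i])
  }
  sum(succ)
}

# Best window of one length by exhaustive slicing. Per-pair per-column
# indicator vectors are extracted once; every window is then recounted
# directly by summing the slice (no incremental updates).
oracle_window_best <- function(mat, sp, len, tie_rule = "all") {
  n <- nrow(mat)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  inds <- lapply(seq_len(nrow(idx)), function(k) {
    a <- mat[idx[k, 1], ]; b <- mat[idx[k, 2], ]
    ok <- a %in% ORACLE_BASES & b %in% ORACLE_BASES
    diff <- ok & a != b
    ts <- diff & ((a %in% c("A", "G")) == (b %in% c("A", "G")))
    list(ok = ok, ts = ts, tv = diff & !ts)
  })
  starts <- seq(1, ncol(mat) - len + 1)
  counts <- vapply(starts, function(s) {
    cols <- s:(s + len - 1)
    d <- matrix(0, n, n)
    for (k in seq_len(nrow(idx))) {
      m <- sum(inds[[k]]$ok[cols])
      dk <- if (m == 0) NA_real_ else {
        P <- sum(inds[[k]]$ts[cols]) / m
        Q <- sum(inds[[k]]$tv[cols]) / m
        if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) NA_real_
        else -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
      }
      d[idx[k, 1], idx[k, 2]] <- d[idx[k, 2], idx[k, 1]] <- dk
    }
    oracle_nn_successes(d, sp, tie_rule)
  }, 0)
  best <- which.max(counts)
  list(counts = counts, max_count = counts[best], best_start = starts[best])
}

# Full brute force over the (length, window) grid with the same grid
# semantics as the search: lengths start, start+inc, ..., then full length.
oracle_shortest <- function(mat, sp, start = 50, increment = 10,
                            tie_rule = "all") {
  L <- ncol(mat)
  target <- oracle_nn_successes(oracle_k2p_matrix(mat), sp, tie_rule)
  lengths <- seq(start, L, by = increment)
  if (lengths[length(lengths)] < L) lengths <- c(lengths, L)
  for (len in lengths) {
    w <- oracle_window_best(mat, sp, len, tie_rule)
    if (w$max_count == target) {
      return(list(length = len, best_start = w$best_start,
                  count = w$max_count, target = target))
    }
  }
  list(length = L, best_start = 1, count = target, target = target)
}

# Random test alignment: clustered species structure with optional gaps and
# ambiguity so pairwise deletion is exercised.
random_marker <- function(n_species, n_per_species, n_cols,
                          between = 0.05, within = 0.01,
                          p_gap = 0, p_ambig = 0) {
  anc <- sample(ORACLE_BASES, n_cols, replace = TRUE)
  mutate <- function(seq, rate) {
    hit <- which(stats::runif(length(seq)) < rate)
    seq[hit] <- vapply(seq[hit],
                       function(b) sample(setdiff(ORACLE_BASES, b), 1), "")
    seq
  }
  rows <- list()
  sp <- character(0)
  for (s in seq_len(n_species)) {
    cons <- mutate(anc, between)
    for (k in seq_len(n_per_species)) {
      x <- mutate(cons, within)
      if (p_gap > 0) x[stats::runif(n_cols) < p_gap] <- "-"
      if (p_ambig > 0) x[stats::runif(n_cols) < p_ambig] <- "N"
      rows[[sprintf("sp%02d_%d", s, k)]] <- x
      sp <- c(sp, sprintf("species%02d", s))
    }
  }
  mat <- do.call(rbind, rows)
  list(
    aln = marker_alignment(mat, "test_marker"),
    species = species_map(rownames(mat), sp),
    sp_vec = sp,
    mat = mat
  )
}

# Tiny aligned-pair builder from strings.
pair_of <- function(ref, oth) {
  suppressMessages(aligned_pair(ref, oth))
}
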