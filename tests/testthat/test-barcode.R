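# Build two sequences realising exact transition/transversion counts over m
# compared sites: reference all 'A', transitions become 'G', transversions 'C'.
seqs_with_counts <- function(n_ts, n_tv, m) {
  a <- rep("A", m)
  b <- rep("A", m)
  if (n_ts > 0) b[seq_len(n_ts)] <- "G"
  if (n_tv > 0) b[n_ts + seq_len(n_tv)] <- "C"
  list(a = a, b = b)
}

test_that("K2P distance matches the closed form and flags saturation", {
  expect_equal(k2p_distance("ACGTACGT", "ACGTACGT"), 0)

  # 200 compared sites, 20 transitions, 10 transversions
  s <- seqs_with_counts(20, 10, 200)
  expect_equal(k2p_distance(s$a, s$b),
               -0.5 * log(1 - 2 * 0.1 - 0.05) - 0.25 * log(1 - 2 * 0.05))
  expect_equal(round(k2p_distance(s$a, s$b), 4), 0.1702)

  # saturation: P = 0.5, Q = 0.1 -> 1 - 2P - Q <= 0
  s2 <- seqs_with_counts(50, 10, 100)
  expect_true(is.na(k2p_distance(s2$a, s2$b)))

  # no comparable site
  expect_true(is.na(k2p_distance("NN--", "AC--")))
  expect_error(k2p_distance("ACGT", "ACG"), "differ in length")

  # K2P >= p-distance whenever defined
  set.seed(17)
  for (rep in 1:20) {
    rm <- random_marker(2, 1, 150, between = 0.1, p_gap = 0.03)
    d <- k2p_distance(rm$mat[1, ], rm$mat[2, ])
    ok <- rm$mat[1, ] %in% c("A", "C", "G", "T") &
      rm$mat[2, ] %in% c("A", "C", "G", "T")
    p <- sum(rm$mat[1, ok] != rm$mat[2, ok]) / sum(ok)
    if (!is.na(d)) expect_gte(d, p)
  }
})

test_that("K2P agrees with ape's K80 distance on gap-free alignments", {
  set.seed(23)
  rm <- random_marker(4, 2, 300, between = 0.08, within = 0.02)
  ours <- suppressMessages(k2p_matrix(rm$aln))
  bin <- ape::as.DNAbin(apply(rm$mat, c(1, 2), tolower))
  theirs <- as.matrix(ape::dist.dna(bin, model = "K80",
                                    pairwise.deletion = TRUE))
  expect_equal(ours, theirs[rownames(ours), colnames(ours)],
               tolerance = 1e-12)
})

test_that("distance matrices are symmetric, zero-diagonal, with symmetric NAs", {
  m3 <- marker_alignment(matrix("A", 3, 10,
                                dimnames = list(paste0("s", 1:3), NULL)))
  expect_true(all(k2p_matrix(m3) == 0))

  set.seed(29)
  rm <- random_marker(3, 2, 80, p_gap = 0.1, p_ambig = 0.05)
  d <- suppressMessages(k2p_matrix(rm$aln))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_equal(d, oracle_k2p_matrix(rm$mat))
})

test_that("nearest-neighbour discrimination applies the conspecific tie rule", {
  # 2 species x 2 identical-within-species samples
  mat <- rbind(
    a1 = strsplit("AAAAAAAAAA", "")[[1]],
    a2 = strsplit("AAAAAAAAAA", "")[[1]],
    b1 = strsplit("AAAAACCCCC", "")[[1]],
    b2 = strsplit("AAAAACCCCC", "")[[1]]
  )
  sp <- species_map(rownames(mat), c("A", "A", "B", "B"))
  r <- near_neighbour(k2p_matrix(marker_alignment(mat)), sp)
  expect_equal(r$pm, 100)
  expect_true(all(r$by_species$success))

  # tie between one conspecific and one heterospecific sample
  tied <- matrix(0, 3, 3, dimnames = list(c("x1", "x2", "y1"),
                                          c("x1", "x2", "y1")))
  tied["x1", "x2"] <- tied["x2", "x1"] <- 0.1
  tied["x1", "y1"] <- tied["y1", "x1"] <- 0.1
  tied["x2", "y1"] <- tied["y1", "x2"] <- 0.2
  sp2 <- species_map(c("x1", "x2", "y1"), c("X", "X", "Y"))
  strict <- near_neighbour(tied, sp2, tie_rule = "all")
  expect_false(strict$samples$success[strict$samples$sample_id == "x1"])
  permissive <- near_neighbour(tied, sp2, tie_rule = "any")
  expect_true(permissive$samples$success[permissive$samples$sample_id == "x1"])

  # a sample with no defined distance fails and is flagged
  und <- matrix(NA_real_, 3, 3, dimnames = dimnames(tied))
  diag(und) <- 0
  und["x1", "x2"] <- und["x2", "x1"] <- 0.1
  r_und <- near_neighbour(und, sp2)
  expect_false(r_und$samples$success[r_und$samples$sample_id == "y1"])

  # single-species input is an error
  expect_error(near_neighbour(tied, species_map(c("x1", "x2", "y1"),
                                                c("X", "X", "X"))),
               "at least 2 species")
})

test_that("near_neighbour agrees with an exhaustive rescan on random matrices", {
  set.seed(37)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    sp_vec <- sample(sprintf("sp%d", 1:3), n, replace = TRUE)
    while (length(unique(sp_vec)) < 2) {
      sp_vec <- sample(sprintf("sp%d", 1:3), n, replace = TRUE)
    }
    ids <- sprintf("s%02d", seq_len(n))
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    vals <- sample(c(0, 0.01, 0.02, 0.05, NA), n * (n - 1) / 2,
                   replace = TRUE)
    d[upper.tri(d)] <- vals
    d[lower.tri(d)] <- t(d)[lower.tri(d)]
    sp <- species_map(ids, sp_vec)
    for (rule in c("all", "any")) {
      r <- near_neighbour(d, sp, tie_rule = rule)
      expect_equal(r$n_success, oracle_nn_successes(d, sp_vec, rule))
    }
  }
})

test_that("window scans reproduce full-length Pm and find diagnostic blocks", {
  set.seed(43)
  rm <- random_marker(4, 3, 120, between = 0.08, within = 0.005)
  full <- window_pm(rm$aln, rm$species, window_length = 120)
  direct <- near_neighbour(suppressMessages(k2p_matrix(rm$aln)), rm$species)
  expect_equal(full$max_pm, direct$pm)
  expect_equal(nrow(full$windows), 1)

  # all variable columns inside [10, 20): every window containing the block
  # attains the maximum
  base <- matrix("A", 8, 60, dimnames = list(sprintf("t%d", 1:8), NULL))
  block <- rbind(
    c("C", "C", "C", "C", "C", "C", "C", "C", "C", "C"),
    c("C", "C", "C", "C", "C", "C", "C", "C", "C", "C"),
    c("G", "G", "G", "G", "G", "G", "G", "G", "G", "G"),
    c("G", "G", "G", "G", "G", "G", "G", "G", "G", "G"),
    c("T", "T", "T", "T", "T", "T", "T", "T", "T", "T"),
    c("T", "T", "T", "T", "T", "T", "T", "T", "T", "T"),
    c("A", "C", "A", "C", "A", "C", "A", "C", "A", "C"),
    c("A", "C", "A", "C", "A", "C", "A", "C", "A", "C")
  )
  base[, 10:19] <- block
  aln <- marker_alignment(base)
  sp <- species_map(sprintf("t%d", 1:8), rep(c("w", "x", "y", "z"), each = 2))
  w <- window_pm(aln, sp, window_length = 25)
  contains <- w$windows$window_start <= 10 &
    w$windows$window_start + 24 >= 19
  expect_true(all(w$windows$pm[contains] == max(w$windows$pm)))
  expect_equal(max(w$windows$pm), 100)

  # a window with zero variable columns gives all-zero distances: everyone is
  # everyone's neighbour, so heterospecific ties fail samples
  w0 <- window_pm(aln, sp, window_length = 5)
  expect_equal(min(w0$windows$pm), 0)
})

test_that("window Pm agrees with exhaustive slicing on random alignments", {
  set.seed(47)
  for (rep in 1:10) {
    rm <- random_marker(3, 2, sample(40:90, 1), between = 0.1,
                        within = 0.02, p_gap = 0.02)
    len <- sample(10:30, 1)
    w <- window_pm(rm$aln, rm$species, window_length = len)
    o <- oracle_window_best(rm$mat, rm$sp_vec, len)
    expect_equal(w$windows$n_success, unname(o$counts))
    expect_equal(w$max_n_success, o$max_count)
    expect_equal(w$best_start, o$best_start)
  }
})

test_that("Pm-length curves skip over-long windows and flatten for diagnostic columns", {
  # one diagnostic column: curve is flat at the full-length Pm from 50 bp on
  base <- matrix("A", 6, 400, dimnames = list(sprintf("u%d", 1:6), NULL))
  base[, 200] <- c("C", "C", "G", "G", "T", "T")
  aln <- marker_alignment(base)
  sp <- species_map(sprintf("u%d", 1:6), rep(c("p", "q", "r"), each = 2))
  curve <- pm_length_curve(aln, sp, lengths = c(50, 100, 150))
  full <- near_neighbour(k2p_matrix(aln), sp)
  expect_true(all(curve$max_pm == full$pm))

  expect_warning(
    short <- pm_length_curve(aln, sp, lengths = c(100, 500)),
    "skipping")
  expect_equal(short$length, 100)
})

test_that("the shortest mini-barcode search matches brute-force enumeration", {
  set.seed(53)
  for (rep in 1:6) {
    rm <- random_marker(3, 2, sample(70:130, 1), between = 0.08,
                        within = 0.01)
    mb <- shortest_minibarcode(rm$aln, rm$species, start = 20, increment = 10)
    o <- oracle_shortest(rm$mat, rm$sp_vec, start = 20, increment = 10)
    expect_equal(mb$shortest_length, o$length)
    expect_equal(mb$best_window_start, o$best_start)
    expect_equal(mb$pm_at_shortest, mb$full_length_pm)
  }
})

test_that("a planted diagnostic block bounds the shortest mini-barcode", {
  sim <- simulate_marker_dataset(n_species = 6, n_per_species = 3,
                                 length = 400, between_divergence = 0.02,
                                 within_divergence = 0,
                                 diagnostic_block = c(100, 40), seed = 61)
  mb <- shortest_minibarcode(sim$alignment, sim$species_map)
  expect_equal(mb$shortest_length, 50)
  # returned window overlaps the planted block
  expect_lte(mb$best_window_start, 139)
  expect_gte(mb$best_window_start + 49, 100)
  expect_equal(mb$pm_at_shortest, 100)
})
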