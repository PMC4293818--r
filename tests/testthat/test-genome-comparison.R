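test_that("single-column substitutions are classified and collapsed", {
  pair <- pair_of("GATTACA", "GACTACA")
  scan <- classify_substitutions(pair)
  expect_equal(scan$summary$n_total, 1)
  expect_equal(scan$events$ref_pos, 3)
  expect_equal(scan$events$type, "transition")
  expect_equal(scan$events$collapsed_type, "T>C")

  # identical sequences: no events, Ts/Tv undefined
  scan0 <- classify_substitutions(pair_of("GATTACA", "GATTACA"))
  expect_equal(scan0$summary$n_total, 0)
  expect_true(is.na(scan0$summary$ts_tv))

  # ambiguity is missing data, not a substitution
  scanN <- classify_substitutions(pair_of("GANTACA", "GACTACA"))
  expect_equal(scanN$summary$n_total, 0)
})

test_that("the 6-class collapsing maps every ordered pair to its canonical class", {
  # each class stands for itself and its complement
  expected <- c("C>T" = "C>T", "G>A" = "C>T", "T>C" = "T>C", "A>G" = "T>C",
                "C>A" = "C>A", "G>T" = "C>A", "A>C" = "A>C", "T>G" = "A>C",
                "C>G" = "C>G", "G>C" = "C>G", "A>T" = "A>T", "T>A" = "A>T")
  for (nm in names(expected)) {
    b <- strsplit(nm, ">")[[1]]
    scan <- classify_substitutions(pair_of(b[1], b[2]), mask_inversions = FALSE)
    expect_equal(scan$events$collapsed_type, unname(expected[nm]), info = nm)
  }
})

test_that("substitution events match a brute-force column scan on random pairs", {
  set.seed(41)
  for (rep in 1:20) {
    L <- sample(50:200, 1)
    ref <- sample(c("A", "C", "G", "T", "-", "N"), L, replace = TRUE,
                  prob = c(0.23, 0.23, 0.23, 0.23, 0.05, 0.03))
    oth <- ifelse(stats::runif(L) < 0.1,
                  sample(c("A", "C", "G", "T", "-"), L, replace = TRUE), ref)
    keep <- !(ref == "-" & oth == "-")
    ref <- ref[keep]; oth <- oth[keep]
    pair <- pair_of(paste(ref, collapse = ""), paste(oth, collapse = ""))
    scan <- classify_substitutions(pair, mask_inversions = FALSE)
    # oracle: direct column scan
    base <- c("A", "C", "G", "T")
    exp_cols <- which(ref %in% base & oth %in% base & ref != oth)
    expect_equal(scan$events$column, exp_cols)
    # conservation of counts
    s <- scan$summary
    expect_equal(s$n_transition + s$n_transversion, s$n_total)
    expect_equal(sum(s$spectrum$n), s$n_total)
    expect_equal(sum(s$by_region$n_total), s$n_total)
  }
})

test_that("swapping reference and other mirrors the spectrum and indel carriers", {
  set.seed(99)
  sim <- simulate_genome_pair(length = 20000, n_substitutions = 80,
                              n_indels = 20, inversion_loops = integer(0),
                              inversion_stems = integer(0), seed = 99)
  fwd <- classify_substitutions(sim$pair, mask_inversions = FALSE)
  rev_pair <- suppressMessages(aligned_pair(sim$pair$other, sim$pair$reference))
  bwd <- classify_substitutions(rev_pair, mask_inversions = FALSE)
  expect_equal(bwd$summary$n_total, fwd$summary$n_total)
  expect_equal(bwd$summary$n_transition, fwd$summary$n_transition)
  mirror <- c("C>T" = "T>C", "T>C" = "C>T", "C>A" = "A>C", "A>C" = "C>A",
              "C>G" = "C>G", "A>T" = "A>T")
  fwd_spec <- setNames(fwd$summary$spectrum$n, fwd$summary$spectrum$collapsed_type)
  bwd_spec <- setNames(bwd$summary$spectrum$n, bwd$summary$spectrum$collapsed_type)
  expect_equal(unname(bwd_spec[mirror[names(fwd_spec)]]), unname(fwd_spec))

  fwd_ind <- suppressMessages(detect_indels(sim$pair))
  bwd_ind <- suppressMessages(detect_indels(rev_pair))
  expect_equal(nrow(bwd_ind), nrow(fwd_ind))
  expect_equal(sum(bwd_ind$carrier == "reference"),
               sum(fwd_ind$carrier == "other"))
})

test_that("Ts/Tv by region divides counts and flags zero denominators", {
  pair <- pair_of("AAAAAAAAAACCCCCCCCCC",
                  "GGGAAAAAAATTACCCCCCC")
  features <- feature_table(c(1, 11), c(10, 20), c("coding", "intron"),
                            c("g1", "i1"))
  scan <- classify_substitutions(pair, features, mask_inversions = FALSE)
  tab <- tstv_by_region(scan)
  coding <- tab[tab$region == "coding", ]
  # 3 A>G transitions, 0 transversions in coding
  expect_equal(coding$n_ts, 3)
  expect_true(coding$undefined)
  intron <- tab[tab$region == "intron", ]
  # 2 C>T transitions, 1 C>A transversion -> 2.00
  expect_equal(intron$ratio, 2)
  # 3 Ts / 2 Tv rounds to 1.50
  pair2 <- pair_of("AAACCAAAAA", "GGGAAAAAAA")
  tab2 <- tstv_by_region(classify_substitutions(pair2, mask_inversions = FALSE))
  expect_equal(tab2$ratio, 1.5)
})

test_that("region lookup stratifies positions and errors out of range", {
  features <- feature_table(c(1, 501), c(300, 800), c("coding", "coding"),
                            c("g1", "g2"))
  expect_equal(region_of(10, features), "coding")
  expect_equal(region_of(400, features), "spacer")   # between genes
  expect_equal(region_of(900, features, reference_length = 1000),
               "unannotated")                        # beyond last gene
  expect_error(region_of(1001, features, reference_length = 1000),
               "outside")
  expect_equal(region_of(c(10, 400), features), c("coding", "spacer"))
})

test_that("indel events are maximal gap runs with terminal runs excluded", {
  pair <- pair_of("ACGT----ACGT", "ACGTTTTTACGT")
  ev <- detect_indels(pair)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$length, 4)
  expect_equal(ev$carrier, "reference")
  expect_equal(ev$ref_pos, 4) # base preceding the gap run

  expect_equal(nrow(detect_indels(pair_of("ACGT", "ACGT"))), 0)

  # terminal gaps are missing ends, not indels
  pair_t <- pair_of("--GTACGTA-", "ACGTA--TAC")
  expect_message(ev_t <- detect_indels(pair_t), "terminal")
  expect_equal(nrow(ev_t), 1)
  expect_equal(ev_t$carrier, "other")

  # histogram bins 1..10 with >10 tail
  h <- indel_length_histogram(tibble::tibble(length = c(1, 1, 2, 34)))
  expect_equal(sum(h$n), 4)
  expect_equal(h$n[h$length_bin == "1"], 2)
  expect_equal(h$n[h$length_bin == ">10"], 1)
})

test_that("planted hairpin inversions are detected with exact loop and stem", {
  sim <- simulate_genome_pair(length = 2000, n_substitutions = 0,
                              n_indels = 0, inversion_loops = 18L,
                              inversion_stems = 11L, seed = 5)
  inv <- detect_inversions(sim$pair)
  expect_equal(nrow(inv), 1)
  expect_equal(inv$loop_length, 18L)
  expect_equal(inv$stem_length, 11L)
  expect_equal(inv$loop_start, sim$truth$inversions$ref_start)
  expect_equal(inv$loop_end, sim$truth$inversions$ref_end)
  # the loop on the other genome is the reverse complement of the reference
  ref_loop <- sim$pair$reference[inv$col_start:inv$col_end]
  oth_loop <- sim$pair$other[inv$col_start:inv$col_end]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_identical(oth_loop, rev(unname(comp[ref_loop])))
  # stems are inverted repeats of each other
  expect_identical(
    inv$stem_right,
    paste(rev(unname(comp[strsplit(inv$stem_left, "")[[1]]])), collapse = ""))

  expect_equal(nrow(detect_inversions(pair_of("ACGTACGT", "ACGTACGT"))), 0)
})

test_that("inversion loops are masked from substitution counts by default", {
  sim <- simulate_genome_pair(length = 5000, n_substitutions = 40,
                              n_indels = 0, inversion_loops = c(19L, 14L),
                              inversion_stems = c(5L, 11L), seed = 11)
  masked <- classify_substitutions(sim$pair)
  expect_equal(masked$summary$n_total, 40)
  unmasked <- classify_substitutions(sim$pair, mask_inversions = FALSE)
  expect_gt(unmasked$summary$n_total, 40)
})
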