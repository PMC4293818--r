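# Mutate one base: transition with probability kappa/(kappa+2), otherwise one
# of the two transversions with equal probability.
TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS_OF <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

mutate_base <- function(base, kappa) {
  if (stats::runif(1) < kappa / (kappa + 2)) {
    unname(TRANSITION_OF[base])
  } else {
    sample(TRANSVERSIONS_OF[[base]], 1)
  }
}

random_sequence <- function(length) {
  sample(DNA_BASES, length, replace = TRUE)
}

# Draw n non-overlapping intervals of the given widths inside [margin+1,
# length-margin], by rejection; widths include any clearance the caller
# padded in. Returns sorted start positions.
place_intervals <- function(n, widths, length, margin = 0,
                            occupied = NULL, max_tries = 10000) {
  starts <- integer(0)
  taken <- occupied %||% tibble(start = integer(), end = integer())
  for (k in seq_len(n)) {
    w <- widths[k]
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample.int(length - w - 2 * margin, 1) + margin
      e <- s + w - 1L
      if (!any(s <= taken$end & e >= taken$start)) {
        taken <- bind_rows(taken, tibble(start = s, end = e))
        starts <- c(starts, s)
        placed <- TRUE
        break
      }
    }
    if (!placed) abort("could not place events without overlap; reduce counts or lengths")
  }
  starts
}

#' Default indel length distribution for simulated genome pairs
#'
#' Mirrors the indel spectrum of a congeneric plastome pair: most indels are
#' single-base, lengths tail off geometrically, a small number exceed 10 bp,
#' and one long (34 bp) event is included.
#'
#' @param n Number of indel events.
#' @return Integer vector of `n` lengths.
#' @export
default_indel_lengths <- function(n) {
  if (n == 0) return(integer(0))
  probs <- c(0.631, 0.13, 0.06, 0.04, 0.025, 0.014, 0.01, 0.01, 0.01, 0.01)
  probs <- c(probs, 1 - sum(probs)) # >10 bp tail
  lens <- sample(1:11, n, replace = TRUE, prob = probs)
  lens[lens == 11] <- sample(11:30, sum(lens == 11), replace = TRUE)
  if (n >= 1) lens[1] <- 34L
  as.integer(lens)
}

#' Simulate an aligned congeneric genome pair with planted events
#'
#' Generates an ancestral sequence uniform over A/C/G/T and derives the
#' "other" genome by planting non-overlapping substitutions (transition
#' probability `kappa/(kappa+2)`), indels (gap runs in one of the two
#' sequences) and hairpin microinversions (a reverse-complemented loop
#' flanked by planted inverted repeats present in both genomes). Event
#' positions are drawn by rejection into non-overlapping slots so the planted
#' truth is exactly recoverable. A feature table partitions the reference
#' into alternating coding/spacer intervals. Defaults emulate a pair of
#' chloroplast genomes from congeneric plant species at ~0.3% divergence.
#'
#' @param length Genome length in bp (default 156000).
#' @param n_substitutions Number of substitutions to plant (default 464).
#' @param kappa Transition/transversion rate bias; the probability that a
#'   substitution is a transition is `kappa/(kappa+2)` (default 2.9, i.e. a
#'   Ts fraction of ~0.59).
#' @param n_indels Number of indel events (default 156).
#' @param indel_lengths Integer vector of indel lengths (recycled/truncated
#'   to `n_indels`); default drawn from [default_indel_lengths()].
#' @param inversion_loops,inversion_stems Loop and stem lengths of planted
#'   microinversions (defaults 19/18/14 bp loops with 3/44/11 bp stems).
#' @param feature_width,spacer_width Widths of the alternating coding and
#'   spacer intervals in the generated feature table.
#' @param seed Integer seed; identical seeds reproduce identical output.
#' @return A list with `pair` ([aligned_pair]), `features` (tibble), and
#'   `truth` (list of tibbles `substitutions`, `indels`, `inversions`, plus
#'   the generator parameters).
#' @export
simulate_genome_pair <- function(length = 156000,
                                 n_substitutions = 464,
                                 kappa = 2.9,
                                 n_indels = 156,
                                 indel_lengths = NULL,
                                 inversion_loops = c(19L, 18L, 14L),
                                 inversion_stems = c(3L, 44L, 11L),
                                 feature_width = 900,
                                 spacer_width = 300,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(inversion_loops) == length(inversion_stems))
  n_inv <- length(inversion_loops)
  if (is.null(indel_lengths)) indel_lengths <- default_indel_lengths(n_indels)
  indel_lengths <- as.integer(rep_len(indel_lengths, n_indels))

  anc <- random_sequence(length)

  # reserve non-overlapping slots: inversions (stem+loop+stem plus 1 bp
  # clearance so greedy stem extension stops where planted), indels (plus
  # 1 bp clearance so runs stay maximal), substitutions
  inv_width <- inversion_loops + 2L * inversion_stems + 2L
  occupied <- tibble(start = integer(), end = integer())
  inv_starts <- integer(0)
  if (n_inv > 0) {
    inv_starts <- place_intervals(n_inv, inv_width, length, margin = 2)
    occupied <- tibble(start = inv_starts, end = inv_starts + inv_width - 1L)
  }
  ind_starts <- integer(0)
  if (n_indels > 0) {
    ind_starts <- place_intervals(n_indels, indel_lengths + 2L, length,
                                  margin = 2, occupied = occupied)
    occupied <- bind_rows(
      occupied,
      tibble(start = ind_starts, end = ind_starts + indel_lengths + 1L))
  }
  sub_pos <- integer(0)
  if (n_substitutions > 0) {
    sub_pos <- place_intervals(n_substitutions,
                               rep(1L, n_substitutions), length,
                               margin = 2, occupied = occupied)
  }

  ref <- anc
  oth <- anc

  # substitutions on the other genome
  sub_truth <- NULL
  if (n_substitutions > 0) {
    new_base <- vapply(ref[sub_pos], mutate_base, "", kappa = kappa,
                       USE.NAMES = FALSE)
    oth[sub_pos] <- new_base
    sub_truth <- tibble(pos = sub_pos, ref_base = ref[sub_pos],
                        other_base = new_base) |>
      mutate(type = ifelse(is_transition(.data$ref_base, .data$other_base),
                           "transition", "transversion")) |>
      arrange(.data$pos)
  } else {
    sub_truth <- tibble(pos = integer(), ref_base = character(),
                        other_base = character(), type = character())
  }

  # inversions: plant stems in both genomes, reverse-complement the loop in
  # the other genome. Loop drawn from {A,C} so its reverse complement
  # mismatches at every column; clearance base forced non-complementary so
  # the recovered stem length is exactly the planted one.
  inv_truth <- purrr::map(seq_len(n_inv), function(i) {
    stem <- inversion_stems[i]
    loop_len <- inversion_loops[i]
    s <- inv_starts[i] + 1L # skip clearance base
    loop_start <- s + stem
    loop_end <- loop_start + loop_len - 1L
    stem_seq <- random_sequence(stem)
    loop_seq <- sample(c("A", "C"), loop_len, replace = TRUE)
    ref[loop_start:loop_end] <<- loop_seq
    ref[(loop_start - stem):(loop_start - 1L)] <<- stem_seq
    ref[(loop_end + 1L):(loop_end + stem)] <<- revcomp(stem_seq)
    # break stem extension beyond the planted repeat
    outer_left <- loop_start - stem - 1L
    outer_right <- loop_end + stem + 1L
    bad <- complement_base(ref[outer_right])
    ref[outer_left] <<- sample(setdiff(DNA_BASES, bad), 1)
    span <- outer_left:outer_right
    oth[span] <<- ref[span]
    oth[loop_start:loop_end] <<- revcomp(loop_seq)
    tibble(loop_start = loop_start, loop_end = loop_end,
           loop_length = loop_len, stem_length = stem)
  }) |> bind_rows()
  if (n_inv == 0) {
    inv_truth <- tibble(loop_start = integer(), loop_end = integer(),
                        loop_length = integer(), stem_length = integer())
  } else {
    inv_truth <- arrange(inv_truth, .data$loop_start)
  }

  # indels: gap run in one sequence (the carrier)
  carriers <- if (n_indels > 0) {
    sample(c("reference", "other"), n_indels, replace = TRUE)
  } else character(0)
  ind_truth <- purrr::map(seq_len(n_indels), function(i) {
    s <- ind_starts[i] + 1L
    e <- s + indel_lengths[i] - 1L
    if (carriers[i] == "reference") ref[s:e] <<- "-" else oth[s:e] <<- "-"
    tibble(pos = s, length = indel_lengths[i], carrier = carriers[i])
  }) |> bind_rows()
  if (n_indels == 0) {
    ind_truth <- tibble(pos = integer(), length = integer(),
                        carrier = character())
  } else {
    ind_truth <- arrange(ind_truth, .data$pos)
  }

  # alternating coding/spacer annotation on the ungapped reference
  ref_len <- sum(ref != "-")
  starts <- seq(1L, ref_len, by = feature_width + spacer_width)
  features <- purrr::map(seq_along(starts), function(i) {
    gene_end <- min(starts[i] + feature_width - 1L, ref_len)
    tibble(start = starts[i], end = gene_end, category = "coding",
           name = sprintf("gene%03d", i))
  }) |> bind_rows()
  features <- feature_table(features$start, features$end, features$category,
                            features$name, reference_length = ref_len)

  pair <- suppressMessages(
    aligned_pair(ref, oth, reference_id = "sim_reference",
                 other_id = "sim_other"))
  # planted coordinates refer to the pre-gap ancestor; translate the
  # substitution/inversion coordinates onto the ungapped reference
  anc_to_ref <- cumsum(ref != "-")
  sub_truth$ref_pos <- anc_to_ref[sub_truth$pos]
  inv_truth$ref_start <- anc_to_ref[inv_truth$loop_start]
  inv_truth$ref_end <- anc_to_ref[inv_truth$loop_end]

  list(
    pair = pair,
    features = features,
    truth = list(
      seed = seed,
      length = length,
      kappa = kappa,
      substitutions = sub_truth,
      indels = ind_truth,
      inversions = inv_truth
    )
  )
}

#' Simulate a multi-species marker alignment with a barcode gap
#'
#' Builds a star phylogeny: a per-species consensus is mutated from a common
#' ancestor at `between_divergence` expected substitutions/site (confined to
#' `diagnostic_block` when given), then each individual is mutated from its
#' species consensus at `within_divergence`. Substitutions use the same
#' transition bias as the genome simulator; no indels are introduced, so
#' distance oracles stay closed-form. Defaults emulate a barcoding study
#' design of 8 congeneric species with 3 accessions each and a pronounced
#' barcode gap.
#'
#' @param n_species Number of species (>= 2; default 8).
#' @param n_per_species Samples per species (default 3).
#' @param length Marker length in bp (default 800).
#' @param between_divergence Expected per-site divergence of each species
#'   consensus from the ancestor (default 0.02).
#' @param within_divergence Expected per-site divergence of an individual
#'   from its species consensus (default 0.001).
#' @param kappa Transition bias (default 2.9).
#' @param diagnostic_block Optional `c(start, length)`: between-species
#'   mutations are confined to these columns.
#' @param marker_name Marker name.
#' @param seed Integer seed.
#' @return A list with `alignment` ([marker_alignment]), `species_map`
#'   (tibble), and `truth` (generator parameters plus the ancestor and
#'   per-species consensus sequences).
#' @export
simulate_marker_dataset <- function(n_species = 8, n_per_species = 3,
                                    length = 800,
                                    between_divergence = 0.02,
                                    within_divergence = 0.001,
                                    kappa = 2.9,
                                    diagnostic_block = NULL,
                                    marker_name = "sim_marker",
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_species < 2) abort("need at least 2 species")
  if (n_per_species < 1) abort("need at least 1 sample per species")
  if (between_divergence < 0 || between_divergence > 0.75 ||
      within_divergence < 0 || within_divergence > 0.75) {
    abort("divergences must lie in [0, 0.75]")
  }
  if (between_divergence < within_divergence) {
    abort("between-species divergence must be >= within-species divergence")
  }
  anc <- random_sequence(length)
  between_sites <- seq_len(length)
  if (!is.null(diagnostic_block)) {
    s <- diagnostic_block[1]
    between_sites <- seq(s, min(s + diagnostic_block[2] - 1L, length))
  }
  mutate_from <- function(seq, rate, sites = seq_along(seq)) {
    hit <- sites[stats::runif(length(sites)) < rate]
    if (length(hit) > 0) {
      seq[hit] <- vapply(seq[hit], mutate_base, "", kappa = kappa)
    }
    seq
  }
  # per-species consensus: expected between_divergence over the whole marker,
  # concentrated on the diagnostic block when one is set
  rate_between <- between_divergence * length / length(between_sites)
  if (rate_between > 1) rate_between <- 1
  consensus <- purrr::map(seq_len(n_species), function(s) {
    mutate_from(anc, rate_between, between_sites)
  })
  seqs <- list()
  ids <- character(0)
  species <- character(0)
  for (s in seq_len(n_species)) {
    for (k in seq_len(n_per_species)) {
      id <- sprintf("sp%02d_s%d", s, k)
      seqs[[id]] <- mutate_from(consensus[[s]], within_divergence)
      ids <- c(ids, id)
      species <- c(species, sprintf("species_%02d", s))
    }
  }
  mat <- do.call(rbind, seqs)
  rownames(mat) <- ids
  list(
    alignment = marker_alignment(mat, marker_name = marker_name),
    species_map = species_map(ids, species),
    truth = list(
      seed = seed, n_species = n_species, n_per_species = n_per_species,
      length = length, between_divergence = between_divergence,
      within_divergence = within_divergence, kappa = kappa,
      diagnostic_block = diagnostic_block,
      ancestor = paste(anc, collapse = ""),
      consensus = vapply(consensus, paste, "", collapse = "")
    )
  )
}
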