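#' Assemble a pipeline run configuration
#'
#' A run configuration names the inputs and parameters of an end-to-end
#' mini-barcode design: genome comparison and diversity scan when a genome
#' pair is given, marker discrimination and shortest-window search when
#' marker alignments and a species map are given. Either part may be omitted;
#' the run executes the stages its inputs allow. Configurations can also be
#' read from a YAML file with the same keys.
#'
#' @param genome_pair Path to a two-record aligned FASTA, or an
#'   [aligned_pair].
#' @param features Path to a feature table TSV, or a [feature_table] tibble.
#' @param markers Named list of paths to marker aligned FASTA files, or of
#'   [marker_alignment] objects.
#' @param species Path to a species-map TSV, or a species map tibble.
#' @param out_dir Output directory (created if absent).
#' @param window_length,step,threshold Diversity-scan parameters.
#' @param start,increment,window_step,tie_rule Mini-barcode search parameters.
#' @param reference_id Reference record id for the genome pair.
#' @return A list of class `run_config`.
#' @export
run_config <- function(genome_pair = NULL, features = NULL, markers = NULL,
                       species = NULL, out_dir = "minibarcodes_out",
                       window_length = 600, step = 25, threshold = 0.012,
                       start = 50, increment = 10, window_step = 1,
                       tie_rule = "all", reference_id = NULL) {
  cfg <- list(
    genome_pair = genome_pair, features = features, markers = markers,
    species = species, out_dir = out_dir,
    window_length = window_length, step = step, threshold = threshold,
    start = start, increment = increment, window_step = window_step,
    tie_rule = tie_rule, reference_id = reference_id
  )
  for (key in c("genome_pair", "features", "species")) {
    p <- cfg[[key]]
    if (is.character(p) && !file.exists(p)) {
      abort(sprintf("%s file not found: %s", key, p))
    }
  }
  for (p in cfg$markers) {
    if (is.character(p) && !file.exists(p)) {
      abort(sprintf("marker file not found: %s", p))
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [run_config()].
#' @param overrides Named list of values overriding the file's keys.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  do.call(run_config, raw)
}

resolve_pair <- function(x, reference_id = NULL) {
  if (inherits(x, "aligned_pair")) x
  else read_alignment(x, kind = "genome_pair", reference_id = reference_id)
}

resolve_marker <- function(x, name) {
  if (inherits(x, "marker_alignment")) x
  else read_alignment(x, kind = "marker", marker_name = name)
}

resolve_species <- function(x) {
  if (is.data.frame(x)) x else read_species_map(x)
}

resolve_features <- function(x) {
  if (is.null(x) || is.data.frame(x)) x else read_feature_table(x)
}

#' Run the end-to-end mini-barcode design pipeline
#'
#' Executes, in order and as the configured inputs allow: (1) genome
#' comparison (substitutions, Ts/Tv by region, indels, microinversions);
#' (2) sliding-window nucleotide diversity and hotspot calling on the genome
#' pair; (3) per-marker variability statistics; (4) nearest-neighbour
#' discrimination and the shortest-mini-barcode search per marker. Every
#' stage writes TSV/JSON artifacts into the output directory, and the run
#' ends with a manifest (JSON) listing parameters, input checksums, per-stage
#' outputs with checksums, and accumulated warnings, plus a summary table of
#' maximum discrimination success and shortest length per marker.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @return The manifest, invisibly, as a list; also written to
#'   `manifest.json` in the output directory.
#' @export
run_design <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)
  emit <- function(path) outputs <<- c(outputs, path)
  params <- config[c("window_length", "step", "threshold", "start",
                     "increment", "window_step", "tie_rule")]

  withCallingHandlers({
    if (!is.null(config$genome_pair)) {
      pair <- resolve_pair(config$genome_pair, config$reference_id)
      features <- resolve_features(config$features)

      inversions <- detect_inversions(pair)
      emit(write_report_tsv(inversions,
                            file.path(config$out_dir, "inversions.tsv")))
      scan <- classify_substitutions(pair, features, inversions = inversions)
      emit(write_report_tsv(scan$events,
                            file.path(config$out_dir, "substitutions.tsv")))
      emit(write_report_json(
        list(summary = glance(scan), spectrum = scan$summary$spectrum,
             by_region = tstv_by_region(scan)),
        file.path(config$out_dir, "substitution_summary.json")))
      indels <- detect_indels(pair, features)
      emit(write_report_tsv(indels,
                            file.path(config$out_dir, "indels.tsv")))

      track <- sliding_pi(pair, window_length = config$window_length,
                          step = config$step)
      emit(write_report_tsv(as_tibble(track),
                            file.path(config$out_dir, "diversity_track.tsv"),
                            params = params[c("window_length", "step")]))
      hotspots <- find_hotspots(track, threshold = config$threshold)
      emit(write_report_tsv(hotspots,
                            file.path(config$out_dir, "hotspots.tsv"),
                            params = params["threshold"]))
    } else {
      note("no genome pair configured: comparison and diversity stages skipped")
    }

    summary_rows <- list()
    if (length(config$markers) > 0 && !is.null(config$species)) {
      species <- resolve_species(config$species)
      names(config$markers) <- names(config$markers) %||%
        vapply(config$markers, function(p)
          if (is.character(p)) sub("\\.[^.]*$", "", basename(p)) else "marker",
          "")
      stats_rows <- list()
      for (nm in names(config$markers)) {
        aln <- resolve_marker(config$markers[[nm]], nm)
        stats_rows[[nm]] <- marker_stats(aln)
        dmat <- k2p_matrix(aln)
        emit(write_report_tsv(
          as_tibble(dmat, rownames = "sample_id"),
          file.path(config$out_dir, sprintf("distances_%s.tsv", nm))))
        disc <- near_neighbour(dmat, species, tie_rule = config$tie_rule)
        emit(write_report_tsv(
          tidy(disc),
          file.path(config$out_dir, sprintf("discrimination_%s.tsv", nm)),
          params = params["tie_rule"]))
        mb <- shortest_minibarcode(aln, species, start = config$start,
                                   increment = config$increment,
                                   window_step = config$window_step,
                                   tie_rule = config$tie_rule)
        emit(write_report_tsv(
          mb$curve,
          file.path(config$out_dir, sprintf("pm_curve_%s.tsv", nm))))
        emit(write_report_json(
          glance(mb),
          file.path(config$out_dir, sprintf("minibarcode_%s.json", nm)),
          params = params))
        summary_rows[[nm]] <- tibble(
          marker = nm,
          max_discrimination_pct = mb$full_length_pm,
          shortest_length = mb$shortest_length,
          window_start = mb$best_window_start
        )
      }
      emit(write_report_tsv(bind_rows(stats_rows),
                            file.path(config$out_dir, "marker_stats.tsv")))
      emit(write_report_tsv(bind_rows(summary_rows),
                            file.path(config$out_dir, "summary.tsv"),
                            params = params))
    } else {
      note("no markers + species map configured: discrimination stages skipped")
    }
  }, message = function(m) {
    note(trimws(conditionMessage(m)))
    invokeRestart("muffleMessage")
  }, warning = function(w) {
    note(trimws(conditionMessage(w)))
    invokeRestart("muffleWarning")
  })

  input_paths <- c(
    if (is.character(config$genome_pair)) config$genome_pair,
    if (is.character(config$features)) config$features,
    if (is.character(config$species)) config$species,
    unlist(Filter(is.character, config$markers))
  )
  manifest <- list(
    tool = "minibarcodes",
    version = as.character(utils::packageVersion("minibarcodes")),
    parameters = params,
    inputs = lapply(input_paths %||% character(0), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(unique(outputs), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    warnings = warnings
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
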