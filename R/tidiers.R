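#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the event table of a substitution scan
#'
#' @param x A `substitution_scan`.
#' @param ... Unused.
#' @return The event tibble (one row per substitution).
#' @export
tidy.substitution_scan <- function(x, ...) x$events

#' One-row summary of a substitution scan
#'
#' @param x A `substitution_scan`.
#' @param ... Unused.
#' @return A one-row tibble: totals, Ts/Tv ratio, and the 6-class spectrum in
#'   wide form.
#' @export
glance.substitution_scan <- function(x, ...) {
  s <- x$summary
  spec <- setNames(as.list(s$spectrum$n), paste0("n_", s$spectrum$collapsed_type))
  bind_cols(
    tibble(n_total = s$n_total, n_transition = s$n_transition,
           n_transversion = s$n_transversion, ts_tv = s$ts_tv),
    as_tibble(spec)
  )
}

#' Per-sample discrimination table
#'
#' @param x A `discrimination_result`.
#' @param ... Unused.
#' @return Tibble with one row per sample: species, nearest-neighbour
#'   distance, the nearest-neighbour set (comma-separated), and success.
#' @export
tidy.discrimination_result <- function(x, ...) {
  x$samples |>
    mutate(nn_set = vapply(.data$nn_set, paste, "", collapse = ","))
}

#' One-row summary of a discrimination result
#'
#' @param x A `discrimination_result`.
#' @param ... Unused.
#' @return Tibble with `pm`, sample and species success counts, and the tie
#'   rule used.
#' @export
glance.discrimination_result <- function(x, ...) {
  tibble(
    pm = x$pm,
    n_success = x$n_success,
    n_samples = x$n_samples,
    n_species_success = sum(x$by_species$success),
    n_species = nrow(x$by_species),
    tie_rule = x$tie_rule
  )
}

#' Length-by-length curve of a mini-barcode search
#'
#' @param x A `minibarcode_result`.
#' @param ... Unused.
#' @return Tibble with `length`, `max_pm`, `best_start` for every window
#'   length scanned.
#' @export
tidy.minibarcode_result <- function(x, ...) x$curve

#' One-row summary of a mini-barcode search
#'
#' @param x A `minibarcode_result`.
#' @param ... Unused.
#' @return Tibble with the marker, shortest length, best window position
#'   (1-based column), and the Pm at the shortest and full lengths.
#' @export
glance.minibarcode_result <- function(x, ...) {
  tibble(
    marker = x$marker_name,
    shortest_length = x$shortest_length,
    best_window_start = x$best_window_start,
    pm_at_shortest = x$pm_at_shortest,
    full_length_pm = x$full_length_pm
  )
}
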