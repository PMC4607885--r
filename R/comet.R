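#' 1-D comet intensity profile
#'
#' A single cell's DNA intensity integrated perpendicular to the
#' electrophoresis axis: strictly increasing positions (micrometers,
#' migration toward increasing position) with nonnegative intensities and
#' a scalar background level. If `background` is `NULL` it is estimated as
#' the minimum intensity over the leading 10% of positions.
#'
#' @param positions strictly increasing numeric vector (um).
#' @param intensity nonnegative intensities, same length.
#' @param background scalar background level, or `NULL` to estimate.
#' @return object of class `comet_profile`.
#' @export
comet_profile <- function(positions, intensity, background = NULL) {
  if (length(positions) != length(intensity)) stopf("input lengths differ")
  if (is.unsorted(positions, strictly = TRUE)) {
    stopf("'positions' must be strictly increasing")
  }
  if (any(intensity < 0)) stopf("'intensity' must be nonnegative")
  if (is.null(background)) {
    lead <- seq_len(max(1L, floor(0.1 * length(positions))))
    background <- min(intensity[lead])
  }
  if (all(intensity <= background)) {
    stopf("profile entirely at or below background")
  }
  structure(list(positions = positions, intensity = intensity,
                 background = background),
            class = "comet_profile")
}

#' @export
print.comet_profile <- function(x, ...) {
  cat(sprintf("comet_profile: %d positions [%g, %g] um, background %g\n",
              length(x$positions), min(x$positions), max(x$positions),
              x$background))
  invisible(x)
}

#' Segment a comet profile into head and tail
#'
#' The head is the contiguous above-background region around the global
#' intensity peak; the boundary is the first position past the head where
#' the intensity falls to or below background. Everything beyond the
#' boundary (migration side) is tail. Deterministic for a given profile.
#'
#' @param profile a [comet_profile()].
#' @return the boundary position (numeric scalar).
#' @export
segment_head_tail <- function(profile) {
  stopifnot(inherits(profile, "comet_profile"))
  above <- profile$intensity > profile$background
  peak <- which.max(profile$intensity)
  i <- peak
  while (i < length(above) && above[i + 1L]) i <- i + 1L
  if (i == length(above)) return(profile$positions[i])
  profile$positions[i + 1L]
}

#' Comet DNA-damage metrics
#'
#' Background-subtracted head/tail metrics for one cell:
#' `tail_dna_fraction` is the tail's share of total net intensity;
#' `tail_length` runs from the boundary to the last above-background tail
#' position; centroids are intensity-weighted position means;
#' `TM = tail_length * tail_dna_fraction` and
#' `OTM = |tail centroid - head centroid| * tail_dna_fraction` (both 0 for
#' an empty tail). `damaged` applies the classification rule
#' `tail_dna_fraction > threshold`.
#'
#' @param profile a [comet_profile()].
#' @param head_boundary boundary position; default from
#'   [segment_head_tail()].
#' @param threshold damage-classification threshold on
#'   `tail_dna_fraction`.
#' @return one-row data.frame: `head_boundary`, `head_centroid`,
#'   `tail_centroid`, `tail_length`, `tail_dna_fraction`, `TM`, `OTM`,
#'   `damaged`.
#' @export
comet_metrics <- function(profile, head_boundary = NULL, threshold = 0.05) {
  stopifnot(inherits(profile, "comet_profile"))
  if (is.null(head_boundary)) head_boundary <- segment_head_tail(profile)
  pos <- profile$positions
  net <- pmax(profile$intensity - profile$background, 0)
  in_tail <- pos >= head_boundary
  total <- sum(net)
  tail_mass <- sum(net[in_tail])
  tail_fraction <- tail_mass / total
  head_centroid <- sum(pos[!in_tail] * net[!in_tail]) / sum(net[!in_tail])
  if (tail_mass > 0) {
    tail_centroid <- sum(pos[in_tail] * net[in_tail]) / tail_mass
    last_tail <- max(pos[in_tail & net > 0])
    tail_length <- last_tail - head_boundary
    otm <- abs(tail_centroid - head_centroid) * tail_fraction
  } else {
    tail_centroid <- NA_real_
    tail_length <- 0
    otm <- 0
  }
  data.frame(head_boundary = head_boundary, head_centroid = head_centroid,
             tail_centroid = tail_centroid, tail_length = tail_length,
             tail_dna_fraction = tail_fraction,
             TM = tail_length * tail_fraction, OTM = otm,
             damaged = tail_fraction > threshold)
}

#' Metrics for a batch of comet profiles
#'
#' @param profiles list of [comet_profile()] objects.
#' @param threshold damage-classification threshold on
#'   `tail_dna_fraction`.
#' @return data.frame with one row per cell (see [comet_metrics()]).
#' @export
comet_metrics_batch <- function(profiles, threshold = 0.05) {
  out <- do.call(rbind, lapply(profiles, comet_metrics,
                               threshold = threshold))
  cbind(cell = seq_along(profiles), out)
}

#' DNA damage rate of a cell population
#'
#' Percentage of cells classified damaged (`tail_dna_fraction >
#' threshold`, or whatever rule produced the `damaged` column). Pair with
#' [chi_square_rate()] to compare conditions.
#'
#' @param metrics data.frame of per-cell metrics with a logical `damaged`
#'   column (e.g. from [comet_metrics_batch()]).
#' @return percentage in \[0, 100\].
#' @export
damage_rate <- function(metrics) {
  if (!NROW(metrics)) stopf("empty cell list")
  if (!"damaged" %in% names(metrics)) stopf("'metrics' lacks a 'damaged' column")
  100 * mean(metrics$damaged)
}
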