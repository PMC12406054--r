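#' Stimulus design for the bilinear model
#'
#' Holds the experimental input channels at their native event description.
#' Channel 1 is the driving input (every encoding trial); channels 2 and up
#' are modulators (the free-viewing trials). The driving channel is
#' mean-centered after discretization so that the endogenous matrix reads as
#' the average connectivity across conditions and the modulators as
#' deviations from that average on free-viewing trials.
#'
#' @param channels list of channels, each a list with elements `name`,
#'   `onsets` (s), `durations` (s) and `mean_center` (logical).
#' @param dt microtime integration step in seconds.
#' @param total_duration total duration of the (concatenated) design in s.
#' @param run_boundaries start times of each run in seconds (first must be 0).
#'   Neuronal and hemodynamic states are reset at each boundary.
#' @return An object of class `"stimulus_design"`.
#' @export
stimulus_design <- function(channels, dt = 0.125, total_duration,
                            run_boundaries = 0) {
  stopifnot(dt > 0, total_duration > 0)
  if (run_boundaries[1L] != 0) stop("first run boundary must be 0")
  if (is.unsorted(run_boundaries, strictly = TRUE) && length(run_boundaries) > 1L)
    stop("run boundaries must be strictly increasing")
  channels <- lapply(channels, function(ch) {
    if (length(ch$durations) == 1L)
      ch$durations <- rep(ch$durations, length(ch$onsets))
    ch
  })
  for (ch in channels) {
    stopifnot(is.character(ch$name), length(ch$onsets) == length(ch$durations))
    if (any(ch$onsets < 0)) stop("negative onset in channel ", ch$name)
    if (any(ch$onsets + ch$durations > total_duration + 1e-9))
      stop("event beyond total duration in channel ", ch$name)
  }
  structure(list(channels = channels, dt = dt,
                 total_duration = total_duration,
                 run_boundaries = run_boundaries),
            class = "stimulus_design")
}

#' Discretize a stimulus design to microtime input channels
#'
#' Each channel becomes a boxcar sampled on the microtime grid: bin `i`
#' covers `[(i-1) dt, i dt)` and is 1 when inside a trial. Channels flagged
#' `mean_center` have their temporal mean removed after discretization.
#' Overlapping events within a channel are merged with a warning.
#'
#' @param design a [stimulus_design()].
#' @return A bins x channels numeric matrix `U` with column names; the bin
#'   count is `ceiling(total_duration / dt)`.
#' @export
build_stimulus_inputs <- function(design) {
  stopifnot(inherits(design, "stimulus_design"))
  n_bins <- ceiling(design$total_duration / design$dt - 1e-9)
  U <- matrix(0, n_bins, length(design$channels))
  colnames(U) <- vapply(design$channels, `[[`, character(1L), "name")
  for (j in seq_along(design$channels)) {
    ch <- design$channels[[j]]
    col <- numeric(n_bins)
    for (i in seq_along(ch$onsets)) {
      a <- floor(ch$onsets[i] / design$dt + 1e-9) + 1L
      b <- floor((ch$onsets[i] + ch$durations[i]) / design$dt + 1e-9)
      if (b < a) next
      b <- min(b, n_bins)
      if (any(col[a:b] > 0))
        warning("overlapping events in channel '", ch$name, "' merged")
      col[a:b] <- 1
    }
    if (isTRUE(ch$mean_center)) col <- col - mean(col)
    U[, j] <- col
  }
  U
}

# microtime bin index (0-based, for the integrator) of each scan; scans run
# per acquisition run, restarting at each run boundary, row 1 = t = 0
scan_bins <- function(design, TR) {
  bounds <- c(design$run_boundaries, design$total_duration)
  times <- unlist(lapply(seq_len(length(bounds) - 1L), function(r) {
    len <- bounds[r + 1L] - bounds[r]
    bounds[r] + seq(0, by = TR, length.out = floor(len / TR + 1e-9))
  }))
  list(times = times,
       bins = as.integer(round(times / design$dt)),
       run = rep(seq_len(length(bounds) - 1L),
                 vapply(seq_len(length(bounds) - 1L), function(r)
                   floor((bounds[r + 1L] - bounds[r]) / TR + 1e-9), numeric(1L))))
}

#' Read or write a BIDS-style events table
#'
#' Events are stored as tab-separated text with columns `onset`, `duration`
#' and `trial_type` (plus any extra columns present).
#'
#' @param path file path of the events TSV.
#' @param events data frame with at least `onset`, `duration`, `trial_type`.
#' @return `read_events()` returns the events data frame.
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("events file misses required column(s): ", paste(miss, collapse = ", "))
  ev
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert an events table to DCM input channels
#'
#' Builds the two-channel design the connectivity model uses: a driving
#' channel containing every encoding trial (mean-centered) and a modulatory
#' channel containing the free-viewing trials only.
#'
#' @param events events data frame (`onset`, `duration`, `trial_type`).
#' @param total_duration,run_boundaries,dt passed to [stimulus_design()].
#' @param free_types `trial_type` values treated as free-viewing.
#' @return A [stimulus_design()].
#' @export
events_to_design <- function(events, total_duration, run_boundaries = 0,
                             dt = 0.125,
                             free_types = c("scene_free", "scrambled_free")) {
  free <- events$trial_type %in% free_types
  stimulus_design(
    channels = list(
      list(name = "encoding", onsets = events$onset,
           durations = events$duration, mean_center = TRUE),
      list(name = "free", onsets = events$onset[free],
           durations = events$duration[free], mean_center = FALSE)),
    dt = dt, total_duration = total_duration, run_boundaries = run_boundaries)
}
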