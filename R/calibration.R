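#' Detect size-standard peaks in a ladder trace
#'
#' Local maxima are ranked by topographic prominence; the `expected_n` most
#' prominent, re-sorted by position, are returned as 0-based position indices.
#' A minimum separation prevents one broad band from contributing twice. If
#' more maxima qualify than expected, the surplus is dropped and the
#' discrepancy reported via `message()`; if fewer are found, all are returned
#' and the count mismatch surfaces in [match_ladder()].
#'
#' @param ladder_trace numeric intensity vector of the ladder lane.
#' @param expected_n number of annotated ladder entries (>= 2).
#' @param min_prominence,min_separation peak-filter settings; defaults 5% of
#'   the dynamic range and 2% of the trace length.
#' @return integer vector of 0-based positions, ascending.
#' @export
detect_ladder_peaks <- function(ladder_trace, expected_n,
                                min_prominence = 0.05 * diff(range(ladder_trace)),
                                min_separation = max(1L, floor(0.02 * length(ladder_trace)))) {
  if (length(ladder_trace) < 8L)
    calibration_error("ladder trace too short (%d positions)", length(ladder_trace))
  if (expected_n < 2L)
    calibration_error("need at least 2 expected ladder peaks, got %d", expected_n)
  if (diff(range(ladder_trace)) == 0)
    calibration_error("ladder trace is flat: no peaks to calibrate on")
  pk <- find_peaks(ladder_trace, min_prominence, min_separation)
  if (nrow(pk) < 2L)
    calibration_error("fewer than 2 ladder peaks detected (%d); check ladder lane and image quality",
                      nrow(pk))
  if (nrow(pk) > expected_n) {
    message(sprintf("ladder: detected %d candidate peaks, keeping the %d most prominent",
                    nrow(pk), expected_n))
    pk <- pk[order(pk$prominence, decreasing = TRUE)[seq_len(expected_n)], ]
    pk <- pk[order(pk$index), ]
  }
  as.integer(pk$index) - 1L
}

#' Match detected ladder peaks to annotated sizes
#'
#' Peaks are paired 1:1 with annotation entries in order along the migration
#' axis; marker flags carry over and the migration direction is inferred from
#' the annotation order. A count mismatch is a hard calibration error stating
#' both counts: the remedy is an updated annotation file, not a silent guess.
#'
#' @param peak_positions sorted 0-based peak positions from
#'   [detect_ladder_peaks()].
#' @param ladder a [size_ladder()].
#' @return object of class `ladder_fit`: list with `knot_positions`,
#'   `knot_sizes_bp`, `marker_mask`, `direction`.
#' @export
match_ladder <- function(peak_positions, ladder) {
  stopifnot(inherits(ladder, "size_ladder"))
  if (is.unsorted(peak_positions, strictly = TRUE))
    calibration_error("peak positions must be strictly increasing")
  n_ann <- nrow(ladder)
  if (length(peak_positions) != n_ann)
    calibration_error(paste0(
      "ladder peak count mismatch: detected %d, annotated %d. ",
      "Please supply an updated annotation file matching the detected peaks."),
      length(peak_positions), n_ann)
  direction <- if (ladder$size_bp[n_ann] > ladder$size_bp[1])
    "size_increases_with_position" else "size_decreases_with_position"
  structure(list(knot_positions = as.numeric(peak_positions),
                 knot_sizes_bp = ladder$size_bp,
                 marker_mask = ladder$is_marker,
                 direction = direction),
            class = "ladder_fit")
}

#' Interpolate a base-pair coordinate for every position
#'
#' Piecewise-linear interpolation of `log10(size_bp)` against position between
#' consecutive ladder knots (electrophoretic mobility is approximately linear
#' in log fragment size); exact at every knot. Positions outside the knot
#' range are extrapolated with the nearest segment's slope and flagged. A
#' linear-in-bp mode is available for instruments with linear migration.
#'
#' @param fit a `ladder_fit` from [match_ladder()].
#' @param n_positions total number of positions (0-based 0..n-1); must cover
#'   the last knot.
#' @param scale `"log10"` (default) or `"linear"`.
#' @return numeric vector of sizes in bp, strictly monotone, with a logical
#'   attribute `"extrapolated"` marking positions outside the knot range.
#' @export
interpolate_sizes <- function(fit, n_positions, scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  kp <- fit$knot_positions
  if (length(kp) < 2L) calibration_error("need >= 2 ladder knots to interpolate")
  if (n_positions < max(kp) + 1L)
    calibration_error("n_positions (%d) does not cover last knot at %d",
                      n_positions, max(kp))
  ks <- if (scale == "log10") log10(fit$knot_sizes_bp) else fit$knot_sizes_bp
  pos <- seq.int(0L, n_positions - 1L)
  y <- stats::approx(kp, ks, xout = pos, rule = 2)$y
  # rule = 2 clamps outside the knots; extend with the end segments' slopes
  lo <- pos < kp[1]
  hi <- pos > kp[length(kp)]
  if (any(lo)) {
    s <- (ks[2] - ks[1]) / (kp[2] - kp[1])
    y[lo] <- ks[1] + s * (pos[lo] - kp[1])
  }
  if (any(hi)) {
    m <- length(kp)
    s <- (ks[m] - ks[m - 1]) / (kp[m] - kp[m - 1])
    y[hi] <- ks[m] + s * (pos[hi] - kp[m])
  }
  out <- if (scale == "log10") 10^y else y
  d <- diff(out)
  if (!(all(d > 0) || all(d < 0)))
    calibration_error("interpolated sizes are not strictly monotone")
  attr(out, "extrapolated") <- lo | hi
  out
}

#' Construct a calibrated per-sample profile
#'
#' @param sample lane name.
#' @param size_bp strictly monotone bp per position (attribute
#'   `"extrapolated"` respected when present).
#' @param intensity intensity per position.
#' @param calibrated_range numeric length-2, outermost non-extrapolated bp.
#' @param marker_windows data.frame with `low_bp`, `high_bp` exclusion
#'   windows (possibly 0 rows).
#' @param normalized,corrected bookkeeping flags.
#' @return object of class `calibrated_profile`.
#' @export
calibrated_profile <- function(sample, size_bp, intensity, calibrated_range,
                               marker_windows = data.frame(low_bp = numeric(),
                                                           high_bp = numeric()),
                               normalized = FALSE, corrected = FALSE) {
  if (length(size_bp) != length(intensity))
    validation_error("profile '%s': size and intensity lengths differ", sample)
  extrap <- attr(size_bp, "extrapolated") %||% rep(FALSE, length(size_bp))
  structure(list(sample = sample,
                 size_bp = as.numeric(size_bp),
                 intensity = as.numeric(intensity),
                 extrapolated = extrap,
                 calibrated_range = as.numeric(calibrated_range),
                 marker_windows = marker_windows,
                 normalized = normalized,
                 corrected = corrected),
            class = "calibrated_profile")
}

#' @export
print.calibrated_profile <- function(x, ...) {
  cat(sprintf("<calibrated_profile> '%s': %d positions, %.0f-%.0f bp%s%s\n",
              x$sample, length(x$size_bp),
              min(x$calibrated_range), max(x$calibrated_range),
              if (x$normalized) ", normalized" else "",
              if (x$corrected) ", background-corrected" else ""))
  invisible(x)
}

#' Positions usable for quantification
#'
#' TRUE where a position lies inside the calibrated (non-extrapolated) range
#' and outside every marker exclusion window.
#'
#' @param profile a [calibrated_profile()].
#' @return logical vector along positions.
#' @export
analysis_mask <- function(profile) {
  m <- !profile$extrapolated
  if (nrow(profile$marker_windows)) {
    for (k in seq_len(nrow(profile$marker_windows))) {
      m <- m & !(profile$size_bp >= profile$marker_windows$low_bp[k] &
                   profile$size_bp <= profile$marker_windows$high_bp[k])
    }
  }
  m
}

min_max_normalize <- function(x, mask) {
  v <- x[mask]
  if (length(v) == 0L || diff(range(v)) == 0) {
    warning("constant-intensity trace: normalized profile is all zeros",
            call. = FALSE)
    return(rep(0, length(x)))
  }
  pmin(pmax((x - min(v)) / (max(v) - min(v)), 0), 1)
}

#' Calibrate a signal table against its size standard
#'
#' Detects the ladder peaks in the designated ladder lane, matches them to the
#' annotation, interpolates a bp coordinate for every position, and returns
#' one calibrated profile per remaining (sample) lane. Marker entries define
#' exclusion windows of +/- `marker_window_frac` around their bp value; these
#' windows and extrapolated positions are excluded from normalization (and,
#' downstream, from quantification) unless `include_markers` is set.
#' Per-sample min-max normalization maps each sample's intensities to [0,1]
#' using only values inside the analysis range, making profiles comparable
#' across lanes and gels independent of loaded DNA concentration; it can be
#' switched off to pass raw intensities through.
#'
#' @param table a [signal_table()].
#' @param ladder a [size_ladder()].
#' @param normalize apply per-sample min-max scaling (default TRUE).
#' @param include_markers keep marker windows in the analysis range.
#' @param ladder_lane lane name or index; default the ladder's own
#'   `ladder_lane` attribute (first lane).
#' @param scale interpolation scale, see [interpolate_sizes()].
#' @param marker_window_frac half-width of marker exclusion windows as a
#'   fraction of the marker size (default 0.10).
#' @param min_prominence,min_separation passed to [detect_ladder_peaks()];
#'   `NULL` for trace-derived defaults.
#' @return list of [calibrated_profile()], one per sample lane (ladder lane
#'   excluded), in lane order.
#' @export
calibrate <- function(table, ladder, normalize = TRUE, include_markers = FALSE,
                      ladder_lane = NULL, scale = c("log10", "linear"),
                      marker_window_frac = 0.10,
                      min_prominence = NULL, min_separation = NULL) {
  stopifnot(inherits(table, "signal_table"), inherits(ladder, "size_ladder"))
  scale <- match.arg(scale)
  lane <- ladder_lane %||% attr(ladder, "ladder_lane") %||% 1L
  li <- if (is.character(lane)) match(lane, table$lane_names) else as.integer(lane)
  if (is.na(li) || li < 1L || li > length(table$lane_names))
    validation_error("ladder lane '%s' not present in signal table", as.character(lane))
  if (length(table$lane_names) < 2L)
    validation_error("signal table holds only the ladder lane: no samples to calibrate")

  trace <- table$intensities[, li]
  args <- list(ladder_trace = trace, expected_n = nrow(ladder))
  if (!is.null(min_prominence)) args$min_prominence <- min_prominence
  if (!is.null(min_separation)) args$min_separation <- min_separation
  peaks <- do.call(detect_ladder_peaks, args)
  fit <- match_ladder(peaks, ladder)
  size_bp <- interpolate_sizes(fit, length(table$positions), scale = scale)
  calibrated_range <- range(fit$knot_sizes_bp)

  mk <- ladder$size_bp[ladder$is_marker]
  marker_windows <- if (include_markers || length(mk) == 0L) {
    data.frame(low_bp = numeric(), high_bp = numeric())
  } else {
    data.frame(low_bp = (1 - marker_window_frac) * mk,
               high_bp = (1 + marker_window_frac) * mk)
  }

  lapply(setdiff(seq_along(table$lane_names), li), function(j) {
    p <- calibrated_profile(sample = table$lane_names[j],
                            size_bp = size_bp,
                            intensity = table$intensities[, j],
                            calibrated_range = calibrated_range,
                            marker_windows = marker_windows,
                            normalized = normalize)
    if (normalize) p$intensity <- min_max_normalize(p$intensity, analysis_mask(p))
    p
  })
}
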