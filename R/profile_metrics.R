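#' Sample-wide background correction
#'
#' Subtracts a single baseline per sample — the minimum intensity observed
#' inside the marker-excluded calibrated range — from the whole trace and
#' clips negatives to zero. A single sample-wide (rather than per-region)
#' baseline matches the behaviour of automated electrophoresis devices, whose
#' outputs are free of lane-specific contrast gradients.
#'
#' @param profile a [calibrated_profile()].
#' @return the corrected profile (`corrected = TRUE`). A constant trace maps
#'   to all zeros.
#' @export
background_correct <- function(profile) {
  stopifnot(inherits(profile, "calibrated_profile"))
  m <- analysis_mask(profile)
  base <- if (any(m)) min(profile$intensity[m]) else min(profile$intensity)
  profile$intensity <- pmax(profile$intensity - base, 0)
  profile$corrected <- TRUE
  profile
}

nucleosome_label <- function(k) {
  greek <- c("mono", "di", "tri", "tetra", "penta", "hexa", "hepta", "octa")
  if (k <= length(greek)) paste0(greek[k], "nucleosomal") else
    sprintf("%d-nucleosomal", k)
}

#' Default nucleosomal size bins
#'
#' Inclusive integer bp ranges, excluding fragments below `min_bp`: the first
#' (mononucleosomal) bin spans `min_bp` to `2 * min_bp` — 100-200 bp with the
#' default floor, the canonical single-nucleosome window — and every
#' subsequent bin has width `step_bp`: 201-400 (dinucleosomal), 401-600,
#' 601-800 and so forth up to `max_bp`. The 200 bp step reflects the
#' periodicity of nucleosome-protected cfDNA.
#'
#' @param step_bp width of the bins after the first (default 200).
#' @param min_bp lower bound of the first bin (default 100).
#' @param max_bp upper bound of the last bin.
#' @return data.frame with columns `label`, `low_bp`, `high_bp`.
#' @export
default_bins <- function(step_bp = 200L, min_bp = 100L, max_bp = 800L) {
  if (step_bp <= 0) validation_error("step_bp must be positive")
  if (min_bp < 0) validation_error("min_bp must be >= 0")
  if (max_bp <= min_bp) validation_error("max_bp (%s) must exceed min_bp (%s)",
                                         max_bp, min_bp)
  lows <- min_bp
  first_high <- if (min_bp > 0) 2 * min_bp else step_bp
  highs <- min(first_high, max_bp)
  while (highs[length(highs)] < max_bp) {
    lows <- c(lows, highs[length(highs)] + 1L)
    highs <- c(highs, min(highs[length(highs)] + step_bp, max_bp))
  }
  data.frame(label = vapply(seq_along(lows), nucleosome_label, character(1)),
             low_bp = as.numeric(lows), high_bp = as.numeric(highs))
}

#' Custom bins from "low-high" strings
#'
#' @param spec character vector like `c("50-700", "100-200")`; labels are the
#'   range strings. Custom bins may extend below the default 100 bp floor.
#' @return bin data.frame as in [default_bins()].
#' @export
parse_bins <- function(spec) {
  parts <- strsplit(spec, "-", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) validation_error("cannot parse bin '%s' (expect low-high)", spec[bad][1])
  low <- as_num(vapply(parts, `[`, "", 1))
  high <- as_num(vapply(parts, `[`, "", 2))
  if (anyNA(low) || anyNA(high) || any(high <= low))
    validation_error("invalid bin bounds in '%s'", paste(spec, collapse = ","))
  data.frame(label = spec, low_bp = low, high_bp = high)
}

# trapezoidal weight of each position: half the bp distance to each neighbour,
# so that sums approximate integrals over bp and are stable under resampling
bp_weights <- function(size_bp) {
  n <- length(size_bp)
  if (n == 1L) return(1)
  d <- abs(diff(size_bp))
  c(d[1] / 2, (d[-1] + d[-(n - 1)]) / 2, d[n - 1] / 2)
}

# integrated signal per position over the analysis range (zero elsewhere)
integrated_signal <- function(profile) {
  w <- profile$intensity * bp_weights(profile$size_bp)
  w[!analysis_mask(profile)] <- 0
  w
}

# per-position bp cells: each position owns the interval between the
# midpoints to its neighbours, end cells mirrored outward by half a spacing.
# Returns a 2-column matrix (lower, upper) for positions sorted ascending.
bp_cells <- function(bp) {
  n <- length(bp)
  if (n == 1L) return(cbind(bp - 0.5, bp + 0.5))
  mid <- (bp[-1] + bp[-n]) / 2
  cbind(c(bp[1] - (bp[2] - bp[1]) / 2, mid),
        c(mid, bp[n] + (bp[n] - bp[n - 1]) / 2))
}

#' Nucleosomal fractions of a profile
#'
#' For each bin, the fraction of total signal whose size falls inside the
#' bin's inclusive integer range: a position with size `s` belongs to
#' `(low, high)` iff `low <= round(s) <= high`. On the continuum, each
#' position owns the bp cell between the midpoints to its neighbours, and a
#' bin collects the intensity-weighted overlap of every cell with
#' `[low - 0.5, high + 0.5]`. This cell-overlap integration makes fractions
#' invariant to how densely the trace is sampled (and reduces to the plain
#' grid sum on a unit-spaced grid). The denominator is the union of all
#' bins; marker windows and extrapolated positions are excluded.
#'
#' @param profile a background-corrected [calibrated_profile()].
#' @param bins data.frame from [default_bins()] or [parse_bins()]; bins must
#'   not overlap.
#' @return data.frame of class `fraction_table` with columns `label`,
#'   `low_bp`, `high_bp`, `fraction`; attribute `total_signal`.
#' @export
nucleosomal_fractions <- function(profile, bins = default_bins()) {
  stopifnot(inherits(profile, "calibrated_profile"))
  if (nrow(bins) > 1L) {
    ob <- order(bins$low_bp)
    if (any(bins$low_bp[ob][-1] <= bins$high_bp[ob][-nrow(bins)]))
      validation_error("bins overlap")
  }
  o <- order(profile$size_bp)
  bp <- profile$size_bp[o]
  x <- profile$intensity[o]
  x[!analysis_mask(profile)[o]] <- 0
  cells <- bp_cells(bp)
  mass <- vapply(seq_len(nrow(bins)), function(k) {
    ov <- pmax(0, pmin(cells[, 2], bins$high_bp[k] + 0.5) -
                 pmax(cells[, 1], bins$low_bp[k] - 0.5))
    sum(x * ov)
  }, numeric(1))
  total <- sum(mass)
  if (total <= 0)
    validation_error("empty profile: no signal inside the requested bins")
  bins$fraction <- mass / total
  structure(bins, total_signal = total,
            class = c("fraction_table", "data.frame"))
}

# Gaussian smoothing along positions, kernel renormalized at the edges
smooth_trace <- function(x, sd_pos) {
  if (sd_pos <= 0) return(x)
  h <- max(1L, ceiling(3 * sd_pos))
  k <- stats::dnorm(-h:h, sd = sd_pos)
  n <- length(x)
  num <- stats::filter(c(rep(0, h), x, rep(0, h)), k, sides = 2)[(h + 1):(h + n)]
  den <- stats::filter(c(rep(0, h), rep(1, n), rep(0, h)), k, sides = 2)[(h + 1):(h + n)]
  as.numeric(num / den)
}

# quadratic-vertex refinement of a peak apex: fit a parabola to the points
# around the grid maximum and take its vertex, averaging out sampling noise
# and sub-grid quantization. Returns a fractional index within the window.
refine_peak_index <- function(x, idx, halfw = 3L) {
  win <- max(1L, idx - halfw):min(length(x), idx + halfw)
  if (length(win) < 3L) return(as.numeric(idx))
  fit <- stats::lm.fit(cbind(1, win, win^2), x[win])
  a <- fit$coefficients[3]
  if (!is.finite(a) || a >= 0) return(as.numeric(idx))
  v <- -fit$coefficients[2] / (2 * a)
  min(max(v, win[1]), win[length(win)])
}

#' Detect and number sample peaks
#'
#' Local maxima of the corrected trace inside the analysis range, using the
#' same prominence / separation defaults as ladder detection, ordered along
#' the size axis and numbered from 0. Each apex is refined to sub-grid
#' precision by a quadratic vertex fit around the maximum before being
#' size-annotated. A light Gaussian smoothing (default sigma 1% of the trace
#' length) is applied before detection so that instrument noise riding on
#' broad bands does not split one band into several numbered peaks; set
#' `smooth_sd = 0` to detect on the raw trace. An empty peak set is a valid
#' result (e.g. a featureless lane).
#'
#' @param profile a background-corrected [calibrated_profile()].
#' @param min_prominence,min_separation peak-filter settings; defaults 5% of
#'   the masked trace's dynamic range, 2% of the trace length.
#' @param smooth_sd Gaussian smoothing sigma in positions applied before
#'   detection; default 1% of the trace length.
#' @return data.frame of class `peak_set` with columns `index` (0-based),
#'   `size_bp`, `height`, `prominence`, ordered by ascending bp.
#' @export
detect_sample_peaks <- function(profile, min_prominence = NULL,
                                min_separation = NULL, smooth_sd = NULL) {
  stopifnot(inherits(profile, "calibrated_profile"))
  m <- analysis_mask(profile)
  x <- smooth_trace(profile$intensity,
                    smooth_sd %||% 0.01 * length(profile$intensity))
  rng <- if (any(m)) diff(range(x[m])) else 0
  pk <- find_peaks(x,
                   min_prominence = min_prominence %||% (0.05 * rng),
                   min_separation = min_separation %||% max(1L, floor(0.02 * length(x))))
  pk <- pk[m[pk$index], , drop = FALSE]
  out <- data.frame(index = integer(0), size_bp = numeric(0),
                    height = numeric(0), prominence = numeric(0))
  if (nrow(pk)) {
    ref <- vapply(pk$index, function(i) refine_peak_index(x, i), numeric(1))
    bp <- stats::approx(seq_along(profile$size_bp), profile$size_bp,
                        xout = ref)$y
    o <- order(bp)
    out <- data.frame(index = seq_along(o) - 1L,
                      size_bp = bp[o],
                      height = pk$height[o],
                      prominence = pk$prominence[o])
  }
  structure(out, class = c("peak_set", "data.frame"))
}

#' Flag potential genomic-DNA contamination
#'
#' High-molecular-weight signal in a cfDNA preparation usually indicates
#' genomic DNA from lysed cells. The fraction of total (bp-weighted) signal
#' above `size_threshold_bp` is reported, and the sample is flagged when it
#' reaches `fraction_threshold`. Both thresholds are defaults of this
#' implementation and should be tuned to the assay.
#'
#' @param profile a background-corrected [calibrated_profile()].
#' @param size_threshold_bp sizes strictly above this count as gDNA
#'   (default 1000).
#' @param fraction_threshold flag when the gDNA fraction reaches this value
#'   (default 0.2).
#' @return list with `gdna_flag` (logical) and `gdna_fraction` (in [0,1]).
#' @export
flag_gdna <- function(profile, size_threshold_bp = 1000,
                      fraction_threshold = 0.2) {
  stopifnot(inherits(profile, "calibrated_profile"))
  w <- integrated_signal(profile)
  total <- sum(w)
  if (total <= 0) validation_error("empty profile: zero total signal")
  frac <- sum(w[profile$size_bp > size_threshold_bp]) / total
  list(gdna_flag = frac >= fraction_threshold, gdna_fraction = frac)
}

#' Per-sample fragment-size summary metrics
#'
#' Treats the corrected trace as an unnormalized density over fragment size:
#' modal size is the bp at the trace maximum; mean and median are
#' intensity-weighted; entropy is Shannon entropy of the normalized trace (in
#' nats by default); skewness is the weighted third standardized moment; the
#' short-to-long ratio divides summed signal in `short_window` by that in
#' `long_window` (the common liquid-biopsy convention 100-150 / 151-220 bp).
#' The gDNA flag of [flag_gdna()] is included.
#'
#' @param profile a background-corrected [calibrated_profile()] with positive
#'   total signal.
#' @param short_window,long_window inclusive bp windows for the ratio.
#' @param entropy_base `"nats"` (natural log, default) or `"bits"`.
#' @param gdna_size_bp,gdna_frac thresholds passed to [flag_gdna()].
#' @return one-row data.frame with columns `sample`, `modal_bp`, `mean_bp`,
#'   `median_bp`, `entropy`, `skewness`, `short_long_ratio` (NA when the long
#'   window carries no signal), `gdna_flag`, `gdna_fraction`.
#' @export
summary_metrics <- function(profile, short_window = c(100, 150),
                            long_window = c(151, 220),
                            entropy_base = c("nats", "bits"),
                            gdna_size_bp = 1000, gdna_frac = 0.2) {
  stopifnot(inherits(profile, "calibrated_profile"))
  entropy_base <- match.arg(entropy_base)
  m <- analysis_mask(profile)
  w <- profile$intensity
  w[!m] <- 0
  total <- sum(w)
  if (total <= 0) validation_error("empty profile: zero total signal")
  bp <- profile$size_bp
  p <- w / total
  modal <- bp[which.max(w)]
  mean_bp <- sum(bp * p)
  o <- order(bp)
  cum <- cumsum(w[o])
  median_bp <- bp[o][which(cum >= 0.5 * total)[1]]
  pp <- p[p > 0]
  entropy <- -sum(pp * log(pp))
  if (entropy_base == "bits") entropy <- entropy / log(2)
  v <- sum(p * (bp - mean_bp)^2)
  skew <- if (v > 0) sum(p * (bp - mean_bp)^3) / v^1.5 else 0
  short_sum <- sum(w[bp >= short_window[1] & bp <= short_window[2]])
  long_sum <- sum(w[bp >= long_window[1] & bp <= long_window[2]])
  ratio <- if (long_sum > 0) short_sum / long_sum else NA_real_
  g <- flag_gdna(profile, gdna_size_bp, gdna_frac)
  data.frame(sample = profile$sample,
             modal_bp = modal, mean_bp = mean_bp, median_bp = median_bp,
             entropy = entropy, skewness = skew, short_long_ratio = ratio,
             gdna_flag = g$gdna_flag, gdna_fraction = g$gdna_fraction)
}
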