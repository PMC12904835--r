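#' Default synthetic ladder fixture
#'
#' 25(marker), 50, 100, 200, 400, 700, 1000, 1500(marker) bp — shaped like the
#' size standards commonly used for cfDNA screening assays, with lower and
#' upper alignment markers flagged.
#'
#' @return a [size_ladder()].
#' @export
default_ladder <- function() {
  size_ladder(c(25, 50, 100, 200, 400, 700, 1000, 1500),
              is_marker = c(TRUE, rep(FALSE, 6), TRUE))
}

# migration model: position linear in log10(bp) (default) or in bp.
# The log model matches the calibration default so knot recovery is exact by
# construction; the linear mode exists to probe calibration robustness under
# model mismatch.
bp_axis <- function(n_positions, span_bp, model = c("log10", "linear")) {
  model <- match.arg(model)
  t <- seq(0, 1, length.out = n_positions)
  if (model == "log10") {
    10^(log10(span_bp[1]) + t * (log10(span_bp[2]) - log10(span_bp[1])))
  } else {
    span_bp[1] + t * (span_bp[2] - span_bp[1])
  }
}

bp_to_position <- function(bp, n_positions, span_bp, model = c("log10", "linear")) {
  model <- match.arg(model)
  t <- if (model == "log10") {
    (log10(bp) - log10(span_bp[1])) / (log10(span_bp[2]) - log10(span_bp[1]))
  } else {
    (bp - span_bp[1]) / (span_bp[2] - span_bp[1])
  }
  t * (n_positions - 1)
}

#' Specification of one synthetic electropherogram trace
#'
#' @param peaks data.frame with columns `center_bp`, `sd_bp`,
#'   `relative_amplitude` (> 0): a Gaussian mixture over fragment size.
#' @param baseline constant background level (>= 0).
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0).
#' @return object of class `trace_spec`.
#' @export
trace_spec <- function(peaks, baseline = 0, noise_sd = 0) {
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("center_bp", "sd_bp", "relative_amplitude") %in% names(peaks)))
  if (any(peaks$relative_amplitude <= 0))
    validation_error("trace spec: amplitudes must be > 0")
  if (baseline < 0 || noise_sd < 0)
    validation_error("trace spec: baseline and noise_sd must be >= 0")
  structure(list(peaks = peaks, baseline = baseline, noise_sd = noise_sd),
            class = "trace_spec")
}

mixture_density <- function(bp, peaks) {
  out <- numeric(length(bp))
  for (k in seq_len(nrow(peaks))) {
    out <- out + peaks$relative_amplitude[k] *
      exp(-(bp - peaks$center_bp[k])^2 / (2 * peaks$sd_bp[k]^2))
  }
  out
}

# brute-force bin fractions of a noiseless mixture on a fine bp grid —
# the oracle every fraction computation is tested against
brute_force_fractions <- function(peaks, bins, span_bp, step = 0.25) {
  grid <- seq(span_bp[1], span_bp[2], by = step)
  dens <- mixture_density(grid, peaks)
  s <- round(grid)
  memb <- vapply(seq_len(nrow(bins)),
                 function(k) s >= bins$low_bp[k] & s <= bins$high_bp[k],
                 logical(length(grid)))
  memb <- matrix(memb, ncol = nrow(bins))
  total <- sum(dens[rowSums(memb) > 0])
  vapply(seq_len(nrow(bins)), function(k) sum(dens[memb[, k]]) / total,
         numeric(1))
}

#' Simulate a multi-lane electropherogram with known ground truth
#'
#' Lane 1 carries the ladder: narrow Gaussian bands at each annotated size,
#' placed via the migration model (position linear in log10 bp by default).
#' Each subsequent lane realizes one [trace_spec()]: a Gaussian mixture over
#' fragment size evaluated at the positions' bp values, plus a constant
#' baseline and seeded Gaussian noise (clamped at zero). The returned ground
#' truth records the true peak sizes and the true nucleosomal-bin fractions
#' of each noiseless mixture, computed by brute-force integration — the
#' oracle for downstream recovery tests.
#'
#' @param specs list of [trace_spec()], one per sample lane.
#' @param ladder a [size_ladder()] shared by all lanes.
#' @param n_positions number of sampling positions (>= 50; default 300).
#' @param seed integer seed for the noise.
#' @param model migration model, `"log10"` (default) or `"linear"`.
#' @param bins bin table used for the ground-truth fractions.
#' @return list with `table` (a [signal_table()], lane 1 = `"ladder"`,
#'   samples `"sample_1"`, ...) and `truth` (per-sample list of `peaks_bp`,
#'   `fractions`, plus `bins` and `model`).
#' @export
simulate_electropherogram <- function(specs, ladder = default_ladder(),
                                      n_positions = 300L, seed = 1L,
                                      model = c("log10", "linear"),
                                      bins = default_bins()) {
  model <- match.arg(model)
  if (n_positions < 50L)
    validation_error("n_positions must be >= 50, got %d", n_positions)
  if (inherits(specs, "trace_spec")) specs <- list(specs)
  span <- range(ladder$size_bp)
  for (sp in specs) {
    if (any(sp$peaks$center_bp < span[1] | sp$peaks$center_bp > span[2]))
      validation_error("peak center outside ladder span [%g, %g] bp",
                       span[1], span[2])
  }
  set.seed(seed)
  # sample a little beyond the outermost ladder bands, as devices do; the
  # ladder peaks must be interior maxima and the overhang exercises the
  # extrapolation flagging downstream
  sim_span <- if (model == "log10") {
    L <- log10(span[2]) - log10(span[1])
    10^(c(log10(span[1]) - 0.04 * L, log10(span[2]) + 0.04 * L))
  } else {
    L <- span[2] - span[1]
    c(max(span[1] - 0.04 * L, 1), span[2] + 0.04 * L)
  }
  bp <- bp_axis(n_positions, sim_span, model)

  ladder_sd <- max(1.2, n_positions / 200)
  pos <- seq_len(n_positions) - 1
  ladder_trace <- numeric(n_positions)
  for (s in ladder$size_bp) {
    c0 <- bp_to_position(s, n_positions, sim_span, model)
    ladder_trace <- ladder_trace + exp(-(pos - c0)^2 / (2 * ladder_sd^2))
  }

  lanes <- matrix(0, n_positions, 1 + length(specs))
  lanes[, 1] <- ladder_trace
  truth <- list()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    tr <- mixture_density(bp, sp$peaks) + sp$baseline
    if (sp$noise_sd > 0) tr <- tr + stats::rnorm(n_positions, 0, sp$noise_sd)
    lanes[, k + 1] <- pmax(tr, 0)
    truth[[paste0("sample_", k)]] <- list(
      peaks_bp = sp$peaks$center_bp,
      fractions = brute_force_fractions(sp$peaks, bins, span))
  }
  list(table = signal_table(positions = pos, intensities = lanes,
                            lane_names = c("ladder", paste0("sample_", seq_along(specs))),
                            source = "device_table"),
       truth = c(truth, list(bins = bins, model = model, span_bp = span)))
}

#' Render a signal table as a synthetic gel image
#'
#' Paints each lane as a vertical strip whose row brightness follows its
#' intensity column (scaled by the table's global maximum), separated by dark
#' gaps, and writes a PNG. Ground-truth lane centers are returned so lane
#' detection can be verified exactly.
#'
#' @param table a [signal_table()] with >= 16 positions.
#' @param lane_width_px strip width in px (>= 2; default 12).
#' @param gap_px gap between strips (default 8).
#' @param polarity `"bands_bright"` (default) or `"bands_dark"` (inverted
#'   grey levels, as in a stained agarose photo).
#' @param path output PNG path (default a tempfile).
#' @return list with `path`, `centers` (1-based ground-truth center columns),
#'   `width`, `height`.
#' @export
render_gel_image <- function(table, lane_width_px = 12L, gap_px = 8L,
                             polarity = c("bands_bright", "bands_dark"),
                             path = tempfile(fileext = ".png")) {
  stopifnot(inherits(table, "signal_table"))
  polarity <- match.arg(polarity)
  if (lane_width_px < 2L)
    validation_error("lane_width_px must be >= 2, got %d", lane_width_px)
  if (gap_px < 1L) validation_error("gap_px must be >= 1")
  h <- length(table$positions)
  if (h < 16L) validation_error("table too short to render (%d rows)", h)
  nl <- length(table$lane_names)
  w <- gap_px + nl * (lane_width_px + gap_px)
  img <- matrix(0, nrow = h, ncol = w)
  scale <- max(table$intensities)
  if (scale <= 0) scale <- 1
  centers <- integer(nl)
  for (k in seq_len(nl)) {
    left <- gap_px + (k - 1L) * (lane_width_px + gap_px) + 1L
    right <- left + lane_width_px - 1L
    centers[k] <- as.integer(floor((left + right) / 2))
    img[, left:right] <- 0.9 * table$intensities[, k] / scale
  }
  if (polarity == "bands_dark") img <- 1 - img
  png::writePNG(img, path)
  list(path = path, centers = centers, width = w, height = h)
}

#' Simulate a two-group cohort with a known fraction shift
#'
#' Generates `2 * n_per_group` sample lanes plus a ladder lane. Every sample
#' is a mononucleosomal (167 bp) + dinucleosomal (334 bp) Gaussian mixture;
#' the mono share of total area is `base_mono + effect` in the disease group
#' versus `base_mono` in the healthy group, with a small per-sample
#' biological jitter and additive trace noise. Used by the type-I-error and
#' power simulations.
#'
#' @param n_per_group samples per group (>= 2).
#' @param effect shift in the mono area share between groups (0 = null).
#' @param seed integer seed.
#' @param noise_sd trace noise standard deviation (default 0.05).
#' @param base_mono mono area share in the reference group (default 0.4).
#' @param jitter_sd per-sample biological jitter of the mono share
#'   (default 0.02).
#' @param n_positions positions per trace (default 250).
#' @return list with `table` (a [signal_table()]), `metadata` (a
#'   `metadata_table` with a `disease` column), and `truth` (per-sample mono
#'   shares and group labels).
#' @export
make_cohort <- function(n_per_group = 6L, effect = 0.25, seed = 1L,
                        noise_sd = 0.05, base_mono = 0.4, jitter_sd = 0.02,
                        n_positions = 250L) {
  if (n_per_group < 2L)
    validation_error("n_per_group must be >= 2, got %d", n_per_group)
  set.seed(seed)
  n <- 2L * n_per_group
  groups <- rep(c("healthy", "disease"), each = n_per_group)
  w <- base_mono + ifelse(groups == "disease", effect, 0) +
    stats::rnorm(n, 0, jitter_sd)
  w <- pmin(pmax(w, 0.02), 0.98)
  sd_m <- 20; sd_d <- 40
  specs <- lapply(w, function(wi) {
    # amplitudes chosen so Gaussian areas are in ratio wi : (1 - wi)
    trace_spec(data.frame(center_bp = c(167, 334), sd_bp = c(sd_m, sd_d),
                          relative_amplitude = c(wi, (1 - wi) * sd_m / sd_d)),
               baseline = 0, noise_sd = noise_sd)
  })
  sim <- simulate_electropherogram(specs, n_positions = n_positions,
                                   seed = seed + 10000L)
  metadata <- data.frame(sample = paste0("sample_", seq_len(n)),
                         disease = groups, stringsAsFactors = FALSE)
  class(metadata) <- c("metadata_table", "data.frame")
  list(table = sim$table, metadata = metadata,
       truth = list(mono_share = w, group = groups,
                    effect = effect, sim = sim$truth))
}
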