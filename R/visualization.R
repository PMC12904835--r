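#' @importFrom rlang .data
NULL

#' Plot specification
#'
#' @param kind `"density"`, `"group_density"`, `"heatmap"` or
#'   `"fraction_bars"`.
#' @param bp_range optional c(low, high) crop in bp.
#' @param group_variable optional metadata column for grouping/averaging.
#' @param crop_markers drop marker exclusion windows from the plotted data
#'   (default TRUE).
#' @param output_format `"png"` (default), `"pdf"` or `"svg"`.
#' @param dpi raster resolution (>= 72; default 300).
#' @param log_bp log-scaled bp axis (default TRUE, the electrophoresis
#'   convention).
#' @return object of class `plot_spec`.
#' @export
plot_spec <- function(kind = c("density", "group_density", "heatmap", "fraction_bars"),
                      bp_range = NULL, group_variable = NULL,
                      crop_markers = TRUE,
                      output_format = c("png", "pdf", "svg"),
                      dpi = 300L, log_bp = TRUE) {
  kind <- match.arg(kind)
  output_format <- match.arg(output_format)
  if (!is.null(bp_range)) {
    if (length(bp_range) != 2L || bp_range[1] >= bp_range[2])
      validation_error("bp_range must be c(low, high) with low < high")
  }
  if (dpi < 72) validation_error("dpi must be >= 72, got %d", dpi)
  structure(list(kind = kind, bp_range = bp_range,
                 group_variable = group_variable,
                 crop_markers = crop_markers,
                 output_format = output_format, dpi = as.integer(dpi),
                 log_bp = log_bp),
            class = "plot_spec")
}

profile_long <- function(p, crop_markers = TRUE, bp_range = NULL) {
  keep <- if (crop_markers) analysis_mask(p) else !p$extrapolated
  if (!is.null(bp_range))
    keep <- keep & p$size_bp >= bp_range[1] & p$size_bp <= bp_range[2]
  data.frame(sample = p$sample, size_bp = p$size_bp[keep],
             intensity = p$intensity[keep])
}

#' Common integer bp grid across profiles
#'
#' 1 bp spacing over the intersection of the profiles' calibrated ranges, so
#' resampled traces never rely on extrapolated sizes.
#' @param profiles list of [calibrated_profile()].
#' @return numeric vector of bp values.
#' @export
common_bp_grid <- function(profiles) {
  lo <- max(vapply(profiles, function(p) min(p$calibrated_range), numeric(1)))
  hi <- min(vapply(profiles, function(p) max(p$calibrated_range), numeric(1)))
  if (hi <= lo) validation_error("profiles share no calibrated bp range")
  seq(ceiling(lo), floor(hi), by = 1)
}

resample_profile <- function(p, grid) {
  o <- order(p$size_bp)
  stats::approx(p$size_bp[o], p$intensity[o], xout = grid, rule = 2)$y
}

#' Prepare per-sample or group-averaged trace data for plotting
#'
#' Pure data step, independent of rendering: crops markers and bp range, and
#' when a group variable is given resamples every profile onto the common
#' 1 bp grid and averages within groups (mean with per-position standard
#' deviation).
#'
#' @param profiles list of [calibrated_profile()].
#' @param spec a [plot_spec()].
#' @param metadata `metadata_table`, required when `spec$group_variable` is
#'   set.
#' @return data.frame: per-sample (`sample`, `size_bp`, `intensity`) or
#'   per-group (`group`, `size_bp`, `mean_intensity`, `sd_intensity`).
#' @export
prepare_profile_data <- function(profiles, spec = plot_spec(), metadata = NULL) {
  if (length(profiles) == 0L) validation_error("no profiles to plot")
  if (is.null(spec$group_variable)) {
    return(do.call(rbind, lapply(profiles, profile_long,
                                 crop_markers = spec$crop_markers,
                                 bp_range = spec$bp_range)))
  }
  if (is.null(metadata) ||
      !spec$group_variable %in% setdiff(names(metadata), "sample"))
    validation_error("unknown group variable '%s'", spec$group_variable %||% "")
  grid <- common_bp_grid(profiles)
  if (!is.null(spec$bp_range))
    grid <- grid[grid >= spec$bp_range[1] & grid <= spec$bp_range[2]]
  if (spec$crop_markers) {
    mw <- profiles[[1]]$marker_windows
    for (k in seq_len(nrow(mw)))
      grid <- grid[!(grid >= mw$low_bp[k] & grid <= mw$high_bp[k])]
  }
  samples <- vapply(profiles, `[[`, "", "sample")
  g <- metadata[[spec$group_variable]][match(samples, metadata$sample)]
  keep <- !is.na(g)
  if (!any(keep)) validation_error("no profile matched the metadata")
  mat <- vapply(profiles[keep], resample_profile, numeric(length(grid)),
                grid = grid)
  mat <- matrix(mat, nrow = length(grid))
  out <- do.call(rbind, lapply(unique(g[keep]), function(lev) {
    cols <- which(g[keep] == lev)
    mm <- mat[, cols, drop = FALSE]
    sdv <- if (ncol(mm) > 1L) apply(mm, 1, stats::sd) else numeric(length(grid))
    data.frame(group = lev, size_bp = grid,
               mean_intensity = rowMeans(mm),
               sd_intensity = sdv)
  }))
  out
}

#' Prepare the sample-by-size heatmap matrix
#'
#' Resamples every profile onto the common 1 bp grid; rows are samples,
#' ordered by metadata group when available, columns the bp grid.
#'
#' @param profiles list of >= 2 [calibrated_profile()].
#' @param spec a [plot_spec()].
#' @param metadata optional `metadata_table` for group-ordered rows.
#' @return list with `matrix` (samples x bp), `grid`, `groups` (per-row
#'   labels or NA).
#' @export
prepare_heatmap_data <- function(profiles, spec = plot_spec("heatmap"),
                                 metadata = NULL) {
  if (length(profiles) < 2L)
    validation_error("heatmap needs >= 2 profiles; use a density plot for a single sample")
  grid <- common_bp_grid(profiles)
  if (!is.null(spec$bp_range))
    grid <- grid[grid >= spec$bp_range[1] & grid <= spec$bp_range[2]]
  if (spec$crop_markers) {
    mw <- profiles[[1]]$marker_windows
    for (k in seq_len(nrow(mw)))
      grid <- grid[!(grid >= mw$low_bp[k] & grid <= mw$high_bp[k])]
  }
  m <- t(vapply(profiles, resample_profile, numeric(length(grid)), grid = grid))
  rownames(m) <- vapply(profiles, `[[`, "", "sample")
  groups <- rep(NA_character_, nrow(m))
  if (!is.null(metadata) && !is.null(spec$group_variable) &&
      spec$group_variable %in% names(metadata)) {
    groups <- as.character(metadata[[spec$group_variable]][
      match(rownames(m), metadata$sample)])
    o <- order(groups, rownames(m), na.last = TRUE)
    m <- m[o, , drop = FALSE]
    groups <- groups[o]
  }
  list(matrix = m, grid = grid, groups = groups)
}

save_plot <- function(gp, path, spec, width = 7, height = 4.5) {
  dev <- switch(spec$output_format, png = "png", pdf = "pdf", svg = "svg")
  ggplot2::ggsave(path, gp, device = dev, dpi = spec$dpi,
                  width = width, height = height)
  path
}

#' Plot fragment-size density traces
#'
#' One trace per sample, or a mean trace with a +/- 1 sd band per group when
#' `spec$group_variable` is set. The bp axis is log-scaled by default.
#'
#' @param profiles list of [calibrated_profile()].
#' @param spec a [plot_spec()].
#' @param metadata optional `metadata_table`.
#' @param path output file; default derived from `prefix`.
#' @param prefix file-name prefix when `path` is NULL.
#' @return the written file path, invisibly.
#' @export
plot_profiles <- function(profiles, spec = plot_spec(), metadata = NULL,
                          path = NULL, prefix = "fragtrace") {
  dat <- prepare_profile_data(profiles, spec, metadata)
  path <- path %||% paste0(prefix, "_", spec$kind, ".", spec$output_format)
  if (is.null(spec$group_variable)) {
    gp <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$size_bp,
                                            y = .data$intensity,
                                            colour = .data$sample)) +
      ggplot2::geom_line(linewidth = 0.5) +
      ggplot2::labs(x = "fragment size (bp)", y = "normalized intensity",
                    colour = "sample")
  } else {
    gp <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$size_bp,
                                            y = .data$mean_intensity,
                                            colour = .data$group,
                                            fill = .data$group)) +
      ggplot2::geom_ribbon(ggplot2::aes(
        ymin = pmax(.data$mean_intensity - .data$sd_intensity, 0),
        ymax = .data$mean_intensity + .data$sd_intensity),
        alpha = 0.25, colour = NA) +
      ggplot2::geom_line(linewidth = 0.6) +
      ggplot2::labs(x = "fragment size (bp)", y = "normalized intensity",
                    colour = spec$group_variable, fill = spec$group_variable)
  }
  if (spec$log_bp) gp <- gp + ggplot2::scale_x_log10()
  gp <- gp + ggplot2::theme_minimal()
  invisible(save_plot(gp, path, spec))
}

#' Plot a sample-by-size intensity heatmap
#'
#' @inheritParams plot_profiles
#' @return the written file path, invisibly.
#' @export
plot_heatmap <- function(profiles, spec = plot_spec("heatmap"), metadata = NULL,
                         path = NULL, prefix = "fragtrace") {
  hd <- prepare_heatmap_data(profiles, spec, metadata)
  path <- path %||% paste0(prefix, "_heatmap.", spec$output_format)
  df <- expand.grid(sample = rownames(hd$matrix), size_bp = hd$grid,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$intensity <- as.vector(hd$matrix)
  df$sample <- factor(df$sample, levels = rev(rownames(hd$matrix)))
  gp <- ggplot2::ggplot(df, ggplot2::aes(x = .data$size_bp, y = .data$sample,
                                         fill = .data$intensity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::labs(x = "fragment size (bp)", y = NULL) +
    ggplot2::theme_minimal()
  if (spec$log_bp) gp <- gp + ggplot2::scale_x_log10()
  invisible(save_plot(gp, path, spec,
                      height = max(3, 0.25 * nrow(hd$matrix) + 1.5)))
}
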