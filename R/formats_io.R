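#' Construct a signal table
#'
#' A signal table is the common currency of the pipeline: one row per gel
#' position (or device sampling point), one column per lane, values being
#' non-negative fluorescence / grey intensities.
#'
#' @param positions integer-like vector of ordered position indices.
#' @param intensities numeric matrix, rows matching `positions`, one column
#'   per lane; finite and non-negative.
#' @param lane_names unique character labels, one per column.
#' @param source `"device_table"` or `"image"`.
#' @return object of class `signal_table` with fields `positions`,
#'   `intensities`, `lane_names`, `source`.
#' @export
signal_table <- function(positions, intensities, lane_names,
                         source = c("device_table", "image")) {
  source <- match.arg(source)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(intensities) != length(positions))
    validation_error("signal table: %d positions but %d intensity rows",
                     length(positions), nrow(intensities))
  if (ncol(intensities) != length(lane_names))
    validation_error("signal table: %d lane names but %d intensity columns",
                     length(lane_names), ncol(intensities))
  if (anyDuplicated(lane_names))
    validation_error("signal table: duplicated lane name '%s'",
                     lane_names[duplicated(lane_names)][1])
  if (!all(is.finite(intensities)))
    validation_error("signal table: non-finite intensity values")
  if (any(intensities < 0))
    validation_error("signal table: negative intensity values")
  colnames(intensities) <- lane_names
  structure(list(positions = as.integer(positions),
                 intensities = intensities,
                 lane_names = as.character(lane_names),
                 source = source),
            class = "signal_table")
}

#' @export
print.signal_table <- function(x, ...) {
  cat(sprintf("<signal_table> %d positions x %d lanes (%s)\n",
              length(x$positions), length(x$lane_names), x$source))
  cat("  lanes:", paste(x$lane_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.signal_table <- function(x, ...) {
  data.frame(position = x$positions, x$intensities, check.names = FALSE)
}

#' Construct a size ladder
#'
#' Ordered annotation of the size standard: fragment sizes in bp, in the order
#' they appear along the migration axis, with optional marker flags. Marker
#' peaks are alignment spikes excluded from biological quantification.
#'
#' @param sizes_bp positive sizes in bp, strictly monotone (ascending or
#'   descending, matching the migration direction of the ladder lane).
#' @param is_marker logical flags, recycled to length of `sizes_bp`.
#' @param ladder_lane lane index or name holding the ladder (default first).
#' @return object of class `size_ladder`: data.frame with columns `size_bp`,
#'   `is_marker`; attribute `ladder_lane`.
#' @export
size_ladder <- function(sizes_bp, is_marker = FALSE, ladder_lane = 1L) {
  sizes_bp <- as.numeric(sizes_bp)
  is_marker <- rep_len(as.logical(is_marker), length(sizes_bp))
  if (length(sizes_bp) == 0L)
    validation_error("size ladder: no entries")
  if (any(!is.finite(sizes_bp)) || any(sizes_bp <= 0))
    validation_error("size ladder: sizes must be positive and finite")
  d <- diff(sizes_bp)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    validation_error("size ladder: sizes must be strictly monotone (got %s)",
                     paste(sizes_bp, collapse = ", "))
  if (sum(!is_marker) < 2L)
    validation_error("size ladder: need >= 2 non-marker sizes for calibration, got %d",
                     sum(!is_marker))
  structure(data.frame(size_bp = sizes_bp, is_marker = is_marker),
            ladder_lane = ladder_lane,
            class = c("size_ladder", "data.frame"))
}

# ---------------------------------------------------------------------------
# delimited-text plumbing: delimiter sniffing, decimal-comma normalization,
# device-export preambles. Device CSV dialects vary regionally, so the reader
# detects rather than assumes.

sniff_delim <- function(line) {
  counts <- c("," = lengths(regmatches(line, gregexpr(",", line, fixed = TRUE))),
              ";" = lengths(regmatches(line, gregexpr(";", line, fixed = TRUE))),
              "\t" = lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE))))
  if (all(counts == 0)) return(NA_character_)
  names(counts)[which.max(counts)]
}

split_fields <- function(line, delim) {
  f <- trimws(strsplit(line, delim, fixed = TRUE)[[1]])
  # strip surrounding double quotes (write.csv-style quoting)
  sub('^"(.*)"$', "\\1", f)
}

# decimal commas only make sense when the field separator is not a comma
normalize_decimal <- function(fields, delim) {
  if (delim == ",") return(fields)
  sub(",", ".", fields, fixed = TRUE)
}

as_num <- function(fields) suppressWarnings(as.numeric(fields))

#' Read an electropherogram signal table from delimited text
#'
#' First column is interpreted as the position index; remaining columns are
#' lanes named by the header row. Comma, semicolon and tab delimiters are
#' detected per file; decimal commas are normalized. The `device_export`
#' dialect additionally tolerates metadata preamble lines before the header,
#' as written by automated electrophoresis instruments.
#'
#' @param path file path.
#' @param dialect `"generic"` (header is the first line) or `"device_export"`
#'   (skip preamble until a header followed by numeric rows).
#' @return a [signal_table()] with `source = "device_table"`.
#' @export
read_signal_table <- function(path, dialect = c("generic", "device_export")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) io_error("signal table file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) format_error("%s: file is empty", path)

  header_i <- 1L
  if (dialect == "device_export") {
    header_i <- NA_integer_
    for (i in seq_len(length(lines) - 1L)) {
      d <- sniff_delim(lines[i])
      if (is.na(d)) next
      nf <- length(split_fields(lines[i], d))
      if (nf < 2L) next
      nxt <- split_fields(lines[i + 1L], d)
      if (length(nxt) == nf &&
          !anyNA(as_num(normalize_decimal(nxt, d)))) {
        header_i <- i
        break
      }
    }
    if (is.na(header_i))
      format_error("%s: no header followed by numeric rows found", path)
  }

  delim <- sniff_delim(lines[header_i])
  if (is.na(delim))
    format_error("%s: line %d: could not detect a delimiter; single-column files are not a signal table",
                 path, header_i)
  header <- split_fields(lines[header_i], delim)
  if (length(header) < 2L)
    format_error("%s: line %d: need a position column plus at least one lane",
                 path, header_i)
  body <- lines[-seq_len(header_i)]
  if (length(body) == 0L)
    format_error("%s: header only, no data rows", path)

  nfield <- length(header)
  vals <- matrix(NA_real_, nrow = length(body), ncol = nfield)
  for (r in seq_along(body)) {
    f <- split_fields(body[r], delim)
    if (length(f) != nfield)
      format_error("%s: row %d has %d fields, expected %d",
                   path, header_i + r, length(f), nfield)
    num <- as_num(normalize_decimal(f, delim))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1]
      format_error("%s: row %d, column '%s': non-numeric value '%s'",
                   path, header_i + r, header[bad], f[bad])
    }
    vals[r, ] <- num
  }
  signal_table(positions = vals[, 1],
               intensities = vals[, -1, drop = FALSE],
               lane_names = header[-1],
               source = "device_table")
}

#' Read a size-standard annotation file
#'
#' Plain text, one ladder entry per line: a fragment size in bp optionally
#' followed by a marker token (`marker`, `M` or `*`, case-insensitive). Lines
#' starting with `#` and blank lines are ignored. Sizes must be strictly
#' monotone in file order, which also encodes the migration direction.
#'
#' @param path file path.
#' @param ladder_lane lane index or name carrying the ladder (default first).
#' @return a [size_ladder()].
#' @export
read_ladder_annotation <- function(path, ladder_lane = 1L) {
  if (!file.exists(path)) io_error("ladder annotation file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    validation_error("%s: annotation file has no entries", path)
  sizes <- numeric(length(idx))
  marker <- logical(length(idx))
  for (k in seq_along(idx)) {
    toks <- strsplit(trimws(lines[idx[k]]), "[,;[:space:]]+")[[1]]
    sz <- as_num(sub(",", ".", toks[1], fixed = TRUE))
    if (is.na(sz))
      format_error("%s: line %d: cannot parse size '%s'", path, idx[k], toks[1])
    sizes[k] <- sz
    marker[k] <- length(toks) > 1L &&
      any(tolower(toks[-1]) %in% c("marker", "m", "*"))
  }
  size_ladder(sizes, marker, ladder_lane = ladder_lane)
}

#' Read a sample metadata table
#'
#' Delimited text with a `sample` column (case-insensitive) keying into the
#' signal table's lane names; every other column becomes a grouping variable.
#' Samples listed here but absent from a signal table are tolerated (they are
#' flagged at stratification time), so one metadata file can serve many gels.
#'
#' @param path file path (CSV/TSV/semicolon-delimited).
#' @return a data.frame of class `metadata_table` whose first column is
#'   `sample`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) io_error("metadata file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) format_error("%s: metadata needs a header and rows", path)
  delim <- sniff_delim(lines[1])
  if (is.na(delim)) format_error("%s: could not detect a delimiter", path)
  header <- split_fields(lines[1], delim)
  si <- which(tolower(header) == "sample")
  if (length(si) == 0L)
    format_error("%s: no 'sample' column (found: %s)", path,
                 paste(header, collapse = ", "))
  si <- si[1]
  rows <- lapply(seq_along(lines)[-1], function(r) {
    f <- split_fields(lines[r], delim)
    if (length(f) != length(header))
      format_error("%s: row %d has %d fields, expected %d",
                   path, r, length(f), length(header))
    f
  })
  m <- do.call(rbind, rows)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- header
  if (anyDuplicated(names(df)))
    validation_error("%s: duplicated grouping column name '%s'", path,
                     names(df)[duplicated(names(df))][1])
  if (anyDuplicated(df[[si]]))
    validation_error("%s: duplicated sample key '%s'", path,
                     df[[si]][duplicated(df[[si]])][1])
  names(df)[si] <- "sample"
  # numeric-looking grouping columns become numeric
  for (j in setdiff(seq_along(df), si)) {
    num <- as_num(df[[j]])
    if (!anyNA(num)) df[[j]] <- num
  }
  df <- df[, c(si, setdiff(seq_along(df), si)), drop = FALSE]
  class(df) <- c("metadata_table", "data.frame")
  df
}

#' Write the full result bundle as CSV files
#'
#' Persists every tabular artifact of a run under `outdir` with deterministic
#' names: raw and normalized intensity matrices, the bp-annotated long
#' profile table, per-sample metrics, nucleosomal fractions, the peak table,
#' and (when present) the group-statistics table.
#'
#' @param results list with any of the fields `raw_table` (signal_table),
#'   `profiles` (list of calibrated profiles), `metrics`, `fractions`,
#'   `peaks` (data.frames), `stats` (data.frame).
#' @param outdir output directory, created if needed.
#' @return named character vector of written paths (the manifest), invisibly.
#' @export
write_outputs <- function(results, outdir) {
  fields <- c("raw_table", "profiles", "metrics", "fractions", "peaks", "stats")
  present <- Filter(function(f) !is.null(results[[f]]), fields)
  if (length(present) == 0L)
    validation_error("write_outputs: empty results bundle, nothing to write")
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(outdir, 2) != 0L)
    io_error("output directory not writable: %s", outdir)

  manifest <- character(0)
  put <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    manifest[[sub("\\.csv$", "", name)]] <<- p
  }
  if (!is.null(results$raw_table))
    put(as.data.frame(results$raw_table), "raw_intensities.csv")
  if (!is.null(results$profiles) && length(results$profiles)) {
    prof <- results$profiles
    wide <- data.frame(position = seq_along(prof[[1]]$size_bp) - 1L,
                       size_bp = prof[[1]]$size_bp)
    for (p in prof) wide[[p$sample]] <- p$intensity
    put(wide, "normalized_intensities.csv")
    long <- do.call(rbind, lapply(prof, function(p) {
      data.frame(sample = p$sample,
                 position = seq_along(p$size_bp) - 1L,
                 size_bp = p$size_bp,
                 intensity = p$intensity,
                 in_analysis_range = analysis_mask(p))
    }))
    put(long, "profiles_bp.csv")
  }
  if (!is.null(results$metrics)) put(results$metrics, "sample_metrics.csv")
  if (!is.null(results$fractions)) put(results$fractions, "nucleosomal_fractions.csv")
  if (!is.null(results$peaks)) put(results$peaks, "peaks.csv")
  if (!is.null(results$stats) && NROW(results$stats) > 0)
    put(results$stats, "group_statistics.csv")
  invisible(manifest)
}
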