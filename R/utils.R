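#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and tests) can distinguish failure modes.
ft_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "fragtrace_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

io_error          <- function(msg, ...) ft_stop("fragtrace_io_error", msg, ...)
format_error      <- function(msg, ...) ft_stop("fragtrace_format_error", msg, ...)
validation_error  <- function(msg, ...) ft_stop("fragtrace_validation_error", msg, ...)
calibration_error <- function(msg, ...) ft_stop("fragtrace_calibration_error", msg, ...)
detection_error   <- function(msg, ...) ft_stop("fragtrace_detection_error", msg, ...)

#' Locate local maxima with topographic prominence
#'
#' Finds local maxima of a 1-D trace, computes each peak's topographic
#' prominence (height above the higher of the two saddle minima separating it
#' from higher terrain), and filters by a minimum prominence and a minimum
#' peak-to-peak separation. Plateaus contribute their central index.
#'
#' @param x numeric trace.
#' @param min_prominence minimum prominence to keep a peak; default 5% of the
#'   trace's dynamic range.
#' @param min_separation minimum index distance between kept peaks; default 2%
#'   of the trace length. When two candidates are closer, the more prominent
#'   one wins.
#' @return data.frame with columns `index` (1-based), `height`, `prominence`,
#'   ordered by index. Zero rows when no peak qualifies.
#' @export
find_peaks <- function(x,
                       min_prominence = 0.05 * diff(range(x, finite = TRUE)),
                       min_separation = max(1L, floor(0.02 * length(x)))) {
  n <- length(x)
  empty <- data.frame(index = integer(), height = numeric(), prominence = numeric())
  if (n < 3) return(empty)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) cand <- c(cand, as.integer(floor((i + j) / 2)))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(cand) == 0L) return(empty)
  prom <- vapply(cand, function(p) {
    h <- x[p]
    lmin <- h
    k <- p - 1L
    while (k >= 1L && x[k] <= h) {
      if (x[k] < lmin) lmin <- x[k]
      k <- k - 1L
    }
    rmin <- h
    k <- p + 1L
    while (k <= n && x[k] <= h) {
      if (x[k] < rmin) rmin <- x[k]
      k <- k + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) == 0L) return(empty)
  ord <- order(prom, decreasing = TRUE)
  kept <- integer(0)
  for (k in ord) {
    if (all(abs(cand[k] - cand[kept]) >= min_separation)) kept <- c(kept, k)
  }
  kept <- sort(cand[kept], index.return = TRUE)
  idx <- kept$x
  data.frame(index = idx,
             height = x[idx],
             prominence = prom[match(idx, cand)])
}

# %||% for defaults
`%||%` <- function(a, b) if (is.null(a)) b else a

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
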