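# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
# Handles ties naturally (ranks are fixed, assignments enumerated), which the
# large-sample machinery in stats::wilcox.test cannot do exactly.
mwu_exact <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  cmb <- utils::combn(m + n, m)
  Us <- colSums(matrix(r[cmb], nrow = m)) - m * (m + 1) / 2
  dev_obs <- abs(U - m * n / 2)
  p <- mean(abs(Us - m * n / 2) >= dev_obs - 1e-12)
  list(statistic = U, p_value = p)
}

#' Partition per-sample values by a metadata variable
#'
#' Joins a per-sample table to the metadata on `sample` and splits it by the
#' requested grouping variable. Samples missing from the metadata (or with an
#' empty value) are dropped with a warning — metadata may legitimately cover
#' more or fewer samples than one gel.
#'
#' @param metrics data.frame with a `sample` column.
#' @param metadata a [read_metadata()] table.
#' @param variable grouping column name.
#' @return named list of data.frames, one per group level.
#' @export
stratify <- function(metrics, metadata, variable) {
  if (!"sample" %in% names(metrics))
    validation_error("metrics table has no 'sample' column")
  if (!variable %in% setdiff(names(metadata), "sample"))
    validation_error("unknown grouping variable '%s' (available: %s)",
                     variable, paste(setdiff(names(metadata), "sample"), collapse = ", "))
  idx <- match(metrics$sample, metadata$sample)
  unmatched <- metrics$sample[is.na(idx)]
  if (length(unmatched))
    warning(sprintf("samples absent from metadata, excluded: %s",
                    paste(unmatched, collapse = ", ")), call. = FALSE)
  keep <- !is.na(idx)
  if (!any(keep))
    validation_error("no sample matched the metadata")
  g <- metadata[[variable]][idx[keep]]
  split(metrics[keep, , drop = FALSE], g)
}

#' Compare a metric between groups with rank-based tests
#'
#' Two groups are compared with a two-sided Mann-Whitney U test — exact by
#' full enumeration when the combined n is at most 20 (ties included),
#' normal approximation with tie correction otherwise. More than two groups
#' use the Kruskal-Wallis test. Fragment metrics from small clinical cohorts
#' are rarely Gaussian, hence the rank-based default; a Welch t-test is
#' available for two groups. Comparisons where any group has n < 3 are
#' computed but flagged `low_n`.
#'
#' @param groups named list of numeric value vectors, one per group.
#' @param metric identifier carried into the result.
#' @param test `"auto"` (MWU for 2 groups, Kruskal-Wallis otherwise),
#'   `"wilcoxon"`, `"kruskal"` or `"welch"`.
#' @return object of class `group_comparison`: list with `metric`, `groups`
#'   (data.frame label/n/mean/median), `statistic`, `p_value`, `test`,
#'   `low_n`.
#' @export
compare_groups <- function(groups, metric = "value",
                           test = c("auto", "wilcoxon", "kruskal", "welch")) {
  test <- match.arg(test)
  if (length(groups) < 2L)
    validation_error("need >= 2 groups, got %d", length(groups))
  sizes <- lengths(groups)
  if (any(sizes == 0L))
    validation_error("group '%s' has no values",
                     names(groups)[sizes == 0L][1] %||% "?")
  labs <- names(groups) %||% paste0("group_", seq_along(groups))
  summ <- data.frame(label = labs, n = as.integer(sizes),
                     mean = vapply(groups, mean, numeric(1)),
                     median = vapply(groups, stats::median, numeric(1)),
                     row.names = NULL)
  if (test == "auto") test <- if (length(groups) == 2L) "wilcoxon" else "kruskal"
  if (test %in% c("wilcoxon", "welch") && length(groups) != 2L)
    validation_error("%s test requires exactly 2 groups", test)
  if (test == "wilcoxon") {
    x <- groups[[1]]; y <- groups[[2]]
    if (length(x) + length(y) <= 20L) {
      res <- mwu_exact(x, y)
      stat <- res$statistic; p <- res$p_value
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    test_name <- "mann_whitney_u"
  } else if (test == "kruskal") {
    kt <- stats::kruskal.test(groups)
    stat <- unname(kt$statistic); p <- kt$p.value
    test_name <- "kruskal_wallis"
  } else {
    tt <- stats::t.test(groups[[1]], groups[[2]])
    stat <- unname(tt$statistic); p <- tt$p.value
    test_name <- "welch_t"
  }
  structure(list(metric = metric, groups = summ,
                 statistic = stat, p_value = p, test = test_name,
                 low_n = any(sizes < 3L)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s, statistic = %.4g, p = %.4g%s\n",
              x$metric, x$test, x$statistic, x$p_value,
              if (x$low_n) " [low n]" else ""))
  print(x$groups)
  invisible(x)
}

#' Compare the size of the nth peak between groups
#'
#' For each sample, the bp size of peak `n` (0-based, by order of occurrence
#' along the size axis) is extracted; samples lacking that peak are excluded
#' with a warning; the remaining values are stratified and compared with
#' [compare_groups()].
#'
#' @param peak_sets named list of `peak_set` tables, names = sample names.
#' @param metadata a [read_metadata()] table.
#' @param variable grouping column name.
#' @param n 0-based peak index.
#' @param test passed to [compare_groups()].
#' @return a `group_comparison` with metric `"peak<n>_bp"`.
#' @export
compare_peak_sizes <- function(peak_sets, metadata, variable, n = 0L,
                               test = "auto") {
  if (n < 0) validation_error("peak index must be >= 0")
  vals <- vapply(peak_sets, function(ps) {
    hit <- ps$size_bp[ps$index == n]
    if (length(hit)) hit[1] else NA_real_
  }, numeric(1))
  if (all(is.na(vals)))
    validation_error("no sample has a peak with index %d", n)
  if (anyNA(vals))
    warning(sprintf("samples lacking peak %d excluded: %s", n,
                    paste(names(vals)[is.na(vals)], collapse = ", ")),
            call. = FALSE)
  df <- data.frame(sample = names(vals)[!is.na(vals)],
                   value = vals[!is.na(vals)], row.names = NULL)
  groups <- stratify(df, metadata, variable)
  compare_groups(lapply(groups, `[[`, "value"),
                 metric = sprintf("peak%d_bp", n), test = test)
}

comparison_row <- function(cmp, variable) {
  g <- cmp$groups
  data.frame(variable = variable,
             metric = cmp$metric,
             groups = paste(g$label, collapse = "|"),
             n = paste(g$n, collapse = "|"),
             group_means = paste(signif(g$mean, 6), collapse = "|"),
             group_medians = paste(signif(g$median, 6), collapse = "|"),
             test = cmp$test,
             statistic = cmp$statistic,
             p_value = cmp$p_value,
             low_n_flag = cmp$low_n)
}

#' Run every group comparison for a result bundle
#'
#' For each grouping variable in the metadata, compares every summary metric
#' column, every nucleosomal fraction bin, and the sizes of the first `K`
#' sample peaks between groups. Raw p-values are primary; a Benjamini-
#' Hochberg adjusted column (per grouping variable) is always added for
#' transparency.
#'
#' @param metrics per-sample metrics data.frame (`sample` + numeric columns).
#' @param fractions long data.frame with columns `sample`, `label`,
#'   `fraction`.
#' @param peak_sets named list of `peak_set` tables.
#' @param metadata a [read_metadata()] table, or NULL for no comparisons.
#' @param K number of leading peaks to compare (default 3).
#' @param test passed to [compare_groups()].
#' @return data.frame, one row per comparison, with columns variable, metric,
#'   group labels/sizes/means/medians, test, statistic, p_value, p_adj,
#'   low_n_flag. Zero rows when `metadata` is NULL.
#' @export
run_all_comparisons <- function(metrics, fractions = NULL, peak_sets = NULL,
                                metadata = NULL, K = 3L, test = "auto") {
  empty <- data.frame(variable = character(), metric = character(),
                      groups = character(), n = character(),
                      group_means = character(), group_medians = character(),
                      test = character(), statistic = numeric(),
                      p_value = numeric(), p_adj = numeric(),
                      low_n_flag = logical())
  if (is.null(metadata)) return(empty)
  vars <- setdiff(names(metadata), "sample")
  if (length(vars) == 0L) return(empty)
  rows <- list()
  for (v in vars) {
    metric_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric, logical(1))],
                           "sample")
    for (mc in metric_cols) {
      df <- metrics[!is.na(metrics[[mc]]), c("sample", mc)]
      if (nrow(df) == 0L) next
      cmp <- tryCatch({
        g <- stratify(df, metadata, v)
        if (length(g) < 2L) NULL else
          compare_groups(lapply(g, `[[`, mc), metric = mc, test = test)
      }, fragtrace_validation_error = function(e) NULL)
      if (!is.null(cmp)) rows[[length(rows) + 1L]] <- comparison_row(cmp, v)
    }
    if (!is.null(fractions)) {
      for (lab in unique(fractions$label)) {
        df <- fractions[fractions$label == lab, c("sample", "fraction")]
        cmp <- tryCatch({
          g <- stratify(df, metadata, v)
          if (length(g) < 2L) NULL else
            compare_groups(lapply(g, `[[`, "fraction"),
                           metric = paste0("fraction_", lab), test = test)
        }, fragtrace_validation_error = function(e) NULL)
        if (!is.null(cmp)) rows[[length(rows) + 1L]] <- comparison_row(cmp, v)
      }
    }
    if (!is.null(peak_sets)) {
      for (pn in seq_len(K) - 1L) {
        cmp <- tryCatch(
          suppressWarnings(compare_peak_sizes(peak_sets, metadata, v, pn, test = test)),
          fragtrace_validation_error = function(e) NULL)
        if (!is.null(cmp)) rows[[length(rows) + 1L]] <- comparison_row(cmp, v)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (v in unique(out$variable)) {
    sel <- out$variable == v
    out$p_adj[sel] <- stats::p.adjust(out$p_value[sel], method = "BH")
  }
  out[, c("variable", "metric", "groups", "n", "group_means", "group_medians",
          "test", "statistic", "p_value", "p_adj", "low_n_flag")]
}
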