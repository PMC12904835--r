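test_that("identical groups give exact p = 1 with ties handled", {
  cmp <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_identical(cmp$test, "mann_whitney_u")
  expect_equal(cmp$p_value, 1)
})

test_that("complete separation at 4 vs 4 gives the enumerated p = 2/70", {
  cmp <- compare_groups(list(a = 1:4, b = 10:13))
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 2 / 70)
})

test_that("exact MWU matches wilcox.test enumeration for tie-free small samples", {
  set.seed(42)
  for (rep in 1:20) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    x <- round(stats::rnorm(m), 6); y <- round(stats::rnorm(n, 0.5), 6)
    ours <- compare_groups(list(x = x, y = y))$p_value
    ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("three groups use Kruskal-Wallis and match the rank-sum formula", {
  set.seed(7)
  g <- list(a = stats::rnorm(5), b = stats::rnorm(6, 1), c = stats::rnorm(4, 2))
  cmp <- compare_groups(g)
  expect_identical(cmp$test, "kruskal_wallis")
  # brute-force H for tie-free data
  vals <- unlist(g)
  r <- rank(vals)
  N <- length(vals)
  idx <- rep(seq_along(g), lengths(g))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  expect_equal(unname(cmp$statistic), H, tolerance = 1e-10)
  expect_equal(cmp$p_value, stats::pchisq(H, df = 2, lower.tail = FALSE))
})

test_that("test results are invariant to group-label and sample order", {
  set.seed(3)
  x <- stats::rnorm(8); y <- stats::rnorm(8, 1)
  p1 <- compare_groups(list(A = x, B = y))$p_value
  p2 <- compare_groups(list(B = y, A = x))$p_value
  p3 <- compare_groups(list(A = sample(x), B = sample(y)))$p_value
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("stratification partitions samples and flags the unmatched", {
  md <- data.frame(sample = paste0("s", 1:6),
                   disease = rep(c("healthy", "tumor"), 3),
                   stage = c("I", "I", "II", "II", "III", "III"))
  class(md) <- c("metadata_table", "data.frame")
  metrics <- data.frame(sample = paste0("s", 1:6), value = 1:6)
  g <- stratify(metrics, md, "disease")
  expect_named(g, c("healthy", "tumor"))
  expect_equal(lengths(lapply(g, `[[`, "value")), c(healthy = 3L, tumor = 3L))
  expect_length(stratify(metrics, md, "stage"), 3)
  extra <- rbind(metrics, data.frame(sample = "s99", value = 7))
  expect_warning(g2 <- stratify(extra, md, "disease"), "s99")
  expect_equal(sum(lengths(lapply(g2, `[[`, "value"))), 6)
  expect_error(stratify(metrics, md, "nope"),
               class = "fragtrace_validation_error")
  none <- data.frame(sample = "zz", value = 1)
  expect_error(suppressWarnings(stratify(none, md, "disease")),
               class = "fragtrace_validation_error")
})

test_that("nth-peak comparison extracts per-sample sizes and tests them", {
  mk_ps <- function(bps) {
    structure(data.frame(index = seq_along(bps) - 1L, size_bp = bps,
                         height = 1, prominence = 1),
              class = c("peak_set", "data.frame"))
  }
  md <- data.frame(sample = paste0("s", 1:10),
                   disease = rep(c("A", "B"), each = 5))
  class(md) <- c("metadata_table", "data.frame")
  # identical first peaks -> p = 1
  same <- setNames(lapply(1:10, function(i) mk_ps(c(167, 334))),
                   paste0("s", 1:10))
  expect_equal(compare_peak_sizes(same, md, "disease", 0)$p_value, 1)
  # clear shift ~150 vs ~170 bp -> significant
  set.seed(5)
  shifted <- setNames(lapply(1:10, function(i) {
    mk_ps(c(ifelse(i <= 5, 150, 170) + stats::rnorm(1, 0, 2), 334))
  }), paste0("s", 1:10))
  cmp <- compare_peak_sizes(shifted, md, "disease", 0)
  expect_lt(cmp$p_value, 0.05)
  expect_identical(cmp$metric, "peak0_bp")
  # requesting a peak nobody has is an error
  expect_error(compare_peak_sizes(same, md, "disease", 3),
               class = "fragtrace_validation_error")
})

test_that("the comparison battery covers variables x (metrics, bins, peaks)", {
  set.seed(11)
  n <- 8
  samples <- paste0("s", 1:n)
  md <- data.frame(sample = samples,
                   disease = rep(c("A", "B"), each = n / 2),
                   sex = rep(c("f", "m"), n / 2))
  class(md) <- c("metadata_table", "data.frame")
  metrics <- data.frame(sample = samples,
                        modal_bp = stats::rnorm(n, 167),
                        mean_bp = stats::rnorm(n, 210),
                        median_bp = stats::rnorm(n, 190),
                        entropy = stats::rnorm(n, 4),
                        skewness = stats::rnorm(n),
                        short_long_ratio = stats::runif(n))
  bins <- default_bins(max_bp = 800)
  fractions <- do.call(rbind, lapply(samples, function(s)
    data.frame(sample = s, label = bins$label,
               fraction = as.numeric(stats::runif(4)))))
  peak_sets <- setNames(lapply(1:n, function(i)
    structure(data.frame(index = 0:2,
                         size_bp = c(167, 334, 501) + stats::rnorm(3),
                         height = 1, prominence = 1),
              class = c("peak_set", "data.frame"))), samples)
  out <- run_all_comparisons(metrics, fractions, peak_sets, md, K = 3)
  expect_equal(nrow(out), 2 * (6 + 4 + 3))
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
  expect_true(all(out$p_adj >= out$p_value - 1e-12))
  # BH within each grouping variable
  for (v in c("disease", "sex")) {
    sel <- out$variable == v
    expect_equal(out$p_adj[sel],
                 stats::p.adjust(out$p_value[sel], method = "BH"))
  }
  # no metadata -> no comparisons, but a well-formed empty frame
  empty <- run_all_comparisons(metrics, fractions, peak_sets, NULL)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("variable", "metric", "p_value", "p_adj") %in% names(empty)))
})

test_that("groups with zero values are rejected and low-n is flagged", {
  expect_error(compare_groups(list(a = numeric(0), b = 1:3)),
               class = "fragtrace_validation_error")
  expect_error(compare_groups(list(a = 1:3)),
               class = "fragtrace_validation_error")
  cmp <- compare_groups(list(a = c(1, 2), b = c(5, 6, 7)))
  expect_true(cmp$low_n)
})
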