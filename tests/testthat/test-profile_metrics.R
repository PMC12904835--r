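test_that("background correction subtracts the sample-wide minimum", {
  p <- make_profile(c(100, 150, 200), c(0.2, 0.7, 0.2))
  expect_equal(background_correct(p)$intensity, c(0, 0.5, 0))
  # idempotent on a zero-baseline trace
  p0 <- background_correct(p)
  expect_equal(background_correct(p0)$intensity, p0$intensity)
})

test_that("fractions are invariant to a constant offset after correction", {
  bp <- seq(100, 800, by = 2)
  base <- exp(-(bp - 167)^2 / 800) + 0.5 * exp(-(bp - 334)^2 / 3200)
  f1 <- nucleosomal_fractions(background_correct(make_profile(bp, base)))
  f2 <- nucleosomal_fractions(background_correct(make_profile(bp, base + 0.17)))
  expect_equal(f1$fraction, f2$fraction, tolerance = 1e-9)
})

test_that("default bins follow the 200 bp nucleosomal convention", {
  b <- default_bins(max_bp = 800)
  expect_equal(b$low_bp, c(100, 201, 401, 601))
  expect_equal(b$high_bp, c(200, 400, 600, 800))
  expect_equal(b$label, c("mononucleosomal", "dinucleosomal",
                          "trinucleosomal", "tetranucleosomal"))
  b2 <- default_bins(step_bp = 100, min_bp = 100, max_bp = 300)
  expect_equal(b2$low_bp, c(100, 201))
  expect_equal(b2$high_bp, c(200, 300))
  expect_error(default_bins(max_bp = 100, min_bp = 100),
               class = "fragtrace_validation_error")
  expect_equal(parse_bins("50-700"),
               data.frame(label = "50-700", low_bp = 50, high_bp = 700))
})

test_that("all signal in one bin gives fraction one there, zero elsewhere", {
  bp <- seq(100, 800, by = 1)
  intens <- ifelse(bp == 150, 1, 0)
  fr <- nucleosomal_fractions(make_profile(bp, intens))
  expect_equal(fr$fraction, c(1, 0, 0, 0))
})

test_that("uniform profile fractions match the brute-force grid sum", {
  fr <- nucleosomal_fractions(make_profile(100:800, rep(1, 701)))
  expect_equal(fr$fraction[1], 101 / 701, tolerance = 1e-3)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-9)
})

test_that("tiling bins sum to one and fractions are resampling-stable", {
  bp1 <- seq(100, 800, by = 2)
  shape <- function(bp) exp(-(bp - 180)^2 / 5000) + 0.4 * exp(-(bp - 360)^2 / 9000)
  f1 <- nucleosomal_fractions(make_profile(bp1, shape(bp1)))
  expect_equal(sum(f1$fraction), 1, tolerance = 1e-9)
  bp2 <- seq(100, 800, by = 1)  # 2x resolution
  f2 <- nucleosomal_fractions(make_profile(bp2, shape(bp2)))
  expect_true(all(abs(f1$fraction - f2$fraction) < 1e-3))
})

test_that("fractions are invariant to positive intensity rescaling", {
  bp <- seq(100, 800, by = 1)
  x <- exp(-(bp - 167)^2 / 800)
  f1 <- nucleosomal_fractions(make_profile(bp, x))
  f2 <- nucleosomal_fractions(make_profile(bp, 7 * x))
  expect_equal(f1$fraction, f2$fraction, tolerance = 1e-12)
})

test_that("an empty profile is an error", {
  expect_error(nucleosomal_fractions(make_profile(100:200, rep(0, 101))),
               "empty", class = "fragtrace_validation_error")
  expect_error(flag_gdna(make_profile(100:200, rep(0, 101))),
               class = "fragtrace_validation_error")
})

test_that("sample peaks are recovered, ordered and 0-based", {
  res <- sim_profiles(list(mono_di_spec()))
  pk <- detect_sample_peaks(res$profiles[[1]])
  expect_equal(pk$index, c(0L, 1L))
  expect_lt(abs(pk$size_bp[1] - 167) / 167, 0.02)
  expect_lt(abs(pk$size_bp[2] - 334) / 334, 0.02)
  # flat profile: empty set is valid
  flat <- make_profile(100:300, rep(0, 201))
  expect_equal(nrow(detect_sample_peaks(flat)), 0)
  # single peak gets index 0
  one <- make_profile(seq(100, 800, 2),
                      exp(-(seq(100, 800, 2) - 300)^2 / 2000))
  expect_equal(detect_sample_peaks(one)$index, 0L)
})

test_that("gDNA flagging thresholds the high-molecular-weight fraction", {
  bp <- seq(100, 6000, by = 10)
  hi <- ifelse(abs(bp - 5000) < 30, 1, 0)
  g <- flag_gdna(make_profile(bp, hi))
  expect_true(g$gdna_flag)
  expect_equal(g$gdna_fraction, 1)
  lo <- ifelse(abs(bp - 170) < 30, 1, 0)
  g2 <- flag_gdna(make_profile(bp, lo))
  expect_false(g2$gdna_flag)
  expect_equal(g2$gdna_fraction, 0)
  # constructed 30/70 mixture on an even grid: brute-force fraction = 0.3
  mix <- numeric(length(bp))
  mix[bp >= 200 & bp < 200 + 700] <- 1    # 70 grid steps below threshold
  mix[bp > 1000 & bp <= 1000 + 300] <- 1  # 30 grid steps above
  g3 <- flag_gdna(make_profile(bp, mix))
  expect_equal(g3$gdna_fraction, 0.3, tolerance = 0.01)
  expect_true(g3$gdna_flag)
})

test_that("summary metrics reproduce degenerate-distribution identities", {
  bp <- seq(100, 400, by = 1)
  delta <- ifelse(bp == 167, 1, 0)
  m <- summary_metrics(make_profile(bp, delta))
  expect_equal(m$modal_bp, 167)
  expect_equal(m$mean_bp, 167)
  expect_equal(m$median_bp, 167)
  expect_equal(m$entropy, 0)
  expect_equal(m$skewness, 0)
  two <- ifelse(bp %in% c(100, 300), 1, 0)
  m2 <- summary_metrics(make_profile(bp, two))
  expect_equal(m2$mean_bp, 200)
  expect_equal(m2$skewness, 0, tolerance = 1e-12)
  expect_equal(m2$entropy, log(2))
})

test_that("weighted moments match an independent brute-force oracle", {
  bp <- c(120, 180, 420)
  w <- c(0.2, 0.5, 0.3)
  m <- summary_metrics(make_profile(bp, w))
  p <- w / sum(w)
  mu <- sum(p * bp)
  v <- sum(p * (bp - mu)^2)
  expect_equal(m$mean_bp, mu)
  expect_equal(m$skewness, sum(p * (bp - mu)^3) / v^1.5)
  expect_equal(m$entropy, -sum(p * log(p)))
  expect_equal(m$modal_bp, 180)
  expect_equal(m$median_bp, 180)  # cumulative weight reaches 0.5 at 180
})

test_that("short/long ratio is undefined (NA) when the long window is empty", {
  bp <- seq(100, 400, by = 1)
  shorty <- ifelse(bp <= 140, 1, 0)
  m <- summary_metrics(make_profile(bp, shorty))
  expect_true(is.na(m$short_long_ratio))
  expect_error(summary_metrics(make_profile(bp, rep(0, length(bp)))),
               class = "fragtrace_validation_error")
})

test_that("mean, median and mode coincide for a symmetric unimodal profile", {
  bp <- seq(100, 500, by = 1)
  sym <- exp(-(bp - 300)^2 / (2 * 40^2))
  m <- summary_metrics(make_profile(bp, sym))
  expect_lt(abs(m$mean_bp - 300), 1)
  expect_lt(abs(m$median_bp - 300), 1)
  expect_lt(abs(m$modal_bp - 300), 1)
})

test_that("entropy is maximal for a uniform profile", {
  bp <- seq(100, 599, by = 1)
  m <- summary_metrics(make_profile(bp, rep(1, 500)))
  expect_equal(m$entropy, log(500), tolerance = 1e-12)
  m2 <- summary_metrics(make_profile(bp, rep(1, 500)), entropy_base = "bits")
  expect_equal(m2$entropy, log2(500), tolerance = 1e-12)
})

test_that("metrics and peaks are concentration-independent end to end", {
  sim <- simulate_electropherogram(list(mono_di_spec(baseline = 0.02)), seed = 6)
  lad <- default_ladder()
  tab2 <- sim$table
  tab2$intensities[, 2] <- tab2$intensities[, 2] * 13.7
  p1 <- background_correct(calibrate(sim$table, lad)[[1]])
  p2 <- background_correct(calibrate(tab2, lad)[[1]])
  m1 <- summary_metrics(p1); m2 <- summary_metrics(p2)
  num <- vapply(m1, is.numeric, logical(1))
  expect_lt(max(abs(unlist(m1[num]) - unlist(m2[num]))), 1e-9)
  expect_lt(max(abs(nucleosomal_fractions(p1)$fraction -
                      nucleosomal_fractions(p2)$fraction)), 1e-9)
  expect_lt(max(abs(detect_sample_peaks(p1)$size_bp -
                      detect_sample_peaks(p2)$size_bp)), 1e-9)
})
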