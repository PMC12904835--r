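test_that("well-formed CSV parses into a signal table with lanes from the header", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("pos,lane_1,lane_2,lane_3",
               "0,0.1,0.2,0.3",
               "1,0.4,0.5,0.6",
               "2,0.7,0.8,0.9",
               "3,1.0,1.1,1.2"), p)
  st <- read_signal_table(p)
  expect_s3_class(st, "signal_table")
  expect_length(st$positions, 4)
  expect_equal(st$lane_names, c("lane_1", "lane_2", "lane_3"))
  expect_equal(unname(st$intensities[2, "lane_2"]), 0.5)
})

test_that("delimiter sniffing handles semicolon+decimal-comma and tab dialects", {
  p <- tempfile()
  writeLines(c("pos;a;b", "0;0,5;1,25", "1;2,0;3,5"), p)
  st <- read_signal_table(p)
  expect_equal(unname(st$intensities[, "a"]), c(0.5, 2.0))
  expect_equal(unname(st$intensities[2, "b"]), 3.5)
  p2 <- tempfile()
  writeLines(c("pos\tx\ty", "0\t1\t2", "1\t3\t4"), p2)
  st2 <- read_signal_table(p2)
  expect_equal(st2$lane_names, c("x", "y"))
})

test_that("device-export dialect skips a metadata preamble", {
  p <- tempfile()
  writeLines(c("Instrument: Model X", "Run started 2025-01-01",
               "pos,s1,s2", "0,1,2", "1,3,4"), p)
  st <- read_signal_table(p, dialect = "device_export")
  expect_equal(st$lane_names, c("s1", "s2"))
  expect_equal(unname(st$intensities[, "s1"]), c(1, 3))
})

test_that("malformed signal tables raise format errors naming the offender", {
  hdr_only <- tempfile(); writeLines("pos,a,b", hdr_only)
  expect_error(read_signal_table(hdr_only), class = "fragtrace_format_error")
  ragged <- tempfile(); writeLines(c("pos,a,b", "0,1,2", "1,3"), ragged)
  expect_error(read_signal_table(ragged), "row 3",
               class = "fragtrace_format_error")
  nonnum <- tempfile(); writeLines(c("pos,a,b", "0,1,oops"), nonnum)
  expect_error(read_signal_table(nonnum), "column 'b'.*oops",
               class = "fragtrace_format_error")
  single <- tempfile(); writeLines(c("pos", "0", "1"), single)
  expect_error(read_signal_table(single), class = "fragtrace_format_error")
  expect_error(read_signal_table(tempfile()), class = "fragtrace_io_error")
})

test_that("write-then-read round trip preserves values and lane count", {
  set.seed(11)
  st <- signal_table(0:49, matrix(runif(150), 50, 3), c("L", "a", "b"))
  p <- write_table_file(st)
  back <- read_signal_table(p)
  expect_equal(back$lane_names, st$lane_names)
  expect_equal(back$intensities, st$intensities, tolerance = 1e-6)
  expect_identical(ncol(back$intensities), 3L)
})

test_that("ladder annotation parses sizes, marker tokens and direction", {
  lad <- read_ladder_annotation(
    write_ladder_file(c("25 marker", "100", "200", "400", "1500 marker")))
  expect_equal(nrow(lad), 5)
  expect_equal(lad$is_marker, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # token variants, case-insensitive
  lad2 <- read_ladder_annotation(
    write_ladder_file(c("25 M", "100", "400 *", "800 MARKER", "1000")))
  expect_equal(lad2$is_marker, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  # descending order is valid (migration direction)
  lad3 <- read_ladder_annotation(write_ladder_file(c("1500", "400", "100")))
  expect_equal(lad3$size_bp, c(1500, 400, 100))
})

test_that("invalid ladder annotations are rejected", {
  expect_error(read_ladder_annotation(
    write_ladder_file(c("100", "50", "200"))),
    "monotone", class = "fragtrace_validation_error")
  empty <- tempfile(); writeLines(character(0), empty)
  expect_error(read_ladder_annotation(empty),
               class = "fragtrace_validation_error")
  expect_error(read_ladder_annotation(
    write_ladder_file(c("100 marker", "200 marker", "400"))),
    class = "fragtrace_validation_error")  # < 2 non-marker sizes
  bad <- write_ladder_file(c("100", "abc", "400"))
  expect_error(read_ladder_annotation(bad), "line 2",
               class = "fragtrace_format_error")
})

test_that("metadata reader yields grouping variables and rejects duplicates", {
  md <- read_metadata(write_metadata_file(
    data.frame(sample = c("s1", "s2", "s3"),
               disease = c("healthy", "tumor", "tumor"),
               sex = c("f", "m", "f"))))
  expect_s3_class(md, "metadata_table")
  expect_equal(setdiff(names(md), "sample"), c("disease", "sex"))
  expect_equal(nrow(md), 3)
  dup <- write_metadata_file(data.frame(sample = c("s1", "s1"),
                                        disease = c("a", "b")))
  expect_error(read_metadata(dup), class = "fragtrace_validation_error")
  nosample <- write_metadata_file(data.frame(id = "s1", disease = "a"))
  expect_error(read_metadata(nosample), class = "fragtrace_format_error")
})

test_that("result bundle writes all tables deterministically", {
  res <- sim_profiles(list(mono_di_spec(), mono_di_spec(amp = c(0.5, 1))))
  metrics <- do.call(rbind, lapply(res$profiles, summary_metrics))
  fracs <- do.call(rbind, lapply(res$profiles, function(p)
    data.frame(sample = p$sample, as.data.frame(nucleosomal_fractions(p)))))
  bundle <- list(raw_table = res$table, profiles = res$profiles,
                 metrics = metrics, fractions = fracs,
                 peaks = data.frame(sample = "sample_1", index = 0L,
                                    size_bp = 167, height = 1, prominence = 1))
  d1 <- file.path(tempdir(), "out_a")
  man <- write_outputs(bundle, d1)
  expect_gte(length(man), 5)
  expect_true(all(file.exists(man)))
  # identical input -> byte-identical files on re-run
  sums1 <- tools::md5sum(sort(unname(man)))
  man2 <- write_outputs(bundle, d1)
  expect_identical(unname(tools::md5sum(sort(unname(man2)))), unname(sums1))
  expect_error(write_outputs(list(), tempdir()),
               class = "fragtrace_validation_error")
})
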