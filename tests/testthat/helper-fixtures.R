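# Shared fixture builders. Everything is generated in code; no stored data.

# canonical cfDNA mixture: mononucleosomal 167 bp + dinucleosomal 334 bp
mono_di_spec <- function(noise_sd = 0, baseline = 0, amp = c(1, 0.5)) {
  trace_spec(data.frame(center_bp = c(167, 334), sd_bp = c(20, 40),
                        relative_amplitude = amp),
             baseline = baseline, noise_sd = noise_sd)
}

write_ladder_file <- function(lines = c("25 marker", "50", "100", "200",
                                        "400", "700", "1000", "1500 marker"),
                              path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}

write_table_file <- function(table, path = tempfile(fileext = ".csv")) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  path
}

write_metadata_file <- function(df, path = tempfile(fileext = ".csv"),
                                sep = ",") {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# bare calibrated profile on an explicit bp grid, full range usable
make_profile <- function(bp, intensity, sample = "s1",
                         marker_windows = data.frame(low_bp = numeric(),
                                                     high_bp = numeric()),
                         corrected = TRUE) {
  calibrated_profile(sample = sample, size_bp = bp, intensity = intensity,
                     calibrated_range = range(bp),
                     marker_windows = marker_windows,
                     corrected = corrected)
}

# calibrated+corrected sample profiles from a simulated table
sim_profiles <- function(specs, seed = 1, n_positions = 300) {
  sim <- simulate_electropherogram(specs, n_positions = n_positions, seed = seed)
  list(profiles = lapply(calibrate(sim$table, default_ladder()),
                         background_correct),
       truth = sim$truth, table = sim$table)
}

# pipeline mono-bin fraction for every sample of a cohort
cohort_mono_fractions <- function(co) {
  profs <- lapply(calibrate(co$table, default_ladder()), background_correct)
  vapply(profs, function(p) nucleosomal_fractions(p)$fraction[1], numeric(1))
}
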