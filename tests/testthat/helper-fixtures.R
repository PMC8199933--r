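# Shared small fixtures, built once per test run.  The 21-pixel grid keeps
# unit tests fast; full-scale geometry is exercised where a test needs it.

small_grid <- mit_grid(21, 0.1)
small_coils <- mit_coils()
small_sens <- build_sensitivity(small_grid, small_coils)

# A tiny normalized, split corpus for training-path tests.
make_tiny_corpus <- function(n_angles = 8, seed = 11) {
  placements <- enumerate_single_placements(0.02, 360 / n_angles, 0.06)
  raw <- simulate_samples(placements, small_sens, small_grid)
  set <- split_samples(normalize_samples(raw),
                       fractions = c(0.8, 0.2, 0), seed = seed)
  raw$split <- set$split
  list(raw = raw, set = set)
}

random_phantom <- function(grid, n_anom = 1) {
  specs <- lapply(seq_len(n_anom), function(i)
    anomaly(stats::runif(1, 0, 0.07), stats::runif(1, 0, 360)))
  place_anomalies(grid, specs)
}
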