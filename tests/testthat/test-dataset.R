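test_that("single-anomaly sweep enumerates the polar raster", {
  sweep <- enumerate_single_placements(0.001, 9, 0.070)
  expect_length(sweep, 2840L)   # 71 radii x 40 angles

  # count equals an independent double-loop enumeration
  cnt <- 0L
  for (r in seq(0, 0.070 + 1e-12, by = 0.001))
    for (t in seq(0, 351, by = 9)) cnt <- cnt + 1L
  expect_identical(length(sweep), cnt)

  # ordering is radius-major and the raster is exact
  expect_equal(sweep[[1]]$rho, 0)
  expect_equal(sweep[[41]]$rho, 0.001)
  expect_equal(sweep[[2]]$theta, 9)

  expect_length(enumerate_single_placements(0.01, 360, 0), 1L)
  expect_error(enumerate_single_placements(0.001, 9, 0.2), "beyond")
  expect_error(enumerate_single_placements(-1, 9, 0.07), "positive")
})

test_that("two-anomaly placements respect separations and the field boundary", {
  base <- enumerate_single_placements(0.02, 90, 0.06)
  pairs <- enumerate_two_anomaly_placements(c(0, 0.04, 0.06), base)
  expect_gt(length(pairs), 0)
  for (pr in pairs) {
    c1 <- mitgan:::anomaly_center(pr[[1]])
    c2 <- mitgan:::anomaly_center(pr[[2]])
    sep <- sqrt(sum((c1 - c2)^2))
    expect_true(min(abs(sep - c(0, 0.04, 0.06))) < 1e-9)
    expect_lte(sqrt(sum(c2^2)) + pr[[2]]$radius, 0.1 + 1e-12)
  }
  # coincident pair rasterizes exactly like the single disk
  g <- small_grid
  pr0 <- pairs[[1]]
  expect_equal(place_anomalies(g, pr0)$values,
               place_anomalies(g, pr0[1])$values)

  # pair count at one separation matches a brute-force enumeration
  brute <- 0L
  for (a1 in base) {
    c1 <- mitgan:::anomaly_center(a1)
    if (sqrt(sum(c1^2)) + a1$radius > 0.1) next
    for (phi in seq(0, 315, by = 45)) {
      c2 <- c1 + 0.06 * c(cos(phi * pi / 180), sin(phi * pi / 180))
      if (sqrt(sum(c2^2)) + a1$radius <= 0.1) brute <- brute + 1L
    }
  }
  only3R <- enumerate_two_anomaly_placements(0.06, base)
  expect_identical(length(only3R), brute)
  expect_error(enumerate_two_anomaly_placements(-0.01, base), "non-negative")
})

test_that("simulated samples pair rasterized phantoms with their projections", {
  placements <- enumerate_single_placements(0.03, 120, 0.06)
  set <- simulate_samples(placements, small_sens, small_grid)
  expect_identical(nrow(set$voltages), length(placements))
  expect_identical(ncol(set$conductivities), small_grid$active_count)
  for (k in c(1, 4)) {
    ph <- place_anomalies(small_grid, set$provenance[[k]]$anomalies)
    expect_equal(set$conductivities[k, ], ph$values)
    expect_equal(set$voltages[k, ], forward_project(small_sens, ph)$values)
  }
})

test_that("rotation augmentation matches the physics of the rotated phantom", {
  placements <- enumerate_single_placements(0.02, 72, 0.06)
  set <- simulate_samples(placements, small_sens, small_grid)
  aug <- augment_by_rotation(set, 2)
  n0 <- nrow(set$voltages)
  expect_identical(nrow(aug$voltages), n0 * 3L)
  expect_identical(augment_by_rotation(set, 0), set)

  for (k in seq_len(n0)) {
    for (num in 1:2) {
      row <- num * n0 + k
      # conductivity: exact re-rasterization at theta + num * 45
      rot <- lapply(set$provenance[[k]]$anomalies, function(a) {
        a$theta <- (a$theta + num * 45) %% 360; a
      })
      ph <- place_anomalies(small_grid, rot)
      expect_equal(aug$conductivities[row, ], ph$values)
      # voltage: block shift consistent with the forward model up to
      # rasterization noise
      v_true <- forward_project(small_sens, ph)$values
      rel <- sqrt(sum((aug$voltages[row, ] - v_true)^2)) /
             sqrt(sum(v_true^2))
      expect_lt(rel, 0.35)
    }
  }
  noprov <- set; noprov$provenance <- vector("list", n0)
  expect_error(augment_by_rotation(noprov, 1), "provenance")
})

test_that("normalization scales blocks to [0,1] and inverts exactly", {
  placements <- enumerate_single_placements(0.03, 120, 0.06)
  raw <- simulate_samples(placements, small_sens, small_grid)
  set <- normalize_samples(raw)
  expect_equal(range(set$voltages), c(0, 1))
  expect_equal(range(set$conductivities), c(0, 1))
  # two-valued conductivity maps anomaly -> 0, background -> 1
  expect_true(all(set$conductivities %in% c(0, 1)))
  bg_pixels <- raw$conductivities == 0.25
  expect_true(all(set$conductivities[bg_pixels] == 1))

  # round trip
  back <- mitgan:::invert_norm(set$voltages, set$normalization$voltage)
  expect_equal(back, raw$voltages, tolerance = 1e-12)

  const <- raw; const$conductivities[] <- 0.25
  expect_warning(normalize_samples(const), "degenerate")
})

test_that("splitting is a seeded partition with floor-sized tail sets", {
  placements <- enumerate_single_placements(0.01, 45, 0.06)
  raw <- simulate_samples(placements, small_sens, small_grid)
  n <- nrow(raw$voltages)
  set <- split_samples(raw, c(0.9, 0.05, 0.05), seed = 3)
  sp <- set$split
  expect_identical(length(sp$validation), as.integer(floor(0.05 * n)))
  expect_identical(length(sp$test), as.integer(floor(0.05 * n)))
  expect_identical(length(sp$train), n - 2L * as.integer(floor(0.05 * n)))
  expect_identical(sort(c(sp$train, sp$validation, sp$test)), seq_len(n))
  expect_identical(split_samples(raw, seed = 3)$split$train, sp$train)
  expect_error(split_samples(raw, c(0.5, 0.3, 0.1)), "sum to 1")
})

test_that("sample sets persist and reload bit-exactly with a metadata sidecar", {
  placements <- enumerate_single_placements(0.02, 90, 0.04)
  set <- split_samples(
    normalize_samples(simulate_samples(placements, small_sens, small_grid)),
    seed = 5)
  path <- file.path(tempdir(), "corpus_test")
  save_samples(set, path)
  expect_true(file.exists(paste0(path, ".meta.json")))
  back <- load_samples(path)
  expect_identical(back$voltages, set$voltages)
  expect_identical(back$conductivities, set$conductivities)
  expect_identical(back$normalization, set$normalization)
  expect_identical(back$split, set$split)

  # corrupt metadata surfaces the offending field
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  meta$n_samples <- 999
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  expect_error(load_samples(path), "n_samples")
  unlink(paste0(path, c(".rds", ".meta.json")))
})
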