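#' Enumerate the single-anomaly polar placement sweep
#'
#' Generates anomaly positions on a polar raster: radii from 0 to
#' `radial_max` in `radial_step` increments, angles from 0 to 360 degrees
#' (exclusive) in `angle_step` increments, ordered radius-major.  The
#' default sweep (0.1 cm radial step, 9 degree angular step, 7.0 cm radial
#' limit) yields 71 x 40 = 2840 placements.  Duplicate center placements at
#' rho = 0 are kept, matching the sweep's count convention.
#'
#' @param radial_step radial increment (m), default 0.001.
#' @param angle_step angular increment (degrees), default 9.
#' @param radial_max largest radius swept (m), default 0.070.
#' @param field_radius imaging-field radius (m) used to validate the sweep.
#' @param radius,conductivity anomaly parameters passed to [anomaly()].
#' @return List of `mit_anomaly` specs.
#' @export
enumerate_single_placements <- function(radial_step = 0.001, angle_step = 9,
                                        radial_max = 0.070,
                                        field_radius = 0.1,
                                        radius = 0.02, conductivity = 0.05) {
  if (radial_step <= 0 || angle_step <= 0)
    stop("`radial_step` and `angle_step` must be positive")
  if (radial_max > field_radius)
    stop("`radial_max` sweeps the anomaly center beyond the imaging field")
  rhos <- seq(0, radial_max + 1e-12, by = radial_step)
  thetas <- seq(0, 360 - angle_step + 1e-9, by = angle_step)
  out <- vector("list", length(rhos) * length(thetas))
  k <- 0L
  for (r in rhos) for (t in thetas) {
    k <- k + 1L
    out[[k]] <- anomaly(r, t, radius, conductivity)
  }
  out
}

#' Enumerate two-anomaly placements at controlled separations
#'
#' Pairs of equal-size anomalies: the first is swept over `base_sweep`
#' (typically a coarsened single-anomaly sweep) and the second is placed at
#' each requested center separation along each orientation, keeping only
#' pairs whose disks lie fully inside the imaging field.  Coincident pairs
#' (separation 0) are emitted once per base placement.
#'
#' @param separations center-to-center distances (m); the resolution study
#'   uses multiples {0, R, 2R, 3R} of the anomaly radius R.
#' @param base_sweep list of `mit_anomaly` specs for the first anomaly.
#' @param orientations directions (degrees) along which the second anomaly
#'   is offset; default multiples of 45.
#' @param field_radius imaging-field radius (m).
#' @return List of 2-element lists of `mit_anomaly` specs.
#' @export
enumerate_two_anomaly_placements <- function(separations, base_sweep,
                                             orientations = seq(0, 315, by = 45),
                                             field_radius = 0.1) {
  if (any(separations < 0)) stop("`separations` must be non-negative")
  out <- list(); k <- 0L
  for (a1 in base_sweep) {
    c1 <- anomaly_center(a1)
    if (sqrt(sum(c1^2)) + a1$radius > field_radius) next
    for (s in separations) {
      phis <- if (s == 0) 0 else orientations
      for (phi in phis) {
        c2 <- c1 + s * c(cos(phi * pi / 180), sin(phi * pi / 180))
        rho2 <- sqrt(sum(c2^2))
        if (rho2 + a1$radius > field_radius) next
        th2 <- (atan2(c2[2], c2[1]) * 180 / pi) %% 360
        k <- k + 1L
        out[[k]] <- list(a1, anomaly(rho2, th2, a1$radius, a1$conductivity))
      }
    }
  }
  out
}

#' Simulate a paired voltage/conductivity sample set
#'
#' Rasterizes each placement on the grid, projects it through the
#' sensitivity model, and collects raw (unnormalized) voltage and
#' conductivity vectors with full placement provenance.
#'
#' @param placements list whose elements are either single `mit_anomaly`
#'   specs or lists of specs (multi-anomaly samples).
#' @param model `mit_sensitivity`.
#' @param grid `mit_grid` (must match the model).
#' @param background background conductivity (S/m).
#' @return Object of class `mit_samples`: matrices `voltages`
#'   (`n x n_meas`) and `conductivities` (`n x active_count`), `provenance`
#'   (per-sample anomaly specs + rotation index), grid descriptors,
#'   `normalized = FALSE`.
#' @export
simulate_samples <- function(placements, model, grid, background = 0.25) {
  stopifnot(inherits(model, "mit_sensitivity"), inherits(grid, "mit_grid"))
  if (grid$active_count != ncol(model$matrix))
    stop("grid and sensitivity model have mismatched pixel counts")
  n <- length(placements)
  if (n == 0L) stop("no placements supplied")
  V <- matrix(0, n, nrow(model$matrix))
  Sg <- matrix(0, n, grid$active_count)
  prov <- vector("list", n)
  for (k in seq_len(n)) {
    specs <- placements[[k]]
    if (inherits(specs, "mit_anomaly")) specs <- list(specs)
    ph <- place_anomalies(grid, specs, background)
    V[k, ] <- forward_project(model, ph)$values
    Sg[k, ] <- ph$values
    prov[[k]] <- list(anomalies = specs, rotation = 0L)
  }
  structure(list(voltages = V, conductivities = Sg, provenance = prov,
                 side_count = grid$side_count,
                 field_radius = grid$field_radius,
                 background = background, normalized = FALSE,
                 normalization = NULL, split = NULL, seed = NULL),
            class = "mit_samples")
}

#' @export
print.mit_samples <- function(x, ...) {
  cat(sprintf("MIT sample set: %d samples (%d measurements -> %d pixels), %s\n",
              nrow(x$voltages), ncol(x$voltages), ncol(x$conductivities),
              if (x$normalized) "normalized [0,1]" else "raw units"))
  if (!is.null(x$split))
    cat(sprintf("  split: %d train / %d validation / %d test\n",
                length(x$split$train), length(x$split$validation),
                length(x$split$test)))
  invisible(x)
}

n_samples <- function(set) nrow(set$voltages)

subset_samples <- function(set, idx) {
  out <- set
  out$voltages <- set$voltages[idx, , drop = FALSE]
  out$conductivities <- set$conductivities[idx, , drop = FALSE]
  out$provenance <- set$provenance[idx]
  out$split <- NULL
  out
}

#' Expand a sample set by 45-degree rotations
#'
#' For each rotation step `num` in `1:times`, the conductivity image is
#' re-rasterized from the anomaly provenance at angle `theta + num * 45`
#' degrees, and the measurement vector is circularly shifted forward by
#' `7 * num` positions (the measurement-space image of the rotation for the
#' eight-coil array).  Originals are retained, so the output holds
#' `(times + 1)` times the input samples.
#'
#' @param set raw (unnormalized) `mit_samples` with provenance.
#' @param times number of rotation copies, 0..7.
#' @return Expanded `mit_samples`.
#' @export
augment_by_rotation <- function(set, times) {
  stopifnot(inherits(set, "mit_samples"))
  if (times < 0 || times > 7) stop("`times` must be between 0 and 7")
  if (set$normalized)
    stop("augment before normalization: rotation acts on raw samples")
  times <- as.integer(times)
  if (times == 0L) return(set)
  if (any(vapply(set$provenance, is.null, TRUE)))
    stop("samples carry no anomaly provenance; cannot augment")
  grid <- mit_grid(set$side_count, set$field_radius)
  n0 <- n_samples(set)
  V <- matrix(0, n0 * (times + 1L), ncol(set$voltages))
  Sg <- matrix(0, n0 * (times + 1L), ncol(set$conductivities))
  V[seq_len(n0), ] <- set$voltages
  Sg[seq_len(n0), ] <- set$conductivities
  prov <- vector("list", n0 * (times + 1L))
  prov[seq_len(n0)] <- set$provenance
  for (num in seq_len(times)) {
    rows <- num * n0 + seq_len(n0)
    for (k in seq_len(n0)) {
      p0 <- set$provenance[[k]]
      rot <- lapply(p0$anomalies, function(a) {
        a$theta <- (a$theta + num * 45) %% 360; a
      })
      ph <- place_anomalies(grid, rot, set$background)
      Sg[rows[k], ] <- ph$values
      V[rows[k], ] <- shift_measurements(set$voltages[k, ], 7L * num)
      prov[[rows[k]]] <- list(anomalies = rot, rotation = num)
    }
  }
  out <- set
  out$voltages <- V; out$conductivities <- Sg; out$provenance <- prov
  out$split <- NULL
  out
}

#' Min-max normalize a sample set to [0, 1]
#'
#' Global min-max scaling applied separately to the voltage block and the
#' conductivity block (one min/max per block over all samples and
#' components), with parameters stored for inversion.  On a two-valued
#' conductivity corpus this maps anomaly pixels to 0 and background pixels
#' to 1, matching the sigmoid output layer of the reconstruction networks.
#'
#' @param set raw `mit_samples`.
#' @return Normalized `mit_samples` with a `normalization` record
#'   (`voltage` and `conductivity` min/max).
#' @export
normalize_samples <- function(set) {
  stopifnot(inherits(set, "mit_samples"))
  if (n_samples(set) == 0L) stop("empty sample set")
  if (set$normalized) return(set)
  norm_block <- function(M, name) {
    lo <- min(M); hi <- max(M)
    if (hi - lo <= 0) {
      warning(sprintf("degenerate (constant) %s block maps to 0", name))
      list(values = M * 0, min = lo, max = hi)
    } else list(values = (M - lo) / (hi - lo), min = lo, max = hi)
  }
  v <- norm_block(set$voltages, "voltage")
  s <- norm_block(set$conductivities, "conductivity")
  out <- set
  out$voltages <- v$values
  out$conductivities <- s$values
  out$normalized <- TRUE
  out$normalization <- list(voltage = list(min = v$min, max = v$max),
                            conductivity = list(min = s$min, max = s$max))
  out
}

apply_norm <- function(x, block) {
  if (block$max - block$min <= 0) return(x * 0)
  (x - block$min) / (block$max - block$min)
}

invert_norm <- function(x, block) {
  if (block$max - block$min <= 0) return(x * 0 + block$min)
  x * (block$max - block$min) + block$min
}

#' Shuffle and split a sample set
#'
#' Seeded permutation followed by a train/validation/test partition.  The
#' validation and test sizes are the floors of their fractions; the
#' remainder goes to training, so fractions (0.9, 0.05, 0.05) on 1000
#' samples give 900/50/50.
#'
#' @param set `mit_samples`.
#' @param fractions length-3 numeric summing to 1
#'   (train, validation, test).
#' @param seed integer seed for the shuffle.
#' @return The set with a `split` field of index vectors `train`,
#'   `validation`, `test` (disjoint, exhaustive).
#' @export
split_samples <- function(set, fractions = c(0.9, 0.05, 0.05), seed = 1L) {
  stopifnot(inherits(set, "mit_samples"), length(fractions) == 3)
  if (abs(sum(fractions) - 1) > 1e-8) stop("`fractions` must sum to 1")
  n <- n_samples(set)
  perm <- with_seed(seed, sample.int(n))
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test
  out <- set
  out$split <- list(train = perm[seq_len(n_train)],
                    validation = perm[n_train + seq_len(n_val)],
                    test = perm[n_train + n_val + seq_len(n_test)])
  out$seed <- as.integer(seed)
  out
}

#' Persist a sample set (array container + JSON metadata sidecar)
#'
#' Writes `<path>.rds` (compressed serialization of the numeric arrays and
#' provenance) and `<path>.meta.json` (shapes, normalization parameters,
#' split sizes, seed, geometry descriptors) so a stored corpus is
#' self-describing.
#'
#' @param set `mit_samples`.
#' @param path file path without extension.
#' @return `path`, invisibly.
#' @export
save_samples <- function(set, path) {
  stopifnot(inherits(set, "mit_samples"))
  saveRDS(unclass(set), paste0(path, ".rds"), compress = "gzip")
  meta <- list(
    format = "mitgan-samples", version = 1L,
    n_samples = n_samples(set),
    n_measurements = ncol(set$voltages),
    n_pixels = ncol(set$conductivities),
    side_count = set$side_count, field_radius = set$field_radius,
    background = set$background, normalized = set$normalized,
    normalization = set$normalization,
    split_sizes = if (is.null(set$split)) NULL else
      lapply(set$split, length),
    seed = set$seed)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a persisted sample set
#'
#' @param path file path without extension, as given to [save_samples()].
#' @return `mit_samples`.
#' @export
load_samples <- function(path) {
  rds <- paste0(path, ".rds"); js <- paste0(path, ".meta.json")
  if (!file.exists(rds)) stop("missing array container: ", rds)
  if (!file.exists(js)) stop("missing metadata sidecar: ", js)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  if (is.null(meta$format) || !identical(meta$format, "mitgan-samples"))
    stop("metadata field `format` is missing or not 'mitgan-samples'")
  raw <- readRDS(rds)
  set <- structure(raw, class = "mit_samples")
  for (fld in c("voltages", "conductivities"))
    if (is.null(set[[fld]]) || !is.matrix(set[[fld]]))
      stop("array container field `", fld, "` is missing or corrupt")
  if (nrow(set$voltages) != meta$n_samples)
    stop("metadata field `n_samples` disagrees with stored arrays")
  if (ncol(set$conductivities) != meta$n_pixels)
    stop("metadata field `n_pixels` disagrees with stored arrays")
  set
}
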