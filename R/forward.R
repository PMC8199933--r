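#' Coil vector potential in the imaging plane (dipole approximation)
#'
#' Each coil is modelled as a magnetic dipole of moment
#' \eqn{m = N I \pi a^2} normal to the imaging plane; its vector potential
#' at an in-plane point is tangential,
#' \eqn{A(r) = (\mu_0 m / 4\pi)\, (\hat z \times \hat d)/|d|^2} with
#' \eqn{d} the offset from the coil center, so the magnitude falls off with
#' the inverse square of the distance.  This quasi-static surrogate keeps
#' the soft-field spatial weighting and the eight-fold symmetry of the coil
#' ring that the reconstruction algorithms rely on; absolute calibration is
#' absorbed into the global sensitivity scale.
#'
#' @param coils `mit_coils`.
#' @param index coil number (1-based, counterclockwise).
#' @param points `n x 2` matrix of (x, y) positions in metres.
#' @return `n x 2` matrix of (Ax, Ay).
#' @export
coil_vector_potential <- function(coils, index, points) {
  stopifnot(inherits(coils, "mit_coils"),
            index >= 1, index <= coils$coil_count)
  points <- rbind(points)
  dx <- points[, 1] - coils$centers[index, 1]
  dy <- points[, 2] - coils$centers[index, 2]
  r2 <- dx^2 + dy^2
  if (any(r2 < (1e-9 * coils$coil_radius)^2))
    stop("field point coincides with the coil center (dipole singularity)")
  m <- 1e-7 * coils$turns * coils$current_rms * pi * coils$coil_radius^2
  r <- sqrt(r2)
  # z-hat cross unit(d) = (-dy, dx)/r ; magnitude m / r^2
  cbind(Ax = -m * dy / (r2 * r), Ay = m * dx / (r2 * r))
}

#' Linearized sensitivity model of the coil array
#'
#' Builds the 56 x n_pixels sensitivity matrix of the linearized forward
#' map \eqn{V = S\,\Delta\sigma}: the entry for measurement pair (i, j) and
#' pixel p is \eqn{\omega\, A_i(p)\cdot A_j(p)\, h^2}, the standard
#' eddy-current perturbation integrand evaluated at the pixel center.
#' Rows are ordered excitation-major with receivers taken cyclically after
#' the excitation coil: (1,2), (1,3), ..., (1,8), (2,3), ..., (2,1), ...,
#' so a 45-degree rotation of the object corresponds to a forward shift of
#' the measurement vector by 7 positions.  Reciprocity (row (i,j) equals
#' row (j,i)) holds exactly by construction.
#'
#' The matrix is normalized by a single global scale chosen so that the
#' peak absolute signal of a reference anomaly (default conductivity and
#' radius, mid-radius position) is 1; measurement units are therefore
#' relative phase-difference units.
#'
#' @param grid `mit_grid`.
#' @param coils `mit_coils`.
#' @param reference reference anomaly used for the global scale
#'   calibration.
#' @param background background conductivity used for the calibration
#'   phantom (S/m).
#' @return Object of class `mit_sensitivity`: `matrix`
#'   (`n_pairs x active_count`), `pairs` (`n_pairs x 2`, excite/receive),
#'   `grid`, `coils`, `scale`.
#' @export
build_sensitivity <- function(grid, coils = mit_coils(),
                              reference = anomaly(grid$field_radius / 2, 0),
                              background = 0.25) {
  stopifnot(inherits(grid, "mit_grid"), inherits(coils, "mit_coils"))
  nc <- coils$coil_count
  omega <- 2 * pi * coils$frequency
  A <- lapply(seq_len(nc), function(k)
    coil_vector_potential(coils, k, grid$pixel_centers))
  pairs <- do.call(rbind, lapply(seq_len(nc), function(i) {
    j <- ((i - 1L + seq_len(nc - 1L)) %% nc) + 1L
    cbind(excite = i, receive = j)
  }))
  S <- matrix(0, nrow(pairs), grid$active_count)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    S[r, ] <- omega * (A[[i]][, 1] * A[[j]][, 1] +
                       A[[i]][, 2] * A[[j]][, 2]) * grid$spacing^2
  }
  model <- structure(list(matrix = S, pairs = pairs, grid = grid,
                          coils = coils, scale = 1), class = "mit_sensitivity")
  ref <- place_anomalies(grid, list(reference), background)
  peak <- max(abs(S %*% (ref$values - background)))
  if (peak > 0) {
    model$matrix <- S / peak
    model$scale <- 1 / peak
  }
  model
}

#' @export
print.mit_sensitivity <- function(x, ...) {
  cat(sprintf("MIT sensitivity model: %d measurements x %d pixels (%d coils)\n",
              nrow(x$matrix), ncol(x$matrix), x$coils$coil_count))
  invisible(x)
}

#' Project a phantom to boundary phase differences
#'
#' Difference imaging: the measurement is `S %*% (sigma - background)`, so
#' a homogeneous phantom maps to the zero vector and the projection is
#' linear in the conductivity perturbation.
#'
#' @param model `mit_sensitivity`.
#' @param phantom `mit_phantom` on the same grid.
#' @return Object of class `mit_frame`: `values` (length 56 for the default
#'   array), `snr_db = Inf`, `pairs`.
#' @export
forward_project <- function(model, phantom) {
  stopifnot(inherits(model, "mit_sensitivity"), inherits(phantom, "mit_phantom"))
  if (length(phantom$values) != ncol(model$matrix))
    stop("phantom and sensitivity model have mismatched pixel counts")
  v <- as.vector(model$matrix %*% (phantom$values - phantom$background))
  structure(list(values = v, snr_db = Inf, pairs = model$pairs, seed = NULL),
            class = "mit_frame")
}

#' @export
print.mit_frame <- function(x, ...) {
  cat(sprintf("MIT measurement frame: %d phase differences, SNR %s dB\n",
              length(x$values),
              if (is.infinite(x$snr_db)) "Inf" else format(x$snr_db)))
  invisible(x)
}

#' Add measurement noise at a prescribed SNR
#'
#' Additive white Gaussian noise with power `signal_power / 10^(snr_db/10)`
#' where the signal power is the mean square of the frame values.  Seeded
#' draws are reproducible and do not disturb the caller's RNG state.
#'
#' @param frame `mit_frame`.
#' @param snr_db signal-to-noise ratio in dB; `Inf` returns the frame
#'   unchanged.
#' @param seed optional integer seed.
#' @return A new `mit_frame` with `snr_db` and `seed` recorded.
#' @export
add_noise <- function(frame, snr_db, seed = NULL) {
  stopifnot(inherits(frame, "mit_frame"))
  if (length(snr_db) != 1L || is.na(snr_db) || snr_db <= 0)
    stop("`snr_db` must be a positive SNR in dB (use Inf for noiseless)")
  if (is.infinite(snr_db)) return(frame)
  p_sig <- mean(frame$values^2)
  sd_noise <- sqrt(p_sig * 10^(-snr_db / 10))
  noise <- with_seed(seed, stats::rnorm(length(frame$values), 0, sd_noise))
  structure(list(values = frame$values + noise, snr_db = snr_db,
                 pairs = frame$pairs, seed = seed), class = "mit_frame")
}

# Run `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Circular shift of a measurement vector by `units` positions forward,
# the measurement-space image of a 45-degree object rotation
# (7 units per step for the 8-coil array).
shift_measurements <- function(values, units) {
  n <- length(values)
  values[((seq_len(n) - 1L - units) %% n) + 1L]
}
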