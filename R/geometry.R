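#' Imaging grid for a circular object field
#'
#' Builds the square sampling lattice used to rasterize conductivity images.
#' Pixel centers sit on a uniform lattice spanning the square
#' \eqn{[-R, R]^2} (spacing \eqn{h = 2R/n}, centers at half-integer
#' multiples of \eqn{h}); a pixel is active when its center lies within the
#' calibrated mask radius \eqn{R - h/2} of the origin.  With the default
#' 67-pixel side and a 0.1 m field radius this yields exactly 3409 active
#' pixels inside the circular imaging field.
#'
#' Active pixels are ordered row-major over the full lattice, top row first
#' (x rightward, y upward, angles counterclockwise from +x); the ordering is
#' the fixed correspondence between conductivity vectors and image pixels
#' used throughout the package.
#'
#' @param side_count integer, pixels per axis (default 67).
#' @param field_radius radius of the circular imaging field in metres
#'   (default 0.1).
#' @return An object of class `mit_grid`: a list with `side_count`,
#'   `field_radius`, `spacing`, `mask_radius`, `active_mask` (logical
#'   `side_count x side_count` matrix, row 1 = top row), `pixel_centers`
#'   (`active_count x 2` matrix of (x, y) in metres) and `active_count`.
#' @examples
#' g <- mit_grid(67, 0.1)
#' g$active_count  # 3409
#' @export
mit_grid <- function(side_count = 67L, field_radius = 0.1) {
  if (length(side_count) != 1L || is.na(side_count) || side_count < 1)
    stop("`side_count` must be a positive integer")
  if (length(field_radius) != 1L || is.na(field_radius) || field_radius <= 0)
    stop("`field_radius` must be a positive length in metres")
  n <- as.integer(side_count)
  R <- field_radius
  h <- 2 * R / n
  centers <- seq(-R + h / 2, by = h, length.out = n)
  xs <- centers                 # column -> x, ascending
  ys <- rev(centers)            # row 1 -> largest y (top row)
  # distance of every lattice node from the origin, row-major
  xm <- matrix(xs, nrow = n, ncol = n, byrow = TRUE)
  ym <- matrix(ys, nrow = n, ncol = n)
  mask_radius <- R - h / 2
  d2 <- xm^2 + ym^2
  active <- d2 <= mask_radius^2 + 1e-15 * R^2
  ord <- which(t(active))       # row-major linear indices over the lattice
  centers_xy <- cbind(x = as.vector(t(xm))[ord], y = as.vector(t(ym))[ord])
  structure(list(
    side_count   = n,
    field_radius = R,
    spacing      = h,
    mask_radius  = mask_radius,
    active_mask  = active,
    pixel_centers = centers_xy,
    active_count = length(ord)
  ), class = "mit_grid")
}

#' @export
print.mit_grid <- function(x, ...) {
  cat(sprintf("MIT imaging grid: %d x %d lattice, field radius %g m\n",
              x$side_count, x$side_count, x$field_radius))
  cat(sprintf("  %d active pixels (spacing %.4g m, mask radius %.4g m)\n",
              x$active_count, x$spacing, x$mask_radius))
  invisible(x)
}

#' Circular coil array around the imaging field
#'
#' Describes the excitation/receiving coil ring: identical coils spaced at
#' equal angles around the object, numbered counterclockwise starting on the
#' +x axis.  Defaults follow an eight-channel system of 30-turn coils of
#' radius 0.025 m whose centers sit 0.11 m from the field center, driven at
#' 1 A RMS and 10 MHz.
#'
#' @param coil_count number of coils (>= 2).
#' @param coil_radius coil radius in metres.
#' @param turns windings per coil.
#' @param center_distance distance of coil centers from the origin (m).
#' @param current_rms excitation current, A RMS.
#' @param frequency excitation frequency, Hz.
#' @return Object of class `mit_coils` with the parameters plus `angles`
#'   (degrees, counterclockwise) and `centers` (`coil_count x 2` matrix, m).
#' @examples
#' coils <- mit_coils()
#' coils$angles        # 0, 45, ..., 315
#' coils$centers[3, ]  # (0, 0.11)
#' @export
mit_coils <- function(coil_count = 8L, coil_radius = 0.025, turns = 30L,
                      center_distance = 0.11, current_rms = 1,
                      frequency = 1e7) {
  if (coil_count < 2) stop("`coil_count` must be at least 2")
  stopifnot(coil_radius > 0, turns > 0, center_distance > 0,
            current_rms > 0, frequency > 0)
  n <- as.integer(coil_count)
  angles <- (seq_len(n) - 1L) * 360 / n
  th <- angles * pi / 180
  structure(list(
    coil_count = n, coil_radius = coil_radius, turns = as.integer(turns),
    center_distance = center_distance, current_rms = current_rms,
    frequency = frequency, angles = angles,
    centers = cbind(x = center_distance * cos(th),
                    y = center_distance * sin(th))
  ), class = "mit_coils")
}

#' @export
print.mit_coils <- function(x, ...) {
  cat(sprintf(
    "MIT coil array: %d coils (r = %g m, %d turns) at %g m, %g A RMS, %g Hz\n",
    x$coil_count, x$coil_radius, x$turns, x$center_distance,
    x$current_rms, x$frequency))
  invisible(x)
}

#' Spherical anomaly specification
#'
#' A conductivity anomaly given in polar coordinates on the imaging plane.
#' The 3-D sphere is rasterized as its equatorial disk, since imaging
#' recovers the single slice through the coil plane.
#'
#' @param rho radial position of the anomaly center (m).
#' @param theta angular position, degrees counterclockwise from +x.
#' @param radius anomaly radius (m), default 0.02.
#' @param conductivity anomaly conductivity (S/m), default 0.05.
#' @return Object of class `mit_anomaly`.
#' @export
anomaly <- function(rho, theta, radius = 0.02, conductivity = 0.05) {
  if (rho < 0) stop("`rho` must be non-negative")
  if (radius <= 0) stop("`radius` must be positive")
  structure(list(rho = rho, theta = theta, radius = radius,
                 conductivity = conductivity),
            class = "mit_anomaly")
}

anomaly_center <- function(a) {
  th <- a$theta * pi / 180
  c(a$rho * cos(th), a$rho * sin(th))
}

#' Rasterize anomalies onto a grid
#'
#' Builds a conductivity phantom: every active pixel takes the anomaly
#' conductivity when its center falls strictly inside an anomaly disk, and
#' the background conductivity otherwise.  Later anomalies in the list
#' overwrite earlier ones where disks overlap.
#'
#' @param grid `mit_grid`.
#' @param anomalies list of [anomaly()] specs (empty list for a homogeneous
#'   phantom).
#' @param background background conductivity, S/m (default 0.25, soft
#'   tissue).
#' @return Object of class `mit_phantom`: `values` (S/m, one per active
#'   pixel), `background`, `anomalies` (provenance for rotation), and grid
#'   descriptors.
#' @seealso [rotate_phantom()]
#' @export
place_anomalies <- function(grid, anomalies = list(), background = 0.25) {
  stopifnot(inherits(grid, "mit_grid"))
  if (inherits(anomalies, "mit_anomaly")) anomalies <- list(anomalies)
  vals <- rep(background, grid$active_count)
  for (a in anomalies) {
    if (!inherits(a, "mit_anomaly")) stop("anomalies must be `mit_anomaly` objects")
    if (a$rho > grid$field_radius)
      stop("anomaly center lies outside the imaging field")
    ctr <- anomaly_center(a)
    d2 <- (grid$pixel_centers[, 1] - ctr[1])^2 +
          (grid$pixel_centers[, 2] - ctr[2])^2
    vals[d2 < a$radius^2] <- a$conductivity
  }
  structure(list(values = vals, background = background,
                 anomalies = anomalies, grid = grid),
            class = "mit_phantom")
}

#' Rotate a phantom by multiples of the coil spacing angle
#'
#' Rotation acts on the recorded anomaly specifications (polar angle
#' advanced by `steps * 45` degrees) followed by re-rasterization on the
#' same grid, so rotated phantoms are exact placements, not resampled
#' images.
#'
#' @param phantom `mit_phantom` built by [place_anomalies()] (its anomaly
#'   provenance is required).
#' @param steps_45deg integer number of 45-degree counterclockwise steps.
#' @return A new `mit_phantom`.
#' @export
rotate_phantom <- function(phantom, steps_45deg) {
  stopifnot(inherits(phantom, "mit_phantom"))
  if (is.null(phantom$anomalies))
    stop("phantom carries no anomaly provenance; cannot rotate")
  rot <- lapply(phantom$anomalies, function(a) {
    a$theta <- (a$theta + steps_45deg * 45) %% 360
    a
  })
  place_anomalies(phantom$grid, rot, phantom$background)
}

#' @export
print.mit_phantom <- function(x, ...) {
  cat(sprintf("MIT phantom: %d pixels, background %g S/m, %d anomaly(ies)\n",
              length(x$values), x$background, length(x$anomalies)))
  invisible(x)
}

#' Map an active-pixel vector to the full square image
#'
#' @param grid `mit_grid`.
#' @param values numeric vector over active pixels (grid ordering).
#' @param fill value for masked-out lattice nodes (default `NA`).
#' @return `side_count x side_count` matrix, row 1 = top image row.
#' @export
as_image <- function(grid, values, fill = NA_real_) {
  stopifnot(inherits(grid, "mit_grid"),
            length(values) == grid$active_count)
  img <- matrix(fill, grid$side_count, grid$side_count)
  img[t(grid$active_mask)] <- values   # row-major fill
  t(img)
}

#' @export
plot.mit_phantom <- function(x, main = "conductivity (S/m)", ...) {
  plot_mit_image(x$grid, x$values, main = main, ...)
}

#' Draw a conductivity image
#'
#' @param grid `mit_grid`.
#' @param values active-pixel vector.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot_mit_image <- function(grid, values, main = "", ...) {
  img <- as_image(grid, values)
  # image() draws x along rows; transpose and flip so the top image row is up
  graphics::image(x = seq_len(grid$side_count), y = seq_len(grid$side_count),
                  z = t(img[grid$side_count:1, , drop = FALSE]),
                  asp = 1, axes = FALSE, xlab = "", ylab = "",
                  main = main, useRaster = TRUE, ...)
  invisible(NULL)
}
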