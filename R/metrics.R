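#' Image-quality metrics
#'
#' The four evaluation indices of the reconstruction study plus the
#' cross-validation MSE, computed on the masked pixel vectors of
#' normalized [0, 1] images.
#'
#' * `mse`: mean squared error averaged per dimension.
#' * `rmse`: its square root.
#' * `ssim`: global (single-window) structural similarity with
#'   `c1 = (k1 L)^2`, `c2 = (k2 L)^2`, `k1 = 0.01`, `k2 = 0.03`; means,
#'   variances and covariance are taken over all pixels of the vector pair.
#' * `psnr`: `10 log10(peak^2 / MSE)` with `peak = 1` for unit-range
#'   images, so `psnr = -20 log10(rmse)`; identical images give `Inf`.
#' * `cc`: Pearson correlation coefficient.
#'
#' @param y,yhat numeric vectors of equal length (truth, reconstruction).
#' @param L dynamic range of the image values (1 for normalized images).
#' @param peak peak signal value (1 for normalized images).
#' @return A single numeric value.
#' @name metrics
NULL

check_lengths <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("`y` and `yhat` must have equal length")
}

#' @rdname metrics
#' @export
mse <- function(y, yhat) {
  check_lengths(y, yhat)
  mean((y - yhat)^2)
}

#' @rdname metrics
#' @export
rmse <- function(y, yhat) sqrt(mse(y, yhat))

#' @rdname metrics
#' @export
ssim <- function(y, yhat, L = 1) {
  check_lengths(y, yhat)
  if (L <= 0) stop("`L` must be positive")
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  mu_y <- mean(y); mu_x <- mean(yhat)
  v_y <- mean((y - mu_y)^2); v_x <- mean((yhat - mu_x)^2)
  cov <- mean((y - mu_y) * (yhat - mu_x))
  ((2 * mu_y * mu_x + c1) * (2 * cov + c2)) /
    ((mu_y^2 + mu_x^2 + c1) * (v_y + v_x + c2))
}

#' @rdname metrics
#' @export
psnr <- function(y, yhat, peak = 1) {
  m <- mse(y, yhat)
  if (m == 0) return(Inf)
  10 * log10(peak^2 / m)
}

#' @rdname metrics
#' @export
cc <- function(y, yhat) {
  check_lengths(y, yhat)
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0)
    stop("correlation undefined for a zero-variance input")
  as.numeric(stats::cor(y, yhat))
}

#' Evaluate reconstructors over a noise sweep
#'
#' For every model and SNR level, adds seeded Gaussian noise to the raw
#' test measurements, reconstructs normalized images, computes the four
#' quality metrics per sample against the normalized truth, and averages.
#' Noise realizations are shared across models at each SNR so comparisons
#' see identical inputs.
#'
#' @param models named list of fitted reconstructors (each with a
#'   `predict(object, V, type = "normalized")` method and a
#'   `normalization` record).
#' @param test_samples raw `mit_samples`.
#' @param snr_levels SNRs in dB (`Inf` for noiseless).
#' @param seed base seed for the noise draws.
#' @return `data.frame` with one row per model x SNR: mean `rmse`, `ssim`,
#'   `psnr`, `cc` and the sample count `n`.
#' @export
evaluate_models <- function(models, test_samples,
                            snr_levels = c(Inf, 80, 40, 20), seed = 1L) {
  stopifnot(is.list(models), length(models) > 0,
            inherits(test_samples, "mit_samples"), !test_samples$normalized)
  if (is.null(names(models)) || any(names(models) == ""))
    stop("`models` must be a named list")
  n <- n_samples(test_samples)
  V0 <- test_samples$voltages
  rows <- list()
  for (s_i in seq_along(snr_levels)) {
    snr <- snr_levels[s_i]
    V <- V0
    if (is.finite(snr)) {
      for (k in seq_len(n)) {
        fr <- structure(list(values = V0[k, ], snr_db = Inf), class = "mit_frame")
        V[k, ] <- add_noise(fr, snr, seed = seed + 1000L * s_i + k)$values
      }
    }
    for (mn in names(models)) {
      mdl <- models[[mn]]
      truth <- apply_norm(test_samples$conductivities,
                          mdl$normalization$conductivity)
      rec <- predict(mdl, V, type = "normalized")
      per <- vapply(seq_len(n), function(k) c(
        rmse = rmse(truth[k, ], rec[k, ]),
        ssim = ssim(truth[k, ], rec[k, ]),
        psnr = psnr(truth[k, ], rec[k, ]),
        cc = cc(truth[k, ], rec[k, ])), numeric(4))
      rows[[length(rows) + 1L]] <- data.frame(
        model = mn, snr_db = snr,
        rmse = mean(per["rmse", ]), ssim = mean(per["ssim", ]),
        psnr = mean(per["psnr", ]), cc = mean(per["cc", ]), n = n)
    }
  }
  do.call(rbind, rows)
}
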