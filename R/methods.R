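coerce_voltages <- function(newdata) {
  if (inherits(newdata, "mit_frame")) matrix(newdata$values, nrow = 1)
  else if (inherits(newdata, "mit_samples")) {
    if (newdata$normalized)
      stop("pass raw (unnormalized) samples; models apply their own ",
           "training normalization")
    newdata$voltages
  } else if (is.null(dim(newdata))) matrix(newdata, nrow = 1)
  else as.matrix(newdata)
}

#' Reconstruct images from measurements with a fitted network
#'
#' Measurements are given in raw phase-difference units; the model applies
#' its stored training normalization to the input and returns images in
#' the normalized [0, 1] space (the network's output space, in which the
#' quality metrics are defined) or denormalized to S/m.
#'
#' @param object fitted `mit_bpnn` or `mit_gan`.
#' @param newdata a `mit_frame`, a numeric measurement vector, a
#'   `n x n_meas` matrix, or raw `mit_samples`.
#' @param type `"normalized"` for [0, 1] images, `"conductivity"` for S/m.
#' @param ... unused.
#' @return Image matrix (`n x n_pixels`), or a vector for a single frame.
#' @export
predict.mit_net <- function(object, newdata,
                            type = c("normalized", "conductivity"), ...) {
  type <- match.arg(type)
  if (is.null(object$normalization))
    stop("model carries no normalization record")
  V <- coerce_voltages(newdata)
  vec <- (inherits(newdata, "mit_frame") || is.null(dim(newdata)))
  Vn <- apply_norm(V, object$normalization$voltage)
  out <- forward_pass(object$network, Vn)
  if (type == "conductivity")
    out <- invert_norm(out, object$normalization$conductivity)
  if (vec) drop(out) else out
}

#' Reconstruct a conductivity image from one measurement frame
#'
#' @param object a fitted reconstructor (`mit_bpnn`, `mit_gan` or
#'   `mit_tikhonov`).
#' @param frame `mit_frame` (raw phase differences).
#' @param ... passed to the predict method.
#' @return Object of class `mit_image`: `values` in S/m over active
#'   pixels, plus grid descriptors; plot with its `plot` method.
#' @export
reconstruct <- function(object, frame, ...) {
  stopifnot(inherits(frame, "mit_frame"))
  vals <- predict(object, frame, type = "conductivity", ...)
  structure(list(values = as.vector(vals),
                 side_count = object$side_count,
                 field_radius = object$field_radius,
                 model = class(object)[1]), class = "mit_image")
}

#' @export
print.mit_image <- function(x, ...) {
  cat(sprintf("MIT reconstruction (%s): %d pixels, range [%.4g, %.4g] S/m\n",
              x$model, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.mit_image <- function(x, main = NULL, ...) {
  grid <- mit_grid(x$side_count, x$field_radius)
  plot_mit_image(grid, x$values,
                 main = if (is.null(main)) x$model else main, ...)
}

#' @export
print.mit_net <- function(x, ...) {
  cat(sprintf("%s reconstructor\n",
              if (inherits(x, "mit_gan")) "Two-stage adversarial (GAN)"
              else "Supervised fully-connected (BPNN)"))
  cat("  generator: {", paste(x$network$sizes, collapse = " "), "}\n")
  if (inherits(x, "mit_gan"))
    cat(sprintf("  stop: %s; selected epoch %d (val MSE %.4g)\n",
                x$stop_reason, x$selected_epoch, x$selected_val_mse))
  hp <- if (is.null(x$history$pretrain)) x$history else x$history$pretrain
  tm <- hp$train_mse
  if (length(tm)) cat(sprintf("  pretraining MSE %.4g -> %.4g (%d epochs)\n",
                              tm[1], tm[length(tm)], length(tm)))
  invisible(x)
}

#' @export
summary.mit_net <- function(object, ...) {
  print(object)
  h <- object$history
  if (length(h$val_mse))
    cat(sprintf("  final validation MSE: %.4g\n",
                h$val_mse[length(h$val_mse)]))
  if (!is.null(h$gen_err) && length(h$gen_err))
    cat(sprintf("  adversarial epochs: %d (gen err %.3f, disc err %.3f)\n",
                length(h$gen_err), h$gen_err[length(h$gen_err)],
                h$disc_err[length(h$disc_err)]))
  invisible(object)
}

#' @export
coef.mit_net <- function(object, ...) {
  list(W = object$network$W, b = object$network$b)
}

#' Residuals of a fitted reconstructor on a sample set
#'
#' @param object fitted `mit_net`.
#' @param samples raw `mit_samples` with conductivity truth.
#' @param ... unused.
#' @return Matrix of normalized-image residuals (predicted - truth).
#' @export
residuals.mit_net <- function(object, samples, ...) {
  stopifnot(inherits(samples, "mit_samples"))
  truth <- apply_norm(samples$conductivities,
                      object$normalization$conductivity)
  predict(object, samples) - truth
}

#' @export
plot.mit_net <- function(x, ...) {
  h <- x$history
  hp <- if (is.null(h$pretrain)) h else h$pretrain
  if (length(hp$train_mse)) {
    graphics::plot(hp$train_mse, type = "l", log = "y",
                   xlab = "epoch", ylab = "MSE",
                   main = "pretraining loss", ...)
    if (length(hp$val_mse) == length(hp$train_mse))
      graphics::lines(hp$val_mse, lty = 2)
  }
  if (!is.null(h$gen_err) && length(h$gen_err)) {
    graphics::plot(h$gen_err, type = "l", xlab = "adversarial epoch",
                   ylab = "cross-entropy error",
                   ylim = range(c(h$gen_err, h$disc_err)),
                   main = "adversarial errors", ...)
    graphics::lines(h$disc_err, lty = 2)
    graphics::legend("topright", c("generator", "discriminator"),
                     lty = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Writes `<path>.rds` (layer weight/bias arrays and training history) and
#' `<path>.meta.json` (architecture, control parameters, stop reason).
#'
#' @param object fitted `mit_net` or `mit_tikhonov`.
#' @param path file path without extension.
#' @return `path` invisibly; `load_model()` returns the fitted object.
#' @export
save_model <- function(object, path) {
  saveRDS(object, paste0(path, ".rds"), compress = "gzip")
  meta <- list(format = "mitgan-model", class = class(object)[1])
  if (inherits(object, "mit_net")) {
    meta$layer_sizes <- object$network$sizes
    meta$activations <- object$network$activations
    meta$stop_reason <- object$stop_reason
    meta$control <- object$control[c("pretrain_epochs", "pretrain_batch",
                                     "gan_epochs", "gan_batch",
                                     "learning_rate", "l2_coeff", "k_disc",
                                     "val_threshold", "seed")]
  } else if (inherits(object, "mit_tikhonov")) {
    meta$lambda <- object$lambda
  }
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  rds <- paste0(path, ".rds")
  if (!file.exists(rds)) stop("missing checkpoint: ", rds)
  readRDS(rds)
}
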