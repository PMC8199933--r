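#' Single-step Tikhonov-regularized reconstruction
#'
#' Classical linear baseline: the difference image solves
#' \eqn{\hat\sigma = (S^T S + \lambda I)^{-1} S^T V}, computed through the
#' equivalent measurement-space (dual) system
#' \eqn{S^T (S S^T + \lambda I)^{-1} V}, which is exact and far cheaper
#' when measurements are much fewer than pixels.  The difference image is
#' added to the background for display in S/m.
#'
#' @param model `mit_sensitivity`.
#' @param frame `mit_frame` (raw phase differences), or a numeric vector.
#' @param lambda non-negative regularization weight.
#' @return Numeric difference-image vector (one value per active pixel).
#' @export
tikhonov_reconstruct <- function(model, frame, lambda) {
  stopifnot(inherits(model, "mit_sensitivity"))
  v <- if (inherits(frame, "mit_frame")) frame$values else as.numeric(frame)
  if (length(v) != nrow(model$matrix))
    stop("measurement length does not match the sensitivity model")
  if (lambda < 0) stop("`lambda` must be non-negative")
  S <- model$matrix
  G <- tcrossprod(S) + lambda * diag(nrow(S))
  as.vector(crossprod(S, solve(G, v)))
}

#' Select the Tikhonov weight by validation grid search
#'
#' Evaluates a log-spaced grid of candidate weights on validation samples
#' and returns the one minimizing the mean reconstruction RMSE (computed
#' on normalized images when normalization parameters are supplied).
#' Deterministic: ties resolve to the first (smallest) candidate.
#'
#' @param model `mit_sensitivity`.
#' @param val_samples raw `mit_samples` with conductivity truth.
#' @param lambdas candidate weights.
#' @param normalization optional normalization record (as stored on
#'   `mit_samples`) defining the metric space.
#' @return The selected lambda, with the evaluated grid and mean RMSEs in
#'   attributes `grid` and `rmse`.
#' @export
select_lambda <- function(model, val_samples,
                          lambdas = 10^seq(-6, 2, length.out = 17),
                          normalization = NULL) {
  stopifnot(inherits(model, "mit_sensitivity"),
            inherits(val_samples, "mit_samples"))
  if (n_samples(val_samples) == 0L) stop("empty validation samples")
  S <- model$matrix
  eg <- eigen(tcrossprod(S), symmetric = TRUE)
  Vt <- val_samples$voltages %*% eg$vectors          # n x 56
  truth <- val_samples$conductivities
  bg <- val_samples$background
  score <- vapply(lambdas, function(lam) {
    W <- sweep(Vt, 2, eg$values + lam, "/") %*% t(eg$vectors)  # (SS'+l)^-1 V
    rec <- W %*% S + bg                               # n x npix, in S/m
    if (!is.null(normalization)) {
      rec <- apply_norm(rec, normalization$conductivity)
      tru <- apply_norm(truth, normalization$conductivity)
    } else tru <- truth
    mean(sqrt(rowMeans((rec - tru)^2)))
  }, numeric(1))
  lam <- lambdas[which.min(score)]
  attr(lam, "grid") <- lambdas
  attr(lam, "rmse") <- score
  lam
}

#' Fit the Tikhonov baseline as a reconstructor object
#'
#' Wraps the closed-form solver in the same predict interface as the
#' network models: raw measurements in, normalized [0, 1] images out.
#' When `lambda` is missing it is chosen by [select_lambda()] on the
#' supplied validation samples.
#'
#' @param model `mit_sensitivity`.
#' @param lambda regularization weight, or `NULL` to select.
#' @param val_samples raw `mit_samples` used for selection when `lambda`
#'   is `NULL`.
#' @param normalization normalization record defining the output space
#'   (take it from the normalized training set).
#' @param lambdas candidate grid for selection.
#' @return Object of class `mit_tikhonov`.
#' @export
mit_tikhonov <- function(model, lambda = NULL, val_samples = NULL,
                         normalization = NULL,
                         lambdas = 10^seq(-6, 2, length.out = 17)) {
  stopifnot(inherits(model, "mit_sensitivity"))
  if (is.null(lambda)) {
    if (is.null(val_samples))
      stop("supply `lambda` or `val_samples` for selection")
    lambda <- select_lambda(model, val_samples, lambdas, normalization)
  }
  structure(list(model = model, lambda = as.numeric(lambda),
                 lambda_grid = attributes(lambda),
                 normalization = normalization,
                 background = if (!is.null(val_samples))
                   val_samples$background else 0.25,
                 side_count = model$grid$side_count,
                 field_radius = model$grid$field_radius),
            class = "mit_tikhonov")
}

#' @export
print.mit_tikhonov <- function(x, ...) {
  cat(sprintf("Tikhonov reconstructor: lambda = %.4g (%d measurements x %d pixels)\n",
              x$lambda, nrow(x$model$matrix), ncol(x$model$matrix)))
  invisible(x)
}

#' @export
predict.mit_tikhonov <- function(object, newdata,
                                 type = c("normalized", "conductivity"),
                                 ...) {
  type <- match.arg(type)
  V <- coerce_voltages(newdata)
  vec <- (inherits(newdata, "mit_frame") || is.null(dim(newdata)))
  S <- object$model$matrix
  G <- tcrossprod(S) + object$lambda * diag(nrow(S))
  rec <- t(crossprod(S, solve(G, t(V)))) + object$background
  if (type == "normalized") {
    if (is.null(object$normalization))
      stop("model carries no normalization record")
    rec <- apply_norm(rec, object$normalization$conductivity)
  }
  if (vec) drop(rec) else rec
}
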