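#' Training hyperparameters
#'
#' Collects the tunable training constants.  Defaults follow the reference
#' protocol of the eight-channel study: 1000 pretraining epochs at batch
#' size 50, adversarial batch size 4000, Adam with learning rate 1e-4 for
#' both networks, L2 weight penalty 1e-5 on the generator during
#' pretraining, one discriminator ascent step per generator step, and a
#' validation-MSE stopping threshold of 0.05.
#'
#' @param pretrain_epochs generator pretraining epochs.
#' @param pretrain_batch pretraining minibatch size.
#' @param gan_epochs cap on adversarial epochs (the stopping rule may fire
#'   earlier).
#' @param gan_batch adversarial minibatch size.
#' @param learning_rate Adam step size for generator pretraining.
#' @param gan_learning_rate Adam step size for both networks in the
#'   adversarial stage; defaults to `learning_rate`.
#' @param l2_coeff L2 penalty coefficient on generator weights.
#' @param gan_fidelity weight of the paired L2 fidelity gradient in the
#'   stage-2 generator update (the discriminator receives generator
#'   outputs with the real conductivity distributions as labels, so the
#'   joint stage keeps the supervised signal); 0 gives the pure
#'   adversarial generator update.
#' @param gan_adversarial weight of the adversarial term in the stage-2
#'   generator loss.
#' @param k_disc discriminator ascent steps per generator step.
#' @param val_threshold validation MSE below which (together with the
#'   generator/discriminator error comparison) adversarial training stops.
#' @param non_saturating if `TRUE` the generator descends
#'   `-log D(G(V))` instead of the literal `log(1 - D(G(V)))`.
#' @param select_best_val return the generator from the adversarial epoch
#'   with the lowest validation MSE (the pretrained state counts as epoch
#'   0) rather than the final epoch.
#' @param seed integer seed controlling initialization and batch order.
#' @param beta1,beta2 Adam moment decay rates.
#' @return A list of class `mit_control`.
#' @export
mit_control <- function(pretrain_epochs = 1000L, pretrain_batch = 50L,
                        gan_epochs = 500L, gan_batch = 4000L,
                        learning_rate = 1e-4, gan_learning_rate = NULL,
                        l2_coeff = 1e-5,
                        gan_fidelity = 1, gan_adversarial = 1e-3,
                        k_disc = 1L, val_threshold = 0.05,
                        non_saturating = FALSE, select_best_val = TRUE,
                        seed = 1L, beta1 = 0.9, beta2 = 0.999) {
  if (is.null(gan_learning_rate)) gan_learning_rate <- learning_rate
  stopifnot(pretrain_epochs >= 0, pretrain_batch > 0, gan_epochs >= 0,
            gan_batch > 0, learning_rate > 0, gan_learning_rate > 0,
            l2_coeff >= 0, gan_fidelity >= 0, gan_adversarial >= 0,
            k_disc >= 1, val_threshold > 0, val_threshold < 1)
  structure(as.list(environment()), class = "mit_control")
}

default_generator_spec <- function(n_in, n_out, init_seed = NULL) {
  if (n_out >= 3000) {
    sizes <- c(n_in, 128L, 256L, 512L, 1024L, 2048L, 4096L, n_out)
    acts <- c("relu", "relu", "relu", "relu", "tanh", "tanh", "sigmoid")
  } else {
    sizes <- c(n_in, 128L, 256L, n_out)
    acts <- c("relu", "tanh", "sigmoid")
  }
  network_spec(sizes, acts, init_seed)
}

default_discriminator_spec <- function(n_in, init_seed = NULL) {
  hidden <- if (n_in >= 3000) c(512L, 128L) else c(128L, 32L)
  network_spec(c(n_in, hidden, 1L),
               c(rep("leaky_relu", length(hidden)), "sigmoid"), init_seed)
}

train_indices <- function(samples) {
  if (!is.null(samples$split)) samples$split$train
  else seq_len(n_samples(samples))
}

val_indices <- function(samples) {
  if (!is.null(samples$split)) samples$split$validation else integer(0)
}

#' Supervised fully-connected reconstructor (pretrained generator / BPNN)
#'
#' Fits the voltage-to-image network by minimizing the per-pixel mean
#' squared error plus an L2 weight penalty with Adam on shuffled
#' minibatches.  This is both the stand-alone BPNN baseline and stage 1 of
#' the two-stage adversarial reconstructor: [mit_gan()] with the same
#' specification and seed starts from exactly this state.
#'
#' @param samples normalized `mit_samples` (see [normalize_samples()]);
#'   when a split is present only the training indices are fitted and the
#'   validation MSE is tracked per epoch.
#' @param spec optional `mit_network` for the generator; default
#'   architecture is chosen from the sample dimensions (the full-scale
#'   corpus gets {56 128 256 512 1024 2048 4096 3409}).
#' @param control `mit_control`.
#' @return Object of class `c("mit_bpnn", "mit_net")` with elements
#'   `network`, `history` (`train_mse`, `val_mse` per epoch),
#'   `normalization`, grid descriptors, `control`, `call`.
#' @seealso [mit_gan()], [predict.mit_net()], [reconstruct()]
#' @export
mit_bpnn <- function(samples, spec = NULL, control = mit_control()) {
  stopifnot(inherits(samples, "mit_samples"))
  if (!samples$normalized)
    stop("`samples` must be normalized (see normalize_samples())")
  if (n_samples(samples) == 0L) stop("empty sample set")
  cl <- match.call()
  tr <- train_indices(samples); va <- val_indices(samples)
  X <- samples$voltages[tr, , drop = FALSE]
  Y <- samples$conductivities[tr, , drop = FALSE]
  Xv <- samples$voltages[va, , drop = FALSE]
  Yv <- samples$conductivities[va, , drop = FALSE]
  if (is.null(spec))
    spec <- default_generator_spec(ncol(X), ncol(Y), control$seed)
  net <- spec
  opt <- adam_init(net)
  n <- nrow(X); m <- ncol(Y)
  hist_tr <- numeric(0); hist_va <- numeric(0)
  run <- function() {
    for (ep in seq_len(control$pretrain_epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = control$pretrain_batch)) {
        idx <- perm[start:min(start + control$pretrain_batch - 1L, n)]
        cache <- net_forward_cache(net, X[idx, , drop = FALSE])
        out <- cache$A[[length(cache$A)]]
        err <- out - Y[idx, , drop = FALSE]
        dOut <- 2 * err / (length(idx) * m)
        grads <- net_backward(net, cache, dOut)
        step <- adam_step(net, grads, opt, control$learning_rate,
                          control$beta1, control$beta2, l2 = control$l2_coeff)
        net <<- step$net; opt <<- step$state
        ep_loss <- ep_loss + sum(err^2)
      }
      hist_tr[ep] <<- ep_loss / (n * m)
      if (length(va))
        hist_va[ep] <<- mse(as.vector(Yv), as.vector(forward_pass(net, Xv)))
    }
  }
  with_seed(control$seed, run())
  structure(list(network = net, history = list(train_mse = hist_tr,
                                               val_mse = hist_va),
                 normalization = samples$normalization,
                 side_count = samples$side_count,
                 field_radius = samples$field_radius,
                 background = samples$background,
                 control = control, call = cl),
            class = c("mit_bpnn", "mit_net"))
}

# Discriminator cross-entropy pieces on clamped outputs.
disc_errors <- function(d_real, d_fake) {
  d_real <- clamp01(d_real); d_fake <- clamp01(d_fake)
  list(gen = -mean(log(d_fake)),
       disc = -0.5 * (mean(log(d_real)) + mean(log(1 - d_fake))))
}

#' Two-stage adversarial reconstructor
#'
#' Stage 1 pretrains the generator (unless a fitted [mit_bpnn()] is
#' supplied).  Stage 2 alternates, on shuffled minibatches, `k_disc`
#' discriminator ascent steps on
#' `mean(log D(sigma)) + mean(log(1 - D(G(V))))` with one generator
#' descent step on the joint objective
#' `gan_fidelity * mse(G(V), sigma) +
#'  gan_adversarial * mean(log(1 - D(G(V))))`
#' (the discriminator judges generator outputs against the real
#' conductivity images, so the joint stage keeps the paired supervised
#' signal; set `gan_fidelity = 0` for the pure adversarial update, and
#' `non_saturating` for that variant), both by Adam.  After each epoch
#' the validation MSE and the
#' generator/discriminator cross-entropy errors are recorded; training
#' stops when the generator error is no larger than the discriminator
#' error and the validation MSE is below `val_threshold`, or at the epoch
#' cap.  The returned generator is the epoch with the lowest validation
#' MSE (the pretrained state included) when `select_best_val` is set.
#'
#' @param samples normalized `mit_samples` with a split (the validation
#'   part drives the stopping rule and model selection).
#' @param gen_spec,disc_spec optional `mit_network` specifications.
#' @param control `mit_control`.
#' @param pretrain optional fitted `mit_bpnn` used as the stage-2 starting
#'   point (must share the sample normalization).
#' @return Object of class `c("mit_gan", "mit_net")`: the selected
#'   `network`, the final `discriminator`, `history` (pretraining plus
#'   per-epoch `gen_err`, `disc_err`, `val_mse`), `stop_reason`
#'   (`"converged"` or `"max_iters"`), `selected_epoch`, normalization and
#'   grid descriptors.
#' @export
mit_gan <- function(samples, gen_spec = NULL, disc_spec = NULL,
                    control = mit_control(), pretrain = NULL) {
  stopifnot(inherits(samples, "mit_samples"))
  if (!samples$normalized)
    stop("`samples` must be normalized (see normalize_samples())")
  cl <- match.call()
  if (is.null(pretrain)) {
    pretrain <- mit_bpnn(samples, spec = gen_spec, control = control)
  } else {
    stopifnot(inherits(pretrain, "mit_bpnn"))
    if (!identical(pretrain$normalization, samples$normalization))
      stop("`pretrain` was fitted under a different normalization")
  }
  G <- pretrain$network
  tr <- train_indices(samples); va <- val_indices(samples)
  X <- samples$voltages[tr, , drop = FALSE]
  Y <- samples$conductivities[tr, , drop = FALSE]
  Xv <- samples$voltages[va, , drop = FALSE]
  Yv <- samples$conductivities[va, , drop = FALSE]
  if (is.null(disc_spec))
    disc_spec <- default_discriminator_spec(ncol(Y), control$seed + 1L)
  D <- disc_spec
  optG <- adam_init(G); optD <- adam_init(D)
  n <- nrow(X)
  val_mse_of <- function(net) {
    if (!length(va)) return(NA_real_)
    mse(as.vector(Yv), as.vector(forward_pass(net, Xv)))
  }
  hist <- list(gen_err = numeric(0), disc_err = numeric(0),
               val_mse = numeric(0))
  best <- list(net = G, val = val_mse_of(G), epoch = 0L)
  stop_reason <- "max_iters"
  run <- function() {
    for (ep in seq_len(control$gan_epochs)) {
      perm <- sample.int(n)
      ge <- de <- 0; nb <- 0L
      for (start in seq(1L, n, by = control$gan_batch)) {
        idx <- perm[start:min(start + control$gan_batch - 1L, n)]
        nb <- nb + 1L
        xb <- X[idx, , drop = FALSE]; yb <- Y[idx, , drop = FALSE]
        M <- length(idx)
        # --- discriminator ascent ---
        for (k in seq_len(control$k_disc)) {
          fake <- forward_pass(G, xb)
          cr <- net_forward_cache(D, yb)
          cf <- net_forward_cache(D, fake)
          dr <- clamp01(cr$A[[length(cr$A)]])
          df <- clamp01(cf$A[[length(cf$A)]])
          # minimize -[mean log D(real) + mean log(1 - D(fake))]
          gr <- net_backward(D, cr, -1 / (M * dr))
          gf <- net_backward(D, cf, 1 / (M * (1 - df)))
          grads <- list(gW = Map("+", gr$gW, gf$gW),
                        gb = Map("+", gr$gb, gf$gb))
          stepD <- adam_step(D, grads, optD, control$gan_learning_rate,
                             control$beta1, control$beta2)
          D <<- stepD$net; optD <<- stepD$state
        }
        # --- generator descent: paired fidelity + adversarial term ---
        cg <- net_forward_cache(G, xb)
        fake <- cg$A[[length(cg$A)]]
        cf <- net_forward_cache(D, fake)
        df <- clamp01(cf$A[[length(cf$A)]])
        # descending mean log(1 - Df): d/dDf = -1/(M (1 - Df));
        # non-saturating descends -mean log Df: d/dDf = -1/(M Df)
        dDf <- if (control$non_saturating) -1 / (M * df)
               else -1 / (M * (1 - df))
        dOut <- control$gan_adversarial * net_backward(D, cf, dDf)$dX
        if (control$gan_fidelity > 0)
          dOut <- dOut + control$gan_fidelity *
            2 * (fake - yb) / (M * ncol(yb))
        gradsG <- net_backward(G, cg, dOut)
        stepG <- adam_step(G, gradsG, optG, control$gan_learning_rate,
                           control$beta1, control$beta2)
        G <<- stepG$net; optG <<- stepG$state
        errs <- disc_errors(clamp01(forward_pass(D, yb)), df)
        ge <- ge + errs$gen; de <- de + errs$disc
      }
      hist$gen_err[ep] <<- ge / nb
      hist$disc_err[ep] <<- de / nb
      vm <- val_mse_of(G)
      hist$val_mse[ep] <<- vm
      if (!is.na(vm) && (is.na(best$val) || vm < best$val))
        best <<- list(net = G, val = vm, epoch = ep)
      # the player-error comparison is meaningful only after the
      # discriminator has adapted to the pretrained generator (one epoch
      # burn-in); the errors are minibatch estimates, so they are compared
      # with a small noise allowance
      if (ep >= 2L && !is.na(vm) &&
          hist$gen_err[ep] <= hist$disc_err[ep] + 0.02 &&
          vm < control$val_threshold) {
        stop_reason <<- "converged"
        break
      }
    }
  }
  with_seed(control$seed + 2L, run())
  selected <- if (control$select_best_val && !is.na(best$val)) best
              else list(net = G, val = val_mse_of(G),
                        epoch = length(hist$val_mse))
  structure(list(network = selected$net, discriminator = D,
                 history = c(list(pretrain = pretrain$history), hist),
                 stop_reason = stop_reason,
                 selected_epoch = selected$epoch,
                 selected_val_mse = selected$val,
                 pretrain_val_mse = if (length(pretrain$history$val_mse))
                   utils::tail(pretrain$history$val_mse, 1) else NA_real_,
                 normalization = samples$normalization,
                 side_count = samples$side_count,
                 field_radius = samples$field_radius,
                 background = samples$background,
                 control = control, call = cl),
            class = c("mit_gan", "mit_net"))
}

#' Closed-form optimal discriminator
#'
#' For fixed generator, the discriminator maximizing the adversarial value
#' function is the pointwise density ratio
#' `p_real / (p_real + p_gen)`; it equals 0.5 wherever the generated
#' density matches the true density, the unique global optimum of the
#' minimax game.
#'
#' @param p_real,p_gen non-negative density values at common evaluation
#'   points.
#' @return Numeric vector of optimal discriminator values.
#' @export
optimal_discriminator <- function(p_real, p_gen) {
  if (length(p_real) != length(p_gen))
    stop("`p_real` and `p_gen` must have equal length")
  if (any(p_real < 0) || any(p_gen < 0))
    stop("densities must be non-negative")
  tot <- p_real + p_gen
  if (any(tot == 0))
    stop("optimal discriminator undefined where both densities vanish")
  p_real / tot
}
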