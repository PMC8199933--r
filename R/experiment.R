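#' Experiment profiles
#'
#' A profile bundles every constant an experiment needs: geometry, sweep
#' parameters, network sizes, training control, and the SNR levels of the
#' evaluation sweep.  `"desk"` is a scaled-down study (33 x 33 grid,
#' coarser sweeps, smaller networks) that runs the full pipeline in
#' minutes on one CPU; `"paper"` reproduces the full-scale protocol
#' (67 x 67 grid, 0.1 cm / 9 degree sweep, the
#' {56 128 256 512 1024 2048 4096 3409} generator) and takes hours.
#'
#' @param name `"desk"` or `"paper"`.
#' @param seed integer master seed.
#' @return A configuration list of class `mit_profile`.
#' @export
mit_profile <- function(name = c("desk", "paper"), seed = 1L) {
  name <- match.arg(name)
  seed <- as.integer(seed)
  cfg <- switch(name,
    desk = list(
      profile = name, seed = seed,
      side_count = 33L, field_radius = 0.1, background = 0.25,
      sweep = list(radial_step = 0.005, angle_step = 15, radial_max = 0.070),
      two_anomaly = list(radial_step = 0.02, angle_step = 45,
                         separations = c(0, 0.04, 0.06)),
      augment_times = 3L,
      fractions = c(0.9, 0.05, 0.05),
      n_test = 200L,
      snr_levels = c(Inf, 80, 40, 20),
      control = mit_control(pretrain_epochs = 160L, pretrain_batch = 50L,
                            gan_epochs = 30L, gan_batch = 512L,
                            learning_rate = 1e-3, gan_learning_rate = 1e-3,
                            val_threshold = 0.005, seed = seed)),
    paper = list(
      profile = name, seed = seed,
      side_count = 67L, field_radius = 0.1, background = 0.25,
      sweep = list(radial_step = 0.001, angle_step = 9, radial_max = 0.070),
      two_anomaly = list(radial_step = 0.01, angle_step = 15,
                         separations = c(0, 0.02, 0.04, 0.06)),
      augment_times = 7L,
      fractions = c(0.9, 0.05, 0.05),
      n_test = 500L,
      snr_levels = c(Inf, 80, 40, 20),
      control = mit_control(seed = seed)))
  structure(cfg, class = "mit_profile")
}

#' Generate the training corpus for a profile
#'
#' Builds geometry and sensitivity model, enumerates the single- and
#' two-anomaly sweeps, simulates, augments by rotation, normalizes and
#' splits.
#'
#' @param cfg `mit_profile`.
#' @return List with `grid`, `coils`, `sensitivity`, `samples`
#'   (normalized + split) and `raw` (unnormalized copy).
#' @export
generate_corpus <- function(cfg) {
  grid <- mit_grid(cfg$side_count, cfg$field_radius)
  coils <- mit_coils()
  sens <- build_sensitivity(grid, coils)
  singles <- enumerate_single_placements(
    cfg$sweep$radial_step, cfg$sweep$angle_step, cfg$sweep$radial_max,
    field_radius = cfg$field_radius)
  base2 <- enumerate_single_placements(
    cfg$two_anomaly$radial_step, cfg$two_anomaly$angle_step,
    cfg$sweep$radial_max, field_radius = cfg$field_radius)
  doubles <- enumerate_two_anomaly_placements(
    cfg$two_anomaly$separations, base2, field_radius = cfg$field_radius)
  raw <- simulate_samples(c(singles, doubles), sens, grid, cfg$background)
  raw <- augment_by_rotation(raw, cfg$augment_times)
  samples <- split_samples(normalize_samples(raw),
                           fractions = cfg$fractions, seed = cfg$seed)
  raw$split <- samples$split
  list(grid = grid, coils = coils, sensitivity = sens,
       samples = samples, raw = raw)
}

#' Fresh random test samples for evaluation
#'
#' Draws single- and two-anomaly phantoms at uniformly random positions
#' (not from the training sweep) and simulates their measurements.
#'
#' @param cfg `mit_profile`.
#' @param sens `mit_sensitivity`.
#' @param grid `mit_grid`.
#' @param n number of samples.
#' @param seed integer seed.
#' @param p_two probability of a two-anomaly phantom.
#' @return Raw `mit_samples`.
#' @export
generate_test_samples <- function(cfg, sens, grid, n = cfg$n_test,
                                  seed = cfg$seed + 7L, p_two = 0.5) {
  rmax <- cfg$sweep$radial_max
  placements <- with_seed(seed, lapply(seq_len(n), function(k) {
    a1 <- anomaly(stats::runif(1, 0, rmax), stats::runif(1, 0, 360))
    if (stats::runif(1) < p_two) {
      repeat {
        sep <- sample(c(0.04, 0.06), 1)
        phi <- stats::runif(1, 0, 360)
        c2 <- anomaly_center(a1) +
          sep * c(cos(phi * pi / 180), sin(phi * pi / 180))
        if (sqrt(sum(c2^2)) + a1$radius <= cfg$field_radius) break
      }
      list(a1, anomaly(sqrt(sum(c2^2)),
                       (atan2(c2[2], c2[1]) * 180 / pi) %% 360))
    } else list(a1)
  }))
  simulate_samples(placements, sens, grid, cfg$background)
}

#' Run the full reconstruction study for a profile
#'
#' Generates the corpus, fits the BPNN baseline, the two-stage GAN
#' (warm-started from the same pretrained state) and the
#' Tikhonov baseline, then evaluates all three on freshly generated test
#' samples over the profile's SNR sweep.
#'
#' @param cfg `mit_profile`.
#' @param quiet suppress progress messages.
#' @return List with the fitted `models`, the `evaluation` data frame,
#'   `corpus`, `test_samples`, and the selected Tikhonov `lambda`.
#' @export
run_study <- function(cfg = mit_profile("desk"), quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  say("generating corpus (%d x %d grid) ...", cfg$side_count, cfg$side_count)
  corpus <- generate_corpus(cfg)
  say("corpus: %d samples", n_samples(corpus$samples))
  say("pretraining generator (BPNN) ...")
  bpnn <- mit_bpnn(corpus$samples, control = cfg$control)
  say("adversarial fine-tuning (GAN) ...")
  gan <- mit_gan(corpus$samples, control = cfg$control, pretrain = bpnn)
  say("GAN stop: %s (selected epoch %d)", gan$stop_reason, gan$selected_epoch)
  val_raw <- subset_samples(corpus$raw, corpus$raw$split$validation)
  tik <- mit_tikhonov(corpus$sensitivity, val_samples = val_raw,
                      normalization = corpus$samples$normalization)
  say("Tikhonov lambda = %.4g", tik$lambda)
  test <- generate_test_samples(cfg, corpus$sensitivity, corpus$grid)
  models <- list(Tikhonov = tik, BPNN = bpnn, GAN = gan)
  say("evaluating on %d fresh samples ...", n_samples(test))
  ev <- evaluate_models(models, test, cfg$snr_levels, seed = cfg$seed + 11L)
  list(models = models, evaluation = ev, corpus = corpus,
       test_samples = test, lambda = tik$lambda, config = cfg)
}

#' Command-line style experiment driver
#'
#' Backend of the `mitgan` command-line script: each subcommand writes its
#' artifacts under `out_dir` (dataset container + metadata, model
#' checkpoints + loss histories, CSV metric tables over the SNR sweep,
#' PNG truth-vs-reconstruction panels).
#'
#' @param subcommand one of `"generate"`, `"train"`, `"evaluate"`,
#'   `"render"`.
#' @param cfg `mit_profile`.
#' @param out_dir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return Invisibly, the paths written.
#' @export
run_experiment <- function(subcommand = c("generate", "train", "evaluate",
                                          "render"),
                           cfg = mit_profile("desk"), out_dir = ".",
                           quiet = TRUE) {
  subcommand <- match.arg(subcommand)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, paste0(...))
  written <- character(0)
  ensure_corpus <- function() {
    if (file.exists(p("dataset.rds"))) {
      samples <- load_samples(p("dataset"))
      grid <- mit_grid(samples$side_count, samples$field_radius)
      list(grid = grid, sensitivity = build_sensitivity(grid),
           samples = samples)
    } else generate_corpus(cfg)
  }
  if (subcommand == "generate") {
    corpus <- generate_corpus(cfg)
    save_samples(corpus$samples, p("dataset"))
    save_samples(corpus$raw, p("dataset_raw"))
    written <- c(p("dataset.rds"), p("dataset.meta.json"),
                 p("dataset_raw.rds"), p("dataset_raw.meta.json"))
  } else if (subcommand == "train") {
    study <- run_study(cfg, quiet = quiet)
    save_samples(study$corpus$samples, p("dataset"))
    save_samples(study$corpus$raw, p("dataset_raw"))
    for (mn in names(study$models))
      save_model(study$models[[mn]], p("model_", tolower(mn)))
    gan <- study$models$GAN
    h <- data.frame(epoch = seq_along(gan$history$gen_err),
                    gen_err = gan$history$gen_err,
                    disc_err = gan$history$disc_err,
                    val_mse = gan$history$val_mse)
    utils::write.csv(h, p("gan_history.csv"), row.names = FALSE)
    utils::write.csv(study$evaluation, p("metrics.csv"), row.names = FALSE)
    written <- p(c("dataset.rds", "metrics.csv", "gan_history.csv"))
  } else if (subcommand == "evaluate") {
    need <- p("model_", c("tikhonov", "bpnn", "gan"), ".rds")
    if (!all(file.exists(need)))
      stop("missing checkpoint(s): run the `train` subcommand first")
    corpus <- ensure_corpus()
    models <- list(Tikhonov = load_model(p("model_tikhonov")),
                   BPNN = load_model(p("model_bpnn")),
                   GAN = load_model(p("model_gan")))
    test <- generate_test_samples(cfg, corpus$sensitivity, corpus$grid)
    ev <- evaluate_models(models, test, cfg$snr_levels, seed = cfg$seed + 11L)
    utils::write.csv(ev, p("metrics.csv"), row.names = FALSE)
    written <- p("metrics.csv")
  } else if (subcommand == "render") {
    need <- p("model_", c("tikhonov", "bpnn", "gan"), ".rds")
    if (!all(file.exists(need)))
      stop("missing checkpoint(s): run the `train` subcommand first")
    corpus <- ensure_corpus()
    models <- list(Tikhonov = load_model(p("model_tikhonov")),
                   BPNN = load_model(p("model_bpnn")),
                   GAN = load_model(p("model_gan")))
    test <- generate_test_samples(cfg, corpus$sensitivity, corpus$grid,
                                  n = 3L)
    for (k in seq_len(n_samples(test))) {
      fr <- structure(list(values = test$voltages[k, ], snr_db = Inf),
                      class = "mit_frame")
      file <- p(sprintf("reconstruction_%02d.png", k))
      grDevices::png(file, width = 1200, height = 320)
      graphics::par(mfrow = c(1, 4), mar = c(1, 1, 3, 1))
      plot_mit_image(corpus$grid, test$conductivities[k, ], main = "truth")
      for (mn in names(models))
        plot(reconstruct(models[[mn]], fr), main = mn)
      grDevices::dev.off()
      written <- c(written, file)
    }
  }
  invisible(written)
}
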