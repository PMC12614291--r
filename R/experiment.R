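# Experiment orchestration: validated configurations, end-to-end runs, the
# t_con x schedule sweep, and the training-set-size sensitivity harness. All
# randomness fans out from one global seed into named sub-seeds (data,
# weight initialization, training, sampling), so individual components can be
# varied while everything else is held fixed.

experiment_defaults <- function() {
  list(
    seed = 1L,
    data = list(n_pairs = 200L, n_val = 20L, shape = c(32L, 32L),
                spacing = c(1, 1),
                anatomy = list(), degradation = list()),
    schedule = list(kind = "cosine", n_steps = 250L,
                    beta_min = 1e-4, beta_max = 0.02, sigma = "beta"),
    model = list(depth = 3L, base_width = 16L, blocks_per_level = 1L,
                 time_embedding_dim = 32L, groups = 8L),
    train = list(steps = 2500L, batch_size = 4L, lr = 1e-3,
                 sampler = list(kind = "uniform", tau = NULL),
                 n_bands = 10L),
    sample = list(t_con = c(250L, 200L), stochastic_z = TRUE, clip_x0 = TRUE),
    eval = list(mask_radius_frac = 0.9, data_range = 4000,
                hist_lower = -950)
  )
}

#' Experiment configuration
#'
#' Builds a validated configuration for [run_experiment()] and the sweep
#' harnesses. Arguments are merged over the package defaults: a scaled-down
#' study of 200 paired 32 x 32 phantom slices (20 held out for evaluation), a
#' cosine schedule over 250 timesteps with \eqn{\beta \in [10^{-4}, 0.02]}, a
#' depth-3/width-16 denoiser, 2500 Adam steps at batch size 4, and
#' noised-conditioned sampling at `t_con = n_steps` (pure-noise start) and
#' `t_con = 0.8 * n_steps`. Unknown keys are rejected.
#'
#' @param ... named blocks (`seed`, `data`, `schedule`, `model`, `train`,
#'   `sample`, `eval`) whose entries override the defaults; see
#'   [experiment_defaults] sources for the full key set.
#' @return A nested list of class `experiment_config`.
#' @export
experiment_config <- function(...) {
  override <- list(...)
  cfg <- experiment_defaults()
  allowed <- list(
    seed = NULL,
    data = c(names(cfg$data)),
    schedule = setdiff(names(formals(make_schedule)), ""),
    model = setdiff(names(formals(denoiser_config)), "input_shape"),
    train = names(cfg$train),
    sample = names(cfg$sample),
    eval = names(cfg$eval)
  )
  for (k in names(override)) {
    if (!k %in% names(cfg)) {
      stop_param("unknown configuration block '", k, "'")
    }
    if (is.list(cfg[[k]]) && is.list(override[[k]])) {
      extra <- setdiff(names(override[[k]]), allowed[[k]])
      if (length(extra)) {
        stop_param("unknown key(s) in '", k, "': ",
                   paste(extra, collapse = ", "))
      }
      cfg[[k]] <- modifyList(cfg[[k]], override[[k]])
    } else {
      cfg[[k]] <- override[[k]]
    }
  }
  # normalize list-shaped scalars/vectors (e.g. after a YAML round trip)
  cfg$seed <- as.integer(cfg$seed)
  cfg$data$shape <- as.integer(unlist(cfg$data$shape))
  cfg$data$n_pairs <- as.integer(cfg$data$n_pairs)
  cfg$data$n_val <- as.integer(cfg$data$n_val)
  cfg$sample$t_con <- as.integer(unlist(cfg$sample$t_con))
  structure(cfg, class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_experiment_config()` returns a validated
#'   `experiment_config`; `write_experiment_config()` returns `path`
#'   invisibly.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw)
}

#' @rdname read_experiment_config
#' @param cfg an [experiment_config()].
#' @export
write_experiment_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# instantiate the generator/model objects a config describes
config_objects <- function(cfg) {
  shape <- as.integer(cfg$data$shape)
  list(
    anatomy = do.call(anatomy_spec, cfg$data$anatomy),
    degradation = do.call(degradation_spec, cfg$data$degradation),
    schedule = do.call(make_schedule, cfg$schedule),
    model_cfg = do.call(denoiser_config,
                        c(list(input_shape = shape), cfg$model))
  )
}

# generate + preprocess + split the paired data a config describes
prepare_data <- function(cfg, obj) {
  sd_data <- derive_seed(cfg$seed, 1L)
  n_total <- cfg$data$n_pairs
  if (cfg$data$n_val >= n_total) {
    stop_param("n_val must be smaller than n_pairs")
  }
  dataset <- make_pair_dataset(n_total, shape = cfg$data$shape,
                               anatomy = obj$anatomy,
                               degradation = obj$degradation,
                               spacing = cfg$data$spacing,
                               seed = sd_data)
  norm <- lapply(dataset, preprocess)
  val_idx <- seq(n_total - cfg$data$n_val + 1L, n_total)
  list(raw = dataset, norm = norm,
       train = norm[-val_idx], val_idx = val_idx)
}

train_from_config <- function(cfg, obj, data) {
  denoiser <- build_denoiser(obj$model_cfg, seed = derive_seed(cfg$seed, 2L))
  sampler <- timestep_distribution(
    cfg$train$sampler$kind, obj$schedule$n_steps,
    tau = cfg$train$sampler$tau %||% obj$schedule$n_steps / 4
  )
  train_diffusion(denoiser, data$train, obj$schedule, sampler,
                  steps = cfg$train$steps, batch_size = cfg$train$batch_size,
                  lr = cfg$train$lr, n_bands = cfg$train$n_bands,
                  seed = derive_seed(cfg$seed, 3L))
}

# sample sCTs for the held-out pairs at one t_con and evaluate in HU space
eval_at_tcon <- function(denoiser, schedule, cfg, data, t_con) {
  shape <- as.integer(cfg$data$shape)
  val_raw <- data$raw[data$val_idx]
  val_norm <- data$norm[data$val_idx]
  nv <- length(val_raw)
  y0 <- vapply(val_norm, function(p) unclass_img(p$cbct),
               matrix(0, shape[1], shape[2]))
  sct_norm <- sample_noised_conditioned(
    denoiser, set_units(y0, "normalized"), schedule, t_con,
    stochastic_z = cfg$sample$stochastic_z, clip_x0 = cfg$sample$clip_x0,
    seed = derive_seed(cfg$seed, 100L + t_con)
  )
  sct_hu <- lapply(seq_len(nv), function(k) to_hu(sct_norm[, , k]))
  mask <- fov_mask(shape, cfg$eval$mask_radius_frac)
  ev <- evaluate_pairs(sct_hu,
                       lapply(val_raw, function(p) p$pct),
                       lapply(val_raw, function(p) p$cbct),
                       mask, data_range = cfg$eval$data_range)
  list(evaluation = ev, sct_hu = sct_hu)
}

#' Run an experiment end to end
#'
#' Generates the paired phantom data, trains the conditional denoiser, samples
#' synthetic CTs for the held-out pairs at every configured `t_con`, evaluates
#' masked MAE/PSNR/NCC against the planning CTs (with the CBCT-vs-pCT metrics
#' alongside), and writes all artifacts to a run directory: `config.yaml`,
#' `schedule.csv`, `loss_history.csv`, `metrics.csv`, the sampled sCT slices
#' as a NIfTI volume per `t_con`, and a model checkpoint. Reruns with the same
#' configuration reproduce identical outputs.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir run directory (created if missing); `NULL` skips writing.
#' @return Invisibly, a list with `metrics` (summary data frame across
#'   `t_con`), `evaluations` (per-`t_con` [evaluate_pairs()] objects), `fit`
#'   (trained denoiser + loss history), `schedule`, `config`, and `run_dir`.
#' @export
run_experiment <- function(cfg = experiment_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  obj <- config_objects(cfg)
  data <- prepare_data(cfg, obj)
  fit <- train_from_config(cfg, obj, data)

  evals <- list()
  metrics <- NULL
  for (t_con in cfg$sample$t_con) {
    res <- eval_at_tcon(fit$denoiser, obj$schedule, cfg, data, t_con)
    evals[[as.character(t_con)]] <- res$evaluation
    s <- res$evaluation$summary
    s$t_con <- t_con
    metrics <- rbind(metrics, s)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      vol <- array(unlist(lapply(res$sct_hu, as.vector)),
                   c(cfg$data$shape, length(res$sct_hu)))
      write_volume(vol, file.path(out_dir,
                                  sprintf("sct_tcon%04d.nii.gz", t_con)),
                   spacing = c(cfg$data$spacing, 3))
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_experiment_config(cfg, file.path(out_dir, "config.yaml"))
    write.csv(schedule_table(obj$schedule),
              file.path(out_dir, "schedule.csv"), row.names = FALSE)
    write.csv(fit$loss_history, file.path(out_dir, "loss_history.csv"),
              row.names = FALSE)
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    save_checkpoint(fit$denoiser, obj$schedule,
                    file.path(out_dir, "checkpoint.rds"), config = cfg)
  }

  invisible(list(metrics = metrics, evaluations = evals, fit = fit,
                 schedule = obj$schedule, config = cfg,
                 run_dir = out_dir))
}

#' Sweep sampling start timestep and noise schedule
#'
#' Trains one model per schedule kind (all other settings held fixed) and
#' evaluates noised-conditioned sampling at every `t_con`, producing the
#' schedule-by-`t_con` metrics grid that shows how the optimal `t_con` depends
#' on how fast each schedule destroys the conditioning anatomy.
#'
#' @param cfg an [experiment_config()].
#' @param t_con_values integer vector of start timesteps.
#' @param schedule_kinds subset of `c("linear", "cosine", "sigmoid")`.
#' @return A data frame: one row per (schedule, t_con, image class) with
#'   masked MAE/PSNR/NCC mean and SD.
#' @export
sweep_tcon <- function(cfg = experiment_config(),
                       t_con_values = cfg$sample$t_con,
                       schedule_kinds = c("linear", "cosine", "sigmoid")) {
  out <- NULL
  for (kind in schedule_kinds) {
    cfg_k <- cfg
    cfg_k$schedule$kind <- kind
    obj <- config_objects(cfg_k)
    data <- prepare_data(cfg_k, obj)
    fit <- train_from_config(cfg_k, obj, data)
    for (t_con in t_con_values) {
      s <- eval_at_tcon(fit$denoiser, obj$schedule, cfg_k, data,
                        t_con)$evaluation$summary
      s$t_con <- t_con
      s$schedule <- kind
      out <- rbind(out, s)
    }
  }
  out
}

#' Training-set-size sensitivity analysis
#'
#' Trains one model per training-set size with everything else (architecture,
#' schedule, step count, evaluation pairs, seeds) held constant, and tabulates
#' the held-out masked metrics per size. The per-size loss histories are
#' returned for overfitting inspection.
#'
#' @param cfg an [experiment_config()].
#' @param train_sizes decreasing integer vector of training-pair counts; each
#'   must not exceed the available training pairs.
#' @return A list with `metrics` (data frame with a `train_size` column) and
#'   `loss_histories` (named list of per-size loss-history data frames).
#' @export
sensitivity_sweep <- function(cfg = experiment_config(),
                              train_sizes) {
  obj <- config_objects(cfg)
  data <- prepare_data(cfg, obj)
  n_avail <- length(data$train)
  if (any(train_sizes > n_avail)) {
    stop_param("train_sizes may not exceed the ", n_avail,
               " available training pairs")
  }
  metrics <- NULL
  histories <- list()
  for (size in train_sizes) {
    data_s <- data
    data_s$train <- data$train[seq_len(size)]
    fit <- train_from_config(cfg, obj, data_s)
    for (t_con in cfg$sample$t_con) {
      s <- eval_at_tcon(fit$denoiser, obj$schedule, cfg, data_s,
                        t_con)$evaluation$summary
      s$t_con <- t_con
      s$train_size <- size
      metrics <- rbind(metrics, s)
    }
    histories[[as.character(size)]] <- fit$loss_history
  }
  list(metrics = metrics, loss_histories = histories)
}
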