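# Config-driven experiment runner.  Configs are flat JSON key/value
# files; every run writes its CSV outputs next to a manifest.json
# recording the effective config, the seeds used and the package
# version, so each output is reproducible from its manifest alone.

experiment_names <- c("sweep", "train", "generalize", "pca", "tuning",
                      "compare-nonlinear", "sparseness-curve")

default_config <- function() {
  list(
    experiment = "sweep",
    # task geometry
    K = 8L, target_start_angle = 0,
    posture_angles = c(-pi / 4, 0, pi / 4),
    n_muscles = 5L, muscle_base_angles = NULL,
    posture_rotations = c(-pi / 4, 0, pi / 4),
    # coding layer
    n_neurons = 2000L, n_neurons_comparison = 200L,
    theta = 3, theta_dense = -1,
    theta_heterogeneity_sd = 0,
    activation = "threshold_linear", beta = 1,
    # learning
    eta = 0.4, lambda = 0, n_trials = 20000L,
    convergence_window = c(0.9, 1),
    # sweep / analysis
    theta_grid = seq(-3, 3.8, length.out = 18),
    runs = 10L, n_novel_targets = 500L, neuron = 1L,
    # bookkeeping
    seed = 1L, out_dir = "."
  )
}

read_config <- function(config) {
  if (is.character(config)) {
    abort_if(!file.exists(config), sprintf("config file '%s' not found", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  abort_if(!is.list(config), "`config` must be a list or a JSON file path")
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  abort_if(length(unknown) > 0,
           "unknown config key(s): ", paste(unknown, collapse = ", "))
  base[names(config)] <- config
  abort_if(!base$experiment %in% experiment_names,
           sprintf("unknown experiment '%s'", base$experiment))
  base
}

config_geometry <- function(cfg) {
  task_geometry(
    targets = target_set(cfg$K, cfg$target_start_angle),
    postures = posture_set(cfg$posture_angles),
    muscles = muscle_geometry(cfg$n_muscles, cfg$muscle_base_angles,
                              cfg$posture_rotations))
}

config_coding <- function(cfg, theta, weight_seed) {
  coding_layer(
    sensory_weights(cfg$n_neurons, seed = weight_seed),
    threshold_spec(theta, cfg$n_neurons,
                   heterogeneity_sd = cfg$theta_heterogeneity_sd,
                   seed = weight_seed),
    activation_spec(cfg$activation, cfg$beta))
}

config_params <- function(cfg, adaptable = "W") {
  learning_params(eta = cfg$eta, lambda = cfg$lambda,
                  n_trials = cfg$n_trials,
                  window = cfg$convergence_window, adaptable = adaptable)
}

write_manifest <- function(cfg, seeds, files) {
  manifest <- list(
    config = cfg[!vapply(cfg, is.null, logical(1))],
    seeds = seeds, files = files,
    package = "sparsemotor",
    version = as.character(utils::packageVersion("sparsemotor")))
  path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run one configured experiment
#'
#' Executes one of the packaged experiments -- threshold sweep, single
#' training run, generalization test, activity PCA, single-neuron
#' tuning, the adaptable-J comparison networks, or the
#' sparseness-vs-threshold curve -- and writes CSV tables plus a JSON
#' manifest into the output directory.
#'
#' @param config a named list of config overrides or the path to a flat
#'   JSON config file.  Unknown keys are rejected.  See the package
#'   vignette for the key reference.
#' @param out_dir output directory (created if missing); overrides the
#'   config's `out_dir`.
#' @return Invisibly, a list with the result object(s) and the paths of
#'   the written files.
#' @export
run_experiment <- function(config = list(), out_dir = NULL) {
  cfg <- read_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  abort_if(file.access(cfg$out_dir, 2) != 0,
           sprintf("output directory '%s' is not writable", cfg$out_dir))
  geometry <- config_geometry(cfg)
  seeds <- as.list(spawn_seeds(cfg$seed, 4L))
  names(seeds) <- c("weights", "train", "train_dense", "novel")
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  result <- switch(cfg$experiment,
    "sweep" = {
      sw <- theta_sweep(cfg$theta_grid, cfg$runs, geometry, cfg$n_neurons,
                        config_params(cfg), cfg$seed,
                        cfg$theta_heterogeneity_sd,
                        activation_spec(cfg$activation, cfg$beta))
      put(data.frame(theta = sw$grid, mean_error = sw$mean_error,
                     sd_error = sw$sd_error, sparseness = sw$sparseness),
          "sweep.csv")
      sw
    },
    "train" = {
      coding <- config_coding(cfg, cfg$theta, seeds$weights)
      fit <- train(geometry, coding, config_params(cfg), seed = seeds$train)
      put(data.frame(trial = seq_along(fit$error), squared_error = fit$error),
          "learning_curve.csv")
      fit
    },
    "generalize" = {
      out <- lapply(c(sparse = cfg$theta, dense = cfg$theta_dense),
        function(th) {
          coding <- config_coding(cfg, th, seeds$weights)
          fit <- train(geometry, coding, config_params(cfg),
                       seed = seeds$train)
          list(train_error = fit$converged_error,
               gen_error = generalization_error(
                 fit, coding, geometry, cfg$n_novel_targets, seeds$novel))
        })
      put(data.frame(regime = names(out),
                     theta = c(cfg$theta, cfg$theta_dense),
                     converged_error = vapply(out, `[[`, 0, "train_error"),
                     generalization_error = vapply(out, `[[`, 0, "gen_error")),
          "generalization.csv")
      out
    },
    "pca" = {
      out <- lapply(c(sparse = cfg$theta, dense = cfg$theta_dense),
        function(th) {
          pca_contributions(
            activity_matrix(config_coding(cfg, th, seeds$weights), geometry))
        })
      put(data.frame(
        component = seq_along(out$sparse$contributions),
        contribution_sparse = out$sparse$contributions,
        contribution_dense = out$dense$contributions), "pca.csv")
      out
    },
    "tuning" = {
      coding <- config_coding(cfg, cfg$theta, seeds$weights)
      tm <- tuning_matrix(cfg$neuron, coding, geometry)
      df <- data.frame(target_angle = geometry$targets$angles, unclass(tm),
                       check.names = FALSE)
      put(df, "tuning.csv")
      tm
    },
    "compare-nonlinear" = {
      out <- lapply(list(J = "J", JW = c("W", "J")), function(adapt) {
        coding <- coding_layer(
          sensory_weights(cfg$n_neurons_comparison, seed = seeds$weights,
                          sd = 0),
          threshold_spec(0, cfg$n_neurons_comparison),
          activation_spec("tanh_positive", cfg$beta))
        train(geometry, coding, config_params(cfg, adaptable = adapt),
              seed = seeds$train)
      })
      put(data.frame(trial = seq_along(out$J$error),
                     squared_error_J_adaptable = out$J$error,
                     squared_error_JW_adaptable = out$JW$error),
          "compare_nonlinear.csv")
      out
    },
    "sparseness-curve" = {
      weights <- sensory_weights(cfg$n_neurons, seed = seeds$weights)
      sp <- vapply(cfg$theta_grid, function(th) {
        sparseness(coding_layer(
          weights,
          threshold_spec(th, cfg$n_neurons,
                         heterogeneity_sd = cfg$theta_heterogeneity_sd,
                         seed = seeds$weights),
          activation_spec(cfg$activation, cfg$beta)), geometry)
      }, numeric(1))
      put(data.frame(theta = cfg$theta_grid, sparseness = sp),
          "sparseness_curve.csv")
      sp
    })

  manifest <- write_manifest(cfg, seeds, files)
  invisible(list(result = result, files = files, manifest = manifest))
}
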