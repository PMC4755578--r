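#' Run a packaged experiment
#'
#' Single entry point behind the command-line wrapper (`inst/cli/infomax.R`).
#' Validates the configuration, runs the requested experiment with every
#' source of randomness derived from `config$seed`, and writes all results
#' (CSVs plus a `summary.json` carrying the full configuration, a
#' configuration hash, the seed and package version) to `config$out`.
#'
#' Experiments:
#' \describe{
#'   \item{`analytic-check`}{Closed-form constants of the ring model:
#'     gamma0, the critical first harmonic 2/gamma0, the objective shift at
#'     selected k1, and the optimal-K amplitude.}
#'   \item{`train-ring`}{Infomax training of the ring model; writes the
#'     learned parameters, objective history and profile harmonics.}
#'   \item{`train-images`}{Ecological model: synthetic textures, whitening,
#'     Gabor feedforward bank, infomax training of K.}
#'   \item{`sweep-scale`}{Scaling sweep of a saved network's K.}
#'   \item{`response-curves`}{Tuning curves with/without K for a saved ring
#'     network.}
#'   \item{`synth-data`}{Write synthetic texture images as PNG.}
#' }
#'
#' @param config Named list. Required: `experiment`, `out`, `seed`.
#'   `force = TRUE` allows writing into an existing output directory.
#'   Remaining entries are experiment-specific and documented in the
#'   defaults of the underlying functions (e.g. `M`, `mean_contrast`,
#'   `eta0`, `max_steps`, `scales`, `params_dir`).
#' @return Invisibly, the list of result objects; all outputs on disk.
#' @export
run_experiment <- function(config) {
  config <- validate_config(config)
  out <- config$out
  if (dir.exists(out) && length(dir(out)) > 0 && !isTRUE(config$force))
    stop("output directory ", out, " exists and is non-empty; ",
         "set force = TRUE to overwrite")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  res <- switch(config$experiment,
    "analytic-check" = exp_analytic_check(config),
    "train-ring" = exp_train_ring(config),
    "train-images" = exp_train_images(config),
    "sweep-scale" = exp_sweep_scale(config),
    "response-curves" = exp_response_curves(config),
    "synth-data" = exp_synth_data(config))
  summary <- c(list(experiment = config$experiment, seed = config$seed,
                    config_hash = config_hash(config),
                    package_version = as.character(
                      utils::packageVersion("infomaxnet")),
                    r_version = R.version.string),
               res$summary)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

validate_config <- function(config) {
  stopifnot(is.list(config))
  known <- c("analytic-check", "train-ring", "train-images", "sweep-scale",
             "response-curves", "synth-data")
  if (is.null(config$experiment) || !config$experiment %in% known)
    stop("config$experiment must be one of: ", paste(known, collapse = ", "))
  if (is.null(config$out)) stop("config$out (output directory) is required")
  if (is.null(config$seed)) config$seed <- 1L
  config$seed <- as.integer(config$seed)
  config
}

# Polynomial rolling hash of the deparsed configuration (mod 2^31 - 1);
# enough to fingerprint a run.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config[order(names(config))]),
                           collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

cfg <- function(config, name, default) {
  if (is.null(config[[name]])) default else config[[name]]
}

exp_analytic_check <- function(config) {
  gamma0 <- logistic(0)$deriv1
  M <- cfg(config, "M", 41)
  K <- optimal_ring_K(M, gamma0)
  fp <- fourier_profile(K)
  k1_grid <- c(0, 2, 4, 6, 7.5)
  shifts <- vapply(k1_grid, analytic_objective_shift, numeric(1),
                   gamma0 = gamma0)
  utils::write.csv(data.frame(k1 = k1_grid, objective_shift = shifts),
                   file.path(config$out, "objective_shift.csv"),
                   row.names = FALSE)
  list(summary = list(gamma0 = gamma0, critical_k1 = 2 / gamma0,
                      optimal_amplitude = M * max(fp$profile)))
}

exp_train_ring <- function(config) {
  spec <- ring_spec(M = cfg(config, "M", 41),
                    mean_contrast = cfg(config, "mean_contrast", 0.1))
  tc <- training_config(eta0 = cfg(config, "eta0", 0.01),
                        batch_size = cfg(config, "batch_size", 100),
                        max_steps = cfg(config, "max_steps", 2000),
                        seed = config$seed)
  st <- train_network(build_ring(spec$M), ring_input_sampler(spec), tc,
                      verbose = cfg(config, "verbose", 0))
  write_training_outputs(st, config$out)
  fp <- fourier_profile(st$params$K)
  list(summary = list(M = spec$M, mean_contrast = spec$mean_contrast,
                      amplitude = profile_amplitude(st$params$K),
                      k1 = unname(fp$k["k1"]),
                      circulant_residual = fp$circulant_residual,
                      final_epsilon = utils::tail(
                        st$objective_history$epsilon_after, 1)),
       state = st)
}

exp_train_images <- function(config) {
  imgs <- synth_textures(cfg(config, "n_images", 12),
                         side = cfg(config, "side", 128),
                         seed = config$seed)
  net <- image_network(imgs, M = cfg(config, "M", 60),
                       d = cfg(config, "d", 8),
                       n_patches = cfg(config, "n_patches", 4000),
                       target_drive = cfg(config, "target_drive", 0.1),
                       seed = config$seed + 1L)
  tc <- training_config(eta0 = cfg(config, "eta0", 0.01),
                        batch_size = cfg(config, "batch_size", 100),
                        max_steps = cfg(config, "max_steps", 400),
                        seed = config$seed + 2L)
  st <- train_network(net$params, code_sampler(net$codes), tc,
                      verbose = cfg(config, "verbose", 0))
  write_training_outputs(st, config$out)
  prof <- orientation_profile(st$params$K, net$bank$orientations)
  utils::write.csv(prof, file.path(config$out, "orientation_profile.csv"),
                   row.names = FALSE)
  list(summary = list(M = net$params$M, d = net$params$N,
                      input_scale = net$input_scale,
                      final_epsilon = utils::tail(
                        st$objective_history$epsilon_after, 1)),
       state = st, net = net)
}

exp_sweep_scale <- function(config) {
  params <- read_network_params(config$params_dir)
  scales <- cfg(config, "scales", seq(0, 1.3, by = 0.05))
  spec <- ring_spec(M = params$M,
                    mean_contrast = cfg(config, "mean_contrast", 0.1))
  X <- sample_ring_inputs(spec, cfg(config, "batch_size", 100),
                          seed = config$seed)
  sw <- scaling_sweep(params, scales, X, popvec_seed = config$seed)
  utils::write.csv(as.data.frame(sw), file.path(config$out, "sweep.csv"),
                   row.names = FALSE)
  list(summary = list(argmin_scale = attr(sw, "argmin_scale")), sweep = sw)
}

exp_response_curves <- function(config) {
  params <- read_network_params(config$params_dir)
  ang <- cfg(config, "stimulus_angle", pi / 2)
  rc <- response_curves(params, c(cos(ang), sin(ang)),
                        contrasts = cfg(config, "contrasts",
                                        c(0.05, 0.1, 0.2)))
  utils::write.csv(rc$curves, file.path(config$out, "curves.csv"),
                   row.names = FALSE)
  utils::write.csv(rc$widths, file.path(config$out, "widths.csv"),
                   row.names = FALSE)
  list(summary = list(n_curves = nrow(rc$widths)), curves = rc)
}

exp_synth_data <- function(config) {
  imgs <- synth_textures(cfg(config, "n_images", 4),
                         side = cfg(config, "side", 128),
                         seed = config$seed)
  for (i in seq_along(imgs))
    png::writePNG(imgs[[i]] / 255,
                  file.path(config$out, sprintf("texture_%03d.png", i)))
  list(summary = list(n_images = length(imgs)))
}

write_training_outputs <- function(st, out) {
  write_network_params(st$params, file.path(out, "params"))
  utils::write.csv(st$objective_history,
                   file.path(out, "objective_history.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(st$config),
                       file.path(out, "training_config.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Interaction strength versus preferred-orientation difference
#'
#' Averages the entries of K over pairs binned by the circular difference of
#' their preferred orientations (180-degree periodicity), the view in which
#' the ecological model's learned interactions show a Mexican-hat shape.
#'
#' @param K M x M interaction matrix.
#' @param orientations_deg Preferred orientations in degrees, [0, 180).
#' @param bin_width Bin width in degrees (default 3).
#' @return data.frame with `dpo_deg` (bin center) and `mean_K`.
#' @export
orientation_profile <- function(K, orientations_deg, bin_width = 3) {
  K <- as.matrix(K)
  M <- nrow(K)
  stopifnot(length(orientations_deg) == M)
  dpo <- abs(outer(orientations_deg, orientations_deg, "-"))
  dpo <- pmin(dpo, 180 - dpo)
  breaks <- seq(0, 90 + bin_width, by = bin_width)
  bins <- cut(as.numeric(dpo), breaks = breaks, include.lowest = TRUE,
              right = FALSE)
  agg <- tapply(as.numeric(K), bins, mean)
  data.frame(dpo_deg = breaks[-length(breaks)][seq_along(agg)] +
               bin_width / 2,
             mean_K = as.numeric(agg))
}
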