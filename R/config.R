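# Run configuration: YAML round-trip, normalization and run manifests.

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "semgpose_run",
    sim = list(n_subjects = 2L, n_gestures = 8L, n_trials = 6L,
               n_channels = 10L, sampling_rate = 100, trial_duration = 2,
               trial_gain_sd = 0.2, electrode_shift_prob = 0.2,
               noise_sd = 0.3),
    data_dir = NULL,                 # read MAT files from here instead of simulating
    preprocess = list(filter = "rms", cutoff = 1, order = 1L,
                      rms_ms = 100, mu = 256, window_ms = 200, stride_ms = 100),
    model = list(representation_dim = 16L, attention_heads = 4L,
                 temporal_filters = 8L, spatial_filters = 4L, dropout = 0.1),
    stage1 = list(epochs = 3L, batch_size = 128L, lr_encoder = 0.001,
                  lr_q = 0.005, lambda1 = 1.0, lambda2 = 0.1,
                  temperature = 0.1),
    distill = list(temperature = 1, alpha = 0.5, epochs = 8L, lr = 0.1,
                   batch_size = 128L),
    split = "db2",
    teacher_filters = 8L
  )
}

#' Read and normalize a run configuration file
#'
#' Reads a YAML run configuration and fills unset keys with package
#' defaults, so that `write_run_config(read_run_config(f))` is stable.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return a named list (class `run_config`).
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user, keep.null = TRUE)
  }
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop("run config must set a seed")
  if (cfg$distill$batch_size < 2 || cfg$stage1$batch_size < 2) {
    stop("batch sizes must be >= 2")
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param cfg a `run_config` list.
#' @param path output path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write a run manifest sufficient to reproduce a run
#'
#' Records the package version, seed, and an MD5 fingerprint of the
#' normalized configuration.
#'
#' @param cfg a `run_config`.
#' @param out_dir run output directory.
#' @return path of the written manifest.
#' @export
write_manifest <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(fileext = ".yaml")
  write_run_config(cfg, tmp)
  manifest <- list(
    package = "semgpose",
    version = as.character(utils::packageVersion("semgpose")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(tmp)),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  file.copy(tmp, file.path(out_dir, "config.yaml"), overwrite = TRUE)
  unlink(tmp)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}
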