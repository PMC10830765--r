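# Experiment configuration: YAML/JSON schema validation with defaults, plus
# provenance sidecars so every artifact records the configuration hash and
# seed that produced it.

config_defaults <- function() {
  list(
    atlases = c("desikan-killiany", "destrieux", "glasser"),
    metrics = c("mahalanobis", "taxicab"),
    taus = c(0, 0.6, 0.7, 0.8),
    normalizations = c("none", "proportional", "residual"),
    tasks = TASK_NAMES,
    k = 5L,
    seed = 1L,
    learning_rate = 0.001,
    epochs = 200L,
    batch_size = 16L,
    patience = 20L,
    class_weights = FALSE,
    min_vertices = 10L,
    output_dir = "results"
  )
}

ATLAS_SIZES <- c("desikan-killiany" = 68L, "destrieux" = 148L, "glasser" = 360L)

#' Validate an experiment configuration
#'
#' Fills defaults (rejection quantiles {0, 0.6, 0.7, 0.8}, learning rate
#' 0.001, k = 5, the three atlases, both distances, all normalization
#' modes), rejects unknown keys and checks every field's domain before any
#' computation starts.
#'
#' @param raw A named list (e.g. parsed YAML/JSON), a YAML file path, or
#'   `NULL`/empty for all defaults.
#' @return Object of class `experiment_config`: the validated list plus
#'   `atlas_sizes` and a `config_hash`.
#' @export
validate_config <- function(raw = NULL) {
  if (is.character(raw) && length(raw) == 1) {
    raw <- yaml::read_yaml(raw)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration must be a named list")
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, raw)

  bad_atlas <- setdiff(cfg$atlases, names(ATLAS_SIZES))
  if (length(bad_atlas)) stop("unknown atlas: ", paste(bad_atlas, collapse = ", "))
  bad_metric <- setdiff(cfg$metrics, c("mahalanobis", "taxicab"))
  if (length(bad_metric)) stop("unknown metric: ", paste(bad_metric, collapse = ", "))
  if (any(cfg$taus < 0 | cfg$taus >= 1)) {
    stop("taus must lie in [0, 1); offending value(s): ",
         paste(cfg$taus[cfg$taus < 0 | cfg$taus >= 1], collapse = ", "))
  }
  bad_norm <- setdiff(cfg$normalizations, c("none", "proportional", "residual"))
  if (length(bad_norm)) stop("unknown normalization: ", paste(bad_norm, collapse = ", "))
  bad_task <- setdiff(cfg$tasks, TASK_NAMES)
  if (length(bad_task)) stop("unknown task: ", paste(bad_task, collapse = ", "))
  if (cfg$k < 2) stop("k must be >= 2")
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive")
  if (cfg$epochs < 1) stop("epochs must be >= 1")

  cfg$atlas_sizes <- ATLAS_SIZES[cfg$atlases]
  cfg$config_hash <- config_hash(cfg)
  structure(cfg, class = "experiment_config")
}

# Stable short hash of the configuration (polynomial rolling hash of its
# deparsed form, kept within integer range).
config_hash <- function(cfg) {
  cfg$config_hash <- NULL
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Training configuration embedded in an experiment config
#' @param cfg An `experiment_config`.
#' @return A [train_config()].
#' @export
config_train <- function(cfg) {
  train_config(learning_rate = cfg$learning_rate, epochs = cfg$epochs,
               batch_size = cfg$batch_size, seed = cfg$seed,
               patience = cfg$patience, class_weights = cfg$class_weights)
}

#' Write a provenance sidecar next to an output artifact
#'
#' Records the configuration hash, seed and timestamp sufficient to
#' regenerate the artifact.
#'
#' @param path Artifact path; the sidecar is written at `<path>.prov.json`.
#' @param cfg An `experiment_config` (or any list with `config_hash` and
#'   `seed`).
#' @param extra Optional named list of extra fields.
#' @return Sidecar path, invisibly.
#' @export
write_sidecar <- function(path, cfg, extra = list()) {
  side <- c(list(config_hash = cfg$config_hash, seed = cfg$seed,
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 artifact = basename(path)), extra)
  out <- paste0(path, ".prov.json")
  jsonlite::write_json(side, out, auto_unbox = TRUE, digits = NA)
  invisible(out)
}
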