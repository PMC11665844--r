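#' Full run configuration
#'
#' Composes the model, loss, training and phantom configurations with the
#' data/output paths. Absent fields take the documented defaults (learning
#' rate 1e-4, batch size 4, 150 epochs, alpha = beta = 1, and so on).
#'
#' @param data_dir,output_dir paths used by the pipeline commands.
#' @param model,loss,train,phantom lists of arguments forwarded to
#'   [model_config()], [loss_config()], [train_config()], [phantom_config()].
#' @return a `run_config` list.
#' @export
run_config <- function(data_dir = ".", output_dir = ".",
                       model = list(), loss = list(), train = list(),
                       phantom = list()) {
  check_known_keys(model, names(formals(model_config)), "model")
  check_known_keys(loss, names(formals(loss_config)), "loss")
  check_known_keys(train, names(formals(train_config)), "train")
  check_known_keys(phantom, names(formals(phantom_config)), "phantom")
  structure(
    list(data_dir = data_dir, output_dir = output_dir,
         model = do.call(model_config, model),
         loss = do.call(loss_config, loss),
         train = do.call(train_config, train),
         phantom = do.call(phantom_config, phantom)),
    class = "run_config"
  )
}

check_known_keys <- function(x, known, where) {
  if (length(x) == 0L) return(invisible(NULL))
  if (is.null(names(x)) || any(names(x) == "")) {
    abort_value("all entries under `", where, "` must be named")
  }
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    abort_value("unknown key(s) under `", where, "`: ",
                paste(unknown, collapse = ", "))
  }
  invisible(NULL)
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected with the offending key named; missing keys take
#' the package defaults.
#'
#' @param path YAML (or JSON) configuration file.
#' @return a validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_value("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_top <- c("data_dir", "output_dir", "model", "loss", "train", "phantom")
  check_known_keys(raw, known_top, "top level")
  do.call(run_config, raw)
}

#' Serialise a run configuration to YAML
#'
#' `load_config(save_config(cfg, path))` round-trips to an equal
#' configuration.
#'
#' @param cfg a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  out <- list(
    data_dir = cfg$data_dir, output_dir = cfg$output_dir,
    model = unclass(cfg$model), loss = unclass(cfg$loss),
    train = unclass(cfg$train), phantom = unclass(cfg$phantom)
  )
  # drop NULLs (e.g. checkpoint_dir) so YAML stays clean
  out$train <- out$train[!vapply(out$train, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}
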