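#' Run configuration round-trip
#'
#' A run configuration merges the architecture flags, training
#' hyperparameters and synthetic-data settings into one structure that
#' round-trips losslessly through a YAML file, so a run is reproducible from
#' its config alone. Defaults are the package defaults everywhere.
#'
#' @param architecture list of \code{\link{ednet_config}} arguments.
#' @param training list of \code{\link{train_config}} arguments.
#' @param data list of \code{\link{synthetic_spec}} arguments (counts given
#'   as per-class named train/test lists).
#' @param weight_init_seed integer seed for weight initialization.
#' @return an object of class \code{"run_config"}.
#' @export
run_config <- function(architecture = list(), training = list(),
                       data = list(), weight_init_seed = 42L) {
  structure(list(architecture = architecture, training = training,
                 data = data,
                 weight_init_seed = as.integer(weight_init_seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a \code{"run_config"}.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(architecture = x$architecture %||% list(),
             training = x$training %||% list(),
             data = x$data %||% list(),
             weight_init_seed = x$weight_init_seed %||% 42L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# materialize the component configs from a run_config
instantiate_run <- function(rc) {
  data_args <- rc$data
  if (!is.null(data_args$counts) && !is.data.frame(data_args$counts)) {
    cc <- data_args$counts
    data_args$counts <- data.frame(class = names(cc$train),
                                   train = unlist(cc$train, use.names = FALSE),
                                   test = unlist(cc$test, use.names = FALSE),
                                   stringsAsFactors = FALSE)
  }
  list(architecture = do.call(ednet_config, rc$architecture),
       training = do.call(train_config, rc$training),
       data = do.call(synthetic_spec, data_args),
       weight_init_seed = rc$weight_init_seed)
}
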