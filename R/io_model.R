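.MODEL_FORMAT <- "scloc-n1nn"
.MODEL_VERSION <- 1L

#' Save and load network models
#'
#' A model file holds the full configuration, every weight and bias array
#' bit-exactly, and optional metadata (e.g. the validation score of a
#' checkpoint). Files embed a format and version tag; loading a file with a
#' different tag fails.
#'
#' @param params an `n1nn_params` object.
#' @param config the `n1nn_config` the parameters were built for.
#' @param path file path.
#' @param meta optional named list of metadata stored verbatim (epoch,
#'   validation accuracy, ...).
#' @return `save_model()`: `path`, invisibly. `load_model()`: a list with
#'   elements `params`, `config`, `meta`.
#' @export
save_model <- function(params, config, path, meta = list()) {
  stopifnot(inherits(params, "n1nn_params"), inherits(config, "n1nn_config"))
  obj <- list(format = .MODEL_FORMAT, version = .MODEL_VERSION,
              config = config, params = params, meta = meta)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("truncated or unreadable model file '",
                                           path, "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, .MODEL_FORMAT)) {
    stop("'", path, "' is not a ", .MODEL_FORMAT, " model file")
  }
  if (!identical(obj$version, .MODEL_VERSION)) {
    stop("model file '", path, "' has format version ", obj$version,
         "; this build reads version ", .MODEL_VERSION)
  }
  obj[c("params", "config", "meta")]
}
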