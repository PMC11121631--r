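#' Build an ensemble from selected checkpoints
#'
#' Flattens per-configuration lists of selected checkpoints into one
#' ensemble. The canonical predictor combines the 6 best checkpoints from
#' each of 4 configurations into 24 members; any non-degenerate combination
#' is allowed as long as all members predict the same classes. Duplicate
#' members (identical parameters) are rejected.
#'
#' @param selected either a list of `list(config =, checkpoints =)` entries
#'   (one per configuration), or a single configuration's
#'   `list(config =, checkpoints =)`.
#' @return list of class `n1nn_ensemble` with `members`, each
#'   `list(config, params, meta)`.
#' @export
build_ensemble <- function(selected) {
  if (!is.null(selected$config)) selected <- list(selected)
  members <- list()
  for (entry in selected) {
    cfg <- entry$config
    cks <- entry$checkpoints
    if (is.null(cfg) || length(cks) == 0) {
      stop("each entry must provide a config and a non-empty checkpoint list")
    }
    for (ck in cks) {
      members[[length(members) + 1L]] <- list(
        config = cfg, params = ck$params,
        meta = list(epoch = ck$epoch,
                    validation_accuracy = ck$validation_accuracy))
    }
  }
  ncls <- vapply(members, function(m) m$config$n_classes, integer(1))
  if (length(unique(ncls)) != 1) {
    stop("all ensemble members must share n_classes; found: ",
         paste(unique(ncls), collapse = ", "))
  }
  sigs <- vapply(members, function(m) param_signature(m$params), numeric(1))
  if (anyDuplicated(sigs)) {
    stop("duplicate checkpoint(s) in ensemble (identical parameters)")
  }
  structure(list(members = members), class = "n1nn_ensemble")
}

#' @export
print.n1nn_ensemble <- function(x, ...) {
  cat("n1nn_ensemble with", length(x$members), "member(s)\n")
  invisible(x)
}

#' Predict with an ensemble
#'
#' Each member produces a class-probability vector; the ensemble output is
#' their unweighted element-wise mean (`rule = "mean"`) or a majority vote
#' over member argmax calls (`rule = "vote"`, reported as vote fractions).
#' The predicted class is the argmax with lowest-index tie-break.
#'
#' @param ensemble an `n1nn_ensemble`.
#' @param x N x D input matrix.
#' @param rule `"mean"` (default) or `"vote"`.
#' @return list with `probs` (named length-8 vector) and `class`.
#' @export
ensemble_predict <- function(ensemble, x, rule = c("mean", "vote")) {
  stopifnot(inherits(ensemble, "n1nn_ensemble"))
  rule <- match.arg(rule)
  P <- vapply(ensemble$members, function(m) {
    n1nn_forward(m$params, m$config, x)$probs
  }, numeric(ensemble$members[[1]]$config$n_classes))
  probs <- if (rule == "mean") {
    rowMeans(P)
  } else {
    votes <- tabulate(apply(P, 2, which.max), nbins = nrow(P))
    votes / sum(votes)
  }
  cls <- .CLASSES[which.max(probs)]
  list(probs = stats::setNames(probs, .CLASSES[seq_along(probs)]), class = cls)
}

#' Predict an encoded dataset with an ensemble
#'
#' @param ensemble an `n1nn_ensemble`.
#' @param xs named list of input matrices (e.g. from [encode_dataset()]).
#' @param rule combination rule, see [ensemble_predict()].
#' @return list with `probs` (matrix, one row per input) and `class`
#'   (character vector of calls).
#' @export
ensemble_predict_all <- function(ensemble, xs, rule = "mean") {
  res <- lapply(xs, function(x) ensemble_predict(ensemble, x, rule))
  probs <- do.call(rbind, lapply(res, `[[`, "probs"))
  rownames(probs) <- names(xs)
  list(probs = probs, class = vapply(res, `[[`, "", "class"))
}

#' Save / load an ensemble as a manifest plus member model files
#'
#' `save_ensemble()` writes each member with [save_model()] into `dir` and a
#' JSON manifest listing the member files. `load_ensemble()` reads the
#' manifest back into an `n1nn_ensemble`.
#'
#' @param ensemble an `n1nn_ensemble`.
#' @param dir directory for the manifest (`manifest.json`) and member files.
#' @return `save_ensemble()`: the manifest path, invisibly;
#'   `load_ensemble()`: an `n1nn_ensemble`.
#' @export
save_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "n1nn_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(ensemble$members))
  for (i in seq_along(ensemble$members)) {
    m <- ensemble$members[[i]]
    files[i] <- sprintf("member_%03d.rds", i)
    save_model(m$params, m$config, file.path(dir, files[i]), meta = m$meta)
  }
  manifest <- list(format = "scloc-ensemble", version = 1L, members = files)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_ensemble
#' @param manifest path to a `manifest.json` written by `save_ensemble()`.
#' @export
load_ensemble <- function(manifest) {
  man <- jsonlite::read_json(manifest)
  if (!identical(man$format, "scloc-ensemble")) {
    stop("'", manifest, "' is not an scloc ensemble manifest")
  }
  dir <- dirname(manifest)
  members <- lapply(man$members, function(f) {
    mod <- load_model(file.path(dir, f))
    list(config = mod$config, params = mod$params, meta = mod$meta)
  })
  structure(list(members = members), class = "n1nn_ensemble")
}
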