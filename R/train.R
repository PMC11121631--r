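#' Training configuration
#'
#' Per-example stochastic gradient descent with a constant learning rate.
#' Every `checkpoint_every` epochs the model is scored on the validation set
#' and a checkpoint (parameters + validation accuracy) is recorded, so a run
#' of `total_epochs` produces exactly `total_epochs / checkpoint_every`
#' checkpoints; the default 5000/10 yields 500. Minibatching, momentum and
#' weight decay are exposed with inert defaults (batch 1, 0, 0).
#'
#' @param learning_rate constant step size (default 0.015; useful range
#'   roughly 0.01-0.02).
#' @param total_epochs number of passes over the training set (default 5000).
#' @param checkpoint_every validate and checkpoint every this many epochs
#'   (default 10); must divide `total_epochs`.
#' @param seed integer seed controlling initialization and the per-epoch
#'   shuffles.
#' @param batch_size examples per gradient step (default 1 = pure SGD).
#' @param momentum,weight_decay optional SGD extras, inert by default.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.015, total_epochs = 5000L,
                         checkpoint_every = 10L, seed = 1L,
                         batch_size = 1L, momentum = 0, weight_decay = 0) {
  tc <- list(learning_rate = learning_rate,
             total_epochs = as.integer(total_epochs),
             checkpoint_every = as.integer(checkpoint_every),
             seed = as.integer(seed), batch_size = as.integer(batch_size),
             momentum = momentum, weight_decay = weight_decay)
  if (tc$total_epochs < 1 || tc$checkpoint_every < 1) {
    stop("total_epochs and checkpoint_every must be positive")
  }
  if (tc$total_epochs %% tc$checkpoint_every != 0) {
    stop("checkpoint_every (", tc$checkpoint_every,
         ") must divide total_epochs (", tc$total_epochs, ")")
  }
  class(tc) <- "train_config"
  tc
}

grad_axpy <- function(params, grads, scale) {
  params$input <- Map(function(p, g) p - scale * g, params$input, grads$input)
  if (length(params$hidden)) {
    params$hidden <- Map(function(pl, gl) {
      Map(function(p, g) p - scale * g, pl, gl)
    }, params$hidden, grads$hidden)
  }
  params$fc <- Map(function(p, g) p - scale * g, params$fc, grads$fc)
  class(params) <- "n1nn_params"
  params
}

# v <- mom * v + g, applied leaf-wise; returns list(v = updated velocity).
velocity_update <- function(vel, grads, mom) {
  upd <- function(v, g) mom * v + g
  vel$input <- Map(upd, vel$input, grads$input)
  if (length(vel$hidden)) {
    vel$hidden <- Map(function(vl, gl) Map(upd, vl, gl),
                      vel$hidden, grads$hidden)
  }
  vel$fc <- Map(upd, vel$fc, grads$fc)
  vel
}

zero_like <- function(params) {
  z <- function(p) p * 0
  list(input = lapply(params$input, z),
       hidden = lapply(params$hidden, function(l) lapply(l, z)),
       fc = lapply(params$fc, z))
}

scale_grads <- function(grads, s) {
  list(input = lapply(grads$input, function(g) g * s),
       hidden = lapply(grads$hidden, function(l) lapply(l, function(g) g * s)),
       fc = lapply(grads$fc, function(g) g * s))
}

#' Accuracy of a single model on an encoded labeled set
#'
#' Fraction of examples whose argmax class (lowest index on ties) matches the
#' target — the overall accuracy Q used to score checkpoints.
#'
#' @param params,config model to evaluate.
#' @param dataset encoded labeled set from [encode_labeled()].
#' @return accuracy in `[0, 1]`.
#' @export
model_accuracy <- function(params, config, dataset) {
  preds <- vapply(dataset$x, function(x) {
    which.max(n1nn_forward(params, config, x)$probs)
  }, integer(1))
  mean(preds == dataset$y)
}

#' Train an N-to-1 network by stochastic gradient descent
#'
#' Minimizes the cross-entropy of the softmax output against the one-hot
#' target, one example at a time, reshuffling the training set every epoch.
#' Every `checkpoint_every` epochs the validation accuracy is measured and a
#' checkpoint (epoch, full parameter snapshot, validation accuracy, mean
#' training loss of the epoch) is appended. Fully reproducible from
#' `tconfig$seed`.
#'
#' @param config an `n1nn_config`.
#' @param tconfig a [train_config()].
#' @param train,valid encoded labeled sets from [encode_labeled()].
#' @param init optional `n1nn_params` to start from (default: fresh
#'   initialization from the seed).
#' @param verbose print progress every checkpoint.
#' @return list of checkpoints (class `n1nn_checkpoints`); each checkpoint
#'   has `epoch`, `params`, `validation_accuracy`, `train_loss`.
#' @export
sgd_train <- function(config, tconfig, train, valid, init = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(config, "n1nn_config"), inherits(tconfig, "train_config"))
  if (length(train$x) == 0 || length(valid$x) == 0) {
    stop("train and valid sets must be non-empty")
  }
  params <- if (is.null(init)) init_params(config, seed = tconfig$seed) else init
  n_train <- length(train$x)
  checkpoints <- vector("list", tconfig$total_epochs %/% tconfig$checkpoint_every)
  ci <- 0L
  lr <- tconfig$learning_rate
  mom <- tconfig$momentum
  vel <- if (mom > 0) zero_like(params) else NULL
  bs <- max(1L, tconfig$batch_size)
  with_seed(derive_seed(tconfig$seed, "shuffle"), {
    for (epoch in seq_len(tconfig$total_epochs)) {
      ord <- sample.int(n_train)
      epoch_loss <- 0
      for (start in seq(1L, n_train, by = bs)) {
        batch <- ord[start:min(start + bs - 1L, n_train)]
        acc_g <- NULL
        for (i in batch) {
          tr <- n1nn_forward(params, config, train$x[[i]])
          l <- n1nn_loss(tr, train$y[i])
          if (!is.finite(l)) {
            stop("non-finite training loss at epoch ", epoch, ", example '",
                 train$ids[i], "'")
          }
          epoch_loss <- epoch_loss + l
          g <- n1nn_backward(params, config, tr, train$y[i])
          acc_g <- if (is.null(acc_g)) g else velocity_update(acc_g, g, 1)
        }
        if (length(batch) > 1L) {
          acc_g <- scale_grads(acc_g, 1 / length(batch))
        }
        if (tconfig$weight_decay > 0) {
          params <- grad_axpy(params, params, lr * tconfig$weight_decay)
        }
        if (mom > 0) {
          vel <- velocity_update(vel, acc_g, mom)
          params <- grad_axpy(params, vel, lr)
        } else {
          params <- grad_axpy(params, acc_g, lr)
        }
      }
      if (epoch %% tconfig$checkpoint_every == 0L) {
        ci <- ci + 1L
        acc <- model_accuracy(params, config, valid)
        checkpoints[[ci]] <- structure(
          list(epoch = epoch, params = params,
               validation_accuracy = acc,
               train_loss = epoch_loss / n_train),
          class = "n1nn_checkpoint")
        if (verbose) {
          message(sprintf("epoch %d: train loss %.4f, valid acc %.3f",
                          epoch, epoch_loss / n_train, acc))
        }
      }
    }
  })
  structure(checkpoints, class = "n1nn_checkpoints")
}

#' Select the best checkpoints by validation accuracy
#'
#' Returns the `n` checkpoints with the highest validation accuracy, ties
#' broken in favor of the earlier epoch, ordered by descending accuracy.
#'
#' @param checkpoints list of checkpoints from [sgd_train()].
#' @param n how many to keep (default 6).
#' @return list of `n` checkpoints.
#' @export
select_best <- function(checkpoints, n = 6L) {
  n <- as.integer(n)
  if (n > length(checkpoints)) {
    stop("requested ", n, " checkpoints but only ", length(checkpoints),
         " are available")
  }
  acc <- vapply(checkpoints, function(ck) ck$validation_accuracy, numeric(1))
  ep <- vapply(checkpoints, function(ck) ck$epoch, numeric(1))
  ord <- order(-acc, ep)
  out <- checkpoints[ord[seq_len(n)]]
  class(out) <- "n1nn_checkpoints"
  out
}

#' Grid search over network configurations
#'
#' Trains each `(n1nn_config, train_config)` cell independently (each with
#' its own seed) and reports the best checkpoint validation accuracy per
#' cell — an accuracy-versus-(semi-context, depth) table. A failing cell is
#' recorded and the grid continues.
#'
#' @param grid list of `list(config =, tconfig =)` cells.
#' @param train,valid encoded labeled sets.
#' @return list with `table` (data frame: gamma, k, hidden_layers,
#'   best_accuracy, best_epoch, error) and `checkpoints` (per-cell list of
#'   all checkpoints, `NULL` for failed cells).
#' @export
grid_search <- function(grid, train, valid) {
  if (length(grid) == 0) stop("grid must be non-empty")
  rows <- vector("list", length(grid))
  cks <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cfg <- grid[[i]]$config; tc <- grid[[i]]$tconfig
    res <- tryCatch({
      ck <- sgd_train(cfg, tc, train, valid)
      best <- select_best(ck, 1L)[[1]]
      cks[[i]] <- ck
      data.frame(gamma = cfg$gamma, k = cfg$k,
                 hidden_layers = n_hidden_layers(cfg),
                 best_accuracy = best$validation_accuracy,
                 best_epoch = best$epoch, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(gamma = cfg$gamma, k = cfg$k,
                 hidden_layers = n_hidden_layers(cfg),
                 best_accuracy = NA_real_, best_epoch = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  list(table = do.call(rbind, rows), checkpoints = cks)
}
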