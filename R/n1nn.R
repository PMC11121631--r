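#' N-to-1 network configuration
#'
#' An N-to-1 convolutional network maps a variable-length sequence (N
#' positions, each a `input_width`-dimensional encoding vector) to a single
#' 8-class probability vector. The architecture is: an input kernel reading a
#' window of `2c+1` positions, a stack of `k` hidden-to-hidden kernels each
#' reading `2*gamma+1` consecutive state vectors, element-wise average
#' pooling over all positions, and a fully connected classifier. Every
#' kernel is itself a two-layer feed-forward network (a windowed layer
#' followed by a kernel of size 1), with sigmoid non-linearities throughout
#' and a softmax output.
#'
#' With no hidden-to-hidden kernel (`k = 0`) the network has 3 hidden layers
#' (two in the input kernel plus the fully connected hidden layer); each
#' additional kernel adds 2, giving `3 + 2k` in total.
#'
#' @param c input semi-context: the input kernel reads `2c+1` residues.
#' @param gamma hidden semi-context: hidden kernels read `2*gamma+1` states.
#' @param k number of hidden-to-hidden kernels (0 or more).
#' @param input_width encoding width D per position (22 for profiles /
#'   harmonized one-hot, 21 for raw one-hot).
#' @param kernel_hidden_units width H of each kernel's internal layer.
#' @param state_units width S of the intermediate state vectors.
#' @param fc_hidden_units width F of the fully connected hidden layer.
#' @param n_classes number of output classes (8, frozen).
#' @return list of class `n1nn_config`.
#' @export
n1nn_config <- function(c = 5L, gamma = 1L, k = 1L, input_width = 22L,
                        kernel_hidden_units = 12L, state_units = 8L,
                        fc_hidden_units = 12L, n_classes = 8L) {
  cfg <- list(c = as.integer(c), gamma = as.integer(gamma), k = as.integer(k),
              input_width = as.integer(input_width),
              kernel_hidden_units = as.integer(kernel_hidden_units),
              state_units = as.integer(state_units),
              fc_hidden_units = as.integer(fc_hidden_units),
              n_classes = as.integer(n_classes))
  if (cfg$c < 0 || cfg$gamma < 0 || cfg$k < 0) {
    stop("semi-contexts c, gamma and kernel count k must be non-negative")
  }
  if (any(unlist(cfg[c("input_width", "kernel_hidden_units", "state_units",
                       "fc_hidden_units", "n_classes")]) < 1)) {
    stop("all layer widths must be at least 1")
  }
  class(cfg) <- "n1nn_config"
  cfg
}

#' @export
print.n1nn_config <- function(x, ...) {
  cat("n1nn_config: input window ", 2 * x$c + 1, " x D=", x$input_width,
      " -> H=", x$kernel_hidden_units, " -> S=", x$state_units,
      "; ", x$k, " hidden kernel(s) (window ", 2 * x$gamma + 1,
      "); FC ", x$fc_hidden_units, " -> ", x$n_classes,
      " classes; ", n_hidden_layers(x), " hidden layers\n", sep = "")
  invisible(x)
}

#' Hidden-layer count of a configuration
#'
#' Two layers in the input kernel, two per hidden-to-hidden kernel, one
#' fully connected hidden layer: `3 + 2k`.
#'
#' @param config an `n1nn_config`.
#' @return integer hidden-layer count.
#' @export
n_hidden_layers <- function(config) {
  stopifnot(inherits(config, "n1nn_config"))
  3L + 2L * config$k
}

# Windowing: row i of the result is the concatenation of rows
# (i-w)..(i+w) of X, with zero rows beyond either end.
window_stack <- function(X, w) {
  if (w == 0L) return(X)
  N <- nrow(X); D <- ncol(X)
  Xpad <- rbind(matrix(0, w, D), X, matrix(0, w, D))
  out <- matrix(0, N, (2L * w + 1L) * D)
  for (j in seq_len(2L * w + 1L)) {
    out[, ((j - 1L) * D + 1L):(j * D)] <- Xpad[j:(j + N - 1L), , drop = FALSE]
  }
  out
}

# Adjoint of window_stack: scatter window-gradient blocks back onto
# positions. Gradients that fall on padding are discarded.
window_unstack <- function(dXw, w, D) {
  N <- nrow(dXw)
  if (w == 0L) return(dXw)
  dXpad <- matrix(0, N + 2L * w, D)
  for (j in seq_len(2L * w + 1L)) {
    rows <- j:(j + N - 1L)
    dXpad[rows, ] <- dXpad[rows, ] + dXw[, ((j - 1L) * D + 1L):(j * D)]
  }
  dXpad[(w + 1L):(w + N), , drop = FALSE]
}

#' Initialize network parameters
#'
#' Weights are drawn uniformly in `[-r, r]` with
#' `r = sqrt(6 / (fan_in + fan_out))` per weight matrix; biases start at
#' zero. Fully reproducible from the seed.
#'
#' For the input kernel's windowed layer the fan-in is taken as the number
#' of *simultaneously active* inputs, `2c + 1`: each window position is a
#' one-hot (or clipped-profile) row carrying unit mass on essentially one of
#' its D columns, so the nominal `(2c+1) * D` fan-in overstates the input
#' scale by a factor of D and would leave first-layer pre-activations an
#' order of magnitude too small to train efficiently. All dense layers use
#' their full fan-in.
#'
#' @param config an `n1nn_config`.
#' @param seed integer RNG seed.
#' @return list of class `n1nn_params` with elements `input`, `hidden`
#'   (list of length `k`) and `fc`, each holding `W1`, `b1`, `W2`, `b2`.
#' @export
init_params <- function(config, seed = 1L) {
  stopifnot(inherits(config, "n1nn_config"))
  D <- config$input_width; H <- config$kernel_hidden_units
  S <- config$state_units; Fc <- config$fc_hidden_units
  C <- config$n_classes
  glorot <- function(n_in, n_out, fan_in = n_in) {
    r <- sqrt(6 / (fan_in + n_out))
    matrix(stats::runif(n_in * n_out, -r, r), n_in, n_out)
  }
  win <- 2L * config$c + 1L
  params <- with_seed(seed, {
    list(
      input = list(W1 = glorot(win * D, H, fan_in = win), b1 = numeric(H),
                   W2 = glorot(H, S), b2 = numeric(S)),
      hidden = lapply(seq_len(config$k), function(i) {
        n_in <- (2L * config$gamma + 1L) * S
        list(W1 = glorot(n_in, H), b1 = numeric(H),
             W2 = glorot(H, S), b2 = numeric(S))
      }),
      fc = list(W1 = glorot(S, Fc), b1 = numeric(Fc),
                W2 = glorot(Fc, C), b2 = numeric(C))
    )
  })
  class(params) <- "n1nn_params"
  params
}

param_signature <- function(params) {
  sum(params$input$W1) + sum(params$fc$W2) +
    if (length(params$hidden)) sum(params$hidden[[1]]$W1) else 0
}

kernel_forward <- function(In, w, lay) {
  Inw <- window_stack(In, w)
  A <- sigmoid(add_bias(Inw %*% lay$W1, lay$b1))
  Out <- sigmoid(add_bias(A %*% lay$W2, lay$b2))
  list(Inw = Inw, A = A, Out = Out)
}

#' Forward pass of the N-to-1 network
#'
#' Applies the input kernel at every position (zero-vector padding beyond the
#' sequence ends), then each hidden kernel, averages the last kernel's
#' per-position outputs element-wise into one vector, and classifies it with
#' the fully connected network (sigmoid hidden layer, softmax output). The
#' returned trace keeps every intermediate activation for backpropagation.
#'
#' @param params an `n1nn_params` object.
#' @param config the matching `n1nn_config`.
#' @param x N x D input matrix (one row per residue position).
#' @return list of class `n1nn_trace` with `probs` (length-8 probability
#'   vector) and the cached activations.
#' @export
n1nn_forward <- function(params, config, x) {
  stopifnot(inherits(params, "n1nn_params"), inherits(config, "n1nn_config"))
  x <- as.matrix(x)
  if (ncol(x) != config$input_width) {
    stop("input width ", ncol(x), " does not match config input_width ",
         config$input_width)
  }
  if (nrow(x) < 1) stop("input must have at least one position")
  inp <- kernel_forward(x, config$c, params$input)
  states <- inp$Out
  hidden <- vector("list", config$k)
  for (j in seq_len(config$k)) {
    hidden[[j]] <- kernel_forward(states, config$gamma, params$hidden[[j]])
    states <- hidden[[j]]$Out
  }
  v <- colMeans(states)
  f <- drop(sigmoid(crossprod(params$fc$W1, v) + params$fc$b1))
  logits <- drop(f %*% params$fc$W2) + params$fc$b2
  e <- exp(logits - max(logits))
  probs <- e / sum(e)
  structure(list(x = x, input = inp, hidden = hidden, v = v, f = f,
                 probs = unname(probs), sig = param_signature(params)),
            class = "n1nn_trace")
}

.scloc_env <- new.env(parent = emptyenv())
.scloc_env$clamp_count <- 0L

#' Cross-entropy loss of a forward trace
#'
#' The relative entropy between a one-hot target and the predicted class
#' distribution reduces to `-log p[target]`. Probabilities below 1e-12 are
#' clamped (a package-level counter, [loss_clamp_count()], records how often).
#'
#' @param trace an `n1nn_trace` from [n1nn_forward()].
#' @param target canonical class name, or a 1-based integer class index.
#' @return non-negative scalar loss.
#' @export
n1nn_loss <- function(trace, target) {
  stopifnot(inherits(trace, "n1nn_trace"))
  t_idx <- if (is.character(target)) class_index(target) + 1L else as.integer(target)
  p <- trace$probs[t_idx]
  if (p < 1e-12) {
    .scloc_env$clamp_count <- .scloc_env$clamp_count + 1L
    p <- 1e-12
  }
  -log(p)
}

#' @rdname n1nn_loss
#' @export
loss_clamp_count <- function() .scloc_env$clamp_count

kernel_backward <- function(fwd, lay, dOut, w, D_in, need_dIn = TRUE) {
  dZ2 <- dOut * fwd$Out * (1 - fwd$Out)
  gW2 <- crossprod(fwd$A, dZ2)
  gb2 <- colSums(dZ2)
  dA <- dZ2 %*% t(lay$W2)
  dZ1 <- dA * fwd$A * (1 - fwd$A)
  gW1 <- crossprod(fwd$Inw, dZ1)
  gb1 <- colSums(dZ1)
  dIn <- if (need_dIn) window_unstack(dZ1 %*% t(lay$W1), w, D_in) else NULL
  list(grad = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2), dIn = dIn)
}

#' Exact analytic gradient of the loss
#'
#' Backpropagates the cross-entropy loss through the fully connected
#' network, the average pooling (distributing a factor 1/N to every
#' position), each hidden kernel and the input kernel. The returned
#' structure is congruent to `n1nn_params`.
#'
#' @param params the `n1nn_params` used to produce `trace`.
#' @param config the matching `n1nn_config`.
#' @param trace the `n1nn_trace` from [n1nn_forward()] on these params.
#' @param target canonical class name or 1-based integer class index.
#' @return list with the same shape as `params`, holding gradients.
#' @export
n1nn_backward <- function(params, config, trace, target) {
  stopifnot(inherits(trace, "n1nn_trace"))
  if (!isTRUE(all.equal(trace$sig, param_signature(params), tolerance = 0))) {
    stop("trace was not produced by these parameters (stale trace)")
  }
  t_idx <- if (is.character(target)) class_index(target) + 1L else as.integer(target)
  N <- nrow(trace$x)
  S <- config$state_units
  # softmax + cross-entropy
  dlogits <- trace$probs
  dlogits[t_idx] <- dlogits[t_idx] - 1
  f <- trace$f; v <- trace$v
  g_fc <- list(W1 = NULL, b1 = NULL, W2 = outer(f, dlogits), b2 = dlogits)
  df <- drop(params$fc$W2 %*% dlogits)
  dzf <- df * f * (1 - f)
  g_fc$W1 <- outer(v, dzf)
  g_fc$b1 <- dzf
  dv <- drop(params$fc$W1 %*% dzf)
  # average pooling: every position receives dv / N
  dStates <- matrix(dv / N, N, S, byrow = TRUE)
  g_hidden <- vector("list", config$k)
  for (j in rev(seq_len(config$k))) {
    bk <- kernel_backward(trace$hidden[[j]], params$hidden[[j]], dStates,
                          config$gamma, S, need_dIn = TRUE)
    g_hidden[[j]] <- bk$grad
    dStates <- bk$dIn
  }
  bk_in <- kernel_backward(trace$input, params$input, dStates, config$c,
                           config$input_width, need_dIn = FALSE)
  structure(list(input = bk_in$grad, hidden = g_hidden, fc = g_fc),
            class = "n1nn_grad")
}

#' Predict class probabilities for one input matrix
#'
#' @inheritParams n1nn_forward
#' @return named length-8 probability vector in frozen class order.
#' @export
predict_proba <- function(params, config, x) {
  p <- n1nn_forward(params, config, x)$probs
  stats::setNames(p, .CLASSES[seq_along(p)])
}
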