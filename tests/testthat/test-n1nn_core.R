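test_that("initialization is seed-deterministic with config-consistent shapes", {
  cfg <- tiny_config(c = 2, gamma = 1, k = 2)
  p1 <- init_params(cfg, seed = 99)
  p2 <- init_params(cfg, seed = 99)
  expect_identical(p1, p2)
  p3 <- init_params(cfg, seed = 100)
  expect_false(identical(p1, p3))

  D <- cfg$input_width; H <- cfg$kernel_hidden_units
  S <- cfg$state_units; Fc <- cfg$fc_hidden_units
  expect_equal(dim(p1$input$W1), c((2 * cfg$c + 1) * D, H))
  expect_equal(dim(p1$input$W2), c(H, S))
  expect_equal(length(p1$hidden), cfg$k)
  expect_equal(dim(p1$hidden[[1]]$W1), c((2 * cfg$gamma + 1) * S, H))
  expect_equal(dim(p1$hidden[[2]]$W2), c(H, S))
  expect_equal(dim(p1$fc$W1), c(S, Fc))
  expect_equal(dim(p1$fc$W2), c(Fc, 8L))
  expect_equal(p1$input$b1, numeric(H))
})

test_that("hidden-layer accounting is 3 + 2k", {
  expect_equal(n_hidden_layers(tiny_config(k = 0)), 3L)
  expect_equal(n_hidden_layers(tiny_config(k = 1)), 5L)
  expect_equal(n_hidden_layers(tiny_config(k = 3)), 9L)
})

test_that("all-zero weights yield the uniform distribution over 8 classes", {
  cfg <- tiny_config()
  p <- constant_params(init_params(cfg, seed = 1), 0)
  tr <- n1nn_forward(p, cfg, random_input(25, seed = 3))
  expect_equal(tr$probs, rep(1 / 8, 8), tolerance = 1e-12)
})

test_that("output is a fixed-size simplex point for any input length", {
  cfg <- tiny_config(c = 2, gamma = 1, k = 1)
  p <- init_params(cfg, seed = 17)
  for (n in c(1L, 30L, 500L)) {
    pr <- n1nn_forward(p, cfg, random_input(n, seed = n))$probs
    expect_length(pr, 8L)
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    expect_true(all(pr > 0))
  }
})

test_that("with no context, pooling makes constant-row inputs length-invariant", {
  cfg <- tiny_config(c = 0, gamma = 0, k = 1)
  p <- init_params(cfg, seed = 23)
  row <- random_input(1, seed = 5)
  x1 <- row[rep(1, 40), ]
  x2 <- row[rep(1, 80), ]
  t1 <- n1nn_forward(p, cfg, x1)
  t2 <- n1nn_forward(p, cfg, x2)
  expect_equal(t1$v, t2$v, tolerance = 1e-12)
  expect_equal(t1$probs, t2$probs, tolerance = 1e-12)
})

test_that("the pooled vector is the element-wise mean over positions", {
  cfg <- tiny_config(c = 1, gamma = 2, k = 2)
  p <- init_params(cfg, seed = 31)
  tr <- n1nn_forward(p, cfg, random_input(13, seed = 7))
  last <- tr$hidden[[cfg$k]]$Out
  expect_equal(tr$v, colMeans(last), tolerance = 1e-12)
})

test_that("cross-entropy loss has its closed-form values and monotonicity", {
  cfg <- tiny_config()
  p <- constant_params(init_params(cfg, seed = 1), 0)
  tr <- n1nn_forward(p, cfg, random_input(10))
  expect_equal(n1nn_loss(tr, "Membrane"), log(8), tolerance = 1e-12)
  expect_equal(n1nn_loss(tr, 1L), log(8), tolerance = 1e-12)

  # loss decreases monotonically as p[target] rises
  fake <- tr
  losses <- vapply(c(0.1, 0.3, 0.6, 0.95), function(pt) {
    fake$probs <- c(pt, rep((1 - pt) / 7, 7))
    n1nn_loss(fake, 1L)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_config(c = 1, gamma = 1, k = 1, state_units = 3,
                     kernel_hidden_units = 4)
  p <- init_params(cfg, seed = 42)
  x <- random_input(7, seed = 11)
  target <- 3L
  g <- n1nn_backward(p, cfg, n1nn_forward(p, cfg, x), target)

  skeleton <- unclass(p)
  flat_p <- unlist(skeleton)
  flat_g <- unlist(unclass(g))
  expect_length(flat_g, length(flat_p))

  loss_at <- function(flat) {
    q <- utils::relist(flat, skeleton)
    class(q) <- "n1nn_params"
    n1nn_loss(n1nn_forward(q, cfg, x), target)
  }
  h <- 1e-5
  set.seed(1)
  idx <- sort(sample(length(flat_p), 60))  # all groups get sampled
  max_rel <- 0
  max_abs <- 0
  for (ii in idx) {
    up <- flat_p; up[ii] <- up[ii] + h
    dn <- flat_p; dn[ii] <- dn[ii] - h
    ng <- (loss_at(up) - loss_at(dn)) / (2 * h)
    scale <- max(abs(ng), abs(flat_g[ii]))
    if (scale >= 1e-4) {
      max_rel <- max(max_rel, abs(ng - flat_g[ii]) / scale)
    } else {
      max_abs <- max(max_abs, abs(ng - flat_g[ii]))
    }
  }
  expect_lt(max_rel, 1e-5)
  expect_lt(max_abs, 1e-8)
})

test_that("gradients vanish where the target probability is 1", {
  cfg <- tiny_config()
  p <- init_params(cfg, seed = 3)
  x <- random_input(6, seed = 1)
  tr <- n1nn_forward(p, cfg, x)
  tr$probs <- c(1, rep(0, 7))  # exact minimum of the loss for target 1
  g <- n1nn_backward(p, cfg, tr, 1L)
  expect_equal(max(abs(unlist(g$fc))), 0, tolerance = 1e-12)
})

test_that("a stale trace is rejected", {
  cfg <- tiny_config()
  p <- init_params(cfg, seed = 3)
  tr <- n1nn_forward(p, cfg, random_input(6))
  p2 <- init_params(cfg, seed = 4)
  expect_error(n1nn_backward(p2, cfg, tr, 1L), "stale")
})

test_that("width mismatches are rejected", {
  cfg <- tiny_config(input_width = 22)
  p <- init_params(cfg, seed = 3)
  expect_error(n1nn_forward(p, cfg, random_input(6, d = 21)), "width")
})
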