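test_that("the recurrent matrix hits the target spectral radius exactly", {
  for (s in 1:5) {
    m <- esn_init(n_inputs = 3, n_neurons = 40, spectral_radius = 0.9,
                  seed = s)
    rho <- max(Mod(eigen(m$W, only.values = TRUE)$values))
    expect_lt(abs(rho - 0.9), 1e-6)
  }
  m2 <- esn_init(3, 40, spectral_radius = 1.3, seed = 1)
  expect_lt(abs(max(Mod(eigen(m2$W, only.values = TRUE)$values)) - 1.3),
            1e-6)
})

test_that("density controls the nonzero count and seeds fix the draw", {
  full <- esn_init(2, 64, recurrent_density = 1, seed = 3)
  expect_identical(sum(full$W != 0), 64L * 64L)
  a <- esn_init(5, 30, seed = 11)
  b <- esn_init(5, 30, seed = 11)
  expect_identical(a$W, b$W)
  expect_identical(a$W_in, b$W_in)
  expect_false(identical(a$W, esn_init(5, 30, seed = 12)$W))
})

test_that("reservoir states follow the leaky-tanh recurrence", {
  m <- esn_init(2, 10, seed = 4)
  zero <- esn_states(m, matrix(0, 7, 2))
  expect_identical(zero, matrix(0, 7, 10))

  u1 <- matrix(c(1, 0), 1, 2)
  expect_equal(esn_states(m, u1)[1, ], tanh(m$W_in[, 1]))

  expect_error(esn_states(m, matrix(NA_real_, 3, 2)), "NA")
  expect_error(esn_states(m, matrix(0, 3, 5)), "channels")
})

test_that("states match a hand-rolled recurrence oracle step by step", {
  m <- esn_init(3, 5, leak_rate = 0.7, seed = 9)
  set.seed(21)
  u <- matrix(runif(60, -1, 1), 20, 3)
  x <- numeric(5)
  oracle <- matrix(0, 20, 5)
  for (t in 1:20) {
    x <- (1 - 0.7) * x + 0.7 * tanh(m$W %*% x + m$W_in %*% u[t, ])
    oracle[t, ] <- x
  }
  expect_lt(max(abs(esn_states(m, u) - oracle)), 1e-12)
})

test_that("the batched multi-sequence runner equals per-sequence runs", {
  m <- esn_init(4, 12, leak_rate = 0.8, seed = 2)
  set.seed(5)
  xs <- replicate(6, matrix(runif(4 * 15, -1, 1), 15, 4),
                  simplify = FALSE)
  batch <- tdsliking:::esn_states_batch(m, xs)
  for (s in seq_along(xs)) {
    expect_lt(max(abs(batch[, , s] - esn_states(m, xs[[s]]))), 1e-13)
  }
})

test_that("the ridge readout matches an independent QR-based oracle", {
  set.seed(8)
  xs <- replicate(4, matrix(runif(30 * 3, -1, 1), 30, 3),
                  simplify = FALSE)
  ys <- lapply(xs, function(u) as.numeric(u %*% c(2, -1, 3)) + rnorm(30))
  lambda <- 1e-3
  fit <- esn(xs, ys, n_neurons = 15, ridge = lambda, seed = 6)
  # oracle: augmented least squares [X; sqrt(l) I] \ [y; 0] solved by QR
  states <- do.call(rbind, lapply(xs, function(u) esn_states(fit, u)))
  X <- cbind(states, 1)
  Xa <- rbind(X, sqrt(lambda) * diag(ncol(X)))
  ya <- c(unlist(ys), numeric(ncol(X)))
  w_oracle <- qr.coef(qr(Xa), ya)
  expect_lt(max(abs(unname(coef(fit)) - w_oracle)), 1e-8)
})

test_that("targets linear in the states are interpolated exactly at full rank", {
  set.seed(14)
  u <- matrix(runif(200 * 2, -1, 1), 200, 2)
  m0 <- esn_init(2, 8, seed = 3)
  st <- esn_states(m0, u)
  beta <- rnorm(8)
  y <- as.numeric(st %*% beta) + 0.5
  fit <- esn(u, y, n_neurons = 8, ridge = 0, seed = 3)
  expect_lt(max(abs(fitted(fit) - y)), 1e-8)
  expect_lt(max(abs(residuals(fit))), 1e-8)
})

test_that("extreme shrinkage drives the readout to zero and lambda=0 can be singular", {
  set.seed(15)
  u <- matrix(runif(40, -1, 1), 20, 2)
  y <- rnorm(20)
  big <- esn(u, y, n_neurons = 6, ridge = 1e12, seed = 1)
  expect_lt(max(abs(coef(big))), 1e-6)
  # constant (zero) input leaves all states at zero -> singular at ridge 0
  expect_error(esn(matrix(0, 20, 2), y, n_neurons = 6, ridge = 0,
                   seed = 1),
               "ridge")
})

test_that("the pooled readout is invariant to training-sequence order", {
  set.seed(16)
  xs <- replicate(5, matrix(runif(45, -1, 1), 15, 3), simplify = FALSE)
  ys <- lapply(xs, function(u) as.numeric(u %*% c(1, 2, -1)))
  f1 <- esn(xs, ys, n_neurons = 10, seed = 4)
  f2 <- esn(rev(xs), rev(ys), n_neurons = 10, seed = 4)
  expect_lt(max(abs(f1$W_out - f2$W_out)), 1e-8)
})

test_that("a model trained on a constant target memorizes it", {
  u <- matrix(0.5, 30, 2)
  fit <- esn(list(u, u, u), list(rep(5, 30), rep(5, 30), rep(5, 30)),
             n_neurons = 20, seed = 7)
  expect_lt(max(abs(predict(fit, u) - 5)), 1e-3)
  expect_error(predict(esn_init(2, 20), u), "fitted")
})

test_that("predictions clip to the liking range only on request", {
  set.seed(30)
  u <- matrix(runif(60, -1, 1), 30, 2)
  fit <- esn(u, rnorm(30, 20, 1), n_neurons = 10, seed = 2)
  raw <- predict(fit, u)
  expect_gt(max(raw), 9)
  expect_lte(max(predict(fit, u, clip = TRUE)), 9)
})

test_that("trajectories from different initial states converge (echo state property)", {
  set.seed(17)
  for (s in 1:5) {
    m <- esn_init(3, 50, spectral_radius = 0.9, leak_rate = 1, seed = s)
    u <- matrix(runif(101 * 3), 101, 3)
    xa <- esn_states(m, u, x0 = runif(50, -1, 1))
    xb <- esn_states(m, u, x0 = runif(50, -1, 1))
    expect_lt(max(abs(xa[101, ] - xb[101, ])), 1e-6)
  }
})

test_that("a fitted model survives a JSON round trip", {
  set.seed(18)
  u <- matrix(runif(60, -1, 1), 20, 3)
  fit <- esn(u, rnorm(20), n_neurons = 12, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_esn(fit, path)
  back <- read_esn(path)
  expect_equal(back$W, fit$W)
  expect_equal(back$W_in, fit$W_in)
  expect_equal(back$W_out, fit$W_out)
  expect_equal(predict(back, u), predict(fit, u))
})

test_that("an ESN recovers a linear liking functional far better than a constant", {
  ds <- simulate_linear_tl(small_dataset(12), noise_sd = 0.3, seed = 3)
  ev <- evaluate_architecture(ds, n_neurons = 128, aux_config = "combo",
                              seed = 1)
  base <- evaluate_architecture(ds, predict_fun = constant_baseline())
  expect_lt(ev$pooled$median, 0.5 * base$pooled$median)
})
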