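#' Initialize an untrained echo state network
#'
#' Draws the fixed random weights of the reservoir: a sparse uniform
#' recurrent matrix rescaled so its spectral radius (largest eigenvalue
#' magnitude) equals `spectral_radius`, and a dense uniform input matrix in
#' `[-input_scaling, input_scaling]`. Only the linear readout is trained
#' later; the reservoir itself never changes.
#'
#' @param n_inputs Number of input channels.
#' @param n_neurons Reservoir size (the study compares 64, 128, 192, 256;
#'   any positive count is accepted).
#' @param spectral_radius Target spectral radius of the recurrent matrix
#'   (default 0.9, inside the echo-state regime).
#' @param leak_rate Leaky-integrator rate in (0, 1\] (default 1, plain tanh
#'   update).
#' @param input_scaling Half-width of the uniform input weights.
#' @param recurrent_density Fraction of nonzero recurrent weights.
#' @param input_density Fraction of nonzero input weights.
#' @param ridge Ridge penalty of the readout (applied to all coefficients,
#'   bias included).
#' @param washout Initial time steps of each sequence excluded from
#'   readout training (default 0: sequences are short and start from a
#'   common quiescent state).
#' @param seed Integer seed; identical seeds give identical weights.
#' @return An object of class `esn` with `fitted = FALSE`.
#' @export
esn_init <- function(n_inputs, n_neurons = 128L, spectral_radius = 0.9,
                     leak_rate = 1.0, input_scaling = 1.0,
                     recurrent_density = 0.1, input_density = 1.0,
                     ridge = 1e-6, washout = 0L, seed = 1L) {
  stopifnot(n_inputs >= 1, n_neurons >= 1, spectral_radius > 0,
            leak_rate > 0, leak_rate <= 1, input_scaling > 0,
            recurrent_density > 0, recurrent_density <= 1,
            input_density > 0, input_density <= 1, ridge >= 0,
            washout >= 0)
  n <- as.integer(n_neurons)
  sub_seed <- as.integer(seed)
  repeat {
    set.seed(sub_seed)
    W <- matrix(stats::runif(n * n, -1, 1), n, n) *
      (matrix(stats::runif(n * n), n, n) < recurrent_density)
    rho <- max(Mod(eigen(W, only.values = TRUE)$values))
    if (rho > 0) break
    # degenerate draw (can only happen at tiny size/density): redraw
    message("recurrent draw had zero spectral radius; redrawing")
    sub_seed <- sub_seed + 1L
  }
  W <- W * (spectral_radius / rho)
  W_in <- matrix(stats::runif(n * n_inputs, -input_scaling, input_scaling),
                 n, n_inputs) *
    (matrix(stats::runif(n * n_inputs), n, n_inputs) < input_density)
  structure(
    list(n_inputs = as.integer(n_inputs), n_neurons = n,
         spectral_radius = spectral_radius, leak_rate = leak_rate,
         input_scaling = input_scaling,
         recurrent_density = recurrent_density,
         input_density = input_density, ridge = ridge,
         washout = as.integer(washout), seed = as.integer(seed),
         W = W, W_in = W_in, W_out = NULL, fitted = FALSE),
    class = "esn"
  )
}

#' Run the reservoir over one input sequence
#'
#' Leaky-tanh state update from a zero initial state:
#' `x(t) = (1 - a) x(t-1) + a tanh(W x(t-1) + W_in u(t))`.
#' The state is reset to zero at the start of every sequence.
#'
#' @param model An `esn` (trained or not).
#' @param u Input matrix `[n_steps x n_inputs]`.
#' @param x0 Initial state (default zero).
#' @return State matrix `[n_steps x n_neurons]`.
#' @export
esn_states <- function(model, u, x0 = NULL) {
  stopifnot(inherits(model, "esn"))
  u <- as.matrix(u)
  if (ncol(u) != model$n_inputs) {
    stop("input has ", ncol(u), " channels; model expects ",
         model$n_inputs, call. = FALSE)
  }
  if (anyNA(u) || any(!is.finite(u))) {
    stop("input series contains NA or non-finite values", call. = FALSE)
  }
  a <- model$leak_rate
  x <- if (is.null(x0)) numeric(model$n_neurons) else as.numeric(x0)
  out <- matrix(0, nrow(u), model$n_neurons)
  for (t in seq_len(nrow(u))) {
    x <- (1 - a) * x +
      a * tanh(as.numeric(model$W %*% x) +
               as.numeric(model$W_in %*% u[t, ]))
    out[t, ] <- x
  }
  out
}

# run the reservoir over many equal-length sequences at once; returns an
# array [n_steps, n_neurons, n_sequences]
esn_states_batch <- function(model, u_list) {
  steps <- unique(vapply(u_list, nrow, 1L))
  stopifnot(length(steps) == 1)
  S <- length(u_list)
  a <- model$leak_rate
  # U[t][, s] = input of sequence s at step t
  U <- array(unlist(u_list, use.names = FALSE),
             dim = c(steps, model$n_inputs, S))
  X <- matrix(0, model$n_neurons, S)
  out <- array(0, dim = c(steps, model$n_neurons, S))
  for (t in seq_len(steps)) {
    X <- (1 - a) * X + a * tanh(model$W %*% X +
                                model$W_in %*% matrix(U[t, , ],
                                                      model$n_inputs, S))
    out[t, , ] <- X
  }
  out
}

# closed-form ridge readout on pooled [states, 1] rows
fit_readout <- function(states, targets, ridge) {
  X <- cbind(states, 1)
  if (nrow(X) < ncol(X)) {
    warning("fewer pooled training rows (", nrow(X),
            ") than readout coefficients (", ncol(X), ")", call. = FALSE)
  }
  A <- crossprod(X) + diag(ridge, ncol(X))
  b <- crossprod(X, targets)
  w <- tryCatch(solve(A, b), error = function(e) {
    if (ridge == 0) {
      stop("readout system is singular at ridge = 0; set ridge > 0",
           call. = FALSE)
    }
    stop(e)
  })
  as.numeric(w)
}

#' Fit an echo state network mapping input series to target curves
#'
#' The central fitting function: draws a fixed random reservoir
#' ([esn_init()]), drives it over every training sequence from a zero
#' initial state, pools the reservoir states (with a bias column) across
#' all sequences and time steps, and solves the ridge-regression readout
#' `min ||y - W_out [x; 1]||^2 + ridge ||W_out||^2` in closed form. The
#' readout is order-invariant in the training sequences.
#'
#' @param x A list of input matrices `[n_steps x n_inputs]` (e.g. from
#'   [encode_curve_set()]), or a single matrix.
#' @param y A list of numeric target curves matching `x` row counts, or a
#'   single vector.
#' @param ... Reservoir and readout hyperparameters passed to
#'   [esn_init()] (`n_neurons`, `spectral_radius`, `leak_rate`,
#'   `input_scaling`, `recurrent_density`, `input_density`, `ridge`,
#'   `washout`, `seed`).
#' @return A fitted object of class `esn`, with components `W_in`, `W`
#'   (fixed random weights), `W_out` (trained readout, last entry the
#'   bias) and training bookkeeping. Methods: [predict.esn()],
#'   [coef.esn()], [fitted.esn()], [residuals.esn()], [summary.esn()],
#'   [print.esn()].
#' @examples
#' set.seed(1)
#' xs <- replicate(5, matrix(runif(60), 20, 3), simplify = FALSE)
#' ys <- lapply(xs, function(m) m %*% c(1, -2, 0.5) + 3)
#' fit <- esn(xs, lapply(ys, as.numeric), n_neurons = 30, seed = 2)
#' fit
#' @export
esn <- function(x, y, ...) {
  if (is.matrix(x)) x <- list(x)
  if (is.numeric(y)) y <- list(y)
  stopifnot(length(x) >= 1, length(x) == length(y))
  x <- lapply(x, as.matrix)
  bad <- which(vapply(x, nrow, 1L) != lengths(y))
  if (length(bad)) {
    stop("sequence ", bad[1], ": input rows and target length differ",
         call. = FALSE)
  }
  model <- esn_init(n_inputs = ncol(x[[1]]), ...)
  steps <- vapply(x, nrow, 1L)
  keep <- lapply(steps, function(s) {
    if (model$washout > 0) seq.int(model$washout + 1L, s) else seq_len(s)
  })
  if (length(unique(steps)) == 1) {
    st <- esn_states_batch(model, x)[keep[[1]], , , drop = FALSE]
    # [steps, neurons, sequences] -> pooled rows, sequence-major
    states <- matrix(aperm(st, c(1, 3, 2)), ncol = model$n_neurons)
  } else {
    states <- do.call(rbind, lapply(seq_along(x), function(s) {
      esn_states(model, x[[s]])[keep[[s]], , drop = FALSE]
    }))
  }
  targets <- unlist(lapply(seq_along(y),
                           function(s) y[[s]][keep[[s]]]),
                    use.names = FALSE)
  model$W_out <- fit_readout(states, targets, model$ridge)
  model$fitted <- TRUE
  model$n_sequences <- length(x)
  model$channel_names <- colnames(x[[1]])
  fv <- as.numeric(cbind(states, 1) %*% model$W_out)
  model$fitted_values <- fv
  model$training_targets <- targets
  model$training_rmse <- sqrt(mean((targets - fv)^2))
  model
}

#' Predict target curves for new input series
#'
#' Runs the fitted reservoir over each new sequence (zero initial state)
#' and applies the linear readout. Predictions are raw by default; set
#' `clip` to constrain them to the 0--9 liking range.
#'
#' @param object A fitted `esn`.
#' @param newdata Input matrix or list of input matrices.
#' @param clip If `TRUE`, clip predictions to `[0, 9]`.
#' @param ... Unused.
#' @return A numeric vector (single matrix input) or list of numeric
#'   vectors.
#' @export
predict.esn <- function(object, newdata, clip = FALSE, ...) {
  if (!isTRUE(object$fitted)) {
    stop("model has not been fitted; call esn() first", call. = FALSE)
  }
  single <- is.matrix(newdata) || is.data.frame(newdata)
  if (single) newdata <- list(as.matrix(newdata))
  preds <- lapply(newdata, function(u) {
    st <- esn_states(object, u)
    p <- as.numeric(cbind(st, 1) %*% object$W_out)
    if (clip) pmin(pmax(p, 0), 9) else p
  })
  if (single) preds[[1]] else preds
}

#' Readout coefficients of a fitted ESN
#'
#' @param object A fitted `esn`.
#' @param ... Unused.
#' @return Named numeric vector: one weight per reservoir neuron plus
#'   `(bias)`.
#' @export
coef.esn <- function(object, ...) {
  if (is.null(object$W_out)) return(NULL)
  stats::setNames(object$W_out,
                  c(paste0("neuron", seq_len(object$n_neurons)), "(bias)"))
}

#' @rdname coef.esn
#' @export
fitted.esn <- function(object, ...) object$fitted_values

#' @rdname coef.esn
#' @export
residuals.esn <- function(object, ...) {
  object$training_targets - object$fitted_values
}

#' @export
print.esn <- function(x, ...) {
  cat("Echo state network",
      if (isTRUE(x$fitted)) "(fitted)" else "(untrained)", "\n")
  cat(sprintf("  reservoir: %d neurons, spectral radius %.3g, leak %.3g, density %.3g\n",
              x$n_neurons, x$spectral_radius, x$leak_rate,
              x$recurrent_density))
  cat(sprintf("  inputs:    %d channels\n", x$n_inputs))
  if (isTRUE(x$fitted)) {
    cat(sprintf("  readout:   ridge %.3g over %d sequences; training RMSE %.4f\n",
                x$ridge, x$n_sequences, x$training_rmse))
  }
  invisible(x)
}

#' @export
summary.esn <- function(object, ...) {
  structure(list(model = object), class = "summary.esn")
}

#' @export
print.summary.esn <- function(x, ...) {
  m <- x$model
  print(m)
  if (isTRUE(m$fitted)) {
    cat("  readout coefficient range: [",
        sprintf("%.4g", min(m$W_out)), ", ",
        sprintf("%.4g", max(m$W_out)), "]\n", sep = "")
    r <- residuals.esn(m)
    cat("  training residuals: ")
    print(summary(r))
  }
  invisible(x)
}

#' Plot training fit of an ESN
#'
#' Observed versus fitted training values, a quick adequacy check.
#'
#' @param x A fitted `esn`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.esn <- function(x, ...) {
  if (!isTRUE(x$fitted)) stop("nothing to plot: model is untrained",
                              call. = FALSE)
  graphics::plot(x$training_targets, x$fitted_values,
                 xlab = "observed", ylab = "fitted",
                 main = "ESN training fit", pch = ".", ...)
  graphics::abline(0, 1, col = "red")
  invisible(x)
}

#' Serialize an ESN to JSON
#'
#' Stores hyperparameters, the input weights, the recurrent weights in
#' triplet (row, column, value) layout and the readout, so a fitted model
#' round-trips through plain text.
#'
#' @param model An `esn`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_esn <- function(model, path) {
  stopifnot(inherits(model, "esn"))
  nz <- which(model$W != 0, arr.ind = TRUE)
  payload <- list(
    params = model[c("n_inputs", "n_neurons", "spectral_radius",
                     "leak_rate", "input_scaling", "recurrent_density",
                     "input_density", "ridge", "washout", "seed")],
    W_in = as.numeric(model$W_in),
    W_triplets = list(i = nz[, 1], j = nz[, 2],
                      x = model$W[nz]),
    W_out = model$W_out,
    fitted = isTRUE(model$fitted),
    channel_names = model$channel_names
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ESN written by [write_esn()]
#'
#' @param path File path.
#' @return An `esn` object.
#' @export
read_esn <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- p$params$n_neurons
  W <- matrix(0, n, n)
  W[cbind(p$W_triplets$i, p$W_triplets$j)] <- p$W_triplets$x
  model <- structure(
    c(p$params,
      list(W = W,
           W_in = matrix(p$W_in, n, p$params$n_inputs),
           W_out = if (length(p$W_out)) as.numeric(p$W_out) else NULL,
           fitted = isTRUE(p$fitted),
           channel_names = p$channel_names)),
    class = "esn"
  )
  model
}
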