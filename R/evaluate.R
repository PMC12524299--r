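#' RMSE between two curves on a shared grid
#'
#' Root mean squared error over grid points,
#' `sqrt(mean((predicted - observed)^2))`.
#'
#' @param predicted,observed Numeric vectors of equal length (or
#'   `curve_set`s, whose TL curves are compared).
#' @return Nonnegative scalar.
#' @examples
#' curve_rmse(c(1, 2, 3), c(2, 3, 4))  # 1
#' @export
curve_rmse <- function(predicted, observed) {
  if (inherits(predicted, "curve_set")) predicted <- predicted$tl
  if (inherits(observed, "curve_set")) observed <- observed$tl
  if (length(predicted) != length(observed)) {
    stop("curves are on different grids (lengths ", length(predicted),
         " vs ", length(observed), ")", call. = FALSE)
  }
  sqrt(mean((predicted - observed)^2))
}

#' Leave-one-pairing-out split of a curve-set collection
#'
#' Training uses every replicate of the seven other conditions (all four
#' single foods plus the three other pairings); testing uses the held-out
#' pairing's replicates. Only pairings may be held out: they are the
#' prediction targets.
#'
#' @param dataset Named list (by condition id) of lists of `curve_set`s.
#' @param held_out Condition id of the pairing to hold out.
#' @param conditions Condition table, as from [food_conditions()].
#' @return List with `train` (named list over the seven training
#'   conditions) and `test` (the held-out pairing's replicates).
#' @export
loco_split <- function(dataset, held_out, conditions = food_conditions()) {
  cond <- get_condition(held_out, conditions)
  if (!cond$is_pairing) {
    stop("held_out must be a pairing; '", held_out,
         "' is a single-item condition", call. = FALSE)
  }
  if (!held_out %in% names(dataset)) {
    stop("dataset has no replicates for condition '", held_out, "'",
         call. = FALSE)
  }
  list(train = dataset[setdiff(names(dataset), held_out)],
       test = dataset[[held_out]])
}

# type-7 median and quartiles of an RMSE vector
rmse_stats <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], values = v)
}

#' Evaluate one architecture by leave-one-pairing-out cross-validation
#'
#' For each pairing: initializes a fresh reservoir, trains the readout on
#' every replicate curve set of the seven other conditions (TDS channels
#' plus the configuration's auxiliary flags as input, the TL curve as
#' target), predicts the TL curve of each held-out replicate from its TDS
#' curves, and records the per-replicate RMSE. Reports per-pairing and
#' pooled median and interquartile range.
#'
#' @param dataset Named list (by condition) of lists of `curve_set`s,
#'   e.g. bootstrap replicates from [bootstrap_panel()].
#' @param n_neurons Reservoir size.
#' @param aux_config Auxiliary flag configuration name (see
#'   [aux_config_names]) or an [encoding_config()].
#' @param conditions Condition table.
#' @param seed Integer seed for the reservoir draw (offset per pairing).
#' @param clip Clip predictions to \[0, 9\] before scoring (default off;
#'   RMSE is computed on raw predictions).
#' @param pooling `"pooled"`: the headline statistic is the median (and
#'   IQR) of the concatenated RMSE values of all pairings;
#'   `"median_of_medians"`: the median of the four per-pairing medians.
#' @param predict_fun Optional stub replacing the ESN: a
#'   `function(train, test)` receiving lists with elements `x`
#'   (encoded inputs) and `y` (observed TL curves), returning a list of
#'   predicted curves for `test`. Used for baselines and oracle checks.
#' @param ... Further hyperparameters for [esn()].
#' @return An object of class `esn_eval`.
#' @export
evaluate_architecture <- function(dataset, n_neurons = 128L,
                                  aux_config = "combo",
                                  conditions = food_conditions(),
                                  seed = 1L, clip = FALSE,
                                  pooling = c("pooled",
                                              "median_of_medians"),
                                  predict_fun = NULL, ...) {
  pooling <- match.arg(pooling)
  cfg <- if (inherits(aux_config, "encoding_config")) aux_config
         else encoding_config(aux_config)
  pairings <- intersect(pairing_ids(conditions), names(dataset))
  if (!length(pairings)) {
    stop("dataset contains no pairing conditions", call. = FALSE)
  }
  encode_all <- function(sets) {
    lapply(sets, function(s) {
      encode_curve_set(s, get_condition(s$condition_id, conditions), cfg)
    })
  }
  per_pairing <- lapply(seq_along(pairings), function(i) {
    sp <- loco_split(dataset, pairings[i], conditions)
    train_sets <- unlist(sp$train, recursive = FALSE, use.names = FALSE)
    train <- list(x = encode_all(train_sets),
                  y = lapply(train_sets, `[[`, "tl"))
    test <- list(x = encode_all(sp$test),
                 y = lapply(sp$test, `[[`, "tl"))
    if (is.null(predict_fun)) {
      fit <- esn(train$x, train$y, n_neurons = n_neurons,
                 seed = as.integer((as.numeric(seed) + i * 331) %%
                                     2147483647), ...)
      preds <- predict(fit, test$x, clip = clip)
    } else {
      preds <- predict_fun(train, test)
      if (clip) preds <- lapply(preds, function(p) pmin(pmax(p, 0), 9))
    }
    rmse <- mapply(curve_rmse, preds, test$y)
    c(rmse_stats(rmse), list(n_test = length(rmse)))
  })
  names(per_pairing) <- pairings
  all_values <- unlist(lapply(per_pairing, `[[`, "values"),
                       use.names = FALSE)
  pooled <- rmse_stats(all_values)
  if (pooling == "median_of_medians") {
    pooled$median <- stats::median(vapply(per_pairing, `[[`, 1,
                                          "median"))
  }
  structure(
    list(n_neurons = as.integer(n_neurons), aux_config = cfg$aux_config,
         aux_dim = aux_dimension(cfg), pooling = pooling, clip = clip,
         per_pairing = per_pairing, pooled = pooled, seed = seed),
    class = "esn_eval"
  )
}

fmt_iqr <- function(s) sprintf("%.2f (%.2f-%.2f)", s$median, s$q1, s$q3)

#' @export
print.esn_eval <- function(x, ...) {
  cat(sprintf("Leave-one-pairing-out evaluation: %d neurons, %d aux flag(s) [%s]\n",
              x$n_neurons, x$aux_dim, x$aux_config))
  cat("  all pairs: median RMSE", fmt_iqr(x$pooled),
      sprintf("over %d replicates\n", length(x$pooled$values)))
  for (p in names(x$per_pairing)) {
    cat(sprintf("  %-18s %s\n", p, fmt_iqr(x$per_pairing[[p]])))
  }
  invisible(x)
}

#' Constant-mean baseline predictor
#'
#' A stub for [evaluate_architecture()]'s `predict_fun`: predicts, for
#' every test replicate and time point, the grand mean of all training TL
#' values. The weakest sensible reference any temporal model must beat.
#'
#' @return A `function(train, test)` suitable for `predict_fun`.
#' @export
constant_baseline <- function() {
  function(train, test) {
    m <- mean(unlist(train$y, use.names = FALSE))
    lapply(test$y, function(obs) rep(m, length(obs)))
  }
}

#' Sweep architectures and collect evaluation results
#'
#' Evaluates every combination of reservoir size and auxiliary flag
#' configuration (by default the full 4 x 8 = 32 grid of the study) with
#' [evaluate_architecture()].
#'
#' @param dataset Named list (by condition) of lists of `curve_set`s.
#' @param neurons Reservoir sizes to try.
#' @param aux_configs Flag configuration names to try.
#' @param conditions Condition table.
#' @param seed Integer seed.
#' @param ... Passed to [evaluate_architecture()].
#' @return List of `esn_eval` objects.
#' @export
sweep_architectures <- function(dataset,
                                neurons = c(64L, 128L, 192L, 256L),
                                aux_configs = aux_config_names,
                                conditions = food_conditions(),
                                seed = 1L, ...) {
  grid <- expand.grid(n = neurons, cfg = aux_configs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    evaluate_architecture(dataset, n_neurons = grid$n[i],
                          aux_config = grid$cfg[i],
                          conditions = conditions, seed = seed, ...)
  })
}

#' Rank evaluated architectures by pooled median RMSE
#'
#' Ascending by the pooled median; ties broken by pooled IQR width, then
#' by architecture label. The report mirrors the study's summary table:
#' one row per architecture with pooled and per-pairing
#' "median (q1-q3)" columns.
#'
#' @param results Nonempty list of `esn_eval` objects.
#' @return A data frame with columns `rank`, `neurons`, `aux_dim`,
#'   `aux_config`, `pooled_median`, `pooled_q1`, `pooled_q3`, `all_pairs`
#'   and one formatted column per pairing.
#' @export
rank_architectures <- function(results) {
  if (!length(results)) stop("no results to rank", call. = FALSE)
  stopifnot(all(vapply(results, inherits, TRUE, "esn_eval")))
  rows <- lapply(results, function(r) {
    base <- data.frame(
      neurons = r$n_neurons, aux_dim = r$aux_dim,
      aux_config = r$aux_config,
      pooled_median = r$pooled$median, pooled_q1 = r$pooled$q1,
      pooled_q3 = r$pooled$q3, all_pairs = fmt_iqr(r$pooled),
      stringsAsFactors = FALSE
    )
    for (p in names(r$per_pairing)) base[[p]] <- fmt_iqr(r$per_pairing[[p]])
    base
  })
  tab <- do.call(rbind, rows)
  label <- sprintf("%s/%s", tab$neurons, tab$aux_config)
  o <- order(tab$pooled_median, tab$pooled_q3 - tab$pooled_q1, label)
  tab <- tab[o, , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}

#' Replace TL curves with a known linear functional of the TDS state
#'
#' Validation helper: rebuilds every TL curve as
#' `tl(t) = weights . tds(., t) + noise`, a fixed linear functional of the
#' instantaneous dominance proportions plus Gaussian noise. A temporal
#' model that reads the TDS input must recover this map and beat a
#' constant predictor by a wide margin.
#'
#' @param dataset Named list (by condition) of lists of `curve_set`s.
#' @param weights Named numeric vector over the attributes (defaults to a
#'   fixed hedonic-like spread of weights between 2 and 8).
#' @param noise_sd Noise standard deviation (default 0.3).
#' @param seed Integer seed.
#' @return The dataset with TL curves replaced (clipped into \[0, 9\] only
#'   if noise pushes them outside).
#' @export
simulate_linear_tl <- function(dataset, weights = NULL, noise_sd = 0.3,
                               seed = 1L) {
  set.seed(seed)
  lapply(dataset, function(sets) {
    lapply(sets, function(s) {
      w <- if (is.null(weights)) {
        stats::setNames(seq(2, 8, length.out = nrow(s$tds)),
                        rownames(s$tds))
      } else weights
      stopifnot(all(rownames(s$tds) %in% names(w)))
      tl <- as.numeric(crossprod(s$tds, w[rownames(s$tds)])) +
        stats::rnorm(length(s$grid), 0, noise_sd)
      s$tl <- pmin(pmax(tl, 0), 9)
      s
    })
  })
}
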