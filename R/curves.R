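#' Evenly spaced time grid on normalized time
#'
#' All curves live on normalized time t in \[0, 1\] (trial time divided by
#' trial duration). The default 101-point grid gives 0.01 resolution,
#' ample for tastings of 10--20 seconds.
#'
#' @param n_points Number of grid points (>= 2).
#' @return Numeric vector of `n_points` evenly spaced values from 0 to 1.
#' @export
time_grid <- function(n_points = 101L) {
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("n_points must be >= 2", call. = FALSE)
  seq(0, 1, length.out = n_points)
}

#' Sample a trial as a step function on a time grid
#'
#' Last-event-carried-forward sampling of one trial on normalized time
#' `t = time_s / duration_s`. Before the first event the value is the
#' sentinel `"none"` for a TDS trial and `0` for a TL trial. A trial with
#' no events yields an all-`"none"` / all-zero vector.
#'
#' @param trial A `trial_record`.
#' @param grid Numeric grid from [time_grid()].
#' @return For TDS, a character vector over the grid (attribute names or
#'   `"none"`); for TL, a numeric vector (0 or the last pressed score).
#' @examples
#' tr <- trial_record("p1", "plain", "TL", 1, 10,
#'                    data.frame(time_s = 5, payload = "7"))
#' trial_step_function(tr, time_grid(5))  # 0 0 7 7 7
#' @export
trial_step_function <- function(trial, grid) {
  stopifnot(inherits(trial, "trial_record"))
  tn <- trial$events$time_s / trial$duration_s
  i <- findInterval(grid, tn)
  if (trial$task == "TDS") {
    out <- rep("none", length(grid))
    out[i > 0] <- trial$events$payload[i[i > 0]]
  } else {
    out <- rep(0, length(grid))
    out[i > 0] <- as.numeric(trial$events$payload[i[i > 0]])
  }
  out
}

#' Construct a curve set
#'
#' A curve set pairs a TDS dominance-proportion matrix with a TL liking
#' curve for one condition on a shared normalized time grid. The residual
#' "none" mass (trials in which nothing had been selected yet) is kept
#' alongside so that attribute mass + none mass = 1 at every grid point;
#' it is never fed to the prediction model.
#'
#' @param condition_id Condition identifier.
#' @param tds Matrix `[n_attributes x n_points]` of dominance proportions
#'   in \[0, 1\], rows named by attribute.
#' @param tl Numeric TL curve in \[0, 9\] over the grid.
#' @param grid Numeric time grid.
#' @param none Numeric vector of residual pre-first-selection mass.
#' @param n_trials Number of trials behind the proportions.
#' @param provenance One of `"panelist"`, `"panel-mean"`,
#'   `"bootstrap-replicate"`.
#' @param replicate_id Identifier within its provenance group.
#' @return An object of class `curve_set`.
#' @export
curve_set <- function(condition_id, tds, tl, grid,
                      none = 1 - colSums(tds), n_trials = NA_integer_,
                      provenance = c("panelist", "panel-mean",
                                     "bootstrap-replicate"),
                      replicate_id = NA_character_) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(tds), !is.null(rownames(tds)),
            ncol(tds) == length(grid), length(tl) == length(grid),
            length(none) == length(grid))
  if (any(tds < -1e-12) || any(tds > 1 + 1e-12)) {
    stop("TDS proportions must lie in [0, 1]", call. = FALSE)
  }
  if (any(tl < -1e-9) || any(tl > 9 + 1e-9)) {
    stop("TL values must lie in [0, 9]", call. = FALSE)
  }
  structure(
    list(condition_id = condition_id, tds = tds, tl = as.numeric(tl),
         grid = as.numeric(grid), none = as.numeric(none),
         n_trials = n_trials, provenance = provenance,
         replicate_id = as.character(replicate_id)),
    class = "curve_set"
  )
}

#' @export
print.curve_set <- function(x, ...) {
  cat(sprintf("<curve_set> %s [%s%s], %d attributes x %d grid points\n",
              x$condition_id, x$provenance,
              if (!is.na(x$replicate_id)) paste0(" ", x$replicate_id) else "",
              nrow(x$tds), length(x$grid)))
  cat(sprintf("  TL range %.2f..%.2f, peak at t = %.2f\n",
              min(x$tl), max(x$tl), x$grid[which.max(x$tl)]))
  invisible(x)
}

#' Plot a curve set
#'
#' Dominance-proportion curves for every attribute with the TL curve
#' overlaid on a secondary 0--9 axis. A quick QC view of one condition.
#'
#' @param x A `curve_set`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.curve_set <- function(x, ...) {
  oldpar <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(oldpar))
  cols <- grDevices::hcl.colors(nrow(x$tds), "Dark 3")
  graphics::matplot(x$grid, t(x$tds), type = "l", lty = 1, col = cols,
                    xlab = "normalized time", ylab = "dominance proportion",
                    ylim = c(0, 1), main = x$condition_id, ...)
  graphics::par(new = TRUE)
  graphics::plot(x$grid, x$tl, type = "l", lwd = 2, col = "black",
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 9))
  graphics::axis(4)
  graphics::mtext("liking", side = 4, line = 2.5)
  graphics::legend("topleft", legend = c(rownames(x$tds), "TL"),
                   col = c(cols, "black"), lty = 1,
                   lwd = c(rep(1, nrow(x$tds)), 2), cex = 0.6, ncol = 2,
                   bty = "n")
  invisible(x)
}

#' Build one panelist's curve pair for one condition
#'
#' TDS proportions are the fraction of that panelist's TDS repetitions in
#' which each attribute was dominant at each grid point; the TL curve is
#' the mean of the TL repetitions' step functions (zero before the first
#' press of each repetition).
#'
#' @param trials List of `trial_record`s: the panelist's TDS and TL
#'   repetitions for a single condition (at least one of each task).
#' @param grid Time grid from [time_grid()].
#' @param attributes Attribute vocabulary giving the row order.
#' @return A `curve_set` with provenance `"panelist"`.
#' @export
build_panelist_curves <- function(trials, grid = time_grid(),
                                  attributes = tds_attributes) {
  stopifnot(length(trials) > 0,
            all(vapply(trials, inherits, TRUE, "trial_record")))
  pid <- unique(vapply(trials, `[[`, "", "panelist_id"))
  cid <- unique(vapply(trials, `[[`, "", "condition_id"))
  if (length(pid) != 1 || length(cid) != 1) {
    stop("all trials must share panelist and condition", call. = FALSE)
  }
  tasks <- vapply(trials, `[[`, "", "task")
  tds_trials <- trials[tasks == "TDS"]
  tl_trials <- trials[tasks == "TL"]
  if (!length(tds_trials) || !length(tl_trials)) {
    stop("need at least one TDS and one TL trial", call. = FALSE)
  }
  steps <- vapply(tds_trials, trial_step_function, character(length(grid)),
                  grid = grid)                    # [n_points x n_reps]
  tds <- t(vapply(attributes,
                  function(a) rowMeans(steps == a),
                  numeric(length(grid))))
  none <- rowMeans(steps == "none")
  tl_steps <- vapply(tl_trials, trial_step_function, numeric(length(grid)),
                     grid = grid)
  curve_set(cid, tds, rowMeans(tl_steps), grid, none = none,
            n_trials = length(tds_trials), provenance = "panelist",
            replicate_id = pid)
}

#' Build per-panelist curve pairs for every condition in an event log
#'
#' @param trials List of `trial_record`s (e.g. from [simulate_panel()] or
#'   [split_event_log()]).
#' @param grid Time grid.
#' @param attributes Attribute vocabulary.
#' @return Named list (by condition id) of lists of panelist `curve_set`s.
#' @export
build_panel_curves <- function(trials, grid = time_grid(),
                               attributes = tds_attributes) {
  cid <- vapply(trials, `[[`, "", "condition_id")
  pid <- vapply(trials, `[[`, "", "panelist_id")
  by_cond <- split(trials, factor(cid, levels = unique(cid)))
  lapply(by_cond, function(tr) {
    p <- vapply(tr, `[[`, "", "panelist_id")
    unname(lapply(split(tr, factor(p, levels = unique(p))),
                  build_panelist_curves, grid = grid,
                  attributes = attributes))
  })
}

#' Average curve sets into a panel-mean curve pair
#'
#' Pointwise unweighted mean of the TDS matrices, none mass and TL curves.
#'
#' @param curve_sets Nonempty list of `curve_set`s sharing condition and
#'   grid.
#' @param provenance Provenance label of the result.
#' @param replicate_id Identifier of the result.
#' @return A `curve_set`.
#' @export
build_panel_mean <- function(curve_sets, provenance = "panel-mean",
                             replicate_id = NA_character_) {
  if (!length(curve_sets)) {
    stop("cannot average an empty list of curve sets", call. = FALSE)
  }
  stopifnot(all(vapply(curve_sets, inherits, TRUE, "curve_set")))
  cid <- unique(vapply(curve_sets, `[[`, "", "condition_id"))
  if (length(cid) != 1) {
    stop("curve sets must share one condition", call. = FALSE)
  }
  g <- curve_sets[[1]]$grid
  if (!all(vapply(curve_sets, function(s) identical(s$grid, g), TRUE))) {
    stop("curve sets must share one time grid", call. = FALSE)
  }
  n <- length(curve_sets)
  tds <- Reduce(`+`, lapply(curve_sets, `[[`, "tds")) / n
  tl <- Reduce(`+`, lapply(curve_sets, `[[`, "tl")) / n
  none <- Reduce(`+`, lapply(curve_sets, `[[`, "none")) / n
  curve_set(cid, tds, tl, g, none = none,
            n_trials = sum(vapply(curve_sets, `[[`, 1L, "n_trials")),
            provenance = provenance, replicate_id = replicate_id)
}
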