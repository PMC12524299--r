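# numeric columns are written with %.17g so doubles survive a CSV
# round trip bit-exactly
fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read an event-log CSV
#'
#' One row per button-press event: `panelist_id`, `condition_id`, `task`,
#' `repetition`, `duration_s`, `time_s`, `payload`. Comma-separated,
#' UTF-8, header mandatory; times in seconds at full double precision.
#'
#' @param trials List of `trial_record`s (or an event-log data frame).
#' @param path File path.
#' @return `write_event_log()`: `path`, invisibly. `read_event_log()`:
#'   a list of `trial_record`s.
#' @export
write_event_log <- function(trials, path) {
  log <- if (is.data.frame(trials)) trials else as_event_log(trials)
  out <- data.frame(
    panelist_id = log$panelist_id, condition_id = log$condition_id,
    task = log$task, repetition = log$repetition,
    duration_s = fmt_num(log$duration_s), time_s = fmt_num(log$time_s),
    payload = log$payload, stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  req <- c("panelist_id", "condition_id", "task", "repetition",
           "duration_s", "time_s", "payload")
  miss <- setdiff(req, names(log))
  if (!length(miss)) log$payload <- as.character(log$payload)
  if (length(miss)) {
    stop("malformed event log ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(log$time_s) | !is.finite(log$duration_s))
  if (length(bad)) {
    stop("malformed event log ", path, ": non-numeric time at row ",
         bad[1] + 1L, call. = FALSE)
  }
  split_event_log(log)
}

#' Write / read curve sets as a long-format CSV
#'
#' One row per (curve set, channel, grid point): `condition_id`,
#' `provenance`, `replicate_id`, `n_trials`, `channel` (an attribute name,
#' `"none"` for the residual pre-first-selection mass, or `"TL"`), `t`,
#' `value`. Values are written at full double precision so curve sets
#' round-trip exactly.
#'
#' @param dataset Named list (by condition) of lists of `curve_set`s, or a
#'   flat list of `curve_set`s.
#' @param path File path.
#' @return `write_curves()`: `path`, invisibly. `read_curves()`: a named
#'   list (by condition) of lists of `curve_set`s.
#' @export
write_curves <- function(dataset, path) {
  sets <- if (all(vapply(dataset, inherits, TRUE, "curve_set"))) {
    dataset
  } else {
    unlist(dataset, recursive = FALSE, use.names = FALSE)
  }
  blocks <- lapply(sets, function(s) {
    channels <- rbind(s$tds, none = s$none, TL = s$tl)
    data.frame(
      condition_id = s$condition_id, provenance = s$provenance,
      replicate_id = s$replicate_id, n_trials = s$n_trials,
      channel = rep(rownames(channels), each = length(s$grid)),
      t = fmt_num(rep(s$grid, times = nrow(channels))),
      value = fmt_num(as.numeric(t(channels))),
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, blocks), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  key <- paste(d$condition_id, d$provenance, d$replicate_id, sep = "\r")
  idx <- split(seq_len(nrow(d)), factor(key, levels = unique(key)))
  sets <- lapply(idx, function(i) {
    block <- d[i, ]
    grid <- sort(unique(block$t))
    chan <- split(block, factor(block$channel,
                                levels = unique(block$channel)))
    mat <- t(vapply(chan, function(b) b$value[order(b$t)],
                    numeric(length(grid))))
    attr_rows <- setdiff(rownames(mat), c("none", "TL"))
    curve_set(block$condition_id[1],
              mat[attr_rows, , drop = FALSE],
              mat["TL", ], grid, none = mat["none", ],
              n_trials = block$n_trials[1],
              provenance = block$provenance[1],
              replicate_id = block$replicate_id[1])
  })
  conds <- vapply(sets, `[[`, "", "condition_id")
  out <- split(unname(sets), factor(conds, levels = unique(conds)))
  lapply(out, unname)
}

#' Write an evaluation report
#'
#' `write_eval_results()` stores a list of `esn_eval` objects (including
#' the raw per-replicate RMSE vectors) as JSON; `write_report()` writes
#' the ranked summary table from [rank_architectures()] as CSV.
#'
#' @param results List of `esn_eval` objects.
#' @param ranked Data frame from [rank_architectures()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_eval_results <- function(results, path) {
  payload <- lapply(results, function(r) {
    list(n_neurons = r$n_neurons, aux_config = r$aux_config,
         aux_dim = r$aux_dim, pooling = r$pooling, clip = r$clip,
         pooled = r$pooled,
         per_pairing = lapply(r$per_pairing, function(p) {
           p[c("median", "q1", "q3", "values")]
         }))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eval_results
#' @export
write_report <- function(ranked, path) {
  utils::write.csv(ranked, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a run configuration file
#'
#' A flat key-value tree in JSON (or YAML when the file extension is
#' `.yml`/`.yaml` and the yaml package is available). Unknown keys are
#' rejected; missing keys take the defaults of [default_run_config()].
#'
#' @param path Configuration file path, or `NULL` for all defaults.
#' @return A named list of run settings.
#' @export
read_run_config <- function(path = NULL) {
  base <- default_run_config()
  if (is.null(path)) return(base)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  utils::modifyList(base, cfg)
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    n_panelists = 16L,
    n_repetitions = 3L,
    grid_points = 101L,
    n_replicates = 100L,
    neurons = c(64L, 128L, 192L, 256L),
    aux_configs = aux_config_names,
    spectral_radius = 0.9,
    leak_rate = 1.0,
    input_scaling = 1.0,
    recurrent_density = 0.1,
    input_density = 1.0,
    ridge = 1e-6,
    washout = 0L,
    clip = FALSE,
    pooling = "pooled"
  )
}
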