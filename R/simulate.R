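#' Construct a single trial record
#'
#' A trial record is one execution of the TDS or TL task by one panelist on
#' one condition: metadata plus an ordered, timestamped event sequence.
#' TDS payloads are attribute names; TL payloads are liking buttons 1..9
#' (stored as character in the event table).
#'
#' @param panelist_id,condition_id,task,repetition,duration_s Trial
#'   metadata; `task` is `"TDS"` or `"TL"`.
#' @param events Data frame with columns `time_s` (strictly increasing,
#'   within `[0, duration_s]`) and `payload` (character).
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(panelist_id, condition_id, task, repetition,
                         duration_s, events) {
  task <- match.arg(task, c("TDS", "TL"))
  if (!is.finite(duration_s) || duration_s <= 0) {
    stop("duration_s must be a positive finite number", call. = FALSE)
  }
  stopifnot(is.data.frame(events),
            all(c("time_s", "payload") %in% names(events)))
  if (nrow(events)) {
    if (any(diff(events$time_s) <= 0)) {
      stop("event times must be strictly increasing", call. = FALSE)
    }
    if (events$time_s[1] <= 0 || events$time_s[nrow(events)] > duration_s) {
      stop("event times must lie in (0, duration_s]", call. = FALSE)
    }
  }
  structure(
    list(panelist_id = panelist_id, condition_id = condition_id,
         task = task, repetition = as.integer(repetition),
         duration_s = duration_s,
         events = data.frame(time_s = as.numeric(events$time_s),
                             payload = as.character(events$payload),
                             stringsAsFactors = FALSE)),
    class = "trial_record"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<%s trial> panelist %s, condition %s, rep %d, %.1f s, %d events\n",
              x$task, x$panelist_id, x$condition_id, x$repetition,
              x$duration_s, nrow(x$events)))
  invisible(x)
}

# counter-based per-trial seed: every trial is reproducible on its own
trial_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) %% 10000) * 100003 + counter * 7919) %%
    2147483646L + 1L
}

#' Simulate one TDS trial
#'
#' Semi-Markov generator of dominant-attribute episodes: after a short
#' initial delay, episodes follow one another with exponential dwell times
#' (mean `dwell_mean_s`); the attribute of each episode is drawn from the
#' selection-probability vector of the phase containing the episode's
#' normalized start time. Only one attribute is dominant at a time.
#'
#' @param profile A [condition_profile()].
#' @param duration_s Trial duration in seconds (positive, finite).
#' @param seed Integer seed; the trial is a pure function of
#'   `(profile, duration_s, seed)`.
#' @param panelist_id,condition_id,repetition Metadata for the record.
#' @return A `trial_record` with `task = "TDS"`.
#' @export
sample_tds_trial <- function(profile, duration_s, seed,
                             panelist_id = "p1", condition_id = "cond",
                             repetition = 1L) {
  if (!is.numeric(duration_s) || !is.finite(duration_s) || duration_s <= 0) {
    stop("duration_s must be a positive finite number", call. = FALSE)
  }
  stopifnot(inherits(profile, "condition_profile"))
  set.seed(seed)
  # first selection happens quickly but strictly after t = 0
  t <- min(stats::rexp(1, rate = 1 / (0.02 * duration_s)),
           0.25 * duration_s)
  times <- numeric(0)
  payloads <- character(0)
  while (t < duration_s) {
    p <- phase_probs(profile, t / duration_s)
    times <- c(times, t)
    payloads <- c(payloads, sample(profile$attributes, 1L, prob = p))
    t <- t + stats::rexp(1, rate = 1 / profile$dwell_mean_s)
  }
  trial_record(panelist_id, condition_id, "TDS", repetition, duration_s,
               data.frame(time_s = times, payload = payloads,
                          stringsAsFactors = FALSE))
}

# dominant attribute of a TDS trial at normalized time u (NA before the
# first press)
dominant_at <- function(tds_trial, u) {
  tn <- tds_trial$events$time_s / tds_trial$duration_s
  i <- findInterval(u, tn)
  ifelse(i == 0, NA_character_, tds_trial$events$payload[pmax(i, 1L)])
}

#' Simulate one TL trial given its companion TDS trial
#'
#' Liking presses arrive as a Poisson process on normalized time (rate
#' `press_rate`) after an initial exponential delay with mean 10% of the
#' trial duration, so the zero-before-first-press convention of TL curves
#' is exercised. Each press scores the hedonic weight of the attribute
#' dominant in the companion trial at that (normalized) moment, plus
#' Gaussian noise, rounded and clipped to the 1..9 buttons. Before the
#' companion's first selection the neutral scale midpoint 5 is used.
#'
#' @param profile A [condition_profile()].
#' @param companion_tds The same panelist/condition/repetition TDS trial.
#' @param duration_s Duration of the TL trial (drawn independently of the
#'   companion's; tasks are separate tastings).
#' @param seed Integer seed.
#' @param panelist_id,condition_id,repetition Metadata for the record.
#' @return A `trial_record` with `task = "TL"`.
#' @export
sample_tl_trial <- function(profile, companion_tds, duration_s, seed,
                            panelist_id = "p1", condition_id = "cond",
                            repetition = 1L) {
  stopifnot(inherits(profile, "condition_profile"))
  if (!inherits(companion_tds, "trial_record") ||
      companion_tds$task != "TDS") {
    stop("companion_tds must be a TDS trial_record", call. = FALSE)
  }
  if (!is.numeric(duration_s) || !is.finite(duration_s) || duration_s <= 0) {
    stop("duration_s must be a positive finite number", call. = FALSE)
  }
  set.seed(seed)
  t <- min(stats::rexp(1, rate = 1 / (0.10 * duration_s)),
           0.9 * duration_s)
  times <- numeric(0)
  while (t < duration_s) {
    times <- c(times, t)
    t <- t + duration_s * stats::rexp(1, rate = profile$press_rate)
  }
  u <- times / duration_s
  dom <- dominant_at(companion_tds, u)
  w <- ifelse(is.na(dom), 5, profile$hedonic_weights[dom])
  score <- round(w + stats::rnorm(length(w), 0, profile$noise_sd))
  score <- pmin(pmax(score, 1), 9)
  trial_record(panelist_id, condition_id, "TL", repetition, duration_s,
               data.frame(time_s = times,
                          payload = as.character(as.integer(score)),
                          stringsAsFactors = FALSE))
}

#' Simulate a full panel session
#'
#' Generates every trial of the study layout: for each panelist, condition
#' and repetition, one TDS trial and one TL trial (scored against that
#' repetition's TDS trial). Trial durations are lognormal around the
#' condition class mean with coefficient of variation
#' `design$duration_cv`. The whole session is a pure function of
#' `(design, profiles, seed)`; each trial draws from its own
#' counter-derived seed, so individual trials are reproducible in
#' isolation.
#'
#' @param design A [study_design()].
#' @param profiles Named list of [condition_profile()] covering every
#'   condition in the design.
#' @param seed Integer seed.
#' @return A list of `trial_record`s of length
#'   `n_panelists * n_conditions * 2 * n_repetitions`.
#' @examples
#' trials <- simulate_panel(study_design(n_panelists = 2), seed = 1)
#' length(trials)  # 2 * 8 * 2 * 3
#' @export
simulate_panel <- function(design = study_design(),
                           profiles = default_profiles(design$attributes),
                           seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  missing_prof <- setdiff(design$conditions$condition_id, names(profiles))
  if (length(missing_prof)) {
    stop("no profile for condition(s): ",
         paste(missing_prof, collapse = ", "), call. = FALSE)
  }
  cv <- design$duration_cv
  sdlog <- sqrt(log(1 + cv^2))
  trials <- vector("list",
                   design$n_panelists * nrow(design$conditions) * 2 *
                     design$n_repetitions)
  k <- 0L   # trial counter driving per-trial seeds
  out <- 0L
  for (p in seq_len(design$n_panelists)) {
    pid <- sprintf("p%02d", p)
    for (ci in seq_len(nrow(design$conditions))) {
      cid <- design$conditions$condition_id[ci]
      m <- design$mean_duration_s[[design$conditions$class[ci]]]
      meanlog <- log(m) - sdlog^2 / 2
      prof <- profiles[[cid]]
      for (r in seq_len(design$n_repetitions)) {
        k <- k + 1L
        set.seed(trial_seed(seed, k))
        dur <- stats::rlnorm(2, meanlog, sdlog)  # TDS and TL durations
        tds <- sample_tds_trial(prof, dur[1], trial_seed(seed, k) + 1L,
                                panelist_id = pid, condition_id = cid,
                                repetition = r)
        k <- k + 1L
        tl <- sample_tl_trial(prof, tds, dur[2], trial_seed(seed, k),
                              panelist_id = pid, condition_id = cid,
                              repetition = r)
        trials[[out + 1L]] <- tds
        trials[[out + 2L]] <- tl
        out <- out + 2L
      }
    }
  }
  trials
}

#' Flatten trial records into an event-log data frame
#'
#' One row per event: `panelist_id`, `condition_id`, `task`, `repetition`,
#' `duration_s`, `time_s`, `payload`. This is the long CSV layout written
#' by [write_event_log()].
#'
#' @param trials List of `trial_record`s.
#' @return A data frame.
#' @export
as_event_log <- function(trials) {
  stopifnot(all(vapply(trials, inherits, TRUE, "trial_record")))
  do.call(rbind, lapply(trials, function(tr) {
    n <- nrow(tr$events)
    if (n == 0) return(NULL)
    data.frame(panelist_id = tr$panelist_id, condition_id = tr$condition_id,
               task = tr$task, repetition = tr$repetition,
               duration_s = tr$duration_s,
               time_s = tr$events$time_s, payload = tr$events$payload,
               stringsAsFactors = FALSE)
  }))
}

#' Rebuild trial records from an event-log data frame
#'
#' @param log Event-log data frame as produced by [as_event_log()] or
#'   [read_event_log()].
#' @return A list of `trial_record`s, in order of first appearance.
#' @export
split_event_log <- function(log) {
  req <- c("panelist_id", "condition_id", "task", "repetition",
           "duration_s", "time_s", "payload")
  miss <- setdiff(req, names(log))
  if (length(miss)) {
    stop("event log is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(log$panelist_id, log$condition_id, log$task, log$repetition,
               sep = "\r")
  idx <- split(seq_len(nrow(log)), factor(key, levels = unique(key)))
  lapply(idx, function(i) {
    i <- i[order(log$time_s[i])]
    trial_record(log$panelist_id[i[1]], log$condition_id[i[1]],
                 log$task[i[1]], log$repetition[i[1]], log$duration_s[i[1]],
                 data.frame(time_s = log$time_s[i],
                            payload = log$payload[i],
                            stringsAsFactors = FALSE))
  })
}
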