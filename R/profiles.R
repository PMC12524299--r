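#' Generative profile of one tasting condition
#'
#' A condition profile drives the synthetic panel generator. Tasting is
#' divided into phases on normalized time \[0, 1\]; within a phase, dominant
#' attributes are drawn from the phase's selection-probability vector.
#' Liking presses are scored from the hedonic weight of the currently
#' dominant attribute plus Gaussian noise, rounded and clipped to the 1..9
#' button scale.
#'
#' @param phases A list of phases, each a list with `interval` (numeric
#'   length 2 on \[0,1\]) and `probs` (named selection probabilities over a
#'   subset of `attributes`; missing attributes get probability 0). The
#'   intervals must tile \[0,1\] without gaps or overlap.
#' @param hedonic_weights Named numeric vector of liking contributions on
#'   the 1--9 scale; attributes not named default to the scale midpoint 5.
#' @param dwell_mean_s Mean dwell time (seconds) of one dominant-attribute
#'   episode.
#' @param press_rate Expected number of liking presses per unit of
#'   normalized time after the first press.
#' @param noise_sd Standard deviation of the liking noise (scale points).
#' @param attributes Attribute vocabulary the probabilities refer to.
#' @return An object of class `condition_profile`.
#' @examples
#' p <- condition_profile(
#'   phases = list(list(interval = c(0, 1), probs = c(sweet = 1))),
#'   hedonic_weights = c(sweet = 7)
#' )
#' @export
condition_profile <- function(phases,
                              hedonic_weights = numeric(0),
                              dwell_mean_s = 2.5,
                              press_rate = 10,
                              noise_sd = 0.7,
                              attributes = tds_attributes) {
  stopifnot(is.list(phases), length(phases) > 0)
  full <- function(p) {
    if (is.null(names(p)) || !all(names(p) %in% attributes)) {
      stop("phase probabilities must be named by known attributes",
           call. = FALSE)
    }
    v <- stats::setNames(numeric(length(attributes)), attributes)
    v[names(p)] <- p
    if (any(v < 0) || abs(sum(v) - 1) > 1e-8) {
      stop("phase probabilities must be nonnegative and sum to 1",
           call. = FALSE)
    }
    v / sum(v)
  }
  phases <- lapply(phases, function(ph) {
    stopifnot(length(ph$interval) == 2, ph$interval[1] < ph$interval[2])
    list(interval = as.numeric(ph$interval), probs = full(ph$probs))
  })
  # phases must tile [0,1]
  ivals <- t(vapply(phases, `[[`, numeric(2), "interval"))
  o <- order(ivals[, 1])
  ivals <- ivals[o, , drop = FALSE]
  if (abs(ivals[1, 1]) > 1e-10 || abs(ivals[nrow(ivals), 2] - 1) > 1e-10 ||
      (nrow(ivals) > 1 &&
       any(abs(ivals[-1, 1] - ivals[-nrow(ivals), 2]) > 1e-10))) {
    stop("phase intervals must tile [0, 1] without gaps or overlap",
         call. = FALSE)
  }
  hw <- stats::setNames(rep(5, length(attributes)), attributes)
  if (length(hedonic_weights)) {
    stopifnot(all(names(hedonic_weights) %in% attributes))
    hw[names(hedonic_weights)] <- hedonic_weights
  }
  structure(
    list(phases = phases[o], hedonic_weights = hw,
         dwell_mean_s = dwell_mean_s, press_rate = press_rate,
         noise_sd = noise_sd, attributes = attributes),
    class = "condition_profile"
  )
}

# selection-probability vector of the phase containing normalized time u
phase_probs <- function(profile, u) {
  for (ph in profile$phases) {
    if (u >= ph$interval[1] && (u < ph$interval[2] || ph$interval[2] >= 1)) {
      return(ph$probs)
    }
  }
  profile$phases[[length(profile$phases)]]$probs
}

#' Default generative profiles for the eight tasting conditions
#'
#' Hand-set profiles emulating the qualitative temporal structure of the
#' cracker-and-spread study: strawberry jam runs sour then wet then sweet
#' with liking above 6 in its sweet middle phase; crackers are dominated by
#' dry, salty/sesame and wheat-like notes with liking below 6; pairings show
#' spread attributes early and cracker attributes late, with an earlier,
#' higher liking peak than the cracker alone.
#'
#' @param attributes Attribute vocabulary.
#' @return Named list of [condition_profile()] objects, one per condition
#'   id of [food_conditions()].
#' @export
default_profiles <- function(attributes = tds_attributes) {
  cp <- function(...) condition_profile(..., attributes = attributes)

  plain <- cp(
    phases = list(
      list(interval = c(0, 0.35),
           probs = c(dry = 0.45, salty = 0.30, wheat_like = 0.20,
                     burned = 0.05)),
      list(interval = c(0.35, 1),
           probs = c(wheat_like = 0.35, salty = 0.25, dry = 0.25,
                     aromatic = 0.15))
    ),
    hedonic_weights = c(dry = 4, salty = 5.5, wheat_like = 5,
                        aromatic = 5.5, burned = 4.5),
    dwell_mean_s = 3, press_rate = 10, noise_sd = 0.7
  )

  sesame <- cp(
    phases = list(
      list(interval = c(0, 0.35),
           probs = c(sesame_like = 0.40, dry = 0.25, aromatic = 0.20,
                     wheat_like = 0.15)),
      list(interval = c(0.35, 1),
           probs = c(sesame_like = 0.35, aromatic = 0.25, wheat_like = 0.25,
                     nutty = 0.15))
    ),
    hedonic_weights = c(sesame_like = 5.5, aromatic = 5.5, wheat_like = 5,
                        dry = 4, nutty = 5.5),
    dwell_mean_s = 3, press_rate = 10, noise_sd = 0.7
  )

  peanut <- cp(
    phases = list(
      list(interval = c(0, 0.4),
           probs = c(nutty = 0.40, buttery = 0.25, smooth = 0.20,
                     sweet = 0.15)),
      list(interval = c(0.4, 1),
           probs = c(smooth = 0.35, sweet = 0.30, nutty = 0.20,
                     buttery = 0.15))
    ),
    hedonic_weights = c(nutty = 6.5, buttery = 6, smooth = 6.5, sweet = 7),
    dwell_mean_s = 1.8, press_rate = 10, noise_sd = 0.7
  )

  strawberry <- cp(
    phases = list(
      list(interval = c(0, 0.25),
           probs = c(sour = 0.55, wet = 0.25, sweet = 0.10, smooth = 0.10)),
      list(interval = c(0.25, 0.5),
           probs = c(wet = 0.45, sweet = 0.30, sour = 0.15, smooth = 0.10)),
      list(interval = c(0.5, 1),
           probs = c(sweet = 0.60, wet = 0.20, smooth = 0.15, sour = 0.05))
    ),
    hedonic_weights = c(sweet = 7.5, wet = 6.5, sour = 5.5, smooth = 6.5),
    dwell_mean_s = 1.8, press_rate = 10, noise_sd = 0.7
  )

  # pairings: spread attributes dominate the first ~45% of the tasting,
  # cracker attributes the remainder, with a few spread notes lingering
  pairing <- function(spread_early, spread_mid, cracker_late, weights) {
    cp(
      phases = list(
        list(interval = c(0, 0.2), probs = spread_early),
        list(interval = c(0.2, 0.45), probs = spread_mid),
        list(interval = c(0.45, 1), probs = cracker_late)
      ),
      hedonic_weights = weights,
      dwell_mean_s = 2.2, press_rate = 10, noise_sd = 0.7
    )
  }

  jam_early <- c(sour = 0.45, wet = 0.30, sweet = 0.15, smooth = 0.10)
  jam_mid <- c(sweet = 0.50, wet = 0.25, sour = 0.10, smooth = 0.15)
  pb_early <- c(nutty = 0.40, buttery = 0.25, smooth = 0.20, sweet = 0.15)
  pb_mid <- c(sweet = 0.35, smooth = 0.30, nutty = 0.20, buttery = 0.15)
  plain_late <- c(dry = 0.25, wheat_like = 0.30, salty = 0.20,
                  sweet = 0.15, aromatic = 0.10)
  sesame_late <- c(sesame_like = 0.30, wheat_like = 0.25, dry = 0.20,
                   sweet = 0.15, aromatic = 0.10)

  jam_pair_w <- c(sweet = 7.5, wet = 6.5, sour = 5.5, smooth = 6.5,
                  dry = 4.5, salty = 5.5, wheat_like = 5.5, aromatic = 5.5,
                  sesame_like = 5.5)
  pb_pair_w <- c(sweet = 7, nutty = 6.5, buttery = 6, smooth = 6.5,
                 dry = 4.5, salty = 5.5, wheat_like = 5.5, aromatic = 5.5,
                 sesame_like = 5.5)

  list(
    plain = plain,
    sesame = sesame,
    peanut = peanut,
    strawberry = strawberry,
    plain_peanut = pairing(pb_early, pb_mid, plain_late, pb_pair_w),
    sesame_peanut = pairing(pb_early, pb_mid, sesame_late, pb_pair_w),
    plain_strawberry = pairing(jam_early, jam_mid, plain_late, jam_pair_w),
    sesame_strawberry = pairing(jam_early, jam_mid, sesame_late, jam_pair_w)
  )
}
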