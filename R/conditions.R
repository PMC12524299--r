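#' Sensory attribute vocabulary for the TDS task
#'
#' The twelve dominance attributes used throughout the package, in the
#' canonical channel order: aromatic, burned, buttery, dry, nutty, salty,
#' sesame_like, smooth, sour, sweet, wet, wheat_like. TDS curve matrices and
#' model input channels follow this order.
#'
#' @format A character vector of length 12.
#' @export
tds_attributes <- c(
  "aromatic", "burned", "buttery", "dry", "nutty", "salty",
  "sesame_like", "smooth", "sour", "sweet", "wet", "wheat_like"
)

#' Tasting conditions of the cracker-and-spread study design
#'
#' The eight tasting conditions: two crackers (plain, sesame), two spreads
#' (peanut, strawberry) and their four binary pairings, each pairing being a
#' cracker served with the spread applied on top.
#'
#' @return A data frame with one row per condition and columns
#'   `condition_id`, `cracker` (`"plain"`, `"sesame"` or `NA`), `spread`
#'   (`"peanut"`, `"strawberry"` or `NA`), `is_pairing` and `class`
#'   (`"cracker"`, `"spread"` or `"pairing"`, which selects the tasting
#'   duration regime).
#' @examples
#' food_conditions()
#' @export
food_conditions <- function() {
  crackers <- c("plain", "sesame")
  spreads <- c("peanut", "strawberry")
  singles <- data.frame(
    condition_id = c(crackers, spreads),
    cracker = c(crackers, NA, NA),
    spread = c(NA, NA, spreads),
    stringsAsFactors = FALSE
  )
  pairs <- expand.grid(cracker = crackers, spread = spreads,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- data.frame(
    condition_id = paste(pairs$cracker, pairs$spread, sep = "_"),
    cracker = pairs$cracker,
    spread = pairs$spread,
    stringsAsFactors = FALSE
  )
  out <- rbind(singles, pairs)
  out$is_pairing <- !is.na(out$cracker) & !is.na(out$spread)
  out$class <- ifelse(out$is_pairing, "pairing",
                      ifelse(!is.na(out$cracker), "cracker", "spread"))
  out
}

#' Look up one condition
#'
#' @param condition_id A condition identifier, e.g. `"plain_strawberry"`.
#' @param conditions Condition table, as from [food_conditions()].
#' @return A one-row data frame describing the condition.
#' @export
get_condition <- function(condition_id, conditions = food_conditions()) {
  i <- match(condition_id, conditions$condition_id)
  if (is.na(i)) {
    stop("unknown condition: '", condition_id, "'", call. = FALSE)
  }
  conditions[i, , drop = FALSE]
}

#' Identifiers of the cracker--spread pairings
#'
#' @param conditions Condition table, as from [food_conditions()].
#' @return Character vector of the pairing condition ids (four by default).
#' @export
pairing_ids <- function(conditions = food_conditions()) {
  conditions$condition_id[conditions$is_pairing]
}

#' Panel study design
#'
#' Constants of the sensory study layout: panel size, repetitions per task,
#' tasting conditions, attribute vocabulary, liking scale and mean tasting
#' durations per condition class. Each panelist performs every condition in
#' both the TDS and the TL task, with `n_repetitions` repetitions each.
#'
#' @param n_panelists Number of panelists (default 16).
#' @param n_repetitions Repetitions per task and condition (default 3).
#' @param conditions Condition table, as from [food_conditions()].
#' @param attributes Attribute vocabulary (default [tds_attributes]).
#' @param liking_scale Integer range of the liking buttons (default 1..9).
#' @param mean_duration_s Named mean tasting durations in seconds per
#'   condition class; crackers and pairings take about twice as long to eat
#'   as a spoonful of spread.
#' @param duration_cv Coefficient of variation of the lognormal trial
#'   duration distribution (default 0.15).
#' @return An object of class `study_design`.
#' @examples
#' d <- study_design()
#' d$n_panelists
#' @export
study_design <- function(n_panelists = 16L,
                         n_repetitions = 3L,
                         conditions = food_conditions(),
                         attributes = tds_attributes,
                         liking_scale = c(1L, 9L),
                         mean_duration_s = c(cracker = 20, spread = 10,
                                             pairing = 20),
                         duration_cv = 0.15) {
  n_panelists <- as.integer(n_panelists)
  n_repetitions <- as.integer(n_repetitions)
  if (n_panelists < 0L) stop("n_panelists must be >= 0", call. = FALSE)
  if (n_repetitions < 1L) stop("n_repetitions must be >= 1", call. = FALSE)
  if (anyDuplicated(attributes)) {
    stop("attributes must be unique", call. = FALSE)
  }
  stopifnot(all(c("condition_id", "cracker", "spread", "is_pairing",
                  "class") %in% names(conditions)))
  if (!all(conditions$class %in% names(mean_duration_s))) {
    stop("mean_duration_s must name every condition class", call. = FALSE)
  }
  structure(
    list(n_panelists = n_panelists,
         n_repetitions = n_repetitions,
         conditions = conditions,
         attributes = attributes,
         liking_scale = as.integer(liking_scale),
         mean_duration_s = mean_duration_s,
         duration_cv = duration_cv),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Panel study design\n")
  cat("  panelists:   ", x$n_panelists, "\n")
  cat("  repetitions: ", x$n_repetitions, " per task\n")
  cat("  conditions:  ", nrow(x$conditions), " (",
      sum(x$conditions$is_pairing), " pairings)\n", sep = "")
  cat("  attributes:  ", length(x$attributes), "\n")
  cat("  trials:      ", x$n_panelists * nrow(x$conditions) * 2 *
        x$n_repetitions, " (", nrow(x$conditions) * 2 * x$n_repetitions,
      " per panelist)\n", sep = "")
  invisible(x)
}
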