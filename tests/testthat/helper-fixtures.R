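# shared fixtures, built in code and memoised for the session

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# a single-phase profile putting all mass on one attribute
degenerate_profile <- function(attribute = "sweet", weight = 5,
                               noise_sd = 0, ...) {
  w <- stats::setNames(weight, attribute)
  condition_profile(
    phases = list(list(interval = c(0, 1),
                       probs = stats::setNames(1, attribute))),
    hedonic_weights = w, noise_sd = noise_sd, ...
  )
}

# a single-phase profile with a cracker-like selection vector
cracker_like_profile <- function(...) {
  condition_profile(
    phases = list(list(
      interval = c(0, 1),
      probs = c(dry = 0.45, salty = 0.3, wheat_like = 0.2, burned = 0.05)
    )),
    hedonic_weights = c(dry = 4, salty = 5.5, wheat_like = 5),
    ...
  )
}

# full default panel (16 panelists) and its bootstrap dataset (B = 100);
# expensive pieces shared across test files
default_trials <- function() {
  memo("trials", simulate_panel(study_design(), seed = 42))
}

default_panel <- function() {
  memo("panel", build_panel_curves(default_trials()))
}

default_dataset <- function() {
  memo("dataset",
       bootstrap_panel(default_panel(), n_replicates = 100, seed = 42))
}

# a small panel for cheap structural tests
small_panel <- function() {
  memo("small_panel", {
    trials <- simulate_panel(study_design(n_panelists = 4), seed = 7)
    build_panel_curves(trials)
  })
}

small_dataset <- function(n_replicates = 8) {
  memo(paste0("small_dataset_", n_replicates),
       bootstrap_panel(small_panel(), n_replicates = n_replicates,
                       seed = 7))
}

# a random curve set on a given grid (valid by construction)
random_curve_set <- function(condition_id = "plain", grid = time_grid(21),
                             seed = 1) {
  set.seed(seed)
  raw <- matrix(stats::runif(12 * length(grid)), 12,
                dimnames = list(tds_attributes, NULL))
  tot <- stats::runif(length(grid))  # column mass <= 1
  tds <- sweep(raw, 2, colSums(raw) / tot, "/")
  curve_set(condition_id, tds, stats::runif(length(grid), 0, 9), grid,
            n_trials = 3L, provenance = "panelist", replicate_id = "p01")
}
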