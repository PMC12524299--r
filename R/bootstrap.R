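#' Bootstrap-resample panelist curve pairs for one condition
#'
#' Data augmentation for small panels: each replicate draws `n_sampled`
#' panelist curve pairs with replacement (TDS and TL drawn together, so the
#' within-panelist coupling between sensation and liking is preserved) and
#' averages them into a single curve pair. With the defaults this turns a
#' 16-panelist condition into 100 averaged curve pairs.
#'
#' @param panelist_sets Nonempty list of panelist `curve_set`s for one
#'   condition on one grid.
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param n_sampled Panelists drawn per replicate (default: the panel
#'   size).
#' @param seed Integer seed; output is a pure function of the inputs and
#'   the seed.
#' @return List of `n_replicates` `curve_set`s with provenance
#'   `"bootstrap-replicate"` and replicate ids `"b001"`, `"b002"`, ...
#' @examples
#' \dontrun{
#' reps <- bootstrap_condition(panel$plain, n_replicates = 100, seed = 7)
#' }
#' @export
bootstrap_condition <- function(panelist_sets, n_replicates = 100L,
                                n_sampled = length(panelist_sets),
                                seed = 1L) {
  if (!length(panelist_sets)) {
    stop("cannot resample an empty panel", call. = FALSE)
  }
  n_replicates <- as.integer(n_replicates)
  n_sampled <- as.integer(n_sampled)
  if (n_replicates < 1L || n_sampled < 1L) {
    stop("n_replicates and n_sampled must be >= 1", call. = FALSE)
  }
  set.seed(seed)
  lapply(seq_len(n_replicates), function(b) {
    idx <- sample.int(length(panelist_sets), n_sampled, replace = TRUE)
    build_panel_mean(panelist_sets[idx], provenance = "bootstrap-replicate",
                     replicate_id = sprintf("b%03d", b))
  })
}

#' Bootstrap-resample every condition of a panel
#'
#' Applies [bootstrap_condition()] to each condition with fresh,
#' independent draws (condition index offsets the seed).
#'
#' @param panel Named list (by condition) of lists of panelist
#'   `curve_set`s, as from [build_panel_curves()].
#' @param n_replicates,n_sampled,seed See [bootstrap_condition()].
#' @return Named list (by condition) of lists of bootstrap `curve_set`s.
#' @export
bootstrap_panel <- function(panel, n_replicates = 100L,
                            n_sampled = NULL, seed = 1L) {
  stopifnot(is.list(panel), length(names(panel)) == length(panel))
  out <- lapply(seq_along(panel), function(i) {
    bootstrap_condition(panel[[i]], n_replicates = n_replicates,
                        n_sampled = if (is.null(n_sampled))
                          length(panel[[i]]) else n_sampled,
                        seed = (as.numeric(seed) + i * 104729) %%
                          2147483647)
  })
  names(out) <- names(panel)
  out
}
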