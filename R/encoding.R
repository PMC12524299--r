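#' Auxiliary flag configurations
#'
#' The eight input encodings compared by the evaluation pipeline. Each adds
#' a block of constant binary channels to the 12 attribute channels:
#'
#' | name            | aux dims | total | flags |
#' |-----------------|----------|-------|-------|
#' | `none`          | 0 | 12 | attribute curves only |
#' | `combo`         | 1 | 13 | combination flag (1 = cracker+spread pairing) |
#' | `cracker_spread`| 2 | 14 | cracker flag, spread flag (both 1 for pairings) |
#' | `exclusive3`    | 3 | 15 | cracker, spread, combination flags, mutually exclusive |
#' | `brand`         | 4 | 16 | premium, sesame, peanut, strawberry (by ingredient presence) |
#' | `brand_combo`   | 5 | 17 | brand flags + combination flag |
#' | `brand_cs`      | 6 | 18 | brand flags + cracker/spread flags (both-1 convention) |
#' | `brand_all`     | 7 | 19 | brand flags + cracker/spread/combination flags |
#'
#' @format Character vector of the eight configuration names.
#' @export
aux_config_names <- c("none", "combo", "cracker_spread", "exclusive3",
                      "brand", "brand_combo", "brand_cs", "brand_all")

#' Build an encoding configuration
#'
#' @param aux_config One of [aux_config_names].
#' @param exclusive_composite For `brand_all` only: whether the
#'   cracker/spread/combination sub-block uses the mutually exclusive
#'   convention (default) or the both-1 cracker/spread convention plus a
#'   combination flag.
#' @return An object of class `encoding_config`.
#' @examples
#' aux_dimension(encoding_config("combo"))      # 1
#' aux_dimension(encoding_config("brand_all"))  # 7
#' @export
encoding_config <- function(aux_config = "none", exclusive_composite = TRUE) {
  aux_config <- match.arg(aux_config, aux_config_names)
  structure(list(aux_config = aux_config,
                 exclusive_composite = isTRUE(exclusive_composite)),
            class = "encoding_config")
}

#' Number of auxiliary input dimensions of a configuration
#'
#' @param cfg An [encoding_config()] (or a configuration name).
#' @return Integer in 0..7; the total model input dimension is this plus
#'   the 12 attribute channels.
#' @export
aux_dimension <- function(cfg) {
  if (is.character(cfg)) cfg <- encoding_config(cfg)
  stopifnot(inherits(cfg, "encoding_config"))
  c(none = 0L, combo = 1L, cracker_spread = 2L, exclusive3 = 3L,
    brand = 4L, brand_combo = 5L, brand_cs = 6L,
    brand_all = 7L)[[cfg$aux_config]]
}

# flag vector (named 0/1) for one condition under one configuration
condition_flags <- function(condition, cfg) {
  stopifnot(inherits(cfg, "encoding_config"))
  has_cracker <- !is.na(condition$cracker)
  has_spread <- !is.na(condition$spread)
  if (!has_cracker && !has_spread) {
    stop("condition must involve a cracker or a spread", call. = FALSE)
  }
  pairing <- has_cracker && has_spread
  combo <- c(combination = as.integer(pairing))
  cs_both <- c(cracker = as.integer(has_cracker),
               spread = as.integer(has_spread))
  cs_excl <- c(cracker = as.integer(has_cracker && !pairing),
               spread = as.integer(has_spread && !pairing),
               combination = as.integer(pairing))
  brand <- c(premium = as.integer(identical(condition$cracker, "plain")),
             sesame = as.integer(identical(condition$cracker, "sesame")),
             peanut = as.integer(identical(condition$spread, "peanut")),
             strawberry = as.integer(identical(condition$spread,
                                               "strawberry")))
  switch(cfg$aux_config,
         none = stats::setNames(integer(0), character(0)),
         combo = combo,
         cracker_spread = cs_both,
         exclusive3 = cs_excl,
         brand = brand,
         brand_combo = c(brand, combo),
         brand_cs = c(brand, cs_both),
         brand_all = c(brand,
                       if (cfg$exclusive_composite) cs_excl
                       else c(cs_both, combo)))
}

#' Encode a curve set as a model input series
#'
#' Assembles the time-by-channel input matrix fed to the reservoir: the 12
#' attribute dominance-proportion channels (the transposed TDS matrix,
#' unmodified) followed by the configuration's constant auxiliary flag
#' channels describing the sample context.
#'
#' @param curve_set A `curve_set`.
#' @param condition One-row condition descriptor (see [get_condition()]);
#'   looked up from the curve set's condition id by default.
#' @param cfg An [encoding_config()].
#' @return Numeric matrix `[n_points x (12 + aux_dimension(cfg))]` with
#'   channel names as column names.
#' @examples
#' \dontrun{
#' u <- encode_curve_set(cs, cfg = encoding_config("combo"))
#' }
#' @export
encode_curve_set <- function(curve_set,
                             condition = get_condition(
                               curve_set$condition_id),
                             cfg = encoding_config("none")) {
  stopifnot(inherits(curve_set, "curve_set"))
  if (!identical(condition$condition_id, curve_set$condition_id)) {
    stop("condition descriptor does not match the curve set", call. = FALSE)
  }
  u <- t(curve_set$tds)
  flags <- condition_flags(condition, cfg)
  if (length(flags)) {
    fm <- matrix(rep(as.numeric(flags), each = nrow(u)), nrow = nrow(u),
                 dimnames = list(NULL, names(flags)))
    u <- cbind(u, fm)
  }
  u
}
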