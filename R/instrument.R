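#' @title NEMS-S-CHILE instrument definitions
#' @name instrument
#' @description
#' An instrument definition packages the food checklist an auditor walks a
#' store with: foods, the measures they belong to, the NOVA processing group
#' of each measure, per-food availability point allocations, and the quality,
#' variety and price-comparison bonus rules. The packaged default is the
#' NEMS-S-CHILE checklist (62 foods, 27 measures, 4 NOVA groups, total score
#' spanning -30 to 100 points).
NULL

# NOVA processing groups; fixed for every definition.
nova_groups <- function() {
  data.frame(
    code = 1:4,
    label = c(
      "Natural or minimally processed foods",
      "Processed culinary ingredients",
      "Processed foods",
      "Ultra-processed food products"
    ),
    stringsAsFactors = FALSE
  )
}

abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("nems_validation_error", "error", "condition")))
}

abort_integrity <- function(msg) {
  stop(errorCondition(msg, class = c("nems_integrity_error", "error", "condition")))
}

#' Construct an instrument definition
#'
#' Low-level constructor used by [load_instrument()] and by tests that build
#' toy checklists. All structural invariants are checked: every food belongs
#' to exactly one measure, dimensions are non-empty, the quality dimension is
#' restricted to fresh-produce measures, group 1-3 foods carry positive
#' availability points and group 4 foods negative ones, and every
#' `healthier` price variant has a `regular` partner in the same measure.
#'
#' @param foods data.frame with columns `id`, `name`, `measure_id`, `points`,
#'   logical dimension flags `availability`, `quality`, `price`, `variety`,
#'   `variant` (one of `"regular"`, `"healthier"`, `"not_applicable"`) and
#'   `counts_as_variety` (does the food count toward its measure's variety
#'   tally, e.g. eggs listed under the legume measure do not).
#' @param measures data.frame with columns `id`, `name`, `group` (NOVA code
#'   1-4), `quality_eligible`, `variety_eligible`.
#' @param price_pairs data.frame with columns `healthier`, `regular` (food
#'   ids compared on unit price).
#' @param quality_rule,variety_rule,price_rule lists of rule constants; see
#'   [default_chile_instrument()] for the packaged values.
#' @param version character version tag.
#' @return An object of class `nems_instrument`.
#' @export
new_instrument <- function(foods, measures, price_pairs = NULL,
                           quality_rule = default_quality_rule(),
                           variety_rule = default_variety_rule(),
                           price_rule = default_price_rule(),
                           version = "custom") {
  foods <- as.data.frame(foods, stringsAsFactors = FALSE)
  measures <- as.data.frame(measures, stringsAsFactors = FALSE)
  if (is.null(price_pairs)) {
    price_pairs <- data.frame(healthier = character(), regular = character(),
                              stringsAsFactors = FALSE)
  }
  if (is.null(foods$variant)) foods$variant <- "not_applicable"
  if (is.null(foods$counts_as_variety)) foods$counts_as_variety <- TRUE
  for (col in c("availability", "quality", "price", "variety")) {
    if (is.null(foods[[col]])) foods[[col]] <- FALSE
  }
  foods$group <- measures$group[match(foods$measure_id, measures$id)]
  instr <- structure(
    list(
      version = version,
      groups = nova_groups(),
      measures = measures,
      foods = foods,
      price_pairs = price_pairs,
      quality_rule = quality_rule,
      variety_rule = variety_rule,
      price_rule = price_rule
    ),
    class = "nems_instrument"
  )
  validate_instrument(instr)
  instr
}

default_quality_rule <- function() {
  # item adequate iff fraction of units in maximum condition > 0.75;
  # store points from the fraction of available produce items adequate:
  # > 0.75 -> 3, [0.50, 0.75] -> 2, [0.25, 0.50) -> 1, < 0.25 -> 0
  list(item_adequate_threshold = 0.75,
       store_breaks = c(0.25, 0.50, 0.75),
       store_points = c(0L, 1L, 2L, 3L))
}

default_variety_rule <- function() {
  # fruits / vegetables: strictly more than 3 *additional* varieties -> +3
  # per measure; legumes: strictly more than 5 varieties in total -> +4
  list(produce_extra_threshold = 3L, produce_bonus = 3L,
       legume_variety_threshold = 5L, legume_bonus = 4L)
}

default_price_rule <- function() {
  # +1 per (healthier, regular) pair whose healthier unit price is no higher
  list(bonus_points = 1L)
}

validate_instrument <- function(instr) {
  foods <- instr$foods
  measures <- instr$measures
  required <- c("id", "name", "measure_id", "points",
                "availability", "quality", "price", "variety",
                "variant", "counts_as_variety", "group")
  missing_cols <- setdiff(required, names(foods))
  if (length(missing_cols) > 0) {
    abort_validation(paste0("foods table is missing column(s): ",
                            paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(foods$id)) {
    abort_validation("duplicate food id(s) in instrument definition")
  }
  if (anyDuplicated(measures$id)) {
    abort_validation("duplicate measure id(s) in instrument definition")
  }
  unknown <- setdiff(foods$measure_id, measures$id)
  if (length(unknown) > 0) {
    abort_validation(paste0("food(s) reference unknown measure: ",
                            paste(unknown, collapse = ", ")))
  }
  if (!all(measures$group %in% 1:4)) {
    abort_validation("measure group codes must be NOVA codes 1-4")
  }
  dims <- foods$availability | foods$quality | foods$price | foods$variety
  if (!all(dims)) {
    abort_validation(paste0("food(s) with empty dimension set: ",
                            paste(foods$id[!dims], collapse = ", ")))
  }
  q_ok <- measures$quality_eligible[match(foods$measure_id, measures$id)]
  if (any(foods$quality & !q_ok)) {
    abort_validation(paste0(
      "quality dimension outside fresh-produce measures: ",
      paste(foods$id[foods$quality & !q_ok], collapse = ", ")))
  }
  bad_pos <- foods$group %in% 1:3 & foods$points <= 0
  bad_neg <- foods$group == 4 & foods$points >= 0
  if (any(bad_pos)) {
    abort_integrity(paste0(
      "group 1-3 food(s) must have positive availability points: ",
      paste(foods$id[bad_pos], collapse = ", ")))
  }
  if (any(bad_neg)) {
    abort_integrity(paste0(
      "group 4 food(s) must have negative availability points: ",
      paste(foods$id[bad_neg], collapse = ", ")))
  }
  if (!all(foods$variant %in% c("regular", "healthier", "not_applicable"))) {
    abort_validation("food variant must be regular, healthier or not_applicable")
  }
  pp <- instr$price_pairs
  if (nrow(pp) > 0) {
    ids_ok <- pp$healthier %in% foods$id & pp$regular %in% foods$id
    if (!all(ids_ok)) abort_validation("price pair references unknown food id")
    same_measure <- foods$measure_id[match(pp$healthier, foods$id)] ==
      foods$measure_id[match(pp$regular, foods$id)]
    if (!all(same_measure)) {
      abort_validation("price pair members must share a measure")
    }
  }
  healthier <- foods$id[foods$variant == "healthier"]
  unpaired <- setdiff(healthier, pp$healthier)
  if (length(unpaired) > 0) {
    abort_validation(paste0("healthier variant(s) without a regular partner: ",
                            paste(unpaired, collapse = ", ")))
  }
  invisible(instr)
}

#' Load an instrument definition from JSON
#'
#' Reads and validates a JSON instrument definition. When the file declares
#' expected food/measure counts (`n_foods`, `n_measures`), a mismatch with
#' the actual content raises an integrity error.
#'
#' @param path path to a JSON instrument file.
#' @return A validated `nems_instrument`.
#' @seealso [default_chile_instrument()], [write_instrument()]
#' @export
load_instrument <- function(path) {
  if (!file.exists(path)) abort_validation(paste0("no such instrument file: ", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  for (field in c("foods", "measures", "version")) {
    if (is.null(raw[[field]])) {
      abort_validation(paste0("instrument file missing field: ", field))
    }
  }
  foods <- raw$foods
  measures <- raw$measures
  # dimensions arrive as a list of character vectors
  dim_list <- foods$dimensions
  foods$dimensions <- NULL
  for (d in c("availability", "quality", "price", "variety")) {
    foods[[d]] <- vapply(dim_list, function(x) d %in% unlist(x), logical(1))
  }
  pp <- raw$price_pairs
  if (is.null(pp) || length(pp) == 0) pp <- NULL
  qr <- raw$quality_rule
  vr <- raw$variety_rule
  pr <- raw$price_rule
  instr <- new_instrument(
    foods = foods, measures = measures, price_pairs = pp,
    quality_rule = list(
      item_adequate_threshold = qr$item_adequate_threshold,
      store_breaks = as.numeric(qr$store_breaks),
      store_points = as.integer(qr$store_points)),
    variety_rule = list(
      produce_extra_threshold = as.integer(vr$produce_extra_threshold),
      produce_bonus = as.integer(vr$produce_bonus),
      legume_variety_threshold = as.integer(vr$legume_variety_threshold),
      legume_bonus = as.integer(vr$legume_bonus)),
    price_rule = list(bonus_points = as.integer(pr$bonus_points)),
    version = raw$version
  )
  if (!is.null(raw$n_foods) && nrow(instr$foods) != raw$n_foods) {
    abort_integrity(sprintf("instrument declares %d foods but contains %d",
                            raw$n_foods, nrow(instr$foods)))
  }
  if (!is.null(raw$n_measures) && nrow(instr$measures) != raw$n_measures) {
    abort_integrity(sprintf("instrument declares %d measures but contains %d",
                            raw$n_measures, nrow(instr$measures)))
  }
  instr
}

#' Write an instrument definition to JSON
#'
#' Serialises to the same schema [load_instrument()] reads; loading the
#' written file reproduces the definition exactly, and rewriting a loaded
#' file is byte-stable.
#'
#' @param instr a `nems_instrument`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_instrument <- function(instr, path) {
  foods <- instr$foods
  dim_names <- c("availability", "quality", "price", "variety")
  dims <- lapply(seq_len(nrow(foods)), function(i) {
    dim_names[c(foods$availability[i], foods$quality[i],
                foods$price[i], foods$variety[i])]
  })
  foods_out <- foods[, c("id", "name", "measure_id", "points",
                         "variant", "counts_as_variety")]
  foods_out$dimensions <- dims
  out <- list(
    schema_version = "1.0",
    instrument = "NEMS-S-CHILE",
    version = instr$version,
    n_foods = nrow(instr$foods),
    n_measures = nrow(instr$measures),
    groups = instr$groups,
    measures = instr$measures,
    foods = foods_out,
    price_pairs = instr$price_pairs,
    quality_rule = instr$quality_rule,
    variety_rule = instr$variety_rule,
    price_rule = instr$price_rule
  )
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' The packaged NEMS-S-CHILE instrument
#'
#' Returns the Chilean adaptation of the NEMS-S checklist: 62 foods in 27
#' measures across the four NOVA processing groups, scored so that the
#' attainable total spans exactly -30 to 100 points. Availability earns
#' positive points for group 1-3 foods (the natural/minimally processed
#' group 1 concentrating the highest share) and negative points for the
#' eight ultra-processed group 4 foods. Fresh fruit and vegetable measures
#' additionally carry the store quality bonus (0-3 points) and the
#' extra-variety bonus (+3 per measure beyond 3 additional varieties);
#' legumes earn +4 beyond 5 varieties; seven (healthier, regular) pairs earn
#' +1 each when the healthier option's unit price is no higher.
#'
#' The per-food split of availability points within each measure is a
#' reconstruction: the published checklist fixes the group subtotal maxima
#' (fruits & vegetables 30, other group-1 foods 40, group 2 10, group 3 20,
#' group 4 -30) but not every per-food value, so the packaged allocation is
#' synthetic within those constraints and can be overridden by editing the
#' JSON definition (see [load_instrument()]).
#'
#' @return A validated `nems_instrument` with 62 foods and 27 measures.
#' @examples
#' instr <- default_chile_instrument()
#' nrow(instr$foods)
#' score_bounds(instr)
#' @export
default_chile_instrument <- function() {
  path <- system.file("extdata", "nems_s_chile.json", package = "nemschile",
                      mustWork = TRUE)
  load_instrument(path)
}

#' Attainable score range of an instrument
#'
#' The score components are additive and independent, so the extremes follow
#' from greedy enumeration: the maximum is attained by a store offering
#' every group 1-3 food with every quality, variety and price bonus earned
#' and no group 4 food; the minimum by a store offering only the group 4
#' foods.
#'
#' @param instr a `nems_instrument`.
#' @return Named numeric vector `c(min = , max = )`.
#' @examples
#' score_bounds(default_chile_instrument())  # -30, 100
#' @export
score_bounds <- function(instr) {
  stopifnot(inherits(instr, "nems_instrument"))
  foods <- instr$foods
  max_avail <- sum(foods$points[foods$group %in% 1:3])
  min_avail <- sum(foods$points[foods$group == 4])
  quality_max <- if (any(foods$quality)) max(instr$quality_rule$store_points) else 0L
  vm <- instr$measures[instr$measures$variety_eligible, , drop = FALSE]
  variety_max <- 0L
  if (nrow(vm) > 0) {
    variety_max <- sum(ifelse(vm$quality_eligible,
                              instr$variety_rule$produce_bonus,
                              instr$variety_rule$legume_bonus))
  }
  price_max <- nrow(instr$price_pairs) * instr$price_rule$bonus_points
  c(min = as.numeric(min_avail),
    max = as.numeric(max_avail + quality_max + variety_max + price_max))
}

#' @export
print.nems_instrument <- function(x, ...) {
  b <- score_bounds(x)
  cat(sprintf("NEMS instrument '%s': %d foods, %d measures, score range [%g, %g]\n",
              x$version, nrow(x$foods), nrow(x$measures), b["min"], b["max"]))
  tab <- table(factor(x$foods$group, levels = 1:4))
  cat(sprintf("  foods per NOVA group: G1=%d G2=%d G3=%d G4=%d\n",
              tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

# --- internal accessors -----------------------------------------------------

# ids of foods carrying the quality dimension (fresh produce)
produce_food_ids <- function(instr) instr$foods$id[instr$foods$quality]

# variety-eligible measures split by kind: produce (fruit/vegetable) measures
# are the quality-eligible ones, the rest (legumes) use the total-variety rule
variety_measures <- function(instr) {
  m <- instr$measures[instr$measures$variety_eligible, , drop = FALSE]
  m$kind <- ifelse(m$quality_eligible, "produce", "legume")
  m
}
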