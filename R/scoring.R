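#' @title NEMS-S-CHILE score computation
#' @name scoring
#' @description
#' The total store score adds four independent components: availability
#' points per food (positive for NOVA groups 1-3, negative for the
#' ultra-processed group 4), a store-level produce quality bonus (0-3), the
#' extra-variety bonuses (+3 per fruit/vegetable measure, +4 for legumes)
#' and the healthier-vs-regular price-comparison bonuses. The packaged
#' instrument yields totals between -30 and 100.
NULL

# observations of one store x evaluator audit, checked against the instrument
check_single_audit <- function(audit, instr) {
  audit <- as.data.frame(audit)
  if (length(unique(paste(audit$store_id, audit$evaluator_id))) > 1) {
    abort_validation("expected observations from a single store x evaluator audit")
  }
  if (!setequal(audit$food_id, instr$foods$id) ||
      nrow(audit) != nrow(instr$foods)) {
    abort_validation("audit must contain exactly one observation per instrument food")
  }
  audit
}

#' Availability subtotals of one audit
#'
#' Sums the allocation-table points of the available foods, split into the
#' reporting components: fruits & vegetables, other group-1 foods, group 2,
#' group 3, and group 4 reported as a positive magnitude.
#'
#' @param audit observations of one store x evaluator (one row per food).
#' @param instr a `nems_instrument`.
#' @return Named numeric vector with elements `fruits_vegetables`,
#'   `other_group1`, `group2`, `group3`, `group4_magnitude`.
#' @export
availability_points <- function(audit, instr) {
  audit <- check_single_audit(audit, instr)
  foods <- instr$foods
  idx <- match(audit$food_id, foods$id)
  pts <- ifelse(audit$available, foods$points[idx], 0)
  grp <- foods$group[idx]
  produce <- foods$quality[idx]  # fresh fruit & vegetable foods
  c(fruits_vegetables = sum(pts[grp == 1 & produce]),
    other_group1 = sum(pts[grp == 1 & !produce]),
    group2 = sum(pts[grp == 2]),
    group3 = sum(pts[grp == 3]),
    group4_magnitude = -sum(pts[grp == 4]))
}

#' Produce quality points of one audit
#'
#' An available produce item is adequate iff more than 75% of its units meet
#' the maximum organoleptic condition (`adequate_fraction >
#' item_adequate_threshold`, strict). Store points come from the fraction of
#' *available* produce items that are adequate: more than 75% earns 3
#' points, 50-74% earns 2, 25-49% earns 1, below 25% earns 0. A store with
#' no produce available scores 0 and is flagged not assessable (attribute
#' `assessable = FALSE`).
#'
#' @inheritParams availability_points
#' @return Integer in 0..3 with attribute `assessable`.
#' @export
quality_points <- function(audit, instr) {
  audit <- check_single_audit(audit, instr)
  qids <- produce_food_ids(instr)
  rows <- audit[audit$food_id %in% qids & audit$available, , drop = FALSE]
  rule <- instr$quality_rule
  if (nrow(rows) == 0) {
    return(structure(rule$store_points[1], assessable = FALSE))
  }
  adequate <- !is.na(rows$adequate_fraction) &
    rows$adequate_fraction > rule$item_adequate_threshold
  frac <- mean(adequate)
  pts <- if (frac > rule$store_breaks[3]) {
    rule$store_points[4]
  } else if (frac >= rule$store_breaks[2]) {
    rule$store_points[3]
  } else if (frac >= rule$store_breaks[1]) {
    rule$store_points[2]
  } else {
    rule$store_points[1]
  }
  structure(pts, assessable = TRUE)
}

# per-measure recorded variety count: highest non-missing extra_varieties
# among the measure's available rows (recorded on any row of the measure)
measure_extras <- function(audit, instr, measure_id) {
  fids <- instr$foods$id[instr$foods$measure_id == measure_id]
  v <- audit$extra_varieties[audit$food_id %in% fids]
  v <- v[!is.na(v)]
  if (length(v) == 0) 0L else max(v)
}

#' Extra-variety points of one audit
#'
#' Fruit and vegetable measures earn +3 each when the store offers strictly
#' more than 3 varieties beyond the checklist. Legumes earn +4 when the
#' total number of legume varieties on offer (available checklist legumes
#' plus recorded extras) strictly exceeds 5.
#'
#' @inheritParams availability_points
#' @return Integer total with attribute `by_measure` (named vector of
#'   per-measure contributions).
#' @export
variety_points <- function(audit, instr) {
  audit <- check_single_audit(audit, instr)
  vm <- variety_measures(instr)
  rule <- instr$variety_rule
  contrib <- integer(nrow(vm))
  names(contrib) <- vm$id
  for (i in seq_len(nrow(vm))) {
    extras <- measure_extras(audit, instr, vm$id[i])
    if (vm$kind[i] == "produce") {
      if (extras > rule$produce_extra_threshold) contrib[i] <- rule$produce_bonus
    } else {
      fids <- instr$foods$id[instr$foods$measure_id == vm$id[i] &
                               instr$foods$counts_as_variety]
      n_checklist <- sum(audit$available[audit$food_id %in% fids])
      if (n_checklist + extras > rule$legume_variety_threshold) {
        contrib[i] <- rule$legume_bonus
      }
    }
  }
  structure(sum(contrib), by_measure = contrib)
}

#' Price-comparison points of one audit
#'
#' For each (healthier, regular) pair of the instrument, the bonus is earned
#' when both foods are available with a recorded unit price and the
#' healthier option's unit price is less than or equal to the regular one's
#' (a tie earns the bonus: the healthy option is no more expensive). Pairs
#' with either price missing contribute 0. Fruits and vegetables carry no
#' price comparison.
#'
#' @inheritParams availability_points
#' @return Integer total with attribute `by_pair` (named by healthier food
#'   id, the group each bonus feeds in attribute `pair_group`).
#' @export
price_points <- function(audit, instr) {
  audit <- check_single_audit(audit, instr)
  pp <- instr$price_pairs
  bonus <- instr$price_rule$bonus_points
  won <- integer(nrow(pp))
  if (nrow(pp) > 0) names(won) <- pp$healthier
  for (i in seq_len(nrow(pp))) {
    h <- audit[audit$food_id == pp$healthier[i], ]
    r <- audit[audit$food_id == pp$regular[i], ]
    if (isTRUE(h$available) && isTRUE(r$available) &&
        !is.na(h$unit_price) && !is.na(r$unit_price) &&
        h$unit_price <= r$unit_price) {
      won[i] <- bonus
    }
  }
  grp <- instr$foods$group[match(pp$healthier, instr$foods$id)]
  structure(sum(won), by_pair = won, pair_group = grp)
}

#' Total NEMS-S-CHILE score of one audit
#'
#' Assembles the score report for one store x evaluator audit. Components
#' satisfy `total = group1_total + group2 + group3 - group4_magnitude` and
#' `group1_total = fruits_vegetables + other_group1`; bonuses are folded
#' into the component of the measure that earns them (quality and
#' fruit/vegetable variety into `fruits_vegetables`; legume variety and the
#' rice price pair into `other_group1`; remaining price pairs into their
#' measure's group).
#'
#' @inheritParams availability_points
#' @return A one-row data.frame of class `nems_score` with columns
#'   `store_id`, `store_type`, `evaluator_id`, `fruits_vegetables`,
#'   `other_group1`, `group1_total`, `group2`, `group3`,
#'   `group4_magnitude`, `quality_points`, `variety_points`, `price_points`,
#'   `quality_assessable`, `total`.
#' @examples
#' instr <- default_chile_instrument()
#' aud <- simulate_audits(sim_config(n_supermarkets = 1, n_street_markets = 0,
#'                                   seed = 1), instr)
#' total_score(split_audits(aud)[[1]], instr)
#' @export
total_score <- function(audit, instr) {
  audit <- check_single_audit(audit, instr)
  avail <- availability_points(audit, instr)
  qual <- quality_points(audit, instr)
  vari <- variety_points(audit, instr)
  pric <- price_points(audit, instr)

  vm <- variety_measures(instr)
  by_meas <- attr(vari, "by_measure")
  produce_variety <- sum(by_meas[vm$id[vm$kind == "produce"]])
  legume_variety <- sum(by_meas[vm$id[vm$kind == "legume"]])
  by_pair <- attr(pric, "by_pair")
  pair_group <- attr(pric, "pair_group")
  price_g1 <- sum(by_pair[pair_group == 1])
  price_g2 <- sum(by_pair[pair_group == 2])
  price_g3 <- sum(by_pair[pair_group == 3])

  fv <- avail[["fruits_vegetables"]] + as.integer(qual) + produce_variety
  other_g1 <- avail[["other_group1"]] + legume_variety + price_g1
  g2 <- avail[["group2"]] + price_g2
  g3 <- avail[["group3"]] + price_g3
  g4 <- avail[["group4_magnitude"]]
  total <- fv + other_g1 + g2 + g3 - g4

  out <- data.frame(
    store_id = audit$store_id[1],
    store_type = audit$store_type[1],
    evaluator_id = audit$evaluator_id[1],
    fruits_vegetables = fv,
    other_group1 = other_g1,
    group1_total = fv + other_g1,
    group2 = g2,
    group3 = g3,
    group4_magnitude = g4,
    quality_points = as.integer(qual),
    variety_points = as.integer(vari),
    price_points = as.integer(pric),
    quality_assessable = attr(qual, "assessable"),
    total = total,
    stringsAsFactors = FALSE
  )
  class(out) <- c("nems_score", "data.frame")
  out
}

#' Score every audit in an audit set
#'
#' @param audits a `nems_audits` object.
#' @param instr a `nems_instrument`.
#' @return Data.frame with one [total_score()] row per store x evaluator,
#'   ordered by store then evaluator.
#' @export
score_audits <- function(audits, instr) {
  singles <- split_audits(audits)
  rows <- lapply(singles, total_score, instr = instr)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$store_id, out$evaluator_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("nems_score", "data.frame")
  out
}
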