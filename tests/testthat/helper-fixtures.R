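# Fixtures are built in code: toy instruments, hand-made audits, and
# independent brute-force oracles used to cross-check the scoring engine.

# two-food toy: one group-1 food worth +5, one group-4 food worth -3,
# no quality/variety/price machinery
toy2_instrument <- function() {
  measures <- data.frame(
    id = c("m1", "m4"), name = c("Staple", "Junk"), group = c(1L, 4L),
    quality_eligible = FALSE, variety_eligible = FALSE,
    stringsAsFactors = FALSE)
  foods <- data.frame(
    id = c("staple", "junk"), name = c("Staple food", "Junk food"),
    measure_id = c("m1", "m4"), points = c(5L, -3L),
    availability = TRUE, quality = FALSE, price = FALSE, variety = FALSE,
    stringsAsFactors = FALSE)
  new_instrument(foods, measures, version = "toy2")
}

# richer <=12-food toy exercising every bonus: produce quality+variety,
# legume variety, two price pairs, a group-3 food and two group-4 foods
toy12_instrument <- function() {
  measures <- data.frame(
    id = c("fruit", "legume", "rice", "oil", "snack", "soda"),
    name = c("Fruit", "Legume", "Rice", "Oil", "Snack", "Soda"),
    group = c(1L, 1L, 1L, 2L, 3L, 4L),
    quality_eligible = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    variety_eligible = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  f <- function(id, m, pts, dims, variant = "not_applicable") {
    data.frame(id = id, name = toupper(id), measure_id = m, points = pts,
               availability = TRUE, quality = "quality" %in% dims,
               price = "price" %in% dims, variety = "variety" %in% dims,
               variant = variant, stringsAsFactors = FALSE)
  }
  foods <- rbind(
    f("apple", "fruit", 2L, c("quality", "variety")),
    f("pear", "fruit", 2L, c("quality", "variety")),
    f("lentil", "legume", 1L, "variety"),
    f("bean", "legume", 1L, "variety"),
    f("rice_w", "rice", 2L, "price", "regular"),
    f("rice_i", "rice", 2L, "price", "healthier"),
    f("oil_v", "oil", 1L, "price", "regular"),
    f("oil_o", "oil", 1L, "price", "healthier"),
    f("snack", "snack", 2L, character(0)),
    f("soda", "soda", -3L, character(0)),
    f("candy", "soda", -2L, character(0)))
  pairs <- data.frame(healthier = c("rice_i", "oil_o"),
                      regular = c("rice_w", "oil_v"), stringsAsFactors = FALSE)
  new_instrument(foods, measures, pairs, version = "toy12")
}

# one produce measure carrying 20 quality-rated items, for exercising the
# store quality bands on a 20-item denominator
quality20_instrument <- function() {
  measures <- data.frame(
    id = "produce", name = "Produce", group = 1L,
    quality_eligible = TRUE, variety_eligible = TRUE, stringsAsFactors = FALSE)
  foods <- data.frame(
    id = sprintf("item%02d", 1:20), name = sprintf("Produce item %d", 1:20),
    measure_id = "produce", points = 1L,
    availability = TRUE, quality = TRUE, price = FALSE, variety = TRUE,
    stringsAsFactors = FALSE)
  new_instrument(foods, measures, version = "quality20")
}

# full-row audit for any instrument; everything defaults to unavailable
make_audit <- function(instr, available = character(0), store_id = "S1",
                       store_type = "supermarket", evaluator_id = "E1",
                       prices = NULL, brands = NULL, fracs = NULL,
                       extras = NULL) {
  foods <- instr$foods
  obs <- data.frame(
    store_id = store_id, store_type = store_type, evaluator_id = evaluator_id,
    food_id = foods$id, available = foods$id %in% available,
    unit_price = NA_integer_, brand_size_key = NA_character_,
    adequate_fraction = NA_real_, extra_varieties = NA_integer_,
    audit_date = "2018-04-15", stringsAsFactors = FALSE)
  set_col <- function(obs, col, values) {
    for (fid in names(values)) obs[obs$food_id == fid, col] <- values[[fid]]
    obs
  }
  if (!is.null(prices)) obs <- set_col(obs, "unit_price", prices)
  if (!is.null(brands)) obs <- set_col(obs, "brand_size_key", brands)
  if (!is.null(fracs)) obs <- set_col(obs, "adequate_fraction", fracs)
  if (!is.null(extras)) obs <- set_col(obs, "extra_varieties", extras)
  obs
}

# the best-case audit of an instrument: every group 1-3 food available with
# adequate quality, abundant varieties and price-bonus-winning prices
best_case_audit <- function(instr, ...) {
  ids <- instr$foods$id[instr$foods$group %in% 1:3]
  price_ids <- instr$foods$id[instr$foods$price]
  vm <- variety_carrier_ids(instr)
  make_audit(
    instr, available = ids, ...,
    prices = stats::setNames(as.list(rep(1000L, length(price_ids))), price_ids),
    brands = stats::setNames(as.list(paste0(price_ids, "_b")), price_ids),
    fracs = stats::setNames(as.list(rep(1.0, sum(instr$foods$quality))),
                            instr$foods$id[instr$foods$quality]),
    extras = stats::setNames(as.list(rep(10L, length(vm))), vm))
}

worst_case_audit <- function(instr, ...) {
  make_audit(instr, available = instr$foods$id[instr$foods$group == 4], ...)
}

# one available, variety-flagged food id per variety-eligible measure
variety_carrier_ids <- function(instr) {
  vmeas <- instr$measures$id[instr$measures$variety_eligible]
  vapply(vmeas, function(mid) {
    instr$foods$id[instr$foods$measure_id == mid & instr$foods$variety][1]
  }, character(1))
}

# ---------------------------------------------------------------------------
# Independent oracle: re-derive the total score of one audit from first
# principles (straight transcription of the printed rules, organised
# differently from the package implementation).
oracle_total <- function(audit, instr) {
  foods <- instr$foods
  total <- 0
  for (i in seq_len(nrow(audit))) {
    if (audit$available[i]) {
      total <- total + foods$points[foods$id == audit$food_id[i]]
    }
  }
  # quality: fraction of available produce items with >75% adequate units
  qids <- foods$id[foods$quality]
  qrows <- audit[audit$food_id %in% qids & audit$available, ]
  if (nrow(qrows) > 0) {
    frac <- mean(!is.na(qrows$adequate_fraction) & qrows$adequate_fraction > 0.75)
    total <- total + if (frac > 0.75) 3 else if (frac >= 0.5) 2 else
      if (frac >= 0.25) 1 else 0
  }
  # variety bonuses
  for (mid in instr$measures$id[instr$measures$variety_eligible]) {
    fids <- foods$id[foods$measure_id == mid]
    ev <- audit$extra_varieties[audit$food_id %in% fids]
    ev <- if (all(is.na(ev))) 0 else max(ev, na.rm = TRUE)
    if (instr$measures$quality_eligible[instr$measures$id == mid]) {
      if (ev > 3) total <- total + 3
    } else {
      countable <- foods$id[foods$measure_id == mid & foods$counts_as_variety]
      n_avail <- sum(audit$available[audit$food_id %in% countable])
      if (n_avail + ev > 5) total <- total + 4
    }
  }
  # price-comparison bonuses
  pp <- instr$price_pairs
  for (i in seq_len(nrow(pp))) {
    h <- audit[audit$food_id == pp$healthier[i], ]
    r <- audit[audit$food_id == pp$regular[i], ]
    if (h$available && r$available && !is.na(h$unit_price) &&
        !is.na(r$unit_price) && h$unit_price <= r$unit_price) {
      total <- total + instr$price_rule$bonus_points
    }
  }
  total
}

# Independent oracle for score bounds: exhaustive enumeration of all 2^n
# availability patterns, taking the best / worst attainable bonus state for
# each pattern via oracle_total on explicitly constructed audits.
oracle_bounds <- function(instr) {
  ids <- instr$foods$id
  n <- length(ids)
  stopifnot(n <= 12)
  price_ids <- instr$foods$id[instr$foods$price]
  vm <- variety_carrier_ids(instr)
  best <- -Inf
  worst <- Inf
  for (mask in 0:(2^n - 1)) {
    avail <- ids[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    hi <- make_audit(
      instr, available = avail,
      prices = stats::setNames(as.list(rep(1000L, length(price_ids))), price_ids),
      fracs = stats::setNames(as.list(rep(1.0, sum(instr$foods$quality))),
                              instr$foods$id[instr$foods$quality]),
      extras = stats::setNames(as.list(rep(10L, sum(vm %in% avail))),
                               vm[vm %in% avail]))
    lo <- make_audit(instr, available = avail)
    best <- max(best, oracle_total(hi, instr))
    worst <- min(worst, oracle_total(lo, instr))
  }
  c(min = worst, max = best)
}

# Exact two-sided Mann-Whitney p by enumerating all assignments of the
# pooled observations to the two groups (distinct values assumed).
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  u_stat <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  u_obs <- u_stat(x, y)
  combos <- utils::combn(length(pooled), m)
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mu <- m * (length(y)) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
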