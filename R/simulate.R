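#' @title Synthetic paired-evaluator audits
#' @name synthetic_data
#' @description
#' A seeded generator of store audits with the statistical structure the
#' reliability analysis assumes: evaluator 1 records the store's true state;
#' evaluator 2 records the truth with independent symmetric per-item
#' recording errors (availability flips, small price reading noise,
#' occasional variety miscounts). Default store counts match the study
#' design (17 supermarkets, 9 street markets) and default availability
#' prevalences point the published way: processed and ultra-processed foods
#' commoner in supermarkets, fresh produce richer in street markets.
NULL

default_prevalence <- function() {
  # rows: component; columns: store type. Direction-calibrated only: true
  # field prevalences are unpublished.
  matrix(c(0.80, 0.95,   # produce (fresh fruit & vegetables)
           0.85, 0.75,   # other group 1
           0.90, 0.30,   # group 2
           0.85, 0.40,   # group 3
           0.95, 0.20),  # group 4
         ncol = 2, byrow = TRUE,
         dimnames = list(c("produce", "other_g1", "g2", "g3", "g4"),
                         c("supermarket", "street_market")))
}

#' Simulation configuration
#'
#' Parameters of the synthetic audit generator. Defaults emulate the study
#' conditions: 17 supermarkets and 9 street markets, each audited twice the
#' same day, with a 2% chance that the second evaluator's availability
#' record flips on any item.
#'
#' @param n_supermarkets,n_street_markets store counts (defaults 17 and 9).
#' @param prevalence 5 x 2 matrix of availability probabilities, rows
#'   `produce`, `other_g1`, `g2`, `g3`, `g4`, columns `supermarket`,
#'   `street_market`; see `nemschile:::default_prevalence()`.
#' @param rater_flip_prob probability the second evaluator's availability
#'   record flips on one item (default 0.02).
#' @param price_location median unit price in CLP of the lognormal
#'   store-level price model (default 1500); per-food multipliers are drawn
#'   once per simulation.
#' @param price_cv coefficient of variation (log scale SD) of store-level
#'   prices (default 0.25).
#' @param price_reading_sd log-scale SD of the second evaluator's price
#'   reading error (default 0.01).
#' @param brand_match_prob probability both evaluators price the same
#'   brand/size (default 0.9); otherwise the second evaluator records a
#'   different brand key and an independent price.
#' @param quality_beta length-2 shape parameters of the Beta distribution of
#'   the adequate-unit fraction of an available produce item (default
#'   `c(8, 2)`, mean 0.8 so most items clear the 75% adequacy threshold).
#' @param quality_reading_sd SD of the second evaluator's fraction reading
#'   error (default 0.05).
#' @param variety_rate Poisson mean of extra varieties per variety-eligible
#'   measure (default 1.5).
#' @param seed integer seed; all randomness derives from this one stream.
#' @return A `nems_sim_config` list.
#' @export
sim_config <- function(n_supermarkets = 17, n_street_markets = 9,
                       prevalence = default_prevalence(),
                       rater_flip_prob = 0.02,
                       price_location = 1500, price_cv = 0.25,
                       price_reading_sd = 0.01, brand_match_prob = 0.9,
                       quality_beta = c(8, 2), quality_reading_sd = 0.05,
                       variety_rate = 1.5, seed = 20180301) {
  cfg <- list(n_supermarkets = n_supermarkets,
              n_street_markets = n_street_markets,
              prevalence = prevalence,
              rater_flip_prob = rater_flip_prob,
              price_location = price_location, price_cv = price_cv,
              price_reading_sd = price_reading_sd,
              brand_match_prob = brand_match_prob,
              quality_beta = quality_beta,
              quality_reading_sd = quality_reading_sd,
              variety_rate = variety_rate, seed = seed)
  probs <- c(cfg$prevalence, cfg$rater_flip_prob, cfg$brand_match_prob)
  if (any(probs < 0 | probs > 1)) {
    abort_validation("probabilities must lie in [0, 1]")
  }
  if (n_supermarkets < 0 || n_street_markets < 0) {
    abort_validation("store counts must be non-negative")
  }
  if (!identical(dim(cfg$prevalence), c(5L, 2L))) {
    abort_validation("prevalence must be a 5 x 2 matrix (component x store type)")
  }
  structure(cfg, class = "nems_sim_config")
}

# component of a food for prevalence lookup
food_component <- function(instr) {
  f <- instr$foods
  ifelse(f$group == 1 & f$quality, "produce",
         ifelse(f$group == 1, "other_g1", paste0("g", f$group)))
}

#' Simulate a paired-evaluator audit set
#'
#' Draws the true state of each store (availability per food, store-level
#' unit prices, adequate-quality fractions, extra-variety counts), records
#' it as evaluator `E1`'s audit, and derives evaluator `E2`'s audit from the
#' truth with independent recording errors. Fully reproducible from
#' `cfg$seed`: the same configuration always yields a byte-identical CSV
#' through [write_audits()].
#'
#' @param cfg a [sim_config()].
#' @param instr a `nems_instrument`.
#' @return A validated `nems_audits` with two audits per store.
#' @examples
#' instr <- default_chile_instrument()
#' aud <- simulate_audits(sim_config(seed = 42), instr)
#' length(unique(aud$store_id))  # 26 stores
#' @export
simulate_audits <- function(cfg, instr) {
  stopifnot(inherits(cfg, "nems_sim_config"), inherits(instr, "nems_instrument"))
  withr::with_seed(cfg$seed, simulate_audits_impl(cfg, instr))
}

simulate_audits_impl <- function(cfg, instr) {
  foods <- instr$foods
  nf <- nrow(foods)
  comp <- food_component(instr)
  # per-food base price multiplier, one draw per simulation
  price_mult <- exp(stats::rnorm(nf, 0, 0.5))
  stores <- data.frame(
    store_id = c(sprintf("SUP%02d", seq_len(cfg$n_supermarkets)),
                 sprintf("MKT%02d", seq_len(cfg$n_street_markets))),
    store_type = rep(c("supermarket", "street_market"),
                     c(cfg$n_supermarkets, cfg$n_street_markets)),
    stringsAsFactors = FALSE)
  vm <- variety_measures(instr)
  # first variety-flagged food of each variety measure carries the count
  variety_carrier <- vapply(vm$id, function(mid) {
    foods$id[foods$measure_id == mid & foods$variety][1]
  }, character(1))

  rows <- vector("list", 2 * nrow(stores))
  for (s in seq_len(nrow(stores))) {
    st <- stores$store_type[s]
    prev <- cfg$prevalence[comp, st]
    truth_avail <- stats::runif(nf) < prev
    store_price <- as.integer(pmax(1, round(
      cfg$price_location * price_mult *
        exp(stats::rnorm(nf, 0, cfg$price_cv)))))
    brand_key <- paste0(foods$id, "_b1")
    truth_frac <- stats::rbeta(nf, cfg$quality_beta[1], cfg$quality_beta[2])
    truth_extras <- stats::rpois(nrow(vm), cfg$variety_rate)
    names(truth_extras) <- vm$id

    flip <- stats::runif(nf) < cfg$rater_flip_prob
    avail2 <- xor(truth_avail, flip)
    same_brand <- stats::runif(nf) < cfg$brand_match_prob
    price2 <- ifelse(
      same_brand,
      pmax(1, round(store_price * exp(stats::rnorm(nf, 0, cfg$price_reading_sd)))),
      pmax(1, round(cfg$price_location * price_mult *
                      exp(stats::rnorm(nf, 0, cfg$price_cv)))))
    brand2 <- ifelse(same_brand, brand_key, paste0(foods$id, "_b2"))
    frac2 <- pmin(1, pmax(0, truth_frac +
                            stats::rnorm(nf, 0, cfg$quality_reading_sd)))
    miscount <- stats::runif(nrow(vm)) < cfg$rater_flip_prob
    extras2 <- pmax(0L, truth_extras +
                      ifelse(miscount, sample(c(-1L, 1L), nrow(vm),
                                              replace = TRUE), 0L))

    mk_audit <- function(ev, avail, price, brand, frac, extras) {
      unit_price <- ifelse(avail & foods$price, as.integer(price), NA_integer_)
      bkey <- ifelse(avail & foods$price, brand, NA_character_)
      afrac <- ifelse(avail & foods$quality, frac, NA_real_)
      ev_col <- rep(NA_integer_, nf)
      for (m in seq_along(variety_carrier)) {
        i <- match(variety_carrier[m], foods$id)
        if (avail[i]) ev_col[i] <- as.integer(extras[m])
      }
      data.frame(store_id = stores$store_id[s], store_type = st,
                 evaluator_id = ev, food_id = foods$id,
                 available = avail, unit_price = unit_price,
                 brand_size_key = bkey, adequate_fraction = afrac,
                 extra_varieties = ev_col, audit_date = "2018-04-15",
                 stringsAsFactors = FALSE)
    }
    rows[[2 * s - 1]] <- mk_audit("E1", truth_avail, store_price, brand_key,
                                  truth_frac, truth_extras)
    rows[[2 * s]] <- mk_audit("E2", avail2, price2, brand2, frac2, extras2)
  }
  obs <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  obs$adequate_fraction <- ifelse(is.na(obs$adequate_fraction), NA_real_,
                                  round(obs$adequate_fraction, 3))
  audit_set(obs, instr)
}

#' Expected kappa under the truth-plus-flip model
#'
#' Closed-form expectation of Cohen's kappa when evaluator 1 records the
#' true availability (prevalence `p`) and evaluator 2 flips each record
#' independently with probability `f`: observed agreement is `1 - f`, and
#' expected agreement comes from the marginals `p` and `p + f(1 - 2p)`.
#' Used as the analytic oracle for the simulator's reliability structure.
#'
#' @param prevalence true availability probability, strictly inside (0, 1).
#' @param flip_prob per-item flip probability of the second evaluator.
#' @return Expected kappa; 1 when `flip_prob = 0`, 0 when `flip_prob = 0.5`
#'   (the second rater is then independent of the truth).
#' @export
expected_kappa <- function(prevalence, flip_prob) {
  if (prevalence <= 0 || prevalence >= 1) {
    abort_validation("prevalence must lie strictly inside (0, 1)")
  }
  if (flip_prob < 0 || flip_prob > 1) {
    abort_validation("flip_prob must lie in [0, 1]")
  }
  p <- prevalence
  f <- flip_prob
  p_o <- 1 - f
  q <- p + f * (1 - 2 * p)       # marginal of the second rater
  p_e <- p * q + (1 - p) * (1 - q)
  (p_o - p_e) / (1 - p_e)
}
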