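test_that("availability subtotals split by component", {
  instr <- toy2_instrument()
  both <- make_audit(instr, available = c("staple", "junk"))
  ap <- availability_points(both, instr)
  expect_equal(ap[["other_group1"]], 5)
  expect_equal(ap[["group4_magnitude"]], 3)
  none <- make_audit(instr)
  expect_true(all(availability_points(none, instr) == 0))
})

test_that("only the ultra-processed foods available floors the score at -30", {
  instr <- default_chile_instrument()
  audit <- worst_case_audit(instr)
  ap <- availability_points(audit, instr)
  expect_equal(ap[["group4_magnitude"]], 30)
  expect_equal(total_score(audit, instr)$total, -30)
})

test_that("quality points follow the printed bands with strict 75% edges", {
  instr <- quality20_instrument()
  pts_for <- function(n_adequate) {
    ids <- instr$foods$id[instr$foods$quality]
    fr <- c(rep(0.9, n_adequate), rep(0.5, 20 - n_adequate))
    audit <- make_audit(instr, available = ids,
                        fracs = stats::setNames(as.list(fr), ids))
    as.integer(quality_points(audit, instr))
  }
  expect_equal(pts_for(16), 3)  # 0.80 of items adequate
  expect_equal(pts_for(12), 2)  # 0.60
  expect_equal(pts_for(6), 1)   # 0.30
  expect_equal(pts_for(2), 0)   # 0.10
  # band edges: exactly 75% is not "more than 75%"; 50% and 25% are inclusive
  expect_equal(pts_for(15), 2)
  expect_equal(pts_for(10), 2)
  expect_equal(pts_for(5), 1)
  # an item at exactly the 75% unit threshold is not adequate
  ids <- instr$foods$id[instr$foods$quality]
  audit <- make_audit(instr, available = ids,
                      fracs = stats::setNames(as.list(rep(0.75, 20)), ids))
  expect_equal(as.integer(quality_points(audit, instr)), 0)
})

test_that("no available produce scores 0 and is flagged not assessable", {
  instr <- default_chile_instrument()
  audit <- make_audit(instr, available = "potato")
  q <- quality_points(audit, instr)
  expect_equal(as.integer(q), 0)
  expect_false(attr(q, "assessable"))
})

test_that("variety bonuses use strict thresholds", {
  instr <- default_chile_instrument()
  legumes <- c("lentils", "beans", "chickpeas", "peas_dried", "broad_beans")
  audit <- make_audit(instr, available = c("apple", "celery", legumes),
                      extras = list(apple = 4L, celery = 4L, lentils = 1L))
  v <- variety_points(audit, instr)
  expect_equal(as.integer(v), 10)  # 3 + 3 + 4
  by_m <- attr(v, "by_measure")
  expect_equal(by_m[["fresh_fruits"]], 3L)
  expect_equal(by_m[["fresh_vegetables"]], 3L)
  expect_equal(by_m[["legumes"]], 4L)

  # exactly 3 extra fruit varieties earns nothing; so does exactly 5 legumes
  boundary <- make_audit(instr, available = c("apple", legumes),
                         extras = list(apple = 3L, lentils = 0L))
  expect_equal(as.integer(variety_points(boundary, instr)), 0)
  # egg is listed under the legume measure but is not a legume variety
  with_egg <- make_audit(instr, available = c(legumes, "egg"))
  expect_equal(as.integer(variety_points(with_egg, instr)), 0)
  none <- make_audit(instr)
  expect_equal(as.integer(variety_points(none, instr)), 0)
})

test_that("price bonus rewards the healthier option at equal or lower price", {
  instr <- default_chile_instrument()
  base <- c("rice_integral", "rice_white")
  pts <- function(hp, rp) {
    audit <- make_audit(instr, available = base,
                        prices = list(rice_integral = hp, rice_white = rp),
                        brands = list(rice_integral = "a", rice_white = "b"))
    as.integer(price_points(audit, instr))
  }
  expect_equal(pts(1000L, 1200L), 1)  # integral cheaper per kg
  expect_equal(pts(1200L, 1200L), 1)  # tie earns the bonus
  expect_equal(pts(1300L, 1200L), 0)
  # missing healthier price contributes 0
  audit <- make_audit(instr, available = base,
                      prices = list(rice_white = 1200L),
                      brands = list(rice_white = "b"))
  expect_equal(as.integer(price_points(audit, instr)), 0)
})

test_that("total score attains the published extremes and the empty store is 0", {
  instr <- default_chile_instrument()
  expect_equal(total_score(best_case_audit(instr), instr)$total, 100)
  expect_equal(total_score(worst_case_audit(instr), instr)$total, -30)
  expect_equal(total_score(make_audit(instr), instr)$total, 0)
})

test_that("score report satisfies its accounting identities", {
  instr <- default_chile_instrument()
  aud <- simulate_audits(sim_config(n_supermarkets = 4, n_street_markets = 3,
                                    seed = 5), instr)
  scores <- score_audits(aud, instr)
  expect_equal(scores$group1_total, scores$fruits_vegetables + scores$other_group1)
  expect_equal(scores$total, scores$group1_total + scores$group2 +
                 scores$group3 - scores$group4_magnitude)
  b <- score_bounds(instr)
  expect_true(all(scores$total >= b[["min"]] & scores$total <= b[["max"]]))
  expect_true(all(scores$group4_magnitude >= 0))
  expect_true(all(scores$quality_points %in% 0:3))
})

test_that("totals are order-invariant and monotone in availability", {
  instr <- toy12_instrument()
  audit <- make_audit(instr, available = c("apple", "lentil", "rice_w", "soda"),
                      fracs = list(apple = 0.9),
                      prices = list(rice_w = 500L), extras = list(apple = 5L))
  shuffled <- audit[withr::with_seed(3, sample(nrow(audit))), ]
  expect_equal(total_score(shuffled, instr)$total, total_score(audit, instr)$total)

  # adding a group 1-3 food never decreases the total; a group-4 never increases
  t0 <- total_score(audit, instr)$total
  plus_g1 <- audit
  plus_g1$available[plus_g1$food_id == "bean"] <- TRUE
  expect_gte(total_score(plus_g1, instr)$total, t0)
  plus_g4 <- audit
  plus_g4$available[plus_g4$food_id == "candy"] <- TRUE
  expect_lte(total_score(plus_g4, instr)$total, t0)
})

test_that("total_score matches the first-principles oracle on random audits", {
  instr <- toy12_instrument()
  ids <- instr$foods$id
  price_ids <- instr$foods$id[instr$foods$price]
  withr::with_seed(42, {
    for (rep in 1:25) {
      avail <- ids[stats::runif(length(ids)) < 0.6]
      audit <- make_audit(
        instr, available = avail,
        prices = stats::setNames(
          as.list(sample(400:1600, length(price_ids))), price_ids),
        fracs = stats::setNames(
          as.list(round(stats::runif(2), 2)), c("apple", "pear")),
        extras = list(apple = sample(0:6, 1), lentil = sample(0:6, 1)))
      # strip annotations from unavailable rows to honour the data contract
      off <- !audit$available
      audit$unit_price[off] <- NA_integer_
      audit$adequate_fraction[off] <- NA_real_
      audit$extra_varieties[off] <- NA_integer_
      expect_equal(total_score(audit, instr)$total, oracle_total(audit, instr))
    }
  })
})
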