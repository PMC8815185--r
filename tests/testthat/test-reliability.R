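test_that("percent agreement reproduces the recurrent published values", {
  x <- rep(TRUE, 26)
  y25 <- c(rep(TRUE, 25), FALSE)
  expect_equal(percent_agreement(x, y25), 96.15)
  y22 <- c(rep(TRUE, 22), rep(FALSE, 4))
  expect_equal(percent_agreement(x, y22), 84.62)
  expect_equal(percent_agreement(x, x), 100)
  expect_equal(percent_agreement(y25, x), percent_agreement(x, y25))
  expect_error(percent_agreement(x, x[-1]), class = "nems_validation_error")
})

test_that("kappa matches the hand-computed 2x2 example and trivial cases", {
  # cross-tab both-yes 24, yes/no 1, no/yes 0, both-no 1:
  # p_o = 650/676, p_e = 602/676, kappa = 48/74
  x <- c(rep(TRUE, 25), FALSE)
  y <- c(rep(TRUE, 24), FALSE, FALSE)
  res <- cohens_kappa(x, y)
  expect_equal(res$value, 48 / 74)
  expect_equal(round(res$value, 2), 0.65)
  expect_equal(res$band, "substantial")

  ident <- c(TRUE, FALSE, TRUE, TRUE)
  res1 <- cohens_kappa(ident, ident)
  expect_equal(res1$value, 1)
  expect_equal(res1$band, "perfect")

  # constant rater: undefined with the published footnote's reason
  res2 <- cohens_kappa(rep(TRUE, 10), c(rep(TRUE, 5), rep(FALSE, 5)))
  expect_true(is.na(res2$value))
  expect_equal(res2$undefined_reason, "<2 levels")
})

test_that("kappa agrees with an independent library implementation", {
  skip_if_not_installed("e1071")
  withr::with_seed(9, {
    for (i in 1:20) {
      x <- stats::runif(30) < 0.6
      y <- xor(x, stats::runif(30) < 0.2)
      if (length(unique(x)) < 2 || length(unique(y)) < 2) next
      ours <- cohens_kappa(x, y)$value
      ref <- e1071::classAgreement(table(x, y))$kappa
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  })
})

test_that("kappa invariances: relabeling, bound by observed agreement", {
  withr::with_seed(10, {
    for (i in 1:20) {
      x <- stats::runif(20) < 0.5
      y <- xor(x, stats::runif(20) < 0.3)
      if (length(unique(x)) < 2 || length(unique(y)) < 2) next
      k <- suppressWarnings(cohens_kappa(x, y)$value)
      # relabel both raters; swap raters (suppress banding warnings for
      # chance-level draws that land below zero)
      expect_equal(suppressWarnings(cohens_kappa(!x, !y)$value), k)
      expect_equal(suppressWarnings(cohens_kappa(y, x)$value), k)
      expect_lte(k, mean(x == y))                      # kappa <= p_o
      expect_gte(k, -1)
      expect_lte(k, 1)
    }
  })
})

test_that("band classifiers match the printed breakpoints", {
  expect_equal(vapply(c(0, 0.2, 0.205, 0.21, 0.4, 0.41, 0.6, 0.61, 0.8, 0.81, 1),
                      kappa_band, character(1)),
               c("mild", "mild", "fair", "fair", "fair", "moderate",
                 "moderate", "substantial", "substantial", "perfect", "perfect"))
  expect_warning(b <- kappa_band(-0.1), "below")
  expect_equal(b, "mild")
  expect_equal(vapply(c(0.1, 0.40, 0.41, 0.59, 0.60, 0.74, 0.75, 0.9),
                      icc_band, character(1)),
               c("bad", "bad", "regular", "regular", "good", "good",
                 "excellent", "excellent"))
})

test_that("icc is exact on identical raters and penalises one-rater shifts", {
  x <- c(3, 8, 5, 10, 6, 2, 9)
  res <- icc(x, x)
  expect_equal(res$value, 1)
  expect_equal(res$band, "excellent")
  shifted <- icc(x, x + 50)
  consist <- icc(x, x + 50, model = "consistency")
  expect_lt(shifted$value, consist$value)  # absolute agreement sees the shift
  expect_equal(consist$value, 1)
  # same constant added to both raters changes nothing
  expect_equal(icc(x + 7, x + 7)$value, 1)
  expect_equal(icc(x, x * 1)$value, icc(x + 3, x + 3)$value)
  # zero between-target variance -> undefined
  flat <- icc(rep(4, 5), rep(4, 5))
  expect_true(is.na(flat$value))
  expect_match(flat$undefined_reason, "zero variance")
})

test_that("icc matches the classical mean-squares decomposition from aov", {
  withr::with_seed(21, {
    n <- 40
    b <- stats::rnorm(n, 0, 2)
    x <- b + stats::rnorm(n)
    y <- b + 0.8 + stats::rnorm(n)
    long <- data.frame(value = c(x, y),
                       target = factor(rep(seq_len(n), 2)),
                       rater = factor(rep(1:2, each = n)))
    ms <- summary(stats::aov(value ~ target + rater, data = long))[[1]]$`Mean Sq`
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    ref_abs <- (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
    ref_con <- (msr - mse) / (msr + mse)
    expect_equal(icc(x, y)$value, ref_abs, tolerance = 1e-10)
    expect_equal(icc(x, y, model = "consistency")$value, ref_con,
                 tolerance = 1e-10)
  })
})

test_that("icc recovers a known intraclass correlation of 0.8", {
  withr::with_seed(2024, {
    n <- 200
    b <- stats::rnorm(n, 0, sqrt(0.8))
    x <- b + stats::rnorm(n, 0, sqrt(0.2))
    y <- b + stats::rnorm(n, 0, sqrt(0.2))
    res <- icc(x, y)
    expect_lt(abs(res$value - 0.8), 0.07)
  })
})

test_that("price matching keeps only same-brand complete pairs", {
  instr <- toy12_instrument()
  a1 <- make_audit(instr, available = c("rice_w", "rice_i", "oil_v"),
                   evaluator_id = "E1",
                   prices = list(rice_w = 1000L, rice_i = 900L, oil_v = 2000L),
                   brands = list(rice_w = "k1", rice_i = "k2", oil_v = "k3"))
  a2 <- make_audit(instr, available = c("rice_w", "rice_i", "oil_v"),
                   evaluator_id = "E2",
                   prices = list(rice_w = 1010L, rice_i = 905L, oil_v = 1990L),
                   brands = list(rice_w = "k1", rice_i = "OTHER", oil_v = "k3"))
  aud <- audit_set(rbind(a1, a2), instr)
  pm <- price_match(aud, instr)
  expect_setequal(pm$food_id, c("rice_w", "oil_v"))  # k2 vs OTHER dropped
  expect_equal(nrow(pm), 2)
  # one price missing -> dropped
  a2b <- a2
  a2b$unit_price[a2b$food_id == "oil_v"] <- NA_integer_
  pm2 <- price_match(audit_set(rbind(a1, a2b), instr), instr)
  expect_equal(pm2$food_id, "rice_w")
})

test_that("error-free paired audits give perfect or undefined agreement", {
  instr <- default_chile_instrument()
  cfg <- sim_config(n_supermarkets = 6, n_street_markets = 4,
                    rater_flip_prob = 0, price_reading_sd = 0,
                    quality_reading_sd = 0, brand_match_prob = 1, seed = 13)
  aud <- simulate_audits(cfg, instr)
  rep <- reliability_report(aud, instr)
  a <- rep$availability
  expect_true(all(is.na(a$kappa) | a$kappa == 1))
  expect_true(all(a$undefined_reason[is.na(a$kappa)] == "<2 levels"))
  expect_true(all(a$percent_agreement == 100))
  expect_true(all(is.na(rep$price$icc) | rep$price$icc == 1))
  v <- rep$variety
  expect_true(all(is.na(v$kappa) | v$kappa == 1))
})

test_that("reliability report covers every food once and excludes odd stores", {
  instr <- default_chile_instrument()
  aud <- simulate_audits(sim_config(n_supermarkets = 4, n_street_markets = 3,
                                    seed = 3), instr)
  # tack on a third evaluator for one store: that store must be excluded
  third <- as.data.frame(aud[aud$store_id == "SUP01" & aud$evaluator_id == "E1", ])
  third$evaluator_id <- "E3"
  odd <- audit_set(rbind(as.data.frame(aud), third), instr)
  expect_warning(rep <- reliability_report(odd, instr), "SUP01")
  expect_equal(rep$n_stores, 6)
  noncomp <- rep$availability[!rep$availability$composite, ]
  expect_setequal(noncomp$food_id, instr$foods$id)
  expect_equal(nrow(noncomp), 62)
  expect_setequal(rep$quality$food_id, produce_ids <- instr$foods$id[instr$foods$quality])
  expect_setequal(rep$price$food_id, instr$foods$id[instr$foods$price])
  expect_equal(nrow(rep$variety), 3)
})

test_that("a 25-of-26-stores disagreement renders as 96.15 with a dash for constants", {
  instr <- toy2_instrument()
  audits <- list()
  for (s in 1:26) {
    sid <- sprintf("S%02d", s)
    audits[[2 * s - 1]] <- make_audit(instr, available = c("staple", "junk"),
                                      store_id = sid, evaluator_id = "E1")
    avail2 <- if (s == 1) "staple" else c("staple", "junk")
    audits[[2 * s]] <- make_audit(instr, available = avail2,
                                  store_id = sid, evaluator_id = "E2")
  }
  aud <- audit_set(do.call(rbind, audits), instr)
  rep <- reliability_report(aud, instr)
  junk <- rep$availability[rep$availability$food_id == "junk", ]
  expect_equal(junk$percent_agreement, 96.15)
  # staple is constant for both raters: undefined kappa, dash in markdown
  staple <- rep$availability[rep$availability$food_id == "staple", ]
  expect_true(is.na(staple$kappa))
  md <- reliability_markdown(rep)
  expect_true(any(grepl("\\| - \\|", md)))
  tmpdir <- withr::local_tempdir()
  paths <- write_reliability(rep, tmpdir)
  expect_true(all(file.exists(paths)))
})
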