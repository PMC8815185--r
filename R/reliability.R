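#' @title Inter-evaluator reliability statistics
#' @name reliability
#' @description
#' Two trained evaluators audit each store on the same day; reliability is
#' summarised per food by percent agreement and Cohen's kappa for
#' dichotomous records (availability, adequate quality, extra variety) and
#' by the intraclass correlation coefficient for unit prices matched on
#' brand/size. Kappa is banded 0-0.20 mild, 0.21-0.40 fair, 0.41-0.60
#' moderate, 0.61-0.80 substantial, 0.81-1.00 perfect; ICC below 0.4 is bad,
#' 0.41-0.59 regular, 0.60-0.74 good, above 0.75 excellent.
NULL

agreement_result <- function(statistic, value, n, band = NA_character_,
                             undefined_reason = NA_character_) {
  structure(list(statistic = statistic, value = value, n = n, band = band,
                 undefined_reason = undefined_reason),
            class = "nems_agreement")
}

#' @export
print.nems_agreement <- function(x, ...) {
  if (is.na(x$value)) {
    cat(sprintf("%s: undefined (%s), n = %d\n", x$statistic,
                x$undefined_reason, x$n))
  } else if (is.na(x$band)) {
    cat(sprintf("%s = %.2f, n = %d\n", x$statistic, x$value, x$n))
  } else {
    cat(sprintf("%s = %.2f (%s), n = %d\n", x$statistic, x$value, x$band, x$n))
  }
  invisible(x)
}

#' Percent agreement between two raters
#'
#' Raw share of identical paired ratings, as a percentage reported to two
#' decimals (25 matches of 26 gives 96.15).
#'
#' @param x,y equal-length vectors of paired ratings.
#' @return Percentage in `[0, 100]`.
#' @export
percent_agreement <- function(x, y) {
  if (length(x) != length(y)) abort_validation("x and y must have equal length")
  if (length(x) == 0) abort_validation("x and y must be non-empty")
  round(100 * mean(x == y), 2)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement for dichotomous ratings: `(p_o - p_e) / (1 -
#' p_e)` with expected agreement from the raters' marginal products. When
#' either rater uses a single level the statistic is undefined and the
#' result carries reason `"<2 levels"` (reliability tables print a dash).
#' The band is assigned on the unrounded statistic; a negative kappa is
#' below the printed scale's floor and is banded `"mild"` with a warning.
#'
#' @param x,y equal-length vectors (logical or two-level) of paired ratings.
#' @return A `nems_agreement` with `statistic = "kappa"`.
#' @examples
#' cohens_kappa(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))  # 1, perfect
#' @export
cohens_kappa <- function(x, y) {
  if (length(x) != length(y)) abort_validation("x and y must have equal length")
  n <- length(x)
  if (n < 2) abort_validation("kappa needs at least 2 paired ratings")
  levels_all <- sort(unique(c(x, y)))
  fx <- factor(x, levels = levels_all)
  fy <- factor(y, levels = levels_all)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(agreement_result("kappa", NA_real_, n,
                            undefined_reason = "<2 levels"))
  }
  tab <- table(fx, fy)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  value <- (p_o - p_e) / (1 - p_e)
  agreement_result("kappa", value, n, band = kappa_band(value))
}

#' Kappa agreement band
#'
#' @param value unrounded kappa.
#' @return One of `"mild"`, `"fair"`, `"moderate"`, `"substantial"`,
#'   `"perfect"`; values below 0 warn (below the scale's floor) and band as
#'   `"mild"`.
#' @export
kappa_band <- function(value) {
  if (is.na(value)) return(NA_character_)
  if (value < 0) warning("negative kappa is below the interpretation scale; banded 'mild'")
  if (value <= 0.20) "mild"
  else if (value <= 0.40) "fair"
  else if (value <= 0.60) "moderate"
  else if (value <= 0.80) "substantial"
  else "perfect"
}

#' ICC agreement band
#'
#' @param value unrounded ICC.
#' @return One of `"bad"`, `"regular"`, `"good"`, `"excellent"`.
#' @export
icc_band <- function(value) {
  if (is.na(value)) return(NA_character_)
  if (value >= 0.75) "excellent"
  else if (value >= 0.60) "good"
  else if (value >= 0.41) "regular"
  else "bad"
}

#' Intraclass correlation coefficient for two raters
#'
#' Single-measure ICC from the two-way mean-squares decomposition. The
#' default is the absolute-agreement form (two-way random effects,
#' interchangeable trained raters), which penalises a systematic shift
#' between raters; `model = "consistency"` gives the two-way mixed
#' consistency form.
#'
#' @param x,y equal-length (>= 3) vectors of paired continuous measurements
#'   on the same targets.
#' @param model `"absolute"` (default) or `"consistency"`.
#' @return A `nems_agreement` with `statistic = "icc"`; undefined with
#'   reason when the targets have zero between-target variance.
#' @export
icc <- function(x, y, model = c("absolute", "consistency")) {
  model <- match.arg(model)
  if (length(x) != length(y)) abort_validation("x and y must have equal length")
  n <- length(x)
  if (n < 3) abort_validation("icc needs at least 3 paired measurements")
  if (anyNA(x) || anyNA(y)) abort_validation("icc inputs must be complete")
  k <- 2
  m <- matrix(c(x, y), ncol = k)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps * max(1, abs(grand))^2) {
    return(agreement_result("icc", NA_real_, n,
                            undefined_reason = "zero variance between targets"))
  }
  value <- if (model == "absolute") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  agreement_result("icc", value, n, band = icc_band(value))
}

# --- pairing the two evaluators of each store -------------------------------

# wide per-store x food table with one column set per evaluator rank
pair_observations <- function(audits, instr) {
  keep <- paired_stores(audits)
  obs <- as.data.frame(audits)
  obs <- obs[obs$store_id %in% keep, , drop = FALSE]
  if (nrow(obs) == 0) {
    abort_validation("no store with exactly two evaluators")
  }
  # evaluator rank within store (stable: sorted evaluator id)
  rank1 <- stats::ave(obs$evaluator_id, obs$store_id,
                      FUN = function(e) as.integer(e == sort(unique(e))[1]))
  o1 <- obs[rank1 == "1", c("store_id", "store_type", "food_id", "available",
                            "unit_price", "brand_size_key",
                            "adequate_fraction", "extra_varieties")]
  o2 <- obs[rank1 == "0", c("store_id", "food_id", "available", "unit_price",
                            "brand_size_key", "adequate_fraction",
                            "extra_varieties")]
  names(o1)[4:8] <- paste0(names(o1)[4:8], "_1")
  names(o2)[3:7] <- paste0(names(o2)[3:7], "_2")
  merge(o1, o2, by = c("store_id", "food_id"), sort = TRUE)
}

#' Matched price pairs between evaluators
#'
#' Price reliability uses only prices recorded by both evaluators for the
#' same type, size and brand: a store contributes a pair for a food only
#' when both evaluators priced the same `brand_size_key` there.
#'
#' @param audits a `nems_audits` with two evaluators per store.
#' @param instr a `nems_instrument`.
#' @return Data.frame `food_id`, `store_id`, `price_1`, `price_2` (one row
#'   per matched pair).
#' @export
price_match <- function(audits, instr) {
  price_match_impl(pair_observations(audits, instr), instr)
}

price_match_impl <- function(po, instr) {
  price_foods <- instr$foods$id[instr$foods$price]
  po <- po[po$food_id %in% price_foods, , drop = FALSE]
  ok <- !is.na(po$unit_price_1) & !is.na(po$unit_price_2) &
    !is.na(po$brand_size_key_1) & !is.na(po$brand_size_key_2) &
    po$brand_size_key_1 == po$brand_size_key_2
  out <- po[ok, c("food_id", "store_id", "unit_price_1", "unit_price_2")]
  names(out)[3:4] <- c("price_1", "price_2")
  rownames(out) <- NULL
  out
}

kappa_cols <- function(res) {
  data.frame(kappa = res$value, kappa_band = res$band,
             undefined_reason = res$undefined_reason,
             stringsAsFactors = FALSE)
}

#' Inter-evaluator reliability report
#'
#' Builds the full reliability report over stores audited by exactly two
#' evaluators (others are excluded with a warning):
#' \describe{
#'   \item{availability}{per food, kappa and percent agreement of the yes/no
#'     availability record over all stores, plus composite any-item rows for
#'     the fruit and vegetable measures (`composite = TRUE`).}
#'   \item{quality}{per produce food, percent agreement and kappa of the
#'     adequate-quality indicator over the stores where both evaluators
#'     marked the item available (`n` varies by food).}
#'   \item{price}{per price-dimension food, absolute-agreement ICC over the
#'     brand/size-matched price pairs from [price_match()].}
#'   \item{variety}{per variety-eligible measure, kappa and percent
#'     agreement of the any-extra-varieties indicator.}
#' }
#' Undefined statistics (constant rater, too few pairs) carry a reason and
#' render as dashes in the exports.
#'
#' @param audits a `nems_audits`.
#' @param instr a `nems_instrument`.
#' @return A `nems_reliability` list with data.frames `availability`,
#'   `quality`, `price`, `variety`.
#' @export
reliability_report <- function(audits, instr) {
  po <- pair_observations(audits, instr)
  foods <- instr$foods

  avail_rows <- lapply(foods$id, function(fid) {
    p <- po[po$food_id == fid, ]
    res <- cohens_kappa(p$available_1, p$available_2)
    cbind(data.frame(food_id = fid,
                     name = foods$name[foods$id == fid],
                     group = foods$group[foods$id == fid],
                     composite = FALSE, stringsAsFactors = FALSE),
          kappa_cols(res),
          data.frame(percent_agreement = percent_agreement(p$available_1,
                                                           p$available_2),
                     n = res$n))
  })
  produce_meas <- instr$measures$id[instr$measures$quality_eligible]
  comp_rows <- lapply(produce_meas, function(mid) {
    fids <- foods$id[foods$measure_id == mid]
    p <- po[po$food_id %in% fids, ]
    any1 <- tapply(p$available_1, p$store_id, any)
    any2 <- tapply(p$available_2, p$store_id, any)
    res <- cohens_kappa(as.logical(any1), as.logical(any2))
    cbind(data.frame(food_id = paste0("any_", mid),
                     name = paste0(instr$measures$name[instr$measures$id == mid],
                                   " (any item)"),
                     group = instr$measures$group[instr$measures$id == mid],
                     composite = TRUE, stringsAsFactors = FALSE),
          kappa_cols(res),
          data.frame(percent_agreement = percent_agreement(as.logical(any1),
                                                           as.logical(any2)),
                     n = res$n))
  })
  availability <- do.call(rbind, c(comp_rows, avail_rows,
                                   list(make.row.names = FALSE)))

  empty_or <- function(x, template) if (is.null(x)) template else x
  empty_quality <- data.frame(
    food_id = character(0), n = integer(0), kappa = numeric(0),
    kappa_band = character(0), undefined_reason = character(0),
    percent_agreement = numeric(0), stringsAsFactors = FALSE)
  empty_price <- data.frame(
    food_id = character(0), n = integer(0), icc = numeric(0),
    icc_band = character(0), undefined_reason = character(0),
    stringsAsFactors = FALSE)
  empty_variety <- data.frame(
    measure_id = character(0), kappa = numeric(0), kappa_band = character(0),
    undefined_reason = character(0), percent_agreement = numeric(0),
    n = integer(0), stringsAsFactors = FALSE)

  thr <- instr$quality_rule$item_adequate_threshold
  quality <- do.call(rbind, lapply(produce_food_ids(instr), function(fid) {
    p <- po[po$food_id == fid & po$available_1 & po$available_2, ]
    n <- nrow(p)
    if (n < 2) {
      return(data.frame(food_id = fid, n = n, kappa = NA_real_,
                        kappa_band = NA_character_,
                        undefined_reason = "fewer than 2 both-available stores",
                        percent_agreement = NA_real_,
                        stringsAsFactors = FALSE))
    }
    a1 <- !is.na(p$adequate_fraction_1) & p$adequate_fraction_1 > thr
    a2 <- !is.na(p$adequate_fraction_2) & p$adequate_fraction_2 > thr
    res <- cohens_kappa(a1, a2)
    cbind(data.frame(food_id = fid, n = n, stringsAsFactors = FALSE),
          kappa_cols(res),
          data.frame(percent_agreement = percent_agreement(a1, a2)))
  }))

  pm <- price_match_impl(po, instr)
  price <- do.call(rbind, lapply(foods$id[foods$price], function(fid) {
    p <- pm[pm$food_id == fid, ]
    n <- nrow(p)
    if (n < 3) {
      return(data.frame(food_id = fid, n = n, icc = NA_real_,
                        icc_band = NA_character_,
                        undefined_reason = "fewer than 3 matched price pairs",
                        stringsAsFactors = FALSE))
    }
    res <- icc(p$price_1, p$price_2)
    data.frame(food_id = fid, n = n, icc = res$value, icc_band = res$band,
               undefined_reason = res$undefined_reason,
               stringsAsFactors = FALSE)
  }))

  vm <- variety_measures(instr)
  variety <- do.call(rbind, lapply(vm$id, function(mid) {
    fids <- foods$id[foods$measure_id == mid]
    p <- po[po$food_id %in% fids, ]
    ex1 <- tapply(p$extra_varieties_1, p$store_id,
                  function(v) any(!is.na(v) & v > 0))
    ex2 <- tapply(p$extra_varieties_2, p$store_id,
                  function(v) any(!is.na(v) & v > 0))
    res <- cohens_kappa(as.logical(ex1), as.logical(ex2))
    cbind(data.frame(measure_id = mid, stringsAsFactors = FALSE),
          kappa_cols(res),
          data.frame(percent_agreement = percent_agreement(as.logical(ex1),
                                                           as.logical(ex2)),
                     n = res$n))
  }))

  structure(list(availability = availability,
                 quality = empty_or(quality, empty_quality),
                 price = empty_or(price, empty_price),
                 variety = empty_or(variety, empty_variety),
                 n_stores = length(unique(po$store_id)),
                 instrument_version = instr$version),
            class = "nems_reliability")
}

#' @export
print.nems_reliability <- function(x, ...) {
  cat(sprintf("NEMS reliability report over %d paired stores (instrument %s)\n",
              x$n_stores, x$instrument_version))
  defined <- x$availability$kappa[!x$availability$composite]
  cat(sprintf("  availability kappa: %d foods, %d undefined, median defined %.2f\n",
              length(defined), sum(is.na(defined)),
              stats::median(defined, na.rm = TRUE)))
  cat(sprintf("  price ICC: %d foods with >=3 matched pairs\n",
              sum(!is.na(x$price$icc))))
  invisible(x)
}

fmt_cell <- function(x, digits = 2) {
  ifelse(is.na(x), "-", formatC(x, format = "f", digits = digits))
}

#' Export a reliability report
#'
#' Writes the four report tables as CSV files (one per table, undefined
#' cells empty) or as a single Markdown document mirroring the published
#' table layout (undefined cells as dashes).
#'
#' @param report a `nems_reliability`.
#' @param dir output directory (created if needed).
#' @param format `"csv"`, `"markdown"`, or both.
#' @return Paths written, invisibly.
#' @export
write_reliability <- function(report, dir, format = c("csv", "markdown")) {
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if ("csv" %in% format) {
    for (tab in c("availability", "quality", "price", "variety")) {
      p <- file.path(dir, paste0("reliability_", tab, ".csv"))
      utils::write.csv(report[[tab]], p, row.names = FALSE, na = "")
      paths <- c(paths, p)
    }
  }
  if ("markdown" %in% format) {
    p <- file.path(dir, "reliability.md")
    writeLines(reliability_markdown(report), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Render a reliability report as Markdown tables
#'
#' @param report a `nems_reliability`.
#' @return Character vector of Markdown lines.
#' @export
reliability_markdown <- function(report) {
  md_table <- function(df) {
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- if (nrow(df) == 0) character(0) else
      apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    c(header, sep, body)
  }
  a <- report$availability
  avail <- data.frame(Food = a$name, Group = a$group,
                      Kappa = fmt_cell(a$kappa),
                      `% agreement` = fmt_cell(a$percent_agreement),
                      check.names = FALSE)
  q <- report$quality
  qual <- data.frame(Food = q$food_id, n = q$n, Kappa = fmt_cell(q$kappa),
                     `% agreement` = fmt_cell(q$percent_agreement),
                     check.names = FALSE)
  p <- report$price
  pric <- data.frame(Food = p$food_id, n = p$n, ICC = fmt_cell(p$icc))
  v <- report$variety
  vari <- data.frame(Measure = v$measure_id, Kappa = fmt_cell(v$kappa),
                     `% agreement` = fmt_cell(v$percent_agreement),
                     check.names = FALSE)
  c("# Inter-evaluator reliability", "",
    sprintf("Paired stores: %d; instrument: %s", report$n_stores,
            report$instrument_version), "",
    "## Availability", "", md_table(avail), "",
    "## Quality (both-available subset)", "", md_table(qual), "",
    "## Price (brand/size-matched pairs)", "", md_table(pric), "",
    "## Extra variety", "", md_table(vari))
}
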