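#' @title Store-type comparison of score distributions
#' @name comparison
#' @description
#' Score components are summarised per store type (mean, SD, median,
#' quartiles) and compared between supermarkets and street markets with the
#' two-sided Mann-Whitney U test. The test choice is a package assumption:
#' the published comparison reports medians and quartiles for small samples
#' without naming its test.
NULL

score_components <- c("group1_total", "fruits_vegetables", "other_group1",
                      "group2", "group3", "group4_magnitude", "total")

#' Descriptive summaries of score reports per store type
#'
#' One row per store type x component with mean, SD, median and quartiles.
#' Quartiles use linear interpolation (`stats::quantile` type 7); reporting
#' conventions for quartiles differ between software, so the method is fixed
#' and documented here. When a store has two evaluators, both score rows
#' enter the summary unless the caller deduplicates first.
#'
#' @param reports data.frame of [total_score()] rows.
#' @return Data.frame `store_type`, `component`, `n`, `mean`, `sd`,
#'   `median`, `q1`, `q3`. Store types without reports are omitted with a
#'   warning.
#' @export
summarize_scores <- function(reports) {
  reports <- as.data.frame(reports)
  if (nrow(reports) == 0) abort_validation("no score reports to summarise")
  present <- unique(reports$store_type)
  absent <- setdiff(store_types, present)
  if (length(absent) > 0) {
    warning("no reports for store type(s): ", paste(absent, collapse = ", "))
  }
  rows <- list()
  for (st in intersect(store_types, present)) {
    sub <- reports[reports$store_type == st, , drop = FALSE]
    for (comp in score_components) {
      v <- sub[[comp]]
      qs <- stats::quantile(v, probs = c(0.25, 0.5, 0.75), type = 7,
                            names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        store_type = st, component = comp, n = length(v),
        mean = mean(v), sd = stats::sd(v),
        median = qs[2], q1 = qs[1], q3 = qs[3],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$sd[is.na(out$sd)] <- 0  # single report: no dispersion
  out
}

#' Two-sided Mann-Whitney U test
#'
#' Exact null distribution when the combined sample size is at most 20 and
#' there are no ties; tie-corrected normal approximation with continuity
#' correction otherwise.
#'
#' @param x,y non-empty numeric score vectors.
#' @return List with `U` (the statistic for `x`) and `p` (two-sided
#'   p-value).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort_validation("both samples must be non-empty")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = unname(wt$p.value))
}

#' Compare score distributions between store types
#'
#' Builds the published-style comparison table: per component, descriptives
#' for each store type side by side and the Mann-Whitney p-value between
#' them. Requires score reports from both store types.
#'
#' @param reports data.frame of [total_score()] rows covering both store
#'   types.
#' @return Data.frame with one row per component: per-type `mean`, `sd`,
#'   `median`, `q1`, `q3` (prefixed `street_` / `super_`) plus `U` and
#'   `p_value`.
#' @export
compare_store_types <- function(reports) {
  reports <- as.data.frame(reports)
  for (st in store_types) {
    if (!any(reports$store_type == st)) {
      abort_validation(paste0("no score reports for store type: ", st))
    }
  }
  summ <- summarize_scores(reports)
  rows <- lapply(score_components, function(comp) {
    sm <- summ[summ$component == comp & summ$store_type == "street_market", ]
    sp <- summ[summ$component == comp & summ$store_type == "supermarket", ]
    xs <- reports[[comp]][reports$store_type == "street_market"]
    ys <- reports[[comp]][reports$store_type == "supermarket"]
    mw <- mann_whitney(xs, ys)
    data.frame(component = comp,
               street_mean = sm$mean, street_sd = sm$sd,
               street_median = sm$median, street_q1 = sm$q1, street_q3 = sm$q3,
               super_mean = sp$mean, super_sd = sp$sd,
               super_median = sp$median, super_q1 = sp$q1, super_q3 = sp$q3,
               U = mw$U, p_value = mw$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a store-type comparison table
#'
#' @param comparison output of [compare_store_types()].
#' @param path output path; `.md` extension writes Markdown, anything else
#'   CSV.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  if (grepl("\\.md$", path)) {
    df <- comparison
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) formatC(v, format = "g", digits = 4))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c("# Score comparison between store types", "",
                 header, sep, body), path)
  } else {
    utils::write.csv(comparison, path, row.names = FALSE, na = "")
  }
  invisible(path)
}
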