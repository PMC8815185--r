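#' @title Store audit records
#' @name audits
#' @description
#' One audit is one evaluator's walk through one store with the instrument:
#' one observation row per instrument food carrying availability, unit price
#' (integer Chilean pesos; CLP has no minor units), a brand/size key used to
#' match prices between evaluators, the fraction of produce units in
#' adequate condition, and extra-variety counts for the variety-eligible
#' measures. An audit set stacks audits; for reliability analysis each store
#' is audited twice on the same day by two evaluators.
NULL

audit_columns <- c("store_id", "store_type", "evaluator_id", "food_id",
                   "available", "unit_price", "brand_size_key",
                   "adequate_fraction", "extra_varieties", "audit_date")

store_types <- c("supermarket", "street_market")

#' Construct an audit set from an observation table
#'
#' Validates an observation table against an instrument definition and
#' returns a `nems_audits` object. Checks: known food ids; no duplicate
#' (store, evaluator, food) rows; every audit covers each instrument food
#' exactly once; `unit_price`, `adequate_fraction` and `extra_varieties`
#' missing whenever `available` is `FALSE`; `adequate_fraction` in `[0, 1]`
#' and only on quality-dimension foods; `extra_varieties` non-negative and
#' only on variety-eligible measures.
#'
#' @param obs data.frame with columns `store_id`, `store_type`
#'   (`"supermarket"` or `"street_market"`), `evaluator_id`, `food_id`,
#'   `available` (logical), `unit_price`, `brand_size_key`,
#'   `adequate_fraction`, `extra_varieties`, `audit_date`.
#' @param instr a `nems_instrument`.
#' @return A `nems_audits` object (a validated data.frame with the columns
#'   above and attribute `instrument_version`).
#' @export
audit_set <- function(obs, instr) {
  obs <- as.data.frame(obs, stringsAsFactors = FALSE)
  missing_cols <- setdiff(audit_columns, names(obs))
  if (length(missing_cols) > 0) {
    abort_validation(paste0("audit table missing column(s): ",
                            paste(missing_cols, collapse = ", ")))
  }
  obs <- obs[, audit_columns]
  if (nrow(obs) == 0) {
    out <- structure(obs, class = c("nems_audits", "data.frame"),
                     instrument_version = instr$version)
    return(out)
  }
  if (!all(obs$store_type %in% store_types)) {
    abort_validation(paste0("store_type must be one of: ",
                            paste(store_types, collapse = ", ")))
  }
  unknown <- setdiff(obs$food_id, instr$foods$id)
  if (length(unknown) > 0) {
    abort_validation(paste0("unknown food id(s) in audits: ",
                            paste(unique(unknown), collapse = ", ")))
  }
  key <- paste(obs$store_id, obs$evaluator_id, obs$food_id, sep = "\r")
  if (anyDuplicated(key)) {
    abort_integrity("duplicate (store, evaluator, food) row(s) in audits")
  }
  # each store x evaluator audit must cover the instrument exactly
  per_audit <- table(paste(obs$store_id, obs$evaluator_id, sep = "\r"))
  if (any(per_audit != nrow(instr$foods))) {
    abort_integrity(sprintf(
      "each audit must contain exactly one observation per instrument food (%d)",
      nrow(instr$foods)))
  }
  if (!is.logical(obs$available) || anyNA(obs$available)) {
    abort_validation("available must be logical with no missing values")
  }
  unavailable <- !obs$available
  leak <- unavailable & (!is.na(obs$unit_price) |
                           !is.na(obs$adequate_fraction) |
                           !is.na(obs$extra_varieties))
  if (any(leak)) {
    abort_integrity(paste0(
      "price/quality/variety recorded on unavailable item(s): ",
      paste(unique(obs$food_id[leak]), collapse = ", ")))
  }
  frac <- obs$adequate_fraction
  if (any(!is.na(frac) & (frac < 0 | frac > 1))) {
    abort_validation("adequate_fraction must lie in [0, 1]")
  }
  qfood <- instr$foods$id[instr$foods$quality]
  if (any(!is.na(frac) & !(obs$food_id %in% qfood))) {
    abort_validation("adequate_fraction recorded on a food without the quality dimension")
  }
  ev <- obs$extra_varieties
  if (any(!is.na(ev) & ev < 0)) {
    abort_validation("extra_varieties must be non-negative")
  }
  vmeas <- instr$measures$id[instr$measures$variety_eligible]
  vfood <- instr$foods$id[instr$foods$measure_id %in% vmeas & instr$foods$variety]
  if (any(!is.na(ev) & !(obs$food_id %in% vfood))) {
    abort_validation("extra_varieties recorded outside variety-eligible measures")
  }
  structure(obs, class = c("nems_audits", "data.frame"),
            instrument_version = instr$version)
}

#' Read audits from CSV
#'
#' Reads a UTF-8, comma-separated audit file with the documented header and
#' validates it against the instrument. Availability accepts
#' `yes/no/1/0/true/false` (case-insensitive); missing values are empty
#' cells, never sentinel numbers, so a quality fraction that was not
#' assessable stays distinguishable from zero.
#'
#' @param path CSV path.
#' @param instr a `nems_instrument`.
#' @return A `nems_audits` object; an empty file yields an empty audit set
#'   with a warning.
#' @export
read_audits <- function(path, instr) {
  if (!file.exists(path)) abort_validation(paste0("no such audit file: ", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0 || !nzchar(trimws(first))) {
    warning("empty audit file: ", path)
    empty <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(audit_columns)), audit_columns),
      stringsAsFactors = FALSE)
    return(audit_set(empty, instr))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                         colClasses = "character")
  missing_cols <- setdiff(setdiff(audit_columns, "audit_date"), names(raw))
  if (length(missing_cols) > 0) {
    abort_validation(paste0("audit CSV missing column(s): ",
                            paste(missing_cols, collapse = ", ")))
  }
  if (is.null(raw$audit_date)) raw$audit_date <- NA_character_
  blank_to_na <- function(x) ifelse(is.na(x) | !nzchar(trimws(x)), NA_character_, trimws(x))
  for (col in names(raw)) raw[[col]] <- blank_to_na(raw[[col]])
  obs <- data.frame(
    store_id = raw$store_id,
    store_type = raw$store_type,
    evaluator_id = raw$evaluator_id,
    food_id = raw$food_id,
    available = parse_yesno(raw$available),
    unit_price = parse_int(raw$unit_price, "unit_price"),
    brand_size_key = raw$brand_size_key,
    adequate_fraction = parse_num(raw$adequate_fraction, "adequate_fraction"),
    extra_varieties = parse_int(raw$extra_varieties, "extra_varieties"),
    audit_date = raw$audit_date,
    stringsAsFactors = FALSE
  )
  audit_set(obs, instr)
}

parse_yesno <- function(x) {
  lx <- tolower(x)
  out <- rep(NA, length(x))
  out[lx %in% c("yes", "1", "true")] <- TRUE
  out[lx %in% c("no", "0", "false")] <- FALSE
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    abort_validation(paste0("unparseable availability value(s): ",
                            paste(bad, collapse = ", ")))
  }
  out
}

parse_int <- function(x, what) {
  out <- suppressWarnings(as.integer(x))
  if (any(is.na(out) & !is.na(x))) {
    abort_validation(paste0("non-integer value in column ", what))
  }
  out
}

parse_num <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  if (any(is.na(out) & !is.na(x))) {
    abort_validation(paste0("non-numeric value in column ", what))
  }
  out
}

#' Write audits to CSV
#'
#' Writes the documented audit CSV (UTF-8, comma-separated, header row,
#' missing values as empty cells). The output round-trips losslessly through
#' [read_audits()], and writing the same audit set twice produces identical
#' bytes.
#'
#' @param audits a `nems_audits` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_audits <- function(audits, path) {
  stopifnot(inherits(audits, "nems_audits"))
  out <- as.data.frame(audits)
  out$available <- ifelse(out$available, "yes", "no")
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, na = "", fileEncoding = "UTF-8",
                   quote = FALSE, eol = "\n")
  invisible(path)
}

#' Split an audit set into single audits
#'
#' @param audits a `nems_audits` object.
#' @return Named list of observation data.frames, one per store x evaluator,
#'   names `"<store_id>/<evaluator_id>"`.
#' @export
split_audits <- function(audits) {
  key <- paste(audits$store_id, audits$evaluator_id, sep = "/")
  split(as.data.frame(audits), key)
}

#' @export
print.nems_audits <- function(x, ...) {
  n_store <- length(unique(x$store_id))
  n_aud <- length(unique(paste(x$store_id, x$evaluator_id)))
  cat(sprintf("NEMS audit set: %d observations, %d stores, %d audits (instrument %s)\n",
              nrow(x), n_store, n_aud, attr(x, "instrument_version")))
  invisible(x)
}

# stores audited by exactly two evaluators; others dropped with a warning
paired_stores <- function(audits) {
  ev <- tapply(audits$evaluator_id, audits$store_id,
               function(e) length(unique(e)))
  bad <- names(ev)[ev != 2]
  if (length(bad) > 0) {
    warning("excluding store(s) without exactly two evaluators: ",
            paste(bad, collapse = ", "))
  }
  setdiff(names(ev), bad)
}
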