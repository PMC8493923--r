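#' Response vocabulary for facility survey files
#'
#' Maps file tokens to the canonical response levels `yes`, `no`,
#' `dont_know`, `missing`, `not_applicable`. Matching is case-insensitive
#' and an empty cell reads as `missing`. The default vocabulary accepts
#' `1/yes/y`, `0/no/n`, `dk/dont_know/don't know`, `missing`/blank and
#' `na/not_applicable/n.a.`.
#'
#' @param ... named character vectors overriding or extending the default
#'   aliases; names must be canonical response levels.
#' @return named character vector token -> canonical level.
#' @export
#' @examples
#' v <- response_vocab(dont_know = "98")
#' unname(v["98"])
response_vocab <- function(...) {
  defaults <- list(
    yes = c("1", "yes", "y"),
    no = c("0", "no", "n"),
    dont_know = c("dk", "dont_know", "don't know"),
    missing = c("", "missing"),
    not_applicable = c("na", "not_applicable", "n.a.")
  )
  extra <- list(...)
  bad <- setdiff(names(extra), response_levels())
  if (length(bad) > 0) {
    stop_cbready(sprintf("unknown response level(s): %s",
                         paste(bad, collapse = ", ")),
                 "cbready_config_error")
  }
  for (lv in names(extra)) defaults[[lv]] <- union(defaults[[lv]], extra[[lv]])
  tokens <- unlist(defaults, use.names = FALSE)
  levels <- rep(names(defaults), lengths(defaults))
  stats::setNames(levels, tolower(tokens))
}

covariate_columns <- function() {
  c("facility_id", "tier", "managing_authority", "region", "teaching",
    "monthly_delivery_volume")
}

#' Read a facility survey from a delimited text file
#'
#' The file is comma-delimited UTF-8 with a header row naming the facility
#' covariates (`facility_id`, `tier`, `managing_authority`, `region`,
#' `teaching` (optional), `monthly_delivery_volume`) and one column per
#' survey item, identified by its registry `item_id`. Item cells use the
#' [response_vocab()] tokens. Columns that are neither covariates nor
#' registry items are rejected.
#'
#' @param path file path.
#' @param registry an [item_registry] used to recognise item columns.
#' @param vocab token mapping from [response_vocab()].
#' @return a data frame of class `facility_survey`: covariates plus one
#'   character column per item holding canonical response levels.
#' @export
read_facility_survey <- function(path, registry = builtin_item_registry(),
                                 vocab = response_vocab()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = character(0),
                         check.names = FALSE)
  required <- c("facility_id", "tier", "managing_authority", "region",
                "monthly_delivery_volume")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) {
    stop_cbready(sprintf("survey file lacks required column(s): %s",
                         paste(miss, collapse = ", ")),
                 "cbready_format_error")
  }
  item_cols <- setdiff(names(raw), covariate_columns())
  unknown <- setdiff(item_cols, registry$item_id)
  if (length(unknown) > 0) {
    stop_cbready(sprintf("unknown column(s) not in the item registry: %s",
                         paste(unknown, collapse = ", ")),
                 "cbready_format_error")
  }
  out <- data.frame(facility_id = raw$facility_id, stringsAsFactors = FALSE)
  if (anyDuplicated(out$facility_id)) {
    stop_cbready("duplicate facility_id in survey file", "cbready_format_error")
  }
  bad_tier <- setdiff(unique(raw$tier), tier_levels())
  if (length(bad_tier) > 0) {
    stop_cbready(sprintf("unknown tier value(s): %s",
                         paste(bad_tier, collapse = ", ")),
                 "cbready_parse_error")
  }
  out$tier <- raw$tier
  out$managing_authority <- raw$managing_authority
  out$region <- raw$region
  out$teaching <- if ("teaching" %in% names(raw)) {
    ifelse(nzchar(raw$teaching), tolower(raw$teaching) %in% c("1", "true", "yes"), NA)
  } else NA
  vol <- suppressWarnings(as.numeric(raw$monthly_delivery_volume))
  bad_vol <- which(nzchar(raw$monthly_delivery_volume) & (is.na(vol) | vol < 0))
  if (length(bad_vol) > 0) {
    stop_cbready(sprintf("non-numeric or negative monthly_delivery_volume in row(s) %s",
                         paste(bad_vol, collapse = ", ")),
                 "cbready_parse_error")
  }
  vol[!nzchar(raw$monthly_delivery_volume)] <- NA_real_
  out$monthly_delivery_volume <- vol
  for (item in item_cols) {
    tok <- tolower(raw[[item]])
    # match() rather than [: the blank token "" is a legal vocabulary name
    lv <- unname(vocab[match(tok, names(vocab))])
    bad <- which(is.na(lv))
    if (length(bad) > 0) {
      stop_cbready(sprintf(
        "unknown response token '%s' at row %d, column '%s'",
        raw[[item]][bad[1]], bad[1], item), "cbready_parse_error")
    }
    out[[item]] <- lv
  }
  structure(out, class = c("facility_survey", "data.frame"))
}

#' Write a facility survey to CSV
#'
#' Canonical response levels are written with the default file tokens
#' (`1`, `0`, `dk`, empty cell, `na`), so a write/read cycle with the
#' default vocabulary is an identity on all fields.
#'
#' @param survey a `facility_survey` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_facility_survey <- function(survey, path) {
  out <- as.data.frame(survey)
  token <- c(yes = "1", no = "0", dont_know = "dk", missing = "",
             not_applicable = "na")
  for (col in setdiff(names(out), covariate_columns())) {
    out[[col]] <- unname(token[out[[col]]])
  }
  out$teaching <- ifelse(is.na(out$teaching), "",
                         ifelse(out$teaching, "1", "0"))
  out$monthly_delivery_volume <- ifelse(is.na(out$monthly_delivery_volume), "",
                                        format(out$monthly_delivery_volume,
                                               trim = TRUE, scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Encode survey responses as a binary response matrix
#'
#' Applies the coding rules used before aggregation: `yes` codes to 1;
#' `no`, `dont_know` and `missing` code to 0. `not_applicable` responses
#' are handled per aggregation purpose. For additive aggregation the cell
#' is excluded (mask `applicable = FALSE`, value 0) so the score denominator
#' adjusts; for principal-components aggregation the cell is coded 0 and
#' kept applicable.
#'
#' @param survey a `facility_survey` (single tier, matching `spec$tier`).
#' @param spec an [index_spec()].
#' @param purpose `"additive"` or `"pca"`.
#' @return object of class `response_matrix`: list with `values`
#'   (facilities x items 0/1 integer matrix), `applicable` (logical matrix),
#'   `facility_ids`, `item_ids`, `purpose`, `tier`.
#' @export
#' @examples
#' reg <- builtin_item_registry()
#' cohort <- generate_cohort(synthetic_config(n_hospitals = 5, n_health_centres = 0,
#'                                            seed = 1), reg)
#' m <- code_responses(cohort, index_spec("SARA", "hospital"), "additive")
#' dim(m$values)
code_responses <- function(survey, spec, purpose = c("additive", "pca")) {
  purpose <- match.arg(purpose)
  stopifnot(inherits(spec, "index_spec"))
  if (nrow(survey) == 0) {
    stop_cbready("survey has no facilities", "cbready_format_error")
  }
  tiers <- unique(survey$tier)
  if (length(tiers) != 1 || tiers != spec$tier) {
    stop_cbready(sprintf(
      "records must all be tier '%s'; found: %s",
      spec$tier, paste(tiers, collapse = ", ")), "cbready_tier_error")
  }
  absent <- setdiff(spec$items, names(survey))
  if (length(absent) > 0) {
    stop_cbready(sprintf("index item(s) absent from all records: %s",
                         paste(absent, collapse = ", ")),
                 "cbready_coverage_error")
  }
  resp <- as.matrix(as.data.frame(survey)[, spec$items, drop = FALSE])
  values <- (resp == "yes") * 1L
  applicable <- matrix(TRUE, nrow(resp), ncol(resp))
  if (purpose == "additive") {
    applicable <- resp != "not_applicable"
    values[!applicable] <- 0L
  }
  dimnames(values) <- list(survey$facility_id, spec$items)
  dimnames(applicable) <- dimnames(values)
  structure(list(
    values = values,
    applicable = applicable,
    facility_ids = survey$facility_id,
    item_ids = spec$items,
    purpose = purpose,
    tier = spec$tier
  ), class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("Response matrix (%s coding): %d facilities x %d items, tier %s\n",
              x$purpose, nrow(x$values), ncol(x$values), x$tier))
  if (any(!x$applicable)) {
    cat(sprintf("  %d not-applicable cells excluded from denominators\n",
                sum(!x$applicable)))
  }
  invisible(x)
}
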