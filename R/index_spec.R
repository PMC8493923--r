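#' Build an index specification for a framework and facility tier
#'
#' An index specification names the ordered items entering one readiness
#' index, their partition into readiness domains, and any domains excluded
#' from domain-weighted aggregation. Hospital specifications nest the
#' health-centre specification of the same framework: hospitals score the
#' base items plus the hospital-only additions (the expanded list covers
#' comprehensive emergency obstetric and newborn care).
#'
#' For the DHS framework the "guidelines, training and supervision" domain
#' is represented in the item list but flagged as excluded from the
#' domain-weighted mean; its items still count under simple addition.
#'
#' @param framework one of `"SARA"`, `"DHS"`, `"WHO_standards"`.
#' @param tier one of `"hospital"`, `"health_centre_clinic"`.
#' @param registry an [item_registry]; defaults to [builtin_item_registry()].
#' @param validate_counts check item totals against the registry's
#'   `reference_counts` attribute (default: yes whenever that attribute is
#'   present, as it is for the shipped registry).
#' @return an object of class `index_spec` with elements `framework`,
#'   `tier`, `items` (ordered item ids), `domains` (named list partitioning
#'   `items`), `excluded_domains` (character), `registry_rows` (the registry
#'   subset).
#' @export
#' @examples
#' spec <- index_spec("SARA", "health_centre_clinic")
#' length(spec$items)        # 15
#' names(spec$domains)       # 3 readiness domains
index_spec <- function(framework = c("SARA", "DHS", "WHO_standards"),
                       tier = c("hospital", "health_centre_clinic"),
                       registry = builtin_item_registry(),
                       validate_counts = !is.null(attr(registry, "reference_counts"))) {
  framework <- match.arg(framework)
  tier <- match.arg(tier)
  rows <- registry[registry$framework == framework, , drop = FALSE]
  keep <- rows$tier_applicability == "both" |
    (tier == "hospital" & rows$tier_applicability == "hospital_only") |
    (tier == "health_centre_clinic" & rows$tier_applicability == "health_centre_only")
  rows <- rows[keep, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop_cbready(sprintf("registry has no %s items for tier %s", framework, tier),
                 "cbready_config_error")
  }
  if (validate_counts) {
    ref <- attr(registry, "reference_counts")
    want <- ref$n_items[ref$framework == framework & ref$tier == tier]
    if (length(want) == 1 && nrow(rows) != want) {
      stop_cbready(sprintf(
        "%s/%s registry has %d items; expected %d",
        framework, tier, nrow(rows), want), "cbready_config_error")
    }
  }
  domains <- split(rows$item_id, factor(rows$domain, levels = unique(rows$domain)))
  excluded <- character(0)
  if (framework == "DHS" && "guidelines_training_supervision" %in% names(domains)) {
    excluded <- "guidelines_training_supervision"
  }
  structure(list(
    framework = framework,
    tier = tier,
    items = rows$item_id,
    domains = domains,
    excluded_domains = excluded,
    registry_rows = rows
  ), class = "index_spec")
}

#' @export
print.index_spec <- function(x, ...) {
  cat(sprintf("Readiness index specification: %s, %s\n", x$framework, x$tier))
  cat(sprintf("  %d items in %d domains\n", length(x$items), length(x$domains)))
  for (dm in names(x$domains)) {
    flag <- if (dm %in% x$excluded_domains) " [excluded from weighting]" else ""
    cat(sprintf("  - %s: %d items%s\n", dm, length(x$domains[[dm]]), flag))
  }
  invisible(x)
}

#' Partition of an index's items into readiness domains
#'
#' @param spec an [index_spec()].
#' @return named list mapping domain name to item ids; the attribute
#'   `excluded_domains` names domains excluded from domain-weighted
#'   aggregation.
#' @export
domain_partition <- function(spec) {
  stopifnot(inherits(spec, "index_spec"))
  structure(spec$domains, excluded_domains = spec$excluded_domains)
}
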