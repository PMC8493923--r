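#' Per-item availability
#'
#' Proportion of facilities with the item available, among facilities where
#' the item is applicable. Items applicable nowhere return `NA`.
#'
#' @param matrix a `response_matrix` (additive coding carries the
#'   applicability mask).
#' @return named numeric vector, one proportion per item.
#' @export
availability <- function(matrix) {
  stopifnot(inherits(matrix, "response_matrix"))
  if (nrow(matrix$values) < 1) {
    stop_cbready("availability needs at least one facility",
                 "cbready_insufficient_data")
  }
  napp <- colSums(matrix$applicable)
  out <- ifelse(napp > 0,
                colSums(matrix$values * matrix$applicable) / napp,
                NA_real_)
  stats::setNames(out, matrix$item_ids)
}

#' Screen out near-universally available items
#'
#' Items available in strictly more than `threshold` of facilities carry
#' little information to differentiate facilities and are excluded from the
#' standards-based candidate pool.
#'
#' @param avail named availability vector from [availability()].
#' @param threshold exclusion threshold (default 0.97; exclusion is strict
#'   `>`).
#' @return list with `retained` and `excluded` item-id vectors and the
#'   `threshold` used.
#' @export
#' @examples
#' screen_universal(c(i1 = 0.98, i2 = 0.97, i3 = 0.5))
screen_universal <- function(avail, threshold = 0.97) {
  stopifnot(threshold >= 0, threshold <= 1)
  excluded <- names(avail)[!is.na(avail) & avail > threshold]
  list(retained = setdiff(names(avail), excluded),
       excluded = excluded,
       threshold = threshold)
}

#' Interitem correlation matrix
#'
#' Pearson correlation of the 0/1 item columns (the phi coefficient) and
#' the mean over off-diagonal pairs. Zero-variance items are dropped with a
#' warning and recorded in the result.
#'
#' @param matrix a `response_matrix` or plain 0/1 matrix.
#' @return list with `matrix` (correlations), `mean` (off-diagonal mean),
#'   `dropped_items`.
#' @export
interitem_correlation <- function(matrix) {
  v <- if (inherits(matrix, "response_matrix")) matrix$values else as.matrix(matrix)
  sds <- apply(v, 2, stats::sd)
  dropped <- colnames(v)[sds == 0]
  if (length(dropped) > 0) {
    warning(sprintf("dropping zero-variance item(s): %s",
                    paste(dropped, collapse = ", ")))
    v <- v[, sds > 0, drop = FALSE]
  }
  if (ncol(v) < 2) {
    stop_cbready("interitem correlation needs >= 2 items with variance",
                 "cbready_insufficient_data")
  }
  R <- stats::cor(v)
  list(matrix = R,
       mean = mean(R[lower.tri(R)]),
       dropped_items = dropped)
}

#' Cronbach's alpha
#'
#' Internal consistency of an item set:
#' \deqn{\alpha = \frac{K}{K-1}\left(1 -
#'   \frac{\sum_i s_i^2}{s_{\mathrm{total}}^2}\right)}
#' with sample variances of the item columns and of the per-facility row
#' sums.
#'
#' @param matrix a `response_matrix` or plain 0/1 matrix.
#' @return alpha, or `NA` (with a warning) when the total-score variance is
#'   zero.
#' @export
cronbach_alpha <- function(matrix) {
  v <- if (inherits(matrix, "response_matrix")) matrix$values else as.matrix(matrix)
  k <- ncol(v)
  if (k < 2) {
    stop_cbready("Cronbach's alpha needs >= 2 items", "cbready_insufficient_data")
  }
  total_var <- stats::var(rowSums(v))
  if (total_var == 0) {
    warning("zero total-score variance; alpha undefined")
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(apply(v, 2, stats::var)) / total_var)
}

#' Classify item variation: rare and widely available items
#'
#' Items available in fewer than `low` of facilities are rare; items
#' available in at least `high` are widely available. Percentages are
#' reported to integer precision (the convention in the comparison table,
#' whose header uses the inclusive bound for wide availability).
#'
#' @param avail availability vector from [availability()].
#' @param low rarity threshold (default 0.40, strict `<`).
#' @param high wide-availability threshold (default 0.90, inclusive `>=`).
#' @return list with item-id vectors `rare` and `wide`, counts `n_rare`,
#'   `n_wide`, integer percentages `pct_rare`, `pct_wide`, and `n_items`.
#' @export
#' @examples
#' classify_item_variation(c(a = 0.39, b = 0.40, c = 0.90, d = 0.95))
classify_item_variation <- function(avail, low = 0.40, high = 0.90) {
  avail <- avail[!is.na(avail)]
  rare <- names(avail)[avail < low]
  wide <- names(avail)[avail >= high]
  n <- length(avail)
  list(rare = rare, wide = wide,
       n_rare = length(rare), n_wide = length(wide),
       pct_rare = round_half_even(100 * length(rare) / n, 0),
       pct_wide = round_half_even(100 * length(wide) / n, 0),
       n_items = n)
}

#' Per-item diagnostics for an item pool
#'
#' Combines availability, the near-universal screen and a per-domain 2PL
#' fit into one table, mirroring the standards-based item-selection
#' procedure: availability is computed per item, items above the universal
#' threshold are flagged for exclusion, and discrimination/difficulty come
#' from a 2PL model fitted within each readiness domain on the retained
#' items.
#'
#' @param survey single-tier `facility_survey`.
#' @param spec an [index_spec()] defining the candidate pool and its
#'   domains.
#' @param universal_threshold passed to [screen_universal()].
#' @param min_discrimination retention flag threshold on `a` (default
#'   0.65; an editorial default, the source procedure pairs statistical
#'   properties with conceptual alignment rather than a single cutoff).
#' @param ... passed to [fit_2pl()].
#' @return data frame of class `item_diagnostics`: `item_id`, `domain`,
#'   `availability`, `excluded_universal`, `a`, `b`, `fit_converged`,
#'   `retained` (not excluded and `a >= min_discrimination`).
#' @export
item_diagnostics <- function(survey, spec, universal_threshold = 0.97,
                             min_discrimination = 0.65, ...) {
  m <- code_responses(survey, spec, "additive")
  avail <- availability(m)
  scr <- screen_universal(avail, universal_threshold)
  out <- data.frame(
    item_id = spec$items,
    domain = rep(names(spec$domains), lengths(spec$domains))[
      match(spec$items, unlist(spec$domains, use.names = FALSE))],
    availability = unname(avail[spec$items]),
    excluded_universal = spec$items %in% scr$excluded,
    a = NA_real_, b = NA_real_, fit_converged = NA,
    stringsAsFactors = FALSE
  )
  for (dm in names(spec$domains)) {
    items <- intersect(spec$domains[[dm]], scr$retained)
    items <- items[!(avail[items] %in% c(0, 1))]
    if (length(items) < 2) next
    sub <- structure(list(
      values = m$values[, items, drop = FALSE],
      applicable = m$applicable[, items, drop = FALSE],
      facility_ids = m$facility_ids, item_ids = items,
      purpose = "additive", tier = m$tier
    ), class = "response_matrix")
    fit <- fit_2pl(sub, ...)
    idx <- match(fit$coefficients$item_id, out$item_id)
    out$a[idx] <- fit$coefficients$a
    out$b[idx] <- fit$coefficients$b
    out$fit_converged[idx] <- fit$converged
  }
  out$retained <- !out$excluded_universal &
    !is.na(out$a) & out$a >= min_discrimination
  structure(out, class = c("item_diagnostics", "data.frame"),
            universal_threshold = universal_threshold,
            min_discrimination = min_discrimination)
}
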