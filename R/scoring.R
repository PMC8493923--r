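#' Simple-addition readiness scores
#'
#' The number of available items is divided by the number of possible items
#' for the facility, each item carrying equal weight. Not-applicable items
#' are excluded and the denominator adjusted, so scores are exact rationals
#' in \[0, 1\].
#'
#' @param matrix a `response_matrix` with `purpose = "additive"`.
#' @return data frame with columns `facility_id`, `score`, `n_applicable`.
#' @export
score_simple <- function(matrix) {
  check_purpose(matrix, "additive")
  napp <- rowSums(matrix$applicable)
  if (any(napp == 0)) {
    stop_cbready(sprintf("facility with no applicable items: %s",
                         paste(matrix$facility_ids[napp == 0], collapse = ", ")),
                 "cbready_undefined_score")
  }
  data.frame(
    facility_id = matrix$facility_ids,
    score = rowSums(matrix$values * matrix$applicable) / napp,
    n_applicable = as.integer(napp),
    stringsAsFactors = FALSE
  )
}

#' Domain-weighted readiness scores
#'
#' Within each readiness domain the available items are summed and divided
#' by the domain's applicable-item count to form a domain score; the
#' composite is the unweighted mean over domains, so each domain carries
#' equal weight regardless of size. Domains flagged as excluded from
#' weighting (and domains with no applicable items for a facility) are
#' dropped from the composite mean, with the denominator adjusted.
#'
#' @param matrix a `response_matrix` with `purpose = "additive"`.
#' @param partition a [domain_partition()] (or an [index_spec()], from which
#'   the partition is taken).
#' @return data frame with `facility_id`, `score`, `n_applicable` and one
#'   `domain_<name>` column per domain (NA where a domain has no applicable
#'   item for the facility).
#' @export
score_domain_weighted <- function(matrix, partition) {
  check_purpose(matrix, "additive")
  if (inherits(partition, "index_spec")) partition <- domain_partition(partition)
  excluded <- attr(partition, "excluded_domains") %||% character(0)
  covered <- unlist(partition, use.names = FALSE)
  if (!setequal(covered, matrix$item_ids)) {
    stop_cbready("domain partition does not cover the matrix items exactly",
                 "cbready_config_error")
  }
  n_fac <- nrow(matrix$values)
  dom_scores <- sapply(partition, function(items) {
    cols <- matrix$item_ids %in% items
    napp <- rowSums(matrix$applicable[, cols, drop = FALSE])
    s <- rowSums((matrix$values * matrix$applicable)[, cols, drop = FALSE])
    ifelse(napp > 0, s / napp, NA_real_)
  })
  dom_scores <- matrix(dom_scores, nrow = n_fac,
                       dimnames = list(NULL, names(partition)))
  use <- !(colnames(dom_scores) %in% excluded)
  composite <- rowMeans(dom_scores[, use, drop = FALSE], na.rm = TRUE)
  if (any(is.nan(composite))) {
    bad <- matrix$facility_ids[is.nan(composite)]
    stop_cbready(sprintf("all domains empty or excluded for facility: %s",
                         paste(bad, collapse = ", ")),
                 "cbready_undefined_score")
  }
  out <- data.frame(
    facility_id = matrix$facility_ids,
    score = composite,
    n_applicable = as.integer(rowSums(matrix$applicable)),
    stringsAsFactors = FALSE
  )
  for (dm in colnames(dom_scores)) out[[paste0("domain_", dm)]] <- dom_scores[, dm]
  out
}

#' Fit the principal-components aggregation model
#'
#' Eigendecomposition of the item correlation matrix (items standardised to
#' unit variance before aggregation). The first component's loadings are
#' oriented so their sum is positive, making higher scores mean greater
#' readiness. The share of variance explained by the first component is its
#' eigenvalue divided by the number of items (the trace of a correlation
#' matrix).
#'
#' @param matrix a `response_matrix` with `purpose = "pca"` (not-applicable
#'   responses already coded to 0).
#' @param drop_degenerate drop zero-variance items with a warning instead of
#'   failing (default `FALSE`: an error lists the offending items).
#' @return object of class `readiness_pca`: `item_ids`, `loadings` (first
#'   component), `eigenvalues`, `variance_explained_first`, `center`,
#'   `scale`, `score_min`, `score_max` (raw-score range seen at fit time),
#'   `dropped_items`.
#' @export
fit_pca <- function(matrix, drop_degenerate = FALSE) {
  check_purpose(matrix, "pca")
  v <- matrix$values
  if (nrow(v) < 2) {
    stop_cbready("PCA needs at least 2 facilities", "cbready_insufficient_data")
  }
  if (ncol(v) < 2) {
    stop_cbready("PCA needs at least 2 items", "cbready_insufficient_data")
  }
  sds <- apply(v, 2, stats::sd)
  degen <- colnames(v)[sds == 0]
  if (length(degen) > 0) {
    if (!drop_degenerate) {
      stop_cbready(sprintf("zero-variance item(s) under PCA coding: %s",
                           paste(degen, collapse = ", ")),
                   "cbready_degenerate_item")
    }
    warning(sprintf("dropping %d zero-variance item(s) from PCA: %s",
                    length(degen), paste(degen, collapse = ", ")))
    v <- v[, sds > 0, drop = FALSE]
    if (ncol(v) < 2) {
      stop_cbready("fewer than 2 items left after dropping degenerate items",
                   "cbready_insufficient_data")
    }
  }
  ctr <- colMeans(v)
  scl <- apply(v, 2, stats::sd)
  R <- stats::cor(v)
  e <- eigen(R, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  v1 <- e$vectors[, 1]
  if (sum(v1) < 0) v1 <- -v1
  z <- scale(v, center = ctr, scale = scl)
  raw <- drop(z %*% v1)
  structure(list(
    item_ids = colnames(v),
    loadings = stats::setNames(v1, colnames(v)),
    eigenvalues = lambda,
    variance_explained_first = lambda[1] / ncol(v),
    center = ctr,
    scale = scl,
    score_min = min(raw),
    score_max = max(raw),
    dropped_items = degen
  ), class = "readiness_pca")
}

#' @export
print.readiness_pca <- function(x, ...) {
  cat(sprintf("Principal-components readiness model: %d items\n", length(x$item_ids)))
  cat(sprintf("  first eigenvalue %.3f (%.1f%% of total variance)\n",
              x$eigenvalues[1], 100 * x$variance_explained_first))
  if (length(x$dropped_items) > 0) {
    cat(sprintf("  dropped zero-variance items: %s\n",
                paste(x$dropped_items, collapse = ", ")))
  }
  invisible(x)
}

#' Principal-components readiness scores
#'
#' Facilities are projected on the first component (standardised item
#' vector times first-component loadings) and the projection is min--max
#' rescaled over the scored cohort, so the least-ready facility scores
#' exactly 0 and the most-ready exactly 1. Scores are therefore
#' cohort-relative: they compare facilities within the scored tier, not
#' across cohorts.
#'
#' @param matrix a `response_matrix` with `purpose = "pca"`, same item set
#'   the model was fitted on.
#' @param model a `readiness_pca` from [fit_pca()].
#' @return data frame with `facility_id`, `score`, `n_applicable`.
#' @export
score_pca <- function(matrix, model) {
  check_purpose(matrix, "pca")
  stopifnot(inherits(model, "readiness_pca"))
  absent <- setdiff(model$item_ids, matrix$item_ids)
  if (length(absent) > 0) {
    stop_cbready(sprintf("matrix lacks model item(s): %s",
                         paste(absent, collapse = ", ")),
                 "cbready_config_error")
  }
  v <- matrix$values[, model$item_ids, drop = FALSE]
  z <- scale(v, center = model$center, scale = model$scale)
  raw <- drop(z %*% model$loadings)
  lo <- min(raw)
  hi <- max(raw)
  if (hi - lo < .Machine$double.eps * max(1, abs(hi))) {
    stop_cbready("all facilities project identically; min-max rescaling undefined",
                 "cbready_undefined_rescale")
  }
  data.frame(
    facility_id = matrix$facility_ids,
    score = (raw - lo) / (hi - lo),
    n_applicable = ncol(v),
    stringsAsFactors = FALSE
  )
}

check_purpose <- function(matrix, purpose) {
  stopifnot(inherits(matrix, "response_matrix"))
  if (matrix$purpose != purpose) {
    stop_cbready(sprintf("response matrix must be coded for '%s' aggregation", purpose),
                 "cbready_config_error")
  }
  invisible(matrix)
}

#' Construct one readiness index for a facility cohort
#'
#' The central constructor: selects the framework's items for the cohort's
#' tier, applies the response-coding rules, aggregates by the requested
#' method, and returns a classed object carrying per-facility scores,
#' per-domain scores (additive methods), per-item availability, and the
#' fitted PCA model when relevant.
#'
#' @param survey a `facility_survey` containing a single tier.
#' @param framework `"SARA"`, `"DHS"` or `"WHO_standards"`.
#' @param method `"simple"`, `"weighted"` or `"pca"`.
#' @param registry an [item_registry].
#' @param drop_degenerate passed to [fit_pca()] for `method = "pca"`
#'   (default `TRUE`: on real cohorts near-universal items may be constant
#'   within a tier, and dropping them with a warning keeps the index
#'   defined).
#' @return object of class `readiness_index`: `scores` data frame,
#'   `framework`, `method`, `tier`, `n_items`, `availability` (per-item
#'   proportion available among applicable facilities), `spec`, `pca`
#'   (model or NULL).
#' @export
#' @examples
#' reg <- builtin_item_registry()
#' cohort <- generate_cohort(synthetic_config(n_hospitals = 40,
#'                                            n_health_centres = 0, seed = 7), reg)
#' idx <- readiness_index(cohort, "SARA", "simple")
#' summary(idx)
readiness_index <- function(survey,
                            framework = c("SARA", "DHS", "WHO_standards"),
                            method = c("simple", "weighted", "pca"),
                            registry = builtin_item_registry(),
                            drop_degenerate = TRUE) {
  framework <- match.arg(framework)
  method <- match.arg(method)
  tiers <- unique(survey$tier)
  if (length(tiers) != 1) {
    stop_cbready("survey must contain a single tier; split before scoring",
                 "cbready_tier_error")
  }
  spec <- index_spec(framework, tiers, registry)
  m_add <- code_responses(survey, spec, "additive")
  pca_model <- NULL
  scores <- switch(method,
    simple = score_simple(m_add),
    weighted = score_domain_weighted(m_add, spec),
    pca = {
      m_pca <- code_responses(survey, spec, "pca")
      pca_model <- fit_pca(m_pca, drop_degenerate = drop_degenerate)
      score_pca(m_pca, pca_model)
    }
  )
  structure(list(
    scores = scores,
    framework = framework,
    method = method,
    tier = tiers,
    n_items = length(spec$items),
    availability = availability(m_add),
    spec = spec,
    pca = pca_model
  ), class = "readiness_index")
}

#' @export
print.readiness_index <- function(x, ...) {
  cat(sprintf("Childbirth service readiness index: %s / %s (%s)\n",
              x$framework, x$method, x$tier))
  cat(sprintf("  %d facilities, %d items\n", nrow(x$scores), x$n_items))
  cat(sprintf("  score median %.3f, IQR %.3f\n",
              stats::median(x$scores$score), stats::IQR(x$scores$score)))
  invisible(x)
}

#' @export
summary.readiness_index <- function(object, ...) {
  s <- summarize_index(object$scores$score)
  s$framework <- object$framework
  s$method <- object$method
  s$tier <- object$tier
  s$n_items <- object$n_items
  class(s) <- c("summary.readiness_index", class(s))
  s
}

#' @export
print.summary.readiness_index <- function(x, ...) {
  cat(sprintf("%s / %s (%s): n=%d, %d items\n",
              x$framework, x$method, x$tier, x$n, x$n_items))
  cat(sprintf("  mean %.3f  median %.3f  sd %.3f  cv %.2f\n",
              x$mean, x$median, x$sd, x$cv))
  cat(sprintf("  skewness %.2f  kurtosis %.2f (non-excess)\n",
              x$skewness, x$kurtosis))
  cat(sprintf("  floor %.1f%%  ceiling %.1f%%\n", x$floor_pct, x$ceiling_pct))
  invisible(x)
}

#' @export
plot.readiness_index <- function(x, breaks = 20, ...) {
  graphics::hist(x$scores$score, breaks = breaks,
                 main = sprintf("%s / %s (%s)", x$framework, x$method, x$tier),
                 xlab = "Readiness score", col = "grey85", border = "white", ...)
  invisible(x)
}

#' Score a cohort under all framework-by-method combinations
#'
#' @param survey single-tier `facility_survey`.
#' @param registry an [item_registry].
#' @param frameworks,methods subsets of the three frameworks / three
#'   aggregation methods.
#' @param drop_degenerate passed to [readiness_index()].
#' @return named list of [readiness_index()] objects
#'   (`"<framework>.<method>"`), class `readiness_battery`.
#' @export
readiness_battery <- function(survey, registry = builtin_item_registry(),
                              frameworks = c("SARA", "DHS", "WHO_standards"),
                              methods = c("simple", "weighted", "pca"),
                              drop_degenerate = TRUE) {
  out <- list()
  for (fw in frameworks) {
    for (me in methods) {
      out[[paste(fw, me, sep = ".")]] <-
        readiness_index(survey, fw, me, registry,
                        drop_degenerate = drop_degenerate)
    }
  }
  structure(out, class = "readiness_battery")
}

#' @export
print.readiness_battery <- function(x, ...) {
  cat(sprintf("Readiness battery: %d indices (%s)\n", length(x), x[[1]]$tier))
  for (nm in names(x)) {
    cat(sprintf("  %-26s median %.3f\n", nm, stats::median(x[[nm]]$scores$score)))
  }
  invisible(x)
}
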