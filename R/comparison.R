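#' Distributional summary of a readiness score vector
#'
#' Central tendency, spread, shape and floor/ceiling behaviour for one
#' index. Skewness is the moment coefficient \eqn{m_3 / m_2^{3/2}} and
#' kurtosis the non-excess \eqn{m_4 / m_2^2} (normal = 3), both on
#' population (divide-by-n) moments; the coefficient of variation is the
#' sample standard deviation divided by the mean.
#'
#' @param scores numeric score vector.
#' @param tol tolerance for counting a score as exactly 0 or 1
#'   (default 1e-9; additive scores are exact rationals, rescaled
#'   principal-component scores hit the endpoints up to rounding).
#' @return list of class `index_summary`: `n`, `mean`, `median`, `sd`,
#'   `iqr`, `skewness`, `kurtosis`, `cv`, `floor_n`, `floor_pct`,
#'   `ceiling_n`, `ceiling_pct`, `n_top`, `n_second`, `pct_second`.
#'   Constant score vectors report `NA` skewness/kurtosis.
#' @export
summarize_index <- function(scores, tol = 1e-9) {
  n <- length(scores)
  if (n < 2) {
    stop_cbready("summary needs at least 2 scores", "cbready_insufficient_data")
  }
  m <- mean(scores)
  d <- scores - m
  m2 <- mean(d^2)
  skew <- if (m2 > 0) mean(d^3) / m2^1.5 else NA_real_
  kurt <- if (m2 > 0) mean(d^4) / m2^2 else NA_real_
  fc <- floor_ceiling(scores, tol = tol)
  ties <- rank_with_ties(scores)
  structure(list(
    n = n, mean = m, median = stats::median(scores),
    sd = stats::sd(scores), iqr = stats::IQR(scores),
    skewness = skew, kurtosis = kurt,
    cv = if (m > 0) stats::sd(scores) / m else NA_real_,
    floor_n = fc$floor_n, floor_pct = fc$floor_pct,
    ceiling_n = fc$ceiling_n, ceiling_pct = fc$ceiling_pct,
    n_top = ties$n_top, n_second = ties$n_second,
    pct_second = ties$pct_second
  ), class = "index_summary")
}

#' Floor and ceiling effects
#'
#' Counts and percentages of facilities scoring exactly 0 (floor) or
#' exactly 1 (ceiling). Percentages are rounded half-to-even at one
#' decimal, the convention under which 34 of 160 prints as 21.2%.
#'
#' @inheritParams summarize_index
#' @return list: `n`, `floor_n`, `floor_pct`, `ceiling_n`, `ceiling_pct`.
#' @export
#' @examples
#' floor_ceiling(c(rep(1, 34), runif(126, 0.2, 0.99)))
floor_ceiling <- function(scores, tol = 1e-9) {
  n <- length(scores)
  fl <- sum(abs(scores) <= tol)
  ce <- sum(abs(scores - 1) <= tol)
  list(n = n, floor_n = fl, floor_pct = pct_of(fl, n),
       ceiling_n = ce, ceiling_pct = pct_of(ce, n))
}

#' Facility rankings with tie analysis
#'
#' Higher scores rank better (rank 1 = most ready). Average ranks are
#' returned for correlation use and dense ranks for tie reporting; the
#' count at the top score and at the second-highest *distinct* score are
#' reported with half-to-even percentages. Additive scores are exact
#' rationals, so distinct-value grouping uses exact equality.
#'
#' @param scores numeric score vector.
#' @return list: `rank_average`, `rank_dense`, `rank_ordinal`,
#'   `tie_sizes` (facilities per distinct score, best first), `n_top`,
#'   `pct_top`, `n_second`, `pct_second`.
#' @export
rank_with_ties <- function(scores) {
  n <- length(scores)
  if (n < 1) stop_cbready("no scores to rank", "cbready_insufficient_data")
  distinct <- sort(unique(scores), decreasing = TRUE)
  dense <- match(scores, distinct)
  sizes <- as.integer(table(factor(dense, levels = seq_along(distinct))))
  n_top <- sizes[1]
  n_second <- if (length(sizes) >= 2) sizes[2] else 0L
  list(
    rank_average = rank(-scores, ties.method = "average"),
    rank_dense = dense,
    rank_ordinal = rank(-scores, ties.method = "first"),
    tie_sizes = sizes,
    n_top = n_top, pct_top = pct_of(n_top, n),
    n_second = n_second, pct_second = pct_of(n_second, n)
  )
}

#' Bland-Altman agreement between two readiness indices
#'
#' Per-facility differences `a - b` are summarised by their mean and sample
#' standard deviation, with limits of agreement at the mean plus or minus
#' exactly 2 SD (the convention used in the difference-vs-mean plots this
#' mirrors), the count of facilities outside the limits, and the Spearman
#' rank correlation of the two score sets.
#'
#' @param a,b [readiness_index()] objects, or numeric vectors (aligned, or
#'   named by facility).
#' @return list of class `bland_altman`: `index_pair`, `n`,
#'   `mean_difference`, `sd_difference`, `loa_lower`, `loa_upper`,
#'   `n_outside_loa`, `rank_correlation`, `differences`, `means`.
#' @export
bland_altman <- function(a, b) {
  pair <- c(deparse(substitute(a))[1], deparse(substitute(b))[1])
  if (inherits(a, "readiness_index")) {
    pair[1] <- paste(a$framework, a$method, sep = ".")
    a <- stats::setNames(a$scores$score, a$scores$facility_id)
  }
  if (inherits(b, "readiness_index")) {
    pair[2] <- paste(b$framework, b$method, sep = ".")
    b <- stats::setNames(b$scores$score, b$scores$facility_id)
  }
  if (!is.null(names(a)) && !is.null(names(b))) {
    only_a <- setdiff(names(a), names(b))
    only_b <- setdiff(names(b), names(a))
    if (length(only_a) > 0 || length(only_b) > 0) {
      stop_cbready(sprintf(
        "facility sets differ (only in first: %s; only in second: %s)",
        paste(only_a, collapse = ", "), paste(only_b, collapse = ", ")),
        "cbready_alignment_error")
    }
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop_cbready("score vectors have different lengths", "cbready_alignment_error")
  }
  d <- a - b
  md <- mean(d)
  sd_d <- stats::sd(d)
  lo <- md - 2 * sd_d
  hi <- md + 2 * sd_d
  structure(list(
    index_pair = pair, n = length(d),
    mean_difference = md, sd_difference = sd_d,
    loa_lower = lo, loa_upper = hi,
    n_outside_loa = sum(d < lo | d > hi),
    rank_correlation = spearman_cor(a, b)$rho,
    differences = unname(d), means = unname((a + b) / 2)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement: %s vs %s (n=%d)\n",
              x$index_pair[1], x$index_pair[2], x$n))
  cat(sprintf("  mean difference %.4f, SD %.4f\n", x$mean_difference, x$sd_difference))
  cat(sprintf("  limits of agreement [%.4f, %.4f]; %d facilities outside\n",
              x$loa_lower, x$loa_upper, x$n_outside_loa))
  cat(sprintf("  Spearman rank correlation %.3f\n", x$rank_correlation))
  invisible(x)
}

#' Difference-vs-mean agreement plot
#'
#' @param x a `bland_altman` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = "Mean of the two scores", ylab = "Difference",
                 main = sprintf("%s vs %s", x$index_pair[1], x$index_pair[2]),
                 pch = 19, col = grDevices::adjustcolor("steelblue", 0.6), ...)
  graphics::abline(h = x$mean_difference, lty = 2)
  graphics::abline(h = c(x$loa_lower, x$loa_upper), lty = 3)
  invisible(x)
}

#' Spearman rank correlation with tie correction
#'
#' Pearson correlation of average ranks, equivalent to the tie-corrected
#' Spearman coefficient; the two-sided p-value uses the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n - 2} degrees of freedom.
#' Pairs with a missing value in either variable are deleted pairwise.
#'
#' @param x,y numeric vectors of equal length.
#' @return list: `rho`, `p_value`, `n` (pairs used). `rho` is `NA` with a
#'   warning when either variable has zero rank variance.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) {
    stop_cbready("x and y must have equal length", "cbready_alignment_error")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) {
    stop_cbready("Spearman correlation needs >= 3 complete pairs",
                 "cbready_insufficient_data")
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero rank variance; Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Interdomain correlation across indices
#'
#' Deconstructs additive (simple or domain-weighted) indices into their
#' domain scores and computes the pairwise Spearman correlation between
#' every pair of domain-score vectors across frameworks, for one tier.
#'
#' @param indices list of [readiness_index()] objects carrying domain
#'   scores (method `"weighted"`), same facilities.
#' @return list: `matrix` (Spearman correlations, rows/cols labelled
#'   `framework.domain`), `n_facilities`. Constant domain vectors yield
#'   `NA` rows with a warning.
#' @export
domain_deconstruction <- function(indices) {
  cols <- list()
  for (idx in indices) {
    sc <- idx$scores
    dom_cols <- grep("^domain_", names(sc), value = TRUE)
    if (length(dom_cols) == 0) next
    for (dc in dom_cols) {
      cols[[paste(idx$framework, sub("^domain_", "", dc), sep = ".")]] <-
        stats::setNames(sc[[dc]], sc$facility_id)
    }
  }
  if (length(cols) < 2) {
    stop_cbready("need domain scores from >= 2 domains (use weighted indices)",
                 "cbready_insufficient_data")
  }
  ids <- names(cols[[1]])
  M <- sapply(cols, function(v) unname(v[ids]))
  p <- ncol(M)
  R <- diag(1, p)
  dimnames(R) <- list(colnames(M), colnames(M))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      r <- tryCatch(suppressWarnings(spearman_cor(M[, i], M[, j])$rho),
                    error = function(e) NA_real_)
      R[i, j] <- R[j, i] <- r
    }
  }
  list(matrix = R, n_facilities = nrow(M))
}

#' Full index-comparison battery for one tier
#'
#' Produces the per-index characteristics table (item counts, rare and
#' widely-available item shares, coefficient of variation, floor and
#' ceiling percentages, Spearman correlation with delivery volume) and the
#' full pairwise Bland-Altman agreement set.
#'
#' @param battery a [readiness_battery()] (or named list of
#'   [readiness_index()] objects) for one tier.
#' @param volumes named numeric vector of monthly delivery volumes
#'   (names = facility ids), or a `facility_survey` from which they are
#'   taken. Facilities with missing volume are dropped pairwise from the
#'   volume correlations only.
#' @return object of class `comparison_report`: `table` (one row per
#'   index), `agreement` (one row per unordered index pair),
#'   `domain_correlations` (when weighted indices are present), `tier`.
#' @export
compare_all <- function(battery, volumes = NULL) {
  stopifnot(length(battery) >= 1)
  tier <- battery[[1]]$tier
  if (inherits(volumes, "facility_survey") || is.data.frame(volumes)) {
    volumes <- stats::setNames(volumes$monthly_delivery_volume,
                               volumes$facility_id)
  }
  rows <- lapply(names(battery), function(nm) {
    idx <- battery[[nm]]
    s <- summarize_index(idx$scores$score)
    varia <- classify_item_variation(idx$availability)
    vol_r <- NA_real_
    vol_p <- NA_real_
    if (!is.null(volumes)) {
      v <- volumes[idx$scores$facility_id]
      sp <- suppressWarnings(spearman_cor(idx$scores$score, v))
      vol_r <- sp$rho
      vol_p <- sp$p_value
    }
    data.frame(
      index = nm, framework = idx$framework, method = idx$method,
      n = s$n, n_items = idx$n_items,
      items_rare_n = varia$n_rare, items_rare_pct = varia$pct_rare,
      items_wide_pct = varia$pct_wide,
      mean = s$mean, median = s$median, sd = s$sd,
      skewness = s$skewness, kurtosis = s$kurtosis, cv = s$cv,
      floor_pct = s$floor_pct, ceiling_pct = s$ceiling_pct,
      n_top = s$n_top, n_second = s$n_second, pct_second = s$pct_second,
      volume_rho = vol_r, volume_p = vol_p,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  nm <- names(battery)
  agree <- list()
  if (length(battery) >= 2) {
    for (i in seq_len(length(battery) - 1)) {
      for (j in (i + 1):length(battery)) {
        ba <- bland_altman(battery[[i]], battery[[j]])
        agree[[length(agree) + 1]] <- data.frame(
          index_a = nm[i], index_b = nm[j], n = ba$n,
          mean_difference = ba$mean_difference,
          sd_difference = ba$sd_difference,
          loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
          n_outside_loa = ba$n_outside_loa,
          rank_correlation = ba$rank_correlation,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  weighted <- battery[vapply(battery, function(x) x$method == "weighted", TRUE)]
  dom <- if (length(weighted) >= 1) {
    tryCatch(domain_deconstruction(weighted), error = function(e) NULL)
  } else NULL
  structure(list(
    table = tab,
    agreement = if (length(agree) > 0) do.call(rbind, agree) else NULL,
    domain_correlations = dom,
    tier = tier
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 3, ...) {
  cat(sprintf("Readiness index comparison (%s): %d indices\n",
              x$tier, nrow(x$table)))
  cols <- c("index", "n_items", "items_rare_pct", "items_wide_pct",
            "cv", "floor_pct", "ceiling_pct", "volume_rho", "volume_p")
  cols <- intersect(cols, names(x$table))
  print(format(x$table[, cols], digits = digits), row.names = FALSE)
  if (!is.null(x$agreement)) {
    cat(sprintf("\nPairwise agreement: SD of differences %.3f to %.3f\n",
                min(x$agreement$sd_difference), max(x$agreement$sd_difference)))
  }
  invisible(x)
}
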