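# Shared fixtures: a tiny registry, hand-built surveys and coded matrices.

toy_registry <- function(n_items = 4, framework = "SARA",
                         domain = "equipment", conditional = NULL) {
  df <- data.frame(
    item_id = sprintf("i%d", seq_len(n_items)),
    label = sprintf("toy item %d", seq_len(n_items)),
    framework = framework,
    domain = domain,
    who_standard = if (framework == "WHO_standards") "physical_resources" else NA_character_,
    tier_applicability = "both",
    conditional_authority = NA_character_,
    stringsAsFactors = FALSE
  )
  if (!is.null(conditional)) df$conditional_authority[conditional] <- "government"
  as_item_registry(df)
}

# survey data frame from a response-token matrix (rows = facilities)
toy_survey <- function(responses, tier = "hospital",
                       authority = "government",
                       volume = NULL) {
  n <- nrow(responses)
  if (is.null(colnames(responses))) {
    colnames(responses) <- sprintf("i%d", seq_len(ncol(responses)))
  }
  out <- data.frame(
    facility_id = sprintf("T%03d", seq_len(n)),
    tier = tier,
    managing_authority = rep_len(authority, n),
    region = "Addis",
    teaching = NA,
    monthly_delivery_volume = volume %||% rep(10, n),
    stringsAsFactors = FALSE
  )
  for (j in seq_len(ncol(responses))) out[[colnames(responses)[j]]] <- responses[, j]
  structure(out, class = c("facility_survey", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# binary matrix -> survey tokens
tokens_from_binary <- function(m) {
  t <- ifelse(m == 1, "yes", "no")
  colnames(t) <- colnames(m) %||% sprintf("i%d", seq_len(ncol(m)))
  t
}

# build a response_matrix directly from a 0/1 matrix (all applicable)
rm_from_binary <- function(m, purpose = "additive", tier = "hospital") {
  if (is.null(colnames(m))) colnames(m) <- sprintf("i%d", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- sprintf("T%03d", seq_len(nrow(m)))
  structure(list(
    values = m,
    applicable = matrix(TRUE, nrow(m), ncol(m), dimnames = dimnames(m)),
    facility_ids = rownames(m),
    item_ids = colnames(m),
    purpose = purpose,
    tier = tier
  ), class = "response_matrix")
}

# independent oracles ------------------------------------------------------

# correlation matrix by the direct covariance / (sd*sd) formula, loops only
oracle_cor <- function(m) {
  p <- ncol(m)
  R <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      xi <- m[, i] - mean(m[, i])
      xj <- m[, j] - mean(m[, j])
      R[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  R
}

# eigenpairs of the item correlation matrix via SVD (independent of eigen())
oracle_pca <- function(m) {
  R <- oracle_cor(m)
  s <- svd(R)
  list(values = s$d, vectors = s$u)
}

# Cronbach's alpha written out item by item
oracle_alpha <- function(m) {
  k <- ncol(m)
  iv <- 0
  for (j in seq_len(k)) iv <- iv + stats::var(m[, j])
  tv <- stats::var(apply(m, 1, sum))
  k / (k - 1) * (1 - iv / tv)
}

# Spearman's rho as Pearson on average ranks, written out
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# central moments written out
oracle_moments <- function(x) {
  n <- length(x); m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  list(mean = m, skewness = m3 / m2^1.5, kurtosis = m4 / m2^2,
       sd = sqrt(sum((x - m)^2) / (n - 1)))
}
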