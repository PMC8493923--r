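test_that("simple addition divides available items by applicable items", {
  m <- rm_from_binary(rbind(c(1, 1, 0, 1), c(1, 1, 1, 1), c(0, 0, 0, 0)))
  s <- score_simple(m)
  expect_equal(s$score, c(0.75, 1, 0))

  # not-applicable item leaves the cell out of the denominator
  reg <- toy_registry(3)
  spec <- index_spec("SARA", "hospital", reg, validate_counts = FALSE)
  survey <- toy_survey(rbind(c("yes", "not_applicable", "no"),
                             c("yes", "yes", "yes")))
  s <- score_simple(code_responses(survey, spec, "additive"))
  expect_equal(s$score, c(1 / 2, 1))
})

test_that("not-applicable denominator adjustment yields exact rationals", {
  reg <- toy_registry(3)
  spec <- index_spec("SARA", "hospital", reg, validate_counts = FALSE)
  survey <- toy_survey(rbind(c("yes", "not_applicable", "no")))
  s <- score_simple(code_responses(survey, spec, "additive"))
  expect_identical(s$score, 1 / 2)
  expect_identical(s$n_applicable, 2L)

  # facility with nothing applicable is an error naming the facility
  survey <- toy_survey(rbind(rep("not_applicable", 3)))
  expect_error(score_simple(code_responses(survey, spec, "additive")),
               "T001", class = "cbready_undefined_score")
})

test_that("domain-weighted scores average domain means with equal weight", {
  reg <- toy_registry(5)
  reg$domain <- c("A", "A", "B", "B", "B")
  reg <- as_item_registry(as.data.frame(reg))
  spec <- index_spec("SARA", "hospital", reg, validate_counts = FALSE)
  survey <- toy_survey(rbind(c("yes", "no", "yes", "yes", "yes")))
  s <- score_domain_weighted(code_responses(survey, spec, "additive"), spec)
  expect_equal(s$score, (0.5 + 1) / 2)
  expect_equal(s$domain_A, 0.5)
  expect_equal(s$domain_B, 1)

  # a fully not-applicable domain drops out of the composite mean
  survey <- toy_survey(rbind(c("not_applicable", "not_applicable", "yes", "no", "no")))
  s <- score_domain_weighted(code_responses(survey, spec, "additive"), spec)
  expect_equal(s$score, 1 / 3)
  expect_true(is.na(s$domain_A))
})

test_that("single-domain weighted scoring reduces exactly to simple addition", {
  set.seed(7)
  for (rep in 1:10) {
    m <- matrix(rbinom(6 * 5, 1, 0.6), 6, 5)
    rm_add <- rm_from_binary(m)
    part <- structure(list(only = colnames(rm_add$values)),
                      excluded_domains = character(0))
    expect_identical(score_domain_weighted(rm_add, part)$score,
                     score_simple(rm_add)$score)
  }
})

test_that("weighted composite equals the mean of its non-excluded domain scores", {
  reg <- toy_registry(6)
  reg$domain <- c("A", "A", "B", "B", "C", "C")
  reg <- as_item_registry(as.data.frame(reg))
  spec <- index_spec("SARA", "hospital", reg, validate_counts = FALSE)
  set.seed(11)
  tok <- tokens_from_binary(matrix(rbinom(8 * 6, 1, 0.5), 8, 6))
  colnames(tok) <- reg$item_id
  survey <- toy_survey(tok)
  s <- score_domain_weighted(code_responses(survey, spec, "additive"), spec)
  recomputed <- rowMeans(cbind(s$domain_A, s$domain_B, s$domain_C))
  expect_equal(s$score, recomputed, tolerance = 1e-12)

  # excluded domain: contributes a domain score but not the composite
  part <- structure(domain_partition(spec), excluded_domains = "C")
  s2 <- score_domain_weighted(code_responses(survey, spec, "additive"), part)
  expect_equal(s2$score, rowMeans(cbind(s2$domain_A, s2$domain_B)), tolerance = 1e-12)
})

test_that("PCA eigenpairs match an independent SVD oracle on a small fixture", {
  set.seed(13)
  m <- matrix(rbinom(6 * 4, 1, c(0.3, 0.5, 0.6, 0.7)), 6, 4, byrow = TRUE)
  while (any(apply(m, 2, sd) == 0)) m <- matrix(rbinom(24, 1, 0.5), 6, 4)
  fit <- fit_pca(rm_from_binary(m, purpose = "pca"))
  orc <- oracle_pca(m)
  expect_equal(fit$eigenvalues, orc$values, tolerance = 1e-8)
  v1 <- orc$vectors[, 1]
  if (sum(v1) < 0) v1 <- -v1
  expect_equal(unname(fit$loadings), v1, tolerance = 1e-8)
  # trace identity: eigenvalues of a correlation matrix sum to the item count
  expect_equal(sum(fit$eigenvalues), 4, tolerance = 1e-10)
  expect_equal(fit$variance_explained_first, fit$eigenvalues[1] / 4)
})

test_that("duplicated items load equally and carry the shared variance", {
  m <- cbind(a = c(0, 1, 0, 1, 1, 0), b = c(0, 1, 0, 1, 1, 0),
             c = c(1, 0, 0, 1, 0, 1))
  fit <- fit_pca(rm_from_binary(m, purpose = "pca"))
  expect_equal(fit$loadings[["a"]], fit$loadings[["b"]], tolerance = 1e-10)
  expect_gte(fit$eigenvalues[1], 2)  # the duplicated pair alone gives lambda1 >= 2
})

test_that("PCA scores hit the min-max endpoints and preserve projection order", {
  set.seed(17)
  m <- matrix(rbinom(6 * 4, 1, 0.5), 6, 4)
  while (any(apply(m, 2, sd) == 0)) m <- matrix(rbinom(24, 1, 0.5), 6, 4)
  rm_pca <- rm_from_binary(m, purpose = "pca")
  fit <- fit_pca(rm_pca)
  s <- score_pca(rm_pca, fit)
  expect_equal(min(s$score), 0, tolerance = 1e-9)
  expect_equal(max(s$score), 1, tolerance = 1e-9)
  expect_true(all(s$score >= -1e-9 & s$score <= 1 + 1e-9))
  # ordering agrees with the oracle projection on standardised items
  orc <- oracle_pca(m)
  v1 <- orc$vectors[, 1]
  if (sum(v1) < 0) v1 <- -v1
  raw <- drop(scale(m) %*% v1)
  expect_equal(s$score, (raw - min(raw)) / (max(raw) - min(raw)),
               tolerance = 1e-8)
})

test_that("degenerate PCA inputs are refused or dropped explicitly", {
  m <- cbind(a = rep(1, 5), b = c(0, 1, 0, 1, 1), c = c(1, 1, 0, 0, 1))
  rm_pca <- rm_from_binary(m, purpose = "pca")
  expect_error(fit_pca(rm_pca), "a", class = "cbready_degenerate_item")
  expect_warning(fit <- fit_pca(rm_pca, drop_degenerate = TRUE), "zero-variance")
  expect_equal(fit$dropped_items, "a")
  expect_setequal(fit$item_ids, c("b", "c"))

  one_fac <- rm_from_binary(matrix(c(1, 0), 1, 2), purpose = "pca")
  expect_error(fit_pca(one_fac), class = "cbready_insufficient_data")

  const <- rm_from_binary(rbind(c(1, 0), c(1, 0), c(1, 0)), purpose = "pca")
  expect_error(fit_pca(const), class = "cbready_degenerate_item")
})

test_that("scores lie in [0,1] and are invariant to item and facility order", {
  set.seed(19)
  reg <- toy_registry(6)
  reg$domain <- rep(c("A", "B"), each = 3)
  reg <- as_item_registry(as.data.frame(reg))
  spec <- index_spec("SARA", "hospital", reg, validate_counts = FALSE)
  for (rep in 1:5) {
    tok <- matrix(sample(c("yes", "no", "not_applicable"), 10 * 6, TRUE,
                         prob = c(.6, .3, .1)), 10, 6,
                  dimnames = list(NULL, reg$item_id))
    survey <- toy_survey(tok)
    m <- code_responses(survey, spec, "additive")
    s1 <- score_simple(m)
    w1 <- score_domain_weighted(m, spec)
    expect_true(all(s1$score >= 0 & s1$score <= 1))
    expect_true(all(w1$score >= 0 & w1$score <= 1))

    perm <- sample(nrow(survey))
    survey2 <- survey[perm, ]
    class(survey2) <- class(survey)
    s2 <- score_simple(code_responses(survey2, spec, "additive"))
    expect_equal(s2$score[match(s1$facility_id, s2$facility_id)], s1$score)

    # item order: permute registry rows, same scores
    reg2 <- as_item_registry(as.data.frame(reg)[sample(6), ])
    spec2 <- index_spec("SARA", "hospital", reg2, validate_counts = FALSE)
    s3 <- score_simple(code_responses(survey, spec2, "additive"))
    expect_equal(s3$score, s1$score)
  }
})

test_that("flipping an available item 0 to 1 never decreases additive scores", {
  set.seed(23)
  reg <- toy_registry(6)
  reg$domain <- rep(c("A", "B"), each = 3)
  reg <- as_item_registry(as.data.frame(reg))
  spec <- index_spec("SARA", "hospital", reg, validate_counts = FALSE)
  for (rep in 1:10) {
    m <- matrix(rbinom(8 * 6, 1, 0.5), 8, 6, dimnames = list(NULL, reg$item_id))
    survey <- toy_survey(tokens_from_binary(m))
    rm_add <- code_responses(survey, spec, "additive")
    base_s <- score_simple(rm_add)$score
    base_w <- score_domain_weighted(rm_add, spec)$score
    zero <- which(m == 0, arr.ind = TRUE)
    if (nrow(zero) == 0) next
    pick <- zero[sample(nrow(zero), 1), ]
    m2 <- m
    m2[pick[1], pick[2]] <- 1
    survey2 <- toy_survey(tokens_from_binary(m2))
    rm2 <- code_responses(survey2, spec, "additive")
    expect_gte(score_simple(rm2)$score[pick[1]], base_s[pick[1]])
    expect_gte(score_domain_weighted(rm2, spec)$score[pick[1]], base_w[pick[1]])
  }
})

test_that("flipping a positively loading item never decreases the PCA score", {
  set.seed(29)
  for (rep in 1:10) {
    m <- matrix(rbinom(12 * 5, 1, 0.5), 12, 5)
    if (any(apply(m, 2, sd) == 0)) next
    rm_pca <- rm_from_binary(m, purpose = "pca")
    fit <- fit_pca(rm_pca)
    zero <- which(m == 0, arr.ind = TRUE)
    pick <- zero[sample(nrow(zero), 1), ]
    if (fit$loadings[pick[2]] <= 0) next
    before <- score_pca(rm_pca, fit)$score[pick[1]]
    m2 <- m
    m2[pick[1], pick[2]] <- 1
    after <- score_pca(rm_from_binary(m2, purpose = "pca"), fit)$score[pick[1]]
    expect_gte(after, before - 1e-12)
  }
})

test_that("perfectly correlated items put all variance on the first component", {
  base <- c(0, 1, 1, 0, 1, 0, 1)
  m <- cbind(a = base, b = base, c = base)
  fit <- fit_pca(rm_from_binary(m, purpose = "pca"))
  expect_equal(fit$variance_explained_first, 1, tolerance = 1e-10)
})

test_that("readiness_index wires coding, scoring and methods together", {
  reg <- toy_registry(6)
  reg$domain <- rep(c("A", "B"), each = 3)
  reg <- as_item_registry(as.data.frame(reg))
  set.seed(31)
  m <- matrix(rbinom(20 * 6, 1, 0.6), 20, 6, dimnames = list(NULL, reg$item_id))
  survey <- toy_survey(tokens_from_binary(m))
  for (method in c("simple", "weighted", "pca")) {
    idx <- readiness_index(survey, "SARA", method, reg)
    expect_s3_class(idx, "readiness_index")
    expect_equal(nrow(idx$scores), 20)
    expect_true(all(idx$scores$score >= -1e-9 & idx$scores$score <= 1 + 1e-9))
    expect_equal(idx$n_items, 6)
  }
  expect_output(print(readiness_index(survey, "SARA", "simple", reg)), "SARA / simple")
  s <- summary(readiness_index(survey, "SARA", "simple", reg))
  expect_s3_class(s, "summary.readiness_index")
  expect_output(print(s), "floor")
})
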