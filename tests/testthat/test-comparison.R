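test_that("index summaries match hand-computed moments", {
  s <- summarize_index(c(0.2, 0.4, 0.6))
  expect_equal(s$mean, 0.4)
  expect_equal(s$sd, 0.2)
  expect_equal(s$cv, 0.5)
  expect_equal(s$skewness, 0, tolerance = 1e-12)  # symmetric sample

  set.seed(79)
  x <- round(runif(8), 3)
  s <- summarize_index(x)
  orc <- oracle_moments(x)
  expect_equal(s$mean, orc$mean, tolerance = 1e-12)
  expect_equal(s$sd, orc$sd, tolerance = 1e-12)
  expect_equal(s$skewness, orc$skewness, tolerance = 1e-12)
  expect_equal(s$kurtosis, orc$kurtosis, tolerance = 1e-12)

  const <- summarize_index(rep(0.5, 6))
  expect_true(is.na(const$skewness) && is.na(const$kurtosis))
})

test_that("floor/ceiling percentages reproduce half-to-even reporting", {
  # 34 of 160 at the ceiling prints 21.2%
  scores <- c(rep(1, 34), seq(0.2, 0.95, length.out = 126))
  fc <- floor_ceiling(scores)
  expect_equal(fc$ceiling_n, 34)
  expect_equal(fc$ceiling_pct, 21.2)
  expect_equal(fc$floor_pct, 0)

  expect_equal(floor_ceiling(rep(1, 10))$ceiling_pct, 100)
  expect_equal(floor_ceiling(c(0, 0.5, 1))$floor_n, 1)

  # pca-style endpoint within tolerance still counts
  expect_equal(floor_ceiling(c(1 - 1e-12, 0.5, 2e-13))$ceiling_n, 1)
  expect_equal(floor_ceiling(c(1 - 1e-12, 0.5, 2e-13))$floor_n, 1)
})

test_that("tie analysis counts facilities at the top two distinct scores", {
  # 50 of 160 at the second-highest distinct score prints 31.2%
  scores <- c(rep(1, 34), rep(21 / 22, 50), seq(0.2, 0.9, length.out = 76))
  t <- rank_with_ties(scores)
  expect_equal(t$n_top, 34)
  expect_equal(t$n_second, 50)
  expect_equal(t$pct_second, 31.2)
  expect_equal(t$pct_top, 21.2)

  all_distinct <- rank_with_ties(c(0.1, 0.5, 0.9))
  expect_true(all(all_distinct$tie_sizes == 1))
  expect_equal(all_distinct$rank_dense, c(3, 2, 1))

  const <- rank_with_ties(rep(0.7, 5))
  expect_equal(const$tie_sizes, 5L)
  expect_equal(const$n_second, 0L)
  expect_equal(const$rank_average, rep(3, 5))
})

test_that("Bland-Altman agreement matches direct computation", {
  a <- c(0.9, 0.8, 0.7, 0.85, 0.6, 0.95, 0.4, 0.55, 0.75, 0.65)
  b <- a + c(0.05, -0.02, 0.01, 0.03, -0.04, 0, 0.02, -0.01, 0.04, -0.03)
  ba <- bland_altman(a, b)
  d <- a - b
  expect_equal(ba$mean_difference, sum(d) / 10, tolerance = 1e-12)
  expect_equal(ba$sd_difference, sqrt(sum((d - mean(d))^2) / 9), tolerance = 1e-12)
  expect_equal(ba$loa_lower, mean(d) - 2 * sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_upper, mean(d) + 2 * sd(d), tolerance = 1e-12)
  expect_equal(ba$n_outside_loa, sum(d < ba$loa_lower | d > ba$loa_upper))
  expect_equal(ba$rank_correlation, oracle_spearman(a, b), tolerance = 1e-12)

  same <- bland_altman(a, a)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$sd_difference, 0)

  shift <- bland_altman(a, a + 0.1)
  expect_equal(shift$mean_difference, -0.1, tolerance = 1e-12)
  expect_equal(shift$sd_difference, 0, tolerance = 1e-12)
})

test_that("Bland-Altman is antisymmetric in the mean and symmetric in the SD", {
  set.seed(83)
  a <- runif(15)
  b <- runif(15)
  ab <- bland_altman(a, b)
  ba <- bland_altman(b, a)
  expect_equal(ab$mean_difference, -ba$mean_difference, tolerance = 1e-12)
  expect_equal(ab$sd_difference, ba$sd_difference, tolerance = 1e-12)
})

test_that("mismatched facility sets raise an alignment error naming them", {
  a <- c(F1 = 0.5, F2 = 0.6, F3 = 0.7)
  b <- c(F1 = 0.5, F2 = 0.6, F9 = 0.7)
  expect_error(bland_altman(a, b), "F3", class = "cbready_alignment_error")
  expect_error(bland_altman(a, b), "F9")
})

test_that("Spearman correlation handles monotone inputs, ties and missing pairs", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)

  set.seed(89)
  x <- sample(1:6, 12, replace = TRUE)  # plenty of ties
  y <- sample(1:6, 12, replace = TRUE)
  got <- spearman_cor(x, y)
  expect_equal(got$rho, oracle_spearman(x, y), tolerance = 1e-12)
  tt <- got$rho * sqrt(10 / (1 - got$rho^2))
  expect_equal(got$p_value, 2 * pt(-abs(tt), 10), tolerance = 1e-12)

  # invariance to strictly monotone transforms
  z <- runif(12)
  expect_equal(spearman_cor(exp(x), log(z + 1))$rho,
               spearman_cor(x, z)$rho, tolerance = 1e-12)

  # missing values are deleted pairwise
  xm <- c(x, NA)
  ym <- c(y, 3)
  expect_equal(spearman_cor(xm, ym)$n, 12)
  expect_equal(spearman_cor(xm, ym)$rho, got$rho)

  expect_warning(und <- spearman_cor(rep(1, 5), 1:5), "undefined")
  expect_true(is.na(und$rho))
  expect_error(spearman_cor(c(1, 2), c(3, 4)), class = "cbready_insufficient_data")
})

test_that("domain deconstruction recovers the shared-trait structure", {
  reg <- builtin_item_registry()
  cohort <- generate_cohort(preset_observed_regime(seed = 97), reg)
  hc <- cohort[cohort$tier == "health_centre_clinic", ]
  class(hc) <- class(cohort)
  idx <- list(
    readiness_index(hc, "SARA", "weighted", reg),
    readiness_index(hc, "WHO_standards", "weighted", reg)
  )
  dd <- domain_deconstruction(idx)
  expect_equal(nrow(dd$matrix), 3 + 4)  # SARA 3 + WHO 4 domains
  expect_equal(unname(diag(dd$matrix)), rep(1, 7))
  expect_equal(dd$matrix, t(dd$matrix))
  # single latent trait drives everything: all interdomain correlations positive
  off <- dd$matrix[lower.tri(dd$matrix)]
  expect_true(all(off > 0))

  # two domains holding identical responses correlate exactly 1
  twin_reg <- as_item_registry(data.frame(
    item_id = c("i1", "i2", "i3", "j1", "j2", "j3"),
    label = "twin", framework = rep(c("SARA", "DHS"), each = 3),
    domain = rep(c("A", "B"), each = 3),
    who_standard = NA_character_, tier_applicability = "both",
    conditional_authority = NA_character_, stringsAsFactors = FALSE))
  set.seed(99)
  m <- matrix(rbinom(10 * 3, 1, 0.6), 10, 3)
  tok <- cbind(tokens_from_binary(m), tokens_from_binary(m))
  colnames(tok) <- twin_reg$item_id
  survey <- toy_survey(tok)
  twin_idx <- list(
    readiness_index(survey, "SARA", "weighted", twin_reg),
    readiness_index(survey, "DHS", "weighted", twin_reg)
  )
  dup <- domain_deconstruction(twin_idx)
  expect_equal(dup$matrix["SARA.A", "DHS.B"], 1, tolerance = 1e-12)
})

test_that("compare_all emits the full per-index table and agreement set", {
  reg <- builtin_item_registry()
  cohort <- generate_cohort(preset_observed_regime(seed = 101), reg)
  hosp <- cohort[cohort$tier == "hospital", ]
  class(hosp) <- class(cohort)
  bat <- suppressWarnings(readiness_battery(hosp, reg))
  rep <- compare_all(bat, hosp)
  expect_s3_class(rep, "comparison_report")
  expect_equal(nrow(rep$table), 9)  # 3 frameworks x 3 methods
  expect_equal(nrow(rep$agreement), choose(9, 2))
  expect_true(all(rep$table$volume_rho > 0))  # positive volume link
  expect_true(all(rep$table$cv > 0))

  # self-comparison sanity: identical indices agree exactly
  self <- compare_all(bat[c(1, 1)], hosp)
  expect_equal(self$agreement$mean_difference, 0)
  expect_equal(self$agreement$sd_difference, 0)

  expect_output(print(rep), "9 indices")
})

test_that("shorter indices produce at least as many top-two ties as longer ones", {
  reg <- builtin_item_registry()
  wins <- 0
  for (seed in 1:20) {
    cohort <- generate_cohort(preset_observed_regime(seed = seed), reg)
    hosp <- cohort[cohort$tier == "hospital", ]
    class(hosp) <- class(cohort)
    short <- readiness_index(hosp, "SARA", "simple", reg)
    long <- readiness_index(hosp, "WHO_standards", "simple", reg)
    ts <- rank_with_ties(short$scores$score)
    tl <- rank_with_ties(long$scores$score)
    if (ts$n_top + ts$n_second >= tl$n_top + tl$n_second) wins <- wins + 1
  }
  expect_gt(wins, 10)  # majority over 20 paired seeds
})

test_that("lowering item difficulties never reduces the expected ceiling", {
  reg <- toy_registry(10)
  spec <- index_spec("SARA", "hospital", reg, validate_counts = FALSE)
  wins <- 0
  for (seed in 1:10) {
    base_params <- local({
      set.seed(seed)
      data.frame(item_id = reg$item_id, a = runif(10, 0.8, 2),
                 b = rnorm(10, 0, 1), stringsAsFactors = FALSE)
    })
    easy_params <- transform(base_params, b = b - 1)
    mk <- function(params) {
      cfg <- synthetic_config(n_hospitals = 200, n_health_centres = 0,
                              item_params = params, seed = seed)
      cohort <- generate_cohort(cfg, reg)
      s <- readiness_index(cohort, "SARA", "simple", reg)
      floor_ceiling(s$scores$score)$ceiling_n
    }
    if (mk(easy_params) >= mk(base_params)) wins <- wins + 1
  }
  expect_gt(wins, 5)
})
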