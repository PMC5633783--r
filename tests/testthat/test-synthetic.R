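test_that("default configuration encodes the reference cohort", {
  cfg <- default_config()
  expect_identical(cfg$n_subjects, 33L)
  expect_equal(cfg$seizure_prob, 15 / 33)
  expect_equal(cfg$age_range, c(18, 62))
  expect_equal(cfg$male_fraction, 23 / 33)
  expect_equal(c(cfg$age_mean, cfg$age_sd), c(33.6, 16.5))
  expect_equal(c(cfg$gcs_mean, cfg$gcs_sd), c(6.15, 3.36))
  expect_equal(c(cfg$gos_mean, cfg$gos_sd), c(5.43, 2.51))
})

test_that("generation is deterministic given the seed", {
  a <- generate_cohort(default_config(), seed = 5)
  b <- generate_cohort(default_config(), seed = 5)
  attr(a, "truth") <- attr(b, "truth") <- NULL
  expect_identical(a, b)
  expect_false(identical(a$acute$values,
                         generate_cohort(default_config(),
                                         seed = 6)$acute$values))
})

test_that("a zero-effect zero-noise configuration yields no thickness change", {
  cfg <- default_config()
  cfg[c("atrophy_intercept", "beta_gcs", "beta_seizure", "beta_age",
        "beta_sex", "noise_sd")] <- 0
  cfg$missing_subject_prob <- 0
  co <- generate_cohort(cfg, seed = 2)
  expect_equal(co$acute$values, co$chronic$values, tolerance = 1e-12)
})

test_that("null cohorts give small finite F statistics downstream", {
  cfg <- default_config()
  cfg[c("beta_gcs", "beta_seizure", "beta_age", "beta_sex")] <- 0
  cfg$missing_subject_prob <- 0
  co <- generate_cohort(cfg, seed = 8)
  sc <- region_scan(co, n_perm = 0, seed = 1)
  F <- sc$results$F[sc$results$status == "tested"]
  expect_true(all(is.finite(F)))
  expect_lt(median(F), 3)   # null F_{2,30} has median ~0.7
})

test_that("OLS refit of the generating model recovers beta_seizure", {
  cfg <- default_config()
  cfg$n_subjects <- 200L
  cfg$noise_sd <- 0.01
  cfg$beta_seizure <- 0.05
  cfg$missing_subject_prob <- 0
  co <- generate_cohort(cfg, seed = 31)
  truth <- attr(co, "truth")$region_betas
  j <- which(truth$affected)[1]
  atr <- relative_atrophy(co$acute, co$chronic)
  s <- co$subjects
  fit <- lm(atr$values[, j] ~ I(15 - s$gcs_e) + s$seizure +
              I(s$age - mean(s$age)) + I(s$sex == "male"))
  est <- summary(fit)$coefficients["s$seizure", ]
  expect_lt(abs(est["Estimate"] - cfg$beta_seizure),
            3 * est["Std. Error"])
})

test_that("sample moments match the configured targets at large n", {
  cfg <- default_config()
  cfg$n_subjects <- 10000L
  co <- generate_cohort(cfg, seed = 1)
  s <- co$subjects
  n <- cfg$n_subjects
  # 3 Monte-Carlo standard errors of each sample moment
  expect_lt(abs(mean(s$age) - cfg$age_mean), 3 * cfg$age_sd / sqrt(n))
  expect_lt(abs(sd(s$age) - cfg$age_sd), 3 * cfg$age_sd / sqrt(2 * n))
  expect_lt(abs(mean(s$gcs_e) - cfg$gcs_mean), 3 * cfg$gcs_sd / sqrt(n))
  expect_lt(abs(sd(s$gcs_e) - cfg$gcs_sd), 3 * cfg$gcs_sd / sqrt(2 * n))
  se_seiz <- sqrt(cfg$seizure_prob * (1 - cfg$seizure_prob) / n)
  expect_lt(abs(mean(s$seizure) - cfg$seizure_prob), 3 * se_seiz)
})

test_that("greater mean atrophy couples to lower GOS-E", {
  for (seed in 1:5) {
    co <- generate_cohort(default_config(), seed = seed)
    truth <- attr(co, "truth")$subject_atrophy
    expect_lt(cor(truth$mean_true_atrophy, co$subjects$gos_e), 0)
  }
})

test_that("generated thickness is strictly positive and below 10 mm", {
  co <- generate_cohort(default_config(), seed = 13)
  expect_true(all(co$acute$values > 0 & co$acute$values < 10))
  expect_true(all(co$chronic$values > 0 & co$chronic$values < 10))
})

test_that("missingness injection obeys its probability and block contract", {
  cfg <- default_config()
  co <- generate_cohort(cfg, seed = 21)

  cfg0 <- cfg; cfg0$missing_subject_prob <- 0
  expect_identical(inject_missingness(co, cfg0, seed = 1), co)

  cfg1 <- cfg; cfg1$missing_subject_prob <- 1
  cfg1$missing_block_size <- 15L
  m <- inject_missingness(co, cfg1, seed = 1)
  expect_true(all(rowSums(m$acute$missing_mask) == 15))
  expect_identical(m$acute$missing_mask, m$chronic$missing_mask)
  # blocks are contiguous in registry order
  runs <- apply(m$acute$missing_mask, 1, function(r) {
    w <- which(r); all(diff(w) == 1)
  })
  expect_true(all(runs))

  cfg_big <- cfg; cfg_big$missing_block_size <- 999L
  expect_error(inject_missingness(co, cfg_big, seed = 1), "exceeds")
})

test_that("default missingness leaves ~10% of regions below the 90% rule", {
  cfg <- default_config()
  # analytic expectation from the binomial lesion-coverage model
  R <- 148; b <- cfg$missing_block_size; N <- cfg$n_subjects
  nstart <- R - b + 1
  cover <- vapply(1:R, function(j)
    (min(j, nstart) - max(1, j - b + 1) + 1) / nstart, numeric(1))
  expected <- mean(pbinom(3, N, cfg$missing_subject_prob * cover,
                          lower.tail = FALSE))
  reps <- 100
  frac <- vapply(seq_len(reps), function(s) {
    co <- inject_missingness(generate_cohort(cfg, seed = s), cfg,
                             seed = s + 5000)
    atr <- relative_atrophy(co$acute, co$chronic)
    mean(!availability_scan(atr, co$N)$tested)
  }, numeric(1))
  mc_se <- sd(frac) / sqrt(reps)
  expect_lt(abs(mean(frac) - expected), 3 * mc_se)
  expect_lt(abs(expected - 0.10), 0.03)   # the sizing target itself
})
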