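mk_thick <- function(vals, missing = NULL, timepoint = "acute") {
  v <- as.matrix(vals)
  if (is.null(missing)) missing <- matrix(FALSE, nrow(v), ncol(v))
  dimnames(missing) <- dimnames(v)
  structure(list(timepoint = timepoint, values = v,
                 missing_mask = missing), class = "thickness_matrix")
}

test_that("relative atrophy follows (acute - chronic)/acute with NA propagation", {
  a <- mk_thick(cbind(r1 = c(2.5, 2.0, 3.0)))
  c <- mk_thick(cbind(r1 = c(2.5, 1.8, 2.7)), timepoint = "chronic")
  atr <- relative_atrophy(a, c)
  expect_equal(atr$values[, 1], c(0, 0.1, 0.1), tolerance = 1e-12,
               ignore_attr = TRUE)

  a2 <- mk_thick(cbind(r1 = c(NA, 2.0)), missing = cbind(c(TRUE, FALSE)))
  c2 <- mk_thick(cbind(r1 = c(2.0, 2.0)), timepoint = "chronic")
  atr2 <- relative_atrophy(a2, c2)
  expect_true(atr2$missing_mask[1, 1])
  expect_true(is.na(atr2$values[1, 1]))
  expect_false(atr2$missing_mask[2, 1])

  a3 <- mk_thick(cbind(r1 = c(-1, 2)))
  expect_error(relative_atrophy(a3, c2), "positive")
})

test_that("relative atrophy equals 1 - chronic/acute", {
  set.seed(42)
  a <- mk_thick(matrix(runif(50, 1.5, 4), 10, 5))
  c <- mk_thick(matrix(runif(50, 1.5, 4), 10, 5), timepoint = "chronic")
  atr <- relative_atrophy(a, c)
  expect_equal(atr$values, 1 - c$values / a$values, tolerance = 1e-12)
})

test_that("the 90% availability rule is inclusive at the boundary", {
  mk_avail <- function(N, n_missing) {
    miss <- matrix(FALSE, N, 1)
    miss[seq_len(n_missing), 1] <- TRUE
    v <- matrix(0.1, N, 1, dimnames = list(NULL, "r1"))
    v[miss] <- NA
    availability_scan(structure(list(values = v, missing_mask = miss,
                                     imputed_mask = miss & FALSE),
                                class = "atrophy_matrix"), N)
  }
  expect_true(mk_avail(33, 3)$tested)     # 30/33 = 0.909
  expect_false(mk_avail(33, 4)$tested)    # 29/33 < 0.9
  expect_true(mk_avail(10, 1)$tested)     # exactly 0.9
  expect_equal(mk_avail(33, 3)$n_available, 30L)
})

test_that("mean substitution fills missing cells with the observed mean", {
  v <- cbind(r1 = c(0.1, 0.2, 0.3, NA), r2 = c(0.05, 0.06, 0.07, 0.08))
  miss <- is.na(v)
  atr <- structure(list(values = v, missing_mask = miss,
                        imputed_mask = miss & FALSE),
                   class = "atrophy_matrix")
  avail <- availability_scan(atr, 4, min_fraction = 0.7)
  imp <- impute_region_means(atr, avail)
  expect_equal(unname(imp$values[4, "r1"]), 0.2)
  expect_true(imp$imputed_mask[4, "r1"])
  expect_identical(imp$values[, "r2"], v[, "r2"])
  expect_false(any(imp$imputed_mask[, "r2"]))
})

test_that("imputation preserves region means and never inflates variance", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    v <- matrix(rnorm(n * 3, 0.05, 0.03), n, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    miss <- matrix(runif(n * 3) < 0.1, n, 3, dimnames = dimnames(v))
    miss[1, ] <- FALSE   # keep at least one observed value per region
    vv <- v; vv[miss] <- NA
    atr <- structure(list(values = vv, missing_mask = miss,
                          imputed_mask = miss & FALSE),
                     class = "atrophy_matrix")
    avail <- availability_scan(atr, n, min_fraction = 0)
    imp <- impute_region_means(atr, avail)
    for (j in 1:3) {
      obs_mean <- mean(vv[!miss[, j], j])
      expect_equal(mean(imp$values[, j]), obs_mean, tolerance = 1e-12)
      expect_lte(var(imp$values[, j]), var(vv[!miss[, j], j]) + 1e-12)
    }
  }
})

test_that("nuisance residualization projects out age and sex", {
  set.seed(3)
  n <- 12
  age <- runif(n, 20, 60)
  sex <- rbinom(n, 1, 0.5)

  # independent normal-equations oracle
  y <- rnorm(n)
  X <- cbind(1, age - mean(age), sex)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(residualize_nuisance(y, age, sex),
               as.numeric(y - X %*% beta), tolerance = 1e-10)

  # residuals orthogonal to the nuisance span
  r <- residualize_nuisance(y, age, sex)
  expect_lt(abs(sum(r)), 1e-8)
  expect_lt(abs(sum(r * age)), 1e-6 * sqrt(sum(r^2) * sum(age^2)))
  expect_lt(abs(sum(r * sex)), 1e-8)

  # a perfect nuisance fit leaves ~0; an orthogonal y is unchanged
  expect_equal(residualize_nuisance(3 * age, age, sex), rep(0, n),
               tolerance = 1e-9)
  y_orth <- residualize_nuisance(rnorm(n), age, sex)
  expect_equal(residualize_nuisance(y_orth, age, sex), y_orth,
               tolerance = 1e-9)

  # single-sex cohort: collinear column dropped with a warning, not an error
  expect_warning(r1 <- residualize_nuisance(y, age, rep(1, n)),
                 "collinear")
  expect_length(r1, n)
})

test_that("character sex codings map onto the male indicator", {
  set.seed(9)
  y <- rnorm(10); age <- runif(10, 20, 60)
  sex_chr <- rep(c("male", "female"), 5)
  sex_int <- rep(c(1, 0), 5)
  expect_identical(residualize_nuisance(y, age, sex_chr),
                   residualize_nuisance(y, age, sex_int))
  expect_identical(residualize_nuisance(y, age, rep(c("M", "F"), 5)),
                   residualize_nuisance(y, age, sex_int))
})

test_that("availability on default synthetic cohorts matches the generator", {
  co <- small_cohort(seed = 40, n = 33, with_missing = TRUE)
  prep <- prepare_atrophy(co)
  expect_identical(prep$availability$tested,
                   prep$availability$fraction_available >= 0.9)
  expect_false(any(prep$atrophy$imputed_mask[
    , !prep$availability$tested]))
  # imputed regions are complete
  tested <- prep$availability$tested
  vals <- prep$atrophy$values[, tested, drop = FALSE]
  expect_false(anyNA(vals))
})
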