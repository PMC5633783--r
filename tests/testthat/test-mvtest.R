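test_that("least-squares coefficients reproduce known and oracle solutions", {
  set.seed(14)
  n <- 10
  X <- cbind(intercept = 1, gcs = rnorm(n), seiz = rbinom(n, 1, 0.5))
  C <- matrix(c(0.5, -0.2, 0.3), 3, 1)
  expect_equal(fit_coefficients(X, X %*% C), C, tolerance = 1e-9,
               ignore_attr = TRUE)

  # predictors orthogonal to the response: predictor rows of B ~ 0
  y0 <- residualize_nuisance(rnorm(n), X[, 2], X[, 3]) # orthogonal to both
  B0 <- fit_coefficients(X, y0)
  expect_lt(max(abs(B0[2:3, ])), 1e-8)

  # random 8 x 3 instance vs dense normal-equations oracle
  X8 <- cbind(1, rnorm(8), rnorm(8))
  y8 <- rnorm(8)
  oracle <- solve(t(X8) %*% X8) %*% t(X8) %*% y8
  expect_equal(fit_coefficients(X8, y8), oracle, tolerance = 1e-8,
               ignore_attr = TRUE)

  Xbad <- cbind(1, 1:8, 2 * (1:8))
  colnames(Xbad) <- c("i", "a", "b")
  expect_error(fit_coefficients(Xbad, y8), "collinear")
})

test_that("Wilks' lambda yields F(2, 30) at N = 33 with one response", {
  set.seed(1)
  X <- cbind(1, rnorm(33), rbinom(33, 1, 0.5))
  ws <- wilks_statistics(X, rnorm(33))
  expect_equal(ws$d1, 2)
  expect_equal(ws$d2, 30)
  expect_equal(ws$nu_H, 2)
  expect_equal(ws$nu_E, 30)
  expect_equal(ws$R2, 1 - ws$lambda, tolerance = 1e-12)
  expect_error(wilks_statistics(X, rep(1, 33)), "degenerate")
  expect_error(wilks_statistics(cbind(1, rnorm(3), rnorm(3)), rnorm(3)),
               "N > q")
})

test_that("the Wilks route equals the classical regression F (p = 1)", {
  set.seed(2024)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    X <- cbind(1, rnorm(n), rnorm(n))
    y <- rnorm(n) + X[, 2] * runif(1, -1, 1)
    ws <- wilks_statistics(X, y)
    expect_equal(ws$F, lm_overall_f(X, y), tolerance = 1e-8)
    expect_equal(ws$F,
                 (ws$R2 / 2) / ((1 - ws$R2) / (n - 3)), tolerance = 1e-8)
  }
})

test_that("multi-response Wilks agrees with the manova oracle", {
  set.seed(55)
  n <- 25
  g <- rnorm(n); s <- rbinom(n, 1, 0.5)
  Y <- cbind(rnorm(n) + 0.5 * g, rnorm(n) - 0.3 * s)
  ws <- wilks_statistics(cbind(1, g, s), Y)
  mv <- summary(stats::manova(Y ~ g + s), test = "Wilks")
  # single omnibus test of both predictors: refit via the overall model
  fit0 <- stats::lm(Y ~ 1)
  fit1 <- stats::lm(Y ~ g + s)
  an <- stats::anova(fit0, fit1, test = "Wilks")
  expect_equal(ws$lambda, an$Wilks[2], tolerance = 1e-8)
  expect_equal(ws$F, an$`approx F`[2], tolerance = 1e-8)
  expect_equal(c(ws$d1, ws$d2), c(an$`num Df`[2], an$`den Df`[2]),
               tolerance = 1e-8)
})

test_that("larger lambda means smaller F at fixed degrees of freedom", {
  lam <- seq(0.05, 0.95, by = 0.05)
  # p = 1, q = 2, N = 33: F = (1 - lambda)/lambda * 15
  F <- (1 - lam) / lam * 15
  expect_true(all(diff(F) < 0))
})

test_that("parametric tail probabilities match closed-form values", {
  expect_equal(parametric_p(0, 2, 30), 1)
  expect_equal(round(parametric_p(6.19, 2, 30), 4), 0.0056)
  expect_equal(round(parametric_p(5.72, 2, 30), 4), 0.0079)
})

test_that("F is invariant to affine predictor rescaling", {
  set.seed(77)
  n <- 33
  g <- rnorm(n); s <- rbinom(n, 1, 0.5); y <- rnorm(n) + 0.3 * g
  F1 <- wilks_statistics(cbind(1, g, s), y)$F
  F2 <- wilks_statistics(cbind(1, 10 * g - 4, s), y)$F
  expect_equal(F1, F2, tolerance = 1e-10)
  # and to nuisance already removed from y
  age <- runif(n, 20, 60); sex <- rbinom(n, 1, 0.5)
  yr <- residualize_nuisance(y, age, sex)
  F3 <- wilks_statistics(cbind(1, g, s), yr)$F
  F4 <- wilks_statistics(cbind(1, g, s),
                         residualize_nuisance(yr, age, sex))$F
  expect_equal(F3, F4, tolerance = 1e-9)
})

test_that("exhaustive permutation matches brute-force enumeration", {
  set.seed(31)
  n <- 5
  X <- cbind(1, rnorm(n), c(1, 0, 0, 1, 0))
  y <- rnorm(n)
  res <- permutation_p(X, y, exhaustive = TRUE)

  # independent enumeration: all 120 row orders through lm()
  perms <- as.matrix(expand.grid(rep(list(1:n), n)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == n), ,
                 drop = FALSE]
  expect_equal(nrow(perms), 120)
  F_obs <- lm_overall_f(X, y)
  F_all <- apply(perms, 1, function(pr) {
    Xp <- X; Xp[, 2:3] <- X[pr, 2:3]
    lm_overall_f(Xp, y)
  })
  expect_equal(res$p_perm, mean(F_all >= F_obs - 1e-9), tolerance = 1e-12)
})

test_that("fast permutation path equals per-permutation refits", {
  set.seed(90)
  n <- 18
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  y <- rnorm(n) + 0.4 * X[, 2]
  res <- permutation_p(X, y, n_perm = 50, seed = 4, return_null = TRUE)
  # replay the same permutation stream and refit each via lm
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(4)
  perms <- t(vapply(1:50, function(k) sample.int(n), integer(n)))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  F_lm <- apply(perms, 1, function(pr) {
    Xp <- X; Xp[, 2:3] <- X[pr, 2:3]
    lm_overall_f(Xp, y)
  })
  expect_equal(res$null_F, F_lm, tolerance = 1e-8)
})

test_that("the smallest attainable permutation p is 1/(n_perm + 1)", {
  set.seed(6)
  n <- 33
  g <- rnorm(n)
  y <- g            # perfect association: observed F dominates
  X <- cbind(1, g, rbinom(n, 1, 0.5))
  res <- permutation_p(X, y + rnorm(n, 0, 1e-4), n_perm = 999, seed = 2)
  expect_equal(res$p_perm, 1 / 1000)
})

test_that("region scan flags untested regions and fills q only when tested", {
  co <- small_cohort(seed = 19, n = 33, with_missing = TRUE)
  sc <- region_scan(co, n_perm = 50, seed = 3)
  r <- sc$results
  expect_identical(sort(unique(r$status)), c("tested", "untested"))
  expect_true(all(is.na(r$F[r$status == "untested"])))
  expect_true(all(!is.na(r$q_value[r$status == "tested"])))
  expect_true(all(r$d1[r$status == "tested"] == 2))
  expect_true(all(r$d2[r$status == "tested"] == co$N - 3))
  expect_true(all(r$p_perm[r$status == "tested"] >= 1 / 51))
  # f2 consistent with R2
  t_rows <- r$status == "tested"
  expect_equal(r$f2[t_rows], r$R2[t_rows] / (1 - r$R2[t_rows]),
               tolerance = 1e-10)
})

test_that("the functional-outcome scan returns a single record", {
  co <- small_cohort(seed = 23, n = 33)
  sc <- region_scan(co, response = "gos", n_perm = 20, seed = 9)
  expect_equal(nrow(sc$results), 1L)
  expect_equal(sc$results$d1, 2)
  expect_equal(sc$results$d2, co$N - 3)
  expect_equal(sc$results$q_value, sc$results$p_param)
})

test_that("scan results serialize and methods run", {
  co <- small_cohort(seed = 29, n = 33, with_missing = TRUE)
  sc <- region_scan(co, n_perm = 0, seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_results(sc$results, f, "step1")
  back <- read_results(f, "step1")
  expect_equal(nrow(back), 148)
  tested <- back$status == "tested"
  expect_equal(back$F[tested], sc$results$F[tested], tolerance = 1e-6)
  expect_output(print(sc), "regions tested")
  expect_output(summary(sc), "Top regions|regions tested")
  expect_true(is.matrix(coef(sc)))
})
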