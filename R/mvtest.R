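# Step 1: per-region multivariate linear regression of atrophy (or outcome)
# on GCS-E and seizure occurrence, with Wilks' lambda -> F inference,
# parametric and permutation p-values.
#
# Conventions (Rencher, Methods of Multivariate Analysis, ch. 10): with
# design X (intercept + q predictors) and N x p response Y,
#   B = (X'X)^-1 X'Y                       least-squares coefficients
#   E = Y'Y - B'X'Y                        residual SSCP
#   H = B'X'Y - N ybar'ybar                regression SSCP
#   Lambda = det(E) / det(E + H),  nu_H = q,  nu_E = N - q - 1
# and Rao's transformation gives an F statistic with
#   d1 = p nu_H,  d2 = w t - (p nu_H - 2)/2,
#   w = nu_E + nu_H - (p + nu_H + 1)/2,
#   t = sqrt((p^2 nu_H^2 - 4) / (p^2 + nu_H^2 - 5))   (t = 1 when degenerate)
#   F = (1 - Lambda^(1/t)) / Lambda^(1/t) * d2 / d1.
# For p = 1, q = 2, N = 33 this is exact: d1 = 2, d2 = 30, and F equals the
# classical overall regression F.

#' Least-squares coefficients of a multivariate linear model
#'
#' Solves the normal equations `B = (X'X)^-1 X'Y` via a QR decomposition
#' (numerically stable; no explicit inverse is formed).
#'
#' @param X Design matrix, N x (1+q), intercept column included.
#' @param Y Response: N-vector or N x p matrix.
#' @return Coefficient matrix B, (1+q) x p.
#' @export
fit_coefficients <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    stop("X and Y must have the same number of rows", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    cn <- colnames(X)
    if (is.null(cn)) cn <- paste0("X", seq_len(ncol(X)))
    bad <- cn[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  B <- qr.coef(qrX, Y)
  B <- as.matrix(B)
  rownames(B) <- colnames(X)
  B
}

#' Wilks' lambda and its F transformation
#'
#' Computes the omnibus test of the q predictor columns of `X` (the intercept
#' is not part of the hypothesis) against the p-column response `Y`, via the
#' residual and regression SSCP matrices, Wilks' lambda, and Rao's
#' lambda-to-F transformation.  For a single response (p = 1) the F statistic
#' is exact and equals the classical overall regression F, and `R2 =
#' 1 - lambda`.
#'
#' @param X Design matrix with leading intercept column and q predictor
#'   columns.
#' @param Y Response vector or N x p matrix.
#' @return List with `lambda`, `F`, `d1`, `d2`, `R2` (NA when p > 1), plus
#'   `nu_H`, `nu_E`, `B`.
#' @export
wilks_statistics <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  N <- nrow(X); p <- ncol(Y); q <- ncol(X) - 1L
  if (q < 1) stop("X must contain an intercept and >= 1 predictor",
                  call. = FALSE)
  if (N <= q + 1)
    stop("need N > q + 1 subjects (error d.f. must be positive)",
         call. = FALSE)
  B <- fit_coefficients(X, Y)
  BtXtY <- crossprod(B, crossprod(X, Y))
  E <- crossprod(Y) - BtXtY
  ybar <- colMeans(Y)
  Tmat <- crossprod(Y) - N * outer(ybar, ybar)   # total (E + H)
  H <- BtXtY - N * outer(ybar, ybar)
  detT <- det(Tmat)
  if (!is.finite(detT) || detT <= .Machine$double.eps * N)
    stop("degenerate response: total SSCP matrix is singular ",
         "(constant response?)", call. = FALSE)
  lambda <- det(E) / detT
  lambda <- min(max(lambda, .Machine$double.xmin), 1)
  nu_H <- q; nu_E <- N - q - 1
  w <- nu_E + nu_H - (p + nu_H + 1) / 2
  disc_num <- p^2 * nu_H^2 - 4
  disc_den <- p^2 + nu_H^2 - 5
  t_exp <- if (disc_num <= 0 || disc_den <= 0) 1 else
    sqrt(disc_num / disc_den)
  d1 <- p * nu_H
  d2 <- w * t_exp - (p * nu_H - 2) / 2
  lam_t <- lambda^(1 / t_exp)
  Fstat <- (1 - lam_t) / lam_t * d2 / d1
  list(lambda = lambda, F = Fstat, d1 = d1, d2 = d2,
       R2 = if (p == 1) 1 - lambda else NA_real_,
       nu_H = nu_H, nu_E = nu_E, B = B)
}

#' Upper tail of the central F distribution
#'
#' @param F F statistic(s), >= 0.
#' @param d1,d2 Numerator and denominator degrees of freedom.
#' @return Upper-tail probability `P(F_{d1,d2} >= F)`.
#' @examples
#' parametric_p(6.19, 2, 30)   # 0.0056
#' @export
parametric_p <- function(F, d1, d2) {
  stopifnot(all(F >= 0), d1 > 0, d2 > 0)
  stats::pf(F, d1, d2, lower.tail = FALSE)
}

# all permutations of 1..n (n <= 8), as an n! x n index matrix
.all_permutations <- function(n) {
  if (n > 8) stop("exhaustive enumeration limited to n <= 8", call. = FALSE)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    block <- cbind(rep(k, nrow(sub)), sub + (sub >= k))
    out[[k]] <- block
  }
  do.call(rbind, out)
}

#' Permutation p-value for the regression F statistic
#'
#' Re-computes the F statistic after randomly permuting the predictor rows of
#' the design matrix jointly (the intercept is untouched, and the pairing of
#' predictor values within a row is preserved), `n_perm` times.  The
#' empirical p-value uses the add-one estimator
#' `(1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`.  With `exhaustive = TRUE`
#' all `N!` row orders are enumerated instead (small N only) and the exact
#' proportion is returned.
#'
#' For a single response the permuted statistics are computed in closed form
#' from permuted cross-products (the predictor Gram matrix is permutation
#' invariant), which makes the default 10,000-permutation scan fast.
#'
#' @param X Design matrix with leading intercept column.
#' @param Y Response vector (or single-column matrix; multi-column responses
#'   fall back to a direct loop).
#' @param n_perm Number of random permutations (>= 1).
#' @param seed Integer seed; the global RNG state is untouched.
#' @param exhaustive Enumerate all row orders instead of sampling.
#' @param return_null Also return the permuted F sample.
#' @return List with `p_perm`, `F_obs`, `n_perm`, and (optionally) `null_F`.
#' @export
permutation_p <- function(X, Y, n_perm = 10000, seed = 1,
                          exhaustive = FALSE, return_null = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  N <- nrow(X); p <- ncol(Y); q <- ncol(X) - 1L
  obs <- wilks_statistics(X, Y)
  perms <- if (exhaustive) {
    .all_permutations(N)
  } else {
    if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
    .with_seed(seed,
      t(vapply(seq_len(n_perm), function(k) sample.int(N),
               integer(N))))
  }
  K <- nrow(perms)
  if (p == 1L) {
    y <- as.numeric(Y)
    yc <- y - mean(y)
    Xc <- sweep(X[, -1, drop = FALSE], 2, colMeans(X[, -1, drop = FALSE]))
    Ainv <- solve(crossprod(Xc))
    sstot <- sum(yc^2)
    Cmat <- matrix(0, K, q)
    for (j in seq_len(q)) {
      Gp <- matrix(Xc[perms, j], K, N)   # row k = predictor j under perm k
      Cmat[, j] <- Gp %*% yc
    }
    ssreg <- rowSums((Cmat %*% Ainv) * Cmat)
    null_F <- (ssreg / q) / ((sstot - ssreg) / (N - q - 1))
  } else {
    null_F <- vapply(seq_len(K), function(k) {
      Xp <- X
      Xp[, -1] <- X[perms[k, ], -1, drop = FALSE]
      wilks_statistics(Xp, Y)$F
    }, numeric(1))
  }
  tol <- 1e-9 * max(1, abs(obs$F))
  hits <- sum(null_F >= obs$F - tol)
  p_perm <- if (exhaustive) hits / K else (1 + hits) / (1 + K)
  out <- list(p_perm = p_perm, F_obs = obs$F, n_perm = K)
  if (return_null) out$null_F <- null_F
  out
}

#' Region-wise multivariate regression scan (analysis step 1)
#'
#' For every region passing the 90% availability rule, fits the multivariate
#' linear model of nuisance-residualized relative atrophy on acute GCS-E and
#' seizure occurrence, and reports Wilks' lambda, the F statistic with its
#' degrees of freedom, parametric and (optionally) permutation p-values,
#' R-squared, Cohen's f-squared, achieved power at the scan's sample size,
#' and Benjamini-Hochberg q-values across tested regions.  With
#' `response = "gos"` the single functional-outcome model (GOS-E on the same
#' predictors) is fitted instead, yielding exactly one record.
#'
#' @param cohort A `cohort_data` object.
#' @param response `"atrophy"` (per-region structural outcome, the default)
#'   or `"gos"` (functional outcome, one record).
#' @param n_perm Permutations per region for the empirical p-value; `0`
#'   skips the permutation step (`p_perm` is `NA`).
#' @param seed Base seed; region `i` uses `seed + i` so regions are
#'   reproducible independently.
#' @param alpha Significance level for FDR rejection (default 0.05).
#' @param fdr_on Which p-value family enters the FDR correction:
#'   `"param"` (default) or `"perm"`.
#' @param min_fraction Availability threshold (default 0.9).
#' @param keep_null Retain each tested region's permuted F sample in the
#'   returned object (`null_F`, a region-named list) for diagnostics.
#' @return An object of class `region_scan`: list with `results` (one row
#'   per region, step-1 schema), `coefficients` (tested regions x
#'   model terms), `response`, `N`, `alpha`, `n_perm`, `fdr_on`, `call`.
#' @seealso [gos_scan()] for step 2, [write_results()] to serialize.
#' @export
region_scan <- function(cohort, response = c("atrophy", "gos"),
                        n_perm = 1000, seed = 1, alpha = 0.05,
                        fdr_on = c("param", "perm"), min_fraction = 0.9,
                        keep_null = FALSE) {
  response <- match.arg(response)
  fdr_on <- match.arg(fdr_on)
  if (fdr_on == "perm" && n_perm < 1)
    stop("fdr_on = \"perm\" requires n_perm >= 1", call. = FALSE)
  N <- cohort$N
  subj <- cohort$subjects
  X <- cbind(intercept = 1, gcs_e = subj$gcs_e, seizure = subj$seizure)

  if (response == "gos") {
    regions <- data.frame(region_id = "gos_e", hemisphere = NA_character_,
                          lobe = NA_character_, stringsAsFactors = FALSE)
    ys <- matrix(as.numeric(subj$gos_e), ncol = 1)
    tested <- TRUE
    n_avail <- N
  } else {
    prep <- prepare_atrophy(cohort, min_fraction)
    regions <- cohort$parcellation[, c("region_id", "hemisphere", "lobe")]
    ys <- prep$atrophy$values
    tested <- prep$availability$tested
    n_avail <- prep$availability$n_available
  }

  n_reg <- nrow(regions)
  res <- data.frame(regions,
                    status = ifelse(rep_len(tested, n_reg), "tested",
                                    "untested"),
                    n_available = rep_len(n_avail, n_reg),
                    lambda = NA_real_, F = NA_real_, d1 = NA_real_,
                    d2 = NA_real_, p_param = NA_real_, p_perm = NA_real_,
                    q_value = NA_real_, R2 = NA_real_, f2 = NA_real_,
                    power = NA_real_, stringsAsFactors = FALSE)
  coefs <- matrix(NA_real_, n_reg, ncol(X),
                  dimnames = list(regions$region_id, colnames(X)))
  null_store <- list()

  for (i in seq_len(n_reg)) {
    if (res$status[i] != "tested") next
    y <- residualize_nuisance(as.numeric(ys[, i]), subj$age, subj$sex)
    ws <- tryCatch(wilks_statistics(X, y), error = function(e) NULL)
    if (is.null(ws)) {
      res$status[i] <- "untested"
      next
    }
    res$lambda[i] <- ws$lambda
    res$F[i] <- ws$F
    res$d1[i] <- ws$d1
    res$d2[i] <- ws$d2
    res$R2[i] <- ws$R2
    res$f2[i] <- cohens_f2(ws$R2)
    res$p_param[i] <- parametric_p(ws$F, ws$d1, ws$d2)
    res$power[i] <- ncf_power(res$f2[i], N, ws$d1, ws$d2, alpha)
    coefs[i, ] <- ws$B[, 1]
    if (n_perm >= 1) {
      pp <- permutation_p(X, y, n_perm = n_perm, seed = seed + i,
                          return_null = keep_null)
      res$p_perm[i] <- pp$p_perm
      if (keep_null) null_store[[res$region_id[i]]] <- pp$null_F
    }
  }

  is_tested <- res$status == "tested"
  if (!any(is_tested))
    warning("no region passed the availability rule; empty scan",
            call. = FALSE)
  else {
    p_in <- if (fdr_on == "perm") res$p_perm[is_tested]
            else res$p_param[is_tested]
    res$q_value[is_tested] <- bh_fdr(p_in, alpha)$q_values
  }

  structure(list(results = res, coefficients = coefs, response = response,
                 N = N, alpha = alpha, n_perm = n_perm, fdr_on = fdr_on,
                 null_F = if (keep_null) null_store,
                 call = match.call()),
            class = "region_scan")
}

#' @export
print.region_scan <- function(x, ...) {
  r <- x$results
  tested <- r$status == "tested"
  cat("Region-wise multivariate regression scan (", x$response,
      " response)\n", sep = "")
  cat("  N = ", x$N, "; predictors: gcs_e + seizure (q = 2); ",
      sum(tested), "/", nrow(r), " regions tested\n", sep = "")
  if (any(tested)) {
    cat("  significant at FDR ", x$alpha, " (on p_",
        x$fdr_on, "): ", sum(r$q_value[tested] <= x$alpha), "\n", sep = "")
    cat("  median F = ", sprintf("%.2f", stats::median(r$F[tested])),
        " on (", r$d1[which(tested)[1]], ", ", r$d2[which(tested)[1]],
        ") d.f.\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.region_scan <- function(object, n_top = 10, ...) {
  print(object)
  r <- object$results
  hit <- r[r$status == "tested" & r$q_value <= object$alpha, , drop = FALSE]
  if (nrow(hit)) {
    hit <- hit[order(hit$q_value, hit$p_param), ]
    cat("\nTop regions by q-value:\n")
    show <- utils::head(hit[, c("region_id", "lobe", "F", "p_param",
                                "q_value", "f2", "power")], n_top)
    show[-(1:2)] <- lapply(show[-(1:2)], signif, 4)
    print(show, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.region_scan <- function(object, ...) object$coefficients

#' @export
plot.region_scan <- function(x, ...) {
  r <- x$results
  tested <- r$status == "tested"
  lobes <- c("frontal", "insular", "limbic", "temporal", "parietal",
             "occipital")
  col <- grDevices::hcl.colors(length(lobes), "Dark 3")[
    match(r$lobe, lobes)]
  col[is.na(col)] <- "grey40"
  y <- -log10(r$q_value)
  plot(seq_len(nrow(r)), y, col = col, pch = ifelse(tested, 16, 4),
       xlab = "region index (registry order)",
       ylab = expression(-log[10](q)),
       main = "Step 1: severity vs regional atrophy", ...)
  graphics::abline(h = -log10(x$alpha), lty = 2)
  graphics::legend("topright", legend = lobes, col = grDevices::hcl.colors(
    length(lobes), "Dark 3"), pch = 16, cex = 0.7, bty = "n")
  invisible(x)
}
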