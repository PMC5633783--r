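# Step 2: per-region Pearson correlation between relative atrophy and the
# 6-month GOS-E, tested via t = r / sqrt((1 - r^2) / (N - 2)) on N - 2 d.f.
# The directional hypothesis is that more atrophy goes with poorer outcome
# (r < 0), so the default p-value is the lower tail.

#' Pearson correlation t test between atrophy and outcome
#'
#' Computes the sample Pearson correlation `r`, the statistic
#' `t = r / sqrt((1 - r^2) / (N - 2))` on `N - 2` degrees of freedom, and
#' its p-value.  By default the test is one-sided for the directional
#' hypothesis `r < 0` (greater atrophy, poorer outcome), matching the sign
#' structure of the cortex-wide analysis; `two_sided = TRUE` doubles the
#' smaller tail.
#'
#' @param atrophy_column Numeric vector of per-subject atrophy values for
#'   one region.
#' @param gos Numeric vector of outcome scores (same length, N >= 3).
#' @param two_sided Use a two-sided p-value (default `FALSE`).
#' @return List with `r`, `t`, `df`, `p` and `overflow` (`TRUE` when
#'   `|r| = 1` makes `t` infinite, in which case `p = 0`).
#' @examples
#' # the t implied by a printed correlation at N = 33:
#' r <- -0.47
#' r / sqrt((1 - r^2) / 31)   # about -2.96
#' @export
pearson_t <- function(atrophy_column, gos, two_sided = FALSE) {
  x <- as.numeric(atrophy_column); y <- as.numeric(gos)
  n <- length(x)
  if (length(y) != n) stop("vectors must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in atrophy or outcome vector", call. = FALSE)
  r <- stats::cor(x, y)
  df <- n - 2
  if (abs(r) >= 1 - .Machine$double.eps) {
    return(list(r = sign(r), t = sign(r) * Inf, df = df, p = 0,
                overflow = TRUE))
  }
  t_stat <- r / sqrt((1 - r^2) / df)
  p <- if (two_sided) 2 * stats::pt(-abs(t_stat), df)
       else stats::pt(t_stat, df)
  list(r = r, t = t_stat, df = df, p = p, overflow = FALSE)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR adjustment: with m p-values sorted ascending, the q-value of
#' the i-th is `min over j >= i of m * p_(j) / j`, clipped to 1; hypotheses
#' with `q <= alpha` are rejected.  The result is stable under permutation
#' of the input order.  Computed via [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (may be empty).
#' @param alpha Rejection level (default 0.05).
#' @return List with `q_values` and logical `rejected`, in input order.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (!length(p_values))
    return(list(q_values = numeric(0), rejected = logical(0)))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, rejected = !is.na(q) & q <= alpha)
}

#' Region-wise atrophy-outcome correlation scan (analysis step 2)
#'
#' For every region passing the availability rule, correlates imputed
#' relative atrophy with the 6-month GOS-E and reports `r`, the t statistic
#' on N - 2 degrees of freedom, the (by default one-sided, lower-tail)
#' p-value and the Benjamini-Hochberg q-value across tested regions.
#' Regions whose correlation is degenerate (e.g. zero atrophy variance, or a
#' constant outcome vector) are reported with status `"untested"` rather
#' than failing the scan.
#'
#' @param cohort A `cohort_data` object.
#' @param atrophy Optional pre-computed imputed `atrophy_matrix`; by default
#'   [prepare_atrophy()] is run on the cohort.
#' @param alpha FDR rejection level (default 0.05).
#' @param two_sided Use two-sided p-values (default `FALSE`).
#' @param min_fraction Availability threshold (default 0.9).
#' @return An object of class `cor_scan`: list with `results` (step-2
#'   schema), `N`, `alpha`, `two_sided`, `call`.
#' @export
gos_scan <- function(cohort, atrophy = NULL, alpha = 0.05,
                     two_sided = FALSE, min_fraction = 0.9) {
  N <- cohort$N
  if (is.null(atrophy)) {
    prep <- prepare_atrophy(cohort, min_fraction)
    atrophy <- prep$atrophy
    avail <- prep$availability
  } else {
    # missing_mask stays TRUE at imputed cells, so this counts only
    # genuinely observed measurements
    avail <- availability_scan(atrophy, N, min_fraction)
  }
  gos <- as.numeric(cohort$subjects$gos_e)
  regions <- cohort$parcellation[, c("region_id", "hemisphere", "lobe")]
  n_reg <- nrow(regions)
  res <- data.frame(regions,
                    status = ifelse(avail$tested, "tested", "untested"),
                    n_available = avail$n_available,
                    r = NA_real_, t = NA_real_, df = NA_real_,
                    p_one_sided = NA_real_, q_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_reg)) {
    if (res$status[i] != "tested") next
    ct <- tryCatch(pearson_t(atrophy$values[, i], gos, two_sided),
                   error = function(e) NULL)
    if (is.null(ct)) {
      res$status[i] <- "untested"
      next
    }
    res$r[i] <- ct$r
    res$t[i] <- ct$t
    res$df[i] <- ct$df
    res$p_one_sided[i] <- ct$p
  }
  tested <- res$status == "tested"
  if (any(tested))
    res$q_value[tested] <- bh_fdr(res$p_one_sided[tested], alpha)$q_values
  else
    warning("no region could be tested in the outcome correlation scan",
            call. = FALSE)
  structure(list(results = res, N = N, alpha = alpha,
                 two_sided = two_sided, call = match.call()),
            class = "cor_scan")
}

#' @export
print.cor_scan <- function(x, ...) {
  r <- x$results
  tested <- r$status == "tested"
  cat("Atrophy-outcome correlation scan (GOS-E)\n")
  cat("  N = ", x$N, " (df = ", x$N - 2, "); ", sum(tested), "/",
      nrow(r), " regions tested; ",
      if (x$two_sided) "two-sided" else "one-sided (r < 0)",
      " p-values\n", sep = "")
  if (any(tested)) {
    cat("  negative r: ", sum(r$r[tested] < 0), "/", sum(tested),
        "; significant at FDR ", x$alpha, ": ",
        sum(r$q_value[tested] <= x$alpha), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.cor_scan <- function(object, n_top = 10, ...) {
  print(object)
  r <- object$results
  hit <- r[r$status == "tested" & r$q_value <= object$alpha, , drop = FALSE]
  if (nrow(hit)) {
    hit <- hit[order(hit$q_value, hit$p_one_sided), ]
    cat("\nTop regions by q-value:\n")
    show <- utils::head(hit[, c("region_id", "lobe", "r", "t",
                                "p_one_sided", "q_value")], n_top)
    show[-(1:2)] <- lapply(show[-(1:2)], signif, 4)
    print(show, row.names = FALSE)
  }
  invisible(object)
}
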