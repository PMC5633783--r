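# Preprocessing: relative atrophy, the 90% availability rule, mean
# substitution, and nuisance residualization of age and sex.

.new_atrophy_matrix <- function(values, missing_mask, imputed_mask = NULL) {
  if (is.null(imputed_mask))
    imputed_mask <- matrix(FALSE, nrow(values), ncol(values),
                           dimnames = dimnames(values))
  structure(list(values = values, missing_mask = missing_mask,
                 imputed_mask = imputed_mask), class = "atrophy_matrix")
}

#' Relative cortical atrophy between two timepoints
#'
#' Computes the relative thickness difference `(acute - chronic) / acute`
#' cell-wise; positive values indicate thinning.  A cell is missing when
#' either timepoint is missing.
#'
#' @param acute,chronic `thickness_matrix` objects with identical subject and
#'   region order (e.g. the `acute`/`chronic` elements of a `cohort_data`).
#' @return An `atrophy_matrix`: list with subjects-by-regions `values`
#'   (dimensionless fractions), logical `missing_mask`, and an all-`FALSE`
#'   `imputed_mask`.
#' @export
relative_atrophy <- function(acute, chronic) {
  if (!identical(dim(acute$values), dim(chronic$values)) ||
      !identical(dimnames(acute$values), dimnames(chronic$values)))
    stop("acute and chronic matrices are not conformable", call. = FALSE)
  if (any(acute$values[!acute$missing_mask] <= 0))
    stop("non-missing acute thickness must be strictly positive",
         call. = FALSE)
  mask <- acute$missing_mask | chronic$missing_mask
  vals <- (acute$values - chronic$values) / acute$values
  vals[mask] <- NA_real_
  .new_atrophy_matrix(vals, mask)
}

#' Region availability under the 90% rule
#'
#' A region's null hypothesis is only tested when thickness measurements
#' (hence atrophy values) are available for at least 90% of subjects; the
#' boundary is inclusive.
#'
#' @param atrophy An `atrophy_matrix`.
#' @param N Subject count (defaults to the matrix row count).
#' @param min_fraction Availability threshold (default 0.9).
#' @return Data frame with columns `region_id`, `n_available`,
#'   `fraction_available`, `tested`.
#' @export
availability_scan <- function(atrophy, N = nrow(atrophy$values),
                              min_fraction = 0.9) {
  n_avail <- colSums(!atrophy$missing_mask)
  data.frame(region_id = colnames(atrophy$values),
             n_available = as.integer(n_avail),
             fraction_available = n_avail / N,
             tested = n_avail / N >= min_fraction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mean-substitution imputation for tested regions
#'
#' Replaces each missing atrophy value in a tested region by the mean of that
#' region's observed values, and records the substitution in `imputed_mask`.
#' Untested regions are left untouched.  Mean substitution preserves the
#' region mean and never increases the variance.
#'
#' @param atrophy An `atrophy_matrix`.
#' @param availability Output of [availability_scan()] on the same matrix.
#' @return The imputed `atrophy_matrix`; imputed cells keep
#'   `missing_mask = TRUE` (no measurement existed) and gain
#'   `imputed_mask = TRUE`.
#' @export
impute_region_means <- function(atrophy, availability) {
  vals <- atrophy$values
  imputed <- atrophy$imputed_mask
  for (j in which(availability$tested)) {
    miss <- atrophy$missing_mask[, j]
    if (!any(miss)) next
    obs <- vals[!miss, j]
    if (!length(obs))
      stop("internal error: tested region with no observed values",
           call. = FALSE)
    vals[miss, j] <- mean(obs)
    imputed[miss, j] <- TRUE
  }
  .new_atrophy_matrix(vals, atrophy$missing_mask, imputed)
}

#' Residualize a response against age and sex
#'
#' Removes the least-squares projection of `y` onto the nuisance design
#' `[1, age_centered, sex]`, returning residuals orthogonal to the
#' intercept, age and sex.  Nuisance regression is applied to the response
#' only; downstream error degrees of freedom are not adjusted.
#'
#' @param y Numeric response vector.
#' @param age Numeric vector of ages (years).
#' @param sex Indicator vector (male = 1, female = 0) or a character/factor
#'   vector with levels `"male"`/`"female"` (or `"M"`/`"F"`).
#' @return Numeric vector of residuals.  If a nuisance column is collinear
#'   (e.g. a single-sex cohort) it is dropped with a warning rather than
#'   failing.
#' @export
residualize_nuisance <- function(y, age, sex) {
  if (is.character(sex) || is.factor(sex))
    sex <- as.integer(as.character(sex) %in% c("male", "M"))
  n <- length(y)
  if (length(age) != n || length(sex) != n)
    stop("y, age and sex must have equal length", call. = FALSE)
  X <- cbind(intercept = rep(1, n), age = age - mean(age), sex = sex)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    warning("nuisance design is rank deficient; dropping collinear ",
            "column(s): ", paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
  }
  as.numeric(qr.resid(qrX, y))
}

#' Full preprocessing for a cohort
#'
#' Convenience wrapper running [relative_atrophy()], [availability_scan()]
#' and [impute_region_means()] in order.
#'
#' @param cohort A `cohort_data` object.
#' @param min_fraction Availability threshold (default 0.9).
#' @return List with elements `atrophy` (imputed `atrophy_matrix`) and
#'   `availability` (data frame).
#' @export
prepare_atrophy <- function(cohort, min_fraction = 0.9) {
  atr <- relative_atrophy(cohort$acute, cohort$chronic)
  avail <- availability_scan(atr, cohort$N, min_fraction)
  list(atrophy = impute_region_means(atr, avail), availability = avail)
}
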