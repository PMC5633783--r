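# Tabular input/output: cohort readers, result writers.
#
# All inputs are plain TSV.  Missing thickness cells may be blank or the
# literal "NA"; blanks are written on output.  Sex is encoded "M"/"F" in
# files and mapped to an indicator (M = 1, F = 0) internally.

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = NULL,
                    stringsAsFactors = FALSE)
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
}

# parse a character thickness cell: "" or "NA" -> NA, otherwise numeric
.parse_thickness <- function(x) {
  x <- trimws(x)
  x[x == "" | toupper(x) == "NA"] <- NA_character_
  suppressWarnings(as.numeric(x))
}

.new_thickness_matrix <- function(values, missing_mask, timepoint) {
  stopifnot(identical(dim(values), dim(missing_mask)))
  structure(list(timepoint = timepoint, values = values,
                 missing_mask = missing_mask),
            class = "thickness_matrix")
}

.validate_thickness <- function(tm, timepoint) {
  obs <- tm$values[!tm$missing_mask]
  if (any(!is.finite(obs)))
    stop("non-finite thickness value(s) in ", timepoint, " table",
         call. = FALSE)
  if (any(obs <= 0) || any(obs >= 10))
    stop("thickness values must be strictly positive and < 10 mm (",
         timepoint, " table violates this)", call. = FALSE)
  invisible(tm)
}

.read_thickness_table <- function(path, timepoint, subject_ids, region_ids) {
  df <- .read_tsv(path)
  .require_columns(df, "subject_id", paste(timepoint, "thickness"))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in ", timepoint, " thickness table: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "), call. = FALSE)
  absent <- setdiff(subject_ids, df$subject_id)
  extra <- setdiff(df$subject_id, subject_ids)
  if (length(absent) || length(extra))
    stop("subject id mismatch between clinical and ", timepoint,
         " thickness tables; missing from thickness: [",
         paste(absent, collapse = ", "), "]; not in clinical: [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  missing_regions <- setdiff(region_ids, names(df))
  if (length(missing_regions))
    stop(timepoint, " thickness table is missing region column(s): ",
         paste(utils::head(missing_regions, 5), collapse = ", "),
         if (length(missing_regions) > 5) ", ...", call. = FALSE)
  # harmonize: rows in clinical-table order, columns in registry order
  df <- df[match(subject_ids, df$subject_id), , drop = FALSE]
  vals <- vapply(region_ids, function(r) .parse_thickness(df[[r]]),
                 numeric(length(subject_ids)))
  vals <- matrix(vals, nrow = length(subject_ids),
                 dimnames = list(subject_ids, region_ids))
  tm <- .new_thickness_matrix(vals, is.na(vals), timepoint)
  .validate_thickness(tm, timepoint)
}

.read_clinical_table <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("subject_id", "age", "sex", "gcs_e", "seizure",
                         "gos_e"), "clinical")
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in clinical table: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "), call. = FALSE)
  sex <- toupper(trimws(df$sex))
  if (!all(sex %in% c("M", "F")))
    stop("sex must be coded \"M\"/\"F\"; found: ",
         paste(setdiff(unique(sex), c("M", "F")), collapse = ", "),
         call. = FALSE)
  seiz <- suppressWarnings(as.numeric(df$seizure))
  if (any(is.na(seiz)) || !all(seiz %in% c(0, 1)))
    stop("seizure must be a binary variable (0 or 1); found: ",
         paste(unique(df$seizure[!df$seizure %in% c("0", "1")]),
               collapse = ", "), call. = FALSE)
  data.frame(subject_id = df$subject_id,
             age = as.numeric(df$age),
             sex = ifelse(sex == "M", "male", "female"),
             gcs_e = as.integer(df$gcs_e),
             seizure = as.integer(seiz),
             gos_e = as.integer(df$gos_e),
             stringsAsFactors = FALSE)
}

.new_cohort <- function(subjects, acute, chronic, parcellation) {
  cohort <- structure(list(N = nrow(subjects), subjects = subjects,
                           acute = acute, chronic = chronic,
                           parcellation = parcellation),
                      class = "cohort_data")
  .validate_cohort(cohort)
}

# N >= 4 (the minimum for positive error d.f. with q = 2) is enforced at
# inference time by wilks_statistics(); reading small fixtures is allowed.
.validate_cohort <- function(cohort) {
  if (cohort$N < 1)
    stop("cohort contains no subjects", call. = FALSE)
  if (!all(cohort$subjects$seizure %in% c(0L, 1L)))
    stop("seizure must be a binary variable (0 or 1)", call. = FALSE)
  for (tp in c("acute", "chronic")) {
    tm <- cohort[[tp]]
    if (!identical(rownames(tm$values), cohort$subjects$subject_id))
      stop("subject order of ", tp, " thickness matrix does not match ",
           "the clinical table", call. = FALSE)
    if (!identical(colnames(tm$values), cohort$parcellation$region_id))
      stop("region order of ", tp, " thickness matrix does not match ",
           "the parcellation registry", call. = FALSE)
    .validate_thickness(tm, tp)
  }
  invisible(cohort)
}

#' Read and validate a cohort from TSV tables
#'
#' Assembles the pipeline's single input bundle from three (optionally four)
#' tab-separated tables: per-subject clinical covariates, acute and chronic
#' per-region cortical thickness (mm), and a parcellation registry.  Blank
#' thickness cells or the literal `"NA"` are treated as missing measurements
#' (e.g. lesion-disrupted contrast).  Subject rows are ordered as in the
#' clinical table and region columns as in the registry, regardless of input
#' order.
#'
#' @param acute_path,chronic_path Paths to thickness TSVs, first column
#'   `subject_id`, one column per `region_id`, cells in mm.
#' @param clinical_path Path to the clinical TSV with columns `subject_id`,
#'   `age` (years), `sex` (`"M"`/`"F"`), `gcs_e`, `seizure` (0/1), `gos_e`.
#' @param parcellation_path Path to a registry TSV with columns `region_id`,
#'   `region_name`, `hemisphere`, `lobe`; `NULL` (default) uses the bundled
#'   registry from [default_parcellation()].
#' @return An object of class `cohort_data`: a list with elements `N`,
#'   `subjects` (data frame), `acute` and `chronic` (each with a
#'   subjects-by-regions `values` matrix and logical `missing_mask`), and
#'   `parcellation`.
#' @seealso [generate_cohort()] for synthetic cohorts, [write_cohort()] for
#'   the inverse operation.
#' @export
read_cohort <- function(acute_path, chronic_path, clinical_path,
                        parcellation_path = NULL) {
  for (p in c(acute_path, chronic_path, clinical_path, parcellation_path))
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  parc <- if (is.null(parcellation_path)) default_parcellation()
          else .validate_parcellation(.read_tsv(parcellation_path))
  subjects <- .read_clinical_table(clinical_path)
  acute <- .read_thickness_table(acute_path, "acute", subjects$subject_id,
                                 parc$region_id)
  chronic <- .read_thickness_table(chronic_path, "chronic",
                                   subjects$subject_id, parc$region_id)
  .new_cohort(subjects, acute, chronic, parc)
}

#' @export
print.cohort_data <- function(x, ...) {
  n_missing <- sum(x$acute$missing_mask) + sum(x$chronic$missing_mask)
  cat("Cohort: ", x$N, " subjects, ", nrow(x$parcellation),
      " cortical regions\n", sep = "")
  cat("  male: ", sum(x$subjects$sex == "male"),
      "; acute seizures: ", sum(x$subjects$seizure), "\n", sep = "")
  cat("  age ", sprintf("%.1f +/- %.1f", mean(x$subjects$age),
                        stats::sd(x$subjects$age)),
      " y; GCS-E ", sprintf("%.2f +/- %.2f", mean(x$subjects$gcs_e),
                            stats::sd(x$subjects$gcs_e)),
      "; GOS-E ", sprintf("%.2f +/- %.2f", mean(x$subjects$gos_e),
                          stats::sd(x$subjects$gos_e)), "\n", sep = "")
  cat("  missing thickness cells (both timepoints): ", n_missing, "\n",
      sep = "")
  invisible(x)
}

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.12g", v)
  }, character(1))
  out
}

.thickness_to_df <- function(tm) {
  vals <- tm$values
  vals[tm$missing_mask] <- NA_real_
  df <- data.frame(subject_id = rownames(vals), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(vals))) df[[colnames(vals)[j]]] <- .fmt_num(vals[, j])
  df
}

#' Write a cohort back to its TSV tables
#'
#' Inverse of [read_cohort()]: writes the clinical, acute- and
#' chronic-thickness tables (and optionally the parcellation registry) of a
#' `cohort_data` object.  Missing thickness cells are written blank.
#'
#' @param cohort A `cohort_data` object.
#' @param dir Output directory (created if absent).
#' @param write_parcellation Also write `parcellation.tsv` (default `TRUE`).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_cohort <- function(cohort, dir, write_parcellation = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(clinical = file.path(dir, "clinical.tsv"),
             acute = file.path(dir, "thickness_acute.tsv"),
             chronic = file.path(dir, "thickness_chronic.tsv"))
  subj <- cohort$subjects
  subj$sex <- ifelse(subj$sex == "male", "M", "F")
  utils::write.table(subj, paths["clinical"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(.thickness_to_df(cohort$acute), paths["acute"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(.thickness_to_df(cohort$chronic), paths["chronic"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (write_parcellation) {
    paths <- c(paths, parcellation = file.path(dir, "parcellation.tsv"))
    utils::write.table(cohort$parcellation, paths["parcellation"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

# fixed column orders for the three result schemas
.result_schemas <- list(
  step1 = c("region_id", "hemisphere", "lobe", "status", "n_available",
            "lambda", "F", "d1", "d2", "p_param", "p_perm", "q_value",
            "R2", "f2", "power"),
  step2 = c("region_id", "hemisphere", "lobe", "status", "n_available",
            "r", "t", "df", "p_one_sided", "q_value"),
  power = c("f2", "n", "d1", "d2", "alpha", "lambda", "power")
)

#' Write a result table as TSV
#'
#' Serializes per-region inference records (step 1 multivariate tests, step 2
#' correlations) or power-analysis records with the fixed column order of the
#' corresponding schema.  Numeric fields are rendered with at least six
#' significant digits; untested regions carry status `"untested"` and empty
#' statistic fields.
#'
#' @param records A data frame of one result type (e.g. the `results` element
#'   of a [region_scan()] or [gos_scan()] object, or a power-analysis row).
#' @param path Output file path.
#' @param schema_id One of `"step1"`, `"step2"`, `"power"`.
#' @return Invisibly, `path`.
#' @export
write_results <- function(records, path, schema_id = c("step1", "step2",
                                                       "power")) {
  schema_id <- match.arg(schema_id)
  cols <- .result_schemas[[schema_id]]
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  records <- as.data.frame(records)
  missing <- setdiff(cols, names(records))
  if (length(missing))
    stop("records do not match schema \"", schema_id,
         "\"; missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- records[, cols, drop = FALSE]
  for (j in names(out))
    if (is.numeric(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  out[is.na(out)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Path to a results TSV.
#' @param schema_id One of `"step1"`, `"step2"`, `"power"`.
#' @return A data frame with numeric statistic columns; empty cells become
#'   `NA`.
#' @export
read_results <- function(path, schema_id = c("step1", "step2", "power")) {
  schema_id <- match.arg(schema_id)
  cols <- .result_schemas[[schema_id]]
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          na.strings = NULL, stringsAsFactors = FALSE)
  .require_columns(df, cols, paste0("results (", schema_id, ")"))
  char_cols <- c("region_id", "hemisphere", "lobe", "status")
  for (j in cols) {
    if (j %in% char_cols) next
    v <- trimws(df[[j]])
    v[v == ""] <- NA_character_
    df[[j]] <- suppressWarnings(as.numeric(v))
  }
  df
}

# One stats file: either a "# ColHeaders ..." comment naming the columns
# (FreeSurfer convention) or a plain header row.
.read_one_aparc <- function(path) {
  lines <- readLines(path)
  ch <- grep("^#\\s*ColHeaders\\b", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (length(ch)) {
    cols <- strsplit(trimws(sub("^#\\s*ColHeaders\\s*", "",
                                ch[length(ch)])), "\\s+")[[1]]
    utils::read.table(text = body, col.names = cols, check.names = FALSE,
                      stringsAsFactors = FALSE)
  } else {
    utils::read.table(text = body, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
}

#' Read FreeSurfer aparc-stats-style per-subject tables
#'
#' Assembles a thickness matrix from one whitespace-delimited stats table per
#' subject (comment lines starting with `#`; columns including `StructName`
#' and `ThickAvg`, as produced by FreeSurfer's anatomical statistics for the
#' Destrieux parcellation).  Structure names are matched to registry region
#' ids as `<hemi>_<StructName>`; registry regions absent from a subject's
#' table are marked missing.
#'
#' @param paths Named character vector: one stats file per subject per
#'   hemisphere, names of the form `"<subject_id>.<lh|rh>"`.
#' @param parcellation Registry data frame (default: bundled registry).
#' @param timepoint Label for the resulting matrix (`"acute"` or
#'   `"chronic"`).
#' @return A `thickness_matrix`-classed list (`values`, `missing_mask`,
#'   `timepoint`), subjects sorted by id.
#' @export
read_aparc_stats <- function(paths, parcellation = default_parcellation(),
                             timepoint = "acute") {
  if (is.null(names(paths)) || any(names(paths) == ""))
    stop("paths must be named \"<subject_id>.<lh|rh>\"", call. = FALSE)
  key <- strsplit(names(paths), ".", fixed = TRUE)
  if (any(lengths(key) != 2) ||
      !all(vapply(key, `[`, "", 2) %in% c("lh", "rh")))
    stop("path names must be of the form \"<subject_id>.<lh|rh>\"",
         call. = FALSE)
  subjects <- sort(unique(vapply(key, `[`, "", 1)))
  region_ids <- parcellation$region_id
  vals <- matrix(NA_real_, length(subjects), length(region_ids),
                 dimnames = list(subjects, region_ids))
  for (i in seq_along(paths)) {
    sid <- key[[i]][1]; hemi <- key[[i]][2]
    tab <- .read_one_aparc(paths[[i]])
    .require_columns(tab, c("StructName", "ThickAvg"),
                     paste0("aparc stats (", names(paths)[i], ")"))
    ids <- paste0(hemi, "_", tab$StructName)
    known <- ids %in% region_ids
    vals[sid, ids[known]] <- as.numeric(tab$ThickAvg[known])
  }
  tm <- .new_thickness_matrix(vals, is.na(vals), timepoint)
  .validate_thickness(tm, timepoint)
}
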