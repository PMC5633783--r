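# Shared fixture builders.  All fixtures are constructed in code at test
# time; nothing is stored on disk.

# a tiny 4-region registry for hand-sized fixtures
tiny_parcellation <- function() {
  data.frame(
    region_id = c("lh_A", "lh_B", "rh_A", "rh_B"),
    region_name = c("Region A", "Region B", "Region A", "Region B"),
    hemisphere = c("left", "left", "right", "right"),
    lobe = c("frontal", "parietal", "frontal", "parietal"),
    stringsAsFactors = FALSE)
}

# write a 3-subject cohort as TSV fixtures; returns the file paths.
# `blank_cell` = c(subject_row, region_col) blanks one acute cell;
# `na_cell` writes the literal "NA" instead.
write_tiny_fixture <- function(dir, blank_cell = NULL, na_cell = NULL,
                               drop_subject_from_acute = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  parc <- tiny_parcellation()
  clin <- data.frame(subject_id = c("s1", "s2", "s3"),
                     age = c(25, 40, 60), sex = c("M", "F", "M"),
                     gcs_e = c(4L, 8L, 12L), seizure = c(1L, 0L, 1L),
                     gos_e = c(3L, 6L, 7L), stringsAsFactors = FALSE)
  th <- function(base) {
    m <- data.frame(subject_id = clin$subject_id, stringsAsFactors = FALSE)
    for (j in seq_along(parc$region_id))
      m[[parc$region_id[j]]] <- sprintf("%.3f", base + 0.1 * j +
                                          0.01 * seq_len(3))
    m
  }
  acute <- th(2.5); chronic <- th(2.3)
  if (!is.null(blank_cell))
    acute[[blank_cell[2] + 1]][blank_cell[1]] <- ""
  if (!is.null(na_cell))
    acute[[na_cell[2] + 1]][na_cell[1]] <- "NA"
  if (!is.null(drop_subject_from_acute))
    acute <- acute[acute$subject_id != drop_subject_from_acute, ]
  paths <- list(acute = file.path(dir, "acute.tsv"),
                chronic = file.path(dir, "chronic.tsv"),
                clinical = file.path(dir, "clinical.tsv"),
                parcellation = file.path(dir, "parc.tsv"))
  write.table(acute, paths$acute, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(chronic, paths$chronic, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(clin, paths$clinical, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(parc, paths$parcellation, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}

# a small generated cohort for downstream tests
small_cohort <- function(seed = 11, n = 20, with_missing = FALSE) {
  cfg <- default_config()
  cfg$n_subjects <- n
  co <- generate_cohort(cfg, seed = seed)
  if (with_missing) co <- inject_missingness(co, cfg, seed = seed + 1)
  co
}

# independent brute-force OLS overall-F oracle via lm()
lm_overall_f <- function(X, y) {
  df <- data.frame(y = y, g = X[, 2], s = X[, 3])
  unname(summary(lm(y ~ g + s, data = df))$fstatistic[1])
}
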