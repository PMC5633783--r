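# End-to-end pipeline: (simulate | read) -> preprocess -> step 1 -> step 2
# -> power, with a run log and a machine-readable manifest.

#' Build and validate a pipeline run configuration
#'
#' A run takes its cohort either from the three input TSVs or from the
#' synthetic generator; exactly one source must be configured.  The
#' configuration is a plain serializable list: persisting it (e.g. as YAML)
#' and re-running reproduces identical outputs for identical inputs and
#' seed.
#'
#' @param out_dir Output directory for all result files.
#' @param acute_path,chronic_path,clinical_path,parcellation_path Input
#'   TSVs (see [read_cohort()]); leave `NULL` to use the synthetic
#'   generator.
#' @param synthetic A `synthetic_config` list ([default_config()]), or
#'   `TRUE` for the defaults; `NULL` when reading from files.
#' @param n_perm Permutations per region in step 1 (default 10000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed for all randomness in the run.
#' @param response Step-1 response: `"atrophy"` or `"gos"`.
#' @param fdr_on p-value family entering the step-1 FDR: `"param"` or
#'   `"perm"`.
#' @param two_sided Two-sided step-2 p-values (default `FALSE`).
#' @param dump_atrophy Also write the imputed atrophy matrix as TSV.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       acute_path = NULL, chronic_path = NULL,
                       clinical_path = NULL, parcellation_path = NULL,
                       synthetic = NULL,
                       n_perm = 10000, alpha = 0.05, seed = 1,
                       response = c("atrophy", "gos"),
                       fdr_on = c("param", "perm"),
                       two_sided = FALSE, dump_atrophy = FALSE) {
  response <- match.arg(response)
  fdr_on <- match.arg(fdr_on)
  have_files <- !is.null(acute_path) || !is.null(chronic_path) ||
    !is.null(clinical_path)
  have_synth <- !is.null(synthetic) && !identical(synthetic, FALSE)
  if (have_files && have_synth)
    stop("configure either input paths or a synthetic block, not both",
         call. = FALSE)
  if (!have_files && !have_synth)
    stop("configuration must provide input paths or a synthetic block",
         call. = FALSE)
  if (have_files &&
      (is.null(acute_path) || is.null(chronic_path) ||
       is.null(clinical_path)))
    stop("file input requires acute_path, chronic_path and clinical_path",
         call. = FALSE)
  if (isTRUE(synthetic)) synthetic <- default_config()
  if (have_synth) .validate_config(synthetic)
  if (n_perm < 0) stop("n_perm must be >= 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)",
                                     call. = FALSE)
  structure(list(out_dir = out_dir, acute_path = acute_path,
                 chronic_path = chronic_path, clinical_path = clinical_path,
                 parcellation_path = parcellation_path,
                 synthetic = synthetic, n_perm = as.integer(n_perm),
                 alpha = alpha, seed = as.integer(seed),
                 response = response, fdr_on = fdr_on,
                 two_sided = two_sided, dump_atrophy = dump_atrophy),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Field names mirror the arguments of [run_config()]; a `synthetic` mapping
#' mirrors the `synthetic_config` field names, overriding the defaults field
#' by field (`synthetic: true` uses the defaults unchanged).
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synthetic) && is.list(raw$synthetic)) {
    cfg <- default_config()
    unknown <- setdiff(names(raw$synthetic), names(cfg))
    if (length(unknown))
      stop("unknown synthetic config field(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    cfg[names(raw$synthetic)] <- raw$synthetic
    raw$synthetic <- cfg
  }
  args <- raw[intersect(names(raw), names(formals(run_config)))]
  do.call(run_config, args)
}

.stage <- function(name, log, expr) {
  log(paste0("stage ", name, ": start"))
  res <- tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  log(paste0("stage ", name, ": done"))
  res
}

#' Run the full analysis pipeline
#'
#' Sequences cohort acquisition (synthetic or file input), preprocessing,
#' the step-1 region scan with permutation validation, the step-2
#' atrophy-outcome correlation scan, and the power analysis.  Writes
#' `step1.tsv`, `step2.tsv`, `power.tsv` (plus the generated input tables
#' and truth tables for synthetic runs, and optionally `atrophy.tsv`), a
#' run log, and `manifest.json` recording the configuration, seed,
#' per-stage counts and MD5 content hashes of every output.  Deterministic:
#' two runs with the same configuration and seed produce byte-identical
#' outputs.
#'
#' @param config A `run_config` list (see [run_config()] /
#'   [read_run_config()]).
#' @param verbose Echo log lines to the console (default `TRUE`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (!inherits(config, "run_config"))
    config <- do.call(run_config, config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    if (verbose) message(msg)
  }
  counts <- list()

  cohort <- .stage("cohort", log, {
    if (!is.null(config$synthetic)) {
      ch <- generate_cohort(config$synthetic, seed = config$seed)
      ch <- inject_missingness(ch, config$synthetic,
                               seed = config$seed + 1)
      write_cohort(ch, config$out_dir)
      write_truth(ch, config$out_dir)
      log(paste0("  synthetic cohort: N = ", ch$N))
      ch
    } else {
      ch <- read_cohort(config$acute_path, config$chronic_path,
                        config$clinical_path, config$parcellation_path)
      log(paste0("  cohort read: N = ", ch$N))
      ch
    }
  })
  counts$N <- cohort$N
  counts$n_regions <- nrow(cohort$parcellation)

  prep <- .stage("preprocess", log, {
    pr <- prepare_atrophy(cohort)
    log(paste0("  regions tested: ", sum(pr$availability$tested), "/",
               nrow(pr$availability), " (>= 90% availability)"))
    if (config$dump_atrophy) {
      vals <- pr$atrophy$values
      vals[pr$atrophy$missing_mask & !pr$atrophy$imputed_mask] <- NA
      df <- data.frame(subject_id = rownames(vals),
                       stringsAsFactors = FALSE)
      for (j in colnames(vals)) df[[j]] <- .fmt_num(vals[, j])
      utils::write.table(df, file.path(config$out_dir, "atrophy.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    pr
  })
  counts$regions_tested <- sum(prep$availability$tested)

  scan1 <- .stage("step1", log, {
    sc <- region_scan(cohort, response = config$response,
                      n_perm = config$n_perm, seed = config$seed,
                      alpha = config$alpha, fdr_on = config$fdr_on)
    tested <- sc$results$status == "tested"
    nrej <- sum(sc$results$q_value[tested] <= config$alpha, na.rm = TRUE)
    log(paste0("  step 1: ", sum(tested), " tested, ", nrej,
               " rejected at FDR ", config$alpha, " (", config$n_perm,
               " permutations/region)"))
    write_results(sc$results, file.path(config$out_dir, "step1.tsv"),
                  "step1")
    sc
  })
  counts$step1_rejected <- sum(
    scan1$results$q_value[scan1$results$status == "tested"] <=
      config$alpha, na.rm = TRUE)

  scan2 <- .stage("step2", log, {
    sc <- gos_scan(cohort, atrophy = prep$atrophy, alpha = config$alpha,
                   two_sided = config$two_sided)
    tested <- sc$results$status == "tested"
    nrej <- sum(sc$results$q_value[tested] <= config$alpha, na.rm = TRUE)
    log(paste0("  step 2: ", sum(tested), " tested, ", nrej,
               " rejected at FDR ", config$alpha))
    write_results(sc$results, file.path(config$out_dir, "step2.tsv"),
                  "step2")
    sc
  })
  counts$step2_rejected <- sum(
    scan2$results$q_value[scan2$results$status == "tested"] <=
      config$alpha, na.rm = TRUE)

  .stage("power", log, {
    N <- cohort$N
    f2_min1 <- min_effect_size(N, 2, N - 3, config$alpha, 0.8)
    f2_min2 <- min_effect_size(N, 1, N - 2, config$alpha, 0.8)
    rows <- rbind(power_record(f2 = f2_min1, n = N, d1 = 2, d2 = N - 3,
                               alpha = config$alpha),
                  power_record(f2 = f2_min2, n = N, d1 = 1, d2 = N - 2,
                               alpha = config$alpha))
    tested_f2 <- scan1$results$f2[scan1$results$status == "tested"]
    if (length(tested_f2)) {
      med <- stats::median(tested_f2)
      rows <- rbind(rows, power_record(f2 = med, n = N, d1 = 2, d2 = N - 3,
                                       alpha = config$alpha))
    }
    log(paste0("  minimum detectable f2 at N = ", N, ": step 1 ",
               sprintf("%.4f", f2_min1), ", step 2 ",
               sprintf("%.4f", f2_min2)))
    write_results(rows, file.path(config$out_dir, "power.tsv"), "power")
    rows
  })

  writeLines(log_lines, log_path)
  outputs <- sort(setdiff(list.files(config$out_dir, full.names = TRUE),
                          file.path(config$out_dir, "manifest.json")))
  hashes <- as.list(tools::md5sum(outputs))
  names(hashes) <- basename(outputs)
  cfg <- unclass(config)
  if (!is.null(cfg$synthetic)) cfg$synthetic <- unclass(cfg$synthetic)
  manifest <- list(config = cfg, seed = config$seed, counts = counts,
                   hashes = hashes)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
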