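#' Build a validated pipeline run configuration
#'
#' Exactly one data source must be given: either file paths (`genotypes` +
#' `metadata`, as written by [make_fixture()]) or a simulation block
#' (`simulate`, a [sim_config()]).
#'
#' @param genotypes path to a tabular genotype file (see
#'   [read_genotype_table()]).
#' @param metadata path to an experiment-record file (see
#'   [read_experiment_records()]).
#' @param simulate a [sim_config()] to generate the inputs instead.
#' @param exclusions extra locus names to exclude (panel flags from the
#'   sidecar always apply).
#' @param max_mismatch,tie_break,prior_self parentage options (see
#'   [assign_paternity()], [selfing_probability()]).
#' @param thresholds a [mating_thresholds()].
#' @param yates_multiple_paternity apply Yates' correction to the
#'   multiple-paternity 2x2 table (default `TRUE`), and to no other table.
#' @param ci_method proportion-CI method for family estimates.
#' @param output_dir optional directory for the JSON report and tabular
#'   artifacts.
#' @param seed run seed (required with `simulate`).
#' @return A validated `run_config` list.
#' @export
run_config <- function(genotypes = NULL, metadata = NULL, simulate = NULL,
                       exclusions = character(0),
                       max_mismatch = 2L, tie_break = "likelihood",
                       prior_self = 0.5, thresholds = mating_thresholds(),
                       yates_multiple_paternity = TRUE,
                       ci_method = "wilson", output_dir = NULL, seed = NULL) {
  cfg <- as.list(environment())
  from_files <- !is.null(genotypes) || !is.null(metadata)
  if (from_files == !is.null(simulate))
    stop("exactly one of genotypes/metadata paths or a simulate block ",
         "must be given")
  if (from_files) {
    if (is.null(genotypes) || is.null(metadata))
      stop("both genotypes and metadata paths are required")
    for (p in c(genotypes, metadata))
      if (!file.exists(p)) stop("input file not found: ", p)
  } else {
    validate_sim_config(simulate)
  }
  stopifnot(prior_self >= 0, prior_self <= 1, max_mismatch >= 0)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full progeny-array analysis pipeline
#'
#' Chains the package end to end: load (or simulate) genotypes and
#' experiment records; apply locus exclusions; compute parental allele
#' frequencies; for every mother with genotyped juveniles, filter juveniles
#' by the inclusion criteria, score the selfing hypothesis and every
#' candidate father, and assign paternity; estimate per-family selfing
#' rates with confidence intervals and sire counts; classify genotype-based
#' and apparent selfing propensities; build the five treatment contingency
#' tables and run Pearson's chi-squared tests (Yates-corrected for the
#' multiple-paternity table only). Deterministic given the configuration,
#' including its seed.
#'
#' @param cfg a [run_config()].
#' @return A `run_report` list: `assignments` (per-juvenile data frame),
#'   `estimates` (per-family data frame), `propensity`, `apparent`,
#'   `tables`, `chi2`, `pooled` (pooled selfing summary), `truth` (only for
#'   simulated runs) and `meta` (seed, options, package version). When
#'   `cfg$output_dir` is set, a JSON report plus tabular artifacts are
#'   written there.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- simulate_experiment(cfg$simulate)
    table <- sim$table; records <- sim$records; truth <- sim$truth
  } else {
    table <- read_genotype_table(cfg$genotypes, "tabular")
    records <- read_experiment_records(cfg$metadata)
  }
  table <- apply_locus_exclusions(table, cfg$exclusions)

  juv <- table$meta[table$meta$generation %in% "F2", , drop = FALSE]
  if (nrow(juv) == 0L) stop("no F2 juveniles in the genotype table")
  freqs <- allele_frequencies(table, generation = c("P0", "F1"))

  rec_idx <- match(unique(juv$mother_id), records$individual_id)
  if (anyNA(rec_idx))
    stop("genotyped mothers missing from experiment records: ",
         paste(unique(juv$mother_id)[is.na(rec_idx)], collapse = ", "))

  families <- lapply(unique(juv$mother_id), function(m) {
    partners <- records$partner_ids[[match(m, records$individual_id)]]
    partners <- intersect(partners, table$meta$individual_id)
    if (length(partners) == 0L)
      stop("mother '", m, "' has no genotyped candidate father")
    assign_family(table, m, juv$individual_id[juv$mother_id == m],
                  candidate_ids = partners,
                  max_mismatch = cfg$max_mismatch,
                  tie_break = cfg$tie_break, allele_freqs = freqs)
  })
  names(families) <- unique(juv$mother_id)

  assignments <- do.call(rbind, lapply(families, assignments_to_df))
  rownames(assignments) <- NULL
  estimates <- do.call(rbind, lapply(families, function(f)
    estimate_selfing_rate(f, ci_method = cfg$ci_method)))
  rownames(estimates) <- NULL

  iso <- records$developed_embryos_isolation[
    match(estimates$mother_id, records$individual_id)] > 0
  defined <- !is.na(estimates$s)
  propensity <- data.frame(individual_id = estimates$mother_id,
                           genotype_based = NA_character_,
                           stringsAsFactors = FALSE)
  if (any(defined))
    propensity$genotype_based[defined] <-
      classify_propensity(iso[defined], estimates$s[defined], cfg$thresholds)
  apparent <- data.frame(individual_id = records$individual_id,
                         apparent = classify_apparent_propensity(records),
                         stringsAsFactors = FALSE)

  tables <- build_treatment_tables(estimates, propensity,
                                   apparent[apparent$apparent != "female_infertile", ],
                                   records)
  chi2 <- lapply(names(tables), function(nm) {
    tryCatch(pearson_chi2(tables[[nm]],
                          yates = nm == "multiple_paternity" &&
                            cfg$yates_multiple_paternity),
             error = function(e) list(error = conditionMessage(e)))
  })
  names(chi2) <- names(tables)

  n_selfed <- sum(estimates$n_selfed)
  n_assigned <- sum(estimates$n_assigned)
  pooled <- list(n_assigned = n_assigned, n_selfed = n_selfed,
                 s = if (n_assigned > 0) n_selfed / n_assigned else NA_real_,
                 ci95 = if (n_assigned > 0)
                   proportion_ci(n_selfed, n_assigned, method = cfg$ci_method)
                 else c(NA_real_, NA_real_),
                 n_genotyped = sum(estimates$n_assigned +
                                     estimates$n_ambiguous +
                                     estimates$n_unassigned +
                                     estimates$n_excluded),
                 assignment_rate = {
                   n_pass <- n_assigned + sum(estimates$n_ambiguous) +
                     sum(estimates$n_unassigned)
                   if (n_pass > 0) n_assigned / n_pass else NA_real_
                 })

  report <- list(assignments = assignments, estimates = estimates,
                 propensity = propensity, apparent = apparent,
                 tables = tables, chi2 = chi2, pooled = pooled,
                 truth = truth,
                 meta = list(seed = cfg$seed,
                             simulated = !is.null(cfg$simulate),
                             max_mismatch = cfg$max_mismatch,
                             tie_break = cfg$tie_break,
                             thresholds = unclass(cfg$thresholds),
                             package_version =
                               as.character(utils::packageVersion("selfarray"))))
  class(report) <- "run_report"
  if (!is.null(cfg$output_dir)) .write_report(report, cfg$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", nrow(x$estimates), "families,",
      x$pooled$n_assigned, "assigned juveniles\n")
  cat(sprintf("  pooled selfing rate: %.3f (%d/%d), assignment rate %.3f\n",
              x$pooled$s, x$pooled$n_selfed, x$pooled$n_assigned,
              x$pooled$assignment_rate))
  invisible(x)
}

.write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$assignments, file.path(dir, "assignments.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(report$estimates, file.path(dir, "family_estimates.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(merge(report$propensity, report$apparent,
                         by = "individual_id", all = TRUE),
                   file.path(dir, "propensity.csv"), row.names = FALSE, na = "")
  json <- list(schema_version = 1L, meta = report$meta, pooled = report$pooled,
               tables = lapply(report$tables, function(t)
                 list(row_labels = rownames(t), col_labels = colnames(t),
                      observed = unclass(t))),
               chi2 = lapply(report$chi2, function(r)
                 if (!is.null(r$error)) list(error = r$error) else
                   list(statistic = r$statistic, df = r$df,
                        p_value = r$p_value,
                        yates_applied = r$yates_applied)))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a simulated fixture to disk
#'
#' Emits the standard file set other tools and tests consume: the genotype
#' table (`genotypes.csv` plus its panel sidecar), experiment records
#' (`records.csv`), truth tables (`truth_f1.csv`, `truth_f2.csv`) and the
#' configuration used (`config.yml`).
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param noise passed to [simulate_experiment()].
#' @return Invisibly, the list of written paths.
#' @export
make_fixture <- function(cfg, out_dir, noise = TRUE) {
  validate_sim_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_experiment(cfg, noise = noise)
  paths <- list(
    genotypes = file.path(out_dir, "genotypes.csv"),
    records = file.path(out_dir, "records.csv"),
    truth_f1 = file.path(out_dir, "truth_f1.csv"),
    truth_f2 = file.path(out_dir, "truth_f2.csv"),
    config = file.path(out_dir, "config.yml"))
  write_genotype_table(sim$table, paths$genotypes, "tabular")
  write_experiment_records(sim$records, paths$records)
  f1 <- sim$truth$f1
  f1$partner_ids <- vapply(f1$partner_ids, paste, "", collapse = ";")
  utils::write.csv(f1, paths$truth_f1, row.names = FALSE)
  utils::write.csv(sim$truth$f2, paths$truth_f2, row.names = FALSE)
  cfg_out <- unclass(cfg)
  cfg_out$propensity_class_probs <- as.list(cfg_out$propensity_class_probs)
  yaml::write_yaml(cfg_out, paths$config)
  invisible(paths)
}
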