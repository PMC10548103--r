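# A deterministic synthetic reconstruction of the original mating-trial
# cohort: per-family paternity assignments and per-individual records
# engineered so that every summary table the package derives from them
# (pooled and per-treatment selfing proportions, multiple-paternity and
# propensity contingency tables) equals the observed counts reported for
# the real experiment. Individual-level detail (ids, which juvenile is
# selfed) is synthetic; only the margins are anchored.

# minimal assignment stub carrying what the summary layer consumes
.ref_assignment <- function(juvenile_id, mother_id, status, father_id = NA_character_) {
  structure(list(juvenile_id = juvenile_id, mother_id = mother_id,
                 status = status, assigned_father_id = father_id,
                 best_mismatches = 0L, n_shared_loci = 9L,
                 n_outcross_consistent = if (status == "selfed") 0L else 3L,
                 all_matches = list(), exclusion_reason = NA_character_),
            class = "paternity_assignment")
}

# one family: n_selfed selfed juveniles plus outcrossed juveniles split
# across `fathers`
.ref_family <- function(mother_id, n_selfed, n_per_father = integer(0),
                        fathers = NULL) {
  if (is.null(fathers) && length(n_per_father))
    fathers <- paste0(mother_id, "_F", seq_along(n_per_father))
  k <- 0L
  mk <- function(status, father = NA_character_) {
    k <<- k + 1L
    .ref_assignment(sprintf("%s_J%02d", mother_id, k), mother_id, status, father)
  }
  c(lapply(seq_len(n_selfed), function(i) mk("selfed")),
    unlist(lapply(seq_along(n_per_father), function(f)
      lapply(seq_len(n_per_father[f]), function(i)
        mk("outcrossed", fathers[f]))), recursive = FALSE))
}

#' Reference cohort matching the published experiment's summary counts
#'
#' Builds a fully synthetic cohort -- 55 genotyped progeny arrays (31
#' once-paired, 24 repeatedly paired mothers; 717 assigned juveniles of
#' which 166 selfed) plus 124 female-fertile individuals for the apparent
#' classification -- whose package-computed summaries reproduce the observed
#' contingency cells of the original experiment: multiple paternity
#' (4, 27; 11, 13), families with non-zero selfing (15, 16; 9, 15), pooled
#' selfed offspring (138, 265; 28, 286), genotype-based propensity
#' (11, 4, 15, 1; 4, 5, 11, 4) and apparent propensity
#' (29, 26, 11; 11, 20, 27). Useful as a worked example and for verifying
#' the contingency-statistics layer end to end; everything below the margins
#' (ids, per-juvenile labels) is synthetic.
#'
#' @return A list:
#'   \describe{
#'     \item{families}{list of 55 elements, each with `mother_id`,
#'       `treatment`, `selfed_in_isolation` and `assignments` (a list of
#'       `paternity_assignment` stubs);}
#'     \item{records}{experiment-record data frame for the 55 mothers plus
#'       the 124 apparent-classification individuals.}
#'   }
#' @export
reference_cohort <- function() {
  fams <- list()
  add <- function(treatment, class, n_selfed, n_per_father) {
    id <- sprintf("RC_M%02d", length(fams) + 1L)
    fams[[length(fams) + 1L]] <<- list(
      mother_id = id, treatment = treatment,
      selfed_in_isolation = class != "outcrosser",
      class = class,
      assignments = .ref_family(id, n_selfed, n_per_father))
  }
  ## once-paired: 31 families, 403 assigned, 138 selfed, 15 with selfing,
  ## 4 with multiple paternity, classes 11 selfer / 4 mixer / 15 switcher /
  ## 1 outcrosser
  for (i in 1:11) add("once_paired", "selfer", 12L, integer(0))
  for (k in c(2L, 2L, 1L, 1L)) add("once_paired", "plastic_mixer", k, 13L - k)
  for (i in 1:11) add("once_paired", "plastic_switcher", 0L, 14L)
  for (i in 1:4) add("once_paired", "plastic_switcher", 0L, 13L)
  add("once_paired", "outcrosser", 0L, 13L)
  ## repeatedly paired: 24 families, 314 assigned, 28 selfed, 9 with
  ## selfing, 11 with multiple paternity, classes 4 / 5 / 11 / 4
  for (sz in c(6L, 6L, 6L)) add("repeatedly_paired", "selfer", 5L, sz - 5L)
  add("repeatedly_paired", "selfer", 5L, integer(0))
  for (k in c(2L, 2L, 2L, 1L, 1L)) add("repeatedly_paired", "plastic_mixer",
                                       k, 14L - k)
  for (i in 1:3) add("repeatedly_paired", "plastic_switcher", 0L, c(8L, 7L))
  for (i in 1:8) add("repeatedly_paired", "plastic_switcher", 0L, 15L)
  for (i in 1:4) add("repeatedly_paired", "outcrosser", 0L, 14L)

  mother_rec <- do.call(rbind, lapply(fams, function(f) {
    iso <- if (f$selfed_in_isolation) 40L else 0L
    data.frame(individual_id = f$mother_id, treatment = f$treatment,
               n_male_copulation_partners = 1L,
               n_female_copulation_partners = 1L,
               eggs_isolation = iso, developed_embryos_isolation = iso,
               eggs_post = 60L, developed_embryos_post = 45L,
               n_juveniles_reared = 45L, n_juveniles_dead = 20L,
               body_size = 14, stringsAsFactors = FALSE)
  }))

  ## apparent cohort: 124 female-fertile individuals, cells
  ## once: 29 selfer / 26 plastic / 11 outcrosser; repeated: 11 / 20 / 27
  app <- function(treatment, kind, n) {
    iso <- if (kind == "apparent_outcrosser") 0L else 30L
    post <- if (kind == "apparent_selfer") 0L else 30L
    data.frame(individual_id = character(n), treatment = treatment,
               n_male_copulation_partners = 1L,
               n_female_copulation_partners =
                 if (kind == "apparent_selfer") 0L else 1L,
               eggs_isolation = iso, developed_embryos_isolation = iso,
               eggs_post = post, developed_embryos_post = post,
               n_juveniles_reared = post, n_juveniles_dead = 0L,
               body_size = 14, stringsAsFactors = FALSE)
  }
  apparent_rec <- rbind(app("once_paired", "apparent_selfer", 29L),
                        app("once_paired", "apparent_plastic", 26L),
                        app("once_paired", "apparent_outcrosser", 11L),
                        app("repeatedly_paired", "apparent_selfer", 11L),
                        app("repeatedly_paired", "apparent_plastic", 20L),
                        app("repeatedly_paired", "apparent_outcrosser", 27L))
  apparent_rec$individual_id <- sprintf("RC_A%03d", seq_len(nrow(apparent_rec)))

  records <- rbind(mother_rec, apparent_rec)
  records$partner_ids <- lapply(records$treatment, function(t)
    if (t == "once_paired") "RC_P1" else paste0("RC_P", 1:6))
  list(families = fams, records = validate_experiment_records(records))
}

#' Summarize the reference cohort through the package's analysis layer
#'
#' Runs [estimate_selfing_rate()], [classify_propensity()],
#' [classify_apparent_propensity()], [build_treatment_tables()] and
#' [pearson_chi2()] over the [reference_cohort()], exactly as
#' [run_pipeline()] does for real or simulated data.
#'
#' @param th a [mating_thresholds()].
#' @return List with `estimates` (55-row data frame), `propensity`,
#'   `apparent`, `tables` (five [contingency_table()]s), `chi2` (five
#'   `chi2_result`s; Yates' correction on the multiple-paternity table
#'   only), and `proportions` -- the pooled and per-treatment summary
#'   proportions in percent.
#' @export
reference_summary <- function(th = mating_thresholds()) {
  rc <- reference_cohort()
  estimates <- do.call(rbind, lapply(rc$families, function(f)
    estimate_selfing_rate(f$assignments)))
  propensity <- data.frame(
    individual_id = estimates$mother_id,
    genotype_based = classify_propensity(
      vapply(rc$families, `[[`, TRUE, "selfed_in_isolation"),
      estimates$s, th),
    stringsAsFactors = FALSE)
  apparent_ids <- grep("^RC_A", rc$records$individual_id)
  apparent <- data.frame(
    individual_id = rc$records$individual_id[apparent_ids],
    apparent = classify_apparent_propensity(rc$records[apparent_ids, ]),
    stringsAsFactors = FALSE)
  tables <- build_treatment_tables(estimates, propensity, apparent, rc$records)
  chi2 <- lapply(names(tables), function(nm)
    pearson_chi2(tables[[nm]], yates = nm == "multiple_paternity"))
  names(chi2) <- names(tables)
  trt <- vapply(rc$families, `[[`, "", "treatment")
  once <- trt == "once_paired"
  proportions <- c(
    pct_offspring_selfed = 100 * sum(estimates$n_selfed) / sum(estimates$n_assigned),
    pct_once_paired_offspring_selfed =
      100 * sum(estimates$n_selfed[once]) / sum(estimates$n_assigned[once]),
    pct_families_with_selfed = 100 * mean(estimates$n_selfed > 0),
    pct_once_paired_families_nonzero = 100 * mean(estimates$n_selfed[once] > 0),
    pct_apparent_outcrossers = 100 * mean(apparent$apparent == "apparent_outcrosser"),
    pct_plastic_switchers = 100 * mean(propensity$genotype_based == "plastic_switcher"))
  list(estimates = estimates, propensity = propensity, apparent = apparent,
       tables = tables, chi2 = chi2, proportions = proportions)
}
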