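#' Mating-system classification thresholds
#'
#' The conventional bands: a selfing rate of 20% or lower signifies primary
#' outcrossing, 80% or higher primary selfing, anything between mixed
#' mating. Both boundaries are inclusive towards the extreme classes.
#'
#' @param t_low,t_high band boundaries, `0 < t_low < t_high < 1`
#'   (defaults 0.2 and 0.8).
#' @return A `mating_thresholds` list.
#' @export
mating_thresholds <- function(t_low = 0.2, t_high = 0.8) {
  if (!(t_low > 0 && t_low < t_high && t_high < 1))
    stop("thresholds must satisfy 0 < t_low < t_high < 1")
  structure(list(t_low = t_low, t_high = t_high), class = "mating_thresholds")
}

#' Estimate a family's selfing rate from paternity assignments
#'
#' Only definitive statuses count: `s = n_selfed / (n_selfed + n_outcrossed)`.
#' Ambiguous, unassigned and excluded juveniles are reported but never enter
#' the denominator. A family with no assigned offspring has an undefined
#' rate (`s = NA`), never an imputed zero.
#'
#' @param assignments list of `paternity_assignment` objects or a
#'   `family_assignment` (see [assign_family()]).
#' @param ci_method proportion-interval method for the 95% CI, passed to
#'   [proportion_ci()].
#' @return A `family_selfing_estimate`: one-row data frame with `mother_id`,
#'   `n_assigned`, `n_selfed`, `n_outcrossed`, `n_ambiguous`, `n_unassigned`,
#'   `n_excluded`, `s`, `ci_lower`, `ci_upper`, `n_sires`,
#'   `multiple_paternity`.
#' @export
estimate_selfing_rate <- function(assignments,
                                  ci_method = c("wilson", "clopper_pearson")) {
  ci_method <- match.arg(ci_method)
  if (inherits(assignments, "family_assignment"))
    assignments <- assignments$assignments
  if (length(assignments) == 0L) stop("no assignments supplied")
  st <- vapply(assignments, `[[`, "", "status")
  mother <- assignments[[1L]]$mother_id
  n_selfed <- sum(st == "selfed")
  n_out <- sum(st == "outcrossed")
  n_assigned <- n_selfed + n_out
  if (n_assigned > 0L) {
    s <- n_selfed / n_assigned
    ci <- proportion_ci(n_selfed, n_assigned, method = ci_method)
    sires <- count_sires(assignments)
    n_sires <- sires$n_sires; mp <- sires$multiple_paternity
  } else {
    s <- NA_real_; ci <- c(NA_real_, NA_real_)
    n_sires <- NA_integer_; mp <- NA
  }
  out <- data.frame(mother_id = mother, n_assigned = n_assigned,
                    n_selfed = n_selfed, n_outcrossed = n_out,
                    n_ambiguous = sum(st == "ambiguous"),
                    n_unassigned = sum(st == "unassigned"),
                    n_excluded = sum(st == "excluded"),
                    s = s, ci_lower = ci[1L], ci_upper = ci[2L],
                    n_sires = n_sires, multiple_paternity = mp,
                    stringsAsFactors = FALSE)
  class(out) <- c("family_selfing_estimate", "data.frame")
  out
}

#' Count genetic sires in a progeny array
#'
#' Distinct assigned fathers, plus the mother counted once when any
#' offspring is selfed. A progeny array has multiple paternity when it has
#' at least two sires -- which for a once-paired mother means it contains
#' both selfed and outcrossed offspring.
#'
#' @param assignments list of `paternity_assignment` objects or a
#'   `family_assignment`.
#' @return List with `n_sires` and `multiple_paternity`.
#' @export
count_sires <- function(assignments) {
  if (inherits(assignments, "family_assignment"))
    assignments <- assignments$assignments
  st <- vapply(assignments, `[[`, "", "status")
  if (!any(st %in% c("selfed", "outcrossed")))
    stop("count_sires needs at least one assigned offspring")
  fathers <- unique(vapply(assignments[st == "outcrossed"], `[[`, "",
                           "assigned_father_id"))
  n <- length(fathers) + as.integer(any(st == "selfed"))
  list(n_sires = n, multiple_paternity = n >= 2L)
}

#' Classify a selfing rate into mating-system bands
#'
#' @param s selfing rate in `[0, 1]` (vectorized).
#' @param th a [mating_thresholds()].
#' @return Character vector: `"primary_outcrossing"` (`s <= t_low`),
#'   `"mixed_mating"`, or `"primary_selfing"` (`s >= t_high`).
#' @export
classify_mating_system <- function(s, th = mating_thresholds()) {
  stopifnot(inherits(th, "mating_thresholds"), all(s >= 0 & s <= 1, na.rm = TRUE))
  out <- ifelse(s <= th$t_low, "primary_outcrossing",
                ifelse(s >= th$t_high, "primary_selfing", "mixed_mating"))
  out[is.na(s)] <- NA_character_
  out
}

#' Genotype-based selfing-propensity classification
#'
#' Combines success at selfing in isolation (developed embryos produced
#' before any mating opportunity) with the genotype-estimated post-isolation
#' selfing rate:
#' \describe{
#'   \item{outcrosser}{never selfed -- neither in isolation nor after;}
#'   \item{plastic_switcher}{selfed in isolation, outcrossed fully once
#'     mates were available (`s_post = 0`);}
#'   \item{plastic_mixer}{selfed in isolation and kept a low rate after
#'     (`0 < s_post <= t_low`);}
#'   \item{selfer}{high selfing rate throughout (`s_post >= t_high`);}
#'   \item{intermediate_unclassified}{selfed in isolation with
#'     `t_low < s_post < t_high` (a pattern the scheme's source data did not
#'     contain, kept for logical closure);}
#'   \item{latent_anomaly}{did not self in isolation yet `s_post > 0` below
#'     `t_high` -- flagged, not an error.}
#' }
#' Switchers and mixers are the two kinds of mixed-mating individuals.
#'
#' @param selfed_in_isolation logical (vectorized).
#' @param s_post post-isolation selfing rate; `NA` is an error directing the
#'   caller to [classify_apparent_propensity()].
#' @param th a [mating_thresholds()].
#' @return Character vector of categories.
#' @export
classify_propensity <- function(selfed_in_isolation, s_post,
                                th = mating_thresholds()) {
  stopifnot(inherits(th, "mating_thresholds"))
  n <- max(length(selfed_in_isolation), length(s_post))
  selfed_in_isolation <- rep_len(selfed_in_isolation, n)
  s_post <- rep_len(s_post, n)
  if (anyNA(s_post))
    stop("undefined post-isolation selfing rate: no assigned offspring; ",
         "use classify_apparent_propensity() for such individuals")
  stopifnot(all(s_post >= 0 & s_post <= 1))
  vapply(seq_len(n), function(i) {
    iso <- selfed_in_isolation[i]; s <- s_post[i]
    if (s >= th$t_high) return("selfer")
    if (!iso) {
      if (s == 0) "outcrosser" else "latent_anomaly"
    } else {
      if (s == 0) "plastic_switcher"
      else if (s <= th$t_low) "plastic_mixer"
      else "intermediate_unclassified"
    }
  }, "")
}

#' Apparent selfing propensity from reproduction timing alone
#'
#' For individuals without genotype-based selfing-rate estimates, propensity
#' is inferred from (i) production of developed embryos in isolation,
#' (ii) post-isolation, and (iii) whether the individual ever copulated in
#' the female role (which is what allows outcrossing):
#' `apparent_outcrosser` reproduced only post-isolation and mated as a
#' female; `apparent_plastic` reproduced in both phases and mated as a
#' female; `apparent_selfer` reproduced (in either or both phases) but never
#' mated as a female; `female_infertile` produced no developed embryos at
#' all -- its propensity is unknown. An individual that reproduced only in
#' isolation yet later mated as a female is classed `apparent_selfer`: all
#' of its realized reproduction was autonomous.
#'
#' @param records experiment-record data frame (see
#'   [read_experiment_records()]).
#' @return Character vector of apparent categories, one per record row.
#' @export
classify_apparent_propensity <- function(records) {
  records <- validate_experiment_records(records)
  iso <- records$developed_embryos_isolation > 0
  post <- records$developed_embryos_post > 0
  female <- records$n_female_copulation_partners > 0
  ifelse(!iso & !post, "female_infertile",
         ifelse(!female, "apparent_selfer",
                ifelse(iso & post, "apparent_plastic",
                       ifelse(post, "apparent_outcrosser", "apparent_selfer"))))
}

# Documented column orders of the treatment tables (rows are always
# once_paired then repeatedly_paired).
.table_layouts <- list(
  multiple_paternity = c("multiple", "single"),
  families_selfing = c("nonzero", "zero"),
  offspring_selfing = c("selfed", "outcrossed"),
  apparent_propensity = c("apparent_selfer", "apparent_plastic",
                          "apparent_outcrosser"),
  genotyped_propensity = c("selfer", "plastic_mixer", "plastic_switcher",
                           "outcrosser"))

#' Build the five treatment contingency tables
#'
#' Cross-tabulates pairing treatment (rows: `once_paired`,
#' `repeatedly_paired`) against: multiple paternity per family (yes/no),
#' families with non-zero selfing (nonzero/zero), pooled offspring counts
#' (selfed/outcrossed), apparent propensity of all female-fertile
#' individuals (selfer/plastic/outcrosser), and genotype-based propensity
#' (selfer/mixer/switcher/outcrosser). Column orders are fixed, documented
#' constants.
#'
#' @param estimates data frame of per-family estimates (rbind of
#'   [estimate_selfing_rate()] rows) for genotyped families; may be `NULL`
#'   to skip the three genotype-based tables.
#' @param propensity data frame with `individual_id` and `genotype_based`
#'   category (see [classify_propensity()]); may be `NULL`.
#' @param apparent data frame with `individual_id` and `apparent` category;
#'   may be `NULL`.
#' @param records experiment-record data frame giving each individual's
#'   `treatment` (required).
#' @return Named list of [contingency_table()] objects (a table is omitted
#'   when its inputs are absent): `multiple_paternity`, `families_selfing`,
#'   `offspring_selfing`, `apparent_propensity`, `genotyped_propensity`.
#' @export
build_treatment_tables <- function(estimates = NULL, propensity = NULL,
                                   apparent = NULL, records) {
  if ((is.null(estimates) || nrow(estimates) == 0L) &&
      (is.null(apparent) || nrow(apparent) == 0L))
    stop("no input: need per-family estimates and/or apparent calls")
  trt_of <- function(ids) {
    i <- match(ids, records$individual_id)
    if (anyNA(i))
      stop("individual missing treatment metadata: ",
           paste(ids[is.na(i)], collapse = ", "))
    factor(records$treatment[i], levels = c("once_paired", "repeatedly_paired"))
  }
  cross <- function(ids, value, levels) {
    unclass(table(trt_of(ids), factor(value, levels = levels)))
  }
  out <- list()
  if (!is.null(estimates) && nrow(estimates) > 0L) {
    est <- estimates[!is.na(estimates$s), , drop = FALSE]
    trt <- trt_of(est$mother_id)
    out$multiple_paternity <- contingency_table(
      cross(est$mother_id,
            ifelse(est$multiple_paternity, "multiple", "single"),
            .table_layouts$multiple_paternity),
      row_labels = levels(trt), col_labels = .table_layouts$multiple_paternity)
    out$families_selfing <- contingency_table(
      cross(est$mother_id, ifelse(est$n_selfed > 0, "nonzero", "zero"),
            .table_layouts$families_selfing),
      row_labels = levels(trt), col_labels = .table_layouts$families_selfing)
    off <- rbind(
      once_paired = c(sum(est$n_selfed[trt == "once_paired"]),
                      sum(est$n_outcrossed[trt == "once_paired"])),
      repeatedly_paired = c(sum(est$n_selfed[trt == "repeatedly_paired"]),
                            sum(est$n_outcrossed[trt == "repeatedly_paired"])))
    out$offspring_selfing <- contingency_table(
      off, row_labels = rownames(off),
      col_labels = .table_layouts$offspring_selfing)
  }
  if (!is.null(propensity) && nrow(propensity) > 0L) {
    keep <- propensity$genotype_based %in% .table_layouts$genotyped_propensity
    p <- propensity[keep, , drop = FALSE]
    out$genotyped_propensity <- contingency_table(
      cross(p$individual_id, p$genotype_based,
            .table_layouts$genotyped_propensity),
      row_labels = c("once_paired", "repeatedly_paired"),
      col_labels = .table_layouts$genotyped_propensity)
  }
  if (!is.null(apparent) && nrow(apparent) > 0L) {
    keep <- apparent$apparent %in% .table_layouts$apparent_propensity
    a <- apparent[keep, , drop = FALSE]
    out$apparent_propensity <- contingency_table(
      cross(a$individual_id, a$apparent, .table_layouts$apparent_propensity),
      row_labels = c("once_paired", "repeatedly_paired"),
      col_labels = .table_layouts$apparent_propensity)
  }
  out
}
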