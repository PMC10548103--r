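#' Mendelian comparison of a juvenile to its mother
#'
#' For every active locus called in both individuals, the juvenile's allele
#' pair is classified against the mother's:
#' \describe{
#'   \item{maternal mismatch}{the juvenile carries no allele present in the
#'     mother (genotyping error or null allele);}
#'   \item{outcross-consistent}{exactly one juvenile allele is absent from
#'     the mother -- that allele must be paternal;}
#'   \item{ambiguous}{both juvenile alleles occur in the mother, so either
#'     could be the paternal one.}
#' }
#' The paternal allele set recorded per locus is the singleton non-maternal
#' allele at outcross-consistent loci and the juvenile's own alleles
#' otherwise (at maternal-mismatch loci this means a candidate father is
#' charged a mismatch only if he carries neither juvenile allele, while the
#' mother -- who by definition carries neither -- is charged one
#' automatically, which is exactly the accounting the selfing hypothesis
#' requires).
#'
#' @param table a [genotype_table()] containing both individuals.
#' @param juvenile_id,mother_id individual ids. If the juvenile's `mother_id`
#'   metadata is set and differs from `mother_id`, an error is raised.
#' @return A `maternal_comparison`: list with `juvenile_id`, `mother_id`,
#'   `shared_loci`, `n_shared_loci`, `maternal_mismatch_loci`,
#'   `outcross_consistent_loci`, `paternal_allele_sets` (named list of
#'   integer vectors over the shared loci).
#' @export
compare_to_mother <- function(table, juvenile_id, mother_id = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  i <- match(juvenile_id, table$meta$individual_id)
  if (is.na(i)) stop("unknown juvenile id: ", juvenile_id)
  recorded <- table$meta$mother_id[i]
  if (is.null(mother_id)) {
    if (is.na(recorded)) stop("juvenile '", juvenile_id, "' has no recorded mother")
    mother_id <- recorded
  } else if (!is.na(recorded) && recorded != mother_id) {
    stop("juvenile '", juvenile_id, "' records mother '", recorded,
         "', not '", mother_id, "'")
  }
  loci <- active_loci(table)
  juv <- .calls_of(table, juvenile_id, loci)
  mom <- .calls_of(table, mother_id, loci)
  shared <- loci[!is.na(juv$a1[loci]) & !is.na(mom$a1[loci])]
  mism <- character(0); outc <- character(0)
  psets <- vector("list", length(shared)); names(psets) <- shared
  for (l in shared) {
    j <- unique(c(juv$a1[[l]], juv$a2[[l]]))
    m <- c(mom$a1[[l]], mom$a2[[l]])
    nonmat <- setdiff(j, m)
    if (length(nonmat) == length(j)) {          # no shared allele
      mism <- c(mism, l)
      psets[[l]] <- j
    } else if (length(nonmat) == 1L) {
      outc <- c(outc, l)
      psets[[l]] <- nonmat
    } else {                                     # all juvenile alleles maternal
      psets[[l]] <- j
    }
  }
  structure(list(juvenile_id = juvenile_id, mother_id = mother_id,
                 shared_loci = shared, n_shared_loci = length(shared),
                 maternal_mismatch_loci = mism,
                 outcross_consistent_loci = outc,
                 paternal_allele_sets = psets),
            class = "maternal_comparison")
}

#' Juvenile inclusion filter for paternity analysis
#'
#' A juvenile enters the paternity analysis only if (i) at least six loci
#' were genotyped successfully in both the juvenile and its mother, (ii) it
#' lacks a maternal allele at no more than two loci, and (iii) with exactly
#' six shared loci, at no more than one locus.
#'
#' @param cmp a [compare_to_mother()] result.
#' @param min_shared,max_maternal_mismatch,boundary_max_mismatch the three
#'   criteria's thresholds (defaults 6, 2, 1).
#' @return A list `pass` (logical) and `reason` (`NA` or one of
#'   `"too_few_shared_loci"`, `"too_many_maternal_mismatches"`,
#'   `"too_many_mismatches_at_minimum_loci"`).
#' @export
passes_inclusion <- function(cmp, min_shared = 6L, max_maternal_mismatch = 2L,
                             boundary_max_mismatch = 1L) {
  stopifnot(inherits(cmp, "maternal_comparison"))
  n_mm <- length(cmp$maternal_mismatch_loci)
  if (cmp$n_shared_loci < min_shared)
    return(list(pass = FALSE, reason = "too_few_shared_loci"))
  if (n_mm > max_maternal_mismatch)
    return(list(pass = FALSE, reason = "too_many_maternal_mismatches"))
  if (cmp$n_shared_loci == min_shared && n_mm > boundary_max_mismatch)
    return(list(pass = FALSE, reason = "too_many_mismatches_at_minimum_loci"))
  list(pass = TRUE, reason = NA_character_)
}

#' Score one sire hypothesis against a juvenile
#'
#' Counts, over the loci called in the juvenile, the mother and the
#' candidate, those at which the candidate possesses no allele from the
#' locus's paternal allele set. The mother herself is a legal candidate and
#' encodes the selfing hypothesis: she automatically mismatches every
#' outcross-consistent and maternal-mismatch locus, so a juvenile with none
#' of either scores her as a perfect selfing match.
#'
#' @param cmp a [compare_to_mother()] result.
#' @param table the [genotype_table()].
#' @param candidate_id candidate sire's id (may equal `cmp$mother_id`).
#' @return A `sire_match`: list with `candidate_id`, `is_selfing_hypothesis`,
#'   `n_comparable_loci`, `mismatch_count`, `mismatch_loci`, `perfect`
#'   (`mismatch_count == 0`), `usable` (`n_comparable_loci > 0`).
#' @export
score_candidate <- function(cmp, table, candidate_id) {
  stopifnot(inherits(cmp, "maternal_comparison"))
  cand <- .calls_of(table, candidate_id, cmp$shared_loci)
  comparable <- cmp$shared_loci[!is.na(cand$a1[cmp$shared_loci])]
  mm <- vapply(comparable, function(l) {
    !any(c(cand$a1[[l]], cand$a2[[l]]) %in% cmp$paternal_allele_sets[[l]])
  }, TRUE)
  structure(list(candidate_id = candidate_id,
                 is_selfing_hypothesis = candidate_id == cmp$mother_id,
                 n_comparable_loci = length(comparable),
                 mismatch_count = sum(mm),
                 mismatch_loci = comparable[mm],
                 perfect = length(comparable) > 0L && sum(mm) == 0L,
                 usable = length(comparable) > 0L),
            class = "sire_match")
}

#' Assign paternity (or selfing) to one juvenile
#'
#' All sire hypotheses -- the mother (selfing) plus every candidate father --
#' are scored with [score_candidate()]. Hypotheses with at most
#' `max_mismatch` mismatching loci are eligible; among these, a unique
#' minimal-mismatch hypothesis wins (status `"selfed"` when it is the
#' mother, `"outcrossed"` otherwise). Ties are broken by per-hypothesis
#' Mendelian transmission likelihood when `tie_break = "likelihood"` and
#' allele frequencies are supplied, and otherwise yield `"ambiguous"` --
#' never a coin flip. With no eligible hypothesis the status is
#' `"unassigned"`; juveniles failing [passes_inclusion()] are `"excluded"`.
#'
#' @param cmp a [compare_to_mother()] result.
#' @param table the [genotype_table()].
#' @param candidate_ids ids of candidate fathers (all potential mates of the
#'   mother, whether or not copulation was observed). The mother is added as
#'   the selfing hypothesis automatically.
#' @param max_mismatch mismatch tolerance (default 2, the maximum observed
#'   among accepted assignments in the experiment this routine reimplements).
#' @param tie_break `"likelihood"` (default) or `"none"`.
#' @param allele_freqs optional per-locus frequency maps (see
#'   [allele_frequencies()]) for the likelihood tie-break.
#' @param check_inclusion apply [passes_inclusion()] first (default `TRUE`).
#' @return A `paternity_assignment`: list with `juvenile_id`, `mother_id`,
#'   `status` in `excluded|selfed|outcrossed|ambiguous|unassigned`,
#'   `assigned_father_id` (`NA` unless outcrossed), `best_mismatches`,
#'   `n_shared_loci`, `n_outcross_consistent`, `all_matches` (list of
#'   `sire_match`), `exclusion_reason`.
#' @export
assign_paternity <- function(cmp, table, candidate_ids,
                             max_mismatch = 2L,
                             tie_break = c("likelihood", "none"),
                             allele_freqs = NULL,
                             check_inclusion = TRUE) {
  stopifnot(inherits(cmp, "maternal_comparison"))
  tie_break <- match.arg(tie_break)
  candidate_ids <- as.character(candidate_ids)
  if (length(candidate_ids) == 0L)
    stop("empty candidate list for juvenile '", cmp$juvenile_id, "'")
  hyp_ids <- unique(c(cmp$mother_id, candidate_ids))
  res <- list(juvenile_id = cmp$juvenile_id, mother_id = cmp$mother_id,
              status = NA_character_, assigned_father_id = NA_character_,
              best_mismatches = NA_integer_,
              n_shared_loci = cmp$n_shared_loci,
              n_outcross_consistent = length(cmp$outcross_consistent_loci),
              all_matches = list(), exclusion_reason = NA_character_)
  class(res) <- "paternity_assignment"
  if (check_inclusion) {
    inc <- passes_inclusion(cmp)
    if (!inc$pass) {
      res$status <- "excluded"
      res$exclusion_reason <- inc$reason
      return(res)
    }
  }
  matches <- lapply(hyp_ids, function(id) score_candidate(cmp, table, id))
  names(matches) <- hyp_ids
  res$all_matches <- matches
  usable <- vapply(matches, `[[`, TRUE, "usable")
  mmc <- vapply(matches, `[[`, 0L, "mismatch_count")
  eligible <- usable & mmc <= max_mismatch
  if (!any(eligible)) {
    res$status <- "unassigned"
    return(res)
  }
  best <- min(mmc[eligible])
  winners <- hyp_ids[eligible & mmc == best]
  res$best_mismatches <- best
  if (length(winners) > 1L && tie_break == "likelihood" && !is.null(allele_freqs)) {
    ll <- vapply(winners, function(id)
      mendelian_log_likelihood(table, cmp$juvenile_id, cmp$mother_id, id,
                               allele_freqs), 0)
    top <- winners[ll == max(ll)]
    if (length(top) == 1L) winners <- top
  }
  if (length(winners) > 1L) {
    res$status <- "ambiguous"
  } else if (winners == cmp$mother_id) {
    res$status <- "selfed"
  } else {
    res$status <- "outcrossed"
    res$assigned_father_id <- winners
  }
  res
}

# Internal: log P(juvenile | mother x candidate) under Mendelian segregation,
# product over active loci called in all three. Loci with zero transmission
# probability (mismatches tolerated as genotyping error) contribute `floor`.
mendelian_log_likelihood <- function(table, juvenile_id, mother_id,
                                     candidate_id, allele_freqs = NULL,
                                     floor = 1e-3) {
  loci <- active_loci(table)
  juv <- .calls_of(table, juvenile_id, loci)
  mom <- .calls_of(table, mother_id, loci)
  can <- .calls_of(table, candidate_id, loci)
  ll <- 0
  for (l in loci) {
    if (is.na(juv$a1[[l]]) || is.na(mom$a1[[l]]) || is.na(can$a1[[l]])) next
    p <- .transmission_prob(c(juv$a1[[l]], juv$a2[[l]]),
                            c(mom$a1[[l]], mom$a2[[l]]),
                            c(can$a1[[l]], can$a2[[l]]))
    ll <- ll + log(max(p, floor))
  }
  ll
}

# P(unordered juvenile pair | two parental genotypes), exact enumeration of
# the four equiprobable transmissions.
.transmission_prob <- function(juv, mother, father) {
  p <- 0
  for (m in mother) for (f in father)
    if ((m == juv[1] && f == juv[2]) || (m == juv[2] && f == juv[1]))
      p <- p + 0.25
  p
}

# P(unordered juvenile pair | mother x random sire from allele frequencies).
.transmission_prob_random <- function(juv, mother, freqs, floor = 1e-3) {
  pf <- function(a) {
    f <- freqs[as.character(a)]
    if (is.na(f)) floor else f
  }
  pm <- function(a) mean(mother == a)     # 0, .5 or 1
  if (juv[1] == juv[2]) pm(juv[1]) * pf(juv[1])
  else pm(juv[1]) * pf(juv[2]) + pm(juv[2]) * pf(juv[1])
}

#' Posterior probability that a juvenile is selfed
#'
#' Compares the selfing hypothesis (mother crossed with herself) against the
#' named candidate fathers and, optionally, a random sire drawn from the
#' population allele frequencies, using exact Mendelian transmission
#' probabilities per locus. The posterior is
#' `prior_self * L(self) / (prior_self * L(self) + (1 - prior_self) * mean(L(outcross)))`
#' with likelihoods multiplied over active loci called in all individuals
#' involved. Unseen alleles receive a floor frequency; loci with zero
#' transmission probability under a hypothesis contribute the same floor
#' (tolerating rare genotyping error) except that a juvenile carrying a
#' non-maternal allele makes the selfing likelihood exactly zero.
#'
#' @param table a [genotype_table()].
#' @param juvenile_id,mother_id individual ids.
#' @param candidate_ids candidate fathers; may be empty when
#'   `include_random_sire = TRUE`.
#' @param allele_freqs per-locus frequency maps (see [allele_frequencies()]).
#' @param prior_self prior probability of selfing (default 0.5,
#'   uninformative).
#' @param include_random_sire add an unnamed random-sire outcross hypothesis
#'   (default `TRUE`).
#' @param floor floor frequency for unseen alleles and error tolerance
#'   (default `1e-3`).
#' @return Posterior probability in `[0, 1]`. An error is raised if every
#'   hypothesis has probability zero (genotype inconsistency).
#' @export
selfing_probability <- function(table, juvenile_id, mother_id, candidate_ids,
                                allele_freqs, prior_self = 0.5,
                                include_random_sire = TRUE, floor = 1e-3) {
  stopifnot(prior_self >= 0, prior_self <= 1)
  loci <- active_loci(table)
  juv <- .calls_of(table, juvenile_id, loci)
  mom <- .calls_of(table, mother_id, loci)
  candidate_ids <- setdiff(as.character(candidate_ids), mother_id)

  # selfing likelihood: zero as soon as a shared locus shows a non-maternal
  # allele; exact segregation elsewhere
  l_self <- 1
  for (l in loci) {
    if (is.na(juv$a1[[l]]) || is.na(mom$a1[[l]])) next
    p <- .transmission_prob(c(juv$a1[[l]], juv$a2[[l]]),
                            c(mom$a1[[l]], mom$a2[[l]]),
                            c(mom$a1[[l]], mom$a2[[l]]))
    l_self <- l_self * p
  }

  l_out <- numeric(0)
  for (id in candidate_ids) {
    can <- .calls_of(table, id, loci)
    lk <- 1
    for (l in loci) {
      if (is.na(juv$a1[[l]]) || is.na(mom$a1[[l]]) || is.na(can$a1[[l]])) next
      p <- .transmission_prob(c(juv$a1[[l]], juv$a2[[l]]),
                              c(mom$a1[[l]], mom$a2[[l]]),
                              c(can$a1[[l]], can$a2[[l]]))
      lk <- lk * max(p, floor)
    }
    l_out <- c(l_out, lk)
  }
  if (include_random_sire) {
    lk <- 1
    for (l in loci) {
      if (is.na(juv$a1[[l]]) || is.na(mom$a1[[l]])) next
      p <- .transmission_prob_random(c(juv$a1[[l]], juv$a2[[l]]),
                                     c(mom$a1[[l]], mom$a2[[l]]),
                                     allele_freqs[[l]], floor)
      lk <- lk * max(p, floor)
    }
    l_out <- c(l_out, lk)
  }
  if (length(l_out) == 0L)
    stop("no outcross hypothesis: supply candidates or include_random_sire = TRUE")
  denom <- prior_self * l_self + (1 - prior_self) * mean(l_out)
  if (denom == 0)
    stop("all hypotheses have probability zero: genotypes inconsistent ",
         "with every considered parentage for juvenile '", juvenile_id, "'")
  prior_self * l_self / denom
}

#' Assign paternity across one progeny array
#'
#' Runs [compare_to_mother()] and [assign_paternity()] for every juvenile of
#' one mother and tallies the outcome. Deterministic given inputs and
#' configuration.
#'
#' @param table a [genotype_table()].
#' @param mother_id the mother.
#' @param juvenile_ids her genotyped juveniles (each must record this mother
#'   or no mother).
#' @param candidate_ids candidate fathers for the whole array.
#' @param max_mismatch,tie_break,allele_freqs passed to [assign_paternity()].
#' @return A `family_assignment`: list with `mother_id`, `assignments`
#'   (list of `paternity_assignment`) and `summary` -- a one-row data frame
#'   with `n_genotyped`, `n_excluded`, `n_passing`, `n_unassigned`,
#'   `n_ambiguous`, `n_assigned`, `n_selfed`, `n_outcrossed` satisfying
#'   `n_genotyped = n_excluded + n_unassigned + n_ambiguous + n_assigned`.
#' @export
assign_family <- function(table, mother_id, juvenile_ids, candidate_ids,
                          max_mismatch = 2L,
                          tie_break = c("likelihood", "none"),
                          allele_freqs = NULL) {
  tie_break <- match.arg(tie_break)
  assignments <- lapply(juvenile_ids, function(j) {
    cmp <- compare_to_mother(table, j, mother_id)
    assign_paternity(cmp, table, candidate_ids, max_mismatch = max_mismatch,
                     tie_break = tie_break, allele_freqs = allele_freqs)
  })
  st <- vapply(assignments, `[[`, "", "status")
  summary <- data.frame(
    mother_id = mother_id,
    n_genotyped = length(st),
    n_excluded = sum(st == "excluded"),
    n_passing = sum(st != "excluded"),
    n_unassigned = sum(st == "unassigned"),
    n_ambiguous = sum(st == "ambiguous"),
    n_assigned = sum(st %in% c("selfed", "outcrossed")),
    n_selfed = sum(st == "selfed"),
    n_outcrossed = sum(st == "outcrossed"),
    stringsAsFactors = FALSE)
  structure(list(mother_id = mother_id, assignments = assignments,
                 summary = summary), class = "family_assignment")
}

#' Flatten paternity assignments to a data frame
#'
#' @param assignments a list of `paternity_assignment` objects (or a
#'   `family_assignment`).
#' @return Data frame with one row per juvenile: `juvenile_id`, `mother_id`,
#'   `status`, `father_id`, `best_mismatches`, `n_shared_loci`,
#'   `n_outcross_consistent_loci`, `exclusion_reason`.
#' @export
assignments_to_df <- function(assignments) {
  if (inherits(assignments, "family_assignment"))
    assignments <- assignments$assignments
  do.call(rbind, lapply(assignments, function(a) {
    data.frame(juvenile_id = a$juvenile_id, mother_id = a$mother_id,
               status = a$status, father_id = a$assigned_father_id,
               best_mismatches = a$best_mismatches,
               n_shared_loci = a$n_shared_loci,
               n_outcross_consistent_loci = a$n_outcross_consistent,
               exclusion_reason = a$exclusion_reason,
               stringsAsFactors = FALSE)
  }))
}
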