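#' Configuration for the mating-trial experiment simulator
#'
#' Defaults emulate a paired-mating-trial experiment on a hermaphroditic
#' freshwater snail: 274 focal F1 individuals from 38 wild-caught P0
#' mothers, genotyped at 9 active microsatellite loci plus one excluded
#' locus segregating a null allele; half the cohort receives a single mating
#' opportunity (one partner), half six sequential opportunities; individuals
#' carry one of four latent selfing-propensity classes (outcrosser, plastic
#' switcher, plastic mixer, selfer); selfed embryos develop and survive
#' less well than outcrossed ones (inbreeding depression at two independent
#' stages); and progeny arrays of 3-22 juveniles per family are genotyped,
#' with the sires of a repeatedly paired mother's genotyped brood restricted
#' to her first 3-5 partners.
#'
#' @param n_loci_active active loci (default 9).
#' @param n_loci_excluded loci flagged excluded, carrying the null allele
#'   (default 1).
#' @param alleles_per_locus allele count per locus (default 10).
#' @param freq_concentration Dirichlet concentration for true allele
#'   frequencies (default 1: high, uneven diversity).
#' @param n_mothers P0 mothers (default 38).
#' @param n_founder_pool unobserved allosperm sires of the F1 generation
#'   (default 80): F1 are outcrossed, but their fathers are absent from the
#'   genotype table.
#' @param n_f1 focal F1 individuals (default 274).
#' @param treatment_split fraction once-paired (default 0.5).
#' @param n_partners_repeated partners of a repeatedly paired individual
#'   (default 6).
#' @param genotyped_partner_window integer vector the per-family candidate
#'   window is drawn from (default `3:5`): genotyped broods of repeatedly
#'   paired mothers were conceived before the later mating opportunities.
#' @param propensity_class_probs named 4-vector of class probabilities,
#'   summing to 1 (defaults 0.306/0.2754/0.0956/0.323 for
#'   outcrosser/switcher/mixer/selfer).
#' @param s_mixer,s_selfer true post-isolation selfing rates of mixers
#'   (`<= 0.2`, default 0.1) and selfers (`>= 0.8`, default 0.95).
#' @param eggs_iso_mean,eggs_post_mean Poisson means for lifetime eggs in
#'   each phase (defaults 100 and 120).
#' @param p_develop_outcrossed,p_develop_selfed per-egg development
#'   probabilities (defaults 0.79 and 0.72).
#' @param p_juv_die_outcrossed,p_juv_die_selfed juvenile death probabilities
#'   before genotyping age (defaults 0.534 and 0.695).
#' @param juveniles_per_family_mean,juveniles_per_family_sd,juveniles_min,juveniles_max
#'   genotyping-target distribution per family (defaults 16, 2, 3, 22).
#' @param n_genotyped_families families selected for genotyping among those
#'   with enough surviving juveniles (default 56).
#' @param dropout_rate per-call allelic dropout probability (default 0.05).
#' @param null_allele_freq frequency of the non-amplifying allele at each
#'   excluded locus (default 0.15).
#' @param seed mandatory RNG seed; expanded internally into per-stage
#'   substreams (frequencies, pedigree, thinning, noise).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_loci_active = 9L, n_loci_excluded = 1L,
                       alleles_per_locus = 10L, freq_concentration = 1,
                       n_mothers = 38L, n_founder_pool = 80L, n_f1 = 274L,
                       treatment_split = 0.5, n_partners_repeated = 6L,
                       genotyped_partner_window = 3:5,
                       propensity_class_probs = c(outcrosser = 0.306,
                                                  plastic_switcher = 0.2754,
                                                  plastic_mixer = 0.0956,
                                                  selfer = 0.323),
                       s_mixer = 0.1, s_selfer = 0.95,
                       eggs_iso_mean = 100, eggs_post_mean = 120,
                       p_develop_outcrossed = 0.79, p_develop_selfed = 0.72,
                       p_juv_die_outcrossed = 0.534, p_juv_die_selfed = 0.695,
                       juveniles_per_family_mean = 16,
                       juveniles_per_family_sd = 2,
                       juveniles_min = 3L, juveniles_max = 22L,
                       n_genotyped_families = 56L,
                       dropout_rate = 0.05, null_allele_freq = 0.15,
                       seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulator configuration
#'
#' @param cfg a [sim_config()] list.
#' @return The config, invisibly validated (errors before any sampling).
#' @export
validate_sim_config <- function(cfg) {
  probs <- c("treatment_split", "s_mixer", "s_selfer",
             "p_develop_outcrossed", "p_develop_selfed",
             "p_juv_die_outcrossed", "p_juv_die_selfed",
             "dropout_rate", "null_allele_freq")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("config field ", p, " must be a probability in [0, 1]")
  if (cfg$alleles_per_locus < 2L) stop("alleles_per_locus must be >= 2")
  if (cfg$n_loci_active < 1L) stop("need at least one active locus")
  cp <- cfg$propensity_class_probs
  if (length(cp) != 4L || any(cp < 0) || abs(sum(cp) - 1) > 1e-6)
    stop("propensity_class_probs must be 4 non-negative values summing to 1")
  if (!setequal(names(cp), c("outcrosser", "plastic_switcher",
                             "plastic_mixer", "selfer")))
    stop("propensity_class_probs must be named outcrosser/plastic_switcher/",
         "plastic_mixer/selfer")
  if (cfg$s_mixer <= 0 || cfg$s_mixer > 0.2)
    stop("s_mixer must lie in (0, 0.2]")
  if (cfg$s_selfer < 0.8 || cfg$s_selfer > 1)
    stop("s_selfer must lie in [0.8, 1]")
  if (cfg$juveniles_min < 1L || cfg$juveniles_max < cfg$juveniles_min)
    stop("invalid juveniles_min/juveniles_max")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    stop("seed must be a single integer")
  cfg
}

# per-stage substream seeds (kept well below 2^31)
.sub_seed <- function(cfg, stage) {
  offsets <- c(freqs = 1L, pedigree = 2L, thinning = 3L, noise = 4L)
  (as.integer(cfg$seed) %% 1000000000L) + offsets[[stage]]
}

# null-allele code at excluded loci; never drawn at active loci
.NULL_ALLELE <- 999L

#' Draw true allele frequencies for the panel
#'
#' One symmetric Dirichlet draw per locus (visible allele codes 101, 103,
#' 105, ...). At each excluded locus, the configured null-allele frequency
#' is assigned to a dedicated non-amplifying allele and the Dirichlet draw
#' is rescaled over the visible alleles.
#'
#' @param cfg a [sim_config()].
#' @return List with `freqs` (named list locus -> named frequency vector)
#'   and `panel` (the [locus_panel()]).
#' @export
draw_allele_frequencies <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(.sub_seed(cfg, "freqs"))
  n_loci <- cfg$n_loci_active + cfg$n_loci_excluded
  lnames <- sprintf("L%02d", seq_len(n_loci))
  excluded <- c(rep(FALSE, cfg$n_loci_active), rep(TRUE, cfg$n_loci_excluded))
  panel <- locus_panel(lnames, excluded = excluded,
                       note = ifelse(excluded, "suspected null alleles", ""))
  codes <- 100L + 2L * seq_len(cfg$alleles_per_locus) - 1L
  freqs <- lapply(seq_len(n_loci), function(j) {
    g <- stats::rgamma(cfg$alleles_per_locus, shape = cfg$freq_concentration)
    f <- stats::setNames(g / sum(g), as.character(codes))
    if (excluded[j] && cfg$null_allele_freq > 0) {
      f <- c(f * (1 - cfg$null_allele_freq),
             stats::setNames(cfg$null_allele_freq, as.character(.NULL_ALLELE)))
    }
    f
  })
  names(freqs) <- lnames
  list(freqs = freqs, panel = panel)
}

#' Simulate founder genotypes under Hardy-Weinberg equilibrium
#'
#' @param freqs named list locus -> named allele-frequency vector (see
#'   [draw_allele_frequencies()]).
#' @param n number of individuals.
#' @param ids optional individual ids (default `FND_001`, ...).
#' @param generation generation label (default `"P0"`).
#' @param panel optional [locus_panel()]; defaults to all loci active.
#' @param seed RNG seed.
#' @return A [genotype_table()] with independent HWE draws per locus.
#' @export
simulate_founder_genotypes <- function(freqs, n, ids = NULL,
                                       generation = "P0", panel = NULL,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loci <- names(freqs)
  if (is.null(ids)) ids <- sprintf("FND_%03d", seq_len(n))
  if (is.null(panel)) panel <- locus_panel(loci)
  draw <- function(f) as.integer(sample(as.integer(names(f)), n,
                                        replace = TRUE, prob = f))
  a1 <- vapply(freqs, draw, integer(n))
  a2 <- vapply(freqs, draw, integer(n))
  if (n == 1L) { a1 <- matrix(a1, 1L); a2 <- matrix(a2, 1L) }
  colnames(a1) <- colnames(a2) <- loci
  genotype_table(ids, generation, NA_character_, a1, a2, panel)
}

# Internal vectorized Mendelian cross: mother/sire allele rows (named by
# locus), n offspring; returns list(a1, a2) matrices (unsorted).
.cross <- function(mom, sire, n, loci) {
  pick <- function(p1, p2) {
    u <- matrix(stats::runif(n * length(loci)) < 0.5, n, length(loci))
    out <- matrix(rep(p1, each = n), n, length(loci))
    alt <- matrix(rep(p2, each = n), n, length(loci))
    out[!u] <- alt[!u]
    out
  }
  ma <- pick(mom$a1[loci], mom$a2[loci])
  pa <- pick(sire$a1[loci], sire$a2[loci])
  # a locus missing in either parent is missing in the offspring
  miss <- is.na(mom$a1[loci]) | is.na(sire$a1[loci])
  ma[, miss] <- NA_integer_; pa[, miss] <- NA_integer_
  list(a1 = ma, a2 = pa)
}

#' Simulate one offspring genotype by Mendelian segregation
#'
#' One allele is drawn uniformly from each parent at every locus,
#' independently across loci; selfing is the special case `sire = mother`.
#' A locus missing in either parent is missing in the offspring.
#'
#' @param table a [genotype_table()] holding both parents.
#' @param mother_id,sire_id parent ids (equal for a selfed offspring).
#' @param offspring_id id for the new individual.
#' @param seed optional RNG seed.
#' @return A one-row [genotype_table()] for the offspring (generation
#'   `"F2"`, mother recorded).
#' @export
simulate_offspring_genotype <- function(table, mother_id, sire_id,
                                        offspring_id = "offspring",
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loci <- table$panel$name
  mom <- .calls_of(table, mother_id, loci)
  sire <- .calls_of(table, sire_id, loci)
  g <- .cross(mom, sire, 1L, loci)
  colnames(g$a1) <- colnames(g$a2) <- loci
  genotype_table(offspring_id, "F2", mother_id, g$a1, g$a2, table$panel)
}

#' Simulate the full mating-trial experiment
#'
#' The generative model: P0 mothers are founders; each F1 is an outcrossed
#' offspring of a P0 mother and an unobserved allosperm sire from a distinct
#' founder pool (so F1 fathers are absent from the data, as in a field
#' cohort). Each F1 receives a latent propensity class and a pairing
#' treatment; partners are drawn from the other F1. Individuals of selfing-
#' capable classes reproduce by selfing during isolation; post-isolation
#' eggs are selfed with the class-specific rate, otherwise sired by a
#' partner inside the family's candidate window. Embryo development and
#' juvenile survival are independently thinned with selfed- versus
#' outcrossed-specific probabilities (inbreeding depression). Families for
#' genotyping are drawn among those with enough surviving juveniles; their
#' surviving juveniles are genotyped up to a per-family target. Genotyping
#' noise (allelic dropout plus null-allele masking) is applied when
#' `noise = TRUE` via [apply_genotyping_noise()].
#'
#' @param cfg a [sim_config()].
#' @param noise apply genotyping noise to the emitted table (default
#'   `TRUE`; the truth table is always noise-free).
#' @return A list:
#'   \describe{
#'     \item{table}{[genotype_table()] of P0 mothers, all F1, and the
#'       genotyped F2 juveniles;}
#'     \item{records}{experiment-record data frame for every F1;}
#'     \item{truth}{list with `f1` (class, true post-isolation selfing rate,
#'       partners, candidate window, genotyped flag), `f2` (true sire and
#'       selfed flag per genotyped juvenile), `freqs`, and `config`.}
#'   }
#' @export
simulate_experiment <- function(cfg, noise = TRUE) {
  validate_sim_config(cfg)
  fr <- draw_allele_frequencies(cfg)
  loci <- names(fr$freqs)

  set.seed(.sub_seed(cfg, "pedigree"))
  mother_ids <- sprintf("P0_%03d", seq_len(cfg$n_mothers))
  mothers <- simulate_founder_genotypes(fr$freqs, cfg$n_mothers,
                                        ids = mother_ids, generation = "P0",
                                        panel = fr$panel)
  pool <- simulate_founder_genotypes(fr$freqs, cfg$n_founder_pool,
                                     ids = sprintf("POOL_%03d",
                                                   seq_len(cfg$n_founder_pool)),
                                     generation = "P0", panel = fr$panel)

  # F1: outcrossed broods sired by the unobserved pool
  f1_ids <- sprintf("F1_%03d", seq_len(cfg$n_f1))
  f1_mother <- sample(mother_ids, cfg$n_f1, replace = TRUE)
  f1_a1 <- matrix(NA_integer_, cfg$n_f1, length(loci),
                  dimnames = list(NULL, loci))
  f1_a2 <- f1_a1
  for (i in seq_len(cfg$n_f1)) {
    mom <- .calls_of(mothers, f1_mother[i], loci)
    sire <- .calls_of(pool, sample(pool$meta$individual_id, 1L), loci)
    g <- .cross(mom, sire, 1L, loci)
    f1_a1[i, ] <- g$a1; f1_a2[i, ] <- g$a2
  }

  n_once <- round(cfg$n_f1 * cfg$treatment_split)
  treatment <- c(rep("once_paired", n_once),
                 rep("repeatedly_paired", cfg$n_f1 - n_once))
  classes <- sample(names(cfg$propensity_class_probs), cfg$n_f1,
                    replace = TRUE, prob = cfg$propensity_class_probs)
  s_true <- c(outcrosser = 0, plastic_switcher = 0,
              plastic_mixer = cfg$s_mixer, selfer = cfg$s_selfer)[classes]
  partners <- lapply(seq_len(cfg$n_f1), function(i) {
    k <- if (treatment[i] == "once_paired") 1L else cfg$n_partners_repeated
    sample(f1_ids[-i], k)
  })
  window <- ifelse(treatment == "once_paired", 1L,
                   sample(cfg$genotyped_partner_window, cfg$n_f1,
                          replace = TRUE))

  set.seed(.sub_seed(cfg, "thinning"))
  can_self <- classes != "outcrosser"
  eggs_iso <- ifelse(can_self, stats::rpois(cfg$n_f1, cfg$eggs_iso_mean), 0L)
  dev_iso <- stats::rbinom(cfg$n_f1, eggs_iso, cfg$p_develop_selfed)
  eggs_post <- stats::rpois(cfg$n_f1, cfg$eggs_post_mean)
  selfed_eggs <- stats::rbinom(cfg$n_f1, eggs_post, s_true)
  out_eggs <- eggs_post - selfed_eggs
  dev_self <- stats::rbinom(cfg$n_f1, selfed_eggs, cfg$p_develop_selfed)
  dev_out <- stats::rbinom(cfg$n_f1, out_eggs, cfg$p_develop_outcrossed)
  die_self <- stats::rbinom(cfg$n_f1, dev_self, cfg$p_juv_die_selfed)
  die_out <- stats::rbinom(cfg$n_f1, dev_out, cfg$p_juv_die_outcrossed)
  surv_self <- dev_self - die_self
  surv_out <- dev_out - die_out
  surv <- surv_self + surv_out

  # choose families to genotype among those with enough survivors
  eligible <- which(surv >= cfg$juveniles_min)
  n_geno <- min(cfg$n_genotyped_families, length(eligible))
  geno_fams <- sort(sample(eligible, n_geno))
  target <- pmin(pmax(round(stats::rnorm(cfg$n_f1,
                                         cfg$juveniles_per_family_mean,
                                         cfg$juveniles_per_family_sd)),
                      cfg$juveniles_min), cfg$juveniles_max)

  f1_table <- genotype_table(f1_ids, "F1", f1_mother, f1_a1, f1_a2, fr$panel)
  parent_table <- .bind_tables(mothers, f1_table)

  juv_rows <- list(); juv_truth <- list(); k <- 0L
  for (i in geno_fams) {
    n_g <- min(surv[i], target[i])
    # hypergeometric split of the genotyped sample into selfed/outcrossed
    n_g_self <- stats::rhyper(1L, surv_self[i], surv_out[i], n_g)
    sires <- c(rep(f1_ids[i], n_g_self),
               sample(partners[[i]][seq_len(window[i])],
                      n_g - n_g_self, replace = TRUE))
    mom <- .calls_of(parent_table, f1_ids[i], loci)
    for (j in seq_len(n_g)) {
      k <- k + 1L
      sire <- .calls_of(parent_table, sires[j], loci)
      g <- .cross(mom, sire, 1L, loci)
      juv_rows[[k]] <- list(id = sprintf("F2_%04d", k), mother = f1_ids[i],
                            a1 = g$a1[1L, ], a2 = g$a2[1L, ])
      juv_truth[[k]] <- data.frame(juvenile_id = sprintf("F2_%04d", k),
                                   mother_id = f1_ids[i], sire_id = sires[j],
                                   selfed = sires[j] == f1_ids[i],
                                   stringsAsFactors = FALSE)
    }
  }

  all_ids <- c(mother_ids, f1_ids, vapply(juv_rows, `[[`, "", "id"))
  all_gen <- c(rep("P0", cfg$n_mothers), rep("F1", cfg$n_f1),
               rep("F2", length(juv_rows)))
  all_mom <- c(rep(NA_character_, cfg$n_mothers), f1_mother,
               vapply(juv_rows, `[[`, "", "mother"))
  j_a1 <- do.call(rbind, lapply(juv_rows, `[[`, "a1"))
  j_a2 <- do.call(rbind, lapply(juv_rows, `[[`, "a2"))
  a1 <- rbind(mothers$a1, f1_a1, j_a1)
  a2 <- rbind(mothers$a2, f1_a2, j_a2)
  table <- genotype_table(all_ids, all_gen, all_mom, a1, a2, fr$panel)

  # copulation-role counts: selfers never mate in the female role; the
  # other classes always do at least once (idealized correspondence between
  # behaviour and class, see the package vignette)
  n_partners <- lengths(partners)
  n_female <- ifelse(classes == "selfer", 0L,
                     1L + stats::rbinom(cfg$n_f1, n_partners - 1L, 0.6))
  n_male <- stats::rbinom(cfg$n_f1, n_partners, 0.6)

  records <- data.frame(individual_id = f1_ids, treatment = treatment,
                        n_male_copulation_partners = n_male,
                        n_female_copulation_partners = n_female,
                        eggs_isolation = eggs_iso,
                        developed_embryos_isolation = dev_iso,
                        eggs_post = eggs_post,
                        developed_embryos_post = dev_self + dev_out,
                        n_juveniles_reared = dev_self + dev_out,
                        n_juveniles_dead = die_self + die_out,
                        body_size = round(stats::rnorm(cfg$n_f1, 14, 1.2), 1),
                        stringsAsFactors = FALSE)
  records$partner_ids <- partners
  records <- validate_experiment_records(records)

  truth <- list(
    f1 = data.frame(individual_id = f1_ids, mother_id = f1_mother,
                    treatment = treatment, class = classes,
                    s_true_post = unname(s_true),
                    selfed_in_isolation = dev_iso > 0,
                    candidate_window = window,
                    genotyped = seq_len(cfg$n_f1) %in% geno_fams,
                    stringsAsFactors = FALSE),
    f2 = if (length(juv_truth)) do.call(rbind, juv_truth) else
      data.frame(juvenile_id = character(0), mother_id = character(0),
                 sire_id = character(0), selfed = logical(0)),
    freqs = fr$freqs, config = cfg)
  truth$f1$partner_ids <- partners

  if (noise) table <- apply_genotyping_noise(table, cfg)
  list(table = table, records = records, truth = truth)
}

# rbind two genotype tables sharing a panel
.bind_tables <- function(x, y) {
  genotype_table(c(x$meta$individual_id, y$meta$individual_id),
                 c(x$meta$generation, y$meta$generation),
                 c(x$meta$mother_id, y$meta$mother_id),
                 rbind(x$a1, y$a1), rbind(x$a2, y$a2), x$panel)
}

#' Apply genotyping noise to a table
#'
#' Two error processes: (1) each locus call is dropped (set missing) with
#' probability `cfg$dropout_rate`; (2) at every excluded locus, carriers of
#' the null allele appear homozygous for their visible allele, and
#' null-allele homozygotes fail to amplify entirely (missing). Heterozygous
#' null carriers thereby mimic maternal mismatches downstream, which is why
#' such loci are excluded from analysis.
#'
#' @param table a [genotype_table()].
#' @param cfg a [sim_config()] (supplies `dropout_rate` and the seed's noise
#'   substream).
#' @return The noisy `genotype_table`.
#' @export
apply_genotyping_noise <- function(table, cfg) {
  validate_sim_config(cfg)
  set.seed(.sub_seed(cfg, "noise"))
  a1 <- table$a1; a2 <- table$a2
  for (l in table$panel$name[table$panel$excluded]) {
    both_null <- !is.na(a1[, l]) & a1[, l] == .NULL_ALLELE &
      a2[, l] == .NULL_ALLELE
    a1[both_null, l] <- NA_integer_; a2[both_null, l] <- NA_integer_
    # canonical sort puts the null code (largest) in a2
    carrier <- !is.na(a2[, l]) & a2[, l] == .NULL_ALLELE
    a2[carrier, l] <- a1[carrier, l]
  }
  if (cfg$dropout_rate > 0) {
    drop <- matrix(stats::runif(length(a1)) < cfg$dropout_rate,
                   nrow(a1), ncol(a1))
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }
  genotype_table(table$meta$individual_id, table$meta$generation,
                 table$meta$mother_id, a1, a2, table$panel)
}

#' Closed-form expected pooled selfing fraction among genotyped juveniles
#'
#' For each propensity class, the fraction of surviving juveniles that are
#' selfed is
#' `s * d_s * v_s / (s * d_s * v_s + (1 - s) * d_o * v_o)` where `d` are the
#' development and `v = 1 - p_die` the survival probabilities. Classes are
#' weighted by their probability times the expected number of genotyped
#' juveniles per family (expected survivors capped at the genotyping
#' target mean). Used as the independent oracle for simulator calibration.
#'
#' @param cfg a [sim_config()].
#' @return Expected pooled selfed fraction among genotyped juveniles.
#' @export
expected_pooled_selfing <- function(cfg) {
  validate_sim_config(cfg)
  s_class <- c(outcrosser = 0, plastic_switcher = 0,
               plastic_mixer = cfg$s_mixer, selfer = cfg$s_selfer)
  v_s <- 1 - cfg$p_juv_die_selfed; v_o <- 1 - cfg$p_juv_die_outcrossed
  per_egg_self <- s_class * cfg$p_develop_selfed * v_s
  per_egg_out <- (1 - s_class) * cfg$p_develop_outcrossed * v_o
  frac_self <- ifelse(per_egg_self + per_egg_out > 0,
                      per_egg_self / (per_egg_self + per_egg_out), 0)
  e_surv <- cfg$eggs_post_mean * (per_egg_self + per_egg_out)
  w <- cfg$propensity_class_probs[names(s_class)] *
    pmin(e_surv, cfg$juveniles_per_family_mean)
  sum(w * frac_self) / sum(w)
}
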