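# shared fixture builders; everything is generated in code

# tiny table: one mother, juveniles and candidates specified as lists of
# allele pairs per locus (NA for a missing call)
make_table <- function(genos, panel = NULL, generation = NULL,
                       mother_of = NULL) {
  ids <- names(genos)
  loci <- names(genos[[1L]])
  if (is.null(panel)) panel <- locus_panel(loci)
  a1 <- do.call(rbind, lapply(genos, function(g) vapply(g, function(p)
    if (is.null(p) || anyNA(p)) NA_integer_ else as.integer(min(p)), 0L)))
  a2 <- do.call(rbind, lapply(genos, function(g) vapply(g, function(p)
    if (is.null(p) || anyNA(p)) NA_integer_ else as.integer(max(p)), 0L)))
  colnames(a1) <- colnames(a2) <- loci
  if (is.null(generation)) generation <- rep("F1", length(ids))
  if (is.null(mother_of)) mother_of <- rep(NA_character_, length(ids))
  genotype_table(ids, generation, mother_of, a1, a2, panel)
}

# random multilocus genotypes for oracle tests: allele codes 1..n_alleles
random_instance <- function(n_candidates, n_loci, n_alleles, missing_p = 0.1) {
  loci <- sprintf("L%02d", seq_len(n_loci))
  rand_geno <- function() {
    g <- lapply(loci, function(l) {
      if (stats::runif(1) < missing_p) NA else sample(n_alleles, 2, replace = TRUE)
    })
    names(g) <- loci
    g
  }
  ids <- c("MOM", "JUV", sprintf("CAND%02d", seq_len(n_candidates)))
  genos <- lapply(ids, function(i) rand_geno())
  names(genos) <- ids
  make_table(genos,
             generation = c("F1", "F2", rep("F1", n_candidates)),
             mother_of = c(NA, "MOM", rep(NA, n_candidates)))
}

# independent re-derivation of the mismatch count of one candidate
# (enumeration from first principles, no shared code with score_candidate)
oracle_mismatch <- function(table, juv_id, mom_id, cand_id) {
  loci <- active_loci(table)
  i <- function(id) match(id, table$meta$individual_id)
  total <- 0L; comparable <- 0L
  for (l in loci) {
    j <- c(table$a1[i(juv_id), l], table$a2[i(juv_id), l])
    m <- c(table$a1[i(mom_id), l], table$a2[i(mom_id), l])
    cand <- c(table$a1[i(cand_id), l], table$a2[i(cand_id), l])
    if (anyNA(j) || anyNA(m) || anyNA(cand)) next
    comparable <- comparable + 1L
    nonmat <- setdiff(unique(j), m)
    paternal <- if (length(nonmat) == 1L) nonmat else unique(j)
    if (!any(cand %in% paternal)) total <- total + 1L
  }
  list(mismatches = total, comparable = comparable)
}

# oracle re-implementation of the whole verdict rule
oracle_assign <- function(table, juv_id, mom_id, cand_ids, max_mismatch = 2L) {
  hyps <- unique(c(mom_id, cand_ids))
  sc <- lapply(hyps, function(h) oracle_mismatch(table, juv_id, mom_id, h))
  ok <- vapply(sc, function(x) x$comparable > 0L && x$mismatches <= max_mismatch, TRUE)
  if (!any(ok)) return(list(status = "unassigned", father = NA_character_))
  mm <- vapply(sc, `[[`, 0L, "mismatches")
  best <- min(mm[ok])
  winners <- hyps[ok & mm == best]
  if (length(winners) > 1L) list(status = "ambiguous", father = NA_character_)
  else if (winners == mom_id) list(status = "selfed", father = NA_character_)
  else list(status = "outcrossed", father = winners)
}

# bespoke noise-free grid simulator: n_fam families, each mother with one
# unrelated candidate father; each juvenile selfed with probability s
sim_grid_families <- function(s, n_fam = 30L, n_juv = 16L, n_loci = 9L,
                              n_alleles = 10L, seed = 1L) {
  set.seed(seed)
  loci <- sprintf("L%02d", seq_len(n_loci))
  freqs <- lapply(loci, function(l)
    stats::setNames(rep(1 / n_alleles, n_alleles), as.character(seq_len(n_alleles))))
  names(freqs) <- loci
  parents <- simulate_founder_genotypes(freqs, 2L * n_fam,
                                        ids = c(sprintf("M%03d", seq_len(n_fam)),
                                                sprintf("D%03d", seq_len(n_fam))),
                                        generation = "F1")
  truth <- list(); fams <- list()
  juv_a1 <- list(); juv_a2 <- list(); juv_ids <- character(0)
  juv_mom <- character(0)
  k <- 0L
  for (f in seq_len(n_fam)) {
    mom <- sprintf("M%03d", f); dad <- sprintf("D%03d", f)
    juvs <- character(n_juv)
    for (j in seq_len(n_juv)) {
      k <- k + 1L
      selfed <- stats::runif(1) < s
      off <- simulate_offspring_genotype(parents, mom,
                                         if (selfed) mom else dad,
                                         offspring_id = sprintf("J%04d", k))
      juv_a1[[k]] <- off$a1; juv_a2[[k]] <- off$a2
      juv_ids <- c(juv_ids, sprintf("J%04d", k))
      juv_mom <- c(juv_mom, mom)
      juvs[j] <- sprintf("J%04d", k)
      truth[[k]] <- data.frame(juvenile_id = juvs[j], selfed = selfed)
    }
    fams[[f]] <- list(mother = mom, father = dad, juveniles = juvs)
  }
  table <- genotype_table(
    c(parents$meta$individual_id, juv_ids),
    c(parents$meta$generation, rep("F2", k)),
    c(parents$meta$mother_id, juv_mom),
    rbind(parents$a1, do.call(rbind, juv_a1)),
    rbind(parents$a2, do.call(rbind, juv_a2)), parents$panel)
  list(table = table, families = fams, truth = do.call(rbind, truth))
}
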