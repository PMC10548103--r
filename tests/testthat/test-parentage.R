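# a 1-locus scaffold used by several blocks
pair_table <- function(juv, mom, cand = NULL, loci = "L1") {
  genos <- list(MOM = mom, JUV = juv)
  if (!is.null(cand)) genos$CAND <- cand
  make_table(genos, generation = c("F1", "F2", "F1")[seq_along(genos)],
             mother_of = c(NA, "MOM", NA)[seq_along(genos)])
}

test_that("maternal comparison classifies loci and paternal allele sets", {
  tb <- pair_table(list(L1 = c(101, 105)), list(L1 = c(101, 103)))
  cmp <- compare_to_mother(tb, "JUV", "MOM")
  expect_identical(cmp$outcross_consistent_loci, "L1")
  expect_identical(cmp$paternal_allele_sets$L1, 105L)

  tb <- pair_table(list(L1 = c(101, 103)), list(L1 = c(101, 103)))
  cmp <- compare_to_mother(tb, "JUV", "MOM")
  expect_length(cmp$outcross_consistent_loci, 0L)
  expect_setequal(cmp$paternal_allele_sets$L1, c(101L, 103L))

  tb <- pair_table(list(L1 = c(103, 105)), list(L1 = c(101, 101)))
  cmp <- compare_to_mother(tb, "JUV", "MOM")
  expect_identical(cmp$maternal_mismatch_loci, "L1")

  # homozygous juvenile sharing its allele: paternal set is that allele
  tb <- pair_table(list(L1 = c(101, 101)), list(L1 = c(101, 103)))
  cmp <- compare_to_mother(tb, "JUV", "MOM")
  expect_identical(cmp$paternal_allele_sets$L1, 101L)

  # missing loci drop out of the shared count
  loci <- sprintf("L%d", 1:9)
  juv <- stats::setNames(rep(list(c(1, 2)), 9), loci)
  juv$L8 <- NA; juv$L9 <- NA
  mom <- stats::setNames(rep(list(c(1, 2)), 9), loci)
  tb <- make_table(list(MOM = mom, JUV = juv))
  expect_identical(compare_to_mother(tb, "JUV", "MOM")$n_shared_loci, 7L)

  # recorded mother conflicting with the requested one is an error
  tb <- pair_table(list(L1 = c(1, 2)), list(L1 = c(1, 2)))
  expect_error(compare_to_mother(tb, "JUV", "CAND"), "records mother")
})

test_that("inclusion criteria follow the three-rule filter", {
  fake <- function(shared, mism) {
    structure(list(n_shared_loci = shared,
                   maternal_mismatch_loci = if (mism) sprintf("M%d", 1:mism)
                   else character(0)),
              class = "maternal_comparison")
  }
  cases <- list(list(5, 0, FALSE, "too_few_shared_loci"),
                list(6, 2, FALSE, "too_many_mismatches_at_minimum_loci"),
                list(6, 1, TRUE, NA),
                list(8, 2, TRUE, NA),
                list(8, 3, FALSE, "too_many_maternal_mismatches"),
                list(7, 0, TRUE, NA))
  for (cs in cases) {
    r <- passes_inclusion(fake(cs[[1]], cs[[2]]))
    expect_identical(r$pass, cs[[3]])
    if (!r$pass) expect_identical(r$reason, cs[[4]])
  }
})

test_that("candidate scoring counts paternal-allele incompatibilities", {
  loci <- sprintf("L%d", 1:9)
  mk <- function(pair) stats::setNames(rep(list(pair), 9), loci)
  # mother (1,3), juvenile (1,5): paternal allele 5 everywhere
  tb <- make_table(list(MOM = mk(c(1, 3)), JUV = mk(c(1, 5)),
                        GOOD = mk(c(5, 7)), ONEOFF = mk(c(5, 7))))
  # break ONEOFF at one locus
  tb$a1["ONEOFF", "L9"] <- 8L; tb$a2["ONEOFF", "L9"] <- 9L
  cmp <- compare_to_mother(tb, "JUV", "MOM")
  expect_true(score_candidate(cmp, tb, "GOOD")$perfect)
  m <- score_candidate(cmp, tb, "ONEOFF")
  expect_identical(m$mismatch_count, 1L)
  expect_false(m$perfect)
  # the selfing hypothesis mismatches every outcross-consistent locus
  expect_identical(score_candidate(cmp, tb, "MOM")$mismatch_count, 9L)

  # juvenile fully explained by the mother: selfing is a perfect match
  tb2 <- make_table(list(MOM = mk(c(1, 3)), JUV = mk(c(1, 3))))
  cmp2 <- compare_to_mother(tb2, "JUV", "MOM")
  expect_true(score_candidate(cmp2, tb2, "MOM")$perfect)

  # maternal-mismatch locus: father with either juvenile allele is fine,
  # selfing hypothesis is charged automatically
  tb3 <- make_table(list(MOM = mk(c(1, 1)), JUV = mk(c(1, 3)),
                         F1C = mk(c(3, 4))))
  tb3$a1["JUV", "L1"] <- 5L; tb3$a2["JUV", "L1"] <- 6L
  cmp3 <- compare_to_mother(tb3, "JUV", "MOM")
  expect_identical(cmp3$maternal_mismatch_loci, "L1")
  expect_identical(score_candidate(cmp3, tb3, "F1C")$mismatch_count, 1L)
  tb3$a1["F1C", "L1"] <- 5L   # father carries one juvenile allele
  expect_identical(score_candidate(cmp3, tb3, "F1C")$mismatch_count, 0L)
  expect_gte(score_candidate(cmp3, tb3, "MOM")$mismatch_count, 1L)
})

test_that("paternity verdicts cover selfed, outcrossed, ambiguous, unassigned", {
  loci <- sprintf("L%d", 1:9)
  mk <- function(pair) stats::setNames(rep(list(pair), 9), loci)
  # selfed: juvenile fully maternal, candidate far off
  tb <- make_table(list(MOM = mk(c(1, 3)), JUV = mk(c(1, 3)),
                        C1 = mk(c(7, 8))))
  cmp <- compare_to_mother(tb, "JUV", "MOM")
  expect_identical(assign_paternity(cmp, tb, "C1")$status, "selfed")

  # outcrossed to a unique perfect candidate
  tb <- make_table(list(MOM = mk(c(1, 3)), JUV = mk(c(1, 5)),
                        C1 = mk(c(5, 7)), C2 = mk(c(8, 9))))
  cmp <- compare_to_mother(tb, "JUV", "MOM")
  a <- assign_paternity(cmp, tb, c("C1", "C2"))
  expect_identical(a$status, "outcrossed")
  expect_identical(a$assigned_father_id, "C1")

  # two perfect candidates, no frequencies: ambiguous
  tb <- make_table(list(MOM = mk(c(1, 3)), JUV = mk(c(1, 5)),
                        C1 = mk(c(5, 7)), C2 = mk(c(5, 9))))
  cmp <- compare_to_mother(tb, "JUV", "MOM")
  expect_identical(assign_paternity(cmp, tb, c("C1", "C2"))$status, "ambiguous")

  # nothing eligible: unassigned
  tb <- make_table(list(MOM = mk(c(1, 3)), JUV = mk(c(1, 5)),
                        C1 = mk(c(8, 9))))
  cmp <- compare_to_mother(tb, "JUV", "MOM")
  expect_identical(assign_paternity(cmp, tb, "C1")$status, "unassigned")

  expect_error(assign_paternity(cmp, tb, character(0)), "empty candidate")
})

test_that("assignment equals exhaustive enumeration on random instances", {
  set.seed(101)
  n_checked <- 0L
  for (rep in 1:120) {
    inst <- random_instance(n_candidates = sample(1:10, 1),
                            n_loci = sample(3:10, 1),
                            n_alleles = sample(3:10, 1),
                            missing_p = 0.15)
    cands <- grep("^CAND", inst$meta$individual_id, value = TRUE)
    cmp <- compare_to_mother(inst, "JUV", "MOM")
    got <- assign_paternity(cmp, inst, cands, tie_break = "none",
                            check_inclusion = FALSE)
    want <- oracle_assign(inst, "JUV", "MOM", cands)
    expect_identical(got$status, want$status)
    if (got$status == "outcrossed")
      expect_identical(got$assigned_father_id, want$father)
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, 120L)
})

test_that("raising the mismatch tolerance never unassigns a juvenile", {
  set.seed(202)
  rank <- c(excluded = 0, unassigned = 1, ambiguous = 2, selfed = 3,
            outcrossed = 3)
  for (rep in 1:40) {
    inst <- random_instance(n_candidates = 4, n_loci = 8, n_alleles = 5,
                            missing_p = 0.1)
    cands <- grep("^CAND", inst$meta$individual_id, value = TRUE)
    cmp <- compare_to_mother(inst, "JUV", "MOM")
    prev <- assign_paternity(cmp, inst, cands, max_mismatch = 0L,
                             check_inclusion = FALSE)
    for (mm in 1:3) {
      cur <- assign_paternity(cmp, inst, cands, max_mismatch = mm,
                              check_inclusion = FALSE)
      expect_gte(rank[[cur$status]], min(rank[[prev$status]], 2))
      prev <- cur
    }
  }
})

test_that("a zero-tolerance selfing call implies a fully maternal genotype", {
  # crafted case: juvenile fully maternal, decoy candidate
  loci9 <- sprintf("L%d", 1:9)
  mk9 <- function(pair) stats::setNames(rep(list(pair), 9), loci9)
  tb0 <- make_table(list(MOM = mk9(c(1, 3)), JUV = mk9(c(3, 3)),
                         C1 = mk9(c(7, 8))))
  cmp0 <- compare_to_mother(tb0, "JUV", "MOM")
  a0 <- assign_paternity(cmp0, tb0, "C1", max_mismatch = 0L,
                         check_inclusion = FALSE)
  expect_identical(a0$status, "selfed")
  expect_length(cmp0$outcross_consistent_loci, 0L)

  set.seed(303)
  for (rep in 1:60) {
    inst <- random_instance(n_candidates = 3, n_loci = 8, n_alleles = 4,
                            missing_p = 0.1)
    cands <- grep("^CAND", inst$meta$individual_id, value = TRUE)
    cmp <- compare_to_mother(inst, "JUV", "MOM")
    a <- assign_paternity(cmp, inst, cands, max_mismatch = 0L,
                          check_inclusion = FALSE)
    if (a$status == "selfed") {
      expect_length(cmp$outcross_consistent_loci, 0L)
      expect_length(cmp$maternal_mismatch_loci, 0L)
    }
  }
})

test_that("selfing posterior matches hand-computed segregation probabilities", {
  # mother (1,2), juvenile (1,2), random sire with p1 = p2 = 0.5:
  # P(J|self) = 0.5, P(J|random) = 0.5, prior 0.5 -> posterior 0.5
  tb <- make_table(list(MOM = list(L1 = c(1, 2)), JUV = list(L1 = c(1, 2))),
                   generation = c("F1", "F2"), mother_of = c(NA, "MOM"))
  freqs <- list(L1 = c(`1` = 0.5, `2` = 0.5))
  expect_equal(selfing_probability(tb, "JUV", "MOM", character(0), freqs), 0.5)

  # non-maternal allele: selfing impossible
  tb2 <- make_table(list(MOM = list(L1 = c(1, 2)), JUV = list(L1 = c(1, 3))),
                    generation = c("F1", "F2"), mother_of = c(NA, "MOM"))
  freqs2 <- list(L1 = c(`1` = 0.4, `2` = 0.3, `3` = 0.3))
  expect_equal(selfing_probability(tb2, "JUV", "MOM", character(0), freqs2), 0)

  # homozygous mother and identical juvenile at rare alleles: posterior
  # grows towards 1 with the number of loci (product-likelihood oracle)
  post_k <- vapply(c(1, 3, 6, 9), function(k) {
    loci <- sprintf("L%d", seq_len(k))
    g <- stats::setNames(rep(list(c(5, 5)), k), loci)
    tbk <- make_table(list(MOM = g, JUV = g),
                      generation = c("F1", "F2"), mother_of = c(NA, "MOM"))
    fk <- stats::setNames(rep(list(c(`5` = 0.01, `6` = 0.99)), k), loci)
    selfing_probability(tbk, "JUV", "MOM", character(0), fk)
  }, 0)
  expect_true(all(diff(post_k) > 0))
  expect_gt(post_k[4], 0.99)
  # closed form at one locus: 1 / (1 + p) with p the rare-allele frequency
  expect_equal(post_k[1], 0.5 / (0.5 + 0.5 * 0.01))
})

test_that("selfing posterior is invariant to allele relabelling and locus order", {
  set.seed(404)
  inst <- random_instance(n_candidates = 3, n_loci = 6, n_alleles = 5,
                          missing_p = 0)
  cands <- grep("^CAND", inst$meta$individual_id, value = TRUE)
  freqs <- allele_frequencies(inst)
  p0 <- selfing_probability(inst, "JUV", "MOM", cands, freqs)

  # relabel alleles: a -> 10 * a + 7
  rl <- inst
  rl$a1 <- rl$a1 * 10L + 7L; rl$a2 <- rl$a2 * 10L + 7L
  rl <- genotype_table(rl$meta$individual_id, rl$meta$generation,
                       rl$meta$mother_id, rl$a1, rl$a2, rl$panel)
  freqs_rl <- lapply(freqs, function(f)
    stats::setNames(f, as.integer(names(f)) * 10L + 7L))
  expect_equal(selfing_probability(rl, "JUV", "MOM", cands, freqs_rl), p0)

  # permute loci
  perm <- sample(ncol(inst$a1))
  pm <- genotype_table(inst$meta$individual_id, inst$meta$generation,
                       inst$meta$mother_id,
                       inst$a1[, perm], inst$a2[, perm],
                       locus_panel(colnames(inst$a1)[perm]))
  expect_equal(selfing_probability(pm, "JUV", "MOM", cands, freqs[perm]), p0)
})

test_that("family assignment bookkeeping loses no juvenile", {
  sim <- sim_grid_families(0.4, n_fam = 4, n_juv = 8, seed = 11)
  for (f in sim$families) {
    fam <- assign_family(sim$table, f$mother, f$juveniles, f$father)
    s <- fam$summary
    expect_identical(s$n_genotyped,
                     s$n_excluded + s$n_unassigned + s$n_ambiguous + s$n_assigned)
    expect_identical(s$n_assigned, s$n_selfed + s$n_outcrossed)
    expect_identical(nrow(assignments_to_df(fam)), length(f$juveniles))
  }
})

test_that("noise-free simulated families recover the true sire", {
  sim <- sim_grid_families(0.5, n_fam = 12, n_juv = 12, seed = 21)
  res <- do.call(rbind, lapply(sim$families, function(f)
    assignments_to_df(assign_family(sim$table, f$mother, f$juveniles, f$father))))
  truth <- sim$truth[match(res$juvenile_id, sim$truth$juvenile_id), ]
  assigned <- res$status %in% c("selfed", "outcrossed")
  expect_gte(mean(assigned), 0.97)
  agree <- (res$status == "selfed") == truth$selfed
  expect_gte(mean(agree[assigned]), 0.99)
  # no false selfing calls among true outcrossed juveniles
  expect_lte(mean(res$status[!truth$selfed] == "selfed"), 0.01)
})
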