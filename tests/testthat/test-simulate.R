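# compact config for fast runs
small_cfg <- function(seed, ...) {
  sim_config(n_mothers = 10L, n_founder_pool = 20L, n_f1 = 60L,
             n_genotyped_families = 15L, seed = seed, ...)
}

test_that("configuration validation fails before any sampling", {
  expect_error(sim_config(seed = 1, s_mixer = 0.5), "s_mixer")
  expect_error(sim_config(seed = 1, s_selfer = 0.5), "s_selfer")
  expect_error(sim_config(seed = 1, dropout_rate = 1.5), "probability")
  expect_error(sim_config(seed = 1, alleles_per_locus = 1L), "alleles")
  expect_error(sim_config(seed = 1,
                          propensity_class_probs = c(outcrosser = 0.5,
                                                     plastic_switcher = 0.5,
                                                     plastic_mixer = 0.5,
                                                     selfer = 0.5)),
               "summing to 1")
  expect_error(sim_config(), "seed")
})

test_that("allele frequency draws are seeded, normalized and calibrated", {
  cfg <- sim_config(seed = 5)
  f1 <- draw_allele_frequencies(cfg)
  f2 <- draw_allele_frequencies(cfg)
  expect_identical(f1, f2)
  expect_true(all(abs(vapply(f1$freqs, sum, 0) - 1) < 1e-12))
  expect_identical(sum(f1$panel$excluded), 1L)
  # the excluded locus carries the null allele at its configured frequency
  null_locus <- f1$panel$name[f1$panel$excluded]
  expect_equal(unname(f1$freqs[[null_locus]]["999"]), cfg$null_allele_freq)

  # Dirichlet moment check: mean frequency per allele is 1/k
  set.seed(6)
  draws <- t(replicate(2000, {
    g <- stats::rgamma(10, 1); g / sum(g)
  }))
  expect_lt(max(abs(colMeans(draws) - 0.1)), 0.01)
})

test_that("founder genotypes follow Hardy-Weinberg at a checked locus", {
  freqs <- list(L1 = c(`1` = 0.3, `2` = 0.7),
                L2 = c(`1` = 1, `2` = 0))
  tb <- simulate_founder_genotypes(freqs, 2000, seed = 7)
  het <- mean(tb$a1[, "L1"] != tb$a2[, "L1"])
  expect_lt(abs(het - 2 * 0.3 * 0.7), 0.02)
  expect_true(all(tb$a1[, "L2"] == 1L & tb$a2[, "L2"] == 1L))
})

test_that("offspring genotypes segregate 1:2:1 under selfing", {
  tb <- make_table(list(MOM = list(L1 = c(1, 2)), DAD = list(L1 = c(3, 3))))
  # homozygote x homozygote is deterministic
  kid <- simulate_offspring_genotype(
    make_table(list(A = list(L1 = c(1, 1)), B = list(L1 = c(3, 3)))),
    "A", "B", seed = 8)
  expect_identical(unname(kid$a1[1, 1]), 1L)
  expect_identical(unname(kid$a2[1, 1]), 3L)

  set.seed(9)
  kinds <- table(vapply(1:4000, function(i) {
    k <- simulate_offspring_genotype(tb, "MOM", "MOM", offspring_id = "k")
    paste(k$a1[1, 1], k$a2[1, 1])
  }, ""))
  props <- as.numeric(kinds[c("1 1", "1 2", "2 2")]) / 4000
  expect_lt(max(abs(props - c(0.25, 0.5, 0.25))), 0.03)
})

test_that("simulation is reproducible and Mendelian-consistent pre-noise", {
  cfg <- small_cfg(13, dropout_rate = 0, null_allele_freq = 0)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$table$a1, s2$table$a1)
  expect_identical(s1$truth$f2, s2$truth$f2)

  # every genotyped juvenile shares an allele with its mother at every locus
  for (i in which(s1$table$meta$generation == "F2")) {
    m <- match(s1$table$meta$mother_id[i], s1$table$meta$individual_id)
    share <- s1$table$a1[i, ] == s1$table$a1[m, ] |
      s1$table$a1[i, ] == s1$table$a2[m, ] |
      s1$table$a2[i, ] == s1$table$a1[m, ] |
      s1$table$a2[i, ] == s1$table$a2[m, ]
    expect_true(all(share, na.rm = TRUE))
  }
})

test_that("degenerate class mixes produce all-selfed or no-selfed truth", {
  all_out <- small_cfg(14, propensity_class_probs = c(outcrosser = 1,
                                                      plastic_switcher = 0,
                                                      plastic_mixer = 0,
                                                      selfer = 0))
  expect_identical(sum(simulate_experiment(all_out)$truth$f2$selfed), 0L)

  all_self <- small_cfg(15, s_selfer = 1,
                        propensity_class_probs = c(outcrosser = 0,
                                                   plastic_switcher = 0,
                                                   plastic_mixer = 0,
                                                   selfer = 1))
  f2 <- simulate_experiment(all_self)$truth$f2
  expect_gt(nrow(f2), 0L)
  expect_true(all(f2$selfed))
  expect_true(all(f2$sire_id == f2$mother_id))
})

test_that("true pooled selfing tracks the closed-form class expectation", {
  cfg <- sim_config(seed = 16, dropout_rate = 0, null_allele_freq = 0)
  sim <- simulate_experiment(cfg)
  expect_lt(abs(mean(sim$truth$f2$selfed) - expected_pooled_selfing(cfg)),
            0.05)
})

test_that("genotyping noise behaves as configured", {
  cfg <- small_cfg(17, dropout_rate = 0, null_allele_freq = 0)
  sim <- simulate_experiment(cfg, noise = FALSE)
  expect_identical(apply_genotyping_noise(sim$table, cfg)$a1, sim$table$a1)

  cfg1 <- small_cfg(17, dropout_rate = 1, null_allele_freq = 0)
  noisy <- apply_genotyping_noise(sim$table, cfg1)
  expect_true(all(is.na(noisy$a1)))

  cfg05 <- small_cfg(18, dropout_rate = 0.05, null_allele_freq = 0)
  fr <- draw_allele_frequencies(cfg05)
  big <- simulate_founder_genotypes(fr$freqs, 1000, panel = fr$panel,
                                    seed = 181)   # 10^4 locus calls
  noisy2 <- apply_genotyping_noise(big, cfg05)
  expect_lt(abs(mean(is.na(noisy2$a1)) - 0.05), 0.01)

  # null-allele masking: no null code survives, carriers become homozygous
  cfgN <- small_cfg(19, dropout_rate = 0, null_allele_freq = 0.3)
  simN <- simulate_experiment(cfgN, noise = FALSE)
  nl <- simN$table$panel$name[simN$table$panel$excluded]
  maskedN <- apply_genotyping_noise(simN$table, cfgN)
  expect_false(any(maskedN$a1[, nl] == 999L | maskedN$a2[, nl] == 999L,
                   na.rm = TRUE))
  carrier <- !is.na(simN$table$a2[, nl]) & simN$table$a2[, nl] == 999L &
    simN$table$a1[, nl] != 999L
  expect_true(any(carrier))
  expect_identical(maskedN$a2[carrier, nl], maskedN$a1[carrier, nl])
})
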