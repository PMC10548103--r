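test_that("chi-squared equals the textbook closed form on random 2x2 tables", {
  set.seed(9)
  closed_form <- function(o, yates) {
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    adj <- if (yates) pmin(abs(o - e), 0.5) else 0
    sum((abs(o - e) - adj)^2 / e)
  }
  for (rep in 1:60) {
    o <- matrix(rpois(4, 20) + 1L, 2, 2)
    for (yates in c(FALSE, TRUE)) {
      r <- pearson_chi2(o, yates = yates)
      expect_equal(r$statistic, closed_form(o, yates))
      expect_equal(r$p_value, stats::pchisq(r$statistic, 1, lower.tail = FALSE))
      expect_equal(rowSums(r$expected), rowSums(o), ignore_attr = TRUE)
      expect_equal(colSums(r$expected), colSums(o), ignore_attr = TRUE)
    }
  }
})

test_that("chi-squared is invariant to transposition and permutation", {
  set.seed(10)
  for (rep in 1:20) {
    o <- matrix(rpois(12, 15) + 1L, 3, 4)
    s0 <- pearson_chi2(o)$statistic
    expect_equal(pearson_chi2(t(o))$statistic, s0)
    expect_equal(pearson_chi2(o[sample(3), sample(4)])$statistic, s0)
    expect_identical(pearson_chi2(o)$df, 6L)
  }
  # independence: table proportional to its margins
  o <- outer(c(2L, 3L), c(5L, 7L, 11L))
  r <- pearson_chi2(o)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("chi-squared input validation rejects degenerate tables", {
  expect_error(pearson_chi2(matrix(c(1, 0, 2, 0), 2, 2)), "margin")
  expect_error(pearson_chi2(matrix(1:6, 2, 3), yates = TRUE), "2x2")
  expect_error(contingency_table(matrix(1:2, 1, 2)), "2x2")
  expect_error(contingency_table(matrix(0L, 2, 2)), "grand total")
})

test_that("proportion intervals match the closed-form Wilson score formula", {
  wilson_oracle <- function(k, n, level = 0.95) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    p <- k / n
    c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))),
      (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)))) /
      (1 + z^2 / n)
  }
  for (kn in list(c(24, 55), c(0, 10), c(10, 10), c(166, 717))) {
    got <- suppressWarnings(proportion_ci(kn[1], kn[2], method = "wilson"))
    expect_equal(got, wilson_oracle(kn[1], kn[2]), tolerance = 1e-8)
    expect_true(got[1] >= 0 && got[2] <= 1)
    expect_true(got[1] <= kn[1] / kn[2] && kn[1] / kn[2] <= got[2])
  }
  expect_equal(suppressWarnings(proportion_ci(0, 10))[1], 0)
  expect_equal(proportion_ci(10, 10, method = "clopper_pearson")[2], 1)
  expect_error(proportion_ci(1, 0), "positive")
})

test_that("Wilson interval has nominal coverage at p = 0.3, n = 50", {
  set.seed(123)
  draws <- stats::rbinom(2000, 50, 0.3)
  covered <- vapply(draws, function(k) {
    ci <- suppressWarnings(proportion_ci(k, 50, method = "wilson"))
    ci[1] <= 0.3 && 0.3 <= ci[2]
  }, TRUE)
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("allele frequencies count alleles and respect exclusions", {
  tb <- make_table(list(A = list(L1 = c(101, 103), L2 = c(1, 2)),
                        B = list(L1 = c(101, 101), L2 = NA)),
                   panel = locus_panel(c("L1", "L2"),
                                       excluded = c(FALSE, TRUE)))
  f <- allele_frequencies(tb)
  expect_named(f, "L1")
  expect_equal(f$L1, c(`101` = 0.75, `103` = 0.25))
  expect_equal(sum(f$L1), 1)
})

test_that("estimated frequencies converge on Dirichlet-drawn truth", {
  cfg <- sim_config(seed = 31, dropout_rate = 0, null_allele_freq = 0,
                    n_loci_excluded = 0L)
  fr <- draw_allele_frequencies(cfg)
  tb <- simulate_founder_genotypes(fr$freqs, 500, panel = fr$panel, seed = 32)
  est <- allele_frequencies(tb)
  for (l in names(est)) {
    truth <- fr$freqs[[l]][names(est[[l]])]
    expect_lt(max(abs(est[[l]] - truth)), 0.05)
  }
})

test_that("F_IS hits the all-heterozygote closed form and HWE zero", {
  # every individual heterozygous (a,b): f = -1 exactly
  genos <- stats::setNames(rep(list(list(L1 = c(1, 2), L2 = c(3, 4))), 20),
                           sprintf("I%02d", 1:20))
  tb <- make_table(genos)
  fis <- fis_weir_cockerham(tb, n_bootstrap = 0)
  expect_equal(fis$f_is, -1)

  # random-mating population: f near 0, inside its own bootstrap CI
  cfg <- sim_config(seed = 41, dropout_rate = 0, null_allele_freq = 0,
                    n_loci_excluded = 0L)
  fr <- draw_allele_frequencies(cfg)
  tb2 <- simulate_founder_genotypes(fr$freqs, 500, panel = fr$panel, seed = 42)
  fis2 <- fis_weir_cockerham(tb2, n_bootstrap = 500, seed = 43)
  expect_lt(abs(fis2$f_is), 0.05)
  expect_true(fis2$ci95[1] <= 0 && 0 <= fis2$ci95[2])
})

test_that("many generations of selfing drive F_IS towards one", {
  cfg <- sim_config(seed = 51, dropout_rate = 0, null_allele_freq = 0,
                    n_loci_excluded = 0L)
  fr <- draw_allele_frequencies(cfg)
  tb <- simulate_founder_genotypes(fr$freqs, 80, panel = fr$panel, seed = 52)
  set.seed(53)
  for (gen in 1:8) {
    ids <- tb$meta$individual_id
    offs <- lapply(seq_along(ids), function(i)
      simulate_offspring_genotype(tb, ids[i], ids[i],
                                  offspring_id = sprintf("G%d_%03d", gen, i)))
    tb <- genotype_table(vapply(offs, function(o) o$meta$individual_id, ""),
                         "F2", NA_character_,
                         do.call(rbind, lapply(offs, `[[`, "a1")),
                         do.call(rbind, lapply(offs, `[[`, "a2")), tb$panel)
  }
  fis <- fis_weir_cockerham(tb, n_bootstrap = 0)
  # inbreeding recursion: F after 8 selfed generations is 1 - 2^-8 = 0.996
  expect_gt(fis$f_is, 0.9)
})

test_that("F_IS is invariant to allele relabelling", {
  set.seed(61)
  inst <- random_instance(n_candidates = 30, n_loci = 6, n_alleles = 5,
                          missing_p = 0.05)
  f0 <- fis_weir_cockerham(inst, n_bootstrap = 0)$f_is
  rl <- genotype_table(inst$meta$individual_id, inst$meta$generation,
                       inst$meta$mother_id,
                       inst$a1 * 7L + 100L, inst$a2 * 7L + 100L, inst$panel)
  expect_equal(fis_weir_cockerham(rl, n_bootstrap = 0)$f_is, f0)
})
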