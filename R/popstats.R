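#' Construct a labelled contingency table
#'
#' @param observed matrix of non-negative integer counts, at least 2x2 with
#'   a positive grand total.
#' @param row_labels,col_labels optional dimension labels.
#' @return A `contingency_table` object (the observed matrix with labels).
#' @export
contingency_table <- function(observed, row_labels = NULL, col_labels = NULL) {
  observed <- as.matrix(observed)
  if (nrow(observed) < 2L || ncol(observed) < 2L)
    stop("contingency table must be at least 2x2")
  if (any(observed < 0) || any(observed != round(observed)))
    stop("observed counts must be non-negative integers")
  if (sum(observed) <= 0) stop("contingency table has zero grand total")
  if (!is.null(row_labels)) rownames(observed) <- row_labels
  if (!is.null(col_labels)) colnames(observed) <- col_labels
  structure(observed, class = c("contingency_table", "matrix"))
}

#' @export
print.contingency_table <- function(x, ...) {
  print(matrix(as.vector(x), nrow(x), ncol(x), dimnames = dimnames(x)))
  invisible(x)
}

#' Pearson's chi-squared test on a contingency table
#'
#' Thin, validated interface over [stats::chisq.test()]:
#' `X^2 = sum((|O - E| - 0.5 * yates)^2 / E)` with expected counts from the
#' row/column margins and `(r-1)(c-1)` degrees of freedom. Yates' continuity
#' correction is permitted only for 2x2 tables (as in the test's standard
#' usage), and the correction term is capped at `|O - E|` so the statistic
#' cannot go negative.
#'
#' @param table a [contingency_table()] (or plain count matrix).
#' @param yates apply Yates' continuity correction (2x2 only; default
#'   `FALSE`).
#' @return A `chi2_result`: list with `statistic`, `df`, `p_value`,
#'   `expected` (matrix), `observed`, `yates_applied`. Zero margins and
#'   zero expected cells are errors.
#' @examples
#' pearson_chi2(contingency_table(rbind(c(4, 27), c(11, 13))), yates = TRUE)
#' @export
pearson_chi2 <- function(table, yates = FALSE) {
  if (!inherits(table, "contingency_table")) table <- contingency_table(table)
  obs <- unclass(table)
  if (any(rowSums(obs) == 0) || any(colSums(obs) == 0))
    stop("zero row or column margin")
  if (yates && !(nrow(obs) == 2L && ncol(obs) == 2L))
    stop("Yates' correction is only defined for 2x2 tables")
  ht <- suppressWarnings(stats::chisq.test(obs, correct = yates))
  if (any(ht$expected <= 0)) stop("expected cell count is zero")
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 expected = ht$expected,
                 observed = obs,
                 yates_applied = yates),
            class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("Pearson chi-squared%s: X2 = %.4g, df = %d, p = %.4g\n",
              if (x$yates_applied) " (Yates-corrected)" else "",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Confidence interval for a binomial proportion
#'
#' @param k number of successes (`0 <= k <= n`).
#' @param n number of trials (`> 0`).
#' @param level confidence level (default 0.95).
#' @param method `"wilson"` (score interval, via
#'   [stats::prop.test()] without continuity correction; default) or
#'   `"clopper_pearson"` (exact, via [stats::binom.test()]).
#' @return Numeric vector `c(lower, upper)`, a subset of `[0, 1]` containing
#'   `k/n`.
#' @export
proportion_ci <- function(k, n, level = 0.95,
                          method = c("wilson", "clopper_pearson")) {
  method <- match.arg(method)
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  # suppressed warning concerns prop.test's test statistic, which is
  # discarded; the Wilson score interval itself is closed-form
  ci <- switch(method,
               wilson = suppressWarnings(
                 stats::prop.test(k, n, conf.level = level,
                                  correct = FALSE))$conf.int,
               clopper_pearson = stats::binom.test(k, n,
                                                   conf.level = level)$conf.int)
  as.numeric(ci)
}

#' Per-locus allele frequencies
#'
#' @param table a [genotype_table()].
#' @param generation optional filter (`"P0"`, `"F1"`, `"F2"` or a vector).
#' @return Named list over active loci; each element a named numeric vector
#'   of frequencies summing to 1. Missing calls are excluded from the
#'   denominators; a locus with no calls is omitted with a warning.
#' @export
allele_frequencies <- function(table, generation = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  keep <- if (is.null(generation)) seq_len(nrow(table$meta))
          else which(table$meta$generation %in% generation)
  if (length(keep) == 0L) stop("no individuals after generation filter")
  out <- list()
  for (l in active_loci(table)) {
    alleles <- c(table$a1[keep, l], table$a2[keep, l])
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) == 0L) {
      warning("locus '", l, "' has no calls; omitted")
      next
    }
    tab <- table(alleles)
    out[[l]] <- stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  }
  out
}

# Weir & Cockerham single-population variance components for one locus.
# Returns c(b = sum_b, c = sum_c) summed over alleles; f = 1 - c/(b + c).
.wc_components <- function(a1, a2) {
  called <- !is.na(a1)
  a1 <- a1[called]; a2 <- a2[called]
  n <- length(a1)
  if (n < 2L) return(c(b = NA_real_, c = NA_real_))
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2L) return(c(b = 0, c = 0))   # monomorphic
  b_sum <- 0; c_sum <- 0
  for (a in alleles) {
    p <- (sum(a1 == a) + sum(a2 == a)) / (2 * n)
    h <- mean((a1 == a) != (a2 == a))                  # het for allele a
    b_sum <- b_sum + n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
    c_sum <- c_sum + h / 2
  }
  c(b = b_sum, c = c_sum)
}

#' Multi-locus inbreeding coefficient (Weir-Cockerham)
#'
#' Estimates the within-population inbreeding coefficient f (F_IS) with the
#' Weir-Cockerham variance-components estimator, summing the b and c
#' components over alleles and active loci:
#' `f = 1 - sum(c) / sum(b + c)`. The 95% CI comes from a percentile
#' bootstrap over loci. Also reports observed heterozygosity and Nei's
#' unbiased expected heterozygosity averaged over loci.
#'
#' @param table a [genotype_table()] with at least 2 individuals.
#' @param generation optional generation filter.
#' @param n_bootstrap bootstrap replicates over loci (default 1000; needs at
#'   least 2 polymorphic loci, otherwise the CI is `NA`).
#' @param seed RNG seed for the bootstrap.
#' @return An `inbreeding_summary`: list with `f_is`, `ci95`, `h_obs`,
#'   `h_exp`, `per_locus_f` (named vector), `n_loci_used`. A panel with no
#'   polymorphic active locus yields `f_is = NA` with a warning.
#' @export
fis_weir_cockerham <- function(table, generation = NULL, n_bootstrap = 1000L,
                               seed = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  keep <- if (is.null(generation)) seq_len(nrow(table$meta))
          else which(table$meta$generation %in% generation)
  if (length(keep) < 2L) stop("need at least 2 individuals")
  loci <- active_loci(table)
  comp <- sapply(loci, function(l)
    .wc_components(table$a1[keep, l], table$a2[keep, l]))
  usable <- !is.na(comp["b", ]) & (comp["b", ] + comp["c", ]) != 0
  if (!any(usable)) {
    warning("no polymorphic active locus: f_is undefined")
    return(structure(list(f_is = NA_real_, ci95 = c(NA_real_, NA_real_),
                          h_obs = NA_real_, h_exp = NA_real_,
                          per_locus_f = stats::setNames(numeric(0), character(0)),
                          n_loci_used = 0L),
                     class = "inbreeding_summary"))
  }
  comp <- comp[, usable, drop = FALSE]
  f_multi <- function(m) 1 - sum(m["c", ]) / sum(m["b", ] + m["c", ])
  f_is <- f_multi(comp)
  per_locus <- apply(comp, 2L, function(x) 1 - x["c"] / (x["b"] + x["c"]))
  names(per_locus) <- colnames(comp)
  ci <- c(NA_real_, NA_real_)
  if (ncol(comp) >= 2L && n_bootstrap > 0L) {
    if (!is.null(seed)) set.seed(seed)
    boots <- vapply(seq_len(n_bootstrap), function(i) {
      f_multi(comp[, sample(ncol(comp), replace = TRUE), drop = FALSE])
    }, 0)
    ci <- unname(stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  }
  h_obs <- mean(vapply(loci, function(l) {
    a1 <- table$a1[keep, l]; a2 <- table$a2[keep, l]
    ok <- !is.na(a1)
    if (!any(ok)) return(NA_real_)
    mean(a1[ok] != a2[ok])
  }, 0), na.rm = TRUE)
  h_exp <- mean(vapply(loci, function(l) {
    a <- c(table$a1[keep, l], table$a2[keep, l]); a <- a[!is.na(a)]
    if (length(a) < 2L) return(NA_real_)
    p <- table(a) / length(a)
    length(a) / (length(a) - 1) * (1 - sum(p^2))   # Nei's unbiased
  }, 0), na.rm = TRUE)
  structure(list(f_is = f_is, ci95 = ci, h_obs = h_obs, h_exp = h_exp,
                 per_locus_f = per_locus, n_loci_used = ncol(comp)),
            class = "inbreeding_summary")
}

#' @export
print.inbreeding_summary <- function(x, ...) {
  cat(sprintf("F_IS = %.4f (95%% CI: %.4f, %.4f), H_obs = %.3f, H_exp = %.3f, %d loci\n",
              x$f_is, x$ci95[1], x$ci95[2], x$h_obs, x$h_exp, x$n_loci_used))
  invisible(x)
}
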