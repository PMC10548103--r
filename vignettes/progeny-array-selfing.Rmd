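---
title: "Estimating individual selfing rates from progeny arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating individual selfing rates from progeny arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfarray)
```

## The problem

Many hermaphroditic animals, such as the freshwater snail *Radix balthica*,
can reproduce either by outcrossing or by self-fertilization. An
individual's selfing rate *s* -- the fraction of its offspring produced by
selfing -- is not observable directly: it must be inferred from the
genotypes of its offspring. `selfarray` implements the progeny-array
approach for experiments in which every potential father of a brood is
known and genotyped: each juvenile is compared to its mother at a panel of
highly polymorphic microsatellite loci, the allele the sire must have
contributed is derived locus by locus, and every candidate sire --
including the mother herself, which is the selfing hypothesis -- is scored
by the number of loci at which it could not have contributed that allele.

This document explains the model, its assumptions, the tunable parameters,
and the design choices made where the procedure was genuinely open.

## Maternal comparison and the paternal allele set

At a locus called in both juvenile and mother, with juvenile allele pair
$J = \{j_1, j_2\}$ and mother pair $M$:

* if no juvenile allele occurs in $M$, the locus is a **maternal mismatch**
  -- under error-free Mendelian inheritance this cannot happen, so it marks
  a genotyping error or a segregating null allele;
* if exactly one juvenile allele is absent from $M$, the locus is
  **outcross-consistent** and the non-maternal allele is the paternal
  allele (a singleton paternal allele set);
* if both juvenile alleles occur in $M$, either may be paternal: the
  paternal allele set is $J$ itself (for a homozygous juvenile sharing its
  allele with the mother, the set is that single allele).

At maternal-mismatch loci the paternal allele set for candidate fathers is
taken to be $J$: the non-maternal allele must be either paternal or
erroneous, so a father carrying either juvenile allele is not penalized.
The selfing hypothesis is scored by the same rule; because the mother by
definition carries no juvenile allele at such a locus, she is charged a
mismatch there automatically, which is the desired accounting (an
erroneous locus weighs against selfing but does not veto it on its own).
One uniform rule therefore covers father candidates and the selfing
hypothesis alike, and makes the whole verdict a single ranking over
hypotheses rather than a two-step procedure with an unspecified
conflict rule.

## Inclusion criteria

A juvenile enters the analysis only if (i) at least six loci are called in
both juvenile and mother, (ii) it lacks a maternal allele at no more than
two loci, and (iii) when exactly six shared loci are available, at no more
than one locus. These filters discard juveniles whose genotypes are too
incomplete or too error-laden for exclusion-based assignment to be
trustworthy; every exclusion is logged with its reason
(`too_few_shared_loci`, `too_many_maternal_mismatches`,
`too_many_mismatches_at_minimum_loci`).

## Verdicts

All hypotheses with at most `max_mismatch` incompatible loci are eligible;
the unique minimal-mismatch eligible hypothesis wins. The default
tolerance is `max_mismatch = 2`, chosen because accepted assignments in
the experiment this routine reimplements showed at most two
father-offspring mismatches; it is configurable. Ties are broken by exact
Mendelian transmission likelihood when population allele frequencies are
supplied, and otherwise yield an explicit `ambiguous` status -- never a
coin flip, so runs are deterministic and ambiguity is visible in the
output. Juveniles with no eligible hypothesis are `unassigned`.

`selfing_probability()` supplements the categorical verdict with a
posterior probability that a juvenile is selfed, comparing the selfing
likelihood $\prod_\ell P(J_\ell \mid M \times M)$ against the named
candidates and, optionally, a population random sire, under a configurable
prior (default 0.5, uninformative). Unseen alleles receive a floor
frequency of $10^{-3}$, and the same floor absorbs isolated zero-likelihood
loci under outcross hypotheses; a non-maternal allele anywhere makes the
selfing likelihood exactly zero. This estimator is the package's own
explicit definition -- external sibship-reconstruction software computes a
related quantity differently, and no attempt is made to emulate it.

## Selfing rates, thresholds and propensity classes

The family selfing rate is $s = n_\mathrm{selfed} / n_\mathrm{assigned}$,
with ambiguous, unassigned and excluded juveniles reported but never in
the denominator; a family with no assigned offspring has an *undefined*
rate, never an imputed zero. Confidence intervals use the Wilson score
interval by default (Clopper-Pearson available); because these broods are
sampled after early mortality has acted, the estimate is a *secondary*
selfing rate.

Classification follows the conventional bands with inclusive boundaries:
$s \le 0.2$ primary outcrossing, $s \ge 0.8$ primary selfing, otherwise
mixed mating. Individual propensity combines success at selfing in
isolation with the post-isolation rate: outcrosser (never selfed),
plastic switcher (selfed in isolation, $s = 0$ after), plastic mixer
(selfed in isolation, $0 < s \le 0.2$ after), selfer ($s \ge 0.8$). Two
extra categories close the map: `intermediate_unclassified`
($0.2 < s < 0.8$ after selfing in isolation) and `latent_anomaly` (selfing
post-isolation without having selfed in isolation); both are flagged so
that the four-category scheme is recovered exactly when they are empty.

The *apparent* classification needs no genotypes: it uses reproduction in
each phase and whether the individual ever copulated in the female role.
One pattern is not covered by the source scheme -- reproduction only in
isolation combined with a female copulation -- and is classed
`apparent_selfer` here, since all of that individual's realized
reproduction was autonomous.

## Contingency statistics

Treatment effects are tested with Pearson's chi-squared on five tables
(multiple paternity, families with non-zero selfing, pooled offspring
counts, apparent propensity, genotype-based propensity), with fixed row
order (once-paired, repeatedly paired) and documented column orders.
Yates' continuity correction is applied to the multiple-paternity 2x2
table only, matching how the original analyses mixed corrected and
uncorrected tests; the flag is exposed. The inbreeding coefficient uses
the Weir-Cockerham single-population variance-components estimator with a
percentile bootstrap over loci for its confidence interval.

## The simulator

`sim_config()` / `simulate_experiment()` encode the generative model of
the experiment: founder mothers in Hardy-Weinberg equilibrium; F1 broods
outcrossed by unobserved allosperm sires (so F1 fathers are absent from
the data, as in a field cohort); half the F1 once-paired, half with six
sequential partners drawn from the cohort itself; latent propensity
classes with probabilities 0.306 / 0.2754 / 0.0956 / 0.323
(outcrosser / switcher / mixer / selfer -- the apparent-propensity
proportions of the original cohort, with the plastic block split by the
genotyped subsample's switcher:mixer ratio); true post-isolation selfing
rates of 0 / 0 / 0.1 / 0.95, package choices inside the class bounds since
no per-class rates are published; inbreeding depression as independent
Bernoulli thinning at two stages (development 0.79 outcrossed vs 0.72
selfed; juvenile death 0.534 vs 0.695), without any explicit genetic
load model; progeny arrays of 3-22 genotyped juveniles (target mean 16,
s.d. 2) in 56 genotyped families; candidate windows of 3-5 partners for
repeatedly paired broods; allelic dropout at 5% per call; and one excluded
locus segregating a null allele (frequency 0.15) whose carriers appear
homozygous -- the realistic reason such a locus is excluded. One global
seed expands into named substreams (frequencies, pedigree, thinning,
noise) so stages can be re-run independently and byte-identically.

What the simulator does *not* emulate: sibling pairings (optional in
principle, absent by default), allosperm storage dynamics, body-size
growth, genotyping artefacts beyond dropout and one null allele, and any
correlation between fecundity and genotype. Passing recovery tests on
simulated data therefore shows that the *inference machinery* is correct
under Mendelian inheritance with realistic noise -- not that every
property of real laboratory data is captured.

## Validation strategy and problem sizes

* **Oracle equivalence**: the full verdict rule is re-implemented from
  first principles in the test helpers and compared on hundreds of random
  instances (up to 10 candidates, 10 loci, 10% missingness).
* **Parameter recovery**: noise-free grids at
  $s \in \{0, 0.1, 0.5, 0.9, 1\}$ with 30 families of 16 juveniles
  (9 loci, 10 equifrequent alleles); the pooled estimate must fall within
  three binomial standard errors of truth, and exactly at the degenerate
  ends.
* **Classification recovery**: on a noise-free simulated cohort at the
  default scale, families with at least 12 assigned offspring must have
  their propensity class recovered for at least 99% of individuals.
  Recovery is judged against the class implied by the realized truth
  labels (the true selfed fraction of the genotyped brood), not the latent
  class: a plastic mixer with true $s = 0.1$ has an appreciable chance of
  a brood of 16 containing no selfed juvenile at all, so latent-class
  recovery is limited by sampling, not by inference, and would not measure
  what the check is for.
* **Statistical invariants**: the chi-squared wrapper is checked against
  the closed-form statistic and for permutation invariance; the Wilson
  interval for 93-97% empirical coverage at $p = 0.3$, $n = 50$; simulated
  founders for Hardy-Weinberg heterozygosity and $F_\mathrm{IS} \approx 0$;
  eight generations of enforced selfing for $F_\mathrm{IS} > 0.9$
  (the inbreeding recursion approaches $1 - 2^{-t}$).

These sizes keep the whole suite under a minute while leaving the checks
statistically sharp.

## Numerical and degenerate-input choices

Allele codes are opaque positive integers; only identity is ever tested.
A locus call is complete or missing -- half-calls are rejected at input
rather than coerced, because every criterion counts loci, not alleles.
Allele pairs are stored canonically sorted, so `(a, b)` and `(b, a)` are
the same datum. Excluding every locus, an empty candidate list, a
zero-margin contingency table, and a monomorphic-only panel are all
errors, not silent degenerate results. Probabilities reported by
`selfing_probability()` error out (rather than returning `NaN`) when every
hypothesis has likelihood zero, which signals a data inconsistency the
caller must see.

## Limitations

Exclusion-based assignment assumes the true sire is among the candidates;
it does not reconstruct pedigrees, estimate genotyping-error rates, or
infer parent pairs. The selfing posterior is a package-defined
likelihood ratio, not a reproduction of any external program's output.
Estimates are secondary selfing rates: differential early mortality of
selfed offspring biases them downward relative to primary rates, which is
a property of the design, not of the estimator.
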