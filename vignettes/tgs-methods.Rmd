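---
title: "Total Genetic Score profiling: models, conventions and limitations"
author: "tgscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Total Genetic Score profiling: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgscore)
```

## The scoring model

The package works with three biallelic performance-enhancing
polymorphisms, each with a designated power- and endurance-predisposing
allele: ACE I/D (D power, I endurance), PPARα C/G (C power, G
endurance) and CKM A/G (G power, A aerobic capacity). The additive
power-oriented scheme scores each genotype 2 (power homozygote), 1
(heterozygote) or 0 (endurance homozygote); the genotype score GS is
the sum over the three loci and the Total Genetic Score rescales it to
the centesimal scale, TGS = GS × 100/6. The model's assumptions are
strong and worth keeping in view: loci contribute additively and with
equal weight, heterozygotes are exactly intermediate, and the three
markers stand in for a far more polygenic architecture. The package
treats the score as a descriptive summary, not a predictor.

Schemes are pluggable objects (`ScoringScheme`) validated to keep every
score in {0, 1, 2} with the heterozygote strictly intermediate;
`reverseScheme()` yields the endurance-oriented mirror, under which
GS ↦ 6 − GS and TGS ↦ 100 − TGS for every profile (a property the test
suite checks over all 27 profiles).

### Orientation bands

A TGS is classified aerobic-, mixed- or power-oriented by two bounds
`(low, high)`: below `low` aerobic, between the bounds inclusive mixed,
above `high` power. No established cut-offs exist for this scale, so
the defaults are the package's own convention: `c(33.33, 66.67)`,
chosen so the bands are symmetric tertiles of the attainable TGS
lattice and split the GS range as 0–1 / 2–4 / 5–6. Classification
happens after 2-decimal rounding, so GS = 2 (TGS 33.33) and GS = 4
(TGS 66.67) both land in the mixed band rather than being pushed out by
floating-point representation. The bounds are configurable everywhere
they are used (`classifyTgsOrientation()`, the `report`/`score`
commands' `--thresholds`, the config file's `threshold_low`/`_high`).
Published TGS category summaries of the reference cohort do not state
their bounds (a reported 47% modal share is not even an attainable
fraction of 24), so the package makes no attempt to reproduce that
figure; with the default bands the modal orientation of cohorts drawn
from the reference frequencies is mixed for most seeds, which the test
suite asserts as a simulation property rather than an exact claim.

### Rounding

All reported percentages round half-up to two decimals
(`roundHalfUp()`), matching how the reference frequencies are printed
(66.67, 77.08); base R's round-half-to-even would print 16.665 as
16.66. Allele percentage pairs are additionally reconciled by largest
remainder so they sum to exactly 100.00; genotype percentages are
reported raw (their sum can differ from 100.00 by a cent, which is how
such tables are conventionally printed) and counts are never adjusted
to force a sum.

## RFLP genotype calling

The digestion key is fixed by the assay: ACE needs no digestion (the
insertion allele amplicon is 597 bp, the deletion allele 319 bp), PPARα
is cut by TaqI (C allele 216 + 50 bp, G allele uncut 266 bp) and CKM by
NcoI (G allele uncut 359 bp, A allele 206 + 153 bp); heterozygotes show
the union of the homozygote patterns, an invariant enforced by the
`DigestKey` validity method.

`callGenotype()` inverts the key under a sizing tolerance: a candidate
matches when observed and expected band sets have equal size and pair
off bijectively within ± `toleranceBp`. The default tolerance is 5 bp —
agarose gel sizing in this fragment range is rarely better — and is
configurable per call. Observed lengths are treated as a set
(duplicates collapse); partial digests are not modelled. Failure is
explicit and classed: `tgs_no_call` carries the nearest candidate by a
symmetric nearest-band distance, `tgs_ambiguous_call` lists all
matching candidates (reachable only at tolerances comparable to the
band separations).

Two hazards are deliberate, documented behaviour rather than errors.
First, a PPARα CG observation whose 266 bp band is absent is
*indistinguishable* from CC and is called CC — the uncut band is the
only discriminating evidence. Second, the 50 bp TaqI product can run
off a gel; `allowMissingSmallest = TRUE` permits a call when only the
smallest expected band is missing and the call stays unambiguous, and
batch output marks such rows `ok_missing_smallest`. Both behaviours are
asserted in the tests.

`simulateFragments()` perturbs expected lengths with seeded Gaussian
noise truncated below at 1 bp. Because Gaussian noise is unbounded, a
band occasionally drifts beyond any finite tolerance: at noise SD 2 bp
and tolerance 5 bp this happens to about 1.2% of bands and produces a
no-call. The round-trip guarantee is therefore stated in two parts: the
caller never returns a *wrong* genotype for simulated observations
(zero wrong calls over 1080 seeded trials in the test suite), and
no-calls stay rare at 2.5σ tolerance and vanish at 5σ.

## Cohort statistics

`genotypeFrequencies()` reports counts and percentages for all three
genotypes at a locus, keeping zero counts (the reference cohort has no
PPARα CC). Missing genotypes are an error that names the athletes;
`dropMissing = TRUE` (CLI `--drop-missing`) instead removes them from
that locus's denominator and logs the exclusion, so silent data loss
cannot happen. Allele counts are 2 × homozygotes + heterozygotes out of
2n. Training volumes are summarised as mean and *sample* SD (n − 1
denominator) to one decimal; the convention is the package's choice, as
descriptive tables rarely state which SD they use.

`countsFromPercentages()` inverts printed 2-decimal percentages at a
known n: counts are `round(pct · n/100)` and are accepted only if they
sum to n and each reproduces its percentage within half a count
(|count·100/n − pct| ≤ 50/n). At n = 24 this recovers the reference
cohort's integer counts uniquely (ACE II 2 / ID 16 / DD 6, PPARα CC 0 /
CG 11 / GG 13, CKM AA 15 / AG 7 / GG 2), and the suite checks the map
is a right inverse of the frequency computation for random count
vectors up to n = 1000. Inconsistent percentages (e.g. 50/50 at n = 3)
raise a reconciliation error reporting the residuals.

### Exact Hardy–Weinberg test

`hweExactTest()` is the conditional exact test for a biallelic marker:
given the observed allele counts, the probability of a heterozygote
count under Hardy–Weinberg proportions is

$$P(n_{AB} \mid n, n_A) = \frac{n!\,n_A!\,n_B!\,2^{n_{AB}}}
  {n_{AA}!\,n_{AB}!\,n_{BB}!\,(2n)!},$$

and the two-sided p-value sums the probabilities of all compatible
heterozygote counts no more probable than the observed one. Ties are
resolved with a 1e-12 relative slack so that configurations equal in
exact arithmetic are included regardless of floating-point route; log
factorials keep the computation stable to n in the thousands. The test
suite verifies agreement with an independent enumeration oracle to
1e-10 over every count vector with n ≤ 50. Like all exact tests it is
conservative: at n = 24 its analytic type-I rate at α = 0.05 is ≈ 0.039
at allele frequency 0.5 (the calibration point used in the tests,
where the conditional distribution is least discrete) and drops to
≈ 0.017 at frequencies near 0.77 — small-cohort non-significance is
weak evidence of equilibrium. The reference study performed no such
test; it is provided because any frequency report invites it.

Shapiro–Wilk normality checks and post hoc power calculations are out
of scope: they are off-the-shelf statistics with no bespoke content
here, and the reference analysis's power figure (0.72) does not map to
a determinable test configuration.

## The synthetic-cohort generator

`pfCohortSpec()` encodes the statistical structure of the reference
24-athlete elite point-fighting cohort: 12 women and 12 men; genotype
probabilities equal to the reference frequencies (ACE II .0833 /
ID .6667 / DD .25; PPARα CC 0 / CG .4583 / GG .5417; CKM AA .625 /
AG .2917 / GG .0833); age 22.1 ± 5.8 y, body mass 66.1 ± 15.4 kg,
height 173.0 ± 9.5 cm; weekly training minutes technique 367.3 ± 153.1,
strength 188.5 ± 122.3, aerobic 134.8 ± 95.5. Only marginal moments are
published, so variables are generated independently — the generator
reproduces marginals, not any genotype–training or anthropometric
covariance real data may carry. Passing tests on synthetic cohorts
therefore demonstrate correctness of the pipeline's computations, not
fidelity to the joint structure of real athletes.

Continuous variables are truncated normal, sampled by rejection (exact
and cheap at these scales). Truncation bounds are plausible
elite-athlete ranges chosen once: minutes ≥ 0, age ≥ 14 y, height
140–210 cm, mass 40–120 kg. Genotypes may alternatively be drawn from
Hardy–Weinberg proportions p²/2pq/q² given one allele frequency
(`powerAlleleFreq` mode, `simulateFromAlleleFreqs()`), which is how the
HWE test's size is calibrated under the null.

Determinism is a contract: one integer seed fully determines the
cohort, byte-for-byte through CSV output, and genotypes and continuous
variables sit on independent derived sub-streams so adding a variable
cannot perturb the genotype draws.

## Problem sizes in the test suite

The suite exercises exhaustive enumerations where they are small (all
27 profiles, all 9 digestion patterns, every HWE count vector with
n ≤ 50) and seeded simulation elsewhere: 1080 round-trip gel calls,
1000 null cohorts of 24 for the HWE size check, and one cohort of
10,000 for frequency recovery within three binomial standard errors.
These sizes keep each property statistically sharp while the whole
suite runs in seconds.

## Known limitations

* Three loci with equal additive weights; no interaction, no weighting
  by effect size, no additional markers (ACTN3, MSTN, COL5A1 are out of
  scope).
* Orientation band bounds are a convention; conclusions that depend on
  the banding should report sensitivity to it.
* The RFLP caller models clean band patterns with symmetric Gaussian
  sizing error; faint bands, partial digests and gel-smile artefacts
  are not modelled.
* The generator reproduces marginal structure only, and the exact HWE
  test is conservative at small n and extreme allele frequencies.
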