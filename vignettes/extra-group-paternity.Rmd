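---
title: "Quantifying extra-group paternity from census and microsatellite data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying extra-group paternity from census and microsatellite data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In group-living, seasonally breeding primates such as rhesus macaques, some
infants are sired by males who were not residents of the mother's group
around conception — extra-group paternity (EGP). Quantifying EGP and asking
which group-level conditions drive it requires chaining several inferences,
each with its own failure modes: reconstructing male residence from census
sightings, assigning paternity from microsatellite genotypes, dating
conception from birth dates, and finally fitting a count model over
group-season cells. `egpat` implements this chain as separable, individually
tested stages, plus a synthetic-population generator with a recorded truth
log so every stage — and the whole chain — can be validated without field
data.

```{r setup}
library(egpat)
```

## Male group membership

Residence is reconstructed from sightings under a confirmation rule: a male
seen in a new group is only assigned to it once his sighted group has
remained constant for 30 consecutive days; if he was seen prospecting,
in a bachelor group, or solitary within those first 30 days, confirmation
requires 60 days. Once confirmed, the immigration date is backdated to the
first sighting in the new group, the previous interval ends the day before,
and death closes the final interval. A male belongs to at most one group per
day; females are philopatric and hold a lifelong interval in their natal
group.

Two numerical choices deserve note. "Constant for 30 days" is only
verifiable up to census cadence, so the builder additionally requires that
no gap between sightings inside a confirmation window exceed
`max_gap_days` (default 7); the rule presumes a near-daily census and the
generator respects that. Tenure is an inclusive count (the first day of
membership is tenure 1) so that a male lost on the day he was last seen
still contributes weight to the instability numerator.

## Paternity by exclusion

Candidate sires for an infant are the genotyped males strictly older than
1250 days and present on the island at the conception reference date, 200
days before birth. For each candidate the package counts exclusion loci
against the mother–infant dyad: a locus mismatches when no assignment of the
infant's two alleles (one maternal, one paternal) is Mendelian-consistent.
Maternity is confirmed first; loci where the infant shares no allele with
the mother are attributed to maternity and skipped in sire counts. The
assignment rules are:

* **strict** — assigned sire has 0 mismatches, every other candidate is
  excluded by ≥ 2 loci;
* **relaxed** — sire 0 mismatches, some other candidate excluded by exactly
  1 locus, none unexcluded;
* **one-mismatch** — sire has exactly 1 mismatch, all others ≥ 2.

Ties are never broken: two candidates with zero mismatches mean no
assignment. Comparisons use jointly typed loci only; candidates sharing
fewer than `min_joint_loci = 13` typed loci with the trio (half the typical
panel) are set aside as unevaluable rather than spuriously "unexcluded".
Likelihood-based confirmation of the kind produced by dedicated parentage
software is out of scope here; the exclusion rules stand alone.

## Conception windows and EGP classification

Gestation is 166.5 ± 7.4 days (mean ± SD). The conception window collects
the integer day-offsets before birth between `ceiling(166.5 - 7.4) = 160`
and `ceiling(166.5 + 7.4) = 174` — 15 consecutive days. The real ±1 SD span
is 159.1–173.9 days; among its integer discretizations only a 15-day bracket
matches the published window length, and `[160, 174]` is the ceiling-based
one. The chosen offsets are recorded in the window's `offsets` attribute so
downstream consumers can see the discretization. On simulated births with
Normal(166.5, 7.4) gestation the true conception date falls inside this
window for ≈ 69% of infants (the ±1 SD mass), which the test suite checks.

To avoid mistaking a migration for an extra-group mating, residence is
evaluated over the window plus a 30-day buffer on each side — 75 days in
total. An offspring is within-group if its sire was a member of the natal
group on *any* of those 75 days (including sires who immigrated on the last
day), extra-group otherwise. Offspring without an assigned sire are logged
and excluded, never guessed.

## Group-season covariates

**Breeding group size and sex ratio.** Size counts members strictly older
than 1250 days at mating-season onset. The sex ratio (females/males)
averages daily mature counts over the whole season by default; the source
convention says only "average", so a single-census-at-onset variant is
available via `method = "onset"`.

**Female synchrony.** For the live-birth mothers of a group-season, the
number of unique dates on which at least one female was in estrus is the
cardinality of the union of their 15-day conception windows, and synchrony
is 15 divided by that number: 1 when all windows coincide, 15/75 = 0.2 for
five disjoint windows. Only live births enter, as miscarriages are not
observed; with ~86% of females giving birth per year this remains a close
proxy.

**Group instability.** Daily membership loss is the summed tenure of mature
males present yesterday but gone today, divided by the summed tenure of all
mature males yesterday — losing a long-term resident destabilizes more than
losing a newcomer. Daily gain is the count of new mature males divided by
the current day's total mature group size. The loss denominator uses
yesterday's male tenures while the gain denominator uses today's total group
size; the asymmetry follows the verbal definition of the index. Each series
is averaged over the season with weights `1/(t+1)` for day `t` after onset
(the "+1" is the natural inverse-lag choice that keeps the onset-day weight
finite), normalized by the weight sum, and the index is loss + gain. Whether
the gain denominator should count immatures is not specified at the source;
mature members are used, configurably.

**Home-range overlap.** Each group's seasonal range is the minimum convex
polygon of its daily location records, rasterized on a shared grid (default
cell 25 m — a usable resolution for a ~15 ha island — anchored at a fixed
origin recorded in the output; cells belong to a range when their center
lies inside or on the hull). A group's male density is breeding males per
occupied cell, and the overlap index of a focal group sums the other
groups' densities over the focal cells. The index is additive over other
groups and intentionally asymmetric between pairs. A zero overlap would
break the downstream log offset, so the pipeline errors unless a positive
floor is requested explicitly.

## The Poisson mixed model

One row per group-season (54 in the full 6 × 9 design): the response is the
EGP count, predictors are the z-scored sex ratio, group size, synchrony and
instability plus the sex ratio × group size interaction, and two log
offsets — offspring born and home-range overlap — enter with coefficients
fixed at 1, because EGP counts scale trivially with both. Random intercepts
for group and cohort are always included; by default each main effect also
gets an uncorrelated random slope within each random effect (10 variance
components). Uncorrelated slopes are the only structure that keeps the model
estimable at n = 54, and the no-slope variant is one flag away
(`include_random_slopes = FALSE`). Estimation is maximum likelihood with the
Laplace approximation via `lme4::glmer` (bobyqa), so likelihood-ratio tests
on fixed effects are valid; the null model for the global LRT keeps random
effects, slopes and offsets. Per-term tests drop the interaction from the
full model and each main effect from the interaction-free reduced model
(1 df each), mirroring how interaction models are conventionally reported.
Convergence failures and singular fits are flagged on the returned object,
never silently dropped.

Diagnostics follow the standard recipe: dispersion is the Pearson
chi-square over residual degrees of freedom; VIFs use the closed form
`1/(1 - R²)` among the four predictors (fixed-effects-only,
interaction-free), cross-checked in the tests against `car::vif`;
`stability_check()` refits leaving out each group and cohort in turn.

```{r, eval = FALSE}
sim <- simulate_egp_study(sim_config(seed = 42))
res <- run_egp_pipeline(sim)
res$fit
res$drop1
egp_confusion(res, sim$truth)
```

## What the generator emulates — and what it does not

`sim_config()` defaults encode the study conditions: 6 groups × 9 cohorts,
lognormal breeding group sizes with mean 82.2 and SD 43.7, drawn sex ratios
1.615 ± 0.318, 86% of mature females conceiving per season at a uniform date
in a 120-day season, gestation Normal(166.5, 7.4) rounded to days, a 28-locus
panel with ~8 alleles per locus (flat-Dirichlet frequencies) and 1.5%
per-locus dropout giving ~27.6 typed loci per individual, and near-daily
(3-day) census sightings consistent with the true membership history.
Mating seasons run mid-August to mid-December so that each cohort's births
fall in one calendar year, which is how the pipeline assigns offspring to
cohorts.

Males transfer between ring-adjacent groups at 0.10 transfers per male-year
and adults die at 0.02 per year; a back-of-envelope expectation for the
instability index under these rates (one to two weighted membership events
per group-season) lands at a few 10⁻⁴, matching the published scale of the
index, and realized means over seeds sit at ~5 × 10⁻⁴ for instability and
~0.11 for synchrony. Surviving juveniles leave the population at 1000 days
of age — emulating the island's management removals — which keeps the
breeding pool to the founder cohort and group sizes stationary across nine
cohorts. Two emergent caveats: symmetric ring migration slowly equalizes
male counts across groups, so realized sex ratios average ~1.47, slightly
below the drawn 1.615; and 14% infant mortality plus removals reproduce
realistic cohort-filter attrition.

Each offspring is extra-group with probability
`plogis(γ₀ + γ₁ z(sex ratio) + γ₂ z(size) + γ₃ z(synchrony) +
γ₄ z(instability) + γ₅ z(sex ratio)·z(size))` computed over the simulated
group-seasons; extra-group sires are drawn from a neighboring group's
residents at conception, within-group sires from the natal group. The
default slopes take the direction and magnitude of the published estimates
and `γ₀ = logit(0.16)` matches the published overall EGP fraction; with all
slopes zero the realized fraction is ~16%, which the acceptance suite
verifies over 20 seeds. A constant covariate (e.g. zero instability when
migration is disabled) is given a zero z-score and thus no effect. Note that
home-range overlap does not enter the generative EGP model: the pipeline's
overlap offset is therefore a control variable that is deliberately
uninformative in the synthetic world, and fitted dispersions on synthetic
data can exceed 1 for that reason.

What passing tests show: the stage logic is faithful (oracle equivalence at
1e-12), the chain recovers planted truth (≥ 99% sires, ≥ 95% EGP flags,
≥ 90% effect signs, 93–97% interval coverage, nominal LRT size). What they
do not show: robustness to census gaps and observation error, genotype
scoring artifacts beyond iid per-allele error, non-ring group geometries,
kin-structured mate choice, or female dispersal. Real data violate the
generator's independence assumptions in all of these ways.

## Simulation design and problem sizes

The statistical validation studies run at the table level rather than
through the full individual-based chain, under the random-intercept
configuration (the published no-random-slope variant): sign recovery uses
100 replicates of a 12 × 18 design with a planted synchrony effect of −0.4;
interval coverage pools the four main effects over 600 replicates of the
6 × 9 design; LRT size uses 200 null replicates. Sire and EGP-flag recovery
run through the full pipeline on an error-free two-cohort pedigree of ~450
offspring, and generator calibration uses 20 full-population seeds. These
sizes keep the whole validation single-threaded at desk scale while leaving
Monte-Carlo error well inside each acceptance band.

## Known limitations

* Exclusion-based assignment has no confidence statement; with degraded
  panels it abstains (ties, unevaluable candidates) rather than quantifying
  uncertainty.
* The conception-window discretization is one of several defensible
  brackets; it is recorded in output metadata rather than assumed canonical.
* The instability index depends on census cadence through the membership
  builder; cadences sparser than the 7-day gap tolerance will silently
  shorten tenures.
* At n = 54 the full random-slope model is frequently singular — the
  honest consequence of a maximal structure on a small design; fits are
  flagged, and the no-slope variant is provided for exactly this reason.
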