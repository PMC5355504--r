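# egpat — extra-group paternity analysis for seasonally breeding primate groups

In group-living primates with female philopatry and male dispersal, some
infants are sired by males who were not residents of the mother's group
around conception (**extra-group paternity**, EGP). `egpat` implements the
full inference chain needed to quantify EGP from long-term census and
microsatellite data and to model its group-level drivers:

1. **Membership** — male group-residence intervals reconstructed from
   sightings under 30/60-day confirmation rules (immigration backdated to the
   first sighting in the new group; one group per male per day; females
   philopatric for life).
2. **Paternity** — Mendelian exclusion over a microsatellite panel:
   candidates are genotyped males older than 1250 days present ≥ 200 days
   before birth; assignments are classified *strict* (sire 0 mismatches, all
   others excluded by ≥ 2 loci), *relaxed* (another candidate excluded by
   exactly 1 locus) or *one-mismatch*; ties are never assigned.
3. **EGP classification** — the conception window is birth − (166.5 ± 7.4)
   days, i.e. day-offsets 160–174 (15 days); residence is evaluated over
   that window ± 30 days (75 days), and an offspring is within-group iff its
   sire was a member of the natal group on ≥ 1 of those days.
4. **Group-season covariates** — breeding group size and sex ratio (mature
   members, strict > 1250 days), female synchrony
   `S = 15 / |union of the mothers' conception windows|`, tenure-weighted
   instability (daily loss/gain proportions averaged with weights `1/(t+1)`
   from season onset), and minimum-convex-polygon home-range overlap (summed
   other-group male density per grid cell over the focal range).
5. **Model** — a Poisson GLMM for per-group-season EGP counts:

   `EGP_count ~ z(sex ratio) * z(group size) + z(synchrony) + z(instability)
   + offset(log offspring born) + offset(log overlap)
   + (1 + slopes | group) + (1 + slopes | cohort)`

   fitted by ML/Laplace via `lme4::glmer`, with full-vs-null and per-term
   likelihood-ratio tests, dispersion, VIFs, and leave-one-group/cohort-out
   stability checks. Reduced (no interaction) and no-random-slope variants
   are flags.

A calibrated individual-based generator (`simulate_egp_study()`) produces
census, sightings, seasons, locations, genotypes and births with a recorded
truth log (true membership, sires, conception dates, EGP flags), so the
whole chain is testable end to end.

## Worked example

```r
library(egpat)
sim <- simulate_egp_study(sim_config(n_cohorts = 3, seed = 42))
res <- run_egp_pipeline(sim, include_random_slopes = FALSE)
egp_confusion(res, sim$truth)   # audit against the recorded truth
```

```
sire recovery: 1.000  egp accuracy: 0.998  conception coverage: 0.697
```

Every retained offspring's sire was recovered (all via the strict rule at
zero genotyping error), 99.8% of EGP flags match the truth, and the true
conception date falls inside the 15-day window for 69.7% of births — the
±1 SD mass of the gestation distribution, as expected.

```r
tail(res$egp_table, 1)   # overall EGP among classified offspring
```

```
   group cohort n_egp n_within      pct
28 total     NA    96      380 20.16807
```

```r
res$fit
```

```
Poisson GLMM for EGP counts (full model)
random slopes: FALSE | converged: TRUE | singular: TRUE | dispersion: 2.362
                      term estimate    se       z
1              (Intercept)  -5.6239 0.186 -30.241
2              z_sex_ratio   0.0973 0.253   0.384
3             z_group_size  -0.1144 0.190  -0.602
4              z_synchrony  -0.2116 0.205  -1.031
5            z_instability  -0.4707 0.213  -2.211
6 z_sex_ratio:z_group_size   0.4560 0.276   1.650
```

```r
res$lrt      # full vs null: chi2 = 17.11, df = 5, p = 0.0043
res$drop1    # interaction tested in the full model, mains in the reduced one
round(res$vif, 2)
#>   z_sex_ratio  z_group_size   z_synchrony z_instability
#>          1.29          2.34          2.12          1.04
```

The fixed-effect estimates are on the log scale per SD of each predictor;
the offsets make the intercept an EGP rate per offspring-overlap unit. On
this three-cohort run the model flags instability (negative) and the global
LRT rejects the null; a single short run is illustrative only — the test
suite does the replicated versions.

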