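## Individual-based synthetic population with recorded truth.
##
## The generator emulates the study system the pipeline targets: a closed
## island population of six social groups followed over nine annual birth
## cohorts, with breeding group sizes around 82 +/- 44, female-biased sex
## ratios around 1.6, ~86% of mature females giving birth per year, gestation
## 166.5 +/- 7.4 days, male dispersal between ring-adjacent groups, a
## microsatellite panel averaging ~27.6 typed loci per individual, and an
## extra-group paternity probability that is log-linear in the z-scored
## group-season covariates. Every emitted table is consistent with a truth
## log (membership history, parentage, conception dates, EGP flags) by
## construction. Management removal of juveniles keeps the breeding pool to
## the founder cohort, so group composition stays near its target over the
## study.

#' Configuration for the synthetic population generator
#'
#' Defaults are the study conditions the pipeline assumes; see the package
#' vignette for the calibration of each value.
#'
#' @param n_groups,n_cohorts Social groups and annual birth cohorts (6 x 9).
#' @param first_cohort_year First birth-cohort calendar year. Default 2004.
#' @param group_size_mean,group_size_sd Target breeding group size
#'   distribution (lognormal; 82.2 +/- 43.7).
#' @param min_group_size Lower clamp on drawn group sizes. Default 20.
#' @param sex_ratio_mean,sex_ratio_sd Breeding sex ratio (females/males)
#'   distribution (1.615 +/- 0.318).
#' @param female_birth_prob Probability a mature female conceives in a given
#'   season. Default 0.86.
#' @param gestation_mean,gestation_sd Gestation length in days
#'   (166.5 +/- 7.4).
#' @param season_length_days Mating-season length. Default 120.
#' @param male_migration_rate Per-male annual rate of group transfer
#'   (natal dispersal plus secondary migration). Default 0.10.
#' @param adult_mortality Annual adult death hazard. Default 0.02.
#' @param infant_mortality Probability an infant dies before age 1.
#'   Default 0.14.
#' @param removed_infant_prob Probability an infant is removed (management)
#'   with its mother before age 1. Default 0.02.
#' @param juvenile_removal_age_days Age at which surviving juveniles leave
#'   the island population (management removal). Default 1000.
#' @param ungenotyped_prob Probability an infant has no genetic sample.
#'   Default 0.005.
#' @param n_loci,n_alleles Microsatellite panel size and alleles per locus
#'   (28 loci, ~8 alleles).
#' @param allele_freqs `"dirichlet"` (flat Dirichlet draw per locus) or
#'   `"uniform"`.
#' @param locus_missing_prob Per-individual per-locus dropout, tuned so the
#'   typed panel averages ~27.6 loci. Default 0.015.
#' @param genotyping_error Per-allele mistyping rate. Default 0.
#' @param egp_gamma Logit-scale coefficients of the extra-group paternity
#'   model: `intercept, sex_ratio, group_size, synchrony, instability,
#'   interaction` applied to z-scored group-season covariates.
#' @param census_interval_days Days between routine sightings of a male.
#'   Default 3 (near-daily census).
#' @param emit_sightings Emit the sightings table (disable when only births
#'   and covariates are needed). Default `TRUE`.
#' @param hr_radius Radius of the ring of group home-range centers (m).
#'   Default 130.
#' @param hr_spread SD of daily location scatter around the center (m).
#'   Default 60.
#' @param hr_points_per_season Daily location records per group-season.
#'   Default 120.
#' @param seed Root seed; sub-generators use fixed offsets from it so stages
#'   can be regenerated independently.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_groups = 6L, n_cohorts = 9L, first_cohort_year = 2004L,
                       group_size_mean = 82.2, group_size_sd = 43.7,
                       min_group_size = 20L,
                       sex_ratio_mean = 1.615, sex_ratio_sd = 0.318,
                       female_birth_prob = 0.86,
                       gestation_mean = 166.5, gestation_sd = 7.4,
                       season_length_days = 120L,
                       male_migration_rate = 0.10,
                       adult_mortality = 0.02,
                       infant_mortality = 0.14,
                       removed_infant_prob = 0.02,
                       juvenile_removal_age_days = 1000L,
                       ungenotyped_prob = 0.005,
                       n_loci = 28L, n_alleles = 8L,
                       allele_freqs = c("dirichlet", "uniform"),
                       locus_missing_prob = 0.015,
                       genotyping_error = 0,
                       egp_gamma = c(intercept = stats::qlogis(0.16),
                                     sex_ratio = 0.39, group_size = -0.36,
                                     synchrony = -0.37, instability = -0.26,
                                     interaction = 0.31),
                       census_interval_days = 3L,
                       emit_sightings = TRUE,
                       hr_radius = 130, hr_spread = 60,
                       hr_points_per_season = 120L,
                       seed = 1L) {
  allele_freqs <- match.arg(allele_freqs)
  rates <- c(female_birth_prob, infant_mortality, removed_infant_prob,
             ungenotyped_prob, locus_missing_prob, genotyping_error)
  stopifnot(all(rates >= 0 & rates <= 1), n_groups >= 2, n_cohorts >= 1,
            group_size_mean > 0, season_length_days > 30, seed == as.integer(seed))
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

.season_calendar <- function(config) {
  yrs <- seq(config$first_cohort_year, length.out = config$n_cohorts)
  onset <- as.Date(sprintf("%d-08-15", yrs - 1L))
  data.frame(cohort_year = yrs, mating_onset = onset,
             mating_end = onset + config$season_length_days - 1L)
}

.group_names <- function(config) LETTERS[seq_len(config$n_groups)]

#' Simulate the population: census, sightings, seasons, locations
#'
#' Founder adults are placed in groups with lognormal breeding sizes and
#' female-biased sex ratios; males transfer between ring-adjacent groups at
#' the configured rate, each transfer separated by at least 90 days so that
#' residence is verifiable under the 30/60-day rules; deaths close
#' membership. Routine sightings are emitted on a near-daily census grid
#' consistent with the true membership history.
#'
#' @param config A [sim_config()] object.
#' @return A list: `census` (founders), `sightings`, `seasons`, `locations`,
#'   `truth_membership` (true intervals, including female philopatry rows),
#'   and bookkeeping used by [simulate_matings()].
#' @export
simulate_population <- function(config = sim_config()) {
  set.seed(config$seed + 1L)
  cal <- .season_calendar(config)
  groups <- .group_names(config)
  t0 <- cal$mating_onset[1] - 400L
  t_end <- cal$mating_end[nrow(cal)] + 60L
  cv <- config$group_size_sd / config$group_size_mean
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(config$group_size_mean) - sdlog^2 / 2

  census <- list(); truth <- list(); ctr <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    size <- round(min(max(stats::rlnorm(1, meanlog, sdlog), config$min_group_size), 250))
    ratio <- min(max(stats::rnorm(1, config$sex_ratio_mean, config$sex_ratio_sd), 0.9), 2.6)
    n_f <- round(size * ratio / (1 + ratio))
    n_m <- size - n_f
    for (s in c(rep("female", n_f), rep("male", n_m))) {
      ctr <- ctr + 1L
      id <- sprintf("F%04d", ctr)
      birth <- t0 - round(stats::runif(1, 4.5 * 365, 15 * 365))
      death <- as.Date(NA)
      if (config$adult_mortality > 0) {
        dth <- t0 + round(stats::rexp(1, config$adult_mortality) * 365)
        if (dth <= t_end) death <- dth
      }
      census[[ctr]] <- data.frame(id = id, sex = s, birth_date = birth,
                                  death_date = death, natal_group = g,
                                  exit_type = "death", stringsAsFactors = FALSE)
      if (s == "male") {
        ## migration history: ring-neighbor transfers, >= 90 days apart,
        ## none within 90 days of death or the end of observation
        mig_dates <- as.Date(character(0)); mig_groups <- character(0)
        cur <- g; tlast <- t0
        repeat {
          gap <- stats::rexp(1, max(config$male_migration_rate, 1e-9)) * 365
          cand <- tlast + round(max(gap, 90))
          lim <- min(t_end - 90L, if (is.na(death)) t_end else death - 90L)
          if (config$male_migration_rate <= 0 || cand > lim) break
          dir <- sample(c(-1L, 1L), 1L)
          cur <- groups[((match(cur, groups) - 1L + dir) %% length(groups)) + 1L]
          mig_dates <- c(mig_dates, cand); mig_groups <- c(mig_groups, cur)
          tlast <- cand
        }
        starts <- c(t0, mig_dates)
        grps <- c(g, mig_groups)
        ends <- c(mig_dates - 1L, death)
        truth[[length(truth) + 1L]] <- data.frame(
          id = id, group = grps, start_date = starts, end_date = ends,
          stringsAsFactors = FALSE)
      } else {
        truth[[length(truth) + 1L]] <- data.frame(
          id = id, group = g, start_date = birth, end_date = death,
          stringsAsFactors = FALSE)
      }
    }
  }
  census <- do.call(rbind, census)
  truth <- do.call(rbind, truth)
  rownames(census) <- rownames(truth) <- NULL

  sightings <- NULL
  if (config$emit_sightings) {
    male_iv <- truth[census$sex[match(truth$id, census$id)] == "male", , drop = FALSE]
    sl <- vector("list", nrow(male_iv))
    for (k in seq_len(nrow(male_iv))) {
      s <- male_iv$start_date[k]
      e <- male_iv$end_date[k]
      e <- min(if (is.na(e)) t_end else e, t_end)
      if (s > e) next
      d <- seq(s, e, by = config$census_interval_days)
      if (d[length(d)] != e) d <- c(d, e)
      sl[[k]] <- data.frame(id = male_iv$id[k], date = d, group = male_iv$group[k],
                            context = "routine", stringsAsFactors = FALSE)
    }
    sightings <- do.call(rbind, sl)
    sightings <- sightings[order(sightings$id, sightings$date), ]
    rownames(sightings) <- NULL
  }

  seasons <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g, cohort_year = cal$cohort_year,
               mating_onset = cal$mating_onset, mating_end = cal$mating_end,
               stringsAsFactors = FALSE)
  }))

  centers <- data.frame(group = groups,
                        x = config$hr_radius * cos(2 * pi * (seq_along(groups) - 1) / length(groups)),
                        y = config$hr_radius * sin(2 * pi * (seq_along(groups) - 1) / length(groups)))
  loc <- list()
  for (gi in seq_along(groups)) {
    for (ci in seq_len(nrow(cal))) {
      n <- config$hr_points_per_season
      loc[[length(loc) + 1L]] <- data.frame(
        group = groups[gi],
        date = cal$mating_onset[ci] + (seq_len(n) - 1L) %% config$season_length_days,
        x = stats::rnorm(n, centers$x[gi], config$hr_spread),
        y = stats::rnorm(n, centers$y[gi], config$hr_spread),
        stringsAsFactors = FALSE)
    }
  }
  locations <- do.call(rbind, loc)
  rownames(locations) <- NULL

  list(census = census, sightings = sightings, seasons = seasons,
       locations = locations, truth_membership = truth,
       calendar = cal, groups = groups, t0 = t0, t_end = t_end)
}

## true mature male residents of a group on a date, from the truth log
.truth_members <- function(truth, group, date) {
  hit <- truth$group == group & truth$start_date <= date &
    (is.na(truth$end_date) | truth$end_date >= date)
  truth$id[hit]
}

#' Simulate conceptions, sires, and births
#'
#' Each mature female conceives with probability `female_birth_prob` per
#' season at a uniform date; gestation is Normal(166.5, 7.4) rounded to whole
#' days. After all conceptions are placed, the group-season covariates (size
#' and sex ratio at onset, synchrony from the conception windows implied by
#' the planned birth dates, tenure-weighted instability from the true
#' membership log) are computed and z-scored, and each offspring is
#' extra-group with probability `plogis(gamma %*% z)`; extra-group sires are
#' drawn from the resident males of a ring-neighboring group at conception,
#' within-group sires from the offspring's own group.
#'
#' @param pop A [simulate_population()] result.
#' @param config The same [sim_config()].
#' @return A list: `births` (`offspring, mother, birth_date, natal_group`),
#'   `truth` (per offspring: mother, true sire, conception date, true EGP
#'   flag, fallback flag, group, cohort), `covariates_true` (the generator's
#'   group-season covariates), and `census` (founders plus offspring rows).
#' @export
simulate_matings <- function(pop, config = sim_config()) {
  set.seed(config$seed + 2L)
  cal <- pop$calendar
  groups <- pop$groups
  founders <- pop$census
  truth_iv <- pop$truth_membership
  sexof <- stats::setNames(founders$sex, founders$id)
  birthof <- stats::setNames(founders$birth_date, founders$id)
  deathof <- stats::setNames(founders$death_date, founders$id)

  lo_off <- ceiling(config$gestation_mean - config$gestation_sd)
  hi_off <- ceiling(config$gestation_mean + config$gestation_sd)

  plan <- list()
  for (ci in seq_len(nrow(cal))) {
    onset <- cal$mating_onset[ci]; send <- cal$mating_end[ci]
    for (g in groups) {
      fem <- founders$id[founders$sex == "female" & founders$natal_group == g &
                           founders$birth_date < onset &
                           (is.na(founders$death_date) | founders$death_date > send)]
      if (!length(fem)) next
      breeds <- fem[stats::runif(length(fem)) < config$female_birth_prob]
      if (!length(breeds)) next
      conc <- onset + sample.int(config$season_length_days, length(breeds),
                                 replace = TRUE) - 1L
      gest <- round(pmin(pmax(stats::rnorm(length(breeds), config$gestation_mean,
                                           config$gestation_sd), 140), 193))
      bd <- conc + gest
      alive <- is.na(deathof[breeds]) | deathof[breeds] >= bd
      if (!any(alive)) next
      plan[[length(plan) + 1L]] <- data.frame(
        mother = breeds[alive], group = g, cohort = cal$cohort_year[ci],
        conception_date = conc[alive], birth_date = bd[alive],
        stringsAsFactors = FALSE)
    }
  }
  plan <- do.call(rbind, plan)

  ## generator-side group-season covariates
  cov <- list()
  for (ci in seq_len(nrow(cal))) {
    onset <- cal$mating_onset[ci]
    for (g in groups) {
      males <- .truth_members(truth_iv[sexof[truth_iv$id] == "male", ], g, onset)
      fems <- .truth_members(truth_iv[sexof[truth_iv$id] == "female", ], g, onset)
      pb <- plan[plan$group == g & plan$cohort == cal$cohort_year[ci], , drop = FALSE]
      if (!nrow(pb) || !length(males)) next
      win <- data.frame(start = pb$birth_date - hi_off, end = pb$birth_date - lo_off)
      syn <- female_synchrony(win)
      inst <- group_instability(g, list(mating_onset = onset, mating_end = cal$mating_end[ci]),
                                truth_iv, founders)
      cov[[length(cov) + 1L]] <- data.frame(
        group = g, cohort = cal$cohort_year[ci],
        size = length(males) + length(fems),
        sex_ratio = length(fems) / length(males),
        synchrony = syn$synchrony, instability = inst$instability,
        n_planned = nrow(pb), stringsAsFactors = FALSE)
    }
  }
  cov <- do.call(rbind, cov)
  ## a constant covariate (e.g. zero instability when migration is off)
  ## contributes nothing to the EGP model
  zs <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  cov$z_sr <- zs(cov$sex_ratio); cov$z_gs <- zs(cov$size)
  cov$z_sy <- zs(cov$synchrony); cov$z_in <- zs(cov$instability)
  gam <- config$egp_gamma
  cov$p_egp <- stats::plogis(gam[["intercept"]] + gam[["sex_ratio"]] * cov$z_sr +
                               gam[["group_size"]] * cov$z_gs +
                               gam[["synchrony"]] * cov$z_sy +
                               gam[["instability"]] * cov$z_in +
                               gam[["interaction"]] * cov$z_sr * cov$z_gs)

  key <- paste(plan$group, plan$cohort)
  p_off <- cov$p_egp[match(key, paste(cov$group, cov$cohort))]
  males_iv <- truth_iv[sexof[truth_iv$id] == "male", , drop = FALSE]
  n <- nrow(plan)
  off_id <- sprintf("O%05d", seq_len(n))
  sire <- character(n); egp <- logical(n); fallback <- logical(n)
  for (i in seq_len(n)) {
    g <- plan$group[i]; conc <- plan$conception_date[i]
    want_egp <- stats::runif(1) < p_off[i]
    gi <- match(g, groups)
    nbr <- groups[c(((gi - 2L) %% length(groups)) + 1L, (gi %% length(groups)) + 1L)]
    pool_in <- .truth_members(males_iv, g, conc)
    pool_out <- unlist(lapply(nbr, function(h) .truth_members(males_iv, h, conc)))
    if (want_egp && length(pool_out)) {
      sire[i] <- if (length(pool_out) == 1L) pool_out else sample(pool_out, 1L)
      egp[i] <- TRUE
    } else {
      if (want_egp) fallback[i] <- TRUE
      if (!length(pool_in)) { sire[i] <- NA_character_; next }
      sire[i] <- if (length(pool_in) == 1L) pool_in else sample(pool_in, 1L)
      egp[i] <- FALSE
    }
  }
  ok <- !is.na(sire)
  plan <- plan[ok, , drop = FALSE]; off_id <- off_id[ok]
  sire <- sire[ok]; egp <- egp[ok]; fallback <- fallback[ok]
  n <- nrow(plan)

  sex_o <- sample(c("male", "female"), n, replace = TRUE)
  u <- stats::runif(n)
  exit_type <- rep("removal", n)
  death <- plan$birth_date + config$juvenile_removal_age_days
  inf_dead <- u < config$infant_mortality
  removed1 <- !inf_dead & u < config$infant_mortality + config$removed_infant_prob
  death[inf_dead] <- plan$birth_date[inf_dead] + sample.int(365L, sum(inf_dead), replace = TRUE) - 1L
  exit_type[inf_dead] <- "death"
  death[removed1] <- plan$birth_date[removed1] + sample.int(365L, sum(removed1), replace = TRUE) - 1L
  ungeno <- stats::runif(n) < config$ungenotyped_prob

  off_census <- data.frame(id = off_id, sex = sex_o, birth_date = plan$birth_date,
                           death_date = death, natal_group = plan$group,
                           exit_type = exit_type, stringsAsFactors = FALSE)
  births <- data.frame(offspring = off_id, mother = plan$mother,
                       birth_date = plan$birth_date, natal_group = plan$group,
                       stringsAsFactors = FALSE)
  truth <- data.frame(offspring = off_id, mother = plan$mother, true_sire = sire,
                      conception_date = plan$conception_date, true_egp = egp,
                      fallback_within = fallback, genotyped = !ungeno,
                      group = plan$group, cohort = plan$cohort,
                      stringsAsFactors = FALSE)
  list(births = births, truth = truth, covariates_true = cov,
       census = rbind(founders, off_census))
}

#' Simulate microsatellite genotypes down a one-generation pedigree
#'
#' Founder alleles are drawn from per-locus allele frequencies (flat
#' Dirichlet by default); offspring inherit one maternal and one paternal
#' allele per locus. Per-allele mistyping and per-locus dropout are applied
#' at the configured rates; ungenotyped offspring are omitted entirely.
#'
#' @param census Combined census (founders + offspring).
#' @param truth Parentage truth log from [simulate_matings()].
#' @param config A [sim_config()] object.
#' @return Long-format genotype `data.frame` (`id, locus, allele1, allele2`)
#'   with the per-locus allele frequencies in the `"allele_freqs"` attribute.
#' @export
simulate_genotypes <- function(census, truth, config = sim_config()) {
  set.seed(config$seed + 3L)
  L <- config$n_loci; A <- config$n_alleles
  freqs <- lapply(seq_len(L), function(l) {
    if (config$allele_freqs == "uniform") rep(1 / A, A)
    else { g <- stats::rgamma(A, 1); g / sum(g) }
  })
  loci <- sprintf("L%02d", seq_len(L))
  ids <- census$id
  founder <- !(ids %in% truth$offspring)
  a1 <- a2 <- matrix(NA_integer_, length(ids), L, dimnames = list(ids, loci))
  for (l in seq_len(L)) {
    nf <- sum(founder)
    a1[founder, l] <- sample.int(A, nf, replace = TRUE, prob = freqs[[l]])
    a2[founder, l] <- sample.int(A, nf, replace = TRUE, prob = freqs[[l]])
  }
  ## offspring: Mendelian transmission (parents are always founders)
  mi <- match(truth$mother, ids); si <- match(truth$true_sire, ids)
  oi <- match(truth$offspring, ids)
  for (l in seq_len(L)) {
    pickm <- stats::runif(length(oi)) < 0.5
    picks <- stats::runif(length(oi)) < 0.5
    a1[oi, l] <- ifelse(pickm, a1[cbind(mi, l)], a2[cbind(mi, l)])
    a2[oi, l] <- ifelse(picks, a1[cbind(si, l)], a2[cbind(si, l)])
  }
  if (config$genotyping_error > 0) {
    for (l in seq_len(L)) {
      for (mat in c("a1", "a2")) {
        m <- get(mat)
        err <- stats::runif(length(ids)) < config$genotyping_error
        if (any(err)) {
          m[err, l] <- sample.int(A, sum(err), replace = TRUE, prob = freqs[[l]])
          assign(mat, m)
        }
      }
    }
  }
  drop <- matrix(stats::runif(length(ids) * L) < config$locus_missing_prob,
                 length(ids), L)
  keep_id <- !(ids %in% truth$offspring[!truth$genotyped])
  rows <- which(!drop & keep_id, arr.ind = TRUE)
  out <- data.frame(id = ids[rows[, 1]], locus = loci[rows[, 2]],
                    allele1 = a1[rows], allele2 = a2[rows],
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$id, ids), out$locus), ]
  rownames(out) <- NULL
  attr(out, "allele_freqs") <- freqs
  out
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_population()], [simulate_matings()], and
#' [simulate_genotypes()] off one root seed and returns every pipeline input
#' plus the truth log.
#'
#' @param config A [sim_config()] object.
#' @return A list with `census`, `sightings`, `seasons`, `locations`,
#'   `genotypes`, `births`, `truth` (parentage), `truth_membership`,
#'   `covariates_true`, and `config`.
#' @export
simulate_egp_study <- function(config = sim_config()) {
  pop <- simulate_population(config)
  mat <- simulate_matings(pop, config)
  gen <- simulate_genotypes(mat$census, mat$truth, config)
  list(census = mat$census, sightings = pop$sightings, seasons = pop$seasons,
       locations = pop$locations, genotypes = gen, births = mat$births,
       truth = mat$truth, truth_membership = pop$truth_membership,
       covariates_true = mat$covariates_true, config = config)
}

#' Write a simulated study to CSV files
#'
#' Emits `census.csv`, `sightings.csv`, `seasons.csv`, `locations.csv`,
#' `genotypes.csv`, `births.csv`, and `truth.csv` into a directory.
#'
#' @param sim A [simulate_egp_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths.
#' @export
write_sim_csvs <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(census = "census.csv", sightings = "sightings.csv",
             seasons = "seasons.csv", locations = "locations.csv",
             genotypes = "genotypes.csv", births = "births.csv",
             truth = "truth.csv")
  paths <- character(0)
  for (nm in names(files)) {
    obj <- sim[[nm]]
    if (is.null(obj)) next
    p <- file.path(dir, files[[nm]])
    utils::write.csv(obj, p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  invisible(paths)
}
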