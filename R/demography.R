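## Census parsing, male group-membership intervals, and breeding-group
## composition. Membership follows the field convention for male dispersal in
## census-based studies: a transfer is confirmed once residence in the new
## group has remained constant for 30 days (60 days when the male was seen
## prospecting, in a bachelor group, or solitary within the first 30 days),
## and the immigration date is backdated to the first sighting in the new
## group. Females are philopatric: lifelong members of their natal group.

#' Residence-confirmation rules for male group membership
#'
#' @param routine_confirm_days Days of constant residence required to confirm
#'   a transfer when all sightings in the confirmation window are routine
#'   group censuses. Default 30.
#' @param prospecting_confirm_days Days of constant residence required when
#'   any sighting within the first `routine_confirm_days` days has context
#'   `"prospecting"`, `"bachelor"`, or `"solitary"`. Default 60.
#' @param maturity_age_days Age in days above which an individual counts as
#'   sexually mature (strict `>`). Default 1250.
#' @param max_gap_days Largest tolerated gap between successive sightings
#'   inside a confirmation window; residence cannot be verified as constant
#'   across a longer census gap. Default 7.
#' @return A list of class `"membership_rules"`.
#' @export
membership_rules <- function(routine_confirm_days = 30L,
                             prospecting_confirm_days = 60L,
                             maturity_age_days = 1250L,
                             max_gap_days = 7L) {
  stopifnot(routine_confirm_days > 0, prospecting_confirm_days > 0,
            maturity_age_days > 0, max_gap_days > 0,
            prospecting_confirm_days >= routine_confirm_days)
  structure(list(routine_confirm_days = as.integer(routine_confirm_days),
                 prospecting_confirm_days = as.integer(prospecting_confirm_days),
                 maturity_age_days = as.integer(maturity_age_days),
                 max_gap_days = as.integer(max_gap_days)),
            class = "membership_rules")
}

.nonroutine_contexts <- c("prospecting", "bachelor", "solitary")

.check_headers <- function(df, expected, what) {
  if (!identical(names(df), expected)) {
    stop(sprintf("%s: expected columns exactly %s, got %s", what,
                 paste(expected, collapse = ","), paste(names(df), collapse = ",")),
         call. = FALSE)
  }
  invisible(df)
}

.as_date <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- !is.na(x) & x != "" & is.na(d)
  if (any(bad)) stop(sprintf("%s: unparseable ISO-8601 date(s): %s", what,
                             paste(utils::head(unique(x[bad]), 3), collapse = ", ")),
                     call. = FALSE)
  d
}

#' Read a census table
#'
#' Expects columns `id,sex,birth_date,death_date,natal_group` (dates ISO-8601,
#' `death_date` may be empty). An optional sixth column `exit_type`
#' (`"death"` or `"removal"`) distinguishes natural deaths from management
#' removals; when absent every exit is treated as a death.
#'
#' @param path Path to a CSV file.
#' @return A validated census `data.frame`.
#' @export
read_census <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (identical(names(df), c("id", "sex", "birth_date", "death_date", "natal_group", "exit_type"))) {
    exp <- names(df)
  } else {
    exp <- c("id", "sex", "birth_date", "death_date", "natal_group")
  }
  .check_headers(df, exp, "census")
  validate_census(data.frame(id = df$id, sex = df$sex,
                             birth_date = .as_date(df$birth_date, "census$birth_date"),
                             death_date = .as_date(ifelse(df$death_date == "", NA, df$death_date),
                                                   "census$death_date"),
                             natal_group = df$natal_group,
                             exit_type = if ("exit_type" %in% names(df)) df$exit_type else "death",
                             stringsAsFactors = FALSE))
}

#' @keywords internal
validate_census <- function(census) {
  stopifnot(is.data.frame(census))
  need <- c("id", "sex", "birth_date", "death_date", "natal_group")
  if (!all(need %in% names(census))) {
    stop("census must have columns ", paste(need, collapse = ","), call. = FALSE)
  }
  if (!"exit_type" %in% names(census)) census$exit_type <- "death"
  if (anyDuplicated(census$id)) stop("census: duplicated individual ids", call. = FALSE)
  if (!all(census$sex %in% c("male", "female"))) {
    stop("census: sex must be 'male' or 'female'", call. = FALSE)
  }
  bad <- !is.na(census$death_date) & census$death_date < census$birth_date
  if (any(bad)) stop("census: death_date before birth_date for ",
                     paste(census$id[bad], collapse = ", "), call. = FALSE)
  census
}

#' Read a sightings table
#'
#' Expects columns `id,date,group,context` with context one of `routine`,
#' `prospecting`, `bachelor`, `solitary`.
#'
#' @param path Path to a CSV file.
#' @return A sightings `data.frame`.
#' @export
read_sightings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  .check_headers(df, c("id", "date", "group", "context"), "sightings")
  data.frame(id = df$id, date = .as_date(df$date, "sightings$date"),
             group = df$group, context = df$context, stringsAsFactors = FALSE)
}

#' Read a mating-season calendar
#'
#' Expects columns `group,cohort_year,mating_onset,mating_end`, one row per
#' group and birth-cohort year. Season dates are a required input: they are
#' field observations, not derivable quantities.
#'
#' @param path Path to a CSV file.
#' @return A seasons `data.frame`.
#' @export
read_seasons <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  .check_headers(df, c("group", "cohort_year", "mating_onset", "mating_end"), "seasons")
  out <- data.frame(group = df$group, cohort_year = as.integer(df$cohort_year),
                    mating_onset = .as_date(df$mating_onset, "seasons$mating_onset"),
                    mating_end = .as_date(df$mating_end, "seasons$mating_end"),
                    stringsAsFactors = FALSE)
  if (any(out$mating_onset >= out$mating_end)) {
    stop("seasons: mating_onset must precede mating_end", call. = FALSE)
  }
  if (anyDuplicated(out[c("group", "cohort_year")])) {
    stop("seasons: one row per (group, cohort_year) required", call. = FALSE)
  }
  out
}

## Confirmation scan for one candidate transfer starting at sighting i.
## Returns confirmed flag plus the index at which the outer scan resumes.
.confirm_candidate <- function(dates, groups, contexts, i, rules) {
  start <- dates[i]
  g <- groups[i]
  need <- rules$routine_confirm_days
  prev <- start
  n <- length(dates)
  j <- i
  while (j <= n) {
    d <- dates[j]
    if (as.integer(d - prev) > rules$max_gap_days) {
      return(list(confirmed = FALSE, next_i = j))
    }
    if (contexts[j] %in% .nonroutine_contexts) {
      ## a non-routine sighting inside the first 30 days escalates to 60
      if (as.integer(d - start) < rules$routine_confirm_days) {
        need <- rules$prospecting_confirm_days
      }
    } else if (groups[j] != g) {
      return(list(confirmed = FALSE, next_i = j))
    } else if (as.integer(d - start) >= need - 1L) {
      ## residence observed constant for `need` days counting the first day
      return(list(confirmed = TRUE, next_i = j + 1L))
    }
    prev <- d
    j <- j + 1L
  }
  list(confirmed = FALSE, next_i = n + 1L)
}

.male_intervals_one <- function(dates, groups, contexts, death, rules) {
  if (anyDuplicated(dates)) {
    dup <- duplicated(dates)
    same <- tapply(groups, as.integer(dates), function(g) length(unique(g)) == 1L)
    if (!all(same)) stop("sightings: conflicting groups for one male on one day", call. = FALSE)
    keep <- !dup
    dates <- dates[keep]; groups <- groups[keep]; contexts <- contexts[keep]
  }
  n <- length(dates)
  cur_group <- NA_character_
  cur_start <- as.Date(NA)
  starts <- ends <- as.Date(character(0))
  grps <- character(0)
  i <- 1L
  while (i <= n) {
    if (contexts[i] %in% .nonroutine_contexts) { i <- i + 1L; next }
    if (!is.na(cur_group) && groups[i] == cur_group) { i <- i + 1L; next }
    res <- .confirm_candidate(dates, groups, contexts, i, rules)
    if (res$confirmed) {
      if (!is.na(cur_group)) {
        starts <- c(starts, cur_start); ends <- c(ends, dates[i] - 1L)
        grps <- c(grps, cur_group)
      }
      cur_group <- groups[i]
      cur_start <- dates[i]
    }
    i <- res$next_i
  }
  if (!is.na(cur_group)) {
    starts <- c(starts, cur_start)
    ends <- c(ends, if (is.na(death)) as.Date(NA) else death)
    grps <- c(grps, cur_group)
  }
  list(group = grps, start_date = starts, end_date = ends)
}

#' Derive group-membership intervals from sightings
#'
#' Male residence is reconstructed from the sighting stream under the 30/60-day
#' confirmation rules in [membership_rules()]: a candidate transfer to a new
#' group becomes a confirmed interval, starting at the first sighting in that
#' group, only once the sighted group has remained constant for the required
#' number of days with no census gap larger than `max_gap_days`. The previous
#' interval ends on the day before the new start; death closes the final open
#' interval. Non-routine sightings (prospecting, bachelor, solitary) never
#' change residence themselves but escalate the confirmation requirement.
#' Females receive a single lifelong interval in their natal group.
#'
#' @param sightings Sightings `data.frame` (`id,date,group,context`), sorted
#'   by id then date; unsorted input is an error, duplicated identical rows
#'   are tolerated.
#' @param census Census `data.frame` (see [read_census()]).
#' @param rules A [membership_rules()] object.
#' @return A `data.frame` with columns `id, group, start_date, end_date`
#'   (`end_date` `NA` = open). Intervals of one individual never overlap.
#' @export
build_membership_intervals <- function(sightings, census, rules = membership_rules()) {
  census <- validate_census(census)
  stopifnot(all(c("id", "date", "group", "context") %in% names(sightings)))
  sightings$date <- .as_date(sightings$date, "sightings$date")
  unknown <- setdiff(unique(sightings$id), census$id)
  if (length(unknown)) {
    stop("sightings for unknown individual(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ord <- order(match(sightings$id, unique(sightings$id)))
  grp_idx <- split(seq_len(nrow(sightings)), sightings$id)
  for (idx in grp_idx) {
    if (is.unsorted(sightings$date[idx])) {
      stop("sightings must be sorted by (individual, date)", call. = FALSE)
    }
  }
  sex <- stats::setNames(census$sex, census$id)
  birth <- stats::setNames(census$birth_date, census$id)
  death <- stats::setNames(census$death_date, census$id)
  bad_life <- vapply(names(grp_idx), function(id) {
    d <- sightings$date[grp_idx[[id]]]
    any(d < birth[[id]]) || (!is.na(death[[id]]) && any(d > death[[id]]))
  }, logical(1))
  if (any(bad_life)) {
    stop("sightings outside the individual's lifespan: ",
         paste(names(grp_idx)[bad_life], collapse = ", "), call. = FALSE)
  }
  male_ids <- names(grp_idx)[sex[names(grp_idx)] == "male"]
  res <- lapply(male_ids, function(id) {
    idx <- grp_idx[[id]]
    iv <- .male_intervals_one(sightings$date[idx], sightings$group[idx],
                              sightings$context[idx], death[[id]], rules)
    if (!length(iv$group)) return(NULL)
    data.frame(id = id, group = iv$group, start_date = iv$start_date,
               end_date = iv$end_date, stringsAsFactors = FALSE)
  })
  males <- do.call(rbind, res)
  fem <- census[census$sex == "female", , drop = FALSE]
  females <- if (nrow(fem)) {
    data.frame(id = fem$id, group = fem$natal_group, start_date = fem$birth_date,
               end_date = fem$death_date, stringsAsFactors = FALSE)
  } else NULL
  out <- rbind(males, females)
  if (is.null(out)) {
    out <- data.frame(id = character(0), group = character(0),
                      start_date = as.Date(character(0)),
                      end_date = as.Date(character(0)), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Individuals resident in a group on a date
#'
#' Intervals are closed on both ends; an open `end_date` (NA) extends
#' indefinitely.
#'
#' @param intervals Output of [build_membership_intervals()].
#' @param group Group identifier.
#' @param date A `Date` (or ISO-8601 string).
#' @return Character vector of individual ids.
#' @export
members_on_date <- function(intervals, group, date) {
  date <- .as_date(date, "date")
  hit <- intervals$group == group & intervals$start_date <= date &
    (is.na(intervals$end_date) | intervals$end_date >= date)
  unique(intervals$id[hit])
}

#' Days of group tenure on a date
#'
#' Inclusive count: on the first day of membership tenure is 1, so that a
#' same-day loss still carries weight in the instability numerator. Returns 0
#' when no interval covers the date.
#'
#' @inheritParams members_on_date
#' @param id Individual id.
#' @return Integer number of days.
#' @export
tenure_on_date <- function(intervals, id, date) {
  date <- .as_date(date, "date")
  hit <- intervals$id == id & intervals$start_date <= date &
    (is.na(intervals$end_date) | intervals$end_date >= date)
  if (!any(hit)) return(0L)
  as.integer(date - max(intervals$start_date[hit])) + 1L
}

.season_row <- function(season) {
  if (is.data.frame(season)) {
    stopifnot(nrow(season) == 1L)
    season <- as.list(season)
  }
  season$mating_onset <- .as_date(season$mating_onset, "mating_onset")
  season$mating_end <- .as_date(season$mating_end, "mating_end")
  stopifnot(season$mating_onset < season$mating_end)
  season
}

#' Breeding-group composition at mating-season onset
#'
#' Counts resident females and males strictly older than `maturity_age_days`
#' (default 1250 days) on the first day of the mating season; breeding group
#' size is their sum.
#'
#' @param group Group identifier.
#' @param season One row of a seasons table (or a list with `mating_onset`,
#'   `mating_end`).
#' @param census Census `data.frame`.
#' @param intervals Membership intervals.
#' @param maturity_age_days Maturity threshold in days (strict `>`).
#' @return Named integer vector `c(n_females =, n_males =)`.
#' @export
breeding_group_composition <- function(group, season, census, intervals,
                                       maturity_age_days = 1250L) {
  season <- .season_row(season)
  onset <- season$mating_onset
  ids <- members_on_date(intervals, group, onset)
  if (!length(ids)) return(c(n_females = 0L, n_males = 0L))
  cc <- census[match(ids, census$id), ]
  mature <- as.integer(onset - cc$birth_date) > maturity_age_days
  c(n_females = sum(mature & cc$sex == "female"),
    n_males = sum(mature & cc$sex == "male"))
}

## Daily counts of mature members of one sex over a date span, via
## difference-array accumulation over interval overlaps.
.daily_mature_counts <- function(group, from, to, census, intervals, sex,
                                 maturity_age_days = 1250L) {
  ndays <- as.integer(to - from) + 1L
  counts <- numeric(ndays)
  iv <- intervals[intervals$group == group, , drop = FALSE]
  if (!nrow(iv)) return(counts)
  cc <- census[match(iv$id, census$id), ]
  keep <- cc$sex == sex
  iv <- iv[keep, , drop = FALSE]; cc <- cc[keep, , drop = FALSE]
  if (!nrow(iv)) return(counts)
  ## mature from the day age first exceeds the threshold
  mature_from <- cc$birth_date + maturity_age_days + 1L
  lo <- pmax(iv$start_date, mature_from, from)
  hi <- iv$end_date
  hi[is.na(hi)] <- to
  hi <- pmin(hi, to)
  ok <- lo <= hi
  if (!any(ok)) return(counts)
  a <- as.integer(lo[ok] - from) + 1L
  b <- as.integer(hi[ok] - from) + 1L
  diffarr <- numeric(ndays + 1L)
  for (k in seq_along(a)) {
    diffarr[a[k]] <- diffarr[a[k]] + 1
    diffarr[b[k] + 1L] <- diffarr[b[k] + 1L] - 1
  }
  cumsum(diffarr)[seq_len(ndays)]
}

#' Breeding-group sex ratio over a mating season
#'
#' Ratio of mature females to mature males. The default averages daily counts
#' of mature resident females and males over every day of the mating season;
#' `method = "onset"` instead uses the single census at season onset.
#'
#' @inheritParams breeding_group_composition
#' @param method `"daily"` (default) or `"onset"`.
#' @return Numeric ratio (mean females / mean males).
#' @export
group_sex_ratio <- function(group, season, census, intervals,
                            method = c("daily", "onset"),
                            maturity_age_days = 1250L) {
  method <- match.arg(method)
  season <- .season_row(season)
  if (method == "onset") {
    comp <- breeding_group_composition(group, season, census, intervals,
                                       maturity_age_days)
    if (comp[["n_males"]] == 0L) {
      stop(sprintf("group %s: no mature males at season onset; sex ratio undefined", group),
           call. = FALSE)
    }
    return(comp[["n_females"]] / comp[["n_males"]])
  }
  f <- .daily_mature_counts(group, season$mating_onset, season$mating_end,
                            census, intervals, "female", maturity_age_days)
  m <- .daily_mature_counts(group, season$mating_onset, season$mating_end,
                            census, intervals, "male", maturity_age_days)
  if (mean(m) == 0) {
    stop(sprintf("group %s: mean mature male count is zero; sex ratio undefined", group),
         call. = FALSE)
  }
  mean(f) / mean(m)
}

#' Filter an offspring cohort for analysis
#'
#' Removes, in order of precedence: infants that died before age one year,
#' infants removed (management) together with their mother before age one
#' year, ungenotyped infants, and infants born into groups that were not
#' present over the entire study period. Every exclusion is logged with a
#' machine-readable reason; retained plus excluded always partition the
#' input.
#'
#' @param births `data.frame` with columns `offspring, mother, birth_date,
#'   natal_group`.
#' @param census Census `data.frame` (with optional `exit_type` column; exits
#'   labelled `"removal"` are management removals).
#' @param genotyped_ids Character vector of genotyped individual ids.
#' @param persistent_groups Groups present throughout the study.
#' @return `list(retained = data.frame, excluded = data.frame(offspring, reason))`.
#' @export
filter_offspring_cohort <- function(births, census, genotyped_ids, persistent_groups) {
  stopifnot(all(c("offspring", "mother", "birth_date", "natal_group") %in% names(births)))
  births$birth_date <- .as_date(births$birth_date, "births$birth_date")
  cc <- census[match(births$offspring, census$id), ]
  if (!"exit_type" %in% names(cc)) cc$exit_type <- "death"
  age_at_exit <- as.integer(cc$death_date - births$birth_date)
  died1 <- !is.na(age_at_exit) & age_at_exit < 365L & cc$exit_type != "removal"
  removed1 <- !is.na(age_at_exit) & age_at_exit < 365L & cc$exit_type == "removal"
  ungeno <- !(births$offspring %in% genotyped_ids)
  badgrp <- !(births$natal_group %in% persistent_groups)
  reason <- rep(NA_character_, nrow(births))
  reason[badgrp] <- "group_not_persistent"
  reason[ungeno] <- "ungenotyped"
  reason[removed1] <- "removed<1y"
  reason[died1] <- "died<1y"
  keep <- is.na(reason)
  list(retained = births[keep, , drop = FALSE],
       excluded = data.frame(offspring = births$offspring[!keep],
                             reason = reason[!keep], stringsAsFactors = FALSE))
}
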