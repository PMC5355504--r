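## Group-season covariates: female reproductive synchrony and tenure-weighted
## group instability.
##
## Synchrony: 15 / (number of unique dates on which at least one live-birth
## mother was estimated to be in estrus, i.e. the union of the females'
## conception windows). 1 = complete synchrony, -> 0 as windows disperse.
##
## Instability: daily membership loss (tenure share of mature males present
## yesterday but gone today) and daily membership gain (new mature males today
## over total mature group size today), each averaged over the mating season
## with weights 1/(t+1) for day t after onset — disturbances near the season
## onset destabilize mating most — and summed.

#' Female reproductive synchrony for one group-season
#'
#' @param windows A `data.frame` with `Date` columns `start` and `end`, one
#'   row per live-birth mother's conception window, or a list of
#'   [conception_window()] objects.
#' @return `list(n_females, unique_estrous_days, synchrony)` where
#'   `synchrony = window length / unique_estrous_days`.
#' @export
female_synchrony <- function(windows) {
  if (is.list(windows) && !is.data.frame(windows) &&
      all(vapply(windows, inherits, logical(1), "conception_window"))) {
    windows <- data.frame(start = as.Date(vapply(windows, function(w) as.character(w$start), "")),
                          end = as.Date(vapply(windows, function(w) as.character(w$end), "")))
  }
  stopifnot(is.data.frame(windows), all(c("start", "end") %in% names(windows)))
  if (!nrow(windows)) {
    stop("female_synchrony: no live-birth mothers; synchrony undefined", call. = FALSE)
  }
  windows$start <- .as_date(windows$start, "windows$start")
  windows$end <- .as_date(windows$end, "windows$end")
  stopifnot(all(windows$start <= windows$end))
  len <- unique(as.integer(windows$end - windows$start) + 1L)
  if (length(len) != 1L) {
    stop("female_synchrony: conception windows must share one length", call. = FALSE)
  }
  days <- unique(unlist(mapply(function(s, e) seq.int(s, e), as.integer(windows$start),
                               as.integer(windows$end), SIMPLIFY = FALSE)))
  u <- length(days)
  list(n_females = nrow(windows), unique_estrous_days = u, synchrony = len / u)
}

.mature_males_on <- function(group, date, intervals, census, maturity_age_days) {
  ids <- members_on_date(intervals, group, date)
  if (!length(ids)) return(character(0))
  cc <- census[match(ids, census$id), ]
  ids[cc$sex == "male" & as.integer(date - cc$birth_date) > maturity_age_days]
}

#' Daily proportional membership loss for a group
#'
#' Mature males present on the previous day but absent on `date` constitute
#' the loss; it is weighted by tenure (days of membership measured on the
#' previous day) and divided by the summed tenures of all mature males
#' present the previous day, so losing a long-term resident destabilizes more
#' than losing a recent immigrant. Returns 0 when no males were present the
#' previous day.
#'
#' @param group Group identifier.
#' @param date A `Date`.
#' @param intervals Membership intervals.
#' @param census Census `data.frame`.
#' @param maturity_age_days Maturity threshold (strict `>`). Default 1250.
#' @return Proportion in `[0, 1]`.
#' @export
membership_loss_daily <- function(group, date, intervals, census,
                                  maturity_age_days = 1250L) {
  date <- .as_date(date, "date")
  prev <- date - 1L
  yest <- .mature_males_on(group, prev, intervals, census, maturity_age_days)
  if (!length(yest)) return(0)
  today <- .mature_males_on(group, date, intervals, census, maturity_age_days)
  ten <- vapply(yest, function(id) tenure_on_date(intervals, id, prev), integer(1))
  lost <- !(yest %in% today)
  sum(ten[lost]) / sum(ten)
}

#' Daily proportional membership gain for a group
#'
#' Mature males present on `date` but absent the previous day, divided by the
#' total mature group size (males plus females) on `date`.
#'
#' @inheritParams membership_loss_daily
#' @return Proportion in `[0, 1]`.
#' @export
membership_gain_daily <- function(group, date, intervals, census,
                                  maturity_age_days = 1250L) {
  date <- .as_date(date, "date")
  today <- .mature_males_on(group, date, intervals, census, maturity_age_days)
  if (!length(today)) return(0)
  yest <- .mature_males_on(group, date - 1L, intervals, census, maturity_age_days)
  new <- sum(!(today %in% yest))
  ids <- members_on_date(intervals, group, date)
  cc <- census[match(ids, census$id), ]
  size <- sum(as.integer(date - cc$birth_date) > maturity_age_days)
  if (size == 0L) return(0)
  new / size
}

#' Inverse-lag weighted instability from daily loss/gain series
#'
#' Day `t` after season onset (onset day is `t = 0`) gets weight
#' `1 / (t + 1)`; weighted averages are normalized by the weight sum and the
#' instability index is their total.
#'
#' @param losses,gains Numeric vectors of daily proportions, element `i`
#'   being day `t = i - 1` of the mating season.
#' @return `list(weighted_loss, weighted_gain, instability)`.
#' @export
weighted_instability <- function(losses, gains) {
  stopifnot(length(losses) == length(gains), length(losses) >= 1L)
  w <- 1 / seq_along(losses)
  list(weighted_loss = sum(w * losses) / sum(w),
       weighted_gain = sum(w * gains) / sum(w),
       instability = sum(w * losses) / sum(w) + sum(w * gains) / sum(w))
}

#' Group instability over a mating season
#'
#' Computes the daily loss and gain series across the season and combines
#' them with [weighted_instability()].
#'
#' @param group Group identifier.
#' @param season One row of a seasons table.
#' @param intervals Membership intervals.
#' @param census Census `data.frame`.
#' @param maturity_age_days Maturity threshold. Default 1250.
#' @return `list(weighted_loss, weighted_gain, instability, losses, gains)`.
#' @export
group_instability <- function(group, season, intervals, census,
                              maturity_age_days = 1250L) {
  season <- .season_row(season)
  days <- seq(season$mating_onset, season$mating_end, by = "day")
  ## presence/tenure grids computed once; per-day set logic on small vectors
  iv <- intervals[intervals$group == group, , drop = FALSE]
  cc <- census[match(iv$id, census$id), ]
  losses <- gains <- numeric(length(days))
  from <- season$mating_onset - 1L
  male <- cc$sex == "male"
  mat_from <- cc$birth_date + maturity_age_days + 1L
  lo_all <- pmax(iv$start_date, mat_from)
  hi_all <- iv$end_date
  hi_all[is.na(hi_all)] <- season$mating_end
  pres <- function(d) which(male & lo_all <= d & hi_all >= d)
  prev_set <- pres(from)
  prev_ten <- as.integer(from - iv$start_date[prev_set]) + 1L
  for (k in seq_along(days)) {
    d <- days[k]
    cur_set <- pres(d)
    if (length(prev_set)) {
      lost <- !(iv$id[prev_set] %in% iv$id[cur_set])
      losses[k] <- if (any(lost)) sum(prev_ten[lost]) / sum(prev_ten) else 0
    }
    if (length(cur_set)) {
      new <- sum(!(iv$id[cur_set] %in% iv$id[prev_set]))
      if (new > 0L) {
        allm <- which(lo_all <= d & hi_all >= d)
        ## females mature too; total mature group size on the current day
        size <- length(unique(iv$id[allm]))
        gains[k] <- if (size > 0L) new / size else 0
      }
    }
    prev_set <- cur_set
    prev_ten <- as.integer(d - iv$start_date[cur_set]) + 1L
  }
  res <- weighted_instability(losses, gains)
  c(res, list(losses = losses, gains = gains))
}
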