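## Conception windows and within-group / extra-group classification.
## The conception window is the span of integer day-offsets before birth
## covered by gestation mean +/- SD; with the default 166.5 +/- 7.4 days this
## is offsets 160..174, i.e. a 15-day window. The window is then widened by a
## 30-day buffer on each side (75 days in total) so that a sire who merely
## migrated near conception is not mistaken for an extra-group male.

#' Gestation and buffer parameters for conception windows
#'
#' @param gestation_mean_days Mean gestation length in days. Default 166.5.
#' @param gestation_sd_days SD of gestation length in days. Default 7.4.
#' @param egp_buffer_days Buffer added on each side of the conception window
#'   for residence evaluation. Default 30.
#' @return A list of class `"conception_params"`.
#' @export
conception_params <- function(gestation_mean_days = 166.5,
                              gestation_sd_days = 7.4,
                              egp_buffer_days = 30L) {
  stopifnot(gestation_mean_days > 0, gestation_sd_days > 0, egp_buffer_days >= 0)
  structure(list(gestation_mean_days = gestation_mean_days,
                 gestation_sd_days = gestation_sd_days,
                 egp_buffer_days = as.integer(egp_buffer_days)),
            class = "conception_params")
}

#' Conception window for a birth date
#'
#' Day offsets run from `ceiling(mean - sd)` to `ceiling(mean + sd)` before
#' birth; under the defaults these are offsets 160 to 174, giving a 15-day
#' window — the only integer-day discretization of the 159.1–173.9 span that
#' matches the published window length. The discretization is recorded in the
#' `offsets` attribute.
#'
#' @param birth_date A `Date` (or ISO-8601 string).
#' @param params A [conception_params()] object.
#' @return `list(start, end, n_days)` of class `"conception_window"`.
#' @export
conception_window <- function(birth_date, params = conception_params()) {
  birth_date <- .as_date(birth_date, "birth_date")
  lo <- ceiling(params$gestation_mean_days - params$gestation_sd_days)
  hi <- ceiling(params$gestation_mean_days + params$gestation_sd_days)
  structure(list(start = birth_date - hi, end = birth_date - lo,
                 n_days = as.integer(hi - lo + 1L)),
            offsets = c(lo, hi), class = "conception_window")
}

#' Residence-evaluation window around a conception window
#'
#' Extends the conception window by `egp_buffer_days` on each side; 75 days
#' under the defaults.
#'
#' @param cw A [conception_window()] object.
#' @param params A [conception_params()] object.
#' @return `list(start, end, n_days)`.
#' @export
egp_window <- function(cw, params = conception_params()) {
  stopifnot(inherits(cw, "conception_window"))
  b <- params$egp_buffer_days
  list(start = cw$start - b, end = cw$end + b,
       n_days = as.integer(cw$n_days + 2L * b))
}

#' Classify one offspring as within-group or extra-group
#'
#' The offspring is within-group when its assigned sire was a member of the
#' offspring's natal group on at least one day of the 75-day evaluation
#' window — deliberately including sires who immigrated into or emigrated
#' from the group during the window — and extra-group otherwise.
#'
#' @param offspring_id Offspring id.
#' @param sire_id Assigned sire id (NA = unclassifiable).
#' @param natal_group Offspring natal group.
#' @param birth_date Offspring birth date.
#' @param intervals Membership intervals.
#' @param params A [conception_params()] object.
#' @return One-row `data.frame`: `offspring, sire, status, window_start,
#'   window_end, overlap_days`. `status` is NA when no sire is assigned.
#' @export
classify_offspring <- function(offspring_id, sire_id, natal_group, birth_date,
                               intervals, params = conception_params()) {
  cw <- conception_window(birth_date, params)
  win <- egp_window(cw, params)
  if (is.na(sire_id)) {
    return(data.frame(offspring = offspring_id, sire = NA_character_,
                      status = NA_character_, window_start = win$start,
                      window_end = win$end, overlap_days = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  iv <- intervals[intervals$id == sire_id & intervals$group == natal_group, , drop = FALSE]
  overlap <- 0L
  if (nrow(iv)) {
    lo <- pmax(iv$start_date, win$start)
    hi <- iv$end_date
    hi[is.na(hi)] <- win$end
    hi <- pmin(hi, win$end)
    overlap <- sum(pmax(0L, as.integer(hi - lo) + 1L))
  }
  data.frame(offspring = offspring_id, sire = sire_id,
             status = if (overlap >= 1L) "within_group" else "extra_group",
             window_start = win$start, window_end = win$end,
             overlap_days = as.integer(overlap), stringsAsFactors = FALSE)
}

#' Classify every assigned offspring
#'
#' @param assignments Output `assignments` of [assign_paternity_all()].
#' @param births `data.frame` with `offspring, mother, birth_date, natal_group`.
#' @param intervals Membership intervals.
#' @param params A [conception_params()] object.
#' @return `list(classifications = data.frame, unclassified =
#'   data.frame(offspring, reason))`; unassigned offspring are logged, not
#'   classified.
#' @export
classify_egp_all <- function(assignments, births, intervals,
                             params = conception_params()) {
  idx <- match(assignments$offspring, births$offspring)
  stopifnot(!anyNA(idx))
  rows <- vector("list", nrow(assignments))
  for (i in seq_len(nrow(assignments))) {
    rows[[i]] <- classify_offspring(assignments$offspring[i], assignments$sire[i],
                                    births$natal_group[idx[i]],
                                    births$birth_date[idx[i]], intervals, params)
  }
  out <- do.call(rbind, rows)
  uncls <- is.na(out$status)
  list(classifications = out[!uncls, , drop = FALSE],
       unclassified = data.frame(offspring = out$offspring[uncls],
                                 reason = rep("sire_unassigned", sum(uncls)),
                                 stringsAsFactors = FALSE))
}

#' Tabulate EGP counts per group and cohort
#'
#' @param classifications Classification `data.frame` (from
#'   [classify_egp_all()]).
#' @param births Births table supplying `natal_group` and `birth_date`;
#'   cohort is the calendar year of birth unless a `cohort` column is present.
#' @return `data.frame(group, cohort, n_egp, n_within, pct)` with marginal
#'   total rows (`group = "total"` per cohort, `cohort = NA` per group, and a
#'   grand total); `pct` is the percentage of classified offspring that are
#'   extra-group.
#' @export
tabulate_egp <- function(classifications, births) {
  idx <- match(classifications$offspring, births$offspring)
  stopifnot(!anyNA(idx))
  grp <- births$natal_group[idx]
  coh <- if ("cohort" %in% names(births)) births$cohort[idx]
         else as.integer(format(.as_date(births$birth_date[idx], "birth_date"), "%Y"))
  egp <- classifications$status == "extra_group"
  cell <- aggregate(cbind(n_egp = egp, n_within = !egp),
                    by = list(group = grp, cohort = coh), FUN = sum)
  cell$pct <- 100 * cell$n_egp / (cell$n_egp + cell$n_within)
  bygrp <- aggregate(cbind(n_egp = egp, n_within = !egp), by = list(group = grp), FUN = sum)
  bygrp$cohort <- NA; bygrp$pct <- 100 * bygrp$n_egp / (bygrp$n_egp + bygrp$n_within)
  bycoh <- aggregate(cbind(n_egp = egp, n_within = !egp), by = list(cohort = coh), FUN = sum)
  bycoh$group <- "total"; bycoh$pct <- 100 * bycoh$n_egp / (bycoh$n_egp + bycoh$n_within)
  tot <- data.frame(group = "total", cohort = NA, n_egp = sum(egp),
                    n_within = sum(!egp))
  tot$pct <- 100 * tot$n_egp / (tot$n_egp + tot$n_within)
  cols <- c("group", "cohort", "n_egp", "n_within", "pct")
  out <- rbind(cell[cols], bygrp[cols], bycoh[cols], tot[cols])
  rownames(out) <- NULL
  out
}
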