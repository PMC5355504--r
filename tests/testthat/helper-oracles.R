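# Independent brute-force oracles. These deliberately re-derive each quantity
# from first principles with naive loops, staying independent of the package's
# vectorized implementations.

# per-locus Mendelian trio check by explicit enumeration of both orderings
oracle_trio_mismatch <- function(off, mom, cand) {
  stopifnot(length(off) == length(mom), length(mom) == length(cand))
  mm <- 0L
  for (l in seq_along(off)) {
    o <- off[[l]]; m <- mom[[l]]; p <- cand[[l]]
    if (is.null(o) || is.null(m) || is.null(p)) next
    maternal_ok <- (o[1] %in% m) || (o[2] %in% m)
    if (!maternal_ok) next  # maternal mismatch: skipped for the sire count
    ok <- ((o[1] %in% m) && (o[2] %in% p)) || ((o[2] %in% m) && (o[1] %in% p))
    if (!ok) mm <- mm + 1L
  }
  mm
}

# members of a group on a date by scanning every interval row
oracle_members <- function(intervals, group, date) {
  out <- character(0)
  for (i in seq_len(nrow(intervals))) {
    if (intervals$group[i] != group) next
    if (intervals$start_date[i] > date) next
    if (!is.na(intervals$end_date[i]) && intervals$end_date[i] < date) next
    out <- c(out, intervals$id[i])
  }
  unique(out)
}

oracle_mature_males <- function(intervals, census, group, date, maturity = 1250L) {
  ids <- oracle_members(intervals, group, date)
  keep <- character(0)
  for (id in ids) {
    row <- census[census$id == id, ]
    if (row$sex == "male" && as.integer(date - row$birth_date) > maturity) {
      keep <- c(keep, id)
    }
  }
  keep
}

oracle_tenure <- function(intervals, id, date) {
  best <- NA
  for (i in seq_len(nrow(intervals))) {
    if (intervals$id[i] != id) next
    if (intervals$start_date[i] > date) next
    if (!is.na(intervals$end_date[i]) && intervals$end_date[i] < date) next
    best <- intervals$start_date[i]
  }
  if (is.na(best)) return(0L)
  as.integer(date - best) + 1L
}

oracle_loss <- function(intervals, census, group, date, maturity = 1250L) {
  yest <- oracle_mature_males(intervals, census, group, date - 1, maturity)
  if (!length(yest)) return(0)
  today <- oracle_mature_males(intervals, census, group, date, maturity)
  num <- den <- 0
  for (id in yest) {
    ten <- oracle_tenure(intervals, id, date - 1)
    den <- den + ten
    if (!(id %in% today)) num <- num + ten
  }
  num / den
}

oracle_gain <- function(intervals, census, group, date, maturity = 1250L) {
  today <- oracle_mature_males(intervals, census, group, date, maturity)
  if (!length(today)) return(0)
  yest <- oracle_mature_males(intervals, census, group, date - 1, maturity)
  new <- sum(!(today %in% yest))
  ids <- oracle_members(intervals, group, date)
  size <- 0
  for (id in ids) {
    row <- census[census$id == id, ]
    if (as.integer(date - row$birth_date) > maturity) size <- size + 1
  }
  if (size == 0) return(0)
  new / size
}

oracle_weighted <- function(losses, gains) {
  w <- 1 / (seq_along(losses) - 1 + 1)
  sum(w * losses) / sum(w) + sum(w * gains) / sum(w)
}

# O(n^3) convex hull: (i, j) is a hull edge iff every other point lies
# on or left of the directed line i -> j; vertices are edge endpoints
oracle_hull_vertices <- function(x, y) {
  n <- length(x)
  vert <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    left <- TRUE
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      cr <- (x[j] - x[i]) * (y[k] - y[i]) - (y[j] - y[i]) * (x[k] - x[i])
      if (cr < 0) { left <- FALSE; break }
    }
    if (left) vert[i] <- vert[j] <- TRUE
  }
  which(vert)
}

# random small interval fixture for oracle-equivalence tests
random_interval_fixture <- function(n_males = 8, n_days = 30, seed = 1) {
  set.seed(seed)
  ids <- sprintf("M%02d", seq_len(n_males))
  census <- mk_census(ids, "male", d0 - sample(1300:4000, n_males, TRUE))
  rows <- lapply(ids, function(id) {
    s <- sample(-20:(n_days - 5), 1)
    e <- s + sample(5:40, 1)
    mk_intervals(id, "A", s, if (runif(1) < 0.8) e else NA)
  })
  list(census = census, intervals = do.call(rbind, rows))
}
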