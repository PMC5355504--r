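test_that("conception windows span gestation mean +/- SD as 15 calendar days", {
  cw <- conception_window(as.Date("2004-06-01"))
  expect_equal(cw$start, as.Date("2003-12-10"))
  expect_equal(cw$end, as.Date("2003-12-24"))
  expect_equal(cw$n_days, 15L)
  expect_equal(attr(cw, "offsets"), c(160, 174))
  # translation invariance: shifting birth by one day shifts the window by one
  cw2 <- conception_window(as.Date("2004-06-02"))
  expect_equal(cw2$start, cw$start + 1)
  expect_equal(cw2$end, cw$end + 1)
  # any birth date yields a 15-day window
  set.seed(3)
  for (bd in d0 + sample(0:3000, 10)) {
    expect_equal(conception_window(as.Date(bd, origin = "1970-01-01"))$n_days, 15L)
  }
})

test_that("the residence-evaluation window is the conception window +/- 30 days", {
  cw <- conception_window(as.Date("2004-06-01"))
  w <- egp_window(cw)
  expect_equal(w$start, as.Date("2003-11-10"))
  expect_equal(w$end, as.Date("2004-01-23"))
  expect_equal(w$n_days, 75L)
  w0 <- egp_window(cw, conception_params(egp_buffer_days = 0))
  expect_equal(w0$start, cw$start)
  expect_equal(w0$end, cw$end)
  expect_equal(w0$n_days, 15L)
})

test_that("classification keys on sire residence during any of the 75 days", {
  bd <- as.Date("2004-06-01")  # window 2003-11-10 .. 2004-01-23
  # resident throughout
  iv <- mk_intervals("s1", "G", -3000, NA)
  expect_equal(classify_offspring("o", "s1", "G", bd, iv)$status, "within_group")
  # immigrated on the last day of the window
  iv <- data.frame(id = "s2", group = "G", start_date = as.Date("2004-01-23"),
                   end_date = as.Date(NA))
  cl <- classify_offspring("o", "s2", "G", bd, iv)
  expect_equal(cl$status, "within_group")
  expect_equal(cl$overlap_days, 1L)
  # emigrated the day before the window opens
  iv <- data.frame(id = "s3", group = "G", start_date = d0 - 3000,
                   end_date = as.Date("2003-11-09"))
  expect_equal(classify_offspring("o", "s3", "G", bd, iv)$status, "extra_group")
  # resident only in another group
  iv <- mk_intervals("s4", "H", -3000, NA)
  expect_equal(classify_offspring("o", "s4", "G", bd, iv)$status, "extra_group")
})

test_that("every classified offspring is exactly within-group or extra-group", {
  set.seed(8)
  iv <- rbind(mk_intervals("s", "G", -200, 100), mk_intervals("s", "H", 101, NA))
  for (off in sample(0:600, 40)) {
    st <- classify_offspring("o", "s", "G", d0 + off, iv)$status
    expect_true(st %in% c("within_group", "extra_group"))
  }
  st <- classify_offspring("o", NA_character_, "G", d0, iv)$status
  expect_true(is.na(st))
})

test_that("enlarging the buffer can only move offspring toward within-group", {
  set.seed(9)
  iv <- rbind(mk_intervals("s", "G", 50, 130), mk_intervals("s", "H", 131, NA))
  for (off in sample(150:500, 25)) {
    bd <- d0 + off
    st10 <- classify_offspring("o", "s", "G", bd, iv, conception_params(egp_buffer_days = 10))$status
    st30 <- classify_offspring("o", "s", "G", bd, iv, conception_params(egp_buffer_days = 30))$status
    st60 <- classify_offspring("o", "s", "G", bd, iv, conception_params(egp_buffer_days = 60))$status
    if (st10 == "within_group") expect_equal(st30, "within_group")
    if (st30 == "within_group") expect_equal(st60, "within_group")
  }
})

test_that("EGP tabulation reports counts, percentages, and additive totals", {
  births <- data.frame(offspring = sprintf("o%03d", 1:102),
                       mother = "m", birth_date = rep(c(d0, d0 + 365), c(51, 51)),
                       natal_group = rep(c("F", "G"), c(51, 51)))
  status <- c(rep(c("extra_group", "within_group"), c(4, 47)),
              rep(c("extra_group", "within_group"), c(10, 41)))
  cls <- data.frame(offspring = births$offspring, sire = "s", status = status)
  tab <- tabulate_egp(cls, births)
  f2004 <- tab[!is.na(tab$cohort) & tab$group == "F" & tab$cohort == 2004, ]
  expect_equal(f2004$n_egp, 4L)
  expect_equal(f2004$n_within, 47L)
  expect_equal(round(f2004$pct, 1), 7.8)
  tot <- tab[tab$group == "total" & is.na(tab$cohort), ]
  expect_equal(tot$n_egp, sum(tab$n_egp[tab$group != "total" & !is.na(tab$cohort)]))
  expect_equal(tot$n_egp + tot$n_within, 102L)
})

test_that("true conception dates fall inside the window at the +/-1 SD rate", {
  cfg <- sim_config(n_cohorts = 2, seed = 19, emit_sightings = FALSE)
  pop <- simulate_population(cfg)
  mat <- simulate_matings(pop, cfg)
  cw <- lapply(mat$births$birth_date, conception_window)
  inside <- mapply(function(w, conc) conc >= w$start && conc <= w$end,
                   cw, mat$truth$conception_date)
  # P(round(gestation) in [160, 174]) for N(166.5, 7.4) ~ 0.688
  expect_gt(mean(inside), 0.64)
  expect_lt(mean(inside), 0.74)
})
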