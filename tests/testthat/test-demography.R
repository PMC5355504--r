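test_that("a transfer confirms after 30 days of constant routine residence", {
  census <- mk_census(c("m1"), "male", d0 - 2000)
  s <- mk_sightings("m1", 0:40, "G")
  iv <- build_membership_intervals(s, census)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$group, "G")
  expect_equal(iv$start_date, d0)  # immigration backdated to first sighting
  expect_true(is.na(iv$end_date))
})

test_that("residence not constant for 30 days yields no interval in the new group", {
  census <- mk_census("m1", "male", d0 - 2000, natal = "H")
  s <- rbind(mk_sightings("m1", 0:20, "G"), mk_sightings("m1", 21:80, "H"))
  iv <- build_membership_intervals(s, census)
  expect_false("G" %in% iv$group)
  expect_equal(iv$group[1], "H")
})

test_that("a prospecting sighting within the first 30 days escalates to the 60-day rule", {
  census <- mk_census("m1", "male", d0 - 2000)
  s <- mk_sightings("m1", 0:65, "G")
  s$context[s$date == d0 + 10] <- "prospecting"
  iv <- build_membership_intervals(s, census)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$start_date, d0)  # start still backdated to first sighting
  # the same male observed only through day 45 cannot confirm under 60 days
  s2 <- mk_sightings("m1", 0:45, "G")
  s2$context[s2$date == d0 + 10] <- "prospecting"
  iv2 <- build_membership_intervals(s2, census)
  expect_equal(nrow(iv2), 0L)
})

test_that("a confirmed transfer closes the previous interval the day before", {
  census <- mk_census("m1", "male", d0 - 2000, death = d0 + 200)
  s <- rbind(mk_sightings("m1", 0:99, "A"), mk_sightings("m1", 100:200, "B"))
  iv <- build_membership_intervals(s, census)
  expect_equal(iv$group, c("A", "B"))
  expect_equal(iv$end_date[1], d0 + 99)
  expect_equal(iv$start_date[2], d0 + 100)
  expect_equal(iv$end_date[2], d0 + 200)  # death closes the open interval
})

test_that("interval building is idempotent and ignores duplicated sightings", {
  census <- mk_census("m1", "male", d0 - 2000)
  s <- rbind(mk_sightings("m1", 0:99, "A"), mk_sightings("m1", 100:200, "B"))
  dup <- s[order(s$id, s$date), ]
  dup <- rbind(dup, dup[seq(1, nrow(dup), by = 7), ])
  dup <- dup[order(dup$id, dup$date), ]
  expect_identical(build_membership_intervals(s, census),
                   build_membership_intervals(dup, census))
})

test_that("invalid sighting streams are rejected", {
  census <- mk_census("m1", "male", d0 - 2000)
  s <- mk_sightings("m1", c(5, 3, 8), "A")
  expect_error(build_membership_intervals(s, census), "sorted")
  s2 <- mk_sightings("ghost", 0:40, "A")
  expect_error(build_membership_intervals(s2, census), "unknown")
})

test_that("no male is a member of two groups on any day (exclusivity)", {
  census <- mk_census(c("m1", "m2"), "male", d0 - 2000)
  s <- rbind(mk_sightings("m1", 0:50, "A"), mk_sightings("m1", 51:120, "B"),
             mk_sightings("m1", 121:200, "C"),
             mk_sightings("m2", 0:200, "B"))
  iv <- build_membership_intervals(s, census)
  for (off in seq(0, 200, by = 13)) {
    for (id in c("m1", "m2")) {
      covering <- sum(iv$id == id & iv$start_date <= d0 + off &
                        (is.na(iv$end_date) | iv$end_date >= d0 + off))
      expect_lte(covering, 1L)
    }
  }
})

test_that("membership lookups respect closed-interval boundaries", {
  iv <- mk_intervals(c("m1", "m2"), "G", c(0, 20), c(9, 40))
  expect_true("m1" %in% members_on_date(iv, "G", d0 + 9))
  expect_false("m1" %in% members_on_date(iv, "G", d0 + 10))
  expect_identical(members_on_date(iv, "G", d0 + 5), "m1")
  expect_identical(members_on_date(iv, "G", d0 + 25), "m2")
})

test_that("tenure is an inclusive day count and 0 for non-members", {
  iv <- mk_intervals("m1", "G", 0, NA)
  expect_equal(tenure_on_date(iv, "m1", d0), 1L)
  expect_equal(tenure_on_date(iv, "m1", d0 + 99), 100L)
  expect_equal(tenure_on_date(iv, "m2", d0 + 5), 0L)
  expect_equal(tenure_on_date(iv, "m1", d0 - 1), 0L)
})

test_that("breeding composition counts members strictly older than 1250 days at onset", {
  season <- mk_season()
  ids <- c(sprintf("f%02d", 1:20), sprintf("m%02d", 1:10), "young", "edge")
  birth <- c(rep(d0 - 3000, 30), d0 - 1000, d0 - 1250)
  census <- mk_census(ids, c(rep("female", 20), rep("male", 12)), birth, natal = "G")
  iv <- mk_intervals(ids, "G", -1500, NA)
  iv$start_date <- pmax(iv$start_date, census$birth_date)
  comp <- breeding_group_composition("G", season, census, iv)
  expect_equal(unname(comp), c(20L, 10L))  # 1250 exactly and younger excluded
  census$birth_date[] <- d0 - 1000
  expect_equal(unname(breeding_group_composition("G", season, census, iv)), c(0L, 0L))
})

test_that("sex ratio averages daily counts over the mating season", {
  season <- mk_season(len = 100)
  ids <- c(sprintf("f%02d", 1:10), sprintf("m%02d", 1:10))
  census <- mk_census(ids, rep(c("female", "male"), each = 10), d0 - 3000, natal = "G")
  iv <- mk_intervals(ids, "G", -500, NA)
  expect_equal(group_sex_ratio("G", season, census, iv), 1.0)
  # 10 males first half, 5 males second half: mean males 7.5
  iv$end_date[16:20] <- d0 + 49
  expect_equal(group_sex_ratio("G", season, census, iv), 10 / 7.5)
  # no males at all -> undefined
  iv2 <- iv[1:10, ]
  expect_error(group_sex_ratio("G", season, census, iv2), "undefined")
})

test_that("daily composition matches brute-force per-day tabulation", {
  fx <- random_interval_fixture(n_males = 10, seed = 42)
  fem <- mk_census(sprintf("f%02d", 1:6), "female", d0 - sample(1300:4000, 6, TRUE))
  census <- rbind(fx$census, fem)
  iv <- rbind(fx$intervals, mk_intervals(fem$id, "A", -100, NA))
  season <- mk_season(len = 25)
  f <- m <- numeric(25)
  for (k in 1:25) {
    day <- d0 + k - 1
    mm <- oracle_mature_males(iv, census, "A", day)
    ids <- oracle_members(iv, "A", day)
    fem_ids <- ids[vapply(ids, function(id) census$sex[census$id == id] == "female", TRUE)]
    fem_ids <- fem_ids[vapply(fem_ids, function(id)
      as.integer(day - census$birth_date[census$id == id]) > 1250, TRUE)]
    f[k] <- length(fem_ids); m[k] <- length(mm)
  }
  expect_equal(group_sex_ratio("A", season, census, iv), mean(f) / mean(m))
})

test_that("cohort filtering logs every exclusion and conserves rows", {
  b <- data.frame(offspring = sprintf("o%d", 1:6), mother = "mom",
                  birth_date = d0, natal_group = c("A", "A", "A", "A", "Z", "A"))
  census <- rbind(
    mk_census("mom", "female", d0 - 4000),
    mk_census("o1", "female", d0, death = d0 + 100),                      # died < 1y
    mk_census("o2", "male", d0, death = d0 + 200, exit_type = "removal"), # removed < 1y
    mk_census("o3", "female", d0),                                       # ungenotyped
    mk_census("o4", "male", d0, death = d0 + 1000),
    mk_census("o5", "female", d0),                                       # fissioned group
    mk_census("o6", "male", d0))
  res <- filter_offspring_cohort(b, census, c("o1", "o2", "o4", "o5", "o6"), c("A", "B"))
  expect_equal(nrow(res$retained) + nrow(res$excluded), nrow(b))
  expect_setequal(res$retained$offspring, c("o4", "o6"))
  got <- setNames(res$excluded$reason, res$excluded$offspring)
  expect_equal(got[["o1"]], "died<1y")
  expect_equal(got[["o2"]], "removed<1y")
  expect_equal(got[["o3"]], "ungenotyped")
  expect_equal(got[["o5"]], "group_not_persistent")
})
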