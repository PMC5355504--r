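test_that("trio mismatch counting follows Mendelian exclusion per locus", {
  g <- mk_genotypes(list(
    off = list(c(1, 2)), mom = list(c(1, 1)), c1 = list(c(2, 3)), c2 = list(c(3, 3))))
  expect_equal(as.integer(trio_mismatch_count("off", "mom", "c1", g)), 0L)
  expect_equal(as.integer(trio_mismatch_count("off", "mom", "c2", g)), 1L)
})

test_that("maternal-mismatch loci are flagged and skipped for the sire count", {
  # locus 2: offspring shares no allele with the mother -> maternal, skipped
  g <- mk_genotypes(list(
    off = list(c(1, 2), c(5, 6)), mom = list(c(1, 1), c(7, 8)),
    cand = list(c(3, 3), c(9, 9))))
  mm <- trio_mismatch_count("off", "mom", "cand", g)
  expect_equal(as.integer(mm), 1L)
  expect_equal(attr(mm, "maternal_mismatch_loci"), 1L)
})

test_that("a planted 10-locus trio counts exactly its 3 inconsistent loci", {
  off <- rep(list(c(1, 2)), 10)
  mom <- rep(list(c(1, 1)), 10)
  cand <- rep(list(c(2, 4)), 10)
  cand[c(3, 6, 9)] <- list(c(5, 5))  # candidate lacks the paternal allele
  g <- mk_genotypes(list(off = off, mom = mom, cand = cand))
  expect_equal(as.integer(trio_mismatch_count("off", "mom", "cand", g)), 3L)
})

test_that("mismatch counts equal the brute-force oracle and ignore allele order", {
  set.seed(11)
  for (rep in 1:25) {
    L <- sample(5:15, 1)
    rand <- function() replicate(L, sample(1:6, 2, TRUE), simplify = FALSE)
    off <- rand(); mom <- rand(); cand <- rand()
    drop <- sample(L, sample(0:2, 1))
    for (i in drop) cand[i] <- list(NULL)
    g <- mk_genotypes(list(off = off, mom = mom, cand = cand))
    got <- as.integer(trio_mismatch_count("off", "mom", "cand", g))
    expect_equal(got, oracle_trio_mismatch(off, mom, cand))
    # swapping allele order anywhere never changes the count
    g2 <- g; tmp <- g2$allele1; g2$allele1 <- g2$allele2; g2$allele2 <- tmp
    expect_equal(as.integer(trio_mismatch_count("off", "mom", "cand", g2)), got)
  }
})

test_that("maternity is confirmed iff every joint locus shares an allele", {
  g <- mk_genotypes(list(off = rep(list(c(2, 2)), 27), mom = rep(list(c(2, 2)), 27)))
  expect_equal(as.character(confirm_maternity("off", "mom", g)), "confirmed")
  g2 <- mk_genotypes(list(off = c(rep(list(c(2, 2)), 26), list(c(3, 4))),
                          mom = rep(list(c(2, 2)), 27)))
  expect_equal(as.character(confirm_maternity("off", "mom", g2)), "mismatched")
})

test_that("candidate sires respect the age and presence boundaries", {
  bd <- d0  # conception reference = d0 - 200
  census <- rbind(
    mk_census("inc", "male", d0 - 200 - 1251),                 # 1251 days: included
    mk_census("edge", "male", d0 - 200 - 1250),                # exactly 1250: excluded
    mk_census("dead", "male", d0 - 4000, death = d0 - 250),    # gone before conception
    mk_census("justdied", "male", d0 - 4000, death = d0 - 200),# present on the day
    mk_census("f", "female", d0 - 4000))
  got <- candidate_sires(bd, census, census$id)
  expect_setequal(got, c("inc", "justdied"))
  expect_setequal(candidate_sires(bd, census, c("inc")), "inc")  # genotyped only
})

test_that("exclusion rules classify strict, relaxed, and one-mismatch assignments", {
  L <- 20
  mom <- rep(list(c(1, 1)), L)
  off <- rep(list(c(1, 2)), L)
  sire <- rep(list(c(2, 3)), L)       # compatible everywhere
  far <- rep(list(c(5, 6)), L)        # excluded at every locus
  near1 <- c(list(c(5, 5)), rep(list(c(2, 3)), L - 1))  # excluded at exactly 1
  g <- mk_genotypes(list(off = off, mom = mom, sire = sire, far = far, near1 = near1))
  pp <- paternity_params(min_joint_loci = 5)
  a <- assign_paternity("off", "mom", c("sire", "far"), g, pp)
  expect_equal(a$rule, "strict"); expect_equal(a$sire, "sire")
  a <- assign_paternity("off", "mom", c("sire", "far", "near1"), g, pp)
  expect_equal(a$rule, "relaxed"); expect_equal(a$sire, "sire")
  # sire with one mismatch, all others >= 2
  sire1 <- c(list(c(7, 7)), rep(list(c(2, 3)), L - 1))
  g2 <- mk_genotypes(list(off = off, mom = mom, sire1 = sire1, far = far))
  a <- assign_paternity("off", "mom", c("sire1", "far"), g2, pp)
  expect_equal(a$rule, "one_mismatch"); expect_equal(a$mismatches, 1L)
})

test_that("ambiguous configurations are never assigned", {
  L <- 20
  mom <- rep(list(c(1, 1)), L); off <- rep(list(c(1, 2)), L)
  twin1 <- rep(list(c(2, 3)), L); twin2 <- rep(list(c(2, 4)), L)
  g <- mk_genotypes(list(off = off, mom = mom, twin1 = twin1, twin2 = twin2))
  pp <- paternity_params(min_joint_loci = 5)
  a <- assign_paternity("off", "mom", c("twin1", "twin2"), g, pp)
  expect_equal(a$rule, "unassigned")
  expect_equal(a$reason, "tied_zero_mismatch")
  expect_equal(assign_paternity("off", "mom", character(0), g, pp)$reason,
               "no_candidates")
})

test_that("true sires are recovered by strict exclusion on an error-free pedigree", {
  cfg <- sim_config(n_cohorts = 1, seed = 31, emit_sightings = FALSE)
  sim <- simulate_egp_study(cfg)
  res <- assign_paternity_all(sim$births, sim$census, sim$genotypes)
  tt <- sim$truth[match(res$assignments$offspring, sim$truth$offspring), ]
  hit <- !is.na(res$assignments$sire) & res$assignments$sire == tt$true_sire
  expect_gte(mean(hit & res$assignments$rule == "strict"), 0.99)
})

test_that("genotyping error increases non-strict assignment rates monotonically", {
  rate_nonstrict <- function(e) {
    cfg <- sim_config(n_groups = 3, n_cohorts = 1, seed = 77,
                      genotyping_error = e, emit_sightings = FALSE)
    sim <- simulate_egp_study(cfg)
    res <- assign_paternity_all(sim$births, sim$census, sim$genotypes)
    mean(res$assignments$rule != "strict")
  }
  r <- vapply(c(0, 0.01, 0.05), rate_nonstrict, numeric(1))
  expect_lte(r[1], r[2])
  expect_lt(r[2], r[3])
  expect_lt(r[1], 0.02)
})
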