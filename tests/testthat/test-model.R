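mk_covariates <- function(seed = 1, n_groups = 6, n_cohorts = 9) {
  set.seed(seed)
  g <- expand.grid(group = LETTERS[1:n_groups], cohort = 2004:(2003 + n_cohorts),
                   stringsAsFactors = FALSE)
  n <- nrow(g)
  data.frame(g, n_offspring = rpois(n, 40) + 5L,
             size = rlnorm(n, log(80), 0.4), sex_ratio = rnorm(n, 1.6, 0.3),
             synchrony = runif(n, 0.08, 0.25), instability = rexp(n, 2000),
             overlap = rlnorm(n, 1, 0.4), egp_count = rpois(n, 5))
}

test_that("the model table z-scores predictors and attaches both log offsets", {
  cov <- mk_covariates()
  tab <- build_model_table(cov)
  expect_equal(nrow(tab), 54L)
  for (v in c("z_sex_ratio", "z_group_size", "z_synchrony", "z_instability")) {
    expect_equal(mean(tab[[v]]), 0, tolerance = 1e-10)
    expect_equal(sd(tab[[v]]), 1, tolerance = 1e-10)
  }
  expect_equal(tab$log_n_offspring, log(cov$n_offspring))
  expect_equal(tab$log_overlap, log(cov$overlap))
  expect_equal(attr(tab, "scaling")$mean[1], mean(cov$sex_ratio))
})

test_that("degenerate model tables are rejected with the offending row named", {
  cov <- mk_covariates()
  cov$synchrony <- 0.15
  expect_error(build_model_table(cov), "constant predictor")
  cov <- mk_covariates()
  cov$overlap[cov$group == "C" & cov$cohort == 2006] <- 0
  expect_error(build_model_table(cov), "C 2006")
  cov <- mk_covariates()
  cov$n_offspring[2] <- 0
  expect_error(build_model_table(cov), "n_offspring")
  cov <- mk_covariates()
  cov$egp_count[1] <- cov$n_offspring[1] + 1L
  expect_error(build_model_table(cov), "exceeds")
})

test_that("offsets carry unit coefficients: scaling exposure shifts only the intercept", {
  tab <- simulate_model_table(seed = 42, beta = c(intercept = -2.3, sex_ratio = 0.3,
                                                  group_size = 0, synchrony = -0.4,
                                                  instability = 0, interaction = 0))
  f1 <- fit_egp_glmm(tab, include_random_slopes = FALSE)
  tab2 <- tab
  tab2$log_n_offspring <- log(3 * tab$n_offspring)
  f2 <- fit_egp_glmm(tab2, include_random_slopes = FALSE)
  est <- function(f, term) f$fixed$estimate[f$fixed$term == term]
  expect_equal(est(f2, "(Intercept)"), est(f1, "(Intercept)") - log(3), tolerance = 1e-4)
  expect_equal(est(f2, "z_synchrony"), est(f1, "z_synchrony"), tolerance = 1e-4)
})

test_that("fixed effects match an independent Poisson GLM when variance collapses", {
  # with near-zero random-effect variance the GLMM estimates should agree
  # with a plain fixed-effects Poisson regression on the same rows
  tab <- simulate_model_table(seed = 7, re_sd = c(group = 0, cohort = 0),
                              beta = c(intercept = -2.3, sex_ratio = 0.35,
                                       group_size = -0.3, synchrony = -0.4,
                                       instability = -0.2, interaction = 0.25))
  f <- fit_egp_glmm(tab, include_random_slopes = FALSE)
  ref <- glm(egp_count ~ z_sex_ratio * z_group_size + z_synchrony + z_instability +
               offset(log_n_offspring) + offset(log_overlap),
             family = poisson, data = tab)
  for (term in c("z_sex_ratio", "z_group_size", "z_synchrony", "z_instability")) {
    expect_equal(f$fixed$estimate[f$fixed$term == term],
                 unname(coef(ref)[term]), tolerance = 1e-3)
  }
})

test_that("a known effect is recovered and the full-vs-null LRT detects it", {
  tab <- simulate_model_table(n_groups = 12, n_cohorts = 18, seed = 99,
                              beta = c(intercept = -2.3, sex_ratio = 0,
                                       group_size = 0, synchrony = -0.4,
                                       instability = 0, interaction = 0))
  f <- fit_egp_glmm(tab, include_random_slopes = FALSE)
  est <- f$fixed$estimate[f$fixed$term == "z_synchrony"]
  expect_lt(abs(est - (-0.4)), 0.1)
  lrt <- lrt_full_vs_null(tab, include_random_slopes = FALSE)
  expect_equal(lrt$df, 5L)
  expect_lt(lrt$p, 0.05)
  expect_gte(lrt$chi2, 0)
})

test_that("drop1 tests the interaction in the full model and mains at 1 df each", {
  tab <- simulate_model_table(seed = 12)
  d1 <- drop1_lrts(tab, include_random_slopes = FALSE)
  expect_equal(nrow(d1), 5L)
  expect_true(all(d1$df == 1L))
  expect_true(all(d1$chi2 >= 0))
  expect_equal(d1$model[d1$term == "z_sex_ratio:z_group_size"], "full")
  expect_setequal(d1$model[d1$term != "z_sex_ratio:z_group_size"], "reduced")
})

test_that("the dispersion parameter is calibrated and ordered by true variance", {
  set.seed(5)
  disp_pois <- disp_nb <- numeric(8)
  for (r in 1:8) {
    tab <- simulate_model_table(seed = 100 + r, re_sd = c(group = 0, cohort = 0))
    f <- fit_egp_glmm(tab, include_random_slopes = FALSE)
    disp_pois[r] <- f$dispersion
    tab$egp_count <- rnbinom(nrow(tab), size = 2, mu = pmax(exp(
      -2.6 + tab$log_n_offspring + tab$log_overlap), 0.1))
    fnb <- fit_egp_glmm(tab, include_random_slopes = FALSE)
    disp_nb[r] <- fnb$dispersion
  }
  expect_equal(mean(disp_pois), 1, tolerance = 0.25)
  expect_gt(mean(disp_nb), mean(disp_pois))
})

test_that("variance inflation factors follow the closed form", {
  set.seed(33)
  n <- 500
  base <- data.frame(z_sex_ratio = rnorm(n), z_group_size = rnorm(n),
                     z_synchrony = rnorm(n), z_instability = rnorm(n))
  v <- vif_check(base)
  expect_true(all(abs(v - 1) < 1.1e-1))  # orthogonal in expectation
  # plant r = 0.8 between two predictors: their VIF -> 1/(1 - 0.64)
  x <- rnorm(n)
  cor08 <- base
  cor08$z_sex_ratio <- x
  cor08$z_group_size <- 0.8 * x + sqrt(1 - 0.64) * rnorm(n)
  v <- vif_check(cor08)
  r2 <- summary(lm(z_group_size ~ z_sex_ratio + z_synchrony + z_instability,
                   data = cor08))$r.squared
  expect_equal(unname(v["z_group_size"]), 1 / (1 - r2), tolerance = 1e-10)
  expect_equal(unname(v["z_group_size"]), 1 / (1 - 0.64), tolerance = 0.35)
  # agreement with the standard implementation on the same fixed-effects model
  if (requireNamespace("car", quietly = TRUE)) {
    cor08$y <- rnorm(n)
    ref <- car::vif(lm(y ~ z_sex_ratio + z_group_size + z_synchrony + z_instability,
                       data = cor08))
    expect_equal(unname(v), unname(ref[names(v)]), tolerance = 1e-8)
  }
  coll <- base
  coll$z_group_size <- 2 * coll$z_sex_ratio
  expect_error(vif_check(coll), "collinear")
})

test_that("leave-one-out stability refits every group and cohort subset", {
  tab <- simulate_model_table(seed = 3, beta = c(intercept = -2.5, sex_ratio = 0.3,
                                                 group_size = 0, synchrony = -0.4,
                                                 instability = 0, interaction = 0))
  st <- stability_check(tab, include_random_slopes = FALSE)
  expect_equal(length(unique(st$estimates$excluded)), 6 + 9)
  expect_equal(sum(startsWith(unique(st$estimates$excluded), "group:")), 6L)
  # leaving out a group removes exactly n_cohorts rows
  expect_equal(sum(tab$group != "G1"), 54L - 9L)
  # homogeneous data: every subset estimate stays near the full-data fit
  full <- fit_egp_glmm(tab, include_random_slopes = FALSE)
  se <- full$fixed$se[full$fixed$term == "z_synchrony"]
  est <- st$estimates$estimate[st$estimates$term == "z_synchrony"]
  expect_true(all(abs(est - full$fixed$estimate[full$fixed$term == "z_synchrony"]) < 2 * se))
})

test_that("random-slope and null specifications build the advertised formulas", {
  tab <- simulate_model_table(seed = 2)
  f <- fit_egp_glmm(tab, include_random_slopes = TRUE)
  expect_s3_class(f, "egp_glmm")
  expect_true(f$dispersion > 0)
  vc <- f$varcomp
  expect_equal(nrow(vc), 10L)  # 2 intercepts + 4 slopes x 2 factors
  fn <- fit_egp_glmm(tab, null_model = TRUE, include_random_slopes = TRUE)
  expect_identical(fn$fixed$term, "(Intercept)")  # no fixed test predictors
  expect_equal(nrow(fn$varcomp), 10L)  # null keeps slopes and offsets
})
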