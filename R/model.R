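## Poisson mixed model for extra-group paternity counts.
##
## Response: EGP count per group-season. Fixed effects: z-scored sex ratio,
## group size, their interaction, synchrony, instability. Offsets: log total
## offspring born and log home-range overlap (coefficients fixed at 1).
## Random effects: intercepts for group and cohort plus, optionally, an
## uncorrelated random slope for each main effect within each random effect.
## Estimation is maximum likelihood (Laplace approximation, lme4::glmer) so
## that likelihood-ratio tests on fixed effects are valid.

.predictor_cols <- c("z_sex_ratio", "z_group_size", "z_synchrony", "z_instability")

#' Build the group-season model table
#'
#' Aggregates EGP counts per group-season, z-transforms the four predictors
#' (mean 0, SD 1 across rows), and attaches the two log offsets. Original
#' predictor means/SDs are kept in the `"scaling"` attribute.
#'
#' @param covariates `data.frame` with one row per group-season and columns
#'   `group, cohort, n_offspring, size, sex_ratio, synchrony, instability,
#'   overlap`.
#' @param classifications Optional classification `data.frame` (from
#'   [classify_egp_all()]) plus `births` to count EGP per group-season; or
#'   supply counts directly via an `egp_count` column in `covariates`.
#' @param births Births table (required with `classifications`).
#' @return A `data.frame` of class `"egp_model_table"` with `egp_count`,
#'   z-scored predictors, `log_n_offspring`, `log_overlap`, and factor
#'   columns `group`, `cohort`.
#' @export
build_model_table <- function(covariates, classifications = NULL, births = NULL) {
  need <- c("group", "cohort", "n_offspring", "size", "sex_ratio",
            "synchrony", "instability", "overlap")
  stopifnot(all(need %in% names(covariates)))
  tab <- covariates
  if (!is.null(classifications)) {
    stopifnot(!is.null(births))
    idx <- match(classifications$offspring, births$offspring)
    grp <- births$natal_group[idx]
    coh <- if ("cohort" %in% names(births)) births$cohort[idx]
           else as.integer(format(.as_date(births$birth_date[idx], "birth_date"), "%Y"))
    key <- paste(tab$group, tab$cohort, sep = "\r")
    cnt <- tapply(classifications$status == "extra_group",
                  paste(grp, coh, sep = "\r"), sum)
    tab$egp_count <- as.integer(cnt[key])
    tab$egp_count[is.na(tab$egp_count)] <- 0L
  }
  stopifnot("egp_count" %in% names(tab))
  rowname <- paste(tab$group, tab$cohort)
  bad <- tab$n_offspring <= 0
  if (any(bad)) stop("build_model_table: n_offspring must be positive (row ",
                     paste(rowname[bad], collapse = ", "), ")", call. = FALSE)
  bad <- tab$overlap <= 0
  if (any(bad)) stop("build_model_table: overlap must be positive (row ",
                     paste(rowname[bad], collapse = ", "), ")", call. = FALSE)
  if (any(tab$egp_count > tab$n_offspring)) {
    stop("build_model_table: egp_count exceeds n_offspring", call. = FALSE)
  }
  src <- c(z_sex_ratio = "sex_ratio", z_group_size = "size",
           z_synchrony = "synchrony", z_instability = "instability")
  scaling <- data.frame(predictor = unname(src),
                        mean = vapply(src, function(v) mean(tab[[v]]), numeric(1)),
                        sd = vapply(src, function(v) stats::sd(tab[[v]]), numeric(1)))
  if (any(scaling$sd == 0)) {
    stop("build_model_table: constant predictor(s): ",
         paste(scaling$predictor[scaling$sd == 0], collapse = ", "), call. = FALSE)
  }
  for (k in names(src)) tab[[k]] <- (tab[[src[[k]]]] - mean(tab[[src[[k]]]])) / stats::sd(tab[[src[[k]]]])
  tab$log_n_offspring <- log(tab$n_offspring)
  tab$log_overlap <- log(tab$overlap)
  tab$group <- factor(tab$group)
  tab$cohort <- factor(tab$cohort)
  out <- tab[, c("group", "cohort", "egp_count", .predictor_cols,
                 "log_n_offspring", "log_overlap", "n_offspring", "overlap")]
  attr(out, "scaling") <- scaling
  class(out) <- c("egp_model_table", "data.frame")
  out
}

.egp_formula <- function(include_interaction, include_random_slopes, null_model) {
  fixed <- if (null_model) "1" else {
    paste(c(.predictor_cols,
            if (include_interaction) "z_sex_ratio:z_group_size"), collapse = " + ")
  }
  re <- c("(1 | group)", "(1 | cohort)")
  if (include_random_slopes) {
    re <- c(re,
            sprintf("(0 + %s | group)", .predictor_cols),
            sprintf("(0 + %s | cohort)", .predictor_cols))
  }
  stats::as.formula(paste("egp_count ~", fixed,
                          "+ offset(log_n_offspring) + offset(log_overlap) +",
                          paste(re, collapse = " + ")))
}

#' Fit the Poisson mixed model for EGP counts
#'
#' @param table An [build_model_table()] result.
#' @param include_interaction Include the sex ratio x group size interaction.
#'   Default `TRUE` (set `FALSE` for the reduced model).
#' @param include_random_slopes Include an uncorrelated random slope for each
#'   main effect within group and within cohort. Default `TRUE` (set `FALSE`
#'   for the intercept-only variant).
#' @param null_model Drop all fixed effects but keep random effects, random
#'   slopes, and offsets. Default `FALSE`.
#' @param control A [lme4::glmerControl()] object; defaults to the bobyqa
#'   optimizer.
#' @return An object of class `"egp_glmm"`: list with the `lme4` fit
#'   (`model`), `fixed` coefficient table, `varcomp`, `logLik`, `dispersion`,
#'   `converged`, `singular`, and the configuration flags. Non-convergence is
#'   flagged, never silently dropped.
#' @export
fit_egp_glmm <- function(table, include_interaction = TRUE,
                         include_random_slopes = TRUE, null_model = FALSE,
                         control = lme4::glmerControl(optimizer = "bobyqa")) {
  stopifnot(is.data.frame(table))
  if (nlevels(droplevels(table$group)) < 2L || nlevels(droplevels(table$cohort)) < 2L) {
    stop("fit_egp_glmm: need >= 2 levels of group and cohort", call. = FALSE)
  }
  form <- .egp_formula(include_interaction, include_random_slopes, null_model)
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(form, data = table, family = stats::poisson(link = "log"),
                control = control)))
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  converged <- fit@optinfo$conv$opt == 0 &&
    !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  co <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(model = fit, formula = form,
                 fixed = data.frame(term = rownames(co), estimate = co[, 1],
                                    se = co[, 2], z = co[, 3],
                                    row.names = NULL),
                 varcomp = vc[, c("grp", "var1", "vcov", "sdcor")],
                 logLik = as.numeric(stats::logLik(fit)),
                 dispersion = dispersion_parameter(fit),
                 converged = converged,
                 singular = lme4::isSingular(fit),
                 include_interaction = include_interaction,
                 include_random_slopes = include_random_slopes,
                 null_model = null_model),
            class = "egp_glmm")
}

#' @export
print.egp_glmm <- function(x, ...) {
  cat("Poisson GLMM for EGP counts",
      if (x$null_model) "(null model)" else
        if (x$include_interaction) "(full model)" else "(reduced model)",
      "\n")
  cat(sprintf("random slopes: %s | converged: %s | singular: %s | dispersion: %.3f\n",
              x$include_random_slopes, x$converged, x$singular, x$dispersion))
  print(x$fixed, digits = 3)
  invisible(x)
}

.loglik <- function(x) if (inherits(x, "egp_glmm")) x$logLik else as.numeric(stats::logLik(x))

#' Likelihood-ratio test of the full model against the null model
#'
#' The null model retains only random effects, random slopes, and offsets;
#' the test statistic is twice the log-likelihood difference with df equal to
#' the number of dropped fixed effects (5 with the interaction, 4 without).
#'
#' @inheritParams fit_egp_glmm
#' @return `data.frame(chi2, df, p)`, with the two fits in attributes
#'   `full` and `null`.
#' @export
lrt_full_vs_null <- function(table, include_interaction = TRUE,
                             include_random_slopes = TRUE,
                             control = lme4::glmerControl(optimizer = "bobyqa")) {
  full <- fit_egp_glmm(table, include_interaction, include_random_slopes,
                       null_model = FALSE, control = control)
  null <- fit_egp_glmm(table, include_interaction, include_random_slopes,
                       null_model = TRUE, control = control)
  df <- 4L + as.integer(include_interaction)
  chi2 <- max(0, 2 * (full$logLik - null$logLik))
  out <- data.frame(chi2 = chi2, df = df,
                    p = stats::pchisq(chi2, df, lower.tail = FALSE))
  attr(out, "full") <- full
  attr(out, "null") <- null
  out
}

#' Per-term likelihood-ratio tests
#'
#' The interaction is tested by dropping it from the full model. Main effects
#' are tested within the reduced (interaction-free) model, where their
#' estimates are interpretable, by dropping each in turn; every test has 1
#' df.
#'
#' @inheritParams fit_egp_glmm
#' @return `data.frame(term, model, chi2, df, p)`.
#' @export
drop1_lrts <- function(table, include_interaction = TRUE,
                       include_random_slopes = TRUE,
                       control = lme4::glmerControl(optimizer = "bobyqa")) {
  refit_without <- function(base_form, term) {
    form <- stats::update(base_form, paste(". ~ . -", term))
    suppressMessages(suppressWarnings(
      lme4::glmer(form, data = table, family = stats::poisson(link = "log"),
                  control = control)))
  }
  rows <- list()
  reduced <- fit_egp_glmm(table, include_interaction = FALSE,
                          include_random_slopes = include_random_slopes,
                          control = control)
  if (include_interaction) {
    full <- fit_egp_glmm(table, include_interaction = TRUE,
                         include_random_slopes = include_random_slopes,
                         control = control)
    chi2 <- max(0, 2 * (full$logLik - reduced$logLik))
    rows[["interaction"]] <- data.frame(term = "z_sex_ratio:z_group_size",
                                        model = "full", chi2 = chi2, df = 1L,
                                        p = stats::pchisq(chi2, 1L, lower.tail = FALSE))
  }
  for (term in .predictor_cols) {
    sub <- refit_without(reduced$formula, term)
    chi2 <- max(0, 2 * (reduced$logLik - .loglik(sub)))
    rows[[term]] <- data.frame(term = term, model = "reduced", chi2 = chi2,
                               df = 1L,
                               p = stats::pchisq(chi2, 1L, lower.tail = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dispersion parameter of a Poisson mixed model
#'
#' Sum of squared Pearson residuals over residual degrees of freedom
#' (observations minus fixed-effect and variance parameters). Values above 1
#' indicate overdispersion.
#'
#' @param fit An `"egp_glmm"` object or an `lme4` fit.
#' @return Numeric dispersion ratio.
#' @export
dispersion_parameter <- function(fit) {
  m <- if (inherits(fit, "egp_glmm")) fit$model else fit
  r <- stats::residuals(m, type = "pearson")
  sum(r^2) / stats::df.residual(m)
}

#' Variance inflation factors of the model-table predictors
#'
#' VIF_j = 1 / (1 - R^2_j) where R^2_j comes from regressing predictor j on
#' the other three — the design-based VIF of the fixed-effects-only,
#' interaction-free model. Near-perfect collinearity is an error.
#'
#' @param table An [build_model_table()] result (or any data.frame with the
#'   four z-scored predictor columns).
#' @return Named numeric vector of VIFs.
#' @export
vif_check <- function(table) {
  X <- as.data.frame(table)[, .predictor_cols]
  out <- vapply(.predictor_cols, function(v) {
    r2 <- suppressWarnings(
      summary(stats::lm(stats::reformulate(setdiff(.predictor_cols, v), v),
                        data = X))$r.squared)
    if (r2 > 1 - 1e-10) {
      stop("vif_check: predictor ", v, " is collinear with the others (R^2 ~ 1)",
           call. = FALSE)
    }
    1 / (1 - r2)
  }, numeric(1))
  out
}

#' Leave-one-out stability of the fixed effects
#'
#' Refits the model excluding each group and each cohort in turn and collects
#' the fixed-effect estimates, the standard check that no single group or
#' cohort drives the result.
#'
#' @inheritParams fit_egp_glmm
#' @return `list(estimates = data.frame(excluded, term, estimate), range =
#'   data.frame(term, min, max, full))`.
#' @export
stability_check <- function(table, include_interaction = TRUE,
                            include_random_slopes = TRUE,
                            control = lme4::glmerControl(optimizer = "bobyqa")) {
  full <- fit_egp_glmm(table, include_interaction, include_random_slopes,
                       control = control)
  subsets <- c(stats::setNames(as.list(levels(droplevels(table$group))),
                               paste0("group:", levels(droplevels(table$group)))),
               stats::setNames(as.list(levels(droplevels(table$cohort))),
                               paste0("cohort:", levels(droplevels(table$cohort)))))
  rows <- list()
  for (nm in names(subsets)) {
    lev <- subsets[[nm]]
    keep <- if (startsWith(nm, "group:")) table$group != lev else table$cohort != lev
    sub <- table[keep, , drop = FALSE]
    sub$group <- droplevels(sub$group); sub$cohort <- droplevels(sub$cohort)
    f <- fit_egp_glmm(sub, include_interaction, include_random_slopes,
                      control = control)
    rows[[nm]] <- data.frame(excluded = nm, term = f$fixed$term,
                             estimate = f$fixed$estimate)
  }
  est <- do.call(rbind, rows)
  rownames(est) <- NULL
  rng <- do.call(rbind, lapply(unique(est$term), function(tm) {
    data.frame(term = tm, min = min(est$estimate[est$term == tm]),
               max = max(est$estimate[est$term == tm]),
               full = full$fixed$estimate[full$fixed$term == tm])
  }))
  list(estimates = est, range = rng)
}

#' Simulate a group-season model table from the Poisson mixed model
#'
#' Draws covariates, offsets, and EGP counts directly at the group-season
#' level — the test harness for parameter recovery, interval coverage, and
#' LRT calibration, bypassing the individual-based generator.
#'
#' @param n_groups,n_cohorts Design size. Defaults 6 and 9.
#' @param beta Fixed effects on the log scale, named `intercept, sex_ratio,
#'   group_size, synchrony, instability, interaction`.
#' @param re_sd Random-intercept SDs, named `group` and `cohort`.
#' @param mean_offspring Mean of the Poisson draw for offspring born per
#'   group-season. Default 40.
#' @param seed Optional integer seed.
#' @return An `"egp_model_table"` with a `"truth"` attribute holding `beta`.
#' @export
simulate_model_table <- function(n_groups = 6L, n_cohorts = 9L,
                                 beta = c(intercept = -2.6, sex_ratio = 0,
                                          group_size = 0, synchrony = 0,
                                          instability = 0, interaction = 0),
                                 re_sd = c(group = 0.15, cohort = 0.15),
                                 mean_offspring = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_groups * n_cohorts
  grid <- expand.grid(group = paste0("G", seq_len(n_groups)),
                      cohort = seq_len(n_cohorts))
  z <- matrix(stats::rnorm(n * 4), n, 4)
  z <- scale(z)  # exact mean 0 / sd 1, as build_model_table guarantees
  n_off <- pmax(5L, stats::rpois(n, mean_offspring))
  ovl <- exp(stats::rnorm(n, 0, 0.3))
  bg <- stats::rnorm(n_groups, 0, re_sd[["group"]])[as.integer(factor(grid$group))]
  bc <- stats::rnorm(n_cohorts, 0, re_sd[["cohort"]])[grid$cohort]
  eta <- beta[["intercept"]] + z %*% beta[c("sex_ratio", "group_size", "synchrony",
                                            "instability")] +
    beta[["interaction"]] * z[, 1] * z[, 2] + log(n_off) + log(ovl) + bg + bc
  y <- stats::rpois(n, exp(eta))
  out <- data.frame(group = factor(grid$group), cohort = factor(grid$cohort),
                    egp_count = y, z_sex_ratio = z[, 1], z_group_size = z[, 2],
                    z_synchrony = z[, 3], z_instability = z[, 4],
                    log_n_offspring = log(n_off), log_overlap = log(ovl),
                    n_offspring = n_off, overlap = ovl)
  attr(out, "truth") <- beta
  class(out) <- c("egp_model_table", "data.frame")
  out
}
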