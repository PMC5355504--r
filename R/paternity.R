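## Exclusion-based parentage assignment over a microsatellite panel.
## A candidate sire mismatches a mother-offspring dyad at a locus when no
## Mendelian assignment of the offspring's two alleles (one maternal, one
## paternal) is possible. Loci where the offspring shares no allele with the
## mother are attributed to maternity and skipped in sire counts: maternity
## is confirmed first and only confirmed dyads enter the paternity analysis.

#' Parameters for candidate-sire filtering and exclusion assignment
#'
#' @param min_sire_age_days Candidate sires must be strictly older than this
#'   (in days) at the conception reference date. Default 1250.
#' @param presence_before_birth_days Candidates must be alive/on-island this
#'   many days before the offspring's birth (the conception reference date).
#'   Default 200.
#' @param min_joint_loci Minimum number of loci jointly typed in offspring,
#'   mother, and candidate for the candidate to be evaluable. Default 13
#'   (half the typical panel).
#' @return A list of class `"paternity_params"`.
#' @export
paternity_params <- function(min_sire_age_days = 1250L,
                             presence_before_birth_days = 200L,
                             min_joint_loci = 13L) {
  stopifnot(min_sire_age_days > 0, presence_before_birth_days > 0,
            min_joint_loci > 0)
  structure(list(min_sire_age_days = as.integer(min_sire_age_days),
                 presence_before_birth_days = as.integer(presence_before_birth_days),
                 min_joint_loci = as.integer(min_joint_loci)),
            class = "paternity_params")
}

#' Read a long-format genotype table
#'
#' Expects columns `id,locus,allele1,allele2` with positive integer allele
#' codes; one row per typed locus, missing loci simply absent.
#'
#' @param path Path to a CSV file.
#' @return A genotype `data.frame`.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_headers(df, c("id", "locus", "allele1", "allele2"), "genotypes")
  validate_genotypes(df)
}

#' @keywords internal
validate_genotypes <- function(genotypes) {
  stopifnot(all(c("id", "locus", "allele1", "allele2") %in% names(genotypes)))
  genotypes$allele1 <- as.integer(genotypes$allele1)
  genotypes$allele2 <- as.integer(genotypes$allele2)
  if (any(is.na(genotypes$allele1)) || any(is.na(genotypes$allele2)) ||
      any(genotypes$allele1 <= 0L) || any(genotypes$allele2 <= 0L)) {
    stop("genotypes: alleles must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(genotypes[c("id", "locus")])) {
    stop("genotypes: duplicated (id, locus) rows", call. = FALSE)
  }
  genotypes
}

## individuals x loci allele matrices (NA = untyped); cached layout used by
## all vectorized comparisons.
.genotype_matrices <- function(genotypes) {
  genotypes <- validate_genotypes(genotypes)
  ids <- unique(genotypes$id)
  loci <- sort(unique(genotypes$locus))
  ri <- match(genotypes$id, ids)
  ci <- match(genotypes$locus, loci)
  a1 <- a2 <- matrix(NA_integer_, nrow = length(ids), ncol = length(loci),
                     dimnames = list(ids, loci))
  a1[cbind(ri, ci)] <- genotypes$allele1
  a2[cbind(ri, ci)] <- genotypes$allele2
  list(a1 = a1, a2 = a2, ids = ids, loci = loci)
}

.geno_row <- function(gm, id) {
  if (!id %in% gm$ids) return(NULL)
  rbind(gm$a1[id, ], gm$a2[id, ])
}

#' Count sire-exclusion loci for a mother-offspring-candidate trio
#'
#' At each locus jointly typed in all three, the trio is Mendelian-consistent
#' when some ordering assigns one offspring allele to the mother and the
#' other to the candidate. Loci where the offspring shares no allele with the
#' mother are maternal mismatches: they are skipped for the sire count and
#' reported in the `"maternal_mismatch_loci"` attribute.
#'
#' @param offspring,mother,candidate Individual ids.
#' @param genotypes Long-format genotype `data.frame`.
#' @return Integer count of sire-exclusion loci, with attributes
#'   `n_joint_loci` and `maternal_mismatch_loci`.
#' @export
trio_mismatch_count <- function(offspring, mother, candidate, genotypes) {
  gm <- .genotype_matrices(genotypes)
  o <- .geno_row(gm, offspring); m <- .geno_row(gm, mother); p <- .geno_row(gm, candidate)
  if (is.null(o) || is.null(m) || is.null(p)) {
    stop("trio_mismatch_count: all three individuals must be genotyped", call. = FALSE)
  }
  joint <- !is.na(o[1, ]) & !is.na(m[1, ]) & !is.na(p[1, ])
  if (!any(joint)) stop("trio_mismatch_count: zero jointly typed loci", call. = FALSE)
  o1 <- o[1, joint]; o2 <- o[2, joint]
  o1m <- o1 == m[1, joint] | o1 == m[2, joint]
  o2m <- o2 == m[1, joint] | o2 == m[2, joint]
  o1c <- o1 == p[1, joint] | o1 == p[2, joint]
  o2c <- o2 == p[1, joint] | o2 == p[2, joint]
  maternal_mm <- !(o1m | o2m)
  consistent <- (o1m & o2c) | (o2m & o1c)
  n <- sum(!consistent & !maternal_mm)
  structure(as.integer(n),
            n_joint_loci = sum(joint),
            maternal_mismatch_loci = sum(maternal_mm))
}

#' Genetically confirm a behavioural maternity
#'
#' Confirmed when the mother shares at least one allele with the offspring at
#' every jointly typed locus (at most `max_mismatch_loci` conflicting loci).
#'
#' @param offspring,mother Individual ids.
#' @param genotypes Long-format genotype `data.frame`.
#' @param max_mismatch_loci Tolerated conflicting loci. Default 0.
#' @return `"confirmed"` or `"mismatched"`, with attribute `mismatch_loci`.
#' @export
confirm_maternity <- function(offspring, mother, genotypes, max_mismatch_loci = 0L) {
  gm <- .genotype_matrices(genotypes)
  o <- .geno_row(gm, offspring); m <- .geno_row(gm, mother)
  if (is.null(o) || is.null(m)) {
    stop("confirm_maternity: offspring and mother must be genotyped", call. = FALSE)
  }
  joint <- !is.na(o[1, ]) & !is.na(m[1, ])
  if (!any(joint)) stop("confirm_maternity: zero jointly typed loci", call. = FALSE)
  share <- (o[1, joint] == m[1, joint]) | (o[1, joint] == m[2, joint]) |
    (o[2, joint] == m[1, joint]) | (o[2, joint] == m[2, joint])
  mm <- sum(!share)
  structure(if (mm <= max_mismatch_loci) "confirmed" else "mismatched",
            mismatch_loci = mm)
}

#' Candidate sires for an offspring
#'
#' Genotyped males strictly older than `min_sire_age_days` at the conception
#' reference date (`birth_date - presence_before_birth_days`) and alive /
#' on-island on that date.
#'
#' @param birth_date Offspring birth date.
#' @param census Census `data.frame`.
#' @param genotyped_ids Ids with genotype data.
#' @param params A [paternity_params()] object.
#' @return Character vector of male ids.
#' @export
candidate_sires <- function(birth_date, census, genotyped_ids,
                            params = paternity_params()) {
  birth_date <- .as_date(birth_date, "birth_date")
  ref <- birth_date - params$presence_before_birth_days
  males <- census[census$sex == "male", , drop = FALSE]
  age <- as.integer(ref - males$birth_date)
  alive <- males$birth_date <= ref & (is.na(males$death_date) | males$death_date >= ref)
  ok <- alive & age > params$min_sire_age_days & males$id %in% genotyped_ids
  males$id[ok]
}

## Mismatch counts of every candidate against one dyad, vectorized over the
## candidate x locus grid. Returns NA for candidates below min_joint_loci.
.candidate_mismatches <- function(gm, offspring, mother, candidates, min_joint_loci) {
  o <- .geno_row(gm, offspring); m <- .geno_row(gm, mother)
  joint_om <- !is.na(o[1, ]) & !is.na(m[1, ])
  o1 <- o[1, ]; o2 <- o[2, ]
  o1m <- o1 == m[1, ] | o1 == m[2, ]
  o2m <- o2 == m[1, ] | o2 == m[2, ]
  maternal_mm <- joint_om & !(o1m | o2m)
  cand <- intersect(candidates, gm$ids)
  c1 <- gm$a1[cand, , drop = FALSE]; c2 <- gm$a2[cand, , drop = FALSE]
  O1 <- matrix(o1, nrow = length(cand), ncol = ncol(c1), byrow = TRUE)
  O2 <- matrix(o2, nrow = length(cand), ncol = ncol(c1), byrow = TRUE)
  o1c <- O1 == c1 | O1 == c2
  o2c <- O2 == c1 | O2 == c2
  okrow <- matrix(joint_om & !maternal_mm, nrow = length(cand), ncol = ncol(c1), byrow = TRUE)
  typed <- okrow & !is.na(c1)
  consistent <- (matrix(o1m, nrow(typed), ncol(typed), byrow = TRUE) & o2c) |
    (matrix(o2m, nrow(typed), ncol(typed), byrow = TRUE) & o1c)
  mm <- rowSums(typed & !consistent, na.rm = TRUE)
  njoint <- rowSums(typed)
  mm[njoint < min_joint_loci] <- NA_integer_
  stats::setNames(as.integer(mm), cand)
}

#' Assign paternity to one offspring by exclusion
#'
#' The unique candidate with minimal mismatches (0 or 1) against the
#' confirmed mother-offspring dyad is assigned, classified as:
#' `strict` (sire 0 mismatches, every other candidate excluded by >= 2 loci),
#' `relaxed` (sire 0, some other candidate excluded by exactly 1 locus, none
#' unexcluded), or `one_mismatch` (sire exactly 1, all others >= 2).
#' Ties and all other configurations return `unassigned`; the analysis never
#' assigns on ambiguity. Candidates typed on fewer than `min_joint_loci`
#' shared loci are unevaluable and set aside (counted, not compared).
#'
#' @param offspring,mother Individual ids.
#' @param candidates Character vector of candidate male ids.
#' @param genotypes Long-format genotype `data.frame`.
#' @param params A [paternity_params()] object.
#' @return A list with `offspring`, `sire` (NA if unassigned), `rule`
#'   (`strict`/`relaxed`/`one_mismatch`/`unassigned`), `mismatches`,
#'   `n_candidates`, `n_unevaluable`, `reason`, and the per-candidate
#'   `candidate_mismatches` vector.
#' @export
assign_paternity <- function(offspring, mother, candidates, genotypes,
                             params = paternity_params()) {
  gm <- if (is.list(genotypes) && !is.data.frame(genotypes) &&
            all(c("a1", "a2", "ids") %in% names(genotypes))) genotypes
        else .genotype_matrices(genotypes)
  base <- list(offspring = offspring, sire = NA_character_, rule = "unassigned",
               mismatches = NA_integer_, n_candidates = length(candidates),
               n_unevaluable = 0L, reason = NA_character_,
               candidate_mismatches = stats::setNames(integer(0), character(0)))
  if (!length(candidates)) { base$reason <- "no_candidates"; return(base) }
  if (!offspring %in% gm$ids || !mother %in% gm$ids) {
    base$reason <- "dyad_ungenotyped"; return(base)
  }
  mm <- .candidate_mismatches(gm, offspring, mother, candidates, params$min_joint_loci)
  base$n_unevaluable <- length(candidates) - sum(!is.na(mm))
  mm <- mm[!is.na(mm)]
  base$candidate_mismatches <- mm
  if (!length(mm)) { base$reason <- "no_evaluable_candidates"; return(base) }
  zero <- names(mm)[mm == 0L]
  one <- names(mm)[mm == 1L]
  if (length(zero) == 1L) {
    others <- mm[names(mm) != zero]
    if (!length(others) || all(others >= 2L)) {
      base$sire <- zero; base$rule <- "strict"; base$mismatches <- 0L
    } else if (all(others >= 1L) && any(others == 1L)) {
      base$sire <- zero; base$rule <- "relaxed"; base$mismatches <- 0L
    }
    return(base)
  }
  if (length(zero) > 1L) { base$reason <- "tied_zero_mismatch"; return(base) }
  if (length(one) == 1L) {
    others <- mm[names(mm) != one]
    if (!length(others) || all(others >= 2L)) {
      base$sire <- one; base$rule <- "one_mismatch"; base$mismatches <- 1L
      return(base)
    }
    base$reason <- "competitor_below_two_loci"; return(base)
  }
  base$reason <- if (length(one) > 1L) "tied_one_mismatch" else "no_compatible_candidate"
  base
}

#' Assign paternity for a whole offspring table
#'
#' Confirms maternity first; offspring whose dyad is not genetically
#' confirmed (or not genotyped) are logged, not assigned. Candidate sires are
#' drawn per offspring by [candidate_sires()].
#'
#' @param births `data.frame` with `offspring, mother, birth_date, natal_group`.
#' @param census Census `data.frame`.
#' @param genotypes Long-format genotype `data.frame`.
#' @param params A [paternity_params()] object.
#' @return `list(assignments = data.frame(offspring, sire, rule, mismatches,
#'   n_candidates), excluded = data.frame(offspring, reason))`.
#' @export
assign_paternity_all <- function(births, census, genotypes,
                                 params = paternity_params()) {
  gm <- .genotype_matrices(genotypes)
  n <- nrow(births)
  sire <- rep(NA_character_, n); rule <- rep("unassigned", n)
  mmc <- rep(NA_integer_, n); ncand <- integer(n)
  excl <- character(0); excl_reason <- character(0)
  for (i in seq_len(n)) {
    off <- births$offspring[i]; mom <- births$mother[i]
    if (!off %in% gm$ids) { excl <- c(excl, off); excl_reason <- c(excl_reason, "offspring_ungenotyped"); next }
    if (!mom %in% gm$ids) { excl <- c(excl, off); excl_reason <- c(excl_reason, "mother_ungenotyped"); next }
    ## maternity check against cached matrices (avoids rebuilding per trio)
    o <- .geno_row(gm, off); m <- .geno_row(gm, mom)
    joint <- !is.na(o[1, ]) & !is.na(m[1, ])
    share <- (o[1, ] == m[1, ]) | (o[1, ] == m[2, ]) | (o[2, ] == m[1, ]) | (o[2, ] == m[2, ])
    if (sum(joint & !share, na.rm = TRUE) > 0L) {
      excl <- c(excl, off); excl_reason <- c(excl_reason, "maternity_mismatch"); next
    }
    cands <- candidate_sires(births$birth_date[i], census, gm$ids, params)
    cands <- setdiff(cands, off)
    res <- assign_paternity(off, mom, cands, gm, params)
    sire[i] <- res$sire; rule[i] <- res$rule
    mmc[i] <- res$mismatches; ncand[i] <- res$n_candidates
  }
  keep <- !(births$offspring %in% excl)
  list(assignments = data.frame(offspring = births$offspring[keep],
                                sire = sire[keep], rule = rule[keep],
                                mismatches = mmc[keep], n_candidates = ncand[keep],
                                stringsAsFactors = FALSE),
       excluded = data.frame(offspring = excl, reason = excl_reason,
                             stringsAsFactors = FALSE))
}
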