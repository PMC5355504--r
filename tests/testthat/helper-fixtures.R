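# Fixture builders shared across test files. Everything is generated in code;
# dates are anchored at an arbitrary origin.

d0 <- as.Date("2004-01-01")

mk_census <- function(ids, sex, birth, death = as.Date(NA), natal = "A",
                      exit_type = "death") {
  data.frame(id = ids, sex = sex, birth_date = birth,
             death_date = death, natal_group = natal,
             exit_type = exit_type, stringsAsFactors = FALSE)
}

# sightings of one male seen daily over day offsets `days` (from d0)
mk_sightings <- function(id, days, group, context = "routine") {
  data.frame(id = id, date = d0 + days, group = group,
             context = context, stringsAsFactors = FALSE)
}

mk_season <- function(onset_off = 0, len = 120) {
  list(mating_onset = d0 + onset_off, mating_end = d0 + onset_off + len - 1)
}

mk_intervals <- function(id, group, start_off, end_off = NA) {
  data.frame(id = id, group = group, start_date = d0 + start_off,
             end_date = if (all(is.na(end_off))) as.Date(NA) else d0 + end_off,
             stringsAsFactors = FALSE)
}

# long genotype table from a named list: geno[[id]] = list of c(a1, a2) per locus
mk_genotypes <- function(geno) {
  do.call(rbind, lapply(names(geno), function(id) {
    al <- geno[[id]]
    keep <- !vapply(al, is.null, logical(1))
    data.frame(id = id, locus = sprintf("L%02d", which(keep)),
               allele1 = vapply(al[keep], `[`, 0, 1),
               allele2 = vapply(al[keep], `[`, 0, 2),
               stringsAsFactors = FALSE)
  }))
}
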