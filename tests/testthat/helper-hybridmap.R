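## Shared fixtures, all generated in code.

# a single small autosome; map expectations do not depend on physical
# length, only simulation cost does
tiny_autosome <- function(length = 2e6, name = "chrA") {
  chromosome_spec(name, length)
}

# an autosome plus an X, for sex-chromosome behavior
tiny_pair <- function(length = 2e6) {
  rbind(chromosome_spec("chrA", length),
        chromosome_spec("chrX", length, is_x = TRUE))
}

# hand-build a cohort whose every F2 has fixed parental strains on a
# single chromosome (no crossovers); useful for read-model tests
constant_cohort <- function(n_f2, chromosome, paternal, maternal) {
  truth <- data.table::rbindlist(lapply(seq_len(n_f2), function(id) {
    data.table::data.table(
      f2_id = id, chrom = chromosome$chrom,
      parent = c("paternal", "maternal"),
      start = 0, end = chromosome$length_bp,
      strain = c(paternal, maternal))
  }))
  data.table::setkey(truth, f2_id, chrom, parent, start)
  list(truth = truth, n_f2 = n_f2, male_x_strain = "CA",
       chromosomes = chromosome)
}

# count true breakpoints per chromatid from a cohort's truth table
truth_breakpoints <- function(cohort) {
  tr <- cohort$truth
  tr[, .(n_true = .N - 1L,
         breakpoints = list(start[start > 0])),
     by = .(f2_id, chrom, parent)]
}
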