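test_that("parental panel sites are biallelic, homozygous, diagnostic and sorted", {
  chrs <- ppa_chromosomes(scale = 0.02)
  p <- make_parental_panel(chrs, sites_per_Mb = 2000, seed = 1)
  expect_setequal(unique(p$chrom), chrs$chrom)
  expect_equal(length(unique(p$chrom)), 6L)  # 2n = 12 karyotype
  # positions strictly increasing within chromosome
  for (ch in chrs$chrom)
    expect_true(!is.unsorted(p[p$chrom == ch]$pos, strictly = TRUE))
  # biallelic with the diagnostic allele private to one strain
  expect_true(all(p$diag_allele != p$shared_allele))
  for (s in strain_labels()) {
    gt <- p[[paste0("gt_", s)]]
    al <- sub("/.*", "", gt)
    expect_true(all(gt == paste(al, al, sep = "/")))  # homozygous
    expect_true(all(al == ifelse(p$diag_strain == s, p$diag_allele,
                                 p$shared_allele)))
  }
  # diagnostic strain approximately uniform
  tab <- table(p$diag_strain)
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
})

test_that("parental panel degenerate and invalid inputs", {
  chrs <- tiny_autosome()
  expect_equal(nrow(make_parental_panel(chrs, sites_per_Mb = 0, seed = 1)), 0L)
  expect_error(make_parental_panel(chrs, sites_per_Mb = -1),
               "nonnegative")
})

test_that("panel site count falls in the Poisson interval of the target density", {
  p <- make_parental_panel(chromosome_spec("c1", 1e7),
                           sites_per_Mb = 100, seed = 42)
  n <- nrow(p)  # direct count of emitted rows
  expect_gte(n, qpois(0.005, 1000))
  expect_lte(n, qpois(0.995, 1000))
})

test_that("gamete with zero crossovers is one intact parental chromosome", {
  ch <- tiny_autosome()
  set.seed(1)
  g <- simulate_gamete(c("CA", "LR"), ch,
                       co_model(0, obligate = FALSE, double_co_rate = 0))
  expect_equal(nrow(g$segments), 1L)
  expect_equal(g$breakpoints, numeric(0))
  expect_equal(g$segments$start, 0)
  expect_equal(g$segments$end, ch$length_bp)
  expect_true(g$segments$strain %in% c("CA", "LR"))
})

test_that("gamete segments tile the chromosome and transitions equal breakpoints", {
  ch <- tiny_autosome()
  set.seed(2)
  for (i in 1:200) {
    m <- co_model(sample(0:3, 1), obligate = FALSE, double_co_rate = 0)
    g <- simulate_gamete(c("CA", "WA"), ch, m)
    s <- g$segments
    expect_equal(s$start[1], 0)
    expect_equal(s$end[nrow(s)], ch$length_bp)
    if (nrow(s) > 1L) {
      expect_equal(s$start[-1], s$end[-nrow(s)])
      expect_true(all(s$strain[-1] != s$strain[-nrow(s)]))
    }
    expect_equal(length(g$breakpoints), nrow(s) - 1L)
  }
})

test_that("obligate single crossover transmits a nonrecombinant chromatid half the time", {
  ch <- tiny_autosome()
  set.seed(3)
  m <- co_model(1, obligate = TRUE, double_co_rate = 0)
  nonrec <- vapply(seq_len(10000), function(i) {
    nrow(simulate_gamete(c("CA", "LR"), ch, m)$segments) == 1L
  }, logical(1))
  frac <- mean(nonrec)
  ci <- qbinom(c(0.005, 0.995), 10000, 0.5) / 10000
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("suppressed regions receive zero crossovers", {
  ch <- tiny_autosome()
  supp <- data.frame(chrom = ch$chrom, start = ch$arm2,
                     end = ch$length_bp)
  m <- co_model(1, obligate = TRUE, double_co_rate = 0,
                suppressed_regions = supp)
  set.seed(4)
  brk <- unlist(lapply(seq_len(10000), function(i)
    simulate_gamete(c("CA", "WA"), ch, m)$breakpoints))
  expect_gt(length(brk), 0)
  expect_true(all(brk < ch$arm2))
})

test_that("male X is transmitted intact, never with exchange", {
  chrs <- tiny_pair()
  x <- chrs[chrs$is_x, ]
  g <- simulate_gamete(c("CA", "WA"), x, co_model(), sex = "male")
  expect_equal(nrow(g$segments), 1L)
  expect_equal(g$segments$strain, "CA")
  g2 <- simulate_gamete(c("CA", "WA"), x, co_model(), sex = "male",
                        male_x_strain = "WA")
  expect_equal(g2$segments$strain, "WA")
})

test_that("cohort defaults to 93 F2 and every F2 carries a WA haplotype", {
  co <- simulate_f2_cohort(chromosomes = tiny_pair(), seed = 5)
  expect_equal(co$n_f2, 93L)
  expect_equal(length(unique(co$truth$f2_id)), 93L)
  has_wa <- co$truth[, any(strain == "WA" & parent == "paternal"),
                     by = f2_id]$V1
  expect_true(all(has_wa))
  # paternal X intact: one segment, zero breakpoints
  px <- co$truth[chrom == "chrX" & parent == "paternal"]
  expect_equal(nrow(px), 93L)
  expect_true(all(px$strain == "CA"))
  # maternal labels never WA, paternal never LR
  expect_false(any(co$truth[parent == "maternal"]$strain == "WA"))
  expect_false(any(co$truth[parent == "paternal"]$strain == "LR"))
})

test_that("without selection the four genotype classes are Mendelian at any locus", {
  # a WA male X makes the WA-presence validation vacuous, so the
  # autosomal locus is exactly Mendelian
  chrs <- tiny_pair()
  co <- simulate_f2_cohort(n_f2 = 10000, chromosomes = chrs, seed = 6,
                           male_x_strain = "WA")
  ch <- chrs[1, ]
  locus <- ch$length_bp / 2
  g <- co$truth[chrom == ch$chrom, {
    seg <- .SD[order(start)]
    strain_here <- seg$strain[findInterval(locus, seg$start)]
    list(strain = strain_here)
  }, by = .(f2_id, parent)]
  pat <- g[parent == "paternal"]$strain
  mat <- g[parent == "maternal"]$strain
  cls <- recompose_genotype(pat, mat)
  tab <- table(factor(cls, levels = genotype_classes()))
  # brute-force tally against the 1:1:1:1 expectation of the double cross
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
})

test_that("relative_viability = 1 reproduces the unselected cohort exactly", {
  ch <- tiny_autosome()
  sel <- viability_selection(ch$chrom, 1e6, "maternal", "CA",
                             relative_viability = 1)
  a <- simulate_f2_cohort(n_f2 = 20, chromosomes = ch, seed = 7)
  b <- simulate_f2_cohort(n_f2 = 20, chromosomes = ch, seed = 7,
                          selection = sel)
  expect_identical(a$truth, b$truth)
})

test_that("zero viability of a genotype every F2 carries aborts with an error", {
  chrs <- tiny_pair()
  # the paternal X is always the male X strain (CA), so v = 0 against it
  # makes the cohort unfillable
  sel <- viability_selection("chrX", 1e5, "paternal", "CA",
                             relative_viability = 0)
  expect_error(
    simulate_f2_cohort(n_f2 = 5, chromosomes = chrs, seed = 8,
                       selection = sel, max_tries = 20),
    "viability")
})

test_that("viability selection thins carriers of the disfavored haplotype", {
  ch <- tiny_autosome()
  sel <- viability_selection(ch$chrom, 1e6, "maternal", "CA",
                             relative_viability = 0.2)
  co <- simulate_f2_cohort(n_f2 = 2000, chromosomes = ch, seed = 9,
                           selection = sel)
  g <- co$truth[parent == "maternal", {
    seg <- .SD[order(start)]
    list(strain = seg$strain[findInterval(1e6, seg$start)])
  }, by = f2_id]
  frac_ca <- mean(g$strain == "CA")
  # expected carrier fraction v/(1+v) = 1/6
  expect_lt(abs(frac_ca - 0.2 / 1.2), 3 * sqrt(1 / 6 * 5 / 6 / 2000))
})

test_that("depth sampling: zero coverage, mean coverage, and error-free limit", {
  ch <- tiny_autosome(2e5)
  sites <- make_parental_panel(ch, sites_per_Mb = 2000, seed = 10)
  co <- constant_cohort(50, ch, paternal = "CA", maternal = "CA")

  d0 <- sample_depths(co, sites, coverage = 0, seed = 11)
  expect_true(all(d0$depth_diag == 0L & d0$depth_shared == 0L))

  d5 <- sample_depths(co, sites, coverage = 5, error_rate = 0.005,
                      seed = 12)
  tot <- d5$depth_diag + d5$depth_shared
  expect_gt(length(tot), 10000)
  se <- sqrt(5 / length(tot))
  expect_lt(abs(mean(tot) - 5), 4 * se)

  # error-free CA/CA F2: no reads ever carry the WA- or LR-diagnostic
  # allele at their diagnostic sites
  d <- sample_depths(co, sites, coverage = 10, error_rate = 0, seed = 13)
  expect_true(all(d[d$diag_strain != "CA"]$depth_diag == 0L))
  expect_true(all(d[d$diag_strain == "CA"]$depth_shared == 0L))
})

test_that("total read count is conserved across error rates (same seed)", {
  ch <- tiny_autosome(2e5)
  sites <- make_parental_panel(ch, sites_per_Mb = 1000, seed = 14)
  co <- constant_cohort(20, ch, paternal = "WA", maternal = "LR")
  totals <- lapply(c(0, 0.01, 0.2), function(e) {
    d <- sample_depths(co, sites, coverage = 5, error_rate = e, seed = 15)
    d$depth_diag + d$depth_shared
  })
  expect_identical(totals[[1]], totals[[2]])
  expect_identical(totals[[1]], totals[[3]])
})

test_that("simulation is deterministic under a fixed seed", {
  chrs <- tiny_pair()
  p1 <- make_parental_panel(chrs, sites_per_Mb = 500, seed = 16)
  p2 <- make_parental_panel(chrs, sites_per_Mb = 500, seed = 16)
  expect_identical(p1, p2)
  c1 <- simulate_f2_cohort(n_f2 = 10, chromosomes = chrs, seed = 17)
  c2 <- simulate_f2_cohort(n_f2 = 10, chromosomes = chrs, seed = 17)
  expect_identical(c1$truth, c2$truth)
  d1 <- sample_depths(c1, p1, seed = 18)
  d2 <- sample_depths(c2, p2, seed = 18)
  expect_identical(d1, d2)
})
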