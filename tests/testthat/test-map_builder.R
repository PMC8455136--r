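## truth-label maps: perfect calls let the map module be tested
## independently of the genotyper
truth_map <- function(cohort, blocks, mapping = "morgan") {
  lab <- truth_block_labels(cohort, blocks)
  calls <- data.table::as.data.table(lab)
  calls[, `:=`(call = recompose_genotype(paternal, maternal),
               no_call_reason = NA_character_)]
  calls[, is_x := chrom %in%
          cohort$chromosomes$chrom[cohort$chromosomes$is_x]]
  ph <- phase_chromatids(calls, blocks)
  list(map = build_map(ph, mapping = mapping), phased = ph)
}

empty_sites <- function() data.frame(chrom = character(), pos = numeric(),
                                     diag_strain = character())

test_that("interval recombination fraction is the discordant share of informative chromatids", {
  r0 <- interval_recombination_fraction(rep("CA", 93), rep("CA", 93))
  expect_equal(r0$r, 0)
  expect_equal(r0$n_informative, 93L)

  left <- c(rep("CA", 90), rep(NA, 3))
  right <- c(rep("LR", 9), rep("CA", 81), rep(NA, 3))
  r <- interval_recombination_fraction(left, right)
  expect_equal(r$r, 0.1)
  expect_equal(r$n_informative, 90L)
  expect_equal(r$n_discordant, 9L)

  none <- interval_recombination_fraction(c(NA, NA), c("CA", NA))
  expect_true(is.na(none$r))

  expect_warning(
    capped <- interval_recombination_fraction(rep("CA", 10),
                                              rep("LR", 10)),
    "capped")
  expect_equal(capped$r, 0.5)
})

test_that("zero crossovers give a flat 0 cM map; cumulative positions are monotone and additive", {
  ch <- tiny_autosome()
  m0 <- co_model(0, obligate = FALSE, double_co_rate = 0)
  co <- simulate_f2_cohort(n_f2 = 30, chromosomes = ch, seed = 51,
                           co_male = m0, co_herm = m0)
  blocks <- bin_sites(empty_sites(), ch)
  tm <- truth_map(co, blocks)
  expect_equal(tm$map$summary$total_cm, c(0, 0))

  co1 <- simulate_f2_cohort(n_f2 = 60, chromosomes = ch, seed = 52)
  tm1 <- truth_map(co1, blocks)
  mar <- tm1$map$marey
  for (side in unique(mar$parent)) {
    cm <- mar[mar$parent == side]$cm_cumulative
    expect_true(all(diff(cm) >= 0))
    r <- mar[mar$parent == side]$r
    expect_equal(cm[length(cm)], sum(r[-1] * 100))  # morgan additivity
  }
})

test_that("summed interval discordance equals total phased transitions", {
  ch <- tiny_autosome()
  co <- simulate_f2_cohort(n_f2 = 80, chromosomes = ch, seed = 53)
  blocks <- bin_sites(empty_sites(), ch)
  tm <- truth_map(co, blocks)
  expect_equal(sum(tm$map$marey$n_discordant, na.rm = TRUE),
               sum(tm$phased$chromatids[mappable == TRUE]$n_crossovers))
})

test_that("expected map length is 50 cM per crossover per meiosis", {
  # a WA male X keeps the autosomal chromatid distribution unconditioned
  chrs <- rbind(tiny_autosome(4e6),
                chromosome_spec("chrX", 4e6, is_x = TRUE))
  blocks <- bin_sites(empty_sites(), chrs)
  for (c_per in c(0, 1, 2)) {
    m <- if (c_per == 0) co_model(0, obligate = FALSE, double_co_rate = 0)
         else co_model(c_per, obligate = TRUE, double_co_rate = 0)
    co <- simulate_f2_cohort(n_f2 = 400, chromosomes = chrs,
                             seed = 54 + c_per, co_male = m, co_herm = m,
                             male_x_strain = "WA")
    tm <- truth_map(co, blocks)
    expected <- 50 * c_per
    # binomial SD of total length at 400 chromatids, plus the small
    # downward bias from crossovers outside the outermost bin midpoints
    tol <- 3 * 100 * sqrt(max(c_per, 0.5) * 0.25 / 400) + 0.05 * expected
    for (len in tm$map$summary$total_cm)
      expect_lt(abs(len - expected), max(tol, 2))
  }
})

test_that("mapping functions agree for small r and diverge as r grows", {
  ch <- tiny_autosome()
  co <- simulate_f2_cohort(n_f2 = 100, chromosomes = ch, seed = 57)
  blocks <- bin_sites(empty_sites(), ch)
  morgan <- truth_map(co, blocks, "morgan")$map$summary$total_cm
  haldane <- truth_map(co, blocks, "haldane")$map$summary$total_cm
  kosambi <- truth_map(co, blocks, "kosambi")$map$summary$total_cm
  # haldane >= kosambi >= morgan, all within a few percent for dense bins
  expect_true(all(haldane >= kosambi - 1e-9))
  expect_true(all(kosambi >= morgan - 1e-9))
  expect_true(all(abs(haldane - morgan) / pmax(morgan, 1) < 0.1))
})

test_that("the X chromosome gets a maternal map only", {
  chrs <- tiny_pair()
  co <- simulate_f2_cohort(n_f2 = 40, chromosomes = chrs, seed = 58)
  blocks <- bin_sites(empty_sites(), chrs)
  tm <- truth_map(co, blocks)
  s <- tm$map$summary
  expect_setequal(s[s$chrom == "chrX"]$parent, "maternal")
  expect_setequal(s[s$chrom == "chrA"]$parent,
                  c("paternal", "maternal"))
})

test_that("arm/center rates recover the simulated arm weighting", {
  ch <- tiny_autosome(6e6)
  blocks <- bin_sites(empty_sites(), ch)
  for (w in c(1, 3)) {
    m <- co_model(1, obligate = TRUE, arm_weight = w, double_co_rate = 0)
    co <- simulate_f2_cohort(n_f2 = 500, chromosomes = ch,
                             seed = 60 + w, co_male = m, co_herm = m)
    tm <- truth_map(co, blocks)
    acs <- arm_center_summary(tm$map, ch)
    for (ratio in acs$ratio$arm_center_ratio)
      expect_lt(abs(ratio - w), w * 0.35)
  }
})

test_that("a suppressed arm produces a flat Marey segment", {
  ch <- tiny_autosome(6e6)
  supp <- data.frame(chrom = ch$chrom, start = ch$arm2, end = ch$length_bp)
  m <- co_model(1, obligate = TRUE, double_co_rate = 0,
                suppressed_regions = supp)
  co <- simulate_f2_cohort(n_f2 = 200, chromosomes = ch, seed = 63,
                           co_male = m, co_herm = m)
  blocks <- bin_sites(empty_sites(), ch)
  tm <- truth_map(co, blocks)
  acs <- arm_center_summary(tm$map, ch)
  right <- acs$regions[acs$regions$region == "right_arm"]
  expect_true(all(right$cm <= 2))
  # the obligate crossover still happens: full length retained elsewhere
  expect_true(all(tm$map$summary$total_cm > 35))
})
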