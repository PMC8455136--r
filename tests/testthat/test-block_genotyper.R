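test_that("blocks tile chromosomes with half-open site assignment", {
  ch <- chromosome_spec("c1", 1e6)
  sites <- data.frame(chrom = "c1", pos = c(0, 99999, 100000, 999999),
                      diag_strain = c("CA", "CA", "WA", "LR"))
  b <- bin_sites(sites, ch)
  expect_equal(nrow(b), 10L)
  expect_equal(b$start, seq(0, 9e5, by = 1e5))
  expect_equal(b$end, seq(1e5, 1e6, by = 1e5))
  # site at exactly 100,000 falls in the second block
  expect_equal(b$n_sites[1:2], c(2L, 1L))
  expect_equal(b$n_WA[2], 1L)
  expect_equal(b$n_LR[10], 1L)
})

test_that("the full-scale karyotype yields 1567 hundred-kb blocks", {
  b <- bin_sites(data.frame(chrom = character(), pos = numeric(),
                            diag_strain = character()),
                 ppa_chromosomes())
  expect_equal(nrow(b), 1567L)
})

test_that("sites beyond the chromosome end are rejected by name", {
  ch <- chromosome_spec("c1", 1e6)
  bad <- data.frame(chrom = "c1", pos = 1e6, diag_strain = "CA")
  expect_error(bin_sites(bad, ch), "c1:1e\\+06|c1:1000000")
  unk <- data.frame(chrom = "c9", pos = 10, diag_strain = "CA")
  expect_error(bin_sites(unk, ch), "c9")
})

test_that("depth fractions are normalised and degenerate depths flagged", {
  f <- compute_fractions(190, 5, 5)
  expect_equal(c(f$f_CA, f$f_WA, f$f_LR), c(0.95, 0.025, 0.025))
  expect_true(f$defined)
  z <- compute_fractions(0, 0, 0)
  expect_false(z$defined)
  expect_true(is.na(z$f_CA))
})

test_that("fractions of a true CA/LR block center on (0.5, 0, 0.5)", {
  ch <- tiny_autosome(1e5)
  sites <- make_parental_panel(ch, sites_per_Mb = 2000, seed = 31)
  co <- constant_cohort(1000, ch, paternal = "CA", maternal = "LR")
  d <- sample_depths(co, sites, coverage = 30, error_rate = 0, seed = 32)
  b <- bin_sites(sites, ch, block_size = 1e5)
  calls <- genotype_blocks(d, b)
  expect_lt(abs(mean(calls$f_CA) - 0.5), 0.01)
  expect_lt(abs(mean(calls$f_LR) - 0.5), 0.01)
  expect_equal(max(calls$f_WA), 0)
  expect_true(all(calls$call == "CA/LR"))
})

test_that("genotype rules call the documented fraction patterns", {
  th <- classifier_thresholds()
  cl <- call_block_genotype(
    f_ca  = c(0.97, 0.48, 0.48, 0.40, 1.00, 0.02),
    f_wa  = c(0.01, 0.04, 0.48, 0.30, 0.00, 0.49),
    f_lr  = c(0.02, 0.48, 0.04, 0.30, 0.00, 0.49),
    total = c(100, 100, 100, 100, 10, 100), thresholds = th)
  expect_equal(cl$call, c("CA/CA", "CA/LR", "CA/WA", "no_call",
                          "no_call", "WA/LR"))
  expect_equal(cl$no_call_reason,
               c(NA, NA, NA, "ambiguous", "low_depth", NA))
})

test_that("zero-depth blocks and malformed fractions are handled", {
  cl <- call_block_genotype(NA_real_, NA_real_, NA_real_, 0)
  expect_equal(cl$call, "no_call")
  expect_equal(cl$no_call_reason, "zero_depth")
  expect_error(call_block_genotype(0.5, 0.2, 0.2, 100),
               "sum to 1")
})

test_that("the printed balance direction is available behind the flag", {
  th <- classifier_thresholds(balance = "beyond")
  cl <- call_block_genotype(0.48, 0.04, 0.48, 100, thresholds = th)
  # a true heterozygote signature fails the printed direction
  expect_equal(cl$call, "no_call")
  cl2 <- call_block_genotype(0.70, 0.04, 0.26, 100, thresholds = th)
  expect_equal(cl2$call, "CA/LR")
})

test_that("X blocks only admit genotypes compatible with the intact paternal X", {
  cl <- call_block_genotype(
    f_ca = c(0.97, 0.48, 0.48, 0.02), f_wa = c(0.01, 0.04, 0.48, 0.49),
    f_lr = c(0.02, 0.48, 0.04, 0.49), total = rep(100, 4),
    is_x = TRUE, male_x_strain = "CA")
  expect_equal(cl$call, c("CA/CA", "CA/LR", "no_call", "no_call"))
  expect_equal(cl$no_call_reason[3:4], rep("incompatible_X", 2))
  # with a WA male X the admissible set flips
  cl2 <- call_block_genotype(
    f_ca = c(0.97, 0.48, 0.48, 0.02), f_wa = c(0.01, 0.04, 0.48, 0.49),
    f_lr = c(0.02, 0.48, 0.04, 0.49), total = rep(100, 4),
    is_x = TRUE, male_x_strain = "WA")
  expect_equal(cl2$call, c("no_call", "no_call", "CA/WA", "WA/LR"))
})

test_that("genotype rules are mutually exclusive over the fraction simplex", {
  # grid search at step 0.005 (acceptance suite refines to 0.001)
  f_ca <- seq(0, 1, by = 0.005)
  grid <- data.table::CJ(f_ca = f_ca, f_wa = f_ca)
  grid <- grid[f_ca + f_wa <= 1]
  grid[, f_lr := 1 - f_ca - f_wa]
  th <- classifier_thresholds(min_classified_reads = 0)
  hit <- function(ca, wa, lr) {
    cbind(ca > th$homozygote_min_fraction,
          lr < th$absent_max_fraction & abs(ca - wa) <= th$het_balance_max,
          wa < th$absent_max_fraction & abs(ca - lr) <= th$het_balance_max,
          ca < th$absent_max_fraction & abs(wa - lr) <= th$het_balance_max)
  }
  n_hit <- rowSums(hit(grid$f_ca, grid$f_wa, grid$f_lr))
  expect_true(all(n_hit <= 1L))
  # and the caller itself never errors on the grid (internal exclusivity
  # check holds)
  cl <- call_block_genotype(grid$f_ca, grid$f_wa, grid$f_lr,
                            total = rep(100, nrow(grid)), thresholds = th)
  expect_true(all(cl$call %in% c(genotype_classes(), "no_call")))
})

test_that("increasing coverage never increases the low-depth no-call rate", {
  ch <- tiny_autosome(5e5)
  sites <- make_parental_panel(ch, sites_per_Mb = 300, seed = 33)
  co <- constant_cohort(200, ch, paternal = "CA", maternal = "LR")
  b <- bin_sites(sites, ch)
  rate <- vapply(c(0.5, 1, 2, 5, 10), function(cov) {
    d <- sample_depths(co, sites, coverage = cov, error_rate = 0.005,
                       seed = 34)
    calls <- genotype_blocks(d, b)
    mean(calls$no_call_reason %in% c("low_depth", "zero_depth"))
  }, numeric(1))
  expect_true(all(diff(rate) <= 0))
})

test_that("block filters drop sparse, undercalled, and distorted blocks", {
  ch <- chromosome_spec("c1", 3e5)
  blocks <- data.table::data.table(
    chrom = "c1", start = c(0, 1e5, 2e5), end = c(1e5, 2e5, 3e5),
    is_x = FALSE, n_CA = 0L, n_WA = 0L, n_LR = 0L,
    n_sites = c(99L, 500L, 500L))
  # 93 F2: block 1 fine but sparse; block 2 has 29/93 uncalled (31.2%);
  # block 3 fully called but totally distorted
  mk_calls <- function(start, calls) {
    data.table::data.table(f2_id = seq_along(calls), chrom = "c1",
                           start = start, end = start + 1e5,
                           is_x = FALSE, call = calls,
                           no_call_reason = ifelse(calls == "no_call",
                                                   "ambiguous", NA))
  }
  balanced <- rep(genotype_classes(), length.out = 93)
  calls <- rbind(
    mk_calls(0, balanced),
    mk_calls(1e5, c(rep("no_call", 29), balanced[1:64])),
    mk_calls(2e5, rep("CA/CA", 93)))
  fb <- filter_blocks(calls, blocks)
  expect_equal(fb$drop_reason,
               c("too_few_sites", "too_many_uncalled", "distorted"))
  expect_false(any(fb$kept))
  # 27/93 uncalled (29.0%) is tolerated
  calls2 <- rbind(mk_calls(0, balanced),
                  mk_calls(1e5, c(rep("no_call", 27), balanced[1:66])),
                  mk_calls(2e5, balanced))
  blocks2 <- data.table::copy(blocks)[, n_sites := 500L]
  fb2 <- filter_blocks(calls2, blocks2)
  expect_true(all(fb2$kept))
})
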