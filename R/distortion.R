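## Segregation distortion diagnostics -----------------------------------

#' Chi-square test of one block's genotype counts against Mendelian
#' expectation
#'
#' The double cross expects the four genotype classes in 1:1:1:1
#' proportion at any autosomal block (each parent transmits its two
#' haplotypes equally).  On the X only the two classes compatible with
#' the intact paternal X occur, expected 1:1 in the maternal allele.
#' Pearson's chi-square without continuity correction is used; with
#' ~93 called F2 the expected class counts are large enough for the
#' asymptotic distribution.
#'
#' @param counts Named integer vector of observed genotype-class counts.
#' @param expected Named proportions summing to 1 (tolerance 1e-8);
#'   defaults to equal proportions over the classes present in
#'   `counts`.
#' @return List with `statistic`, `df` (`#classes - 1`), `p_value`,
#'   `observed`, `expected`.
#' @export
#' @examples
#' block_distortion_test(c(`CA/CA` = 23, `CA/WA` = 23,
#'                         `CA/LR` = 23, `WA/LR` = 24))
block_distortion_test <- function(counts, expected = NULL) {
  counts <- unlist(counts)
  if (sum(counts) < 1) stop("no called F2 in block")
  k <- length(counts)
  if (is.null(expected)) expected <- rep(1 / k, k)
  if (length(expected) != k)
    stop("expected proportions must match the number of classes")
  if (abs(sum(expected) - 1) > 1e-8)
    stop("expected proportions must sum to 1")
  e <- sum(counts) * expected
  stat <- sum((counts - e)^2 / e)
  df <- k - 1L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       observed = counts, expected = e)
}

#' Per-block segregation distortion over a call matrix
#'
#' Applies [block_distortion_test()] to every block of a call matrix.
#' Autosomal blocks are tested against 1:1:1:1 over the four genotype
#' classes; X blocks against 1:1 over the two classes compatible with
#' the intact paternal X.  Blocks with no called F2 get `NA`.
#'
#' @param calls Call matrix from [genotype_blocks()].
#' @param male_x_strain Paternal X strain.
#' @return `data.table` with `chrom`, `start`, `end`, `is_x`,
#'   `n_called`, one count column per genotype class, `statistic`, `df`,
#'   `p_value`.
#' @export
distortion_test_blocks <- function(calls, male_x_strain = "CA") {
  calls <- as.data.table(calls)
  classes <- genotype_classes()
  x_classes <- classes[decompose_genotype(classes)$paternal ==
                         male_x_strain]
  cnt <- dcast(calls[call != "no_call", .N, by = .(chrom, start, call)],
               chrom + start ~ call, value.var = "N", fill = 0L)
  for (g in classes) if (!g %in% names(cnt)) cnt[, (g) := 0L]
  out <- merge(unique(calls[, .(chrom, start, end, is_x)]), cnt,
               by = c("chrom", "start"), all.x = TRUE)
  for (g in classes) out[is.na(get(g)), (g) := 0L]
  obs <- as.matrix(out[, ..classes])
  n_called <- rowSums(obs)
  stat <- rep(NA_real_, nrow(out))
  df <- rep(NA_integer_, nrow(out))
  auto <- !out$is_x & n_called > 0
  if (any(auto)) {
    e <- n_called[auto] / length(classes)
    stat[auto] <- rowSums((obs[auto, , drop = FALSE] - e)^2 / e)
    df[auto] <- length(classes) - 1L
  }
  xb <- out$is_x & n_called > 0
  if (any(xb)) {
    ox <- obs[xb, x_classes, drop = FALSE]
    nx <- rowSums(ox)
    ex <- nx / length(x_classes)
    stat[xb] <- rowSums((ox - ex)^2 / ex)
    df[xb] <- length(x_classes) - 1L
  }
  out[, n_called := n_called]
  out[, `:=`(statistic = stat, df = df,
             p_value = pchisq(stat, df, lower.tail = FALSE))]
  setorder(out, chrom, start)
  out[]
}

#' Inheritance bias among nonrecombinant chromatids
#'
#' Among chromatids with zero crossovers on one chromosome from one
#' parent, counts the two parental strains and reports the
#' favored:disfavored ratio (>= 1 by orientation).  Under neutrality the
#' ratio is ~1; viability selection with relative viability v against
#' one strain's carriers gives an expected ratio of 1/v.
#'
#' @param phased A [phase_chromatids()] result (or chromatids table).
#' @param chrom Chromosome name.
#' @param parent `"paternal"` or `"maternal"`.
#' @return List with `chromosome`, `parent`, `counts` (named, both
#'   strains), `favored`, `disfavored`, `ratio` (`Inf` with
#'   `infinite = TRUE` when the disfavored count is 0).
#' @export
nonrecombinant_ratio <- function(phased, chrom, parent) {
  ch <- if (inherits(phased, "phased_cohort")) phased$chromatids
        else as.data.table(phased)
  stopifnot(parent %in% c("paternal", "maternal"))
  strains <- if (parent == "paternal") c("CA", "WA") else c("CA", "LR")
  keep <- which(ch$chrom == chrom & ch$parent == parent &
                  ch$mappable & !ch$low_information &
                  ch$n_crossovers == 0L)
  sel <- ch[keep, , drop = FALSE]
  counts <- setNames(rep(0L, 2L), strains)
  tab <- table(factor(sel$strain, levels = strains))
  counts[names(tab)] <- as.integer(tab)
  favored <- names(counts)[which.max(counts)]
  disfavored <- setdiff(names(counts), favored)[1L]
  ratio <- if (counts[disfavored] == 0L) Inf
           else unname(counts[favored] / counts[disfavored])
  list(chromosome = chrom, parent = parent, counts = counts,
       favored = favored, disfavored = disfavored, ratio = ratio,
       infinite = !is.finite(ratio))
}

#' Per-block frequency of one parental strain
#'
#' The physical profile of haplotype inheritance: for each block, the
#' fraction of called chromatids of the given parent that carry
#' `strain`.  Feeds [distortion_gradient()].
#'
#' @param phased A [phase_chromatids()] result (or labels table).
#' @param parent `"paternal"` or `"maternal"`.
#' @param strain Strain whose frequency is profiled.
#' @return `data.table` with `chrom`, `start`, `end`, `bin_mid`, `n`
#'   (called chromatids), `freq`.
#' @export
haplotype_frequency <- function(phased, parent, strain) {
  labels <- if (inherits(phased, "phased_cohort")) phased$labels
            else as.data.table(phased)
  stopifnot(parent %in% c("paternal", "maternal"))
  lab <- labels[[parent]]
  d <- labels[, .(chrom, start, end, lab = lab)]
  out <- d[, .(n = sum(!is.na(lab)),
               freq = mean(lab[!is.na(lab)] == strain)),
           by = .(chrom, start, end)]
  out[n == 0L, freq := NA_real_]
  out[, bin_mid := (start + end) / 2]
  setorder(out, chrom, start)
  out[]
}

#' Trend test for a distortion gradient along a chromosome
#'
#' Fits the least-squares slope of per-bin haplotype frequency against
#' physical position and assesses it with a permutation test (bin
#' labels permuted, two-sided on |slope|).  A significant slope whose
#' sign points toward a chromosome end is the signature of a selected
#' locus there.
#'
#' @param freq Per-bin frequencies (NA bins dropped).
#' @param pos Bin positions in bp.
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Optional integer seed for the permutations.
#' @return List with `slope` (frequency change per bp), `intercept`,
#'   `p_value`, `n_bins`, `n_perm`.
#' @export
distortion_gradient <- function(freq, pos, n_perm = 10000L, seed = NULL) {
  stopifnot(length(freq) == length(pos))
  keep <- !is.na(freq) & !is.na(pos)
  freq <- freq[keep]; pos <- pos[keep]
  if (length(freq) < 3L) stop("need at least 3 bins for a gradient test")
  if (!is.null(seed)) set.seed(seed)
  xc <- pos - mean(pos)
  ssx <- sum(xc^2)
  slope <- sum(xc * freq) / ssx
  intercept <- mean(freq) - slope * mean(pos)
  if (var(freq) == 0) {
    return(list(slope = 0, intercept = mean(freq), p_value = 1,
                n_bins = length(freq), n_perm = 0L))
  }
  perm <- vapply(seq_len(n_perm), function(i) {
    sum(xc * sample(freq)) / ssx
  }, numeric(1))
  p <- (1 + sum(abs(perm) >= abs(slope))) / (n_perm + 1)
  list(slope = slope, intercept = intercept, p_value = p,
       n_bins = length(freq), n_perm = as.integer(n_perm))
}
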