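## Block genotyping from depth fractions --------------------------------

#' Thresholds for the four-way depth-fraction genotype caller
#'
#' Within a block the caller sees the strain depth fractions
#' `f_CA + f_WA + f_LR = 1`.  The rules are: `CA/CA` iff
#' `f_CA > homozygote_min_fraction`; a heterozygote `X/Y` iff the third
#' strain's fraction is below `absent_max_fraction` and the two carrier
#' fractions are balanced.  With `balance = "within"` (the default)
#' balance means `|f_X - f_Y| <= het_balance_max`, which accepts the
#' fraction signature (~0.5, ~0.5, ~0) that true heterozygotes produce
#' under diagnostic-allele counting.  `balance = "beyond"` applies the
#' opposite inequality (`> het_balance_max`), retained for comparison
#' only; it rejects balanced heterozygote signatures.
#'
#' @param homozygote_min_fraction Minimum `f_CA` for a `CA/CA` call
#'   (default 0.95).
#' @param absent_max_fraction Maximum fraction of the strain absent from
#'   a heterozygous genotype (default 0.05).
#' @param het_balance_max Balance tolerance between the two carrier
#'   fractions (default 0.10).
#' @param min_classified_reads Minimum diagnostic reads in the block for
#'   any call (default 20; set to 0 to disable the gate).
#' @param balance `"within"` or `"beyond"`, see above.
#' @return List of class `"classifier_thresholds"`.
#' @export
classifier_thresholds <- function(homozygote_min_fraction = 0.95,
                                  absent_max_fraction = 0.05,
                                  het_balance_max = 0.10,
                                  min_classified_reads = 20,
                                  balance = c("within", "beyond")) {
  balance <- match.arg(balance)
  if (!(absent_max_fraction > 0 &&
        absent_max_fraction < homozygote_min_fraction &&
        homozygote_min_fraction <= 1))
    stop("need 0 < absent_max_fraction < homozygote_min_fraction <= 1")
  stopifnot(het_balance_max >= 0, min_classified_reads >= 0)
  structure(list(homozygote_min_fraction = homozygote_min_fraction,
                 absent_max_fraction = absent_max_fraction,
                 het_balance_max = het_balance_max,
                 min_classified_reads = min_classified_reads,
                 balance = balance),
            class = "classifier_thresholds")
}

#' Tile chromosomes into non-overlapping genotyping blocks
#'
#' Blocks of `block_size` bp (default 100 kb) tile each chromosome from
#' 0; the final block may be shorter.  Sites are assigned by half-open
#' interval `[start, end)`, so a site at position 100,000 falls in the
#' second block.
#'
#' @param sites Informative-site table (`chrom`, `pos`, `diag_strain`).
#' @param chromosomes Chromosome table.
#' @param block_size Block width in bp (> 0).
#' @return `data.table` with `chrom`, `start`, `end`, `is_x`, per-strain
#'   site counts `n_CA`, `n_WA`, `n_LR` and total `n_sites`.  The
#'   `block_size` is carried as an attribute.
#' @export
bin_sites <- function(sites, chromosomes, block_size = 1e5) {
  stopifnot(is.numeric(block_size), block_size > 0)
  chromosomes <- as_chromosome_table(chromosomes)
  sites <- as.data.table(sites)
  if (nrow(sites)) {
    bad <- !(sites$chrom %in% chromosomes$chrom)
    if (any(bad))
      stop("site on unknown chromosome: ",
           sites$chrom[bad][1L], ":", sites$pos[bad][1L])
    len <- chromosomes$length_bp[match(sites$chrom, chromosomes$chrom)]
    out_of_range <- sites$pos < 0 | sites$pos >= len
    if (any(out_of_range))
      stop("site beyond chromosome end: ",
           sites$chrom[out_of_range][1L], ":",
           sites$pos[out_of_range][1L])
  }
  grid <- rbindlist(lapply(seq_len(nrow(chromosomes)), function(i) {
    L <- chromosomes$length_bp[i]
    starts <- seq(0, by = block_size, length.out = ceiling(L / block_size))
    data.table(chrom = chromosomes$chrom[i], start = starts,
               end = pmin(starts + block_size, L),
               is_x = chromosomes$is_x[i])
  }))
  if (nrow(sites)) {
    s <- sites[, .(chrom, start = floor(pos / block_size) * block_size,
                   diag_strain)]
    cnt <- dcast(s[, .N, by = .(chrom, start, diag_strain)],
                 chrom + start ~ diag_strain, value.var = "N", fill = 0L)
  } else {
    cnt <- data.table(chrom = character(), start = numeric())
  }
  for (s in strain_labels())
    if (!s %in% names(cnt)) cnt[, (s) := 0L]
  setnames(cnt, strain_labels(), paste0("n_", strain_labels()),
           skip_absent = TRUE)
  out <- merge(grid, cnt, by = c("chrom", "start"), all.x = TRUE)
  for (col in paste0("n_", strain_labels()))
    out[is.na(get(col)), (col) := 0L]
  out[, n_sites := n_CA + n_WA + n_LR]
  setorder(out, chrom, start)
  setattr(out, "block_size", block_size)
  out[]
}

#' Depth fractions from per-strain diagnostic read counts
#'
#' Forms the strain fractions `f_CA + f_WA + f_LR = 1` that drive the
#' genotype caller.  When per-strain diagnostic-site counts are given,
#' each strain's depth is first normalised to reads per diagnostic site
#' (`depth / sites`); the number of diagnostic sites per strain in a
#' block is itself a random (and, in real panels, systematically
#' unequal) quantity, and without this normalisation its noise
#' propagates into the fractions undiminished by sequencing depth.
#' With equal site counts (the default) the fractions reduce to plain
#' relative depths.
#'
#' @param depth_ca,depth_wa,depth_lr Diagnostic-allele read counts
#'   (vectors of equal length).
#' @param sites_ca,sites_wa,sites_lr Diagnostic-site counts per strain
#'   in the block (default 1 each, i.e. unnormalised).
#' @return `data.table` with the raw depths, `total`, fractions `f_CA`,
#'   `f_WA`, `f_LR` (NA when `total` is 0) and `defined`.
#' @export
#' @examples
#' compute_fractions(190, 5, 5)
compute_fractions <- function(depth_ca, depth_wa, depth_lr,
                              sites_ca = 1L, sites_wa = 1L,
                              sites_lr = 1L) {
  tot <- depth_ca + depth_wa + depth_lr
  rate_ca <- ifelse(sites_ca > 0, depth_ca / sites_ca, 0)
  rate_wa <- ifelse(sites_wa > 0, depth_wa / sites_wa, 0)
  rate_lr <- ifelse(sites_lr > 0, depth_lr / sites_lr, 0)
  rtot <- rate_ca + rate_wa + rate_lr
  data.table(depth_CA = depth_ca, depth_WA = depth_wa, depth_LR = depth_lr,
             total = tot,
             f_CA = ifelse(tot > 0, rate_ca / rtot, NA_real_),
             f_WA = ifelse(tot > 0, rate_wa / rtot, NA_real_),
             f_LR = ifelse(tot > 0, rate_lr / rtot, NA_real_),
             defined = tot > 0)
}

#' Call a four-way block genotype from depth fractions
#'
#' Vectorised over blocks.  Rules (with default thresholds): `CA/CA` iff
#' `f_CA > 0.95`; `CA/LR` iff `f_WA < 0.05` and `|f_CA - f_LR| <= 0.10`;
#' `CA/WA` and `WA/LR` by symmetry.  The rule set is mutually exclusive.
#' Any call additionally requires `total >= min_classified_reads`.
#' Failures yield `"no_call"` with reason `zero_depth`, `low_depth`,
#' `ambiguous`, or -- on the X, where the intact paternal X restricts
#' the admissible classes -- `incompatible_X`.
#'
#' @param f_ca,f_wa,f_lr Fraction vectors summing to 1 where defined
#'   (checked to 1e-9).
#' @param total Total classified (diagnostic) reads per block.
#' @param thresholds A [classifier_thresholds()].
#' @param is_x Logical vector (recycled): is the block on the X?
#' @param male_x_strain Paternal X strain; on the X only genotypes with
#'   this paternal component are admissible.
#' @return `data.table` with `call` (one of the four classes or
#'   `"no_call"`) and `no_call_reason` (NA for calls).
#' @export
call_block_genotype <- function(f_ca, f_wa, f_lr, total,
                                thresholds = classifier_thresholds(),
                                is_x = FALSE, male_x_strain = "CA") {
  stopifnot(inherits(thresholds, "classifier_thresholds"))
  n <- length(f_ca)
  is_x <- rep_len(is_x, n)
  defined <- !is.na(f_ca) & total > 0
  ssum <- f_ca + f_wa + f_lr
  if (any(defined & abs(ssum - 1) > 1e-9))
    stop("internal error: fractions do not sum to 1")

  th <- thresholds
  bal <- function(fi, fj) {
    if (th$balance == "within") abs(fi - fj) <= th$het_balance_max
    else abs(fi - fj) > th$het_balance_max
  }
  rule <- cbind(
    `CA/CA` = f_ca > th$homozygote_min_fraction,
    `CA/WA` = f_lr < th$absent_max_fraction & bal(f_ca, f_wa),
    `CA/LR` = f_wa < th$absent_max_fraction & bal(f_ca, f_lr),
    `WA/LR` = f_ca < th$absent_max_fraction & bal(f_wa, f_lr))
  rule[is.na(rule)] <- FALSE
  n_hit <- rowSums(rule)
  if (any(n_hit > 1L))
    stop("internal error: genotype rules are not mutually exclusive ",
         "for the supplied thresholds")
  hit <- ifelse(n_hit == 1L, max.col(rule, ties.method = "first"),
                NA_integer_)
  call <- colnames(rule)[hit]

  # admissible X genotypes carry the intact paternal X strain
  allowed_x <- genotype_classes()[
    vapply(genotype_classes(), function(g) {
      male_x_strain %in% decompose_genotype(g)$paternal
    }, logical(1))]
  incompat <- is_x & !is.na(call) & !(call %in% allowed_x)

  reason <- rep(NA_character_, n)
  reason[!defined] <- "zero_depth"
  low <- defined & total < th$min_classified_reads
  reason[low] <- "low_depth"
  amb <- defined & !low & is.na(call)
  reason[amb] <- "ambiguous"
  reason[defined & !low & incompat] <- "incompatible_X"
  call[!is.na(reason)] <- "no_call"
  data.table(call = call, no_call_reason = reason)
}

#' Genotype every F2 in every block
#'
#' Aggregates diagnostic-allele depths per F2 per block per strain,
#' forms the site-normalised depth fractions (see
#' [compute_fractions()]), and applies [call_block_genotype()].  Every
#' F2 x block combination is represented, including zero-depth ones.
#'
#' @param depths Depth table from [sample_depths()] or
#'   [read_depths_tsv()] (`f2_id`, `chrom`, `pos`, `diag_strain`,
#'   `depth_diag`).
#' @param blocks Block table from [bin_sites()].
#' @param thresholds A [classifier_thresholds()].
#' @param male_x_strain Paternal X strain.
#' @return `data.table`: `f2_id`, `chrom`, `start`, `end`, `is_x`,
#'   per-strain depths, `total`, fractions, `call`, `no_call_reason`.
#' @export
genotype_blocks <- function(depths, blocks,
                            thresholds = classifier_thresholds(),
                            male_x_strain = "CA") {
  depths <- as.data.table(depths)
  blocks <- as.data.table(blocks)
  block_size <- attr(blocks, "block_size") %||%
    max(blocks$end - blocks$start)
  bad <- !(depths$chrom %in% unique(blocks$chrom))
  if (any(bad))
    stop("depth record on unknown chromosome: ",
         depths$chrom[bad][1L], ":", depths$pos[bad][1L],
         " (f2 ", depths$f2_id[bad][1L], ")")

  agg <- depths[, .(d = sum(depth_diag)),
                by = .(f2_id, chrom,
                       start = floor(pos / block_size) * block_size,
                       diag_strain)]
  wide <- dcast(agg, f2_id + chrom + start ~ diag_strain,
                value.var = "d", fill = 0L)
  for (s in strain_labels())
    if (!s %in% names(wide)) wide[, (s) := 0L]
  setnames(wide, strain_labels(), paste0("depth_", strain_labels()))

  grid <- CJ(f2_id = sort(unique(depths$f2_id)), idx = seq_len(nrow(blocks)))
  grid <- cbind(grid[, .(f2_id)],
                blocks[grid$idx, .(chrom, start, end, is_x,
                                   n_CA, n_WA, n_LR)])
  calls <- merge(grid, wide, by = c("f2_id", "chrom", "start"), all.x = TRUE)
  for (col in paste0("depth_", strain_labels()))
    calls[is.na(get(col)), (col) := 0L]
  fr <- compute_fractions(calls$depth_CA, calls$depth_WA, calls$depth_LR,
                          calls$n_CA, calls$n_WA, calls$n_LR)
  calls[, `:=`(total = fr$total, f_CA = fr$f_CA, f_WA = fr$f_WA,
               f_LR = fr$f_LR)]
  calls[, c("n_CA", "n_WA", "n_LR") := NULL]
  cl <- call_block_genotype(calls$f_CA, calls$f_WA, calls$f_LR,
                            calls$total, thresholds,
                            is_x = calls$is_x,
                            male_x_strain = male_x_strain)
  calls[, `:=`(call = cl$call, no_call_reason = cl$no_call_reason)]
  setorder(calls, chrom, start, f2_id)
  calls[]
}

#' Filter blocks on site count, call rate, and segregation distortion
#'
#' A block is kept iff it has at least `min_sites` diagnostic sites, at
#' most `max_uncalled_fraction` of F2 uncalled, and a segregation
#' distortion p-value above `distortion_alpha`.  Drop reasons are
#' recorded with that precedence (`too_few_sites`, `too_many_uncalled`,
#' `distorted`).
#'
#' @param calls Call matrix from [genotype_blocks()].
#' @param blocks Block table from [bin_sites()].
#' @param min_sites Minimum diagnostic sites per block (default 100).
#' @param max_uncalled_fraction Maximum tolerated fraction of uncalled
#'   F2 (default 0.30).
#' @param distortion_alpha Distortion filter level (default 0.001;
#'   blocks with p <= alpha are dropped).
#' @param male_x_strain Paternal X strain (fixes the Mendelian
#'   expectation on the X).
#' @return `data.table`: blocks plus `n_called`, `n_uncalled`,
#'   `p_value`, `kept`, `drop_reason`.
#' @export
filter_blocks <- function(calls, blocks, min_sites = 100,
                          max_uncalled_fraction = 0.30,
                          distortion_alpha = 0.001,
                          male_x_strain = "CA") {
  blocks <- as.data.table(blocks)
  calls <- as.data.table(calls)
  n_f2 <- uniqueN(calls$f2_id)
  rates <- calls[, .(n_called = sum(call != "no_call"),
                     n_uncalled = sum(call == "no_call")),
                 by = .(chrom, start)]
  dist <- distortion_test_blocks(calls, male_x_strain = male_x_strain)
  out <- merge(blocks, rates, by = c("chrom", "start"), all.x = TRUE)
  out <- merge(out, dist[, .(chrom, start, statistic, df, p_value)],
               by = c("chrom", "start"), all.x = TRUE)
  out[is.na(n_called), `:=`(n_called = 0L, n_uncalled = n_f2)]
  out[, drop_reason := NA_character_]
  out[!is.na(p_value) & p_value <= distortion_alpha,
      drop_reason := "distorted"]
  out[n_uncalled / n_f2 > max_uncalled_fraction,
      drop_reason := "too_many_uncalled"]
  out[n_sites < min_sites, drop_reason := "too_few_sites"]
  out[, kept := is.na(drop_reason)]
  setorder(out, chrom, start)
  setattr(out, "block_size", attr(blocks, "block_size"))
  out[]
}
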