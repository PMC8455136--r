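## Genetic map construction ---------------------------------------------

#' Recombination fraction between two adjacent bins
#'
#' `r` is the fraction of chromatids whose strain label differs between
#' the two bins, among chromatids called at both.  Values above 0.5 are
#' capped at 0.5 with a warning (adjacent dense bins should be tightly
#' linked).
#'
#' @param labels_left,labels_right Strain labels per chromatid at the
#'   two bins (`NA` = uncalled).
#' @return List with `r` (NA when no chromatid is informative),
#'   `n_informative`, `n_discordant`.
#' @export
#' @examples
#' interval_recombination_fraction(rep("CA", 10),
#'                                 c(rep("CA", 9), "LR"))
interval_recombination_fraction <- function(labels_left, labels_right) {
  stopifnot(length(labels_left) == length(labels_right))
  inf <- !is.na(labels_left) & !is.na(labels_right)
  n <- sum(inf)
  if (n == 0L)
    return(list(r = NA_real_, n_informative = 0L, n_discordant = 0L))
  disc <- sum(labels_left[inf] != labels_right[inf])
  r <- disc / n
  if (r > 0.5) {
    warning("interval recombination fraction ", signif(r, 3),
            " capped at 0.5")
    r <- 0.5
  }
  list(r = r, n_informative = n, n_discordant = disc)
}

map_function <- function(mapping) {
  switch(mapping,
         morgan = function(r) r,
         haldane = function(r) ifelse(r >= 0.5, Inf, -0.5 * log(1 - 2 * r)),
         kosambi = function(r) ifelse(r >= 0.5, Inf,
                                      0.25 * log((1 + 2 * r) / (1 - 2 * r))),
         stop("unknown mapping function: ", mapping))
}

#' Build sex-specific genetic maps (Marey representation)
#'
#' Treats each kept block as a single locus placed at its midpoint and
#' estimates, for every interval between adjacent bins, the
#' recombination fraction `r` from the phased chromatids.  Because the
#' block containing a crossover is frequently uncalled at shallow
#' coverage (its depth fractions are intermediate), transitions are
#' counted between consecutive *called* bins of each chromatid and each
#' transition is assigned to the adjacent-bin interval containing its
#' breakpoint midpoint; the denominator of interval `j` is the number
#' of chromatids with called bins on both sides of the interval.  With
#' complete data this reduces to the plain adjacent-bin discordance
#' fraction, and in all cases the summed interval counts equal the
#' total transition count from [phase_chromatids()].  Map distance
#' accumulates with the chosen mapping function; the default `morgan`
#' (identity, cM = 100 r summed over intervals) is appropriate for
#' dense bins where per-interval `r` is small; `haldane` and `kosambi`
#' are available for comparison.  One map is produced per chromosome
#' per parent, except that the X has no paternal map.  Intervals with
#' no informative chromatid contribute 0 cM and are flagged via
#' `n_informative = 0`.
#'
#' @param phased A [phase_chromatids()] result (or its `labels` table).
#' @param mapping `"morgan"`, `"haldane"`, or `"kosambi"`.
#' @return List of class `"genetic_map"`: `marey` (`data.table` of
#'   `chrom`, `parent`, `start`, `end`, `bin_mid`, `r`,
#'   `n_informative`, `n_discordant`, `cm_cumulative`; the interval
#'   columns describe the interval ending at each bin, `NA` for the
#'   first) and `summary` (`chrom`, `parent`, `n_bins`, `total_cm`).
#' @export
build_map <- function(phased, mapping = c("morgan", "haldane", "kosambi")) {
  mapping <- match.arg(mapping)
  mf <- map_function(mapping)
  labels <- if (inherits(phased, "phased_cohort")) phased$labels
            else as.data.table(phased)

  out <- vector("list", 0L)
  for (ch in unique(labels$chrom)) {
    lab_ch <- labels[chrom == ch]
    x_chrom <- isTRUE(lab_ch$is_x[1L])
    bl <- unique(lab_ch[, .(start, end)])
    setorder(bl, start)
    if (nrow(bl) < 2L) {
      warning("chromosome ", ch, " has fewer than 2 kept blocks; ",
              "empty map")
      next
    }
    k <- nrow(bl)
    mids <- (bl$start + bl$end) / 2
    for (side in c("paternal", "maternal")) {
      if (x_chrom && side == "paternal") next
      m <- dcast(lab_ch, f2_id ~ start, value.var = side)
      m <- as.matrix(m[, -1L, drop = FALSE])
      m <- m[, order(as.numeric(colnames(m))), drop = FALSE]
      stopifnot(ncol(m) == k)
      disc <- n_inf <- integer(k - 1L)
      for (i in seq_len(nrow(m))) {
        called <- which(!is.na(m[i, ]))
        if (length(called) < 2L) next
        f <- called[1L]; l <- called[length(called)]
        n_inf[f:(l - 1L)] <- n_inf[f:(l - 1L)] + 1L
        lab <- m[i, called]
        change <- which(lab[-1L] != lab[-length(lab)])
        for (tr in change) {
          a <- called[tr]; b <- called[tr + 1L]
          co_mid <- (bl$end[a] + bl$start[b]) / 2
          j <- min(max(findInterval(co_mid, mids), 1L), k - 1L)
          disc[j] <- disc[j] + 1L
        }
      }
      r <- ifelse(n_inf > 0L, disc / n_inf, NA_real_)
      capped <- !is.na(r) & r > 0.5
      if (any(capped)) {
        warning(sum(capped), " interval(s) on ", ch, " (", side,
                ") capped at r = 0.5")
        r[capped] <- 0.5
      }
      cm_step <- ifelse(is.na(r), 0, mf(r)) * 100
      out[[length(out) + 1L]] <-
        data.table(chrom = ch, parent = side,
                   start = bl$start, end = bl$end,
                   bin_mid = mids,
                   r = c(NA_real_, r),
                   n_informative = c(NA_integer_, n_inf),
                   n_discordant = c(NA_integer_, disc),
                   cm_cumulative = cumsum(c(0, cm_step)))
    }
  }
  marey <- rbindlist(out)
  if (nrow(marey) == 0L)
    return(structure(list(marey = marey,
                          summary = data.table(chrom = character(),
                                               parent = character(),
                                               n_bins = integer(),
                                               total_cm = numeric())),
                     class = "genetic_map"))
  smry <- marey[, .(n_bins = .N, total_cm = max(cm_cumulative)),
                by = .(chrom, parent)]
  structure(list(marey = marey, summary = smry[]), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map:", nrow(x$summary), "chromosome x parent maps\n")
  print(x$summary)
  invisible(x)
}

#' Recombination rate per chromosome region (arms versus center)
#'
#' Assigns each adjacent-bin interval to the left arm, center, or right
#' arm by the interval's physical midpoint, sums interval cM per region,
#' and reports cM/Mb together with the pooled arm:center rate ratio.
#' Region physical sizes are taken from the chromosome spec's arm
#' boundaries.
#'
#' @param map A [build_map()] result.
#' @param chromosomes Chromosome table with arm boundaries.
#' @return List with `regions` (`data.table` of `chrom`, `parent`,
#'   `region`, `cm`, `mb`, `cm_per_mb`) and `ratio` (`data.table` of
#'   `chrom`, `parent`, `arm_center_ratio`).
#' @export
arm_center_summary <- function(map, chromosomes) {
  stopifnot(inherits(map, "genetic_map"))
  chromosomes <- as_chromosome_table(chromosomes)
  marey <- map$marey
  res <- vector("list", 0L)
  for (ch in unique(marey$chrom)) {
    spec <- chrom_row(chromosomes, ch)
    mb <- c(left_arm = spec$arm1,
            center = spec$arm2 - spec$arm1,
            right_arm = spec$length_bp - spec$arm2) / 1e6
    for (side in unique(marey[chrom == ch]$parent)) {
      mm <- marey[chrom == ch & parent == side]
      setorder(mm, bin_mid)
      if (nrow(mm) < 2L) next
      step_cm <- diff(mm$cm_cumulative)
      step_mid <- (mm$bin_mid[-1L] + mm$bin_mid[-nrow(mm)]) / 2
      region <- ifelse(step_mid < spec$arm1, "left_arm",
                       ifelse(step_mid < spec$arm2, "center", "right_arm"))
      cm <- vapply(names(mb), function(rg) sum(step_cm[region == rg]),
                   numeric(1))
      res[[length(res) + 1L]] <-
        data.table(chrom = ch, parent = side, region = names(mb),
                   cm = unname(cm), mb = unname(mb),
                   cm_per_mb = unname(cm / mb))
    }
  }
  regions <- rbindlist(res)
  if (nrow(regions) == 0L)
    return(list(regions = data.table(chrom = character(),
                                     parent = character(),
                                     region = character(),
                                     cm = numeric(), mb = numeric(),
                                     cm_per_mb = numeric()),
                ratio = data.table(chrom = character(),
                                   parent = character(),
                                   arm_center_ratio = numeric())))
  ratio <- regions[, .(
    arm_center_ratio =
      (sum(cm[region != "center"]) / sum(mb[region != "center"])) /
      (sum(cm[region == "center"]) / sum(mb[region == "center"]))),
    by = .(chrom, parent)]
  list(regions = regions[], ratio = ratio[])
}
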