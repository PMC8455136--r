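## Cross-informative site selection -------------------------------------

#' Per-strain read-depth acceptance bounds
#'
#' Computes, for each parental strain, the interval mean +/- 3 standard
#' deviations of its site depths (floored at 0).  Sites whose depth
#' falls outside the interval in any strain are rejected as likely
#' repeats, collapsed duplications, or dropouts.
#'
#' @param parental Parental site table with depth columns `dp_CA`,
#'   `dp_WA`, `dp_LR` (see [make_parental_panel()] or
#'   [read_parental_vcf()]).
#' @return `data.frame` with one row per strain: `strain`, `mean`, `sd`,
#'   `lower`, `upper`.
#' @export
#' @examples
#' p <- make_parental_panel(ppa_chromosomes(scale = 0.01), 500, seed = 1)
#' compute_depth_bounds(p)
compute_depth_bounds <- function(parental) {
  if (!is.data.frame(parental) || nrow(parental) == 0L)
    stop("parental site table is empty")
  rows <- lapply(strain_labels(), function(s) {
    d <- parental[[paste0("dp_", s)]]
    if (is.null(d)) stop("missing depth column dp_", s)
    d <- d[!is.na(d)]
    if (length(d) == 0L) stop("no depths for strain ", s)
    m <- mean(d); sdev <- if (length(d) > 1L) sd(d) else 0
    data.frame(strain = s, mean = m, sd = sdev,
               lower = max(0, m - 3 * sdev), upper = m + 3 * sdev,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify parental sites as cross-informative or rejected
#'
#' A site is accepted as cross-informative iff (1) all three parents are
#' homozygous, (2) every parental depth lies within its strain's bounds,
#' (3) exactly two alleles segregate among the parents, and (4) exactly
#' one strain carries the minority allele (that strain is diagnostic).
#' Failures are typed, in order of precedence: `missing` (genotype or
#' depth absent), `het`, `depth`, `not_biallelic`, `not_diagnostic`.
#'
#' @param parental Parental site table (`chrom`, `pos`, `gt_*`, `dp_*`).
#' @param bounds Depth bounds from [compute_depth_bounds()]; computed
#'   from `parental` when `NULL`.
#' @return `data.table`: input columns plus `status` (`"informative"` or
#'   a rejection reason) and, for accepted sites, `diag_strain`,
#'   `diag_allele`, `shared_allele`.
#' @export
classify_sites <- function(parental, bounds = NULL) {
  if (!is.data.frame(parental) || nrow(parental) == 0L)
    stop("parental site table is empty")
  if (is.null(bounds)) bounds <- compute_depth_bounds(parental)
  dt <- as.data.table(parental)
  n <- nrow(dt)
  strains <- strain_labels()

  a1 <- a2 <- matrix(NA_character_, n, 3L, dimnames = list(NULL, strains))
  dp_ok <- matrix(FALSE, n, 3L)
  miss <- rep(FALSE, n)
  for (j in seq_along(strains)) {
    s <- strains[j]
    gt <- dt[[paste0("gt_", s)]]
    dp <- dt[[paste0("dp_", s)]]
    if (is.null(gt) || is.null(dp))
      stop("parental table must have gt_", s, " and dp_", s, " columns")
    parts <- tstrsplit(gt, "/", fixed = TRUE)
    a1[, j] <- parts[[1L]]
    a2[, j] <- if (length(parts) > 1L) parts[[2L]] else parts[[1L]]
    b <- bounds[bounds$strain == s, ]
    dp_ok[, j] <- !is.na(dp) & dp >= b$lower & dp <= b$upper
    miss <- miss | is.na(gt) | is.na(dp)
  }
  het <- rowSums(a1 != a2, na.rm = TRUE) > 0
  depth_bad <- rowSums(!dp_ok) > 0

  # allele structure among the three (homozygous) parental calls: with
  # two alleles the split is always 2:1, so the minority strain is the
  # diagnostic one
  ab <- a1[, 1L] == a1[, 2L]
  ac <- a1[, 1L] == a1[, 3L]
  bc <- a1[, 2L] == a1[, 3L]
  ab[is.na(ab)] <- FALSE; ac[is.na(ac)] <- FALSE; bc[is.na(bc)] <- FALSE
  n_alleles <- 1L + (!ab) + (!ac & !bc)
  diag_idx <- integer(n)
  diag_idx[ab & !ac] <- 3L   # CA == WA, LR private
  diag_idx[ac & !ab] <- 2L   # CA == LR, WA private
  diag_idx[bc & !ab] <- 1L   # WA == LR, CA private

  status <- rep("informative", n)
  status[diag_idx == 0L] <- "not_diagnostic"
  status[n_alleles != 2L] <- "not_biallelic"
  status[depth_bad] <- "depth"
  status[het] <- "het"
  status[miss] <- "missing"

  dt[, status := status]
  ok <- status == "informative"
  ds <- rep(NA_character_, n); da <- rep(NA_character_, n)
  sa <- rep(NA_character_, n)
  ds[ok] <- strains[diag_idx[ok]]
  da[ok] <- a1[cbind(which(ok), diag_idx[ok])]
  shared_col <- ifelse(diag_idx == 1L, 2L, 1L)  # any majority carrier
  sa[ok] <- a1[cbind(which(ok), shared_col[ok])]
  dt[, diag_strain := ds]
  dt[, diag_allele := da]
  dt[, shared_allele := sa]
  dt[]
}

#' Tally cross-informative sites by diagnostic strain
#'
#' @param sites Either a classified table from [classify_sites()] (rows
#'   with `status != "informative"` are ignored) or any site table with
#'   a `diag_strain` column.
#' @return List with `total` (named count per strain, genome-wide) and
#'   `by_chromosome` (`data.table` of per-chromosome counts).
#' @export
tally_informative <- function(sites) {
  dt <- as.data.table(sites)
  if ("status" %in% names(dt)) dt <- dt[status == "informative"]
  strains <- strain_labels()
  if (nrow(dt) == 0L) {
    return(list(total = setNames(rep(0L, 3L), strains),
                by_chromosome = data.table(chrom = character(),
                                           diag_strain = character(),
                                           n = integer())))
  }
  by_chr <- dt[, .(n = .N), by = .(chrom, diag_strain)]
  tot <- setNames(rep(0L, 3L), strains)
  agg <- dt[, .(n = .N), by = diag_strain]
  tot[agg$diag_strain] <- agg$n
  list(total = tot, by_chromosome = by_chr[])
}
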