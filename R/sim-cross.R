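## Meiosis and cohort simulation ----------------------------------------

#' Crossover model for one meiosis
#'
#' Parameterises where and how often crossovers (COs) are placed on a
#' bivalent.  The default emulates the obligate single CO per chromosome
#' per meiosis with arm-enriched placement: CO positions are drawn from
#' a piecewise-uniform density with relative weight `arm_weight` on the
#' two arms and 1 on the center, renormalised after zeroing any
#' `suppressed_regions`.
#'
#' @param co_per_meiosis Mean (Poisson mode) or fixed (obligate mode)
#'   number of COs per bivalent per meiosis.
#' @param obligate If `TRUE`, every meiosis receives exactly
#'   `round(co_per_meiosis)` COs (at least one), plus one extra CO with
#'   probability `double_co_rate`.  If `FALSE`, the CO count is
#'   Poisson(`co_per_meiosis`) and `double_co_rate` is ignored.
#' @param arm_weight Relative CO density on the arms versus the center
#'   (default 3; arms recombine more than centers).
#' @param suppressed_regions Optional `data.frame` with columns `chrom`,
#'   `start`, `end` (0-based half-open bp) receiving zero CO density,
#'   emulating structural CO suppression in hybrids.
#' @param double_co_rate Probability that an obligate meiosis carries a
#'   second, independently placed CO.  Default 0.006, the order of the
#'   rare doubles observed in real cohorts (6/1012 chromatids).
#'
#' @return A list of class `"co_model"`.
#' @export
co_model <- function(co_per_meiosis = 1, obligate = TRUE, arm_weight = 3,
                     suppressed_regions = NULL, double_co_rate = 0.006) {
  stopifnot(is.numeric(co_per_meiosis), co_per_meiosis >= 0,
            is.numeric(arm_weight), arm_weight >= 0,
            is.numeric(double_co_rate), double_co_rate >= 0,
            double_co_rate <= 1)
  if (!is.null(suppressed_regions)) {
    stopifnot(is.data.frame(suppressed_regions),
              all(c("chrom", "start", "end") %in% names(suppressed_regions)))
    if (any(suppressed_regions$end <= suppressed_regions$start))
      stop("suppressed_regions must have end > start")
  }
  if (obligate && round(co_per_meiosis) < 1)
    stop("obligate mode requires co_per_meiosis >= 1")
  structure(list(co_per_meiosis = co_per_meiosis, obligate = isTRUE(obligate),
                 arm_weight = arm_weight,
                 suppressed_regions = suppressed_regions,
                 double_co_rate = double_co_rate),
            class = "co_model")
}

#' Viability selection at a single locus
#'
#' Models differential survival of F2 zygotes: an F2 whose haplotype of
#' the given parental origin carries `strain` at the locus survives with
#' probability `relative_viability`; all other F2 survive with
#' probability 1.  `relative_viability = 1` means no selection.  This is
#' the hybrid-incompatibility scenario in which specific loci are toxic
#' to some hybrid progeny, producing segregation distortion.
#'
#' @param chrom,pos Locus position (bp, 0-based).
#' @param parent `"paternal"` or `"maternal"`: which inherited haplotype
#'   is inspected.
#' @param strain Disfavored strain label at the locus.
#' @param relative_viability Survival probability in `(0, 1]` for
#'   carriers (0 is accepted but can make the cohort unfillable).
#'
#' @return A list of class `"viability_selection"`.
#' @export
viability_selection <- function(chrom, pos, parent = c("maternal", "paternal"),
                                strain, relative_viability) {
  parent <- match.arg(parent)
  stopifnot(strain %in% strain_labels(),
            is.numeric(relative_viability),
            relative_viability >= 0, relative_viability <= 1)
  structure(list(chrom = chrom, pos = as.numeric(pos), parent = parent,
                 strain = strain,
                 relative_viability = relative_viability),
            class = "viability_selection")
}

#' Simulate a panel of strain-diagnostic parental variants
#'
#' Emits biallelic sites, each homozygous in all three parental strains
#' and diagnostic for exactly one of them (that strain carries a private
#' nucleotide; the other two share the alternative).  Site counts per
#' chromosome are Poisson(`sites_per_Mb` x Mb); positions are uniform,
#' distinct, and strictly increasing; the diagnostic strain is assigned
#' uniformly.  Per-strain read depths are Poisson with the given means.
#'
#' @param chromosomes Chromosome table (see [ppa_chromosomes()]).
#' @param sites_per_Mb Expected marker density per Mb.  The default 8900
#'   matches a dense short-read variant panel (~1.4 M sites over a
#'   156.7 Mb genome, ~890 sites per 100 kb block).
#' @param depth_means Named per-strain mean sequencing depths; defaults
#'   to deep parental sequencing (CA and LR 86x, WA 61x).
#' @param seed Optional integer seed (`set.seed`) for reproducibility.
#'
#' @return `data.table` with one row per site: `chrom`, `pos` (0-based),
#'   `diag_strain`, `diag_allele`, `shared_allele`, per-strain genotypes
#'   `gt_CA`, `gt_WA`, `gt_LR` (as `"A/A"`) and depths `dp_CA`, `dp_WA`,
#'   `dp_LR`.
#' @export
make_parental_panel <- function(chromosomes, sites_per_Mb = 8900,
                                depth_means = c(CA = 86, WA = 61, LR = 86),
                                seed = NULL) {
  chromosomes <- as_chromosome_table(chromosomes)
  if (!is.numeric(sites_per_Mb) || length(sites_per_Mb) != 1L ||
      is.na(sites_per_Mb) || sites_per_Mb < 0)
    stop("sites_per_Mb must be a single nonnegative number")
  stopifnot(all(strain_labels() %in% names(depth_means)))
  if (!is.null(seed)) set.seed(seed)

  nt <- c("A", "C", "G", "T")
  out <- lapply(seq_len(nrow(chromosomes)), function(i) {
    L <- chromosomes$length_bp[i]
    n <- rpois(1L, sites_per_Mb * L / 1e6)
    n <- min(n, L)
    if (n == 0L) return(NULL)
    pos <- sort(sample.int(L, n)) - 1  # 0-based, distinct, increasing
    shared <- sample(nt, n, replace = TRUE)
    # diagnostic allele differs from the shared one
    diag <- vapply(shared, function(s) sample(setdiff(nt, s), 1L), character(1))
    ds <- sample(strain_labels(), n, replace = TRUE)
    dt <- data.table(chrom = chromosomes$chrom[i], pos = pos,
                     diag_strain = ds, diag_allele = unname(diag),
                     shared_allele = shared)
    for (s in strain_labels()) {
      a <- ifelse(ds == s, diag, shared)
      dt[, paste0("gt_", s) := paste(a, a, sep = "/")]
      dt[, paste0("dp_", s) := rpois(n, depth_means[[s]])]
    }
    dt
  })
  out <- rbindlist(out)
  if (nrow(out) == 0L)
    out <- data.table(chrom = character(), pos = numeric(),
                      diag_strain = character(), diag_allele = character(),
                      shared_allele = character(),
                      gt_CA = character(), dp_CA = integer(),
                      gt_WA = character(), dp_WA = integer(),
                      gt_LR = character(), dp_LR = integer())
  out[]
}

## internal: draw n CO positions from the piecewise-uniform density
sample_co_positions <- function(n, chromosome, model) {
  if (n == 0L) return(numeric(0))
  L <- chromosome$length_bp
  pts <- c(0, chromosome$arm1, chromosome$arm2, L)
  supp <- model$suppressed_regions
  if (!is.null(supp)) {
    supp <- supp[supp$chrom == chromosome$chrom, , drop = FALSE]
    if (nrow(supp)) {
      s0 <- pmax(0, pmin(L, supp$start))
      s1 <- pmax(0, pmin(L, supp$end))
      pts <- c(pts, s0, s1)
    }
  } else {
    supp <- data.frame(start = numeric(0), end = numeric(0))
  }
  pts <- sort(unique(pts))
  lo <- head(pts, -1L)
  hi <- tail(pts, -1L)
  mid <- (lo + hi) / 2
  w <- ifelse(mid < chromosome$arm1 | mid >= chromosome$arm2,
              model$arm_weight, 1)
  if (nrow(supp))
    for (j in seq_len(nrow(supp)))
      w[mid >= supp$start[j] & mid < supp$end[j]] <- 0
  mass <- w * (hi - lo)
  if (sum(mass) <= 0)
    stop("crossover density is zero everywhere on ", chromosome$chrom)
  piece <- sample.int(length(mass), n, replace = TRUE, prob = mass)
  runif(n, lo[piece], hi[piece])
}

#' Simulate the chromatid transmitted by one meiosis
#'
#' Simulates a bivalent of the two parental homologs (each as two sister
#' chromatids), places COs according to `model`, and returns one of the
#' four chromatids chosen uniformly.  Each CO involves one chromatid of
#' each homolog, chosen uniformly, so with an obligate single CO the
#' transmitted chromatid is recombinant with probability 1/2.  For the X
#' chromosome in a male parent no exchange is modeled: the single X is
#' transmitted intact.
#'
#' @param parents Length-2 character, the two strains of the F1 parent
#'   (`c("CA", "WA")` for the male, `c("CA", "LR")` for the
#'   hermaphrodite).
#' @param chromosome A single chromosome spec (one-row `data.frame` or
#'   list with `chrom`, `length_bp`, `is_x`, `arm1`, `arm2`).
#' @param model A [co_model()].
#' @param sex `"male"` or `"hermaphrodite"`; with `sex = "male"` and an
#'   X chromosome the intact `male_x_strain` haplotype is returned.
#' @param male_x_strain Strain of the male F1's single X (default
#'   `"CA"`).
#'
#' @return List with `segments` (`data.frame` of `start`, `end`,
#'   `strain` tiling `[0, length)`) and `breakpoints` (numeric bp).
#' @export
simulate_gamete <- function(parents, chromosome, model = co_model(),
                            sex = c("hermaphrodite", "male"),
                            male_x_strain = "CA") {
  sex <- match.arg(sex)
  if (is.data.frame(chromosome)) chromosome <- as.list(chromosome[1, ])
  stopifnot(length(parents) == 2L, all(parents %in% strain_labels()),
            parents[1] != parents[2], inherits(model, "co_model"))
  L <- chromosome$length_bp

  if (isTRUE(chromosome$is_x) && sex == "male") {
    return(list(segments = data.frame(start = 0, end = L,
                                      strain = male_x_strain,
                                      stringsAsFactors = FALSE),
                breakpoints = numeric(0)))
  }

  n_co <- if (model$obligate) {
    max(1L, as.integer(round(model$co_per_meiosis))) +
      (runif(1) < model$double_co_rate)
  } else {
    rpois(1L, model$co_per_meiosis)
  }
  pos <- sort(sample_co_positions(n_co, chromosome, model))

  # four chromatids: slots 1,2 are sisters of parents[1]; 3,4 of
  # parents[2].  The transmitted chromatid is a molecule traced through
  # the bivalent: at each CO it is involved in, its path crosses to the
  # partner strand on the other homolog, so every involvement flips the
  # carried ancestry (each CO involves one chromatid per homolog,
  # chosen uniformly).
  slot <- sample.int(4L, 1L)
  lab_of <- function(s) if (s <= 2L) parents[1] else parents[2]
  seg_start <- 0
  starts <- numeric(0); labels <- character(0); brk <- numeric(0)
  lab <- lab_of(slot)
  for (p in pos) {
    a <- sample.int(2L, 1L)        # chromatid of homolog 1
    b <- 2L + sample.int(2L, 1L)   # chromatid of homolog 2
    if (slot == a) slot <- b else if (slot == b) slot <- a
    if (lab_of(slot) != lab) {
      starts <- c(starts, seg_start); labels <- c(labels, lab)
      brk <- c(brk, p)
      seg_start <- p
      lab <- lab_of(slot)
    }
  }
  starts <- c(starts, seg_start); labels <- c(labels, lab)
  list(segments = data.frame(start = starts,
                             end = c(starts[-1], L),
                             strain = labels, stringsAsFactors = FALSE),
       breakpoints = brk)
}

## internal: strain carried at position `pos` by a segments data.frame
strain_at <- function(segments, pos) {
  segments$strain[findInterval(pos, segments$start)]
}

#' Simulate an F2 cohort from the double cross
#'
#' Each F2 hermaphrodite inherits, per chromosome, one chromatid from a
#' CA/WA male F1 (spermatocyte meiosis) and one from a CA/LR
#' hermaphrodite F1 (oocyte meiosis).  The paternal X is transmitted
#' intact (`male_x_strain`), so all F2 are XX.  Each F2 is required to
#' carry a WA haplotype somewhere, emulating marker-validated cross
#' progeny; F2 without any WA segment are redrawn.  Optional viability
#' selection thins the cohort by rejection sampling.
#'
#' @param n_f2 Cohort size after validation/selection (default 93, the
#'   size of the sequenced study cohort).
#' @param chromosomes Chromosome table.
#' @param co_male,co_herm [co_model()]s for the male and hermaphrodite
#'   F1 parent.
#' @param selection Optional [viability_selection()].
#' @param male_x_strain Strain of the male F1's single X.
#' @param seed Optional integer seed.
#' @param max_tries Attempt budget per accepted F2 before an error is
#'   raised (guards against unfillable cohorts, e.g. zero viability of a
#'   genotype every F2 must carry).
#'
#' @return List of class `"f2_cohort"`: `truth` (`data.table` of
#'   ground-truth haplotype segments with columns `f2_id`, `chrom`,
#'   `parent`, `start`, `end`, `strain`), `n_f2`, `male_x_strain`,
#'   `chromosomes`, and the models used.  Segment boundaries tile each
#'   chromosome; adjacent segments differ in strain; breakpoints are the
#'   internal segment starts.
#' @export
simulate_f2_cohort <- function(n_f2 = 93, chromosomes = ppa_chromosomes(),
                               co_male = co_model(), co_herm = co_model(),
                               selection = NULL, male_x_strain = "CA",
                               seed = NULL, max_tries = 200L) {
  chromosomes <- as_chromosome_table(chromosomes)
  stopifnot(is.numeric(n_f2), n_f2 > 0)
  stopifnot(male_x_strain %in% c("CA", "WA"))
  if (!is.null(selection)) {
    stopifnot(inherits(selection, "viability_selection"))
    if (!selection$chrom %in% chromosomes$chrom)
      stop("selection locus on unknown chromosome: ", selection$chrom)
  }
  if (!is.null(seed)) set.seed(seed)
  n_f2 <- as.integer(n_f2)

  draw_one <- function(id) {
    segs <- vector("list", 2L * nrow(chromosomes))
    k <- 0L
    for (i in seq_len(nrow(chromosomes))) {
      ch <- as.list(chromosomes[i, ])
      pat <- simulate_gamete(c("CA", "WA"), ch, co_male, sex = "male",
                             male_x_strain = male_x_strain)
      mat <- simulate_gamete(c("CA", "LR"), ch, co_herm,
                             sex = "hermaphrodite")
      k <- k + 1L
      segs[[k]] <- data.table(f2_id = id, chrom = ch$chrom,
                              parent = "paternal", pat$segments)
      k <- k + 1L
      segs[[k]] <- data.table(f2_id = id, chrom = ch$chrom,
                              parent = "maternal", mat$segments)
    }
    rbindlist(segs)
  }

  accept <- function(truth1) {
    # validated cross progeny: a WA haplotype must be present
    if (!any(truth1$strain == "WA" & truth1$parent == "paternal"))
      return(FALSE)
    if (is.null(selection) || selection$relative_viability >= 1)
      return(TRUE)
    seg <- truth1[chrom == selection$chrom & parent == selection$parent]
    carrier <- strain_at(seg, selection$pos) == selection$strain
    !carrier || runif(1) < selection$relative_viability
  }

  kept <- vector("list", n_f2)
  for (id in seq_len(n_f2)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- draw_one(id)
      if (accept(cand)) { kept[[id]] <- cand; ok <- TRUE; break }
    }
    if (!ok)
      stop("could not fill cohort slot ", id, " after ", max_tries,
           " attempts; viability selection may exclude all genotypes")
  }
  truth <- rbindlist(kept)
  setkey(truth, f2_id, chrom, parent, start)
  structure(list(truth = truth, n_f2 = n_f2,
                 male_x_strain = male_x_strain,
                 chromosomes = chromosomes,
                 co_male = co_male, co_herm = co_herm,
                 selection = selection, seed = seed),
            class = "f2_cohort")
}

#' @export
print.f2_cohort <- function(x, ...) {
  cat("F2 cohort:", x$n_f2, "individuals,",
      nrow(x$chromosomes), "chromosomes\n")
  nco <- x$truth[, .N - uniqueN(paste(f2_id, chrom, parent))]
  cat("  crossover breakpoints in truth:", nco, "\n")
  cat("  male X strain:", x$male_x_strain, "\n")
  invisible(x)
}

#' Sample shallow-coverage allele depths for an F2 cohort
#'
#' Sequencing is modeled per F2, per site, per inherited haplotype: read
#' depth is Poisson(`coverage / 2`) on each haplotype, each read reports
#' the allele its haplotype carries (the site's diagnostic allele if the
#' haplotype strain equals the site's diagnostic strain, otherwise the
#' shared allele), mis-reporting the other allele with probability
#' `error_rate`.  The total read count per site is conserved between
#' draw and report.
#'
#' @param cohort An [simulate_f2_cohort()] result (or any list with a
#'   `truth` segments table and `n_f2`).
#' @param sites Site table from [make_parental_panel()] (needs `chrom`,
#'   `pos`, `diag_strain`).
#' @param coverage Mean total fold-coverage per F2 (default 5, the
#'   study's shallow shotgun depth).
#' @param error_rate Per-read misassignment probability in `[0, 0.5)`.
#' @param seed Optional integer seed.
#'
#' @return `data.table` with one row per F2 x site: `f2_id`, `chrom`,
#'   `pos`, `diag_strain`, `depth_diag` (reads carrying the diagnostic
#'   allele) and `depth_shared`.
#' @export
sample_depths <- function(cohort, sites, coverage = 5, error_rate = 0.005,
                          seed = NULL) {
  stopifnot(is.list(cohort), !is.null(cohort$truth))
  if (!is.numeric(coverage) || coverage < 0)
    stop("coverage must be >= 0")
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must be in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  sites <- as.data.table(sites)
  truth <- keyed_truth(cohort$truth)
  f2_ids <- sort(unique(truth$f2_id))

  blocks <- vector("list", 0L)
  carr_p <- vector("list", 0L)
  carr_m <- vector("list", 0L)
  for (ch in unique(sites$chrom)) {
    s <- sites[chrom == ch]
    setorder(s, pos)
    spos <- s$pos
    sdiag <- s$diag_strain
    for (id in f2_ids) {
      segp <- truth[.(id, ch, "paternal")]
      segm <- truth[.(id, ch, "maternal")]
      if (nrow(segp) == 0L || is.na(segp$start[1]))
        stop("cohort has no segments for f2 ", id, " on ", ch)
      key <- length(blocks) + 1L
      blocks[[key]] <- data.table(f2_id = id, chrom = ch, pos = spos,
                                  diag_strain = sdiag)
      carr_p[[key]] <- segp$strain[findInterval(spos, segp$start)] == sdiag
      carr_m[[key]] <- segm$strain[findInterval(spos, segm$start)] == sdiag
    }
  }
  out <- rbindlist(blocks)
  cp <- unlist(carr_p, use.names = FALSE)
  cm <- unlist(carr_m, use.names = FALSE)
  N <- nrow(out)

  d_p <- rpois(N, coverage / 2)
  d_m <- rpois(N, coverage / 2)
  fl_p <- if (error_rate > 0) rbinom(N, d_p, error_rate) else integer(N)
  fl_m <- if (error_rate > 0) rbinom(N, d_m, error_rate) else integer(N)
  diag_p <- ifelse(cp, d_p - fl_p, fl_p)
  diag_m <- ifelse(cm, d_m - fl_m, fl_m)
  out[, depth_diag := as.integer(diag_p + diag_m)]
  out[, depth_shared := as.integer(d_p + d_m) - depth_diag]
  out[]
}

## internal: truth table keyed for (f2_id, chrom, parent) subsetting
keyed_truth <- function(truth) {
  truth <- as.data.table(truth)
  if (!identical(key(truth), c("f2_id", "chrom", "parent", "start"))) {
    truth <- copy(truth)
    setkey(truth, f2_id, chrom, parent, start)
  }
  truth
}

#' True block-level haplotype labels from simulation truth
#'
#' For validation and oracle tests: the strain carried at each block
#' midpoint by each simulated chromatid, in the same layout as the
#' phased labels produced by [phase_chromatids()].
#'
#' @param cohort An [simulate_f2_cohort()] result.
#' @param blocks Block table from [bin_sites()].
#' @return `data.table` with `f2_id`, `chrom`, `start`, `end`,
#'   `paternal`, `maternal` strain labels.
#' @export
truth_block_labels <- function(cohort, blocks) {
  blocks <- as.data.table(blocks)
  truth <- keyed_truth(cohort$truth)
  f2_ids <- sort(unique(truth$f2_id))
  res <- vector("list", 0L)
  for (ch in unique(blocks$chrom)) {
    b <- blocks[chrom == ch]
    setorder(b, start)
    mids <- (b$start + b$end) / 2
    for (id in f2_ids) {
      segp <- truth[.(id, ch, "paternal")]
      segm <- truth[.(id, ch, "maternal")]
      res[[length(res) + 1L]] <-
        data.table(f2_id = id, chrom = ch, start = b$start, end = b$end,
                   paternal = segp$strain[findInterval(mids, segp$start)],
                   maternal = segm$strain[findInterval(mids, segm$start)])
    }
  }
  rbindlist(res)
}
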