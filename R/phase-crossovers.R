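## Phasing block genotypes into parental chromatids ---------------------

#' Decompose a block genotype into parental haplotype strains
#'
#' The double cross makes phasing deterministic: WA haplotypes can only
#' arrive through the sperm of the CA/WA male F1 and LR haplotypes only
#' through the ova of the CA/LR hermaphrodite F1, so each of the four
#' genotypes maps bijectively to a (paternal, maternal) strain pair.
#'
#' @param call Character vector of genotype calls; `"no_call"` and `NA`
#'   yield `NA` in both components.
#' @return List with `paternal` (CA or WA) and `maternal` (CA or LR)
#'   character vectors.
#' @export
#' @examples
#' decompose_genotype(c("CA/CA", "CA/WA", "CA/LR", "WA/LR"))
decompose_genotype <- function(call) {
  pat <- c("CA/CA" = "CA", "CA/WA" = "WA", "CA/LR" = "CA", "WA/LR" = "WA")
  mat <- c("CA/CA" = "CA", "CA/WA" = "CA", "CA/LR" = "LR", "WA/LR" = "LR")
  list(paternal = unname(pat[call]), maternal = unname(mat[call]))
}

#' Recompose a genotype from parental haplotype strains
#'
#' Inverse of [decompose_genotype()].
#'
#' @param paternal CA or WA; @param maternal CA or LR.
#' @return Genotype class character vector.
#' @export
recompose_genotype <- function(paternal, maternal) {
  stopifnot(all(is.na(paternal) | paternal %in% c("CA", "WA")),
            all(is.na(maternal) | maternal %in% c("CA", "LR")))
  ifelse(is.na(paternal) | is.na(maternal), NA_character_,
         ifelse(paternal == "CA",
                ifelse(maternal == "CA", "CA/CA", "CA/LR"),
                ifelse(maternal == "CA", "CA/WA", "WA/LR")))
}

#' Call crossovers along one chromatid's ordered block labels
#'
#' A crossover is called at each strain change between consecutive
#' *called* blocks; its interval runs from the end of the left called
#' block to the start of the right called block, so missing blocks widen
#' the interval but never create or destroy a transition.  The
#' breakpoint point-estimate is the interval midpoint.  Chromatids with
#' fewer than two called blocks carry no information and are flagged.
#'
#' @param labels Character strain labels per block, ordered by block
#'   start; `NA` marks uncalled blocks.
#' @param starts,ends Block coordinates (bp), same order as `labels`.
#' @return List: `crossovers` (`data.frame` of `left`, `right`,
#'   `midpoint`), `n_crossovers`, `n_called`, `low_information`.
#' @export
call_crossovers <- function(labels, starts, ends) {
  stopifnot(length(labels) == length(starts),
            length(labels) == length(ends))
  if (is.unsorted(starts)) {
    o <- order(starts)
    labels <- labels[o]; starts <- starts[o]; ends <- ends[o]
  }
  called <- which(!is.na(labels))
  if (length(called) < 2L) {
    return(list(crossovers = data.frame(left = numeric(0),
                                        right = numeric(0),
                                        midpoint = numeric(0)),
                n_crossovers = 0L, n_called = length(called),
                low_information = TRUE))
  }
  lab <- labels[called]
  change <- which(lab[-1L] != lab[-length(lab)])
  left <- ends[called[change]]
  right <- starts[called[change + 1L]]
  list(crossovers = data.frame(left = left, right = right,
                               midpoint = (left + right) / 2),
       n_crossovers = length(change), n_called = length(called),
       low_information = FALSE)
}

#' Phase a call matrix into parental chromatids and crossovers
#'
#' Decomposes every called block into paternal/maternal strain labels
#' and calls crossovers per F2 per chromosome per parent.  Only blocks
#' present in `blocks` (normally the kept set from [filter_blocks()])
#' are used.  The paternal X is a single intact haplotype by design and
#' is marked unmappable (`mappable = FALSE`); it is excluded from
#' chromatid tallies and maps.  Chromatids with more than `suspect_co`
#' crossovers are flagged `suspect` (possible genotyping error), but no
#' smoothing is applied: every transition counts.
#'
#' @param calls Call matrix from [genotype_blocks()].
#' @param blocks Block table; rows with a `kept` column equal to `FALSE`
#'   are ignored.
#' @param male_x_strain Paternal X strain.
#' @param suspect_co Flag threshold for per-chromatid crossover count.
#' @return List of class `"phased_cohort"`:
#'   * `labels`: `data.table` (`f2_id`, `chrom`, `start`, `end`, `is_x`,
#'     `paternal`, `maternal`);
#'   * `chromatids`: per-chromatid summary (`f2_id`, `chrom`, `parent`,
#'     `n_called`, `n_crossovers`, `is_recombinant`, `low_information`,
#'     `suspect`, `mappable`, `strain` -- the single strain label for
#'     nonrecombinant chromatids, `NA` otherwise);
#'   * `crossovers`: crossover intervals (`f2_id`, `chrom`, `parent`,
#'     `left`, `right`, `midpoint`).
#' @export
phase_chromatids <- function(calls, blocks, male_x_strain = "CA",
                             suspect_co = 3L) {
  calls <- as.data.table(calls)
  blocks <- as.data.table(blocks)
  if ("kept" %in% names(blocks)) blocks <- blocks[kept == TRUE]
  use <- merge(calls, blocks[, .(chrom, start)], by = c("chrom", "start"))
  dec <- decompose_genotype(ifelse(use$call == "no_call", NA, use$call))
  labels <- use[, .(f2_id, chrom, start, end, is_x)]
  labels[, `:=`(paternal = dec$paternal, maternal = dec$maternal)]
  setorder(labels, f2_id, chrom, start)

  chromatids <- vector("list", 0L)
  crossovers <- vector("list", 0L)
  for (side in c("paternal", "maternal")) {
    res <- labels[, {
      cc <- call_crossovers(get(side), start, end)
      xl <- cc$crossovers
      list(n_called = cc$n_called,
           n_crossovers = cc$n_crossovers,
           low_information = cc$low_information,
           strain = if (cc$n_crossovers == 0L && cc$n_called > 0L)
             get(side)[!is.na(get(side))][1L] else NA_character_,
           co_left = list(xl$left), co_right = list(xl$right),
           x_chrom = is_x[1L])
    }, by = .(f2_id, chrom)]
    res[, parent := side]
    chromatids[[side]] <- res
  }
  ch <- rbindlist(chromatids)
  co <- ch[lengths(co_left) > 0L,
           .(left = as.numeric(unlist(co_left)),
             right = as.numeric(unlist(co_right))),
           by = .(f2_id, chrom, parent)]
  co[, midpoint := (left + right) / 2]
  ch[, `:=`(co_left = NULL, co_right = NULL)]
  ch[, is_recombinant := n_crossovers >= 1L]
  ch[, suspect := n_crossovers > suspect_co]
  ch[, mappable := !(x_chrom & parent == "paternal")]
  setnames(ch, "x_chrom", "is_x")
  setcolorder(ch, c("f2_id", "chrom", "parent", "is_x", "n_called",
                    "n_crossovers", "is_recombinant", "low_information",
                    "suspect", "strain", "mappable"))
  setorder(ch, f2_id, chrom, parent)
  structure(list(labels = labels[], chromatids = ch[], crossovers = co[]),
            class = "phased_cohort")
}

#' Summarise chromatids: nonrecombinant and double-crossover fractions
#'
#' Fractions are computed over informative chromatids (at least two
#' called blocks); the intact paternal X is excluded from all
#' denominators, since no male-specific map exists for the X.
#'
#' @param phased A [phase_chromatids()] result (or its `chromatids`
#'   table).
#' @return List with `per_parent` and `per_chromosome` `data.table`s of
#'   chromatid counts, nonrecombinant fractions, and double-CO
#'   (`n_crossovers >= 2`) fractions.
#' @export
tally_chromatids <- function(phased) {
  ch <- if (inherits(phased, "phased_cohort")) phased$chromatids
        else as.data.table(phased)
  ch <- ch[mappable == TRUE & low_information == FALSE]
  summarise <- function(d, by) {
    d[, .(n_chromatids = .N,
          n_nonrecombinant = sum(n_crossovers == 0L),
          fraction_nonrecombinant = mean(n_crossovers == 0L),
          n_double_co = sum(n_crossovers >= 2L),
          fraction_double_co = mean(n_crossovers >= 2L)),
      by = by]
  }
  list(per_parent = summarise(ch, "parent"),
       per_chromosome = summarise(ch, c("chrom", "parent")))
}
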