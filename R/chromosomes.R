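## Chromosome specifications --------------------------------------------

#' Describe a chromosome for simulation and mapping
#'
#' A chromosome is described by its name, physical length, whether it is
#' the X, and two coordinates splitting it into left arm / center /
#' right arm.  The distal arms of nematode chromosomes recombine at
#' higher rates than the centers, so the crossover simulator and the
#' arm/center map summaries both need the arm boundaries.
#'
#' @param name Chromosome identifier (e.g. `"chrI"`).
#' @param length Physical length in bp (positive integer).
#' @param is_x Logical; `TRUE` for the X chromosome.  Hermaphrodites are
#'   XX, males XO: the single male X has no pairing partner, does not
#'   recombine, and yields no male-specific map.
#' @param arm_boundaries Numeric length-2, strictly increasing, within
#'   `[0, length]`.  Defaults to the outer thirds
#'   (`c(length/3, 2*length/3)`).
#'
#' @return A one-row `data.frame` with columns `chrom`, `length_bp`,
#'   `is_x`, `arm1`, `arm2`.
#' @seealso [ppa_chromosomes()] for the default six-chromosome karyotype.
#' @export
chromosome_spec <- function(name, length, is_x = FALSE, arm_boundaries = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  length <- as.numeric(length)
  if (!is.finite(length) || length <= 0)
    stop("chromosome length must be a positive number of bp")
  if (is.null(arm_boundaries))
    arm_boundaries <- c(length / 3, 2 * length / 3)
  arm_boundaries <- as.numeric(arm_boundaries)
  if (length(arm_boundaries) != 2L ||
      !all(is.finite(arm_boundaries)) ||
      arm_boundaries[1] >= arm_boundaries[2] ||
      arm_boundaries[1] < 0 || arm_boundaries[2] > length)
    stop("arm_boundaries must be two increasing coordinates within [0, length]")
  data.frame(chrom = name, length_bp = length, is_x = isTRUE(is_x),
             arm1 = arm_boundaries[1], arm2 = arm_boundaries[2],
             stringsAsFactors = FALSE)
}

#' Default six-chromosome karyotype
#'
#' Returns the 2n = 12 karyotype used throughout the package: five
#' autosomes (I--V) and the X, with approximate assembly lengths
#' totalling 156.7 Mb, chromosome I the longest.  Arm boundaries default
#' to the outer thirds of each chromosome.
#'
#' @param scale Multiplier applied to all physical lengths.  Genetic map
#'   lengths do not depend on physical scale, so scaled-down genomes
#'   (e.g. `scale = 0.2`) reproduce the same map expectations at a
#'   fraction of the simulation cost.
#'
#' @return `data.frame` of chromosome specifications (one row per
#'   chromosome; see [chromosome_spec()]).
#' @export
#' @examples
#' ppa_chromosomes()
ppa_chromosomes <- function(scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  nm <- c("chrI", "chrII", "chrIII", "chrIV", "chrV", "chrX")
  mb <- c(36.8, 27.4, 25.5, 29.1, 21.2, 16.7)
  do.call(rbind, lapply(seq_along(nm), function(i) {
    chromosome_spec(nm[i], round(mb[i] * 1e6 * scale), is_x = nm[i] == "chrX")
  }))
}

## internal: validate a chromosome table and return it keyed by name
as_chromosome_table <- function(chromosomes) {
  need <- c("chrom", "length_bp", "is_x", "arm1", "arm2")
  if (!is.data.frame(chromosomes) || !all(need %in% names(chromosomes)))
    stop("chromosomes must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (nrow(chromosomes) == 0L) stop("chromosome table is empty")
  if (anyDuplicated(chromosomes$chrom))
    stop("duplicated chromosome names")
  ok <- chromosomes$length_bp > 0 &
    chromosomes$arm1 < chromosomes$arm2 &
    chromosomes$arm1 >= 0 & chromosomes$arm2 <= chromosomes$length_bp
  if (!all(ok))
    stop("invalid chromosome spec for: ",
         paste(chromosomes$chrom[!ok], collapse = ", "))
  chromosomes
}

chrom_row <- function(chromosomes, name) {
  i <- match(name, chromosomes$chrom)
  if (is.na(i)) stop("unknown chromosome: ", name)
  as.list(chromosomes[i, , drop = FALSE])
}
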