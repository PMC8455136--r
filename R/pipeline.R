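## End-to-end pipeline --------------------------------------------------

#' Pipeline configuration
#'
#' Collects every tunable of the simulate -> sites -> genotype ->
#' phase -> map -> distortion chain with the package defaults: a 93-F2
#' cohort of the double cross, obligate single crossover per chromosome
#' per meiosis with arm weight 3, ~5x coverage with 0.5% read error,
#' 100 kb blocks, the 0.95/0.05/0.10 fraction thresholds, the
#' 100-site / 30%-uncalled / p <= 0.001 block filters, and the morgan
#' mapping function.  The default genome is the six-chromosome
#' karyotype scaled to 20% physical length (31.3 Mb), which keeps the
#' simulation light while leaving every genetic-map expectation
#' unchanged.
#'
#' @param chromosomes Chromosome table.
#' @param sites_per_Mb Marker density for the simulated parental panel.
#' @param n_f2 Cohort size.
#' @param coverage,error_rate Read-sampling parameters
#'   ([sample_depths()]).
#' @param co_male,co_herm Crossover models per F1 parent ([co_model()]).
#' @param selection Optional [viability_selection()].
#' @param male_x_strain Strain of the male F1's intact X.
#' @param thresholds Caller thresholds ([classifier_thresholds()]).
#' @param block_size Genotyping block width (bp).
#' @param min_sites,max_uncalled_fraction,distortion_alpha Block
#'   filters ([filter_blocks()]).
#' @param mapping Mapping function for [build_map()].
#' @param gradient_n_perm Permutations for the per-chromosome gradient
#'   tests run by the pipeline.
#' @param seed Seed for the whole run.
#' @param out_dir Optional directory; when set, [run_pipeline()] writes
#'   all artifacts there.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(chromosomes = ppa_chromosomes(scale = 0.2),
                            sites_per_Mb = 8900,
                            n_f2 = 93,
                            coverage = 5,
                            error_rate = 0.005,
                            co_male = co_model(),
                            co_herm = co_model(),
                            selection = NULL,
                            male_x_strain = "CA",
                            thresholds = classifier_thresholds(),
                            block_size = 1e5,
                            min_sites = 100,
                            max_uncalled_fraction = 0.30,
                            distortion_alpha = 0.001,
                            mapping = "morgan",
                            gradient_n_perm = 1000L,
                            seed = 1L,
                            out_dir = NULL) {
  cfg <- list(chromosomes = as_chromosome_table(chromosomes),
              sites_per_Mb = sites_per_Mb, n_f2 = n_f2,
              coverage = coverage, error_rate = error_rate,
              co_male = co_male, co_herm = co_herm,
              selection = selection, male_x_strain = male_x_strain,
              thresholds = thresholds, block_size = block_size,
              min_sites = min_sites,
              max_uncalled_fraction = max_uncalled_fraction,
              distortion_alpha = distortion_alpha, mapping = mapping,
              gradient_n_perm = as.integer(gradient_n_perm),
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

log_stage <- function(quiet, ...) if (!quiet) message(...)

#' Run the full recombination-mapping pipeline on simulated data
#'
#' Chains simulate -> sites -> genotype -> phase -> map -> distortion
#' under a single seed, logging the filtering funnel (sites accepted and
#' rejected by reason, blocks dropped by reason, chromatids flagged).
#' When `config$out_dir` is set, all artifacts are written: parental
#' VCF, sites TSV/BED, depths TSV, truth JSON, block BED, call and
#' fraction TSV, chromatid and crossover TSV, Marey and summary TSV,
#' distortion TSV, and a JSON run manifest (configuration, seed,
#' package version, funnel counts).
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return List with every intermediate and final object: `parental`,
#'   `bounds`, `classified`, `sites`, `cohort`, `depths`, `blocks`,
#'   `calls`, `distortion`, `filtered_blocks`, `phased`, `tally`,
#'   `map`, `arm_summary`, `bias`, `gradients`, `funnel`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)

  log_stage(quiet, "simulate: parental panel (",
            config$sites_per_Mb, " sites/Mb)")
  parental <- make_parental_panel(config$chromosomes,
                                  sites_per_Mb = config$sites_per_Mb)
  log_stage(quiet, "simulate: F2 cohort (n = ", config$n_f2, ")")
  cohort <- simulate_f2_cohort(n_f2 = config$n_f2,
                               chromosomes = config$chromosomes,
                               co_male = config$co_male,
                               co_herm = config$co_herm,
                               selection = config$selection,
                               male_x_strain = config$male_x_strain)
  log_stage(quiet, "simulate: depths (", config$coverage, "x, error ",
            config$error_rate, ")")
  depths <- sample_depths(cohort, parental, coverage = config$coverage,
                          error_rate = config$error_rate)

  bounds <- compute_depth_bounds(parental)
  classified <- classify_sites(parental, bounds)
  sites <- classified[classified$status == "informative"]
  site_funnel <- table(classified$status)
  log_stage(quiet, "sites: ", nrow(sites), "/", nrow(classified),
            " cross-informative")
  depths_inf <- merge(depths,
                      sites[, list(chrom, pos)], by = c("chrom", "pos"))

  blocks <- bin_sites(sites, config$chromosomes,
                      block_size = config$block_size)
  calls <- genotype_blocks(depths_inf, blocks,
                           thresholds = config$thresholds,
                           male_x_strain = config$male_x_strain)
  distortion <- distortion_test_blocks(calls,
                                       male_x_strain =
                                         config$male_x_strain)
  filtered <- filter_blocks(calls, blocks,
                            min_sites = config$min_sites,
                            max_uncalled_fraction =
                              config$max_uncalled_fraction,
                            distortion_alpha = config$distortion_alpha,
                            male_x_strain = config$male_x_strain)
  block_funnel <- table(factor(filtered$drop_reason,
                               levels = c("too_few_sites",
                                          "too_many_uncalled",
                                          "distorted")),
                        useNA = "no")
  log_stage(quiet, "blocks: ", sum(filtered$kept), "/", nrow(filtered),
            " kept (dropped: ",
            paste(names(block_funnel), block_funnel, sep = "=",
                  collapse = ", "), ")")

  phased <- phase_chromatids(calls, filtered,
                             male_x_strain = config$male_x_strain)
  # distortion reporting is based on the unfiltered call matrix:
  # coherent chromosome-scale distortion would otherwise remove its own
  # blocks through the distortion filter
  phased_unfiltered <- phase_chromatids(calls, blocks,
                                        male_x_strain =
                                          config$male_x_strain)
  tally <- tally_chromatids(phased)
  log_stage(quiet, "chromatids: ",
            sum(phased$chromatids$suspect), " flagged suspect (>3 COs), ",
            sum(phased$chromatids$low_information), " low-information")

  map <- build_map(phased, mapping = config$mapping)
  arm_summary <- arm_center_summary(map, config$chromosomes)

  bias <- list()
  gradients <- list()
  for (i in seq_len(nrow(config$chromosomes))) {
    ch <- config$chromosomes$chrom[i]
    for (side in c("paternal", "maternal")) {
      if (config$chromosomes$is_x[i] && side == "paternal") next
      key <- paste(ch, side, sep = ".")
      b <- nonrecombinant_ratio(phased_unfiltered, ch, side)
      bias[[key]] <- b
      hf <- haplotype_frequency(phased_unfiltered, side, b$favored)
      hf <- hf[hf$chrom == ch & !is.na(hf$freq)]
      gradients[[key]] <-
        if (nrow(hf) >= 3L)
          c(list(chromosome = ch, parent = side, strain = b$favored),
            distortion_gradient(hf$freq, hf$bin_mid,
                                n_perm = config$gradient_n_perm))
        else NULL
    }
  }

  funnel <- list(sites = as.list(site_funnel),
                 blocks_total = nrow(filtered),
                 blocks_kept = sum(filtered$kept),
                 blocks_dropped = as.list(block_funnel),
                 chromatids_suspect = sum(phased$chromatids$suspect),
                 chromatids_low_information =
                   sum(phased$chromatids$low_information))

  result <- list(parental = parental, bounds = bounds,
                 classified = classified, sites = sites,
                 cohort = cohort, depths = depths, blocks = blocks,
                 calls = calls, distortion = distortion,
                 filtered_blocks = filtered, phased = phased,
                 phased_unfiltered = phased_unfiltered,
                 tally = tally, map = map, arm_summary = arm_summary,
                 bias = bias, gradients = gradients, funnel = funnel,
                 config = config)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, quiet)
  result
}

write_pipeline_outputs <- function(result, quiet = FALSE) {
  dir.create(result$config$out_dir, recursive = TRUE,
             showWarnings = FALSE)
  p <- function(f) file.path(result$config$out_dir, f)
  write_parental_vcf(result$parental, p("parental.vcf"),
                     result$config$chromosomes)
  write_sites_tsv(result$sites, p("informative_sites.tsv"))
  write_sites_bed(result$sites, p("informative_sites.bed"))
  write_depths_tsv(result$depths, result$parental, p("f2_depths.tsv"))
  write_truth_json(result$cohort, p("sim_truth.json"))
  write_blocks_bed(result$blocks, p("blocks.bed"))
  fwrite(result$calls, p("block_calls.tsv"), sep = "\t")
  fwrite(result$filtered_blocks, p("block_filter.tsv"), sep = "\t")
  fwrite(result$phased$chromatids, p("chromatids.tsv"), sep = "\t")
  fwrite(result$phased$crossovers, p("crossovers.tsv"), sep = "\t")
  fwrite(result$map$marey, p("marey.tsv"), sep = "\t")
  fwrite(result$map$summary, p("map_summary.tsv"), sep = "\t")
  fwrite(result$distortion, p("distortion.tsv"), sep = "\t")
  manifest <- list(
    package = "hybridmap",
    version = as.character(utils::packageVersion("hybridmap")),
    r_version = R.version.string,
    seed = result$config$seed,
    config = config_manifest(result$config),
    funnel = result$funnel)
  jsonlite::write_json(manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  log_stage(quiet, "wrote artifacts to ", result$config$out_dir)
  invisible(result$config$out_dir)
}

config_manifest <- function(cfg) {
  out <- cfg
  out$chromosomes <- as.data.frame(cfg$chromosomes)
  out$co_male <- unclass(cfg$co_male)
  out$co_herm <- unclass(cfg$co_herm)
  if (!is.null(cfg$selection)) out$selection <- unclass(cfg$selection)
  out$thresholds <- unclass(cfg$thresholds)
  unclass(out)
}
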