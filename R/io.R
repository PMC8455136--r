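## File formats ---------------------------------------------------------
##
## Interchange conventions: TSV with documented headers for sites,
## depths, calls and maps; VCF for parental variants (1-based, as the
## format requires); BED (0-based half-open) for sites and blocks; JSON
## for truth, summaries and the run manifest.  All non-VCF coordinates
## are 0-based half-open.

#' Write a parental variant panel as a minimal VCF
#'
#' Emits a VCFv4.2 file with the three strains as samples and GT:DP
#' fields.  REF is the CA (reference strain) allele; ALT the other
#' segregating allele.  Positions are converted to 1-based.
#'
#' @param sites Panel from [make_parental_panel()].
#' @param path Output path.
#' @param chromosomes Optional chromosome table; adds `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_parental_vcf <- function(sites, path, chromosomes = NULL) {
  sites <- as.data.table(sites)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=hybridmap",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  if (!is.null(chromosomes))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          chromosomes$chrom,
                          as.integer(chromosomes$length_bp)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", strain_labels()),
                      collapse = "\t"))
  allele_of <- function(s)
    ifelse(sites$diag_strain == s, sites$diag_allele, sites$shared_allele)
  ref <- allele_of("CA")
  alt <- ifelse(sites$diag_allele == ref, sites$shared_allele,
                sites$diag_allele)
  fmt_sample <- function(s) {
    gt <- ifelse(allele_of(s) == ref, "0/0", "1/1")
    paste0(gt, ":", sites[[paste0("dp_", s)]])
  }
  body <- paste(sites$chrom, format(sites$pos + 1, scientific = FALSE,
                                    trim = TRUE),
                ".", ref, alt, ".", "PASS", ".", "GT:DP",
                fmt_sample("CA"), fmt_sample("WA"), fmt_sample("LR"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a multi-sample parental VCF into a parental site table
#'
#' Uses \pkg{vcfR} to parse GT and DP for the three strain samples
#' (sample names must be CA, WA, LR).  Only SNVs are retained;
#' positions are converted to 0-based.
#'
#' @param path VCF path.
#' @return `data.table` with `chrom`, `pos`, `gt_*` (as `"A/A"`),
#'   `dp_*` columns, ready for [classify_sites()].
#' @export
read_parental_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  miss <- setdiff(strain_labels(), colnames(gt))
  if (length(miss))
    stop("VCF lacks samples: ", paste(miss, collapse = ", "))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snv <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt)
  out <- data.table(chrom = fix[snv, "CHROM"],
                    pos = as.numeric(fix[snv, "POS"]) - 1)
  decode <- function(codes, i) {
    a <- rep(NA_character_, length(codes))
    a[!is.na(codes) & codes %in% c("0/0", "0|0")] <- ref[snv][
      !is.na(codes) & codes %in% c("0/0", "0|0")]
    a[!is.na(codes) & codes %in% c("1/1", "1|1")] <- alt[snv][
      !is.na(codes) & codes %in% c("1/1", "1|1")]
    het <- !is.na(codes) & codes %in% c("0/1", "1/0", "0|1", "1|0")
    a[het] <- paste0(ref[snv][het], "/", alt[snv][het])
    hom <- !is.na(a) & !grepl("/", a)
    a[hom] <- paste0(a[hom], "/", a[hom])
    a
  }
  for (s in strain_labels()) {
    out[, paste0("gt_", s) := decode(gt[snv, s])]
    out[, paste0("dp_", s) := dp[snv, s]]
  }
  setorder(out, chrom, pos)
  out[]
}

#' @rdname sites_tsv
#' @export
write_sites_tsv <- function(sites, path) {
  fwrite(as.data.table(sites), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read and write site tables as TSV
#'
#' Plain TSV with header; coordinates 0-based half-open.
#'
#' @param sites Site table; @param path File path.
#' @return The table (read) or `path` invisibly (write).
#' @name sites_tsv
#' @export
read_sites_tsv <- function(path) {
  fread(path, sep = "\t")
}

#' Write sites or blocks as BED (0-based half-open)
#'
#' @param sites Informative-site table; @param blocks block table;
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  sites <- as.data.table(sites)
  fwrite(sites[, .(chrom, start = as.integer(pos),
                   end = as.integer(pos) + 1L, name = diag_strain)],
         path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_bed
#' @export
write_blocks_bed <- function(blocks, path) {
  blocks <- as.data.table(blocks)
  fwrite(blocks[, .(chrom, start = as.integer(start),
                    end = as.integer(end),
                    name = paste0("n_sites=", n_sites))],
         path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write F2 allele depths as long TSV
#'
#' One row per F2 x site x allele with a positive read count, columns
#' `f2_id`, `chrom`, `pos` (0-based), `allele` (nucleotide), `depth`.
#' Zero-depth alleles are omitted; they carry no information and are
#' reconstructed implicitly on read.
#'
#' @param depths Wide depth table from [sample_depths()].
#' @param sites Site table supplying the allele nucleotides.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depths_tsv <- function(depths, sites, path) {
  depths <- as.data.table(depths)
  sites <- as.data.table(sites)
  m <- merge(depths, sites[, .(chrom, pos, diag_allele, shared_allele)],
             by = c("chrom", "pos"))
  long <- rbind(
    m[depth_diag > 0, .(f2_id, chrom, pos, allele = diag_allele,
                        depth = depth_diag)],
    m[depth_shared > 0, .(f2_id, chrom, pos, allele = shared_allele,
                          depth = depth_shared)])
  setorder(long, f2_id, chrom, pos)
  fwrite(long, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a long depth TSV back into the wide per-site layout
#'
#' @param path Depth TSV from [write_depths_tsv()].
#' @param sites Site table (defines diagnostic strain and alleles).
#' @return Wide `data.table` as produced by [sample_depths()]; sites
#'   with no reads for an F2 are absent (they contribute zero depth).
#' @export
read_depths_tsv <- function(path, sites) {
  long <- fread(path, sep = "\t")
  sites <- as.data.table(sites)
  m <- merge(long,
             sites[, .(chrom, pos, diag_strain, diag_allele,
                       shared_allele)],
             by = c("chrom", "pos"))
  unknown <- is.na(m$diag_allele) |
    (m$allele != m$diag_allele & m$allele != m$shared_allele)
  if (any(unknown))
    stop("depth record with allele absent from the site table at line ",
         which(unknown)[1L])
  out <- m[, .(depth_diag = sum(depth[allele == diag_allele]),
               depth_shared = sum(depth[allele == shared_allele])),
           by = .(f2_id, chrom, pos, diag_strain)]
  setorder(out, f2_id, chrom, pos)
  out[]
}

#' Write and read simulation ground truth as JSON
#'
#' Records the per-F2, per-chromosome, per-parent haplotype segments
#' and crossover breakpoints (0-based half-open bp), plus cohort
#' metadata.
#'
#' @param cohort An [simulate_f2_cohort()] result.
#' @param path Output path.
#' @return `path` invisibly (write); a list with `truth` table and
#'   metadata (read).
#' @export
write_truth_json <- function(cohort, path) {
  payload <- list(
    coordinates = "0-based half-open bp",
    n_f2 = cohort$n_f2,
    male_x_strain = cohort$male_x_strain,
    seed = cohort$seed,
    segments = as.data.frame(cohort$truth))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- as.data.table(payload$segments)
  setkey(truth, f2_id, chrom, parent, start)
  list(truth = truth, n_f2 = payload$n_f2,
       male_x_strain = payload$male_x_strain, seed = payload$seed)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML may set any argument of [pipeline_config()]; `chromosomes`
#' is given as a list of `{name, length, is_x, arm_boundaries}`
#' records, `co_male`/`co_herm` as [co_model()] argument lists, and
#' `selection` as a [viability_selection()] argument list.
#'
#' @param path YAML path.
#' @return A [pipeline_config()] list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$chromosomes))
    args$chromosomes <- do.call(rbind, lapply(y$chromosomes, function(ch)
      chromosome_spec(ch$name, ch$length, isTRUE(ch$is_x),
                      ch$arm_boundaries)))
  for (cm in c("co_male", "co_herm"))
    if (!is.null(y[[cm]])) args[[cm]] <- do.call(co_model, y[[cm]])
  if (!is.null(y$selection))
    args$selection <- do.call(viability_selection, y$selection)
  if (!is.null(y$thresholds))
    args$thresholds <- do.call(classifier_thresholds, y$thresholds)
  do.call(pipeline_config, args)
}
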