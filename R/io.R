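# Plain-text interchange: TSV readers/writers for the tables each stage
# consumes or emits, and BED export for candidate regions.

write_tsv_ <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_ <- function(path, required) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if_not(all(required %in% names(x)),
              "%s lacks required columns: %s", path,
              paste(setdiff(required, names(x)), collapse = ", "))
  x
}

#' Read / write pool count tables
#'
#' Columns: `locus_id`, `chrom`, `pos_bp`, `ref_depth`, `alt_depth`.
#' @param x a pool count table (see [pool_counts]).
#' @param path file path.
#' @return `read_pool_counts` returns the data.frame; the writer returns
#'   `path` invisibly.
#' @export
write_pool_counts <- function(x, path) write_tsv_(x, path)

#' @rdname write_pool_counts
#' @export
read_pool_counts <- function(path) {
  read_tsv_(path, c("chrom", "pos_bp", "ref_depth", "alt_depth"))
}

#' Read / write cross count tables
#'
#' Columns: `cross_class`, `maternal`, `n_green`, `n_white`
#' (see [screen_models]).
#' @inheritParams write_pool_counts
#' @export
write_cross_counts <- function(x, path) write_tsv_(x, path)

#' @rdname write_cross_counts
#' @export
read_cross_counts <- function(path) {
  read_tsv_(path, c("cross_class", "maternal", "n_green", "n_white"))
}

#' Read / write recombinant record tables
#'
#' Columns: `id`, `phenotype`, `partner_genotype`, `f3_green`, `f3_white`,
#' plus one ordered column per marker (see
#' [simulate_recombinant_records]).
#' @inheritParams write_pool_counts
#' @export
write_recombinant_records <- function(x, path) write_tsv_(x, path)

#' @rdname write_recombinant_records
#' @export
read_recombinant_records <- function(path) {
  read_tsv_(path, c("id", "phenotype", "partner_genotype",
                    "f3_green", "f3_white"))
}

#' Read / write linkage maps as a loci TSV
#'
#' The TSV holds one row per locus (`locus_id`, `chrom`, `pos_cM`, `pos_bp`,
#' `chrom_length_cM`); chromosomes are reconstructed from the per-locus
#' length column.
#' @param map a [linkage_map].
#' @param path file path.
#' @export
write_linkage_map <- function(map, path) {
  loci <- map$loci
  loci$chrom_length_cM <-
    map$chromosomes$length_cM[match(loci$chrom, map$chromosomes$chrom)]
  write_tsv_(loci, path)
}

#' @rdname write_linkage_map
#' @export
read_linkage_map <- function(path) {
  x <- read_tsv_(path, c("locus_id", "chrom", "pos_cM", "chrom_length_cM"))
  chroms <- unique(x[, c("chrom", "chrom_length_cM")])
  names(chroms) <- c("chrom", "length_cM")
  linkage_map(chroms, x[, setdiff(names(x), "chrom_length_cM")])
}

#' Export genotype codes of a population as TSV
#'
#' Individual x locus table of codes `G`/`H`/`N`, with phenotype and
#' cytoplasm columns when available.
#' @param pop a `cross_population`.
#' @param path file path.
#' @export
write_genotypes <- function(pop, path) {
  codes <- as.data.frame(genotype_codes(pop))
  out <- cbind(data.frame(individual = sprintf("ind%05d",
                                               seq_len(nrow(codes))),
                          cytoplasm = pop$cytoplasm), codes)
  if (!is.null(pop$phenotype)) out <- cbind(out[, 1:2],
                                            phenotype = pop$phenotype,
                                            out[, -(1:2)])
  write_tsv_(out, path)
}

#' Export candidate regions as BED
#'
#' Half-open 0-based intervals (BED convention); the score column carries
#' the peak window's mean frequency difference.
#' @param regions region table from [call_regions] (`top_regions` or
#'   `bottom_regions`).
#' @param path file path.
#' @export
write_regions_bed <- function(regions, path) {
  stop_if_not(is.data.frame(regions), "no regions to write")
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start_bp,
                    end = regions$end_bp,
                    name = sprintf("region%02d", seq_len(nrow(regions))),
                    score = signif(regions$peak_mean_diff, 4))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
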