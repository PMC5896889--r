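#' Construct a linkage map
#'
#' A linkage map holds the chromosomes (with genetic lengths in centimorgans)
#' and the loci the simulator tracks: causal loci, genotyping markers, and/or
#' SNP-panel sites.  Physical (bp) positions are optional but, when present,
#' must increase with genetic position within a chromosome.
#'
#' @param chromosomes data.frame with columns `chrom` (character) and
#'   `length_cM` (positive numeric).
#' @param loci data.frame with columns `locus_id` (unique character), `chrom`,
#'   `pos_cM` (in `[0, length_cM]`), and optionally `pos_bp` (integer or NA).
#' @return An object of class `linkage_map`: a list with the two validated
#'   data frames, loci sorted by chromosome and genetic position.
#' @examples
#' chr <- data.frame(chrom = c("chr13", "chr14"), length_cM = c(100, 100))
#' loci <- data.frame(locus_id = c("hl13", "hl14"), chrom = c("chr13", "chr14"),
#'                    pos_cM = c(95, 50), pos_bp = c(28500000, 15000000))
#' linkage_map(chr, loci)
#' @export
linkage_map <- function(chromosomes, loci) {
  stop_if_not(is.data.frame(chromosomes) &&
                all(c("chrom", "length_cM") %in% names(chromosomes)),
              "'chromosomes' needs columns chrom, length_cM")
  stop_if_not(is.data.frame(loci) &&
                all(c("locus_id", "chrom", "pos_cM") %in% names(loci)),
              "'loci' needs columns locus_id, chrom, pos_cM")
  chromosomes$chrom <- as.character(chromosomes$chrom)
  stop_if_not(!anyDuplicated(chromosomes$chrom), "duplicated chromosome ids")
  stop_if_not(all(chromosomes$length_cM > 0), "chromosome lengths must be > 0")
  loci$locus_id <- as.character(loci$locus_id)
  loci$chrom <- as.character(loci$chrom)
  if (!"pos_bp" %in% names(loci)) loci$pos_bp <- NA_real_
  stop_if_not(!anyDuplicated(loci$locus_id), "locus ids must be unique")
  stop_if_not(all(loci$chrom %in% chromosomes$chrom),
              "loci reference unknown chromosomes")
  len <- chromosomes$length_cM[match(loci$chrom, chromosomes$chrom)]
  stop_if_not(all(loci$pos_cM >= 0 & loci$pos_cM <= len),
              "locus positions must lie in [0, chromosome length]")
  ord <- order(match(loci$chrom, chromosomes$chrom), loci$pos_cM, loci$pos_bp)
  loci <- loci[ord, , drop = FALSE]
  rownames(loci) <- NULL
  # bp increasing with cM where present (strictly where cM strictly does)
  for (ch in unique(loci$chrom)) {
    d <- loci[loci$chrom == ch & !is.na(loci$pos_bp), ]
    ok <- diff(d$pos_bp) > 0 | (diff(d$pos_cM) == 0 & diff(d$pos_bp) >= 0)
    stop_if_not(all(ok),
                "bp positions must strictly increase with cM on %s", ch)
  }
  structure(list(chromosomes = chromosomes, loci = loci),
            class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  cat(sprintf("<linkage_map> %d chromosomes (%.0f cM total), %d loci\n",
              nrow(x$chromosomes), sum(x$chromosomes$length_cM),
              nrow(x$loci)))
  invisible(x)
}

#' Minimal two-locus map for the hybrid-lethality system
#'
#' Fourteen 100-cM chromosomes (the *Mimulus* karyotype) carrying the two
#' causal loci: `hl13` near the distal end of chromosome 13 and `hl14`
#' mid-chromosome 14.  Physical positions use a constant 300 kb/cM scaling
#' (a genome of ~420 Mb over ~1400 cM).
#'
#' @param hl13_cM,hl14_cM genetic positions of the causal loci.
#' @param chrom_length_cM common chromosome length in cM.
#' @param bp_per_cM physical-per-genetic scaling used for bp coordinates.
#' @return A [linkage_map].
#' @export
mimulus_causal_map <- function(hl13_cM = 95, hl14_cM = 50,
                               chrom_length_cM = 100, bp_per_cM = 3e5) {
  chroms <- data.frame(chrom = sprintf("chr%02d", 1:14),
                       length_cM = chrom_length_cM)
  loci <- data.frame(locus_id = c("hl13", "hl14"),
                     chrom = c("chr13", "chr14"),
                     pos_cM = c(hl13_cM, hl14_cM),
                     pos_bp = round(c(hl13_cM, hl14_cM) * bp_per_cM))
  linkage_map(chroms, loci)
}

#' Add loci to an existing map
#'
#' @param map a [linkage_map].
#' @param loci data.frame of additional loci (same columns as in
#'   [linkage_map]).
#' @return A new [linkage_map] containing both sets of loci.
#' @export
add_loci <- function(map, loci) {
  stopifnot(inherits(map, "linkage_map"))
  if (!"pos_bp" %in% names(loci)) loci$pos_bp <- NA_real_
  linkage_map(map$chromosomes,
              rbind(map$loci[, c("locus_id", "chrom", "pos_cM", "pos_bp")],
                    loci[, c("locus_id", "chrom", "pos_cM", "pos_bp")]))
}

#' Simulate a parent-differentiating SNP panel
#'
#' Emulates a genome-wide panel of SNPs ascertained as fixed differences
#' between the reference-genome lineage and the *M. nasutus* parent (the alt
#' allele is the nasutus-lineage allele).  Because the mapping parent of the
#' reference lineage is not itself sequenced, a small fraction of panel sites
#' violate the shared-SNP assumption: at those, the guttatus mapping parent
#' also carries the alt allele, so the site is uninformative and reads alt in
#' every pool.  SNPs are placed uniformly at random, proportional to
#' chromosome length, at unique bp coordinates.
#'
#' @param n_snps total number of panel SNPs.
#' @param map a [linkage_map] giving chromosomes (defaults to
#'   [mimulus_causal_map()]).
#' @param shared_violation_rate fraction of SNPs where the guttatus parent
#'   carries the alt allele (default 0.02).
#' @param bp_per_cM physical-per-genetic scaling.
#' @param seed optional integer seed.
#' @return data.frame of class `snp_panel` with columns `locus_id`, `chrom`,
#'   `pos_cM`, `pos_bp`, `g_carries_alt`.
#' @export
simulate_snp_panel <- function(n_snps, map = mimulus_causal_map(),
                               shared_violation_rate = 0.02,
                               bp_per_cM = 3e5, seed = NULL) {
  stop_if_not(n_snps >= 1, "n_snps must be >= 1")
  stop_if_not(shared_violation_rate >= 0 && shared_violation_rate < 1,
              "shared_violation_rate must be in [0, 1)")
  restore <- seed_scope(seed); on.exit(restore(), add = TRUE)
  ch <- map$chromosomes
  # apportion SNPs by length, remainders to the longest chromosomes
  raw <- n_snps * ch$length_cM / sum(ch$length_cM)
  n_per <- floor(raw)
  extra <- n_snps - sum(n_per)
  if (extra > 0) {
    idx <- order(raw - n_per, decreasing = TRUE)[seq_len(extra)]
    n_per[idx] <- n_per[idx] + 1L
  }
  pieces <- lapply(seq_len(nrow(ch)), function(i) {
    k <- n_per[i]
    if (k == 0) return(NULL)
    max_bp <- round(ch$length_cM[i] * bp_per_cM)
    bp <- sort(sample.int(max_bp, k))
    cm <- bp / bp_per_cM
    data.frame(locus_id = sprintf("%s_s%06d", ch$chrom[i], seq_len(k)),
               chrom = ch$chrom[i], pos_cM = cm, pos_bp = bp)
  })
  panel <- do.call(rbind, pieces)
  rownames(panel) <- NULL
  panel$g_carries_alt <- stats::runif(nrow(panel)) < shared_violation_rate
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Build a simulation map carrying a SNP panel
#'
#' Combines the causal/marker loci of `map` with the panel SNPs so that every
#' panel site is an explicitly simulated locus (pool genotypes at panel SNPs
#' are then exact, not interpolated).
#'
#' @param panel an `snp_panel` (see [simulate_snp_panel]).
#' @param map the base [linkage_map] carrying causal loci.
#' @return A [linkage_map] with causal loci plus panel SNPs.
#' @export
map_with_panel <- function(panel, map = mimulus_causal_map()) {
  stopifnot(inherits(map, "linkage_map"))
  base <- map$loci
  keep <- !(panel$pos_bp %in% base$pos_bp & panel$chrom %in% base$chrom)
  add <- panel[keep, c("locus_id", "chrom", "pos_cM", "pos_bp")]
  linkage_map(map$chromosomes, rbind(base, add))
}
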