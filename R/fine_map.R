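# Recombinant fine-mapping: progeny tests, two-locus concordance, and
# minimal-interval narrowing from informative recombinants.

#' Classify an F3 progeny test
#'
#' A green F2 that is heterozygous at the target locus (with the partner
#' fixed incompatible) segregates white seedlings 3:1 among its selfed
#' progeny; a compatible homozygote segregates none.  Observing any white
#' seedling therefore proves heterozygosity; observing none is decisive for
#' homozygosity only when the family is large enough that an all-green
#' outcome would be improbable under 3:1, i.e. when the exact binomial tail
#' \eqn{0.75^n < \alpha}.  The smallest decisive family at `alpha = 0.05`
#' is n = 11 (`0.75^11` is about 0.042).
#'
#' @param n_green,n_white observed F3 counts.
#' @param alpha significance level (default 0.05).
#' @return `"segregating_het"`, `"homozygous_compatible"`, or `"ambiguous"`.
#' @examples
#' progeny_test(30, 10)  # segregating_het
#' progeny_test(40, 0)   # homozygous_compatible
#' progeny_test(8, 0)    # ambiguous
#' @export
progeny_test <- function(n_green, n_white, alpha = 0.05) {
  n <- n_green + n_white
  stop_if_not(n >= 1, "zero-size family")
  if (n_white > 0) return("segregating_het")
  if (0.75^n_green < alpha) "homozygous_compatible" else "ambiguous"
}

#' Two-locus genotype-phenotype concordance table
#'
#' Tabulates individuals by genotype code at the two locus-linked marker
#' sets and phenotype (the nine-class table), and reports the concordance of
#' the white class: the fraction of white individuals carrying the lethal
#' marker genotype (homozygous G at the first locus, homozygous N at the
#' second).  Markers sit outside the causal loci, so recombination between
#' marker and locus makes concordance fall below 1.
#'
#' @param genotypes data.frame with columns named by `loci` (codes
#'   `G`/`H`/`N`, NA allowed) and a `phenotype` column
#'   (`"green"`/`"white"`).
#' @param loci the two marker-set columns, ordered (G-requiring locus
#'   first).
#' @return list: `table` (genotype x genotype x phenotype counts),
#'   `white_concordance` (NA if no white individuals),
#'   `n_white`, `n_green`, `n_excluded` (rows missing either call),
#'   `green_lethal_class` (green individuals with the lethal genotype).
#' @export
concordance <- function(genotypes, loci = c("hl13", "hl14")) {
  stop_if_not(all(c(loci, "phenotype") %in% names(genotypes)),
              "missing genotype columns")
  g1 <- genotypes[[loci[1]]]; g2 <- genotypes[[loci[2]]]
  keep <- !is.na(g1) & !is.na(g2)
  n_excluded <- sum(!keep)
  g1 <- factor(g1[keep], levels = c("G", "H", "N"))
  g2 <- factor(g2[keep], levels = c("G", "H", "N"))
  ph <- genotypes$phenotype[keep]
  tab <- table(g1, g2, ph, dnn = c(loci[1], loci[2], "phenotype"))
  white <- ph == "white"
  conc <- if (any(white)) {
    mean(g1[white] == "G" & g2[white] == "N")
  } else NA_real_
  list(table = tab, white_concordance = conc,
       n_white = sum(white), n_green = sum(!white),
       n_excluded = n_excluded,
       green_lethal_class = sum(!white & g1 == "G" & g2 == "N"))
}

#' Infer the causal-locus genotype of a recombinant record
#'
#' White seedlings must be homozygous for the incompatible allele at the
#' target locus (and at the partner).  Green seedlings are informative only
#' through progeny testing, and only when the partner locus is fixed for its
#' incompatible allele (otherwise F3 segregation does not isolate the target
#' locus): a segregating family implies heterozygosity, a decisively
#' non-segregating family implies the compatible homozygote.
#'
#' @param record one-row data.frame or list with `phenotype`,
#'   `partner_genotype`, `f3_green`, `f3_white`.
#' @param incompatible_allele incompatible homozygous code at the target
#'   locus (`"G"` for hl13, `"N"` for hl14).
#' @param partner_incompatible incompatible homozygous code at the partner.
#' @param alpha progeny-test significance level.
#' @return Genotype code `"G"`, `"H"`, `"N"`, or NA (uninformative).
#' @export
infer_causal_genotype <- function(record, incompatible_allele = "G",
                                  partner_incompatible = "N",
                                  alpha = 0.05) {
  stop_if_not(record$phenotype %in% c("green", "white"),
              "phenotype must be green or white")
  compatible <- setdiff(c("G", "N"), incompatible_allele)
  if (record$phenotype == "white") return(incompatible_allele)
  if (is.null(record$partner_genotype) || is.na(record$partner_genotype) ||
      record$partner_genotype != partner_incompatible) {
    return(NA_character_)
  }
  if (is.na(record$f3_green) || is.na(record$f3_white)) return(NA_character_)
  switch(progeny_test(record$f3_green, record$f3_white, alpha),
         segregating_het = "H",
         homozygous_compatible = compatible,
         ambiguous = NA_character_)
}

#' Classify every record of a recombinant panel
#'
#' @param records data.frame as produced by [simulate_recombinant_records]
#'   (or read from TSV): `id`, `phenotype`, `partner_genotype`, `f3_green`,
#'   `f3_white`, plus marker columns.
#' @inheritParams infer_causal_genotype
#' @return The records with an added `inferred_genotype` column.
#' @export
classify_records <- function(records, incompatible_allele = "G",
                             partner_incompatible = "N", alpha = 0.05) {
  records$inferred_genotype <- vapply(seq_len(nrow(records)), function(i) {
    g <- infer_causal_genotype(records[i, ], incompatible_allele,
                               partner_incompatible, alpha)
    if (is.null(g)) NA_character_ else g
  }, character(1))
  records
}

#' A half-open genomic interval
#'
#' @param chrom chromosome id.
#' @param start_bp,end_bp 0-based half-open bounds (`start < end`).
#' @param flank_left,flank_right flanking marker ids (optional).
#' @param spans_gap flag for intervals spanning an assembly gap of unknown
#'   size (interval length is then a lower bound).
#' @return list of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start_bp, end_bp, flank_left = NA,
                             flank_right = NA, spans_gap = FALSE) {
  stop_if_not(start_bp < end_bp, "need start_bp < end_bp")
  structure(list(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
                 flank_left = flank_left, flank_right = flank_right,
                 spans_gap = spans_gap),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s:%s-%s (%s bp%s; flanks %s | %s)\n",
              x$chrom, format(x$start_bp, big.mark = ","),
              format(x$end_bp, big.mark = ","),
              format(x$end_bp - x$start_bp, big.mark = ","),
              if (isTRUE(x$spans_gap)) ", spans assembly gap" else "",
              x$flank_left, x$flank_right))
  invisible(x)
}

# gap index g in 0..k denotes the segment left of marker 1 (g = 0), between
# markers g and g+1, or right of marker k (g = k).  A record with inferred
# causal genotype `geno` is consistent with gap g if either flanking marker
# call equals `geno` or is missing (missing calls are wildcards; a candidate
# position between two markers is accepted if compatible with either flank,
# a conservative rule that can leave intervals slightly wide but never
# wrongly narrow).
consistent_gaps <- function(marker_calls, geno) {
  k <- length(marker_calls)
  ok <- is.na(marker_calls) | marker_calls == geno
  left <- c(TRUE, ok)    # gap g has left flank marker g (gap 0: none)
  right <- c(ok, TRUE)   # gap g has right flank marker g+1 (gap k: none)
  # gap 0 and gap k have only one flank: require that flank to be consistent
  cons <- left | right
  cons[1] <- ok[1]
  cons[k + 1] <- ok[k]
  which(cons) - 1L
}

#' Narrow a candidate interval from informative recombinants
#'
#' Returns the minimal marker-bounded interval such that placing the causal
#' locus anywhere inside it is consistent with every informative record:
#' equivalently, the span of the marker gaps in the intersection of each
#' record's consistent-gap set.  Records whose inferred causal genotype is NA
#' are uninformative and ignored; with no informative records the current
#' interval is returned unchanged.  An empty intersection signals genotyping
#' error or a wrong model and raises an error listing the conflicting
#' records.
#'
#' @param records classified records (see [classify_records]) with an
#'   `inferred_genotype` column and one column per marker.
#' @param markers data.frame `marker_id`, `pos_bp` ordered along the
#'   chromosome (optionally `chrom`).
#' @param current optional [genomic_interval] to intersect with (also
#'   supplies outer bounds when the consistent gaps touch the panel ends).
#' @return A [genomic_interval] with attributes `gaps` (consistent gap
#'   indices).
#' @export
narrow_interval <- function(records, markers, current = NULL) {
  stop_if_not(nrow(markers) >= 2, "need >= 2 markers")
  stop_if_not(!is.unsorted(markers$pos_bp, strictly = TRUE),
              "markers must be ordered by position")
  stop_if_not(all(markers$marker_id %in% names(records)),
              "records lack some marker columns")
  stop_if_not("inferred_genotype" %in% names(records),
              "records must carry inferred_genotype (see classify_records)")
  chrom <- markers$chrom[1] %||% if (!is.null(current)) current$chrom else NA
  k <- nrow(markers)
  info <- which(!is.na(records$inferred_genotype))
  all_gaps <- 0:k
  if (!length(info)) {
    if (!is.null(current)) return(current)
    return(structure(genomic_interval(chrom, markers$pos_bp[1],
                                      markers$pos_bp[k],
                                      markers$marker_id[1],
                                      markers$marker_id[k]),
                     gaps = all_gaps))
  }
  per_record <- lapply(info, function(i) {
    calls <- as.character(unlist(records[i, markers$marker_id]))
    consistent_gaps(calls, records$inferred_genotype[i])
  })
  gaps <- Reduce(intersect, per_record, accumulate = FALSE)
  if (!length(gaps)) {
    detail <- vapply(seq_along(info), function(j)
      sprintf("%s:{%s}", records$id[info[j]] %||% info[j],
              paste(per_record[[j]], collapse = ",")), character(1))
    stop("narrow_interval: no causal position is consistent with all ",
         "informative records (genotyping error or wrong model?). ",
         "Per-record consistent gaps: ", paste(detail, collapse = "; "),
         call. = FALSE)
  }
  lo <- min(gaps); hi <- max(gaps)
  start_bp <- if (lo == 0) {
    if (!is.null(current)) current$start_bp else markers$pos_bp[1] - 1
  } else markers$pos_bp[lo]
  end_bp <- if (hi == k) {
    if (!is.null(current)) current$end_bp else markers$pos_bp[k] + 1
  } else markers$pos_bp[hi + 1]
  iv <- genomic_interval(chrom, start_bp, end_bp,
                         flank_left = if (lo == 0) NA else markers$marker_id[lo],
                         flank_right = if (hi == k) NA else markers$marker_id[hi + 1],
                         spans_gap = isTRUE(current$spans_gap))
  attr(iv, "gaps") <- gaps
  iv
}
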