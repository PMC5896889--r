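# Shared fixtures, all built in code.

# single-chromosome map with named markers at given cM positions
one_chrom_map <- function(pos_cM, ids = sprintf("m%d", seq_along(pos_cM)),
                          length_cM = 100) {
  linkage_map(data.frame(chrom = "c1", length_cM = length_cM),
              data.frame(locus_id = ids, chrom = "c1", pos_cM = pos_cM,
                         pos_bp = round(pos_cM * 1e5)))
}

# map of n unlinked loci (one per chromosome)
unlinked_map <- function(n) {
  linkage_map(data.frame(chrom = sprintf("u%04d", seq_len(n)), length_cM = 50),
              data.frame(locus_id = sprintf("L%04d", seq_len(n)),
                         chrom = sprintf("u%04d", seq_len(n)), pos_cM = 25))
}

# diagnostic-SNP panel in the shape of the real one: 10 positions, three
# haplotypes (two guttatus copies, one nasutus), each with a private allele
# so that no haplotype is contained in the union of the other two
toy_hap_panel <- function() {
  states <- rbind(
    G1 = c("A", "A", "A", "A", "A", "A", "A", "A", "A", "G"),
    G2 = c("C", "C", "C", "A", "A", "A", "A", "C", "A", "C"),
    N1 = c("A", "A", "A", "C", "C", "C", "C", "C", "C", "A"))
  colnames(states) <- sprintf("p%02d", 1:10)
  haplotype_panel(states)
}

# observation = superposition of the given haplotypes' states
superpose <- function(panel, haps, positions = colnames(panel$states)) {
  obs <- lapply(positions, function(p) unique(panel$states[haps, p]))
  names(obs) <- positions
  obs
}

NON_STOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

# random open reading frame: ATG + random non-stop codons + TAA
random_cds <- function(n_codons = 300) {
  paste0("ATG",
         paste(sample(NON_STOP_CODONS, n_codons - 2, replace = TRUE),
               collapse = ""),
         "TAA")
}

# independent Pearson chi-squared oracle (two cells, hand formula)
pearson_gof <- function(n_white, n_green, p_white) {
  n <- n_white + n_green
  exp_w <- n * p_white
  exp_g <- n * (1 - p_white)
  (n_white - exp_w)^2 / exp_w + (n_green - exp_g)^2 / exp_g
}

# cross counts reconstructed from the printed population sizes and white
# percentages of the reciprocal F2s (rounded to whole seedlings)
reconstructed_f2_counts <- function() {
  w1 <- round(0.0736 * 516)   # 38
  w2 <- round(0.0575 * 661)   # 38
  data.frame(cross_class = c("F2", "F2"),
             maternal = c("G", "N"),
             n_green = c(516 - w1, 661 - w2),
             n_white = c(w1, w2))
}

# brute-force oracle for interval narrowing: try every marker gap against
# every informative record with plain loops
bf_consistent_gaps <- function(records, markers) {
  k <- nrow(markers)
  ok_gaps <- integer(0)
  for (g in 0:k) {
    all_ok <- TRUE
    for (i in seq_len(nrow(records))) {
      geno <- records$inferred_genotype[i]
      if (is.na(geno)) next
      calls <- as.character(unlist(records[i, markers$marker_id]))
      ok_at <- function(j) is.na(calls[j]) || calls[j] == geno
      ok <- if (g == 0) ok_at(1)
            else if (g == k) ok_at(k)
            else ok_at(g) || ok_at(g + 1)
      if (!ok) { all_ok <- FALSE; break }
    }
    if (all_ok) ok_gaps <- c(ok_gaps, g)
  }
  ok_gaps
}

# random small fine-mapping instance for oracle-equivalence checks
random_narrow_instance <- function(n_markers, n_records) {
  markers <- data.frame(marker_id = sprintf("m%02d", seq_len(n_markers)),
                        chrom = "c1",
                        pos_bp = sort(sample.int(1e6, n_markers)))
  calls <- matrix(sample(c("G", "H", "N", NA), n_markers * n_records,
                         replace = TRUE, prob = c(0.3, 0.3, 0.3, 0.1)),
                  n_records, dimnames = list(NULL, markers$marker_id))
  records <- data.frame(id = sprintf("r%02d", seq_len(n_records)),
                        inferred_genotype = sample(c("G", "H", "N", NA),
                                                   n_records, replace = TRUE,
                                                   prob = c(0.3, 0.3, 0.3, 0.1)))
  list(records = cbind(records, as.data.frame(calls)), markers = markers)
}
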