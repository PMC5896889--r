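# Placing duplicate gene copies onto loci by haplotype association, and
# assessing copy functionality from CDS sequence and transcript evidence.

#' Define a diagnostic-SNP haplotype panel
#'
#' A small set of SNP positions within the gene whose joint allele states
#' distinguish the gene copies (haplotypes), e.g. the two guttatus copies G1
#' and G2 and the single nasutus copy N1.
#'
#' @param states character matrix: rows = haplotypes (named), columns =
#'   diagnostic positions (named), entries = single nucleotide states.
#' @return Object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(states) {
  stop_if_not(is.matrix(states) && !is.null(rownames(states)) &&
                !is.null(colnames(states)), "states must be a named matrix")
  stop_if_not(nrow(states) >= 2, "need >= 2 haplotypes")
  stop_if_not(!anyDuplicated(apply(states, 1, paste, collapse = "")),
              "haplotype state vectors must be pairwise distinct")
  informative <- vapply(seq_len(ncol(states)), function(j)
    length(unique(states[, j])) > 1, logical(1))
  stop_if_not(all(informative),
              "every position must be informative for >= 1 haplotype pair")
  structure(list(states = states), class = "haplotype_panel")
}

#' Call haplotypes present in a superposed observation
#'
#' Genomic PCR amplifies every copy an individual carries, so the observation
#' at each diagnostic position is a *set* of allele states.  A panel
#' haplotype is called present when its full state vector is contained in
#' the observed superposition at every observed position.  When diagnostic
#' positions are missing from the observation, haplotypes that are
#' distinguished from another called haplotype only at missing positions are
#' reported as ambiguous.
#'
#' @param observed named list: position id -> character vector of observed
#'   states.  Positions absent from the list are treated as unobserved.
#' @param panel a [haplotype_panel].
#' @return list: `called` (haplotype names), `ambiguous` (subset of called
#'   haplotypes not distinguishable on the observed positions).
#' @export
call_haplotypes <- function(observed, panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  states <- panel$states
  obs_pos <- names(observed)
  stop_if_not(all(obs_pos %in% colnames(states)),
              "observation at non-panel position: %s",
              paste(setdiff(obs_pos, colnames(states)), collapse = ", "))
  contained <- vapply(rownames(states), function(h) {
    all(vapply(obs_pos, function(p) states[h, p] %in% observed[[p]],
               logical(1)))
  }, logical(1))
  called <- rownames(states)[contained]
  ambiguous <- character(0)
  if (length(obs_pos) < ncol(states) && length(called) > 0) {
    sig <- apply(states[called, obs_pos, drop = FALSE], 1, paste,
                 collapse = "")
    ambiguous <- called[sig %in% sig[duplicated(sig)]]
  }
  list(called = called, ambiguous = ambiguous)
}

#' Place gene copies onto loci by presence/genotype association
#'
#' For each haplotype (gene copy) and each candidate (locus, parental
#' allele), counts the individuals whose copy presence contradicts the
#' candidate: a copy residing at locus L on the allele-a haplotype must be
#' detected exactly in individuals whose genotype at L contains a (presence
#' is dominant: the copy is amplified from either homolog).  A haplotype is
#' placed when a single candidate has zero mismatches; otherwise its best
#' candidates are reported with mismatch counts and it is left unplaced.
#'
#' @param presence logical matrix: individuals x haplotypes.
#' @param genotypes data.frame of genotype codes (`G`/`H`/`N`) with one
#'   column per locus.
#' @param loci locus ids (columns of `genotypes`) considered as candidate
#'   locations.
#' @param alleles parental alleles considered (default `c("G", "N")`).
#' @return list: `placement` (data.frame haplotype, locus, allele,
#'   mismatches, status `placed`/`unplaced`), `candidates` (all candidate
#'   scores).
#' @export
infer_placement <- function(presence, genotypes, loci = c("hl13", "hl14"),
                            alleles = c("G", "N")) {
  stop_if_not(is.matrix(presence) && is.logical(presence) &&
                !is.null(colnames(presence)), "presence must be a named logical matrix")
  stop_if_not(all(loci %in% names(genotypes)), "missing genotype columns")
  classes <- unique(do.call(paste, genotypes[loci]))
  stop_if_not(length(classes) >= 2,
              "fewer than 2 two-locus genotype classes: unidentifiable")
  cand <- expand.grid(locus = loci, allele = alleles,
                      stringsAsFactors = FALSE)
  scores <- lapply(colnames(presence), function(h) {
    mism <- vapply(seq_len(nrow(cand)), function(i) {
      predicted <- genotypes[[cand$locus[i]]] %in% c(cand$allele[i], "H")
      sum(presence[, h] != predicted)
    }, numeric(1))
    data.frame(haplotype = h, cand, mismatches = mism)
  })
  scores <- do.call(rbind, scores)
  placement <- lapply(split(scores, scores$haplotype), function(d) {
    best <- d[d$mismatches == min(d$mismatches), ]
    placed <- min(d$mismatches) == 0 && nrow(best) == 1
    data.frame(haplotype = d$haplotype[1],
               locus = if (placed) best$locus else NA_character_,
               allele = if (placed) best$allele else NA_character_,
               mismatches = min(d$mismatches),
               status = if (placed) "placed" else "unplaced")
  })
  placement <- do.call(rbind, placement)
  rownames(placement) <- NULL
  list(placement = placement, candidates = scores)
}

#' Simulate the nine-genotype-class copy-mapping panel
#'
#' Builds the F2 validation panel of the mapping design: `n_green_rep`
#' replicates of each of the eight viable two-locus genotype classes plus
#' `n_white` replicates of the white (G at hl13, N at hl14) class -- 96
#' individuals at the study's 10/16 values -- and derives each individual's
#' copy-presence vector from a planted placement map, optionally corrupting
#' entries at rate `flip_rate`.
#'
#' @param placements data.frame `haplotype`, `locus`, `allele` giving the
#'   planted truth (default: the divergent-resolution arrangement G1 and N1
#'   at hl13, G2 at hl14).
#' @param n_green_rep replicates per green genotype class (default 10).
#' @param n_white replicates of the white class (default 16).
#' @param flip_rate per-entry corruption probability (default 0).
#' @param seed optional integer seed.
#' @return list: `genotypes` (data.frame hl13, hl14, phenotype), `presence`
#'   (logical matrix), `truth` (the placements).
#' @export
simulate_copy_panel <- function(placements = data.frame(
                                  haplotype = c("G1", "G2", "N1"),
                                  locus = c("hl13", "hl14", "hl13"),
                                  allele = c("G", "G", "N")),
                                n_green_rep = 10, n_white = 16,
                                flip_rate = 0, seed = NULL) {
  restore <- seed_scope(seed); on.exit(restore(), add = TRUE)
  classes <- expand.grid(hl13 = c("G", "H", "N"), hl14 = c("G", "H", "N"),
                         stringsAsFactors = FALSE)
  white <- classes$hl13 == "G" & classes$hl14 == "N"
  reps <- ifelse(white, n_white, n_green_rep)
  genotypes <- classes[rep(seq_len(nrow(classes)), reps), ]
  genotypes$phenotype <- ifelse(genotypes$hl13 == "G" & genotypes$hl14 == "N",
                                "white", "green")
  rownames(genotypes) <- NULL
  presence <- vapply(seq_len(nrow(placements)), function(i) {
    genotypes[[placements$locus[i]]] %in% c(placements$allele[i], "H")
  }, logical(nrow(genotypes)))
  colnames(presence) <- placements$haplotype
  if (flip_rate > 0) {
    flip <- matrix(stats::runif(length(presence)) < flip_rate,
                   nrow(presence))
    presence <- xor(presence, flip)
  }
  list(genotypes = genotypes, presence = presence, truth = placements)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

codons_of <- function(seq) {
  n <- floor(nchar(seq) / 3)
  substring(seq, 3 * (seq_len(n) - 1) + 1, 3 * seq_len(n))
}

#' Detect frameshifts and premature stop codons in a CDS
#'
#' Globally aligns a query CDS to an intact reference CDS (affine gap
#' penalties), computes the net indel offset, and flags a frameshift when
#' the offset is not a multiple of 3.  The query is then translated in the
#' reference reading frame from the aligned start, and every stop codon
#' falling before the reference's terminal stop is reported as premature --
#' the signature of a small insertion (e.g. a single adenine) that truncates
#' the protein.
#'
#' @param query,ref nucleotide CDS strings (A/C/G/T).  The reference must
#'   translate open: length a multiple of 3 with no internal stop codon.
#' @param match,mismatch,gap_opening,gap_extension alignment parameters
#'   (defaults 1, -1, 10, 0.5).
#' @return list: `frameshift` (logical), `net_offset` (net inserted minus
#'   deleted bases, mod 3 in `offset_mod3`), `premature_stops` (query codon
#'   indices), `n_premature`, `truncated_protein_length` (codons before the
#'   first stop, or full length), `score`.
#' @examples
#' ref <- "ATGGCTGCTGCAGCTGCAGCATAA"
#' detect_frameshift(ref, ref)$frameshift  # FALSE
#' @export
detect_frameshift <- function(query, ref, match = 1, mismatch = -1,
                              gap_opening = 10, gap_extension = 0.5) {
  query <- toupper(query); ref <- toupper(ref)
  stop_if_not(grepl("^[ACGT]+$", query) && grepl("^[ACGT]+$", ref),
              "sequences must contain only A/C/G/T")
  stop_if_not(nchar(ref) %% 3 == 0, "reference length must be a multiple of 3")
  ref_codons <- codons_of(ref)
  internal <- ref_codons[-length(ref_codons)]
  stop_if_not(!any(internal %in% STOP_CODONS),
              "reference must translate open (no internal stop codons)")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = sm,
    gapOpening = gap_opening, gapExtension = gap_extension)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  n_ins <- sum(sub == "-")   # bases present in query only
  n_del <- sum(pat == "-")   # bases present in reference only
  net <- n_ins - n_del
  frameshift <- (net %% 3) != 0
  # map query positions to reference coordinates (last ref base at or before)
  ref_coord <- cumsum(sub != "-")
  q_to_ref <- ref_coord[pat != "-"]
  # translate query in frame from its start; find stop codons
  q_codons <- codons_of(query)
  stops <- which(q_codons %in% STOP_CODONS)
  ref_stop_start <- if (ref_codons[length(ref_codons)] %in% STOP_CODONS) {
    nchar(ref) - 2L
  } else Inf
  premature <- stops[q_to_ref[3 * (stops - 1) + 1] < ref_stop_start]
  list(frameshift = frameshift, net_offset = net,
       offset_mod3 = net %% 3,
       premature_stops = premature, n_premature = length(premature),
       truncated_protein_length = if (length(stops)) min(stops) - 1L
                                  else length(q_codons),
       score = Biostrings::score(aln))
}

#' Call expressed copies from transcript variant evidence
#'
#' RNA-derived reads only sample expressed copies, so the haplotypes called
#' from transcript allele states at the diagnostic positions identify which
#' copies a sample expresses.  Positions with coverage below `min_coverage`
#' are masked; a sample with every position masked (e.g. the near-zero
#' transcript coverage of lethal seedlings) is classified `not_expressed`.
#'
#' @param observed named list: position id -> character vector of transcript
#'   allele states.
#' @param coverage named numeric: read coverage per diagnostic position.
#' @param panel a [haplotype_panel].
#' @param min_coverage minimum reads per position (default 5).
#' @return list: `status` (`"expressed"` / `"not_expressed"`), `called`,
#'   `ambiguous`, `masked_positions`.
#' @export
expressed_copies <- function(observed, coverage, panel, min_coverage = 5) {
  stopifnot(inherits(panel, "haplotype_panel"))
  pos <- names(observed)
  stop_if_not(all(pos %in% names(coverage)),
              "coverage missing for some observed positions")
  keep <- pos[coverage[pos] >= min_coverage]
  masked <- setdiff(pos, keep)
  if (!length(keep)) {
    return(list(status = "not_expressed", called = character(0),
                ambiguous = character(0), masked_positions = masked))
  }
  calls <- call_haplotypes(observed[keep], panel)
  list(status = "expressed", called = calls$called,
       ambiguous = calls$ambiguous, masked_positions = masked)
}
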