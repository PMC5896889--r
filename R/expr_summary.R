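# Post-differential-expression summarisation: triple-comparison
# intersection, row Z-scores, and polymerase-class misexpression reports.
# DE testing itself is consumed from upstream tools, not recomputed.

#' Intersect three pairwise differential-expression comparisons
#'
#' A gene is retained iff it is flagged significant in all three pairwise
#' comparisons of the focal class against each green class; its effect is
#' summarised as the unweighted mean log2 fold-change across the three and
#' its direction as the sign of that mean.  Direction consistency is not
#' required for membership, but sign-discordant genes are flagged.
#'
#' @param comparisons list of exactly three data.frames, each with columns
#'   `gene`, `log2fc`, `significant` (logical), over the same gene universe.
#' @return data.frame: `gene`, `mean_log2fc`, `direction` (`"up"`/`"down"`),
#'   `sign_discordant`.
#' @export
intersect_significant <- function(comparisons) {
  stop_if_not(is.list(comparisons) && length(comparisons) == 3,
              "need exactly three comparisons")
  for (d in comparisons) {
    stop_if_not(all(c("gene", "log2fc", "significant") %in% names(d)),
                "comparison tables need gene, log2fc, significant")
  }
  comparisons <- lapply(comparisons, function(d) d[order(d$gene), ])
  genes <- comparisons[[1]]$gene
  for (d in comparisons[-1]) {
    stop_if_not(identical(d$gene, genes),
                "comparisons must share one gene universe")
  }
  sig <- Reduce(`&`, lapply(comparisons, `[[`, "significant"))
  fc <- do.call(cbind, lapply(comparisons, `[[`, "log2fc"))
  keep <- which(sig)
  out <- data.frame(gene = genes[keep],
                    mean_log2fc = rowMeans(fc)[keep],
                    stringsAsFactors = FALSE)
  out$direction <- ifelse(out$mean_log2fc >= 0, "up", "down")
  sgn <- sign(fc[keep, , drop = FALSE])
  out$sign_discordant <- apply(sgn, 1, function(s) length(unique(s[s != 0])) > 1)
  rownames(out) <- NULL
  out
}

#' Row Z-scores of an expression matrix
#'
#' Standardises each gene (row) to mean 0 and population (divisor n)
#' standard deviation 1, the scaling used for relative-expression heatmaps.
#' Constant rows map to all zeros.
#'
#' @param mat numeric matrix, genes x samples, non-negative abundances
#'   (FPKM scale); at least 2 samples.
#' @param divisor `"n"` (population form, default) or `"n-1"` (sample form).
#' @return Matrix of the same shape.
#' @export
row_zscore <- function(mat, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  stop_if_not(is.matrix(mat) && ncol(mat) >= 2,
              "need a matrix with >= 2 samples")
  stop_if_not(all(mat >= 0), "abundances must be non-negative")
  m <- rowMeans(mat)
  dev <- mat - m
  denom <- if (divisor == "n") ncol(mat) else ncol(mat) - 1
  s <- sqrt(rowSums(dev^2) / denom)
  z <- dev / s
  z[s == 0, ] <- 0
  z
}

#' Per-polymerase-class misexpression report
#'
#' Splits a misexpressed gene set by transcribing-polymerase class (PEP,
#' PEP_and_NEP, NEP) and direction, reporting counts and gene lists per
#' cell; genes absent from the class map are listed as unmapped.  The
#' expected signature of a disabled plastid-encoded polymerase is
#' PEP-transcribed photosynthesis genes down and NEP-transcribed `rpo`
#' homologs up.
#'
#' @param gene_set data.frame from [intersect_significant] (`gene`,
#'   `direction`).
#' @param class_map data.frame `gene`, `class` with class in
#'   `PEP`, `PEP_and_NEP`, `NEP`.
#' @return list: `counts` (class x direction matrix), `genes` (nested list
#'   class -> direction -> gene ids), `unmapped` (gene ids).
#' @export
class_misexpression_report <- function(gene_set, class_map) {
  stop_if_not(all(c("gene", "class") %in% names(class_map)),
              "class_map needs gene, class")
  lv <- c("PEP", "PEP_and_NEP", "NEP")
  stop_if_not(all(class_map$class %in% lv), "unknown polymerase class")
  cls <- class_map$class[match(gene_set$gene, class_map$gene)]
  unmapped <- gene_set$gene[is.na(cls)]
  mapped <- !is.na(cls)
  counts <- table(factor(cls[mapped], levels = lv),
                  factor(gene_set$direction[mapped],
                         levels = c("up", "down")))
  genes <- lapply(lv, function(cl) {
    lapply(c("up", "down"), function(dir)
      gene_set$gene[mapped & cls == cl & gene_set$direction == dir])
  })
  genes <- stats::setNames(lapply(genes, stats::setNames,
                                  c("up", "down")), lv)
  list(counts = unclass(counts), genes = genes, unmapped = unmapped)
}

#' Simulate differential-expression tables and an FPKM matrix
#'
#' Synthetic stand-in for an upstream DE pipeline so the summarisation stage
#' is testable without RNA-seq: a planted fraction of genes is truly
#' misexpressed (flagged in all three white-vs-green comparisons, with a
#' consistent sign and log2 fold-change centred on `effect_size`), and null
#' genes are flagged independently in each comparison at `fp_rate`.  The
#' FPKM matrix carries the planted effects in the white-class samples with
#' the study's replicate structure (3 + 3 + 5 green, 6 white).
#'
#' @param n_genes number of genes (study-scale default 27948).
#' @param fraction_misexpressed planted misexpressed fraction (default 0.03).
#' @param effect_size mean |log2 fold-change| of planted genes (default 2).
#' @param fp_rate per-comparison false-positive flag rate for nulls
#'   (default 0.01).
#' @param noise_sd sd of per-comparison log2fc noise (default 0.25).
#' @param seed optional integer seed.
#' @return list: `comparisons` (three DE tables), `fpkm` (matrix with sample
#'   classes in `colnames`), `planted` (data.frame gene, sign).
#' @export
simulate_de_tables <- function(n_genes = 27948, fraction_misexpressed = 0.03,
                               effect_size = 2, fp_rate = 0.01,
                               noise_sd = 0.25, seed = NULL) {
  restore <- seed_scope(seed); on.exit(restore(), add = TRUE)
  genes <- sprintf("gene%06d", seq_len(n_genes))
  n_plant <- round(fraction_misexpressed * n_genes)
  planted_idx <- sort(sample.int(n_genes, n_plant))
  sgn <- integer(n_genes)
  sgn[planted_idx] <- sample(c(-1L, 1L), n_plant, replace = TRUE)
  comparisons <- lapply(1:3, function(k) {
    fc <- stats::rnorm(n_genes, mean = sgn * effect_size, sd = noise_sd)
    sig <- sgn != 0 | stats::runif(n_genes) < fp_rate
    data.frame(gene = genes, log2fc = fc, significant = sig,
               comparison = sprintf("white_vs_green%d", k),
               stringsAsFactors = FALSE)
  })
  classes <- c(rep("DPR102-gutt", 3), rep("DPR104-nas", 3),
               rep("green_F2", 5), rep("white_F2", 6))
  base <- stats::rlnorm(n_genes, meanlog = 2, sdlog = 1)
  fpkm <- vapply(seq_along(classes), function(j) {
    mu <- base
    if (classes[j] == "white_F2") mu <- mu * 2^(sgn * effect_size)
    mu * stats::rlnorm(n_genes, 0, 0.2)
  }, numeric(n_genes))
  rownames(fpkm) <- genes
  colnames(fpkm) <- sprintf("%s_r%d", classes, stats::ave(
    seq_along(classes), classes, FUN = seq_along))
  attr(fpkm, "class_labels") <- classes
  list(comparisons = comparisons, fpkm = fpkm,
       planted = data.frame(gene = genes[planted_idx],
                            sign = sgn[planted_idx]))
}
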