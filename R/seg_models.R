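# Segregation-model catalog and the chi-squared screen.

#' The default catalog of competing genetic models
#'
#' @return Named list of [incompatibility_spec] objects covering the four
#'   model families screened against the cross counts.  The catalog is
#'   extensible: pass your own named list of specs to [screen_models].
#' @export
model_catalog <- function() {
  list(
    two_locus_recessive_recessive =
      incompatibility_spec("two_locus_recessive_recessive"),
    one_locus_recessive = incompatibility_spec("one_locus_recessive"),
    two_locus_dominant_recessive =
      incompatibility_spec("two_locus_dominant_recessive"),
    cyto_nuclear_recessive = incompatibility_spec("cyto_nuclear_recessive"))
}

# Exact per-locus offspring genotype distributions (probabilities over codes
# G/H/N) for each cross class; all probabilities are dyadic rationals, so
# the enumeration below is exact in double precision.
locus_distribution <- function(cross_class, parent_code = NULL) {
  switch(cross_class,
    parental_self = NULL,  # handled by caller (parent is homozygous)
    F1 = c(G = 0, H = 1, N = 0),
    F2 = c(G = 0.25, H = 0.5, N = 0.25),
    F3 = switch(parent_code,
                G = c(G = 1, H = 0, N = 0),
                H = c(G = 0.25, H = 0.5, N = 0.25),
                N = c(G = 0, H = 0, N = 1)),
    stop("unknown cross class: ", cross_class, call. = FALSE))
}

#' Expected white fraction under a genetic model
#'
#' Exact Mendelian expectation (unlinked causal loci) obtained by enumerating
#' per-locus offspring genotype distributions and applying the model's
#' lethality predicate.  Under the two-locus recessive-recessive model the F2
#' expectation is 1/16 (the double-homozygote class), and F1s and parental
#' selfs never produce white seedlings.
#'
#' @param spec an [incompatibility_spec].
#' @param cross_class one of `"parental_self"`, `"F1"`, `"F2"`, `"F3"`.
#' @param maternal maternal-line label `"G"` or `"N"` (sets the cytoplasm;
#'   for `parental_self` it also identifies the selfed line).
#' @param parent_codes for `cross_class = "F3"`: named character vector of
#'   the F2 parent's genotype codes (`G`/`H`/`N`) at the model's causal loci.
#' @return Expected white fraction (exact dyadic rational).
#' @examples
#' expected_white_fraction(incompatibility_spec(), "F2")        # 1/16
#' expected_white_fraction(incompatibility_spec(), "F3",
#'   parent_codes = c(hl13 = "H", hl14 = "N"))                  # 1/4
#' @export
expected_white_fraction <- function(spec,
                                    cross_class = c("F2", "F1",
                                                    "parental_self", "F3"),
                                    maternal = "G", parent_codes = NULL) {
  stopifnot(inherits(spec, "incompatibility_spec"))
  cross_class <- match.arg(cross_class)
  stop_if_not(maternal %in% c("G", "N"), "maternal must be 'G' or 'N'")
  loci <- causal_loci(spec)
  if (cross_class == "parental_self") {
    codes <- matrix(maternal, 1, length(loci), dimnames = list(NULL, loci))
    return(as.numeric(is_lethal_genotype(codes, maternal, spec)))
  }
  dists <- lapply(loci, function(l) {
    pc <- if (cross_class == "F3") {
      stop_if_not(!is.null(parent_codes) && l %in% names(parent_codes),
                  "F3 requires parent_codes at locus '%s'", l)
      parent_codes[[l]]
    } else NULL
    locus_distribution(cross_class, pc)
  })
  grid <- expand.grid(lapply(dists, names), stringsAsFactors = FALSE)
  names(grid) <- loci
  prob <- Reduce(`*`, lapply(seq_along(loci), function(i) dists[[i]][grid[[i]]]))
  codes <- as.matrix(grid)
  sum(prob[is_lethal_genotype(codes, maternal, spec)])
}

#' Chi-squared goodness of fit of observed seedling counts
#'
#' Pearson chi-squared test of the observed white/green split against an
#' expected white fraction, with 1 degree of freedom and no continuity
#' correction.  For boundary expectations (0 or 1) the exact rule applies:
#' any discordant observation rejects the model (p = 0), otherwise the data
#' are perfectly consistent (p = 1).
#'
#' @param n_green,n_white observed counts.
#' @param p_white expected white fraction in `[0, 1]`.
#' @return list: `statistic`, `df`, `p_value`, `expected_white`.
#' @export
chisq_gof <- function(n_green, n_white, p_white) {
  n <- n_green + n_white
  stop_if_not(n >= 1, "zero total count")
  stop_if_not(p_white >= 0 && p_white <= 1, "p_white must be in [0, 1]")
  if (p_white == 0 || p_white == 1) {
    discordant <- if (p_white == 0) n_white > 0 else n_green > 0
    return(list(statistic = NA_real_, df = NA_integer_,
                p_value = as.numeric(!discordant),
                expected_white = n * p_white))
  }
  ht <- suppressWarnings(
    stats::chisq.test(c(n_white, n_green), p = c(p_white, 1 - p_white)))
  list(statistic = unname(ht$statistic), df = 1L,
       p_value = unname(ht$p.value), expected_white = n * p_white)
}

#' Test homogeneity of reciprocal F2 white fractions
#'
#' 2x2 Pearson chi-squared test (no continuity correction) of equal white
#' fractions in the two reciprocal F2 populations.  If homogeneity is not
#' rejected the counts are pooled; otherwise a possible cyto-nuclear
#' asymmetry is flagged (reciprocal directions differ only in cytoplasm).
#'
#' @param counts_dir1,counts_dir2 lists or 1-row data.frames with `n_green`,
#'   `n_white` for the two cross directions.
#' @param alpha significance level (default 0.05).
#' @return list: `statistic`, `p_value`, `homogeneous`, `pooled` (list with
#'   `n_green`, `n_white`, or NULL), `cyto_nuclear_flag`.
#' @export
reciprocal_homogeneity <- function(counts_dir1, counts_dir2, alpha = 0.05) {
  w <- c(counts_dir1$n_white, counts_dir2$n_white)
  g <- c(counts_dir1$n_green, counts_dir2$n_green)
  stop_if_not(all(w + g >= 1), "zero total count in a direction")
  tab <- rbind(w, g)
  if (identical(w[1] * g[2], w[2] * g[1])) {
    st <- 0; p <- 1  # identical fractions: avoid chisq.test zero-margin edge
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    st <- unname(ht$statistic); p <- unname(ht$p.value)
  }
  hom <- p >= alpha
  list(statistic = st, p_value = p, homogeneous = hom,
       pooled = if (hom) list(n_green = sum(g), n_white = sum(w)) else NULL,
       cyto_nuclear_flag = !hom)
}

#' Screen a table of cross counts against the model catalog
#'
#' For every model, tests each cross class with [chisq_gof] (or the exact
#' boundary rule) at its model-specific expectation; a model is rejected if
#' any cross class rejects it at `alpha`.
#'
#' @param counts data.frame with columns `cross_class` (`parental_self`,
#'   `F1`, `F2`), `maternal` (`"G"`/`"N"`), `n_green`, `n_white`.
#' @param catalog named list of [incompatibility_spec]s (default
#'   [model_catalog()]).
#' @param alpha significance level (default 0.05).
#' @return data.frame of verdicts: one row per model with the minimum
#'   p-value, the rejecting cross class (if any), and
#'   `verdict` (`"rejected"` / `"not_rejected"`).
#' @export
screen_models <- function(counts, catalog = model_catalog(), alpha = 0.05) {
  stop_if_not(is.data.frame(counts) && nrow(counts) > 0, "empty count table")
  stop_if_not(all(c("cross_class", "maternal", "n_green", "n_white") %in%
                    names(counts)), "missing count-table columns")
  stop_if_not(any(counts$cross_class == "F2"),
              "at least one F2 count is required")
  stop_if_not(all(counts$n_green >= 0 & counts$n_white >= 0 &
                    counts$n_green + counts$n_white >= 1),
              "invalid counts")
  rows <- lapply(names(catalog), function(mname) {
    spec <- catalog[[mname]]
    res <- lapply(seq_len(nrow(counts)), function(i) {
      p0 <- expected_white_fraction(spec, counts$cross_class[i],
                                    maternal = counts$maternal[i])
      gof <- chisq_gof(counts$n_green[i], counts$n_white[i], p0)
      data.frame(cross_class = counts$cross_class[i],
                 maternal = counts$maternal[i],
                 expected_white = p0, statistic = gof$statistic,
                 p_value = gof$p_value)
    })
    res <- do.call(rbind, res)
    rej <- res$p_value < alpha
    data.frame(model = mname,
               n_classes_tested = nrow(res),
               min_p = min(res$p_value),
               rejected_by = if (any(rej))
                 paste(res$cross_class[rej], res$maternal[rej],
                       sep = ":", collapse = ",") else NA_character_,
               verdict = if (any(rej)) "rejected" else "not_rejected")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}
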