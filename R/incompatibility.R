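#' Specify a hybrid-incompatibility genetic model
#'
#' Defines the deterministic lethality predicate for one member of the model
#' catalog.  The central model is the two-locus recessive-recessive
#' Dobzhansky-Muller incompatibility: a seedling is white (lethal,
#' chlorophyll-less) if and only if it is homozygous for guttatus alleles at
#' `hl13` and homozygous for nasutus alleles at `hl14` -- the genotype that
#' carries no functional copy of the duplicated gene.  Alternative families
#' are provided for model screening:
#'
#' * `one_locus_recessive`: lethal when homozygous for the incompatible
#'   allele at a single locus (3:1 green:white in F2).
#' * `two_locus_dominant_recessive`: one partner acts dominantly
#'   (3/16 white in F2).
#' * `cyto_nuclear_recessive`: lethal only with the incompatible cytoplasm
#'   and a homozygous nuclear partner (1/4 white in one F2 direction, 0 in
#'   the reciprocal).
#'
#' @param model model family name (see above).
#' @param locus_G,locus_N causal loci of the two-locus recessive model: the
#'   locus requiring homozygous-G and the locus requiring homozygous-N.
#' @param one_locus,one_allele locus and lethal homozygous allele of the
#'   one-locus model.
#' @param dominant_locus,dominant_allele,recessive_locus,recessive_allele
#'   parameters of the dominant-recessive model (lethal when carrying at
#'   least one dominant incompatible allele and homozygous at the recessive
#'   partner).
#' @param cyto_incompatible,cyto_locus,cyto_allele parameters of the
#'   cyto-nuclear model (lethal with `cyto_incompatible` cytoplasm and
#'   homozygosity for `cyto_allele` at `cyto_locus`).
#' @return An object of class `incompatibility_spec`.
#' @examples
#' spec <- incompatibility_spec()  # two-locus recessive-recessive
#' @export
incompatibility_spec <- function(model = c("two_locus_recessive_recessive",
                                           "one_locus_recessive",
                                           "two_locus_dominant_recessive",
                                           "cyto_nuclear_recessive"),
                                 locus_G = "hl13", locus_N = "hl14",
                                 one_locus = "hl14", one_allele = "N",
                                 dominant_locus = "hl13",
                                 dominant_allele = "G",
                                 recessive_locus = "hl14",
                                 recessive_allele = "N",
                                 cyto_incompatible = "G",
                                 cyto_locus = "hl14", cyto_allele = "N") {
  model <- match.arg(model)
  loci <- switch(model,
    two_locus_recessive_recessive = c(locus_G, locus_N),
    one_locus_recessive = one_locus,
    two_locus_dominant_recessive = c(dominant_locus, recessive_locus),
    cyto_nuclear_recessive = cyto_locus)
  structure(list(model = model, loci = unique(loci),
                 locus_G = locus_G, locus_N = locus_N,
                 one_locus = one_locus, one_allele = one_allele,
                 dominant_locus = dominant_locus,
                 dominant_allele = dominant_allele,
                 recessive_locus = recessive_locus,
                 recessive_allele = recessive_allele,
                 cyto_incompatible = cyto_incompatible,
                 cyto_locus = cyto_locus, cyto_allele = cyto_allele),
            class = "incompatibility_spec")
}

#' @export
print.incompatibility_spec <- function(x, ...) {
  cat(sprintf("<incompatibility_spec> %s (causal loci: %s)\n",
              x$model, paste(x$loci, collapse = ", ")))
  invisible(x)
}

#' Causal loci required by a model
#' @param spec an [incompatibility_spec].
#' @return Character vector of locus ids.
#' @export
causal_loci <- function(spec) spec$loci

# Deterministic lethality predicate on genotype codes (G/H/N) and cytoplasm.
# `codes`: character matrix with one column per needed locus.
is_lethal_genotype <- function(codes, cytoplasm, spec) {
  stopifnot(inherits(spec, "incompatibility_spec"))
  col <- function(l) {
    stop_if_not(l %in% colnames(codes), "missing causal locus '%s'", l)
    codes[, l]
  }
  switch(spec$model,
    two_locus_recessive_recessive =
      col(spec$locus_G) == "G" & col(spec$locus_N) == "N",
    one_locus_recessive = col(spec$one_locus) == spec$one_allele,
    two_locus_dominant_recessive =
      col(spec$dominant_locus) %in% c(spec$dominant_allele, "H") &
        col(spec$recessive_locus) == spec$recessive_allele,
    cyto_nuclear_recessive =
      cytoplasm == spec$cyto_incompatible &
        col(spec$cyto_locus) == spec$cyto_allele)
}

#' Phenotype individuals under an incompatibility model
#'
#' Applies the model's deterministic lethality predicate to each individual's
#' genotype at the causal loci (plus cytoplasm for cyto-nuclear models).
#'
#' @param x a `cross_population` or [diplotype].
#' @param spec an [incompatibility_spec].
#' @return Character vector of `"green"` / `"white"`.
#' @examples
#' map <- mimulus_causal_map()
#' ind <- diplotype(c(0, 1), c(0, 1), map)   # GG at hl13, NN at hl14
#' phenotype(ind, incompatibility_spec())    # "white"
#' @export
phenotype <- function(x, spec) {
  codes <- genotype_codes(x, loci = causal_loci(spec))
  unname(ifelse(is_lethal_genotype(codes, x$cytoplasm, spec),
                "white", "green"))
}
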