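# Core forward-simulation machinery.
#
# Alleles are parental-origin labels: 0L = G (M. guttatus lineage),
# 1L = N (M. nasutus lineage).  A diplotype is a phased pair of haplotypes
# over the map's loci; a population stores all haplotypes as two integer
# matrices (individual x locus) so meiosis can be vectorised across
# individuals.

ALLELE_G <- 0L
ALLELE_N <- 1L

new_population <- function(hap1, hap2, cytoplasm, map) {
  stopifnot(is.matrix(hap1), is.matrix(hap2),
            all(dim(hap1) == dim(hap2)),
            length(cytoplasm) == nrow(hap1))
  structure(list(hap1 = hap1, hap2 = hap2,
                 cytoplasm = as.character(cytoplasm), map = map),
            class = "cross_population")
}

#' @export
print.cross_population <- function(x, ...) {
  cat(sprintf("<cross_population> %d individuals x %d loci (cytoplasm: %s)\n",
              nrow(x$hap1), ncol(x$hap1),
              paste(unique(x$cytoplasm), collapse = "/")))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a `cross_population`.
#' @return Integer count.
#' @export
n_individuals <- function(pop) nrow(pop$hap1)

#' Construct a single phased individual
#'
#' @param hap1,hap2 integer vectors over the map's loci (0 = G allele,
#'   1 = N allele), or single characters `"G"`/`"N"` recycled to all loci.
#' @param map a [linkage_map].
#' @param cytoplasm maternal-lineage label (`"G"` or `"N"`).
#' @return An object of class `diplotype`.
#' @export
diplotype <- function(hap1, hap2, map, cytoplasm = "G") {
  L <- nrow(map$loci)
  expand <- function(h) {
    if (is.character(h) && length(h) == 1) h <- rep(match(h, c("G", "N")) - 1L, L)
    stop_if_not(length(h) == L, "haplotype length must equal number of loci")
    stop_if_not(all(h %in% c(0L, 1L)), "alleles must be 0 (G) or 1 (N)")
    stats::setNames(as.integer(h), map$loci$locus_id)
  }
  structure(list(hap1 = expand(hap1), hap2 = expand(hap2),
                 cytoplasm = cytoplasm, map = map),
            class = "diplotype")
}

#' Extract one individual from a population
#' @param pop a `cross_population`.
#' @param i individual index.
#' @return A [diplotype].
#' @export
get_individual <- function(pop, i) {
  stop_if_not(i >= 1 && i <= n_individuals(pop), "index out of range")
  diplotype(pop$hap1[i, ], pop$hap2[i, ], pop$map, pop$cytoplasm[i])
}

#' Subset a population by individual index
#' @param pop a `cross_population`.
#' @param idx integer (or logical) index vector.
#' @return A `cross_population`.
#' @export
subset_population <- function(pop, idx) {
  out <- new_population(pop$hap1[idx, , drop = FALSE],
                        pop$hap2[idx, , drop = FALSE],
                        pop$cytoplasm[idx], pop$map)
  if (!is.null(pop$phenotype)) out$phenotype <- pop$phenotype[idx]
  out
}

#' Genotype codes at chosen loci
#'
#' @param x a `cross_population` or [diplotype].
#' @param loci locus ids (default: all loci on the map).
#' @return Character matrix (individual x locus) of codes `"G"` (homozygous
#'   guttatus), `"H"` (heterozygous), `"N"` (homozygous nasutus).
#' @export
genotype_codes <- function(x, loci = NULL) {
  if (inherits(x, "diplotype")) {
    h1 <- rep_rows(x$hap1, 1); h2 <- rep_rows(x$hap2, 1)
  } else {
    h1 <- x$hap1; h2 <- x$hap2
  }
  if (!is.null(loci)) {
    stop_if_not(all(loci %in% colnames(h1)), "unknown loci: %s",
                paste(setdiff(loci, colnames(h1)), collapse = ", "))
    h1 <- h1[, loci, drop = FALSE]; h2 <- h2[, loci, drop = FALSE]
  }
  m <- matrix(c("G", "H", "N")[h1 + h2 + 1L], nrow = nrow(h1),
              dimnames = dimnames(h1))
  m
}

# Vectorised gamete formation.  h1/h2 are parent haplotype matrices with one
# row per gamete to be drawn (rows may repeat a single parent).  Crossovers
# follow the Haldane (no-interference) model: between adjacent loci d cM
# apart the parental haplotype switches with probability (1 - exp(-d/50))/2;
# chromosomes assort independently.
# Which homolog (FALSE = hap1, TRUE = hap2) transmits at each locus of one
# chromosome, for n gametes: a random starting homolog, then switches
# between adjacent loci with the Haldane recombination fraction.
transmit_hap2 <- function(n, pos_cM) {
  k <- length(pos_cM)
  cur <- sample.int(2L, n, replace = TRUE) == 1L
  use2 <- matrix(FALSE, n, k)
  use2[, 1] <- cur
  if (k > 1) {
    r <- 0.5 * (1 - exp(-diff(pos_cM) / 50))
    u <- stats::runif(n * (k - 1))
    dim(u) <- c(n, k - 1)
    for (j in 2:k) {
      cur <- xor(cur, u[, j - 1] < r[j - 1])
      use2[, j] <- cur
    }
  }
  use2
}

cross_gametes <- function(h1, h2, map) {
  n <- nrow(h1)
  gam <- matrix(0L, n, ncol(h1), dimnames = dimnames(h1))
  loci <- map$loci
  for (ch in unique(loci$chrom)) {
    idx <- which(loci$chrom == ch)       # loci already sorted by pos_cM
    use2 <- transmit_hap2(n, loci$pos_cM[idx])
    seg <- h1[, idx, drop = FALSE]
    sel <- which(use2)
    seg[sel] <- h2[, idx, drop = FALSE][sel]
    gam[, idx] <- seg
  }
  gam
}

# Fast path for n gametes from one parent given as haplotype vectors
# (avoids expanding the parent to full n-row matrices).
cross_gametes_single <- function(v1, v2, map, n) {
  gam <- matrix(0L, n, length(v1), dimnames = list(NULL, names(v1)))
  loci <- map$loci
  for (ch in unique(loci$chrom)) {
    idx <- which(loci$chrom == ch)
    use2 <- transmit_hap2(n, loci$pos_cM[idx])
    seg <- matrix(v1[idx], n, length(idx), byrow = TRUE)
    sel <- which(use2)
    seg[sel] <- v2[idx][(sel - 1L) %/% n + 1L]
    gam[, idx] <- seg
  }
  gam
}

#' Simulate meiosis in one parent
#'
#' Draws gametes under the Haldane map function (no crossover interference):
#' the recombinant fraction between loci d cM apart is
#' \eqn{(1 - e^{-d/50})/2}, and different chromosomes assort independently.
#'
#' @param parent a [diplotype].
#' @param n number of gametes to draw.
#' @param seed optional integer seed.
#' @return Integer matrix (gamete x locus) of parental-origin alleles.
#' @export
meiosis <- function(parent, n = 1, seed = NULL) {
  stopifnot(inherits(parent, "diplotype"))
  restore <- seed_scope(seed); on.exit(restore(), add = TRUE)
  cross_gametes_single(parent$hap1, parent$hap2, parent$map, n)
}

#' Cross two parents
#'
#' Each offspring unites one independent gamete from each parent.  The
#' cytoplasm (maternal-lineage) label is inherited from `parent_a`, the
#' maternal parent.
#'
#' @param parent_a maternal [diplotype].
#' @param parent_b paternal [diplotype].
#' @param n_offspring number of offspring.
#' @param seed optional integer seed.
#' @return A `cross_population`.
#' @export
mate <- function(parent_a, parent_b, n_offspring, seed = NULL) {
  stopifnot(inherits(parent_a, "diplotype"), inherits(parent_b, "diplotype"))
  stop_if_not(identical(parent_a$map$loci$locus_id,
                        parent_b$map$loci$locus_id),
              "parents are not on the same map")
  stop_if_not(n_offspring >= 1, "n_offspring must be >= 1")
  restore <- seed_scope(seed); on.exit(restore(), add = TRUE)
  g_a <- cross_gametes_single(parent_a$hap1, parent_a$hap2, parent_a$map,
                              n_offspring)
  g_b <- cross_gametes_single(parent_b$hap1, parent_b$hap2, parent_b$map,
                              n_offspring)
  new_population(g_a, g_b, rep(parent_a$cytoplasm, n_offspring), parent_a$map)
}

#' Self-fertilise a parent
#' @inheritParams mate
#' @param parent a [diplotype].
#' @return A `cross_population` of selfed offspring.
#' @export
self_cross <- function(parent, n_offspring, seed = NULL) {
  mate(parent, parent, n_offspring, seed = seed)
}

# One selfed offspring per parent row; used to generate many independent
# F3 families in a single vectorised pass.
self_each <- function(pop, parent_idx) {
  h1 <- pop$hap1[parent_idx, , drop = FALSE]
  h2 <- pop$hap2[parent_idx, , drop = FALSE]
  g1 <- cross_gametes(h1, h2, pop$map)
  g2 <- cross_gametes(h1, h2, pop$map)
  new_population(g1, g2, pop$cytoplasm[parent_idx], pop$map)
}

#' Expected homozygosity after serial self-fertilisation
#'
#' For a founder fully heterozygous at its segregating sites, each generation
#' of selfing halves the expected heterozygosity, so after `g` generations the
#' genome is expected to be \eqn{1 - (1/2)^g} homozygous (0.875 after three
#' generations).
#'
#' @param generations_selfed non-negative integer.
#' @return Expected homozygous fraction in `[0, 1]`.
#' @examples
#' expected_homozygosity(3)  # 0.875
#' @export
expected_homozygosity <- function(generations_selfed) {
  stop_if_not(length(generations_selfed) == 1 &&
                is.finite(generations_selfed) &&
                generations_selfed >= 0 &&
                generations_selfed == round(generations_selfed),
              "generations_selfed must be a non-negative integer")
  1 - 0.5^generations_selfed
}

#' Build the two parental inbred lines
#'
#' The nasutus founder (a natural selfer) is homozygous N everywhere.  The
#' guttatus founder starts fully heterozygous (an outbred wild plant), is
#' self-fertilised for `selfing_generations_G` generations (simulated with
#' linkage, leaving residual heterozygosity of about
#' \eqn{(1/2)^g}), and is then forced homozygous G at the causal loci --
#' mirroring the empirical confirmation that the mapping line was homozygous
#' at both lethality loci -- and at `panel_loci` (SNP-panel sites are
#' ascertained as fixed interspecific differences, so the mapping parent is
#' treated as homozygous for the reference-lineage allele there; assumption
#' failures are modelled separately by the panel's `g_carries_alt` flag).
#'
#' @param map a [linkage_map].
#' @param selfing_generations_G generations of selfing for the guttatus
#'   founder (default 3).
#' @param causal_loci locus ids forced homozygous G in the guttatus founder
#'   (those present on the map).
#' @param panel_loci optional locus ids also forced homozygous G.
#' @param seed optional integer seed.
#' @return `list(founder_G =, founder_N =)` of [diplotype]s with cytoplasm
#'   labels `"G"` and `"N"`.
#' @export
make_parental_lines <- function(map, selfing_generations_G = 3,
                                causal_loci = c("hl13", "hl14"),
                                panel_loci = NULL, seed = NULL) {
  stopifnot(inherits(map, "linkage_map"))
  restore <- seed_scope(seed); on.exit(restore(), add = TRUE)
  founder_N <- diplotype("N", "N", map, cytoplasm = "N")
  g <- diplotype("G", "N", map, cytoplasm = "G")  # fully heterozygous outbred
  if (selfing_generations_G > 0) {
    for (i in seq_len(selfing_generations_G)) {
      g <- get_individual(self_cross(g, 1), 1)
    }
  }
  # Sites that fixed during selfing are guttatus-lineage alleles (they read
  # as the reference allele on an interspecific panel); only sites still
  # heterozygous retain one nasutus-like allele.
  hom <- g$hap1 == g$hap2
  g$hap1[hom] <- ALLELE_G
  g$hap2[hom] <- ALLELE_G
  fix <- intersect(c(causal_loci, panel_loci), map$loci$locus_id)
  g$hap1[fix] <- ALLELE_G
  g$hap2[fix] <- ALLELE_G
  list(founder_G = g, founder_N = founder_N)
}
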