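# Design-level simulators: whole crossing schemes and pooled sequencing.

#' Simulate an F2 hybrid population
#'
#' Builds the two parental inbred lines, crosses them to a single F1 (all F1s
#' from inbred parents are genetically identical at fixed-difference loci),
#' self-fertilises it to `n` F2s, and phenotypes them under the supplied
#' incompatibility model.
#'
#' @param n number of F2 individuals.
#' @param spec an [incompatibility_spec] (default: two-locus
#'   recessive-recessive).
#' @param map a [linkage_map]; defaults to the minimal causal-locus map.
#' @param maternal `"G"` or `"N"`: which line is the maternal parent of the
#'   F1 (sets the cytoplasm of the whole F2 population).
#' @param selfing_generations_G selfing generations for the guttatus founder.
#' @param panel_loci optional ids forced homozygous G in the guttatus founder
#'   (see [make_parental_lines]).
#' @param founders optional precomputed `list(founder_G, founder_N)`.
#' @param seed optional integer seed.
#' @return A `cross_population` with an added `phenotype` element
#'   (`"green"`/`"white"` per individual).
#' @examples
#' pop <- simulate_f2_population(1000, seed = 1)
#' mean(pop$phenotype == "white")  # ~1/16
#' @export
simulate_f2_population <- function(n, spec = incompatibility_spec(),
                                   map = mimulus_causal_map(),
                                   maternal = c("G", "N"),
                                   selfing_generations_G = 3,
                                   panel_loci = NULL, founders = NULL,
                                   seed = NULL) {
  maternal <- match.arg(maternal)
  restore <- seed_scope(seed); on.exit(restore(), add = TRUE)
  if (is.null(founders)) {
    founders <- make_parental_lines(map, selfing_generations_G,
                                    panel_loci = panel_loci)
  }
  mother <- if (maternal == "G") founders$founder_G else founders$founder_N
  father <- if (maternal == "G") founders$founder_N else founders$founder_G
  f1 <- get_individual(mate(mother, father, 1), 1)
  f2 <- self_cross(f1, n)
  f2$phenotype <- phenotype(f2, spec)
  f2$founders <- founders
  f2$f1 <- f1
  f2
}

#' Simulate an F3 family from one F2 parent
#'
#' @param f2_parent a [diplotype] (e.g. from [get_individual]).
#' @param n family size.
#' @param spec an [incompatibility_spec].
#' @param seed optional integer seed.
#' @return A `cross_population` of the selfed family, with `phenotype`.
#' @export
simulate_f3_family <- function(f2_parent, n, spec = incompatibility_spec(),
                               seed = NULL) {
  restore <- seed_scope(seed); on.exit(restore(), add = TRUE)
  fam <- self_cross(f2_parent, n)
  fam$phenotype <- phenotype(fam, spec)
  fam
}

#' Pooled sequencing counts over a SNP panel
#'
#' Emulates short-read sequencing of a DNA pool: per SNP the total depth is
#' Poisson around `mean_depth`, and alt reads are binomial with success
#' probability equal to the pool's alt-allele frequency adjusted for a
#' symmetric per-read error `error_rate`.  The alt allele is the
#' nasutus-lineage allele, except at panel sites flagged `g_carries_alt`,
#' where both parents read alt (the shared-SNP ascertainment assumption
#' fails) so the site's alt frequency is 1 regardless of pool composition.
#' Zero-depth SNPs are emitted with both depths 0 (missing data).
#'
#' @param members a `cross_population` (or list of [diplotype]s) forming the
#'   pool.
#' @param panel an `snp_panel`; panel SNPs must be loci of the members' map.
#' @param mean_depth mean sequencing depth per SNP.
#' @param error_rate per-read symmetric error probability in `[0, 0.5)`
#'   (default 0.005).
#' @param seed optional integer seed.
#' @return data.frame: `locus_id`, `chrom`, `pos_bp`, `ref_depth`,
#'   `alt_depth`.
#' @export
pool_counts <- function(members, panel, mean_depth, error_rate = 0.005,
                        seed = NULL) {
  stop_if_not(error_rate >= 0 && error_rate < 0.5,
              "error_rate must be in [0, 0.5)")
  if (is.list(members) && !inherits(members, "cross_population")) {
    stop_if_not(length(members) > 0, "empty pool")
    map <- members[[1]]$map
    members <- new_population(
      do.call(rbind, lapply(members, function(d) rep_rows(d$hap1, 1))),
      do.call(rbind, lapply(members, function(d) rep_rows(d$hap2, 1))),
      vapply(members, function(d) d$cytoplasm, character(1)), map)
  }
  stop_if_not(n_individuals(members) > 0, "empty pool")
  ids <- panel$locus_id
  stop_if_not(all(ids %in% colnames(members$hap1)),
              "panel SNPs must be loci of the members' map")
  restore <- seed_scope(seed); on.exit(restore(), add = TRUE)
  n2 <- 2 * n_individuals(members)
  p_alt <- (colSums(members$hap1[, ids, drop = FALSE]) +
              colSums(members$hap2[, ids, drop = FALSE])) / n2
  p_alt[panel$g_carries_alt] <- 1
  p_read <- p_alt * (1 - error_rate) + (1 - p_alt) * error_rate
  depth <- stats::rpois(length(ids), mean_depth)
  alt <- stats::rbinom(length(ids), depth, p_read)
  data.frame(locus_id = ids, chrom = panel$chrom, pos_bp = panel$pos_bp,
             ref_depth = depth - alt, alt_depth = alt)
}

#' Simulate the two-pool F3 bulked-segregant design
#'
#' Reproduces the second BSA round of the study design: green F2s homozygous
#' nasutus at `hl14` are self-fertilised into F3 families; the white pool
#' takes one white seedling from each of `n_white_pool` segregating families
#' (parents heterozygous at `hl13`), and the green pool takes one green
#' seedling from each of `n_green_pool` non-segregating families (parents
#' homozygous nasutus at `hl13`).  Because every pooled seedling comes from
#' an independent F2 family, markers unlinked to the lethality loci are
#' expected at 50% frequency in both pools, while the white pool is fixed
#' guttatus at `hl13` and both pools are fixed nasutus at `hl14`.
#'
#' @param panel an `snp_panel` (see [simulate_snp_panel]).
#' @param spec an [incompatibility_spec]; must be the two-locus
#'   recessive-recessive model for the design's selection logic to apply.
#' @param n_white_pool,n_green_pool pool sizes (study values 34 and 26).
#' @param mean_depth,error_rate sequencing model passed to [pool_counts].
#' @param map base causal map (panel SNPs are added to it).
#' @param family_try F3 seedlings drawn per family when searching for a
#'   white seedling.
#' @param batch F2 individuals simulated per batch while collecting parents.
#' @param maternal maternal line of the F1.
#' @param seed optional integer seed.
#' @return list: `white_counts` / `green_counts` (pool count tables),
#'   `white_members` / `green_members` (`cross_population`s), `map`, and
#'   `truth` (bp positions of the causal loci).
#' @export
simulate_f3_bsa_pools <- function(panel, spec = incompatibility_spec(),
                                  n_white_pool = 34, n_green_pool = 26,
                                  mean_depth = 30, error_rate = 0.005,
                                  map = mimulus_causal_map(),
                                  family_try = 16, batch = 700,
                                  maternal = "G", seed = NULL) {
  stop_if_not(spec$model == "two_locus_recessive_recessive",
              "the F3 pooling design assumes the two-locus recessive model")
  restore <- seed_scope(seed); on.exit(restore(), add = TRUE)
  sim_map <- map_with_panel(panel, map)
  founders <- make_parental_lines(sim_map, panel_loci = panel$locus_id)
  # collect F2 parents of the two family types
  white_parents <- NULL; green_parents <- NULL
  need_w <- n_white_pool; need_g <- n_green_pool
  guard <- 0
  while ((need_w > 0 || need_g > 0) && guard < 20) {
    guard <- guard + 1
    f2 <- simulate_f2_population(batch, spec, sim_map, maternal = maternal,
                                 founders = founders)
    codes <- genotype_codes(f2, loci = c(spec$locus_G, spec$locus_N))
    is_w <- codes[, 1] == "H" & codes[, 2] == "N"   # segregating family
    is_g <- codes[, 1] == "N" & codes[, 2] == "N"   # non-segregating family
    take <- function(pool, idx, need) {
      idx <- which(idx)[seq_len(min(sum(idx), need))]
      if (!length(idx)) return(pool)
      sub <- subset_population(f2, idx)
      if (is.null(pool)) sub else
        new_population(rbind(pool$hap1, sub$hap1), rbind(pool$hap2, sub$hap2),
                       c(pool$cytoplasm, sub$cytoplasm), f2$map)
    }
    white_parents <- take(white_parents, is_w, need_w)
    green_parents <- take(green_parents, is_g, need_g)
    need_w <- n_white_pool - if (is.null(white_parents)) 0 else n_individuals(white_parents)
    need_g <- n_green_pool - if (is.null(green_parents)) 0 else n_individuals(green_parents)
  }
  stop_if_not(need_w <= 0 && need_g <= 0,
              "failed to collect enough F2 family parents")
  # one white F3 seedling per segregating family
  white_rows <- integer(n_white_pool)
  pending <- seq_len(n_white_pool)
  offspring <- NULL
  while (length(pending)) {
    fam_idx <- rep(pending, each = family_try)
    kids <- self_each(white_parents, fam_idx)
    kids$phenotype <- phenotype(kids, spec)
    got <- tapply(seq_along(fam_idx)[kids$phenotype == "white"],
                  fam_idx[kids$phenotype == "white"], min)
    if (length(got)) {
      sel <- as.integer(unlist(got))
      sub <- subset_population(kids, sel)
      offspring <- if (is.null(offspring)) sub else
        new_population(rbind(offspring$hap1, sub$hap1),
                       rbind(offspring$hap2, sub$hap2),
                       c(offspring$cytoplasm, sub$cytoplasm), kids$map)
      pending <- setdiff(pending, as.integer(names(got)))
    }
  }
  white_members <- offspring
  # one (green) F3 seedling per non-segregating family
  green_members <- self_each(green_parents, seq_len(n_green_pool))
  list(white_counts = pool_counts(white_members, panel, mean_depth, error_rate),
       green_counts = pool_counts(green_members, panel, mean_depth, error_rate),
       white_members = white_members, green_members = green_members,
       map = sim_map,
       truth = list(
         hl13 = sim_map$loci[sim_map$loci$locus_id == spec$locus_G,
                             c("chrom", "pos_bp")],
         hl14 = sim_map$loci[sim_map$loci$locus_id == spec$locus_N,
                             c("chrom", "pos_bp")]))
}

#' Simulate a recombinant fine-mapping panel
#'
#' Generates an F2 population over a target chromosome carrying the causal
#' locus and a set of ordered markers, plus the partner causal locus, and
#' assembles the per-individual records used by the fine-mapping stage:
#' ordered marker genotypes, phenotype, partner-locus genotype and (for green
#' individuals) simulated F3 family counts for progeny testing.  White
#' seedlings carry no F3 counts (they are destructively sampled).
#'
#' @param n_f2 F2 individuals to simulate.
#' @param markers data.frame: `marker_id`, `pos_cM`, `pos_bp`, ordered along
#'   the target chromosome.
#' @param target `"hl13"` or `"hl14"`: which causal locus is being mapped.
#' @param spec an [incompatibility_spec] (two-locus recessive model).
#' @param f3_n F3 family size for progeny tests.
#' @param map base causal map.
#' @param maternal maternal line of the F1.
#' @param seed optional integer seed.
#' @return list: `records` (data.frame with id, phenotype, partner_genotype,
#'   f3_green, f3_white, and one column per marker), `markers`, `truth`
#'   (causal locus chrom/bp and each individual's true causal genotype).
#' @export
simulate_recombinant_records <- function(n_f2, markers, target = "hl13",
                                         spec = incompatibility_spec(),
                                         f3_n = 40,
                                         map = mimulus_causal_map(),
                                         maternal = "G", seed = NULL) {
  stop_if_not(target %in% c(spec$locus_G, spec$locus_N),
              "target must be one of the model's causal loci")
  restore <- seed_scope(seed); on.exit(restore(), add = TRUE)
  target_chrom <- map$loci$chrom[map$loci$locus_id == target]
  partner <- setdiff(c(spec$locus_G, spec$locus_N), target)
  mk <- data.frame(locus_id = markers$marker_id, chrom = target_chrom,
                   pos_cM = markers$pos_cM,
                   pos_bp = markers$pos_bp %||% NA_real_)
  sim_map <- add_loci(map, mk)
  f2 <- simulate_f2_population(n_f2, spec, sim_map, maternal = maternal,
                               panel_loci = markers$marker_id)
  marker_codes <- genotype_codes(f2, loci = markers$marker_id)
  causal_codes <- genotype_codes(f2, loci = c(target, partner))
  f3_green <- rep(NA_integer_, n_f2)
  f3_white <- rep(NA_integer_, n_f2)
  greens <- which(f2$phenotype == "green")
  if (length(greens)) {
    fam_idx <- rep(greens, each = f3_n)
    kids <- self_each(f2, fam_idx)
    ph <- phenotype(kids, spec)
    w <- tapply(ph == "white", fam_idx, sum)
    f3_white[as.integer(names(w))] <- as.integer(w)
    f3_green[as.integer(names(w))] <- f3_n - as.integer(w)
  }
  records <- data.frame(id = sprintf("F2_%04d", seq_len(n_f2)),
                        phenotype = f2$phenotype,
                        partner_genotype = causal_codes[, partner],
                        f3_green = f3_green, f3_white = f3_white,
                        stringsAsFactors = FALSE)
  records <- cbind(records, as.data.frame(marker_codes))
  list(records = records, markers = markers,
       truth = list(chrom = target_chrom,
                    pos_bp = sim_map$loci$pos_bp[sim_map$loci$locus_id == target],
                    pos_cM = sim_map$loci$pos_cM[sim_map$loci$locus_id == target],
                    causal_genotype = causal_codes[, target]))
}
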