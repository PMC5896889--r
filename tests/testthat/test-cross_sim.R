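# Forward cross simulator: founders, meiosis, crossing schemes, pooling.

test_that("expected homozygosity follows the selfing closed form", {
  expect_identical(expected_homozygosity(0), 0)
  expect_equal(expected_homozygosity(3), 0.875)
  expect_equal(expected_homozygosity(10), 0.9990234375)
  expect_error(expected_homozygosity(-1), "non-negative")
  expect_error(expected_homozygosity(1.5), "non-negative")
  # independent oracle: per-locus heterozygosity chain over unlinked loci,
  # halving each generation by direct Bernoulli simulation
  set.seed(401)
  n_loci <- 1e4
  het <- rep(TRUE, n_loci)
  for (g in 1:10) het <- het & (runif(n_loci) < 0.5)
  p <- 1 - expected_homozygosity(10)
  expect_lt(abs(mean(het) - p), 3 * sqrt(p * (1 - p) / n_loci))
})

test_that("parental founders have the required genotype structure", {
  map <- unlinked_map(2000)
  fnd <- make_parental_lines(add_loci(map, data.frame(
    locus_id = c("hl13", "hl14"), chrom = c("u0001", "u0002"),
    pos_cM = c(40, 40))), selfing_generations_G = 3, seed = 402)
  g <- fnd$founder_G; n <- fnd$founder_N
  expect_true(all(n$hap1 == 1L) && all(n$hap2 == 1L))
  expect_identical(unname(g$hap1[c("hl13", "hl14")]), c(0L, 0L))
  expect_identical(unname(g$hap2[c("hl13", "hl14")]), c(0L, 0L))
  # residual heterozygosity ~ (1/2)^3 at non-causal loci
  non_causal <- setdiff(names(g$hap1), c("hl13", "hl14"))
  het <- mean(g$hap1[non_causal] != g$hap2[non_causal])
  expect_lt(abs(het - 0.125), 3 * sqrt(0.125 * 0.875 / length(non_causal)))
  # homozygous loci carry the guttatus allele (fixed interspecific diffs)
  hom <- g$hap1 == g$hap2
  expect_true(all(g$hap1[hom] == 0L))
  # large-g analog: effectively fully homozygous
  fnd2 <- make_parental_lines(unlinked_map(500),
                              selfing_generations_G = 30, seed = 403)
  expect_true(all(fnd2$founder_G$hap1 == fnd2$founder_G$hap2))
})

test_that("meiosis follows the Haldane map function", {
  par0 <- diplotype("G", "N", one_chrom_map(c(20, 20)))
  g <- meiosis(par0, 500, seed = 404)
  expect_true(all(g[, 1] == g[, 2]))  # 0 cM apart: always co-inherited
  # d = 10 cM on one chromosome
  par10 <- diplotype("G", "N", one_chrom_map(c(20, 30)))
  g10 <- meiosis(par10, 1e5, seed = 405)
  r_obs <- mean(g10[, 1] != g10[, 2])
  r_exp <- 0.5 * (1 - exp(-10 / 50))
  expect_lt(abs(r_obs - r_exp), 3 * sqrt(r_exp * (1 - r_exp) / 1e5))
  # different chromosomes: independent assortment
  map2 <- linkage_map(data.frame(chrom = c("c1", "c2"), length_cM = 100),
                      data.frame(locus_id = c("a", "b"),
                                 chrom = c("c1", "c2"), pos_cM = 50))
  gx <- meiosis(diplotype("G", "N", map2), 1e5, seed = 406)
  r2 <- mean(gx[, 1] != gx[, 2])
  expect_lt(abs(r2 - 0.5), 3 * sqrt(0.25 / 1e5))
  # d in {1, 10, 50}: Haldane within 3 SE
  for (d in c(1, 10, 50)) {
    pd <- diplotype("G", "N", one_chrom_map(c(10, 10 + d)))
    gd <- meiosis(pd, 1e5, seed = 400 + d)
    re <- 0.5 * (1 - exp(-d / 50))
    expect_lt(abs(mean(gd[, 1] != gd[, 2]) - re),
              3 * sqrt(re * (1 - re) / 1e5))
  }
})

test_that("gametes are mosaics of the parental haplotypes", {
  map <- one_chrom_map(seq(0, 90, by = 10))
  set.seed(407)
  h1 <- sample(0:1, 10, replace = TRUE)
  h2 <- 1L - h1  # heterozygous everywhere so origin is identifiable
  par <- diplotype(h1, h2, map)
  g <- meiosis(par, 200, seed = 408)
  from1 <- sweep(g, 2, par$hap1, `==`)
  from2 <- sweep(g, 2, par$hap2, `==`)
  expect_true(all(from1 | from2))
})

test_that("mate combines one gamete from each parent and tracks cytoplasm", {
  map <- one_chrom_map(c(10, 50, 90))
  homG <- diplotype("G", "G", map, cytoplasm = "G")
  homN <- diplotype("N", "N", map, cytoplasm = "N")
  selfed <- self_cross(homG, 50, seed = 409)
  expect_true(all(selfed$hap1 == 0L) && all(selfed$hap2 == 0L))
  f1 <- mate(homN, homG, 50, seed = 410)
  expect_true(all(genotype_codes(f1) == "H"))
  expect_true(all(f1$cytoplasm == "N"))  # maternal parent listed first
  # map mismatch rejected
  other <- diplotype("G", "G", one_chrom_map(c(10, 50)))
  expect_error(mate(homG, other, 5), "same map")
  # F2 single-locus genotype frequencies 1:2:1 (chi-squared, alpha 0.001)
  f1i <- get_individual(mate(homG, homN, 1, seed = 411), 1)
  f2 <- self_cross(f1i, 1e4, seed = 412)
  tab <- table(factor(genotype_codes(f2)[, 2], levels = c("G", "H", "N")))
  p <- chisq.test(tab, p = c(0.25, 0.5, 0.25))$p.value
  expect_gt(p, 0.001)
})

test_that("phenotype applies the two-locus recessive lethality predicate", {
  map <- mimulus_causal_map()
  spec <- incompatibility_spec()
  expect_identical(phenotype(diplotype(c(0, 1), c(0, 1), map), spec), "white")
  expect_identical(phenotype(diplotype(c(0, 1), c(1, 1), map), spec), "green")
  expect_identical(phenotype(diplotype(c(1, 1), c(1, 1), map), spec), "green")
  # missing causal locus rejected
  expect_error(phenotype(diplotype("G", "N", one_chrom_map(c(1, 2))), spec),
               "unknown loci|missing causal locus")
})

test_that("F2 and F3 white fractions match Mendelian expectations", {
  pop <- simulate_f2_population(1e5, seed = 413)
  p <- 1 / 16
  expect_lt(abs(mean(pop$phenotype == "white") - p),
            3 * sqrt(p * (1 - p) / 1e5))
  # F1s are never white
  fnd <- pop$founders
  f1 <- mate(fnd$founder_G, fnd$founder_N, 500, seed = 414)
  expect_true(all(phenotype(f1, incompatibility_spec()) == "green"))
  # F3 from a (H @ hl13, N @ hl14) parent: 1/4 white
  parent <- diplotype(c(0, 1), c(1, 1), mimulus_causal_map())
  fam <- simulate_f3_family(parent, 1e4, seed = 415)
  expect_lt(abs(mean(fam$phenotype == "white") - 0.25),
            3 * sqrt(0.25 * 0.75 / 1e4))
})

test_that("pool counts reflect pool allele frequencies and the error model", {
  panel <- simulate_snp_panel(200, seed = 416)
  map <- map_with_panel(panel)
  nn <- diplotype("N", "N", map, cytoplasm = "N")
  pool <- self_cross(nn, 10, seed = 417)  # fixed NN pool
  cnt0 <- pool_counts(pool, panel, mean_depth = 40, error_rate = 0,
                      seed = 418)
  fr <- per_snp_freq(cnt0)
  expect_true(all(fr$freq[!fr$masked] == 1))
  # symmetric error pulls the frequency to 1 - e
  cnt1 <- pool_counts(pool, panel, mean_depth = 1e5, error_rate = 0.01,
                      seed = 419)
  fr1 <- per_snp_freq(cnt1)
  expect_lt(max(abs(fr1$freq - 0.99)), 3 * sqrt(0.01 * 0.99 / 1e5) * 5)
  expect_lt(abs(mean(fr1$freq) - 0.99), 0.001)
  # invalid error rate and empty pools rejected
  expect_error(pool_counts(pool, panel, 30, error_rate = 0.6), "error_rate")
  expect_error(pool_counts(list(), panel, 30), "empty pool")
  # zero-depth SNPs are emitted as missing and masked downstream
  cntz <- pool_counts(pool, panel, mean_depth = 0.5, seed = 420)
  frz <- per_snp_freq(cntz)
  expect_true(any(frz$depth == 0))
  expect_true(all(is.na(frz$freq[frz$depth == 0])))
})

test_that("a fixed seed reproduces populations and pool counts bit-identically", {
  a <- simulate_f2_population(300, seed = 421)
  b <- simulate_f2_population(300, seed = 421)
  expect_identical(a$hap1, b$hap1)
  expect_identical(a$hap2, b$hap2)
  expect_identical(a$phenotype, b$phenotype)
  panel <- simulate_snp_panel(100, seed = 422)
  pool <- self_cross(diplotype("N", "N", map_with_panel(panel)), 5, seed = 1)
  expect_identical(pool_counts(pool, panel, 30, seed = 423),
                   pool_counts(pool, panel, 30, seed = 423))
})
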