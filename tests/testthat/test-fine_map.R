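# Fine-mapping: progeny tests, concordance, interval narrowing.

test_that("progeny tests classify by the exact binomial tail", {
  expect_identical(progeny_test(30, 10), "segregating_het")
  expect_identical(progeny_test(40, 0), "homozygous_compatible")
  expect_identical(progeny_test(8, 0), "ambiguous")
  expect_error(progeny_test(0, 0), "zero-size")
  # minimal decisive all-green family at alpha = 0.05 is exactly n = 11
  expect_identical(progeny_test(10, 0), "ambiguous")
  expect_identical(progeny_test(11, 0), "homozygous_compatible")
  expect_true(0.75^10 > 0.05 && 0.75^11 < 0.05)
})

test_that("concordance is 1 with coincident markers and matches the closed form with offsets", {
  # markers exactly at the causal loci
  pop <- simulate_f2_population(3000, seed = 601)
  codes <- as.data.frame(genotype_codes(pop, c("hl13", "hl14")))
  codes$phenotype <- pop$phenotype
  cc <- concordance(codes)
  expect_identical(cc$white_concordance, 1)
  expect_identical(cc$green_lethal_class, 0L)
  # markers 1 cM from each causal locus: white-class concordance equals
  # ((1-r13)(1-r14))^2 with Haldane r at 1 cM
  map <- mimulus_causal_map()
  map <- add_loci(map, data.frame(locus_id = c("m13", "m14"),
                                  chrom = c("chr13", "chr14"),
                                  pos_cM = c(96, 51)))
  pop2 <- simulate_f2_population(24000, map = map,
                                 panel_loci = c("m13", "m14"), seed = 602)
  codes2 <- as.data.frame(genotype_codes(pop2, c("m13", "m14")))
  names(codes2) <- c("hl13", "hl14")
  codes2$phenotype <- pop2$phenotype
  cc2 <- concordance(codes2)
  r <- 0.5 * (1 - exp(-1 / 50))
  p_exp <- (1 - r)^4
  se <- sqrt(p_exp * (1 - p_exp) / cc2$n_white)
  expect_lt(cc2$white_concordance, 1)
  expect_lt(abs(cc2$white_concordance - p_exp), 3 * se)
  # empty white class: concordance undefined
  greens <- codes[codes$phenotype == "green", ]
  expect_true(is.na(concordance(greens)$white_concordance))
  # rows with missing calls are excluded and counted
  codes$hl13[1:5] <- NA
  expect_identical(concordance(codes)$n_excluded, 5L)
})

test_that("causal genotypes are inferred from phenotype and progeny tests", {
  rec <- function(ph, partner, g = NA, w = NA) {
    list(phenotype = ph, partner_genotype = partner, f3_green = g,
         f3_white = w)
  }
  expect_identical(infer_causal_genotype(rec("white", "N")), "G")
  expect_identical(infer_causal_genotype(rec("green", "N", 30, 10)), "H")
  expect_identical(infer_causal_genotype(rec("green", "N", 40, 0)), "N")
  # no F3 data, ambiguous family, or uninformative partner: unknown
  expect_true(is.na(infer_causal_genotype(rec("green", "N"))))
  expect_true(is.na(infer_causal_genotype(rec("green", "N", 8, 0))))
  expect_true(is.na(infer_causal_genotype(rec("green", "H", 30, 10))))
  # mapping the hl14 side flips the incompatible alleles
  expect_identical(infer_causal_genotype(rec("white", "G"),
                                         incompatible_allele = "N",
                                         partner_incompatible = "G"), "N")
})

test_that("narrow_interval recovers a hand-built breakpoint gap", {
  markers <- data.frame(marker_id = sprintf("m%d", 1:5), chrom = "c1",
                        pos_bp = c(100, 200, 300, 400, 500) * 1000)
  # three recombinants whose breakpoints together pin down the gap m3-m4:
  # r1 excludes everything left of m3, r3 everything right of m4
  records <- data.frame(
    id = c("r1", "r2", "r3"),
    inferred_genotype = c("G", "G", "H"),
    m1 = c("H", "G", "H"), m2 = c("H", "G", "H"), m3 = c("H", "G", "H"),
    m4 = c("G", "G", "N"), m5 = c("G", "H", "N"))
  iv <- narrow_interval(records, markers)
  expect_identical(attr(iv, "gaps"), 3L)
  expect_identical(iv$start_bp, 300000)
  expect_identical(iv$end_bp, 400000)
  expect_identical(iv$flank_left, "m3")
  expect_identical(iv$flank_right, "m4")
  # matches the loop-based brute force
  expect_identical(attr(iv, "gaps"), bf_consistent_gaps(records, markers))
  # no informative records: input interval unchanged
  rec0 <- records; rec0$inferred_genotype <- NA
  cur <- genomic_interval("c1", 50, 600000)
  expect_identical(narrow_interval(rec0, markers, cur), cur)
  # records implying disjoint segments raise an inconsistency error
  bad <- data.frame(id = c("a", "b"), inferred_genotype = c("G", "G"),
                    m1 = c("G", "N"), m2 = c("N", "N"), m3 = c("N", "N"),
                    m4 = c("N", "G"))
  mk4 <- markers[1:4, ]
  expect_error(narrow_interval(bad, mk4), "consistent with all")
})

test_that("narrow_interval equals exhaustive search on random instances", {
  set.seed(603)
  n_checked <- 0
  for (i in 1:60) {
    inst <- random_narrow_instance(sample(4:9, 1), sample(3:12, 1))
    bf <- bf_consistent_gaps(inst$records, inst$markers)
    if (!length(bf)) {
      if (any(!is.na(inst$records$inferred_genotype))) {
        expect_error(narrow_interval(inst$records, inst$markers))
      }
      next
    }
    iv <- narrow_interval(inst$records, inst$markers)
    expect_identical(sort(attr(iv, "gaps")), sort(bf))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 10)
})

test_that("adding an informative record never widens the interval", {
  set.seed(604)
  for (i in 1:20) {
    inst <- random_narrow_instance(6, 10)
    bf_all <- bf_consistent_gaps(inst$records, inst$markers)
    if (!length(bf_all)) next
    iv_all <- narrow_interval(inst$records, inst$markers)
    iv_some <- narrow_interval(inst$records[1:5, ], inst$markers)
    expect_gte(iv_all$start_bp, iv_some$start_bp)
    expect_lte(iv_all$end_bp, iv_some$end_bp)
  }
})

test_that("intervals from simulated error-free panels contain the causal position", {
  # whole-chain soundness: simulate recombinant panels, classify records,
  # narrow.  Every interval that is returned must contain the true causal
  # bp.  A rare double crossover hugging the causal locus makes a record
  # conflict with every candidate position; the narrower is specified to
  # report that as an inconsistency rather than return a wrong interval, so
  # such panels must error (they are counted and must stay rare).
  markers <- data.frame(marker_id = sprintf("m%d", 1:6),
                        pos_cM = c(80, 88, 93, 97, 99.2, 100),
                        pos_bp = c(80, 88, 93, 97, 99.2, 100) * 3e5)
  hits <- 0; returned <- 0; conflicts <- 0
  for (rep in 1:15) {
    sim <- simulate_recombinant_records(250, markers, f3_n = 40,
                                        seed = 605 + rep)
    recs <- classify_records(sim$records)
    # inference soundness: classified genotypes match the simulated truth
    known <- !is.na(recs$inferred_genotype)
    expect_true(all(recs$inferred_genotype[known] ==
                      sim$truth$causal_genotype[known]))
    iv <- tryCatch(
      narrow_interval(recs, data.frame(marker_id = markers$marker_id,
                                       chrom = "chr13",
                                       pos_bp = markers$pos_bp)),
      error = function(e) {
        expect_match(conditionMessage(e), "consistent with all")
        NULL
      })
    if (is.null(iv)) { conflicts <- conflicts + 1; next }
    returned <- returned + 1
    hits <- hits + (iv$start_bp <= sim$truth$pos_bp &&
                      sim$truth$pos_bp < iv$end_bp)
  }
  expect_identical(hits, returned)  # no returned interval excludes the truth
  expect_gte(returned, 8)
  expect_lte(conflicts, 7)
})
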