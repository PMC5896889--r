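# Copy placement by haplotype association, frameshift detection,
# expressed-copy calls.

test_that("haplotype calls follow the containment rule on superpositions", {
  panel <- toy_hap_panel()
  expect_setequal(call_haplotypes(superpose(panel, c("G2", "N1")),
                                  panel)$called, c("G2", "N1"))
  expect_setequal(call_haplotypes(superpose(panel, "G1"), panel)$called,
                  "G1")
  expect_setequal(call_haplotypes(superpose(panel, c("G1", "G2", "N1")),
                                  panel)$called, c("G1", "G2", "N1"))
  # observation at a non-panel position is rejected
  expect_error(call_haplotypes(list(p99 = "A"), panel), "non-panel")
  # monotonicity: adding observed states never removes a called haplotype
  obs <- superpose(panel, "G2")
  before <- call_haplotypes(obs, panel)$called
  obs_plus <- lapply(names(obs), function(p)
    unique(c(obs[[p]], panel$states["N1", p])))
  names(obs_plus) <- names(obs)
  after <- call_haplotypes(obs_plus, panel)$called
  expect_true(all(before %in% after))
})

test_that("missing diagnostic positions create reported ambiguity", {
  mini <- haplotype_panel(rbind(X = c("A", "A"), Y = c("A", "C"),
                                Z = c("G", "C")) |>
                            (\(m) { colnames(m) <- c("q1", "q2"); m })())
  # only q1 observed as {A}: X and Y are indistinguishable there
  r <- call_haplotypes(list(q1 = "A"), mini)
  expect_setequal(r$called, c("X", "Y"))
  expect_setequal(r$ambiguous, c("X", "Y"))
  # full observation of a single haplotype: unambiguous
  r2 <- call_haplotypes(list(q1 = "A", q2 = "A"), mini)
  expect_identical(r2$called, "X")
  expect_identical(r2$ambiguous, character(0))
})

test_that("the nine-class panel places all three copies perfectly", {
  sim <- simulate_copy_panel(seed = 701)
  expect_identical(nrow(sim$genotypes), 96L)  # 10 x 8 green + 16 white
  expect_identical(sum(sim$genotypes$phenotype == "white"), 16L)
  res <- infer_placement(sim$presence, sim$genotypes)
  pl <- res$placement[order(res$placement$haplotype), ]
  expect_identical(pl$status, rep("placed", 3))
  expect_identical(pl$mismatches, rep(0, 3))
  expect_identical(pl$locus, c("hl13", "hl14", "hl13"))
  expect_identical(pl$allele, c("G", "G", "N"))
})

test_that("corrupted or uninformative presence patterns are not called placed", {
  sim <- simulate_copy_panel(seed = 702)
  # one flipped individual: best candidate reported with mismatch count 1
  pres <- sim$presence
  pres[1, "G1"] <- !pres[1, "G1"]
  res <- infer_placement(pres, sim$genotypes)
  g1 <- res$placement[res$placement$haplotype == "G1", ]
  expect_identical(g1$status, "unplaced")
  expect_identical(g1$mismatches, 1)
  best <- res$candidates[res$candidates$haplotype == "G1", ]
  expect_identical(best$mismatches[best$locus == "hl13" & best$allele == "G"],
                   1)
  # haplotype present in every individual matches no candidate
  pres2 <- sim$presence
  pres2[, "N1"] <- TRUE
  res2 <- infer_placement(pres2, sim$genotypes)
  expect_identical(
    res2$placement$status[res2$placement$haplotype == "N1"], "unplaced")
  expect_gt(min(res2$candidates$mismatches[res2$candidates$haplotype == "N1"]),
            0)
  # fewer than two genotype classes is unidentifiable
  one_class <- sim$genotypes[sim$genotypes$hl13 == "G" &
                               sim$genotypes$hl14 == "G", ]
  expect_error(infer_placement(sim$presence[1:10, ], one_class[1:10, ]),
               "unidentifiable|classes")
})

test_that("planted placements are recovered exactly across seeded replicates", {
  combos <- expand.grid(locus = c("hl13", "hl14"), allele = c("G", "N"),
                        stringsAsFactors = FALSE)
  ok <- 0
  for (rep in 1:100) {
    set.seed(703 + rep)
    pick <- sample(nrow(combos), 3)
    truth <- data.frame(haplotype = c("h1", "h2", "h3"),
                        combos[pick, ], row.names = NULL)
    sim <- simulate_copy_panel(truth, seed = 800 + rep)
    res <- infer_placement(sim$presence, sim$genotypes)
    pl <- res$placement[match(truth$haplotype, res$placement$haplotype), ]
    ok <- ok + (all(pl$status == "placed") &&
                  identical(pl$locus, truth$locus) &&
                  identical(pl$allele, truth$allele) &&
                  all(pl$mismatches == 0))
  }
  expect_identical(ok, 100)
})

test_that("frameshift detection flags single-base insertions with downstream stops", {
  set.seed(704)
  ref <- random_cds(300)  # long enough that a shifted frame hits a stop
  expect_false(detect_frameshift(ref, ref)$frameshift)
  expect_identical(detect_frameshift(ref, ref)$n_premature, 0L)
  # single adenine inserted mid-gene
  at <- 75
  ins <- paste0(substr(ref, 1, at), "A", substr(ref, at + 1, nchar(ref)))
  r <- detect_frameshift(ins, ref)
  expect_true(r$frameshift)
  expect_identical(r$offset_mod3, 1)
  expect_gte(r$n_premature, 1)
  expect_lt(r$truncated_protein_length, nchar(ref) / 3 - 1)
  # in-frame 3-bp insertion of a non-stop codon: silent
  ins3 <- paste0(substr(ref, 1, 75), "GGA", substr(ref, 76, nchar(ref)))
  r3 <- detect_frameshift(ins3, ref)
  expect_false(r3$frameshift)
  expect_identical(r3$net_offset, 3L)
  expect_identical(r3$n_premature, 0L)
  # invalid inputs
  expect_error(detect_frameshift("ATGNNNTAA", ref), "A/C/G/T")
  expect_error(detect_frameshift(ref, paste0(ref, "A")), "multiple of 3")
  expect_error(detect_frameshift(ref, sub("TAA$", "TAACCCTAA",
                                          sub("^ATG", "ATGTAA", ref))),
               "translate open")
})

test_that("multiple-of-3 indels never shift the frame", {
  set.seed(705)
  for (i in 1:20) {
    ref <- random_cds(50)
    codon_at <- 3 * sample(5:40, 1)
    width <- 3 * sample(1:3, 1)
    ins <- paste0(substr(ref, 1, codon_at),
                  paste(sample(NON_STOP_CODONS, width / 3, replace = TRUE),
                        collapse = ""),
                  substr(ref, codon_at + 1, nchar(ref)))
    del <- paste0(substr(ref, 1, codon_at),
                  substr(ref, codon_at + width + 1, nchar(ref)))
    expect_identical(detect_frameshift(ins, ref)$offset_mod3, 0)
    expect_false(detect_frameshift(ins, ref)$frameshift)
    expect_identical(detect_frameshift(del, ref)$offset_mod3, 0)
    expect_false(detect_frameshift(del, ref)$frameshift)
  }
})

test_that("expressed-copy calls respect the coverage mask", {
  panel <- toy_hap_panel()
  pos <- colnames(panel$states)
  cov_full <- setNames(rep(20, 10), pos)
  # sample expressing only G2
  r <- expressed_copies(superpose(panel, "G2"), cov_full, panel)
  expect_identical(r$status, "expressed")
  expect_identical(r$called, "G2")
  # mixed transcripts
  r2 <- expressed_copies(superpose(panel, c("G2", "N1")), cov_full, panel)
  expect_setequal(r2$called, c("G2", "N1"))
  # all positions under coverage: not expressed (the lethal-seedling case)
  r0 <- expressed_copies(superpose(panel, "G2"), setNames(rep(0, 10), pos),
                         panel)
  expect_identical(r0$status, "not_expressed")
  expect_identical(r0$called, character(0))
  expect_setequal(r0$masked_positions, pos)
  # partial masking drops masked positions from the call
  cov_half <- cov_full; cov_half[1:5] <- 0
  r5 <- expressed_copies(superpose(panel, "G2"), cov_half, panel)
  expect_identical(r5$status, "expressed")
  expect_true("G2" %in% r5$called)
  expect_setequal(r5$masked_positions, pos[1:5])
})
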