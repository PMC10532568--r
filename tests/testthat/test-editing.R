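test_that("rule (ii): 3 reads, 3% frequency, 10x coverage, per replicate", {
  design <- mini_design()
  # 3/30 = 10%: called
  fx <- ed_fixture(design)
  s <- call_editing_sites(fx$dna, fx$rna, list(), design)
  expect_equal(nrow(s$sites), 1)
  expect_equal(s$sites$ed_type, "U-to-C")
  expect_true(all(s$edited[1, ] >= 3 & s$edited[1, ] / s$depth[1, ] >= 0.03 &
                    s$depth[1, ] >= 10))
  # 3/100 = exactly 3%: passes; 2/100 fails the 3-read rule
  fx3 <- ed_fixture(design, rna = setNames(rep(list(c(depth = 100, ed = 3)), 6),
                                           design$samples))
  expect_equal(nrow(call_editing_sites(fx3$dna, fx3$rna, list(), design)$sites), 1)
  fx2 <- ed_fixture(design, rna = setNames(rep(list(c(depth = 100, ed = 2)), 6),
                                           design$samples))
  expect_equal(nrow(call_editing_sites(fx2$dna, fx2$rna, list(), design)$sites), 0)
  # 3% minus epsilon: 3/101 fails the frequency rule
  fxe <- ed_fixture(design, rna = setNames(rep(list(c(depth = 101, ed = 3)), 6),
                                           design$samples))
  expect_equal(nrow(call_editing_sites(fxe$dna, fxe$rna, list(), design)$sites), 0)
  # depth 9 fails the coverage rule
  fxd <- ed_fixture(design, rna = setNames(rep(list(c(depth = 9, ed = 3)), 6),
                                           design$samples))
  expect_equal(nrow(call_editing_sites(fxd$dna, fxd$rna, list(), design)$sites), 0)
})

test_that("rule (iii): DNA must be deep enough and free of non-reference reads", {
  design <- mini_design()
  # any DNA alternative read kills the site
  fx <- ed_fixture(design, dna_depth = 40, dna_alt = 2)
  expect_equal(nrow(call_editing_sites(fx$dna, fx$rna, list(), design)$sites), 0)
  # shallow DNA kills the site
  fx2 <- ed_fixture(design, dna_depth = 9)
  expect_equal(nrow(call_editing_sites(fx2$dna, fx2$rna, list(), design)$sites), 0)
  # position absent from the DNA pileup is unsupported
  fx3 <- ed_fixture(design)
  fx3$dna$pos0 <- 999
  expect_equal(nrow(call_editing_sites(fx3$dna, fx3$rna, list(), design)$sites), 0)
})

test_that("rule (iv): splice-adjacent positions at offsets 1..4 die, 5 lives", {
  design <- mini_design()
  gm <- gene_model("g1", "c1", "+", exons = rbind(c(100, 200), c(260, 400)),
                   cds = rbind(c(100, 200), c(260, 361)))
  # intron [200, 260): boundary cuts at 200 and 260
  for (off in 0:3) {   # intronic side: offsets 1..4 from the donor cut
    fx <- ed_fixture(design, pos0 = 200 + off)
    expect_equal(nrow(call_editing_sites(fx$dna, fx$rna, list(gm), design)$sites), 0)
  }
  fx5 <- ed_fixture(design, pos0 = 204)   # 5th base into the intron
  expect_equal(nrow(call_editing_sites(fx5$dna, fx5$rna, list(gm), design)$sites), 1)
  for (off in 1:4) {   # exonic side of the acceptor cut at 260
    fx <- ed_fixture(design, pos0 = 260 + off - 1)
    expect_equal(nrow(call_editing_sites(fx$dna, fx$rna, list(gm), design)$sites), 0)
  }
  fx5b <- ed_fixture(design, pos0 = 264)
  expect_equal(nrow(call_editing_sites(fx5b$dna, fx5b$rna, list(gm), design)$sites), 1)
  # observed junctions add exclusion zones too
  oj <- data.frame(contig = "c1", donor0 = 500, acceptor0 = 560,
                   sample = "S1_1", reads = 50, clean_overhang = TRUE)
  fx_j <- ed_fixture(design, pos0 = 503)
  expect_equal(nrow(call_editing_sites(fx_j$dna, fx_j$rna, list(), design,
                                       observed_junctions = oj)$sites), 0)
})

test_that("rule (v): presence needs >= 2 replicates of some stage", {
  design <- mini_design()
  one_rep <- setNames(rep(list(c(depth = 30, ed = 0)), 6), design$samples)
  one_rep[["S1_1"]] <- c(depth = 30, ed = 9)
  fx <- ed_fixture(design, rna = one_rep)
  expect_equal(nrow(call_editing_sites(fx$dna, fx$rna, list(), design)$sites), 0)
  two_rep <- one_rep; two_rep[["S1_2"]] <- c(depth = 30, ed = 9)
  fx2 <- ed_fixture(design, rna = two_rep)
  s <- call_editing_sites(fx2$dna, fx2$rna, list(), design)
  expect_equal(s$sites$stages, "S1")
  expect_equal(unname(s$presence[1, ]), c(TRUE, FALSE))
  # merged mode pools the stage but still wants two supporting replicates
  s_m <- call_editing_sites(fx2$dna, fx2$rna, list(), design,
                            merge_replicates = TRUE)
  expect_equal(nrow(s_m$sites), 1)
  s_m1 <- call_editing_sites(fx$dna, fx$rna, list(), design,
                             merge_replicates = TRUE)
  expect_equal(nrow(s_m1$sites), 0)
})

test_that("editing types: sense naming, strand complement, involution", {
  expect_equal(classify_editing_type("T", "C", "+"), "U-to-C")
  expect_equal(classify_editing_type("A", "G", "-"), "U-to-C")   # complement
  expect_equal(classify_editing_type("A", "G", "+"), "A-to-I(G)")
  expect_equal(classify_editing_type("G", "A", "+"), "G-to-A")
  expect_equal(classify_editing_type("C", "T", "+"), "C-to-U")
  expect_equal(classify_editing_type("T", "A", "+"), "U-to-A")
  # involution under strand flip across all 12 substitutions
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pairs <- expand.grid(r = bases, a = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$r != pairs$a, ]
  expect_equal(nrow(pairs), 12)
  types <- mapply(classify_editing_type, pairs$r, pairs$a, "+")
  expect_equal(length(unique(types)), 12)
  for (i in seq_len(nrow(pairs))) {
    expect_equal(classify_editing_type(pairs$r[i], pairs$a[i], "+"),
                 classify_editing_type(comp[pairs$r[i]], comp[pairs$a[i]], "-"))
  }
})

test_that("editing level, per-stage level, intensity and stage specificity", {
  design <- mini_design()
  rna <- setNames(list(c(depth = 30, ed = 3), c(depth = 30, ed = 3),
                       c(depth = 30, ed = 3), c(depth = 100, ed = 8),
                       c(depth = 100, ed = 8), c(depth = 100, ed = 8)),
                  design$samples)
  fx <- ed_fixture(design, rna = rna)
  s <- call_editing_sites(fx$dna, fx$rna, list(), design)
  lv <- editing_level(s)
  expect_equal(unname(lv[1, "S1_1"]), 0.10)   # 3/30
  expect_equal(unname(lv[1, "S2_1"]), 0.08)   # 8/100
  stl <- stage_editing_level(s)
  expect_equal(unname(stl[1, ]), c(0.10, 0.08))
  # intensity: 1 site, 5e6 mapped reads -> 0.2 events per million
  mt <- setNames(rep(5e6, 6), design$samples)
  expect_equal(unname(editing_intensity(s, mt)), c(0.2, 0.2))
  # doubling mapped reads halves intensity
  expect_equal(unname(editing_intensity(s, mt * 2)), c(0.1, 0.1))
  expect_error(editing_intensity(s, mt * 0), class = "fdrm_data_error")
  # specificity bookkeeping conserves the site total
  spec <- stage_specificity(s)
  expect_equal(sum(spec$sharing), nrow(s$sites))
  expect_equal(unname(spec$per_stage_specific), c(0, 0))  # present in both stages
})

test_that("called sites never violate rules (i)-(v) on simulated data", {
  design <- stage_design()
  gen <- simulate_genome(n_genes = 25, seed = 21)
  ed <- simulate_editing(gen$models, gen$genome, design, n_sites = 60,
                         n_neg = 6, seed = 22)
  s <- call_editing_sites(ed$dna, ed$rna, gen$models, design,
                          genome = gen$genome)
  expect_gt(nrow(s$sites), 0)
  cuts <- splice_boundary_cuts(gen$models)
  for (i in seq_len(nrow(s$sites))) {
    pres_st <- strsplit(s$sites$stages[i], ",")[[1]]
    for (st in pres_st) {
      reps <- design$replicates[[st]]
      cand <- s$candidate[i, reps]
      expect_gte(sum(cand), 2)
      ok <- s$edited[i, reps][cand] >= 3 &
        s$edited[i, reps][cand] / s$depth[i, reps][cand] >= 0.03 &
        s$depth[i, reps][cand] >= 10
      expect_true(all(ok))
    }
    cc <- cuts$cut[cuts$contig == s$sites$contig[i]]
    if (length(cc)) expect_true(all(s$sites$pos0[i] < cc - 4 |
                                      s$sites$pos0[i] > cc + 3))
  }
  # every called site is homozygous-reference and deep in DNA
  dkey <- paste0(ed$dna$contig, ":", ed$dna$pos0)
  for (i in seq_len(nrow(s$sites))) {
    drow <- ed$dna[dkey == paste0(s$sites$contig[i], ":", s$sites$pos0[i]), ]
    expect_gte(pileup_depth(drow), 10)
    expect_equal(pileup_depth(drow), drow[[s$sites$ref_plus[i]]])
  }
})
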