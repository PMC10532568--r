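# a 4-exon gene on either strand for classifier truth tables
classifier_gene <- function(strand) {
  cds <- paste0("ATG", strrep("GCT", 40), "TAA")   # 126 nt
  intr <- function(ch) paste0("GT", strrep(ch, 50), "AG")
  build_coding_gene(cds, introns = c(intr("C"), intr("T"), intr("G")),
                    cut_sites = c(40, 80, 120), utr5 = strrep("G", 20),
                    utr3 = strrep("T", 20), strand = strand, pad = 200)
}

all_samples_j <- function(design, contig, d, a, reads, clean = TRUE) {
  do.call(rbind, lapply(design$samples, function(sm)
    jrow(contig, d, a, sm, reads, clean)))
}

test_that("shared-end alternatives resolve to A5SS/A3SS by strand", {
  design <- mini_design()
  for (strand in c("+", "-")) {
    tg <- classifier_gene(strand)
    ann <- gene_introns(tg$model)
    # vary the genomic right end (acceptor side) of intron 1
    jx <- rbind(all_samples_j(design, "chr1", ann[1, 1], ann[1, 2], 30),
                all_samples_j(design, "chr1", ann[1, 1], ann[1, 2] - 12, 10))
    ev <- classify_as_events(list(tg$model), jx)
    expect_equal(nrow(ev$events), 1)
    expect_equal(ev$events$as_type, if (strand == "+") "A3SS" else "A5SS")
    # vary the genomic left end (donor side) of intron 2
    jx2 <- rbind(all_samples_j(design, "chr1", ann[2, 1], ann[2, 2], 30),
                 all_samples_j(design, "chr1", ann[2, 1] + 9, ann[2, 2], 10))
    ev2 <- classify_as_events(list(tg$model), jx2)
    expect_equal(ev2$events$as_type, if (strand == "+") "A5SS" else "A3SS")
  }
})

test_that("exon skipping, intron retention and terminal events classify by structure", {
  design <- mini_design()
  tg <- classifier_gene("+")
  gm <- tg$model; ann <- gene_introns(gm); ex <- gm$exons
  # CE: e1->e3 skip plus both inclusion junctions
  jx <- rbind(all_samples_j(design, "chr1", ann[1, 1], ann[1, 2], 20),
              all_samples_j(design, "chr1", ann[2, 1], ann[2, 2], 20),
              all_samples_j(design, "chr1", ann[1, 1], ann[2, 2], 20))
  ev <- classify_as_events(list(gm), jx)
  expect_equal(ev$events$as_type, "CE")
  expect_equal(ev$events$start0, unname(ex[2, 1]))
  expect_equal(ev$events$end0, unname(ex[2, 2]))

  # IR: spliced reads plus uniform intronic coverage
  jx_ir <- all_samples_j(design, "chr1", ann[3, 1], ann[3, 2], 15)
  rg <- do.call(rbind, lapply(design$samples, function(sm)
    data.frame(contig = "chr1", start0 = ann[3, 1], end0 = ann[3, 2],
               sample = sm, mean_cov = 5)))
  ev_ir <- classify_as_events(list(gm), jx_ir, rg)
  expect_equal(ev_ir$events$as_type, "IR")
  expect_equal(c(ev_ir$events$intron_start0, ev_ir$events$intron_end0),
               unname(c(ann[3, 1], ann[3, 2])))

  # AFE on '+': novel exon upstream of exon 1 splicing into exon 2
  jx_t <- rbind(all_samples_j(design, "chr1", ann[1, 1], ann[1, 2], 30),
                all_samples_j(design, "chr1", ex[1, 1] - 60, ann[1, 2], 10))
  ev_t <- classify_as_events(list(gm), jx_t)
  expect_equal(ev_t$events$as_type, "AFE")
  # same structure on '-' is an ALE
  tgm <- classifier_gene("-")
  annm <- gene_introns(tgm$model); exm <- tgm$model$exons
  jx_tm <- rbind(all_samples_j(design, "chr1", annm[1, 1], annm[1, 2], 30),
                 all_samples_j(design, "chr1", exm[1, 1] - 60, annm[1, 2], 10))
  ev_tm <- classify_as_events(list(tgm$model), jx_tm)
  expect_equal(ev_tm$events$as_type, "ALE")

  # junction in no gene is dropped, one with both ends novel is complex
  jx_x <- rbind(all_samples_j(design, "chr1", 5, 60, 50),
                all_samples_j(design, "chr1", ann[1, 1], ann[1, 2], 30),
                all_samples_j(design, "chr1",
                              floor((ex[1, 1] + ex[1, 2]) / 2),
                              floor((ex[2, 1] + ex[2, 2]) / 2), 10))
  ev_x <- classify_as_events(list(gm), jx_x, flank = 50)
  expect_equal(ev_x$events$as_type, "complex")
  # unclean overhangs are excluded before counting
  jx_u <- all_samples_j(design, "chr1", ann[1, 1], ann[1, 2] - 12, 10,
                        clean = FALSE)
  ev_u <- classify_as_events(list(gm), rbind(
    all_samples_j(design, "chr1", ann[1, 1], ann[1, 2], 30), jx_u))
  expect_equal(nrow(ev_u$events), 0)
})

test_that("evidence filter enforces the 10-read, >25-coverage and rare-isoform rules", {
  design <- mini_design()
  tg <- classifier_gene("+")
  ann <- gene_introns(tg$model)
  mk <- function(inc_rep, exc_rep) {
    jx <- rbind(all_samples_j(design, "chr1", ann[1, 1], ann[1, 2], inc_rep),
                all_samples_j(design, "chr1", ann[1, 1], ann[1, 2] - 12, exc_rep))
    classify_as_events(list(tg$model), jx)
  }
  # per-stage pooled values are 3x the per-replicate reads
  expect_equal(nrow(filter_as_events(mk(3, 3), design)$events), 0)    # jn 9 < 10
  expect_equal(nrow(filter_as_events(mk(8, 1), design)$events), 0)    # minor 3 < 5
  # inclusion 24, exclusion 2 pooled: coverage 26 but minor support 2 -> removed
  d1 <- stage_design(stages = "S1", n_reps = 1)
  jx <- rbind(jrow("chr1", ann[1, 1], ann[1, 2] - 12, "S1_1", 24),
              jrow("chr1", ann[1, 1], ann[1, 2], "S1_1", 2))
  ev <- classify_as_events(list(tg$model), jx)
  expect_equal(nrow(filter_as_events(ev, d1)$events), 0)
  # inclusion 80, exclusion 20 -> retained; filtering is idempotent
  jx2 <- rbind(jrow("chr1", ann[1, 1], ann[1, 2] - 12, "S1_1", 80),
               jrow("chr1", ann[1, 1], ann[1, 2], "S1_1", 20))
  ev2 <- classify_as_events(list(tg$model), jx2)
  f1 <- filter_as_events(ev2, d1)
  expect_equal(nrow(f1$events), 1)
  f2 <- filter_as_events(f1, d1)
  expect_identical(f1$events, f2$events)
})

test_that("PSI: ratio, boundaries, effective-length normalization, NA handling", {
  d1 <- stage_design(stages = "S1", n_reps = 1)
  tg <- classifier_gene("+")
  ann <- gene_introns(tg$model)
  mk <- function(inc, exc) {
    jx <- rbind(jrow("chr1", ann[1, 1], ann[1, 2] - 12, "S1_1", inc),
                jrow("chr1", ann[1, 1], ann[1, 2], "S1_1", exc))
    classify_as_events(list(tg$model), jx)
  }
  expect_equal(unname(compute_psi(mk(30, 10), d1)[1, 1]), 0.75)
  expect_equal(unname(compute_psi(mk(30, 0), d1)[1, 1]), 1.0)
  # CE with two inclusion junctions (20, 20) vs one skip (20): PSI 0.5
  jx <- rbind(jrow("chr1", ann[1, 1], ann[1, 2], "S1_1", 20),
              jrow("chr1", ann[2, 1], ann[2, 2], "S1_1", 20),
              jrow("chr1", ann[1, 1], ann[2, 2], "S1_1", 20))
  ev <- classify_as_events(list(tg$model), jx)
  expect_equal(ev$events$as_type, "CE")
  expect_equal(unname(compute_psi(ev, d1)[1, 1]), 0.5)
  # zero denominator -> NA, not 0, and below a coverage floor -> NA
  design2 <- mini_design()
  jx2 <- do.call(rbind, lapply(design2$replicates$S1, function(sm) rbind(
    jrow("chr1", ann[1, 1], ann[1, 2] - 12, sm, 30),
    jrow("chr1", ann[1, 1], ann[1, 2], sm, 10))))
  ev2 <- classify_as_events(list(tg$model), jx2)
  psi2 <- compute_psi(ev2, design2)
  expect_true(is.na(psi2[1, "S2"]))
  expect_equal(unname(psi2[1, "S1"]), 0.75)
  # monotone in inclusion holding exclusion fixed
  vals <- vapply(c(10, 20, 40, 80), function(i)
    unname(compute_psi(mk(i, 10), d1)[1, 1]), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("Fisher exact p equals exhaustive enumeration for margins <= 30", {
  set.seed(11)
  for (i in 1:40) {
    tb <- rmultinom(1, sample(10:30, 1), prob = runif(4, 0.1, 1))
    p <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p, fisher_oracle(tb[1], tb[2], tb[3], tb[4]), tolerance = 1e-9)
    expect_equal(p, fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("differential splicing applies the dPSI/p/FDR conjunction", {
  design <- stage_design(stages = c("S1", "S2"), n_reps = 1)
  tg <- classifier_gene("+")
  ann <- gene_introns(tg$model)
  mk2 <- function(i1, e1, i2, e2) {
    jx <- rbind(jrow("chr1", ann[1, 1], ann[1, 2] - 12, "S1_1", i1),
                jrow("chr1", ann[1, 1], ann[1, 2], "S1_1", e1),
                jrow("chr1", ann[1, 1], ann[1, 2] - 12, "S2_1", i2),
                jrow("chr1", ann[1, 1], ann[1, 2], "S2_1", e2))
    classify_as_events(list(tg$model), jx)
  }
  # balanced table: dPSI 0, p 1
  r0 <- differential_splicing(mk2(50, 50, 50, 50), design, "S1", "S2")
  expect_equal(r0$delta_psi, 0)
  expect_equal(r0$pvalue, 1)
  expect_false(r0$significant)
  # strong shift: dPSI 0.4, p from the hypergeometric oracle
  r1 <- differential_splicing(mk2(90, 10, 50, 50), design, "S1", "S2")
  expect_equal(r1$delta_psi, 0.4)
  expect_equal(r1$pvalue, fisher_oracle(90, 10, 50, 50), tolerance = 1e-9)
  expect_true(r1$significant)
  # large dPSI but weak counts: not significant
  r2 <- differential_splicing(mk2(9, 1, 5, 5), design, "S1", "S2")
  expect_equal(r2$delta_psi, 0.4)
  expect_true(r2$pvalue > 0.05)
  expect_false(r2$significant)
  # undefined PSI in one stage: untestable
  r3 <- differential_splicing(mk2(50, 50, 0, 0), design, "S1", "S2")
  expect_false(r3$testable)
  expect_true(is.na(r3$pvalue))
})

test_that("process specificity requires significance in exactly one process", {
  design <- stage_design()
  base <- data.frame(event_id = "e1", stageA = "Myc", stageB = "Scl",
                     significant = TRUE, stringsAsFactors = FALSE)
  ps <- process_specific_events(base, design)
  expect_equal(ps$specific_process, "sclerotia")
  multi <- rbind(base,
                 data.frame(event_id = "e1", stageA = "Myc", stageB = "Knot",
                            significant = TRUE))
  ps2 <- process_specific_events(multi, design)
  expect_true(is.na(ps2$specific_process))
  none <- data.frame(event_id = "e2", stageA = "Myc", stageB = "Scl",
                     significant = FALSE)
  ps3 <- process_specific_events(none, design)
  expect_equal(ps3$processes, "")
  expect_true(is.na(ps3$specific_process))
})
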