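test_that("site location: precedence, codon arithmetic, intergenic fallback", {
  tg <- toy_gene_plus()
  gm <- tg$model
  # first CDS base: codon 1, position 1
  pos_cds1 <- gm$cds[1, 1]
  ann <- locate_site(data.frame(contig = "chr1", pos0 = pos_cds1), list(gm),
                     tg$genome)
  expect_equal(ann$feature, "CDS")
  expect_equal(c(ann$codon_index, ann$codon_position), c(1, 1))
  # a UTR3 base and an intronic base
  ann3 <- locate_site(data.frame(contig = "chr1", pos0 = gm$utr3[1, 1] + 2),
                      list(gm))
  expect_equal(ann3$feature, "UTR3")
  intr <- gene_introns(gm)
  anni <- locate_site(data.frame(contig = "chr1", pos0 = intr[1, 1] + 5),
                      list(gm))
  expect_equal(anni$feature, "intron")
  # outside every gene
  annx <- locate_site(data.frame(contig = "chr1", pos0 = 2), list(gm))
  expect_equal(annx$feature, "intergenic")
  expect_true(is.na(annx$gene_id))
  expect_error(locate_site(data.frame(contig = "chr1", pos0 = 1e6), list(gm),
                           tg$genome), class = "fdrm_consistency_error")
  # codon arithmetic round-trips the CDS offset
  off <- 1730
  expect_equal((577 - 1) * 3 + (3 - 1), off)
  ce <- coding_effect_from_cds(paste0("ATG", strrep("GAA", 600), "TAA"), off, "T")
  expect_equal(c(ce$codon_index, ce$codon_position), c(577, 3))
})

test_that("codon effects: stop gained/lost, synonymous, missense", {
  # UAC -> UAG at the third base: stop gained
  cds <- paste0("ATG", "TAC", strrep("GCT", 3), "TGA")
  ce <- coding_effect_from_cds(cds, 5, "G")   # codon 2, position 3, C>G
  expect_equal(ce$effect, "stop_gained")
  expect_equal(c(ce$aa_ref, ce$aa_alt), c("Y", "*"))
  expect_equal(ce$residues_lost, 5 - 2 + 1)   # residues 2..5 all lost
  # CUU -> CUC: synonymous leucine
  ce2 <- coding_effect_from_cds(paste0("ATG", "CTT", "TAA"), 5, "C")
  expect_equal(ce2$effect, "synonymous")
  # stop UAA -> UAC: stop lost
  ce3 <- coding_effect_from_cds(paste0("ATG", "AAA", "TAA"), 8, "C")
  expect_equal(ce3$effect, "stop_lost")
  expect_equal(ce3$aa_alt, "Y")
  # missense
  ce4 <- coding_effect_from_cds(paste0("ATG", "AAA", "TAA"), 3, "G")
  expect_equal(ce4$effect, "missense")
  expect_error(coding_effect_from_cds("ATGA", 0, "C"), class = "fdrm_model_error")
})

test_that("predict_coding_effect maps genomic positions through either strand", {
  for (strand in c("+", "-")) {
    tg <- build_coding_gene(cds = paste0("ATG", "TAC", "CTT", "TAA"),
                            strand = strand, pad = 60)
    gm <- tg$model
    # genomic position of CDS offset 5 (codon 2 pos 3)
    bl <- if (strand == "+") gm$cds[1, 1] + 5 else gm$cds[1, 2] - 1 - 5
    alt_plus <- if (strand == "-") "C" else "G"   # sense G either way
    ce <- predict_coding_effect(gm, tg$genome, bl, alt_plus)
    expect_equal(ce$effect, "stop_gained")
    expect_equal(ce$codon_index, 2)
  }
})

test_that("effect classification agrees with a full-translation oracle", {
  set.seed(33)
  codons <- apply(expand.grid(b1 = c("T", "C", "A", "G"), b2 = c("T", "C", "A", "G"),
                              b3 = c("T", "C", "A", "G")), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  n_trials <- 2000
  for (t in seq_len(n_trials)) {
    L <- sample(5:30, 1)
    cds <- paste0("ATG", paste(sample(sense, L, replace = TRUE), collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1))
    off <- sample(seq_len(nchar(cds)), 1) - 1
    ref <- substr(cds, off + 1, off + 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    ce <- coding_effect_from_cds(cds, off, alt)
    mut <- cds; substr(mut, off + 1, off + 1) <- alt
    p0 <- translate_cds(cds); p1 <- translate_cds(mut)
    expect_equal(ce$effect == "synonymous", identical(p0, p1))
    if (ce$effect == "stop_gained") {
      # surviving + lost residues (new stop excluded) = original length
      surviving <- ce$codon_index - 1
      expect_equal(surviving + ce$residues_lost, nchar(p0) - 1)
    }
  }
})

test_that("isoform effects: in-frame insertion/deletion, frameshift, premature stop", {
  # 54-nt retained intron, in frame, no stop -> +18 residues
  intron54 <- paste0("GTA", strrep("GCC", 16), "AAG")
  tg <- build_coding_gene(cds = paste0("ATG", strrep("GAT", 100), "TAA"),
                          introns = c(intron54), cut_sites = c(30 + 150),
                          utr5 = strrep("C", 30), pad = 80)
  intr <- gene_introns(tg$model)
  ev <- list(as_type = "IR", start0 = intr[1, 1], end0 = intr[1, 2])
  fx <- predict_isoform_effect(ev, tg$model, tg$genome)
  expect_equal(fx$consequence, "in_frame_insertion")
  expect_equal(fx$aa_delta, 18)
  # 57-nt serine-rich intron -> +19
  intron57 <- strrep("AGC", 19)
  tg2 <- build_coding_gene(cds = paste0("ATG", strrep("GAT", 100), "TAA"),
                           introns = c(intron57), cut_sites = c(30 + 150),
                           utr5 = strrep("C", 30), pad = 80)
  intr2 <- gene_introns(tg2$model)
  fx2 <- predict_isoform_effect(list(as_type = "IR", start0 = intr2[1, 1],
                                     end0 = intr2[1, 2]), tg2$model, tg2$genome)
  expect_equal(fx2$consequence, "in_frame_insertion")
  expect_equal(fx2$aa_delta, 19)
  # 50-nt intron -> frameshift
  tg3 <- build_coding_gene(cds = paste0("ATG", strrep("GAT", 100), "TAA"),
                           introns = paste0("GT", strrep("C", 46), "AG"),
                           cut_sites = c(30 + 150), utr5 = strrep("C", 30),
                           pad = 80)
  intr3 <- gene_introns(tg3$model)
  fx3 <- predict_isoform_effect(list(as_type = "IR", start0 = intr3[1, 1],
                                     end0 = intr3[1, 2]), tg3$model, tg3$genome)
  expect_equal(fx3$consequence, "frameshift")
  # in-frame intron containing a stop -> premature_stop
  intron_stop <- paste0("GTA", "TAA", strrep("GCC", 15), "AAG")
  tg4 <- build_coding_gene(cds = paste0("ATG", strrep("GAT", 100), "TAA"),
                           introns = intron_stop, cut_sites = c(30 + 150),
                           utr5 = strrep("C", 30), pad = 80)
  intr4 <- gene_introns(tg4$model)
  fx4 <- predict_isoform_effect(list(as_type = "IR", start0 = intr4[1, 1],
                                     end0 = intr4[1, 2]), tg4$model, tg4$genome)
  expect_equal(fx4$consequence, "premature_stop")
  # intron inside the UTR leaves the CDS untouched
  tg5 <- build_coding_gene(cds = paste0("ATG", strrep("GAT", 20), "TAA"),
                           introns = paste0("GT", strrep("C", 50), "AG"),
                           cut_sites = 10, utr5 = strrep("C", 30), pad = 80)
  intr5 <- gene_introns(tg5$model)
  fx5 <- predict_isoform_effect(list(as_type = "IR", start0 = intr5[1, 1],
                                     end0 = intr5[1, 2]), tg5$model, tg5$genome)
  expect_equal(fx5$consequence, "utr_only")
  # skipping a 30-nt in-frame internal exon -> in_frame_deletion of 10 aa
  cds <- paste0("ATG", strrep("GAT", 100), "TAA")
  tg6 <- build_coding_gene(cds = cds,
                           introns = c(paste0("GT", strrep("C", 40), "AG"),
                                       paste0("GT", strrep("T", 40), "AG")),
                           cut_sites = c(60, 90), utr5 = strrep("C", 30),
                           pad = 80)
  ex6 <- tg6$model$exons
  fx6 <- predict_isoform_effect(list(as_type = "CE", start0 = ex6[2, 1],
                                     end0 = ex6[2, 2]), tg6$model, tg6$genome)
  expect_equal(fx6$consequence, "in_frame_deletion")
  expect_equal(fx6$aa_delta, -10)
})

test_that("hypergeometric enrichment matches enumeration and applies cutoffs", {
  background <- sprintf("g%03d", 1:60)
  term_map <- rbind(
    data.frame(gene_id = background[1:10], term = "T_hit"),
    data.frame(gene_id = background[11:40], term = "T_bg"),
    data.frame(gene_id = background[41:45], term = "T_zero"))
  gene_set <- background[1:12]   # all 10 T_hit genes plus 2 others
  res <- enrich_terms(gene_set, term_map, background)
  hit <- res[res$term == "T_hit", ]
  expect_equal(hit$hits_k, 10)
  # oracle: enumerate the hypergeometric mass directly
  oracle_p <- function(k, K, N, n)
    sum(vapply(k:min(K, n), function(x)
      choose(K, x) * choose(N - K, n - x) / choose(N, n), numeric(1)))
  expect_equal(hit$pvalue, oracle_p(10, 10, 60, 12), tolerance = 1e-12)
  expect_true(hit$significant)
  zero <- res[res$term == "T_zero", ]
  expect_equal(zero$hits_k, 0)
  expect_false(zero$significant)
  expect_gte(zero$pvalue, 0.3)
  # random fixture against the oracle
  set.seed(44)
  tm <- data.frame(gene_id = sample(background, 200, replace = TRUE),
                   term = sample(paste0("T", 1:20), 200, replace = TRUE))
  gs <- sample(background, 15)
  r2 <- enrich_terms(gs, tm, background)
  for (i in seq_len(nrow(r2))) {
    expect_equal(r2$pvalue[i],
                 oracle_p(r2$hits_k[i], r2$term_size_K[i], 60, 15),
                 tolerance = 1e-9)
  }
  expect_error(enrich_terms("gX", term_map, background), class = "fdrm_data_error")
  expect_error(enrich_terms("g001", term_map, character(0)),
               class = "fdrm_data_error")
})
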