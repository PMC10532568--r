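# fdrm — developmental transcriptome modification analysis

`fdrm` is an R package for asking how a multi-stage fungal developmental
transcriptome is modified *beyond* transcription. It targets the classic
mushroom life-cycle design — nine stages (basidiospores BS, germinating
spores BS12h/BS24h, vegetative mycelia Myc, oidia- and sclerotia-forming
mycelia Oidia/Scl, hyphal knots Knot, primordia Pri, young fruiting bodies
YFB) with three biological replicates, grouped into five developmental
processes — and provides four analysis layers plus a synthetic-data module
with planted ground truth:

* **Expression** — CPM filtering (CPM > 1 in ≥ 2/3 replicates), TMM
  normalization, relative expression `RE_ik = (x_ik − min_i)/(max_i − min_i)`
  on log2 TMM values, an exact negative-binomial test with DEG rule
  |log2FC| > 2 and BH-adjusted p < 0.05, and Ward clustering of DEG
  profiles into six archetypes.
* **Alternative splicing** — classification of the eight canonical event
  types (IR, A5SS, A3SS, CE, MXE, AFE, ALE, complex) from junction
  evidence, percent spliced in `PSI = inc/(inc + exc)` with
  effective-length normalization, evidence filters (≥ 10-read junctions,
  coverage > 25, rare isoform ≥ 5 reads and > 5%), and differential
  splicing at |ΔPSI| > 0.1, p < 0.05, FDR < 0.05 (Fisher exact on pooled
  counts, BH).
* **RNA editing** — a DNA-vs-RNA pileup caller under five rules (quality
  25 pileups; ≥ 3 reads / ≥ 3% / depth ≥ 10; homozygous-reference DNA with
  depth ≥ 10; > 4 bases from any splice boundary; ≥ 2 replicates per
  stage), twelve sense-strand editing types with U-to-C conventions
  (A→G is A-to-I(G)), editing level = edited/depth, per-stage intensity
  in events per million mapped reads, and stage-specificity bookkeeping.
* **Effects & phylotranscriptomics** — codon-level consequences of edits
  (synonymous/missense/stop gained with residues lost/stop lost),
  isoform-level consequences of splicing alternatives (in-frame
  insertion/deletion, frameshift, premature stop), hypergeometric term
  enrichment (p < 0.2, q < 0.2, BH), transcriptome age and divergence
  indices `TAI_k = Σ ps_i e_ik / Σ e_ik`, and modification-by-phylostratum
  ratios against the genome background.

Inputs are standard formats (FASTA, GFF3, SAM/BAM, TSV matrices) or a
documented plain-text evidence dialect (pileup, junction and
region-coverage TSVs), so every step runs without alignment files; outputs
are VCF 4.2, BED12-like tables and TSVs. See the methods vignette
(`vignettes/methods.Rmd`) for the models, assumptions and design choices.

## Worked example

```r
library(fdrm)
design <- stage_design()                       # 9 stages x 3 replicates
gen <- simulate_genome(n_genes = 40, seed = 7)

ed <- simulate_editing(gen$models, gen$genome, design, n_sites = 80,
                       n_neg = 10, seed = 11)
sites <- call_editing_sites(ed$dna, ed$rna, gen$models, design,
                            genome = gen$genome)
sites
#> editing_sites: 61 sites; top types: U-to-C, A-to-I(G), C-to-U
head(sort(table(sites$sites$ed_type), decreasing = TRUE), 4)
#>    U-to-C A-to-I(G)    C-to-U    G-to-A
#>        33         7         5         5
length(stage_specificity(sites)$specific)
#> [1] 44                                   # sites present in exactly one stage
```

61 of the 80 planted sites pass the five filter rules (the remainder have
true levels below the 3% callable floor), none of the 40 planted negative
controls is called, U-to-C dominates as planted, and 44 sites are
stage-specific. Splicing on the same toy genome:

```r
sp <- simulate_splicing(gen$models, design, n_events_per_type = 2,
                        coverage = 200, seed = 3)
ev <- filter_as_events(classify_as_events(gen$models, sp$junctions, sp$regions),
                       design)
ev
#> as_events: 16 events (A3SS:2 A5SS:2 AFE:2 ALE:2 CE:2 complex:2 IR:2 MXE:2) across 27 samples
diff <- differential_splicing_all(ev, design)
sum(diff$significant)
#> [1] 25                                   # significant stage-pair comparisons
sum(!is.na(process_specific_events(diff, design)$specific_process))
#> [1] 4                                    # events specific to one process
```

All 16 planted events are recovered with their planted types and regions.
Finally, a coding consequence of one called edit:

```r
ann <- locate_site(sites, gen$models, gen$genome)
i <- which(ann$feature == "CDS")[1]
predict_coding_effect(gen$models[[ann$gene_id[i]]], gen$genome,
                      sites$sites$pos0[i], sites$sites$alt_plus[i])
#> site contig_1:1350:A>G (U-to-C): codon 207 pos 3, L -> L, synonymous
```

A command-line entry point wraps the same pipeline:

```sh
inst/cli/fdrm simulate  --config cfg.yaml --out run/
inst/cli/fdrm splicing  --config cfg.yaml --out run/
inst/cli/fdrm editing   --config cfg.yaml --out run/
```

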