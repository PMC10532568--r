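---
title: "Models and methods behind fdrm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fdrm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model of the data

`fdrm` analyses how a fungal developmental transcriptome is modified beyond
transcription. The design it targets is a nine-stage mushroom life cycle —
basidiospores (BS), germinating spores (BS12h, BS24h), vegetative mycelia
(Myc), oidia- and sclerotia-forming mycelia (Oidia, Scl), hyphal knots
(Knot), primordia (Pri) and young fruiting bodies (YFB) — with three
biological replicates per stage, grouped into five developmental processes
(germination, oidiation, sclerotia formation, fruiting, sporulation). The
package consumes alignments or, equivalently, documented plain-text evidence
tables (pileups, junction counts, region coverage, count matrices), so the
entire pipeline is testable without sequencing data.

Four analytical layers sit on this design:

1. **Expression** — CPM filtering, TMM normalization, per-gene min-max
   relative expression, an exact negative-binomial test for differential
   expression, and clustering of DEG profiles into six archetypes.
2. **Alternative splicing (AS)** — classification of eight event types from
   junction evidence, percent spliced in (PSI), and Fisher-based
   differential splicing.
3. **RNA editing (RE)** — a five-rule caller that compares RNA pileups with
   a DNA pileup from the same strain, types the substitutions on the
   transcript sense strand, and tracks stage presence.
4. **Effects and phylotranscriptomics** — codon-level consequences of edits,
   isoform-level consequences of splicing alternatives, hypergeometric term
   enrichment, and transcriptome age/divergence indices (TAI/TDI).

# Thresholds and their meaning

All tunable parameters default to the standard values for this kind of
developmental analysis; they live in `fdrm_default_config()`.

| Parameter | Default | Meaning |
|---|---|---|
| CPM filter | > 1 in ≥ 2 of 3 replicates of ≥ 1 stage | gene is expressed |
| DEG rule | \|log2FC\| > 2 and BH-adjusted p < 0.05 | four-fold change |
| junction support | ≥ 10 reads in a stage | AS event evidence |
| total coverage | > 25 reads in that stage | AS event evidence |
| rare isoform | ≥ 5 reads and > 5% ratio | minor isoform is real |
| overhang | no mismatch/indel within 6 bases | junction is trustworthy |
| differential AS | \|ΔPSI\| > 0.1, p < 0.05, BH FDR < 0.05 | significance |
| editing quality | base and mapping quality ≥ 25 | pileup construction |
| editing evidence | ≥ 3 reads, ≥ 3%, depth ≥ 10 | per-replicate candidate |
| DNA support | depth ≥ 10, zero non-reference reads | not a genomic variant |
| splice clearance | > 4 bases from any junction boundary | not a mis-alignment |
| replication | same substitution in ≥ 2 of 3 replicates | stage presence |
| enrichment | p < 0.2 and q < 0.2 (BH) | reported terms |

Coordinates are 0-based half-open everywhere internally; GFF3 and VCF are
emitted 1-based, BED 0-based, matching each standard exactly.

# Differential expression

Rather than delegating testing to a count-model package, `fdrm`
implements the simplest published exact-test variant explicitly so its
behaviour is fully specified: counts are TMM-normalized and scaled to a common effective
library size, a **single common dispersion** is estimated by method of
moments (median over per-gene `(s² − m)/m²` on pooled within-group moments,
floored at zero), and each gene is tested with the exact conditional
negative-binomial test on group sums. This deliberately diverges from
empirical-Bayes tagwise shrinkage: with three replicates per group and a
four-fold DEG threshold, the common-dispersion exact test is conservative
and transparent, and its power on planted four-fold changes exceeds 95% at
library size 10⁶ (verified in the acceptance suite). The TMM implementation
follows the published recipe (30% M-trim, 5% A-trim, precision weights,
reference = sample with upper quartile closest to the mean); unlike some
implementations the factor vector is *not* rescaled to geometric mean 1 —
the reference factor is exactly 1 — which changes nothing downstream
because only ratios of effective library sizes matter. The unit tests
verify agreement with an independent implementation up to that rescaling.

For the relative-expression transform `RE = (x − min)/(max − min)` the
input is `log2(TMM-CPM + 1)`; the pseudo-count (the data's own convention
is silent here) avoids −∞ at zero counts, and a constant gene maps to all
zeros so the range invariant holds. DEG profiles are clustered with Ward
linkage on Euclidean distances between per-stage mean RE, cut at k = 6 —
nothing in the data dictates a particular clustering algorithm, so
Ward/Euclidean/k = 6 (matching the six recurring developmental archetypes)
is this package's design choice; genes are sorted lexicographically first so ties resolve
deterministically.

# The splicing classifier

The event detector compares observed junctions (and intronic coverage)
against single-isoform gene models:

* shared-donor/shared-acceptor junction pairs are **A5SS/A3SS**,
  strand-resolved — a pair sharing its genomic-left end varies the 3'
  splice site on `+` genes but the 5' splice site on `-` genes;
* a junction joining two non-adjacent annotated boundaries is a **CE**
  (one exon skipped) or **complex** (several);
* two single-exon skip junctions around adjacent internal exons that are
  never joined to each other are an **MXE**;
* an annotated intron with both spliced reads and intronic coverage is an
  **IR**;
* a novel junction splicing from outside the annotated terminal exon into
  the first (or last) annotated acceptor/donor is an **AFE/ALE**;
* anything left is **complex**.

Junctions that cannot be assigned to exactly one gene (intergenic, or
falling into overlapping genes) are dropped, as are junctions without a
clean 6-base overhang. PSI pools replicates within a stage and divides each
side's raw count by its number of distinct supporting junctions
(effective-length normalization) before the ratio — a cassette exon with
two inclusion junctions of 20 reads each against one 20-read skip junction
gives PSI 0.5, not 2/3. A zero denominator yields `NA`, never 0.
Differential splicing uses a two-sided Fisher exact test on the pooled 2×2
inclusion/exclusion table — a deliberately simple, fully-specified choice;
concordance with black-box splicing detectors is explicitly out of scope. An event is process-specific when it is significant in at least one
stage-pair comparison of exactly one process.

# The editing caller

Candidates are called **per replicate** (the evidence rule), then filtered
by DNA support, splice clearance and replication. Two design points were
genuinely open and are resolved as follows, both switchable:

* *Per-replicate vs merged calling*: default per replicate, because the
  2-of-3 replicate rule is naturally defined at replicate level. A merged
  mode applies the evidence rule to stage-pooled tallies and then still
  demands two supporting replicates.
* *DNA depth floor*: "no non-reference DNA reads" is only meaningful at
  some minimum DNA coverage; the floor defaults to 10, mirroring the RNA
  coverage floor, with a strict zero-tolerance for non-reference DNA reads
  (`dna_alt_tol` relaxes this to a fraction).

The splice-exclusion zone covers the four bases on either side of every
boundary of annotated introns *and* junctions observed in the RNA evidence;
the fifth base is the first allowed one. Editing types are named on the
transcript sense strand (A→G reported as A-to-I(G), T→C as U-to-C);
intergenic sites use the plus strand, and a site inside overlapping genes
on both strands is reported under the first gene's strand with the
alternative typing flagged. Per-stage level is the mean of `edited/depth`
over the replicates in which the site is present; editing intensity is
events per million mapped reads per replicate, averaged within stage.

# Effect prediction

Coding effects substitute the edited base into its codon (standard nuclear
code, table 1 — the organism's code is not stated, and fungal nuclear
genes use the standard table) and compare amino acids; `stop_gained`
reports `residues_lost`, the count from the affected codon through the
original final residue. Isoform effects rebuild both isoform CDSs — intron
retention inserts, cassette/alt-site events delete, mutually exclusive
exons swap — and classify frameshift (length change not divisible by 3),
premature stop, in-frame insertion/deletion with signed `aa_delta`, or
`utr_only` when the CDS is untouched. Enrichment is the one-sided
hypergeometric upper tail with BH adjustment over user-supplied term maps.

# Phylotranscriptomics

TAI/TDI are expression-weighted mean strata; the expression input is
TMM-normalized CPM averaged over replicates on the **linear** scale (the
established index definition uses linear expression; a log-scale variant
can be fed in by the caller since the function is agnostic to its input
matrix). The relative value `RV = (v − min)/(max − min)` normalizes each
index across stages; a constant series maps to zeros by convention.
Modification-by-phylostratum reports, per stratum, the proportion of
modified genes relative to the genome background, with `NA` for empty
strata.

# The synthetic world

The generators emulate the stated design — 9 stages × 3 replicates with
the labels above — and plant known truth:

* `simulate_genome()`: uniform-random contigs; genes with 2–6 exons,
  complete CDSs (constructively stop-free), GT..AG introns of 48–90 nt
  (short, fungal-like), UTRs, random strand, and old-biased phylostratum
  labels PS1–PS12. Intergenic gaps (≥ 1100 nt) exceed twice the junction
  assignment flank so evidence is never ambiguous between neighbours.
  Protein lengths 120–400 aa and UTR lengths are desk-scale choices fixed
  once.
* `simulate_expression()`: NB counts over log-normal baselines; six
  archetypal stage templates; planted DEGs at |log2FC| ≥ 2 (default 4).
  Because planting DEGs shifts stage totals, raw CPM compresses the
  planted fold change; TMM — the pipeline's own correction — restores it,
  and the tests measure recovery on that scale. `dispersion = 0` is the
  Poisson limit.
* `simulate_splicing()`: all eight event types, inclusion counts drawn
  `Binomial(coverage, PSI)` per replicate, constitutive support for
  untouched introns, truth manifest with per-stage PSI.
* `simulate_editing()`: homozygous-reference DNA; U-to-C-dominant type
  weights; true levels Beta(1, 11.346) (mean 0.081); stage sets biased to
  single-stage presence with sclerotia over-represented; four negative
  control classes (DNA variants, splice-adjacent positions, single-replicate
  signals, sub-threshold signals).

What a green test does and does not establish: the simulated world has no
alignment errors, no strand bias, no overdispersed editing levels across
replicates and no overlapping genes, so recovery rates here bound the
idealized behaviour of the statistics, not performance on real libraries.
Dataset-scale tallies (thousands of AS events, hundreds of editing sites)
require real sequencing depth and are design anchors only; the acceptance
suite instead pins the two worked
molecular examples (a 137-residue truncation from a stop-gaining edit at
codon 577 of a 713-residue protein; +18 and +19 residue in-frame intron
retentions) and property-level guarantees (≥ 95% planted-site recovery
with zero negative-control calls, PSI within ±0.05 at coverage 200, DEG
power ≥ 95% at the stated depth, oracle equivalence of Fisher/BH/TMM/
translation paths).

# Numerical notes and limitations

* The exact NB test enumerates the conditional distribution; for totals
  above 2×10⁵ the support is windowed to ±45 conditional standard
  deviations (excluded mass < 10⁻²⁵).
* Fisher p-values use the "sum of probabilities ≤ observed" definition
  with a 10⁻⁷ relative tie tolerance, matching the classical two-sided
  test.
* The DEG power criterion is computed over 200 planted instances arranged
  as 20 simulated matrices × 10 planted genes to stay inside the runtime
  budget; this estimates per-gene power under BH across 500 genes per run.
* One isoform per gene is assumed on input; the classifier discovers
  alternatives from evidence rather than from multi-isoform annotation.
* Known limitations: no hyper-editing rescue, no read-level simulation
  (pileups and junction tables are generated directly), and milRNA–UTR hybridization is out of
  scope (UTR edits are recorded in the VCF so such analyses can be re-run
  externally).
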