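#' Default editing-type sampling weights
#'
#' U-to-C dominates; G-to-A, C-to-U and A-to-I(G) are the next most common;
#' the remaining eight substitutions share the rest.
#'
#' @return named numeric vector over the 12 editing types
#' @export
editing_type_weights <- function() {
  w <- c("U-to-C" = 0.55, "G-to-A" = 0.08, "C-to-U" = 0.08, "A-to-I(G)" = 0.08)
  rest <- c("A-to-C", "A-to-U", "C-to-G", "C-to-A", "G-to-C", "G-to-U",
            "U-to-G", "U-to-A")
  c(w, setNames(rep((1 - sum(w)) / length(rest), length(rest)), rest))
}

# sense ref/alt bases for a type label
type_to_bases <- function(type) {
  if (type == "A-to-I(G)") return(c("A", "G"))
  m <- regmatches(type, regexec("^(.)-to-(.)$", type))[[1]]
  un <- function(b) if (b == "U") "T" else b
  c(un(m[2]), un(m[3]))
}

#' Simulate DNA/RNA pileups with planted editing sites
#'
#' Plants `n_sites` editing sites across genic (CDS/UTR) and intergenic
#' positions: types drawn from `type_weights` (U-to-C dominant by default),
#' true levels from a Beta distribution with mean 0.081 by default, stage
#' presence biased towards single-stage sites with sclerotia
#' over-represented. The DNA pileup is homozygous reference everywhere; RNA
#' alternative-base fractions are drawn per replicate as
#' Binomial(depth, level). Sites keep >= 5 nt clearance from every splice
#' boundary and never collide.
#'
#' Four negative-control classes are planted (`n_neg` each): (a) positions
#' with a genuine DNA variant, (b) positions within 4 nt of a splice
#' boundary, (c) signals confined to a single replicate, and (d)
#' sub-threshold signals (depth < 10, < 3 supporting reads, or frequency
#' < 3%). None of these may be called.
#'
#' @param models named list of `gene_model`
#' @param genome a `genome_ref`
#' @param design a `stage_design`
#' @param n_sites planted true sites
#' @param type_weights named weights over the 12 editing types
#' @param level_shape Beta(shape1, shape2) for true levels (mean
#'   shape1/(shape1+shape2); default mean 0.081)
#' @param min_level floor applied to drawn levels
#' @param rna_depth,dna_depth mean per-sample read depths (Poisson)
#' @param frac_intergenic fraction of sites placed between genes
#' @param stage_weights stage sampling weights (named; default biased to Scl)
#' @param single_stage_probs distribution of the number of presence stages
#' @param n_neg negative controls per class
#' @param seed RNG seed
#' @param level_fn optional function(n) overriding the Beta level draw
#' @return list: `dna` and `rna` pileup data.frames, `truth` data.frame
#'   (class "positive"/"neg_dna_variant"/"neg_splice"/"neg_single_rep"/
#'   "neg_subthreshold", type, true level, stage set), `mapped_totals`
#'   (named per-sample mapped-read totals)
#' @export
simulate_editing <- function(models, genome, design, n_sites = 200,
                             type_weights = editing_type_weights(),
                             level_shape = c(1, 11.346), min_level = 0.02,
                             rna_depth = 80, dna_depth = 60,
                             frac_intergenic = 0.4, stage_weights = NULL,
                             single_stage_probs = c(0.72, 0.14, 0.08, 0.06),
                             n_neg = 10, seed = 1, level_fn = NULL) {
  set.seed(seed)
  stages <- design$stages
  samples <- design$samples
  if (is.null(stage_weights)) {
    stage_weights <- setNames(rep(1, length(stages)), stages)
    if ("Scl" %in% stages) stage_weights["Scl"] <- 2.5
  }
  cuts <- splice_boundary_cuts(models)
  used <- character(0)
  bases <- c("A", "C", "G", "T")

  splice_clear <- function(contig, pos0, min_dist = 5) {
    cc <- cuts$cut[cuts$contig == contig]
    !length(cc) || all(pos0 < cc - min_dist | pos0 > cc + min_dist - 1)
  }
  gene_regions <- lapply(models, function(gm)
    list(gm = gm, span = gene_span(gm)))
  intergenic_pos <- function(ref_needed) {
    for (try in 1:200) {
      ct <- sample(names(genome), 1)
      p <- sample.int(nchar(genome[[ct]]), 1) - 1
      in_gene <- any(vapply(gene_regions, function(gr)
        gr$gm$contig == ct && gr$span[1] <= p && p < gr$span[2], logical(1)))
      if (in_gene) next
      key <- paste0(ct, ":", p)
      if (key %in% used) next
      if (substr(genome[[ct]], p + 1, p + 1) != ref_needed) next
      return(list(contig = ct, pos0 = p))
    }
    NULL
  }
  genic_pos <- function(ref_sense_needed, min_dist = 5) {
    for (try in 1:200) {
      gm <- models[[sample.int(length(models), 1)]]
      ref_plus_needed <- if (gm$strand == "-") comp_base(ref_sense_needed)
      else ref_sense_needed
      ivs <- rbind(gm$cds, gm$utr5, gm$utr3)
      iv <- ivs[sample.int(nrow(ivs), 1), ]
      if (iv[2] - iv[1] < 3) next
      p <- sample(seq(iv[1], iv[2] - 1), 1)
      key <- paste0(gm$contig, ":", p)
      if (key %in% used) next
      if (!splice_clear(gm$contig, p, min_dist)) next
      if (substr(genome[[gm$contig]], p + 1, p + 1) != ref_plus_needed) next
      return(list(contig = gm$contig, pos0 = p, gm = gm))
    }
    NULL
  }

  rna_rows <- list(); dna_rows <- list(); truth <- list()
  add_pileup_row <- function(store, contig, pos0, ref, sample, tal) {
    row <- data.frame(contig = contig, pos0 = pos0, ref = ref, sample = sample,
                      A = tal["A"], C = tal["C"], G = tal["G"], T = tal["T"],
                      N = 0L, row.names = NULL, stringsAsFactors = FALSE)
    if (store == "rna") rna_rows[[length(rna_rows) + 1]] <<- row
    else dna_rows[[length(dna_rows) + 1]] <<- row
  }
  tally <- function(ref, alt, depth, ed) {
    tal <- setNames(rep(0L, 4), bases)
    tal[ref] <- as.integer(depth - ed)
    if (ed > 0) tal[alt] <- as.integer(ed)
    tal
  }
  draw_stages <- function() {
    k <- sample(seq_along(single_stage_probs), 1, prob = single_stage_probs)
    sample(stages, min(k, length(stages)), prob = stage_weights[stages])
  }
  draw_level <- function() {
    if (!is.null(level_fn)) return(level_fn(1))
    max(min_level, rbeta(1, level_shape[1], level_shape[2]))
  }

  plant <- function(class, level = NULL, pos_override = NULL,
                    dna_variant = FALSE, single_rep = FALSE,
                    sub_kind = NULL) {
    type <- sample(names(type_weights), 1, prob = type_weights)
    sb <- type_to_bases(type)
    genic <- is.null(pos_override) && runif(1) >= frac_intergenic
    if (!is.null(pos_override)) {
      loc <- pos_override
      strand <- loc$strand %||% "+"
    } else if (genic) {
      loc <- genic_pos(sb[1])
      if (is.null(loc)) return(invisible(FALSE))
      strand <- loc$gm$strand
    } else {
      loc <- intergenic_pos(sb[1])
      if (is.null(loc)) return(invisible(FALSE))
      strand <- "+"
    }
    ref_plus <- if (strand == "-") comp_base(sb[1]) else sb[1]
    alt_plus <- if (strand == "-") comp_base(sb[2]) else sb[2]
    if (substr(genome[[loc$contig]], loc$pos0 + 1, loc$pos0 + 1) != ref_plus)
      return(invisible(FALSE))
    key <- paste0(loc$contig, ":", loc$pos0)
    if (key %in% used)
      stop_fdrm("fdrm_sim_error", "site collision at %s", key)
    used <<- c(used, key)
    lv <- level %||% draw_level()
    pres <- draw_stages()
    # RNA evidence
    for (sm in samples) {
      st <- design$sample_stage[sm]
      depth <- max(10L, rpois(1, rna_depth))
      ed <- 0L
      active <- st %in% pres
      if (!is.null(sub_kind)) {
        if (sub_kind == "low_depth") { depth <- 8L; ed <- if (active) 3L else 0L }
        else if (sub_kind == "few_reads") { depth <- 60L; ed <- if (active) 2L else 0L }
        else if (sub_kind == "low_freq") { depth <- 160L; ed <- if (active) 3L else 0L }
      } else if (single_rep) {
        ed <- if (active && sm == design$replicates[[pres[1]]][1])
          rbinom(1, depth, max(lv, 0.3)) else 0L
      } else if (active) {
        ed <- rbinom(1, depth, lv)
      }
      add_pileup_row("rna", loc$contig, loc$pos0, ref_plus, sm,
                     tally(ref_plus, alt_plus, depth, ed))
    }
    # DNA evidence
    ddep <- max(10L, rpois(1, dna_depth))
    dna_alt <- if (dna_variant) as.integer(round(ddep / 2)) else 0L
    add_pileup_row("dna", loc$contig, loc$pos0, ref_plus, "DNA",
                   tally(ref_plus, alt_plus, ddep, dna_alt))
    truth[[length(truth) + 1]] <<- data.frame(
      contig = loc$contig, pos0 = loc$pos0, class = class,
      ref_plus = ref_plus, alt_plus = alt_plus, strand = strand,
      ed_type = type, true_level = lv,
      stages = paste(sort(pres), collapse = ","),
      gene_id = if (!is.null(loc$gm)) loc$gm$gene_id else NA_character_,
      stringsAsFactors = FALSE)
    invisible(TRUE)
  }

  n_done <- 0
  while (n_done < n_sites) {
    if (plant("positive")) n_done <- n_done + 1
  }
  # (a) DNA-variant positions
  for (i in seq_len(n_neg)) plant("neg_dna_variant", level = 0.5, dna_variant = TRUE)
  # (b) splice-adjacent positions (within 4 nt of a boundary)
  nb <- 0
  while (nb < n_neg && nrow(cuts) > 0) {
    ci <- sample.int(nrow(cuts), 1)
    offs <- c(0:3, -4:-1)
    p <- cuts$cut[ci] + sample(offs, 1)
    ct <- cuts$contig[ci]
    if (p < 0 || p >= nchar(genome[[ct]])) next
    if (paste0(ct, ":", p) %in% used) next
    refb <- substr(genome[[ct]], p + 1, p + 1)
    if (!refb %in% bases) next
    gm_hit <- Filter(function(gr) gr$gm$contig == ct && gr$span[1] <= p &&
                       p < gr$span[2], gene_regions)
    strand <- if (length(gm_hit)) gm_hit[[1]]$gm$strand else "+"
    ref_sense <- if (strand == "-") comp_base(refb) else refb
    alt_sense <- sample(setdiff(bases, ref_sense), 1)
    # force-type the planting at this exact position
    ok <- local({
      alt_plus <- if (strand == "-") comp_base(alt_sense) else alt_sense
      used <<- c(used, paste0(ct, ":", p))
      lv <- 0.4
      pres <- draw_stages()
      for (sm in samples) {
        st <- design$sample_stage[sm]
        depth <- max(10L, rpois(1, rna_depth))
        ed <- if (st %in% pres) rbinom(1, depth, lv) else 0L
        add_pileup_row("rna", ct, p, refb, sm, tally(refb, alt_plus, depth, ed))
      }
      ddep <- max(10L, rpois(1, dna_depth))
      add_pileup_row("dna", ct, p, refb, "DNA", tally(refb, alt_plus, ddep, 0L))
      truth[[length(truth) + 1]] <<- data.frame(
        contig = ct, pos0 = p, class = "neg_splice", ref_plus = refb,
        alt_plus = alt_plus, strand = strand,
        ed_type = classify_editing_type(refb, alt_plus, strand),
        true_level = lv, stages = paste(sort(pres), collapse = ","),
        gene_id = NA_character_, stringsAsFactors = FALSE)
      TRUE
    })
    if (ok) nb <- nb + 1
  }
  # (c) single-replicate signals
  for (i in seq_len(n_neg)) plant("neg_single_rep", single_rep = TRUE)
  # (d) sub-threshold signals
  kinds <- rep(c("low_depth", "few_reads", "low_freq"), length.out = n_neg)
  for (i in seq_len(n_neg)) plant("neg_subthreshold", sub_kind = kinds[i])

  truth <- rbind_rows(truth)
  rna <- rbind_rows(rna_rows)
  dna <- rbind_rows(dna_rows)
  mapped <- setNames(round(rpois(length(samples), 5e6)), samples)
  fdrm_log("simulate_editing: %d positives, %d rows RNA pileup",
           sum(truth$class == "positive"), nrow(rna))
  list(dna = dna, rna = rna, truth = truth, mapped_totals = mapped)
}

#' Write a ground-truth manifest as JSON
#' @param manifest list of truth tables (any structure of data.frames)
#' @param path output file
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
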