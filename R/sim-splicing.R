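#' Simulate junction evidence with planted alternative-splicing events
#'
#' Plants events of up to all 8 types in multi-exon genes (at most one event
#' per gene; genes lacking the required exon structure for a type are
#' skipped with a warning). For every planted event a per-stage true PSI is
#' drawn (optionally shifted within one developmental process to create
#' differential events), and per-replicate inclusion/exclusion read counts
#' are drawn binomially: inclusion ~ Binomial(coverage, PSI), exclusion =
#' coverage - inclusion. All remaining annotated introns receive
#' constitutive junction support. Intron-retention inclusion evidence is
#' emitted as region coverage over the intron.
#'
#' The inclusion isoform follows the classifier conventions: retained intron
#' (IR), included exon (CE), proximal splice-site form (A5SS/A3SS), left
#' exon (MXE), annotated form (AFE/ALE/complex).
#'
#' @param models named list of `gene_model`
#' @param design a `stage_design`
#' @param n_events_per_type events to plant per type
#' @param coverage per-replicate total event coverage
#' @param types event types to plant
#' @param diff_frac fraction of events given a stage-varying PSI
#' @param constitutive_cov junction reads for non-event introns
#' @param seed RNG seed
#' @return list: `junctions` (junction-evidence data.frame), `regions`
#'   (region-coverage data.frame), `truth` (data.frame with gene, type,
#'   expected event region and one `psi_<stage>` column per stage)
#' @export
simulate_splicing <- function(models, design, n_events_per_type = 2,
                              coverage = 200,
                              types = c("IR", "A5SS", "A3SS", "CE", "MXE",
                                        "AFE", "ALE", "complex"),
                              diff_frac = 0.5, constitutive_cov = 80,
                              seed = 1) {
  set.seed(seed)
  stages <- design$stages
  samples <- design$samples
  jrows <- list(); rrows <- list(); truth <- list()
  used_genes <- character(0)
  used_introns <- character(0)   # gene|intron-index used by an event

  draw_psi <- function() {
    base <- runif(1, 0.25, 0.75)
    psi <- setNames(rep(base, length(stages)), stages)
    if (runif(1) < diff_frac && length(design$processes)) {
      pr <- design$processes[[sample.int(length(design$processes), 1)]]
      shift <- sample(c(-1, 1), 1) * runif(1, 0.2, 0.4)
      psi[pr[-1]] <- pmin(0.95, pmax(0.05, base + shift))
    }
    psi
  }
  emit_junction <- function(gm, d, a, reads_by_sample, clean = TRUE) {
    jrows[[length(jrows) + 1]] <<- data.frame(
      contig = gm$contig, donor0 = unname(d), acceptor0 = unname(a),
      sample = samples,
      reads = as.integer(reads_by_sample), clean_overhang = clean,
      stringsAsFactors = FALSE)
  }
  emit_region <- function(gm, s, e, cov_by_sample) {
    rrows[[length(rrows) + 1]] <<- data.frame(
      contig = gm$contig, start0 = unname(s), end0 = unname(e), sample = samples,
      mean_cov = as.numeric(cov_by_sample), stringsAsFactors = FALSE)
  }
  rep_counts <- function(psi) {
    # per-sample (inclusion, exclusion) draws at the sample's stage PSI
    p <- psi[design$sample_stage[samples]]
    inc <- rbinom(length(samples), coverage, p)
    list(inc = inc, exc = coverage - inc)
  }

  pick1 <- function(v) v[sample.int(length(v), 1)]   # sample(x, 1) misbehaves for scalar x
  pickable <- function(min_exons) {
    ok <- vapply(models, function(gm)
      nrow(gm$exons) >= min_exons && !gm$gene_id %in% used_genes, logical(1))
    names(models)[ok]
  }

  for (type in types) {
    for (rep_i in seq_len(n_events_per_type)) {
      min_ex <- switch(type, IR = 2, A5SS = 2, A3SS = 2, CE = 3, MXE = 4,
                       AFE = 2, ALE = 2, complex = 2)
      cand <- pickable(min_ex)
      if (type == "MXE") {
        cand <- Filter(function(g) nrow(models[[g]]$exons) >= 4, cand)
      }
      if (!length(cand)) {
        warning(sprintf("simulate_splicing: no gene available for type %s", type))
        next
      }
      gm <- models[[sample(cand, 1)]]
      ann <- gene_introns(gm); ex <- gm$exons; n <- nrow(ex)
      psi <- draw_psi()
      cc <- rep_counts(psi)
      region <- NULL
      ok <- TRUE
      switch(type,
        IR = {
          j <- sample.int(nrow(ann), 1)
          emit_junction(gm, ann[j, 1], ann[j, 2], cc$exc)
          emit_region(gm, ann[j, 1], ann[j, 2], cc$inc)
          used_introns <- c(used_introns, paste0(gm$gene_id, "|", j))
          region <- ann[j, ]
        },
        CE = {
          k <- pick1(2:(n - 1))         # skipped internal exon
          emit_junction(gm, ann[k - 1, 1], ann[k - 1, 2], cc$inc)
          emit_junction(gm, ann[k, 1], ann[k, 2], cc$inc)
          emit_junction(gm, ann[k - 1, 1], ann[k, 2], cc$exc)
          used_introns <- c(used_introns, paste0(gm$gene_id, "|", c(k - 1, k)))
          region <- ex[k, ]
        },
        MXE = {
          k <- pick1(2:(n - 2))         # exons k (A) and k+1 (B)
          emit_junction(gm, ex[k - 1, 2], ex[k, 1], cc$inc)       # into A
          emit_junction(gm, ex[k, 2], ex[k + 2, 1], cc$inc)       # A skips B
          emit_junction(gm, ex[k - 1, 2], ex[k + 1, 1], cc$exc)   # skip A into B
          emit_junction(gm, ex[k + 1, 2], ex[k + 2, 1], cc$exc)   # B onward
          used_introns <- c(used_introns,
                            paste0(gm$gene_id, "|", c(k - 1, k, k + 1)))
          region <- c(ex[k, 1], ex[k + 1, 2])
        },
        A5SS = ,
        A3SS = {
          # vary the genomic right end iff (A3SS on +) or (A5SS on -)
          vary_right <- (type == "A3SS") == (gm$strand == "+")
          j <- sample.int(nrow(ann), 1)
          ilen <- ann[j, 2] - ann[j, 1]
          delta <- pick1(9:min(30, ilen - 25))
          if (vary_right) {
            novel <- c(ann[j, 1], ann[j, 2] - delta)   # shorter intron
            region <- c(novel[2], ann[j, 2])
          } else {
            novel <- c(ann[j, 1] + delta, ann[j, 2])
            region <- c(ann[j, 1], novel[1])
          }
          # novel (shorter intron) is the inclusion isoform
          emit_junction(gm, novel[1], novel[2], cc$inc)
          emit_junction(gm, ann[j, 1], ann[j, 2], cc$exc)
          used_introns <- c(used_introns, paste0(gm$gene_id, "|", j))
        },
        AFE = ,
        ALE = {
          # novel terminal exon on the transcript 5' (AFE) or 3' (ALE) side
          left_side <- (type == "AFE") == (gm$strand == "+")
          off <- sample(40:120, 1)
          if (left_side) {
            d <- ex[1, 1] - off
            if (d < 0) { ok <- FALSE } else {
              emit_junction(gm, ann[1, 1], ann[1, 2], cc$inc)
              emit_junction(gm, d, ann[1, 2], cc$exc)
              used_introns <- c(used_introns, paste0(gm$gene_id, "|", 1))
              region <- c(d, ex[1, 1])
            }
          } else {
            a <- ex[n, 2] + off
            emit_junction(gm, ann[n - 1, 1], ann[n - 1, 2], cc$inc)
            emit_junction(gm, ann[n - 1, 1], a, cc$exc)
            used_introns <- c(used_introns, paste0(gm$gene_id, "|", n - 1))
            region <- c(ex[n, 2], a)
          }
        },
        complex = {
          # both ends novel, nested within one annotated intron's
          # neighbourhood (mid-exon donor and acceptor)
          j <- sample.int(nrow(ann), 1)
          exl <- ex[j, ]; exr <- ex[j + 1, ]
          d <- floor((exl[1] + exl[2]) / 2)
          a <- floor((exr[1] + exr[2]) / 2)
          emit_junction(gm, ann[j, 1], ann[j, 2], cc$inc)
          emit_junction(gm, d, a, cc$exc)
          used_introns <- c(used_introns, paste0(gm$gene_id, "|", j))
          region <- c(d, a)
        })
      if (!ok) {
        warning(sprintf("simulate_splicing: type %s not placeable in %s",
                        type, gm$gene_id))
        next
      }
      used_genes <- c(used_genes, gm$gene_id)
      tr <- data.frame(gene_id = gm$gene_id, as_type = type,
                       contig = gm$contig, start0 = unname(region[1]),
                       end0 = unname(region[2]), stringsAsFactors = FALSE)
      for (s in stages) tr[[paste0("psi_", s)]] <- unname(psi[s])
      truth[[length(truth) + 1]] <- tr
    }
  }

  # constitutive support for all annotated introns not used by events
  for (gm in models) {
    ann <- gene_introns(gm)
    for (j in seq_len(nrow(ann))) {
      if (paste0(gm$gene_id, "|", j) %in% used_introns) next
      emit_junction(gm, ann[j, 1], ann[j, 2],
                    rpois(length(samples), constitutive_cov))
    }
  }
  junctions <- rbind_rows(jrows)
  regions <- if (length(rrows))
    rbind_rows(rrows)
  else data.frame(contig = character(0), start0 = numeric(0),
                  end0 = numeric(0), sample = character(0),
                  mean_cov = numeric(0))
  truth <- rbind_rows(truth)
  fdrm_log("simulate_splicing: %d events planted", nrow(truth))
  list(junctions = junctions, regions = regions, truth = truth)
}
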