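#' Classify alternative-splicing events from junction evidence
#'
#' Compares observed splice-junction evidence (and intronic region coverage)
#' against single-isoform gene models and emits one event per detected
#' alternative, typed as one of: `IR` (intron retention), `A5SS`/`A3SS`
#' (alternative 5'/3' splice site, strand-resolved so the varying site is
#' named relative to the transcript), `CE` (cassette exon), `MXE` (mutually
#' exclusive exons), `AFE`/`ALE` (alternative first/last exon) or `complex`.
#'
#' Junctions lacking a clean overhang (mismatch/indel within 6 bases of the
#' junction) are excluded before counting. Junctions that cannot be assigned
#' to exactly one gene (intergenic, or overlapping several genes) are dropped
#' with a log entry; assignment allows a `flank` margin beyond the annotated
#' gene span so alternative terminal exons remain assignable.
#'
#' The inclusion isoform is, by convention: the intron-retaining form (IR),
#' the exon-including form (CE), the form using the proximal splice site and
#' hence retaining more exonic sequence (A5SS/A3SS), the genomically left
#' exon (MXE), and the annotated form (AFE/ALE/complex).
#'
#' @param gene_models named list of `gene_model`
#' @param junctions junction-evidence data.frame (see [read_junctions()])
#' @param region_counts optional region-coverage data.frame giving mean
#'   intronic coverage, required to detect intron retention
#' @param flank gene-assignment margin in nt (default 500)
#' @return an `as_events` object: `$events` (one row per event),
#'   `$inclusion`, `$exclusion` (raw event x sample count matrices) and
#'   `$junction_support` (max single-junction read count per event x sample)
#' @export
classify_as_events <- function(gene_models, junctions, region_counts = NULL,
                               flank = 500) {
  n_in <- nrow(junctions)
  junctions <- junctions[junctions$clean_overhang, , drop = FALSE]
  fdrm_log("classify_as_events: %d/%d junction rows clean", nrow(junctions), n_in)
  samples <- sort(unique(junctions$sample))
  jkey <- paste0(junctions$contig, ":", junctions$donor0, "-", junctions$acceptor0)
  keys <- unique(jkey)
  jc <- matrix(0, nrow = length(keys), ncol = length(samples),
               dimnames = list(keys, samples))
  agg <- tapply(junctions$reads, list(jkey, junctions$sample), sum)
  jc[rownames(agg), colnames(agg)] <- ifelse(is.na(agg), 0, agg)
  jinfo <- data.frame(key = keys,
                      contig = sub(":.*", "", keys),
                      donor0 = as.numeric(sub(".*:(\\d+)-.*", "\\1", keys)),
                      acceptor0 = as.numeric(sub(".*-", "", keys)),
                      stringsAsFactors = FALSE)

  # assign each junction to exactly one gene
  gid <- vapply(seq_len(nrow(jinfo)), function(i) {
    hits <- character(0)
    for (gm in gene_models) {
      if (gm$contig != jinfo$contig[i]) next
      sp <- gene_span(gm)
      if (jinfo$donor0[i] >= sp[1] - flank && jinfo$acceptor0[i] <= sp[2] + flank)
        hits <- c(hits, gm$gene_id)
    }
    if (length(hits) == 1) hits else NA_character_
  }, character(1))
  n_drop <- sum(is.na(gid))
  if (n_drop) fdrm_log("classify_as_events: %d junctions dropped (intergenic/ambiguous)", n_drop)
  jinfo$gene <- gid

  ev <- list(); inc <- list(); exc <- list(); jsup <- list()
  zero <- setNames(rep(0, length(samples)), samples)
  counts_of <- function(kset) {
    kset <- intersect(kset, keys)
    if (!length(kset)) return(zero)
    colSums(jc[kset, , drop = FALSE])
  }
  max_of <- function(kset) {
    kset <- intersect(kset, keys)
    if (!length(kset)) return(zero)
    apply(jc[kset, , drop = FALSE], 2, max)
  }
  add_event <- function(gm, type, s0, e0, inc_keys, exc_keys, n_inc, n_exc,
                        inc_counts = NULL, intron = c(NA, NA)) {
    id <- sprintf("%s|%s|%s:%d-%d", gm$gene_id, type, gm$contig, s0, e0)
    if (id %in% names(ev)) return(invisible(NULL))
    ev[[id]] <<- data.frame(event_id = id, gene_id = gm$gene_id,
                            contig = gm$contig, strand = gm$strand,
                            as_type = type, start0 = s0, end0 = e0,
                            intron_start0 = intron[1], intron_end0 = intron[2],
                            n_inc = n_inc, n_exc = n_exc, stringsAsFactors = FALSE)
    inc[[id]] <<- if (is.null(inc_counts)) counts_of(inc_keys) else inc_counts
    exc[[id]] <<- counts_of(exc_keys)
    jsup[[id]] <<- pmax(max_of(inc_keys), max_of(exc_keys))
    invisible(NULL)
  }

  for (gm in gene_models) {
    gj <- jinfo[!is.na(jinfo$gene) & jinfo$gene == gm$gene_id, , drop = FALSE]
    if (nrow(gj) == 0) next
    ex <- gm$exons; n <- nrow(ex)
    ann <- gene_introns(gm)
    ikey <- function(d, a) sprintf("%s:%d-%d", gm$contig, d, a)
    ann_keys <- if (nrow(ann)) ikey(ann[, 1], ann[, 2]) else character(0)
    obs <- setNames(rep(FALSE, nrow(gj)), gj$key)
    observed <- function(k) k %in% gj$key
    consumed <- character(0)

    # -- mutually exclusive exons: adjacent internal exon pairs (A, B) where
    #    both single-exon skip junctions are seen but A and B are never joined
    if (n >= 4) for (k in 2:(n - 2)) {
      skipA <- ikey(ex[k - 1, 2], ex[k + 1, 1])
      skipB <- ikey(ex[k, 2], ex[k + 2, 1])
      joinAB <- ikey(ex[k, 2], ex[k + 1, 1])
      if (observed(skipA) && observed(skipB) && !observed(joinAB)) {
        add_event(gm, "MXE", ex[k, 1], ex[k + 1, 2],
                  inc_keys = c(ikey(ex[k - 1, 2], ex[k, 1]), skipB),
                  exc_keys = c(skipA, ikey(ex[k + 1, 2], ex[k + 2, 1])),
                  n_inc = 2, n_exc = 2)
        consumed <- c(consumed, skipA, skipB)
      }
    }

    # -- exon skipping: junction from one annotated donor to a downstream
    #    annotated acceptor (single skip -> CE; multi-exon skip -> complex)
    if (nrow(ann) >= 2) {
      for (i in seq_len(nrow(gj))) {
        k <- gj$key[i]
        if (k %in% consumed || k %in% ann_keys) next
        jfrom <- match(gj$donor0[i], ann[, 1])
        jto <- match(gj$acceptor0[i], ann[, 2])
        if (is.na(jfrom) || is.na(jto) || jto <= jfrom) next
        inc_keys <- ann_keys[jfrom:jto]
        type <- if (jto == jfrom + 1) "CE" else "complex"
        add_event(gm, type, ex[jfrom + 1, 1], ex[jto, 2],
                  inc_keys = inc_keys, exc_keys = k,
                  n_inc = length(inc_keys), n_exc = 1)
        consumed <- c(consumed, k)
      }
    }

    # -- intron retention: annotated intron with spliced reads and intronic
    #    region coverage
    if (!is.null(region_counts) && nrow(ann)) {
      rc <- region_counts[region_counts$contig == gm$contig, , drop = FALSE]
      for (j in seq_len(nrow(ann))) {
        if (!observed(ann_keys[j])) next
        ov <- rc[rc$start0 < ann[j, 2] & rc$end0 > ann[j, 1], , drop = FALSE]
        if (nrow(ov) == 0 || sum(ov$mean_cov) <= 0) next
        cov <- zero
        ag <- tapply(ov$mean_cov, ov$sample, mean)
        cov[names(ag)] <- ag
        add_event(gm, "IR", ann[j, 1], ann[j, 2],
                  inc_keys = character(0), exc_keys = ann_keys[j],
                  n_inc = 1, n_exc = 1, inc_counts = cov,
                  intron = c(ann[j, 1], ann[j, 2]))
      }
    }

    # -- novel junctions sharing one end with the annotation
    for (i in seq_len(nrow(gj))) {
      k <- gj$key[i]
      if (k %in% consumed || k %in% ann_keys) next
      d <- gj$donor0[i]; a <- gj$acceptor0[i]
      share_d <- which(ann[, 1] == d)
      share_a <- which(ann[, 2] == a)
      if (length(share_a) == 1 && d < ex[1, 1]) {
        # alternative leftmost terminal exon
        type <- if (gm$strand == "+") "AFE" else "ALE"
        add_event(gm, type, d, ex[1, 1],
                  inc_keys = ann_keys[share_a], exc_keys = k, n_inc = 1, n_exc = 1)
        consumed <- c(consumed, k)
      } else if (length(share_d) == 1 && a > ex[n, 2]) {
        # alternative rightmost terminal exon
        type <- if (gm$strand == "+") "ALE" else "AFE"
        add_event(gm, type, ex[n, 2], a,
                  inc_keys = ann_keys[share_d], exc_keys = k, n_inc = 1, n_exc = 1)
        consumed <- c(consumed, k)
      } else if (length(share_d) == 1) {
        # shared donor (genomic left), acceptor varies: on '+' the varying
        # site is the transcript 3' splice site (A3SS); on '-' the 5' (A5SS)
        a_ann <- ann[share_d, 2]
        type <- if (gm$strand == "+") "A3SS" else "A5SS"
        inc_k <- if (a < a_ann) k else ann_keys[share_d]   # shorter intron includes more
        exc_k <- if (a < a_ann) ann_keys[share_d] else k
        add_event(gm, type, min(a, a_ann), max(a, a_ann),
                  inc_keys = inc_k, exc_keys = exc_k, n_inc = 1, n_exc = 1)
        consumed <- c(consumed, k)
      } else if (length(share_a) == 1) {
        d_ann <- ann[share_a, 1]
        type <- if (gm$strand == "+") "A5SS" else "A3SS"
        inc_k <- if (d > d_ann) k else ann_keys[share_a]
        exc_k <- if (d > d_ann) ann_keys[share_a] else k
        add_event(gm, type, min(d, d_ann), max(d, d_ann),
                  inc_keys = inc_k, exc_keys = exc_k, n_inc = 1, n_exc = 1)
        consumed <- c(consumed, k)
      }
    }

    # -- leftovers: both ends novel -> complex, against best-overlapping
    #    annotated intron
    for (i in seq_len(nrow(gj))) {
      k <- gj$key[i]
      if (k %in% consumed || k %in% ann_keys) next
      d <- gj$donor0[i]; a <- gj$acceptor0[i]
      best <- character(0)
      if (nrow(ann)) {
        ov <- pmin(ann[, 2], a) - pmax(ann[, 1], d)
        if (any(ov > 0)) best <- ann_keys[which.max(ov)]
      }
      add_event(gm, "complex", d, a, inc_keys = best, exc_keys = k,
                n_inc = max(1, length(best)), n_exc = 1)
    }
  }

  events <- rbind_rows(unname(ev))
  if (is.null(events)) {
    events <- data.frame(event_id = character(0), gene_id = character(0),
                         contig = character(0), strand = character(0),
                         as_type = character(0), start0 = numeric(0),
                         end0 = numeric(0), intron_start0 = numeric(0),
                         intron_end0 = numeric(0), n_inc = numeric(0),
                         n_exc = numeric(0))
    mat0 <- matrix(0, 0, length(samples), dimnames = list(NULL, samples))
    return(structure(list(events = events, inclusion = mat0, exclusion = mat0,
                          junction_support = mat0, samples = samples),
                     class = "as_events"))
  }
  o <- order(events$contig, events$start0, events$event_id)
  events <- events[o, , drop = FALSE]
  bindrows <- function(l) {
    m <- do.call(rbind, l)[o, , drop = FALSE]
    rownames(m) <- events$event_id
    m
  }
  structure(list(events = events, inclusion = bindrows(unname(inc)),
                 exclusion = bindrows(unname(exc)),
                 junction_support = bindrows(unname(jsup)), samples = samples),
            class = "as_events")
}

#' @export
print.as_events <- function(x, ...) {
  cat(sprintf("as_events: %d events (%s) across %d samples\n", nrow(x$events),
              paste(names(table(x$events$as_type)), table(x$events$as_type),
                    sep = ":", collapse = " "), length(x$samples)))
  invisible(x)
}

subset_events <- function(events, keep) {
  structure(list(events = events$events[keep, , drop = FALSE],
                 inclusion = events$inclusion[keep, , drop = FALSE],
                 exclusion = events$exclusion[keep, , drop = FALSE],
                 junction_support = events$junction_support[keep, , drop = FALSE],
                 samples = events$samples), class = "as_events")
}

# pooled per-stage raw counts for a count matrix (event x sample)
pool_by_stage <- function(m, design) {
  stages <- design$stages
  out <- matrix(0, nrow(m), length(stages),
                dimnames = list(rownames(m), stages))
  for (s in stages) {
    reps <- intersect(design$replicates[[s]], colnames(m))
    if (length(reps)) out[, s] <- rowSums(m[, reps, drop = FALSE])
  }
  out
}

#' Apply the evidence filters to classified AS events
#'
#' An event is retained iff there is at least one stage (replicates pooled)
#' where all of the following hold: at least `min_junction_reads` reads
#' support a junction of the event, total coverage exceeds `min_total_cov`
#' reads, and the minor isoform reaches `rare_min_expr` reads and an
#' abundance ratio above `rare_min_ratio`. Defaults are the standard 10-read
#' junction support, coverage > 25, and the rare-isoform rule (>= 5 reads and
#' > 5%). Filtering is idempotent.
#'
#' @param events an `as_events` object
#' @param design a `stage_design`
#' @param min_junction_reads,min_total_cov,rare_min_expr,rare_min_ratio
#'   thresholds as described
#' @return filtered `as_events`
#' @export
filter_as_events <- function(events, design, min_junction_reads = 10,
                             min_total_cov = 25, rare_min_expr = 5,
                             rare_min_ratio = 0.05) {
  if (nrow(events$events) == 0) return(events)
  inc <- pool_by_stage(events$inclusion, design)
  exc <- pool_by_stage(events$exclusion, design)
  jn <- pool_by_stage(events$junction_support, design)
  tot <- inc + exc
  minor <- pmin(inc, exc)
  ok <- jn >= min_junction_reads & tot > min_total_cov &
    minor >= rare_min_expr & (minor / pmax(tot, 1)) > rare_min_ratio
  keep <- rowSums(ok, na.rm = TRUE) > 0
  fdrm_log("filter_as_events: %d/%d retained", sum(keep), length(keep))
  subset_events(events, keep)
}

#' Percent spliced in (PSI) per stage
#'
#' Replicates are pooled within each stage; inclusion and exclusion counts
#' are each divided by their number of distinct supporting junction positions
#' (effective-length normalization) before the ratio
#' \eqn{PSI = inc/(inc + exc)}. For intron retention the inclusion evidence is
#' the mean intronic coverage and the exclusion evidence the spliced junction
#' reads. A stage with zero pooled evidence (or below `coverage_floor`) gets
#' `NA`, never 0.
#'
#' @param events an `as_events` object
#' @param design a `stage_design`
#' @param coverage_floor minimum raw pooled evidence for PSI to be defined
#' @return event x stage matrix of PSI values in [0, 1] (NA when undefined)
#' @export
compute_psi <- function(events, design, coverage_floor = 0) {
  inc <- pool_by_stage(events$inclusion, design) / events$events$n_inc
  exc <- pool_by_stage(events$exclusion, design) / events$events$n_exc
  raw <- pool_by_stage(events$inclusion, design) +
    pool_by_stage(events$exclusion, design)
  psi <- inc / (inc + exc)
  psi[raw == 0 | raw < coverage_floor] <- NA_real_
  psi
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional hypergeometric test; the two-sided p-value sums all table
#' probabilities not exceeding that of the observed table (with a 1e-7
#' relative tolerance against ties), matching the classical definition.
#'
#' @param a,b,c,d non-negative integer cell counts, rows = conditions,
#'   columns = isoforms
#' @return p-value in (0, 1]
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  x <- lo:hi
  probs <- dhyper(x, r1, r2, c1)
  p_obs <- probs[a - lo + 1]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Differential splicing between two stages
#'
#' Pools replicate inclusion/exclusion counts within each stage, computes
#' \eqn{\Delta PSI = PSI_A - PSI_B} (effective-length normalized) and a
#' two-sided Fisher exact p-value on the pooled raw 2x2 table (counts rounded
#' to integers). Events with undefined PSI in either stage are marked
#' untestable. Significance requires |dPSI| > 0.1, p < 0.05 and
#' Benjamini-Hochberg FDR < 0.05 across the tested events of the comparison.
#'
#' @param events an `as_events` object (normally after [filter_as_events()])
#' @param design a `stage_design`
#' @param stageA,stageB stage labels
#' @param dpsi_min,p_max,fdr_max significance thresholds
#' @return data.frame with one row per event
#' @export
differential_splicing <- function(events, design, stageA, stageB,
                                  dpsi_min = 0.1, p_max = 0.05, fdr_max = 0.05) {
  if (!all(c(stageA, stageB) %in% design$stages))
    stop_fdrm("fdrm_design_error", "stage not in design")
  psi <- compute_psi(events, design)
  inc <- round(pool_by_stage(events$inclusion, design))
  exc <- round(pool_by_stage(events$exclusion, design))
  n <- nrow(events$events)
  res <- data.frame(event_id = events$events$event_id,
                    as_type = events$events$as_type,
                    stageA = stageA, stageB = stageB,
                    psi_a = psi[, stageA], psi_b = psi[, stageB],
                    delta_psi = psi[, stageA] - psi[, stageB],
                    pvalue = NA_real_, fdr = NA_real_,
                    testable = !is.na(psi[, stageA]) & !is.na(psi[, stageB]),
                    significant = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  for (i in seq_len(n)) {
    if (!res$testable[i]) next
    res$pvalue[i] <- fisher_exact_2x2(inc[i, stageA], exc[i, stageA],
                                      inc[i, stageB], exc[i, stageB])
  }
  res$fdr[res$testable] <- bh_adjust(res$pvalue[res$testable])
  res$significant <- res$testable & !is.na(res$delta_psi) &
    abs(res$delta_psi) > dpsi_min & res$pvalue < p_max & res$fdr < fdr_max
  res
}

#' Differential splicing over a set of stage pairs
#'
#' @param events an `as_events` object
#' @param design a `stage_design`
#' @param pairs data.frame with columns `stageA`, `stageB` and optionally
#'   `process` (default: all within-process pairs of the design)
#' @param ... passed to [differential_splicing()]
#' @return combined data.frame with a `process` column when provided
#' @export
differential_splicing_all <- function(events, design,
                                      pairs = process_stage_pairs(design), ...) {
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- differential_splicing(events, design, pairs$stageA[i], pairs$stageB[i], ...)
    if ("process" %in% names(pairs)) r$process <- pairs$process[i]
    r
  })
  rbind_rows(out)
}

#' Process-specific differential splicing
#'
#' Labels an event process-specific when it is significantly differentially
#' spliced in at least one stage-pair comparison of exactly one developmental
#' process.
#'
#' @param diff combined results from [differential_splicing_all()]; each row
#'   must carry `event_id`, `stageA`, `stageB`, `significant`
#' @param design a `stage_design`
#' @return data.frame with `event_id`, `processes` (comma-joined) and
#'   `specific_process` (NA unless exactly one)
#' @export
process_specific_events <- function(diff, design) {
  proc_of_pair <- function(sa, sb) {
    names(Filter(function(p) sa %in% p && sb %in% p, design$processes))
  }
  ids <- unique(diff$event_id)
  out <- lapply(ids, function(id) {
    d <- diff[diff$event_id == id & diff$significant %in% TRUE, , drop = FALSE]
    procs <- unique(unlist(mapply(proc_of_pair, d$stageA, d$stageB,
                                  SIMPLIFY = FALSE)))
    data.frame(event_id = id,
               processes = paste(sort(procs), collapse = ","),
               specific_process = if (length(procs) == 1) procs else NA_character_,
               stringsAsFactors = FALSE)
  })
  rbind_rows(out)
}
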