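#' Nine-stage developmental design
#'
#' Builds the stage/replicate layout used throughout the pipeline. The default
#' is the nine developmental stages of the mushroom life cycle — basidiospores
#' (BS), half-germinated (BS12h) and fully germinated (BS24h) spores,
#' vegetative mycelia (Myc), oidia-forming (Oidia) and sclerotia-forming (Scl)
#' mycelia, hyphal knots (Knot), primordia (Pri) and young fruiting bodies
#' (YFB) — with three biological replicates each, grouped into five
#' developmental processes:
#' germination (BS, BS12h, BS24h), oidiation (Myc, Oidia),
#' sclerotia (Myc, Scl), fruiting (Myc, Knot, Pri) and
#' sporulation (Pri, YFB, BS).
#'
#' @param stages ordered character vector of stage labels
#' @param n_reps replicates per stage (default 3)
#' @param processes named list mapping process name to an ordered subset of
#'   `stages`; the default five processes are only constructed when `stages`
#'   contains all stages they reference
#' @return an object of class `stage_design` with elements `stages`,
#'   `replicates` (named list stage -> sample ids), `samples`, `sample_stage`
#'   (named vector sample -> stage) and `processes`
#' @export
#' @examples
#' d <- stage_design()
#' d$replicates$Scl
stage_design <- function(stages = c("BS", "BS12h", "BS24h", "Myc", "Oidia",
                                    "Scl", "Knot", "Pri", "YFB"),
                         n_reps = 3,
                         processes = NULL) {
  stopifnot(length(stages) >= 1, !anyDuplicated(stages), n_reps >= 1)
  if (is.null(processes)) {
    default <- list(
      germination = c("BS", "BS12h", "BS24h"),
      oidiation   = c("Myc", "Oidia"),
      sclerotia   = c("Myc", "Scl"),
      fruiting    = c("Myc", "Knot", "Pri"),
      sporulation = c("Pri", "YFB", "BS")
    )
    processes <- Filter(function(p) all(p %in% stages), default)
  } else {
    ok <- vapply(processes, function(p) all(p %in% stages), logical(1))
    if (!all(ok)) stop_fdrm("fdrm_design_error", "process references unknown stage")
  }
  replicates <- lapply(stages, function(s) paste(s, seq_len(n_reps), sep = "_"))
  names(replicates) <- stages
  samples <- unlist(replicates, use.names = FALSE)
  sample_stage <- rep(stages, each = n_reps)
  names(sample_stage) <- samples
  structure(list(stages = stages, replicates = replicates, samples = samples,
                 sample_stage = sample_stage, processes = processes),
            class = "stage_design")
}

#' @export
print.stage_design <- function(x, ...) {
  cat(sprintf("stage_design: %d stages x %d replicates, %d processes\n",
              length(x$stages), length(x$replicates[[1]]), length(x$processes)))
  invisible(x)
}

#' All within-process stage pairs
#'
#' Enumerates the unordered stage pairs inside each developmental process;
#' these are the comparisons used to call process-specific events.
#'
#' @param design a `stage_design`
#' @return data.frame with columns `process`, `stageA`, `stageB`
#' @export
process_stage_pairs <- function(design) {
  stopifnot(inherits(design, "stage_design"))
  out <- list()
  for (p in names(design$processes)) {
    st <- design$processes[[p]]
    if (length(st) < 2) next
    cmb <- utils::combn(st, 2)
    out[[p]] <- data.frame(process = p, stageA = cmb[1, ], stageB = cmb[2, ],
                           stringsAsFactors = FALSE)
  }
  rbind_rows(out)
}

stage_of_samples <- function(design, samples) {
  st <- design$sample_stage[samples]
  if (anyNA(st)) stop_fdrm("fdrm_design_error", "sample not in design")
  st
}
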