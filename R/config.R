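#' Run configuration for the screening / DMR-calling pipeline
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Defaults follow the published analysis settings: an expression ratio of 5
#' with an expression floor of 1 TPM/FPKM for the specificity screen, an
#' absolute methylation difference of 0.35 for DMR attribution (0.20 in the
#' relaxed mode), and a 2 kb promoter window for TSS-relative classification.
#'
#' @param ratio_threshold Minimum expression ratio (target vs. reference
#'   central tendency) for a preferential-expression call. Must be > 1.
#' @param expression_floor Minimum expression (TPM or FPKM) of the target
#'   context for any preferential call.
#' @param dmr_delta Minimum absolute per-CpG methylation difference
#'   (target mean - panel mean) for DMR candidacy; in (0, 1]. The standard
#'   threshold is 0.35; the relaxed mode uses 0.20.
#' @param min_cpgs Minimum number of member CpGs in a DMR.
#' @param max_gap_bp Maximum genomic distance (bp) between consecutive member
#'   CpGs of a DMR or LMR run.
#' @param promoter_window_bp Promoter window W: the span on each side of the
#'   TSS used to classify DMRs as promoter-proximal.
#' @param intergenic_horizon_bp Maximum |TSS distance| for a DMR to be
#'   assigned to a gene as `intergenic_near`; farther DMRs stay unassigned.
#' @param lmr_min_run Minimum number of consecutive low CpGs in an LMR.
#' @param lmr_cpg_ceiling Maximum methylation fraction of every member CpG
#'   of an LMR.
#' @param lmr_baseline_margin An LMR's mean methylation must be at least this
#'   far below the genome-wide mean of the same sample.
#' @param brain_central_tendency Central tendency used for the other-brain
#'   denominator of the cerebellum call (`"median"`, the Methods convention,
#'   or `"mean"`).
#' @param nonbrain_central_tendency Central tendency for the non-brain
#'   denominator (`"mean"` or `"median"`).
#' @param min_coverage Minimum read coverage for a CpG to enter the delta
#'   series; only applied to tracks that carry a coverage column.
#' @param rng_seed Optional integer seed recorded with the run.
#'
#' @return A list of class `"ms_config"`.
#' @examples
#' cfg <- run_config()
#' relaxed <- run_config(dmr_delta = 0.20)
#' @export
run_config <- function(ratio_threshold = 5,
                       expression_floor = 1,
                       dmr_delta = 0.35,
                       min_cpgs = 3,
                       max_gap_bp = 250,
                       promoter_window_bp = 2000,
                       intergenic_horizon_bp = 25000,
                       lmr_min_run = 5,
                       lmr_cpg_ceiling = 0.5,
                       lmr_baseline_margin = 0.3,
                       brain_central_tendency = c("median", "mean"),
                       nonbrain_central_tendency = c("mean", "median"),
                       min_coverage = 0,
                       rng_seed = NULL) {
  brain_central_tendency <- match.arg(brain_central_tendency)
  nonbrain_central_tendency <- match.arg(nonbrain_central_tendency)
  stopifnot(is.numeric(ratio_threshold), length(ratio_threshold) == 1L)
  if (ratio_threshold <= 1)
    stop("ratio_threshold must be > 1")
  if (dmr_delta <= 0 || dmr_delta > 1)
    stop("dmr_delta must lie in (0, 1]")
  if (promoter_window_bp < 0)
    stop("promoter_window_bp must be >= 0")
  if (expression_floor < 0)
    stop("expression_floor must be >= 0")
  if (min_cpgs < 1 || lmr_min_run < 1)
    stop("min_cpgs and lmr_min_run must be >= 1")
  if (max_gap_bp < 1)
    stop("max_gap_bp must be >= 1")
  if (lmr_cpg_ceiling < 0 || lmr_cpg_ceiling > 1)
    stop("lmr_cpg_ceiling must lie in [0, 1]")
  structure(list(
    ratio_threshold = as.numeric(ratio_threshold),
    expression_floor = as.numeric(expression_floor),
    dmr_delta = as.numeric(dmr_delta),
    min_cpgs = as.integer(min_cpgs),
    max_gap_bp = as.integer(max_gap_bp),
    promoter_window_bp = as.integer(promoter_window_bp),
    intergenic_horizon_bp = as.integer(intergenic_horizon_bp),
    lmr_min_run = as.integer(lmr_min_run),
    lmr_cpg_ceiling = as.numeric(lmr_cpg_ceiling),
    lmr_baseline_margin = as.numeric(lmr_baseline_margin),
    brain_central_tendency = brain_central_tendency,
    nonbrain_central_tendency = nonbrain_central_tendency,
    min_coverage = as.numeric(min_coverage),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  ), class = "ms_config")
}

#' Read a run configuration from a DCF text file
#'
#' The file uses `Field: value` lines (Debian-control format, as read by
#' [read.dcf()]); any field of [run_config()] may appear. Unknown fields are
#' an error. Values given in `overrides` (e.g. parsed CLI flags) take
#' precedence over the file.
#'
#' @param path Path to the configuration file.
#' @param overrides Named list of config values that override the file.
#' @return An `"ms_config"` object.
#' @export
read_run_config <- function(path, overrides = list()) {
  fields <- list()
  if (!is.null(path)) {
    m <- read.dcf(path)
    if (nrow(m) != 1L)
      stop("config file must contain exactly one record: ", path)
    fields <- as.list(m[1L, ])
    known <- names(formals(run_config))
    bad <- setdiff(names(fields), known)
    if (length(bad))
      stop("unknown config field(s): ", paste(bad, collapse = ", "))
    numeric_fields <- setdiff(known,
      c("brain_central_tendency", "nonbrain_central_tendency"))
    for (nm in intersect(names(fields), numeric_fields))
      fields[[nm]] <- as.numeric(fields[[nm]])
  }
  fields[names(overrides)] <- overrides
  do.call(run_config, fields)
}

#' @export
print.ms_config <- function(x, ...) {
  cat("methylscreen run configuration\n")
  for (nm in names(x))
    cat(sprintf("  %-26s %s\n", nm,
                if (is.null(x[[nm]])) "NULL" else format(x[[nm]])))
  invisible(x)
}
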