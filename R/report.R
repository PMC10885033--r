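#' Percentage with half-up rounding
#'
#' Computes `100 * numerator / denominator` rounded half-up to the given
#' number of decimals (3.047 -> 3.0 at one decimal; 4.739 -> 5 at zero),
#' matching the convention used for set-vs-universe (one decimal) and
#' intersection-vs-set (nearest integer) figures.
#'
#' @param numerator,denominator Non-negative counts; `denominator` must be
#'   positive.
#' @param decimals Number of decimals to keep.
#' @return The rounded percentage as a plain number.
#' @examples
#' percent(422, 13847, 1)  # 3.0
#' percent(20, 422, 0)     # 5
#' @export
percent <- function(numerator, denominator, decimals = 1) {
  if (denominator <= 0) stop("denominator must be > 0")
  x <- 100 * numerator / denominator
  f <- 10^decimals
  # half-up, with a tiny epsilon so values like 2.5 stored as 2.4999... round up
  floor(x * f + 0.5 + 1e-9) / f
}

#' Assemble a screen report
#'
#' Collects the headline numbers of one run — universe size, per-context
#' preferential set sizes with percentages of the universe, the dual
#' intersection with its percentage of the first set, the per-culture
#' overlap matrix, and (when per-gene summaries are supplied) the count of
#' genes associated with at least one DMR. Gene lists are sorted so the
#' report is deterministic.
#'
#' @param universe Character vector: the filtered gene universe.
#' @param myob_set,cbl_set Preferential sets (character vectors).
#' @param dual_set Their intersection (from [intersect_dual()]).
#' @param overlap Optional data.frame from [overlap_matrix()].
#' @param summaries Optional per-gene summaries (see
#'   [summarize_epigenetics()]); enables `n_genes_with_dmrs`.
#' @param config The [run_config()] of the run (recorded for provenance).
#' @return A list of class `"screen_report"`.
#' @export
build_report <- function(universe, myob_set, cbl_set, dual_set,
                         overlap = NULL, summaries = NULL,
                         config = run_config()) {
  if (length(setdiff(c(myob_set, cbl_set), universe)))
    stop("preferential sets contain genes outside the universe")
  rep <- list(
    universe_size = length(universe),
    n_myob = length(myob_set),
    n_cbl = length(cbl_set),
    n_dual = length(dual_set),
    pct_myob = percent(length(myob_set), length(universe), 1),
    pct_cbl = percent(length(cbl_set), length(universe), 1),
    pct_dual_of_myob = if (length(myob_set))
      percent(length(dual_set), length(myob_set), 0) else 0,
    myob_genes = sort(myob_set),
    cbl_genes = sort(cbl_set),
    dual_genes = sort(dual_set),
    overlap = overlap,
    n_genes_with_dmrs = if (!is.null(summaries))
      count_genes_with_dmrs(summaries) else NA_integer_,
    n_summarized = if (!is.null(summaries)) nrow(summaries) else NA_integer_,
    config = config)
  class(rep) <- "screen_report"
  rep
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("Gene universe: %d genes\n", x$universe_size))
  cat(sprintf("Myoblast-preferential: %d (%.1f%%)\n", x$n_myob, x$pct_myob))
  cat(sprintf("Cerebellum-preferential: %d (%.1f%%)\n", x$n_cbl, x$pct_cbl))
  cat(sprintf("Dual (both contexts): %d (~%d%% of the myoblast set)\n",
              x$n_dual, as.integer(x$pct_dual_of_myob)))
  if (!is.null(x$overlap)) {
    cat("Per-culture overlap with the cerebellum set:\n")
    for (i in seq_len(nrow(x$overlap)))
      cat(sprintf("  %-10s %4d preferential, %4d also cerebellum\n",
                  x$overlap$culture[i], x$overlap$n_preferential[i],
                  x$overlap$n_overlap[i]))
  }
  if (!is.na(x$n_genes_with_dmrs))
    cat(sprintf("Genes with >= 1 DMR: %d of %d\n",
                x$n_genes_with_dmrs, x$n_summarized))
  invisible(x)
}

#' Write a screen report as TSV key-value pairs plus gene lists
#'
#' @param report A `"screen_report"`.
#' @param path Output TSV path for the scalar summary; gene lists go to
#'   `<path>.genes.tsv`.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  scalars <- data.frame(
    key = c("universe_size", "n_myob", "n_cbl", "n_dual", "pct_myob",
            "pct_cbl", "pct_dual_of_myob", "n_genes_with_dmrs"),
    value = c(report$universe_size, report$n_myob, report$n_cbl,
              report$n_dual, report$pct_myob, report$pct_cbl,
              report$pct_dual_of_myob, report$n_genes_with_dmrs))
  write_table(scalars, path)
  lists <- rbind(
    data.frame(set = "myob", gene_id = report$myob_genes),
    data.frame(set = "cbl", gene_id = report$cbl_genes),
    data.frame(set = "dual", gene_id = report$dual_genes))
  write_table(lists, paste0(path, ".genes.tsv"))
  invisible(path)
}

#' Write a screen report as human-readable markdown
#'
#' @param report A `"screen_report"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_md <- function(report, path) {
  ln <- c(
    "# Preferential-expression screen report", "",
    sprintf("- Gene universe: **%d** genes", report$universe_size),
    sprintf("- Myoblast-preferential: **%d** (%.1f%% of the universe)",
            report$n_myob, report$pct_myob),
    sprintf("- Cerebellum-preferential: **%d** (%.1f%% of the universe)",
            report$n_cbl, report$pct_cbl),
    sprintf("- Preferential in both: **%d** (~%d%% of the myoblast set)",
            report$n_dual, as.integer(report$pct_dual_of_myob)))
  if (!is.null(report$overlap)) {
    ln <- c(ln, "", "| culture | preferential | also cerebellum |",
            "|---|---|---|",
            sprintf("| %s | %d | %d |", report$overlap$culture,
                    report$overlap$n_preferential, report$overlap$n_overlap))
  }
  if (!is.na(report$n_genes_with_dmrs))
    ln <- c(ln, "",
            sprintf("- Genes associated with at least one DMR: **%d** of %d",
                    report$n_genes_with_dmrs, report$n_summarized))
  cfg <- report$config
  ln <- c(ln, "",
          sprintf("Thresholds: ratio >= %g, floor >= %g, DMR delta >= %g.",
                  cfg$ratio_threshold, cfg$expression_floor, cfg$dmr_delta))
  writeLines(ln, path)
  invisible(path)
}
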