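#' Classify DMRs relative to one gene's TSS
#'
#' Distances are signed and strand-aware: measured from the TSS to the
#' nearest DMR edge, positive downstream of the TSS in the direction of
#' transcription, negative upstream, 0 for a DMR overlapping the TSS.
#' Classes, in precedence order:
#'
#' * `promoter_downstream` — DMR overlaps the W bp immediately downstream
#'   of the TSS;
#' * `promoter_upstream` — DMR overlaps the W bp immediately upstream;
#' * `intragenic` — DMR overlaps the gene body beyond the promoter window;
#' * `intergenic_near` — otherwise, within the intergenic horizon
#'   (25 kb by default) of the TSS;
#' * `NA` — farther than the horizon (unassigned).
#'
#' The precedence makes the classification a partition: each DMR-gene pair
#' receives exactly one class.
#'
#' @param dmrs DMR table (rows on the gene's chromosome).
#' @param gene A single-row [gene_annotation()].
#' @param config A [run_config()] (promoter window W, intergenic horizon).
#' @return Data.frame with one row per DMR: `location_class`,
#'   `tss_distance`.
#' @export
classify_dmr_location <- function(dmrs, gene, config = run_config()) {
  stopifnot(nrow(gene) == 1L)
  if (nrow(dmrs) && any(dmrs$chrom != gene$chrom))
    stop("DMR on a different chromosome than the gene")
  W <- config$promoter_window_bp
  tss <- gene$tss
  plus <- gene$strand == "+"
  # signed distance from the TSS to the nearest DMR edge (half-open
  # interval boundaries; 0 if the DMR covers the TSS). A DMR ending 1 kb
  # before a plus-strand TSS is at -1000; mirroring all coordinates and
  # flipping the strand preserves both class and distance exactly.
  dist <- if (plus) {
    ifelse(dmrs$start <= tss & tss < dmrs$end, 0L,
           ifelse(dmrs$start > tss, dmrs$start - tss, dmrs$end - tss))
  } else {
    ifelse(dmrs$start <= tss & tss < dmrs$end, 0L,
           ifelse(dmrs$end <= tss, tss + 1L - dmrs$end,
                  tss + 1L - dmrs$start))
  }
  ovl <- function(s, e) pmax(dmrs$start, s) < pmin(dmrs$end, e)
  if (plus) {
    in_down <- ovl(tss, tss + W)
    in_up <- ovl(tss - W, tss)
  } else {
    in_down <- ovl(tss + 1L - W, tss + 1L)
    in_up <- ovl(tss + 1L, tss + 1L + W)
  }
  in_body <- ovl(gene$start, gene$end)
  cls <- ifelse(in_down, "promoter_downstream",
         ifelse(in_up, "promoter_upstream",
         ifelse(in_body, "intragenic",
         ifelse(abs(dist) <= config$intergenic_horizon_bp,
                "intergenic_near", NA_character_))))
  data.frame(location_class = cls, tss_distance = as.integer(dist),
             stringsAsFactors = FALSE)
}

#' Assign each DMR to its nearest gene and classify its location
#'
#' Nearest-gene assignment by absolute signed TSS distance, ties broken by
#' lexicographic gene id; DMRs farther than the intergenic horizon from
#' every TSS remain unassigned (`gene_id` NA).
#'
#' @param dmrs DMR table.
#' @param annotation A [gene_annotation()].
#' @param config A [run_config()].
#' @return The DMR table with added `gene_id`, `location_class`,
#'   `tss_distance` columns.
#' @export
assign_dmrs_to_genes <- function(dmrs, annotation, config = run_config()) {
  n <- nrow(dmrs)
  dmrs$gene_id <- rep(NA_character_, n)
  dmrs$location_class <- rep(NA_character_, n)
  dmrs$tss_distance <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    cand <- annotation[annotation$chrom == dmrs$chrom[i], , drop = FALSE]
    if (!nrow(cand)) next
    res <- do.call(rbind, lapply(seq_len(nrow(cand)), function(k)
      classify_dmr_location(dmrs[i, , drop = FALSE],
                            cand[k, , drop = FALSE], config)))
    res$gene_id <- cand$gene_id
    res <- res[!is.na(res$location_class), , drop = FALSE]
    if (!nrow(res)) next
    res <- res[order(abs(res$tss_distance), res$gene_id), , drop = FALSE]
    dmrs$gene_id[i] <- res$gene_id[1L]
    dmrs$location_class[i] <- res$location_class[1L]
    dmrs$tss_distance[i] <- res$tss_distance[1L]
  }
  dmrs
}

.location_classes <- c("promoter_upstream", "promoter_downstream",
                       "intragenic", "intergenic_near")

#' Summarize one gene's differential-methylation landscape
#'
#' Tallies the DMRs assigned to the gene by direction and TSS-relative
#' location class, and sets promoter flags when a hypo- or hypermethylated
#' DMR falls in either promoter window. Optionally counts LMRs overlapping
#' the promoter region (`tss +- W`).
#'
#' @param gene A single-row [gene_annotation()].
#' @param dmrs DMR table already assigned to genes
#'   (see [assign_dmrs_to_genes()]); only rows with this `gene_id` count.
#' @param lmrs Optional LMR table.
#' @param config A [run_config()].
#' @return One-row data.frame: `gene_id`, `n_hypo`, `n_hyper`, one count
#'   per location class, `has_promoter_hypom`, `has_promoter_hyperm`, and
#'   `n_promoter_lmrs` when `lmrs` is given.
#' @export
summarize_gene_epigenetics <- function(gene, dmrs, lmrs = NULL,
                                       config = run_config()) {
  stopifnot(nrow(gene) == 1L)
  d <- dmrs[!is.na(dmrs$gene_id) & dmrs$gene_id == gene$gene_id, ,
            drop = FALSE]
  prom <- c("promoter_upstream", "promoter_downstream")
  out <- data.frame(gene_id = gene$gene_id,
                    n_hypo = sum(d$direction == "hypo"),
                    n_hyper = sum(d$direction == "hyper"),
                    stringsAsFactors = FALSE)
  for (cl in .location_classes)
    out[[paste0("n_", cl)]] <- sum(d$location_class == cl)
  out$has_promoter_hypom <- any(d$direction == "hypo" &
                                  d$location_class %in% prom)
  out$has_promoter_hyperm <- any(d$direction == "hyper" &
                                   d$location_class %in% prom)
  if (!is.null(lmrs)) {
    W <- config$promoter_window_bp
    out$n_promoter_lmrs <- sum(
      lmrs$chrom == gene$chrom &
        pmax(lmrs$start, gene$tss - W) < pmin(lmrs$end, gene$tss + W + 1L))
  }
  out
}

#' Per-gene epigenetic summaries for a whole annotation
#'
#' Convenience wrapper: assigns DMRs to genes, then summarizes every gene.
#'
#' @param annotation A [gene_annotation()].
#' @param dmrs DMR table (unassigned is fine).
#' @param lmrs Optional LMR table.
#' @param config A [run_config()].
#' @return Data.frame with one row per gene (see
#'   [summarize_gene_epigenetics()]).
#' @export
summarize_epigenetics <- function(annotation, dmrs, lmrs = NULL,
                                  config = run_config()) {
  if (is.null(dmrs$gene_id))
    dmrs <- assign_dmrs_to_genes(dmrs, annotation, config)
  out <- do.call(rbind, lapply(seq_len(nrow(annotation)), function(k)
    summarize_gene_epigenetics(annotation[k, , drop = FALSE], dmrs, lmrs,
                               config)))
  rownames(out) <- NULL
  out
}

#' Build minimal summaries from published per-gene DMR counts
#'
#' Adapter for external tables that report only hypo-/hypermethylated DMR
#' counts per gene (no coordinates), e.g. a transcribed publication table.
#'
#' @param counts Data.frame with columns `gene_id`, `n_hypo`, `n_hyper`.
#' @return A summaries data.frame usable by [count_genes_with_dmrs()].
#' @export
summaries_from_counts <- function(counts) {
  stopifnot(all(c("gene_id", "n_hypo", "n_hyper") %in% names(counts)))
  data.frame(gene_id = as.character(counts$gene_id),
             n_hypo = as.integer(counts$n_hypo),
             n_hyper = as.integer(counts$n_hyper),
             stringsAsFactors = FALSE)
}

#' Count genes associated with at least one DMR
#'
#' @param summaries Per-gene summaries (needs `n_hypo`, `n_hyper`).
#' @return Integer count of genes with `n_hypo + n_hyper >= 1`.
#' @export
count_genes_with_dmrs <- function(summaries) {
  sum(summaries$n_hypo + summaries$n_hyper >= 1L)
}

#' Any-overlap interval lookup (half-open semantics)
#'
#' A query overlaps a track interval iff `max(starts) < min(ends)`. Backed
#' by `GenomicRanges::findOverlaps`.
#'
#' @param queries Data.frame with `chrom`, `start`, `end`.
#' @param track Data.frame with `chrom`, `start`, `end` (e.g. a chromatin
#'   state BED read elsewhere).
#' @return A list, one integer vector of `track` row indices per query row.
#' @export
overlap_intervals <- function(queries, track) {
  if (!nrow(queries)) return(list())
  if (!nrow(track))
    return(rep(list(integer(0)), nrow(queries)))
  gr_q <- GenomicRanges::GRanges(
    queries$chrom, IRanges::IRanges(queries$start + 1L, queries$end))
  gr_t <- GenomicRanges::GRanges(
    track$chrom, IRanges::IRanges(track$start + 1L, track$end))
  hits <- GenomicRanges::findOverlaps(gr_q, gr_t)
  out <- rep(list(integer(0)), nrow(queries))
  qh <- S4Vectors::queryHits(hits); th <- S4Vectors::subjectHits(hits)
  for (i in seq_along(qh))
    out[[qh[i]]] <- c(out[[qh[i]]], th[i])
  lapply(out, sort)
}
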