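#' Per-CpG methylation difference between target replicates and a panel
#'
#' Restricts to CpGs present in every target and every panel track (after
#' per-track coverage filtering, for tracks that carry coverage) and
#' computes, per CpG, the unweighted mean of the target fractions minus the
#' unweighted mean of the panel fractions.
#'
#' @param target_tracks List of [methylome_track()] replicates (>= 1).
#' @param panel_tracks List of reference-panel tracks (>= 1).
#' @param min_coverage Minimum coverage for a CpG to be retained in a
#'   track; ignored for tracks without a coverage column.
#' @return A data.frame sorted by (chrom, pos): `chrom`, `pos`, `delta`,
#'   `target_mean`, `panel_mean`.
#' @export
per_cpg_delta <- function(target_tracks, panel_tracks, min_coverage = 0) {
  if (!length(target_tracks) || !length(panel_tracks))
    stop("need at least one target and one panel track")
  if (inherits(target_tracks, "data.frame")) target_tracks <- list(target_tracks)
  if (inherits(panel_tracks, "data.frame")) panel_tracks <- list(panel_tracks)
  prep <- function(tr) {
    df <- as.data.frame(tr)
    if (min_coverage > 0 && !is.null(df$coverage))
      df <- df[df$coverage >= min_coverage, , drop = FALSE]
    df$key <- paste(df$chrom, df$pos, sep = ":")
    df
  }
  tlist <- lapply(target_tracks, prep)
  plist <- lapply(panel_tracks, prep)
  common <- Reduce(intersect, lapply(c(tlist, plist), `[[`, "key"))
  if (!length(common)) stop("no CpGs common to all tracks")
  meth_at <- function(df) df$meth[match(common, df$key)]
  tmat <- vapply(tlist, meth_at, numeric(length(common)))
  pmat <- vapply(plist, meth_at, numeric(length(common)))
  if (length(common) == 1L) { tmat <- rbind(tmat); pmat <- rbind(pmat) }
  tmean <- rowMeans(tmat); pmean <- rowMeans(pmat)
  ref <- tlist[[1L]][match(common, tlist[[1L]]$key), c("chrom", "pos")]
  out <- data.frame(chrom = ref$chrom, pos = ref$pos,
                    delta = tmean - pmean,
                    target_mean = tmean, panel_mean = pmean,
                    stringsAsFactors = FALSE)
  # per-replicate deltas support the optional strict consistency mode
  for (i in seq_len(ncol(tmat)))
    out[[paste0("delta_rep", i)]] <- tmat[, i] - pmean
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Maximal qualifying runs over one chromosome's candidate/sign/gap
# structure. A run is broken by any evaluated CpG that is not a candidate
# of the same sign, or by a gap > max_gap_bp between consecutive members.
.segment_runs <- function(pos, ok, sgn, max_gap_bp, min_len) {
  n <- length(pos)
  if (!n) return(integer(0))
  # run id changes where: previous CpG not a same-sign candidate, or gap too big
  new_run <- ok & c(TRUE,
                    !(ok[-n] & sgn[-1] == sgn[-n] &
                      (pos[-1] - pos[-n]) <= max_gap_bp))
  run_id <- integer(n)
  run_id[ok] <- cumsum(new_run)[ok]
  run_id
}

#' Call DMRs from a per-CpG delta series by threshold segmentation
#'
#' Candidate CpGs have `|delta| >= dmr_delta` (inclusive: a delta of
#' exactly 0.35 qualifies at the standard threshold). A DMR is a maximal
#' run of sign-consistent candidates in which consecutive members are at
#' most `max_gap_bp` apart and which contains at least `min_cpgs` members;
#' any intervening evaluated CpG of the opposite sign or below threshold
#' breaks the run. Output intervals span the first member CpG to the last
#' member CpG + 1 and are sorted and non-overlapping.
#'
#' @param delta_series Data.frame from [per_cpg_delta()] (needs `chrom`,
#'   `pos`, `delta`; `delta_rep*` columns enable the strict mode).
#' @param config A [run_config()]; `dmr_delta = 0.20` gives the relaxed
#'   mode.
#' @param strict_replicates If `TRUE`, a called DMR is additionally
#'   required to have every target replicate's run-mean delta agree with
#'   the run direction at magnitude >= `dmr_delta / 2`; DMRs driven by a
#'   single aberrant replicate are dropped. Needs the `delta_rep*`
#'   columns that [per_cpg_delta()] emits.
#' @return A DMR table: `chrom`, `start`, `end`, `direction`
#'   (`hypo`/`hyper`), `n_cpgs`, `mean_delta`.
#' @examples
#' cfg <- run_config()
#' s <- data.frame(chrom = "chr1", pos = seq(0, 90, 10),
#'                 delta = c(0, rep(0.75, 8), 0))
#' call_dmrs(s, cfg)  # one hyper DMR over the 8 high CpGs
#' @export
call_dmrs <- function(delta_series, config = run_config(),
                      strict_replicates = FALSE) {
  if (!nrow(delta_series)) return(new_dmr_table())
  rep_cols <- grep("^delta_rep", names(delta_series), value = TRUE)
  if (strict_replicates && !length(rep_cols))
    stop("strict_replicates needs the delta_rep* columns from per_cpg_delta()")
  out <- new_dmr_table()
  for (ch in unique(delta_series$chrom)) {
    d <- delta_series[delta_series$chrom == ch, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    ok <- abs(d$delta) >= config$dmr_delta
    sgn <- sign(d$delta)
    run_id <- .segment_runs(d$pos, ok, sgn, config$max_gap_bp, config$min_cpgs)
    if (!any(ok)) next
    for (rid in unique(run_id[run_id > 0])) {
      i <- which(run_id == rid)
      if (length(i) < config$min_cpgs) next
      md <- mean(d$delta[i])
      if (strict_replicates) {
        rep_means <- vapply(rep_cols, function(cc) mean(d[[cc]][i]),
                            numeric(1))
        if (!all(sign(rep_means) == sign(md) &
                   abs(rep_means) >= config$dmr_delta / 2)) next
      }
      out <- rbind(out, new_dmr_table(
        ch, d$pos[i[1L]], d$pos[i[length(i)]] + 1L,
        if (md > 0) "hyper" else "hypo", length(i), md))
    }
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dmr_table", "data.frame")
  out
}

#' Call low-methylated regions against the track's genome-wide baseline
#'
#' The genome baseline is the mean methylation over all CpGs of the track.
#' An LMR is a maximal run of at least `lmr_min_run` consecutive CpGs, each
#' at most `lmr_cpg_ceiling`, with gaps at most `max_gap_bp`, whose run
#' mean lies at least `lmr_baseline_margin` below the baseline. On a
#' uniformly low track nothing is called: no region is lower than the rest
#' of its own genome.
#'
#' @param track A [methylome_track()].
#' @param config A [run_config()].
#' @return An LMR table: `chrom`, `start`, `end`, `n_cpgs`, `mean_meth`,
#'   `genome_baseline`.
#' @export
call_lmrs <- function(track, config = run_config()) {
  if (!nrow(track)) return(new_lmr_table())
  baseline <- mean(track$meth)
  out <- new_lmr_table()
  for (ch in unique(track$chrom)) {
    d <- track[track$chrom == ch, , drop = FALSE]
    ok <- d$meth <= config$lmr_cpg_ceiling
    run_id <- .segment_runs(d$pos, ok, rep(1, nrow(d)), config$max_gap_bp,
                            config$lmr_min_run)
    if (!any(ok)) next
    for (rid in unique(run_id[run_id > 0])) {
      i <- which(run_id == rid)
      if (length(i) < config$lmr_min_run) next
      mm <- mean(d$meth[i])
      if (mm > baseline - config$lmr_baseline_margin) next
      out <- rbind(out, new_lmr_table(
        ch, d$pos[i[1L]], d$pos[i[length(i)]] + 1L, length(i), mm, baseline))
    }
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lmr_table", "data.frame")
  out
}
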