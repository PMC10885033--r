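# Independent brute-force oracles. Deliberately written as transparent
# scalar loops over one gene / one CpG at a time, so they share no code
# path with the vectorized implementations they check.

# Per-gene re-evaluation of the culture-preferential rule.
oracle_culture_call <- function(mat, target, R, E) {
  passed <- character(0)
  for (g in rownames(mat$values)) {
    num <- mat$values[g, target]
    others <- mat$values[g, setdiff(colnames(mat$values), target)]
    den <- sum(others) / length(others)
    ok <- if (den > 0) (num / den >= R) && (num >= E) else (num >= E)
    if (ok) passed <- c(passed, g)
  }
  passed
}

# Per-gene re-evaluation of the cerebellum rule with zero-denominator rescue.
oracle_cbl_call <- function(mat, R, E, brain_ct = "median") {
  g <- mat$groups
  cbl <- names(g)[g == "cerebellum"]
  bo <- names(g)[g == "brain_other"]
  nb <- names(g)[g == "non_brain"]
  passed <- character(0)
  for (gene in rownames(mat$values)) {
    num <- mat$values[gene, cbl]
    db <- if (brain_ct == "median") median(mat$values[gene, bo])
          else mean(mat$values[gene, bo])
    dn <- mean(mat$values[gene, nb])
    strict_max <- num > 0 && all(num > mat$values[gene, c(bo, nb)])
    ok_b <- if (db > 0) num / db >= R else strict_max
    ok_n <- if (dn > 0) num / dn >= R else strict_max
    if (num >= E && ok_b && ok_n) passed <- c(passed, gene)
  }
  passed
}

# Per-gene re-evaluation of the four universe criteria.
oracle_universe <- function(tissue, culture, ann, E, whitelist = character()) {
  keep <- character(0)
  bt <- setNames(ann$biotype, ann$gene_id)
  for (g in rownames(tissue$values)) {
    if (!g %in% rownames(culture$values)) next
    b <- if (g %in% names(bt)) bt[[g]] else "other"
    if (b == "mito") next
    if (b != "protein_coding" && !g %in% whitelist) next
    if (!any(tissue$values[g, ] >= E)) next
    if (!any(culture$values[g, ] >= E)) next
    keep <- c(keep, g)
  }
  keep
}

# Greedy one-CpG-at-a-time builder of maximal qualifying DMR runs.
oracle_dmrs <- function(series, delta, min_cpgs, max_gap) {
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    direction = character(), n_cpgs = integer(),
                    mean_delta = numeric(), stringsAsFactors = FALSE)
  for (ch in unique(series$chrom)) {
    d <- series[series$chrom == ch, ]
    d <- d[order(d$pos), ]
    run <- integer(0)  # row indices of the current run
    flush <- function(run) {
      if (length(run) >= min_cpgs) {
        md <- mean(d$delta[run])
        out <<- rbind(out, data.frame(
          chrom = ch, start = d$pos[run[1]], end = d$pos[run[length(run)]] + 1L,
          direction = if (md > 0) "hyper" else "hypo",
          n_cpgs = length(run), mean_delta = md, stringsAsFactors = FALSE))
      }
    }
    for (i in seq_len(nrow(d))) {
      cand <- abs(d$delta[i]) >= delta
      if (!cand) { flush(run); run <- integer(0); next }
      if (length(run)) {
        same_sign <- sign(d$delta[i]) == sign(d$delta[run[length(run)]])
        close_by <- d$pos[i] - d$pos[run[length(run)]] <= max_gap
        contiguous <- i == run[length(run)] + 1L
        if (same_sign && close_by && contiguous) {
          run <- c(run, i)
        } else {
          flush(run); run <- i
        }
      } else run <- i
    }
    flush(run)
  }
  rownames(out) <- NULL
  out
}

# Greedy builder of maximal low-methylation runs, then the mean filter.
oracle_lmrs <- function(track, min_run, ceiling, margin, max_gap) {
  baseline <- mean(track$meth)
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    n_cpgs = integer(), mean_meth = numeric(),
                    genome_baseline = numeric(), stringsAsFactors = FALSE)
  for (ch in unique(track$chrom)) {
    d <- track[track$chrom == ch, ]
    run <- integer(0)
    flush <- function(run) {
      if (length(run) >= min_run && mean(d$meth[run]) <= baseline - margin)
        out <<- rbind(out, data.frame(
          chrom = ch, start = d$pos[run[1]], end = d$pos[run[length(run)]] + 1L,
          n_cpgs = length(run), mean_meth = mean(d$meth[run]),
          genome_baseline = baseline, stringsAsFactors = FALSE))
    }
    for (i in seq_len(nrow(d))) {
      if (d$meth[i] > ceiling) { flush(run); run <- integer(0); next }
      if (length(run) &&
          (i != run[length(run)] + 1L ||
           d$pos[i] - d$pos[run[length(run)]] > max_gap)) {
        flush(run); run <- i
      } else run <- c(run, i)
    }
    flush(run)
  }
  rownames(out) <- NULL
  out
}

# Quadratic any-overlap scan, half-open semantics.
oracle_overlaps <- function(queries, track) {
  lapply(seq_len(nrow(queries)), function(i) {
    hits <- integer(0)
    for (j in seq_len(nrow(track))) {
      if (queries$chrom[i] == track$chrom[j] &&
          max(queries$start[i], track$start[j]) <
          min(queries$end[i], track$end[j]))
        hits <- c(hits, j)
    }
    hits
  })
}
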