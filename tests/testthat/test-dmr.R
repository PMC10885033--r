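cfg <- run_config()

test_that("per-CpG delta: arithmetic, intersection rule, coverage filter", {
  mk <- function(pos, meth, cov = NULL, id = "t")
    methylome_track(rep("chr1", length(pos)), pos, meth, cov, id)
  targets <- list(mk(c(100, 200), c(0.9, 0.5)),
                  mk(c(100, 200), c(0.8, 0.5)),
                  mk(c(100, 200), c(0.85, 0.5)))
  panel <- lapply(1:2, function(i) mk(c(100, 200), c(0.1, 0.5)))
  ds <- per_cpg_delta(targets, panel)
  expect_equal(ds$delta[ds$pos == 100], 0.75)
  expect_equal(ds$delta[ds$pos == 200], 0)

  # CpG absent from one panel sample drops out of the series
  panel2 <- list(mk(c(100, 200), c(0.1, 0.5)), mk(200, 0.5))
  ds2 <- per_cpg_delta(targets, panel2)
  expect_equal(ds2$pos, 200L)
  expect_error(per_cpg_delta(list(mk(1, 0.5)), list(mk(2, 0.5))),
               "no CpGs common")

  # coverage: filtered only where a coverage column exists; monotone in
  # min_coverage
  t_cov <- mk(c(100, 200, 300), c(0.9, 0.9, 0.9), cov = c(5, 30, 30))
  p_nocov <- mk(c(100, 200, 300), c(0.1, 0.1, 0.1))
  expect_equal(per_cpg_delta(list(t_cov), list(p_nocov), 10)$pos,
               c(200L, 300L))
  prev <- per_cpg_delta(list(t_cov), list(p_nocov), 0)$pos
  for (mc in c(1, 10, 31)) {
    cur <- tryCatch(
      per_cpg_delta(list(t_cov), list(p_nocov), mc)$pos,
      error = function(e) integer(0))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("random delta series match brute-force recomputation", {
  set.seed(31)
  n <- 80
  pos <- cumsum(sample(c(30, 150), n, TRUE))  # CpG sites are genomic: shared
  mk_rand <- function(id) {
    keep <- sort(sample(n, n - 5))  # each track misses a few sites
    methylome_track(rep("chrR", n - 5), pos[keep], round(runif(n - 5), 3),
                    sample_id = id)
  }
  targets <- lapply(1:3, function(i) mk_rand(paste0("t", i)))
  panel <- lapply(1:4, function(i) mk_rand(paste0("p", i)))
  ds <- per_cpg_delta(targets, panel)
  # brute force at each common position
  common <- Reduce(intersect, lapply(c(targets, panel), function(x) x$pos))
  expect_setequal(ds$pos, common)
  for (p in sample(common, 10)) {
    tv <- sapply(targets, function(x) x$meth[x$pos == p])
    pv <- sapply(panel, function(x) x$meth[x$pos == p])
    expect_equal(ds$delta[ds$pos == p], mean(tv) - mean(pv))
  }
})

test_that("call_dmrs: construction, boundaries, relaxed mode", {
  # 10 consecutive high CpGs flanked by zeros -> one hyper DMR
  s <- data.frame(chrom = "chr1", pos = seq(0, 190, 10),
                  delta = c(rep(0, 5), rep(0.75, 10), rep(0, 5)))
  d <- call_dmrs(s, cfg)
  expect_equal(nrow(d), 1L)
  expect_equal(d$direction, "hyper")
  expect_equal(d$n_cpgs, 10L)
  expect_equal(c(d$start, d$end), c(50L, 141L))
  expect_equal(d$mean_delta, 0.75)

  # threshold is inclusive: 0.35 qualifies, 0.34 does not
  s2 <- data.frame(chrom = "chr1", pos = seq(0, 90, 10), delta = 0.34)
  expect_equal(nrow(call_dmrs(s2, cfg)), 0L)
  s2$delta <- 0.35
  expect_equal(nrow(call_dmrs(s2, cfg)), 1L)

  # a -0.25 run appears only in the relaxed 0.20 mode
  s3 <- data.frame(chrom = "chr1", pos = seq(0, 90, 10), delta = -0.25)
  expect_equal(nrow(call_dmrs(s3, cfg)), 0L)
  relaxed <- run_config(dmr_delta = 0.20)
  d3 <- call_dmrs(s3, relaxed)
  expect_equal(d3$direction, "hypo")
  expect_equal(d3$n_cpgs, 10L)

  # sign flips and big gaps break runs; min_cpgs prunes short runs
  s4 <- data.frame(chrom = "chr1",
                   pos = c(0, 10, 20, 30, 40, 1000, 1010, 1020),
                   delta = c(0.5, 0.5, -0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  d4 <- call_dmrs(s4, cfg)  # runs: {0,10}, {-}, {30,40}, {1000..1020}
  expect_equal(nrow(d4), 1L)
  expect_equal(c(d4$start, d4$end), c(1000L, 1021L))
  expect_equal(nrow(call_dmrs(s4[0, ], cfg)), 0L)
})

test_that("call_dmrs equals exhaustive oracle on random series (property)", {
  set.seed(32)
  for (rep in 1:60) {
    s <- random_delta_series(sample(50:300, 1))
    got <- call_dmrs(s, cfg)
    want <- oracle_dmrs(s, cfg$dmr_delta, cfg$min_cpgs, cfg$max_gap_bp)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$direction, want$direction)
      expect_equal(got$mean_delta, want$mean_delta)
    }
    # sorted, non-overlapping output
    if (nrow(got) > 1)
      expect_true(all(got$start[-1] >= got$end[-nrow(got)]))
  }
})

test_that("every standard-delta DMR is contained in a relaxed-delta DMR", {
  set.seed(33)
  relaxed <- run_config(dmr_delta = 0.20)
  for (rep in 1:20) {
    s <- random_delta_series(200)
    std <- call_dmrs(s, cfg)
    rel <- call_dmrs(s, relaxed)
    for (i in seq_len(nrow(std))) {
      inside <- any(rel$start <= std$start[i] & rel$end >= std$end[i] &
                      rel$direction == std$direction[i])
      expect_true(inside)
    }
  }
})

test_that("strict replicate mode drops runs driven by a subset of replicates", {
  cfg <- run_config()
  mk <- function(meth, id)
    methylome_track(rep("chr1", 10), seq(0, 90, 10), meth, sample_id = id)
  hi <- rep(0.9, 10); lo <- rep(0.1, 10)
  # rep3 looks like the panel: mean delta still ~0.53, but inconsistent
  targets_bad <- list(mk(hi, "t1"), mk(hi, "t2"), mk(lo, "t3"))
  targets_good <- list(mk(hi, "t1"), mk(hi, "t2"), mk(hi, "t3"))
  panel <- list(mk(lo, "p1"), mk(lo, "p2"))
  ds_bad <- per_cpg_delta(targets_bad, panel)
  ds_good <- per_cpg_delta(targets_good, panel)
  expect_equal(nrow(call_dmrs(ds_bad, cfg)), 1L)               # default keeps
  expect_equal(nrow(call_dmrs(ds_bad, cfg, strict_replicates = TRUE)), 0L)
  expect_equal(nrow(call_dmrs(ds_good, cfg, strict_replicates = TRUE)), 1L)
  expect_error(call_dmrs(ds_bad[, c("chrom", "pos", "delta")], cfg,
                         strict_replicates = TRUE), "delta_rep")
})

test_that("call_lmrs: construction, baseline logic, oracle equivalence", {
  # low 10-CpG run in a 0.8 genome -> one LMR over that run
  n <- 100
  meth <- rep(0.8, n); meth[41:50] <- 0.1
  tr <- methylome_track(rep("chr1", n), seq(0, by = 50, length.out = n),
                        meth, sample_id = "s")
  l <- call_lmrs(tr, cfg)
  expect_equal(nrow(l), 1L)
  expect_equal(c(l$start, l$end), c(2000L, 2451L))
  expect_equal(l$n_cpgs, 10L)
  expect_equal(l$mean_meth, 0.1)

  # uniformly low genome: nothing is lower than the rest of itself
  flat <- methylome_track(rep("chr1", n), seq(0, by = 50, length.out = n),
                          rep(0.1, n), sample_id = "s")
  expect_equal(nrow(call_lmrs(flat, cfg)), 0L)

  set.seed(34)
  for (rep in 1:30) {
    tr <- random_track(sample(50:200, 1))
    got <- call_lmrs(tr, cfg)
    want <- oracle_lmrs(tr, cfg$lmr_min_run, cfg$lmr_cpg_ceiling,
                        cfg$lmr_baseline_margin, cfg$max_gap_bp)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$mean_meth, want$mean_meth)
    }
  }
})
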