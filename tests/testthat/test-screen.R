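cfg <- run_config()

test_that("gene-universe filter applies all four criteria", {
  set.seed(21)
  n <- 60
  tv <- matrix(runif(n * 52, 0, 4), n, 52,
               dimnames = list(sprintf("g%02d", 1:n), NULL))
  cv <- matrix(runif(n * 6, 0, 4), n, 6,
               dimnames = list(sprintf("g%02d", 1:n), NULL))
  tissue <- make_tissue_matrix(tv)
  culture <- make_culture_matrix(cv)
  bt <- sample(c("protein_coding", "ncRNA", "mito", "other"), n, TRUE,
               prob = c(0.7, 0.15, 0.05, 0.1))
  ann <- gene_annotation(sprintf("g%02d", 1:n), "chr1",
                         seq(0, by = 2000, length.out = n),
                         seq(1000, by = 2000, length.out = n),
                         rep(c("+", "-"), length.out = n), bt)
  wl <- sprintf("g%02d", which(bt == "ncRNA"))[1]
  got <- filter_gene_universe(tissue, culture, ann, cfg, whitelist = wl)
  expect_identical(got, oracle_universe(tissue, culture, ann,
                                        cfg$expression_floor, wl))

  # targeted cases: a hot mito gene is excluded, floor failures are excluded
  tv2 <- matrix(10, 3, 52, dimnames = list(c("m", "lowT", "ok"), NULL))
  tv2["lowT", ] <- 0.5
  cv2 <- matrix(10, 3, 6, dimnames = list(c("m", "lowT", "ok"), NULL))
  ann2 <- gene_annotation(c("m", "lowT", "ok"), "chr1", c(0, 100, 200) * 10,
                          c(50, 150, 250) * 10, "+",
                          c("mito", "protein_coding", "protein_coding"))
  got2 <- filter_gene_universe(make_tissue_matrix(tv2),
                               make_culture_matrix(cv2), ann2, cfg)
  expect_identical(got2, "ok")
})

test_that("culture-preferential call matches per-gene brute force", {
  set.seed(22)
  n <- 100
  cv <- matrix(rlnorm(n * 6, 0.5, 1.5), n, 6,
               dimnames = list(sprintf("g%03d", 1:n), NULL))
  cv[sample(length(cv), 40)] <- 0  # exercise zero denominators
  culture <- make_culture_matrix(cv)
  for (target in c("Myoblast", "ESC")) {
    res <- call_culture_preferential(culture, target, cfg)
    expect_identical(res$set,
                     oracle_culture_call(culture, target,
                                         cfg$ratio_threshold,
                                         cfg$expression_floor))
    # every passing call satisfies its inequality when recomputed
    p <- res$calls[res$calls$passed, ]
    expect_true(all(p$numerator >= cfg$expression_floor))
    expect_true(all(p$denominator == 0 |
                      p$numerator / p$denominator >= cfg$ratio_threshold))
  }
  expect_error(call_culture_preferential(culture, "HeLa", cfg), "absent")
})

test_that("culture boundary semantics: ratio exactly R passes, floor binds", {
  cv <- matrix(c(10, 2, 2, 2, 2, 2,    # ratio exactly 5 -> pass
                 0.9, 0, 0, 0, 0, 0,   # zero denom but below floor -> fail
                 2, 0, 0, 0, 0, 0),    # zero denom, above floor -> pass (Inf)
               3, 6, byrow = TRUE, dimnames = list(c("b", "f", "z"), NULL))
  res <- call_culture_preferential(make_culture_matrix(cv), "Myoblast", cfg)
  expect_setequal(res$set, c("b", "z"))
  expect_true(is.infinite(res$calls$ratio[res$calls$gene_id == "z"]))
})

test_that("cerebellum call matches brute force incl. rescue rule", {
  set.seed(23)
  n <- 120
  tv <- matrix(rlnorm(n * 52, 0, 1.5), n, 52,
               dimnames = list(sprintf("g%03d", 1:n), NULL))
  tv[sample(n, 30), 12:52] <- 0  # zero non-brain denominators
  tissue <- make_tissue_matrix(tv)
  res <- call_cerebellum_preferential(tissue, cfg)
  expect_identical(res$set, oracle_cbl_call(tissue, cfg$ratio_threshold,
                                            cfg$expression_floor))
  # mean mode agrees with its own oracle
  cfg_mean <- run_config(brain_central_tendency = "mean")
  expect_identical(call_cerebellum_preferential(tissue, cfg_mean)$set,
                   oracle_cbl_call(tissue, 5, 1, brain_ct = "mean"))

  # rescue: all non-brain 0, cerebellum the strict maximum -> rescue_applied
  tv2 <- matrix(0.2, 2, 52, dimnames = list(c("resc", "tie"), NULL))
  tv2["resc", ] <- c(8, rep(0.5, 10), rep(0, 41))
  tv2["tie", ] <- c(8, c(8, rep(0.5, 9)), rep(0, 41))  # tied max -> no rescue
  res2 <- call_cerebellum_preferential(make_tissue_matrix(tv2), cfg)
  expect_identical(res2$set, "resc")
  expect_true(res2$calls$rescue_applied[res2$calls$gene_id == "resc"])
  bad_groups <- make_culture_matrix(matrix(1, 1, 6,
                                           dimnames = list("g", NULL)))
  expect_error(call_cerebellum_preferential(bad_groups, cfg),
               "cardinalities")
})

test_that("cerebellum boundary: both ratios exactly 5 at TPM 1 passes", {
  tv <- matrix(0.2, 1, 52, dimnames = list("b", NULL))
  tv["b", ] <- c(1, rep(0.2, 10), rep(0.2, 41))
  res <- call_cerebellum_preferential(make_tissue_matrix(tv), cfg)
  expect_identical(res$set, "b")
})

test_that("set algebra: intersection and overlap matrix", {
  a <- sprintf("m%03d", 1:422)
  b <- c(sprintf("m%03d", 1:20), sprintf("c%03d", 1:219))
  expect_length(intersect_dual(a, b), 20L)
  expect_length(intersect_dual(a, sprintf("x%d", 1:5)), 0L)
  set.seed(24)
  r1 <- sample(letters, 12); r2 <- sample(letters, 12)
  expect_setequal(intersect_dual(r1, r2), unique(r2[r2 %in% r1]))

  sim <- simulate_expression(
    400, c(dual_specific = 5, culture_ESC_specific = 8, cbl_only = 10),
    noise_sd = 0, rng_seed = 3)
  cbl <- call_cerebellum_preferential(sim$tissue, cfg)$set
  ov <- overlap_matrix(sim$culture, cbl, cfg)
  expect_setequal(ov$culture, colnames(sim$culture$values))
  # only myoblasts share planted genes with cerebellum here
  expect_equal(ov$n_overlap[ov$culture == "Myoblast"], 5L)
  expect_equal(sum(ov$n_overlap[ov$culture != "Myoblast"]), 0L)
  expect_true(all(ov$n_overlap <= pmin(ov$n_preferential, length(cbl))))
  ov0 <- overlap_matrix(sim$culture, character(0), cfg)
  expect_true(all(ov0$n_overlap == 0L))
})

test_that("monotonicity: raising R never adds genes, lowering E never removes", {
  sim <- simulate_expression(300, c(dual_specific = 10, myob_only = 20),
                             noise_sd = 0.4, rng_seed = 8)
  for (R2 in c(6, 8, 12)) {
    tighter <- run_config(ratio_threshold = R2)
    expect_true(all(call_culture_preferential(sim$culture, "Myoblast",
                                              tighter)$set %in%
                    call_culture_preferential(sim$culture, "Myoblast",
                                              cfg)$set))
    expect_true(all(call_cerebellum_preferential(sim$tissue, tighter)$set %in%
                    call_cerebellum_preferential(sim$tissue, cfg)$set))
  }
  looser <- run_config(expression_floor = 0.1)
  expect_true(all(call_culture_preferential(sim$culture, "Myoblast",
                                            cfg)$set %in%
                  call_culture_preferential(sim$culture, "Myoblast",
                                            looser)$set))
})
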