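#' @name simulate
#' @title Synthetic data with planted ground truth
#' @description
#' The generators in this file emulate the statistical structure the screen
#' and DMR caller assume — they are first-class, tested code, not fixtures.
#' Expression noise is multiplicative log-normal (expression data are
#' scale-heavy); methylation noise is Beta (bounded fractions). Planted
#' effect sizes sit far from the decision thresholds (10x expression
#' contrast vs. the ratio threshold of 5; |delta| >= 0.5 vs. the DMR
#' threshold of 0.35) so recovery under noise is testable, while dedicated
#' boundary classes sit exactly at the thresholds to pin comparator
#' semantics.
NULL

.culture_names <- c("Myoblast", "NHLF", "NHEK", "HUVEC", "LCL", "ESC")

.tissue_layout <- function() {
  ids <- c("cerebellum",
           sprintf("brain_other_%02d", 1:10),
           sprintf("non_brain_%02d", 1:41))
  groups <- stats::setNames(
    c("cerebellum", rep("brain_other", 10), rep("non_brain", 41)), ids)
  groups
}

#' Simulate tissue and cell-culture expression matrices with planted classes
#'
#' Produces a 52-sample tissue matrix (1 cerebellum, 10 other brain regions,
#' 41 non-brain tissues; TPM) and a 6-culture matrix (myoblasts plus five
#' heterologous cultures; FPKM), with each gene drawn from a planted class:
#'
#' * `dual_specific` — 10x enriched in myoblasts (vs. the other cultures)
#'   and in cerebellum (vs. other brain and non-brain tissues).
#' * `myob_only` / `cbl_only` — enriched in one context only.
#' * `culture_<NAME>_specific` — enriched in another culture
#'   (e.g. `culture_ESC_specific`).
#' * `broadly_expressed` — flat moderate expression everywhere.
#' * `silent` — below the expression floor everywhere.
#' * `zero_denominator_rescue` — all 41 non-brain TPM exactly 0 and
#'   cerebellum the tissue-wide maximum (exercises the rescue rule).
#' * `boundary_ratio` — emitted noise-free with the myoblast/other-culture
#'   ratio exactly equal to the ratio threshold and expression exactly at
#'   the floor scale; pins the inclusive comparator. These genes are not
#'   cerebellum-preferential.
#'
#' Expression is `planted mean * exp(N(0, noise_sd^2))` (truncation at 0 is
#' vacuous for a log-normal), except for `boundary_ratio` genes which are
#' exact.
#'
#' @param n_genes Total number of genes.
#' @param class_counts Named integer vector of planted class sizes; any
#'   remainder becomes `broadly_expressed`. Must sum to <= `n_genes`.
#'   The default is a canonical mix (50 dual-specific, 100 each
#'   myoblast-/cerebellum-only, 20 per other culture, 5 rescue, 5 boundary,
#'   100 silent per 2000 genes) scaled proportionally to `n_genes`.
#' @param noise_sd Standard deviation of the log-normal noise (log scale).
#' @param rng_seed Integer seed; identical seeds give identical output.
#' @param config A [run_config()]; supplies the ratio threshold and floor
#'   used to position the boundary class.
#' @return A list with elements `tissue` ([expression_matrix()], TPM),
#'   `culture` ([expression_matrix()], FPKM) and `manifest` (data.frame
#'   `gene_id`, `class`).
#' @examples
#' sim <- simulate_expression(200, c(dual_specific = 5), noise_sd = 0,
#'                            rng_seed = 1)
#' table(sim$manifest$class)
#' @export
simulate_expression <- function(n_genes,
                                class_counts = NULL,
                                noise_sd = 0.2,
                                rng_seed = 1,
                                config = run_config()) {
  stopifnot(noise_sd >= 0, n_genes >= 1)
  if (is.null(class_counts)) {
    canonical <- c(dual_specific = 50, myob_only = 100, cbl_only = 100,
                   culture_ESC_specific = 20, culture_LCL_specific = 20,
                   culture_NHEK_specific = 20, culture_HUVEC_specific = 20,
                   culture_NHLF_specific = 20, zero_denominator_rescue = 5,
                   boundary_ratio = 5, silent = 100)
    class_counts <- round(canonical * n_genes / 2000)
  }
  class_counts <- class_counts[class_counts > 0]
  if (sum(class_counts) > n_genes)
    stop("class_counts exceed n_genes")
  known <- c("dual_specific", "myob_only", "cbl_only", "broadly_expressed",
             "silent", "zero_denominator_rescue", "boundary_ratio",
             paste0("culture_", setdiff(.culture_names, "Myoblast"),
                    "_specific"))
  bad <- setdiff(names(class_counts), known)
  if (length(bad)) stop("unknown planted class(es): ", paste(bad, collapse = ", "))

  set.seed(rng_seed)
  ids <- sprintf("g%05d", seq_len(n_genes))
  classes <- rep("broadly_expressed", n_genes)
  slots <- sample.int(n_genes, sum(class_counts))
  classes[slots] <- rep(names(class_counts), class_counts)
  manifest <- data.frame(gene_id = ids, class = classes,
                         stringsAsFactors = FALSE)

  tgroups <- .tissue_layout()
  tissue_ids <- names(tgroups)
  hi <- 50; lo <- 5; flat <- 10; silent_mu <- 0.2
  R <- config$ratio_threshold; E <- config$expression_floor

  tmu <- matrix(flat, n_genes, length(tissue_ids),
                dimnames = list(ids, tissue_ids))
  cmu <- matrix(flat, n_genes, length(.culture_names),
                dimnames = list(ids, .culture_names))
  is_cbl <- tgroups == "cerebellum"
  is_bo <- tgroups == "brain_other"
  is_nb <- tgroups == "non_brain"

  set_tissue <- function(cls, cbl, bo, nb) {
    i <- classes == cls
    tmu[i, is_cbl] <<- cbl; tmu[i, is_bo] <<- bo; tmu[i, is_nb] <<- nb
  }
  set_culture <- function(cls, target, target_val, other_val) {
    i <- classes == cls
    cmu[i, ] <<- other_val
    cmu[i, target] <<- target_val
  }

  set_tissue("dual_specific", hi, lo, lo)
  set_culture("dual_specific", "Myoblast", hi, lo)
  set_culture("myob_only", "Myoblast", hi, lo)
  set_tissue("cbl_only", hi, lo, lo)
  for (cu in setdiff(.culture_names, "Myoblast"))
    set_culture(paste0("culture_", cu, "_specific"), cu, hi, lo)
  set_tissue("silent", silent_mu, silent_mu, silent_mu)
  i <- classes == "silent"; cmu[i, ] <- silent_mu
  set_tissue("zero_denominator_rescue", hi, 2, 0)
  # boundary: exact ratio R in the myoblast context, floor-scale numerator
  set_culture("boundary_ratio", "Myoblast", R * E, E)

  lognoise <- function(mu) {
    if (noise_sd == 0) return(mu)
    mu * exp(matrix(stats::rnorm(length(mu), 0, noise_sd), nrow(mu)))
  }
  tval <- lognoise(tmu); cval <- lognoise(cmu)
  exact <- classes %in% "boundary_ratio"
  tval[exact, ] <- tmu[exact, ]; cval[exact, ] <- cmu[exact, ]
  dimnames(tval) <- dimnames(tmu); dimnames(cval) <- dimnames(cmu)

  list(tissue = expression_matrix(tval, "TPM", tgroups),
       culture = expression_matrix(
         cval, "FPKM", stats::setNames(.culture_names, .culture_names)),
       manifest = manifest)
}

#' Simulate a non-overlapping gene annotation
#'
#' Genes are placed sequentially with random gaps on the given chromosomes,
#' with a mixture of strands (at least one minus-strand gene whenever
#' `n_genes >= 2`) and a biotype mixture that always includes at least one
#' `ncRNA` and one `mito` gene when the fractions are positive and
#' `n_genes` allows, so the gene-universe filter is exercised.
#'
#' @param n_genes Number of genes.
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#' @param rng_seed Integer seed.
#' @param gene_length Range (min, max) of gene body lengths in bp.
#' @param frac_ncrna,frac_mito Fractions of genes given those biotypes.
#' @return A [gene_annotation()].
#' @export
simulate_annotation <- function(n_genes,
                                chrom_sizes = c(chrSim1 = 1e6, chrSim2 = 1e6),
                                rng_seed = 1,
                                gene_length = c(2000, 10000),
                                frac_ncrna = 0.10, frac_mito = 0.02) {
  set.seed(rng_seed)
  ids <- sprintf("g%05d", seq_len(n_genes))
  n_chrom <- length(chrom_sizes)
  chrom_of <- sort(rep_len(seq_len(n_chrom), n_genes))
  lens <- as.integer(round(stats::runif(n_genes, gene_length[1], gene_length[2])))
  start <- integer(n_genes); chrom <- character(n_genes)
  for (ci in seq_len(n_chrom)) {
    idx <- which(chrom_of == ci)
    if (!length(idx)) next
    size <- chrom_sizes[ci]
    need <- sum(lens[idx])
    slack <- size - need - 1000 * length(idx)  # >= 1 kb gap between genes
    if (slack < 0)
      stop("insufficient genome length on ", names(chrom_sizes)[ci])
    gaps <- 1000 + floor(slack * diff(c(0, sort(stats::runif(length(idx))))))
    pos <- cumsum(gaps) + cumsum(c(0, lens[idx[-length(idx)]]))
    start[idx] <- as.integer(pos)
    chrom[idx] <- names(chrom_sizes)[ci]
  }
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  if (n_genes >= 2 && length(unique(strand)) == 1L)
    strand[n_genes] <- setdiff(c("+", "-"), strand[1L])
  biotype <- rep("protein_coding", n_genes)
  n_nc <- if (frac_ncrna > 0) max(1L, round(frac_ncrna * n_genes)) else 0L
  n_mt <- if (frac_mito > 0) max(1L, round(frac_mito * n_genes)) else 0L
  if (n_nc + n_mt >= n_genes) stop("biotype fractions leave no protein_coding genes")
  special <- sample.int(n_genes, n_nc + n_mt)
  biotype[special[seq_len(n_nc)]] <- "ncRNA"
  if (n_mt) biotype[special[n_nc + seq_len(n_mt)]] <- "mito"
  gene_annotation(ids, chrom, start, start + lens, strand, biotype)
}

#' Build a planted-region table for the methylome simulator
#'
#' Fills in default target/panel methylation means by region type:
#' `hyper_dmr` 0.90 vs 0.20, `hypo_dmr` 0.10 vs 0.80, `lmr` 0.05 in both
#' classes. Explicit `target_mean` / `panel_mean` columns override the
#' defaults (used e.g. to plant sub-threshold regions).
#'
#' @param chrom,start,end Region coordinates (0-based half-open).
#' @param type `"hypo_dmr"`, `"hyper_dmr"` or `"lmr"`.
#' @param target_mean,panel_mean Optional explicit per-region means.
#' @return A data.frame usable as `planted_regions`.
#' @export
plant_regions <- function(chrom, start, end, type,
                          target_mean = NA_real_, panel_mean = NA_real_) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), type = as.character(type),
                   target_mean = as.numeric(target_mean),
                   panel_mean = as.numeric(panel_mean),
                   stringsAsFactors = FALSE)
  defaults <- list(hyper_dmr = c(0.90, 0.20), hypo_dmr = c(0.10, 0.80),
                   lmr = c(0.05, 0.05))
  bad <- setdiff(df$type, names(defaults))
  if (length(bad)) stop("unknown region type(s): ", paste(bad, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    d <- defaults[[df$type[i]]]
    if (is.na(df$target_mean[i])) df$target_mean[i] <- d[1]
    if (is.na(df$panel_mean[i])) df$panel_mean[i] <- d[2]
  }
  if (any(df$target_mean < 0 | df$target_mean > 1 |
          df$panel_mean < 0 | df$panel_mean > 1))
    stop("planted means must lie in [0, 1]")
  df
}

#' Simulate replicated target and reference-panel methylomes
#'
#' Lays a deterministic CpG grid over each chromosome (`cpg_spacing_bg`
#' apart in background, `cpg_spacing_region` apart inside planted regions,
#' approximating CpG-island density) and draws each CpG's methylation from
#' a Beta distribution whose mean is the planted region mean for that
#' sample class (target vs. panel) or the common background mean.
#' `beta_concentration = Inf` gives the noise-free mode in which every CpG
#' equals its planted mean exactly.
#'
#' @param planted_regions Data.frame from [plant_regions()]; regions must
#'   not overlap and must fit inside `chrom_sizes`.
#' @param chrom_sizes Named vector of chromosome lengths. Defaults to the
#'   chromosomes named in `planted_regions` with a 10 kb margin past the
#'   last region.
#' @param n_target_reps Number of target biological replicates (default 3,
#'   mirroring a replicated EM-seq target).
#' @param n_panel Number of reference-panel samples (default 6).
#' @param cpg_spacing_region,cpg_spacing_bg CpG grid spacing (bp) inside
#'   planted regions and in background.
#' @param beta_concentration Beta concentration (alpha + beta); larger is
#'   less noisy; `Inf` = noise-free.
#' @param background_mean Genome background methylation mean (both classes).
#' @param coverage_lambda If non-`NULL`, adds a Poisson(`lambda`) coverage
#'   column to every track.
#' @param rng_seed Integer seed.
#' @return A list with `target` (list of [methylome_track()]), `panel`
#'   (list of tracks), and `manifest` (the planted-region table with means
#'   resolved; attribute `background_mean`).
#' @export
simulate_methylomes <- function(planted_regions,
                                chrom_sizes = NULL,
                                n_target_reps = 3,
                                n_panel = 6,
                                cpg_spacing_region = 20,
                                cpg_spacing_bg = 200,
                                beta_concentration = 100,
                                background_mean = 0.75,
                                coverage_lambda = NULL,
                                rng_seed = 1) {
  stopifnot(beta_concentration > 0, n_target_reps >= 1, n_panel >= 1)
  pr <- plant_regions(planted_regions$chrom, planted_regions$start,
                      planted_regions$end, planted_regions$type,
                      if (is.null(planted_regions$target_mean))
                        NA_real_ else planted_regions$target_mean,
                      if (is.null(planted_regions$panel_mean))
                        NA_real_ else planted_regions$panel_mean)
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(pr$end, pr$chrom, max) + 10000
    chrom_sizes <- stats::setNames(as.integer(chrom_sizes), names(chrom_sizes))
  }
  if (!all(pr$chrom %in% names(chrom_sizes)))
    stop("planted region on a chromosome absent from chrom_sizes")
  if (any(pr$end > chrom_sizes[pr$chrom]))
    stop("planted region extends past its chromosome")
  for (ch in unique(pr$chrom)) {
    p <- pr[pr$chrom == ch, ]
    p <- p[order(p$start), ]
    if (nrow(p) > 1 && any(p$start[-1] < p$end[-nrow(p)]))
      stop("planted regions overlap on ", ch)
  }

  # deterministic CpG grid, shared by all samples
  grid <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    bg <- seq(0L, chrom_sizes[[ch]] - 1L, by = as.integer(cpg_spacing_bg))
    p <- pr[pr$chrom == ch, , drop = FALSE]
    reg_pos <- integer(); reg_idx <- integer()
    which_global <- which(pr$chrom == ch)
    for (k in seq_len(nrow(p))) {
      rp <- seq(p$start[k], p$end[k] - 1L, by = as.integer(cpg_spacing_region))
      reg_pos <- c(reg_pos, rp)
      reg_idx <- c(reg_idx, rep(which_global[k], length(rp)))
    }
    in_region <- rep(FALSE, length(bg))
    for (k in seq_len(nrow(p)))
      in_region <- in_region | (bg >= p$start[k] & bg < p$end[k])
    pos <- c(bg[!in_region], reg_pos)
    idx <- c(rep(NA_integer_, sum(!in_region)), reg_idx)
    o <- order(pos)
    data.frame(chrom = ch, pos = as.integer(pos[o]), region = idx[o],
               stringsAsFactors = FALSE)
  }))
  grid <- grid[order(grid$chrom, grid$pos), ]

  set.seed(rng_seed)
  draw <- function(mu) {
    if (is.infinite(beta_concentration)) return(mu)
    fixed <- mu <= 0 | mu >= 1
    out <- mu
    if (any(!fixed)) {
      m <- mu[!fixed]
      out[!fixed] <- stats::rbeta(length(m), m * beta_concentration,
                                  (1 - m) * beta_concentration)
    }
    out
  }
  mean_for <- function(class) {
    mu <- rep(background_mean, nrow(grid))
    in_reg <- !is.na(grid$region)
    mu[in_reg] <- if (class == "target") pr$target_mean[grid$region[in_reg]]
                  else pr$panel_mean[grid$region[in_reg]]
    mu
  }
  make_track <- function(class, id) {
    meth <- draw(mean_for(class))
    cov <- if (is.null(coverage_lambda)) NULL
           else stats::rpois(nrow(grid), coverage_lambda)
    methylome_track(grid$chrom, grid$pos, meth, cov, id)
  }
  target <- lapply(seq_len(n_target_reps), function(i)
    make_track("target", sprintf("target_rep%d", i)))
  panel <- lapply(seq_len(n_panel), function(i)
    make_track("panel", sprintf("panel_%02d", i)))
  attr(pr, "background_mean") <- background_mean
  list(target = target, panel = panel, manifest = pr)
}

#' Write a full simulated dataset to a directory
#'
#' Emits expression TSVs with group maps, bedGraph methylomes, a BED12
#' annotation, and the ground-truth manifests as TSV — the file set the
#' `simulate` CLI subcommand produces.
#'
#' @param dir Output directory (created if needed).
#' @param expr Result of [simulate_expression()]; optional.
#' @param meth Result of [simulate_methylomes()]; optional.
#' @param annotation A [gene_annotation()]; optional.
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(dir, expr = NULL, meth = NULL,
                                    annotation = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  if (!is.null(expr)) {
    write_expression_matrix(expr$tissue, p("tissue_tpm.tsv"),
                            p("tissue_groups.tsv"))
    write_expression_matrix(expr$culture, p("culture_fpkm.tsv"),
                            p("culture_groups.tsv"))
    write_table(expr$manifest, p("expression_manifest.tsv"))
  }
  if (!is.null(meth)) {
    for (tr in c(meth$target, meth$panel))
      write_bedgraph_methylome(tr, p(paste0(attr(tr, "sample_id"),
                                            ".bedGraph")))
    write_table(meth$manifest, p("methylation_manifest.tsv"))
  }
  if (!is.null(annotation))
    write_annotation(annotation, p("annotation.bed"))
  invisible(dir)
}
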