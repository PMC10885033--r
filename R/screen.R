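#' Filter the gene universe shared by the tissue and culture datasets
#'
#' A gene enters the screening universe iff it (i) is present in both
#' expression matrices, (ii) is protein-coding (or on the explicit
#' whitelist of non-coding genes to keep), (iii) is not mitochondrially
#' located, and (iv) shows appreciable expression — at least one tissue
#' and at least one culture at or above the expression floor.
#'
#' @param tissue_mat Tissue [expression_matrix()] (TPM).
#' @param culture_mat Cell-culture [expression_matrix()] (FPKM).
#' @param annotation A [gene_annotation()]; genes absent from it are
#'   treated as biotype `other` (excluded unless whitelisted).
#' @param config A [run_config()] (supplies the floor).
#' @param whitelist Character vector of non-protein-coding gene ids to keep
#'   anyway. Mito genes are never kept.
#' @return Character vector of gene ids, in tissue-matrix order.
#' @export
filter_gene_universe <- function(tissue_mat, culture_mat, annotation,
                                 config = run_config(),
                                 whitelist = character()) {
  shared <- intersect(gene_ids(tissue_mat), gene_ids(culture_mat))
  if (!length(shared))
    stop("tissue and culture matrices share no gene ids")
  shared <- gene_ids(tissue_mat)[gene_ids(tissue_mat) %in% shared]
  biotype <- stats::setNames(annotation$biotype, annotation$gene_id)[shared]
  biotype[is.na(biotype)] <- "other"
  E <- config$expression_floor
  keep_bt <- (biotype == "protein_coding" | shared %in% whitelist) &
    biotype != "mito"
  t_ok <- apply(tissue_mat$values[shared, , drop = FALSE] >= E, 1L, any)
  c_ok <- apply(culture_mat$values[shared, , drop = FALSE] >= E, 1L, any)
  shared[keep_bt & t_ok & c_ok]
}

#' Call genes preferentially expressed in one cell culture
#'
#' A gene passes for the target culture iff its FPKM there divided by the
#' unweighted mean FPKM of the other cultures is at least the ratio
#' threshold, and its FPKM in the target is at least the expression floor.
#' If the other-culture mean is exactly 0 while the target meets the floor,
#' the gene passes with ratio `Inf` (the only way to be "5-fold above"
#' nothing is to be expressed at all).
#'
#' @param culture_mat Cell-culture [expression_matrix()].
#' @param target_culture Sample id of the culture of interest.
#' @param config A [run_config()].
#' @param genes Optional gene universe to restrict to (e.g. from
#'   [filter_gene_universe()]); default all genes of the matrix.
#' @return A list with `set` (character vector of passing gene ids, in
#'   matrix order) and `calls` (per-gene data.frame: `gene_id`, `context`,
#'   `numerator`, `denominator`, `ratio`, `passed`).
#' @export
call_culture_preferential <- function(culture_mat, target_culture,
                                      config = run_config(), genes = NULL) {
  if (!target_culture %in% sample_ids(culture_mat))
    stop("target culture absent from matrix: ", target_culture)
  if (ncol(culture_mat$values) < 2L)
    stop("need at least two culture samples")
  if (is.null(genes)) genes <- gene_ids(culture_mat)
  v <- culture_mat$values[genes, , drop = FALSE]
  num <- v[, target_culture]
  others <- setdiff(sample_ids(culture_mat), target_culture)
  den <- rowMeans(v[, others, drop = FALSE])
  R <- config$ratio_threshold; E <- config$expression_floor
  ratio <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, NaN))
  passed <- num >= E & ifelse(den > 0, num / den >= R, num >= E)
  calls <- data.frame(gene_id = genes, context = target_culture,
                      numerator = num, denominator = den, ratio = ratio,
                      passed = passed, row.names = NULL,
                      stringsAsFactors = FALSE)
  list(set = genes[passed], calls = calls)
}

#' Call genes preferentially expressed in cerebellum
#'
#' A gene passes iff its cerebellum TPM is at least the expression floor,
#' and its ratio to the central tendency of the 10 other brain regions
#' (median by default) and to the mean of the 41 non-brain tissues both
#' meet the ratio threshold. When a denominator is exactly 0 the
#' corresponding criterion instead passes iff the cerebellum TPM is
#' positive and strictly the maximum over all tissues (the
#' zero-denominator rescue); such passes are flagged `rescue_applied`.
#'
#' @param tissue_mat Tissue [expression_matrix()]; its group map must label
#'   exactly one sample `cerebellum` and at least one each of
#'   `brain_other` / `non_brain`.
#' @param config A [run_config()].
#' @param genes Optional gene universe restriction.
#' @return A list with `set` and `calls` (columns `gene_id`, `context`,
#'   `numerator`, `denom_brain`, `denom_nonbrain`, `ratio_brain`,
#'   `ratio_nonbrain` — `NA` where the denominator is 0 —, `passed`,
#'   `rescue_applied`).
#' @export
call_cerebellum_preferential <- function(tissue_mat, config = run_config(),
                                         genes = NULL) {
  g <- group_of(tissue_mat)
  cbl <- names(g)[g == "cerebellum"]
  bo <- names(g)[g == "brain_other"]
  nb <- names(g)[g == "non_brain"]
  if (length(cbl) != 1L || !length(bo) || !length(nb))
    stop("group cardinalities wrong: need exactly one cerebellum sample ",
         "plus brain_other and non_brain samples")
  if (is.null(genes)) genes <- gene_ids(tissue_mat)
  v <- tissue_mat$values[genes, , drop = FALSE]
  num <- v[, cbl]
  ct <- function(x, how) if (how == "median") stats::median(x) else mean(x)
  den_b <- apply(v[, bo, drop = FALSE], 1L, ct, config$brain_central_tendency)
  den_n <- apply(v[, nb, drop = FALSE], 1L, ct, config$nonbrain_central_tendency)
  R <- config$ratio_threshold; E <- config$expression_floor
  others_max <- apply(v[, c(bo, nb), drop = FALSE], 1L, max)
  is_strict_max <- num > 0 & num > others_max
  crit <- function(den) ifelse(den > 0, num / den >= R, is_strict_max)
  crit_b <- crit(den_b); crit_n <- crit(den_n)
  passed <- num >= E & crit_b & crit_n
  rescue <- passed & (den_b == 0 | den_n == 0)
  calls <- data.frame(
    gene_id = genes, context = "cerebellum", numerator = num,
    denom_brain = den_b, denom_nonbrain = den_n,
    ratio_brain = ifelse(den_b > 0, num / den_b, NA_real_),
    ratio_nonbrain = ifelse(den_n > 0, num / den_n, NA_real_),
    passed = passed, rescue_applied = rescue,
    row.names = NULL, stringsAsFactors = FALSE)
  list(set = genes[passed], calls = calls)
}

#' Intersect two preferential-expression gene sets
#'
#' @param setA,setB Character vectors of gene ids.
#' @return The intersection, ordered by gene id.
#' @export
intersect_dual <- function(setA, setB) {
  sort(intersect(setA, setB))
}

#' Per-culture overlap with a cerebellum-preferential set
#'
#' Runs the culture-preferential call for every culture of the matrix (each
#' against the mean of the others) and intersects each resulting set with
#' the given cerebellum set.
#'
#' @param culture_mat Cell-culture [expression_matrix()].
#' @param cbl_set Character vector of cerebellum-preferential gene ids.
#' @param config A [run_config()].
#' @param genes Optional gene universe restriction.
#' @return A data.frame with one row per culture: `culture`,
#'   `n_preferential`, `n_overlap`, and a list-column `genes` of the
#'   overlapping ids (sorted).
#' @export
overlap_matrix <- function(culture_mat, cbl_set, config = run_config(),
                           genes = NULL) {
  cultures <- sample_ids(culture_mat)
  sets <- lapply(cultures, function(cu)
    call_culture_preferential(culture_mat, cu, config, genes)$set)
  overlaps <- lapply(sets, intersect_dual, cbl_set)
  out <- data.frame(culture = cultures,
                    n_preferential = lengths(sets),
                    n_overlap = lengths(overlaps),
                    stringsAsFactors = FALSE)
  out$genes <- overlaps
  out
}
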