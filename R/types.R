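#' Construct an expression matrix with sample-group labels
#'
#' The central expression container: a genes x samples matrix of
#' non-negative TPM or FPKM values plus a group label per sample. Tissue
#' runs use groups `"cerebellum"`, `"brain_other"` and `"non_brain"`;
#' cell-culture runs use the culture name as its own group.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). No negatives, no NAs.
#' @param unit `"TPM"` or `"FPKM"`.
#' @param groups Named character vector mapping every sample id to exactly
#'   one group label.
#' @return An object of class `"expr_matrix"`.
#' @examples
#' v <- matrix(c(1, 2, 0, 5, 3, 3), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
#' em <- expression_matrix(v, "TPM", c(s1 = "cerebellum", s2 = "non_brain"))
#' @export
expression_matrix <- function(values, unit = c("TPM", "FPKM"), groups) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (anyNA(values))
    stop("missing expression values are not allowed")
  if (any(values < 0))
    stop("negative expression values are not allowed")
  groups <- groups[colnames(values)]
  if (anyNA(groups) || is.null(names(groups)))
    stop("every sample must have exactly one group label")
  structure(list(values = values, unit = unit,
                 groups = stats::setNames(as.character(groups),
                                          colnames(values))),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]; groups: %s\n",
              nrow(x$values), ncol(x$values), x$unit,
              paste(unique(group_of(x)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Accessors for expression matrices
#'
#' @param mat An [expression_matrix()].
#' @return Character vector of gene ids / sample ids.
#' @export
gene_ids <- function(mat) rownames(mat$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(mat) colnames(mat$values)

group_of <- function(mat) stats::setNames(mat$groups, colnames(mat$values))

#' Construct a per-CpG methylome track
#'
#' Ordered per-CpG records for one sample: chromosome, 0-based cytosine
#' position, methylation fraction in \[0, 1\], and optional read coverage.
#' Positions must be strictly increasing within each chromosome (records are
#' sorted by chromosome, then position, on construction; duplicated
#' positions are an error).
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 0-based CpG cytosine positions.
#' @param meth Numeric vector of methylation fractions in \[0, 1\].
#' @param coverage Optional non-negative integer vector of read coverage;
#'   `NULL` (the default) disables coverage filtering for this sample.
#' @param sample_id Identifier of the sample.
#' @return A data.frame of class `"methylome_track"` with attribute
#'   `sample_id`, columns `chrom`, `pos`, `meth` (and `coverage` if given).
#' @export
methylome_track <- function(chrom, pos, meth, coverage = NULL,
                            sample_id = "sample") {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(meth) == n)
  if (anyNA(meth) || any(meth < 0) || any(meth > 1))
    stop("methylation fractions must lie in [0, 1]")
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   meth = as.numeric(meth), stringsAsFactors = FALSE)
  if (!is.null(coverage)) {
    stopifnot(length(coverage) == n)
    if (any(coverage < 0)) stop("coverage must be >= 0")
    df$coverage <- as.integer(coverage)
  }
  o <- order(df$chrom, df$pos)
  df <- df[o, , drop = FALSE]
  dup <- unlist(tapply(df$pos, df$chrom, function(p) duplicated(p)),
                use.names = FALSE)
  if (any(dup))
    stop("positions must be strictly increasing within a chromosome")
  rownames(df) <- NULL
  attr(df, "sample_id") <- sample_id
  class(df) <- c("methylome_track", "data.frame")
  df
}

#' Construct a gene annotation table
#'
#' Internal coordinates are uniformly 0-based half-open; the TSS is `start`
#' for plus-strand genes and `end - 1` for minus-strand genes.
#'
#' @param gene_id Character vector of unique gene ids.
#' @param chrom Chromosome per gene.
#' @param start,end 0-based half-open gene body interval, `start < end`.
#' @param strand `"+"` or `"-"` per gene.
#' @param biotype One of `"protein_coding"`, `"ncRNA"`, `"mito"`, `"other"`.
#' @return A data.frame of class `"gene_annotation"` with an added `tss`
#'   column.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand,
                            biotype = "protein_coding") {
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) stop("duplicate gene ids in annotation")
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  start <- as.integer(start); end <- as.integer(end)
  if (any(end <= start)) stop("gene end must exceed start")
  biotype <- rep_len(as.character(biotype), n)
  ok_bt <- c("protein_coding", "ncRNA", "mito", "other")
  if (!all(biotype %in% ok_bt))
    stop("biotype must be one of: ", paste(ok_bt, collapse = ", "))
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   start = start, end = end,
                   strand = as.character(strand),
                   tss = ifelse(strand == "+", start, end - 1L),
                   biotype = biotype,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

# Minimal constructors used by the callers; plain data.frames with a class
# tag so downstream code can sanity-check what it receives.
new_dmr_table <- function(chrom = character(), start = integer(),
                          end = integer(), direction = character(),
                          n_cpgs = integer(), mean_delta = numeric()) {
  df <- data.frame(chrom = chrom, start = as.integer(start),
                   end = as.integer(end), direction = direction,
                   n_cpgs = as.integer(n_cpgs),
                   mean_delta = as.numeric(mean_delta),
                   stringsAsFactors = FALSE)
  class(df) <- c("dmr_table", "data.frame")
  df
}

new_lmr_table <- function(chrom = character(), start = integer(),
                          end = integer(), n_cpgs = integer(),
                          mean_meth = numeric(), genome_baseline = numeric()) {
  df <- data.frame(chrom = chrom, start = as.integer(start),
                   end = as.integer(end), n_cpgs = as.integer(n_cpgs),
                   mean_meth = as.numeric(mean_meth),
                   genome_baseline = as.numeric(genome_baseline),
                   stringsAsFactors = FALSE)
  class(df) <- c("lmr_table", "data.frame")
  df
}
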