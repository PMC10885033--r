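#' Read a genes x samples expression matrix from delimited text
#'
#' Expects tab-separated text with a header row of sample ids and gene ids
#' in the first column. Every cell must parse as a non-negative real;
#' missing cells are an error. The group map is a two-column TSV
#' (`sample_id`, `group`) covering every sample of the matrix (a literal
#' `sample_id<TAB>group` header line is tolerated and skipped).
#'
#' @param path Path to the expression TSV.
#' @param unit `"TPM"` or `"FPKM"`.
#' @param group_map Either a path to the two-column group-map TSV or a named
#'   character vector `sample_id -> group`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, unit = c("TPM", "FPKM"), group_map) {
  unit <- match.arg(unit)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("expression file needs a gene-id column and >=1 sample")
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals))
    stop("expression matrix contains non-numeric or missing cells")
  rownames(vals) <- ids
  if (is.character(group_map) && length(group_map) == 1L && is.null(names(group_map)))
    group_map <- read_group_map(group_map)
  expression_matrix(vals, unit, group_map)
}

read_group_map <- function(path) {
  gm <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(gm) != 2L) stop("group map must have exactly two columns")
  if (identical(tolower(as.character(gm[1L, ])), c("sample_id", "group")))
    gm <- gm[-1L, , drop = FALSE]
  stats::setNames(as.character(gm[[2L]]), as.character(gm[[1L]]))
}

#' Write an expression matrix (and optionally its group map) to TSV
#'
#' @param mat An [expression_matrix()].
#' @param path Output TSV path.
#' @param group_map_path Optional path for the two-column group map.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, group_map_path = NULL) {
  df <- data.frame(gene_id = gene_ids(mat), mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(group_map_path)) {
    gm <- data.frame(sample_id = sample_ids(mat), group = mat$groups)
    utils::write.table(gm, group_map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a per-CpG methylome from bedGraph
#'
#' Accepts 4 or 5 columns: chrom, start, end, methylation fraction and an
#' optional coverage column. Each record must be a single CpG cytosine
#' (`end == start + 1`), fractions must lie in \[0, 1\], and positions must
#' be sorted strictly increasing within each chromosome.
#'
#' @param path Path to the bedGraph file. Lines starting with `track` or
#'   `#` are skipped.
#' @param sample_id Identifier to attach to the track.
#' @return A [methylome_track()].
#' @export
read_bedgraph_methylome <- function(path, sample_id = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines) & nzchar(lines)]
  if (!length(lines)) stop("empty bedGraph: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- unique(lengths(parts))
  if (length(ncol) != 1L || !(ncol %in% 4:5))
    stop("bedGraph must have a uniform 4 or 5 columns")
  m <- matrix(unlist(parts), ncol = ncol, byrow = TRUE)
  start <- as.integer(m[, 2L]); end <- as.integer(m[, 3L])
  if (any(end != start + 1L))
    stop("bedGraph records must be single-base CpG cytosines (end == start + 1)")
  meth <- as.numeric(m[, 4L])
  if (anyNA(meth) || any(meth < 0) || any(meth > 1))
    stop("methylation fraction outside [0, 1]")
  chrom <- m[, 1L]
  # constructor sorts; an out-of-order input is rejected, not silently fixed
  o <- order(chrom, start)
  if (!identical(o, seq_along(start)))
    stop("bedGraph positions are not sorted within chromosome")
  coverage <- if (ncol == 5L) as.integer(m[, 5L]) else NULL
  methylome_track(chrom, start, meth, coverage, sample_id)
}

#' Write a methylome track as bedGraph
#'
#' @param track A [methylome_track()].
#' @param path Output path. Coverage, when present, is written as a 5th
#'   column.
#' @return `path`, invisibly.
#' @export
write_bedgraph_methylome <- function(track, path) {
  df <- data.frame(track$chrom, track$pos, track$pos + 1L,
                   format(track$meth, trim = TRUE, scientific = FALSE,
                          digits = 15))
  if (!is.null(track$coverage)) df$cov <- track$coverage
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation from BED12 or minimal GTF
#'
#' BED12 is 0-based half-open and is kept as is; the writer of this package
#' encodes the biotype in the name column as `gene_id|biotype`. GTF is
#' 1-based closed and is converted to 0-based half-open here — this is the
#' single conversion site of the package. Only GTF lines with feature
#' `gene` are used; `gene_id` and (if present) `gene_biotype` are taken
#' from the attributes column.
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (by extension), `"bed12"` or `"gtf"`.
#' @return A [gene_annotation()].
#' @export
read_annotation <- function(path, format = c("auto", "bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "bed12"
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "bed12") {
    if (any(lengths(parts) < 6L)) stop("BED annotation needs >= 6 columns")
    m <- t(vapply(parts, function(p) p[1:6], character(6)))
    name <- strsplit(m[, 4L], "|", fixed = TRUE)
    gene_id <- vapply(name, `[`, "", 1L)
    biotype <- vapply(name, function(x)
      if (length(x) >= 2L) x[2L] else "protein_coding", "")
    gene_annotation(gene_id, m[, 1L], as.integer(m[, 2L]),
                    as.integer(m[, 3L]), m[, 6L], biotype)
  } else {
    keep <- vapply(parts, function(p) length(p) >= 9L && p[3L] == "gene",
                   logical(1))
    parts <- parts[keep]
    if (!length(parts)) stop("no 'gene' features in GTF: ", path)
    attr_field <- function(attrs, key) {
      m <- regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs))
      if (!length(m)) return(NA_character_)
      sub(paste0(key, ' "([^"]*)"'), "\\1", m)
    }
    gene_id <- vapply(parts, function(p) attr_field(p[9L], "gene_id"), "")
    biotype <- vapply(parts, function(p) {
      b <- attr_field(p[9L], "gene_biotype")
      if (is.na(b)) "protein_coding" else b
    }, "")
    chrom <- vapply(parts, `[`, "", 1L)
    start1 <- as.integer(vapply(parts, `[`, "", 4L))
    end1 <- as.integer(vapply(parts, `[`, "", 5L))
    strand <- vapply(parts, `[`, "", 7L)
    # GTF 1-based closed [start1, end1] -> 0-based half-open [start1-1, end1)
    gene_annotation(gene_id, chrom, start1 - 1L, end1, strand, biotype)
  }
}

#' Write a gene annotation as BED12 or minimal GTF
#'
#' @param ann A [gene_annotation()].
#' @param path Output path.
#' @param format `"bed12"` (name column `gene_id|biotype`) or `"gtf"`
#'   (coordinates converted back to 1-based closed, biotype in
#'   `gene_biotype`).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, format = c("bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "bed12") {
    n <- nrow(ann)
    df <- data.frame(ann$chrom, ann$start, ann$end,
                     paste0(ann$gene_id, "|", ann$biotype), 0L, ann$strand,
                     ann$start, ann$end, "0,0,0", 1L,
                     ann$end - ann$start, 0L)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    attrs <- sprintf('gene_id "%s"; gene_biotype "%s";',
                     ann$gene_id, ann$biotype)
    df <- data.frame(ann$chrom, "methylscreen", "gene",
                     ann$start + 1L, ann$end, ".", ann$strand, ".", attrs)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write called DMRs as BED6 plus annotation columns
#'
#' Columns: chrom, start, end, name (`dmr_<i>_<direction>`), score
#' (`round(1000 * |mean_delta|)`, browser convention), strand (`.`), then
#' `n_cpgs`, `mean_delta`, `direction`.
#'
#' @param dmrs A DMR table from [call_dmrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmrs_bed <- function(dmrs, path) {
  n <- nrow(dmrs)
  df <- data.frame(dmrs$chrom, dmrs$start, dmrs$end,
                   if (n) paste0("dmr_", seq_len(n), "_", dmrs$direction)
                   else character(),
                   if (n) round(1000 * abs(dmrs$mean_delta)) else integer(),
                   rep(".", n),
                   dmrs$n_cpgs,
                   if (n) format(dmrs$mean_delta, trim = TRUE,
                                 scientific = FALSE, digits = 15)
                   else character(),
                   dmrs$direction)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read back a DMR BED written by [write_dmrs_bed()]
#'
#' @param path Path to the BED6+3 file.
#' @return A DMR table (chrom, start, end, direction, n_cpgs, mean_delta).
#' @export
read_dmrs_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(new_dmr_table())
  m <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  if (ncol(m) < 9L) stop("expected BED6 + n_cpgs/mean_delta/direction columns")
  new_dmr_table(m[, 1L], as.integer(m[, 2L]), as.integer(m[, 3L]),
                m[, 9L], as.integer(m[, 7L]), as.numeric(m[, 8L]))
}

#' Write any tabular report as TSV
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
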