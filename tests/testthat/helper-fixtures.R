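# Small in-code fixture builders shared across test files.

# A tissue-shaped expression matrix (1 cerebellum + 10 brain_other +
# 41 non_brain) from a per-gene value function.
make_tissue_matrix <- function(values) {
  groups <- c(cerebellum = "cerebellum",
              setNames(rep("brain_other", 10), sprintf("bo%02d", 1:10)),
              setNames(rep("non_brain", 41), sprintf("nb%02d", 1:41)))
  stopifnot(ncol(values) == 52)
  colnames(values) <- names(groups)
  expression_matrix(values, "TPM", groups)
}

# A 6-culture matrix from a genes x 6 value matrix.
make_culture_matrix <- function(values) {
  cultures <- c("Myoblast", "NHLF", "NHEK", "HUVEC", "LCL", "ESC")
  stopifnot(ncol(values) == 6)
  colnames(values) <- cultures
  expression_matrix(values, "FPKM", setNames(cultures, cultures))
}

# Random delta series on a single chromosome; mix of candidate and
# sub-threshold deltas, occasional large positional gaps.
random_delta_series <- function(n, gap_mix = c(20, 50, 400)) {
  gaps <- sample(gap_mix, n, replace = TRUE,
                 prob = c(0.6, 0.3, 0.1))
  data.frame(chrom = "chrR", pos = cumsum(gaps),
             delta = round(runif(n, -1, 1), 2),
             stringsAsFactors = FALSE)
}

# Random methylome track on one chromosome.
random_track <- function(n, sample_id = "r") {
  methylome_track(rep("chrR", n), cumsum(sample(c(20, 100, 400), n, TRUE)),
                  round(runif(n), 3), sample_id = sample_id)
}

table1_fixture_path <- function() {
  system.file("extdata", "table1_myob_cbl_dmr_counts.tsv",
              package = "methylscreen")
}
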