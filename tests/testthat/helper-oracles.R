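# Independent oracles and small shared fixtures, written from first
# principles so they never share code with the implementation they check.

# Product-moment correlation from the raw-sums formula.
pcc_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# Pooled-variance two-sample t statistic, textbook form.
t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# A two-gene annotation with midpoints exactly `gap_bp` apart.
two_gene_annotation <- function(gap_bp = 1000) {
  annotation_table(tibble::tibble(
    gene_id = c("gA", "gB"), chromosome = "chr1",
    start = c(500, 500 + gap_bp), end = c(900, 900 + gap_bp),
    strand = "+"
  ))
}

# Small simulation config used across tests.
quick_config <- function(...) {
  sim_config(n_chromosomes = 1, genes_per_chromosome = 9,
             n_blocks = 2, samples_per_block = 10, seed = 11L, ...)
}
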