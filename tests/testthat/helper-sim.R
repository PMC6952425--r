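# Small shared fixtures for the tests.

# Hand-built gene-model tibble with a chrom_sizes attribute.
make_genes <- function(..., sizes) {
  g <- tibble::tibble(...)
  attr(g, "chrom_sizes") <- sizes
  g
}

# Hand-built read set from parallel vectors.
make_reads <- function(chrom, start, end, strand = "+", total = NULL,
                       sizes = NULL) {
  n <- max(length(chrom), length(start), length(end), length(strand))
  rs <- polprof::read_set(
    tibble::tibble(chrom = rep_len(chrom, n), start = rep_len(start, n),
                   end = rep_len(end, n), strand = rep_len(strand, n)),
    total_mapped = if (is.null(total)) n else total)
  if (!is.null(sizes)) attr(rs, "chrom_sizes") <- sizes
  rs
}

# A small, fast study configuration used across module tests: one 120-kb
# chromosome, 20 genes, modest depth. Same model as the default study, just
# smaller.
small_config <- function(seed = 1L, ...) {
  polprof::sim_config(
    chrom_length = 120000, n_genes = 20,
    gene_classes = list(
      coact = polprof::gene_class(
        6,
        multipliers = list(control = c(up = 1), smk1 = c(up = 0.5)),
        tata_prob = 0.8,
        de = c(mutant_vs_wt = 2, smk1_vs_control = -2))),
    depth = 2e4, seed = seed, ...)
}

# Build a set-level enrichment profile object directly from bin values, for
# tests of the window comparison that need exact inputs.
make_profile <- function(rel, enrichment, bin_size = 60, anchor = "tss") {
  structure(tibble::tibble(rel = rel, enrichment = enrichment),
            aggregate = "set_mean", pseudocount = 1, anchor = anchor,
            flank = max(abs(rel)) + bin_size, bin_size = bin_size,
            n_body_bins = 100,
            class = c("enrichment_profile", class(tibble::tibble())))
}
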