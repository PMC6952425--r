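# Shared coordinate helpers. All genomic intervals in this package are
# 0-based half-open [start, end); anchors and relative positions are in
# transcription direction (negative = upstream of the anchor).

#' Transcription start sites of gene models
#'
#' For a plus-strand gene the TSS is the interval start; for a minus-strand
#' gene it is `end - 1` (the last base of the 0-based half-open interval).
#' "Downstream" always means the direction of transcription.
#'
#' @param genes A gene-model tibble with columns `chrom`, `start`, `end`,
#'   `strand` (0-based half-open coordinates).
#' @return Integer vector of TSS positions, one per gene.
#' @export
tss_position <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' Transcription end sites of gene models
#'
#' The TES is the final transcribed base: `end - 1` for plus-strand genes,
#' the interval start for minus-strand genes.
#'
#' @inheritParams tss_position
#' @return Integer vector of TES positions, one per gene.
#' @export
tes_position <- function(genes) {
  ifelse(genes$strand == "+", genes$end - 1L, genes$start)
}

# Map a transcription-direction interval [rel_lo, rel_hi) around an anchor
# to genomic 0-based half-open coordinates.
rel_to_genomic <- function(anchor, strand, rel_lo, rel_hi) {
  plus <- strand == "+"
  gstart <- ifelse(plus, anchor + rel_lo, anchor - rel_hi + 1L)
  gend <- ifelse(plus, anchor + rel_hi, anchor - rel_lo + 1L)
  list(start = as.integer(gstart), end = as.integer(gend))
}

# Deterministic per-operation RNG stream: hash the operation label and fold
# it into the user seed, staying inside the 32-bit integer range.
op_seed <- function(seed, op) {
  h <- 0
  for (k in utf8ToInt(op)) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_op_seed <- function(seed, op, code) {
  withr::with_seed(op_seed(seed, op), code)
}

# Truncated standard normal on [-4, 4] via inverse-CDF sampling.
rnorm_trunc4 <- function(n) {
  lo <- pnorm(-4)
  qnorm(runif(n, lo, 1 - lo))
}

chrom_sizes_of <- function(genes, chrom_sizes = NULL) {
  if (!is.null(chrom_sizes)) return(chrom_sizes)
  attr(genes, "chrom_sizes")
}

assert_gene_models <- function(genes) {
  need <- c("chrom", "start", "end", "strand", "gene_id")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0) {
    abort(paste0("gene models are missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  invisible(genes)
}
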