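#' Construct a read set
#'
#' A read set is a tibble of aligned single-end reads (`chrom`, `start`,
#' `end`, `strand`; 0-based half-open) carrying the library's total mapped
#' read count as an attribute. The total is what densities are normalised
#' by, so it must not change when reads are subset or extended.
#'
#' @param reads Data frame with columns `chrom`, `start`, `end`, `strand`.
#' @param total_mapped Total mapped reads of the library; defaults to
#'   `nrow(reads)`.
#' @param fragment_length Optional fragment-extension length associated
#'   with the library.
#' @return A `read_set` tibble.
#' @export
read_set <- function(reads, total_mapped = nrow(reads),
                     fragment_length = NULL) {
  reads <- as_tibble(reads)
  need <- c("chrom", "start", "end", "strand")
  miss <- setdiff(need, names(reads))
  if (length(miss) > 0) {
    abort(paste0("read set is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(reads$start >= reads$end)) abort("reads must satisfy start < end")
  if (total_mapped < nrow(reads)) {
    abort("total_mapped cannot be smaller than the number of records")
  }
  structure(reads, total_mapped = total_mapped,
            fragment_length = fragment_length,
            class = c("read_set", class(reads)))
}

#' Total mapped reads of a read set
#' @param reads A [read_set()].
#' @return The stored total mapped count.
#' @export
total_mapped <- function(reads) {
  tm <- attr(reads, "total_mapped")
  if (is.null(tm)) nrow(reads) else tm
}

#' Extend reads to fragment length
#'
#' Replaces every read by the `length`-bp interval starting at its 5' end
#' in read-strand direction (the standard fragment-extension step before
#' coverage computation), clipping at chromosome boundaries when sizes are
#' known. The total mapped count is unchanged.
#'
#' @param reads A [read_set()].
#' @param length Extension length in bp.
#' @param chrom_sizes Optional named vector of chromosome lengths used for
#'   clipping (taken from the `chrom_sizes` attribute if present).
#' @return A [read_set()] of extended fragments.
#' @export
extend_reads <- function(reads, length = 200, chrom_sizes = NULL) {
  chrom_sizes <- chrom_sizes %||% attr(reads, "chrom_sizes")
  plus <- reads$strand == "+"
  start <- ifelse(plus, reads$start, reads$end - length)
  end <- ifelse(plus, reads$start + length, reads$end)
  start <- pmax(start, 0)
  if (!is.null(chrom_sizes)) {
    end <- pmin(end, unname(chrom_sizes[reads$chrom]))
  }
  out <- tibble(chrom = reads$chrom, start = as.integer(start),
                end = as.integer(end), strand = reads$strand)
  rs <- read_set(out, total_mapped = total_mapped(reads),
                 fragment_length = length)
  attr(rs, "chrom_sizes") <- chrom_sizes
  rs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

reads_granges <- function(reads) {
  GenomicRanges::GRanges(reads$chrom,
                         IRanges::IRanges(reads$start + 1L, reads$end))
}
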