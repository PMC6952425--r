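#' Specify a core-promoter motif search
#'
#' A motif is an IUPAC consensus scanned in a window relative to the TSS
#' on the sense strand (optionally both orientations). The defaults follow
#' common core-promoter practice: TATA-box `TATAWAWR` in `[-100, 0)` and
#' initiator `YYANWYY` in `[-5, +5)`.
#'
#' @param name Motif label.
#' @param consensus IUPAC consensus string.
#' @param window Length-2 integer, search window in bp relative to the
#'   TSS (transcription direction, half-open).
#' @param both_strands Also scan the reverse complement of the consensus.
#' @return A `motif_spec` list.
#' @export
motif_spec <- function(name, consensus, window, both_strands = FALSE) {
  if (nchar(consensus) == 0) abort("consensus must be non-empty")
  bad <- setdiff(strsplit(toupper(consensus), "")[[1]],
                 names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad) > 0) {
    abort(paste0("consensus contains non-IUPAC letters: ",
                 paste(bad, collapse = ", ")))
  }
  structure(list(name = name, consensus = toupper(consensus),
                 window = as.integer(window), both_strands = both_strands),
            class = "motif_spec")
}

#' @rdname motif_spec
#' @export
tata_motif <- function() motif_spec("TATA", "TATAWAWR", c(-100L, 0L))

#' @rdname motif_spec
#' @export
inr_motif <- function() motif_spec("Inr", "YYANWYY", c(-5L, 5L))

#' Sense-strand promoter sequences around TSSs
#'
#' Extracts the window of a motif specification around every TSS on the
#' sense strand (reverse-complemented for minus-strand genes). Genes whose
#' window falls outside the chromosome are skipped with a warning count.
#'
#' @param genes Gene models.
#' @param sequence A [Biostrings::DNAStringSet] of chromosome sequences.
#' @param window Length-2 integer window relative to the TSS.
#' @return Named [Biostrings::DNAStringSet] (names = gene ids) for the
#'   genes whose window is in bounds.
#' @export
promoter_sequences <- function(genes, sequence, window = c(-100L, 0L)) {
  assert_gene_models(genes)
  anchors <- tss_position(genes)
  g <- rel_to_genomic(anchors, genes$strand, window[1], window[2])
  sizes <- setNames(Biostrings::width(sequence), names(sequence))
  ok <- g$start >= 0 & g$end <= unname(sizes[genes$chrom]) &
    genes$chrom %in% names(sequence)
  if (any(!ok)) {
    warn(paste0(sum(!ok), " gene(s) skipped: promoter window outside sequence"))
  }
  idx <- which(ok)
  if (length(idx) == 0) return(Biostrings::DNAStringSet())
  out <- Biostrings::DNAStringSet(vapply(idx, function(j) {
    s <- Biostrings::subseq(sequence[[genes$chrom[j]]],
                            g$start[j] + 1L, g$end[j])
    if (genes$strand[j] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1)))
  names(out) <- genes$gene_id[idx]
  out
}

#' Promoter motif enrichment in a gene set
#'
#' Scans the motif consensus (IUPAC-aware) in each gene's promoter window
#' and tests whether hits are over-represented in the gene set relative to
#' the union of set and background, with the one-sided hypergeometric test.
#'
#' @param genes Gene models covering both sets.
#' @param sequence Chromosome sequences ([Biostrings::DNAStringSet]).
#' @param set,background Character vectors of gene ids.
#' @param motif A [motif_spec()] (default [tata_motif()]).
#' @return One-row tibble: `motif_name`, `consensus`, `window_lo`, `window_hi`,
#'   `n_set`, `hits_set`, `n_background`, `hits_background`, `p`.
#' @export
motif_enrichment <- function(genes, sequence, set, background,
                             motif = tata_motif()) {
  stopifnot(inherits(motif, "motif_spec"))
  ids <- unique(c(set, background))
  missing <- setdiff(ids, genes$gene_id)
  if (length(missing) > 0) {
    abort(paste0("gene ids absent from gene models: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  sub <- genes[genes$gene_id %in% ids, ]
  proms <- promoter_sequences(sub, sequence, motif$window)
  hit <- motif_hits(proms, motif)
  hit_ids <- names(proms)[hit]
  set_in <- intersect(set, names(proms))
  bg_in <- intersect(background, names(proms))
  uni <- union(set_in, bg_in)
  k <- length(intersect(set_in, hit_ids))
  K <- length(intersect(uni, hit_ids))
  p <- exp(phyper(k - 1, K, length(uni) - K, length(set_in),
                  lower.tail = FALSE, log.p = TRUE))
  tibble(motif_name = motif$name, consensus = motif$consensus,
         window_lo = motif$window[1], window_hi = motif$window[2],
         n_set = length(set_in), hits_set = k,
         n_background = length(bg_in),
         hits_background = length(intersect(bg_in, hit_ids)),
         p = p)
}

#' IUPAC motif hits in a set of sequences
#'
#' @param seqs A [Biostrings::DNAStringSet].
#' @param motif A [motif_spec()].
#' @return Logical vector: does each sequence contain at least one match?
#' @export
motif_hits <- function(seqs, motif) {
  if (length(seqs) == 0) return(logical(0))
  n <- Biostrings::vcountPattern(motif$consensus, seqs, fixed = FALSE)
  if (motif$both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(motif$consensus)))
    n <- n + Biostrings::vcountPattern(rc, seqs, fixed = FALSE)
  }
  n > 0
}
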