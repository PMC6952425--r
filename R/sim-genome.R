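#' Generate a toy genome with non-overlapping gene models
#'
#' Places `n_genes` non-overlapping genes (roughly half per strand) on
#' random-nucleotide chromosomes, separated by gaps of at least 1 kb, and
#' records every planted property (class, occupancy multipliers, TATA-box
#' planting, DE effects) in a truth table. Genes flagged for TATA planting
#' carry a `TATAAAAG` instance on the sense strand at -30 +/- 5 bp from
#' their TSS.
#'
#' @param config A [sim_config()] object.
#' @param with_sequence Generate the nucleotide sequence (default). Large
#'   simulation sweeps that only need coordinates can skip it; the
#'   `sequence` element is then an empty set and no motifs are planted
#'   (truth records `tata_planted` as drawn, but there is no sequence to
#'   carry the instances).
#' @return A list with elements
#'   \describe{
#'     \item{genes}{Tibble of gene models (`chrom`, `start`, `end`,
#'       `strand`, `gene_id`, `class`), 0-based half-open, with a
#'       `chrom_sizes` attribute.}
#'     \item{sequence}{A [Biostrings::DNAStringSet] of chromosome
#'       sequences.}
#'     \item{truth}{Tibble with one row per gene recording class,
#'       `tata_planted`, applied per-condition component multipliers
#'       (`mult_<condition>_<component>` columns) and planted log2
#'       fold-changes (`de_<contrast>` columns).}
#'   }
#' @export
simulate_genome <- function(config, with_sequence = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_op_seed(config$seed, "genome", {
    chroms <- paste0("chr", seq_len(config$n_chroms))
    sizes <- setNames(rep(config$chrom_length, config$n_chroms), chroms)

    make_seqs <- function() {
      if (!with_sequence) return(Biostrings::DNAStringSet())
      Biostrings::DNAStringSet(vapply(chroms, function(ch) {
        paste(sample(c("A", "C", "G", "T"), config$chrom_length,
                     replace = TRUE), collapse = "")
      }, character(1)))
    }

    if (config$n_genes == 0) {
      genes <- tibble(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      gene_id = character(), class = character())
      attr(genes, "chrom_sizes") <- sizes
      return(list(genes = genes, sequence = make_seqs(), truth = tibble()))
    }

    # even split of genes across chromosomes
    per_chrom <- rep(config$n_genes %/% config$n_chroms, config$n_chroms)
    extra <- config$n_genes %% config$n_chroms
    if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L

    gap_min <- 1000L
    lens_all <- integer(0)
    starts_all <- integer(0)
    chrom_all <- character(0)
    for (i in seq_len(config$n_chroms)) {
      n <- per_chrom[i]
      if (n == 0) next
      excess <- max(config$mean_gene_length - config$min_gene_length, 0)
      lens <- config$min_gene_length +
        if (excess > 0) as.integer(round(rexp(n, 1 / excess))) else 0L
      slack <- config$chrom_length - sum(lens) - (n + 1L) * gap_min
      if (slack < 0) {
        abort(paste0("genome too small: chromosome ", chroms[i],
                     " cannot hold ", n, " genes with >=1 kb gaps"))
      }
      w <- runif(n + 1)
      extra_gap <- floor(slack * w / sum(w))
      gaps <- gap_min + extra_gap
      starts <- cumsum(gaps[seq_len(n)] + c(0L, lens[-n]))
      lens_all <- c(lens_all, lens)
      starts_all <- c(starts_all, as.integer(starts))
      chrom_all <- c(chrom_all, rep(chroms[i], n))
    }

    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    gene_id <- sprintf("g%04d", seq_len(config$n_genes))

    class_names <- names(config$gene_classes)
    class_vec <- rep(class_names,
                     vapply(config$gene_classes, `[[`, integer(1), "n"))
    class_vec <- sample(class_vec) # decouple class from genomic position

    genes <- tibble(chrom = chrom_all, start = starts_all,
                    end = starts_all + lens_all, strand = strand,
                    gene_id = gene_id, class = class_vec)
    attr(genes, "chrom_sizes") <- sizes

    # TATA planting on the sense strand at -30 +/- 5
    tata_prob <- vapply(config$gene_classes, `[[`, numeric(1), "tata_prob")
    tata_planted <- rbinom(config$n_genes, 1, tata_prob[class_vec]) == 1
    motif <- "TATAAAAG"
    seqs <- make_seqs()
    if (with_sequence && any(tata_planted)) {
      anchors <- tss_position(genes)
      for (j in which(tata_planted)) {
        off <- -30L + sample(-5:5, 1)
        g <- rel_to_genomic(anchors[j], genes$strand[j], off,
                            off + nchar(motif))
        if (g$start < 0 || g$end > sizes[[genes$chrom[j]]]) next
        ins <- if (genes$strand[j] == "+") motif else {
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(motif)))
        }
        seqs[[genes$chrom[j]]] <- Biostrings::replaceAt(
          seqs[[genes$chrom[j]]],
          IRanges::IRanges(g$start + 1L, g$end), ins)
      }
    }

    truth <- tibble(gene_id = gene_id, class = class_vec,
                    tata_planted = tata_planted)
    for (cond in sim_conditions(config)) {
      mult <- t(vapply(class_vec,
                       function(cl) class_multipliers(config, cl, cond),
                       numeric(4)))
      for (comp in c("up", "pause", "body", "tes")) {
        truth[[paste0("mult_", cond, "_", comp)]] <- mult[, comp]
      }
    }
    contrasts <- unique(unlist(lapply(config$gene_classes,
                                      function(cl) names(cl$de))))
    for (ctr in contrasts) {
      lfc <- vapply(class_vec, function(cl) {
        de <- config$gene_classes[[cl]]$de
        if (is.null(de) || !ctr %in% names(de)) 0 else unname(de[[ctr]])
      }, numeric(1))
      truth[[paste0("de_", ctr)]] <- lfc
    }

    list(genes = genes, sequence = seqs, truth = truth)
  })
}
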