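# File interchange. Gene models and reads travel as BED/GFF3/SAM, genome
# sequence as FASTA, tables as TSV, simulation configs as YAML. All
# on-disk interval formats follow their native conventions (BED 0-based
# half-open, GFF3/SAM 1-based) and are converted to the package's 0-based
# half-open tibbles on read.

#' Read gene models from BED or GFF3
#'
#' Uses `rtracklayer` to parse the file and converts to the package's
#' 0-based half-open tibble convention (GFF3 starts are shifted by -1).
#'
#' @param path BED (6 or 12 column) or GFF3 file.
#' @return Gene-model tibble (`chrom`, `start`, `end`, `strand`,
#'   `gene_id`).
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading gene models requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  ids <- if (!is.null(gr$name)) gr$name else
    if (!is.null(gr$ID)) gr$ID else sprintf("g%04d", seq_along(gr))
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)),
         gene_id = as.character(ids))
}

#' Write gene models as BED12
#'
#' Single-block BED12 records (whole gene as one block), scores 0.
#'
#' @param genes Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed12 <- function(genes, path) {
  assert_gene_models(genes)
  bed <- tibble(chrom = genes$chrom, start = genes$start, end = genes$end,
                name = genes$gene_id, score = 0L, strand = genes$strand,
                thick_start = genes$start, thick_end = genes$end,
                rgb = "0,0,0", block_count = 1L,
                block_sizes = paste0(genes$end - genes$start, ","),
                block_starts = "0,")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' @param genes Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  assert_gene_models(genes)
  lines <- c("##gff-version 3",
             sprintf("%s\tpolprof\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start + 1L, genes$end,
                     genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write reads as 6-column BED
#'
#' Columns: chrom, start, end, name, score, strand (BED convention,
#' 0-based half-open).
#'
#' @param reads A [read_set()].
#' @param path File path.
#' @param total_mapped Total mapped count to attach on read (defaults to
#'   the number of records).
#' @return `write_reads_bed()` returns `path` invisibly;
#'   `read_reads_bed()` returns a [read_set()].
#' @export
write_reads_bed <- function(reads, path) {
  out <- tibble(chrom = reads$chrom, start = reads$start, end = reads$end,
                name = sprintf("r%07d", seq_len(nrow(reads))),
                score = 0L, strand = reads$strand)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_reads_bed
#' @export
read_reads_bed <- function(path, total_mapped = NULL) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                            "score", "strand"),
                        col_types = "ciicic", progress = FALSE)
  read_set(df[c("chrom", "start", "end", "strand")],
           total_mapped = total_mapped %||% nrow(df))
}

#' Write reads as coordinate-sorted SAM
#'
#' Minimal unpaired alignments: flag 0/16, MAPQ 255, CIGAR `<len>M`,
#' sequence and qualities omitted (`*`).
#'
#' @param reads A [read_set()].
#' @param path Output path.
#' @param chrom_sizes Named vector of chromosome lengths for the header
#'   (defaults to the `chrom_sizes` attribute).
#' @return `path`, invisibly.
#' @export
write_reads_sam <- function(reads, path, chrom_sizes = NULL) {
  chrom_sizes <- chrom_sizes %||% attr(reads, "chrom_sizes")
  if (is.null(chrom_sizes)) {
    m <- tapply(reads$end, reads$chrom, max)
    chrom_sizes <- setNames(as.integer(m), names(m))
  }
  ord <- order(match(reads$chrom, names(chrom_sizes)), reads$start)
  r <- reads[ord, ]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                      as.integer(chrom_sizes)))
  body <- sprintf("r%07d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                  seq_len(nrow(r)), ifelse(r$strand == "-", 16L, 0L),
                  r$chrom, r$start + 1L, r$end - r$start)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read single-end reads from a SAM/BAM file
#'
#' SAM files are converted through `Rsamtools`; the alignment flag gives
#' the strand and `total_mapped` defaults to the number of records.
#'
#' @param path SAM or BAM file.
#' @param total_mapped Optional library total.
#' @return A [read_set()].
#' @export
read_reads_sam <- function(path, total_mapped = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("reading SAM/BAM requires the Rsamtools package")
  }
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth", "strand", "cigar")))[[1]]
  keep <- !is.na(res$pos)
  len <- vapply(res$cigar[keep], function(cg) {
    sum(as.integer(regmatches(cg, gregexpr("[0-9]+(?=[MDN=X])", cg,
                                           perl = TRUE))[[1]]))
  }, numeric(1))
  df <- tibble(chrom = as.character(res$rname[keep]),
               start = res$pos[keep] - 1L,
               end = res$pos[keep] - 1L + as.integer(len),
               strand = as.character(res$strand[keep]))
  read_set(df, total_mapped = total_mapped %||% nrow(df))
}

#' Write chromosome sequences as FASTA
#' @param sequence A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(sequence, path) {
  Biostrings::writeXStringSet(sequence, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write a set-level profile as TSV
#'
#' One row per bin: `rel`, `ip_mean`, `input_mean`, `enrichment`.
#'
#' @param profile An `enrichment_profile` (set-level).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path)
  invisible(path)
}

#' Save and load a simulation configuration as YAML
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$gene_classes <- lapply(x$gene_classes, function(cl) {
    cl <- unclass(cl)
    if (!is.null(cl$multipliers)) {
      cl$multipliers <- lapply(cl$multipliers, as.list)
    }
    if (!is.null(cl$de)) cl$de <- as.list(cl$de)
    cl
  })
  x$amplitudes <- as.list(x$amplitudes)
  if (!is.null(x$tes_shift)) x$tes_shift <- as.list(x$tes_shift)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  classes <- lapply(x$gene_classes, function(cl) {
    gene_class(cl$n,
               multipliers = if (!is.null(cl$multipliers))
                 lapply(cl$multipliers, unlist),
               tata_prob = cl$tata_prob %||% 0,
               de = if (!is.null(cl$de)) unlist(cl$de),
               de_power = cl$de_power %||% 0.9)
  })
  sim_config(n_chroms = x$n_chroms, chrom_length = x$chrom_length,
             n_genes = x$n_genes, min_gene_length = x$min_gene_length,
             mean_gene_length = x$mean_gene_length, gene_classes = classes,
             amplitudes = unlist(x$amplitudes),
             pause_center = x$pause_center,
             upstream_center = x$upstream_center, peak_sd = x$peak_sd,
             tes_shift = if (!is.null(x$tes_shift)) unlist(x$tes_shift),
             background_rate = x$background_rate, depth = x$depth,
             fragment_length = x$fragment_length, seed = x$seed)
}
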