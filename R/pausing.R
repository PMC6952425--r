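#' Genome-wide input-normalised binned ratio track
#'
#' Tiles every chromosome with fixed-width bins, computes RPKM-scaled
#' densities (count x 1e9 / (bin bp x total mapped)) for the IP and input
#' libraries after fragment extension, and returns their per-bin ratio
#' with a pseudocount guard — the track pausing indices are read from.
#'
#' @param ip,input [read_set()] objects on the same genome.
#' @param chrom_sizes Named vector of chromosome lengths (defaults to the
#'   `chrom_sizes` attribute of `ip`, then of `input`).
#' @param bin_size Bin width in bp (default 60).
#' @param extend Fragment-extension length applied to both libraries
#'   before counting (default 200).
#' @param pseudocount Added to numerator and denominator RPKM.
#' @return A `ratio_track` tibble: `chrom`, `start`, `end`, `rpkm_ip`,
#'   `rpkm_input`, `ratio`.
#' @export
ratio_track <- function(ip, input, chrom_sizes = NULL, bin_size = 60,
                        extend = 200, pseudocount = 1) {
  chrom_sizes <- chrom_sizes %||% attr(ip, "chrom_sizes") %||%
    attr(input, "chrom_sizes")
  if (is.null(chrom_sizes)) {
    mx <- function(r) tapply(r$end, r$chrom, max)
    m <- mx(bind_rows(as_tibble(ip)[c("chrom", "end")],
                      as_tibble(input)[c("chrom", "end")]) %>%
              rename(chrom = "chrom"))
    chrom_sizes <- setNames(as.integer(m), names(m))
  }
  tm_ip <- total_mapped(ip); tm_in <- total_mapped(input)
  if (tm_ip == 0 || tm_in == 0) abort("zero mapped reads in a library")

  bins <- purrr::map_dfr(names(chrom_sizes), function(ch) {
    size <- chrom_sizes[[ch]]
    starts <- seq(0L, size - 1L, by = bin_size)
    tibble(chrom = ch, start = as.integer(starts),
           end = as.integer(pmin(starts + bin_size, size)))
  })
  bin_gr <- GenomicRanges::GRanges(bins$chrom,
                                   IRanges::IRanges(bins$start + 1L, bins$end))
  count_lib <- function(reads) {
    ext <- extend_reads(reads, extend, chrom_sizes)
    GenomicRanges::countOverlaps(bin_gr, reads_granges(ext))
  }
  w <- bins$end - bins$start
  bins$rpkm_ip <- count_lib(ip) * 1e9 / (w * tm_ip)
  bins$rpkm_input <- count_lib(input) * 1e9 / (w * tm_in)
  bins$ratio <- (bins$rpkm_ip + pseudocount) / (bins$rpkm_input + pseudocount)
  structure(bins, bin_size = bin_size, pseudocount = pseudocount,
            chrom_sizes = chrom_sizes,
            class = c("ratio_track", class(tibble())))
}

# Overlap-weighted mean of the track ratio over arbitrary regions.
region_track_mean <- function(track, chrom, gstart, gend) {
  out <- rep(NA_real_, length(gstart))
  ok <- which(gend > gstart)
  if (length(ok) == 0) return(out)
  reg_gr <- GenomicRanges::GRanges(chrom[ok],
                                   IRanges::IRanges(gstart[ok] + 1L, gend[ok]))
  trk_gr <- GenomicRanges::GRanges(track$chrom,
                                   IRanges::IRanges(track$start + 1L, track$end))
  hits <- GenomicRanges::findOverlaps(reg_gr, trk_gr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- pmin(gend[ok][qi], track$end[si]) - pmax(gstart[ok][qi], track$start[si])
  num <- tapply(ov * track$ratio[si], qi, sum)
  den <- tapply(ov, qi, sum)
  out[ok][as.integer(names(num))] <- as.numeric(num / den)
  out
}

#' Promoter-proximal pausing indices
#'
#' For each gene, averages the input-normalised ratio track (overlap-
#' weighted at region edges) over the relaxed pausing region
#' (-500..+500 from the TSS), the stringent pausing region (TSS..+500) and
#' the gene body (+500..TES), all in transcription direction, and forms
#' the pausing index as pausing-region mean divided by body mean. Genes
#' whose body is shorter than one complete bin are excluded with a
#' recorded reason. The set-level index is the arithmetic mean of per-gene
#' indices over usable genes (see [glance()]).
#'
#' @param track A [ratio_track()].
#' @param genes Gene models (tibble with `chrom`, `start`, `end`,
#'   `strand`, `gene_id`).
#' @param gene_set Optional character vector restricting to a gene set.
#' @param min_body_bp Minimum body length in bp for a gene to be usable
#'   (default 60, one complete bin).
#' @param body_floor Genes with body mean at or below this value are
#'   excluded (default 0; with a positive pseudocount the body mean is
#'   always positive, so no gene is excluded by the floor by default).
#' @return A `pausing_result` tibble: `gene_id`, `relaxed`, `stringent`,
#'   `body_mean`, `usable`, `exclusion_reason`.
#' @export
pausing_indices <- function(track, genes, gene_set = NULL, min_body_bp = 60,
                            body_floor = 0) {
  assert_gene_models(genes)
  if (!is.null(gene_set)) {
    missing <- setdiff(gene_set, genes$gene_id)
    if (length(missing) > 0) {
      abort(paste0("gene set ids absent from gene models: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    genes <- genes[genes$gene_id %in% gene_set, ]
  }
  L <- genes$end - genes$start
  tssg <- tss_position(genes)
  reg <- function(lo, hi) rel_to_genomic(tssg, genes$strand, lo, hi)
  relaxed_g <- reg(-500L, 500L)
  stringent_g <- reg(0L, 500L)
  body_g <- reg(500L, L)

  relaxed_m <- region_track_mean(track, genes$chrom, relaxed_g$start, relaxed_g$end)
  stringent_m <- region_track_mean(track, genes$chrom, stringent_g$start, stringent_g$end)
  body_m <- region_track_mean(track, genes$chrom, body_g$start, body_g$end)

  body_len <- L - 500L
  reason <- rep(NA_character_, nrow(genes))
  reason[body_len < min_body_bp] <- "body_shorter_than_one_bin"
  low <- is.na(reason) & (is.na(body_m) | body_m <= body_floor)
  reason[low] <- "body_mean_at_or_below_floor"
  usable <- is.na(reason)

  out <- tibble(gene_id = genes$gene_id,
                relaxed = ifelse(usable, relaxed_m / body_m, NA_real_),
                stringent = ifelse(usable, stringent_m / body_m, NA_real_),
                body_mean = body_m, usable = usable,
                exclusion_reason = reason)
  if (!any(usable)) {
    tab <- table(reason)
    abort(paste0("no usable genes for pausing indices (",
                 paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                       collapse = ", "), ")"))
  }
  structure(out, min_body_bp = min_body_bp,
            class = c("pausing_result", class(tibble())))
}

#' Per-gene pausing indices as a plain tibble
#' @param x A `pausing_result`.
#' @param ... Unused.
#' @return The per-gene tibble.
#' @export
tidy.pausing_result <- function(x, ...) as_tibble(x)

#' Set-level pausing-index summary
#'
#' Arithmetic mean of per-gene indices over usable genes, per region
#' definition.
#'
#' @param x A `pausing_result`.
#' @param ... Unused.
#' @return Tibble with columns `region`, `index`, `n_genes`.
#' @export
glance.pausing_result <- function(x, ...) {
  ok <- x$usable
  tibble(region = c("relaxed", "stringent"),
         index = c(mean(x$relaxed[ok]), mean(x$stringent[ok])),
         n_genes = sum(ok))
}
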