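#' Binned, depth-normalised read densities around anchors
#'
#' Counts extended fragments overlapping fixed-width bins around a genomic
#' anchor (TSS, TES or peak summit) or over the scaled gene body, and
#' normalises to reads per kilobase per million mapped reads
#' (count x 1e9 / (bin width x total mapped)). A fragment increments every
#' bin it overlaps. Bins are enumerated in transcription direction, so for
#' minus-strand genes positive relative coordinates run genomically
#' right-to-left. Bins extending beyond chromosome bounds are kept but
#' flagged missing (`NA` density).
#'
#' @param reads A [read_set()] of (already extended) fragments; see
#'   [extend_reads()].
#' @param genes Gene models or anchor intervals: a tibble with `chrom`,
#'   `start`, `end`, and optionally `strand` (default `"+"`), `gene_id`
#'   and, for `anchor = "summit"`, a `summit` column giving the summit
#'   offset from `start`.
#' @param anchor One of `"tss"`, `"tes"`, `"summit"`, `"genebody"`.
#' @param flank Half-window in bp for fixed-width anchors; must be a
#'   multiple of `bin_size`.
#' @param bin_size Bin width in bp for fixed-width anchors.
#' @param n_body_bins Number of equal parts the gene body is divided into
#'   when `anchor = "genebody"` (default 100, i.e. 1% bins); bin labels are
#'   then body-percent indices `0 .. n_body_bins - 1`.
#' @param chrom_sizes Named vector of chromosome lengths (defaults to the
#'   `chrom_sizes` attribute of `genes`); used to flag out-of-bounds bins.
#' @param library Optional library label (`"ip"` / `"input"`) stored with
#'   the profile.
#' @return A `density_profile` tibble with columns `gene_id`, `rel` (bin
#'   start relative to the anchor, or body-percent index), `width`,
#'   `count` and `density`.
#' @export
bin_density <- function(reads, genes,
                        anchor = c("tss", "tes", "summit", "genebody"),
                        flank = 600, bin_size = 60, n_body_bins = 100,
                        chrom_sizes = NULL, library = NULL) {
  anchor <- match.arg(anchor)
  tm <- total_mapped(reads)
  if (tm == 0) abort("read set has zero total mapped reads")
  genes <- as_tibble(genes)
  if (!"strand" %in% names(genes)) genes$strand <- "+"
  if (!"gene_id" %in% names(genes)) {
    genes$gene_id <- if ("name" %in% names(genes)) genes$name else
      sprintf("iv%04d", seq_len(nrow(genes)))
  }
  chrom_sizes <- chrom_sizes_of(genes, chrom_sizes)

  empty <- tibble(gene_id = character(), rel = numeric(), width = integer(),
                  count = integer(), density = numeric())
  if (nrow(genes) == 0) {
    return(new_density_profile(empty, anchor, flank, bin_size, n_body_bins,
                               library, tm))
  }

  if (anchor == "genebody") {
    if (n_body_bins < 1) abort("n_body_bins must be >= 1")
    L <- genes$end - genes$start
    idx <- rep(seq_len(nrow(genes)), each = n_body_bins)
    j <- rep(seq_len(n_body_bins) - 1L, times = nrow(genes))
    lo <- floor(j * L[idx] / n_body_bins)
    hi <- floor((j + 1L) * L[idx] / n_body_bins)
    tssg <- tss_position(genes)
    g <- rel_to_genomic(tssg[idx], genes$strand[idx], lo, hi)
    bins <- tibble(gene_id = genes$gene_id[idx], rel = as.numeric(j),
                   chrom = genes$chrom[idx], gstart = g$start, gend = g$end)
  } else {
    if (flank %% bin_size != 0) abort("flank must be a multiple of bin_size")
    rel_starts <- seq(-flank, flank - bin_size, by = bin_size)
    anchors <- switch(anchor,
      tss = tss_position(genes),
      tes = tes_position(genes),
      summit = if ("summit" %in% names(genes)) genes$start + genes$summit
               else (genes$start + genes$end) %/% 2L)
    idx <- rep(seq_len(nrow(genes)), each = length(rel_starts))
    rel <- rep(rel_starts, times = nrow(genes))
    g <- rel_to_genomic(anchors[idx], genes$strand[idx], rel, rel + bin_size)
    bins <- tibble(gene_id = genes$gene_id[idx], rel = as.numeric(rel),
                   chrom = genes$chrom[idx], gstart = g$start, gend = g$end)
  }
  bins$width <- bins$gend - bins$gstart

  oob <- bins$gstart < 0
  if (!is.null(chrom_sizes)) {
    oob <- oob | bins$gend > unname(chrom_sizes[bins$chrom])
  }
  bins$count <- 0L
  ok <- !oob & bins$width > 0
  if (any(ok) && nrow(reads) > 0) {
    bin_gr <- GenomicRanges::GRanges(
      bins$chrom[ok], IRanges::IRanges(bins$gstart[ok] + 1L, bins$gend[ok]))
    bins$count[ok] <- GenomicRanges::countOverlaps(bin_gr, reads_granges(reads))
  }
  bins$count[oob] <- NA_integer_
  bins$density <- bins$count * 1e9 / (bins$width * tm)

  out <- bins %>% select("gene_id", "rel", "width", "count", "density")
  new_density_profile(out, anchor, flank, bin_size, n_body_bins, library, tm)
}

new_density_profile <- function(df, anchor, flank, bin_size, n_body_bins,
                                library, total_mapped) {
  structure(df, anchor = anchor, flank = flank, bin_size = bin_size,
            n_body_bins = n_body_bins, library = library,
            total_mapped = total_mapped,
            class = c("density_profile", class(tibble())))
}

profile_params <- function(p) {
  list(anchor = attr(p, "anchor"), flank = attr(p, "flank"),
       bin_size = attr(p, "bin_size"), n_body_bins = attr(p, "n_body_bins"))
}

#' Fold enrichment of IP over input densities
#'
#' Divides the normalised IP read density of every bin by the corresponding
#' input density. The default (`aggregate = "set_mean"`) first averages
#' densities over genes per bin and then takes the ratio, which is how
#' set-level profiles are plotted; `"per_gene"` takes gene-wise ratios. A
#' pseudocount (in density units) is added to numerator and denominator to
#' guard zero-input bins. Bins missing in either library for a gene
#' (chromosome edge) are excluded pairwise from the aggregation.
#'
#' @param ip,input `density_profile` objects from [bin_density()] with the
#'   same anchor parameters and gene list.
#' @param pseudocount Density added to numerator and denominator
#'   (default 1.0; 0 is allowed).
#' @param aggregate `"set_mean"` (mean densities, then ratio) or
#'   `"per_gene"` (gene-wise ratios).
#' @param genes Optional character vector restricting the profiles to a
#'   gene set before aggregation.
#' @return An `enrichment_profile` tibble: for `set_mean`, columns `rel`,
#'   `ip_mean`, `input_mean`, `enrichment`, `n_genes`; for `per_gene`,
#'   columns `gene_id`, `rel`, `ip`, `input`, `enrichment`.
#' @export
fold_enrichment <- function(ip, input, pseudocount = 1,
                            aggregate = c("set_mean", "per_gene"),
                            genes = NULL) {
  aggregate <- match.arg(aggregate)
  pi_ <- profile_params(ip); pn <- profile_params(input)
  if (!identical(pi_, pn)) abort("ip and input profiles differ in anchor parameters")
  if (!setequal(unique(ip$gene_id), unique(input$gene_id))) {
    abort("ip and input profiles differ in gene lists")
  }
  if (!setequal(unique(ip$rel), unique(input$rel))) {
    abort("ip and input profiles differ in bin labels")
  }
  if (!is.null(genes)) {
    missing <- setdiff(genes, unique(ip$gene_id))
    if (length(missing) > 0) {
      abort(paste0("gene set contains ids absent from the profile: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    ip <- ip[ip$gene_id %in% genes, ]
    input <- input[input$gene_id %in% genes, ]
  }
  joined <- dplyr::inner_join(
    as_tibble(ip)[c("gene_id", "rel", "density")],
    as_tibble(input)[c("gene_id", "rel", "density")],
    by = c("gene_id", "rel"), suffix = c("_ip", "_input")) %>%
    filter(!is.na(.data$density_ip) & !is.na(.data$density_input))

  eps <- pseudocount
  if (aggregate == "set_mean") {
    out <- joined %>%
      group_by(.data$rel) %>%
      summarise(ip_mean = mean(.data$density_ip),
                input_mean = mean(.data$density_input),
                n_genes = dplyr::n(), .groups = "drop") %>%
      mutate(enrichment = (.data$ip_mean + eps) / (.data$input_mean + eps)) %>%
      arrange(.data$rel) %>%
      select("rel", "ip_mean", "input_mean", "enrichment", "n_genes")
  } else {
    out <- joined %>%
      rename(ip = "density_ip", input = "density_input") %>%
      mutate(enrichment = (.data$ip + eps) / (.data$input + eps)) %>%
      arrange(.data$gene_id, .data$rel)
  }
  structure(out, aggregate = aggregate, pseudocount = pseudocount,
            anchor = pi_$anchor, flank = pi_$flank, bin_size = pi_$bin_size,
            n_body_bins = pi_$n_body_bins,
            class = c("enrichment_profile", class(tibble())))
}
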