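#' Simulate an IP or input sequencing library
#'
#' Draws `depth` fragments whose 5' starts follow the compositional
#' occupancy model of the configuration: per gene, truncated Gaussians at
#' the upstream recruitment centre and at the promoter-proximal pause
#' centre, a uniform elongation component over `[TSS + 500, TES]`, and a
#' truncated Gaussian at the TES (plus any per-condition downstream
#' termination shift), all in strand-aware transcription-direction
#' coordinates, on top of genome-wide uniform background. Component weights
#' (`amplitudes` x class multipliers, background `background_rate` per kb)
#' are normalised jointly so each library totals `depth` fragments
#' (multinomial). Input libraries draw from the background alone.
#'
#' Reads are `fragment_length` bp long, anchored at their 5' start, carry
#' the strand of their gene (background reads: random strand), and are
#' clipped at chromosome boundaries; fragments falling entirely outside a
#' chromosome are dropped, which is the only way the returned library can
#' be smaller than `depth`.
#'
#' @param genes Gene models from [simulate_genome()].
#' @param config The [sim_config()] used to generate `genes`.
#' @param condition Condition label; must have multipliers for every class
#'   that declares any.
#' @param library `"ip"` or `"input"`.
#' @return A [read_set()]: tibble (`chrom`, `start`, `end`, `strand`) with
#'   `total_mapped` and `fragment_length` attributes.
#' @export
simulate_reads <- function(genes, config, condition,
                           library = c("ip", "input")) {
  stopifnot(inherits(config, "sim_config"))
  assert_gene_models(genes)
  library <- match.arg(library)
  if (!condition %in% sim_conditions(config)) {
    abort(paste0("unknown condition: '", condition, "'"))
  }
  sizes <- chrom_sizes_of(genes)
  total_len <- sum(sizes)
  flen <- config$fragment_length

  with_op_seed(config$seed, paste("reads", condition, library), {
    n_genes <- nrow(genes)
    if (library == "ip" && n_genes > 0) {
      mult <- t(vapply(genes$class,
                       function(cl) class_multipliers(config, cl, condition),
                       numeric(4)))
      w_comp <- sweep(mult, 2, config$amplitudes[c("up", "pause", "body", "tes")],
                      `*`) # genes x 4
    } else {
      w_comp <- matrix(0, nrow = n_genes, ncol = 4)
    }
    w_bg <- config$background_rate * total_len / 1000
    weights <- c(as.vector(w_comp), w_bg)
    counts <- as.vector(rmultinom(1, config$depth, weights / sum(weights)))
    cnt <- matrix(counts[seq_len(4 * n_genes)], nrow = n_genes, ncol = 4)
    n_bg <- counts[4 * n_genes + 1]

    tssg <- if (n_genes > 0) tss_position(genes) else integer(0)
    glen <- genes$end - genes$start
    shift <- 0
    if (!is.null(config$tes_shift) && condition %in% names(config$tes_shift)) {
      shift <- config$tes_shift[[condition]]
    }

    gauss_rel <- function(n_per_gene, center_per_gene) {
      idx <- rep.int(seq_along(n_per_gene), n_per_gene)
      rel <- round(center_per_gene[idx] +
                     config$peak_sd * rnorm_trunc4(sum(n_per_gene)))
      list(idx = idx, rel = rel)
    }

    up <- gauss_rel(cnt[, 1], rep(config$upstream_center, n_genes))
    pa <- gauss_rel(cnt[, 2], rep(config$pause_center, n_genes))
    te <- gauss_rel(cnt[, 4], (glen - 1) + shift)
    bidx <- rep.int(seq_len(n_genes), cnt[, 3])
    body <- list(idx = bidx,
                 rel = floor(runif(length(bidx), 500, glen[bidx])))

    idx <- c(up$idx, pa$idx, body$idx, te$idx)
    rel <- c(up$rel, pa$rel, body$rel, te$rel)
    plus <- genes$strand[idx] == "+"
    g5 <- ifelse(plus, tssg[idx] + rel, tssg[idx] - rel)
    sig <- tibble(chrom = genes$chrom[idx],
                  g5 = as.integer(g5),
                  strand = genes$strand[idx])

    # background: uniform over the concatenated genome, random strand
    if (n_bg > 0) {
      pos <- floor(runif(n_bg, 0, total_len))
      offs <- cumsum(c(0, as.numeric(sizes)))
      ci <- findInterval(pos, offs, rightmost.closed = FALSE)
      bg <- tibble(chrom = names(sizes)[ci],
                   g5 = as.integer(pos - offs[ci]),
                   strand = sample(c("+", "-"), n_bg, replace = TRUE))
    } else {
      bg <- tibble(chrom = character(), g5 = integer(), strand = character())
    }

    all <- bind_rows(sig, bg)
    plus <- all$strand == "+"
    start <- ifelse(plus, all$g5, all$g5 - flen + 1L)
    end <- ifelse(plus, all$g5 + flen, all$g5 + 1L)
    lim <- unname(sizes[all$chrom])
    start <- pmax(start, 0L)
    end <- pmin(end, lim)
    keep <- start < end
    reads <- tibble(chrom = all$chrom[keep],
                    start = as.integer(start[keep]),
                    end = as.integer(end[keep]),
                    strand = all$strand[keep]) %>%
      arrange(.data$chrom, .data$start, .data$end)
    read_set(reads, fragment_length = flen)
  })
}
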