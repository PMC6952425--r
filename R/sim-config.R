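#' Describe a gene class for the occupancy simulator
#'
#' A gene class groups genes that share occupancy multipliers, planted
#' promoter motifs and planted differential-expression effects. Multipliers
#' scale the four occupancy components (upstream recruitment, promoter-
#' proximal pause, gene-body elongation, termination) per condition; a class
#' declared without multipliers uses 1 for every component in every
#' condition.
#'
#' @param n Number of genes in the class.
#' @param multipliers Named list, one element per condition, each a named
#'   numeric vector with entries `up`, `pause`, `body`, `tes` (missing
#'   entries default to 1). `NULL` means all components 1 everywhere.
#' @param tata_prob Probability that a gene of this class carries a planted
#'   TATA-box instance in its core promoter (at -30 +/- 5 bp from the TSS).
#' @param de Named numeric vector of planted log2 fold-changes, one entry
#'   per differential-expression contrast (e.g.
#'   `c(mutant_vs_wt = 2, smk1_vs_control = -2)`). `NULL` means no planted
#'   expression effect.
#' @param de_power Probability that a planted expression effect is called
#'   significant in the simulated DE table.
#' @return A `gene_class` list.
#' @export
gene_class <- function(n, multipliers = NULL, tata_prob = 0, de = NULL,
                       de_power = 0.9) {
  stopifnot(n >= 0, tata_prob >= 0, tata_prob <= 1,
            de_power >= 0, de_power <= 1)
  if (!is.null(multipliers)) {
    for (cond in names(multipliers)) {
      m <- multipliers[[cond]]
      full <- c(up = 1, pause = 1, body = 1, tes = 1)
      full[names(m)] <- m
      if (any(full < 0)) abort("component multipliers must be >= 0")
      multipliers[[cond]] <- full
    }
  }
  structure(list(n = as.integer(n), multipliers = multipliers,
                 tata_prob = tata_prob, de = de, de_power = de_power),
            class = "gene_class")
}

#' Configure the synthetic Pol II occupancy study
#'
#' Bundles all parameters of the synthetic test bed: a toy genome, gene
#' models split into classes, and a compositional model of immunoprecipitated
#' fragment 5' starts. Per gene the model mixes a Gaussian upstream
#' recruitment component, a Gaussian promoter-proximal pause peak (default
#' centre +50), uniform gene-body elongation coverage over
#' `[TSS + 500, TES]`, and a Gaussian termination component at the TES
#' (optionally shifted downstream per condition), on top of genome-wide
#' uniform background. Input libraries draw from the background alone.
#'
#' The default configuration is the study design used throughout the
#' package's own validation: one 1-Mb chromosome, 200 genes of which 50
#' "coact" genes (co-activated targets) lose half their recruitment
#' component under the `smk1` condition, and 2e5 fragments per library.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_genes Total number of genes.
#' @param min_gene_length Minimum gene length in bp; must exceed
#'   `pause_center + 500` so that pausing regions fit inside genes.
#' @param mean_gene_length Mean of the (shifted-exponential) gene-length
#'   distribution.
#' @param gene_classes Named list of [gene_class()] objects. Class sizes
#'   must sum to at most `n_genes`; leftover genes form a `background`
#'   class with all multipliers 1.
#' @param amplitudes Named numeric `c(up=, pause=, body=, tes=)`: relative
#'   expected fragment weights per gene for the four components (scaled
#'   jointly with the background so that each library totals `depth`).
#' @param pause_center Pause-peak centre, bp downstream of the TSS.
#' @param upstream_center Recruitment-peak centre, bp relative to the TSS
#'   (negative = upstream).
#' @param peak_sd Standard deviation (bp) of the Gaussian components,
#'   truncated at +/- 4 sd.
#' @param tes_shift Named numeric, downstream shift (bp) of the termination
#'   component per condition; conditions not named shift by 0.
#' @param background_rate Background fragments per kb (relative weight).
#' @param depth Total fragments per library.
#' @param fragment_length Fragment (and simulated read) length in bp.
#' @param seed Integer master seed; every stochastic operation draws from a
#'   stream derived from `(seed, operation label)`.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_chroms = 1,
                       chrom_length = 1e6,
                       n_genes = 200,
                       min_gene_length = 2000,
                       mean_gene_length = 2500,
                       gene_classes = list(
                         coact = gene_class(
                           50,
                           multipliers = list(
                             control = c(up = 1),
                             smk1 = c(up = 0.5)
                           ),
                           tata_prob = 0.8,
                           de = c(mutant_vs_wt = 2, smk1_vs_control = -2)
                         )
                       ),
                       amplitudes = c(up = 30, pause = 100, body = 60,
                                      tes = 30),
                       pause_center = 50,
                       upstream_center = -150,
                       peak_sd = 80,
                       tes_shift = NULL,
                       background_rate = 20,
                       depth = 2e5,
                       fragment_length = 200,
                       seed = 1L) {
  amp <- c(up = 0, pause = 0, body = 0, tes = 0)
  amp[names(amplitudes)] <- amplitudes
  if (any(amp < 0)) abort("amplitudes must all be >= 0")
  if (depth <= 0) abort("depth must be > 0")
  if (min_gene_length <= pause_center + 500) {
    abort("min_gene_length must exceed pause_center + 500 so pausing regions fit")
  }
  if (!is.null(gene_classes)) {
    if (is.null(names(gene_classes)) || any(names(gene_classes) == "")) {
      abort("gene_classes must be a named list")
    }
    total <- sum(vapply(gene_classes, function(x) x$n, integer(1)))
    if (total > n_genes) abort("gene-class sizes sum to more than n_genes")
    if (total < n_genes && !"background" %in% names(gene_classes)) {
      gene_classes$background <- gene_class(n_genes - total)
    }
  } else if (n_genes > 0) {
    gene_classes <- list(background = gene_class(n_genes))
  }
  cfg <- structure(list(
    n_chroms = as.integer(n_chroms), chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes), min_gene_length = as.integer(min_gene_length),
    mean_gene_length = mean_gene_length, gene_classes = gene_classes,
    amplitudes = amp, pause_center = pause_center,
    upstream_center = upstream_center, peak_sd = peak_sd,
    tes_shift = tes_shift, background_rate = background_rate,
    depth = depth, fragment_length = as.integer(fragment_length),
    seed = as.integer(seed)), class = "sim_config")
  cfg
}

#' Conditions declared by a simulation configuration
#'
#' The union of condition names appearing in any class's multipliers or in
#' `tes_shift`; `"control"` if none are declared.
#'
#' @param config A [sim_config()] object.
#' @return Character vector of condition labels.
#' @export
sim_conditions <- function(config) {
  conds <- unlist(lapply(config$gene_classes,
                         function(cl) names(cl$multipliers)))
  conds <- union(conds, names(config$tes_shift))
  if (length(conds) == 0) "control" else unique(conds)
}

# Component multiplier lookup with the documented defaults: classes without
# explicit multipliers are 1 everywhere; classes with explicit multipliers
# must name the condition.
class_multipliers <- function(config, class_name, condition) {
  cl <- config$gene_classes[[class_name]]
  if (is.null(cl)) abort(paste0("unknown gene class: ", class_name))
  if (is.null(cl$multipliers)) {
    return(c(up = 1, pause = 1, body = 1, tes = 1))
  }
  m <- cl$multipliers[[condition]]
  if (is.null(m)) {
    abort(paste0("class '", class_name,
                 "' has no multipliers for condition '", condition, "'"))
  }
  m
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  genome:", x$n_chroms, "chromosome(s) x", x$chrom_length, "bp;",
      x$n_genes, "genes (>=", x$min_gene_length, "bp)\n")
  cat("  classes:", paste(sprintf("%s(n=%d)", names(x$gene_classes),
                                  vapply(x$gene_classes, `[[`, integer(1), "n")),
                          collapse = ", "), "\n")
  cat("  amplitudes: up", x$amplitudes[["up"]], "pause", x$amplitudes[["pause"]],
      "body", x$amplitudes[["body"]], "tes", x$amplitudes[["tes"]],
      "| background", x$background_rate, "/kb\n")
  cat("  depth:", x$depth, "fragments/library; fragment",
      x$fragment_length, "bp; seed", x$seed, "\n")
  invisible(x)
}
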