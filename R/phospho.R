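phospho_intensity_cols <- function(table, control = NULL, treatment = NULL) {
  control <- control %||% grep("^control_", names(table), value = TRUE)
  treatment <- treatment %||% grep("^treatment_", names(table), value = TRUE)
  if (length(control) < 2 || length(treatment) < 2) {
    abort("need at least 2 replicate columns per group (control_*/treatment_*)")
  }
  list(control = control, treatment = treatment)
}

#' Normalise phosphopeptide intensities to total signal
#'
#' Divides every intensity column by its column total, so each sample's
#' relative intensities sum to one. Idempotent.
#'
#' @param table Intensity table (tibble with `control_*`/`treatment_*`
#'   columns, or columns named in `control`/`treatment`).
#' @param control,treatment Optional explicit column names per group.
#' @return The table with normalised intensity columns.
#' @export
normalize_intensities <- function(table, control = NULL, treatment = NULL) {
  cols <- phospho_intensity_cols(table, control, treatment)
  for (col in c(cols$control, cols$treatment)) {
    total <- sum(table[[col]])
    if (total <= 0) abort(paste0("sample '", col, "' has zero total intensity"))
    table[[col]] <- table[[col]] / total
  }
  table
}

#' Differential phosphorylation per peptide
#'
#' Tests each peptide for an abundance difference between treatment and
#' control on log2-transformed relative intensities (zero intensities are
#' floored at half the smallest nonzero value in the table before the
#' log). The default test is the moderated t-test (empirical-Bayes
#' variance shrinkage via limma), which retains power at small replicate
#' numbers; `method = "welch"` runs per-peptide Welch t-tests instead.
#' P-values are Benjamini-Hochberg adjusted across peptides; a peptide is
#' flagged `increased` when its adjusted p falls below `alpha` and its
#' treatment mean exceeds its control mean. Peptides with identical values
#' in every replicate are degenerate and get p = 1.
#'
#' @param table Intensity table; see [normalize_intensities()] (applied
#'   internally when `normalize = TRUE`, the default).
#' @param control,treatment Optional explicit column names per group.
#' @param alpha Adjusted-p cutoff for the `increased` flag.
#' @param method `"moderated"` (default) or `"welch"`.
#' @param normalize Normalise to total signal first.
#' @return Tibble: `peptide_id`, `protein_id`, `site` (when present),
#'   `log2fc`, `p`, `p_adj`, `increased`, `degenerate`; the test method is
#'   stored in the `method` attribute.
#' @export
differential_phospho <- function(table, control = NULL, treatment = NULL,
                                 alpha = 0.05,
                                 method = c("moderated", "welch"),
                                 normalize = TRUE) {
  method <- match.arg(method)
  cols <- phospho_intensity_cols(table, control, treatment)
  if (normalize) {
    table <- normalize_intensities(table, cols$control, cols$treatment)
  }
  mat <- as.matrix(table[, c(cols$control, cols$treatment)])
  nz <- mat[mat > 0]
  if (length(nz) == 0) abort("all intensities are zero")
  floor_val <- min(nz) / 2
  mat[mat == 0] <- floor_val
  lmat <- log2(mat)

  nc <- length(cols$control); nt <- length(cols$treatment)
  grp <- rep(c(0, 1), c(nc, nt))
  degenerate <- apply(lmat, 1, function(v) max(v) == min(v))
  lfc <- rowMeans(lmat[, grp == 1, drop = FALSE]) -
    rowMeans(lmat[, grp == 0, drop = FALSE])

  if (method == "moderated") {
    design <- cbind(intercept = 1, treatment = grp)
    fit <- limma::eBayes(limma::lmFit(lmat, design))
    p <- fit$p.value[, "treatment"]
  } else {
    p <- apply(lmat, 1, function(v) {
      x <- v[grp == 1]; y <- v[grp == 0]
      if (sd(x) == 0 && sd(y) == 0) return(if (mean(x) == mean(y)) 1 else 0)
      t.test(x, y)$p.value
    })
  }
  p[degenerate] <- 1
  p_adj <- p.adjust(p, method = "BH")

  out <- tibble(peptide_id = table$peptide_id,
                protein_id = if ("protein_id" %in% names(table))
                  table$protein_id else NA_character_,
                log2fc = unname(lfc), p = unname(p), p_adj = unname(p_adj),
                increased = unname(p_adj < alpha & lfc > 0),
                degenerate = unname(degenerate))
  if ("site" %in% names(table)) {
    out <- dplyr::bind_cols(out[1:2], tibble(site = table$site), out[-(1:2)])
  }
  structure(out, method = method, alpha = alpha,
            class = c("phospho_diff", class(tibble())))
}

#' Rank candidate phosphatase substrates
#'
#' Collapses differential-phosphorylation results to proteins (best, i.e.
#' minimum, adjusted p among each protein's increased peptides), keeps
#' proteins that also scored in the reporter screen, and ranks ascending
#' by best adjusted p (ties broken by protein id). Co-purification with
#' the phosphatase complex is annotated but is not a filter.
#'
#' @param diff Result of [differential_phospho()].
#' @param reporter_hits Character vector of proteins that affected the
#'   reporter.
#' @param copurified Character vector of proteins found in the complex
#'   co-purification.
#' @return Tibble: `protein_id`, `best_p_adj`, `n_increased`,
#'   `reporter_hit` (all `TRUE` after filtering), `copurified`, `rank`.
#'   Empty when no protein qualifies.
#' @export
rank_candidates <- function(diff, reporter_hits, copurified = character(0)) {
  inc <- diff[diff$increased, ]
  if (nrow(inc) == 0) {
    return(tibble(protein_id = character(), best_p_adj = numeric(),
                  n_increased = integer(), reporter_hit = logical(),
                  copurified = logical(), rank = integer()))
  }
  as_tibble(inc) %>%
    group_by(.data$protein_id) %>%
    summarise(best_p_adj = min(.data$p_adj),
              n_increased = dplyr::n(), .groups = "drop") %>%
    filter(.data$protein_id %in% reporter_hits) %>%
    mutate(reporter_hit = TRUE,
           copurified = .data$protein_id %in% copurified) %>%
    arrange(.data$best_p_adj, .data$protein_id) %>%
    mutate(rank = row_number()) %>%
    select("protein_id", "best_p_adj", "n_increased", "reporter_hit",
           "copurified", "rank")
}
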