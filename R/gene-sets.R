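#' Build regulated gene sets from a differential-expression table
#'
#' Classifies genes at a false-discovery-rate cutoff. The primary contrast
#' `mutant_vs_wt` yields `up_in_mutant` / `down_in_mutant`; every other
#' contrast `X` (an RNAi vs control comparison within the mutant) yields
#' `activated_by_X` (significantly lower under the RNAi, i.e. the gene
#' requires X for activation) and `repressed_by_X` (significantly higher).
#'
#' @param de Expression table: `gene_id` plus, per contrast `X`, columns
#'   `log2fc_X` and `q_X` (q in `[0, 1]`).
#' @param fdr FDR cutoff on q (default 0.05).
#' @return Long tibble with columns `set` and `gene_id`.
#' @export
classify_regulated <- function(de, fdr = 0.05) {
  qcols <- grep("^q_", names(de), value = TRUE)
  contrasts <- sub("^q_", "", qcols)
  for (ctr in contrasts) {
    fc <- paste0("log2fc_", ctr)
    if (!fc %in% names(de)) abort(paste0("missing contrast column: ", fc))
  }
  if (length(contrasts) == 0) abort("missing contrast column: q_<contrast>")
  sets <- list()
  pick <- function(ctr, dir) {
    sig <- de[[paste0("q_", ctr)]] < fdr
    fc <- de[[paste0("log2fc_", ctr)]]
    de$gene_id[sig & (if (dir > 0) fc > 0 else fc < 0)]
  }
  if ("mutant_vs_wt" %in% contrasts) {
    sets$up_in_mutant <- pick("mutant_vs_wt", +1)
    sets$down_in_mutant <- pick("mutant_vs_wt", -1)
  }
  for (ctr in setdiff(contrasts, "mutant_vs_wt")) {
    lab <- sub("_vs_control$", "", ctr)
    sets[[paste0("activated_by_", lab)]] <- pick(ctr, -1)
    sets[[paste0("repressed_by_", lab)]] <- pick(ctr, +1)
  }
  purrr::imap_dfr(sets, function(g, nm) tibble(set = nm, gene_id = g))
}

#' Fraction of mutant expression changes suppressed by an RNAi
#'
#' Quantifies how much of the mutant-induced gene activation (or
#' repression) an RNAi knockdown reverses. Under the default
#' `opposing_significant` mode a gene counts as suppressed when the RNAi
#' vs control contrast within the mutant changes it significantly in the
#' direction opposing its mutant effect. Under `attenuated` it counts when
#' its fold-change versus wild type under the RNAi shrinks below
#' `attenuation` times the original mutant fold-change (computed from a
#' `log2fc_<rnai>_vs_wt` column if present, otherwise as the sum of the
#' within-mutant RNAi contrast and the mutant contrast).
#'
#' @param de Expression table as in [classify_regulated()].
#' @param set Which mutant set to assess: `"up_in_mutant"` or
#'   `"down_in_mutant"`.
#' @param rnai_contrast Name of the within-mutant RNAi contrast, e.g.
#'   `"smk1_vs_control"`.
#' @param fdr FDR cutoff (both for set construction and, in
#'   `opposing_significant` mode, for calling the reversal).
#' @param mode `"opposing_significant"` (default) or `"attenuated"`.
#' @param attenuation Fraction threshold for `attenuated` mode.
#' @return One-row tibble: `set`, `rnai_contrast`, `mode`, `n`,
#'   `n_suppressed`, `fraction`.
#' @export
suppression_fraction <- function(de, set = c("up_in_mutant", "down_in_mutant"),
                                 rnai_contrast, fdr = 0.05,
                                 mode = c("opposing_significant", "attenuated"),
                                 attenuation = 0.5) {
  set <- match.arg(set)
  mode <- match.arg(mode)
  for (col in c(paste0("q_", rnai_contrast), paste0("log2fc_", rnai_contrast))) {
    if (!col %in% names(de)) abort(paste0("missing contrast column: ", col))
  }
  sets <- classify_regulated(de, fdr)
  members <- sets$gene_id[sets$set == set]
  if (length(members) == 0) abort(paste0("set '", set, "' is empty"))
  d <- de[de$gene_id %in% members, ]
  dir <- if (set == "up_in_mutant") +1 else -1
  if (mode == "opposing_significant") {
    fc <- d[[paste0("log2fc_", rnai_contrast)]]
    q <- d[[paste0("q_", rnai_contrast)]]
    suppressed <- q < fdr & (if (dir > 0) fc < 0 else fc > 0)
  } else {
    vs_wt_col <- paste0("log2fc_", sub("_vs_control$", "", rnai_contrast),
                        "_vs_wt")
    fc_wt <- if (vs_wt_col %in% names(d)) d[[vs_wt_col]] else
      d$log2fc_mutant_vs_wt + d[[paste0("log2fc_", rnai_contrast)]]
    suppressed <- abs(fc_wt) < attenuation * abs(d$log2fc_mutant_vs_wt)
  }
  tibble(set = set, rnai_contrast = rnai_contrast, mode = mode,
         n = nrow(d), n_suppressed = sum(suppressed),
         fraction = sum(suppressed) / nrow(d))
}

#' Hypergeometric gene-set overlap test
#'
#' One-sided upper-tail test of whether two gene sets drawn from a common
#' universe overlap more than expected: `p = P[X >= |A intersect B|]` with
#' `X ~ Hypergeometric(N = |universe|, K = |A|, n = |B|)`, computed exactly
#' in log space.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe Character vector; both sets must be subsets.
#' @return One-row tibble: `n_a`, `n_b`, `n_overlap`, `n_universe`, `p`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  out_a <- setdiff(set_a, universe); out_b <- setdiff(set_b, universe)
  if (length(out_a) + length(out_b) > 0) {
    abort(paste0("sets contain ids outside the universe: ",
                 paste(head(c(out_a, out_b), 5), collapse = ", ")))
  }
  k <- length(intersect(set_a, set_b))
  p <- exp(phyper(k - 1, length(set_a), length(universe) - length(set_a),
                  length(set_b), lower.tail = FALSE, log.p = TRUE))
  tibble(n_a = length(set_a), n_b = length(set_b), n_overlap = k,
         n_universe = length(universe), p = p)
}
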