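#' Simulate a differential-expression table from planted truth
#'
#' For every contrast recorded in the truth table (`de_<contrast>`
#' columns), draws a log2 fold-change around the planted value and a
#' q-value: genes without a planted effect get q uniform on (0, 1) — so a
#' nominal `fdr` fraction of them are false positives, as in a real
#' screen — while planted genes fall below the cutoff with their class's
#' `de_power`.
#'
#' @param truth Truth table from [simulate_genome()].
#' @param config The generating [sim_config()].
#' @param fdr Significance cutoff the planted power refers to.
#' @param lfc_sd Standard deviation of the log2 fold-change noise.
#' @return Tibble: `gene_id` plus `log2fc_<contrast>` and `q_<contrast>`
#'   per contrast.
#' @export
simulate_de_table <- function(truth, config, fdr = 0.05, lfc_sd = 0.2) {
  stopifnot(inherits(config, "sim_config"))
  de_cols <- grep("^de_", names(truth), value = TRUE)
  if (length(de_cols) == 0) {
    abort("truth table has no planted DE contrasts (de_* columns)")
  }
  with_op_seed(config$seed, "de_table", {
    n <- nrow(truth)
    power <- vapply(truth$class, function(cl) {
      config$gene_classes[[cl]]$de_power
    }, numeric(1))
    out <- tibble(gene_id = truth$gene_id)
    for (col in de_cols) {
      ctr <- sub("^de_", "", col)
      planted <- truth[[col]]
      out[[paste0("log2fc_", ctr)]] <- rnorm(n, planted, lfc_sd)
      q <- runif(n)
      hit <- planted != 0 & rbinom(n, 1, power) == 1
      q[hit] <- runif(sum(hit), 0, fdr)
      out[[paste0("q_", ctr)]] <- q
    }
    out
  })
}

#' Simulate a phosphopeptide intensity table with planted effects
#'
#' Log-normal peptide intensities over control and treatment replicates;
#' planted peptides are shifted by `effect_fold` in the treatment group.
#' Peptides are grouped into proteins; planted peptides occupy dedicated
#' proteins (named `PLANT_...`) so protein-level recovery can be scored
#' against the truth.
#'
#' @param n_peptides Total number of peptides.
#' @param n_planted Number of peptides carrying the planted fold-change.
#' @param effect_fold Fold-change (linear scale) of planted peptides in
#'   treatment; scalar or vector of length `n_planted`. 1 means no effect
#'   (nothing is flagged planted).
#' @param noise_sd Replicate noise standard deviation on the log2 scale.
#' @param n_replicates Replicates per group (must be >= 2).
#' @param peptides_per_protein Peptides grouped per protein.
#' @param seed Integer seed.
#' @return List with `table` (tibble: `peptide_id`, `protein_id`, `site`,
#'   `control_<i>`, `treatment_<i>` columns) and `truth` (tibble:
#'   `peptide_id`, `protein_id`, `planted`, `effect_fold`).
#' @export
simulate_phospho_table <- function(n_peptides = 2000, n_planted = 20,
                                   effect_fold = 2, noise_sd = 0.25,
                                   n_replicates = 3,
                                   peptides_per_protein = 2, seed = 1L) {
  if (n_replicates < 2) abort("n_replicates must be >= 2")
  if (n_planted > n_peptides) abort("n_planted cannot exceed n_peptides")
  effect <- rep_len(effect_fold, max(n_planted, 1))
  with_op_seed(seed, "phospho_table", {
    peptide_id <- sprintf("pep%05d", seq_len(n_peptides))
    planted <- seq_len(n_peptides) <= n_planted
    lfc <- rep(0, n_peptides)
    if (n_planted > 0) lfc[planted] <- log2(effect[seq_len(n_planted)])
    planted <- planted & lfc != 0

    n_plant_prot <- ceiling(n_planted / peptides_per_protein)
    prot_planted <- sprintf("PLANT_%03d",
                            rep(seq_len(max(n_plant_prot, 1)),
                                each = peptides_per_protein))[seq_len(n_planted)]
    n_null <- n_peptides - n_planted
    prot_null <- sprintf("PROT_%04d",
                         rep(seq_len(ceiling(n_null / peptides_per_protein)),
                             each = peptides_per_protein))[seq_len(n_null)]
    protein_id <- c(prot_planted, prot_null)

    base <- rnorm(n_peptides, 20, 2)
    tab <- tibble(peptide_id = peptide_id, protein_id = protein_id,
                  site = sprintf("S%d", sample(1:999, n_peptides, TRUE)))
    for (i in seq_len(n_replicates)) {
      tab[[paste0("control_", i)]] <- 2^(base + rnorm(n_peptides, 0, noise_sd))
    }
    for (i in seq_len(n_replicates)) {
      tab[[paste0("treatment_", i)]] <-
        2^(base + lfc + rnorm(n_peptides, 0, noise_sd))
    }
    truth <- tibble(peptide_id = peptide_id, protein_id = protein_id,
                    planted = planted, effect_fold = 2^lfc)
    list(table = tab, truth = truth)
  })
}
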