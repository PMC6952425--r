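#' Average an enrichment profile over a gene set
#'
#' Per-bin arithmetic mean (with standard error and gene count) of a
#' per-gene enrichment profile across the genes of a set; bins missing for
#' a gene are excluded gene-wise.
#'
#' @param enrichment A per-gene `enrichment_profile` from
#'   [fold_enrichment()] (`aggregate = "per_gene"`).
#' @param gene_set Character vector of gene ids (`NULL` = all genes in the
#'   profile).
#' @return Tibble with columns `rel`, `mean`, `se`, `n`.
#' @export
metagene <- function(enrichment, gene_set = NULL) {
  if (!"gene_id" %in% names(enrichment)) {
    abort("metagene() needs a per-gene enrichment profile (aggregate = 'per_gene')")
  }
  if (!is.null(gene_set)) {
    if (length(gene_set) == 0) abort("gene set is empty")
    missing <- setdiff(gene_set, unique(enrichment$gene_id))
    if (length(missing) > 0) {
      abort(paste0("gene set ids absent from profile: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    enrichment <- enrichment[enrichment$gene_id %in% gene_set, ]
  }
  if (nrow(enrichment) == 0) abort("gene set is empty")
  as_tibble(enrichment) %>%
    group_by(.data$rel) %>%
    summarise(mean = mean(.data$enrichment),
              se = sd(.data$enrichment) / sqrt(dplyr::n()),
              n = dplyr::n(), .groups = "drop") %>%
    arrange(.data$rel)
}

#' Test an anchor window for an occupancy difference between conditions
#'
#' Compares the per-bin fold-enrichment values of two conditions inside a
#' window around the anchor (default -600..+600 bp, i.e. 20 bins at 60 bp)
#' with a t-test across bins: by default a paired test (pairs = bins, the
#' same genomic bin under the two conditions), optionally unpaired Welch.
#' Only bins fully contained in the window are used. Note that adjacent
#' bins are correlated (fragments span several bins), so the across-bin
#' test can be anticonservative; see the package vignette.
#'
#' @param a,b `enrichment_profile` objects for the two conditions with
#'   identical anchor parameters. Set-level profiles are compared as is;
#'   per-gene profiles are first averaged over `gene_set` (mean of
#'   per-gene ratios).
#' @param gene_set Optional gene set used when `a`/`b` are per-gene
#'   profiles.
#' @param window Numeric length-2, window in bp relative to the anchor.
#' @param method `"paired"` (default) or `"welch"`.
#' @return A `window_comparison` object; see [tidy()] and [glance()]
#'   methods. If the two conditions are bin-wise identical the p-value is
#'   1 by convention; if the per-bin differences are a non-zero constant
#'   the paired p-value is 0 (infinite t).
#' @export
compare_window <- function(a, b, gene_set = NULL, window = c(-600, 600),
                           method = c("paired", "welch")) {
  method <- match.arg(method)
  bs_a <- attr(a, "bin_size"); bs_b <- attr(b, "bin_size")
  if (!identical(attr(a, "anchor"), attr(b, "anchor")) ||
      !identical(bs_a, bs_b)) {
    abort("profiles differ in anchor or bin size")
  }
  vals <- function(p) {
    if ("gene_id" %in% names(p)) {
      mg <- metagene(p, gene_set)
      tibble(rel = mg$rel, enrichment = mg$mean)
    } else {
      tibble(rel = p$rel, enrichment = p$enrichment)
    }
  }
  va <- vals(a); vb <- vals(b)
  joined <- dplyr::inner_join(va, vb, by = "rel", suffix = c("_a", "_b")) %>%
    filter(.data$rel >= window[1], .data$rel + bs_a <= window[2]) %>%
    arrange(.data$rel)
  if (nrow(joined) < 3) abort("fewer than 3 usable bins in the window")

  x <- joined$enrichment_a; y <- joined$enrichment_b
  if (method == "paired") {
    d <- x - y
    if (all(d == 0)) {
      tstat <- NA_real_; p <- 1
    } else if (sd(d) == 0) {
      tstat <- sign(mean(d)) * Inf; p <- 0
    } else {
      tt <- t.test(x, y, paired = TRUE)
      tstat <- unname(tt$statistic); p <- tt$p.value
    }
  } else {
    if (sd(x) == 0 && sd(y) == 0) {
      tstat <- NA_real_; p <- if (mean(x) == mean(y)) 1 else 0
    } else {
      tt <- t.test(x, y)
      tstat <- unname(tt$statistic); p <- tt$p.value
    }
  }
  structure(list(window = window, method = method, n_bins = nrow(joined),
                 bins = joined, t = tstat, p = p,
                 mean_a = mean(x), mean_b = mean(y),
                 estimate = mean(x) - mean(y)),
            class = "window_comparison")
}

#' @export
print.window_comparison <- function(x, ...) {
  cat("<window_comparison> ", x$method, " t-test across ", x$n_bins,
      " bins in [", x$window[1], ", ", x$window[2], ")\n", sep = "")
  cat(sprintf("  mean A = %.4g, mean B = %.4g, t = %.3f, p = %.4g\n",
              x$mean_a, x$mean_b, x$t, x$p))
  invisible(x)
}

#' Tidy a window comparison into per-bin rows
#' @param x A `window_comparison`.
#' @param ... Unused.
#' @return Tibble with one row per bin (`rel`, `enrichment_a`,
#'   `enrichment_b`).
#' @export
tidy.window_comparison <- function(x, ...) x$bins

#' One-row summary of a window comparison
#' @param x A `window_comparison`.
#' @param ... Unused.
#' @return One-row tibble with the window, method, bin count, means, t and
#'   p.
#' @export
glance.window_comparison <- function(x, ...) {
  tibble(window_lo = x$window[1], window_hi = x$window[2],
         method = x$method, n_bins = x$n_bins,
         mean_a = x$mean_a, mean_b = x$mean_b,
         estimate = x$estimate, statistic = x$t, p.value = x$p)
}
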