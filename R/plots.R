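#' Plot an enrichment profile
#'
#' Set-level profiles are drawn as a fold-enrichment line over the
#' anchor-relative coordinate; per-gene profiles are averaged first (mean
#' of per-gene ratios) with a standard-error ribbon.
#'
#' @param object An `enrichment_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_profile <- function(object, ...) {
  if ("gene_id" %in% names(object)) {
    mg <- metagene(object)
    p <- ggplot2::ggplot(mg, ggplot2::aes(x = .data$rel, y = .data$mean)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           alpha = 0.2) +
      ggplot2::geom_line()
  } else {
    p <- ggplot2::ggplot(as_tibble(object),
                         ggplot2::aes(x = .data$rel, y = .data$enrichment)) +
      ggplot2::geom_line()
  }
  p + ggplot2::labs(
    x = sprintf("position relative to %s (bp)", attr(object, "anchor")),
    y = "fold enrichment over input") +
    ggplot2::theme_minimal()
}

#' Overlay metagene profiles of several conditions
#'
#' @param profiles Named list of set-level `enrichment_profile` objects
#'   (names = condition labels).
#' @param window Optional window to shade (e.g. the tested -600..+600
#'   region).
#' @return A ggplot.
#' @export
plot_metagene <- function(profiles, window = NULL) {
  df <- purrr::imap_dfr(profiles, function(p, nm) {
    tibble(condition = nm, rel = p$rel, enrichment = p$enrichment)
  })
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rel, y = .data$enrichment,
                                        colour = .data$condition))
  if (!is.null(window)) {
    g <- g + ggplot2::annotate("rect", xmin = window[1], xmax = window[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.1)
  }
  g + ggplot2::geom_line() +
    ggplot2::labs(x = "position relative to anchor (bp)",
                  y = "fold enrichment over input", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-gene pausing-index distributions
#'
#' @param object A `pausing_result`.
#' @param ... Unused.
#' @return A ggplot (log10-scaled index distributions per region
#'   definition).
#' @export
autoplot.pausing_result <- function(object, ...) {
  df <- as_tibble(object) %>%
    filter(.data$usable) %>%
    tidyr::pivot_longer(c("relaxed", "stringent"), names_to = "region",
                        values_to = "index")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$index)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "pausing index") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
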