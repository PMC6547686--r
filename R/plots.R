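#' Plot k-mer enrichment (Z-score versus occurrence)
#'
#' The classic RRE summary: each k-mer positioned by its occurrence count
#' (log10) and enrichment Z-score against the shuffled background, colored
#' by class (G-rich, AU-rich, other). Degenerate k-mers are dropped.
#'
#' @param object A `kmer_enrichment` tibble from [kmer_zscores()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kmer_enrichment <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), !.data$degenerate,
                      .data$count > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$count), y = .data$z,
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(
      "G-rich" = "#c0392b", "AU-rich" = "#8e44ad", "other" = "grey60"
    )) +
    ggplot2::labs(x = "log10 occurrence", y = "Z-score",
                  colour = "k-mer class") +
    ggplot2::theme_minimal()
}

#' Plot a metagene profile against its randomized null
#'
#' Observed per-bin density as a line; the null mean with a +/- 2 SD ribbon
#' in grey when null columns are present (i.e. for [metagene()] output).
#'
#' @param object A `metagene_profile` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$bin_start + df$bin_end) / 2
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid))
  if (all(c("null_mean", "null_sd") %in% names(df))) {
    p <- p +
      ggplot2::geom_ribbon(
        ggplot2::aes(ymin = pmax(0, .data$null_mean - 2 * .data$null_sd),
                     ymax = .data$null_mean + 2 * .data$null_sd),
        fill = "grey80"
      ) +
      ggplot2::geom_line(ggplot2::aes(y = .data$null_mean),
                         colour = "black")
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), colour = "#c0392b") +
    ggplot2::labs(
      x = sprintf("nt downstream of %s",
                  gsub("_", " ", attr(object, "anchor") %||% "anchor")),
      y = "cluster density"
    ) +
    ggplot2::theme_minimal()
}

#' Cumulative distribution curves per occupancy bin
#'
#' Empirical CDFs of per-gene values (log2 fold change or delta-TE) for each
#' bin, the standard display for occupancy-stratified knockout responses.
#'
#' @param values Tibble: gene_id, value.
#' @param bins Tibble from [bin_targets()].
#' @param xlab Axis label for the value.
#' @return A ggplot.
#' @export
plot_binned_cdf <- function(values, bins, xlab = "log2 fold change (KO/WT)") {
  df <- dplyr::inner_join(values, bins, by = "gene_id") |>
    dplyr::filter(!is.na(.data$value), !is.na(.data$bin))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, colour = .data$bin)) +
    ggplot2::stat_ecdf(linewidth = 0.7) +
    ggplot2::labs(x = xlab, y = "cumulative fraction", colour = "bin") +
    ggplot2::theme_minimal()
}

#' Plot an exponential decay fit
#'
#' @param object A `decay_fit` from [fit_halflife()].
#' @param ... Unused.
#' @return A ggplot of the observed levels (log scale) and fitted decay.
#' @export
autoplot.decay_fit <- function(object, ...) {
  df <- tibble(time = object$timepoints, level = object$levels)
  line <- tibble(
    time = seq(min(df$time), max(df$time), length.out = 50)
  )
  fit <- lm(log(df$level) ~ df$time)
  line$level <- exp(coef(fit)[1] + coef(fit)[2] * line$time)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$level)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "#2980b9") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time after transcription block (h)",
                  y = "relative mRNA level") +
    ggplot2::theme_minimal()
}
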