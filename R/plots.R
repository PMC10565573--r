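#' Plot per-site RNA allele fractions
#'
#' Point-range plot of the non-reference RNA allele fraction per heterozygous
#' site with its Clopper-Pearson interval, colored by imbalance verdict, with
#' the balanced 0.5 expectation as a dashed line — the per-sample view of
#' allele-specific expression.
#'
#' @param results A [test_imbalance()] (or [allele_fraction()]) tibble.
#' @return A ggplot object.
#' @export
plot_allele_fractions <- function(results) {
  x <- as_tibble(results)
  if (!"verdict" %in% names(x)) x$verdict <- "unclassified"
  ggplot2::ggplot(
    x,
    ggplot2::aes(
      x = factor(.data$pos), y = .data$f_rna, color = .data$verdict
    )
  ) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", color = "grey40") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "heterozygous SNV position",
      y = "non-reference RNA allele fraction",
      color = "verdict"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a tumor/normal allele-fraction contrast
#'
#' @param object A `tn_contrast` from [compare_tumor_normal()].
#' @param ... Unused.
#' @return A ggplot object with paired tumor and normal fractions per site.
#' @method autoplot tn_contrast
#' @export
autoplot.tn_contrast <- function(object, ...) {
  long <- object$sites |>
    select("pos", tumor = "f_rna_tumor", normal = "f_rna_normal") |>
    tidyr::pivot_longer(
      c("tumor", "normal"),
      names_to = "condition", values_to = "f_rna"
    )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = factor(.data$pos), y = .data$f_rna,
      color = .data$condition, group = .data$condition
    )
  ) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "heterozygous SNV position",
      y = "non-reference RNA allele fraction",
      color = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot normalized viability by cell line
#'
#' Jittered normalized Day-8 values per line, colored by biological
#' replicate, mirroring how growth-in-low-attachment results are usually
#' shown.
#'
#' @param normalized Output of [normalize_viability()].
#' @return A ggplot object.
#' @export
plot_viability <- function(normalized) {
  ggplot2::ggplot(
    as_tibble(normalized),
    ggplot2::aes(
      x = .data$line, y = .data$value_norm, color = factor(.data$bio_rep)
    )
  ) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 2) +
    ggplot2::stat_summary(
      fun = stats::median, geom = "crossbar", width = 0.4, color = "black",
      linewidth = 0.3
    ) +
    ggplot2::labs(
      x = NULL, y = "viability (fold of Day-0 mean)",
      color = "biological\nreplicate"
    ) +
    ggplot2::theme_minimal()
}
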