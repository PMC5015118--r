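#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a set-based scan result
#'
#' @param x A `fastbat_result`.
#' @param ... Unused.
#' @return A plain tibble of the per-set results (sorted by p-value), with
#'   a `significant` flag at the scan's Bonferroni threshold.
#' @method tidy fastbat_result
#' @export
tidy.fastbat_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$significant <- out$p_fastbat < attr(x, "threshold")
  out
}

#' One-row summary of a set-based scan
#'
#' @param x A `fastbat_result`.
#' @param ... Unused.
#' @return Tibble with number of sets tested/skipped, the Bonferroni
#'   threshold, the number of significant sets, and the smallest p-value.
#' @method glance fastbat_result
#' @export
glance.fastbat_result <- function(x, ...) {
  tibble::tibble(
    n_sets = nrow(x),
    n_skipped = nrow(attr(x, "skipped") %||% tibble::tibble()),
    alpha = attr(x, "alpha"),
    threshold = attr(x, "threshold"),
    n_significant = sum(x$p_fastbat < attr(x, "threshold")),
    min_p = min(x$p_fastbat)
  )
}

#' Quantile-quantile plot of set-based p-values
#'
#' Observed vs expected -log10 p under the global null, the standard
#' calibration display for a genome-wide scan; the Bonferroni threshold is
#' drawn as a horizontal line.
#'
#' @param object A `fastbat_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fastbat_result
#' @export
autoplot.fastbat_result <- function(object, ...) {
  n <- nrow(object)
  df <- tibble::tibble(
    expected = -log10(stats::ppoints(n)),
    observed = sort(-log10(object$p_fastbat), decreasing = TRUE)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "threshold")),
                        colour = "red", linetype = 3) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      title = "Set-based association p-values"
    )
}

#' Plot a pruning power sweep
#'
#' Mean 1-df chi-squared power against the LD r^2 cutoff, for all genes and
#' for genes harbouring a causal variant.
#'
#' @param object A `power_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_sweep
#' @export
autoplot.power_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("power_all", "power_causal"),
                            names_to = "genes", values_to = "power")
  df$genes <- ifelse(df$genes == "power_all", "all genes",
                     "genes with a causal variant")
  ggplot2::ggplot(df, ggplot2::aes(.data$r2_cutoff, .data$power,
                                   colour = .data$genes)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::labs(x = expression(LD ~ r^2 ~ cutoff),
                  y = expression(mean ~ chi[1]^2),
                  colour = NULL,
                  title = "LD-pruned set test power")
}
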