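# ggplot2 diagnostics for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_line geom_point
#'   geom_vline geom_density labs facet_wrap theme_minimal after_stat
#' @export
ggplot2::autoplot

#' Plot a mixture fit over the pooled log-count histogram
#'
#' @param object a `mixture_fit`.
#' @param counts the pooled counts the fit was computed from.
#' @param thresholds optional `threshold_pair` drawn as vertical lines.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mixture_fit <- function(object, counts, thresholds = NULL, ...) {
  x <- log(counts[counts > object$min_count])
  grid <- seq(min(x), max(x), length.out = 400)
  dens <- purrr::map_dfr(seq_along(object$pi), function(k) {
    tibble(log_count = grid, component = factor(k),
           density = object$pi[k] *
             dskewnorm(grid, object$xi[k], object$omega[k], object$alpha[k]))
  })
  p <- ggplot(tibble(log_count = x), aes(x = .data$log_count)) +
    geom_histogram(aes(y = after_stat(.data$density)), bins = 60,
                   fill = "grey80", colour = "grey60") +
    geom_line(data = dens,
              aes(y = .data$density, colour = .data$component)) +
    labs(x = "log UMI count", y = "density",
         title = "Skew-normal mixture over pooled barcode counts") +
    theme_minimal()
  if (!is.null(thresholds)) {
    p <- p + geom_vline(xintercept = log(c(thresholds$t_lo, thresholds$t_hi)),
                        linetype = "dashed")
  }
  p
}

#' Per-barcode diffusion-score density plot
#'
#' Mirrors the density-per-barcode view used to spot separation-of-function
#' variants: one density per barcode group, ordered by mean score.
#'
#' @param barcode_scores tibble `group_id, cell_id, score`.
#' @param classes optional output of [classify_barcodes()] used to colour
#'   the densities.
#' @return a ggplot.
#' @export
plot_diffusion_density <- function(barcode_scores, classes = NULL) {
  d <- barcode_scores |>
    group_by(.data$group_id) |>
    mutate(mean_score = mean(.data$score)) |>
    ungroup()
  if (!is.null(classes)) {
    d <- left_join(d, select(classes, "group_id", "class"), by = "group_id")
  } else {
    d$class <- "barcode"
  }
  ggplot(d, aes(x = .data$score,
                group = stats::reorder(.data$group_id, .data$mean_score),
                colour = .data$class)) +
    geom_density() +
    labs(x = "diffusion score", y = "density",
         title = "Diffusion-score distribution per barcode group") +
    theme_minimal()
}

#' AUC volcano-style plot of a differential-expression result
#'
#' @param object a `de_result`.
#' @param ... unused.
#' @return a ggplot (AUC against -log10 q-value; AUC < 0.5 is
#'   downregulation in group A).
#' @export
autoplot.de_result <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$auc, y = -log10(pmax(.data$q_value, 1e-300)),
             colour = .data$significant)) +
    geom_point(size = 0.8) +
    geom_vline(xintercept = 0.5, linetype = "dashed") +
    labs(x = "AUC (A vs B)", y = "-log10 q-value",
         title = "Rank-sum AUC differential expression") +
    theme_minimal()
}
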