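# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a skew-normal mixture fit
#'
#' @param x a `mixture_fit`.
#' @param ... unused.
#' @return tibble with one row per component: weight, location, scale,
#'   slant, and whether it is the ambient component.
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(component = seq_along(x$pi), weight = x$pi, location = x$xi,
         scale = x$omega, slant = x$alpha,
         ambient = seq_along(x$pi) == x$ambient_component)
}

#' @rdname tidy.mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_components = length(x$pi), log_lik = x$loglik,
         converged = x$converged, iterations = length(x$loglik_trace))
}

#' Tidy an evaluation report
#'
#' @param x an `eval_report` from [evaluate_classification()].
#' @param ... unused.
#' @return one-row tibble of confusion counts, precision and recall.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
         precision = x$precision, recall = x$recall,
         precision_pct = x$precision_pct, recall_pct = x$recall_pct)
}

#' Glance at a differential-expression result
#'
#' @param x a `de_result` from [de_auc()].
#' @param ... unused.
#' @return one-row tibble with group sizes, numbers of significant genes by
#'   direction and the FDR level used.
#' @export
glance.de_result <- function(x, ...) {
  tibble(n_genes = nrow(x), n_a = attr(x, "n_a"), n_b = attr(x, "n_b"),
         n_significant = sum(x$significant),
         n_up = sum(x$significant & x$direction == "up"),
         n_down = sum(x$significant & x$direction == "down"),
         fdr_level = attr(x, "fdr_level"))
}
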