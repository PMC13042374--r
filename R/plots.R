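#' @importFrom ggplot2 ggplot aes geom_col geom_line geom_abline geom_step
#'   geom_histogram labs theme_minimal facet_wrap autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot signature contributions of a deconvolution
#'
#' @param object A [deconvolute()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.deconvolution <- function(object, ...) {
  d <- object$contributions %>%
    dplyr::mutate(kind = ifelse(.data$is_background, "background",
                                "tumor-associated"))
  ggplot(d, aes(x = stats::reorder(.data$signature, -.data$contribution),
                y = .data$contribution, fill = .data$kind)) +
    geom_col() +
    labs(x = NULL, y = "relative contribution", fill = NULL,
         title = sprintf("reconstruction cosine %.4f, tumor-associated %.3f",
                         object$cosine, object$cosmic_total)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a 96-context mutation profile
#'
#' @param profile Tibble from [build_profile()].
#' @return A ggplot with one panel per substitution class.
#' @export
plot_profile <- function(profile) {
  d <- profile %>%
    dplyr::mutate(substitution = substr(.data$context, 3, 5),
                  context = factor(.data$context, levels = sbs96_contexts()))
  ggplot(d, aes(x = .data$context, y = .data$frequency,
                fill = .data$substitution)) +
    geom_col(show.legend = FALSE) +
    facet_wrap(~substitution, scales = "free_x", nrow = 1) +
    labs(x = NULL, y = "frequency") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' ROC curve of cross-validated prediction scores
#'
#' @param object A [nested_cv()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_result <- function(object, ...) {
  s <- object$scores
  o <- order(s$score, decreasing = TRUE)
  tpr <- cumsum(s$label[o] == 1) / sum(s$label == 1)
  fpr <- cumsum(s$label[o] == 0) / sum(s$label == 0)
  d <- tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  ggplot(d, aes(.data$fpr, .data$tpr)) +
    geom_step() +
    geom_abline(linetype = "dashed", colour = "grey") +
    labs(x = "1 - specificity", y = "sensitivity",
         title = sprintf("AUC %.3f", object$auc)) +
    theme_minimal()
}

#' Fragment-size distributions of Mut- vs Wt-DNA
#'
#' @param partition An [partition_by_allele()] result.
#' @param binwidth Histogram bin width in bp.
#' @return A ggplot.
#' @export
plot_size_distribution <- function(partition, binwidth = 5) {
  d <- dplyr::bind_rows(
    dplyr::mutate(partition$mut, class = "Mut-DNA"),
    dplyr::mutate(partition$wt, class = "Wt-DNA")
  )
  ggplot(d, aes(.data$length, fill = .data$class)) +
    geom_histogram(aes(y = ggplot2::after_stat(.data$density)),
                   binwidth = binwidth, position = "identity", alpha = 0.5) +
    labs(x = "fragment length (bp)", y = "density", fill = NULL) +
    theme_minimal()
}
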