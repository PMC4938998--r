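# ggplot2 visualisations for the main result objects.

#' Ring-count histogram of a scaffold summary
#'
#' Number of distinct scaffolds per ring count, split by exclusivity class.
#'
#' @param object A `scaffold_summary` from [summarize_scaffolds()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scaffold_summary <- function(object, ...) {
  ggplot2::ggplot(object$ring_histogram,
                  ggplot2::aes(x = .data$n_rings, y = .data$n_scaffolds,
                               fill = .data$exclusivity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_x_continuous(breaks = function(l) {
      seq(floor(l[1]), ceiling(l[2]))
    }) +
    ggplot2::labs(x = "Rings per scaffold", y = "Distinct scaffolds",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Curation waterfall of an assay dataset
#'
#' Unique compounds remaining after each curation stage.
#'
#' @param ds An `assay_tbl` that has passed through [run_pipeline()] (or any
#'   subset of its stages).
#' @return A ggplot object.
#' @export
plot_audit <- function(ds) {
  trail <- audit_trail(ds)
  trail$stage <- factor(trail$stage, levels = trail$stage)
  ggplot2::ggplot(trail, ggplot2::aes(x = .data$stage, y = .data$n_after)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_after), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "Unique compounds remaining") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' MOA category counts of a MOA analysis result
#'
#' @param object A `moa_result` from [moa_mmp_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.moa_result <- function(object, ...) {
  counts <- tibble::tibble(
    moa_category = factor(object$pairs$moa_category,
                          c("same_moa", "weak_cliff", "strong_cliff"))
  ) |>
    dplyr::count(.data$moa_category, .drop = FALSE)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$moa_category, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "Matched molecular pairs") +
    ggplot2::theme_minimal()
}
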