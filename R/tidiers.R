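# broom-style accessors and ggplot2 views for fitted models and property
# matrices.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a gene model
#'
#' @param x A trained `gene_model`.
#' @param ... Unused.
#' @return The per-epoch history tibble (loss, accuracy, validation metrics).
#' @method tidy gene_model
#' @export
tidy.gene_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history yet")
  x$history
}

#' @rdname tidy.gene_model
#' @method glance gene_model
#' @export
glance.gene_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = if (is.null(h)) 0L else nrow(h),
    final_loss = if (is.null(h)) NA_real_ else h$loss[nrow(h)],
    final_accuracy = if (is.null(h)) NA_real_ else h$accuracy[nrow(h)],
    n_parameters = sum(vapply(x$params, length, integer(1))),
    input_dim = x$input_dim,
    threshold = x$threshold
  )
}

#' Tidy the training history of a peptide model
#'
#' @param x A trained `peptide_model`.
#' @param ... Unused.
#' @return The per-epoch history tibble (loss and validation accuracy, F1,
#'   MCC).
#' @method tidy peptide_model
#' @export
tidy.peptide_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history yet")
  x$history
}

#' @rdname tidy.peptide_model
#' @method glance peptide_model
#' @export
glance.peptide_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    task = x$task %||% NA_character_,
    epochs = if (is.null(h)) 0L else nrow(h),
    best_val_loss = if (is.null(h)) NA_real_ else min(h$val_loss),
    best_val_accuracy = if (is.null(h)) NA_real_ else max(h$val_accuracy),
    n_parameters = sum(vapply(x$params, length, integer(1))),
    embedding = x$provider$mode,
    threshold = x$threshold
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", if (isTRUE(x$trained)) "trained" else "untrained",
      ", input width ", x$input_dim,
      ", ", sum(vapply(x$params, length, integer(1))), " parameters\n",
      sep = "")
  invisible(x)
}

#' @export
print.peptide_model <- function(x, ...) {
  cat("<peptide_model ", x$task %||% "?", "> ",
      if (isTRUE(x$trained)) "trained" else "untrained",
      ", embeddings: ", x$provider$mode,
      ", ", sum(vapply(x$params, length, integer(1))), " parameters\n",
      sep = "")
  invisible(x)
}

history_plot <- function(h, title) {
  long <- tidyr::pivot_longer(h, -"epoch", names_to = "metric",
                              values_to = "value")
  long <- long[!is.na(long$value), , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(title = title, x = "epoch", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' Training-history curves
#'
#' @param object A trained `gene_model` or `peptide_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gene_model
#' @export
autoplot.gene_model <- function(object, ...) {
  history_plot(tidy(object), "Gene model training history")
}

#' @rdname autoplot.gene_model
#' @method autoplot peptide_model
#' @export
autoplot.peptide_model <- function(object, ...) {
  history_plot(tidy(object), "Peptide model training history")
}

#' Heatmap of normalized physicochemical properties
#'
#' The package's analogue of the classic peptide-property heatmap: one row
#' per peptide, one column per property, min-max normalized.
#'
#' @param object A `property_matrix` (raw values are normalized internally).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot property_matrix
#' @export
autoplot.property_matrix <- function(object, ...) {
  norm <- if (is.null(attr(object, "mins"))) {
    normalize_properties(object)
  } else object
  long <- tidyr::pivot_longer(norm, -"id", names_to = "property",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$property, y = .data$id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "normalized") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' GRAVY versus net charge, colored by Boman index
#'
#' @param matrix A `property_matrix` (raw values).
#' @return A ggplot object.
#' @export
plot_property_scatter <- function(matrix) {
  ggplot2::ggplot(matrix,
                  ggplot2::aes(x = .data$gravy, y = .data$net_charge_pH7,
                               color = .data$boman)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_viridis_c() +
    ggplot2::labs(x = "GRAVY (hydrophobicity)", y = "net charge at pH 7",
                  color = "Boman index") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
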