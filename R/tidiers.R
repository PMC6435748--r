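#' Tidy methods for result objects
#'
#' `tidy()` returns the per-unit table of a result (per-cell morphology for
#' sheath records, per-pair JIs for a JI report, the per-checkpoint log for
#' a training run); `glance()` returns a one-row summary.
#'
#' @param x a `sheath_records`, `ji_report` or `train_log` object.
#' @param ... unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.sheath_records <- function(x, ...) cell_morphology(x)

#' @rdname tidiers
#' @export
glance.sheath_records <- function(x, ...) summarize_well(x)

#' @rdname tidiers
#' @export
tidy.ji_report <- function(x, ...) x$per_cell

#' @rdname tidiers
#' @export
glance.ji_report <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$per_cell),
                 median_ji = stats::median(x$per_cell$ji),
                 mean_ji = mean(x$per_cell$ji), global_ji = x$global_ji,
                 n_unpaired_ref = x$n_unpaired_ref,
                 n_unpaired_test = x$n_unpaired_test)
}

#' @rdname tidiers
#' @export
tidy.train_log <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname tidiers
#' @export
glance.train_log <- function(x, ...) {
  tibble::tibble(steps = max(x$step), final_train_loss = dplyr::last(x$train_loss),
                 best_val_ji = max(x$val_mean_ji),
                 best_val_ji_step = x$step[which.max(x$val_mean_ji)])
}

#' Plot a training log
#'
#' Validation loss and mean Jaccard index against training step.
#'
#' @param object a `train_log`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.train_log <- function(object, ...) {
  df <- tidy.train_log(object)
  long <- dplyr::bind_rows(
    tibble::tibble(step = df$step, value = df$val_loss, what = "validation loss"),
    tibble::tibble(step = df$step, value = df$val_mean_ji, what = "validation mean JI"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "training step", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot sheath records over the well
#'
#' Draws each sheath's pixels colored by owning cell, with nucleus
#' centroids marked — a quick visual check of per-cell association.
#'
#' @param object a `sheath_records` table.
#' @param max_px subsample cap on plotted pixels (keeps plots light).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sheath_records <- function(object, max_px = 200000, ...) {
  d <- sheath_dim(object)
  df <- dplyr::bind_rows(lapply(seq_len(nrow(object)), function(i) {
    px <- object$px[[i]]
    tibble::tibble(y = (px - 1) %% d[1], x = (px - 1) %/% d[1],
                   cell = factor(object$cell_id[i]))
  }))
  if (nrow(df) > max_px) df <- df[seq(1, nrow(df), length.out = max_px), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$cell)) +
    ggplot2::geom_point(shape = 15, size = 0.3, show.legend = FALSE) +
    ggplot2::scale_y_reverse(limits = c(d[1], 0)) +
    ggplot2::xlim(0, d[2]) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  cells <- attr(object, "cells")
  if (!is.null(cells) && nrow(cells))
    p <- p + ggplot2::geom_point(
      data = cells, ggplot2::aes(x = .data$centroid_x, y = .data$centroid_y),
      inherit.aes = FALSE, shape = 3, size = 1.5, colour = "black")
  p
}
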