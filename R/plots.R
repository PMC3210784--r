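#' Plot a movie frame with optional mask outline
#'
#' @param movie A `cell_movie` (or any list with `frames`).
#' @param frame Frame index.
#' @param mask Optional label matrix overlaid as filled regions.
#' @return A ggplot object.
#' @export
plot_frame <- function(movie, frame = 1L, mask = NULL) {
  img <- if (inherits(movie, "cell_movie")) movie$frames[[frame]] else
    movie[[frame]]
  df <- tibble(x = rep(seq_len(ncol(img)), each = nrow(img)),
               y = rep(seq_len(nrow(img)), times = ncol(img)),
               grey = as.vector(img))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$grey)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("frame", frame)) +
    ggplot2::theme_minimal()
  if (!is.null(mask)) {
    md <- tibble(x = rep(seq_len(ncol(mask)), each = nrow(mask)),
                 y = rep(seq_len(nrow(mask)), times = ncol(mask)),
                 label = as.vector(mask)) %>%
      filter(.data$label > 0L)
    p <- p + ggplot2::geom_tile(data = md, fill = "red", alpha = 0.25)
  }
  p
}

#' Plot proliferation curves
#'
#' @param counts A proliferation tibble (`frame`, `n_cells`), or a
#'   named list of them for comparison (e.g. detected vs truth).
#' @param frame_interval Minutes per frame for the time axis.
#' @return A ggplot object.
#' @export
plot_proliferation <- function(counts, frame_interval = 15) {
  if (is.data.frame(counts)) counts <- list(cells = counts)
  df <- purrr::imap_dfr(counts, ~ mutate(.x, series = .y))
  ggplot2::ggplot(df, ggplot2::aes((.data$frame - 1) * frame_interval / 60,
                                   .data$n_cells,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [h]", y = "cell count", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-frame detection error rates
#'
#' @param report Output of [evaluate_detection()].
#' @return A ggplot object.
#' @export
plot_detection_rates <- function(report) {
  df <- report %>%
    select("frame", "far", "frr") %>%
    tidyr::pivot_longer(c("far", "frr"), names_to = "rate")
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, 100 * .data$value,
                                   colour = toupper(.data$rate))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "error rate [%]", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the life-time distribution of complete paths
#'
#' @param lifetimes Output of [lifetime_distribution()].
#' @param binwidth Histogram bin width in minutes (default
#'   Freedman-Diaconis).
#' @return A ggplot object.
#' @export
plot_lifetimes <- function(lifetimes, binwidth = NULL) {
  if (is.null(binwidth) && nrow(lifetimes) > 1) {
    iqr <- stats::IQR(lifetimes$lifetime_min)
    binwidth <- max(1, 2 * iqr / nrow(lifetimes)^(1 / 3))
  }
  ggplot2::ggplot(lifetimes, ggplot2::aes(.data$lifetime_min / 60)) +
    ggplot2::geom_histogram(binwidth = binwidth / 60, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "life time [h]", y = "complete paths") +
    ggplot2::theme_minimal()
}

#' Plot the sibling-symmetry distribution
#'
#' @param symmetry Output of [sibling_symmetry()].
#' @return A ggplot object.
#' @export
plot_sibling_symmetry <- function(symmetry) {
  ggplot2::ggplot(symmetry, ggplot2::aes(.data$symmetry_min / 60)) +
    ggplot2::geom_histogram(bins = 21, fill = "darkgreen",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "sibling life-time difference [h]",
                  y = "divisions") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a validated tracking result
#'
#' Life time of each accepted complete path against the time its path
#' ends -- the view that reveals confluency-driven cell-cycle
#' prolongation.
#'
#' @param object A `lineage_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lineage_result
#' @export
autoplot.lineage_result <- function(object, ...) {
  lt <- lifetime_distribution(object$complete, object$frame_interval)
  ggplot2::ggplot(lt, ggplot2::aes(.data$end_time_min / 60,
                                   .data$lifetime_min / 60)) +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
    ggplot2::labs(x = "path end time [h]", y = "life time [h]") +
    ggplot2::theme_minimal()
}
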