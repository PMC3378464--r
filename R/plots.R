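#' Plot a structural profile with optional nucleosome calls
#'
#' Line plot of one or more feature profiles along a chromosome region, with
#' called (and/or true) nucleosomes as translucent 147 bp rectangles.
#'
#' @param profile Profile tibble (`chrom`, `feature`, `pos`, `value`).
#' @param calls Optional calls tibble to overlay.
#' @param truth Optional reference tibble (`chrom`, `start`, `end`) overlaid
#'   in a second colour.
#' @param xlim Optional bp range to display.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, calls = NULL, truth = NULL, xlim = NULL) {
  if (!is.null(xlim)) {
    profile <- profile[profile$pos >= xlim[1] & profile$pos <= xlim[2], ]
  }
  g <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::facet_grid(feature ~ chrom, scales = "free") +
    ggplot2::labs(x = "position (bp)", y = "structural value") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    tr <- if (is.null(xlim)) truth else {
      truth[truth$end >= xlim[1] & truth$start <= xlim[2], ]
    }
    g <- g + ggplot2::geom_rect(
      data = tr,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "steelblue", alpha = 0.15)
  }
  if (!is.null(calls)) {
    cl <- if (is.null(xlim)) calls else {
      calls[calls$end >= xlim[1] & calls$start <= xlim[2], ]
    }
    g <- g + ggplot2::geom_rect(
      data = cl,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "darkorange", alpha = 0.2)
  }
  g
}

#' Plot an anchor-averaged metaprofile
#'
#' @param agg Output of [aggregate_around_anchors()].
#' @return A ggplot object.
#' @export
plot_metaprofile <- function(agg) {
  aes <- if ("class" %in% names(agg)) {
    ggplot2::aes(x = .data$offset, y = .data$value, colour = .data$class)
  } else {
    ggplot2::aes(x = .data$offset, y = .data$value)
  }
  ggplot2::ggplot(agg, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "offset from anchor (bp)", y = "mean signal") +
    ggplot2::theme_minimal()
}

#' Plot sensitivity/specificity/F across distance cutoffs
#'
#' @param eval_tbl Output of [evaluate_calls()] over several cutoffs.
#' @return A ggplot object.
#' @export
plot_evaluation <- function(eval_tbl) {
  long <- tidyr::pivot_longer(
    eval_tbl[, c("source", "cutoff_bp", "se", "sp", "f_measure")],
    c("se", "sp", "f_measure"), names_to = "metric")
  long$metric <- factor(long$metric, c("se", "sp", "f_measure"),
                        c("sensitivity", "specificity", "F-measure"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff_bp, y = .data$value,
                                     colour = .data$source)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "distance cutoff L (bp)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_occupancy Coefficient path of the LARS fit: each
#'   feature's standardized coefficient against the path step, with the
#'   selected stopping point marked.
#' @param object A `nuc_lars` object.
#' @param ... Unused.
#' @export
autoplot.nuc_lars <- function(object, ...) {
  path <- as_tibble(object$path)
  path$step <- seq_len(nrow(path)) - 1L
  long <- tidyr::pivot_longer(path, -"step", names_to = "feature",
                              values_to = "coefficient")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$coefficient,
                                     colour = .data$feature)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$stop_index,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "LARS step", y = "standardized coefficient") +
    ggplot2::theme_minimal()
}
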