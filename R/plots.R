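#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col labs
#'   facet_wrap theme_minimal
NULL

#' Plot a fragment-length spectrum
#'
#' @param object A `length_spectrum`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot length_spectrum
#' @export
autoplot.length_spectrum <- function(object, ...) {
  ggplot(object, aes(x = .data$length, y = .data$frequency)) +
    geom_col(width = 1) +
    labs(x = "fragment length (bp)", y = "fraction of fragments") +
    theme_minimal()
}

#' Plot a WPS track
#'
#' @param object A `wps_track`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot wps_track
#' @export
autoplot.wps_track <- function(object, ...) {
  ggplot(object, aes(x = .data$pos, y = .data$score)) +
    geom_line() +
    labs(x = "position (bp)", y = "WPS") +
    theme_minimal()
}

#' Plot an averaged WPS profile
#'
#' @param object A `wps_profile`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot wps_profile
#' @export
autoplot.wps_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$offset, y = .data$mean_wps)) +
    geom_line() +
    labs(x = "offset from region center (bp)", y = "mean WPS") +
    theme_minimal()
}

#' Plot a position profile
#'
#' Composition profiles are drawn per channel; profiles with a per-end
#' split are faceted by end.
#'
#' @param object A `position_profile`.
#' @param normalized For termini composition profiles, plot the
#'   mode-normalized log2 values instead of raw proportions.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot position_profile
#' @export
autoplot.position_profile <- function(object, normalized = FALSE, ...) {
  ycol <- if (normalized && "norm_log2" %in% names(object)) "norm_log2"
          else "value"
  p <- ggplot(object, aes(x = .data$offset, y = .data[[ycol]],
                          colour = .data$channel)) +
    geom_line() +
    labs(x = "offset (bp)", y = ycol, colour = NULL) +
    theme_minimal()
  if ("end" %in% names(object)) p <- p + facet_wrap(~end)
  p
}

#' Plot a per-position oligo depth profile
#'
#' @param object A `depth_profile`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot depth_profile
#' @export
autoplot.depth_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$pct_len, y = .data$depth)) +
    geom_line() +
    labs(x = "percent across oligo", y = "depth") +
    theme_minimal()
}
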