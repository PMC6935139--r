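#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and one-row summaries of fragmentomics results
#'
#' Result tables are already tidy tibbles; `tidy()` strips the result class
#' and returns the plain tibble, while `glance()` gives the one-row summary
#' a pipeline would log.
#'
#' @param x A `length_spectrum`, `wps_track`, `wps_profile` or
#'   `depth_profile`.
#' @param ... Ignored.
#' @return `tidy()`: a tibble. `glance()`: a one-row tibble.
#' @name fragmentoscope-tidiers
NULL

#' @rdname fragmentoscope-tidiers
#' @method tidy length_spectrum
#' @export
tidy.length_spectrum <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname fragmentoscope-tidiers
#' @method tidy wps_track
#' @export
tidy.wps_track <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname fragmentoscope-tidiers
#' @method tidy position_profile
#' @export
tidy.position_profile <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname fragmentoscope-tidiers
#' @method glance length_spectrum
#' @export
glance.length_spectrum <- function(x, ...) {
  n <- sum(x$count)
  tibble(
    n_fragments = n,
    modal_length = modal_length(x),
    mean_length = sum(x$length * x$count) / n,
    min_length = min(x$length),
    max_length = max(x$length)
  )
}

#' @rdname fragmentoscope-tidiers
#' @method glance wps_track
#' @export
glance.wps_track <- function(x, ...) {
  at <- track_attrs(x)
  tibble(
    contig = x$contig[1], start = at$start, end = at$end,
    window = at$w, lmin = at$lmin, lmax = at$lmax,
    mean_score = mean(x$score), sd_score = stats::sd(x$score)
  )
}

#' @rdname fragmentoscope-tidiers
#' @method glance depth_profile
#' @export
glance.depth_profile <- function(x, ...) {
  design <- attr(x, "design")
  tibble(
    oligo_id = x$oligo_id[1],
    total_len = nrow(x),
    mean_depth = mean(x$depth),
    overhang_core_ratio = if (design$overhang_len >= 1) {
      overhang_coverage_ratio(x, design)
    } else NA_real_
  )
}

unclass_result <- function(x) {
  class(x) <- setdiff(class(x),
                      c("length_spectrum", "wps_track", "wps_profile",
                        "position_profile", "depth_profile"))
  x
}
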