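#' Window protection score (WPS)
#'
#' The WPS at position p counts, over fragments in a length bin, how many
#' fragments span the whole window centered at p minus how many have an
#' endpoint base inside it: a fragment `[s, e)` contributes -1 when `s` or
#' `e - 1` falls in the window `[p - W/2, p + W/2)`, +1 when it spans the
#' window entirely (`s < p - W/2` and `e > p + W/2`), and 0 otherwise. High
#' scores mark nuclease-protected (nucleosome- or factor-occupied) DNA.
#'
#' Implemented with difference-array sweeps in O(n + region length); the
#' test suite checks exact equality with a per-position brute-force
#' evaluation of the rule.
#'
#' @param frags Fragment tibble.
#' @param contig Contig to score.
#' @param start,end Scored region, 0-based half-open.
#' @param w Window size in bp; must be even, window is `[p - w/2, p + w/2)`.
#' @param lmin,lmax Closed fragment-length bin; fragments outside are
#'   ignored before scoring.
#' @return A tibble of class `wps_track` with columns `contig`, `pos`,
#'   `score`; attributes record `w`, `lmin`, `lmax`, and region bounds.
#' @export
raw_wps <- function(frags, contig, start, end, w = 120L,
                    lmin = 120L, lmax = 180L) {
  frags <- validate_fragments(frags)
  if (w %% 2L != 0L || w < 2L) abort("window size must be even and >= 2")
  if (end <= start) abort("empty region")
  len <- frags$end - frags$start
  keep <- frags$contig == contig & len >= lmin & len <= lmax
  s <- frags$start[keep]; e <- frags$end[keep]
  npos <- end - start
  half <- w %/% 2L

  acc <- numeric(npos + 1L)
  add <- function(lo, hi, sign) {
    # add `sign` to positions lo..hi (genomic), clipped to the region
    ok <- hi >= start & lo <= end - 1L
    if (!any(ok)) return(invisible(NULL))
    li <- pmax(lo[ok], start) - start + 1L
    hi2 <- pmin(hi[ok], end - 1L) - start + 2L
    acc <<- acc + sign * (tabulate(li, npos + 1L) - tabulate(hi2, npos + 1L))
    invisible(NULL)
  }
  if (length(s) > 0) {
    # p such that s is in window: s - w/2 < p <= s + w/2
    add(s - half + 1L, s + half, -1)
    # p such that e-1 is in window
    add(e - 1L - half + 1L, e - 1L + half, -1)
    # fragments with both endpoints in the window were subtracted twice
    both_lo <- pmax(s - half + 1L, e - 1L - half + 1L)
    both_hi <- pmin(s + half, e - 1L + half)
    ok <- both_lo <= both_hi
    add(both_lo[ok], both_hi[ok], +1)
    # spanning: s < p - w/2 and e > p + w/2
    span_lo <- s + half + 1L
    span_hi <- e - half - 1L
    ok <- span_lo <= span_hi
    add(span_lo[ok], span_hi[ok], +1)
  }
  score <- cumsum(acc)[seq_len(npos)]
  new_track(tibble(contig = contig, pos = seq.int(start, end - 1L),
                   score = score),
            w = w, lmin = lmin, lmax = lmax, start = start, end = end)
}

new_track <- function(x, ...) {
  structure(as_tibble(x), class = c("wps_track", class(as_tibble(x))), ...)
}

track_attrs <- function(track) {
  attributes(track)[c("w", "lmin", "lmax", "start", "end")]
}

#' Median-adjust a WPS track in fixed segments
#'
#' Subtracts, within each non-overlapping `segment` bp block of the track
#' (blocks anchored at the track's first position; the last block may be
#' shorter), that block's median score, so every block has median zero.
#'
#' @param track A `wps_track`.
#' @param segment Block length in bp.
#' @return The adjusted `wps_track`.
#' @export
normalize_wps <- function(track, segment = 1000L) {
  stopifnot(segment >= 1)
  block <- (track$pos - track$pos[1]) %/% segment
  sc <- track$score
  for (b in unique(block)) {
    i <- block == b
    sc[i] <- sc[i] - median(sc[i])
  }
  out <- track
  out$score <- sc
  out
}

sg_smooth_vec <- function(x, window, order) {
  k <- window %/% 2L
  n <- length(x)
  if (n < window) abort("track shorter than the smoothing window")
  coef <- as.numeric(signal::sgolay(p = order, n = window)[k + 1L, ])
  # mirror padding (reflection about the end points, end point not repeated)
  xp <- c(x[(k + 1L):2L], x, x[(n - 1L):(n - k)])
  y <- stats::filter(xp, rev(coef), sides = 2L)
  as.numeric(y[(k + 1L):(k + n)])
}

#' Savitzky-Golay smoothing of a WPS track
#'
#' Fits a centered least-squares polynomial of the given order over a
#' sliding window and evaluates it at the center. Order-2 smoothing over
#' 21 bp removes position noise while preserving nucleosome-scale peaks
#' (any quadratic signal passes through unchanged). Edges are handled by
#' mirror-padding the track by half a window.
#'
#' @param track A `wps_track`.
#' @param window Odd window width in bp.
#' @param order Polynomial order; `window >= order + 2`.
#' @return The smoothed `wps_track`.
#' @export
smooth_wps <- function(track, window = 21L, order = 2L) {
  if (window %% 2L == 0L) abort("smoothing window must be odd")
  if (window < order + 2L) abort("smoothing window too small for the order")
  out <- track
  out$score <- sg_smooth_vec(track$score, window, order)
  out
}

#' Average WPS profile over a set of regions
#'
#' Computes, for each region, the WPS track over `anchor +/- halfspan`
#' (anchor = the region's center), optionally median-normalizes (1000 bp
#' segments) and Savitzky-Golay smooths each track, then averages tracks
#' across regions per offset. With `orient = TRUE` the tracks of `-` strand
#' regions are reversed before averaging.
#'
#' @param frags Fragment tibble.
#' @param regions Region tibble (`contig`, `start`, `end`, optional
#'   `strand`).
#' @param halfspan Half-width of the profile in bp.
#' @param w,lmin,lmax WPS window and fragment-length bin (see [raw_wps()]).
#' @param normalize,smooth Apply [normalize_wps()] / [smooth_wps()] per
#'   region track.
#' @param segment,smooth_window,smooth_order Normalization and smoothing
#'   parameters.
#' @param orient Reverse `-` strand regions before averaging.
#' @return A tibble of class `wps_profile` with columns `offset`,
#'   `mean_wps`, `n_regions`.
#' @export
average_wps <- function(frags, regions, halfspan = 1000L, w = 120L,
                        lmin = 120L, lmax = 180L, normalize = TRUE,
                        smooth = TRUE, segment = 1000L,
                        smooth_window = 21L, smooth_order = 2L,
                        orient = FALSE) {
  if (nrow(regions) == 0) abort("no regions")
  anchors <- (regions$start + regions$end) %/% 2L
  if (any(anchors - halfspan < 0)) {
    bad <- which(anchors - halfspan < 0)[1]
    abort(sprintf("region %d extends outside the scored area", bad))
  }
  offsets <- seq.int(-halfspan, halfspan)
  acc <- numeric(length(offsets))
  for (i in seq_len(nrow(regions))) {
    tr <- raw_wps(frags, regions$contig[i], anchors[i] - halfspan,
                  anchors[i] + halfspan + 1L, w = w,
                  lmin = lmin, lmax = lmax)
    if (normalize) tr <- normalize_wps(tr, segment)
    if (smooth) tr <- smooth_wps(tr, smooth_window, smooth_order)
    sc <- tr$score
    if (orient && "strand" %in% names(regions) &&
        identical(regions$strand[i], "-")) {
      sc <- rev(sc)
    }
    acc <- acc + sc
  }
  structure(
    tibble(offset = offsets, mean_wps = acc / nrow(regions),
           n_regions = nrow(regions)),
    class = c("wps_profile", class(tibble())),
    w = w, lmin = lmin, lmax = lmax
  )
}

#' Oscillation period of an averaged WPS profile
#'
#' Mean spacing between successive local maxima of the profile whose
#' offsets fall in `[lo_offset, hi_offset]`. A local maximum must be
#' strictly greater than every neighbour within +/-20 bp and must have its
#' full neighbourhood available (positions too close to the profile ends
#' cannot be certified as maxima). Phased nucleosome arrays around an
#' occluding factor yield spacings near the nucleosome repeat length.
#'
#' @param profile A `wps_profile` (or any tibble with `offset` and
#'   `mean_wps`).
#' @param lo_offset,hi_offset Offset range to scan.
#' @param neighborhood Half-width (bp) a maximum must dominate.
#' @return Mean peak-to-peak spacing in bp.
#' @export
wps_periodicity <- function(profile, lo_offset, hi_offset,
                            neighborhood = 20L) {
  if (hi_offset - lo_offset < 2L * neighborhood) {
    abort("offset span too short")
  }
  y <- profile$mean_wps
  n <- length(y)
  is_max <- vapply(seq_len(n), function(i) {
    if (i - neighborhood < 1L || i + neighborhood > n) return(FALSE)
    j <- (i - neighborhood):(i + neighborhood)
    j <- j[j != i]
    all(y[i] > y[j])
  }, logical(1))
  peaks <- profile$offset[is_max]
  peaks <- peaks[peaks >= lo_offset & peaks <= hi_offset]
  if (length(peaks) < 2L) abort("fewer than 2 local maxima: no oscillation")
  mean(diff(peaks))
}

#' Pearson correlation between two WPS tracks
#'
#' @param a,b `wps_track` tibbles over the same region.
#' @return Pearson correlation of per-position scores.
#' @export
track_correlation <- function(a, b) {
  if (nrow(a) != nrow(b) || !all(a$pos == b$pos) ||
      !all(a$contig == b$contig)) {
    abort("tracks must cover the same region")
  }
  if (stats::sd(a$score) == 0 || stats::sd(b$score) == 0) {
    abort("zero variance in a track: correlation undefined")
  }
  cor(a$score, b$score)
}
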