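#' Per-position read depth over an oligo
#'
#' Counts, for every position of a duplex-oligo reference (core plus
#' overhang), the number of reads covering it -- the per-oligo analogue of
#' a depth pileup. Reads are matched to oligos by id (the `contig` column).
#'
#' @param reads Fragment tibble in oligo coordinates (`contig` = oligo id).
#' @param design One row of an oligo design table (see
#'   [duplex_oligo_pool()]).
#' @return A tibble of class `depth_profile` with columns `oligo_id`,
#'   `pos`, `depth`, `pct_len` (position as percent across the oligo,
#'   `pos / (total_len - 1) * 100`).
#' @export
per_position_depth <- function(reads, design) {
  validate_oligo_designs(design)
  if (nrow(design) != 1) abort("per_position_depth takes a single design row")
  total <- design$core_len + design$overhang_len
  r <- reads[reads$contig == design$oligo_id, ]
  if (nrow(r) > 0 && (any(r$start < 0) || any(r$end > total))) {
    abort(sprintf("read outside reference bounds for %s", design$oligo_id))
  }
  depth <- integer(total)
  if (nrow(r) > 0) {
    acc <- tabulate(r$start + 1L, total + 1L) - tabulate(r$end + 1L, total + 1L)
    depth <- cumsum(acc)[seq_len(total)]
  }
  structure(
    tibble(oligo_id = design$oligo_id, pos = seq.int(0L, total - 1L),
           depth = as.integer(depth),
           pct_len = seq.int(0L, total - 1L) / (total - 1L) * 100),
    class = c("depth_profile", class(tibble())),
    design = design
  )
}

#' Overhang-to-core coverage ratio
#'
#' Mean depth over the single-stranded overhang positions divided by mean
#' depth over the double-stranded core. When every strand of a duplex is
#' emitted equally often with native ends, only the strand carrying the
#' overhang covers it, so the ratio is exactly 0.5 regardless of overhang
#' type, length (1-6 nt) or end; end-polishing drives it to 1 (5' fill-in)
#' or 0 (3' chew-back).
#'
#' @param profile A `depth_profile` from [per_position_depth()].
#' @param design The matching design row.
#' @return The ratio as a fraction.
#' @export
overhang_coverage_ratio <- function(profile, design) {
  validate_oligo_designs(design)
  if (design$overhang_len < 1) {
    abort("design has no overhang: ratio undefined")
  }
  total <- design$core_len + design$overhang_len
  over <- if (design$overhang_end == "right") {
    profile$pos >= design$core_len
  } else {
    profile$pos < design$overhang_len
  }
  core_depth <- mean(profile$depth[!over])
  if (core_depth == 0) abort("zero core depth")
  mean(profile$depth[over]) / core_depth
}

#' Fraction of full-length reads for one oligo
#'
#' Under the coupling-efficiency model the expectation is `q^(n-1)` for a
#' designed length n, so this fraction decays with oligo length.
#'
#' @param reads Oligo read tibble (needs `observed_len`).
#' @param designed_len Designed length (nt).
#' @return `count(observed_len == designed_len) / count(reads)`.
#' @export
full_length_fraction <- function(reads, designed_len) {
  if (nrow(reads) == 0) abort("no reads")
  mean(reads$observed_len == designed_len)
}

#' Length spectrum of truncation products
#'
#' Histogram of observed lengths restricted to truncations
#' (`observed_len < designed_len`), frequency-normalized over truncations
#' only. Under sub-unity coupling the truncation lengths are near-uniform
#' across the oligo.
#'
#' @param reads Oligo read tibble.
#' @param designed_len Designed length (nt).
#' @return A `length_spectrum` (empty when there are no truncations).
#' @export
truncation_spectrum <- function(reads, designed_len) {
  if (nrow(reads) == 0) abort("no reads")
  tr <- reads$observed_len[reads$observed_len < designed_len]
  if (length(tr) == 0) {
    return(new_spectrum(tibble(length = integer(), count = integer(),
                               frequency = numeric())))
  }
  length_histogram(tr)
}
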