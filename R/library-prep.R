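#' In-silico library preparation of duplex templates
#'
#' `apply_srsly()` models a single-stranded (native-end) preparation: each
#' strand of the duplex becomes a fragment with its coordinates untouched --
#' the top strand as `(top_start, top_end, +)` and the bottom strand as
#' `(bottom_start, bottom_end, -)`.
#'
#' `apply_end_polishing()` models conventional double-stranded preparation:
#' at each duplex end a 5' overhang is filled in (the outer coordinate is
#' kept) and a 3' overhang is chewed back (the inner coordinate is kept). In
#' both cases the surviving coordinate is the 5' terminus of the strand that
#' carries it, so the blunted molecule is always `[top_start, bottom_end)`,
#' emitted once per strand. End polishing therefore preserves every native
#' 5' end and rewrites every 3' end to mirror the complementary strand's 5'
#' end.
#'
#' @param templates Duplex template tibble (see
#'   [simulate_cfdna_templates()]).
#' @return A fragment tibble with two rows per template.
#' @export
#' @examples
#' t <- tibble::tibble(contig = "c", top_start = 100L, top_end = 200L,
#'                     bottom_start = 95L, bottom_end = 195L)
#' apply_srsly(t)
#' apply_end_polishing(t)
apply_srsly <- function(templates) {
  t <- validate_templates(templates)
  fragments(
    contig = rep(t$contig, 2L),
    start = c(t$top_start, t$bottom_start),
    end = c(t$top_end, t$bottom_end),
    strand = rep(c("+", "-"), each = nrow(t))
  )
}

#' @rdname apply_srsly
#' @export
apply_end_polishing <- function(templates) {
  t <- validate_templates(templates)
  if (any(t$bottom_end <= t$top_start)) {
    abort("degenerate duplex: bottom_end <= top_start")
  }
  fragments(
    contig = rep(t$contig, 2L),
    start = rep(t$top_start, 2L),
    end = rep(t$bottom_end, 2L),
    strand = rep(c("+", "-"), each = nrow(t))
  )
}
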