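#' Simulate a reference sequence with nucleosome-encoding dinucleotides
#'
#' Draws an i.i.d. uniform A/C/G/T background and, under each nucleosome dyad
#' (within +/-73 bp), overwrites positions in 10 bp register with
#' bendability-encoding bases: positions at phase 0 (mod 10) relative to the
#' dyad are drawn from the weak bases W = \{A, T\} with probability
#' `0.5 + dinuc_amplitude`, and positions at phase 5 are drawn from the
#' strong bases S = \{C, G\} with the same probability. This reproduces, in
#' aggregate, the A/T-rich minor-groove-in / G/C-rich minor-groove-out
#' oscillation of histone-wrapped DNA.
#'
#' @param length Contig length in bp.
#' @param dyads Integer vector of dyad positions (0-based), each within
#'   `[73, length - 73)`.
#' @param cfg A [sim_config()]; uses `dinuc_amplitude` and `seed`.
#' @param contig Contig name for the returned reference.
#' @return A single-contig `DNAStringSet`.
#' @export
simulate_reference <- function(length, dyads, cfg = sim_config(),
                               contig = "sim") {
  stopifnot(length >= 1)
  dyads <- as.integer(dyads)
  if (any(dyads < 73L | dyads >= length - 73L)) {
    abort("dyad positions must lie within [73, length - 73)")
  }
  seed_from_config(cfg)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  amp <- cfg$dinuc_amplitude
  if (base::length(dyads) > 0) {
    off <- seq(-73L, 73L)
    phase <- ((off %% 10L) + 10L) %% 10L
    w_off <- off[phase == 0L]
    s_off <- off[phase == 5L]
    w_pos <- unique(as.vector(outer(dyads, w_off, `+`)))
    s_pos <- unique(as.vector(outer(dyads, s_off, `+`)))
    draw <- function(pos, favored, other) {
      take <- runif(base::length(pos)) < 0.5 + amp
      pool_f <- sample(favored, base::length(pos), replace = TRUE)
      pool_o <- sample(other, base::length(pos), replace = TRUE)
      ifelse(take, pool_f, pool_o)
    }
    bases[w_pos + 1L] <- draw(w_pos, c("A", "T"), c("C", "G"))
    bases[s_pos + 1L] <- draw(s_pos, c("C", "G"), c("A", "T"))
  }
  ref <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(ref) <- contig
  ref
}

#' Lay nucleosome dyads on a regular grid with positional jitter
#'
#' @param length Contig length (bp).
#' @param spacing Repeat length (bp).
#' @param jitter_sd SD of Gaussian positional jitter (bp).
#' @param margin Dyads are kept within `[margin, length - margin)`.
#' @return Sorted integer vector of dyad positions.
#' @keywords internal
dyad_grid <- function(length, spacing, jitter_sd = 5, margin = 100L) {
  grid <- seq.int(margin, length - margin - 1L, by = spacing)
  dy <- as.integer(round(grid + rnorm(base::length(grid), 0, jitter_sd)))
  sort(pmin(pmax(dy, margin), length - margin - 1L))
}
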