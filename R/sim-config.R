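#' Simulation configuration
#'
#' Bundles every parameter of the synthetic cfDNA / oligo generator. The
#' defaults encode the biological regime the generator emulates:
#' chromatosomes protect 167 bp (core particle 144 bp), nucleosomes repeat
#' every ~180 bp, nuclease access to the exposed minor groove cuts a 10.4 bp
#' ladder into sub-nucleosomal fragments, transcription-factor footprints
#' protect 35-80 bp, and phosphoramidite synthesis couples with ~99%
#' efficiency per cycle.
#'
#' @param nucleosome_spacing Nucleosome repeat length in bp.
#' @param chromatosome_len Chromatosome-protected length in bp.
#' @param core_len Nucleosome core-particle protected length in bp.
#' @param cut_period Sub-nucleosomal cut-ladder period in bp (may be
#'   non-integer; ladder rungs are rounded to integer lengths).
#' @param subnucleosomal_weight Probability that a template is a ladder
#'   truncation rather than a full chromatosome span.
#' @param length_jitter_sd SD (bp) of the chromatosome-length jitter.
#' @param overhang_probs Data frame with columns `type` (`"blunt"`, `"five"`,
#'   `"three"`), `len` (nt, 0 for blunt) and `prob`; the per-end overhang
#'   distribution. See [default_overhang_probs()].
#' @param footprint_len_range Length-2 integer vector; protected-fragment
#'   lengths (bp) at transcription-factor footprints.
#' @param coupling_efficiency Per-cycle nucleotide coupling probability `q`
#'   for oligo synthesis, in (0, 1].
#' @param dinuc_amplitude Bias added to 0.5 for periodic weak/strong base
#'   placement under nucleosome dyads (0 = no encoding, 0.5 = saturated).
#' @param bead_bias If `TRUE`, oligo reads are additionally thinned by a
#'   logistic length-recovery curve (midpoint `bead_midpoint`, scale
#'   `bead_scale`) emulating cleanup losses of very short oligos.
#' @param bead_midpoint,bead_scale Logistic recovery parameters (nt).
#' @param seed Integer seed; every generator call is reproducible given it.
#'
#' @return A list with class `"sim_config"`.
#' @export
sim_config <- function(nucleosome_spacing = 180L,
                       chromatosome_len = 167L,
                       core_len = 144L,
                       cut_period = 10.4,
                       subnucleosomal_weight = 0.15,
                       length_jitter_sd = 3,
                       overhang_probs = default_overhang_probs(),
                       footprint_len_range = c(35L, 80L),
                       coupling_efficiency = 0.99,
                       dinuc_amplitude = 0.3,
                       bead_bias = FALSE,
                       bead_midpoint = 33,
                       bead_scale = 3,
                       seed = NULL) {
  stopifnot(
    nucleosome_spacing > 0, chromatosome_len > 0, core_len > 0,
    cut_period > 0, length_jitter_sd >= 0,
    subnucleosomal_weight >= 0, subnucleosomal_weight <= 1,
    dinuc_amplitude >= 0, dinuc_amplitude <= 0.5,
    coupling_efficiency > 0, coupling_efficiency <= 1,
    length(footprint_len_range) == 2,
    footprint_len_range[1] <= footprint_len_range[2]
  )
  op <- as_tibble(overhang_probs)
  stopifnot(all(c("type", "len", "prob") %in% names(op)),
            all(op$type %in% c("blunt", "five", "three")),
            all(op$len >= 0), all(op$len <= 6),
            all(op$prob >= 0), sum(op$prob) > 0)
  if (any(op$type == "blunt" & op$len != 0) ||
      any(op$type != "blunt" & op$len == 0)) {
    abort("overhang length 0 if and only if type is 'blunt'")
  }
  op$prob <- op$prob / sum(op$prob)
  structure(
    list(
      nucleosome_spacing = as.integer(nucleosome_spacing),
      chromatosome_len = as.integer(chromatosome_len),
      core_len = as.integer(core_len),
      cut_period = cut_period,
      subnucleosomal_weight = subnucleosomal_weight,
      length_jitter_sd = length_jitter_sd,
      overhang_probs = op,
      footprint_len_range = as.integer(footprint_len_range),
      coupling_efficiency = coupling_efficiency,
      dinuc_amplitude = dinuc_amplitude,
      bead_bias = isTRUE(bead_bias),
      bead_midpoint = bead_midpoint,
      bead_scale = bead_scale,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @param p_blunt,p_five,p_three Marginal probabilities of a blunt end, a 5'
#'   overhang and a 3' overhang; overhang lengths are uniform on
#'   `len_range[1]..len_range[2]`.
#' @param len_range Overhang length range in nt.
#' @export
default_overhang_probs <- function(p_blunt = 0.4, p_five = 0.3,
                                   p_three = 0.3, len_range = c(1L, 6L)) {
  lens <- seq.int(len_range[1], len_range[2])
  k <- length(lens)
  tibble(
    type = c("blunt", rep("five", k), rep("three", k)),
    len = c(0L, lens, lens),
    prob = c(p_blunt, rep(p_five / k, k), rep(p_three / k, k))
  )
}

#' @rdname sim_config
#' @export
blunt_only_overhangs <- function() {
  tibble(type = "blunt", len = 0L, prob = 1)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  scalars <- x[!names(x) %in% "overhang_probs"]
  for (nm in names(scalars)) {
    v <- scalars[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(v)) "NULL" else paste(v, collapse = ", ")))
  }
  op <- x$overhang_probs
  marg <- tapply(op$prob, op$type, sum)
  cat(sprintf("  %-22s %s\n", "overhang_probs",
              paste(names(marg), round(marg, 3), sep = "=", collapse = " ")))
  invisible(x)
}

# Seed the RNG from a config, locally to the calling generator.
seed_from_config <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  invisible(NULL)
}
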