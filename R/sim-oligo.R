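#' Simulate reads from synthesized single-stranded oligo pools
#'
#' Models phosphoramidite synthesis with per-cycle coupling efficiency `q`:
#' a molecule of designed length n is full length with probability
#' `q^(n-1)`; otherwise it is a truncation whose observed length is uniform
#' on 1..n-1. Purification retains full-length molecules always and
#' truncations with probability rho (`desalt` 1, `hplc` 0.35, `page` 0.12 --
#' calibration constants chosen only to give the qualitative
#' desalt < HPLC < PAGE purity ordering). Molecules are resampled until
#' `reads_per_oligo` reads survive per oligo. With `cfg$bead_bias`, reads are
#' additionally thinned by a logistic length-recovery curve emulating
#' cleanup losses of very short oligos.
#'
#' @param designed_lengths Integer vector of designed oligo lengths (nt);
#'   oligo ids are `oligo_<length>` unless `ids` is given.
#' @param reads_per_oligo Reads to emit per oligo.
#' @param cfg A [sim_config()]; uses `coupling_efficiency` and `seed`.
#' @param purification One of `"desalt"`, `"hplc"`, `"page"`.
#' @param ids Optional character vector of oligo ids.
#' @return A tibble with columns `oligo_id`, `designed_len`, `observed_len`,
#'   `full_length`.
#' @export
simulate_oligo_reads <- function(designed_lengths, reads_per_oligo,
                                 cfg = sim_config(),
                                 purification = c("desalt", "hplc", "page"),
                                 ids = NULL) {
  purification <- match.arg(purification)
  stopifnot(all(designed_lengths >= 1), reads_per_oligo >= 1)
  q <- cfg$coupling_efficiency
  if (q <= 0) abort("coupling efficiency must be positive")
  rho <- c(desalt = 1, hplc = 0.35, page = 0.12)[[purification]]
  seed_from_config(cfg)
  if (is.null(ids)) ids <- paste0("oligo_", designed_lengths)

  sample_one <- function(n, id) {
    got <- integer(0)
    while (length(got) < reads_per_oligo) {
      m <- max(1000L, 2L * (reads_per_oligo - length(got)))
      full <- runif(m) < q^(n - 1)
      obs <- ifelse(full, n,
                    if (n > 1) sample.int(n - 1L, m, replace = TRUE)
                    else n)
      keep <- full | runif(m) < rho
      if (cfg$bead_bias) {
        recov <- 1 / (1 + exp(-(obs - cfg$bead_midpoint) / cfg$bead_scale))
        keep <- keep & runif(m) < recov
      }
      got <- c(got, obs[keep])
    }
    got <- got[seq_len(reads_per_oligo)]
    tibble(oligo_id = id, designed_len = as.integer(n),
           observed_len = as.integer(got), full_length = got == n)
  }
  dplyr::bind_rows(purrr::map2(designed_lengths, ids, sample_one))
}

#' Synthetic duplex-oligo designs and templates
#'
#' `duplex_oligo_pool()` builds the standard 12-member design pool: each
#' duplex has an identifiable complementary core (50 nt), one blunt end, and
#' on the other end a 5' or 3' single-stranded overhang of 1-6 nt.
#' `oligo_templates()` converts designs to duplex templates in each oligo's
#' own 0-based coordinate system (contig = oligo id), ready for
#' [apply_srsly()] / [apply_end_polishing()].
#'
#' @param core_len Complementary-core length (nt).
#' @param overhang_lens Overhang lengths present in the pool.
#' @return `duplex_oligo_pool()`: a design tibble with columns `oligo_id`,
#'   `core_len`, `overhang_end`, `overhang_type`, `overhang_len`.
#' @export
duplex_oligo_pool <- function(core_len = 50L, overhang_lens = 1:6) {
  designs <- tidyr::expand_grid(
    overhang_type = c("five", "three"),
    overhang_len = as.integer(overhang_lens)
  )
  tibble(
    oligo_id = paste0("oligo_", substr(designs$overhang_type, 1, 1),
                      designs$overhang_len),
    core_len = as.integer(core_len),
    overhang_end = "right",
    overhang_type = designs$overhang_type,
    overhang_len = designs$overhang_len
  )
}

#' @rdname duplex_oligo_pool
#' @param designs Design tibble as returned by [duplex_oligo_pool()].
#' @export
oligo_templates <- function(designs) {
  validate_oligo_designs(designs)
  core <- designs$core_len
  len <- designs$overhang_len
  # blunt left end at 0; the overhang (if any) protrudes on the right:
  # a right-end 5' overhang belongs to the bottom strand, a 3' to the top.
  top_end <- ifelse(designs$overhang_type == "three", core + len, core)
  bottom_end <- ifelse(designs$overhang_type == "five", core + len, core)
  tibble(
    contig = designs$oligo_id,
    top_start = 0L, top_end = as.integer(top_end),
    bottom_start = 0L, bottom_end = as.integer(bottom_end)
  )
}

validate_oligo_designs <- function(designs) {
  req <- c("oligo_id", "core_len", "overhang_end", "overhang_type",
           "overhang_len")
  if (!all(req %in% names(designs))) {
    abort(paste0("oligo design table needs columns: ",
                 paste(req, collapse = ", ")))
  }
  if (any(designs$core_len < 1)) abort("core_len must be >= 1")
  none <- designs$overhang_len == 0
  if (any(none != (designs$overhang_type == "none"))) {
    abort("overhang_len 0 if and only if overhang_type is 'none'")
  }
  if (any(designs$overhang_len < 0 | designs$overhang_len > 6)) {
    abort("overhang_len must be in 0..6")
  }
  invisible(as_tibble(designs))
}
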