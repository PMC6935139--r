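#' Simulate nucleosome-protected duplex cfDNA templates
#'
#' Generates double-stranded template molecules before any library
#' preparation. Dyads are laid on a `nucleosome_spacing` grid with 5 bp
#' positional jitter; each template picks a random dyad and is either a full
#' chromatosome span (length ~ Normal(`chromatosome_len`,
#' `length_jitter_sd`), probability `1 - subnucleosomal_weight`) or a
#' one-sided cut-ladder truncation of that span to length
#' `round(chromatosome_len - k * cut_period)`, k uniform on 1..8, with the
#' cut side chosen at random. Each duplex end then independently receives an
#' overhang drawn from `overhang_probs`, implemented by extending the
#' protruding strand outward; a 5' overhang protrudes the strand whose 5'
#' terminus is at that end, a 3' overhang the opposite strand.
#'
#' A duplex template row has columns `contig`, `top_start`, `top_end`,
#' `bottom_start`, `bottom_end`: the top strand reads 5'->3' left to right,
#' the bottom strand 5'->3' right to left.
#'
#' @param cfg A [sim_config()].
#' @param ref_length Contig length the templates must fit inside (bp).
#' @param n Number of templates.
#' @param contig Contig name.
#' @return A list with `templates` (tibble of duplex rows) and `dyads`
#'   (integer vector of dyad positions used).
#' @export
simulate_cfdna_templates <- function(cfg = sim_config(), ref_length = 1e6,
                                     n, contig = "sim") {
  stopifnot(n >= 1)
  seed_from_config(cfg)
  margin <- 100L
  if (ref_length < 2 * margin + cfg$chromatosome_len) {
    abort("ref_length too small for the configured protection length")
  }
  dyads <- dyad_grid(ref_length, cfg$nucleosome_spacing, 5, margin)

  draw <- function(m) {
    dyad <- dyads[sample.int(length(dyads), m, replace = TRUE)]
    ladder <- runif(m) < cfg$subnucleosomal_weight
    len <- integer(m)
    len[!ladder] <- as.integer(round(rnorm(sum(!ladder),
                                           cfg$chromatosome_len,
                                           cfg$length_jitter_sd)))
    k <- sample.int(8L, sum(ladder), replace = TRUE)
    len[ladder] <- as.integer(round(cfg$chromatosome_len - k * cfg$cut_period))
    len <- pmax(len, 20L)
    full_start <- dyad - cfg$chromatosome_len %/% 2L
    start <- integer(m)
    # full spans centered on the dyad; ladder truncations keep one native side
    start[!ladder] <- dyad[!ladder] - len[!ladder] %/% 2L
    cut_left <- runif(sum(ladder)) < 0.5
    ls <- full_start[ladder]
    le <- ls + cfg$chromatosome_len
    start[ladder] <- ifelse(cut_left, le - len[ladder], ls)
    tibble(dyad = dyad, start = start, end = start + len)
  }

  add_overhangs <- function(core) {
    m <- nrow(core)
    op <- cfg$overhang_probs
    pick <- function() op[sample.int(nrow(op), m, replace = TRUE,
                                     prob = op$prob), ]
    left <- pick(); right <- pick()
    top_start <- core$start - ifelse(left$type == "five", left$len, 0L)
    bottom_start <- core$start - ifelse(left$type == "three", left$len, 0L)
    bottom_end <- core$end + ifelse(right$type == "five", right$len, 0L)
    top_end <- core$end + ifelse(right$type == "three", right$len, 0L)
    tibble(
      contig = contig,
      top_start = as.integer(top_start), top_end = as.integer(top_end),
      bottom_start = as.integer(bottom_start),
      bottom_end = as.integer(bottom_end)
    )
  }

  templates <- add_overhangs(draw(n))
  in_bounds <- function(t) {
    pmin(t$top_start, t$bottom_start) >= 0L &
      pmax(t$top_end, t$bottom_end) <= ref_length
  }
  bad <- which(!in_bounds(templates))
  attempts <- n
  while (length(bad) > 0) {
    attempts <- attempts + length(bad)
    if (attempts > 100 * n) {
      abort("resampling cap reached: templates do not fit the contig")
    }
    redo <- add_overhangs(draw(length(bad)))
    templates[bad, ] <- redo
    bad <- bad[!in_bounds(redo)]
  }
  list(templates = templates, dyads = dyads)
}

#' Simulate transcription-factor footprint loci with phased nucleosomes
#'
#' Emulates CTCF-like loci: the bound factor occludes nucleosomes at its
#' site, protecting short fragments (length uniform on
#' `footprint_len_range`, centered at the site +/- 3 bp), while flanking
#' nucleosome arrays phased at `site +/- (90 + m * nucleosome_spacing)`,
#' m = 0..5, protect chromatosome-length fragments. The short:long mixture
#' is 1:4. Sites are laid 4 kb apart on one synthetic contig so their
#' +/-1 kb neighbourhoods never interact.
#'
#' @param cfg A [sim_config()].
#' @param n_sites Number of binding sites.
#' @param frags_per_site Templates generated per site.
#' @return A list with `sites` (region tibble; each site is the 1 bp
#'   interval at its center), `templates` (duplex tibble) and `ref_length`.
#' @export
simulate_ctcf_locus <- function(cfg = sim_config(), n_sites, frags_per_site) {
  stopifnot(n_sites >= 1, frags_per_site >= 1)
  seed_from_config(cfg)
  site_spacing <- 4000L
  centers <- 2000L + site_spacing * (seq_len(n_sites) - 1L)
  ref_length <- 2000L + site_spacing * n_sites

  n_short <- max(1L, round(frags_per_site / 5))
  n_long <- frags_per_site - n_short
  dyad_off <- as.integer(outer(c(-1L, 1L), 90L + cfg$nucleosome_spacing * (0:5)))

  fp_pool <- seq.int(cfg$footprint_len_range[1], cfg$footprint_len_range[2])
  per_site <- function(center) {
    shor_len <- fp_pool[sample.int(length(fp_pool), n_short, replace = TRUE)]
    shor_mid <- center + sample(-3:3, n_short, replace = TRUE)
    # per-template positional dispersion (sd 5 bp), as for the cfDNA dyad
    # grid: nucleosomes are phased, not fixed, across molecules
    long_dyad <- center + dyad_off[sample.int(length(dyad_off), n_long,
                                              replace = TRUE)] +
      as.integer(round(rnorm(n_long, 0, 5)))
    long_len <- pmax(20L, as.integer(round(rnorm(n_long, cfg$chromatosome_len,
                                                 cfg$length_jitter_sd))))
    len <- c(shor_len, long_len)
    mid <- c(shor_mid, long_dyad)
    start <- mid - len %/% 2L
    tibble(start = start, end = start + len)
  }

  core <- dplyr::bind_rows(lapply(centers, per_site))
  op <- cfg$overhang_probs
  m <- nrow(core)
  pick <- function() op[sample.int(nrow(op), m, replace = TRUE,
                                   prob = op$prob), ]
  left <- pick(); right <- pick()
  templates <- tibble(
    contig = "sim",
    top_start = as.integer(core$start -
                             ifelse(left$type == "five", left$len, 0L)),
    top_end = as.integer(core$end +
                           ifelse(right$type == "three", right$len, 0L)),
    bottom_start = as.integer(core$start -
                                ifelse(left$type == "three", left$len, 0L)),
    bottom_end = as.integer(core$end +
                              ifelse(right$type == "five", right$len, 0L))
  )
  sites <- tibble(contig = "sim", start = centers, end = centers + 1L,
                  strand = ".")
  list(sites = sites, templates = templates, ref_length = ref_length)
}

validate_templates <- function(t) {
  req <- c("contig", "top_start", "top_end", "bottom_start", "bottom_end")
  if (!all(req %in% names(t))) {
    abort(paste0("duplex template table needs columns: ",
                 paste(req, collapse = ", ")))
  }
  if (any(t$top_end <= t$top_start) || any(t$bottom_end <= t$bottom_start)) {
    abort("duplex strand intervals must be non-empty")
  }
  overlap <- pmin(t$top_end, t$bottom_end) - pmax(t$top_start, t$bottom_start)
  if (any(overlap < 10)) {
    abort("duplex strands must overlap by at least 10 bp")
  }
  if (any(abs(t$top_start - t$bottom_start) > 6) ||
      any(abs(t$top_end - t$bottom_end) > 6)) {
    abort("overhangs longer than 6 nt are not valid duplex templates")
  }
  as_tibble(t)
}
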