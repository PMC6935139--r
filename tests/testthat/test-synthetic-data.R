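test_that("reference generator encodes the 10 bp weak/strong register", {
  # amplitude 0: no bias anywhere
  cfg0 <- sim_config(dinuc_amplitude = 0, seed = 4)
  ref0 <- simulate_reference(1e5, seq(500, 99000, by = 250), cfg0)
  base_freq <- table(strsplit(as.character(ref0[[1]]), "")[[1]]) / 1e5
  expect_true(all(abs(base_freq - 0.25) < 0.01))

  # amplitude 0.5: saturated weak bases at phase-0 positions under dyads
  cfg1 <- sim_config(dinuc_amplitude = 0.5, seed = 5)
  dyads <- seq(500, 99000, by = 250)
  ref1 <- simulate_reference(1e5, dyads, cfg1)
  chars <- strsplit(as.character(ref1[[1]]), "")[[1]]
  w_pos <- as.vector(outer(dyads, seq(-70, 70, by = 10), `+`))
  expect_true(all(chars[w_pos + 1] %in% c("A", "T")))

  expect_error(simulate_reference(1000, 10, cfg0), "dyad")
})

test_that("nucleosomal W-indicator autocorrelates at lag 10", {
  cfg <- sim_config(dinuc_amplitude = 0.3, seed = 6)
  dyads <- seq(150, by = 250, length.out = 398)
  ref <- simulate_reference(1e5, dyads, cfg)
  chars <- strsplit(as.character(ref[[1]]), "")[[1]]
  # W-indicator restricted to nucleosomal positions of one dyad register
  nuc_pos <- sort(as.vector(outer(dyads, -73:73, `+`)))
  w <- as.numeric(chars[nuc_pos + 1] %in% c("A", "T"))
  ac <- as.numeric(acf(w, lag.max = 15, plot = FALSE)$acf)[-1]
  expect_equal(which.max(ac[5:15]) + 4, 10)
})

test_that("cfDNA template generator produces the configured length modes", {
  # single chromatosome mode when the ladder is off
  cfg <- sim_config(subnucleosomal_weight = 0, seed = 7)
  sim <- simulate_cfdna_templates(cfg, ref_length = 2e5, n = 5000)
  core_len <- with(sim$templates,
                   pmin(top_end, bottom_end) - pmax(top_start, bottom_start))
  expect_true(all(abs(core_len - 167) <= 5 * cfg$length_jitter_sd))

  # blunt-only overhang model: both strands share the same interval
  cfgb <- sim_config(overhang_probs = blunt_only_overhangs(), seed = 8)
  simb <- simulate_cfdna_templates(cfgb, ref_length = 2e5, n = 2000)
  expect_equal(simb$templates$top_start, simb$templates$bottom_start)
  expect_equal(simb$templates$top_end, simb$templates$bottom_end)

  # overhang lengths never exceed 6 nt and duplexes stay duplexed
  cfgd <- sim_config(seed = 9)
  simd <- simulate_cfdna_templates(cfgd, ref_length = 2e5, n = 2000)
  expect_true(all(abs(simd$templates$top_start -
                        simd$templates$bottom_start) <= 6))
  expect_true(all(abs(simd$templates$top_end -
                        simd$templates$bottom_end) <= 6))
})

test_that("default generator shows ladder maxima near 167 - k*10.4", {
  cfg <- sim_config(seed = 10)
  sim <- simulate_cfdna_templates(cfg, ref_length = 1e6, n = 1e5)
  top_len <- sim$templates$top_end - sim$templates$top_start
  counts <- tabulate(top_len, 200)
  for (k in 1:4) {
    rung <- round(167 - k * 10.4)
    # local maximum within +/-3 bp of the predicted rung
    window <- counts[(rung - 3):(rung + 3)]
    expect_equal(which.max(window), 4, tolerance = 1,
                 label = sprintf("rung k=%d", k))
  }
})

test_that("generation is reproducible bit-for-bit under a fixed seed", {
  cfg <- sim_config(seed = 11)
  a <- simulate_cfdna_templates(cfg, ref_length = 1e5, n = 500)
  b <- simulate_cfdna_templates(cfg, ref_length = 1e5, n = 500)
  expect_identical(a, b)
  ra <- simulate_reference(5000, c(500, 900), sim_config(seed = 12))
  rb <- simulate_reference(5000, c(500, 900), sim_config(seed = 12))
  expect_identical(as.character(ra), as.character(rb))
  oa <- simulate_oligo_reads(c(40, 60), 100, sim_config(seed = 13))
  ob <- simulate_oligo_reads(c(40, 60), 100, sim_config(seed = 13))
  expect_identical(oa, ob)
})

test_that("native-end preparation never modifies coordinates", {
  t <- tibble::tibble(contig = "c", top_start = 100L, top_end = 200L,
                      bottom_start = 95L, bottom_end = 195L)
  out <- apply_srsly(t)
  expect_equal(out$start, c(100L, 95L))
  expect_equal(out$end, c(200L, 195L))
  expect_equal(out$strand, c("+", "-"))

  blunt <- tibble::tibble(contig = "c", top_start = 100L, top_end = 200L,
                          bottom_start = 100L, bottom_end = 200L)
  outb <- apply_srsly(blunt)
  expect_equal(outb$start, c(100L, 100L))
  expect_equal(outb$end, c(200L, 200L))

  # conservation: the multiset of output lengths is the two strand lengths
  set.seed(14)
  sim <- simulate_cfdna_templates(sim_config(seed = 14), 1e5, 200)
  fr <- apply_srsly(sim$templates)
  expect_setequal(
    fr$end - fr$start,
    c(sim$templates$top_end - sim$templates$top_start,
      sim$templates$bottom_end - sim$templates$bottom_start)
  )
})

test_that("end polishing blunts to [top_start, bottom_end) in all overhang configurations", {
  # hand-walked oracle: at each end, fill in 5' overhangs (keep the outer
  # coordinate) and chew back 3' overhangs (keep the inner coordinate); the
  # survivor is always the 5' terminus of the strand carrying it.
  for (left_type in c("blunt", "five", "three")) {
    for (right_type in c("blunt", "five", "three")) {
      for (ln in 0:6) {
        ll <- if (left_type == "blunt") 0L else ln
        rl <- if (right_type == "blunt") 0L else ln
        if ((left_type != "blunt" && ln == 0) ||
            (right_type != "blunt" && ln == 0)) next
        s <- 100L; e <- 200L
        top_start <- s - if (left_type == "five") ll else 0L
        bottom_start <- s - if (left_type == "three") ll else 0L
        bottom_end <- e + if (right_type == "five") rl else 0L
        top_end <- e + if (right_type == "three") rl else 0L
        t <- tibble::tibble(contig = "c", top_start = top_start,
                            top_end = top_end, bottom_start = bottom_start,
                            bottom_end = bottom_end)
        # oracle walk: left end keeps min(start) if 5' overhang (fill-in
        # extends the recessed bottom strand), keeps max(start) if 3'
        # (chew-back removes the protruding bottom 3'); right end symmetric.
        left_keep <- if (left_type == "five") min(top_start, bottom_start)
                     else max(top_start, bottom_start)
        right_keep <- if (right_type == "five") max(top_end, bottom_end)
                      else min(top_end, bottom_end)
        out <- apply_end_polishing(t)
        expect_equal(unique(out$start), left_keep)
        expect_equal(unique(out$end), right_keep)
        expect_equal(unique(out$start), top_start)
        expect_equal(unique(out$end), bottom_end)
      }
    }
  }
})

test_that("polishing examples match the fill-in/chew-back walk", {
  t3 <- tibble::tibble(contig = "c", top_start = 100L, top_end = 200L,
                       bottom_start = 95L, bottom_end = 195L)
  out3 <- apply_end_polishing(t3)  # 3' overhangs both ends
  expect_equal(unique(out3$start), 100L)
  expect_equal(unique(out3$end), 195L)

  t5 <- tibble::tibble(contig = "c", top_start = 100L, top_end = 200L,
                       bottom_start = 105L, bottom_end = 205L)
  out5 <- apply_end_polishing(t5)  # 5' overhangs both ends
  expect_equal(unique(out5$start), 100L)
  expect_equal(unique(out5$end), 205L)

  blunt <- tibble::tibble(contig = "c", top_start = 100L, top_end = 200L,
                          bottom_start = 100L, bottom_end = 200L)
  expect_equal(apply_end_polishing(blunt)[, c("start", "end")],
               apply_srsly(blunt)[, c("start", "end")])
})

test_that("5' coordinates agree between prep modes; 3' differ with overhangs", {
  cfg <- sim_config(seed = 15)
  sim <- simulate_cfdna_templates(cfg, 2e5, 3000)
  native <- apply_srsly(sim$templates)
  polished <- apply_end_polishing(sim$templates)
  five_of <- function(fr) ifelse(fr$strand == "+", fr$start, fr$end - 1L)
  three_of <- function(fr) ifelse(fr$strand == "+", fr$end - 1L, fr$start)
  expect_identical(five_of(native), five_of(polished))
  expect_gt(sum(three_of(native) != three_of(polished)), 0)

  # blunt-only models give identical interval multisets
  cfgb <- sim_config(overhang_probs = blunt_only_overhangs(), seed = 16)
  simb <- simulate_cfdna_templates(cfgb, 2e5, 1000)
  expect_identical(apply_srsly(simb$templates)[, c("start", "end")],
                   apply_end_polishing(simb$templates)[, c("start", "end")])
})

test_that("CTCF locus generator places footprints and phased arrays", {
  cfg <- sim_config(seed = 17)
  loc <- simulate_ctcf_locus(cfg, n_sites = 1, frags_per_site = 5)
  expect_equal(nrow(loc$templates), 5)

  cfg50 <- sim_config(footprint_len_range = c(50, 50), seed = 18)
  loc50 <- simulate_ctcf_locus(cfg50, n_sites = 20, frags_per_site = 50)
  fr <- apply_srsly(loc50$templates)
  core <- with(loc50$templates,
               pmin(top_end, bottom_end) - pmax(top_start, bottom_start))
  short <- core[core < 100]
  expect_true(all(short == 50))

  # short-fragment midpoints pile up at site centers
  cfg2 <- sim_config(seed = 19)
  loc2 <- simulate_ctcf_locus(cfg2, n_sites = 200, frags_per_site = 100)
  fr2 <- apply_srsly(loc2$templates)
  len2 <- fr2$end - fr2$start
  sel <- len2 >= 35 & len2 <= 80 & fr2$strand == "+"
  mid <- (fr2$start[sel] + fr2$end[sel]) %/% 2
  centers <- loc2$sites$start
  site_of <- centers[findInterval(mid, centers - 2000) ]
  dist <- mid - site_of
  expect_lt(stats::quantile(abs(dist), 0.9), 30)
})

test_that("oligo read generator follows the coupling-efficiency model", {
  # q = 1: everything is full length under any purification
  cfg1 <- sim_config(coupling_efficiency = 1, seed = 20)
  r1 <- simulate_oligo_reads(c(40, 100), 2000, cfg1, "page")
  expect_true(all(r1$full_length))

  # closed form q^(n-1) at q = 0.99, n = 60: 0.553
  cfg <- sim_config(coupling_efficiency = 0.99, seed = 21)
  r <- simulate_oligo_reads(60, 1e5, cfg, "desalt")
  expect_equal(mean(r$full_length), 0.99^59, tolerance = 0.02)

  # expected full-length fraction strictly decreases with length
  lens <- seq(40, 120, by = 20)
  rr <- simulate_oligo_reads(lens, 2e4, sim_config(seed = 22), "desalt")
  frac <- tapply(rr$full_length, rr$designed_len, mean)
  expect_true(all(diff(frac[as.character(lens)]) < 0))

  # read accounting
  expect_equal(nrow(rr), length(lens) * 2e4)
  expect_true(all(rr$observed_len >= 1 & rr$observed_len <= rr$designed_len))
  expect_equal(rr$full_length, rr$observed_len == rr$designed_len)
})
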