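#' Terminal base-composition profiles
#'
#' Computes, strand-resolved, the base composition around both termini of a
#' fragment set. For each fragment the 5' profile reads 5'->3' into the
#' fragment from offset `-upstream` to `+downstream` (offset 0 = the 5'
#' terminal base); the 3' profile reads across the 3' terminus with the same
#' offset convention along the fragment's own strand (negative offsets are
#' inside the fragment, positive are downstream genomic context). Bases are
#' complemented for `-` fragments so profiles always describe the read
#' strand. Proportions at each offset are computed over all fragments
#' (positions with N excluded); each channel is then divided by its modal
#' proportion across offsets and log2-transformed, so that deviations from
#' background composition appear as departures from zero.
#'
#' Fragments whose flanks would leave the contig are skipped (count stored
#' in attribute `n_skipped`); it is an error if all are skipped.
#'
#' @param frags Fragment tibble.
#' @param ref Reference (see [as_reference()]).
#' @param upstream,downstream Window extent in bp around each terminus.
#' @return A tibble of class `position_profile` with columns `end`
#'   (`"five_prime"` / `"three_prime"`), `offset`, `channel` (base), `value`
#'   (raw proportion) and `norm_log2`.
#' @export
termini_composition <- function(frags, ref, upstream = 2, downstream = 34) {
  frags <- validate_fragments(frags)
  if (nrow(frags) == 0) abort("no fragments")
  chars <- reference_chars(ref)
  offsets <- seq.int(-upstream, downstream)

  dir <- ifelse(frags$strand == "+", 1L, -1L)
  t5 <- ifelse(frags$strand == "+", frags$start, frags$end - 1L)
  t3 <- ifelse(frags$strand == "+", frags$end - 1L, frags$start)
  clen <- vapply(chars, length, 0L)[frags$contig]
  reach <- max(upstream, downstream)
  lo <- pmin(t5 - dir * reach, t5 + dir * reach,
             t3 - dir * reach, t3 + dir * reach)
  hi <- pmax(t5 - dir * reach, t5 + dir * reach,
             t3 - dir * reach, t3 + dir * reach)
  ok <- lo >= 0 & hi < clen
  n_skipped <- sum(!ok)
  if (!any(ok)) abort("all fragments fall outside the reference")
  frags <- frags[ok, ]; dir <- dir[ok]; t5 <- t5[ok]; t3 <- t3[ok]

  count_end <- function(anchor) {
    res <- lapply(offsets, function(k) {
      pos <- anchor + dir * k
      b <- character(length(pos))
      for (ctg in unique(frags$contig)) {
        i <- frags$contig == ctg
        b[i] <- chars[[ctg]][pos[i] + 1L]
      }
      b <- ifelse(dir == 1L, b, chartr("ACGT", "TGCA", b))
      b <- b[b %in% c("A", "C", "G", "T")]
      tab <- table(factor(b, levels = c("A", "C", "G", "T")))
      as.numeric(tab) / max(1L, length(b))
    })
    mat <- do.call(rbind, res)  # offsets x 4
    tibble(
      offset = rep(offsets, times = 4L),
      channel = rep(c("A", "C", "G", "T"), each = length(offsets)),
      value = as.vector(mat)
    )
  }

  out <- dplyr::bind_rows(
    dplyr::mutate(count_end(t5), end = "five_prime"),
    dplyr::mutate(count_end(t3), end = "three_prime")
  )
  out <- dplyr::group_by(out, .data$end, .data$channel)
  out <- dplyr::mutate(out, norm_log2 = {
    m <- proportion_mode(.data$value)
    if (m == 0) NA_real_ else log2(.data$value / m)
  })
  out <- dplyr::ungroup(out)
  out <- dplyr::select(out, "end", "offset", "channel", "value", "norm_log2")
  new_profile(out, anchor = "terminus", n_skipped = n_skipped)
}

# Modal value of a continuous proportion series: most frequent value after
# rounding to 3 decimals (ties resolve to the smaller value).
proportion_mode <- function(x) {
  r <- round(x, 3)
  tab <- table(r)
  as.numeric(names(tab)[which.max(tab)])
}

new_profile <- function(x, anchor, ...) {
  structure(as_tibble(x),
            class = c("position_profile", class(as_tibble(x))),
            anchor = anchor, normalized = FALSE, ...)
}

# weak = two hydrogen bonds (A/T pairs), strong = three (C/G pairs)
dinuc_class <- function(b1, b2) {
  w1 <- b1 %in% c("A", "T"); w2 <- b2 %in% c("A", "T")
  s1 <- b1 %in% c("C", "G"); s2 <- b2 %in% c("C", "G")
  out <- rep(NA_character_, length(b1))
  out[w1 & w2] <- "weak"
  out[s1 & s2] <- "strong"
  out[(w1 & s2) | (s1 & w2)] <- "mixed"
  out
}

dinuc_freq_at <- function(chars, contig, pos) {
  # pos: genomic start of the top-strand dimer, one per observation
  b1 <- character(length(pos)); b2 <- b1
  for (ctg in unique(contig)) {
    i <- contig == ctg
    b1[i] <- chars[[ctg]][pos[i] + 1L]
    b2[i] <- chars[[ctg]][pos[i] + 2L]
  }
  cls <- dinuc_class(b1, b2)
  tab <- table(factor(cls, levels = c("weak", "strong", "mixed")))
  as.numeric(tab) / max(1L, sum(tab))
}

#' Dinucleotide class profile around fragment midpoints
#'
#' For fragments of one exact insert length on the forward strand (the
#' standard orientation filter for merged-read data), counts the
#' dinucleotide starting at
#' every genomic offset relative to the fragment midpoint
#' (`midpoint = start + floor(insert_len / 2)`), from
#' `-(floor(L/2) + flank)` to `+(L - floor(L/2) + flank - 2)`, and reports
#' per-offset frequencies of the weak (AA/AT/TA/TT), strong (CC/CG/GC/GG)
#' and mixed classes. Nucleosome-protected fragments on bendability-encoded
#' DNA show ~10 bp weak/strong oscillation inside the fragment span. Each
#' offset is counted exactly once per fragment, so the two per-end context
#' windows can never double-count their overlap inside short fragments.
#'
#' @param frags Fragment tibble.
#' @param ref Reference.
#' @param insert_len Exact fragment length to select (bp).
#' @param flank Genomic context beyond each fragmentation point (bp).
#' @return A `position_profile` tibble with columns `offset`, `channel`
#'   (`weak`/`strong`/`mixed`) and `value` (frequency).
#' @export
dinucleotide_midpoint_profile <- function(frags, ref, insert_len,
                                          flank = 100) {
  frags <- validate_fragments(frags)
  sel <- frags$end - frags$start == insert_len & frags$strand == "+"
  frags <- frags[sel, ]
  chars <- reference_chars(ref)
  half <- insert_len %/% 2L
  offsets <- seq.int(-(half + flank), insert_len - half + flank - 2L)
  if (nrow(frags) > 0) {
    clen <- vapply(chars, length, 0L)[frags$contig]
    mid <- frags$start + half
    ok <- mid + offsets[1] >= 0 & mid + offsets[length(offsets)] + 1L < clen
    frags <- frags[ok, ]
  }
  if (nrow(frags) == 0) {
    abort(sprintf(
      "no qualifying fragments (length == %d, strand '+', in bounds)",
      insert_len))
  }
  mid <- frags$start + half
  mat <- vapply(offsets, function(k) {
    dinuc_freq_at(chars, frags$contig, mid + k)
  }, numeric(3))  # 3 x offsets
  out <- tibble(
    offset = rep(offsets, each = 3L),
    channel = rep(c("weak", "strong", "mixed"), times = length(offsets)),
    value = as.vector(mat)
  )
  new_profile(out, anchor = "midpoint", insert_len = insert_len)
}

#' Dinucleotide class profiles at fragment termini
#'
#' Per fragment end, reports weak/strong/mixed dinucleotide frequencies on
#' an inward-positive offset axis: offsets `-out..-1` lie outside the
#' fragment, offset 0 is the terminal base, and `+1..+into` lie inside. The
#' dimer at offset k is the base at offset k together with its inward
#' neighbour, read 5'->3' along the fragment's strand -- the convention
#' under which end-polished (blunted) libraries carrying both strands give
#' exactly mirror-symmetric 5' and 3' profiles, because the weak and strong
#' classes are closed under reverse complement.
#'
#' @param frags Fragment tibble.
#' @param ref Reference.
#' @param into,out Bases inside / outside the fragment (bp).
#' @param strands `"+"` (default; the forward-read orientation filter),
#'   `"-"`, or `"both"`.
#' @return A `position_profile` tibble with columns `end`, `offset`,
#'   `channel`, `value`.
#' @export
dinucleotide_termini_profile <- function(frags, ref, into = 9, out = 10,
                                         strands = "+") {
  frags <- validate_fragments(frags)
  if (!strands %in% c("+", "-", "both")) {
    abort("strands must be '+', '-' or 'both'")
  }
  if (strands != "both") frags <- frags[frags$strand == strands, ]
  chars <- reference_chars(ref)
  offsets <- seq.int(-out, into)
  if (nrow(frags) > 0) {
    clen <- vapply(chars, length, 0L)[frags$contig]
    reach <- max(into, out) + 2L
    ok <- frags$start - reach >= 0 & frags$end + reach < clen
    frags <- frags[ok, ]
  }
  if (nrow(frags) == 0) {
    abort(sprintf("no qualifying fragments (strand filter '%s', in bounds)",
                  strands))
  }
  plus <- frags$strand == "+"
  L <- frags$end - frags$start
  one_end <- function(which_end) {
    mat <- vapply(offsets, function(k) {
      # along-strand index of the dimer's 5'-most base
      a <- if (which_end == "five_prime") k else L - 2L - k
      g <- ifelse(plus, frags$start + a, frags$end - 2L - a)
      dinuc_freq_at(chars, frags$contig, g)
    }, numeric(3))
    tibble(
      end = which_end,
      offset = rep(offsets, each = 3L),
      channel = rep(c("weak", "strong", "mixed"), times = length(offsets)),
      value = as.vector(mat)
    )
  }
  out_tbl <- dplyr::bind_rows(one_end("five_prime"), one_end("three_prime"))
  new_profile(out_tbl, anchor = "terminus_dinuc")
}

#' Median-filter normalization of a position profile
#'
#' Divides each channel (within each end, where present) by the median of
#' that channel's values across all offsets, centering profiles around 1 so
#' oscillations read as relative enrichment/depletion.
#'
#' @param profile A `position_profile` with a `value` column.
#' @return The profile with `value` normalized; attribute `normalized` set.
#' @export
median_normalize <- function(profile) {
  stopifnot(is.data.frame(profile), "value" %in% names(profile))
  grp <- intersect(c("end", "channel"), names(profile))
  out <- dplyr::group_by(profile, dplyr::across(dplyr::all_of(grp)))
  meds <- dplyr::summarise(out, m = median(.data$value), .groups = "drop")
  if (any(meds$m == 0)) abort("channel median is zero: cannot normalize")
  out <- dplyr::mutate(out, value = .data$value / median(.data$value))
  out <- dplyr::ungroup(out)
  attrs <- attributes(profile)
  structure(out,
            class = class(profile),
            anchor = attrs$anchor,
            normalized = TRUE)
}
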