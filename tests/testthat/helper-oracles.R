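# Shared fixtures and independent oracles, built in code at test time.

# Random reference of i.i.d. uniform bases.
random_reference <- function(len, contig = "sim", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                collapse = "")
  as_reference(setNames(seqs, contig))
}

# Random fragment table on one contig.
random_fragments <- function(n, contig_len, contig = "sim",
                             len_range = c(50, 200), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- seq.int(len_range[1], len_range[2])
  len <- pool[sample.int(length(pool), n, replace = TRUE)]
  start <- sample.int(contig_len - max(len) - 1L, n, replace = TRUE) - 1L
  fragments(rep(contig, n), start, start + len,
            sample(c("+", "-"), n, replace = TRUE))
}

# Brute-force WPS: literal per-position evaluation of the scoring rule,
# independent of the difference-array implementation.
brute_wps <- function(frags, contig, start, end, w, lmin, lmax) {
  len <- frags$end - frags$start
  keep <- frags$contig == contig & len >= lmin & len <= lmax
  s <- frags$start[keep]; e <- frags$end[keep]
  vapply(seq.int(start, end - 1L), function(p) {
    win_lo <- p - w %/% 2L
    win_hi <- p + w %/% 2L  # window is [win_lo, win_hi)
    score <- 0L
    for (i in seq_along(s)) {
      start_in <- s[i] >= win_lo && s[i] < win_hi
      end_in <- (e[i] - 1L) >= win_lo && (e[i] - 1L) < win_hi
      if (start_in || end_in) {
        score <- score - 1L
      } else if (s[i] < win_lo && e[i] > win_hi) {
        score <- score + 1L
      }
    }
    score
  }, integer(1))
}

# Independent Savitzky-Golay value at the center of a window: solve the
# local least-squares polynomial fit directly.
ls_polyfit_center <- function(y, order) {
  n <- length(y)
  x <- seq_len(n) - (n + 1) / 2
  fit <- stats::lm(y ~ poly(x, order, raw = TRUE))
  unname(stats::predict(fit, newdata = data.frame(x = 0)))
}

# Reverse complement for plain strings (oracle-side).
rc <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, "")[[1]], identity, ""))
}
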