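#' Build a fragment table
#'
#' Fragments are the package's central currency: one sequenced template
#' molecule per row, as a stranded, 0-based, half-open interval on a contig
#' (the BED convention). All coordinates in the package follow this
#' convention; a fragment's length is `end - start` and a `-` fragment's
#' 5' terminus sits at genomic coordinate `end - 1`.
#'
#' @param contig Character vector of contig names.
#' @param start,end Integer vectors; 0-based half-open interval, `end > start`.
#' @param strand Character vector of `"+"` / `"-"` (recycled).
#'
#' @return A tibble with columns `contig`, `start`, `end`, `strand`.
#' @export
#' @examples
#' fragments("chr1", 100, 267)
fragments <- function(contig, start, end, strand = "+") {
  out <- tibble(
    contig = as.character(contig),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), length(contig))
  )
  validate_fragments(out)
}

#' @rdname fragments
#' @param x A data frame to validate as a fragment table.
#' @export
validate_fragments <- function(x) {
  req <- c("contig", "start", "end", "strand")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("fragment table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(x$contig) | !nzchar(x$contig))) {
    abort("fragment contig names must be non-empty")
  }
  if (any(x$end <= x$start)) {
    bad <- which(x$end <= x$start)[1]
    abort(sprintf("fragment %d has end <= start (empty interval)", bad))
  }
  if (!all(x$strand %in% c("+", "-"))) {
    abort("fragment strand must be '+' or '-'")
  }
  as_tibble(x)
}

#' Read fragments or regions from a BED file
#'
#' Parses 3- or 6-column BED (tab-separated, 0-based half-open). Column 6
#' (strand) is optional; fragments default to `"+"`, regions to `"."`.
#'
#' @param path Path to a BED file.
#' @return A tibble of fragments (`read_fragments`) or regions
#'   (`read_regions`) in file order.
#' @export
read_fragments <- function(path) {
  bed <- read_bed(path, default_strand = "+")
  if (!all(bed$strand %in% c("+", "-"))) {
    abort("fragment strand must be '+' or '-'")
  }
  bad <- which(bed$end <= bed$start)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d has end <= start (empty interval)",
                  path, bad[1]))
  }
  bed
}

#' @rdname read_fragments
#' @export
read_regions <- function(path) {
  bed <- read_bed(path, default_strand = ".")
  bad <- which(bed$end <= bed$start)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d has end <= start (empty interval)",
                  path, bad[1]))
  }
  bed
}

read_bed <- function(path, default_strand) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(contig = character(), start = integer(),
                  end = integer(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("%s: line %d has fewer than 3 tab-separated columns",
                  path, which(nf < 3)[1]))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("%s: line %d has a non-integer coordinate",
                  path, which(is.na(start) | is.na(end))[1]))
  }
  strand <- ifelse(nf >= 6,
                   vapply(fields, function(f) f[min(6L, length(f))], ""),
                   default_strand)
  tibble(
    contig = vapply(fields, `[[`, "", 1),
    start = start, end = end, strand = strand
  )
}

#' Write fragments to a BED file
#'
#' Writes 6-column BED; round-trips with [read_fragments()].
#'
#' @param x Fragment tibble (see [fragments()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(x, path) {
  x <- validate_fragments(x)
  bed <- tibble(
    contig = x$contig, start = x$start, end = x$end,
    name = if ("name" %in% names(x)) x$name else ".",
    score = 0L, strand = x$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Reference sequences
#'
#' References are held as [Biostrings::DNAStringSet] objects keyed by contig.
#' `as_reference()` accepts a named character vector or a `DNAStringSet`;
#' `read_reference()`/`write_reference()` go through FASTA.
#'
#' @param x Named character vector of sequences, or a `DNAStringSet`.
#' @return A `DNAStringSet`.
#' @export
as_reference <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      abort("reference sequences must be named by contig")
    }
    return(Biostrings::DNAStringSet(toupper(x)))
  }
  abort("cannot interpret object as a reference sequence set")
}

#' @rdname as_reference
#' @param path FASTA path.
#' @export
read_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  # drop FASTA description text after the first whitespace
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' @rdname as_reference
#' @param ref Reference (`DNAStringSet` or named character).
#' @export
write_reference <- function(ref, path) {
  Biostrings::writeXStringSet(as_reference(ref), path)
  invisible(path)
}

#' Fetch fragment sequences with genomic flanks
#'
#' Returns, for each fragment, the nucleotide sequence of the fragment plus
#' flanking genomic context, always reading 5'->3' along the fragment's own
#' strand. For a `+` fragment this is the top-strand sequence of
#' `[start - flank5, end + flank3)`; for a `-` fragment it is the reverse
#' complement of `[start - flank3, end + flank5)`. Requests outside the
#' contig are an error -- there is no silent clipping.
#'
#' @param ref Reference (see [as_reference()]).
#' @param frags Fragment tibble.
#' @param flank5,flank3 Flank widths in bp on the fragment's 5' and 3' sides.
#' @return Character vector of sequences, one per fragment; each has length
#'   `(end - start) + flank5 + flank3`.
#' @export
fetch_sequence <- function(ref, frags, flank5 = 0, flank3 = 0) {
  ref <- as_reference(ref)
  frags <- validate_fragments(frags)
  if (nrow(frags) == 0) return(character())
  widths <- setNames(Biostrings::width(ref), names(ref))
  unknown <- setdiff(unique(frags$contig), names(ref))
  if (length(unknown) > 0) {
    abort(paste0("contig not in reference: ", unknown[1]))
  }
  plus <- frags$strand == "+"
  lo <- ifelse(plus, frags$start - flank5, frags$start - flank3)
  hi <- ifelse(plus, frags$end + flank3, frags$end + flank5)
  if (any(lo < 0) || any(hi > widths[frags$contig])) {
    abort("requested range extends outside contig bounds")
  }
  seqs <- character(nrow(frags))
  for (ctg in unique(frags$contig)) {
    i <- frags$contig == ctg
    s <- as.character(ref[[ctg]])
    seqs[i] <- substring(s, lo[i] + 1L, hi[i])
  }
  if (any(!plus)) {
    rc <- Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[!plus]))
    seqs[!plus] <- as.character(rc)
  }
  seqs
}

# Strand-resolved reverse complement of bare character vectors.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split each contig of a reference into a character vector of single bases,
# returned as a named list. Used by profile code for random base access.
reference_chars <- function(ref) {
  ref <- as_reference(ref)
  out <- lapply(seq_along(ref), function(i) {
    strsplit(toupper(as.character(ref[[i]])), "", fixed = TRUE)[[1]]
  })
  names(out) <- names(ref)
  out
}
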