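#' Construct a locus sequence with exon/intron segmentation
#'
#' A `geis_locus` bundles a DNA sequence with an ordered exon/intron
#' segmentation of it, the substrate for guide enumeration and donor assembly.
#' Coordinates are 1-based closed and local to the locus.
#'
#' @param name Locus name.
#' @param sequence DNA string (characters `ACGTN`, case-insensitive).
#' @param segments Data frame with columns `kind` (`"exon"`/`"intron"`),
#'   `start`, `end`. Segments must tile the sequence without gaps or overlaps
#'   and alternate exon/intron.
#' @param non_canonical_ok Allow introns that do not start with `GT` and end
#'   with `AG`. Default `FALSE`: canonical splice dinucleotides are enforced.
#' @return An object of class `geis_locus`.
#' @export
locus_sequence <- function(name, sequence, segments, non_canonical_ok = FALSE) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", sequence) || nchar(sequence) == 0)
    stop("sequence must be a non-empty DNA string over ACGTN")
  segments <- as.data.frame(segments)
  stopifnot(all(c("kind", "start", "end") %in% names(segments)))
  segments$kind <- as.character(segments$kind)
  if (!all(segments$kind %in% c("exon", "intron")))
    stop("segment kind must be 'exon' or 'intron'")
  if (any(segments$end < segments$start)) stop("segment with end < start")
  if (segments$start[1] != 1 || segments$end[nrow(segments)] != nchar(sequence))
    stop("segments must tile the sequence end to end")
  if (nrow(segments) > 1) {
    if (any(segments$start[-1] != segments$end[-nrow(segments)] + 1))
      stop("segments must be contiguous and non-overlapping")
    if (any(segments$kind[-1] == segments$kind[-nrow(segments)]))
      stop("segments must alternate exon/intron")
  }
  is_intron <- segments$kind == "intron"
  segments$index <- NA_integer_
  segments$index[is_intron] <- seq_len(sum(is_intron))
  segments$index[!is_intron] <- seq_len(sum(!is_intron))
  if (!non_canonical_ok && any(is_intron)) {
    for (i in which(is_intron)) {
      a <- segments$start[i]; b <- segments$end[i]
      if (substr(sequence, a, a + 1) != "GT" || substr(sequence, b - 1, b) != "AG")
        stop("intron ", segments$index[i], " lacks canonical GT...AG boundaries; ",
             "set non_canonical_ok = TRUE to keep it")
    }
  }
  structure(list(name = name, sequence = sequence, segments = segments),
            class = "geis_locus")
}

#' @export
print.geis_locus <- function(x, ...) {
  s <- x$segments
  cat("Locus '", x$name, "': ", nchar(x$sequence), " nt, ",
      sum(s$kind == "exon"), " exon(s), ", sum(s$kind == "intron"),
      " intron(s)\n", sep = "")
  cat(paste0(" ", s$kind, " ", s$index, " [", s$start, "-", s$end, "]",
             collapse = "\n"), "\n")
  invisible(x)
}

# Internal: segment row for an intron index, or for the segment containing pos.
.intron_segment <- function(locus, intron_index) {
  s <- locus$segments
  row <- s[s$kind == "intron" & s$index == intron_index, , drop = FALSE]
  if (nrow(row) != 1) stop("no intron with index ", intron_index)
  row
}

.segment_at <- function(locus, pos) {
  s <- locus$segments
  i <- which(s$start <= pos & s$end >= pos)
  if (length(i) != 1) stop("position ", pos, " outside locus")
  s[i, , drop = FALSE]
}
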