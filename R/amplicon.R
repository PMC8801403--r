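#' Alignment scoring scheme for amplicon reads
#'
#' @param match Match score (default +2).
#' @param mismatch Mismatch score (default -3); `N` scores as a mismatch
#'   against everything, including itself.
#' @param gap_open Gap-opening penalty, positive (default 5).
#' @param gap_extend Per-base gap-extension penalty, positive (default 2); a
#'   gap of length L costs `gap_open + L * gap_extend`.
#' @return An object of class `align_scoring`.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = 5,
                          gap_extend = 2) {
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

# Substitution matrix over ACGTN with N treated as a universal mismatch.
.sub_matrix <- function(scoring) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m)[1:4] <- scoring$match
  m["N", "N"] <- scoring$mismatch
  m
}

# Vectorized core: align a DNAStringSet of reads against one reference.
.align_set <- function(reads, reference, scoring) {
  aln <- Biostrings::pairwiseAlignment(
    reads, Biostrings::DNAString(reference),
    substitutionMatrix = .sub_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "overlap")
  list(aln = aln,
       score = Biostrings::score(aln),
       identity = Biostrings::nmatch(aln) / Biostrings::nchar(aln),
       span = Biostrings::nchar(aln))
}

#' Align one amplicon read to the wild-type reference
#'
#' Affine-gap pairwise alignment (ends-free global, so truncated Sanger reads
#' and reads padded with extra flanking sequence align without end-gap
#' penalties). The read is aligned in both orientations and the better-scoring
#' one is kept. Identity is matches over aligned columns.
#'
#' @param read DNA string (or `DNAString`) of the read.
#' @param reference DNA string of the wild-type amplicon reference.
#' @param scoring An [align_scoring()] scheme.
#' @param min_identity,min_length QC thresholds: reads shorter than
#'   `min_length` nt, reads whose aligned span is shorter than `min_length`
#'   columns (ends-free alignment can clip junk reads down to a short perfect
#'   stretch), or reads aligning below `min_identity` are flagged
#'   `qc_pass = FALSE` and should be excluded from calling.
#' @return An object of class `read_alignment`: list with the
#'   `PairwiseAlignments` object (`aln`), `score`, `identity`, `strand`
#'   (orientation kept), `qc_pass` and `qc_reason`.
#' @export
align_read <- function(read, reference, scoring = align_scoring(),
                       min_identity = 0.9, min_length = 50) {
  read <- toupper(as.character(read))
  fwd <- .align_set(Biostrings::DNAStringSet(read), reference, scoring)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(read)))
  rev <- .align_set(Biostrings::DNAStringSet(rc), reference, scoring)
  use_rev <- rev$score > fwd$score
  pick <- if (use_rev) rev else fwd
  qc_reason <- NULL
  if (nchar(read) < min_length) qc_reason <- "read shorter than min_length"
  else if (pick$span < min_length)
    qc_reason <- "aligned span shorter than min_length"
  else if (pick$identity < min_identity) qc_reason <- "identity below threshold"
  structure(list(aln = pick$aln, score = pick$score, identity = pick$identity,
                 strand = if (use_rev) "-" else "+",
                 qc_pass = is.null(qc_reason),
                 qc_reason = if (is.null(qc_reason)) NA_character_ else qc_reason),
            class = "read_alignment")
}

#' @export
print.read_alignment <- function(x, ...) {
  cat("Read alignment: score ", x$score, ", identity ",
      sprintf("%.4f", x$identity), ", strand ", x$strand,
      if (x$qc_pass) ", QC pass" else paste0(", QC FAIL (", x$qc_reason, ")"),
      "\n", sep = "")
  invisible(x)
}

# Internal: gapped pattern/subject strings and the reference coordinate of
# each alignment column, from a length-1 PairwiseAlignments.
.alignment_columns <- function(aln) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sstart <- Biostrings::start(Biostrings::subject(aln))
  refpos <- cumsum(s != "-") + sstart - 1L  # for gap columns: preceding ref base
  list(p = p, s = s, refpos = refpos,
       ref_lo = sstart, ref_hi = max(refpos))
}

# Internal: call one variant from alignment columns. `q`/`q2` are the edited
# span in reference coordinates (for insertions q is the base preceding the
# insertion point). Returns "converted", "unconverted" or "ambiguous".
#
# Substitutions are read base-by-base off the aligned span. Indels are read
# by sequence comparison over a window around the designed site: the read
# bases aligned to reference window [q - w, q2 + w] must spell either the
# wild-type window (unconverted) or the window with the designed indel
# applied (converted). This makes the call invariant to equivalent gap
# placements in repetitive context, where "the same" indel admits several
# optimal alignments.
.call_one <- function(cols, kind, q, q2, ref, alt, window = 8L) {
  amb <- "ambiguous"
  within <- function(pos) pos >= cols$ref_lo && pos <= cols$ref_hi
  if (kind == "substitution") {
    if (!within(q) || !within(q2)) return(amb)
    cr <- which(cols$s != "-" & cols$refpos >= q & cols$refpos <= q2)
    if (length(cr) != q2 - q + 1L) return(amb)
    # a non-designed insertion inside the span is ambiguous
    if (any(cols$s[seq(min(cr), max(cr))] == "-")) return(amb)
    rd <- paste(cols$p[cr], collapse = "")
    if (rd == alt) "converted" else if (rd == ref) "unconverted" else amb
  } else {
    w1 <- q - window; w2 <- q2 + window
    if (!within(w1) || !within(w2)) return(amb)
    keep <- (cols$s != "-" & cols$refpos >= w1 & cols$refpos <= w2) |
            (cols$s == "-" & cols$refpos >= w1 & cols$refpos < w2)
    idx <- which(keep)
    rd <- paste(cols$p[idx][cols$p[idx] != "-"], collapse = "")
    rf <- paste(cols$s[idx][cols$s[idx] != "-"], collapse = "")
    if (nchar(rf) != w2 - w1 + 1L) return(amb)  # window interrupted
    rel <- q - w1 + 1L                           # variant start within window
    expected <- if (kind == "insertion") {
      paste0(substr(rf, 1L, rel), alt, substr(rf, rel + 1L, nchar(rf)))
    } else {                                     # deletion of ref at q..q2
      paste0(substr(rf, 1L, rel - 1L), substr(rf, rel + nchar(ref), nchar(rf)))
    }
    if (rd == expected) "converted" else if (rd == rf) "unconverted" else amb
  }
}

#' Call designed variants from a read alignment
#'
#' For each designed variant, decides whether the read carries the donor
#' (alt) allele (`converted`), the wild-type allele (`unconverted`), or
#' neither / cannot be decided (`ambiguous`): variants outside the aligned
#' span of a truncated read, spans interrupted by non-designed indels, and
#' unexpected bases all yield `ambiguous`.
#'
#' @param alignment A [align_read()] result (or a length-1
#'   `PairwiseAlignments`).
#' @param variant_specs Variant table (see [assemble_donor()]); positions in
#'   locus coordinates.
#' @param ref_start Locus coordinate of the first base of the alignment
#'   reference, used to translate variant positions (default 1).
#' @return Named character vector of calls, one per variant.
#' @export
call_variants <- function(alignment, variant_specs, ref_start = 1) {
  aln <- if (inherits(alignment, "read_alignment")) alignment$aln else alignment
  cols <- .alignment_columns(aln)
  v <- as.data.frame(variant_specs)
  if (is.null(v$kind))
    v$kind <- ifelse(v$ref %in% c("", ".", "-"), "insertion",
                     ifelse(v$alt %in% c("", ".", "-"), "deletion",
                            "substitution"))
  if (is.null(v$id)) v$id <- paste0("v", seq_len(nrow(v)))
  v$ref <- ifelse(v$ref %in% c(".", "-"), "", v$ref)
  v$alt <- ifelse(v$alt %in% c(".", "-"), "", v$alt)
  out <- vapply(seq_len(nrow(v)), function(k) {
    q <- v$position[k] - ref_start + 1L
    q2 <- if (v$kind[k] == "insertion") q else q + nchar(v$ref[k]) - 1L
    .call_one(cols, v$kind[k], q, q2, v$ref[k], v$alt[k])
  }, character(1))
  setNames(out, v$id)
}

#' Build the reads-by-variants call matrix
#'
#' Aligns every read to the wild-type reference (both orientations, ends-free
#' affine alignment), drops reads failing QC, and calls every designed
#' variant on the survivors. This matrix is the substrate for all
#' conversion-tract statistics.
#'
#' @param reads A `DNAStringSet`, named character vector, or path to a FASTA
#'   file of amplicon reads.
#' @param reference Wild-type amplicon reference (DNA string).
#' @param variant_specs Variant table with `position`, `ref`, `alt` (and
#'   optionally `kind`, `id`, `tract_distance`), positions in locus
#'   coordinates.
#' @param min_identity QC: minimum alignment identity (default 0.9).
#' @param min_length QC: minimum read length in nt (default 50).
#' @param ref_start Locus coordinate of the first reference base (default 1).
#' @param scoring An [align_scoring()] scheme.
#' @return An object of class `read_call_matrix`: list with `calls` (character
#'   matrix, reads x variants, values `converted`/`unconverted`/`ambiguous`),
#'   `identity` (per kept read), `strand`, `variants` (the spec table ordered
#'   by `tract_distance` when present), and `qc` (`n_input`, `n_pass`,
#'   `n_fail`).
#' @export
build_matrix <- function(reads, reference, variant_specs,
                         min_identity = 0.9, min_length = 50, ref_start = 1,
                         scoring = align_scoring()) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- Biostrings::readDNAStringSet(reads)
  if (!methods::is(reads, "DNAStringSet"))
    reads <- Biostrings::DNAStringSet(toupper(reads))
  if (length(reads) == 0) stop("no reads supplied")
  if (is.null(names(reads)) || anyDuplicated(names(reads)))
    names(reads) <- paste0("read_", seq_along(reads))

  v <- as.data.frame(variant_specs)
  if (is.null(v$id)) v$id <- paste0("v", seq_len(nrow(v)))
  if (!is.null(v$tract_distance)) v <- v[order(v$tract_distance), , drop = FALSE]

  fwd <- .align_set(reads, reference, scoring)
  rev <- .align_set(Biostrings::reverseComplement(reads), reference, scoring)
  use_rev <- rev$score > fwd$score
  identity <- ifelse(use_rev, rev$identity, fwd$identity)
  span <- ifelse(use_rev, rev$span, fwd$span)
  pass <- Biostrings::nchar(reads) >= min_length & span >= min_length &
    identity >= min_identity
  if (!any(pass))
    stop("no reads passed QC (", length(reads), " input); ",
         "check the reference or lower min_identity")

  idx <- which(pass)
  calls <- matrix(NA_character_, length(idx), nrow(v),
                  dimnames = list(names(reads)[idx], v$id))
  for (r in seq_along(idx)) {
    i <- idx[r]
    aln <- if (use_rev[i]) rev$aln[i] else fwd$aln[i]
    calls[r, ] <- call_variants(aln, v, ref_start = ref_start)
  }
  structure(list(calls = calls,
                 identity = identity[idx],
                 strand = ifelse(use_rev[idx], "-", "+"),
                 variants = v,
                 qc = list(n_input = length(reads), n_pass = length(idx),
                           n_fail = length(reads) - length(idx))),
            class = "read_call_matrix")
}

#' @export
print.read_call_matrix <- function(x, ...) {
  cat("Read call matrix: ", nrow(x$calls), " read(s) x ", ncol(x$calls),
      " variant(s)  [QC: ", x$qc$n_pass, "/", x$qc$n_input, " passed]\n",
      sep = "")
  tab <- apply(x$calls, 2, function(col)
    c(converted = sum(col == "converted"),
      unconverted = sum(col == "unconverted"),
      ambiguous = sum(col == "ambiguous")))
  print(tab)
  invisible(x)
}

#' Write / read a call matrix as TSV
#'
#' The TSV has one row per read (first column `read_id`) and one column per
#' variant, cells holding `converted`/`unconverted`/`ambiguous`.
#'
#' @param matrix A `read_call_matrix`.
#' @param file Path.
#' @return `file` (writer) or a `read_call_matrix` with the calls and, if
#'   available, variant metadata (reader; `variants` holds ids only).
#' @export
write_matrix_tsv <- function(matrix, file) {
  d <- data.frame(read_id = rownames(matrix$calls), matrix$calls,
                  check.names = FALSE)
  write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(file) {
  d <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  calls <- as.matrix(d[, -1, drop = FALSE])
  rownames(calls) <- d$read_id
  structure(list(calls = calls, identity = rep(NA_real_, nrow(calls)),
                 strand = rep(NA_character_, nrow(calls)),
                 variants = data.frame(id = colnames(calls)),
                 qc = list(n_input = nrow(calls), n_pass = nrow(calls),
                           n_fail = 0L)),
            class = "read_call_matrix")
}

#' Reference affine-gap alignment score (dynamic-programming oracle)
#'
#' Direct quadratic Gotoh dynamic program computing the optimal affine-gap
#' alignment score, independent of the production alignment route; used for
#' cross-validation. Conventions match [align_scoring()]: a gap of length L
#' costs `gap_open + L * gap_extend`, and with `ends_free = TRUE` terminal
#' gaps in either sequence are free.
#'
#' @param a,b DNA strings.
#' @param scoring An [align_scoring()] scheme.
#' @param ends_free Free terminal gaps (default `TRUE`, matching
#'   [align_read()]).
#' @return The optimal alignment score (numeric scalar).
#' @export
nw_reference_score <- function(a, b, scoring = align_scoring(),
                               ends_free = TRUE) {
  nw_score_cpp(toupper(as.character(a)), toupper(as.character(b)),
               match = scoring$match, mismatch = scoring$mismatch,
               gap_open = scoring$gap_open, gap_extend = scoring$gap_extend,
               ends_free = ends_free)
}
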