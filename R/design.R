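#' Splice-safety policy for intronic guide placement
#'
#' Cuts inside an intron must spare the splice signals: the donor splice site
#' (the `GT` and its immediate context at the 5' end of the intron) and the
#' acceptor side (branch point, polypyrimidine tract and the terminal `AG`).
#' The policy gives the sizes of the two exclusion zones, in nucleotides from
#' the respective intron end.
#'
#' @param donor_window_nt Exclusion zone at the intron 5' end (default 20).
#' @param acceptor_window_nt Exclusion zone at the intron 3' end, wide enough
#'   to cover the branch point and polypyrimidine tract (default 50).
#' @return An object of class `splice_policy`.
#' @export
splice_policy <- function(donor_window_nt = 20, acceptor_window_nt = 50) {
  if (donor_window_nt < 2 || acceptor_window_nt < 2)
    stop("safety windows must be at least 2 nt (the GT/AG dinucleotides)")
  structure(list(donor_window_nt = as.integer(donor_window_nt),
                 acceptor_window_nt = as.integer(acceptor_window_nt)),
            class = "splice_policy")
}

#' Enumerate splice-safe SpCas9 guides in an intron
#'
#' Scans both strands of the locus for 20-mer protospacers followed by an
#' `NGG` PAM whose blunt cut (3 nt 5' of the PAM, between protospacer
#' positions 17 and 18) falls inside the chosen intron outside both
#' splice-safety windows. `cut_position` is reported as the locus coordinate
#' of the base immediately 5' (locus sense) of the cut.
#'
#' Protospacer+PAM sites overlapping an `N` base are never admissible.
#'
#' @param locus A [locus_sequence()] object.
#' @param intron_index Which intron (1-based, in locus order) to target.
#' @param policy A [splice_policy()].
#' @param target_position Locus coordinate used to order candidates by
#'   ascending distance of their cut to the target; defaults to the intron
#'   midpoint.
#' @return A data frame with columns `protospacer`, `pam`, `strand`,
#'   `cut_position`, `intron_index`, `dist_to_5p_boundary`
#'   (nt from the intron start to the cut base, inclusive),
#'   `dist_to_3p_boundary` (nt from the cut to the intron end), and
#'   `distance_to_target`, sorted by `distance_to_target`. If the intron
#'   admits no safe site an empty data frame is returned with a warning.
#' @export
enumerate_guides <- function(locus, intron_index, policy = splice_policy(),
                             target_position = NULL) {
  seg <- .intron_segment(locus, intron_index)
  a <- seg$start; b <- seg$end
  if (is.null(target_position)) target_position <- (a + b) %/% 2
  n <- nchar(locus$sequence)
  lo <- a + policy$donor_window_nt        # admissible cut_position range
  hi <- b - policy$acceptor_window_nt - 1L

  empty <- data.frame(protospacer = character(), pam = character(),
                      strand = character(), cut_position = integer(),
                      intron_index = integer(), dist_to_5p_boundary = integer(),
                      dist_to_3p_boundary = integer(),
                      distance_to_target = integer())
  if (lo > hi) {
    warning("intron ", intron_index, " (", b - a + 1,
            " nt) admits no cut outside the safety windows")
    return(empty)
  }
  subj <- Biostrings::DNAString(locus$sequence)
  cand <- list()
  # plus strand: protospacer [s, s+19], PAM [s+20, s+22] with GG at s+21..s+22,
  # cut between s+16 and s+17
  gg <- Biostrings::start(Biostrings::matchPattern("GG", subj))
  s <- gg - 21L
  s <- s[s >= 1L & s + 22L <= n]
  if (length(s)) {
    cut <- s + 16L
    keep <- cut >= lo & cut <= hi
    s <- s[keep]; cut <- cut[keep]
    if (length(s)) {
      site <- substring(locus$sequence, s, s + 22L)
      ok <- !grepl("N", site, fixed = TRUE)
      if (any(ok))
        cand$plus <- data.frame(
          protospacer = substring(site[ok], 1, 20),
          pam = substring(site[ok], 21, 23),
          strand = "+", cut_position = cut[ok])
    }
  }
  # minus strand: CC at t..t+1 (PAM NGG on minus reads plus-strand [t, t+2]),
  # protospacer plus-strand span [t+3, t+22], cut between t+5 and t+6
  cc <- Biostrings::start(Biostrings::matchPattern("CC", subj))
  t0 <- cc
  t0 <- t0[t0 >= 1L & t0 + 22L <= n]
  if (length(t0)) {
    cut <- t0 + 5L
    keep <- cut >= lo & cut <= hi
    t0 <- t0[keep]; cut <- cut[keep]
    if (length(t0)) {
      site <- substring(locus$sequence, t0, t0 + 22L)
      ok <- !grepl("N", site, fixed = TRUE)
      if (any(ok)) {
        rc <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(site[ok])))
        cand$minus <- data.frame(
          protospacer = substring(rc, 1, 20),
          pam = substring(rc, 21, 23),
          strand = "-", cut_position = cut[ok])
      }
    }
  }
  out <- do.call(rbind, cand)
  if (is.null(out) || nrow(out) == 0) {
    warning("intron ", intron_index, " contains no admissible protospacer")
    return(empty)
  }
  out$intron_index <- intron_index
  out$dist_to_5p_boundary <- out$cut_position - a + 1L
  out$dist_to_3p_boundary <- b - out$cut_position
  out$distance_to_target <- abs(out$cut_position - as.integer(target_position))
  out <- out[order(out$distance_to_target, out$cut_position, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nearest flanking intron and conversion-tract budget for an exonic target
#'
#' For a target position inside an exon, picks the flanking intron that
#' minimizes the distance from the target to the exon boundary. That distance
#' is the conversion-tract budget: a donor cut in the chosen intron must drive
#' a tract at least this long to reach the target. For an internal exon the
#' budget never exceeds half the exon length (rounded up), which is why a
#' 600-nt exon is always reachable with a 300-nt tract.
#'
#' @param locus A [locus_sequence()] object.
#' @param target_position Locus coordinate of the edit, inside an exon.
#' @return A list with `intron_index`, `side` (`"left"`/`"right"`, which
#'   flanking intron) and `tract_budget_nt` (distance from target to the
#'   chosen exon boundary, counting the target base). Midpoint ties break
#'   toward the left (5') intron.
#' @export
nearest_intron <- function(locus, target_position) {
  seg <- .segment_at(locus, target_position)
  if (seg$kind == "intron")
    stop("target position ", target_position, " lies in intron ", seg$index,
         "; place the cut in that intron directly instead of using a tract")
  s <- locus$segments
  i <- which(s$start == seg$start & s$kind == "exon")
  has_left <- i > 1L
  has_right <- i < nrow(s)
  if (!has_left && !has_right)
    stop("single-exon locus: no flanking intron available")
  left_budget <- target_position - seg$start + 1L
  right_budget <- seg$end - target_position + 1L
  side <-
    if (!has_left) "right"
    else if (!has_right) "left"
    else if (left_budget <= right_budget) "left" else "right"
  list(
    intron_index = s$index[if (side == "left") i - 1L else i + 1L],
    side = side,
    tract_budget_nt = if (side == "left") left_budget else right_budget
  )
}

#' Scan a donor sequence for transcription-terminating motifs
#'
#' The selection cassette is transcribed from within an intron, so the donor
#' must not carry polyadenylation signals that would truncate the host
#' pre-mRNA. Scans the donor sense strand for the canonical `AATAAA` and the
#' common `ATTAAA` poly(A) signal hexamers (overlapping occurrences included).
#'
#' @param seq DNA string.
#' @return Data frame with columns `motif` and `position` (1-based start),
#'   sorted by position; zero rows when the sequence is clean.
#' @export
scan_terminators <- function(seq) {
  seq <- toupper(seq)
  subj <- Biostrings::DNAString(seq)
  hits <- lapply(c("AATAAA", "ATTAAA"), function(m) {
    p <- Biostrings::start(Biostrings::matchPattern(m, subj))
    if (length(p)) data.frame(motif = m, position = p) else NULL
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(motif = character(), position = integer())
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply a variant table to a sequence window
#'
#' Applies substitutions, insertions and deletions (locus coordinates) to a
#' subsequence of the locus starting at locus coordinate `offset + 1`.
#' Variants are applied right to left so earlier edits do not shift later
#' coordinates.
#'
#' @param seq DNA string (the window).
#' @param variants Variant table with `kind`, `position`, `ref`, `alt`.
#' @param offset Locus coordinate of the base before the window (default 0).
#' @return The edited window.
#' @export
apply_variants <- function(seq, variants, offset = 0L) {
  if (is.null(variants) || nrow(variants) == 0) return(seq)
  v <- variants[order(variants$position, decreasing = TRUE), , drop = FALSE]
  for (k in seq_len(nrow(v))) {
    p <- v$position[k] - offset
    ref <- v$ref[k]; alt <- v$alt[k]
    switch(v$kind[k],
      substitution = {
        substr(seq, p, p + nchar(ref) - 1L) <- alt
      },
      insertion = {  # insert alt between p and p+1
        seq <- paste0(substr(seq, 1L, p), alt, substr(seq, p + 1L, nchar(seq)))
      },
      deletion = {
        seq <- paste0(substr(seq, 1L, p - 1L),
                      substr(seq, p + nchar(ref), nchar(seq)))
      },
      stop("unknown variant kind: ", v$kind[k])
    )
  }
  seq
}

# Internal: normalize/validate a variant table against the locus sequence.
.check_variants <- function(variants, locus_seq) {
  v <- as.data.frame(variants)
  stopifnot(all(c("position", "ref", "alt") %in% names(v)))
  v$ref <- toupper(ifelse(is.na(v$ref) | v$ref %in% c(".", "-"), "", v$ref))
  v$alt <- toupper(ifelse(is.na(v$alt) | v$alt %in% c(".", "-"), "", v$alt))
  if (is.null(v$kind)) {
    v$kind <- ifelse(v$ref == "", "insertion",
                     ifelse(v$alt == "", "deletion", "substitution"))
  }
  if (any(v$kind == "substitution" & nchar(v$ref) != nchar(v$alt)))
    stop("substitution variants must have ref and alt of equal length")
  if (any(v$kind == "substitution" & nchar(v$ref) == 0))
    stop("substitution variants must have a non-empty ref allele")
  for (k in seq_len(nrow(v))) {
    if (v$kind[k] == "insertion") next
    span <- substr(locus_seq, v$position[k], v$position[k] + nchar(v$ref[k]) - 1L)
    if (span != v$ref[k])
      stop("variant ref allele mismatch at locus position ", v$position[k],
           ": locus has '", span, "', variant says '", v$ref[k], "'")
  }
  if (is.null(v$id)) v$id <- paste0("v", seq_len(nrow(v)))
  v
}

# Internal: nt from the blunt cut (after base `cut`) to the nearest edited
# base, counting that base; insertions measure to the insertion point.
.tract_distance <- function(v, cut) {
  vapply(seq_len(nrow(v)), function(k) {
    p <- v$position[k]
    if (v$kind[k] == "insertion") return(abs(p - cut))
    p2 <- p + nchar(v$ref[k]) - 1L        # edited span p..p2
    if (p2 <= cut) cut - p2 + 1L
    else if (p >= cut + 1L) p - cut
    else 0L                                # span straddles the cut
  }, numeric(1))
}

#' Assemble a GEIS donor template
#'
#' Copies homology arms of `ha_length` nt from the locus on both sides of the
#' cut, applies the designed variants to the arms, and places the selection
#' cassette exactly at the cut. Safety checks record whether the arms meet
#' the minimum length found necessary for recombination (500 nt) and whether
#' the donor carries poly(A)-signal terminator motifs (see
#' [scan_terminators()]).
#'
#' @param locus A [locus_sequence()] object.
#' @param cut_position Locus coordinate of the base immediately 5' of the
#'   blunt cut; the cut must fall inside an intron segment.
#' @param ha_length Homology arm length in nt (per arm).
#' @param cassette DNA string of the selection-marker insert (e.g. a
#'   promoter-driven fluorophore cassette).
#' @param variants Variant table (columns `position`, `ref`, `alt`, optional
#'   `kind` and `id`; empty/`.`/`-` alleles encode insertions and deletions),
#'   positions in locus coordinates. All edited bases must lie within the
#'   arms. May be `NULL`.
#' @return An object of class `donor_design`: list with `left_ha`,
#'   `right_ha`, `cassette`, `ha_length`, `cut_position`, `variants` (with
#'   `tract_distance` added, ordered by it), `safety` (`ha_ok`,
#'   `terminators`), and `locus_name`.
#' @export
assemble_donor <- function(locus, cut_position, ha_length, cassette,
                           variants = NULL) {
  stopifnot(ha_length >= 1)
  seg <- .segment_at(locus, cut_position)
  if (seg$kind != "intron" || cut_position >= seg$end)
    stop("cut must fall strictly inside an intron segment")
  n <- nchar(locus$sequence)
  l1 <- cut_position - ha_length + 1L
  r2 <- cut_position + ha_length
  if (l1 < 1L || r2 > n)
    stop("homology arms of ", ha_length, " nt extend beyond the locus")
  cassette <- toupper(cassette)

  v <- NULL
  if (!is.null(variants) && nrow(as.data.frame(variants)) > 0) {
    v <- .check_variants(variants, locus$sequence)
    # every edited base inside one of the arms
    for (k in seq_len(nrow(v))) {
      p <- v$position[k]
      p2 <- if (v$kind[k] == "insertion") p else p + nchar(v$ref[k]) - 1L
      in_left <- p >= l1 && p2 <= cut_position
      in_right <- p >= cut_position + 1L && p2 <= r2
      at_cut_ins <- v$kind[k] == "insertion" && p == cut_position
      if (!(in_left || in_right || at_cut_ins))
        stop("variant '", v$id[k], "' at position ", p,
             " lies outside the homology arms")
    }
    v$tract_distance <- .tract_distance(v, cut_position)
    v <- v[order(v$tract_distance), , drop = FALSE]
    rownames(v) <- NULL
  }

  left_raw <- substr(locus$sequence, l1, cut_position)
  right_raw <- substr(locus$sequence, cut_position + 1L, r2)
  lv <- if (!is.null(v)) v[v$position <= cut_position, , drop = FALSE]
  rv <- if (!is.null(v)) v[v$position > cut_position, , drop = FALSE]
  left_ha <- apply_variants(left_raw, lv, offset = l1 - 1L)
  right_ha <- apply_variants(right_raw, rv, offset = cut_position)

  donor_seq <- paste0(left_ha, cassette, right_ha)
  structure(list(
    left_ha = left_ha, right_ha = right_ha, cassette = cassette,
    ha_length = as.integer(ha_length), cut_position = as.integer(cut_position),
    variants = v, locus_name = locus$name,
    safety = list(ha_ok = ha_length >= 500,
                  terminators = scan_terminators(donor_seq))
  ), class = "donor_design")
}

#' Full donor sequence of a design
#' @param design A `donor_design` object.
#' @return DNA string `left_ha + cassette + right_ha`.
#' @export
donor_sequence <- function(design) {
  paste0(design$left_ha, design$cassette, design$right_ha)
}

#' @export
print.donor_design <- function(x, ...) {
  cat("GEIS donor for locus '", x$locus_name, "'\n", sep = "")
  cat("  arms: ", x$ha_length, " nt each (",
      if (x$safety$ha_ok) "meets" else "BELOW", " the 500-nt minimum); ",
      "cassette: ", nchar(x$cassette), " nt at cut position ",
      x$cut_position, "\n", sep = "")
  nv <- if (is.null(x$variants)) 0L else nrow(x$variants)
  cat("  variants: ", nv, sep = "")
  if (nv > 0)
    cat(" (tract distances: ",
        paste(x$variants$tract_distance, collapse = ", "), " nt)", sep = "")
  cat("\n  terminator motifs in donor: ", nrow(x$safety$terminators), "\n",
      sep = "")
  invisible(x)
}

#' Read a variant table from a VCF-like TSV
#'
#' Expects a header line with at least `position`, `ref`, `alt` (optional
#' `id`, `kind`); `.`/`-`/empty alleles encode insertions and deletions.
#'
#' @param file Path to the TSV.
#' @return A data frame suitable for [assemble_donor()].
#' @export
read_variants_tsv <- function(file) {
  v <- read.delim(file, stringsAsFactors = FALSE)
  names(v) <- tolower(names(v))
  stopifnot(all(c("position", "ref", "alt") %in% names(v)))
  v
}

#' Write a variant table to TSV
#' @param variants Variant data frame.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_variants_tsv <- function(variants, file) {
  v <- as.data.frame(variants)
  v$ref[v$ref == ""] <- "."
  v$alt[v$alt == ""] <- "."
  write.table(v, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
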