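#' Parse gene models from a GFF3 annotation
#'
#' Reads exon and CDS features from a GFF3 file (GENCODE dialect: features
#' carry `transcript_id`/`gene_id` attributes) and assembles one transcript
#' model per transcript. Coordinates are kept in the native GFF3 convention,
#' 1-based closed intervals, which is also the Bioconductor convention used
#' throughout this package.
#'
#' @param file Path to a GFF3 file, plain or gzip-compressed.
#' @param protein_coding_only If `TRUE` (default) and the annotation carries a
#'   `transcript_type` (or `transcript_biotype`) attribute, only
#'   `protein_coding` transcripts are kept. UTR-excluded exon lengths are
#'   undefined for non-coding transcripts, so this is the sensible default for
#'   editability analyses. When the attribute is absent all transcripts are
#'   kept.
#' @param validate Check structural invariants (exons non-overlapping within a
#'   transcript, each CDS contained in an exon). Default `TRUE`.
#'
#' @return An object of class `transcript_models`: a list with data frames
#'   `exons` and `cds` (columns `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end`) and `n_transcripts`.
#'
#' @details Malformed GFF3 lines (fewer than 9 tab-separated fields,
#'   non-numeric coordinates, or `end < start`) abort with an error naming the
#'   offending line number. CDS rows without a transcript identifier are
#'   skipped with a warning. Features on unplaced contigs are retained.
#'   Unstranded (`.`) exon features are rejected: first/last exon flags require
#'   strand.
#'
#' @seealso [exon_records()], [editability_report()], [write_gff3()]
#' @export
parse_gff3 <- function(file, protein_coding_only = TRUE, validate = TRUE) {
  if (!file.exists(file)) stop("annotation file not found: ", file)
  .gff3_prescan(file)
  gr <- rtracklayer::import(file, format = "gff3")
  md <- S4Vectors::mcols(gr)
  tx_id <- .attr_col(md, c("transcript_id", "Parent"))
  gene_id <- .attr_col(md, c("gene_id"))
  tx_type <- .attr_col(md, c("transcript_type", "transcript_biotype"))

  is_exon <- as.character(md$type) == "exon"
  is_cds <- as.character(md$type) == "CDS"
  if (any(is_cds & is.na(tx_id))) {
    warning(sum(is_cds & is.na(tx_id)),
            " CDS feature(s) without a parent transcript identifier; skipped")
    is_cds <- is_cds & !is.na(tx_id)
  }
  is_exon <- is_exon & !is.na(tx_id)
  if (protein_coding_only && !all(is.na(tx_type))) {
    keep <- !is.na(tx_type) & tx_type == "protein_coding"
    is_exon <- is_exon & keep
    is_cds <- is_cds & keep
  }
  as_df <- function(idx, with_gene = TRUE) {
    d <- data.frame(
      transcript_id = tx_id[idx],
      chrom = as.character(GenomicRanges::seqnames(gr))[idx],
      strand = as.character(GenomicRanges::strand(gr))[idx],
      start = GenomicRanges::start(gr)[idx],
      end = GenomicRanges::end(gr)[idx],
      stringsAsFactors = FALSE
    )
    if (with_gene) d$gene_id <- gene_id[idx]
    d
  }
  exons <- as_df(which(is_exon))
  cds <- as_df(which(is_cds), with_gene = FALSE)
  if (nrow(exons) > 0 && any(exons$strand == "*"))
    stop("unstranded ('.') exon features are not supported; ",
         "first/last exon assignment requires strand")
  ord <- order(exons$transcript_id, exons$start)
  exons <- exons[ord, , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(cds) > 0) {
    cds <- cds[order(cds$transcript_id, cds$start), , drop = FALSE]
    rownames(cds) <- NULL
  }
  out <- structure(
    list(exons = exons, cds = cds,
         n_transcripts = length(unique(exons$transcript_id))),
    class = "transcript_models"
  )
  if (validate) .validate_models(out)
  out
}

# Line-level sanity scan so parse failures name the line number.
.gff3_prescan <- function(file) {
  con <- if (grepl("\\.gz$", file)) gzfile(file, "rt") else file(file, "rt")
  on.exit(close(con))
  i <- 0L
  repeat {
    lines <- readLines(con, n = 5000L)
    if (length(lines) == 0L) break
    for (ln in lines) {
      i <- i + 1L
      if (ln == "" || startsWith(ln, "#")) next
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 9L)
        stop("malformed GFF3 line ", i, ": expected 9 tab-separated fields, got ",
             length(f))
      s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
      if (is.na(s) || is.na(e))
        stop("malformed GFF3 line ", i, ": non-numeric coordinates")
      if (e < s)
        stop("malformed GFF3 line ", i, ": end (", f[5], ") < start (", f[4], ")")
    }
  }
  invisible(TRUE)
}

# Pick the first available attribute column; Parent values like
# "transcript:ENST..." are stripped to the bare id. Returns character or NA.
.attr_col <- function(md, candidates) {
  for (nm in candidates) {
    if (nm %in% colnames(md)) {
      v <- md[[nm]]
      if (methods::is(v, "List") || is.list(v)) {
        v <- vapply(v, function(x) if (length(x)) as.character(x[[1]]) else NA_character_,
                    character(1))
      }
      v <- sub("^transcript:", "", as.character(v))
      v[v == ""] <- NA_character_
      return(v)
    }
  }
  rep(NA_character_, nrow(md))
}

.validate_models <- function(models) {
  ex <- models$exons
  if (nrow(ex) == 0) return(invisible(TRUE))
  if (any(ex$end < ex$start)) stop("exon interval with end < start")
  gx <- GenomicRanges::GRanges(paste0(ex$transcript_id, "|", ex$chrom),
                               IRanges::IRanges(ex$start, ex$end))
  hits <- GenomicRanges::findOverlaps(gx, drop.self = TRUE)
  if (length(hits) > 0)
    stop("overlapping exons within a transcript: e.g. ",
         ex$transcript_id[S4Vectors::queryHits(hits)[1]])
  cd <- models$cds
  if (nrow(cd) > 0) {
    gc <- GenomicRanges::GRanges(paste0(cd$transcript_id, "|", cd$chrom),
                                 IRanges::IRanges(cd$start, cd$end))
    w <- GenomicRanges::countOverlaps(gc, gx, type = "within")
    if (any(w != 1L))
      stop("CDS interval not contained in exactly one exon of its transcript: ",
           cd$transcript_id[which(w != 1L)[1]])
  }
  invisible(TRUE)
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("Transcript models:", x$n_transcripts, "transcript(s),",
      nrow(x$exons), "exon row(s),", nrow(x$cds), "CDS row(s)\n")
  invisible(x)
}

#' Serialize transcript models back to GFF3
#'
#' Writes the exon and CDS rows of a `transcript_models` object as GFF3,
#' preserving all intervals, so that `parse_gff3(write_gff3(x))` round-trips.
#'
#' @param models A `transcript_models` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_gff3 <- function(models, file) {
  attr_of <- function(tx, gene) {
    if (is.null(gene)) sprintf("transcript_id=%s", tx)
    else sprintf("ID=%s.%s;transcript_id=%s;gene_id=%s",
                 tx, seq_along(tx), tx, gene)
  }
  ex <- models$exons
  rows <- sprintf("%s\tgeis\texon\t%d\t%d\t.\t%s\t.\t%s",
                  ex$chrom, ex$start, ex$end, ex$strand,
                  sprintf("transcript_id=%s;gene_id=%s", ex$transcript_id, ex$gene_id))
  cd <- models$cds
  if (nrow(cd) > 0)
    rows <- c(rows, sprintf("%s\tgeis\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                            cd$chrom, cd$start, cd$end, cd$strand,
                            sprintf("transcript_id=%s", cd$transcript_id)))
  writeLines(c("##gff-version 3", rows), file)
  invisible(file)
}

#' Per-exon length records (UTR included and excluded)
#'
#' Expands transcript models into one record per (transcript, exon) with the
#' full exon length and the coding length, i.e. the summed overlap of the exon
#' with its transcript's CDS intervals. Exon rank (`exon_index`) and the
#' first/last flags follow transcription order, which on the minus strand is
#' the reverse of genomic order.
#'
#' @param models A `transcript_models` object from [parse_gff3()].
#' @param dedupe Collapse records sharing an identical exon interval
#'   (`chrom`, `strand`, `start`, `end`) across transcripts, keeping one copy.
#'   Default `FALSE`: exons are counted once per transcript, matching a naive
#'   per-row scan of the annotation.
#'
#' @return A data frame with columns `transcript_id`, `exon_index`,
#'   `chrom`, `strand`, `start`, `end`, `length_full`, `length_coding`,
#'   `is_first`, `is_last`.
#' @export
exon_records <- function(models, dedupe = FALSE) {
  ex <- models$exons
  if (nrow(ex) == 0)
    return(data.frame(transcript_id = character(), exon_index = integer(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      length_full = integer(), length_coding = integer(),
                      is_first = logical(), is_last = logical()))
  # exons are sorted by (transcript, genomic start); rank within transcript
  n_by_tx <- table(ex$transcript_id)
  genomic_rank <- stats::ave(seq_len(nrow(ex)), ex$transcript_id,
                             FUN = seq_along)
  n_tx <- as.integer(n_by_tx[ex$transcript_id])
  exon_index <- ifelse(ex$strand == "-", n_tx - genomic_rank + 1L, genomic_rank)

  length_coding <- integer(nrow(ex))
  cd <- models$cds
  if (nrow(cd) > 0) {
    gx <- GenomicRanges::GRanges(paste0(ex$transcript_id, "|", ex$chrom),
                                 IRanges::IRanges(ex$start, ex$end))
    gc <- GenomicRanges::GRanges(paste0(cd$transcript_id, "|", cd$chrom),
                                 IRanges::IRanges(cd$start, cd$end))
    GenomeInfoDb_safe <- suppressWarnings  # differing seqlevels are expected
    hits <- GenomeInfoDb_safe(GenomicRanges::findOverlaps(gx, gc))
    if (length(hits) > 0) {
      qh <- S4Vectors::queryHits(hits)
      ov <- pmin(ex$end[qh], cd$end[S4Vectors::subjectHits(hits)]) -
        pmax(ex$start[qh], cd$start[S4Vectors::subjectHits(hits)]) + 1L
      agg <- tapply(ov, qh, sum)
      length_coding[as.integer(names(agg))] <- as.integer(agg)
    }
  }
  rec <- data.frame(
    transcript_id = ex$transcript_id,
    exon_index = as.integer(exon_index),
    chrom = ex$chrom, strand = ex$strand,
    start = ex$start, end = ex$end,
    length_full = ex$end - ex$start + 1L,
    length_coding = length_coding,
    is_first = exon_index == 1L,
    is_last = exon_index == n_tx,
    stringsAsFactors = FALSE
  )
  stopifnot(all(rec$length_coding >= 0), all(rec$length_coding <= rec$length_full))
  if (dedupe) {
    key <- paste(rec$chrom, rec$strand, rec$start, rec$end, sep = ":")
    rec <- rec[!duplicated(key), , drop = FALSE]
    rownames(rec) <- NULL
  }
  rec
}

.record_lengths <- function(records, mode) {
  mode <- match.arg(mode, c("utr_excluded", "utr_included"))
  if (mode == "utr_excluded") {
    len <- records$length_coding
    len[len > 0]  # fully untranslated exons are excluded from coding fractions
  } else {
    records$length_full
  }
}

#' Fraction of exons longer than a threshold
#'
#' The statistic behind the editability argument: with a conversion-tract
#' budget of half the exon length (a cut can always be placed in the nearer
#' flanking intron), an exon is editable when its (coding) length is at most
#' twice the feasible tract, so the fraction of coding exons exceeding 600 nt
#' bounds the fraction of targets out of reach.
#'
#' @param records Data frame from [exon_records()].
#' @param threshold_nt Length threshold in nucleotides (default 600).
#' @param mode `"utr_excluded"` (coding length; fully untranslated exons are
#'   dropped from the denominator) or `"utr_included"` (full exon length).
#' @return A single fraction in `[0, 1]`.
#' @export
fraction_exceeding <- function(records, threshold_nt = 600,
                               mode = c("utr_excluded", "utr_included")) {
  len <- .record_lengths(records, match.arg(mode))
  if (length(len) == 0)
    stop("no exon records remain after mode filtering; fraction is undefined")
  mean(len > threshold_nt)
}

#' Exon length histogram
#'
#' @param records Data frame from [exon_records()].
#' @param mode `"utr_excluded"` or `"utr_included"`; see [fraction_exceeding()].
#' @param bin_edges Strictly increasing numeric vector of bin edges covering
#'   all observed lengths; bins are left-closed, right-open except the last,
#'   which is closed.
#' @return An object of class `length_distribution`: list with `bin_edges`,
#'   `counts`, `n_total`, `mode`.
#' @export
length_distribution <- function(records, mode = c("utr_excluded", "utr_included"),
                                bin_edges = c(0, 100, 200, 300, 400, 500, 600,
                                              800, 1000, 2000, Inf)) {
  mode <- match.arg(mode)
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  len <- .record_lengths(records, mode)
  if (any(len < bin_edges[1] | len > bin_edges[length(bin_edges)]))
    stop("exon lengths fall outside bin_edges")
  counts <- as.integer(
    table(cut(len, breaks = bin_edges, right = FALSE, include.lowest = TRUE))
  )
  structure(list(bin_edges = bin_edges, counts = counts,
                 n_total = length(len), mode = mode),
            class = "length_distribution")
}

#' @export
print.length_distribution <- function(x, ...) {
  cat("Exon length distribution (", x$mode, "), n = ", x$n_total, "\n", sep = "")
  lab <- paste0("[", head(x$bin_edges, -1), ",", x$bin_edges[-1], ")")
  print(setNames(x$counts, lab))
  invisible(x)
}

#' Editability summary under a conversion-tract budget
#'
#' Summarises, per annotation, how many exons could be edited by placing the
#' double-strand break in the nearer flanking intron: an exon is counted
#' editable when its UTR-excluded length is at most `max_exon_nt` (so the
#' required conversion tract is at most `max_exon_nt / 2`). Also counts how
#' many of the over-threshold exons are first or last exons, which typically
#' carry long UTRs.
#'
#' @param models A `transcript_models` object, or a named list of them (one
#'   per species/annotation); for a list, one row per element plus a pooled
#'   row is returned.
#' @param max_exon_nt Editability threshold on coding exon length (default
#'   600 nt).
#' @param dedupe Passed to [exon_records()].
#' @return A data frame with columns `annotation`, `n_exons`, `n_over`,
#'   `fraction_over`, `fraction_editable`, `n_over_first_or_last`.
#' @export
editability_report <- function(models, max_exon_nt = 600, dedupe = FALSE) {
  if (inherits(models, "transcript_models")) models <- list(annotation = models)
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- paste0("annotation", seq_along(models))
  one <- function(rec, label) {
    coding <- rec[rec$length_coding > 0, , drop = FALSE]
    if (nrow(coding) == 0) stop("no coding exons in ", label)
    over <- coding$length_coding > max_exon_nt
    data.frame(
      annotation = label,
      n_exons = nrow(coding),
      n_over = sum(over),
      fraction_over = mean(over),
      fraction_editable = 1 - mean(over),
      n_over_first_or_last = sum(over & (coding$is_first | coding$is_last)),
      stringsAsFactors = FALSE
    )
  }
  recs <- lapply(models, exon_records, dedupe = dedupe)
  out <- do.call(rbind, Map(one, recs, names(models)))
  if (length(recs) > 1)
    out <- rbind(out, one(do.call(rbind, recs), "pooled"))
  rownames(out) <- NULL
  out
}
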