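#' Configuration for the synthetic GEIS experiment
#'
#' Bundles every knob of the synthetic-data generator. The defaults reproduce
#' the study conditions of the conversion-tract experiment: a three-exon
#' locus with the cut in the second intron, a 800-nt left homology arm
#' carrying seven variants 45, 90, 171, 386, 490, 596 and 696 nt from the
#' double-strand break, 624 sequenced amplicons, a geometric tract model with
#' per-nucleotide continuation probability 0.9989 (survival about 0.65 at
#' 400 nt), Sanger-like substitution errors at 0.001/base, and a clone screen
#' of 24 clones per donor type with true-positive probabilities 21/24
#' (ssDNA) and 10/24 (dsDNA).
#'
#' @param seed Integer seed; all generator output is deterministic given it.
#' @param exon_lengths,intron_lengths Locus layout in nt (exons alternate
#'   with introns); introns must be at least 80 nt.
#' @param cut_intron,cut_offset Which intron hosts the cut and how far
#'   (nt) the cut base sits from the intron start.
#' @param ha_length Homology arm length per arm (nt).
#' @param cassette_length Length of the generated selection cassette (nt);
#'   the cassette is resampled until free of poly(A)-signal motifs.
#' @param variant_distances Distances (nt) of the designed variants from the
#'   cut, strictly increasing, all on the left arm.
#' @param variant_kinds Variant kinds recycled along `variant_distances`
#'   (`"substitution"`, `"insertion"`, `"deletion"`).
#' @param tract_family,tract_p Tract-length family (only `"geometric"`) and
#'   its per-nucleotide continuation probability.
#' @param n_reads Number of amplicon reads to simulate.
#' @param error_rate Per-base substitution sequencing-error rate.
#' @param indel_error_rate Per-base indel sequencing-error rate (default 0;
#'   Sanger consensus reads rarely contain indel errors).
#' @param non_hdr_fraction Fraction of reads that are pure wild type
#'   (e.g. false-positive clones), default 0.
#' @param clone_p Named vector of per-clone true-positive probabilities by
#'   donor type.
#' @param n_clones Clones genotyped per donor type.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1,
                       exon_lengths = c(200, 700, 600),
                       intron_lengths = c(300, 400),
                       cut_intron = 2, cut_offset = 100,
                       ha_length = 800, cassette_length = 200,
                       variant_distances = c(45, 90, 171, 386, 490, 596, 696),
                       variant_kinds = "substitution",
                       tract_family = "geometric", tract_p = 0.9989,
                       n_reads = 624, error_rate = 0.001,
                       indel_error_rate = 0, non_hdr_fraction = 0,
                       clone_p = c(ssDNA = 21 / 24, dsDNA = 10 / 24),
                       n_clones = 24) {
  stopifnot(length(exon_lengths) == length(intron_lengths) + 1)
  if (any(intron_lengths < 80))
    stop("locus layout too small: introns must be at least 80 nt")
  if (any(variant_distances <= 0) ||
      is.unsorted(variant_distances, strictly = TRUE))
    stop("variant_distances must be positive and strictly increasing")
  probs <- c(tract_p, error_rate, indel_error_rate, non_hdr_fraction, clone_p)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (tract_p >= 1 || tract_p <= 0)
    stop("tract_p must lie strictly in (0, 1)")
  tract_family <- match.arg(tract_family, "geometric")
  structure(list(seed = as.integer(seed),
                 exon_lengths = as.integer(exon_lengths),
                 intron_lengths = as.integer(intron_lengths),
                 cut_intron = as.integer(cut_intron),
                 cut_offset = as.integer(cut_offset),
                 ha_length = as.integer(ha_length),
                 cassette_length = as.integer(cassette_length),
                 variant_distances = as.numeric(variant_distances),
                 variant_kinds = rep_len(variant_kinds,
                                         length(variant_distances)),
                 tract_family = tract_family, tract_p = tract_p,
                 n_reads = as.integer(n_reads), error_rate = error_rate,
                 indel_error_rate = indel_error_rate,
                 non_hdr_fraction = non_hdr_fraction,
                 clone_p = clone_p, n_clones = as.integer(n_clones)),
            class = "sim_config")
}

#' Generate a random locus with canonical splice anatomy
#'
#' Builds a random DNA sequence tiled by the configured exon/intron layout.
#' Every intron gets canonical `GT...AG` boundaries, a branch-point adenine
#' 20-40 nt upstream of the acceptor, and a 10-nt polypyrimidine tract
#' immediately before the terminal `AG`, so the locus passes the canonical
#' checks in [locus_sequence()] and supports splice-safe guide enumeration.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [locus_sequence()] object.
#' @export
make_locus <- function(config) {
  with_seed(config$seed, {
    ne <- length(config$exon_lengths)
    lens <- integer(2 * ne - 1)
    kinds <- character(2 * ne - 1)
    lens[seq(1, 2 * ne - 1, by = 2)] <- config$exon_lengths
    kinds[seq(1, 2 * ne - 1, by = 2)] <- "exon"
    if (ne > 1) {
      lens[seq(2, 2 * ne - 2, by = 2)] <- config$intron_lengths
      kinds[seq(2, 2 * ne - 2, by = 2)] <- "intron"
    }
    total <- sum(lens)
    base <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    for (i in which(kinds == "intron")) {
      a <- starts[i]; b <- ends[i]
      base[a] <- "G"; base[a + 1L] <- "T"
      base[b - 1L] <- "A"; base[b] <- "G"
      base[(b - 11L):(b - 2L)] <- sample(c("C", "T"), 10, replace = TRUE)
      bp <- b - sample(20:40, 1)
      base[bp] <- "A"
    }
    locus_sequence(paste0("synthetic_locus_seed", config$seed),
                   paste(base, collapse = ""),
                   data.frame(kind = kinds, start = starts, end = ends))
  })
}

# Internal: locus coordinate of the cut for a config.
.config_cut <- function(config, locus) {
  seg <- .intron_segment(locus, config$cut_intron)
  seg$start + config$cut_offset - 1L
}

#' Designed variants at given distances from the cut
#'
#' Places one variant per requested distance on the left homology arm:
#' substitutions are single-base transversions; insertions add a 3-mer and
#' deletions remove 3 bases, with alleles/contexts chosen so the resulting
#' alignments have a unique gap placement (no homopolymer shift ambiguity).
#'
#' @param locus A [locus_sequence()].
#' @param cut_position Locus coordinate of the cut base.
#' @param distances Tract distances in nt (see [assemble_donor()] for the
#'   convention).
#' @param kinds Variant kinds, recycled along `distances`.
#' @return A variant table for [assemble_donor()], with `id` of the form
#'   `"M<distance>"`.
#' @export
variants_at_distances <- function(locus, cut_position, distances,
                                  kinds = "substitution") {
  kinds <- rep_len(kinds, length(distances))
  seq <- locus$sequence
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  rows <- lapply(seq_along(distances), function(k) {
    d <- distances[k]
    switch(kinds[k],
      substitution = {
        p <- cut_position - d + 1L
        ref <- substr(seq, p, p)
        data.frame(id = paste0("M", d), kind = "substitution", position = p,
                   ref = ref, alt = unname(flip[ref]))
      },
      insertion = {
        p <- cut_position - d          # insert between p and p+1
        left <- substr(seq, p, p); right <- substr(seq, p + 1L, p + 1L)
        # first inserted base must differ from the base after the insertion
        # point and the last from the base before it, so the gap cannot shift
        first <- unname(flip[right]); last <- unname(flip[left])
        mid <- if (first == "G" || last == "G") "C" else "G"
        data.frame(id = paste0("M", d), kind = "insertion", position = p,
                   ref = "", alt = paste0(first, mid, last))
      },
      deletion = {
        p2 <- cut_position - d + 1L    # nearest deleted base
        len <- 3L
        repeat {                       # grow until the gap cannot shift
          p <- p2 - len + 1L
          ok <- substr(seq, p - 1L, p - 1L) != substr(seq, p2, p2) &&
                substr(seq, p2 + 1L, p2 + 1L) != substr(seq, p, p)
          if (ok || len > 10L) break
          len <- len + 1L
        }
        data.frame(id = paste0("M", d), kind = "deletion", position = p,
                   ref = substr(seq, p, p2), alt = "")
      },
      stop("unknown variant kind: ", kinds[k]))
  })
  do.call(rbind, rows)
}

# Internal: random cassette free of poly(A)-signal motifs, drawn from the
# current RNG stream.
.make_cassette <- function(len) {
  for (i in 1:100) {
    cas <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    if (nrow(scan_terminators(cas)) == 0) return(cas)
  }
  stop("could not generate a terminator-free cassette")
}

#' Simulate amplicon reads under the conversion-tract model
#'
#' For each read, a tract length L is drawn from the configured family
#' (geometric: `P(L >= d) = p^d`); the read incorporates exactly the donor
#' variants with distance at most L (nested incorporation), then acquires iid
#' per-base sequencing errors. A `non_hdr_fraction` of reads is pure wild
#' type. Reads span the left homology arm: the wild-type reference of that
#' span is returned for downstream alignment. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param locus Optional [locus_sequence()]; defaults to `make_locus(config)`.
#' @param donor Optional `donor_design`; defaults to a donor assembled at the
#'   configured cut with [variants_at_distances()] and a generated cassette.
#' @return An object of class `geis_sim`: list with `reads` (named
#'   `DNAStringSet`), `truth` (data frame `read_id`, `is_hdr`, `tract_length`
#'   plus attribute-free matrix `incorporation`), `reference` (wild-type
#'   left-arm sequence), `ref_start` (locus coordinate of its first base),
#'   `variants`, `donor`, `locus`, `config`.
#' @export
simulate_reads <- function(config, locus = NULL, donor = NULL) {
  if (is.null(locus)) locus <- make_locus(config)
  cut <- .config_cut(config, locus)
  if (is.null(donor)) {
    v <- variants_at_distances(locus, cut, config$variant_distances,
                               config$variant_kinds)
    cassette <- with_seed(config$seed + 101L,
                          .make_cassette(config$cassette_length))
    donor <- assemble_donor(locus, cut, config$ha_length, cassette, v)
  }
  v <- donor$variants
  ref_start <- cut - config$ha_length + 1L
  reference <- substr(locus$sequence, ref_start, cut)

  with_seed(config$seed + 1L, {
    n <- config$n_reads
    K <- nrow(v)
    is_hdr <- runif(n) >= config$non_hdr_fraction
    L <- ifelse(is_hdr, rgeom(n, prob = 1 - config$tract_p), -1)
    inc <- outer(L, v$tract_distance, ">=")
    dimnames(inc) <- list(sprintf("read_%04d", seq_len(n)), v$id)

    # nested incorporation => at most K + 1 distinct edited sequences
    n_inc <- rowSums(inc)
    templates <- vapply(0:K, function(k) {
      vk <- v[seq_len(K) <= k, , drop = FALSE]  # v is ordered by distance
      apply_variants(reference, vk, offset = ref_start - 1L)
    }, character(1))
    seqs <- templates[n_inc + 1L]

    # iid sequencing errors
    flip_err <- function(s) {
      ch <- strsplit(s, "")[[1]]
      len <- length(ch)
      hit <- which(runif(len) < config$error_rate)
      if (length(hit)) {
        ch[hit] <- vapply(ch[hit], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      }
      if (config$indel_error_rate > 0) {
        ih <- which(runif(len) < config$indel_error_rate)
        for (pos in rev(ih)) {
          if (runif(1) < 0.5 && length(ch) > 1) ch <- ch[-pos]
          else ch <- append(ch, sample(c("A", "C", "G", "T"), 1), after = pos)
        }
      }
      paste(ch, collapse = "")
    }
    if (config$error_rate > 0 || config$indel_error_rate > 0)
      seqs <- vapply(seqs, flip_err, character(1), USE.NAMES = FALSE)

    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- rownames(inc)
    truth <- data.frame(read_id = rownames(inc), is_hdr = is_hdr,
                        tract_length = ifelse(is_hdr, L, NA_real_))
    structure(list(reads = reads,
                   truth = list(table = truth, incorporation = inc),
                   reference = reference, ref_start = ref_start,
                   variants = v, donor = donor, locus = locus,
                   config = config),
              class = "geis_sim")
  })
}

#' @export
print.geis_sim <- function(x, ...) {
  cat("Synthetic GEIS experiment: ", length(x$reads), " read(s), ",
      nrow(x$variants), " designed variant(s), tract p = ",
      x$config$tract_p, "\n", sep = "")
  invisible(x)
}

#' Ground-truth call matrix of a simulation
#'
#' Converts the simulator's incorporation table into a `read_call_matrix`
#' (no ambiguity, perfect calls), the reference against which the
#' alignment-based calls of [build_matrix()] are judged, and a fast substrate
#' for statistics at large n.
#'
#' @param sim A `geis_sim` from [simulate_reads()].
#' @return A `read_call_matrix`.
#' @export
truth_matrix <- function(sim) {
  inc <- sim$truth$incorporation
  calls <- ifelse(inc, "converted", "unconverted")
  structure(list(calls = calls, identity = rep(1, nrow(calls)),
                 strand = rep("+", nrow(calls)),
                 variants = sim$variants,
                 qc = list(n_input = nrow(calls), n_pass = nrow(calls),
                           n_fail = 0L)),
            class = "read_call_matrix")
}

#' Simulate a clone genotyping screen
#'
#' Bernoulli clone genotypes per donor type, feeding [clone_report()]:
#' each genotyped clone is truly recombined with the configured
#' per-donor-type probability. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Data frame with `clone_id`, `donor_type`, `positive`.
#' @export
simulate_clone_experiment <- function(config) {
  if (config$n_clones <= 0) stop("n_clones must be positive")
  with_seed(config$seed + 2L, {
    types <- names(config$clone_p)
    if (is.null(types)) types <- paste0("donor", seq_along(config$clone_p))
    do.call(rbind, lapply(seq_along(config$clone_p), function(i) {
      data.frame(clone_id = sprintf("%s_clone_%02d", types[i],
                                    seq_len(config$n_clones)),
                 donor_type = types[i],
                 positive = rbinom(config$n_clones, 1, config$clone_p[i]) == 1)
    }))
  })
}

#' Write a simulated experiment to files
#'
#' Emits `reads.fasta`, `locus.fasta`, `donor.fasta`, `reference.fasta`,
#' `truth.tsv` (read table plus incorporation flags), `variants.tsv` and
#' `config.json` into a directory.
#'
#' @param sim A `geis_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$reads, file.path(dir, "reads.fasta"))
  loc <- Biostrings::DNAStringSet(sim$locus$sequence)
  names(loc) <- sim$locus$name
  Biostrings::writeXStringSet(loc, file.path(dir, "locus.fasta"))
  don <- Biostrings::DNAStringSet(donor_sequence(sim$donor))
  names(don) <- paste0(sim$locus$name, "_donor")
  Biostrings::writeXStringSet(don, file.path(dir, "donor.fasta"))
  ref <- Biostrings::DNAStringSet(sim$reference)
  names(ref) <- paste0(sim$locus$name, "_amplicon_ref")
  Biostrings::writeXStringSet(ref, file.path(dir, "reference.fasta"))
  tt <- cbind(sim$truth$table,
              as.data.frame(sim$truth$incorporation))
  write.table(tt, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_variants_tsv(sim$variants, file.path(dir, "variants.tsv"))
  cfg <- sim$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
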