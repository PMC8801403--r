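# Independent oracles used across the suite. These deliberately re-derive
# results by direct enumeration / closed form, sharing no code path with the
# package internals they check.

toy_gff3 <- function() system.file("extdata", "toy.gff3", package = "geis")

revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# Brute-force guide scanner: tests every offset of the locus directly.
bf_guides <- function(locus, intron_index, donor_w = 20, acceptor_w = 50) {
  seq <- locus$sequence
  n <- nchar(seq)
  s <- locus$segments
  row <- s[s$kind == "intron" & s$index == intron_index, ]
  a <- row$start; b <- row$end
  lo <- a + donor_w; hi <- b - acceptor_w - 1
  out <- list()
  if (n >= 23) for (i in 1:(n - 22)) {
    site <- substr(seq, i, i + 22)
    if (grepl("N", site, fixed = TRUE)) next
    if (substr(site, 22, 23) == "GG") {            # plus PAM at i+20..i+22
      cut <- i + 16
      if (cut >= lo && cut <= hi)
        out[[length(out) + 1]] <- data.frame(
          protospacer = substr(site, 1, 20), pam = substr(site, 21, 23),
          strand = "+", cut_position = cut)
    }
    if (substr(site, 1, 2) == "CC") {              # minus PAM at i..i+2
      cut <- i + 5
      if (cut >= lo && cut <= hi) {
        rc <- revcomp_chr(site)
        out[[length(out) + 1]] <- data.frame(
          protospacer = substr(rc, 1, 20), pam = substr(rc, 21, 23),
          strand = "-", cut_position = cut)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(protospacer = character(), pam = character(),
                      strand = character(), cut_position = integer()))
  do.call(rbind, out)
}

guide_key <- function(df) {
  sort(paste(df$protospacer, df$pam, df$strand, df$cut_position, sep = "|"))
}

# Naive overlapping substring search for terminator motifs.
bf_terminators <- function(seq) {
  out <- list()
  for (m in c("AATAAA", "ATTAAA")) {
    for (i in seq_len(max(nchar(seq) - 5, 0)))
      if (substr(seq, i, i + 5) == m)
        out[[length(out) + 1]] <- data.frame(motif = m, position = i)
  }
  if (length(out) == 0) return(data.frame(motif = character(),
                                          position = integer()))
  d <- do.call(rbind, out)
  d[order(d$position), , drop = FALSE]
}

# Interval-censored geometric log-likelihood recomputed per read straight
# from the call matrix (no shared code with tract_intervals), vectorized
# over a grid of p values. Non-nested reads are skipped, matching the
# fitter's default.
grid_loglik <- function(calls, distances, pgrid) {
  ll <- numeric(length(pgrid))
  for (r in seq_len(nrow(calls))) {
    cv <- distances[calls[r, ] == "converted"]
    uc <- distances[calls[r, ] == "unconverted"]
    if (length(cv) == 0 && length(uc) == 0) next
    if (length(cv) > 0 && length(uc) > 0 && max(cv) >= min(uc)) next
    a <- if (length(cv)) max(cv) else 0
    b <- if (length(uc)) min(uc[uc > a], Inf) else Inf
    ll <- ll + log(pgrid^a - (if (is.finite(b)) pgrid^b else 0))
  }
  ll
}

grid_mle <- function(calls, distances, step = 1e-4) {
  pgrid <- seq(step, 1 - step, by = step)
  pgrid[which.max(grid_loglik(calls, distances, pgrid))]
}

# Small nested ground-truth call matrix drawn directly from the geometric
# model (independent of the package simulator).
draw_calls <- function(n, p, distances) {
  L <- rgeom(n, prob = 1 - p)
  conv <- outer(L, distances, ">=")
  matrix(ifelse(conv, "converted", "unconverted"), n, length(distances),
         dimnames = list(paste0("r", seq_len(n)), paste0("M", distances)))
}

as_call_matrix <- function(calls, distances) {
  structure(list(calls = calls, identity = rep(1, nrow(calls)),
                 strand = rep("+", nrow(calls)),
                 variants = data.frame(id = colnames(calls),
                                       tract_distance = distances),
                 qc = list(n_input = nrow(calls), n_pass = nrow(calls),
                           n_fail = 0L)),
            class = "read_call_matrix")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Mutate a sequence with substitutions and small indels, for alignment pairs.
mutate_dna <- function(seq, sub_rate = 0.02, indel_rate = 0.005) {
  ch <- strsplit(seq, "")[[1]]
  hit <- runif(length(ch)) < sub_rate
  ch[hit] <- sapply(ch[hit], function(b) sample(setdiff(c("A","C","G","T"), b), 1))
  ih <- which(runif(length(ch)) < indel_rate)
  for (pos in rev(ih)) {
    if (runif(1) < 0.5 && length(ch) > 1) ch <- ch[-pos]
    else ch <- append(ch, sample(c("A","C","G","T"), 1), after = pos)
  }
  paste(ch, collapse = "")
}
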