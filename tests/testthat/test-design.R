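# A locus built so that the middle intron contains exactly one NGG site:
# background is G/C-free except for the splice dinucleotides and one AGG.
single_pam_locus <- function() {
  exon1 <- strrep("A", 50)
  # intron: GT + 118 T + TAGG + T*120 + 10 pyrimidines are T already + AG
  intron <- paste0("GT", strrep("T", 118), "TAGG", strrep("T", 124), "AG")
  exon2 <- strrep("A", 50)
  seq <- paste0(exon1, intron, exon2)
  locus_sequence("one_pam", seq, data.frame(
    kind = c("exon", "intron", "exon"),
    start = c(1, 51, 51 + nchar(intron)),
    end = c(50, 50 + nchar(intron), nchar(seq))))
}

test_that("a single embedded PAM yields exactly the expected guide", {
  locus <- single_pam_locus()
  g <- enumerate_guides(locus, 1)
  # GG sits at positions 173-174, so the protospacer starts at 152 and the
  # cut falls after base 168, well inside the 20/50 safety windows
  expect_equal(nrow(g), 1L)
  expect_equal(g$strand, "+")
  expect_equal(g$cut_position, 168L)
  expect_equal(g$pam, "AGG")
  expect_equal(g$protospacer, substr(locus$sequence, 152, 171))
  # and the brute-force scanner agrees exactly
  expect_equal(guide_key(g), guide_key(bf_guides(locus, 1)))
})

test_that("cuts inside the splice-safety windows are rejected", {
  locus <- single_pam_locus()
  # acceptor window of 150 swallows the single site (cut 168 is 131 nt from
  # the intron 3' end at 298)
  g <- suppressWarnings(enumerate_guides(locus, 1,
                                         splice_policy(20, 150)))
  expect_equal(nrow(g), 0L)
  # a 60-nt intron can host no admissible cut at all under 20/50 windows
  tiny <- locus_sequence("tiny", paste0(strrep("A", 30),
                                        paste0("GT", strrep("T", 46),
                                               strrep("T", 10), "AG"),
                                        strrep("A", 30)),
                         data.frame(kind = c("exon", "intron", "exon"),
                                    start = c(1, 31, 91),
                                    end = c(30, 90, 120)))
  expect_warning(g0 <- enumerate_guides(tiny, 1), "admits no cut")
  expect_equal(nrow(g0), 0L)
})

test_that("enumerated guides equal a brute-force scan on random loci", {
  set.seed(42)
  for (i in 1:10) {
    cfg <- sim_config(seed = 1000 + i,
                      exon_lengths = sample(100:300, 3, replace = TRUE),
                      intron_lengths = sample(150:400, 2, replace = TRUE))
    locus <- make_locus(cfg)
    for (k in 1:2) {
      g <- suppressWarnings(enumerate_guides(locus, k))
      expect_equal(guide_key(g), guide_key(bf_guides(locus, k)))
    }
  }
})

test_that("guides never overlap degenerate bases", {
  locus <- single_pam_locus()
  seq <- locus$sequence
  substr(seq, 160, 160) <- "N"     # inside the only protospacer
  locusN <- locus_sequence("one_pam_N", seq, locus$segments[1:3])
  expect_warning(g <- enumerate_guides(locusN, 1), "no admissible")
  expect_equal(nrow(g), 0L)
})

test_that("nearest_intron picks the closer flank and halves the exon", {
  cfg <- sim_config(seed = 7, exon_lengths = c(200, 600, 200),
                    intron_lengths = c(300, 300))
  locus <- make_locus(cfg)
  s <- locus$segments
  ex2 <- s[s$kind == "exon" & s$index == 2, ]
  # 100 nt into a 600-nt internal exon: left intron, budget 100
  r <- nearest_intron(locus, ex2$start + 99)
  expect_equal(r$side, "left")
  expect_equal(r$intron_index, 1L)
  expect_equal(r$tract_budget_nt, 100L)
  # 300 nt in: still feasible with a 300-nt tract
  expect_equal(nearest_intron(locus, ex2$start + 299)$tract_budget_nt, 300L)
  # target in an intron is an error directing the caller to cut there
  expect_error(nearest_intron(locus, s$start[s$kind == "intron"][1] + 5),
               "directly")
  # first exon must use its right intron
  expect_equal(nearest_intron(locus, 10)$side, "right")
})

test_that("midpoint ties break left and budgets never exceed half the exon", {
  cfg <- sim_config(seed = 8, exon_lengths = c(150, 601, 150),
                    intron_lengths = c(200, 200))
  locus <- make_locus(cfg)
  s <- locus$segments
  ex2 <- s[s$kind == "exon" & s$index == 2, ]
  mid <- ex2$start + 300   # position 301 of 601: equidistant
  r <- nearest_intron(locus, mid)
  expect_equal(r$side, "left")
  expect_equal(r$tract_budget_nt, 301L)
  for (pos in seq(ex2$start, ex2$end, by = 23)) {
    b <- nearest_intron(locus, pos)$tract_budget_nt
    expect_lte(b, ceiling((ex2$end - ex2$start + 1) / 2) + 1)
  }
})

test_that("terminator scan matches a naive substring search", {
  expect_equal(scan_terminators(paste0(strrep("C", 10), "AATAAA", strrep("C", 5)))$position, 11L)
  expect_equal(nrow(scan_terminators(strrep("CGCT", 100))), 0L)
  # overlapping signals: AATAAATTAAA holds AATAAA at 1, ATTAAA at 6
  ov <- scan_terminators("AATAAATTAAA")
  expect_equal(ov$position, c(1L, 6L))
  set.seed(11)
  big <- random_dna(10000)
  expect_equal(scan_terminators(big), bf_terminators(big),
               ignore_attr = TRUE)
})

test_that("donor assembly reproduces the designed tract distances", {
  cfg <- sim_config(seed = 9)
  locus <- make_locus(cfg)
  cut <- geis:::.config_cut(cfg, locus)
  v <- variants_at_distances(locus, cut, cfg$variant_distances)
  donor <- assemble_donor(locus, cut, 800, strrep("GATC", 50), v)
  expect_equal(donor$variants$tract_distance,
               c(45, 90, 171, 386, 490, 596, 696))
  expect_true(donor$safety$ha_ok)
  # arms below the 500-nt minimum are flagged
  v_near <- v[v$tract_distance < 250, , drop = FALSE]
  short <- assemble_donor(locus, cut, 250, strrep("GATC", 50), v_near)
  expect_false(short$safety$ha_ok)
})

test_that("a variant-free donor reconstructs locus plus cassette exactly", {
  cfg <- sim_config(seed = 10)
  locus <- make_locus(cfg)
  cut <- geis:::.config_cut(cfg, locus)
  donor <- assemble_donor(locus, cut, 600, "GATTACA")
  expect_equal(donor_sequence(donor),
               paste0(substr(locus$sequence, cut - 599, cut), "GATTACA",
                      substr(locus$sequence, cut + 1, cut + 600)))
})

test_that("variants round-trip through the donor arms", {
  cfg <- sim_config(seed = 12,
                    variant_kinds = c("substitution", "insertion", "deletion"))
  locus <- make_locus(cfg)
  cut <- geis:::.config_cut(cfg, locus)
  v <- variants_at_distances(locus, cut, cfg$variant_distances,
                             cfg$variant_kinds)
  donor <- assemble_donor(locus, cut, 800, "GATTACA", v)
  # applying the variant list to the raw locus window reproduces the arm
  expect_equal(donor$left_ha,
               apply_variants(substr(locus$sequence, cut - 799, cut),
                              donor$variants, offset = cut - 800))
})

test_that("donor assembly rejects inconsistent variants and placements", {
  cfg <- sim_config(seed = 13)
  locus <- make_locus(cfg)
  cut <- geis:::.config_cut(cfg, locus)
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  actual <- substr(locus$sequence, cut - 44, cut - 44)
  bad <- data.frame(position = cut - 44, ref = unname(flip[actual]),
                    alt = actual)
  expect_error(assemble_donor(locus, cut, 800, "GATTACA", bad),
               "mismatch")
  far <- data.frame(position = cut - 900,
                    ref = substr(locus$sequence, cut - 900, cut - 900),
                    alt = "A")
  far$alt <- ifelse(far$ref == "A", "C", "A")
  expect_error(assemble_donor(locus, cut, 800, "GATTACA", far),
               "outside the homology arms")
  # the cut itself must be intronic
  s <- locus$segments
  exonic <- s$start[s$kind == "exon"][2] + 10
  expect_error(assemble_donor(locus, exonic, 100, "GATTACA"), "intron")
})

test_that("variant TSV round-trips including indel encoding", {
  v <- data.frame(id = c("a", "b", "c"), kind = c("substitution", "insertion",
                                                  "deletion"),
                  position = c(10L, 20L, 30L),
                  ref = c("A", "", "CCT"), alt = c("G", "TTG", ""))
  tmp <- tempfile(fileext = ".tsv")
  write_variants_tsv(v, tmp)
  back <- read_variants_tsv(tmp)
  expect_equal(back$position, v$position)
  expect_equal(back$ref, c("A", ".", "CCT"))
  expect_equal(back$alt, c("G", "TTG", "."))
})

test_that("exported apply_variants handles all three kinds with offsets", {
  v <- data.frame(kind = c("substitution", "insertion", "deletion"),
                  position = c(103L, 105L, 106L),
                  ref = c("A", "", "TT"), alt = c("G", "CC", ""),
                  id = c("s", "i", "d"))
  # local window starts at locus coordinate 101
  expect_equal(apply_variants("AAAAATTAAA", v, offset = 100L),
               "AAGAACCAAA")
})
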