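test_that("toy annotation parses to the hand-counted transcript models", {
  models <- parse_gff3(toy_gff3())
  expect_s3_class(models, "transcript_models")
  expect_equal(models$n_transcripts, 2L)

  t1 <- models$exons[models$exons$transcript_id == "t1", ]
  expect_equal(t1$start, c(101, 501, 801))
  expect_equal(t1$end, c(400, 700, 1500))
  expect_equal(unique(t1$strand), "+")

  t2 <- models$exons[models$exons$transcript_id == "t2", ]
  expect_equal(t2$start, c(1001, 2001, 2901))
  expect_equal(t2$end, c(1800, 2650, 3000))
  expect_equal(unique(t2$strand), "-")

  expect_equal(nrow(models$cds), 4L)
})

test_that("exon records carry UTR-included/excluded lengths and strand-aware ranks", {
  rec <- exon_records(parse_gff3(toy_gff3()))
  r1 <- rec[rec$transcript_id == "t1", ]
  # exon [101,400] with CDS [251,400]: full 300, coding 150
  expect_equal(r1$length_full, c(300, 200, 700))
  expect_equal(r1$length_coding, c(150, 200, 0))
  expect_equal(r1$exon_index, 1:3)
  expect_true(r1$is_first[1] && r1$is_last[3])

  # minus strand: genomic order is the reverse of transcription order
  r2 <- rec[rec$transcript_id == "t2", ]
  expect_equal(r2$length_full, c(800, 650, 100))
  expect_equal(r2$length_coding, c(700, 550, 0))
  expect_equal(r2$exon_index, c(3, 2, 1))
  expect_true(r2$is_first[3] && r2$is_last[1])
  expect_true(all(rec$length_coding <= rec$length_full))
})

test_that("per-transcript coding lengths sum to the total CDS length", {
  models <- parse_gff3(toy_gff3())
  rec <- exon_records(models)
  cds_len <- tapply(models$cds$end - models$cds$start + 1,
                    models$cds$transcript_id, sum)
  rec_len <- tapply(rec$length_coding, rec$transcript_id, sum)
  expect_equal(as.numeric(rec_len[names(cds_len)]), as.numeric(cds_len))
})

test_that("fraction_exceeding matches hand counts and is monotone in threshold", {
  rec <- exon_records(parse_gff3(toy_gff3()))
  # coding lengths 150, 200, 700, 550: one of four exceeds 600
  expect_equal(fraction_exceeding(rec, 600, "utr_excluded"), 0.25)
  expect_equal(fraction_exceeding(rec, 100, "utr_excluded"), 1.0)
  # full lengths 300, 200, 700, 800, 650, 100: three of six exceed 600
  expect_equal(fraction_exceeding(rec, 600, "utr_included"), 0.5)
  # long UTR-bearing exons: UTR-included fraction >= UTR-excluded at 600
  expect_gte(fraction_exceeding(rec, 600, "utr_included"),
             fraction_exceeding(rec, 600, "utr_excluded"))
  fr <- sapply(c(0, 150, 300, 550, 600, 700, 1000),
               function(th) fraction_exceeding(rec, th, "utr_excluded"))
  expect_true(all(diff(fr) <= 0))
  expect_error(fraction_exceeding(rec[0, ], 600), "undefined")
})

test_that("editability report counts over-budget exons and their first/last status", {
  rep <- editability_report(parse_gff3(toy_gff3()), max_exon_nt = 600)
  expect_equal(rep$n_exons, 4L)
  expect_equal(rep$n_over, 1L)
  expect_equal(rep$fraction_editable, 0.75)
  # the 700-nt coding exon is the last exon of t2
  expect_equal(rep$n_over_first_or_last, 1L)

  # a transcript whose only coding exon is 601 nt is entirely uneditable
  m <- parse_gff3(toy_gff3())
  m$exons <- m$exons[m$exons$transcript_id == "t2" & m$exons$start == 1001, ]
  m$cds <- data.frame(transcript_id = "t2", chrom = "chr2", strand = "-",
                      start = 1100, end = 1700)
  expect_equal(editability_report(m)$fraction_editable, 0)
})

test_that("deduplication collapses exons shared between transcripts", {
  models <- parse_gff3(toy_gff3())
  dup <- models$exons[models$exons$transcript_id == "t1", ]
  dup$transcript_id <- "t1b"
  models$exons <- rbind(models$exons, dup)
  dupc <- models$cds[models$cds$transcript_id == "t1", ]
  dupc$transcript_id <- "t1b"
  models$cds <- rbind(models$cds, dupc)
  expect_equal(nrow(exon_records(models)), 9L)
  expect_equal(nrow(exon_records(models, dedupe = TRUE)), 6L)
  # duplicate rows change no fraction under dedupe
  expect_equal(
    fraction_exceeding(exon_records(models, dedupe = TRUE), 600),
    fraction_exceeding(exon_records(parse_gff3(toy_gff3())), 600))
})

test_that("GFF3 round-trip preserves all intervals", {
  models <- parse_gff3(toy_gff3())
  tmp <- tempfile(fileext = ".gff3")
  write_gff3(models, tmp)
  back <- parse_gff3(tmp)
  cols <- c("transcript_id", "chrom", "strand", "start", "end")
  expect_equal(back$exons[cols], models$exons[cols])
  expect_equal(back$cds[cols[-1]], models$cds[cols[-1]])
})

test_that("malformed annotations fail loudly, empty ones parse to nothing", {
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttoy\texon\t500\t100\t.\t+\t.\ttranscript_id=tx"), bad)
  expect_error(parse_gff3(bad), "line 2")

  short <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr1\ttoy\texon\t100"), short)
  expect_error(parse_gff3(short), "line 2")

  empty <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(parse_gff3(empty)$n_transcripts, 0L)

  unstranded <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttoy\texon\t100\t500\t.\t.\t.\ttranscript_id=tx"),
             unstranded)
  expect_error(parse_gff3(unstranded), "strand")
})

test_that("length distributions bin every exon exactly once", {
  rec <- exon_records(parse_gff3(toy_gff3()))
  ld <- length_distribution(rec, "utr_excluded")
  expect_equal(sum(ld$counts), ld$n_total)
  expect_equal(ld$n_total, 4L)
  ld2 <- length_distribution(rec, "utr_included")
  expect_equal(ld2$n_total, 6L)
  expect_error(length_distribution(rec, bin_edges = c(0, 100)), "outside")
})
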