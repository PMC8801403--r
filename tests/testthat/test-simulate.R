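test_that("generated loci have canonical splice anatomy", {
  cfg <- sim_config(seed = 31)
  locus <- make_locus(cfg)
  s <- locus$segments
  expect_equal(s$kind, c("exon", "intron", "exon", "intron", "exon"))
  for (i in which(s$kind == "intron")) {
    a <- s$start[i]; b <- s$end[i]
    expect_equal(substr(locus$sequence, a, a + 1), "GT")
    expect_equal(substr(locus$sequence, b - 1, b), "AG")
    # 10-nt polypyrimidine tract just upstream of the AG
    expect_true(grepl("^[CT]{10}$",
                      substr(locus$sequence, b - 11, b - 2)))
    # a branch-point adenine 20-40 nt upstream of the acceptor
    expect_true(grepl("A", substr(locus$sequence, b - 40, b - 20)))
  }
  # constructor enforces the same invariants, so re-validation passes
  expect_s3_class(locus_sequence(locus$name, locus$sequence,
                                 locus$segments[c("kind", "start", "end")]),
                  "geis_locus")
})

test_that("generators are deterministic given the seed", {
  cfg <- sim_config(seed = 32, n_reads = 50)
  expect_identical(make_locus(cfg)$sequence, make_locus(cfg)$sequence)
  s1 <- simulate_reads(cfg); s2 <- simulate_reads(cfg)
  expect_identical(as.character(s1$reads), as.character(s2$reads))
  expect_identical(s1$truth, s2$truth)
  expect_identical(simulate_clone_experiment(cfg),
                   simulate_clone_experiment(cfg))
  # and a different seed changes the sequence
  expect_false(identical(make_locus(sim_config(seed = 33))$sequence,
                         make_locus(cfg)$sequence))
})

test_that("undersized layouts and bad probabilities are rejected", {
  expect_error(sim_config(intron_lengths = c(60, 200),
                          exon_lengths = c(100, 100, 100)), "80 nt")
  expect_error(sim_config(tract_p = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(variant_distances = c(90, 45)),
               "strictly increasing")
})

test_that("incorporation is nested and matches the geometric closed form", {
  cfg <- sim_config(seed = 34, n_reads = 10000, error_rate = 0,
                    tract_p = 0.995)
  sim <- simulate_reads(cfg)
  inc <- sim$truth$incorporation
  # nesting: every incorporation vector is a downward-closed prefix
  n_inc <- rowSums(inc)
  expect_true(all(inc[cbind(which(n_inc > 0), n_inc[n_inc > 0])]))
  expect_true(all(!inc[n_inc < ncol(inc), , drop = FALSE][
    cbind(seq_len(sum(n_inc < ncol(inc))), n_inc[n_inc < ncol(inc)] + 1)]))
  # per-read truth: L = 200 converts exactly the sites at 45, 90, 171
  r200 <- which(sim$truth$table$tract_length == 200)
  if (length(r200) > 0)
    expect_equal(unname(inc[r200[1], ]),
                 c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  # closed form: P(converted at 45) = 0.995^45 = 0.798
  expect_lt(abs(mean(inc[, "M45"]) - 0.995^45), 0.015)
})

test_that("the p -> 1 limit converts everything and wild-type fraction dilutes", {
  cfg <- sim_config(seed = 35, n_reads = 200, error_rate = 0,
                    tract_p = 1 - 1e-12)
  sim <- simulate_reads(cfg)
  expect_true(all(sim$truth$incorporation))

  cfg_wt <- sim_config(seed = 36, n_reads = 400, error_rate = 0,
                       non_hdr_fraction = 0.5)
  sim_wt <- simulate_reads(cfg_wt)
  expect_false(any(sim_wt$truth$incorporation[!sim_wt$truth$table$is_hdr, ]))
  expect_lt(abs(mean(sim_wt$truth$table$is_hdr) - 0.5), 0.1)
})

test_that("clone screens follow their true-positive probabilities", {
  expect_false(any(simulate_clone_experiment(
    sim_config(seed = 37, clone_p = c(ssDNA = 0)))$positive))
  expect_true(all(simulate_clone_experiment(
    sim_config(seed = 38, clone_p = c(ssDNA = 1)))$positive))
  # E[positives] = 24 x 21/24 = 21 at the default ssDNA rate
  tot <- sapply(1:2000, function(i) {
    tab <- simulate_clone_experiment(sim_config(seed = 10000 + i))
    sum(tab$positive[tab$donor_type == "ssDNA"])
  })
  expect_lt(abs(mean(tot) - 21), 0.2)
})

test_that("every intron of at least 150 nt admits a safe guide", {
  set.seed(40)
  for (i in 1:30) {
    cfg <- sim_config(seed = 2000 + i,
                      exon_lengths = sample(80:200, 3, replace = TRUE),
                      intron_lengths = sample(150:500, 2, replace = TRUE))
    locus <- make_locus(cfg)
    for (k in 1:2)
      expect_gt(nrow(enumerate_guides(locus, k)), 0)
  }
})

test_that("simulated experiments write a complete file bundle", {
  cfg <- sim_config(seed = 41, n_reads = 10, error_rate = 0)
  sim <- simulate_reads(cfg)
  dir <- file.path(tempdir(), "geis_sim_test")
  write_sim(sim, dir)
  expect_true(all(file.exists(file.path(dir,
    c("reads.fasta", "locus.fasta", "donor.fasta", "reference.fasta",
      "truth.tsv", "variants.tsv", "config.json")))))
  back <- Biostrings::readDNAStringSet(file.path(dir, "reads.fasta"))
  expect_equal(as.character(back), as.character(sim$reads),
               ignore_attr = TRUE)
  cfg_back <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(cfg_back$tract_p, cfg$tract_p)
})

test_that("simulate -> align -> call -> fit round trip recovers the truth", {
  cfg <- sim_config(seed = 42, n_reads = 150, error_rate = 0.001)
  sim <- simulate_reads(cfg)
  m <- build_matrix(sim$reads, sim$reference, sim$variants,
                    ref_start = sim$ref_start)
  expect_equal(m$qc$n_pass, 150L)
  # with a 0.001 error rate almost all calls still match the truth
  agree <- mean(m$calls == truth_matrix(sim)$calls)
  expect_gt(agree, 0.97)
  fit <- fit_tract_model(m)
  expect_true(fit$ci[1] <= cfg$tract_p && cfg$tract_p <= fit$ci[2])
})
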