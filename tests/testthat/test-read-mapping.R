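test_that("the k-mer index enumerates genome positions exactly", {
  cfg <- mapper_config(seed_kmer_length = 4L)
  idx <- build_index("ACGTACGT", cfg)
  expect_equal(lookup_kmer(idx, "ACGT"), c(1L, 5L))
  expect_equal(lookup_kmer(idx, "CGTA"), 2L)
  expect_equal(lookup_kmer(idx, "TTTT"), integer(0))

  cfg8 <- mapper_config(seed_kmer_length = 8L)
  idx8 <- build_index("ACGTACGT", cfg8)
  expect_equal(lookup_kmer(idx8, "ACGTACGT"), 1L)
  expect_error(build_index("ACG", mapper_config(seed_kmer_length = 5L)),
               "exceeds")
})

test_that("candidate enumeration equals the brute-force scan oracle", {
  genome <- random_genome(5000, seed = 42)
  cfg <- mapper_config(seed_kmer_length = 8L, max_mismatches = 2L)
  idx <- build_index(genome, cfg)
  set.seed(99)
  for (i in 1:40) {
    start <- sample(nchar(genome) - 29, 1)
    read <- substring(genome, start, start + 29)
    nmut <- sample(0:2, 1)
    if (nmut > 0) {
      at <- sample(30, nmut)
      for (j in at) {
        old <- substr(read, j, j)
        substr(read, j, j) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
    }
    if (runif(1) < 0.5) read <- revcomp(read)
    rec <- map_read(read, idx, cfg)
    oracle <- naive_candidates(genome, read, cfg$max_mismatches)
    got <- rec$candidate_sites[order(rec$candidate_sites$pos,
                                     rec$candidate_sites$strand), ]
    rownames(got) <- rownames(oracle) <- NULL
    expect_equal(got, oracle)
  }
})

test_that("the ambiguity policy assigns, discards and reports statuses", {
  set.seed(1)
  template <- random_genome(200, seed = 7)
  copies <- rep(template, 14)
  # carriers: 6 copies share an alternative base at one diagnostic column
  diag_at <- 100L
  alt <- if (substr(template, diag_at, diag_at) == "A") "C" else "A"
  for (i in 1:6) substr(copies[i], diag_at, diag_at) <- alt
  spacer <- random_genome(120, seed = 8)
  genome <- paste0(spacer,
                   paste(vapply(seq_along(copies), function(i)
                     paste0(copies[i], random_genome(60, seed = 100 + i)),
                     ""), collapse = ""),
                   random_genome(1500, seed = 9))
  cfg <- mapper_config(seed_kmer_length = 10L, max_mismatches = 1L)
  idx <- build_index(genome, cfg)

  # unique background read
  u <- map_read(substring(genome, nchar(genome) - 900, nchar(genome) - 866),
                idx, cfg)
  expect_equal(u$status, "unique")
  expect_equal(u$n_candidates, 1L)

  # interior family read: 14 identical sites > cap 10
  interior <- substring(template, 10, 44)
  rec <- map_read(interior, idx, cfg)
  expect_equal(rec$status, "discarded_too_ambiguous")
  expect_equal(rec$n_candidates, 14L)
  expect_null(rec$chosen_site)

  # read spanning the diagnostic column from a carrier: 6 candidates
  carrier_read <- substring(copies[1], diag_at - 17, diag_at + 17)
  rec6 <- map_read(carrier_read, idx, cfg)
  expect_equal(rec6$n_candidates, 6L)
  expect_equal(rec6$status, "ambiguous_assigned")

  # random placement is uniform across the tied sites
  many <- map_readset(rep(carrier_read, 10000), idx, cfg)
  freq <- table(many$pos)
  expect_equal(length(freq), 6)
  gof <- chisq.test(as.vector(freq))
  expect_gt(gof$p.value, 0.001)
})

test_that("reads shorter than the seed are unmapped with a reason", {
  idx <- build_index(random_genome(1000), mapper_config())
  rec <- map_read("ACGT", idx, mapper_config())
  expect_equal(rec$status, "unmapped")
  expect_match(rec$reason, "shorter")
})

test_that("read-set mapping conserves reads and is seed-deterministic", {
  cfg <- tiny_config(seed = 13, n_reads = 4000L)
  g <- generate_genome(cfg)
  tr <- ground_truth(g$genome, g$annotation, cfg)
  rs <- simulate_reads(g$genome, g$annotation, tr, "3dNH4", cfg)
  mcfg <- mapper_config(rng_seed = 77L)
  idx <- build_index(g$genome, mcfg)
  al1 <- map_readset(rs, idx, mcfg)
  al2 <- map_readset(rs, idx, mcfg)
  expect_identical(al1$pos, al2$pos)
  s <- mapping_summary(al1)
  expect_equal(sum(s[c("unmapped", "unique", "ambiguous_assigned",
                       "discarded_too_ambiguous")]),
               unname(s["total"]))
  expect_equal(unname(s["total"]), nrow(rs))
})

test_that("error-free unique reads are mapped back to their true features", {
  cfg <- tiny_config(seed = 17, n_reads = 5000L)
  g <- generate_genome(cfg)
  tr <- ground_truth(g$genome, g$annotation, cfg)
  rs <- simulate_reads(g$genome, g$annotation, tr, "3dN2", cfg)
  idx <- build_index(g$genome)
  al <- map_readset(rs, idx)
  cnt <- count_reads(al, g$annotation)
  truth_cnt <- table(factor(rs$feature, levels = g$annotation$locus_tag))
  uniq_frac <- mean(al$status == "unique")
  expect_gt(uniq_frac, 0.95)
  # every feature's mapped count matches the simulated origin count to
  # within the handful of reads lost to chance ambiguity
  expect_true(all(abs(cnt$count - as.vector(truth_cnt)) <=
                    sum(al$status != "unique")))
  agree <- al$status == "unique" &
    g$annotation$locus_tag[findInterval(
      ifelse(al$strand_ref == "+", al$pos, al$pos + nchar(al$seq) - 1L),
      g$annotation$start)] == rs$feature
  expect_gt(mean(agree[al$status == "unique"]), 0.999)
})

test_that("SAM export writes well-formed records for every read", {
  cfg <- tiny_config(seed = 19, n_reads = 300L)
  g <- generate_genome(cfg)
  tr <- ground_truth(g$genome, g$annotation, cfg)
  rs <- simulate_reads(g$genome, g$annotation, tr, "5dNH4", cfg)
  idx <- build_index(g$genome)
  al <- map_readset(rs, idx)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(al, sam)
  lines <- readLines(sam)
  expect_equal(sum(!startsWith(lines, "@")), nrow(al))
  body <- strsplit(lines[!startsWith(lines, "@")], "\t")
  flags <- vapply(body, function(x) as.integer(x[2]), 0L)
  expect_equal(sum(bitwAnd(flags, 4L) == 0),
               sum(al$status %in% c("unique", "ambiguous_assigned")))
})
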