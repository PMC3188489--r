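test_that("the pileup tallies every aligned base on the forward strand", {
  genome <- random_genome(2000, seed = 61)
  # one forward read of length 30: 30 columns of coverage 1
  r1 <- substring(genome, 101, 130)
  al <- fake_alignments(101L, "+", r1)
  p <- build_pileup(al, genome)
  expect_equal(nrow(p), 30)
  expect_equal(sort(p$pos), 101:130)
  expect_true(all(p$base == strsplit(r1, "")[[1]][order(p$pos)]))

  # reverse-strand reads contribute complemented bases at forward positions
  r2 <- revcomp(substring(genome, 501, 530))
  al2 <- fake_alignments(501L, "-", r2)
  p2 <- build_pileup(al2, genome)
  expect_equal(sort(p2$pos), 501:530)
  expect_true(all(p2$base[order(p2$pos)] ==
                    strsplit(substring(genome, 501, 530), "")[[1]]))
})

test_that("pileup equals a naive per-position tally on a small instance", {
  genome <- random_genome(2000, seed = 67)
  set.seed(68)
  n <- 120
  starts <- sample(1900, n)
  minus <- runif(n) < 0.5
  seqs <- substring(genome, starts, starts + 49)
  seqs[minus] <- revcomp(seqs[minus])
  al <- fake_alignments(starts, ifelse(minus, "-", "+"), seqs)
  p <- build_pileup(al, genome)
  expect_equal(nrow(p), n * 50)  # coverage conservation

  # brute-force tally: count read overlaps per position
  tally <- integer(2000)
  for (i in seq_len(n))
    tally[starts[i]:(starts[i] + 49)] <- tally[starts[i]:(starts[i] + 49)] + 1L
  cov <- table(p$pos)
  expect_equal(as.vector(cov), tally[as.integer(names(cov))])
  expect_equal(sum(tally), nrow(p))
  # error-free reads reproduce the reference at every column
  refs <- substring(genome, p$pos, p$pos)
  expect_true(all(p$base == refs))
})

test_that("the filter cascade enforces its boundary thresholds exactly", {
  # coverage 9, all variant, perfect qualities: criterion 3 rejects
  p9 <- pileup_column(100, "G", rep("A", 9), rep(30, 9), rep(30, 9))
  expect_equal(nrow(call_snps(p9)), 0)

  # coverage 10 with 2 variants (20 %): criterion 4 rejects
  p20 <- pileup_column(100, "G", c(rep("G", 8), "A", "A"), rep(30, 10),
                       rep(30, 10))
  expect_equal(nrow(call_snps(p20)), 0)

  # coverage 10 with 3 variants (30 %), qualities passing: accepted
  p30 <- pileup_column(100, "G", c(rep("G", 7), rep("A", 3)), rep(30, 10),
                       rep(30, 10))
  calls <- call_snps(p30)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$variant, "A")
  expect_equal(calls$variants, "G/A")
  expect_equal(calls$coverage, 10L)
  expect_equal(calls$variant_fraction, 0.3)

  # criterion 2: variant base quality must exceed 20 strictly
  pq <- pileup_column(100, "G", c(rep("G", 7), rep("A", 3)),
                      c(rep(30, 7), rep(20, 3)), rep(30, 10))
  expect_equal(nrow(call_snps(pq)), 0)
  pq21 <- pileup_column(100, "G", c(rep("G", 7), rep("A", 3)),
                        c(rep(30, 7), rep(21, 3)), rep(30, 10))
  expect_equal(nrow(call_snps(pq21)), 1)

  # criterion 1: observations from reads with mean quality < 15 are dropped
  pr <- pileup_column(100, "G", c(rep("G", 7), rep("A", 4)), rep(30, 11),
                      c(rep(30, 7), rep(30, 3), 14.9))
  r <- call_snps(pr)
  expect_equal(r$coverage, 10L)
  expect_equal(r$variant_fraction, 0.3)
  pr15 <- pileup_column(100, "G", c(rep("G", 6), rep("A", 4)), rep(30, 10),
                        c(rep(30, 6), rep(30, 3), 14.9))
  expect_equal(nrow(call_snps(pr15)), 0)  # coverage drops to 9
})

test_that("tightening any threshold never increases accepted calls", {
  set.seed(71)
  genome <- random_genome(500, seed = 71)
  rows <- list()
  for (pos in seq(10, 490, by = 10)) {
    cov <- sample(5:40, 1)
    nvar <- rbinom(1, cov, runif(1, 0.05, 0.8))
    ref <- substring(genome, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    rows[[length(rows) + 1L]] <- data.frame(
      pos = pos, base = c(rep(ref, cov - nvar), rep(alt, nvar)),
      base_qual = sample(10:40, cov, replace = TRUE),
      read_mean_qual = runif(cov, 5, 40),
      read_id = sprintf("p%d_%d", pos, seq_len(cov)),
      stringsAsFactors = FALSE)
  }
  p <- do.call(rbind, rows)
  attr(p, "reference") <- genome
  class(p) <- c("pileup", "data.frame")

  base_cfg <- snp_filter_config()
  n0 <- nrow(call_snps(p, base_cfg))
  tighter <- list(
    snp_filter_config(min_read_mean_quality = 25),
    snp_filter_config(min_base_quality = 30),
    snp_filter_config(min_coverage = 20),
    snp_filter_config(min_variant_fraction = 0.5))
  for (cfg in tighter)
    expect_lte(nrow(call_snps(p, cfg)), n0)
})

test_that("spiked variants are recovered through the full pipeline", {
  cfg <- tiny_config(seed = 73, genome_length = 20000L, n_orfs = 8L,
                     n_rrna_trna = 0L, rrna_read_fraction = 0,
                     n_reads = 30000L)
  g <- generate_genome(cfg)
  # spike the two most expressed ORFs so the coverage precondition holds
  shares <- ground_truth(g$genome, g$annotation, cfg)$shares[, "3dNH4"]
  loci <- names(sort(shares, decreasing = TRUE))[1:2]
  spikes <- data.frame(locus_tag = loci, orf_position = c(120L, 240L),
                       alt_base = "N", allele_fraction = 0.5,
                       stringsAsFactors = FALSE)
  # choose valid alternative bases on each ORF's coding strand
  for (i in seq_len(nrow(spikes))) {
    row <- g$annotation[g$annotation$locus_tag == spikes$locus_tag[i], ]
    pos <- if (row$strand == "+") row$start + spikes$orf_position[i] - 1L
           else row$end - spikes$orf_position[i] + 1L
    ref <- substring(g$genome, pos, pos)
    alt_fwd <- if (ref == "C") "T" else "C"
    spikes$alt_base[i] <- if (row$strand == "+") alt_fwd
                          else revcomp(alt_fwd)
  }
  cfg$snp_spikes <- spikes
  tr <- ground_truth(g$genome, g$annotation, cfg)
  rs <- simulate_reads(g$genome, g$annotation, tr, "3dNH4", cfg)
  al <- map_readset(rs, build_index(g$genome))
  p <- build_pileup(al, g$genome)
  calls <- call_snps(p)
  # perfect recall at high coverage, no false calls on error-free reads
  expect_setequal(calls$genome_pos, tr$spikes$genome_pos)
  expect_true(all(calls$coverage >= 50))
  expect_true(all(abs(calls$variant_fraction - 0.5) < 0.15))
})

test_that("codon effects are annotated strand-aware", {
  # forward ORF: ATG GAA CGG = Met Glu Arg
  coding <- "ATGGAACGG"
  genome_f <- paste0(strrep("T", 10), coding, strrep("T", 10))
  ann_f <- data.frame(locus_tag = "F1", start = 11L, end = 19L,
                      strand = "+", rna_class = "mRNA",
                      functional_class = "other", annotation = "x",
                      is_family = NA, paralog_group = NA,
                      stringsAsFactors = FALSE)
  call_f <- data.frame(genome_pos = 14L, reference = "G", variant = "A",
                       variants = "G/A", coverage = 20L,
                       variant_fraction = 0.5, stringsAsFactors = FALSE)
  out_f <- annotate_effect(call_f, ann_f, genome_f)
  expect_equal(out_f$orf_position, 4L)
  expect_equal(out_f$effect, "non-synonymous")
  expect_equal(out_f$aa_change, "Glu -> Lys")

  # the same ORF on the reverse strand
  genome_r <- paste0(strrep("T", 10), revcomp(coding), strrep("T", 10))
  ann_r <- ann_f
  ann_r$strand <- "-"
  ann_r$locus_tag <- "R1"
  # coding position 4 (G of GAA) sits at forward position end - 4 + 1 = 16,
  # where the forward reference is the complement C; coding G>A is forward C>T
  call_r <- data.frame(genome_pos = 16L, reference = "C", variant = "T",
                       variants = "C/T", coverage = 20L,
                       variant_fraction = 0.5, stringsAsFactors = FALSE)
  out_r <- annotate_effect(call_r, ann_r, genome_r)
  expect_equal(out_r$orf_position, 4L)
  expect_equal(out_r$aa_change, "Glu -> Lys")

  # third-position wobble: CGG -> CGA stays Arg
  call_w <- data.frame(genome_pos = 19L, reference = "G", variant = "A",
                       variants = "G/A", coverage = 20L,
                       variant_fraction = 0.5, stringsAsFactors = FALSE)
  out_w <- annotate_effect(call_w, ann_f, genome_f)
  expect_equal(out_w$effect, "synonymous")
  expect_equal(out_w$aa_change, "-")

  # a position outside every ORF is non-coding
  call_o <- data.frame(genome_pos = 2L, reference = "T", variant = "A",
                       variants = "T/A", coverage = 20L,
                       variant_fraction = 0.5, stringsAsFactors = FALSE)
  expect_equal(annotate_effect(call_o, ann_f, genome_f)$effect, "non-coding")
})

test_that("mutating the genome reverses non-synonymous annotations", {
  ctx <- snp_context_orfs()
  out <- annotate_effect(ctx$calls, ctx$annotation, ctx$genome)
  nonsyn <- out[out$effect == "non-synonymous", ]
  for (i in seq_len(nrow(nonsyn))) {
    g2 <- ctx$genome
    substr(g2, nonsyn$genome_pos[i], nonsyn$genome_pos[i]) <-
      nonsyn$variant[i]
    back <- nonsyn[i, c("genome_pos", "variant", "reference", "variants",
                        "coverage", "variant_fraction")]
    names(back)[2:3] <- c("reference", "variant")
    out2 <- annotate_effect(back, ctx$annotation, g2)
    parts <- strsplit(nonsyn$aa_change[i], " -> ", fixed = TRUE)[[1]]
    expect_equal(out2$aa_change, paste(parts[2], "->", parts[1]))
  }
})

test_that("sample intersection is order-independent and associative", {
  mk <- function(pos) {
    data.frame(genome_pos = pos, reference = "G", variant = "A",
               variants = "G/A", coverage = 20L, variant_fraction = 0.5,
               stringsAsFactors = FALSE)
  }
  a <- mk(c(10L, 20L, 30L, 40L))
  b <- mk(c(20L, 30L, 50L))
  c3 <- mk(c(30L, 20L, 70L))
  i1 <- intersect_samples(a, b, c3)
  expect_equal(i1$genome_pos, c(20L, 30L))
  i2 <- intersect_samples(c3, a, b)
  expect_equal(i1$genome_pos, i2$genome_pos)
  nested <- intersect_samples(intersect_samples(a, b), c3)
  expect_equal(nested$genome_pos, i1$genome_pos)

  expect_equal(nrow(intersect_samples(mk(1:3 * 10L), mk(4:6 * 10L))), 0)
  same <- intersect_samples(a, a)
  expect_equal(same$genome_pos, a$genome_pos)

  # variant sets union across samples
  b2 <- b
  b2$variant[b2$genome_pos == 20] <- "T"
  b2$variants[b2$genome_pos == 20] <- "G/T"
  u <- intersect_samples(a, b2)
  expect_equal(u$variants[u$genome_pos == 20], "G/A/T")
})

test_that("VCF export writes one record per accepted call", {
  p30 <- pileup_column(100, "G", c(rep("G", 7), rep("A", 3)), rep(30, 10),
                       rep(30, 10))
  calls <- call_snps(p30)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_snp_vcf(calls, vcf, genome_length = 1000L)
  lines <- readLines(vcf)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 1)
  expect_match(body, "^chr\t100\t\\.\tG\tA\t.*DP=10;AF=0\\.3000")
})
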