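test_that("genome generation is deterministic under the seed", {
  cfg <- tiny_config(seed = 11)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$annotation, g2$annotation)

  g3 <- generate_genome(tiny_config(seed = 12))
  expect_false(identical(g1$genome, g3$genome))

  tr <- ground_truth(g1$genome, g1$annotation, cfg)
  r1 <- simulate_reads(g1$genome, g1$annotation, tr, "3dNH4", cfg)
  r2 <- simulate_reads(g1$genome, g1$annotation, tr, "3dNH4", cfg)
  expect_identical(r1, r2)
})

test_that("paralog families are planted with the requested structure", {
  fam <- paralog_family(14, 1.0, "IS4", orf_length = 600L,
                        n_diagnostic_sites = 2L, n_carriers = 6L)
  cfg <- tiny_config(seed = 3, genome_length = 40000L, n_orfs = 5L,
                     paralog_families = list(fam))
  g <- generate_genome(cfg)
  ann <- g$annotation
  copies <- ann[!is.na(ann$paralog_group) & ann$paralog_group != "", ]
  copies <- copies[grepl("IS4", copies$paralog_group), ]
  expect_equal(nrow(copies), 14)
  seqs <- substring(g$genome, copies$start, copies$end)
  mat <- do.call(rbind, strsplit(seqs, ""))
  n_diff <- sum(apply(mat, 2, function(col) length(unique(col)) > 1))
  expect_equal(n_diff, 2)
  # each diagnostic column splits the family 6 vs 8
  diff_cols <- which(apply(mat, 2, function(col) length(unique(col)) > 1))
  for (j in diff_cols)
    expect_setequal(as.vector(table(mat[, j])), c(6, 8))
})

test_that("an empty feature request yields a bare random genome", {
  cfg <- tiny_config(n_orfs = 0L, n_rrna_trna = 0L)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$annotation), 0)
  expect_equal(nchar(g$genome), cfg$genome_length)
})

test_that("oversized feature requests raise a sizing error", {
  cfg <- tiny_config(genome_length = 5000L, n_orfs = 50L)
  expect_error(generate_genome(cfg), "capacity")
})

test_that("rRNA/tRNA read carry-over matches the configured fraction", {
  cfg <- tiny_config(seed = 5, n_reads = 100000L,
                     rrna_read_fraction = c(0.8, 0.8, 0.51))
  g <- generate_genome(cfg)
  tr <- ground_truth(g$genome, g$annotation, cfg)
  rs <- simulate_reads(g$genome, g$annotation, tr, "3dNH4", cfg)
  nc_loci <- g$annotation$locus_tag[g$annotation$rna_class %in%
                                      c("rRNA", "tRNA")]
  x <- sum(rs$feature %in% nc_loci)
  # exact binomial oracle: central 99.99 % interval around n * p
  bounds <- qbinom(c(5e-5, 1 - 5e-5), 1e5, 0.8)
  expect_gte(x, bounds[1])
  expect_lte(x, bounds[2])
})

test_that("per-feature read counts follow the multinomial expectation", {
  cfg <- tiny_config(seed = 8, genome_length = 80000L, n_orfs = 60L,
                     n_reads = 100000L)
  g <- generate_genome(cfg)
  tr <- ground_truth(g$genome, g$annotation, cfg)
  rs <- simulate_reads(g$genome, g$annotation, tr, "3dN2", cfg)
  shares <- tr$shares[, "3dN2"]
  obs <- table(factor(rs$feature, levels = names(shares)))
  expect_gte(length(shares), 50)
  gof <- suppressWarnings(
    chisq.test(as.vector(obs), p = shares, rescale.p = TRUE))
  expect_gt(gof$p.value, 0.001)
})

test_that("spiked variants are emitted at the configured allele fraction", {
  spikes <- data.frame(locus_tag = "SYN_0003", orf_position = 150L,
                       alt_base = "A", allele_fraction = 1.0,
                       stringsAsFactors = FALSE)
  cfg <- tiny_config(seed = 21, genome_length = 20000L, n_orfs = 8L,
                     n_rrna_trna = 0L, rrna_read_fraction = 0,
                     n_reads = 40000L, snp_spikes = spikes)
  g <- generate_genome(cfg)
  # ensure the spiked alternative differs from the reference
  row <- g$annotation[g$annotation$locus_tag == "SYN_0003", ]
  pos <- if (row$strand == "+") row$start + 149L else row$end - 149L
  ref_fwd <- substring(g$genome, pos, pos)
  alt_cod <- if (ref_fwd == "A") "C" else "A"
  cfg$snp_spikes$alt_base <- if (row$strand == "+") alt_cod
                             else revcomp(alt_cod)
  tr <- ground_truth(g$genome, g$annotation, cfg)
  expect_equal(nrow(tr$spikes), 1)
  p <- tr$spikes$genome_pos[1]

  rs <- simulate_reads(g$genome, g$annotation, tr, "3dNH4", cfg)
  rl <- attr(rs, "read_length")
  cover <- rs$start <= p & rs$start + rl - 1L >= p
  fwd_seq <- ifelse(rs$strand == "-", revcomp(rs$seq), rs$seq)
  base_at <- substr(fwd_seq[cover], p - rs$start[cover] + 1L,
                    p - rs$start[cover] + 1L)
  # allele fraction 1: every overlapping read carries the alternative
  expect_gt(sum(cover), 0)
  expect_true(all(base_at == tr$spikes$alt[1]))

  # allele fraction 0.5 recovered within 5 percentage points at >= 200x
  cfg$snp_spikes$allele_fraction <- 0.5
  tr2 <- ground_truth(g$genome, g$annotation, cfg)
  rs2 <- simulate_reads(g$genome, g$annotation, tr2, "3dNH4", cfg)
  cover2 <- rs2$start <= p & rs2$start + rl - 1L >= p
  fwd2 <- ifelse(rs2$strand == "-", revcomp(rs2$seq), rs2$seq)
  base2 <- substr(fwd2[cover2], p - rs2$start[cover2] + 1L,
                  p - rs2$start[cover2] + 1L)
  expect_gte(sum(cover2), 200)
  af <- mean(base2 == tr2$spikes$alt[1])
  expect_lt(abs(af - 0.5), 0.05)
})

test_that("truth tables round-trip through TSV and stay normalised", {
  cfg <- tiny_config(seed = 2)
  g <- generate_genome(cfg)
  tr <- ground_truth(g$genome, g$annotation, cfg)
  dir <- withr::local_tempdir()
  write_truth_tables(tr, dir)
  back <- read_truth_tables(dir)
  expect_equal(back$shares, tr$shares, tolerance = 1e-9)
  expect_true(all(abs(colSums(back$shares) - 1) < 1e-9))
  expect_equal(nrow(back$spikes), 0)  # header-only variant file
})

test_that("zero requested reads yields an empty FASTQ with a warning", {
  cfg <- tiny_config(seed = 2, n_reads = 0L)
  g <- generate_genome(cfg)
  tr <- ground_truth(g$genome, g$annotation, cfg)
  expect_warning(rs <- simulate_reads(g$genome, g$annotation, tr,
                                      "3dNH4", cfg), "zero")
  expect_equal(nrow(rs), 0)
})

test_that("FASTA and FASTQ output round-trips", {
  cfg <- tiny_config(seed = 9, n_reads = 200L)
  g <- generate_genome(cfg)
  tr <- ground_truth(g$genome, g$annotation, cfg)
  rs <- simulate_reads(g$genome, g$annotation, tr, "5dNH4", cfg)
  fa <- withr::local_tempfile(fileext = ".fasta")
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_genome_fasta(g$genome, fa)
  write_reads_fastq(rs, fq)
  expect_identical(unname(read_genome_fasta(fa)), g$genome)
  back <- read_reads_fastq(fq)
  expect_identical(back$seq, rs$seq)
  expect_identical(back$qual, rs$qual)
})
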