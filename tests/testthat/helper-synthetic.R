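# Shared builders and independent oracles for the test suite.

# small, fast simulation: no paralog families unless asked for
tiny_config <- function(seed = 1, genome_length = 30000L, n_orfs = 15L,
                        n_rrna_trna = 2L, n_reads = 5000L,
                        read_length = c(50L, 50L, 35L),
                        rrna_read_fraction = c(0.5, 0.5, 0.3),
                        paralog_families = list(), ...) {
  simulation_config(seed = seed, genome_length = genome_length,
                    n_orfs = n_orfs, n_rrna_trna = n_rrna_trna,
                    n_reads = n_reads, read_length = read_length,
                    rrna_read_fraction = rrna_read_fraction,
                    paralog_families = paralog_families, ...)
}

random_genome <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# exhaustive best-tier candidate enumeration: the brute-force oracle the
# seed-and-extend mapper must reproduce on small genomes
naive_candidates <- function(genome, read, max_mm) {
  L <- nchar(genome)
  len <- nchar(read)
  gch <- strsplit(genome, "")[[1]]
  hits <- data.frame(pos = integer(0), strand = character(0),
                     mismatches = integer(0))
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else revcomp(read)
    qch <- strsplit(q, "")[[1]]
    for (p in seq_len(L - len + 1)) {
      d <- sum(gch[p:(p + len - 1)] != qch)
      if (d <= max_mm)
        hits <- rbind(hits, data.frame(pos = p, strand = strand,
                                       mismatches = d))
    }
  }
  if (nrow(hits) == 0) return(hits)
  hits <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
  hits[order(hits$pos, hits$strand), , drop = FALSE]
}

# hand-built pileup column for exact filter-boundary checks
pileup_column <- function(pos, ref, bases, base_quals, read_means,
                          genome_length = 1000L) {
  genome <- strrep(ref, genome_length)
  out <- data.frame(pos = rep(as.integer(pos), length(bases)),
                    base = bases, base_qual = as.integer(base_quals),
                    read_mean_qual = read_means,
                    read_id = sprintf("r%03d", seq_along(bases)),
                    stringsAsFactors = FALSE)
  attr(out, "reference") <- genome
  class(out) <- c("pileup", "data.frame")
  out
}

# expression table straight from a count vector (bypasses mapping)
table_from_counts <- function(counts, lengths, sample = "s",
                              classes = NULL, annotations = NULL,
                              exclude_ncrna = TRUE) {
  n <- length(counts)
  if (is.null(classes)) classes <- rep("other", n)
  if (is.null(annotations)) annotations <- classes
  starts <- cumsum(c(1L, head(lengths + 10L, -1)))
  ann <- data.frame(locus_tag = sprintf("G%04d", seq_len(n)),
                    start = starts, end = starts + lengths - 1L,
                    strand = "+", rna_class = rep("mRNA", n),
                    functional_class = classes, annotation = annotations,
                    is_family = NA_character_,
                    paralog_group = NA_character_,
                    stringsAsFactors = FALSE)
  cnt <- data.frame(locus_tag = ann$locus_tag, count = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(cnt, "intergenic") <- 0L
  attr(cnt, "total_assigned") <- sum(counts)
  compute_rpkm(cnt, ann, sample = sample, exclude_ncrna = exclude_ncrna)
}

# alignments data frame shaped like a map_readset() result
fake_alignments <- function(pos, strand, seq, qual = NULL,
                            status = "unique") {
  n <- length(pos)
  if (is.null(qual)) qual <- strrep("?", nchar(seq))  # Q30
  data.frame(read_id = sprintf("fr%04d", seq_len(n)), seq = seq,
             qual = qual, pos = as.integer(pos), strand_ref = strand,
             mismatches = 0L, n_candidates = 1L,
             status = rep_len(status, n), stringsAsFactors = FALSE)
}
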