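#' Paralog family specification
#'
#' Describes one family of near-identical insertion-sequence (IS) paralogs to
#' be planted in the synthetic genome. Copies are derived from a single random
#' template. With `identity < 1` each copy is mutated independently at rate
#' `(1 - identity) / 2` so that the expected pairwise identity between copies
#' is `identity`. With `identity = 1` and `n_diagnostic_sites > 0`, all copies
#' are identical except at the requested number of engineered diagnostic
#' columns, where the first `n_carriers` copies share an alternative base.
#' This emulates the dominant ambiguity structure of repeat-laden
#' actinobacterial genomes, where a 14-copy IS4 family at ~99 % nucleotide
#' identity is distinguishable only at isolated columns.
#'
#' @param size number of copies (>= 2).
#' @param identity expected pairwise nucleotide identity, in `[0.9, 1]`.
#' @param label IS family label (stored in the annotation).
#' @param orf_length copy length in nt, a multiple of 3.
#' @param n_diagnostic_sites engineered discriminating columns (identity = 1
#'   families only).
#' @param n_carriers number of copies carrying the alternative base at each
#'   diagnostic column.
#' @return a `paralog_family` list.
#' @export
paralog_family <- function(size, identity = 1, label = "IS4",
                           orf_length = 900L, n_diagnostic_sites = 0L,
                           n_carriers = 0L) {
  stopifnot(size >= 2, orf_length %% 3 == 0)
  if (identity < 0.9 || identity > 1)
    stop("paralog identity must lie in [0.9, 1]")
  if (n_diagnostic_sites > 0 && identity < 1)
    stop("diagnostic sites are only defined for identity = 1 families")
  if (n_diagnostic_sites > 0 && (n_carriers < 1 || n_carriers >= size))
    stop("n_carriers must be in [1, size) when diagnostic sites are used")
  structure(list(size = as.integer(size), identity = identity, label = label,
                 orf_length = as.integer(orf_length),
                 n_diagnostic_sites = as.integer(n_diagnostic_sites),
                 n_carriers = as.integer(n_carriers)),
            class = "paralog_family")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic transcriptome generator. The defaults
#' emulate, at desk scale, the study conditions of a repeat-laden
#' actinobacterial culture experiment: three culture conditions (`3dNH4`,
#' `3dN2`, `5dNH4`), 76 nt reads for the three-day samples versus 35 nt for
#' the five-day sample, heavy rRNA/tRNA carry-over (80 % of reads in the
#' three-day samples, 51 % in the five-day sample), a 14-copy identical IS4
#' paralog family with two diagnostic columns carried by six copies, and a
#' six-copy IS66 family at 99 % identity. Reads are error-free by default
#' (`error_rate = 0`) with constant Phred quality `base_quality`; a fraction
#' of deliberately low-quality reads can be requested to exercise the SNP
#' read-quality filter.
#'
#' @param seed integer seed governing every random draw of the generator.
#' @param genome_length genome size in nt.
#' @param n_orfs number of single-copy mRNA ORFs (paralog family members are
#'   added on top).
#' @param n_rrna_trna number of rRNA/tRNA features.
#' @param conditions condition labels.
#' @param read_length per-condition read length (nt), recycled if scalar.
#' @param n_reads per-condition read count, recycled if scalar.
#' @param rrna_read_fraction per-condition fraction of reads originating from
#'   rRNA/tRNA, in `[0, 1]`.
#' @param paralog_families list of [paralog_family()] specifications.
#' @param orf_length_range range of single-copy ORF lengths (rounded to
#'   multiples of 3).
#' @param gc genome G+C fraction (actinobacterial default 0.71).
#' @param condition_effects named list mapping a functional class to a named
#'   vector of per-condition expression multipliers.
#' @param snp_spikes data frame with columns `locus_tag`, `orf_position`
#'   (1-based on the coding strand), `alt_base` (coding strand) and
#'   `allele_fraction` in `(0, 1]`.
#' @param deletion_windows data frame of 1-based inclusive genome intervals
#'   (`start`, `end`) used by the enrichment analysis.
#' @param error_rate per-base sequencing substitution rate.
#' @param base_quality constant Phred quality assigned to simulated bases.
#' @param low_quality_read_fraction fraction of reads assigned
#'   `low_quality_value` at every base.
#' @param low_quality_value Phred value for low-quality reads.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 200000L,
                              n_orfs = 120L,
                              n_rrna_trna = 6L,
                              conditions = c("3dNH4", "3dN2", "5dNH4"),
                              read_length = c(76L, 76L, 35L),
                              n_reads = c(100000L, 100000L, 100000L),
                              rrna_read_fraction = c(0.80, 0.80, 0.51),
                              paralog_families = list(
                                paralog_family(14, 1.0, "IS4",
                                               n_diagnostic_sites = 2L,
                                               n_carriers = 6L),
                                paralog_family(6, 0.99, "IS66")),
                              orf_length_range = c(300L, 1500L),
                              gc = 0.71,
                              condition_effects = list(
                                transposase = c("3dNH4" = 1.00,
                                                "3dN2" = 1.35,
                                                "5dNH4" = 1.30),
                                nif = c("3dNH4" = 1.00, "3dN2" = 2.50,
                                        "5dNH4" = 1.60)),
                              snp_spikes = NULL,
                              deletion_windows = NULL,
                              error_rate = 0,
                              base_quality = 30L,
                              low_quality_read_fraction = 0,
                              low_quality_value = 8L) {
  nc <- length(conditions)
  expand <- function(x) {
    if (length(x) == 1L) x <- rep(x, nc)
    stopifnot(length(x) == nc)
    setNames(x, conditions)
  }
  read_length <- expand(read_length)
  n_reads <- expand(n_reads)
  rrna_read_fraction <- expand(rrna_read_fraction)
  if (any(rrna_read_fraction < 0 | rrna_read_fraction > 1))
    stop("rrna_read_fraction must lie in [0, 1]")
  if (!is.null(snp_spikes)) {
    stopifnot(all(c("locus_tag", "orf_position", "alt_base",
                    "allele_fraction") %in% names(snp_spikes)))
    if (any(snp_spikes$allele_fraction <= 0 | snp_spikes$allele_fraction > 1))
      stop("allele fractions must lie in (0, 1]")
  }
  if (!is.null(deletion_windows)) {
    stopifnot(all(c("start", "end") %in% names(deletion_windows)))
    if (any(deletion_windows$start < 1 |
            deletion_windows$end > genome_length |
            deletion_windows$start > deletion_windows$end))
      stop("deletion windows must be valid intervals within the genome")
  }
  for (fam in paralog_families) stopifnot(inherits(fam, "paralog_family"))
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 n_orfs = as.integer(n_orfs),
                 n_rrna_trna = as.integer(n_rrna_trna),
                 conditions = conditions, read_length = read_length,
                 n_reads = n_reads, rrna_read_fraction = rrna_read_fraction,
                 paralog_families = paralog_families,
                 orf_length_range = as.integer(orf_length_range), gc = gc,
                 condition_effects = condition_effects,
                 snp_spikes = snp_spikes,
                 deletion_windows = deletion_windows,
                 error_rate = error_rate,
                 base_quality = as.integer(base_quality),
                 low_quality_read_fraction = low_quality_read_fraction,
                 low_quality_value = as.integer(low_quality_value)),
            class = "simulation_config")
}

.random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  at <- sample.int(n, k)
  for (i in at) {
    old <- substr(seq, i, i)
    substr(seq, i, i) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  seq
}

.other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
}

#' Generate a synthetic genome and annotation
#'
#' Lays out rRNA/tRNA features, single-copy mRNA ORFs and the requested
#' paralog families at shuffled positions with random intergenic gaps on a
#' random background of the configured G+C content. Features never overlap,
#' mRNA ORF lengths are multiples of 3, and the output is byte-deterministic
#' under `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `genome` (character scalar) and `annotation`, a data
#'   frame with columns `locus_tag`, `start`, `end`, `strand`, `rna_class`,
#'   `functional_class`, `annotation`, `is_family`, `paralog_group`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)

  feats <- list()
  add <- function(len, rna_class, functional_class, annotation,
                  is_family = NA_character_, paralog_group = NA_character_,
                  seq = NA_character_, strand = NA_character_) {
    feats[[length(feats) + 1L]] <<- list(len = as.integer(len),
                                         rna_class = rna_class,
                                         functional_class = functional_class,
                                         annotation = annotation,
                                         is_family = is_family,
                                         paralog_group = paralog_group,
                                         seq = seq, strand = strand)
  }

  if (config$n_rrna_trna > 0) {
    n_r <- ceiling(config$n_rrna_trna / 2)
    for (i in seq_len(n_r))
      add(1500L, "rRNA", "other", "ribosomal RNA")
    for (i in seq_len(config$n_rrna_trna - n_r))
      add(80L, "tRNA", "other", "transfer RNA")
  }

  class_pool <- c(hypothetical = 0.30, transposase = 0.04, pseudogene = 0.02,
                  phage = 0.03, CRISPR_associated = 0.02, nif = 0.03,
                  other = 0.56)
  annot_text <- c(hypothetical = "hypothetical protein",
                  transposase = "transposase, IS630",
                  pseudogene = "pseudogene",
                  phage = "phage integrase",
                  CRISPR_associated = "CRISPR-associated protein",
                  nif = "nitrogenase component",
                  other = "ABC transporter")
  if (config$n_orfs > 0) {
    lens <- sample(seq(config$orf_length_range[1], config$orf_length_range[2],
                       by = 3L), config$n_orfs, replace = TRUE)
    cls <- sample(names(class_pool), config$n_orfs, replace = TRUE,
                  prob = class_pool)
    for (i in seq_len(config$n_orfs))
      add(lens[i], "mRNA", cls[i], annot_text[[cls[i]]])
  }

  for (fi in seq_along(config$paralog_families)) {
    fam <- config$paralog_families[[fi]]
    template <- .random_dna(fam$orf_length, config$gc)
    diag_sites <- integer(0)
    diag_alt <- character(0)
    if (fam$n_diagnostic_sites > 0) {
      diag_sites <- round(seq_len(fam$n_diagnostic_sites) /
                            (fam$n_diagnostic_sites + 1) * fam$orf_length)
      diag_alt <- .other_base(vapply(diag_sites, function(p)
        substr(template, p, p), ""))
    }
    group <- paste0(fam$label, "_fam", fi)
    for (ci in seq_len(fam$size)) {
      s <- template
      if (fam$identity < 1) s <- .mutate_seq(s, (1 - fam$identity) / 2)
      if (length(diag_sites) && ci <= fam$n_carriers)
        for (j in seq_along(diag_sites))
          substr(s, diag_sites[j], diag_sites[j]) <- diag_alt[j]
      add(fam$orf_length, "mRNA", "transposase",
          paste0("transposase, ", fam$label),
          is_family = fam$label, paralog_group = group, seq = s,
          strand = "+")
    }
  }

  nf <- length(feats)
  if (nf == 0) {
    genome <- .random_dna(config$genome_length, config$gc)
    ann <- data.frame(locus_tag = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      rna_class = character(0), functional_class = character(0),
                      annotation = character(0), is_family = character(0),
                      paralog_group = character(0), stringsAsFactors = FALSE)
    return(list(genome = genome, annotation = ann))
  }

  lens <- vapply(feats, `[[`, 0L, "len")
  slack <- config$genome_length - sum(lens)
  if (slack < nf + 1)
    stop("requested features exceed genome capacity: need at least ",
         sum(lens) + nf + 1, " nt, have ", config$genome_length)

  ord <- sample.int(nf)
  feats <- feats[ord]
  lens <- lens[ord]
  gaps <- as.vector(rmultinom(1, slack - (nf + 1L), rep(1, nf + 1L))) + 1L
  starts <- integer(nf)
  pos <- 1L
  for (i in seq_len(nf)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + lens[i]
  }

  genome <- .random_dna(config$genome_length, config$gc)
  strands <- vapply(feats, function(f)
    if (is.na(f$strand)) sample(c("+", "-"), 1) else f$strand, "")
  for (i in seq_len(nf)) {
    s <- feats[[i]]$seq
    if (is.na(s)) s <- .random_dna(lens[i], config$gc)
    substr(genome, starts[i], starts[i] + lens[i] - 1L) <- s
  }

  ann <- data.frame(
    locus_tag = sprintf("SYN_%04d", seq_len(nf)),
    start = starts,
    end = starts + lens - 1L,
    strand = strands,
    rna_class = vapply(feats, `[[`, "", "rna_class"),
    functional_class = vapply(feats, `[[`, "", "functional_class"),
    annotation = vapply(feats, `[[`, "", "annotation"),
    is_family = vapply(feats, `[[`, "", "is_family"),
    paralog_group = vapply(feats, `[[`, "", "paralog_group"),
    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(ann$locus_tag), all(ann$end <= config$genome_length))
  list(genome = genome, annotation = ann)
}

#' Ground-truth expression shares and spiked variants
#'
#' Draws per-feature expression weights (log-normal, with per-condition
#' multipliers for configured functional classes) and converts them into
#' per-condition expected read shares. rRNA/tRNA features jointly receive
#' `rrna_read_fraction` of the reads; coding features split the remainder in
#' proportion to weight times length (a fragmenting library yields reads in
#' proportion to molar abundance times transcript length, so the per-gene
#' weight is what RPKM estimates). Configured SNP spikes are resolved to
#' genome coordinates with strand-aware alternative bases.
#'
#' @param genome genome string from [generate_genome()].
#' @param annotation annotation data frame from [generate_genome()].
#' @param config a [simulation_config()].
#' @return a `ground_truth` list with `shares` (features x conditions matrix,
#'   columns summing to 1), `weights` (same shape), and `spikes` (data frame
#'   with `genome_pos`, `ref`, `alt`, `allele_fraction`, `locus_tag`,
#'   `orf_position`).
#' @export
ground_truth <- function(genome, annotation, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  nf <- nrow(annotation)
  conds <- config$conditions
  weights <- matrix(rlnorm(nf, 0, 1), nf, length(conds),
                    dimnames = list(annotation$locus_tag, conds))
  for (cls in names(config$condition_effects)) {
    mult <- config$condition_effects[[cls]]
    rows <- annotation$functional_class == cls
    for (cond in intersect(conds, names(mult)))
      weights[rows, cond] <- weights[rows, cond] * mult[[cond]]
  }
  shares <- matrix(0, nf, length(conds),
                   dimnames = list(annotation$locus_tag, conds))
  is_nc <- annotation$rna_class %in% c("rRNA", "tRNA")
  len <- annotation$end - annotation$start + 1
  for (cond in conds) {
    frac <- config$rrna_read_fraction[[cond]]
    w <- weights[, cond] * len
    if (any(is_nc)) {
      shares[is_nc, cond] <- frac * w[is_nc] / sum(w[is_nc])
    } else {
      frac <- 0
    }
    if (any(!is_nc))
      shares[!is_nc, cond] <- (1 - frac) * w[!is_nc] / sum(w[!is_nc])
  }
  stopifnot(all(abs(colSums(shares) - 1) < 1e-9))

  spikes <- data.frame(genome_pos = integer(0), ref = character(0),
                       alt = character(0), allele_fraction = numeric(0),
                       locus_tag = character(0), orf_position = integer(0),
                       stringsAsFactors = FALSE)
  if (!is.null(config$snp_spikes) && nrow(config$snp_spikes) > 0) {
    sp <- config$snp_spikes
    idx <- match(sp$locus_tag, annotation$locus_tag)
    if (anyNA(idx)) stop("snp_spikes reference unknown locus tags")
    strand <- annotation$strand[idx]
    pos <- ifelse(strand == "+",
                  annotation$start[idx] + sp$orf_position - 1L,
                  annotation$end[idx] - sp$orf_position + 1L)
    alt_fwd <- ifelse(strand == "+", sp$alt_base, .revcomp_chr(sp$alt_base))
    ref <- substring(genome, pos, pos)
    if (any(ref == alt_fwd))
      stop("spiked alternative base equals the reference base")
    spikes <- data.frame(genome_pos = as.integer(pos), ref = ref,
                         alt = alt_fwd,
                         allele_fraction = sp$allele_fraction,
                         locus_tag = sp$locus_tag,
                         orf_position = as.integer(sp$orf_position),
                         stringsAsFactors = FALSE)
  }
  structure(list(shares = shares, weights = weights, spikes = spikes),
            class = "ground_truth")
}

#' Simulate a single-end read set for one condition
#'
#' Feature read counts are multinomial with the ground-truth expected shares;
#' start positions are uniform within the feature; strand is random (the
#' library is unstranded); spiked variant positions emit the alternative base
#' with probability equal to the allele fraction; optional uniform
#' substitution errors and per-read quality classes are applied last.
#'
#' @param genome,annotation output of [generate_genome()].
#' @param truth a [ground_truth()] object.
#' @param condition condition label.
#' @param config the [simulation_config()].
#' @param seed RNG seed; defaults to `config$seed` so that two conditions
#'   with identical shares and sizes produce identical read sets.
#' @return a `read_set` data frame with columns `read_id`, `seq`, `qual`,
#'   `feature`, `start`, `strand` and attributes `condition`, `read_length`.
#' @export
simulate_reads <- function(genome, annotation, truth, condition, config,
                           seed = config$seed) {
  stopifnot(inherits(truth, "ground_truth"),
            condition %in% config$conditions)
  set.seed(seed)
  n <- config$n_reads[[condition]]
  rl <- config$read_length[[condition]]
  empty <- data.frame(read_id = character(0), seq = character(0),
                      qual = character(0), feature = character(0),
                      start = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  attr(empty, "condition") <- condition
  attr(empty, "read_length") <- rl
  class(empty) <- c("read_set", "data.frame")
  if (n == 0) {
    warning("zero reads requested; returning an empty read set")
    return(empty)
  }
  shares <- truth$shares[, condition]
  active <- shares > 0
  flen <- annotation$end - annotation$start + 1
  if (any(active & flen < rl))
    stop("read length exceeds the shortest expressed feature length")
  counts <- as.vector(rmultinom(1, n, shares))
  fidx <- rep(seq_len(nrow(annotation)), counts)
  starts <- annotation$start[fidx] +
    floor(runif(length(fidx)) * (flen[fidx] - rl + 1))
  starts <- as.integer(starts)
  seqs <- substring(genome, starts, starts + rl - 1L)

  if (nrow(truth$spikes) > 0) {
    for (si in seq_len(nrow(truth$spikes))) {
      p <- truth$spikes$genome_pos[si]
      hit <- which(starts <= p & starts + rl - 1L >= p)
      if (!length(hit)) next
      take <- hit[runif(length(hit)) < truth$spikes$allele_fraction[si]]
      for (i in take)
        substr(seqs[i], p - starts[i] + 1L, p - starts[i] + 1L) <-
          truth$spikes$alt[si]
    }
  }

  if (config$error_rate > 0) {
    nerr <- rbinom(1, length(seqs) * rl, config$error_rate)
    if (nerr > 0) {
      at_read <- sample.int(length(seqs), nerr, replace = TRUE)
      at_off <- sample.int(rl, nerr, replace = TRUE)
      for (j in seq_len(nerr)) {
        old <- substr(seqs[at_read[j]], at_off[j], at_off[j])
        substr(seqs[at_read[j]], at_off[j], at_off[j]) <-
          sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
    }
  }

  minus <- runif(length(seqs)) < 0.5
  if (any(minus)) seqs[minus] <- .revcomp_chr(seqs[minus])

  qual <- strrep(rawToChar(as.raw(33L + config$base_quality)), rl)
  quals <- rep(qual, length(seqs))
  if (config$low_quality_read_fraction > 0) {
    low <- runif(length(seqs)) < config$low_quality_read_fraction
    quals[low] <- strrep(rawToChar(as.raw(33L + config$low_quality_value)), rl)
  }

  reads <- data.frame(
    read_id = sprintf("%s_read_%07d", condition, seq_along(seqs)),
    seq = seqs, qual = quals,
    feature = annotation$locus_tag[fidx],
    start = starts,
    strand = ifelse(minus, "-", "+"),
    stringsAsFactors = FALSE)
  attr(reads, "condition") <- condition
  attr(reads, "read_length") <- rl
  class(reads) <- c("read_set", "data.frame")
  reads
}

#' Write and read ground-truth tables
#'
#' Persists the expected read shares and the spiked-variant registry as TSV
#' so downstream assertions can run against files rather than in-memory
#' objects. `read_truth_tables()` re-normalises shares column-wise on load.
#'
#' @param truth a [ground_truth()] object.
#' @param dir output directory (created if missing).
#' @return `write_truth_tables()` returns the two file paths invisibly;
#'   `read_truth_tables()` returns a `ground_truth`-shaped list.
#' @export
write_truth_tables <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  shares_path <- file.path(dir, "expected_shares.tsv")
  spikes_path <- file.path(dir, "spiked_variants.tsv")
  shares <- data.frame(locus_tag = rownames(truth$shares), truth$shares,
                       check.names = FALSE, stringsAsFactors = FALSE)
  write.table(shares, shares_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truth$spikes, spikes_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(shares = shares_path, spikes = spikes_path))
}

#' @rdname write_truth_tables
#' @export
read_truth_tables <- function(dir) {
  shares <- read.delim(file.path(dir, "expected_shares.tsv"),
                       check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(shares[, -1, drop = FALSE])
  rownames(m) <- shares$locus_tag
  m <- sweep(m, 2, colSums(m), "/")
  spikes <- read.delim(file.path(dir, "spiked_variants.tsv"),
                       stringsAsFactors = FALSE,
                       colClasses = c(ref = "character", alt = "character"))
  structure(list(shares = m, weights = NULL, spikes = spikes),
            class = "ground_truth")
}

#' Sequence and annotation input/output
#'
#' Thin wrappers over Biostrings for FASTA/FASTQ and over TSV for the
#' annotation table; `export_gff3()` converts the annotation to GFF3 through
#' GenomicRanges/rtracklayer when those packages are available.
#'
#' @param genome genome string.
#' @param path output file.
#' @param name sequence name used in FASTA/SAM headers.
#' @export
write_genome_fasta <- function(genome, path, name = "chr") {
  x <- Biostrings::DNAStringSet(setNames(genome, name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname write_genome_fasta
#' @param reads a `read_set` data frame.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id)),
    Biostrings::PhredQuality(reads$qual))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_reads_fastq <- function(path) {
  # metadata-column drop on the quality track is expected and harmless
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(read_id = names(x), seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' @rdname write_genome_fasta
#' @param annotation annotation data frame.
#' @export
write_annotation_tsv <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_annotation_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname write_genome_fasta
#' @export
export_gff3 <- function(annotation, path, name = "chr") {
  if (!requireNamespace("GenomicRanges", quietly = TRUE) ||
      !requireNamespace("rtracklayer", quietly = TRUE))
    stop("GenomicRanges and rtracklayer are required for GFF3 export")
  gr <- GenomicRanges::GRanges(
    seqnames = name,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand)
  gr$type <- ifelse(annotation$rna_class == "mRNA", "CDS",
                    paste0(annotation$rna_class))
  gr$ID <- annotation$locus_tag
  gr$product <- annotation$annotation
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
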