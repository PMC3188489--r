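#' Mapper configuration
#'
#' Settings for the repeat-aware read mapper. Candidate sites are all genome
#' positions (both strands) achieving the minimal Hamming mismatch count for
#' the read, up to `max_mismatches`. A read with a single candidate is
#' `unique`; with 2..`ambiguity_cap` candidates one site is chosen uniformly
#' at random (`ambiguous_assigned`); with more than `ambiguity_cap`
#' candidates the read is `discarded_too_ambiguous`, mirroring the policy of
#' allowing ten ambiguous map sites and placing best-hit ties at random.
#'
#' @param ambiguity_cap maximum number of tied candidate sites before a read
#'   is discarded (default 10).
#' @param max_mismatches Hamming mismatch allowance (default 2, no indels).
#' @param seed_kmer_length seed/index k-mer length; candidate enumeration is
#'   exhaustive when `(max_mismatches + 1) * seed_kmer_length <=` read length.
#' @param rng_seed seed for the random placement of ties.
#' @return a `mapper_config` list.
#' @export
mapper_config <- function(ambiguity_cap = 10L, max_mismatches = 2L,
                          seed_kmer_length = 11L, rng_seed = 1L) {
  stopifnot(ambiguity_cap >= 1, max_mismatches >= 0, seed_kmer_length >= 1)
  structure(list(ambiguity_cap = as.integer(ambiguity_cap),
                 max_mismatches = as.integer(max_mismatches),
                 seed_kmer_length = as.integer(seed_kmer_length),
                 rng_seed = as.integer(rng_seed)),
            class = "mapper_config")
}

#' Build the genome k-mer index
#'
#' Hashes every forward-strand k-mer of the genome to its 1-based positions.
#' Reverse-strand hits are found at query time by looking up the reverse
#' complement of the read, so the index itself stores one strand only.
#'
#' @param genome genome string (coerced to upper case).
#' @param config a [mapper_config()].
#' @return a `genome_index` object.
#' @export
build_index <- function(genome, config = mapper_config()) {
  stopifnot(nchar(genome) > 0)
  g <- toupper(genome)
  ptr <- kmer_index_build(g, config$seed_kmer_length)
  structure(list(ptr = ptr, k = config$seed_kmer_length,
                 genome_length = nchar(g)),
            class = "genome_index")
}

#' @rdname build_index
#' @param index a `genome_index`.
#' @param kmer query k-mer of exactly the index k-mer length.
#' @return `lookup_kmer()`: sorted 1-based forward-strand positions.
#' @export
lookup_kmer <- function(index, kmer) {
  stopifnot(inherits(index, "genome_index"))
  kmer_index_lookup(index$ptr, toupper(kmer))
}

.check_seed_cover <- function(read_length, config) {
  need <- (config$max_mismatches + 1L) * config$seed_kmer_length
  if (any(read_length < need))
    warning("reads shorter than (max_mismatches + 1) * seed_kmer_length: ",
            "candidate enumeration may miss high-mismatch sites")
}

#' Map a single read
#'
#' Enumerates all best-tier candidate sites and applies the ambiguity policy.
#' Ties are placed with the session RNG (seed with `set.seed()` for
#' reproducibility).
#'
#' @param read read sequence.
#' @param index a [build_index()] result.
#' @param config a [mapper_config()].
#' @param read_id identifier stored in the record.
#' @return an `alignment_record` list with `read_id`, `candidate_sites`
#'   (data frame of `pos`, `strand`, `mismatches`), `n_candidates`,
#'   `chosen_site` (one-row data frame or `NULL`) and `status`.
#' @export
map_read <- function(read, index, config = mapper_config(),
                     read_id = "read_1") {
  stopifnot(inherits(index, "genome_index"))
  read <- toupper(read)
  if (nchar(read) < index$k) {
    rec <- list(read_id = read_id,
                candidate_sites = data.frame(pos = integer(0),
                                             strand = character(0),
                                             mismatches = integer(0)),
                n_candidates = 0L, chosen_site = NULL, status = "unmapped",
                reason = "read shorter than seed k-mer")
    class(rec) <- "alignment_record"
    return(rec)
  }
  .check_seed_cover(nchar(read), config)
  cand <- map_candidates(index$ptr, read, config$max_mismatches)
  sites <- data.frame(pos = cand$pos,
                      strand = c("+", "-")[cand$strand + 1L],
                      mismatches = cand$mismatches,
                      stringsAsFactors = FALSE)
  n <- nrow(sites)
  if (n == 0) {
    status <- "unmapped"; chosen <- NULL
  } else if (n > config$ambiguity_cap) {
    status <- "discarded_too_ambiguous"; chosen <- NULL
  } else if (n == 1) {
    status <- "unique"; chosen <- sites[1, , drop = FALSE]
  } else {
    status <- "ambiguous_assigned"
    chosen <- sites[sample.int(n, 1), , drop = FALSE]
  }
  rec <- list(read_id = read_id, candidate_sites = sites, n_candidates = n,
              chosen_site = chosen, status = status)
  class(rec) <- "alignment_record"
  rec
}

#' Map a read set
#'
#' Vectorised mapping of a whole read set under the ambiguity policy. The
#' random placement of ties is deterministic under `config$rng_seed`.
#'
#' @param reads a `read_set` data frame (from [simulate_reads()] or
#'   [read_reads_fastq()]), or a character vector of sequences.
#' @param index a [build_index()] result.
#' @param config a [mapper_config()].
#' @return an `alignments` data frame with one row per read: `read_id`,
#'   `seq`, `qual`, `pos`, `strand`, `mismatches`, `n_candidates`, `status`,
#'   plus simulator truth columns when present. The status tabulation is
#'   attached as attribute `summary`.
#' @export
map_readset <- function(reads, index, config = mapper_config()) {
  stopifnot(inherits(index, "genome_index"))
  if (is.character(reads))
    reads <- data.frame(read_id = sprintf("read_%07d", seq_along(reads)),
                        seq = reads, qual = NA_character_,
                        stringsAsFactors = FALSE)
  seqs <- toupper(reads$seq)
  if (nrow(reads)) .check_seed_cover(nchar(seqs), config)
  set.seed(config$rng_seed)
  res <- map_readset_cpp(index$ptr, seqs, config$max_mismatches,
                         config$ambiguity_cap)
  out <- reads
  out$pos <- res$pos
  out$strand_ref <- ifelse(is.na(res$strand), NA_character_,
                           c("+", "-")[res$strand + 1L])
  out$mismatches <- res$mismatches
  out$n_candidates <- res$n_candidates
  out$status <- .status_levels[res$status + 1L]
  # reads too short for the index cannot be mapped at all
  short <- nchar(seqs) < index$k
  if (any(short)) {
    out$status[short] <- "unmapped"
    out$pos[short] <- NA_integer_
  }
  attr(out, "summary") <- mapping_summary(out)
  attr(out, "genome_length") <- index$genome_length
  class(out) <- c("alignments", "data.frame")
  out
}

#' Tabulate mapping outcomes
#'
#' @param alignments a [map_readset()] result.
#' @return named integer vector over the four statuses plus `total`.
#' @export
mapping_summary <- function(alignments) {
  counts <- table(factor(alignments$status, levels = .status_levels))
  c(as.vector(counts), total = nrow(alignments)) |>
    setNames(c(.status_levels, "total"))
}

#' Write alignments as SAM
#'
#' Emits a minimal single-reference SAM: assigned reads get FLAG 0/16 and a
#' `75M`-style CIGAR (the mapper is indel-free); unmapped and discarded reads
#' get FLAG 4. The candidate count is carried in the `XC:i` tag and the
#' status in `XS:Z`, so discarded-too-ambiguous reads remain identifiable.
#'
#' @param alignments a [map_readset()] result.
#' @param path output file.
#' @param genome_length reference length (taken from the alignments attribute
#'   when omitted).
#' @param name reference sequence name.
#' @export
write_sam <- function(alignments, path, genome_length = NULL, name = "chr") {
  if (is.null(genome_length))
    genome_length <- attr(alignments, "genome_length")
  stopifnot(!is.null(genome_length))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", name, as.integer(genome_length)))
  a <- alignments
  mapped <- a$status %in% c("unique", "ambiguous_assigned")
  seq_out <- a$seq
  qual_out <- if (is.null(a$qual)) rep("*", nrow(a)) else a$qual
  qual_out[is.na(qual_out)] <- "*"
  minus <- mapped & a$strand_ref == "-"
  if (any(minus)) {
    seq_out[minus] <- .revcomp_chr(seq_out[minus])
    qual_out[minus] <- vapply(qual_out[minus], function(q)
      if (q == "*") q else paste(rev(strsplit(q, "")[[1]]), collapse = ""), "")
  }
  flag <- ifelse(mapped, ifelse(a$strand_ref == "-", 16L, 0L), 4L)
  rname <- ifelse(mapped, name, "*")
  pos <- ifelse(mapped, a$pos, 0L)
  mapq <- ifelse(a$status == "unique", 60L, ifelse(mapped, 0L, 0L))
  cigar <- ifelse(mapped, paste0(nchar(a$seq), "M"), "*")
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tXC:i:%d\tXS:Z:%s",
                   a$read_id, flag, rname, pos, mapq, cigar, seq_out,
                   qual_out, a$n_candidates, a$status)
  writeLines(c(hdr, lines), path)
  invisible(path)
}
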