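#' Packaged worked-example tables
#'
#' Two small plain-text tables from a published transcriptome survey of
#' *Frankia* sp. CcI3 ship with the package as worked examples:
#' the 100 most expressed coding ORFs (by RPKM, ribosomal RNAs omitted) for
#' each of three culture conditions, and the 21 filtered SNPs detected in
#' all three samples with their codon effects.
#'
#' @param condition optional condition label to filter the top-100 table.
#' @return `load_top100_fixture()`: data frame `condition`, `annotation`,
#'   `locus_tag`, `rpkm`; `load_common_snps_fixture()`: data frame
#'   `locus_tag`, `annotation`, `orf_position`, `reference`, `variants`,
#'   `aa_change`.
#' @export
load_top100_fixture <- function(condition = NULL) {
  path <- system.file("extdata", "top100_rpkm_cci3.tsv",
                      package = "frankiatx", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(condition)) df <- df[df$condition == condition, , drop = FALSE]
  df
}

#' @rdname load_top100_fixture
#' @export
load_common_snps_fixture <- function() {
  path <- system.file("extdata", "common_snps_cci3.tsv",
                      package = "frankiatx", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(reference = "character"))
}

#' @rdname load_top100_fixture
#' @return `top100_hypothetical_counts()`: named integer vector of
#'   hypothetical-protein counts per condition among the top 100.
#' @export
top100_hypothetical_counts <- function() {
  df <- load_top100_fixture()
  vapply(split(df, df$condition), count_category, 0L)[
    unique(df$condition)]
}

# search the codon table for a (ref codon, alt codon) pair consistent with a
# variant record: ref_base at the given within-codon offset, mutated to
# alt_base, with the requested amino-acid transition (or synonymy)
.codon_for_change <- function(ref_base, alt_base, offset, ref_aa3 = NULL,
                              alt_aa3 = NULL) {
  bases <- c("A", "C", "G", "T")
  for (b1 in bases) for (b2 in bases) {
    codon <- c(b1, b2)
    codon <- append(codon, ref_base, after = offset)
    codon <- paste(codon, collapse = "")
    alt_codon <- codon
    substr(alt_codon, offset + 1L, offset + 1L) <- alt_base
    aa1 <- .translate_codon(codon)
    aa2 <- .translate_codon(alt_codon)
    if (aa1 == "*" || aa2 == "*") next
    if (is.null(ref_aa3)) {
      if (aa1 == aa2) return(codon)
    } else if (.aa3[[aa1]] == ref_aa3 && .aa3[[aa2]] == alt_aa3) {
      return(codon)
    }
  }
  stop("no codon context realises ", ref_base, ">", alt_base, " at offset ",
       offset, " with change ", ref_aa3, " -> ", alt_aa3)
}

#' Synthetic ORFs matching the codon contexts of a variant table
#'
#' For each record of a variant table (locus tag, 1-based ORF position,
#' reference base, variant set, amino-acid change) this constructs a
#' synthetic forward-strand ORF whose codon at that position realises
#' exactly the recorded substitution effect, then lays the ORFs on a
#' synthetic genome. The output feeds [annotate_effect()], which must
#' re-derive every recorded effect from the sequence alone; the
#' construction never copies effect labels into the result.
#'
#' @param records a table in the shape of [load_common_snps_fixture()].
#' @param gap intergenic spacing between the synthetic ORFs (nt).
#' @return list with `genome`, `annotation` and `calls` (a `snp_calls` data
#'   frame of the records at genome coordinates, without effect columns).
#' @export
snp_context_orfs <- function(records = load_common_snps_fixture(),
                             gap = 50L) {
  loci <- unique(records$locus_tag)
  orf_seqs <- list()
  for (lt in loci) {
    rec <- records[records$locus_tag == lt, , drop = FALSE]
    n_codons <- ceiling(max(rec$orf_position) / 3)
    codons <- rep("GGC", n_codons)  # glycine filler
    for (i in seq_len(nrow(rec))) {
      pos <- rec$orf_position[i]
      offset <- (pos - 1L) %% 3L
      ci <- (pos - 1L) %/% 3L + 1L
      ref <- rec$reference[i]
      alleles <- strsplit(rec$variants[i], "/", fixed = TRUE)[[1]]
      alt <- setdiff(alleles, ref)
      if (length(alt) != 1)
        stop("record ", lt, ":", pos, " does not define a single variant")
      aac <- rec$aa_change[i]
      if (aac == "-") {
        codons[ci] <- .codon_for_change(ref, alt, offset)
      } else {
        parts <- strsplit(aac, " -> ", fixed = TRUE)[[1]]
        codons[ci] <- .codon_for_change(ref, alt, offset, parts[1], parts[2])
      }
    }
    orf_seqs[[lt]] <- paste(codons, collapse = "")
  }
  lens <- vapply(orf_seqs, nchar, 0L)
  starts <- gap + cumsum(c(0L, head(lens + gap, -1))) + 1L
  genome_len <- sum(lens) + gap * (length(lens) + 1L)
  genome <- strrep("A", genome_len)
  for (i in seq_along(orf_seqs))
    substr(genome, starts[i], starts[i] + lens[i] - 1L) <- orf_seqs[[i]]
  annotation <- data.frame(
    locus_tag = loci, start = starts, end = starts + lens - 1L,
    strand = "+", rna_class = "mRNA", functional_class = "other",
    annotation = records$annotation[match(loci, records$locus_tag)],
    is_family = NA_character_, paralog_group = NA_character_,
    stringsAsFactors = FALSE)
  idx <- match(records$locus_tag, loci)
  alt <- mapply(function(v, r) setdiff(strsplit(v, "/")[[1]], r),
                records$variants, records$reference)
  calls <- data.frame(
    genome_pos = starts[idx] + records$orf_position - 1L,
    reference = records$reference,
    variant = unname(alt),
    variants = paste(records$reference, unname(alt), sep = "/"),
    coverage = NA_integer_, variant_fraction = NA_real_,
    stringsAsFactors = FALSE)
  class(calls) <- c("snp_calls", "data.frame")
  list(genome = genome, annotation = annotation, calls = calls)
}
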