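#' SNP filter configuration
#'
#' The four-criterion filter cascade applied to pileup columns:
#' (1) observations from reads whose mean base quality is below
#' `min_read_mean_quality` are discarded; (2) observations of the variant
#' base must have base quality strictly above `min_base_quality`;
#' (3) at least `min_coverage` observations must remain at the position;
#' (4) the variant must be present in at least `min_variant_fraction` of the
#' remaining observations. Coverage and fraction are evaluated after the
#' quality filters, i.e. the criteria act as a cascade.
#'
#' @param min_read_mean_quality criterion 1 threshold (default 15; reads
#'   with mean quality below it are discarded).
#' @param min_base_quality criterion 2 threshold (default 20; variant bases
#'   must exceed it strictly).
#' @param min_coverage criterion 3 threshold (default 10).
#' @param min_variant_fraction criterion 4 threshold (default 0.25).
#' @return an `snp_filter_config` list.
#' @export
snp_filter_config <- function(min_read_mean_quality = 15,
                              min_base_quality = 20,
                              min_coverage = 10,
                              min_variant_fraction = 0.25) {
  stopifnot(min_read_mean_quality > 0, min_base_quality > 0,
            min_coverage > 0, min_variant_fraction > 0,
            min_variant_fraction <= 1)
  structure(list(min_read_mean_quality = min_read_mean_quality,
                 min_base_quality = min_base_quality,
                 min_coverage = min_coverage,
                 min_variant_fraction = min_variant_fraction),
            class = "snp_filter_config")
}

#' Build a per-position pileup from assigned alignments
#'
#' Tallies, for every covered genome position, the observed base, its Phred
#' base quality and the mean quality of the carrying read. Reverse-strand
#' alignments contribute the complement of their read bases so every
#' observation is expressed on the forward reference strand. Only assigned
#' reads (`unique` or `ambiguous_assigned`) contribute.
#'
#' @param alignments a [map_readset()] result carrying `seq` and `qual`.
#' @param genome genome string (stored as the `reference` attribute).
#' @return a `pileup` data frame: `pos`, `base`, `base_qual`,
#'   `read_mean_qual`, `read_id`.
#' @export
build_pileup <- function(alignments, genome) {
  a <- alignments[alignments$status %in% c("unique", "ambiguous_assigned"), ,
                  drop = FALSE]
  if (nrow(a) == 0) {
    out <- data.frame(pos = integer(0), base = character(0),
                      base_qual = integer(0), read_mean_qual = numeric(0),
                      read_id = character(0), stringsAsFactors = FALSE)
    attr(out, "reference") <- genome
    class(out) <- c("pileup", "data.frame")
    return(out)
  }
  len <- nchar(a$seq)
  minus <- a$strand_ref == "-"
  oriented_seq <- a$seq
  oriented_seq[minus] <- .revcomp_chr(oriented_seq[minus])
  oriented_qual <- a$qual
  oriented_qual[minus] <- vapply(oriented_qual[minus], function(q)
    intToUtf8(rev(utf8ToInt(q))), "")

  qlist <- lapply(oriented_qual, function(q) utf8ToInt(q) - 33L)
  read_mean <- vapply(qlist, mean, 0)

  pos <- rep(a$pos, len) + sequence(len) - 1L
  bases <- unlist(strsplit(toupper(oriented_seq), "", fixed = TRUE),
                  use.names = FALSE)
  quals <- unlist(qlist, use.names = FALSE)
  out <- data.frame(pos = as.integer(pos), base = bases,
                    base_qual = as.integer(quals),
                    read_mean_qual = rep(read_mean, len),
                    read_id = rep(a$read_id, len),
                    stringsAsFactors = FALSE)
  attr(out, "reference") <- genome
  class(out) <- c("pileup", "data.frame")
  out
}

#' Call SNPs through the filter cascade
#'
#' Applies the four criteria of [snp_filter_config()] per pileup column.
#' The most frequent non-reference base is the primary variant; further
#' non-reference bases are appended to the variant set only if they pass
#' the base-quality, coverage and fraction criteria independently.
#'
#' @param pileup a [build_pileup()] result (or any data frame with its
#'   columns plus a `reference` attribute or `genome` argument).
#' @param config an [snp_filter_config()].
#' @param genome reference genome string (defaults to the pileup attribute).
#' @return a `snp_calls` data frame: `genome_pos`, `reference`, `variant`,
#'   `variants` (formatted set such as `"G/A"`), `coverage`,
#'   `variant_fraction`.
#' @export
call_snps <- function(pileup, config = snp_filter_config(), genome = NULL) {
  if (is.null(genome)) genome <- attr(pileup, "reference")
  stopifnot(!is.null(genome))
  empty <- data.frame(genome_pos = integer(0), reference = character(0),
                      variant = character(0), variants = character(0),
                      coverage = integer(0), variant_fraction = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("snp_calls", "data.frame")
  if (nrow(pileup) == 0) return(empty)

  # criterion 1: drop observations from low-mean-quality reads
  p <- pileup[pileup$read_mean_qual >= config$min_read_mean_quality, ,
              drop = FALSE]
  if (nrow(p) == 0) return(empty)

  # restrict to positions where any non-reference base is observed at all
  refs <- substring(genome, p$pos, p$pos)
  has_var <- p$pos %in% unique(p$pos[p$base != refs])
  p <- p[has_var, , drop = FALSE]
  if (nrow(p) == 0) return(empty)

  idx <- split(seq_len(nrow(p)), p$pos)
  calls <- lapply(idx, function(i) {
    pos <- p$pos[i[1]]
    ref <- substring(genome, pos, pos)
    base <- p$base[i]
    qual <- p$base_qual[i]
    nonref <- setdiff(unique(base), ref)
    freq <- vapply(nonref, function(b) sum(base == b), 0L)
    nonref <- nonref[order(-freq, nonref)]
    passing <- character(0)
    stats <- NULL
    for (b in nonref) {
      is_var <- base == b
      # criterion 2: variant-base observations must exceed the base-quality
      # threshold; failing variant observations are dropped from the column
      drop <- is_var & qual <= config$min_base_quality
      coverage <- sum(!drop)
      vcount <- sum(is_var & !drop)
      if (vcount == 0) next
      frac <- vcount / coverage
      # criteria 3 and 4
      if (coverage >= config$min_coverage &&
          frac >= config$min_variant_fraction) {
        passing <- c(passing, b)
        if (is.null(stats))
          stats <- list(coverage = coverage, fraction = frac)
      }
    }
    if (!length(passing) || !(nonref[1] %in% passing)) return(NULL)
    data.frame(genome_pos = pos, reference = ref, variant = passing[1],
               variants = paste(c(ref, passing), collapse = "/"),
               coverage = as.integer(stats$coverage),
               variant_fraction = stats$fraction,
               stringsAsFactors = FALSE)
  })
  calls <- calls[!vapply(calls, is.null, TRUE)]
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  out <- out[order(out$genome_pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_calls", "data.frame")
  out
}

.codon_at <- function(genome, ann_row, codon_index) {
  if (ann_row$strand == "+") {
    s <- ann_row$start + 3L * codon_index
    substring(genome, s, s + 2L)
  } else {
    e <- ann_row$end - 3L * codon_index
    .revcomp_chr(substring(genome, e - 2L, e))
  }
}

#' Annotate codon effects of SNP calls
#'
#' Locates each call within the annotation, computes its 1-based position on
#' the coding strand of the containing mRNA ORF, translates the reference
#' and variant codons (strand-aware) and classifies the change as
#' synonymous (reported `"-"`), non-synonymous (reported as e.g.
#' `"Arg -> Gln"` in three-letter code) or non-coding when the position
#' falls outside every mRNA ORF.
#'
#' @param calls a [call_snps()] result.
#' @param annotation annotation data frame; mRNA ORF lengths must be
#'   multiples of 3.
#' @param genome genome string.
#' @return the calls with columns `locus_tag`, `orf_position`, `effect`
#'   (`synonymous`, `non-synonymous`, `non-coding`) and `aa_change`.
#' @export
annotate_effect <- function(calls, annotation, genome) {
  mrna <- annotation[annotation$rna_class == "mRNA", , drop = FALSE]
  if (nrow(mrna) &&
      any((mrna$end - mrna$start + 1) %% 3 != 0))
    stop("mRNA ORF lengths must be divisible by 3 for effect annotation")
  n <- nrow(calls)
  locus <- rep(NA_character_, n)
  orf_pos <- rep(NA_integer_, n)
  effect <- rep("non-coding", n)
  aa_change <- rep("-", n)
  for (i in seq_len(n)) {
    pos <- calls$genome_pos[i]
    hit <- which(mrna$start <= pos & mrna$end >= pos)
    if (!length(hit)) next
    row <- mrna[hit[1], ]
    locus[i] <- row$locus_tag
    op <- if (row$strand == "+") pos - row$start + 1L else row$end - pos + 1L
    orf_pos[i] <- op
    codon_index <- (op - 1L) %/% 3L
    offset <- (op - 1L) %% 3L
    ref_codon <- .codon_at(genome, row, codon_index)
    alt <- calls$variant[i]
    if (!alt %in% c("A", "C", "G", "T"))
      stop("ambiguous variant base at position ", pos)
    alt_coding <- if (row$strand == "+") alt else .revcomp_chr(alt)
    alt_codon <- ref_codon
    substr(alt_codon, offset + 1L, offset + 1L) <- alt_coding
    ref_aa <- .translate_codon(ref_codon)
    alt_aa <- .translate_codon(alt_codon)
    if (identical(ref_aa, alt_aa)) {
      effect[i] <- "synonymous"
    } else {
      effect[i] <- "non-synonymous"
      aa_change[i] <- paste(.aa3[[ref_aa]], "->", .aa3[[alt_aa]])
    }
  }
  calls$locus_tag <- locus
  calls$orf_position <- orf_pos
  calls$effect <- effect
  calls$aa_change <- aa_change
  calls
}

#' Intersect SNP calls across samples
#'
#' Keeps the calls present (by genome position) in every supplied sample
#' and unions their variant sets. Order-independent and associative.
#'
#' @param ... two or more [call_snps()] results, or a single list of them.
#' @return a `snp_calls` data frame of the common positions with unioned
#'   `variants` and per-position minimum coverage across samples.
#' @export
intersect_samples <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && is.list(lists[[1]]) &&
      !is.data.frame(lists[[1]]))
    lists <- lists[[1]]
  stopifnot(length(lists) >= 2)
  common <- Reduce(intersect, lapply(lists, function(x) x$genome_pos))
  common <- sort(common)
  empty <- data.frame(genome_pos = integer(0), reference = character(0),
                      variant = character(0), variants = character(0),
                      coverage = integer(0), variant_fraction = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("snp_calls", "data.frame")
  if (!length(common)) return(empty)
  rows <- lapply(common, function(pos) {
    recs <- lapply(lists, function(x) x[x$genome_pos == pos, , drop = FALSE])
    ref <- recs[[1]]$reference[1]
    alts <- unique(unlist(lapply(recs, function(r)
      setdiff(strsplit(r$variants[1], "/", fixed = TRUE)[[1]], ref))))
    data.frame(genome_pos = pos, reference = ref,
               variant = recs[[1]]$variant[1],
               variants = paste(c(ref, sort(alts)), collapse = "/"),
               coverage = min(vapply(recs, function(r) r$coverage[1], 0L)),
               variant_fraction =
                 min(vapply(recs, function(r) r$variant_fraction[1], 0)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("snp_calls", "data.frame")
  out
}

#' Write SNP calls as VCF
#'
#' Minimal VCFv4.2 with coverage (`DP`), variant fraction (`AF`) and, when
#' [annotate_effect()] has run, the effect class and amino-acid change in
#' INFO.
#'
#' @param calls a `snp_calls` data frame.
#' @param path output file.
#' @param name reference sequence name.
#' @param genome_length contig length for the header (optional).
#' @export
write_snp_vcf <- function(calls, path, name = "chr", genome_length = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Filtered coverage\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant fraction\">",
           "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Codon effect\">",
           "##INFO=<ID=AAC,Number=1,Type=String,Description=\"Amino acid change\">")
  if (!is.null(genome_length))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", name,
                          as.integer(genome_length)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf("DP=%d;AF=%.4f", calls$coverage, calls$variant_fraction)
  if ("effect" %in% names(calls))
    info <- paste0(info, ";EFF=", calls$effect, ";AAC=",
                   gsub(" ", "", calls$aa_change))
  lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", name, calls$genome_pos,
                   calls$reference, calls$variant, info)
  writeLines(c(hdr, lines), path)
  invisible(path)
}
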