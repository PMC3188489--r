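#' Log-transform and median-centre an expression matrix
#'
#' Builds the genes x samples matrix underlying the heat map: RPKM values
#' are log2-transformed after adding a pseudocount (log scale with RPKM 0
#' handled), then each gene row is centred on its median, so black in the
#' rendered map is the gene's median expression across samples. Genes with
#' zero RPKM in every sample carry no signal and are dropped with a message.
#'
#' @param tables named list (>= 2) of [compute_rpkm()] tables sharing an
#'   annotation.
#' @param pseudocount added before the log (default 1).
#' @param genes optional locus tags to restrict the matrix (defaults to all
#'   mRNA features).
#' @return numeric matrix with `transform` attribute recording the log base,
#'   pseudocount and centering statistic.
#' @export
transform_matrix <- function(tables, pseudocount = 1, genes = NULL) {
  stopifnot(length(tables) >= 2)
  locus <- tables[[1]]$locus_tag
  for (tb in tables) stopifnot(identical(tb$locus_tag, locus))
  keep <- tables[[1]]$rna_class == "mRNA"
  if (!is.null(genes)) keep <- keep & locus %in% genes
  M <- vapply(tables, function(tb) tb$rpkm[keep], numeric(sum(keep)))
  rownames(M) <- locus[keep]
  zero <- rowSums(M) == 0
  if (any(zero)) {
    message("dropping ", sum(zero), " all-zero gene rows")
    M <- M[!zero, , drop = FALSE]
  }
  M <- log2(M + pseudocount)
  M <- M - apply(M, 1, median)
  attr(M, "transform") <- list(log_base = 2, pseudocount = pseudocount,
                               centering = "median")
  M
}

# correlation distance robust to constant rows: two flat profiles are
# identical (distance 0); a flat profile carries no shape information
# relative to a varying one (distance 1)
.cor_dist <- function(M) {
  C <- suppressWarnings(cor(t(M)))
  flat <- apply(M, 1, sd) == 0
  if (any(flat)) {
    C[flat, ] <- 0
    C[, flat] <- 0
    C[flat, flat] <- 1
  }
  diag(C) <- 1
  as.dist(1 - C)
}

#' Hierarchically cluster genes and samples
#'
#' Clusters both axes of the transformed matrix (1 - Pearson correlation
#' distance, average linkage, by default) and cuts the gene dendrogram at
#' the smallest height giving `k` groups, labelled with roman numerals.
#' An optional per-gene variance scaling is available but off by default:
#' median subtraction alone is the normalisation applied before map
#' generation.
#'
#' @param M matrix from [transform_matrix()].
#' @param distance `"pearson"` (1 - correlation) or `"euclidean"`.
#' @param linkage agglomeration method for [stats::hclust()].
#' @param k number of gene expression groups (default 5).
#' @param scale_rows divide each centred row by its standard deviation.
#' @return a `heatmap_model` list: `matrix`, `gene_tree`, `sample_tree`,
#'   `groups` (named factor with roman-numeral levels), `params`.
#' @export
cluster_genes_samples <- function(M, distance = c("pearson", "euclidean"),
                                  linkage = "average", k = 5,
                                  scale_rows = FALSE) {
  distance <- match.arg(distance)
  stopifnot(all(is.finite(M)))
  if (nrow(M) < k)
    stop("fewer genes (", nrow(M), ") than requested groups (", k, ")")
  if (scale_rows) {
    s <- apply(M, 1, sd)
    M[s > 0, ] <- M[s > 0, , drop = FALSE] / s[s > 0]
  }
  dg <- if (distance == "pearson") .cor_dist(M) else dist(M)
  ds <- if (distance == "pearson") .cor_dist(t(M)) else dist(t(M))
  gene_tree <- hclust(dg, method = linkage)
  sample_tree <- hclust(ds, method = linkage)
  cuts <- cutree(gene_tree, k = k)
  groups <- factor(as.character(as.roman(cuts)),
                   levels = as.character(as.roman(seq_len(k))))
  names(groups) <- rownames(M)
  structure(list(matrix = M, gene_tree = gene_tree,
                 sample_tree = sample_tree, groups = groups,
                 params = list(distance = distance, linkage = linkage,
                               k = k, scale_rows = scale_rows)),
            class = "heatmap_model")
}

#' Export the heat map and group lists
#'
#' Writes a red/black/green rendering (red above the gene median, green
#' below, black at the median) ordered by the dendrograms, the clustered
#' matrix as TSV, and the gene-to-group table as TSV.
#'
#' @param model a [cluster_genes_samples()] result.
#' @param prefix output path prefix; files `<prefix>_heatmap.png`,
#'   `<prefix>_matrix.tsv`, `<prefix>_groups.tsv` are produced.
#' @param width,height image size in pixels.
#' @return invisible named vector of the written paths.
#' @export
export_heatmap <- function(model, prefix, width = 800, height = 1000) {
  stopifnot(inherits(model, "heatmap_model"))
  M <- model$matrix[model$gene_tree$order, model$sample_tree$order,
                    drop = FALSE]
  png_path <- paste0(prefix, "_heatmap.png")
  mat_path <- paste0(prefix, "_matrix.tsv")
  grp_path <- paste0(prefix, "_groups.tsv")

  pal <- colorRampPalette(c("green", "black", "red"))(255)
  lim <- max(abs(M), 1e-12)
  png(png_path, width = width, height = height)
  par(mar = c(4, 1, 1, 6))
  image(t(M)[, rev(seq_len(nrow(M))), drop = FALSE], col = pal,
        zlim = c(-lim, lim), axes = FALSE)
  axis(1, at = seq(0, 1, length.out = ncol(M)), labels = colnames(M))
  dev.off()

  write.table(data.frame(locus_tag = rownames(M), M, check.names = FALSE),
              mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  groups <- model$groups[rownames(model$matrix)]
  write.table(data.frame(locus_tag = names(groups),
                         group = as.character(groups)),
              grp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(heatmap = png_path, matrix = mat_path, groups = grp_path))
}

#' @rdname export_heatmap
#' @param path a `<prefix>_groups.tsv` file.
#' @return `read_heatmap_groups()`: named factor of group labels.
#' @export
read_heatmap_groups <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(factor(df$group), df$locus_tag)
}
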