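#' causanet: causal gene network reconstruction from genetical genomics data
#'
#' Four-step pipeline: (1) phenotype-discriminative module discovery on a
#' molecular interactome ([discover_modules]); (2) module-level eQTL mapping by
#' two-stage sparse partial least squares ([map_module_eqtls]); (3) eQTL-anchored
#' Bayesian subnetwork learning over all module pairs, accumulated into a
#' causation matrix ([accumulate_causation]); (4) Beta-random-field ranking and
#' global network assembly ([infer_ranks], [assemble_global_network]).
#' [run_pipeline] orchestrates everything; [simulate_dataset] generates
#' synthetic data with known causal truth for validation.
#'
#' @importFrom stats cor pf rbinom rnorm runif rbeta sd var hclust cutree dist
#'   manova anova lm quantile setNames
#' @importFrom utils read.delim write.table combn head modifyList
#' @keywords internal
"_PACKAGE"

#' Expression matrix container
#'
#' Genes-by-samples numeric matrix, assumed already normalized (log scale).
#' Gene identifiers must be unique, values complete (imputation, if any, is the
#' caller's explicit responsibility), and at least four samples are required.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids character vectors; default to dimnames.
#' @return An object of class `ExpressionMatrix`: list with elements `values`,
#'   `gene_ids`, `sample_ids`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing expression value at gene '%s', sample '%s'",
                 gene_ids[idx[1L]], sample_ids[idx[2L]]))
  }
  if (ncol(values) < 4L) stop("at least 4 samples are required")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' Genotype matrix container
#'
#' SNPs-by-samples additive dosage matrix with entries in \{0,1,2\} and a
#' genomic position for every SNP. Chromosome names are kept verbatim as
#' strings; they must match the gene annotation's naming.
#'
#' @param dosages numeric matrix, SNPs in rows, samples in columns, entries in
#'   \{0,1,2\} (no missing values; see [read_genotype_matrix] for imputation).
#' @param positions data.frame with columns `snp_id`, `chrom`, `pos` covering
#'   every row of `dosages`.
#' @param snp_ids,sample_ids character vectors; default to dimnames.
#' @return An object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(dosages, positions, snp_ids = rownames(dosages),
                            sample_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(snp_ids) || is.null(sample_ids))
    stop("SNP and sample identifiers are required")
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids")
  bad <- which(!dosages %in% c(0, 1, 2))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(dosages))
    stop(sprintf("dosage %s at SNP '%s', sample '%s' is not in {0,1,2}",
                 format(dosages[bad[1L]]), snp_ids[idx[1L]],
                 sample_ids[idx[2L]]))
  }
  positions <- as.data.frame(positions)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(positions)))
    stop("positions must have columns snp_id, chrom, pos")
  missing_pos <- setdiff(snp_ids, positions$snp_id)
  if (length(missing_pos))
    stop("SNP(s) without a position: ", paste(head(missing_pos, 5L), collapse = ", "))
  positions <- positions[match(snp_ids, positions$snp_id), need]
  if (any(positions$pos < 0) || any(positions$pos != floor(positions$pos)))
    stop("positions must be nonnegative integers")
  positions$chrom <- as.character(positions$chrom)
  rownames(positions) <- NULL
  dimnames(dosages) <- list(snp_ids, sample_ids)
  structure(list(dosages = dosages, snp_ids = as.character(snp_ids),
                 sample_ids = as.character(sample_ids), positions = positions),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d SNPs x %d samples (%d chromosome(s))\n",
              length(x$snp_ids), length(x$sample_ids),
              length(unique(x$positions$chrom))))
  invisible(x)
}

#' Undirected molecular-interaction network
#'
#' Stores each unordered gene pair once (endpoints sorted lexicographically),
#' with self-loops and duplicates removed.
#'
#' @param edges two-column data.frame or matrix of gene id pairs.
#' @return An object of class `Interactome`: data.frame with columns `gene1`,
#'   `gene2` (gene1 < gene2), attribute `genes` holding the vertex universe.
#' @export
interactome <- function(edges) {
  edges <- as.data.frame(edges)[, 1:2]
  names(edges) <- c("gene1", "gene2")
  edges$gene1 <- as.character(edges$gene1)
  edges$gene2 <- as.character(edges$gene2)
  edges <- edges[edges$gene1 != edges$gene2, , drop = FALSE]
  a <- pmin(edges$gene1, edges$gene2)
  b <- pmax(edges$gene1, edges$gene2)
  edges <- data.frame(gene1 = a, gene2 = b, stringsAsFactors = FALSE)
  edges <- edges[!duplicated(paste(edges$gene1, edges$gene2, sep = "\r")), ,
                 drop = FALSE]
  edges <- edges[order(edges$gene1, edges$gene2), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, genes = sort(unique(c(edges$gene1, edges$gene2))),
            class = c("Interactome", "data.frame"))
}

#' Binary phenotype labels
#'
#' @param sample_ids character vector.
#' @param labels vector with exactly two distinct values; each group must have
#'   at least 3 samples (needed for group-wise correlations and the Hotelling
#'   test).
#' @return An object of class `PhenotypeLabels`.
#' @export
phenotype_labels <- function(sample_ids, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("exactly two distinct phenotype labels are required, got ",
         nlevels(labels))
  if (length(sample_ids) != length(labels))
    stop("sample_ids and labels differ in length")
  if (any(table(labels) < 3L))
    stop("each phenotype group needs at least 3 samples")
  structure(list(sample_ids = as.character(sample_ids), labels = labels),
            class = "PhenotypeLabels")
}

#' Gene annotation table
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (basepair coordinates, start <= end).
#' @return An object of class `GeneAnnotation` (a validated data.frame).
#' @export
gene_annotation <- function(df) {
  df <- as.data.frame(df)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("gene annotation needs columns gene_id, chrom, start, end")
  df <- df[, need]
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotation")
  if (any(df$start > df$end)) stop("gene annotation has start > end")
  rownames(df) <- NULL
  structure(df, class = c("GeneAnnotation", "data.frame"))
}

## internal: reorder labels to a given sample order
reorder_labels <- function(labels, sample_ids) {
  idx <- match(sample_ids, labels$sample_ids)
  if (anyNA(idx)) stop("phenotype labels missing for sample(s): ",
                       paste(head(sample_ids[is.na(idx)], 5L), collapse = ", "))
  phenotype_labels(labels$sample_ids[idx], labels$labels[idx])
}
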