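#' Read an expression matrix from a tab-delimited file
#'
#' Expects a header row of sample ids and a first column of gene ids. Every
#' value cell must parse as a number; duplicate gene rows and empty cells are
#' load errors naming the offending row/column.
#'
#' @param path file path.
#' @return An [expression_matrix].
#' @export
read_expression_matrix <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE, quote = "")
  if (ncol(raw) < 2L) stop("malformed expression file: need gene id column plus samples")
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene row(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  empty <- which(vals == "" | is.na(vals))
  if (length(empty)) {
    idx <- arrayInd(empty[1L], dim(vals))
    stop(sprintf("empty expression value at gene '%s', sample '%s'",
                 gene_ids[idx[1L]], sample_ids[idx[2L]]))
  }
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(vals))
    stop(sprintf("non-numeric expression value '%s' at gene '%s', sample '%s'",
                 vals[bad[1L]], gene_ids[idx[1L]], sample_ids[idx[2L]]))
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  expression_matrix(num)
}

#' Write an expression matrix
#' @param expr an [expression_matrix].
#' @param path file path.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(gene_id = expr$gene_ids, expr$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix (dosage TSV or VCF) with SNP positions
#'
#' Dosage input is a tab-delimited SNPs-by-samples table (header = sample ids,
#' first column = SNP ids) with entries in \{0,1,2\} or missing (`NA`/empty).
#' A `.vcf` input is parsed from the GT field as an allele-count dosage, and the
#' annotation is taken from the VCF CHROM/POS columns. Otherwise
#' `annotation_path` must be a 3-column TSV (snp_id, chrom, pos).
#'
#' With `impute = TRUE`, missing dosages are replaced by the per-SNP rounded
#' mean; with `impute = FALSE` any missing value is an error.
#'
#' @param path dosage TSV or VCF file path.
#' @param annotation_path SNP annotation TSV (ignored for VCF input).
#' @param impute replace missing dosages by the per-SNP rounded mean.
#' @return A [genotype_matrix].
#' @export
read_genotype_matrix <- function(path, annotation_path = NULL, impute = TRUE) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    parsed <- parse_vcf_dosages(path)
    dos <- parsed$dosages
    ann <- parsed$positions
  } else {
    raw <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                      check.names = FALSE, quote = "")
    snp_ids <- raw[[1L]]
    sample_ids <- colnames(raw)[-1L]
    vals <- as.matrix(raw[, -1L, drop = FALSE])
    vals[vals == ""] <- NA_character_
    dos <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
    nonnum <- which(is.na(dos) & !is.na(vals) & toupper(vals) != "NA")
    if (length(nonnum)) {
      idx <- arrayInd(nonnum[1L], dim(vals))
      stop(sprintf("non-numeric dosage '%s' at SNP '%s', sample '%s'",
                   vals[nonnum[1L]], snp_ids[idx[1L]], sample_ids[idx[2L]]))
    }
    dimnames(dos) <- list(snp_ids, sample_ids)
    if (is.null(annotation_path)) stop("annotation_path is required for dosage input")
    ann <- read.delim(annotation_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
    names(ann)[1:3] <- c("snp_id", "chrom", "pos")
  }
  bad <- which(!is.na(dos) & !dos %in% c(0, 1, 2))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(dos))
    stop(sprintf("dosage %s at SNP '%s', sample '%s' is not in {0,1,2}",
                 format(dos[bad[1L]]), rownames(dos)[idx[1L]],
                 colnames(dos)[idx[2L]]))
  }
  if (anyNA(dos)) {
    if (!impute) {
      idx <- which(is.na(dos), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing dosage at SNP '%s', sample '%s' (impute = FALSE)",
                   rownames(dos)[idx[1L]], colnames(dos)[idx[2L]]))
    }
    for (i in which(rowSums(is.na(dos)) > 0L)) {
      m <- mean(dos[i, ], na.rm = TRUE)
      if (is.nan(m)) stop(sprintf("SNP '%s' has no observed dosages", rownames(dos)[i]))
      dos[i, is.na(dos[i, ])] <- max(0, min(2, round(m)))
    }
  }
  genotype_matrix(dos, ann)
}

## internal: minimal VCF GT parser (text VCF, GT first FORMAT key or sole field)
parse_vcf_dosages <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("malformed VCF: no #CHROM header line")
  cols <- strsplit(sub("^#", "", lines[hdr[1L]]), "\t", fixed = TRUE)[[1L]]
  if (length(cols) < 10L) stop("VCF has no sample columns")
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr[1L])]
  body <- body[!startsWith(body, "#")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  n <- length(fields)
  dos <- matrix(NA_real_, n, length(samples))
  snp_id <- character(n); chrom <- character(n); pos <- integer(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    chrom[i] <- f[1L]; pos[i] <- as.integer(f[2L])
    snp_id[i] <- if (f[3L] == ".") paste0(f[1L], ":", f[2L]) else f[3L]
    gt_idx <- match("GT", strsplit(f[9L], ":", fixed = TRUE)[[1L]])
    if (is.na(gt_idx)) stop("VCF record without GT field at ", snp_id[i])
    gts <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, "", gt_idx)
    alleles <- strsplit(gts, "[/|]")
    dos[i, ] <- vapply(alleles, function(a) {
      if (any(a == ".")) return(NA_real_)
      sum(as.numeric(a) > 0)
    }, numeric(1L))
  }
  dimnames(dos) <- list(snp_id, samples)
  list(dosages = dos,
       positions = data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                              stringsAsFactors = FALSE))
}

#' Write a genotype matrix (dosage TSV + annotation TSV)
#' @param geno a [genotype_matrix].
#' @param path dosage TSV path.
#' @param annotation_path annotation TSV path.
#' @export
write_genotype_matrix <- function(geno, path, annotation_path) {
  df <- data.frame(snp_id = geno$snp_ids, geno$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(geno$positions, annotation_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read phenotype labels (TSV: sample_id, label)
#' @param path file path.
#' @return A [phenotype_labels].
#' @export
read_phenotype_labels <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  phenotype_labels(df[[1L]], df[[2L]])
}

#' Write phenotype labels
#' @param labels a [phenotype_labels].
#' @param path file path.
#' @export
write_phenotype_labels <- function(labels, path) {
  write.table(data.frame(sample_id = labels$sample_ids,
                         label = as.character(labels$labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation (TSV: gene_id, chrom, start, end)
#' @param path file path.
#' @return A [gene_annotation].
#' @export
read_gene_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df)[1:4] <- c("gene_id", "chrom", "start", "end")
  gene_annotation(df)
}

#' Read an interactome (2-column TSV without header, or SIF)
#'
#' SIF lines are `source relation target [target ...]` separated by whitespace;
#' the relation token is ignored. Plain TSV input is two headerless columns of
#' gene ids.
#'
#' @param path file path; `.sif` extension selects SIF parsing.
#' @return An [interactome].
#' @export
read_interactome <- function(path) {
  if (grepl("\\.sif$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    pairs <- do.call(rbind, lapply(strsplit(lines, "[ \t]+"), function(tok) {
      if (length(tok) < 3L) stop("malformed SIF line: ", paste(tok, collapse = " "))
      cbind(tok[1L], tok[-(1:2)])
    }))
    interactome(pairs)
  } else {
    df <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
    interactome(df)
  }
}

#' Write an interactome as a 2-column TSV
#' @param net an [interactome].
#' @param path file path.
#' @export
write_interactome <- function(net, path) {
  write.table(as.data.frame(net), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Align expression, genotypes and labels on shared samples
#'
#' Restricts all three inputs to the intersection of their sample ids, in the
#' expression matrix's order (the canonical sample order for all downstream
#' stages). Dropped samples are reported in a warning. Fewer than 4 shared
#' samples is an error. Idempotent.
#'
#' @param expr an [expression_matrix].
#' @param geno a [genotype_matrix].
#' @param labels a [phenotype_labels].
#' @return list with elements `expr`, `geno`, `labels`, all sample-aligned.
#' @export
align_samples <- function(expr, geno, labels) {
  shared <- expr$sample_ids[expr$sample_ids %in% geno$sample_ids &
                            expr$sample_ids %in% labels$sample_ids]
  if (length(shared) < 4L)
    stop("fewer than 4 samples shared across expression, genotypes and labels")
  dropped <- setdiff(unique(c(expr$sample_ids, geno$sample_ids,
                              labels$sample_ids)), shared)
  if (length(dropped))
    warning("dropping ", length(dropped), " unshared sample(s): ",
            paste(head(dropped, 10L), collapse = ", "))
  expr2 <- expression_matrix(expr$values[, shared, drop = FALSE])
  geno2 <- genotype_matrix(geno$dosages[, shared, drop = FALSE], geno$positions)
  labels2 <- reorder_labels(labels, shared)
  list(expr = expr2, geno = geno2, labels = labels2)
}

#' Write a global network (edge TSV + SIF companion)
#'
#' The TSV has columns source, target, c_source_target, c_target_source,
#' rank_source, rank_target; the SIF companion (same path with a `.sif`
#' extension) has lines `source regulates target`. [read_network] on the TSV
#' reproduces the edge set exactly.
#'
#' @param net a `GlobalNetwork` as produced by [assemble_global_network].
#' @param path edge TSV path.
#' @return the TSV path, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "GlobalNetwork"))
  ed <- net$edges
  rk <- setNames(net$ranks$final_order, net$ranks$gene)
  df <- data.frame(source = ed$source, target = ed$target,
                   c_source_target = ed$c_st, c_target_source = ed$c_ts,
                   rank_source = unname(rk[ed$source]),
                   rank_target = unname(rk[ed$target]),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sif <- sub("\\.[^.]*$", ".sif", path)
  if (identical(sif, path)) sif <- paste0(path, ".sif")
  writeLines(if (nrow(df)) paste(df$source, "regulates", df$target) else character(0),
             sif)
  invisible(path)
}

#' Read a global network edge TSV written by [write_network]
#' @param path edge TSV path.
#' @return A `GlobalNetwork` (ranks reconstructed from the edge rows).
#' @export
read_network <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  edges <- data.frame(source = as.character(df$source),
                      target = as.character(df$target),
                      c_st = df$c_source_target, c_ts = df$c_target_source,
                      stringsAsFactors = FALSE)
  rk <- unique(data.frame(
    gene = c(edges$source, edges$target),
    final_order = c(df$rank_source, df$rank_target),
    stringsAsFactors = FALSE))
  rk <- rk[order(rk$final_order), , drop = FALSE]
  ranks <- data.frame(gene = rk$gene, mean_rank = as.numeric(rk$final_order),
                      sd_rank = rep(NA_real_, nrow(rk)),
                      final_order = rk$final_order,
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, ranks = ranks), class = "GlobalNetwork")
}

#' @export
print.GlobalNetwork <- function(x, ...) {
  cat(sprintf("GlobalNetwork: %d oriented edges over %d ranked genes\n",
              nrow(x$edges), nrow(x$ranks)))
  invisible(x)
}

#' Write discovered modules as TSV (one row per module)
#' @param modules list of modules from [discover_modules].
#' @param path file path.
#' @export
write_modules <- function(modules, path) {
  df <- data.frame(
    module_id = vapply(modules, function(m) m$id, ""),
    seed = vapply(modules, function(m) m$seed, ""),
    members = vapply(modules, function(m) paste(m$members, collapse = ","), ""),
    t2 = vapply(modules, function(m) m$t2, 0),
    pvalue = vapply(modules, function(m) m$pvalue, 0),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write module eQTL representatives as TSV
#' @param eqtls list of `ModuleEqtls` from [map_module_eqtls].
#' @param path file path.
#' @export
write_module_eqtls <- function(eqtls, path) {
  rows <- lapply(eqtls, function(me) {
    if (!nrow(me$eqtls)) return(NULL)
    cbind(module_id = me$module_id, me$eqtls)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(module_id = character(), snp_id = character(),
                     chrom = character(), pos = integer(),
                     block_id = character(), wilks_p = numeric())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a causation matrix as square TSV with gene ids
#' @param C integer causation matrix with dimnames.
#' @param path file path.
#' @export
write_causation_matrix <- function(C, path) {
  df <- data.frame(gene_id = rownames(C), C, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_causation_matrix
#' @export
read_causation_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  C <- as.matrix(df[, -1L, drop = FALSE])
  rownames(C) <- df[[1L]]
  storage.mode(C) <- "double"
  C
}
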