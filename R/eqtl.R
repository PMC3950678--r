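#' Cis-window candidate SNPs for a module
#'
#' Union over module members of SNPs lying within `window` basepairs of the
#' gene's transcription start or stop (i.e. position in
#' `[start - window, end + window]`) on the gene's chromosome. Unannotated
#' genes are skipped with a warning. Result is deduplicated and ordered by
#' (chromosome, position).
#'
#' @param module a `Module` (or any list with a `members` character vector).
#' @param genes a [gene_annotation].
#' @param geno a [genotype_matrix].
#' @param window cis window in basepairs (default 1e6).
#' @return character vector of SNP ids (possibly empty).
#' @export
cis_candidate_snps <- function(module, genes, geno, window = 1e6) {
  members <- module$members
  ann <- genes[genes$gene_id %in% members, , drop = FALSE]
  missing <- setdiff(members, ann$gene_id)
  if (length(missing))
    warning("unannotated module gene(s) skipped: ",
            paste(missing, collapse = ", "))
  pos <- geno$positions
  keep <- rep(FALSE, nrow(pos))
  for (i in seq_len(nrow(ann))) {
    keep <- keep | (pos$chrom == ann$chrom[i] &
                    pos$pos >= ann$start[i] - window &
                    pos$pos <= ann$end[i] + window)
  }
  hits <- pos[keep, , drop = FALSE]
  hits <- hits[order(hits$chrom, hits$pos), , drop = FALSE]
  unique(hits$snp_id)
}

#' Two-stage chromosome-wise SPLS SNP selection for a module
#'
#' Stage 1 runs an SPLS fit of the module expression on each chromosome's
#' candidate SNPs separately; stage 2 refits on the union of the stage-1
#' selections and returns its active set. Both stages are tuned independently
#' by cross-validation unless `eta`/`K` are fixed in `params`. SNPs
#' monomorphic in the aligned samples are dropped beforehand.
#'
#' @param module a `Module`.
#' @param geno a [genotype_matrix] (sample-aligned with `expr`).
#' @param expr an [expression_matrix].
#' @param genes a [gene_annotation].
#' @param params list of options: `window` (1e6), `eta_grid`, `K_grid`,
#'   `folds` (5), `seed`, and optional fixed `eta`, `K` (skip tuning).
#' @return character vector of selected SNP ids (possibly empty).
#' @export
two_stage_select <- function(module, geno, expr, genes, params = list()) {
  p <- modifyList(list(window = 1e6, eta_grid = seq(0.1, 0.9, by = 0.1),
                       K_grid = 1:5, folds = 5L, seed = 1L,
                       eta = NULL, K = NULL), params)
  cands <- cis_candidate_snps(module, genes, geno, p$window)
  if (!length(cands)) return(character(0))
  Y <- t(expr$values[module$members, , drop = FALSE])
  dos <- geno$dosages[cands, , drop = FALSE]
  mono <- apply(dos, 1L, function(v) length(unique(v)) < 2L)
  cands <- cands[!mono]
  if (!length(cands)) return(character(0))
  chroms <- geno$positions$chrom[match(cands, geno$positions$snp_id)]

  select_once <- function(snps, stage_seed) {
    X <- t(geno$dosages[snps, , drop = FALSE])
    if (is.null(p[["eta"]]) || is.null(p[["K"]])) {
      tuned <- tune_spls(X, Y, eta_grid = p$eta_grid, K_grid = p$K_grid,
                         folds = p$folds, seed = stage_seed)
      eta <- tuned$eta; K <- tuned$K
    } else { eta <- p[["eta"]]; K <- p[["K"]] }
    fit <- spls_fit(X, Y, eta = eta, K = K)
    snps[fit$selected]
  }

  stage1 <- character(0)
  for (ci in seq_along(sort(unique(chroms)))) {
    ch <- sort(unique(chroms))[ci]
    snps <- cands[chroms == ch]
    stage1 <- c(stage1, select_once(snps, derive_seed(p$seed, ci)))
  }
  if (!length(stage1)) return(character(0))
  if (length(unique(chroms)) == 1L) return(stage1)  # stage 2 degenerates
  select_once(stage1, derive_seed(p$seed, 0L))
}

#' Cluster SNPs into linkage blocks by complete-linkage position clustering
#'
#' Within each chromosome, SNPs are agglomeratively clustered on pairwise
#' basepair distance with complete linkage; the tree is cut at `cut_bp`
#' (default 500 kb, the conventional linkage-block size), so no block contains
#' two SNPs farther apart than the cut.
#'
#' @param snp_ids character vector of SNP ids.
#' @param geno a [genotype_matrix] supplying positions.
#' @param cut_bp complete-linkage cut distance in basepairs (default 5e5).
#' @return list of `SnpBlock` objects: lists with `chrom`, `members`,
#'   `representative` (NA until [manova_representative]), `wilks_p`.
#' @export
cluster_snp_blocks <- function(snp_ids, geno, cut_bp = 5e5) {
  if (!length(snp_ids)) return(list())
  pos <- geno$positions[match(snp_ids, geno$positions$snp_id), , drop = FALSE]
  if (anyNA(pos$snp_id)) stop("SNP(s) without positions")
  blocks <- list()
  for (ch in sort(unique(pos$chrom))) {
    sub <- pos[pos$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    if (nrow(sub) == 1L) {
      cl <- 1L
    } else {
      hc <- hclust(dist(sub$pos), method = "complete")
      cl <- cutree(hc, h = cut_bp)
    }
    for (k in sort(unique(cl))) {
      blocks[[length(blocks) + 1L]] <- structure(
        list(chrom = ch, members = sub$snp_id[cl == k],
             representative = NA_character_, wilks_p = NA_real_),
        class = "SnpBlock")
    }
  }
  # deterministic order: chromosome, then leftmost member position
  first_pos <- vapply(blocks, function(b)
    min(geno$positions$pos[match(b$members, geno$positions$snp_id)]), 0)
  chrom <- vapply(blocks, function(b) b$chrom, "")
  blocks[order(chrom, first_pos)]
}

#' Pick a block's representative SNP by MANOVA strength
#'
#' For every member SNP the module expression matrix is tested against the
#' genotype groups (the dosage levels present among \{0,1,2\}) by one-way
#' MANOVA; association strength is the Wilks' lambda p-value (an ordinary
#' one-way ANOVA F p-value when the module has a single gene). The
#' representative is the member with the smallest p-value; ties and
#' monomorphic members (assigned p = 1) resolve to the smaller position.
#'
#' @param block a `SnpBlock` from [cluster_snp_blocks].
#' @param Y samples x genes module expression matrix.
#' @param geno a [genotype_matrix].
#' @return the block with `representative` and `wilks_p` filled.
#' @export
manova_representative <- function(block, Y, geno) {
  if (!length(block$members)) stop("empty SNP block")
  Y <- as.matrix(Y)
  pvals <- vapply(block$members, function(s) {
    g <- factor(geno$dosages[s, ])
    if (nlevels(g) < 2L) return(1)
    p <- tryCatch({
      if (ncol(Y) >= 2L) {
        fit <- manova(Y ~ g)
        summary(fit, test = "Wilks")$stats[1L, "Pr(>F)"]
      } else {
        anova(lm(Y[, 1L] ~ g))[["Pr(>F)"]][1L]
      }
    }, error = function(e) 1)
    if (is.na(p)) 1 else p
  }, numeric(1L))
  pos <- geno$positions$pos[match(block$members, geno$positions$snp_id)]
  ord <- order(pvals, pos)
  block$representative <- block$members[ord[1L]]
  block$wilks_p <- unname(pvals[ord[1L]])
  block
}

#' Map the driving eQTLs of one module
#'
#' Pipeline: cis-window candidates -> two-stage SPLS selection -> 500-kb
#' complete-linkage SNP blocks -> one MANOVA representative per block.
#'
#' @inheritParams two_stage_select
#' @param params see [two_stage_select]; additionally `block_cut` (default 5e5).
#' @return An object of class `ModuleEqtls`: list with `module_id` and an
#'   `eqtls` data.frame (snp_id, chrom, pos, block_id, wilks_p), empty when no
#'   SNP was selected.
#' @export
map_module_eqtls <- function(module, geno, expr, genes, params = list()) {
  block_cut <- if (is.null(params$block_cut)) 5e5 else params$block_cut
  sel <- two_stage_select(module, geno, expr, genes, params)
  empty <- data.frame(snp_id = character(), chrom = character(),
                      pos = integer(), block_id = character(),
                      wilks_p = numeric(), stringsAsFactors = FALSE)
  if (!length(sel))
    return(structure(list(module_id = module$id, eqtls = empty),
                     class = "ModuleEqtls"))
  blocks <- cluster_snp_blocks(sel, geno, block_cut)
  Y <- t(expr$values[module$members, , drop = FALSE])
  rows <- lapply(seq_along(blocks), function(i) {
    b <- manova_representative(blocks[[i]], Y, geno)
    data.frame(snp_id = b$representative, chrom = b$chrom,
               pos = geno$positions$pos[match(b$representative,
                                              geno$positions$snp_id)],
               block_id = sprintf("%s_block%d", module$id, i),
               wilks_p = b$wilks_p, stringsAsFactors = FALSE)
  })
  structure(list(module_id = module$id, eqtls = do.call(rbind, rows)),
            class = "ModuleEqtls")
}

#' @export
print.ModuleEqtls <- function(x, ...) {
  cat(sprintf("ModuleEqtls %s: %d representative SNP(s)\n",
              x$module_id, nrow(x$eqtls)))
  invisible(x)
}

## internal: deterministic sub-seed derivation (Lehmer step, stays < 2^31 - 1)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483647)
}
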