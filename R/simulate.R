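#' Ground-truth model for synthetic genetical-genomics data
#'
#' Builds the causal truth that the generator realizes: per module a linear
#' chain of genes (g1 -> g2 -> ... with effect `edge_effect`), one cis-eQTL
#' linkage block whose anchor SNP drives the module's head gene with effect
#' `eqtl_effect`, and a phenotype group shift `group_effect` on the head gene
#' (propagating down the chain), which is what makes the module
#' discriminative. Optional condition-gated edges (active only in group 1)
#' emulate disease-specific coexpression rewiring. A pool of background noise
#' genes and decoy SNP blocks provides realistic negatives.
#'
#' Genomic layout per module m (chromosome `as.character(m)`): genes every
#' 60 kb from 1.2 Mb; the causal eQTL block (anchor + `ld_size - 1` linked
#' SNPs, 10 kb apart) at 0.9 Mb; decoy blocks of 2 SNPs at 1.6 Mb and 2.2 Mb
#' (each > 500 kb from the causal block, inside the cis windows). Background
#' genes sit from 3 Mb onward.
#'
#' @param n_modules number of causal modules (default 6).
#' @param genes_per_module chain length per module (default 5).
#' @param edge_effect linear effect of each chain edge (default 0.8).
#' @param eqtl_effect per-dosage effect of the anchor SNP on the head gene
#'   (default 1).
#' @param group_effect phenotype-group mean shift on each head gene
#'   (default 0.5, about one residual SD).
#' @param noise_sd residual SD of every gene (default 0.5).
#' @param maf minor allele frequency of anchor and decoy SNPs (default 0.3).
#' @param ld_size SNPs per causal linkage block (default 3).
#' @param ld_eps per-sample probability that a linked SNP is redrawn instead
#'   of copying its anchor (default 0.05).
#' @param n_background background noise genes (default 30).
#' @param condition_edges integer: number of chain edges (one per module, the
#'   last edge, up to this count) that are active only in phenotype group 1
#'   (default 0).
#' @param seed integer seed for the gene-label assignment. Gene ids are drawn
#'   as a seeded random permutation of `G001, G002, ...` so that, as with real
#'   gene symbols, lexicographic order carries no information about causal
#'   order (several downstream tie-breaks are lexicographic and must not be
#'   able to recover the truth from names alone).
#' @return An object of class `TruthModel`: list with `genes`, `dag`
#'   (from, to, beta, condition), `eqtl_map` (snp_id, gene, effect),
#'   `group_effects`, `noise_sd`, `maf`, `ld_eps`, `snp_layout`,
#'   `gene_annotation`.
#' @export
truth_model <- function(n_modules = 6L, genes_per_module = 5L,
                        edge_effect = 0.8, eqtl_effect = 1,
                        group_effect = 0.5, noise_sd = 0.5, maf = 0.3,
                        ld_size = 3L, ld_eps = 0.05, n_background = 30L,
                        condition_edges = 0L, seed = 1L) {
  if (maf <= 0 || maf > 0.5) stop("maf must be in (0, 0.5]")
  n_genes <- n_modules * genes_per_module + n_background
  set.seed(seed)
  labels_pool <- sample(sprintf("G%03d", seq_len(n_genes)))
  mods <- lapply(seq_len(n_modules), function(m) {
    labels_pool[(m - 1L) * genes_per_module + seq_len(genes_per_module)]
  })
  bg <- if (n_background > 0L) {
    labels_pool[n_modules * genes_per_module + seq_len(n_background)]
  } else character(0)
  dag <- do.call(rbind, lapply(seq_len(n_modules), function(m) {
    g <- mods[[m]]
    if (length(g) < 2L) return(NULL)
    data.frame(from = g[-length(g)], to = g[-1L], beta = edge_effect,
               condition = FALSE, stringsAsFactors = FALSE)
  }))
  if (is.null(dag))
    dag <- data.frame(from = character(), to = character(), beta = numeric(),
                      condition = logical())
  if (condition_edges > 0L) {
    # gate the last chain edge of the first `condition_edges` modules
    for (m in seq_len(min(condition_edges, n_modules))) {
      g <- mods[[m]]
      idx <- which(dag$from == g[length(g) - 1L] & dag$to == g[length(g)])
      dag$condition[idx] <- TRUE
    }
  }
  snp_rows <- list(); eqtl_rows <- list()
  for (m in seq_len(n_modules)) {
    ch <- as.character(m)
    anchor <- sprintf("S%02dQ1", m)
    block <- c(anchor,
               if (ld_size > 1L) sprintf("S%02dQ%d", m, 2:ld_size))
    snp_rows[[length(snp_rows) + 1L]] <- data.frame(
      snp_id = block, chrom = ch, pos = 9e5 + (seq_along(block) - 1L) * 1e4,
      block = sprintf("causal_%02d", m), anchor = anchor,
      stringsAsFactors = FALSE)
    for (dk in 1:2) {
      danchor <- sprintf("S%02dD%d1", m, dk)
      dblock <- c(danchor, sprintf("S%02dD%d2", m, dk))
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        snp_id = dblock, chrom = ch,
        pos = c(1.6e6, 2.2e6)[dk] + (seq_along(dblock) - 1L) * 1e4,
        block = sprintf("decoy_%02d_%d", m, dk), anchor = danchor,
        stringsAsFactors = FALSE)
    }
    eqtl_rows[[length(eqtl_rows) + 1L]] <- data.frame(
      snp_id = anchor, gene = mods[[m]][1L], effect = eqtl_effect,
      stringsAsFactors = FALSE)
  }
  snp_layout <- do.call(rbind, snp_rows)
  ann_mod <- do.call(rbind, lapply(seq_len(n_modules), function(m) {
    g <- mods[[m]]
    start <- 1.2e6 + (seq_along(g) - 1L) * 6e4
    data.frame(gene_id = g, chrom = as.character(m), start = start,
               end = start + 1e4, stringsAsFactors = FALSE)
  }))
  ann_bg <- if (length(bg)) {
    chrom <- as.character(rep_len(seq_len(max(n_modules, 1L)), length(bg)))
    start <- 3e6 + 1e5 * (seq_along(bg) - 1L)
    data.frame(gene_id = bg, chrom = chrom, start = start, end = start + 1e4,
               stringsAsFactors = FALSE)
  } else NULL
  structure(list(
    genes = c(unlist(mods), bg), modules = mods, background = bg,
    dag = dag,
    eqtl_map = do.call(rbind, eqtl_rows),
    group_effects = data.frame(gene = vapply(mods, `[`, "", 1L),
                               delta = group_effect, stringsAsFactors = FALSE),
    noise_sd = noise_sd, maf = maf, ld_eps = ld_eps,
    snp_layout = snp_layout,
    gene_annotation = gene_annotation(rbind(ann_mod, ann_bg))),
    class = "TruthModel")
}

#' Simulate genotypes under the truth model
#'
#' Block-anchor SNPs are drawn `Binomial(2, maf)` (Hardy-Weinberg); the other
#' SNPs of a block copy their anchor, except that each sample is independently
#' redrawn from `Binomial(2, maf)` with probability `ld_eps`, producing strong
#' but imperfect within-block linkage.
#'
#' @param truth a [truth_model].
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @return A [genotype_matrix].
#' @export
simulate_genotypes <- function(truth, n_samples, seed = 1L) {
  set.seed(seed)
  layout <- truth$snp_layout
  samples <- sprintf("S%03d", seq_len(n_samples))
  dos <- matrix(0, nrow(layout), n_samples,
                dimnames = list(layout$snp_id, samples))
  for (bl in unique(layout$block)) {
    rows <- which(layout$block == bl)
    anchor_id <- layout$anchor[rows[1L]]
    anchor_dos <- rbinom(n_samples, 2L, truth$maf)
    for (r in rows) {
      if (layout$snp_id[r] == anchor_id) {
        dos[r, ] <- anchor_dos
      } else {
        flip <- runif(n_samples) < truth$ld_eps
        dos[r, ] <- ifelse(flip, rbinom(n_samples, 2L, truth$maf), anchor_dos)
      }
    }
  }
  genotype_matrix(dos, data.frame(snp_id = layout$snp_id,
                                  chrom = layout$chrom, pos = layout$pos,
                                  stringsAsFactors = FALSE))
}

#' Balanced two-group phenotype labels for simulated samples
#' @param n_samples number of samples (first half "case", second "control").
#' @return A [phenotype_labels].
#' @export
simulate_labels <- function(n_samples) {
  samples <- sprintf("S%03d", seq_len(n_samples))
  phenotype_labels(samples, rep(c("case", "control"),
                                c(ceiling(n_samples / 2), floor(n_samples / 2))))
}

#' Simulate expression from the linear-Gaussian structural equation model
#'
#' In topological order of the truth DAG, each gene is the sum of its parents'
#' values times the edge effects (condition-gated edges contribute only in
#' phenotype group 1), its eQTL dosages times their effects, its group shift,
#' and Gaussian noise with SD `noise_sd`.
#'
#' @param truth a [truth_model].
#' @param geno a [genotype_matrix] from [simulate_genotypes].
#' @param labels a [phenotype_labels] over the same samples.
#' @param seed integer seed.
#' @return An [expression_matrix].
#' @export
simulate_expression <- function(truth, geno, labels, seed = 1L) {
  set.seed(seed)
  samples <- geno$sample_ids
  labels <- reorder_labels(labels, samples)
  in_g1 <- labels$labels == levels(labels$labels)[1L]
  genes <- truth$genes
  n <- length(samples)
  X <- matrix(0, length(genes), n, dimnames = list(genes, samples))
  order_genes <- topo_sort_genes(genes, truth$dag)
  for (g in order_genes) {
    val <- rnorm(n, 0, truth$noise_sd)
    pe <- truth$dag[truth$dag$to == g, , drop = FALSE]
    for (k in seq_len(nrow(pe))) {
      gate <- if (pe$condition[k]) in_g1 else TRUE
      val <- val + pe$beta[k] * X[pe$from[k], ] * gate
    }
    qe <- truth$eqtl_map[truth$eqtl_map$gene == g, , drop = FALSE]
    for (k in seq_len(nrow(qe)))
      val <- val + qe$effect[k] * geno$dosages[qe$snp_id[k], ]
    de <- truth$group_effects[truth$group_effects$gene == g, , drop = FALSE]
    if (nrow(de)) val <- val + de$delta[1L] * in_g1
    X[g, ] <- val
  }
  expression_matrix(X)
}

## topological order of gene ids under the truth dag (cycle -> error)
topo_sort_genes <- function(genes, dag) {
  indeg <- setNames(rep(0L, length(genes)), genes)
  tab <- table(dag$to)
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  ready <- sort(names(indeg)[indeg == 0L])
  while (length(ready)) {
    g <- ready[1L]; ready <- ready[-1L]
    out <- c(out, g)
    kids <- dag$to[dag$from == g]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) ready <- sort(c(ready, k))
    }
  }
  if (length(out) != length(genes)) stop("cycle detected in truth dag")
  out
}

#' Build a synthetic interactome: truth skeleton plus decoy edges
#'
#' The undirected skeleton of the truth DAG plus `n_decoy_edges` random
#' non-truth gene pairs (no duplicates, no self-loops) drawn over the full
#' gene universe including background genes.
#'
#' @param truth a [truth_model].
#' @param n_decoy_edges number of decoy edges.
#' @param seed integer seed.
#' @return An [interactome].
#' @export
make_interactome <- function(truth, n_decoy_edges = 300L, seed = 1L) {
  set.seed(seed)
  genes <- truth$genes
  skel <- unique(data.frame(
    gene1 = pmin(truth$dag$from, truth$dag$to),
    gene2 = pmax(truth$dag$from, truth$dag$to), stringsAsFactors = FALSE))
  all_pairs <- t(combn(sort(genes), 2L))
  keys <- paste(all_pairs[, 1L], all_pairs[, 2L], sep = "\r")
  truth_keys <- paste(skel$gene1, skel$gene2, sep = "\r")
  avail <- which(!keys %in% truth_keys)
  if (n_decoy_edges > length(avail))
    stop("requested ", n_decoy_edges, " decoy edges but only ",
         length(avail), " non-truth pairs exist")
  decoys <- all_pairs[sample(avail, n_decoy_edges), , drop = FALSE]
  interactome(rbind(as.matrix(skel), decoys))
}

#' Simulate a complete synthetic genetical-genomics dataset
#'
#' Convenience wrapper: [truth_model] + [simulate_genotypes] +
#' [simulate_labels] + [simulate_expression] + [make_interactome], with
#' sub-seeds derived from one master seed.
#'
#' @param n_samples number of samples (default 200).
#' @param n_decoy_edges decoy interactome edges (default 300).
#' @param seed master integer seed.
#' @param ... passed to [truth_model].
#' @return list with `truth`, `expr`, `geno`, `labels`, `interactome`,
#'   `gene_annotation`.
#' @export
simulate_dataset <- function(n_samples = 200L, n_decoy_edges = 300L,
                             seed = 1L, ...) {
  truth <- truth_model(seed = derive_seed(seed, 10L), ...)
  geno <- simulate_genotypes(truth, n_samples, seed = derive_seed(seed, 11L))
  labels <- simulate_labels(n_samples)
  expr <- simulate_expression(truth, geno, labels,
                              seed = derive_seed(seed, 12L))
  net <- make_interactome(truth, n_decoy_edges, seed = derive_seed(seed, 13L))
  list(truth = truth, expr = expr, geno = geno, labels = labels,
       interactome = net, gene_annotation = truth$gene_annotation)
}

#' Concordance of an inferred oriented network with a directed reference
#'
#' Only inferred edges whose unordered pair occurs in the reference are
#' compared (edges absent from the reference, and reference edges not
#' inferred, are ignored): `concordant` counts matching orientations,
#' `inverted` the rest, and `rate = concordant / overlap`. Zero overlap
#' leaves the rate `NA` with a warning.
#'
#' @param inferred data.frame with columns `source`, `target` (e.g.
#'   `GlobalNetwork$edges` or [major_direction_network] output).
#' @param reference data.frame with columns `from`, `to` (e.g.
#'   `truth$dag`).
#' @return list with `concordant`, `inverted`, `overlap`, `rate`.
#' @export
evaluate_concordance <- function(inferred, reference) {
  ref_fwd <- paste(reference$from, reference$to, sep = "\r")
  ref_pairs <- paste(pmin(reference$from, reference$to),
                     pmax(reference$from, reference$to), sep = "\r")
  inf_dir <- paste(inferred$source, inferred$target, sep = "\r")
  inf_pairs <- paste(pmin(inferred$source, inferred$target),
                     pmax(inferred$source, inferred$target), sep = "\r")
  in_ref <- inf_pairs %in% ref_pairs
  overlap <- sum(in_ref)
  if (!overlap) {
    warning("no inferred edge overlaps the reference; rate undefined")
    return(list(concordant = 0L, inverted = 0L, overlap = 0L, rate = NA_real_))
  }
  concordant <- sum(inf_dir[in_ref] %in% ref_fwd)
  list(concordant = concordant, inverted = overlap - concordant,
       overlap = overlap, rate = concordant / overlap)
}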