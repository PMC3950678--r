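#' Overall and between-group correlations for interactome edges
#'
#' For every interaction (x1, x2) with both genes in the expression matrix,
#' computes `r1 = |PCC(x1, x2)|` over all samples and
#' `r2 = |PCC within group 1 - PCC within group 2|`, the differential
#' coexpression signal. Edges with a gene absent from the expression matrix, or
#' with constant expression in any required stratum (correlation undefined),
#' are skipped; the skipped count is reported via `message()`.
#'
#' @param expr an [expression_matrix].
#' @param labels a [phenotype_labels] covering the expression samples; each
#'   group must have at least 3 samples.
#' @param net an [interactome].
#' @return data.frame with columns `gene1`, `gene2`, `r1`, `r2`.
#' @export
interaction_correlations <- function(expr, labels, net) {
  labels <- reorder_labels(labels, expr$sample_ids)
  grp <- labels$labels
  if (any(table(grp) < 3L)) stop("each phenotype group needs at least 3 samples")
  present <- net$gene1 %in% expr$gene_ids & net$gene2 %in% expr$gene_ids
  if (any(!present))
    message(sum(!present), " interaction(s) skipped: gene not in expression matrix")
  ed <- net[present, , drop = FALSE]
  if (!nrow(ed)) return(data.frame(gene1 = character(), gene2 = character(),
                                   r1 = numeric(), r2 = numeric()))
  pair_cor <- function(cols) {
    # row-standardize, then pairwise PCC as a scaled inner product
    X <- expr$values[, cols, drop = FALSE]
    n <- ncol(X)
    Z <- X - rowMeans(X)
    s <- sqrt(rowSums(Z^2))
    Z <- Z / ifelse(s > 0, s, NA_real_)
    rowSums(Z[ed$gene1, , drop = FALSE] * Z[ed$gene2, , drop = FALSE])
  }
  g1 <- labels$sample_ids[grp == levels(grp)[1L]]
  g2 <- labels$sample_ids[grp == levels(grp)[2L]]
  r_all <- pair_cor(labels$sample_ids)
  r_g1 <- pair_cor(g1)
  r_g2 <- pair_cor(g2)
  out <- data.frame(gene1 = ed$gene1, gene2 = ed$gene2,
                    r1 = abs(r_all), r2 = abs(r_g1 - r_g2),
                    stringsAsFactors = FALSE)
  ok <- stats::complete.cases(out)
  if (any(!ok))
    message(sum(!ok), " interaction(s) skipped: undefined correlation ",
            "(constant expression)")
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentile ranks (fraction of values <= each value)
#'
#' The maximum maps to 1.0 and ties share a percentile, matching the exclusion
#' rule "below the 90th percentile".
#'
#' @param values nonempty numeric vector.
#' @return numeric vector of percentiles in (0, 1].
#' @export
percentile_rank <- function(values) {
  if (!length(values)) stop("percentile_rank: empty value list")
  rank(values, ties.method = "max") / length(values)
}

#' Bonding scores for scored interactions
#'
#' Each interaction receives two percentiles: `q1`, the percentile of its
#' overall coexpression `r1`, and `q2`, the percentile of its between-group
#' correlation difference `r2`, both taken over all retained interactions.
#' The bonding score is `max(q1, q2)`: an interaction bonds strongly if it
#' either correlates highly across all samples or displays a large disparity
#' between the two phenotype groups.
#'
#' @param scores data.frame from [interaction_correlations].
#' @return the same data.frame with columns `q1`, `q2`, `bonding` appended.
#' @export
bonding_scores <- function(scores) {
  if (!nrow(scores)) {
    scores$q1 <- numeric(0); scores$q2 <- numeric(0); scores$bonding <- numeric(0)
    return(scores)
  }
  scores$q1 <- percentile_rank(scores$r1)
  scores$q2 <- percentile_rank(scores$r2)
  scores$bonding <- pmax(scores$q1, scores$q2)
  scores
}

#' Two-sample Hotelling T-squared test
#'
#' `T2 = (n1 n2 / (n1 + n2)) d' S_pooled^-1 d` with `d` the difference of group
#' mean vectors and `S_pooled` the pooled covariance; the p-value comes from
#' `F = ((n1 + n2 - p - 1) / (p (n1 + n2 - 2))) T2` on `(p, n1 + n2 - p - 1)`
#' degrees of freedom. A computationally singular pooled covariance is
#' regularized with a ridge `1e-6 * trace(S)/p` on the diagonal.
#'
#' @param x numeric matrix, p variables (genes) in rows, n samples in columns.
#' @param labels a [phenotype_labels], or a length-n vector/factor with two
#'   levels in column order of `x`.
#' @return list with elements `t2`, `pvalue`, `df` (c(p, n1 + n2 - p - 1)).
#' @export
hotelling_t2 <- function(x, labels) {
  x <- rbind(x)  # keep matrix shape for p = 1
  if (inherits(labels, "PhenotypeLabels")) {
    if (is.null(colnames(x))) {
      stopifnot(ncol(x) == length(labels$sample_ids))
      grp <- labels$labels
    } else grp <- reorder_labels(labels, colnames(x))$labels
  } else grp <- factor(labels)
  if (nlevels(grp) != 2L) stop("hotelling_t2 needs exactly two groups")
  p <- nrow(x)
  x1 <- x[, grp == levels(grp)[1L], drop = FALSE]
  x2 <- x[, grp == levels(grp)[2L], drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  if (p >= n1 + n2 - 1L)
    stop("hotelling_t2 needs p < n1 + n2 - 1 (got p = ", p, ", n = ", n1 + n2, ")")
  d <- rowMeans(x1) - rowMeans(x2)
  c1 <- x1 - rowMeans(x1); c2 <- x2 - rowMeans(x2)
  S <- (tcrossprod(c1) + tcrossprod(c2)) / (n1 + n2 - 2L)
  sol <- tryCatch(solve(S, d), error = function(e) {
    ridge <- 1e-6 * sum(diag(S)) / p
    if (ridge <= 0) ridge <- 1e-12
    solve(S + diag(ridge, p), d)
  })
  t2 <- (n1 * n2 / (n1 + n2)) * sum(d * sol)
  fstat <- (n1 + n2 - p - 1) / (p * (n1 + n2 - 2)) * t2
  pval <- pf(fstat, p, n1 + n2 - p - 1, lower.tail = FALSE)
  list(t2 = t2, pvalue = pval, df = c(p, n1 + n2 - p - 1))
}

#' Grow a phenotype-discriminative module from a seed gene
#'
#' Greedy expansion over the scored interactome: at each round the interactions
#' linking a current member to an outside neighbor are collected, candidates
#' are tried in decreasing bonding order (ties broken lexicographically by gene
#' id), and only candidates with bonding above `r_cut` are eligible. A
#' candidate is admitted iff the Hotelling T-squared test of the enlarged
#' member set is significant at `alpha`. Expansion stops when no eligible
#' candidate passes, or the module reaches `size_cap`.
#'
#' @param seed gene id, present in both interactome and expression matrix.
#' @param scores bonding-scored interactions from [bonding_scores].
#' @param expr an [expression_matrix].
#' @param labels a [phenotype_labels].
#' @param r_cut bonding percentile cutoff (default 0.90: interactions below
#'   the 90th percentile are never used).
#' @param alpha Hotelling significance gate (default 0.05).
#' @param size_cap maximum module size (default 10; larger modules rarely share
#'   driving eQTLs and inflate subnetwork learning cost).
#' @return A `Module`: list with `seed`, `members` (insertion order), `t2`,
#'   `pvalue` of the final member set, and a per-step `trace` data.frame.
#' @export
expand_module <- function(seed, scores, expr, labels, r_cut = 0.90,
                          alpha = 0.05, size_cap = 10L) {
  if (!seed %in% expr$gene_ids) stop("seed gene '", seed, "' not in expression matrix")
  in_net <- seed %in% scores$gene1 | seed %in% scores$gene2
  members <- seed
  trace <- list()
  labels <- reorder_labels(labels, expr$sample_ids)
  n <- length(expr$sample_ids)
  if (in_net) repeat {
    if (length(members) >= size_cap) break
    on1 <- scores$gene1 %in% members
    on2 <- scores$gene2 %in% members
    frontier <- scores[xor(on1, on2), , drop = FALSE]
    if (!nrow(frontier)) break
    cand_gene <- ifelse(frontier$gene1 %in% members, frontier$gene2, frontier$gene1)
    # best bonding per outside gene
    best <- tapply(frontier$bonding, cand_gene, max)
    cand <- data.frame(gene = names(best), bonding = as.numeric(best),
                       stringsAsFactors = FALSE)
    cand <- cand[cand$bonding > r_cut, , drop = FALSE]
    cand <- cand[order(-cand$bonding, cand$gene), , drop = FALSE]
    admitted_one <- FALSE
    for (k in seq_len(nrow(cand))) {
      g <- cand$gene[k]
      trial <- c(members, g)
      if (length(trial) >= n - 1L) next  # Hotelling needs p < n - 1
      ht <- hotelling_t2(expr$values[trial, , drop = FALSE], labels)
      trace[[length(trace) + 1L]] <-
        data.frame(candidate = g, bonding = cand$bonding[k],
                   pvalue = ht$pvalue, admitted = ht$pvalue < alpha,
                   stringsAsFactors = FALSE)
      if (ht$pvalue < alpha) {
        members <- trial
        admitted_one <- TRUE
        break
      }
    }
    if (!admitted_one) break
  }
  ht <- hotelling_t2(expr$values[members, , drop = FALSE], labels)
  structure(list(id = paste0("mod_", seed), seed = seed, members = members,
                 t2 = ht$t2, pvalue = ht$pvalue,
                 trace = if (length(trace)) do.call(rbind, trace) else
                   data.frame(candidate = character(), bonding = numeric(),
                              pvalue = numeric(), admitted = logical())),
            class = "Module")
}

#' @export
print.Module <- function(x, ...) {
  cat(sprintf("Module %s (seed %s): %d member(s), T2 = %.3g, p = %.3g\n",
              x$id, x$seed, length(x$members), x$t2, x$pvalue))
  invisible(x)
}

#' Discover discriminative modules from every seed gene
#'
#' Runs [expand_module] from every gene in the intersection of the interactome
#' and expression universes, drops singleton modules, and deduplicates modules
#' with identical member sets (keeping the first seed's record). Overlapping
#' modules are retained.
#'
#' @inheritParams expand_module
#' @param net an [interactome].
#' @return list of `Module` objects.
#' @export
discover_modules <- function(expr, labels, net, r_cut = 0.90, alpha = 0.05,
                             size_cap = 10L) {
  scores <- bonding_scores(interaction_correlations(expr, labels, net))
  seeds <- sort(intersect(attr(net, "genes"), expr$gene_ids))
  mods <- lapply(seeds, expand_module, scores = scores, expr = expr,
                 labels = labels, r_cut = r_cut, alpha = alpha,
                 size_cap = size_cap)
  mods <- Filter(function(m) length(m$members) > 1L, mods)
  keys <- vapply(mods, function(m) paste(sort(m$members), collapse = "\r"), "")
  mods[!duplicated(keys)]
}
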