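#' Posterior-mean control potentials from a causation matrix
#'
#' The control potential `P[i, j]` — the probability that gene i directly
#' alters the activity of gene j — gets a conjugate Beta posterior
#' `Beta(1 + c_ij, 1 + c_ji)` from the causation records; this returns its
#' posterior mean `(c_ij + 1) / (c_ij + c_ji + 2)`, so `P[j, i] = 1 - P[i, j]`
#' and unobserved pairs sit at the symmetric 0.5.
#'
#' @param C causation matrix from [accumulate_causation].
#' @return numeric matrix `P` with `P[i, j] + P[j, i] = 1` off-diagonal
#'   (diagonal fixed at 0.5, unused).
#' @export
control_potentials <- function(C) {
  C <- as.matrix(C)
  P <- (C + 1) / (C + t(C) + 2)
  diag(P) <- 0.5
  P
}

#' Sample K control-potential fields from the Beta posteriors
#'
#' Each replicate draws `P[i, j] ~ Beta(1 + c_ij, 1 + c_ji)` independently for
#' every supported pair (`c_ij + c_ji >= 1`, i < j) and sets
#' `P[j, i] = 1 - P[i, j]`. Pairs with no causation record carry no
#' orientation evidence and stay at the neutral 0.5, where they can never be
#' counted as ranking errors (they may still be moved off 0.5 later by
#' transitive enhancement). Reproducible under `seed`.
#'
#' @param C causation matrix.
#' @param K number of replicate fields (default 100).
#' @param seed integer seed.
#' @return list of K control-potential matrices.
#' @export
sample_control_fields <- function(C, K = 100L, seed = 1L) {
  if (K < 1L) stop("K must be >= 1")
  C <- as.matrix(C)
  N <- nrow(C)
  ut <- upper.tri(C) & (C + t(C)) >= 1
  a <- 1 + C[ut]; b <- 1 + t(C)[ut]
  set.seed(seed)
  lapply(seq_len(K), function(k) {
    P <- matrix(0.5, N, N, dimnames = dimnames(C))
    draws <- rbeta(length(a), a, b)
    P[ut] <- draws
    P_t <- t(P); P_t[ut] <- 1 - draws
    P[lower.tri(P)] <- t(P_t)[lower.tri(P)]
    P
  })
}

#' Enhance control potentials with one-intermediate transitive odds
#'
#' Direct control odds are `O_ij = P_ij / (1 - P_ij)`. For every common
#' neighbor h of i and j in the support graph (pairs with any causation
#' count), the transitive odds of the length-2 path are
#' `T_ihj = P_ih P_hj / (1 - P_ih P_hj)`; terms with `T <= 1` carry weak
#' transitive information and are discarded. The overall control odds combine
#' direct and retained transitive evidence elementwise,
#' `W_ij = max(O_ij, max_h T_ihj)`, and the enhanced control potential is the
#' renormalization `P*_ij = W_ij / (W_ij + W_ji)`. Only path length R = 1
#' (one intermediate gene) is supported.
#'
#' @param P control-potential matrix ([control_potentials] or one sampled
#'   field).
#' @param support_adj logical adjacency of the support graph (typically
#'   `(C + t(C)) >= 1`); dimnames must match `P`.
#' @param R path length; only 1 is supported.
#' @return An object of class `OddsMatrices`: list with `O` (direct odds),
#'   `W` (overall odds), `Pstar` (enhanced potentials).
#' @export
enhanced_control_potentials <- function(P, support_adj, R = 1L) {
  if (!identical(as.integer(R), 1L)) stop("only R = 1 is supported")
  P <- as.matrix(P)
  N <- nrow(P)
  eps <- 1e-12
  if (any(P <= 0 | P >= 1)) {
    warning("control potentials at 0/1 clamped to [1e-12, 1 - 1e-12]")
    P <- pmin(pmax(P, eps), 1 - eps)
  }
  adj <- (as.matrix(support_adj) != 0)
  diag(adj) <- FALSE
  O <- P / (1 - P)
  diag(O) <- 1
  W <- O
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    hs <- which(adj[i, ] & adj[, j])
    hs <- setdiff(hs, c(i, j))
    if (!length(hs)) next
    prod_ih_hj <- P[i, hs] * P[hs, j]
    trans <- prod_ih_hj / (1 - prod_ih_hj)
    trans <- trans[trans > 1]
    if (length(trans)) W[i, j] <- max(W[i, j], max(trans))
  }
  Pstar <- W / (W + t(W))
  diag(Pstar) <- 0.5
  structure(list(O = O, W = W, Pstar = Pstar), class = "OddsMatrices")
}

## ranking cost: number of lower-triangle entries > 0.5 after permuting
## Pstar rows/columns into rank order (an "error" is a lower-ranked gene
## regulating a higher-ranked one)
rank_cost <- function(Pstar, ord) {
  M <- Pstar[ord, ord]
  sum(M[lower.tri(M)] > 0.5)
}

#' Optimal rank order of a control-potential field by simulated annealing
#'
#' Finds a permutation of the genes minimizing the number of lower-triangle
#' entries of the permuted enhanced-potential matrix that exceed 0.5.
#' Proposals are random transpositions of two rank positions, accepted by the
#' Metropolis rule `exp(-deltaJ / T)` under a geometric cooling schedule
#' `T_t = T0 * alpha^t`. Stops early after `patience` proposals without a new
#' best, or when a zero-cost order is found. Returns the best-seen
#' permutation; deterministic under `seed`.
#'
#' @param Pstar enhanced control-potential matrix (dimnames = genes).
#' @param iters maximum proposals (default 20000).
#' @param T0 initial temperature (default 1).
#' @param cooling geometric cooling factor (default 0.9995).
#' @param patience early stop after this many non-improving proposals
#'   (default 5000).
#' @param seed integer seed.
#' @return character vector of gene ids, highest (most upstream) rank first,
#'   with attribute `cost` (the achieved error count).
#' @export
anneal_rank <- function(Pstar, iters = 20000L, T0 = 1, cooling = 0.9995,
                        patience = 5000L, seed = 1L) {
  N <- nrow(Pstar)
  genes <- rownames(Pstar)
  if (is.null(genes)) genes <- as.character(seq_len(N))
  set.seed(seed)
  gt <- Pstar > 0.5   # precomputed comparisons; all costs depend only on these
  ord <- sample.int(N)  # random start: the input row order carries no rank info
  if (N < 2L) ord <- seq_len(N)
  J <- rank_cost_logical(gt, ord)
  best_ord <- ord; best_J <- J
  since_best <- 0L
  temp <- T0
  if (N >= 2L) for (it in seq_len(iters)) {
    ab <- sort(sample.int(N, 2L))
    a <- ab[1L]; b <- ab[2L]
    u <- ord[a]; v <- ord[b]
    dJ <- (gt[u, v] - gt[v, u])
    if (b - a > 1L) {
      mid <- ord[(a + 1L):(b - 1L)]
      dJ <- dJ + sum(gt[mid, v]) + sum(gt[u, mid]) -
                 sum(gt[mid, u]) - sum(gt[v, mid])
    }
    if (dJ <= 0 || runif(1L) < exp(-dJ / temp)) {
      ord[a] <- v; ord[b] <- u
      J <- J + dJ
      if (J < best_J) {
        best_J <- J; best_ord <- ord; since_best <- 0L
      } else since_best <- since_best + 1L
    } else since_best <- since_best + 1L
    if (best_J == 0L || since_best >= patience) break
    temp <- temp * cooling
  }
  structure(genes[best_ord], cost = best_J)
}

## cost from the precomputed ">0.5" logical matrix
rank_cost_logical <- function(gt, ord) {
  M <- gt[ord, ord]
  sum(M[lower.tri(M)])
}

#' Exhaustive rank-order minimization (test oracle)
#'
#' Enumerates all permutations (N <= 9) and returns the cost-minimal order;
#' ties resolve to the lexicographically smallest permutation (by position in
#' the row order of `Pstar`).
#'
#' @inheritParams anneal_rank
#' @return character vector of gene ids with attribute `cost`.
#' @export
brute_force_rank <- function(Pstar) {
  N <- nrow(Pstar)
  if (N > 9L) stop("brute_force_rank supports N <= 9")
  genes <- rownames(Pstar)
  if (is.null(genes)) genes <- as.character(seq_len(N))
  gt <- Pstar > 0.5
  perms <- all_permutations(N)
  best <- NULL; best_J <- Inf
  for (k in seq_len(nrow(perms))) {
    J <- rank_cost_logical(gt, perms[k, ])
    if (J < best_J) { best_J <- J; best <- perms[k, ] }
  }
  structure(genes[best], cost = best_J)
}

## all permutations of 1..n in lexicographic order (n x n! too big past 9)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Consensus rank coordinates over replicate orders
#'
#' Each gene's rank position is averaged over the K replicate permutations;
#' the final integer order sorts genes by ascending mean position, ties broken
#' by gene id.
#'
#' @param perms list of K permutations (character vectors over identical gene
#'   sets, as from [anneal_rank]).
#' @return data.frame with columns `gene`, `mean_rank`, `sd_rank`,
#'   `final_order` (a permutation of 1..N; 1 = most upstream).
#' @export
consensus_ranks <- function(perms) {
  if (!length(perms)) stop("need at least one permutation")
  genes <- sort(perms[[1L]])
  pos <- vapply(perms, function(p) match(genes, p), numeric(length(genes)))
  pos <- matrix(pos, nrow = length(genes))
  mean_rank <- rowMeans(pos)
  sd_rank <- if (ncol(pos) > 1L) apply(pos, 1L, sd) else rep(0, length(genes))
  ord <- order(mean_rank, genes)
  final <- integer(length(genes))
  final[ord] <- seq_along(genes)
  data.frame(gene = genes, mean_rank = mean_rank, sd_rank = sd_rank,
             final_order = final, stringsAsFactors = FALSE)
}

#' Infer consensus rank coordinates from a causation matrix
#'
#' Samples `K` control-potential fields from the Beta posteriors, enhances
#' each with transitive odds over the support graph, finds each field's
#' optimal order by simulated annealing (per-replicate derived seeds), and
#' returns the consensus rank coordinates.
#'
#' @param C causation matrix.
#' @param K number of sampled fields (default 100).
#' @param seed master integer seed.
#' @param iters,T0,cooling,patience annealing schedule, see [anneal_rank].
#' @return data.frame as from [consensus_ranks].
#' @export
infer_ranks <- function(C, K = 100L, seed = 1L, iters = 20000L, T0 = 1,
                        cooling = 0.9995, patience = 5000L) {
  support <- (C + t(C)) >= 1
  fields <- sample_control_fields(C, K = K, seed = derive_seed(seed, 1L))
  perms <- lapply(seq_along(fields), function(k) {
    enh <- enhanced_control_potentials(fields[[k]], support)
    anneal_rank(enh$Pstar, iters = iters, T0 = T0, cooling = cooling,
                patience = patience, seed = derive_seed(seed, 1000L + k))
  })
  consensus_ranks(perms)
}

#' Assemble the global causal network from counts and rank coordinates
#'
#' Every unordered gene pair with any causation support (`c_ij + c_ji >= 1`)
#' becomes an edge, oriented from the higher-ranked (more upstream) gene to
#' the lower-ranked one — including major-direction ties `c_ij == c_ji`, which
#' the baseline cannot orient.
#'
#' @param C causation matrix.
#' @param ranks rank coordinates from [infer_ranks]/[consensus_ranks]; must
#'   cover all genes of `C`.
#' @return An object of class `GlobalNetwork`: list with `edges` (source,
#'   target, c_st, c_ts) and `ranks`.
#' @export
assemble_global_network <- function(C, ranks) {
  genes <- rownames(C)
  missing <- setdiff(genes, ranks$gene)
  if (length(missing))
    stop("gene(s) missing from ranks: ", paste(head(missing, 5L), collapse = ", "))
  rk <- setNames(ranks$final_order, ranks$gene)
  out <- list()
  for (i in seq_len(nrow(C) - 1L)) for (j in (i + 1L):ncol(C)) {
    if (C[i, j] + C[j, i] < 1L) next
    gi <- genes[i]; gj <- genes[j]
    if (rk[gi] < rk[gj]) {  # i ranked above j
      out[[length(out) + 1L]] <- data.frame(
        source = gi, target = gj, c_st = C[i, j], c_ts = C[j, i],
        stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        source = gj, target = gi, c_st = C[j, i], c_ts = C[i, j],
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(out)) do.call(rbind, out) else
    data.frame(source = character(), target = character(),
               c_st = integer(), c_ts = integer())
  structure(list(edges = edges, ranks = ranks[order(ranks$final_order), ]),
            class = "GlobalNetwork")
}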