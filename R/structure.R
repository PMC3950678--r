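#' Structural blacklist for an eQTL-anchored subnetwork
#'
#' Forbids every directed edge into an eQTL node (genes cannot regulate the
#' germline genotype) and every edge between two eQTL nodes; gene-gene edges
#' are unrestricted. This asymmetry is what lets the genotype anchors break
#' the likelihood equivalence of gene-only structures.
#'
#' @param gene_nodes,eqtl_nodes disjoint character vectors of node names.
#' @return logical matrix `bl` with `bl[i, j]` TRUE when edge i -> j is
#'   forbidden; dimnames are `c(gene_nodes, eqtl_nodes)`.
#' @export
build_blacklist <- function(gene_nodes, eqtl_nodes) {
  if (length(intersect(gene_nodes, eqtl_nodes)))
    stop("gene and eQTL node sets overlap")
  nodes <- c(gene_nodes, eqtl_nodes)
  bl <- matrix(FALSE, length(nodes), length(nodes),
               dimnames = list(nodes, nodes))
  if (length(eqtl_nodes)) bl[, eqtl_nodes] <- TRUE
  diag(bl) <- FALSE
  bl
}

#' Assemble a subnetwork learning problem for a pair of modules
#'
#' Node set = union of the two modules' gene members plus the union of their
#' eQTL representatives; data matrix = aligned expression values and 0/1/2
#' dosages, samples in rows. Module membership and physical interactions are
#' deliberately NOT encoded: only the blacklist constrains the search.
#'
#' @param members_a,members_b character vectors of module gene members.
#' @param eqtls_a,eqtls_b character vectors of eQTL SNP ids (may be empty).
#' @param expr an [expression_matrix].
#' @param geno a [genotype_matrix] (sample-aligned with `expr`).
#' @return An object of class `SubnetworkProblem`: list with `data`,
#'   `gene_nodes`, `eqtl_nodes`, `blacklist`.
#' @export
subnetwork_problem <- function(members_a, members_b, eqtls_a, eqtls_b,
                               expr, geno) {
  gene_nodes <- sort(unique(c(members_a, members_b)))
  eqtl_nodes <- sort(unique(c(eqtls_a, eqtls_b)))
  dat <- t(expr$values[gene_nodes, , drop = FALSE])
  if (length(eqtl_nodes)) {
    gdat <- t(geno$dosages[eqtl_nodes, , drop = FALSE])
    dat <- cbind(dat, gdat)
  }
  if (anyNA(dat)) stop("subnetwork data contains missing values")
  structure(list(data = dat, gene_nodes = gene_nodes, eqtl_nodes = eqtl_nodes,
                 blacklist = build_blacklist(gene_nodes, eqtl_nodes)),
            class = "SubnetworkProblem")
}

## random DAG under blacklist/parent-cap constraints: random topological
## order, each permitted forward edge kept with probability prob
random_dag <- function(nodes, blacklist, max_parents, prob = 0.2) {
  d <- length(nodes)
  adj <- matrix(FALSE, d, d, dimnames = list(nodes, nodes))
  ord <- sample.int(d)
  for (jpos in 2:d) {
    j <- ord[jpos]
    for (ipos in seq_len(jpos - 1L)) {
      i <- ord[ipos]
      if (!blacklist[i, j] && sum(adj[, j]) < max_parents &&
          runif(1L) < prob)
        adj[i, j] <- TRUE
    }
  }
  adj
}

## directed path from -> to? (BFS on the logical adjacency)
has_path <- function(adj, from, to) {
  visited <- logical(ncol(adj))
  frontier <- which(adj[from, ])
  while (length(frontier)) {
    if (to %in% frontier) return(TRUE)
    visited[frontier] <- TRUE
    frontier <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !visited)
  }
  FALSE
}

## one greedy hill climb from a start DAG. Move deltas are cached per target
## column and invalidated only when that column's parent set changes; local
## scores are memoised in `state` across starts and module pairs.
hc_climb <- function(state, adj, blacklist, max_parents, eps = 1e-10) {
  d <- ncol(adj)
  local <- vapply(seq_len(d), function(j)
    bge_local_score(state, j, which(adj[, j])), numeric(1L))
  delta_add <- matrix(NA_real_, d, d)  # score gain of adding i -> j
  delta_del <- matrix(NA_real_, d, d)  # score gain of deleting i -> j
  refresh_col <- function(j) {
    pa <- which(adj[, j])
    for (i in seq_len(d)) {
      if (i == j) next
      if (adj[i, j]) {
        delta_del[i, j] <<- bge_local_score(state, j, setdiff(pa, i)) - local[j]
        delta_add[i, j] <<- NA_real_
      } else if (!blacklist[i, j]) {
        delta_add[i, j] <<- bge_local_score(state, j, c(pa, i)) - local[j]
        delta_del[i, j] <<- NA_real_
      } else {
        delta_add[i, j] <<- NA_real_; delta_del[i, j] <<- NA_real_
      }
    }
  }
  for (j in seq_len(d)) refresh_col(j)

  pick_lex <- function(idx) {
    # deterministic tie-break: smallest (source, target)
    ij <- arrayInd(idx, c(d, d))
    idx[order(ij[, 1L], ij[, 2L])][1L]
  }
  repeat {
    reach <- reachability(adj)
    indeg <- colSums(adj)
    open_col <- matrix(indeg < max_parents, d, d, byrow = TRUE)
    valid_add <- !is.na(delta_add) & !t(reach) & open_col
    best <- NULL
    add_ok <- which(valid_add & delta_add > eps)
    if (length(add_ok)) {
      mx <- max(delta_add[add_ok])
      at <- pick_lex(add_ok[delta_add[add_ok] >= mx - eps / 2])
      best <- list(delta = mx, type = "add", idx = at)
    }
    del_ok <- which(!is.na(delta_del) & delta_del > eps)
    if (length(del_ok)) {
      mx <- max(delta_del[del_ok])
      if (is.null(best) || mx > best$delta + eps) {
        at <- pick_lex(del_ok[delta_del[del_ok] >= mx - eps / 2])
        best <- list(delta = mx, type = "del", idx = at)
      }
    }
    # reversals: gain = delete(i->j) + add(j->i); test acyclicity lazily,
    # best-gain first, only for candidates that beat the current best
    edges <- which(adj)
    if (length(edges)) {
      ij <- arrayInd(edges, c(d, d))
      gain <- delta_del[edges] + delta_add[cbind(ij[, 2L], ij[, 1L])]
      gain[!(indeg[ij[, 1L]] < max_parents)] <- NA_real_
      ord <- order(-gain, ij[, 1L], ij[, 2L], na.last = NA)
      for (k in ord) {
        g <- gain[k]
        if (g <= eps || (!is.null(best) && g <= best$delta + eps)) break
        i <- ij[k, 1L]; j <- ij[k, 2L]
        adj2 <- adj; adj2[i, j] <- FALSE
        if (!has_path(adj2, i, j)) {
          best <- list(delta = g, type = "rev", idx = edges[k])
          break
        }
      }
    }
    if (is.null(best)) break
    at <- arrayInd(best$idx, c(d, d))
    i <- at[1L]; j <- at[2L]
    if (best$type == "add") {
      adj[i, j] <- TRUE
    } else if (best$type == "del") {
      adj[i, j] <- FALSE
    } else {
      adj[i, j] <- FALSE; adj[j, i] <- TRUE
      local[i] <- bge_local_score(state, i, which(adj[, i]))
      refresh_col(i)
    }
    local[j] <- bge_local_score(state, j, which(adj[, j]))
    refresh_col(j)
  }
  list(adj = adj, score = sum(local))
}

#' Learn an eQTL-anchored subnetwork by score-based hill climbing
#'
#' Greedy hill climbing over add/delete/reverse moves maximizing the BGe
#' marginal likelihood, respecting acyclicity, the blacklist, and a parent-set
#' cap, starting from the empty graph plus `restarts` random restarts
#' (constraint-respecting random DAGs). Equal-scoring moves resolve by
#' lexicographic (source, target) order, so the result is deterministic given
#' the seed.
#'
#' @param problem a [subnetwork_problem].
#' @param restarts number of random restarts beyond the empty start (default 5).
#' @param max_parents parent-set cap (default 4).
#' @param seed integer seed for the random restarts.
#' @return An object of class `Dag`: list with `adj` (logical adjacency,
#'   `adj[i, j]` means i -> j), `score`, `nodes`, `gene_nodes`, `eqtl_nodes`.
#' @export
learn_subnetwork <- function(problem, restarts = 5L, max_parents = 4L,
                             seed = 1L) {
  state <- bge_state(problem$data)
  nodes <- colnames(problem$data)
  d <- length(nodes)
  max_parents <- min(max_parents, state$n - 2L)
  bl <- problem$blacklist[nodes, nodes]
  empty <- matrix(FALSE, d, d, dimnames = list(nodes, nodes))
  best <- hc_climb(state, empty, bl, max_parents)
  if (restarts > 0L && d > 1L) {
    set.seed(seed)
    for (r in seq_len(restarts)) {
      start <- random_dag(nodes, bl, max_parents)
      res <- hc_climb(state, start, bl, max_parents)
      if (res$score > best$score + 1e-10) best <- res
    }
  }
  structure(list(adj = best$adj, score = best$score, nodes = nodes,
                 gene_nodes = problem$gene_nodes,
                 eqtl_nodes = problem$eqtl_nodes),
            class = "Dag")
}

#' @export
print.Dag <- function(x, ...) {
  cat(sprintf("Dag: %d nodes, %d edges, score %.4f\n",
              length(x$nodes), sum(x$adj), x$score))
  invisible(x)
}

#' Accumulate pairwise-module subnetworks into the causation matrix
#'
#' For every unordered pair of modules, learns the eQTL-anchored subnetwork on
#' the union of their members and eQTLs, and increments `C[i, j]` for every
#' learned directed gene-gene edge i -> j (eQTL edges are not counted). Each
#' pair uses a sub-seed derived from the master seed and the pair identity, so
#' the result is independent of processing order and of `jobs`.
#'
#' @param modules list of `Module` objects (>= 2).
#' @param module_eqtls list of `ModuleEqtls` aligned with `modules`.
#' @param expr an [expression_matrix].
#' @param geno a [genotype_matrix] (sample-aligned).
#' @param restarts,max_parents see [learn_subnetwork].
#' @param seed master integer seed.
#' @param jobs number of worker processes for module pairs (forked; >1 only
#'   effective on unix).
#' @return integer causation matrix `C` (N x N, dimnames = sorted union of
#'   module genes, zero diagonal).
#' @export
accumulate_causation <- function(modules, module_eqtls, expr, geno,
                                 restarts = 5L, max_parents = 4L, seed = 1L,
                                 jobs = 1L) {
  if (length(modules) < 2L) stop("need at least 2 modules")
  stopifnot(length(module_eqtls) == length(modules))
  genes <- sort(unique(unlist(lapply(modules, `[[`, "members"))))
  N <- length(genes)
  pairs <- combn(length(modules), 2L)
  run_pair <- function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    prob <- subnetwork_problem(modules[[a]]$members, modules[[b]]$members,
                               module_eqtls[[a]]$eqtls$snp_id,
                               module_eqtls[[b]]$eqtls$snp_id,
                               expr, geno)
    dag <- learn_subnetwork(prob, restarts = restarts,
                            max_parents = max_parents,
                            seed = derive_seed(seed, a * 100003 + b))
    gadj <- dag$adj[dag$gene_nodes, dag$gene_nodes, drop = FALSE]
    which(gadj, arr.ind = TRUE)  # gene-gene edges only
  }
  ncores <- if (.Platform$OS.type == "unix") max(1L, as.integer(jobs)) else 1L
  edge_lists <- if (ncores > 1L) {
    parallel::mclapply(seq_len(ncol(pairs)), run_pair, mc.cores = ncores)
  } else {
    lapply(seq_len(ncol(pairs)), run_pair)
  }
  C <- matrix(0L, N, N, dimnames = list(genes, genes))
  for (k in seq_len(ncol(pairs))) {
    hits <- edge_lists[[k]]
    if (!nrow(hits)) next
    a <- pairs[1L, k]; b <- pairs[2L, k]
    gn <- sort(unique(c(modules[[a]]$members, modules[[b]]$members)))
    for (e in seq_len(nrow(hits)))
      C[gn[hits[e, 1L]], gn[hits[e, 2L]]] <- C[gn[hits[e, 1L]], gn[hits[e, 2L]]] + 1L
  }
  C
}

#' Major-direction baseline network from a causation matrix
#'
#' For each unordered gene pair with any causation support, emits the edge in
#' the majority direction; when `C[i, j] == C[j, i]` the direction cannot be
#' decided and no edge is created (the case the random-field ranking recovers).
#'
#' @param C causation matrix from [accumulate_causation].
#' @return data.frame with columns `source`, `target`, `c_st`, `c_ts`.
#' @export
major_direction_network <- function(C) {
  genes <- rownames(C)
  out <- list()
  for (i in seq_len(nrow(C) - 1L)) for (j in (i + 1L):ncol(C)) {
    cij <- C[i, j]; cji <- C[j, i]
    if (cij + cji < 1L || cij == cji) next
    if (cij > cji) {
      out[[length(out) + 1L]] <- data.frame(
        source = genes[i], target = genes[j], c_st = cij, c_ts = cji,
        stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        source = genes[j], target = genes[i], c_st = cji, c_ts = cij,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(source = character(), target = character(),
                      c_st = integer(), c_ts = integer()))
  do.call(rbind, out)
}
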