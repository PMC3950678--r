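# Shared fixtures, built in code at test time.

# tiny expression/genotype/label triple with consistent sample ids
tiny_expr <- function(n_genes = 3L, n_samples = 8L, seed = 1L) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                 dimnames = list(sprintf("g%d", seq_len(n_genes)),
                                 sprintf("s%d", seq_len(n_samples))))
  expression_matrix(vals)
}

tiny_labels <- function(n_samples = 8L) {
  phenotype_labels(sprintf("s%d", seq_len(n_samples)),
                   rep(c("case", "control"), length.out = n_samples))
}

balanced_labels <- function(n_samples) {
  phenotype_labels(sprintf("s%d", seq_len(n_samples)),
                   rep(c("case", "control"), each = n_samples / 2))
}

tiny_geno <- function(n_snps = 4L, n_samples = 8L, seed = 2L,
                      chrom = "1", pos = NULL) {
  set.seed(seed)
  dos <- matrix(sample(0:2, n_snps * n_samples, replace = TRUE), n_snps,
                n_samples,
                dimnames = list(sprintf("snp%d", seq_len(n_snps)),
                                sprintf("s%d", seq_len(n_samples))))
  if (is.null(pos)) pos <- seq_len(n_snps) * 1e5
  genotype_matrix(dos, data.frame(snp_id = rownames(dos), chrom = chrom,
                                  pos = pos))
}

# random antisymmetric control-potential field
random_field <- function(N, seed) {
  set.seed(seed)
  P <- matrix(0.5, N, N, dimnames = list(LETTERS[seq_len(N)],
                                         LETTERS[seq_len(N)]))
  ut <- upper.tri(P)
  P[ut] <- runif(sum(ut))
  P[lower.tri(P)] <- 1 - t(P)[lower.tri(P)]
  P
}

# sequential normal-Wishart predictive-density oracle for the marginal
# likelihood of an l-dimensional data subset (independent of the BGe
# determinant-formula route it cross-checks)
seq_nw_logml <- function(x, mu0, alpha_mu, wishart_df, Tmat) {
  x <- as.matrix(x)
  l <- ncol(x)
  nu <- mu0; a <- alpha_mu; d <- wishart_df; Tt <- Tmat
  ll <- 0
  for (i in seq_len(nrow(x))) {
    dfp <- d - l + 1
    S <- Tt * (a + 1) / (a * dfp)
    xi <- x[i, ] - nu
    Sc <- chol(S)
    quad <- sum(backsolve(Sc, xi, transpose = TRUE)^2)
    ll <- ll + lgamma((dfp + l) / 2) - lgamma(dfp / 2) -
      (l / 2) * log(dfp * pi) - sum(log(diag(Sc))) -
      (dfp + l) / 2 * log1p(quad / dfp)
    Tt <- Tt + (a / (a + 1)) * tcrossprod(xi)
    nu <- (a * nu + x[i, ]) / (a + 1)
    a <- a + 1; d <- d + 1
  }
  ll
}

# exhaustive best-scoring DAG over all blacklist-respecting structures
exhaustive_best_dag <- function(data, blacklist) {
  nodes <- colnames(data)
  st <- bge_state(data)
  cand <- expand.grid(i = nodes, j = nodes, stringsAsFactors = FALSE)
  cand <- cand[cand$i != cand$j & !blacklist[cbind(cand$i, cand$j)], ]
  ne <- nrow(cand)
  best <- NULL; best_score <- -Inf
  for (mask in 0:(2^ne - 1)) {
    adj <- matrix(FALSE, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    sel <- which(bitwAnd(mask, 2^(0:(ne - 1))) > 0)
    for (k in sel) adj[cand$i[k], cand$j[k]] <- TRUE
    if (causanet:::is_cyclic(adj)) next
    sc <- gaussian_network_score(st, adj)
    if (sc > best_score) { best_score <- sc; best <- adj }
  }
  list(adj = best, score = best_score)
}
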