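dag_named <- function(nodes, edges = NULL) {
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (!is.null(edges)) for (e in edges) adj[e[1], e[2]] <- TRUE
  adj
}

test_that("BGe score decomposes symmetrically on the empty graph", {
  set.seed(51)
  dat <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("A", "B")))
  dat[, 2] <- dat[, 1] + rnorm(60)   # any joint distribution
  st <- bge_state(dat)
  empty <- dag_named(c("A", "B"))
  sc <- gaussian_network_score(st, empty)
  local_A <- causanet:::bge_subset_logml(st, 1L)
  local_B <- causanet:::bge_subset_logml(st, 2L)
  expect_equal(sc, local_A + local_B, tolerance = 1e-12)
  # identical marginal data -> identical single-node terms
  dat2 <- cbind(A = dat[, 1], B = dat[, 1])
  st2 <- bge_state(dat2)
  expect_equal(causanet:::bge_subset_logml(st2, 1L),
               causanet:::bge_subset_logml(st2, 2L), tolerance = 1e-12)
})

test_that("score equivalence holds for A->B vs B->A, on any data", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30 + 10 * seed
    dat <- cbind(A = rnorm(n), B = rnorm(n, sd = 2))
    dat[, 2] <- dat[, 2] + seed * 0.3 * dat[, 1]
    expect_equal(gaussian_network_score(dat, dag_named(c("A", "B"),
                                                       list(c("A", "B")))),
                 gaussian_network_score(dat, dag_named(c("A", "B"),
                                                       list(c("B", "A")))),
                 tolerance = 1e-8)
  }
})

test_that("all 3-node Markov-equivalence classes score consistently", {
  set.seed(52)
  n <- 80
  dat <- cbind(A = rnorm(n), B = rnorm(n), C = rnorm(n))
  dat[, 2] <- dat[, 2] + 0.7 * dat[, 1]
  dat[, 3] <- dat[, 3] + 0.5 * dat[, 2]
  nodes <- c("A", "B", "C")
  chain_class <- list(    # A->B->C, A<-B->C, A<-B<-C: one equivalence class
    dag_named(nodes, list(c("A", "B"), c("B", "C"))),
    dag_named(nodes, list(c("B", "A"), c("B", "C"))),
    dag_named(nodes, list(c("C", "B"), c("B", "A"))))
  scores <- vapply(chain_class, function(d) gaussian_network_score(dat, d),
                   numeric(1))
  expect_equal(max(scores) - min(scores), 0, tolerance = 1e-8)
  # the collider A->B<-C is its own class and scores differently here
  collider <- dag_named(nodes, list(c("A", "B"), c("C", "B")))
  expect_gt(abs(gaussian_network_score(dat, collider) - scores[1]), 1e-4)
})

test_that("BGe marginal likelihood matches the sequential predictive oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 25 + 5 * seed
    dat <- cbind(A = rnorm(n), B = rnorm(n))
    dat[, 2] <- dat[, 2] + 0.4 * seed * dat[, 1]
    st <- bge_state(dat)
    # 2-dim joint term
    or2 <- seq_nw_logml(dat, colMeans(dat), st$alpha_mu, st$alpha_w,
                        diag(st$t_scale, 2))
    expect_equal(causanet:::bge_subset_logml(st, 1:2), or2, tolerance = 1e-6)
    # 1-dim marginal term uses the subset-adjusted Wishart df
    or1 <- seq_nw_logml(dat[, 1, drop = FALSE], mean(dat[, 1]), st$alpha_mu,
                        st$alpha_w - 2 + 1, matrix(st$t_scale))
    expect_equal(causanet:::bge_subset_logml(st, 1L), or1, tolerance = 1e-6)
    # full scores assembled from these terms: A->B = p(A) + p(AB)/p(A)
    expect_equal(gaussian_network_score(st, dag_named(c("A", "B"),
                                                      list(c("A", "B")))),
                 or2, tolerance = 1e-6)
  }
})

test_that("blacklist enumerates exactly the eQTL-anchoring constraints", {
  bl <- build_blacklist(c("g1", "g2"), "q")
  expect_equal(sum(bl), 2L)
  expect_true(bl["g1", "q"] && bl["g2", "q"])
  expect_equal(sum(build_blacklist(c("g1", "g2"), character(0))), 0L)
  bl2 <- build_blacklist(character(0), c("q1", "q2"))
  expect_equal(sum(bl2), 2L)
  expect_true(bl2["q1", "q2"] && bl2["q2", "q1"])
  expect_error(build_blacklist(c("a", "q"), "q"), "overlap")
})

test_that("the eQTL anchor breaks likelihood equivalence of gene pairs", {
  set.seed(53)
  n <- 300
  Q <- rbinom(n, 2, 0.3)
  A <- Q + rnorm(n, 0, 0.7)
  B <- 0.8 * A + rnorm(n, 0, 0.7)
  dat <- cbind(A = A, B = B, Q = Q)
  nodes <- colnames(dat)
  st <- bge_state(dat)
  fwd <- dag_named(nodes, list(c("Q", "A"), c("A", "B")))
  rev <- dag_named(nodes, list(c("Q", "A"), c("B", "A")))
  # same skeleton, but B->A creates a collider at A: scores now differ
  expect_gt(gaussian_network_score(st, fwd) - gaussian_network_score(st, rev),
            1)
})

test_that("exhaustive search over anchored 3-node DAGs recovers Q->A->B", {
  set.seed(54)
  n <- 500
  Q <- rbinom(n, 2, 0.3)
  A <- Q + rnorm(n, 0, 0.7)
  B <- 0.8 * A + rnorm(n, 0, 0.7)
  dat <- cbind(A = A, B = B, Q = Q)
  bl <- build_blacklist(c("A", "B"), "Q")
  best <- exhaustive_best_dag(dat, bl)
  expect_true(best$adj["Q", "A"])
  expect_true(best$adj["A", "B"])
  expect_equal(sum(best$adj), 2L)
})

test_that("hill climbing matches the exhaustive oracle and respects constraints", {
  set.seed(55)
  n <- 500
  Q <- rbinom(n, 2, 0.3)
  A <- Q + rnorm(n, 0, 0.7)
  B <- 0.8 * A + rnorm(n, 0, 0.7)
  C <- 0.8 * B + rnorm(n, 0, 0.7)
  samples <- sprintf("s%d", 1:n)
  ev <- t(cbind(A = A, B = B, C = C))
  colnames(ev) <- samples
  expr <- expression_matrix(ev)
  geno <- genotype_matrix(matrix(Q, 1, n, dimnames = list("Q", samples)),
                          data.frame(snp_id = "Q", chrom = "1", pos = 1))
  prob <- subnetwork_problem("A", c("B", "C"), "Q", character(0), expr, geno)
  dag <- learn_subnetwork(prob, restarts = 3, seed = 9)
  gene_edges <- which(dag$adj[c("A", "B", "C"), c("A", "B", "C")],
                      arr.ind = TRUE)
  found <- paste(rownames(gene_edges),
                 c("A", "B", "C")[gene_edges[, 2]], sep = ">")
  expect_setequal(found, c("A>B", "B>C"))
  # blacklist respected: nothing points into Q
  expect_equal(sum(dag$adj[, "Q"]), 0L)
})

test_that("independent noise yields a near-empty learned graph", {
  set.seed(56)
  n <- 200
  dat <- matrix(rnorm(4 * n), n, 4, dimnames = list(NULL, letters[1:4]))
  prob <- structure(list(data = dat, gene_nodes = letters[1:4],
                         eqtl_nodes = character(0),
                         blacklist = build_blacklist(letters[1:4],
                                                     character(0))),
                    class = "SubnetworkProblem")
  dag <- learn_subnetwork(prob, restarts = 2, seed = 10)
  expect_lte(sum(dag$adj), 1L)
  # hill climbing never scores below the empty graph
  empty_score <- gaussian_network_score(dat, dag_named(letters[1:4]))
  expect_gte(dag$score, empty_score)
})

test_that("blacklist holds across many random anchored problems", {
  set.seed(57)
  for (r in 1:25) {
    n <- 60
    Q1 <- rbinom(n, 2, 0.4); Q2 <- rbinom(n, 2, 0.4)
    dat <- cbind(g1 = rnorm(n) + Q1, g2 = rnorm(n), g3 = rnorm(n) + Q2,
                 q1 = Q1, q2 = Q2)
    prob <- structure(list(data = dat, gene_nodes = c("g1", "g2", "g3"),
                           eqtl_nodes = c("q1", "q2"),
                           blacklist = build_blacklist(c("g1", "g2", "g3"),
                                                       c("q1", "q2"))),
                      class = "SubnetworkProblem")
    dag <- learn_subnetwork(prob, restarts = 1, seed = r)
    expect_equal(sum(dag$adj[, c("q1", "q2")]), 0L)
  }
})

test_that("causation accumulation counts gene edges independent of order and jobs", {
  set.seed(58)
  n <- 150
  samples <- sprintf("s%d", seq_len(n))
  Q1 <- rbinom(n, 2, 0.4); Q2 <- rbinom(n, 2, 0.4)
  a <- Q1 + rnorm(n, 0, 0.5); b <- 0.8 * a + rnorm(n, 0, 0.5)
  c_ <- Q2 + rnorm(n, 0, 0.5); d <- 0.8 * c_ + rnorm(n, 0, 0.5)
  vals <- rbind(a = a, b = b, c = c_, d = d)
  colnames(vals) <- samples
  expr <- expression_matrix(vals)
  dos <- rbind(q1 = Q1, q2 = Q2)
  colnames(dos) <- samples
  geno <- genotype_matrix(dos, data.frame(snp_id = c("q1", "q2"),
                                          chrom = "1", pos = c(1e5, 9e6)))
  mods <- list(structure(list(id = "m1", seed = "a", members = c("a", "b")),
                         class = "Module"),
               structure(list(id = "m2", seed = "c", members = c("c", "d")),
                         class = "Module"),
               structure(list(id = "m3", seed = "a", members = c("a", "d")),
                         class = "Module"))
  eqs <- list(
    structure(list(module_id = "m1",
                   eqtls = data.frame(snp_id = "q1")), class = "ModuleEqtls"),
    structure(list(module_id = "m2",
                   eqtls = data.frame(snp_id = "q2")), class = "ModuleEqtls"),
    structure(list(module_id = "m3",
                   eqtls = data.frame(snp_id = "q1")), class = "ModuleEqtls"))
  C1 <- accumulate_causation(mods, eqs, expr, geno, restarts = 2, seed = 3)
  expect_equal(diag(C1), setNames(rep(0L, 4), c("a", "b", "c", "d")))
  expect_gte(C1["a", "b"], 1L)
  # reordering the modules changes nothing
  C2 <- accumulate_causation(mods[c(3, 1, 2)], eqs[c(3, 1, 2)], expr, geno,
                             restarts = 2, seed = 3)
  expect_equal(C1, C2)
  if (.Platform$OS.type == "unix") {
    C3 <- accumulate_causation(mods, eqs, expr, geno, restarts = 2, seed = 3,
                               jobs = 2L)
    expect_equal(C1, C3)
  }
})

test_that("major direction orients by count majority and drops ties", {
  C <- matrix(0L, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  C["x", "y"] <- 5L; C["y", "x"] <- 2L
  C["y", "z"] <- 3L; C["z", "y"] <- 3L
  net <- major_direction_network(C)
  expect_equal(nrow(net), 1L)
  expect_equal(net$source, "x")
  expect_equal(net$target, "y")
  expect_equal(nrow(major_direction_network(C * 0L)), 0L)
})
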