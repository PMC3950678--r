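count_matrix <- function(genes) {
  matrix(0L, length(genes), length(genes), dimnames = list(genes, genes))
}

test_that("Beta posterior means follow (c_ij + 1)/(c_ij + c_ji + 2)", {
  C <- count_matrix(c("a", "b", "c"))
  C["a", "b"] <- 3L; C["b", "a"] <- 1L
  C["a", "c"] <- 9L
  P <- control_potentials(C)
  expect_equal(P["b", "c"], 0.5)            # no records -> symmetric prior
  expect_equal(P["a", "b"], 4 / 6)
  expect_equal(P["a", "c"], 10 / 11)
  expect_equal(P + t(P), matrix(1, 3, 3), ignore_attr = TRUE)
})

test_that("sampled Beta fields are antisymmetric, calibrated and reproducible", {
  C <- count_matrix(c("a", "b"))
  C["a", "b"] <- 3L; C["b", "a"] <- 1L
  fields <- sample_control_fields(C, K = 10000L, seed = 99)
  draws <- vapply(fields, function(P) P["a", "b"], numeric(1))
  expect_equal(mean(draws), 2 / 3, tolerance = 0.01)
  for (P in fields[1:5]) expect_equal(P["b", "a"], 1 - P["a", "b"])

  # decisive counts concentrate near 1
  Cd <- count_matrix(c("a", "b"))
  Cd["a", "b"] <- 1000L
  dd <- vapply(sample_control_fields(Cd, K = 100L, seed = 7),
               function(P) P["a", "b"], numeric(1))
  expect_true(all(dd > 0.99))

  expect_identical(sample_control_fields(C, K = 5L, seed = 3),
                   sample_control_fields(C, K = 5L, seed = 3))
})

test_that("transitive odds enhance strong paths and discard weak ones", {
  genes <- c("i", "h", "j")
  P <- matrix(0.5, 3, 3, dimnames = list(genes, genes))
  P["i", "h"] <- 0.8; P["h", "i"] <- 0.2
  P["h", "j"] <- 0.8; P["j", "h"] <- 0.2
  support <- matrix(TRUE, 3, 3, dimnames = list(genes, genes))
  enh <- enhanced_control_potentials(P, support)
  # T = 0.64/0.36 for the i->h->j path, retained (> 1)
  expect_equal(enh$W["i", "j"], 0.64 / 0.36, tolerance = 1e-12)
  expect_gt(enh$Pstar["i", "j"], 0.5)

  # weak path 0.6 * 0.6 gives odds 0.5625 <= 1: discarded, potential neutral
  P2 <- P
  P2["i", "h"] <- 0.6; P2["h", "i"] <- 0.4
  P2["h", "j"] <- 0.6; P2["j", "h"] <- 0.4
  enh2 <- enhanced_control_potentials(P2, support)
  expect_equal(enh2$W["i", "j"], 1)          # direct odds at the neutral 0.5
  expect_equal(enh2$Pstar["i", "j"], 0.5)

  # overall odds never fall below the direct odds
  expect_true(all(enh$W >= enh$O))
  expect_error(enhanced_control_potentials(P, support, R = 2), "R = 1")
})

test_that("without common neighbors enhancement is a rank-preserving no-op", {
  genes <- c("i", "j", "k")
  P <- random_field(3, seed = 61)
  dimnames(P) <- list(genes, genes)
  support <- matrix(FALSE, 3, 3, dimnames = list(genes, genes))
  support["i", "j"] <- support["j", "i"] <- TRUE  # no shared neighbor
  enh <- enhanced_control_potentials(P, support)
  # Pstar = O/(O + O') is the squashing map P^2/(P^2 + (1-P)^2): it fixes
  # 0.5, preserves order, so every downstream ranking coincides with P's
  expect_equal(enh$Pstar, P^2 / (P^2 + (1 - P)^2), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_identical(enh$Pstar > 0.5, P > 0.5)
  expect_identical(order(enh$Pstar[upper.tri(P)]), order(P[upper.tri(P)]))
  # antisymmetry everywhere
  expect_equal(enh$Pstar + t(enh$Pstar), matrix(1, 3, 3),
               ignore_attr = TRUE)
  # rank assembly is literally unchanged
  expect_identical(as.character(brute_force_rank(enh$Pstar)),
                   as.character(brute_force_rank(P)))
})

test_that("consistent transitive paths never decrease the enhanced potential", {
  genes <- c("i", "h", "j")
  base <- matrix(0.5, 3, 3, dimnames = list(genes, genes))
  base["i", "j"] <- 0.6; base["j", "i"] <- 0.4
  no_neighbors <- matrix(FALSE, 3, 3, dimnames = list(genes, genes))
  no_neighbors["i", "j"] <- no_neighbors["j", "i"] <- TRUE
  all_support <- matrix(TRUE, 3, 3, dimnames = list(genes, genes))
  plain <- enhanced_control_potentials(base, no_neighbors)$Pstar["i", "j"]
  with_path <- base
  with_path["i", "h"] <- 0.9; with_path["h", "i"] <- 0.1
  with_path["h", "j"] <- 0.9; with_path["j", "h"] <- 0.1
  enhanced <- enhanced_control_potentials(with_path, all_support)$Pstar["i", "j"]
  expect_gte(enhanced, plain)
})

test_that("annealing solves a unique zero-error order and degenerate fields", {
  genes <- c("A", "B", "C")
  P <- matrix(0.5, 3, 3, dimnames = list(genes, genes))
  P["A", "B"] <- 0.9; P["B", "A"] <- 0.1
  P["A", "C"] <- 0.8; P["C", "A"] <- 0.2
  P["B", "C"] <- 0.7; P["C", "B"] <- 0.3
  ord <- anneal_rank(P, seed = 1)
  expect_equal(as.character(ord), c("A", "B", "C"))
  expect_equal(attr(ord, "cost"), 0L)

  # all-0.5 field: every order has zero cost; result is a valid permutation
  P5 <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  ord5 <- anneal_rank(P5, seed = 2)
  expect_setequal(as.character(ord5), letters[1:4])
  expect_equal(attr(ord5, "cost"), 0L)
})

test_that("annealing attains the brute-force minimum on random N=7 fields", {
  matches <- vapply(1:20, function(r) {
    P <- random_field(7, seed = 100 + r)
    bf <- brute_force_rank(P)
    an <- anneal_rank(P, seed = 200 + r)
    attr(an, "cost") == attr(bf, "cost")
  }, logical(1))
  expect_gte(sum(matches), 19L)
})

test_that("brute force is an exhaustive oracle dominating annealing", {
  P <- matrix(0.5, 2, 2, dimnames = list(c("i", "j"), c("i", "j")))
  P["i", "j"] <- 0.4; P["j", "i"] <- 0.6
  expect_equal(as.character(brute_force_rank(P)), c("j", "i"))
  for (r in 1:5) {
    P6 <- random_field(6, seed = 300 + r)
    expect_lte(attr(brute_force_rank(P6), "cost"),
               attr(anneal_rank(P6, seed = r), "cost"))
  }
  expect_error(brute_force_rank(random_field(10, seed = 1)), "N <= 9")
})

test_that("consensus ranks average replicate positions with id tie-breaks", {
  p1 <- c("u", "v", "w")
  expect_equal(consensus_ranks(list(p1))$final_order, 1:3)
  expect_equal(consensus_ranks(list(p1))$sd_rank, rep(0, 3))
  # two replicates that swap u and v: tie on mean, broken by gene id
  r2 <- consensus_ranks(list(c("u", "v", "w"), c("v", "u", "w")))
  expect_equal(r2$final_order[r2$gene == "u"], 1L)
  expect_equal(r2$final_order[r2$gene == "v"], 2L)
})

test_that("decisive counts along a 10-gene chain are recovered end to end", {
  genes <- sprintf("g%02d", 1:10)
  C <- count_matrix(genes)
  for (k in 1:9) C[genes[k], genes[k + 1]] <- 10L
  ranks <- infer_ranks(C, K = 25L, seed = 5)
  expect_equal(ranks$gene[order(ranks$final_order)], genes)
  net <- assemble_global_network(C, ranks)
  expect_equal(nrow(net$edges), 9L)
  expect_equal(net$edges$source, genes[1:9])
  expect_equal(net$edges$target, genes[2:10])
})

test_that("rank assembly orients support pairs the major-direction baseline drops", {
  genes <- c("i", "h", "j")
  C <- count_matrix(genes)
  C["i", "h"] <- 9L
  C["h", "j"] <- 9L
  C["i", "j"] <- 2L; C["j", "i"] <- 2L   # tie: baseline cannot orient
  major <- major_direction_network(C)
  expect_false(any((major$source == "i" & major$target == "j") |
                   (major$source == "j" & major$target == "i")))
  ranks <- infer_ranks(C, K = 25L, seed = 8)
  net <- assemble_global_network(C, ranks)
  tie_edge <- net$edges[net$edges$source %in% c("i", "j") &
                        net$edges$target %in% c("i", "j"), ]
  expect_equal(nrow(tie_edge), 1L)
  expect_equal(tie_edge$source, "i")
  expect_equal(tie_edge$target, "j")
  # strictly more supported pairs oriented than the baseline
  expect_gt(nrow(net$edges), nrow(major))
})

test_that("assembly requires rank coverage and support", {
  genes <- c("a", "b")
  C <- count_matrix(genes)
  ranks <- consensus_ranks(list(genes))
  expect_equal(nrow(assemble_global_network(C, ranks)$edges), 0L)
  C["a", "b"] <- 1L
  expect_error(assemble_global_network(C, ranks[ranks$gene == "a", ]),
               "missing")
})
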