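test_that("Yule trees have the requested size and regime", {
  t2 <- simulate_tree(2, regime = 0.1, seed = 1)
  expect_equal(length(t2$tip.label), 2L)
  expect_equal(t2$Nnode, 1L)
  t8 <- simulate_tree(8, regime = 0.1, seed = 2)
  expect_true(all(t8$edge.length == 0.1))
  tr <- simulate_tree(8, regime = c(0.05, 0.3), seed = 3)
  expect_true(all(tr$edge.length >= 0.05 & tr$edge.length <= 0.3))
  # determinism
  expect_identical(ape::write.tree(simulate_tree(12, 0.2, seed = 7)),
                   ape::write.tree(simulate_tree(12, 0.2, seed = 7)))
  expect_error(simulate_tree(1, 0.1, seed = 1), ">= 2")
})

test_that("zero branch lengths copy the root everywhere", {
  fam <- evolve_sequences(simulation_spec(
    tree = simulate_tree(6, regime = 0, seed = 4),
    model = build_model("WAG"), L = 50, seed = 4))
  root_seq <- true_ancestor(fam, "N1")
  for (nd in rownames(fam$ancestors)) {
    expect_equal(true_ancestor(fam, nd), root_seq)
  }
  for (id in rownames(fam$alignment)) {
    expect_equal(paste(unclass(fam$alignment)[id, ], collapse = ""), root_seq)
  }
  expect_true(all(fam$branch_changes$n_changes == 0))
})

test_that("long branches drive leaf composition to the equilibrium", {
  m <- build_model("WAG")
  fam <- evolve_sequences(simulation_spec(
    tree = ape::read.tree(text = "(A:1e4,B:1e4);"),
    model = m, L = 10000, seed = 5))
  counts <- table(factor(unclass(fam$alignment)["A", ], levels = AA20))
  p <- stats::chisq.test(counts, p = m$freqs)$p.value
  expect_gt(p, 0.001)
})

test_that("branch identity fraction matches the analytic expectation", {
  m <- build_model("WAG")
  t <- 0.2
  L <- 5000
  fam <- evolve_sequences(simulation_spec(
    tree = ape::read.tree(text = sprintf("(A:%f,B:0)N1;", t)),
    model = m, L = L, seed = 6))
  # P(site identical across one branch of length t) = sum_i pi_i P_ii(t)
  P <- transition_matrix(m, t)
  p_same <- sum(m$freqs * diag(P))
  root <- strsplit(true_ancestor(fam, "N1"), "")[[1]]
  leaf <- unclass(fam$alignment)["A", ]
  frac <- mean(root == leaf)
  expect_lt(abs(frac - p_same), 3 * sqrt(p_same * (1 - p_same) / L))
})

test_that("overrides are applied at the node and inherited by descendants", {
  phy <- ape::read.tree(text = "((A:0.1,B:0.1)N2:0.1,C:0.1)N1;")
  ov <- tibble::tibble(node = c("N2", "A"), column = c(5L, 5L),
                       residue = c("W", "C"))
  fam <- evolve_sequences(simulation_spec(
    tree = phy, model = build_model("WAG"), L = 10, overrides = ov, seed = 7))
  expect_equal(substr(true_ancestor(fam, "N2"), 5, 5), "W")
  # B inherits the N2 override, A re-overrides it
  expect_equal(unname(unclass(fam$alignment)["B", 5]), "W")
  expect_equal(unname(unclass(fam$alignment)["A", 5]), "C")
  expect_error(evolve_sequences(simulation_spec(
    tree = phy, model = build_model("WAG"), L = 10, seed = 7,
    overrides = tibble::tibble(node = "NOPE", column = 1L, residue = "A"))),
    "non-existent")
})

test_that("C-terminal truncation produces trailing gaps only where asked", {
  fam <- evolve_sequences(simulation_spec(
    tree = simulate_tree(4, 0.1, seed = 8), model = build_model("WAG"),
    L = 30, truncate_leaves = c(L1 = 5L), seed = 8))
  m <- unclass(fam$alignment)
  expect_true(all(m["L1", 26:30] == "-"))
  expect_true(all(m["L1", 1:25] != "-"))
  expect_true(all(m["L2", ] != "-"))
})

test_that("simulation is a pure function of the seed", {
  s1 <- evolve_sequences(simulation_spec(n_leaves = 6, regime = 0.2,
                                         model = build_model("WAG"),
                                         L = 40, seed = 9))
  s2 <- evolve_sequences(simulation_spec(n_leaves = 6, regime = 0.2,
                                         model = build_model("WAG"),
                                         L = 40, seed = 9))
  expect_identical(unclass(s1$alignment), unclass(s2$alignment))
  expect_identical(s1$ancestors, s2$ancestors)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
})

test_that("simulated data prefer the generating model's likelihood", {
  m_true <- build_model("WAG")
  fam <- evolve_sequences(simulation_spec(
    n_leaves = 8, regime = 0.25, model = m_true, L = 800, seed = 10))
  ll_true <- log_likelihood(fam$tree, fam$alignment, m_true)$loglik
  ll_other <- log_likelihood(fam$tree, fam$alignment,
                             build_model("Dayhoff"))$loglik
  expect_gt(ll_true, ll_other)
})

test_that("the peroxidase-like fixture carries its designed truth", {
  fx <- make_peroxidase_like_fixture(seed = 12)
  # truth types by construction
  for (i in seq_len(nrow(fx$expected_types))) {
    nd <- fx$expected_types$node[i]
    p <- classify_catalytic_profile(true_ancestor(fx$family, nd),
                                    fx$sites, fx$rules)
    expect_equal(p$type, fx$expected_types$type[i], label = nd)
  }
  expect_equal(nrow(fx$family$alignment), 10L)
  expect_equal(ncol(fx$family$alignment), 300L)
  # determinism of the accuracy table
  r1 <- ancestor_recovery_experiment(0.1, n_leaves = 6, L = 50,
                                     replicates = 2, seed = 3)
  r2 <- ancestor_recovery_experiment(0.1, n_leaves = 6, L = 50,
                                     replicates = 2, seed = 3)
  expect_identical(r1$per_node, r2$per_node)
})
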