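test_that("zero-divergence cherries collapse to the equilibrium frequency", {
  m <- build_model("WAG")
  phy <- ape::read.tree(text = "(A:0,B:0);")
  aln <- as_alignment(c(A = "W", B = "W"))
  ll <- log_likelihood(phy, aln, m)
  expect_equal(ll$loglik, log(m$freqs[["W"]]), tolerance = 1e-12)
  # all-gap columns contribute nothing
  aln2 <- as_alignment(c(A = "W-", B = "W-"))
  expect_equal(log_likelihood(phy, aln2, m)$loglik, ll$loglik,
               tolerance = 1e-12)
})

test_that("pruning equals brute-force enumeration on random 4-leaf instances", {
  for (seed in 1:8) {
    inst <- make_4leaf_instance(seed, L = 6,
                                alpha = if (seed %% 2) NULL else 0.7,
                                k = 2L)
    ll <- log_likelihood(inst$tree, inst$aln, inst$model)
    oracle <- brute_force_4leaf(inst$states, inst$bl, inst$model)
    expect_equal(ll$site_loglik, oracle$site_loglik, tolerance = 1e-10)
    expect_equal(ll$loglik, sum(ll$site_loglik), tolerance = 1e-8)
  }
})

test_that("missing leaf sequences are refused", {
  m <- build_model("WAG")
  phy <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,C:0.1);")
  aln <- as_alignment(c(A = "MK", B = "ML"))
  expect_error(log_likelihood(phy, aln, m), "C")
})

test_that("likelihood is invariant to root placement on a branch", {
  m <- build_model("WAG", alpha = 0.9, k = 4)
  aln <- random_alignment(c("A", "B", "C", "D"), 40, seed = 9)
  t1 <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.3,D:0.4):0.15);")
  t2 <- ape::read.tree(text = "((A:0.1,B:0.2):0.15,(C:0.3,D:0.4):0.05);")
  t3 <- ape::read.tree(text = "((A:0.1,B:0.2):0.2,(C:0.3,D:0.4):0.0);")
  lls <- sapply(list(t1, t2, t3), function(t) log_likelihood(t, aln, m)$loglik)
  expect_lt(max(lls) - min(lls), 1e-8)
})

test_that("site-pattern compression leaves per-site values unchanged", {
  m <- build_model("WAG", alpha = 0.5, k = 2)
  phy <- ape::read.tree(text = "((A:0.1,B:0.2):0.1,(C:0.15,D:0.25):0.1);")
  # duplicate columns must receive bit-identical site log-likelihoods
  base <- random_alignment(c("A", "B", "C", "D"), 10, seed = 3)
  dup <- as_alignment(apply(unclass(base)[, c(1:10, 1:10)], 1, paste,
                            collapse = ""))
  ll <- log_likelihood(phy, dup, m)
  expect_identical(ll$site_loglik[1:10], ll$site_loglik[11:20])
})

test_that("pruning agrees with an independent likelihood implementation", {
  skip_if_not_installed("phangorn")
  inst <- make_4leaf_instance(21, L = 30)
  ll <- log_likelihood(inst$tree, inst$aln, inst$model)
  pd <- phangorn::phyDat(unclass(inst$aln), type = "AA")
  fit <- phangorn::pml(ape::unroot(inst$tree), pd, model = "WAG", k = 1)
  expect_equal(ll$loglik, as.numeric(stats::logLik(fit)), tolerance = 1e-6)
})

test_that("branch-length optimisation recovers a known divergence", {
  m <- build_model("WAG")
  # identical leaves drive both branches to the lower clamp
  phy <- ape::read.tree(text = "(A:0.3,B:0.3);")
  aln_same <- as_alignment(c(
    A = paste(rep("ACDEFGHIKL", 5), collapse = ""),
    B = paste(rep("ACDEFGHIKL", 5), collapse = "")))
  ob <- optimize_branch_lengths(phy, aln_same, m)
  expect_true(all(ob$tree$edge.length <= 1e-6))
  expect_false(is.unsorted(ob$trace))

  # data simulated at total path length 0.3 is recovered within 10%
  fam <- evolve_sequences(simulation_spec(
    tree = ape::read.tree(text = "(A:0.15,B:0.15);"),
    model = m, L = 5000, seed = 42))
  ob2 <- optimize_branch_lengths(ape::read.tree(text = "(A:0.05,B:0.05);"),
                                 fam$alignment, m)
  expect_equal(sum(ob2$tree$edge.length), 0.3, tolerance = 0.1 * 0.3)
  expect_false(is.unsorted(ob2$trace))
})

test_that("gamma-shape estimation recovers the simulated shape", {
  m_true <- build_model("WAG", alpha = 0.7, k = 4)
  fam <- evolve_sequences(simulation_spec(
    n_leaves = 16, regime = 0.3, model = m_true, L = 2000, seed = 11))
  est <- estimate_gamma_shape(fam$tree, fam$alignment, build_model("WAG"))
  expect_lt(abs(est$alpha - 0.7) / 0.7, 0.25)
  expect_false(est$at_upper_bound)
  # determinism
  est2 <- estimate_gamma_shape(fam$tree, fam$alignment, build_model("WAG"))
  expect_identical(est$alpha, est2$alpha)
})

test_that("rate-homogeneous data push the gamma shape to the upper bound", {
  m_true <- build_model("WAG")
  fam <- evolve_sequences(simulation_spec(
    n_leaves = 12, regime = 0.3, model = m_true, L = 1500, seed = 13))
  expect_message(
    est <- estimate_gamma_shape(fam$tree, fam$alignment, build_model("WAG"),
                                bounds = c(0.05, 20)),
    "rate-homogeneous")
  expect_true(est$at_upper_bound)
})

test_that("model comparison ranks the generating model first", {
  m_true <- build_model("WAG")
  fam <- evolve_sequences(simulation_spec(
    n_leaves = 8, regime = 0.25, model = m_true, L = 1000, seed = 17))
  cmp <- compare_models(fam$tree, fam$alignment,
                        c("LG", "WAG", "Dayhoff"))
  expect_equal(cmp$model[cmp$rank == 1], "WAG")
  f <- withr::local_tempfile(fileext = ".json")
  write_model_comparison(cmp, f)
  expect_equal(jsonlite::read_json(f)[[1]]$model, cmp$model[1])
  # single model and unknown names are refused
  expect_error(compare_models(fam$tree, fam$alignment, "WAG"), "at least 2")
  expect_error(compare_models(fam$tree, fam$alignment, c("WAG", "XYZ")),
               "unknown")
})
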