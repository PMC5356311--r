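# A 200-column context with the catalytic positions at their conventional
# residue numbers (the reference is ungapped, so residue n == column n).
typing_context <- function() {
  base <- paste(rep("G", 200), collapse = "")
  ref <- with_residues(base, c(37, 41, 183, 172), c("E", "E", "D", "A"))
  aln <- as_alignment(c(ref = ref))
  sites <- map_reference_positions(aln, "ref", c(37, 41, 183, 172),
                                   labels = c("37", "41", "183", "172"))
  list(base = base, sites = sites, rules = site_rules())
}

test_that("catalytic profiles reproduce the canonical family labels", {
  ctx <- typing_context()
  cases <- list(
    # residues at 37/41/183/172           expected    mn_site
    list(c("E", "E", "D", "A"), "MnP",          "typical"),
    list(c("E", "E", "D", "W"), "VP",           "typical"),
    list(c("D", "E", "N", "W"), "LiP",          "none"),
    list(c("E", "E", "R", "A"), "GP",           "blocked"),
    list(c("G", "E", "D", "A"), "MnP-atypical", "atypical"),
    list(c("G", "E", "D", "W"), "VP-atypical",  "atypical"))
  for (cs in cases) {
    seq <- with_residues(ctx$base, c(37, 41, 183, 172), cs[[1]])
    p <- classify_catalytic_profile(seq, ctx$sites, ctx$rules)
    expect_equal(p$type, cs[[2]])
    expect_equal(p$mn_site, cs[[3]])
  }
})

test_that("the type mapping is total and pure", {
  for (mn in c("typical", "atypical", "blocked", "none")) {
    for (trp in c(TRUE, FALSE)) {
      expect_true(is.character(peroxasr:::peroxidase_type(mn, trp)))
    }
  }
  # lysine blocks like arginine; histidine does not
  ctx <- typing_context()
  pk <- classify_catalytic_profile(
    with_residues(ctx$base, c(37, 41, 183, 172), c("E", "E", "K", "A")),
    ctx$sites, ctx$rules)
  expect_equal(pk$type, "GP")
  ph <- classify_catalytic_profile(
    with_residues(ctx$base, c(37, 41, 183, 172), c("E", "E", "H", "A")),
    ctx$sites, ctx$rules)
  expect_equal(ph$type, "MnP-atypical")
})

test_that("classification ignores residues outside the named positions", {
  ctx <- typing_context()
  s1 <- with_residues(ctx$base, c(37, 41, 183, 172), c("E", "E", "D", "W"))
  s2 <- with_residues(s1, c(1, 100, 200), c("M", "F", "Y"))
  p1 <- classify_catalytic_profile(s1, ctx$sites, ctx$rules)
  p2 <- classify_catalytic_profile(s2, ctx$sites, ctx$rules)
  expect_equal(p1$type, p2$type)
  expect_equal(p1$mn_site, p2$mn_site)
})

test_that("gapped catalytic positions count as mismatches and are flagged", {
  ctx <- typing_context()
  s <- with_residues(ctx$base, c(37, 41, 183, 172), c("-", "E", "D", "W"))
  p <- classify_catalytic_profile(s, ctx$sites, ctx$rules)
  expect_equal(p$exact_triad_matches, 2L)
  expect_equal(p$gapped_positions, "37")
  expect_equal(p$type, "VP-atypical")
})

test_that("ancestor sets are partitioned into the triad subsets", {
  ctx <- typing_context()
  mk <- function(res) with_residues(ctx$base, c(37, 41, 183, 172), res)
  seqs <- c(rep(mk(c("E", "E", "D", "W")), 5),   # typical + Trp
            rep(mk(c("E", "E", "D", "A")), 5),   # typical, no Trp
            rep(mk(c("E", "E", "R", "A")), 3),   # basic-blocked
            rep(mk(c("D", "E", "D", "A")), 2))   # atypical
  set <- structure(list(
    node = "NX",
    samples = tibble::tibble(sequence = seqs, threshold = 0.2,
                             log_posterior = 0,
                             is_most_probable = FALSE),
    gap_mask = rep(FALSE, 200)), class = "ancestor_set")
  part <- partition_ancestor_set(set, ctx$sites, ctx$rules)
  expect_equal(sum(part$subset_fractions$fraction), 1)
  expect_equal(sum(part$type_fractions$fraction), 1)
  sf <- setNames(part$subset_fractions$fraction, part$subset_fractions$level)
  expect_equal(sf[["typical-triad"]], 10 / 15)
  expect_equal(sf[["basic-blocked"]], 3 / 15)
  expect_equal(sf[["atypical"]], 2 / 15)
  tf <- setNames(part$type_fractions$fraction, part$type_fractions$level)
  expect_equal(tf[["VP"]], 5 / 15)
  expect_equal(tf[["MnP"]], 5 / 15)

  # a uniform set reports fraction 1.00 for its single type
  set2 <- set
  set2$samples <- set2$samples[1:5, ]
  part2 <- partition_ancestor_set(set2, ctx$sites, ctx$rules)
  expect_equal(part2$type_fractions$fraction, 1)
  expect_equal(part2$type_fractions$level, "VP")
})

test_that("site rules round-trip through YAML", {
  rules <- site_rules(triad = c("10" = "E", "14" = "E", "90" = "D"),
                      trp = c("80" = "W"))
  f <- withr::local_tempfile(fileext = ".yml")
  write_site_rules(rules, f)
  rules2 <- read_site_rules(f)
  expect_equal(rules2$triad, rules$triad)
  expect_equal(rules2$trp, rules$trp)
  expect_equal(rules2$basic, c("R", "K"))
})

test_that("reconstructed motif states match designed truth when confident", {
  # simulated families with forced motif states: classify the reconstructed
  # most-probable ancestor and compare with the designed truth whenever all
  # motif-position posteriors are confident
  for (seed in c(3, 9)) {
    fx <- make_peroxidase_like_fixture(seed = seed)
    posts <- marginal_posteriors(fx$family$tree, fx$family$alignment,
                                 fx$family$spec$model)
    for (i in seq_len(nrow(fx$expected_types))) {
      nd <- fx$expected_types$node[i]
      mp <- most_probable_sequence(posts[[nd]])
      conf <- posts[[nd]]$max_posterior[fx$sites$column]
      if (all(conf >= 0.9)) {
        p <- classify_catalytic_profile(mp, fx$sites, fx$rules)
        expect_equal(p$type, fx$expected_types$type[i],
                     label = paste("node", nd, "seed", seed))
      }
    }
  }
})
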