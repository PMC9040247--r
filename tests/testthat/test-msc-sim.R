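test_that("scenario validation rejects inconsistent configurations", {
  expect_error(scenario("((A:1,B:2):1,C:2);", loci = 10), "ultrametric")
  expect_error(triplet_scenario(1, 10, gamma = 1.5), "gamma")
  expect_error(
    scenario("(((A:1,B:1):1,C:2):3,O:5);", loci = 10, outgroup = "O",
             pulses = list(list(donor = "C", recipient = "A", time = 2.5,
                                gamma = 0.5))),
    "lifespan")  # A's branch ends at t=1
  expect_error(
    scenario("(((A:1,B:1):1,C:2):3,O:5);", loci = 10,
             rates = list(list(tips = c("A", "C"), r = 2))),
    "monophyletic")
})

test_that("star-tree triplet topologies are exchangeable", {
  sc <- scenario("(((A:1,B:1):1e-9,C:1):3,O:4);", loci = 3000,
                 pop_scale = 1, outgroup = "O", seed = 11)
  counts <- sister_pair_counts(simulate_gene_trees(sc), "O")
  expect_length(counts, 3L)
  sigma3 <- 3 * sqrt(3000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - 1000) < sigma3))
})

test_that("discordance matches the closed form (1/3) e^{-T}", {
  loci <- 6000
  sc <- triplet_scenario(T = 1, loci = loci, seed = 5)
  counts <- sister_pair_counts(simulate_gene_trees(sc), "O")
  p_disc <- exp(-1) / 3
  sigma3 <- 3 * sqrt(loci * p_disc * (1 - p_disc))
  for (cls in c("((A,C),B);", "(A,(B,C));"))
    expect_lt(abs(counts[[cls]] - loci * p_disc), sigma3)
})

test_that("a gamma=1 pulse reroutes the recipient to the donor branch", {
  # B jumps into C's branch at t=0.5; they share it until t=2, so
  # P(B sister to C) = 1 - (2/3) e^{-1.5}
  loci <- 2000
  sc <- triplet_scenario(T = 1, loci = loci, seed = 13, gamma = 1)
  counts <- sister_pair_counts(simulate_gene_trees(sc), "O")
  p <- 1 - (2 / 3) * exp(-1.5)
  sigma3 <- 3 * sqrt(loci * p * (1 - p))
  expect_lt(abs(counts[["(A,(B,C));"]] - loci * p), sigma3)
})

test_that("simulation is reproducible and prefix-stable in locus count", {
  sc <- triplet_scenario(T = 0.5, loci = 10, seed = 99)
  g1 <- simulate_gene_trees(sc)
  g2 <- simulate_gene_trees(sc)
  nwk <- function(g) vapply(g$trees, write_newick, character(1L),
                            canonical = TRUE)
  expect_identical(nwk(g1), nwk(g2))
  sc5 <- triplet_scenario(T = 0.5, loci = 5, seed = 99)
  expect_identical(nwk(simulate_gene_trees(sc5)), nwk(g1)[1:5])
})

test_that("scale_branch_lengths applies mu and clade multipliers", {
  sc <- triplet_scenario(T = 1, loci = 50, seed = 2, mu = 0.01)
  gts <- simulate_gene_trees(sc)
  subs <- scale_branch_lengths(gts)
  expect_identical(subs$units, "subs")
  # r = 1 everywhere: substitution lengths are mu * coalescent lengths
  for (i in c(1L, 25L))
    expect_equal(subs$trees[[i]]$edge.length,
                 0.01 * gts$trees[[i]]$edge.length, tolerance = 1e-12)
  # mu = 0 zeroes everything
  sc0 <- sc; sc0$mu <- 0
  expect_true(all(vapply(scale_branch_lengths(gts, sc0)$trees,
                         function(t) all(t$edge.length == 0), logical(1L))))
  # clade multiplier r = 5 on A's terminal branch (spans exactly [0,1])
  scr <- scenario("(((A:1,B:1):1,C:2):3,O:5);", loci = 300, mu = 0.01,
                  pop_scale = 1, outgroup = "O",
                  rates = list(list(tips = "A", r = 5)), seed = 21)
  rtt <- rowMeans(vapply(scale_branch_lengths(simulate_gene_trees(scr))$trees,
                         function(t) root_to_tip_lengths(t)[c("A", "B")],
                         numeric(2L)))
  # A picks up an extra mu*(5-1)*1 relative to B, exactly
  expect_equal(rtt[["A"]] - rtt[["B"]], 0.01 * 4, tolerance = 0.005)
})

test_that("simulate_alignment follows the JC69 closed form and is seeded", {
  tr <- parse_newick("(A:0.05,B:0.05);")
  a1 <- simulate_alignment(tr, 50000, seed = 7)
  a2 <- simulate_alignment(tr, 50000, seed = 7)
  expect_identical(a1, a2)
  p <- p_distance(a1["A", ], a1["B", ])
  p_exp <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  expect_lt(abs(p - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 50000))
  # zero-length star: identical sequences
  star <- parse_newick("(A:0,B:0,C:0);")
  s <- simulate_alignment(star, 100, seed = 3)
  expect_identical(s["A", ], s["B", ])
  expect_identical(s["A", ], s["C", ])
  expect_error(simulate_alignment(tr, 0), "positive")
  # HKY with large kappa enriches transitions over transversions
  trh <- parse_newick("(A:0.3,B:0.3);")
  h <- simulate_alignment(trh, 20000, model = "HKY", seed = 9, kappa = 20)
  diffs <- h["A", ] != h["B", ]
  ts <- paste0(pmin(h["A", diffs], h["B", diffs]),
               pmax(h["A", diffs], h["B", diffs])) %in% c("AG", "CT")
  expect_gt(mean(ts), 0.6)
})

test_that("extract_site_patterns polarizes biallelic sites by the outgroup", {
  aln <- rbind(A = c("G", "A", "G", "A"),
               B = c("G", "A", "C", "A"),
               C = c("A", "A", "T", "A"),
               O = c("A", "A", "G", "-"))
  pat <- extract_site_patterns(aln, "O")
  # column 1 biallelic -> (1,1,0|0); column 2 invariant, 3 triallelic,
  # 4 gapped: all dropped
  expect_equal(ncol(pat), 1L)
  expect_equal(unname(pat[, 1L]), c(1L, 1L, 0L, 0L))
  expect_equal(attr(pat, "site_index"), 1L)
  inv <- rbind(A = rep("A", 5), B = rep("A", 5), O = rep("A", 5))
  expect_warning(empty <- extract_site_patterns(inv, "O"), "biallelic")
  expect_equal(ncol(empty), 0L)
})

test_that("expected_topology_freq evaluates the MSC closed form", {
  expect_equal(unname(expected_topology_freq(0)), rep(1 / 3, 3))
  expect_equal(unname(expected_topology_freq(500)), c(1, 0, 0))
  f <- expected_topology_freq(0.5)
  expect_equal(unname(f[2L]), exp(-0.5) / 3, tolerance = 1e-12)
  expect_equal(sum(f), 1)
  expect_error(expected_topology_freq(-1), ">= 0")
})

test_that("bundled scenarios emit the configured locus counts and taxa", {
  tri <- tribe_scenario(loci = 5, seed = 1)
  expect_length(tri$species_tree$tip.label, 6L)
  expect_length(simulate_gene_trees(tri), 5L)
  expect_equal(tribe_scenario()$loci, 2608L)
  sub <- subtribe_scenario(loci = 4, seed = 1)
  expect_length(sub$species_tree$tip.label, 5L)
  expect_equal(subtribe_scenario()$loci, 1865L)
})
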