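# Printed model-comparison table values used as frozen expectations; the
# alignment has n = 55,296 sites and the parameter ladder K = 188..192.
tab4 <- data.frame(
  model = c("M0", "M1", "M2", "M3"),
  logL = -c(198619.36, 196765.6138, 196572.4365, 196503.1014),
  K = c(188L, 189L, 190L, 192L),
  AICc = c(397616.0097, 393910.5308, 393526.1902, 393391.5477))

test_that("aicc reproduces the published model-table cells", {
  n <- 55296
  for (i in seq_len(nrow(tab4)))
    expect_lt(abs(aicc(tab4$logL[i], tab4$K[i], n) - tab4$AICc[i]), 0.01)
  # concatenation-table cells (different K)
  expect_lt(abs(aicc(-194843.878, 366, n) - 390424.65), 0.01)
  expect_lt(abs(aicc(-191946.283, 389, n) - 384676.09), 0.01)
  # large-n limit approaches plain AIC
  expect_lt(abs(aicc(-100, 10, 1e9) - 220), 1e-5)
  expect_error(aicc(-10, 10, 11), "undefined")
})

test_that("lrt reproduces the published likelihood-ratio row", {
  expect_lt(abs(lrt(tab4$logL[1], tab4$logL[2], 1)$Lambda - 3707.492572), 1e-3)
  expect_lt(abs(lrt(tab4$logL[2], tab4$logL[3], 1)$Lambda - 386.354476), 1e-3)
  expect_lt(abs(lrt(tab4$logL[3], tab4$logL[4], 2)$Lambda - 138.670312), 1e-3)
  eq <- lrt(-100, -100, 1)
  expect_equal(eq$Lambda, 0); expect_equal(eq$p, 1)
  expect_error(lrt(-90, -100, 1), "misordered")
})

test_that("clock_param_count reproduces the published K ladder", {
  expect_equal(clock_param_count(180, 8, 0), 188)
  expect_equal(clock_param_count(180, 8, 1), 189)
  expect_equal(clock_param_count(180, 8, 2), 190)
  expect_equal(clock_param_count(180, 8, 4), 192)
})

# independent oracle: likelihood by exhaustive summation over all internal
# state assignments
enumeration_loglik <- function(alignment, tree, edge_lens, freqs = rep(0.25, 4)) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    phylodisc:::pmat(edge_lens[e]))
  internals <- (nt + 1L):nn
  grid <- do.call(expand.grid, rep(list(1:4), length(internals)))
  ll <- 0
  for (s in seq_len(ncol(alignment))) {
    states <- integer(nn)
    states[seq_len(nt)] <- match(alignment[tree$tip.label, s], c("A", "C", "G", "T"))
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      states[internals] <- unlist(grid[g, ])
      pr <- freqs[states[nt + 1L]]
      for (e in seq_len(nrow(tree$edge)))
        pr <- pr * P[[e]][states[tree$edge[e, 1L]], states[tree$edge[e, 2L]]]
      tot <- tot + pr
    }
    ll <- ll + log(tot)
  }
  ll
}

test_that("clock_loglik equals closed forms and the enumeration oracle", {
  # two taxa, one site: JC69 transition formula
  tr <- parse_newick("(A:0.5,B:0.5);")
  cm <- clock_model(tr, mu = 0.1)
  match_site <- matrix(c("A", "A"), 2, 1, dimnames = list(c("A", "B"), NULL))
  mism_site <- matrix(c("A", "G"), 2, 1, dimnames = list(c("A", "B"), NULL))
  d <- 0.1
  expect_equal(clock_loglik(match_site, cm),
               log(0.25 * (0.25 + 0.75 * exp(-4 * d / 3))), tolerance = 1e-12)
  expect_equal(clock_loglik(mism_site, cm),
               log(0.25 * (0.25 - 0.25 * exp(-4 * d / 3))), tolerance = 1e-12)
  # r = 1 multipliers are a no-op
  topo <- parse_newick("(((A:1,B:1):1,C:2):1,D:3);")
  aln <- simulate_alignment(phylodisc:::edge_durations(topo, c(0,0,0,0,3,2,1)/3),
                            200, seed = 2)
  cm0 <- clock_model(topo, mu = 0.05)
  cm1 <- clock_model(topo, mu = 0.05, rates = list(list(tips = c("A", "B"), r = 1)))
  expect_equal(clock_loglik(aln, cm0), clock_loglik(aln, cm1), tolerance = 1e-12)
  # enumeration oracle on small random instances
  set.seed(14)
  for (rep in 1:3) {
    k <- sample(4:6, 1)
    topo <- random_rooted_tree(LETTERS[seq_len(k)], lengths = FALSE)
    topo$edge.length <- runif(nrow(topo$edge), 0.05, 0.5)
    aln <- simulate_alignment(topo, 30, seed = rep)
    cm <- clock_model(topo, mu = 1)
    expect_equal(clock_loglik(aln, cm),
                 enumeration_loglik(aln, topo, topo$edge.length),
                 tolerance = 1e-10)
  }
})

test_that("fit_local_clocks recovers a clade multiplier and ranks models", {
  topo <- parse_newick("(((A:1,B:1):1,(C:1,D:1):1):1,(E:2,F:2):1);")
  truth <- list(list(tips = c("A", "B"), r = 5))
  r <- phylodisc:::edge_rate_multipliers(topo, truth)
  st <- topo; st$edge.length <- 0.05 * r * topo$edge.length
  aln <- simulate_alignment(st, 5000, seed = 42)
  lad <- fit_local_clocks(aln, topo, list(c("A", "B")), n_starts = 2, seed = 1)
  expect_identical(attr(lad, "best"), "M1")
  rhat <- attr(lad, "fits")[[2L]]$rates[["A,B"]]
  expect_gt(rhat, 4); expect_lt(rhat, 6)
  expect_true(lad$significant[2L])
  expect_true(all(diff(lad$logL) > -1e-6))
  expect_error(fit_local_clocks(aln, topo, list(c("A", "C"))), "monophyletic")
})

test_that("p_distance uses pairwise deletion", {
  expect_equal(p_distance(c("A", "C", "G", "T"), c("A", "C", "G", "T")), 0)
  expect_equal(p_distance(c("A", "C", "G", "T"), c("A", "C", "G", "A")), 0.25)
  expect_equal(p_distance(c("A", "C", "-", "T"), c("A", "C", "G", "T")), 0)
  expect_equal(p_distance(c("A", "C", "-", "T"), c("G", "C", "G", "T")), 1 / 3)
  expect_warning(p_distance(c("-", "-"), c("A", "C")), "comparable")
  expect_error(p_distance(c("A"), c("A", "C")), "length")
})

test_that("clade_rate_summary summarizes and tests root-to-tip lengths", {
  # ultrametric: all means equal
  ul <- parse_newick("((A:1,B:1):2,(C:2,D:2):1);")
  s <- clade_rate_summary(ul, list(left = c("A", "B")))
  expect_equal(s$summary$mean[1L], s$summary$mean[2L])
  expect_true(is.null(s$anova) || s$anova$p.value > 0.999)
  # a fast clade shows the configured ratio
  sc <- scenario("(((A:1,B:1):1,C:2):3,O:5);", loci = 200, mu = 0.01,
                 pop_scale = 1, outgroup = "O",
                 rates = list(list(tips = "A", r = 5.58)), seed = 2)
  gts <- scale_branch_lengths(simulate_gene_trees(sc))
  rtt <- rowMeans(vapply(gts$trees, function(t)
    root_to_tip_lengths(t)[c("A", "B", "C", "O")], numeric(4L)))
  # A's terminal branch spans [0,1] at r=5.58; the excess over B is exact
  expect_equal(rtt[["A"]] - rtt[["B"]], 0.01 * 4.58, tolerance = 0.004)
  # degenerate single-tip clades: descriptive only
  s2 <- clade_rate_summary(ul, list(a = "A", c = "C"))
  expect_null(s2$t_test)
})
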