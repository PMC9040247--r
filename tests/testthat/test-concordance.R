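species5 <- parse_newick("(((((Jas:1,Ole:1):1,For:2):1,Fon:3):1,Myx:4):1,Out:5);")

test_that("quartet_scores: concordant and uniform gene trees", {
  trees <- replicate(50, species5, simplify = FALSE)
  qs <- quartet_scores(species5, trees)
  expect_true(all(abs(qs$q1 - 1) < 1e-12))
  expect_true(all(qs$q2 == 0 & qs$q3 == 0))
  # 4-taxon case: uniform mixture over the three resolutions
  st4 <- parse_newick("(((A,B),C),D);")
  alts <- list("(((A,B),C),D);", "(((A,C),B),D);", "(((B,C),A),D);")
  trees4 <- lapply(rep(alts, 30), parse_newick)
  qs4 <- quartet_scores(st4, trees4)
  expect_equal(unlist(qs4[1, c("q1", "q2", "q3")]), c(q1 = 1/3, q2 = 1/3, q3 = 1/3),
               tolerance = 1e-12)
  # permuting gene-tree order changes nothing
  expect_equal(quartet_scores(st4, rev(trees4)), qs4)
})

test_that("quartet scores track the MSC closed form on a simulated branch", {
  loci <- 2500
  gts <- simulate_gene_trees(triplet_scenario(T = 1, loci = loci, seed = 23))
  st <- parse_newick("(((A:1,B:1):1,C:2):3,O:5);")
  qs <- quartet_scores(st, gts)
  row <- qs[qs$branch == "A,B|C,O", ]
  p <- exp(-1) / 3
  sigma3 <- 3 * sqrt(p * (1 - p) / loci)
  expect_lt(abs(row$q2 - p), sigma3)
  expect_lt(abs(row$q3 - p), sigma3)
  expect_equal(row$q1 + row$q2 + row$q3, 1, tolerance = 1e-9)
})

test_that("gene_concordance_factor counts decisive trees", {
  st4 <- parse_newick("(((A,B),C),D);")
  all_match <- replicate(40, st4, simplify = FALSE)
  expect_equal(gene_concordance_factor(st4, all_match)$gCF, 100)
  half <- c(replicate(20, st4, simplify = FALSE),
            replicate(20, parse_newick("(((A,C),B),D);"), simplify = FALSE))
  g <- gene_concordance_factor(st4, half)
  expect_equal(g$gCF, 50)
  expect_equal(g$n1, 20L); expect_equal(g$n2 + g$n3, 20L)
  expect_equal(g$n_decisive, 40L)
})

test_that("site_concordance_factor: constructed counts and noise floor", {
  # 4-taxon alignment: 60 sites support AB|CD, 20 each alternative
  st4 <- parse_newick("((A,B),(C,D));")
  ab <- c("A", "A", "C", "C"); ac <- c("A", "C", "A", "C"); ad <- c("A", "C", "C", "A")
  aln <- cbind(matrix(ab, 4, 60), matrix(ac, 4, 20), matrix(ad, 4, 20))
  rownames(aln) <- c("A", "B", "C", "D")
  s <- site_concordance_factor(st4, aln, n_quartets = 10, seed = 1)
  expect_equal(s$sCF, 60)
  # i.i.d. random sequences: no signal, sCF near 33.3
  set.seed(2)
  rnd <- matrix(sample(c("A", "C", "G", "T"), 4 * 20000, replace = TRUE), 4)
  rownames(rnd) <- c("A", "B", "C", "D")
  s0 <- site_concordance_factor(st4, rnd, n_quartets = 5, seed = 1)
  expect_lt(abs(s0$sCF - 100 / 3), 3)
  # informative alignment simulated on the species tree beats the floor
  stl <- parse_newick("((A:0.05,B:0.05):0.1,(C:0.05,D:0.05):0.1);")
  sim <- simulate_alignment(stl, 5000, seed = 5)
  s1 <- site_concordance_factor(stl, sim, n_quartets = 5, seed = 1)
  expect_gt(s1$sCF, 40)
})

test_that("polytomy_test matches the df=2 closed form and a generic oracle", {
  pt <- polytomy_test(c(100, 100, 100))
  expect_equal(pt$chi2, 0); expect_equal(pt$p, 1); expect_false(pt$reject)
  pt2 <- polytomy_test(c(50, 25, 25))
  expect_equal(pt2$chi2, 12.5)
  expect_equal(pt2$p, exp(-6.25), tolerance = 1e-12)
  expect_true(polytomy_test(c(300, 0, 0))$reject)
  expect_error(polytomy_test(c(0, 0, 0)), "zero")
  set.seed(9)
  for (i in 1:200) {
    n <- as.numeric(rmultinom(1, sample(30:300, 1), prob = runif(3, 0.5, 1)))
    if (sum(n) == 0) next
    ours <- polytomy_test(n)
    oracle <- suppressWarnings(chisq.test(n, p = rep(1 / 3, 3)))
    expect_equal(ours$chi2, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(ours$p, oracle$p.value, tolerance = 1e-10)
  }
})

test_that("gCF equals 100 n1/(n1+n2+n3) when every tree is decisive", {
  gts <- simulate_gene_trees(triplet_scenario(T = 0.5, loci = 400, seed = 3))
  st <- parse_newick("(((A:1,B:1):1,C:2):3,O:5);")
  g <- gene_concordance_factor(st, gts)
  expect_equal(g$n_decisive, 400L)  # 4-taxon trees always display a split
  expect_equal(g$gCF, 100 * g$n1 / (g$n1 + g$n2 + g$n3))
})

test_that("phyparts_map classifies concordance and computes ICA", {
  st4 <- parse_newick("(((A,B),C),D);")
  # no conflict
  pp <- phyparts_map(st4, replicate(30, st4, simplify = FALSE),
                     support_cutoff = NULL)
  expect_true(all(pp$ICA == 1))
  expect_true(all(pp$concordant == 30L))
  # 50/50 split between the reference and one alternative: ICA = 0
  half <- c(replicate(25, st4, simplify = FALSE),
            replicate(25, parse_newick("(((A,C),B),D);"), simplify = FALSE))
  pp2 <- phyparts_map(st4, half, support_cutoff = NULL)
  expect_equal(pp2$ICA, 0, tolerance = 1e-12)
  expect_equal(pp2$conflict_main, 25L)
  # support 70 at the branch is uninformative at cutoff 80
  lo <- parse_newick("(((A,B)70,C)95,D);")
  pp3 <- phyparts_map(st4, list(lo), support_cutoff = 80)
  expect_equal(pp3$uninformative, 1L)
  expect_equal(pp3$concordant, 0L)
  pp4 <- phyparts_map(st4, list(lo), support_cutoff = 60)
  expect_equal(pp4$concordant, 1L)
})

test_that("exhaustive_species_tree recovers obvious and simulated truths", {
  st <- parse_newick("(((A,B),C),O);")
  same <- replicate(30, st, simplify = FALSE)
  res <- exhaustive_species_tree(same, "O")
  expect_identical(res$best, canonical_topology_id(st, "O"))
  expect_equal(res$score, max(res$scores))
  # 3-ingroup argmax equals the majority triplet topology
  mix <- c(replicate(10, parse_newick("(((A,B),C),O);"), simplify = FALSE),
           replicate(4, parse_newick("(((A,C),B),O);"), simplify = FALSE))
  expect_identical(exhaustive_species_tree(mix, "O")$best, "((A,B),C);")
  expect_error(exhaustive_species_tree(
    list(parse_newick(paste0("((((((((A,B),C),D),E),F),G),H),O);"))), "O"),
    "7 ingroup")
  # simulated recovery, scaled down from the 100x2608 example for runtime
  set.seed(77)
  hits <- 0L
  truth <- canonical_topology_id(parse_newick("(((A,B),C),O);"), "O")
  for (rep in 1:10) {
    gts <- simulate_gene_trees(triplet_scenario(T = 0.3, loci = 300,
                                                seed = 1000 + rep))
    if (identical(exhaustive_species_tree(gts, "O")$best, truth))
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("branch_concordance assembles the per-branch report", {
  gts <- simulate_gene_trees(triplet_scenario(T = 0.8, loci = 150, seed = 4))
  subs <- scale_branch_lengths(gts)
  st <- parse_newick("(((A:1,B:1):1,C:2):3,O:5);")
  aln <- do.call(cbind, lapply(seq_len(30), function(i)
    simulate_alignment(subs$trees[[i]], 200, seed = i)))
  rep <- branch_concordance(st, gts, alignment = aln, support_cutoff = NULL)
  expect_true(all(c("branch", "q1", "gCF", "sCF", "chi2", "p_polytomy",
                    "concordant", "ICA") %in% names(rep)))
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$q1 + rep$q2 + rep$q3, 1, tolerance = 1e-9)
})
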