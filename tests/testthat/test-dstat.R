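test_that("count_abba_baba follows the polarized pattern definitions", {
  m <- rbind(A = c(0L, 1L, 1L, 0L), B = c(1L, 0L, 1L, 1L),
             C = c(1L, 1L, 0L, 1L), O = c(0L, 0L, 0L, 1L))
  ct <- count_abba_baba(m, "A", "B", "C", "O")
  # col1 ABBA; col2 BABA; col3 BBAA; col4 repolarized: (1,0,0) -> none
  expect_equal(ct$nABBA, 1L); expect_equal(ct$nBABA, 1L)
  expect_equal(ct$nBBAA, 1L); expect_equal(ct$n_sites_used, 4L)
  # swapping P1 and P2 exchanges ABBA and BABA
  m2 <- rbind(A = c(0L, 0L, 1L), B = c(1L, 1L, 0L), C = c(1L, 1L, 1L),
              O = c(0L, 0L, 0L))
  a <- count_abba_baba(m2, "A", "B", "C", "O")
  b <- count_abba_baba(m2, "B", "A", "C", "O")
  expect_equal(a$nABBA, b$nBABA)
  expect_equal(a$nBABA, b$nABBA)
  expect_error(count_abba_baba(m, "A", "B", "Z", "O"), "missing")
})

test_that("nABBA is close to nBABA without introgression", {
  gts <- scale_branch_lengths(simulate_gene_trees(
    triplet_scenario(T = 1, loci = 300, seed = 6, mu = 5e-3)))
  bc <- block_counts_from_sim(gts, 200, c("A", "B", "C"), "O", seed = 8)
  A <- sum(bc[, "nABBA"]); B <- sum(bc[, "nBABA"])
  expect_lt(abs(A - B), 3 * sqrt(A + B))
})

test_that("d_with_jackknife computes D, Z and the sign-based call", {
  even <- data.frame(nABBA = rep(5L, 25), nBABA = rep(5L, 25))
  r <- d_with_jackknife(even)
  expect_equal(r$D, 0); expect_equal(r$Z, 0); expect_false(r$significant)
  pooled <- data.frame(nABBA = rep(6L, 25), nBABA = rep(2L, 25))
  expect_equal(d_with_jackknife(pooled)$D, 0.5)
  set.seed(3)
  skew <- data.frame(nABBA = rpois(40, 12), nBABA = rpois(40, 3))
  r2 <- d_with_jackknife(skew, "P1", "P2", "P3")
  expect_true(r2$significant)
  expect_identical(r2$pair, c("P2", "P3"))
  # D < 0 implicates (P1, P3)
  r3 <- d_with_jackknife(data.frame(nABBA = skew$nBABA, nBABA = skew$nABBA),
                         "P1", "P2", "P3")
  expect_identical(r3$pair, c("P1", "P3"))
  expect_equal(r3$D, -r2$D)
  expect_warning(d_with_jackknife(data.frame(nABBA = 3:7, nBABA = 1:5)),
                 "blocks")
})

test_that("jackknife SE tracks the replicate SD of D", {
  # iid Poisson blocks: compare the jackknife SE to the empirical SD of D
  set.seed(11)
  ses <- ds <- numeric(200)
  for (i in 1:200) {
    bc <- data.frame(nABBA = rpois(50, 8), nBABA = rpois(50, 6))
    r <- d_with_jackknife(bc)
    ses[i] <- r$SE; ds[i] <- r$D
  }
  expect_lt(abs(mean(ses) - sd(ds)) / sd(ds), 0.2)
})

test_that("triplet_scan enumerates triplets and is order-invariant", {
  set.seed(4)
  taxa <- c("A", "B", "C", "D", "E")
  mats <- replicate(30, {
    m <- matrix(rbinom(6 * 40, 1, 0.4), 6, 40)
    rownames(m) <- c(taxa, "O")
    m["O", ] <- 0L
    m
  }, simplify = FALSE)
  st <- parse_newick("(((((A:1,B:1):1,C:2):1,D:3):1,E:4):1,O:5);")
  scan <- triplet_scan(mats, taxa, "O", species_tree = st)
  expect_equal(nrow(scan), choose(5, 3))
  scan2 <- triplet_scan(mats, rev(taxa), "O", species_tree = st)
  expect_equal(scan, scan2)
  # sister pair follows the species tree: A,B triplet rows keep (A,B) first
  row <- scan[scan$P3 == "C" & scan$P1 == "A", ]
  expect_equal(row$P2, "B")
  # no species tree: all 3 orderings per triplet, flagged
  scan3 <- triplet_scan(mats[1:22], c("A", "B", "C"), "O")
  expect_equal(nrow(scan3), 3L)
  expect_identical(attr(scan3, "ordering"), "all")
  scan4 <- triplet_scan(mats[1:22], c("A", "B", "C"), "O", species_tree = st)
  expect_equal(nrow(scan4), 1L)
})

test_that("pairwise_mean_abs_d averages |D| per implicated pair", {
  res <- data.frame(P1 = c("A", "A"), P2 = c("B", "B"), P3 = c("C", "D"),
                    nABBA = c(15, 12), nBABA = c(5, 6),
                    D = c(0.5, 0.2), Z = c(4, 5), P = c(0, 0),
                    significant = c(TRUE, TRUE),
                    pair_a = c("B", "B"), pair_b = c("C", "D"),
                    stringsAsFactors = FALSE)
  m <- pairwise_mean_abs_d(res)
  expect_equal(m$display["B", "C"], 0.5)
  expect_equal(m$display["B", "D"], 0.2)
  expect_equal(m$display, t(m$display))
  # two triplets implicating the same pair: mean
  res2 <- res; res2$P3 <- c("C", "C"); res2$D <- c(0.2, 0.4)
  expect_equal(pairwise_mean_abs_d(res2)$display["B", "C"], 0.3)
  # nothing significant: display all zeros, raw retains the means
  res3 <- res; res3$significant <- FALSE
  m3 <- pairwise_mean_abs_d(res3)
  expect_true(all(m3$display == 0))
  expect_equal(m3$raw["B", "C"], 0.5)
})

test_that("D detects a simulated introgression pulse", {
  sc <- triplet_scenario(T = 1, loci = 300, seed = 31, gamma = 0.3)
  gts <- scale_branch_lengths(simulate_gene_trees(sc))
  bc <- block_counts_from_sim(gts, 300, c("A", "B", "C"), "O", seed = 5)
  r <- d_with_jackknife(as.data.frame(bc), "A", "B", "C")
  expect_gt(r$D, 0)
  expect_gt(r$Z, 3)
  expect_identical(r$pair, c("B", "C"))
})
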