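# Quartet scores, gene/site concordance factors, quartet-based polytomy
# test, PhyParts-style reference mapping with internode certainty, and an
# exhaustive quartet-score species-tree search for small taxon sets.

# internal branches of the unrooted interpretation of a binary species tree,
# each with its four adjacent tip sets (A, B on one side; C, D on the other)
branch_adjacent_sets <- function(species_tree) {
  tr <- species_tree
  if (length(tr$tip.label) > 3L) tr <- ape::unroot(tr)
  nt <- length(tr$tip.label)
  taxa <- sort(tr$tip.label)
  desc <- descendant_tip_sets(tr)
  parent <- integer(nt + tr$Nnode)
  children <- vector("list", nt + tr$Nnode)
  for (e in seq_len(nrow(tr$edge))) {
    parent[tr$edge[e, 2L]] <- tr$edge[e, 1L]
    children[[tr$edge[e, 1L]]] <- c(children[[tr$edge[e, 1L]]], tr$edge[e, 2L])
  }
  root <- nt + 1L
  out <- list()
  for (v in seq_len(nt + tr$Nnode)) {
    if (v <= nt || v == root) next           # internal, non-basal nodes
    u <- parent[v]
    chv <- children[[v]]
    if (length(chv) != 2L) stop("species tree must be binary")
    A <- desc[[chv[1L]]]; B <- desc[[chv[2L]]]
    if (u == root) {
      others <- setdiff(children[[u]], v)
      if (length(others) == 1L) {
        w <- others
        chw <- children[[w]]
        if (is.null(chw)) next               # pendant edge: trivial split
        C <- desc[[chw[1L]]]; D <- desc[[chw[2L]]]
      } else if (length(others) == 2L) {
        C <- desc[[others[1L]]]; D <- desc[[others[2L]]]
      } else stop("species tree must be binary")
    } else {
      sib <- setdiff(children[[u]], v)
      C <- desc[[sib[1L]]]
      D <- setdiff(taxa, c(A, B, C))
    }
    if (!length(C) || !length(D)) next
    key <- split_key(c(A, B), taxa)
    out[[key]] <- list(key = key, sets = list(A = A, B = B, C = C, D = D))
  }
  out
}

# logical split-membership matrix of a tree over `taxa` (columns), rows =
# non-trivial splits; TRUE marks the side containing taxa[1]
split_matrix <- function(tree, taxa) {
  keys <- split_keys(tree)
  M <- matrix(FALSE, length(keys), length(taxa),
              dimnames = list(keys, taxa))
  for (i in seq_along(keys)) {
    side1 <- strsplit(strsplit(keys[i], "|", fixed = TRUE)[[1L]][1L], ",",
                      fixed = TRUE)[[1L]]
    M[i, side1] <- TRUE
  }
  M
}

# induced resolution of quartet (a,b,c,d): 1 = ab|cd, 2 = ac|bd, 3 = ad|bc,
# 0 = unresolved; M is a split matrix covering these taxa
quartet_resolution_from_splits <- function(M, a, b, c, d) {
  if (!nrow(M)) return(0L)
  xa <- M[, a]; xb <- M[, b]; xc <- M[, c]; xd <- M[, d]
  s <- xa + xb + xc + xd
  cand <- which(s == 2L)
  for (i in cand) {
    if (xa[i] == xb[i]) return(1L)
    if (xa[i] == xc[i]) return(2L)
    return(3L)
  }
  0L
}

#' Quartet support scores for each species-tree branch
#'
#' For every internal branch of the (unrooted) species tree, all quartets
#' with one taxon from each of the four branch-adjacent subtree sets are
#' tallied across gene trees: `q1` is the fraction of gene-tree quartets
#' matching the species-tree resolution, `q2` and `q3` the two alternatives.
#'
#' @param species_tree Rooted binary `phylo`.
#' @param trees A `gene_tree_set` or list of `phylo` over the same taxa.
#' @return data.frame: branch (split key), q1, q2, q3, n_quartets counted.
#' @export
quartet_scores <- function(species_tree, trees) {
  tl <- if (inherits(trees, "gene_tree_set")) trees$trees else trees
  taxa <- sort(species_tree$tip.label)
  branches <- branch_adjacent_sets(species_tree)
  if (!length(branches)) stop("species tree has no internal branches to score")
  quartet_sets <- lapply(branches, function(br) {
    with(br$sets, expand.grid(a = A, b = B, c = C, d = D,
                              stringsAsFactors = FALSE))
  })
  tally <- matrix(0, length(branches), 3L)
  for (tr in tl) {
    M <- split_matrix(tr, taxa)
    for (bi in seq_along(branches)) {
      qs <- quartet_sets[[bi]]
      for (r in seq_len(nrow(qs))) {
        res <- quartet_resolution_from_splits(M, qs$a[r], qs$b[r], qs$c[r], qs$d[r])
        if (res > 0L) tally[bi, res] <- tally[bi, res] + 1
      }
    }
  }
  tot <- rowSums(tally)
  data.frame(branch = names(branches),
             q1 = tally[, 1L] / tot, q2 = tally[, 2L] / tot,
             q3 = tally[, 3L] / tot, n_quartets = tot,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene concordance factor per species-tree branch
#'
#' `gCF` is the percentage of decisive gene trees whose bipartition set
#' contains the branch; a gene tree is decisive for a branch when it
#' displays one of the branch's three resolutions (the species split
#' `AB|CD`, or `AC|BD`, or `AD|BC` over the four adjacent subtree sets).
#'
#' @inheritParams quartet_scores
#' @return data.frame: branch, gCF, n1, n2, n3 (decisive trees per
#'   resolution), n_decisive, n_trees.
#' @export
gene_concordance_factor <- function(species_tree, trees) {
  tl <- if (inherits(trees, "gene_tree_set")) trees$trees else trees
  taxa <- sort(species_tree$tip.label)
  branches <- branch_adjacent_sets(species_tree)
  alt_keys <- lapply(branches, function(br) with(br$sets, c(
    split_key(c(A, B), taxa), split_key(c(A, C), taxa), split_key(c(A, D), taxa))))
  counts <- matrix(0L, length(branches), 3L)
  for (tr in tl) {
    ks <- split_keys(tr)
    for (bi in seq_along(branches)) {
      m <- which(alt_keys[[bi]] %in% ks)
      if (length(m) == 1L) counts[bi, m] <- counts[bi, m] + 1L
    }
  }
  dec <- rowSums(counts)
  data.frame(branch = names(branches),
             gCF = ifelse(dec > 0, 100 * counts[, 1L] / dec, NA_real_),
             n1 = counts[, 1L], n2 = counts[, 2L], n3 = counts[, 3L],
             n_decisive = dec, n_trees = length(tl),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Site concordance factor per species-tree branch
#'
#' For each branch, `n_quartets` random quartets (one taxon per adjacent
#' subtree set) are drawn; within each quartet, decisive sites (those
#' splitting the four taxa 2-2) are counted for the three arrangements, and
#' the branch sCF is the mean percentage of decisive sites supporting the
#' species-tree arrangement across quartets.
#'
#' @param species_tree Rooted binary `phylo`.
#' @param alignment Character matrix (taxa x sites); typically per-locus
#'   alignments concatenated column-wise.
#' @param n_quartets Quartets sampled per branch (default 100).
#' @param seed Integer seed making the quartet sample reproducible.
#' @return data.frame: branch, sCF, n_quartets_used.
#' @export
site_concordance_factor <- function(species_tree, alignment, n_quartets = 100L,
                                    seed = 1L) {
  branches <- branch_adjacent_sets(species_tree)
  set.seed(seed)
  res <- lapply(branches, function(br) {
    A <- br$sets$A; B <- br$sets$B; C <- br$sets$C; D <- br$sets$D
    vals <- numeric(0L)
    for (i in seq_len(n_quartets)) {
      a <- A[sample.int(length(A), 1L)]; b <- B[sample.int(length(B), 1L)]
      c_ <- C[sample.int(length(C), 1L)]; d <- D[sample.int(length(D), 1L)]
      xa <- alignment[a, ]; xb <- alignment[b, ]
      xc <- alignment[c_, ]; xd <- alignment[d, ]
      ok <- xa %in% DNA_STATES & xb %in% DNA_STATES &
            xc %in% DNA_STATES & xd %in% DNA_STATES
      s1 <- sum(ok & xa == xb & xc == xd & xa != xc)
      s2 <- sum(ok & xa == xc & xb == xd & xa != xb)
      s3 <- sum(ok & xa == xd & xb == xc & xa != xb)
      tot <- s1 + s2 + s3
      if (tot > 0) vals <- c(vals, 100 * s1 / tot)
    }
    c(sCF = if (length(vals)) mean(vals) else NA_real_, n = length(vals))
  })
  data.frame(branch = names(branches),
             sCF = vapply(res, `[[`, numeric(1L), "sCF"),
             n_quartets_used = vapply(res, `[[`, numeric(1L), "n"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Quartet-based polytomy test
#'
#' Tests the null hypothesis that a branch is a polytomy, i.e. that the
#' three resolutions are equally frequent among `n1 + n2 + n3` decisive gene
#' trees, with the Pearson statistic
#' `chi2 = sum_i (n_i - N/3)^2 / (N/3)` on 2 degrees of freedom.
#'
#' @param counts Numeric vector of three non-negative counts.
#' @return List: `chi2`, `df` (= 2), `p`, and `reject` at P < 0.05.
#' @export
polytomy_test <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  N <- sum(counts)
  if (N == 0) stop("all counts are zero; the test is undefined")
  e <- N / 3
  chi2 <- sum((counts - e)^2 / e)
  p <- stats::pchisq(chi2, df = 2L, lower.tail = FALSE)
  list(chi2 = chi2, df = 2L, p = p, reject = p < 0.05)
}

# split keys of a tree together with the support of the subtending node
split_table <- function(tree) {
  taxa <- sort(tree$tip.label)
  n <- length(taxa)
  nt <- length(tree$tip.label)
  desc <- descendant_tip_sets(tree)
  sup <- branch_supports(tree)
  keys <- character(0L); supports <- numeric(0L)
  for (node in (nt + 1L):(nt + tree$Nnode)) {
    s <- desc[[node]]
    if (length(s) < 2L || length(s) > n - 2L) next
    k <- split_key(s, taxa)
    if (k %in% keys) next
    keys <- c(keys, k)
    supports <- c(supports, sup[node - nt])
  }
  data.frame(key = keys, support = supports, stringsAsFactors = FALSE)
}

split_sides <- function(key) {
  sides <- strsplit(key, "|", fixed = TRUE)[[1L]]
  lapply(strsplit(sides, ",", fixed = TRUE), identity)
}

# two splits over the same taxon set conflict iff all four side
# intersections are non-empty
splits_conflict <- function(k1, k2) {
  s1 <- split_sides(k1); s2 <- split_sides(k2)
  for (a in s1) for (b in s2)
    if (!length(intersect(a, b))) return(FALSE)
  TRUE
}

#' PhyParts-style gene-tree mapping onto a reference tree
#'
#' Each gene tree is classified against every internal reference branch as
#' concordant (it contains the branch's bipartition with adequate support),
#' conflicting (it contains a well-supported incompatible bipartition;
#' subdivided into the most common alternative vs the rest), or
#' uninformative (its relevant branches fall below `support_cutoff`).
#' Internode certainty "all" (ICA) is computed per branch from the relative
#' frequencies of the reference bipartition and its observed conflicting
#' bipartitions among informative trees, with logarithm base equal to the
#' number of retained bipartition classes, so an even split scores 0 and no
#' conflict scores 1. Classes rarer than `min_freq` are excluded.
#'
#' @param reference Rooted `phylo` reference (species) tree.
#' @param trees `gene_tree_set` or list of `phylo` carrying support values
#'   as internal node labels.
#' @param support_cutoff Support threshold below which a gene-tree branch is
#'   ignored (default 80, the conventional cutoff); `NULL` disables
#'   filtering. Branches without a numeric support value are retained.
#' @param min_freq Minimum relative frequency for a bipartition class to
#'   enter the ICA computation (default 0.05).
#' @return data.frame: branch, concordant, conflict_main, conflict_other,
#'   uninformative, ICA, ref_absent flag.
#' @export
phyparts_map <- function(reference, trees, support_cutoff = 80,
                         min_freq = 0.05) {
  tl <- if (inherits(trees, "gene_tree_set")) trees$trees else trees
  ref_keys <- split_keys(reference)
  if (!length(ref_keys)) stop("reference tree has no internal branches")
  gene_tables <- lapply(tl, split_table)
  out <- lapply(ref_keys, function(rk) {
    concord <- 0L; alt_tally <- integer(0L); uninf <- 0L
    for (gt in gene_tables) {
      kept <- gt
      if (!is.null(support_cutoff))
        kept <- gt[is.na(gt$support) | gt$support >= support_cutoff, , drop = FALSE]
      if (rk %in% kept$key) {
        concord <- concord + 1L
        next
      }
      confl <- kept$key[vapply(kept$key, splits_conflict, logical(1L), k2 = rk)]
      if (length(confl)) {
        sup <- kept$support[match(confl, kept$key)]
        sup[is.na(sup)] <- -Inf
        pick <- confl[order(-sup, confl)][1L]
        alt_tally[pick] <- if (pick %in% names(alt_tally)) alt_tally[[pick]] + 1L else 1L
      } else {
        uninf <- uninf + 1L
      }
    }
    informative <- concord + sum(alt_tally)
    ica <- NA_real_
    if (informative > 0L) {
      freqs <- c(ref = concord, alt_tally) / informative
      freqs <- freqs[freqs > 0]
      keep <- freqs >= min_freq
      if (!any(keep)) keep <- rep(TRUE, length(freqs))
      p <- freqs[keep] / sum(freqs[keep])
      k <- length(p)
      ica <- if (k == 1L) 1 else 1 + sum(p * log(p) / log(k))
    }
    alt_sorted <- sort(alt_tally, decreasing = TRUE)
    data.frame(branch = rk, concordant = concord,
               conflict_main = if (length(alt_sorted)) unname(alt_sorted[1L]) else 0L,
               conflict_other = sum(alt_sorted) - if (length(alt_sorted)) alt_sorted[1L] else 0L,
               uninformative = uninf, ICA = ica,
               ref_absent = concord == 0L, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# quartet resolution table of one tree across a fixed list of quartets
tree_quartet_vector <- function(tree, quartets, taxa) {
  M <- split_matrix(tree, taxa)
  vapply(seq_len(nrow(quartets)), function(i)
    quartet_resolution_from_splits(M, quartets[i, 1L], quartets[i, 2L],
                                   quartets[i, 3L], quartets[i, 4L]),
    integer(1L))
}

#' Exhaustive quartet-score species-tree search
#'
#' Evaluates every rooted binary topology over the ingroup (outgroup fixed
#' at the root) by its total quartet score: the number of induced quartet
#' topologies shared with the gene-tree collection, summed over all quartets
#' and gene trees. Returns the argmax (lexicographically smallest identifier
#' on ties). A desk-scale surrogate for summary-coalescent species-tree
#' estimation, valid for at most 7 ingroup taxa.
#'
#' @param trees `gene_tree_set` or list of `phylo`.
#' @param outgroup Outgroup label present in every tree.
#' @return List: `best` (topology id), `score`, `ties` (ids sharing the
#'   maximum), `scores` (named vector over all candidates).
#' @export
exhaustive_species_tree <- function(trees, outgroup) {
  tl <- if (inherits(trees, "gene_tree_set")) trees$trees else trees
  taxa <- sort(tl[[1L]]$tip.label)
  if (!outgroup %in% taxa) stop("outgroup not present in the trees")
  ingroup <- setdiff(taxa, outgroup)
  if (length(ingroup) > 7L)
    stop("exhaustive search refused for more than 7 ingroup taxa")
  quartets <- t(utils::combn(taxa, 4L))
  nq <- nrow(quartets)
  # accumulate observed quartet-resolution counts, memoized on the split set
  Q <- matrix(0, nq, 3L)
  memo <- new.env(parent = emptyenv())
  for (tr in tl) {
    key <- paste(sort(split_keys(tr)), collapse = ";")
    v <- memo[[key]]
    if (is.null(v)) {
      v <- tree_quartet_vector(tr, quartets, taxa)
      memo[[key]] <- v
    }
    for (q in seq_len(nq)) if (v[q] > 0L) Q[q, v[q]] <- Q[q, v[q]] + 1
  }
  cands <- enumerate_rooted_topologies(ingroup)
  scores <- vapply(cands, function(id) {
    nwk <- paste0("(", sub(";$", "", id), ",", outgroup, ");")
    ct <- parse_newick(nwk)
    v <- tree_quartet_vector(ct, quartets, taxa)
    sum(Q[cbind(seq_len(nq), pmax(v, 1L))][v > 0L])
  }, numeric(1L))
  best <- max(scores)
  ties <- sort(names(scores)[scores == best])
  list(best = ties[1L], score = best, ties = ties, scores = scores)
}

#' Per-branch concordance report
#'
#' Convenience wrapper combining [quartet_scores()],
#' [gene_concordance_factor()], [site_concordance_factor()] (when an
#' alignment is given), the polytomy test on the gene-count triple, and
#' [phyparts_map()], in the column layout of a per-branch TSV report.
#'
#' @inheritParams quartet_scores
#' @param alignment Optional concatenated alignment for sCF.
#' @param support_cutoff Support cutoff for the PhyParts-style mapping.
#' @param n_quartets,seed sCF sampling parameters.
#' @return data.frame with one row per internal species-tree branch.
#' @export
branch_concordance <- function(species_tree, trees, alignment = NULL,
                               support_cutoff = 80, n_quartets = 100L,
                               seed = 1L) {
  qs <- quartet_scores(species_tree, trees)
  gcf <- gene_concordance_factor(species_tree, trees)
  pp <- phyparts_map(species_tree, trees, support_cutoff = support_cutoff)
  res <- merge(qs, gcf, by = "branch", sort = FALSE)
  pol <- t(vapply(seq_len(nrow(res)), function(i) {
    pt <- polytomy_test(c(res$n1[i], res$n2[i], res$n3[i]))
    c(chi2 = pt$chi2, p_polytomy = pt$p)
  }, numeric(2L)))
  res <- cbind(res, pol)
  if (!is.null(alignment)) {
    scf <- site_concordance_factor(species_tree, alignment,
                                   n_quartets = n_quartets, seed = seed)
    res <- merge(res, scf[, c("branch", "sCF")], by = "branch", sort = FALSE)
  } else {
    res$sCF <- NA_real_
  }
  res <- merge(res, pp[, c("branch", "concordant", "conflict_main",
                           "conflict_other", "uninformative", "ICA")],
               by = "branch", sort = FALSE)
  res
}
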