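# ABBA-BABA D-statistics on polarized biallelic site patterns, with
# block-jackknife standard errors, full triplet scans, and the pairwise
# mean |D| matrix.

#' Count ABBA/BABA/BBAA site patterns for one ordered triplet
#'
#' Patterns are read off a 0/1 matrix polarized so the outgroup allele is 0:
#' for the rooted arrangement `(((P1,P2),P3),O)` a site is ABBA when
#' `(P1,P2,P3) = (0,1,1)`, BABA when `(1,0,1)` and BBAA when `(1,1,0)`.
#' Sites with missing values in any of the four taxa are skipped.
#'
#' @param patterns Integer 0/1 matrix (taxa x sites); rows named.
#' @param P1,P2,P3 Ingroup taxa in the species-tree order (P1, P2 sisters).
#' @param outgroup Outgroup row used to (re)polarize the patterns.
#' @return List of class `triplet_pattern_counts`: `nABBA`, `nBABA`,
#'   `nBBAA`, `n_sites_used`, and the taxon assignment.
#' @export
count_abba_baba <- function(patterns, P1, P2, P3, outgroup) {
  need <- c(P1, P2, P3, outgroup)
  miss <- setdiff(need, rownames(patterns))
  if (length(miss)) stop("missing taxa in pattern matrix: ",
                         paste(miss, collapse = ", "))
  o <- patterns[outgroup, ]
  x1 <- patterns[P1, ]; x2 <- patterns[P2, ]; x3 <- patterns[P3, ]
  ok <- !(is.na(o) | is.na(x1) | is.na(x2) | is.na(x3))
  # polarize relative to the outgroup (0 = ancestral)
  x1 <- xor(x1[ok] == 1L, o[ok] == 1L)
  x2 <- xor(x2[ok] == 1L, o[ok] == 1L)
  x3 <- xor(x3[ok] == 1L, o[ok] == 1L)
  structure(list(P1 = P1, P2 = P2, P3 = P3, outgroup = outgroup,
                 nABBA = sum(!x1 & x2 & x3),
                 nBABA = sum(x1 & !x2 & x3),
                 nBBAA = sum(x1 & x2 & !x3),
                 n_sites_used = sum(ok)),
            class = "triplet_pattern_counts")
}

#' D-statistic with delete-one block-jackknife Z-score
#'
#' `D = (nABBA - nBABA) / (nABBA + nBABA)` from pooled counts; the standard
#' error comes from delete-one jackknife over blocks (by default one block
#' per locus), `Z = D / SE`, and the two-sided normal P value. Following the
#' usual convention, `|Z| > 3` flags significant gene flow: between P2 and
#' P3 when D > 0 and between P1 and P3 when D < 0.
#'
#' @param block_counts data.frame or matrix with columns `nABBA`, `nBABA`,
#'   one row per block.
#' @param P1,P2,P3 Optional taxon labels carried into the gene-flow call.
#' @return List of class `d_result`: `D`, `Z`, `P`, `SE`, `significant`
#'   (`|Z| > 3`), `pair` (the implicated pair or `NA`), pooled counts and
#'   number of blocks.
#' @export
d_with_jackknife <- function(block_counts, P1 = NA, P2 = NA, P3 = NA) {
  bc <- as.data.frame(block_counts)
  stopifnot(all(c("nABBA", "nBABA") %in% names(bc)))
  bc <- bc[bc$nABBA + bc$nBABA > 0, , drop = FALSE]
  m <- nrow(bc)
  A <- sum(bc$nABBA); B <- sum(bc$nBABA)
  if (A + B == 0)
    return(structure(list(D = NA_real_, Z = NA_real_, P = NA_real_,
                          SE = NA_real_, significant = FALSE, pair = NA,
                          nABBA = 0, nBABA = 0, n_blocks = 0,
                          P1 = P1, P2 = P2, P3 = P3), class = "d_result"))
  D <- (A - B) / (A + B)
  if (m < 20L)
    warning("fewer than 20 non-empty blocks (", m, "); jackknife SE is unstable")
  if (m >= 2L) {
    Dm <- vapply(seq_len(m), function(i) {
      a <- A - bc$nABBA[i]; b <- B - bc$nBABA[i]
      if (a + b == 0) return(NA_real_)
      (a - b) / (a + b)
    }, numeric(1L))
    Dm <- Dm[!is.na(Dm)]
    mm <- length(Dm)
    SE <- sqrt((mm - 1) / mm * sum((Dm - mean(Dm))^2))
  } else {
    SE <- NA_real_
  }
  Z <- if (!is.na(SE) && SE > 0) D / SE else if (D == 0) 0 else NA_real_
  P <- if (is.na(Z)) NA_real_ else 2 * stats::pnorm(-abs(Z))
  significant <- !is.na(Z) && abs(Z) > 3
  pair <- NA
  if (significant) pair <- if (D > 0) c(P2, P3) else c(P1, P3)
  structure(list(D = D, Z = Z, P = P, SE = SE, significant = significant,
                 pair = pair, nABBA = A, nBABA = B, n_blocks = m,
                 P1 = P1, P2 = P2, P3 = P3), class = "d_result")
}

#' @export
print.d_result <- function(x, ...) {
  cat(sprintf("D = %.4f  Z = %.2f  P = %.3g  (ABBA %d / BABA %d, %d blocks)\n",
              x$D, x$Z, x$P, x$nABBA, x$nBABA, x$n_blocks))
  invisible(x)
}

# order an unordered triplet so the species-tree sister pair is (P1, P2);
# returns c(P1, P2, P3) with P1 < P2 lexicographically
order_triplet <- function(triplet, species_tree, outgroup) {
  id <- canonical_topology_id(
    ape::keep.tip(species_tree, c(triplet, outgroup)), outgroup)
  # the sister pair is the innermost "(x,y)" pair of the 3-taxon id
  inner <- regmatches(id, gregexpr("\\(([^(),]+),([^(),]+)\\)", id))[[1L]]
  pair <- strsplit(gsub("[()]", "", inner[1L]), ",", fixed = TRUE)[[1L]]
  p3 <- setdiff(triplet, pair)
  c(sort(pair), p3)
}

#' D-statistic scan over all taxon triplets
#'
#' Runs [count_abba_baba()] and [d_with_jackknife()] for every unordered
#' ingroup triplet, with `(P1, P2)` assigned to the species-tree sister pair
#' when a species tree is supplied. Blocks default to one per locus.
#'
#' @param patterns 0/1 matrix (taxa x sites) or list of per-locus matrices
#'   (each becoming one jackknife block).
#' @param ingroup Character vector of ingroup taxa (>= 3).
#' @param outgroup Outgroup label.
#' @param species_tree Optional `phylo` fixing the sister pair per triplet;
#'   without it all three orderings are evaluated and flagged.
#' @param blocks Optional integer vector assigning each site (column) to a
#'   jackknife block when `patterns` is a single matrix; default one block.
#' @return data.frame with one row per evaluated arrangement: P1, P2, P3,
#'   nABBA, nBABA, D, Z, P, significant, pair_a, pair_b.
#' @export
triplet_scan <- function(patterns, ingroup, outgroup, species_tree = NULL,
                         blocks = NULL) {
  if (length(ingroup) < 3L) stop("need at least 3 ingroup taxa")
  if (is.list(patterns) && !is.matrix(patterns)) {
    mats <- patterns
  } else {
    if (is.null(blocks)) blocks <- rep(1L, ncol(patterns))
    mats <- lapply(split(seq_len(ncol(patterns)), blocks),
                   function(j) patterns[, j, drop = FALSE])
  }
  triplets <- utils::combn(sort(ingroup), 3L, simplify = FALSE)
  rows <- list()
  for (tri in triplets) {
    orderings <- if (!is.null(species_tree)) {
      list(order_triplet(tri, species_tree, outgroup))
    } else {
      lapply(1:3, function(i) c(sort(tri[-i]), tri[i]))
    }
    for (ord in orderings) {
      bc <- t(vapply(mats, function(m) {
        ct <- count_abba_baba(m, ord[1L], ord[2L], ord[3L], outgroup)
        c(nABBA = ct$nABBA, nBABA = ct$nBABA)
      }, numeric(2L)))
      dr <- d_with_jackknife(as.data.frame(bc), ord[1L], ord[2L], ord[3L])
      rows[[length(rows) + 1L]] <- data.frame(
        P1 = ord[1L], P2 = ord[2L], P3 = ord[3L],
        nABBA = dr$nABBA, nBABA = dr$nBABA, D = dr$D, Z = dr$Z, P = dr$P,
        significant = dr$significant,
        pair_a = if (dr$significant) dr$pair[1L] else NA_character_,
        pair_b = if (dr$significant) dr$pair[2L] else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "ordering") <- if (is.null(species_tree)) "all" else "species_tree"
  res
}

#' Pairwise mean |D| matrix
#'
#' For every species pair, the mean of |D| over all triplet results that
#' implicate that pair as the gene-flow pair. The display matrix zeroes
#' pairs with no significant result (the usual figure convention); the raw
#' matrix averages |D| over the candidate pair of every result regardless of
#' significance.
#'
#' @param results data.frame from [triplet_scan()].
#' @param taxa Optional taxon ordering for the matrix.
#' @return List with `display` and `raw` symmetric matrices.
#' @export
pairwise_mean_abs_d <- function(results, taxa = NULL) {
  if (is.null(taxa))
    taxa <- sort(unique(c(results$P1, results$P2, results$P3)))
  disp <- raw <- matrix(0, length(taxa), length(taxa),
                        dimnames = list(taxa, taxa))
  nsig <- nraw <- matrix(0L, length(taxa), length(taxa),
                         dimnames = list(taxa, taxa))
  for (i in seq_len(nrow(results))) {
    D <- results$D[i]
    if (is.na(D)) next
    cand <- if (D >= 0) c(results$P2[i], results$P3[i])
            else c(results$P1[i], results$P3[i])
    raw[cand[1L], cand[2L]] <- raw[cand[1L], cand[2L]] + abs(D)
    nraw[cand[1L], cand[2L]] <- nraw[cand[1L], cand[2L]] + 1L
    if (isTRUE(results$significant[i])) {
      disp[cand[1L], cand[2L]] <- disp[cand[1L], cand[2L]] + abs(D)
      nsig[cand[1L], cand[2L]] <- nsig[cand[1L], cand[2L]] + 1L
    }
  }
  # symmetrize by combining (a,b) and (b,a) accumulations
  sym <- function(acc, n) {
    out <- matrix(0, length(taxa), length(taxa), dimnames = dimnames(acc))
    for (a in seq_along(taxa)) for (b in seq_along(taxa)) {
      if (a >= b) next
      tot <- acc[a, b] + acc[b, a]
      cnt <- n[a, b] + n[b, a]
      out[a, b] <- out[b, a] <- if (cnt > 0L) tot / cnt else 0
    }
    out
  }
  list(display = sym(disp, nsig), raw = sym(raw, nraw))
}
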