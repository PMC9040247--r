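# All-pairs Robinson-Foulds matrices and classical PCoA tree-space
# embedding.

#' All-pairs Robinson-Foulds distance matrix
#'
#' @param trees `gene_tree_set` or list of `phylo` over a shared leaf set.
#' @param normalized Normalize each distance by `2 (n - 3)`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
rf_matrix <- function(trees, normalized = FALSE) {
  tl <- if (inherits(trees, "gene_tree_set")) trees$trees else trees
  m <- length(tl)
  labs <- sort(tl[[1L]]$tip.label)
  for (tr in tl) if (!identical(sort(tr$tip.label), labs))
    stop("all trees must share the same leaf set")
  keysets <- lapply(tl, split_keys)
  n <- length(labs)
  denom <- if (normalized && n > 3L) 2 * (n - 3) else 1
  D <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    d <- length(setdiff(keysets[[i]], keysets[[j]])) +
         length(setdiff(keysets[[j]], keysets[[i]]))
    D[i, j] <- D[j, i] <- d / denom
  }
  nm <- names(tl)
  if (is.null(nm)) nm <- paste0("tree", seq_len(m))
  dimnames(D) <- list(nm, nm)
  D
}

#' Classical principal coordinates analysis (Torgerson MDS)
#'
#' Double-centers the squared distance matrix, eigendecomposes, and scales
#' eigenvectors by the square root of their (positive) eigenvalues. Negative
#' eigenvalues are reported but not used for coordinates.
#'
#' @param D Symmetric non-negative distance matrix.
#' @param n_axes Number of axes to retain (capped at the number of positive
#'   eigenvalues).
#' @return Object of class `treespace_pcoa`: `coords` (points x axes),
#'   `eigenvalues` (all, descending), `var_explained` (fractions over
#'   positive eigenvalues), `negative_eigenvalues` count.
#' @export
pcoa <- function(D, n_axes = 2L) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("distance matrix must be symmetric")
  m <- nrow(D)
  J <- diag(m) - matrix(1 / m, m, m)
  B <- -0.5 * J %*% (D^2) %*% J
  es <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- es$values
  pos <- which(ev > max(ev[1L], 0) * 1e-12)
  if (!length(pos)) {
    coords <- matrix(0, m, max(1L, n_axes))
  } else {
    k <- min(n_axes, length(pos))
    coords <- es$vectors[, pos[seq_len(k)], drop = FALSE] %*%
      diag(sqrt(ev[pos[seq_len(k)]]), k, k)
    if (k < n_axes)
      coords <- cbind(coords, matrix(0, m, n_axes - k))
  }
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  neg <- sum(ev < -max(abs(ev[1L]), 1e-12) * 1e-8)
  if (neg > 0)
    warning(neg, " negative eigenvalue(s) truncated (non-Euclidean distances)")
  structure(list(coords = coords, eigenvalues = ev,
                 var_explained = pmax(ev, 0) / sum(pmax(ev, 0)),
                 negative_eigenvalues = neg),
            class = "treespace_pcoa")
}

#' @export
print.treespace_pcoa <- function(x, ...) {
  cat("PCoA embedding:", nrow(x$coords), "points,", ncol(x$coords), "axes;",
      "first-axis variance:", sprintf("%.1f%%", 100 * x$var_explained[1L]), "\n")
  invisible(x)
}
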