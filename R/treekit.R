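# Rooted-tree data model on top of ape's "phylo": Newick I/O, bipartitions,
# canonical topology identifiers, topology enumeration, Robinson-Foulds
# distance and root-to-tip path lengths.

#' Parse a Newick string into a validated phylo tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. Branch lengths and
#' internal-node labels (conventionally bootstrap/support values) are
#' preserved. Leaf labels must be unique and branch lengths non-negative.
#'
#' @param text A single Newick string, terminated by `;`.
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed Newick: unmatched ')' at character %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("malformed Newick: %d '(' left unclosed at end of string", depth))
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick: could not parse tree")
  validate_tree(tr)
  tr
}

#' @keywords internal
validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE))
    stop("negative branch length(s) are not allowed")
  sup <- branch_supports(tree)
  if (any(!is.na(sup) & (sup < 0 | sup > 100)))
    stop("support values must lie in [0, 100]")
  invisible(tree)
}

#' Extract numeric support values stored as internal-node labels
#'
#' @param tree A `phylo` object.
#' @return Numeric vector over internal nodes (NA where no numeric label).
#' @export
branch_supports <- function(tree) {
  nn <- tree$Nnode
  if (is.null(tree$node.label)) return(rep(NA_real_, nn))
  suppressWarnings(as.numeric(tree$node.label))
}

# smallest descendant tip label per node (character), used for canonical order
min_desc_label <- function(tree) {
  nt <- length(tree$tip.label)
  nnode <- nt + tree$Nnode
  out <- character(nnode)
  out[seq_len(nt)] <- tree$tip.label
  # postorder over edges guarantees children before parents
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    if (out[p] == "" || out[ch] < out[p]) out[p] <- out[ch]
  }
  out
}

#' Write a phylo tree as a Newick string
#'
#' Round-trips through [parse_newick()] up to numeric formatting. With
#' `canonical = TRUE` children are emitted sorted by their smallest
#' descendant leaf label, so the output is a deterministic function of the
#' rooted topology.
#'
#' @param tree A `phylo` object.
#' @param canonical Emit children in canonical (sorted) order.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string.
#' @export
write_newick <- function(tree, canonical = FALSE, digits = 10) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  nedge <- nrow(tree$edge)
  kids <- vector("list", nt + tree$Nnode)
  for (e in seq_len(nedge)) kids[[tree$edge[e, 1L]]] <- c(kids[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  edge_of <- integer(nt + tree$Nnode)
  edge_of[tree$edge[, 2L]] <- seq_len(nedge)
  has_len <- !is.null(tree$edge.length)
  nl <- tree$node.label
  mins <- if (canonical) min_desc_label(tree) else NULL
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  rec <- function(node) {
    if (node <= nt) {
      s <- tree$tip.label[node]
    } else {
      ch <- kids[[node]]
      if (canonical) ch <- ch[order(mins[ch])]
      s <- paste0("(", paste(vapply(ch, rec, character(1L)), collapse = ","), ")")
      if (!is.null(nl)) {
        lab <- nl[node - nt]
        if (!is.na(lab) && nzchar(lab)) s <- paste0(s, lab)
      }
    }
    if (has_len && node != root) s <- paste0(s, ":", fmt(tree$edge.length[edge_of[node]]))
    s
  }
  paste0(rec(root), ";")
}

# tip-label sets below every node, as a list indexed by node id
descendant_tip_sets <- function(tree) {
  nt <- length(tree$tip.label)
  out <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) out[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

# canonical string key of the non-trivial split defined by tip set `side`
# within taxon set `taxa`: the side holding the overall smallest label comes
# first; labels sorted within sides.
split_key <- function(side, taxa) {
  other <- setdiff(taxa, side)
  s1 <- sort(side); s2 <- sort(other)
  if (s2[1L] < s1[1L]) { tmp <- s1; s1 <- s2; s2 <- tmp }
  paste0(paste(s1, collapse = ","), "|", paste(s2, collapse = ","))
}

# all non-trivial unrooted split keys of a tree (deduplicated)
split_keys <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  if (n < 4L) return(character(0L))
  desc <- descendant_tip_sets(tree)
  nt <- n
  keys <- character(0L)
  for (node in (nt + 1L):(nt + tree$Nnode)) {
    s <- desc[[node]]
    if (length(s) < 2L || length(s) > n - 2L) next
    keys <- c(keys, split_key(s, labs))
  }
  unique(keys)
}

#' Non-trivial bipartitions of a tree
#'
#' One bipartition per internal edge of the unrooted interpretation of the
#' tree; trivial (leaf) splits and the root split are excluded. Each
#' bipartition is canonical: the side holding the lexicographically smallest
#' taxon is listed first, labels sorted within sides.
#'
#' @param tree A `phylo` object.
#' @return A list of class `bipartition_set`; each element has `$side1`,
#'   `$side2` and a canonical `$key`. Trees with fewer than 4 leaves yield an
#'   empty set.
#' @export
bipartitions <- function(tree) {
  taxa <- sort(tree$tip.label)
  keys <- split_keys(tree)
  out <- lapply(keys, function(k) {
    sides <- strsplit(k, "|", fixed = TRUE)[[1L]]
    list(side1 = strsplit(sides[1L], ",", fixed = TRUE)[[1L]],
         side2 = strsplit(sides[2L], ",", fixed = TRUE)[[1L]],
         key = k)
  })
  names(out) <- keys
  structure(out, class = "bipartition_set", taxa = taxa)
}

# canonical rooted-topology string: lengths dropped, children sorted by
# smallest descendant label
topo_string <- function(tree) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  kids <- vector("list", nt + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) kids[[tree$edge[e, 1L]]] <- c(kids[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  mins <- min_desc_label(tree)
  rec <- function(node) {
    if (node <= nt) return(tree$tip.label[node])
    ch <- kids[[node]]
    ch <- ch[order(mins[ch])]
    paste0("(", paste(vapply(ch, rec, character(1L)), collapse = ","), ")")
  }
  paste0(rec(root), ";")
}

#' Canonical topology identifier of a gene tree
#'
#' The tree is rerooted on the outgroup's pendant edge, the outgroup is
#' dropped, and the remaining rooted ingroup topology is serialized with
#' children sorted by smallest descendant label and branch lengths ignored.
#' The identifier is invariant to branch lengths, child order and input
#' rooting.
#'
#' @param tree A `phylo` object containing `outgroup` among its leaves.
#' @param outgroup Single leaf label used to root the tree.
#' @return A canonical topology string (the `TopologyID`).
#' @export
canonical_topology_id <- function(tree, outgroup) {
  o <- match(outgroup, tree$tip.label)
  if (is.na(o))
    stop("outgroup '", outgroup, "' is not among the leaf labels")
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  # adjacency list of the unrooted interpretation; degree-2 nodes (the input
  # root) are suppressed during traversal
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  rec <- function(node, from) {
    nbr <- adj[[node]]
    nbr <- nbr[nbr != from]
    if (!length(nbr)) return(list(s = tree$tip.label[node],
                                  min = tree$tip.label[node]))
    if (length(nbr) == 1L) return(rec(nbr, node))   # pass through degree-2
    subs <- lapply(nbr, rec, from = node)
    ord <- order(vapply(subs, `[[`, character(1L), "min"))
    subs <- subs[ord]
    list(s = paste0("(", paste(vapply(subs, `[[`, character(1L), "s"),
                               collapse = ","), ")"),
         min = subs[[1L]]$min)
  }
  paste0(rec(adj[[o]][1L], o)$s, ";")
}

#' Enumerate all rooted binary leaf-labeled topologies
#'
#' Generates the `(2k - 3)!!` distinct rooted binary topologies over `k`
#' ingroup labels by stepwise leaf addition, returning canonical topology
#' identifiers compatible with [canonical_topology_id()].
#'
#' @param ingroup_labels Character vector of 2 to 8 unique labels.
#' @return Sorted character vector of topology identifiers.
#' @export
enumerate_rooted_topologies <- function(ingroup_labels) {
  labs <- as.character(ingroup_labels)
  k <- length(labs)
  if (anyDuplicated(labs)) stop("ingroup labels must be unique")
  if (k < 2L) stop("need at least 2 ingroup labels")
  if (k > 8L)
    stop("refusing to enumerate rooted topologies for more than 8 ingroup taxa (",
         "(2k-3)!! grows too quickly)")
  labs <- sort(labs)
  # nested-list representation; insert next label on every edge incl. above root
  insert_all <- function(top, lab) {
    res <- list(list(top, lab))  # new root above the old one
    recurse <- function(node) {
      if (!is.list(node)) return(list())
      out <- list()
      for (i in 1:2) {
        repl <- node
        repl[[i]] <- list(node[[i]], lab)
        out <- c(out, list(repl))
        for (sub in recurse(node[[i]])) {
          repl2 <- node
          repl2[[i]] <- sub
          out <- c(out, list(repl2))
        }
      }
      out
    }
    c(res, recurse(top))
  }
  tops <- list(list(labs[1L], labs[2L]))
  for (i in seq_len(k)[-(1:2)]) {
    tops <- unlist(lapply(tops, insert_all, lab = labs[i]), recursive = FALSE)
  }
  to_string <- function(node) {
    if (!is.list(node)) return(node)
    a <- to_string(node[[1L]]); b <- to_string(node[[2L]])
    # order children by smallest descendant label
    ka <- gsub("[();]", "", a); ka <- min(strsplit(ka, ",", fixed = TRUE)[[1L]])
    kb <- gsub("[();]", "", b); kb <- min(strsplit(kb, ",", fixed = TRUE)[[1L]])
    if (kb < ka) { tmp <- a; a <- b; b <- tmp }
    paste0("(", a, ",", b, ")")
  }
  ids <- vapply(tops, function(t) paste0(to_string(t), ";"), character(1L))
  ids <- sort(unique(ids))
  expected <- dfactorial_odd(2L * k - 3L)
  if (length(ids) != expected)
    stop("internal error: enumerated ", length(ids), " topologies, expected ", expected)
  ids
}

# odd double factorial n!! for odd n >= -1
dfactorial_odd <- function(n) {
  if (n <= 0L) return(1)
  prod(seq(1L, n, by = 2L))
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of non-trivial unrooted bipartitions; the
#' normalized version divides by `2 (n - 3)` so two fully resolved trees that
#' share no split score 1. Polytomous trees contribute whatever splits they
#' have.
#'
#' @param t1,t2 `phylo` objects over the same leaf set.
#' @param normalized Divide by the maximum `2 (n - 3)`.
#' @return A single non-negative number.
#' @export
rf_distance <- function(t1, t2, normalized = FALSE) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2))
    stop("trees have different leaf sets; prune them explicitly first")
  k1 <- split_keys(t1); k2 <- split_keys(t2)
  d <- length(setdiff(k1, k2)) + length(setdiff(k2, k1))
  if (normalized) {
    n <- length(l1)
    if (n <= 3L) return(0)
    d <- d / (2 * (n - 3))
  }
  d
}

#' Root-to-tip path lengths
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return Named numeric vector: sum of branch lengths from root to each leaf.
#' @export
root_to_tip_lengths <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  nt <- length(tree$tip.label)
  depth <- numeric(nt + tree$Nnode)
  pr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (e in seq_len(nrow(pr$edge))) {
    depth[pr$edge[e, 2L]] <- depth[pr$edge[e, 1L]] + pr$edge.length[e]
  }
  stats::setNames(depth[seq_len(nt)], tree$tip.label)
}
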