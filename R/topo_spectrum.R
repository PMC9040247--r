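# Gene-tree topology classification and frequency spectra.

#' Classify one gene tree into a canonical rooted topology
#'
#' Delegates to [canonical_topology_id()] after checking the tree carries the
#' outgroup and the full ingroup. Trees whose ingroup part is not fully
#' resolved (polytomies) are flagged `"unresolved"` rather than classified.
#'
#' @param tree A `phylo`.
#' @param outgroup Outgroup leaf label.
#' @param ingroup Optional expected ingroup labels (checked when given).
#' @return A topology identifier string, or `NA` with attribute
#'   `unresolved = TRUE` for polytomous trees.
#' @export
classify_topology <- function(tree, outgroup, ingroup = NULL) {
  labs <- tree$tip.label
  need <- c(outgroup, ingroup)
  miss <- setdiff(need, labs)
  if (length(miss)) stop("tree is missing taxa: ", paste(miss, collapse = ", "))
  id <- canonical_topology_id(tree, outgroup)
  k <- length(labs) - 1L
  # a resolved rooted ingroup topology has k - 1 internal nodes -> k - 1 "("
  if (lengths(regmatches(id, gregexpr("(", id, fixed = TRUE))) < k - 1L) {
    out <- NA_character_
    attr(out, "unresolved") <- TRUE
    return(out)
  }
  id
}

#' Topology frequency spectrum of a gene-tree set
#'
#' Classifies every tree and reports counts and frequencies over the full
#' enumerated universe of rooted ingroup topologies (zero rows included).
#' Unresolved trees are excluded from the denominator and reported
#' separately. Ranks are by decreasing count with lexicographic topology-id
#' tie-break.
#'
#' @param trees A `gene_tree_set` or list of `phylo`.
#' @param outgroup Outgroup label.
#' @return A `topology_spectrum`: data.frame (topology_id, rank, count,
#'   frequency) plus attributes `total` (classified trees) and `unresolved`.
#' @export
topology_spectrum <- function(trees, outgroup) {
  tl <- if (inherits(trees, "gene_tree_set")) trees$trees else trees
  if (!length(tl)) stop("no trees supplied")
  labs <- sort(tl[[1L]]$tip.label)
  ingroup <- setdiff(labs, outgroup)
  ids <- vapply(tl, function(tr) {
    id <- classify_topology(tr, outgroup)
    if (is.na(id)) NA_character_ else id
  }, character(1L))
  unresolved <- sum(is.na(ids))
  ids <- ids[!is.na(ids)]
  if (!length(ids)) stop("no classifiable (fully resolved) trees")
  universe <- enumerate_rooted_topologies(ingroup)
  counts <- table(factor(ids, levels = universe))
  bad <- setdiff(unique(ids), universe)
  if (length(bad))
    stop("classified topology outside the enumerated universe: ", bad[1L])
  df <- data.frame(topology_id = universe, count = as.integer(counts),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$topology_id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$frequency <- df$count / sum(df$count)
  rownames(df) <- NULL
  df <- df[, c("topology_id", "rank", "count", "frequency")]
  structure(df, class = c("topology_spectrum", "data.frame"),
            total = sum(df$count), unresolved = unresolved)
}

#' @export
print.topology_spectrum <- function(x, n = 10L, ...) {
  cat("Topology spectrum:", attr(x, "total"), "classified trees over",
      nrow(x), "possible topologies (", attr(x, "unresolved"),
      "unresolved excluded )\n")
  print.data.frame(utils::head(x, n))
  invisible(x)
}
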