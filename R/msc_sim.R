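# Multispecies-coalescent gene-tree simulator with discrete introgression
# pulses, clade rate multipliers, sequence simulation (JC69/HKY) and
# biallelic site-pattern extraction.

#' Define a coalescent-with-introgression simulation scenario
#'
#' The species tree is ultrametric with branch lengths in arbitrary time
#' units (for example Ma). `pop_scale` converts time to coalescent units:
#' within a species branch, each lineage pair coalesces at rate
#' `1 / pop_scale` per time unit, so a branch of duration `T * pop_scale`
#' spans `T` coalescent units. Introgression is modeled as instantaneous
#' unidirectional pulses: at the pulse time (looking backward), every lineage
#' in the recipient branch jumps to the donor branch independently with
#' probability `gamma` (the inheritance probability).
#'
#' @param species_tree Newick string or `phylo`; rooted, binary, ultrametric,
#'   branch lengths in time units.
#' @param loci Number of gene trees to simulate.
#' @param mu Substitution rate (substitutions/site/time unit).
#' @param pop_scale Time units per coalescent unit; a single number, or a
#'   number plus per-branch overrides via `branch_scales`.
#' @param branch_scales Optional list of `list(tips=, scale=)` overriding
#'   `pop_scale` on the branch above the MRCA of `tips`.
#' @param pulses Optional list of `list(donor=, recipient=, time=, gamma=)`;
#'   `donor`/`recipient` are tip-label vectors identifying a species-tree
#'   branch by the clade beneath it.
#' @param rates Optional list of `list(tips=, r=)`: rate multiplier `r`
#'   applied to every species-tree branch inside the clade of `tips`
#'   (including its stem); background rate 1.
#' @param locus_length Sites per simulated locus alignment.
#' @param model Substitution model for sequence simulation.
#' @param kappa Transition/transversion rate ratio (HKY only).
#' @param outgroup Optional outgroup label recorded for downstream stages.
#' @param seed Integer seed; the scenario is fully reproducible given it.
#' @return An object of class `msc_scenario`.
#' @export
scenario <- function(species_tree, loci, mu = 1e-3, pop_scale = 1,
                     branch_scales = NULL, pulses = NULL, rates = NULL,
                     locus_length = 500L, model = c("JC69", "HKY"),
                     kappa = 2, outgroup = NULL, seed = 1L) {
  if (is.character(species_tree)) species_tree <- parse_newick(species_tree)
  model <- match.arg(model)
  sc <- structure(
    list(species_tree = species_tree, loci = as.integer(loci), mu = mu,
         pop_scale = pop_scale, branch_scales = branch_scales,
         pulses = pulses, rates = rates,
         locus_length = as.integer(locus_length), model = model,
         kappa = kappa, outgroup = outgroup, seed = as.integer(seed)),
    class = "msc_scenario")
  validate_scenario(sc)
  sc
}

#' @export
print.msc_scenario <- function(x, ...) {
  cat("MSC scenario:", length(x$species_tree$tip.label), "taxa,",
      x$loci, "loci, mu =", x$mu, "\n")
  cat("  pulses:", if (is.null(x$pulses)) 0 else length(x$pulses),
      " rate multipliers:", if (is.null(x$rates)) 0 else length(x$rates), "\n")
  invisible(x)
}

# --- species-tree geometry ---------------------------------------------------

# node times (before present), parents, children, branch intervals
species_tree_internals <- function(st, tol = 1e-8) {
  nt <- length(st$tip.label)
  depth <- numeric(nt + st$Nnode)
  pr <- ape::reorder.phylo(st, "cladewise")
  for (e in seq_len(nrow(pr$edge)))
    depth[pr$edge[e, 2L]] <- depth[pr$edge[e, 1L]] + pr$edge.length[e]
  h <- max(depth[seq_len(nt)])
  if (max(depth[seq_len(nt)]) - min(depth[seq_len(nt)]) > tol * max(h, 1))
    stop("species tree must be ultrametric (contemporaneous tips)")
  node_time <- h - depth
  node_time[seq_len(nt)] <- 0
  parent <- integer(nt + st$Nnode)
  for (e in seq_len(nrow(st$edge))) parent[st$edge[e, 2L]] <- st$edge[e, 1L]
  children <- vector("list", nt + st$Nnode)
  for (e in seq_len(nrow(st$edge)))
    children[[st$edge[e, 1L]]] <- c(children[[st$edge[e, 1L]]], st$edge[e, 2L])
  root <- nt + 1L
  list(ntips = nt, root = root, node_time = node_time, parent = parent,
       children = children, desc = descendant_tip_sets(st))
}

# species-tree branch id (= node id below the branch) for a clade tip set
branch_for_clade <- function(st, si, tips) {
  tips <- as.character(tips)
  miss <- setdiff(tips, st$tip.label)
  if (length(miss)) stop("unknown taxa in clade spec: ", paste(miss, collapse = ", "))
  if (length(tips) == 1L) return(match(tips, st$tip.label))
  cand <- which(vapply(si$desc, function(d) setequal(d, tips), logical(1L)))
  if (!length(cand))
    stop("clade {", paste(sort(tips), collapse = ","), "} is not monophyletic in the species tree")
  cand[1L]
}

# branch lifespan [t_low, t_high]
branch_interval <- function(si, b) {
  hi <- if (b == si$root) Inf else si$node_time[si$parent[b]]
  c(si$node_time[b], hi)
}

validate_scenario <- function(sc) {
  st <- sc$species_tree
  if (is.null(st$edge.length)) stop("species tree needs branch lengths (times)")
  si <- species_tree_internals(st)
  if (sc$loci < 1L) stop("loci must be >= 1")
  if (sc$mu < 0) stop("mu must be >= 0")
  if (any(unlist(sc$pop_scale) <= 0)) stop("pop_scale must be > 0")
  for (p in sc$pulses) {
    if (p$gamma < 0 || p$gamma > 1) stop("pulse gamma must lie in [0, 1]")
    bd <- branch_for_clade(st, si, p$donor)
    br <- branch_for_clade(st, si, p$recipient)
    if (bd == br) stop("pulse donor and recipient must differ")
    id <- branch_interval(si, bd); ir <- branch_interval(si, br)
    if (p$time <= max(id[1], ir[1]) || p$time >= min(id[2], ir[2]))
      stop("pulse time ", p$time, " is outside the joint lifespan of donor and recipient")
  }
  for (r in sc$rates) {
    if (r$r <= 0) stop("rate multipliers must be > 0")
    branch_for_clade(st, si, r$tips)
  }
  if (!is.null(sc$outgroup) && !sc$outgroup %in% st$tip.label)
    stop("outgroup is not a species-tree tip")
  invisible(sc)
}

# per-branch rate multiplier and coalescent scale vectors
branch_parameter_maps <- function(sc, si) {
  st <- sc$species_tree
  nb <- si$ntips + st$Nnode
  rmult <- rep(1, nb)
  for (r in sc$rates) {
    b <- branch_for_clade(st, si, r$tips)
    inside <- if (b <= si$ntips) b else
      c(b, which(vapply(seq_len(nb), function(v)
        v != b && all(si$desc[[v]] %in% si$desc[[b]]), logical(1L))))
    rmult[inside] <- r$r
  }
  scale <- rep(if (is.numeric(sc$pop_scale)) sc$pop_scale[1L] else 1, nb)
  for (bs in sc$branch_scales) {
    b <- branch_for_clade(st, si, bs$tips)
    scale[b] <- bs$scale
  }
  list(rmult = rmult, scale = scale)
}

# --- per-locus coalescent ----------------------------------------------------

# one gene tree; lengths in time units, attr "wlen" = rate-weighted lengths
sim_one_locus <- function(si, maps, events) {
  nt <- si$ntips
  n_gt_nodes <- 2L * nt - 1L
  gt_child <- matrix(0L, nt - 1L, 2L)
  gt_time <- numeric(nt - 1L)
  par_of <- integer(n_gt_nodes)       # parent gene-tree node (creation ids)
  raw_len <- numeric(n_gt_nodes)
  w_len <- numeric(n_gt_nodes)
  # active lineages
  lin_node <- seq_len(nt)             # gene-tree node carried by each lineage
  lin_host <- seq_len(nt)             # species branch currently hosting it
  lin_w <- numeric(nt)                # accumulated rate-weighted length
  lin_t0 <- numeric(nt)               # birth time of the pending edge
  t <- 0
  next_internal <- nt                 # creation counter for internal nodes
  ei <- 1L
  nev <- nrow(events)
  repeat {
    t_next <- if (ei <= nev) events$time[ei] else Inf
    # coalesce within [t, t_next)
    repeat {
      if (length(lin_node) < 2L) break
      hosts <- unique(lin_host)
      rate_b <- vapply(hosts, function(b) {
        k <- sum(lin_host == b)
        k * (k - 1) / 2 / maps$scale[b]
      }, numeric(1L))
      R <- sum(rate_b)
      if (R == 0) break
      w <- stats::rexp(1L, R)
      if (t + w >= t_next) break
      dt <- w
      lin_w <- lin_w + dt * maps$rmult[lin_host]
      t <- t + w
      b <- hosts[sample.int(length(hosts), 1L, prob = rate_b)]
      in_b <- which(lin_host == b)
      pair <- if (length(in_b) == 2L) in_b else in_b[sample.int(length(in_b), 2L)]
      next_internal <- next_internal + 1L
      j <- next_internal - nt
      gt_child[j, ] <- lin_node[pair]
      gt_time[j] <- t
      for (q in pair) {
        par_of[lin_node[q]] <- next_internal
        raw_len[lin_node[q]] <- t - lin_t0[q]
        w_len[lin_node[q]] <- lin_w[q]
      }
      keep <- pair[1L]
      lin_node[keep] <- next_internal
      lin_w[keep] <- 0
      lin_t0[keep] <- t
      drop <- pair[2L]
      lin_node <- lin_node[-drop]; lin_host <- lin_host[-drop]
      lin_w <- lin_w[-drop]; lin_t0 <- lin_t0[-drop]
    }
    if (ei > nev) break
    dt <- t_next - t
    lin_w <- lin_w + dt * maps$rmult[lin_host]
    t <- t_next
    if (events$type[ei] == "merge") {
      v <- events$node[ei]
      ch <- si$children[[v]]
      lin_host[lin_host %in% ch] <- v
    } else {                           # pulse
      hit <- which(lin_host == events$recipient[ei])
      if (length(hit)) {
        move <- hit[stats::runif(length(hit)) < events$gamma[ei]]
        lin_host[move] <- events$donor[ei]
      }
    }
    ei <- ei + 1L
  }
  # assemble phylo: renumber internal creation ids so the root (last created,
  # creation id 2*nt-1) becomes ape node nt+1
  renum <- function(id) if (id <= nt) id else nt + (n_gt_nodes - id + 1L)
  edge <- matrix(0L, n_gt_nodes - 1L, 2L)
  elen <- numeric(n_gt_nodes - 1L)
  wlen <- numeric(n_gt_nodes - 1L)
  r <- 0L
  for (id in seq_len(n_gt_nodes - 1L)) {   # every node except the root
    r <- r + 1L
    edge[r, ] <- c(renum(par_of[id]), renum(id))
    elen[r] <- raw_len[id]
    wlen[r] <- w_len[id]
  }
  tr <- list(edge = edge, edge.length = elen, Nnode = nt - 1L,
             tip.label = character(nt))
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  attr(tr, "wlen") <- wlen
  tr
}

#' Simulate gene trees under the multispecies coalescent with pulses
#'
#' For each locus one lineage per species is traced backward in time; within
#' each species branch lineage pairs coalesce at rate 1 per coalescent unit,
#' at each pulse every recipient lineage jumps to the donor branch with
#' probability `gamma`, and remaining lineages coalesce above the root. Each
#' locus uses its own RNG seed derived from the scenario seed, so locus `i`
#' is invariant to the total locus count.
#'
#' @param sc An `msc_scenario`.
#' @return A `gene_tree_set`: list of `phylo` trees (branch lengths in
#'   coalescent units when `pop_scale` is uniform, else time units), with
#'   unit tag and provenance. Each tree carries an attribute `wlen` holding
#'   rate-multiplier-weighted branch lengths in time units, consumed by
#'   [scale_branch_lengths()].
#' @export
simulate_gene_trees <- function(sc) {
  validate_scenario(sc)
  st <- sc$species_tree
  si <- species_tree_internals(st)
  maps <- branch_parameter_maps(sc, si)
  internal_nodes <- (si$ntips + 1L):(si$ntips + st$Nnode)
  ev <- data.frame(time = si$node_time[internal_nodes], type = "merge",
                   node = internal_nodes, donor = NA_integer_,
                   recipient = NA_integer_, gamma = NA_real_)
  for (p in sc$pulses) {
    ev <- rbind(ev, data.frame(
      time = p$time, type = "pulse", node = NA_integer_,
      donor = branch_for_clade(st, si, p$donor),
      recipient = branch_for_clade(st, si, p$recipient), gamma = p$gamma))
  }
  ev <- ev[order(ev$time), , drop = FALSE]
  uniform_scale <- is.null(sc$branch_scales)
  scale0 <- if (is.numeric(sc$pop_scale)) sc$pop_scale[1L] else 1
  set.seed(sc$seed)
  locus_seeds <- sample.int(.Machine$integer.max - 1L, sc$loci)
  trees <- vector("list", sc$loci)
  for (i in seq_len(sc$loci)) {
    set.seed(locus_seeds[i])
    tr <- sim_one_locus(si, maps, ev)
    tr$tip.label <- st$tip.label
    if (uniform_scale) tr$edge.length <- tr$edge.length / scale0
    trees[[i]] <- tr
  }
  structure(list(trees = trees,
                 units = if (uniform_scale) "coalescent" else "time",
                 taxa = sort(st$tip.label), scenario = sc, seed = sc$seed,
                 locus_seeds = locus_seeds),
            class = "gene_tree_set")
}

#' @export
print.gene_tree_set <- function(x, ...) {
  cat("Gene tree set:", length(x$trees), "trees over",
      length(x$taxa), "taxa; units:", x$units, "\n")
  invisible(x)
}

#' @export
length.gene_tree_set <- function(x) length(x$trees)

#' Convert coalescent/time branch lengths to substitutions per site
#'
#' Each branch segment is scaled by the global rate `mu` and by the rate
#' multiplier of the species-tree branch that hosted the lineage during that
#' segment (pulse-transferred segments take the donor clade's rate). The
#' traversal record is kept by the simulator, so this works even when a gene
#' lineage crosses several species branches with different rates.
#'
#' @param gts A `gene_tree_set` produced by [simulate_gene_trees()].
#' @param sc The scenario (supplies `mu`); defaults to the one stored in
#'   `gts`.
#' @return A `gene_tree_set` with branch lengths in substitutions/site.
#' @export
scale_branch_lengths <- function(gts, sc = gts$scenario) {
  stopifnot(inherits(gts, "gene_tree_set"))
  out <- gts
  out$trees <- lapply(gts$trees, function(tr) {
    w <- attr(tr, "wlen")
    if (is.null(w)) stop("gene tree lacks the simulator's traversal record (wlen)")
    tr$edge.length <- sc$mu * w
    tr
  })
  out$units <- "subs"
  out
}

# --- sequence simulation -----------------------------------------------------

DNA_STATES <- c("A", "C", "G", "T")

# transition probability matrix, branch length t in expected subs/site
pmat <- function(t, model = "JC69", kappa = 2, freqs = rep(0.25, 4)) {
  if (model == "JC69") {
    same <- 0.25 + 0.75 * exp(-4 * t / 3)
    diff <- 0.25 - 0.25 * exp(-4 * t / 3)
    P <- matrix(diff, 4L, 4L)
    diag(P) <- same
    dimnames(P) <- list(DNA_STATES, DNA_STATES)
    return(P)
  }
  # HKY: build rate matrix, normalize to 1 expected sub per unit, exponentiate
  Q <- matrix(1, 4L, 4L)
  transitions <- rbind(c(1L, 3L), c(3L, 1L), c(2L, 4L), c(4L, 2L))  # A<->G, C<->T
  for (i in seq_len(nrow(transitions))) Q[transitions[i, 1L], transitions[i, 2L]] <- kappa
  Q <- sweep(Q, 2L, freqs, "*")
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(freqs * diag(Q))
  Q <- Q / rate
  # symmetrize for a stable eigendecomposition: S = D^1/2 Q D^-1/2
  d <- sqrt(freqs)
  S <- diag(d) %*% Q %*% diag(1 / d)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  P <- diag(1 / d) %*% es$vectors %*% diag(exp(t * es$values)) %*% t(es$vectors) %*% diag(d)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(DNA_STATES, DNA_STATES)
  P
}

#' Simulate a multiple-sequence alignment on a tree
#'
#' Sites evolve i.i.d. down the tree under JC69 or HKY; branch lengths are
#' interpreted as expected substitutions per site.
#'
#' @param tree Rooted `phylo` with branch lengths in substitutions/site.
#' @param length Number of sites (> 0).
#' @param model `"JC69"` or `"HKY"`.
#' @param seed Integer seed; the alignment is deterministic given it.
#' @param kappa,freqs HKY parameters (transition/transversion ratio and base
#'   frequencies).
#' @return Character matrix (taxa x sites) with rownames = tip labels.
#' @export
simulate_alignment <- function(tree, length, model = c("JC69", "HKY"),
                               seed = 1L, kappa = 2, freqs = rep(0.25, 4)) {
  model <- match.arg(model)
  length <- as.integer(length)
  if (length <= 0L) stop("alignment length must be positive")
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  set.seed(seed)
  nt <- length(tree$tip.label)
  states <- matrix(0L, nt + tree$Nnode, length)
  root <- nt + 1L
  states[root, ] <- sample.int(4L, length, replace = TRUE, prob = freqs)
  pr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pr$edge))) {
    p <- pr$edge[e, 1L]; ch <- pr$edge[e, 2L]
    P <- pmat(pr$edge.length[e], model, kappa, freqs)
    ps <- states[p, ]
    cs <- integer(length)
    for (s in 1:4) {
      idx <- which(ps == s)
      if (length(idx))
        cs[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
    }
    states[ch, ] <- cs
  }
  aln <- matrix(DNA_STATES[states[seq_len(nt), , drop = FALSE]], nt, length)
  rownames(aln) <- tree$tip.label
  aln
}

#' Extract polarized biallelic site patterns from an alignment
#'
#' Keeps strictly biallelic columns with no gaps or ambiguity codes and
#' recodes them 0/1 with the outgroup allele as 0 (ancestral).
#'
#' @param alignment Character matrix (taxa x sites), rownames = taxa.
#' @param outgroup Row name used for polarization.
#' @return Integer 0/1 matrix (taxa x retained sites) with attribute
#'   `site_index` giving the original column of each retained site.
#' @export
extract_site_patterns <- function(alignment, outgroup) {
  if (!outgroup %in% rownames(alignment))
    stop("outgroup '", outgroup, "' not among alignment rows")
  valid <- matrix(alignment %in% DNA_STATES, nrow(alignment))
  ok <- colSums(valid) == nrow(alignment)
  n_alleles <- apply(alignment, 2L, function(col) length(unique(col)))
  keep <- which(ok & n_alleles == 2L)
  if (!length(keep)) {
    warning("no biallelic sites found")
    m <- matrix(integer(0L), nrow(alignment), 0L,
                dimnames = list(rownames(alignment), NULL))
    attr(m, "site_index") <- integer(0L)
    return(m)
  }
  anc <- alignment[outgroup, keep]
  m <- matrix(0L, nrow(alignment), length(keep),
              dimnames = list(rownames(alignment), NULL))
  for (j in seq_along(keep)) m[, j] <- as.integer(alignment[, keep[j]] != anc[j])
  attr(m, "site_index") <- keep
  m
}

#' Closed-form triplet topology frequencies under the MSC
#'
#' For a triplet whose two deeper species coalesce across an internal branch
#' of `T` coalescent units (no introgression), the concordant topology has
#' probability `1 - (2/3) exp(-T)` and each discordant topology
#' `(1/3) exp(-T)`.
#'
#' @param T Internal branch length in coalescent units (>= 0).
#' @return Numeric vector `c(concordant, discordant1, discordant2)`.
#' @export
expected_topology_freq <- function(T) {
  if (T < 0) stop("T must be >= 0")
  d <- exp(-T) / 3
  c(concordant = 1 - 2 * d, discordant1 = d, discordant2 = d)
}

# --- bundled scenarios -------------------------------------------------------

#' Default tribe-level scenario (5 ingroup taxa + outgroup, 2608 loci)
#'
#' Emulates a five-tribe radiation compressed into ~8 Ma roughly 60 Ma ago:
#' short internal branches (~0.3 coalescent units) generating heavy ILS, one
#' ancient introgression pulse into the `Ole` lineage from `For` with
#' inheritance probability 0.73, and a fast-evolving `Jas` clade (rate
#' multiplier 5.58123 relative to background 1).
#'
#' @param loci Number of loci (default 2608).
#' @param seed Integer seed.
#' @param gamma Inheritance probability of the For -> Ole pulse.
#' @param jas_rate Rate multiplier of the Jas clade.
#' @return An `msc_scenario`.
#' @export
tribe_scenario <- function(loci = 2608L, seed = 1L, gamma = 0.73,
                           jas_rate = 5.58123) {
  nwk <- paste0("(((((Jas:52.47,Ole:52.47):3.03,For:55.5):2.5,",
                "Fon:58):2.51,Myx:60.51):2.08,Out:62.59);")
  pulses <- if (gamma > 0)
    list(list(donor = "For", recipient = "Ole", time = 45, gamma = gamma))
  rates <- if (jas_rate != 1) list(list(tips = "Jas", r = jas_rate))
  scenario(nwk, loci = loci, mu = 1e-3, pop_scale = 8,
           pulses = pulses, rates = rates, locus_length = 500L,
           outgroup = "Out", seed = seed)
}

#' Default subtribe-level scenario (4 ingroup taxa + outgroup, 1865 loci)
#'
#' Emulates a four-subtribe divergence spread over 46.7 to 39.4 Ma with
#' moderate ILS (internal branches ~0.6 coalescent units), a weak pulse from
#' `Lig` into the ancestor of `Fra`+`Olei`, and a fast `Lig` clade (rate
#' multiplier 2.29322).
#'
#' @param loci Number of loci (default 1865).
#' @param seed Integer seed.
#' @param gamma Inheritance probability of the pulse (0 disables it).
#' @param lig_rate Rate multiplier of the Lig clade.
#' @return An `msc_scenario`.
#' @export
subtribe_scenario <- function(loci = 1865L, seed = 1L, gamma = 0.1,
                              lig_rate = 2.29322) {
  nwk <- paste0("((Sch:46.66,(Lig:43,(Fra:39.43,Olei:39.43):3.57):3.66)",
                ":5.81,Out:52.47);")
  pulses <- if (gamma > 0)
    list(list(donor = "Lig", recipient = c("Fra", "Olei"), time = 41, gamma = gamma))
  rates <- if (lig_rate != 1) list(list(tips = "Lig", r = lig_rate))
  scenario(nwk, loci = loci, mu = 1e-3, pop_scale = 6,
           pulses = pulses, rates = rates, locus_length = 500L,
           outgroup = "Out", seed = seed)
}
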