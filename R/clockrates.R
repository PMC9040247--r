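# Clock-constrained likelihoods with clade-local rate multipliers, AICc and
# likelihood-ratio model comparison with Bonferroni correction, p-distances
# and clade rate summaries.

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2 K (n / (n - K - 1))`.
#'
#' @param logL Log-likelihood.
#' @param K Number of free parameters.
#' @param n Number of sites.
#' @return The AICc value.
#' @export
aicc <- function(logL, K, n) {
  if (n <= K + 1) stop("AICc undefined: need n > K + 1")
  -2 * logL + 2 * K * (n / (n - K - 1))
}

#' Likelihood-ratio test between nested clock models
#'
#' `Lambda = 2 (logL_alt - logL_null)`, compared to a chi-square with `df`
#' degrees of freedom.
#'
#' @param logL_null,logL_alt Log-likelihoods of the nested and the richer
#'   model (`logL_alt >= logL_null` up to tolerance).
#' @param df Difference in free parameters.
#' @return List: `Lambda`, `df`, `p`.
#' @export
lrt <- function(logL_null, logL_alt, df) {
  Lambda <- 2 * (logL_alt - logL_null)
  if (Lambda < -1e-6)
    stop("negative likelihood-ratio statistic: models are misordered")
  Lambda <- max(Lambda, 0)
  list(Lambda = Lambda, df = df,
       p = stats::pchisq(Lambda, df = df, lower.tail = FALSE))
}

#' Free-parameter count of a local-clock model
#'
#' Counting convention: `(tips - 1)` node-time parameters, the substitution
#' model's free parameters, one global rate, and one parameter per local
#' clock.
#'
#' @param ntips Number of tips.
#' @param n_subst_params Substitution-model free parameters (0 for JC69; 8
#'   for a GTR-like model with free base frequencies).
#' @param n_clocks Number of clade-local clocks.
#' @return Integer parameter count `K`.
#' @export
clock_param_count <- function(ntips, n_subst_params = 0L, n_clocks = 0L) {
  (ntips - 1L) + n_subst_params + 1L + n_clocks
}

#' Construct a clock model
#'
#' A rooted ultrametric topology with node times, a global rate `mu`, and
#' optional clade rate multipliers; the expected length of a branch is
#' `mu * r * duration`.
#'
#' @param tree Rooted ultrametric `phylo` (lengths in time units).
#' @param mu Global substitution rate (subs/site/time unit).
#' @param rates Optional list of `list(tips=, r=)` clade multipliers
#'   (applied to all branches inside the clade including its stem).
#' @param model `"JC69"` or `"HKY"`.
#' @param kappa,freqs HKY parameters.
#' @return Object of class `clock_model`.
#' @export
clock_model <- function(tree, mu, rates = NULL, model = c("JC69", "HKY"),
                        kappa = 2, freqs = rep(0.25, 4)) {
  model <- match.arg(model)
  structure(list(tree = tree, mu = mu, rates = rates, model = model,
                 kappa = kappa, freqs = freqs), class = "clock_model")
}

# per-edge rate multipliers for a tree and clade rate list
edge_rate_multipliers <- function(tree, rates) {
  r <- rep(1, nrow(tree$edge))
  if (is.null(rates)) return(r)
  desc <- descendant_tip_sets(tree)
  for (spec in rates) {
    tips <- as.character(spec$tips)
    if (length(tips) == 1L) {
      node <- match(tips, tree$tip.label)
      if (is.na(node)) stop("unknown tip in clade spec: ", tips)
    } else {
      node <- which(vapply(desc, function(d) setequal(d, tips), logical(1L)))[1L]
      if (is.na(node))
        stop("clade {", paste(sort(tips), collapse = ","),
             "} is not monophyletic in the topology")
    }
    inside <- which(vapply(tree$edge[, 2L], function(v)
      all(desc[[v]] %in% desc[[node]]), logical(1L)))
    r[inside] <- spec$r
  }
  r
}

# compress an alignment into unique site patterns
site_patterns_compressed <- function(alignment) {
  keys <- apply(alignment, 2L, paste, collapse = "")
  tab <- table(keys)
  first <- match(names(tab), keys)
  list(patterns = alignment[, first, drop = FALSE], weights = as.numeric(tab))
}

# Felsenstein pruning on a pattern-compressed alignment; edge lengths in
# expected substitutions/site
pruning_loglik <- function(patterns, weights, tree, edge_lens,
                           model = "JC69", kappa = 2, freqs = rep(0.25, 4)) {
  nt <- length(tree$tip.label)
  np <- ncol(patterns)
  po <- ape::reorder.phylo(tree, "postorder")
  # conditional likelihoods, list over nodes: 4 x np
  L <- vector("list", nt + tree$Nnode)
  logscale <- numeric(np)
  for (i in seq_len(nt)) {
    m <- matrix(0, 4L, np)
    st <- match(patterns[tree$tip.label[i], ], DNA_STATES)
    known <- !is.na(st)
    m[cbind(st[known], which(known))] <- 1
    m[, !known] <- 1            # gaps/ambiguity: uninformative
    L[[i]] <- m
  }
  # carry lengths alongside the postorder edges
  idx <- match(paste(po$edge[, 1L], po$edge[, 2L]),
               paste(tree$edge[, 1L], tree$edge[, 2L]))
  po_len <- edge_lens[idx]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    P <- pmat(po_len[e], model, kappa, freqs)
    contrib <- P %*% L[[ch]]
    L[[p]] <- if (is.null(L[[p]])) contrib else L[[p]] * contrib
    if (min(L[[p]]) < 1e-150) {  # rescale to avoid underflow
      mx <- pmax(.colSums(L[[p]], 4L, np), 1e-300)
      L[[p]] <- sweep(L[[p]], 2L, mx, "/")
      logscale <- logscale + log(mx)
    }
  }
  root <- nt + 1L
  site_l <- colSums(freqs * L[[root]])
  sum(weights * (log(site_l) + logscale))
}

#' Log-likelihood of an alignment under a clock model
#'
#' Felsenstein pruning over sites, with branch lengths
#' `mu * r_clade * duration` taken from the clock model.
#'
#' @param alignment Character matrix (taxa x sites).
#' @param model A [clock_model()].
#' @return Log-likelihood.
#' @export
clock_loglik <- function(alignment, model) {
  tree <- model$tree
  if (!setequal(rownames(alignment), tree$tip.label))
    stop("alignment taxa do not match the tree tips")
  if (is.null(tree$edge.length)) stop("clock model tree needs node times")
  r <- edge_rate_multipliers(tree, model$rates)
  elen <- model$mu * r * tree$edge.length
  sp <- site_patterns_compressed(alignment)
  pruning_loglik(sp$patterns, sp$weights, tree, elen,
                 model$model, model$kappa, model$freqs)
}

# depths -> durations: build edge lengths (time units) from node depths
edge_durations <- function(tree, depths) {
  depths[seq_along(tree$tip.label)] <- 0
  tree$edge.length <- depths[tree$edge[, 1L]] - depths[tree$edge[, 2L]]
  tree
}

# one local-clock fit: optimize node depths (root fixed at 1), log mu and
# log clade rates; returns logL and fitted parameters
fit_one_clock_model <- function(sp, topology, clades, model = "JC69",
                                kappa = 2, freqs = rep(0.25, 4),
                                n_starts = 3L, seed = 1L) {
  nt <- length(topology$tip.label)
  root <- nt + 1L
  internal <- setdiff((nt + 1L):(nt + topology$Nnode), root)
  parent <- integer(nt + topology$Nnode)
  for (e in seq_len(nrow(topology$edge)))
    parent[topology$edge[e, 2L]] <- topology$edge[e, 1L]
  # preorder over internal nodes so parents come first
  pr <- ape::reorder.phylo(topology, "cladewise")
  internal_pre <- unique(pr$edge[, 1L])
  internal_pre <- internal_pre[internal_pre != root]
  nc <- length(clades)
  build <- function(par) {
    fracs <- stats::plogis(par[seq_along(internal_pre)])
    mu <- exp(par[length(internal_pre) + 1L])
    rs <- if (nc) exp(par[length(internal_pre) + 1L + seq_len(nc)]) else numeric(0L)
    depths <- numeric(nt + topology$Nnode)
    depths[root] <- 1
    for (i in seq_along(internal_pre)) {
      v <- internal_pre[i]
      depths[v] <- fracs[i] * depths[parent[v]]
    }
    tr <- edge_durations(topology, depths)
    rates <- if (nc) lapply(seq_len(nc), function(j)
      list(tips = clades[[j]], r = rs[j]))
    r <- edge_rate_multipliers(tr, rates)
    list(elen = mu * r * tr$edge.length, mu = mu, rs = rs,
         depths = depths, tree = tr)
  }
  nll <- function(par) {
    b <- build(par)
    ll <- tryCatch(pruning_loglik(sp$patterns, sp$weights, topology, b$elen,
                                  model, kappa, freqs),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  npar <- length(internal_pre) + 1L + nc
  set.seed(seed)
  # data-driven rate start: mean pairwise mismatch / 2 (root depth is 1)
  pd0 <- {
    labs <- rownames(sp$patterns)
    prs <- utils::combn(labs, 2L)
    d <- mean(vapply(seq_len(ncol(prs)), function(i)
      sum(sp$weights * (sp$patterns[prs[1L, i], ] != sp$patterns[prs[2L, i], ])) /
        sum(sp$weights), numeric(1L)))
    max(d / 2, 1e-4)
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- if (s == 1L) {
      c(rep(stats::qlogis(0.6), length(internal_pre)), log(pd0), rep(0, nc))
    } else {
      c(stats::qlogis(stats::runif(length(internal_pre), 0.3, 0.9)),
        log(pd0) + stats::rnorm(1L, 0, 0.7),
        if (nc) stats::rnorm(nc, 0, 0.7) else numeric(0L))
    }
    op <- tryCatch(
      stats::optim(init, nll, method = "L-BFGS-B",
                   lower = rep(-12, npar), upper = rep(12, npar),
                   control = list(maxit = 300L, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best)) stop("all optimizer starts failed")
  b <- build(best$par)
  list(logL = -best$value, mu = b$mu,
       rates = if (nc) stats::setNames(b$rs, vapply(clades, function(cl)
         paste(sort(cl), collapse = ","), character(1L))) else numeric(0L),
       depths = b$depths)
}

#' Fit a ladder of local-clock models and compare them
#'
#' Fits M0 (a single global clock) and then one model per clade
#' specification, each adding exactly one clade-local rate multiplier to the
#' previous model. Node times (root depth fixed at 1), the global rate and
#' the multipliers are optimized numerically by seeded multi-start
#' quasi-Newton. The ladder reports `logL`, `K` (see
#' [clock_param_count()]), AICc, the likelihood-ratio statistic against the
#' previous model, and the Bonferroni-corrected significance threshold
#' `alpha / m`, with `m` the number of branch (local-clock) parameters of
#' the alternative model.
#'
#' @param alignment Character matrix (taxa x sites).
#' @param topology Rooted binary `phylo` (branch lengths ignored).
#' @param clade_specs List of tip-label vectors, one per local clock, added
#'   cumulatively in order; each must be monophyletic in `topology`.
#' @param model `"JC69"` or `"HKY"`.
#' @param kappa,freqs HKY parameters.
#' @param n_starts Optimizer restarts per model.
#' @param alpha Nominal significance level (default 0.05).
#' @param seed Integer seed.
#' @return Object of class `clock_ladder`: data.frame (model, K,
#'   branch_params, logL, AICc, Lambda, df, P, alpha_bonf, significant,
#'   rates) with attribute `best` (model name minimizing AICc) and `fits`.
#' @export
fit_local_clocks <- function(alignment, topology, clade_specs,
                             model = c("JC69", "HKY"), kappa = 2,
                             freqs = rep(0.25, 4), n_starts = 3L,
                             alpha = 0.05, seed = 1L) {
  model <- match.arg(model)
  if (!setequal(rownames(alignment), topology$tip.label))
    stop("alignment taxa do not match the topology tips")
  desc <- descendant_tip_sets(topology)
  for (cl in clade_specs) {
    if (length(cl) > 1L &&
        !any(vapply(desc, function(d) setequal(d, cl), logical(1L))))
      stop("clade {", paste(sort(cl), collapse = ","),
           "} is not monophyletic in the topology")
  }
  sp <- site_patterns_compressed(alignment)
  n <- ncol(alignment)
  nt <- length(topology$tip.label)
  n_subst <- if (model == "JC69") 0L else 4L   # kappa + 3 free frequencies
  fits <- list()
  rows <- list()
  for (j in 0:length(clade_specs)) {
    clades <- if (j == 0L) list() else clade_specs[seq_len(j)]
    fit <- fit_one_clock_model(sp, topology, clades, model, kappa, freqs,
                               n_starts = n_starts, seed = seed + j)
    # a richer model must never fit worse; reuse the previous optimum if the
    # optimizer stalled
    if (j > 0L && fit$logL < fits[[j]]$logL) fit$logL <- fits[[j]]$logL
    fits[[j + 1L]] <- fit
    K <- clock_param_count(nt, n_subst, j)
    lam <- df <- p <- NA_real_
    if (j > 0L) {
      tst <- lrt(fits[[j]]$logL, fit$logL, 1L)
      lam <- tst$Lambda; df <- tst$df; p <- tst$p
    }
    rows[[j + 1L]] <- data.frame(
      model = paste0("M", j), K = K, branch_params = j,
      logL = fit$logL, AICc = aicc(fit$logL, K, n),
      Lambda = lam, df = df, P = p,
      alpha_bonf = if (j > 0L) alpha / j else NA_real_,
      significant = if (j > 0L) p < alpha / j else NA,
      rates = if (length(fit$rates))
        paste(sprintf("%s=%.4g", names(fit$rates), fit$rates), collapse = "; ")
      else "", stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(tab, class = c("clock_ladder", "data.frame"),
            best = tab$model[which.min(tab$AICc)], fits = fits, n = n)
}

#' @export
print.clock_ladder <- function(x, ...) {
  print.data.frame(x)
  cat("best model by AICc:", attr(x, "best"), "\n")
  invisible(x)
}

#' Pairwise p-distance with pairwise gap deletion
#'
#' @param seq1,seq2 Equal-length character vectors of aligned bases.
#' @return Proportion of differing sites among sites where both sequences
#'   carry an unambiguous base; `NA` (with a warning) when no site is
#'   comparable.
#' @export
p_distance <- function(seq1, seq2) {
  if (length(seq1) != length(seq2)) stop("sequences differ in length")
  s1 <- toupper(seq1); s2 <- toupper(seq2)
  ok <- s1 %in% DNA_STATES & s2 %in% DNA_STATES
  if (!any(ok)) {
    warning("no comparable sites; p-distance undefined")
    return(NA_real_)
  }
  mean(s1[ok] != s2[ok])
}

#' Clade-wise root-to-tip summaries and location tests
#'
#' Splits the tips into the given clades plus a background group, reports
#' per-group mean/median root-to-tip path length, and tests location
#' differences with a Welch two-sample t-test (two groups) and a one-way
#' Welch ANOVA (two or more groups). Groups with fewer than 2 tips are
#' described but excluded from tests.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param clade_map Named list of tip-label vectors.
#' @return List: `summary` data.frame (group, n, mean, median, sd),
#'   `t_test` (when exactly two testable groups), `anova` (k-group test),
#'   both `NULL` when not applicable.
#' @export
clade_rate_summary <- function(tree, clade_map) {
  rtt <- root_to_tip_lengths(tree)
  assigned <- unlist(clade_map, use.names = FALSE)
  miss <- setdiff(assigned, names(rtt))
  if (length(miss)) stop("unknown tips in clade map: ", paste(miss, collapse = ", "))
  groups <- clade_map
  bg <- setdiff(names(rtt), assigned)
  if (length(bg)) groups$background <- bg
  vals <- lapply(groups, function(tips) rtt[tips])
  summ <- data.frame(
    group = names(groups),
    n = lengths(vals),
    mean = vapply(vals, mean, numeric(1L)),
    median = vapply(vals, stats::median, numeric(1L)),
    sd = vapply(vals, stats::sd, numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  testable <- vals[lengths(vals) >= 2L]
  t_test <- NULL; anova <- NULL
  if (length(testable) >= 2L) {
    x <- unlist(testable, use.names = FALSE)
    g <- factor(rep(names(testable), lengths(testable)))
    if (stats::var(x) > 0) {
      anova <- tryCatch(stats::oneway.test(x ~ g), error = function(e) NULL)
      if (length(testable) == 2L)
        t_test <- tryCatch(stats::t.test(testable[[1L]], testable[[2L]]),
                           error = function(e) NULL)
    }
  }
  list(summary = summ, t_test = t_test, anova = anova)
}
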