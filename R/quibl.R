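# Discrimination of ILS-only vs ILS+introgression from triplet internal
# branch length distributions: exponential vs exponential + shifted
# exponential mixture, fitted by EM and compared by BIC.

#' Triplet internal branch lengths by topology class
#'
#' Each gene tree is pruned to the triplet plus outgroup and rooted on the
#' outgroup; the sister pair determines the topology class and the length of
#' the single internal branch (above the sister-pair cherry) is recorded in
#' that class's list. Zero-length and unresolved cases are skipped and
#' counted.
#'
#' @param trees `gene_tree_set` or list of `phylo` with branch lengths.
#' @param triplet Character vector of three ingroup taxa.
#' @param outgroup Outgroup label.
#' @return Named list (one per topology class, named by the sorted sister
#'   pair `"X,Y"`) of numeric length vectors, with attributes `skipped`
#'   (unresolved) and `zero_length` counts.
#' @export
triplet_branch_lengths <- function(trees, triplet, outgroup) {
  tl <- if (inherits(trees, "gene_tree_set")) trees$trees else trees
  stopifnot(length(triplet) == 3L)
  triplet <- sort(triplet)
  classes <- utils::combn(triplet, 2L, paste, collapse = ",")
  out <- stats::setNames(vector("list", 3L), sort(classes))
  for (k in names(out)) out[[k]] <- numeric(0L)
  skipped <- 0L; zeros <- 0L
  for (tr in tl) {
    pr <- ape::keep.tip(tr, c(triplet, outgroup))
    if (length(pr$tip.label) > 3L) pr <- ape::unroot(pr)
    pr <- ape::root(pr, outgroup = outgroup, resolve.root = TRUE)
    desc <- descendant_tip_sets(pr)
    nt <- length(pr$tip.label)
    cherry <- NULL
    for (v in (nt + 1L):(nt + pr$Nnode)) {
      d <- desc[[v]]
      if (length(d) == 2L && !outgroup %in% d) { cherry <- v; break }
    }
    if (is.null(cherry)) { skipped <- skipped + 1L; next }
    e <- which(pr$edge[, 2L] == cherry)
    len <- pr$edge.length[e]
    key <- paste(sort(desc[[cherry]]), collapse = ",")
    if (len <= 0) { zeros <- zeros + 1L; next }
    out[[key]] <- c(out[[key]], len)
  }
  attr(out, "skipped") <- skipped
  attr(out, "zero_length") <- zeros
  attr(out, "triplet") <- triplet
  out
}

# mixture log-likelihood: pi * Exp(lambda) + (1-pi) * (C + Exp(lambda))
quibl_mix_loglik <- function(t, pi, lambda, C) {
  f1 <- lambda * exp(-lambda * t)
  f2 <- ifelse(t >= C, lambda * exp(-lambda * (t - C)), 0)
  sum(log(pi * f1 + (1 - pi) * f2))
}

# EM for (pi, lambda) at fixed shift C; returns fit with logL trace
quibl_em_fixed_C <- function(t, C, pi0 = 0.5, max_iter = 500L, tol = 1e-8) {
  n <- length(t)
  pi <- pi0
  lambda <- 1 / mean(t)
  ll_old <- -Inf
  trace <- numeric(0L)
  for (it in seq_len(max_iter)) {
    f1 <- lambda * exp(-lambda * t)
    f2 <- ifelse(t >= C, lambda * exp(-lambda * (t - C)), 0)
    denom <- pi * f1 + (1 - pi) * f2
    if (any(denom <= 0)) break
    g2 <- (1 - pi) * f2 / denom
    g1 <- 1 - g2
    pi <- mean(g1)
    pi <- min(max(pi, 1e-9), 1)
    s <- sum(g1 * t + g2 * pmax(t - C, 0))
    if (s <= 0) break
    lambda <- n / s
    ll <- quibl_mix_loglik(t, pi, lambda, C)
    trace <- c(trace, ll)
    if (ll < ll_old - 1e-6)
      stop("EM log-likelihood decreased (", ll_old, " -> ", ll, ")")
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(pi = pi, lambda = lambda, C = C,
       logL = quibl_mix_loglik(t, pi, lambda, C), trace = trace)
}

#' Fit the ILS-only and ILS+introgression branch-length models
#'
#' Model 1 (ILS only) is a single exponential with rate `lambda`
#' (1 free parameter). Model 2 is a two-component mixture sharing `lambda`:
#' with probability `pi` a plain exponential (discordance from deep
#' coalescence alone) and with probability `1 - pi` an exponential shifted
#' by a delay `C >= 0` (an additional divergence or introgression event),
#' i.e. `f(t) = pi la e^(-la t) + (1 - pi) la e^(-la (t - C)) [t >= C]`
#' (3 free parameters). Model 2 is fitted by expectation-maximization over
#' `(pi, lambda)` at candidate shifts `C` placed on data quantiles, followed
#' by local refinement of `C`; `C = 0` is always among the candidates, which
#' guarantees `logL2 >= logL1` (the models are nested). Models are compared
#' by `BIC = -2 logL + k log(N)`; `dBIC = BIC2 - BIC1 < -10` is the
#' conventional stringent evidence for the mixture.
#'
#' @param lengths Positive numeric vector of internal branch lengths.
#' @param seed Integer seed (the fit itself is deterministic; kept for API
#'   stability).
#' @return List of class `quibl_fit`: `n`, `lambda1`, `logL1`, `BIC1`,
#'   `pi`, `lambda2`, `C`, `logL2`, `BIC2`, `dBIC`, `mixture_preferred`
#'   (dBIC < -10), `low_power` (n < 30).
#' @export
fit_quibl_models <- function(lengths, seed = 1L) {
  t <- as.numeric(lengths)
  if (any(t <= 0)) stop("lengths must be positive (filter zeros upstream)")
  n <- length(t)
  if (n < 2L) stop("need at least 2 lengths")
  if (max(t) - min(t) < .Machine$double.eps * max(t))
    stop("degenerate data: all lengths are (numerically) equal; fit refused")
  lambda1 <- 1 / mean(t)
  logL1 <- n * log(lambda1) - lambda1 * sum(t)
  cand_C <- sort(unique(c(0, min(t) / 2, min(t) * 0.99,
                          stats::quantile(t, seq(0.05, 0.95, by = 0.05),
                                          names = FALSE))))
  # two-phase search: short EM across all (C, pi0) starts, full EM on the
  # leaders
  starts <- expand.grid(C = cand_C, pi0 = c(0.05, 0.1, 0.3, 0.5, 0.7, 0.9, 0.95))
  short <- lapply(seq_len(nrow(starts)), function(i)
    quibl_em_fixed_C(t, starts$C[i], starts$pi0[i], max_iter = 60L, tol = 1e-6))
  ord <- order(-vapply(short, `[[`, numeric(1L), "logL"))
  fits <- lapply(ord[seq_len(min(5L, length(ord)))], function(i)
    quibl_em_fixed_C(t, short[[i]]$C, short[[i]]$pi))
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1L), "logL"))]]
  # local refinement of C, bracketed by the neighbouring candidates
  ci <- findInterval(best$C, cand_C)
  lo <- if (ci > 1L) cand_C[ci - 1L] else 0
  hi <- if (ci < length(cand_C)) cand_C[ci + 1L] else max(t)
  if (hi > lo) {
    op <- stats::optimize(function(C) quibl_em_fixed_C(t, C, best$pi)$logL,
                          interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
    ref <- quibl_em_fixed_C(t, op$maximum, best$pi)
    if (ref$logL > best$logL) best <- ref
  }
  # direct polish of (pi, lambda, C) from the EM optimum
  pol <- tryCatch(stats::optim(
    c(stats::qlogis(min(max(best$pi, 1e-6), 1 - 1e-6)), log(best$lambda),
      best$C),
    function(p) {
      C <- max(p[3L], 0)
      -quibl_mix_loglik(t, stats::plogis(p[1L]), exp(p[2L]), C)
    }, method = "Nelder-Mead", control = list(maxit = 300L)),
    error = function(e) NULL)
  if (!is.null(pol) && -pol$value > best$logL) {
    best <- list(pi = stats::plogis(pol$par[1L]), lambda = exp(pol$par[2L]),
                 C = max(pol$par[3L], 0), logL = -pol$value,
                 trace = best$trace)
  }
  logL2 <- max(best$logL, logL1)   # numerical guard for the nested family
  BIC1 <- -2 * logL1 + 1 * log(n)
  BIC2 <- -2 * logL2 + 3 * log(n)
  structure(list(n = n, lambda1 = lambda1, logL1 = logL1, BIC1 = BIC1,
                 pi = best$pi, lambda2 = best$lambda, C = best$C,
                 logL2 = logL2, BIC2 = BIC2, dBIC = BIC2 - BIC1,
                 mixture_preferred = (BIC2 - BIC1) < -10,
                 low_power = n < 30L, em_trace = best$trace),
            class = "quibl_fit")
}

#' @export
print.quibl_fit <- function(x, ...) {
  cat(sprintf(
    "QuIBL fit (n=%d): lambda1=%.3g logL1=%.2f | pi=%.3f lambda2=%.3g C=%.3g logL2=%.2f | dBIC=%.2f\n",
    x$n, x$lambda1, x$logL1, x$pi, x$lambda2, x$C, x$logL2, x$dBIC))
  invisible(x)
}

#' QuIBL scan over all triplets and topology classes
#'
#' One mixture fit per (triplet, topology class): `C(k,3) x 3` rows.
#' Introgression is called only on topology classes discordant with the
#' supplied species tree, at `dBIC < -10`.
#'
#' @param trees `gene_tree_set` or list of `phylo` (substitution-unit
#'   lengths).
#' @param ingroup Ingroup taxa (>= 3).
#' @param outgroup Outgroup label.
#' @param species_tree Rooted `phylo` defining concordant classes.
#' @param min_n Classes with fewer lengths than this are reported unfitted.
#' @return data.frame: triplet, topology (sister pair), discordant, N,
#'   lambda1, logL1, BIC1, pi, lambda2, C, logL2, BIC2, dBIC, call,
#'   low_power.
#' @export
quibl_scan <- function(trees, ingroup, outgroup, species_tree, min_n = 5L) {
  if (length(ingroup) < 3L) stop("need at least 3 ingroup taxa")
  triplets <- utils::combn(sort(ingroup), 3L, simplify = FALSE)
  rows <- list()
  for (tri in triplets) {
    tbl <- triplet_branch_lengths(trees, tri, outgroup)
    sp_ord <- order_triplet(tri, species_tree, outgroup)
    concordant_class <- paste(sort(sp_ord[1:2]), collapse = ",")
    total_n <- sum(lengths(tbl))
    for (cls in names(tbl)) {
      t <- tbl[[cls]]
      discordant <- cls != concordant_class
      base <- data.frame(triplet = paste(tri, collapse = ","),
                         topology = cls, discordant = discordant,
                         N = length(t), stringsAsFactors = FALSE)
      fit <- NULL
      if (length(t) >= min_n)
        fit <- tryCatch(fit_quibl_models(t), error = function(e) NULL)
      if (is.null(fit)) {
        row <- cbind(base, data.frame(
          lambda1 = NA_real_, logL1 = NA_real_, BIC1 = NA_real_,
          pi = NA_real_, lambda2 = NA_real_, C = NA_real_,
          logL2 = NA_real_, BIC2 = NA_real_, dBIC = NA_real_,
          call = FALSE, low_power = TRUE))
      } else {
        row <- cbind(base, data.frame(
          lambda1 = fit$lambda1, logL1 = fit$logL1, BIC1 = fit$BIC1,
          pi = fit$pi, lambda2 = fit$lambda2, C = fit$C,
          logL2 = fit$logL2, BIC2 = fit$BIC2, dBIC = fit$dBIC,
          call = discordant && fit$mixture_preferred,
          low_power = fit$low_power))
      }
      row$triplet_total <- total_n
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Pairwise introgressed-tree proportion matrix from a QuIBL scan
#'
#' For every discordant (triplet, topology) row, the proportion of that
#' triplet's gene trees attributed to the delayed mixture component is
#' `(1 - pi) * N_class / N_triplet`; rows without a significant call
#' contribute 0. Values are averaged per species pair over all rows whose
#' topology unites that pair.
#'
#' @param scan data.frame from [quibl_scan()].
#' @return Symmetric matrix of mean introgressed proportions.
#' @export
pairwise_introgression <- function(scan) {
  taxa <- sort(unique(unlist(strsplit(scan$triplet, ",", fixed = TRUE))))
  acc <- cnt <- matrix(0, length(taxa), length(taxa),
                       dimnames = list(taxa, taxa))
  disc <- scan[scan$discordant, , drop = FALSE]
  for (i in seq_len(nrow(disc))) {
    pair <- strsplit(disc$topology[i], ",", fixed = TRUE)[[1L]]
    val <- 0
    if (isTRUE(disc$call[i]) && !is.na(disc$pi[i]) && disc$triplet_total[i] > 0)
      val <- (1 - disc$pi[i]) * disc$N[i] / disc$triplet_total[i]
    acc[pair[1L], pair[2L]] <- acc[pair[1L], pair[2L]] + val
    cnt[pair[1L], pair[2L]] <- cnt[pair[1L], pair[2L]] + 1
  }
  out <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  for (a in seq_along(taxa)) for (b in seq_along(taxa)) {
    if (a >= b) next
    tot <- acc[a, b] + acc[b, a]
    n <- cnt[a, b] + cnt[b, a]
    out[a, b] <- out[b, a] <- if (n > 0) tot / n else 0
  }
  out
}
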