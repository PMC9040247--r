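# Orchestration: configuration, per-stage seeding, report assembly and a
# minimal command-line entry point.

#' Build a pipeline run configuration
#'
#' All analysis thresholds are explicit fields and are persisted beside the
#' outputs, so every run is self-describing. A single master seed fans out
#' to independent per-stage seeds, so toggling one stage never perturbs
#' another's randomness.
#'
#' @param scenario An `msc_scenario` supplying synthetic inputs (gene trees,
#'   alignments, site patterns).
#' @param out_dir Output directory for stage TSVs, the resolved
#'   configuration and the log.
#' @param seed Master seed.
#' @param z_cutoff D-statistic significance threshold on |Z| (default 3).
#' @param dbic_cutoff QuIBL mixture-acceptance threshold (default -10).
#' @param support_cutoff Gene-tree support cutoff for concordance mapping
#'   (default 80).
#' @param alpha Polytomy-test significance level (default 0.05).
#' @param scf_quartets Quartets sampled per branch for sCF.
#' @param stages Character vector of stages to run, a subset of
#'   `c("spectrum","concord","dstat","quibl","clock","treespace")`.
#' @param clock_clades Clade specs (list of tip vectors) for the clock
#'   ladder; defaults to the scenario's rate-multiplier clades.
#' @param treespace_trees Number of gene trees embedded by PCoA.
#' @return Object of class `run_config`.
#' @export
run_config <- function(scenario, out_dir, seed = 1L, z_cutoff = 3,
                       dbic_cutoff = -10, support_cutoff = 80, alpha = 0.05,
                       scf_quartets = 100L,
                       stages = c("spectrum", "concord", "dstat", "quibl",
                                  "clock", "treespace"),
                       clock_clades = NULL, treespace_trees = 100L) {
  if (is.null(clock_clades) && !is.null(scenario$rates))
    clock_clades <- lapply(scenario$rates, function(r) as.character(r$tips))
  structure(list(scenario = scenario, out_dir = out_dir,
                 seed = as.integer(seed), z_cutoff = z_cutoff,
                 dbic_cutoff = dbic_cutoff, support_cutoff = support_cutoff,
                 alpha = alpha, scf_quartets = as.integer(scf_quartets),
                 stages = stages, clock_clades = clock_clades,
                 treespace_trees = as.integer(treespace_trees)),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' The species tree travels as a Newick string; write -> read -> write is
#' the identity on the serialized form.
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `read_config` returns a `run_config`; `write_config` the path,
#'   invisibly.
#' @export
write_config <- function(config, path) {
  sc <- config$scenario
  lst <- list(
    scenario = list(
      species_tree = write_newick(sc$species_tree),
      loci = sc$loci, mu = sc$mu, pop_scale = sc$pop_scale,
      branch_scales = sc$branch_scales, pulses = sc$pulses, rates = sc$rates,
      locus_length = sc$locus_length, model = sc$model, kappa = sc$kappa,
      outgroup = sc$outgroup, seed = sc$seed),
    out_dir = config$out_dir, seed = config$seed,
    z_cutoff = config$z_cutoff, dbic_cutoff = config$dbic_cutoff,
    support_cutoff = config$support_cutoff, alpha = config$alpha,
    scf_quartets = config$scf_quartets, stages = config$stages,
    clock_clades = config$clock_clades,
    treespace_trees = config$treespace_trees)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  s <- lst$scenario
  fix_specs <- function(x) if (is.null(x)) NULL else
    lapply(x, function(e) lapply(e, unlist))
  sc <- scenario(s$species_tree, loci = s$loci, mu = s$mu,
                 pop_scale = s$pop_scale,
                 branch_scales = fix_specs(s$branch_scales),
                 pulses = fix_specs(s$pulses), rates = fix_specs(s$rates),
                 locus_length = s$locus_length, model = s$model,
                 kappa = s$kappa, outgroup = s$outgroup, seed = s$seed)
  run_config(sc, lst$out_dir, seed = lst$seed, z_cutoff = lst$z_cutoff,
             dbic_cutoff = lst$dbic_cutoff,
             support_cutoff = lst$support_cutoff, alpha = lst$alpha,
             scf_quartets = lst$scf_quartets, stages = unlist(lst$stages),
             clock_clades = if (is.null(lst$clock_clades)) NULL else
               lapply(lst$clock_clades, unlist),
             treespace_trees = lst$treespace_trees)
}

# deterministic per-stage seeds derived from the master seed
stage_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 8L)
  stats::setNames(s, c("sim", "alignments", "spectrum", "concord", "dstat",
                       "quibl", "clock", "treespace"))
}

#' Write a data.frame or matrix as a TSV report
#'
#' UTF-8, header row, `NA` for missing values, numbers rounded to
#' `digits` significant digits. Matrices gain a leading label column.
#'
#' @param x data.frame or matrix.
#' @param path Output file.
#' @param digits Significant digits (default 6).
#' @return The path, invisibly.
#' @export
write_report <- function(x, path, digits = 6L) {
  if (is.matrix(x)) {
    df <- data.frame(label = rownames(x), as.data.frame(x, optional = TRUE),
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], signif, digits = digits)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full discordance-dissection pipeline
#'
#' Simulates gene trees (and locus alignments where needed) from the
#' configured scenario, then runs the enabled stages: topology spectrum,
#' per-branch concordance (quartet scores, gCF/sCF, polytomy test,
#' PhyParts-style mapping with ICA), the D-statistic triplet scan with
#' block jackknife and pairwise mean |D| matrix, the QuIBL scan and
#' pairwise introgression matrix, the local-clock ladder, and the RF/PCoA
#' tree-space embedding. Every stage writes a TSV into `out_dir`; the
#' resolved configuration and a log accompany them. Identical configuration
#' and seed give byte-identical outputs.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- stage_seeds(config$seed)
  logf <- file.path(config$out_dir, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), ...,
                               "\n", file = logf, append = TRUE)
  cat("", file = logf)
  write_config(config, file.path(config$out_dir, "config.json"))
  logline("config written; master seed", config$seed)
  sc <- config$scenario
  sc$seed <- seeds[["sim"]]
  outgroup <- sc$outgroup
  if (is.null(outgroup)) stop("scenario must name an outgroup")
  species_tree <- sc$species_tree
  ingroup <- setdiff(species_tree$tip.label, outgroup)
  results <- list(config = config)
  gts <- simulate_gene_trees(sc)
  gts_subs <- scale_branch_lengths(gts)
  logline("simulated", length(gts), "gene trees")
  writeLines(vapply(gts_subs$trees, write_newick, character(1L)),
             file.path(config$out_dir, "gene_trees.nwk"))
  need_aln <- any(c("concord", "dstat") %in% config$stages)
  alns <- NULL
  if (need_aln) {
    set.seed(seeds[["alignments"]])
    aln_seeds <- sample.int(.Machine$integer.max - 1L, length(gts))
    alns <- lapply(seq_along(gts$trees), function(i)
      simulate_alignment(gts_subs$trees[[i]], sc$locus_length,
                         model = sc$model, seed = aln_seeds[i],
                         kappa = sc$kappa))
    logline("simulated", length(alns), "locus alignments of",
            sc$locus_length, "bp")
  }
  for (stage in config$stages) {
    res <- switch(stage,
      spectrum = {
        spec <- topology_spectrum(gts_subs, outgroup)
        write_report(spec, file.path(config$out_dir, "topology_spectrum.tsv"))
        spec
      },
      concord = {
        conc <- branch_concordance(species_tree, gts_subs,
                                   alignment = do.call(cbind, alns),
                                   support_cutoff = config$support_cutoff,
                                   n_quartets = config$scf_quartets,
                                   seed = seeds[["concord"]])
        write_report(conc, file.path(config$out_dir, "branch_concordance.tsv"))
        conc
      },
      dstat = {
        pats <- lapply(alns, extract_site_patterns, outgroup = outgroup)
        pats <- pats[vapply(pats, ncol, integer(1L)) > 0L]
        dtab <- triplet_scan(pats, ingroup, outgroup,
                             species_tree = species_tree)
        dmat <- pairwise_mean_abs_d(dtab, taxa = sort(ingroup))
        write_report(dtab, file.path(config$out_dir, "dstat_triplets.tsv"))
        write_report(dmat$display, file.path(config$out_dir, "dstat_pairs.tsv"))
        list(triplets = dtab, pairs = dmat)
      },
      quibl = {
        qtab <- quibl_scan(gts_subs, ingroup, outgroup, species_tree)
        qmat <- pairwise_introgression(qtab)
        write_report(qtab, file.path(config$out_dir, "quibl_scan.tsv"))
        write_report(qmat, file.path(config$out_dir, "quibl_pairs.tsv"))
        list(scan = qtab, pairs = qmat)
      },
      clock = {
        # one concatenated alignment simulated on the rate-scaled species tree
        st_subs <- species_tree
        si <- species_tree_internals(species_tree)
        maps <- branch_parameter_maps(sc, si)
        r_edge <- maps$rmult[species_tree$edge[, 2L]]
        st_subs$edge.length <- sc$mu * r_edge * species_tree$edge.length
        clock_aln <- simulate_alignment(st_subs, max(sc$locus_length * 20L, 5000L),
                                        model = sc$model,
                                        seed = seeds[["clock"]], kappa = sc$kappa)
        specs <- config$clock_clades
        if (is.null(specs) || !length(specs)) {
          ladder <- NULL
        } else {
          ladder <- fit_local_clocks(clock_aln, species_tree, specs,
                                     model = sc$model, alpha = config$alpha,
                                     seed = seeds[["clock"]])
          write_report(as.data.frame(ladder),
                       file.path(config$out_dir, "clock_ladder.tsv"))
        }
        ladder
      },
      treespace = {
        k <- min(config$treespace_trees, length(gts))
        D <- rf_matrix(gts_subs$trees[seq_len(k)], normalized = TRUE)
        emb <- pcoa(D, n_axes = 2L)
        write_report(D, file.path(config$out_dir, "rf_matrix.tsv"))
        coords <- cbind(as.data.frame(emb$coords),
                        var_explained_1 = emb$var_explained[1L],
                        var_explained_2 = emb$var_explained[2L])
        write_report(data.frame(tree = rownames(emb$coords), coords),
                     file.path(config$out_dir, "pcoa_coords.tsv"))
        emb
      },
      stop("unknown stage: ", stage))
    results[[stage]] <- res
    logline("stage", stage, "done")
  }
  logline("pipeline complete")
  invisible(results)
}

#' Minimal command-line entry point
#'
#' Subcommands: `run` (full pipeline from a JSON config), `simulate`
#' (gene trees only). Flags: `--config`, `--seed`, `--out`.
#'
#' @param args Character vector, default `commandArgs(TRUE)`.
#' @return Exit status, invisibly.
#' @export
pd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: phylodisc <run|simulate> --config FILE [--seed N] [--out DIR]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opt <- function(flag, default = NULL) {
    i <- match(flag, args)
    if (is.na(i) || i == length(args)) default else args[i + 1L]
  }
  cfg_path <- opt("--config")
  if (is.null(cfg_path)) { message(usage); return(invisible(1L)) }
  config <- read_config(cfg_path)
  seed <- opt("--seed"); if (!is.null(seed)) config$seed <- as.integer(seed)
  out <- opt("--out"); if (!is.null(out)) config$out_dir <- out
  if (cmd == "run") {
    run_pipeline(config)
  } else if (cmd == "simulate") {
    sc <- config$scenario
    gts <- scale_branch_lengths(simulate_gene_trees(sc))
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(vapply(gts$trees, write_newick, character(1L)),
               file.path(config$out_dir, "gene_trees.nwk"))
  } else {
    message(usage); return(invisible(1L))
  }
  invisible(0L)
}
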