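# Shared fixtures: small scenarios and tree generators, all built in code.

# random rooted binary tree over labels, by sequential random leaf grafting
random_rooted_tree <- function(labels, lengths = TRUE) {
  nwk <- labels[1L]
  for (lab in labels[-1L]) {
    # graft onto a random current leaf or onto the whole tree
    if (stats::runif(1L) < 1 / (2L * nchar(nwk))) {
      nwk <- sprintf("(%s,%s)", nwk, lab)
    } else {
      present <- labels[seq_len(match(lab, labels) - 1L)]
      target <- sample(present, 1L)
      nwk <- sub(paste0("(?<![A-Za-z])", target, "(?![A-Za-z])"),
                 sprintf("(%s,%s)", target, lab), nwk, perl = TRUE)
    }
  }
  tr <- parse_newick(paste0(nwk, ";"))
  if (lengths) tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  tr
}

# a 3-ingroup + outgroup scenario with one internal branch of T coalescent
# units: (((A,B):T, C), O)
triplet_scenario <- function(T, loci, seed = 1L, gamma = 0, mu = 5e-3,
                             pulse_into = "B", pulse_from = "C") {
  nwk <- sprintf("(((A:1,B:1):%g,C:%g):3,O:%g);", T, 1 + T, 4 + T)
  pulses <- if (gamma > 0)
    list(list(donor = pulse_from, recipient = pulse_into, time = 0.5,
              gamma = gamma))
  scenario(nwk, loci = loci, mu = mu, pop_scale = 1, pulses = pulses,
           outgroup = "O", seed = seed)
}

# triplet sister-pair frequency table from a gene tree set (fast classifier)
sister_pair_counts <- function(gts, outgroup) {
  ids <- vapply(gts$trees, canonical_topology_id, character(1L),
                outgroup = outgroup)
  table(ids)
}

# per-locus ABBA/BABA block counts for one ordered triplet, straight from
# simulated alignments
block_counts_from_sim <- function(gts_subs, locus_length, ord, outgroup,
                                  seed = 1L) {
  set.seed(seed)
  aln_seeds <- sample.int(.Machine$integer.max - 1L, length(gts_subs$trees))
  t(vapply(seq_along(gts_subs$trees), function(i) {
    aln <- simulate_alignment(gts_subs$trees[[i]], locus_length,
                              seed = aln_seeds[i])
    pat <- suppressWarnings(extract_site_patterns(aln, outgroup))
    if (!ncol(pat)) return(c(nABBA = 0, nBABA = 0))
    ct <- count_abba_baba(pat, ord[1L], ord[2L], ord[3L], outgroup)
    c(nABBA = ct$nABBA, nBABA = ct$nBABA)
  }, numeric(2L)))
}
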