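#' Demonstration species tree of a rapid plant radiation
#'
#' A nine-species ingroup in four major groups plus an outgroup,
#' with node ages (years) chosen to emulate a young, ILS-rich radiation:
#' an ingroup crown burst at 550 ky with backbone internodes of 100-180
#' ky, group crowns 140-220 ky, and the outgroup split at 2 My.  With
#' the default scaling (Ne = 1e5 diploids, 2.5 generations/year; one
#' coalescent unit = 80,000 years) the internodes span roughly 1-2.25
#' coalescent units, the regime of pervasive gene-tree discordance
#' characteristic of such clades.
#'
#' @param Ne,gen_per_year population scaling passed to
#'   [sim_species_tree()].
#' @param accessions_per_species accessions sampled per ingroup species
#'   (ids `<species>_1` ... when more than one).
#' @return a `sim_species_tree`.
#' @export
demo_species_tree <- function(Ne = 1e5, gen_per_year = 2.5,
                              accessions_per_species = 1L) {
  species <- c("esc1", "esc2", "esc3", "arc1", "arc2",
               "per1", "per2", "hab1", "hab2", "out")
  k <- accessions_per_species
  acc <- character(0)
  for (sp in species) {
    n <- if (sp == "out") 1L else k
    ids <- if (n == 1L) sp else paste0(sp, "_", seq_len(n))
    acc <- c(acc, stats::setNames(rep(sp, n), ids))
  }
  groups <- c(esc1 = "Esculentum", esc2 = "Esculentum", esc3 = "Esculentum",
              arc1 = "Arcanum", arc2 = "Arcanum",
              per1 = "Peruvianum", per2 = "Peruvianum",
              hab1 = "Hirsutum", hab2 = "Hirsutum", out = "Outgroup")
  sim_species_tree(demo_newick(), Ne = Ne, gen_per_year = gen_per_year,
                   accessions = acc,
                   groups = stats::setNames(unname(groups[unname(acc)]),
                                            names(acc)))
}

# species-level newick, branch lengths in years, ultrametric.
# A burst-like radiation: backbone internodes of 80-180 ky (1-2.25
# coalescent units at the default scaling), the regime in which
# incomplete lineage sorting pervades gene trees.
demo_newick <- function() {
  paste0(
    "((((((esc1:80000,esc2:80000):60000,esc3:140000):180000,",
    "(arc1:150000,arc2:150000):170000):100000,",
    "(per1:220000,per2:220000):200000):130000,",
    "(hab1:180000,hab2:180000):370000):1450000,out:2000000);")
}

#' Demonstration accession-level guide tree (27 ingroup accessions)
#'
#' The [demo_species_tree()] topology with three accessions per ingroup
#' species, resolved by small within-species splits (15/30 ky), plus
#' the outgroup accession: the guide tree used for trio role
#' assignment, giving choose(27, 3) = 2,925 analysable trios.
#'
#' @return a rooted ultrametric `phylo` with 28 tips (27 ingroup +
#'   `out`).
#' @export
demo_accession_tree <- function() {
  nwk <- demo_newick()
  t1 <- 15000L; t2 <- 30000L
  for (sp in c("esc1", "esc2", "esc3", "arc1", "arc2",
               "per1", "per2", "hab1", "hab2")) {
    m <- regmatches(nwk, regexpr(sprintf("%s:[0-9]+", sp), nwk))
    len <- as.integer(sub(".*:", "", m))
    repl <- sprintf("((%s_1:%d,%s_2:%d):%d,%s_3:%d):%d",
                    sp, t1, sp, t1, t2 - t1, sp, t2, len - t2)
    nwk <- sub(sprintf("%s:[0-9]+", sp), repl, nwk)
  }
  ape::read.tree(text = nwk)
}
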