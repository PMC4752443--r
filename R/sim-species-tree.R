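#' Species tree for multispecies-coalescent simulation
#'
#' Wraps a rooted ultrametric species tree whose branch lengths are in
#' years, together with the population-genetic scaling used to convert
#' ages into coalescent units: `age_cu = age_years * gen_per_year /
#' (2 * Ne)`.  Defaults (`Ne = 1e5` diploids, 2.5 generations per year)
#' are those of a perennial plant radiation.
#'
#' @param tree a rooted ultrametric `phylo` object or newick string,
#'   branch lengths in years.
#' @param Ne diploid effective population size (every branch shares it).
#' @param gen_per_year generations per year.
#' @param accessions named character vector mapping accession id ->
#'   species tip label (>= 1 accession per sampled species).  Default:
#'   one accession per tip, named after it.
#' @param groups optional named character vector mapping accession ->
#'   major group label, used by reporting helpers.
#' @return a `sim_species_tree` object.
#' @export
sim_species_tree <- function(tree, Ne = 1e5, gen_per_year = 2.5,
                             accessions = NULL, groups = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stopf("tree must be a phylo or newick string")
  if (!ape::is.rooted(tree)) stopf("species tree must be rooted")
  if (!ape::is.ultrametric(tree, tol = 1e-6))
    stopf("species tree must be ultrametric (ages in years)")
  nt <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  age_yr <- max(depth) - depth          # per node, years before present
  age_yr[seq_len(nt)] <- 0
  if (is.null(accessions)) {
    accessions <- stats::setNames(tree$tip.label, tree$tip.label)
  }
  if (!all(accessions %in% tree$tip.label))
    stopf("accession map refers to species absent from the tree: %s",
          paste(setdiff(accessions, tree$tip.label), collapse = ","))
  parent <- rep(NA_integer_, nt + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  structure(list(tree = tree, Ne = Ne, gen_per_year = gen_per_year,
                 accessions = accessions, groups = groups,
                 age_yr = age_yr,
                 age_cu = age_yr * gen_per_year / (2 * Ne),
                 parent = parent, root = nt + 1L, n_tip = nt,
                 events = list()),
            class = "sim_species_tree")
}

#' @export
print.sim_species_tree <- function(x, ...) {
  cat(sprintf(paste0("sim_species_tree: %d species, %d accessions, ",
                     "Ne = %g, %g gen/yr, %d introgression event(s)\n"),
              x$n_tip, length(x$accessions), x$Ne, x$gen_per_year,
              length(x$events)))
  invisible(x)
}

#' Convert years to coalescent units under a simulation tree's scaling
#' @param sst a `sim_species_tree`.
#' @param years time in years.
#' @return time in coalescent units (2 Ne generations).
#' @export
years_to_cu <- function(sst, years) years * sst$gen_per_year / (2 * sst$Ne)

# node id of the species-tree branch for a species label or set of labels
lineage_node <- function(sst, x) {
  if (length(x) == 1L) {
    i <- match(x, sst$tree$tip.label)
    if (is.na(i)) stopf("species %s not in tree", x)
    return(i)
  }
  ape::getMRCA(sst$tree, x)
}

#' Add an introgression pulse to a simulation species tree
#'
#' The pulse model: for each simulated gene, with probability
#' `proportion` all lineages of the recipient branch are rerouted
#' through the donor branch at `time_years` (equivalently, a fraction
#' gamma of the recipient's genes trace their ancestry through the
#' donor).  Donor and recipient may be species labels or character
#' vectors of species (an ancestral branch, given by its descendant
#' tips).
#'
#' @param sst a `sim_species_tree`.
#' @param donor,recipient species label(s) identifying the two branches.
#' @param time_years pulse time; must lie within the lifetime of both
#'   branches (younger than their divergence).
#' @param proportion gamma in `[0, 1]`; a zero-proportion event is
#'   dropped (it cannot alter any genealogy).
#' @param genes optional integer vector: restrict the pulse to these
#'   gene indices (a contiguous block emulates a chromosomally localized
#'   recent introgression).
#' @return the updated `sim_species_tree`.
#' @export
inject_introgression <- function(sst, donor, recipient, time_years,
                                 proportion, genes = NULL) {
  stopifnot(inherits(sst, "sim_species_tree"))
  if (proportion < 0 || proportion > 1) stopf("proportion must be in [0,1]")
  dn <- lineage_node(sst, donor)
  rn <- lineage_node(sst, recipient)
  if (dn == rn) stopf("donor and recipient must be distinct branches")
  t_cu <- years_to_cu(sst, time_years)
  for (n in c(dn, rn)) {
    lo <- sst$age_cu[n]
    hi <- if (is.na(sst$parent[n])) Inf else sst$age_cu[sst$parent[n]]
    if (t_cu < lo || t_cu >= hi)
      stopf("event time %g yr is outside the lifetime of branch %d", time_years, n)
  }
  if (proportion == 0) return(sst)
  sst$events[[length(sst$events) + 1L]] <-
    list(donor = dn, recipient = rn, time_cu = t_cu,
         time_years = time_years, gamma = proportion, genes = genes)
  sst
}
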