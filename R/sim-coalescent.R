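# Structured (multispecies) coalescent over a labeled species tree.
#
# A genealogy is simulated backwards in time: each sampled lineage starts
# in its species' branch ("population"); within a population lineages
# coalesce at rate k(k-1)/2 per coalescent unit; at a speciation time the
# daughter populations merge; an introgression pulse moves all lineages
# of the recipient branch into the donor branch.  Coalescence between
# lineages of different species therefore can never predate the species
# divergence (unless rerouted by a pulse), which is the multispecies-
# coalescent constraint.

# Simulate one genealogy.  events: data.frame(time, type, node, donor)
# sorted by (time, speciation-before-introgression).  Returns merge
# records: parallel vectors c1, c2 (child ids; tips are 1..n_tip,
# internal node m has id n_tip + m) and height (coalescent units).
sim_one_genealogy <- function(n_tip, pop0, events, children_of) {
  pop <- c(pop0, rep(NA_integer_, n_tip - 1L))
  c1 <- c2 <- integer(n_tip - 1L)
  hmerge <- numeric(n_tip - 1L)
  active <- seq_len(n_tip)
  nxt <- n_tip + 1L
  m <- 0L
  t_cur <- 0
  n_ev <- nrow(events)
  for (e in seq_len(n_ev + 1L)) {
    t_end <- if (e <= n_ev) events$time[e] else Inf
    for (p in unique(pop[active])) {
      ids <- active[pop[active] == p]
      t <- t_cur
      while (length(ids) >= 2L) {
        k <- length(ids)
        t <- t + stats::rexp(1L, k * (k - 1L) / 2)
        if (t >= t_end) break
        pick <- sample.int(k, 2L)
        m <- m + 1L
        c1[m] <- ids[pick[1L]]
        c2[m] <- ids[pick[2L]]
        hmerge[m] <- t
        pop[nxt] <- p
        ids <- c(ids[-pick], nxt)
        nxt <- nxt + 1L
      }
      active <- c(active[pop[active] != p], ids)
    }
    if (length(active) == 1L && e > n_ev) break
    if (e <= n_ev) {
      t_cur <- t_end
      if (events$type[e] == "spec") {
        node <- events$node[e]
        sel <- active[pop[active] %in% children_of[[node]]]
        pop[sel] <- node
      } else {
        sel <- active[pop[active] == events$node[e]]
        pop[sel] <- events$donor[e]
      }
    }
  }
  list(c1 = c1[seq_len(m)], c2 = c2[seq_len(m)],
       height = hmerge[seq_len(m)], n_tip = n_tip)
}

# newick string from merge records (branch lengths in coalescent units)
records_to_newick <- function(rec, tips) {
  n <- rec$n_tip
  nh <- function(id) if (id <= n) 0 else rec$height[id - n]
  str1 <- function(id, parent_h) {
    bl <- parent_h - nh(id)
    if (id <= n) sprintf("%s:%.10g", tips[id], bl)
    else {
      mm <- id - n
      sprintf("(%s,%s):%.10g", str1(rec$c1[mm], rec$height[mm]),
              str1(rec$c2[mm], rec$height[mm]), bl)
    }
  }
  m <- length(rec$height)
  sprintf("(%s,%s);", str1(rec$c1[m], rec$height[m]),
          str1(rec$c2[m], rec$height[m]))
}

# per-branch descendant tip sets of a merge record; returns list:
# desc[[id]] = integer tip ids below node id
records_descendants <- function(rec) {
  n <- rec$n_tip
  desc <- vector("list", n + length(rec$height))
  for (i in seq_len(n)) desc[[i]] <- i
  for (m in seq_along(rec$height))
    desc[[n + m]] <- c(desc[[rec$c1[m]]], desc[[rec$c2[m]]])
  desc
}

# branches of a merge record: child node id, parent height, length
records_branches <- function(rec) {
  n <- rec$n_tip
  nh <- c(rep(0, n), rec$height)
  child <- c(rec$c1, rec$c2)
  ph <- c(rec$height, rec$height)
  data.frame(child = child, length = ph - nh[child])
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Draws `n_genes` independent genealogies of the sampled lineages
#' (one or two per accession) constrained by the species tree, honouring
#' any introgression pulses added with [inject_introgression()].  Branch
#' lengths are in coalescent units (2 Ne generations).
#'
#' @param sst a [sim_species_tree()].
#' @param n_genes number of unlinked genes.
#' @param seed integer seed; identical seeds reproduce identical newick
#'   strings.
#' @param lineages_per_accession 2 for diploid accessions (tip labels
#'   get `.h1`/`.h2` suffixes), 1 for haploid sampling (tips named by
#'   accession).
#' @return a list of `phylo` objects (class `radscan_genetrees`) with
#'   attributes: `records` (raw merge records per gene), `tips`,
#'   `introgressed` (per-gene truth table), `applied` (gene x event
#'   logical matrix), `sst`, `seed`.
#' @export
simulate_gene_trees <- function(sst, n_genes, seed,
                                lineages_per_accession = 2L) {
  stopifnot(inherits(sst, "sim_species_tree"))
  k <- as.integer(lineages_per_accession)
  stopifnot(k %in% 1:2)
  acc <- names(sst$accessions)
  tips <- if (k == 2L) paste0(rep(acc, each = 2L), c(".h1", ".h2"))
          else acc
  tip_species <- rep(unname(sst$accessions), each = k)
  pop0 <- match(tip_species, sst$tree$tip.label)
  n_tip <- length(tips)
  nt <- sst$n_tip
  children_of <- vector("list", nt + sst$tree$Nnode)
  for (i in seq_len(nrow(sst$tree$edge)))
    children_of[[sst$tree$edge[i, 1]]] <-
      c(children_of[[sst$tree$edge[i, 1]]], sst$tree$edge[i, 2])
  spec <- data.frame(time = sst$age_cu[(nt + 1L):(nt + sst$tree$Nnode)],
                     type = "spec", node = (nt + 1L):(nt + sst$tree$Nnode),
                     donor = NA_integer_)
  ev <- sst$events
  records <- vector("list", n_genes)
  applied <- matrix(FALSE, n_genes, length(ev))
  with_seed(seed, {
    for (g in seq_len(n_genes)) {
      evs <- spec
      for (j in seq_along(ev)) {
        e <- ev[[j]]
        eligible <- is.null(e$genes) || g %in% e$genes
        if (eligible && stats::runif(1L) < e$gamma) {
          applied[g, j] <- TRUE
          evs <- rbind(evs, data.frame(time = e$time_cu, type = "intro",
                                       node = e$recipient, donor = e$donor))
        }
      }
      evs <- evs[order(evs$time, evs$type != "spec"), , drop = FALSE]
      records[[g]] <- sim_one_genealogy(n_tip, pop0, evs, children_of)
    }
  })
  res <- vector("list", n_genes)
  for (g in seq_len(n_genes))
    res[[g]] <- ape::read.tree(text = records_to_newick(records[[g]], tips))
  structure(res, class = c("radscan_genetrees", "list"),
            records = records, tips = tips,
            introgressed = data.frame(
              gene = seq_len(n_genes),
              introgressed = if (length(ev)) rowSums(applied) > 0
                             else rep(FALSE, n_genes)),
            applied = applied, sst = sst, seed = seed,
            lineages_per_accession = k)
}

#' Check the multispecies-coalescent consistency of simulated genealogies
#'
#' Verifies, for every coalescence joining lineages of different
#' species, that it is not more recent than the species divergence.
#' Only meaningful for pulse-free simulations (an introgression pulse
#' legitimately violates the constraint: that is its signal).
#'
#' @param trees output of [simulate_gene_trees()].
#' @param genes gene indices to check (default: all).
#' @return TRUE invisibly, or an error describing the violation.
#' @export
check_msc_consistency <- function(trees, genes = seq_along(trees)) {
  sst <- attr(trees, "sst")
  if (length(sst$events))
    stopf("consistency check applies to pulse-free simulations")
  k <- attr(trees, "lineages_per_accession")
  tip_species_id <- match(rep(unname(sst$accessions), each = k),
                          sst$tree$tip.label)
  sp_mrca <- ape::mrca(sst$tree, full = FALSE)
  div_cu <- matrix(sst$age_cu[sp_mrca], nrow(sp_mrca))
  for (g in genes) {
    rec <- attr(trees, "records")[[g]]
    desc <- records_descendants(rec)
    for (m in seq_along(rec$height)) {
      s1 <- unique(tip_species_id[desc[[rec$c1[m]]]])
      s2 <- unique(tip_species_id[desc[[rec$c2[m]]]])
      need <- max(div_cu[s1, s2, drop = FALSE])
      if (rec$height[m] < need - 1e-9)
        stopf("gene %d: coalescence at %g cu predates species divergence %g",
              g, rec$height[m], need)
    }
  }
  invisible(TRUE)
}
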