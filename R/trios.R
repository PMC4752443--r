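#' Enumerate D-statistic trios from a species tree
#'
#' For every unordered 3-subset of the ingroup accessions, assigns the
#' roles P1, P2 (the pair with the most recent common ancestor, i.e. the
#' sister pair of the induced triplet) and P3, fixed by the rooted guide
#' tree.  With n ingroup accessions this yields choose(n, 3)
#' assignments.
#'
#' @param tree rooted `phylo` over accessions (or a
#'   [sim_species_tree()], whose accession-level tree is derived by
#'   substituting each species tip with its accessions as a star).
#' @param ingroup character vector of ingroup accession ids.
#' @param outgroup outgroup accession id recorded in each assignment.
#' @return data.frame: `p1`, `p2`, `p3`, `outgroup`.
#' @export
enumerate_trios <- function(tree, ingroup, outgroup) {
  tree <- accession_tree(tree)
  missing <- setdiff(c(ingroup, outgroup), tree$tip.label)
  if (length(missing))
    stopf("accessions absent from guide tree: %s",
          paste(missing, collapse = ","))
  if (length(ingroup) < 3L) stopf("need at least three ingroup accessions")
  depth <- ape::node.depth.edgelength(tree)
  mrca <- ape::mrca(tree)
  idx <- match(ingroup, tree$tip.label)
  combs <- utils::combn(seq_along(ingroup), 3L)
  out <- vector("list", ncol(combs))
  for (c_i in seq_len(ncol(combs))) {
    tri <- combs[, c_i]
    t_idx <- idx[tri]
    d12 <- depth[mrca[t_idx[1], t_idx[2]]]
    d13 <- depth[mrca[t_idx[1], t_idx[3]]]
    d23 <- depth[mrca[t_idx[2], t_idx[3]]]
    dm <- c(d12, d13, d23)
    best <- which(dm == max(dm))
    if (length(best) > 1L)
      stopf("trio {%s} is unresolved in the guide tree",
            paste(ingroup[tri], collapse = ","))
    pair <- switch(best, c(1L, 2L), c(1L, 3L), c(2L, 3L))
    p3 <- setdiff(1:3, pair)
    out[[c_i]] <- data.frame(p1 = ingroup[tri[pair[1]]],
                             p2 = ingroup[tri[pair[2]]],
                             p3 = ingroup[tri[p3]],
                             outgroup = outgroup)
  }
  do.call(rbind, out)
}

# accession-level guide tree: each species tip of a sim_species_tree is
# replaced by its accessions (zero-length star when several)
accession_tree <- function(x) {
  if (inherits(x, "phylo")) return(x)
  stopifnot(inherits(x, "sim_species_tree"))
  tr <- x$tree
  for (sp in unique(unname(x$accessions))) {
    accs <- names(x$accessions)[x$accessions == sp]
    if (length(accs) == 1L) {
      tr$tip.label[tr$tip.label == sp] <- accs
    } else {
      star <- sprintf("(%s):0;", paste0(accs, ":0", collapse = ","))
      tr <- ape::bind.tree(tr, ape::read.tree(text = star),
                           where = which(tr$tip.label == sp))
    }
  }
  tr
}
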