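#' Count rooted triplet topologies of gene trees
#'
#' Each gene tree is pruned to the trio plus outgroup, rooted on the
#' outgroup, and classified by which pair of the trio forms the cherry:
#' concordant `(p1,p2)`, or one of the two discordant arrangements.
#' Trees missing a taxon or unresolved after pruning are skipped and
#' reported.
#'
#' @param trees list of `phylo` objects (or `radscan_genetrees`).
#' @param p1,p2,p3 the trio, ordered so `(p1,p2)` is the species-tree
#'   sister pair.
#' @param outgroup outgroup tip used to root each tree; `NULL` when the
#'   trees are already rooted genealogies.
#' @return list: `counts` (named: concordant, disc_p1p3, disc_p2p3),
#'   `proportions`, `n_resolved`, `n_skipped`, `n_unresolved`.
#' @export
count_topologies <- function(trees, p1, p2, p3, outgroup = NULL) {
  need <- c(p1, p2, p3, outgroup)
  n_skip <- 0L; n_unres <- 0L
  counts <- c(concordant = 0L, disc_p1p3 = 0L, disc_p2p3 = 0L)
  for (tr in trees) {
    if (!all(need %in% tr$tip.label)) { n_skip <- n_skip + 1L; next }
    t4 <- ape::keep.tip(tr, need)
    if (!is.null(outgroup)) {
      t4 <- ape::root(t4, outgroup, resolve.root = TRUE)
      t3 <- ape::drop.tip(t4, outgroup)
    } else t3 <- t4
    if (t3$Nnode < 2L) { n_unres <- n_unres + 1L; next }
    mr <- ape::mrca(t3)
    i <- function(a) match(a, t3$tip.label)
    root <- length(t3$tip.label) + 1L
    cherry <- if (mr[i(p1), i(p2)] != root) "concordant"
    else if (mr[i(p1), i(p3)] != root) "disc_p1p3"
    else "disc_p2p3"
    counts[cherry] <- counts[cherry] + 1L
  }
  n_res <- sum(counts)
  if (n_skip > 0)
    warning(sprintf("%d tree(s) skipped for missing taxa", n_skip))
  list(counts = counts,
       proportions = if (n_res > 0) counts / n_res else counts * NA_real_,
       n_resolved = n_res, n_skipped = n_skip, n_unresolved = n_unres)
}

#' Estimate the introgressed gene fraction from topology counts
#'
#' Under ILS alone the two discordant triplet topologies are equally
#' frequent; introgression inflates the one uniting the exchanging
#' pair.  The introgressed proportion is estimated as the difference of
#' the two discordant proportions.
#'
#' @param tc result of [count_topologies()].
#' @return list: `estimate` = |prop(disc_p1p3) - prop(disc_p2p3)|,
#'   `implicated_pair` (`"p1-p3"` or `"p2-p3"`), and the proportions.
#' @export
introgressed_fraction <- function(tc) {
  if (tc$n_resolved == 0) stopf("no resolved trees")
  p13 <- tc$proportions[["disc_p1p3"]]
  p23 <- tc$proportions[["disc_p2p3"]]
  list(estimate = abs(p13 - p23),
       implicated_pair = if (p13 >= p23) "p1-p3" else "p2-p3",
       prop_disc_p1p3 = p13, prop_disc_p2p3 = p23,
       prop_concordant = tc$proportions[["concordant"]])
}
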