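# Gene-tree / window-tree discordance profiling.

# canonical key of a tree's unrooted topology: the sorted set of
# nontrivial bipartitions, each encoded by its lexicographically
# smaller side over the sorted taxon labels
topology_key <- function(tree, taxa = NULL) {
  if (!is.null(taxa)) tree <- ape::keep.tip(tree, taxa)
  splits_of(tree, sorted = TRUE)$key
}

# nontrivial bipartitions of an unrooted tree as canonical strings
splits_of <- function(tree, sorted = FALSE) {
  tree <- ape::unroot(tree)
  labs <- sort(tree$tip.label)
  n <- length(labs)
  bp <- ape::prop.part(tree)
  ord <- match(attr(bp, "labels"), labs)
  keys <- character(0)
  for (s in bp) {
    side <- sort(ord[s])
    if (length(side) <= 1L || length(side) >= n - 1L) next
    comp <- setdiff(seq_len(n), side)
    a <- paste(side, collapse = ",")
    b <- paste(comp, collapse = ",")
    keys <- c(keys, if (a < b) a else b)
  }
  keys <- unique(keys)
  list(splits = keys,
       key = if (sorted) paste(sort(keys), collapse = ";") else NULL,
       labels = labs)
}

#' Count distinct unrooted topologies in a tree set
#'
#' Trees are pruned to the common taxon set and classified as unrooted
#' label-identical topologies (identical nontrivial bipartition sets,
#' i.e. Robinson-Foulds distance zero); branch lengths and newick child
#' rotations are ignored.
#'
#' @param trees list of `phylo` objects.
#' @return integer: number of distinct topology classes (attribute
#'   `classes` gives the class id per tree).
#' @export
count_distinct_topologies <- function(trees) {
  if (!length(trees)) return(0L)
  taxa <- Reduce(intersect, lapply(trees, `[[`, "tip.label"))
  if (length(taxa) < 4L)
    stopf("trees share fewer than four taxa")
  keys <- vapply(trees, topology_key, character(1), taxa = taxa)
  cls <- match(keys, unique(keys))
  structure(length(unique(keys)), classes = cls)
}

#' Bipartition support of a reference tree's branches
#'
#' For each internal branch of the reference tree, the proportion of
#' trees whose bipartition set contains that branch's bipartition
#' (exact containment: a polytomy supports nothing it does not resolve).
#'
#' @param trees list of `phylo` objects.
#' @param reference a `phylo`; its taxa must be present in every tree
#'   (trees are pruned to the reference's taxon set).
#' @return data.frame: `split` (canonical key), `size` (smaller-side
#'   taxon count), `branch_length` (from the reference, `NA` when
#'   absent), `support`.
#' @export
bipartition_support <- function(trees, reference) {
  taxa <- sort(reference$tip.label)
  for (tr in trees)
    if (!all(taxa %in% tr$tip.label))
      stopf("a tree lacks reference taxa")
  ref_splits <- splits_with_lengths(reference)
  tree_splits <- lapply(trees, function(tr)
    splits_of(ape::keep.tip(tr, taxa))$splits)
  support <- vapply(ref_splits$split, function(s)
    mean(vapply(tree_splits, function(x) s %in% x, logical(1))),
    numeric(1))
  data.frame(split = ref_splits$split, size = ref_splits$size,
             branch_length = ref_splits$branch_length,
             support = support, row.names = NULL)
}

# reference splits with their branch lengths
splits_with_lengths <- function(tree) {
  labs <- sort(tree$tip.label)
  n <- length(labs)
  un <- ape::unroot(tree)
  nt <- length(un$tip.label)
  desc <- vector("list", nt + un$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- match(un$tip.label[i], labs)
  edges <- un$edge[order(un$edge[, 2]), , drop = FALSE]
  po <- ape::reorder.phylo(un, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  rows <- list()
  for (k in seq_len(nrow(po$edge))) {
    ch <- po$edge[k, 2]
    if (ch <= nt) next
    side <- sort(desc[[ch]])
    if (length(side) <= 1L || length(side) >= n - 1L) next
    comp <- setdiff(seq_len(n), side)
    a <- paste(side, collapse = ","); b <- paste(comp, collapse = ",")
    rows[[length(rows) + 1L]] <- data.frame(
      split = if (a < b) a else b,
      size = min(length(side), length(comp)),
      branch_length = if (!is.null(po$edge.length)) po$edge.length[k]
                      else NA_real_)
  }
  out <- do.call(rbind, rows)
  out[!duplicated(out$split), , drop = FALSE]
}

#' Correlation between internal branch length and bipartition support
#'
#' Shorter internodes sort less completely and are therefore expected
#' to show more gene-tree discordance; a positive rank correlation
#' between reference branch length and support is the signature of
#' ILS-driven (rather than error-driven) discordance.
#'
#' @param support data.frame from [bipartition_support()].
#' @return list: `rho` (Spearman), `p`, `n_branches`, `ties` (TRUE when
#'   support is constant, making the correlation undefined).
#' @export
branchlen_vs_concordance <- function(support) {
  ok <- !is.na(support$branch_length)
  x <- support$branch_length[ok]; y <- support$support[ok]
  if (length(x) < 3L)
    return(list(rho = NA_real_, p = NA_real_, n_branches = length(x),
                ties = FALSE))
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    return(list(rho = NA_real_, p = NA_real_, n_branches = length(x),
                ties = TRUE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value,
       n_branches = length(x), ties = FALSE)
}

#' Per-taxon instability across a tree set
#'
#' Scores how volatile each taxon's position is across trees: for each
#' taxon, the mean (over other taxa) standard deviation (over trees) of
#' the topological (nodal) distance between the pair.  A taxon that
#' jumps between clades accumulates large variance against everything
#' else and ranks first; identical trees give all-zero scores.  The
#' contract is the ranking, not the absolute value.
#'
#' @param trees list of `phylo` objects (>= 2), pruned to their common
#'   taxon set.
#' @return named numeric vector of instability scores, decreasing order.
#' @export
taxon_instability <- function(trees) {
  if (length(trees) < 2L) stopf("need at least two trees")
  taxa <- sort(Reduce(intersect, lapply(trees, `[[`, "tip.label")))
  if (length(taxa) < 3L) stopf("fewer than three shared taxa")
  nd <- lapply(trees, function(tr) {
    t2 <- ape::keep.tip(tr, taxa)
    t2$edge.length <- rep(1, nrow(t2$edge))
    d <- ape::cophenetic.phylo(t2)
    d[taxa, taxa]
  })
  arr <- simplify2array(nd)          # taxa x taxa x trees
  sds <- apply(arr, c(1, 2), stats::sd)
  score <- rowMeans(sds)
  sort(score, decreasing = TRUE)
}
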