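#' Environmental partition of accessions
#'
#' A binary classification of accessions by an environmental factor.
#' The scan is only informative when ecology is not confounded with
#' phylogeny, so a valid partition must place members of at least one
#' species (or major group) on both sides and must not coincide with a
#' clade of the species tree.
#'
#' @param factor_name label of the environmental axis.
#' @param groups named character vector accession -> group label
#'   (exactly two labels).
#' @param provenance free-text note on how the classification was
#'   derived.
#' @return an `env_partition` object.
#' @export
env_partition <- function(factor_name, groups, provenance = NA_character_) {
  labs <- unique(unname(groups))
  if (length(labs) != 2L)
    stopf("partition must have exactly two non-empty groups")
  structure(list(factor_name = factor_name, groups = groups,
                 labels = labs, provenance = provenance),
            class = "env_partition")
}

#' Validate an environmental partition against the phylogeny
#'
#' @param p an [env_partition()].
#' @param sst a [sim_species_tree()] (supplies the accession -> species
#'   map and the species tree).
#' @return character vector of violations (empty when the partition is
#'   usable).
#' @export
validate_partition <- function(p, sst) {
  v <- character(0)
  unknown <- setdiff(names(p$groups), names(sst$accessions))
  if (length(unknown))
    stopf("unknown accessions in partition: %s",
          paste(unknown, collapse = ","))
  for (lab in p$labels)
    if (!sum(p$groups == lab)) v <- c(v, sprintf("group '%s' is empty", lab))
  split_on <- function(map) {
    m <- map[names(p$groups)]
    any(vapply(unique(unname(m)), function(s) {
      length(unique(p$groups[names(m)[m == s]])) > 1L
    }, logical(1)))
  }
  split_species <- split_on(sst$accessions) ||
    (!is.null(sst$groups) && split_on(sst$groups))
  if (!split_species)
    v <- c(v, "no species or group occurs in both ecological categories")
  v <- c(v, partition_clade_congruence(p$groups, sst))
  v
}

#' Scan for variants perfectly associated with an environmental partition
#'
#' A site is a perfect association ("hit") when every contrasted
#' accession has data and the allele sets of the two groups are
#' completely disjoint.  `n_variants_examined` counts all
#' class-qualifying variable sites with complete data over the
#' contrasted accessions (sites with more than two alleles among them
#' are excluded, as in the pattern-counting operations).
#'
#' @param h a `haploid_matrix` with `class` annotations (or supply
#'   `classes`).
#' @param p an [env_partition()].
#' @param class `"nonsynonymous"` (default), `"synonymous"` or `"any"`.
#' @return an `association_scan`: list with `factor_name`,
#'   `n_variants_examined`, `m` (hit count) and `hits` (data.frame
#'   gene, chrom, pos, class, allele per group).
#' @export
scan_perfect_association <- function(h, p, class = "nonsynonymous") {
  stopifnot(inherits(h, "haploid_matrix"))
  acc <- names(p$groups)
  missing <- setdiff(acc, h$accessions)
  if (length(missing)) stopf("partition accessions absent: %s",
                             paste(missing, collapse = ","))
  g1 <- acc[p$groups == p$labels[1]]
  g2 <- acc[p$groups == p$labels[2]]
  x <- h$h[, acc, drop = FALSE]
  complete <- rowSums(is.na(x)) == 0
  cls_ok <- if (class == "any") rep(TRUE, n_sites(h))
            else !is.na(h$class) & h$class == class
  nall <- vapply(seq_len(n_sites(h)), function(i)
    length(unique(x[i, ])), integer(1))
  examined <- complete & cls_ok & nall == 2L
  hit <- examined & vapply(seq_len(n_sites(h)), function(i) {
    a1 <- unique(x[i, g1]); a2 <- unique(x[i, g2])
    !length(intersect(a1, a2))
  }, logical(1))
  hits <- data.frame(gene = if (!is.null(h$gene)) h$gene[hit]
                            else NA_character_,
                     chrom = h$chrom[hit], pos = h$pos[hit],
                     class = if (!is.null(h$class)) h$class[hit]
                             else class,
                     allele_group1 = vapply(which(hit), function(i)
                       paste(sort(unique(x[i, g1])), collapse = "/"), ""),
                     allele_group2 = vapply(which(hit), function(i)
                       paste(sort(unique(x[i, g2])), collapse = "/"), ""))
  structure(list(factor_name = p$factor_name,
                 n_variants_examined = sum(examined),
                 m = sum(hit), hits = hits, class = class,
                 partition = p),
            class = "association_scan")
}

#' Null probability of a perfect association under the coalescent
#'
#' Simulates single-variable-site genes over the species tree (one
#' haploid lineage per contrasted accession; the single variable site
#' is realised by one mutation placed on the genealogy with probability
#' proportional to branch length) and estimates q, the probability that
#' the derived-allele carrier set splits the contrasted accessions
#' exactly along the partition (either polarity).  This is the
#' hemiplasy rate the association scan must beat.
#'
#' @param sst a [sim_species_tree()].
#' @param p an [env_partition()].
#' @param n_genes simulated single-site genes.
#' @param seed integer seed.
#' @param method `"sample"` draws the mutation (one Bernoulli trial per
#'   gene); `"expected"` uses the per-genealogy matching branch-length
#'   fraction (same expectation, smaller Monte-Carlo error).
#' @return list: `q`, `se` (Monte-Carlo standard error), `n_genes`,
#'   `method`, `seed`.
#' @export
estimate_null_probability <- function(sst, p, n_genes = 1e5, seed = 1L,
                                      method = c("sample", "expected")) {
  method <- match.arg(method)
  if (n_genes < 1) stopf("n_genes must be positive")
  acc <- names(p$groups)
  sub <- sim_species_tree(keep_species(sst, acc),
                          Ne = sst$Ne, gen_per_year = sst$gen_per_year,
                          accessions = sst$accessions[acc])
  g1 <- sort(match(acc[p$groups == p$labels[1]], acc))
  trees <- simulate_gene_trees(sub, n_genes, seed,
                               lineages_per_accession = 1L)
  records <- attr(trees, "records")
  n <- length(acc)
  per_gene <- with_seed(seed + 1L, vapply(records, function(rec) {
    br <- records_branches(rec)
    desc <- records_descendants(rec)
    match_len <- 0
    for (k in seq_len(nrow(br))) {
      d <- sort(desc[[br$child[k]]])
      if (identical(d, g1) || identical(d, sort(setdiff(seq_len(n), g1))))
        match_len <- match_len + br$length[k]
    }
    frac <- match_len / sum(br$length)
    if (method == "expected") frac
    else as.numeric(stats::runif(1L) < frac)
  }, numeric(1)))
  q <- mean(per_gene)
  se <- stats::sd(per_gene) / sqrt(n_genes)
  list(q = q, se = se, n_genes = n_genes, method = method, seed = seed)
}

# restrict a species tree to the species sampled by `acc`essions
keep_species <- function(sst, acc) {
  sp <- unique(unname(sst$accessions[acc]))
  if (length(sp) < 2L) stopf("need at least two species")
  ape::keep.tip(sst$tree, sp)
}

#' Dataset-level significance of an association count
#'
#' Probability of a dataset with at least `m` perfect associations
#' among `n` examined variants when each is independently a hemiplasy
#' hit with probability `q`: the binomial method evaluates
#' `P[Binom(n, q) >= m]` directly; the full-resimulation method draws
#' dataset hit counts and reports the exceedance proportion.  The two
#' agree within Monte-Carlo error under per-gene independence.  The
#' default `>=` is the standard "at least as extreme" convention (so
#' observing zero hits is never significant); `"greater"` counts only
#' datasets strictly exceeding the observation, which is
#' indistinguishable in the large-count regime.
#'
#' @param m observed hits.
#' @param n variants examined.
#' @param q per-variant null probability.
#' @param method `"binomial"` or `"resim"`.
#' @param n_datasets replicate datasets for `"resim"`.
#' @param seed seed for `"resim"`.
#' @param exceedance `"geq"` (default) or `"greater"`.
#' @return p-value.
#' @export
dataset_pvalue <- function(m, n, q, method = c("binomial", "resim"),
                           n_datasets = 10000L, seed = 1L,
                           exceedance = c("geq", "greater")) {
  method <- match.arg(method)
  exceedance <- match.arg(exceedance)
  stopifnot(q >= 0, q <= 1)
  thr <- if (exceedance == "geq") m - 1L else m
  if (method == "binomial")
    return(stats::pbinom(thr, n, q, lower.tail = FALSE))
  draws <- with_seed(seed, stats::rbinom(n_datasets, n, q))
  mean(draws > thr)
}

#' Full-resimulation dataset p-value from fresh genealogies
#'
#' Re-simulates entire datasets of `n` single-site genes (fresh
#' genealogies each time, no binomial shortcut) and reports the
#' proportion with a hit count exceeding `m`.  This is the expensive
#' cross-check of [dataset_pvalue()]'s binomial method.
#'
#' @inheritParams estimate_null_probability
#' @param m observed hits.
#' @param n variants per dataset.
#' @param n_datasets replicate datasets.
#' @param exceedance `"geq"` (default) or `"greater"`, as in
#'   [dataset_pvalue()].
#' @return list: `p`, `counts` (per-dataset hit counts).
#' @export
resimulate_dataset_pvalue <- function(sst, p, m, n, n_datasets = 200L,
                                      seed = 1L,
                                      exceedance = c("geq", "greater")) {
  exceedance <- match.arg(exceedance)
  counts <- integer(n_datasets)
  for (d in seq_len(n_datasets)) {
    est <- estimate_null_probability(sst, p, n_genes = n,
                                     seed = seed + d, method = "sample")
    counts[d] <- as.integer(round(est$q * n))
  }
  thr <- if (exceedance == "geq") m - 1L else m
  list(p = mean(counts > thr), counts = counts)
}

#' Linked synonymous variants at association hits
#'
#' Under introgression a localized block of variants tracks the
#' partition regardless of coding effect, whereas selection on a
#' standing nonsynonymous variant does not drag synonymous neighbours
#' to fixation in both groups.  For each gene with a nonsynonymous hit,
#' counts the synonymous sites in the same gene that are also perfectly
#' associated; genes with one or more are flagged
#' introgression-ambiguous.
#'
#' @param scan an `association_scan` from [scan_perfect_association()].
#' @param h the `haploid_matrix` that was scanned.
#' @return data.frame: `gene`, `n_assoc_syn`, `introgression_ambiguous`.
#' @export
linked_synonymous_check <- function(scan, h) {
  syn <- scan_perfect_association(h, scan$partition, class = "synonymous")
  genes <- unique(scan$hits$gene)
  n_syn <- vapply(genes, function(g)
    sum(syn$hits$gene == g, na.rm = TRUE), integer(1))
  data.frame(gene = genes, n_assoc_syn = n_syn,
             introgression_ambiguous = n_syn >= 1L, row.names = NULL)
}
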