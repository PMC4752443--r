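#' Simulate a diploid variant matrix from gene trees
#'
#' Places infinite-sites mutations on each genealogy (site positions
#' drawn uniformly within the gene's span; mutated branch drawn with
#' probability proportional to branch length), so the derived-allele
#' carriers of a site are exactly the leaves below the mutated branch
#' and there is no back-mutation.  Genes are laid out on one synthetic
#' chromosome at a fixed spacing, so genomic-window operations are
#' exercised.  Diploid genotypes pair each accession's two sampled
#' lineages; heterozygosity therefore arises naturally from coalescent
#' depth.  Each site carries a synonymous/nonsynonymous flag emulating a
#' transcriptome variant matrix (sites are not tied to a realised codon
#' sequence; codon-level operations use explicit [gene_model()]s).
#'
#' @param trees output of [simulate_gene_trees()].
#' @param sites_per_gene fixed number of variable sites per gene; or
#'   `NULL` to draw Poisson(`theta`/2 x total tree length) mutations.
#' @param theta population mutation parameter per gene (used when
#'   `sites_per_gene` is `NULL`).
#' @param seed integer seed.
#' @param chrom synthetic chromosome name.
#' @param gene_spacing bp between gene starts (sites of gene g fall in
#'   `[(g-1)*gene_spacing, g*gene_spacing)`).
#' @param p_nonsyn probability that a simulated variant is flagged
#'   nonsynonymous.
#' @param inbreeding per-accession inbreeding coefficient F in `[0, 1]`
#'   (scalar or named vector): at each site, with probability F the
#'   accession's genotype is collapsed to its first lineage's allele,
#'   so fully selfing accessions (F = 1) show no heterozygosity while
#'   outcrossers (F = 0, default) pair their two sampled lineages.
#' @return a `variant_matrix` with `gene` and `class` annotations and
#'   attributes `truth` (per-gene introgression truth table carried from
#'   the trees), `gene_coords`, and `seed`.
#' @export
simulate_variants <- function(trees, sites_per_gene = 20L, theta = NULL,
                              seed = 1L, chrom = "chr1",
                              gene_spacing = 10000L, p_nonsyn = 0.5,
                              inbreeding = 0) {
  stopifnot(inherits(trees, "radscan_genetrees"))
  k <- attr(trees, "lineages_per_accession")
  sst <- attr(trees, "sst")
  acc <- names(sst$accessions)
  n_acc <- length(acc)
  f_in <- if (length(inbreeding) == 1L)
    stats::setNames(rep(inbreeding, n_acc), acc)
  else {
    if (!all(acc %in% names(inbreeding)))
      stopf("inbreeding must name every accession")
    inbreeding[acc]
  }
  records <- attr(trees, "records")
  n_genes <- length(records)
  out <- with_seed(seed, {
    rows <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      rec <- records[[g]]
      br <- records_branches(rec)
      desc <- records_descendants(rec)
      n_mut <- if (!is.null(sites_per_gene)) sites_per_gene
               else stats::rpois(1L, theta / 2 * sum(br$length))
      if (n_mut == 0) next
      if (n_mut > gene_spacing)
        stopf("more mutations than available positions in gene %d", g)
      b <- sample.int(nrow(br), n_mut, replace = TRUE, prob = br$length)
      offs <- sort(sample.int(gene_spacing, n_mut)) - 1L
      a1 <- matrix(NA_character_, n_mut, n_acc)
      a2 <- matrix(NA_character_, n_mut, n_acc)
      ref <- character(n_mut); cls <- character(n_mut)
      for (s in seq_len(n_mut)) {
        anc_der <- sample(c("A", "C", "G", "T"), 2L)
        carriers <- desc[[br$child[b[s]]]]
        tip_allele <- rep(anc_der[1L], rec$n_tip)
        tip_allele[carriers] <- anc_der[2L]
        if (k == 2L) {
          h1 <- tip_allele[seq(1L, 2L * n_acc, by = 2L)]
          h2 <- tip_allele[seq(2L, 2L * n_acc, by = 2L)]
          if (any(f_in > 0)) {
            collapse <- stats::runif(n_acc) < f_in
            h2[collapse] <- h1[collapse]
          }
        } else {
          h1 <- h2 <- tip_allele
        }
        a1[s, ] <- pmin(h1, h2)
        a2[s, ] <- pmax(h1, h2)
        ref[s] <- anc_der[1L]
        cls[s] <- if (stats::runif(1L) < p_nonsyn) "nonsynonymous"
                  else "synonymous"
      }
      rows[[g]] <- list(pos = (g - 1L) * gene_spacing + offs, ref = ref,
                        a1 = a1, a2 = a2, class = cls,
                        gene = rep(sprintf("g%04d", g), n_mut))
    }
    rows
  })
  keep <- !vapply(out, is.null, logical(1))
  if (!any(keep)) {
    empty <- matrix(character(0), 0, n_acc, dimnames = list(NULL, acc))
    vm <- variant_matrix(character(0), integer(0), character(0),
                         empty, empty, accessions = acc,
                         class = character(0), gene = character(0))
  } else {
    rows <- out[keep]
    a1 <- do.call(rbind, lapply(rows, `[[`, "a1"))
    a2 <- do.call(rbind, lapply(rows, `[[`, "a2"))
    colnames(a1) <- colnames(a2) <- acc
    vm <- variant_matrix(chrom = rep(chrom, nrow(a1)),
                         pos = unlist(lapply(rows, `[[`, "pos")),
                         ref = unlist(lapply(rows, `[[`, "ref")),
                         a1 = a1, a2 = a2, accessions = acc,
                         class = unlist(lapply(rows, `[[`, "class")),
                         gene = unlist(lapply(rows, `[[`, "gene")))
  }
  attr(vm, "truth") <- attr(trees, "introgressed")
  attr(vm, "gene_coords") <- data.frame(
    gene = sprintf("g%04d", seq_len(n_genes)), chrom = chrom,
    start = (seq_len(n_genes) - 1L) * gene_spacing,
    end = seq_len(n_genes) * gene_spacing)
  attr(vm, "seed") <- seed
  vm
}

#' Inject environment-sorted ancestral alleles into a variant matrix
#'
#' Emulates differential fixation of ancestrally segregating variants
#' between two sets of accessions living under contrasting ecological
#' conditions: at `n_sites` new nonsynonymous-flagged sites (one per
#' chosen gene), group-1 accessions are fixed for one allele and
#' group-2 accessions for another, so the two groups' allele sets are
#' disjoint by construction.  Accessions outside the partition are set
#' missing at the injected sites.  A partition congruent with a clade of
#' the species tree is refused: such a contrast could not separate
#' ecology from phylogeny.
#'
#' @param vm a `variant_matrix` with `gene` annotations (e.g. from
#'   [simulate_variants()]).
#' @param partition named character vector accession -> group label
#'   (exactly two labels).
#' @param n_sites number of sites to inject.
#' @param seed integer seed.
#' @param sst optional [sim_species_tree()] used for the clade-congruence
#'   refusal check (strongly recommended).
#' @param genes optional gene ids to target (default: sampled without
#'   replacement from the genes present).
#' @return list with elements `matrix` (the augmented `variant_matrix`)
#'   and `truth` (data.frame: gene, chrom, pos, group alleles, labels).
#' @export
inject_environment_alleles <- function(vm, partition, n_sites, seed = 1L,
                                       sst = NULL, genes = NULL) {
  labs <- unique(unname(partition))
  if (length(labs) != 2L) stopf("partition must have exactly two groups")
  g1 <- names(partition)[partition == labs[1]]
  g2 <- names(partition)[partition == labs[2]]
  if (!length(g1) || !length(g2)) stopf("both groups must be non-empty")
  if (!all(names(partition) %in% vm$accessions))
    stopf("partition names absent from matrix: %s",
          paste(setdiff(names(partition), vm$accessions), collapse = ","))
  if (!is.null(sst)) {
    v <- partition_clade_congruence(partition, sst)
    if (length(v)) stopf("partition congruent with a clade: %s", v[1])
  }
  if (n_sites == 0) return(list(matrix = vm, truth = data.frame()))
  if (is.null(vm$gene)) stopf("matrix carries no gene annotation")
  pool <- unique(vm$gene)
  if (is.null(genes)) {
    if (length(pool) < n_sites) stopf("not enough genes to place %d sites", n_sites)
    genes <- with_seed(seed, sample(pool, n_sites))
  }
  gc <- attr(vm, "gene_coords")
  truth <- NULL
  add <- with_seed(seed + 1L, {
    lapply(seq_len(n_sites), function(i) {
      gn <- genes[i]
      used <- vm$pos[vm$gene == gn]
      span <- if (!is.null(gc)) gc[gc$gene == gn, ] else
        data.frame(chrom = vm$chrom[vm$gene == gn][1],
                   start = min(used), end = max(used) + 1L)
      free <- setdiff(seq.int(span$start, span$end - 1L), used)
      pos <- sample(free, 1L)
      alleles <- sample(c("A", "C", "G", "T"), 2L)
      list(gene = gn, chrom = span$chrom, pos = pos,
           x = alleles[1], y = alleles[2])
    })
  })
  n <- n_sites(vm)
  for (a in add) {
    row1 <- matrix(NA_character_, 1, length(vm$accessions),
                   dimnames = list(NULL, vm$accessions))
    row2 <- row1
    row1[1, g1] <- a$x; row2[1, g1] <- a$x
    row1[1, g2] <- a$y; row2[1, g2] <- a$y
    ins <- findInterval(a$pos, vm$pos)
    idx_before <- seq_len(ins)
    idx_after <- if (ins < n_sites(vm)) (ins + 1L):n_sites(vm) else integer(0)
    splice <- function(v, x) c(v[idx_before], x, v[idx_after])
    vm2 <- variant_matrix(
      chrom = splice(vm$chrom, a$chrom), pos = splice(vm$pos, a$pos),
      ref = splice(vm$ref, a$x),
      a1 = rbind(vm$a1[idx_before, , drop = FALSE], row1,
                 vm$a1[idx_after, , drop = FALSE]),
      a2 = rbind(vm$a2[idx_before, , drop = FALSE], row2,
                 vm$a2[idx_after, , drop = FALSE]),
      accessions = vm$accessions,
      class = splice(vm$class, "nonsynonymous"),
      gene = splice(vm$gene, a$gene))
    attr(vm2, "truth") <- attr(vm, "truth")
    attr(vm2, "gene_coords") <- attr(vm, "gene_coords")
    vm <- vm2
  }
  truth <- data.frame(gene = vapply(add, `[[`, "", "gene"),
                      chrom = vapply(add, `[[`, "", "chrom"),
                      pos = vapply(add, function(a) a$pos, numeric(1)),
                      allele_group1 = vapply(add, `[[`, "", "x"),
                      allele_group2 = vapply(add, `[[`, "", "y"),
                      group1 = labs[1], group2 = labs[2])
  list(matrix = vm, truth = truth)
}

# violations of the "not congruent with a clade" requirement; character(0)
# when the partition is phylogenetically incongruent as required
partition_clade_congruence <- function(partition, sst) {
  labs <- unique(unname(partition))
  out <- character(0)
  sp_of <- sst$accessions[names(partition)]
  for (lab in labs) {
    accs <- names(partition)[partition == lab]
    sps <- unique(unname(sp_of[accs]))
    other_sps <- unique(unname(sp_of[setdiff(names(partition), accs)]))
    if (length(intersect(sps, other_sps))) next  # a species is split: fine
    full <- all(vapply(sps, function(s) {
      members <- names(sst$accessions)[sst$accessions == s]
      all(members %in% accs | !members %in% names(partition))
    }, logical(1)))
    if (!full) next
    if (length(sps) == 1L || ape::is.monophyletic(sst$tree, sps))
      out <- c(out, sprintf("group '%s' equals clade {%s}", lab,
                            paste(sps, collapse = ",")))
  }
  out
}
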