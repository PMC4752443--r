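#' Select the representative accession per species for one gene
#'
#' To maximise the alignment tested, only the accession with the most
#' aligned codons is retained per ingroup species (ties broken by
#' lexicographically first accession id), and likewise one outgroup
#' accession.  A species with no covered accession makes the gene
#' untestable.
#'
#' @param coverage named numeric vector: aligned-codon count per
#'   accession for this gene (`NA` or 0 = no data).
#' @param species named character vector accession -> species.
#' @param outgroup character vector of outgroup accession ids.
#' @return list: `representatives` (data.frame species, accession,
#'   codons), `outgroup_accession`, `testable` (logical), `reason`.
#' @export
select_representatives <- function(coverage, species, outgroup) {
  ingroup_acc <- setdiff(names(coverage), outgroup)
  pick <- function(accs) {
    cov <- coverage[accs]
    cov[is.na(cov)] <- 0
    if (all(cov == 0)) return(NULL)
    best <- accs[cov == max(cov)]
    sort(best)[1]
  }
  sps <- unique(unname(species[ingroup_acc]))
  rows <- lapply(sps, function(sp) {
    accs <- ingroup_acc[species[ingroup_acc] == sp]
    a <- pick(accs)
    if (is.null(a)) return(data.frame(species = sp,
                                      accession = NA_character_,
                                      codons = 0))
    data.frame(species = sp, accession = a, codons = unname(coverage[a]))
  })
  reps <- do.call(rbind, rows)
  og <- pick(intersect(outgroup, names(coverage)))
  missing_sp <- reps$species[is.na(reps$accession)]
  testable <- length(missing_sp) == 0 && !is.null(og)
  list(representatives = reps, outgroup_accession = og %||% NA_character_,
       testable = testable,
       reason = if (testable) NA_character_
                else if (length(missing_sp))
                  sprintf("no data for species %s",
                          paste(missing_sp, collapse = ","))
                else "no outgroup data")
}

#' Aligned-codon coverage of a gene per accession
#'
#' A codon counts as aligned for an accession when the accession has
#' data at every variant site falling inside the codon (codons with no
#' variant site count as aligned, matching a reference-anchored
#' alignment).
#'
#' @param h a `haploid_matrix`.
#' @param model a [gene_model()].
#' @return named integer vector of aligned-codon counts per accession.
#' @export
codon_coverage <- function(h, model) {
  n_codons <- (model$cds_length - model$frame) %/% 3L
  in_gene <- h$chrom == model$chrom &
    !is.na(vapply(h$pos, function(p) cds_offset(model, p), integer(1)))
  sites <- which(in_gene)
  codon_of <- vapply(h$pos[sites], function(p) {
    off <- cds_offset(model, p) - model$frame
    if (off < 0) NA_integer_ else off %/% 3L
  }, integer(1))
  out <- stats::setNames(rep(n_codons, length(h$accessions)), h$accessions)
  if (!length(sites)) return(out)
  for (a in h$accessions) {
    bad <- unique(codon_of[is.na(h$h[sites, a])])
    out[a] <- n_codons - length(stats::na.omit(bad))
  }
  out
}

#' Unambiguous clade-diagnostic substitutions in one gene
#'
#' A site is counted as a lineage-specific substitution for the target
#' clade only when the allele set sampled from the target accessions
#' and the allele set sampled from all other accessions (outgroup
#' included in the nontarget side) are completely nonoverlapping;
#' polymorphism within either side is allowed provided the two sets
#' stay disjoint.  Sites are only considered when at least one allele
#' is available for each ingroup species and for at least one outgroup
#' accession.  Each qualifying site is classified synonymous or
#' nonsynonymous from the codon change.
#'
#' @param h a `haploid_matrix`.
#' @param model a [gene_model()] for the gene.
#' @param cds_sequence spliced coding sequence (see
#'   [classify_substitution()]).
#' @param target character vector: target-clade accession ids.
#' @param species named character vector accession -> species (ingroup
#'   accessions).
#' @param outgroup character vector of outgroup accession ids.
#' @return a `clade_substitution_record`: list with `gene`, `n_nonsyn`,
#'   `n_syn`, and `sites` (data.frame of position, class, amino acids,
#'   allele sets).
#' @export
clade_diagnostic_sites <- function(h, model, cds_sequence, target,
                                   species, outgroup) {
  ingroup_acc <- names(species)
  nontarget <- setdiff(c(ingroup_acc, outgroup), target)
  sites <- which(h$chrom == model$chrom)
  recs <- list()
  for (i in sites) {
    off <- cds_offset(model, h$pos[i])
    if (is.na(off)) next
    by_sp <- vapply(unique(unname(species)), function(sp) {
      accs <- ingroup_acc[species[ingroup_acc] == sp]
      any(!is.na(h$h[i, accs]))
    }, logical(1))
    if (!all(by_sp)) next
    if (!any(!is.na(h$h[i, outgroup]))) next
    tgt <- unique(stats::na.omit(h$h[i, target]))
    oth <- unique(stats::na.omit(h$h[i, nontarget]))
    if (!length(tgt) || length(intersect(tgt, oth))) next
    cls <- classify_substitution(model, cds_sequence, h$pos[i],
                                 tgt[1], oth[1])
    if (is.na(cls) || cls == "noncoding") next
    # any cross pair changing the protein marks the site nonsynonymous
    if (cls == "synonymous" && (length(tgt) > 1 || length(oth) > 1)) {
      pairs <- expand.grid(tgt, oth, stringsAsFactors = FALSE)
      any_ns <- any(apply(pairs, 1, function(p)
        identical(classify_substitution(model, cds_sequence, h$pos[i],
                                        p[1], p[2]), "nonsynonymous")))
      if (any_ns) cls <- "nonsynonymous"
    }
    aa <- substitution_aa(model, cds_sequence, h$pos[i], tgt[1], oth[1])
    recs[[length(recs) + 1L]] <- data.frame(
      pos = h$pos[i], class = cls,
      aa_target = aa[1], aa_other = aa[2],
      target_alleles = paste(sort(tgt), collapse = "/"),
      other_alleles = paste(sort(oth), collapse = "/"))
  }
  sites_df <- if (length(recs)) do.call(rbind, recs)
              else data.frame(pos = integer(0), class = character(0),
                              aa_target = character(0),
                              aa_other = character(0),
                              target_alleles = character(0),
                              other_alleles = character(0))
  structure(list(gene = model$gene_id,
                 n_nonsyn = sum(sites_df$class == "nonsynonymous"),
                 n_syn = sum(sites_df$class == "synonymous"),
                 sites = sites_df),
            class = "clade_substitution_record")
}

#' Monophyly eligibility of a target clade in a gene tree
#'
#' A gene is testable for a target group only if the gene tree contains
#' a branch ancestral to all of the group's accessions, i.e. the group
#' is monophyletic in the outgroup-rooted gene tree.  With rampant ILS
#' this branch is frequently absent, which is exactly why eligibility
#' must be verified per gene.
#'
#' @param tree a `phylo` gene tree.
#' @param target character vector of target accession tips.
#' @param outgroup tip(s) used to root the tree (optional when the tree
#'   is already rooted).
#' @return list: `eligible` (logical), `reason` (`NA` when eligible).
#' @export
monophyly_eligibility <- function(tree, target, outgroup = NULL) {
  missing <- setdiff(c(target, outgroup), tree$tip.label)
  if (length(missing))
    return(list(eligible = FALSE,
                reason = sprintf("missing taxa: %s",
                                 paste(missing, collapse = ","))))
  if (!is.null(outgroup))
    tree <- ape::root(tree, outgroup, resolve.root = TRUE)
  ok <- ape::is.monophyletic(tree, target)
  list(eligible = ok,
       reason = if (ok) NA_character_ else "target clade not monophyletic")
}

#' Positive-selection proportion and FDR arithmetic
#'
#' Summarises per-gene branch-site test p-values for one target clade:
#' the proportion of testable genes significant at `alpha` and the
#' implied false discovery rate `FDR = (alpha x n_tested) /
#' n_significant` (undefined when nothing is significant).
#'
#' @param p_values numeric vector of per-gene p-values (`NA`s dropped).
#' @param alpha significance level (default 0.01).
#' @return list: `n_tested`, `n_significant`, `proportion`, `fdr`,
#'   `alpha`.
#' @export
significance_summary <- function(p_values, alpha = 0.01) {
  p <- p_values[!is.na(p_values)]
  if (any(p < 0 | p > 1)) stopf("p-values must be in [0,1]")
  n <- length(p)
  k <- sum(p < alpha)
  list(n_tested = n, n_significant = k,
       proportion = if (n > 0) k / n else NA_real_,
       fdr = if (k > 0) alpha * n / k else NA_real_,
       alpha = alpha)
}

#' Binomial excess-nonsynonymous test (not the branch-site LRT)
#'
#' A simple built-in alternative when external branch-site likelihood
#' ratio p-values are unavailable: tests whether the observed
#' nonsynonymous share of a gene's clade-diagnostic substitutions
#' exceeds the gene's nonsynonymous opportunity ratio.  This is a
#' cruder screen than a codon-model LRT and is labelled as such.
#'
#' @param n_nonsyn,n_syn diagnostic substitution counts.
#' @param opportunity_ratio expected nonsynonymous fraction under
#'   neutrality (nonsynonymous sites / total sites; ~0.75 for a typical
#'   codon composition).
#' @return p-value of the one-sided exact binomial test.
#' @export
excess_nonsyn_test <- function(n_nonsyn, n_syn, opportunity_ratio = 0.75) {
  tot <- n_nonsyn + n_syn
  if (tot == 0) return(NA_real_)
  stats::binom.test(n_nonsyn, tot, opportunity_ratio,
                    alternative = "greater")$p.value
}
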