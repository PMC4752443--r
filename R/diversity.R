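#' Per-accession heterozygosity
#'
#' H = heterozygous sites / assayed sites, computed per accession over
#' the sites where that accession has data.  An accession with no
#' assayed sites gets `NA`, not 0.
#'
#' @param vm a `variant_matrix` (the high-depth filtered set is the
#'   recommended input).
#' @return data.frame: `accession`, `n_assayed`, `n_het`, `H`.
#' @export
heterozygosity <- function(vm) {
  has <- !is.na(vm$a1)
  het <- has & (vm$a1 != vm$a2)
  n_assayed <- colSums(has)
  n_het <- colSums(het)
  data.frame(accession = vm$accessions, n_assayed = n_assayed,
             n_het = n_het,
             H = ifelse(n_assayed > 0, n_het / n_assayed, NA_real_),
             row.names = NULL)
}

#' Proportion of heterozygous sites sorting in other species
#'
#' For each accession, the fraction of its heterozygous sites at which
#' both alleles of the pair are also observed outside its own species
#' (as polymorphism or fixed differences).  Roughly constant shared
#' proportions across accessions, against widely varying H, indicate
#' that heterozygosity is dominated by sorting ancestral variation
#' rather than accession-specific mutation.
#'
#' @param vm a `variant_matrix`.
#' @param species named character vector accession -> species.
#' @param strict if TRUE both alleles must segregate within a single
#'   other species; default: anywhere outside the focal species.
#' @param denominator `"observed"` restricts to het sites with at least
#'   one non-focal observation (default); `"all"` uses every het site.
#' @return data.frame: `accession`, `n_het_considered`, `n_shared`,
#'   `shared_prop`.
#' @export
shared_het_profile <- function(vm, species, strict = FALSE,
                               denominator = c("observed", "all")) {
  denominator <- match.arg(denominator)
  if (length(unique(species[vm$accessions])) < 2L)
    stopf("at least two species are required")
  res <- lapply(vm$accessions, function(acc) {
    foc_sp <- species[[acc]]
    others <- vm$accessions[species[vm$accessions] != foc_sp]
    het_sites <- which(!is.na(vm$a1[, acc]) & vm$a1[, acc] != vm$a2[, acc])
    n_cons <- 0L; n_shared <- 0L
    for (i in het_sites) {
      pair <- c(vm$a1[i, acc], vm$a2[i, acc])
      obs <- c(vm$a1[i, others], vm$a2[i, others])
      if (denominator == "observed" && all(is.na(obs))) next
      n_cons <- n_cons + 1L
      shared <- if (strict) {
        any(vapply(unique(species[others]), function(sp) {
          o <- others[species[others] == sp]
          all(pair %in% c(vm$a1[i, o], vm$a2[i, o]))
        }, logical(1)))
      } else all(pair %in% obs)
      if (shared) n_shared <- n_shared + 1L
    }
    data.frame(accession = acc, n_het_considered = n_cons,
               n_shared = n_shared,
               shared_prop = if (n_cons > 0) n_shared / n_cons else NA_real_)
  })
  do.call(rbind, res)
}

#' Group-specific allele sharing of a focal accession
#'
#' For each group, the proportion of the focal accession's heterozygous
#' sites that carry at least one allele which is otherwise specific to
#' that group (observed in the group, absent everywhere else, focal
#' accession excluded throughout).  High proportions for two groups
#' diagnose a recent hybrid between them.
#'
#' @param vm a `variant_matrix`.
#' @param focal focal accession id.
#' @param groups named character vector accession -> group label.
#' @return named numeric vector of per-group proportions (attribute
#'   `n_het` = focal het-site count); all `NA` when the focal accession
#'   has no heterozygous sites.
#' @export
group_specific_allele_share <- function(vm, focal, groups) {
  stopifnot(focal %in% vm$accessions)
  others <- setdiff(vm$accessions, focal)
  others <- others[others %in% names(groups)]
  labs <- unique(unname(groups[others]))
  het_sites <- which(!is.na(vm$a1[, focal]) & vm$a1[, focal] != vm$a2[, focal])
  counts <- stats::setNames(numeric(length(labs)), labs)
  if (!length(het_sites)) {
    out <- stats::setNames(rep(NA_real_, length(labs)), labs)
    attr(out, "n_het") <- 0L
    return(out)
  }
  for (i in het_sites) {
    pair <- unique(c(vm$a1[i, focal], vm$a2[i, focal]))
    allele_groups <- lapply(labs, function(g) {
      o <- others[groups[others] == g]
      unique(stats::na.omit(c(vm$a1[i, o], vm$a2[i, o])))
    })
    names(allele_groups) <- labs
    for (g in labs) {
      rest <- unique(unlist(allele_groups[setdiff(labs, g)]))
      spec <- setdiff(allele_groups[[g]], rest)
      if (any(pair %in% spec)) counts[g] <- counts[g] + 1
    }
  }
  out <- counts / length(het_sites)
  attr(out, "n_het") <- length(het_sites)
  out
}

#' Pairwise sequence distance between accessions
#'
#' d(i, j) = mismatching sites / jointly non-missing sites of a
#' haploid-resolved matrix; symmetric with zero diagonal; a pair with no
#' joint coverage gets `NA`.
#'
#' @param h a `haploid_matrix`.
#' @return numeric accession x accession matrix.
#' @export
pairwise_distance <- function(h) {
  stopifnot(inherits(h, "haploid_matrix"))
  m <- length(h$accessions)
  d <- matrix(0, m, m, dimnames = list(h$accessions, h$accessions))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j <= i) next
      joint <- !is.na(h$h[, i]) & !is.na(h$h[, j])
      n <- sum(joint)
      d[i, j] <- d[j, i] <- if (n == 0) NA_real_
                            else sum(h$h[joint, i] != h$h[joint, j]) / n
    }
  }
  d
}
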