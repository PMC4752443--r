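# Five-taxon D_FOIL system for polarized site patterns on the symmetric
# quintet (((P1,P2),(P3,P4)),O) with the (P1,P2) divergence more recent
# than the (P3,P4) divergence.
#
# Patterns are written P1 P2 P3 P4 O with A = outgroup (ancestral) state
# and B = derived.  Each component statistic contrasts a "left" and
# "right" pattern set whose members are exchanged by swapping the taxa
# within one cherry, so every component has expectation zero under
# ILS-only evolution regardless of divergence times:
#
#   DFO = (BABAA + BBBAA) - (BAABA + BBABA)   P1-side affinity: P3 vs P4
#   DIL = (ABBAA + BBBAA) - (ABABA + BBABA)   P2-side affinity: P3 vs P4
#   DFI = (BABAA + BABBA) - (ABBAA + ABBBA)   P3-side affinity: P1 vs P2
#   DOL = (BAABA + BABBA) - (ABABA + ABBBA)   P4-side affinity: P1 vs P2
#
# The triple-derived patterns carry the direction signal: a lineage
# introgressed INTO the (P1,P2) side attaches inside the (P3,P4) clade
# and can ride its ancestral stem (BABBA/ABBBA), whereas a lineage
# introgressed INTO the (P3,P4) side rides the (P1,P2) ancestral stem
# (BBBAA/BBABA).  The joint sign signature of the four components over
# the introgression scenarios is therefore unique per donor->recipient
# pair, ancestral exchanges give the two-zero signatures, and
# ILS/no-flow gives all zeros.

.dfoil_patterns <- c("AAAAA", "AAABA", "AABAA", "AABBA",
                     "ABAAA", "ABABA", "ABBAA", "ABBBA",
                     "BAAAA", "BAABA", "BABAA", "BABBA",
                     "BBAAA", "BBABA", "BBBAA", "BBBBA")

.dfoil_components <- list(
  DFO = list(L = c("BABAA", "BBBAA"), R = c("BAABA", "BBABA")),
  DIL = list(L = c("ABBAA", "BBBAA"), R = c("ABABA", "BBABA")),
  DFI = list(L = c("BABAA", "BABBA"), R = c("ABBAA", "ABBBA")),
  DOL = list(L = c("BAABA", "BABBA"), R = c("ABABA", "ABBBA")))

# rows: expected component signs per introgression scenario
# (+1 / -1 must be significant with that sign; 0 must be non-significant)
.dfoil_signatures <- data.frame(
  direction = c("P3=>P1", "P4=>P1", "P3=>P2", "P4=>P2",
                "P1=>P3", "P2=>P3", "P1=>P4", "P2=>P4",
                "anc(P1,P2)<=>P3", "anc(P1,P2)<=>P4"),
  DFO = c(+1, -1,  0,  0, +1, +1, -1, -1, +1, -1),
  DIL = c( 0,  0, +1, -1, +1, +1, -1, -1, +1, -1),
  DFI = c(+1, +1, -1, -1, +1, -1,  0,  0,  0,  0),
  DOL = c(+1, +1, -1, -1,  0,  0, +1, -1,  0,  0))

#' Count polarized five-taxon site patterns
#'
#' @param h a `haploid_matrix`.
#' @param p1,p2,p3,p4,outgroup accession ids of the symmetric quintet.
#' @param windows optional data.frame from [partition_windows()].
#' @return matrix of counts (windows or 1 row) x 16 pattern columns.
#' @export
dfoil_patterns <- function(h, p1, p2, p3, p4, outgroup, windows = NULL) {
  cols <- c(p1, p2, p3, p4, outgroup)
  missing <- setdiff(cols, h$accessions)
  if (length(missing)) stopf("accessions not in matrix: %s",
                             paste(missing, collapse = ","))
  x <- h$h[, cols, drop = FALSE]
  ok <- rowSums(is.na(x)) == 0 & site_allele_count(h) == 2L
  o <- x[, 5L]
  bits <- (x[, 1L] != o) * 8L + (x[, 2L] != o) * 4L +
    (x[, 3L] != o) * 2L + (x[, 4L] != o) * 1L
  bits[!ok] <- NA
  wi <- if (is.null(windows)) rep(1L, length(bits))
        else window_index(h, windows)
  nw <- if (is.null(windows)) 1L else nrow(windows)
  counts <- matrix(0L, nw, 16L,
                   dimnames = list(NULL, .dfoil_patterns))
  keep <- !is.na(bits) & !is.na(wi)
  if (any(keep)) {
    tab <- table(factor(wi[keep], levels = seq_len(nw)),
                 factor(bits[keep], levels = 0:15))
    counts[] <- as.integer(tab)
  }
  counts
}

#' D_FOIL statistics and introgression direction calls
#'
#' Computes the four component statistics per window from five-taxon
#' polarized site-pattern counts, tests each against its ILS
#' expectation of zero (two-sided exact binomial test of the left-set
#' count among left+right), and matches the joint sign signature to a
#' donor -> recipient direction.  A direction is called only when every
#' component behaves as its signature requires: nonzero components
#' significant (`p < p_threshold`) with the correct sign, zero
#' components non-significant.
#'
#' @param h a `haploid_matrix`.
#' @param p1,p2,p3,p4,outgroup the quintet; `((p1,p2),(p3,p4))` must be
#'   the species-tree topology with the (p1,p2) split the more recent.
#' @param windows optional data.frame from [partition_windows()]
#'   (omitted: one genome-wide row).
#' @param sst optional [sim_species_tree()] or accession-level `phylo`
#'   used to verify the symmetric quintet topology (an asymmetric
#'   quintet is refused).
#' @param p_threshold per-component significance threshold for the
#'   direction call (default 0.001).
#' @return data.frame per window: the four statistics, their p-values,
#'   `n_informative`, and `direction` (a donor/recipient label,
#'   `"none"`, or `"ambiguous"`).
#' @export
dfoil <- function(h, p1, p2, p3, p4, outgroup, windows = NULL, sst = NULL,
                  p_threshold = 0.001) {
  if (!is.null(sst)) check_symmetric_quintet(sst, p1, p2, p3, p4)
  counts <- dfoil_patterns(h, p1, p2, p3, p4, outgroup, windows)
  res <- dfoil_stats(counts)
  res$direction <- vapply(seq_len(nrow(res)), function(i)
    dfoil_direction(res[i, ], p_threshold), character(1))
  if (!is.null(windows)) res <- cbind(windows[, c("chrom", "start", "end")], res)
  res
}

#' Component statistics from a pattern-count matrix
#'
#' @param counts matrix from [dfoil_patterns()].
#' @return data.frame with columns `DFO`, `DIL`, `DFI`, `DOL`, their
#'   p-values `pFO` ... `pOL`, and `n_informative`.  A component with no
#'   informative counts is reported as 0 with p = 1 (no signal).
#' @export
dfoil_stats <- function(counts) {
  out <- data.frame(row.names = seq_len(nrow(counts)))
  informative <- unique(unlist(lapply(.dfoil_components, unlist)))
  for (nm in names(.dfoil_components)) {
    L <- rowSums(counts[, .dfoil_components[[nm]]$L, drop = FALSE])
    R <- rowSums(counts[, .dfoil_components[[nm]]$R, drop = FALSE])
    tot <- L + R
    D <- ifelse(tot > 0, (L - R) / tot, 0)
    p <- mapply(function(l, t) if (t == 0) 1
                else stats::binom.test(l, t, 0.5)$p.value, L, tot)
    out[[nm]] <- D
    out[[sub("D", "p", nm)]] <- p
  }
  out$n_informative <- rowSums(counts[, informative, drop = FALSE])
  out
}

dfoil_direction <- function(row, p_threshold) {
  comp <- c("DFO", "DIL", "DFI", "DOL")
  pval <- as.numeric(row[c("pFO", "pIL", "pFI", "pOL")])
  val <- as.numeric(row[comp])
  sig <- pval < p_threshold
  if (!any(sig)) return("none")
  for (r in seq_len(nrow(.dfoil_signatures))) {
    want <- as.numeric(.dfoil_signatures[r, comp])
    okay <- all(ifelse(want == 0, !sig, sig & sign(val) == want))
    if (okay) return(.dfoil_signatures$direction[r])
  }
  "ambiguous"
}

check_symmetric_quintet <- function(sst, p1, p2, p3, p4) {
  tr <- accession_tree(sst)
  need <- c(p1, p2, p3, p4)
  missing <- setdiff(need, tr$tip.label)
  if (length(missing)) stopf("quintet taxa absent from tree: %s",
                             paste(missing, collapse = ","))
  tr4 <- ape::keep.tip(tr, need)
  depth <- ape::node.depth.edgelength(tr4)
  mrca <- ape::mrca(tr4)
  i <- function(a) match(a, tr4$tip.label)
  d12 <- depth[mrca[i(p1), i(p2)]]
  d34 <- depth[mrca[i(p3), i(p4)]]
  d13 <- depth[mrca[i(p1), i(p3)]]
  if (!(d12 > d13 && d34 > d13))
    stopf("((%s,%s),(%s,%s)) is not the symmetric quintet topology",
          p1, p2, p3, p4)
  root_age <- max(depth) - depth
  if (root_age[mrca[i(p1), i(p2)]] > root_age[mrca[i(p3), i(p4)]] + 1e-9)
    stopf("the (P1,P2) divergence must be more recent than (P3,P4); swap the pairs")
  invisible(TRUE)
}
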