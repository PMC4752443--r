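#' Gene model for codon classification
#'
#' A minimal protein-coding gene model: ordered coding intervals on a
#' chromosome (0-based half-open, in genomic order), a strand, and a
#' reading-frame offset.  The spliced coding length minus the frame
#' offset must be divisible by 3.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param intervals two-column matrix (start, end) of coding intervals,
#'   0-based half-open, sorted by genomic start.
#' @param frame reading-frame offset (0, 1 or 2) applied at the 5' end
#'   of the spliced transcript.
#' @return a `gene_model` object.
#' @export
gene_model <- function(gene_id, chrom, strand = "+", intervals, frame = 0L) {
  intervals <- matrix(as.integer(intervals), ncol = 2)
  if (any(intervals[, 2] <= intervals[, 1]))
    stopf("empty or inverted coding interval in gene %s", gene_id)
  if (is.unsorted(intervals[, 1]))
    stopf("coding intervals of %s must be sorted by start", gene_id)
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  len <- sum(intervals[, 2] - intervals[, 1])
  if ((len - frame) %% 3 != 0)
    stopf("coding length %d minus frame %d of %s is not divisible by 3",
          len, frame, gene_id)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 intervals = intervals, frame = as.integer(frame),
                 cds_length = len),
            class = "gene_model")
}

#' Map a genomic position to a spliced CDS offset
#'
#' @param model a [gene_model()].
#' @param gpos genomic position (0-based).
#' @return 0-based offset within the spliced CDS in transcription
#'   direction (frame not yet subtracted), or `NA` if `gpos` falls
#'   outside the coding intervals.
#' @export
cds_offset <- function(model, gpos) {
  iv <- model$intervals
  off <- NA_integer_
  cum <- 0L
  for (k in seq_len(nrow(iv))) {
    if (gpos >= iv[k, 1] && gpos < iv[k, 2]) {
      off <- cum + (gpos - iv[k, 1])
      break
    }
    cum <- cum + (iv[k, 2] - iv[k, 1])
  }
  if (is.na(off)) return(NA_integer_)
  if (model$strand == "-") off <- model$cds_length - 1L - off
  off
}

#' Classify a nucleotide substitution as synonymous or nonsynonymous
#'
#' Translates the two codons that differ only at the focal site under
#' the standard genetic code; a change of amino acid marks the
#' substitution nonsynonymous.  Sites outside the coding intervals are
#' `"noncoding"`.  For minus-strand models the supplied alleles (given
#' on the plus strand) are complemented before translation.  The
#' classification is symmetric in the two alleles.
#'
#' @param model a [gene_model()].
#' @param cds_sequence character scalar or vector: the spliced coding
#'   sequence of the gene, 5'->3' in transcription direction (frame
#'   offset already relative to its first base).
#' @param site_offset genomic position of the site (0-based).
#' @param allele_a,allele_b the two alleles, plus-strand orientation.
#' @return `"synonymous"`, `"nonsynonymous"`, `"noncoding"`, or `NA`
#'   when the codon context is incomplete (missing or ambiguous bases).
#' @export
classify_substitution <- function(model, cds_sequence, site_offset,
                                  allele_a, allele_b) {
  off <- cds_offset(model, site_offset)
  if (is.na(off)) return("noncoding")
  off <- off - model$frame
  if (off < 0) return(NA_character_)
  cds <- if (length(cds_sequence) == 1L)
    strsplit(toupper(cds_sequence), "")[[1]]
  else toupper(cds_sequence)
  codon_i <- off %/% 3L
  codon_pos <- off %% 3L
  idx <- model$frame + codon_i * 3L + 0:2
  if (max(idx) + 1L > length(cds)) return(NA_character_)
  codon <- cds[idx + 1L]
  if (model$strand == "-") {
    allele_a <- complement(allele_a)
    allele_b <- complement(allele_b)
  }
  ca <- cb <- codon
  ca[codon_pos + 1L] <- toupper(allele_a)
  cb[codon_pos + 1L] <- toupper(allele_b)
  if (any(!c(ca, cb) %in% c("A", "C", "G", "T"))) return(NA_character_)
  aa <- seqinr::translate(ca)
  ab <- seqinr::translate(cb)
  if (identical(aa, ab)) "synonymous" else "nonsynonymous"
}

#' Amino acids encoded by a substitution's two codons
#'
#' Companion to [classify_substitution()] for reporting the amino-acid
#' change at a coding site.
#'
#' @inheritParams classify_substitution
#' @return character vector `c(aa_a, aa_b)`, or `NA`s when unavailable.
#' @export
substitution_aa <- function(model, cds_sequence, site_offset,
                            allele_a, allele_b) {
  off <- cds_offset(model, site_offset)
  if (is.na(off)) return(c(NA_character_, NA_character_))
  off <- off - model$frame
  if (off < 0) return(c(NA_character_, NA_character_))
  cds <- if (length(cds_sequence) == 1L)
    strsplit(toupper(cds_sequence), "")[[1]]
  else toupper(cds_sequence)
  codon_i <- off %/% 3L; codon_pos <- off %% 3L
  idx <- model$frame + codon_i * 3L + 0:2
  if (max(idx) + 1L > length(cds)) return(c(NA_character_, NA_character_))
  codon <- cds[idx + 1L]
  if (model$strand == "-") {
    allele_a <- complement(allele_a); allele_b <- complement(allele_b)
  }
  ca <- cb <- codon
  ca[codon_pos + 1L] <- toupper(allele_a)
  cb[codon_pos + 1L] <- toupper(allele_b)
  if (any(!c(ca, cb) %in% c("A", "C", "G", "T")))
    return(c(NA_character_, NA_character_))
  c(seqinr::translate(ca), seqinr::translate(cb))
}
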