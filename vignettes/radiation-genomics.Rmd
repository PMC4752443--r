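---
title: "Methods: introgression, lineage-specific substitution and environmental association in a rapid radiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: introgression, lineage-specific substitution and environmental association in a rapid radiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radscan)
```

## The problem

In a rapid species radiation, three processes generate adaptive
variation, and all three leave their mark as phylogenetic discordance:
incomplete lineage sorting (ILS) of ancestral polymorphism, post-speciation
introgression, and lineage-specific de novo substitution.  `radscan`
implements the analyses needed to separate them in a clade-wide
multisample variant matrix: windowed ABBA–BABA D-statistics with a block
bootstrap, the five-taxon D_FOIL direction system, gene-tree topology
counting, unambiguous clade-diagnostic substitution counting, and a
phylogenetic genome-wide environmental association scan ("PhyloGWAS")
judged against a multispecies-coalescent null.  A structured-coalescent
simulator supplies synthetic datasets with known truth tables, which is
how every method here is validated.

## Data model and conventions

The central container is the `variant_matrix`: sites × accessions, one
unordered diploid allele pair per cell, with optional per-site
synonymous/nonsynonymous class and gene annotations.  Coordinates are
0-based half-open internally; every human-readable report prints 1-based
positions (the VCF display convention).  Genotypes are filtered by
preset profiles — `HQ` (depth ≥ 3, mapping quality ≥ 30) and `HD`
(depth ≥ 10, MQ ≥ 30) — with failing genotypes set missing and sites
below a data minimum dropped.  Multiallelic sites (more than two alleles
across accessions) stay in the matrix but are excluded from all
pattern-counting and association operations, the conservative reading
for methods defined on biallelic patterns.  Missing data is a dedicated
`NA` sentinel, never an ambiguity code.

Heterozygous genotypes enter haploid analyses through
`resolve_heterozygotes()`: one of the two alleles is chosen at random.
One global seeded stream is consumed in site-major, accession-minor
order, with one draw per cell whether or not the cell is heterozygous,
so the resolution is reproducible and insensitive to which cells happen
to be heterozygous.  Whether such a draw should be fixed once per
site-accession or redrawn per analysis is underdetermined; the global
stream (fix once per matrix/seed, reuse everywhere) is this package's
choice, and every function that consumes randomness takes an explicit
seed.

## The synthetic study system

`demo_species_tree()` is a nine-species ingroup in four major groups
plus an outgroup.  Node ages are in years and are converted to
coalescent units as `age × gen_per_year / (2 Ne)` with Ne = 1e5 diploids
and 2.5 generations per year — one coalescent unit is 80,000 years.  The
ingroup crown sits at 550 ky with backbone internodes of 100–180 ky
(1.25–2.25 coalescent units) and group crowns of 140–220 ky: a burst
radiation in the regime where ILS pervades gene trees, which is the
defining feature of the clade being emulated.  The outgroup splits at
2 My, deep enough to polarize site patterns reliably.

`simulate_gene_trees()` draws genealogies under the structured
coalescent: two lineages per diploid accession (one for haploid
sampling), within-branch coalescence at rate k(k−1)/2, populations
merging at speciation times.  By construction no inter-species
coalescence can predate the species split, and a test verifies this
invariant on every simulated set.  Introgression is a gene-level pulse:
with probability γ (optionally restricted to a contiguous gene block,
emulating a chromosomally localized recent transfer) all recipient-branch
lineages of that gene are rerouted into the donor branch at the event
time.  This matches the "fraction of the genome exchanged" framing of
pulse estimates, and the per-gene outcome is recorded in a truth table.

`simulate_variants()` places infinite-sites mutations on each genealogy
(branch chosen proportional to length), so derived-allele carriers are
exactly the leaves below the mutated branch and "derived" is
unambiguous.  Genes are laid on one synthetic chromosome at 10-kb
spacing so 100-kb windows hold ten genes.  Each site carries a
nonsynonymous/synonymous flag (default half and half) rather than a
realised codon; codon-level operations (`classify_substitution`,
`clade_diagnostic_sites`) instead take explicit gene models and coding
sequences.  Per-accession inbreeding coefficients collapse genotypes to
one lineage with probability F, reproducing the selfing/outcrossing
heterozygosity gradient of such clades.  What the generator does *not*
emulate: sequencing error, coverage variation along transcripts,
back-mutation, selection on the injected alleles, and recombination
within genes (each gene is one genealogy).  Passing tests therefore
demonstrate correctness of the inference machinery under the model the
methods themselves assume, not robustness to alignment artefacts.

`inject_environment_alleles()` overwrites sites where one accession
group is fixed for allele X and the other for allele Y — the *outcome*
of environment-driven differential fixation of ancestral variants, not
its dynamics — and refuses partitions congruent with a clade, since such
a contrast could never separate ecology from phylogeny.

## Introgression statistics

`enumerate_trios()` assigns P1, P2 (the sister pair of the induced
triplet) and P3 for every 3-subset of ingroup accessions using the
rooted guide tree; 27 accessions give choose(27,3) = 2,925 trios.
`count_patterns()` polarizes biallelic sites by the outgroup allele and
counts ABBA/BABA; D = (ABBA − BABA)/(ABBA + BABA).  Window significance
is a two-sided exact binomial test of the two counts — the standard
small-window choice; a chi-squared alternative sits behind a flag.  The
binomial treats sites as independent, which linked sites within a gene
are not; that is precisely why the transcriptome-wide judgement uses
`bootstrap_d()`, resampling whole windows with replacement (10,000
replicates) and asking whether the percentile 95% CI excludes zero.
`cladewide_summary()` counts windows passing |D| ≥ 0.2, p < 1e-4 and
|ABBA − BABA| ≥ 10 for at least one trio and divides by windows ×
branches queried; the branch list is user-supplied because the
denominator depends on which admixed taxa are excluded.

### The D_FOIL system

For a symmetric quintet (((P1,P2),(P3,P4)),O) with the (P1,P2) split
the more recent, sites are coded by which of P1–P4 carry the derived
(non-outgroup) allele.  Each component statistic contrasts a left and
right pattern set whose members map onto each other when the taxa
within one cherry are swapped, so every component has expectation zero
under ILS alone, at any divergence times:

| component | left          | right         | contrast            |
|-----------|---------------|---------------|---------------------|
| DFO       | BABAA + BBBAA | BAABA + BBABA | P1-side: P3 vs P4   |
| DIL       | ABBAA + BBBAA | ABABA + BBABA | P2-side: P3 vs P4   |
| DFI       | BABAA + BABBA | ABBAA + ABBBA | P3-side: P1 vs P2   |
| DOL       | BAABA + BABBA | ABABA + ABBBA | P4-side: P1 vs P2   |

The triple-derived patterns carry the direction signal.  A lineage
introgressed *into* the (P1,P2) side attaches within the (P3,P4) clade
and can ride its ancestral stem, inflating BABBA/ABBBA; a lineage
introgressed *into* the (P3,P4) side rides the (P1,P2) stem, inflating
BBBAA/BBABA.  The resulting joint sign signature is unique for each of
the eight directed recent scenarios; ancestral exchanges with the
(P1,P2) stem give the two-zero signatures (±, ±, 0, 0); ILS gives all
zeros.  The signature table was validated against an independent
coalescent implementation across all twelve scenarios before being
frozen into the package.  Per window, each component gets a two-sided
binomial p-value (left-set count among left + right); a direction is
called only when every component behaves as its signature requires —
nonzero components significant at p < 0.001 with the matching sign,
zero components non-significant.  Components with no informative counts
are reported as 0 with p = 1 ("no signal"), so empty windows are
`"none"`, never spurious calls.

`count_topologies()` classifies rooted triplet topologies of per-gene
trees; under ILS the two discordant classes are exchangeable, so
`introgressed_fraction()` estimates the exchanged proportion as the
absolute difference of their frequencies.  On pulse simulations with
γ ∈ {0.1, 0.3} over 5,000 genes this recovers γ within ±0.03 (the small
positive bias is the probability the rerouted lineage fails to coalesce
within the donor branch, under 1% in the test geometry).

## Clade-diagnostic substitutions

`clade_diagnostic_sites()` counts a substitution as lineage-specific
only when the target clade's sampled allele set and the allele set of
all other accessions (outgroup pooled with the nontarget side) are
completely nonoverlapping, and only at sites with at least one allele
per ingroup species and one outgroup accession.  Polymorphism on either
side is tolerated while the sets stay disjoint; if any cross-side codon
pair changes the amino acid the site is tabulated nonsynonymous.  This
deliberately trades power for unambiguity: no ancestral-state
reconstruction is attempted, because rampant ILS makes tree-based
placement unreliable.  `select_representatives()` keeps the
best-covered accession per species (ties: lexicographically first id),
`monophyly_eligibility()` requires the target branch to exist in the
outgroup-rooted gene tree, and `significance_summary()` performs the
proportion/FDR arithmetic (FDR = α·n_tested/n_significant, undefined at
zero significants; all values reported unrounded).  The branch-site
likelihood-ratio test itself is an external step whose per-gene
p-values this package ingests; `excess_nonsyn_test()` is a built-in
binomial screen against a nonsynonymous opportunity ratio, provided so
the pipeline runs end to end, and is *not* that codon-model test.

## PhyloGWAS

`scan_perfect_association()` reports sites where every contrasted
accession has data and the two environmental groups' allele sets are
disjoint; `n_variants_examined` counts all class-qualifying variable
sites with complete data (so "perfect" is never an artefact of
missingness).  The null asks how often ILS alone produces such a
perfect association: `estimate_null_probability()` simulates
single-variable-site genes — one haploid lineage per contrasted
accession, one mutation placed branch-proportionally — and measures the
probability q that the derived-carrier set equals the partition (either
polarity).  A Rao-Blackwellised `"expected"` mode (matching branch-length
fraction per genealogy) gives the same expectation at lower Monte-Carlo
cost.  `dataset_pvalue()` then evaluates P[Binom(n, q) ≥ m], equivalent
to full dataset re-simulation under per-gene independence;
`resimulate_dataset_pvalue()` retains the expensive route as a
cross-check, and the two agree within Monte-Carlo error in the
acceptance suite.  The ≥ convention is the standard "at least as
extreme" p-value (observing zero hits can never be significant); a
strictly-greater variant sits behind the `exceedance` flag and differs
only on ties.  The desk-scale null uses 1e4–1e6 simulated genes rather
than 1e9; q is reported with its Monte-Carlo standard error so the
resolution limit is explicit.  Null genealogies sample one lineage per
accession and, by default, only the contrasted accessions' species —
both taxon-set choices are parameters.  `linked_synonymous_check()`
counts synonymous variants in hit genes that also track the partition:
a localized block of associated variants regardless of coding effect is
the signature of introgression rather than selection on a standing
nonsynonymous variant, and such genes are flagged ambiguous.

## Discordance profiling

Topologies are compared as unrooted, label-identical trees via
canonical bipartition-set keys (Robinson–Foulds distance zero means the
same class), so newick rotations and branch lengths never split a
class.  `bipartition_support()` uses exact containment — a polytomy
supports nothing it does not resolve — and
`branchlen_vs_concordance()` reports the Spearman correlation between
internal branch length and support, the ILS signature (short internodes
sort less).  The three-taxon law, support = 1 − (2/3)e^(−t) for an
internode of t coalescent units, anchors both the simulator and the
support machinery analytically.  `taxon_instability()` scores each
taxon by the mean (over partners) standard deviation (over trees) of
their topological nodal distance; the published instability index this
emulates is defined in software we do not re-implement, so the contract
here is rank agreement — a regrafted rogue taxon must rank first, and
identical trees must score zero — not absolute values.

## Numerical choices and problem sizes

Defaults follow the study conditions: Ne = 1e5, 2.5 generations/year,
10,000 bootstrap replicates, thresholds |D| ≥ 0.2 / p < 1e-4 /
|ABBA−BABA| ≥ 10, window minimum of 100 aligned sites, α = 0.01 for the
selection summaries, p < 0.001 per D_FOIL component, association α =
2.5e-4.  Zero-count statistics are reported as undefined (`NA`) for D —
never 0 — and as 0 with p = 1 for D_FOIL components, where "no signal"
and "balanced signal" lead to the same (non-)call.  Test and acceptance
simulations use 10,000 genes for the three-taxon analytic checks,
5,000 genes for pulse recovery, 2–3 × 1e4 single-site genes for the
hemiplasy null and 1,000–1,500 re-simulated datasets for the p-value
cross-check; these sizes put Monte-Carlo error well inside each
assertion's tolerance (stated as multiples of the binomial standard
error, never as free constants).

## Known limitations

Per-window binomial p-values inherit the site-independence assumption;
with ten genes per window a single tilted genealogy can push a small
window past the thresholds, which is why clade-wide counts are
descriptive and the bootstrap carries the genome-wide judgement.  The
introgressed-fraction estimator is slightly conservative when the donor
branch is short (failed donor-side coalescence).  D_FOIL requires the
symmetric quintet with the (P1,P2) split the more recent and refuses
anything else.  The simulator's variant classes are labels, not
realised codons, so end-to-end codon tests use explicit gene models.
Real-data features outside the generator's scope (sequencing error,
reference bias, within-gene recombination) are untested by construction.
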