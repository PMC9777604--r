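---
title: "Identifying and characterizing a plant nsLTP gene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and characterizing a plant nsLTP gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvltp)
```

## The problem

Plant non-specific lipid transfer proteins (nsLTPs) are small secreted
proteins that shuttle lipids and participate in stress responses. A family
member is recognized by two structural hallmarks: an N-terminal signal
peptide (the precursor is secreted; the mature protein is the precursor
minus the signal peptide) and, inside the mature protein, the
eight-cysteine motif (ECM)

```
C - X(s1) - C - X(s2) - CC - X(s3) - C X C - X(s4) - C - X(s5) - C
```

eight cysteines whose five variable inter-cysteine spacings `s1..s5`
distinguish the nsLTP types (I-XI). The C3C4 pair is adjacent and the
C5-X-C6 element carries exactly one spacer residue by definition, so a
motif occurrence is fully described by its five spacings plus its
flanking offsets.

`pvltp` implements the complete desk-side half of a genome-wide family
study: motif detection, type classification, the candidate filter
cascade, mature-protein physicochemistry, chromosome mapping with
tandem-duplicate detection, a light phylogeny, and expression
summarization. The wet/remote half — BLAST/HMMER homology searches,
signal-peptide *prediction*, RNA-seq processing — is deliberately out of
scope: those results enter as plain annotation tables.

## The spacing grammar

Classification is defined as joint spacing-set membership: a type admits
a spacing vector iff every component lies in that type's allowed set.
The shipped grammar covers the five types observed in the common bean
reference family:

```{r grammar}
str(default_grammar(), vec.len = 8)
```

The allowed sets are the union of the type-diversity ranges and the
values observed in the 58-gene reference table (for type II, `s4` takes
`{23, 26}` because the two sources disagree; the union validates both).
Joint disjointness is machine-checked, so assignment can never be
ambiguous:

```{r disjoint}
check_disjoint(default_grammar())$disjoint
```

Classifying the reference family's 58 published spacing strings
reproduces every published type label:

```{r classify}
tab <- load_family_table()
cls <- vapply(tab$ecm_string, function(s)
  classify_spacing(parse_ecm_string(s)), character(1), USE.NAMES = FALSE)
table(cls)
all(cls == tab$ltp_type)
```

Classification by residue similarity is a non-goal: spacing-set
membership is deterministic, auditable, and reproduces the reference
labels exactly.

## Motif scanning

`scan_ecm()` reports every window of eight cysteines in the
C/C/CC/CXC/C/C arrangement whose spacings fall inside per-spacing bounds
(default: the envelope of the grammar). By default spacer segments must
be cysteine-free — classical nsLTPs have exactly eight cysteines, and the
restriction removes combinatorial ambiguity; `allow_c_in_spacers = TRUE`
switches to exhaustive subset enumeration for exploratory scans. The
suite checks the scanner against a brute-force oracle that enumerates all
8-subsets of cysteine positions on short sequences.

## The filter cascade

`run_identification()` evaluates each protein in a fixed stage order,
recording for every input a trace naming the stage that rejected it:

1. redundancy collapse (identical residue strings keep the smallest id);
2. homology intake — optional, only when a hit table is supplied
   (E-value cutoff `1e-5`);
3. ECM scan + classification (on the cleaved mature region when a
   signal-peptide entry exists, else on the precursor);
4. signal-peptide requirement;
5. HyPRP exclusion: the source literature discards "hybrid proline-rich
   proteins" without defining them, so the package uses an operational
   rule — a pre-ECM region of at least 10 residues with proline fraction
   at or above 0.20 — with both knobs exposed in `pipeline_config()`;
6. an exclusion id-list hook for α-amylase-inhibitor / storage-protein
   screens (the screen itself is upstream);
7. mature length: "more than 120 residues" is strict — 120 passes, 121
   fails.

Accepted candidates are characterized from their gene models (CDS
length, intron count = CDS segments − 1, coordinates) and named
`<prefix><type>.<k>` within each type by chromosome (natural order) and
start position. Re-deriving names for the shuffled reference table
reproduces all 58 published names, which pins down the naming convention.

## Physicochemistry

Molecular weight is the sum of standard average residue masses plus one
water (18.0153 Da), matching the convention of the common web tools. The
theoretical pI is the root of the Henderson–Hasselbalch net-charge
function under the Bjellqvist pKa set (termini 7.50/3.55; side chains
D 4.05, E 4.45, C 9.00, Y 10.00, H 5.98, K 10.00, R 12.00), found by
bisection on [0, 14] to 0.005 pH — net charge is strictly decreasing in
pH, so the root is unique. Cysteines are treated as free thiols; the four
disulfide bonds of the folded scaffold are a documented simplification.
The tests verify the bisection against an independent 0.001-resolution
grid search.

The reference table prints MW/pI but not the underlying residues, so
those columns are consumed as data, never recomputed; the family summary
(`summarize_family()`) reproduces the published column statistics (mean
mature MW 9.82 kDa, mean pI 7.52, and the printed extremes) from the
fixture, with kDa and pI rounded half-up to two decimals to match the
table's precision.

```{r summary}
s <- summarize_family(tab)
s$stats[, c("mw_kda", "pi", "sp_len", "cds_length_bp")]
```

## Genome mapping and tandem clusters

Tandem-duplicate detection chains same-chromosome family members whose
intergenic gap (next start − previous end) stays at or below `max_gap`
(default 100 kb, a common operational definition), emitting maximal
chains of two or more genes; overlapping genes chain, and `same_type`
restricts chains to one type. The reference study reports 23 genes in 10
clusters on chromosomes 1 and 2, but that figure is inconsistent with its
own coordinate table (chromosome 2 holds a single family member) and is
not reproducible under any simple distance or gene-order rule we could
construct, so the detector is validated by its invariants — maximality,
order invariance, monotonicity in `max_gap` — and by planted synthetic
arrays, not by the printed counts.

## Phylogeny

Because the eight motif cysteines are homologous by definition,
alignment of ECM domains needs no heuristic aligner: each of the seven
variable segments (pre-C1, the five spacers, post-C8) is right-padded
with gaps to its per-segment maximum (`anchor_align()`), anchors land in
shared columns, and the result is exactly reproducible. Distances are
p-distances over gap-free columns; trees come from an in-house
Saitou–Nei neighbor joining with deterministic tie-breaking (smallest
index pair) and negative branch lengths clamped to zero with a warning.
On additive matrices NJ provably recovers the generating tree; the suite
verifies this on simulated 8-leaf trees and checks 4-taxon topologies
against the closed-form quartet criterion. Bootstrap support and
multi-species trees (which require external sequence sets) are out of
scope.

## Expression

`ddct_fold()` implements the Livak method: per-replicate
ΔCt = target − reference, ΔΔCt = mean treatment − mean control,
fold = 2^−ΔΔCt; error bars re-evaluate the fold at mean ± sd of the
treatment ΔCt. Technical replicates are averaged into their biological
replicate first (`average_technical()`), so n is the number of
biological replicates. Significance uses a two-sided Welch t-test on the
ΔCt replicates — the source figures mark p < 0.05 without naming a test,
and Welch is robust to unequal variances; the choice is documented and
swappable. Heatmap preparation applies log2(FPKM + 1) (pseudocount
exposed), optional row z-scoring (constant rows become zero with a
warning), and a deterministic complete-linkage row ordering in which the
subtree containing the smallest original row index always leads — this
reduces to input order for all-equal matrices, which a smallest-subtree
rule would not.

## Synthetic data and what passing means

Every generator is a pure function of (parameters, seed). Planted nsLTPs
follow the reference family's geometry: signal peptides 16–42 residues
(the published range) with hydrophobic-biased composition, spacings drawn
uniformly from the type's allowed sets, cysteine-free spacers from a
uniform background over the 19 non-C residues, mature regions at most
120 residues. Decoys violate exactly one rule each (no ECM, withheld
signal-peptide entry, ≥30 % proline pre-region, oversize mature region).
Gene models place genes in specified tandem arrays with 0–1 introns;
qPCR tables invert the Livak formula around planted folds with Gaussian
replicate noise; FPKM matrices plant organ programs over a log-normal
baseline.

The suite's problem sizes are deliberate desk-scale choices: proteomes of
up to 70 records over 20 seeds, 8-leaf trees over 20 seeds, 3 biological
replicates at 0.1-cycle noise. Passing them shows the machinery is
correct on sequences with exactly the planted structure — uniform
residue composition, single motifs, clean annotations. It does not show
robustness to the messiness of real proteomes (compositional bias,
truncated gene models, multiple motif-like regions), and the genome-scale
discovery itself is not reproducible offline; what is reproducible — every
statistic derivable from the printed 58-gene table — is asserted exactly.

## Numerical conventions

* Coordinates are 1-based inclusive everywhere public, as in GFF3.
* Primary transcript = id ending `.1`, else longest CDS, ties by
  smallest id.
* kDa and pI reporting rounds half-up to 2 decimals; the pI bisection
  tolerance is 0.005 pH; NJ branch-length recovery is asserted to 1e−9.
* The family-table integrity rules (`aa = cds/3 − 1`, `aa = sp + mp`)
  are checked and reported (`check_table_arithmetic()`), never silently
  fixed; the shipped table intentionally retains the one published
  arithmetic inconsistency.

## Known limitations

* MW/pI ignore disulfide bonds and post-translational modification.
* The HyPRP rule is operational, not a published definition.
* The tandem `max_gap` rule is one of several reasonable definitions;
  published cluster counts that depend on an opaque tool configuration
  are not reproduced.
* The anchored alignment assumes the motif cysteines are correctly
  identified; badly degenerate motifs should be excluded upstream.
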