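---
title: "Methods: comparative profiling of plant biomass-degrading metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative profiling of plant biomass-degrading metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hortus)
```

# The analysis this package implements

Communities that deconstruct plant biomass — herbivore gut microbiota,
compost, and the fungus gardens leaf-cutter ants cultivate as an external
digestive organ — are commonly characterised through four linked analyses:
top-hit taxonomic binning of assembled sequence, carbohydrate-active enzyme
(CAZyme) annotation of the predicted proteome, cross-metagenome clustering
of functional proportion profiles, and fragment recruitment of reads
against the genomes of candidate symbionts. `hortus` implements that chain
end-to-end at desk scale, together with a synthetic-community generator
that makes each step testable against known truth.

# Top-hit binning

Each query (contig, singleton, read or protein) is searched against a
labelled reference collection and the single best hit at
e-value ≤ `evalue_max` (default $10^{-5}$) decides its assignment. The
binning makes no attempt at lowest-common-ancestor reasoning: the
unclassified set is defined purely by the absence of a classified top hit,
so "Unknown" absorbs both no-hit queries and hits whose subject has no
resolvable taxonomy. Genus tables can be weighted by sequence count or by
nucleotides; for predicted proteins the weight is coding nucleotides,
$3 \cdot \mathrm{aa} + 3$ (three bases per residue plus the stop codon).
Rank ties are broken lexicographically by genus and flagged, since a
deterministic table is a prerequisite for regression testing. Rankings
produced by different methods (nucleotide-weighted, protein-weighted, or an
externally supplied composition-based binner's output) are compared over
the union of genera; genera absent from one method are reported as missing
rather than rank 0, and the concordance statistic is Spearman's rank
correlation over the shared genera.

# The search engine and its statistics

The built-in engine is a desk-scale stand-in for a production aligner:
k-mer seeding (default k = 11 nucleotide, k = 4 protein) locates candidate
subjects and diagonals, and Smith–Waterman local alignment
(`Biostrings::pairwiseAlignment`) restricted to a window around the seeded
diagonal produces the score, from which percent identity is computed as
matches over alignment columns. Scoring is match +1 / mismatch −1 with
affine gaps −2/−1 for nucleotide, and BLOSUM62 with gap open/extend 11/1
for protein. E-values use the standard extreme-value form
$E = m \, n \, 2^{-\mathrm{bit}}$ with nominal Karlin–Altschul-style
parameters ($\lambda = \ln 3$, $K = 1/3$ for the +1/−1 scheme;
$\lambda = 0.267$, $K = 0.041$ for BLOSUM62), where $n$ is the size of the
database actually indexed — so the $10^{-5}$ threshold scales with the
fixture rather than assuming a production-size database. Nucleotide
queries are searched on both strands, with minus-strand hits reported in
subject-descending coordinates. Ties on score resolve by lower e-value,
then lexicographically smallest subject id. Externally computed hits in
the standard 12-column tabular dialect can replace the engine wholesale
via `read_tabular_hits()`.

The engine does not attempt to reproduce any specific production tool's
scores bit-for-bit; its contract, enforced by tests, is that on pairs of
desk-scale sequences its alignment score equals a full dynamic-programming
(Gotoh) oracle's and that identity is exact for substitution-only pairs.

# Dual-evidence CAZyme annotation

A protein is annotated to family $F$ only when **both** evidence channels
accept it at the e-value threshold: a hit to one of $F$'s member proteins,
and a hit to $F$'s correlated protein-domain model. The channels are joined
through the family-to-domain correlation table, so member evidence for one
family plus domain evidence for a different, uncorrelated family is
rejected for both. Design decisions taken where the procedure is
underdetermined:

* Domain evidence is implemented as similarity search against domain
  consensus sequences. The contract that matters — an independent second
  evidence channel keyed by the correlation list — is preserved; profile
  scoring models would sharpen sensitivity but change nothing structural.
* A *module* is one (protein, family) pair. A protein hitting two members
  of the same family is one module (families are de-duplicated per
  protein); a protein with evidence for two families contributes two.
* For nucleotide input the evidence is gathered over all six translated
  frames (`annotate_cazy_translated()`); a hit in any frame counts for its
  channel, and the annotation is attributed to the contig. This makes the
  call frame-agnostic: a contig and its reverse complement annotate
  identically.

The naive ORF caller (`call_orfs()`) that feeds protein-level annotation
reports every ATG-to-nearest-in-frame-stop frame of at least
`min_orf_codons` codons (default 60, a typical bacterial floor), including
nested ORFs that share a stop. Reporting nested starts costs little at
desk scale and guarantees that a gene planted by the simulator is present
in the output at its exact coordinates regardless of upstream context; a
production gene finder would replace this component without touching the
annotation contract.

# Proportion profiles and UPGMA clustering

For each metagenome the annotated features (CAZy families or COG ids) are
reduced to proportions of the metagenome's annotated total, giving a
row-stochastic matrix over the union of observed features. Pairwise row
correlation gives similarity; distance is $d = 1 - r$ — the transform is
deliberately the simplest monotone choice, it is recorded in the output's
metadata, and triangle-inequality violations (possible since $1 - r$ is
not a metric) are logged, never rejected. Spearman is the default
correlation and Pearson is available as an explicit option; both are
legitimate readings of the procedure this package reproduces, which is
described with each at different points, so neither is asserted as
canonical and reports can carry both.

UPGMA is implemented directly rather than delegated, for one reason:
deterministic tie-breaking. Equal-distance merges take the
lexicographically smallest eligible pair (clusters ordered by their
smallest leaf label), and children are emitted in label order, so the
newick string is a canonical function of the distance matrix. Cluster
distances follow the unweighted average rule — the size-weighted
incremental update, equal to the mean of original pairwise distances
between member sets — and branch lengths are half the merge distance minus
the child's height, so trees are exactly ultrametric and cophenetic
distances reproduce merge heights. Tests verify exact agreement with a
brute-force mean-over-member-pairs oracle on 1,000 random matrices
($n \le 6$), with `stats::hclust(..., "average")` heights, and exact
cophenetic round-trips on ultrametric inputs. The tree is kept rooted
(UPGMA is inherently rooted); consumers may unroot downstream.

# Fragment recruitment

Draft-genome contigs are concatenated into a *pseudogenome* in ascending
length order by default — descending is available as an explicit option,
since both conventions appear in practice, and the choice is recorded on
the object. Offsets give an exact two-way map between global and
(contig, local) coordinates. Each read is recruited to its single best
genome across the whole database; reads with no accepted hit are excluded.
Identities are banded into half-open intervals $[lo, hi)$ with the topmost
band closed at 100, defaulting to five 5-point bands from 75 to 100;
identities below the lowest band are counted in an explicit below-range
bucket so band counts always sum to the recruited total. The strain-level
statistic is the fraction of recruited reads with identity strictly above
98 — strict because the cutoff is conventionally written ">98%". Reads
whose alignment spans a contig junction inside a pseudogenome are scored
against the concatenated sequence as-is and flagged, preserving
auditability without discarding data. Per-genome identity summaries (mean
± sample SD) are restricted to genomes with strictly more than
`min_reads` (default 100) recruited reads. GC tracks use 10 kb windows at
1 kb steps by default — smooth at draft-genome scale — and report deviation
from the genome-wide mean.

# What the synthetic generator emulates — and what it does not

`community_spec()` fixes the study conditions: genera with relative
abundances, genome lengths and GC fractions; per-genus strain divergence;
read length; and a per-base read error rate. Genomes are i.i.d. base
sequences at the requested GC; strains substitute each site independently
with probability δ, uniformly over the three alternatives; reads start
uniformly, come off either strand, and accrue i.i.d. substitution errors.
Mutation and error are substitution-only (an indel-free model) so that
identity is analytically predictable: an error-free read of length $L$
from a strain at divergence δ carries $\mathrm{Binomial}(L, \delta)$
mismatches, and the fraction of reads above 98 % identity has a closed
binomial-tail expectation that the tests use as an oracle. The generator
does **not** model repeats, homopolymer-error profiles of pyrosequencing,
plasmids, horizontal transfer, or compositional heterogeneity along a
genome; passing tests therefore demonstrate the correctness of the
statistics under the stated model, not robustness to those real-data
features. Every operation draws from its own RNG stream derived from the
seed plus a fixed per-operation offset, so adding a pipeline step never
perturbs the draws of later steps and fixed seeds give byte-identical
outputs.

Default divergences used in the recovery analyses are δ = 0.001 (a
same-strain scenario, >98 %-identity fraction near 1) and δ = 0.03 (a
related-species scenario, fraction near 0.13 for 250 bp reads) — values
chosen to straddle the 98 % cutoff decisively while remaining within the
range observed between bacterial strains and congeneric species.

# Problem sizes and numerical conventions

The shipped checks run on synthetic communities sized for a single CPU:
genomes of 12–30 kb, 200–600 reads per recruitment experiment, 100
replicates for the clustering-recovery rates, 1,000 random matrices for
the UPGMA oracle sweep, and 200 ultrametric matrices in the acceptance
script — sizes chosen so the full suite completes in minutes while leaving
the Monte-Carlo intervals tight enough to be informative. Statistical
assertions use central 99 % binomial intervals around their oracle
expectations. Equality tolerances: profile rows sum to 1 within $10^{-9}$;
similarity symmetry within $10^{-12}$; cophenetic round-trips within
$10^{-9}$. One acceptance-level analysis — reproducing recruited-read
identity fractions for two particular sequenced symbionts from the
deposited read archives — is documented as requiring those archives and is
not runnable from the package alone.

# Known limitations

* The search engine is desk-scale: indexing is in-memory and alignment is
  exact only within the seeded window; highly repetitive references could
  mislead the diagonal heuristic. Production searches should be imported
  through the tabular-hit reader.
* Local alignment trims a terminal mismatch when doing so raises the
  score, so identity for reads with an end-base error is computed over
  $L - 1$ columns; at the divergences studied this shifts banding
  fractions by well under a percentage point, and the tests account for it
  with a small additive slack.
* $1 - r$ distances are not metric; UPGMA is well-defined regardless, but
  users wanting a metric embedding should transform similarities
  themselves before clustering.
* COG annotation is best-hit only; proteins genuinely belonging to several
  orthologous groups receive one.
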