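---
title: "Detecting sortase-dependent pilus gene clusters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sortase-dependent pilus gene clusters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piluscan)
```

# The biological problem

Gram-positive bacteria, including gut commensals such as bifidobacteria,
assemble surface pili by covalent polymerization of pilin subunits.  A
dedicated class C sortase cleaves the threonine–glycine bond of each
subunit's C-terminal cell wall sorting signal (CWSS, consensus LPxTG)
and joins the released threonine to a conserved lysine in the *pilin
motif* of the next subunit; a glutamic-acid-bearing *E-box* of the major
subunit participates in incorporating minor subunits.  The genes encode
this machinery in compact operons — one major pilin (*fimA*/*fimP*), one
or two minor pilins (*fimB*/*fimQ*), and the sortase (*srtA*) — typically
flanked by mobile elements, terminated by a 3' rho-independent hairpin,
and carrying compositional signatures of horizontal acquisition.

`piluscan` turns this architecture into an explicit, testable pipeline:
motif grammar → per-gene role call → locus assembly → terminator, mobile
element, pseudogene and horizontal-gene-transfer (HGT) evidence, with
companion tools for pilin phylogenies (Kimura two-parameter distances +
neighbour joining) and qRT-PCR fold changes, plus a fully seeded
synthetic-genome generator that provides ground truth for every stage.

# Motif grammar

## PSSMs over published motif instances

The three hallmark motifs ship as 16 published instances each (CWSS,
width 6; pilin motif, width 10; E-box, width 12; see
`pilinMotifTable()`).  Where the source material verifies motifs by
inspection, we formalize them as position-specific scoring matrices: the
score of amino acid $a$ at column $p$ is

$$ s_{ap} = \ln\frac{(n_{ap}+\alpha)/(N+20\alpha)}{b}, $$

with pseudocount $\alpha = 1$ and uniform background $b = 1/20$.  A
window's score is the sum of its column scores; windows containing a
non-standard residue (`X`, internal stop) never match.  The reporting
threshold defaults to the *minimum training-instance self-score*, chosen
so that no published instance can be missed — sensitivity is anchored to
the real diversity of the training set rather than to its consensus.

Properties that follow (and are tested): a column observed in all 16
instances scores $\ln(17/36 \cdot 20) \approx 2.246$; an unobserved
residue scores $\ln(20/36) \approx -0.588$; scanning equals an
exhaustive window scorer everywhere.

## Detectors on top of the PSSMs

* **CWSS** (`detectCwss`): the biological constraint is positional, so
  the detector requires the exact LPxTG core (positions 1, 2, 4, 5) and
  a window start within the final 50 residues (`c_term_window`,
  configurable).  The PSSM score *ranks* competing windows but is not
  thresholded here: an LPxTG whose free positions are absent from the
  training set is still a sorting signal.  Anchor flags report the
  conserved residues (T–G bond site for the CWSS, terminal K for the
  pilin motif — a soft flag, since one published instance ends in T —
  and E at E-box position 5).
* **Sec signal** (`detectSecSignal`): a transparent heuristic, not a
  trained predictor — at least one K/R in the first 7 residues
  (n-region) and a window of ≥ 8 residues with mean Kyte–Doolittle
  hydropathy ≥ 1.5 inside the first 45 residues (h-region).  Values are
  deliberately permissive; the heuristic's job is to separate secreted
  pilins from cytoplasmic background, not to predict cleavage sites.
* **Sortase** (`detectSortaseC`): product text matching /sortase/i, or
  the catalytic T-L-x-T-C motif at a plausible length (200–550
  residues).  The class C vs class A call is *contextual*: a sortase
  inside an assembled locus is reported as a class C candidate, an
  isolated one as a housekeeping class A candidate.

Role grammar (`classifyPilins`): sortase first; MAJOR_PILIN = CWSS +
pilin motif + E-box above threshold + Sec; MINOR_PILIN = CWSS + Sec
without the full major set; otherwise NONE.

# Locus assembly

`findLoci` chains role-carrying genes left-to-right per contig while the
intergenic gap stays ≤ 500 nt (`max_intergenic_gap`).  The default
reflects the tight packing of these operons; it is an artifact decision
(no maximum distance is stated in the literature we formalize) and is
configurable.  Gene order within a locus is unconstrained — both
major-first and minor-first arrangements occur in nature — only
composition (exactly 1 major, 0–2 minors, exactly 1 sortase), shared
strand, and the gap rule are enforced.  Chains that contain pilins but
violate composition are reported as `partial`, never dropped, because
downstream analyses (e.g. expression work restricted to "typical" loci)
need to see them.  Sortase-only chains are returned separately as class
A candidates.

Slippage pseudogenes (`flagPseudogeneFrameshift`): a single-nucleotide
homopolymer run of ≥ 8 nt (`min_run`; the motivating natural case is a
nine-guanine stretch, 8 leaves sensitivity margin) plus corroborating
evidence — an internal stop or a pilin/fimbrial product annotation.
Both the run and the evidence type are reported.

# Terminator hairpins

`findInvertedRepeats` enumerates *perfect* stems (Watson–Crick plus
optional G·U wobble) with stem ≥ 8 bp and loop 3–10 nt.  Every register
placement of a stem is a candidate; representations whose loop could
legally shrink (loop-terminal bases pair and the shrunken loop is still
≥ 3 nt) are removed as duplicates of the longer stem.  Mismatches and
bulges are outside the model: keeping stems perfect keeps the free
energy a plain nearest-neighbor sum that a reviewer can check by hand.

`hairpinDeltaG` sums stacked-pair free energies from a packaged table of
RNA nearest-neighbor parameters (Watson–Crick ΔG°37 values after Xia et
al. 1998) plus a loop-initiation term by loop length (Turner-style, 3–10
nt).  Wobble pairs use a documented simplification — stack as the
corresponding A·U pair plus +0.5 kcal/mol per wobble pair in the step —
rather than the full wobble parameter set.  Consequences: absolute ΔG
values are parameter-table-dependent and are reported, not matched
against externally published per-locus numbers; orderings (more pairs ⇒
more negative; G·C stems more stable than A·U stems) are exact and
tested.

`callTerminator` searches the coding strand from the locus 3' end to 150
nt downstream (`terminator_window`) and returns the most negative-ΔG
candidate at or below −12 kcal/mol (`dg_cutoff`), ties broken by
proximity to the locus.  The cutoff is chosen so that hairpins in the
stability range reported for natural pilus-operon terminators (roughly
−22 to −34 kcal/mol) are called with wide margin while weak chance
stems in random downstream sequence are not.  No poly-U tract is
required (none is asserted by the source material); truncated windows at
contig edges are searched and flagged.

# HGT signals

`gcContent` excludes N from the denominator.  The genome baseline for
`locusHgtMetrics` is the pool of *annotated CDSs*, not raw contig
sequence, because the comparison of interest is gene-vs-gene
composition; the locus value is computed over the concatenated member
CDSs and `gc_delta` is reported in percentage points.  Note the baseline
includes the locus itself, which dilutes `gc_delta` by the locus's share
of the CDS pool (≈ 2–6 % on the synthetic genomes; visible in the
acceptance numbers as means slightly below the planted shift).

Codon usage bias is quantified as relative synonymous codon usage over
the 59 informative codons (stops and the single-codon Met/Trp families
excluded), with a pseudocount of 0.5 per codon so empty families are
defined:

$$ RSCU(c) = n_{fam}\cdot\frac{n_c + 0.5}{\sum_{c' \in fam}(n_{c'}+0.5)}, $$

and the distance between two gene sets is the mean absolute difference
of their RSCU vectors — symmetric, nonnegative, zero exactly on
identical usage.  Chi-square or cosine alternatives were considered and
rejected for this release in favor of the transparent zero-identity
property.

# Phylogeny

`k2pDistance` implements the Kimura two-parameter estimator with
pairwise deletion (sites with a gap or ambiguity in either row are
dropped for that pair):

$$ d = -\tfrac12\ln\!\big((1-2P-Q)\sqrt{1-2Q}\big), $$

with standard errors from Kimura's variance formula.  Saturated pairs
($1-2P-Q \le 0$ or $1-2Q \le 0$) raise an error naming the pair.
`njTree` is an in-package Saitou–Nei neighbour-joining agglomeration
with the rate-corrected Q criterion; ties are broken by the
lexicographic order of the joined clusters' smallest leaf labels, so
results are fully deterministic, and negative branch lengths are clamped
to zero with the clamped total recorded.  `ape` supplies the `phylo`
container and newick IO, and `ape::dist.dna`/`ape::nj` serve as
independent cross-checks in the test suite — never as the
implementation.

`bootstrapSupport` resamples alignment columns with replacement,
rebuilds each replicate through the same K2P + NJ path, and reports each
internal bipartition's support as the percentage of successful
replicates containing it; replicates with saturated pairs are skipped
with a warning and excluded from the denominator.  The conventional
default is 1000 replicates; the test suite runs 25–100 to stay fast.
Trees are nucleotide-based and unrooted — outgroup rooting is left to
the user, since no outgroup is intrinsic to the method.

# qPCR fold changes

The efficiency-corrected ΔΔCt scheme with multi-reference
normalization: replicate Cts are averaged (at the Ct level — averaging
RQs instead would bias folds upward under noise), relative quantities
are $E^{\Delta Ct}$ against the calibrator condition (default
`"glucose"`, amplification efficiency default $E = 2$, per-run
configurable in $(1, 2]$), and target RQs are divided by the geometric
mean of the reference-gene RQs (the conventional reference set is
*atpD*, *tufA*, *rpoB*, *ldh*).  Two invariances pin the arithmetic
down: a global Ct offset cancels exactly, and duplicated identical
reference genes change nothing.  No significance testing is attached —
folds are descriptive.

One calibration note: with Ct noise σ = 0.2 cycles, 3 replicates and 4
reference genes, a single recovered fold has a relative error of ≈ 13 %
(1 SD), so per-replicate recovery within 20 % is not statistically
guaranteed; the recovery checks therefore bound the *mean* recovered
fold across seeds, which concentrates as $13\%/\sqrt{n}$.

# The synthetic-genome generator

`generateGenome` emulates a bacterial genome at the level this pipeline
consumes: background CDSs drawn codon-by-codon at a target per-base G+C
(default 0.60, a bifidobacteria-like value), stop codons rejected,
neutral product vocabulary, random strands, random intergenic spacers
(50–250 nt).  Background proteins are rejection-screened to contain no
LPxTG core and no T-L-x-T-C motif, so false-positive tests are
meaningful rather than vacuous.

`plantLocus` inserts the canonical architecture on the plus strand:
major pilin (Sec signal + pilin motif + E-box + CWSS, instances drawn
verbatim from the packaged published set so sensitivity reflects real
diversity, not the consensus), 0–2 minors (Sec + CWSS, screened against
accidentally carrying a full major motif set), a TLVTC sortase under a
neutral "hypothetical protein" product (so the motif branch, not the
keyword branch, is exercised), optional transposase flanks, an optional
GC-rich hairpin 40 nt downstream, and an optional frameshifted
pilin-like pseudogene with a nine-G run.  Locus gene *bodies* are drawn
as free codons at the shifted G+C — amino-acid composition then follows
the codon model, as in a gene acquired from a donor genome of that
composition — and only motif/signal segments are fixed residues
reverse-translated with synonymous-codon weights $\propto e^{\lambda
\cdot gc}$, λ solved by bisection.  Because fixed segments respond less
than 1:1 to the codon-level target, the generator calibrates its working
G+C in a short fixed-point loop until the realized member-CDS G+C hits
the planted shift (default +9 points against the realized background-CDS
baseline).  Planted pilin CDSs are additionally screened against ≥ 8 nt
homopolymer runs so the pseudogene flag can only fire on the planted
pseudogene.

`evolveAlignment` simulates the K2P substitution process exactly (root
uniform over A/C/G/T; closed-form transition/transversion probabilities
per branch length, rate ratio κ), and `simulateCt` plants fold changes
as Ct shifts with Gaussian noise.  Every generator consumes an explicit
seed and restores the caller's RNG state, so all fixtures are
reproducible byte-for-byte.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: realistic gene-length and operon
statistics, rRNA/tRNA features, genuine codon-usage structure beyond
GC3, sequence homology between planted pilins and real pilin families
(detection here is motif-driven, not similarity-driven), partial or
degraded natural loci, and assembly or annotation errors in the input
GFF3.

# Problem sizes and determinism

The shipped test suite and the acceptance script use: 20 genomes of 200
background genes with 1–3 planted loci each for locus recovery; 100
random 5–8-taxon additive matrices for NJ topology; 100 replicates of
10,000-site two-taxon alignments for K2P recovery; 20 seeds for qPCR
fold recovery; bootstrap demonstrations at 25–100 replicates.  These
sizes give stable statistics (binomial SEs of a few percent) while the
whole suite runs in about a minute and a half.  All randomness flows
through explicit seeds; `annotateGenome` itself is deterministic, and
its `report.json` is byte-identical across runs on the same input.

# Known limitations

* Sec-signal detection is a hydropathy heuristic; it will not match a
  trained signal-peptide predictor on real proteomes.
* Hairpin stems are perfect (no bulges or mismatches) and wobble
  stacking is simplified, so ΔG values are internally consistent rather
  than thermodynamically definitive.
* Gene order within a locus is unconstrained; a locus assembled from
  genuinely independent neighboring genes that happen to satisfy
  composition would not be distinguished.
* Multi-segment CDSs are rejected (bacterial scope); protein trees and
  multiple sequence alignment are out of scope (alignments are inputs).
* The pseudogene flag is evidence-gated and will miss frameshifts whose
  annotation carries neither an internal stop nor a pilin-like product.
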