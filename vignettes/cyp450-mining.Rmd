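---
title: "Mining and classifying cytochrome P450 genes from plant transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and classifying cytochrome P450 genes from plant transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypminer)
```

## The problem

Cytochrome P450s (CYP450s) are the largest enzyme superfamily in plants
and catalyze key oxidation steps in secondary metabolism, including the
diterpenoid pathways that produce pharmacologically active compounds
such as the tanshinones of *Salvia miltiorrhiza*.  Mining a newly
assembled transcriptome for CYP450 genes involves a standard but
delicate chain of steps: extracting open reading frames from oriented
transcripts, deciding which proteins are full-length, assigning
nomenclature-compliant names by identity to curated references,
characterizing the proteins, relating their expression to pathway
marker genes, and screening for antisense transcripts that may regulate
them.  `cypminer` implements this chain as composable, individually
tested functions, together with a seeded generator of synthetic
transcriptomes whose planted ground truth lets every stage be validated
exactly.

## Curation model

Transcripts are assumed oriented (strand-specific libraries: the given
strand is the sense strand), so only the three forward frames are
scanned.  `find_orfs()` reports, per frame, every maximal M-to-stop ORF
plus terminal open fragments that run off a transcript edge; the
longest candidate is the representative (ties broken toward the lowest
frame index, then the smallest start — the convention is arbitrary but
fixed and documented).

Full-length status follows three rules with the thresholds in
`curation_thresholds()`:

* **full**: starts with M, ends at an in-frame stop, and the local
  alignment to the packaged 463-residue domain consensus covers at
  least 85% of the model;
* **partial**: missing start or stop, or coverage below 80%;
* **flagged**: start and stop present but coverage in the 80–85% band.
  This band is reported explicitly rather than silently resolved,
  because such proteins genuinely require inspection of their family
  alignment (disrupted domains, unusual N-termini).

`domain_coverage()` is a deterministic stand-in for a profile-HMM scan.
A single consensus sequence is weaker than a profile for remote family
members, so the function separates *detection* from *envelope
estimation*, the way profile scanners do: a stringent local alignment
(BLOSUM45, gap open 10 / extend 0.5) must reach a raw score of 190
before the protein is considered to match the domain at all (random
full-length sequences top out around 166 in simulation; genuine
fragments score above 210), and the covered span is then measured under
permissive gap costs (open 6 / extend 0.3) so that remote but genuine
matches extend across the model.  Insignificant proteins get coverage
0.  The consensus is a packaged data file (labelled synthetic — it is a
constructed stand-in, swappable for any 463-residue consensus).

Merging with previously known sequences uses nucleotide local
alignment at ≥ 97% identity over ≥ 300 aligned nucleotides, keeping the
longer sequence and logging every decision.

## Nomenclature assignment

The standard CYP identity tiers are applied against a reference panel:
≥ 97% to a reference makes the query an allelic variant of it, ≥ 55%
places it in the reference's subfamily (next free member number),
≥ 40% in its family (first unused subfamily letter), and anything below
40% is discarded as contamination.  Boundary values classify to the
higher rank (≥ semantics; sources mix ">97%" and "97% cutoff" phrasing,
so the convention is fixed here and tested at the exact boundaries).

Identity is measured on a global alignment with free end gaps
(BLOSUM62, gap open 11 / extend 1), with the aligned columns as the
denominator.  End-free semantics keep the measure stable for fragment
queries; the denominator is switchable to the shorter sequence length.
The alignment kernel is implemented in C++ with a documented tie-break
(diagonal > gap-in-subject > gap-in-query, earliest terminal cell on
the last row then last column) so results are reproducible to the bit;
the test suite holds it equal to an independently coded reference DP
and to an independent overlap aligner's scores.

Two guards stand in for the upstream database screens a full mining
pipeline would run before classification: ORFs whose domain coverage is
below 0.20 are not CYP candidates, and references aligning over fewer
than 50 columns are invisible to `nearest_reference()` (identity over a
chance island of a few residues carries no homology signal and would
otherwise outrank genuine hits).  Partial sequences are classified at
their best supported rank but flagged provisional and never consume a
new subfamily letter, since a fragment cannot anchor a new subfamily.

## Characterization

Molecular weight is the sum of average residue masses plus one water
(reported in kDa, rounded to one decimal in tables).  The isoelectric
point solves for zero net charge over the termini and D, E, C, Y, H, K,
R with the Bjellqvist pKa set, by bisection on pH 0–14 to |charge| <
1e-4; the charge function is monotone in pH, so bisection is exact up
to tolerance (verified against a dense grid scan).

The four diagnostic motifs are scanned with degenerate patterns, with
A-type (CYP71-clan) and non-A-type variants: heme-binding
`PFGXGRRXCXG` / `XFXXGXRXCXG`, PERF `FXPERF` / `FXPXRX` (the extended
form with the conserved F at −2; the classical 4-residue form is
available via `cyp_motifs(extended = FALSE)`), K-helix `EXXR`, and
I-helix `AGXDT` / `AGX[ED]T`.  The five-position flank kept around
each hit is interpreted as five residues (the natural unit for protein
logos).  `motif_logo()` emits position-frequency matrices with
per-column information content `log2(20) −` entropy.

## Phylogenetics

Distances are Poisson-corrected proportions of differing sites,
`d = −ln(1 − p)`, with pairwise deletion of gap columns; ambiguous `X`
residues are excluded along with gaps (whether legacy tools excluded
ambiguities under "pairwise deletion" is unspecified; excluding them is
the conservative choice).  Saturated pairs (p = 1) fail explicitly.
Trees are Neighbor-Joining (via `ape::nj`) with negative branch
lengths floored at zero and reported.  Bootstrap support resamples
alignment columns with replacement under a caller-supplied seed;
support is the percentage of replicate trees containing each internal
bipartition, and `collapse_weak_branches()` contracts branches at or
below 50% into polytomies (the "shown only above 50%" convention).
The multiple sequence alignment is an input, not computed here.

## Expression analysis

FPKM ≤ 1 counts as not expressed.  Profiles are `log2(FPKM + 1)`
centered by the row mean over the three tissues; base 2 is the default
(the base changes heat-map values, not Euclidean/Ward topology).
Clustering is Ward on Euclidean distances in the "Ward.D2"
(squared-update) sense — stated explicitly because implementations
differ — and is verified against a naive O(n³) Lance–Williams oracle.

Marker co-expression uses the Pearson correlation of three-tissue mean
profiles with `r ≥ 0.9` as the co-expression rule.  With only three
points, r is highly degenerate (|r| near 1 arises easily); this mirrors
the three-tissue design the method targets and is flagged here as a
known limitation rather than silently "fixed".  Candidates require the
dual evidence of co-expression *and* pathway membership, exactly.
qPCR concordance averages technical replicates before ΔCt, references
the calibrator tissue for ΔΔCt, converts with `2^(−ΔΔCt)`, and averages
biological replicates last (both per-replicate and mean-of-ΔΔCt
summaries are reported).  A gene is rank-validated when the ordering of
its three tissue means agrees between platforms.

## Antisense screening

Coding sequences are aligned locally against the reverse complement of
every transcript (match +1 / mismatch −2, gap open 5 / extend 2).  A
pair is reported when all four filters hold: opposite strand, alignment
length ≥ 100 nt, E-value ≤ 1e-50, identity ≥ 99%.  E-values use the
Karlin–Altschul formula with fixed constants λ = 1.33, K = 0.621 for
this scoring so results are bit-reproducible.  A looser scan-stage
cutoff (1e-5) is applied first; with the other filters it is
effectively redundant and retained for fidelity to the two-stage
screening procedure.  Sense–antisense pairs are then classed positive
(r ≥ 0.9), negative (r ≤ −0.9) or neutral on their expression profiles.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the
study conditions used by the acceptance checks.

* **Reference panel** — entries derive from the packaged consensus with
  the four motif islands held fixed.  Families, subfamilies and members
  are separated by *disjoint* mutated position sets (115 positions at
  the subfamily level, 20 at the member level, of 463), so pairwise
  Hamming identities land mid-tier by construction: within subfamily
  ≈ 0.91, across subfamilies ≈ 0.42–0.50, across families ≈ 0.2–0.35.
  Realized alignment identities are verified against the tier bands
  (≥ 0.55 / [0.40, 0.55) / < 0.40) with the package's own identity
  operation; violations retry under a derived seed and then fail
  explicitly.
* **Transcriptome** — full-length genes back-translate panel-derived
  proteins mutated to controlled identities (point substitutions only,
  uniform synonymous codons, motif islands protected, so planted
  identity is exact); a stop codon is planted in frame immediately
  upstream of each ATG so the ORF is exactly recoverable.  Partials
  lack a stop (5′-anchored fragments) or a start (3′-anchored fragments
  at ≤ 70% of the protein, so an internal M cannot fake a full-length
  call).  Antisense transcripts embed reverse complements of ≥ 100 nt
  CDS windows; flank bases at the window boundaries are forced to
  mismatch the continuing CDS so a local alignment cannot extend past
  the plant and dilute its identity, and every plant is verified with
  the pipeline's own scan.  Decoys are random sequence.
* **Expression** — three tissues (root, leaf, flower).  The marker gene
  has a root-high profile, mirroring root-accumulating pathway
  products; co-expressed genes are positive scalings of it (r = 1
  before noise); antisense transcripts receive profiles matching their
  planted class, 12 positive and 3 negative at the default count of 15;
  other genes draw from templates kept below |r| = 0.8 with the marker.
  Noise is multiplicative log2-normal; the default noise is zero, which
  is the condition under which the pipeline's recovery is asserted to
  be exact.
* **qPCR** — inverts the 2^(−ΔΔCt) model: Ct = 30 − log2(FPKM) for
  targets, a flat Ct 18 endogenous control, 3 biological × 3 technical
  replicates, Gaussian cycle noise at each level (default 0).

What the generator does *not* emulate: read-level noise, assembly
artifacts and chimeras, alternative splicing, 3-tissue library-size
imbalance, and real CYP sequence phylogeny (panel families are
equidistant mutation clouds, not a realistic gene tree).  Passing the
planted-truth checks therefore demonstrates the correctness of the
pipeline's logic and thresholds, not performance on real assemblies.

## Numerical and design choices

* Identity denominator: aligned columns, end gaps free; documented
  alternative: shorter-sequence length.
* Curation/rank boundaries all use ≥ semantics and are unit-tested at
  the exact cutoff values (0.80/0.85 coverage; 0.40/0.55/0.97
  identity; FPKM > 1 expressed).
* The mean protein length in table summaries is rounded half-up to an
  integer (the convention of published gene tables).
* Problem sizes in the default test run: the reference DP oracle is
  exercised on 100 random pairs, the ORF enumeration oracle on 300
  random sequences, the pI grid oracle on 50 peptides, Ward on 5–8
  genes, NJ round-trips on 4–10 taxa, and the end-to-end recovery on
  the default bundle of 65 transcripts — sizes chosen to make the
  properties sharp while keeping a full test run fast.
* All generator randomness flows through a single seed per invocation,
  with deterministic child seeds per sub-generator; identical
  configurations yield byte-identical bundles.

## Known limitations

* A consensus-alignment proxy cannot fully replace a profile HMM; very
  remote or highly disrupted domains may still be under-covered, which
  is why the 80–85% band is surfaced as `flagged` rather than decided.
* Pearson r on three tissue means is degenerate; co-expression calls
  should be treated as screening evidence, not inference.
* Provisional names are deterministic but are not official
  nomenclature: real naming requires the community registry.
* Antisense detection without a genome cannot distinguish cis- from
  trans-acting pairs.
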