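---
title: "Mining, dating and comparing endogenous retroviruses: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining, dating and comparing endogenous retroviruses: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervatlas)
```

## The problem

Endogenous retroviruses (ERVs) are germline-fixed remnants of ancient
retroviral infections.  A provirus integrates as
5'LTR–PBS–*gag*/*pol*/*env*–PPT–3'LTR, flanked by a short target-site
duplication (TSD) of host sequence, and the two long terminal repeats
(LTRs) are identical at the moment of integration.  Because each LTR then
accumulates neutral substitutions independently, their divergence clocks
the insertion; because integration is essentially irreversible,
an insertion shared at homologous positions in two species demonstrates
that it predates their split.  `ervatlas` implements the complete desk
workflow around these facts: translated homology screening with
retroviral POL protein probes, paired-LTR structure calling with TSD,
primer-binding-site (PBS) and polypurine-tract (PPT) annotation, lineage
clustering with consensus construction and standard ERV nomenclature,
solo-LTR classification, Kimura two-parameter (K2P) insertion dating, and
orthologous-insertion detection between two genomes.

Every stage can be exercised against a provirus simulator whose planted
elements carry known ages and states, so the pipeline's behavior is
measurable against ground truth rather than only against itself.

## The dating model

For the gap- and N-free columns of a global alignment of a provirus's two
LTRs, with transition proportion $P$ and transversion proportion $Q$, the
K2P distance is

$$D = -\tfrac12\ln(1 - 2P - Q) - \tfrac14\ln(1 - 2Q),$$

and the insertion age is $T = (D/R)/2$: the factor 2 reflects the two
independently evolving LTR copies, and $R$ is the neutral substitution
rate per site per year.  Lacking a pangolin-specific estimate, the
default is the average mammalian neutral rate $R = 2.2\times10^{-9}$;
it is a config key (`rate`) and can be set per lineage.  When
$1-2P-Q \le 0$ or $1-2Q \le 0$ the distance is saturated: the element is
flagged and excluded from dating rather than assigned an arbitrary age.
Ages are reported in Mya to two decimals.  No correction is attempted for
gene conversion or CpG hypermutation; both bias paired-LTR clocks on real
data and are listed as caveats in the output, not modeled.

The LTR–LTR alignment for dating is *global* (end gaps penalized), since
both repeat boundaries are structurally determined upstream; gap and N
columns are excluded from the site counts (complete deletion).

## The simulator

`simulate_genome()` builds i.i.d. background DNA at a configurable GC
fraction (default 0.42, a typical mammalian value) and plants
template-derived elements.  A template is LTR + PBS (reverse complement
of a labeled tRNA 3' 18-mer) + GAG/POL/ENV open reading frames carrying
the canonical motif set at recorded positions + a purine PPT + an
identical second LTR.  Planting duplicates the 4–6 bp at the insertion
point on both sides (the TSD), mutates each LTR *independently* for the
element's age and the internal region once, so the expected LTR–LTR
divergence is $2Rt$ — exactly the quantity the dating model inverts.

Substitutions follow the K2P forward process simulated exactly: per-site
Poisson event counts at total rate $R$, each event a transition with
probability $\kappa/(\kappa+1)$.  Multiple hits at one site occur
naturally, which is what the logarithmic correction must undo; a
matrix-free event-wise simulation was chosen over sampling from the
transition matrix precisely so that the estimator is tested against a
true multiple-hit process.  The default $\kappa = 2$ (transitions twice
the total transversion rate) is a typical mammalian transition bias; it
is a config key and recorded in the truth table conditions.

Element states: `intact`; `degraded` (a premature stop overwrites an
in-frame codon about one third into each ORF); `solo` (a single mutated
LTR plus TSD, the footprint of LTR–LTR recombination); `nested` (a
LINE-1-like cassette — random DNA with a poly-A tail — inserted between
ENV and the PPT).  Elements are spaced at least ~20 kb apart (config
`min_spacing`) so that solo/remnant classification has unambiguous truth;
the simulator refuses overlapping insertions rather than shifting them.

Two deliberate idealizations: no indels and no insertion-site preference.
Consequently passing tests demonstrate correctness of the *decision
rules* (thresholds, geometry, clock inversion) under the assumed neutral
substitution process, not robustness to indel-rich decay, tandem
repeats, or segmental duplication found in real assemblies.

### Unambiguous insertion sites

A subtle identifiability issue drives one simulator rule.  If the host
base immediately preceding the target site happens to equal the
element's terminal base, the flanking duplication reads one base longer
than the planted TSD, and *no* sequence-level method can recover the
planted boundary — the two interpretations are byte-identical.  (Real
annotators resolve this with the TG…CA LTR termini, which this package
deliberately does not enforce.)  `plant()` therefore slides the insertion
point by a few bases to a site where the planted TSD is the unique
maximal flanking duplication within the boundary-refinement search range.
This is an extension of the simulator's unambiguous-truth principle, not
a change to the biology being emulated.

## Alignment kernels

Seeding-and-extension search stands in for the external BLAST family:

* **protein-vs-translated** (tBLASTn-like): exact 5-mer seeds of the
  probe against all six frame translations; seeds clustered by diagonal
  (±16) with a two-hit requirement, then gapped Smith–Waterman extension
  (BLOSUM62, gaps 11+1L) over the seeded window, with exact mapping of
  amino-acid coordinates back to genome nucleotides and strand.
* **nucleotide** (BLASTn-like): exact 11-mer seeds, +2/−3 with gaps
  5+2L.
* **discontiguous nucleotide** (dc-megablast-like): one fixed 21-of-28
  coding-style spaced seed (every third position of the first 21 columns
  is a wildcard).

Identity is computed over aligned non-gap columns (N and X never match,
including against themselves); coverage over the full query length —
the conventions the published thresholds assume.  E-values use the
Karlin–Altschul form $E = Kmn\,e^{-\lambda S}$ with fixed $(\lambda, K)$
per scoring scheme (0.625/0.41 nucleotide, 0.267/0.041 BLOSUM62-gapped).
These are approximations to external-search statistics: the screening
thresholds, not raw E-value agreement, are the contract.  The dynamic
programming itself is delegated to `Biostrings::pairwiseAlignment`; the
test suite checks it against an independent exhaustive-enumeration
oracle.

## Structure calling

Candidate loci from the POL screen (identity ≥ 30%, query coverage
≥ 40%, E ≤ 1e−5, same-strand hits merged within 1 kb) are expanded by
16 kb and scanned for same-strand direct repeats with LTR geometry: each
repeat 100–7000 bp, starts 1000–15000 bp apart, pairwise similarity
≥ 0.85.  Minus-strand candidates are analyzed on the reverse complement
of the window and mapped back.

Boundary determination needed three refinements beyond naive
exact-match extension of the repeat alignment, all motivated by failure
modes observed on simulated data:

1. *Noisy-end trimming.*  A spurious local-alignment extension into the
   flanks stitches chance matches with gaps; true LTR–LTR alignments are
   gap-free near their ends.  Terminal segments containing gap columns
   within 15 columns of the end are dropped, and the boundary is placed
   on a clean run of five exact matches.
2. *Mismatch-tolerant joint extension.*  Point divergence between the
   two repeats stops single-base exact extension early; extension jumps
   an isolated mismatch when at least 4 of the next 6 outward columns
   still match.
3. *TSD-anchored refinement.*  Because the bases flanking the two repeat
   copies can match by chance, both boundaries can shift in lockstep.
   Among joint shifts of up to ±6 bp, the pair exposing the longest
   exact flanking duplication (ties: smallest shift) is taken.

PBS annotation scans up to 20 bp downstream of the 5' LTR (backing off
6 bp into the called repeat, since the internal boundary may overshoot)
for the reverse complement of each library tRNA 18-mer with at most two
mismatches; the PPT is the longest window ≥ 10 bp with purine fraction
≥ 0.9, ending on a purine within 20 bp of the 3' LTR.  These are
annotations: full-length status requires only paired LTRs plus an
internal region (≥ 500 bp); a degraded PBS does not demote an element.

## Lineages, consensus and solo LTRs

Full-length elements are clustered by single-linkage at > 90% pairwise
global identity (the clustering dial the consensus construction
requires; single linkage was chosen over average linkage as the more
permissive interpretation of "copies of the same element", and is a
config key).  Copies genome-wide are retrieved with the lineage
consensus as query at > 4 kb aligned length and ≥ 80% identity.
Consensus sequences use a star alignment to the longest member with
per-column majority vote (ties to the earliest copy; columns gapped in
more than half the rows dropped).  Since the simulator plants no indels,
the star approximation is exact up to boundary jitter; on indel-rich
real data a progressive MSA would be preferable and consensus functions
accept any pre-aligned input.

Solo LTRs: LTR-consensus hits at E ≤ 1e−5, coverage > 10%, identity
> 80% are solo iff no second qualifying LTR hit and no internal-region
remnant lies within 15,000 bp on either side (the same window as the
pairing geometry), then grouped at > 90% identity.  Names follow
`ERV-<Genus>.<letter><n>-<host>` / `SoloLTR-…`: letters by descending
copy number (ties by leftmost coordinate), copies numbered in genomic
order; letters extend a…z, aa, ab… past 26 lineages.  A letter is
assigned even for a genus with a single lineage, keeping names stable
when a second lineage appears.

## Orthologous insertions

For an element of genome A and a candidate partner locus of genome B
(found by an 80%/80% RT nucleotide search), 30 kb flanks are extracted
(clipped at contig ends, achieved lengths recorded).  Retained
discontiguous-seed alignments between corresponding flanks must be
≥ 500 bp at E ≤ 1e−5; the insertion-region alignment must itself cover
at least 500 bp (or half the shorter region) — a handful of identical
columns between unrelated sequences would otherwise read as high
"identity" — and the verdict is `ortholog` iff the insertion regions
align at ≥ 85% identity *and* the union of retained alignments
covers ≥ 50% of A's achieved flanks (both flanks jointly, on A's
coordinate system — the interpretation chosen where the rule's wording
is ambiguous).  A is the query genome by convention; verdicts are
symmetric on simulated data up to tie-breaking.

## Study conditions and problem sizes

The bundled demo (`demo_plan()`) plants 22 elements of three lineages
(two gamma-like, one beta-like) at ages 0–10 Myr — intact, degraded,
solo and nested states, two on the minus strand — into ~780 kb of
background; the orthology demo derives a species pair at 8 Myr
speciation from an ancestor carrying 5 insertions, then adds 3 and 2
private ones.  These sizes keep a complete run plus its replicated
acceptance checks within a few minutes on one CPU while leaving every
decision rule exercised: recall/boundary checks see ≥ 20 elements,
clock-recovery checks use 50 replicates per age at 600 bp LTR length,
and the orthology rule is swept at 2, 8 and 16 Myr speciation.  The
acceptance script additionally runs a 16.4-Myr species pair carrying
five shared insertions — the depth and count relevant to the pangolin
species split this kind of analysis is applied to.

## Numerical and degenerate-input choices

* Empty local alignments score 0; identity is NA, never 0/0.
* Saturated K2P inputs are flagged, not errored, at the catalog level;
  `k2p_distance` itself reports `saturated = TRUE` with `D = NA`.
* Ambiguity codes collapse to N on input; N never matches anything,
  including N, in any identity computation or seed.
* ORFs run from the first ATG after the previous stop (configurable
  `require_atg`) to the next stop or element end; reported lengths
  include the stop codon, and only ORFs strictly longer than 180 nt are
  kept by default.
* Motif patterns treat `X` positions as "any residue except a stop";
  matching never crosses `*`.  `CX6C` is suppressed at anchors where
  `CX6CC` matches, so the beta/gamma envelope call is unambiguous.
* All randomness flows from the single config seed; reruns with the same
  config are byte-identical.

## Known limitations

Indels, recombination (other than the solo-LTR deletion the classifier
targets), selection, CpG effects and insertion-site preference are not
simulated; nested elements are flagged, not untangled; phylogenetic
inference (tree building, clade support) is out of scope — lineage
genus labels come from the probe panel that seeded each lineage.  The
E-value model omits edge-effect and composition corrections.  Exact
reproduction of counts from real genome assemblies additionally depends
on the probe panel and search-engine dialect used.
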