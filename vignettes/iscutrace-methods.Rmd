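---
title: "Methods: tracing frataxin and scaffold co-evolution across prokaryotic proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracing frataxin and scaffold co-evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iscutrace)
```

## The scientific question

Frataxin is essential in eukaryotes but nearly dispensable in most bacteria,
and the identity of a single scaffold residue — position 108 of IscU, Ile/Leu/
Val in most prokaryotes but Met in eukaryote-like scaffolds — tracks that
difference. `iscutrace` implements the comparative-genomics side of that
story as a reproducible pipeline: detect CyaY (frataxin) and U-family
(scaffold) homologs across proteomes, classify scaffold candidates with an
explicit four-criterion rule, take a census of the residue at reference
position 108, profile CyaY/IscU co-occurrence, reconstruct gain/loss
histories on a species tree, and flag horizontal-transfer candidates. Every
stage is exercised end-to-end on simulated corpora with planted ground
truth, because the original genome snapshot such analyses run on is never
exactly reconstructible.

## Profile models and glocal alignment

A family is represented by a column-wise log-odds profile built from a seed
alignment. Per-column frequencies use a background-weighted pseudocount,

$$ f_c(a) = \frac{n_c(a) + \alpha\, q(a)}{n_c + \alpha}, \qquad
   s_c(a) = \log_2 \frac{f_c(a)}{q(a)} \ \text{bits}, $$

with uniform background $q$ and $\alpha = 1$ by default. Columns with at
least 50% gaps in the seed are non-match columns and are excluded from
scoring — a standard profile-construction heuristic. The reference row of
the seed anchors residue numbering: reference position 108, the motif window
99–103, and the three conserved cysteines are all addressed in that
numbering.

Queries are aligned *glocally*: the profile must be traversed end to end
(each match column matched or deleted) while query flanks overhang free.
This makes "homology with the entire sequence" measurable as coverage, and
exposes extra domains as long unaligned flanks. Gap runs of length $k$ cost
$g_o + k\,g_e$ bits, defaults $g_o = 4$, $g_e = 1$; deletion–insertion
adjacency is permitted (each run opens its own gap), so the dynamic program
optimizes over exactly the path space a brute-force enumeration explores —
that equivalence is asserted in the tests on hundreds of small random
instances. Traceback ties resolve match > deletion > insertion, making
outputs bit-reproducible. `X` residues score 0 bits everywhere; this is a
deliberate neutral treatment of ambiguity.

We do not train transition probabilities or re-derive analytic E-value
statistics: the search is a retrieval step, and a deterministic DP is
auditable against an independent oracle.

## Empirical E-values

Scores are calibrated against residue-shuffled decoys drawn from the target
database itself. The null survival function is empirical below the top
decile of decoy scores and an exponential tail fitted (by its mean excess)
to the scores strictly above the decile boundary; the E-value is
$E(s) = N\,\hat P(S \ge s)$ for a database of $N$ sequences. Fitting
strictly above the boundary keeps $E$ monotone non-increasing even with
tied scores. Calibration requires at least 100 shuffles (default 1000) and
at least 10 scores in the tail region, and is fully determined by one
integer seed recorded in the calibration object.

The two retrieval policies mirror the published analysis: domain-mode
screening keeps hits with $E \le 0.1$; the stringent full-sequence CyaY
policy additionally requires coverage $\ge 0.9$ and $E \le 1.7\times10^{-7}$.
Both thresholds are configuration, logged in every run manifest. Whether the
0.1 cut is applied per-domain or per-sequence is exposed as the choice of
profile; nothing else distinguishes the modes.

## The four-criterion scaffold rule

A U-family hit is accepted as an IscU homolog only if all four hold:

1. **Conserved cysteines** — Cys aligned at the three reference positions
   with the highest Cys conservation in the seed (all must reach the 0.95
   gate; auto-detected rather than hard-coded, since only Cys106 is pinned
   by the literature).
2. **Chaperone-recognition motif** — residues aligned at 99–103 match
   `LPPVK` with at most one substitution at non-proline positions. Family
   logos show cross-species variation at the non-proline positions, so an
   exact-match rule would be too strict; the prolines are kept invariant.
   The pattern and budget are configurable and logged.
3. **No additional domain** — both unaligned query flanks are at most 50
   residues. This operationalizes "no extra domain" deterministically and
   rejects NifU-like multi-domain fusions without a second domain scan.
4. **isc gene neighborhood** — at least one *other* gene labeled from the
   isc vocabulary (`iscR iscS iscU iscA hscB hscA fdx iscX`) within ±5
   positions in gene order. The window is inclusive at 5 and the gene never
   counts itself.

Acceptance is the strict conjunction; tests exercise all 16 flag
combinations. Before the census, accepted homologs are deduplicated to one
representative per species (highest score), because the census counts
species, not loci.

## Census and sequence logos

The residue-108 census counts the residue aligned at reference position 108
per taxonomy group, and reports the Ile/Leu/Val fraction. Logos over 99–108
use per-column frequencies with gaps excluded from the denominator and
information content $R_i = \log_2 20 - H_i$ bits; an invariant column gives
$\log_2 20 \approx 4.32$ bits, a uniform column 0. No small-sample
correction is applied by default (the corpora here are small and the logo is
descriptive).

## Phylogenetic profiling, parsimony, and HGT

Presence/absence of the two families over all corpus taxa feeds a
co-occurrence report (the four presence combinations plus the list of taxa
violating the cyaY ⊆ iscU containment) and ancestral reconstruction:

* **Fitch mode** minimizes state changes, implemented as a binary-state
  Sankoff pass so multifurcations are handled exactly; root ties resolve to
  *absent*, consistent with inferring that the gene was missing in the last
  bacterial common ancestor.
* **Dollo mode** allows a single gain, placed at the MRCA of the present
  leaves, and minimizes losses below it (the spanning-subtree labeling);
  cost is losses + 1.

Both are reported side by side because a deep loss-only scenario and a
multi-gain scenario cannot be distinguished on presence data alone. Both
costs are verified against exhaustive enumeration over all internal
labelings on hundreds of random trees of up to 8 leaves, and the Fitch score
is independently cross-checked against `phangorn::fitch`.

Gene trees for HGT screening are built by neighbor joining (via `ape::nj`)
on profile-anchored distances (1 − identity over jointly aligned match
columns). Negative NJ branches are clamped to zero with the deficit moved to
the sister branch, preserving total tree length. A leaf is flagged as a
transfer candidate when all of its $k = 3$ nearest leaves (patristic
distance, deterministic tie-break by label) belong to a different phylum and
fewer than two neighbors share its phylum. This k-NN incongruence rule is an
operationalization of visual tree inspection, not a claim about how any
particular published analysis was curated.

## The synthetic corpus and what it does (not) show

The simulator emits the exact input formats the pipeline consumes (per-genome
FASTA, gene table TSV, Newick tree, taxonomy TSV, truth JSON). Its defaults
define the study conditions used throughout the tests:

* 40 genomes on a Yule species tree (birth rate 1, seed-deterministic),
  partitioned into ~6 phyla as lineages crossing a time slice; clades under
  3 leaves are absorbed into the phylum of their nearest relatives so
  incongruence analysis has meaningful groups.
* iscU in every genome; cyaY planted on the clade whose size is closest to
  25 (a "proteobacteria-like" origin). A two-state Markov mode with
  gain/loss rates (0.3/0.15 for iscU, 0.2/0.3 for cyaY per unit branch
  length) serves the co-occurrence tests; its dependency rule — cyaY gain
  only where iscU is present, iscU loss forbidden while cyaY persists —
  guarantees zero containment violations by construction.
* A "rickettsia-like" clade of ~12 genomes carries Met at 108; all other
  genomes draw Ile/Leu/Val (weights 0.5/0.3/0.2).
* Sequences evolve by column-independent resampling from the seed-observed
  column distributions (probability $1-e^{-\rho\,\ell}$ per column per
  branch of length $\ell$, $\rho = 0.1$), with cysteine and motif columns
  invariant and column 108 forced to the clade state. The rate is chosen so
  corpus identities span roughly 60–90%, keeping gene trees informative
  without saturating distances. Resampling from seed-observed (not
  pseudocount-smoothed) distributions means planted homologs never carry
  residues the family has never shown — the same reason the seed's column
  108 is a realistic Ile/Leu/Val/Met mixture rather than invariant Ile: a
  planted Val at an invariant-Ile column would be cheaper to explain as an
  indel than as a match.
* Genomes carry 30–100 genes: random background proteins (100–300 residues),
  a 3-gene isc-operon block, the planted families (iscU adjacent to the
  operon with probability `p_ctx`, default 1; cyaY always far from it, as
  observed in real genomes), and 30 decoys — NifU-like fusions (scaffold
  plus a 200-residue extra segment, placed in operon context so only the
  flank criterion rejects them), SufU-like motif-scrambled homologs,
  structural-only frataxin analogs (random, length-matched), and random
  proteins.
* Two horizontal transfers: distinct donors, recipients preferring distinct
  cyaY-free phyla, donor never in the recipient's phylum; the transferred
  copy diverges 2% per column.

What passing tests show: the pipeline recovers planted composition exactly,
the criteria reject the decoy classes for the intended single reason, and
the parsimony/NJ/alignment machinery agrees with independent oracles. What
they do not show: robustness to indels and alignment error (the simulator
introduces no indels outside decoy fusions), to annotation noise in gene
labels, to draft or contaminated assemblies, or to real Pfam-scale emission
statistics. Headline counts from any particular historical genome snapshot
are inherently snapshot-bound and are not targets here.

## Numerical choices and degenerate inputs

* All internal column indices are 0/1-based consistently: reference
  numbering is 1-based and appears only at I/O and in criteria.
* Empty genome → empty hit table (not an error); empty classification list →
  empty census; a logo column with no aligned residues reports NA
  information.
* Fewer than three qualifying cysteine columns is an error naming the
  shortfall; unequal seed rows, unknown residues, and missing leaf states
  are errors.
* Problem sizes in the test-suite: oracle comparisons use trees and
  profiles of up to 8 leaves/columns (exhaustive spaces of ≤ 2^7 labelings
  and a few 10^5 paths), 50-replicate Monte-Carlo loops use lighter genome
  backgrounds (15–25 genes) since the tested signal lives in the planted
  families, not the background size.
* Every stochastic step (tree, presence, sequences, decoys, shuffles) is
  driven by one integer seed recorded in the truth file, calibration
  objects, and run manifests; reruns are byte-identical.

## Known limitations

Besides the simulator simplifications above: the E-value null is empirical
(shuffled decoys), so extreme tail extrapolation inherits the exponential
assumption; the no-extra-domain criterion is a flank-length proxy, not a
domain architecture scan; Dollo's single-gain assumption is imposed, not
tested; and the k-NN HGT rule cannot see transfers between sister phyla or
very recent transfers within a phylum.
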