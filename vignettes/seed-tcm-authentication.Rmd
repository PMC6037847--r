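---
title: "Methods: DNA-barcode authentication of seed herbal medicines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNA-barcode authentication of seed herbal medicines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedbarcode)
```

## The problem

Seed-derived herbal drugs are traded as dried seeds, which are hard to
identify morphologically and easy to substitute, accidentally or
deliberately. DNA barcoding sidesteps morphology: a short standardized
region — here the nuclear ribosomal ITS2 spacer as the core marker and the
chloroplast psbA-trnH intergenic spacer as the supplementary one — is
amplified from the material, sequenced, and compared against a reference
library of expert-identified voucher specimens (standard reference
materials, SRM). A market sample is then judged by whether its best
reference match is (a) confident enough and (b) a species the
pharmacopoeia accepts for the drug on the label.

`seedbarcode` implements this workflow end to end: reference-library
construction and validation, in-silico marker extraction, identity search,
tree-based discrimination assessment, per-sample classification, and
survey aggregation — plus a sequence simulator that generates libraries
and whole market surveys with known ground truth, so that every stage can
be validated without any external data.

## The decision rule

For a sequenced sample declared as drug $D$ the pipeline searches the
library marker by marker (ITS2 first, psbA-trnH as fallback) and collects
the *top species set*: every species whose best reference hit ties with
the overall best percent identity (tie margin 0 by default, on identities
rounded to 1 decimal place). With identity threshold $\tau = 98\%$
(inclusive, "at least 98"):

1. no usable sequence → **amplification failure**;
2. best identity $< \tau$ → **mislabeled** (sub-threshold rule; a config
   flag can instead file these as completely undetermined);
3. top set $\subseteq$ accepted($D$), single species → **authentic**;
4. top set $\subseteq$ accepted($D$), several species of a multi-origin
   drug → **partially undetermined** (the material is genuine at the drug
   level but the congeners cannot be told apart);
5. top set mixes accepted and non-accepted species at the same identity →
   **completely undetermined**;
6. top set entirely outside accepted($D$) → **mislabeled**.

Percent identity is BLAST-style: identical columns over total alignment
columns, gaps included in the denominator. This convention matters —
excluding gap columns would inflate identities of truncated matches past
the threshold — and is therefore fixed and documented rather than left to
an alignment library's default.

One genuinely open design point: a confident (say 100%) match to a
*non-accepted* congener of a multi-origin drug can be read either as
mislabeling (the cascade above) or as "partially undetermined" on the
argument that genuine and false material are still separable. The default
follows the cascade; `decision_config(adulterant_match_in_multiorigin =
"partially_undetermined")` selects the lenient reading.

## Alignment

Identity search uses an affine-gap pairwise aligner (match +1, mismatch
−1, gap open −2, gap extend −1; a gap run of length $L$ costs
$open + (L-1)\,extend$), global when the two lengths are within a factor
of two of each other and local otherwise. The aligner is implemented in
C++ with a deterministic traceback (diagonal preferred, then vertical,
then horizontal gap), so identical inputs always give byte-identical
alignments. The scoring values are a documented convention, configurable
through `scoring_scheme()`; the classification depends on the identity
ratio far more than on the exact scores. The test suite checks the
dynamic program against an exhaustive enumeration of all alignments for
short sequences, so optimality does not rest on the implementation
checking itself.

## Distances, trees, discrimination

Species discrimination is assessed the way barcoding studies conventionally
do it: Kimura 2-parameter distances, a neighbor-joining tree, bootstrap
supports, and a check that each drug's sequences form a distinct,
non-overlapping group.

* **K2P.** Sites where either row has a gap or ambiguity code are dropped
  per pair (pairwise deletion, the common default in MEGA-style
  workflows). With transition proportion $P$ and transversion proportion
  $Q$, $d = -\tfrac12 \ln[(1-2P-Q)\sqrt{1-2Q}]$. Saturated pairs (either
  log argument non-positive) raise a dedicated error class so callers can
  distinguish saturation from malformed input.
* **NJ.** Saitou–Nei agglomeration on the Q-criterion. Negative branch
  estimates are clamped to zero with the deficit moved to the sister
  branch, preserving the joined pair's path length. Ties on the
  Q-criterion (detected within a relative tolerance of $10^{-10}$) are
  broken by the lexicographically smallest pair of cluster labels, each
  cluster keyed by its smallest member taxon. Labels, not matrix indices,
  are the tie-break because index-based choices make the output depend on
  input row order — which would break the contract that bootstrap
  supports are invariant under leaf permutation.
* **Bootstrap.** Alignment columns are resampled with replacement;
  replicate $r$ draws under seed $seed + r$, making runs reproducible and
  replicates independent of each other. Support of an internal edge is
  the percentage of replicates containing the same bipartition.
  Replicates with a saturated pair are skipped and counted, with a
  warning if more than 10% drop out.
* **Monophyly.** A group is discriminated when some bipartition of the
  unrooted tree isolates exactly its leaves; singletons count as
  monophyletic. Before assessment, internal edges shorter than
  `collapse_tol` (default $10^{-8}$) are collapsed into polytomies. This
  matters for sequence-identical congeners: with all pairwise distances
  zero, a binary NJ tree still has to pick *some* join order, and the
  deterministic tie-break would hand such groups an apparent — and
  meaningless — resolution. A zero-length edge carries no signal and is
  treated as unresolved, which is also how polytomy-collapsed published
  trees read.

Full maximum-likelihood tree search is deliberately out of scope: the
quantity of interest is group discrimination, and NJ over the identical
K2P distances is the documented substitute.

## The simulator

`simulate_library()` generates a reference library on a star of drug
clades: one root sequence, drug ancestors at `inter_species_divergence`
from the root, accepted species (and one adulterant species per drug)
another `inter` below their drug ancestor, and voucher records scattered
at `intra_species_divergence` around their species sequence. Substitutions
follow a transition/transversion rate process whose stationary
frequencies are the ancestor's own base composition (HKY-style); at
uniform composition it reduces exactly to Kimura's two-parameter model.
`ti_tv_ratio` ($\kappa$, default 2 — a typical nuclear ribosomal value)
is the *expected transition:transversion count ratio*, the quantity one
actually measures by counting sites. Composition preservation is not a
nicety: a pure K80 process pulls every sequence toward 50% GC, and an
AT-rich spacer like psbA-trnH (target 24% GC, printed range 21–29%)
would leave its band within a single inter-species branch.

Defaults mirror the scale of a pharmacopoeia seed-drug collection: 51
drugs from 64 accepted species (40 single-origin, 9 double, 2 triple),
three records per species — 192 SRM records — with ITS2 length drawn per
species from a normal (mean 220 bp, sd 20) truncated to 190–280 bp and
root GC fixed at exactly 61% (psbA-trnH: 328 ± 45 bp in 262–520, GC 24%).
Exact root composition, rather than a binomial draw, keeps every seed's
GC inside the narrow psbA-trnH band; the composition-preserving
substitution process then holds the library mean at the target.

Two deliberate degeneracies reproduce the failure modes seen in real
market surveys:

* **indistinguishable multi-origin drugs** (3 by default): all accepted
  congeners share one identical barcode — queries tie exactly across the
  accepted set and land in *partially undetermined*;
* a **confusable drug** (1 by default): its adulterant is
  sequence-identical to the accepted species — queries tie across
  accepted and non-accepted names and land in *completely undetermined*.

Records of these drug groups are generated with zero record-level noise
and a shared length. That is intentional: the undetermined categories are
driven by *exact* identity ties (the "100% match to several names"
situation), and independent per-record noise would break a tie that, in
the real system, exists because the haplotypes genuinely coincide.

Divergence defaults are conventions, not measured values: intra 0.002 and
inter 0.08 substitutions/site put conspecific identity near 99.6% and
congeneric identity near 85%, far on either side of the 98% rule — the
regime the marker choice itself presupposes. The real intra/inter figures
for the study's taxa are not published per species, so the simulator makes
the assumed regime explicit and testable instead.

`simulate_survey()` plants a labeled composition — by default 309
authentic, 30 mislabeled, 41 undetermined (34 completely, 7 partially)
and 20 amplification failures out of 400 — drawing authentic samples from
resolvable drugs, mislabeled ones from a declared drug's adulterant,
undetermined ones from the degenerate drug groups, and emitting failures
as `no_amplification` manifest rows. Sequenced samples are emitted as full
amplicons (forward primer + core + reverse-complemented reverse primer) so
the pipeline's extraction stage is exercised, with per-sample sequencing
noise 0.001 substitutions/site.

What the simulator does *not* emulate — and what passing tests therefore
do not show about real data: indels and alignment ambiguity (cores differ
only by 3' truncation, so multiple alignment is trivial padding),
chimeras and contamination, heterogeneous rate variation across sites,
real taxonomic sequence composition beyond the length/GC moments, and
mixed-species material. On real surveys the practical accuracy bound is
usually reference-library coverage, which the simulation by construction
cannot probe.

## Marker extraction

Extraction anchors the four standard universal primers (ITS2F/ITS3R,
PA/TH) by ungapped scanning with a mismatch budget (default 10% of primer
length), IUPAC-aware on both sides, taking the leftmost minimal-mismatch
placement; the reverse primer is located by scanning the reverse
complement, which prefers the placement nearest the 3' end. If either
anchor is missing, the reverse complement of the input is tried before
giving up. The extracted core excludes the primer sites — whether
"complete ITS2" should include them is undefined in common usage, so the
exclusive convention is fixed here. A profile-HMM annotator would be the
heavier-duty alternative for real consensus sequences; for primer-flanked
amplicons the anchor scan is exact and transparent. Strict mode treats
anchor-free sequences as failures (the default — silent pass-through
hides upstream problems); permissive mode passes them through flagged,
when their length is plausible for the marker.

## Numerical conventions

* Identities are reported to 1 decimal place, rounding half away from
  zero; the threshold comparison is `>= 98.0` on the rounded value.
  Survey percentages round half-up to 2 decimals.
* Branch lengths are serialized at full precision (`%.17g`), so
  fixed-seed runs produce byte-identical newick files.
* All stochastic entry points take an explicit integer seed and restore
  the caller's RNG state; the same `(spec, seed)` reproduces every output
  byte for byte.
* Problem sizes in the validation suite are chosen to keep each
  experiment at desk scale: the NJ oracle sweep uses 200 matrices of 4–6
  taxa (exhaustive topology enumeration is feasible to 105 topologies),
  the discrimination experiment 20 drugs with 100 bootstrap replicates,
  and the end-to-end recovery experiment the full 400-sample composition
  against the 51-drug default library.

## Known limitations

* The identity search scans the whole library per query (no heuristic
  seeding); fine for libraries of a few hundred records, not for
  GenBank-scale references. An optional exact k-mer screen exists but is
  off by default because at barcode-level divergences it rarely filters.
* Center-star multiple alignment is provided for toy and simulated data
  only; real consensus sequences should be aligned with a dedicated MSA
  tool before tree building.
* The five-way classification assumes one species per sample; mixtures
  (powdered blends) need mini-barcodes or NGS readouts and are out of
  scope.
* Monophyly is assessed on the NJ topology only; it is a discrimination
  check, not a phylogenetic inference.
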