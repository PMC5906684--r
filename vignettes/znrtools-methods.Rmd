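---
title: "Methods: comparative analysis of zinc-ribbon and SH3-fold domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of zinc-ribbon and SH3-fold domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(znrtools)
```

## Scope and scientific background

Zinc ribbons (ZnRs) are small beta-domains held together not by a hydrophobic
core but by a zinc ion chelated by two cysteine pairs, one from each of two
beta-hairpin turns ("knuckles", consensus motif CPxCG with the cysteines at
motif positions 1 and 4). The archaeal chromatin-compacting proteins
Cren7 and Sul7 have an SH3-like beta-barrel morphology but retain, in many
homologs, two to four cysteines exactly at the positions of ZnR knuckles --
the signature of a zinc-ribbon ancestry with secondary loss of chelation. A
separate line of evidence concerns the chromo-like superfamily of SH3-fold
domains, which recognize methylated peptides through a cage of about five
aromatic residues (Y, W, F and, by convention adopted here, H).

`znrtools` implements the computational steps such an analysis needs as
reusable, tested functions:

* motif scanning and chelation-state calling (`find_knuckles()`,
  `classify_chelation()`),
* aromatic-cage conservation profiling over family alignments
  (`map_cage_columns()`, `aromatic_fraction_profile()`, `compare_families()`),
* topology-based ZnR typing from C-alpha coordinates (`assign_strands()`,
  `pair_strands()`, `classify_znr_type()`, `detect_zn_site()`),
* structural superposition and TM-score alignment (`kabsch_superpose()`,
  `tm_score()`, `align_structures()`),
* identity-based redundancy clustering (`global_align_identity()`,
  `cluster_by_identity()`),
* dual-evidence consensus trees over clade-level similarity matrices
  (`build_channel()`, `single_linkage()`, `strict_consensus()`,
  `build_clade_tree()`),

plus synthetic-data generators that emulate the statistical and geometric
structure each stage assumes, so the whole pipeline is testable without
external databases. Profile searches (PSI-BLAST, JACKHMMER, HHpred), DALI
and alignment programs are upstream producers of this package's *inputs*;
they are deliberately not reimplemented, and DALI Z-scores / HHpred E-values
are consumed as given.

## Knuckle scanning and chelation states

Every 5-residue window is scored: +2 for cysteines at window positions 1 and
4, +1 if exactly one is present, plus +1 bonuses for proline at position 2
and glycine at position 5. The proline/glycine contributions are bonuses
rather than requirements because degraded knuckles -- the ones that matter
for the partial/lost analysis -- frequently deviate from the consensus.
`classify_chelation()` picks the best-scoring pair of non-overlapping hits
whose starts are 10--60 residues apart (configurable); these bounds stand in
for the structural requirement that the knuckles occupy the turns of
hairpins beta1/beta2 and beta4/beta5 of one small domain, which cannot be
checked in sequences lacking structures. The chelation state follows the
motif-cysteine count of the chosen pair: 4 = intact, 2--3 = partial,
<= 1 = lost. Sequences shorter than five residues return `lost` with no
hits rather than an error.

The sequence generator builds flank + knuckle + spacer + knuckle + flank,
with flanks, spacers and substitutions drawn from the 19 non-cysteine amino
acids. Restricting cysteine to the motif positions is what makes the planted
state exactly recoverable; it also means recovery rates measured on these
simulations say nothing about false knuckles arising from incidental
cysteine pairs in real proteins. States are assigned by largest-remainder
quota, not multinomially, so small test sets match the requested mix
exactly.

```{r}
sim <- simulate_knuckle_sequences(knuckle_sim_spec(n_sequences = 6, seed = 1))
data.frame(
  truth = sim$true_states,
  called = vapply(sim$records, function(r) classify_chelation(r)$state,
                  character(1)))
```

## Aromatic-cage profiles

`aromatic_fraction_profile()` computes, for each of the five cage columns,
the fraction of rows carrying Y/W/F/H among rows carrying any residue. Gaps
are excluded from the denominator by default -- conservation is a property
of the residues present -- and the per-column non-gap fraction is reported
as `coverage` so the choice is auditable; `include_gaps = TRUE` provides the
alternative denominator. Cage columns are user input, typically mapped from
an annotated reference structure via `map_cage_columns()`; automatic cage
detection from structure is out of scope. Within the aromatic class the four
letters are treated as one category, so the generator draws uniformly among
them: relative frequencies of Y vs W vs F vs H are not modelled.

## Zinc-ribbon typing from C-alpha geometry

Strand assignment uses C-alpha distance windows in the spirit of P-SEA
rather than hydrogen-bond (DSSP-style) assignment: the typing criteria are
purely topological, many deposited ZnRs lack complete backbones, and
C-alpha criteria keep the module free of heavy dependencies. Residue *i* is
strand-like when d(CA_i, CA_i+2) lies in [6.1, 7.4] A and d(CA_i, CA_i+3)
in [9.0, 11.1] A; runs of at least three such labels become strands. A
label at *i* attests the geometry of residues *i..i+3*, so a run ending at
*j* yields a segment ending at *j + 3* (capped at the next run): an
isolated ideal strand is covered in full, and the segments of antiparallel
partners stay in register. Strands are paired when at least two
sequence-consecutive residue pairs lie within 5.6 A (standard inter-strand
C-alpha distances are 4.5--5.2 A, plus tolerance). All thresholds are
exposed as arguments.

The decision table over sheet components is:

| strands | components | call |
|---|---|---|
| 4 | {b1,b2}, {b3,b4}, both hairpins | type1A |
| 5 | {b1,b2,b5}, {b3,b4} | type1B |
| 5 | {b1,b2}, {b3,b4,b5} | type2 |
| otherwise | -- | unclassified |

The five-stranded Cren7/SH3-like barrel deliberately maps to
`unclassified`: the analysis only needs to recognize that Cren7-like domains
*retain* ZnR topology in their hairpin turns, so no barrel class is
introduced. The circular-permutation relationship between type-1B and
type-2 is recorded in the evidence text, never detected automatically.
Because the original typology was assigned by expert inspection, borderline
real structures may legitimately disagree with this operationalization.

`detect_zn_site()` calls a site chelation-competent when some four-cysteine
subset has all pairwise ligand-atom distances within 8 A, using S-gamma
when present, else C-beta, else C-alpha with 1.5 A of extra slack (C-alpha
positions constrain the side chains only loosely).

### Idealized structure generator

`simulate_znr_structure()` builds textbook beta-geometry: pleated strands
with 3.8 A consecutive C-alpha spacing (3.35 A rise, +-0.9 A pleat, so
d(i,i+2) ~ 6.7 A and d(i,i+3) ~ 10.2 A), antiparallel partners at 4.8 A
sheet spacing with pleats in register, and turns/linkers made of 3.8 A
chords on circular arcs curved strongly enough that no connector residue is
ever strand-like. The default strand length is 8 residues, at the upper end
of what small beta-barrel domains show, which keeps automatic strand
detection stable; total domain sizes (41--67 residues) match the ~50--60
residue domains under study. The four knuckle cysteines sit at the two
chelating turn apices and carry S-gamma atoms placed at chelating distance
(2.3 A) from the implied zinc position, emulating the conserved chelation
geometry. The generator does not attempt realistic side-chain packing, loop
conformations, or the sequence diversity of real families; classification
accuracy on these models demonstrates that the decision table matches the
intended topologies, not that it is robust to real structural idiosyncrasy.

`noise_sd` (and `perturb_rigid()`'s `jitter_sd`) is the RMS *total*
displacement of each atom -- an isotropic 3D Gaussian with per-axis standard
deviation `noise_sd/sqrt(3)` -- matching how coordinate uncertainty is
usually quoted as a single RMS figure in angstrom. At 0.3 A RMS jitter,
planted types are recovered for >= 90% of seeds (the suite measures this
over 100 seeds per type); at zero noise recovery is exact.

```{r}
m <- simulate_znr_structure(znr_sim_spec("type2"))
classify_znr_type(pair_strands(m, assign_strands(m)))
detect_zn_site(m)
```

## Superposition and TM-score alignment

`kabsch_superpose()` is the closed-form least-squares fit (SVD with the
reflection excluded); degenerate inputs (fewer than three points,
collinear sets) are errors. The TM-score of an alignment is

    TM = (1/L_norm) * sum_i 1/(1 + (d_i/d0)^2),
    d0 = max(0.5, 1.24 * (L_norm - 15)^(1/3) - 1.8),

with distances taken under the superposition that maximizes the sum, found
by seeded iterative re-fitting on the close pairs. The 0.5 A floor on `d0`
matters for these ~50--60 residue domains.

`align_structures()` searches alignments deterministically: gapless
threading seeds (fragment lengths: full common length, half, and 20, the
last at a stride of 5 offsets) plus a secondary-structure seed matching
strand segments in order; each seed is refined by iterating superposition,
per-pair scoring `1/(1+(d_ij/d0)^2)`, global dynamic programming with
affine gaps (open 0.6, extension free -- terminal gaps therefore cost a
single opening), and re-fitting on pairs within `2*d0`, until the alignment
is stable (at most 30 rounds). Ties between seeds break toward more aligned
pairs, then the earlier seed, so results are bit-reproducible; there are no
stochastic restarts. Self-alignments give TM = 1 exactly, and swapping the
inputs under shorter-length normalization reproduces the same TM to 1e-6.

A faithful reimplementation of a published heuristic cannot promise
bit-identical output to that heuristic, so cross-implementation comparisons
of TM-scores should be read at fold-level resolution (~ +-0.05); that is
also the tolerance the test suite applies to the published Cren7-vs-ZnR
benchmark when its coordinate files are supplied (they are not shipped with
the package; see `tests/testthat/test-acceptance.R`).

## Identity clustering

`global_align_identity()` is an exact Needleman-Wunsch with match +1,
mismatch 0, linear gap -1 and a deterministic diagonal-then-up traceback;
identity is matches over alignment columns and coverage is the fraction of
the longer sequence aligned to residues. Exact dynamic programming replaces
BLAST-style heuristics because inputs are desk-scale and exactness is
reproducible. `cluster_by_identity()` connects sequences meeting both the
identity (S) and coverage (L) thresholds and takes connected components
(single linkage), mirroring classic BLAST-based redundancy clustering;
representatives are the longest members with lexicographic tie-breaks, so
output order is stable. Raising S can only split clusters, never merge
them.

## Consensus clade trees

E-values become similarities via -log10, clipped to [0, 300] (the cap
absorbs underflowed E = 0; values above 1 clip to 0); Z-scores are used
as-is, clipped at 0. Asymmetric matrices are symmetrized by the mean, a
one-sided missing value defers to the present direction, and cells missing
in both directions get similarity 0: absence of a reported hit is weak
evidence of dissimilarity in both source programs. Distances are
`s_max - s'` with a zero diagonal, so only similarity *ranks* matter to the
single-linkage topology (monotone rank-preserving transforms leave it
unchanged, a property the suite tests).

Single linkage is used because these domains are too small and divergent
for character-based phylogenetics; the dendrogram is a statement about
evidence strength, not branch lengths. Ties break toward the pair whose
lexicographically smallest member label is smallest, making the Newick
output platform-independent. Each evidence channel is clustered separately
and the strict consensus of the two dendrograms is reported, the reading of
"consensus clustering" most consistent with two parallel channels; with
exactly two inputs, strict and majority-rule consensus coincide. Kept
internal nodes carry support 2. The simulation default -- nine leaves in
three planted groups, within/between mean Z of 8/2 (and the same on the
-log10 E scale), unit noise, 10% missing cells -- represents a clearly
resolvable clade structure with realistic incompleteness; the suite
measures >= 95% recovery of all planted clades over 200 seeds.

```{r}
pair <- simulate_similarity_pair(clade_sim_spec(seed = 5))
newick_string(build_clade_tree(pair$evalue, pair$zscore))
```

## Numerical and interface choices

* Column indices are 1-based everywhere, as alignment figures cite them;
  PDB residue numbers are taken from the file, never renumbered, and
  insertion-code order is preserved.
* The gap character is `-`; `.` is normalized on read. Missing similarity
  cells stay missing at read time -- imputation is the consumer's decision.
* FASTA/Stockholm parsing is strict: duplicate identifiers, illegal residue
  characters and ragged alignments are errors naming the offending line or
  row, which matters more here than permissiveness.
* Synthetic PDB output is fixed-width ATOM records that round-trip through
  an independent reader (bio3d's), to %8.3f precision.
* All generators take explicit integer seeds and restore the caller's RNG
  state; identical seeds give identical objects, bit for bit.
* Problem sizes used by the test suite and the acceptance script (300
  sequences, 100--200 simulation seeds, 1000 random alignments, one million
  oracle quaternions) were chosen so the full suite runs in well under a
  minute per module on a single CPU while keeping binomial/Monte-Carlo
  margins comfortable.

## Command-line interface

A thin executable (`inst/cli/znrtools`) exposes the subcommands
`scan-knuckles`, `cluster-seqs`, `cage-profile`, `znr-type`, `superpose`,
`clade-tree` and `simulate` over the exported functions, with `--key value`
flags, an optional YAML `--config` (flags win) and `--verbose` logging to
stderr. The R functions remain the primary interface; the CLI adds nothing
the functions do not expose.

## Known limitations

* The typing decision table operationalizes a visual classification; real
  borderline structures (segment-swapped Ku/MarR-like ribbons, barrels with
  strand order variations) are reported `unclassified` by design.
* Chelation-state calling from sequence alone cannot verify that the
  cysteines are spatially adjacent; the spacing bounds are a proxy.
* The synthetic structures are idealized: recovery rates quantify the
  internal consistency of generator and classifier, not performance on
  deposited coordinates.
* DALI Z-scores and profile-profile E-values are inputs; nothing here
  reproduces their database-dependent statistics.
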