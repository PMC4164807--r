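---
title: "Evolutionary trace analysis of paralogous protein families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary trace analysis of paralogous protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etrace)
```

## The problem

Close paralogs — the beta-secretases BACE1 and BACE2 are the motivating
case — share fold, mechanism and most of their active site, yet differ in
substrate specificity and clinical relevance. The evolutionary trace (ET)
idea is that the residues responsible for such functional divergence are
those that are *invariant within each paralog group of orthologs but differ
between groups*, while residues required by the shared chemistry are
invariant across all groups. `etrace` implements this comparison for the
two-group case and joins the result onto crystal structures.

## The procedure

Given a multiple sequence alignment of orthologs spanning the two paralog
groups:

1. **Tree and partition.** Pairwise uncorrected p-distances (mismatch
   fraction over columns where neither sequence is gapped) feed a
   neighbor-joining reconstruction (`neighbor_joining()`). The tree is cut
   at a single edge into two leaf groups. `auto_partition()` picks the edge
   maximising the minimum between-group patristic distance — the deepest
   split — which for a family of two well-separated paralog clades is the
   edge between them. `partition_at_edge()` is the manual, authoritative
   override, because where a published analysis placed its cut is a choice
   the tree alone cannot always recover.
2. **Consensus and classification.** Within each group, every alignment
   column resolves to a single residue (gaps ignored), to `VARIABLE`
   (two or more residues), or to `ALL_GAP`. A column is `CONSERVED` when
   both groups resolve to the same residue, `GROUP_SPECIFIC` when both
   resolve to single but different residues, and `NEUTRAL` otherwise. The
   three classes partition the columns.
3. **ET sequence.** The classification renders as a string: the residue
   letter for conserved columns, `X` for group-specific, `-` for neutral.
4. **Structure mapping.** `map_to_query()` walks the query's alignment row,
   skipping its gaps, numbering residues from a user-supplied offset
   (crystal-structure numbering is rarely 1-based, and the offset is only
   recoverable from the PDB file itself, so it is an explicit input).
5. **Binding site and superposition.** A residue belongs to the
   ligand-binding site when any of its atoms lies within the cutoff
   (default 5.0 Å, closed interval) of any ligand atom. Two chains are
   compared by pairing C-alphas through a global sequence alignment and
   superposing the paired coordinates with the SVD-based Kabsch fit,
   reporting the residual RMSD.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| identity threshold | 80 (%) | `filter_by_identity()` keeps orthologs *strictly above* this global identity to the query ("more than 80%") |
| distance cutoff | 5.0 (Å) | binding-site membership, inclusive (`<=`) |
| chain | `"A"` | chain analysed in each structure |
| numbering offset | per query | first residue number in structure numbering |
| NW scoring | 1 / −1 / −2 | match / mismatch / per-gap; a simple linear scheme — identity filtering needs only a monotone similarity, not a substitution matrix |
| `--min-group-identity` analogue | none | within-group invariance is required at 100%; "conserved" is taken literally, with no majority fallback |

## Decisions where the design was open

- **Identity measure.** Selection of orthologs is defined by global
  alignment identity over non-gap aligned columns. It is deterministic and
  self-contained; any monotone similarity gives the same ranking near the
  threshold.
- **Distance model.** Uncorrected p-distance. At >80% identity,
  multiple-hit corrections change distances by far less than the
  between-paralog separation that determines the partition.
- **Columns conserved in one group, variable in the other** are `NEUTRAL`:
  group-specificity requires invariance in *both* groups, keeping the three
  classes a true partition and matching the trace-residue notion at a
  fixed partition.
- **Gap handling.** Gaps are ignored within a group; a column that is all
  gaps in some group cannot be called in that group and is `NEUTRAL`.
- **Negative NJ branch lengths** are clamped to zero with the deficit
  moved to the sister branch, preserving path lengths through the join;
  ties in the Q-criterion break by the lexicographically smallest pair of
  clade labels, so reconstruction is reproducible regardless of input
  order.
- **Ligand definition.** By default every non-water HETATM residue is the
  ligand. Peptidomimetic inhibitors are sometimes deposited as a short
  polymer chain, so `ligand_selection()` accepts a chain or residue-name
  override, which is the authoritative route when reproducing a published
  site table.
- **Inclusive cutoff.** "Within 5 Å" is read as a closed condition; a
  contact at exactly 5.000 Å is in the site.
- **Altlocs** keep the first conformer; occupancies are ignored for
  distances.

## The synthetic-data generator

`simulate_family()` emulates the data regime of a two-paralog ortholog
family: two groups of 7 sequences (a human query plus six mammals is the
typical ortholog panel), alignment length 501 (the length of human BACE1),
and column-status fractions 0.38 / 0.25 / 0.37, close to the
conserved/group-specific shares observed in the beta-secretase family.
Conserved and group-specific columns are invariant within groups by
construction; neutral columns draw residues from a small alphabet
(default 4 letters) with an extra per-sequence substitution rate
(default 0.1), and at least two distinct residues are forced within each
group so that a planted neutral column is genuinely variable. Because
planted invariance is never perturbed, classification must recover the
planted truth exactly — which is what the recovery tests assert, at any
noise level.

What the generator does *not* emulate: phylogenetic autocorrelation
(neutral substitutions are i.i.d. per sequence, not evolved along the
tree), indels beyond those the user writes in, rate variation, and
composition bias. Passing the recovery tests therefore shows the
classification logic and plumbing are correct, not that real families
with borderline within-group variation would be classified the way
another study classified them.

`simulate_complex()` builds an ideal alpha-helix (1.5 Å rise, 100° twist,
2.3 Å radius; or a straight chain at 3.8 Å spacing) with N/CA/C/O backbone
atoms and places ligand atoms at exact requested distances from chosen
C-alphas, radially outward. The true binding site is re-measured from the
coordinates as written to disk (PDB keeps 3 decimals), so boundary
fixtures at exactly the cutoff use the straight geometry, whose
coordinates are exact in 3 decimals.

## Numerical choices

- NW traceback tie-break: diagonal, then gap-in-second, then
  gap-in-first — fixed so alignments are reproducible.
- Kabsch uses the SVD with a determinant correction forcing a proper
  rotation; degenerate (collinear) inputs still return a valid rotation.
- Q-criterion ties and the auto-partition's ties (equal minimum
  separation) break deterministically: most balanced split, then label
  order.
- Percentages report at one decimal, matching how such fractions are
  conventionally quoted (189 of 501 residues → 37.7).

## Problem sizes in the shipped tests

The test-suite simulations use alignments of 60–200 columns with 4–7
sequences per group across roughly a hundred seeds, toy complexes of up to
390 residues, and brute-force oracles (exhaustive alignment enumeration up
to length 8, all-pairs distance scans, quaternion-grid rotation search)
on correspondingly small instances. These sizes were chosen so each oracle
remains obviously correct and the whole suite runs comfortably on a
laptop; recovery results are exact, not asymptotic, so larger instances
add cost without adding evidence.

## Known limitations

- Only two-group partitions; the full multi-rank trace of the original ET
  method (sweeping partitions down the tree) is out of scope.
- The crystal structures of the worked example (PDB 1FKN and 2EWY) are not
  distributed with the package; drop `1fkn.pdb` and `2ewy.pdb` into
  `inst/extdata/` to activate the structure-dependent checks and the
  real-structure entries of the acceptance report. The packaged
  binding-site table ships instead as `bace_binding_sites.tsv`.
- C-alpha pairing for superposition is sequence-alignment based; pair
  counts from structure-based alignment methods can differ by a few
  residues for divergent pairs.
- No mmCIF parsing, no solvent accessibility, no figure rendering.
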