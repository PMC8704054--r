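---
title: "Methods: the QTY substitution engine and its comparison battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the QTY substitution engine and its comparison battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtykit)
```

## The problem and the model

Integral membrane proteins of the 7TM (GPCR) architecture carry seven
α-helices whose lipid-facing residues are strongly hydrophobic — dominated
by leucine, isoleucine, valine and phenylalanine. Outside a bilayer or a
detergent micelle these proteins aggregate. The QTY code is a minimal
design rule for water-solubilizing them: inside the transmembrane segments,
replace each of those four residues with a polar, uncharged residue of
similar side-chain shape:

| from | to | rationale |
|------|----|-----------|
| L    | Q  | similar side-chain volume, amide replaces alkyl |
| I    | T  | β-branched for β-branched |
| V    | T  | β-branched for β-branched |
| F    | Y  | aromatic for aromatic, adds one hydroxyl |

Only the source set {L, I, V, F} and target set {Q, T, Y} are fixed by the
code; the per-residue pairing above is the canonical one from the original
design work and is shipped as *data* (`qty_map()`), not logic, so that
alternative codes — e.g. replacing Q/T/Y by alanine, arginine or glycine to
probe helix propensity — are one `substitution_map()` call away.

Because the transform substitutes in place, native and variant share one
coordinate system: identity is positional (no gaps, no aligner), the
variant differs from the native exactly at the recorded events, and
re-applying the map to a variant is a no-op (Q, T, Y are not sources).
These three facts are enforced as property tests.

## Substitution scope

Scope is a set of segment kinds, default `{TM}`. Published QTY designs
sometimes additionally modify residues in intracellular loops and the
C-terminus; which residues is a per-design choice that cannot be derived
from any rule, so the engine exposes it as an explicit
`extra_positions` override rather than guessing. Under TM-only scope the
reproduced identity and mass deltas for real receptors are expected to land
close to, but not exactly on, published per-design values — the published
designs' extra-TM edits are the residual.

## Segment annotations

TM boundaries are *input*, not something the package tries to recover:
curated segment tables (TSV: `label, kind, start, end`, 1-based inclusive)
or UniProt `FT TRANSMEM` features are authoritative. A Kyte–Doolittle
sliding-window scan (`infer_tm_segments()`, window 19, threshold 1.6,
minimum run 15 — the classic TM-scan settings) exists strictly as a
fallback of documented lower quality; whenever both sources are available
the table wins. All sequence coordinates are 1-based inclusive (the UniProt
feature convention); conversions happen only inside implementations.

Sequences are validated strictly: the 20 standard one-letter codes only.
Ambiguity letters (B, Z, X) and non-standard residues (U, O) are rejected
rather than guessed because substitution, mass and charge computations need
exact identities.

## Physical chemistry

Molecular weight is the sum of *average* residue masses plus one water
(18.0153 Da), the Expasy Compute pI/MW convention, so deltas are comparable
with values computed there. Mass deltas are computed from unrounded sums
and only rounded (2 decimals, half-up) for reporting; this keeps the
per-event conservation law — pair ΔMW equals the signed sum of
(target − source) residue masses — tight to well under 0.01 Da. The
per-event deltas of the QTY alphabet are +14.97 (L→Q), −12.05 (I→T),
+1.97 (V→T) and +16.00 Da (F→Y): QTY variants are always within a few
percent of native mass.

Net charge at a given pH is the Henderson–Hasselbalch sum: positive terms
for the free N-terminus, K, R and H (`1/(1+10^(pH−pKa))`), negative terms
for the free C-terminus, D, E, C and Y (`−1/(1+10^(pKa−pH))`). The default
pKa set is the Bjellqvist set as deployed by Expasy, including the
residue-specific N-terminal α-amino pKas; the classic Lehninger set ships
as an alternative. Cysteines are treated as free (no disulfide correction),
again matching Expasy. Both sets live in editable TSVs under
`inst/extdata/tables/`.

Every term of the charge sum is strictly decreasing in pH, so the
isoelectric point is the unique zero; it is found by bisection on [0, 14]
to a 0.001 tolerance and reported to 2 decimals. The test suite checks the
bisection against an independent composition-based grid scan (step 1e-3,
linear interpolation at the sign change) on 1,000 random sequences for
both pKa sets. Because Q and T are non-ionizable and tyrosine's phenol
(pKa 10) is barely ionized at neutral pH, QTY substitution moves the
pH-7 charge by less than 0.001 per added tyrosine — which is why published
QTY pairs show pI shifts of only a few hundredths of a unit.

## Structure comparison

PDB input uses a fixed-column parser (no structural-bioinformatics R
package is assumed): first MODEL by default, HETATM ignored, alternate
locations resolved to the highest-occupancy conformer with ties going to
altLoc `A`.

Residue correspondence between a native structure and its variant is by
residue number within a chosen chain pair (`match_residues()`), with
intersection semantics so crystal-structure gaps simply drop out — valid
precisely because QTY pairs are substitution-only and share numbering. A
guard requires ≥ 30% identical residue names over the matched set to catch
mispaired chains; a flexible structural aligner is deliberately out of
scope. Superposition is the Kabsch algorithm: centroid shift, SVD of the
3×3 covariance, and a sign correction that forces det(R) = +1 so
mirror-image inputs are never "solved" by a reflection. RMSD is computed
over Cα atoms only — side chains differ by construction in a QTY pair, so
all-atom RMSD would be meaningless. The implementation is checked against
an independent quaternion-eigenvector (Horn) solver to 1e-6 on random
instances. Published RMSDs for real receptor pairs (about 1.0–1.4 Å) come
from flexible alignments of predicted full structures and are not asserted
by this package's tests; they are desk-unreproducible without those model
files.

`trim_to_segments()` restricts a model to TM residues before superposition,
mirroring the practice of comparing 7TM bundles with termini and loops
removed.

## Ideal-helix and bundle fixtures

`build_ideal_helix()` places Cα i at angle `i·100°` and height `i·1.5 Å` on
a cylinder of radius 2.3 Å — the canonical α-helix constants (3.6 residues
and 5.4 Å per turn). The radius is the standard Cα helical radius; it is
needed by the generator but not by the recovered rise/twist.
`helix_geometry()` re-measures these constants from coordinates alone: the
axis is initialized by principal components and refined by a least-squares
cylinder fit (minimizing the variance of radial distances — exact for
noiseless helices, where plain PCA alone is biased at the 1e-2 level for a
36-residue helix); rise is the mean per-residue axial translation and twist
the mean angular offset about the fitted axis. The acceptance report
regenerates a 36-residue helix and recovers 1.5 Å and 3.6 residues/turn to
machine precision.

`build_bundle()` arranges ideal helices with vertical axes equally spaced
on a circle (default radius 9.5 Å, a 7TM-like packing), alternating
up/down orientation as in an antiparallel bundle. With a sequence and
annotation, each TM segment provides one helix carrying the real residue
numbers and names — which is how the synthetic native/variant bundle pair
gets *identical coordinates with relabelled residues*, the cleanest
possible test bed for the surface contrast.

## Solvent-accessible surface and hydrophobic patches

SASA is Shrake–Rupley: for each atom, points quasi-uniformly distributed on
the expanded sphere (radius r_atom + 1.4 Å probe) are tested against all
neighbouring expanded spheres; the accessible fraction scales the analytic
sphere area. The point set is a deterministic golden-spiral lattice — no
RNG, so SASA is bit-reproducible; 960 points/atom keeps the single-sphere
error under 1% and the 7-helix-bundle total stable to < 0.5% under point
doubling. Radii are a united-atom vdW set (C 1.70, N 1.55, O 1.52, S 1.80
Å) in an editable TSV.

The hydrophobic set defaults to exactly {L, I, V, F} — the four residues
the QTY code touches — so the native-vs-variant contrast is not diluted by
apolar residues the code leaves alone; an extended set adding A, M, W, C is
available. The hydrophobic exposed fraction is the summed SASA of
hydrophobic-set residues over total SASA; on identical coordinates, QTY
relabelling can only remove members from the set, so the fraction can only
decrease — asserted as a property. Patches are connected components of
exposed hydrophobic residues (per-residue SASA > 10 Å²) linked when
Cα–Cα ≤ 8 Å. The thresholds are stated defaults, tunable per call: no
published numeric patch definition exists (the contrast is shown visually
in the literature), which is why patch acceptance is property-based rather
than value-based.

## The synthetic 7TM generator: what it does and does not emulate

`synth_7tm_sequence()` emits an N-terminal polar stretch (25–40 aa), seven
TM segments of 20–25 residues drawn from {L, I, V, F, A, G}, alternating
intracellular/extracellular polar loops (10–25 aa) and a C-terminal tail
(40–60 aa) — about 350 residues, a typical chemokine-receptor length. TM
composition weights put the expected L+I+V+F share at 52%, the middle of
the ~46–58% membrane-variation band observed for real GPCR QTY designs,
so the synthetic pair exercises realistic substitution densities. All
randomness flows through an explicit seed; fixture files are byte-identical
across re-runs.

What a green test on this fixture establishes: the engine's bookkeeping
(events, rates, deltas), the conservation laws, and the direction and
rough magnitude of the surface contrast. What it does not establish:
agreement with any particular receptor's published identity/ΔMW/ΔpI values
(real designs modify extra-TM residues by hand), real side-chain packing
(bundles are Cα-only cylinders), loop geometry, or anything about
prediction quality of externally supplied models. The
battery over real UniProt entries (`receptor_battery()`) covers the former
gap but requires a one-time network fetch; offline it reports its inputs
as missing and the corresponding acceptance test fails loudly rather than
silently skipping.

## Numerical choices and degenerate inputs

- Percentages, pI and masses are reported to 2 decimals, half-up (matching
  printed conventions like "67.05%"); internal computation is unrounded.
- Kabsch requires ≥ 3 non-collinear points (collinearity detected via the
  second singular value of the centred reference).
- `infer_tm_segments()` scores only full windows; ties and plateaus need no
  tie-break because run extraction is deterministic.
- Empty patch reports are valid outputs, not errors; an annotation that
  covers nothing present in a model is an error.
- The bisection bracket [0, 14] always straddles the root because the
  termini alone guarantee a positive charge at pH 0 and a negative one at
  pH 14.

## Known limitations

- No gapped alignment: pairs whose lengths differ are rejected by design.
- SASA is O(n²) in atoms in pure R — fine for Cα bundles and single-chain
  receptors (seconds), not tuned for large complexes.
- The UniProt flat-text reader consumes only `AC`/`ID`, `FT TRANSMEM` and
  the `SQ` block; full flat-file or XML parsing is out of scope.
- Topology (inside/outside) prediction, signal peptides, disulfide
  corrections and PTMs are out of scope.
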