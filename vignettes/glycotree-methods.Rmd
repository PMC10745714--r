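---
title: "Tree-based conformer sampling of oligosaccharides: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-based conformer sampling of oligosaccharides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A gas-phase oligosaccharide folds under three nested constraints, and
`glycotree` enumerates conformers exactly along that hierarchy.

**Glycosidic linkage classes (region SI).** Each glycosidic bond is
restricted to two torsional basins: *cis* (syn/syn), applied as
Φ = −80°, Ψ = 90°, and *trans* (anti/syn), applied as Φ = 50°, Ψ = 120°,
with Φ = O5(child)–C1(child)–O(bridge)–Cx(parent) and
Ψ = C1–O(bridge)–Cx–C(x−1)(parent). The presets are applied *exactly*,
not approximately: these structures are pre-optimization seeds, and
exactness makes geometry testable to 10⁻⁶ degree. For 1→6 linkages the
extra exocyclic torsion ω (O6–C6–C5–O5 of the parent) defaults to the gg
staggered rotamer (−60°) unless a hydrogen-bond chain repositions it; no
ω values are part of the class definition.

**Hydrogen-bond chain motifs (region SII).** Conformer families
("groups") are distinguished by cooperative chains of
O–H···O / N–H···O bonds written in arrow notation: in
`OH4_M -> OH3_M -> OH2_M -> OH3'` each site donates its hydrogen to the
next site's oxygen, so the acceptor of one step is the donor of the
next. Chains may terminate on acceptor-only oxygens: ring oxygens,
glycosidic bridge oxygens, or a bare anomeric oxygen. A bond "counts"
when the donor-oxygen to acceptor-oxygen distance is **strictly below
2.8 Å**. Whether that printed criterion refers to the heavy-atom or the
H···O separation is not stated in the source material; we chose the
heavy-atom reading because the dotted bond annotations in structure
figures connect oxygen positions, and we expose the threshold (and an
optional D–H···A angle filter, off by default) through
`hbond_criteria()`.

**Cooperative directions (region SIII).** A reversible chain can run
clockwise or counterclockwise; reversal drops terminal acceptor-only
oxygens and inverts the hydroxyl backbone
(`OH6_M -> OH6' -> OH6 -> OG` becomes `OH6 -> OH6' -> OH6_M`). The
conformer count of a group is the product of 2 over its reversible
units minus the direction combinations removed by conflict rules:

* *mutual pointing* — for a declared pair of facing sites (e.g. the
  mannose OH6/OH4 pair across the ring), a conflict fires when each side
  is oriented toward the other: it either ends a chain as a free
  terminal acceptor (its hydrogen unconstrained, pointing back) or
  donates directly to the other site, with at least one side a free
  terminal acceptor;
* *double donation* — one hydroxyl cannot donate in two chains;
* *orientation clash* — a chain cannot use a donor whose position was
  consumed by a glycosidic bond (condensation removed the hydrogen it
  would donate).

The source text states *which* variants are high-energy but gives no
quantitative geometric definition of "pointing at each other"; the rule
above is an operational reconstruction, and facing pairs are therefore
declared **per group** in the catalog data rather than derived globally
— the same site pair conflicts on the trans–trans₁ skeleton but not on
the cis–cis₁ one, where the rings fold differently.

## Catalogs are data

The group inventories are themselves a curated scientific object, so
they ship as JSON under `inst/extdata/catalogs/`, separate from the
enumeration engine: each group lists its linkage classes, chain units
with reversibility flags (composite units may give the reversed
realization explicitly — the long trisaccharide lower chain reverses
only its mannose segment while the amide relay keeps its direction),
facing pairs, and an expected count that `validate_catalog()` checks
against the derived count. Users can define new molecules without
touching code.

Two caveats on fidelity. For the cis–cis₁ trisaccharide groups L, M, N
and the upper chains of group O, the defining figure content is not
reproduced in the text we worked from; their chains are plausible
reconstructions that honour the stated counts (8, 8, 8 and 4) and the
stated conflict ("the clockwise M-ring direction conflicts with the
OH6_M orientation"). Similarly the chitobiose block conformations and
the strategy-3 pentasaccharide groups reference prior work we do not
have; they are minimal plausible encodings, marked as such. The group Q
upper chain is encoded as `OH3' -> OH6_M` where the text prints
`OH3 -> OH6_M`; the printed form would make OH3 of the reducing ring
donate in two upper chains at once, so we read it as a prime-mark typo.

## Geometry: an idealized, deterministic kernel

Templates are idealized ⁴C₁ pyranose chairs: the six ring atoms sit on
an analytically exact tetrahedral chair with **uniform 1.50 Å ring
bonds** (the exact chair requires equal bonds; mixing C–C 1.53 Å and
C–O 1.43 Å inside the ring would leave a closure gap, and these are
seeds for external optimization anyway). Exocyclic bonds use standard
lengths (C–C 1.53, C–O 1.43, O–H 0.96, N–H 1.01, C=O 1.22 Å) and
tetrahedral angles. Mannose carries axial hydroxyls at C1 and C2,
equatorial at C3 and C4; GlcNAc is all-equatorial with the acetamido
group at C2 (standard β-D-GlcNAc; the source only gives the structural
formula). Torsion signs follow the IUPAC convention throughout; the
source never states its sign convention, so the cis/trans presets are
applied in IUPAC signs.

Glycosidic condensation removes the child's anomeric hydroxyl (O + H)
and the parent's hydroxyl hydrogen — three atoms per linkage — and the
parent oxygen becomes an acceptor-only bridge site. The split-line
upper/lower partition is realized as the least-squares plane through the
named ring oxygens, oriented so most hydroxymethyl carbons fall on the
positive (upper) side; sites on the plane itself count as upper, with a
10⁻⁷ Å tolerance absorbing rigid-motion float noise.

## Rotamer solving

Chains are solved sequentially from each chain's first donor. A donor
hydroxyl torsion is chosen by a 5° grid scan plus golden-section
refinement minimizing the H···acceptor distance, ties broken toward the
smaller absolute torsion; on single-torsion instances this matches an
exhaustive 1° scan (a property test asserts it). When a hydroxymethyl
group must donate or accept, its ω torsion is set **once** to bring the
moving oxygen to an ideal O···O separation of 2.7 Å (just inside the
2.8 Å criterion) and then held, so later steps of a relay cannot break
earlier ones; plain distance minimization is the wrong objective for a
torsion that moves a heavy atom (it collapses the oxygens onto each
other). Steps whose heavy-atom separation still fails the criterion are
reported as infeasible, not fatal — on idealized seeds some printed
bonds (e.g. long M-ring to reducing-ring contacts) are genuinely out of
reach before optimization, mirroring bonds that disappear during
external optimization. Unconstrained hydroxyls finish in the staggered
rotamer (60°, −60°, 180°) farthest from any other hydrogen. Non-bonded
heavy atoms closer than 1.8 Å produce a warning, never a rejection:
pruning is by hydrogen-bond conflicts, not steric scoring.

## Pentasaccharide block combination

Strategy 1 crosses the three lowest-energy trimannose blocks with the
two lowest-energy trisaccharide blocks (selection: annotated relative
energy ≤ 10 kJ/mol). Inherited chains are adapted to the
pentasaccharide topology by dropping every step whose donor or acceptor
position was consumed by a linkage — this single rule reproduces both
documented issues with the duplicated central mannose (its OH6 carries
the 1→6 bond and can no longer donate; its OH3 likewise) — and when the
shared OH2 would donate in both parent blocks, only the
trisaccharide-side bond (OH2→OH3 of the adjacent GlcNAc) is kept, since
the OH2→ring-O variant duplicates a strategy-2 configuration: 3 × 2 = 6
configurations. Strategy 2 crosses 3 trimannose × 2 chitobiose blocks
with a free cis/trans class on the junction linkage: 12. Strategy 3
builds 4 groups from the 2 × 2 choices of which neighbour (disaccharide
or central mannose) the upper and lower terminal mannoses hydrogen-bond
to. Directions are not re-expanded inside blocks — cooperative
directions were fixed when the blocks were analysed.

The shipped block energies are **synthetic stand-ins** (files are marked
`synthetic`): true block energies require external quantum chemistry.
The one real number among them, a 20.1 kJ/mol trimannose conformer, sits
outside the 10 kJ/mol window and exercises the selection. Counts (6, 12,
4) do not depend on the stand-in values, only on how many blocks pass
the window (3, 2, 2), which matches the documented selections.

## Spectra and thermochemistry

Externally computed harmonic modes are scaled by type — 0.9734 for O–H
stretches, 0.9600 for N–H stretches — or by the single global factor
0.9603 used with the cheaper B3LYP/6-31G* level on large systems;
whether that global factor applies beyond stretches is not stated, so
the package applies it to every mode under the `use_global` switch and
documents the choice here. Band envelopes are sums of
normalized Gaussians or Lorentzians (default FWHM 15 cm⁻¹, a typical
width for comparison with ion-dip spectra), so the integrated envelope
equals the summed stick intensities. Boltzmann populations use
w ∝ exp(−ΔG/RT) with R = 0.008314 kJ/(mol·K), T = 298.15 K by default;
weights are invariant under energy offsets and sum to one to 10⁻¹².
`rank_conformers()` sorts stably by 0 K energy or 298.15 K Gibbs energy
and reports rank changes between the two — the reordering between 0 K
and room temperature is exactly what makes high-temperature energetics
necessary when assigning experimental spectra. Unit conversions from
hartree use 627.509474 kcal/mol × 4.184.

## What a green test does and does not establish

The test suite establishes: exact torsion presets; exact per-group
conformer counts, equal to an independent brute-force expansion of all
direction assignments filtered by the conflict rules; the strict 2.8 Å
detector boundary (located by bisection to 10⁻³ Å); solver optimality on
single-torsion instances; round-trip fidelity of every file format; and
the stated invariances (rigid motion, energy offsets, area
conservation). It does **not** establish that the built structures are
low-energy — that verdict belongs to the external quantum-chemistry
engine the package writes inputs for — nor that the reconstructed
figure-only chains (cis–cis₁ L/M/N/O uppers, chitobiose blocks,
strategy-3 groups) match the original figures bond-for-bond; they match
the published counts and conflict statements.

## Known limitations

* Idealized seeds: no ring-pucker variation (⁴C₁ only), no energy
  minimization, no force field; some printed hydrogen bonds are
  geometrically infeasible before optimization and are reported as such.
* Mannose and GlcNAc only; other residues (Glc, Gal, Fuc...) would need
  new templates.
* Hydrogen-bond detection is distance-based; no CH···O or bifurcated
  bonds, no energetic scoring.
* The amide seed orientation is planar-idealized; close contacts around
  the acetamido group in some conformers are left to the external
  optimizer (warnings, not rejections).
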