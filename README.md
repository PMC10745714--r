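# glycotree

Tree-based conformer generation for gas-phase oligosaccharides.

## The problem

Gas-phase structure assignment of oligosaccharides (IRID/IRMPD
spectroscopy plus quantum chemistry) needs good starting conformers, but
full-space conformational searches of even a trisaccharide produce far
more candidates than DFT can digest, while still missing chemically
obvious hydrogen-bonded folds. For flexible polyols the low-energy
structures are organised by three nested choices, which this package
turns into a systematic, *enumerable* building tree:

1. **SI — glycosidic linkage classes.** Each glycosidic bond sits in one
   of two (Φ, Ψ) basins: *cis* (syn/syn, Φ = −80°, Ψ = 90°) and *trans*
   (anti/syn, Φ = 50°, Ψ = 120°), with
   Φ = O5(child)–C1(child)–O(bridge)–Cx(parent) and
   Ψ = C1–O(bridge)–Cx–C(x−1).
2. **SII — inter-ring hydrogen-bond chain motifs.** Cooperative relays of
   O–H···O / N–H···O bonds written in arrow notation
   (`OH6_M -> OH6' -> OH6 -> OG`: each site donates its hydrogen to the
   next site's oxygen). A geometric criterion (heavy-atom distance
   strictly below 2.8 Å) decides which bonds count.
3. **SIII — cooperative directions.** Each reversible chain can run
   clockwise or counterclockwise; conflict rules (two hydroxyls pointing
   at each other, double donation, donors consumed by a glycosidic bond)
   prune impossible combinations.

The package ships curated motif catalogs for the N-glycan fragments
Manβ(1,4)GlcNAcβ(1,4)GlcNAc (20 groups, A–T) and the branched trimannose
Manα(1,3)[Manα(1,6)]Man (13 groups, A–M), three block-combination
strategies that assemble the core pentasaccharide
Manα(1,3)[Manα(1,6)]Manβ(1,4)GlcNAcβ(1,4)GlcNAc from those blocks, a
geometry kernel (idealized ⁴C₁ pyranose templates, Z-matrix builder,
torsion setting, hydroxyl rotamer solving), and post-processing for
externally computed spectra and energies (mode-type harmonic scale
factors 0.9734/0.9600, global 0.9603; Gaussian/Lorentzian band
envelopes; Boltzmann populations at 298.15 K). Structures are
*pre-optimization seeds*: the package writes XYZ/PDB files and
B3LYP/MP2 input decks, and reads frequency/energy tables back — it never
runs quantum chemistry itself.

## Worked example

```r
library(glycotree)

res <- enumerate_conformers(builtin_catalog("trisaccharide-trans-trans1"))
res
#> <enumeration_result 'trisaccharide-trans-trans1': 4 conformers in 2 groups>
#>  group count
#>      A     3
#>      B     1
```

Two groups share the trans–trans₁ skeleton: group A (cooperative upper
and lower relays, 2 × 2 directions minus the variant where OH6 and OH4
of the mannose point at each other = 3 conformers) and group B (fixed
upper bonds, one surviving lower direction). Each conformer carries its
built 78-atom structure and the hydrogen bonds the rotamer solver
realized:

```r
res$conformers[[1]]$realized[, c(1, 2, 3, 4, 5)]
#>   donor donor_residue acceptor acceptor_residue distance
#> 1   OH6             M      OH6               G' 2.700000
#> 2   OH4             M      OH3                M 2.799381
#> 3   OH3             M      OH2                M 2.799381
#> 4   OH3            G'     NHCO               G' 2.066409
#> 5  NHCO            G'      OH3                G 2.602620
#> 6   OH3             G     NHCO                G 2.066409
```

All distances sit strictly below the 2.8 Å criterion. Population
weighting of two conformers separated by 4.1 kJ/mol in Gibbs free energy
at 298.15 K:

```r
round(boltzmann_weights(c(0, 4.1)), 3)
#> [1] 0.839 0.161
```

The same workflow from the shell (`exec/glycotree`):

```sh
glycotree enumerate --catalog trisaccharide-trans-trans1 --out out/
glycotree build --catalog trimannose --conformer A1 --out A1.gjf \
    --format qm --level "B3LYP/6-311+G*" --task opt
glycotree spectra --freqs freqs.tsv --fwhm 15 --out envelope.tsv
glycotree rank --energies energies.tsv --key gibbs298
glycotree validate-catalog --catalog my_catalog.json
```

Pentasaccharide catalogs are built at run time from low-energy blocks:

```r
penta <- combine_blocks(2)            # 3 x 2 blocks x {cis, trans} junction
total_conformers(enumerate_conformers(penta, build_structures = FALSE))
#> [1] 12
```

## Layout

- `R/` — geometry kernel, templates, linkage builder, hydrogen-bond
  model, enumerator, block combination, spectra/thermo, I/O, CLI
- `inst/extdata/catalogs/` — motif catalogs (JSON; groups are data, not
  code)
- `inst/extdata/blocks/` — block sets with synthetic stand-in energies
- `vignettes/glycotree-methods.Rmd` — model, assumptions, numerical
  choices, limitations
- `tests/testthat/` — unit, property and acceptance suites
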