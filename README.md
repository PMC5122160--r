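# cif2print

Batch conversion of crystal structures (CIF) into watertight, 3D-printable
ball-and-stick mesh models.

## The problem

3D-printed crystal structures are valuable teaching and research props, but
turning a Crystallographic Information File into a printable file by hand is
tedious: the asymmetric unit must be expanded by the space-group symmetry
(and, for extended solids, packed into a unit cell), solvent molecules and
counterions stripped, the structure scaled to printable dimensions, and the
geometry exported as a *closed* surface — printers reject meshes with open
cylinder ends, missing sphere triangles, or inconsistently wound faces.
`cif2print` automates the whole chain for any number of CIFs.

## Method

For each CIF the pipeline:

1. parses cell parameters `(a, b, c, α, β, γ)`, xyz symmetry operators and
   fractional atom sites (CIF 1.1, old and new symmetry tags);
2. applies every operator `x' = R x + t` to every site, wraps into `[0, 1)`,
   orthogonalizes (`a` along x, `b` in the xy plane — Cartesian distances
   equal metric-tensor distances `√(Δxᵀ G Δx)`), and merges duplicate
   images; `--packed` mode additionally retains every lattice translate
   whose fractional coordinates lie within one cell (±1e-4), so corner
   atoms appear on all 8 corners;
3. perceives bonds with the covalent-radius rule
   `0.4 Å < d ≤ r_cov(i) + r_cov(j) + 0.45 Å` (no H–H bonds);
4. partitions atoms into connected fragments and keeps the one with the
   most atoms — equal-sized fragments (enantiomer pairs) are tied-broken
   deterministically by lowest atom index; `--per-molecule` exports every
   fragment instead;
5. builds one geodesic sphere per atom (23% of the van der Waals radius)
   and two colour-split half-bond cylinders per bond, scales everything
   tenfold (1 Å → 10 model units, read as mm), each shell independently
   closed and outward-wound;
6. writes VRML 2.0 (indexed face sets with per-vertex colour — never
   Sphere/Cylinder/Cone primitives) and binary or ASCII STL
   (exactly `84 + 50 n` bytes in binary).

`validateShell()` checks the printability contract: 0 boundary edges,
0 non-manifold edges, consistent winding, positive signed volume, no
degenerate triangles.

## Worked example

```r
library(cif2print)

# a synthetic P-1 co-crystal: 10-atom molecule + 2 solvents + counterion
fx <- makeFixture("cocrystal")
writeLines(fx$cif, "cocrystal.cif")

rec <- readCif("cocrystal.cif")
rec
#> StructureRecord 'cocrystal_seed0': 17 site(s), 2 symmetry operator(s)
#> CrystalCell: a=26.0000 b=18.0000 c=18.0000 A  alpha=90.00 beta=90.00 gamma=90.00 deg  V=8424.00 A^3
#>   asymmetric unit: Cx10 Clx1 Hx4 Ox2

atoms <- expandSymmetry(rec)                    # 34 atoms after P-1 expansion
frags <- findFragments(atoms, perceiveBonds(atoms))
vapply(frags, natoms, integer(1))
#> [1] 10 10  3  3  3  3  1  1

selectPrimary(frags)
#> Fragment: 10 atom(s), 9 bond(s); atom indices 1,3,5,7,9,11,13,15,...

convertStructure("cocrystal.cif", jobConfig(outputDir = "."))
#>             file status reason nFragments keptAtoms deletedFragments          outputs
#> 1 cocrystal.cif      ok                8        10                7 cocrystal.wrl;cocrystal.stl
```

The 8 fragments are the two symmetry copies of the molecule, four solvent
copies and two counterions; only one 10-atom molecule survives (7 fragments
deleted) and is exported as `cocrystal.wrl` / `cocrystal.stl` (10 spheres +
18 half-bonds, 4352 triangles, 217,684 bytes of binary STL = 84 + 50·4352).
Every shell passes validation:

```r
str(validateShell(icosphere(c(0, 0, 0), 1, 2)))
#> $ boundaryEdges        : int 0
#> $ nonManifoldEdges     : int 0
#> $ orientationConsistent: logi TRUE
#> $ signedVolume         : num 4.05
#> $ degenerateTriangles  : int 0
#> $ watertight           : logi TRUE
```

For extended solids use `jobConfig(mode = "packed")`: the rock-salt fixture
packs to 27 atoms forming one connected network, which is exported whole.

## Command line

```sh
Rscript inst/cli/cif2print.R convert my.cif --format vrml,stl --out models/
Rscript inst/cli/cif2print.R convert solid.cif --packed
Rscript inst/cli/cif2print.R batch list.txt --per-molecule --out models/
Rscript inst/cli/cif2print.R validate models/my.stl
Rscript inst/cli/cif2print.R make-fixture cocrystal --seed 3
```

Batch runs isolate failures per file and end with an `ok/failed` summary;
exit status is 0 iff every file converted.

## Limitations

Bond perception is distance-based only (no bond orders, no
metal-coordination special cases); disordered sites with occupancy < 0.5
are dropped and the rest treated as fully occupied; when a counterion out-
numbers the molecule of interest the counterion wins the size-based
selection — use `--per-molecule` to keep everything. See the methods
vignette (`vignettes/cif2print-methods.Rmd`) for the full design rationale.
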