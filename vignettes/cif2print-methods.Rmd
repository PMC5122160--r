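---
title: "From crystallographic data to printable meshes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From crystallographic data to printable meshes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cif2print)
```

# The conversion model

`cif2print` treats a crystal structure as three layers of data. The **CIF
layer** carries the unit cell, the space-group operators in xyz form, and
the asymmetric unit in fractional coordinates. The **chemical layer** is
derived: symmetry images of the sites, a distance-based bond graph over
them, and the connected components of that graph (molecules, or the bonded
network of an extended solid). The **geometry layer** is one closed
triangle-mesh shell per atom and per half-bond, in output model units.

The pipeline commits to a specific, opinionated reading of "make this CIF
printable": apply the symmetry so whole molecules appear; keep the largest
connected fragment (the molecule of interest in most small-molecule
structures, the whole network in an extended solid); scale tenfold so a
molecule a few Angstrom across becomes a model a few centimetres across in
millimetre units; and guarantee that every emitted shell is independently
watertight so printer software can union them.

## Symmetry expansion

Operators are parsed exactly from their xyz grammar (`"-x+1/2, y, -z"`),
with fractional and decimal translations treated identically and reduced
into $[0, 1)$. Every (site, operator) image is generated, wrapped into the
unit cell, and orthogonalized with the standard convention ($a$ along the
first Cartesian axis, $b$ in the first–second plane), so Cartesian
distances agree with metric-tensor distances
$\sqrt{\Delta x^\top G\, \Delta x}$ to machine precision — the test suite
holds this to $10^{-9}$ Å over a thousand random triclinic cells.

Special positions make images coincide; images of the same element closer
than `dedupTol` merge, the copy with the lowest (site, operator) provenance
surviving. **`dedupTol` defaults to 0.01 Å**: CIF coordinates are printed
to 4 decimal places, so genuine duplicates agree to about $10^{-4}$ of a
cell edge ($\sim 10^{-3}$ Å for typical cells), while real interatomic
contacts are two orders of magnitude larger. Close contacts between
*different* elements are never merged — they usually indicate disorder and
are reported, not silently altered.

Packing (for extended solids) starts from the expanded images and keeps
every lattice translate, over shifts $\{-1, 0, \dots, r\}$ per axis, whose
fractional coordinates all lie within $[-\varepsilon, r + \varepsilon]$.
**`boundaryEps` defaults to $10^{-4}$ fractional**: large enough to catch
printed-precision atoms sitting on a face, small enough never to admit an
interior atom's neighbour-cell copy. An atom exactly on a corner therefore
appears 8 times, on a face twice — the familiar packed-cell picture.
Wrapping happens *before* packing so the enumeration window is
well-defined. The packing tolerance of interactive viewers is not
documented anywhere; counts for atoms sitting exactly on boundaries are
tolerance-sensitive by nature, which is why the fixture generator never
jitters special positions (see below).

## Bond perception and fragment selection

Two atoms bond iff

$$0.4\,\text{Å} < d_{ij} \le r_{\mathrm{cov}}(i) + r_{\mathrm{cov}}(j) + t,$$

with single-bond covalent radii and **`bondTol` $t = 0.45$ Å**, mirroring
the additive heuristic crystallographic viewers use. The 0.4 Å floor
rejects coincidence duplicates that survive deduplication (e.g. disorder
artifacts); H–H pairs are excluded outright, which prevents spurious
bridges between close hydrogens. Elements without a tabulated radius fall
back to 1.5 Å with a warning rather than failing a whole batch. A uniform
spatial grid with cells the size of the largest cutoff keeps perception
near-linear; the test suite checks it bond-for-bond against a quadratic
reference.

Fragments are the connected components of the bond graph (computed with
`igraph`; the tests re-derive them by label propagation). Selection keeps
the fragment with the most atoms. Ties are real — enantiomer pairs related
by inversion always have equal atom counts — and are broken by the lowest
contained atom index. A deterministic tie-break was chosen over random
selection deliberately: batch conversions must be byte-reproducible, and
either mirror image is equally "correct". The cost of size-based selection
is documented and accepted: when a counterion out-counts the molecule of
interest, the counterion wins (the `bigCounterion` fixture reproduces
exactly this). Per-molecule mode is the mitigation — every fragment, both
enantiomers and all co-crystal partners included, becomes its own output
file.

For packed solids the same largest-fragment rule applies; if the kept
network ever excludes packed atoms (a split ionic framework), the pipeline
says so rather than deciding silently.

## Mesh construction

Atom spheres are geodesic: an icosahedron subdivided `sphereLevel` times
with vertices projected to the sphere, giving exactly $20 \cdot 4^L$
triangles and $10 \cdot 4^L + 2$ vertices. **Level 2 (320 triangles)** is
the default — at print scale the chord error is far below printer
resolution, and file sizes stay modest. Bonds are split at the midpoint
into two capped cylinders of **`cylSegments` = 16** facets, each coloured
by its adjacent atom's element, so two-tone bonds come out of multi-colour
printers correctly.

Three decisions shape the printability guarantee:

* **Every shell is independently closed; overlapping shells are not
  boolean-unioned.** Printer slicers union overlapping closed shells
  natively. CSG union of near-tangent spheres and cylinders is numerically
  fragile and can *introduce* the very defects it is meant to remove.
* **Half-bond cylinders end flush at atom centres, buried inside the atom
  sphere.** The sphere radius (23% of the van der Waals radius — about
  0.28 Å even for hydrogen) always exceeds the bond radius (0.15 Å), an
  invariant the builder enforces, so the flat caps can never surface.
  Rounded shared endcaps are therefore unnecessary; each cap is generated
  exactly once, inside its own shell.
* **No axes, unit-cell guides, labels or open surfaces are ever
  generated**, so nothing needs deleting or repairing afterwards.

The **scale factor defaults to 10**. Model units are read as millimetres
by print services, so 1 Å becomes 1 cm and typical molecules land at
1–10 cm per axis — the test suite asserts the 1–100 model-unit bounding
box for all molecular fixtures.

`validateShell()` is the gatekeeper: boundary-edge count, non-manifold
edge count, opposite-traversal orientation consistency, signed volume by
the divergence theorem (positive means outward normals), degenerate
triangles (area below $10^{-12}$), and the smallest bounding-box extent as
a thickness proxy. Export refuses non-watertight bundles unless forced.

## Serialization

VRML 2.0 output contains only indexed face sets with per-vertex colour —
by construction there is nothing to post-process, and the high-level node
names (`Sphere`, `Cylinder`, `Cone`) never occur in the file. Numbers
carry 6 significant digits, which at millimetre scale is sub-micron.
Binary STL follows the fixed 84 + 50·n byte layout with normals recomputed
from winding; ASCII STL and an auto-detecting reader exist for round-trip
testing and interoperability. STL collapses colour, so all shells merge
into a single solid there; VRML keeps one shape per shell. All writers are
fully deterministic (fixed formatting, no timestamps), which is what makes
repeated batch runs byte-identical.

# The fixture generator

Real crystal structures come with accession baggage; the test conditions
instead come from four synthetic CIFs whose ground truth is known by
construction:

* **`p1_molecule`** — water in a 15 Å cubic P1 cell: the minimal
  one-fragment case (3 atoms, 2 bonds, 7 shells).
* **`cocrystal`** — a 10-atom carbon horseshoe (bond length 1.5 Å,
  non-adjacent separations > 2.8 Å, so the chain is rigid under the bond
  rule), two bent 3-atom solvents and a chloride ion, on general positions
  in P-1 with centroids placed so that no inter-fragment contact comes
  within 2.5 Å of any bonding cutoff. Expansion doubles everything:
  fragment sizes 10, 10, 3, 3, 3, 3, 1, 1.
* **`rocksalt`** — Na and Cl with the explicit face-centering operator
  list in a 5.64 Å cell: 8 atoms expanded, 27 packed (8 corners + 6 faces
  of Na, 12 edges + 1 centre of Cl), one connected network.
* **`enantiomer_pair`** — a 5-atom chiral fragment (C bonded to N, O, F,
  Cl at tetrahedral directions) and its inversion image: the canonical
  selection tie.

A non-zero seed perturbs coordinates by at most $5 \times 10^{-4}$
fractional through a small deterministic congruential generator — enough
to exercise deduplication and tolerance handling, far too small to alter
any bond or fragment. The rock-salt special positions are exempt (moving
a corner atom off the corner changes packed counts by design, not by
tolerance); its cell length absorbs the jitter instead.

What the fixtures deliberately do **not** emulate: thermal displacement
and disorder models, partial occupancies other than the drop-below-0.5
rule, curved/aromatic geometry, metal coordination distances at the edge
of the bond tolerance, and multi-thousand-atom frameworks. Passing tests
demonstrate the machinery — parsing, symmetry, selection, mesh and format
contracts — not chemical universality on arbitrary COD entries.

A separate generator, `syntheticCod7004704()`, mirrors the *composition*
of one published worked example (COD entry 7004704: a terpyridine
derivative co-crystallized with chloroform and water in P-1): one 43-atom
molecule + CHCl$_3$ + H$_2$O per asymmetric unit, expanding to fragment
sizes 43, 43, 5, 5, 3, 3 with exactly one molecule surviving default
selection. Its geometry is synthetic (a compact heavy-atom cluster), which
the file name and documentation state plainly; it stands in for the real
entry so the example runs without any network access.

# Numerical and degenerate-input policy

* CIF numbers with standard uncertainties (`0.1234(5)`) strip the
  parentheses; `.`/`?` become missing, and missing occupancy means 1.
* Sites with occupancy < 0.5 are dropped, the rest treated as full — one
  self-consistent model per file, chosen because fractional-atom printing
  is meaningless. This cutoff is this package's own policy decision.
* Multi-block CIFs use the first block with both a cell and atom sites.
* Element symbols resolve from `_atom_site_type_symbol` when present
  (charge suffixes stripped: `Pb2+` → Pb), else from the leading letters
  of the label; two-letter guesses that are not elements degrade to their
  one-letter prefix (`Cx` → C).
* A zero-length bond request (coincident cylinder endpoints) is an error;
  zero-area triangles never arise from valid input but are counted by
  validation.
* Fractional wraps snap values within $10^{-9}$ of 1 back to 0 so
  floating-point noise cannot split an atom across a cell boundary.

# Problem sizes

The shipped test and acceptance workloads use the sizes that make each
property legible: metric-tensor agreement over 1000 random cells;
printability over all four fixtures at 10 seeds each (1830 shells);
determinism over 100 repeated conversions of the enantiomer fixture; and
batch behaviour over a 3-file list with one corrupt member plus a
100-fixture mixed batch (about 15 s on one CPU), the desk-scale stand-in
for production-size runs. Production batches of tens of thousands of CIFs
are out of scope here; nothing in the design is size-limited beyond linear
time and memory in atoms and triangles.

# Known limitations

Distance-based bonding has no notion of bond order, aromaticity, or
coordination chemistry; unusual metal–ligand distances can fragment or
over-connect a network, and the only remedies exposed are `bondTol` and
per-molecule export. Space-group *symbols* are not interpreted — operators
must be listed (the identity is assumed when absent), as they are in
database CIFs. Anisotropic displacement, wireframe/space-filling styles,
and mesh repair of externally produced files are out of scope.
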