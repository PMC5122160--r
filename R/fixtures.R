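# Synthetic CIF fixtures with ground truth known by construction: an
# isolated molecule in P1, a co-crystal with solvent and counterion in
# P-1, a rock-salt-like extended solid with an explicit centering-operator
# list, and an enantiomer pair related by inversion. All operator lists
# are explicit, so no space-group database is needed.

# Tiny deterministic LCG in [0,1); keeps the global RNG untouched.
.lcg <- function(seed) {
  state <- as.numeric(seed %% 2^31)
  function() {
    state <<- (1103515245 * state + 12345) %% 2^31
    state / 2^31
  }
}

# Perturbation of at most `amp` per coordinate, derived from the seed.
.jitter_sites <- function(sites, seed, amp = 5e-4) {
  if (seed == 0L) return(sites)
  rng <- .lcg(seed)
  for (col in c("fx", "fy", "fz"))
    sites[[col]] <- sites[[col]] +
      vapply(seq_len(nrow(sites)), function(i) (rng() - 0.5) * 2 * amp,
             numeric(1))
  sites
}

.sites_df <- function(label, element, fracCart) {
  data.frame(label = label, element = element,
             fx = fracCart[, 1], fy = fracCart[, 2], fz = fracCart[, 3],
             occupancy = 1, stringsAsFactors = FALSE)
}

# Place a small Cartesian point cloud (Angstrom, centred near 0) at a
# fractional centroid of an orthogonal cell.
.place <- function(xyz, centroid, cell_len) {
  sweep(sweep(xyz, 2, colMeans(xyz)), 2, cell_len, "/") +
    matrix(centroid, nrow = nrow(xyz), ncol = 3, byrow = TRUE)
}

.fixture_p1_molecule <- function() {
  a <- 15
  ang <- 104.5 * pi / 180
  o <- c(0.5, 0.5, 0.5)
  h1 <- o + c(0.96, 0, 0) / a
  h2 <- o + 0.96 * c(cos(ang), sin(ang), 0) / a
  sites <- .sites_df(c("O1", "H1", "H2"), c("O", "H", "H"),
                     rbind(o, h1, h2))
  list(cell = crystalCell(a, a, a), symops = "x,y,z", sites = sites,
       expected = list(siteCount = 3L, expandedCount = 3L,
                       fragmentSizes = 3L, primarySize = 3L, bondCount = 2L))
}

# 10-atom rigid carbon chain bent into a horseshoe arc (bond 1.5 A,
# non-adjacent separations > 2.8 A), Cartesian, centred later by .place().
.chain10 <- function() {
  r <- 3.0
  step <- 2 * asin(1.5 / (2 * r))
  th <- (0:9) * step
  cbind(r * cos(th), r * sin(th), 0)
}

# Bent 3-atom solvent (water-like geometry).
.solvent3 <- function() {
  ang <- 104.5 * pi / 180
  rbind(c(0, 0, 0), c(0.96, 0, 0), 0.96 * c(cos(ang), sin(ang), 0))
}

# 12-atom carbon ring, used as the oversized counterion.
.ring12 <- function() {
  th <- 2 * pi * (0:11) / 12
  r <- 1.45 / (2 * sin(pi / 12))
  cbind(r * cos(th), r * sin(th), 0)
}

.fixture_cocrystal <- function(bigCounterion = FALSE) {
  len <- c(26, 18, 18)
  chain <- .place(.chain10(), c(0.26, 0.22, 0.24), len)
  sol1 <- .place(.solvent3(), c(0.30, 0.62, 0.20), len)
  sol2 <- .place(.solvent3(), c(0.18, 0.35, 0.68), len)
  if (bigCounterion) {
    ion <- .place(.ring12(), c(0.62, 0.60, 0.62), len)
    ion_sites <- .sites_df(paste0("X", 1:12), rep("C", 12), ion)
    frag_sizes <- c(12L, 12L, 10L, 10L, 3L, 3L, 3L, 3L)
    primary <- 12L
  } else {
    ion_sites <- .sites_df("Cl1", "Cl", matrix(c(0.55, 0.10, 0.55), 1))
    frag_sizes <- c(10L, 10L, 3L, 3L, 3L, 3L, 1L, 1L)
    primary <- 10L
  }
  sites <- rbind(
    .sites_df(paste0("C", 1:10), rep("C", 10), chain),
    .sites_df(c("O1", "H1", "H2"), c("O", "H", "H"), sol1),
    .sites_df(c("O2", "H3", "H4"), c("O", "H", "H"), sol2),
    ion_sites)
  nsite <- nrow(sites)
  list(cell = crystalCell(len[1], len[2], len[3]),
       symops = c("x,y,z", "-x,-y,-z"), sites = sites,
       expected = list(siteCount = nsite, expandedCount = 2L * nsite,
                       fragmentSizes = frag_sizes, primarySize = primary))
}

.fixture_rocksalt <- function() {
  sites <- .sites_df(c("Na1", "Cl1"), c("Na", "Cl"),
                     rbind(c(0, 0, 0), c(0.5, 0.5, 0.5)))
  list(cell = crystalCell(5.64, 5.64, 5.64),
       symops = c("x,y,z", "x+1/2,y+1/2,z", "x+1/2,y,z+1/2", "x,y+1/2,z+1/2"),
       sites = sites,
       expected = list(siteCount = 2L, expandedCount = 8L,
                       packedCount = 27L, packedFragmentSizes = 27L))
}

.fixture_enantiomer_pair <- function() {
  len <- c(14, 14, 14)
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  lengths <- c(1.47, 1.43, 1.39, 1.79)  # C-N, C-O, C-F, C-Cl
  xyz <- rbind(c(0, 0, 0), dirs * lengths)
  cloud <- .place(xyz, c(0.20, 0.23, 0.26), len)
  sites <- .sites_df(c("C1", "N1", "O1", "F1", "Cl1"),
                     c("C", "N", "O", "F", "Cl"), cloud)
  list(cell = crystalCell(len[1], len[2], len[3]),
       symops = c("x,y,z", "-x,-y,-z"), sites = sites,
       expected = list(siteCount = 5L, expandedCount = 10L,
                       fragmentSizes = c(5L, 5L), primarySize = 5L))
}

#' Generate a synthetic CIF fixture with known ground truth
#'
#' Builds one of four synthetic crystal structures and returns both its
#' CIF text and the ground-truth expectations computed by construction:
#'
#' * `p1_molecule`: a water molecule in a 15 Angstrom cubic P1 cell
#'   (3 sites, O-H 0.96 Angstrom).
#' * `cocrystal`: a 10-atom rigid carbon chain, two bent 3-atom solvent
#'   molecules and a single-atom chloride counterion, all on general
#'   positions in P-1, centroids kept far enough apart that symmetry
#'   images never fuse fragments. With `bigCounterion = TRUE` the ion is
#'   a 12-atom ring, larger than the chain — reproducing the documented
#'   failure mode where the counterion, not the molecule of interest,
#'   survives selection.
#' * `rocksalt`: Na and Cl at (0,0,0) and (1/2,1/2,1/2) with the explicit
#'   face-centering operator list in a 5.64 Angstrom cubic cell.
#' * `enantiomer_pair`: a 5-atom chiral fragment and its mirror image
#'   related by the P-1 inversion.
#'
#' A non-zero `seed` perturbs non-structural decimals (at most 5e-4
#' fractional) to exercise tolerance handling; bonding and fragment
#' topology are unaffected. The rock-salt fixture's special positions are
#' never perturbed (a corner atom must stay on the corner); its cell
#' length absorbs the jitter instead.
#'
#' @param kind One of `"p1_molecule"`, `"cocrystal"`, `"rocksalt"`,
#'   `"enantiomer_pair"`.
#' @param seed Integer; 0 means no perturbation.
#' @param bigCounterion Co-crystal only: make the counterion the largest
#'   fragment (default FALSE).
#' @return list with `cif` (CIF text), `record` (the
#'   [StructureRecord-class] it encodes) and `expected` (list of
#'   ground-truth values: site/expanded/packed counts, fragment sizes,
#'   selected-fragment size).
#' @examples
#' fx <- makeFixture("cocrystal")
#' fx$expected$fragmentSizes
#' @export
makeFixture <- function(kind = c("p1_molecule", "cocrystal", "rocksalt",
                                 "enantiomer_pair"),
                        seed = 0L, bigCounterion = FALSE) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    p1_molecule = .fixture_p1_molecule(),
    cocrystal = .fixture_cocrystal(bigCounterion),
    rocksalt = .fixture_rocksalt(),
    enantiomer_pair = .fixture_enantiomer_pair())
  cell <- spec$cell
  sites <- spec$sites
  if (kind == "rocksalt") {
    if (seed != 0L) {
      rng <- .lcg(seed)
      d <- (rng() - 0.5) * 2e-3
      cell <- crystalCell(cell@a + d, cell@b + d, cell@c + d)
    }
  } else {
    sites <- .jitter_sites(sites, seed)
  }
  record <- new("StructureRecord", name = paste0(kind, "_seed", seed),
                cell = cell, symops = spec$symops, sites = sites)
  list(cif = writeCif(record), record = record, expected = spec$expected)
}

#' Synthetic stand-in for the COD 7004704 worked example
#'
#' A synthetic co-crystal constructed to mirror the fragment composition
#' of COD entry 7004704 (a pyridinyl-terpyridine derivative crystallized
#' with chloroform and water in P-1): the asymmetric unit holds one
#' 43-atom molecule (21 C + 6 N heavy-atom core with 16 H), one CHCl3 and
#' one H2O, so symmetry expansion yields two copies of each — fragment
#' sizes 43, 43, 5, 5, 3, 3 — and the default pipeline keeps exactly one
#' 43-atom molecule. The geometry is synthetic (a compact heavy-atom
#' lattice, not the published structure); only the composition and
#' fragment topology emulate the real entry. A copy of the CIF ships as
#' `inst/extdata/cod7004704-synthetic.cif`.
#'
#' @return list with `cif`, `record` and `expected`, as [makeFixture()].
#' @export
syntheticCod7004704 <- function() {
  len <- c(22, 16, 16)
  # 27 heavy atoms on a 3x3x3 grid, spacing 1.5 A: corners/edges/centre are
  # C (21), face centres are N (6); 16 H point outward from corner and
  # edge atoms.
  g <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2)) * 1.5
  nboundary <- rowSums(g == 1.5)     # 0 on corner, 1 on edge, 2 on face, 3 centre
  element <- ifelse(nboundary == 2, "N", "C")
  hv_host <- which(nboundary <= 1)   # corners + edges: 20 candidates
  hosts <- hv_host[seq_len(16L)]
  centre <- c(1.5, 1.5, 1.5)
  hx <- t(vapply(hosts, function(i) {
    d <- g[i, ] - centre
    g[i, ] + d / sqrt(sum(d^2))     # 1.0 A outward
  }, numeric(3)))
  mol <- rbind(g, hx)
  mol_el <- c(element, rep("H", 16))
  mol_lab <- paste0(mol_el, seq_along(mol_el))

  # chloroform
  s109 <- sin(109.47 * pi / 180); c109 <- cos(109.47 * pi / 180)
  cl <- t(vapply(0:2, function(k) {
    1.77 * c(s109 * cos(2 * pi * k / 3), s109 * sin(2 * pi * k / 3), c109)
  }, numeric(3)))
  chcl3 <- rbind(c(0, 0, 0), c(0, 0, 1.09), cl)
  chcl3_el <- c("C", "H", "Cl", "Cl", "Cl")

  water <- .solvent3()
  water_el <- c("O", "H", "H")

  sites <- rbind(
    .sites_df(mol_lab, mol_el, .place(mol, c(0.25, 0.25, 0.25), len)),
    .sites_df(paste0("S", 1:5), chcl3_el, .place(chcl3, c(0.25, 0.70, 0.28), len)),
    .sites_df(paste0("W", 1:3), water_el, .place(water, c(0.55, 0.05, 0.60), len)))
  record <- new("StructureRecord", name = "cod7004704_synthetic",
                cell = crystalCell(len[1], len[2], len[3]),
                symops = c("x,y,z", "-x,-y,-z"), sites = sites)
  list(cif = writeCif(record), record = record,
       expected = list(siteCount = 51L, expandedCount = 102L,
                       fragmentSizes = c(43L, 43L, 5L, 5L, 3L, 3L),
                       primarySize = 43L))
}
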