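# Watertight shell construction: geodesic spheres for atoms, capped
# cylinders for half-bonds, assembled into a scaled ball-and-stick model.
# Every shell is independently closed and outward-wound; overlapping
# shells are left to the printer software to union.

#' Construct a StyleConfig
#'
#' @param scale Unitless factor applied to all coordinates (default 10,
#'   so 1 Angstrom becomes 10 model units, read as millimetres).
#' @param sphereFraction Atom sphere radius as a fraction of the van der
#'   Waals radius (default 0.23).
#' @param bondRadius Bond cylinder radius in Angstrom (default 0.15).
#' @param sphereLevel Icosphere subdivision level (default 2).
#' @param cylSegments Cylinder facet count (default 16).
#' @return A validated [StyleConfig-class].
#' @export
styleConfig <- function(scale = 10, sphereFraction = 0.23, bondRadius = 0.15,
                        sphereLevel = 2L, cylSegments = 16L) {
  new("StyleConfig", scale = as.numeric(scale),
      sphereFraction = as.numeric(sphereFraction),
      bondRadius = as.numeric(bondRadius),
      sphereLevel = as.integer(sphereLevel),
      cylSegments = as.integer(cylSegments))
}

.mesh <- function(vertices, triangles, color) {
  new("TriangleMesh", vertices = vertices,
      triangles = matrix(as.integer(triangles), ncol = 3),
      vertexColors = matrix(rep(as.numeric(color), each = nrow(vertices)),
                            ncol = 3))
}

# Unit icosahedron with outward-wound faces.
.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- matrix(c(
    -1,  phi, 0,   1,  phi, 0,  -1, -phi, 0,   1, -phi, 0,
     0, -1,  phi,  0,  1,  phi,  0, -1, -phi,  0,  1, -phi,
     phi, 0, -1,   phi, 0,  1,  -phi, 0, -1,  -phi, 0,  1
  ), ncol = 3, byrow = TRUE)
  v <- v / sqrt(rowSums(v^2))
  f <- matrix(c(
    1, 12, 6,  1, 6, 2,   1, 2, 8,   1, 8, 11,  1, 11, 12,
    2, 6, 10,  6, 12, 5,  12, 11, 3, 11, 8, 7,  8, 2, 9,
    4, 10, 5,  4, 5, 3,   4, 3, 7,   4, 7, 9,   4, 9, 10,
    5, 10, 6,  3, 5, 12,  7, 3, 11,  9, 7, 8,   10, 9, 2
  ), ncol = 3, byrow = TRUE)
  list(v = v, f = f)
}

#' Geodesic sphere mesh
#'
#' Builds a geodesic sphere by `level` rounds of 4-way subdivision of an
#' icosahedron, projecting every vertex onto the sphere. The result has
#' exactly `20 * 4^level` triangles and `10 * 4^level + 2` vertices, is
#' closed, and is wound counter-clockwise seen from outside (positive
#' signed volume).
#'
#' @param center numeric(3) sphere centre.
#' @param radius Sphere radius (> 0), model units.
#' @param level Subdivision level (>= 0).
#' @param color RGB triple in [0, 255] applied to every vertex.
#' @return A [TriangleMesh-class].
#' @examples
#' m <- icosphere(c(0, 0, 0), 1, level = 2)
#' nrow(meshVertices(m)) # 162
#' @export
icosphere <- function(center, radius, level = 2L, color = c(200, 200, 200)) {
  stopifnot(radius > 0, level >= 0)
  ico <- .icosahedron()
  v <- ico$v; f <- ico$f
  for (iter in seq_len(level)) {
    nv <- nrow(v)
    edge_mid <- new.env(hash = TRUE, parent = emptyenv())
    newv <- list()
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      id <- edge_mid[[k]]
      if (!is.null(id)) return(id)
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1L]] <<- p
      id <- nv + length(newv)
      edge_mid[[k]] <- id
      id
    }
    newf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(t - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  v <- sweep(v * radius, 2, center, "+")
  .mesh(v, f, color)
}

#' Closed (capped) cylinder mesh
#'
#' A tube of `segments` rectangular facets (two triangles each) between
#' two end rings, closed by two fan-triangulated flat disks around end
#' centre vertices: `4 * segments` triangles and `2 * segments + 2`
#' vertices, outward-wound.
#'
#' @param pStart,pEnd numeric(3) axis endpoints (must differ).
#' @param radius Cylinder radius (> 0), model units.
#' @param segments Facet count around the axis (>= 3).
#' @param color RGB triple in [0, 255].
#' @return A [TriangleMesh-class].
#' @export
cappedCylinder <- function(pStart, pEnd, radius, segments = 16L,
                           color = c(200, 200, 200)) {
  stopifnot(radius > 0, segments >= 3)
  axis <- pEnd - pStart
  h <- sqrt(sum(axis^2))
  if (h < 1e-12) stop("degenerate bond: cylinder endpoints coincide")
  w <- axis / h
  # any unit vector not parallel to w
  seed <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed - sum(seed * w) * w
  u <- u / sqrt(sum(u^2))
  vperp <- c(w[2] * u[3] - w[3] * u[2],
             w[3] * u[1] - w[1] * u[3],
             w[1] * u[2] - w[2] * u[1])
  s <- as.integer(segments)
  ang <- 2 * pi * (seq_len(s) - 1L) / s
  ring <- outer(cos(ang), u) + outer(sin(ang), vperp)   # s x 3 unit offsets
  bot <- sweep(ring * radius, 2, pStart, "+")
  top <- sweep(ring * radius, 2, pEnd, "+")
  verts <- rbind(bot, top, pStart, pEnd)
  ib <- seq_len(s); it <- s + seq_len(s)
  icb <- 2L * s + 1L; ict <- 2L * s + 2L
  nxt <- c(seq_len(s)[-1], 1L)
  side <- rbind(cbind(ib, it[nxt], it),      # wound so normals point outward
                cbind(ib, ib[nxt], it[nxt]))
  capb <- cbind(icb, ib[nxt], ib)            # bottom cap faces -w
  capt <- cbind(ict, it, it[nxt])            # top cap faces +w
  .mesh(verts, rbind(side, capb, capt), color)
}

# Bounding-box centre of a set of points.
.bbox_center <- function(xyz) (apply(xyz, 2, max) + apply(xyz, 2, min)) / 2

#' Build a scaled ball-and-stick shell list for a fragment
#'
#' Emits one geodesic sphere per atom (radius `sphereFraction` times the
#' element's van der Waals radius) and two half-bond cylinders per bond,
#' each half running from an atom centre to the bond midpoint and coloured
#' by that atom's element. The fragment is centred at its bounding-box
#' centre and every coordinate (and radius) is multiplied by
#' `style@scale`, so the default scale of 10 turns a molecule a few
#' Angstrom across into a model a few centimetres across in millimetre
#' units. Cylinder ends at atom centres are buried inside the atom
#' spheres, so no cap ever surfaces; each shell is independently closed.
#'
#' @param fragment A [Fragment-class] (from [findFragments()]).
#' @param atoms The expanded-atom data.frame the fragment indexes into.
#' @param style A [StyleConfig-class].
#' @return list of [TriangleMesh-class] shells: all atom spheres first
#'   (in fragment atom order), then the two halves of each bond.
#' @examples
#' rec <- readCif(makeFixture("p1_molecule")$cif)
#' atoms <- expandSymmetry(rec)
#' frag <- selectPrimary(findFragments(atoms, perceiveBonds(atoms)))
#' length(buildBallStick(frag, atoms)) # 7 shells: 3 spheres + 4 half-bonds
#' @export
buildBallStick <- function(fragment, atoms, style = styleConfig()) {
  stopifnot(is(fragment, "Fragment"), is(style, "StyleConfig"))
  idx <- fragment@atomIndices
  sub <- atoms[idx, , drop = FALSE]
  xyz <- as.matrix(sub[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, .bbox_center(xyz)) * style@scale
  rownames(xyz) <- NULL
  pos <- function(global_i) xyz[match(global_i, idx), ]

  radii <- vdwRadius(sub$element) * style@sphereFraction * style@scale
  bond_r <- style@bondRadius * style@scale
  if (nrow(fragment@bonds) > 0 && any(radii[match(
        unique(c(fragment@bonds$i, fragment@bonds$j)), idx)] <= bond_r))
    stop("bond radius must be smaller than every bonded atom's sphere radius")

  cols <- elementColor(sub$element)
  shells <- vector("list", nrow(sub) + 2L * nrow(fragment@bonds))
  for (k in seq_len(nrow(sub)))
    shells[[k]] <- icosphere(xyz[k, ], radii[k], style@sphereLevel, cols[k, ])
  nb <- nrow(fragment@bonds)
  for (b in seq_len(nb)) {
    i <- fragment@bonds$i[b]; j <- fragment@bonds$j[b]
    pi_ <- pos(i); pj <- pos(j)
    mid <- (pi_ + pj) / 2
    ci <- cols[match(i, idx), ]; cj <- cols[match(j, idx), ]
    shells[[nrow(sub) + 2L * b - 1L]] <-
      cappedCylinder(pi_, mid, bond_r, style@cylSegments, ci)
    shells[[nrow(sub) + 2L * b]] <-
      cappedCylinder(mid, pj, bond_r, style@cylSegments, cj)
  }
  shells
}

#' Validate a mesh shell for 3D printability
#'
#' Checks the closed-surface contract required by printers: every
#' undirected edge shared by exactly two triangles (zero boundary and
#' zero non-manifold edges), consistent counter-clockwise winding (each
#' shared edge traversed in opposite directions by its two triangles),
#' positive signed volume (outward normals), no degenerate triangles, and
#' a minimum feature-thickness proxy (smallest bounding-box extent, which
#' for a closed shell bounds the thinnest printable dimension).
#'
#' @param mesh A [TriangleMesh-class].
#' @return list with components `boundaryEdges`, `nonManifoldEdges`
#'   (counts, 0 required), `orientationConsistent` (logical),
#'   `signedVolume` (model units cubed, > 0 required),
#'   `degenerateTriangles` (count of triangles with area < 1e-12),
#'   `minFeature` (smallest bbox extent) and `watertight` (TRUE iff all
#'   checks pass).
#' @examples
#' validateShell(icosphere(c(0, 0, 0), 1))$watertight # TRUE
#' @export
validateShell <- function(mesh) {
  stopifnot(is(mesh, "TriangleMesh"))
  v <- mesh@vertices; f <- mesh@triangles
  # directed edges a->b for each triangle (a,b,c): ab, bc, ca
  from <- c(f[, 1], f[, 2], f[, 3])
  to   <- c(f[, 2], f[, 3], f[, 1])
  lo <- pmin(from, to); hi <- pmax(from, to)
  ekey <- paste(lo, hi)
  cnt <- table(ekey)
  boundary <- sum(cnt == 1L)
  nonmanifold <- sum(cnt > 2L)
  # orientation: a shared edge must appear once as a->b and once as b->a
  dir <- from < to
  fwd <- table(ekey[dir]); bwd <- table(ekey[!dir])
  shared <- names(cnt)[cnt == 2L]
  fcnt <- as.integer(fwd[shared]); fcnt[is.na(fcnt)] <- 0L
  bcnt <- as.integer(bwd[shared]); bcnt[is.na(bcnt)] <- 0L
  orientation <- all(fcnt == 1L & bcnt == 1L)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  ab <- b - a; ac <- cc - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  areas <- sqrt(rowSums(cr^2)) / 2
  degen <- sum(areas < 1e-12)
  svol <- sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
              a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
              a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
  used <- unique(as.integer(f))
  ext <- apply(v[used, , drop = FALSE], 2, max) -
         apply(v[used, , drop = FALSE], 2, min)
  res <- list(boundaryEdges = as.integer(boundary),
              nonManifoldEdges = as.integer(nonmanifold),
              orientationConsistent = orientation,
              signedVolume = svol,
              degenerateTriangles = as.integer(degen),
              minFeature = min(ext))
  res$watertight <- res$boundaryEdges == 0L && res$nonManifoldEdges == 0L &&
    res$orientationConsistent && res$signedVolume > 0 &&
    res$degenerateTriangles == 0L
  res
}
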