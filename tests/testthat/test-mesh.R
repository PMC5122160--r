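test_that("icosphere has the exact geodesic vertex/triangle counts and Euler characteristic 2", {
  for (lvl in 0:2) {
    m <- icosphere(c(0, 0, 0), 1, lvl)
    nv <- nrow(meshVertices(m)); nt <- nrow(meshTriangles(m))
    expect_equal(nv, 10 * 4^lvl + 2)
    expect_equal(nt, 20 * 4^lvl)
    ne <- nt * 3L / 2L           # closed: each edge shared by 2 triangles
    expect_equal(nv - ne + nt, 2)
  }
})

test_that("icosphere signed volume approaches the sphere volume from below", {
  m <- icosphere(c(1, 2, 3), 1, 3)
  vol <- oracle_signed_volume(m)
  expect_lt(abs(vol - 4 * pi / 3) / (4 * pi / 3), 0.02)
  expect_lt(vol, 4 * pi / 3)     # inscribed polyhedron
  expect_equal(validateShell(m)$signedVolume, vol, tolerance = 1e-12)
})

test_that("capped cylinder has the counting-formula size and near-exact volume", {
  cy <- cappedCylinder(c(0, 0, 0), c(0, 0, 2), 1, 16)
  expect_equal(nrow(meshTriangles(cy)), 64L)
  expect_equal(nrow(meshVertices(cy)), 34L)
  rep <- validateShell(cy)
  expect_equal(rep$boundaryEdges, 0L)
  expect_true(rep$watertight)

  fine <- cappedCylinder(c(1, -1, 0.5), c(2, 3, -1), 1, 64)
  h <- sqrt(sum((c(2, 3, -1) - c(1, -1, 0.5))^2))
  expect_lt(abs(oracle_signed_volume(fine) - pi * h) / (pi * h), 0.01)

  expect_error(cappedCylinder(c(1, 1, 1), c(1, 1, 1), 0.2), "degenerate bond")
})

test_that("validateShell reports injected defects", {
  m <- icosphere(c(0, 0, 0), 1, 1)
  ok <- validateShell(m)
  expect_true(ok$watertight)
  expect_gt(ok$signedVolume, 0)

  # delete one triangle -> 3 boundary edges
  holed <- new("TriangleMesh", vertices = meshVertices(m),
               triangles = meshTriangles(m)[-1, ],
               vertexColors = meshColors(m))
  expect_equal(validateShell(holed)$boundaryEdges, 3L)
  expect_false(validateShell(holed)$watertight)

  # flip one winding -> orientation inconsistency
  tri <- meshTriangles(m)
  tri[1, ] <- tri[1, c(1, 3, 2)]
  flipped <- new("TriangleMesh", vertices = meshVertices(m),
                 triangles = tri, vertexColors = meshColors(m))
  expect_false(validateShell(flipped)$orientationConsistent)
  expect_false(validateShell(flipped)$watertight)

  # inside-out shell: volume goes negative
  inv <- new("TriangleMesh", vertices = meshVertices(m),
             triangles = meshTriangles(m)[, c(1, 3, 2)],
             vertexColors = meshColors(m))
  expect_lt(validateShell(inv)$signedVolume, 0)
})

.diatomic_record <- function(d = 1.13, el = c("C", "O")) {
  a <- 12
  new("StructureRecord", name = "diatomic", cell = crystalCell(a, a, a),
      symops = "x,y,z",
      sites = data.frame(label = c("A1", "A2"), element = el,
                         fx = c(0.3, 0.3 + d / a), fy = 0.3, fz = 0.3,
                         occupancy = 1))
}

test_that("ball-and-stick output is scaled tenfold and shell counts follow atoms + 2 bonds", {
  rec <- .diatomic_record()
  atoms <- expandSymmetry(rec)
  frag <- selectPrimary(findFragments(atoms, perceiveBonds(atoms)))
  shells <- buildBallStick(frag, atoms, styleConfig(scale = 10))
  expect_length(shells, 4L)  # 2 spheres + 2 half-bond cylinders
  c1 <- colMeans(meshVertices(shells[[1]]))
  c2 <- colMeans(meshVertices(shells[[2]]))
  expect_equal(sqrt(sum((c1 - c2)^2)), 11.3, tolerance = 1e-9)

  # single isolated atom gives one shell
  one <- .diatomic_record(6, c("He", "He"))
  a1 <- expandSymmetry(one)
  f1 <- findFragments(a1, perceiveBonds(a1))
  expect_length(buildBallStick(f1[[1]], a1), 1L)
})

test_that("half-bond shells meet exactly at the bond midpoint with each atom's colour", {
  fx <- makeFixture("p1_molecule")
  atoms <- expandSymmetry(fx$record)
  bonds <- perceiveBonds(atoms)
  frag <- selectPrimary(findFragments(atoms, bonds))
  style <- styleConfig()
  shells <- buildBallStick(frag, atoms, style)
  expect_length(shells, 7L)  # 3 spheres + 2 x 2 half-bonds

  # recompute midpoints independently from the input geometry
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  ctr <- (apply(xyz, 2, max) + apply(xyz, 2, min)) / 2
  model <- sweep(xyz, 2, ctr) * style@scale
  for (b in seq_len(nrow(bonds))) {
    mid <- (model[bonds$i[b], ] + model[bonds$j[b], ]) / 2
    half1 <- shells[[3 + 2 * b - 1]]; half2 <- shells[[3 + 2 * b]]
    # the two halves share the midpoint: its cap-centre vertex is a vertex
    # of both cylinders
    d1 <- min(sqrt(rowSums(sweep(meshVertices(half1), 2, mid)^2)))
    d2 <- min(sqrt(rowSums(sweep(meshVertices(half2), 2, mid)^2)))
    expect_lt(d1, 1e-9); expect_lt(d2, 1e-9)
    # half-bond colours match the adjacent atoms' element colours
    expect_equal(meshColors(half1)[1, ],
                 as.numeric(elementColor(atoms$element[bonds$i[b]])),
                 ignore_attr = TRUE)
    expect_equal(meshColors(half2)[1, ],
                 as.numeric(elementColor(atoms$element[bonds$j[b]])),
                 ignore_attr = TRUE)
  }
})

test_that("pairwise model distances are input distances times the scale", {
  fx <- makeFixture("enantiomer_pair")
  atoms <- expandSymmetry(fx$record)
  frag <- selectPrimary(findFragments(atoms, perceiveBonds(atoms)))
  shells <- buildBallStick(frag, atoms, styleConfig(scale = 10))
  idx <- atomIndices(frag)
  centers <- t(vapply(seq_along(idx),
                      function(k) colMeans(meshVertices(shells[[k]])),
                      numeric(3)))
  din <- as.matrix(dist(atoms[idx, c("x", "y", "z")]))
  dout <- as.matrix(dist(centers))
  off <- din > 0
  expect_lt(max(abs(dout[off] / din[off] - 10)), 1e-6)
})

test_that("fixture models at scale 10 land in the 1-100 model-unit range per axis", {
  for (kind in c("p1_molecule", "cocrystal", "enantiomer_pair")) {
    rec <- makeFixture(kind)$record
    atoms <- expandSymmetry(rec)
    frag <- selectPrimary(findFragments(atoms, perceiveBonds(atoms)))
    shells <- buildBallStick(frag, atoms)
    allv <- do.call(rbind, lapply(shells, meshVertices))
    ext <- apply(allv, 2, max) - apply(allv, 2, min)
    expect_true(all(ext >= 1 & ext <= 100), info = kind)
  }
})

test_that("style invariants are enforced", {
  expect_error(styleConfig(scale = 0), "scale")
  expect_error(styleConfig(sphereFraction = 1.5), "sphereFraction")
  expect_error(styleConfig(cylSegments = 2), "cylSegments")
  # a bond radius exceeding the smallest bonded sphere is refused
  fx <- makeFixture("p1_molecule")
  atoms <- expandSymmetry(fx$record)
  frag <- selectPrimary(findFragments(atoms, perceiveBonds(atoms)))
  expect_error(buildBallStick(frag, atoms, styleConfig(bondRadius = 0.5)),
               "bond radius")
})
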