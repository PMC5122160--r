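test_that("xyz operator strings parse to the expected rotation and translation", {
  id <- parseSymop("x,y,z")
  expect_equal(id@R, diag(3), ignore_attr = TRUE)
  expect_equal(id@t, c(0, 0, 0))

  op <- parseSymop("-x+1/2, y, -z+1/2")
  expect_equal(op@R, diag(c(-1, 1, -1)), ignore_attr = TRUE)
  expect_equal(op@t, c(0.5, 0, 0.5))

  swap <- parseSymop("y,x,z")
  expect_equal(swap@R, rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1)),
               ignore_attr = TRUE)
  expect_equal(det(swap@R), -1)

  # decimal and fractional translations parse identically; order-free terms
  expect_equal(parseSymop("0.5-x, y, z")@t, parseSymop("1/2-x, y, z")@t)
  expect_equal(parseSymop("1/2-x, y, z")@R, parseSymop("-x+1/2, y, z")@R)
  expect_error(parseSymop("x,y"), "3 comma-separated")
  expect_error(parseSymop("x,y,w"), "cannot parse")
})

test_that("parse-format round trip preserves the operator", {
  ops <- c("x,y,z", "-x,-y,-z", "-x+1/2, y, -z+1/2", "y,x,z",
           "x+1/2,y+1/2,z", "-y+3/4, x+1/4, z+1/3", "0.5+x, -y, z-1/2")
  for (s in ops) {
    op <- parseSymop(s)
    op2 <- parseSymop(formatSymop(op))
    expect_equal(op2@R, op@R, info = s)
    expect_equal(op2@t, op@t, tolerance = 1e-9, info = s)
  }
})

test_that("fracToCart matches the orthogonal cell and fixes the origin", {
  cub <- crystalCell(10, 10, 10)
  expect_equal(fracToCart(cub, c(0.5, 0.25, 0.1)), c(5.0, 2.5, 1.0))
  tric <- crystalCell(7.1, 8.3, 9.9, 81, 95, 103)
  expect_equal(fracToCart(tric, c(0, 0, 0)), c(0, 0, 0))
  expect_equal(fracToCart(cub, c(0, 0, 0)), c(0, 0, 0))
})

test_that("Cartesian distances equal metric-tensor distances on random triclinic cells", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    prm <- c(runif(3, 3, 30), runif(3, 60, 120))
    cell <- tryCatch(crystalCell(prm[1], prm[2], prm[3], prm[4], prm[5], prm[6]),
                     error = function(e) NULL)
    if (is.null(cell)) next
    f1 <- runif(3); f2 <- runif(3)
    d_impl <- sqrt(sum((fracToCart(cell, f1) - fracToCart(cell, f2))^2))
    d_oracle <- oracle_metric_dist(prm[1], prm[2], prm[3], prm[4], prm[5],
                                   prm[6], f1, f2)
    worst <- max(worst, abs(d_impl - d_oracle))
  }
  expect_lt(worst, 1e-9)
})

.p1_record <- function(frac, element = "C", a = 10) {
  frac <- matrix(frac, ncol = 3)
  new("StructureRecord", name = "t", cell = crystalCell(a, a, a),
      symops = "x,y,z",
      sites = data.frame(label = paste0("X", seq_len(nrow(frac))),
                         element = element,
                         fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
                         occupancy = 1))
}

test_that("P-1 expansion handles special and general positions", {
  rec <- .p1_record(c(0, 0, 0))
  rec@symops <- c("x,y,z", "-x,-y,-z")
  expect_equal(nrow(expandSymmetry(rec)), 1L)  # inversion fixed point

  rec2 <- .p1_record(c(0.1, 0.2, 0.3))
  rec2@symops <- c("x,y,z", "-x,-y,-z")
  at <- expandSymmetry(rec2)
  expect_equal(nrow(at), 2L)
  expect_equal(unlist(at[1, c("fx", "fy", "fz")]), c(0.1, 0.2, 0.3),
               ignore_attr = TRUE)
  expect_equal(unlist(at[2, c("fx", "fy", "fz")]), c(0.9, 0.8, 0.7),
               ignore_attr = TRUE)
})

test_that("P-1 expansion of 8 general-position sites gives 16 atoms, matching brute force", {
  set.seed(11)
  frac <- matrix(runif(24, 0.05, 0.45), ncol = 3)
  rec <- .p1_record(frac, a = 30)
  rec@symops <- c("x,y,z", "-x,-y,-z")
  at <- expandSymmetry(rec)
  expect_equal(nrow(at), 16L)
  expect_equal(length(oracle_expand(rec)), 16L)
})

test_that("expansion agrees with the brute-force oracle on every fixture", {
  for (kind in c("p1_molecule", "cocrystal", "rocksalt", "enantiomer_pair")) {
    rec <- makeFixture(kind, seed = 5L)$record
    at <- expandSymmetry(rec)
    orc <- oracle_expand(rec)
    expect_equal(nrow(at), length(orc), info = kind)
    # same multiset of wrapped fractional positions
    key <- function(f) paste(round(f, 6), collapse = ",")
    expect_setequal(apply(at[, c("fx", "fy", "fz")], 1, key),
                    vapply(orc, function(o) key(o$f), character(1)))
  }
})

test_that("group closure: applying any operator maps the expanded set into itself", {
  for (kind in c("cocrystal", "rocksalt")) {
    rec <- makeFixture(kind)$record
    at <- expandSymmetry(rec)
    M <- orthoMatrix(cellOf(rec))
    fr <- as.matrix(at[, c("fx", "fy", "fz")])
    for (s in symopStrings(rec)) {
      op <- parseSymop(s)
      img <- t(apply(fr, 1, function(f) {
        f2 <- op@R %*% f + op@t
        f2 <- f2 - floor(f2)
        f2[f2 > 1 - 1e-9] <- 0
        f2
      }))
      cart_all <- t(M %*% t(fr))
      for (r in seq_len(nrow(img))) {
        p <- as.numeric(M %*% img[r, ])
        d <- sqrt(rowSums(sweep(cart_all, 2, p)^2))
        expect_lt(min(d[at$element == at$element[r]]), 0.01)
      }
    }
  }
})

test_that("packing places boundary atoms on every incident boundary", {
  corner <- .p1_record(c(0, 0, 0))
  pk <- packCell(corner)
  expect_equal(nrow(pk), 8L)
  want <- oracle_pack_p1(c(0, 0, 0))
  expect_setequal(apply(pk[, c("fx", "fy", "fz")], 1, paste, collapse = ","),
                  apply(want, 1, paste, collapse = ","))

  interior <- .p1_record(c(0.5, 0.5, 0.5))
  expect_equal(nrow(packCell(interior)), 1L)

  face <- .p1_record(c(0.5, 0.5, 0))
  pf <- packCell(face)
  expect_equal(nrow(pf), 2L)
  expect_setequal(pf$fz, c(0, 1))
})

test_that("packing with zero tolerance of an interior structure equals expansion", {
  rec <- makeFixture("cocrystal")$record
  ex <- expandSymmetry(rec)
  pk <- packCell(rec, boundaryEps = 0)
  expect_equal(nrow(pk), nrow(ex))
  expect_equal(sort(apply(pk[, c("fx", "fy", "fz")], 1, paste, collapse = ",")),
               sort(apply(ex[, c("fx", "fy", "fz")], 1, paste, collapse = ",")))
})

test_that("expansion and packing counts never exceed the enumeration bound", {
  for (kind in c("p1_molecule", "cocrystal", "rocksalt", "enantiomer_pair")) {
    rec <- makeFixture(kind)$record
    nsites <- nrow(atomSites(rec)); nops <- length(symopStrings(rec))
    expect_lte(nrow(expandSymmetry(rec)), nsites * nops)
    expect_lte(nrow(packCell(rec)), nsites * nops * 27)
  }
})

test_that("Cartesian coordinates are consistent with the orthogonalization map", {
  rec <- makeFixture("rocksalt")$record
  at <- packCell(rec)
  M <- orthoMatrix(cellOf(rec))
  cart <- t(M %*% t(as.matrix(at[, c("fx", "fy", "fz")])))
  expect_lt(max(abs(cart - as.matrix(at[, c("x", "y", "z")]))), 1e-9)
})
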