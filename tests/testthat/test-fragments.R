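.atoms_df <- function(element, xyz) {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  data.frame(element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

test_that("the covalent-radius bond rule with floor and H-H exclusion", {
  # two carbons 1.40 A apart: within 0.76 + 0.76 + 0.45
  b <- perceiveBonds(.atoms_df(c("C", "C"), c(0, 0, 0, 1.4, 0, 0)))
  expect_equal(nrow(b), 1L)
  expect_equal(b$length, 1.4)

  # C and H 2.50 A apart: beyond 0.76 + 0.31 + 0.45
  expect_equal(nrow(perceiveBonds(.atoms_df(c("C", "H"),
                                            c(0, 0, 0, 2.5, 0, 0)))), 0L)

  # coincidence duplicates below the 0.4 A floor never bond
  expect_equal(nrow(perceiveBonds(.atoms_df(c("C", "C"),
                                            c(0, 0, 0, 0.2, 0, 0)))), 0L)

  # H-H pairs never bond regardless of distance
  expect_equal(nrow(perceiveBonds(.atoms_df(c("H", "H"),
                                            c(0, 0, 0, 0.6, 0, 0)))), 0L)

  # unknown element falls back to 1.5 A with a warning
  expect_warning(b2 <- perceiveBonds(.atoms_df(c("Zz", "C"),
                                               c(0, 0, 0, 2.0, 0, 0))),
                 "falling back")
  expect_equal(nrow(b2), 1L)
})

test_that("grid-based bond search agrees with the brute-force oracle on all fixtures", {
  for (kind in c("p1_molecule", "cocrystal", "rocksalt", "enantiomer_pair")) {
    rec <- makeFixture(kind, seed = 2L)$record
    atoms <- if (kind == "rocksalt") packCell(rec) else expandSymmetry(rec)
    got <- perceiveBonds(atoms)
    want <- oracle_bonds(atoms)
    nb <- if (is.null(want)) 0L else nrow(want)
    expect_equal(nrow(got), nb, info = kind)
    if (nb > 0) {
      expect_equal(got$i, as.integer(want[, 1]), info = kind)
      expect_equal(got$j, as.integer(want[, 2]), info = kind)
      expect_equal(got$length, want[, 3], tolerance = 1e-12, info = kind)
    }
  }
})

test_that("fragments partition the atoms and match brute-force components", {
  for (kind in c("p1_molecule", "cocrystal", "rocksalt", "enantiomer_pair")) {
    rec <- makeFixture(kind)$record
    atoms <- if (kind == "rocksalt") packCell(rec) else expandSymmetry(rec)
    bonds <- perceiveBonds(atoms)
    frags <- findFragments(atoms, bonds)
    all_idx <- sort(unlist(lapply(frags, atomIndices)))
    expect_equal(all_idx, seq_len(nrow(atoms)), info = kind)    # partition
    expect_equal(sum(vapply(frags, natoms, integer(1))), nrow(atoms))
    want <- oracle_components(nrow(atoms),
                              as.matrix(bonds[, c("i", "j")]))
    got_sets <- lapply(frags, function(f) sort(atomIndices(f)))
    want_sets <- lapply(want, sort)
    expect_setequal(vapply(got_sets, paste, character(1), collapse = ","),
                    vapply(want_sets, paste, character(1), collapse = ","))
  }
})

test_that("the co-crystal fixture fragments into the designed size multiset", {
  fx <- makeFixture("cocrystal")
  atoms <- expandSymmetry(fx$record)
  frags <- findFragments(atoms, perceiveBonds(atoms))
  sizes <- vapply(frags, natoms, integer(1))
  expect_equal(sort(sizes, decreasing = TRUE),
               sort(fx$expected$fragmentSizes, decreasing = TRUE))
  # sorted by size descending, ties by lowest atom index
  expect_true(all(diff(sizes) <= 0))
})

test_that("zero bonds give one single-atom fragment per atom", {
  atoms <- .atoms_df(rep("He", 5), as.numeric(rbind(1:5 * 10, 0, 0)))
  bonds <- perceiveBonds(atoms)
  expect_equal(nrow(bonds), 0L)
  frags <- findFragments(atoms, bonds)
  expect_length(frags, 5L)
  expect_true(all(vapply(frags, natoms, integer(1)) == 1L))
})

test_that("selectPrimary keeps the largest fragment and breaks ties deterministically", {
  fx <- makeFixture("cocrystal")
  atoms <- expandSymmetry(fx$record)
  frags <- findFragments(atoms, perceiveBonds(atoms))
  expect_equal(natoms(selectPrimary(frags)), 10L)

  # enantiomer tie: the kept mirror copy contains the lowest atom index
  fe <- makeFixture("enantiomer_pair")
  ea <- expandSymmetry(fe$record)
  ef <- findFragments(ea, perceiveBonds(ea))
  expect_equal(vapply(ef, natoms, integer(1)), c(5L, 5L))
  kept <- selectPrimary(ef)
  expect_equal(min(atomIndices(kept)), 1L)

  # invariance under permutation of the fragment list
  set.seed(9)
  for (i in 1:20) {
    perm <- sample(ef)
    expect_equal(atomIndices(selectPrimary(perm)), atomIndices(kept))
  }
  expect_error(selectPrimary(list()), "no fragments")

  # single fragment returns itself
  single <- findFragments(.atoms_df("C", c(0, 0, 0)),
                          data.frame(i = integer(0), j = integer(0),
                                     length = numeric(0)))
  expect_equal(atomIndices(selectPrimary(single)), 1L)
})

test_that("an oversized counterion wins selection (documented failure mode)", {
  fx <- makeFixture("cocrystal", bigCounterion = TRUE)
  atoms <- expandSymmetry(fx$record)
  frags <- findFragments(atoms, perceiveBonds(atoms))
  expect_equal(sort(vapply(frags, natoms, integer(1)), decreasing = TRUE),
               fx$expected$fragmentSizes)
  kept <- selectPrimary(frags)
  expect_equal(natoms(kept), 12L)  # the ring ion, not the 10-atom molecule
  expect_equal(atoms$element[atomIndices(kept)], rep("C", 12))
})
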