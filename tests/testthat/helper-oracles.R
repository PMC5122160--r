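# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths (and igraph).

# Distance between two fractional points from the metric tensor
# G_ij = |v_i||v_j| cos(angle_ij), built directly from cell parameters.
oracle_metric_dist <- function(a, b, c, alpha, beta, gamma, f1, f2) {
  d2r <- pi / 180
  ca <- cos(alpha * d2r); cb <- cos(beta * d2r); cg <- cos(gamma * d2r)
  G <- matrix(c(a * a,      a * b * cg, a * c * cb,
                a * b * cg, b * b,      b * c * ca,
                a * c * cb, b * c * ca, c * c), nrow = 3)
  df <- f1 - f2
  sqrt(drop(t(df) %*% G %*% df))
}

# Brute-force symmetry expansion: all (site, op) images, wrapped, with
# O(n^2) same-element dedup at `tol` Cartesian. Returns fractional coords.
oracle_expand <- function(record, tol = 0.01) {
  ops <- lapply(symopStrings(record), parseSymop)
  sites <- atomSites(record)
  M <- orthoMatrix(cellOf(record))
  out <- list()
  for (s in seq_len(nrow(sites))) {
    f0 <- as.numeric(sites[s, c("fx", "fy", "fz")])
    for (o in seq_along(ops)) {
      f <- ops[[o]]@R %*% f0 + ops[[o]]@t
      f <- f - floor(f)
      f[f > 1 - 1e-9] <- 0
      out[[length(out) + 1L]] <- list(el = sites$element[s], f = as.numeric(f))
    }
  }
  keep <- list()
  for (cand in out) {
    dup <- FALSE
    for (k in keep) {
      if (k$el == cand$el &&
          sqrt(sum((M %*% (k$f - cand$f))^2)) < tol) { dup <- TRUE; break }
    }
    if (!dup) keep[[length(keep) + 1L]] <- cand
  }
  keep
}

# Brute-force O(n^2) bond list under the same rule as perceiveBonds.
oracle_bonds <- function(atoms, bondTol = 0.45) {
  n <- nrow(atoms)
  rcov <- suppressWarnings(covalentRadius(atoms$element))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  res <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d > 0.4 && d <= rcov[i] + rcov[j] + bondTol &&
        !(atoms$element[i] == "H" && atoms$element[j] == "H"))
      res <- rbind(res, c(i, j, d))
  }
  res
}

# Connected components by label propagation (no igraph).
oracle_components <- function(n, bonds) {
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    if (!is.null(bonds) && nrow(bonds) > 0) for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      m <- min(lab[i], lab[j])
      if (lab[i] != m || lab[j] != m) {
        lab[lab == max(lab[i], lab[j])] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(split(seq_len(n), lab))
}

# Signed volume of a triangle mesh by the divergence theorem, written
# directly from the triangle list.
oracle_signed_volume <- function(mesh) {
  v <- meshVertices(mesh); f <- meshTriangles(mesh)
  total <- 0
  for (t in seq_len(nrow(f))) {
    a <- v[f[t, 1], ]; b <- v[f[t, 2], ]; cc <- v[f[t, 3], ]
    total <- total + det(rbind(a, b, cc)) / 6
  }
  total
}

# Enumerate the 27 neighbour translations of wrapped images and filter by
# the packing window: the oracle for packCell on P1 structures.
oracle_pack_p1 <- function(frac, ranges = c(1, 1, 1), eps = 1e-4) {
  out <- NULL
  for (sx in -1:ranges[1]) for (sy in -1:ranges[2]) for (sz in -1:ranges[3]) {
    f <- frac + c(sx, sy, sz)
    if (all(f >= -eps & f <= ranges + eps)) out <- rbind(out, f)
  }
  out
}

write_fixture_cif <- function(fx, dir = tempdir(), name = "fixture.cif") {
  path <- file.path(dir, name)
  writeLines(fx$cif, path)
  path
}
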