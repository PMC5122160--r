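# Space-group symmetry: xyz-operator parsing, fractional->Cartesian
# orthogonalization, symmetry expansion of the asymmetric unit, and
# unit-cell packing with boundary tolerance.

#' Construct a CrystalCell
#'
#' @param a,b,c Cell edge lengths in Angstrom (> 0).
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return A validated [CrystalCell-class].
#' @examples
#' crystalCell(5.64, 5.64, 5.64, 90, 90, 90)
#' @export
crystalCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  new("CrystalCell", a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      gamma = as.numeric(gamma))
}

#' @rdname cellVolume
#' @export
setMethod("cellVolume", "CrystalCell", function(cell) {
  ca <- cos(c(cell@alpha, cell@beta, cell@gamma) * pi / 180)
  cell@a * cell@b * cell@c * sqrt(1 - sum(ca^2) + 2 * prod(ca))
})

#' @rdname orthoMatrix
#' @export
setMethod("orthoMatrix", "CrystalCell", function(cell) {
  d2r <- pi / 180
  ca <- cos(cell@alpha * d2r); cb <- cos(cell@beta * d2r)
  cg <- cos(cell@gamma * d2r); sg <- sin(cell@gamma * d2r)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) stop("invalid cell: non-positive metric volume")
  v <- sqrt(disc)
  matrix(c(cell@a, cell@b * cg,           cell@c * cb,
           0,      cell@b * sg,           cell@c * (ca - cb * cg) / sg,
           0,      0,                     cell@c * v / sg),
         nrow = 3, byrow = TRUE)
})

#' Fractional to Cartesian coordinates
#'
#' Applies the cell's orthogonalization map (a along x, b in the xy plane).
#' Cartesian distances computed from the result equal metric-tensor
#' distances \eqn{\sqrt{\Delta x^T G \Delta x}}.
#'
#' @param cell A [CrystalCell-class].
#' @param frac numeric(3) or an n x 3 matrix of fractional coordinates.
#' @return Cartesian coordinates in Angstrom, same shape as `frac`.
#' @examples
#' fracToCart(crystalCell(10, 10, 10), c(0.5, 0.25, 0.1)) # 5.0 2.5 1.0
#' @export
fracToCart <- function(cell, frac) {
  M <- orthoMatrix(cell)
  if (is.matrix(frac)) t(M %*% t(frac)) else as.numeric(M %*% frac)
}

# --- xyz operator grammar ----------------------------------------------

# One component like "-x+1/2" -> list(row = c(-1, 0, 0), t = 0.5).
.parse_symop_component <- function(comp, full) {
  s <- gsub("[[:space:]]", "", tolower(comp))
  if (!nzchar(s)) stop("empty component in symmetry operator '", full, "'")
  row <- c(0, 0, 0); trans <- 0
  pat <- "^([+-]?)(x|y|z|[0-9]+(\\.[0-9]+)?(/[0-9]+)?)"
  while (nzchar(s)) {
    m <- regmatches(s, regexec(pat, s))[[1]]
    if (length(m) == 0 || !nzchar(m[1]))
      stop("cannot parse component '", comp, "' of symmetry operator '",
           full, "'")
    sign <- if (m[2] == "-") -1 else 1
    term <- m[3]
    if (term %in% c("x", "y", "z")) {
      ax <- match(term, c("x", "y", "z"))
      row[ax] <- row[ax] + sign
    } else if (grepl("/", term, fixed = TRUE)) {
      parts <- as.numeric(strsplit(term, "/", fixed = TRUE)[[1]])
      trans <- trans + sign * parts[1] / parts[2]
    } else {
      trans <- trans + sign * as.numeric(term)
    }
    s <- substring(s, nchar(m[1]) + 1L)
  }
  if (!all(row %in% c(-1, 0, 1)))
    stop("coefficient outside {-1,0,1} in component '", comp, "'")
  list(row = row, t = trans - floor(trans))
}

#' Parse an xyz symmetry-operator string
#'
#' Accepts the comma-separated triplet grammar of CIF symmetry operators:
#' tokens x, y, z with optional signs, plus integer, decimal, or fractional
#' translations in any order (`"-x+1/2, y, 0.5-z"`). Case-insensitive and
#' whitespace-tolerant. Decimal and fractional forms of the same
#' translation parse identically; translations are reduced into [0, 1).
#'
#' @param opString Operator string, e.g. `"-x+1/2, y, -z+1/2"`.
#' @return A [SymOp-class].
#' @examples
#' parseSymop("-x+1/2, y, -z+1/2")
#' @export
parseSymop <- function(opString) {
  comps <- strsplit(opString, ",", fixed = TRUE)[[1]]
  if (length(comps) != 3L)
    stop("symmetry operator '", opString, "' must have 3 comma-separated components")
  parsed <- lapply(comps, .parse_symop_component, full = opString)
  R <- do.call(rbind, lapply(parsed, `[[`, "row"))
  new("SymOp", R = R, t = vapply(parsed, `[[`, numeric(1), "t"))
}

#' Format a SymOp back to an xyz string
#'
#' Inverse of [parseSymop()] up to operator equivalence: the returned
#' string re-parses to the same R and t. Translations are written as small
#' fractions (denominators up to 12) when one matches to 1e-9, else as
#' decimals.
#'
#' @param op A [SymOp-class].
#' @return character(1), e.g. `"-x+1/2,y,-z+1/2"`.
#' @export
formatSymop <- function(op) {
  stopifnot(is(op, "SymOp"))
  axes <- c("x", "y", "z")
  comp <- character(3)
  for (r in 1:3) {
    s <- ""
    for (c in 1:3) {
      v <- op@R[r, c]
      if (v == 1) s <- paste0(s, if (nzchar(s)) "+" else "", axes[c])
      else if (v == -1) s <- paste0(s, "-", axes[c])
    }
    tv <- op@t[r]
    if (tv > 1e-12) {
      frac <- NA_character_
      for (den in 2:12) {
        num <- round(tv * den)
        if (num > 0 && abs(tv - num / den) < 1e-9) {
          g <- .gcd(num, den)
          frac <- paste0(num / g, "/", den / g)
          break
        }
      }
      s <- paste0(s, "+", if (is.na(frac)) format(tv) else frac)
    }
    comp[r] <- if (nzchar(s)) s else "0"
  }
  paste(comp, collapse = ",")
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

# --- expansion and packing ---------------------------------------------

# Wrap fractional coordinates into [0, 1), snapping values within 1e-9 of
# the upper boundary back to 0 so floating-point noise cannot split an
# atom across the cell.
.wrap_frac <- function(f) {
  f <- f - floor(f)
  f[f > 1 - 1e-9] <- 0
  f
}

# Greedy first-wins merge: atoms is a data.frame in deterministic priority
# order; two atoms merge iff same element and Cartesian distance < tol.
# Returns the logical keep mask. Uses a coarse grid so cost stays near
# linear in atom count.
.dedup_atoms <- function(atoms, tol) {
  n <- nrow(atoms)
  keep <- logical(n)
  cellsize <- max(tol, 1e-6)
  key <- function(p) paste(floor(p / cellsize), collapse = ",")
  grid <- new.env(hash = TRUE, parent = emptyenv())
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  for (i in seq_len(n)) {
    p <- xyz[i, ]
    base <- floor(p / cellsize)
    dup <- FALSE
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      k <- paste(base + c(dx, dy, dz), collapse = ",")
      for (j in grid[[k]]) {
        if (atoms$element[j] == atoms$element[i] &&
            sum((xyz[j, ] - p)^2) < tol^2) { dup <- TRUE; break }
      }
      if (dup) break
    }
    if (!dup) {
      keep[i] <- TRUE
      k <- key(p)
      grid[[k]] <- c(grid[[k]], i)
    }
  }
  keep
}

#' Apply space-group symmetry to the asymmetric unit
#'
#' Generates every (site, operator) image, wraps fractional coordinates
#' into [0, 1), converts to Cartesian, and merges duplicate images: two
#' images of the same element closer than `dedupTol` are one atom, the
#' copy with the lowest (site, operator) provenance winning. Output order
#' is deterministic (site-major, then operator). Hetero-element contacts
#' below `dedupTol` are kept and flagged with a message (likely disorder).
#'
#' @param structure A [StructureRecord-class].
#' @param dedupTol Merge tolerance in Angstrom (default 0.01).
#' @return data.frame of expanded atoms with columns `label`, `element`,
#'   `fx`, `fy`, `fz` (fractional, wrapped), `x`, `y`, `z` (Cartesian,
#'   Angstrom), `site`, `symop` (1-based provenance) and `sx`, `sy`, `sz`
#'   (integer lattice shift, all 0 here).
#' @examples
#' rec <- readCif(makeFixture("p1_molecule")$cif)
#' expandSymmetry(rec)
#' @export
expandSymmetry <- function(structure, dedupTol = 0.01) {
  stopifnot(is(structure, "StructureRecord"), dedupTol > 0)
  ops <- lapply(symopStrings(structure), parseSymop)
  sites <- atomSites(structure)
  nops <- length(ops); nsit <- nrow(sites)
  rows <- vector("list", nsit * nops)
  k <- 0L
  for (s in seq_len(nsit)) {
    f0 <- as.numeric(sites[s, c("fx", "fy", "fz")])
    for (o in seq_len(nops)) {
      f <- .wrap_frac(as.numeric(ops[[o]]@R %*% f0 + ops[[o]]@t))
      k <- k + 1L
      rows[[k]] <- c(f, s, o)
    }
  }
  m <- do.call(rbind, rows)
  atoms <- data.frame(
    label = sites$label[m[, 4]], element = sites$element[m[, 4]],
    fx = m[, 1], fy = m[, 2], fz = m[, 3],
    site = as.integer(m[, 4]), symop = as.integer(m[, 5]),
    sx = 0L, sy = 0L, sz = 0L, stringsAsFactors = FALSE)
  cart <- fracToCart(cellOf(structure), as.matrix(atoms[, c("fx", "fy", "fz")]))
  atoms$x <- cart[, 1]; atoms$y <- cart[, 2]; atoms$z <- cart[, 3]
  atoms <- atoms[, c("label", "element", "fx", "fy", "fz",
                     "x", "y", "z", "site", "symop", "sx", "sy", "sz")]
  keep <- .dedup_atoms(atoms, dedupTol)
  .flag_close_hetero(atoms[keep, , drop = FALSE], dedupTol)
  out <- atoms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.flag_close_hetero <- function(atoms, tol) {
  n <- nrow(atoms)
  if (n < 2L || n > 500L) return(invisible())
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  diff_el <- outer(atoms$element, atoms$element, "!=")
  close <- d < tol & diff_el & upper.tri(d)
  if (any(close))
    message(sum(close), " hetero-element contact(s) below ", tol,
            " Angstrom kept (possible disorder artifact)")
  invisible()
}

#' Pack one or more unit cells
#'
#' Starting from [expandSymmetry()]'s images, enumerates integer lattice
#' translations from -1 up to `ranges[axis]` on each axis and keeps a copy
#' when every fractional coordinate lies within
#' `[-boundaryEps, range + boundaryEps]`. Atoms sitting on a cell face,
#' edge or corner therefore appear on every incident boundary (8 copies
#' for a corner atom of one cell). Duplicates merge as in expansion.
#'
#' @param structure A [StructureRecord-class].
#' @param ranges integer(3), cells to fill per axis (default `c(1, 1, 1)`).
#' @param boundaryEps Fractional boundary tolerance (default 1e-4).
#' @param dedupTol Merge tolerance in Angstrom (default 0.01).
#' @return data.frame as in [expandSymmetry()]; `sx`, `sy`, `sz` carry the
#'   lattice shift of each copy and `fx`..`fz` are the shifted (unwrapped)
#'   fractional coordinates.
#' @examples
#' rec <- readCif(makeFixture("rocksalt")$cif)
#' nrow(packCell(rec)) # 27 for the rock-salt cell
#' @export
packCell <- function(structure, ranges = c(1L, 1L, 1L), boundaryEps = 1e-4,
                     dedupTol = 0.01) {
  stopifnot(length(ranges) == 3L, all(ranges >= 1), boundaryEps >= 0)
  base <- expandSymmetry(structure, dedupTol = dedupTol)
  shifts <- expand.grid(sz = -1:ranges[3], sy = -1:ranges[2], sx = -1:ranges[1])
  shifts <- shifts[order(shifts$sx, shifts$sy, shifts$sz), c("sx", "sy", "sz")]
  out <- vector("list", nrow(base))
  for (i in seq_len(nrow(base))) {
    f <- as.numeric(base[i, c("fx", "fy", "fz")])
    fs <- sweep(as.matrix(shifts), 2, f, "+")
    ok <- fs[, 1] >= -boundaryEps & fs[, 1] <= ranges[1] + boundaryEps &
          fs[, 2] >= -boundaryEps & fs[, 2] <= ranges[2] + boundaryEps &
          fs[, 3] >= -boundaryEps & fs[, 3] <= ranges[3] + boundaryEps
    if (!any(ok)) next
    rep_row <- base[rep(i, sum(ok)), , drop = FALSE]
    rep_row[, c("fx", "fy", "fz")] <- fs[ok, , drop = FALSE]
    rep_row[, c("sx", "sy", "sz")] <- as.matrix(shifts)[ok, , drop = FALSE]
    out[[i]] <- rep_row
  }
  atoms <- do.call(rbind, out)
  # deterministic priority: site-major, then symop, then shift order
  atoms <- atoms[order(atoms$site, atoms$symop, atoms$sx, atoms$sy, atoms$sz), ]
  cart <- fracToCart(cellOf(structure), as.matrix(atoms[, c("fx", "fy", "fz")]))
  atoms$x <- cart[, 1]; atoms$y <- cart[, 2]; atoms$z <- cart[, 3]
  keep <- .dedup_atoms(atoms, dedupTol)
  out <- atoms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
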