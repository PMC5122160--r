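# Bond perception from covalent radii and partition of the expanded atom
# set into connected fragments (molecules or extended-solid networks).

#' Perceive bonds from covalent radii
#'
#' Two atoms are bonded iff their Cartesian distance d satisfies
#' `0.4 < d <= r_cov(i) + r_cov(j) + bondTol`, mirroring common
#' crystallographic-viewer heuristics. The 0.4 Angstrom floor discards
#' coincidence duplicates; H-H pairs are never bonded. A uniform spatial
#' grid keeps the cost near linear in atom count. Elements without a
#' tabulated radius fall back to 1.5 Angstrom with a warning.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` (as
#'   produced by [expandSymmetry()] or [packCell()]).
#' @param bondTol Additive bond tolerance in Angstrom (default 0.45).
#' @return data.frame of bonds with columns `i`, `j` (row indices into
#'   `atoms`, `i < j`) and `length` (Angstrom), ordered by (`i`, `j`).
#' @examples
#' rec <- readCif(makeFixture("p1_molecule")$cif)
#' perceiveBonds(expandSymmetry(rec)) # the two O-H bonds of water
#' @export
perceiveBonds <- function(atoms, bondTol = 0.45) {
  n <- nrow(atoms)
  if (n < 2L) return(data.frame(i = integer(0), j = integer(0),
                                length = numeric(0)))
  rcov <- covalentRadius(atoms$element)
  maxcut <- max(rcov) * 2 + bondTol
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  cellidx <- floor(xyz / maxcut)
  key <- apply(cellidx, 1, paste, collapse = ",")
  grid <- split(seq_len(n), key)
  isH <- atoms$element == "H"
  ii <- jj <- integer(0); dd <- numeric(0)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (k in names(grid)) {
    a <- grid[[k]]
    base <- as.numeric(strsplit(k, ",", fixed = TRUE)[[1]])
    for (r in seq_len(nrow(offs))) {
      k2 <- paste(base + offs[r, ], collapse = ",")
      b <- grid[[k2]]
      if (is.null(b)) next
      pairkey <- paste(min(k, k2), max(k, k2))
      if (!is.null(seen[[pairkey]])) next
      seen[[pairkey]] <- TRUE
      cand <- expand.grid(a = a, b = b)
      # same cell: each unordered pair once; cross cell: all pairs, ordered
      if (identical(k, k2)) cand <- cand[cand$a < cand$b, , drop = FALSE]
      ca <- pmin(cand$a, cand$b); cb <- pmax(cand$a, cand$b)
      if (length(ca) == 0) next
      d <- sqrt(rowSums((xyz[ca, , drop = FALSE] -
                         xyz[cb, , drop = FALSE])^2))
      cut <- rcov[ca] + rcov[cb] + bondTol
      ok <- d > 0.4 & d <= cut & !(isH[ca] & isH[cb])
      ii <- c(ii, ca[ok]); jj <- c(jj, cb[ok]); dd <- c(dd, d[ok])
    }
  }
  o <- order(ii, jj)
  data.frame(i = as.integer(ii[o]), j = as.integer(jj[o]), length = dd[o])
}

#' Partition atoms into connected fragments
#'
#' Connected components of the bond graph; isolated atoms become
#' single-atom fragments. Fragments are returned sorted by decreasing atom
#' count, ties broken by the lowest contained atom index.
#'
#' @param atoms Expanded-atom data.frame.
#' @param bonds Bond data.frame from [perceiveBonds()].
#' @return list of [Fragment-class] objects partitioning `seq_len(nrow(atoms))`.
#' @export
findFragments <- function(atoms, bonds) {
  n <- nrow(atoms)
  if (n == 0L) return(list())
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds) > 0)
    g <- igraph::add_edges(g, rbind(bonds$i, bonds$j))
  memb <- igraph::components(g)$membership
  frags <- lapply(split(seq_len(n), memb), function(idx) {
    idx <- sort(as.integer(idx))
    fb <- bonds[bonds$i %in% idx & bonds$j %in% idx, , drop = FALSE]
    rownames(fb) <- NULL
    new("Fragment", atomIndices = idx, bonds = fb)
  })
  sizes <- vapply(frags, function(f) length(f@atomIndices), integer(1))
  firsts <- vapply(frags, function(f) f@atomIndices[1L], integer(1))
  unname(frags[order(-sizes, firsts)])
}

#' Select the fragment to print
#'
#' Returns the fragment with the greatest number of atoms; all others are
#' discarded downstream (duplicate molecules with the same atom count and
#' smaller molecules alike). Ties — enantiomer pairs have equal atom
#' counts — are broken deterministically by the lowest contained atom
#' index, so repeated runs always keep the same copy.
#'
#' @param fragments Non-empty list of [Fragment-class] objects.
#' @return The selected [Fragment-class].
#' @export
selectPrimary <- function(fragments) {
  if (length(fragments) == 0L) stop("no fragments to select from")
  sizes <- vapply(fragments, function(f) length(f@atomIndices), integer(1))
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    firsts <- vapply(fragments[best], function(f) f@atomIndices[1L], integer(1))
    best <- best[which.min(firsts)]
  }
  fragments[[best[1L]]]
}
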