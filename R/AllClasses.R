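#' @import methods
NULL

#' Crystallographic unit cell
#'
#' Holds the six cell parameters of a triclinic (or higher-symmetry) unit
#' cell: edge lengths in Angstrom and inter-axial angles in degrees. The
#' validity method rejects degenerate cells (non-positive lengths, angles
#' outside (0, 180), or a metric with non-positive volume).
#'
#' @slot a,b,c numeric(1). Cell edge lengths in Angstrom.
#' @slot alpha,beta,gamma numeric(1). Cell angles in degrees.
#'
#' @seealso [crystalCell()], [cellVolume()], [orthoMatrix()], [fracToCart()]
#' @export
setClass("CrystalCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric"))

setValidity("CrystalCell", function(object) {
  len <- c(object@a, object@b, object@c)
  ang <- c(object@alpha, object@beta, object@gamma)
  if (length(len) != 3L || any(!is.finite(len)) || any(len <= 0))
    return("cell lengths must be finite and > 0")
  if (length(ang) != 3L || any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    return("cell angles must lie in (0, 180) degrees")
  ca <- cos(ang * pi / 180)
  disc <- 1 - sum(ca^2) + 2 * prod(ca)
  if (disc <= 0) return("cell metric has non-positive volume")
  TRUE
})

#' One CIF data block: cell, symmetry operators, asymmetric unit
#'
#' The parsed content of a single CIF data block that the conversion
#' pipeline needs: a [CrystalCell-class], the space-group operator strings
#' in xyz form (identity injected when the file lists none), and the
#' asymmetric-unit atom sites as a data.frame with columns `label`,
#' `element`, `fx`, `fy`, `fz` (fractional coordinates) and `occupancy`.
#'
#' @slot name character(1). Data-block identifier.
#' @slot cell A [CrystalCell-class].
#' @slot symops character. Ordered xyz operator strings, non-empty.
#' @slot sites data.frame. Ordered atom sites, non-empty.
#'
#' @seealso [readCif()], [writeCif()], [expandSymmetry()]
#' @export
setClass("StructureRecord",
  representation(name = "character", cell = "CrystalCell",
                 symops = "character", sites = "data.frame"))

setValidity("StructureRecord", function(object) {
  if (length(object@name) != 1L) return("name must be a single string")
  if (length(object@symops) < 1L) return("symops must be non-empty")
  need <- c("label", "element", "fx", "fy", "fz", "occupancy")
  if (!all(need %in% names(object@sites)))
    return(paste("sites must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@sites) < 1L) return("sites must be non-empty")
  TRUE
})

#' Affine space-group symmetry operator
#'
#' A symmetry operator in fractional space: x' = R x + t, parsed from an
#' xyz string such as `"-x+1/2, y, -z+1/2"`. R has entries in {-1, 0, 1}
#' with determinant +1 (proper) or -1 (improper); t is reduced into [0, 1).
#'
#' @slot R 3x3 numeric matrix, the rotation part.
#' @slot t numeric(3), the translation part, each component in [0, 1).
#'
#' @seealso [parseSymop()], [formatSymop()]
#' @export
setClass("SymOp", representation(R = "matrix", t = "numeric"))

setValidity("SymOp", function(object) {
  if (!all(dim(object@R) == c(3L, 3L))) return("R must be 3x3")
  if (!all(object@R %in% c(-1, 0, 1))) return("R entries must be in {-1, 0, 1}")
  d <- round(det(object@R))
  if (!d %in% c(-1, 1)) return("det(R) must be -1 or +1")
  if (length(object@t) != 3L) return("t must have length 3")
  if (any(object@t < 0 | object@t >= 1)) return("t components must lie in [0, 1)")
  TRUE
})

#' Connected fragment of an expanded structure
#'
#' A connected set of expanded atoms together with the bonds internal to
#' it: one molecule, or one network of an extended solid. Indices refer to
#' rows of the expanded-atom data.frame the fragment was derived from.
#'
#' @slot atomIndices integer. Row indices of member atoms (sorted).
#' @slot bonds data.frame. Internal bonds with columns `i`, `j`, `length`.
#'
#' @seealso [findFragments()], [selectPrimary()]
#' @export
setClass("Fragment",
  representation(atomIndices = "integer", bonds = "data.frame"))

setValidity("Fragment", function(object) {
  if (length(object@atomIndices) < 1L) return("fragment must contain atoms")
  if (is.unsorted(object@atomIndices, strictly = TRUE))
    return("atomIndices must be strictly increasing")
  if (nrow(object@bonds) > 0 &&
      !all(c(object@bonds$i, object@bonds$j) %in% object@atomIndices))
    return("bonds must reference member atoms")
  TRUE
})

#' Indexed triangle mesh shell
#'
#' One closed mesh shell (an atom sphere or a half-bond cylinder) in output
#' model units, with a colour per vertex. Triangles are counter-clockwise
#' when viewed from outside, so right-hand-rule normals point outward.
#'
#' @slot vertices n x 3 numeric matrix of vertex positions.
#' @slot triangles m x 3 integer matrix of 1-based vertex indices.
#' @slot vertexColors n x 3 numeric matrix, RGB in [0, 255].
#'
#' @seealso [icosphere()], [cappedCylinder()], [validateShell()]
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", triangles = "matrix",
                 vertexColors = "matrix"))

setValidity("TriangleMesh", function(object) {
  if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
  if (ncol(object@triangles) != 3L) return("triangles must be m x 3")
  if (nrow(object@triangles) < 1L) return("mesh must have triangles")
  idx <- as.integer(object@triangles)
  if (any(idx < 1L) || any(idx > nrow(object@vertices)))
    return("triangle indices out of range")
  if (!all(dim(object@vertexColors) == dim(object@vertices)))
    return("vertexColors must match vertices in shape")
  if (any(object@vertexColors < 0 | object@vertexColors > 255))
    return("vertexColors must be RGB in [0, 255]")
  TRUE
})

#' Ball-and-stick styling parameters
#'
#' Controls the geometry and colouring of exported models. Defaults give the
#' conventional ball-and-stick look: atom spheres at 23% of the van der
#' Waals radius, 0.15 Angstrom bond cylinders, and a 10x scale so that one
#' Angstrom maps to 10 model units (read as millimetres by print services).
#'
#' @slot scale numeric(1) > 0. Multiplies all coordinates (default 10).
#' @slot sphereFraction numeric(1) in (0, 1]. Atom sphere radius as a
#'   fraction of the element's van der Waals radius (default 0.23).
#' @slot bondRadius numeric(1) > 0. Bond cylinder radius in Angstrom
#'   (default 0.15); must stay below every bonded atom's sphere radius so
#'   cylinder end caps are buried inside the spheres.
#' @slot sphereLevel integer(1) >= 0. Icosphere subdivision level (default 2).
#' @slot cylSegments integer(1) >= 3. Cylinder facet count (default 16).
#'
#' @seealso [styleConfig()], [buildBallStick()]
#' @export
setClass("StyleConfig",
  representation(scale = "numeric", sphereFraction = "numeric",
                 bondRadius = "numeric", sphereLevel = "integer",
                 cylSegments = "integer"))

setValidity("StyleConfig", function(object) {
  if (object@scale <= 0) return("scale must be > 0")
  if (object@sphereFraction <= 0 || object@sphereFraction > 1)
    return("sphereFraction must lie in (0, 1]")
  if (object@bondRadius <= 0) return("bondRadius must be > 0")
  if (object@sphereLevel < 0L) return("sphereLevel must be >= 0")
  if (object@cylSegments < 3L) return("cylSegments must be >= 3")
  TRUE
})

#' A set of shells ready for serialization
#'
#' Bundles the mesh shells of one model with an identifier and a free-text
#' units note that the VRML writer embeds as a comment. Construction via
#' [exportBundle()] validates every shell for printability unless forced.
#'
#' @slot shells list of [TriangleMesh-class] objects, non-empty.
#' @slot name character(1). Model identifier.
#' @slot unitsNote character(1). Provenance/units comment.
#'
#' @seealso [exportBundle()], [writeVrml()], [writeStl()]
#' @export
setClass("ExportBundle",
  representation(shells = "list", name = "character", unitsNote = "character"))

setValidity("ExportBundle", function(object) {
  if (length(object@shells) < 1L) return("shells must be non-empty")
  if (!all(vapply(object@shells, is, logical(1), class2 = "TriangleMesh")))
    return("all shells must be TriangleMesh objects")
  if (length(object@name) != 1L) return("name must be a single string")
  TRUE
})
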