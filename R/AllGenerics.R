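#' Cell volume in cubic Angstrom
#'
#' Volume from the triclinic formula
#' \eqn{V = abc\sqrt{1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma +
#' 2\cos\alpha\cos\beta\cos\gamma}}.
#'
#' @param cell A [CrystalCell-class].
#' @return numeric(1), volume in cubic Angstrom.
#' @examples
#' cellVolume(crystalCell(10, 10, 10, 90, 90, 90)) # 1000
#' @export
setGeneric("cellVolume", function(cell) standardGeneric("cellVolume"))

#' Orthogonalization matrix of a cell
#'
#' The 3x3 matrix M mapping fractional to Cartesian coordinates
#' (cart = M frac), with the convention that a lies along the first
#' Cartesian axis and b in the first-second plane.
#'
#' @param cell A [CrystalCell-class].
#' @return 3x3 numeric matrix (Angstrom).
#' @seealso [fracToCart()]
#' @export
setGeneric("orthoMatrix", function(cell) standardGeneric("orthoMatrix"))

#' @rdname structure-accessors
#' @export
setGeneric("structureName", function(x) standardGeneric("structureName"))

#' @rdname structure-accessors
#' @export
setGeneric("cellOf", function(x) standardGeneric("cellOf"))

#' @rdname structure-accessors
#' @export
setGeneric("symopStrings", function(x) standardGeneric("symopStrings"))

#' @rdname structure-accessors
#' @export
setGeneric("atomSites", function(x) standardGeneric("atomSites"))

#' @rdname mesh-accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname mesh-accessors
#' @export
setGeneric("meshTriangles", function(x) standardGeneric("meshTriangles"))

#' @rdname mesh-accessors
#' @export
setGeneric("meshColors", function(x) standardGeneric("meshColors"))

#' @rdname fragment-accessors
#' @export
setGeneric("atomIndices", function(x) standardGeneric("atomIndices"))

#' @rdname fragment-accessors
#' @export
setGeneric("fragmentBonds", function(x) standardGeneric("fragmentBonds"))

#' @rdname fragment-accessors
#' @export
setGeneric("natoms", function(x) standardGeneric("natoms"))
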