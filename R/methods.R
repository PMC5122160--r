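#' Accessors for StructureRecord
#'
#' `structureName()` returns the data-block identifier, `cellOf()` the
#' [CrystalCell-class], `symopStrings()` the xyz operator strings, and
#' `atomSites()` the asymmetric-unit atom-site data.frame.
#'
#' @param x A [StructureRecord-class].
#' @return See individual descriptions.
#' @name structure-accessors
NULL

#' @rdname structure-accessors
#' @export
setMethod("structureName", "StructureRecord", function(x) x@name)

#' @rdname structure-accessors
#' @export
setMethod("cellOf", "StructureRecord", function(x) x@cell)

#' @rdname structure-accessors
#' @export
setMethod("symopStrings", "StructureRecord", function(x) x@symops)

#' @rdname structure-accessors
#' @export
setMethod("atomSites", "StructureRecord", function(x) x@sites)

#' Accessors for TriangleMesh
#'
#' `meshVertices()` returns the n x 3 vertex matrix, `meshTriangles()` the
#' m x 3 index matrix, `meshColors()` the per-vertex RGB matrix.
#'
#' @param x A [TriangleMesh-class].
#' @return A numeric (or integer) matrix; see descriptions.
#' @name mesh-accessors
NULL

#' @rdname mesh-accessors
#' @export
setMethod("meshVertices", "TriangleMesh", function(x) x@vertices)

#' @rdname mesh-accessors
#' @export
setMethod("meshTriangles", "TriangleMesh", function(x) x@triangles)

#' @rdname mesh-accessors
#' @export
setMethod("meshColors", "TriangleMesh", function(x) x@vertexColors)

#' Accessors for Fragment
#'
#' `atomIndices()` returns the member atom indices (rows of the
#' expanded-atom table), `fragmentBonds()` the internal bond data.frame,
#' `natoms()` the member count.
#'
#' @param x A [Fragment-class].
#' @return See individual descriptions.
#' @name fragment-accessors
NULL

#' @rdname fragment-accessors
#' @export
setMethod("atomIndices", "Fragment", function(x) x@atomIndices)

#' @rdname fragment-accessors
#' @export
setMethod("fragmentBonds", "Fragment", function(x) x@bonds)

#' @rdname fragment-accessors
#' @export
setMethod("natoms", "Fragment", function(x) length(x@atomIndices))

setMethod("show", "CrystalCell", function(object) {
  cat(sprintf("CrystalCell: a=%.4f b=%.4f c=%.4f A  alpha=%.2f beta=%.2f gamma=%.2f deg  V=%.2f A^3\n",
              object@a, object@b, object@c, object@alpha, object@beta,
              object@gamma, cellVolume(object)))
})

setMethod("show", "StructureRecord", function(object) {
  cat(sprintf("StructureRecord '%s': %d site(s), %d symmetry operator(s)\n",
              object@name, nrow(object@sites), length(object@symops)))
  show(object@cell)
  el <- table(object@sites$element)
  cat("  asymmetric unit:",
      paste(names(el), el, sep = "x", collapse = " "), "\n")
})

setMethod("show", "SymOp", function(object) {
  cat("SymOp:", formatSymop(object),
      sprintf("(det %+d)\n", as.integer(round(det(object@R)))))
})

setMethod("show", "Fragment", function(object) {
  cat(sprintf("Fragment: %d atom(s), %d bond(s); atom indices %s%s\n",
              length(object@atomIndices), nrow(object@bonds),
              paste(utils::head(object@atomIndices, 8), collapse = ","),
              if (length(object@atomIndices) > 8) ",..." else ""))
})

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d triangles\n",
              nrow(object@vertices), nrow(object@triangles)))
})

setMethod("show", "StyleConfig", function(object) {
  cat(sprintf("StyleConfig: scale=%g sphereFraction=%g bondRadius=%g A sphereLevel=%d cylSegments=%d\n",
              object@scale, object@sphereFraction, object@bondRadius,
              object@sphereLevel, object@cylSegments))
})

setMethod("show", "ExportBundle", function(object) {
  ntri <- sum(vapply(object@shells, function(s) nrow(s@triangles), integer(1)))
  cat(sprintf("ExportBundle '%s': %d shell(s), %d triangles\n",
              object@name, length(object@shells), ntri))
})
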