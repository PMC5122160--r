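# Serialization of shell lists to VRML 2.0 (indexed face sets, per-vertex
# colour) and STL (binary little-endian or ASCII). Geometry is always
# written as raw triangles: the node types Sphere, Cylinder and Cone never
# appear, so files need no post-processing before printing.

#' Bundle shells for export
#'
#' Wraps a shell list with a model name and units note, validating every
#' shell with [validateShell()] first: a bundle containing a non-watertight
#' shell is refused unless `force = TRUE`.
#'
#' @param shells Non-empty list of [TriangleMesh-class] objects.
#' @param name Model identifier (used in headers/comments).
#' @param unitsNote Free-text provenance comment embedded in VRML output.
#' @param force Skip the watertightness gate (default FALSE).
#' @return An [ExportBundle-class].
#' @export
exportBundle <- function(shells, name = "model",
                         unitsNote = "model units are millimetres",
                         force = FALSE) {
  if (length(shells) == 0L) stop("refusing to bundle an empty shell list")
  if (!force) {
    ok <- vapply(shells, function(s) validateShell(s)$watertight, logical(1))
    if (!all(ok))
      stop("shell(s) ", paste(which(!ok), collapse = ", "),
           " fail the printability check; fix or use force = TRUE")
  }
  new("ExportBundle", shells = shells, name = name, unitsNote = unitsNote)
}

# Format numbers with 6 significant digits, plain notation, no NaN/Inf.
.fmt6 <- function(x) {
  stopifnot(all(is.finite(x)))
  formatC(signif(x, 6), format = "fg", flag = "#", width = 1)
}

#' Write an ExportBundle as VRML 2.0
#'
#' Emits a `#VRML V2.0 utf8` file in which each shell is one Shape node
#' whose geometry is an IndexedFaceSet with per-vertex colour and
#' -1-terminated coordinate-index runs. No high-level primitive nodes
#' (Sphere, Cylinder, Cone) are ever emitted, so the file can go straight
#' to multi-colour 3D printing. Numbers carry 6 significant digits.
#'
#' @param bundle An [ExportBundle-class].
#' @param destination Output file path (conventionally `.wrl`).
#' @return `destination`, invisibly.
#' @export
writeVrml <- function(bundle, destination) {
  stopifnot(is(bundle, "ExportBundle"))
  con <- file(destination, open = "wt")
  on.exit(close(con))
  writeLines(c("#VRML V2.0 utf8",
               paste0("# model: ", bundle@name),
               paste0("# ", bundle@unitsNote)), con)
  for (shell in bundle@shells) {
    v <- shell@vertices
    f <- shell@triangles
    col <- shell@vertexColors / 255
    pts <- paste(.fmt6(v[, 1]), .fmt6(v[, 2]), .fmt6(v[, 3]), collapse = ", ")
    cols <- paste(.fmt6(col[, 1]), .fmt6(col[, 2]), .fmt6(col[, 3]),
                  collapse = ", ")
    idx <- paste(f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L, -1L, collapse = ", ")
    writeLines(c(
      "Shape {",
      "  appearance Appearance { material Material { } }",
      "  geometry IndexedFaceSet {",
      "    solid TRUE",
      "    colorPerVertex TRUE",
      paste0("    coord Coordinate { point [ ", pts, " ] }"),
      paste0("    color Color { color [ ", cols, " ] }"),
      paste0("    coordIndex [ ", idx, " ]"),
      "  }",
      "}"), con)
  }
  invisible(destination)
}

# Unit right-hand-rule normals of each triangle; zero-area faces get (0,0,0).
.face_normals <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
             ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
             ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Write an ExportBundle as STL
#'
#' Binary mode writes the standard little-endian layout: an 80-byte
#' header, a 4-byte triangle count, then 50 bytes per triangle (12 floats
#' for normal + three vertices, 2-byte attribute = 0), so the file is
#' exactly `84 + 50 n` bytes. Normals are recomputed from vertex winding
#' (right-hand rule). STL carries no colour, so all shells are
#' concatenated into one solid by default; `perShell = TRUE` writes one
#' `solid`/`endsolid` block per shell in ASCII mode instead.
#'
#' @param bundle An [ExportBundle-class].
#' @param destination Output file path (conventionally `.stl`).
#' @param mode `"binary"` (default) or `"ascii"`.
#' @param perShell ASCII only: one solid block per shell (default FALSE).
#' @return `destination`, invisibly.
#' @export
writeStl <- function(bundle, destination, mode = c("binary", "ascii"),
                     perShell = FALSE) {
  stopifnot(is(bundle, "ExportBundle"))
  mode <- match.arg(mode)
  tri_of <- function(shell) {
    v <- shell@vertices; f <- shell@triangles
    list(n = .face_normals(v, f),
         a = v[f[, 1], , drop = FALSE],
         b = v[f[, 2], , drop = FALSE],
         c = v[f[, 3], , drop = FALSE])
  }
  parts <- lapply(bundle@shells, tri_of)
  if (mode == "binary") {
    nmat <- do.call(rbind, lapply(parts, `[[`, "n"))
    amat <- do.call(rbind, lapply(parts, `[[`, "a"))
    bmat <- do.call(rbind, lapply(parts, `[[`, "b"))
    cmat <- do.call(rbind, lapply(parts, `[[`, "c"))
    stopifnot(all(is.finite(c(nmat, amat, bmat, cmat))))
    ntri <- nrow(nmat)
    con <- file(destination, open = "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", paste0("cif2print: ", bundle@name)))
    writeBin(header[1:80], con)
    writeBin(as.integer(ntri), con, size = 4L, endian = "little")
    # interleave: 12 floats then the 2-byte attribute, per triangle
    floats <- cbind(nmat, amat, bmat, cmat)  # ntri x 12
    for (i in seq_len(ntri)) {
      writeBin(as.numeric(floats[i, ]), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(destination, open = "wt")
    on.exit(close(con))
    emit <- function(p, nm) {
      writeLines(paste0("solid ", nm), con)
      for (i in seq_len(nrow(p$n))) {
        writeLines(c(
          sprintf("  facet normal %e %e %e", p$n[i, 1], p$n[i, 2], p$n[i, 3]),
          "    outer loop",
          sprintf("      vertex %e %e %e", p$a[i, 1], p$a[i, 2], p$a[i, 3]),
          sprintf("      vertex %e %e %e", p$b[i, 1], p$b[i, 2], p$b[i, 3]),
          sprintf("      vertex %e %e %e", p$c[i, 1], p$c[i, 2], p$c[i, 3]),
          "    endloop",
          "  endfacet"), con)
      }
      writeLines(paste0("endsolid ", nm), con)
    }
    if (perShell) {
      for (k in seq_along(parts))
        emit(parts[[k]], paste0(bundle@name, "_shell", k))
    } else {
      merged <- list(n = do.call(rbind, lapply(parts, `[[`, "n")),
                     a = do.call(rbind, lapply(parts, `[[`, "a")),
                     b = do.call(rbind, lapply(parts, `[[`, "b")),
                     c = do.call(rbind, lapply(parts, `[[`, "c")))
      stopifnot(all(is.finite(unlist(merged))))
      emit(merged, bundle@name)
    }
  }
  invisible(destination)
}

#' Read an STL file
#'
#' Auto-detects the dialect: a file is ASCII iff it starts with `solid`
#' and parses fully as ASCII STL; anything else is read as binary. For a
#' binary file the byte length must equal `84 + 50 n` for the declared
#' triangle count n, otherwise a corrupt-file error is raised.
#'
#' @param source STL file path.
#' @return list with `triangles` (n x 9 matrix: vertex1, vertex2, vertex3
#'   coordinates per row) and `normals` (n x 3, as stored in the file).
#' @export
readStl <- function(source) {
  head_raw <- readBin(source, "raw", n = 5L)
  if (identical(rawToChar(head_raw), "solid")) {
    parsed <- tryCatch(.read_stl_ascii(source), error = function(e) NULL)
    if (!is.null(parsed)) return(parsed)
  }
  .read_stl_binary(source)
}

.read_stl_ascii <- function(source) {
  lines <- trimws(readLines(source, warn = FALSE))
  nidx <- grep("^facet normal ", lines)
  normals <- t(vapply(strsplit(sub("^facet normal ", "", lines[nidx]), "\\s+"),
                      function(x) as.numeric(x[1:3]), numeric(3)))
  vidx <- grep("^vertex ", lines)
  if (length(vidx) != 3L * length(nidx) || length(nidx) == 0L)
    stop("not a complete ASCII STL")
  verts <- t(vapply(strsplit(sub("^vertex ", "", lines[vidx]), "\\s+"),
                    function(x) as.numeric(x[1:3]), numeric(3)))
  if (anyNA(verts) || anyNA(normals)) stop("unparseable ASCII STL numbers")
  tri <- matrix(t(verts), ncol = 9, byrow = TRUE)
  list(triangles = tri, normals = matrix(normals, ncol = 3))
}

.read_stl_binary <- function(source) {
  sz <- file.size(source)
  if (is.na(sz) || sz < 84) stop("corrupt STL: file shorter than header")
  con <- file(source, open = "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (ntri < 0 || sz != 84 + 50 * as.numeric(ntri))
    stop("corrupt STL: declared triangle count disagrees with file size")
  tri <- matrix(0, nrow = ntri, ncol = 9)
  normals <- matrix(0, nrow = ntri, ncol = 3)
  for (i in seq_len(ntri)) {
    vals <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    invisible(readBin(con, "raw", n = 2L))
    normals[i, ] <- vals[1:3]
    tri[i, ] <- vals[4:12]
  }
  list(triangles = tri, normals = normals)
}
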