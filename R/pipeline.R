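# End-to-end conversion: CIF -> symmetry expansion (or packing) -> bond
# perception -> fragment selection -> ball-and-stick shells -> VRML/STL.
# The batch driver isolates per-file failures so one bad CIF never aborts
# a run.

#' Conversion job configuration
#'
#' @param mode `"molecular"` (symmetry expansion only, the default) or
#'   `"packed"` (fill one unit cell with boundary tolerance, for extended
#'   solids).
#' @param perMolecule Export every fragment as its own model instead of
#'   keeping only the largest — preserves co-crystal partners, both
#'   enantiomers and counterions (default FALSE).
#' @param style A [StyleConfig-class].
#' @param formats Character subset of `c("vrml", "stl")`, non-empty.
#' @param outputDir Directory for output files (created if missing).
#' @param dedupTol,bondTol,boundaryEps Tolerances passed to
#'   [expandSymmetry()], [perceiveBonds()] and [packCell()].
#' @param stlMode `"binary"` or `"ascii"` STL dialect.
#' @return list of class `"JobConfig"`.
#' @export
jobConfig <- function(mode = c("molecular", "packed"), perMolecule = FALSE,
                      style = styleConfig(), formats = c("vrml", "stl"),
                      outputDir = ".", dedupTol = 0.01, bondTol = 0.45,
                      boundaryEps = 1e-4, stlMode = "binary") {
  mode <- match.arg(mode)
  formats <- match.arg(formats, several.ok = TRUE)
  if (length(formats) == 0L) stop("formats must be non-empty")
  stopifnot(is(style, "StyleConfig"))
  structure(list(mode = mode, perMolecule = perMolecule, style = style,
                 formats = formats, outputDir = outputDir,
                 dedupTol = dedupTol, bondTol = bondTol,
                 boundaryEps = boundaryEps, stlMode = stlMode),
            class = "JobConfig")
}

.entry <- function(file, status, reason = "", nFragments = NA_integer_,
                   keptAtoms = NA_integer_, deletedFragments = NA_integer_,
                   outputs = character(0)) {
  data.frame(file = file, status = status, reason = reason,
             nFragments = nFragments, keptAtoms = keptAtoms,
             deletedFragments = deletedFragments,
             outputs = paste(outputs, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Convert one CIF into 3D-printable model files
#'
#' Runs the full chain: [readCif()], then [expandSymmetry()] (molecular
#' mode) or [packCell()] (packed mode), [perceiveBonds()],
#' [findFragments()], [selectPrimary()] (or every fragment when
#' `perMolecule`), [buildBallStick()], and the writers for each requested
#' format. Deleted-fragment counts are reported; no axis or cell-guide
#' geometry is ever generated. On any stage error the entry is marked
#' failed with the stage name and any partially written outputs are
#' removed.
#'
#' @param cifPath Path to a readable CIF file.
#' @param config A [jobConfig()] list.
#' @return One-row data.frame: `file`, `status` (`"ok"`/`"failed"`),
#'   `reason`, `nFragments`, `keptAtoms`, `deletedFragments`, `outputs`
#'   (semicolon-joined paths).
#' @examples
#' fx <- makeFixture("p1_molecule")
#' cif <- tempfile(fileext = ".cif"); writeLines(fx$cif, cif)
#' convertStructure(cif, jobConfig(outputDir = tempdir(), formats = "stl"))
#' @export
convertStructure <- function(cifPath, config = jobConfig()) {
  stopifnot(inherits(config, "JobConfig"))
  stage <- "read_cif"
  written <- character(0)
  res <- tryCatch({
    record <- readCif(cifPath)
    stage <- "symmetry"
    atoms <- if (config$mode == "packed")
      packCell(record, boundaryEps = config$boundaryEps,
               dedupTol = config$dedupTol)
    else expandSymmetry(record, dedupTol = config$dedupTol)
    stage <- "fragments"
    bonds <- perceiveBonds(atoms, bondTol = config$bondTol)
    frags <- findFragments(atoms, bonds)
    kept <- if (config$perMolecule) frags else list(selectPrimary(frags))
    stage <- "mesh"
    if (!dir.exists(config$outputDir))
      dir.create(config$outputDir, recursive = TRUE)
    stem <- sub("\\.[Cc][Ii][Ff]$", "", basename(cifPath))
    bundles <- vector("list", length(kept))
    for (k in seq_along(kept)) {
      nm <- if (config$perMolecule && length(kept) > 1L)
        sprintf("%s_mol%d", stem, k) else stem
      bundles[[k]] <- exportBundle(
        buildBallStick(kept[[k]], atoms, config$style), name = nm)
    }
    stage <- "write"
    outs <- character(0)
    for (b in bundles) {
      if ("vrml" %in% config$formats) {
        p <- file.path(config$outputDir, paste0(b@name, ".wrl"))
        writeVrml(b, p); written <- c(written, p); outs <- c(outs, p)
      }
      if ("stl" %in% config$formats) {
        p <- file.path(config$outputDir, paste0(b@name, ".stl"))
        writeStl(b, p, mode = config$stlMode)
        written <- c(written, p); outs <- c(outs, p)
      }
    }
    keptAtoms <- sum(vapply(kept, natoms, integer(1)))
    if (config$mode == "packed" && !config$perMolecule &&
        keptAtoms < nrow(atoms))
      message(basename(cifPath), ": kept network excludes ",
              nrow(atoms) - keptAtoms, " packed atom(s)")
    .entry(cifPath, "ok", nFragments = length(frags),
           keptAtoms = keptAtoms,
           deletedFragments = length(frags) - length(kept),
           outputs = outs)
  }, error = function(e) {
    unlink(written)
    .entry(cifPath, "failed", reason = paste0(stage, ": ",
                                              conditionMessage(e)))
  })
  res
}

#' Batch-convert a list of CIF files
#'
#' Processes the files named in `listFile` (one path per line; blank
#' lines and `#` comments ignored) in order, with per-file isolation: a
#' failure is recorded and the batch continues. A summary line with
#' ok/failed counts is written to stderr.
#'
#' @param listFile Text file of CIF paths (relative paths resolve against
#'   the list file's directory if not found from the working directory).
#' @param config A [jobConfig()] list.
#' @return data.frame with one row per input file (see
#'   [convertStructure()]), with attribute `"summary"` = named counts.
#' @export
runBatch <- function(listFile, config = jobConfig()) {
  if (!file.exists(listFile)) stop("list file not found: ", listFile)
  lines <- trimws(readLines(listFile, warn = FALSE))
  paths <- lines[nzchar(lines) & !startsWith(lines, "#")]
  base <- dirname(listFile)
  entries <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    if (!file.exists(p) && file.exists(file.path(base, p)))
      p <- file.path(base, p)
    entries[[i]] <- convertStructure(p, config)
    msg <- entries[[i]]
    message(sprintf("[%d/%d] %s: %s%s", i, length(paths), basename(p),
                    msg$status,
                    if (nzchar(msg$reason)) paste0(" (", msg$reason, ")") else ""))
  }
  report <- if (length(entries)) do.call(rbind, entries) else
    .entry("", "")[0, ]
  ok <- sum(report$status == "ok")
  message(sprintf("batch complete: %d ok, %d failed of %d",
                  ok, nrow(report) - ok, nrow(report)))
  attr(report, "summary") <- c(ok = ok, failed = nrow(report) - ok,
                               total = nrow(report))
  report
}
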