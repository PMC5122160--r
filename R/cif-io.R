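# CIF 1.1 reading and writing, limited to the subset the pipeline needs:
# cell parameters, symmetry-operator loops, and atom-site loops. Tolerant
# of quoted strings, semicolon text fields, '#' comments, and either the
# old (_symmetry_equiv_pos_as_xyz) or new (_space_group_symop_operation_xyz)
# operator tags. Loop columns are matched by tag name, never by position.

# Split one CIF line into tokens, honouring single/double quotes and
# stopping at an unquoted '#'.
.cif_tokenize_line <- function(line) {
  tokens <- character(0)
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == "#") break
    if (ch %in% c("'", "\"")) {
      # quote ends at quote followed by whitespace or end-of-line
      j <- i + 1L
      while (j <= n) {
        if (substr(line, j, j) == ch &&
            (j == n || substr(line, j + 1L, j + 1L) %in% c(" ", "\t"))) break
        j <- j + 1L
      }
      tokens <- c(tokens, substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1L
      tokens <- c(tokens, substr(line, i, j - 1L))
      i <- j
    }
  }
  tokens
}

# Tokenize full CIF text into a flat token vector. Semicolon text fields
# become single tokens; data_/loop_ keywords and _tags pass through.
.cif_tokenize <- function(lines) {
  tokens <- character(0)
  i <- 1L; n <- length(lines)
  while (i <= n) {
    line <- lines[[i]]
    if (startsWith(line, ";")) {
      body <- substring(line, 2L)
      i <- i + 1L
      while (i <= n && !startsWith(lines[[i]], ";")) {
        body <- paste(body, lines[[i]], sep = "\n")
        i <- i + 1L
      }
      tokens <- c(tokens, body)
      i <- i + 1L
    } else {
      tokens <- c(tokens, .cif_tokenize_line(line))
      i <- i + 1L
    }
  }
  tokens
}

# Group tokens into data blocks; each block is a list(name, items, loops)
# where items is a named character vector and loops a list of
# list(tags, values-matrix-by-column).
.cif_parse_blocks <- function(tokens) {
  blocks <- list()
  cur <- NULL
  i <- 1L; n <- length(tokens)
  flush <- function() if (!is.null(cur)) blocks[[length(blocks) + 1L]] <<- cur
  is_tag <- function(x) startsWith(x, "_")
  is_kw <- function(x) grepl("^(data_|loop_$|stop_$|global_$|save_)", tolower(x))
  while (i <= n) {
    tok <- tokens[[i]]
    low <- tolower(tok)
    if (startsWith(low, "data_")) {
      flush()
      cur <- list(name = substring(tok, 6L), items = character(0), loops = list())
      i <- i + 1L
    } else if (is.null(cur)) {
      i <- i + 1L  # tokens before any data block: ignore
    } else if (low == "loop_") {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && is_tag(tokens[[i]])) { tags <- c(tags, tolower(tokens[[i]])); i <- i + 1L }
      vals <- character(0)
      while (i <= n && !is_tag(tokens[[i]]) && !is_kw(tokens[[i]])) {
        vals <- c(vals, tokens[[i]]); i <- i + 1L
      }
      if (length(tags) > 0 && length(vals) >= length(tags)) {
        nrow <- length(vals) %/% length(tags)
        m <- matrix(vals[seq_len(nrow * length(tags))],
                    ncol = length(tags), byrow = TRUE,
                    dimnames = list(NULL, tags))
        cur$loops[[length(cur$loops) + 1L]] <- m
      }
    } else if (is_tag(tok)) {
      if (i + 1L <= n && !is_tag(tokens[[i + 1L]]) && !is_kw(tokens[[i + 1L]])) {
        cur$items[[tolower(tok)]] <- tokens[[i + 1L]]
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  flush()
  blocks
}

# Parse a CIF numeric field, stripping a trailing parenthesized standard
# uncertainty: "0.1234(5)" -> 0.1234. "." and "?" give NA.
.cif_num <- function(s) {
  s <- trimws(s)
  s[s %in% c(".", "?")] <- NA_character_
  s <- sub("\\(\\d+\\)$", "", s)
  suppressWarnings(as.numeric(s))
}

.symop_tags <- c("_symmetry_equiv_pos_as_xyz", "_space_group_symop_operation_xyz")

# Extract cell/symops/sites from one parsed block; NULL if the block lacks
# a cell or an atom-site loop.
.block_to_record <- function(block) {
  cell_tags <- paste0("_cell_", c("length_a", "length_b", "length_c",
                                  "angle_alpha", "angle_beta", "angle_gamma"))
  cv <- .cif_num(block$items[cell_tags])
  if (any(is.na(cv))) return(NULL)

  site_loop <- NULL
  for (lp in block$loops)
    if (any(grepl("^_atom_site_fract_", colnames(lp)))) { site_loop <- lp; break }
  if (is.null(site_loop)) return(NULL)

  symops <- character(0)
  for (lp in block$loops) {
    hit <- intersect(.symop_tags, colnames(lp))
    if (length(hit) > 0) { symops <- unname(lp[, hit[[1L]]]); break }
  }
  if (length(symops) == 0)  # operator given as a plain (non-loop) item
    for (tg in .symop_tags)
      if (tg %in% names(block$items)) symops <- unname(block$items[[tg]])
  if (length(symops) == 0) symops <- "x,y,z"

  cols <- colnames(site_loop)
  need <- c("_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z")
  if (!all(need %in% cols)) return(NULL)
  label <- if ("_atom_site_label" %in% cols) site_loop[, "_atom_site_label"]
           else paste0("X", seq_len(nrow(site_loop)))
  raw_el <- if ("_atom_site_type_symbol" %in% cols)
    site_loop[, "_atom_site_type_symbol"] else sub("[^A-Za-z].*$", "", label)
  element <- .normalize_element(raw_el)
  if (anyNA(element))
    stop("unrecognized element symbol(s): ",
         paste(unique(raw_el[is.na(element)]), collapse = ", "))
  occ <- if ("_atom_site_occupancy" %in% cols)
    .cif_num(site_loop[, "_atom_site_occupancy"]) else rep(1, nrow(site_loop))
  occ[is.na(occ)] <- 1
  sites <- data.frame(
    label = unname(label), element = element,
    fx = .cif_num(site_loop[, need[1]]),
    fy = .cif_num(site_loop[, need[2]]),
    fz = .cif_num(site_loop[, need[3]]),
    occupancy = occ, stringsAsFactors = FALSE)
  if (anyNA(sites[, c("fx", "fy", "fz")]))
    stop("unparseable fractional coordinate in atom-site loop")

  keep <- sites$occupancy >= 0.5
  if (!all(keep))
    message(sum(!keep), " site(s) with occupancy < 0.5 dropped")
  sites <- sites[keep, , drop = FALSE]
  if (nrow(sites) == 0) return(NULL)
  rownames(sites) <- NULL

  new("StructureRecord",
      name = if (nzchar(block$name)) block$name else "unnamed",
      cell = crystalCell(cv[1], cv[2], cv[3], cv[4], cv[5], cv[6]),
      symops = symops, sites = sites)
}

#' Read a CIF file into a StructureRecord
#'
#' Parses CIF 1.1 text and returns the first data block that contains both
#' cell parameters and an atom-site loop. Element symbols are normalized
#' (charge suffixes such as `"Pb2+"` stripped); parenthesized standard
#' uncertainties on numbers are dropped; an identity operator is injected
#' when the file lists no symmetry loop; sites with occupancy below 0.5
#' are dropped and remaining partial occupancies treated as full. Other
#' data blocks of a multi-block file are skipped with a message.
#'
#' @param source Path to a CIF file, or a character vector of CIF text
#'   (multi-element, or single string with newlines).
#' @return A [StructureRecord-class].
#' @examples
#' cif <- makeFixture("p1_molecule")$cif
#' rec <- readCif(cif)
#' atomSites(rec)
#' @export
readCif <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    readLines(source, warn = FALSE)
  else unlist(strsplit(source, "\n", fixed = TRUE))
  blocks <- .cif_parse_blocks(.cif_tokenize(lines))
  if (length(blocks) == 0) stop("no cell: no data block found")
  rec <- NULL
  for (k in seq_along(blocks)) {
    rec <- tryCatch(.block_to_record(blocks[[k]]), error = function(e) stop(e))
    if (!is.null(rec)) {
      if (k > 1L) message("skipped ", k - 1L, " earlier data block(s) lacking cell or atoms")
      if (k < length(blocks))
        message("skipped ", length(blocks) - k, " later data block(s); one structure per file")
      return(rec)
    }
  }
  # distinguish the two failure modes for a clearer error
  has_cell <- any(vapply(blocks, function(b)
    !anyNA(.cif_num(b$items[paste0("_cell_", c("length_a", "length_b", "length_c"))])),
    logical(1)))
  if (!has_cell) stop("no cell: missing cell parameters in every data block")
  stop("no atoms: no usable atom-site loop in any data block")
}

#' Write a StructureRecord as CIF text
#'
#' Emits a minimal CIF 1.1 data block (cell, symmetry-operator loop,
#' atom-site loop) that [readCif()] round-trips. Fractional coordinates are
#' written with 6 decimal places.
#'
#' @param record A [StructureRecord-class].
#' @param path Optional file path; when `NULL` the CIF text is returned
#'   as a single character string.
#' @return `path` invisibly when writing to file, else the CIF text.
#' @export
writeCif <- function(record, path = NULL) {
  stopifnot(is(record, "StructureRecord"))
  cell <- cellOf(record)
  sites <- atomSites(record)
  out <- c(
    paste0("data_", structureName(record)),
    sprintf("_cell_length_a    %.6f", cell@a),
    sprintf("_cell_length_b    %.6f", cell@b),
    sprintf("_cell_length_c    %.6f", cell@c),
    sprintf("_cell_angle_alpha %.6f", cell@alpha),
    sprintf("_cell_angle_beta  %.6f", cell@beta),
    sprintf("_cell_angle_gamma %.6f", cell@gamma),
    "loop_",
    "_space_group_symop_operation_xyz",
    sprintf("'%s'", symopStrings(record)),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy",
    sprintf("%s %s %.6f %.6f %.6f %.4f",
            sites$label, sites$element, sites$fx, sites$fy, sites$fz,
            sites$occupancy))
  text <- paste(out, collapse = "\n")
  if (is.null(path)) return(text)
  writeLines(text, path)
  invisible(path)
}
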