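# Embedded element tables: single-bond covalent radii (Cordero-style),
# van der Waals radii (Bondi-style with common extensions), and CPK-style
# display colours. Radii in Angstrom, colours as RGB in [0, 255].

.covalent_radius <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76,
  N = 0.71, O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41,
  Al = 1.21, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06,
  K = 2.03, Ca = 1.76, Sc = 1.70, Ti = 1.60, V = 1.53, Cr = 1.39,
  Mn = 1.39, Fe = 1.32, Co = 1.26, Ni = 1.24, Cu = 1.32, Zn = 1.22,
  Ga = 1.22, Ge = 1.20, As = 1.19, Se = 1.20, Br = 1.20, Kr = 1.16,
  Rb = 2.20, Sr = 1.95, Y = 1.90, Zr = 1.75, Nb = 1.64, Mo = 1.54,
  Tc = 1.47, Ru = 1.46, Rh = 1.42, Pd = 1.39, Ag = 1.45, Cd = 1.44,
  In = 1.42, Sn = 1.39, Sb = 1.39, Te = 1.38, I = 1.39, Xe = 1.40,
  Cs = 2.44, Ba = 2.15, La = 2.07, Ce = 2.04, Nd = 2.01, Sm = 1.98,
  Eu = 1.98, Gd = 1.96, Dy = 1.92, Er = 1.89, Yb = 1.87, Lu = 1.87,
  Hf = 1.75, Ta = 1.70, W = 1.62, Re = 1.51, Os = 1.44, Ir = 1.41,
  Pt = 1.36, Au = 1.36, Hg = 1.32, Tl = 1.45, Pb = 1.46, Bi = 1.48,
  Th = 2.06, U = 1.96)

.vdw_radius <- c(
  H = 1.20, He = 1.40, Li = 1.81, Be = 1.53, B = 1.92, C = 1.70,
  N = 1.55, O = 1.52, F = 1.47, Ne = 1.54, Na = 2.27, Mg = 1.73,
  Al = 1.84, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88,
  K = 2.75, Ca = 2.31, Ni = 1.63, Cu = 1.40, Zn = 1.39, Ga = 1.87,
  Ge = 2.11, As = 1.85, Se = 1.90, Br = 1.85, Kr = 2.02, Rb = 3.03,
  Sr = 2.49, Pd = 1.63, Ag = 1.72, Cd = 1.58, In = 1.93, Sn = 2.17,
  Sb = 2.06, Te = 2.06, I = 1.98, Xe = 2.16, Cs = 3.43, Ba = 2.68,
  Pt = 1.75, Au = 1.66, Hg = 1.55, Tl = 1.96, Pb = 2.02, Bi = 2.07,
  U = 1.86)

.element_color <- matrix(c(
  255, 255, 255,  # H
  217, 255, 255,  # He
  204, 128, 255,  # Li
  194, 255,   0,  # Be
  255, 181, 181,  # B
  144, 144, 144,  # C
   48,  80, 248,  # N
  255,  13,  13,  # O
  144, 224,  80,  # F
  179, 227, 245,  # Ne
  171,  92, 242,  # Na
  138, 255,   0,  # Mg
  191, 166, 166,  # Al
  240, 200, 160,  # Si
  255, 128,   0,  # P
  255, 255,  48,  # S
   31, 240,  31,  # Cl
  128, 209, 227,  # Ar
  143,  64, 212,  # K
   61, 255,   0,  # Ca
  224, 102,  51,  # Fe
  200, 128,  51,  # Cu
   80, 208,  80,  # Ni
  125, 128, 176,  # Zn
  166,  41,  41,  # Br
  148,   0, 148,  # I
  208, 208, 224,  # Pt
  255, 209,  35,  # Au
  184, 184, 208,  # Hg
   87,  89,  97,  # Pb
  158,  79, 181,  # Bi
  0,   144, 255   # U
), ncol = 3, byrow = TRUE,
  dimnames = list(c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
                    "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
                    "Fe", "Cu", "Ni", "Zn", "Br", "I", "Pt", "Au", "Hg",
                    "Pb", "Bi", "U"), c("r", "g", "b")))

.known_elements <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "D")

#' Element radii and colours
#'
#' Lookup helpers for the embedded element tables. `covalentRadius()`
#' returns single-bond covalent radii used for bond perception (unknown
#' elements fall back to 1.5 Angstrom with a warning); `vdwRadius()`
#' returns van der Waals radii used to size atom spheres (fallback 1.7
#' Angstrom with a warning); `elementColor()` returns CPK-style RGB rows
#' in [0, 255] (unknown elements get pink).
#'
#' @param element character vector of element symbols (e.g. `"C"`, `"Pb"`).
#' @return `covalentRadius`/`vdwRadius`: numeric vector in Angstrom;
#'   `elementColor`: length(element) x 3 numeric matrix.
#' @examples
#' covalentRadius(c("C", "H"))
#' elementColor("O")
#' @export
covalentRadius <- function(element) {
  r <- unname(.covalent_radius[element])
  miss <- is.na(r)
  if (any(miss)) {
    warning("no covalent radius for element(s) ",
            paste(unique(element[miss]), collapse = ", "),
            "; falling back to 1.5 Angstrom")
    r[miss] <- 1.5
  }
  r
}

#' @rdname covalentRadius
#' @export
vdwRadius <- function(element) {
  r <- unname(.vdw_radius[element])
  miss <- is.na(r)
  if (any(miss)) {
    warning("no van der Waals radius for element(s) ",
            paste(unique(element[miss]), collapse = ", "),
            "; falling back to 1.7 Angstrom")
    r[miss] <- 1.7
  }
  r
}

#' @rdname covalentRadius
#' @export
elementColor <- function(element) {
  out <- matrix(NA_real_, nrow = length(element), ncol = 3,
                dimnames = list(element, c("r", "g", "b")))
  hit <- element %in% rownames(.element_color)
  out[hit, ] <- .element_color[element[hit], , drop = FALSE]
  out[!hit, ] <- rep(c(255, 20, 147), each = sum(!hit))  # fallback pink
  out
}

# Strip charge/oxidation suffixes from a CIF type symbol: "Pb2+" -> "Pb",
# "O2-" -> "O", "Cu+" -> "Cu". Returns NA for unrecognizable symbols.
.normalize_element <- function(sym) {
  s <- sub("^([A-Za-z]{1,2}).*$", "\\1", trimws(sym))
  s <- paste0(toupper(substr(s, 1, 1)), tolower(substr(s, 2, nchar(s))))
  # a two-letter guess that is not an element may be a one-letter element
  # with a label suffix (e.g. "CA" meaning calcium stays Ca, but "Cx" -> C)
  bad <- !(s %in% .known_elements) & nchar(s) == 2
  s[bad] <- substr(s[bad], 1, 1)
  s[!(s %in% .known_elements)] <- NA_character_
  s
}
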