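# Per-element reference data: atomic masses (amu), covalent radii (Angstrom,
# Cordero-style), Bondi-style van der Waals radii (Angstrom) and Pauling
# electronegativities.  Enough coverage for organic/biomolecular systems.

.element_data <- local({
  df <- data.frame(
    element = c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I",
                "NA", "K", "MG", "CA", "ZN", "FE", "SE", "B", "SI"),
    mass    = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 18.998,
                35.45, 79.904, 126.904, 22.990, 39.098, 24.305, 40.078,
                65.38, 55.845, 78.971, 10.81, 28.085),
    rcov    = c(0.31, 0.76, 0.71, 0.66, 1.05, 1.07, 0.57, 1.02, 1.20,
                1.39, 1.66, 2.03, 1.41, 1.76, 1.22, 1.32, 1.20, 0.84, 1.11),
    rvdw    = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.47, 1.75, 1.85,
                1.98, 2.27, 2.75, 1.73, 2.31, 1.39, 2.00, 1.90, 1.92, 2.10),
    eneg    = c(2.20, 2.55, 3.04, 3.44, 2.58, 2.19, 3.98, 3.16, 2.96,
                2.66, 0.93, 0.82, 1.31, 1.00, 1.65, 1.83, 2.55, 2.04, 1.90),
    stringsAsFactors = FALSE
  )
  rownames(df) <- df$element
  df
})

.element_lookup <- function(element, what) {
  key <- toupper(element)
  bad <- !(key %in% rownames(.element_data))
  if (any(bad))
    stop("unknown element(s): ", paste(unique(element[bad]), collapse = ", "))
  .element_data[key, what]
}

#' Atomic masses for element symbols
#' @param element Character vector of element symbols.
#' @return Numeric vector of masses in amu.
#' @export
element_mass <- function(element) .element_lookup(element, "mass")

#' Covalent radii for element symbols
#' @param element Character vector of element symbols.
#' @return Numeric vector of covalent radii in Angstrom.
#' @export
element_covalent_radius <- function(element) .element_lookup(element, "rcov")

#' Van der Waals radii for element symbols
#' @param element Character vector of element symbols.
#' @return Numeric vector of Bondi-style vdW radii in Angstrom.
#' @export
element_vdw_radius <- function(element) .element_lookup(element, "rvdw")

element_electronegativity <- function(element) .element_lookup(element, "eneg")

is_known_element <- function(element) toupper(element) %in% rownames(.element_data)

# Infer an element symbol from a PDB atom name: strip digits/primes, take the
# leading alphabetic characters, prefer two-letter matches only when the raw
# name occupies column 13 (handled by caller passing a candidate).
guess_element <- function(atom_name) {
  vapply(atom_name, function(nm) {
    s <- gsub("[^A-Za-z]", "", nm)
    if (nchar(s) == 0L) stop("cannot infer element from atom name '", nm, "'")
    two <- toupper(substr(s, 1L, 2L))
    one <- toupper(substr(s, 1L, 1L))
    # Two-letter element only if the one-letter prefix is not itself valid
    # (avoids reading "CA" the calcium in a protein C-alpha).
    if (!(one %in% rownames(.element_data)) && two %in% rownames(.element_data))
      return(two)
    if (one %in% rownames(.element_data)) return(one)
    stop("cannot infer element from atom name '", nm, "'")
  }, character(1L), USE.NAMES = FALSE)
}
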