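# Amino-acid side-chain templates in internal coordinates.
#
# Each heavy atom is placed by (bond_ref, angle_ref, dihedral_ref) atom
# names, a bond length (Angstrom), an angle (degrees) and a dihedral that is
# either a constant or an expression in the chi torsions ("chi1", "chi2+120",
# ...).  Hydrogens are not templated individually: each heavy atom carries an
# expected hydrogen count and hybridisation, and hydrogens are constructed
# geometrically (see hydrogens.R).  Bond geometry uses standard single/double
# bond lengths; five-membered rings close only approximately, which is
# adequate for a generic-parameter force field.

sc_atom <- function(name, el, b, a, d, r, ang, dih) {
  list(name = name, el = el, b = b, a = a, d = d, r = r, ang = ang, dih = dih)
}

# common first side-chain atom: dihedral CB-CA-N-C fixed by backbone chirality
.cb <- sc_atom("CB", "C", "CA", "N", "C", 1.53, 110.5, "-122.5")

.sidechain_templates <- list(
  GLY = list(atoms = list(), chi = list(), extra_bonds = list(),
             h = list(CA = c(2, 3))),
  ALA = list(atoms = list(.cb), chi = list(), extra_bonds = list(),
             h = list(CB = c(3, 3))),
  SER = list(atoms = list(.cb,
               sc_atom("OG", "O", "CB", "CA", "N", 1.41, 110.5, "chi1")),
             chi = list(c("N", "CA", "CB", "OG")), extra_bonds = list(),
             h = list(CB = c(2, 3), OG = c(1, 3))),
  CYS = list(atoms = list(.cb,
               sc_atom("SG", "S", "CB", "CA", "N", 1.81, 114.0, "chi1")),
             chi = list(c("N", "CA", "CB", "SG")), extra_bonds = list(),
             h = list(CB = c(2, 3), SG = c(1, 3))),
  THR = list(atoms = list(.cb,
               sc_atom("OG1", "O", "CB", "CA", "N", 1.41, 109.5, "chi1"),
               sc_atom("CG2", "C", "CB", "CA", "N", 1.52, 110.5, "chi1-120")),
             chi = list(c("N", "CA", "CB", "OG1")), extra_bonds = list(),
             h = list(CB = c(1, 3), OG1 = c(1, 3), CG2 = c(3, 3))),
  VAL = list(atoms = list(.cb,
               sc_atom("CG1", "C", "CB", "CA", "N", 1.52, 110.5, "chi1"),
               sc_atom("CG2", "C", "CB", "CA", "N", 1.52, 110.5, "chi1+122")),
             chi = list(c("N", "CA", "CB", "CG1")), extra_bonds = list(),
             h = list(CB = c(1, 3), CG1 = c(3, 3), CG2 = c(3, 3))),
  LEU = list(atoms = list(.cb,
               sc_atom("CG", "C", "CB", "CA", "N", 1.53, 116.0, "chi1"),
               sc_atom("CD1", "C", "CG", "CB", "CA", 1.52, 110.5, "chi2"),
               sc_atom("CD2", "C", "CG", "CB", "CA", 1.52, 110.5, "chi2+122")),
             chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
             extra_bonds = list(),
             h = list(CB = c(2, 3), CG = c(1, 3), CD1 = c(3, 3), CD2 = c(3, 3))),
  ILE = list(atoms = list(.cb,
               sc_atom("CG1", "C", "CB", "CA", "N", 1.53, 110.5, "chi1"),
               sc_atom("CG2", "C", "CB", "CA", "N", 1.52, 110.5, "chi1-122"),
               sc_atom("CD1", "C", "CG1", "CB", "CA", 1.52, 113.0, "chi2")),
             chi = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
             extra_bonds = list(),
             h = list(CB = c(1, 3), CG1 = c(2, 3), CG2 = c(3, 3), CD1 = c(3, 3))),
  MET = list(atoms = list(.cb,
               sc_atom("CG", "C", "CB", "CA", "N", 1.52, 114.0, "chi1"),
               sc_atom("SD", "S", "CG", "CB", "CA", 1.81, 112.7, "chi2"),
               sc_atom("CE", "C", "SD", "CG", "CB", 1.79, 100.2, "chi3")),
             chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
                        c("CB", "CG", "SD", "CE")),
             extra_bonds = list(),
             h = list(CB = c(2, 3), CG = c(2, 3), CE = c(3, 3))),
  PRO = list(atoms = list(.cb,
               sc_atom("CG", "C", "CB", "CA", "N", 1.50, 104.0, "30"),
               sc_atom("CD", "C", "CG", "CB", "CA", 1.51, 105.0, "-35")),
             chi = list(), extra_bonds = list(c("CD", "N")),
             h = list(CB = c(2, 3), CG = c(2, 3), CD = c(2, 3))),
  PHE = list(atoms = list(.cb,
               sc_atom("CG", "C", "CB", "CA", "N", 1.50, 113.8, "chi1"),
               sc_atom("CD1", "C", "CG", "CB", "CA", 1.39, 120.8, "chi2"),
               sc_atom("CD2", "C", "CG", "CB", "CA", 1.39, 120.8, "chi2+180"),
               sc_atom("CE1", "C", "CD1", "CG", "CB", 1.39, 120.0, "180"),
               sc_atom("CE2", "C", "CD2", "CG", "CB", 1.39, 120.0, "180"),
               sc_atom("CZ", "C", "CE1", "CD1", "CG", 1.39, 120.0, "0")),
             chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
             extra_bonds = list(c("CZ", "CE2")),
             h = list(CB = c(2, 3), CD1 = c(1, 2), CD2 = c(1, 2),
                      CE1 = c(1, 2), CE2 = c(1, 2), CZ = c(1, 2))),
  TYR = list(atoms = list(.cb,
               sc_atom("CG", "C", "CB", "CA", "N", 1.51, 113.8, "chi1"),
               sc_atom("CD1", "C", "CG", "CB", "CA", 1.39, 120.8, "chi2"),
               sc_atom("CD2", "C", "CG", "CB", "CA", 1.39, 120.8, "chi2+180"),
               sc_atom("CE1", "C", "CD1", "CG", "CB", 1.39, 120.0, "180"),
               sc_atom("CE2", "C", "CD2", "CG", "CB", 1.39, 120.0, "180"),
               sc_atom("CZ", "C", "CE1", "CD1", "CG", 1.39, 120.0, "0"),
               sc_atom("OH", "O", "CZ", "CE1", "CD1", 1.38, 120.0, "180")),
             chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
             extra_bonds = list(c("CZ", "CE2")),
             h = list(CB = c(2, 3), CD1 = c(1, 2), CD2 = c(1, 2),
                      CE1 = c(1, 2), CE2 = c(1, 2), OH = c(1, 3))),
  TRP = list(atoms = list(.cb,
               sc_atom("CG", "C", "CB", "CA", "N", 1.50, 114.0, "chi1"),
               sc_atom("CD1", "C", "CG", "CB", "CA", 1.37, 127.0, "chi2"),
               sc_atom("CD2", "C", "CG", "CB", "CA", 1.43, 126.6, "chi2+180"),
               sc_atom("NE1", "N", "CD1", "CG", "CB", 1.38, 110.1, "180"),
               sc_atom("CE2", "C", "NE1", "CD1", "CG", 1.37, 109.0, "0"),
               sc_atom("CE3", "C", "CD2", "CG", "CD1", 1.40, 133.9, "180"),
               sc_atom("CZ2", "C", "CE2", "CD2", "CE3", 1.40, 122.3, "0"),
               sc_atom("CZ3", "C", "CE3", "CD2", "CE2", 1.39, 118.7, "0"),
               sc_atom("CH2", "C", "CZ2", "CE2", "CD2", 1.37, 117.4, "0")),
             chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
             extra_bonds = list(c("CE2", "CD2"), c("CH2", "CZ3")),
             h = list(CB = c(2, 3), CD1 = c(1, 2), NE1 = c(1, 2),
                      CE3 = c(1, 2), CZ2 = c(1, 2), CZ3 = c(1, 2),
                      CH2 = c(1, 2))),
  HIS = list(atoms = list(.cb,
               sc_atom("CG", "C", "CB", "CA", "N", 1.49, 113.8, "chi1"),
               sc_atom("ND1", "N", "CG", "CB", "CA", 1.38, 122.7, "chi2"),
               sc_atom("CD2", "C", "CG", "CB", "CA", 1.36, 131.0, "chi2+180"),
               sc_atom("CE1", "C", "ND1", "CG", "CB", 1.32, 109.0, "180"),
               sc_atom("NE2", "N", "CE1", "ND1", "CG", 1.32, 108.0, "0")),
             chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
             extra_bonds = list(c("NE2", "CD2")),
             # epsilon-protonated tautomer by default
             h = list(CB = c(2, 3), CD2 = c(1, 2), CE1 = c(1, 2),
                      NE2 = c(1, 2))),
  ASP = list(atoms = list(.cb,
               sc_atom("CG", "C", "CB", "CA", "N", 1.52, 112.6, "chi1"),
               sc_atom("OD1", "O", "CG", "CB", "CA", 1.25, 118.4, "chi2"),
               sc_atom("OD2", "O", "CG", "CB", "CA", 1.25, 118.4, "chi2+180")),
             chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
             extra_bonds = list(), h = list(CB = c(2, 3))),
  ASN = list(atoms = list(.cb,
               sc_atom("CG", "C", "CB", "CA", "N", 1.52, 112.6, "chi1"),
               sc_atom("OD1", "O", "CG", "CB", "CA", 1.23, 120.8, "chi2"),
               sc_atom("ND2", "N", "CG", "CB", "CA", 1.33, 116.4, "chi2+180")),
             chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
             extra_bonds = list(),
             h = list(CB = c(2, 3), ND2 = c(2, 2))),
  GLU = list(atoms = list(.cb,
               sc_atom("CG", "C", "CB", "CA", "N", 1.52, 114.1, "chi1"),
               sc_atom("CD", "C", "CG", "CB", "CA", 1.52, 112.6, "chi2"),
               sc_atom("OE1", "O", "CD", "CG", "CB", 1.25, 118.4, "chi3"),
               sc_atom("OE2", "O", "CD", "CG", "CB", 1.25, 118.4, "chi3+180")),
             chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
                        c("CB", "CG", "CD", "OE1")),
             extra_bonds = list(), h = list(CB = c(2, 3), CG = c(2, 3))),
  GLN = list(atoms = list(.cb,
               sc_atom("CG", "C", "CB", "CA", "N", 1.52, 114.1, "chi1"),
               sc_atom("CD", "C", "CG", "CB", "CA", 1.52, 112.6, "chi2"),
               sc_atom("OE1", "O", "CD", "CG", "CB", 1.23, 120.8, "chi3"),
               sc_atom("NE2", "N", "CD", "CG", "CB", 1.33, 116.4, "chi3+180")),
             chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
                        c("CB", "CG", "CD", "OE1")),
             extra_bonds = list(),
             h = list(CB = c(2, 3), CG = c(2, 3), NE2 = c(2, 2))),
  LYS = list(atoms = list(.cb,
               sc_atom("CG", "C", "CB", "CA", "N", 1.52, 114.1, "chi1"),
               sc_atom("CD", "C", "CG", "CB", "CA", 1.52, 111.8, "chi2"),
               sc_atom("CE", "C", "CD", "CG", "CB", 1.52, 111.8, "chi3"),
               sc_atom("NZ", "N", "CE", "CD", "CG", 1.47, 111.0, "chi4")),
             chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
                        c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
             extra_bonds = list(),
             h = list(CB = c(2, 3), CG = c(2, 3), CD = c(2, 3), CE = c(2, 3),
                      NZ = c(3, 3))),
  ARG = list(atoms = list(.cb,
               sc_atom("CG", "C", "CB", "CA", "N", 1.52, 114.1, "chi1"),
               sc_atom("CD", "C", "CG", "CB", "CA", 1.52, 111.8, "chi2"),
               sc_atom("NE", "N", "CD", "CG", "CB", 1.46, 112.0, "chi3"),
               sc_atom("CZ", "C", "NE", "CD", "CG", 1.33, 124.2, "chi4"),
               sc_atom("NH1", "N", "CZ", "NE", "CD", 1.33, 120.0, "0"),
               sc_atom("NH2", "N", "CZ", "NE", "CD", 1.33, 120.0, "180")),
             chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
                        c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
             extra_bonds = list(),
             h = list(CB = c(2, 3), CG = c(2, 3), CD = c(2, 3), NE = c(1, 2),
                      NH1 = c(2, 2), NH2 = c(2, 2)))
)

#' Number of rotatable side-chain chi bonds per residue type
#' @param resname Three-letter residue code(s).
#' @return Integer vector.
#' @export
n_chi <- function(resname) {
  resname <- toupper(resname)
  bad <- !(resname %in% names(.sidechain_templates))
  if (any(bad)) stop("unknown residue code: ",
                     paste(unique(resname[bad]), collapse = ", "))
  unname(vapply(.sidechain_templates[resname], function(t) length(t$chi), 0L))
}

residue_template <- function(resname) {
  resname <- toupper(resname)
  t <- .sidechain_templates[[resname]]
  if (is.null(t)) stop("unknown residue code: ", resname)
  t
}

resolve_dihedral_expr <- function(expr, chi) {
  if (grepl("^chi", expr)) {
    m <- regmatches(expr, regexec("^chi([0-9]+)([+-][0-9.]+)?$", expr))[[1L]]
    k <- as.integer(m[2L])
    off <- if (nzchar(m[3L])) as.numeric(m[3L]) else 0
    if (k > length(chi)) stop("chi", k, " not supplied")
    wrap_angle(chi[k] + off)
  } else as.numeric(expr)
}

# Rebuild the side chain of residue `res_i` from the template for `resname`,
# at the chi angles `chi` (degrees).  Heavy atoms only; hydrogens are added
# by add_residue_hydrogens().  Backbone atoms must be present.
build_sidechain <- function(sys, res_i, resname, chi = NULL) {
  tpl <- residue_template(resname)
  if (is.null(chi)) chi <- rep(180, length(tpl$chi))
  if (length(chi) != length(tpl$chi))
    stop(sprintf("%s needs %d chi angle(s), got %d", resname,
                 length(tpl$chi), length(chi)))
  # drop everything but the backbone (incl. its hydrogens)
  ix <- residue_atoms(sys, res_i)
  keep_names <- c("N", "CA", "C", "O", "H", "OXT", "H1", "H2", "H3")
  drop <- ix[!(sys$atoms$name[ix] %in% keep_names)]
  # only atoms of res_i are dropped and its backbone stays, so no residue
  # disappears and res_i keeps its index
  if (length(drop)) sys <- remove_atoms(sys, drop)
  sys$residues$name[res_i] <- toupper(resname)
  sys$residues$kind[res_i] <- "amino"
  for (a in tpl$atoms) {
    ix <- residue_atoms(sys, res_i)
    nm <- sys$atoms$name[ix]
    ref <- function(x) {
      j <- ix[nm == x]
      if (length(j) == 0L) stop("template reference atom ", x, " missing")
      j[1L]
    }
    bi <- ref(a$b); ai <- ref(a$a); di <- ref(a$d)
    xyz <- coords(sys)
    pos <- place_atom(xyz[di, ], xyz[ai, ], xyz[bi, ], a$r, a$ang,
                      resolve_dihedral_expr(a$dih, chi))
    sys <- add_atoms(sys, res_i, a$name, a$el, matrix(pos, 1L),
                     bond_to = list(bi))
  }
  ix <- residue_atoms(sys, res_i)
  nm <- sys$atoms$name[ix]
  for (eb in tpl$extra_bonds) {
    i1 <- ix[nm == eb[1L]]; i2 <- ix[nm == eb[2L]]
    if (length(i1) && length(i2))
      sys$bonds <- normalize_bonds(rbind(sys$bonds, c(i1[1L], i2[1L])),
                                   nrow(sys$atoms))
  }
  sys
}

find_backbone <- function(sys, res_i) {
  ix <- residue_atoms(sys, res_i)
  ix[sys$atoms$name[ix] %in% c("N", "CA", "C", "O")]
}

#' Mutate an amino residue to another type
#'
#' Backbone atoms (N, CA, C, O) keep their coordinates; the side chain is
#' rebuilt from the internal-coordinate template at the first rotamer of
#' `library`, and hydrogens are reconstructed.
#'
#' @param sys A `molsys` object.
#' @param res_i Residue index.
#' @param new_name Three-letter code of the target residue.
#' @param library A [rotamer_library()]; its first rotamer sets the new chi
#'   angles (default: the built-in three-state library, first entry).
#' @return The mutated system.
#' @export
mutate_residue <- function(sys, res_i, new_name, library = rotamer_library()) {
  new_name <- toupper(new_name)
  if (!(new_name %in% names(.sidechain_templates)))
    stop("unknown residue code: ", new_name)
  if (sys$residues$kind[res_i] != "amino")
    stop("can only mutate amino residues")
  rot <- enumerate_rotamers(new_name, library)
  chi <- if (length(rot)) rot[[1L]] else numeric(0)
  sys <- build_sidechain(sys, res_i, new_name, chi)
  add_residue_hydrogens(sys, res_i)
}
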