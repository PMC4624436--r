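# Sidechain construction from ideal internal coordinates. Each sidechain
# atom is placed by the NeRF construction from three reference atoms, a bond
# length, a bond angle, and a torsion that is either fixed or tied to a
# rotameric chi angle (chi index + constant offset). Geometry values are
# standard amino-acid ideal values; ring closure for Pro and the aromatics
# is approximate at the tenth-of-degree level, which is ample for density
# fitting at crystallographic resolutions.

sc_atom <- function(name, refs, bond, angle, chi = NA, offset = 0, tors = NA) {
  list(name = name, refs = refs, bond = bond, angle = angle,
       chi = chi, offset = offset, tors = tors)
}

# CB from the backbone frame; the -122.6 degree improper (N-C-CA-CB) yields
# the L-amino-acid configuration.
CB_TEMPLATE <- list(sc_atom("CB", c("N", "C", "CA"), 1.530, 110.4, tors = -122.6))

sidechain_templates <- function() {
  t <- list()
  t$ALA <- list()
  t$GLY <- NULL
  t$SER <- list(sc_atom("OG",  c("N", "CA", "CB"), 1.417, 110.8, chi = 1))
  t$CYS <- list(sc_atom("SG",  c("N", "CA", "CB"), 1.808, 113.8, chi = 1))
  t$THR <- list(sc_atom("OG1", c("N", "CA", "CB"), 1.433, 109.6, chi = 1),
                sc_atom("CG2", c("N", "CA", "CB"), 1.521, 110.5, chi = 1, offset = -120))
  t$VAL <- list(sc_atom("CG1", c("N", "CA", "CB"), 1.527, 110.7, chi = 1),
                sc_atom("CG2", c("N", "CA", "CB"), 1.527, 110.7, chi = 1, offset = 122.3))
  t$ILE <- list(sc_atom("CG1", c("N", "CA", "CB"), 1.530, 110.4, chi = 1),
                sc_atom("CG2", c("N", "CA", "CB"), 1.521, 110.5, chi = 1, offset = -122.3),
                sc_atom("CD1", c("CA", "CB", "CG1"), 1.513, 113.9, chi = 2))
  t$LEU <- list(sc_atom("CG",  c("N", "CA", "CB"), 1.530, 116.3, chi = 1),
                sc_atom("CD1", c("CA", "CB", "CG"), 1.521, 110.7, chi = 2),
                sc_atom("CD2", c("CA", "CB", "CG"), 1.521, 110.7, chi = 2, offset = 122.3))
  t$PRO <- list(sc_atom("CG",  c("N", "CA", "CB"), 1.495, 104.5, chi = 1),
                sc_atom("CD",  c("CA", "CB", "CG"), 1.507, 105.5, chi = 2))
  t$ASP <- list(sc_atom("CG",  c("N", "CA", "CB"), 1.516, 112.6, chi = 1),
                sc_atom("OD1", c("CA", "CB", "CG"), 1.249, 118.4, chi = 2),
                sc_atom("OD2", c("CA", "CB", "CG"), 1.249, 118.4, chi = 2, offset = 180))
  t$ASN <- list(sc_atom("CG",  c("N", "CA", "CB"), 1.516, 112.6, chi = 1),
                sc_atom("OD1", c("CA", "CB", "CG"), 1.231, 120.8, chi = 2),
                sc_atom("ND2", c("CA", "CB", "CG"), 1.328, 116.4, chi = 2, offset = 180))
  t$GLU <- list(sc_atom("CG",  c("N", "CA", "CB"), 1.520, 114.1, chi = 1),
                sc_atom("CD",  c("CA", "CB", "CG"), 1.516, 112.6, chi = 2),
                sc_atom("OE1", c("CB", "CG", "CD"), 1.249, 118.4, chi = 3),
                sc_atom("OE2", c("CB", "CG", "CD"), 1.249, 118.4, chi = 3, offset = 180))
  t$GLN <- list(sc_atom("CG",  c("N", "CA", "CB"), 1.520, 114.1, chi = 1),
                sc_atom("CD",  c("CA", "CB", "CG"), 1.516, 112.6, chi = 2),
                sc_atom("OE1", c("CB", "CG", "CD"), 1.231, 120.8, chi = 3),
                sc_atom("NE2", c("CB", "CG", "CD"), 1.328, 116.4, chi = 3, offset = 180))
  t$MET <- list(sc_atom("CG",  c("N", "CA", "CB"), 1.520, 114.1, chi = 1),
                sc_atom("SD",  c("CA", "CB", "CG"), 1.803, 112.7, chi = 2),
                sc_atom("CE",  c("CB", "CG", "SD"), 1.791, 100.9, chi = 3))
  t$LYS <- list(sc_atom("CG",  c("N", "CA", "CB"), 1.520, 114.1, chi = 1),
                sc_atom("CD",  c("CA", "CB", "CG"), 1.520, 111.3, chi = 2),
                sc_atom("CE",  c("CB", "CG", "CD"), 1.520, 111.3, chi = 3),
                sc_atom("NZ",  c("CG", "CD", "CE"), 1.489, 111.9, chi = 4))
  t$ARG <- list(sc_atom("CG",  c("N", "CA", "CB"), 1.520, 114.1, chi = 1),
                sc_atom("CD",  c("CA", "CB", "CG"), 1.520, 111.3, chi = 2),
                sc_atom("NE",  c("CB", "CG", "CD"), 1.461, 112.0, chi = 3),
                sc_atom("CZ",  c("CG", "CD", "NE"), 1.329, 124.2, chi = 4),
                sc_atom("NH1", c("CD", "NE", "CZ"), 1.326, 120.0, tors = 0),
                sc_atom("NH2", c("CD", "NE", "CZ"), 1.326, 120.0, tors = 180))
  t$HIS <- list(sc_atom("CG",  c("N", "CA", "CB"), 1.497, 113.8, chi = 1),
                sc_atom("ND1", c("CA", "CB", "CG"), 1.371, 122.7, chi = 2),
                sc_atom("CD2", c("CA", "CB", "CG"), 1.356, 131.2, chi = 2, offset = 180),
                sc_atom("CE1", c("CB", "CG", "ND1"), 1.319, 109.2, tors = 180),
                sc_atom("NE2", c("CB", "CG", "CD2"), 1.374, 107.2, tors = 180))
  aro <- function(cg_bond = 1.502) {
    list(sc_atom("CG",  c("N", "CA", "CB"), cg_bond, 113.8, chi = 1),
         sc_atom("CD1", c("CA", "CB", "CG"), 1.384, 120.8, chi = 2),
         sc_atom("CD2", c("CA", "CB", "CG"), 1.384, 120.8, chi = 2, offset = 180),
         sc_atom("CE1", c("CB", "CG", "CD1"), 1.382, 120.8, tors = 180),
         sc_atom("CE2", c("CB", "CG", "CD2"), 1.382, 120.8, tors = 180),
         sc_atom("CZ",  c("CG", "CD1", "CE1"), 1.382, 120.0, tors = 0))
  }
  t$PHE <- aro()
  t$TYR <- c(aro(), list(sc_atom("OH", c("CD1", "CE1", "CZ"), 1.376, 119.9, tors = 180)))
  t$TRP <- list(sc_atom("CG",  c("N", "CA", "CB"), 1.498, 113.6, chi = 1),
                sc_atom("CD1", c("CA", "CB", "CG"), 1.365, 126.9, chi = 2),
                sc_atom("CD2", c("CA", "CB", "CG"), 1.433, 126.7, chi = 2, offset = 180),
                sc_atom("NE1", c("CB", "CG", "CD1"), 1.374, 110.2, tors = 180),
                sc_atom("CE2", c("CG", "CD1", "NE1"), 1.370, 109.0, tors = 0),
                sc_atom("CE3", c("CB", "CG", "CD2"), 1.398, 133.9, tors = 180),
                sc_atom("CZ2", c("CD1", "NE1", "CE2"), 1.394, 130.1, tors = 180),
                sc_atom("CZ3", c("CG", "CD2", "CE3"), 1.382, 118.8, tors = 180),
                sc_atom("CH2", c("NE1", "CE2", "CZ2"), 1.368, 117.5, tors = 180))
  t
}

sidechain_element <- function(name) {
  first <- substr(name, 1, 1)
  if (first %in% c("O", "N", "S")) first else "C"
}

#' Build a sidechain from chi angles on a given backbone
#'
#' @param backbone named list or matrix giving N, CA, C positions (and any
#'   already-placed atoms); rownames/names are atom names.
#' @param resid 3-letter residue code.
#' @param chi numeric vector of chi angles (degrees), length [chi_count()].
#' @param include_cb build CB as well (set `FALSE` if the backbone already
#'   carries a CB that should be kept).
#' @return matrix of sidechain atom positions with rownames = atom names
#'   (includes CB when `include_cb`).
#' @export
build_sidechain <- function(backbone, resid, chi = numeric(), include_cb = TRUE) {
  resid <- toupper(resid)
  if (resid == "GLY") return(matrix(numeric(0), 0, 3))
  tmpl <- sidechain_templates()[[resid]]
  if (is.null(tmpl) && resid != "ALA") stop("no sidechain template for ", resid)
  if (length(chi) != chi_count(resid)) {
    stop(sprintf("%s requires %d chi angles, got %d", resid, chi_count(resid), length(chi)))
  }
  pos <- list()
  getpos <- function(nm) {
    if (!is.null(pos[[nm]])) return(pos[[nm]])
    if (is.matrix(backbone)) {
      if (nm %in% rownames(backbone)) return(backbone[nm, ])
    } else if (!is.null(backbone[[nm]])) return(backbone[[nm]])
    stop("reference atom not available: ", nm)
  }
  entries <- if (include_cb) c(CB_TEMPLATE, tmpl) else tmpl
  for (e in entries) {
    tors <- if (!is.na(e$chi)) chi[e$chi] + e$offset else e$tors
    pos[[e$name]] <- place_atom(getpos(e$refs[1]), getpos(e$refs[2]),
                                getpos(e$refs[3]), e$bond, e$angle, tors)
  }
  out <- do.call(rbind, pos)
  rownames(out) <- names(pos)
  out
}

#' Measure sidechain chi angles of a residue's atom table
#'
#' @param atoms atom tibble for one conformer (must contain the backbone and
#'   sidechain atoms named per PDB convention).
#' @param resid 3-letter residue code.
#' @return numeric vector of chi angles (degrees), length [chi_count()].
#' @export
measure_chi <- function(atoms, resid) {
  resid <- toupper(resid)
  nchi <- chi_count(resid)
  if (nchi == 0) return(numeric())
  chains <- list(
    c("N", "CA", "CB", switch(resid, SER = "OG", CYS = "SG", THR = "OG1",
                              VAL = "CG1", ILE = "CG1", "CG")),
    c("CA", "CB", switch(resid, ILE = "CG1", "CG"),
      switch(resid, ILE = "CD1", LEU = "CD1", PRO = "CD", ASP = "OD1",
             ASN = "OD1", PHE = "CD1", TYR = "CD1", TRP = "CD1", HIS = "ND1",
             MET = "SD", "CD")),
    c("CB", "CG", switch(resid, MET = "SD", "CD"),
      switch(resid, MET = "CE", GLU = "OE1", GLN = "OE1", ARG = "NE", "CE")),
    c("CG", "CD", switch(resid, ARG = "NE", "CE"), switch(resid, ARG = "CZ", "NZ"))
  )
  vapply(seq_len(nchi), function(k) {
    nm <- chains[[k]]
    p <- lapply(nm, function(n) atom_xyz(atoms, n))
    if (any(vapply(p, is.null, TRUE))) return(NA_real_)
    dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
  }, 0)
}
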