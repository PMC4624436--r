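# Backbone construction from phi/psi torsions, torsion measurement, and a
# phi/psi-window secondary-structure heuristic used to suppress peptide-flip
# sampling inside helices and sheets.

BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.0, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8)

#' Build an idealized single-conformer chain from phi/psi angles
#'
#' Constructs backbone atoms (N, CA, C, O) with ideal bond geometry and trans
#' peptide bonds, adds CB for non-glycine residues, and optionally builds
#' sidechains at supplied chi angles.
#'
#' @param resids character vector of 3-letter residue codes.
#' @param phi,psi torsion vectors (degrees), same length as `resids`; `phi[1]`
#'   and `psi[length(psi)]` are unused.
#' @param chain chain identifier.
#' @param chis optional list of chi-angle vectors per residue (NULL entries
#'   leave only CB).
#' @param bfac isotropic B-factor assigned to every atom.
#' @return a [protein_model()].
#' @export
build_chain <- function(resids, phi, psi, chain = "A", chis = NULL, bfac = 15) {
  n <- length(resids)
  stopifnot(length(phi) == n, length(psi) == n)
  g <- BB_GEOM
  rows <- list()
  # seed first residue in a canonical pose
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  Cc <- place_atom(c(0, 1, 0), N, CA, g$ca_c, g$ang_n_ca_c, -60)
  prev <- NULL
  for (i in seq_len(n)) {
    if (i > 1) {
      N <- place_atom(prev$N, prev$CA, prev$C, g$c_n, g$ang_ca_c_n, psi[i - 1])
      CA <- place_atom(prev$CA, prev$C, N, g$n_ca, g$ang_c_n_ca, 180)  # omega trans
      Cc <- place_atom(prev$C, N, CA, g$ca_c, g$ang_n_ca_c, phi[i])
    }
    O <- place_atom(N, CA, Cc, g$c_o, g$ang_ca_c_o,
                    if (i < n) psi[i] + 180 else 180)
    res_atoms <- rbind(N = N, CA = CA, C = Cc, O = O)
    if (resids[i] != "GLY") {
      chi_i <- if (!is.null(chis) && !is.null(chis[[i]])) chis[[i]] else NULL
      if (!is.null(chi_i)) {
        sc <- build_sidechain(res_atoms, resids[i], chi_i)
      } else {
        sc <- build_sidechain(res_atoms, "ALA", numeric())
      }
      res_atoms <- rbind(res_atoms, sc)
    }
    rows[[i]] <- tibble::tibble(
      chain = chain, resno = i, icode = "", resid = resids[i],
      name = rownames(res_atoms),
      element = vapply(rownames(res_atoms), sidechain_element, ""),
      altloc = "", x = res_atoms[, 1], y = res_atoms[, 2], z = res_atoms[, 3],
      occ = 1, b = bfac)
    prev <- list(N = N, CA = CA, C = Cc)
  }
  protein_model(dplyr::bind_rows(rows))
}

#' Measure backbone phi/psi torsions of a (single-conformer) model
#'
#' @param model a `protein_model`; for multiconformer residues the first
#'   conformer trace is used.
#' @return tibble with chain, resno, phi, psi (degrees; NA at termini).
#' @export
measure_phi_psi <- function(model) {
  rt <- residue_table(model)
  out <- rt[, c("chain", "resno", "icode", "resid")]
  out$phi <- NA_real_
  out$psi <- NA_real_
  bb <- function(i, nm) {
    ens <- residue_ensemble(model, rt$chain[i], rt$resno[i], rt$icode[i])
    atom_xyz(ens$conformers[[1]]$atoms, nm)
  }
  for (i in seq_len(nrow(rt))) {
    if (i > 1 && rt$chain[i - 1] == rt$chain[i] && rt$resno[i - 1] == rt$resno[i] - 1) {
      p <- list(bb(i - 1, "C"), bb(i, "N"), bb(i, "CA"), bb(i, "C"))
      if (!any(vapply(p, is.null, TRUE))) out$phi[i] <- dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
    }
    if (i < nrow(rt) && rt$chain[i + 1] == rt$chain[i] && rt$resno[i + 1] == rt$resno[i] + 1) {
      p <- list(bb(i, "N"), bb(i, "CA"), bb(i, "C"), bb(i + 1, "N"))
      if (!any(vapply(p, is.null, TRUE))) out$psi[i] <- dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
    }
  }
  out
}

#' Assign coarse secondary structure from phi/psi windows
#'
#' Residues inside runs of at least `min_run` consecutive helical or strand
#' phi/psi combinations are labelled "H" or "E"; everything else is coil
#' ("C"). Peptide-flip sampling is suppressed for H/E residues.
#'
#' @param model a `protein_model`.
#' @param min_run minimum run length for an assignment.
#' @return tibble with chain, resno and `ss` in {"H","E","C"}.
#' @export
assign_secondary_structure <- function(model, min_run = 3) {
  tp <- measure_phi_psi(model)
  heli <- !is.na(tp$phi) & !is.na(tp$psi) &
    tp$phi > -100 & tp$phi < -30 & tp$psi > -77 & tp$psi < -7
  strand <- !is.na(tp$phi) & !is.na(tp$psi) &
    tp$phi > -170 & tp$phi < -70 & (tp$psi > 90 | tp$psi < -170)
  lab <- ifelse(heli, "H", ifelse(strand, "E", "C"))
  # dissolve runs shorter than min_run
  r <- rle(lab)
  r$values[r$lengths < min_run & r$values != "C"] <- "C"
  tp$ss <- inverse.rle(r)
  tp[, c("chain", "resno", "icode", "resid", "ss")]
}
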