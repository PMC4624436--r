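# Multiconformer protein model containers.
#
# A `protein_model` stores one flat atom table plus an optional unit cell.
# Alternate conformations are encoded the way deposited PDB entries encode
# them: an altloc letter per atom ("" for the sole conformation), occupancies
# in [0,1], and isotropic or anisotropic B-factors. Residue-level "ensemble"
# views group the flat table into conformers on demand.

ATOM_COLS <- c("chain", "resno", "icode", "resid", "name", "element",
               "altloc", "x", "y", "z", "occ", "b",
               "u11", "u22", "u33", "u12", "u13", "u23")

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Construct a multiconformer protein model
#'
#' @param atoms a data frame with columns `chain`, `resno`, `icode`, `resid`,
#'   `name`, `element`, `altloc`, `x`, `y`, `z`, `occ`, `b` and optionally the
#'   anisotropic displacement columns `u11`..`u23` (Angstrom^2, `NA` when
#'   absent).
#' @param cell optional named unit-cell vector `c(a, b, c, alpha, beta,
#'   gamma)` (Angstrom / degrees).
#' @return an object of class `protein_model`.
#' @export
protein_model <- function(atoms, cell = NULL) {
  atoms <- tibble::as_tibble(atoms)
  for (col in setdiff(ATOM_COLS, names(atoms))) {
    atoms[[col]] <- if (col %in% c("icode", "altloc")) "" else NA_real_
  }
  atoms <- atoms[, ATOM_COLS]
  if (any(atoms$occ < -1e-9 | atoms$occ > 1 + 1e-9, na.rm = TRUE)) {
    stop("atom occupancies must lie in [0, 1]")
  }
  if (any(atoms$b < 0, na.rm = TRUE)) stop("isotropic B-factors must be >= 0")
  structure(list(atoms = atoms, cell = cell), class = "protein_model")
}

#' @export
print.protein_model <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<protein_model> %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atoms), nrow(rt), length(unique(rt$chain))))
  multi <- sum(rt$n_conformers > 1)
  if (multi > 0) cat(sprintf("  %d residue(s) with alternate conformations\n", multi))
  invisible(x)
}

#' Residue-level summary of a model
#'
#' @param model a `protein_model`.
#' @return a tibble with one row per residue: chain, resno, icode, resid,
#'   altloc labels present and conformer count.
#' @export
residue_table <- function(model) {
  a <- model$atoms
  key <- paste(a$chain, a$resno, a$icode, sep = "\r")
  idx <- !duplicated(key)
  out <- tibble::tibble(chain = a$chain[idx], resno = a$resno[idx],
                        icode = a$icode[idx], resid = a$resid[idx])
  alts <- split(a$altloc, key)[unique(key)]
  out$altlocs <- vapply(alts, function(v) paste(sort(unique(v[v != ""])), collapse = ""), "")
  out$n_conformers <- pmax(1L, nchar(out$altlocs))
  out
}

residue_key_match <- function(atoms, chain, resno, icode = "") {
  atoms$chain == chain & atoms$resno == resno & atoms$icode == icode
}

#' Extract a residue ensemble (conformer view) from a model
#'
#' Atoms carrying a blank altloc in a partially split residue are treated as
#' shared and replicated into every conformer, following deposited-PDB
#' convention.
#'
#' @param model a `protein_model`.
#' @param chain,resno,icode residue identifier.
#' @return an object of class `residue_ensemble`: chain/resno/icode/resid plus
#'   a list of conformers, each `list(altloc, occ, atoms)`.
#' @export
residue_ensemble <- function(model, chain, resno, icode = "") {
  sel <- model$atoms[residue_key_match(model$atoms, chain, resno, icode), ]
  if (nrow(sel) == 0) stop("no such residue: ", chain, resno, icode)
  labs <- sort(unique(sel$altloc[sel$altloc != ""]))
  shared <- sel[sel$altloc == "", ]
  if (length(labs) == 0) {
    confs <- list(list(altloc = "", occ = min(sel$occ), atoms = sel))
  } else {
    confs <- lapply(labs, function(l) {
      own <- sel[sel$altloc == l, ]
      at <- dplyr::bind_rows(shared, own)
      list(altloc = l, occ = stats::median(own$occ), atoms = at)
    })
  }
  structure(list(chain = chain, resno = resno, icode = icode,
                 resid = sel$resid[1], conformers = confs),
            class = "residue_ensemble")
}

#' @export
print.residue_ensemble <- function(x, ...) {
  cat(sprintf("<residue_ensemble> %s %s%d%s: %d conformer(s), occ = %s\n",
              x$resid, x$chain, x$resno, x$icode, length(x$conformers),
              paste(sprintf("%.2f", vapply(x$conformers, `[[`, 0, "occ")),
                    collapse = "/")))
  invisible(x)
}

#' Flatten a residue ensemble back to an atom table
#'
#' Shared atoms (identical coordinates across all conformers to `tol`) are
#' emitted once with a blank altloc; conformer-specific atoms carry
#' consecutive altloc letters when more than one conformer is present.
#'
#' @param ens a `residue_ensemble`.
#' @param tol coordinate tolerance (Angstrom) for detecting shared atoms.
#' @return an atom tibble.
#' @export
ensemble_atoms <- function(ens, tol = 1e-6) {
  confs <- ens$conformers
  if (length(confs) == 1) {
    at <- confs[[1]]$atoms
    at$altloc <- ""
    at$occ <- 1
    return(at)
  }
  if (length(confs) > 26) stop("more than 26 conformers cannot be altloc-labelled")
  nm0 <- confs[[1]]$atoms$name
  shared_names <- nm0
  for (cf in confs[-1]) {
    keep <- vapply(shared_names, function(nm) {
      i <- match(nm, confs[[1]]$atoms$name)
      j <- match(nm, cf$atoms$name)
      !is.na(j) &&
        max(abs(unlist(confs[[1]]$atoms[i, c("x", "y", "z")]) -
                  unlist(cf$atoms[j, c("x", "y", "z")]))) < tol
    }, TRUE)
    shared_names <- shared_names[keep]
  }
  rows <- list()
  sh <- confs[[1]]$atoms[confs[[1]]$atoms$name %in% shared_names, ]
  if (nrow(sh) > 0) {
    sh$altloc <- ""
    sh$occ <- 1
    rows[[length(rows) + 1]] <- sh
  }
  for (i in seq_along(confs)) {
    own <- confs[[i]]$atoms[!(confs[[i]]$atoms$name %in% shared_names), ]
    if (nrow(own) > 0) {
      own$altloc <- LETTERS[i]
      own$occ <- confs[[i]]$occ
      rows[[length(rows) + 1]] <- own
    }
  }
  dplyr::bind_rows(rows)
}

#' Validate protein-model invariants
#'
#' Checks residue numbering order, per-residue occupancy sums, consistent
#' conformer atom names, and peptide-bond continuity (C(i)-N(i+1) < 2 A)
#' along every conformer trace.
#'
#' @param model a `protein_model`.
#' @return invisibly `TRUE`; stops with a message on violation.
#' @export
validate_model <- function(model) {
  rt <- residue_table(model)
  for (ch in unique(rt$chain)) {
    rn <- rt$resno[rt$chain == ch]
    if (any(diff(rn) < 0)) stop("residue numbering not increasing in chain ", ch)
  }
  a <- model$atoms
  key <- paste(a$chain, a$resno, a$icode, a$name, sep = "\r")
  for (k in unique(key[a$altloc != ""])) {
    s <- sum(a$occ[key == k & a$altloc != ""])
    if (s > 1 + 1e-6) stop("occupancy sum ", signif(s, 4), " > 1 for atom group ", k)
  }
  for (ch in unique(rt$chain)) {
    sub <- rt[rt$chain == ch, ]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1)) {
      if (sub$resno[i + 1] != sub$resno[i] + 1) next
      e1 <- residue_ensemble(model, ch, sub$resno[i], sub$icode[i])
      e2 <- residue_ensemble(model, ch, sub$resno[i + 1], sub$icode[i + 1])
      ok <- FALSE
      for (c1 in e1$conformers) for (c2 in e2$conformers) {
        p1 <- atom_xyz(c1$atoms, "C"); p2 <- atom_xyz(c2$atoms, "N")
        if (!is.null(p1) && !is.null(p2) && vec_norm(p2 - p1) < 2.0) ok <- TRUE
      }
      if (!ok) stop("broken peptide bond between ", ch, sub$resno[i],
                    " and ", ch, sub$resno[i + 1])
    }
  }
  invisible(TRUE)
}

# position of a named atom in an atom table (first match), or NULL
atom_xyz <- function(atoms, name, altloc = NULL) {
  sel <- atoms$name == name
  if (!is.null(altloc)) sel <- sel & atoms$altloc %in% c(altloc, "")
  i <- which(sel)
  if (length(i) == 0) return(NULL)
  as.numeric(atoms[i[1], c("x", "y", "z")])
}

atom_matrix <- function(atoms) {
  m <- as.matrix(atoms[, c("x", "y", "z")])
  rownames(m) <- atoms$name
  m
}

#' Collapse multiconformer input to its highest-occupancy conformer
#'
#' Fitting starts from a single-conformer model; any residues that already
#' carry alternate conformations are reduced to the conformer with the
#' largest occupancy (ties: first altloc letter) and a warning is issued.
#'
#' @param model a `protein_model`.
#' @return a single-conformer `protein_model`.
#' @export
collapse_to_major <- function(model) {
  rt <- residue_table(model)
  multi <- rt[rt$n_conformers > 1, ]
  if (nrow(multi) == 0) return(model)
  warning(sprintf("collapsing %d multiconformer residue(s) to their highest-occupancy conformer",
                  nrow(multi)))
  keep <- rep(TRUE, nrow(model$atoms))
  a <- model$atoms
  for (i in seq_len(nrow(multi))) {
    ens <- residue_ensemble(model, multi$chain[i], multi$resno[i], multi$icode[i])
    occs <- vapply(ens$conformers, `[[`, 0, "occ")
    best <- ens$conformers[[which.max(occs)]]$altloc
    sel <- residue_key_match(a, multi$chain[i], multi$resno[i], multi$icode[i])
    keep[sel & !(a$altloc %in% c("", best))] <- FALSE
  }
  a <- a[keep, ]
  a$altloc <- ""
  a$occ <- 1
  protein_model(a, model$cell)
}
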