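# Candidate conformer generation: density-moment ellipsoids, guide-atom
# displacement targets, backbone enumeration (flips x displacements, closed
# by nullspace IK), and rotamer-library sidechain decoration with the
# small-residue 40/10 degree and large-residue hierarchical 50/4.5 degree
# windows.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

#' Sampler configuration
#'
#' @param mc_ampl backbone displacement scale (the mainchain amplitude;
#'   typical sweep values 0.1, 0.2, 0.3).
#' @param jitter uniform random addition to the scale (default 0.05).
#' @param half_width fragment half-width in residues (fragment length 7).
#' @param flips enable peptide-flip sampling outside helices/sheets.
#' @param seed RNG seed for the jitter draws.
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(mc_ampl = 0.2, jitter = 0.05, half_width = 3,
                           flips = TRUE, seed = 1) {
  stopifnot(mc_ampl > 0, jitter >= 0, half_width >= 1)
  structure(list(mc_ampl = mc_ampl, jitter = jitter, half_width = half_width,
                 flips = flips, seed = seed), class = "sampler_config")
}

#' Density-weighted second-moment (anisotropy) tensor around an atom
#'
#' Replaces the anisotropic-refinement thermal ellipsoid: the tensor of
#' positive density within `radius` of `center`, normalized by the total
#' positive density so it is invariant under map rescaling.
#'
#' @param map a [density_map()].
#' @param center 3-vector (guide-atom position).
#' @param radius integration sphere radius (Angstrom).
#' @return list: `tensor` (3x3), `values` (eigenvalues, decreasing),
#'   `vectors` (eigenvector columns), `fallback` (TRUE when no positive
#'   density was found and an isotropic tensor was substituted).
#' @export
density_moment_tensor <- function(map, center, radius) {
  idx <- voxel_mask(map, matrix(center, 1), radius)
  dims <- dim(map$values)
  w <- map$values[idx]
  keep <- w > 0
  if (length(idx) == 0 || !any(keep)) {
    warning("no positive density around the guide atom; isotropic fallback tensor")
    t0 <- diag(3) * (radius^2 / 5)
    e <- eigen(t0, symmetric = TRUE)
    return(list(tensor = t0, values = e$values, vectors = e$vectors, fallback = TRUE))
  }
  ai <- arrayInd(idx[keep], dims)
  xyz <- mask_points(ai, map)
  w <- w[keep]
  ctr <- colSums(xyz * w) / sum(w)
  dc <- t(t(xyz) - ctr)
  t0 <- crossprod(dc * sqrt(w)) / sum(w)
  e <- eigen(t0, symmetric = TRUE)
  list(tensor = t0, values = e$values, vectors = e$vectors, fallback = FALSE)
}

#' Guide-atom displacement targets along the ellipsoid axes
#'
#' Six targets: base +/- mc_ampl * sqrt(lambda_j) along each eigenvector,
#' each magnitude perturbed by a uniform random addition of up to +/- jitter
#' * sqrt(lambda_j).
#'
#' @param tensor result of [density_moment_tensor()].
#' @param base guide-atom position (3-vector).
#' @param cfg a [sampler_config()].
#' @return 6 x 3 matrix of target positions.
#' @export
sample_guide_displacements <- function(tensor, base, cfg) {
  out <- matrix(NA_real_, 6, 3)
  r <- 0
  for (j in 1:3) {
    lam <- max(tensor$values[j], 0)
    ej <- tensor$vectors[, j]
    for (sgn in c(1, -1)) {
      r <- r + 1
      mag <- cfg$mc_ampl * sqrt(lam)
      if (cfg$jitter > 0) mag <- mag + stats::runif(1, -cfg$jitter, cfg$jitter) * sqrt(lam)
      out[r, ] <- base + sgn * mag * ej
    }
  }
  out
}

guide_atom_name <- function(resid) if (toupper(resid) == "GLY") "O" else "CB"

fragment_bond_ok <- function(fragment, ref_fragment, tol_frac = 0.10) {
  res <- fragment_residues(fragment)
  for (i in seq_len(length(res) - 1)) {
    g <- function(fr, rn, nm) {
      as.numeric(fr$atoms[fr$atoms$resno == rn & fr$atoms$name == nm, c("x", "y", "z")][1, ])
    }
    b_new <- vec_norm(g(fragment, res[i + 1], "N") - g(fragment, res[i], "C"))
    b_old <- vec_norm(g(ref_fragment, res[i + 1], "N") - g(ref_fragment, res[i], "C"))
    if (abs(b_new - b_old) > tol_frac * b_old) return(FALSE)
  }
  TRUE
}

# Replace the center peptide (k -> k+1) of a fragment with a flip-centroid
# candidate, rebuild the CB atoms of both flanking residues, and relax the
# rigid-body pose of the five peptide atoms so the two junction bonds
# (N_k-CA_k and CA_k+1-C_k+1) keep their input lengths.
apply_flip_to_fragment <- function(fragment, cluster) {
  at <- fragment$atoms
  k <- fragment$center
  g <- function(rn, nm) as.numeric(at[at$resno == rn & at$name == nm, c("x", "y", "z")][1, ])
  p <- peptide_unit(rbind(CA1 = g(k, "CA"), C1 = g(k, "C"), O1 = g(k, "O"),
                          N2 = g(k + 1, "N"), CA2 = g(k + 1, "CA")))
  cand0 <- apply_flip_centroid(p, cluster)
  nk <- g(k, "N"); ck1 <- g(k + 1, "C")
  b1_ref <- vec_norm(p["CA1", ] - nk)
  b2_ref <- vec_norm(ck1 - p["CA2", ])
  ctr <- colMeans(cand0)
  m0 <- t(t(cand0) - ctr)
  pose <- function(par) {
    R <- rotation_matrix_axis(if (vec_norm(par[4:6]) < 1e-9) c(1, 0, 0) else par[4:6],
                              rad2deg(vec_norm(par[4:6])))
    t(t(m0 %*% t(R)) + ctr + par[1:3])
  }
  # residuals: the two junction bond strains plus a weak tether to the
  # centroid-placed pose; solved by damped Gauss-Newton on the 6 pose DOF
  resid_fn <- function(par) {
    m <- pose(par)
    c(vec_norm(m[1, ] - nk) - b1_ref,
      vec_norm(ck1 - m[5, ]) - b2_ref,
      0.1 * as.numeric(m - cand0))
  }
  par <- rep(0, 6)
  r0 <- resid_fn(par)
  for (gn in 1:8) {
    J <- matrix(0, length(r0), 6)
    h <- 1e-5
    for (j in 1:6) {
      pj <- par; pj[j] <- pj[j] + h
      J[, j] <- (resid_fn(pj) - r0) / h
    }
    step <- tryCatch(solve(crossprod(J) + diag(1e-8, 6), -crossprod(J, r0)),
                     error = function(e) NULL)
    if (is.null(step)) break
    par_new <- par + as.numeric(step)
    r_new <- resid_fn(par_new)
    if (sum(r_new^2) >= sum(r0^2) - 1e-14) break
    par <- par_new
    r0 <- r_new
    if (sum(r0[1:2]^2) < 1e-10) break
  }
  m <- pose(par)
  rownames(m) <- rownames(cand0)
  set_atom <- function(rn, nm, xyz) {
    i <- which(at$resno == rn & at$name == nm)[1]
    at[i, c("x", "y", "z")] <<- as.list(xyz)
  }
  set_atom(k, "CA", m["CA1", ]); set_atom(k, "C", m["C1", ]); set_atom(k, "O", m["O1", ])
  set_atom(k + 1, "N", m["N2", ]); set_atom(k + 1, "CA", m["CA2", ])
  # rebuild CB on the moved backbone frames
  for (rn in c(k, k + 1)) {
    row_cb <- which(at$resno == rn & at$name == "CB")
    if (length(row_cb) == 1) {
      gg <- function(nm) as.numeric(at[at$resno == rn & at$name == nm, c("x", "y", "z")][1, ])
      cb <- build_sidechain(list(N = gg("N"), CA = gg("CA"), C = gg("C")), "ALA", numeric())
      at[row_cb, c("x", "y", "z")] <- as.list(cb["CB", ])
    }
  }
  fragment$atoms <- at
  fragment
}

#' Enumerate backbone candidates for a residue
#'
#' Candidates are the product of flip states (unflipped + four centroid
#' flips when allowed) and guide displacements (undisplaced + six ellipsoid
#' directions): 35 candidates with flips, 7 without. Flips are applied to
#' the center peptide first; each displaced candidate is closed by nullspace
#' IK. Candidates whose IK fails to converge or that break closure/bond
#' invariants are dropped.
#'
#' @param fragment fragment centered on residue k ([extract_fragment()]).
#' @param flips_allowed logical (FALSE inside helices/sheets).
#' @param tensor [density_moment_tensor()] at the guide atom.
#' @param cfg a [sampler_config()].
#' @param centroids flip clusters ([load_flip_centroids()]).
#' @return list of candidates: `atoms`, `provenance` (flip, direction),
#'   `ik` diagnostics.
#' @export
enumerate_backbones <- function(fragment, flips_allowed, tensor, cfg,
                                centroids = load_flip_centroids()) {
  at <- fragment$atoms
  k <- fragment$center
  res <- fragment_residues(fragment)
  resid_k <- at$resid[at$resno == k][1]
  guide_nm <- guide_atom_name(resid_k)
  can_flip <- flips_allowed && (k + 1) %in% res && k %in% res[-length(res)]
  flip_states <- c(list(NULL), if (can_flip) centroids else NULL)
  out <- list()
  for (fs in flip_states) {
    frag_f <- if (is.null(fs)) fragment else
      tryCatch(apply_flip_to_fragment(fragment, fs), error = function(e) NULL)
    if (is.null(frag_f)) next
    guide_row <- which(frag_f$atoms$resno == k & frag_f$atoms$name == guide_nm)[1]
    if (is.na(guide_row)) guide_row <- which(frag_f$atoms$resno == k & frag_f$atoms$name == "O")[1]
    base <- as.numeric(frag_f$atoms[guide_row, c("x", "y", "z")])
    targets <- rbind(base, sample_guide_displacements(tensor, base, cfg))
    for (ti in seq_len(nrow(targets))) {
      if (ti == 1) {
        cand <- list(fragment = frag_f,
                     converged = TRUE, distance = 0, anchor_shift = 0, iterations = 0L)
      } else {
        cand <- nullspace_ik_close(frag_f, guide_row, targets[ti, ])
        # displacement targets are sampling suggestions: keep partial results
        # (flagged in the ik diagnostics) as long as closure and covalent
        # geometry are intact
        if (cand$anchor_shift > 0.01) next
        if (!fragment_bond_ok(cand$fragment, fragment)) next
      }
      out[[length(out) + 1]] <- list(
        atoms = cand$fragment$atoms,
        provenance = list(center = k,
                          flip = if (is.null(fs)) "none" else fs$name,
                          direction = ti - 1L),
        ik = cand[c("converged", "distance", "anchor_shift", "iterations")])
    }
  }
  out
}

small_chi_offsets <- function(resid) {
  if (toupper(resid) == "PRO") c(-10, 0, 10) else c(-20, -10, 0, 10, 20)
}

LARGE_CHI_OFFSETS <- seq(-25, by = 4.5, length.out = 12)

clash_free <- function(atoms, factor = 0.4) {
  sc <- which(!(atoms$name %in% c("N", "CA", "C", "O", "CB")))
  if (length(sc) == 0) return(TRUE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- VDW_RADII[toupper(atoms$element)]
  rad[is.na(rad)] <- 1.7
  for (i in sc) {
    other <- which(abs(atoms$resno - atoms$resno[i]) > 0)
    if (length(other) == 0) next
    d <- sqrt(colSums((t(xyz[other, , drop = FALSE]) - xyz[i, ])^2))
    if (any(d < factor * (rad[i] + rad[other]))) return(FALSE)
  }
  TRUE
}

build_center_sidechain <- function(candidate, center, resid, chi, memo = NULL) {
  if (!is.null(memo) && !is.null(memo$base)) {
    base <- memo$base; tmpl <- memo$tmpl; bb <- memo$bb
    sc <- build_sidechain(bb, resid, chi)
  } else {
    at <- candidate$atoms
    g <- function(nm) as.numeric(at[at$resno == center & at$name == nm, c("x", "y", "z")][1, ])
    bb <- list(N = g("N"), CA = g("CA"), C = g("C"))
    sc <- build_sidechain(bb, resid, chi)
    keep <- !(at$resno == center & !(at$name %in% c("N", "CA", "C", "O")))
    base <- at[keep, ]
    tmpl <- at[at$resno == center, ][1, ]
    if (!is.null(memo)) {
      memo$base <- base; memo$tmpl <- tmpl; memo$bb <- bb
    }
  }
  scrows <- tmpl[rep(1, nrow(sc)), ]
  scrows$name <- rownames(sc)
  scrows$element <- vapply(rownames(sc), sidechain_element, "")
  scrows$x <- sc[, 1]; scrows$y <- sc[, 2]; scrows$z <- sc[, 3]
  out <- dplyr::bind_rows(base, scrows)
  out[order(out$resno), ]
}

#' Decorate backbone candidates with a small-residue sidechain
#'
#' For each backbone x rotamer, the full Cartesian product of chi offsets
#' {-20,-10,0,+10,+20} degrees per chi (Pro: {-10,0,+10} to respect ring
#' closure) is built with ideal internal coordinates.
#'
#' @param backbones list from [enumerate_backbones()].
#' @param resid small residue type (ASN, ASP, CYS, ILE, LEU, PRO, SER, THR,
#'   VAL).
#' @param library rotamer library.
#' @param center center residue number (defaults to the provenance of the
#'   first backbone's fragment center, supplied by the caller).
#' @param clash_filter drop candidates with internal steric overlap worse
#'   than 0.4 x summed vdW radii.
#' @return list of candidate conformers: `atoms`, `provenance`.
#' @export
decorate_small_sidechain <- function(backbones, resid, library, center,
                                     clash_filter = FALSE) {
  resid <- toupper(resid)
  if (!resid %in% SMALL_SIDECHAINS) stop(resid, " is not a small sidechain type")
  rots <- rotamers_for(library, resid)
  offsets <- small_chi_offsets(resid)
  nchi <- chi_count(resid)
  grids <- as.matrix(do.call(expand.grid, rep(list(offsets), nchi)))
  out <- list()
  for (bi in seq_along(backbones)) {
    memo <- new.env(parent = emptyenv())
    for (ri in seq_along(rots)) {
      for (gi in seq_len(nrow(grids))) {
        chi <- rots[[ri]]$chi + grids[gi, ]
        atoms <- build_center_sidechain(backbones[[bi]], center, resid, chi, memo)
        if (clash_filter && !clash_free(atoms)) next
        out[[length(out) + 1]] <- list(
          atoms = atoms,
          provenance = c(backbones[[bi]]$provenance,
                         list(rotamer = rots[[ri]]$rotamer, chi = chi)))
      }
    }
  }
  out
}

#' Hierarchically decorate backbones with a large-residue sidechain
#'
#' Level l samples chi_l over a 50-degree window in 4.5-degree steps (12
#' offsets) around each surviving partial conformation, builds atoms through
#' chi_l's terminal atom, and passes the pool to `select_fn`, whose
#' survivors seed the next level, until the full sidechain is built.
#'
#' @param backbones list from [enumerate_backbones()].
#' @param resid large residue type (ARG, GLU, GLN, HIS, LYS, MET, PHE, TRP,
#'   TYR).
#' @param library rotamer library.
#' @param center center residue number.
#' @param select_fn function(candidates, level) -> indices of survivors
#'   (identity by default).
#' @return list of fully built candidate conformers.
#' @export
decorate_large_sidechain <- function(backbones, resid, library, center,
                                     select_fn = function(cands, level) seq_along(cands)) {
  resid <- toupper(resid)
  if (!resid %in% LARGE_SIDECHAINS) stop(resid, " is not a large sidechain type")
  rots <- rotamers_for(library, resid)
  nchi <- chi_count(resid)
  # survivors at level l: list of (backbone index, chi prefix of length l)
  surv <- list()
  for (bi in seq_along(backbones)) for (ri in seq_along(rots)) {
    surv[[length(surv) + 1]] <- list(bi = bi, rot = ri, chi = numeric(0))
  }
  for (level in seq_len(nchi)) {
    pool <- list()
    meta <- list()
    for (s in surv) {
      for (off in LARGE_CHI_OFFSETS) {
        chi <- c(s$chi, rots[[s$rot]]$chi[level] + off)
        full_chi <- c(chi, rots[[s$rot]]$chi[seq_len(nchi)[-seq_len(level)]])
        atoms <- build_center_sidechain(backbones[[s$bi]], center, resid, full_chi)
        pool[[length(pool) + 1]] <- list(
          atoms = atoms,
          provenance = c(backbones[[s$bi]]$provenance,
                         list(rotamer = rots[[s$rot]]$rotamer, chi = full_chi,
                              level = level)))
        meta[[length(meta) + 1]] <- list(bi = s$bi, rot = s$rot, chi = chi)
      }
    }
    keep <- select_fn(pool, level)
    if (length(keep) == 0) keep <- 1L  # fall back to the best/first candidate
    surv <- meta[keep]
    if (level == nchi) {
      return(pool[keep])
    }
  }
  list()
}
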