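# Nullspace inverse kinematics on a backbone fragment. Free degrees of
# freedom are the phi/psi dihedrals of the interior residues; rotating a
# dihedral moves all chain-downstream atoms. Guide-atom steps are projected
# onto the nullspace of the anchor-closure Jacobian (N, CA, C of the last
# fragment residue; the first residue is upstream of every free dihedral and
# cannot move), so chain closure is preserved to first order; a Gauss-Newton
# correction removes the second-order anchor drift after each step.
#
# The iteration works on a plain coordinate matrix with precomputed
# dihedral metadata (axis atom rows + moved-atom sets); the fragment tibble
# is only touched on entry and exit.

fragment_residues <- function(fragment) sort(unique(fragment$atoms$resno))

#' Extract a working fragment from a model
#'
#' @param model single-conformer [protein_model()].
#' @param chain chain id.
#' @param center center residue number k.
#' @param half_width residues on each side (fragment length 2*half_width+1,
#'   truncated at chain ends).
#' @return list with `atoms` (tibble), `chain`, `center`.
#' @export
extract_fragment <- function(model, chain, center, half_width = 3) {
  rt <- residue_table(model)
  rt <- rt[rt$chain == chain, ]
  lo <- max(min(rt$resno), center - half_width)
  hi <- min(max(rt$resno), center + half_width)
  at <- model$atoms[model$atoms$chain == chain &
                      model$atoms$resno >= lo & model$atoms$resno <= hi, ]
  at <- at[order(at$resno), ]
  list(atoms = at, chain = chain, center = center)
}

# free dihedrals of a fragment: phi/psi of interior residues
free_dihedrals <- function(fragment, exclude = character()) {
  res <- fragment_residues(fragment)
  if (length(res) < 3) return(character(0))
  interior <- res[-c(1, length(res))]
  dh <- as.vector(rbind(paste0("phi_", interior), paste0("psi_", interior)))
  setdiff(dh, exclude)
}

# precompute, for each dihedral: axis endpoint rows and moved-atom rows
dihedral_meta <- function(fragment, dihedrals) {
  at <- fragment$atoms
  lapply(dihedrals, function(dh) {
    parts <- strsplit(dh, "_")[[1]]
    type <- parts[1]; i <- as.integer(parts[2])
    if (type == "phi") {
      p_row <- which(at$resno == i & at$name == "N")[1]
      u_row <- which(at$resno == i & at$name == "CA")[1]
      moved <- at$resno > i | (at$resno == i & !(at$name %in% c("N", "CA")))
    } else {
      p_row <- which(at$resno == i & at$name == "CA")[1]
      u_row <- which(at$resno == i & at$name == "C")[1]
      moved <- at$resno > i | (at$resno == i & at$name == "O")
    }
    list(p_row = p_row, u_row = u_row, moved = which(moved))
  })
}

# indices of anchor atoms (N, CA, C of the last fragment residue)
anchor_rows <- function(fragment) {
  res <- fragment_residues(fragment)
  last <- res[length(res)]
  which(fragment$atoms$resno == last & fragment$atoms$name %in% c("N", "CA", "C"))
}

cross_rows <- function(u, M) {
  # u x m for each row m of M
  cbind(u[2] * M[, 3] - u[3] * M[, 2],
        u[3] * M[, 1] - u[1] * M[, 3],
        u[1] * M[, 2] - u[2] * M[, 1])
}

# Jacobian (3*length(rows) x n_dihedrals) of selected atom positions
ik_jacobian_mat <- function(X, meta, rows) {
  J <- matrix(0, 3 * length(rows), length(meta))
  for (j in seq_along(meta)) {
    mt <- meta[[j]]
    p <- X[mt$p_row, ]
    u <- vec_unit(X[mt$u_row, ] - p)
    sel <- rows %in% mt$moved
    if (!any(sel)) next
    rr <- which(sel)
    contrib <- cross_rows(u, t(t(X[rows[rr], , drop = FALSE]) - p))
    for (a in seq_along(rr)) J[(3 * rr[a] - 2):(3 * rr[a]), j] <- contrib[a, ]
  }
  J
}

apply_steps_mat <- function(X, meta, dtheta_rad) {
  for (j in seq_along(meta)) {
    th <- dtheta_rad[j]
    if (abs(th) < 1e-13) next
    mt <- meta[[j]]
    p <- X[mt$p_row, ]
    u <- vec_unit(X[mt$u_row, ] - p)
    R <- rotation_matrix_axis(u, rad2deg(th))
    X[mt$moved, ] <- t(R %*% (t(X[mt$moved, , drop = FALSE]) - p) + p)
  }
  X
}

nullspace_basis <- function(J, tol = 1e-8) {
  s <- svd(J, nv = ncol(J))
  rank <- sum(s$d > tol * max(s$d, 1e-300))
  if (rank >= ncol(J)) return(matrix(0, ncol(J), 0))
  s$v[, (rank + 1):ncol(J), drop = FALSE]
}

pinv_solve <- function(J, b, tol = 1e-8) {
  s <- svd(J)
  keep <- s$d > tol * max(s$d, 1e-300)
  if (!any(keep)) return(rep(0, ncol(J)))
  as.numeric(s$v[, keep, drop = FALSE] %*%
               ((t(s$u[, keep, drop = FALSE]) %*% b) / s$d[keep]))
}

#' Deform a fragment so a guide atom approaches a target, keeping closure
#'
#' Projected-gradient steps on the guide-to-target distance restricted to
#' the nullspace of the anchor Jacobian, with Gauss-Newton anchor-drift
#' correction after every step. Terminates when the guide is within `tol` of
#' the target or after `max_iter` iterations; each accepted step strictly
#' decreases the guide distance.
#'
#' @param fragment a fragment from [extract_fragment()].
#' @param guide_row row index of the guide atom in `fragment$atoms`.
#' @param target 3-vector target position.
#' @param exclude_dihedrals dihedral names (e.g. "psi_6") held fixed.
#' @param tol convergence distance (Angstrom).
#' @param max_iter iteration cap.
#' @param max_step largest guide move attempted per iteration (Angstrom).
#' @return list: `fragment` (deformed), `converged`, `distance`,
#'   `anchor_shift`, `iterations`.
#' @export
nullspace_ik_close <- function(fragment, guide_row, target,
                               exclude_dihedrals = character(),
                               tol = 0.05, max_iter = 200, max_step = 0.5) {
  dihedrals <- free_dihedrals(fragment, exclude_dihedrals)
  anch <- anchor_rows(fragment)
  X <- as.matrix(fragment$atoms[, c("x", "y", "z")])
  anchor0 <- X[anch, , drop = FALSE]
  dist0 <- vec_norm(X[guide_row, ] - target)
  if (dist0 <= tol) {
    return(list(fragment = fragment, converged = TRUE, distance = dist0,
                anchor_shift = 0, iterations = 0L))
  }
  if (length(dihedrals) < 6) {
    return(list(fragment = fragment, converged = FALSE, distance = dist0,
                anchor_shift = 0, iterations = 0L))
  }
  meta <- dihedral_meta(fragment, dihedrals)
  it <- 0L
  dist <- dist0
  repeat {
    it <- it + 1L
    if (it > max_iter || dist <= tol) break
    dir <- target - X[guide_row, ]
    Jc <- ik_jacobian_mat(X, meta, anch)
    Jg <- ik_jacobian_mat(X, meta, guide_row)
    N <- nullspace_basis(Jc)
    if (ncol(N) == 0) break
    # Gauss-Newton step restricted to the closure nullspace; falls back to
    # the projected gradient when the restricted system is degenerate
    A <- Jg %*% N
    step_dir <- as.numeric(N %*% pinv_solve(A, dir))
    pred <- as.numeric(Jg %*% step_dir)
    if (vec_norm(pred) < 1e-10) {
      g <- as.numeric(t(Jg) %*% dir)
      step_dir <- as.numeric(N %*% (t(N) %*% g))
      pred <- as.numeric(Jg %*% step_dir)
      if (vec_norm(pred) < 1e-10) break
    }
    scale <- min(dist, max_step) / vec_norm(pred)
    improved <- FALSE
    for (bt in 1:6) {
      Xt <- apply_steps_mat(X, meta, step_dir * scale)
      for (cc in 1:3) {  # remove second-order anchor drift
        err <- as.numeric(t(anchor0 - Xt[anch, , drop = FALSE]))
        if (vec_norm(err) < 1e-5) break
        Jc_t <- ik_jacobian_mat(Xt, meta, anch)
        Xt <- apply_steps_mat(Xt, meta, pinv_solve(Jc_t, err))
      }
      nd <- vec_norm(Xt[guide_row, ] - target)
      if (nd < dist - 1e-9) {
        X <- Xt; dist <- nd; improved <- TRUE
        break
      }
      scale <- scale / 2
    }
    if (!improved) break
  }
  fragment$atoms$x <- X[, 1]; fragment$atoms$y <- X[, 2]; fragment$atoms$z <- X[, 3]
  list(fragment = fragment, converged = dist <= tol, distance = dist,
       anchor_shift = max(sqrt(rowSums((X[anch, , drop = FALSE] - anchor0)^2))),
       iterations = it)
}
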