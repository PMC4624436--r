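# Occupancy selection: QP pre-fit and threshold/cardinality-constrained
# MIQP against masked residual density.
#
# The MIQP min ||rho_o - sum_i w_i rho_i^c||^2 with w_i in {0} u [t, 1] and
# sum w <= 1 is solved exactly: the QP pre-fit (threshold relaxed to 0)
# prunes to the candidates with non-vanishing occupancy, and the MIQP over
# the survivors is solved by enumerating every admissible support set (at
# most floor(1/t) members) and solving each small inequality-constrained
# least-squares subproblem by complete active-set enumeration. With at most
# 30 survivors and cardinality <= 5 this is fast and certifiably optimal.

#' Resolution-dependent occupancy threshold schedule
#'
#' Declared default: t = 0.25 (up to four conformers) below 1.8 Angstrom,
#' t = 0.33 (up to three) at or beyond.
#'
#' @param d resolution (Angstrom).
#' @return threshold t in (0, 1].
#' @export
threshold_for_resolution <- function(d) ifelse(d < 1.8, 0.25, 1 / 3)

# density of atoms evaluated at arbitrary points (mask voxel centers); an
# optional environment memoizes per-atom contributions (candidates sharing
# a backbone reuse most atoms)
density_at_points <- function(atoms, pts, d, cutoff = 3 + mask_radius(d),
                              cache = NULL) {
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(atoms))) {
    occ <- atoms$occ[i]
    if (occ == 0) next
    key <- NULL
    if (!is.null(cache)) {
      key <- sprintf("%.4f|%.4f|%.4f|%s|%.3f", atoms$x[i], atoms$y[i],
                     atoms$z[i], atoms$element[i], atoms$b[i])
      hit <- cache[[key]]
      if (!is.null(hit)) {
        out <- out + occ * hit
        next
      }
    }
    ff <- FORM_FACTORS[[toupper(atoms$element[i])]]
    if (is.null(ff)) stop("no form factor for element: ", atoms$element[i])
    B <- max(atoms$b[i], 0)
    r2 <- (pts[, 1] - atoms$x[i])^2 + (pts[, 2] - atoms$y[i])^2 +
      (pts[, 3] - atoms$z[i])^2
    sel <- r2 <= cutoff^2
    contrib <- numeric(nrow(pts))
    if (any(sel)) {
      acc <- numeric(sum(sel))
      for (k in seq_along(ff$a)) {
        w <- max(ff$b[k] + B, 0.1)
        acc <- acc + ff$a[k] * (4 * pi / w)^1.5 * exp(-4 * pi^2 * r2[sel] / w)
      }
      contrib[sel] <- acc
    }
    if (!is.null(cache)) cache[[key]] <- contrib
    out <- out + occ * contrib
  }
  out
}

mask_atom_rows <- function(atoms) {
  # fitting mask generators: sidechain atoms (CB and beyond) + carbonyl O
  which(!(atoms$name %in% c("N", "CA", "C")))
}

#' Build an occupancy-selection problem from a residual map
#'
#' The fitting mask is the union of spheres of radius [mask_radius()] around
#' every candidate's sidechain (CB and beyond) and carbonyl O atoms; the
#' residual density and each candidate's calculated density are restricted
#' to that mask.
#'
#' @param residual_map background-subtracted [density_map()].
#' @param candidates list of candidate atom tables (the rebuilt atoms of
#'   each candidate conformer).
#' @param d resolution (Angstrom).
#' @param t occupancy threshold in (0, 1].
#' @return object of class `selection_problem`: `target`, `A` (voxels x
#'   candidates), `mask` (linear indices), `t`, `d`.
#' @export
build_problem <- function(residual_map, candidates, d, t = threshold_for_resolution(d)) {
  stopifnot(t > 0, t <= 1, length(candidates) >= 1)
  r <- mask_radius(d)
  centers <- do.call(rbind, lapply(candidates, function(at) {
    as.matrix(at[mask_atom_rows(at), c("x", "y", "z")])
  }))
  mask <- voxel_mask(residual_map, centers, r)
  if (length(mask) == 0) stop("empty fitting mask")
  dims <- dim(residual_map$values)
  ai <- arrayInd(mask, dims)
  pts <- mask_points(ai, residual_map)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  A <- vapply(candidates, function(at) density_at_points(at, pts, d, cache = cache),
              numeric(length(mask)))
  A <- matrix(A, nrow = length(mask))
  structure(list(target = residual_map$values[mask], A = A, mask = mask,
                 t = t, d = d), class = "selection_problem")
}

new_occupancy_solution <- function(w, t, objective, provenance) {
  structure(list(weights = w, z = as.integer(w > 0), threshold = t,
                 objective = objective, provenance = provenance),
            class = "occupancy_solution")
}

#' @export
print.occupancy_solution <- function(x, ...) {
  sel <- which(x$weights > 0)
  cat(sprintf("<occupancy_solution> %d/%d selected (t = %.2f, %s), RSS = %.4g\n",
              length(sel), length(x$weights), x$threshold, x$provenance,
              x$objective))
  if (length(sel) > 0) {
    cat("  ", paste(sprintf("#%d: %.3f", sel, x$weights[sel]), collapse = "  "), "\n")
  }
  invisible(x)
}

# active-set nonnegative least squares (Lawson-Hanson), minimizing
# ||A w - b||^2 + 2 * mu * sum(w) over w >= 0. mu > 0 is the multiplier of
# the simplex constraint sum(w) <= 1 (see qp_fit).
nnls_fit <- function(A, b, mu = 0, tol = 1e-10) {
  n <- ncol(A)
  P <- logical(n)
  w <- rep(0, n)
  resid <- b
  # scale-aware entry criterion: a column joins only if its gradient is a
  # meaningful fraction of what a unit-norm column could explain
  colnorm <- sqrt(colSums(A^2))
  gate <- 1e-6 * max(colnorm) * sqrt(sum(b^2))
  for (outer in seq_len(min(3 * n, 200L))) {
    grad <- as.numeric(crossprod(A, resid)) - mu
    grad[P] <- -Inf
    j <- which.max(grad)
    if (grad[j] <= gate) break
    P[j] <- TRUE
    repeat {
      s <- rep(0, n)
      AP <- A[, P, drop = FALSE]
      GP <- crossprod(AP)
      gP <- as.numeric(crossprod(AP, b)) - mu
      fit <- tryCatch(solve(GP, gP), error = function(e) NULL)
      if (is.null(fit)) {
        P[j] <- FALSE
        break
      }
      s[P] <- fit
      if (all(s[P] > tol)) {
        w <- s
        break
      }
      neg <- P & s <= tol
      alpha <- min(w[neg] / (w[neg] - s[neg] + 1e-300))
      w <- w + alpha * (s - w)
      P[P & w <= tol] <- FALSE
    }
    resid <- b - as.numeric(A %*% w)
  }
  w
}

#' Convex QP pre-fit (threshold relaxed to zero)
#'
#' Minimizes ||target - A w||^2 subject to w >= 0 and sum(w) <= 1, the
#' convex relaxation of the selection MIQP. Solved by active-set
#' nonnegative least squares; when the simplex constraint is active its
#' Lagrange multiplier is found by bisection (each trial is another NNLS
#' solve), which is exact for this strictly convex problem.
#'
#' @param problem a [build_problem()] result.
#' @return an `occupancy_solution` with provenance "relaxation".
#' @export
qp_fit <- function(problem) {
  A <- problem$A
  b <- problem$target
  w <- nnls_fit(A, b)
  if (sum(w) > 1 + 1e-9) {
    lo <- 0
    hi <- max(as.numeric(crossprod(A, b)))  # sum(w) = 0 at this multiplier
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      wm <- nnls_fit(A, b, mu = mid)
      if (sum(wm) > 1) lo <- mid else hi <- mid
      if (abs(sum(wm) - 1) < 1e-9) break
    }
    w <- nnls_fit(A, b, mu = hi)
    if (sum(w) > 1) w <- w / sum(w)  # remove residual bisection slack
  }
  w[w < 1e-9] <- 0
  obj <- sum((b - as.numeric(A %*% w))^2)
  new_occupancy_solution(w, 0, obj, "relaxation")
}

# exact minimization of ||b - A_S w||^2 over w_i >= t, sum w <= 1 for one
# support S, by complete enumeration of active constraint sets
solve_support <- function(G, g, btb, S, t) {
  kk <- length(S)
  if (kk * t > 1 + 1e-12) return(NULL)
  GS <- G[S, S, drop = FALSE]
  gS <- g[S]
  # interior shortcut: if the unconstrained minimizer over this support is
  # feasible it is optimal, and no active-set enumeration is needed
  w0 <- tryCatch(solve(GS, gS), error = function(e) NULL)
  if (!is.null(w0) && all(w0 >= t - 1e-9) && sum(w0) <= 1 + 1e-9) {
    obj <- btb - 2 * sum(gS * w0) + as.numeric(t(w0) %*% GS %*% w0)
    return(list(w = as.numeric(w0), obj = obj))
  }
  best <- NULL
  for (Lmask in 0:(2^kk - 1)) {
    L <- which(bitwAnd(Lmask, 2^(seq_len(kk) - 1)) > 0)
    FR <- setdiff(seq_len(kk), L)
    for (sum_active in c(FALSE, TRUE)) {
      w <- rep(t, kk)
      if (length(FR) > 0) {
        GFF <- GS[FR, FR, drop = FALSE]
        rhs <- gS[FR] - if (length(L) > 0)
          GS[FR, L, drop = FALSE] %*% rep(t, length(L)) else 0
        if (sum_active) {
          # equality sum(w_F) = 1 - t|L| via KKT bordered system
          nf <- length(FR)
          K <- rbind(cbind(GFF, rep(1, nf)), c(rep(1, nf), 0))
          rr <- c(rhs, 1 - t * length(L))
          wf <- tryCatch(solve(K, rr), error = function(e) NULL)
          if (is.null(wf)) next
          w[FR] <- wf[seq_len(nf)]
        } else {
          wf <- tryCatch(solve(GFF, rhs), error = function(e) NULL)
          if (is.null(wf)) next
          w[FR] <- wf
        }
      } else if (sum_active && abs(t * kk - 1) > 1e-9) next
      if (any(w < t - 1e-9)) next
      if (sum(w) > 1 + 1e-9) next
      obj <- btb - 2 * sum(gS * w) + as.numeric(t(w) %*% GS %*% w)
      if (is.null(best) || obj < best$obj - 1e-12) best <- list(w = w, obj = obj)
    }
  }
  best
}

#' Exact MIQP occupancy selection over QP survivors
#'
#' Enumerates every support set of the candidates with non-vanishing
#' pre-fit occupancy (truncated to the 30 largest with a warning), of size
#' at most floor(1/t), and solves each threshold-constrained least-squares
#' subproblem exactly. Ties are broken toward fewer conformers, then
#' lexicographic candidate order.
#'
#' @param problem a [build_problem()] result.
#' @param prefit the [qp_fit()] solution (computed when NULL).
#' @return an `occupancy_solution` with provenance "exhaustive".
#' @export
miqp_select <- function(problem, prefit = NULL) {
  if (is.null(prefit)) prefit <- qp_fit(problem)
  A <- problem$A
  b <- problem$target
  t <- problem$t
  surv <- which(prefit$weights > 0)
  if (length(surv) == 0) surv <- seq_len(ncol(A))
  if (length(surv) > 30) {
    warning("truncating MIQP survivors to the 30 largest pre-fit occupancies")
    surv <- surv[order(prefit$weights[surv], decreasing = TRUE)[1:30]]
    surv <- sort(surv)
  }
  m <- floor(1 / t + 1e-9)
  # Gram restricted to survivors (avoids the full n x n crossproduct)
  As <- A[, surv, drop = FALSE]
  Gs <- crossprod(As)
  gs <- as.numeric(crossprod(As, b))
  btb <- sum(b^2)
  best <- NULL
  best_S <- NULL  # in survivor-local indices
  for (k in seq_len(min(m, length(surv)))) {
    combs <- utils::combn(seq_along(surv), k)
    for (ci in seq_len(ncol(combs))) {
      S <- combs[, ci]
      r <- solve_support(Gs, gs, btb, S, t)
      if (is.null(r)) next
      better <- is.null(best) || r$obj < best$obj - 1e-12 ||
        (abs(r$obj - best$obj) <= 1e-12 &&
           (length(S) < length(best_S) ||
              (length(S) == length(best_S) &&
                 paste(surv[S], collapse = ",") < paste(surv[best_S], collapse = ","))))
      if (better) {
        best <- r
        best_S <- S
      }
    }
  }
  w <- rep(0, ncol(A))
  w[surv[best_S]] <- best$w
  new_occupancy_solution(w, t, best$obj, "exhaustive")
}

#' Occupancy-selection survivor callback for hierarchical sidechain building
#'
#' Returns a function(candidates, level) that fits the density built so far
#' and keeps the conformations with non-zero MIQP occupancy (at most
#' floor(1/t)).
#'
#' @param residual_map background-subtracted [density_map()].
#' @param d resolution.
#' @param t occupancy threshold.
#' @return selection callback for [decorate_large_sidechain()].
#' @export
make_density_select_fn <- function(residual_map, d, t = threshold_for_resolution(d)) {
  function(cands, level) {
    atoms_list <- lapply(cands, candidate_rebuilt_atoms)
    prob <- tryCatch(build_problem(residual_map, atoms_list, d, t),
                     error = function(e) NULL)
    if (is.null(prob)) return(seq_along(cands))
    sol <- tryCatch(miqp_select(prob), error = function(e) NULL)
    if (is.null(sol)) return(seq_along(cands))
    keep <- which(sol$weights > 0)
    if (length(keep) == 0) seq_len(1) else keep
  }
}

#' Fragment-level occupancy selection over combined conformations
#'
#' Combines per-residue conformer sets into full-fragment conformations
#' (the Cartesian product C_f = prod C_i), fits them by QP + MIQP so every
#' atom in a selected fragment conformation carries one occupancy, and
#' falls back to divide-and-conquer when C_f exceeds `cap`.
#'
#' @param conformer_sets list (one per residue) of lists of candidate atom
#'   tables.
#' @param residual_map background-subtracted [density_map()].
#' @param d resolution.
#' @param t occupancy threshold.
#' @param cap combinatorial cap triggering divide-and-conquer.
#' @return list: `solution` (an `occupancy_solution` over the selected
#'   combinations), `combos` (matrix of per-residue conformer indices, one
#'   row per selected fragment conformation), `weights`.
#' @export
fragment_select <- function(conformer_sets, residual_map, d,
                            t = threshold_for_resolution(d), cap = 1024) {
  K <- length(conformer_sets)
  counts <- vapply(conformer_sets, length, 0L)
  r <- mask_radius(d)
  centers <- do.call(rbind, lapply(unlist(conformer_sets, recursive = FALSE),
                                   function(at) as.matrix(at[mask_atom_rows(at), c("x", "y", "z")])))
  mask <- voxel_mask(residual_map, centers, r)
  if (length(mask) == 0) stop("empty fitting mask")
  dims <- dim(residual_map$values)
  ai <- arrayInd(mask, dims)
  pts <- mask_points(ai, residual_map)
  b <- residual_map$values[mask]
  # per-residue candidate density columns on the union mask
  cols <- lapply(conformer_sets, function(set) {
    matrix(vapply(set, function(at) density_at_points(at, pts, d),
                  numeric(length(mask))), nrow = length(mask))
  })
  solve_range <- function(lo, hi) {
    cf <- prod(counts[lo:hi])
    if (cf <= cap) {
      combos <- as.matrix(do.call(expand.grid, lapply(lo:hi, function(i) seq_len(counts[i]))))
    } else {
      midpt <- (lo + hi) / 2
      split_at <- lo + which.min(abs(seq(lo, hi - 1) + 0.5 - midpt)) - 1
      left <- solve_range(lo, split_at)
      right <- solve_range(split_at + 1, hi)
      li <- rep(seq_len(nrow(left)), each = nrow(right))
      ri <- rep(seq_len(nrow(right)), times = nrow(left))
      combos <- cbind(left[li, , drop = FALSE], right[ri, , drop = FALSE])
    }
    Acomb <- matrix(0, length(mask), nrow(combos))
    for (j in seq_len(nrow(combos))) {
      for (i in seq_len(ncol(combos))) {
        Acomb[, j] <- Acomb[, j] + cols[[lo + i - 1]][, combos[j, i]]
      }
    }
    prob <- structure(list(target = b, A = Acomb, mask = mask, t = t, d = d),
                      class = "selection_problem")
    sol <- miqp_select(prob)
    keep <- which(sol$weights > 0)
    out <- combos[keep, , drop = FALSE]
    attr(out, "solution") <- sol
    attr(out, "weights") <- sol$weights[keep]
    out
  }
  combos <- solve_range(1, K)
  list(solution = attr(combos, "solution"),
       combos = matrix(as.matrix(combos), nrow = nrow(combos)),
       weights = attr(combos, "weights"))
}

#' Divide-and-conquer fragment selection
#'
#' Convenience wrapper over [fragment_select()] with a caller-chosen
#' combinatorial cap: fragments whose combined count exceeds `cap` are split
#' at the residue boundary nearest the midpoint, each segment is fitted by
#' MIQP, and the surviving segment conformations are recombined and
#' re-fitted.
#'
#' @inheritParams fragment_select
#' @param cap segment size cap.
#' @return as [fragment_select()].
#' @export
divide_and_conquer <- function(conformer_sets, residual_map, d,
                               t = threshold_for_resolution(d), cap = 1024) {
  fragment_select(conformer_sets, residual_map, d, t, cap)
}
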