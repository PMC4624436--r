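# Shared fixtures and independent oracles for the test suite. Oracles are
# written without reference to the package's own solver paths.

# short irregular-loop chain with optional sidechains
toy_chain <- function(resids = c("ALA", "SER", "ALA"), chis = NULL) {
  n <- length(resids)
  build_chain(resids, phi = rep(-85, n), psi = rep(75, n), chis = chis)
}

# serine conformer variants of residue 2 in a 3-residue chain
ser_conformers <- function(model, chi_values) {
  lapply(chi_values, function(chi) {
    at <- model$atoms
    g <- function(nm) as.numeric(at[at$resno == 2 & at$name == nm,
                                    c("x", "y", "z")][1, ])
    sc <- build_sidechain(list(N = g("N"), CA = g("CA"), C = g("C")), "SER", chi)
    at[at$resno == 2 & at$name == "OG", c("x", "y", "z")] <- as.list(sc["OG", ])
    at[at$resno == 2, ]
  })
}

# noiseless observed map for a weighted mixture of residue-2 conformers
mixture_problem <- function(weights, chi_values, d = 1.5, t = 0.25,
                            decoy_chis = numeric()) {
  m <- toy_chain(c("ALA", "SER", "ALA"), chis = list(NULL, c(64), NULL))
  confs <- ser_conformers(m, c(chi_values, decoy_chis))
  grid <- grid_for_atoms(m$atoms, d)
  truth_atoms <- dplyr::bind_rows(lapply(seq_along(weights), function(i) {
    at <- confs[[i]]
    at$occ <- weights[i]
    at
  }))
  obs <- calc_density(dplyr::bind_rows(truth_atoms, m$atoms[m$atoms$resno != 2, ]),
                      grid)
  residual <- background_subtract(obs, m, which(m$atoms$resno == 2), d)
  build_problem(residual, confs, d, t)
}

# independent MIQP oracle: support enumeration + quadprog per support
oracle_miqp <- function(A, b, t) {
  n <- ncol(A)
  m <- floor(1 / t + 1e-9)
  best <- NULL
  for (k in seq_len(min(m, n))) {
    combs <- utils::combn(n, k)
    for (ci in seq_len(ncol(combs))) {
      S <- combs[, ci]
      if (k * t > 1 + 1e-12) next
      AS <- A[, S, drop = FALSE]
      G <- crossprod(AS) + diag(1e-10, k)
      g <- as.numeric(crossprod(AS, b))
      Amat <- cbind(diag(k), -rep(1, k))
      bvec <- c(rep(t, k), -1)
      sol <- tryCatch(quadprog::solve.QP(G, g, Amat, bvec),
                      error = function(e) NULL)
      if (is.null(sol)) next
      w <- sol$solution
      obj <- sum((b - as.numeric(AS %*% w))^2)
      if (is.null(best) || obj < best$obj - 1e-9) {
        wfull <- rep(0, n)
        wfull[S] <- w
        best <- list(w = wfull, obj = obj)
      }
    }
  }
  best
}

# brute-force Lennard-Jones pair sum (O(n^2), no pair table reuse)
oracle_lj <- function(model, params = lj_params()) {
  at <- model$atoms
  n <- nrow(at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- params$radii[toupper(at$element)]
  rad[is.na(rad)] <- 1.7
  # bond graph by distance, BFS to depth 3
  bonded <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    lim <- if (toupper(at$element[i]) == "S" || toupper(at$element[j]) == "S") 2.1 else 1.85
    compat <- at$altloc[i] == at$altloc[j] || at$altloc[i] == "" || at$altloc[j] == ""
    if (compat && sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < lim) {
      bonded[i, j] <- bonded[j, i] <- TRUE
    }
  }
  sep_ok <- function(i, j) {
    # TRUE if bond separation > 3
    frontier <- i
    seen <- i
    for (depth in 1:3) {
      frontier <- setdiff(which(apply(bonded[frontier, , drop = FALSE], 2, any)), seen)
      if (j %in% frontier) return(FALSE)
      seen <- c(seen, frontier)
    }
    TRUE
  }
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!(at$altloc[i] == at$altloc[j] || at$altloc[i] == "" || at$altloc[j] == "")) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d >= params$cutoff || d < 1e-6) next
    if (!sep_ok(i, j)) next
    rm <- rad[i] + rad[j]
    s <- s + params$epsilon * ((rm / d)^12 - 2 * (rm / d)^6)
  }
  unname(s)
}

# exact hypergeometric upper tail by direct factorial summation (small n)
oracle_hyper_tail <- function(hits, total, bg_hits, bg_total) {
  num <- 0
  for (k in hits:min(total, bg_hits)) {
    num <- num + choose(bg_hits, k) * choose(bg_total - bg_hits, total - k)
  }
  num / choose(bg_total, total)
}

local_centroids <- function() {
  cents <- load_flip_centroids()
  names(cents) <- vapply(cents, `[[`, "", "name")
  cents
}

iso_tensor <- function(lam = 0.25) {
  list(tensor = diag(3) * lam, values = rep(lam, 3), vectors = diag(3),
       fallback = FALSE)
}
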