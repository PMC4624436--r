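# Occupancy selection: QP pre-fit, exact MIQP, fragment synchronization.

test_that("fitting masks are built from sidechain and carbonyl O atoms", {
  prob_env <- mixture_problem(c(0.7, 0.3), c(64, 178), decoy_chis = -65)
  expect_s3_class(prob_env, "selection_problem")
  expect_gt(length(prob_env$mask), 50)
  # glycine-style candidates (no sidechain): mask comes from the O atom
  m <- toy_chain(c("ALA", "GLY", "ALA"))
  d <- 1.5
  obs <- calc_density(m$atoms, grid_for_atoms(m$atoms, d), d)
  sel <- which(m$atoms$resno == 2 & !(m$atoms$name %in% c("N", "CA")))
  residual <- background_subtract(obs, m, sel, d)
  cand <- list(m$atoms[sel, ])
  prob <- build_problem(residual, cand, d, 0.25)
  opos <- atom_xyz(m$atoms[m$atoms$resno == 2, ], "O")
  ai <- arrayInd(prob$mask, dim(residual$values))
  pts <- cbind(residual$origin[1] + (ai[, 1] - 1) * residual$spacing[1],
               residual$origin[2] + (ai[, 2] - 1) * residual$spacing[2],
               residual$origin[3] + (ai[, 3] - 1) * residual$spacing[3])
  dmax <- max(sqrt(colSums((t(pts) - opos)^2)))
  # C atom also generates mask voxels; all lie within r of some generator
  gens <- m$atoms[sel, ]
  mind <- apply(pts, 1, function(p)
    min(sqrt((gens$x - p[1])^2 + (gens$y - p[2])^2 + (gens$z - p[3])^2)))
  expect_true(all(mind <= mask_radius(d) + max(residual$spacing)))
})

test_that("QP pre-fit recovers noiseless mixtures exactly", {
  prob <- mixture_problem(c(0.7, 0.3), c(64, 178), decoy_chis = -65)
  pf <- qp_fit(prob)
  expect_equal(pf$weights[1:2], c(0.7, 0.3), tolerance = 1e-6)
  expect_equal(pf$weights[3], 0, tolerance = 1e-6)
  # single candidate explaining the target exactly
  prob1 <- mixture_problem(1, 64)
  pf1 <- qp_fit(prob1)
  expect_equal(pf1$weights, 1, tolerance = 1e-6)
  expect_lt(pf1$objective, 1e-10 * sum(prob1$target^2))
})

test_that("MIQP selection matches the independent oracle on random instances", {
  skip_if_not_installed("quadprog")
  set.seed(31)
  for (rep in 1:100) {
    nv <- sample(25:60, 1)
    nc <- sample(2:12, 1)
    A <- matrix(abs(rnorm(nv * nc)), nv, nc)
    t <- runif(1, 0.15, 0.9)
    k_true <- sample(seq_len(min(nc, floor(1 / t))), 1)
    S <- sample(seq_len(nc), k_true)
    w_true <- rep(0, nc)
    raw <- runif(k_true, t, 1)
    w_true[S] <- raw / max(1, sum(raw))
    w_true[S] <- pmax(w_true[S], t)
    if (sum(w_true) > 1) w_true[S] <- t  # keep feasible
    b <- as.numeric(A %*% w_true) + rnorm(nv, 0, 0.02)
    prob <- structure(list(target = b, A = A, t = t, d = 1.5),
                      class = "selection_problem")
    sol <- miqp_select(prob, qp_fit(prob))
    orc <- oracle_miqp(A, b, t)
    expect_equal(sol$objective, orc$obj, tolerance = 1e-6)
    # solution invariants: w in {0} u [t, 1], sum <= 1, cardinality bound
    nz <- sol$weights[sol$weights > 0]
    expect_true(all(nz >= t - 1e-9 & nz <= 1 + 1e-9))
    expect_lte(sum(sol$weights), 1 + 1e-9)
    expect_lte(sum(sol$weights > 0), floor(1 / t + 1e-9))
    expect_equal(sol$z, as.integer(sol$weights > 0))
  }
})

test_that("selection respects thresholds, relaxation bounds, and singletons", {
  prob <- mixture_problem(c(0.5, 0.5), c(64, 178), t = 0.2,
                          decoy_chis = c(-65, -170, -30, 100, 140, 30, -120, 75))
  pf <- qp_fit(prob)
  sol <- miqp_select(prob, pf)
  expect_equal(sol$weights[1:2], c(0.5, 0.5), tolerance = 1e-6)
  expect_true(all(sol$weights[-(1:2)] < 1e-6))
  # relaxation bound and best-singleton bound
  expect_lte(pf$objective, sol$objective + 1e-9)
  singles <- vapply(seq_len(ncol(prob$A)), function(j) {
    p1 <- structure(list(target = prob$target,
                         A = prob$A[, j, drop = FALSE], t = 1, d = prob$d),
                    class = "selection_problem")
    miqp_select(p1, qp_fit(p1))$objective
  }, 0)
  expect_lte(sol$objective, min(singles) + 1e-9)
  # t = 1 forces exactly one conformer
  prob1 <- prob; prob1$t <- 1
  s1 <- miqp_select(prob1, qp_fit(prob1))
  expect_equal(sum(s1$weights > 0), 1)
  # t = 0.25 caps the selection at four
  prob4 <- prob; prob4$t <- 0.25
  expect_lte(sum(miqp_select(prob4, qp_fit(prob4))$weights > 0), 4)
})

test_that("cardinality bound holds under fuzzed thresholds", {
  set.seed(33)
  for (rep in 1:25) {
    nc <- sample(3:10, 1)
    A <- matrix(abs(rnorm(40 * nc)), 40, nc)
    b <- as.numeric(A %*% runif(nc, 0, 0.4)) + rnorm(40, 0, 0.05)
    t <- runif(1, 0.1, 1)
    prob <- structure(list(target = b, A = A, t = t, d = 1.5),
                      class = "selection_problem")
    sol <- miqp_select(prob, qp_fit(prob))
    expect_lte(sum(sol$weights > 0), floor(1 / t + 1e-9))
    nz <- sol$weights[sol$weights > 0]
    if (length(nz) > 0) expect_true(all(nz >= t - 1e-9))
  }
})

test_that("fragment selection multiplies conformer sets and shares occupancies", {
  m <- toy_chain(c("ALA", "SER", "SER", "ALA"),
                 chis = list(NULL, c(64), c(-65), NULL))
  d <- 1.5
  # truth: two fragment-wide states at 60/40 over residues 2-3 (unequal
  # occupancies make the cross-residue pairing identifiable from density)
  mk <- function(resno, chi) {
    at <- m$atoms
    g <- function(nm) as.numeric(at[at$resno == resno & at$name == nm,
                                    c("x", "y", "z")][1, ])
    sc <- build_sidechain(list(N = g("N"), CA = g("CA"), C = g("C")), "SER", chi)
    at[at$resno == resno & at$name == "OG", c("x", "y", "z")] <- as.list(sc["OG", ])
    at[at$resno == resno, ]
  }
  stateA <- list(mk(2, 64), mk(3, -65))
  stateB <- list(mk(2, 178), mk(3, 60))
  grid <- grid_for_atoms(m$atoms, d)
  truth_atoms <- dplyr::bind_rows(
    lapply(stateA, function(at) within(at, occ <- 0.6)),
    lapply(stateB, function(at) within(at, occ <- 0.4)),
    m$atoms[!(m$atoms$resno %in% 2:3), ])
  obs <- calc_density(truth_atoms, grid)
  residual <- background_subtract(obs, m, which(m$atoms$resno %in% 2:3), d)
  sets <- list(list(stateA[[1]], stateB[[1]], mk(2, -65)),
               list(stateA[[2]], stateB[[2]], mk(3, 178)))
  fs <- fragment_select(sets, residual, d, t = 0.2)
  expect_equal(nrow(fs$combos), 2)
  expect_equal(sort(fs$weights), c(0.4, 0.6), tolerance = 1e-4)
  combos <- fs$combos[order(fs$combos[, 1]), , drop = FALSE]
  expect_equal(unname(as.matrix(combos)), rbind(c(1, 1), c(2, 2)))  # states stay linked
  # divide-and-conquer agrees with exhaustive enumeration on the same input
  dc <- divide_and_conquer(sets, residual, d, t = 0.2, cap = 4)
  expect_equal(sort(dc$weights), sort(fs$weights), tolerance = 1e-6)
  expect_lte(dc$solution$objective, fs$solution$objective * 1.05 + 1e-9)
})
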