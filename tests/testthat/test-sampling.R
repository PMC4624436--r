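# Conformer sampling: moment tensors, guide displacements, IK, backbone
# enumeration, sidechain decoration.

test_that("density moment tensor reflects blob shape and normalization", {
  at <- tibble::tibble(chain = "A", resno = 1L, icode = "", resid = "ALA",
                       name = "C", element = "C", altloc = "",
                       x = 0, y = 0, z = 0, occ = 1, b = 20)
  g <- grid_for_atoms(at, 1.0, spacing = 0.2, margin = 4)
  sph <- calc_density(at, g)
  t1 <- density_moment_tensor(sph, c(0, 0, 0), 1.5)
  expect_lt(t1$values[1] / t1$values[3], 1.1)     # spherical: near-equal eigenvalues
  # two blobs displaced along x: major axis within 5 degrees of x
  two <- dplyr::bind_rows(within(at, x <- -0.7), within(at, x <- 0.7))
  blobs <- calc_density(two, g)
  t2 <- density_moment_tensor(blobs, c(0, 0, 0), 2.0)
  ang <- acos(min(1, abs(sum(t2$vectors[, 1] * c(1, 0, 0))))) * 180 / pi
  expect_lt(ang, 5)
  # invariance under positive rescaling of the map
  scaled <- density_map(blobs$values * 7.3, blobs$origin, blobs$spacing, 1.0)
  t3 <- density_moment_tensor(scaled, c(0, 0, 0), 2.0)
  expect_equal(t3$tensor, t2$tensor, tolerance = 1e-12)
  # all-nonpositive density: isotropic fallback with warning
  neg <- density_map(-abs(blobs$values) - 1, blobs$origin, blobs$spacing, 1.0)
  expect_warning(t4 <- density_moment_tensor(neg, c(0, 0, 0), 1.5), "fallback")
  expect_true(t4$fallback)
})

test_that("guide displacements follow the ellipsoid axes and scale", {
  tens <- iso_tensor(0.25)
  base <- c(1, 2, 3)
  cfg0 <- sampler_config(mc_ampl = 0.2, jitter = 0)
  tg <- sample_guide_displacements(tens, base, cfg0)
  expect_equal(nrow(tg), 6)
  mags <- sqrt(rowSums((tg - matrix(base, 6, 3, byrow = TRUE))^2))
  expect_equal(mags, rep(0.2 * 0.5, 6), tolerance = 1e-12)  # isotropic, no jitter
  # magnitudes scale linearly with mc_ampl
  for (ma in c(0.1, 0.3)) {
    tgm <- sample_guide_displacements(tens, base,
                                      sampler_config(mc_ampl = ma, jitter = 0))
    m2 <- sqrt(rowSums((tgm - matrix(base, 6, 3, byrow = TRUE))^2))
    expect_equal(m2 / mags, rep(ma / 0.2, 6), tolerance = 1e-12)
  }
})

test_that("nullspace IK moves the guide while pinning the anchors", {
  m <- build_chain(rep("ALA", 7), phi = rep(-85, 7), psi = rep(75, 7))
  frag <- extract_fragment(m, "A", 4)
  gr <- which(frag$atoms$resno == 4 & frag$atoms$name == "CB")
  base <- as.numeric(frag$atoms[gr, c("x", "y", "z")])
  # identity target: zero iterations, fragment untouched
  r0 <- nullspace_ik_close(frag, gr, base)
  expect_equal(r0$iterations, 0L)
  expect_equal(r0$fragment$atoms$x, frag$atoms$x)
  # random displacements: anchors fixed, guide converges
  set.seed(21)
  for (i in 1:20) {
    tgt <- base + runif(3, -0.15, 0.15)
    r <- nullspace_ik_close(frag, gr, tgt)
    expect_lt(r$anchor_shift, 0.01)
    expect_lt(r$distance, vec_norm(tgt - base) + 1e-12)  # strictly improved
  }
})

test_that("candidate counts match the sampling scheme exactly", {
  m <- build_chain(rep(c("ALA", "GLY", "ALA"), 4)[1:11],
                   phi = rep(-85, 11), psi = rep(75, 11))
  frag <- extract_fragment(m, "A", 6)
  cents <- load_flip_centroids()
  cfg <- sampler_config(mc_ampl = 0.2, jitter = 0.05)
  set.seed(4)
  bb <- enumerate_backbones(frag, TRUE, iso_tensor(), cfg, cents)
  expect_length(bb, 35)                         # (1 + 4 flips) x (1 + 6)
  set.seed(4)
  bb7 <- enumerate_backbones(frag, FALSE, iso_tensor(), cfg, cents)
  expect_length(bb7, 7)                         # flips suppressed in helix/sheet
  # unflipped, undisplaced identity candidate is always present
  ident <- Filter(function(cc) cc$provenance$flip == "none" &&
                    cc$provenance$direction == 0L, bb)
  expect_length(ident, 1)
  expect_equal(ident[[1]]$atoms$x, frag$atoms$x)
  # glycine center: guide is the backbone O, count unchanged
  fragG <- extract_fragment(m, "A", 5)
  expect_equal(m$atoms$resid[m$atoms$resno == 5][1], "GLY")
  set.seed(4)
  bbG <- enumerate_backbones(fragG, TRUE, iso_tensor(), cfg, cents)
  expect_length(bbG, 35)
})

test_that("emitted candidates preserve covalent geometry and closure", {
  m <- build_chain(rep("ALA", 11), phi = rep(-85, 11), psi = rep(75, 11))
  frag <- extract_fragment(m, "A", 6)
  cents <- load_flip_centroids()
  set.seed(5)
  bb <- enumerate_backbones(frag, TRUE, iso_tensor(), sampler_config(0.3), cents)
  res <- sort(unique(frag$atoms$resno))
  first <- res[1]; last <- res[length(res)]
  anch0 <- frag$atoms[frag$atoms$resno %in% c(first, last) &
                        frag$atoms$name %in% c("N", "CA", "C"), ]
  for (cc in bb) {
    at <- cc$atoms
    anch <- at[at$resno %in% c(first, last) & at$name %in% c("N", "CA", "C"), ]
    expect_lt(max(abs(as.matrix(anch[, c("x", "y", "z")]) -
                        as.matrix(anch0[, c("x", "y", "z")]))), 0.011)
    for (i in seq_len(length(res) - 1)) {
      g <- function(rn, nm) as.numeric(at[at$resno == rn & at$name == nm,
                                          c("x", "y", "z")][1, ])
      b <- vec_norm(g(res[i + 1], "N") - g(res[i], "C"))
      expect_lt(abs(b - 1.329) / 1.329, 0.101)
    }
  }
})

test_that("small-residue decoration enumerates the 40/10 degree windows", {
  m <- build_chain(c(rep("ALA", 5), "SER", rep("ALA", 5)),
                   phi = rep(-85, 11), psi = rep(75, 11),
                   chis = c(rep(list(NULL), 5), list(c(64)), rep(list(NULL), 5)))
  frag <- extract_fragment(m, "A", 6)
  cents <- load_flip_centroids()
  lib <- load_rotamer_library()
  set.seed(6)
  bb <- enumerate_backbones(frag, TRUE, iso_tensor(), sampler_config(0.2), cents)
  sc <- decorate_small_sidechain(bb, "SER", lib, 6)
  expect_length(sc, length(bb) * 3 * 5)          # 35 x 3 rotamers x 5 offsets
  # offsets per chi are exactly {-20,-10,0,+10,+20} and chi builds exactly
  one_bb <- decorate_small_sidechain(bb[1], "SER", lib, 6)
  chis <- vapply(one_bb, function(cc)
    measure_chi(cc$atoms[cc$atoms$resno == 6, ], "SER"), 0)
  rot_chis <- vapply(rotamers_for(lib, "SER"), function(r) r$chi, 0)
  expected <- sort(as.numeric(outer(rot_chis, c(-20, -10, 0, 10, 20), `+`)))
  delta <- sort(((chis + 180) %% 360) - 180)
  expect_equal(delta, sort(((expected + 180) %% 360) - 180), tolerance = 1e-5)
  # proline uses the restricted offsets
  expect_equal(small_chi_offsets("PRO"), c(-10, 0, 10))
})

test_that("hierarchical decoration uses 12 offsets per level and honors survivors", {
  expect_length(LARGE_CHI_OFFSETS, 12)
  expect_equal(range(LARGE_CHI_OFFSETS), c(-25, 24.5))
  m <- build_chain(c("ALA", "MET", "ALA"), phi = rep(-85, 3), psi = rep(75, 3),
                   chis = list(NULL, c(-65, -65, -70), NULL))
  frag <- extract_fragment(m, "A", 2, half_width = 1)
  bb1 <- list(list(atoms = frag$atoms, provenance = list(center = 2L, flip = "none",
                                                         direction = 0L)))
  lib <- load_rotamer_library()
  rots <- length(rotamers_for(lib, "MET"))
  level_sizes <- c()
  keep_all <- function(cands, level) {
    level_sizes <<- c(level_sizes, length(cands))
    seq_along(cands)
  }
  out <- decorate_large_sidechain(bb1, "MET", lib, 2, select_fn = keep_all)
  expect_equal(level_sizes, c(rots * 12, rots * 12 * 12, rots * 12 * 12 * 12))
  expect_length(out, rots * 12^3)
  # survivor-limited path: keep only 2 per level
  keep2 <- function(cands, level) seq_len(min(2, length(cands)))
  out2 <- decorate_large_sidechain(bb1, "MET", lib, 2, select_fn = keep2)
  expect_length(out2, 2)
})
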