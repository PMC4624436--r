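# Peptide frames, flip centroids, flip detection, clustering, turn and
# enrichment statistics.

test_that("peptide frames are orthonormal, right-handed, and equivariant", {
  ref <- reference_peptide()
  fr <- peptide_frame(ref)
  expect_lt(max(abs(t(fr$R) %*% fr$R - diag(3))), 1e-12)
  expect_equal(det(fr$R), 1, tolerance = 1e-12)
  # reference expressed in its own frame: identity rotation, zero origin
  expect_lt(max(abs(fr$R - diag(3))), 1e-12)
  expect_equal(fr$origin, c(0, 0, 0), tolerance = 1e-12)
  # rigid motion of the peptide composes with the frame rotation exactly
  Rt <- rotation_matrix_axis(c(1, 2, -1), 63)
  shifted <- t(Rt %*% t(unclass(ref))) + matrix(c(3, -2, 5), 5, 3, byrow = TRUE)
  rownames(shifted) <- rownames(ref)
  fr2 <- peptide_frame(peptide_unit(shifted))
  expect_lt(max(abs(fr2$R - Rt %*% fr$R)), 1e-9)
  # collinear O1 degenerates
  bad <- unclass(ref)
  bad["O1", ] <- bad["CA1", ] + 1.24 * (bad["CA2", ] - bad["CA1", ]) /
    vec_norm(bad["CA2", ] - bad["CA1", ]) * 1.1
  expect_error(peptide_frame(structure(bad, class = class(ref))),
               "degenerate|bond length")
})

test_that("shipped centroids have the published rotation classes and CA shifts", {
  cents <- load_flip_centroids()
  expect_length(cents, 4)
  expect_setequal(vapply(cents, `[[`, "", "name"),
                  c("tweaked_down", "simple_down", "left", "right"))
  ref <- reference_peptide()
  rot <- vapply(cents, function(cl) detect_flip(ref, cl$coords)$rotation, 0)
  names(rot) <- vapply(cents, `[[`, "", "name")
  expect_lt(abs(abs(rot[["tweaked_down"]]) - 180), 10)
  expect_lt(abs(abs(rot[["simple_down"]]) - 180), 10)
  expect_lt(abs(rot[["left"]] - 120), 10)
  expect_lt(abs(rot[["right"]] + 120), 10)
  expect_true(sign(rot[["left"]]) != sign(rot[["right"]]))
  for (cl in cents) {
    expect_gt(vec_norm(cl$coords["CA1", ] - ref["CA1", ]), 0.2)
    expect_gt(vec_norm(cl$coords["CA2", ] - ref["CA2", ]), 0.2)
  }
})

test_that("centroid application is rigid and produces detectable flips", {
  cents <- load_flip_centroids()
  ref <- reference_peptide()
  target <- peptide_unit(rotate_about_axis(unclass(ref) +
                                             matrix(c(4, 1, -2), 5, 3, byrow = TRUE),
                                           c(0, 0, 0), c(2, 1, 1), 40))
  for (cl in cents) {
    cand <- apply_flip_centroid(target, cl)
    # internal 10-pair distance set preserved (rigid transform)
    expect_lt(max(abs(dist(cl$coords) - dist(cand))), 1e-9)
    det <- detect_flip(target, cand)
    expect_true(det$is_flip)
  }
})

test_that("flip detection applies all three geometric criteria symmetrically", {
  ref <- reference_peptide()
  self <- detect_flip(ref, ref)
  expect_false(self$is_flip)
  expect_equal(self$rotation, 0)
  # sub-90-degree rotation is rejected
  p60 <- unclass(ref)
  p60["O1", ] <- rotate_about_axis(matrix(ref["O1", ], 1), ref["CA1", ],
                                   ref["CA2", ] - ref["CA1", ], 60)
  p60["C1", ] <- rotate_about_axis(matrix(ref["C1", ], 1), ref["CA1", ],
                                   ref["CA2", ] - ref["CA1", ], 60)
  p60["N2", ] <- rotate_about_axis(matrix(ref["N2", ], 1), ref["CA1", ],
                                   ref["CA2", ] - ref["CA1", ], 60)
  d60 <- detect_flip(ref, peptide_unit(p60))
  expect_false(d60$is_flip)
  expect_equal(abs(d60$rotation), 60, tolerance = 1)
  # diverged flanking CA is rejected even with a large rotation: translate
  # the whole flipped unit so both CA atoms move beyond 1.5 A
  cents <- load_flip_centroids()
  moved <- unclass(apply_flip_centroid(ref, cents[[2]])) +
    matrix(c(0, 0, 1.7), 5, 3, byrow = TRUE)
  dm <- detect_flip(ref, peptide_unit(moved))
  expect_false(dm$is_flip)
  # symmetry of the decision and rotation magnitude
  cand <- apply_flip_centroid(ref, cents[[1]])
  d1 <- detect_flip(ref, cand); d2 <- detect_flip(cand, ref)
  expect_equal(d1$is_flip, d2$is_flip)
  expect_equal(abs(d1$rotation), abs(d2$rotation), tolerance = 1e-6)
})

test_that("k-means recovers planted clusters and matches stats::kmeans", {
  set.seed(11)
  cents <- load_flip_centroids()
  planted <- do.call(rbind, lapply(1:4, function(i) {
    base <- as.numeric(t(cents[[i]]$coords))
    t(replicate(20, base + rnorm(15, 0, 0.1 / sqrt(3))))
  }))
  truth <- rep(1:4, each = 20)
  cl <- cluster_flips(planted, k = 4, nstart = 10, seed = 3)
  # exact partition recovery (up to label permutation)
  tab <- table(truth, cl$assignment)
  expect_true(all(apply(tab, 1, function(r) sum(r > 0)) == 1))
  # inertia non-increasing across Lloyd iterations
  expect_true(all(diff(cl$inertia_trace) <= 1e-9))
  # agreement with the reference implementation's optimum
  km <- stats::kmeans(planted, centers = 4, nstart = 25)
  expect_equal(cl$inertia, km$tot.withinss / 5, tolerance = 1e-6)
  # k = 1: centroid equals the coordinate mean
  c1 <- cluster_flips(planted, k = 1, nstart = 2, seed = 1)
  expect_equal(as.numeric(c1$centroids), colMeans(planted), tolerance = 1e-9)
  # the four shipped centroids cluster into singletons with zero inertia
  pure <- do.call(rbind, lapply(cents, function(cl) as.numeric(t(cl$coords))))
  c4 <- cluster_flips(pure, k = 4, nstart = 25, seed = 2)
  expect_equal(sort(c4$size), rep(1L, 4))
  expect_lt(c4$inertia, 1e-12)
  expect_error(cluster_flips(pure, k = 5), "exceeds")
})

test_that("tight turns require the i-1 to i+2 mainchain hydrogen bond", {
  # ideal type-I beta turn: residues i+1, i+2 with canonical turn torsions
  turn <- build_chain(rep("ALA", 5), phi = c(-60, -60, -60, -90, -60),
                      psi = c(120, 120, -30, 0, 120))
  prev <- residue_ensemble(turn, "A", 2)$conformers[[1]]$atoms
  nxt <- residue_ensemble(turn, "A", 5)$conformers[[1]]$atoms
  d_on <- vec_norm(atom_xyz(nxt, "N") - atom_xyz(prev, "O"))
  expect_lt(d_on, 3.5)  # geometry sanity: the turn closes
  expect_true(is_tight_turn(turn, "A", 3))
  # extended chain: no turn
  ext <- build_chain(rep("ALA", 5), phi = rep(-120, 5), psi = rep(130, 5))
  expect_false(is_tight_turn(ext, "A", 3))
  # chain start: no residue i-1
  expect_false(is_tight_turn(turn, "A", 1))
  expect_equal(attr(is_tight_turn(turn, "A", 1), "reason"), "chain terminus")
})

test_that("glycine enrichment equals the exact hypergeometric tail", {
  # small-count brute force agreement
  for (case in list(c(5, 12, 20, 60), c(3, 8, 10, 40), c(0, 6, 15, 80))) {
    expect_equal(glycine_enrichment(case[1], case[2], case[3], case[4]),
                 oracle_hyper_tail(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-12)
  }
  expect_equal(glycine_enrichment(0, 24, 6092, 78094), 1)
  expect_lt(glycine_enrichment(40, 79, 6092, 78094), 1e-22)
  expect_lt(glycine_enrichment(5, 24, 6092, 78094), 0.05)
  expect_error(glycine_enrichment(-1, 5, 10, 100), "non-negative")
  expect_error(glycine_enrichment(6, 5, 10, 100), "exceed")
})

test_that("flip mining recovers the planted flip and its context flags", {
  cents <- local_centroids()
  truth <- build_flip_truth(cents$simple_down, occ_a = 0.5)
  obs <- mine_flips(list(case1 = truth))
  expect_true(nrow(obs) >= 1)
  hit <- obs[obs$resno == 6, ]
  expect_true(hit$is_flip)
  expect_gt(abs(hit$rotation), 150)
  expect_false(hit$gly_first)
  expect_true(hit$gly_second)
  # mined B-state coordinates cluster onto the generating centroid
  bcoords <- matrix(as.numeric(hit[1, paste0("coord_", 1:15)]), 1)
  cl <- cluster_flips(rbind(bcoords, t(as.numeric(t(cents$simple_down$coords)))),
                      k = 1, nstart = 1, seed = 1)
  expect_lt(sqrt(cl$inertia / 2), 0.8)  # within 0.8 A RMSD of the centroid
})
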