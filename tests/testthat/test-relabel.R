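# Lennard-Jones scoring, Monte-Carlo relabeling, conformer merging.

# two-residue toy with conformer pairs that clash unless labels pair up
clash_toy <- function() {
  m <- toy_chain(c("ALA", "SER", "ALA", "SER", "ALA"),
                 chis = list(NULL, c(64), NULL, c(-65), NULL))
  split_residue <- function(model, resno, shift) {
    ens <- residue_ensemble(model, "A", resno)
    a <- ens$conformers[[1]]
    b <- ens$conformers[[1]]
    b$atoms[b$atoms$name == "OG", c("x", "y", "z")] <-
      as.list(unlist(b$atoms[b$atoms$name == "OG", c("x", "y", "z")]) + shift)
    ens$conformers <- list(modifyList(a, list(occ = 0.5)),
                           modifyList(b, list(occ = 0.5)))
    at <- ensemble_atoms(ens)
    protein_model(dplyr::bind_rows(model$atoms[model$atoms$resno != resno, ], at))
  }
  og2 <- atom_xyz(m$atoms[m$atoms$resno == 2, ], "OG")
  og4 <- atom_xyz(m$atoms[m$atoms$resno == 4, ], "OG")
  # push residue 4's B conformer OG towards residue 2's B conformer OG
  m2 <- split_residue(m, 2, (og4 - og2) * 0.45)
  split_residue(m2, 4, (og2 - og4) * 0.45)
}

test_that("LJ pair terms hit their minimum at the radius sum and match brute force", {
  p <- lj_params()
  two <- tibble::tibble(chain = "A", resno = c(1L, 5L), icode = "",
                        resid = "ALA", name = "CA", element = "C", altloc = "",
                        x = c(0, 2 * p$radii[["C"]]), y = 0, z = 0, occ = 1, b = 10)
  m <- protein_model(two)
  expect_equal(lj_score(m, params = p), -p$epsilon, tolerance = 1e-12)
  # brute-force equality on a bigger model
  toy <- clash_toy()
  expect_equal(lj_score(toy, params = p), oracle_lj(toy, p), tolerance = 1e-9)
  # single-conformer model: score independent of (empty) assignment
  m1 <- toy_chain(c("ALA", "ALA"))
  expect_equal(lj_score(m1, list()), lj_score(m1, NULL))
})

test_that("downhill relabeling finds the non-clashing pairing", {
  toy <- clash_toy()
  # exhaustive oracle over the 2x2 label assignments of the two residues
  rt <- residue_table(toy)
  keys <- paste(rt$chain, rt$resno, rt$icode, sep = "\r")[rt$n_conformers > 1]
  perms <- list(c(A = "A", B = "B"), c(A = "B", B = "A"))
  best_oracle <- Inf
  for (p1 in perms) for (p2 in perms) {
    asg <- stats::setNames(list(p1, p2), keys)
    best_oracle <- min(best_oracle, lj_score(toy, asg))
  }
  for (seed in 1:10) {
    rl <- monte_carlo_relabel(toy, steps = 300, trials = 3, seed = seed)
    expect_lte(rl$score, rl$initial_score)           # downhill only
    expect_equal(rl$score, best_oracle, tolerance = 1e-9)
  }
})

test_that("relabeling only permutes altloc letters", {
  toy <- clash_toy()
  rl <- monte_carlo_relabel(toy, steps = 200, trials = 2, seed = 1)
  out <- apply_relabel(toy, rl$assignment)
  expect_identical(out$atoms[, c("x", "y", "z", "occ", "b")],
                   toy$atoms[, c("x", "y", "z", "occ", "b")])
  expect_setequal(unique(out$atoms$altloc), unique(toy$atoms$altloc))
})

test_that("relabeling with no contacts leaves the score unchanged", {
  m <- toy_chain(c("ALA", "SER", "ALA"), chis = list(NULL, c(64), NULL))
  ens <- residue_ensemble(m, "A", 2)
  b <- ens$conformers[[1]]
  b$atoms[b$atoms$name == "OG", "x"] <- b$atoms[b$atoms$name == "OG", "x"] + 0.8
  ens$conformers <- list(modifyList(ens$conformers[[1]], list(occ = 0.6)),
                         modifyList(b, list(occ = 0.4)))
  m2 <- protein_model(dplyr::bind_rows(m$atoms[m$atoms$resno != 2, ],
                                       ensemble_atoms(ens)))
  rl <- monte_carlo_relabel(m2, steps = 100, trials = 2, seed = 3)
  expect_equal(rl$score, rl$initial_score)
})

test_that("duplicate conformers merge and occupancies renormalize", {
  m <- toy_chain(c("ALA", "SER", "ALA"), chis = list(NULL, c(64), NULL))
  ens <- residue_ensemble(m, "A", 2)
  a <- modifyList(ens$conformers[[1]], list(occ = 0.5, altloc = "A"))
  b <- modifyList(ens$conformers[[1]], list(occ = 0.5, altloc = "B"))
  ens$conformers <- list(a, b)
  m2 <- protein_model(dplyr::bind_rows(m$atoms[m$atoms$resno != 2, ],
                                       ensemble_atoms(ens)))
  merged <- merge_duplicate_conformers(m2, 0.15)
  e2 <- residue_ensemble(merged, "A", 2)
  expect_length(e2$conformers, 1)
  expect_equal(e2$conformers[[1]]$occ, 1.0)
  # distinct conformers (1 A apart) stay unmerged but renormalize
  b2 <- b
  b2$atoms[b2$atoms$name == "OG", "x"] <-
    b2$atoms[b2$atoms$name == "OG", "x"] + 1
  ens$conformers <- list(modifyList(a, list(occ = 0.4)),
                         modifyList(b2, list(occ = 0.4)))
  m3 <- protein_model(dplyr::bind_rows(m$atoms[m$atoms$resno != 2, ],
                                       ensemble_atoms(ens)))
  m3m <- merge_duplicate_conformers(m3, 0.1)
  e3 <- residue_ensemble(m3m, "A", 2)
  expect_length(e3$conformers, 2)
  expect_equal(sum(vapply(e3$conformers, `[[`, 0, "occ")), 1, tolerance = 1e-9)
})

test_that("merging is order-independent", {
  m <- toy_chain(c("ALA", "SER", "ALA"), chis = list(NULL, c(64), NULL))
  ens <- residue_ensemble(m, "A", 2)
  shift_og <- function(cf, dx) {
    cf$atoms[cf$atoms$name == "OG", "x"] <-
      cf$atoms[cf$atoms$name == "OG", "x"] + dx
    cf
  }
  base <- ens$conformers[[1]]
  confs <- list(modifyList(base, list(occ = 0.3)),
                modifyList(shift_og(base, 0.02), list(occ = 0.3)),
                modifyList(shift_og(base, 1.2), list(occ = 0.2)),
                modifyList(shift_og(base, 1.22), list(occ = 0.2)))
  results <- lapply(list(1:4, 4:1, c(2, 4, 1, 3), c(3, 1, 4, 2)), function(ord) {
    ens$conformers <- lapply(seq_along(ord), function(i)
      modifyList(confs[[ord[i]]], list(altloc = LETTERS[i])))
    for (i in seq_along(ens$conformers)) {
      ens$conformers[[i]]$atoms$altloc <- LETTERS[i]
    }
    mm <- protein_model(dplyr::bind_rows(m$atoms[m$atoms$resno != 2, ],
                                         ensemble_atoms(ens)))
    out <- merge_duplicate_conformers(mm, 0.15)
    e <- residue_ensemble(out, "A", 2)
    list(n = length(e$conformers),
         occ = sort(round(vapply(e$conformers, `[[`, 0, "occ"), 9)),
         x = sort(round(vapply(e$conformers, function(cf)
           atom_xyz(cf$atoms, "OG")[1], 0), 6)))
  })
  for (r in results[-1]) expect_equal(r, results[[1]])
})
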