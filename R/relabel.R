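# Model assembly bookkeeping: Lennard-Jones scored altloc relabeling
# (downhill Monte Carlo), duplicate-conformer merging, and occupancy
# renormalization. Relabeling only permutes altloc letters; coordinates,
# occupancies and B-factors are untouched.

#' Lennard-Jones parameters for the relabeling score
#'
#' @param radii named per-element van der Waals radii (Angstrom).
#' @param epsilon well depth (arbitrary units).
#' @param cutoff interaction cutoff (Angstrom).
#' @return list of class `lj_params`.
#' @export
lj_params <- function(radii = VDW_RADII, epsilon = 0.2, cutoff = 6) {
  stopifnot(all(radii > 0), cutoff >= 2 * max(radii))
  structure(list(radii = radii, epsilon = epsilon, cutoff = cutoff),
            class = "lj_params")
}

# bond graph by distance (covalent if < 1.85 A, 2.1 A when sulfur involved),
# within-conformer only; returns matrix of bonded index pairs
bond_pairs <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  out <- list()
  for (i in seq_len(n - 1)) {
    d <- sqrt(colSums((t(xyz[(i + 1):n, , drop = FALSE]) - xyz[i, ])^2))
    lim <- ifelse(toupper(atoms$element[(i + 1):n]) == "S" |
                    toupper(atoms$element[i]) == "S", 2.1, 1.85)
    compat <- atoms$altloc[(i + 1):n] == atoms$altloc[i] |
      atoms$altloc[(i + 1):n] == "" | atoms$altloc[i] == ""
    j <- which(d < lim & compat)
    if (length(j) > 0) out[[length(out) + 1]] <- cbind(i, i + j)
  }
  if (length(out) == 0) matrix(0L, 0, 2) else do.call(rbind, out)
}

# bond-separation matrix up to depth 3 (sparse: list of excluded pairs)
excluded_pairs <- function(atoms, max_sep = 3) {
  bp <- bond_pairs(atoms)
  n <- nrow(atoms)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bp))) {
    adj[[bp[r, 1]]] <- c(adj[[bp[r, 1]]], bp[r, 2])
    adj[[bp[r, 2]]] <- c(adj[[bp[r, 2]]], bp[r, 1])
  }
  excl <- new.env(hash = TRUE)
  for (i in seq_len(n)) {
    seen <- i
    frontier <- i
    for (depth in seq_len(max_sep)) {
      frontier <- setdiff(unique(unlist(adj[frontier])), seen)
      if (length(frontier) == 0) break
      seen <- c(seen, frontier)
      for (j in frontier) if (j > i) assign(paste(i, j), TRUE, envir = excl)
    }
  }
  excl
}

# precompute interacting pair table: indices, LJ energy at current geometry
lj_pair_table <- function(model, params) {
  at <- model$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(at)
  excl <- excluded_pairs(at)
  rad <- params$radii[toupper(at$element)]
  rad[is.na(rad)] <- 1.7
  pairs <- list()
  for (i in seq_len(n - 1)) {
    d <- sqrt(colSums((t(xyz[(i + 1):n, , drop = FALSE]) - xyz[i, ])^2))
    j <- which(d < params$cutoff & d > 1e-6)
    if (length(j) == 0) next
    jj <- i + j
    keep <- !vapply(jj, function(q) exists(paste(i, q), envir = excl), TRUE)
    jj <- jj[keep]; dj <- d[j][keep]
    if (length(jj) == 0) next
    rm <- rad[i] + rad[jj]
    e <- params$epsilon * ((rm / dj)^12 - 2 * (rm / dj)^6)
    pairs[[length(pairs) + 1]] <-
      data.frame(i = i, j = jj, e = e)
  }
  if (length(pairs) == 0) return(data.frame(i = integer(), j = integer(), e = numeric()))
  do.call(rbind, pairs)
}

residue_key <- function(atoms) paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")

# effective altloc labels under an assignment (list: residue key -> named
# map from original altloc letter to new letter)
effective_labels <- function(atoms, assignment) {
  lab <- atoms$altloc
  if (length(assignment) == 0) return(lab)
  key <- residue_key(atoms)
  for (k in names(assignment)) {
    sel <- key == k & lab != ""
    lab[sel] <- unname(assignment[[k]][lab[sel]])
  }
  lab
}

#' Lennard-Jones score of a label assignment
#'
#' Sum of 12-6 terms over non-bonded atom pairs (bond separation > 3) that
#' are altloc-compatible: same letter, or either atom shared (blank).
#'
#' @param model a [protein_model()].
#' @param assignment list: residue key -> named letter permutation (identity
#'   when empty or NULL).
#' @param params [lj_params()].
#' @param pair_table precomputed pair table (internal reuse).
#' @return numeric score (lower is better).
#' @export
lj_score <- function(model, assignment = list(), params = lj_params(),
                     pair_table = NULL) {
  if (is.null(pair_table)) pair_table <- lj_pair_table(model, params)
  lab <- effective_labels(model$atoms, assignment)
  li <- lab[pair_table$i]; lj <- lab[pair_table$j]
  sum(pair_table$e[li == lj | li == "" | lj == ""])
}

#' Downhill Monte-Carlo altloc relabeling
#'
#' Proposes random label swaps within random multiconformer residues and
#' accepts only strict score improvements; `steps` proposals per trial over
#' `trials` independent trials, returning the best assignment found.
#'
#' @param model a [protein_model()].
#' @param params [lj_params()].
#' @param steps proposals per trial (default 10000).
#' @param trials independent trials (default 10).
#' @param seed RNG seed.
#' @return list: `assignment`, `score`, `initial_score`, `trace` (best score
#'   per trial).
#' @export
monte_carlo_relabel <- function(model, params = lj_params(), steps = 10000,
                                trials = 10, seed = 1) {
  rt <- residue_table(model)
  multi <- rt[rt$n_conformers > 1, ]
  pair_table <- lj_pair_table(model, params)
  init <- lj_score(model, list(), params, pair_table)
  if (nrow(multi) == 0) {
    return(list(assignment = list(), score = init, initial_score = init,
                trace = rep(init, trials)))
  }
  keys <- paste(multi$chain, multi$resno, multi$icode, sep = "\r")
  letters_of <- lapply(seq_len(nrow(multi)), function(i) {
    strsplit(multi$altlocs[i], "")[[1]]
  })
  # delta scoring: a proposal only changes terms involving the proposed
  # residue, so precompute, per residue, the pair rows that touch it
  key_all <- residue_key(model$atoms)
  touch <- lapply(keys, function(k) {
    which(key_all[pair_table$i] == k | key_all[pair_table$j] == k)
  })
  score_rows <- function(rows, lab) {
    li <- lab[pair_table$i[rows]]; lj <- lab[pair_table$j[rows]]
    sum(pair_table$e[rows][li == lj | li == "" | lj == ""])
  }
  set.seed(seed)
  best <- NULL
  trace <- numeric(trials)
  for (tr in seq_len(trials)) {
    asg <- stats::setNames(lapply(letters_of, function(l) stats::setNames(l, l)), keys)
    lab <- effective_labels(model$atoms, asg)
    sc <- lj_score(model, asg, params, pair_table)
    for (s in seq_len(steps)) {
      ri <- sample.int(length(keys), 1)
      l <- letters_of[[ri]]
      if (length(l) < 2) next
      sw <- sample(seq_along(l), 2)
      prop_map <- asg[[ri]]
      tmp <- prop_map[l[sw[1]]]
      prop_map[l[sw[1]]] <- prop_map[l[sw[2]]]
      prop_map[l[sw[2]]] <- tmp
      rows <- touch[[ri]]
      sel <- key_all == keys[ri] & model$atoms$altloc != ""
      lab_new <- lab
      lab_new[sel] <- unname(prop_map[model$atoms$altloc[sel]])
      delta <- score_rows(rows, lab_new) - score_rows(rows, lab)
      if (delta < -1e-12) {
        asg[[ri]] <- prop_map
        lab <- lab_new
        sc <- sc + delta
      }
    }
    trace[tr] <- sc
    if (is.null(best) || sc < best$score) best <- list(assignment = asg, score = sc)
  }
  c(best, list(initial_score = init, trace = trace))
}

#' Apply a relabeling assignment to a model
#'
#' @param model a [protein_model()].
#' @param assignment from [monte_carlo_relabel()].
#' @return relabeled [protein_model()] (coordinates untouched).
#' @export
apply_relabel <- function(model, assignment) {
  model$atoms$altloc <- effective_labels(model$atoms, assignment)
  model
}

#' Merge indistinguishable conformers and renormalize occupancies
#'
#' Conformer pairs with all-atom RMSD below `tol` are merged
#' (single-linkage; occupancies summed, the highest-occupancy member kept)
#' and the remaining occupancies rescaled to sum to exactly 1 per residue.
#'
#' @param model a [protein_model()].
#' @param tol merge tolerance (Angstrom all-atom RMSD; default 0.15).
#' @return a [protein_model()].
#' @export
merge_duplicate_conformers <- function(model, tol = 0.15) {
  stopifnot(tol > 0)
  rt <- residue_table(model)
  out <- list()
  for (i in seq_len(nrow(rt))) {
    ens <- residue_ensemble(model, rt$chain[i], rt$resno[i], rt$icode[i])
    confs <- ens$conformers
    if (length(confs) > 1) {
      nmref <- sort(confs[[1]]$atoms$name)
      coords <- lapply(confs, function(cf) {
        at <- cf$atoms[match(nmref, cf$atoms$name), ]
        as.matrix(at[, c("x", "y", "z")])
      })
      nc <- length(confs)
      dm <- matrix(0, nc, nc)
      for (a in seq_len(nc - 1)) for (b in (a + 1):nc) {
        dm[a, b] <- dm[b, a] <- coord_rmsd(coords[[a]], coords[[b]])
      }
      grp <- stats::cutree(stats::hclust(stats::as.dist(dm), method = "single"),
                           h = tol)
      merged <- lapply(sort(unique(grp)), function(gg) {
        members <- which(grp == gg)
        occs <- vapply(confs[members], `[[`, 0, "occ")
        rep_i <- members[order(-occs, vapply(members, function(mi)
          sum(coords[[mi]]), 0))[1]]
        list(altloc = confs[[rep_i]]$altloc, occ = sum(occs),
             atoms = confs[[rep_i]]$atoms)
      })
      confs <- merged
    }
    tot <- sum(vapply(confs, `[[`, 0, "occ"))
    confs <- lapply(confs, function(cf) {
      cf$occ <- cf$occ / tot
      cf
    })
    # stable letters: decreasing occupancy, ties by prior label
    ord <- order(-vapply(confs, `[[`, 0, "occ"),
                 vapply(confs, `[[`, "", "altloc"))
    ens$conformers <- confs[ord]
    out[[i]] <- ensemble_atoms(ens)
  }
  protein_model(dplyr::bind_rows(out), model$cell)
}
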