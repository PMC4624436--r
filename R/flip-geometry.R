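# Peptide-flip geometry: canonical peptide frames, stereotyped flip-centroid
# transforms, flip detection between conformer pairs, k-means clustering of
# observed flip geometries, tight-turn detection, and glycine-enrichment
# statistics.
#
# A "peptide unit" is the five backbone heavy atoms CA1, C1, O1, N2, CA2 of
# the peptide linking residues k and k+1, stored as a 5 x 3 coordinate
# matrix with those rownames.

PEPTIDE_ATOMS <- c("CA1", "C1", "O1", "N2", "CA2")

#' Construct / validate a peptide unit
#'
#' @param coords 5 x 3 matrix with rownames CA1, C1, O1, N2, CA2.
#' @return the validated matrix (class `peptide_unit`).
#' @export
peptide_unit <- function(coords) {
  coords <- as.matrix(coords)
  if (!identical(rownames(coords), PEPTIDE_ATOMS) || ncol(coords) != 3) {
    stop("peptide unit needs a 5x3 matrix with rownames CA1, C1, O1, N2, CA2")
  }
  b_co <- vec_norm(coords["C1", ] - coords["O1", ])
  if (b_co < 1.0 || b_co > 1.5) stop("C1-O1 bond length out of range: ", signif(b_co, 3))
  for (pr in list(c("CA1", "C1"), c("N2", "CA2"))) {
    b <- vec_norm(coords[pr[1], ] - coords[pr[2], ])
    if (b < 1.2 || b > 1.8) stop(pr[1], "-", pr[2], " bond length out of range: ", signif(b, 3))
  }
  class(coords) <- c("peptide_unit", class(coords))
  coords
}

# peptide unit of the k -> k+1 peptide for one conformer trace
peptide_unit_from <- function(model, chain, resno, altloc = NULL, icode = "") {
  e1 <- residue_ensemble(model, chain, resno, icode)
  e2 <- residue_ensemble(model, chain, resno + 1)
  pick <- function(ens) {
    if (is.null(altloc)) return(ens$conformers[[1]]$atoms)
    labs <- vapply(ens$conformers, `[[`, "", "altloc")
    i <- match(altloc, labs)
    ens$conformers[[if (is.na(i)) 1 else i]]$atoms
  }
  a1 <- pick(e1); a2 <- pick(e2)
  m <- rbind(CA1 = atom_xyz(a1, "CA"), C1 = atom_xyz(a1, "C"),
             O1 = atom_xyz(a1, "O"), N2 = atom_xyz(a2, "N"),
             CA2 = atom_xyz(a2, "CA"))
  peptide_unit(m)
}

#' Local coordinate frame of a peptide unit
#'
#' x = unit(CA1 -> CA2); y = Gram-Schmidt orthogonalized unit(CA1 -> O1);
#' z = x cross y. Right-handed and orthonormal by construction.
#'
#' @param p a [peptide_unit()].
#' @return list with `origin` (CA1) and `R` (3x3 rotation, columns x,y,z).
#' @export
peptide_frame <- function(p) {
  x <- p["CA2", ] - p["CA1", ]
  o <- p["CA1", ]
  v <- p["O1", ] - p["CA1", ]
  xu <- vec_unit(x)
  y <- v - sum(v * xu) * xu
  if (vec_norm(y) < 1e-6) stop("degenerate peptide frame: O1 collinear with CA1->CA2")
  yu <- vec_unit(y)
  list(origin = o, R = cbind(xu, yu, vec_cross(xu, yu), deparse.level = 0))
}

# express a unit in a frame (frame coords), and back
to_frame <- function(coords, frame) {
  out <- sweep(as.matrix(coords), 2, frame$origin) %*% frame$R
  rownames(out) <- rownames(coords)
  out
}
from_frame <- function(coords, frame) {
  out <- sweep(as.matrix(coords) %*% t(frame$R), 2, frame$origin, `+`)
  rownames(out) <- rownames(coords)
  out
}

#' Ideal reference peptide in its canonical frame
#'
#' @return a [peptide_unit()] with CA1 at the origin and frame = identity.
#' @export
reference_peptide <- function() {
  m <- build_chain(c("GLY", "GLY"), phi = c(NA, -85), psi = c(130, NA))
  a1 <- m$atoms[m$atoms$resno == 1, ]
  a2 <- m$atoms[m$atoms$resno == 2, ]
  p <- peptide_unit(rbind(CA1 = atom_xyz(a1, "CA"), C1 = atom_xyz(a1, "C"),
                          O1 = atom_xyz(a1, "O"), N2 = atom_xyz(a2, "N"),
                          CA2 = atom_xyz(a2, "CA")))
  fr <- peptide_frame(p)
  peptide_unit(to_frame(p, fr))
}

#' Construct the four synthetic flip-cluster centroid geometries
#'
#' The four stereotyped flip geometries ("tweaked_down", "simple_down",
#' "left", "right") are generated from the ideal reference peptide: the
#' flanking CA atoms are translated in the peptide plane (first CA "down",
#' second CA "up", all displacements > 0.2 A) and the C1/O1/N2 cluster is
#' rigidly rotated about the new CA-CA axis by the cluster's nominal
#' rotation (~180, ~180, +120, -120 degrees). These are synthetic stand-ins
#' constructed to satisfy the published geometric properties of the
#' empirically clustered centroids.
#'
#' @return list of four `flip_cluster` objects: `name`, `rotation_class`,
#'   `coords` (5x3, reference frame), `reference` (the reference peptide).
#' @export
synthetic_flip_centroids <- function() {
  ref <- reference_peptide()
  specs <- list(
    tweaked_down = list(theta = 178, s1 = c(0.15, -0.9, 0), s2 = c(-0.15, 0.45, 0)),
    simple_down  = list(theta = 180, s1 = c(0.00, -0.28, 0), s2 = c(0.00, 0.28, 0)),
    left         = list(theta = 120, s1 = c(0.00, -0.25, 0), s2 = c(0.00, 0.25, 0)),
    right        = list(theta = -120, s1 = c(0.00, -0.25, 0), s2 = c(0.00, 0.25, 0))
  )
  lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    ca1 <- ref["CA1", ] + sp$s1
    ca2 <- ref["CA2", ] + sp$s2
    u_old <- vec_unit(ref["CA2", ] - ref["CA1", ])
    u_new <- vec_unit(ca2 - ca1)
    # align old axis onto new axis, then rotate about the new axis
    axis <- vec_cross(u_old, u_new)
    R_align <- if (vec_norm(axis) < 1e-9) diag(3) else {
      rotation_matrix_axis(axis, rad2deg(atan2(vec_norm(axis), sum(u_old * u_new))))
    }
    R_th <- rotation_matrix_axis(u_new, sp$theta)
    mv <- function(base_new, base_old, atom) {
      base_new + as.numeric(R_th %*% R_align %*% (ref[atom, ] - base_old))
    }
    co <- rbind(CA1 = ca1,
                C1 = mv(ca1, ref["CA1", ], "C1"),
                O1 = NA, N2 = mv(ca2, ref["CA2", ], "N2"), CA2 = ca2)
    co["O1", ] <- co["C1", ] + as.numeric(R_th %*% R_align %*% (ref["O1", ] - ref["C1", ]))
    structure(list(name = nm, rotation_class = sp$theta,
                   coords = peptide_unit(co), reference = ref),
              class = "flip_cluster")
  })
}

#' Load flip-cluster centroid geometries from a text file
#'
#' @param path centroid file; defaults to the synthetic centroid fixture
#'   shipped with the package. Format: `cluster <name> <rotation_class>`
#'   header lines each followed by five `atom x y z` lines (reference-frame
#'   coordinates), plus one `cluster reference 0` block.
#' @return list of four `flip_cluster` objects.
#' @export
load_flip_centroids <- function(path = system.file("extdata", "flip_centroids_synthetic.txt",
                                                   package = "altconf")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  blocks <- list()
  i <- 1
  while (i <= length(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (f[1] != "cluster") stop("expected 'cluster' header at centroid file line ", i)
    nm <- f[2]; rot <- as.numeric(f[3])
    co <- matrix(NA_real_, 5, 3, dimnames = list(PEPTIDE_ATOMS, NULL))
    for (j in 1:5) {
      g <- strsplit(trimws(lines[i + j]), "\\s+")[[1]]
      if (!g[1] %in% PEPTIDE_ATOMS) stop("unexpected atom '", g[1], "' in centroid file")
      co[g[1], ] <- as.numeric(g[2:4])
    }
    if (anyNA(co)) stop("incomplete atom set for cluster ", nm)
    blocks[[nm]] <- list(rot = rot, coords = co)
    i <- i + 6
  }
  if (!"reference" %in% names(blocks)) stop("centroid file lacks the reference block")
  ref <- peptide_unit(blocks$reference$coords)
  blocks$reference <- NULL
  if (length(blocks) != 4) stop("expected exactly 4 centroid clusters, got ", length(blocks))
  lapply(names(blocks), function(nm) {
    structure(list(name = nm, rotation_class = blocks[[nm]]$rot,
                   coords = peptide_unit(blocks[[nm]]$coords), reference = ref),
              class = "flip_cluster")
  })
}

#' Map a flip-cluster centroid onto a target peptide
#'
#' The centroid geometry (stored in the reference frame) is carried into the
#' target peptide's local frame by a rigid homogeneous transform, yielding a
#' candidate flipped conformation of that peptide.
#'
#' @param p target [peptide_unit()].
#' @param cluster a `flip_cluster`.
#' @return a [peptide_unit()] with the centroid geometry in p's frame.
#' @export
apply_flip_centroid <- function(p, cluster) {
  fr <- peptide_frame(p)
  peptide_unit(from_frame(cluster$coords, fr))
}

#' Detect a peptide flip between two conformations of the same peptide
#'
#' A flip requires (i) the carbonyl C-O bonds to point away from each other
#' (O-O distance > C-C distance + 1 A), (ii) a rotation of at least 90
#' degrees of O1 about the CA-CA axis, and (iii) both flanking CA atoms to
#' reconverge to < 1.5 A.
#'
#' @param conf_a,conf_b [peptide_unit()]s of the two conformations.
#' @return list with `is_flip`, `rotation` (signed degrees), and `reason`.
#' @export
detect_flip <- function(conf_a, conf_b) {
  oo <- vec_norm(conf_a["O1", ] - conf_b["O1", ])
  cc <- vec_norm(conf_a["C1", ] - conf_b["C1", ])
  ca1 <- vec_norm(conf_a["CA1", ] - conf_b["CA1", ])
  ca2 <- vec_norm(conf_a["CA2", ] - conf_b["CA2", ])
  # rotation of O1 about the CA-CA axis, after aligning flanking CA midpoints
  mid_a <- (conf_a["CA1", ] + conf_a["CA2", ]) / 2
  mid_b <- (conf_b["CA1", ] + conf_b["CA2", ]) / 2
  ax_a <- conf_a["CA2", ] - conf_a["CA1", ]
  ax_b <- conf_b["CA2", ] - conf_b["CA1", ]
  axs <- ax_a / vec_norm(ax_a) + ax_b / vec_norm(ax_b)
  rotation <- 0
  reason <- ""
  if (vec_norm(axs) < 1e-9) {
    reason <- "degenerate axis"
  } else {
    u <- vec_unit(axs)
    va <- conf_a["O1", ] - mid_a; va <- va - sum(va * u) * u
    vb <- conf_b["O1", ] - mid_b; vb <- vb - sum(vb * u) * u
    if (vec_norm(va) < 1e-9 || vec_norm(vb) < 1e-9) {
      reason <- "O1 on axis"
    } else {
      rotation <- rad2deg(atan2(sum(vec_cross(va, vb) * u), sum(va * vb)))
    }
  }
  ok <- reason == "" & oo > cc + 1 & abs(rotation) >= 90 & ca1 < 1.5 & ca2 < 1.5
  if (reason == "" && !ok) {
    reason <- if (oo <= cc + 1) "carbonyls not anti" else if (abs(rotation) < 90)
      "rotation below 90 degrees" else "flanking CA diverged"
  }
  list(is_flip = ok, rotation = rotation, reason = reason)
}

#' k-means clustering of superposed peptide-flip geometries
#'
#' Lloyd's algorithm under the 5-atom RMSD metric (Euclidean distance on the
#' flattened 15-dimensional coordinates divided by sqrt(5)); centroids are
#' coordinate-wise means. Multiple random restarts are run and the solution
#' with the lowest inertia (sum of squared distances) is kept.
#'
#' @param observations n x 15 matrix (or list of 5x3 matrices) of flip
#'   geometries already superposed into a common frame.
#' @param k number of clusters.
#' @param nstart random restarts (default 25).
#' @param max_iter Lloyd iteration cap per restart.
#' @param seed RNG seed for the restarts.
#' @return list with `centroids` (k x 15), `assignment`, `inertia`,
#'   `inertia_trace` (per-iteration, best restart) and `size`.
#' @export
cluster_flips <- function(observations, k, nstart = 25, max_iter = 100, seed = 1) {
  if (is.list(observations)) {
    observations <- do.call(rbind, lapply(observations, function(m) as.numeric(t(m))))
  }
  X <- as.matrix(observations)
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of observations")
  set.seed(seed)
  best <- NULL
  for (s in seq_len(nstart)) {
    ctr <- X[sample.int(n, k), , drop = FALSE]
    assign_prev <- rep(0L, n)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(ctr) +
        outer(rep(1, n), rowSums(ctr^2))
      asg <- max.col(-d2)
      inertia <- sum(d2[cbind(seq_len(n), asg)]) / 5  # RMSD^2 units
      trace <- c(trace, inertia)
      for (j in seq_len(k)) {
        if (any(asg == j)) ctr[j, ] <- colMeans(X[asg == j, , drop = FALSE])
      }
      if (identical(asg, assign_prev)) break
      assign_prev <- asg
    }
    d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(ctr) +
      outer(rep(1, n), rowSums(ctr^2))
    asg <- max.col(-d2)
    inertia <- sum(pmax(d2[cbind(seq_len(n), asg)], 0)) / 5
    if (is.null(best) || inertia < best$inertia - 1e-12) {
      best <- list(centroids = ctr, assignment = asg, inertia = inertia,
                   inertia_trace = trace,
                   size = tabulate(asg, k))
    }
  }
  best
}

#' Tight-turn test for the peptide at residue i
#'
#' A peptide i -> i+1 sits in a tight turn when the i-1 carbonyl oxygen
#' accepts a mainchain hydrogen bond from the i+2 amide nitrogen: O...N
#' distance <= `dist_max` and C=O...N angle >= `angle_min` (hydrogens
#' implicit).
#'
#' @param model a [protein_model()].
#' @param chain,resno identify residue i (the first residue of the peptide).
#' @param dist_max,angle_min geometric hydrogen-bond criteria.
#' @return TRUE/FALSE (FALSE with attribute `reason` at chain termini).
#' @export
is_tight_turn <- function(model, chain, resno, dist_max = 3.5, angle_min = 90) {
  rt <- residue_table(model)
  has <- function(rn) any(rt$chain == chain & rt$resno == rn)
  if (!has(resno - 1) || !has(resno + 2)) {
    return(structure(FALSE, reason = "chain terminus"))
  }
  prev <- residue_ensemble(model, chain, resno - 1)$conformers[[1]]$atoms
  nxt <- residue_ensemble(model, chain, resno + 2)$conformers[[1]]$atoms
  O <- atom_xyz(prev, "O"); C <- atom_xyz(prev, "C"); N <- atom_xyz(nxt, "N")
  if (is.null(O) || is.null(C) || is.null(N)) return(structure(FALSE, reason = "missing atoms"))
  d <- vec_norm(N - O)
  ang <- angle_3pt(C, O, N)
  isTRUE(d <= dist_max && ang >= angle_min)
}

#' One-tailed glycine enrichment p-value (hypergeometric)
#'
#' Exact upper-tail probability of observing at least `hits` glycines among
#' `total` draws from a background of `bg_hits` glycines out of `bg_total`
#' residues (Fisher's exact test, enrichment tail).
#'
#' @param hits,total observed glycine count and sample size.
#' @param bg_hits,bg_total background glycine count and population size.
#' @return p-value.
#' @export
glycine_enrichment <- function(hits, total, bg_hits, bg_total) {
  if (any(c(hits, total, bg_hits, bg_total) < 0)) stop("counts must be non-negative")
  if (hits > total || bg_hits > bg_total) stop("hits cannot exceed totals")
  stats::phyper(hits - 1, bg_hits, bg_total - bg_hits, total, lower.tail = FALSE)
}

#' Training-set flip counts and glycine background
#'
#' The per-cluster composition of the curated flip training set (79
#' examples over four geometry clusters) and the background residue
#' composition for enrichment testing, as shipped with the package.
#'
#' @param path tab-separated counts file (defaults to the shipped table).
#' @return list: `counts` (tibble: cluster, n_examples, n_tight_turn,
#'   n_gly_first, n_gly_second) and `background` (named vector with
#'   `glycines` and `residues`).
#' @export
flip_training_counts <- function(path = system.file("extdata", "flip_training_counts.tsv",
                                                    package = "altconf")) {
  raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           col.names = c("cluster", "n_examples", "n_tight_turn",
                                         "n_gly_first", "n_gly_second"))
  bg <- raw[raw$cluster == "background", ]
  counts <- tibble::as_tibble(raw[raw$cluster != "background", ])
  list(counts = counts,
       background = c(glycines = bg$n_gly_second, residues = bg$n_examples))
}

#' Mine flip observations from multiconformer models
#'
#' Scans every chain for consecutive residue pairs where both residues carry
#' two alternate conformations, applies the flip criteria to the two peptide
#' units, and tabulates the geometry and context of each accepted flip.
#' Pairs with more than two peptide conformations or a cis peptide in either
#' state are excluded; candidates that fail only the geometric criteria are
#' reported with `is_flip = FALSE`.
#'
#' @param models named list of [protein_model()]s (names = structure ids).
#' @return tibble of flip observations: structure, chain, resno, rotation,
#'   flags, and the B-conformer coordinates superposed into the reference
#'   frame (columns `coord_1`..`coord_15`) for clustering.
#' @export
mine_flips <- function(models) {
  if (inherits(models, "protein_model")) models <- list(model = models)
  ref <- reference_peptide()
  rows <- list()
  for (sid in names(models)) {
    model <- models[[sid]]
    rt <- residue_table(model)
    for (ch in unique(rt$chain)) {
      sub <- rt[rt$chain == ch, ]
      for (i in seq_len(nrow(sub) - 1)) {
        if (sub$resno[i + 1] != sub$resno[i] + 1) next
        if (sub$n_conformers[i] < 2 || sub$n_conformers[i + 1] < 2) next
        if (sub$n_conformers[i] > 2 || sub$n_conformers[i + 1] > 2) next  # >2 alt peptides excluded
        pa <- try(peptide_unit_from(model, ch, sub$resno[i], altloc = "A"), silent = TRUE)
        pb <- try(peptide_unit_from(model, ch, sub$resno[i], altloc = "B"), silent = TRUE)
        if (inherits(pa, "try-error") || inherits(pb, "try-error")) next
        # exclude cis peptides (omega far from 180) in either state
        omega_of <- function(p) abs(dihedral_angle(p["CA1", ], p["C1", ], p["N2", ], p["CA2", ]))
        if (omega_of(pa) < 150 || omega_of(pb) < 150) next
        det <- detect_flip(pa, pb)
        fr <- peptide_frame(pa)
        bset <- to_frame(pb, fr)
        rows[[length(rows) + 1]] <- tibble::tibble(
          structure = sid, chain = ch, resno = sub$resno[i],
          resid1 = sub$resid[i], resid2 = sub$resid[i + 1],
          rotation = det$rotation, is_flip = det$is_flip,
          in_turn = as.logical(is_tight_turn(model, ch, sub$resno[i])),
          gly_first = sub$resid[i] == "GLY",
          gly_second = sub$resid[i + 1] == "GLY",
          !!!stats::setNames(as.list(as.numeric(t(bset))), paste0("coord_", 1:15)))
      }
    }
  }
  if (length(rows) == 0) return(tibble::tibble())
  dplyr::bind_rows(rows)
}
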