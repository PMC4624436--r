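# Pipeline orchestration: per-residue fitting (background subtraction,
# backbone enumeration, sidechain decoration, QP -> MIQP selection),
# fragment synchronization, relabeling, merging, and truth evaluation.

#' Pipeline configuration
#'
#' @param resolution map resolution d (Angstrom).
#' @param mc_ampl mainchain amplitude for this run (one of the typical sweep
#'   values 0.1 / 0.2 / 0.3).
#' @param t occupancy threshold; NULL uses [threshold_for_resolution()].
#' @param seed master seed; every stochastic stage derives a deterministic
#'   per-residue sub-seed from it, so results are independent of worker
#'   count.
#' @param flips enable peptide-flip sampling.
#' @param jitter displacement jitter fraction.
#' @param workers parallel workers for per-residue fitting.
#' @param relabel_steps,relabel_trials Monte-Carlo relabeling schedule.
#' @param merge_tol duplicate-conformer merge tolerance (Angstrom).
#' @param residues optional residue numbers to fit (NULL = all standard
#'   amino acids).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(resolution, mc_ampl = 0.2, t = NULL, seed = 1,
                            flips = TRUE, jitter = 0.05, workers = 1,
                            relabel_steps = 10000, relabel_trials = 10,
                            merge_tol = 0.15, residues = NULL) {
  stopifnot(resolution > 0, mc_ampl > 0)
  if (is.null(t)) t <- threshold_for_resolution(resolution)
  structure(list(resolution = resolution, mc_ampl = mc_ampl, t = t,
                 seed = seed, flips = flips, jitter = jitter,
                 workers = workers, relabel_steps = relabel_steps,
                 relabel_trials = relabel_trials, merge_tol = merge_tol,
                 residues = residues), class = "pipeline_config")
}

# rows of model$atoms rebuilt when fitting residue k: the residue's
# sidechain (CB and beyond), its carbonyl C and O, and the next residue's
# amide N (flip-affected peptide atoms)
rebuild_selection <- function(model, chain, k) {
  a <- model$atoms
  which((a$chain == chain & a$resno == k & !(a$name %in% c("N", "CA"))) |
          (a$chain == chain & a$resno == k + 1 & a$name == "N"))
}

# the corresponding atoms of a candidate fragment
candidate_rebuilt_atoms <- function(cand) {
  k <- cand$provenance$center
  at <- cand$atoms
  at[(at$resno == k & !(at$name %in% c("N", "CA"))) |
       (at$resno == k + 1 & at$name == "N"), ]
}

#' Fit alternate conformations for one residue
#'
#' Builds the background-subtracted fitting target, enumerates backbone
#' candidates (ellipsoid displacements x peptide flips, closed by nullspace
#' IK), decorates them with rotamer-library sidechains (hierarchically for
#' large residues), and selects occupancies by QP followed by exact MIQP.
#'
#' @param model single-conformer [protein_model()].
#' @param obs observed [density_map()] (already scaled to the model).
#' @param chain,k residue to fit.
#' @param cfg [pipeline_config()].
#' @param centroids flip centroids ([load_flip_centroids()]).
#' @param library rotamer library ([load_rotamer_library()]).
#' @param ss secondary-structure table ([assign_secondary_structure()]);
#'   computed when NULL.
#' @return list: `ensemble` ([residue_ensemble()]), `solution`
#'   (`occupancy_solution` or NULL), `n_candidates`, `flip` (TRUE when a
#'   selected conformer pair is related by a peptide flip), `degraded`.
#' @export
fit_residue <- function(model, obs, chain, k, cfg,
                        centroids = load_flip_centroids(),
                        library = load_rotamer_library(), ss = NULL) {
  d <- cfg$resolution
  ens_in <- residue_ensemble(model, chain, k)
  fallback <- function(reason) {
    ens_in$conformers[[1]]$occ <- 1
    list(ensemble = ens_in, solution = NULL, n_candidates = 0L,
         flip = FALSE, degraded = TRUE, reason = reason)
  }
  resid_k <- ens_in$resid
  if (!resid_k %in% AA3) return(fallback("nonstandard residue"))
  sel <- rebuild_selection(model, chain, k)
  if (length(sel) == 0) return(fallback("empty rebuild selection"))
  residual <- background_subtract(obs, model, sel, d)
  guide_nm <- guide_atom_name(resid_k)
  gpos <- atom_xyz(ens_in$conformers[[1]]$atoms, guide_nm)
  if (is.null(gpos)) gpos <- atom_xyz(ens_in$conformers[[1]]$atoms, "O")
  tensor <- suppressWarnings(
    density_moment_tensor(residual, gpos, mask_radius(d) + 0.7))
  if (is.null(ss)) ss <- assign_secondary_structure(model)
  ss_k <- ss$ss[ss$chain == chain & ss$resno == k]
  flips_allowed <- cfg$flips && length(ss_k) == 1 && ss_k == "C"
  frag <- extract_fragment(model, chain, k)
  scfg <- sampler_config(mc_ampl = cfg$mc_ampl, jitter = cfg$jitter,
                         flips = cfg$flips, seed = cfg$seed)
  set.seed((cfg$seed * 7919L + k) %% .Machine$integer.max)
  bb <- enumerate_backbones(frag, flips_allowed, tensor, scfg, centroids)
  if (length(bb) == 0) return(fallback("no backbone candidates"))
  t <- cfg$t
  cands <- if (resid_k %in% SMALL_SIDECHAINS) {
    decorate_small_sidechain(bb, resid_k, library, k)
  } else if (resid_k %in% LARGE_SIDECHAINS) {
    decorate_large_sidechain(bb, resid_k, library, k,
                             select_fn = make_density_select_fn(residual, d, t))
  } else {
    bb
  }
  if (length(cands) == 0) return(fallback("no candidates"))
  rebuilt <- lapply(cands, candidate_rebuilt_atoms)
  prob <- tryCatch(build_problem(residual, rebuilt, d, t), error = function(e) NULL)
  if (is.null(prob)) return(fallback("empty fitting mask"))
  sol <- tryCatch(miqp_select(prob, qp_fit(prob)), error = function(e) NULL)
  if (is.null(sol) || sum(sol$weights) <= 0) return(fallback("selection failed"))
  keep <- which(sol$weights > 0)
  keep <- keep[order(-sol$weights[keep])]
  confs <- lapply(seq_along(keep), function(j) {
    ci <- keep[j]
    at <- cands[[ci]]$atoms
    at <- at[at$resno == k, ]
    at$altloc <- if (length(keep) == 1) "" else LETTERS[j]
    at$occ <- sol$weights[ci]
    list(altloc = at$altloc[1], occ = sol$weights[ci], atoms = at,
         provenance = cands[[ci]]$provenance)
  })
  ens <- ens_in
  ens$conformers <- confs
  flip <- FALSE
  if (length(confs) > 1) {
    units <- lapply(confs, function(cf) conformer_peptide_unit(model, chain, k, cf$atoms))
    for (a in seq_len(length(units) - 1)) for (b in (a + 1):length(units)) {
      if (!is.null(units[[a]]) && !is.null(units[[b]]) &&
          detect_flip(units[[a]], units[[b]])$is_flip) flip <- TRUE
    }
  }
  list(ensemble = ens, solution = sol, n_candidates = length(cands),
       flip = flip, degraded = FALSE, reason = "")
}

# peptide unit k -> k+1 with residue k's atoms taken from `atoms` and
# residue k+1 from the (single-conformer) model; NULL at the terminus
conformer_peptide_unit <- function(model, chain, k, atoms) {
  rt <- residue_table(model)
  if (!any(rt$chain == chain & rt$resno == k + 1)) return(NULL)
  nxt <- residue_ensemble(model, chain, k + 1)$conformers[[1]]$atoms
  m <- rbind(CA1 = atom_xyz(atoms, "CA"), C1 = atom_xyz(atoms, "C"),
             O1 = atom_xyz(atoms, "O"), N2 = atom_xyz(nxt, "N"),
             CA2 = atom_xyz(nxt, "CA"))
  if (any(vapply(seq_len(5), function(i) is.null(m[i, ]) || anyNA(m[i, ]), TRUE))) {
    return(NULL)
  }
  tryCatch(peptide_unit(m), error = function(e) NULL)
}

# do two conformers differ in backbone position?
backbone_differs <- function(c1, c2, tol = 0.05) {
  for (nm in BACKBONE_ATOMS) {
    p1 <- atom_xyz(c1$atoms, nm); p2 <- atom_xyz(c2$atoms, nm)
    if (!is.null(p1) && !is.null(p2) && vec_norm(p1 - p2) > tol) return(TRUE)
  }
  FALSE
}

#' Run the full multiconformer fitting pipeline
#'
#' Fits every residue, synchronizes fragments of consecutive backbone
#' multiconformers with a second MIQP, relabels altlocs by downhill Monte
#' Carlo on a Lennard-Jones score, merges indistinguishable conformers, and
#' renormalizes occupancies.
#'
#' @param model input [protein_model()] (multiconformer input is collapsed
#'   to its highest-occupancy conformer first).
#' @param obs observed [density_map()].
#' @param cfg [pipeline_config()].
#' @param scale_obs least-squares scale the observed map to the model's
#'   calculated density first.
#' @return list: `model` (final multiconformer [protein_model()]), `report`
#'   (per-residue tibble), `relabel` (score trace), `fragments` (residue
#'   runs synchronized).
#' @export
run_pipeline <- function(model, obs, cfg, scale_obs = TRUE) {
  centroids <- load_flip_centroids()
  library <- load_rotamer_library()
  model <- suppressWarnings(collapse_to_major(model))
  d <- cfg$resolution
  if (scale_obs) {
    calc <- calc_density(model$atoms, grid = obs, resolution = d)
    msk <- voxel_mask(obs, as.matrix(model$atoms[, c("x", "y", "z")]), mask_radius(d))
    obs <- scale_obs_to_calc(obs, calc, msk)
  }
  ss <- assign_secondary_structure(model)
  rt <- residue_table(model)
  todo <- rt[rt$resid %in% AA3, ]
  if (!is.null(cfg$residues)) todo <- todo[todo$resno %in% cfg$residues, ]
  fit_one <- function(i) {
    fit_residue(model, obs, todo$chain[i], todo$resno[i], cfg,
                centroids = centroids, library = library, ss = ss)
  }
  fits <- if (cfg$workers > 1) {
    parallel::mclapply(seq_len(nrow(todo)), fit_one, mc.cores = cfg$workers)
  } else {
    lapply(seq_len(nrow(todo)), fit_one)
  }
  names(fits) <- paste(todo$chain, todo$resno)
  # fragment synchronization: maximal runs of consecutive residues with
  # multiple backbone conformations
  multi_bb <- vapply(fits, function(f) {
    cf <- f$ensemble$conformers
    length(cf) > 1 && any(vapply(seq_len(length(cf) - 1), function(a)
      backbone_differs(cf[[a]], cf[[a + 1]]), TRUE))
  }, TRUE)
  fragments <- list()
  i <- 1
  while (i <= nrow(todo)) {
    if (multi_bb[i]) {
      j <- i
      while (j < nrow(todo) && multi_bb[j + 1] &&
             todo$chain[j + 1] == todo$chain[j] &&
             todo$resno[j + 1] == todo$resno[j] + 1) j <- j + 1
      fragments[[length(fragments) + 1]] <- i:j
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  frag_multi <- Filter(function(ix) length(ix) > 1, fragments)
  for (ix in frag_multi) {
    sets <- lapply(ix, function(q) {
      lapply(fits[[q]]$ensemble$conformers, function(cf) {
        at <- cf$atoms
        at$occ <- 1  # candidate densities are unit-occupancy; w carries the scale
        prov <- list(center = todo$resno[q])
        candidate_rebuilt_atoms(list(atoms = at, provenance = prov))
      })
    })
    sel_rows <- unlist(lapply(ix, function(q)
      rebuild_selection(model, todo$chain[q], todo$resno[q])))
    residual <- background_subtract(obs, model, unique(sel_rows), d)
    fsol <- tryCatch(fragment_select(sets, residual, d, cfg$t),
                     error = function(e) NULL)
    if (is.null(fsol) || nrow(fsol$combos) == 0) next
    for (ii in seq_along(ix)) {
      q <- ix[ii]
      confs <- lapply(seq_len(nrow(fsol$combos)), function(j) {
        src <- fits[[q]]$ensemble$conformers[[fsol$combos[j, ii]]]
        src$occ <- fsol$weights[j]
        src$altloc <- if (nrow(fsol$combos) == 1) "" else LETTERS[j]
        src$atoms$altloc <- src$altloc
        src$atoms$occ <- src$occ
        src
      })
      fits[[q]]$ensemble$conformers <- confs
      fits[[q]]$fragment_synced <- TRUE
    }
  }
  # assemble intermediate model
  parts <- list()
  for (i in seq_len(nrow(rt))) {
    key <- paste(rt$chain[i], rt$resno[i])
    if (key %in% names(fits)) {
      parts[[i]] <- ensemble_atoms(fits[[key]]$ensemble)
    } else {
      ens <- residue_ensemble(model, rt$chain[i], rt$resno[i], rt$icode[i])
      parts[[i]] <- ensemble_atoms(ens)
    }
  }
  inter <- protein_model(dplyr::bind_rows(parts), model$cell)
  inter <- merge_duplicate_conformers(inter, cfg$merge_tol)
  rl <- monte_carlo_relabel(inter, steps = cfg$relabel_steps,
                            trials = cfg$relabel_trials, seed = cfg$seed)
  final <- apply_relabel(inter, rl$assignment)
  report <- dplyr::bind_rows(lapply(seq_len(nrow(todo)), function(i) {
    f <- fits[[i]]
    tibble::tibble(
      chain = todo$chain[i], resno = todo$resno[i], resid = todo$resid[i],
      n_conformers = length(f$ensemble$conformers),
      occupancies = paste(sprintf("%.3f", vapply(f$ensemble$conformers, `[[`, 0, "occ")),
                          collapse = "/"),
      flip = f$flip, n_candidates = f$n_candidates,
      objective = if (is.null(f$solution)) NA_real_ else f$solution$objective,
      degraded = f$degraded, reason = f$reason)
  }))
  list(model = final, report = report, relabel = rl,
       fragments = lapply(frag_multi, function(ix) todo$resno[ix]))
}

#' Save pipeline results (multiconformer PDB + JSON report)
#'
#' @param result list returned by [run_pipeline()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly the paths written.
#' @export
save_results <- function(result, dir, prefix = "altconf") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pdb <- file.path(dir, paste0(prefix, "_multiconformer.pdb"))
  js <- file.path(dir, paste0(prefix, "_report.json"))
  write_pdb(result$model, pdb)
  payload <- list(residues = result$report,
                  fragments = result$fragments,
                  relabel_score = result$relabel$score,
                  relabel_trace = result$relabel$trace)
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(pdb = pdb, json = js))
}

#' Compare a fitted multiconformer model against the generating truth
#'
#' Flip true positives: percent of true-flip peptides also flipped in the
#' fitted model. Flip false positives: percent of fitted-flip peptides with
#' no flip in the truth (also reported per evaluated residue). Rotamer
#' false positives: percent of fitted sidechain rotamers (nearest library
#' rotamer by chi angles) absent from the truth rotamer set at that
#' residue.
#'
#' @param fitted,truth [protein_model()]s over the same residues.
#' @param library rotamer library for rotamer assignment.
#' @param residues optional residue-number subset to evaluate.
#' @return one-row tibble of metrics plus per-residue detail in the
#'   `detail` attribute.
#' @export
evaluate_against_truth <- function(fitted, truth,
                                   library = load_rotamer_library(),
                                   residues = NULL) {
  rt_f <- residue_table(fitted)
  rt_t <- residue_table(truth)
  if (!identical(rt_f[, c("chain", "resno", "resid")],
                 rt_t[, c("chain", "resno", "resid")])) {
    stop("fitted and truth models cover different residues")
  }
  rt <- rt_f
  if (!is.null(residues)) rt <- rt[rt$resno %in% residues, ]
  flip_at <- function(model, chain, k) {
    rtm <- residue_table(model)
    if (!any(rtm$chain == chain & rtm$resno == k + 1)) return(FALSE)
    ens <- residue_ensemble(model, chain, k)
    if (length(ens$conformers) < 2) return(FALSE)
    units <- lapply(ens$conformers, function(cf)
      conformer_peptide_unit(model, chain, k, cf$atoms))
    for (a in seq_len(length(units) - 1)) for (b in (a + 1):length(units)) {
      if (!is.null(units[[a]]) && !is.null(units[[b]]) &&
          detect_flip(units[[a]], units[[b]])$is_flip) return(TRUE)
    }
    FALSE
  }
  rot_label <- function(chi, resid) {
    rots <- rotamers_for(library, resid)
    if (length(rots) == 0 || length(chi) == 0 || anyNA(chi)) return(NA_character_)
    dists <- vapply(rots, function(r) {
      dd <- abs((chi - r$chi + 180) %% 360 - 180)
      sqrt(mean(dd^2))
    }, 0)
    rots[[which.min(dists)]]$rotamer
  }
  detail <- dplyr::bind_rows(lapply(seq_len(nrow(rt)), function(i) {
    ch <- rt$chain[i]; k <- rt$resno[i]; rs <- rt$resid[i]
    tf <- flip_at(truth, ch, k)
    ff <- flip_at(fitted, ch, k)
    rot_f <- rot_t <- character(0)
    if (chi_count(rs) > 0) {
      rot_f <- unique(stats::na.omit(vapply(residue_ensemble(fitted, ch, k)$conformers,
                                            function(cf) rot_label(measure_chi(cf$atoms, rs), rs), "")))
      rot_t <- unique(stats::na.omit(vapply(residue_ensemble(truth, ch, k)$conformers,
                                            function(cf) rot_label(measure_chi(cf$atoms, rs), rs), "")))
    }
    tibble::tibble(chain = ch, resno = k, resid = rs,
                   truth_flip = tf, fitted_flip = ff,
                   n_rot_fitted = length(rot_f),
                   n_rot_fp = sum(!(rot_f %in% rot_t)))
  }))
  n_truth <- sum(detail$truth_flip)
  n_fit <- sum(detail$fitted_flip)
  tp <- sum(detail$truth_flip & detail$fitted_flip)
  fp <- sum(detail$fitted_flip & !detail$truth_flip)
  out <- tibble::tibble(
    flip_tp_pct = if (n_truth > 0) 100 * tp / n_truth else NA_real_,
    flip_fp_pct = if (n_fit > 0) 100 * fp / n_fit else 0,
    flip_fp_per_residue_pct = 100 * fp / nrow(detail),
    rotamer_fp_pct = if (sum(detail$n_rot_fitted) > 0)
      100 * sum(detail$n_rot_fp) / sum(detail$n_rot_fitted) else 0,
    n_residues = nrow(detail))
  attr(out, "detail") <- detail
  out
}
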