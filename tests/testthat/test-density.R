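# Density synthesis, scaling, masking, map I/O, synthetic datasets.

test_that("mask radius follows the piecewise resolution formula", {
  expect_equal(mask_radius(1.5), 1.0)
  expect_equal(mask_radius(3.0), 1.5)
  expect_equal(mask_radius(4.0), 2.0)
  expect_error(mask_radius(0), "positive")
  d <- seq(0.5, 6, by = 0.05)
  r <- mask_radius(d)
  expect_true(all(diff(r) >= -1e-12))            # non-decreasing
  expect_lt(abs(mask_radius(3 - 1e-9) - mask_radius(3 + 1e-9)), 1e-6)  # continuous
})

test_that("atomic density integrates to the electron count and is linear", {
  at <- tibble::tibble(chain = "A", resno = 1L, icode = "", resid = "ALA",
                       name = "C", element = "C", altloc = "",
                       x = 0, y = 0, z = 0, occ = 1, b = 15)
  g <- grid_for_atoms(at, 1.0, spacing = 0.25, margin = 6)
  dm <- calc_density(at, g, cutoff = 6)
  integral <- sum(dm$values) * prod(dm$spacing)
  expect_equal(integral, 6, tolerance = 0.02)    # carbon: 6 electrons
  half <- at; half$occ <- 0.5
  expect_equal(calc_density(half, g, cutoff = 6)$values * 2, dm$values)
  zero <- at; zero$occ <- 0
  expect_true(all(calc_density(zero, g)$values == 0))
  # additive over atoms
  two <- dplyr::bind_rows(at, within(at, x <- 2))
  d2 <- calc_density(two, g, cutoff = 6)
  d_second <- calc_density(within(at, x <- 2), g, cutoff = 6)
  expect_equal(d2$values, dm$values + d_second$values, tolerance = 1e-12)
})

test_that("observed-map scaling recovers gain and offset", {
  m <- toy_chain(rep("ALA", 3))
  cm <- calc_density(m$atoms, grid_for_atoms(m$atoms, 1.5), 1.5)
  msk <- voxel_mask(cm, as.matrix(m$atoms[, c("x", "y", "z")]), 1.5)
  obs <- density_map(2 * cm$values + 1, cm$origin, cm$spacing, 1.5)
  sc <- scale_obs_to_calc(obs, cm, msk)
  expect_equal(attr(sc, "gain"), 2, tolerance = 1e-9)
  expect_equal(attr(sc, "offset"), 1, tolerance = 1e-9)
  expect_lt(max(abs(sc$values[msk] - cm$values[msk])), 1e-9)
  ident <- scale_obs_to_calc(cm, cm, msk)
  expect_equal(attr(ident, "gain"), 1, tolerance = 1e-9)
  expect_equal(attr(ident, "offset"), 0, tolerance = 1e-9)
  # noisy gain recovery within 1%
  set.seed(1)
  noisy <- density_map(1.7 * cm$values + rnorm(length(cm$values), 0, 0.01),
                       cm$origin, cm$spacing, 1.5)
  expect_gt(length(msk), 1000)
  expect_equal(attr(scale_obs_to_calc(noisy, cm, msk), "gain"), 1.7,
               tolerance = 0.01)
  expect_error(scale_obs_to_calc(obs, cm, msk[1:5]), "degenerate")
})

test_that("background subtraction leaves the selected residue's density", {
  m <- toy_chain(c("ALA", "SER", "ALA"), chis = list(NULL, c(64), NULL))
  d <- 1.5
  obs <- calc_density(m$atoms, grid_for_atoms(m$atoms, d), d)
  sel <- which(m$atoms$resno == 2)
  res <- background_subtract(obs, m, sel, d)
  own <- calc_density(m$atoms[sel, ], obs, d)
  expect_lt(sqrt(mean((res$values - own$values)^2)), 0.01 * max(own$values))
  # full-model selection returns the observed map unchanged
  expect_equal(background_subtract(obs, m, seq_len(nrow(m$atoms)), d)$values,
               obs$values)
  expect_error(background_subtract(obs, m, integer(0), d), "empty")
})

test_that("background subtraction is local to the selection", {
  m <- toy_chain(c("ALA", "SER", "ALA", "ALA", "SER", "ALA"),
                 chis = list(NULL, c(64), NULL, NULL, c(-65), NULL))
  d <- 1.5
  obs <- calc_density(m$atoms, grid_for_atoms(m$atoms, d), d)
  r1 <- background_subtract(obs, m, which(m$atoms$resno == 2), d)
  r2 <- background_subtract(obs, m, which(m$atoms$resno == 5), d)
  diffmap <- abs(r1$values - r2$values)
  ai <- arrayInd(which(diffmap > 1e-6), dim(diffmap))
  pts <- cbind(obs$origin[1] + (ai[, 1] - 1) * obs$spacing[1],
               obs$origin[2] + (ai[, 2] - 1) * obs$spacing[2],
               obs$origin[3] + (ai[, 3] - 1) * obs$spacing[3])
  near <- m$atoms[m$atoms$resno %in% c(2, 5), ]
  mind <- apply(pts, 1, function(p) {
    min(sqrt((near$x - p[1])^2 + (near$y - p[2])^2 + (near$z - p[3])^2))
  })
  expect_true(all(mind < 2 * mask_radius(d) + 3))  # differences stay near the residues
})

test_that("CCP4 map round trip preserves grid and values", {
  m <- toy_chain(rep("ALA", 2))
  cm <- calc_density(m$atoms, grid_for_atoms(m$atoms, 1.5), 1.5)
  tf <- tempfile(fileext = ".ccp4")
  write_map(cm, tf)
  cm2 <- read_map(tf)
  expect_lt(max(abs(cm$values - cm2$values)), 1e-6 * max(abs(cm$values)))
  expect_equal(cm2$spacing, cm$spacing, tolerance = 1e-6)
  expect_equal(cm2$origin, cm$origin, tolerance = 1e-4)
  expect_equal(cm2$resolution, 1.5, tolerance = 1e-6)
})

test_that("axis-permuted maps read back to identical Cartesian values", {
  m <- toy_chain(rep("ALA", 2))
  cm <- calc_density(m$atoms, grid_for_atoms(m$atoms, 2.0), 2.0)
  # write a variant with column/row swapped (MAPC=2, MAPR=1): same Cartesian
  # content, permuted file layout
  tf <- tempfile(fileext = ".ccp4")
  dims <- dim(cm$values)
  con <- file(tf, "wb")
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  start <- round(cm$origin / cm$spacing)
  wi(dims[c(2, 1, 3)]); wi(2); wi(start[c(2, 1, 3)]); wi(dims)
  wf(dims * cm$spacing); wf(c(90, 90, 90)); wi(c(2, 1, 3))
  wf(c(min(cm$values), max(cm$values), mean(cm$values)))
  wi(1); wi(0); wi(rep(0, 12)); wf(cm$resolution); wi(rep(0, 12))
  wf(cm$origin)
  writeChar("MAP ", con, 4, eos = NULL); wi(16708); wf(sd(cm$values)); wi(0)
  writeBin(raw(800), con)
  wf(as.numeric(aperm(cm$values, c(2, 1, 3))))
  close(con)
  cm3 <- read_map(tf)
  expect_equal(dim(cm3$values), dim(cm$values))
  expect_lt(max(abs(cm3$values - cm$values)), 1e-5 * max(abs(cm$values)))
  expect_equal(cm3$spacing, cm$spacing, tolerance = 1e-6)
  expect_equal(cm3$origin, cm$origin, tolerance = 1e-3)
})

test_that("an independent map reader agrees with the written header", {
  skip_if(Sys.which("python") == "")
  m <- toy_chain(rep("ALA", 2))
  cm <- calc_density(m$atoms, grid_for_atoms(m$atoms, 2.0), 2.0)
  tf <- tempfile(fileext = ".ccp4")
  tf2 <- tempfile(fileext = ".ccp4")
  write_map(cm, tf)
  code <- sprintf(paste0(
    "import gemmi\nm = gemmi.read_ccp4_map(%s)\n",
    "m.write_ccp4_map(%s)\n"), shQuote(tf), shQuote(tf2))
  ok <- tryCatch(system2("python", "-", input = code, stderr = TRUE, stdout = TRUE),
                 warning = function(w) NULL)
  skip_if(is.null(ok) || !is.null(attr(ok, "status")), "gemmi unavailable")
  cm3 <- read_map(tf2, resolution = 2.0)
  expect_equal(dim(cm3$values), dim(cm$values))
  expect_lt(max(abs(cm3$values - cm$values)), 1e-5 * max(abs(cm$values)))
})

test_that("synthetic datasets follow the B-inflation and noise protocol", {
  m <- toy_chain(rep("ALA", 3))
  sp <- synthetic_spec(m, 2.0, d0 = 1.2)
  ds <- generate_synthetic_dataset(sp, seed = 1)
  expect_true(all(abs(ds$model$atoms$b - m$atoms$b - 8.0) < 1e-12))
  sp0 <- synthetic_spec(m, 1.2, d0 = 1.2, noise_frac = 0)
  ds0 <- generate_synthetic_dataset(sp0, seed = 1)
  expect_equal(ds0$obs$values, ds0$calc$values, tolerance = 1e-10)
  expect_true(all(ds0$model$atoms$b == m$atoms$b))  # d = d0: zero inflation
  expect_error(synthetic_spec(m, 1.0, d0 = 1.2), "native resolution")
})

test_that("map-truth correlation decreases with the noise fraction", {
  m <- toy_chain(rep("ALA", 3))
  cors <- sapply(c(0, 0.1, 0.3), function(nf) {
    mean(sapply(1:5, function(s) {
      ds <- generate_synthetic_dataset(
        synthetic_spec(m, 1.5, noise_frac = nf), seed = s)
      cor(as.numeric(ds$obs$values), as.numeric(ds$calc$values))
    }))
  })
  expect_true(all(diff(cors) < 0))
})

test_that("anisotropic tensors convert to isotropic B before synthesis", {
  m <- toy_chain(rep("ALA", 2))
  m$atoms$u11[1] <- 0.3; m$atoms$u22[1] <- 0.2; m$atoms$u33[1] <- 0.1
  m$atoms$u12[1] <- 0; m$atoms$u13[1] <- 0; m$atoms$u23[1] <- 0
  ds <- generate_synthetic_dataset(synthetic_spec(m, 1.2, noise_frac = 0), seed = 1)
  expect_equal(ds$model$atoms$b[1], 8 * pi^2 * 0.2, tolerance = 1e-9)
  expect_true(all(is.na(ds$model$atoms$u11)))
})
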