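# Density maps: synthesis, sampling, scoring, CCP4/MRC round trips.

one_atom_model <- function(pos = c(6, 5, 5), cell = unit_cell(12, 10, 11)) {
  protein_model(list(residue_from_coords(
    "GLY", "A", 1, matrix(pos, 1, 3, dimnames = list("CA", NULL)))), cell = cell)
}

test_that("synthetic maps peak at atoms and integrate to the electron count", {
  map <- synthesize_map(one_atom_model(), sigma = 0.5, spacing = 0.15)
  w <- which(map$grid == max(map$grid), arr.ind = TRUE)[1, ]
  step <- c(12, 10, 11) / dim(map$grid)
  expect_lt(max(abs((w - 1) * step - c(6, 5, 5))), max(step))
  vox <- prod(step)
  expect_equal(sum(map$grid) * vox, 6, tolerance = 0.02)  # carbon electron count
  # rmsd equals an independent standard deviation
  expect_equal(map$rmsd, sd(as.numeric(map$grid)), tolerance = 1e-12)
  expect_error(synthesize_map(one_atom_model(), spacing = -1), "spacing")
})

test_that("noise is reproducible by seed and absent when requested", {
  m <- one_atom_model()
  a <- synthesize_map(m, sigma = 0.5, spacing = 0.3, noise_sd = 0.5, seed = 3)
  b <- synthesize_map(m, sigma = 0.5, spacing = 0.3, noise_sd = 0.5, seed = 3)
  cc <- synthesize_map(m, sigma = 0.5, spacing = 0.3, noise_sd = 0.5, seed = 4)
  expect_identical(a$grid, b$grid)
  expect_false(identical(a$grid, cc$grid))
  n0 <- synthesize_map(m, sigma = 0.5, spacing = 0.3, noise_sd = 0, seed = 3)
  n1 <- synthesize_map(m, sigma = 0.5, spacing = 0.3, noise_sd = 0, seed = 4)
  expect_identical(n0$grid, n1$grid)
})

test_that("normalized sampling: degenerate maps, r = 0, ramp averaging, periodicity", {
  flat <- density_map(array(5, dim = c(8, 8, 8)), unit_cell(8, 8, 8))
  expect_error(sample_rho_prime(flat, c(1, 1, 1)), "degenerate")
  # forcing the normalization constants recovers value / rmsd
  flat$rmsd <- 2; flat$mean <- 0
  expect_equal(sample_rho_prime(flat, c(1, 1, 1), r = 0.7), 2.5)
  # linear ramp: averaging over +/- r cancels along the gradient
  g <- array(rep(seq_len(20), times = 400), dim = c(20, 20, 20))
  ramp <- density_map(g, unit_cell(20, 20, 20))
  expect_equal(sample_rho_prime(ramp, c(7.3, 5, 5), 0.8),
               sample_rho_prime(ramp, c(7.3, 5, 5), 0), tolerance = 1e-9)
  # periodic sampling equals sampling an explicitly tiled grid
  big <- array(0, dim = c(40, 20, 20))
  big[1:20, , ] <- g; big[21:40, , ] <- g
  bigmap <- density_map(big, unit_cell(40, 20, 20))
  bigmap$mean <- ramp$mean; bigmap$rmsd <- ramp$rmsd
  for (x in c(-3.2, 1.1, 19.7)) {
    expect_equal(sample_rho_prime(ramp, c(x, 4.5, 9.2), 0),
                 sample_rho_prime(bigmap, c(x %% 20 + 20, 4.5, 9.2), 0),
                 tolerance = 1e-9)
  }
})

test_that("density_score applies the below-threshold penalty as specified", {
  res <- fx_residue("SER", 60)
  model <- assign_cell(protein_model(list(res)), padding = 5)
  map <- synthesize_map(model, sigma = 0.6, spacing = 0.25)
  coords <- residue_atom_pos(model$residues[[1]], c("CB", "OG"))
  rho <- sample_rho_prime(map, coords, 0)
  # penalty inactive when every atom is above the threshold
  expect_equal(density_score(map, coords, density_params(0, k_t = min(rho) - 1, k_f = 7)),
               sum(rho))
  # neutral parameters give the plain sum
  expect_equal(density_score(map, coords, density_params(0, 0, 1)), sum(rho))
  # single atom below threshold by delta loses (k_f - 1) * delta
  kt <- rho[2] + 0.3
  pen <- density_score(map, matrix(coords[2, ], 1, 3), density_params(0, kt, 3))
  expect_equal(pen, unname(rho[2]) - (3 - 1) * 0.3, tolerance = 1e-9)
  # monotone in rho: raising k_f never increases the score
  expect_lte(density_score(map, coords, density_params(0, kt, 5)),
             density_score(map, coords, density_params(0, kt, 1)) + 1e-12)
  expect_equal(density_score(map, matrix(numeric(0), 0, 3)), 0)
})

test_that("density_score is invariant under joint rigid motion of model and grid", {
  # translating the model by whole grid periods leaves scores unchanged
  res <- fx_residue("THR", -60)
  model <- assign_cell(protein_model(list(res)), padding = 5)
  map <- synthesize_map(model, sigma = 0.6, spacing = 0.25)
  coords <- residue_atom_pos(model$residues[[1]], c("CB", "OG1", "CG2"))
  shift <- c(map$cell$a, 0, 0)
  expect_equal(density_score(map, coords),
               density_score(map, sweep(coords, 2, -shift)), tolerance = 1e-9)
})

test_that("the true conformation outscores distant alternatives in its own map", {
  set.seed(5)
  res <- fx_residue("MET", c(-60, 180, 75))
  model <- assign_cell(protein_model(list(res)), padding = 6)
  map <- synthesize_map(model, sigma = 0.6, spacing = 0.25)
  truth <- conformation_from_residue(model$residues[[1]])
  inv <- invert_transform(local_frame(model$residues[[1]]))
  d_true <- density_score(map, apply_transform(inv, truth$coords))
  for (rep in 1:10) {
    alt <- fx_conf("MET", runif(3, -180, 180))
    if (sidechain_rmsd(alt, truth) <= 0.3) next
    expect_gt(d_true, density_score(map, apply_transform(inv, alt$coords)))
  }
})

test_that("CCP4/MRC round trip and axis-order resolution", {
  model <- assign_cell(protein_model(list(fx_residue("SER", 60))), padding = 4)
  map <- synthesize_map(model, sigma = 0.6, spacing = 0.4)
  f <- withr::local_tempfile(fileext = ".mrc")
  write_map(map, f)
  back <- read_map(f)
  expect_equal(dim(back$grid), dim(map$grid))
  expect_lt(max(abs(back$grid - map$grid)), 1e-5)
  expect_equal(back$rmsd, map$rmsd, tolerance = 1e-5)
  # permuted-axis file (sections fastest) is restored to x,y,z layout
  raw <- readBin(f, "raw", file.info(f)$size)
  d <- dim(map$grid)
  con <- file(f, "wb")
  writeBin(as.integer(c(d[3], d[1], d[2])), con, size = 4, endian = "little")
  writeBin(raw[13:64], con)  # mode, nstart, mxyz, cell
  writeBin(as.integer(c(3L, 1L, 2L)), con, size = 4, endian = "little")
  writeBin(raw[77:1024], con)
  writeBin(as.numeric(aperm(map$grid, c(3, 1, 2))), con, size = 4, endian = "little")
  close(con)
  perm <- read_map(f)
  expect_lt(max(abs(perm$grid - map$grid)), 1e-5)
  # unsupported mode errors explicitly
  con <- file(f, "wb")
  writeBin(as.integer(d), con, size = 4, endian = "little")
  writeBin(77L, con, size = 4, endian = "little")
  writeBin(raw[17:1024], con); close(con)
  expect_error(read_map(f), "mode")
})
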