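# Model I/O: PDB round trips, local frames, chi angles, nomenclature.

test_that("PDB round trip preserves cell, altlocs and coordinates", {
  res1 <- fx_residue("SER", 60, num = 1L)
  res2 <- fx_residue("LEU", c(-60, 170), num = 2L)
  # altloc pair on SER OG
  og <- res1$atoms[res1$atoms$name == "OG", ]
  res1$atoms$alt_loc[res1$atoms$name == "OG"] <- "A"
  res1$atoms$occupancy[res1$atoms$name == "OG"] <- 0.6
  ogb <- og; ogb$alt_loc <- "B"; ogb$occupancy <- 0.4; ogb$x <- ogb$x + 0.8
  res1$atoms <- rbind(res1$atoms, ogb)
  model <- protein_model(list(res1, res2), cell = unit_cell(30, 40, 50))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(model, f)
  back <- read_pdb(f)
  expect_length(back$residues, 2)
  expect_false(is.null(back$cell))
  expect_equal(back$cell$a, 30)
  expect_setequal(back$residues[[1]]$atoms$alt_loc[back$residues[[1]]$atoms$name == "OG"],
                  c("A", "B"))
  # coordinates to 1e-3 through a second round trip
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(back, f2)
  back2 <- read_pdb(f2)
  for (i in 1:2) {
    a <- back$residues[[i]]$atoms; b <- back2$residues[[i]]$atoms
    expect_equal(as.matrix(a[, c("x", "y", "z")]), as.matrix(b[, c("x", "y", "z")]),
                 tolerance = 1e-3)
  }
})

test_that("missing CRYST1 flags the model non-crystallographic", {
  model <- protein_model(list(fx_residue("ALA")))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(model, f)
  expect_null(read_pdb(f)$cell)
})

test_that("write_pdb emits the expected records", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(protein_model(list()), f)
  expect_identical(readLines(f), "END")
  ala <- residue_from_coords("ALA", "A", 1, rbind(
    canonical_backbone(),
    O = place_atom(canonical_backbone()["N", ], c(0, 0, 0),
                   canonical_backbone()["C", ], 1.231, 120.8, 45),
    build_sidechain("ALA")))
  write_pdb(protein_model(list(ala)), f)
  lines <- readLines(f)
  expect_length(grep("^ATOM", lines), 5)  # N, CA, C, O, CB
  expect_error(write_pdb(protein_model(list({
    r <- fx_residue("SER", 60); r$atoms$name[1] <- "ABCDE"; r
  })), f), "too long")
})

test_that("local_frame is canonical, deterministic and self-inverting", {
  res <- fx_residue("SER", 60)
  tf <- local_frame(res)
  expect_equal(tf$R, diag(3), tolerance = 1e-12)
  expect_equal(tf$t, c(0, 0, 0), tolerance = 1e-12)
  set.seed(4)
  for (rep in 1:20) {
    R <- rotation_about_axis(rnorm(3), runif(1, -180, 180))
    t0 <- rnorm(3, 0, 10)
    moved <- res
    xyz <- as.matrix(res$atoms[, c("x", "y", "z")])
    moved$atoms[, c("x", "y", "z")] <- t(R %*% t(xyz)) + rep(t0, each = nrow(xyz))
    tf2 <- local_frame(moved)
    back <- apply_transform(tf2, as.matrix(moved$atoms[, c("x", "y", "z")]))
    expect_lt(max(abs(back - xyz)), 1e-6)
    # frame-superposed side chains are identical
    expect_lt(sidechain_rmsd(conformation_from_residue(res),
                             conformation_from_residue(moved)), 1e-6)
  }
  noca <- res; noca$atoms <- noca$atoms[noca$atoms$name != "CA", ]
  expect_error(local_frame(noca), "CA")
})

test_that("chi angles follow the standard definitions", {
  expect_identical(chi_angles(fx_residue("ALA")), numeric(0))
  expect_equal(chi_angles(fx_residue("SER", 60)), 60, tolerance = 0.1)
  expect_length(chi_angles(fx_residue("ARG", c(-60, 180, 65, -170))), 4)
  set.seed(11)
  for (rt in sidechain_types()) {
    chi <- runif(length(chi_definitions(rt)), -179, 179)
    got <- chi_angles(fx_residue(rt, chi))
    if (length(got)) expect_lt(max(abs(wrap_angle(got - chi))), 1e-6)
  }
  incomplete <- fx_residue("VAL", 60)
  incomplete$atoms <- incomplete$atoms[incomplete$atoms$name != "CG1", ]
  expect_error(chi_angles(incomplete), "CG1")
})

test_that("set_chi rotates only the distal atoms", {
  res <- fx_residue("LYS", c(-60, 180, 180, 60))
  res2 <- set_chi(res, 2, -75)
  expect_equal(chi_angles(res2), c(-60, -75, 180, 60), tolerance = 1e-6)
  expect_equal(residue_atom_pos(res2, c("CB", "CG")),
               residue_atom_pos(res, c("CB", "CG")), tolerance = 1e-12)
})

test_that("symmetric-residue nomenclature is normalized into [-90, 90]", {
  phe <- fx_residue("PHE", c(-60, 120))
  out <- normalize_nomenclature(phe)
  expect_true(out$swapped)
  expect_lte(abs(chi_angles(out$residue)[2]), 90)
  again <- normalize_nomenclature(out$residue)
  expect_false(again$swapped)
  asp <- fx_residue("ASP", c(-60, 30))
  expect_false(normalize_nomenclature(asp)$swapped)
  # idempotence across types and random torsions
  set.seed(21)
  for (rt in c("ASP", "GLU", "PHE", "TYR", "ARG", "LEU", "VAL")) {
    chi <- runif(length(chi_definitions(rt)), -179, 179)
    one <- normalize_nomenclature(fx_residue(rt, chi))
    two <- normalize_nomenclature(one$residue)
    expect_false(two$swapped)
  }
})

test_that("inverted Thr/Ile chirality is rejected, not renamed", {
  for (rt in c("THR", "ILE")) {
    res <- fx_residue(rt, rep(60, length(chi_definitions(rt))))
    expect_false(normalize_nomenclature(res)$rejected)
    sw <- if (rt == "THR") c("OG1", "CG2") else c("CG1", "CG2")
    at <- res$atoms
    i <- which(at$name == sw[1]); j <- which(at$name == sw[2])
    tmp <- at[i, c("x", "y", "z")]
    at[i, c("x", "y", "z")] <- at[j, c("x", "y", "z")]
    at[j, c("x", "y", "z")] <- tmp
    res$atoms <- at
    out <- normalize_nomenclature(res)
    expect_true(out$rejected)
    expect_match(out$reason, "chirality")
  }
})

test_that("sidechain_rmsd: metric properties and hand-built cases", {
  a <- fx_conf("SER", 60)
  expect_equal(sidechain_rmsd(a, a), 0)
  b <- fx_conf("SER", 60)
  b$coords["OG", ] <- b$coords["OG", ] + c(0.5, 0, 0)
  expect_equal(sidechain_rmsd(a, b), 0.5, tolerance = 1e-12)
  expect_error(sidechain_rmsd(a, fx_conf("THR", 60)), "type mismatch")
  set.seed(31)
  for (rep in 1:10) {
    cs <- lapply(1:3, function(z) fx_conf("MET", runif(3, -180, 180)))
    d12 <- sidechain_rmsd(cs[[1]], cs[[2]])
    d21 <- sidechain_rmsd(cs[[2]], cs[[1]])
    d13 <- sidechain_rmsd(cs[[1]], cs[[3]])
    d23 <- sidechain_rmsd(cs[[2]], cs[[3]])
    expect_equal(d12, d21)
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("symmetry operators parse and map fractional coordinates", {
  op <- parse_symop("-X,Y+1/2,-Z")
  expect_equal(op$R, matrix(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), 3, 3))
  expect_equal(op$t, c(0, 0.5, 0))
  cell <- unit_cell(10, 20, 30, spacegroup = "P 21 21 21")
  expect_length(cell$ops, 4)
  expect_equal(cell$ops[[1]]$R, diag(3))  # identity always present
  # fractional <-> orthogonal round trip
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(orth_coords(cell, frac_coords(cell, x)), x, tolerance = 1e-12)
})
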