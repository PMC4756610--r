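# Energy terms: self-energy algebra, nonbonded pair/backbone terms,
# polar-H variants and flips.

test_that("self-energy: relative terms vanish for the best conformation", {
  p <- energy_params(w_d = 1, w_p = 0.5)
  # the conformation maximizing both D and p costs zero
  expect_equal(e_self(10, 10, 0.7, 0.7, 0, p), 0)
  # with zero weights only the backbone term remains
  p0 <- energy_params(w_d = 0, w_p = 0)
  expect_equal(e_self(3, 10, 0.1, 0.7, 1.25, p0), 1.25)
  # hand-computed two-conformer case: D = (10, 8), p irrelevant at w_p = 0
  p1 <- energy_params(w_d = 1, w_p = 0)
  expect_equal(c(e_self(10, 10, 0.7, 0.7, 0, p1), e_self(8, 10, 0.3, 0.7, 0, p1)),
               c(0, 2))
  # simplified energy is the self-energy without the backbone term
  expect_equal(e_self_simplified(8, 10, 0.3, 0.7, p), e_self(8, 10, 0.3, 0.7, 0, p))
  expect_equal(e_self(8, 10, 0.3, 0.7, 5, p) - e_self_simplified(8, 10, 0.3, 0.7, p), 5)
  # identical D and p across conformers: all simplified energies equal
  expect_equal(e_self_simplified(4, 4, 0.2, 0.2, p), 0)
  # p = 0 is capped, not infinite
  expect_equal(e_self(10, 10, 0, 0.5, 0, p), p$w_p * p$p_cap)
  # nonnegative when the backbone term is absent
  set.seed(3)
  for (rep in 1:50) {
    D <- runif(4, 0, 20); pr <- runif(4); pr <- pr / sum(pr)
    e <- vapply(1:4, function(s) e_self(D[s], max(D), pr[s], max(pr), 0, p), numeric(1))
    expect_gte(min(e), 0)
  }
})

test_that("with w_p = 0 and no backbone term the E_self ranking follows D", {
  p <- energy_params(w_d = 2, w_p = 0)
  set.seed(8)
  D <- runif(6, 0, 30); pr <- runif(6); pr <- pr / sum(pr)
  e <- vapply(1:6, function(s) e_self(D[s], max(D), pr[s], max(pr), 0, p), numeric(1))
  expect_identical(order(e), order(-D))
})

test_that("pairwise nonbonded energy: cutoff, LJ minimum, symmetry", {
  ep <- energy_params()
  far_a <- matrix(c(0, 0, 0), 1, 3, dimnames = list("CD1", NULL))
  far_b <- matrix(c(50, 0, 0), 1, 3, dimnames = list("CD1", NULL))
  expect_equal(e_pair("LEU", far_a, "LEU", far_b, ep), 0)
  # two neutral united CH3 atoms at the LJ minimum separation give -epsilon
  sig <- 3.905; eps <- 0.175
  rmin <- 2^(1 / 6) * sig
  at_min <- matrix(c(rmin, 0, 0), 1, 3, dimnames = list("CD1", NULL))
  expect_equal(e_pair("LEU", far_a, "LEU", at_min, ep), -eps, tolerance = 1e-9)
  # argument order does not matter
  a <- fx_conf("LYS", c(-60, 180, 180, 60))$coords + 2
  b <- fx_conf("SER", 60)$coords
  expect_equal(e_pair("LYS", a, "SER", b, ep), e_pair("SER", b, "LYS", a, ep))
  expect_error(e_pair("LEU", matrix(0, 1, 3, dimnames = list("XX9", NULL)),
                      "LEU", far_b, ep), "class")
})

test_that("backbone interaction: exclusions and donor-orientation sign", {
  ep <- energy_params(include_symmetry = FALSE)
  iso <- protein_model(list(fx_residue("SER", 60)))
  cf <- conformation_from_residue(iso$residues[[1]])
  # an isolated residue sees only its own (excluded) backbone: zero
  expect_equal(e_backbone("SER", cf$coords, iso, 1, ep), 0)
  # a serine hydroxyl donor pointing at a backbone carbonyl O is more
  # favorable than pointing away
  m <- synthetic_chain(4, types = "SER", seed = 2)
  res <- m$residues[[2]]
  base <- conformation_from_residue(res)
  inv <- invert_transform(local_frame(res))
  hv <- generate_h_variants(base)
  placed <- lapply(hv, function(v) apply_transform(inv, v$coords))
  e <- vapply(placed, function(co) e_backbone("SER", co, m, 2, ep), numeric(1))
  expect_gt(max(e) - min(e), 0)  # H orientation matters
  # the chosen orientation with the H nearest a carbonyl O is lowest
  env <- backbone_environment(m)
  oxy <- as.matrix(env[env$name == "O" & env$res_idx != 2, c("x", "y", "z")])
  hdist <- vapply(placed, function(co) min(sqrt(rowSums(
    sweep(oxy, 2, co["HG", ])^2))), numeric(1))
  expect_equal(which.min(e), which.min(hdist))
})

test_that("energy tables are reproducible bit-for-bit", {
  m <- synthetic_chain(3, types = c("SER", "THR"), seed = 5)
  ep <- energy_params()
  cf <- conformation_from_residue(m$residues[[1]])
  inv <- invert_transform(local_frame(m$residues[[1]]))
  co <- apply_transform(inv, cf$coords)
  expect_identical(e_backbone(m$residues[[1]]$res_type, co, m, 1, ep),
                   e_backbone(m$residues[[1]]$res_type, co, m, 1, ep))
})

test_that("polar hydrogen variants follow the prescribed torsions", {
  ser <- fx_conf("SER", 60)
  hv <- generate_h_variants(ser)
  expect_length(hv, 3)
  tors <- vapply(hv, function(v) {
    co <- rbind(CA = c(0, 0, 0), v$coords)
    dihedral_angle(co["CA", ], co["CB", ], co["OG", ], co["HG", ])
  }, numeric(1))
  expect_equal(sort(tors), c(-60, 60, 180), tolerance = 0.1)
  # Leu: no polar H, unchanged
  leu <- fx_conf("LEU", c(-60, 170))
  expect_length(generate_h_variants(leu), 1)
  # Tyr: two variants at 0 and 180, measured back from the built geometry
  tyr <- fx_conf("TYR", c(-60, 80))
  tv <- generate_h_variants(tyr)
  expect_length(tv, 2)
  tt <- vapply(tv, function(v) dihedral_angle(v$coords["CE1", ], v$coords["CZ", ],
                                              v$coords["OH", ], v$coords["HH", ]),
               numeric(1))
  expect_equal(sort(abs(tt)), c(0, 180), tolerance = 0.1)
  # His: three protonation states with ring-plane hydrogens
  his <- fx_conf("HIS", c(-60, 80))
  hhv <- generate_h_variants(his)
  expect_length(hhv, 3)
  expect_setequal(vapply(hhv, function(v) v$h_variant, character(1)),
                  c("HD1", "HE2", "HD1+HE2"))
})

test_that("terminal-group flips swap identities and are involutions", {
  asn <- fx_conf("ASN", c(-60, 40))
  fl <- generate_flips(asn)
  expect_length(fl, 2)
  expect_equal(fl[[2]]$coords["OD1", ], asn$coords["ND2", ])
  expect_equal(fl[[2]]$coords["ND2", ], asn$coords["OD1", ])
  back <- generate_flips(fl[[2]])
  expect_equal(back[[2]]$coords, asn$coords)
  val <- fx_conf("VAL", 60)
  expect_length(generate_flips(val), 1)
  his <- fx_conf("HIS", c(-60, 80))
  fh <- generate_flips(his)
  expect_equal(fh[[2]]$coords["ND1", ], his$coords["CD2", ])
  expect_equal(fh[[2]]$coords["NE2", ], his$coords["CE1", ])
})
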