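# Conformer library: filters, deduplication, clustering, cuts,
# expansion, frequencies, container round trips.

test_that("filter_conformation screens clashes, geometry and completeness", {
  leu <- fx_residue("LEU", c(-60, 170))
  expect_true(filter_conformation(leu, NULL)$accept)
  ser <- fx_residue("SER", 60)
  og <- residue_atom_pos(ser, "OG")
  ctx <- data.frame(element = "O", x = og[1] + 0.4, y = og[2], z = og[3])
  out <- filter_conformation(ser, ctx)   # ~2.6 A overlap >> 0.4 A
  expect_false(out$accept)
  expect_identical(out$reason, "clash")
  val <- fx_residue("VAL", 60)
  val$atoms <- val$atoms[val$atoms$name != "CG1", ]
  expect_identical(filter_conformation(val, NULL)$reason, "incomplete")
  # a grossly distorted bond (>6 sigma) is rejected
  bent <- fx_residue("SER", 60)
  i <- which(bent$atoms$name == "OG")
  bent$atoms[i, c("x", "y", "z")] <- bent$atoms[i, c("x", "y", "z")] + 0.5
  expect_false(filter_conformation(bent, NULL)$accept)
})

test_that("deduplication follows the 0.1-Angstrom rule and is order-stable", {
  a <- fx_conf("SER", 60)
  b <- fx_conf("SER", 60)
  expect_length(deduplicate(list(a, b)), 1)
  expect_equal(deduplicate(list(a, b))[[1]]$count, 2L)
  close_ <- fx_conf("SER", 60)
  close_$coords["OG", ] <- close_$coords["OG", ] + c(0.05, 0, 0)
  expect_length(deduplicate(list(a, close_)), 1)
  spread <- lapply(c(0, 0.2, 0.4), function(dx) {
    cf <- fx_conf("SER", 60); cf$coords["OG", ] <- cf$coords["OG", ] + c(dx, 0, 0); cf
  })
  expect_length(deduplicate(spread), 3)
  # order stability: identical input order gives identical output
  set.seed(2)
  pool <- lapply(runif(12, -180, 180), function(chi) fx_conf("CYS", chi))
  d1 <- deduplicate(pool); d2 <- deduplicate(pool)
  expect_identical(d1, d2)
})

test_that("complete-linkage trees merge at the expected heights with weighted medoids", {
  two <- lapply(c(60, 100), function(chi) fx_conf("SER", chi))
  d <- sidechain_rmsd(two[[1]], two[[2]])
  lib <- build_tree(list(SER = two))
  expect_equal(lib$types$SER$hclust$height, d, tolerance = 1e-12)
  # three conformers at pairwise distances ~ (d1, d1, d2 > d1):
  # first merge at d1, top merge at the complete-linkage maximum
  three <- lapply(c(60, 80, 140), function(chi) fx_conf("SER", chi))
  dm <- outer(seq_along(three), seq_along(three),
              Vectorize(function(i, j) sidechain_rmsd(three[[i]], three[[j]])))
  lib3 <- build_tree(list(SER = three))
  hh <- lib3$types$SER$hclust$height
  expect_equal(hh[1], min(dm[upper.tri(dm)]), tolerance = 1e-12)
  expect_equal(hh[2], max(dm), tolerance = 1e-12)
  # occurrence-weighted medoid: the heavily observed central member wins
  trio <- lapply(c(50, 60, 70), function(chi) fx_conf("SER", chi))
  trio[[2]]$count <- 9L
  libm <- build_tree(list(SER = trio))
  reps <- cut_level(libm, 10)$SER
  expect_length(reps, 1)
  expect_identical(reps[[1]]$id, "SER_002")
})

test_that("medoids match brute-force weighted minimization", {
  set.seed(12)
  confs <- lapply(runif(20, -180, 180), function(chi) fx_conf("MET", runif(3, -180, 180)))
  for (i in seq_along(confs)) confs[[i]]$count <- sample(1:10, 1)
  lib <- build_tree(list(MET = confs))
  tt <- lib$types$MET
  for (X in c(0.5, 1.5, 3)) {
    grp <- cutree(tt$hclust, h = X)
    reps <- cut_level(lib, X)$MET
    for (ri in seq_along(reps)) {
      members <- attr(reps[[ri]], "members")
      score <- sapply(members, function(m)
        sum(tt$dist[m, members] * tt$counts[members]))
      best <- members[which.min(score)]
      expect_identical(reps[[ri]]$id, tt$confs[[best]]$id)
    }
  }
})

test_that("level cuts respect the max-pairwise bound and nest properly", {
  lib <- fx_small_library()
  for (rt in names(lib$types)) {
    tt <- lib$types[[rt]]
    n <- length(tt$confs)
    for (X in c(0.4, 0.7, 1.0)) {
      reps <- cut_level(lib, X, rt)[[rt]]
      covered <- integer(0)
      for (rep_ in reps) {
        members <- attr(rep_, "members")
        covered <- c(covered, members)
        if (length(members) > 1)
          expect_lte(max(tt$dist[members, members]), X + 1e-9)
      }
      expect_setequal(covered, seq_len(n))  # cuts partition the leaves
    }
    # refinement: every 0.4-cluster lies inside one 1.0-cluster
    r04 <- cut_level(lib, 0.4, rt)[[rt]]
    r10 <- cut_level(lib, 1.0, rt)[[rt]]
    coarse <- lapply(r10, attr, "members")
    for (rep_ in r04) {
      inside <- vapply(coarse, function(m) all(attr(rep_, "members") %in% m),
                       logical(1))
      expect_equal(sum(inside), 1)
    }
    # extreme cuts
    expect_length(cut_level(lib, 100, rt)[[rt]], 1)
    mind <- if (n > 1) min(tt$dist[upper.tri(tt$dist)]) else 1
    expect_length(cut_level(lib, mind * 0.99, rt)[[rt]], n)
  }
})

test_that("cluster expansion returns the refined neighborhood of a pick", {
  lib <- fx_small_library()
  rt <- names(which(vapply(lib$types, function(t) length(t$confs), integer(1)) >= 6))[1]
  reps <- cut_level(lib, 0.7, rt)[[rt]]
  sel <- reps[[1]]
  ex <- expand_cluster(lib, sel, 1.5, 0.4, 0.7)
  # includes the pick's own refined representatives
  own_high <- cut_level(lib, 0.4, rt)[[rt]]
  own_ids <- vapply(own_high[vapply(own_high, function(r)
    any(attr(r, "members") %in% attr(sel, "members")), logical(1))],
    function(r) r$id, character(1))
  expect_true(all(own_ids %in% vapply(ex, function(cf) cf$id, character(1))))
  expect_error(expand_cluster(lib, sel, 0.4, 1.5, 0.7), "levels")
  # degenerate tree: a single-cluster type expands to all fine-level medoids
  small <- build_tree(list(SER = lapply(c(58, 60, 62), function(chi) fx_conf("SER", chi))))
  exs <- expand_cluster(small, cut_level(small, 0.7)$SER[[1]], 1.5, 0.4, 0.7)
  expect_setequal(vapply(exs, function(cf) cf$id, character(1)),
                  vapply(cut_level(small, 0.4)$SER, function(cf) cf$id, character(1)))
})

test_that("inverse-distance frequency assignment matches its closed forms", {
  confs <- lapply(c(-60, 60, 180), function(chi) fx_conf("SER", chi))
  lib <- build_tree(list(SER = confs))
  # single sample: uniform after normalization
  tab1 <- data.frame(res_type = "SER", chi1 = -60, chi2 = NA, chi3 = NA, chi4 = NA,
                     probability = 0.8)
  f1 <- assign_frequencies(lib, tab1)
  expect_equal(vapply(f1$types$SER$confs, function(cf) cf$frequency, numeric(1)),
               rep(1 / 3, 3))
  # exact chi match takes the sample's probability before normalization
  tab2 <- data.frame(res_type = "SER", chi1 = c(-60, 60, 180), chi2 = NA, chi3 = NA,
                     chi4 = NA, probability = c(0.5, 0.3, 0.2))
  f2 <- assign_frequencies(lib, tab2)
  expect_equal(vapply(f2$types$SER$confs, function(cf) cf$frequency, numeric(1)),
               c(0.5, 0.3, 0.2), tolerance = 1e-9)
  # two equidistant samples average arithmetically before normalization
  conf0 <- list(fx_conf("SER", 0))
  lib0 <- build_tree(list(SER = conf0))
  tab3 <- data.frame(res_type = "SER", chi1 = c(-40, 40), chi2 = NA, chi3 = NA,
                     chi4 = NA, probability = c(0.9, 0.1))
  f3 <- assign_frequencies(lib0, tab3)
  expect_equal(f3$types$SER$confs[[1]]$frequency, 1)  # single conf normalizes to 1
  # missing type falls back to uniform with a warning
  expect_warning(assign_frequencies(lib, data.frame(
    res_type = "LEU", chi1 = -60, chi2 = 170, chi3 = NA, chi4 = NA,
    probability = 1)), "uniform")
  # frequencies always sum to one per type
  full <- assign_frequencies(fx_small_library(), fx_rotamer_table())
  for (rt in names(full$types)) {
    expect_equal(sum(vapply(full$types[[rt]]$confs, function(cf) cf$frequency,
                            numeric(1))), 1, tolerance = 1e-9)
  }
})

test_that("the library container round-trips and rejects corrupt files", {
  lib <- assign_frequencies(fx_small_library(), fx_rotamer_table())
  f <- withr::local_tempfile(fileext = ".json")
  save_library(lib, f)
  back <- load_library(f)
  for (rt in names(lib$types)) {
    for (X in c(0.4, 0.7, 1.5)) {
      expect_identical(vapply(cut_level(lib, X, rt)[[rt]], function(cf) cf$id, character(1)),
                       vapply(cut_level(back, X, rt)[[rt]], function(cf) cf$id, character(1)))
    }
  }
  # partial read of one residue type equals the corresponding slice
  rt1 <- names(lib$types)[1]
  part <- load_library(f, types = rt1)
  expect_identical(names(part$types), rt1)
  expect_equal(part$types[[rt1]]$dist, back$types[[rt1]]$dist, tolerance = 1e-12)
  # truncation is a schema error, not silent corruption
  txt <- readLines(f, warn = FALSE)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(txt, collapse = ""), 1, 200), bad)
  expect_error(load_library(bad))
  # schema version mismatch
  bad2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(schema = "other-0", types = list()), bad2,
                       auto_unbox = TRUE)
  expect_error(load_library(bad2), "schema")
})
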