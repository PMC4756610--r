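# Search engines: brute-force oracle, lazy stage-I selection, stage-II
# graph search, DEE criteria, stage-III refinement, collision detection.

test_that("brute_force_gmec handles degenerate shapes and refuses blowups", {
  one <- energy_tables(list(c(3, 1, 2)))
  expect_equal(brute_force_gmec(one)$assignment, 2L)
  # independent residues decompose into per-residue minima
  indep <- energy_tables(list(c(2, 1), c(0.5, 3), c(7, 4, 6)))
  expect_equal(brute_force_gmec(indep)$assignment, c(2L, 1L, 2L))
  expect_error(brute_force_gmec(energy_tables(rep(list(1:10), 9)), bound = 1e6),
               "bound")
})

test_that("stage I selects lazily and flags fully clashing residues", {
  # single residue, no environment: global minimizer, one check only
  r1 <- stage1_fit(list(c(3, 1, 2)), function(i, s) FALSE)
  expect_equal(r1$conf, 2L)
  expect_equal(r1$checks, 1L)
  # best conformer clashes, second does not: exactly two clash checks
  r2 <- stage1_fit(list(c(3, 1, 2)), function(i, s) s == 2)
  expect_equal(r2$conf, 3L)
  expect_equal(r2$checks, 2L)
  expect_true(r2$ok)
  # everything clashes: lowest-energy conformation kept, flagged
  r3 <- stage1_fit(list(c(3, 1, 2)), function(i, s) TRUE)
  expect_equal(r3$conf, 2L)
  expect_false(r3$ok)
  expect_error(stage1_fit(list(numeric(0)), function(i, s) FALSE), "no conformations")
})

test_that("stage II returns stage I unchanged when nothing collides", {
  res <- stage2_resolve(list(c(0, 1), c(0, 2)), function(i, s, j, t) FALSE)
  expect_equal(res$conf, c(1L, 1L))
  expect_equal(res$n_expanded, 0L)
  expect_true(res$optimal)
})

test_that("the worked graph example reproduces the expected search trace", {
  ex <- fx_worked_example()
  res <- stage2_resolve(ex$E, ex$clash_fun)
  # expansion order: v1, v2, (v1,w4), v3; then the terminal (v3, w2)
  expect_equal(res$expansions$residue[1:4], c(1L, 1L, 2L, 1L))
  expect_equal(res$expansions$conf[1:4], c(1L, 2L, 4L, 3L))
  expect_equal(res$expansions$g[1:4], c(0, 5, 7, 8))
  n <- nrow(res$expansions)
  expect_equal(unname(unlist(res$expansions[n, c("residue", "conf")])), c(2L, 2L))
  expect_equal(res$conf, c(3L, 2L, 1L))
  expect_equal(res$cost, 8)
  expect_true(res$optimal)
})

test_that("stage II matches exhaustive enumeration on random clash instances", {
  set.seed(42)
  for (rep in 1:40) {
    inst <- fx_rand_clash_instance()
    enum <- fx_enumerate_clash(inst)
    res <- stage2_resolve(inst$E, inst$clash_fun)
    if (!is.na(enum$optimum)) {
      got <- sum(vapply(seq_len(inst$n), function(i) inst$E[[i]][res$conf[i]],
                        numeric(1)))
      expect_true(res$optimal)
      expect_equal(got, enum$optimum, tolerance = 1e-9)
    } else {
      expect_false(res$optimal)
      expect_gt(length(res$unfittable), 0)
    }
  }
})

test_that("the stage-II heuristic never overestimates the remaining cost", {
  set.seed(43)
  for (rep in 1:15) {
    inst <- fx_rand_clash_instance()
    enum <- fx_enumerate_clash(inst)
    res <- stage2_resolve(inst$E, inst$clash_fun)
    if (is.na(enum$optimum)) next
    base <- vapply(inst$E, min, numeric(1))
    for (row in seq_len(nrow(res$expansions))) {
      ranks <- as.integer(strsplit(res$expansions$ranks[row], ",")[[1]])
      confs <- vapply(seq_len(inst$n), function(i) order(inst$E[[i]])[ranks[i]],
                      integer(1))
      # best feasible completion reachable by rank-monotone moves
      ok <- enum$feasible
      for (i in seq_len(inst$n)) {
        ok <- ok & (enum$grid[, i] %in% order(inst$E[[i]])[ranks[i]:length(inst$E[[i]])])
      }
      if (!any(ok)) next
      g <- res$expansions$g[row]
      h <- res$expansions$h[row]
      true_remaining <- min(enum$energy[ok]) - sum(base) - g
      expect_lte(h, true_remaining + 1e-9)
    }
  }
})

test_that("DEE criteria eliminate textbook dominance and only that", {
  # conformation 1 dominated by 2 in self and every pairwise column
  tb <- energy_tables(list(c(5, 1), c(0, 0)),
                      list("1|2" = rbind(c(2, 3), c(1, 2))))
  expect_true(1L %in% dee_goldstein(tb, list(c(TRUE, TRUE), c(TRUE, TRUE)), 1))
  # an instance where Goldstein converges but split elimination removes
  # one more conformation: conformation 3 is beaten by different
  # competitors in different regions of the witness's space, so the
  # single-competitor min-term bound stays negative
  E <- list(c(0, 0, 1), c(0, 0))
  pairm <- rbind(c(0, 10), c(10, 0), c(4, 4))
  tb2 <- energy_tables(E, list("1|2" = pairm))
  alive <- list(rep(TRUE, 3), rep(TRUE, 2))
  expect_length(dee_goldstein(tb2, alive, 1), 0)
  split_out <- dee_split_single(tb2, alive, 1)
  expect_identical(split_out, 3L)
  bf <- brute_force_gmec(tb2)
  expect_false(bf$assignment[1] %in% split_out)
})

test_that("no criterion ever eliminates the enumerated optimum (random instances)", {
  set.seed(44)
  for (rep in 1:60) {
    tb <- fx_rand_tables(sample(3:5, 1), 6)
    bf <- brute_force_gmec(tb)
    alive <- lapply(tb$k, function(kk) rep(TRUE, kk))
    for (i in seq_len(tb$n)) {
      expect_false(bf$assignment[i] %in% dee_goldstein(tb, alive, i))
      expect_false(bf$assignment[i] %in% dee_split_single(tb, alive, i))
      expect_false(bf$assignment[i] %in% dee_split_magic_bullet(tb, alive, i))
    }
    for (i in seq_len(tb$n - 1)) for (j in (i + 1):tb$n) {
      dp <- dee_pairs_goldstein(tb, alive, i, j)
      expect_false(dp[bf$assignment[i], bf$assignment[j]])
    }
  }
})

test_that("stage III equals the brute-force optimum and is deterministic", {
  set.seed(45)
  for (rep in 1:50) {
    tb <- fx_rand_tables(sample(2:6, 1), 8)
    bf <- brute_force_gmec(tb)
    s3 <- stage3_refine(tb)
    expect_equal(s3$energy, bf$energy, tolerance = 1e-9)
    expect_equal(total_energy(tb, s3$assignment), s3$energy, tolerance = 1e-12)
  }
  tb <- fx_rand_tables(5, 6)
  a <- stage3_refine(tb); b <- stage3_refine(tb)
  expect_identical(a, b)
  # the pairs-elimination route (large-cluster path) is exact too
  for (rep in 1:10) {
    tb <- fx_rand_tables(4, 5)
    s3p <- stage3_refine(tb, astar_threshold = 2)
    expect_equal(s3p$energy, brute_force_gmec(tb)$energy, tolerance = 1e-9)
  }
})

test_that("all-singleton eliminations bypass the cluster search entirely", {
  # strong dominance everywhere: Goldstein fixes every residue
  tb <- energy_tables(list(c(0, 10), c(0, 10), c(0, 10)),
                      list("1|2" = matrix(0.01, 2, 2), "2|3" = matrix(0.01, 2, 2)))
  s3 <- stage3_refine(tb)
  expect_equal(s3$assignment, c(1L, 1L, 1L))
  expect_length(s3$clusters, 0)  # A* never invoked
})

test_that("collision detection with 27-cell symmetry equals brute force", {
  # far apart in a large P1 cell: nothing collides
  cell <- unit_cell(100, 100, 100)
  mk <- function(ctr) {
    co <- matrix(rep(ctr, each = 2), 2, 3) + rbind(c(0, 0, 0), c(1.4, 0, 0))
    rownames(co) <- c("CB", "CG")
    list(res_idx = 1, coords = co, elements = c("C", "C"))
  }
  cm <- clash_model()
  far <- list(mk(c(10, 10, 10)), mk(c(60, 60, 60)))
  far[[2]]$res_idx <- 2
  expect_equal(nrow(detect_collisions(far, cm, cell)), 0)
  # a residue near the face of a 10 A cell collides with its own image
  small <- unit_cell(10, 30, 30)
  near <- list(list(res_idx = 1,
                    coords = matrix(c(0.6, 15, 15, 9.4, 15, 15), 2, 3, byrow = TRUE,
                                    dimnames = list(c("CB", "CG"), NULL)),
                    elements = c("C", "C")))
  hits <- detect_collisions(near, cm, small)
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$i == 1 & hits$j == 1))
  expect_true(any(grepl("[+-]1", hits$image)))
  # pruned vs brute force on random crystallographic instances
  set.seed(46)
  for (rep in 1:20) {
    inst <- fx_collision_instance()
    a <- detect_collisions(inst$placed, cm, inst$cell, method = "pruned")
    b <- detect_collisions(inst$placed, cm, inst$cell, method = "brute")
    expect_identical(a, b)
  }
  # non-crystallographic mode checks only direct contacts
  direct <- detect_collisions(near, cm, cell = NULL)
  expect_equal(nrow(direct), 0)
})
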