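# Shared fixtures, built in code and memoized across test files.

.fx <- new.env()

# residue with ideal geometry at given chi angles, in the canonical frame
fx_residue <- function(res_type, chi = NULL, chain = "A", num = 1L) {
  if (is.null(chi)) chi <- rep(-60, length(chi_definitions(res_type)))
  coords <- rbind(canonical_backbone(), build_sidechain(res_type, chi))
  residue_from_coords(res_type, chain, num, coords)
}

fx_conf <- function(res_type, chi) {
  conformation_from_residue(fx_residue(res_type, chi))
}

fx_rotamer_table <- function() {
  if (is.null(.fx$tab)) .fx$tab <- synthetic_rotamer_table()
  .fx$tab
}

# small library for unit tests (fast to build)
fx_small_library <- function() {
  if (is.null(.fx$small_lib)) {
    chains <- lapply(1:10, function(s) synthetic_chain(15, seed = s))
    .fx$small_lib <- build_library(chains, fx_rotamer_table())$library
  }
  .fx$small_lib
}

# dense benchmark library (the study conditions for end-to-end recovery)
fx_bench_library <- function() {
  if (is.null(.fx$bench_lib)) {
    chains <- lapply(1:40, function(s) synthetic_chain(25, seed = s))
    .fx$bench_lib <- build_library(chains, fx_rotamer_table())$library
  }
  .fx$bench_lib
}

# planted-rotamer ground-truth model in a P1 cell plus its noise-free map
fx_planted <- function(n_res = 30, seed = 99, sigma = 0.7, spacing = 0.3,
                       noise_sd = 0, map_seed = 7, library = fx_bench_library()) {
  m0 <- synthetic_chain(n_res, seed = seed)
  pl <- plant_library_rotamers(m0, library, seed = seed + 1)
  model <- assign_cell(pl$model, padding = 6)
  map <- synthesize_map(model, sigma = sigma, spacing = spacing,
                        noise_sd = noise_sd, seed = map_seed)
  list(model = model, map = map, truth = pl$truth)
}

# random energy-table instance for the combinatorial engines
fx_rand_tables <- function(n, kmax, pair_density = 0.8, scale = 3) {
  k <- sample(2:kmax, n, replace = TRUE)
  E <- lapply(k, function(kk) round(runif(kk, 0, scale), 3))
  pair <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) if (runif(1) < pair_density)
    pair[[paste0(i, "|", j)]] <-
      matrix(round(runif(k[i] * k[j], -scale, scale), 3), k[i], k[j])
  energy_tables(E, pair)
}

# random clash-constrained instance (energies + synthetic clash graph)
fx_rand_clash_instance <- function(n_max = 5, k_max = 6, p_clash = 0.35) {
  n <- sample(2:n_max, 1)
  k <- sample(2:k_max, n, replace = TRUE)
  E <- lapply(k, function(kk) sort(round(runif(kk, 0, 5), 3)))
  cl <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    cl[[paste0(i, "|", j)]] <- matrix(runif(k[i] * k[j]) < p_clash, k[i], k[j])
  clash_fun <- function(i, s, j, t) {
    m <- cl[[paste0(min(i, j), "|", max(i, j))]]
    if (i < j) m[s, t] else m[t, s]
  }
  list(n = n, k = k, E = E, clash_fun = clash_fun)
}

# enumerate a clash-constrained instance: optimal feasible energy (NA if
# none) plus the full grid/feasibility for reuse
fx_enumerate_clash <- function(inst) {
  grid <- as.matrix(expand.grid(lapply(inst$k, seq_len)))
  feas <- apply(grid, 1, function(a) {
    for (i in seq_len(inst$n - 1)) for (j in (i + 1):inst$n)
      if (inst$clash_fun(i, a[i], j, a[j])) return(FALSE)
    TRUE
  })
  en <- apply(grid, 1, function(a)
    sum(vapply(seq_len(inst$n), function(i) inst$E[[i]][a[i]], numeric(1))))
  list(grid = grid, feasible = feas, energy = en,
       optimum = if (any(feas)) min(en[feas]) else NA_real_)
}

# the worked graph-search example: three residues v, w, u
fx_worked_example <- function() {
  E <- list(v = c(0, 5, 8), w = c(0, 0, 2, 7, 9), u = c(0, 1, 3, 8))
  clash <- list()
  clash[["1|2"]] <- matrix(FALSE, 3, 5)
  clash[["1|2"]][1, 1:3] <- TRUE   # v1 clashes w1..w3
  clash[["1|2"]][3, 1] <- TRUE     # v3 clashes w1
  clash[["1|3"]] <- matrix(FALSE, 3, 4)
  clash[["1|3"]][2, 1:3] <- TRUE   # v2 clashes u1..u3
  clash[["2|3"]] <- matrix(FALSE, 5, 4)
  clash[["2|3"]][4, 1:2] <- TRUE   # w4 clashes u1, u2
  clash_fun <- function(i, s, j, t) {
    m <- clash[[paste0(min(i, j), "|", max(i, j))]]
    if (i < j) m[s, t] else m[t, s]
  }
  list(E = E, clash_fun = clash_fun)
}

# random crystallographic instance for collision detection: a few short
# side chains in a small P1 cell so periodic contacts occur
fx_collision_instance <- function(n_res = 4, cell_edge = 14) {
  cell <- unit_cell(cell_edge, cell_edge + 2, cell_edge - 2)
  placed <- lapply(seq_len(n_res), function(i) {
    ctr <- runif(3, 0, cell_edge)
    coords <- sweep(matrix(rnorm(12, 0, 1.4), 4, 3), 2, ctr, "+")
    rownames(coords) <- c("CB", "CG", "CD", "CE")
    list(res_idx = i, coords = coords, elements = c("C", "C", "C", "C"))
  })
  list(placed = placed, cell = cell)
}
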