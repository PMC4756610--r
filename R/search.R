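# Combinatorial search engines over per-residue conformation sets:
#  - stage 2: best-first search over a directed graph with horizontal
#    (next-ranked conformation) and vertical (best compatible partner)
#    edges, resolving steric collisions under the simplified energy;
#  - stage 3: dead-end elimination (Goldstein, single/two-residue split,
#    pairs) followed by exact A* over residual interaction clusters;
#  - a brute-force enumerator serving as the optimality oracle.
#
# All functions here operate on plain energy tables so they can be
# exercised on synthetic instances independently of any structure.

.elim_eps <- 1e-9

#' Energy tables for one fitting problem
#'
#' @param E list per residue of self-energy vectors (one value per
#'   conformation)
#' @param pair named list of pairwise energy matrices, element `"i|j"`
#'   (i < j) holding the k_i x k_j matrix E_pair; absent pairs are
#'   non-interacting (zero)
#' @return object of class `energy_tables`
#' @export
energy_tables <- function(E, pair = list()) {
  stopifnot(is.list(E), all(vapply(E, is.numeric, logical(1))))
  structure(list(E = E, pair = pair, n = length(E),
                 k = vapply(E, length, integer(1))),
            class = "energy_tables")
}

pair_key <- function(i, j) paste0(min(i, j), "|", max(i, j))

# E_pair(i conf s, j conf t); zero when the pair is absent.
ep_lookup <- function(tables, i, s, j, t) {
  m <- tables$pair[[pair_key(i, j)]]
  if (is.null(m)) return(0)
  if (i < j) m[s, t] else m[t, s]
}

# full k_i x k_j pair matrix oriented (i rows, j cols)
ep_matrix <- function(tables, i, j) {
  m <- tables$pair[[pair_key(i, j)]]
  if (is.null(m)) return(matrix(0, tables$k[i], tables$k[j]))
  if (i < j) m else t(m)
}

#' Total energy of a joint assignment (self plus pairwise terms)
#' @param tables an `energy_tables`
#' @param assignment integer vector of conformation indices
#' @return energy
#' @export
total_energy <- function(tables, assignment) {
  e <- sum(vapply(seq_len(tables$n), function(i) tables$E[[i]][assignment[i]],
                  numeric(1)))
  for (key in names(tables$pair)) {
    ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    e <- e + tables$pair[[key]][assignment[ij[1]], assignment[ij[2]]]
  }
  e
}

#' Exhaustive global-minimum search (test oracle)
#'
#' Enumerates every joint assignment of the energy tables and returns the
#' global minimum-energy conformation; ties are broken toward the
#' lexicographically smallest assignment.
#'
#' @param tables an `energy_tables`
#' @param bound refuse enumeration beyond this many assignments
#' @return list with `assignment` (integer vector) and `energy`
#' @export
brute_force_gmec <- function(tables, bound = 1e7) {
  sz <- prod(as.numeric(tables$k))
  if (sz > bound) stop("enumeration bound exceeded: ", sz, " assignments")
  n <- tables$n
  # grid with the FIRST residue varying slowest -> row order is
  # lexicographic in the assignment vector
  grid <- as.matrix(rev(expand.grid(rev(lapply(tables$k, seq_len)))))
  colnames(grid) <- NULL
  e <- numeric(nrow(grid))
  for (i in seq_len(n)) e <- e + tables$E[[i]][grid[, i]]
  for (key in names(tables$pair)) {
    ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    m <- tables$pair[[key]]
    e <- e + m[cbind(grid[, ij[1]], grid[, ij[2]])]
  }
  best <- which.min(e)  # first index among ties = lexicographically smallest
  list(assignment = as.integer(grid[best, ]), energy = e[best])
}

# --- stage 1 ---------------------------------------------------------------

#' Stage I: independent per-residue selection with lazy clash checks
#'
#' For each residue, conformations are examined in increasing simplified
#' self-energy order and checked against the fixed environment only when
#' selected (lazy evaluation); the first non-clashing conformation wins.
#' If every conformation clashes, the lowest-energy one is kept and the
#' residue is flagged as an unfittable candidate.
#'
#' @param E list per residue of simplified self-energy vectors
#' @param env_clash function(i, s) -> TRUE if conformation s of residue i
#'   clashes with the fixed environment (backbone, CB, heteroatoms)
#' @return list with `conf` (selected index per residue), `ok` (logical:
#'   clash-free), `checks` (clash evaluations per residue) and `feasible`
#'   (list of clash-free conformation indices, ranked, populated lazily)
#' @export
stage1_fit <- function(E, env_clash) {
  n <- length(E)
  conf <- integer(n); ok <- logical(n); checks <- integer(n)
  for (i in seq_len(n)) {
    if (!length(E[[i]])) stop("residue ", i, " has no conformations in the library")
    ord <- order(E[[i]])
    sel <- NA_integer_
    for (s in ord) {
      checks[i] <- checks[i] + 1L
      if (!env_clash(i, s)) { sel <- s; break }
    }
    if (is.na(sel)) {
      conf[i] <- ord[1]; ok[i] <- FALSE
    } else {
      conf[i] <- sel; ok[i] <- TRUE
    }
  }
  list(conf = conf, ok = ok, checks = checks)
}

# --- stage 2 ---------------------------------------------------------------

#' Stage II: collision resolution by best-first graph search
#'
#' Resolves steric collisions among the stage-I conformations under the
#' simplified energy. Nodes carry a joint assignment plus a focus
#' residue; each node offers at most two moves: the horizontal edge
#' advances the focus residue to its next-ranked conformation, and the
#' vertical edge binds the focus's clash partner to its best compatible
#' (lowest-energy non-clashing, at or above its current rank)
#' conformation, shifting the focus to the partner. Nodes are expanded in
#' order of accumulated cost g (energy above the unconstrained minimum;
#' ties: fewer clashes, then lexicographic assignment); a collision-free
#' node is terminal, and the search stops when every open node's
#' estimated total cost f = g + h (h: minimum of the two move costs,
#' which never overestimates the remaining cost) reaches the best
#' terminal's cost. The result is the collision-free assignment
#' minimizing the total simplified energy.
#'
#' @param E list per residue of simplified self-energy vectors (only
#'   environment-feasible conformations should be included)
#' @param clash_fun function(i, s, j, t) -> TRUE if conformation s of
#'   residue i clashes with conformation t of residue j (callers embed
#'   symmetry-image checks here)
#' @param max_expansions safety cap on node expansions
#' @return list with `conf` (selected index per residue), `cost`,
#'   `optimal` (logical), `unfittable` (residue indices in unresolved
#'   clashes), `expansions` (data frame log: focus residue, conformation,
#'   g) and `n_expanded`
#' @export
stage2_resolve <- function(E, clash_fun, max_expansions = 100000) {
  n <- length(E)
  ord <- lapply(E, order)                 # rank -> original conf index
  Es <- lapply(seq_len(n), function(i) E[[i]][ord[[i]]])
  gap <- lapply(Es, function(v) v - v[1])
  k <- vapply(E, length, integer(1))
  memo <- new.env(parent = emptyenv())
  clash_rank <- function(i, ri, j, rj) {
    key <- paste(i, ri, j, rj)
    v <- memo[[key]]
    if (is.null(v)) {
      v <- isTRUE(clash_fun(i, ord[[i]][ri], j, ord[[j]][rj]))
      memo[[key]] <- v
    }
    v
  }
  clashes_of <- function(a) {
    out <- list()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (clash_rank(i, a[i], j, a[j])) out[[length(out) + 1L]] <- c(i, j)
    }
    out
  }
  g_of <- function(a) sum(vapply(seq_len(n), function(i) gap[[i]][a[i]], numeric(1)))

  root <- rep(1L, n)
  root_cl <- clashes_of(root)
  empty_log <- data.frame(residue = integer(0), conf = integer(0), g = numeric(0))
  result <- function(a, cost, optimal, unfit, log, expanded) {
    list(conf = vapply(seq_len(n), function(i) ord[[i]][a[i]], integer(1)),
         ranks = a, cost = cost, optimal = optimal,
         unfittable = unfit, expansions = log, n_expanded = expanded)
  }
  if (!length(root_cl)) {
    return(result(root, 0, TRUE, integer(0), empty_log, 0L))
  }

  # open list
  keys <- character(0); G <- numeric(0); Fv <- numeric(0); NCl <- integer(0)
  states <- list()
  seen <- new.env(parent = emptyenv())
  node_moves <- function(a, focus, cl) {
    # refocus onto a clashing residue if needed (lowest pair first)
    inpair <- which(vapply(cl, function(p) focus %in% p, logical(1)))
    if (!length(inpair)) { focus <- cl[[1]][1]; inpair <- which(vapply(cl, function(p) focus %in% p, logical(1))) }
    partners <- sort(unique(unlist(lapply(cl[inpair], function(p) setdiff(p, focus)))))
    w <- partners[1]
    moves <- list()
    if (a[focus] < k[focus]) {
      b <- a; b[focus] <- a[focus] + 1L
      moves[[length(moves) + 1L]] <- list(a = b, focus = focus,
                                          dg = gap[[focus]][b[focus]] - gap[[focus]][a[focus]])
    }
    r <- a[w] + 1L
    while (r <= k[w]) {
      if (!clash_rank(focus, a[focus], w, r)) break
      r <- r + 1L
    }
    if (r <= k[w]) {
      b <- a; b[w] <- r
      moves[[length(moves) + 1L]] <- list(a = b, focus = w,
                                          dg = gap[[w]][r] - gap[[w]][a[w]])
    }
    moves
  }
  push <- function(a, focus, cl) {
    key <- paste(sprintf("%04d", c(a, focus)), collapse = ",")
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    g <- g_of(a)
    h <- if (!length(cl)) 0 else {
      mv <- node_moves(a, focus, cl)
      if (!length(mv)) Inf else min(vapply(mv, function(m) m$dg, numeric(1)))
    }
    keys[length(keys) + 1L] <<- key
    G[length(G) + 1L] <<- g
    Fv[length(Fv) + 1L] <<- g + h
    NCl[length(NCl) + 1L] <<- length(cl)
    states[[length(states) + 1L]] <<- list(a = a, focus = focus, cl = cl)
  }
  push(root, root_cl[[1]][1], root_cl)

  best_cost <- Inf; best_a <- NULL
  best_effort <- list(a = root, ncl = length(root_cl), g = 0)
  log_res <- integer(0); log_conf <- integer(0); log_g <- numeric(0)
  log_h <- numeric(0); log_ranks <- character(0)
  expanded <- 0L
  while (length(keys)) {
    # pop: lowest g, then fewer clashes, then lexicographic assignment key
    o <- order(G, NCl, keys)[1]
    st <- states[[o]]; g <- G[o]; h <- Fv[o] - g
    keys <- keys[-o]; G <- G[-o]; Fv <- Fv[-o]; NCl <- NCl[-o]
    states[o] <- NULL
    if (g >= best_cost) next
    expanded <- expanded + 1L
    log_res <- c(log_res, st$focus)
    log_conf <- c(log_conf, ord[[st$focus]][st$a[st$focus]])
    log_g <- c(log_g, g)
    log_h <- c(log_h, h)
    log_ranks <- c(log_ranks, paste(st$a, collapse = ","))
    if (!length(st$cl)) {
      if (g < best_cost) { best_cost <- g; best_a <- st$a }
    } else {
      if (length(st$cl) < best_effort$ncl ||
          (length(st$cl) == best_effort$ncl && g < best_effort$g)) {
        best_effort <- list(a = st$a, ncl = length(st$cl), g = g)
      }
      for (m in node_moves(st$a, st$focus, st$cl)) {
        cl2 <- clashes_of(m$a)
        push(m$a, m$focus, cl2)
      }
    }
    if (expanded >= max_expansions) break
    if (length(Fv) && min(Fv) >= best_cost) break
  }
  log <- data.frame(residue = log_res, conf = log_conf, g = log_g, h = log_h,
                    ranks = log_ranks, stringsAsFactors = FALSE)
  if (!is.null(best_a)) {
    return(result(best_a, best_cost, TRUE, integer(0), log, expanded))
  }
  # no collision-free assignment found: best effort, flag clash residues
  a <- best_effort$a
  unfit <- sort(unique(unlist(clashes_of(a))))
  result(a, g_of(a), FALSE, unfit, log, expanded)
}

# --- dead-end elimination --------------------------------------------------

# Per-competitor interaction bounds: for residue i and conformations
# (r, t), the matrix of min_u [E_pair(i,r,j,u) - E_pair(i,t,j,u)] over
# alive conformations u of every other residue j.
.dee_contrib <- function(tables, alive, i, r, t) {
  vapply(seq_len(tables$n), function(j) {
    if (j == i) return(0)
    au <- which(alive[[j]])
    m <- ep_matrix(tables, i, j)
    min(m[r, au] - m[t, au])
  }, numeric(1))
}

#' Goldstein dead-end elimination for one residue
#'
#' Eliminates every conformation r of residue i for which some competitor
#' t satisfies `E(r) - E(t) + sum_j min_u [E_pair(r,u) - E_pair(t,u)] > 0`
#' (r cannot be part of the global minimum).
#'
#' @param tables an `energy_tables`
#' @param alive list of logical vectors (surviving conformations)
#' @param i residue index
#' @return indices of newly eliminated conformations of residue i
#' @export
dee_goldstein <- function(tables, alive, i) {
  ar <- which(alive[[i]])
  if (length(ar) < 2) return(integer(0))
  out <- integer(0)
  for (r in ar) {
    for (t in setdiff(ar, c(r, out))) {
      bound <- tables$E[[i]][r] - tables$E[[i]][t] +
        sum(.dee_contrib(tables, alive, i, r, t))
      if (bound > .elim_eps) { out <- c(out, r); break }
    }
  }
  out
}

#' Single-residue split dead-end elimination
#'
#' Splits the conformation space on one other residue k: conformation r
#' of residue i is eliminated when, for every conformation v of k, some
#' competitor t(v) makes the Goldstein-style bound (with k's interaction
#' taken at v rather than at its minimum) positive.
#'
#' @inheritParams dee_goldstein
#' @return indices of newly eliminated conformations of residue i
#' @export
dee_split_single <- function(tables, alive, i) {
  ar <- which(alive[[i]])
  if (length(ar) < 2) return(integer(0))
  others <- setdiff(which(vapply(alive, any, logical(1))), i)
  out <- integer(0)
  for (r in ar) {
    comp <- setdiff(ar, r)
    contrib <- lapply(comp, function(t) .dee_contrib(tables, alive, i, r, t))
    eliminated <- FALSE
    for (k in others) {
      av <- which(alive[[k]])
      mk <- ep_matrix(tables, i, k)
      okv <- vapply(av, function(v) {
        any(vapply(seq_along(comp), function(ti) {
          t <- comp[ti]
          # Goldstein bound with k's min term replaced by the split cell
          base_k <- tables$E[[i]][r] - tables$E[[i]][t] +
            sum(contrib[[ti]]) - contrib[[ti]][k]
          base_k + (mk[r, v] - mk[t, v]) > .elim_eps
        }, logical(1)))
      }, logical(1))
      if (all(okv)) { out <- c(out, r); eliminated <- TRUE; break }
    }
    if (eliminated) next
  }
  out
}

#' Two-residue ("magic bullet") split dead-end elimination
#'
#' Splits on a pair of witness residues (k1, k2): conformation r of
#' residue i is eliminated when for every joint conformation cell
#' (v1, v2) some competitor makes the split Goldstein bound positive.
#' Strictly stronger than the single split; applied last in the
#' elimination cycle.
#'
#' @inheritParams dee_goldstein
#' @return indices of newly eliminated conformations of residue i
#' @export
dee_split_magic_bullet <- function(tables, alive, i) {
  ar <- which(alive[[i]])
  if (length(ar) < 2) return(integer(0))
  others <- setdiff(which(vapply(alive, any, logical(1))), i)
  if (length(others) < 2) return(integer(0))
  out <- integer(0)
  for (r in ar) {
    comp <- setdiff(ar, r)
    contrib <- lapply(comp, function(t) .dee_contrib(tables, alive, i, r, t))
    base_full <- vapply(seq_along(comp), function(ti)
      tables$E[[i]][r] - tables$E[[i]][comp[ti]] + sum(contrib[[ti]]), numeric(1))
    eliminated <- FALSE
    for (k1i in seq_len(length(others) - 1)) {
      for (k2i in (k1i + 1):length(others)) {
        k1 <- others[k1i]; k2 <- others[k2i]
        a1 <- which(alive[[k1]]); a2 <- which(alive[[k2]])
        m1 <- ep_matrix(tables, i, k1); m2 <- ep_matrix(tables, i, k2)
        all_cells <- TRUE
        for (v1 in a1) {
          if (!all_cells) break
          for (v2 in a2) {
            hit <- FALSE
            for (ti in seq_along(comp)) {
              t <- comp[ti]
              b <- base_full[ti] - contrib[[ti]][k1] - contrib[[ti]][k2] +
                (m1[r, v1] - m1[t, v1]) + (m2[r, v2] - m2[t, v2])
              if (b > .elim_eps) { hit <- TRUE; break }
            }
            if (!hit) { all_cells <- FALSE; break }
          }
        }
        if (all_cells) { out <- c(out, r); eliminated <- TRUE; break }
      }
      if (eliminated) break
    }
  }
  out
}

#' Goldstein dead-end elimination on conformation pairs
#'
#' Flags pairs (r of i, s of j) that cannot occur together in the global
#' minimum: some competitor pair (t, u) satisfies the pairwise Goldstein
#' bound. A conformation is eliminated outright when all of its pairs
#' with some residue are dead.
#'
#' @inheritParams dee_goldstein
#' @param j second residue index (i < j)
#' @param dead_pairs optional existing k_i x k_j logical matrix
#' @return updated k_i x k_j logical matrix of dead pairs
#' @export
dee_pairs_goldstein <- function(tables, alive, i, j, dead_pairs = NULL) {
  ai <- which(alive[[i]]); aj <- which(alive[[j]])
  if (is.null(dead_pairs)) dead_pairs <- matrix(FALSE, tables$k[i], tables$k[j])
  if (length(ai) < 2 && length(aj) < 2) return(dead_pairs)
  others <- setdiff(which(vapply(alive, any, logical(1))), c(i, j))
  mij <- ep_matrix(tables, i, j)
  E2 <- outer(tables$E[[i]], tables$E[[j]], "+") + mij
  # min over v of the combined interaction difference, per residue k
  comb_min <- function(r, s, t, u) {
    if (!length(others)) return(0)
    sum(vapply(others, function(kk) {
      av <- which(alive[[kk]])
      mi <- ep_matrix(tables, i, kk); mj <- ep_matrix(tables, j, kk)
      min(mi[r, av] + mj[s, av] - mi[t, av] - mj[u, av])
    }, numeric(1)))
  }
  cand <- expand.grid(t = ai, u = aj)
  for (r in ai) for (s in aj) {
    if (dead_pairs[r, s]) next
    for (ci in seq_len(nrow(cand))) {
      t <- cand$t[ci]; u <- cand$u[ci]
      if ((t == r && u == s) || dead_pairs[t, u]) next
      b <- E2[r, s] - E2[t, u] + comb_min(r, s, t, u)
      if (b > .elim_eps) { dead_pairs[r, s] <- TRUE; break }
    }
  }
  dead_pairs
}

run_dee_cycle <- function(tables, alive, criteria = c("goldstein", "split", "magic")) {
  log <- list()
  for (crit in criteria) {
    fun <- switch(crit, goldstein = dee_goldstein, split = dee_split_single,
                  magic = dee_split_magic_bullet)
    repeat {
      removed <- 0L
      for (i in seq_len(tables$n)) {
        if (sum(alive[[i]]) < 2) next
        el <- fun(tables, alive, i)
        if (length(el)) {
          alive[[i]][el] <- FALSE
          removed <- removed + length(el)
          log[[length(log) + 1L]] <- data.frame(criterion = crit, residue = i,
                                                eliminated = length(el))
        }
      }
      if (removed == 0L) break
    }
  }
  list(alive = alive, log = if (length(log)) do.call(rbind, log) else
    data.frame(criterion = character(0), residue = integer(0), eliminated = integer(0)))
}

# connected components of the interaction graph among `residues`
# (edges where any surviving pair energy exceeds the sparsity threshold)
interaction_clusters <- function(tables, alive, residues, eps = 1e-6) {
  if (!length(residues)) return(list())
  parent <- stats::setNames(residues, residues)
  findp <- function(x) {
    r <- x
    while (parent[[as.character(r)]] != r) r <- parent[[as.character(r)]]
    r
  }
  for (a in seq_along(residues)) {
    for (b in seq_len(a - 1L)) {
      i <- residues[b]; j <- residues[a]
      m <- ep_matrix(tables, i, j)
      sub <- m[which(alive[[i]]), which(alive[[j]]), drop = FALSE]
      if (any(abs(sub) > eps)) {
        ra <- findp(i); rb <- findp(j)
        if (ra != rb) parent[[as.character(max(ra, rb))]] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(residues, findp, numeric(1))
  lapply(unique(roots), function(r) residues[roots == r])
}

# Exact A* over one interaction cluster (classic rotamer-space A*:
# residues assigned in order; h sums per-unassigned-residue minima of
# self + interactions with the assigned prefix + minimal interactions
# within the unassigned suffix -- an admissible lower bound).
astar_cluster <- function(tables, alive, cluster, max_expansions = 200000) {
  m <- length(cluster)
  aliveix <- lapply(cluster, function(i) which(alive[[i]]))
  pm <- list()
  for (a in seq_len(m)) for (b in seq_len(m)) if (a != b)
    pm[[paste(a, b)]] <- ep_matrix(tables, cluster[a], cluster[b])
  selfE <- lapply(seq_len(m), function(a) tables$E[[cluster[a]]])
  hmin <- function(prefix) {
    # lower bound for completing `prefix` (length q < m)
    q <- length(prefix)
    if (q == m) return(0)
    tot <- 0
    for (a in (q + 1L):m) {
      best <- Inf
      for (s in aliveix[[a]]) {
        v <- selfE[[a]][s]
        if (q) for (b in seq_len(q)) v <- v + pm[[paste(a, b)]][s, prefix[b]]
        if (a < m) for (b in (a + 1L):m) v <- v + min(pm[[paste(a, b)]][s, aliveix[[b]]])
        best <- min(best, v)
      }
      tot <- tot + best
    }
    tot
  }
  g_of <- function(prefix) {
    q <- length(prefix)
    v <- 0
    for (a in seq_len(q)) {
      v <- v + selfE[[a]][prefix[a]]
      if (a > 1) for (b in seq_len(a - 1L)) v <- v + pm[[paste(a, b)]][prefix[a], prefix[b]]
    }
    v
  }
  open_g <- numeric(0); open_f <- numeric(0); open_states <- list()
  push <- function(prefix) {
    g <- g_of(prefix)
    open_g[length(open_g) + 1L] <<- g
    open_f[length(open_f) + 1L] <<- g + hmin(prefix)
    open_states[[length(open_states) + 1L]] <<- prefix
  }
  push(integer(0))
  expanded <- 0L
  while (length(open_f)) {
    o <- order(open_f, open_g)[1]
    prefix <- open_states[[o]]
    open_g <- open_g[-o]; open_f <- open_f[-o]; open_states[o] <- NULL
    if (length(prefix) == m) {
      return(list(assignment = prefix, energy = g_of(prefix), expansions = expanded))
    }
    expanded <- expanded + 1L
    if (expanded > max_expansions) break
    nxt <- length(prefix) + 1L
    for (s in aliveix[[nxt]]) push(c(prefix, s))
  }
  # expansion cap hit: fall back to exhaustive enumeration over survivors
  E_sub <- lapply(seq_len(m), function(a) {
    e <- selfE[[a]]; e[setdiff(seq_along(e), aliveix[[a]])] <- Inf; e
  })
  pair_sub <- list()
  for (a in seq_len(m - 1)) for (b in (a + 1):m)
    pair_sub[[pair_key(a, b)]] <- pm[[paste(a, b)]]
  bf <- brute_force_gmec(energy_tables(E_sub, pair_sub))
  list(assignment = bf$assignment, energy = bf$energy, expansions = expanded)
}

#' Stage III: full dead-end elimination with exact cluster resolution
#'
#' Runs the elimination cycle (Goldstein, then single-residue split, then
#' two-residue split, each iterated to a fixed point), clusters the
#' undetermined residues by the presence of pairwise interactions, and
#' resolves each cluster exactly: clusters below `astar_threshold`
#' residues by A*, larger clusters by a pairs-elimination cycle followed
#' by repeated singles elimination and A*. Returns the global minimum of
#' the total energy over the surviving conformations.
#'
#' @param tables an `energy_tables` (full self-energies)
#' @param astar_threshold cluster size below which A* is used directly
#' @return list with `assignment`, `energy`, `alive`, `dee_log` and
#'   `clusters`
#' @export
stage3_refine <- function(tables, astar_threshold = 15) {
  n <- tables$n
  alive <- lapply(tables$k, function(kk) rep(TRUE, kk))
  cyc <- run_dee_cycle(tables, alive)
  alive <- cyc$alive
  assignment <- integer(n)
  fixed <- vapply(alive, sum, integer(1)) == 1L
  assignment[fixed] <- vapply(which(fixed), function(i) which(alive[[i]]), integer(1))
  undet <- which(!fixed)
  # fold fixed residues' pair interactions into the self-energies of the rest
  tbl2 <- tables
  for (i in undet) {
    for (j in which(fixed)) {
      m <- ep_matrix(tables, i, j)
      tbl2$E[[i]] <- tbl2$E[[i]] + m[, assignment[j]]
    }
  }
  clusters <- interaction_clusters(tbl2, alive, undet)
  info <- list()
  for (cl in clusters) {
    if (length(cl) == 1L) {
      i <- cl[1]
      cand <- which(alive[[i]])
      assignment[i] <- cand[which.min(tbl2$E[[i]][cand])]
      next
    }
    alive_cl <- alive
    if (length(cl) >= astar_threshold) {
      # pairs-elimination cycle, then repeat singles, then A*
      for (ci in seq_len(length(cl) - 1)) for (cj in (ci + 1):length(cl)) {
        i <- cl[ci]; j <- cl[cj]
        dp <- dee_pairs_goldstein(tbl2, alive_cl, i, j)
        # conformations whose every surviving pair with j is dead die too
        for (r in which(alive_cl[[i]]))
          if (all(dp[r, which(alive_cl[[j]])])) alive_cl[[i]][r] <- FALSE
        for (s in which(alive_cl[[j]]))
          if (all(dp[which(alive_cl[[i]]), s])) alive_cl[[j]][s] <- FALSE
      }
      cyc2 <- run_dee_cycle(tbl2, alive_cl, criteria = "goldstein")
      alive_cl <- cyc2$alive
    }
    sol <- astar_cluster(tbl2, alive_cl, cl)
    assignment[cl] <- sol$assignment
    info[[length(info) + 1L]] <- list(residues = cl, expansions = sol$expansions)
  }
  list(assignment = assignment, energy = total_energy(tables, assignment),
       alive = alive, dee_log = cyc$log, clusters = info)
}
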