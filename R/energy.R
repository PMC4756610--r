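# Energy terms: density-relative and frequency-relative self-energy,
# nonbonded (Coulomb + Lennard-Jones 12-6, united-atom) pair and backbone
# interactions, polar-hydrogen variants and amide/imidazole flips.

.pkg_extdata <- function(name) {
  p <- system.file("extdata", name, package = "rotafit")
  if (!nzchar(p)) p <- file.path("inst", "extdata", name)  # pre-install fallback
  if (!file.exists(p)) stop("bundled data file not found: ", name)
  p
}

.nb_tables <- local({
  cache <- new.env()
  function() {
    if (!is.null(cache$cls)) return(list(cls = cache$cls, map = cache$map))
    cls <- utils::read.table(.pkg_extdata("nonbonded_params.txt"), header = FALSE,
                             col.names = c("class", "sigma", "epsilon", "charge"),
                             stringsAsFactors = FALSE)
    rownames(cls) <- cls$class
    map <- utils::read.table(.pkg_extdata("atom_classes.txt"), header = FALSE,
                             col.names = c("res_type", "atom", "class"),
                             stringsAsFactors = FALSE)
    cache$cls <- cls
    cache$map <- stats::setNames(map$class, paste(map$res_type, map$atom))
    list(cls = cache$cls, map = cache$map)
  }
})

# sigma/epsilon/charge for atoms of one residue type; element-based
# fallback for unmapped names (errors when strict).
atom_nb_params <- function(res_type, atom_names, strict = TRUE) {
  tb <- .nb_tables()
  cl <- tb$map[paste(res_type, atom_names)]
  generic <- tb$map[paste("*", atom_names)]
  cl[is.na(cl)] <- generic[is.na(cl)]
  if (anyNA(cl)) {
    if (strict) stop("no nonbonded class for atom(s): ",
                     paste(atom_names[is.na(cl)], collapse = ", "), " of ", res_type)
    cl[is.na(cl)] <- "CH2"
  }
  tb$cls[cl, c("sigma", "epsilon", "charge")]
}

#' Energy-function parameters
#'
#' @param w_d density-fit weight
#' @param w_p rotamer-frequency weight
#' @param density a `density_params`
#' @param dielectric distance-independent dielectric constant
#' @param cutoff nonbonded distance cutoff, Angstrom
#' @param p_cap cap on the frequency term -log(p/p_max) for unseen
#'   conformations (p = 0)
#' @param include_symmetry include crystallographic images in backbone and
#'   pairwise interactions
#' @param repulsion_cap upper bound on any single atom-pair nonbonded
#'   energy, kcal/mol (soft repulsion: discrete rotamers tolerate small
#'   overlaps; hard steric exclusion is handled by the clash model)
#' @return object of class `energy_params`
#' @export
energy_params <- function(w_d = 1, w_p = 0.05, density = density_params(),
                          dielectric = 4, cutoff = 8, p_cap = 20,
                          include_symmetry = TRUE, repulsion_cap = 10) {
  stopifnot(w_d >= 0, w_p >= 0, dielectric > 0, cutoff > 0, repulsion_cap > 0)
  structure(list(w_d = w_d, w_p = w_p, density = density,
                 dielectric = dielectric, cutoff = cutoff, p_cap = p_cap,
                 include_symmetry = include_symmetry,
                 repulsion_cap = repulsion_cap),
            class = "energy_params")
}

.coulomb_k <- 332.06  # kcal mol^-1 A e^-2

# Nonbonded energy between two atom sets (united-atom LJ 12-6 with
# geometric combining rules + Coulomb with constant dielectric), zero
# beyond the cutoff. The per-pair energy is capped at `repulsion_cap` so
# that sub-Angstrom contact imprecision of discrete rotamers cannot
# dominate the density term (soft-repulsion convention of side-chain
# packing programs); steric exclusion proper is the clash model's job.
nonbonded_energy <- function(pa, xa, pb, xb, params) {
  if (!nrow(xa) || !nrow(xb)) return(0)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 1e-4] <- 1e-4
  within <- d2 <= params$cutoff^2
  if (!any(within)) return(0)
  sig <- sqrt(outer(pa$sigma, pb$sigma))
  eps <- sqrt(outer(pa$epsilon, pb$epsilon))
  qq <- outer(pa$charge, pb$charge)
  s6 <- (sig^2 / d2)^3
  e <- 4 * eps * (s6^2 - s6) + .coulomb_k * qq / (params$dielectric * sqrt(d2))
  e <- pmin(e, params$repulsion_cap)
  sum(e[within])
}

#' Pairwise nonbonded interaction energy of two placed side chains
#'
#' Only the nonbonded term (Coulomb + Lennard-Jones) is used for
#' side-chain/side-chain interactions. Symmetric in its arguments; zero
#' when all atom pairs lie beyond the cutoff.
#'
#' @param res_type_a,res_type_b residue types
#' @param coords_a,coords_b placed coordinate matrices (global frame,
#'   atom-name rownames; polar-H variants resolved)
#' @param params an `energy_params`
#' @return energy, kcal/mol
#' @export
e_pair <- function(res_type_a, coords_a, res_type_b, coords_b,
                   params = energy_params()) {
  pa <- atom_nb_params(res_type_a, rownames(coords_a))
  pb <- atom_nb_params(res_type_b, rownames(coords_b))
  nonbonded_energy(pa, coords_a, pb, coords_b, params)
}

#' Backbone environment of a model
#'
#' Main-chain atoms (plus amide hydrogens built on the fly, OXT, and CB
#' of every residue) with residue bookkeeping for the bonded-exclusion
#' rule; the fixed environment for clash checks and backbone energies.
#' @param model a `protein_model`
#' @param add_amide_h place amide hydrogens
#' @return data frame: res_idx, name, res_type, x, y, z
#' @export
backbone_environment <- function(model, add_amide_h = TRUE) {
  rows <- list()
  prevC <- NULL
  for (i in seq_along(model$residues)) {
    res <- model$residues[[i]]
    pos <- residue_atom_pos(res, c("N", "CA", "C", "O", "CB", "OXT"))
    for (nm in rownames(pos)) {
      if (anyNA(pos[nm, ])) next
      rows[[length(rows) + 1L]] <- data.frame(
        res_idx = i, name = nm, res_type = res$res_type,
        x = pos[nm, 1], y = pos[nm, 2], z = pos[nm, 3], stringsAsFactors = FALSE)
    }
    if (add_amide_h && !is.null(prevC) && !anyNA(pos["N", ]) && !anyNA(pos["CA", ]) &&
        res$res_type != "PRO") {
      h <- pos["N", ] + 1.0 * vunit(vunit(pos["N", ] - prevC) +
                                    vunit(pos["N", ] - pos["CA", ]))
      rows[[length(rows) + 1L]] <- data.frame(
        res_idx = i, name = "H", res_type = res$res_type,
        x = h[1], y = h[2], z = h[3], stringsAsFactors = FALSE)
    }
    prevC <- if (anyNA(pos["C", ])) NULL else pos["C", ]
  }
  do.call(rbind, rows)
}

# Environment rows excluded for residue i's side chain: the residue's own
# main chain (1-2/1-3/1-4 bonded), the preceding residue's C/O and the
# following residue's N/H.
env_exclusion <- function(env, i) {
  own <- env$res_idx == i
  prev <- env$res_idx == i - 1 & env$name %in% c("C", "O")
  nxt <- env$res_idx == i + 1 & env$name %in% c("N", "H")
  own | prev | nxt
}

#' Interaction energy of a placed side chain with the protein backbone
#'
#' Nonbonded energy between the side-chain atoms and all main-chain
#' atoms, amide hydrogens and CB atoms of the model (optionally including
#' crystallographic images within the cutoff), excluding the residue's
#' own bonded backbone neighborhood.
#'
#' @param res_type residue type of the side chain
#' @param coords placed side-chain coordinates (atom-name rownames)
#' @param model the `protein_model` providing the fixed backbone
#' @param res_idx index of the residue the side chain belongs to
#' @param params an `energy_params`
#' @param env precomputed [backbone_environment()] (recomputed if NULL)
#' @return energy, kcal/mol
#' @export
e_backbone <- function(res_type, coords, model, res_idx,
                       params = energy_params(), env = NULL) {
  if (is.null(env)) env <- backbone_environment(model)
  keep <- env[!env_exclusion(env, res_idx), , drop = FALSE]
  if (!nrow(keep)) return(0)
  xb <- as.matrix(keep[, c("x", "y", "z")])
  pb <- do.call(rbind, lapply(seq_len(nrow(keep)), function(j)
    atom_nb_params(keep$res_type[j], keep$name[j])))
  pa <- atom_nb_params(res_type, rownames(coords))
  e <- nonbonded_energy(pa, coords, pb, xb, params)
  if (params$include_symmetry && !is.null(model$cell)) {
    ctr <- colMeans(coords)
    rad <- sqrt(max(rowSums(sweep(coords, 2, ctr)^2)))
    imgs <- symmetry_images(as.matrix(env[, c("x", "y", "z")]), model$cell,
                            center = ctr, radius = rad + params$cutoff,
                            include_identity = FALSE)
    if (nrow(imgs$coords)) {
      keep2 <- imgs$source
      pb2 <- do.call(rbind, lapply(keep2, function(j)
        atom_nb_params(env$res_type[j], env$name[j])))
      e <- e + nonbonded_energy(pa, coords, pb2, imgs$coords, params)
    }
  }
  e
}

# Frequency-relative term: -log(p / p_max), capped; the most frequent
# conformation costs zero.
freq_term <- function(p, p_max, cap = 20) {
  if (is.na(p) || p <= 0 || p_max <= 0) return(cap)
  min(cap, -log(p / p_max))
}

#' Self-energy of a conformation (density, frequency and backbone terms)
#'
#' `E_self = w_d * (max_n D - D) + w_p * (-log(p / p_max)) + E_backbone`:
#' the density term is relative to the best-fitting conformation of the
#' same residue, the frequency term is relative to its most frequent
#' conformation (zero cost for the best in each), and the backbone term
#' is the nonbonded interaction with the fixed backbone.
#'
#' @param D density score of this conformation
#' @param D_max maximum density score over the residue's conformations
#' @param p,p_max frequency of this / the most frequent conformation
#' @param e_bb backbone interaction energy of this conformation
#' @param params an `energy_params`
#' @return energy
#' @export
e_self <- function(D, D_max, p, p_max, e_bb, params = energy_params()) {
  params$w_d * (D_max - D) + params$w_p * freq_term(p, p_max, params$p_cap) + e_bb
}

#' Simplified self-energy (backbone term removed); used in stages I-II
#' @inheritParams e_self
#' @return energy
#' @export
e_self_simplified <- function(D, D_max, p, p_max, params = energy_params()) {
  e_self(D, D_max, p, p_max, 0, params)
}

# --- polar hydrogens and flips --------------------------------------------

# In-plane exocyclic bisector H placement (imidazole N-H).
.bisector_h <- function(n, nb1, nb2, bond = 1.0) {
  n + bond * vunit(vunit(n - nb1) + vunit(n - nb2))
}

add_h_atom <- function(conf, name, pos) {
  conf$coords <- rbind(conf$coords, matrix(pos, 1, 3, dimnames = list(name, NULL)))
  conf
}

#' Generate polar-hydrogen variants of a conformation
#'
#' Rotatable hydroxyl hydrogens are enumerated at X-X-O-H torsions of
#' -60/60/180 degrees for Ser and Thr and 0/180 degrees for Tyr; His
#' yields its three protonation states (delta-only, epsilon-only,
#' doubly protonated). Types without polar side-chain hydrogens return
#' the conformation unchanged.
#'
#' @param conf a `conformation` (canonical or placed coordinates)
#' @return list of conformations with hydrogens appended
#' @export
generate_h_variants <- function(conf) {
  co <- conf$coords
  rt <- conf$res_type
  if (rt %in% c("SER", "THR")) {
    # CA is the canonical-frame origin when not stored explicitly
    ca <- if ("CA" %in% rownames(co)) co["CA", ] else c(0, 0, 0)
    og <- if (rt == "SER") "OG" else "OG1"
    hn <- if (rt == "SER") "HG" else "HG1"
    lapply(c(-60, 60, 180), function(tor) {
      h <- place_atom(ca, co["CB", ], co[og, ], 0.96, 108.5, tor)
      v <- add_h_atom(conf, hn, h)
      v$h_variant <- sprintf("%s%+d", hn, as.integer(tor))
      v
    })
  } else if (rt == "TYR") {
    lapply(c(0, 180), function(tor) {
      h <- place_atom(co["CE1", ], co["CZ", ], co["OH", ], 0.96, 110.0, tor)
      v <- add_h_atom(conf, "HH", h)
      v$h_variant <- sprintf("HH%+d", as.integer(tor))
      v
    })
  } else if (rt == "HIS") {
    hd <- .bisector_h(co["ND1", ], co["CG", ], co["CE1", ])
    he <- .bisector_h(co["NE2", ], co["CD2", ], co["CE1", ])
    out <- list(add_h_atom(conf, "HD1", hd),
                add_h_atom(conf, "HE2", he),
                add_h_atom(add_h_atom(conf, "HD1", hd), "HE2", he))
    out[[1]]$h_variant <- "HD1"; out[[2]]$h_variant <- "HE2"
    out[[3]]$h_variant <- "HD1+HE2"
    out
  } else {
    list(conf)
  }
}

.flip_pairs <- list(
  ASN = list(c("OD1", "ND2")),
  GLN = list(c("OE1", "NE2")),
  HIS = list(c("ND1", "CD2"), c("CE1", "NE2")))

#' Generate terminal-group flips for Asn/Gln/His
#'
#' Returns the conformation and its 180-degree flipped counterpart, in
#' which the near-isosteric terminal atoms exchange identities at
#' unchanged positions (OD1/ND2 for Asn, OE1/NE2 for Gln, the imidazole
#' ring pairs for His). Flipping twice restores the original identity
#' assignment; other residue types return the conformation alone.
#'
#' @param conf a `conformation`
#' @return list of 1 or 2 conformations
#' @export
generate_flips <- function(conf) {
  pairs <- .flip_pairs[[conf$res_type]]
  if (is.null(pairs)) return(list(conf))
  flipped <- conf
  co <- conf$coords
  rn <- rownames(co)
  for (p in pairs) {
    i <- match(p[1], rn); j <- match(p[2], rn)
    tmp <- co[i, ]; co[i, ] <- co[j, ]; co[j, ] <- tmp
  }
  flipped$coords <- co
  flipped$flip_state <- if (identical(conf$flip_state, "flipped")) "original" else "flipped"
  list(conf, flipped)
}
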