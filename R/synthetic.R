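# Synthetic fixture generation: rotamer-frequency tables, polypeptide
# chains with library-style rotamers, and planted-rotamer models. These
# generators define the study conditions for all desk-scale benchmarks;
# they emulate well-refined single-conformer crystal structures, not the
# full heterogeneity of experimental data.

.chi_wells <- function(res_type, k) {
  sp3 <- list(ang = c(-60, 180, 60), p = c(0.45, 0.35, 0.20))
  nchi <- n_chi(res_type)
  # terminal torsion of planar groups
  if (k == nchi) {
    if (res_type %in% c("PHE", "TYR", "HIS"))
      return(list(ang = c(80, -80, 0), p = c(0.40, 0.40, 0.20)))
    if (res_type %in% c("ASP", "GLU"))
      return(list(ang = c(-30, 30, 80), p = c(0.40, 0.35, 0.25)))
    if (res_type %in% c("ASN", "GLN"))
      return(list(ang = c(-60, 60, 180), p = c(0.40, 0.35, 0.25)))
    if (res_type == "TRP")
      return(list(ang = c(90, -90), p = c(0.55, 0.45)))
  }
  if (res_type == "PRO" && k == 1) return(list(ang = c(28, -28), p = c(0.5, 0.5)))
  if (res_type == "PRO" && k == 2) return(list(ang = c(-35, 35), p = c(0.5, 0.5)))
  if (k >= 3) return(list(ang = c(-60, 180), p = c(0.45, 0.55)))
  sp3
}

#' Synthetic backbone-independent rotamer-frequency table
#'
#' Builds a rotamer sampling table (chi-tuple, probability mass) from
#' canonical gauche/trans wells, one row per well combination, normalized
#' per residue type. This is a synthetic stand-in for an experimental
#' backbone-independent rotamer library, adequate for frequency
#' interpolation in tests and synthetic benchmarks.
#'
#' @param types residue types to include (default: all side-chain types)
#' @return data frame with columns res_type, chi1..chi4, probability
#' @export
synthetic_rotamer_table <- function(types = sidechain_types()) {
  rows <- list()
  for (rt in types) {
    nchi <- n_chi(rt)
    if (nchi == 0) next
    wells <- lapply(seq_len(nchi), function(k) .chi_wells(rt, k))
    combos <- expand.grid(lapply(wells, function(w) seq_along(w$ang)))
    p <- apply(combos, 1, function(ix)
      prod(vapply(seq_len(nchi), function(k) wells[[k]]$p[ix[k]], numeric(1))))
    p <- p / sum(p)
    for (i in seq_len(nrow(combos))) {
      chi <- rep(NA_real_, 4)
      for (k in seq_len(nchi)) chi[k] <- wells[[k]]$ang[combos[i, k]]
      rows[[length(rows) + 1L]] <- data.frame(
        res_type = rt, chi1 = chi[1], chi2 = chi[2], chi3 = chi[3], chi4 = chi[4],
        probability = p[i], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Read/write a rotamer-frequency sample table
#' @param path whitespace-delimited text file (res_type chi1..chi4 probability,
#'   "." for absent chi)
#' @return data frame as from [synthetic_rotamer_table()]
#' @export
read_rotamer_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          na.strings = ".")
  df$res_type <- toupper(df$res_type)
  df
}

#' @rdname read_rotamer_table
#' @param table rotamer table data frame
#' @export
write_rotamer_table <- function(table, path) {
  out <- table
  for (cn in c("chi1", "chi2", "chi3", "chi4"))
    out[[cn]] <- ifelse(is.na(out[[cn]]), ".", format(out[[cn]]))
  utils::write.table(out, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Sample one rotamer (chi vector) for a residue type from a table.
sample_rotamer <- function(table, res_type, jitter_sd = 0) {
  sm <- table[table$res_type == res_type, , drop = FALSE]
  nchi <- n_chi(res_type)
  if (!nrow(sm)) return(wrap_angle(stats::runif(nchi, -180, 180)))
  i <- sample.int(nrow(sm), 1, prob = sm$probability)
  chi <- as.numeric(sm[i, c("chi1", "chi2", "chi3", "chi4")])[seq_len(nchi)]
  if (jitter_sd > 0) chi <- chi + stats::rnorm(nchi, 0, jitter_sd)
  wrap_angle(chi)
}

#' Generate a synthetic polypeptide with rotameric side chains
#'
#' Builds an ideal-geometry backbone at the given phi/psi (default: an
#' extended beta conformation, which keeps side chains well separated)
#' and attaches side chains drawn from a rotamer-frequency table with
#' Gaussian chi jitter.
#'
#' @param n_res number of residues
#' @param types residue types to draw from
#' @param seed RNG seed
#' @param phi,psi backbone dihedrals, degrees
#' @param jitter_sd chi jitter standard deviation, degrees
#' @param rotamer_table table as from [synthetic_rotamer_table()]
#' @param chain_id chain identifier
#' @return a `protein_model` (no unit cell; see [assign_cell()])
#' @export
synthetic_chain <- function(n_res, types = sidechain_types(), seed = 1,
                            phi = -120, psi = 135, jitter_sd = 8,
                            rotamer_table = synthetic_rotamer_table(),
                            chain_id = "A") {
  set.seed(seed)
  res_types <- sample(types, n_res, replace = TRUE)
  residues <- vector("list", n_res)
  # seed backbone for residue 1
  N <- c(0, 0, 0); CA <- c(1.458, 0, 0)
  C <- place_atom(c(-1, 1, 0), N, CA, 1.525, 111.0, -150)
  for (i in seq_len(n_res)) {
    rt <- res_types[i]
    O <- place_atom(N, CA, C, 1.231, 120.8, wrap_angle(psi + 180))
    bb <- rbind(N = N, CA = CA, C = C)
    chi <- sample_rotamer(rotamer_table, rt, jitter_sd)
    sc <- build_sidechain(rt, chi, backbone = bb)
    coords <- rbind(bb, O = O, sc)
    residues[[i]] <- residue_from_coords(rt, chain_id, i, coords)
    if (i < n_res) {
      Nn <- place_atom(N, CA, C, 1.329, 116.2, psi)
      CAn <- place_atom(CA, C, Nn, 1.458, 121.7, 180)
      Cn <- place_atom(C, Nn, CAn, 1.525, 111.0, phi)
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  protein_model(residues)
}

#' Enclose a model in a P1 unit cell
#'
#' Translates the model into the positive octant and assigns an
#' orthogonal P1 cell with the given padding on all sides (so periodic
#' images are separated by at least twice the padding).
#'
#' @param model a `protein_model`
#' @param padding Angstrom of empty space per side
#' @return the translated model with a `unit_cell`
#' @export
assign_cell <- function(model, padding = 6) {
  at <- model_all_atoms(model)
  lo <- c(min(at$x), min(at$y), min(at$z))
  hi <- c(max(at$x), max(at$y), max(at$z))
  shift <- padding - lo
  model$residues <- lapply(model$residues, function(res) {
    res$atoms$x <- res$atoms$x + shift[1]
    res$atoms$y <- res$atoms$y + shift[2]
    res$atoms$z <- res$atoms$z + shift[3]
    res
  })
  if (nrow(model$heteroatoms)) {
    model$heteroatoms$x <- model$heteroatoms$x + shift[1]
    model$heteroatoms$y <- model$heteroatoms$y + shift[2]
    model$heteroatoms$z <- model$heteroatoms$z + shift[3]
  }
  dimc <- hi - lo + 2 * padding
  model$cell <- unit_cell(dimc[1], dimc[2], dimc[3])
  model
}

#' Replace a model's side chains with library conformations
#'
#' For each residue with a side chain, draws a leaf conformation of the
#' matching type from the library (weighted by occurrence count) and
#' places it onto the residue's backbone. The result is a model whose
#' rotamers are exactly representable by the library — the ground truth
#' for planted-rotamer recovery experiments.
#'
#' @param model a `protein_model`
#' @param library a `conformer_library`
#' @param seed RNG seed
#' @param cm a `clash_model` used to keep the planted structure
#'   stereochemically sound; the default uses the unreduced contact
#'   distances (`adjustment = 0`) because the 0.3-Angstrom reduction
#'   models coordinate-error tolerance during fitting, not the geometry
#'   of a refined structure
#' @return list with `model` (side chains replaced) and `truth`
#'   (per-residue library conformation ids)
#' @export
plant_library_rotamers <- function(model, library, seed = 1,
                                   cm = clash_model(adjustment = 0)) {
  set.seed(seed)
  truth <- character(length(model$residues))
  env <- backbone_environment(model)
  envX <- as.matrix(env[, c("x", "y", "z")])
  envE <- element_of(env$name)
  placed_sc <- list()
  for (i in seq_along(model$residues)) {
    res <- model$residues[[i]]
    tt <- library$types[[res$res_type]]
    if (is.null(tt)) { truth[i] <- NA_character_; next }
    inv <- invert_transform(local_frame(res))
    keep <- which(!env_exclusion(env, i))
    # weighted draw without replacement until a clash-free rotamer is
    # found (a well-refined structure has none); fall back to the first
    # draw if every conformation clashes
    ord <- sample.int(length(tt$confs), length(tt$confs), prob = tt$counts)
    pick <- ord[1]; pick_pc <- NULL
    for (j in ord) {
      pc <- apply_transform(inv, tt$confs[[j]]$coords)
      el <- element_of(rownames(pc))
      hit <- any_clash(cm, pc, el, envX[keep, , drop = FALSE], envE[keep])
      if (!hit) for (other in placed_sc) {
        if (any_clash(cm, pc, el, other$coords, other$elements)) { hit <- TRUE; break }
      }
      if (!hit) { pick <- j; pick_pc <- list(coords = pc, elements = el); break }
    }
    cf <- tt$confs[[pick]]
    truth[i] <- cf$id
    if (!is.null(pick_pc)) placed_sc[[length(placed_sc) + 1L]] <- pick_pc
    model$residues[[i]] <- set_residue_sidechain(res, cf)
  }
  list(model = model, truth = truth)
}

# Replace the side chain (CB onward) of a residue with a placed
# conformation, keeping backbone atoms.
set_residue_sidechain <- function(residue, conf) {
  set_residue_sidechain_global(residue, place_conformation(conf, residue))
}

# As above, but from coordinates already in the global frame.
set_residue_sidechain_global <- function(residue, placed) {
  keep <- residue$atoms[residue$atoms$name %in% c("N", "CA", "C", "O", "OXT"), ,
                        drop = FALSE]
  add <- do.call(rbind, lapply(rownames(placed), function(nm)
    atom_row(nm, element_of(nm), placed[nm, ],
             b_factor = mean(keep$b_factor))))
  residue$atoms <- rbind(keep, add)
  rownames(residue$atoms) <- NULL
  residue
}

#' Strip a residue's side chain beyond CB
#' @param residue a `residue`
#' @param keep_cb keep the CB atom
#' @return the truncated residue
#' @export
strip_sidechain <- function(residue, keep_cb = TRUE) {
  keep <- c("N", "CA", "C", "O", "OXT", if (keep_cb) "CB")
  residue$atoms <- residue$atoms[residue$atoms$name %in% keep, , drop = FALSE]
  rownames(residue$atoms) <- NULL
  residue
}
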