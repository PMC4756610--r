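# Conformation objects: one side-chain pose in the canonical backbone
# frame, plus nomenclature normalization of symmetric and pseudo-chiral
# residues.

#' Construct a conformation
#'
#' A conformation is one side-chain pose (CB plus all side-chain heavy
#' atoms) expressed in the canonical local frame, with an occurrence
#' count and, once frequencies are assigned, a probability p(c).
#'
#' @param res_type three-letter residue code
#' @param coords coordinate matrix with atom-name rownames (canonical frame)
#' @param count occurrence count from the source data
#' @param frequency normalized occurrence frequency p(c)
#' @param flip_state for Asn/Gln/His: which terminal-group orientation
#' @param id optional identifier
#' @return object of class `conformation`
#' @export
conformation <- function(res_type, coords, count = 1L, frequency = NA_real_,
                         flip_state = NA_character_, id = NA_character_) {
  stopifnot(is.matrix(coords), !is.null(rownames(coords)))
  structure(list(res_type = toupper(res_type), coords = coords,
                 count = as.integer(count), frequency = frequency,
                 flip_state = flip_state, id = id),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("conformation %s (%d atoms, count %d, p=%.4g)\n",
              x$res_type, nrow(x$coords), x$count,
              if (is.na(x$frequency)) NA else x$frequency))
  invisible(x)
}

#' Extract a residue's side chain as a conformation in the canonical frame
#'
#' @param residue a `residue` with N, CA, C present
#' @param strict error (TRUE) or return NULL (FALSE) when side-chain atoms
#'   are missing
#' @return a `conformation`, or NULL
#' @export
conformation_from_residue <- function(residue, strict = TRUE) {
  tpl <- sidechain_template(residue$res_type)
  nms <- if (is.null(tpl$zmat)) character(0) else tpl$zmat$name
  if (!length(nms)) return(NULL)
  pos <- residue_atom_pos(residue, nms)
  if (anyNA(pos)) {
    if (strict) stop(sprintf("residue %s %s: incomplete side chain (missing %s)",
                             residue$res_type, residue_id(residue),
                             paste(nms[apply(is.na(pos), 1, any)], collapse = ", ")))
    return(NULL)
  }
  tf <- local_frame(residue)
  conformation(residue$res_type, apply_transform(tf, pos))
}

#' Place a conformation onto a residue's backbone
#'
#' Maps canonical-frame conformation coordinates into global coordinates
#' through the inverse of the residue's local frame.
#'
#' @param conf a `conformation`
#' @param residue the target `residue` (provides the backbone frame)
#' @return coordinate matrix in global (orthogonal) coordinates
#' @export
place_conformation <- function(conf, residue) {
  apply_transform(invert_transform(local_frame(residue)), conf$coords)
}

#' Side-chain r.m.s.d. between two conformations
#'
#' Root-mean-square deviation over all side-chain atoms excluding CB,
#' computed in the canonical frame (main-chain N/CA/C superposition is
#' implied by the frame).
#'
#' @param conf_a,conf_b conformations of the same residue type
#' @return r.m.s.d. in Angstrom
#' @export
sidechain_rmsd <- function(conf_a, conf_b) {
  if (conf_a$res_type != conf_b$res_type)
    stop("residue type mismatch: ", conf_a$res_type, " vs ", conf_b$res_type)
  nm_a <- setdiff(rownames(conf_a$coords), "CB")
  nm_b <- setdiff(rownames(conf_b$coords), "CB")
  if (!setequal(nm_a, nm_b))
    stop("atom-set mismatch: ", paste(union(setdiff(nm_a, nm_b), setdiff(nm_b, nm_a)),
                                      collapse = ", "))
  if (!length(nm_a)) return(0)
  d <- conf_a$coords[nm_a, , drop = FALSE] - conf_b$coords[nm_a, , drop = FALSE]
  sqrt(mean(rowSums(d * d)))
}

# --- nomenclature normalization -------------------------------------------

# Governing torsion reaching the symmetric terminal atom, per type.
.sym_torsions <- list(
  ASP = list(q = c("CA", "CB", "CG", "OD1"), swaps = list(c("OD1", "OD2"))),
  GLU = list(q = c("CB", "CG", "CD", "OE1"), swaps = list(c("OE1", "OE2"))),
  PHE = list(q = c("CA", "CB", "CG", "CD1"), swaps = list(c("CD1", "CD2"), c("CE1", "CE2"))),
  TYR = list(q = c("CA", "CB", "CG", "CD1"), swaps = list(c("CD1", "CD2"), c("CE1", "CE2"))),
  ARG = list(q = c("CD", "NE", "CZ", "NH1"), swaps = list(c("NH1", "NH2"))))

# Amide/imidazole identity swaps used only in the symmetric clustering mode.
.sym_mode_torsions <- list(
  ASN = list(q = c("CA", "CB", "CG", "OD1"), swaps = list(c("OD1", "ND2"))),
  GLN = list(q = c("CB", "CG", "CD", "OE1"), swaps = list(c("OE1", "NE2"))),
  HIS = list(q = c("CA", "CB", "CG", "ND1"), swaps = list(c("ND1", "CD2"), c("CE1", "NE2"))))

swap_atom_names <- function(residue, pairs) {
  nm <- residue$atoms$name
  for (p in pairs) {
    i <- nm == p[1]; j <- nm == p[2]
    nm[i] <- p[2]; nm[j] <- p[1]
  }
  residue$atoms$name <- nm
  # swapping N<->O or N<->C identities also swaps elements
  residue$atoms$element <- element_of(residue$atoms$name)
  residue
}

chirality_sign <- function(residue, center, n1, n2, n3) {
  pos <- residue_atom_pos(residue, c(center, n1, n2, n3))
  if (anyNA(pos)) return(NA_real_)
  u <- pos[n1, ] - pos[center, ]
  v <- pos[n2, ] - pos[center, ]
  w <- pos[n3, ] - pos[center, ]
  sign(sum(u * vcross(v, w)))
}

# Reference chirality signs measured on the ideal templates.
.template_chirality <- local({
  env <- new.env()
  get_sign <- function(res_type, center, n1, n2, n3) {
    key <- paste(res_type, center)
    if (!is.null(env[[key]])) return(env[[key]])
    coords <- build_sidechain(res_type, rep(60, n_chi(res_type)))
    bb <- canonical_backbone()
    all <- rbind(bb, coords)
    u <- all[n1, ] - all[center, ]; v <- all[n2, ] - all[center, ]; w <- all[n3, ] - all[center, ]
    env[[key]] <- sign(sum(u * vcross(v, w)))
    env[[key]]
  }
  get_sign
})

#' Normalize atom nomenclature of symmetric and pseudo-chiral residues
#'
#' For Arg/Asp/Glu/Phe/Tyr the names of the symmetric terminal atoms are
#' swapped when the governing torsion lies outside \[-90, 90\] degrees,
#' bringing it into range. Leu/Val equivalent atoms are swapped when the
#' local pseudo-chirality is reversed; Thr/Ile with inverted chirality are
#' flagged rejected. With `symmetric = TRUE` (clustering mode) Asn/Gln/His
#' additionally have their amide/imidazole atom identities swapped by the
#' same torsion rule.
#'
#' @param residue a `residue` with complete side chain
#' @param symmetric treat Asn/Gln/His as symmetric (clustering mode)
#' @return list with `residue` (possibly renamed), `rejected` (logical),
#'   `swapped` (logical) and `reason`
#' @export
normalize_nomenclature <- function(residue, symmetric = FALSE) {
  out <- list(residue = residue, rejected = FALSE, swapped = FALSE, reason = NA_character_)
  rt <- residue$res_type
  tor_rule <- .sym_torsions[[rt]]
  if (symmetric && is.null(tor_rule)) tor_rule <- .sym_mode_torsions[[rt]]
  if (!is.null(tor_rule)) {
    pos <- residue_atom_pos(residue, tor_rule$q)
    if (anyNA(pos)) return(out)
    tor <- dihedral_angle(pos[1, ], pos[2, ], pos[3, ], pos[4, ])
    if (tor < -90 || tor > 90) {
      out$residue <- swap_atom_names(residue, tor_rule$swaps)
      out$swapped <- TRUE
    }
    return(out)
  }
  if (rt == "LEU") {
    s <- chirality_sign(residue, "CG", "CB", "CD1", "CD2")
    ref <- .template_chirality("LEU", "CG", "CB", "CD1", "CD2")
    if (!is.na(s) && s != ref) {
      out$residue <- swap_atom_names(residue, list(c("CD1", "CD2")))
      out$swapped <- TRUE
    }
  } else if (rt == "VAL") {
    s <- chirality_sign(residue, "CB", "CA", "CG1", "CG2")
    ref <- .template_chirality("VAL", "CB", "CA", "CG1", "CG2")
    if (!is.na(s) && s != ref) {
      out$residue <- swap_atom_names(residue, list(c("CG1", "CG2")))
      out$swapped <- TRUE
    }
  } else if (rt == "THR") {
    s <- chirality_sign(residue, "CB", "CA", "OG1", "CG2")
    ref <- .template_chirality("THR", "CB", "CA", "OG1", "CG2")
    if (!is.na(s) && s != ref) {
      out$rejected <- TRUE; out$reason <- "inverted chirality"
    }
  } else if (rt == "ILE") {
    s <- chirality_sign(residue, "CB", "CA", "CG1", "CG2")
    ref <- .template_chirality("ILE", "CB", "CA", "CG1", "CG2")
    if (!is.na(s) && s != ref) {
      out$rejected <- TRUE; out$reason <- "inverted chirality"
    }
  }
  out
}
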