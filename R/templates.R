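# Side-chain topology templates: internal coordinates, chi definitions and
# ideal-geometry builders in the canonical backbone frame.
#
# Each template row places one atom d from three reference atoms a-b-c
# (all previously placed) with bond |c-d|, angle b-c-d and torsion
# a-b-c-d. The torsion is either fixed (chi = NA) or follows chi_k with a
# constant offset, so arbitrary rotamers can be generated. Values are
# ideal single-conformer geometry consistent with standard stereochemical
# targets; branch offsets and the C-N-CA-CB improper (+122.5 deg) encode
# L-amino-acid chirality.

.zrow <- function(name, element, a, b, c, bond, angle, chi = NA, offset = 0) {
  data.frame(name = name, element = element, a = a, b = b, c = c,
             bond = bond, angle = angle, chi = chi, offset = offset,
             stringsAsFactors = FALSE)
}

.cb_row <- function() .zrow("CB", "C", "C", "N", "CA", 1.530, 110.5, NA, 122.5)

.sidechain_templates <- local({
  z <- .zrow
  cb <- .cb_row()
  tpl <- list()

  tpl$SER <- list(
    zmat = rbind(cb, z("OG", "O", "N", "CA", "CB", 1.417, 110.8, 1L)),
    chi = list(c("N", "CA", "CB", "OG")))
  tpl$CYS <- list(
    zmat = rbind(cb, z("SG", "S", "N", "CA", "CB", 1.808, 113.8, 1L)),
    chi = list(c("N", "CA", "CB", "SG")))
  tpl$THR <- list(
    zmat = rbind(cb,
      z("OG1", "O", "N", "CA", "CB", 1.433, 109.6, 1L),
      z("CG2", "C", "N", "CA", "CB", 1.521, 110.5, 1L, 120)),
    chi = list(c("N", "CA", "CB", "OG1")))
  tpl$VAL <- list(
    zmat = rbind(cb,
      z("CG1", "C", "N", "CA", "CB", 1.521, 110.5, 1L),
      z("CG2", "C", "N", "CA", "CB", 1.521, 110.5, 1L, -122)),
    chi = list(c("N", "CA", "CB", "CG1")))
  tpl$ILE <- list(
    zmat = rbind(cb,
      z("CG1", "C", "N", "CA", "CB", 1.530, 110.4, 1L),
      z("CG2", "C", "N", "CA", "CB", 1.521, 110.5, 1L, 124),
      z("CD1", "C", "CA", "CB", "CG1", 1.513, 113.8, 2L)),
    chi = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")))
  tpl$LEU <- list(
    zmat = rbind(cb,
      z("CG", "C", "N", "CA", "CB", 1.530, 116.3, 1L),
      z("CD1", "C", "CA", "CB", "CG", 1.521, 110.7, 2L),
      z("CD2", "C", "CA", "CB", "CG", 1.521, 110.7, 2L, -120)),
    chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")))
  tpl$ASN <- list(
    zmat = rbind(cb,
      z("CG", "C", "N", "CA", "CB", 1.516, 112.6, 1L),
      z("OD1", "O", "CA", "CB", "CG", 1.231, 120.8, 2L),
      z("ND2", "N", "CA", "CB", "CG", 1.328, 116.4, 2L, 180)),
    chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")))
  tpl$ASP <- list(
    zmat = rbind(cb,
      z("CG", "C", "N", "CA", "CB", 1.516, 112.6, 1L),
      z("OD1", "O", "CA", "CB", "CG", 1.249, 118.4, 2L),
      z("OD2", "O", "CA", "CB", "CG", 1.249, 118.4, 2L, 180)),
    chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")))
  tpl$GLN <- list(
    zmat = rbind(cb,
      z("CG", "C", "N", "CA", "CB", 1.520, 114.1, 1L),
      z("CD", "C", "CA", "CB", "CG", 1.516, 112.6, 2L),
      z("OE1", "O", "CB", "CG", "CD", 1.231, 120.8, 3L),
      z("NE2", "N", "CB", "CG", "CD", 1.328, 116.4, 3L, 180)),
    chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
               c("CB", "CG", "CD", "OE1")))
  tpl$GLU <- list(
    zmat = rbind(cb,
      z("CG", "C", "N", "CA", "CB", 1.520, 114.1, 1L),
      z("CD", "C", "CA", "CB", "CG", 1.516, 112.6, 2L),
      z("OE1", "O", "CB", "CG", "CD", 1.249, 118.4, 3L),
      z("OE2", "O", "CB", "CG", "CD", 1.249, 118.4, 3L, 180)),
    chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
               c("CB", "CG", "CD", "OE1")))
  tpl$MET <- list(
    zmat = rbind(cb,
      z("CG", "C", "N", "CA", "CB", 1.520, 114.1, 1L),
      z("SD", "S", "CA", "CB", "CG", 1.803, 112.7, 2L),
      z("CE", "C", "CB", "CG", "SD", 1.791, 100.9, 3L)),
    chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
               c("CB", "CG", "SD", "CE")))
  tpl$LYS <- list(
    zmat = rbind(cb,
      z("CG", "C", "N", "CA", "CB", 1.520, 114.1, 1L),
      z("CD", "C", "CA", "CB", "CG", 1.520, 111.3, 2L),
      z("CE", "C", "CB", "CG", "CD", 1.520, 111.3, 3L),
      z("NZ", "N", "CG", "CD", "CE", 1.489, 111.9, 4L)),
    chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
               c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")))
  tpl$ARG <- list(
    zmat = rbind(cb,
      z("CG", "C", "N", "CA", "CB", 1.520, 114.1, 1L),
      z("CD", "C", "CA", "CB", "CG", 1.520, 111.3, 2L),
      z("NE", "N", "CB", "CG", "CD", 1.461, 112.0, 3L),
      z("CZ", "C", "CG", "CD", "NE", 1.329, 124.2, 4L),
      z("NH1", "N", "CD", "NE", "CZ", 1.326, 120.0, NA, 0),
      z("NH2", "N", "CD", "NE", "CZ", 1.326, 120.0, NA, 180)),
    chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
               c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")))
  tpl$HIS <- list(
    zmat = rbind(cb,
      z("CG", "C", "N", "CA", "CB", 1.497, 113.8, 1L),
      z("ND1", "N", "CA", "CB", "CG", 1.378, 122.7, 2L),
      z("CD2", "C", "CA", "CB", "CG", 1.354, 131.0, 2L, 180),
      z("CE1", "C", "CB", "CG", "ND1", 1.320, 109.3, NA, 180),
      z("NE2", "N", "CB", "CG", "CD2", 1.374, 107.2, NA, 180)),
    chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")))
  tpl$PHE <- list(
    zmat = rbind(cb,
      z("CG", "C", "N", "CA", "CB", 1.502, 113.8, 1L),
      z("CD1", "C", "CA", "CB", "CG", 1.384, 120.8, 2L),
      z("CD2", "C", "CA", "CB", "CG", 1.384, 120.8, 2L, 180),
      z("CE1", "C", "CB", "CG", "CD1", 1.382, 120.8, NA, 180),
      z("CE2", "C", "CB", "CG", "CD2", 1.382, 120.8, NA, 180),
      z("CZ", "C", "CG", "CD1", "CE1", 1.382, 120.0, NA, 0)),
    chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")))
  tpl$TYR <- list(
    zmat = rbind(tpl$PHE$zmat,
      z("OH", "O", "CD1", "CE1", "CZ", 1.376, 119.9, NA, 180)),
    chi = tpl$PHE$chi)
  tpl$TRP <- list(
    zmat = rbind(cb,
      z("CG", "C", "N", "CA", "CB", 1.498, 113.6, 1L),
      z("CD1", "C", "CA", "CB", "CG", 1.365, 126.9, 2L),
      z("CD2", "C", "CA", "CB", "CG", 1.433, 126.6, 2L, 180),
      z("NE1", "N", "CB", "CG", "CD1", 1.374, 110.2, NA, 180),
      z("CE2", "C", "CB", "CG", "CD2", 1.409, 107.2, NA, 180),
      z("CE3", "C", "CB", "CG", "CD2", 1.398, 133.9, NA, 0),
      z("CZ2", "C", "CG", "CD2", "CE2", 1.394, 122.4, NA, 180),
      z("CZ3", "C", "CG", "CD2", "CE3", 1.382, 118.6, NA, 180),
      z("CH2", "C", "CD2", "CE2", "CZ2", 1.400, 117.5, NA, 0)),
    chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")))
  tpl$PRO <- list(
    zmat = rbind(cb,
      z("CG", "C", "N", "CA", "CB", 1.492, 104.5, 1L),
      z("CD", "C", "CA", "CB", "CG", 1.503, 106.1, 2L)),
    chi = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")))
  tpl$ALA <- list(zmat = cb, chi = list())
  tpl$GLY <- list(zmat = NULL, chi = list())
  tpl
})

#' Canonical backbone positions used by the templates
#'
#' CA at the origin, N on the -x axis at the ideal N-CA distance, C in
#' the xy-plane at the ideal N-CA-C angle.
#' @return 3x3 matrix with rows N, CA, C
#' @export
canonical_backbone <- function() {
  th <- deg2rad(180 - 111.0)
  rbind(N = c(-1.458, 0, 0),
        CA = c(0, 0, 0),
        C = 1.525 * c(cos(th), sin(th), 0))
}

#' Residue types that carry a side chain beyond C-beta
#' @return character vector of 18 three-letter codes
#' @export
sidechain_types <- function() {
  setdiff(names(.sidechain_templates), c("ALA", "GLY"))
}

#' Side-chain template for a residue type
#' @param res_type three-letter residue code
#' @return list with `zmat` (internal-coordinate table) and `chi`
#'   (list of defining atom quadruples)
#' @export
sidechain_template <- function(res_type) {
  tpl <- .sidechain_templates[[toupper(res_type)]]
  if (is.null(tpl)) stop("unknown residue type: ", res_type)
  tpl
}

#' Chi-angle atom quadruples for a residue type
#' @inheritParams sidechain_template
#' @return list of character(4) vectors (empty for Ala/Gly)
#' @export
chi_definitions <- function(res_type) sidechain_template(res_type)$chi

n_chi <- function(res_type) length(chi_definitions(res_type))

#' Build ideal side-chain coordinates at given chi angles
#'
#' Constructs CB and all side-chain heavy atoms in the canonical backbone
#' frame from the internal-coordinate template of the residue type.
#'
#' @param res_type three-letter residue code
#' @param chi numeric vector of chi angles, degrees (length
#'   `length(chi_definitions(res_type))`)
#' @param backbone optional 3x3 matrix with rows N, CA, C to build onto;
#'   defaults to the canonical backbone
#' @return numeric matrix (n_atoms x 3) with atom-name rownames
#' @export
build_sidechain <- function(res_type, chi = numeric(), backbone = NULL) {
  tpl <- sidechain_template(res_type)
  if (is.null(tpl$zmat)) {
    m <- matrix(numeric(0), 0, 3)
    rownames(m) <- character(0)
    return(m)
  }
  nchi <- length(tpl$chi)
  if (length(chi) != nchi)
    stop(sprintf("%s requires %d chi angle(s), got %d", res_type, nchi, length(chi)))
  if (is.null(backbone)) backbone <- canonical_backbone()
  pos <- list(N = backbone["N", ], CA = backbone["CA", ], C = backbone["C", ])
  zm <- tpl$zmat
  for (k in seq_len(nrow(zm))) {
    tor <- if (is.na(zm$chi[k])) zm$offset[k] else chi[zm$chi[k]] + zm$offset[k]
    pos[[zm$name[k]]] <- place_atom(pos[[zm$a[k]]], pos[[zm$b[k]]], pos[[zm$c[k]]],
                                    zm$bond[k], zm$angle[k], tor)
  }
  out <- do.call(rbind, pos[zm$name])
  rownames(out) <- zm$name
  out
}

# Parent (bonded predecessor) of each template atom; used to find the set
# of atoms that move under a chi rotation.
template_parents <- function(res_type) {
  zm <- sidechain_template(res_type)$zmat
  if (is.null(zm)) return(character(0))
  stats::setNames(zm$c, zm$name)
}

# All template atoms in the subtree below `root` (atoms whose bonded
# chain to CA passes through root), root excluded.
template_descendants <- function(res_type, root) {
  par <- template_parents(res_type)
  out <- character(0)
  grow <- names(par)[par == root]
  while (length(grow)) {
    out <- c(out, grow)
    grow <- names(par)[par %in% grow]
  }
  out
}

#' Measure the chi angles of a residue
#'
#' @param residue a `residue` object with complete side chain
#' @return numeric vector of chi angles in degrees, range (-180, 180];
#'   empty for Ala/Gly
#' @export
chi_angles <- function(residue) {
  defs <- chi_definitions(residue$res_type)
  if (!length(defs)) return(numeric(0))
  need <- unique(unlist(defs))
  pos <- residue_atom_pos(residue, need)
  if (anyNA(pos)) {
    miss <- need[apply(is.na(pos), 1, any)]
    stop(sprintf("residue %s %s%d: incomplete side chain, missing %s",
                 residue$res_type, residue$chain_id, residue$seq_num,
                 paste(miss, collapse = ", ")))
  }
  vapply(defs, function(q) dihedral_angle(pos[q[1], ], pos[q[2], ], pos[q[3], ], pos[q[4], ]),
         numeric(1))
}

#' Chi angles from a coordinate matrix in any frame
#' @param coords matrix with rownames including the defining atoms
#' @param res_type residue type
#' @keywords internal
chi_from_coords <- function(coords, res_type) {
  defs <- chi_definitions(res_type)
  vapply(defs, function(q) {
    if (!all(q %in% rownames(coords))) return(NA_real_)
    dihedral_angle(coords[q[1], ], coords[q[2], ], coords[q[3], ], coords[q[4], ])
  }, numeric(1))
}

#' Rotate a residue's side chain to a target chi angle
#'
#' Rotates all atoms distal to the chi-k bond about that bond so that
#' chi-k equals `value`; other chi angles are unchanged.
#'
#' @param residue a `residue` object
#' @param k chi index (1-based)
#' @param value target angle, degrees
#' @return the modified residue
#' @export
set_chi <- function(residue, k, value) {
  defs <- chi_definitions(residue$res_type)
  if (k < 1 || k > length(defs)) stop("chi index out of range for ", residue$res_type)
  q <- defs[[k]]
  cur <- chi_angles(residue)[k]
  delta <- wrap_angle(value - cur)
  moving <- template_descendants(residue$res_type, q[3])
  pos <- residue_atom_pos(residue, c(q[2], q[3]))
  R <- rotation_about_axis(pos[q[2], ] - pos[q[3], ], delta)
  idx <- which(residue$atoms$name %in% moving)
  if (length(idx)) {
    xyz <- as.matrix(residue$atoms[idx, c("x", "y", "z")])
    xyz <- t(R %*% (t(xyz) - pos[q[3], ]) + pos[q[3], ])
    residue$atoms[idx, c("x", "y", "z")] <- xyz
  }
  residue
}
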