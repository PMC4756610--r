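# Rigid-body geometry: frames, dihedrals, internal-coordinate atom placement.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  a / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle in degrees into (-180, 180]
#' @param x angle(s) in degrees
#' @return wrapped angle(s)
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Signed dihedral angle of four points
#'
#' @param p1,p2,p3,p4 3-vectors (orthogonal coordinates, Angstrom)
#' @return dihedral in degrees, range (-180, 180]
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(rad2deg(atan2(y, x)))
}

#' Bond angle at p2 for points p1-p2-p3, degrees
#' @keywords internal
bond_angle <- function(p1, p2, p3) {
  u <- vunit(p1 - p2)
  v <- vunit(p3 - p2)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three reference positions `a`, `b`, `c`, returns the position `d`
#' such that |c-d| = `bond`, angle(b,c,d) = `angle` and
#' dihedral(a,b,c,d) = `dihedral`.
#'
#' @param a,b,c 3-vectors
#' @param bond bond length c-d, Angstrom
#' @param angle bond angle b-c-d, degrees
#' @param dihedral torsion a-b-c-d, degrees
#' @return 3-vector
#' @export
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- deg2rad(angle)
  tor <- deg2rad(dihedral)
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               -bond * sin(ang) * sin(tor))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  # columns: bc, m, n form a right-handed frame at c
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

#' Rotation matrix about an arbitrary axis (Rodrigues formula)
#' @param axis 3-vector (need not be unit)
#' @param angle rotation angle, degrees
#' @return 3x3 rotation matrix
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- vunit(axis)
  th <- deg2rad(angle)
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

#' Rigid transform as rotation + translation
#'
#' A `rigid_transform` maps x to `R %*% x + t`.
#' @param R 3x3 rotation
#' @param t length-3 translation
#' @return object of class `rigid_transform`
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param tf a `rigid_transform`
#' @param x numeric 3-vector or n-by-3 matrix
#' @return transformed coordinates, same shape as `x`
#' @export
apply_transform <- function(tf, x) {
  if (is.matrix(x)) {
    t(tf$R %*% t(x) + tf$t)
  } else {
    as.numeric(tf$R %*% x + tf$t)
  }
}

#' Invert a rigid transform
#' @param tf a `rigid_transform`
#' @return the inverse `rigid_transform`
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), -as.numeric(t(tf$R) %*% tf$t))
}

#' Compose rigid transforms (a after b)
#' @keywords internal
compose_transform <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

# Canonical local frame convention: CA at the origin, N exactly along -x,
# C in the xy-plane with positive y. Deterministic for any non-degenerate
# backbone.
frame_from_nca_c <- function(n, ca, c) {
  xhat <- -vunit(n - ca)
  cv <- c - ca
  yraw <- cv - sum(cv * xhat) * xhat
  yhat <- vunit(yraw)
  zhat <- vcross(xhat, yhat)
  R <- rbind(xhat, yhat, zhat)
  dimnames(R) <- NULL
  rigid_transform(R, as.numeric(-R %*% ca))
}

#' Local canonical frame of a residue
#'
#' Returns the rigid transform that superimposes the residue's main-chain
#' N, CA, C atoms onto the canonical frame: CA at the origin, N along the
#' negative x axis, C in the xy-plane (positive y side). Side chains
#' expressed in this frame are directly comparable across residues.
#'
#' @param residue a `residue` object (see [read_pdb()])
#' @return a `rigid_transform` mapping global to canonical coordinates
#' @export
local_frame <- function(residue) {
  need <- c("N", "CA", "C")
  pos <- residue_atom_pos(residue, need)
  if (anyNA(pos)) {
    miss <- need[apply(is.na(pos), 1, any)]
    stop(sprintf("residue %s %s%d: missing backbone atom(s) %s",
                 residue$res_type, residue$chain_id, residue$seq_num,
                 paste(miss, collapse = ", ")))
  }
  frame_from_nca_c(pos["N", ], pos["CA", ], pos["C", ])
}
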