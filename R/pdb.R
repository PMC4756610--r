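# Protein model container and PDB I/O.
#
# Reading goes through bio3d::read.pdb; the CRYST1 record is taken from
# the raw file because bio3d does not retain it. Writing emits standard
# fixed-width PDB v3 ATOM/HETATM/CRYST1/END records.

.sg_ops <- list(
  "P 1"          = c("X,Y,Z"),
  "P 1 21 1"     = c("X,Y,Z", "-X,Y+1/2,-Z"),
  "C 1 2 1"      = c("X,Y,Z", "-X,Y,-Z", "X+1/2,Y+1/2,Z", "-X+1/2,Y+1/2,-Z"),
  "P 21 21 21"   = c("X,Y,Z", "X+1/2,-Y+1/2,-Z", "-X,Y+1/2,-Z+1/2", "-X+1/2,-Y,Z+1/2"),
  "P 21 21 2"    = c("X,Y,Z", "-X,-Y,Z", "X+1/2,-Y+1/2,-Z", "-X+1/2,Y+1/2,-Z"),
  "P 43 21 2"    = c("X,Y,Z", "-X,-Y,Z+1/2", "-Y+1/2,X+1/2,Z+3/4", "Y+1/2,-X+1/2,Z+1/4",
                     "-X+1/2,Y+1/2,-Z+3/4", "X+1/2,-Y+1/2,-Z+1/4", "Y,X,-Z", "-Y,-X,-Z+1/2"))

#' Parse a symmetry-operator triplet string
#'
#' Converts an operator such as `"-X,Y+1/2,-Z"` into a 3x3 rotation
#' matrix and fractional translation vector.
#'
#' @param s triplet string (components separated by commas)
#' @return list with `R` (3x3) and `t` (length 3, fractional)
#' @export
parse_symop <- function(s) {
  parts <- strsplit(toupper(gsub(" ", "", s)), ",")[[1]]
  if (length(parts) != 3) stop("malformed symmetry operator: ", s)
  R <- matrix(0, 3, 3); tt <- numeric(3)
  axes <- c(X = 1L, Y = 2L, Z = 3L)
  for (i in 1:3) {
    expr <- parts[i]
    # tokenize into signed terms: -X, +1/2, +Y, 0.25 ...
    toks <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (tok in toks) {
      sign <- if (startsWith(tok, "-")) -1 else 1
      body <- sub("^[+-]", "", tok)
      if (body %in% names(axes)) {
        R[i, axes[[body]]] <- sign
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        nm <- as.numeric(strsplit(body, "/")[[1]])
        tt[i] <- tt[i] + sign * nm[1] / nm[2]
      } else if (grepl("^[0-9.]+$", body)) {
        tt[i] <- tt[i] + sign * as.numeric(body)
      } else stop("cannot parse symmetry token '", tok, "' in ", s)
    }
  }
  list(R = R, t = tt)
}

#' Construct a crystallographic unit cell
#'
#' @param a,b,c cell edges, Angstrom
#' @param alpha,beta,gamma cell angles, degrees
#' @param spacegroup space-group symbol (Hermann-Mauguin, as on CRYST1);
#'   operators are looked up in a bundled table of common groups
#' @param symops optional explicit operator triplet strings overriding the
#'   space-group lookup
#' @return object of class `unit_cell`
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                      spacegroup = "P 1", symops = NULL) {
  stopifnot(a > 0, b > 0, c > 0)
  if (is.null(symops)) {
    symops <- .sg_ops[[spacegroup]]
    if (is.null(symops)) {
      warning("space group '", spacegroup,
              "' not in the bundled operator table; using identity only")
      symops <- "X,Y,Z"
    }
  }
  ops <- lapply(symops, parse_symop)
  ca <- cos(deg2rad(alpha)); cb <- cos(deg2rad(beta)); cg <- cos(deg2rad(gamma))
  sg <- sin(deg2rad(gamma))
  cx <- c * cb
  cy <- c * (ca - cb * cg) / sg
  cz <- sqrt(max(0, c^2 - cx^2 - cy^2))
  orth <- matrix(c(a, 0, 0, b * cg, b * sg, 0, cx, cy, cz), 3, 3)
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
                 spacegroup = spacegroup, ops = ops,
                 orth = orth, frac = solve(orth)),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell %.2f %.2f %.2f  %.1f %.1f %.1f  %s (%d ops)\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$spacegroup, length(x$ops)))
  invisible(x)
}

#' Convert between orthogonal and fractional coordinates
#' @param cell a `unit_cell`
#' @param xyz orthogonal coordinates (3-vector or n x 3 matrix)
#' @return coordinates in the other system, same shape
#' @export
frac_coords <- function(cell, xyz) {
  if (is.matrix(xyz)) t(cell$frac %*% t(xyz)) else as.numeric(cell$frac %*% xyz)
}
#' @rdname frac_coords
#' @param frac fractional coordinates
#' @export
orth_coords <- function(cell, frac) {
  if (is.matrix(frac)) t(cell$orth %*% t(frac)) else as.numeric(cell$orth %*% frac)
}

new_residue <- function(res_type, chain_id, seq_num, atoms, insertion_code = "") {
  structure(list(res_type = toupper(res_type), chain_id = chain_id,
                 seq_num = as.integer(seq_num), insertion_code = insertion_code,
                 atoms = atoms),
            class = "residue")
}

empty_atom_table <- function() {
  data.frame(name = character(), element = character(),
             x = numeric(), y = numeric(), z = numeric(),
             occupancy = numeric(), b_factor = numeric(), alt_loc = character(),
             stringsAsFactors = FALSE)
}

atom_row <- function(name, element, pos, occupancy = 1, b_factor = 20, alt_loc = "") {
  data.frame(name = name, element = element, x = pos[1], y = pos[2], z = pos[3],
             occupancy = occupancy, b_factor = b_factor, alt_loc = alt_loc,
             stringsAsFactors = FALSE)
}

#' Build a residue object from a coordinate matrix
#' @param res_type,chain_id,seq_num residue identity
#' @param coords matrix with atom-name rownames
#' @param b_factor B factor assigned to all atoms
#' @return a `residue`
#' @export
residue_from_coords <- function(res_type, chain_id, seq_num, coords, b_factor = 20) {
  atoms <- do.call(rbind, lapply(rownames(coords), function(nm) {
    atom_row(nm, element_of(nm), coords[nm, ], b_factor = b_factor)
  }))
  new_residue(res_type, chain_id, seq_num, atoms)
}

element_of <- function(name) {
  n <- gsub("[0-9']", "", toupper(name))
  first <- substr(n, 1, 1)
  ifelse(first %in% c("C", "N", "O", "S", "H", "P"), first, substr(n, 1, 2))
}

#' Positions of named atoms of a residue
#'
#' When alternate locations are present the highest-occupancy (then
#' lowest-B) copy is used.
#'
#' @param residue a `residue`
#' @param names atom names to extract
#' @return length(names) x 3 matrix with NA rows for absent atoms
#' @export
residue_atom_pos <- function(residue, names) {
  at <- residue$atoms
  out <- matrix(NA_real_, length(names), 3, dimnames = list(names, c("x", "y", "z")))
  for (nm in names) {
    rows <- which(at$name == nm)
    if (!length(rows)) next
    if (length(rows) > 1) {
      rows <- rows[order(-at$occupancy[rows], at$b_factor[rows])]
    }
    out[nm, ] <- as.numeric(at[rows[1], c("x", "y", "z")])
  }
  out
}

residue_id <- function(residue) {
  paste0(residue$chain_id, residue$seq_num, residue$insertion_code)
}

#' Construct a protein model
#' @param residues list of `residue` objects
#' @param cell a `unit_cell` or NULL (non-crystallographic)
#' @param heteroatoms data frame of heteroatoms (waters, ions, ligands)
#' @return object of class `protein_model`
#' @export
protein_model <- function(residues, cell = NULL, heteroatoms = NULL) {
  ids <- vapply(residues, residue_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate residue identifiers: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  if (is.null(heteroatoms)) heteroatoms <- empty_atom_table()
  structure(list(residues = residues, cell = cell, heteroatoms = heteroatoms),
            class = "protein_model")
}

#' @export
print.protein_model <- function(x, ...) {
  cat(sprintf("protein model: %d residues, %d heteroatoms, %s\n",
              length(x$residues), nrow(x$heteroatoms),
              if (is.null(x$cell)) "non-crystallographic" else
                paste0("space group ", x$cell$spacegroup)))
  invisible(x)
}

#' Read a PDB file into a protein model
#'
#' ATOM records become residues (chain/residue order and alternate
#' locations preserved); HETATM records become heteroatoms. A CRYST1
#' record, when present, provides the unit cell and space group; without
#' one the model is flagged non-crystallographic.
#'
#' @param path PDB file path
#' @return a `protein_model`
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB file ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom
  cell <- NULL
  lines <- readLines(path, warn = FALSE)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr)) {
    f <- cr[1]
    vals <- suppressWarnings(as.numeric(c(substr(f, 7, 15), substr(f, 16, 24),
                                          substr(f, 25, 33), substr(f, 34, 40),
                                          substr(f, 41, 47), substr(f, 48, 54))))
    sg <- trimws(substr(f, 56, 66))
    if (!anyNA(vals) && all(vals[1:3] > 0) && !(all(vals[1:3] == 1)))
      cell <- unit_cell(vals[1], vals[2], vals[3], vals[4], vals[5], vals[6],
                        spacegroup = if (nzchar(sg)) sg else "P 1")
  }
  prot <- at[at$type == "ATOM", , drop = FALSE]
  het <- at[at$type == "HETATM", , drop = FALSE]
  mk_atoms <- function(df) {
    data.frame(name = df$elety,
               element = ifelse(is.na(df$elesy) | df$elesy == "", element_of(df$elety),
                                toupper(df$elesy)),
               x = df$x, y = df$y, z = df$z,
               occupancy = ifelse(is.na(df$o), 1, df$o),
               b_factor = ifelse(is.na(df$b), 0, df$b),
               alt_loc = ifelse(is.na(df$alt), "", df$alt),
               stringsAsFactors = FALSE)
  }
  residues <- list()
  if (nrow(prot)) {
    ins <- ifelse(is.na(prot$insert), "", prot$insert)
    key <- paste(prot$chain, prot$resno, ins, sep = "|")
    for (k in unique(key)) {
      df <- prot[key == k, , drop = FALSE]
      residues[[length(residues) + 1L]] <-
        new_residue(df$resid[1], df$chain[1], df$resno[1], mk_atoms(df),
                    insertion_code = ifelse(is.na(df$insert[1]), "", df$insert[1]))
    }
  }
  protein_model(residues, cell = cell,
                heteroatoms = if (nrow(het)) mk_atoms(het) else empty_atom_table())
}

fmt_atom_name <- function(name, element) {
  if (nchar(name) > 4) stop("atom name too long for PDB field: ", name)
  if (nchar(name) == 4) name
  else if (nchar(element) == 1) sprintf(" %-3s", name)
  else sprintf("%-4s", name)
}

#' Write a protein model to a PDB file
#'
#' Emits CRYST1 (when a cell is present), fixed-width ATOM/HETATM records
#' with coordinates to three decimals, and END.
#'
#' @param model a `protein_model`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_pdb <- function(model, path) {
  lines <- character(0)
  if (!is.null(model$cell)) {
    cl <- model$cell
    lines <- c(lines, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                              cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma,
                              cl$spacegroup, 1L))
  }
  serial <- 0L
  rec <- function(type, a, resid, chain, resno, ins) {
    serial <<- serial + 1L
    sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, fmt_atom_name(a$name, a$element), a$alt_loc, resid,
            chain, resno, ins, a$x, a$y, a$z, a$occupancy, a$b_factor, a$element)
  }
  for (res in model$residues) {
    for (i in seq_len(nrow(res$atoms))) {
      lines <- c(lines, rec("ATOM", res$atoms[i, ], res$res_type, res$chain_id,
                            res$seq_num, res$insertion_code))
    }
  }
  if (nrow(model$heteroatoms)) {
    for (i in seq_len(nrow(model$heteroatoms))) {
      lines <- c(lines, rec("HETATM", model$heteroatoms[i, ], "HOH", "W", i, ""))
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Collapse alternate conformations to a single one
#'
#' For residues with alternate locations, keeps per atom name the copy
#' with the higher occupancy, breaking ties by the lower B factor.
#'
#' @param model a `protein_model`
#' @return the model with single-conformation residues
#' @export
collapse_altlocs <- function(model) {
  model$residues <- lapply(model$residues, function(res) {
    at <- res$atoms
    if (!any(nzchar(at$alt_loc))) return(res)
    keep <- unlist(lapply(split(seq_len(nrow(at)), at$name), function(ix) {
      ix[order(-at$occupancy[ix], at$b_factor[ix])][1]
    }))
    at <- at[sort(keep), , drop = FALSE]
    at$alt_loc <- ""
    at$occupancy <- 1
    rownames(at) <- NULL
    res$atoms <- at
    res
  })
  model
}
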