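# Steric clash model and collision detection with crystallographic
# symmetry (all 27 neighboring unit cells), using bounding-sphere pruning
# with an all-pairs brute-force reference path.

#' Construct a clash model
#'
#' Distance cutoffs per element pair below which two atoms are considered
#' to clash. The bundled table holds minimum observed contact distances;
#' `adjustment` is subtracted from all cutoffs (default 0.3 Angstrom, to
#' tolerate main-chain position error during model building). Waters,
#' ions and ligands use their own threshold.
#'
#' @param adjustment Angstrom subtracted from all cutoffs (>= 0)
#' @param hetero_min minimum side-chain to heteroatom distance, Angstrom
#' @param table optional cutoff table (elem_a, elem_b, min_dist) replacing
#'   the bundled one
#' @return object of class `clash_model`
#' @export
clash_model <- function(adjustment = 0.3, hetero_min = 2.2, table = NULL) {
  stopifnot(adjustment >= 0)
  if (is.null(table)) {
    table <- utils::read.table(.pkg_extdata("clash_cutoffs.txt"), header = FALSE,
                               col.names = c("elem_a", "elem_b", "min_dist"),
                               stringsAsFactors = FALSE)
  }
  elems <- sort(unique(c(table$elem_a, table$elem_b)))
  m <- matrix(2.2, length(elems), length(elems), dimnames = list(elems, elems))
  for (i in seq_len(nrow(table))) {
    m[table$elem_a[i], table$elem_b[i]] <- table$min_dist[i]
    m[table$elem_b[i], table$elem_a[i]] <- table$min_dist[i]
  }
  structure(list(cutoffs = pmax(m - adjustment, 0.5),
                 hetero_min = max(hetero_min - adjustment, 0.5),
                 adjustment = adjustment,
                 max_cutoff = max(m) - adjustment),
            class = "clash_model")
}

clash_cutoff_lookup <- function(cm, elems_a, elems_b) {
  ea <- ifelse(elems_a %in% rownames(cm$cutoffs), elems_a, "C")
  eb <- ifelse(elems_b %in% rownames(cm$cutoffs), elems_b, "C")
  matrix(cm$cutoffs[cbind(rep(ea, times = length(eb)),
                          rep(eb, each = length(ea)))],
         length(ea), length(eb))
}

# TRUE if any atom pair between the two sets is below its cutoff.
any_clash <- function(cm, xa, ea, xb, eb, hetero_b = NULL) {
  if (!nrow(xa) || !nrow(xb)) return(FALSE)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  cut <- clash_cutoff_lookup(cm, ea, eb)
  if (!is.null(hetero_b)) cut[, hetero_b] <- cm$hetero_min
  any(d2 < cut^2 - 1e-12)
}

#' Symmetry-related images of a coordinate block
#'
#' Applies every space-group operator combined with lattice translations
#' of -1/0/+1 cells along each axis (the 27 neighboring unit cells) and
#' returns the transformed copies, optionally restricted to atoms within
#' `radius` of `center`. The identity image (identity operator, zero
#' shift) is excluded unless requested.
#'
#' @param coords n x 3 orthogonal coordinates
#' @param cell a `unit_cell`
#' @param center,radius optional spherical restriction
#' @param include_identity keep the untransformed copy
#' @return list with `coords` (stacked matrix), `source` (original row
#'   index per image atom) and `image` (operator/cell label per atom)
#' @export
symmetry_images <- function(coords, cell, center = NULL, radius = NULL,
                            include_identity = FALSE) {
  fr <- frac_coords(cell, coords)
  out <- list(); src <- list(); lab <- list()
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  for (k in seq_along(cell$ops)) {
    op <- cell$ops[[k]]
    f2 <- t(op$R %*% t(fr)) + rep(op$t, each = nrow(fr))
    for (s in seq_len(nrow(shifts))) {
      if (!include_identity && k == 1 && all(shifts[s, ] == 0)) next
      xo <- orth_coords(cell, f2 + rep(shifts[s, ], each = nrow(f2)))
      keep <- seq_len(nrow(xo))
      if (!is.null(center)) {
        keep <- which(rowSums(sweep(xo, 2, center)^2) <= radius^2)
        if (!length(keep)) next
      }
      out[[length(out) + 1L]] <- xo[keep, , drop = FALSE]
      src[[length(src) + 1L]] <- keep
      lab[[length(lab) + 1L]] <- rep(sprintf("op%d_%+d%+d%+d", k, shifts[s, 1],
                                             shifts[s, 2], shifts[s, 3]),
                                     length(keep))
    }
  }
  if (!length(out)) {
    return(list(coords = matrix(numeric(0), 0, 3), source = integer(0),
                image = character(0)))
  }
  list(coords = do.call(rbind, out), source = unlist(src), image = unlist(lab))
}

# enumerate (operator k, shift) image transforms of a cell
.image_transforms <- function(cell) {
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  tr <- list()
  for (k in seq_along(cell$ops)) {
    for (s in seq_len(nrow(shifts))) {
      tr[[length(tr) + 1L]] <- list(op = k, shift = as.numeric(shifts[s, ]),
                                    identity = (k == 1 && all(shifts[s, ] == 0)))
    }
  }
  tr
}

apply_image <- function(cell, coords, tr) {
  op <- cell$ops[[tr$op]]
  fr <- frac_coords(cell, coords)
  orth_coords(cell, t(op$R %*% t(fr)) + rep(op$t + tr$shift, each = nrow(fr)))
}

#' Detect colliding residue pairs in a joint side-chain assignment
#'
#' With a crystallographic cell, collisions are searched between every
#' residue and every symmetry image (all operators, 27 neighboring unit
#' cells) of every residue, including a residue's own images. Bounding
#' spheres around each placed side chain prune the candidate image pairs
#' before exact atom-pair distances are checked; `method = "brute"`
#' checks every atom pair of every image directly and exists as the
#' correctness reference.
#'
#' @param placed list per residue: list(res_idx, coords, elements)
#' @param cm a `clash_model`
#' @param cell a `unit_cell` or NULL (asymmetric-unit checks only)
#' @param method "pruned" (bounding spheres) or "brute" (all pairs)
#' @return data frame with columns i, j (indices into `placed`) and
#'   `image` (operator/cell label, "asu" for direct contacts)
#' @export
detect_collisions <- function(placed, cm, cell = NULL,
                              method = c("pruned", "brute")) {
  method <- match.arg(method)
  n <- length(placed)
  res <- list()
  add <- function(i, j, image) res[[length(res) + 1L]] <<-
    data.frame(i = i, j = j, image = image, stringsAsFactors = FALSE)
  nonempty <- vapply(placed, function(p) nrow(p$coords) > 0, logical(1))
  # direct (asymmetric-unit) contacts
  for (i in seq_len(n)) {
    if (!nonempty[i]) next
    for (j in seq_len(n)) {
      if (j <= i || !nonempty[j]) next
      if (any_clash(cm, placed[[i]]$coords, placed[[i]]$elements,
                    placed[[j]]$coords, placed[[j]]$elements))
        add(i, j, "asu")
    }
  }
  if (!is.null(cell)) {
    trs <- .image_transforms(cell)
    ctr <- lapply(placed, function(p) if (nrow(p$coords)) colMeans(p$coords) else c(0, 0, 0))
    rad <- vapply(seq_len(n), function(i) {
      p <- placed[[i]]
      if (!nrow(p$coords)) return(0)
      sqrt(max(rowSums(sweep(p$coords, 2, ctr[[i]])^2)))
    }, numeric(1))
    for (tr in trs) {
      if (tr$identity) next
      lab <- sprintf("op%d_%+d%+d%+d", tr$op, tr$shift[1], tr$shift[2], tr$shift[3])
      for (j in seq_len(n)) {
        if (!nonempty[j]) next
        cj <- apply_image(cell, placed[[j]]$coords, tr)
        ctj <- colMeans(cj)
        for (i in seq_len(n)) {
          if (!nonempty[i]) next
          # each unordered image pair once: i <= j over non-identity images
          if (i > j) next
          if (method == "pruned") {
            if (vnorm(ctj - ctr[[i]]) > rad[i] + rad[j] + cm$max_cutoff) next
          }
          if (any_clash(cm, placed[[i]]$coords, placed[[i]]$elements,
                        cj, placed[[j]]$elements))
            add(i, j, lab)
        }
      }
    }
  }
  if (!length(res)) {
    return(data.frame(i = integer(0), j = integer(0), image = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out[order(out$i, out$j, out$image), , drop = FALSE]
}
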