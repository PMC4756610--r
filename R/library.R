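# Hierarchical conformer library: geometry/clash filters, deduplication,
# complete-linkage clustering with weighted medoids, level cuts (clX),
# local cluster expansion, frequency assignment and a versioned JSON
# container.

.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

.lib_schema_version <- "rotafit-library-1"

# Ideal geometry targets derived from the side-chain templates; sigma
# values follow standard stereochemical-target conventions.
.geometry_targets <- local({
  cache <- new.env()
  function(res_type) {
    if (!is.null(cache[[res_type]])) return(cache[[res_type]])
    zm <- sidechain_template(res_type)$zmat
    bb <- canonical_backbone()
    cb <- build_sidechain(res_type, rep(-60, n_chi(res_type)))
    tg <- list(
      bonds = data.frame(a = zm$c, b = zm$name, target = zm$bond, sigma = 0.02),
      angles = data.frame(a = zm$b, b = zm$c, c = zm$name, target = zm$angle, sigma = 2.5),
      cb_mean = if ("CB" %in% rownames(cb)) cb["CB", ] else NULL,
      cb_sigma = 0.25)
    cache[[res_type]] <- tg
    tg
  }
})

#' Screen a residue's side-chain conformation for library inclusion
#'
#' Rejects conformations that (a) overlap context atoms by more than
#' 0.4 Angstrom in van der Waals radii, (b) have a bond length or angle
#' deviating more than 6 sigma from the ideal stereochemical target,
#' (c) have a CB position more than 5 sigma from the type mean in the
#' canonical frame, or (d) are incomplete.
#'
#' @param residue a `residue` (nomenclature-normalized)
#' @param context data frame of surrounding atoms (columns element, x, y,
#'   z), excluding the residue itself; may be NULL
#' @param max_overlap van der Waals overlap cutoff, Angstrom
#' @return list with `accept` (logical) and `reason`
#' @export
filter_conformation <- function(residue, context = NULL, max_overlap = 0.4) {
  tpl <- sidechain_template(residue$res_type)
  if (is.null(tpl$zmat)) return(list(accept = FALSE, reason = "no side chain"))
  nms <- tpl$zmat$name
  pos <- residue_atom_pos(residue, nms)
  if (anyNA(pos)) return(list(accept = FALSE, reason = "incomplete"))
  # clash screen against the context
  if (!is.null(context) && nrow(context)) {
    cx <- as.matrix(context[, c("x", "y", "z")])
    rc <- .vdw_radii[context$element]
    rc[is.na(rc)] <- 1.7
    for (i in seq_along(nms)) {
      ra <- .vdw_radii[[element_of(nms[i])]]
      d <- sqrt(colSums((t(cx) - pos[i, ])^2))
      if (any((ra + rc) - d > max_overlap))
        return(list(accept = FALSE, reason = "clash"))
    }
  }
  # stereochemical targets
  tg <- .geometry_targets(residue$res_type)
  bbpos <- residue_atom_pos(residue, c("N", "CA", "C"))
  allpos <- rbind(bbpos, pos)
  for (i in seq_len(nrow(tg$bonds))) {
    b <- tg$bonds[i, ]
    d <- vnorm(allpos[b$a, ] - allpos[b$b, ])
    if (abs(d - b$target) > 6 * b$sigma)
      return(list(accept = FALSE, reason = "bond geometry"))
  }
  for (i in seq_len(nrow(tg$angles))) {
    an <- tg$angles[i, ]
    a <- bond_angle(allpos[an$a, ], allpos[an$b, ], allpos[an$c, ])
    if (abs(a - an$target) > 6 * an$sigma)
      return(list(accept = FALSE, reason = "angle geometry"))
  }
  # CB position in the canonical frame
  if (!is.null(tg$cb_mean)) {
    tf <- local_frame(residue)
    cb <- apply_transform(tf, pos["CB", ])
    if (vnorm(cb - tg$cb_mean) > 5 * tg$cb_sigma)
      return(list(accept = FALSE, reason = "CB deviation"))
  }
  list(accept = TRUE, reason = NA_character_)
}

#' Remove conformational redundancy
#'
#' Greedy pass in input order (callers order by decreasing source
#' resolution quality): a conformation is retained only if its side-chain
#' r.m.s.d. to every previously retained conformation exceeds `min_rmsd`;
#' otherwise the count of its nearest retained conformation is
#' incremented. Order-stable.
#'
#' @param confs list of `conformation`s of one residue type
#' @param min_rmsd redundancy threshold, Angstrom
#' @return list of retained conformations with updated counts
#' @export
deduplicate <- function(confs, min_rmsd = 0.1) {
  kept <- list()
  for (cf in confs) {
    if (!length(kept)) { kept[[1]] <- cf; next }
    d <- vapply(kept, sidechain_rmsd, numeric(1), conf_b = cf)
    j <- which.min(d)
    if (d[j] > min_rmsd) kept[[length(kept) + 1L]] <- cf
    else kept[[j]]$count <- kept[[j]]$count + cf$count
  }
  kept
}

# Weighted medoid: member minimizing the occurrence-weighted sum of
# r.m.s.d. values to all other members; ties -> lowest index.
weighted_medoid <- function(dmat, counts, members) {
  if (length(members) == 1) return(members)
  score <- as.numeric(dmat[members, members, drop = FALSE] %*% counts[members])
  members[which.min(score)]
}

build_type_tree <- function(confs) {
  n <- length(confs)
  dmat <- matrix(0, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dmat[i, j] <- dmat[j, i] <- sidechain_rmsd(confs[[i]], confs[[j]])
    }
  }
  hc <- if (n > 1) stats::hclust(stats::as.dist(dmat), method = "complete") else NULL
  list(confs = confs, dist = dmat, hclust = hc,
       counts = vapply(confs, function(cf) cf$count, integer(1)))
}

#' Build a hierarchical conformer library
#'
#' Per residue type, computes all pairwise side-chain r.m.s.d. values
#' (excluding CB), performs complete-linkage agglomerative clustering and
#' stores the full linkage so the hierarchy can be cut at any level X
#' (clX) or locally expanded.
#'
#' @param confs_by_type named list (residue type -> list of deduplicated
#'   `conformation`s)
#' @return object of class `conformer_library`
#' @export
build_tree <- function(confs_by_type) {
  types <- list()
  for (rt in names(confs_by_type)) {
    confs <- confs_by_type[[rt]]
    if (!length(confs)) next
    for (i in seq_along(confs)) confs[[i]]$id <- sprintf("%s_%03d", rt, i)
    types[[rt]] <- build_type_tree(confs)
  }
  structure(list(types = types), class = "conformer_library")
}

#' @export
print.conformer_library <- function(x, ...) {
  cat("conformer library:\n")
  for (rt in names(x$types))
    cat(sprintf("  %s: %d conformations\n", rt, length(x$types[[rt]]$confs)))
  invisible(x)
}

type_cut_groups <- function(tt, X) {
  n <- length(tt$confs)
  if (n == 1) return(rep(1L, 1))
  stats::cutree(tt$hclust, h = X)
}

#' Cut the library hierarchy at level X (the clX library)
#'
#' Partitions the leaves of each residue type into the maximal clusters
#' whose complete-linkage merge height (equivalently, maximum pairwise
#' side-chain r.m.s.d.) is at most X Angstrom, and returns the weighted
#' medoid of each cluster. Representative counts and frequencies are the
#' totals over the cluster members.
#'
#' @param library a `conformer_library`
#' @param X cut level, Angstrom (> 0)
#' @param types optional subset of residue types
#' @return named list (type -> list of representative `conformation`s);
#'   each representative carries a `members` attribute with leaf indices
#' @export
cut_level <- function(library, X, types = NULL) {
  stopifnot(X > 0)
  if (is.null(types)) types <- names(library$types)
  out <- list()
  for (rt in types) {
    tt <- library$types[[rt]]
    if (is.null(tt)) next
    grp <- type_cut_groups(tt, X)
    reps <- list()
    for (g in sort(unique(grp))) {
      members <- which(grp == g)
      med <- weighted_medoid(tt$dist, tt$counts, members)
      cf <- tt$confs[[med]]
      cf$count <- sum(tt$counts[members])
      fr <- vapply(tt$confs[members], function(z) z$frequency, numeric(1))
      cf$frequency <- if (all(is.na(fr))) NA_real_ else sum(fr, na.rm = TRUE)
      attr(cf, "members") <- members
      reps[[length(reps) + 1L]] <- cf
    }
    out[[rt]] <- reps
  }
  out
}

#' Expand the cluster neighborhood of a selected conformation
#'
#' Finds the cluster K1 containing `selected_conf` at `search_level`,
#' ascends to its superset K2 at the coarser `low_level`, then descends
#' and returns the medoids of all descendants of K2 at the finer
#' `high_level`. The selected conformation's own refined representatives
#' are always included.
#'
#' @param library a `conformer_library`
#' @param selected_conf a `conformation` with a library id
#' @param low_level coarse level, Angstrom (e.g. 1.5)
#' @param high_level fine level, Angstrom (e.g. 0.4)
#' @param search_level the level the selection was made at (e.g. 0.7)
#' @return list of representative `conformation`s
#' @export
expand_cluster <- function(library, selected_conf, low_level = 1.5,
                           high_level = 0.4, search_level = 0.7) {
  if (!(low_level > search_level && search_level > high_level))
    stop("expansion levels must satisfy low_level > search_level > high_level")
  rt <- selected_conf$res_type
  tt <- library$types[[rt]]
  if (is.null(tt)) stop("residue type not in library: ", rt)
  ids <- vapply(tt$confs, function(cf) cf$id, character(1))
  leaf <- match(selected_conf$id, ids)
  if (is.na(leaf)) stop("conformation id not found in library: ", selected_conf$id)
  grp_low <- type_cut_groups(tt, low_level)
  k2_members <- which(grp_low == grp_low[leaf])
  grp_high <- type_cut_groups(tt, high_level)
  reps <- list()
  for (g in sort(unique(grp_high[k2_members]))) {
    members <- which(grp_high == g)
    med <- weighted_medoid(tt$dist, tt$counts, members)
    cf <- tt$confs[[med]]
    cf$count <- sum(tt$counts[members])
    fr <- vapply(tt$confs[members], function(z) z$frequency, numeric(1))
    cf$frequency <- if (all(is.na(fr))) NA_real_ else sum(fr, na.rm = TRUE)
    reps[[length(reps) + 1L]] <- cf
  }
  reps
}

chi_of_conformation <- function(cf) {
  chi_from_coords(rbind(canonical_backbone(), cf$coords), cf$res_type)
}

torus_dist <- function(a, b) {
  k <- min(length(a), length(b))
  if (k == 0) return(Inf)
  sqrt(sum(wrap_angle(a[seq_len(k)] - b[seq_len(k)])^2))
}

#' Assign occurrence frequencies by inverse-distance interpolation
#'
#' Each conformation's frequency is interpolated from a table of rotamer
#' frequency samples (chi-space probability masses, backbone-independent)
#' with inverse-distance weights `1/d^q` on the chi torus (degrees). An
#' exact chi match takes the sample's probability directly. Frequencies
#' are then normalized to sum to one per residue type.
#'
#' @param library a `conformer_library`
#' @param samples data frame with columns `res_type`, `chi1`..`chi4`
#'   (NA-padded) and `probability`
#' @param q inverse-distance exponent
#' @return the library with frequencies filled in
#' @export
assign_frequencies <- function(library, samples, q = 2) {
  for (rt in names(library$types)) {
    tt <- library$types[[rt]]
    sm <- samples[samples$res_type == rt, , drop = FALSE]
    n <- length(tt$confs)
    if (!nrow(sm)) {
      warning("no rotamer-frequency samples for ", rt, "; using uniform frequencies")
      p <- rep(1 / n, n)
    } else {
      chic <- c("chi1", "chi2", "chi3", "chi4")
      smchi <- lapply(seq_len(nrow(sm)), function(i) {
        v <- as.numeric(sm[i, chic]); v[!is.na(v)]
      })
      p <- vapply(seq_len(n), function(i) {
        chi <- chi_of_conformation(tt$confs[[i]])
        d <- vapply(smchi, torus_dist, numeric(1), a = chi)
        if (any(d == 0)) return(mean(sm$probability[d == 0]))
        w <- 1 / d^q
        sum(w * sm$probability) / sum(w)
      }, numeric(1))
      p <- p / sum(p)
    }
    for (i in seq_len(n)) library$types[[rt]]$confs[[i]]$frequency <- p[i]
  }
  library
}

#' Save a conformer library to a versioned JSON container
#'
#' Losslessly stores coordinates, counts, frequencies and linkage per
#' residue type.
#'
#' @param library a `conformer_library`
#' @param path output path
#' @return `path`, invisibly
#' @export
save_library <- function(library, path) {
  types <- lapply(library$types, function(tt) {
    list(atoms = rownames(tt$confs[[1]]$coords),
         coords = lapply(tt$confs, function(cf) as.numeric(cf$coords)),
         counts = vapply(tt$confs, function(cf) cf$count, integer(1)),
         frequencies = vapply(tt$confs, function(cf) cf$frequency, numeric(1)),
         ids = vapply(tt$confs, function(cf) cf$id, character(1)),
         merge = if (is.null(tt$hclust)) NULL else tt$hclust$merge,
         height = if (is.null(tt$hclust)) NULL else tt$hclust$height,
         order = if (is.null(tt$hclust)) NULL else tt$hclust$order,
         dist = as.numeric(tt$dist[upper.tri(tt$dist)]))
  })
  obj <- list(schema = .lib_schema_version, types = types)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a conformer library (optionally a subset of residue types)
#' @param path container path written by [save_library()]
#' @param types optional residue types to load
#' @return a `conformer_library`
#' @export
load_library <- function(path, types = NULL) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("unreadable library container ", path,
                                           ": ", conditionMessage(e)))
  if (is.null(obj$schema) || !identical(obj$schema, .lib_schema_version))
    stop("library container schema mismatch: expected ", .lib_schema_version,
         ", found ", if (is.null(obj$schema)) "none" else obj$schema)
  want <- if (is.null(types)) names(obj$types) else intersect(types, names(obj$types))
  out <- list()
  for (rt in want) {
    tt <- obj$types[[rt]]
    natoms <- length(tt$atoms)
    coords_list <- if (is.list(tt$coords)) tt$coords else
      lapply(seq_len(nrow(tt$coords)), function(i) tt$coords[i, ])
    confs <- lapply(seq_along(coords_list), function(i) {
      m <- matrix(as.numeric(coords_list[[i]]), natoms, 3)
      rownames(m) <- tt$atoms
      conformation(rt, m, count = tt$counts[i], frequency = tt$frequencies[i],
                   id = tt$ids[i])
    })
    n <- length(confs)
    dmat <- matrix(0, n, n)
    dmat[upper.tri(dmat)] <- as.numeric(tt$dist)
    dmat <- dmat + t(dmat)
    hc <- NULL
    if (!is.null(tt$merge) && n > 1) {
      hc <- structure(list(merge = matrix(as.integer(unlist(tt$merge)), ncol = 2),
                           height = as.numeric(tt$height),
                           order = as.integer(tt$order),
                           labels = NULL, method = "complete",
                           call = NULL, dist.method = "sidechain_rmsd"),
                      class = "hclust")
    }
    out[[rt]] <- list(confs = confs, dist = dmat, hclust = hc,
                      counts = vapply(confs, function(cf) cf$count, integer(1)))
  }
  structure(list(types = out), class = "conformer_library")
}
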