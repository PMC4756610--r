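# Evaluation kit: perturbation test sets (TS_dX_rY-style), accuracy
# metrics, a density-significance proxy and validation classification.

#' Perturbation specification for test-set generation
#'
#' @param delete_fraction X: fraction of eligible residues whose side
#'   chains are removed past CB
#' @param randomize_fraction Y: fraction whose chi angles are randomized
#' @param seed RNG seed
#' @param max_rotation half-width of the uniform chi rotation, degrees
#' @return object of class `perturbation_spec`
#' @export
perturbation_spec <- function(delete_fraction = 0, randomize_fraction = 0,
                              seed = 1, max_rotation = 40) {
  if (delete_fraction < 0 || delete_fraction > 1 ||
      randomize_fraction < 0 || randomize_fraction > 1)
    stop("fractions must lie in [0, 1]")
  if (delete_fraction + randomize_fraction > 1)
    stop("delete_fraction + randomize_fraction must not exceed 1")
  structure(list(delete_fraction = delete_fraction,
                 randomize_fraction = randomize_fraction,
                 seed = seed, max_rotation = max_rotation),
            class = "perturbation_spec")
}

# residues whose side chains can be perturbed/refit: anything with
# rotatable chi angles except Pro (degenerate ring sampling)
perturbable <- function(residue) {
  residue$res_type %in% setdiff(sidechain_types(), "PRO") &&
    !anyNA(residue_atom_pos(residue, c("N", "CA", "C")))
}

#' Does a residue carry all side-chain heavy atoms of its type?
#' @param residue a `residue`
#' @return logical
#' @export
has_complete_sidechain <- function(residue) {
  tpl <- sidechain_template(residue$res_type)
  if (is.null(tpl$zmat)) return(FALSE)
  !anyNA(residue_atom_pos(residue, tpl$zmat$name))
}

#' Perturb a model into a TS_dX_rY-style test case
#'
#' Deletes the side chains (past CB) of an X-fraction of the eligible
#' residues and randomizes a disjoint Y-fraction by rotating every chi
#' angle by an independent uniform draw in +/- `max_rotation` degrees.
#' Deterministic given the spec's seed; the returned ground truth allows
#' exact restoration.
#'
#' @param model a `protein_model`
#' @param spec a `perturbation_spec`
#' @return list with `model` (perturbed), `truth` (original residues for
#'   every touched index) and `touched` (data frame: index, action, draws)
#' @export
perturb_model <- function(model, spec) {
  elig <- which(vapply(model$residues, function(r)
    perturbable(r) && has_complete_sidechain(r), logical(1)))
  set.seed(spec$seed)
  n_del <- round(spec$delete_fraction * length(elig))
  n_rand <- round(spec$randomize_fraction * length(elig))
  n_rand <- min(n_rand, length(elig) - n_del)
  picked <- if (n_del + n_rand > 0) sample(elig, n_del + n_rand) else integer(0)
  del <- picked[seq_len(n_del)]
  rnd <- picked[setdiff(seq_len(n_del + n_rand), seq_len(n_del))]
  truth <- model$residues[picked]
  names(truth) <- as.character(picked)
  rows <- list()
  for (i in del) {
    model$residues[[i]] <- strip_sidechain(model$residues[[i]])
    rows[[length(rows) + 1L]] <- data.frame(index = i, action = "deleted",
                                            draws = NA_character_)
  }
  for (i in rnd) {
    res <- model$residues[[i]]
    k <- n_chi(res$res_type)
    dr <- stats::runif(k, -spec$max_rotation, spec$max_rotation)
    cur <- chi_angles(res)
    for (kk in seq_len(k)) res <- set_chi(res, kk, cur[kk] + dr[kk])
    model$residues[[i]] <- res
    rows[[length(rows) + 1L]] <- data.frame(index = i, action = "randomized",
                                            draws = paste(round(dr, 4), collapse = ";"))
  }
  touched <- if (length(rows)) do.call(rbind, rows) else
    data.frame(index = integer(0), action = character(0), draws = character(0))
  list(model = model, truth = truth, touched = touched)
}

#' Restore a perturbed model from its ground-truth record
#' @param model the perturbed `protein_model`
#' @param truth the `truth` element returned by [perturb_model()]
#' @return the restored model
#' @export
restore_model <- function(model, truth) {
  for (nm in names(truth)) model$residues[[as.integer(nm)]] <- truth[[nm]]
  model
}

# chi deviations between two residues, with optional symmetric treatment
# (terminal-swap-equivalent conformations compared as equal)
max_chi_dev <- function(res_a, res_b, symmetric_ngh = TRUE) {
  na <- normalize_nomenclature(res_a, symmetric = symmetric_ngh &&
                                 res_a$res_type %in% c("ASN", "GLN", "HIS"))
  nb <- normalize_nomenclature(res_b, symmetric = symmetric_ngh &&
                                 res_b$res_type %in% c("ASN", "GLN", "HIS"))
  ca <- chi_angles(na$residue); cb <- chi_angles(nb$residue)
  if (!length(ca)) return(0)
  dev <- abs(wrap_angle(ca - cb))
  # the terminal torsion of two-fold symmetric groups is only defined
  # modulo 180 degrees (the swapped naming is the same structure)
  twofold <- res_a$res_type %in% c("ASP", "GLU", "PHE", "TYR") ||
    (symmetric_ngh && res_a$res_type %in% c("ASN", "GLN", "HIS"))
  if (twofold) {
    k <- length(dev)
    dev[k] <- min(dev[k], 180 - dev[k])
  }
  max(dev)
}

residue_pair_rmsd <- function(res_a, res_b, symmetric_ngh = TRUE) {
  na <- normalize_nomenclature(res_a, symmetric = symmetric_ngh &&
                                 res_a$res_type %in% c("ASN", "GLN", "HIS"))
  nb <- normalize_nomenclature(res_b, symmetric = symmetric_ngh &&
                                 res_b$res_type %in% c("ASN", "GLN", "HIS"))
  sidechain_rmsd(conformation_from_residue(na$residue),
                 conformation_from_residue(nb$residue))
}

#' Side-chain modeling accuracy
#'
#' Percentage of eligible residues (Ala and Gly excluded) whose fitted
#' side chain matches the reference under the chosen criterion: r.m.s.d.
#' of at most 0.5 Angstrom over side-chain atoms beyond CB
#' (`"rmsd_0.5"`), or every chi angle within 20 degrees (`"chi_20"`).
#' Asn/Gln/His are compared under symmetric terminal-group treatment when
#' `symmetric_ngh` is TRUE.
#'
#' @param reference,fitted `protein_model`s with corresponding residues
#' @param criterion `"rmsd_0.5"` or `"chi_20"`
#' @param symmetric_ngh treat Asn/Gln/His terminal groups as symmetric
#' @return list with `percent`, `n_eligible`, `n_matched` and the
#'   per-residue logical vector `matched` (NA for ineligible residues)
#' @export
accuracy <- function(reference, fitted, criterion = c("rmsd_0.5", "chi_20"),
                     symmetric_ngh = TRUE) {
  criterion <- match.arg(criterion)
  ids_ref <- vapply(reference$residues, residue_id, character(1))
  ids_fit <- vapply(fitted$residues, residue_id, character(1))
  matched <- rep(NA, length(reference$residues))
  for (i in seq_along(reference$residues)) {
    ra <- reference$residues[[i]]
    j <- match(ids_ref[i], ids_fit)
    if (is.na(j)) next
    rb <- fitted$residues[[j]]
    if (ra$res_type %in% c("ALA", "GLY") || ra$res_type != rb$res_type) next
    if (!has_complete_sidechain(ra) || !has_complete_sidechain(rb)) next
    matched[i] <- if (criterion == "rmsd_0.5") {
      residue_pair_rmsd(ra, rb, symmetric_ngh) <= 0.5
    } else {
      max_chi_dev(ra, rb, symmetric_ngh) <= 20
    }
  }
  n_elig <- sum(!is.na(matched))
  if (n_elig == 0) {
    return(list(percent = NA_real_, n_eligible = 0L, n_matched = 0L,
                matched = matched))
  }
  list(percent = 100 * sum(matched, na.rm = TRUE) / n_elig,
       n_eligible = n_elig, n_matched = sum(matched, na.rm = TRUE),
       matched = matched)
}

#' Density-significance Z-score of a side chain
#'
#' Mean normalized density over the side-chain atoms (CB onward),
#' expressed in map-r.m.s.d. units — a simplified real-space support
#' proxy; values above 1 indicate a side chain supported by density.
#'
#' @param map a `density_map`
#' @param residue a `residue`
#' @return Z-score, or NA when the residue has no side-chain atoms
#' @export
density_significance <- function(map, residue) {
  tpl <- sidechain_template(residue$res_type)
  if (is.null(tpl$zmat)) return(NA_real_)
  pos <- residue_atom_pos(residue, tpl$zmat$name)
  pos <- pos[!apply(is.na(pos), 1, any), , drop = FALSE]
  if (!nrow(pos)) return(NA_real_)
  mean(sample_rho_prime(map, pos, 0))
}

#' Classify fitting results for model validation
#'
#' Per residue: `unfittable` when the search could not place a
#' collision-free conformation (a main-chain or sequence warning);
#' `rebuilt` when the original model lacked the side chain and the
#' fitted one occupies significant density; `improved_fit` when the
#' conformation changed (some chi beyond 20 degrees) into more
#' significant density; `changed` when it changed without better
#' support; `match` otherwise.
#'
#' @param original_model the model before refitting
#' @param solution a fit `solution` (see [fit_model()])
#' @param map the `density_map` used for fitting
#' @param z_threshold significance threshold
#' @return data frame: residue id, type, status, category, z_original,
#'   z_fitted, max_chi_dev
#' @export
classify_validation <- function(original_model, solution, map, z_threshold = 1) {
  fitted <- solution$model
  out <- list()
  for (i in seq_along(original_model$residues)) {
    ro <- original_model$residues[[i]]
    rf <- fitted$residues[[i]]
    st <- solution$status$status[i]
    zo <- if (has_complete_sidechain(ro)) density_significance(map, ro) else NA_real_
    zf <- if (has_complete_sidechain(rf)) density_significance(map, rf) else NA_real_
    cat_ <- "match"; dev <- NA_real_
    if (identical(st, "unfittable")) {
      cat_ <- "unfittable"
    } else if (!has_complete_sidechain(ro)) {
      cat_ <- if (!is.na(zf) && zf > z_threshold) "rebuilt" else "match"
    } else if (has_complete_sidechain(rf) && ro$res_type == rf$res_type &&
               !(ro$res_type %in% c("ALA", "GLY"))) {
      dev <- max_chi_dev(ro, rf)
      if (dev > 20) {
        cat_ <- if (!is.na(zf) && !is.na(zo) && zf > zo) "improved_fit" else "changed"
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      id = residue_id(ro), res_type = ro$res_type, status = st, category = cat_,
      z_original = zo, z_fitted = zf, max_chi_dev = dev, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
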