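# End-to-end workflows: library building from coordinate sets, the
# three-stage side-chain fitting driver, and model evaluation reports.

#' Fitting configuration
#'
#' @param search_level conformer-library cut used for stages I-II,
#'   Angstrom (cl0.7 by default: a good accuracy/speed compromise)
#' @param expand_low,expand_high cluster-expansion levels for stage III
#'   (coarse superset / fine refinement)
#' @param clash_adjustment Angstrom subtracted from all clash cutoffs
#' @param energy an `energy_params`
#' @param astar_threshold cluster size below which stage III uses A*
#'   directly; larger clusters get a pairs-elimination cycle first
#' @param expand enable stage-III cluster expansion
#' @param h_variants enable polar-hydrogen variant enumeration
#' @param keep_existing only rebuild missing/flagged side chains
#' @param max_candidates stage-III candidate cap per residue (falls back
#'   to the unexpanded set beyond it)
#' @param seed RNG seed recorded with the run
#' @return object of class `fit_config`
#' @export
fit_config <- function(search_level = 0.7, expand_low = 1.5, expand_high = 0.4,
                       clash_adjustment = 0.3, energy = energy_params(),
                       astar_threshold = 15, expand = TRUE, h_variants = TRUE,
                       keep_existing = FALSE, max_candidates = 80, seed = 1) {
  stopifnot(expand_low > search_level, search_level > expand_high)
  structure(list(search_level = search_level, expand_low = expand_low,
                 expand_high = expand_high, clash_adjustment = clash_adjustment,
                 energy = energy, astar_threshold = astar_threshold,
                 expand = expand, h_variants = h_variants,
                 keep_existing = keep_existing, max_candidates = max_candidates,
                 seed = seed),
            class = "fit_config")
}

#' Build a conformer library from a set of model chains
#'
#' Runs the full library pipeline: altloc selection (higher occupancy,
#' then lower B), nomenclature normalization (Asn/Gln/His treated as
#' symmetric), geometry/clash/chirality filters, optional
#' density-significance screening, 0.1-Angstrom deduplication (processing
#' chains in the given order, highest-quality first), complete-linkage
#' clustering and frequency assignment.
#'
#' @param chains list of `protein_model`s (ordered by decreasing source
#'   quality/resolution)
#' @param rotamer_table frequency samples (see [synthetic_rotamer_table()])
#' @param maps optional list of `density_map`s parallel to `chains` for
#'   density-significance screening
#' @param min_significance density Z-score below which conformations are
#'   screened out (only with maps)
#' @param min_count drop conformations observed fewer times (substitute
#'   for manual outlier inspection)
#' @return list with `library` (a `conformer_library`) and `report`
#'   (counts per filter reason)
#' @export
build_library <- function(chains, rotamer_table = synthetic_rotamer_table(),
                          maps = NULL, min_significance = 1, min_count = 1) {
  confs <- list()
  report <- c(input = 0L, accepted = 0L, rejected_clash = 0L,
              rejected_geometry = 0L, rejected_incomplete = 0L,
              rejected_chirality = 0L, rejected_density = 0L, no_sidechain = 0L)
  for (ci in seq_along(chains)) {
    model <- collapse_altlocs(chains[[ci]])
    atoms_by_res <- lapply(model$residues, function(r) r$atoms)
    for (ri in seq_along(model$residues)) {
      res <- model$residues[[ri]]
      report["input"] <- report["input"] + 1L
      if (!(res$res_type %in% sidechain_types())) {
        report["no_sidechain"] <- report["no_sidechain"] + 1L
        next
      }
      nn <- normalize_nomenclature(res, symmetric = res$res_type %in%
                                     c("ASN", "GLN", "HIS"))
      if (nn$rejected) {
        report["rejected_chirality"] <- report["rejected_chirality"] + 1L
        next
      }
      res <- nn$residue
      # context: all other residues' atoms (bonded main-chain atoms of the
      # sequence neighbors excluded) plus heteroatoms
      ctx <- do.call(rbind, lapply(seq_along(atoms_by_res), function(rj) {
        if (rj == ri) return(NULL)
        at <- atoms_by_res[[rj]]
        if (abs(rj - ri) == 1)
          at <- at[!(at$name %in% c("N", "CA", "C", "O", "H")), , drop = FALSE]
        at[, c("element", "x", "y", "z")]
      }))
      if (nrow(model$heteroatoms))
        ctx <- rbind(ctx, model$heteroatoms[, c("element", "x", "y", "z")])
      fl <- filter_conformation(res, ctx)
      if (!fl$accept) {
        key <- switch(fl$reason, clash = "rejected_clash",
                      incomplete = "rejected_incomplete", "rejected_geometry")
        report[key] <- report[key] + 1L
        next
      }
      if (!is.null(maps) && !is.null(maps[[ci]])) {
        z <- density_significance(maps[[ci]], res)
        if (!is.na(z) && z < min_significance) {
          report["rejected_density"] <- report["rejected_density"] + 1L
          next
        }
      }
      cf <- conformation_from_residue(res, strict = FALSE)
      if (is.null(cf)) {
        report["rejected_incomplete"] <- report["rejected_incomplete"] + 1L
        next
      }
      report["accepted"] <- report["accepted"] + 1L
      confs[[cf$res_type]] <- c(confs[[cf$res_type]], list(cf))
    }
  }
  dedup <- lapply(confs, deduplicate)
  if (min_count > 1) {
    dedup <- lapply(dedup, function(l) Filter(function(cf) cf$count >= min_count, l))
    dedup <- Filter(length, dedup)
  }
  lib <- build_tree(dedup)
  lib <- assign_frequencies(lib, rotamer_table)
  list(library = lib, report = report)
}

# placed candidate bookkeeping for one residue
.place_candidates <- function(confs, residue) {
  inv <- invert_transform(local_frame(residue))
  lapply(confs, function(cf) {
    cf$placed <- apply_transform(inv, cf$coords)
    cf$elements <- element_of(rownames(cf$coords))
    cf
  })
}

.heavy <- function(coords) coords[!startsWith(rownames(coords), "H"), , drop = FALSE]

#' Fit side chains into density with the three-stage search
#'
#' Stage I ranks each residue's library conformations by the simplified
#' self-energy (density + frequency) and picks the best
#' environment-compatible one with lazy clash evaluation. Stage II
#' resolves side-chain/side-chain collisions — including contacts with
#' crystallographic images across the 27 neighboring unit cells — by
#' best-first graph search, yielding the optimal collision-free
#' assignment under the simplified energy. Stage III expands candidates
#' around the selected conformations (finer library level, Asn/Gln/His
#' flips, polar-H variants), computes full self- and pairwise energies
#' and extracts the global minimum-energy conformation by dead-end
#' elimination plus exact cluster search.
#'
#' @param model a `protein_model` (fixed backbone)
#' @param map a `density_map` covering the model
#' @param library a `conformer_library`
#' @param config a `fit_config`
#' @return a `solution`: list with `model` (side chains rebuilt),
#'   `status` (per-residue data frame), `energy` and `diagnostics`
#' @export
fit_model <- function(model, map, library, config = fit_config()) {
  model <- collapse_altlocs(model)
  cm <- clash_model(config$clash_adjustment)
  ep <- config$energy
  env <- backbone_environment(model)
  envX <- as.matrix(env[, c("x", "y", "z")])
  envE <- element_of(env$name)
  het <- model$heteroatoms
  n_res <- length(model$residues)

  status <- rep("skipped", n_res)
  reason <- rep(NA_character_, n_res)
  eligible <- which(vapply(model$residues, function(r) {
    perturbable(r) && r$res_type %in% names(library$types)
  }, logical(1)))
  for (i in seq_len(n_res)) {
    rt <- model$residues[[i]]$res_type
    if (rt %in% setdiff(sidechain_types(), "PRO") &&
        !(rt %in% names(library$types)) && !(i %in% eligible))
      reason[i] <- "type absent from library"
  }
  if (config$keep_existing) {
    eligible <- eligible[!vapply(model$residues[eligible], has_complete_sidechain,
                                 logical(1))]
  }
  had_sidechain <- vapply(model$residues, has_complete_sidechain, logical(1))

  # symmetry images of the fixed environment near the model
  ext <- NULL
  if (!is.null(model$cell)) {
    allX <- rbind(envX, if (nrow(het)) as.matrix(het[, c("x", "y", "z")]))
    ctr <- colMeans(allX)
    rad <- sqrt(max(rowSums(sweep(allX, 2, ctr)^2)))
    img <- symmetry_images(envX, model$cell, center = ctr,
                           radius = rad + cm$max_cutoff + 1)
    if (nrow(img$coords)) ext <- list(coords = img$coords, elements = envE[img$source])
  }

  reps_by_type <- cut_level(library, config$search_level,
                            unique(vapply(model$residues[eligible],
                                          function(r) r$res_type, character(1))))
  cands <- vector("list", n_res)
  D <- vector("list", n_res); P <- vector("list", n_res); Ex <- vector("list", n_res)
  for (i in eligible) {
    res <- model$residues[[i]]
    cands[[i]] <- .place_candidates(reps_by_type[[res$res_type]], res)
    D[[i]] <- vapply(cands[[i]], function(cf) density_score(map, cf$placed, ep$density),
                     numeric(1))
    P[[i]] <- vapply(cands[[i]], function(cf) cf$frequency, numeric(1))
    Ex[[i]] <- vapply(seq_along(cands[[i]]), function(s)
      e_self_simplified(D[[i]][s], max(D[[i]]), P[[i]][s], max(P[[i]]), ep), numeric(1))
  }

  # environment clash check (backbone/CB/heteroatoms/symmetry images and
  # the conformation's own crystallographic images), memoized
  env_ok_cache <- lapply(seq_len(n_res), function(i)
    rep(NA, length(cands[[i]])))
  env_clash <- function(i, s) {
    v <- env_ok_cache[[i]][s]
    if (!is.na(v)) return(v)
    cf <- cands[[i]][[s]]
    keep <- !env_exclusion(env, i)
    hit <- any_clash(cm, cf$placed, cf$elements, envX[keep, , drop = FALSE],
                     envE[keep])
    if (!hit && nrow(het)) {
      hit <- any_clash(cm, cf$placed, cf$elements,
                       as.matrix(het[, c("x", "y", "z")]), het$element,
                       hetero_b = rep(TRUE, nrow(het)))
    }
    if (!hit && !is.null(ext)) {
      hit <- any_clash(cm, cf$placed, cf$elements, ext$coords, ext$elements)
    }
    if (!hit && !is.null(model$cell)) {
      # own symmetry image
      ctr <- colMeans(cf$placed)
      rad <- sqrt(max(rowSums(sweep(cf$placed, 2, ctr)^2)))
      img <- symmetry_images(cf$placed, model$cell, center = ctr,
                             radius = 2 * rad + cm$max_cutoff)
      if (nrow(img$coords))
        hit <- any_clash(cm, cf$placed, cf$elements, img$coords,
                         cf$elements[img$source])
    }
    env_ok_cache[[i]][s] <<- hit
    hit
  }

  s1 <- stage1_fit(Ex[eligible], function(ii, s) env_clash(eligible[ii], s))
  sel <- integer(n_res)
  sel[eligible] <- s1$conf
  status[eligible] <- ifelse(s1$ok, "fitted", "unfittable")

  # stage 2 over residues with at least one environment-feasible conformation
  feas <- lapply(seq_len(n_res), function(i) {
    if (!(i %in% eligible)) return(integer(0))
    which(!vapply(seq_along(cands[[i]]), function(s) env_clash(i, s), logical(1)))
  })
  s2_res <- eligible[vapply(eligible, function(i) length(feas[[i]]) > 0, logical(1))]
  pair_clash <- function(ii, s, jj, t) {
    i <- s2_res[ii]; j <- s2_res[jj]
    a <- cands[[i]][[feas[[i]][s]]]; b <- cands[[j]][[feas[[j]][t]]]
    hit <- any_clash(cm, a$placed, a$elements, b$placed, b$elements)
    if (!hit && !is.null(model$cell)) {
      ctr <- colMeans(a$placed)
      rad <- sqrt(max(rowSums(sweep(a$placed, 2, ctr)^2))) +
        sqrt(max(rowSums(sweep(b$placed, 2, colMeans(b$placed))^2)))
      img <- symmetry_images(b$placed, model$cell, center = ctr,
                             radius = rad + cm$max_cutoff)
      if (nrow(img$coords))
        hit <- any_clash(cm, a$placed, a$elements, img$coords, b$elements[img$source])
    }
    hit
  }
  s2 <- NULL
  if (length(s2_res)) {
    s2 <- stage2_resolve(lapply(s2_res, function(i) Ex[[i]][feas[[i]]]), pair_clash)
    for (ii in seq_along(s2_res)) sel[s2_res[ii]] <- feas[[s2_res[ii]]][s2$conf[ii]]
    if (length(s2$unfittable)) {
      unfit <- s2_res[s2$unfittable]
      status[unfit] <- "unfittable"
    }
  }

  # ---- stage 3: expansion, flips, polar H, full energies, DEE + A* ----
  fit_res <- intersect(eligible, which(status != "unfittable"))
  cand3 <- vector("list", n_res)
  for (i in fit_res) {
    res <- model$residues[[i]]
    base <- cands[[i]][[sel[i]]]
    set <- list(base)
    if (config$expand && !is.na(base$id)) {
      exp <- tryCatch(expand_cluster(library, base, config$expand_low,
                                     config$expand_high, config$search_level),
                      error = function(e) list())
      ids <- vapply(set, function(cf) cf$id, character(1))
      for (cf in exp) if (!(cf$id %in% ids)) { set <- c(set, list(cf)); ids <- c(ids, cf$id) }
    }
    # flips and polar-H variants are generated in the canonical frame
    # (CA at the origin), then every candidate is placed onto the backbone
    variants <- function(conf_set) {
      out <- list()
      for (cf in conf_set) {
        for (f2 in generate_flips(cf)) {
          vs <- if (config$h_variants) generate_h_variants(f2) else list(f2)
          out <- c(out, vs)
        }
      }
      out
    }
    withH <- variants(set)
    if (length(withH) > config$max_candidates) {
      warning("residue ", residue_id(res), ": candidate set exceeds cap; ",
              "using unexpanded conformations")
      withH <- variants(list(base))
    }
    inv <- invert_transform(local_frame(res))
    withH <- lapply(withH, function(cf) {
      cf$coords <- apply_transform(inv, cf$coords)
      cf$elements <- element_of(rownames(cf$coords))
      cf
    })
    cand3[[i]] <- withH
  }

  tbl_E <- list(); tbl_pair <- list()
  idx_map <- fit_res
  for (a in seq_along(idx_map)) {
    i <- idx_map[a]
    cs <- cand3[[i]]
    Dv <- vapply(cs, function(cf) density_score(map, .heavy(cf$coords), ep$density),
                 numeric(1))
    Pv <- vapply(cs, function(cf) cf$frequency, numeric(1))
    Eb <- vapply(cs, function(cf) e_backbone(cf$res_type, cf$coords, model, i, ep, env),
                 numeric(1))
    own_img <- vapply(cs, function(cf) {
      if (is.null(model$cell) || !ep$include_symmetry) return(0)
      ctr <- colMeans(cf$coords)
      rad <- sqrt(max(rowSums(sweep(cf$coords, 2, ctr)^2)))
      img <- symmetry_images(cf$coords, model$cell, center = ctr,
                             radius = 2 * rad + ep$cutoff)
      if (!nrow(img$coords)) return(0)
      pa <- atom_nb_params(cf$res_type, rownames(cf$coords))
      nonbonded_energy(pa, cf$coords, pa[img$source, ], img$coords, ep) / 2
    }, numeric(1))
    tbl_E[[a]] <- vapply(seq_along(cs), function(s)
      e_self(Dv[s], max(Dv), Pv[s], max(Pv), Eb[s] + own_img[s], ep), numeric(1))
  }
  # pairwise tables for residues within interaction range
  if (length(idx_map) > 1) {
    sph <- lapply(idx_map, function(i) {
      allc <- do.call(rbind, lapply(cand3[[i]], function(cf) cf$coords))
      ctr <- colMeans(allc)
      list(ctr = ctr, rad = sqrt(max(rowSums(sweep(allc, 2, ctr)^2))))
    })
    for (a in seq_len(length(idx_map) - 1)) {
      for (b in (a + 1):length(idx_map)) {
        if (vnorm(sph[[a]]$ctr - sph[[b]]$ctr) >
            sph[[a]]$rad + sph[[b]]$rad + ep$cutoff) next
        i <- idx_map[a]; j <- idx_map[b]
        m <- matrix(0, length(cand3[[i]]), length(cand3[[j]]))
        for (s in seq_along(cand3[[i]])) for (t in seq_along(cand3[[j]])) {
          m[s, t] <- e_pair(cand3[[i]][[s]]$res_type, cand3[[i]][[s]]$coords,
                            cand3[[j]][[t]]$res_type, cand3[[j]][[t]]$coords, ep)
        }
        if (any(abs(m) > 1e-9)) tbl_pair[[pair_key(a, b)]] <- m
      }
    }
  }
  s3 <- NULL
  if (length(idx_map)) {
    s3 <- stage3_refine(energy_tables(tbl_E, tbl_pair),
                        astar_threshold = config$astar_threshold)
  }

  # ---- write back ----
  final_conf <- vector("list", n_res)
  for (a in seq_along(idx_map)) {
    i <- idx_map[a]
    cf <- cand3[[i]][[s3$assignment[a]]]
    final_conf[[i]] <- cf
    model$residues[[i]] <- set_residue_sidechain_global(
      model$residues[[i]], .heavy(cf$coords))
    if (identical(cf$flip_state, "flipped") && status[i] == "fitted")
      status[i] <- "flipped"
    if (!had_sidechain[i] && status[i] %in% c("fitted", "flipped"))
      status[i] <- "rebuilt"
  }
  for (i in setdiff(eligible, idx_map)) {
    # unfittable: keep the best-effort conformation from stages I-II
    cf <- cands[[i]][[sel[i]]]
    final_conf[[i]] <- cf
    model$residues[[i]] <- set_residue_sidechain_global(
      model$residues[[i]], .heavy(cf$placed))
  }
  # final collision audit
  placed <- lapply(seq_len(n_res), function(i) {
    cf <- final_conf[[i]]
    if (is.null(cf)) return(list(res_idx = i, coords = matrix(numeric(0), 0, 3),
                                 elements = character(0)))
    co <- .heavy(if (!is.null(cf$placed)) cf$placed else cf$coords)
    list(res_idx = i, coords = co, elements = element_of(rownames(co)))
  })
  audit <- detect_collisions(placed, cm, model$cell)
  if (nrow(audit)) {
    for (i in unique(c(audit$i, audit$j))) {
      if (status[i] %in% c("fitted", "flipped", "rebuilt")) status[i] <- "unfittable"
    }
  }
  status_df <- data.frame(
    id = vapply(model$residues, residue_id, character(1)),
    res_type = vapply(model$residues, function(r) r$res_type, character(1)),
    status = status, reason = reason, stringsAsFactors = FALSE)
  structure(list(
    model = model,
    status = status_df,
    energy = if (!is.null(s3)) s3$energy else NA_real_,
    diagnostics = list(
      stage1 = list(checks = s1$checks, ok = s1$ok),
      stage2 = if (!is.null(s2)) list(n_expanded = s2$n_expanded,
                                      cost = s2$cost, optimal = s2$optimal),
      stage3 = if (!is.null(s3)) list(dee_log = s3$dee_log, clusters = s3$clusters),
      collisions = audit,
      config = config)),
    class = "solution")
}

#' @export
print.solution <- function(x, ...) {
  tb <- table(x$status$status)
  cat("side-chain fitting solution:",
      paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
      sprintf("| energy %.3f\n", x$energy))
  invisible(x)
}

#' Evaluate a fitted model against a reference
#'
#' Computes both accuracy criteria and, when a map is given, the
#' density-adjusted accuracy: the percentage of residues with
#' significant density whose conformation either matches the reference
#' (all chi within 20 degrees) or occupies more significant density than
#' the reference.
#'
#' @param reference,fitted `protein_model`s
#' @param map optional `density_map`
#' @param z_threshold significance threshold for the adjusted accuracy
#' @return list with `per_residue` (data frame) and `summary`
#' @export
evaluate_models <- function(reference, fitted, map = NULL, z_threshold = 1) {
  ids_ref <- vapply(reference$residues, residue_id, character(1))
  ids_fit <- vapply(fitted$residues, residue_id, character(1))
  if (!all(ids_ref %in% ids_fit)) {
    stop("residue mismatch between models: ",
         paste(utils::head(setdiff(ids_ref, ids_fit), 5), collapse = ", "))
  }
  acc_r <- accuracy(reference, fitted, "rmsd_0.5")
  acc_c <- accuracy(reference, fitted, "chi_20")
  rows <- list()
  for (i in seq_along(reference$residues)) {
    ra <- reference$residues[[i]]
    rb <- fitted$residues[[match(ids_ref[i], ids_fit)]]
    elig <- !is.na(acc_c$matched[i])
    dev <- if (elig) max_chi_dev(ra, rb) else NA_real_
    rmsd <- if (elig) residue_pair_rmsd(ra, rb) else NA_real_
    zo <- if (!is.null(map) && has_complete_sidechain(ra))
      density_significance(map, ra) else NA_real_
    zf <- if (!is.null(map) && has_complete_sidechain(rb))
      density_significance(map, rb) else NA_real_
    cat_ <- if (!elig) "ineligible"
    else if (isTRUE(acc_c$matched[i])) "match"
    else if (!is.na(zf) && !is.na(zo) && zf > zo) "improved_fit"
    else "changed"
    rows[[length(rows) + 1L]] <- data.frame(
      id = ids_ref[i], res_type = ra$res_type, rmsd = rmsd, max_chi_dev = dev,
      z_reference = zo, z_fitted = zf, category = cat_, stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  summ <- list(accuracy_rmsd_0.5 = acc_r$percent,
               accuracy_chi_20 = acc_c$percent,
               n_eligible = acc_c$n_eligible,
               categories = as.list(table(per$category)))
  if (!is.null(map)) {
    sig <- !is.na(per$z_reference) & per$category != "ineligible" &
      (pmax(per$z_reference, per$z_fitted, na.rm = TRUE) > z_threshold)
    good <- per$category %in% c("match", "improved_fit")
    summ$ed_adjusted_accuracy <- if (any(sig)) 100 * sum(good & sig) / sum(sig)
                                 else NA_real_
    summ$fraction_improved <- if (acc_c$n_eligible)
      100 * sum(per$category == "improved_fit") / acc_c$n_eligible else NA_real_
  }
  list(per_residue = per, summary = summ)
}

#' Write an evaluation report (TSV table + JSON summary)
#' @param report result of [evaluate_models()]
#' @param tsv_path,json_path output paths
#' @return invisibly, the report
#' @export
write_eval_report <- function(report, tsv_path, json_path) {
  utils::write.table(report$per_residue, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(report$summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
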