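#' @title Rigid pharmacophore matching
#' @description The matcher enumerates kind-compatible injective assignments
#'   of ligand annotation points to model features (essential features must
#'   all be matched, optional features may be skipped), superposes the
#'   assigned points onto the feature centers by least squares, and accepts
#'   the pose when every matched point falls within its feature radius, the
#'   aromatic normal agrees within the angular tolerance, no ligand heavy
#'   atom lies strictly inside an excluded volume, and no ligand oxygen lies
#'   inside the exclO sphere. Directional features contribute a second
#'   superposition pair one Angstrom along their direction, which makes a
#'   two-feature (cation + aromatic) match rigidly determinate.
#' @name match
NULL

#' Fit RMSD between matched feature centers and annotation points
#'
#' @param points n x 3 matrix of annotation-point positions (ligand frame).
#' @param centers n x 3 matrix of matched feature centers (model frame).
#' @param transform optional rigid transform; when NULL it is computed by
#'   least squares, which requires at least 3 pairs.
#' @return the root mean squared center-to-point distance after transform.
#' @export
fit_rmsd <- function(points, centers, transform = NULL) {
  points <- rbind(points); centers <- rbind(centers)
  stopifnot(nrow(points) == nrow(centers))
  if (is.null(transform)) {
    if (nrow(points) < 3)
      stop("underdetermined superposition: need >= 3 matched pairs")
    transform <- kabsch(points, centers)
  }
  moved <- apply_transform(points, transform)
  sqrt(mean(rowSums((moved - centers)^2)))
}

# enumerate injective assignments of points to features;
# features: list; cand: list of integer vectors (candidate point indices
# per feature, NA allowed for optional); returns matrix (rows = features)
assign_enum <- function(features, cand) {
  nf <- length(features)
  out <- list()
  rec <- function(k, used, acc) {
    if (k > nf) { out[[length(out) + 1L]] <<- acc; return(invisible()) }
    for (p in cand[[k]]) {
      if (!is.na(p) && p %in% used) next
      rec(k + 1L, if (is.na(p)) used else c(used, p), c(acc, p))
    }
  }
  rec(1L, integer(0), integer(0))
  out
}

match_pose <- function(points, feats, sign_combo, model, heavy_xyz,
                       oxy_xyz, assignment) {
  # build superposition sets
  P <- NULL; C <- NULL
  dir_rows <- list()
  for (k in seq_along(feats)) {
    p <- assignment[k]
    if (is.na(p)) next
    f <- feats[[k]]
    pt <- points[[p]]
    P <- rbind(P, pt$pos); C <- rbind(C, f$center)
    if (!is.null(f$direction) && !is.null(pt$dir)) {
      s <- sign_combo[[as.character(k)]]
      if (is.null(s)) s <- 1
      P <- rbind(P, pt$pos + s * pt$dir)
      C <- rbind(C, f$center + f$direction)
      dir_rows[[length(dir_rows) + 1L]] <- list(k = k, s = s)
    }
  }
  if (is.null(P) || nrow(P) < 3) return(NULL)
  tf <- kabsch(P, C)
  moved <- apply_transform(P, tf)
  # radius and direction checks on real pairs
  row <- 1
  for (k in seq_along(feats)) {
    p <- assignment[k]
    if (is.na(p)) next
    f <- feats[[k]]
    if (sqrt(sum((moved[row, ] - f$center)^2)) > f$radius) return(NULL)
    row <- row + 1
    if (!is.null(f$direction) && !is.null(points[[p]]$dir)) {
      dirv <- moved[row, ] - moved[row - 1, ]
      ang <- vec_angle(dirv, f$direction)
      ang <- min(ang, 180 - ang)  # unsigned normal
      if (ang > f$direction_tol) return(NULL)
      row <- row + 1
    }
  }
  # steric checks
  hx <- apply_transform(heavy_xyz, tf)
  for (v in model$excluded_volumes) {
    d2 <- rowSums(sweep(hx, 2, v$center)^2)
    if (any(d2 < v$radius^2 - 1e-12)) return(NULL)
  }
  if (!is.null(model$exclO) && !is.null(oxy_xyz) && nrow(oxy_xyz)) {
    ox <- apply_transform(oxy_xyz, tf)
    d2 <- rowSums(sweep(ox, 2, model$exclO$center)^2)
    if (any(d2 < model$exclO$radius^2 - 1e-12)) return(NULL)
  }
  list(transform = tf,
       fit_rmsd = sqrt(mean(rowSums((moved - C)^2))),
       n_matched = sum(!is.na(assignment)))
}

#' Match a conformer against a pharmacophore model
#'
#' @param conformer a `conformer` (needs `xyz`; `topology` taken from the
#'   conformer or passed explicitly).
#' @param model a [pharm_model()].
#' @param topology optional [mol_topology()].
#' @param points optional pre-perceived annotation points.
#' @return the best valid hit (minimal fit RMSD; ties broken by more
#'   optional features matched, then assignment order) as a list of class
#'   `pharm_hit` with `ligand_id`, `transform`, `fit_rmsd`, `pairs`,
#'   `delta_e`, `n_matched`, or NULL when the conformer does not fit.
#' @export
match_conformer <- function(conformer, model, topology = NULL,
                            points = NULL) {
  if (is.null(topology)) topology <- conformer$topology
  if (is.null(points)) points <- perceive(conformer, topology)
  feats <- model$features
  kinds <- vapply(points, `[[`, character(1), "kind")
  heavy_xyz <- conformer$xyz[topology$heavy, , drop = FALSE]
  oxy <- which(topology$element == "O")
  oxy_xyz <- if (length(oxy)) conformer$xyz[oxy, , drop = FALSE] else NULL

  cand <- lapply(feats, function(f) {
    ix <- which(kinds %in% f$kinds)
    if (!f$essential) ix <- c(ix, NA_integer_)
    if (!length(ix)) integer(0) else ix
  })
  if (any(vapply(cand, length, integer(1)) == 0)) return(NULL)

  # distance-compatibility pruning between essential feature pairs
  fd <- as.matrix(stats::dist(do.call(rbind,
    lapply(feats, `[[`, "center"))))
  ppos <- do.call(rbind, lapply(points, `[[`, "pos"))
  pd <- as.matrix(stats::dist(ppos))
  assignments <- assign_enum(feats, cand)
  ok_assign <- Filter(function(a) {
    for (i in seq_along(a)) {
      if (is.na(a[i])) next
      for (j in seq_len(i - 1L)) {
        if (is.na(a[j])) next
        tol <- feats[[i]]$radius + feats[[j]]$radius
        if (abs(pd[a[i], a[j]] - fd[i, j]) > tol) return(FALSE)
      }
    }
    TRUE
  }, assignments)

  dir_feats <- which(vapply(feats, function(f) !is.null(f$direction),
                            logical(1)))
  best <- NULL
  for (a in ok_assign) {
    sign_sets <- list(stats::setNames(list(), character(0)))
    active_dirs <- dir_feats[!is.na(a[dir_feats])]
    if (length(active_dirs)) {
      combos <- expand.grid(rep(list(c(1, -1)), length(active_dirs)))
      sign_sets <- lapply(seq_len(nrow(combos)), function(r)
        stats::setNames(as.list(combos[r, ]), as.character(active_dirs)))
    }
    for (sc in sign_sets) {
      pose <- match_pose(points, feats, sc, model, heavy_xyz, oxy_xyz, a)
      if (is.null(pose)) next
      better <- is.null(best) ||
        pose$fit_rmsd < best$fit_rmsd - 1e-12 ||
        (abs(pose$fit_rmsd - best$fit_rmsd) <= 1e-12 &&
           pose$n_matched > best$n_matched)
      if (better) {
        best <- pose
        best$assignment <- a
      }
    }
  }
  if (is.null(best)) return(NULL)
  pairs <- data.frame(
    feature = vapply(feats, `[[`, character(1), "name"),
    point = best$assignment,
    stringsAsFactors = FALSE
  )
  structure(list(
    ligand_id = conformer$ligand_id,
    transform = best$transform,
    fit_rmsd = best$fit_rmsd,
    pairs = pairs[!is.na(pairs$point), ],
    n_matched = best$n_matched,
    delta_e = conformer$delta_e,
    xyz = conformer$xyz
  ), class = "pharm_hit")
}

#' @export
print.pharm_hit <- function(x, ...) {
  cat("<pharm_hit> ", x$ligand_id, ": fit RMSD ",
      sprintf("%.3f", x$fit_rmsd), " A over ", x$n_matched,
      " features (dE ", sprintf("%.2f", x$delta_e), ")\n", sep = "")
  invisible(x)
}

#' Screen conformer ensembles against a pharmacophore model
#'
#' @param ensembles list of [generate_conformers()] ensembles. Ensembles
#'   sharing a `ligand_id` (amine invertomers) are pooled into one ligand
#'   row.
#' @param model a [pharm_model()].
#' @param anchor_set optional [anchor_set()]; when given, hydrogen-bond
#'   geometry of each best hit is evaluated against the named anchors.
#' @return a `screen_report`: list with `rows` (per-ligand data.frame: id,
#'   class, `n_conf`, `n_hit`, best-hit `delta_e` / `fit_rmsd`), `summary`
#'   per-class hit counts, `best_hits` (named list of `pharm_hit`), and
#'   `hbonds` (named list of H-bond record data.frames when `anchor_set`
#'   is given).
#' @export
screen <- function(ensembles, model, anchor_set = NULL) {
  stopifnot(length(ensembles) > 0)
  ids <- vapply(ensembles, `[[`, character(1), "ligand_id")
  rows <- list(); best_hits <- list(); hbonds <- list()
  for (id in unique(ids)) {
    group <- ensembles[ids == id]
    n_conf <- 0L; n_hit <- 0L
    best <- NULL; best_ens <- NULL
    for (ens in group) {
      for (ci in seq_along(ens$conformers)) {
        cf <- ens$conformers[[ci]]
        n_conf <- n_conf + 1L
        hit <- match_conformer(cf, model, topology = ens$topology)
        if (!is.null(hit)) {
          n_hit <- n_hit + 1L
          if (is.null(best) || hit$delta_e < best$delta_e - 1e-12 ||
              (abs(hit$delta_e - best$delta_e) <= 1e-12 &&
                 hit$fit_rmsd < best$fit_rmsd)) {
            best <- hit
            best$conf_index <- ci
            best_ens <- ens
          }
        }
      }
    }
    cls <- group[[1]]$activity_class
    rows[[id]] <- data.frame(
      id = id, activity_class = cls, n_conf = n_conf, n_hit = n_hit,
      delta_e = if (is.null(best)) NA_real_ else best$delta_e,
      fit_rmsd = if (is.null(best)) NA_real_ else best$fit_rmsd,
      stringsAsFactors = FALSE
    )
    if (!is.null(best)) {
      best_hits[[id]] <- best
      if (!is.null(anchor_set))
        hbonds[[id]] <- evaluate_hit(best, anchor_set,
                                     topology = best_ens$topology)
    }
  }
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  summary <- stats::aggregate(n_hit > 0 ~ activity_class, data = rows,
                              FUN = sum)
  names(summary) <- c("activity_class", "ligands_hit")
  summary$ligands_total <- as.vector(table(rows$activity_class)[
    summary$activity_class])
  structure(list(rows = rows, summary = summary, best_hits = best_hits,
                 hbonds = hbonds, model = model),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report> ", nrow(x$rows), " ligands\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s %d/%d hit\n", s$activity_class[i],
                s$ligands_hit[i], s$ligands_total[i]))
  invisible(x)
}
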