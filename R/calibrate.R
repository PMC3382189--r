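#' @title Calibration of the pharmacophore against the training set
#' @description The placement of the feature cluster relative to the
#'   excluded-volume shell, the per-feature match radii and the
#'   excluded-volume radii are tuned automatically by a seeded
#'   derivative-free search (random restarts + coordinate descent) that
#'   maximizes training-set discrimination: reward hit full and partial
#'   agonists, penalize hit inactives. This replaces interactive manual
#'   alignment tuning with a reproducible procedure.
#' @name calibrate
NULL

#' Discrimination objective of a screen report
#'
#' `score = w_full * (#full hit) + w_partial * (#partial hit) -
#'  w_inactive * (#inactive hit)`.
#'
#' @param report a `screen_report` (or its `rows` data.frame) covering the
#'   training set.
#' @param weights named numeric vector with `full`, `partial`, `inactive`.
#' @return the scalar score (higher is better).
#' @examples
#' rows <- data.frame(activity_class = c("full", "inactive"),
#'                    n_hit = c(3, 0))
#' objective(rows)
#' @export
objective <- function(report,
                      weights = c(full = 1, partial = 0.5, inactive = 1)) {
  rows <- if (inherits(report, "screen_report")) report$rows else report
  if (anyNA(rows$n_hit)) stop("incomplete report")
  hits <- function(cls) sum(rows$n_hit[rows$activity_class == cls] > 0)
  weights[["full"]] * hits("full") +
    weights[["partial"]] * hits("partial") -
    weights[["inactive"]] * hits("inactive")
}

#' Calibration configuration
#'
#' @param t_bound per-axis translation bound for the excluded-volume shell
#'   (Angstrom).
#' @param rot_bound per-axis rotation bound (degrees).
#' @param feature_r_bounds feature match-radius bounds (Angstrom).
#' @param ev_delta_bound excluded-volume radius perturbation bound.
#' @param exclO_r_bounds exclO radius bounds.
#' @param weights objective weights, see [objective()].
#' @param seed integer seed for the restart sampling.
#' @param budget maximum number of objective evaluations (>= 1); random
#'   restarts continue until it is exhausted.
#' @param n_restarts retained for configuration records; the first start
#'   is always the unperturbed model.
#' @export
calibration_config <- function(t_bound = 2, rot_bound = 20,
                               feature_r_bounds = c(0.5, 1.5),
                               ev_delta_bound = 0.4,
                               exclO_r_bounds = c(1.0, 2.0),
                               weights = c(full = 1, partial = 0.5,
                                           inactive = 1),
                               seed = 2012, budget = 2000,
                               n_restarts = 8) {
  stopifnot(budget >= 1, feature_r_bounds[1] < feature_r_bounds[2],
            exclO_r_bounds[1] < exclO_r_bounds[2])
  list(t_bound = t_bound, rot_bound = rot_bound,
       feature_r_bounds = feature_r_bounds,
       ev_delta_bound = ev_delta_bound, exclO_r_bounds = exclO_r_bounds,
       weights = weights, seed = seed, budget = budget,
       n_restarts = n_restarts)
}

#' Pre-compute candidate poses for fast model evaluation
#'
#' Enumerates, once, every feature-compatible pose of every conformer with
#' all feature radii inflated to `r_max` (a superset of the poses valid at
#' any radius within the calibration bounds), storing per-pose feature
#' distances, the transformed heavy-atom and oxygen coordinates, the
#' aromatic angle and the conformer strain. Model variants are then
#' evaluated by filtering this table, which is exactly equivalent to
#' re-screening.
#'
#' @param ensembles list of conformer ensembles.
#' @param model the template [pharm_model()] (feature geometry is fixed
#'   during calibration).
#' @param r_max largest feature radius that may arise during calibration.
#' @return an opaque list used by [calibrate()] (one entry per ligand).
#' @export
precompute_candidates <- function(ensembles, model, r_max = 1.5) {
  feats <- model$features
  infl <- model
  infl$features <- lapply(feats, function(f) { f$radius <- r_max; f })
  infl$excluded_volumes <- list()
  infl$exclO <- NULL
  ids <- vapply(ensembles, `[[`, character(1), "ligand_id")
  out <- list()
  for (id in unique(ids)) {
    group <- ensembles[ids == id]
    cands <- list()
    for (ens in group) {
      topo <- ens$topology
      heavy <- which(topo$heavy)
      oxy <- which(topo$element == "O")
      for (cf in ens$conformers) {
        poses <- match_all_poses(cf, infl, topo)
        for (p in poses) {
          hx <- apply_transform(cf$xyz[heavy, , drop = FALSE],
                                p$transform)
          ox <- if (length(oxy))
            apply_transform(cf$xyz[oxy, , drop = FALSE], p$transform)
          else NULL
          cands[[length(cands) + 1L]] <- list(
            feat_dist = p$feat_dist, delta_e = cf$delta_e,
            fit_rmsd = p$fit_rmsd, n_matched = p$n_matched,
            heavy = hx, oxy = ox)
        }
      }
    }
    if (length(cands)) {
      ord <- order(vapply(cands, `[[`, numeric(1), "delta_e"),
                   vapply(cands, `[[`, numeric(1), "fit_rmsd"))
      cands <- cands[ord]
    }
    out[[id]] <- list(id = id,
                      activity_class = group[[1]]$activity_class,
                      n_conf = sum(vapply(group, function(e)
                        length(e$conformers), integer(1))),
                      cands = cands)
  }
  out
}

# all valid poses of a conformer (used by candidate pre-computation and
# anchor-set derivation); steric constraints of `model` are applied
match_all_poses <- function(conformer, model, topology = NULL) {
  if (is.null(topology)) topology <- conformer$topology
  points <- perceive(conformer, topology)
  feats <- model$features
  kinds <- vapply(points, `[[`, character(1), "kind")
  heavy_xyz <- conformer$xyz[topology$heavy, , drop = FALSE]
  oxy <- which(topology$element == "O")
  oxy_xyz <- if (length(oxy)) conformer$xyz[oxy, , drop = FALSE] else NULL
  cand <- lapply(feats, function(f) {
    ix <- which(kinds %in% f$kinds)
    if (!f$essential) ix <- c(ix, NA_integer_)
    ix
  })
  if (any(vapply(cand, length, integer(1)) == 0)) return(list())
  fd <- as.matrix(stats::dist(do.call(rbind,
    lapply(feats, `[[`, "center"))))
  ppos <- do.call(rbind, lapply(points, `[[`, "pos"))
  pd <- as.matrix(stats::dist(ppos))
  assignments <- Filter(function(a) {
    for (i in seq_along(a)) {
      if (is.na(a[i])) next
      for (j in seq_len(i - 1L)) {
        if (is.na(a[j])) next
        tol <- feats[[i]]$radius + feats[[j]]$radius
        if (abs(pd[a[i], a[j]] - fd[i, j]) > tol) return(FALSE)
      }
    }
    TRUE
  }, assign_enum(feats, cand))
  dir_feats <- which(vapply(feats, function(f) !is.null(f$direction),
                            logical(1)))
  poses <- list()
  for (a in assignments) {
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
      # per-feature center distances after the pose transform
      fdist <- rep(NA_real_, length(feats))
      for (k in seq_along(feats)) {
        if (is.na(a[k])) next
        moved <- apply_transform(points[[a[k]]]$pos, pose$transform)
        fdist[k] <- sqrt(sum((moved - feats[[k]]$center)^2))
      }
      pose$feat_dist <- fdist
      pose$assignment <- a
      poses[[length(poses) + 1L]] <- pose
    }
  }
  poses
}

# does one ligand hit under a parameter vector?
ligand_hit_theta <- function(lg, feats, ev_centers, ev_r, exclO_center,
                             theta) {
  nf <- length(feats)
  f_r <- theta$feature_r
  for (cd in lg$cands) {
    ok <- TRUE
    for (k in seq_len(nf)) {
      d <- cd$feat_dist[k]
      if (is.na(d)) {
        if (feats[[k]]$essential) { ok <- FALSE; break }
      } else if (d > f_r[k]) { ok <- FALSE; break }
    }
    if (!ok) next
    if (!is.null(ev_centers) && nrow(ev_centers)) {
      d2 <- cross_dist2(cd$heavy, ev_centers)
      if (any(t(t(d2) < ev_r^2 - 1e-12))) next
    }
    if (!is.null(exclO_center) && !is.null(cd$oxy)) {
      d2o <- rowSums(sweep(cd$oxy, 2, exclO_center)^2)
      if (any(d2o < theta$exclO_r^2 - 1e-12)) next
    }
    return(TRUE)
  }
  FALSE
}

# evaluate candidate table under a parameter vector
eval_theta <- function(cands, feats, ev0, exclO_center, theta, weights) {
  tf <- euler_transform(theta$rot[1], theta$rot[2], theta$rot[3],
                        theta$tr[1], theta$tr[2], theta$tr[3])
  ev_centers <- if (length(ev0$centers)) apply_transform(ev0$centers, tf)
    else NULL
  ev_r <- ev0$radius + theta$ev_delta[ev0$tag_idx]
  rows <- do.call(rbind, lapply(cands, function(lg) {
    data.frame(activity_class = lg$activity_class,
               n_hit = as.integer(ligand_hit_theta(
                 lg, feats, ev_centers, ev_r, exclO_center, theta)))
  }))
  objective(rows, weights)
}

theta_to_model <- function(model, theta) {
  tf <- euler_transform(theta$rot[1], theta$rot[2], theta$rot[3],
                        theta$tr[1], theta$tr[2], theta$tr[3])
  for (k in seq_along(model$features))
    model$features[[k]]$radius <- theta$feature_r[k]
  tags <- c("aliphatic_H", "aromatic_H", "polar_H", "ring_centroid")
  model$excluded_volumes <- lapply(model$excluded_volumes, function(v) {
    v$center <- as.vector(apply_transform(v$center, tf))
    v$radius <- v$radius + theta$ev_delta[match(v$origin_tag, tags)]
    v
  })
  if (!is.null(model$exclO)) model$exclO$radius <- theta$exclO_r
  model$frame_tag <- paste0(model$frame_tag, "+calibrated")
  model
}

theta_perturbation_norm <- function(theta, theta0) {
  sum(abs(theta$feature_r - theta0$feature_r)) +
    sum(abs(theta$ev_delta - theta0$ev_delta)) +
    abs(theta$exclO_r - theta0$exclO_r)
}

theta_transform_norm <- function(theta) {
  sqrt(sum(theta$tr^2)) + sqrt(sum(theta$rot^2)) / 10
}

#' Calibrate a pharmacophore model on the training library
#'
#' Seeded random-restart + coordinate-descent search over the rigid
#' placement of the excluded-volume shell relative to the feature cluster
#' (6 degrees of freedom), the per-feature match radii, the per-tag
#' excluded-volume radius perturbations and the exclO radius. The
#' incumbent objective is monotone non-decreasing; ties prefer the smaller
#' radius perturbation, then the smaller transform. Fully reproducible for
#' a fixed seed.
#'
#' @param model0 starting [pharm_model()].
#' @param ensembles conformer ensembles of the training library (generated
#'   with a fixed seed so the objective landscape is deterministic).
#' @param anchor_set optional [anchor_set()]; if given and `model0` has no
#'   excluded volumes, the shell is built from it with [ev_radii()].
#' @param config a [calibration_config()].
#' @param candidates optional result of [precompute_candidates()] (reused
#'   across calls).
#' @return `calibration_result`: list with `model`, `objective`,
#'   `objective0`, `trace` (data.frame: `eval`, `objective`, `incumbent`),
#'   `confusion` (per-class ligands hit at the optimum), `improved` and
#'   `warning` flags.
#' @export
calibrate <- function(model0, ensembles, anchor_set = NULL,
                      config = calibration_config(),
                      candidates = NULL) {
  if (!length(model0$excluded_volumes) && !is.null(anchor_set))
    model0$excluded_volumes <- build_excluded_volumes(anchor_set)
  feats <- model0$features
  nf <- length(feats)
  if (is.null(candidates))
    candidates <- precompute_candidates(ensembles, model0,
      r_max = config$feature_r_bounds[2])
  ev0 <- list(
    centers = if (length(model0$excluded_volumes))
      do.call(rbind, lapply(model0$excluded_volumes, `[[`, "center"))
    else matrix(numeric(0), 0, 3),
    radius = vapply(model0$excluded_volumes, `[[`, numeric(1), "radius"),
    tag_idx = match(vapply(model0$excluded_volumes, `[[`, character(1),
                           "origin_tag"),
                    c("aliphatic_H", "aromatic_H", "polar_H",
                      "ring_centroid"))
  )
  exclO_center <- if (is.null(model0$exclO)) NULL else model0$exclO$center
  exclO_r0 <- if (is.null(model0$exclO)) 1.5 else model0$exclO$radius

  theta0 <- list(tr = c(0, 0, 0), rot = c(0, 0, 0),
                 feature_r = vapply(feats, `[[`, numeric(1), "radius"),
                 ev_delta = c(0, 0, 0, 0), exclO_r = exclO_r0)
  clamp_theta <- function(th) {
    th$tr <- pmin(pmax(th$tr, -config$t_bound), config$t_bound)
    th$rot <- pmin(pmax(th$rot, -config$rot_bound), config$rot_bound)
    th$feature_r <- pmin(pmax(th$feature_r, config$feature_r_bounds[1]),
                         config$feature_r_bounds[2])
    th$ev_delta <- pmin(pmax(th$ev_delta, -config$ev_delta_bound),
                        config$ev_delta_bound)
    th$exclO_r <- min(max(th$exclO_r, config$exclO_r_bounds[1]),
                      config$exclO_r_bounds[2])
    th
  }
  n_eval <- 0L
  trace <- list()
  score_of <- function(th) {
    n_eval <<- n_eval + 1L
    eval_theta(candidates, feats, ev0, exclO_center, th, config$weights)
  }

  best_th <- theta0
  best_score <- score_of(theta0)
  score0 <- best_score
  trace[[1]] <- data.frame(eval = 1L, objective = best_score,
                           incumbent = best_score)
  better_than_best <- function(score, th) {
    if (score > best_score + 1e-12) return(TRUE)
    if (score < best_score - 1e-12) return(FALSE)
    p1 <- theta_perturbation_norm(th, theta0)
    p0 <- theta_perturbation_norm(best_th, theta0)
    if (p1 < p0 - 1e-12) return(TRUE)
    if (p1 > p0 + 1e-12) return(FALSE)
    theta_transform_norm(th) < theta_transform_norm(best_th) - 1e-12
  }
  record <- function(score) {
    trace[[length(trace) + 1L]] <<-
      data.frame(eval = n_eval, objective = score,
                 incumbent = best_score)
  }

  set.seed(config$seed %% .Machine$integer.max)
  rand_theta <- function() {
    clamp_theta(list(
      tr = stats::runif(3, -config$t_bound, config$t_bound),
      rot = stats::runif(3, -config$rot_bound, config$rot_bound),
      feature_r = stats::runif(nf, config$feature_r_bounds[1],
                               config$feature_r_bounds[2]),
      ev_delta = stats::runif(4, -config$ev_delta_bound,
                              config$ev_delta_bound),
      exclO_r = stats::runif(1, config$exclO_r_bounds[1],
                             config$exclO_r_bounds[2])))
  }
  dims <- function(th) {
    list(
      list(get = function(t) t$tr[1], set = function(t, v) { t$tr[1] <- v; t }, step = 0.5),
      list(get = function(t) t$tr[2], set = function(t, v) { t$tr[2] <- v; t }, step = 0.5),
      list(get = function(t) t$tr[3], set = function(t, v) { t$tr[3] <- v; t }, step = 0.5),
      list(get = function(t) t$rot[1], set = function(t, v) { t$rot[1] <- v; t }, step = 5),
      list(get = function(t) t$rot[2], set = function(t, v) { t$rot[2] <- v; t }, step = 5),
      list(get = function(t) t$rot[3], set = function(t, v) { t$rot[3] <- v; t }, step = 5),
      lapply(seq_len(nf), function(k)
        list(get = function(t) t$feature_r[k],
             set = function(t, v) { t$feature_r[k] <- v; t }, step = 0.2)),
      lapply(1:4, function(k)
        list(get = function(t) t$ev_delta[k],
             set = function(t, v) { t$ev_delta[k] <- v; t }, step = 0.1)),
      list(list(get = function(t) t$exclO_r,
                set = function(t, v) { t$exclO_r <- v; t }, step = 0.2))
    )
  }
  flatten_dims <- function(d) {
    out <- list()
    for (e in d) {
      if (!is.null(e$get)) out[[length(out) + 1L]] <- e
      else for (e2 in e) out[[length(out) + 1L]] <- e2
    }
    out
  }
  dimlist <- flatten_dims(dims(theta0))

  descend <- function(start_th) {
    cur <- clamp_theta(start_th)
    cur_score <- score_of(cur)
    if (better_than_best(cur_score, cur)) {
      best_th <<- cur; best_score <<- cur_score
    }
    record(cur_score)
    step_scale <- 1
    repeat {
      improved_round <- FALSE
      for (dm in dimlist) {
        if (n_eval >= config$budget) return(invisible())
        for (sgn in c(1, -1)) {
          trial <- clamp_theta(dm$set(cur, dm$get(cur) +
                                        sgn * dm$step * step_scale))
          s <- score_of(trial)
          accept <- s > cur_score + 1e-12
          if (accept) {
            cur <- trial; cur_score <- s; improved_round <- TRUE
          }
          if (better_than_best(s, trial)) {
            best_th <<- trial; best_score <<- s
          }
          record(s)
          if (n_eval >= config$budget) return(invisible())
          if (accept) break
        }
      }
      if (!improved_round) {
        step_scale <- step_scale / 2
        if (step_scale < 0.24) break
      }
    }
    invisible()
  }

  # the unperturbed model is always the first start; the remaining
  # budget is spent on random restarts (hit-count objectives are stepped,
  # so restarts, not local steps, cross plateaus)
  restart <- 0L
  while (n_eval < config$budget) {
    start <- if (restart == 0L) theta0 else rand_theta()
    descend(start)
    restart <- restart + 1L
  }

  trace <- do.call(rbind, trace)
  trace$incumbent <- cummax(trace$incumbent)
  best_model <- theta_to_model(model0, best_th)
  # confusion at the optimum
  tf_best <- euler_transform(best_th$rot[1], best_th$rot[2],
                             best_th$rot[3], best_th$tr[1],
                             best_th$tr[2], best_th$tr[3])
  ev_centers_best <- if (length(ev0$centers))
    apply_transform(ev0$centers, tf_best) else NULL
  ev_r_best <- ev0$radius + best_th$ev_delta[ev0$tag_idx]
  conf <- do.call(rbind, lapply(candidates, function(lg)
    data.frame(id = lg$id, activity_class = lg$activity_class,
               hit = ligand_hit_theta(lg, feats, ev_centers_best,
                                      ev_r_best, exclO_center, best_th),
               stringsAsFactors = FALSE)))
  confusion <- stats::aggregate(hit ~ activity_class, data = conf,
                                FUN = sum)
  structure(list(model = best_model, theta = best_th,
                 objective = best_score, objective0 = score0,
                 trace = trace, confusion = confusion,
                 per_ligand = conf,
                 improved = best_score > score0 + 1e-12,
                 warning = best_score <= score0 + 1e-12),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> objective ", x$objective0, " -> ",
      x$objective, " over ", nrow(x$trace), " evaluations\n", sep = "")
  print(x$confusion)
  invisible(x)
}
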