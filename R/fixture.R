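#' @title Construction of the shipped model and anchor-set fixtures
#' @description No receptor coordinates exist for this system, so the
#'   shipped anchor set is constructed in the pharmacophore frame from the
#'   training ligands themselves: the feature cluster is read off a
#'   reference full-agonist pose, pocket hydrogen sites are placed on a
#'   shell around that pose (receptor atoms sit within contact distance of
#'   a bound agonist), sites that would clash with any active's best pose
#'   are discarded, and the remainder are ranked greedily by how many
#'   inactive poses they block -- an automated, reproducible analogue of
#'   shaping excluded volumes to the binding pocket and tuning them for
#'   training-set discrimination. All quantities computed against this
#'   fixture are model-consistent constructions, not measurements.
#' @name fixture
NULL

golden_dirs <- function(k = 14) {
  i <- seq_len(k) - 0.5
  phi <- acos(1 - 2 * i / k)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Derive the feature cluster from a reference agonist conformer
#'
#' Places the Asp-TM3 cation feature on the protonated nitrogen, the Aro
#' feature on the catechol(-like) aromatic ring centroid with its normal,
#' and the optional Ser-TM5 hydrogen-bond feature on the in-plane
#' projected point of the para-like hydroxyl that points away from the
#' amine (the deep TM5 side). Everything is then expressed in a canonical
#' frame: ring centroid at the origin, cation on the +x axis in the z = 0
#' plane, ring normal along +z.
#'
#' @param conformer reference conformer (a `conformer` with `topology`).
#' @param topology optional [mol_topology()].
#' @param radius default feature match radius.
#' @param direction_tol aromatic angular tolerance (degrees).
#' @return list with `model` (a [pharm_model()] without steric elements)
#'   and `frame` (the rigid transform from conformer to model frame).
#' @export
derive_feature_model <- function(conformer, topology = NULL, radius = 1.0,
                                 direction_tol = 30) {
  if (is.null(topology)) topology <- conformer$topology
  pts <- perceive(conformer, topology)
  kinds <- vapply(pts, `[[`, character(1), "kind")
  cat_pt <- pts[[which(kinds == "cation")[1]]]
  aro_idx <- which(kinds == "aromatic")
  # prefer the hydroxyl-bearing (catechol-like) ring
  oh_carbons <- integer(0)
  for (i in which(topology$element == "O")) {
    nb <- topology$adj[[i]]
    if (any(!topology$heavy[nb]))
      oh_carbons <- c(oh_carbons, nb[topology$heavy[nb] &
                                       topology$aromatic[nb]])
  }
  pick <- aro_idx[1]
  for (ai in aro_idx)
    if (any(pts[[ai]]$atoms %in% oh_carbons)) { pick <- ai; break }
  aro_pt <- pts[[pick]]

  grp <- hbond_groups(topology)
  don <- grp$donors
  ser_pt <- NULL
  prefer <- c("p", "m", "O")
  for (lab in prefer) {
    dsub <- don[don$label == lab, , drop = FALSE]
    if (!nrow(dsub)) next
    o_atom <- dsub$d[1]
    proj <- Filter(function(p) p$kind == "donor_proj" &&
                     p$atoms[1] == o_atom, pts)
    if (!length(proj)) next
    dist_cat <- vapply(proj, function(p) vnorm(p$pos - cat_pt$pos),
                       numeric(1))
    ser_pt <- proj[[which.max(dist_cat)]]
    break
  }

  # canonical frame
  origin <- aro_pt$pos
  z <- unitize(aro_pt$dir)
  v <- cat_pt$pos - origin
  v_in <- v - sum(v * z) * z
  if (vnorm(v_in) < 1e-6) stop("degenerate reference geometry")
  x <- unitize(v_in)
  if (sum((cat_pt$pos - origin) * z) < 0) {  # keep cation at z >= 0 side
    z <- -z
    v_in <- v - sum(v * z) * z
    x <- unitize(v_in)
  }
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  rot <- rbind(x, y, z)  # world -> frame rows
  frame <- list(R = rot, t = as.vector(-rot %*% origin))
  to_frame <- function(p) as.vector(apply_transform(p, frame))

  feats <- list(
    pharm_feature("AspTM3", "cation", to_frame(cat_pt$pos), radius,
                  essential = TRUE),
    pharm_feature("Aro", "aromatic", c(0, 0, 0), radius,
                  essential = TRUE, direction = c(0, 0, 1),
                  direction_tol = direction_tol)
  )
  if (!is.null(ser_pt))
    feats[[3]] <- pharm_feature("SerTM5",
                                c("donor_proj", "acceptor_proj"),
                                to_frame(ser_pt$pos), radius,
                                essential = FALSE)
  list(model = pharm_model(feats, frame_tag = "reference-agonist-frame"),
       frame = frame)
}

collect_poses <- function(ensembles, model) {
  ids <- vapply(ensembles, `[[`, character(1), "ligand_id")
  out <- list()
  for (id in unique(ids)) {
    group <- ensembles[ids == id]
    poses <- list()
    for (ens in group) {
      heavy <- which(ens$topology$heavy)
      oxy <- which(ens$topology$element == "O")
      for (cf in ens$conformers) {
        for (p in match_all_poses(cf, model, ens$topology)) {
          poses[[length(poses) + 1L]] <- list(
            heavy = apply_transform(cf$xyz[heavy, , drop = FALSE],
                                    p$transform),
            oxy = if (length(oxy))
              apply_transform(cf$xyz[oxy, , drop = FALSE], p$transform)
            else NULL,
            heavy_aromatic = ens$topology$aromatic[heavy],
            heavy_element = ens$topology$element[heavy],
            delta_e = cf$delta_e, fit_rmsd = p$fit_rmsd)
        }
      }
    }
    if (length(poses)) {
      ord <- order(vapply(poses, `[[`, numeric(1), "delta_e"),
                   vapply(poses, `[[`, numeric(1), "fit_rmsd"))
      poses <- poses[ord]
    }
    out[[id]] <- list(id = id,
                      activity_class = group[[1]]$activity_class,
                      poses = poses)
  }
  out
}

#' Derive the synthetic receptor anchor set
#'
#' See the module description: shell sites around the reference agonist
#' pose, filtered to spare every active's best pose, greedily selected to
#' block inactive poses; named hydrogen-bond anchors placed at the
#' pharmacophore projection points; exclO centred on the ether oxygen of
#' the doxanthrine pose it must reject.
#'
#' @param feature_model features-only [pharm_model()] from
#'   [derive_feature_model()].
#' @param ensembles training-library conformer ensembles.
#' @param ref_id reference full agonist.
#' @param shell_dist site distance from ligand atoms (Angstrom).
#' @param max_sites cap on selected hydrogen sites.
#' @param margin clearance margin (Angstrom).
#' @return an [anchor_set()].
#' @export
derive_anchor_set <- function(feature_model, ensembles,
                              ref_id = "(R)-NPA",
                              shell_dist = c(2.6, 3.0, 3.4),
                              max_sites = 60, margin = 0.05) {
  radii <- ev_radii("final")
  poses <- collect_poses(ensembles, feature_model)
  if (!length(poses[[ref_id]]$poses))
    stop("reference ligand has no feature pose")
  ref <- poses[[ref_id]]$poses[[1]]

  active_ids <- names(poses)[vapply(poses, function(p)
    p$activity_class %in% c("full", "partial") && length(p$poses) > 0,
    logical(1))]
  inactive_ids <- names(poses)[vapply(poses, function(p)
    p$activity_class == "inactive" && length(p$poses) > 0, logical(1))]
  active_best <- lapply(poses[active_ids], function(p) p$poses[[1]]$heavy)

  # candidate shell sites around the best poses of the full agonists
  # (receptor atoms lie within contact distance of the bound agonist)
  shell_src <- poses[names(poses)[vapply(poses, function(p)
    p$activity_class == "full" && length(p$poses) > 0, logical(1))]]
  dirs <- golden_dirs(26)
  cand <- list()
  for (ps in shell_src) {
    hx <- ps$poses[[1]]$heavy
    for (i in seq_len(nrow(hx))) {
      for (d in seq_len(nrow(dirs))) {
        for (sd in shell_dist) {
          site <- hx[i, ] + dirs[d, ] * sd
          if (min(sqrt(rowSums(sweep(hx, 2, site)^2))) < sd - 0.4)
            next  # buried in the ligand
          tag <- if (ps$poses[[1]]$heavy_element[i] %in% c("O", "N"))
            "polar_H"
          else if (ps$poses[[1]]$heavy_aromatic[i]) "aromatic_H"
          else "aliphatic_H"
          cand[[length(cand) + 1L]] <- list(site = site, tag = tag,
                                            r = radii[[tag]])
        }
      }
    }
  }
  # de-duplicate on a coarse grid
  keyed <- vapply(cand, function(cd)
    paste(cd$tag, paste(round(cd$site / 0.7), collapse = ",")),
    character(1))
  cand <- cand[!duplicated(keyed)]
  # spare every active's best pose
  cand <- Filter(function(cd) {
    for (ab in active_best)
      if (min(rowSums(sweep(ab, 2, cd$site)^2)) <
          (cd$r + margin)^2) return(FALSE)
    TRUE
  }, cand)

  # greedy cover of inactive poses (ties: finish nearly-blocked ligands)
  inpose <- list(); inlig <- character(0)
  for (id in inactive_ids)
    for (p in poses[[id]]$poses) {
      inpose[[length(inpose) + 1L]] <- p$heavy
      inlig <- c(inlig, id)
    }
  blocked <- logical(length(inpose))
  blocks <- lapply(cand, function(cd) {
    which(vapply(inpose, function(hx)
      min(rowSums(sweep(hx, 2, cd$site)^2)) < (cd$r - margin)^2,
      logical(1)))
  })
  sel <- integer(0)
  repeat {
    remaining <- which(!blocked)
    if (!length(remaining) || length(sel) >= max_sites) break
    # weight poses of nearly-completed ligands higher
    lig_left <- table(inlig[remaining])
    w <- 1 / as.numeric(lig_left[inlig])
    gain <- vapply(seq_along(cand), function(i) {
      if (i %in% sel) return(-1)
      new <- setdiff(blocks[[i]], which(blocked))
      if (!length(new)) return(0)
      sum(w[new])
    }, numeric(1))
    if (max(gain) <= 0) break
    pick <- which.max(gain)
    sel <- c(sel, pick)
    blocked[blocks[[pick]]] <- TRUE
  }
  hs <- if (length(sel)) data.frame(
    x = vapply(cand[sel], function(cd) cd$site[1], numeric(1)),
    y = vapply(cand[sel], function(cd) cd$site[2], numeric(1)),
    z = vapply(cand[sel], function(cd) cd$site[3], numeric(1)),
    tag = vapply(cand[sel], `[[`, character(1), "tag"),
    stringsAsFactors = FALSE)
  else data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                  tag = character(0))

  # ring centroids above/below the aromatic feature plane (pi-stacking
  # partners), kept only when they spare the active poses
  rc <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0))
  for (zs in c(4.8, -4.8)) {
    site <- c(0, 0, zs)
    okc <- TRUE
    for (ab in active_best)
      if (min(rowSums(sweep(ab, 2, site)^2)) <
          (radii[["ring_centroid"]] + margin)^2) okc <- FALSE
    if (okc) rc <- rbind(rc, data.frame(x = site[1], y = site[2],
                                        z = site[3]))
  }

  # named hydrogen-bond anchors at the pharmacophore projection points
  feats <- feature_model$features
  fname <- vapply(feats, `[[`, character(1), "name")
  ser <- if ("SerTM5" %in% fname)
    feats[[which(fname == "SerTM5")]]$center else c(-5.5, 0, 0)
  asp <- feats[[which(fname == "AspTM3")]]$center
  # His393 near the meta-hydroxyl projection side, extracellular-ward
  his <- ser + c(0.8, 2.6, 1.4)
  anchors <- data.frame(
    name = c("Ser193:OG", "Ser193:O", "His393:NE2", "Asn186:OD1",
             "Asp114:OD"),
    element = c("O", "O", "N", "O", "O"),
    role = c("both", "acceptor", "both", "both", "acceptor"),
    x = c(ser[1], ser[1] + 1.2, his[1], his[1] + 1.5, asp[1] + 1.2),
    y = c(ser[2], ser[2] - 2.0, his[2], his[2] + 2.2, asp[2] + 1.0),
    z = c(ser[3], ser[3] + 1.5, his[3], his[3] + 2.0, asp[3] + 2.2),
    stringsAsFactors = FALSE
  )
  anchor_set(anchors, hs, rc, frame_tag = "synthetic-pocket-fixture")
}

#' Derive the exclO sphere from the doxanthrine ether oxygen
#'
#' @param feature_model features-only model.
#' @param ensembles training ensembles (must include doxanthrine).
#' @param radius default sphere radius; shrunk if an active's best-pose
#'   oxygen would fall inside.
#' @return list with `center` and `radius`, or NULL when doxanthrine has
#'   no feature pose.
#' @export
derive_exclO <- function(feature_model, ensembles, radius = 1.5) {
  poses <- collect_poses(ensembles, feature_model)
  dox <- poses[["doxanthrine"]]
  if (is.null(dox) || !length(dox$poses)) return(NULL)
  # ether oxygen: O with two heavy neighbours
  ens <- ensembles[[which(vapply(ensembles, `[[`, character(1),
                                 "ligand_id") == "doxanthrine")[1]]]
  topo <- ens$topology
  oxy <- which(topo$element == "O")
  ether_local <- which(vapply(oxy, function(i) {
    nb <- topo$adj[[i]]
    sum(topo$heavy[nb]) == 2 && !any(!topo$heavy[nb])
  }, logical(1)))
  if (!length(ether_local)) return(NULL)
  center <- dox$poses[[1]]$oxy[ether_local[1], ]
  # keep the sphere clear of the oxygens of active best poses
  r <- radius
  for (id in names(poses)) {
    p <- poses[[id]]
    if (!p$activity_class %in% c("full", "partial") || !length(p$poses))
      next
    ox <- p$poses[[1]]$oxy
    if (is.null(ox) || !nrow(ox)) next
    dmin <- sqrt(min(rowSums(sweep(ox, 2, center)^2)))
    if (dmin < r) r <- max(0.8, dmin - 0.05)
  }
  list(center = as.numeric(center), radius = r)
}
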