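#' @title Synthetic probe and decoy conformers
#' @description Probe conformers are minimal synthetic ligands constructed
#'   to present one annotation point per (essential) feature of a model,
#'   optionally displaced by a bounded jitter; decoys perturb a probe so
#'   that exactly one model constraint is violated. Both are test fixtures:
#'   they exercise the matcher with known ground truth.
#' @name probe
NULL

probe_topology_skeleton <- function(n_c, has_n, has_o) {
  # benzene ring (aromatic), optional isolated N+, optional O-H donor
  element <- c(rep("C", n_c))
  sybyl <- rep("C.ar", n_c)
  charge <- rep(0L, n_c)
  bonds <- data.frame(a1 = seq_len(n_c),
                      a2 = c(seq_len(n_c)[-1], 1L),
                      type = "ar", stringsAsFactors = FALSE)
  if (has_n) {
    element <- c(element, "N"); sybyl <- c(sybyl, "N.4")
    charge <- c(charge, 1L)
  }
  if (has_o) {
    ni <- length(element)
    element <- c(element, "O", "H"); sybyl <- c(sybyl, "O.3", "H")
    charge <- c(charge, 0L, 0L)
    bonds <- rbind(bonds, data.frame(a1 = ni + 1L, a2 = ni + 2L,
                                     type = "1"))
  }
  n <- length(element)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$a1[k]; j <- bonds$a2[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  structure(list(smiles = "<probe>", n_atoms = n, element = element,
                 sybyl = sybyl, aromatic = grepl("ar", sybyl),
                 charge = charge, heavy = element != "H",
                 bonds = bonds, adj = adj), class = "mol_topology")
}

perp_basis <- function(n) {
  n <- unitize(n)
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitize(ref - sum(ref * n) * n)
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(u = u, v = v)
}

#' Build a probe conformer for a pharmacophore model
#'
#' Constructs a synthetic conformer (benzene ring for the aromatic
#' feature, a protonated nitrogen for the cation feature, an aliphatic
#' hydroxyl for a projected hydrogen-bond feature) whose annotation points
#' coincide with the feature centers, each displaced by at most `jitter`
#' along a fixed per-feature axis. With `jitter = 0` the downstream fit
#' RMSD is exactly 0.
#'
#' @param model a [pharm_model()] whose essential features include one
#'   `cation` and one `aromatic` feature.
#' @param jitter displacement magnitude in Angstrom (deterministic axis
#'   cycle x, y, z across features).
#' @param include_optional also realize optional features.
#' @param jitter_only index of a single feature to displace (default all).
#' @return a `conformer` with an attached `topology` attribute-free list
#'   (`$topology`), `delta_e = 0`.
#' @export
make_probe_conformer <- function(model, jitter = 0,
                                 include_optional = TRUE,
                                 jitter_only = NULL) {
  stopifnot(jitter >= 0)
  feats <- model$features
  use <- vapply(feats, function(f) f$essential || include_optional,
                logical(1))
  feats <- feats[use]
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  kinds1 <- vapply(feats, function(f) f$kinds[1], character(1))
  n_aro <- sum(kinds1 == "aromatic")
  n_cat <- sum(kinds1 == "cation")
  if (n_aro != 1 || n_cat != 1)
    stop("probe construction expects exactly one aromatic and one cation ",
         "feature")
  has_o <- any(kinds1 %in% c("donor_proj", "acceptor_proj"))
  topo <- probe_topology_skeleton(6L, TRUE, has_o)
  xyz <- matrix(0, topo$n_atoms, 3)
  aro <- feats[[which(kinds1 == "aromatic")]]
  disp <- function(k) {
    if (!is.null(jitter_only) && k != jitter_only) return(c(0, 0, 0))
    axes[[(k - 1L) %% 3L + 1L]] * jitter
  }
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    ctr <- f$center + disp(k)
    if (kinds1[k] == "aromatic") {
      nrm <- if (is.null(f$direction)) c(0, 0, 1) else f$direction
      b <- perp_basis(nrm)
      r <- 1.39
      for (j in 0:5) {
        th <- j * pi / 3
        xyz[j + 1L, ] <- ctr + r * (cos(th) * b$u + sin(th) * b$v)
      }
    } else if (kinds1[k] == "cation") {
      xyz[7L, ] <- ctr
    } else {
      dirv <- unitize(aro$center - f$center)
      opos <- ctr + dirv * 2.8  # O sits 2.8 A toward the ring; the O-H
                                # projection then lands exactly on ctr
      oi <- which(topo$element == "O")[1]
      hi <- oi + 1L
      xyz[oi, ] <- opos
      xyz[hi, ] <- opos + unitize(ctr - opos) * 0.96
    }
  }
  structure(list(ligand_id = "probe", key = "probe", xyz = xyz,
                 delta_e = 0, seed_tag = "probe", topology = topo),
            class = "conformer")
}

#' Build a decoy conformer violating exactly one model constraint
#'
#' Starts from the exact (`jitter = 0`) probe and perturbs it:
#' `"radius"` displaces the cation point beyond its feature radius,
#' `"direction"` tilts the aromatic ring past the angular tolerance,
#' `"excluded_volume"` adds a heavy atom at the first excluded-volume
#' center, `"exclO"` adds an oxygen at the exclO center, and
#' `"missing_essential"` removes the cation atom.
#'
#' @param model a [pharm_model()].
#' @param violation which constraint to violate.
#' @return a `conformer`.
#' @export
make_decoy_conformer <- function(model,
                                 violation = c("radius", "direction",
                                               "excluded_volume", "exclO",
                                               "missing_essential")) {
  violation <- match.arg(violation)
  feats <- model$features
  kinds1 <- vapply(feats, function(f) f$kinds[1], character(1))
  probe <- make_probe_conformer(model, 0)
  topo <- probe$topology
  xyz <- probe$xyz
  if (violation == "radius") {
    k <- which(kinds1 == "cation")[1]
    ni <- which(topo$element == "N")[1]
    xyz[ni, ] <- feats[[k]]$center + c(feats[[k]]$radius + 1.0, 0, 0)
  } else if (violation == "direction") {
    k <- which(kinds1 == "aromatic")[1]
    f <- feats[[k]]
    ring <- which(topo$aromatic)
    # tilt about the in-plane axis perpendicular to the cation direction:
    # re-aligning the normal would then displace the cation point, so the
    # violation cannot be absorbed by a rigid re-superposition
    kc <- which(kinds1 == "cation")[1]
    vcat <- feats[[kc]]$center - f$center
    axis <- c(f$direction[2] * vcat[3] - f$direction[3] * vcat[2],
              f$direction[3] * vcat[1] - f$direction[1] * vcat[3],
              f$direction[1] * vcat[2] - f$direction[2] * vcat[1])
    if (sqrt(sum(axis^2)) < 1e-9) axis <- perp_basis(f$direction)$u
    tilt <- axis_rotation(axis, f$direction_tol + 25)
    ctr <- colMeans(xyz[ring, , drop = FALSE])
    xyz[ring, ] <- sweep(sweep(xyz[ring, , drop = FALSE], 2, ctr) %*%
                           t(tilt), 2, ctr, "+")
  } else if (violation == "excluded_volume") {
    if (!length(model$excluded_volumes))
      stop("model has no excluded volumes")
    ev <- model$excluded_volumes[[1]]
    topo2 <- probe_topology_skeleton(6L, TRUE,
                                     any(topo$element == "O"))
    topo2$element <- c(topo2$element, "C")
    topo2$sybyl <- c(topo2$sybyl, "C.3")
    topo2$charge <- c(topo2$charge, 0L)
    topo2$heavy <- c(topo2$heavy, TRUE)
    topo2$aromatic <- c(topo2$aromatic, FALSE)
    topo2$adj <- c(topo2$adj, list(integer(0)))
    topo2$n_atoms <- topo2$n_atoms + 1L
    xyz <- rbind(xyz, ev$center)
    topo <- topo2
  } else if (violation == "exclO") {
    if (is.null(model$exclO)) stop("model has no exclO sphere")
    topo2 <- topo
    topo2$element <- c(topo2$element, "O")
    topo2$sybyl <- c(topo2$sybyl, "O.3")
    topo2$charge <- c(topo2$charge, 0L)
    topo2$heavy <- c(topo2$heavy, TRUE)
    topo2$aromatic <- c(topo2$aromatic, FALSE)
    topo2$adj <- c(topo2$adj, list(integer(0)))
    topo2$n_atoms <- topo2$n_atoms + 1L
    xyz <- rbind(xyz, model$exclO$center)
    topo <- topo2
  } else {
    ni <- which(topo$element == "N")[1]
    topo$charge[ni] <- 0L  # no longer a cation point
  }
  structure(list(ligand_id = paste0("decoy-", violation), key = "decoy",
                 xyz = xyz, delta_e = 0, seed_tag = "decoy",
                 topology = topo), class = "conformer")
}
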