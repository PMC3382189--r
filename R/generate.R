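#' @title Systematic torsion-search conformer generation
#' @description Conformer ensembles are generated by serial torsion driving:
#'   every acyclic rotatable bond is driven over a small set of canonical
#'   dihedral values, sterically implausible grid points are discarded, the
#'   surviving geometries are relaxed with MMFF94 and de-duplicated by
#'   heavy-atom RMSD, and the ensemble is cut at a strain-energy window
#'   relative to its most stable member (default 4 kcal/mol).
#' @name generate
NULL

mol_graph <- function(topology) {
  igraph::graph_from_edgelist(
    cbind(topology$bonds$a1, topology$bonds$a2), directed = FALSE)
}

bond_in_ring <- function(topology, a1, a2) {
  g <- mol_graph(topology)
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(a1, a2)))
  is.finite(igraph::distances(g2, v = a1, to = a2)[1, 1])
}

atom_sp2 <- function(topology, i) {
  topology$aromatic[i] ||
    grepl("\\.(2|ar|co2|pl3)$", topology$sybyl[i]) ||
    any(topology$bonds$type == "2" &
          (topology$bonds$a1 == i | topology$bonds$a2 == i))
}

#' Identify rotatable bonds and their torsion grids
#'
#' Acyclic single bonds between non-terminal heavy atoms, plus hydroxyl
#' C-O bonds (aryl O-H is driven over the two in-plane orientations).
#' Symmetric terminal rotors (methyl, ammonium) are excluded.
#'
#' @param topology a [mol_topology()].
#' @return data.frame with `a`, `b`, `c`, `d` (torsion reference quadruple)
#'   and a list-column `grid` of dihedral values in degrees.
#' @keywords internal
rotatable_bonds <- function(topology) {
  bonds <- topology$bonds
  out <- list()
  for (k in seq_len(nrow(bonds))) {
    if (!bonds$type[k] %in% "1") next
    b <- bonds$a1[k]; c <- bonds$a2[k]
    if (!topology$heavy[b] || !topology$heavy[c]) next
    if (bond_in_ring(topology, b, c)) next
    nb_b <- setdiff(topology$adj[[b]], c)
    nb_c <- setdiff(topology$adj[[c]], b)
    if (!length(nb_b) || !length(nb_c)) next
    term_b <- all(!topology$heavy[nb_b])
    term_c <- all(!topology$heavy[nb_c])
    hydroxyl <- (term_b && topology$element[b] == "O") ||
                (term_c && topology$element[c] == "O")
    if ((term_b || term_c) && !hydroxyl) next  # CH3 / NH3+ style rotor
    if (hydroxyl) {
      o <- if (term_b && topology$element[b] == "O") b else c
      cc <- if (o == b) c else b
      h <- nb_b
      if (o == c) h <- nb_c
      h <- h[!topology$heavy[h]][1]
      if (is.na(h)) next
      ref <- setdiff(topology$adj[[cc]], o)
      ref <- ref[topology$heavy[ref]][1]
      if (is.na(ref)) next
      grid <- if (topology$aromatic[cc]) c(0, 180) else c(60, 180, 300)
      out[[length(out) + 1L]] <- list(a = ref, b = cc, c = o, d = h,
                                      grid = grid)
      next
    }
    pick_ref <- function(nb) {
      hv <- nb[topology$heavy[nb]]
      if (length(hv)) hv[1] else nb[1]
    }
    a <- pick_ref(nb_b); d <- pick_ref(nb_c)
    sp2 <- atom_sp2(topology, b) || atom_sp2(topology, c)
    grid <- if (sp2) c(0, 90, 180, 270) else c(60, 180, 300)
    out[[length(out) + 1L]] <- list(a = a, b = b, c = c, d = d, grid = grid)
  }
  out
}

dihedral <- function(xyz, a, b, c, d) {
  b1 <- xyz[b, ] - xyz[a, ]
  b2 <- xyz[c, ] - xyz[b, ]
  b3 <- xyz[d, ] - xyz[c, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

moving_side <- function(topology, b, c) {
  # atoms on the c-side of bond b-c
  seen <- logical(topology$n_atoms)
  seen[c] <- TRUE
  queue <- c
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (nb in topology$adj[[cur]]) {
      if (nb == b && cur == c) next
      if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
    }
  }
  which(seen)
}

set_torsion <- function(xyz, topology, rot, side, target_deg) {
  cur <- dihedral(xyz, rot$a, rot$b, rot$c, rot$d)
  # rotating the c-side about the b->c axis by +theta decreases the
  # a-b-c-d dihedral as measured by dihedral()
  delta <- cur - target_deg
  rotm <- axis_rotation(xyz[rot$c, ] - xyz[rot$b, ], delta)
  pivot <- xyz[rot$b, ]
  xyz[side, ] <- sweep(sweep(xyz[side, , drop = FALSE], 2, pivot) %*%
                         t(rotm), 2, pivot, "+")
  xyz
}

#' Generate a conformer ensemble by serial torsion search
#'
#' @param ligand one row of an [expand_library()] table (needs `id`, `key`,
#'   `smiles`), or a list with at least `id` and `smiles`.
#' @param window strain-energy window in kcal/mol; conformers above
#'   `window` relative to the most stable member are discarded.
#' @param max_confs maximum ensemble size.
#' @param seed integer; recorded in `seed_tag` and used for the (rare)
#'   deterministic subsampling of oversized torsion grids. The torsion
#'   search itself is systematic and has no internal randomness.
#' @param rmsd_cutoff heavy-atom RMSD (Angstrom) under which two relaxed
#'   geometries are considered duplicates.
#' @param grid_cap largest torsion grid expanded exhaustively.
#' @param steps MMFF94 minimization steps per grid point.
#' @return an object of class `conformer_ensemble`: list with `ligand_id`,
#'   `key`, `topology`, `conformers` (each with `xyz`, `delta_e`,
#'   `seed_tag`), `window` and `generator_params`. Conformers are sorted by
#'   ascending `delta_e` and the first one always has `delta_e = 0`.
#' @examples
#' \donttest{
#' lib <- expand_library(build_library())
#' ens <- generate_conformers(lib[lib$id == "dopamine", ], window = 4)
#' length(ens$conformers)
#' }
#' @export
generate_conformers <- function(ligand, window = 4, max_confs = 300,
                                seed = 2012, rmsd_cutoff = 0.3,
                                grid_cap = 1500, steps = 200) {
  stopifnot(window > 0, max_confs >= 1)
  ligand <- as.list(ligand)
  key <- if (!is.null(ligand$key)) ligand$key else ligand$id
  topology <- mol_topology(ligand$smiles)
  starts <- frozen_embeddings(key)
  if (!length(starts)) starts <- list(embed_smiles(ligand$smiles))
  for (s in starts)
    if (nrow(s) != topology$n_atoms)
      stop("conformer generation failed: embedding size mismatch for ",
           ligand$id)
  rots <- rotatable_bonds(topology)
  heavy <- which(topology$heavy)

  if (length(rots)) {
    grids <- lapply(rots, `[[`, "grid")
    combos <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
    if (nrow(combos) * length(starts) > grid_cap) {
      set.seed(seed %% .Machine$integer.max)
      ncap <- max(1L, grid_cap %/% length(starts))
      combos <- combos[sort(sample.int(nrow(combos),
                                       min(nrow(combos), ncap))), ,
                       drop = FALSE]
    }
    sides <- lapply(rots, function(r) moving_side(topology, r$b, r$c))
    g <- mol_graph(topology)
    gdist <- igraph::distances(g, v = heavy, to = heavy)
    far <- which(gdist >= 4 & upper.tri(gdist), arr.ind = TRUE)
    coords_list <- list()
    for (xyz0 in starts) {
      for (i in seq_len(nrow(combos))) {
        xyz <- xyz0
        for (r in seq_along(rots))
          xyz <- set_torsion(xyz, topology, rots[[r]], sides[[r]],
                             combos[i, r])
        hxyz <- xyz[heavy, , drop = FALSE]
        if (nrow(far)) {
          d2 <- rowSums((hxyz[far[, 1], , drop = FALSE] -
                           hxyz[far[, 2], , drop = FALSE])^2)
          if (any(d2 < 1.8^2)) next
        }
        coords_list[[length(coords_list) + 1L]] <- xyz
      }
    }
  } else {
    coords_list <- starts
  }
  if (!length(coords_list))
    stop("conformer generation failed: no clash-free torsion grid point ",
         "for ", ligand$id)

  # single-point screen, then relax the plausible band
  fin <- tempfile(fileext = ".sdf")
  on.exit(unlink(fin), add = TRUE)
  write_sdf(topology, coords_list, fin)
  e0 <- ob_energies(fin)
  band <- which(e0 <= min(e0, na.rm = TRUE) + window + 6)
  relaxed <- ob_minimize(topology, coords_list[band], steps = steps)

  ord <- order(relaxed$energy)
  sel_full <- list(); sel_e <- numeric(0); sel_heavy <- list()
  for (i in ord) {
    xi <- relaxed$coords[[i]][heavy, , drop = FALSE]
    dup <- FALSE
    for (s in sel_heavy)
      if (aligned_rmsd(xi, s) < rmsd_cutoff) { dup <- TRUE; break }
    if (!dup) {
      sel_heavy[[length(sel_heavy) + 1L]] <- xi
      sel_full[[length(sel_full) + 1L]] <- relaxed$coords[[i]]
      sel_e <- c(sel_e, relaxed$energy[i])
    }
  }
  delta_e <- sel_e - sel_e[1]
  inwin <- which(delta_e <= window)
  inwin <- inwin[seq_len(min(length(inwin), max_confs))]
  seed_tag <- sprintf("torsion-grid/seed=%d", seed)
  conformers <- lapply(inwin, function(i) {
    structure(list(ligand_id = ligand$id, key = key,
                   xyz = sel_full[[i]], delta_e = delta_e[i],
                   seed_tag = seed_tag), class = "conformer")
  })
  structure(list(
    ligand_id = ligand$id,
    key = key,
    activity_class = ligand$activity_class,
    topology = topology,
    conformers = conformers,
    window = window,
    generator_params = list(method = "serial-torsion-mmff94",
                            max_confs = max_confs, seed = seed,
                            rmsd_cutoff = rmsd_cutoff, steps = steps)
  ), class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  de <- vapply(x$conformers, `[[`, numeric(1), "delta_e")
  cat("<conformer_ensemble> ", x$ligand_id, ": ", length(x$conformers),
      " conformers, dE range [0, ",
      sprintf("%.2f", max(de)), "] kcal/mol (window ", x$window, ")\n",
      sep = "")
  invisible(x)
}

#' Write a conformer ensemble as a multi-record SD file
#'
#' Each record carries `delta_e` and `seed_tag` SD tags.
#' @param ensemble a [generate_conformers()] result.
#' @param path output file.
#' @export
write_ensemble_sdf <- function(ensemble, path) {
  de <- vapply(ensemble$conformers, `[[`, numeric(1), "delta_e")
  st <- vapply(ensemble$conformers, `[[`, character(1), "seed_tag")
  write_sdf(ensemble$topology,
            lapply(ensemble$conformers, `[[`, "xyz"), path,
            tags = list(delta_e = sprintf("%.6f", de), seed_tag = st),
            title = ensemble$ligand_id)
}

#' Read a conformer ensemble back from an SD file written by
#' [write_ensemble_sdf()]
#'
#' @param path SD file.
#' @param topology the ligand's [mol_topology()] (SD files do not retain
#'   aromatic typing).
#' @param ligand_id ligand identifier.
#' @param window energy window to record.
#' @export
read_ensemble_sdf <- function(path, topology, ligand_id = "ligand",
                              window = 4) {
  recs <- read_sdf(path)
  conformers <- lapply(recs, function(r) {
    xyz <- as.matrix(r$atoms[, c("x", "y", "z")]); dimnames(xyz) <- NULL
    structure(list(ligand_id = ligand_id, key = ligand_id, xyz = xyz,
                   delta_e = as.numeric(r$tags[["delta_e"]]),
                   seed_tag = unname(r$tags[["seed_tag"]])),
              class = "conformer")
  })
  structure(list(ligand_id = ligand_id, key = ligand_id,
                 activity_class = NA_character_, topology = topology,
                 conformers = conformers, window = window,
                 generator_params = list(method = "sdf-import")),
            class = "conformer_ensemble")
}
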