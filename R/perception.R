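#' @title Ligand annotation-point perception
#' @description Converts a conformer into the typed interaction points the
#'   pharmacophore matcher consumes: one cation point per protonated
#'   nitrogen (the Asp-TM3 salt-bridge partner), one aromatic point per
#'   aromatic ring (centroid plus unsigned normal, for directional pi
#'   stacking), projected hydrogen-bond donor/acceptor points at the
#'   idealized partner position 2.8 Angstrom from the heavy atom, and one
#'   `oxygen_atom` point per oxygen (for the excluded-oxygen rule).
#' @name perception
NULL

#' Aromatic rings of a topology
#'
#' @param topology a [mol_topology()].
#' @return list of integer vectors (ring atom indices in cyclic order).
#' @keywords internal
aromatic_rings <- function(topology) {
  ar <- topology$bonds[topology$bonds$type == "ar", , drop = FALSE]
  if (!nrow(ar)) return(list())
  g <- igraph::graph_from_edgelist(cbind(ar$a1, ar$a2), directed = FALSE)
  rings <- list()
  seen <- character(0)
  for (k in seq_len(nrow(ar))) {
    a <- ar$a1[k]; b <- ar$a2[k]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(a, b)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = a, to = b))
    p <- as.integer(sp$vpath[[1]])
    if (length(p) < 4 || length(p) > 6) next
    key <- paste(sort(p), collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    rings[[length(rings) + 1L]] <- p
  }
  rings
}

#' In-plane projected points for an aryl hydroxyl (or aryl amine) donor
#'
#' A hydroxyl on an aromatic ring prefers the ring plane, so an extended
#' hydrogen-bond feature can only be reached at two in-plane positions
#' separated by 120 degrees: the two points are placed at distance `dist`
#' from the oxygen, rotated +/-60 degrees from the C-O extension about the
#' ring normal (syn/anti lone-pair and O-H geometry).
#'
#' @param o oxygen position (length-3).
#' @param c_ar attached aromatic-carbon position.
#' @param normal unit ring normal.
#' @param center a point in the ring plane (ring centroid).
#' @param dist projection distance in Angstrom (ideal heavy-atom
#'   hydrogen-bond separation, default 2.8).
#' @return 2 x 3 matrix of projected points, exactly in the ring plane.
#' @export
project_aryl_donor <- function(o, c_ar, normal, center, dist = 2.8) {
  n <- unitize(normal)
  drop_in <- function(p) p - sum((p - center) * n) * n
  o_in <- drop_in(o)
  c_in <- drop_in(c_ar)
  dir0 <- unitize(o_in - c_in)
  p1 <- o_in + as.vector(axis_rotation(n, 60) %*% dir0) * dist
  p2 <- o_in + as.vector(axis_rotation(n, -60) %*% dir0) * dist
  rbind(p1, p2)
}

annotation_point <- function(kind, pos, dir = NULL, atoms = integer(0)) {
  list(kind = kind, pos = as.numeric(pos),
       dir = if (is.null(dir)) NULL else unitize(dir),
       atoms = as.integer(atoms))
}

#' Perceive annotation points of a conformer
#'
#' @param conformer a `conformer` (with `xyz`) plus its topology, or a
#'   `conformer_ensemble` member; pass `topology` explicitly when the
#'   conformer does not carry one.
#' @param topology the ligand [mol_topology()].
#' @param proj_dist projection distance for hydrogen-bond points.
#' @return list of annotation points (`kind`, `pos`, `dir` or NULL,
#'   `atoms`), kinds in `cation`, `aromatic`, `donor_proj`,
#'   `acceptor_proj`, `acceptor_atom`, `oxygen_atom`.
#' @export
perceive <- function(conformer, topology = NULL, proj_dist = 2.8) {
  if (is.null(topology)) topology <- conformer$topology
  if (is.null(topology)) stop("topology required")
  xyz <- conformer$xyz
  if (is.null(xyz)) stop("unembedded conformer")
  if (nrow(xyz) != topology$n_atoms) stop("unembedded conformer")
  pts <- list()
  el <- topology$element

  # cation: protonated nitrogen
  for (i in which(el == "N" & topology$charge > 0))
    pts[[length(pts) + 1L]] <- annotation_point("cation", xyz[i, ],
                                                atoms = i)

  # aromatic rings: centroid + (unsigned) normal
  rings <- aromatic_rings(topology)
  ring_info <- list()
  for (r in rings) {
    pf <- plane_fit(xyz[r, , drop = FALSE])
    ring_info[[length(ring_info) + 1L]] <-
      list(atoms = r, center = pf$center, normal = pf$normal)
    pts[[length(pts) + 1L]] <- annotation_point("aromatic", pf$center,
                                                dir = pf$normal, atoms = r)
  }
  ring_of_atom <- function(i) {
    for (ri in ring_info) if (i %in% ri$atoms) return(ri)
    NULL
  }

  # hydrogen-bond donors (O-H, N-H) and acceptors
  for (i in which(topology$heavy)) {
    nb <- topology$adj[[i]]
    hs <- nb[!topology$heavy[nb]]
    hv <- nb[topology$heavy[nb]]
    if (el[i] == "O" && length(hs)) {
      ar_c <- hv[topology$aromatic[hv]]
      if (length(ar_c)) {
        ri <- ring_of_atom(ar_c[1])
        pp <- project_aryl_donor(xyz[i, ], xyz[ar_c[1], ], ri$normal,
                                 ri$center, proj_dist)
        for (k in 1:2) {
          dirk <- unitize(pp[k, ] - xyz[i, ])
          pts[[length(pts) + 1L]] <-
            annotation_point("donor_proj", pp[k, ], dir = dirk, atoms = i)
          pts[[length(pts) + 1L]] <-
            annotation_point("acceptor_proj", pp[k, ], dir = dirk,
                             atoms = i)
        }
      } else {
        for (h in hs) {
          dirh <- unitize(xyz[h, ] - xyz[i, ])
          pts[[length(pts) + 1L]] <-
            annotation_point("donor_proj", xyz[i, ] + dirh * proj_dist,
                             dir = dirh, atoms = i)
        }
        pts[[length(pts) + 1L]] <-
          annotation_point("acceptor_atom", xyz[i, ], atoms = i)
      }
    } else if (el[i] == "N" && length(hs) && topology$charge[i] <= 0) {
      for (h in hs) {
        dirh <- unitize(xyz[h, ] - xyz[i, ])
        pts[[length(pts) + 1L]] <-
          annotation_point("donor_proj", xyz[i, ] + dirh * proj_dist,
                           dir = dirh, atoms = i)
      }
    }
    # acceptors without hydrogens
    if (el[i] == "O" && !length(hs)) {
      if (any(topology$bonds$type == "2" &
              (topology$bonds$a1 == i | topology$bonds$a2 == i))) {
        # carbonyl: project along the C=O extension
        cdir <- unitize(xyz[i, ] - xyz[hv[1], ])
        pts[[length(pts) + 1L]] <-
          annotation_point("acceptor_proj", xyz[i, ] + cdir * proj_dist,
                           dir = cdir, atoms = i)
      }
      pts[[length(pts) + 1L]] <- annotation_point("acceptor_atom",
                                                  xyz[i, ], atoms = i)
    }
    if (el[i] == "N" && !length(hs) && topology$charge[i] <= 0 &&
        length(hv) <= 2) {
      # pyridine-type lone pair
      lp <- c(0, 0, 0)
      for (j in hv) lp <- lp - unitize(xyz[j, ] - xyz[i, ])
      if (vnorm(lp) > 1e-6) {
        lp <- unitize(lp)
        pts[[length(pts) + 1L]] <-
          annotation_point("acceptor_proj", xyz[i, ] + lp * proj_dist,
                           dir = lp, atoms = i)
      }
      pts[[length(pts) + 1L]] <- annotation_point("acceptor_atom",
                                                  xyz[i, ], atoms = i)
    }
    if (el[i] == "O")
      pts[[length(pts) + 1L]] <- annotation_point("oxygen_atom", xyz[i, ],
                                                  atoms = i)
  }
  pts
}

#' Tabulate annotation-point kinds
#' @param points result of [perceive()].
#' @return named integer table.
#' @export
annotation_counts <- function(points) {
  table(vapply(points, `[[`, character(1), "kind"))
}

#' Serialize annotation points to JSON
#' @param points result of [perceive()].
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
annotations_json <- function(points, path = NULL) {
  payload <- lapply(points, function(p) {
    list(kind = p$kind, xyz = round(p$pos, 4),
         dir = if (is.null(p$dir)) NULL else round(p$dir, 6),
         atoms = p$atoms)
  })
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                         digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Hydrogen-bond groups of a ligand
#'
#' Extracts donor (heavy atom + hydrogen) pairs and acceptor heavy atoms,
#' with meta/para labels for hydroxyls on the dopamine-like aromatic ring
#' (position counted around the ring from the carbon that carries the
#' chain leading to the protonated nitrogen).
#'
#' @param topology a [mol_topology()].
#' @return list with `donors` data.frame (`d`, `h`, `label`) and
#'   `acceptors` data.frame (`a`, `label`).
#' @export
hbond_groups <- function(topology) {
  el <- topology$element
  rings <- aromatic_rings(topology)
  g <- mol_graph(topology)
  catn <- which(el == "N" & topology$charge > 0)
  ring_pos_label <- function(o) {
    # o: aryl oxygen; find its ring carbon and the chain-attachment carbon
    hv <- topology$adj[[o]]
    hv <- hv[topology$heavy[hv]]
    car <- hv[topology$aromatic[hv]]
    if (!length(car) || !length(catn)) return(NA_character_)
    ring <- NULL
    for (r in rings) if (car[1] %in% r) { ring <- r; break }
    if (is.null(ring)) return(NA_character_)
    # attachment atom: ring atom closest in the graph to the cation N
    dN <- igraph::distances(g, v = ring, to = catn[1])[, 1]
    att <- ring[which.min(dN)]
    k1 <- which(ring == car[1]); k2 <- which(ring == att)
    sep <- min(abs(k1 - k2), length(ring) - abs(k1 - k2))
    c("ipso", "ortho", "m", "p")[pmin(sep, 3) + 1]
  }
  donors <- data.frame(d = integer(0), h = integer(0),
                       label = character(0), stringsAsFactors = FALSE)
  acceptors <- data.frame(a = integer(0), label = character(0),
                          stringsAsFactors = FALSE)
  for (i in which(topology$heavy)) {
    nb <- topology$adj[[i]]
    hs <- nb[!topology$heavy[nb]]
    if (!el[i] %in% c("O", "N")) next
    lab <- if (el[i] == "O") ring_pos_label(i) else NA_character_
    if (length(hs) && !(el[i] == "N" && topology$charge[i] > 0 &&
                        length(hs) >= 3)) {
      for (h in hs)
        donors <- rbind(donors, data.frame(d = i, h = h,
          label = if (is.na(lab)) el[i] else lab,
          stringsAsFactors = FALSE))
    } else if (length(hs) && el[i] == "N" && topology$charge[i] > 0) {
      # primary ammonium: a donor too, label as N+
      for (h in hs)
        donors <- rbind(donors, data.frame(d = i, h = h, label = "N+",
                                           stringsAsFactors = FALSE))
    }
    if (el[i] == "O" || (el[i] == "N" && !length(hs) &&
                         topology$charge[i] <= 0))
      acceptors <- rbind(acceptors, data.frame(a = i,
        label = if (is.na(lab)) el[i] else lab, stringsAsFactors = FALSE))
  }
  list(donors = donors, acceptors = acceptors)
}
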