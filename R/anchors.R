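#' @title Receptor anchors and hydrogen-bond geometry
#' @description Receptor-side geometry enters the pipeline as an abstract
#'   anchor set: named hydrogen-bonding atoms of the orthosteric pocket
#'   (Ser193 side-chain OG and backbone O in TM5, His393 NE2 in TM6, Asn186
#'   in the second extracellular loop, Asp114 OD in TM3), plus the pocket
#'   hydrogen sites and aromatic ring centroids from which the excluded
#'   volume shell is built. No receptor coordinates were ever deposited for
#'   this system, so the shipped anchor set is a synthetic fixture
#'   constructed in the pharmacophore frame (see [derive_anchor_set()]);
#'   hydrogen-bond numbers computed against it are model-consistent
#'   quantities, not experimental measurements.
#' @name anchors
NULL

#' Construct an anchor set
#'
#' @param anchors data.frame with `name`, `element`, `role` (`donor`,
#'   `acceptor` or `both`), `x`, `y`, `z`.
#' @param hydrogen_sites data.frame with `x`, `y`, `z`, `tag` (one of
#'   `aliphatic_H`, `aromatic_H`, `polar_H`).
#' @param ring_centroids data.frame with `x`, `y`, `z`.
#' @param frame_tag provenance string.
#' @export
anchor_set <- function(anchors,
                       hydrogen_sites = data.frame(x = numeric(0),
                         y = numeric(0), z = numeric(0),
                         tag = character(0)),
                       ring_centroids = data.frame(x = numeric(0),
                         y = numeric(0), z = numeric(0)),
                       frame_tag = "model-frame") {
  stopifnot(all(c("name", "element", "role", "x", "y", "z") %in%
                  names(anchors)))
  bad <- setdiff(unique(hydrogen_sites$tag),
                 c("aliphatic_H", "aromatic_H", "polar_H"))
  if (length(bad)) stop("unknown hydrogen-site tag: ",
                        paste(bad, collapse = ", "))
  pos <- rbind(as.matrix(anchors[, c("x", "y", "z")]),
               as.matrix(hydrogen_sites[, c("x", "y", "z")]),
               as.matrix(ring_centroids[, c("x", "y", "z")]))
  if (length(pos) && !all(is.finite(pos)))
    stop("anchor-set coordinates must be finite")
  structure(list(anchors = anchors, hydrogen_sites = hydrogen_sites,
                 ring_centroids = ring_centroids, frame_tag = frame_tag),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat("<anchor_set> [", x$frame_tag, "] ", nrow(x$anchors),
      " anchors, ", nrow(x$hydrogen_sites), " hydrogen sites, ",
      nrow(x$ring_centroids), " ring centroids\n", sep = "")
  invisible(x)
}

#' Serialize / load an anchor set as JSON
#' @param aset an [anchor_set()].
#' @param path output file (write) / input file (read).
#' @export
write_anchors_json <- function(aset, path = NULL) {
  payload <- list(schema = "dopaphore/anchor_set/1",
                  frame_tag = aset$frame_tag,
                  anchors = aset$anchors,
                  hydrogen_sites = aset$hydrogen_sites,
                  ring_centroids = aset$ring_centroids)
  js <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(path)) }
  js
}

#' @rdname write_anchors_json
#' @export
read_anchors_json <- function(path) {
  p <- jsonlite::fromJSON(path)
  as_df <- function(d, cols) {
    if (is.null(d) || !length(d)) {
      out <- as.data.frame(stats::setNames(
        rep(list(numeric(0)), length(cols)), cols))
      if ("tag" %in% cols) out$tag <- character(0)
      return(out)
    }
    as.data.frame(d, stringsAsFactors = FALSE)
  }
  anchor_set(as_df(p$anchors, c("name", "element", "role", "x", "y", "z")),
             as_df(p$hydrogen_sites, c("x", "y", "z", "tag")),
             as_df(p$ring_centroids, c("x", "y", "z")),
             frame_tag = p$frame_tag)
}

#' Load the shipped synthetic anchor-set fixture
#' @export
shipped_anchor_set <- function() {
  read_anchors_json(system.file("extdata", "anchor_set.json",
                                package = "dopaphore", mustWork = TRUE))
}

#' Excluded-volume radii presets
#'
#' The shell is initialized from Bondi van der Waals radii (1.2 Angstrom
#' aliphatic, 1.0 aromatic hydrogens; hydroxy/amine hydrogens take the
#' benzene value) and tuned to effective final radii of 2.0 (aliphatic)
#' and 1.8 (aromatic), with 2.5-Angstrom spheres on aromatic ring
#' centroids.
#'
#' @param stage `"final"` (tuned) or `"bondi"` (initial van der Waals).
#' @return named numeric vector of radii per origin tag.
#' @export
ev_radii <- function(stage = c("final", "bondi")) {
  stage <- match.arg(stage)
  if (stage == "bondi")
    c(aliphatic_H = 1.2, aromatic_H = 1.0, polar_H = 1.0,
      ring_centroid = 2.5)
  else
    c(aliphatic_H = 2.0, aromatic_H = 1.8, polar_H = 1.8,
      ring_centroid = 2.5)
}

#' Build excluded volumes from an anchor set
#'
#' One sphere per pocket hydrogen site (radius by tag) and one per
#' aromatic ring centroid.
#'
#' @param aset an [anchor_set()].
#' @param radii named radii per tag, as from [ev_radii()].
#' @return list of [excluded_volume()]s of length
#'   `nrow(hydrogen_sites) + nrow(ring_centroids)`.
#' @export
build_excluded_volumes <- function(aset, radii = ev_radii("final")) {
  evs <- list()
  hs <- aset$hydrogen_sites
  for (i in seq_len(nrow(hs))) {
    tag <- hs$tag[i]
    if (!tag %in% names(radii)) stop("unknown tag: ", tag)
    evs[[length(evs) + 1L]] <-
      excluded_volume(c(hs$x[i], hs$y[i], hs$z[i]), radii[[tag]], tag)
  }
  rc <- aset$ring_centroids
  for (i in seq_len(nrow(rc))) {
    evs[[length(evs) + 1L]] <-
      excluded_volume(c(rc$x[i], rc$y[i], rc$z[i]),
                      radii[["ring_centroid"]], "ring_centroid")
  }
  evs
}

#' Hydrogen-bond distance and angle with acceptance verdict
#'
#' Heavy-atom separation `d` and the donor-heavy-atom / hydrogen /
#' acceptor angle. A geometry is `ok` for d in [2.4, 3.8] Angstrom and
#' angle in 180 +/- 40 degrees (closed intervals); `borderline` when it
#' misses a bound by at most +0.3 Angstrom / -12 degrees (the convention
#' used to flag just-outside contacts such as 4.1 Angstrom at 151
#' degrees); otherwise `fail`.
#'
#' @param donor_heavy,hydrogen,acceptor_heavy length-3 coordinates.
#' @return list with `d`, `angle`, `verdict`.
#' @export
hbond_geometry <- function(donor_heavy, hydrogen, acceptor_heavy) {
  pts <- rbind(donor_heavy, hydrogen, acceptor_heavy)
  if (any(!is.finite(pts))) stop("degenerate geometry: non-finite point")
  if (min(stats::dist(pts)) < 1e-9) stop("degenerate geometry")
  d <- vnorm(acceptor_heavy - donor_heavy)
  ang <- point_angle(donor_heavy, hydrogen, acceptor_heavy)
  hbond_verdict(d, ang)
}

hbond_verdict <- function(d, ang) {
  d_ok <- d >= 2.4 && d <= 3.8
  a_ok <- ang >= 140 && ang <= 220
  d_bl <- d >= 2.4 - 0.3 && d <= 3.8 + 0.3
  a_bl <- ang >= 140 - 12 && ang <= 220 + 12
  verdict <- if (d_ok && a_ok) "ok"
  else if (d_bl && a_bl) "borderline"
  else "fail"
  list(d = d, angle = ang, verdict = verdict)
}

#' Evaluate hydrogen-bond geometry of a hit against the receptor anchors
#'
#' Transforms the ligand's donor and acceptor groups into the model frame
#' with the hit's rigid transform and reports, for each named anchor and
#' each ligand hydrogen-bonding group, the best (distance, angle) pairing.
#' Catechol hydroxyls are reported as separate meta (`m`) and para (`p`)
#' rows. When the receptor anchor is the donor its hydrogen is idealized
#' on the donor-acceptor axis (receptor hydrogen positions are unknown),
#' giving a 180-degree angle. Pairings farther than `max_report_dist` are
#' omitted, mirroring how distant contacts are not reported in screening
#' tables.
#'
#' @param hit a `pharm_hit` (carries `xyz` and `transform`).
#' @param aset an [anchor_set()].
#' @param topology the ligand [mol_topology()].
#' @param max_report_dist maximum heavy-atom distance reported (Angstrom).
#' @return data.frame with `anchor`, `group`, `d`, `angle`, `verdict`.
#' @export
evaluate_hit <- function(hit, aset, topology, max_report_dist = 4.5) {
  stopifnot(inherits(hit, "pharm_hit"))
  xyz <- apply_transform(hit$xyz, hit$transform)
  grp <- hbond_groups(topology)
  out <- data.frame(anchor = character(0), group = character(0),
                    d = numeric(0), angle = numeric(0),
                    verdict = character(0), stringsAsFactors = FALSE)
  an <- aset$anchors
  for (i in seq_len(nrow(an))) {
    apos <- c(an$x[i], an$y[i], an$z[i])
    cand <- list()
    if (an$role[i] %in% c("acceptor", "both")) {
      for (k in seq_len(nrow(grp$donors))) {
        dpos <- xyz[grp$donors$d[k], ]
        hpos <- xyz[grp$donors$h[k], ]
        d <- vnorm(apos - dpos)
        if (d > max_report_dist || d < 1e-9) next
        ang <- point_angle(dpos, hpos, apos)
        cand[[length(cand) + 1L]] <-
          data.frame(anchor = an$name[i], group = grp$donors$label[k],
                     d = d, angle = ang,
                     verdict = hbond_verdict(d, ang)$verdict,
                     stringsAsFactors = FALSE)
      }
    }
    if (an$role[i] %in% c("donor", "both")) {
      for (k in seq_len(nrow(grp$acceptors))) {
        ap <- xyz[grp$acceptors$a[k], ]
        d <- vnorm(apos - ap)
        if (d > max_report_dist || d < 1e-9) next
        cand[[length(cand) + 1L]] <-
          data.frame(anchor = an$name[i], group = grp$acceptors$label[k],
                     d = d, angle = 180,
                     verdict = hbond_verdict(d, 180)$verdict,
                     stringsAsFactors = FALSE)
      }
    }
    if (!length(cand)) next
    cd <- do.call(rbind, cand)
    # best pairing per ligand group: ok > borderline > fail, then closest
    # to the 2.8-Angstrom optimum
    rank <- match(cd$verdict, c("ok", "borderline", "fail"))
    for (gname in unique(cd$group)) {
      sub <- cd[cd$group == gname, , drop = FALSE]
      rsub <- rank[cd$group == gname]
      best <- order(rsub, abs(sub$d - 2.8))[1]
      out <- rbind(out, sub[best, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}
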