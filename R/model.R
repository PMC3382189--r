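#' @title Pharmacophore model container
#' @description A pharmacophore model is a fixed 3D arrangement of typed
#'   features in a model frame: the essential Asp-TM3 cation feature (the
#'   salt bridge to the TM3 aspartate), the essential aromatic feature with
#'   a stacking direction, the optional Ser-TM5 projected hydrogen-bond
#'   feature, a shell of excluded volumes encoding the steric bulk of the
#'   binding pocket, and an excluded-oxygen (exclO) sphere that forbids
#'   ligand oxygen atoms in a hydrophobic subpocket.
#' @name model
NULL

#' Construct a pharmacophore feature
#'
#' @param name feature name (e.g. `"AspTM3"`, `"Aro"`, `"SerTM5"`).
#' @param kinds annotation-point kinds the feature can match.
#' @param center length-3 position in the model frame (Angstrom).
#' @param radius match tolerance radius (> 0).
#' @param essential must the feature be matched for a hit?
#' @param direction optional unit vector (unsigned semantics for aromatic
#'   normals).
#' @param direction_tol angular tolerance in degrees.
#' @export
pharm_feature <- function(name, kinds, center, radius = 1.0,
                          essential = TRUE, direction = NULL,
                          direction_tol = 30) {
  stopifnot(radius > 0, length(center) == 3)
  list(name = name, kinds = kinds, center = as.numeric(center),
       radius = radius, essential = isTRUE(essential),
       direction = if (is.null(direction)) NULL else unitize(direction),
       direction_tol = direction_tol)
}

#' Construct an excluded volume
#'
#' @param center length-3 position (model frame, Angstrom).
#' @param radius sphere radius; ligand heavy atoms may not be strictly
#'   inside.
#' @param origin_tag provenance of the sphere: `aliphatic_H`, `aromatic_H`,
#'   `polar_H` or `ring_centroid`.
#' @export
excluded_volume <- function(center, radius,
                            origin_tag = c("aliphatic_H", "aromatic_H",
                                           "polar_H", "ring_centroid")) {
  origin_tag <- match.arg(origin_tag)
  stopifnot(radius > 0, length(center) == 3)
  list(center = as.numeric(center), radius = radius,
       origin_tag = origin_tag)
}

#' Assemble a pharmacophore model
#'
#' @param features list of [pharm_feature()]s; at least one essential.
#' @param excluded_volumes list of [excluded_volume()]s.
#' @param exclO optional list with `center` and `radius`: a sphere that no
#'   ligand oxygen atom may enter.
#' @param frame_tag provenance string for the model frame.
#' @export
pharm_model <- function(features, excluded_volumes = list(), exclO = NULL,
                        frame_tag = "model-frame") {
  ess <- vapply(features, `[[`, logical(1), "essential")
  if (!any(ess)) stop("a pharmacophore model needs >=1 essential feature")
  structure(list(features = features,
                 excluded_volumes = excluded_volumes,
                 exclO = exclO, frame_tag = frame_tag),
            class = "pharm_model")
}

#' @export
print.pharm_model <- function(x, ...) {
  cat("<pharm_model> [", x$frame_tag, "]\n", sep = "")
  for (f in x$features)
    cat(sprintf("  %-8s r=%.2f %s%s\n", f$name, f$radius,
                if (f$essential) "essential" else "optional",
                if (is.null(f$direction)) "" else
                  sprintf(" dir tol=%g", f$direction_tol)))
  cat("  ", length(x$excluded_volumes), " excluded volumes; exclO ",
      if (is.null(x$exclO)) "absent" else
        sprintf("r=%.2f", x$exclO$radius), "\n", sep = "")
  invisible(x)
}

#' Serialize a pharmacophore model to JSON
#' @param model a [pharm_model()].
#' @param path output file; when NULL the JSON string is returned.
#' @export
write_model_json <- function(model, path = NULL) {
  payload <- list(
    schema = "dopaphore/pharm_model/1",
    frame_tag = model$frame_tag,
    features = lapply(model$features, function(f) {
      out <- list(name = f$name, kinds = as.list(f$kinds),
                  center = f$center, radius = f$radius,
                  essential = f$essential)
      if (!is.null(f$direction)) {
        out$direction <- f$direction
        out$direction_tol <- f$direction_tol
      }
      out
    }),
    excluded_volumes = lapply(model$excluded_volumes, function(v)
      list(center = v$center, radius = v$radius,
           origin_tag = v$origin_tag)),
    exclO = if (is.null(model$exclO)) NULL else
      list(center = model$exclO$center, radius = model$exclO$radius)
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(path)) }
  js
}

#' Read a pharmacophore model from JSON
#' @param path JSON file or string written by [write_model_json()].
#' @export
read_model_json <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- lapply(p$features, function(f)
    pharm_feature(f$name, unlist(f$kinds), unlist(f$center), f$radius,
                  f$essential,
                  direction = if (is.null(f$direction)) NULL else
                    unlist(f$direction),
                  direction_tol = if (is.null(f$direction_tol)) 30 else
                    f$direction_tol))
  evs <- lapply(p$excluded_volumes, function(v)
    excluded_volume(unlist(v$center), v$radius, v$origin_tag))
  exclO <- if (is.null(p$exclO)) NULL else
    list(center = unlist(p$exclO$center), radius = p$exclO$radius)
  pharm_model(feats, evs, exclO, p$frame_tag)
}

#' Load the shipped refined D2 full-agonist pharmacophore model
#' @return a [pharm_model()].
#' @export
refined_model <- function() {
  read_model_json(system.file("extdata", "refined_model.json",
                              package = "dopaphore", mustWork = TRUE))
}

#' Ablate a pharmacophore model
#'
#' Two ablations probe what the model's selectivity rests on:
#' `drop_excluded_volumes` removes the whole excluded-volume shell (the
#' exclO sphere is a separate identity and is retained);
#' `tm5_essential` promotes the optional Ser-TM5 hydrogen-bond feature to
#' essential.
#'
#' @param model a [pharm_model()].
#' @param mode `"drop_excluded_volumes"` or `"tm5_essential"`.
#' @return a modified copy of the model.
#' @export
ablate <- function(model, mode = c("drop_excluded_volumes",
                                   "tm5_essential")) {
  mode <- match.arg(mode)
  if (mode == "drop_excluded_volumes") {
    model$excluded_volumes <- list()
  } else {
    idx <- which(vapply(model$features, `[[`, character(1), "name") ==
                   "SerTM5")
    if (!length(idx)) stop("model has no SerTM5 feature to promote")
    model$features[[idx]]$essential <- TRUE
  }
  model
}
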