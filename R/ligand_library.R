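#' @title The D2 agonist training library
#' @description The 30-ligand dopamine D2 training set: 13 full agonists,
#'   5 partial agonists and 12 structurally similar inactive compounds,
#'   encoded as isomeric SMILES with the most basic aliphatic or alicyclic
#'   nitrogen protonated (+1, physiological-pH convention; phenols neutral).
#' @name ligand_library
NULL

#' Load the shipped 30-ligand D2 training library
#'
#' @param path optional path to a tab-separated ligand table with columns
#'   `id`, `activity_class`, `amine_config_policy`, `smiles`. Defaults to
#'   the library shipped with the package.
#' @return a data.frame of class `ligand_library` with one row per ligand:
#'   `id`, `activity_class` (`full`/`partial`/`inactive`),
#'   `amine_config_policy` (`fixed`/`enumerate`) and isomeric `smiles`.
#' @examples
#' lib <- build_library()
#' table(lib$activity_class)
#' @export
build_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "d2_ligands.tsv", package = "dopaphore",
                        mustWork = TRUE)
  lib <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "activity_class", "amine_config_policy", "smiles")
  if (!all(need %in% names(lib)))
    stop("ligand table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(lib$activity_class),
                 c("full", "partial", "inactive"))
  if (length(bad)) stop("unknown activity class: ", paste(bad, collapse = ","))
  class(lib) <- c("ligand_library", "data.frame")
  lib
}

#' @export
print.ligand_library <- function(x, ...) {
  cat("<ligand_library> ", nrow(x), " ligands (",
      sum(x$activity_class == "full"), " full / ",
      sum(x$activity_class == "partial"), " partial / ",
      sum(x$activity_class == "inactive"), " inactive)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Enumerate the two pyramidal configurations of a protonated tertiary amine
#'
#' A protonated tertiary amine is configurationally stable on the binding
#' time scale, so ligands flagged `amine_config_policy = "enumerate"` are
#' screened as both nitrogen invertomers. The invertomers are encoded by
#' stamping the `[NH+]` token of the parent SMILES with `@`/`@@`.
#'
#' @param ligand one row of a [build_library()] table (data.frame or list).
#' @return data.frame with two rows sharing the parent `id`, with `config`
#'   (`"a"`/`"b"`) and the stereo-annotated `smiles`.
#' @examples
#' lib <- build_library()
#' enumerate_amine_configs(lib[lib$id == "quinpirole", ])
#' @export
enumerate_amine_configs <- function(ligand) {
  ligand <- as.list(ligand)
  if (!identical(ligand$amine_config_policy, "enumerate"))
    stop("not applicable: ligand '", ligand$id,
         "' has no enumerable tertiary amine")
  smi <- ligand$smiles
  if (!grepl("[NH+]", smi, fixed = TRUE))
    stop("not applicable: no [NH+] tertiary ammonium token in ", ligand$id)
  out <- data.frame(
    id = rep(ligand$id, 2),
    activity_class = rep(ligand$activity_class, 2),
    amine_config_policy = "fixed",
    config = c("a", "b"),
    smiles = c(sub("[NH+]", "[N@H+]", smi, fixed = TRUE),
               sub("[NH+]", "[N@@H+]", smi, fixed = TRUE)),
    stringsAsFactors = FALSE
  )
  out
}

#' Expand a ligand library into screening variants
#'
#' Ligands with `amine_config_policy = "enumerate"` contribute both amine
#' invertomers (config `a`/`b`); the rest contribute themselves (config
#' `a`). The `key` column (`id` or `id#b`) identifies frozen embeddings.
#'
#' @param lib a [build_library()] table.
#' @return data.frame with columns `id`, `key`, `config`,
#'   `activity_class`, `smiles`.
#' @export
expand_library <- function(lib) {
  rows <- lapply(seq_len(nrow(lib)), function(i) {
    lg <- lib[i, ]
    if (lg$amine_config_policy == "enumerate") {
      e <- enumerate_amine_configs(lg)
      data.frame(id = e$id, key = paste0(e$id, c("", "#b")),
                 config = e$config, activity_class = e$activity_class,
                 smiles = e$smiles, stringsAsFactors = FALSE)
    } else {
      data.frame(id = lg$id, key = lg$id, config = "a",
                 activity_class = lg$activity_class, smiles = lg$smiles,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Frozen 3D embeddings of the shipped library
#'
#' The upstream `--gen3d` rotor search is time-seeded, so the embeddings
#' that seed the torsion search are generated once and frozen as
#' plain-text coordinate tables. A variant can carry several embeddings
#' (distinct ring puckers; for enantiomer pairs the mirror image of the
#' partner's embedding, which guarantees that mirror-image ligands are
#' sampled symmetrically and discrimination between them is purely
#' steric).
#'
#' @param key ligand key as in [expand_library()].
#' @return list of n x 3 coordinate matrices (empty when no frozen
#'   embedding exists).
#' @keywords internal
frozen_embeddings <- function(key) {
  emb <- .dopaphore_cache("embeddings", {
    dir <- system.file("extdata", package = "dopaphore")
    files <- list.files(dir, pattern = "^embeddings.*\\.tsv$",
                        full.names = TRUE)
    if (!length(files)) NULL
    else do.call(rbind, lapply(files, utils::read.delim,
                               stringsAsFactors = FALSE))
  })
  if (is.null(emb)) return(list())
  rows <- emb[emb$key == key, , drop = FALSE]
  if (!nrow(rows)) return(list())
  lapply(split(rows, rows$emb), function(r)
    as.matrix(r[order(r$atom), c("x", "y", "z")]))
}

.dopaphore_env <- new.env(parent = emptyenv())

.dopaphore_cache <- function(name, value) {
  if (!exists(name, envir = .dopaphore_env)) {
    assign(name, force(value), envir = .dopaphore_env)
  }
  get(name, envir = .dopaphore_env)
}
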