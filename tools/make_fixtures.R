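# Builds the frozen fixtures shipped in inst/extdata:
#   1. embeddings.tsv     -- one 3D embedding per library variant (the
#                            upstream --gen3d rotor search is time-seeded,
#                            so the seed structure is generated once here
#                            and frozen)
#   2. refined_model.json -- feature cluster read off the reference
#                            full-agonist pose + excluded volumes + exclO
#   3. anchor_set.json    -- synthetic receptor-pocket fixture
# Run from the package root with the package installed:
#   Rscript tools/make_fixtures.R [stage]
suppressMessages(library(dopaphore))

args <- commandArgs(trailingOnly = TRUE)
stage <- if (length(args)) args[[1]] else "all"

lib <- expand_library(build_library("inst/extdata/d2_ligands.tsv"))

if (stage %in% c("all", "embeddings")) {
  n_try <- 5          # stochastic gen3d attempts per variant
  rmsd_distinct <- 0.7
  max_per_key <- 4

  topo_of <- list()
  emb_of <- list()
  for (i in seq_len(nrow(lib))) {
    key <- lib$key[i]
    smi <- lib$smiles[i]
    topo <- mol_topology(smi)
    topo_of[[key]] <- topo
    heavy <- which(topo$heavy)
    kept <- list()
    for (t in seq_len(n_try)) {
      xyz <- tryCatch(embed_smiles(smi), error = function(e) NULL)
      if (is.null(xyz)) next
      xyz <- dopaphore:::ob_minimize(topo, list(xyz),
                                     steps = 500)$coords[[1]]
      dup <- FALSE
      for (k in kept)
        if (dopaphore:::aligned_rmsd(xyz[heavy, ], k[heavy, ]) <
            rmsd_distinct) { dup <- TRUE; break }
      if (!dup) kept[[length(kept) + 1L]] <- xyz
      if (length(kept) >= 3) break
    }
    stopifnot(length(kept) >= 1)
    emb_of[[key]] <- kept
    cat(sprintf("embedded %-16s %d distinct\n", key, length(kept)))
  }

  # enantiomer mirror completion: the mirror image of a conformer of A is
  # a valid conformer of its enantiomer B; adding it makes the sampling of
  # mirror pairs exactly symmetric. talipexole/dopamine/SKF38393 have
  # achiral heavy-atom skeletons, so they mirror onto themselves (for
  # talipexole, onto the other amine invertomer).
  pairs <- list(
    c("sumanirole", "(S)-sumanirole"), c("(R,R)-PHNO", "(S,S)-PHNO"),
    c("(3S,9R)-6a", "(3R,9S)-6b"), c("(S)-5-OH-DPAT", "(R)-5-OH-DPAT"),
    c("(R)-7-OH-DPAT", "(S)-7-OH-DPAT"), c("(R)-3-PPP", "(S)-3-PPP"),
    c("A77636", "A77641"), c("A70108", "A70360"), c("DHX", "(-)-DHX"),
    c("talipexole", "talipexole"), c("dopamine", "dopamine"),
    c("SKF38393", "SKF38393"))
  keys_of <- function(id) lib$key[lib$id == id]
  n_sig <- function(topo, xyz) {
    ni <- which(topo$element == "N" & topo$charge > 0)[1]
    nb <- sort(topo$adj[[ni]])[1:4]
    m <- sweep(xyz[nb[2:4], , drop = FALSE], 2, xyz[nb[1], ])
    sign(det(m))
  }
  mirror <- function(xyz) { xyz[, 1] <- -xyz[, 1]; xyz }
  add_emb <- function(key, xyz) {
    topo <- topo_of[[key]]
    heavy <- which(topo$heavy)
    for (k in emb_of[[key]])
      if (dopaphore:::aligned_rmsd(xyz[heavy, ], k[heavy, ]) <
          rmsd_distinct) return(invisible(FALSE))
    if (length(emb_of[[key]]) >= max_per_key) return(invisible(FALSE))
    emb_of[[key]] <<- c(emb_of[[key]], list(xyz))
    invisible(TRUE)
  }
  for (pr in pairs) {
    for (dir in list(c(1, 2), c(2, 1))) {
      ka <- keys_of(pr[dir[1]]); kb <- keys_of(pr[dir[2]])
      if (!identical(topo_of[[ka[1]]]$element,
                     topo_of[[kb[1]]]$element)) {
        cat("skip mirror (atom order differs):", pr[1], pr[2], "\n")
        next
      }
      for (k1 in ka) {
        for (x in emb_of[[k1]]) {
          mx <- mirror(x)
          target <- kb[1]
          if (length(kb) > 1) {
            sig <- n_sig(topo_of[[kb[1]]], mx)
            sigs <- vapply(kb, function(k2)
              n_sig(topo_of[[k2]], emb_of[[k2]][[1]]), numeric(1))
            hitk <- kb[sigs == sig]
            if (length(hitk)) target <- hitk[1]
          }
          add_emb(target, mx)
        }
      }
    }
  }

  rows <- list()
  for (key in lib$key)
    for (e in seq_along(emb_of[[key]])) {
      xyz <- emb_of[[key]][[e]]
      rows[[length(rows) + 1L]] <-
        data.frame(key = key, emb = e, atom = seq_len(nrow(xyz)),
                   x = round(xyz[, 1], 4), y = round(xyz[, 2], 4),
                   z = round(xyz[, 3], 4))
    }
  emb <- do.call(rbind, rows)
  # split into <64 KB files
  unlink(list.files("inst/extdata", pattern = "^embeddings.*\\.tsv$",
                    full.names = TRUE))
  nchunk <- ceiling(sum(nchar(emb$key) + 30) / 60000)
  idx <- cut(seq_len(nrow(emb)), nchunk, labels = FALSE)
  for (ch in unique(idx))
    write.table(emb[idx == ch, ],
                sprintf("inst/extdata/embeddings_%d.tsv", ch),
                sep = "\t", row.names = FALSE, quote = FALSE)
  cat("wrote", nchunk, "embedding files,", nrow(emb), "rows\n")
}

if (stage %in% c("all", "model")) {
  ens <- readRDS("scratch/ens_frozen.rds")
  ref <- ens[["(R)-NPA"]]
  fm <- derive_feature_model(ref$conformers[[1]], ref$topology)
  feature_model <- fm$model
  aset <- derive_anchor_set(feature_model, ens)
  exo <- derive_exclO(feature_model, ens)
  model <- pharm_model(feature_model$features,
                       build_excluded_volumes(aset),
                       exclO = exo,
                       frame_tag = feature_model$frame_tag)
  write_anchors_json(aset, "inst/extdata/anchor_set.json")
  write_model_json(model, "inst/extdata/refined_model.json")
  cat("model:", length(model$excluded_volumes), "EVs, exclO",
      if (is.null(exo)) "absent" else sprintf("r=%.2f", exo$radius), "\n")
}
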