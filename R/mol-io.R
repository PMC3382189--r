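#' @title Molecule topology and 3D structure shuttling
#' @description Small-molecule structures move between the package and the
#'   Open Babel command-line tools as Tripos mol2 (atom typing, aromatic
#'   bonds) and MDL V2000 SDF (coordinates, formal charges, SD tags).
#'   Formatting of the files written here is fully deterministic, which the
#'   reproducibility contract of the conformer generator relies on.
#' @name mol-io
NULL

ob_available <- function() {
  nzchar(Sys.which("obabel")) && nzchar(Sys.which("obenergy"))
}

require_obabel <- function() {
  if (!ob_available())
    stop("Open Babel tools (obabel, obenergy) are required on the PATH")
}

ob_call <- function(args, stdin_file = NULL) {
  out <- suppressWarnings(system2("obabel", args,
    stdout = TRUE, stderr = FALSE,
    stdin = if (is.null(stdin_file)) "" else stdin_file))
  out
}

#' Parse a Tripos mol2 file
#'
#' Reads one or more molecule records, returning atoms (element, Sybyl type,
#' coordinates) and bonds (with aromatic `ar` types preserved).
#'
#' @param path path to a mol2 file.
#' @return list of molecule records, each a list with `atoms` (data.frame:
#'   `eleno`, `element`, `type`, `x`, `y`, `z`) and `bonds` (data.frame:
#'   `a1`, `a2`, `type`).
#' @keywords internal
parse_mol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mol_starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (!length(mol_starts)) stop("no MOLECULE records in ", path)
  bounds <- c(mol_starts, length(lines) + 1L)
  lapply(seq_along(mol_starts), function(i) {
    chunk <- lines[bounds[i]:(bounds[i + 1] - 1L)]
    asec <- grep("^@<TRIPOS>ATOM", chunk)[1]
    bsec <- grep("^@<TRIPOS>BOND", chunk)[1]
    send <- c(grep("^@<TRIPOS>", chunk), length(chunk) + 1L)
    aend <- min(send[send > asec]) - 1L
    bend <- min(send[send > bsec]) - 1L
    atom_lines <- chunk[(asec + 1L):aend]
    atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
    af <- do.call(rbind, strsplit(trimws(atom_lines), "\\s+"))
    atoms <- data.frame(
      eleno = as.integer(af[, 1]),
      element = sub("\\..*$", "", af[, 6]),
      type = af[, 6],
      x = as.numeric(af[, 3]),
      y = as.numeric(af[, 4]),
      z = as.numeric(af[, 5]),
      stringsAsFactors = FALSE
    )
    bond_lines <- chunk[(bsec + 1L):bend]
    bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
    bf <- do.call(rbind, strsplit(trimws(bond_lines), "\\s+"))
    bonds <- data.frame(
      a1 = as.integer(bf[, 2]),
      a2 = as.integer(bf[, 3]),
      type = bf[, 4],
      stringsAsFactors = FALSE
    )
    list(atoms = atoms, bonds = bonds)
  })
}

#' Build a molecule topology from SMILES
#'
#' Converts a SMILES string with Open Babel twice (mol2 for Sybyl atom types
#' and aromatic bond perception, SDF for formal charges); both conversions
#' preserve input atom order, with hydrogens appended after the heavy atoms.
#'
#' @param smiles a SMILES string.
#' @return an object of class `mol_topology`: list with `smiles`, `n_atoms`,
#'   `element`, `sybyl`, `aromatic` (atom is in an aromatic ring), `charge`
#'   (formal), `heavy` (logical), `bonds` data.frame and `adj` adjacency
#'   list.
#' @export
mol_topology <- function(smiles) {
  require_obabel()
  m2 <- tempfile(fileext = ".mol2")
  sd <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(m2, sd)), add = TRUE)
  ob_call(c(shQuote(paste0("-:", smiles)), "-omol2", "-h", "-O", m2))
  ob_call(c(shQuote(paste0("-:", smiles)), "-osdf", "-h", "-O", sd))
  if (!file.exists(m2) || !file.size(m2))
    stop("SMILES could not be interpreted: ", smiles)
  rec <- parse_mol2(m2)[[1]]
  sdf <- read_sdf(sd)[[1]]
  if (nrow(rec$atoms) != nrow(sdf$atoms) ||
      any(rec$atoms$element != sdf$atoms$element))
    stop("atom order mismatch between mol2 and sdf conversions")
  n <- nrow(rec$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(rec$bonds))) {
    i <- rec$bonds$a1[k]; j <- rec$bonds$a2[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  structure(list(
    smiles = smiles,
    n_atoms = n,
    element = rec$atoms$element,
    sybyl = rec$atoms$type,
    aromatic = grepl("\\.ar$", rec$atoms$type),
    charge = sdf$charges,
    heavy = rec$atoms$element != "H",
    bonds = rec$bonds,
    adj = adj
  ), class = "mol_topology")
}

#' @export
print.mol_topology <- function(x, ...) {
  cat("<mol_topology> ", x$smiles, "\n  ",
      sum(x$heavy), " heavy atoms, ", sum(!x$heavy), " hydrogens, ",
      nrow(x$bonds), " bonds, ", sum(x$aromatic), " aromatic atoms\n",
      sep = "")
  invisible(x)
}

#' Write conformations as an MDL V2000 SD file
#'
#' @param topology a [mol_topology()].
#' @param coords_list list of n x 3 coordinate matrices.
#' @param path output path.
#' @param tags optional named list of equal-length vectors written as SD
#'   tags on each record (e.g. `delta_e`, `seed_tag`).
#' @param title record title prefix.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(topology, coords_list, path, tags = NULL,
                      title = "dopaphore") {
  n <- topology$n_atoms
  nb <- nrow(topology$bonds)
  btype <- ifelse(topology$bonds$type %in% c("ar", "am"), 4L,
                  suppressWarnings(as.integer(topology$bonds$type)))
  btype[is.na(btype)] <- 1L
  chg_idx <- which(topology$charge != 0)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (m in seq_along(coords_list)) {
    xyz <- coords_list[[m]]
    lines <- c(
      sprintf("%s_%d", title, m), "  dopaphore", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              xyz[, 1], xyz[, 2], xyz[, 3], topology$element),
      sprintf("%3d%3d%3d  0  0  0  0",
              topology$bonds$a1, topology$bonds$a2, btype)
    )
    if (length(chg_idx)) {
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg_idx)),
        paste0(sprintf("%4d%4d", chg_idx, topology$charge[chg_idx]),
               collapse = "")))
    }
    lines <- c(lines, "M  END")
    for (tg in names(tags)) {
      lines <- c(lines, sprintf(">  <%s>", tg),
                 as.character(tags[[tg]][m]), "")
    }
    lines <- c(lines, "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read an MDL V2000 SD file
#'
#' @param path path to an SDF.
#' @return list of records: `atoms` data.frame (`element`, `x`, `y`, `z`),
#'   `charges` (formal, from M CHG), `bonds` data.frame and `tags` (named
#'   character vector of SD tags).
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- list()
  for (r in seq_along(starts)) {
    chunk <- lines[starts[r]:ends[r]]
    if (length(chunk) < 4L || !any(nzchar(chunk))) next
    counts <- chunk[4]
    na <- as.integer(substr(counts, 1, 3))
    nb <- as.integer(substr(counts, 4, 6))
    al <- chunk[5:(4 + na)]
    atoms <- data.frame(
      element = trimws(substr(al, 32, 34)),
      x = as.numeric(substr(al, 1, 10)),
      y = as.numeric(substr(al, 11, 20)),
      z = as.numeric(substr(al, 21, 30)),
      stringsAsFactors = FALSE
    )
    bl <- chunk[(5 + na):(4 + na + nb)]
    bonds <- data.frame(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      type = substr(bl, 7, 9),
      stringsAsFactors = FALSE
    )
    charges <- integer(na)
    for (cl in grep("^M  CHG", chunk, value = TRUE)) {
      f <- as.integer(strsplit(trimws(substr(cl, 7, nchar(cl))),
                               "\\s+")[[1]])
      nset <- f[1]
      for (k in seq_len(nset)) charges[f[2 * k]] <- f[2 * k + 1]
    }
    tags <- character(0)
    tag_at <- grep("^> *<", chunk)
    for (ti in tag_at) {
      nm <- sub("^> *<([^>]+)>.*$", "\\1", chunk[ti])
      tags[nm] <- if (ti + 1 <= length(chunk)) chunk[ti + 1] else ""
    }
    out[[length(out) + 1L]] <- list(atoms = atoms, charges = charges,
                                    bonds = bonds, tags = tags)
  }
  out
}

#' Embed a SMILES string in 3D with Open Babel
#'
#' Runs `obabel --gen3d` (build + force-field clean-up + rotor search). The
#' upstream rotor search is time-seeded, so embeddings of flexible molecules
#' are not run-to-run reproducible; the shipped library therefore carries
#' frozen embedded coordinates (see [build_library()]), and this function is
#' the fallback for user-supplied ligands.
#'
#' @param smiles SMILES string.
#' @return n x 3 coordinate matrix in the atom order of [mol_topology()].
#' @export
embed_smiles <- function(smiles) {
  require_obabel()
  m2 <- tempfile(fileext = ".mol2")
  on.exit(unlink(m2), add = TRUE)
  ob_call(c(shQuote(paste0("-:", smiles)), "-omol2", "--gen3d", "-h",
            "-O", m2))
  if (!file.exists(m2) || !file.size(m2))
    stop("conformer generation failed: 3D embedding of ", smiles)
  rec <- parse_mol2(m2)[[1]]
  xyz <- as.matrix(rec$atoms[, c("x", "y", "z")])
  if (all(abs(xyz) < 1e-8)) stop("conformer generation failed: ", smiles)
  dimnames(xyz) <- NULL
  xyz
}

#' Minimize conformations with MMFF94 and return strain energies
#'
#' Writes the conformations to SDF, runs `obabel --minimize` (steepest
#' descent, MMFF94) followed by `obenergy`, and returns relaxed coordinates
#' plus absolute MMFF94 energies. Deterministic for identical input.
#'
#' @param topology a [mol_topology()].
#' @param coords_list list of n x 3 matrices.
#' @param steps minimization steps.
#' @return list with `coords` (list of relaxed matrices) and `energy`
#'   (numeric, kcal/mol).
#' @keywords internal
ob_minimize <- function(topology, coords_list, steps = 200,
                        terms = "screened") {
  require_obabel()
  fin <- tempfile(fileext = ".sdf")
  fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_sdf(topology, coords_list, fin)
  ob_call(c(fin, "-O", fout, "--minimize", "--steps",
            as.character(steps), "--ff", "MMFF94"))
  recs <- read_sdf(fout)
  if (length(recs) != length(coords_list))
    stop("minimization dropped records (", length(recs), "/",
         length(coords_list), ")")
  coords <- lapply(recs, function(r) {
    xyz <- as.matrix(r$atoms[, c("x", "y", "z")]); dimnames(xyz) <- NULL; xyz
  })
  list(coords = coords, energy = ob_energies(fout, terms))
}

#' MMFF94 single-point energies of an SD file
#'
#' `terms = "total"` returns the full MMFF94 energy; `terms = "screened"`
#' subtracts the intramolecular electrostatic term. The screened variant
#' is used for strain-energy ranking of protonated ligands: in the gas
#' phase the unscreened charge-aromatic attraction collapses cationic
#' amines onto their own aromatic rings, while in water (the condition the
#' 4 kcal/mol window refers to) those interactions are essentially
#' screened out.
#' @keywords internal
ob_energies <- function(sdf_path, terms = c("screened", "total")) {
  terms <- match.arg(terms)
  out <- suppressWarnings(system2("obenergy",
    c("-ff", "MMFF94", sdf_path), stdout = TRUE, stderr = FALSE))
  num <- function(pattern) {
    ln <- grep(pattern, out, value = TRUE)
    as.numeric(sub(".*=\\s*([-0-9.eE+]+).*$", "\\1", ln))
  }
  tot <- num("^TOTAL ENERGY")
  if (terms == "total") return(tot)
  ele <- num("^\\s*TOTAL ELECTROSTATIC ENERGY")
  if (length(ele) != length(tot))
    stop("obenergy output could not be parsed")
  tot - ele
}
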