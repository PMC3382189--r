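# Shared fixtures: toy models, synthetic matching instances, and a
# session-level cache of library conformer ensembles (conformer
# generation shells out to Open Babel, so ensembles are built once per
# test run and reused).

.ens_env <- new.env(parent = emptyenv())

get_ensemble <- function(key, window = 4, seed = 2012) {
  nm <- paste0(key, "/", window, "/", seed)
  if (!exists(nm, envir = .ens_env)) {
    lib <- expand_library(build_library())
    row <- lib[lib$key == key, ]
    stopifnot(nrow(row) == 1)
    assign(nm, generate_conformers(row, window = window, seed = seed),
           envir = .ens_env)
  }
  get(nm, envir = .ens_env)
}

all_ensembles <- function(window = 4, seed = 2012) {
  lib <- expand_library(build_library())
  lapply(lib$key, get_ensemble, window = window, seed = seed)
}

toy_model <- function(radius = 1.0, with_ser = TRUE, evs = list(),
                      exclO = NULL) {
  feats <- list(
    pharm_feature("AspTM3", "cation", c(4.5, 0.5, 0), radius,
                  essential = TRUE),
    pharm_feature("Aro", "aromatic", c(0, 0, 0), radius,
                  essential = TRUE, direction = c(0, 0, 1),
                  direction_tol = 30)
  )
  if (with_ser)
    feats[[3]] <- pharm_feature("SerTM5",
                                c("donor_proj", "acceptor_proj"),
                                c(-4, 1.5, 0.5), radius,
                                essential = FALSE)
  pharm_model(feats, evs, exclO = exclO, frame_tag = "toy")
}

# a fake conformer carrying pre-built annotation points (the matcher is a
# pure geometry engine; these instances exercise it without a molecule)
fake_conformer <- function(points, heavy_xyz = matrix(c(500, 500, 500),
                                                      1, 3)) {
  n <- nrow(heavy_xyz)
  topo <- structure(list(
    smiles = "<fake>", n_atoms = n, element = rep("C", n),
    sybyl = rep("C.3", n), aromatic = rep(FALSE, n),
    charge = rep(0L, n), heavy = rep(TRUE, n),
    bonds = data.frame(a1 = integer(0), a2 = integer(0),
                       type = character(0)),
    adj = rep(list(integer(0)), n)), class = "mol_topology")
  list(conformer = structure(list(ligand_id = "fake", key = "fake",
                                  xyz = heavy_xyz, delta_e = 0,
                                  seed_tag = "fake", topology = topo),
                             class = "conformer"),
       topology = topo, points = points)
}

rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

rand_rigid <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  R <- rbind(
    c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
      2 * (q[2] * q[4] + q[1] * q[3])),
    c(2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] - q[1] * q[2])),
    c(2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
      1 - 2 * (q[2]^2 + q[3]^2)))
  list(R = R, t = stats::rnorm(3, sd = 4))
}

# random small matching instance: a model with 2-4 features and a point
# cloud derived from a jittered copy of the feature centers plus clutter
rand_instance <- function(seed) {
  set.seed(seed)
  nf <- sample(2:4, 1)
  kinds_pool <- c("cation", "donor_proj", "acceptor_proj")
  feats <- list(
    pharm_feature("F1", "cation", stats::rnorm(3, sd = 3), 1.0,
                  essential = TRUE),
    pharm_feature("F2", "aromatic", stats::rnorm(3, sd = 3), 1.0,
                  essential = TRUE, direction = rand_unit(),
                  direction_tol = 40)
  )
  if (nf >= 3)
    feats[[3]] <- pharm_feature("F3", sample(kinds_pool, 1),
                                stats::rnorm(3, sd = 3), 1.0,
                                essential = sample(c(TRUE, FALSE), 1))
  if (nf >= 4)
    feats[[4]] <- pharm_feature("F4", sample(kinds_pool, 1),
                                stats::rnorm(3, sd = 3), 1.0,
                                essential = FALSE)
  model <- pharm_model(feats, frame_tag = "rand")
  tf <- rand_rigid()
  pts <- list()
  for (f in feats) {
    if (stats::runif(1) < 0.85) {  # usually provide a matching point
      pos <- as.vector(apply_transform(
        f$center + stats::rnorm(3, sd = 0.4), tf))
      dir <- if (!is.null(f$direction)) {
        d0 <- f$direction + stats::rnorm(3, sd = 0.15)
        as.vector(tf$R %*% (d0 / sqrt(sum(d0^2))))
      } else NULL
      pts[[length(pts) + 1L]] <- list(kind = f$kinds[1], pos = pos,
                                      dir = dir, atoms = 1L)
    }
  }
  # clutter points
  for (k in seq_len(sample(0:3, 1)))
    pts[[length(pts) + 1L]] <- list(
      kind = sample(c(kinds_pool, "aromatic"), 1),
      pos = stats::rnorm(3, sd = 5),
      dir = rand_unit(), atoms = 1L)
  if (!length(pts))
    pts[[1]] <- list(kind = "cation", pos = stats::rnorm(3), dir = NULL,
                     atoms = 1L)
  list(model = model, points = pts)
}

# a small synthetic calibration problem with an optimum known by
# exhaustive enumeration: two probe "actives" fit the features, one
# "inactive" (an exact probe plus one heavy atom on the centroid-cation
# axis, so the atom sits at the same place in both admissible poses) is
# blocked by sliding the single excluded volume down in z
toy_calibration_problem <- function() {
  model <- toy_model(radius = 1.0, with_ser = FALSE)
  mk_ens <- function(id, cls, conf) {
    structure(list(ligand_id = id, key = id, activity_class = cls,
                   topology = conf$topology, conformers = list(conf),
                   window = 4,
                   generator_params = list(method = "probe")),
              class = "conformer_ensemble")
  }
  active1 <- make_probe_conformer(model, 0)
  active1$ligand_id <- "act1"
  active2 <- make_probe_conformer(model, 0.2)
  active2$ligand_id <- "act2"
  inactive <- make_probe_conformer(model, 0)
  topo <- inactive$topology
  topo$element <- c(topo$element, "C")
  topo$sybyl <- c(topo$sybyl, "C.3")
  topo$charge <- c(topo$charge, 0L)
  topo$heavy <- c(topo$heavy, TRUE)
  topo$aromatic <- c(topo$aromatic, FALSE)
  topo$adj <- c(topo$adj, list(integer(0)))
  topo$n_atoms <- topo$n_atoms + 1L
  inactive$topology <- topo
  inactive$xyz <- rbind(inactive$xyz, c(2.93, 0.33, 0))
  inactive$ligand_id <- "bad1"
  model$excluded_volumes <- list(
    excluded_volume(c(2.93, 0.33, 2.0), 1.5, "aliphatic_H"))
  list(model = model,
       ensembles = list(mk_ens("act1", "full", active1),
                        mk_ens("act2", "full", active2),
                        mk_ens("bad1", "inactive", inactive)))
}
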