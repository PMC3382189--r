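test_that("fit RMSD closed forms hold", {
  pts <- matrix(rnorm(12), 4, 3)
  expect_equal(fit_rmsd(pts, pts,
                        transform = list(R = diag(3), t = c(0, 0, 0))), 0)
  # one pair displaced by d with the identity transform: d / sqrt(n)
  for (n in c(3, 5, 8)) {
    for (d in c(0.5, 1.7)) {
      centers <- matrix(rnorm(n * 3), n, 3)
      moved <- centers
      moved[1, ] <- moved[1, ] + c(d, 0, 0)
      expect_equal(fit_rmsd(moved, centers,
                            transform = list(R = diag(3),
                                             t = c(0, 0, 0))),
                   d / sqrt(n), tolerance = 1e-12)
    }
  }
  expect_error(fit_rmsd(matrix(rnorm(6), 2, 3),
                        matrix(rnorm(6), 2, 3)),
               "underdetermined")
})

test_that("least-squares superposition matches the quaternion oracle", {
  set.seed(7)
  for (rep in 1:25) {
    x <- matrix(rnorm(15, sd = 3), 5, 3)
    tf <- rand_rigid()
    y <- apply_transform(x, tf) + matrix(rnorm(15, sd = 0.2), 5, 3)
    a <- kabsch(x, y)
    b <- horn_superpose(x, y)
    expect_equal(a$rmsd, b$rmsd, tolerance = 1e-8)
    expect_equal(fit_rmsd(x, y), b$rmsd, tolerance = 1e-8)
  }
})

test_that("an exact probe scores a zero-RMSD hit", {
  model <- toy_model()
  probe <- make_probe_conformer(model, 0)
  hit <- match_conformer(probe, model)
  expect_false(is.null(hit))
  expect_lt(hit$fit_rmsd, 1e-8)
  expect_equal(hit$n_matched, 3L)
})

test_that("bounded jitter bounds the fit RMSD", {
  model <- toy_model()
  probe <- make_probe_conformer(model, 0.3)
  hit <- match_conformer(probe, model)
  expect_false(is.null(hit))
  expect_lte(hit$fit_rmsd, 0.3 + 1e-9)
})

test_that("displacing one essential point beyond its radius kills the hit", {
  model <- toy_model()
  probe <- make_probe_conformer(model, 1.0 + 1.0, jitter_only = 1)
  expect_null(match_conformer(probe, model))
})

test_that("each decoy violates exactly its targeted constraint", {
  # all features essential: the probe pose is then rigidly pinned and a
  # perturbation cannot be absorbed by choosing another valid pose
  ev <- list(excluded_volume(c(2, 3.2, 1.2), 1.5, "aliphatic_H"))
  model <- toy_model(evs = ev, exclO = list(center = c(-2, -3, 1),
                                            radius = 1.5))
  model$features[[3]]$essential <- TRUE
  expect_false(is.null(match_conformer(make_probe_conformer(model, 0),
                                       model)))
  for (v in c("radius", "direction", "excluded_volume", "exclO",
              "missing_essential")) {
    decoy <- make_decoy_conformer(model, v)
    expect_null(match_conformer(decoy, model), label = v)
  }
  # an atom exactly at an excluded-volume center is a clash by
  # construction
  d <- make_decoy_conformer(model, "excluded_volume")
  expect_equal(d$xyz[nrow(d$xyz), ], ev[[1]]$center)
})

test_that("matcher agrees with the exhaustive enumeration oracle", {
  n_ok <- 0
  for (seed in 1:200) {
    inst <- rand_instance(seed)
    fk <- fake_conformer(inst$points)
    hit <- match_conformer(fk$conformer, inst$model,
                           points = inst$points)
    oracle <- naive_match(inst$points, inst$model)
    if (is.null(oracle)) {
      expect_null(hit, label = paste("seed", seed))
    } else {
      expect_false(is.null(hit), label = paste("seed", seed))
      expect_equal(hit$fit_rmsd, oracle, tolerance = 1e-6,
                   label = paste("seed", seed))
      n_ok <- n_ok + 1
    }
  }
  expect_gt(n_ok, 40)  # the instance generator must exercise real hits
})

test_that("matching is invariant under rigid motion of the conformer", {
  model <- toy_model()
  set.seed(11)
  for (jit in c(0, 0.25)) {
    probe <- make_probe_conformer(model, jit)
    h0 <- match_conformer(probe, model)
    for (rep in 1:5) {
      tf <- rand_rigid()
      p2 <- probe
      p2$xyz <- apply_transform(probe$xyz, tf)
      h2 <- match_conformer(p2, model)
      expect_false(is.null(h2))
      expect_equal(h2$fit_rmsd, h0$fit_rmsd, tolerance = 1e-6)
    }
  }
})

test_that("relaxing constraints never converts a hit into a miss", {
  set.seed(23)
  checked <- 0
  for (seed in 201:260) {
    inst <- rand_instance(seed)
    ev <- list(excluded_volume(rnorm(3, sd = 4), 1.5, "aliphatic_H"))
    model <- inst$model
    model$excluded_volumes <- ev
    fk <- fake_conformer(inst$points,
                         heavy_xyz = matrix(rnorm(9, sd = 4), 3, 3))
    hit <- match_conformer(fk$conformer, model, points = inst$points)
    if (is.null(hit)) next
    checked <- checked + 1
    # enlarge every feature radius
    m2 <- model
    m2$features <- lapply(m2$features, function(f) {
      f$radius <- f$radius * 1.5; f
    })
    expect_false(is.null(match_conformer(fk$conformer, m2,
                                         points = inst$points)))
    # delete the excluded volume
    m3 <- model
    m3$excluded_volumes <- list()
    expect_false(is.null(match_conformer(fk$conformer, m3,
                                         points = inst$points)))
    # demote every optional-able feature to optional (keep one essential)
    m4 <- model
    for (k in seq_along(m4$features)[-1])
      m4$features[[k]]$essential <- FALSE
    expect_false(is.null(match_conformer(fk$conformer, m4,
                                         points = inst$points)))
  }
  expect_gt(checked, 10)
})

test_that("matching is deterministic including tie-breaks", {
  for (seed in c(3, 17, 91)) {
    inst <- rand_instance(seed)
    fk <- fake_conformer(inst$points)
    h1 <- match_conformer(fk$conformer, inst$model, points = inst$points)
    h2 <- match_conformer(fk$conformer, inst$model, points = inst$points)
    expect_identical(h1, h2)
  }
})

test_that("screening tallies hits per ligand with #h <= #c", {
  ens <- lapply(c("dopamine", "(S)-DPAT", "doxanthrine"), get_ensemble)
  model <- refined_model()
  rep <- screen(ens, model)
  expect_true(all(rep$rows$n_hit <= rep$rows$n_conf))
  expect_equal(sum(rep$summary$ligands_hit),
               sum(rep$rows$n_hit > 0))
  # an unsatisfiable model yields no hits at all
  far <- toy_model()
  far$features[[1]]$center <- c(500, 0, 0)
  far$features[[1]]$radius <- 1e-6
  rep0 <- screen(ens, far)
  expect_true(all(rep0$rows$n_hit == 0))
})

test_that("doxanthrine is rejected by the shipped refined model", {
  rep <- screen(list(get_ensemble("doxanthrine")), refined_model())
  expect_equal(rep$rows$n_hit, 0L)
})

test_that("model ablations behave monotonically", {
  model <- refined_model()
  noev <- ablate(model, "drop_excluded_volumes")
  expect_equal(length(noev$excluded_volumes), 0L)
  expect_false(is.null(noev$exclO))  # exclO is a separate identity
  ess <- ablate(model, "tm5_essential")
  idx <- which(vapply(ess$features, `[[`, character(1), "name") ==
                 "SerTM5")
  expect_true(ess$features[[idx]]$essential)
  expect_error(ablate(model, "bogus"))
  ens <- lapply(c("dopamine", "(S)-DPAT", "doxanthrine", "quinpirole"),
                get_ensemble)
  h0 <- screen(ens, model)$rows
  h1 <- screen(ens, noev)$rows
  h2 <- screen(ens, ablate(noev, "tm5_essential"))$rows
  expect_true(all(h1$n_hit >= h0$n_hit))          # fewer constraints
  expect_true(all(h2$n_hit <= h1$n_hit))          # more constraints
  # the donor-free full agonist cannot satisfy an essential TM5 feature
  expect_equal(h2$n_hit[h2$id == "(S)-DPAT"], 0L)
})

test_that("model JSON round-trips", {
  model <- refined_model()
  f <- tempfile(fileext = ".json")
  write_model_json(model, f)
  back <- read_model_json(f)
  expect_equal(length(back$features), length(model$features))
  for (k in seq_along(model$features)) {
    expect_equal(back$features[[k]]$center, model$features[[k]]$center)
    expect_equal(back$features[[k]]$radius, model$features[[k]]$radius)
    expect_equal(back$features[[k]]$essential,
                 model$features[[k]]$essential)
  }
  expect_equal(length(back$excluded_volumes),
               length(model$excluded_volumes))
  expect_equal(back$exclO, model$exclO)
})
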