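test_that("dopamine perceives the catechol-amine point set", {
  ens <- get_ensemble("dopamine")
  pts <- perceive(ens$conformers[[1]], ens$topology)
  counts <- annotation_counts(pts)
  expect_equal(unname(counts["cation"]), 1L)
  expect_equal(unname(counts["aromatic"]), 1L)
  expect_equal(unname(counts["donor_proj"]), 4L)   # 2 per aryl hydroxyl
  expect_equal(unname(counts["oxygen_atom"]), 2L)
})

test_that("a bare aromatic ring yields one aromatic point and nothing else", {
  ens <- generate_conformers(list(id = "benzene", smiles = "c1ccccc1"))
  pts <- perceive(ens$conformers[[1]], ens$topology)
  expect_equal(length(pts), 1L)
  expect_equal(pts[[1]]$kind, "aromatic")
  expect_equal(sqrt(sum(pts[[1]]$dir^2)), 1, tolerance = 1e-8)
})

test_that("the hydroxyl-free agonist has no hydrogen-bond projections", {
  ens <- get_ensemble("(S)-DPAT")
  pts <- perceive(ens$conformers[[1]], ens$topology)
  kinds <- vapply(pts, `[[`, character(1), "kind")
  expect_true("cation" %in% kinds)
  expect_true("aromatic" %in% kinds)
  expect_false(any(kinds %in% c("donor_proj", "acceptor_proj",
                                "oxygen_atom")))
})

test_that("aryl-hydroxyl projections obey the in-plane 120-degree rule", {
  for (dist in c(2.8, 2.5)) {
    # synthetic phenol-like geometry: ring in the z = 0 plane
    center <- c(0, 0, 0)
    normal <- c(0, 0, 1)
    c_ar <- c(1.4, 0, 0)
    o <- c(2.76, 0, 0)
    pp <- project_aryl_donor(o, c_ar, normal, center, dist = dist)
    v1 <- pp[1, ] - o; v2 <- pp[2, ] - o
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    expect_equal(ang, 120, tolerance = 1e-6)
    expect_lt(max(abs(pp[, 3])), 1e-6)          # in plane
    expect_equal(sqrt(sum(v1^2)), dist, tolerance = 1e-8)
    expect_equal(sqrt(sum(v2^2)), dist, tolerance = 1e-8)
    # independent construction: rotate the C->O extension by +/-60 in 2D
    dir0 <- (o - c_ar) / sqrt(sum((o - c_ar)^2))
    for (s in c(60, -60)) {
      th <- s * pi / 180
      rot2 <- c(cos(th) * dir0[1] - sin(th) * dir0[2],
                sin(th) * dir0[1] + cos(th) * dir0[2], 0)
      expected <- o + rot2 * dist
      expect_true(min(sqrt(rowSums(sweep(pp, 2, expected)^2))) < 1e-6)
    }
  }
  # real molecule: every aryl donor projection lies in its ring plane
  ens <- get_ensemble("dopamine")
  pts <- perceive(ens$conformers[[1]], ens$topology)
  aro <- pts[[which(vapply(pts, `[[`, character(1), "kind") ==
                      "aromatic")]]
  for (p in pts) {
    if (p$kind != "donor_proj") next
    expect_lt(abs(sum((p$pos - aro$pos) * aro$dir)), 1e-6)
  }
})

test_that("perception is equivariant under rigid motion", {
  ens <- get_ensemble("dopamine")
  cf <- ens$conformers[[1]]
  pts <- perceive(cf, ens$topology)
  set.seed(42)
  for (rep in 1:5) {
    tf <- rand_rigid()
    cf2 <- cf
    cf2$xyz <- apply_transform(cf$xyz, tf)
    pts2 <- perceive(cf2, ens$topology)
    expect_equal(length(pts2), length(pts))
    # compare as kind-wise point sets: the refitted ring normal's sign
    # is arbitrary, which can swap the order of the paired projections
    kinds2 <- vapply(pts2, `[[`, character(1), "kind")
    for (i in seq_along(pts)) {
      target <- as.vector(apply_transform(pts[[i]]$pos, tf))
      same <- which(kinds2 == pts[[i]]$kind)
      dmin <- min(vapply(pts2[same], function(p)
        sqrt(sum((p$pos - target)^2)), numeric(1)))
      expect_lt(dmin, 1e-6)
    }
  }
})

test_that("annotation counts depend on topology, not conformation", {
  ens <- get_ensemble("quinpirole")
  ref <- annotation_counts(perceive(ens$conformers[[1]], ens$topology))
  for (cf in ens$conformers)
    expect_equal(annotation_counts(perceive(cf, ens$topology)), ref)
})

test_that("annotation JSON dump is well-formed", {
  ens <- get_ensemble("dopamine")
  js <- annotations_json(perceive(ens$conformers[[1]], ens$topology))
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(length(parsed), 12L)  # incl. paired acceptor projections
  expect_true(all(vapply(parsed, function(p)
    length(p$xyz) == 3, logical(1))))
})
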