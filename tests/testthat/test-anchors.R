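test_that("excluded-volume radii presets are the published values", {
  b <- ev_radii("bondi")
  expect_equal(unname(b[c("aliphatic_H", "aromatic_H")]), c(1.2, 1.0))
  expect_equal(unname(b["polar_H"]), 1.0)  # benzene value for O-H/N-H
  f <- ev_radii("final")
  expect_equal(unname(f[c("aliphatic_H", "aromatic_H",
                          "ring_centroid")]), c(2.0, 1.8, 2.5))
})

test_that("excluded volumes are built one per site with tagged radii", {
  hs <- data.frame(x = c(0, 1, 2), y = 0, z = 0,
                   tag = c("aliphatic_H", "aromatic_H", "polar_H"))
  rc <- data.frame(x = 9, y = 9, z = 9)
  anch <- data.frame(name = "Asp114:OD", element = "O",
                     role = "acceptor", x = 0, y = 0, z = 5)
  aset <- anchor_set(anch, hs, rc)
  evs <- build_excluded_volumes(aset)
  expect_equal(length(evs), nrow(hs) + nrow(rc))
  expect_equal(vapply(evs, `[[`, numeric(1), "radius"),
               c(2.0, 1.8, 1.8, 2.5))
  evb <- build_excluded_volumes(aset, ev_radii("bondi"))
  expect_equal(vapply(evb, `[[`, numeric(1), "radius"),
               c(1.2, 1.0, 1.0, 2.5))
  hs_bad <- hs; hs_bad$tag[1] <- "mystery_H"
  expect_error(anchor_set(anch, hs_bad), "unknown hydrogen-site tag")
})

test_that("hydrogen-bond windows are closed intervals with a borderline band", {
  # boundary distances at exactly 180 degrees (collinear)
  for (d in c(2.4, 3.8)) {
    r <- hbond_geometry(c(0, 0, 0), c(1, 0, 0), c(d, 0, 0))
    expect_equal(r$d, d)
    expect_equal(r$angle, 180)
    expect_equal(r$verdict, "ok")
  }
  # collinear 2.8 gives exactly 180
  r <- hbond_geometry(c(0, 0, 0), c(0.98, 0, 0), c(2.8, 0, 0))
  expect_equal(r$angle, 180)
  expect_equal(r$verdict, "ok")
  # boundary angle 140 inside the window
  expect_equal(dopaphore:::hbond_verdict(3.0, 140)$verdict, "ok")
  expect_equal(dopaphore:::hbond_verdict(3.0, 220)$verdict, "ok")
  # the published in-window example: 2.9 A at 157 degrees
  expect_equal(dopaphore:::hbond_verdict(2.9, 157)$verdict, "ok")
  # just-outside contacts are flagged, not failed: 4.1 A at 151 degrees
  expect_equal(dopaphore:::hbond_verdict(4.1, 151)$verdict, "borderline")
  expect_equal(dopaphore:::hbond_verdict(3.0, 128)$verdict, "borderline")
  # clear failures
  expect_equal(dopaphore:::hbond_verdict(4.2, 151)$verdict, "fail")
  expect_equal(dopaphore:::hbond_verdict(3.0, 120)$verdict, "fail")
  expect_error(hbond_geometry(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)),
               "degenerate")
})

test_that("hbond geometry matches an independent vector oracle", {
  set.seed(5)
  for (rep in 1:50) {
    d0 <- rnorm(3, sd = 3); h <- rnorm(3, sd = 3); a <- rnorm(3, sd = 3)
    if (min(dist(rbind(d0, h, a))) < 1e-3) next
    r <- hbond_geometry(d0, h, a)
    # oracle: law-of-cosines angle and explicit norm
    dd <- sqrt(sum((a - d0)^2))
    u <- d0 - h; v <- a - h
    ang <- atan2(sqrt(sum((c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1]))^2)),
                 sum(u * v)) * 180 / pi
    expect_equal(r$d, dd, tolerance = 1e-9)
    expect_equal(r$angle, ang, tolerance = 1e-9)
  }
})

test_that("hbond geometry is rigid-motion invariant; d symmetric, angle not", {
  set.seed(9)
  d0 <- c(0, 0, 0); h <- c(0.8, 0.4, 0); a <- c(2.8, 1.2, 0.5)
  r0 <- hbond_geometry(d0, h, a)
  for (rep in 1:5) {
    tf <- rand_rigid()
    r1 <- hbond_geometry(as.vector(apply_transform(d0, tf)),
                         as.vector(apply_transform(h, tf)),
                         as.vector(apply_transform(a, tf)))
    expect_equal(r1$d, r0$d, tolerance = 1e-9)
    expect_equal(r1$angle, r0$angle, tolerance = 1e-9)
  }
  # the heavy-atom distance does not depend on which side donates
  rs <- hbond_geometry(a, h, d0)
  expect_equal(rs$d, r0$d, tolerance = 1e-12)
  # but reversing the roles means measuring at the other side's
  # hydrogen, which changes the angle
  h_other <- a + c(-0.9, 0.3, 0.1)
  rrev <- hbond_geometry(a, h_other, d0)
  expect_false(isTRUE(all.equal(rrev$angle, r0$angle)))
})

test_that("evaluate_hit reports an ideal constructed hydrogen bond as ok", {
  model <- toy_model()
  probe <- make_probe_conformer(model, 0)
  hit <- match_conformer(probe, model)
  # probe hydroxyl: O at 2.8 A from the SerTM5 point, O-H collinear
  oi <- which(probe$topology$element == "O")
  ser <- model$features[[3]]$center
  anch <- data.frame(name = "Ser193:OG", element = "O", role = "both",
                     x = ser[1], y = ser[2], z = ser[3])
  rec <- evaluate_hit(hit, anchor_set(anch), probe$topology)
  ok <- rec[rec$verdict == "ok", ]
  expect_gte(nrow(ok), 1)
  expect_equal(ok$d[1], 2.8, tolerance = 1e-6)
  expect_equal(ok$angle[1], 180, tolerance = 1e-4)
})

test_that("a donor-free ligand yields no heteroatom hydrogen-bond records", {
  ens <- get_ensemble("(S)-DPAT")
  rep <- screen(list(ens), refined_model(),
                anchor_set = shipped_anchor_set())
  hb <- rep$hbonds[["(S)-DPAT"]]
  if (!is.null(hb) && nrow(hb)) {
    # only the charged-amine group can appear; no hydroxyl rows exist
    expect_true(all(hb$group %in% c("N", "N+")))
  }
  succeed()
})

test_that("anchor sets round-trip through JSON", {
  aset <- shipped_anchor_set()
  f <- tempfile(fileext = ".json")
  write_anchors_json(aset, f)
  back <- read_anchors_json(f)
  expect_equal(back$anchors, aset$anchors)
  expect_equal(back$hydrogen_sites, aset$hydrogen_sites)
  expect_equal(back$ring_centroids, aset$ring_centroids)
  expect_equal(back$frame_tag, aset$frame_tag)
})
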