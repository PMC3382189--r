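test_that("the discrimination objective is the weighted hit balance", {
  mk <- function(f, p, i) {
    data.frame(
      activity_class = rep(c("full", "partial", "inactive"),
                           c(13, 5, 12)),
      n_hit = c(rep(1, f), rep(0, 13 - f), rep(1, p), rep(0, 5 - p),
                rep(1, i), rep(0, 12 - i)))
  }
  expect_equal(objective(mk(13, 5, 0)), 15.5)
  expect_equal(objective(mk(0, 0, 0)), 0)
  # the published optimum pattern: 11 full + 4 partial - 1 inactive
  expect_equal(objective(mk(11, 4, 1)), 12)
  rows <- mk(3, 1, 1); rows$n_hit[1] <- NA
  expect_error(objective(rows), "incomplete")
})

test_that("calibration recovers the enumerable optimum of a toy problem", {
  toy <- toy_calibration_problem()
  # exhaustive enumeration over the z-translation of the excluded-volume
  # shell (the only discriminating degree of freedom): moving the sphere
  # down by ~1.6 engulfs the inactive's extra atom and no probe atom
  cands <- precompute_candidates(toy$ensembles, toy$model)
  best_enum <- -Inf
  for (tz in seq(-2, 2, by = 0.1)) {
    th <- list(tr = c(0, 0, tz), rot = c(0, 0, 0),
               feature_r = c(1, 1), ev_delta = c(0, 0, 0, 0),
               exclO_r = 1.5)
    s <- dopaphore:::eval_theta(cands, toy$model$features,
      list(centers = matrix(toy$model$excluded_volumes[[1]]$center, 1, 3),
           radius = 1.5, tag_idx = 1L),
      NULL, th, c(full = 1, partial = 0.5, inactive = 1))
    best_enum <- max(best_enum, s)
  }
  expect_equal(best_enum, 2)  # both actives kept, the inactive blocked
  cal <- calibrate(toy$model, toy$ensembles,
                   config = calibration_config(seed = 4, budget = 1500),
                   candidates = cands)
  expect_equal(cal$objective, best_enum)
  expect_gte(cal$objective, cal$objective0)
})

test_that("the incumbent objective is monotone and seed-reproducible", {
  toy <- toy_calibration_problem()
  cands <- precompute_candidates(toy$ensembles, toy$model)
  c1 <- calibrate(toy$model, toy$ensembles,
                  config = calibration_config(seed = 11, budget = 300),
                  candidates = cands)
  expect_true(all(diff(c1$trace$incumbent) >= 0))
  c2 <- calibrate(toy$model, toy$ensembles,
                  config = calibration_config(seed = 11, budget = 300),
                  candidates = cands)
  expect_identical(c1$trace, c2$trace)
  expect_identical(c1$theta, c2$theta)
  c3 <- calibrate(toy$model, toy$ensembles,
                  config = calibration_config(seed = 12, budget = 300),
                  candidates = cands)
  expect_true(all(diff(c3$trace$incumbent) >= 0))
})

test_that("calibrated-model evaluation agrees with a full re-screen", {
  toy <- toy_calibration_problem()
  cal <- calibrate(toy$model, toy$ensembles,
                   config = calibration_config(seed = 4, budget = 300))
  rep <- screen(toy$ensembles, cal$model)
  agree <- merge(rep$rows[, c("id", "n_hit")],
                 cal$per_ligand[, c("id", "hit")])
  expect_equal(agree$n_hit > 0, agree$hit)
})
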