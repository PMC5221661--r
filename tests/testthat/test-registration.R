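test_that("landmark_fit: identity, pure translation, rotation about centroid", {
  fr <- image_frame(100, 100, 1)
  xy <- cbind(c(20, 40, 60, 50, 30), c(30, 20, 40, 60, 55))
  fixed <- point_pattern(xy[, 1], xy[, 2], "canal", "left", fr)
  pairs <- cbind(1:5, 1:5)

  f0 <- landmark_fit(fixed, fixed, pairs)
  expect_equal(f0$transform$theta, 0, tolerance = 1e-12)
  expect_equal(c(f0$transform$tx, f0$transform$ty), c(0, 0), tolerance = 1e-12)
  expect_equal(f0$rms, 0, tolerance = 1e-12)

  mv <- point_pattern(xy[, 1] - 5, xy[, 2] + 3, "canal", "left", fr)
  ft <- landmark_fit(mv, fixed, pairs)
  expect_equal(ft$transform$theta, 0, tolerance = 1e-9)
  expect_equal(c(ft$transform$tx, ft$transform$ty), c(5, -3), tolerance = 1e-9)

  # forward transform: rotate 30 deg about the centroid then translate (4, 7)
  ctr <- colMeans(xy)
  fwd <- neuromastsym:::about_center(
    rigid_transform(FALSE, 30 * pi / 180, 4, 7), ctr)
  moved <- neuromastsym:::transform_xy(xy, fwd)
  mv2 <- point_pattern(moved[, 1], moved[, 2], "canal", "left", fr)
  # recover the inverse mapping mv2 -> fixed
  fb <- landmark_fit(mv2, fixed, pairs)
  inv <- inverse_transform(fwd)
  expect_equal(fb$transform$theta, inv$theta, tolerance = 1e-9)
  expect_equal(c(fb$transform$tx, fb$transform$ty), c(inv$tx, inv$ty),
               tolerance = 1e-9)
  expect_lt(fb$rms, 1e-9)

  expect_error(landmark_fit(mv, fixed, pairs[1, , drop = FALSE]), "at least 2")
})

test_that("landmark_fit matches the exhaustive theta-grid minimizer on noisy problems", {
  set.seed(202)
  fr <- image_frame(200, 200, 1)
  for (rep in 1:20) {
    base <- cbind(runif(4, 40, 160), runif(4, 40, 160))
    # rotate about the landmark centroid so the frame clamp below never binds
    t_true <- neuromastsym:::about_center(
      rigid_transform(FALSE, runif(1, -pi, pi),
                      runif(1, -10, 10), runif(1, -10, 10)),
      colMeans(base))
    noisy <- neuromastsym:::transform_xy(base, t_true) +
      matrix(rnorm(8, 0, 0.5), 4, 2)
    noisy <- pmin(pmax(noisy, 0), 200)
    mv <- point_pattern(base[, 1], base[, 2], "canal", "left", fr)
    fx <- point_pattern(noisy[, 1], noisy[, 2], "canal", "left", fr)
    fit <- landmark_fit(mv, fx, cbind(1:4, 1:4))
    orc <- oracle_landmark_theta(base, noisy, step = 0.001)
    dth <- abs(fit$transform$theta - orc$theta)
    dth <- min(dth, 2 * pi - dth)
    expect_lt(dth, 0.001)
  }
})

test_that("landmark_fit never introduces a reflection and handles scale", {
  set.seed(55)
  fr <- image_frame(200, 200, 1)
  base <- cbind(runif(5, 40, 160), runif(5, 40, 160))
  for (rep in 1:20) {
    noisy <- pmin(pmax(base + matrix(rnorm(10, 0, 6), 5, 2), 0), 200)
    fit <- landmark_fit(point_pattern(base[, 1], base[, 2], "canal", "left", fr),
                        point_pattern(noisy[, 1], noisy[, 2], "canal", "left", fr),
                        cbind(1:5, 1:5), allow_scale = TRUE)
    expect_false(fit$transform$reflect)
    expect_gt(fit$transform$scale, 0)
    A <- neuromastsym:::transform_matrix(fit$transform)
    expect_gt(A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1], 0)  # det > 0
  }

  # similarity recovery: known scale round-trips
  sc <- neuromastsym:::transform_xy(base, rigid_transform(FALSE, 0.4, 3, -2, 1.2))
  fit2 <- landmark_fit(point_pattern(base[, 1], base[, 2], "canal", "left", fr),
                       point_pattern(sc[, 1], sc[, 2], "canal", "left", fr),
                       cbind(1:5, 1:5), allow_scale = TRUE)
  expect_equal(fit2$transform$scale, 1.2, tolerance = 1e-9)
  expect_equal(fit2$transform$theta, 0.4, tolerance = 1e-9)
})

test_that("refine_by_score recovers the perfect-overlap optimum and never worsens", {
  pair <- fixture_mirror_pair()
  left <- pair$left
  moving <- reflect_pattern(pair$right, "vertical_line")
  lsup <- subset_type(left, "superficial")
  msup <- subset_type(moving, "superficial")
  canvas <- canvas_for_patterns(list(lsup), pad = 10)
  scorer <- neuromastsym:::make_overlap_scorer(
    neuromastsym:::pattern_xy(lsup), neuromastsym:::pattern_xy(msup),
    canvas, dot_radius = 3)

  perfect <- scorer(rigid_transform())
  expect_equal(perfect, 1.0, tolerance = 1e-12)

  ctr <- colMeans(neuromastsym:::pattern_xy(msup))
  init <- neuromastsym:::about_center(
    rigid_transform(FALSE, 3 * pi / 180, 2, 2), ctr)
  ref <- refine_by_score(moving, left, init, scorer)
  expect_equal(ref$score, perfect, tolerance = 1e-9)
  expect_gte(ref$score, scorer(init))

  # init already optimal: stays at the optimum
  ref2 <- refine_by_score(moving, left, rigid_transform(), scorer)
  expect_equal(ref2$score, perfect, tolerance = 1e-12)

  # monotone acceptance on an arbitrary (bad) start within the trust region
  bad <- neuromastsym:::about_center(
    rigid_transform(FALSE, -4 * pi / 180, -3, 1), ctr)
  ref3 <- refine_by_score(moving, left, bad, scorer)
  expect_gte(ref3$score, scorer(bad))

  expect_error(refine_by_score(moving, left, init, function(t) NaN),
               "non-finite")
})

test_that("triplicate_align: perfect mirror gives R = 1 in every trial", {
  pair <- fixture_mirror_pair()
  trials <- triplicate_align(pair$left, pair$right,
                             cfg = registration_config(seed = 9))
  expect_length(trials, 3)
  for (tr in trials) expect_equal(tr$r, 1.0, tolerance = 1e-9)
})

test_that("triplicate_align is deterministic: same seed bit-identical, zero jitter degenerate", {
  p <- generate_bilateral_pattern(n_superficial = 12, n_canal = 4,
                                  params = asymmetry_params(sigma = 3, seed = 77))
  a <- triplicate_align(p$left, p$right, cfg = registration_config(seed = 5))
  b <- triplicate_align(p$left, p$right, cfg = registration_config(seed = 5))
  expect_identical(a, b)

  z <- triplicate_align(p$left, p$right,
                        cfg = registration_config(jitter_sigma = 0, seed = 5))
  expect_identical(z[[1]], z[[2]])
  expect_identical(z[[2]], z[[3]])

  # trial R variance shrinks as jitter shrinks
  v_for <- function(js) {
    tr <- triplicate_align(p$left, p$right,
                           cfg = registration_config(jitter_sigma = js,
                                                     n_trials = 5, seed = 5))
    var(vapply(tr, `[[`, numeric(1), "r"))
  }
  expect_lte(v_for(0), v_for(4) + 1e-12)
  expect_equal(v_for(0), 0)
})

test_that("triplicate_align errors name the empty side", {
  fr <- image_frame(50, 50, 1)
  canal_only <- point_pattern(c(10, 40), c(10, 40), "canal", "left", fr)
  ok <- fixture_pattern("right")
  expect_error(triplicate_align(canal_only, ok), "left")
  ok_l <- fixture_pattern("left")
  canal_only_r <- point_pattern(c(10, 40), c(10, 40), "canal", "right", fr)
  expect_error(triplicate_align(ok_l, canal_only_r), "right")
})

test_that("auto canal pairing matches explicit rank-order correspondence", {
  pair <- fixture_mirror_pair()
  left <- pair$left
  # explicit pairs: canal indices sorted along x on each side
  li <- which(left$type == "canal")
  moving <- reflect_pattern(pair$right, "vertical_line")
  ri <- which(pair$right$type == "canal")
  explicit <- cbind(left = li[order(left$x[li])],
                    right = ri[order(moving$x[ri])])
  a <- triplicate_align(pair$left, pair$right, explicit,
                        cfg = registration_config(seed = 4))
  b <- triplicate_align(pair$left, pair$right, NULL,
                        cfg = registration_config(seed = 4))
  expect_equal(vapply(a, `[[`, numeric(1), "r"),
               vapply(b, `[[`, numeric(1), "r"))
})
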