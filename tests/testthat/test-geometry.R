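test_that("regular polygons place vertices on the circumscribed circle", {
  sq <- env_polygon(4, 1, c(0, 0))
  expect_equal(sq$rings[[1]],
               cbind(c(1, 0, -1, 0), c(0, 1, 0, -1)), tolerance = 1e-12)

  tri <- env_polygon(3, 1, c(0, 0))
  ang <- atan2(tri$rings[[1]][, 2], tri$rings[[1]][, 1]) %% (2 * pi)
  expect_equal(sort(ang), c(0, 2 * pi / 3, 4 * pi / 3), tolerance = 1e-12)

  hex <- env_polygon(6, 2, c(1, 1))
  d <- sqrt(rowSums(sweep(hex$rings[[1]], 2, c(1, 1))^2))
  expect_equal(d, rep(2, 6), tolerance = 1e-12)

  expect_error(env_polygon(2, 1), class = "gridscape_error_invalid_shape")
})

test_that("connected arenas obey area additivity and containment", {
  for (d in c(0, 0.5, 1)) {
    env <- env_connected("square", "square", 1.8, 0.8, d)
    expect_equal(arena_area(env), 2 * 1.8^2 + d * 0.8, tolerance = 0.01)
    expect_equal(unname(env$bbox["xmax"] - env$bbox["xmin"]), 2 * 1.8 + d)
  }
  env <- env_connected("square", "square", 1.8, 0.8, 1)
  # mid-corridor point is inside, wall point is not
  expect_true(arena_contains(env, 1.8 + 0.5, 0.9))
  expect_false(arena_contains(env, 1.8 + 0.5, 0.2))
  expect_error(env_connected("square", "square", 1.8, 2, 0.5),
               class = "gridscape_error_invalid_shape")

  # circle-circle: corridor endpoints lie on both circles and the
  # boundary closes; verify with a dense point-in-polygon sample
  cc <- env_connected("circle", "circle", 1.8, 0.8, 0.5)
  gx <- seq(cc$bbox["xmin"] + 0.01, cc$bbox["xmax"] - 0.01, length.out = 60)
  gy <- seq(cc$bbox["ymin"] + 0.01, cc$bbox["ymax"] - 0.01, length.out = 30)
  pts <- expand.grid(x = gx, y = gy)
  inside <- arena_contains(cc, pts$x, pts$y)
  in_rooms <- (sqrt((pts$x - 0.9)^2 + (pts$y - 0.9)^2) < 0.9 - 1e-3) |
    (sqrt((pts$x - (1.8 + 0.5 + 0.9))^2 + (pts$y - 0.9)^2) < 0.9 - 1e-3)
  expect_true(all(inside[in_rooms]))
  in_corridor <- pts$x > 1.8 & pts$x < 2.3 & abs(pts$y - 0.9) < 0.4 - 1e-3
  expect_true(all(inside[in_corridor]))
})

test_that("concave arenas degenerate correctly and have the right areas", {
  expect_equal(arena_area(env_concave("annulus", 2, 0)), pi * 4, tolerance = 0.01)
  expect_equal(arena_area(env_concave("horseshoe", 2, 0)), pi * 2, tolerance = 0.01)
  expect_equal(arena_area(env_concave("annulus", 2, 1)), pi * 3, tolerance = 0.01)
  expect_equal(arena_area(env_concave("s_shape", 2, 1)), 2 * pi * 3 / 2,
               tolerance = 0.01)
  expect_error(env_concave("annulus", 1, 1), class = "gridscape_error_invalid_shape")

  # Monte-Carlo containment oracle for the annulus area
  set.seed(7)
  n <- 20000
  px <- runif(n, -2, 2); py <- runif(n, -2, 2)
  mc_area <- mean(arena_contains(env_concave("annulus", 2, 1), px, py)) * 16
  expect_equal(mc_area, pi * 3, tolerance = 0.05)

  # degeneracy: annulus(r, 0) is a disc (no point near centre excluded)
  expect_true(arena_contains(env_concave("annulus", 2, 0), 0, 0))
  expect_false(arena_contains(env_concave("annulus", 2, 1), 0, 0))
})

test_that("polygons converge to the circle as sides increase", {
  # Hausdorff distance between the inscribed polygon and its circle is
  # r (1 - cos(pi/n)): strictly decreasing in n
  haus <- vapply(c(3, 4, 6, 8, 12, 24, 60), function(n) {
    env <- env_polygon(n, 1)
    th <- seq(0, 2 * pi, length.out = 1441)[-1441]
    circle <- cbind(cos(th), sin(th))
    max(gridscape:::cpp_wall_distance(env$rings, circle[, 1], circle[, 2]))
  }, numeric(1))
  expect_true(all(diff(haus) < 0))
  expect_equal(haus, 1 - cos(pi / c(3, 4, 6, 8, 12, 24, 60)), tolerance = 1e-4)
})

test_that("containment and wall distance agree on interior samples", {
  env <- env_polygon(6, 1)
  set.seed(3)
  px <- runif(300, -1, 1); py <- runif(300, -1, 1)
  inside <- arena_contains(env, px, py)
  d <- wall_distance(env, px[inside], py[inside])
  expect_true(all(d > 0))
  # dense-sampling oracle for the distance
  ring <- env$rings[[1]]
  dense <- NULL
  for (i in seq_len(nrow(ring))) {
    j <- if (i == nrow(ring)) 1 else i + 1
    t <- seq(0, 1, length.out = 400)
    dense <- rbind(dense, cbind(ring[i, 1] + t * (ring[j, 1] - ring[i, 1]),
                                ring[i, 2] + t * (ring[j, 2] - ring[i, 2])))
  }
  idx <- head(which(inside), 20)
  for (k in idx) {
    oracle <- min(sqrt((dense[, 1] - px[k])^2 + (dense[, 2] - py[k])^2))
    expect_lt(abs(wall_distance(env, px[k], py[k]) - oracle), 1e-4)
  }
  expect_error(wall_distance(env, 2, 2), class = "gridscape_error_outside_arena")
})

test_that("wall distance has the expected closed-form values", {
  sq <- env_square(1, center = c(0, 0))
  expect_equal(wall_distance(sq, 0, 0), 0.5, tolerance = 1e-12)
  ann <- env_concave("annulus", 2, 1)
  expect_equal(wall_distance(ann, 1.5, 0), 0.5, tolerance = 1e-3)
})

test_that("transforming arena interpolates breadth and labels configurations", {
  env <- env_transforming(5, 2, 5, transform_time = 100)
  expect_equal(breadth_at(env, 0), 2)
  expect_equal(breadth_at(env, 50), 3.5)
  expect_equal(breadth_at(env, 100), 5)
  expect_equal(breadth_at(env, 200), 5)
  expect_identical(config_label(env, c(0, 50, 98.4, 99)), c(1L, 1L, 2L, 2L))
  a0 <- arena_at(env, 0)
  expect_equal(unname(a0$bbox[c("xmax", "ymax")]), c(5, 2))
  expect_error(env_transforming(5, 2, 4), class = "gridscape_error_invalid_transform")
})

test_that("equal-area split matches the closed-form trapezoid solution", {
  expect_equal(gridscape:::equal_area_split_x(env_square(0.9)), 0.45,
               tolerance = 0.01)
  # width(x) = 0.2 + 0.8 x / 1.9; solve 0.2 x + 0.4 x^2 / 1.9 = area / 2
  area <- (0.2 + 1.0) / 2 * 1.9
  roots <- polyroot(c(-area / 2, 0.2, 0.4 / 1.9))
  x_half <- Re(roots[Re(roots) > 0 & abs(Im(roots)) < 1e-9])
  expect_equal(gridscape:::equal_area_split_x(env_trapezoid()), x_half,
               tolerance = 0.02)
})
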