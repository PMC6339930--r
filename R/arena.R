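#' @useDynLib gridscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats runif
NULL

# Arena objects -------------------------------------------------------------
#
# An arena is a closed 2-D region bounded by one outer polyline and zero or
# more hole polylines (rings).  All curved walls are discretised as
# polylines with 360 vertices per full circle, which keeps boundary error
# well below the rate-map bin size used downstream.

ARC_VERTICES <- 360L

new_arena <- function(rings, label, kind, params = list()) {
  xs <- unlist(lapply(rings, function(r) r[, 1]))
  ys <- unlist(lapply(rings, function(r) r[, 2]))
  structure(
    list(
      rings = rings,
      bbox = c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys)),
      label = label,
      kind = kind,
      params = params
    ),
    class = "gridscape_arena"
  )
}

#' @export
print.gridscape_arena <- function(x, ...) {
  cat(sprintf(
    "<arena: %s> %d ring(s), bbox [%.2f, %.2f] x [%.2f, %.2f], area %.3f\n",
    x$label, length(x$rings), x$bbox["xmin"], x$bbox["xmax"],
    x$bbox["ymin"], x$bbox["ymax"], arena_area(x)
  ))
  invisible(x)
}

drop_duplicate_vertices <- function(m, tol = 1e-12) {
  keep <- c(TRUE, rowSums(abs(diff(m)) > tol) > 0)
  m <- m[keep, , drop = FALSE]
  n <- nrow(m)
  if (n > 1 && all(abs(m[n, ] - m[1, ]) < tol)) m <- m[-n, , drop = FALSE]
  m
}

arc_points <- function(center, radius, from, to, n = NULL) {
  if (is.null(n)) {
    n <- max(2L, ceiling(abs(to - from) / (2 * pi) * ARC_VERTICES))
  }
  th <- seq(from, to, length.out = n + 1L)
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

#' Regular polygon arena
#'
#' Vertices sit at angles `2*pi*k/n` (k = 0, ..., n-1) on a circle of the
#' given radius, so the polygon is inscribed in that circle.
#'
#' @param n_sides Number of sides (>= 3).
#' @param radius Circumradius in arena units.
#' @param center Numeric length-2 centre.
#' @return A `gridscape_arena`.
#' @export
env_polygon <- function(n_sides, radius = 1, center = c(0, 0)) {
  if (n_sides < 3) {
    abort("n_sides must be at least 3", class = "gridscape_error_invalid_shape")
  }
  if (radius <= 0) {
    abort("radius must be positive", class = "gridscape_error_invalid_shape")
  }
  k <- seq_len(n_sides) - 1L
  ring <- cbind(
    center[1] + radius * cos(2 * pi * k / n_sides),
    center[2] + radius * sin(2 * pi * k / n_sides)
  )
  new_arena(list(ring), sprintf("polygon-%d", n_sides), "polygon",
            list(n_sides = n_sides, radius = radius, center = center))
}

#' Axis-aligned square arena
#'
#' @param side Side length.
#' @param center Numeric length-2 centre.
#' @export
env_square <- function(side, center = c(side / 2, side / 2)) {
  if (side <= 0) abort("side must be positive", class = "gridscape_error_invalid_shape")
  h <- side / 2
  ring <- cbind(center[1] + c(-h, h, h, -h), center[2] + c(-h, -h, h, h))
  new_arena(list(ring), "square", "square", list(side = side, center = center))
}

#' Circular arena
#'
#' @param radius Radius.
#' @param center Numeric length-2 centre.
#' @export
env_circle <- function(radius, center = c(0, 0)) {
  if (radius <= 0) abort("radius must be positive", class = "gridscape_error_invalid_shape")
  ring <- drop_duplicate_vertices(arc_points(center, radius, 0, 2 * pi))
  new_arena(list(ring), "circle", "circle", list(radius = radius, center = center))
}

#' Isosceles trapezoid arena
#'
#' The two parallel walls are vertical: a narrow wall of height
#' `width_left` at x = 0 and a broad wall of height `width_right` at
#' x = `length`, both centred on y = 0.  Defaults follow the published
#' trapezoid proportions used in polarised-enclosure grid studies.
#'
#' @param width_left,width_right Heights of the parallel walls.
#' @param length Distance between the parallel walls.
#' @export
env_trapezoid <- function(width_left = 0.2, width_right = 1, length = 1.9) {
  if (min(width_left, width_right, length) <= 0) {
    abort("trapezoid dimensions must be positive", class = "gridscape_error_invalid_shape")
  }
  ring <- cbind(
    c(0, length, length, 0),
    c(-width_left / 2, -width_right / 2, width_right / 2, width_left / 2)
  )
  new_arena(list(ring), "trapezoid", "trapezoid",
            list(width_left = width_left, width_right = width_right, length = length))
}

# Boundary of one room of a connected arena, from its top corridor
# attachment counterclockwise round the far side to the bottom attachment
# (left room), or bottom-to-top (right room).
room_path <- function(shape, side, x_offset, y_top, y_bot, left) {
  yc <- side / 2
  cw <- y_top - y_bot
  if (shape == "square") {
    if (left) {
      rbind(
        c(x_offset + side, y_top), c(x_offset + side, side), c(x_offset, side),
        c(x_offset, 0), c(x_offset + side, 0), c(x_offset + side, y_bot)
      )
    } else {
      rbind(
        c(x_offset, y_bot), c(x_offset, 0), c(x_offset + side, 0),
        c(x_offset + side, side), c(x_offset, side), c(x_offset, y_top)
      )
    }
  } else {
    r <- side / 2
    cen <- c(x_offset + r, yc)
    dx <- sqrt(r^2 - (cw / 2)^2)
    phi <- atan2(cw / 2, dx)
    if (left) {
      arc_points(cen, r, phi, 2 * pi - phi)
    } else {
      arc_points(cen, r, pi + phi, 3 * pi - phi)
    }
  }
}

#' Two rooms connected by a corridor
#'
#' Two rooms (squares of side `room_size` or circles of diameter
#' `room_size`) separated by `distance` along the x axis and joined by an
#' axis-aligned corridor of width `corridor_width` centred on the rooms'
#' shared horizontal axis.  The boundary is a single closed curve.
#'
#' @param shape_a,shape_b `"square"` or `"circle"`.
#' @param room_size Square side or circle diameter.
#' @param corridor_width Corridor width (must not exceed the room face).
#' @param distance Separation between the facing room walls (corridor
#'   length for square rooms).
#' @export
env_connected <- function(shape_a = c("square", "circle"),
                          shape_b = c("square", "circle"),
                          room_size = 1.8, corridor_width = 0.8,
                          distance = 0.8) {
  shape_a <- match.arg(shape_a)
  shape_b <- match.arg(shape_b)
  if (room_size <= 0 || corridor_width <= 0 || distance < 0) {
    abort("room_size and corridor_width must be positive, distance non-negative",
          class = "gridscape_error_invalid_shape")
  }
  if (corridor_width > room_size ||
      (corridor_width >= room_size && (shape_a == "circle" || shape_b == "circle"))) {
    abort("corridor is wider than a room face", class = "gridscape_error_invalid_shape")
  }
  yc <- room_size / 2
  y_top <- yc + corridor_width / 2
  y_bot <- yc - corridor_width / 2
  a <- room_path(shape_a, room_size, 0, y_top, y_bot, left = TRUE)
  b <- room_path(shape_b, room_size, room_size + distance, y_top, y_bot, left = FALSE)
  ring <- drop_duplicate_vertices(rbind(a, b))
  new_arena(
    list(ring), sprintf("%s-%s d=%g", shape_a, shape_b, distance), "connected",
    list(
      shape_a = shape_a, shape_b = shape_b, room_size = room_size,
      corridor_width = corridor_width, distance = distance,
      # x ranges used to assign samples to compartments
      a_max = room_size, b_min = room_size + distance
    )
  )
}

#' Concave arenas: annulus, horseshoe, S-shape
#'
#' The annulus is the band between two concentric circles (`r_inner = 0`
#' degenerates to a disc).  The horseshoe is the band between two
#' concentric semicircles closed by straight caps (`r_inner = 0`
#' degenerates to a half-disc).  The S-shape concatenates two horseshoes
#' at a common end, one inverted.
#'
#' @param kind `"annulus"`, `"horseshoe"` or `"s_shape"`.
#' @param r_outer Outer radius.
#' @param r_inner Inner radius (>= 0 and < `r_outer`).
#' @export
env_concave <- function(kind = c("annulus", "horseshoe", "s_shape"),
                        r_outer = 2, r_inner = 0) {
  kind <- match.arg(kind)
  if (r_inner < 0 || r_inner >= r_outer) {
    abort("need 0 <= r_inner < r_outer", class = "gridscape_error_invalid_shape")
  }
  rings <- switch(kind,
    annulus = {
      outer <- drop_duplicate_vertices(arc_points(c(0, 0), r_outer, 0, 2 * pi))
      if (r_inner > 0) {
        inner <- drop_duplicate_vertices(arc_points(c(0, 0), r_inner, 0, 2 * pi))
        list(outer, inner)
      } else {
        list(outer)
      }
    },
    horseshoe = {
      path <- arc_points(c(0, 0), r_outer, 0, pi)
      path <- if (r_inner > 0) {
        rbind(path, arc_points(c(0, 0), r_inner, pi, 0))
      } else {
        rbind(path, c(0, 0))
      }
      list(drop_duplicate_vertices(path))
    },
    s_shape = {
      c2 <- c(r_outer + r_inner, 0)
      path <- arc_points(c(0, 0), r_outer, 0, pi)
      if (r_inner > 0) path <- rbind(path, arc_points(c(0, 0), r_inner, pi, 0))
      else path <- rbind(path, c(0, 0))
      path <- rbind(path, arc_points(c2, r_outer, pi, 2 * pi))
      if (r_inner > 0) path <- rbind(path, arc_points(c2, r_inner, 2 * pi, pi))
      else path <- rbind(path, c2)
      list(drop_duplicate_vertices(path))
    }
  )
  new_arena(rings, sprintf("%s r=%g/%g", kind, r_outer, r_inner), kind,
            list(r_outer = r_outer, r_inner = r_inner))
}

#' Rectangle that transforms into a square during exploration
#'
#' The arena is `[0, length] x [0, breadth(t)]`; the breadth grows
#' linearly from `breadth_start` to `breadth_end` over `transform_time`
#' seconds and stays there.  The end state must be the square
#' (`breadth_end == length`).  `config_label()` reports configuration 1
#' while the shape is still a rectangle and 2 once the breadth reaches
#' 99% of the square.
#'
#' @param length Fixed x extent.
#' @param breadth_start,breadth_end Initial and final y extent.
#' @param transform_time Seconds over which the breadth grows.
#' @export
env_transforming <- function(length = 5, breadth_start = 2, breadth_end = 5,
                             transform_time = 300) {
  if (breadth_end != length) {
    abort("breadth_end must equal length (final shape is the square)",
          class = "gridscape_error_invalid_transform")
  }
  if (breadth_start >= breadth_end || breadth_start <= 0 || transform_time <= 0) {
    abort("need 0 < breadth_start < breadth_end and transform_time > 0",
          class = "gridscape_error_invalid_transform")
  }
  structure(
    list(
      length = length, breadth_start = breadth_start,
      breadth_end = breadth_end, transform_time = transform_time,
      label = sprintf("transforming %gx%g->%gx%g", length, breadth_start,
                      length, breadth_end)
    ),
    class = c("gridscape_transforming", "gridscape_arena_like")
  )
}

#' Breadth of a transforming arena at time t
#' @param env A transforming arena.
#' @param t Time(s) in seconds.
#' @export
breadth_at <- function(env, t) {
  stopifnot(inherits(env, "gridscape_transforming"))
  pmin(env$breadth_end,
       env$breadth_start +
         (env$breadth_end - env$breadth_start) * pmax(t, 0) / env$transform_time)
}

#' Configuration label of a transforming arena
#'
#' 1 while the arena is rectangular, 2 once the breadth has reached 99%
#' of the square side.
#' @inheritParams breadth_at
#' @export
config_label <- function(env, t) {
  ifelse(breadth_at(env, t) >= 0.99 * env$length, 2L, 1L)
}

#' Freeze a (possibly transforming) arena at a time point
#' @param env Arena.
#' @param t Time in seconds.
#' @export
arena_at <- function(env, t = 0) {
  if (inherits(env, "gridscape_transforming")) {
    b <- breadth_at(env, t)
    ring <- cbind(c(0, env$length, env$length, 0), c(0, 0, b, b))
    new_arena(list(ring), sprintf("%s @t=%g", env$label, t), "rectangle",
              list(length = env$length, breadth = b))
  } else {
    env
  }
}

# Queries --------------------------------------------------------------------

#' Point containment test
#'
#' @param env Arena (static or transforming).
#' @param x,y Coordinates (vectorised).
#' @param t Time, used only for transforming arenas.
#' @return Logical vector.
#' @export
arena_contains <- function(env, x, y, t = 0) {
  env <- arena_at(env, t)
  cpp_points_in_rings(env$rings, as.numeric(x), as.numeric(y))
}

#' Distance to the nearest wall
#'
#' Euclidean distance from interior points to the nearest boundary curve
#' (outer wall or hole wall).  Errors if any point lies outside.
#' @inheritParams arena_contains
#' @export
wall_distance <- function(env, x, y, t = 0) {
  env <- arena_at(env, t)
  inside <- cpp_points_in_rings(env$rings, as.numeric(x), as.numeric(y))
  if (!all(inside)) {
    abort("point(s) outside the arena", class = "gridscape_error_outside_arena")
  }
  cpp_wall_distance(env$rings, as.numeric(x), as.numeric(y))
}

shoelace <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Arena area
#'
#' Polygonal area of the outer ring minus any holes (shoelace formula on
#' the discretised boundary).
#' @param env Arena.
#' @export
arena_area <- function(env) {
  env <- arena_at(env, 0)
  a <- shoelace(env$rings[[1]])
  if (length(env$rings) > 1) {
    a <- a - sum(vapply(env$rings[-1], shoelace, numeric(1)))
  }
  a
}

#' Arena boundary as a tibble
#'
#' One row per vertex with a `ring` index (ring 1 is the outer wall).
#' @param env Arena.
#' @export
arena_boundary <- function(env) {
  env <- arena_at(env, 0)
  purrr::map2_dfr(env$rings, seq_along(env$rings), function(r, i) {
    tibble(ring = i, x = c(r[, 1], r[1, 1]), y = c(r[, 2], r[1, 2]))
  })
}

#' @export
as_tibble.gridscape_arena <- function(x, ...) arena_boundary(x)

# Which compartment of a connected arena a sample falls in.
# Returns "a", "b" or "corridor".
arena_compartment <- function(env, x, y) {
  stopifnot(env$kind == "connected")
  p <- env$params
  ifelse(x < p$a_max, "a", ifelse(x > p$b_min, "b", "corridor"))
}

# Equal-area vertical split abscissa: the x at which the area left of the
# cut equals half the total (used for the trapezoid/square half analyses).
equal_area_split_x <- function(env) {
  env0 <- arena_at(env, 0)
  xs <- seq(env0$bbox["xmin"], env0$bbox["xmax"], length.out = 513)
  # width of the arena cross-section at each x, via fine y sampling
  ny <- 257
  ys <- seq(env0$bbox["ymin"], env0$bbox["ymax"], length.out = ny)
  dy <- ys[2] - ys[1]
  width <- vapply(xs, function(x0) {
    sum(cpp_points_in_rings(env0$rings, rep(x0, ny), ys)) * dy
  }, numeric(1))
  cum <- cumsum((width[-1] + width[-length(width)]) / 2 * diff(xs))
  xs[1 + which.min(abs(cum - cum[length(cum)] / 2))]
}
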