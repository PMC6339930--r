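# The five environmental-geometry studies, end to end.  Every study
# trains the full model from scratch per seed (sharing the seed's
# head-direction layer across arena conditions, since it depends only on
# heading statistics), scores gridness, and summarises per-seed trends
# by majority slope sign and median R^2.

hd_for_seed <- function(seed, params) {
  train_hd_som(params$grid_shape, params$som_samples, params$som_epochs,
               seed = derive_seeds(seed, c("trajectory", "som", "lahn"))[["som"]])
}

# Whole-arena HGS per LAHN neuron for a response matrix.
neuron_hgs <- function(traj, resp, bin_size, smoothing_sigma, max_lag) {
  vapply(seq_len(ncol(resp)), function(i) {
    rm <- rate_map(traj, resp[, i], bin_size, smoothing_sigma)
    as.numeric(hgs(autocorrelogram(rm, max_lag = max_lag)))
  }, numeric(1))
}

# Neurons counted as grid-like: every neuron with positive whole-arena
# HGS, and in any case the top `k_min` scorers, so per-run averages rest
# on a stable number of units.
grid_neuron_set <- function(scores, k_min = 5) {
  pos <- which(!is.na(scores) & scores > 0)
  top <- order(scores, decreasing = TRUE)[seq_len(min(k_min, length(scores)))]
  sort(union(pos, top))
}

#' Connected-arena shape study
#'
#' Trains the model in a two-room arena (square-square, square-circle or
#' circle-circle) and tracks the best grid neuron's local and global HGS
#' across training checkpoints, fitting a linear trend per seed.
#'
#' @param pair `"square-square"`, `"square-circle"` or `"circle-circle"`.
#' @param duration Session length (s).
#' @param seeds Integer seeds (one full run each).
#' @param n_checkpoints Training checkpoints scored.
#' @param params Model parameters, see [model_params()].
#' @param room_size,corridor_width,distance Arena dimensions.
#' @param bin_size,smoothing_sigma,max_lag Map/autocorrelogram settings.
#' @return A `gridscape_study`: per-checkpoint scores, per-seed trends
#'   and the majority-sign summary.
#' @export
run_connected_shapes <- function(pair = c("square-square", "square-circle",
                                          "circle-circle"),
                                 duration = 900, seeds = 1:5,
                                 n_checkpoints = 6, params = model_params(),
                                 room_size = 1.8, corridor_width = 0.8,
                                 distance = 0.8, bin_size = 0.01,
                                 smoothing_sigma = 1, max_lag = 0.25) {
  pair <- match.arg(pair)
  shapes <- strsplit(pair, "-")[[1]]
  env <- env_connected(shapes[1], shapes[2], room_size, corridor_width, distance)
  scores <- purrr::map_dfr(seeds, function(seed) {
    hd <- hd_for_seed(seed, params)
    model <- train_grid_model(env, duration, params, n_checkpoints, seed, hd = hd)
    final <- replay_responses(model, "final")
    best <- which.max(neuron_hgs(model$traj, final, bin_size, smoothing_sigma, max_lag))
    cps <- model$checkpoints[-1] # skip iteration-0 weights
    purrr::map_dfr(cps, function(cp) {
      resp <- lahn_replay(model$chi, cp$q, cp$w)
      lg <- tryCatch(
        local_global_hgs(env, model$traj, resp[, best], bin_size, smoothing_sigma),
        gridscape_error_insufficient_sampling = function(e) {
          warning(sprintf("seed %d: compartment undersampled; scores dropped", seed))
          tibble(hgs_local = NA_real_, hgs_global = NA_real_)
        }
      )
      tibble(seed = seed, iter = cp$iter, neuron = best,
             hgs_local = lg$hgs_local, hgs_global = lg$hgs_global)
    })
  })
  st <- summarize_trends(scores, "iter", c("hgs_local", "hgs_global"))
  new_study(paste0("connected_shapes:", pair), scores, st$trends, st$summary,
            list(pair = pair))
}

#' Connected-arena distance study
#'
#' Two square rooms at increasing separation; per distance the model is
#' trained to the end of the session and the best grid neuron's final
#' local and global HGS are recorded, then regressed on distance per
#' seed.
#'
#' @param d_values Increasing compartment separations (arena units).
#' @inheritParams run_connected_shapes
#' @export
run_connected_distance <- function(d_values = seq(0.1, 1, by = 0.1),
                                   duration = 900, seeds = 1:5,
                                   params = model_params(), room_size = 1.8,
                                   corridor_width = 0.8, bin_size = 0.01,
                                   smoothing_sigma = 1, max_lag = 0.25) {
  if (is.unsorted(d_values)) {
    abort("d_values must be increasing", class = "gridscape_error_invalid_params")
  }
  scores <- purrr::map_dfr(seeds, function(seed) {
    hd <- hd_for_seed(seed, params)
    purrr::map_dfr(d_values, function(d) {
      env <- env_connected("square", "square", room_size, corridor_width, d)
      model <- train_grid_model(env, duration, params, n_checkpoints = 1,
                                seed = seed, hd = hd)
      final <- replay_responses(model, "final")
      best <- which.max(neuron_hgs(model$traj, final, bin_size,
                                   smoothing_sigma, max_lag))
      lg <- tryCatch(
        local_global_hgs(env, model$traj, final[, best], bin_size,
                         smoothing_sigma),
        gridscape_error_insufficient_sampling = function(e) {
          warning(sprintf("seed %d d=%g: compartment undersampled; scores dropped",
                          seed, d))
          tibble(hgs_local = NA_real_, hgs_global = NA_real_)
        }
      )
      tibble(seed = seed, d = d, neuron = best,
             hgs_local = lg$hgs_local, hgs_global = lg$hgs_global)
    })
  })
  st <- summarize_trends(scores, "d", c("hgs_local", "hgs_global"))
  new_study("connected_distance", scores, st$trends, st$summary)
}

#' Convex-arena study (square vs trapezoid)
#'
#' Trains the model in a square and in an isosceles trapezoid of matched
#' dimensions, splits each arena into two halves of equal area by a
#' vertical cut, and reports per-half HGS, half-map similarity and
#' ellipticity averaged over the grid-like neurons of each run.
#'
#' @inheritParams run_connected_shapes
#' @param square_side Side of the square arena.
#' @param trapezoid `list(width_left, width_right, length)`.
#' @export
run_convex <- function(duration = 600, seeds = 1:5, params = model_params(),
                       square_side = 0.9,
                       trapezoid = list(width_left = 0.2, width_right = 1,
                                        length = 1.9),
                       bin_size = 0.01, smoothing_sigma = 1, max_lag = 0.25) {
  envs <- list(
    square = env_square(square_side),
    trapezoid = env_trapezoid(trapezoid$width_left, trapezoid$width_right,
                              trapezoid$length)
  )
  scores <- purrr::map_dfr(seeds, function(seed) {
    hd <- hd_for_seed(seed, params)
    purrr::imap_dfr(envs, function(env, shape) {
      model <- train_grid_model(env, duration, params, n_checkpoints = 1,
                                seed = seed, hd = hd)
      final <- replay_responses(model, "final")
      whole <- neuron_hgs(model$traj, final, bin_size, smoothing_sigma, max_lag)
      sel <- grid_neuron_set(whole)
      split <- equal_area_split_x(env)
      per_neuron <- purrr::map_dfr(sel, function(i) {
        resp <- final[, i]
        left <- model$traj$x < split
        half_score <- function(keep) {
          rm <- rate_map_xy(model$traj$x[keep], model$traj$y[keep], resp[keep],
                            bin_size, smoothing_sigma)
          as.numeric(hgs(autocorrelogram(rm, max_lag = max_lag)))
        }
        rm_all <- rate_map(model$traj, resp, bin_size, smoothing_sigma)
        ac_all <- autocorrelogram(rm_all, max_lag = max_lag)
        tibble(
          neuron = i,
          hgs_left = half_score(left),
          hgs_right = half_score(!left),
          hgs_whole = whole[i],
          half_similarity = tryCatch(
            half_map_similarity(rm_all, split = split),
            error = function(e) NA_real_
          ),
          ellipticity = tryCatch(ellipticity(ac_all), error = function(e) NA_real_)
        )
      })
      dplyr::summarise(
        per_neuron,
        seed = seed, shape = shape, n_grid_neurons = dplyr::n(),
        dplyr::across(c("hgs_left", "hgs_right", "hgs_whole",
                        "half_similarity", "ellipticity"),
                      ~ mean(.x, na.rm = TRUE))
      )
    })
  })
  summary <- scores |>
    dplyr::group_by(.data$shape) |>
    dplyr::summarise(dplyr::across(c("hgs_left", "hgs_right", "hgs_whole",
                                     "half_similarity", "ellipticity"),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  new_study("convex", scores, trends = NULL, summary = summary)
}

#' Concave-arena study
#'
#' HGS (averaged over grid-like neurons) as the inner radius of an
#' annulus, horseshoe or S-shaped arena grows, with a per-seed linear
#' trend against the radius.
#'
#' @param kind `"annulus"`, `"horseshoe"` or `"s_shape"`.
#' @param radii Increasing inner radii.
#' @param r_outer Outer radius (must exceed `max(radii)`).
#' @inheritParams run_connected_shapes
#' @export
run_concave <- function(kind = c("annulus", "horseshoe", "s_shape"),
                        radii = NULL, r_outer = NULL, duration = 360,
                        seeds = 1:5, params = model_params(), bin_size = 0.01,
                        smoothing_sigma = 1, max_lag = 0.25) {
  kind <- match.arg(kind)
  if (is.null(radii)) radii <- if (kind == "s_shape") seq(0, 1, 0.2) else seq(0, 2, 0.2)
  if (is.null(r_outer)) r_outer <- if (kind == "s_shape") 2 else 3
  if (is.unsorted(radii)) {
    abort("radii must be increasing", class = "gridscape_error_invalid_params")
  }
  scores <- purrr::map_dfr(seeds, function(seed) {
    hd <- hd_for_seed(seed, params)
    purrr::map_dfr(radii, function(r) {
      env <- env_concave(kind, r_outer, r)
      model <- train_grid_model(env, duration, params, n_checkpoints = 1,
                                seed = seed, hd = hd)
      final <- replay_responses(model, "final")
      whole <- neuron_hgs(model$traj, final, bin_size, smoothing_sigma, max_lag)
      sel <- grid_neuron_set(whole)
      tibble(seed = seed, r_inner = r, n_grid_neurons = length(sel),
             hgs = mean(whole[sel]))
    })
  })
  st <- summarize_trends(scores, "r_inner", "hgs")
  new_study(paste0("concave:", kind), scores, st$trends, st$summary,
            list(kind = kind, r_outer = r_outer))
}

#' Polygon-sides study
#'
#' HGS (averaged over grid-like neurons) in regular n-sided polygons as
#' n grows from triangle toward circle.
#'
#' @param n_range Increasing side counts (all >= 3).
#' @param radius Polygon circumradius.
#' @inheritParams run_connected_shapes
#' @export
run_polygon <- function(n_range = 3:10, radius = 1, duration = 360,
                        seeds = 1:5, params = model_params(), bin_size = 0.01,
                        smoothing_sigma = 1, max_lag = 0.25) {
  if (any(n_range < 3)) {
    abort("all n must be >= 3", class = "gridscape_error_invalid_shape")
  }
  scores <- purrr::map_dfr(seeds, function(seed) {
    hd <- hd_for_seed(seed, params)
    purrr::map_dfr(sort(n_range), function(n) {
      env <- env_polygon(n, radius)
      model <- train_grid_model(env, duration, params, n_checkpoints = 1,
                                seed = seed, hd = hd)
      final <- replay_responses(model, "final")
      whole <- neuron_hgs(model$traj, final, bin_size, smoothing_sigma, max_lag)
      sel <- grid_neuron_set(whole)
      tibble(seed = seed, n_sides = n, n_grid_neurons = length(sel),
             hgs = mean(whole[sel]))
    })
  })
  st <- summarize_trends(scores, "n_sides", "hgs")
  new_study("polygon", scores, st$trends, st$summary)
}

#' Transforming-arena decoding study
#'
#' Simulates a rectangle growing into a square with concurrent model
#' training, then trains three configuration decoders on LAHN population
#' responses: (i) the online response log of the network learning to
#' convergence over the session (the concurrent-training protocol), (ii)
#' the full session replayed through a partially trained checkpoint
#' (earliest snapshot at or after 10% of the convergence iteration,
#' weights frozen) and (iii) the same replay through the untrained
#' initial weights.  Reports held-out accuracy for (i) and (ii) and
#' per-configuration MSE for (i) and (iii), plus the spatial
#' classification map of the converged decoder.
#'
#' @inheritParams run_connected_shapes
#' @param length,breadth_start Arena dimensions (the square side equals
#'   `length`).
#' @param transform_frac Fraction of the session over which the breadth
#'   grows.
#' @param sample_every Keep every k-th timestep as a decoder sample.
#' @param decoder List of decoder settings (`hidden_size`,
#'   `learning_rate`, `epochs`, `train_frac`).
#' @export
run_transforming <- function(duration = 600, seeds = 1:5,
                             params = model_params(), length = 5,
                             breadth_start = 2, transform_frac = 0.5,
                             sample_every = 5,
                             decoder = list(hidden_size = 20,
                                            learning_rate = 0.01,
                                            epochs = 200, train_frac = 0.8)) {
  env <- env_transforming(length, breadth_start, length,
                          transform_time = transform_frac * duration)
  runs <- purrr::map(seeds, function(seed) {
    hd <- hd_for_seed(seed, params)
    model <- train_grid_model(env, duration, params, n_checkpoints = 10,
                              seed = seed, hd = hd)
    labels <- config_label(env, model$traj$t)
    keep <- seq(1, nrow(model$traj), by = sample_every)
    dec_seed <- derive_seeds(seed, c("decoder"))[["decoder"]]
    fit_on <- function(resp) {
      train_decoder(resp[keep, , drop = FALSE], labels[keep],
                    hidden_size = decoder$hidden_size,
                    learning_rate = decoder$learning_rate,
                    epochs = decoder$epochs,
                    train_frac = decoder$train_frac, seed = dec_seed)
    }
    trained <- fit_on(model$response_log)
    partial <- fit_on(replay_responses(model, partial_checkpoint_index(model)))
    untrained <- fit_on(replay_responses(model, 1))
    cls_map <- tibble(
      x = model$traj$x[keep][trained$predictions$index],
      y = model$traj$y[keep][trained$predictions$index],
      label = trained$predictions$label,
      output = trained$predictions$output
    )
    list(
      row = tibble(
        seed = seed,
        accuracy_trained = 100 * trained$accuracy,
        accuracy_partial = 100 * partial$accuracy,
        mse_trained_c1 = trained$mse_by_config$mse[1],
        mse_trained_c2 = trained$mse_by_config$mse[2],
        mse_untrained_c1 = untrained$mse_by_config$mse[1],
        mse_untrained_c2 = untrained$mse_by_config$mse[2],
        partial_iter = model$checkpoints[[partial_checkpoint_index(model)]]$iter
      ),
      cls_map = cls_map
    )
  })
  scores <- purrr::map_dfr(runs, "row")
  summary <- scores |>
    dplyr::summarise(dplyr::across(dplyr::starts_with(c("accuracy", "mse")), mean))
  new_study("transforming", scores, trends = NULL, summary = summary,
            extra = list(classification_map = runs[[1]]$cls_map, arena = env))
}
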