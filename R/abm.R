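#' Simulation world configuration
#'
#' Parameters of the off-lattice agent-based model. Defaults follow the
#' experimental calibration: 1 patch = 1 mm, one step = 0.1 s, speed 2
#' patches/step (2 cm/s), direction updates every 4 steps (0.4 s) via the
#' Weber turning rule with two 45-degree sectors of radius 20 patches
#' centred 45 degrees left and right of the heading, 0.1 pheromone units
#' deposited per move, 1000 ants entering with probability 1/1000 per step,
#' and a detection threshold of 50 units below which turning is pure noise.
#' The turning noise SDs (`sigma1` on-response, `sigma2` below threshold)
#' are calibrated so that ~35 degrees is the off-trail scale of direction
#' changes per 0.4 s while trails stay stable.
#'
#' Geometry `"arena"` is an open circular arena (diameter 1000 patches,
#' nest at the centre; agents get a back-to-nest label at rate 1 per 10
#' simulated minutes). Geometry `"bridge"` is a symmetric binary bridge 440
#' patches end to end: nest disc, proximal stem, a diamond of four
#' 45-degree branch capsules of half-width 10, distal stem and food disc;
#' agents reaching the food are labelled back-to-nest. Labelled agents
#' within 2 cm of the nest head straight to it and leave the world
#' (rejoining the entry pool).
#'
#' @param geometry `"arena"` or `"bridge"`.
#' @param n_ants colony size.
#' @param patch_size mm per patch.
#' @param dt seconds per step.
#' @param speed patches per step.
#' @param turn_every steps between direction updates.
#' @param A turning amplitude in degrees (the fitted Weber amplitude).
#' @param sigma1 SD (deg) of the directional noise added to the pheromone
#'   response above the detection threshold.
#' @param sigma2 SD (deg) of the exploratory noise below the threshold.
#' @param sense_radius,sense_offset,sense_half_angle sector radius
#'   (patches), centre offset from the heading and half-width (degrees).
#' @param deposit pheromone units laid per move.
#' @param entry_prob per-step probability for a pooled ant to enter.
#' @param return_prob per-step probability of acquiring the back-to-nest
#'   label (arena only; bridge labels at the food).
#' @param detection_threshold sector-sum threshold (units).
#' @param evap_half_life evaporation half-life (s) or `Inf`.
#' @param arena_diameter open-arena diameter in patches.
#' @param homing_radius distance (patches) from the nest at which a
#'   labelled ant heads straight in.
#' @param bridge bridge geometry constants (versioned defaults; see
#'   [bridge_geometry()]).
#' @return A `world_config` list.
#' @export
world_config <- function(geometry = c("arena", "bridge"), n_ants = 1000,
                         patch_size = 1, dt = 0.1, speed = 2,
                         turn_every = 4, A = 35, sigma1 = 15, sigma2 = 35,
                         sense_radius = 20, sense_offset = 45,
                         sense_half_angle = 22.5, deposit = 0.1,
                         entry_prob = 1 / 1000, return_prob = dt / 600,
                         detection_threshold = 50, evap_half_life = Inf,
                         arena_diameter = 1000, homing_radius = 20,
                         bridge = bridge_geometry()) {
  geometry <- match.arg(geometry)
  stopifnot(entry_prob >= 0, entry_prob <= 1, return_prob >= 0,
            return_prob <= 1, speed > 0, patch_size > 0, dt > 0,
            turn_every >= 1, sense_radius > 0, n_ants >= 1)
  cfg <- list(
    geometry = if (geometry == "arena") 0L else 1L,
    geometry_name = geometry, n_ants = as.integer(n_ants),
    patch_size = patch_size, dt = dt, speed = speed,
    turn_every = as.integer(turn_every), A = A, sigma1 = sigma1,
    sigma2 = sigma2, sense_radius = sense_radius,
    sense_offset = sense_offset, sense_half_angle = sense_half_angle,
    deposit = deposit, entry_prob = entry_prob, return_prob = return_prob,
    detection_threshold = detection_threshold,
    evap_half_life = evap_half_life, arena_radius = arena_diameter / 2,
    homing_radius = homing_radius,
    bridge_half_width = bridge$half_width, bridge_y_nest = bridge$y_nest,
    bridge_y1 = bridge$y1, bridge_y2 = bridge$y2,
    bridge_y_food = bridge$y_food, bridge_vertex_x = bridge$vertex_x,
    bridge_region_r = bridge$region_r)
  if (geometry == "arena") {
    n <- as.integer(arena_diameter / patch_size)
    cfg$grid_dim <- c(n, n)
    cfg$origin_x <- -arena_diameter / 2
    cfg$origin_y <- -arena_diameter / 2
  } else {
    pad <- bridge$vertex_x + bridge$half_width + 10
    cfg$grid_dim <- c(as.integer(ceiling(bridge$y_food + bridge$region_r +
                                           5)), as.integer(2 * pad))
    cfg$origin_x <- -pad
    cfg$origin_y <- 0
  }
  structure(cfg, class = "world_config")
}

#' Binary-bridge geometry constants
#'
#' Versioned geometry of the symmetric binary bridge: 440 patches end to
#' end along +y, corridors of half-width 10 patches, branches at 45 degrees
#' meeting side vertices 100 patches off-axis, and nest/food discs of
#' radius 20 patches at the extremities.
#'
#' @export
bridge_geometry <- function() {
  list(half_width = 10, y_nest = 20, y1 = 120, y2 = 320, y_food = 420,
       vertex_x = 100, region_r = 20, version = "1")
}

#' Initialise an empty simulation world
#'
#' All ants start in the nest pool (out of the world) and the field is
#' empty.
#'
#' @param config a [world_config()].
#' @return A `world_state` list (agent vectors, field, time, move count).
#' @export
init_world <- function(config) {
  n <- config$n_ants
  structure(list(
    x = numeric(n), y = numeric(n), heading = numeric(n),
    in_world = integer(n), label = integer(n), last_food = integer(n),
    steps_since_turn = integer(n),
    field = matrix(0, config$grid_dim[1], config$grid_dim[2]),
    t = 0, moves = 0), class = "world_state")
}

#' Advance the world by `n_steps` steps
#'
#' One step: pooled ants enter with `entry_prob`; each in-world ant updates
#' its heading every `turn_every` steps by the Weber turning rule, moves
#' `speed` patches along its heading (with the border rule applied when the
#' move would leave the world), deposits `deposit` units at its new patch,
#' and acquires/uses back-to-nest labels. Agents update in fixed id order;
#' all draws come from R's RNG, so runs are reproducible under
#' `set.seed()`.
#'
#' @param world a `world_state` from [init_world()].
#' @param config the matching [world_config()].
#' @param n_steps number of steps to advance.
#' @export
step_world <- function(world, config, n_steps = 1) {
  res <- abm_run_cpp(world, unclass(config), as.integer(n_steps), FALSE,
                     FALSE, 0L)
  structure(res$state, class = "world_state")
}

#' Weber turning rule
#'
#' The direction update used by the simulator: with `L` and `R` the sector
#' sums ahead-left and ahead-right, the turn is
#' `A * (L - R) / (L + R) + e1` when `L + R` reaches the detection
#' threshold (`e1 ~ N(0, sigma1)`), else pure exploratory noise
#' `e2 ~ N(0, sigma2)`. Exposed for direct use and testing; draws use R's
#' RNG.
#'
#' @param pos numeric (x, y) in patches.
#' @param heading degrees.
#' @param field pheromone matrix (patch grid) or [pheromone_field()].
#' @param config a [world_config()].
#' @return A list with the new `heading`, the turn `dalpha`, the sector
#'   sums `L`, `R`, and whether the ant was `above` threshold.
#' @export
turn_rule <- function(pos, heading, field, config) {
  g <- if (inherits(field, "pheromone_field")) field$grid else field
  ox <- config$origin_x; oy <- config$origin_y
  L <- sector_sum_cpp(g, config$patch_size, ox, oy, pos[1], pos[2], heading,
                      config$sense_offset - config$sense_half_angle,
                      config$sense_offset + config$sense_half_angle,
                      TRUE, TRUE, config$sense_radius)
  R <- sector_sum_cpp(g, config$patch_size, ox, oy, pos[1], pos[2], heading,
                      -config$sense_offset - config$sense_half_angle,
                      -config$sense_offset + config$sense_half_angle,
                      TRUE, TRUE, config$sense_radius)
  above <- (L + R) >= config$detection_threshold
  dalpha <- if (above)
    config$A * (L - R) / (L + R) + rnorm(1, 0, config$sigma1)
  else rnorm(1, 0, config$sigma2)
  list(heading = wrap180(heading + dalpha), dalpha = dalpha, L = L, R = R,
       above = above)
}

#' Border rule
#'
#' Open arena: an ant heading against the circular wall aligns with the
#' wall tangent closest to its current heading (an exact head-on tie is
#' broken towards the left tangent). Bridge: the ant aligns with its
#' corridor's axis pointing away from the latest visited site (nest or
#' food).
#'
#' @param pos numeric (x, y) in patches.
#' @param heading degrees.
#' @param config a [world_config()].
#' @param from_food `TRUE` if the latest visited site is the food (bridge
#'   only).
#' @return The new heading in degrees.
#' @export
border_rule <- function(pos, heading, config, from_food = FALSE) {
  if (config$geometry == 0L) {
    radial <- rad2deg(atan2(pos[2], pos[1]))
    tl <- wrap180(radial + 90)
    tr <- wrap180(radial - 90)
    if (abs(wrap180(tl - heading)) <= abs(wrap180(tr - heading))) tl else tr
  } else {
    g <- config
    s <- sqrt(2) / 2
    ym <- (g$bridge_y1 + g$bridge_y2) / 2
    parts <- list(
      list(inside = abs(pos[1]) <= g$bridge_half_width &&
             pos[2] >= g$bridge_y_nest && pos[2] <= g$bridge_y1,
           axis = c(0, 1)),
      list(inside = dist_to_segment(pos, c(0, g$bridge_y1),
                                    c(-g$bridge_vertex_x, ym)) <=
             g$bridge_half_width, axis = c(-s, s)),
      list(inside = dist_to_segment(pos, c(-g$bridge_vertex_x, ym),
                                    c(0, g$bridge_y2)) <=
             g$bridge_half_width, axis = c(s, s)),
      list(inside = dist_to_segment(pos, c(0, g$bridge_y1),
                                    c(g$bridge_vertex_x, ym)) <=
             g$bridge_half_width, axis = c(s, s)),
      list(inside = dist_to_segment(pos, c(g$bridge_vertex_x, ym),
                                    c(0, g$bridge_y2)) <=
             g$bridge_half_width, axis = c(-s, s)),
      list(inside = abs(pos[1]) <= g$bridge_half_width &&
             pos[2] >= g$bridge_y2 && pos[2] <= g$bridge_y_food,
           axis = c(0, 1)),
      list(inside = sqrt(pos[1]^2 + (pos[2] - g$bridge_y_nest)^2) <=
             g$bridge_region_r, axis = c(0, 1)),
      list(inside = sqrt(pos[1]^2 + (pos[2] - g$bridge_y_food)^2) <=
             g$bridge_region_r, axis = c(0, 1)))
    sgn <- if (from_food) -1 else 1
    hx <- cos(deg2rad(heading)); hy <- sin(deg2rad(heading))
    best <- -2; bh <- heading
    for (p in parts) {
      if (!p$inside) next
      ax <- sgn * p$axis[1]; ay <- sgn * p$axis[2]
      dot <- ax * hx + ay * hy
      if (dot > best) { best <- dot; bh <- rad2deg(atan2(ay, ax)) }
    }
    bh
  }
}

dist_to_segment <- function(p, a, b) {
  v <- b - a
  t <- sum((p - a) * v) / sum(v^2)
  t <- min(max(t, 0), 1)
  sqrt(sum((p - a - t * v)^2))
}

#' Run the binary-bridge simulation
#'
#' Simulates the bridge for `minutes` of simulated time, recording
#' per-second counts of in-world agents on each branch (an agent is "on a
#' branch" when inside a branch capsule and clear of the central stem
#' column) and summarising them as percentages over 3-minute windows.
#'
#' @param config a bridge [world_config()].
#' @param minutes simulated minutes.
#' @param window_s summary window in seconds.
#' @param world optional starting `world_state` (e.g. with a pre-laid
#'   field); a fresh empty world by default.
#' @return A list: `counts` (per-second `t_s, n_left, n_right,
#'   n_elsewhere, n_in_world`), `windows` (per-window branch percentages),
#'   `state` (final world), `moves`.
#' @export
run_bridge <- function(config, minutes = 60, window_s = 180, world = NULL) {
  stopifnot(config$geometry == 1L)
  if (is.null(world)) world <- init_world(config)
  n_steps <- as.integer(round(minutes * 60 / config$dt))
  res <- abm_run_cpp(world, unclass(config), n_steps, TRUE, FALSE, 0L)
  counts <- as.data.frame(res$counts)
  list(counts = counts, windows = branch_fractions(counts, window_s),
       state = structure(res$state, class = "world_state"),
       moves = res$state$moves)
}

#' Branch percentages in fixed time windows
#'
#' Aggregates per-second branch counts into windows, reporting the
#' percentage of branch-resident agents on each branch (seconds with no
#' agents on either branch contribute nothing to the window).
#'
#' @param counts per-second counts from [run_bridge()].
#' @param window_s window length in seconds (180 = 3 minutes).
#' @export
branch_fractions <- function(counts, window_s = 180) {
  w <- floor((counts$t_s - 1e-9) / window_s)
  agg <- function(v) tapply(v, w, sum)
  nl <- agg(counts$n_left); nr <- agg(counts$n_right)
  tot <- nl + nr
  data.frame(window = as.integer(names(nl)),
             t_mid_s = (as.integer(names(nl)) + 0.5) * window_s,
             pct_left = 100 * nl / pmax(tot, 1),
             pct_right = 100 * nr / pmax(tot, 1),
             n_branch_seconds = tot)
}

#' Plateau percentage on the majority branch
#'
#' The majority branch is the side with the larger mean share over the
#' final `n_final` windows; returns its mean percentage over those windows.
#'
#' @param windows window table from [branch_fractions()].
#' @param n_final number of final windows to average.
#' @export
plateau_majority <- function(windows, n_final = 5) {
  tailw <- utils::tail(windows, n_final)
  mean(pmax(0, if (mean(tailw$pct_left) >= mean(tailw$pct_right))
    tailw$pct_left else tailw$pct_right))
}

#' Run the open-arena simulation
#'
#' Simulates trail formation in the circular arena, recording the spatial
#' Gini coefficient of the pheromone field at 5-minute checkpoints and,
#' optionally, summed per-second occupancy images per checkpoint interval
#' (the arena-level "photographs" of the simulated trails).
#'
#' @param config an arena [world_config()].
#' @param minutes simulated minutes.
#' @param checkpoint_minutes checkpoint spacing.
#' @param record_occupancy accumulate per-checkpoint occupancy images.
#' @return A list: `gini` (`t_s, gini`), `occupancy` (list of integer
#'   matrices), `counts` (per-second in-world totals), `state`.
#' @export
run_open_arena <- function(config, minutes = 60, checkpoint_minutes = 5,
                           record_occupancy = TRUE) {
  stopifnot(config$geometry == 0L)
  world <- init_world(config)
  n_steps <- as.integer(round(minutes * 60 / config$dt))
  cp <- as.integer(round(checkpoint_minutes * 60 / config$dt))
  res <- abm_run_cpp(world, unclass(config), n_steps, TRUE, record_occupancy,
                     cp)
  list(gini = data.frame(t_s = res$gini_t, gini = res$gini),
       occupancy = res$occupancy,
       counts = as.data.frame(res$counts),
       state = structure(res$state, class = "world_state"))
}

#' Write occupancy images as PNG artifacts
#'
#' Renders each summed-occupancy checkpoint image (log scale) to
#' `occupancy_XX.png` under `dir`, for visual inspection of simulated
#' trails.
#'
#' @param occupancy list of integer matrices from [run_open_arena()].
#' @param dir output directory.
#' @export
write_occupancy_images <- function(occupancy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(occupancy))
  for (k in seq_along(occupancy)) {
    paths[k] <- file.path(dir, sprintf("occupancy_%02d.png", k))
    png(paths[k], width = 600, height = 600)
    op <- graphics::par(mar = c(0, 0, 0, 0))
    graphics::image(log1p(occupancy[[k]]), col = gray(seq(1, 0, length.out = 64)),
                    axes = FALSE, useRaster = TRUE)
    graphics::par(op)
    dev.off()
  }
  invisible(paths)
}
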