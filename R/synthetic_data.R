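#' Ground-truth parameters for synthetic trajectory generation
#'
#' Encodes the generative turning rule: above the detection threshold
#' `C0` the turning angle per 0.4 s update is
#' `A * (CL - CR) / (CL + CR) + N(0, noise_sd)` (a Weber response with
#' slope-concentration exponent -1); below it the turn is pure exploratory
#' noise of SD `wide_sd`. Agents move at constant `speed`.
#'
#' @param A amplitude in degrees.
#' @param C0 detection threshold in pheromone units.
#' @param noise_sd response noise SD, degrees.
#' @param wide_sd below-threshold noise SD, degrees.
#' @param speed agent speed in mm/s (~2 cm/s as observed).
#' @export
synthetic_truth <- function(A = 35, C0 = 50, noise_sd = 35, wide_sd = 35,
                            speed = 20) {
  stopifnot(noise_sd >= 0, wide_sd >= 0, speed > 0, C0 >= 0)
  structure(list(A = A, C0 = C0, noise_sd = noise_sd, wide_sd = wide_sd,
                 speed = speed, exponent = -1), class = "synthetic_truth")
}

#' Deterministic test fields
#'
#' Simple pheromone patterns with known structure: `uniform` (constant
#' value), `single_trail` (a straight ridge with Gaussian cross-section
#' through `point` along `angle`), `cross_trails` (sum of two single
#' trails) and `gradient` (linear ramp along +x).
#'
#' @param pattern one of `"uniform"`, `"single_trail"`, `"cross_trails"`,
#'   `"gradient"`.
#' @param nrow,ncol grid size in cells.
#' @param cell_size mm per cell.
#' @param value uniform value / gradient maximum.
#' @param peak ridge peak height (units).
#' @param width ridge Gaussian SD (mm).
#' @param point a point on the ridge line (mm); defaults to the grid
#'   centre.
#' @param angle ridge direction in degrees.
#' @param angle2 second ridge direction for `cross_trails`.
#' @return A [pheromone_field()].
#' @export
gen_static_field <- function(pattern = c("uniform", "single_trail",
                                         "cross_trails", "gradient"),
                             nrow = 200, ncol = 200, cell_size = 1,
                             value = 1, peak = 200, width = 3,
                             point = NULL, angle = 0, angle2 = 90) {
  pattern <- match.arg(pattern)
  cx <- (seq_len(ncol) - 0.5) * cell_size
  cy <- (seq_len(nrow) - 0.5) * cell_size
  if (is.null(point)) point <- c(ncol, nrow) * cell_size / 2
  ridge <- function(ang) {
    u <- c(cos(deg2rad(ang)), sin(deg2rad(ang)))
    # distance from cell centre to the line through `point` along u
    dx <- outer(rep(1, nrow), cx - point[1])
    dy <- outer(cy - point[2], rep(1, ncol))
    d <- abs(dx * u[2] - dy * u[1])
    peak * exp(-d^2 / (2 * width^2))
  }
  g <- switch(pattern,
    uniform = matrix(value, nrow, ncol),
    single_trail = ridge(angle),
    cross_trails = ridge(angle) + ridge(angle2),
    gradient = outer(rep(1, nrow), value * (cx - min(cx)) /
                       max(cx - min(cx))))
  pheromone_field(g, cell_size = cell_size)
}

#' Generate Weber-responding synthetic trajectories
#'
#' Simulates `n_ants` agents at 25 Hz in a rectangular arena. Every 0.4 s
#' (10 frames) each agent turns according to the truth rule evaluated on
#' the pheromone map *as it was `lag` seconds earlier* — the same lagged
#' quantity the inference pipeline annotates — either on a co-evolving
#' passage-count field laid down by the agents themselves (default) or on
#' a supplied static field. Every drawn turn is logged with the `CL`, `CR`
#' it used, giving the recovery oracle. Turns whose straight segment would
#' leave the arena are redirected towards the centre and flagged `wall`.
#'
#' @param truth a [synthetic_truth()].
#' @param n_ants number of agents.
#' @param duration seconds of simulated time.
#' @param arena `c(width, height)` in mm.
#' @param fps frames per second (25; turns every 10 frames).
#' @param field optional static [pheromone_field()]; when supplied the
#'   field does not co-evolve and no deposits are laid.
#' @param half_life evaporation half-life of the co-evolving field (s).
#' @param lag response look-back in seconds.
#' @param radius,half_angle sensing sector geometry (mm / degrees).
#' @param cell_size grid cell size of the co-evolving field (mm).
#' @return A list: `trajectories` (`ant_id, t_s, x_mm, y_mm`),
#'   `truth_log` (`event_idx, ant_id, t_s, dalpha_true, CL_true, CR_true,
#'   above_threshold, wall`), and the generation parameters.
#' @export
gen_weber_trajectories <- function(truth, n_ants = 100, duration = 600,
                                   arena = c(500, 500), fps = 25,
                                   field = NULL, half_life = Inf, lag = 16,
                                   radius = 10, half_angle = 45,
                                   cell_size = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  static <- NULL
  if (!is.null(field)) {
    stopifnot(inherits(field, "pheromone_field"))
    static <- field$grid
    arena <- c(ncol(field$grid), nrow(field$grid)) * field$cell_size
    cell_size <- field$cell_size
  }
  res <- gen_weber_traj_cpp(
    as.integer(n_ants), duration, fps, truth$speed, truth$A,
    truth$noise_sd, truth$wide_sd, truth$C0, lag, 10L, arena[1], arena[2],
    cell_size, 1, half_life, radius, half_angle, static)
  traj <- data.frame(ant_id = res$ant_id, t_s = res$t_s, x_mm = res$x_mm,
                     y_mm = res$y_mm)
  lg <- as.data.frame(res$log)
  lg <- cbind(event_idx = seq_len(nrow(lg)), lg)
  lg$above_threshold <- as.logical(lg$above_threshold)
  lg$wall <- as.logical(lg$wall)
  list(trajectories = traj, truth_log = lg, truth = truth,
       params = list(n_ants = n_ants, duration = duration, arena = arena,
                     fps = fps, half_life = half_life, lag = lag,
                     radius = radius, half_angle = half_angle,
                     cell_size = cell_size, static = !is.null(field)))
}

#' Generate pheromone-independent null trajectories
#'
#' Pure directional random walks: the same motion model as
#' [gen_weber_trajectories()] with the pheromone coupling switched off
#' (`A = 0`, threshold infinite, so every turn is `N(0, wide_sd)` noise).
#' Used for null tests — band slopes indistinguishable from 0, flat
#' correlation maps, speed medians flat across concentration bands.
#'
#' @inheritParams gen_weber_trajectories
#' @param wide_sd turning noise SD, degrees.
#' @param speed agent speed, mm/s.
#' @export
gen_null_trajectories <- function(n_ants = 100, duration = 600,
                                  arena = c(500, 500), fps = 25,
                                  wide_sd = 35, speed = 20) {
  truth <- synthetic_truth(A = 0, C0 = Inf, noise_sd = wide_sd,
                           wide_sd = wide_sd, speed = speed)
  gen_weber_trajectories(truth, n_ants = n_ants, duration = duration,
                         arena = arena, fps = fps)
}
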