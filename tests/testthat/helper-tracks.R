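# Analytic trajectory builders used across tests.

# straight constant-velocity track: speed in mm/s, heading in degrees
straight_track <- function(ant_id = 1, n_frames = 100, fps = 25,
                           speed = 20, heading = 0, start = c(50, 50)) {
  tt <- (seq_len(n_frames) - 1) / fps
  data.frame(ant_id = ant_id, t_s = tt,
             x_mm = start[1] + speed * tt * cos(heading * pi / 180),
             y_mm = start[2] + speed * tt * sin(heading * pi / 180))
}

# piecewise-straight track that turns by `turn` degrees at every segment
# boundary (every `seg` frames), mimicking the generator's motion model
turning_track <- function(turns, seg = 10, fps = 25, speed = 20,
                          start = c(100, 100), heading0 = 0, ant_id = 1) {
  hd <- heading0 + cumsum(c(0, turns))
  x <- start[1]; y <- start[2]
  xs <- x; ys <- y
  for (h in hd) {
    for (i in seq_len(seg)) {
      x <- x + speed / fps * cos(h * pi / 180)
      y <- y + speed / fps * sin(h * pi / 180)
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  n <- length(xs)
  data.frame(ant_id = ant_id, t_s = (seq_len(n) - 1) / fps, x_mm = xs,
             y_mm = ys)
}

# events table built directly (for fit-level tests that do not need
# trajectories)
make_events <- function(CL, CR, dalpha, speed = 2, t0 = NULL, ant = 1L) {
  n <- length(dalpha)
  if (is.null(t0)) t0 <- seq_len(n) * 0.8
  structure(data.frame(
    ant_id = rep_len(ant, n), t0_s = t0, x_mm = 0, y_mm = 0,
    heading_pre_deg = 0, heading_post_deg = dalpha, dalpha_deg = dalpha,
    disp_pre_mm = 8, disp_post_mm = 8, speed_cms = rep_len(speed, n),
    CL = CL, CR = CR), class = c("tracking_events", "data.frame"))
}

# standard small synthetic run shared by a few tests
small_weber_run <- function(seed = 1, n_ants = 40, duration = 300,
                            arena = c(300, 300)) {
  set.seed(seed)
  gen <- gen_weber_trajectories(synthetic_truth(), n_ants = n_ants,
                                duration = duration, arena = arena)
  gen
}
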