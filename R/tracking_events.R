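#' Extract tracking events from trajectories
#'
#' The unit of analysis is a tracking event: every `cadence_frames` frames an
#' ant's position is marked, the ant is followed for `segment_frames` frames,
#' marked again, followed for `segment_frames` more frames and marked a third
#' time. Each segment's heading is the chord between its end marks; the
#' turning angle `dalpha` is the wrapped heading difference (degrees,
#' anticlockwise positive, so positive angles are left turns). The event is
#' anchored at the middle mark: `t0` and `(x, y)` are the time and position
#' at the junction between the two segments. Speed is the post-segment
#' displacement over the segment duration, in cm/s.
#'
#' Trajectories shorter than one event window yield no events; events whose
#' marks contain missing positions are skipped (count in attribute
#' `n_skipped`).
#'
#' @param traj trajectory data frame (`ant_id, t_s, x_mm, y_mm`) sampled at
#'   `frame_rate`.
#' @param frame_rate frames per second (default 25).
#' @param cadence_frames frames between event starts (default 20, i.e.
#'   0.8 s).
#' @param segment_frames frames per segment (default 10, i.e. 0.4 s).
#' @param exclude_encounters drop events during which another ant comes
#'   within `encounter_radius` mm (off by default; synthetic agents do not
#'   interact).
#' @param encounter_radius encounter distance in mm.
#' @return A `tracking_events` data frame with `CL`/`CR` unset (`NA`) until
#'   [annotate_concentrations()] fills them.
#' @export
extract_events <- function(traj, frame_rate = 25, cadence_frames = 20,
                           segment_frames = 10, exclude_encounters = FALSE,
                           encounter_radius = 5) {
  check_trajectories(traj)
  traj <- traj[order(traj$ant_id, traj$t_s), , drop = FALSE]
  out <- lapply(split(traj, traj$ant_id), function(tr) {
    n <- nrow(tr)
    if (n < 2 * segment_frames + 1) return(NULL)
    i0 <- seq(1L, n - 2L * segment_frames, by = cadence_frames)
    i1 <- i0 + segment_frames
    i2 <- i1 + segment_frames
    dx1 <- tr$x_mm[i1] - tr$x_mm[i0]; dy1 <- tr$y_mm[i1] - tr$y_mm[i0]
    dx2 <- tr$x_mm[i2] - tr$x_mm[i1]; dy2 <- tr$y_mm[i2] - tr$y_mm[i1]
    h_pre <- rad2deg(atan2(dy1, dx1))
    h_post <- rad2deg(atan2(dy2, dx2))
    seg_s <- segment_frames / frame_rate
    data.frame(
      ant_id = tr$ant_id[i1], t0_s = tr$t_s[i1],
      x_mm = tr$x_mm[i1], y_mm = tr$y_mm[i1],
      heading_pre_deg = h_pre, heading_post_deg = h_post,
      dalpha_deg = wrap180(h_post - h_pre),
      disp_pre_mm = sqrt(dx1^2 + dy1^2),
      disp_post_mm = sqrt(dx2^2 + dy2^2),
      speed_cms = sqrt(dx2^2 + dy2^2) / seg_s / 10,
      CL = NA_real_, CR = NA_real_)
  })
  ev <- do.call(rbind, out)
  if (is.null(ev)) ev <- empty_events()
  rownames(ev) <- NULL
  ok <- stats::complete.cases(ev[, c("x_mm", "y_mm", "heading_pre_deg",
                                     "heading_post_deg", "dalpha_deg")])
  n_skipped <- sum(!ok)
  ev <- ev[ok, , drop = FALSE]
  if (exclude_encounters && nrow(ev) > 0)
    ev <- drop_encounters(ev, traj, frame_rate, segment_frames,
                          encounter_radius)
  structure(ev, n_skipped = n_skipped,
            class = c("tracking_events", "data.frame"))
}

empty_events <- function() {
  ev <- data.frame(ant_id = integer(), t0_s = numeric(), x_mm = numeric(),
                   y_mm = numeric(), heading_pre_deg = numeric(),
                   heading_post_deg = numeric(), dalpha_deg = numeric(),
                   disp_pre_mm = numeric(), disp_post_mm = numeric(),
                   speed_cms = numeric(), CL = numeric(), CR = numeric())
  ev
}

# conservative encounter filter: drop events whose window overlaps a time at
# which any other ant is within `radius` mm of the focal ant
drop_encounters <- function(ev, traj, frame_rate, segment_frames, radius) {
  win <- segment_frames / frame_rate
  keep <- vapply(seq_len(nrow(ev)), function(k) {
    tt <- traj[traj$t_s >= ev$t0_s[k] - win & traj$t_s <= ev$t0_s[k] + win, ]
    others <- tt[tt$ant_id != ev$ant_id[k], ]
    if (nrow(others) == 0) return(TRUE)
    all(sqrt((others$x_mm - ev$x_mm[k])^2 +
               (others$y_mm - ev$y_mm[k])^2) > radius)
  }, logical(1))
  ev[keep, , drop = FALSE]
}

#' Filter out barely-moving events
#'
#' Retains events whose two segment displacements are both at least
#' `min_disp` mm (default 4 mm = 0.4 cm); direction and turning angle are
#' unreliable below that. Retained/discarded counts are attached as
#' attributes `n_retained` / `n_discarded`.
#'
#' @param events a `tracking_events` data frame.
#' @param min_disp minimum displacement per segment, mm.
#' @export
filter_events <- function(events, min_disp = 4) {
  stopifnot(min_disp >= 0)
  keep <- events$disp_pre_mm >= min_disp & events$disp_post_mm >= min_disp
  out <- events[keep, , drop = FALSE]
  structure(out, n_retained = sum(keep), n_discarded = sum(!keep),
            class = c("tracking_events", "data.frame"))
}

#' Annotate events with lagged left/right pheromone sums
#'
#' Fills `CL` and `CR` with the total pheromone in the front-left and
#' front-right sectors (radius `radius`, each spanning `2 * half_angle`
#' degrees) at the event position and pre-segment heading, evaluated on the
#' pheromone map as it was `lag` seconds before the event. The lag avoids
#' correlating an ant's turn with the pheromone it itself just deposited.
#'
#' @param events a `tracking_events` data frame.
#' @param field either a static [pheromone_field()] (used as-is for every
#'   event) or a [field_replayer()], which reproduces the field at
#'   `t0 - lag` exactly by replaying deposits.
#' @param lag look-back in seconds (default 16). Events with `t0 - lag < 0`
#'   are dropped (count in attribute `n_dropped_lag`); with a static field
#'   the lag is irrelevant and nothing is dropped.
#' @param radius sector radius in mm.
#' @param half_angle sector half-opening in degrees (45 = 90-degree
#'   sectors).
#' @export
annotate_concentrations <- function(events, field, lag = 16, radius = 10,
                                    half_angle = 45) {
  n_dropped <- 0L
  if (inherits(field, "pheromone_field")) {
    ext <- field_extent(field)
    out_of_grid <- events$x_mm < ext$xlim[1] | events$x_mm > ext$xlim[2] |
      events$y_mm < ext$ylim[1] | events$y_mm > ext$ylim[2]
    if (any(out_of_grid))
      stop(sprintf("event position (%g, %g) is outside the grid",
                   events$x_mm[which(out_of_grid)[1]],
                   events$y_mm[which(out_of_grid)[1]]))
    cc <- static_annotate(events, field, radius, half_angle)
  } else if (inherits(field, "field_replayer")) {
    keep <- events$t0_s - lag >= -1e-9
    n_dropped <- sum(!keep)
    events <- events[keep, , drop = FALSE]
    ord <- order(events$t0_s)
    st <- field$stream
    cc <- matrix(NA_real_, nrow(events), 2)
    cc[ord, ] <- replay_annotate_cpp(
      st$t, st$cell, st$dq, field$dim_rc[1], field$dim_rc[2],
      field$cell_size, field$origin[1], field$origin[2], field$half_life,
      events$x_mm[ord], events$y_mm[ord], events$heading_pre_deg[ord],
      events$t0_s[ord] - lag, radius, half_angle)
  } else {
    stop("`field` must be a pheromone_field or a field_replayer")
  }
  events$CL <- cc[, 1]
  events$CR <- cc[, 2]
  structure(events, n_dropped_lag = n_dropped,
            class = c("tracking_events", "data.frame"))
}

static_annotate <- function(events, field, radius, half_angle) {
  n <- nrow(events)
  cc <- matrix(0, n, 2)
  for (k in seq_len(n)) {
    cc[k, 1] <- sector_sum_cpp(field$grid, field$cell_size, field$origin[1],
                               field$origin[2], events$x_mm[k],
                               events$y_mm[k], events$heading_pre_deg[k],
                               0, 2 * half_angle, TRUE, TRUE, radius)
    cc[k, 2] <- sector_sum_cpp(field$grid, field$cell_size, field$origin[1],
                               field$origin[2], events$x_mm[k],
                               events$y_mm[k], events$heading_pre_deg[k],
                               -2 * half_angle, 0, TRUE, FALSE, radius)
  }
  cc
}

#' Restrict events to an interior analysis region
#'
#' Keeps events whose anchor position lies inside the given rectangle.
#' Mirrors the experimental design, where individual behaviour is analysed
#' only within the camera's field of view well away from the arena border:
#' near a wall, which turns an ant can complete depends on the wall, which
#' biases response estimates there.
#'
#' @param events a `tracking_events` data frame.
#' @param xlim,ylim analysis-region bounds in mm.
#' @export
clip_events <- function(events, xlim, ylim) {
  keep <- events$x_mm >= xlim[1] & events$x_mm <= xlim[2] &
    events$y_mm >= ylim[1] & events$y_mm <= ylim[2]
  structure(events[keep, , drop = FALSE],
            class = c("tracking_events", "data.frame"))
}
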