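#' Read and write trajectory tables
#'
#' Trajectories are tabular time-stamped positions with columns
#' `ant_id, t_s, x_mm, y_mm` (UTF-8 CSV, `.` decimal). Rows are normalized to
#' (ant_id, t_s) order on read, with a warning if the file was shuffled;
#' duplicated or otherwise non-increasing time stamps within an ant are an
#' error naming the offending row. Round-trips are lossless to well below
#' 1e-6 mm.
#'
#' @param path CSV file path.
#' @return A data frame with the four trajectory columns.
#' @export
read_trajectories <- function(path) {
  traj <- utils::read.csv(path)
  need <- c("ant_id", "t_s", "x_mm", "y_mm")
  miss <- setdiff(need, names(traj))
  if (length(miss))
    stop("missing trajectory column(s): ", paste(miss, collapse = ", "))
  traj <- traj[, need]
  if (nrow(traj) == 0) return(traj)
  ord <- order(traj$ant_id, traj$t_s)
  if (any(ord != seq_len(nrow(traj)))) {
    warning("trajectory rows were not sorted by (ant_id, t_s); re-sorting")
    traj <- traj[ord, , drop = FALSE]
    rownames(traj) <- NULL
  }
  same_ant <- traj$ant_id[-1] == traj$ant_id[-nrow(traj)]
  dup <- which(diff(traj$t_s) <= 0 & same_ant)
  if (length(dup))
    stop(sprintf("non-monotone time for ant %s at row %d",
                 traj$ant_id[dup[1] + 1], dup[1] + 1L))
  traj
}

#' @rdname read_trajectories
#' @param traj trajectory data frame.
#' @export
write_trajectories <- function(traj, path) {
  check_trajectories(traj)
  utils::write.csv(traj[, c("ant_id", "t_s", "x_mm", "y_mm")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_trajectories <- function(traj) {
  need <- c("ant_id", "t_s", "x_mm", "y_mm")
  miss <- setdiff(need, names(traj))
  if (length(miss))
    stop("missing trajectory column(s): ", paste(miss, collapse = ", "))
  invisible(traj)
}

#' Read and write tracking-event tables
#'
#' Events use the CSV dialect `ant_id,t0_s,x_mm,y_mm,heading_pre_deg,`
#' `heading_post_deg,dalpha_deg,disp_pre_mm,disp_post_mm,speed_cms,CL,CR`.
#'
#' @param path CSV file path.
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path)
  need <- event_columns()
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("missing event column(s): ", paste(miss, collapse = ", "))
  class(ev) <- c("tracking_events", "data.frame")
  ev
}

#' @rdname read_events
#' @param events events data frame.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events)[, event_columns()], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

event_columns <- function() {
  c("ant_id", "t0_s", "x_mm", "y_mm", "heading_pre_deg", "heading_post_deg",
    "dalpha_deg", "disp_pre_mm", "disp_post_mm", "speed_cms", "CL", "CR")
}

write_manifest <- function(out_dir, config, seed) {
  manifest <- list(
    package = "stigmergy",
    version = as.character(utils::packageVersion("stigmergy")),
    seed = seed,
    config = config,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

#' Run one pipeline stage
#'
#' Dispatches one of the pipeline stages on a configuration list (or a YAML
#' file holding one), writes its outputs plus a `manifest.json` (config echo,
#' package version, seed) into `config$out`, and returns the stage result
#' invisibly. Stages: `generate_synthetic`, `build_field`, `extract_events`,
#' `fit_weber`, `correlation_map`, `simulate_bridge`, `simulate_arena`,
#' `bifurcation`. Runs are deterministic given `config$seed`.
#'
#' @param config named list with at least `stage` and `out`, or the path to
#'   a YAML file holding one.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$stage), !is.null(config$out))
  stage <- config$stage
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  res <- tryCatch(
    switch(stage,
      generate_synthetic = stage_generate_synthetic(config, out),
      build_field = stage_build_field(config, out),
      extract_events = stage_extract_events(config, out),
      fit_weber = stage_fit_weber(config, out),
      correlation_map = stage_correlation_map(config, out),
      simulate_bridge = stage_simulate_bridge(config, out),
      simulate_arena = stage_simulate_arena(config, out),
      bifurcation = stage_bifurcation(config, out),
      stop("unknown stage: ", stage)),
    error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  write_manifest(out, config, seed)
  invisible(res)
}

cfg <- function(config, name, default) {
  if (is.null(config[[name]])) default else config[[name]]
}

stage_generate_synthetic <- function(config, out) {
  truth <- do.call(synthetic_truth, cfg(config, "truth", list()))
  gen <- gen_weber_trajectories(
    truth, n_ants = cfg(config, "n_ants", 100),
    duration = cfg(config, "duration", 600),
    arena = unlist(cfg(config, "arena", c(500, 500))))
  write_trajectories(gen$trajectories, file.path(out, "trajectories.csv"))
  utils::write.csv(gen$truth_log, file.path(out, "truth_log.csv"),
                   row.names = FALSE, quote = FALSE)
  gen
}

stage_build_field <- function(config, out) {
  traj <- read_trajectories(config$trajectories)
  fld <- field_from_trajectories(
    traj, half_life = cfg(config, "half_life", Inf),
    until = cfg(config, "until", NULL))
  write_field(fld, file.path(out, "field"))
  fld
}

stage_extract_events <- function(config, out) {
  traj <- read_trajectories(config$trajectories)
  ev <- extract_events(traj)
  ev <- filter_events(ev, min_disp = cfg(config, "min_disp", 4))
  hist <- field_replayer(traj, half_life = cfg(config, "half_life", Inf))
  ev <- annotate_concentrations(ev, hist, lag = cfg(config, "lag", 16))
  write_events(ev, file.path(out, "events.csv"))
  ev
}

stage_fit_weber <- function(config, out) {
  ev <- read_events(config$events)
  threshold <- cfg(config, "threshold", 50)
  slopes <- band_slope_fit(ev, n_bands = cfg(config, "bands", 6),
                           threshold = threshold)
  pl <- powerlaw_fit(slopes, min_sumC = threshold)
  dw <- direct_weber_fit(ev, C0 = threshold)
  utils::write.csv(as.data.frame(slopes), file.path(out, "band_slopes.csv"),
                   row.names = FALSE)
  fit <- list(
    banded_powerlaw = list(A = pl$A, nu = pl$nu, nu_ci95 = pl$nu_ci,
                           A_ci95 = pl$A_ci, n_bands = pl$n_bands),
    direct = list(A = dw$A, C0 = dw$C0, A_ci95 = dw$ci95,
                  resid_sd = dw$resid_sd, n = dw$n))
  jsonlite::write_json(fit, file.path(out, "weber_fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(slopes = slopes, powerlaw = pl, direct = dw)
}

stage_correlation_map <- function(config, out) {
  ev <- read_events(config$events)
  traj <- read_trajectories(config$trajectories)
  hist <- field_replayer(traj, half_life = cfg(config, "half_life", Inf))
  cm <- correlation_map(ev, hist, lag = cfg(config, "lag", 16))
  utils::write.csv(as.data.frame(cm), file.path(out, "correlation_map.csv"),
                   row.names = FALSE)
  cm
}

stage_simulate_bridge <- function(config, out) {
  wc <- do.call(world_config,
                c(list(geometry = "bridge"), cfg(config, "world", list())))
  run <- run_bridge(wc, minutes = cfg(config, "minutes", 60))
  utils::write.csv(run$counts, file.path(out, "branch_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(run$windows, file.path(out, "branch_windows.csv"),
                   row.names = FALSE)
  run
}

stage_simulate_arena <- function(config, out) {
  wc <- do.call(world_config,
                c(list(geometry = "arena"), cfg(config, "world", list())))
  run <- run_open_arena(wc, minutes = cfg(config, "minutes", 60))
  utils::write.csv(data.frame(t_s = run$gini$t_s, gini = run$gini$gini),
                   file.path(out, "field_gini.csv"), row.names = FALSE)
  if (length(run$occupancy))
    write_occupancy_images(run$occupancy, out)
  run
}

stage_bifurcation <- function(config, out) {
  params <- bridge_model_params(
    phi = 0, retire_rate = cfg(config, "retire_rate", 0.1),
    choice = do.call(choice_params, cfg(config, "choice", list())))
  phi_grid <- seq(cfg(config, "phi_min", 0.1), cfg(config, "phi_max", 5),
                  length.out = cfg(config, "points", 50))
  bd <- bifurcation_diagram(params, phi_grid)
  utils::write.csv(bd$points, file.path(out, "diagram.csv"),
                   row.names = FALSE)
  bd
}
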