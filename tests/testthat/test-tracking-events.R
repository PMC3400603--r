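test_that("straight tracks yield zero turning angles at the true speed", {
  traj <- straight_track(n_frames = 101, speed = 20, heading = 33)
  ev <- extract_events(traj)
  # event count bound: floor((n_frames - 2*segment)/cadence) + 1
  expect_lte(nrow(ev), floor((101 - 20) / 20) + 1)
  expect_equal(nrow(ev), 5)
  expect_equal(ev$dalpha_deg, rep(0, 5), tolerance = 1e-10)
  expect_equal(ev$speed_cms, rep(2, 5), tolerance = 1e-10)
  expect_equal(ev$disp_pre_mm, rep(8, 5), tolerance = 1e-10)
})

test_that("turning angles carry the anticlockwise-positive sign", {
  # one 90-degree left turn at the first segment boundary
  traj <- turning_track(c(90, 0, 0))
  ev <- extract_events(traj)
  expect_equal(ev$dalpha_deg[1], 90, tolerance = 1e-10)
  # right turn is negative
  trj2 <- turning_track(c(-90, 0, 0))
  expect_equal(extract_events(trj2)$dalpha_deg[1], -90, tolerance = 1e-10)
})

test_that("extraction round-trips the generator's ground-truth log", {
  gen <- small_weber_run(seed = 3)
  ev <- filter_events(extract_events(gen$trajectories))
  hist <- field_replayer(gen$trajectories,
                         extent = list(origin = c(0, 0),
                                       dim_rc = c(300, 300)))
  ev <- annotate_concentrations(ev, hist)
  m <- merge(as.data.frame(ev), gen$truth_log,
             by.x = c("ant_id", "t0_s"), by.y = c("ant_id", "t_s"))
  expect_gt(nrow(m), 1000)
  expect_lt(max(abs(m$dalpha_deg - m$dalpha_true)), 1e-8)
  expect_equal(m$CL, m$CL_true)
  expect_equal(m$CR, m$CR_true)
})

test_that("the displacement filter keeps exactly the moving events", {
  set.seed(4)
  n <- 500
  ev <- make_events(CL = runif(n), CR = runif(n), dalpha = rnorm(n))
  ev$disp_pre_mm <- runif(n, 0, 10)
  ev$disp_post_mm <- runif(n, 0, 10)
  # brute-force count
  keep <- ev$disp_pre_mm >= 4 & ev$disp_post_mm >= 4
  f <- filter_events(ev, 4)
  expect_equal(nrow(f), sum(keep))
  expect_equal(attr(f, "n_discarded"), sum(!keep))
  # an event moving 3 mm in one segment is discarded
  e1 <- make_events(0, 0, 0)
  e1$disp_pre_mm <- 3
  expect_equal(nrow(filter_events(e1)), 0)
  # min_disp = 0 is the identity
  expect_equal(nrow(filter_events(ev, 0)), n)
})

test_that("annotation fills lagged sector sums with the documented edge
           cases", {
  ev <- make_events(CL = NA, CR = NA, dalpha = rep(0, 4),
                    t0 = c(10, 20, 30, 40))
  ev$x_mm <- rep(50, 4); ev$y_mm <- rep(50, 4)
  # zero field: all zero
  z <- pheromone_field(matrix(0, 100, 100))
  a <- annotate_concentrations(ev, z)
  expect_equal(a$CL, rep(0, 4))
  expect_equal(a$CR, rep(0, 4))
  # pheromone only ahead-left (heading 0 = +x): CR = 0
  g <- matrix(0, 100, 100); g[55:58, 54:58] <- 5  # a patch ahead-left
  fl <- pheromone_field(g)
  b <- annotate_concentrations(ev, fl)
  expect_true(all(b$CL > 0))
  expect_equal(b$CR, rep(0, 4))
  # uniform field: CL ~ CR within a one-cell boundary layer
  u <- pheromone_field(matrix(1, 100, 100))
  cu <- annotate_concentrations(ev, u)
  expect_lt(max(abs(cu$CL - cu$CR)), 2 * 10 + pi * 5)
  # replayer: events before the lag are dropped and counted
  traj <- straight_track(n_frames = 1000)
  ee <- extract_events(traj)
  r <- field_replayer(traj, extent = list(origin = c(0, 0),
                                          dim_rc = c(900, 200)))
  an <- annotate_concentrations(ee, r, lag = 16)
  expect_equal(attr(an, "n_dropped_lag"), sum(ee$t0_s < 16))
  expect_true(all(an$t0_s >= 16))
})

test_that("mirror reflection negates turning angles and swaps sectors", {
  gen <- small_weber_run(seed = 5, n_ants = 10, duration = 120)
  traj <- gen$trajectories
  H <- 300
  mirrored <- transform(traj, y_mm = H - y_mm)
  ev <- filter_events(extract_events(traj))
  evm <- filter_events(extract_events(mirrored))
  expect_equal(evm$dalpha_deg, -ev$dalpha_deg, tolerance = 1e-9)
  ext <- list(origin = c(0, 0), dim_rc = c(H, 300))
  a <- annotate_concentrations(ev, field_replayer(traj, extent = ext))
  am <- annotate_concentrations(evm, field_replayer(mirrored, extent = ext))
  expect_equal(am$CL, a$CR)
  expect_equal(am$CR, a$CL)
})

test_that("missing positions skip events with a logged count", {
  traj <- straight_track(n_frames = 61)
  traj$x_mm[31] <- NA  # corrupts the middle mark of the second event
  ev <- extract_events(traj)
  expect_equal(attr(ev, "n_skipped"), 1L)
  expect_false(any(is.na(ev$dalpha_deg)))
})

test_that("short trajectories produce no events without error", {
  traj <- straight_track(n_frames = 15)
  ev <- extract_events(traj)
  expect_equal(nrow(ev), 0)
})

test_that("clip_events restricts to the interior analysis region", {
  ev <- make_events(CL = 1:5, CR = 1:5, dalpha = rep(0, 5))
  ev$x_mm <- c(10, 50, 100, 250, 290)
  ev$y_mm <- rep(150, 5)
  cl <- clip_events(ev, c(25, 275), c(25, 275))
  expect_equal(cl$x_mm, c(50, 100, 250))
})
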