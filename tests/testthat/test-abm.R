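test_that("the turning rule follows the thresholded Weber form", {
  cfg <- world_config("arena", sigma1 = 0, sigma2 = 0)
  # symmetric pheromone: no turn
  g <- matrix(10, 200, 200)
  cfg2 <- cfg; cfg2$origin_x <- 0; cfg2$origin_y <- 0
  tr <- turn_rule(c(100, 100), 0, g, cfg2)
  expect_equal(tr$dalpha, 0)
  expect_gt(tr$L, cfg$detection_threshold)
  # all pheromone on the left: maximal turn +A
  gl <- matrix(0, 200, 200)
  gl[111:125, 86:115] <- 10  # patch above the ant (left of heading 0)
  trl <- turn_rule(c(100, 100), 0, gl, cfg2)
  expect_equal(trl$R, 0)
  expect_equal(trl$dalpha, cfg$A)
  # below threshold: pure exploratory noise of SD sigma2
  cfgn <- world_config("arena", sigma2 = 35)
  cfgn$origin_x <- 0; cfgn$origin_y <- 0
  set.seed(20)
  draws <- replicate(4000, turn_rule(c(100, 100), 0,
                                     matrix(0, 200, 200), cfgn)$dalpha)
  expect_lt(abs(mean(draws)), 35 * 4 / sqrt(4000))
  expect_equal(sd(draws), 35, tolerance = 0.05)
})

test_that("a lone noise-free agent runs straight and lays 0.1 units per
           move", {
  cfg <- world_config("arena", n_ants = 1, sigma1 = 0, sigma2 = 0,
                      entry_prob = 0, return_prob = 0)
  w <- init_world(cfg)
  w$x[1] <- -100; w$y[1] <- 50; w$heading[1] <- 0; w$in_world[1] <- 1L
  w2 <- step_world(w, cfg, 50)
  expect_equal(w2$x[1], -100 + 50 * 2)
  expect_equal(w2$y[1], 50)
  expect_equal(w2$moves, 50)
  expect_equal(sum(w2$field), 0.1 * 50)
  # conservation with many stochastic agents and no evaporation
  cfg2 <- world_config("bridge", n_ants = 200)
  set.seed(21)
  w3 <- step_world(init_world(cfg2), cfg2, 3000)
  expect_equal(sum(w3$field), 0.1 * w3$moves, tolerance = 1e-9)
})

test_that("the border rule aligns with the minimum-change wall tangent", {
  cfg <- world_config("arena")
  # ant near the +x wall heading 30 degrees off the radial: the nearer
  # tangent is at +90; change must not exceed 90 degrees
  h <- border_rule(c(499, 0), 30, cfg)
  expect_equal(h, 90)
  h2 <- border_rule(c(499, 0), -30, cfg)
  expect_equal(h2, -90)
  # exact head-on impact breaks the tie towards the left tangent
  h3 <- border_rule(c(499, 0), 0, cfg)
  expect_equal(h3, 90)
  # bridge: a nest-bound... food-bound ant grazing the stem wall aligns
  # towards the food end; a returning ant towards the nest
  cfgb <- world_config("bridge")
  expect_equal(border_rule(c(9.5, 60), 20, cfgb, from_food = FALSE), 90)
  expect_equal(border_rule(c(9.5, 60), -160, cfgb, from_food = TRUE), -90)
})

test_that("entries follow the per-step entry probability", {
  cfg <- world_config("arena", n_ants = 1000, entry_prob = 1 / 1000,
                      return_prob = 0)
  set.seed(22)
  w <- step_world(init_world(cfg), cfg, 2000)
  entered <- sum(w$in_world)
  expected <- 1000 * (1 - (1 - 1 / 1000)^2000)
  expect_lt(abs(entered - expected), 4 * sqrt(1000 * 0.865 * 0.135))
})

test_that("same seed gives bit-identical runs", {
  cfg <- world_config("bridge")
  set.seed(23)
  r1 <- run_bridge(cfg, minutes = 3)
  set.seed(23)
  r2 <- run_bridge(cfg, minutes = 3)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$state$field, r2$state$field)
})

test_that("a noise-free agent on a straight pre-laid trail follows it", {
  cfg <- world_config("arena", n_ants = 1, sigma1 = 0, sigma2 = 0,
                      entry_prob = 0, return_prob = 0,
                      detection_threshold = 1)
  w <- init_world(cfg)
  # trail along y = 0 (grid rows centred on the x axis)
  mid <- nrow(w$field) / 2
  w$field[(mid - 1):(mid + 2), ] <- 5
  w$x[1] <- -200; w$y[1] <- 1.3; w$heading[1] <- 10; w$in_world[1] <- 1L
  w2 <- step_world(w, cfg, 150)
  expect_lt(abs(w2$y[1]), 4)   # stayed on the trail band
  expect_gt(w2$x[1], 50)       # kept moving along it
})

test_that("a mirrored initial deposit flips the chosen branch", {
  cfg <- world_config("bridge")
  seed_field <- function(side) {
    w <- init_world(cfg)
    # strong pre-laid deposit on one branch's lower half
    ym <- (cfg$bridge_y1 + cfg$bridge_y2) / 2
    xs <- round(seq(5, cfg$bridge_vertex_x - 5, by = 1))
    ys <- round(cfg$bridge_y1 + xs * (ym - cfg$bridge_y1) /
                  cfg$bridge_vertex_x)
    for (k in seq_along(xs)) {
      j <- floor((side * xs[k] - cfg$origin_x)) + 1
      i <- floor((ys[k] - cfg$origin_y)) + 1
      w$field[i, j] <- w$field[i, j] + 500
    }
    w
  }
  set.seed(24)
  wl <- run_bridge(cfg, minutes = 10, world = seed_field(-1))
  set.seed(24)
  wr <- run_bridge(cfg, minutes = 10, world = seed_field(1))
  pl <- utils::tail(wl$windows$pct_left, 1)
  pr <- utils::tail(wr$windows$pct_left, 1)
  expect_gt(pl, 60)
  expect_lt(pr, 40)
})
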