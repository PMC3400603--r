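test_that("band slopes equal the normal-equation solution and recover
           noiseless linear responses exactly", {
  set.seed(11)
  n <- 3000
  sumC <- runif(n, 60, 600)
  frac <- runif(n, -0.9, 0.9)
  CL <- sumC * (1 + frac) / 2; CR <- sumC * (1 - frac) / 2
  k0 <- 0.12
  ev <- make_events(CL, CR, dalpha = k0 * (CL - CR))
  bands <- data.frame(lo = c(60, 200), hi = c(200, 600),
                      mid = sqrt(c(60 * 200, 200 * 600)))
  sl <- band_slope_fit(ev, bands = bands, min_n = 100, n_boot = 50)
  expect_equal(sl$k, c(k0, k0), tolerance = 1e-12)
  # independent oracle: through-origin lm per band
  inb <- sumC >= 60 & sumC < 200
  k_lm <- unname(coef(lm(dalpha_deg ~ 0 + I(CL - CR), data = ev[inb, ])))
  expect_equal(sl$k[1], k_lm, tolerance = 1e-10)
  # null data: CI covers 0
  set.seed(12)
  ev0 <- make_events(CL, CR, dalpha = rnorm(n, 0, 20))
  sl0 <- band_slope_fit(ev0, bands = bands, min_n = 100, n_boot = 400)
  expect_true(all(sl0$ci_lo <= 0 & sl0$ci_hi >= 0))
  # small bands are flagged undefined
  tiny <- band_slope_fit(ev, bands = bands, min_n = n + 1, n_boot = 0)
  expect_true(all(!tiny$defined))
  expect_true(all(is.na(tiny$k)))
})

test_that("the log-log fit recovers exact power laws", {
  sl <- data.frame(lo = NA, hi = NA, mid = c(60, 120, 240, 480, 960),
                   defined = TRUE)
  sl$k <- 35 / sl$mid
  pl <- powerlaw_fit(sl)
  expect_equal(pl$nu, -1, tolerance = 1e-12)
  expect_equal(pl$A, 35, tolerance = 1e-9)
  sl$k <- 35 * sl$mid^(-0.5)
  expect_equal(powerlaw_fit(sl)$nu, -0.5, tolerance = 1e-12)
  # non-positive slopes are excluded with a warning
  sl$k[2] <- -0.1
  expect_warning(pl2 <- powerlaw_fit(sl), "non-positive")
  expect_equal(pl2$n_bands, 4)
  # too few usable bands errors
  expect_error(powerlaw_fit(sl[1:3, ]), "at least 3")
})

test_that("the direct Weber fit is exact on noiseless data and scale
           invariant", {
  set.seed(13)
  n <- 2000
  sumC <- runif(n, 60, 500)
  frac <- runif(n, -1, 1)
  CL <- sumC * (1 + frac) / 2; CR <- sumC * (1 - frac) / 2
  ev <- make_events(CL, CR, dalpha = 35 * (CL - CR) / (CL + CR))
  fit <- direct_weber_fit(ev, C0 = 50, n_boot = 0)
  expect_equal(fit$A, 35, tolerance = 1e-12)
  # all pheromone on one side: fitted A equals the mean turn magnitude
  side <- sample(c(-1, 1), n, replace = TRUE)
  ev1 <- make_events(CL = sumC * (side == 1), CR = sumC * (side == -1),
                     dalpha = side * 35 + rnorm(n, 0, 5))
  f1 <- direct_weber_fit(ev1, C0 = 50, n_boot = 0)
  expect_equal(f1$A, mean(ev1$dalpha_deg * side), tolerance = 1e-10)
  expect_lt(abs(f1$A - 35), 1)
  # multiplying all concentrations and the threshold by 10 leaves A fixed
  ev10 <- ev
  ev10$CL <- ev$CL * 10; ev10$CR <- ev$CR * 10
  expect_equal(direct_weber_fit(ev10, C0 = 500, n_boot = 0)$A, fit$A)
  # profiled threshold locates a planted hard threshold
  below <- make_events(CL = runif(n, 5, 20), CR = runif(n, 5, 20),
                       dalpha = rnorm(n, 0, 5))
  evt <- rbind(ev, below)
  class(evt) <- c("tracking_events", "data.frame")
  pf <- direct_weber_fit(evt, profile = TRUE, n_boot = 0)
  expect_gt(pf$C0, 35)
  expect_lt(pf$C0, 80)
  expect_error(direct_weber_fit(ev, C0 = 1e9), "above")
})

test_that("antisymmetry: negating angles and swapping sides flips the
           fitted response", {
  gen <- small_weber_run(seed = 14)
  ev <- filter_events(extract_events(gen$trajectories))
  hist <- field_replayer(gen$trajectories,
                         extent = list(origin = c(0, 0),
                                       dim_rc = c(300, 300)))
  ev <- annotate_concentrations(ev, hist)
  # mirror image (negate angles AND swap sides): estimates are invariant,
  # because both sign flips cancel in the through-origin regression
  mir <- ev
  mir$dalpha_deg <- -ev$dalpha_deg
  mir$CL <- ev$CR; mir$CR <- ev$CL
  bands <- make_bands(ev, n_bands = 3, threshold = 10)
  a <- band_slope_fit(ev, bands = bands, min_n = 50, n_boot = 0)
  b <- band_slope_fit(mir, bands = bands, min_n = 50, n_boot = 0)
  expect_equal(b$k, a$k)
  # a single flip (swap sides, keep angles) reverses the sign
  sw <- ev
  sw$CL <- ev$CR; sw$CR <- ev$CL
  c_ <- band_slope_fit(sw, bands = bands, min_n = 50, n_boot = 0)
  expect_equal(c_$k, -a$k)
  expect_equal(direct_weber_fit(sw, C0 = 10, n_boot = 0)$A,
               -direct_weber_fit(ev, C0 = 10, n_boot = 0)$A)
  # lambda-scaling: k scales as 1/lambda, exponent unchanged
  sc <- ev
  sc$CL <- ev$CL * 4; sc$CR <- ev$CR * 4
  bands4 <- bands; bands4$lo <- bands$lo * 4; bands4$hi <- bands$hi * 4
  bands4$mid <- bands$mid * 4
  k4 <- band_slope_fit(sc, bands = bands4, min_n = 50, n_boot = 0)$k
  expect_equal(k4, a$k / 4, tolerance = 1e-10)
})

test_that("the correlation map recovers a planted probe offset and stays
           inside the permutation band under shuffling", {
  set.seed(15)
  f <- gen_static_field("cross_trails", nrow = 200, ncol = 200, peak = 200,
                        width = 4, angle = 25, angle2 = 115)
  n <- 4000
  ev <- make_events(CL = NA, CR = NA, dalpha = numeric(n))
  ev$x_mm <- runif(n, 40, 160); ev$y_mm <- runif(n, 40, 160)
  ev$heading_pre_deg <- runif(n, -180, 180)
  # plant the response at offset (forward 10, lateral 6)
  th <- ev$heading_pre_deg * pi / 180
  ux <- cos(th); uy <- sin(th)
  val_at <- function(fw, lt) {
    px <- ev$x_mm + fw * ux - lt * uy
    py <- ev$y_mm + fw * uy + lt * ux
    f$grid[cbind(floor(py) + 1, floor(px) + 1)]
  }
  L <- val_at(10, 6); R <- val_at(10, -6)
  pred <- ifelse(L + R > 0, (L - R) / (L + R), 0)
  ev$dalpha_deg <- 35 * pred + rnorm(n, 0, 10)
  cm <- correlation_map(ev, f, forward = seq(0, 20, 2),
                        lateral = seq(0, 12, 2), min_n = 200)
  best <- cm[which.max(cm$rho), ]
  expect_equal(best$forward, 10)
  expect_equal(best$lateral, 6)
  # shuffled angles: whole map within the family-wise permutation band
  set.seed(16)
  ev$dalpha_deg <- sample(ev$dalpha_deg)
  cm0 <- correlation_map(ev, f, forward = seq(0, 20, 2),
                         lateral = seq(0, 12, 2), min_n = 200,
                         permutations = 200)
  expect_lt(max(abs(cm0$rho), na.rm = TRUE), attr(cm0, "perm_band"))
  # lateral 0 pairs a pixel with itself: undefined
  expect_true(all(is.na(cm0$rho[cm0$lateral == 0])))
})

test_that("speed summaries are exact for constant speed and detect a
           planted speed-concentration coupling", {
  set.seed(17)
  n <- 6000
  sumC <- runif(n, 60, 600)
  ev <- make_events(CL = sumC / 2, CR = sumC / 2, dalpha = rnorm(n),
                    speed = 2)
  bands <- make_bands(ev, n_bands = 4, threshold = 60)
  sp <- speed_vs_pheromone(ev, bands)
  expect_equal(sp$median, rep(2, 4))
  # planted increasing speed
  ev2 <- ev
  ev2$speed_cms <- 1 + sumC / 300 + rnorm(n, 0, 0.05)
  sp2 <- speed_vs_pheromone(ev2, bands)
  expect_true(all(diff(sp2$median) > 0))
  # empty band flagged
  b0 <- data.frame(lo = 1e5, hi = 2e5, mid = 1.5e5)
  expect_equal(speed_vs_pheromone(ev, b0)$n, 0L)
})

test_that("turning autocorrelation matches the AR(1) closed form and
           vanishes for i.i.d. angles", {
  set.seed(18)
  phi <- 0.6
  n <- 4000
  a <- as.numeric(arima.sim(list(ar = phi), n, sd = 10))
  ev <- make_events(CL = 1, CR = 1, dalpha = a, t0 = seq_len(n) * 0.8)
  ac <- turning_autocorrelation(ev, max_lag = 4)
  expect_equal(ac$acf[1], phi, tolerance = 0.05)
  expect_equal(ac$acf[2], phi^2, tolerance = 0.06)
  iid <- make_events(CL = 1, CR = 1, dalpha = rnorm(n, 0, 35),
                     t0 = seq_len(n) * 0.8)
  ac0 <- turning_autocorrelation(iid, max_lag = 4)
  expect_true(all(abs(ac0$acf) < 4 / sqrt(ac0$n_pairs)))
  # gaps break pairs: lags with too few pairs are undefined
  few <- make_events(CL = 1, CR = 1, dalpha = rnorm(10),
                     t0 = seq_len(10) * 0.8)
  expect_true(all(is.na(turning_autocorrelation(few, max_lag = 2)$acf)))
})
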