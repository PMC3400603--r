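test_that("the Weber drift has the contrast form", {
  expect_equal(weber_drift(4, 4, 0.3), 0)
  expect_equal(weber_drift(7, 0, 0.3), 0.3)
  expect_equal(weber_drift(30, 10, 0.3), weber_drift(3, 1, 0.3))
  expect_error(weber_drift(0, 0, 0.3), "positive")
})

test_that("left_probability is a symmetric sigmoid with the documented
           limits", {
  cp <- choice_params(c = 0.5, n_steps = 25, sigma = 1, K = 10)
  expect_equal(left_probability(cp, 5, 5), 0.5)
  expect_equal(left_probability(cp, 3, 1) + left_probability(cp, 1, 3), 1)
  # monotone in the concentration difference
  p <- left_probability(cp, seq(0, 10, 0.5), 10 - seq(0, 10, 0.5))
  expect_true(all(diff(p) > 0))
  # strong drift saturates towards 1
  cps <- choice_params(c = 5, n_steps = 400, sigma = 0.5, K = 0)
  expect_gt(left_probability(cps, 1, 0), 1 - 1e-12)
  # an infinite threshold washes out the choice
  ck <- choice_params(c = 0.5, n_steps = 25, sigma = 1, K = 1e9)
  expect_equal(left_probability(ck, 100, 1), 0.5, tolerance = 1e-5)
  # K = 0 with zero concentrations is an error
  c0 <- choice_params(K = 0)
  expect_error(left_probability(c0, 0, 0), "positive")
})

test_that("the Monte-Carlo walk matches the closed form", {
  cp <- choice_params(c = 0.2, n_steps = 25, sigma = 1, K = 0)
  set.seed(30)
  m0 <- mc_walk_oracle(cp, 1, 1, 2e4)
  expect_equal(m0$p_left, 0.5, tolerance = 1e-12)  # antithetic symmetry
  # saturation under overwhelming drift
  cps <- choice_params(c = 10, n_steps = 1, sigma = 1, K = 0)
  expect_gt(mc_walk_oracle(cps, 1, 0, 2e4)$p_left, 0.999)
  # sweep: closed form within 3 (conservative) SEs of the oracle
  for (ctr in c(0.2, 0.6)) for (n in c(9, 49)) for (sg in c(0.5, 2)) {
    cpx <- choice_params(c = 0.2, n_steps = n, sigma = sg, K = 0)
    p <- left_probability(cpx, 1 + ctr, 1 - ctr)
    mc <- mc_walk_oracle(cpx, 1 + ctr, 1 - ctr, 2e4)
    expect_lt(abs(mc$p_left - p), 3 * pmax(mc$se, 1e-6))
  }
  # mean walker displacement is n * V (drift check at the walk level)
  cpm <- choice_params(c = 0.4, n_steps = 50, sigma = 1, K = 0)
  V <- weber_drift(3, 1, 0.4)
  p_mid <- left_probability(cpm, 3, 1)
  expect_equal(qnorm(p_mid) * cpm$sigma * sqrt(cpm$n_steps),
               cpm$n_steps * V, tolerance = 1e-9)
})

test_that("stationary states form mirror pairs summing to phi/r", {
  cp <- choice_params()
  expect_equal(stationary_states(bridge_model_params(0, 0.1, cp)),
               data.frame(C_L = 0, C_R = 0, x = 0.5))
  st <- stationary_states(bridge_model_params(3, 0.1, cp))
  expect_equal(nrow(st), 3)
  expect_equal(st$C_L + st$C_R, rep(30, 3))
  expect_equal(sort(st$x), sort(1 - st$x))  # L/R relabelling symmetry
  # below the critical flux only the symmetric root survives
  st0 <- stationary_states(bridge_model_params(0.5, 0.1, cp))
  expect_equal(nrow(st0), 1)
  expect_equal(st0$x, 0.5)
})

test_that("the bifurcation diagram shows a pitchfork with the closed-form
           critical flux", {
  cp <- choice_params()
  bp <- bridge_model_params(1, 0.1, cp)
  bd <- bifurcation_diagram(bp, seq(0.2, 4, length.out = 15))
  # bisected critical flux agrees with the independent linearisation
  expect_equal(bd$critical_phi, bd$critical_phi_closed_form,
               tolerance = 1e-6)
  pts <- bd$points
  below <- pts[pts$phi < bd$critical_phi, ]
  expect_true(all(below$x == 0.5 & below$stable))
  above <- pts[pts$phi > bd$critical_phi + 0.2, ]
  for (ph in unique(above$phi)) {
    s <- above[above$phi == ph, ]
    expect_equal(nrow(s), 3)
    expect_false(s$stable[s$x == 0.5])
    expect_true(all(s$stable[s$x != 0.5]))
    xs <- sort(s$x[s$x != 0.5])
    expect_equal(xs[1], 1 - xs[2], tolerance = 1e-6)
  }
})

test_that("stability flags agree with numerical integration", {
  skip_if_not_installed("deSolve")
  cp <- choice_params()
  for (phi in c(0.6, 2, 3.5)) {
    bp <- bridge_model_params(phi, 0.1, cp)
    st <- stationary_states(bp)
    total <- phi / 0.1
    rhs <- function(t, y, parms) {
      FL <- left_probability(cp, y[1], y[2])
      list(c(phi * FL - 0.1 * y[1], phi * (1 - FL) - 0.1 * y[2]))
    }
    # integrate from a slightly perturbed symmetric start
    y0 <- c(total / 2 * 1.02, total / 2 * 0.98)
    out <- deSolve::ode(y0, seq(0, 400, 5), rhs, NULL)
    xf <- out[nrow(out), 2] / (out[nrow(out), 2] + out[nrow(out), 3])
    stable_x <- st$x[vapply(seq_len(nrow(st)), function(i)
      stigmergy:::is_stable(bp, st$C_L[i], st$C_R[i]), logical(1))]
    expect_lt(min(abs(stable_x - xf)), 1e-3)
  }
})

test_that("the Deneubourg comparison curve is sigmoidal and proportional
           at a = 1", {
  expect_equal(deneubourg_choice(5, 5), 0.5)
  expect_equal(deneubourg_choice(3, 1, h = 0, a = 1), 0.75)
  expect_gt(deneubourg_choice(3, 1, h = 6, a = 2),
            deneubourg_choice(3, 1, h = 6, a = 1))
})
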