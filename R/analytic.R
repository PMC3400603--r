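#' Drift-diffusion choice model parameters
#'
#' Parameters of the biased random walk an ant performs on its way to the
#' branching point of a binary bridge: at each of `n_steps` steps the
#' lateral position drifts by `c * (C_L - C_R) / (C_L + C_R + K)` (positive
#' towards the left branch) plus Gaussian directional noise of SD `sigma`.
#' `K >= 0` softens the contrast at low total pheromone, capturing the
#' detection threshold: as concentrations fall well below `K` the choice
#' becomes random.
#'
#' @param c drift amplitude per step (dimensionless).
#' @param n_steps number of walk steps before the branching point.
#' @param sigma per-step directional SD.
#' @param K additive threshold constant in the contrast denominator.
#' @export
choice_params <- function(c = 0.5, n_steps = 25, sigma = 1, K = 10) {
  stopifnot(sigma > 0, n_steps >= 1, K >= 0)
  structure(list(c = c, n_steps = as.integer(n_steps), sigma = sigma,
                 K = K), class = "choice_params")
}

#' Weber drift per step
#'
#' The per-step drift implied by a proportional (Weber's-law) response:
#' `c * (C_L - C_R) / (C_L + C_R)`. Invariant under rescaling both
#' concentrations; errors on zero total concentration (use the thresholded
#' form in [left_probability()] instead).
#'
#' @param C_L,C_R pheromone concentrations on the two branches.
#' @param c drift amplitude per step.
#' @export
weber_drift <- function(C_L, C_R, c) {
  if (any(C_L + C_R <= 0))
    stop("C_L + C_R must be positive; use left_probability() with K > 0 ",
         "for zero concentrations")
  c * (C_L - C_R) / (C_L + C_R)
}

#' Probability of choosing the left branch
#'
#' Closed-form first-passage probability of the drift-diffusion walk: the
#' end position after `n` steps is Normal with mean `n * V` and SD
#' `sigma * sqrt(n)`, so the probability of arriving left of the branching
#' point is `0.5 * (1 + erf(sqrt(n) * V / (sqrt(2) * sigma)))` with
#' `V = c * (C_L - C_R) / (C_L + C_R + K)`. A sigmoidal function of the
#' concentration difference: proportional individual responses plus
#' directional noise yield a nonlinear collective choice. Satisfies
#' `P_L(C_L, C_R) + P_L(C_R, C_L) = 1` exactly.
#'
#' @param params a [choice_params()].
#' @param C_L,C_R branch concentrations (vectors recycle).
#' @export
left_probability <- function(params, C_L, C_R) {
  stopifnot(inherits(params, "choice_params"))
  den <- C_L + C_R + params$K
  if (any(den <= 0))
    stop("C_L + C_R + K must be positive (set K > 0 to regularize zero ",
         "concentrations)")
  V <- params$c * (C_L - C_R) / den
  pnorm(sqrt(params$n_steps) * V / params$sigma)
}

#' Monte-Carlo random-walk oracle for the branch choice
#'
#' Simulates the biased Gaussian walk (`x_0 = 0`,
#' `x_{t+1} = x_t + V + N(0, sigma)`; positive displacement = towards the
#' left branch) and returns the fraction of walkers finishing left of the
#' branching point with its binomial standard error. Walkers are simulated
#' in antithetic pairs (each noise path used with both signs), which keeps
#' the estimator unbiased while making the reported binomial SE a
#' conservative error bound. Used as the independent check of
#' [left_probability()].
#'
#' @param params a [choice_params()].
#' @param C_L,C_R branch concentrations.
#' @param n_walkers number of walkers (at least 1000).
#' @export
mc_walk_oracle <- function(params, C_L, C_R, n_walkers = 1e5) {
  stopifnot(inherits(params, "choice_params"), n_walkers >= 1e3)
  den <- C_L + C_R + params$K
  if (den <= 0) stop("C_L + C_R + K must be positive")
  V <- params$c * (C_L - C_R) / den
  p <- mc_walk_cpp(as.integer(n_walkers), params$n_steps, V, params$sigma)
  list(p_left = p, se = sqrt(max(p * (1 - p), 1 / n_walkers) / n_walkers))
}

#' Two-branch flux model parameters
#'
#' The branch concentrations evolve as
#' `dC_L/dt = phi * F_L(C_L, C_R) - r * C_L` (and symmetrically for R),
#' where `phi` is the total flux of ants per unit time, `F_L` the left
#' choice probability from [left_probability()], and `r` the spontaneous
#' retirement rate of pheromone-marked traffic from each branch.
#'
#' @param phi total flux of individuals per unit time.
#' @param retire_rate retirement rate (positive).
#' @param choice a [choice_params()].
#' @export
bridge_model_params <- function(phi, retire_rate = 0.1,
                                choice = choice_params()) {
  stopifnot(phi >= 0, retire_rate > 0)
  structure(list(phi = phi, retire_rate = retire_rate, choice = choice),
            class = "bridge_model_params")
}

branch_rhs <- function(params, C) {
  FL <- left_probability(params$choice, C[1], C[2])
  c(params$phi * FL - params$retire_rate * C[1],
    params$phi * (1 - FL) - params$retire_rate * C[2])
}

#' Stationary states of the two-branch model
#'
#' At stationarity `F_L + F_R = 1` forces the total `C_L + C_R =
#' phi / retire_rate`; the stationary `C_L` values are roots of
#' `C_L = (phi / r) * F_L(C_L, total - C_L)`, found by a sign-change scan
#' over a fine grid followed by bisection. The symmetric root
#' `C_L = total / 2` always exists and is included analytically; asymmetric
#' roots come in mirror pairs.
#'
#' @param params a [bridge_model_params()].
#' @param grid_points scan resolution.
#' @param tol relative bisection tolerance.
#' @return A data frame `C_L, C_R, x` (`x = C_L / total`), one row per
#'   stationary state, sorted by `x`.
#' @export
stationary_states <- function(params, grid_points = 1e4, tol = 1e-10) {
  stopifnot(inherits(params, "bridge_model_params"))
  total <- params$phi / params$retire_rate
  if (total == 0)
    return(data.frame(C_L = 0, C_R = 0, x = 0.5))
  g <- function(cl)
    cl - total * left_probability(params$choice, cl, total - cl)
  grid <- seq(0, total, length.out = grid_points + 1)
  gv <- g(grid)
  roots <- total / 2
  sign_change <- which(gv[-length(gv)] * gv[-1] < 0)
  for (i in sign_change) {
    r <- uniroot(g, c(grid[i], grid[i + 1]),
                 tol = tol * max(total, 1))$root
    if (all(abs(r - roots) > 1e-6 * max(total, 1)))
      roots <- c(roots, r)
  }
  exact0 <- setdiff(which(gv == 0), c())
  for (i in exact0) {
    r <- grid[i]
    if (all(abs(r - roots) > 1e-6 * max(total, 1)))
      roots <- c(roots, r)
  }
  roots <- sort(roots)
  data.frame(C_L = roots, C_R = total - roots, x = roots / total)
}

# Jacobian of the two-branch dynamics at (C_L, C_R), by central finite
# differences of F_L (F_R = 1 - F_L).
branch_jacobian <- function(params, C_L, C_R) {
  h <- 1e-6 * max(1, C_L + C_R)
  dFL_dL <- (left_probability(params$choice, C_L + h, C_R) -
               left_probability(params$choice, C_L - h, C_R)) / (2 * h)
  dFL_dR <- (left_probability(params$choice, C_L, C_R + h) -
               left_probability(params$choice, C_L, C_R - h)) / (2 * h)
  phi <- params$phi; r <- params$retire_rate
  matrix(c(phi * dFL_dL - r, phi * dFL_dR,
           -phi * dFL_dL, -phi * dFL_dR - r), 2, 2, byrow = TRUE)
}

is_stable <- function(params, C_L, C_R) {
  ev <- eigen(branch_jacobian(params, C_L, C_R), only.values = TRUE)$values
  all(Re(ev) < 0)
}

#' Bifurcation diagram of the two-branch model
#'
#' Stationary states and their linear stability (sign of the real parts of
#' the Jacobian eigenvalues) across a grid of total fluxes. The diagram is
#' a pitchfork: below a critical flux the symmetric state is the only
#' (stable) one; above it the symmetric state is unstable and two stable
#' mirror-image asymmetric states appear. `critical_phi` is refined by
#' bisection on the stability of the symmetric state; the closed form
#' `K * retire_rate / (c * sqrt(2 * n / pi) / sigma - 1)` (from linearising the
#' choice function at the symmetric state) is reported alongside as
#' `critical_phi_closed_form`.
#'
#' @param params a [bridge_model_params()] (its `phi` is ignored).
#' @param phi_grid increasing vector of fluxes.
#' @param grid_points scan resolution per flux.
#' @return A `bifurcation_result` list: `points` (data frame `phi, C_L,
#'   C_R, x, stable`), `critical_phi`, `critical_phi_closed_form`.
#' @export
bifurcation_diagram <- function(params, phi_grid, grid_points = 2000) {
  stopifnot(all(diff(phi_grid) > 0))
  pts <- lapply(phi_grid, function(phi) {
    p <- bridge_model_params(phi, params$retire_rate, params$choice)
    st <- tryCatch(stationary_states(p, grid_points = grid_points),
                   error = function(e) NULL)
    if (is.null(st))
      return(data.frame(phi = phi, C_L = NA, C_R = NA, x = NA,
                        stable = NA))
    st$phi <- phi
    st$stable <- vapply(seq_len(nrow(st)), function(i)
      is_stable(p, st$C_L[i], st$C_R[i]), logical(1))
    st[, c("phi", "C_L", "C_R", "x", "stable")]
  })
  points <- do.call(rbind, pts)
  sym_unstable <- function(phi) {
    p <- bridge_model_params(phi, params$retire_rate, params$choice)
    total <- phi / params$retire_rate
    !is_stable(p, total / 2, total / 2)
  }
  crit <- critical_phi_bisect(sym_unstable, phi_grid)
  structure(list(points = points, critical_phi = crit,
                 critical_phi_closed_form =
                   critical_flux_closed_form(params)),
            class = "bifurcation_result")
}

critical_phi_bisect <- function(sym_unstable, phi_grid, iters = 60) {
  un <- vapply(phi_grid, sym_unstable, logical(1))
  if (!any(un)) return(NA_real_)
  if (all(un)) return(phi_grid[1])
  hi <- phi_grid[which(un)[1]]
  lo <- phi_grid[max(which(!un[seq_len(which(un)[1])]))]
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (sym_unstable(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' @rdname bifurcation_diagram
#' @export
critical_flux_closed_form <- function(params) {
  ch <- params$choice
  slope <- ch$c * sqrt(2 * ch$n_steps / pi) / ch$sigma
  if (slope <= 1) return(NA_real_)
  params$retire_rate * ch$K / (slope - 1)
}

#' @export
print.bifurcation_result <- function(x, ...) {
  cat(sprintf(
    "<bifurcation_result> %d flux values, critical phi = %.4g (closed form %.4g)\n",
    length(unique(x$points$phi)), x$critical_phi,
    x$critical_phi_closed_form))
  invisible(x)
}

#' Deneubourg binary choice function
#'
#' The classical sigmoidal choice probability
#' `(h + L)^a / ((h + L)^a + (h + R)^a)` used in double-bridge models,
#' provided as a comparison curve for the erf choice of
#' [left_probability()] (not fitted to data).
#'
#' @param L,R branch pheromone concentrations.
#' @param h threshold constant.
#' @param a nonlinearity exponent (2 in the classical trail model; 1 is
#'   the proportional case).
#' @export
deneubourg_choice <- function(L, R, h = 6, a = 2) {
  (h + L)^a / ((h + L)^a + (h + R)^a)
}
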