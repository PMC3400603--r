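#' Logarithmic total-pheromone bands
#'
#' Six (by default) logarithmically spaced bands of total pheromone
#' `sumC = CL + CR` between the detection threshold and the 99th percentile
#' of the annotated events, used to stratify the turning-angle regression.
#'
#' @param events annotated `tracking_events`.
#' @param n_bands number of bands.
#' @param threshold lower edge (pheromone units); below it the turning
#'   response is expected to be pure noise.
#' @param upper upper edge; default the 99th percentile of `sumC`.
#' @return A data frame with columns `lo`, `hi` and `mid` (geometric mean of
#'   the edges).
#' @export
make_bands <- function(events, n_bands = 6, threshold = 50, upper = NULL) {
  sumC <- events$CL + events$CR
  if (is.null(upper)) upper <- as.numeric(quantile(sumC, 0.99, na.rm = TRUE))
  if (!is.finite(upper) || upper <= threshold)
    stop("not enough events above the detection threshold to form bands")
  edges <- exp(seq(log(threshold), log(upper), length.out = n_bands + 1))
  data.frame(lo = edges[-length(edges)], hi = edges[-1],
             mid = sqrt(edges[-length(edges)] * edges[-1]))
}

#' Per-band linear turning response
#'
#' Within each band of total pheromone, fits the turning angle against the
#' left-right pheromone difference through the origin,
#' `dalpha = k * (CL - CR)`, by ordinary least squares on the unbinned
#' events (the no-intercept form is forced by the left/right antisymmetry of
#' the response). 95% confidence intervals come from a nonparametric
#' bootstrap over events. Binned means/SDs of `dalpha` in 20-unit `CL - CR`
#' intervals are attached (attribute `"binned"`) for plotting only.
#'
#' @param events annotated `tracking_events`.
#' @param bands band table from [make_bands()]; built from `n_bands` and
#'   `threshold` when `NULL`.
#' @param n_bands,threshold passed to [make_bands()] when `bands` is `NULL`.
#' @param min_n minimum events per band; below it the slope is reported
#'   undefined (`NA`) and flagged.
#' @param n_boot bootstrap resamples for the CIs.
#' @param ci_level confidence level of the per-band bootstrap intervals.
#' @param bin_width width of the plotting bins in pheromone units.
#' @return A `band_slopes` data frame: `lo, hi, mid, k, ci_lo, ci_hi, n,
#'   resid_sd, defined`.
#' @export
band_slope_fit <- function(events, bands = NULL, n_bands = 6, threshold = 50,
                           min_n = 200, n_boot = 1000, ci_level = 0.95,
                           bin_width = 20) {
  ev <- events[is.finite(events$CL) & is.finite(events$CR), , drop = FALSE]
  if (is.null(bands)) bands <- make_bands(ev, n_bands, threshold)
  sumC <- ev$CL + ev$CR
  dC <- ev$CL - ev$CR
  da <- ev$dalpha_deg
  binned_all <- list()
  res <- lapply(seq_len(nrow(bands)), function(b) {
    inb <- sumC >= bands$lo[b] & sumC < bands$hi[b]
    n <- sum(inb)
    if (n < min_n || sum(dC[inb]^2) == 0)
      return(data.frame(lo = bands$lo[b], hi = bands$hi[b],
                        mid = bands$mid[b], k = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, n = n, resid_sd = NA_real_,
                        defined = FALSE))
    x <- dC[inb]; yv <- da[inb]
    k <- sum(x * yv) / sum(x^2)
    r <- yv - k * x
    ks <- origin_slope_boot(x, yv, n_boot, ci_level)
    binned_all[[b]] <<- bin_dalpha(x, yv, bin_width, band = b)
    data.frame(lo = bands$lo[b], hi = bands$hi[b], mid = bands$mid[b],
               k = k, ci_lo = ks[1], ci_hi = ks[2], n = n,
               resid_sd = sd(r), defined = TRUE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, binned = do.call(rbind, binned_all),
            class = c("band_slopes", "data.frame"))
}

origin_slope_boot <- function(x, y, n_boot, ci_level = 0.95) {
  if (n_boot <= 0) return(c(NA_real_, NA_real_))
  ks <- boot_origin_slope_cpp(x, y, as.integer(n_boot))
  a <- (1 - ci_level) / 2
  as.numeric(quantile(ks, c(a, 1 - a), na.rm = TRUE))
}

bin_dalpha <- function(dC, da, width, band) {
  br <- seq(floor(min(dC) / width) * width,
            ceiling(max(dC) / width) * width + width, by = width)
  g <- cut(dC, br, include.lowest = TRUE)
  mids <- (br[-length(br)] + br[-1]) / 2
  n <- as.integer(table(g))
  data.frame(band = band, dC_mid = mids, n = n,
             mean = as.numeric(tapply(da, g, mean)),
             sd = as.numeric(tapply(da, g, sd)))
}

#' Power-law relation between band slope and total pheromone
#'
#' Fits `log k = log A + nu * log sumC` by non-weighted linear least squares
#' of the log-transformed band slopes against the geometric band midpoints,
#' restricted to bands with midpoint at least `min_sumC` (the detection
#' threshold; below it the slope-concentration curve bends down). A slope
#' exponent `nu = -1` is the Weber's-law case, where the turning angle
#' depends only on the contrast `(CL - CR) / (CL + CR)`.
#'
#' @param slopes a `band_slopes` table from [band_slope_fit()].
#' @param min_sumC restrict to bands with geometric midpoint `>= min_sumC`.
#' @return A `powerlaw_fit` list: `A`, `nu`, their 95% CIs, `n_bands`, and
#'   the underlying `lm` fit.
#' @export
powerlaw_fit <- function(slopes, min_sumC = 50) {
  use <- slopes$defined & slopes$mid >= min_sumC
  if (any(use & !is.na(slopes$k) & slopes$k <= 0)) {
    warning("excluding band(s) with non-positive slope from the log-log fit")
    use <- use & slopes$k > 0
  }
  if (sum(use) < 3)
    stop("need at least 3 bands with defined positive slopes above min_sumC")
  fit <- lm(log(k) ~ log(mid), data = slopes[use, ])
  ci <- suppressMessages(confint(fit))
  structure(list(A = exp(coef(fit)[[1]]), nu = coef(fit)[[2]],
                 A_ci = exp(ci[1, ]), nu_ci = ci[2, ],
                 n_bands = sum(use), fit = fit),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law slope-concentration fit over %d bands:\n  k = A * sumC^nu, A = %.3g [%.3g, %.3g], nu = %.3f [%.3f, %.3f]\n",
    x$n_bands, x$A, x$A_ci[1], x$A_ci[2], x$nu, x$nu_ci[1], x$nu_ci[2]))
  invisible(x)
}

#' Direct Weber's-law fit of the turning response
#'
#' Least-squares fit of `dalpha = A * (CL - CR) / (CL + CR)` over events
#' with total pheromone at or above the detection threshold `C0`. With `C0`
#' fixed the amplitude has the closed form
#' `A = sum(x * dalpha) / sum(x^2)` with `x` the Michelson contrast; with
#' `profile = TRUE` the threshold is profiled over a grid, scoring each
#' candidate by the residual sum of squares over *all* events (events below
#' the candidate threshold are predicted to turn 0 on average). The fit is
#' invariant under rescaling all concentrations (and `C0`) by a common
#' factor.
#'
#' @param events annotated `tracking_events`.
#' @param C0 detection threshold in pheromone units (fixed unless profiled).
#' @param profile profile `C0` over `C0_grid` instead of fixing it.
#' @param C0_grid candidate thresholds; default 40 points over the 0-90%
#'   quantile range of `sumC`.
#' @param n_boot bootstrap resamples for the 95% CI of `A`.
#' @return A `weber_fit` list: `A`, `C0`, `ci95`, `resid_sd`, `n`, `method`.
#' @export
direct_weber_fit <- function(events, C0 = 50, profile = FALSE,
                             C0_grid = NULL, n_boot = 1000) {
  ev <- events[is.finite(events$CL) & is.finite(events$CR), , drop = FALSE]
  sumC <- ev$CL + ev$CR
  da <- ev$dalpha_deg
  fit_at <- function(c0) {
    above <- sumC >= c0 & sumC > 0
    if (!any(above)) return(NULL)
    x <- (ev$CL[above] - ev$CR[above]) / sumC[above]
    if (sum(x^2) == 0) return(NULL)
    A <- sum(x * da[above]) / sum(x^2)
    rss <- sum((da[above] - A * x)^2) + sum(da[!above]^2)
    list(A = A, rss = rss, above = above, x = x)
  }
  if (profile) {
    if (is.null(C0_grid))
      C0_grid <- quantile(sumC[sumC > 0], seq(0.02, 0.9, length.out = 40))
    cand <- lapply(C0_grid, fit_at)
    ok <- !vapply(cand, is.null, logical(1))
    if (!any(ok)) stop("no events above any candidate threshold")
    rss <- vapply(cand[ok], `[[`, numeric(1), "rss")
    C0 <- as.numeric(C0_grid[ok][which.min(rss)])
    method <- "direct-profiled"
  } else method <- "direct"
  f <- fit_at(C0)
  if (is.null(f)) stop("no events above the detection threshold")
  resid <- da[f$above] - f$A * f$x
  ci <- origin_slope_boot(f$x, da[f$above], n_boot)
  structure(list(A = f$A, C0 = C0, ci95 = ci, resid_sd = sd(resid),
                 n = sum(f$above), method = method),
            class = "weber_fit")
}

#' @export
print.weber_fit <- function(x, ...) {
  cat(sprintf(
    "Weber turning response (%s): dalpha = A * (CL - CR)/(CL + CR)\n  A = %.2f deg [%.2f, %.2f], C0 = %.3g units, resid SD = %.1f deg, n = %d\n",
    x$method, x$A, x$ci95[1], x$ci95[2], x$C0, x$resid_sd, x$n))
  invisible(x)
}

#' Pixel-pair correlation map of the turning response
#'
#' For each offset `(forward, lateral)` in the ant-centred frame (forward
#' along the pre-segment heading, lateral positive to the left), the probe
#' pixel and its mirror image across the heading axis give a predicted
#' turning angle `(C(p_left) - C(p_right)) / (C(p_left) + C(p_right))` per
#' event; the map reports the Pearson correlation of that prediction with
#' the observed turning angles. Events whose pair has zero total pheromone
#' (or falls off-grid) are skipped for that offset; offsets with fewer than
#' `min_n` valid events are flagged undefined.
#'
#' @param events annotated `tracking_events`.
#' @param field a static [pheromone_field()] or a [field_replayer()].
#' @param forward,lateral offset grids in mm (lateral `>= 0`; the mirror
#'   pair supplies the other side).
#' @param lag look-back in seconds (replayer only).
#' @param min_n minimum valid events per offset.
#' @param permutations if positive, also computes a family-wise null band:
#'   the turning angles are shuffled across events this many times, the
#'   maximum `|rho|` over the map is recorded per shuffle, and its
#'   `perm_quantile` quantile is attached as attribute `"perm_band"` (a map
#'   entirely within the band is consistent with no pheromone response
#'   anywhere).
#' @param perm_quantile quantile of the permuted max-`|rho|` distribution
#'   used for the band.
#' @return A `correlation_map` data frame: `forward, lateral, rho, n`.
#' @export
correlation_map <- function(events, field, forward = seq(-16, 24, by = 2),
                            lateral = seq(0, 20, by = 2), lag = 16,
                            min_n = 50, permutations = 0,
                            perm_quantile = 0.95) {
  grid <- expand.grid(forward = forward, lateral = lateral)
  if (inherits(field, "pheromone_field")) {
    vals <- static_offsets(events, field, grid)
    da <- events$dalpha_deg
  } else if (inherits(field, "field_replayer")) {
    keep <- events$t0_s - lag >= -1e-9
    events <- events[keep, , drop = FALSE]
    ord <- order(events$t0_s)
    st <- field$stream
    vv <- replay_offsets_cpp(
      st$t, st$cell, st$dq, field$dim_rc[1], field$dim_rc[2],
      field$cell_size, field$origin[1], field$origin[2], field$half_life,
      events$x_mm[ord], events$y_mm[ord], events$heading_pre_deg[ord],
      events$t0_s[ord] - lag, grid$forward, grid$lateral)
    vals <- list(left = vv$left, right = vv$right)
    da <- events$dalpha_deg[ord]
  } else stop("`field` must be a pheromone_field or a field_replayer")
  rho <- n_ok <- numeric(nrow(grid))
  preds <- vector("list", nrow(grid))
  oks <- vector("list", nrow(grid))
  for (o in seq_len(nrow(grid))) {
    L <- vals$left[, o]; R <- vals$right[, o]
    tot <- L + R
    ok <- is.finite(tot) & tot > 0
    n_ok[o] <- sum(ok)
    pred <- (L[ok] - R[ok]) / tot[ok]
    defined <- n_ok[o] >= min_n && sd(pred) > 0 && sd(da[ok]) > 0
    rho[o] <- if (defined) cor(pred, da[ok]) else NA_real_
    if (defined && permutations > 0) {
      preds[[o]] <- pred
      oks[[o]] <- which(ok)
    }
  }
  out <- structure(data.frame(forward = grid$forward,
                              lateral = grid$lateral, rho = rho, n = n_ok),
                   class = c("correlation_map", "data.frame"))
  if (permutations > 0) {
    defined_o <- which(!vapply(preds, is.null, logical(1)))
    max_perm <- vapply(seq_len(permutations), function(b) {
      da_p <- sample(da)
      max(vapply(defined_o, function(o)
        abs(cor(preds[[o]], da_p[oks[[o]]])), numeric(1)))
    }, numeric(1))
    attr(out, "perm_band") <- as.numeric(quantile(max_perm, perm_quantile))
    attr(out, "perm_quantile") <- perm_quantile
  }
  out
}

static_offsets <- function(events, field, grid) {
  th <- deg2rad(events$heading_pre_deg)
  ux <- cos(th); uy <- sin(th)
  n <- nrow(events); m <- nrow(grid)
  L <- R <- matrix(NA_real_, n, m)
  nr <- nrow(field$grid); nc <- ncol(field$grid)
  for (o in seq_len(m)) {
    for (sgn in c(1, -1)) {
      lx <- -uy * sgn * grid$lateral[o]
      ly <- ux * sgn * grid$lateral[o]
      px <- events$x_mm + grid$forward[o] * ux + lx
      py <- events$y_mm + grid$forward[o] * uy + ly
      j <- floor((px - field$origin[1]) / field$cell_size) + 1
      i <- floor((py - field$origin[2]) / field$cell_size) + 1
      ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
      v <- rep(NA_real_, n)
      v[ok] <- field$grid[cbind(i[ok], j[ok])]
      if (sgn > 0) L[, o] <- v else R[, o] <- v
    }
  }
  list(left = L, right = R)
}

#' Speed as a function of total pheromone
#'
#' Box-plot statistics (median, quartiles, whiskers at 1.5 IQR, outlier
#' count) of event speed per band of total pheromone, for moving events
#' (apply [filter_events()] first).
#'
#' @param events annotated `tracking_events`.
#' @param bands band table from [make_bands()]; built with defaults when
#'   `NULL`. Use `threshold = 0` bands to include unmarked ground.
#' @inheritParams band_slope_fit
#' @return A data frame of per-band box statistics; empty bands are flagged
#'   with `n = 0` and `NA` statistics.
#' @export
speed_vs_pheromone <- function(events, bands = NULL, n_bands = 6,
                               threshold = 50) {
  ev <- events[is.finite(events$CL) & is.finite(events$CR), , drop = FALSE]
  if (is.null(bands)) bands <- make_bands(ev, n_bands, threshold)
  sumC <- ev$CL + ev$CR
  res <- lapply(seq_len(nrow(bands)), function(b) {
    sp <- ev$speed_cms[sumC >= bands$lo[b] & sumC < bands$hi[b]]
    if (length(sp) == 0)
      return(data.frame(lo = bands$lo[b], hi = bands$hi[b], n = 0L,
                        median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                        whisker_lo = NA_real_, whisker_hi = NA_real_,
                        n_outliers = NA_integer_))
    bs <- boxplot.stats(sp)
    data.frame(lo = bands$lo[b], hi = bands$hi[b], n = length(sp),
               median = bs$stats[3], q1 = bs$stats[2], q3 = bs$stats[4],
               whisker_lo = bs$stats[1], whisker_hi = bs$stats[5],
               n_outliers = length(bs$out))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Turning-angle autocorrelation
#'
#' Lagged Pearson autocorrelation of the turning angle within each ant's
#' ordered event sequence, pooled over ants. Pairs are formed only between
#' events separated by exactly `k` cadence intervals; lags with fewer than
#' `min_pairs` pairs are reported undefined.
#'
#' @param events `tracking_events` (annotated or not).
#' @param max_lag maximum lag in seconds.
#' @param cadence event cadence in seconds (0.8 s by default).
#' @param min_pairs minimum pooled pairs per lag.
#' @return A data frame `lag_s, acf, n_pairs`.
#' @export
turning_autocorrelation <- function(events, max_lag = 8, cadence = 0.8,
                                    min_pairs = 30) {
  lags <- seq_len(floor(max_lag / cadence))
  by_ant <- split(events[, c("t0_s", "dalpha_deg")], events$ant_id)
  res <- lapply(lags, function(k) {
    xs <- ys <- list()
    for (tr in by_ant) {
      tr <- tr[order(tr$t0_s), ]
      n <- nrow(tr)
      if (n <= k) next
      i <- seq_len(n - k)
      ok <- abs(tr$t0_s[i + k] - tr$t0_s[i] - k * cadence) < 0.02
      xs[[length(xs) + 1]] <- tr$dalpha_deg[i][ok]
      ys[[length(ys) + 1]] <- tr$dalpha_deg[i + k][ok]
    }
    x <- unlist(xs); y <- unlist(ys)
    data.frame(lag_s = k * cadence,
               acf = if (length(x) >= min_pairs) cor(x, y) else NA_real_,
               n_pairs = length(x))
  })
  do.call(rbind, res)
}
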