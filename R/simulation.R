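## Simulation from a (fitted or specified) model: state sequences, tracks,
## utilisation distributions, and the parameter-recovery harness.

#' Simulate a latent state sequence
#'
#' Draws the Markov chain from the covariate-dependent transition matrices:
#' the initial state comes from the stationary distribution of the first
#' matrix, subsequent states from the rows of successive matrices.
#'
#' @param tm a `transition_model`.
#' @param times `POSIXct` step start times (length = number of steps), used
#'   to build the transition covariates.
#' @param seed RNG seed.
#' @return Integer state vector, one per step.
#' @export
simulate_states <- function(tm, times, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(times)
  omega <- transition_omega(times, tm$covariates)
  G <- transition_matrix(tm, omega)
  s <- integer(n)
  s[1] <- sample.int(tm$K, 1, prob = stationary_distribution(G[, , 1]))
  for (t in seq_len(n - 1))
    s[t + 1] <- sample.int(tm$K, 1, prob = G[s[t], , t + 1])
  s
}

#' Simulate a track from a state-switching step selection model
#'
#' First simulates the state sequence from the transition model (time
#' covariates advance by `interval`), then, at each step, proposes
#' `n_proposals` endpoints uniformly on the disc of radius `r` about the
#' current location, weights each by `exp(c . beta)` under the current
#' state's coefficients (weight 0 outside the study-area boundary or on
#' missing cells — a reflective-by-rejection boundary), and samples the next
#' location proportionally to the weights. The first step omits the
#' turning-angle covariate (no previous bearing). The first `burn_in`
#' locations are discarded to remove dependence on the starting conditions.
#'
#' @param model an `hmmssf_model` whose coefficient columns match
#'   `formula` on `land`.
#' @param land a `landscape`.
#' @param formula the [ssf_formula()] whose columns match `model$beta`.
#' @param n_steps number of steps to simulate (before burn-in removal).
#' @param interval sampling interval in seconds.
#' @param start numeric `c(x, y)` start location; default uniform over the
#'   boundary (rejection-sampled onto valid cells).
#' @param start_time `POSIXct` time of the first location.
#' @param n_proposals proposed endpoints per step (default 10000; bias
#'   shrinks as coverage of the disc improves).
#' @param r proposal disc radius; defaults to `mu_L + 5 * sigma_L` of the
#'   fastest state, covering the vast majority of kernel mass.
#' @param burn_in locations discarded from the front (default 1000).
#' @param seed RNG seed.
#' @param id individual id label for the returned track.
#' @return A list with `track` (a `track`), `states` (generating state per
#'   retained step) and `r` (the disc radius used).
#' @export
simulate_track <- function(model, land, formula, n_steps,
                           interval = 1800, start = NULL,
                           start_time = as.POSIXct("2020-01-01 00:00:00",
                                                   tz = "UTC"),
                           n_proposals = 10000, r = NULL, burn_in = 1000,
                           seed = NULL, id = "sim1") {
  stopifnot(inherits(model, "hmmssf_model"), inherits(land, "landscape"),
            n_proposals >= 1, burn_in < n_steps)
  if (!is.null(seed)) set.seed(as.integer(seed))
  mp <- movement_params(model)
  if (is.null(r)) {
    if (!any(mp$gamma_valid))
      stop("cannot choose a disc radius: no state has a valid gamma ",
           "step-length distribution; supply r")
    r <- max(mp$mu_L + 5 * mp$sigma_L, na.rm = TRUE)
  }
  stopifnot(r > 0)
  bnd <- land$boundary
  times <- start_time + (seq_len(n_steps + 1) - 1) * interval
  states <- simulate_states(model$transitions, times[seq_len(n_steps)])

  if (is.null(start)) {
    repeat {
      start <- c(stats::runif(1, bnd[1], bnd[2]),
                 stats::runif(1, bnd[3], bnd[4]))
      if (extract_covariates(land, start[1], start[2])$valid) break
    }
  }
  x <- numeric(n_steps + 1); y <- numeric(n_steps + 1)
  x[1] <- start[1]; y[1] <- start[2]
  prev_bearing <- NA_real_
  cols <- design_colnames(land, formula)
  if (!identical(cols, colnames(model$beta)) &&
      length(cols) != ncol(model$beta))
    stop("model coefficients do not match the formula/landscape columns")
  for (s in seq_len(n_steps)) {
    rr <- r * sqrt(stats::runif(n_proposals))
    aa <- stats::runif(n_proposals, -pi, pi)
    px <- x[s] + rr * cos(aa)
    py <- y[s] + rr * sin(aa)
    first <- is.na(prev_bearing)
    th <- if (first) rep(0, n_proposals) else wrap_angle(aa - prev_bearing)
    cm <- covariate_matrix(land, formula, px, py, rr, th,
                           drop_theta = first)
    lw <- as.numeric(cm$X %*% model$beta[states[s], ])
    lw[!cm$valid | rr <= 0] <- -Inf
    lw[px < bnd[1] | px > bnd[2] | py < bnd[3] | py > bnd[4]] <- -Inf
    if (all(!is.finite(lw)))
      stop("boundary starvation at step ", s, ", location (",
           signif(x[s], 6), ", ", signif(y[s], 6),
           "): all proposal weights are zero")
    w <- exp(lw - max(lw[is.finite(lw)]))
    pick <- sample.int(n_proposals, 1, prob = w)
    x[s + 1] <- px[pick]; y[s + 1] <- py[pick]
    prev_bearing <- atan2(y[s + 1] - y[s], x[s + 1] - x[s])
  }
  keep <- (burn_in + 1):(n_steps + 1)
  tr <- track(id, times[keep], x[keep], y[keep])
  list(track = tr, states = states[keep[-length(keep)]], r = r)
}

#' Estimate a utilisation distribution by kernel density smoothing
#'
#' Bins locations on the landscape lattice and convolves with an isotropic
#' Gaussian kernel of standard deviation `bandwidth` (map units), then
#' renormalises so the density integrates to 1 over the grid. Optionally
#' restricts to the endpoints of steps in one state (behaviour-specific
#' space use).
#'
#' @param sims a result of [simulate_track()], a list of such results, a
#'   `track`/list of tracks, or a data frame with columns `x`, `y` (and
#'   optionally `state`).
#' @param bandwidth Gaussian kernel standard deviation in map units.
#' @param land a `landscape` supplying the evaluation lattice.
#' @param state optional state index: keep only locations reached by steps
#'   simulated/decoded in that state.
#' @return An object of class `ud_grid`: a `covariate_layer` of densities
#'   plus the bandwidth.
#' @export
estimate_ud <- function(sims, bandwidth, land, state = NULL) {
  stopifnot(inherits(land, "landscape"), bandwidth > 0)
  pts <- ud_points(sims)
  if (!is.null(state)) {
    if (is.null(pts$state)) stop("no state information to filter on")
    pts <- pts[!is.na(pts$state) & pts$state == state, ]
  }
  if (!nrow(pts)) stop("no locations selected for the utilisation distribution")
  if (nrow(pts) < 100)
    warning("utilisation distribution estimated from only ", nrow(pts),
            " locations")
  res <- land$resolution
  ext <- land$extent
  any_layer <- land$layers[[1]]
  nr <- nrow(any_layer$values); nc <- ncol(any_layer$values)
  ci <- cell_index(any_layer, pts$x, pts$y)
  ok <- ci$inside
  counts <- matrix(0, nr, nc)
  tab <- table(factor((ci$col[ok] - 1) * nr + ci$row[ok],
                      levels = seq_len(nr * nc)))
  counts[] <- as.numeric(tab)
  # separable Gaussian blur, zero padding (mass near edges is truncated,
  # hence the final renormalisation over the grid)
  sigma <- bandwidth / res
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  blur1 <- function(v) {
    vp <- c(rep(0, half), v, rep(0, half))
    as.numeric(stats::filter(vp, k, sides = 2))[half + seq_along(v)]
  }
  dens <- apply(counts, 2, blur1)
  dens <- t(apply(dens, 1, blur1))
  dens[dens < 0] <- 0
  dens <- dens / (sum(dens) * res^2)
  layer <- covariate_layer(dens, ext, "ud", "continuous")
  structure(list(layer = layer, bandwidth = bandwidth, n = nrow(pts)),
            class = "ud_grid")
}

#' @export
print.ud_grid <- function(x, ...) {
  cat(sprintf("<ud_grid> bandwidth %g, %d locations, %d x %d cells\n",
              x$bandwidth, x$n, nrow(x$layer$values), ncol(x$layer$values)))
  invisible(x)
}

#' Write a utilisation distribution as an ESRI ASCII grid
#'
#' @param ud a `ud_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ud <- function(ud, path) write_raster(ud$layer, path)

# normalise the many accepted input shapes to data.frame(x, y, state?)
ud_points <- function(sims) {
  if (is.data.frame(sims)) {
    stopifnot(all(c("x", "y") %in% names(sims)))
    return(sims)
  }
  if (inherits(sims, "track"))
    return(data.frame(x = sims$x[sims$observed], y = sims$y[sims$observed]))
  if (is.list(sims) && !is.null(sims$track)) sims <- list(sims)
  parts <- lapply(sims, function(s) {
    if (inherits(s, "track"))
      return(data.frame(x = s$x[s$observed], y = s$y[s$observed],
                        state = NA_integer_))
    tr <- s$track
    # location t+1 is the endpoint of step t and inherits its state
    data.frame(x = tr$x[-1], y = tr$y[-1], state = s$states)
  })
  do.call(rbind, parts)
}

#' Parameter-recovery simulation study
#'
#' Simulate-then-fit loop: for each replicate, simulates a track from the
#' true model on the supplied landscape, rebuilds the case-control design
#' with fresh controls, refits, and compares estimates with truth. Reports
#' per-parameter mean error, root-mean-square error and 95% CI coverage.
#' Replicates use sub-seeds derived deterministically from `seed`, so
#' results are independent of execution order; fit failures are counted and
#' reported, not fatal.
#'
#' @param model true `hmmssf_model` (states are relabelled slow-first to
#'   match the fitting convention).
#' @param land a `landscape`.
#' @param formula the [ssf_formula()] matching the model columns.
#' @param n_steps steps per simulated track (default 1000).
#' @param n_replicates number of replicates (default 50).
#' @param seed master seed.
#' @param N controls per step for the refit.
#' @param n_starts starting values per refit (the truth-adjacent moment
#'   start makes 1-2 usually sufficient here).
#' @param n_proposals proposal endpoints per simulated step.
#' @param interval sampling interval (seconds).
#' @param burn_in simulated locations discarded per track.
#' @return A list with `table` (per-parameter summary), `estimates`
#'   (replicate x parameter matrix), `truth`, and `n_failed`.
#' @export
recovery_study <- function(model, land, formula, n_steps = 1000,
                           n_replicates = 50, seed = 1, N = 25,
                           n_starts = 2, n_proposals = 10000,
                           interval = 1800, burn_in = 100) {
  model <- order_states(model)$model
  truth <- c(as.numeric(t(model$beta)), as.numeric(model$transitions$alpha))
  est <- se <- matrix(NA_real_, n_replicates, length(truth))
  n_failed <- 0L
  nm <- NULL
  for (rep_i in seq_len(n_replicates)) {
    sub_seed <- (as.integer(seed) + 7919L * rep_i) %% .Machine$integer.max
    res <- tryCatch({
      sim <- simulate_track(model, land, formula, n_steps = n_steps,
                            interval = interval,
                            n_proposals = n_proposals, burn_in = burn_in,
                            seed = sub_seed, id = paste0("rep", rep_i))
      ss <- sample_controls(sim$track, N = N, seed = sub_seed + 1L)
      des <- build_design(ss, land, formula)
      fit_hmmssf(des, K = model$K,
                 transition_covariates = model$transitions$covariates,
                 n_starts = n_starts, seed = sub_seed + 2L)
    }, error = function(e) e)
    if (inherits(res, "error")) { n_failed <- n_failed + 1L; next }
    est[rep_i, ] <- res$par
    se[rep_i, ] <- res$se
    if (is.null(nm)) nm <- names(res$par)
  }
  if (is.null(nm)) stop("all ", n_replicates, " replicates failed")
  ok <- !is.na(est[, 1])
  err <- sweep(est[ok, , drop = FALSE], 2, truth)
  lo <- est[ok, , drop = FALSE] - 1.96 * se[ok, , drop = FALSE]
  hi <- est[ok, , drop = FALSE] + 1.96 * se[ok, , drop = FALSE]
  cover <- sweep(lo, 2, truth, "<=") & sweep(hi, 2, truth, ">=")
  table <- data.frame(parameter = nm, truth = truth,
                      mean_error = colMeans(err),
                      rmse = sqrt(colMeans(err^2)),
                      coverage = colMeans(cover),
                      n_ok = sum(ok))
  colnames(est) <- nm
  list(table = table, estimates = est, truth = truth, n_failed = n_failed)
}
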