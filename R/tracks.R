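#' Telemetry tracks on a regular time grid
#'
#' A `track` holds an ordered series of locations for one individual at a
#' strictly regular sampling interval. Gaps in the original data are kept as
#' rows with `observed = FALSE` so that step indices stay aligned with the
#' time grid (the likelihood treats such steps as missing, contributing an
#' identity matrix).
#'
#' @param id individual identifier.
#' @param times `POSIXct` timestamps, equally spaced.
#' @param x,y coordinates in projected planar map units (`NA` allowed when
#'   unobserved).
#' @param observed logical; defaults to `!is.na(x) & !is.na(y)`.
#' @return An object of class `track`.
#' @export
track <- function(id, times, x, y, observed = NULL) {
  stopifnot(length(times) == length(x), length(x) == length(y))
  if (is.null(observed)) observed <- !is.na(x) & !is.na(y)
  if (length(times) >= 2) {
    d <- diff(as.numeric(times))
    if (any(d <= 0)) stop("timestamps must be strictly increasing")
    if (max(abs(d - d[1])) > 1e-6 * d[1])
      stop("timestamps not on a regular grid; use read_tracks() to regularise")
  }
  structure(list(id = as.character(id), times = times,
                 x = as.numeric(x), y = as.numeric(y),
                 observed = as.logical(observed)),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track '%s'> T = %d (%d observed), interval %s\n",
              x$id, length(x$times), sum(x$observed),
              if (length(x$times) > 1)
                format(diff(x$times[1:2])) else "NA"))
  invisible(x)
}

#' Read telemetry tracks from CSV
#'
#' Expects columns `id`, `time` (ISO-8601), `x`, `y`. Each individual's series
#' is snapped to a regular grid of spacing `interval` anchored at its first
#' fix; rows are inserted with `observed = FALSE` wherever a grid time has no
#' fix. Timestamps further than `tol` (a fraction of the interval, default
#' 10%) from the nearest grid time are an error, as are duplicate grid times.
#'
#' @param path CSV file path.
#' @param interval sampling interval in seconds (or a `difftime`).
#' @param tol snapping tolerance as a fraction of `interval`.
#' @param tz timezone for parsing timestamps.
#' @return A list of `track` objects, one per individual.
#' @export
read_tracks <- function(path, interval, tol = 0.1, tz = "UTC") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "time", "x", "y")
  if (!all(need %in% names(df)))
    stop("track file must have columns: ", paste(need, collapse = ", "))
  df$time <- as.POSIXct(df$time, tz = tz,
                        tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                       "%Y-%m-%d %H:%M:%OS",
                                       "%Y-%m-%d %H:%M",
                                       "%Y-%m-%d"))
  if (anyNA(df$time)) stop("unparseable timestamps in ", path)
  dt <- as.numeric(interval, units = "secs")
  lapply(split(df, df$id), function(d) {
    d <- d[order(d$time), ]
    t0 <- as.numeric(d$time[1])
    k <- (as.numeric(d$time) - t0) / dt
    off <- abs(k - round(k))
    if (any(off > tol))
      stop("individual '", d$id[1], "': ", sum(off > tol),
           " timestamp(s) not resolvable to the ", dt, "s grid (tolerance ",
           tol, " of interval)")
    k <- as.integer(round(k))
    if (anyDuplicated(k))
      stop("individual '", d$id[1], "': duplicate timestamps on the grid")
    grid <- seq(0L, max(k))
    xg <- rep(NA_real_, length(grid)); yg <- xg
    xg[k + 1L] <- d$x; yg[k + 1L] <- d$y
    track(d$id[1],
          as.POSIXct(t0 + grid * dt, tz = tz, origin = "1970-01-01"),
          xg, yg)
  })
}

#' Write tracks to CSV
#'
#' Same dialect as [read_tracks()]: columns `id`, `time`, `x`, `y`; missing
#' locations are written with empty coordinates.
#'
#' @param tracks a `track` or list of tracks.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "track")) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(id = tr$id,
               time = format(tr$times, "%Y-%m-%dT%H:%M:%S"),
               x = tr$x, y = tr$y)))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Step geometry: lengths, bearings and turning angles
#'
#' Step `t` runs from location `t` to `t + 1`; its turning angle is the
#' signed change in bearing relative to the previous step
#' (counter-clockwise positive, in `(-pi, pi]`). The first step of a track
#' has no previous bearing, so its turning angle is `NA` and the step is not
#' `usable` when the model includes the turning-angle covariate. A step is
#' `usable` only if its start, end and the previous location are all
#' observed.
#'
#' @param tr a `track`.
#' @return A `data.frame` with one row per step: `step` (index), `t0`
#'   (start time), `x0, y0, x1, y1`, `L` (Euclidean length), `bearing`,
#'   `theta` (turning angle), `usable`.
#' @export
step_metrics <- function(tr) {
  stopifnot(inherits(tr, "track"))
  T_ <- length(tr$x)
  if (T_ < 2) stop("track must have at least 2 locations")
  i <- seq_len(T_ - 1)
  dx <- tr$x[i + 1] - tr$x[i]
  dy <- tr$y[i + 1] - tr$y[i]
  L <- sqrt(dx^2 + dy^2)
  bearing <- atan2(dy, dx)
  theta <- c(NA_real_, wrap_angle(diff(bearing)))
  ends_ok <- tr$observed[i] & tr$observed[i + 1]
  prev_ok <- c(FALSE, tr$observed[i[-length(i)]])
  usable <- ends_ok & prev_ok
  bad <- which(ends_ok & L == 0)
  if (length(bad))
    stop("zero-length step(s) at index ", paste(utils::head(bad, 5), collapse = ", "),
         ": log step length undefined. Jitter coordinates (see jitter_track()) ",
         "or remove the duplicated fixes.")
  data.frame(step = i, t0 = tr$times[i],
             x0 = tr$x[i], y0 = tr$y[i],
             x1 = tr$x[i + 1], y1 = tr$y[i + 1],
             L = L, bearing = bearing, theta = theta,
             usable = usable)
}

# wrap angles to (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

#' Jitter duplicated fixes to remove zero-length steps
#'
#' Zero step lengths make `log(L)` undefined under the gamma parameterisation
#' and silently dropping them would bias the step-length model; the default
#' behaviour of [step_metrics()] is therefore a hard error. This opt-in helper
#' displaces every location uniformly within a disc of radius `radius`.
#'
#' @param tr a `track`.
#' @param radius jitter radius in map units.
#' @param seed RNG seed.
#' @return The jittered `track`.
#' @export
jitter_track <- function(tr, radius, seed = NULL) {
  stopifnot(inherits(tr, "track"), radius > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(tr$x)
  r <- radius * sqrt(stats::runif(n))
  a <- stats::runif(n, -pi, pi)
  tr$x <- tr$x + r * cos(a)
  tr$y <- tr$y + r * sin(a)
  tr
}

#' Write a step table to CSV
#'
#' One row per step with geometry and usability flags, in the layout
#' produced by [step_metrics()].
#'
#' @param tracks a `track` or list of tracks.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_steps <- function(tracks, path) {
  if (inherits(tracks, "track")) tracks <- list(tracks)
  tabs <- lapply(tracks, function(tr) {
    m <- step_metrics(tr)
    cbind(id = tr$id, m)
  })
  out <- do.call(rbind, tabs)
  out$t0 <- format(out$t0, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Cyclic time-of-day covariates
#'
#' Maps the hour of day `tau` to the pair `(cos(2*pi*tau/24),
#' sin(2*pi*tau/24))`, the standard cyclic expansion for diel effects on
#' state-transition probabilities.
#'
#' @param times `POSIXct` timestamps, or numeric hours of day.
#' @return A matrix with columns `tod_cos` and `tod_sin`.
#' @export
cyclic_time_covariates <- function(times) {
  tau <- if (inherits(times, "POSIXct")) {
    lt <- as.POSIXlt(times)
    lt$hour + lt$min / 60 + lt$sec / 3600
  } else as.numeric(times)
  cbind(tod_cos = cos(2 * pi * tau / 24),
        tod_sin = sin(2 * pi * tau / 24))
}
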